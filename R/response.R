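#' Therapy-response classification
#'
#' Four schemes classify each patient into complete response (CR), partial
#' response (PR), stable disease (SD) or progressive disease (PD) from the
#' relative change `ratio_pct = follow_up / baseline * 100`:
#'
#' * **BR** (biochemical response, serum PSA): PR if ratio <= 50, PD if
#'   ratio >= 125, SD strictly between. CR is reserved for PSA falling to
#'   undetectable under therapy. Patients whose disease never expressed PSA
#'   (flagged `psa_negative`) are not classifiable and get NA.
#' * **PERCIST** (hottest-lesion SUVmax): PR if ratio <= 70, PD if
#'   ratio >= 130 *or* a new lesion appeared (the new lesion forces PD
#'   regardless of ratio), SD strictly between; CR when follow-up shows no
#'   malignant uptake.
#' * **PSMA_TV / TL_PSMA** (whole-body volume biomarkers): same 70/130
#'   cutoffs; CR when follow-up burden is zero; NA when the ratio is
#'   undefined (e.g. unusable baseline scan).
#'
#' Boundary semantics are inclusive on the PR and PD sides (<=, >=) and
#' strict for SD, so every defined ratio maps to exactly one category.
#'
#' @name response-classification
NULL

response_row <- function(patient_id, scheme, category, ratio_pct = NA_real_,
                         new_lesion = NA, psa_negative = NA,
                         pd_by_new_lesion_only = NA) {
  data.frame(patient_id = patient_id, scheme = scheme, category = category,
             ratio_pct = ratio_pct, new_lesion = new_lesion,
             psa_negative = psa_negative,
             pd_by_new_lesion_only = pd_by_new_lesion_only,
             stringsAsFactors = FALSE)
}

# interval partition shared by all schemes: PR <= pr_max < SD < pd_min <= PD
classify_ratio <- function(ratio, pr_max, pd_min) {
  if (is.na(ratio)) return(NA_character_)
  if (ratio <= pr_max) "PR" else if (ratio >= pd_min) "PD" else "SD"
}

#' Biochemical response from serum PSA
#'
#' @param psa_baseline,psa_follow_up serum PSA (ng/mL) at the two
#'   timepoints.
#' @param psa_negative logical; `TRUE` for PSA-negative disease (PSA never
#'   reflected tumour burden) — classification is withheld (NA).
#' @param patient_id carried through.
#' @return One-row assessment data frame (see [response-classification]).
#' @export
classify_br <- function(psa_baseline, psa_follow_up, psa_negative = FALSE,
                        patient_id = NA_character_) {
  if (isTRUE(psa_negative))
    return(response_row(patient_id, "BR", NA_character_,
                        psa_negative = TRUE))
  if (is.na(psa_baseline) || is.na(psa_follow_up))
    stop("missing PSA without the psa_negative flag")
  rc <- relative_change(psa_baseline, psa_follow_up, "PSA")
  cat_ <- if (!is.na(psa_follow_up) && psa_follow_up == 0 && psa_baseline > 0)
    "CR" else classify_ratio(rc$ratio_pct, 50, 125)
  response_row(patient_id, "BR", cat_, rc$ratio_pct, psa_negative = FALSE)
}

#' PERCIST-style response from the hottest lesion's SUVmax
#'
#' The hottest lesion is determined independently at each timepoint
#' (regardless of how many lesions there are); a new lesion at follow-up
#' forces PD whatever the SUVmax ratio.
#'
#' @param suvmax_baseline,suvmax_follow_up hottest-lesion SUVmax at each
#'   timepoint; NA / 0 at follow-up means no malignant uptake.
#' @param new_lesion logical new-lesion flag (expert reading; not computed).
#' @param patient_id carried through.
#' @return One-row assessment data frame. `pd_by_new_lesion_only` is TRUE
#'   when PD was driven by the new lesion while the SUVmax ratio alone would
#'   not have reached 130%.
#' @export
classify_percist <- function(suvmax_baseline, suvmax_follow_up,
                             new_lesion = FALSE,
                             patient_id = NA_character_) {
  ratio <- if (!is.na(suvmax_baseline) && suvmax_baseline > 0 &&
               !is.na(suvmax_follow_up))
    suvmax_follow_up / suvmax_baseline * 100 else NA_real_
  no_uptake <- is.na(suvmax_follow_up) || suvmax_follow_up == 0
  if (isTRUE(new_lesion)) {
    pd_only <- is.na(ratio) || ratio < 130
    return(response_row(patient_id, "PERCIST", "PD", ratio,
                        new_lesion = TRUE,
                        pd_by_new_lesion_only = pd_only))
  }
  if (no_uptake && !is.na(suvmax_baseline))
    return(response_row(patient_id, "PERCIST", "CR", ratio,
                        new_lesion = FALSE, pd_by_new_lesion_only = FALSE))
  cat_ <- classify_ratio(ratio, 70, 130)
  response_row(patient_id, "PERCIST", cat_, ratio, new_lesion = FALSE,
               pd_by_new_lesion_only = FALSE)
}

#' Response from whole-body volume biomarkers
#'
#' @param scheme `"PSMA_TV"` or `"TL_PSMA"`.
#' @param baseline,follow_up biomarker values at the two timepoints; or pass
#'   a [relative_change] object as `change`.
#' @param change optional [relative_change]; overrides baseline/follow_up.
#' @param patient_id carried through.
#' @return One-row assessment data frame.
#' @export
classify_volume <- function(scheme = c("PSMA_TV", "TL_PSMA"),
                            baseline = NA_real_, follow_up = NA_real_,
                            change = NULL, patient_id = NA_character_) {
  scheme <- match.arg(scheme)
  if (is.null(change)) change <- relative_change(baseline, follow_up, scheme)
  cat_ <- if (!is.na(change$follow_up) && change$follow_up == 0 &&
              !is.na(change$baseline) && change$baseline > 0)
    "CR" else classify_ratio(change$ratio_pct, 70, 130)
  response_row(patient_id, scheme, cat_, change$ratio_pct)
}

#' Cross-tabulate response schemes
#'
#' Counts categories per scheme and, for every pair of schemes, the number
#' of patients whose categories disagree and the number of *relevant*
#' disagreements — one scheme calling PD while the other does not, the
#' discrepancies that change clinical management. Patients with NA in either
#' scheme of a pair are excluded from that pair only (pairwise, not
#' listwise).
#'
#' @param assessments data frame with columns `patient_id`, `scheme`,
#'   `category` (stackable rows from the `classify_*` functions).
#' @return List of class `agreement_matrix`: `counts` (scheme x category
#'   table), `pairwise` (data frame `scheme_a`, `scheme_b`, `n_compared`,
#'   `n_disagree`, `n_relevant`), `new_lesion_counts` (when
#'   PERCIST rows carry flags: patients with any new lesion, and those PD by
#'   new lesion only).
#' @export
cross_tabulate <- function(assessments) {
  stopifnot(nrow(assessments) >= 1)
  schemes <- unique(assessments$scheme)
  counts <- table(scheme = assessments$scheme,
                  category = factor(assessments$category,
                                    levels = c("CR", "PR", "SD", "PD")),
                  useNA = "no")
  wide <- stats::reshape(
    assessments[, c("patient_id", "scheme", "category")],
    idvar = "patient_id", timevar = "scheme", direction = "wide")
  names(wide) <- sub("^category\\.", "", names(wide))
  pw <- NULL
  if (length(schemes) >= 2) {
    cmb <- utils::combn(schemes, 2)
    pw <- do.call(rbind, lapply(seq_len(ncol(cmb)), function(i) {
      a <- wide[[cmb[1, i]]]; b <- wide[[cmb[2, i]]]
      ok <- !is.na(a) & !is.na(b)
      dis <- ok & a != b
      rel <- dis & xor(a == "PD", b == "PD")
      data.frame(scheme_a = cmb[1, i], scheme_b = cmb[2, i],
                 n_compared = sum(ok), n_disagree = sum(dis),
                 n_relevant = sum(rel))
    }))
  }
  nl <- NULL
  pc <- assessments[assessments$scheme == "PERCIST", , drop = FALSE]
  if (nrow(pc) && "new_lesion" %in% names(pc)) {
    nl <- list(any_new_lesion = sum(pc$new_lesion %in% TRUE),
               pd_by_new_lesion_only =
                 sum(pc$pd_by_new_lesion_only %in% TRUE))
  }
  structure(list(counts = counts, pairwise = pw, by_patient = wide,
                 new_lesion_counts = nl),
            class = "agreement_matrix")
}

#' @export
print.agreement_matrix <- function(x, ...) {
  cat("<agreement_matrix>\n")
  print(x$counts)
  if (!is.null(x$pairwise)) {
    cat("\npairwise disagreements (relevant = PD vs non-PD):\n")
    print(x$pairwise, row.names = FALSE)
  }
  if (!is.null(x$new_lesion_counts))
    cat(sprintf("\nnew lesions: %d patients (%d rated PD by new lesion only)\n",
                x$new_lesion_counts$any_new_lesion,
                x$new_lesion_counts$pd_by_new_lesion_only))
  invisible(x)
}
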