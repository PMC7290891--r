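#' Aggregate lesions into whole-body tumour-burden biomarkers
#'
#' PSMA-TV is the sum of the segmented lesion volumes (cm^3); TL-PSMA sums
#' each lesion's volume times its SUVmean (dimensionally volume x SUV;
#' conventionally reported in cm^3 since SUV is dimensionless). With no
#' lesions both are zero and the hottest-lesion SUVmax is undefined.
#'
#' @param lesions data frame from [segment_lesions()] (columns `volume_cm3`,
#'   `suv_mean`, `suv_max` are used).
#' @param patient_id,timepoint study annotations.
#' @param psa_ng_ml optional serum PSA at the same timepoint.
#' @return One-row data frame: `patient_id`, `timepoint`, `n_lesions`,
#'   `psma_tv_cm3`, `tl_psma`, `hottest_suv_max`, `psa_ng_ml`.
#' @export
aggregate_study <- function(lesions, patient_id = NA_character_,
                            timepoint = NA_character_, psa_ng_ml = NA_real_) {
  n <- nrow(lesions)
  data.frame(
    patient_id = patient_id,
    timepoint = timepoint,
    n_lesions = n,
    psma_tv_cm3 = if (n) sum(lesions$volume_cm3) else 0,
    tl_psma = if (n) sum(lesions$volume_cm3 * lesions$suv_mean) else 0,
    hottest_suv_max = if (n) max(lesions$suv_max) else NA_real_,
    psa_ng_ml = psa_ng_ml
  )
}

#' Relative change between timepoints
#'
#' Follow-up value as a percentage of baseline:
#' `ratio_pct = follow_up / baseline * 100`. The ratio is undefined
#' (`defined = FALSE`) when the baseline is zero or either value is missing;
#' downstream classification maps undefined ratios to NA. The signed change
#' often quoted in clinic is `ratio_pct - 100`.
#'
#' @param baseline,follow_up non-negative values (NA allowed).
#' @param quantity optional label carried through.
#' @return A list of class `relative_change`: `quantity`, `baseline`,
#'   `follow_up`, `ratio_pct`, `delta_pct`, `defined`.
#' @export
relative_change <- function(baseline, follow_up, quantity = NA_character_) {
  if ((!is.na(baseline) && baseline < 0) ||
      (!is.na(follow_up) && follow_up < 0))
    stop("values must be non-negative")
  defined <- !is.na(baseline) && !is.na(follow_up) && baseline > 0
  ratio <- if (defined) follow_up / baseline * 100 else NA_real_
  structure(list(quantity = quantity, baseline = baseline,
                 follow_up = follow_up, ratio_pct = ratio,
                 delta_pct = if (defined) ratio - 100 else NA_real_,
                 defined = defined),
            class = "relative_change")
}
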