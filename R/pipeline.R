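#' Run the full study on tabular biomarker data
#'
#' Orchestrates the downstream half of the pipeline once per-study
#' biomarkers exist (from [run_study_imaging()] or supplied directly, e.g.
#' re-analysing printed values): relative changes, response classification
#' under all four schemes, cross-scheme agreement, and — when two methods
#' measured the same biomarker — Bland-Altman agreement per biomarker per
#' timepoint.
#'
#' Patients with unusable inputs propagate NA (with a warning) rather than
#' aborting the run: a PSA-negative patient gets no BR category, a patient
#' without a usable baseline gets no volume-scheme category.
#'
#' @param studies data frame with one row per patient x timepoint x method:
#'   columns `patient_id`, `timepoint` (`"baseline"`/`"follow_up"`),
#'   `method`, `psma_tv_cm3`, `tl_psma`, and optionally `hottest_suv_max`.
#' @param clinical data frame with one row per patient: `patient_id`,
#'   `psa_baseline`, `psa_followup`, `psa_negative`, `new_lesion`.
#' @param convention relative-difference convention for [bland_altman()].
#' @param out_dir optional directory; when given, writes `studies.csv`,
#'   `response.csv`, `agreement.json` and `summary.json` there.
#' @return List of class `study_report`: `studies`, `response` (one row per
#'   patient x scheme x method), `cross_tab` (per method), `agreement`
#'   (list of [bland_altman] results keyed `<quantity>_<timepoint>`).
#' @export
run_study <- function(studies, clinical, convention = "pair_mean",
                      out_dir = NULL) {
  need <- c("patient_id", "timepoint", "method", "psma_tv_cm3", "tl_psma")
  if (!all(need %in% names(studies)))
    stop("`studies` lacks columns: ",
         paste(setdiff(need, names(studies)), collapse = ", "))
  if (!"hottest_suv_max" %in% names(studies))
    studies$hottest_suv_max <- NA_real_
  methods <- sort(unique(studies$method))
  patients <- unique(clinical$patient_id)

  get_val <- function(pid, m, tp, col) {
    r <- studies[studies$patient_id == pid & studies$method == m &
                 studies$timepoint == tp, col]
    if (length(r) == 0) NA_real_ else r[[1]]
  }

  response <- list()
  for (pid in patients) {
    cl <- clinical[clinical$patient_id == pid, ]
    br <- classify_br(cl$psa_baseline, cl$psa_followup,
                      isTRUE(cl$psa_negative), patient_id = pid)
    br$method <- NA_character_
    response[[length(response) + 1L]] <- br
    for (m in methods) {
      pc <- classify_percist(get_val(pid, m, "baseline", "hottest_suv_max"),
                             get_val(pid, m, "follow_up", "hottest_suv_max"),
                             isTRUE(cl$new_lesion), patient_id = pid)
      tv <- classify_volume("PSMA_TV",
                            get_val(pid, m, "baseline", "psma_tv_cm3"),
                            get_val(pid, m, "follow_up", "psma_tv_cm3"),
                            patient_id = pid)
      tl <- classify_volume("TL_PSMA",
                            get_val(pid, m, "baseline", "tl_psma"),
                            get_val(pid, m, "follow_up", "tl_psma"),
                            patient_id = pid)
      for (x in list(pc, tv, tl)) {
        x$method <- m
        response[[length(response) + 1L]] <- x
      }
      if (is.na(tv$category))
        warning("patient ", pid, " (", m,
                "): volume ratio undefined, NA propagated")
    }
  }
  response <- do.call(rbind, response)

  cross_tab <- lapply(stats::setNames(methods, methods), function(m) {
    keep <- is.na(response$method) | response$method == m
    cross_tabulate(response[keep, , drop = FALSE])
  })

  agreement <- list()
  if (length(methods) == 2) {
    for (tp in c("baseline", "follow_up")) {
      for (col in c("psma_tv_cm3", "tl_psma")) {
        a <- vapply(patients, get_val, numeric(1), m = methods[1],
                    tp = tp, col = col)
        b <- vapply(patients, get_val, numeric(1), m = methods[2],
                    tp = tp, col = col)
        ok <- !is.na(a) & !is.na(b) & (a + b) > 0
        if (sum(ok) >= 2)
          agreement[[paste(col, tp, sep = "_")]] <-
            bland_altman(a[ok], b[ok], convention = convention)
      }
    }
  }

  report <- structure(list(studies = studies, response = response,
                           cross_tab = cross_tab, agreement = agreement),
                      class = "study_report")
  if (!is.null(out_dir)) write_study_report(report, out_dir)
  report
}

write_study_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$studies, file.path(out_dir, "studies.csv"),
                   row.names = FALSE)
  utils::write.csv(report$response, file.path(out_dir, "response.csv"),
                   row.names = FALSE)
  agr <- lapply(report$agreement, function(x)
    list(n_pairs = x$n_pairs, bias_pct = x$bias_pct, sd_pct = x$sd_pct,
         loa_low = x$loa_low, loa_high = x$loa_high, rc_pct = x$rc_pct,
         n_outliers = sum(x$table$outlier)))
  jsonlite::write_json(agr, file.path(out_dir, "agreement.json"),
                       auto_unbox = TRUE, digits = NA)
  summ <- lapply(report$cross_tab, function(ct) list(
    counts = as.data.frame(ct$counts), pairwise = ct$pairwise,
    new_lesion_counts = ct$new_lesion_counts))
  jsonlite::write_json(summ, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Run the study from SUV volumes
#'
#' Imaging front end: for each scan, derives the segmentation threshold from
#' the requested reference region, segments lesions, aggregates them into
#' whole-body biomarkers, and hands the resulting table to [run_study()] —
#' so tabular and imaging entry points share all downstream code and yield
#' identical classifications for identical biomarker numbers.
#'
#' @param scans list of scan descriptors, each a list with `patient_id`,
#'   `timepoint`, `method`, `volume` (an [suv_volume] or a NIfTI path),
#'   `reference` (`"liver"` or `"aorta"`), `ref_center_mm`, and optionally
#'   `exclude` (logical array) and `min_voxels`.
#' @param clinical as in [run_study()].
#' @param ... passed to [run_study()].
#' @return A `study_report`; its `studies` element carries the derived
#'   biomarkers plus the threshold used per scan.
#' @export
run_study_imaging <- function(scans, clinical, ...) {
  rows <- lapply(scans, function(sc) {
    vol <- sc$volume
    if (is.character(vol))
      vol <- read_volume(vol, patient_id = sc$patient_id,
                         timepoint = sc$timepoint)
    ref <- switch(match.arg(sc$reference, c("liver", "aorta")),
                  liver = liver_reference(vol, sc$ref_center_mm),
                  aorta = aorta_reference(vol, sc$ref_center_mm))
    les <- segment_lesions(vol, ref$threshold_suv,
                           exclude = sc$exclude,
                           min_voxels = if (is.null(sc$min_voxels)) 1L
                                        else sc$min_voxels)
    q <- aggregate_study(les, patient_id = sc$patient_id,
                         timepoint = sc$timepoint)
    q$method <- sc$method
    q$threshold_suv <- ref$threshold_suv
    q
  })
  run_study(do.call(rbind, rows), clinical, ...)
}

#' One-command synthetic demonstration study
#'
#' Generates a small synthetic cohort end to end: per patient, paired
#' baseline/follow-up phantoms with lesions whose volumes shrink or grow
#' under "therapy" are segmented via the liver-derived threshold (method A);
#' a second software's readings (method B) are emulated by perturbing method
#' A's biomarkers with Gaussian relative differences, the same model used by
#' [generate_paired_measurements()]. Serum PSA is synthesized to track
#' tumour-volume change. The result exercises every stage: segmentation,
#' biomarkers, response classification, cross-tabulation and Bland-Altman
#' agreement.
#'
#' @param n_patients patients to simulate (default 3, kept small: each needs
#'   four phantom segmentations).
#' @param seed RNG seed; the full report is deterministic given the seed.
#' @param out_dir optional output directory, as in [run_study()].
#' @return A `study_report`.
#' @export
demo_study <- function(n_patients = 3, seed = 1L, out_dir = NULL) {
  scen <- with_seed(seed, {
    list(growth = stats::runif(n_patients, 0.4, 2.2),
         rd = stats::rnorm(4 * n_patients, 0, 15),
         psa0 = stats::rlnorm(n_patients, log(20), 0.8))
  })
  rows <- list(); k <- 0L
  for (i in seq_len(n_patients)) {
    pid <- sprintf("SYN%02d", i)
    r0 <- 10 + 2 * i
    for (tp in c("baseline", "follow_up")) {
      r <- if (tp == "baseline") r0 else r0 * scen$growth[i]^(1 / 3)
      spec <- phantom_spec(
        grid_shape = c(40, 40, 40), voxel_size_mm = 4, background_suv = 0.5,
        liver_center_mm = c(48, 48, 80), liver_radius_mm = 30,
        liver_mean_suv = 5, liver_sd_suv = 0.4,
        lesions = list(
          lesion_spec(c(112, 112, 60), "sphere", r, peak_suv = 12),
          lesion_spec(c(112, 48, 110), "sphere", 0.8 * r, peak_suv = 9)),
        psf_sigma_mm = 2, noise_sd = 0.1,
        seed = seed + 13L * i + (tp == "follow_up"))
      ph <- generate_phantom(spec)
      vol <- ph$volume; vol$patient_id <- pid; vol$timepoint <- tp
      ref <- liver_reference(vol, c(48, 48, 80))
      les <- segment_lesions(vol, ref$threshold_suv)
      q <- aggregate_study(les, patient_id = pid, timepoint = tp)
      q$method <- "A"
      rows[[length(rows) + 1L]] <- q
      # emulate a second software tool: same scan, relative-difference noise
      k <- k + 1L
      d <- scen$rd[k] / 200
      qb <- q
      qb$method <- "B"
      qb$psma_tv_cm3 <- q$psma_tv_cm3 * (1 - d) / (1 + d)
      k <- k + 1L
      d <- scen$rd[k] / 200
      qb$tl_psma <- q$tl_psma * (1 - d) / (1 + d)
      rows[[length(rows) + 1L]] <- qb
    }
  }
  studies <- do.call(rbind, rows)
  tv0 <- studies$psma_tv_cm3[studies$method == "A" &
                             studies$timepoint == "baseline"]
  tv1 <- studies$psma_tv_cm3[studies$method == "A" &
                             studies$timepoint == "follow_up"]
  clinical <- data.frame(
    patient_id = sprintf("SYN%02d", seq_len(n_patients)),
    psa_baseline = scen$psa0,
    psa_followup = scen$psa0 * tv1 / tv0,
    psa_negative = FALSE, new_lesion = FALSE)
  run_study(studies, clinical, out_dir = out_dir)
}
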