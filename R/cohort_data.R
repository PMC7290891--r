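#' Bundled cohort response classifications
#'
#' Published per-patient therapy-response classifications of a 21-patient
#' castration-resistant prostate cancer cohort under taxane chemotherapy,
#' each patient assessed by PERCIST, biochemical response (BR) and the
#' volume biomarkers ΔPSMA-TV / ΔTL-PSMA computed with two software tools
#' (method A: commercial workstation; method B: open-source plugin). Two
#' patients had PSA-negative disease (no BR classification); one patient's
#' baseline scan was unusable (tracer extravasation), so the volume ratios
#' are missing while a new lesion still allowed PERCIST classification.
#'
#' @return Data frame with columns `patient_id`, `percist`, `new_lesion`,
#'   `br`, `psa_negative`, `dpsma_tv_a`, `dtl_psma_a`, `dpsma_tv_b`,
#'   `dtl_psma_b`. Category columns hold `"CR"/"PR"/"SD"/"PD"` or NA.
#' @export
cohort_classifications <- function() {
  path <- system.file("extdata", "cohort_classifications.csv",
                      package = "petburden", mustWork = TRUE)
  utils::read.csv(path, na.strings = "", stringsAsFactors = FALSE)
}

#' Bundled disagreement worked examples
#'
#' The six patients of the same cohort with a clinically relevant
#' disagreement between biochemical response and ΔPSMA-TV (one scheme PD,
#' the other not), with their printed signed relative changes
#' (`delta_pct = ratio_pct - 100`) and overall survival. The survival
#' columns are pass-through metadata, not modelled.
#'
#' @return Data frame with columns `patient_id`, `br`, `dpsma_tv`,
#'   `delta_psa_pct`, `delta_psma_tv_pct`, `os_days`, `death`.
#' @export
disagreement_cases <- function() {
  path <- system.file("extdata", "disagreement_cases.csv",
                      package = "petburden", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
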