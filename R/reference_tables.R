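#' Reference per-patient comparison tables
#'
#' Per-patient maximum and mean stress/strain values from a 20-patient
#' multilayer vs single-layer coronary plaque comparison study (systolic
#' inflation of OCT-derived thin-slice models), bundled as plain CSV. These
#' are the inputs for the pure-arithmetic summary pipeline: feeding a table
#' through [summarize_comparison_table()] and [paired_t()] reproduces its
#' published cohort Mean, SD, relative-difference and significance entries.
#'
#' @param region `"plaque"` (lumen inner wall), `"cap"` or `"outwall"`.
#' @param measure `"stress"` (kPa) or `"strain"` (dimensionless).
#' @return data frame with columns `patient`, `multi_max`, `single_max`,
#'   `diff_max_pct`, `multi_mean`, `single_mean`, `diff_mean_pct`.
#' @export
reference_comparison_table <- function(region = c("plaque", "cap", "outwall"),
                                       measure = c("stress", "strain")) {
  region <- match.arg(region)
  measure <- match.arg(measure)
  path <- system.file("extdata", "reference_tables",
                      paste0(region, "_", measure, ".csv"),
                      package = "vesselfem", mustWork = TRUE)
  utils::read.csv(path)
}
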