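#' Published KHPS reference tables
#'
#' Small reference tables transcribed from the published dual-trajectory
#' analysis of the KHPS older-adult cohort (n = 3983, 8 annual waves),
#' bundled as plain CSV under `inst/extdata`. They serve as fixed inputs for
#' arithmetic checks (recomputing printed shares and percentages from counts,
#' re-running model selection on the printed criteria grid); they are not
#' outputs of this package.
#'
#' @param which one of `"fit_criteria"` (goodness-of-fit grid: channel, J,
#'   trajectory-convention BIC and AIC), `"baseline_depression"` (baseline
#'   characteristic counts by depression trajectory group, including the
#'   anxiety-group cross-tabulation), `"baseline_anxiety"` (selected counts
#'   by anxiety trajectory group).
#' @return data.frame.
#' @export
khps_reference_table <- function(which = c("fit_criteria",
                                           "baseline_depression",
                                           "baseline_anxiety")) {
  which <- match.arg(which)
  path <- system.file("extdata", paste0("khps_", which, ".csv"),
                      package = "dualtraj", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
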