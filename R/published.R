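#' Published COVID-19 to brain-structure MR summary results
#'
#' Transcriptions of the published summary tables from a two-sample MR
#' study of COVID-19 phenotypes (infection, hospitalized, severe, critical)
#' on brain structural traits: the nominally significant main results
#' (per-method beta, 95% CI, SE, p) and their sensitivity diagnostics
#' (Cochran's Q, MR-Egger intercept, MR-PRESSO global p). These printed
#' values serve as worked-example inputs for checking the package's Wald
#' inference arithmetic; values are as printed (4 decimal places), so
#' reconstructions are limited by that precision.
#'
#' @param which `"main"` or `"sensitivity"`.
#' @return Data frame.
#' @export
published_results <- function(which = c("main", "sensitivity")) {
  which <- match.arg(which)
  file <- if (which == "main") "covid19_brain_mr_main_results.tsv" else
    "covid19_brain_mr_sensitivity.tsv"
  path <- system.file("extdata", file, package = "mrgrid", mustWork = TRUE)
  utils::read.delim(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}
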