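#' Bonferroni-corrected significance threshold
#'
#' @param alpha Family-wise error rate.
#' @param n_tests Number of tests in the family (>= 1).
#' @return `alpha / n_tests`.
#' @export
bonferroni_threshold <- function(alpha, n_tests) {
  stopifnot(n_tests >= 1)
  alpha / n_tests
}

#' Are the causal-effect directions consistent across methods?
#'
#' TRUE if and only if the headline IVW estimate, the weighted median and
#' the MR-Egger slope all have the same sign and none is exactly zero. Any
#' missing or not-computed method yields FALSE, with the reason attached as
#' attribute `"reason"`.
#'
#' @param estimates An `mr_result` data frame from [run_all_methods()].
#' @param ivw_method Which IVW row is the headline estimate (`"ivw_re"` or
#'   `"ivw_fixed"`).
#' @return Logical scalar with attribute `reason` (NA when TRUE).
#' @export
direction_consistent <- function(estimates, ivw_method = "ivw_re") {
  need <- c(ivw_method, "weighted_median", "egger_slope")
  th <- estimates$theta[match(need, estimates$method)]
  out <- function(val, reason) structure(val, reason = reason)
  if (any(is.na(th))) {
    miss <- need[is.na(th)]
    return(out(FALSE, paste("method missing or not computed:",
                            paste(miss, collapse = ", "))))
  }
  if (any(th == 0)) return(out(FALSE, "a method estimate is exactly 0"))
  if (length(unique(sign(th))) > 1) {
    return(out(FALSE, "estimate directions disagree"))
  }
  out(TRUE, NA_character_)
}

#' Apply the nominal and Bonferroni significance rules
#'
#' Nominal significance requires the headline IVW p-value below `alpha`
#' together with direction-consistency across all methods; family-wise
#' significance replaces `alpha` by the Bonferroni threshold
#' `alpha / n_tests`. Bonferroni significance therefore always implies
#' nominal significance.
#'
#' @param p_ivw Headline IVW p-value.
#' @param consistent Logical from [direction_consistent()].
#' @param alpha Nominal level (default 0.05).
#' @param n_tests Bonferroni family size.
#' @return List with `nominal_significant`, `bonferroni_significant`,
#'   `alpha`, `n_tests`, `bonferroni_threshold`.
#' @export
classify <- function(p_ivw, consistent, alpha = 0.05, n_tests = 1) {
  thr <- bonferroni_threshold(alpha, n_tests)
  ok <- isTRUE(as.logical(consistent)) && !is.na(p_ivw)
  list(nominal_significant = ok && p_ivw < alpha,
       bonferroni_significant = ok && p_ivw < thr,
       alpha = alpha, n_tests = as.integer(n_tests),
       bonferroni_threshold = thr)
}

grid_null_result <- function(exposure_name, outcome_name, n_tests, status) {
  list(exposure = exposure_name, outcome = outcome_name, n_snps = 0L,
       estimates = NULL, sensitivity = NULL,
       nominal_significant = FALSE, direction_consistent = FALSE,
       bonferroni_significant = FALSE,
       n_tests_in_family = as.integer(n_tests), status = status)
}

#' Run the full analysis grid
#'
#' For every exposure-by-outcome pair: instrument selection, allele
#' harmonization, all causal estimators, sensitivity diagnostics, and the
#' significance/direction decision rules under Bonferroni control over the
#' grid. Each pair draws its own seed from the master seed and the pair
#' key, so results do not depend on execution order. Per-pair failures
#' (no instruments, no overlapping variants, errors) produce structured
#' null rows that preserve the grid shape.
#'
#' @param exposures Named list of exposure `summary_dataset`s.
#' @param outcomes Named list of outcome `summary_dataset`s.
#' @param ld_reference An `ld_reference` or `NULL`.
#' @param annotations Confounder annotation data frame or `NULL`.
#' @param config An [mr_config()]; `family_size_override` replaces the
#'   realized grid size in the Bonferroni rule without touching any
#'   estimate.
#' @return Object of class `mr_grid`: list with `results` (one entry per
#'   pair), `family_size`, `config`. Use [as.data.frame()] or
#'   [write_results()] for the tabular form.
#' @export
run_grid <- function(exposures, outcomes, ld_reference = NULL,
                     annotations = NULL, config = mr_config()) {
  stopifnot(length(exposures) >= 1, length(outcomes) >= 1,
            !is.null(names(exposures)), !is.null(names(outcomes)))
  n_pairs <- length(exposures) * length(outcomes)
  n_tests <- if (!is.null(config$family_size_override)) {
    as.integer(config$family_size_override)
  } else n_pairs
  results <- list()
  for (en in names(exposures)) {
    for (on in names(outcomes)) {
      key <- paste(en, on, sep = " -> ")
      cfg <- config
      cfg$seed <- derive_seed(config$seed, en, on)
      results[[key]] <- tryCatch({
        inst <- select_instruments(exposures[[en]], outcomes[[on]],
                                   ld_reference, annotations, cfg)
        if (inst$no_instruments) {
          grid_null_result(en, on, n_tests, "no_instruments")
        } else {
          h <- harmonize(inst, outcomes[[on]],
                         palindrome_window = cfg$palindrome_window,
                         palindrome_policy = cfg$palindrome_policy,
                         exposure_name = en, outcome_name = on)
          if (nrow(h$pairs) == 0) {
            grid_null_result(en, on, n_tests, "no_overlapping_variants")
          } else {
            est <- run_all_methods(h, cfg)
            sens <- sensitivity_report(h, cfg)
            main <- if (cfg$ivw_mode == "fixed") "ivw_fixed" else "ivw_re"
            p_main <- est$pval[match(main, est$method)]
            if (is.na(p_main) && nrow(h$pairs) == 1) {
              p_main <- est$pval[match("wald_ratio", est$method)]
            }
            dc <- direction_consistent(est, ivw_method = main)
            cls <- classify(p_main, dc, cfg$alpha, n_tests)
            list(exposure = en, outcome = on,
                 n_snps = nrow(h$pairs), estimates = est,
                 sensitivity = sens,
                 nominal_significant = cls$nominal_significant,
                 direction_consistent = isTRUE(as.logical(dc)),
                 bonferroni_significant = cls$bonferroni_significant,
                 n_tests_in_family = as.integer(n_tests),
                 status = "ok", instruments = inst, harmonized = h)
          }
        }
      }, error = function(e) {
        grid_null_result(en, on, n_tests, paste0("error: ",
                                                 conditionMessage(e)))
      })
    }
  }
  structure(list(results = results, family_size = n_tests, config = config),
            class = "mr_grid")
}

#' Tabulate an analysis grid
#'
#' One row per exposure-by-outcome-by-method combination, merging the
#' estimate columns with the pair's sensitivity diagnostics; failed pairs
#' contribute a single placeholder row with their status. This table
#' serializes losslessly through [write_results()]/[read_results()].
#'
#' @param x An `mr_grid`.
#' @param row.names,optional,... Ignored (S3 signature).
#' @return Data frame.
#' @export
as.data.frame.mr_grid <- function(x, row.names = NULL, optional = FALSE,
                                  ...) {
  rows <- lapply(x$results, function(r) {
    if (is.null(r$estimates)) {
      data.frame(exposure = r$exposure, outcome = r$outcome,
                 n_snps = 0L, method = r$status, theta = NA_real_,
                 ci_low = NA_real_, ci_high = NA_real_, se = NA_real_,
                 pval = NA_real_, q_stat = NA_real_, q_pval = NA_real_,
                 egger_intercept = NA_real_,
                 egger_intercept_pval = NA_real_, presso_pval = NA_real_,
                 stringsAsFactors = FALSE)
    } else {
      est <- r$estimates
      data.frame(exposure = r$exposure, outcome = r$outcome,
                 n_snps = r$n_snps, method = est$method, theta = est$theta,
                 ci_low = est$ci_low, ci_high = est$ci_high, se = est$se,
                 pval = est$pval, q_stat = r$sensitivity$q_stat,
                 q_pval = r$sensitivity$q_pval,
                 egger_intercept = r$sensitivity$egger_intercept,
                 egger_intercept_pval = r$sensitivity$egger_intercept_pval,
                 presso_pval = r$sensitivity$presso_global_pval,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.mr_grid <- function(x, ...) {
  n_ok <- sum(vapply(x$results, function(r) r$status == "ok", logical(1)))
  cat(sprintf("<mr_grid> %d pairs (%d analyzed), Bonferroni family size %d\n",
              length(x$results), n_ok, x$family_size))
  invisible(x)
}
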