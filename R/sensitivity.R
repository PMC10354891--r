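#' Cochran's Q heterogeneity test
#'
#' `Q = sum w_j (theta_j - theta)^2` over per-variant Wald ratios, with the
#' first-order inverse-variance weights
#' `w_j = beta_exposure^2 / se_outcome^2` that match the Wald-ratio
#' standard-error convention (so Q is consistent with the IVW weighting).
#' Under homogeneity Q is chi-square with `J - 1` degrees of freedom.
#'
#' @param x A `harmonized_set` or pairs data frame with at least 2 pairs.
#' @param theta Reference slope; defaults to the fixed-effect IVW estimate.
#' @return List with `q_stat`, `q_pval`, `df`.
#' @export
cochran_q <- function(x, theta = NULL) {
  p <- as_pairs(x)
  j <- nrow(p)
  if (j < 2) stop("Cochran's Q needs >= 2 pairs")
  if (is.null(theta)) theta <- mr_ivw(p, "fixed")$theta
  w <- p$beta_exposure^2 / p$se_outcome^2
  ratios <- p$beta_outcome / p$beta_exposure
  q <- sum(w * (ratios - theta)^2)
  list(q_stat = q,
       q_pval = stats::pchisq(q, df = j - 1, lower.tail = FALSE),
       df = j - 1)
}

#' MR-Egger intercept test for directional pleiotropy
#'
#' Two-sided t-test (on `J - 2` degrees of freedom) of the MR-Egger
#' regression intercept against zero; a non-zero intercept indicates
#' directional horizontal pleiotropy.
#'
#' @param x A `harmonized_set`, pairs data frame, or the list returned by
#'   [mr_egger()].
#' @return List with `intercept`, `se`, `pval`.
#' @export
egger_intercept_test <- function(x) {
  fit <- if (is.list(x) && !is.data.frame(x) &&
             all(c("slope", "intercept") %in% names(x))) x else mr_egger(x)
  list(intercept = fit$intercept$theta, se = fit$intercept$se,
       pval = fit$intercept$pval)
}

# Leave-one-out fixed-effect IVW slopes in O(J) via sum updates.
loo_ivw_slopes <- function(bx, by, w) {
  sxy <- sum(w * bx * by)
  sxx <- sum(w * bx^2)
  (sxy - w * bx * by) / (sxx - w * bx^2)
}

#' Leave-one-out IVW estimates
#'
#' Recomputes the fixed-effect IVW estimate excluding each variant in turn
#' and flags variants whose exclusion changes the sign of the estimate
#' relative to the full set.
#'
#' @param x A `harmonized_set` or pairs data frame with at least 3 pairs.
#' @return Data frame with one row per excluded variant: `variant_id`,
#'   `theta`, `se`, `pval`, `sign_change`.
#' @export
leave_one_out <- function(x) {
  p <- as_pairs(x)
  j <- nrow(p)
  if (j < 3) stop("leave-one-out needs >= 3 pairs")
  full <- mr_ivw(p, "fixed")$theta
  rows <- lapply(seq_len(j), function(i) {
    est <- mr_ivw(p[-i, , drop = FALSE], "fixed")
    data.frame(variant_id = p$variant_id[i], theta = est$theta,
               se = est$se, pval = est$pval,
               sign_change = sign(est$theta) != sign(full),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' MR-PRESSO global test for horizontal pleiotropy
#'
#' Computes the observed leave-one-out residual sum of squares
#' `RSS_obs = sum_j w_j (beta_outcome_j - theta_(-j) * beta_exposure_j)^2`
#' with `w_j = 1/se_outcome_j^2` and `theta_(-j)` the fixed-effect IVW slope
#' excluding variant j, then compares it to a parametric null: in each of
#' `n_sim` replicates the exposure effects are redrawn from
#' `N(beta_exposure_j, se_exposure_j^2)` (exposure treated as fixed where
#' its standard error is missing) and the outcome effects from
#' `N(theta_(-j) * beta_exposure_j, se_outcome_j^2)`, and the same
#' leave-one-out RSS is recomputed on the simulated data. The Monte-Carlo
#' p-value is `(1 + #(RSS* >= RSS_obs)) / (n_sim + 1)`, so its smallest
#' attainable value is `1/(n_sim + 1)`.
#'
#' @param x A `harmonized_set` or pairs data frame with at least 4 pairs.
#' @param n_sim Number of simulated null replicates; fewer than 100 flags
#'   the result as low-resolution (with a warning).
#' @param seed Seed for the simulation stream (required).
#' @return List with `rss_obs`, `pval`, `n_sim`, `seed`, `low_resolution`.
#' @export
mr_presso_global <- function(x, n_sim = 2000, seed = NULL) {
  p <- as_pairs(x)
  j <- nrow(p)
  if (j < 4) stop("MR-PRESSO global test needs >= 4 pairs")
  if (is.null(seed)) stop("seed is required for the MR-PRESSO simulation")
  low <- n_sim < 100
  if (low) warning("n_sim < 100: MR-PRESSO p-value resolution is coarse")
  bx <- p$beta_exposure
  by <- p$beta_outcome
  w <- 1 / p$se_outcome^2
  se_x <- ifelse(is.na(p$se_exposure), 0, p$se_exposure)
  theta_loo <- loo_ivw_slopes(bx, by, w)
  rss_obs <- sum(w * (by - theta_loo * bx)^2)
  rss_null <- with_seed(seed, {
    bxs <- matrix(stats::rnorm(j * n_sim, bx, se_x), nrow = j)
    bys <- matrix(stats::rnorm(j * n_sim, theta_loo * bx, p$se_outcome),
                  nrow = j)
    sxy <- colSums(w * bxs * bys)
    sxx <- colSums(w * bxs^2)
    th <- (rep(sxy, each = j) - w * bxs * bys) /
      (rep(sxx, each = j) - w * bxs^2)
    colSums(w * (bys - th * bxs)^2)
  })
  list(rss_obs = rss_obs,
       pval = (1 + sum(rss_null >= rss_obs)) / (n_sim + 1),
       n_sim = as.integer(n_sim), seed = as.integer(seed),
       low_resolution = low)
}

#' Heterogeneity and pleiotropy diagnostics for one analysis
#'
#' Assembles Cochran's Q, the MR-Egger intercept test and the MR-PRESSO
#' global test into the sensitivity report accompanying each causal
#' estimate. Diagnostics whose preconditions fail (too few pairs) are
#' reported as `NA`.
#'
#' @param x A `harmonized_set` or pairs data frame.
#' @param config An [mr_config()] providing `n_sim` and `seed`.
#' @return Object of class `sensitivity_report`: `q_stat`, `q_pval`,
#'   `egger_intercept`, `egger_intercept_pval`, `presso_rss_obs`,
#'   `presso_global_pval`, `n_sim`, `seed`.
#' @export
sensitivity_report <- function(x, config = mr_config()) {
  p <- as_pairs(x)
  j <- nrow(p)
  rep <- list(q_stat = NA_real_, q_pval = NA_real_,
              egger_intercept = NA_real_, egger_intercept_pval = NA_real_,
              presso_rss_obs = NA_real_, presso_global_pval = NA_real_,
              n_sim = as.integer(config$n_sim),
              seed = derive_seed(config$seed, "presso"))
  if (j >= 2) {
    q <- cochran_q(p)
    rep$q_stat <- q$q_stat
    rep$q_pval <- q$q_pval
  }
  if (j >= 3) {
    it <- egger_intercept_test(p)
    rep$egger_intercept <- it$intercept
    rep$egger_intercept_pval <- it$pval
  }
  if (j >= 4) {
    pg <- mr_presso_global(p, n_sim = config$n_sim, seed = rep$seed)
    rep$presso_rss_obs <- pg$rss_obs
    rep$presso_global_pval <- pg$pval
  }
  structure(rep, class = "sensitivity_report")
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat(sprintf(paste0("<sensitivity_report> Q=%.4g (p=%.4g); ",
                     "Egger intercept=%.4g (p=%.4g); ",
                     "MR-PRESSO global p=%.4g (n_sim=%d)\n"),
              x$q_stat, x$q_pval, x$egger_intercept, x$egger_intercept_pval,
              x$presso_global_pval, x$n_sim))
  invisible(x)
}
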