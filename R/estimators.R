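#' Construct an MR estimate with Wald-type inference
#'
#' Builds the standard estimate row from a point estimate and its standard
#' error: two-sided p-value and equal-tailed 95% confidence interval from
#' the normal distribution, or from the t distribution when `df` is given.
#' The interval identity `ci = theta -/+ q * se` holds exactly for every
#' emitted estimate.
#'
#' @param method Method label (e.g. `"ivw_fixed"`, `"egger_slope"`).
#' @param theta Point estimate.
#' @param se Standard error (> 0), or `NA` for point-only estimates.
#' @param n_snps Number of variants used.
#' @param df Degrees of freedom for t-based inference; `NULL` for normal.
#' @param conf_level Confidence level, default 0.95.
#' @return One-row data frame: `method`, `theta`, `se`, `ci_low`, `ci_high`,
#'   `pval`, `n_snps`, `note`.
#' @export
mr_estimate <- function(method, theta, se, n_snps, df = NULL,
                        conf_level = 0.95) {
  a <- (1 - conf_level) / 2
  if (is.na(se)) {
    q <- NA_real_; p <- NA_real_
  } else if (is.null(df)) {
    q <- stats::qnorm(1 - a)
    p <- 2 * stats::pnorm(-abs(theta / se))
  } else {
    q <- stats::qt(1 - a, df)
    p <- 2 * stats::pt(-abs(theta / se), df)
  }
  data.frame(method = method, theta = theta, se = se,
             ci_low = theta - q * se, ci_high = theta + q * se,
             pval = p, n_snps = as.integer(n_snps), note = NA_character_,
             stringsAsFactors = FALSE)
}

mr_not_computed <- function(method, n_snps, note) {
  data.frame(method = method, theta = NA_real_, se = NA_real_,
             ci_low = NA_real_, ci_high = NA_real_, pval = NA_real_,
             n_snps = as.integer(n_snps), note = note,
             stringsAsFactors = FALSE)
}

#' Per-variant Wald ratio estimate
#'
#' The single-variant causal estimate `theta = beta_outcome/beta_exposure`
#' with first-order delta-method standard error
#' `se_outcome/|beta_exposure|` (optionally the second-order form that also
#' propagates the exposure-side error).
#'
#' @param pair One-row harmonized pair (or list) with `beta_exposure`,
#'   `se_exposure`, `beta_outcome`, `se_outcome`.
#' @param second_order Include the exposure-side variance term.
#' @return One-row estimate data frame (see [mr_estimate()]).
#' @export
wald_ratio <- function(pair, second_order = FALSE) {
  bx <- pair$beta_exposure
  by <- pair$beta_outcome
  if (bx == 0) stop("undefined Wald ratio: beta_exposure is 0")
  theta <- by / bx
  se <- if (second_order) {
    sqrt(pair$se_outcome^2 / bx^2 + by^2 * pair$se_exposure^2 / bx^4)
  } else {
    pair$se_outcome / abs(bx)
  }
  mr_estimate("wald_ratio", theta, se, 1L)
}

#' Inverse-variance weighted estimate
#'
#' Combines per-variant Wald ratios with weights `1/se_outcome^2`,
#' equivalently the zero-intercept weighted least-squares regression of the
#' outcome effects on the exposure effects (implemented via [stats::lm()]).
#' The fixed-effect standard error is `(sum w * bx^2)^(-1/2)`; the
#' multiplicative random-effects variant inflates it by
#' `max(1, sqrt(Q/(J-1)))`, where Q is Cochran's heterogeneity statistic.
#' Inference is normal-based.
#'
#' @param x A `harmonized_set` or pairs data frame.
#' @param mode `"multiplicative_re"` or `"fixed"`.
#' @return One-row estimate data frame, method `ivw_re` or `ivw_fixed`
#'   (`wald_ratio` when only one pair is available).
#' @export
mr_ivw <- function(x, mode = c("multiplicative_re", "fixed")) {
  mode <- match.arg(mode)
  p <- as_pairs(x)
  j <- nrow(p)
  if (j == 0) stop("no harmonized pairs")
  if (j == 1) return(wald_ratio(p[1, ]))
  if (all(p$beta_exposure == 0)) {
    stop("degenerate design: all exposure effects are 0")
  }
  w <- 1 / p$se_outcome^2
  fit <- stats::lm(beta_outcome ~ 0 + beta_exposure, data = p, weights = w)
  theta <- unname(stats::coef(fit)[1])
  se_fixed <- sqrt(1 / sum(w * p$beta_exposure^2))
  q <- sum(w * stats::residuals(fit)^2)
  se <- if (mode == "fixed") se_fixed else
    se_fixed * max(1, sqrt(q / (j - 1)))
  est <- mr_estimate(if (mode == "fixed") "ivw_fixed" else "ivw_re",
                     theta, se, j)
  attr(est, "q_stat") <- q
  est
}

#' MR-Egger regression
#'
#' Weighted least-squares regression of outcome on exposure effects with a
#' free intercept, each pair first oriented so the exposure effect is
#' non-negative (both signs flipped where it is negative; the input set is
#' not mutated). Weights are `1/se_outcome^2`; coefficient standard errors
#' use the unscaled covariance multiplied by `max(1, residual SD)`, with
#' t-based p-values and intervals on `J - 2` degrees of freedom. The
#' intercept estimates the average directional pleiotropic effect; the
#' slope is the pleiotropy-adjusted causal effect.
#'
#' @param x A `harmonized_set` or pairs data frame with at least 3 pairs.
#' @return List with `slope` and `intercept` estimate rows (methods
#'   `egger_slope`, `egger_intercept`).
#' @export
mr_egger <- function(x) {
  p <- as_pairs(x)
  j <- nrow(p)
  if (j < 3) stop("insufficient instruments: MR-Egger needs >= 3 pairs")
  s <- ifelse(p$beta_exposure < 0, -1, 1)
  d <- data.frame(bx = p$beta_exposure * s, by = p$beta_outcome * s)
  w <- 1 / p$se_outcome^2
  fit <- stats::lm(by ~ bx, data = d, weights = w)
  est <- stats::coef(fit)
  # unscaled covariance and residual SD computed directly (summary.lm
  # warns on exact fits, which are legitimate inputs here)
  xtwx <- crossprod(sqrt(w) * cbind("(Intercept)" = 1, bx = d$bx))
  se_unscaled <- sqrt(diag(solve(xtwx)))
  sigma <- sqrt(sum(w * stats::residuals(fit)^2) / (j - 2))
  se <- se_unscaled * max(1, sigma)
  list(slope = mr_estimate("egger_slope", unname(est["bx"]),
                           unname(se["bx"]), j, df = j - 2),
       intercept = mr_estimate("egger_intercept", unname(est["(Intercept)"]),
                               unname(se["(Intercept)"]), j, df = j - 2))
}

# Weighted median of x under weights w by linear interpolation of the
# order statistics against centred cumulative weights.
weighted_median_point <- function(x, w) {
  o <- order(x)
  x <- x[o]
  w <- w[o] / sum(w)
  s <- cumsum(w) - w / 2
  if (0.5 <= s[1]) return(x[1])
  k <- length(x)
  if (0.5 >= s[k]) return(x[k])
  i <- max(which(s < 0.5))
  x[i] + (0.5 - s[i]) / (s[i + 1] - s[i]) * (x[i + 1] - x[i])
}

#' Weighted median estimate
#'
#' Orders the per-variant Wald ratios and interpolates across inverse-
#' variance weights (normalized, cumulated, centred by half their own mass)
#' at probability 0.5. Consistent when variants carrying less than half the
#' weight are invalid instruments. The standard error is the spread of the
#' estimate over `n_boot` parametric-bootstrap replicates that redraw both
#' effect estimates from normal distributions centred on the observed
#' values with their reported standard errors; inference is normal-based.
#'
#' @param x A `harmonized_set` or pairs data frame with at least 3 pairs.
#' @param n_boot Bootstrap replicates; `0` returns the point estimate only
#'   (`se`, `ci` and `pval` set `NA`).
#' @param seed Seed for the bootstrap stream (required when `n_boot > 0`).
#' @return One-row estimate data frame, method `weighted_median`.
#' @export
mr_weighted_median <- function(x, n_boot = 1000, seed = NULL) {
  p <- as_pairs(x)
  j <- nrow(p)
  if (j < 3) stop("insufficient instruments: weighted median needs >= 3 pairs")
  ratio_of <- function(bx, by, se_y) {
    theta <- by / bx
    w <- (abs(bx) / se_y)^2   # 1 / se(theta)^2, first-order
    weighted_median_point(theta, w)
  }
  theta <- ratio_of(p$beta_exposure, p$beta_outcome, p$se_outcome)
  if (n_boot == 0) {
    est <- mr_estimate("weighted_median", theta, NA_real_, j)
    return(est)
  }
  if (is.null(seed)) stop("seed is required for the weighted-median bootstrap")
  se_x <- ifelse(is.na(p$se_exposure), 0, p$se_exposure)
  boot <- with_seed(seed, {
    bxs <- matrix(stats::rnorm(j * n_boot, p$beta_exposure, se_x), nrow = j)
    bys <- matrix(stats::rnorm(j * n_boot, p$beta_outcome, p$se_outcome),
                  nrow = j)
    vapply(seq_len(n_boot), function(k) {
      ratio_of(bxs[, k], bys[, k], p$se_outcome)
    }, numeric(1))
  })
  mr_estimate("weighted_median", theta, stats::sd(boot), j)
}

#' Run all causal-effect estimators on a harmonized set
#'
#' Emits the fixed-effect and multiplicative random-effects IVW estimates,
#' the weighted median, and the MR-Egger slope and intercept. Methods whose
#' preconditions are not met (fewer than 2 or 3 pairs) are returned as
#' structured "not computed" rows rather than errors; a single pair yields
#' the Wald ratio. Output is deterministic for a fixed configuration seed
#' (the weighted-median bootstrap stream is derived from it).
#'
#' @param x A `harmonized_set` or pairs data frame.
#' @param config An [mr_config()] providing `ivw_mode` (which IVW variant is
#'   flagged as the headline method downstream), `n_boot` and `seed`.
#' @return Data frame of estimate rows, class `mr_result`.
#' @export
run_all_methods <- function(x, config = mr_config()) {
  p <- as_pairs(x)
  j <- nrow(p)
  if (j == 0) stop("no harmonized pairs")
  rows <- list()
  if (j == 1) {
    rows$wald <- wald_ratio(p[1, ])
    rows$ivw_f <- mr_not_computed("ivw_fixed", j, "not computed: < 2 SNPs")
    rows$ivw_r <- mr_not_computed("ivw_re", j, "not computed: < 2 SNPs")
  } else {
    rows$ivw_f <- mr_ivw(p, "fixed")
    rows$ivw_r <- mr_ivw(p, "multiplicative_re")
  }
  if (j >= 3) {
    wm_seed <- derive_seed(config$seed, "weighted_median")
    rows$wm <- mr_weighted_median(p, n_boot = config$n_boot, seed = wm_seed)
    eg <- mr_egger(p)
    rows$eg_s <- eg$slope
    rows$eg_i <- eg$intercept
  } else {
    rows$wm <- mr_not_computed("weighted_median", j, "not computed: < 3 SNPs")
    rows$eg_s <- mr_not_computed("egger_slope", j, "not computed: < 3 SNPs")
    rows$eg_i <- mr_not_computed("egger_intercept", j,
                                 "not computed: < 3 SNPs")
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("mr_result", "data.frame")
  out
}
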