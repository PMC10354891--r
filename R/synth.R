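#' Specify a per-variant horizontal-pleiotropy law
#'
#' Describes how direct (non-mediated) effects `alpha_j` on the outcome are
#' generated for simulated instruments:
#' * `none` — all zero (every instrument valid);
#' * `balanced` — `alpha_j ~ N(0, sigma^2)`, zero mean, InSIDE holds;
#' * `directional` — `alpha_j ~ N(mu, sigma^2)`, non-zero mean, InSIDE
#'   holds (independent of instrument strength);
#' * `inside_violated` — `alpha_j` correlated (coefficient `rho`) with the
#'   true exposure effects, breaking the InSIDE assumption;
#' * `contaminated` — a fraction of instruments receive
#'   `N(mu, sigma^2)` direct effects, the rest are valid.
#'
#' @param type One of the law names above.
#' @param mu,sigma Mean and SD of the direct effects (outcome units).
#' @param rho Correlation with the exposure effects (`inside_violated`).
#' @param fraction Invalid fraction (`contaminated`), in \[0, 1\].
#' @return List of class `pleiotropy_law`.
#' @export
pleiotropy_law <- function(type = c("none", "balanced", "directional",
                                    "inside_violated", "contaminated"),
                           mu = 0, sigma = 0, rho = 0, fraction = 0) {
  type <- match.arg(type)
  stopifnot(sigma >= 0, rho >= -1, rho <= 1, fraction >= 0, fraction <= 1)
  structure(list(type = type, mu = mu, sigma = sigma, rho = rho,
                 fraction = fraction), class = "pleiotropy_law")
}

#' Ground truth for a simulated two-sample MR dataset
#'
#' Defines the generative model: `J` instruments with true exposure effects
#' `gamma_j` drawn as `|N(gamma_mu, gamma_sigma^2)|` truncated below at
#' `gamma_min` (effect alleles oriented to increase the exposure), direct
#' effects `alpha_j` from the pleiotropy law, true outcome effects
#' `Gamma_j = theta * gamma_j + alpha_j`, and observed effects drawn with
#' independent exposure- and outcome-side sampling noise (the two-sample
#' design). Background null variants have `gamma = alpha = 0`. Default SE
#' ranges put the per-variant F statistic `(gamma/se_x)^2` between roughly
#' 25 and 20,000, so the weak-instrument screen is non-trivial.
#'
#' @param theta True causal effect of the exposure on the outcome.
#' @param J Number of instruments.
#' @param gamma_mu,gamma_sigma,gamma_min Exposure effect-size law.
#' @param pleiotropy A [pleiotropy_law()].
#' @param se_x_range,se_y_range Ranges of per-variant standard errors
#'   (uniform draws) for exposure and outcome.
#' @param n_null_snps Background variants below instrument strength.
#' @param ld_blocks Optional list with `sizes` (integer partition of the
#'   variant list) and `r2` (within-block squared correlation) used for
#'   position layout and [simulate_ld()].
#' @param palindromic_fraction Fraction of variants assigned A/T or C/G
#'   allele pairs, exercising palindrome handling.
#' @param n_exposure,n_outcome Reported GWAS sample sizes.
#' @param seed Seed; all randomness in [simulate_pair()] flows from it.
#' @return List of class `synthetic_truth`.
#' @export
synthetic_truth <- function(theta = 0.1, J = 30,
                            gamma_mu = 0, gamma_sigma = 0.15,
                            gamma_min = 0.06,
                            pleiotropy = pleiotropy_law("none"),
                            se_x_range = c(0.003, 0.012),
                            se_y_range = c(0.01, 0.02),
                            n_null_snps = 0,
                            ld_blocks = NULL,
                            palindromic_fraction = 0.1,
                            n_exposure = 1e6, n_outcome = 5e4,
                            seed = 1) {
  stopifnot(J >= 1, gamma_sigma >= 0, gamma_min >= 0,
            inherits(pleiotropy, "pleiotropy_law"),
            length(se_x_range) == 2, length(se_y_range) == 2,
            n_null_snps >= 0, palindromic_fraction >= 0,
            palindromic_fraction <= 1)
  if (!is.null(ld_blocks)) {
    stopifnot(is.list(ld_blocks), sum(ld_blocks$sizes) == J + n_null_snps)
  }
  structure(list(theta = theta, J = as.integer(J), gamma_mu = gamma_mu,
                 gamma_sigma = gamma_sigma, gamma_min = gamma_min,
                 pleiotropy = pleiotropy, se_x_range = se_x_range,
                 se_y_range = se_y_range,
                 n_null_snps = as.integer(n_null_snps),
                 ld_blocks = ld_blocks,
                 palindromic_fraction = palindromic_fraction,
                 n_exposure = n_exposure, n_outcome = n_outcome,
                 seed = as.integer(seed)),
            class = "synthetic_truth")
}

# |N(mu, sigma)| truncated below at gamma_min, by vectorized rejection.
draw_gamma <- function(n, mu, sigma, gamma_min) {
  g <- abs(stats::rnorm(n, mu, sigma))
  for (it in 1:1000) {
    bad <- g < gamma_min
    if (!any(bad)) break
    g[bad] <- abs(stats::rnorm(sum(bad), mu, sigma))
  }
  g[g < gamma_min] <- gamma_min
  g
}

draw_alpha <- function(law, gamma) {
  n <- length(gamma)
  switch(law$type,
         none = rep(0, n),
         balanced = stats::rnorm(n, 0, law$sigma),
         directional = stats::rnorm(n, law$mu, law$sigma),
         inside_violated = {
           z <- if (stats::sd(gamma) > 0) {
             (gamma - mean(gamma)) / stats::sd(gamma)
           } else rep(0, n)
           law$mu + law$sigma *
             (law$rho * z + sqrt(1 - law$rho^2) * stats::rnorm(n))
         },
         contaminated = {
           a <- rep(0, n)
           k <- round(law$fraction * n)
           if (k > 0) {
             idx <- sample.int(n, k)
             a[idx] <- stats::rnorm(k, law$mu, law$sigma)
           }
           a
         })
}

.non_palindromic_pairs <- rbind(c("A", "C"), c("A", "G"), c("C", "A"),
                                c("C", "T"), c("G", "A"), c("G", "T"),
                                c("T", "C"), c("T", "G"))
.palindromic_pairs <- rbind(c("A", "T"), c("T", "A"),
                            c("C", "G"), c("G", "C"))

# Positions spaced 20 Mb apart (beyond the default clumping window) except
# within an LD block, whose members sit 5 kb apart.
layout_positions <- function(m, ld_blocks) {
  if (is.null(ld_blocks)) return(20e6 * seq_len(m))
  block <- rep(seq_along(ld_blocks$sizes), ld_blocks$sizes)
  within <- stats::ave(seq_len(m), block, FUN = seq_along)
  20e6 * block + 5e3 * (within - 1)
}

#' Simulate a paired exposure/outcome summary-statistics dataset
#'
#' Generates, under the model in [synthetic_truth()], observed per-variant
#' effects `beta_X ~ N(gamma, se_x^2)` and `beta_Y ~ N(Gamma, se_y^2)` with
#' independent noise on the two sides, Wald p-values (floored at 1e-300 to
#' respect the record invariant p > 0), allele pairs (with the configured
#' palindromic fraction), frequencies, and positions laid out so that only
#' LD-block mates fall within the default clumping window. Zero entries in
#' the SE ranges are honoured (observed effects equal their true values)
#' with stored SEs floored at 1e-12 so records remain valid. Two calls with
#' the same truth are identical.
#'
#' @param truth A [synthetic_truth()].
#' @param exposure_name,outcome_name Trait labels.
#' @return List with `exposure` and `outcome` (`summary_dataset`s over the
#'   same variants), `truth_table` (per-variant `gamma`, `alpha`, `Gamma`,
#'   `is_instrument`), and `truth` (the input).
#' @export
simulate_pair <- function(truth, exposure_name = "simulated_exposure",
                          outcome_name = "simulated_outcome") {
  stopifnot(inherits(truth, "synthetic_truth"))
  with_seed(truth$seed, {
    m <- truth$J + truth$n_null_snps
    is_inst <- c(rep(TRUE, truth$J), rep(FALSE, truth$n_null_snps))
    ids <- sprintf("rs%07d", seq_len(m))
    pos <- layout_positions(m, truth$ld_blocks)
    chrom <- rep("1", m)

    gamma <- c(draw_gamma(truth$J, truth$gamma_mu, truth$gamma_sigma,
                          truth$gamma_min),
               rep(0, truth$n_null_snps))
    alpha <- rep(0, m)
    alpha[is_inst] <- draw_alpha(truth$pleiotropy, gamma[is_inst])
    big_gamma <- truth$theta * gamma + alpha

    se_x <- stats::runif(m, truth$se_x_range[1], truth$se_x_range[2])
    se_y <- stats::runif(m, truth$se_y_range[1], truth$se_y_range[2])
    beta_x <- stats::rnorm(m, gamma, se_x)
    beta_y <- stats::rnorm(m, big_gamma, se_y)
    se_x_store <- pmax(se_x, 1e-12)
    se_y_store <- pmax(se_y, 1e-12)
    p_x <- pmax(2 * stats::pnorm(-abs(beta_x / se_x_store)), 1e-300)
    p_y <- pmax(2 * stats::pnorm(-abs(beta_y / se_y_store)), 1e-300)

    eaf <- stats::runif(m, 0.05, 0.95)
    eaf_out <- pmin(0.99, pmax(0.01, eaf + stats::rnorm(m, 0, 0.005)))
    pal <- stats::runif(m) < truth$palindromic_fraction
    pick <- function(pairs, k) pairs[sample.int(nrow(pairs), k,
                                                replace = TRUE), ,
                                     drop = FALSE]
    alleles <- matrix("", m, 2)
    if (any(pal)) alleles[pal, ] <- pick(.palindromic_pairs, sum(pal))
    if (any(!pal)) alleles[!pal, ] <- pick(.non_palindromic_pairs, sum(!pal))

    rec <- function(beta, se, p, eafs, n) {
      data.frame(variant_id = ids, chrom = chrom, pos = pos,
                 effect_allele = alleles[, 1], other_allele = alleles[, 2],
                 eaf = eafs, beta = beta, se = se, pval = p, n = n,
                 stringsAsFactors = FALSE)
    }
    exposure <- summary_dataset(exposure_name, "exposure",
                                rec(beta_x, se_x_store, p_x, eaf,
                                    truth$n_exposure))
    outcome <- summary_dataset(outcome_name, "outcome",
                               rec(beta_y, se_y_store, p_y, eaf_out,
                                   truth$n_outcome))
    truth_table <- data.frame(variant_id = ids, is_instrument = is_inst,
                              gamma = gamma, alpha = alpha,
                              big_gamma = big_gamma, se_x = se_x_store,
                              se_y = se_y_store, stringsAsFactors = FALSE)
    list(exposure = exposure, outcome = outcome, truth_table = truth_table,
         truth = truth)
  })
}

#' Simulate an already-harmonized instrument set
#'
#' Fast path for estimator studies: generates the same instrument-level
#' effects as [simulate_pair()] and returns them as a `harmonized_set`
#' directly, bypassing file I/O, selection, and allele bookkeeping (so the
#' instrument count is exactly `J`).
#'
#' @param truth A [synthetic_truth()].
#' @return A `harmonized_set` of the `J` instruments.
#' @export
simulate_harmonized <- function(truth) {
  d <- simulate_pair(truth)
  keep <- d$truth_table$is_instrument
  e <- d$exposure$records[keep, , drop = FALSE]
  o <- d$outcome$records[keep, , drop = FALSE]
  harmonized_set(data.frame(variant_id = e$variant_id,
                            effect_allele = e$effect_allele,
                            other_allele = e$other_allele,
                            beta_exposure = e$beta, se_exposure = e$se,
                            eaf_exposure = e$eaf, pval_exposure = e$pval,
                            beta_outcome = o$beta, se_outcome = o$se,
                            eaf_outcome = o$eaf,
                            stringsAsFactors = FALSE),
                 exposure_name = d$exposure$trait_name,
                 outcome_name = d$outcome$trait_name)
}

#' Simulate a block-structured LD reference
#'
#' Within-block squared correlations are set to `within_r2`, between-block
#' to 0, with a unit diagonal.
#'
#' @param variant_ids Variant identifiers.
#' @param block_sizes Integer partition of `variant_ids` into blocks.
#' @param within_r2 Squared correlation inside each block.
#' @param pos Optional per-variant positions stored on the reference.
#' @return An `ld_reference`.
#' @export
simulate_ld <- function(variant_ids, block_sizes, within_r2 = 0.9,
                        pos = NULL) {
  m <- length(variant_ids)
  stopifnot(sum(block_sizes) == m, within_r2 >= 0, within_r2 <= 1)
  block <- rep(seq_along(block_sizes), block_sizes)
  r2 <- outer(block, block, `==`) * within_r2
  diag(r2) <- 1
  ld_reference(variant_ids, r2, pos = pos)
}

#' Simulate a confounder-annotation table
#'
#' Flags a seeded random subset of variants with sub-threshold p-values in
#' the given confounder categories (these are exactly the variants a
#' default confounder filter removes), plus an optional fraction of benign
#' annotations with p-values well above any removal threshold.
#'
#' @param variant_ids Variant identifiers.
#' @param confounded_fraction Fraction flagged with strong confounder
#'   associations (count = `round(fraction * length(variant_ids))`).
#' @param categories Categories to draw from for the flagged variants.
#' @param p_range Range of flagged p-values (log-uniform), below 5e-8 by
#'   default.
#' @param benign_fraction Fraction given weak annotations
#'   (p in \[1e-6, 1e-3\], category `"benign"`).
#' @param seed Seed.
#' @return Annotation data frame (`variant_id`, `trait`, `category`,
#'   `pval`).
#' @export
simulate_annotations <- function(variant_ids, confounded_fraction = 0.1,
                                 categories = c("psychiatric",
                                                "fluid intelligence",
                                                "obesity", "hypoxemia"),
                                 p_range = c(1e-30, 1e-9),
                                 benign_fraction = 0.1, seed = 1) {
  stopifnot(confounded_fraction >= 0, confounded_fraction <= 1)
  with_seed(seed, {
    m <- length(variant_ids)
    k <- round(confounded_fraction * m)
    kb <- round(benign_fraction * m)
    rows <- list()
    if (k > 0) {
      flagged <- sample(variant_ids, k)
      cat_i <- sample(categories, k, replace = TRUE)
      lp <- stats::runif(k, log10(p_range[1]), log10(p_range[2]))
      rows$conf <- data.frame(variant_id = flagged,
                              trait = paste0(cat_i, " trait"),
                              category = cat_i, pval = 10^lp,
                              stringsAsFactors = FALSE)
    }
    if (kb > 0) {
      benign <- sample(variant_ids, kb)
      rows$ben <- data.frame(variant_id = benign, trait = "benign trait",
                             category = "benign",
                             pval = stats::runif(kb, 1e-6, 1e-3),
                             stringsAsFactors = FALSE)
    }
    out <- if (length(rows) > 0) do.call(rbind, rows) else
      data.frame(variant_id = character(0), trait = character(0),
                 category = character(0), pval = numeric(0),
                 stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
  })
}

#' Canonical simulation scenarios
#'
#' Named [synthetic_truth()] configurations covering the estimators'
#' validity conditions: `null` (no causal effect, all instruments valid),
#' `causal` (theta = 0.1, valid instruments), `balanced_pleiotropy`
#' (zero-mean direct effects), `directional_pleiotropy` (mean-0.05 direct
#' effects, InSIDE holds), `inside_violated` (direct effects correlated
#' with instrument strength), `minority_invalid` (30% of instruments
#' carry directional direct effects) and `majority_invalid` (60%; the
#' weighted-median consistency condition is void here).
#'
#' @param J Instruments per scenario.
#' @param theta Causal effect for the non-null scenarios.
#' @param seed Master seed; each scenario derives its own.
#' @return Named list of `synthetic_truth` objects.
#' @export
scenario_suite <- function(J = 30, theta = 0.1, seed = 1) {
  mk <- function(name, th, law) {
    synthetic_truth(theta = th, J = J, pleiotropy = law,
                    seed = derive_seed(seed, "scenario", name))
  }
  list(
    null = mk("null", 0, pleiotropy_law("none")),
    causal = mk("causal", theta, pleiotropy_law("none")),
    balanced_pleiotropy = mk("balanced_pleiotropy", theta,
                             pleiotropy_law("balanced", sigma = 0.01)),
    directional_pleiotropy = mk("directional_pleiotropy", theta,
                                pleiotropy_law("directional", mu = 0.05,
                                               sigma = 0.01)),
    inside_violated = mk("inside_violated", theta,
                         pleiotropy_law("inside_violated", sigma = 0.03,
                                        rho = 0.7)),
    minority_invalid = mk("minority_invalid", theta,
                          pleiotropy_law("contaminated", mu = 0.05,
                                         sigma = 0.01, fraction = 0.3)),
    majority_invalid = mk("majority_invalid", theta,
                          pleiotropy_law("contaminated", mu = 0.05,
                                         sigma = 0.01, fraction = 0.6))
  )
}
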