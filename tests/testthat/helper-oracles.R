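# Independent oracles used to cross-check the estimators and selection
# algorithms. These are deliberately coded from the defining formulas
# (explicit sums, normal-equation solves, linear scans) and share no code
# with the implementation under test.

oracle_ivw <- function(bx, by, se_y) {
  w <- 1 / se_y^2
  theta <- sum(w * bx * by) / sum(w * bx^2)
  se_fixed <- 1 / sqrt(sum(w * bx^2))
  q <- sum(w * (by - theta * bx)^2)
  list(theta = theta, se_fixed = se_fixed, q = q,
       se_re = se_fixed * max(1, sqrt(q / (length(bx) - 1))))
}

oracle_egger <- function(bx, by, se_y) {
  s <- ifelse(bx < 0, -1, 1)
  bx <- bx * s
  by <- by * s
  w <- 1 / se_y^2
  # 2x2 weighted normal equations for (intercept, slope)
  a11 <- sum(w); a12 <- sum(w * bx); a22 <- sum(w * bx^2)
  b1 <- sum(w * by); b2 <- sum(w * bx * by)
  det <- a11 * a22 - a12^2
  alpha <- (a22 * b1 - a12 * b2) / det
  slope <- (a11 * b2 - a12 * b1) / det
  j <- length(bx)
  resid <- by - alpha - slope * bx
  sigma2 <- sum(w * resid^2) / (j - 2)
  scale <- max(1, sqrt(sigma2))
  se_alpha <- sqrt(a22 / det) * scale
  se_slope <- sqrt(a11 / det) * scale
  list(intercept = alpha, slope = slope,
       se_intercept = se_alpha, se_slope = se_slope,
       p_intercept = 2 * pt(-abs(alpha / se_alpha), j - 2),
       p_slope = 2 * pt(-abs(slope / se_slope), j - 2))
}

oracle_weighted_median <- function(theta, w) {
  o <- order(theta)
  theta <- theta[o]
  w <- w[o] / sum(w)
  s <- cumsum(w) - w / 2
  approx(x = s, y = theta, xout = 0.5, rule = 2, ties = "ordered")$y
}

# Brute-force greedy clump over explicit pairwise lookups.
oracle_clump <- function(rec, r2_fun, clump_r2, window) {
  rec <- rec[order(rec$pval, rec$variant_id), , drop = FALSE]
  kept <- character(0)
  alive <- rep(TRUE, nrow(rec))
  repeat {
    i <- which(alive)
    if (length(i) == 0) break
    i <- i[1]
    kept <- c(kept, rec$variant_id[i])
    alive[i] <- FALSE
    for (k in which(alive)) {
      if (rec$chrom[k] == rec$chrom[i] &&
          abs(rec$pos[k] - rec$pos[i]) <= window &&
          r2_fun(rec$variant_id[i], rec$variant_id[k]) >= clump_r2) {
        alive[k] <- FALSE
      }
    }
  }
  kept
}

# Random well-formed GWAS records (eaf/n occasionally missing).
random_records <- function(n, seed) {
  set.seed(seed)
  data.frame(
    variant_id = sprintf("rs%05d", sample.int(99999, n)),
    chrom = as.character(sample(1:22, n, replace = TRUE)),
    pos = sample.int(2e8, n),
    effect_allele = sample(c("A", "C"), n, replace = TRUE),
    other_allele = sample(c("G", "T"), n, replace = TRUE),
    eaf = ifelse(runif(n) < 0.8, runif(n), NA),
    beta = rnorm(n, 0, 0.1),
    se = runif(n, 0.005, 0.05),
    pval = runif(n),
    n = ifelse(runif(n) < 0.8, sample.int(1e6, n), NA),
    stringsAsFactors = FALSE
  )
}

make_pairs <- function(bx, by, se_x = 0.01, se_y = 1) {
  j <- length(bx)
  data.frame(variant_id = sprintf("rs%04d", seq_len(j)),
             beta_exposure = bx, se_exposure = rep_len(se_x, j),
             beta_outcome = by, se_outcome = rep_len(se_y, j),
             stringsAsFactors = FALSE)
}

random_pairs <- function(j, seed) {
  set.seed(seed)
  make_pairs(bx = rnorm(j, 0, 1), by = rnorm(j, 0, 1),
             se_x = runif(j, 0.01, 0.1), se_y = runif(j, 0.5, 1.5))
}

single_record <- function(variant_id = "rs1", ea = "A", oa = "G",
                          beta = 0.1, se = 0.02, eaf = 0.3, pval = 1e-6,
                          chrom = "1", pos = 1000) {
  data.frame(variant_id = variant_id, chrom = chrom, pos = pos,
             effect_allele = ea, other_allele = oa, eaf = eaf,
             beta = beta, se = se, pval = pval, n = 1e5,
             stringsAsFactors = FALSE)
}
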