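test_that("Wald ratio arithmetic and delta-method error are exact", {
  p <- make_pairs(bx = 0.2, by = 0.1, se_x = 0.01, se_y = 0.05)
  est <- wald_ratio(p[1, ])
  expect_equal(est$theta, 0.5)
  expect_equal(est$se, 0.25)

  null <- wald_ratio(make_pairs(0.2, 0, se_y = 0.05)[1, ])
  expect_equal(null$theta, 0)
  expect_equal(null$pval, 1)

  expect_error(wald_ratio(make_pairs(0, 0.1)[1, ]), "beta_exposure")

  set.seed(131)
  for (i in 1:50) {
    bx <- rnorm(1); by <- rnorm(1)
    se_x <- runif(1, 0.01, 0.2); se_y <- runif(1, 0.1, 1)
    pp <- make_pairs(bx, by, se_x, se_y)[1, ]
    expect_equal(wald_ratio(pp)$theta, by / bx, tolerance = 1e-12)
    expect_equal(wald_ratio(pp)$se, se_y / abs(bx), tolerance = 1e-12)
    expect_equal(wald_ratio(pp, second_order = TRUE)$se,
                 sqrt(se_y^2 / bx^2 + by^2 * se_x^2 / bx^4),
                 tolerance = 1e-12)
  }
})

test_that("IVW reproduces the hand-computed two-variant example", {
  p <- make_pairs(bx = c(1, 1), by = c(0.5, 0.7), se_y = c(1, 1))
  est <- mr_ivw(p, "fixed")
  expect_equal(est$theta, 0.6, tolerance = 1e-12)
  expect_equal(est$se, 1 / sqrt(2), tolerance = 1e-12)
})

test_that("IVW equals the closed-form weighted regression through origin", {
  for (seed in 1:100) {
    p <- random_pairs(sample(3:12, 1), seed = seed)
    o <- oracle_ivw(p$beta_exposure, p$beta_outcome, p$se_outcome)
    fx <- mr_ivw(p, "fixed")
    re <- mr_ivw(p, "multiplicative_re")
    expect_equal(fx$theta, o$theta, tolerance = 1e-10)
    expect_equal(fx$se, o$se_fixed, tolerance = 1e-10)
    expect_equal(re$theta, o$theta, tolerance = 1e-10)
    expect_equal(re$se, o$se_re, tolerance = 1e-10)
  }
})

test_that("IVW degenerate and single-pair behaviour follows the contract", {
  expect_error(mr_ivw(make_pairs(c(0, 0), c(0.1, 0.2))), "degenerate")
  one <- mr_ivw(make_pairs(0.2, 0.1, se_y = 0.05), "fixed")
  expect_equal(one$method, "wald_ratio")
  expect_equal(one$theta, 0.5)
  # equal weights and equal exposure effects reduce to a mean of ratios
  p <- make_pairs(bx = rep(0.5, 4), by = c(0.1, 0.2, 0.3, 0.4),
                  se_y = rep(1, 4))
  expect_equal(mr_ivw(p, "fixed")$theta,
               mean(p$beta_outcome / p$beta_exposure), tolerance = 1e-12)
})

test_that("MR-Egger equals the normal-equations oracle", {
  for (seed in 1:100) {
    p <- random_pairs(sample(4:15, 1), seed = seed + 500)
    o <- oracle_egger(p$beta_exposure, p$beta_outcome, p$se_outcome)
    eg <- mr_egger(p)
    expect_equal(eg$slope$theta, o$slope, tolerance = 1e-10)
    expect_equal(eg$slope$se, o$se_slope, tolerance = 1e-10)
    expect_equal(eg$intercept$theta, o$intercept, tolerance = 1e-10)
    expect_equal(eg$intercept$se, o$se_intercept, tolerance = 1e-10)
    expect_equal(eg$intercept$pval, o$p_intercept, tolerance = 1e-10)
  }
})

test_that("MR-Egger recovers exact-fit and offset constructions", {
  bx <- c(0.1, 0.25, 0.4, 0.6, 0.9)
  exact <- make_pairs(bx, by = 0.7 * bx, se_y = 0.5)
  eg <- mr_egger(exact)
  expect_equal(eg$slope$theta, 0.7, tolerance = 1e-12)
  expect_equal(eg$intercept$theta, 0, tolerance = 1e-12)
  expect_equal(eg$intercept$pval, 1, tolerance = 1e-12)

  offset <- make_pairs(bx, by = 0.03 + 0.7 * bx, se_y = 0.5)
  eg2 <- mr_egger(offset)
  expect_equal(eg2$intercept$theta, 0.03, tolerance = 1e-12)
  expect_equal(eg2$slope$theta, 0.7, tolerance = 1e-12)

  expect_error(mr_egger(make_pairs(c(1, 2), c(1, 2))), "insufficient")
})

test_that("weighted median interpolates the weighted order statistics", {
  p <- make_pairs(bx = c(1, 1, 1), by = c(0.4, 0.5, 0.9), se_y = 1)
  est <- mr_weighted_median(p, n_boot = 0)
  expect_equal(est$theta, 0.5, tolerance = 1e-12)

  for (seed in 1:100) {
    p <- random_pairs(sample(3:20, 1), seed = seed + 900)
    ratios <- p$beta_outcome / p$beta_exposure
    w <- (p$beta_exposure / p$se_outcome)^2
    expect_equal(mr_weighted_median(p, n_boot = 0)$theta,
                 oracle_weighted_median(ratios, w), tolerance = 1e-10)
  }
})

test_that("the weighted-median bootstrap is seeded and reproducible", {
  p <- random_pairs(10, seed = 141)
  a <- mr_weighted_median(p, n_boot = 300, seed = 7)
  b <- mr_weighted_median(p, n_boot = 300, seed = 7)
  expect_identical(a$se, b$se)
  c <- mr_weighted_median(p, n_boot = 300, seed = 8)
  expect_false(identical(a$se, c$se))
  expect_error(mr_weighted_median(p, n_boot = 100), "seed")
})

test_that("all estimators agree on exact linear data through the origin", {
  bx <- c(-0.3, 0.12, 0.25, 0.4, 0.65)
  p <- make_pairs(bx, by = 1.3 * bx, se_y = c(0.4, 0.6, 0.5, 0.7, 0.45))
  expect_equal(mr_ivw(p, "fixed")$theta, 1.3, tolerance = 1e-10)
  expect_equal(mr_egger(p)$slope$theta, 1.3, tolerance = 1e-10)
  expect_equal(mr_weighted_median(p, n_boot = 0)$theta, 1.3,
               tolerance = 1e-10)
})

test_that("estimates are scale-equivariant in the exposure effects", {
  p <- random_pairs(12, seed = 151)
  for (c0 in c(2, -0.5)) {
    p2 <- p
    p2$beta_exposure <- p$beta_exposure * c0
    expect_equal(mr_ivw(p2, "fixed")$theta, mr_ivw(p, "fixed")$theta / c0,
                 tolerance = 1e-10)
    expect_equal(mr_egger(p2)$slope$theta, mr_egger(p)$slope$theta / c0,
                 tolerance = 1e-10)
    expect_equal(mr_weighted_median(p2, n_boot = 0)$theta,
                 mr_weighted_median(p, n_boot = 0)$theta / c0,
                 tolerance = 1e-10)
  }
})

test_that("run_all_methods handles preconditions and the CI identity", {
  p2 <- make_pairs(c(0.2, 0.3), c(0.1, 0.2), se_y = 0.1)
  res <- run_all_methods(p2, mr_config(seed = 1))
  expect_true(all(is.finite(res$theta[res$method %in% c("ivw_fixed",
                                                        "ivw_re")])))
  expect_true(all(is.na(res$theta[res$method %in%
                                    c("weighted_median", "egger_slope")])))
  expect_match(res$note[res$method == "weighted_median"], "not computed")

  p1 <- make_pairs(0.2, 0.1, se_y = 0.1)
  res1 <- run_all_methods(p1, mr_config(seed = 1))
  expect_true("wald_ratio" %in% res1$method)

  tr <- synthetic_truth(theta = 0.2, J = 12, seed = 161)
  h <- simulate_harmonized(tr)
  cfg <- mr_config(seed = 5, n_boot = 200)
  full <- run_all_methods(h, cfg)
  emitted <- full[!is.na(full$se), ]
  zq <- qnorm(0.975)
  tq <- qt(0.975, nrow(h$pairs) - 2)
  q <- ifelse(emitted$method %in% c("egger_slope", "egger_intercept"),
              tq, zq)
  expect_equal(emitted$ci_low, emitted$theta - q * emitted$se,
               tolerance = 1e-12)
  expect_equal(emitted$ci_high, emitted$theta + q * emitted$se,
               tolerance = 1e-12)

  # identical configuration implies bitwise-identical stochastic output
  full2 <- run_all_methods(h, cfg)
  expect_identical(full$se, full2$se)
})
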