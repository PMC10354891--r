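test_that("p-value filtering is strict and order-preserving", {
  rec <- rbind(single_record("rs1", pval = 1e-6),
               single_record("rs2", pval = 1e-5),
               single_record("rs3", pval = 2e-5))
  expect_equal(filter_by_pvalue(rec, 1e-5)$variant_id, "rs1")
  expect_equal(filter_by_pvalue(rec, 1)$variant_id,
               c("rs1", "rs2", "rs3"))

  rec2 <- random_records(200, seed = 31)
  thr <- 0.3
  got <- filter_by_pvalue(rec2, thr)$variant_id
  want <- character(0)                      # loop-based oracle
  for (i in seq_len(nrow(rec2))) {
    if (rec2$pval[i] < thr) want <- c(want, rec2$variant_id[i])
  }
  expect_identical(got, want)
})

test_that("per-variant F statistic is the squared Wald z-score", {
  expect_equal(per_snp_f(0.02, 0.004), 25)
  expect_equal(per_snp_f(0, 0.01), 0)
  set.seed(41)
  beta <- rnorm(50)
  se <- runif(50, 0.1, 1)
  expect_equal(per_snp_f(beta, se), (beta / se)^2, tolerance = 1e-15)
  expect_error(per_snp_f(0.1, 0), "se")
})

test_that("LD clumping keeps the most significant variant per region", {
  expect_equal(as.character(ld_clump(single_record("rs1"))), "rs1")

  rec <- rbind(single_record("rs1", pos = 1000, pval = 1e-8),
               single_record("rs2", pos = 2000, pval = 1e-6))
  ld <- ld_reference(c("rs1", "rs2"),
                     matrix(c(1, 0.5, 0.5, 1), 2, 2))
  expect_equal(as.character(ld_clump(rec, ld)), "rs1")
})

test_that("clumping matches the brute-force oracle and pairwise audit", {
  for (seed in 1:10) {
    set.seed(seed)
    k <- 20
    ids <- sprintf("v%02d", 1:k)
    a <- matrix(runif(k * k), k)
    r2 <- (a + t(a)) / 2
    diag(r2) <- 1
    dimnames(r2) <- list(ids, ids)
    rec <- data.frame(variant_id = ids,
                      chrom = as.character(sample(1:2, k, replace = TRUE)),
                      pos = sample.int(3e7, k),
                      effect_allele = "A", other_allele = "G",
                      eaf = 0.3, beta = 0.1, se = 0.02,
                      pval = runif(k), n = 1e5,
                      stringsAsFactors = FALSE)
    ld <- ld_reference(ids, r2)
    got <- as.character(ld_clump(rec, ld, clump_r2 = 0.3,
                                 clump_window_bp = 1e7))
    want <- oracle_clump(rec, function(i, j) r2[i, j], 0.3, 1e7)
    expect_identical(got, want)
    # no surviving pair violates the independence criterion
    for (i in got) for (j in got) {
      if (i != j &&
          rec$chrom[rec$variant_id == i] == rec$chrom[rec$variant_id == j] &&
          abs(rec$pos[rec$variant_id == i] -
              rec$pos[rec$variant_id == j]) <= 1e7) {
        expect_lt(r2[i, j], 0.3)
      }
    }
    # invariant to input row order
    perm <- sample.int(k)
    expect_identical(as.character(ld_clump(rec[perm, ], ld, 0.3, 1e7)), got)
  }
})

test_that("variants absent from the LD reference are kept as independent", {
  rec <- rbind(single_record("rs1", pos = 1000, pval = 1e-8),
               single_record("rs2", pos = 2000, pval = 1e-6))
  kept <- ld_clump(rec, ld_reference("rs1", matrix(1, 1, 1)))
  expect_setequal(as.character(kept), c("rs1", "rs2"))
  expect_equal(attr(kept, "not_in_ld"), "rs2")
})

test_that("proxy search returns the strongest qualifying partner", {
  out <- summary_dataset("o", "outcome",
                         rbind(single_record("rs2"), single_record("rs3")))
  r2 <- matrix(c(1, 0.9, 0.85, 0.9, 1, 0, 0.85, 0, 1), 3, 3)
  ld <- ld_reference(c("rs1", "rs2", "rs3"), r2)
  px <- find_proxy("rs1", out, ld)
  expect_equal(px$variant_id, "rs2")
  expect_equal(px$r2, 0.9)

  # boundary: r2 exactly at the threshold does not qualify (strict >)
  r2b <- matrix(c(1, 0.8, 0.8, 1), 2, 2)
  expect_null(find_proxy("rs1", out, ld_reference(c("rs1", "rs2"), r2b)))
  expect_null(find_proxy("rs1", out, NULL))
})

test_that("proxy search equals an argmax scan on random candidates", {
  set.seed(51)
  k <- 51
  ids <- c("target", sprintf("c%02d", 1:(k - 1)))
  r2 <- diag(k)
  r2[1, -1] <- r2[-1, 1] <- runif(k - 1)
  ld <- ld_reference(ids, r2)
  out_rec <- do.call(rbind, lapply(ids[-1], function(v) {
    single_record(v, pos = sample.int(1e6, 1))
  }))
  out <- summary_dataset("o", "outcome", out_rec)
  px <- find_proxy("target", out, ld, proxy_r2 = 0.5)
  best <- NULL; best_r2 <- 0.5              # linear-scan oracle
  for (v in ids[-1]) {
    if (r2[1, match(v, ids)] > best_r2) {
      best_r2 <- r2[1, match(v, ids)]
      best <- v
    }
  }
  expect_equal(px$variant_id, best)
  expect_equal(px$r2, best_r2)
})

test_that("confounder pruning removes only sub-threshold listed categories", {
  ann <- data.frame(
    variant_id = c("rs332040", "rs2", "rs3"),
    trait = c("worry or anxiety", "height", "body mass index"),
    category = c("psychiatric", "anthropometric", "obesity"),
    pval = c(5.28e-22, 1e-30, 1e-6),
    stringsAsFactors = FALSE)
  cats <- c("psychiatric", "obesity")
  res <- confounder_filter(c("rs332040", "rs2", "rs3"), ann, cats, 5e-8)
  expect_equal(res$kept, c("rs2", "rs3"))   # rs2: category not listed;
  expect_equal(res$removal_log$variant_id, "rs332040")  # rs3: p above cut
  expect_equal(res$removal_log$trait, "worry or anxiety")
  expect_equal(res$removal_log$pval, 5.28e-22)
})

test_that("confounder pruning matches a set-comprehension oracle", {
  set.seed(61)
  ids <- sprintf("rs%03d", 1:100)
  ann <- data.frame(
    variant_id = sample(ids, 150, replace = TRUE),
    trait = "t",
    category = sample(c("psychiatric", "obesity", "benign"), 150,
                      replace = TRUE),
    pval = 10^runif(150, -12, -2),
    stringsAsFactors = FALSE)
  cats <- c("psychiatric", "obesity")
  res <- confounder_filter(ids, ann, cats, 5e-8)
  bad <- unique(ann$variant_id[ann$category %in% cats & ann$pval < 5e-8])
  expect_setequal(res$kept, setdiff(ids, bad))
  expect_identical(res$kept, ids[!ids %in% bad])  # order preserved
})

test_that("full instrument selection composes the stages with audit", {
  tr <- synthetic_truth(theta = 0.3, J = 3, n_null_snps = 47, seed = 71)
  d <- simulate_pair(tr)
  inst <- select_instruments(d$exposure, d$outcome,
                             config = mr_config(seed = 1))
  expect_equal(nrow(inst$selected), 3)
  expect_setequal(inst$selected$variant_id,
                  d$truth_table$variant_id[d$truth_table$is_instrument])
  expect_true(all(diff(inst$audit) <= 0))   # monotone attrition
  expect_true(all(inst$f_stats >= 10))
  expect_false(inst$no_instruments)
})

test_that("no variant below threshold yields an explicit empty result", {
  rec <- rbind(single_record("rs1", pval = 0.5),
               single_record("rs2", pval = 0.9))
  exp <- summary_dataset("e", "exposure", rec)
  out <- summary_dataset("o", "outcome", rec)
  inst <- select_instruments(exp, out, config = mr_config(seed = 1))
  expect_true(inst$no_instruments)
  expect_equal(unname(inst$audit["input"]), 2)
  expect_equal(unname(inst$audit["post_p_filter"]), 0)
})

test_that("an instrument missing from the outcome is replaced by its proxy", {
  tr <- synthetic_truth(theta = 0.3, J = 4, seed = 81,
                        ld_blocks = list(sizes = c(2, 1, 1), r2 = 0.95),
                        palindromic_fraction = 0)
  d <- simulate_pair(tr)
  ld <- simulate_ld(d$exposure$records$variant_id, c(2, 1, 1),
                    within_r2 = 0.95)
  # make the block lead the clump index, then drop it from the outcome so
  # its block-mate must stand in as proxy
  ids <- d$exposure$records$variant_id
  erec <- d$exposure$records
  erec$pval[1] <- 1e-250
  exp <- summary_dataset("e", "exposure", erec)
  out_rec <- d$outcome$records[d$outcome$records$variant_id != ids[1], ]
  out <- summary_dataset("o", "outcome", out_rec)
  inst <- select_instruments(exp, out, ld, config = mr_config(seed = 1))
  expect_false(ids[1] %in% inst$selected$variant_id)
  expect_equal(inst$proxy_log$variant_id, ids[1])
  expect_equal(inst$proxy_log$proxy, ids[2])
  expect_true(ids[2] %in% inst$selected$variant_id)
  expect_true(all(diff(inst$audit) <= 0))
})
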