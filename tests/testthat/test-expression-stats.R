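make_ct <- function(dct_control, dct_treated, base_ref = 15) {
  rows <- list()
  for (i in seq_along(dct_control)) {
    rows[[length(rows) + 1L]] <- data.frame(
      sample = sprintf("c%d", i), condition = "control",
      gene = c("GAPDH", "ernaX"),
      ct = c(base_ref, base_ref + dct_control[i]))
  }
  for (i in seq_along(dct_treated)) {
    rows[[length(rows) + 1L]] <- data.frame(
      sample = sprintf("t%d", i), condition = "treated",
      gene = c("GAPDH", "ernaX"),
      ct = c(base_ref, base_ref + dct_treated[i]))
  }
  do.call(rbind, rows)
}

test_that("ddCt identities: no change gives 1, one-cycle shift gives 0.5", {
  ct <- make_ct(rep(5, 4), rep(5, 4))
  fc <- ddct_fold_change(ct, "ernaX", "GAPDH")
  expect_equal(fc$fold_change, rep(1, 8))

  ct2 <- make_ct(rep(5, 4), rep(6, 4))
  fc2 <- ddct_fold_change(ct2, "ernaX", "GAPDH")
  expect_equal(fc2$fold_change[fc2$condition == "treated"], rep(0.5, 4))
  # control group's own median fold change is 1 by construction
  expect_equal(median(fc2$fold_change[fc2$condition == "control"]), 1)

  # a different amplification efficiency changes the exponent base
  fc3 <- ddct_fold_change(ct2, "ernaX", "GAPDH", efficiency = 1.9)
  expect_equal(fc3$fold_change[fc3$condition == "treated"],
               rep(1.9^-1, 4))
})

test_that("ddCt is invariant to a constant added to all Cts of a sample", {
  withr::with_seed(71, {
    ct <- make_ct(rnorm(5, 5), rnorm(5, 6))
    fc <- ddct_fold_change(ct, "ernaX", "GAPDH")
    ct_shift <- ct
    for (s in unique(ct$sample)) {
      delta <- runif(1, -3, 3)
      ct_shift$ct[ct_shift$sample == s] <-
        ct_shift$ct[ct_shift$sample == s] + delta
    }
    fc_shift <- ddct_fold_change(ct_shift, "ernaX", "GAPDH")
    expect_equal(fc_shift$fold_change, fc$fold_change)
  })
})

test_that("ddCt matches a spreadsheet-style recomputation on random tables", {
  withr::with_seed(72, {
    for (rep in 1:4) {
      dc <- rnorm(5, 5, 0.5); dt <- rnorm(5, 6, 0.5)
      ct <- make_ct(dc, dt)
      fc <- ddct_fold_change(ct, "ernaX", "GAPDH")
      # independent recompute: dCt - median(control dCt), then 2^-ddCt
      expected <- 2^(-(c(dc, dt) - median(dc)))
      expect_equal(fc$fold_change, expected)
    }
  })
  # missing reference drops the sample with a warning
  ct <- make_ct(rep(5, 3), rep(6, 3))
  ct <- ct[!(ct$sample == "t1" & ct$gene == "GAPDH"), ]
  expect_warning(fc <- ddct_fold_change(ct, "ernaX", "GAPDH"), "excluded")
  expect_false("t1" %in% fc$sample)
})

test_that("signed-rank exact p equals sign-flip enumeration for all n <= 10", {
  withr::with_seed(73, {
    for (n in 3:10) {
      for (rep in 1:3) {
        d <- round(rnorm(n), 1)
        d[d == 0] <- 0.1
        got <- wilcoxon_test(d, 0, mode = "signed_rank")
        expect_equal(got$method, "exact_enumeration")
        expect_equal(got$p_value, oracle_wilcoxon_signed_p(d))
      }
    }
    # agreement with stats::wilcox.test in the tie-free exact regime
    for (rep in 1:5) {
      d <- rnorm(9)
      got <- wilcoxon_test(d, 0)
      ref <- stats::wilcox.test(d, mu = 0, exact = TRUE)
      expect_equal(got$p_value, ref$p.value)
      expect_equal(unname(got$statistic), unname(ref$statistic))
    }
  })
})

test_that("one-sample worked example and zero-difference policy", {
  got <- wilcoxon_test(c(0.4, 0.5, 0.6, 0.45, 0.55), 1)
  expect_equal(got$p_value,
               oracle_wilcoxon_signed_p(c(0.4, 0.5, 0.6, 0.45, 0.55) - 1))
  expect_equal(got$p_value, 2 / 32)  # all five differences negative

  # identical paired vectors: every difference dropped, flagged undefined
  same <- wilcoxon_test(c(1, 2, 3), c(1, 2, 3))
  expect_true(same$flagged)
  expect_true(is.na(same$p_value))
  expect_equal(same$n_dropped, 3L)
})

test_that("rank-sum exact p equals assignment enumeration and handles ties", {
  withr::with_seed(74, {
    for (rep in 1:5) {
      a <- sample(1:5, 5, replace = TRUE)
      b <- sample(1:5, 6, replace = TRUE)
      got <- wilcoxon_test(a, b, mode = "rank_sum")
      expect_equal(got$method, "exact_enumeration")
      expect_equal(got$p_value, oracle_wilcoxon_ranksum_p(a, b))
    }
    # large-sample normal path stays close to wilcox.test with correction
    a <- rnorm(20); b <- rnorm(20, 0.5)
    got <- wilcoxon_test(a, b, mode = "rank_sum")
    ref <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
  })
})

test_that("pooled t-test matches the closed form and handles degeneracy", {
  expect_equal(students_t_test(c(1, 2, 3), c(1, 2, 3))$statistic, 0)
  same <- students_t_test(c(2, 2, 2), c(2, 2, 2))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  degen <- students_t_test(c(2, 2, 2), c(3, 3, 3))
  expect_true(degen$flagged)

  withr::with_seed(75, {
    for (rep in 1:5) {
      a <- rnorm(6); b <- rnorm(8, 0.5)
      got <- students_t_test(a, b)
      # textbook pooled-variance formula, computed independently
      sp2 <- ((6 - 1) * var(a) + (8 - 1) * var(b)) / (6 + 8 - 2)
      tstat <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 6 + 1 / 8))
      expect_equal(got$statistic, tstat)
      expect_equal(got$p_value, 2 * pt(-abs(tstat), 12))
    }
  })
})

test_that("viability normalizes each arm to its own drug-free mean", {
  v <- data.frame(cell_line = "L1",
                  arm = rep(c("targeting", "scrambled"), each = 4),
                  concentration = rep(c(0, 0, 5, 5), 2),
                  value = c(100, 100, 50, 60, 200, 200, 150, 170))
  nv <- normalize_viability(v)
  expect_equal(nv$normalized,
               c(1, 1, 0.5, 0.6, 1, 1, 0.75, 0.85))
  # all-equal table normalizes to all ones
  v2 <- v; v2$value <- 7
  expect_equal(normalize_viability(v2)$normalized, rep(1, 8))
  # random table equals brute-force groupwise division
  withr::with_seed(76, {
    v3 <- data.frame(cell_line = sample(c("A", "B"), 30, TRUE),
                     arm = sample(c("targeting", "scrambled"), 30, TRUE),
                     concentration = sample(c(0, 3, 5), 30, TRUE),
                     value = runif(30, 10, 100))
    # guarantee a drug-free row per group
    combos <- unique(v3[c("cell_line", "arm")])
    extra <- data.frame(cell_line = combos$cell_line, arm = combos$arm,
                        concentration = 0, value = 50)
    v3 <- rbind(v3, extra)
    nv3 <- normalize_viability(v3)
    for (i in seq_len(nrow(v3))) {
      grp <- v3$cell_line == v3$cell_line[i] & v3$arm == v3$arm[i]
      expect_equal(nv3$normalized[i],
                   v3$value[i] / mean(v3$value[grp & v3$concentration == 0]))
    }
  })
  # missing drug-free row is a named error
  v4 <- v[v$concentration != 0 | v$arm != "targeting", ]
  expect_error(normalize_viability(v4), "targeting")
})

test_that("synthetic knockdown tables recover the planted fold change", {
  # noise-free closed forms
  ct0 <- simulate_knockdown_ct(n_experiments = 4, true_fold = 1,
                               ct_noise_sd = 0, seed = 1)
  fc0 <- ddct_fold_change(ct0, "eRNA1", "GAPDH")
  expect_equal(fc0$fold_change, rep(1, 8))
  ct5 <- simulate_knockdown_ct(n_experiments = 4, true_fold = 0.5,
                               ct_noise_sd = 0, seed = 1)
  fc5 <- ddct_fold_change(ct5, "eRNA1", "GAPDH")
  expect_equal(fc5$fold_change[fc5$condition == "treated"], rep(0.5, 4))

  # with realistic noise the median treated fold stays in the two-fold
  # knockdown regime for most seeds
  hits <- 0L
  for (s in 1:10) {
    ct <- simulate_knockdown_ct(n_experiments = 8, true_fold = 0.5,
                                ct_noise_sd = 0.3, seed = s)
    fc <- ddct_fold_change(ct, "eRNA1", "GAPDH")
    med <- median(fc$fold_change[fc$condition == "treated"])
    if (med >= 0.4 && med <= 0.6) hits <- hits + 1L
  }
  expect_gte(hits, 8L)
})
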