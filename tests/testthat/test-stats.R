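test_that("bland_altman degenerate cases: zero and constant differences", {
  x <- c(1, 2, 3, 4, 5)
  ba0 <- bland_altman(x, x)
  expect_equal(ba0$bias, 0)
  expect_equal(c(ba0$loa_low, ba0$loa_high), c(0, 0))
  expect_equal(ba0$n_outside, 0)
  expect_equal(ba0$p_bias, 1)

  ba5 <- bland_altman(x, x + 5)
  expect_equal(ba5$bias, 5)
  expect_equal(c(ba5$loa_low, ba5$loa_high), c(5, 5))
  expect_true(ba5$degenerate)
  expect_equal(ba5$p_bias, 0)

  expect_error(bland_altman(1:2, 2:3), "at least 3")
  expect_error(bland_altman(1:4, 1:5), "paired")
})

test_that("bland_altman matches the 1.96*SD definition against base R", {
  set.seed(13)
  m <- rnorm(40, 100, 10); a <- m + rnorm(40, 2, 3)
  ba <- bland_altman(m, a)
  d <- a - m
  expect_equal(ba$bias, mean(d))
  expect_equal(ba$loa_high, mean(d) + 1.96 * sd(d))
  expect_equal(ba$loa_low, mean(d) - 1.96 * sd(d))
  expect_equal(ba$p_bias, t.test(d)$p.value)
  expect_equal(ba$shapiro_p, shapiro.test(d)$p.value)
})

test_that("bland_altman flags non-normal differences as not applicable", {
  set.seed(14)
  m <- rnorm(60)
  a <- m + rexp(60)^3  # strongly skewed differences
  ba <- bland_altman(m, a)
  expect_lt(ba$shapiro_p, 0.05)
  expect_false(ba$applicable)
})

test_that("wilcoxon: all-zero differences give the flagged p = 1 result", {
  w <- wilcoxon_signed_rank(1:8, 1:8)
  expect_true(w$no_difference)
  expect_equal(w$p_value, 1)
  expect_equal(w$n_nonzero, 0)
  expect_error(wilcoxon_signed_rank(c(1, 2, 3, 4, 5, 6), c(1, 2, 3, 4, 5, 7)),
               "nonzero")
})

test_that("wilcoxon exact tail: n=6 all-positive differences give P = 1/32", {
  m <- rep(0, 6)
  a <- c(1, 2, 3, 4, 5, 6)
  w <- wilcoxon_signed_rank(m, a)
  expect_identical(w$method, "exact")
  expect_equal(w$p_value, 2 / 64)
  expect_equal(w$w_plus, 21)
})

test_that("wilcoxon exact equals enumeration oracle and base R (no ties)", {
  set.seed(15)
  for (n in 5:10) {
    for (rep in 1:3) {
      d <- round(rnorm(n, 0.3, 1), 3)
      d <- d[d != 0]
      if (length(d) < 5) next
      w <- wilcoxon_signed_rank(rep(0, length(d)), d)
      expect_equal(w$p_value, oracle_signed_rank_p(d), tolerance = 1e-12)
      # independent cross-check against the reference implementation
      expect_equal(w$p_value,
                   suppressWarnings(wilcox.test(d, exact = TRUE)$p.value),
                   tolerance = 1e-9)
    }
  }
})

test_that("wilcoxon exact handles midrank ties via enumeration", {
  set.seed(16)
  for (rep in 1:5) {
    d <- sample(c(-3, -2, -1, 1, 1, 2, 2, 3), 7, replace = TRUE)
    d <- d[d != 0]
    if (length(d) < 5) next
    w <- wilcoxon_signed_rank(rep(0, length(d)), d)
    expect_equal(w$p_value, oracle_signed_rank_p(d), tolerance = 1e-12)
  }
})

test_that("wilcoxon normal path agrees with base R continuity correction", {
  set.seed(17)
  m <- rnorm(60); a <- m + rnorm(60, 0.3)
  w <- wilcoxon_signed_rank(m, a, exact_max = 25)
  ref <- wilcox.test(a, m, paired = TRUE, exact = FALSE, correct = TRUE)
  expect_identical(w$method, "normal")
  expect_equal(w$p_value, ref$p.value, tolerance = 1e-9)
})

test_that("spearman: perfect concordance/discordance and monotone invariance", {
  x <- c(3, 1, 4, 1.5, 9, 2.6)
  y <- exp(x)  # strictly monotone transform
  expect_equal(spearman_rank(x, y)$r, 1)
  expect_equal(spearman_rank(x, -y)$r, -1)
  set.seed(18)
  a <- rnorm(20); b <- rnorm(20)
  r0 <- spearman_rank(a, b)$r
  expect_equal(spearman_rank(exp(a), b)$r, r0)
  expect_equal(spearman_rank(a, b^3 + 5 * b)$r, r0)
  expect_error(spearman_rank(rep(1, 6), 1:6), "constant")
  expect_error(spearman_rank(1:3, 1:3), "n >= 4")
})

test_that("spearman equals Pearson-on-midranks oracle and base R with ties", {
  x <- c(1, 2, 2, 3, 3, 3, 7, 8)
  y <- c(5, 5, 6, 6, 9, 9, 9, 10)
  s <- spearman_rank(x, y)
  oracle <- cor(rank(x), rank(y))  # Pearson on midranks
  expect_equal(s$r, oracle, tolerance = 1e-12)
  ref <- suppressWarnings(cor.test(x, y, method = "spearman"))
  expect_equal(s$r, unname(ref$estimate), tolerance = 1e-12)
})

test_that("delta_dose is a magnitude and excludes incomplete pairs", {
  df <- data.frame(case_id = c("c1", "c1", "c2"),
                   structure = "CTV", metric = "D_mean",
                   manual = c(5058.71, 100, NA),
                   auto = c(4972.37, 100, 50))
  expect_message(out <- delta_dose(df), "excluded")
  expect_equal(nrow(out), 2)
  expect_equal(out$delta[1], 86.34, tolerance = 1e-9)
  expect_equal(out$delta[2], 0)
  # sign-convention flip leaves the magnitude unchanged
  df2 <- df[1:2, ]; tmp <- df2$manual; df2$manual <- df2$auto; df2$auto <- tmp
  expect_equal(delta_dose(df2)$delta, out$delta)
})

test_that("correlation table recovers planted signals and flags small cells", {
  set.seed(19)
  n <- 12
  geom <- data.frame(case_id = sprintf("c%02d", 1:n), structure = "Pelvic Bone",
                     dsc = runif(n, 0.5, 0.8), jc = runif(n, 0.4, 0.7),
                     hd95_mm = runif(n, 2, 20))
  # delta constructed as exact monotone function of hd95
  delta <- data.frame(case_id = geom$case_id, structure = "Pelvic Bone",
                      metric = "D_mean", manual = 0,
                      auto = geom$hd95_mm^2, delta = geom$hd95_mm^2)
  ct <- correlation_table(geom, delta)
  row_hd <- ct$table[ct$table$geom_metric == "95%HD", ]
  expect_equal(row_hd$r, 1)
  expect_true(row_hd$strong)
  expect_equal(dim(ct$heatmap), c(1L, 3L))

  ct2 <- correlation_table(geom[1:3, ], delta[1:3, ])
  expect_true(all(is.na(ct2$table$r)))
})

test_that("permuted deltas show small correlation on average", {
  set.seed(20)
  n <- 40
  ps <- replicate(50, {
    geom <- data.frame(case_id = seq_len(n), structure = "Bladder",
                       dsc = runif(n), jc = runif(n), hd95_mm = runif(n))
    delta <- data.frame(case_id = seq_len(n), structure = "Bladder",
                        metric = "D_mean", manual = 0, auto = 0,
                        delta = rnorm(n))
    ct <- correlation_table(geom, delta)
    ct$table$p_value[ct$table$geom_metric == "DSC"]
  })
  # p-values approximately uniform under the null
  expect_gt(mean(ps), 0.35)
  expect_lt(mean(ps), 0.65)
  expect_lt(mean(ps < 0.05), 0.15)
})
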