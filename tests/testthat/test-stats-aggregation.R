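test_that("score histograms are duration-normalised and merge by frame count", {
  h6 <- reba_histogram(rep(6L, 40))
  expect_equal(unname(h6$rel_freq["6"]), 1)
  expect_equal(h6$mean_reba, 6)
  expect_equal(reba_histogram(rep(c(4L, 8L), 25))$mean_reba, 6)
  m <- merge_reba_histograms(reba_histogram(rep(4L, 100)),
                             reba_histogram(rep(8L, 300)))
  expect_equal(m$mean_reba, 7)              # (100*4 + 300*8) / 400
  expect_equal(m$total_frames, 400L)
  ## associativity
  h1 <- reba_histogram(rep(2L, 10)); h2 <- reba_histogram(rep(5L, 30))
  h3 <- reba_histogram(rep(9L, 60))
  left <- merge_reba_histograms(merge_reba_histograms(h1, h2), h3)
  right <- merge_reba_histograms(h1, merge_reba_histograms(h2, h3))
  expect_equal(left$rel_freq, right$rel_freq)
  expect_error(reba_histogram(integer(0)), "empty")
  expect_error(reba_histogram(c(1L, 15L)), "1..14")
})

test_that("risk bands follow the published action-level edges", {
  b <- risk_bands(reba_histogram(rep(1L, 5)))
  expect_equal(unname(b["negligible"]), 1)
  scores <- c(rep(5L, 63), rep(9L, 29), rep(2L, 8))
  b2 <- risk_bands(reba_histogram(scores))
  expect_equal(unname(b2[c("medium", "high", "low")]), c(0.63, 0.29, 0.08))
  expect_equal(sum(b2), 1)
  b3 <- risk_bands(reba_histogram(rep(11L, 3)))
  expect_equal(unname(b3["very_high"]), 1)
})

test_that("MWU matches exhaustive enumeration for all group sizes up to 5", {
  set.seed(101)
  for (na in 2:5) for (nb in 2:5) {
    a <- round(rnorm(na), 6)
    b <- round(rnorm(nb, 0.5), 6)
    got <- mwu_test(a, b)
    expect_equal(got$p_value, mwu_enum_p(a, b), tolerance = 1e-12,
                 label = sprintf("exact p at n = %d + %d", na, nb))
    cd <- cliffs_delta(a, b)
    expect_equal(cd$delta, cliffs_enum(a, b), tolerance = 1e-12)
  }
  ## printed small-sample case: complete separation at n = 3 + 3
  got <- mwu_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(got$p_value, 2 / 20)         # one-sided tail 1/20, two-sided
  expect_lt(got$statistic_z, 0)             # group a stochastically smaller
})

test_that("the MWU normal approximation tracks enumeration at moderate n", {
  set.seed(55)
  a <- rnorm(8); b <- rnorm(8, 0.8)
  got <- mwu_test(a, b, exact_max = 0)      # force the normal path
  expect_equal(got$p_value, mwu_enum_p(a, b), tolerance = 0.02 / got$p_value)
  ## z sign convention and degenerate input
  expect_equal(mwu_test(c(1, 2, 2, 3), c(1, 2, 2, 3))$statistic_z, 0)
  expect_equal(mwu_test(c(1, 2, 2, 3), c(1, 2, 2, 3))$p_value, 1)
  expect_gt(mwu_test(c(4, 5, 6), c(1, 2, 3))$statistic_z, 0)
  expect_error(mwu_test(rep(2, 5), rep(2, 4)), "degenerate")
  ## cross-check the tie-corrected z against the classic formula via
  ## wilcox.test's statistic bookkeeping
  set.seed(9)
  x <- sample(1:4, 30, TRUE); y <- sample(2:5, 25, TRUE)
  got <- mwu_test(x, y)
  wt <- suppressWarnings(stats::wilcox.test(x, y, correct = TRUE,
                                            exact = FALSE))
  expect_equal(unname(got$U), unname(wt$statistic))
  expect_equal(got$p_value, wt$p.value, tolerance = 1e-10)
})

test_that("Kruskal-Wallis behaves as a rank test should", {
  g_id <- list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3))
  expect_equal(kruskal_wallis(g_id)$statistic_h, 0)
  set.seed(4)
  g_shift <- list(rnorm(5), rnorm(5, 4), rnorm(5, 8))
  kw <- kruskal_wallis(g_shift)
  expect_lt(kw$p_value, 0.01)
  ## invariant under monotone transforms of the pooled data
  g_exp <- lapply(g_shift, exp)
  expect_equal(kruskal_wallis(g_exp)$statistic_h, kw$statistic_h)
  expect_error(kruskal_wallis(g_shift[1:2]), "3 groups")
})

test_that("pairwise phase comparison yields calibrated simultaneous intervals", {
  set.seed(12)
  same <- list(p1 = rnorm(12), p2 = rnorm(12), p3 = rnorm(12))
  tab <- pairwise_phase_comparison(same)
  expect_true(all(tab$lower <= 0 & tab$upper >= 0))
  shifted <- list(p1 = rnorm(12), p2 = rnorm(12, 20), p3 = rnorm(12, 40))
  tab2 <- pairwise_phase_comparison(shifted)
  expect_true(all(tab2$significant))
  expect_true(all(tab2$lower > 0 | tab2$upper < 0))
  ## relative interval width shrinks with n
  width_rel <- function(n, seed) {
    set.seed(seed)
    g <- list(a = rnorm(n), b = rnorm(n, 1), c = rnorm(n, 2))
    tab <- pairwise_phase_comparison(g)
    mean((tab$upper - tab$lower) / (3 * n))  # scale by the rank range
  }
  expect_lt(width_rel(100, 31), width_rel(10, 31))
})

test_that("Bonferroni-Holm is step-down with strictest threshold alpha/m", {
  bh <- bonferroni_holm(rep(0.001, 12), alpha = 0.05)
  expect_equal(min(bh$threshold), 0.05 / 12)
  expect_equal(round(min(bh$threshold), 4), 0.0042)
  expect_equal(bonferroni_holm(0.03)$threshold, 0.05)
  expect_false(any(bonferroni_holm(rep(1, 6))$reject))
  ## rejections agree with stats::p.adjust on random families
  set.seed(19)
  for (i in 1:20) {
    p <- runif(sample(3:12, 1))^2
    bh <- bonferroni_holm(p, alpha = 0.05)
    expect_identical(bh$reject, unname(stats::p.adjust(p, "holm") <= 0.05))
  }
  expect_error(bonferroni_holm(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("Cliff's delta bands follow the stated cut points", {
  expect_equal(cliffs_delta(5, 5), list(delta = 0, band = "small"))
  expect_equal(cliffs_delta(c(1, 2), c(3, 4)), list(delta = -1, band = "large"))
  expect_equal(cliffs_delta(c(1, 2, 3), c(2, 3, 4))$delta, -5 / 9)
  expect_identical(cliffs_delta(c(1, 2, 3), c(2, 3, 4))$band, "large")
  ## boundary assignment: |delta| = 0.33 and 0.5 are medium
  a <- c(rep(0, 67), rep(2, 33)); b <- c(rep(1, 100))
  expect_identical(cliffs_delta(a, b)$band, "medium")  # delta = -0.34 -> medium
  expect_identical(cliffs_delta(c(0, 0, 2, 2), c(1, 1, 1, 3))$band, "small")
})

test_that("the KS gate accepts Gaussian and rejects skewed or degenerate samples", {
  set.seed(42)
  expect_true(ks_normality_gate(rnorm(500)))
  expect_false(ks_normality_gate(rexp(500)))
  expect_false(ks_normality_gate(rep(3, 10)))
  expect_error(ks_normality_gate(c(1, 2, 3)), "n >= 5")
})

test_that("the MWU keeps its nominal type-I error under the null generator", {
  set.seed(2024)
  rejections <- replicate(1000, {
    s <- simulate_subject_scores(12, 16, delta_deg = 0, subject_sd = 2)
    mwu_test(s$a, s$b)$p_value < 0.05
  })
  expect_gte(mean(rejections), 0.03)
  expect_lte(mean(rejections), 0.07)
})

test_that("a large injected effect is recovered with the right sign essentially always", {
  set.seed(7)
  off <- offset_for_delta(0.9, 2)
  hits <- replicate(200, {
    s <- simulate_subject_scores(12, 16, delta_deg = off, subject_sd = 2)
    cliffs_delta(s$b, s$a)$delta > 0
  })
  expect_gte(mean(hits), 0.99)
})
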