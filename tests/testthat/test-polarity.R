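test_that("ON/OFF scoring splits on the interface-parallel line", {
  cells <- data.frame(soma_x = c(10, 10, 10), soma_y = c(5, 6, 7),
                      marker_x = c(12, 10, 9.95), marker_y = c(5, 6, 7))
  cnt <- score_onoff(cells, tie_epsilon_um = 0.1)
  expect_equal(cnt$n_on, 1L)           # 2 um toward the pillars
  expect_equal(cnt$n_unclassified, 2L) # on the line / within epsilon
  expect_equal(cnt$n_off, 0L)
  # binomial recovery at p_true = 0.65
  set.seed(17)
  n <- 1e4
  on <- rbinom(n, 1, 0.65)
  cohort <- data.frame(soma_x = 0, soma_y = seq_len(n),
                       marker_x = ifelse(on == 1, 1.5, -1.5),
                       marker_y = seq_len(n))
  cnt2 <- score_onoff(cohort)
  p_hat <- cnt2$n_on / (cnt2$n_on + cnt2$n_off)
  expect_lt(abs(p_hat - 0.65), 3 * sqrt(0.65 * 0.35 / n))
})

test_that("binomial SEMs reproduce printed cohort uncertainties", {
  expect_equal(round(unlist(proportion_sem(count_from_summary(53, 69.8))[1:2]), 1),
               c(p_hat_pct = 69.8, sem_pct = 6.3))
  expect_equal(round(proportion_sem(count_from_summary(112, 65.2))$sem_pct, 1),
               4.5)
  all_on <- proportion_sem(polarity_count(25, 0))
  expect_equal(all_on$p_hat_pct, 100)
  expect_equal(all_on$sem_pct, 0)
  expect_error(proportion_sem(polarity_count(0, 0)), "no classified")
})

test_that("the binomial SEM peaks at 50% and vanishes at the extremes", {
  n <- 64
  sems <- vapply(0:n, function(k)
    proportion_sem(polarity_count(k, n - k))$sem_pct, numeric(1))
  expect_equal(which.max(sems), n / 2 + 1L)
  expect_equal(sems[c(1, n + 1)], c(0, 0))
})

test_that("chi-square GOF matches hand arithmetic and the base oracle", {
  even <- chisq_gof(polarity_count(40, 40))
  expect_equal(even$chi2, 0)
  expect_equal(even$p, 1)
  c73 <- chisq_gof(count_from_summary(112, 65.2))  # 73 ON of 112
  expect_equal(c73$chi2, 2 * (73 - 56)^2 / 56)
  expect_lt(c73$p, 0.05)
  expect_equal(c73$p, 1.3e-3, tolerance = 0.02)
  c64 <- chisq_gof(count_from_summary(109, 58.7))  # 64 ON of 109
  expect_gt(c64$p, 0.05)
  expect_lt(c64$p, 0.1)
  # against the stats oracle, incl. an asymmetric null
  for (cnt in list(polarity_count(30, 20), polarity_count(11, 45, null_p = 0.25))) {
    ours <- chisq_gof(cnt)
    ref <- suppressWarnings(
      chisq.test(c(cnt$n_on, cnt$n_off), p = c(cnt$null_p, 1 - cnt$null_p)))
    expect_equal(ours$chi2, unname(ref$statistic))
    expect_equal(ours$p, ref$p.value)
  }
  expect_error(chisq_gof(polarity_count(0, 0)), "no classified")
})

test_that("chi-square p-values are calibrated under the binomial null", {
  set.seed(23)
  rej <- mean(vapply(1:2000, function(i) {
    k <- rbinom(1, 100, 0.5)
    chisq_gof(polarity_count(k, 100 - k))$p <= 0.05
  }, logical(1)))
  expect_gt(rej, 0.02)
  expect_lt(rej, 0.08)
})

test_that("pooled proportions behave like a weighted mean", {
  golgi <- list(count_from_summary(53, 69.8), count_from_summary(53, 64.2))
  expect_equal(round(pooled_proportion(golgi)), 67)
  single <- count_from_summary(43, 67.4)
  expect_equal(pooled_proportion(list(single)),
               proportion_sem(single)$p_hat_pct)
  mix <- list(polarity_count(10, 30), polarity_count(30, 10))
  pooled <- pooled_proportion(mix)
  expect_gt(pooled, 25)
  expect_lt(pooled, 75)
})

test_that("the quadrant test scores the axon-base quadrant at null 25%", {
  cells <- data.frame(soma_x = 0, soma_y = 0,
                      marker_x = c(1, -1, 0.1), marker_y = c(0, 0, 1),
                      axon_dx = 1, axon_dy = 0)
  cnt <- quadrant_golgi_test(cells)
  expect_equal(cnt$n_on, 1L)   # along the axon
  expect_equal(cnt$n_off, 2L)  # 180 degrees and perpendicular
  expect_equal(cnt$null_p, 0.25)
  # a missing axis is skipped, not an error
  cells$axon_dx[2] <- NA
  expect_equal(quadrant_golgi_test(cells)$n_unclassified, 1L)
  # uniform Golgi angle gives ~25% ON
  set.seed(31)
  th <- runif(4000, 0, 2 * pi)
  unif <- data.frame(soma_x = 0, soma_y = 0, marker_x = cos(th),
                     marker_y = sin(th), axon_dx = 1, axon_dy = 0)
  u <- quadrant_golgi_test(unif)
  p_hat <- u$n_on / (u$n_on + u$n_off)
  expect_lt(abs(p_hat - 0.25), 3 * sqrt(0.25 * 0.75 / 4000))
})

test_that("growth-cone area comparison is a symmetric equal-variance t-test", {
  a <- c(10, 12, 11, 13)
  same <- growthcone_area_test(a, a)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  set.seed(41)
  hits <- mean(vapply(1:100, function(i) {
    g1 <- rnorm(30, 20, 4); g2 <- rnorm(30, 35, 6)
    growthcone_area_test(g1, g2)$p < 0.05
  }, logical(1)))
  expect_gte(hits, 0.95)
  g1 <- rnorm(10, 20, 4); g2 <- rnorm(10, 30, 5)
  fwd <- growthcone_area_test(g1, g2)
  rev <- growthcone_area_test(g2, g1)
  expect_equal(fwd$t, -rev$t)
  expect_equal(fwd$p, rev$p)
  expect_error(growthcone_area_test(c(1, 1), c(2, 2)), "degenerate")
})

test_that("the bundled cohort table is complete and self-consistent", {
  tab <- polarity_cohorts()
  expect_equal(nrow(tab), 12L)
  expect_true(all(c("marker", "n", "pct_on", "pm_printed_pct") %in% names(tab)))
  expect_true(all(tab$n > 0 & tab$pct_on >= 0 & tab$pct_on <= 100))
  # ON counts recovered from printed percentages are whole cells
  on <- round(tab$pct_on / 100 * tab$n)
  expect_true(all(abs(on - tab$pct_on / 100 * tab$n) < 0.5))
})
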