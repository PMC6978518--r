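test_that("carrier Fisher test reproduces the published odds ratios", {
  all_cancers <- carrier_fisher(2, 715, 12, 257)
  expect_equal(signif(all_cancers$odds_ratio, 2), 0.060)
  expect_lt(all_cancers$p_value, 0.001)
  expect_equal(signif(all_cancers$conf_int, 2), c(0.0065, 0.27),
               tolerance = 0.05)
  crc <- carrier_fisher(1, 716, 2, 38)
  expect_equal(signif(crc$odds_ratio, 2), 0.027)
  expect_equal(signif(crc$p_value, 2), 0.0079, tolerance = 0.05)
  # symmetric table: odds ratio 1, p = 1
  sym <- carrier_fisher(5, 100, 5, 100)
  expect_equal(sym$odds_ratio, 1)
  expect_equal(sym$p_value, 1)
  expect_error(carrier_fisher(0, 0, 5, 10), "degenerate")
})

test_that("exact p matches full hypergeometric enumeration on small tables", {
  oracle_fisher_p <- function(a, b, c, d) {
    m <- a + b; n <- c + d; k <- a + c
    support <- max(0, k - n):min(k, m)
    pmf <- dhyper(support, m, n, k)
    p_obs <- dhyper(a, m, n, k)
    sum(pmf[pmf <= p_obs * (1 + 1e-7)])
  }
  set.seed(21)
  for (i in 1:25) {
    tot <- sample(8:60, 1)
    a <- sample(0:(tot %/% 4), 1); b <- sample(1:(tot %/% 4), 1)
    c <- sample(0:(tot %/% 4), 1); d <- sample(1:(tot %/% 4), 1)
    if ((a + c) == 0) next
    expect_equal(carrier_fisher(a, b, c, d)$p_value,
                 oracle_fisher_p(a, b, c, d), tolerance = 1e-7,
                 info = paste(a, b, c, d))
  }
})

test_that("Haldane correction applies only to zero-cell tables and is reported", {
  expect_message(z <- carrier_fisher(0, 100, 5, 95), "Haldane")
  expect_true(z$haldane)
  expect_equal(z$odds_ratio, (0.5 * 95.5) / (100.5 * 5.5))
  nz <- carrier_fisher(1, 99, 5, 95)
  expect_false(nz$haldane)
  expect_equal(nz$odds_ratio, (1 * 95) / (99 * 5))
})

test_that("direction-of-effect test behaves at the extremes and drops ties", {
  # all risk alleles depleted, all protective enriched: OR at the floor
  f1 <- c(rep(0.3, 10), rep(0.5, 10))
  f2 <- c(rep(0.4, 10), rep(0.4, 10))
  sign <- c(rep(1, 10), rep(-1, 10))
  suppressMessages(res <- direction_bias_test(f1, f2, sign))
  expect_lt(res$odds_ratio, 0.05)
  expect_lt(res$p_value, 1e-4)
  expect_message(direction_bias_test(c(0.1, 0.3, 0.2), c(0.1, 0.2, 0.3),
                                     c(1, 1, -1)), "dropped")
})

test_that("null direction-of-effect p-values are approximately uniform", {
  ps <- vapply(1:60, function(s) {
    set.seed(1000 + s)
    f2 <- runif(300, 0.1, 0.9)
    f1 <- f2 + rnorm(300, 0, 0.02)
    sgn <- sample(c(-1, 1), 300, replace = TRUE)
    direction_bias_test(f1, f2, sgn)$p_value
  }, 0)
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
})

test_that("polygenic scores follow the dosage formula with imputation", {
  def <- data.frame(locus = c("L1", "L2"), beta = c(1, 0.5),
                    ref_freq = c(0.25, 0.5))
  D <- matrix(c(2, NA, 1, 1), 2, 2,
              dimnames = list(NULL, c("L1", "L2")))
  # call rate 0.5 at L1 removes it entirely under the 97% rule
  s <- polygenic_score(D, def)
  expect_equal(attr(s, "n_loci"), 1L)
  expect_equal(as.numeric(s), c(0.5, 0.5))
  # single retained locus, beta 1, dosage 2
  s2 <- polygenic_score(matrix(2, 1, 1, dimnames = list(NULL, "L1")),
                        def[1, ])
  expect_equal(as.numeric(s2), 2)
  # a fully missing locus is imputed as 2 f for every individual when the
  # call-rate filter is disabled
  D3 <- matrix(NA_real_, 3, 1, dimnames = list(NULL, "L1"))
  s3 <- polygenic_score(D3, def[1, ], min_call_rate = 0)
  expect_equal(as.numeric(s3), rep(2 * 0.25 * 1, 3))
  # scoring simulated genotypes at known frequencies matches 2 sum(f beta)
  set.seed(31)
  n <- 4000
  freqs <- runif(30, 0.1, 0.9)
  betas <- rnorm(30, 0, 0.2)
  G <- sapply(freqs, function(f) rbinom(n, 2, f))
  colnames(G) <- paste0("V", 1:30)
  def_big <- data.frame(locus = colnames(G), beta = betas,
                        ref_freq = freqs)
  s_all <- polygenic_score(G, def_big)
  expected <- 2 * sum(freqs * betas)
  expect_lt(abs(mean(s_all) - expected), 3 * sd(s_all) / sqrt(n))
  expect_message(polygenic_score(G[, 1:29], def_big), "absent")
})

test_that("expected cohort score equals the frequency-weighted mean", {
  expect_equal(expected_cohort_score(
    data.frame(locus = "L1", freq = 0.5),
    data.frame(locus = "L1", beta = 1)), 1)
  def0 <- data.frame(locus = c("a", "b"), beta = c(0, 0))
  fr <- data.frame(locus = c("a", "b"), freq = c(0.2, 0.9))
  expect_equal(expected_cohort_score(fr, def0), 0)
  set.seed(41)
  fr2 <- data.frame(locus = sprintf("x%02d", 1:40), freq = runif(40))
  def2 <- data.frame(locus = fr2$locus, beta = rnorm(40))
  expect_equal(expected_cohort_score(fr2, def2),
               (2 / 40) * sum(fr2$freq * def2$beta), tolerance = 1e-12)
  expect_error(expected_cohort_score(fr2[-1, ], def2), "missing")
})

test_that("drift bootstrap is seed-deterministic with the exact tie-case p", {
  cfg <- sim_config(seed = 77, n_pool_loci = 2000, n_score_loci = 40)
  fr <- gen_cohort_freqs(cfg)
  b1 <- drift_bootstrap(fr$freq_study, fr$freq_other, fr$score_def,
                        B = 500, seed = 5)
  b2 <- drift_bootstrap(fr$freq_study, fr$freq_other, fr$score_def,
                        B = 500, seed = 5)
  expect_identical(b1$p_value, b2$p_value)
  expect_identical(b1$depletion_normalised, b2$depletion_normalised)
  # identical cohorts: every round ties and the printed formula forces the
  # floor p = 1/(B+1), halving exactly when B doubles
  cfg0 <- sim_config(seed = 78, drift_scale = 0, n_pool_loci = 500,
                     n_score_loci = 30)
  fr0 <- gen_cohort_freqs(cfg0)
  p1 <- drift_bootstrap(fr0$freq_study, fr0$freq_other, fr0$score_def,
                        B = 999, seed = 1)$p_value
  p2 <- drift_bootstrap(fr0$freq_study, fr0$freq_other, fr0$score_def,
                        B = 1999, seed = 1)$p_value
  expect_equal(p1, 1 / 1000)
  expect_equal(p2, 1 / 2000)
  expect_error(drift_bootstrap(fr0$freq_study, fr0$freq_other,
                               fr0$score_def, B = 10, seed = 1,
                               min_call_rate = 1.01), "empty")
})

test_that("power curve has the null floor, monotonicity, and matches simulation", {
  null_pc <- power_curve(0, 1, n_grid = c(10, 100, 1000))
  expect_equal(null_pc$power_by_n$power, rep(0.05, 3))
  pc <- power_curve(0.5, 1, n_grid = 2^(2:10))
  expect_true(all(diff(pc$power_by_n$power) >= 0))
  pc_big <- power_curve(0.8, 1, n_grid = 2^(2:10))
  expect_true(all(pc_big$power_by_n$power >= pc$power_by_n$power))
  # inversion is consistent: interpolated n reproduces the power
  n80 <- pc$n_by_power$n[pc$n_by_power$power == 0.8]
  expect_equal(power.t.test(n = n80, delta = 0.5, sd = 1)$power, 0.8,
               tolerance = 0.02)
  # Monte-Carlo rejection rates at three grid points
  set.seed(51)
  for (n in c(10, 30, 80)) {
    B <- 1e5
    x <- matrix(rnorm(n * B, 0.5, 1), n)
    y <- matrix(rnorm(n * B, 0, 1), n)
    mx <- colMeans(x); my <- colMeans(y)
    vx <- (colSums(x^2) - n * mx^2) / (n - 1)
    vy <- (colSums(y^2) - n * my^2) / (n - 1)
    tstat <- (mx - my) / sqrt((vx + vy) / n)
    crit <- qt(0.975, 2 * n - 2)
    mc <- mean(abs(tstat) > crit)
    analytic <- power.t.test(n = n, delta = 0.5, sd = 1)$power
    expect_lt(abs(mc - analytic), 0.02)
  }
})

test_that("Holm correction matches the step-down definition", {
  expect_equal(holm_correct(0.03), 0.03)
  expect_equal(holm_correct(c(0.01, 0.04)), c(0.02, 0.04))
  set.seed(61)
  for (i in 1:10) {
    p <- runif(sample(2:12, 1))
    expect_equal(holm_correct(p), oracle_holm(p))
  }
})
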