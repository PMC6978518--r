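test_that("trend fit is exact on noiseless lines and rescales per decade", {
  age <- seq(70, 90, length.out = 50)
  y <- 100 - 0.4 * age
  fit <- trend_fit(y, age)
  expect_equal(fit$slope_per_decade, -4, tolerance = 1e-10)
  expect_lt(diff(fit$conf_int), 1e-8)
  # per-decade slope is 10x the per-year slope of the underlying lm
  expect_equal(fit$slope_per_decade,
               10 * unname(coef(fit$fit)["age"]))
  # transformations are applied before fitting
  fit_log <- trend_fit(10^(2 - 0.03 * age), age, "log10")
  expect_equal(fit_log$slope_per_decade, -0.3, tolerance = 1e-8)
  fit_pow <- trend_fit((50 - 0.3 * age)^(1 / 0.7), age, "power0.7")
  expect_equal(fit_pow$slope_per_decade, -3, tolerance = 1e-8)
  expect_error(trend_fit(y[1:2], age[1:2]), "3 observations")
  expect_error(trend_fit(y, rep(80, 50)), "constant")
})

test_that("Wald confidence interval has nominal coverage under the null", {
  hits <- vapply(1:200, function(s) {
    set.seed(s)
    age <- runif(500, 70, 95)
    y <- 5 + rnorm(500)
    ci <- trend_fit(y, age)$conf_int
    ci[1] <= 0 && ci[2] >= 0
  }, TRUE)
  expect_gte(mean(hits), 0.93)
  expect_lte(mean(hits), 0.97)
})

test_that("trend LRT equals the deviance-form oracle and detects differences", {
  set.seed(71)
  age <- runif(300, 70, 90)
  grp <- rep(c("A", "B"), 150)
  y <- 10 - 0.2 * age + rnorm(300, 0, 0.5)
  res <- lrt_trend_difference(y, age, grp)
  # identical generating slopes: no evidence
  expect_gt(res$p_value, 0.05)
  expect_equal(res$df, 1L)
  # Gaussian-lm identity: LRT statistic = n log(RSS0 / RSS1)
  rss0 <- sum(residuals(res$null_fit)^2)
  rss1 <- sum(residuals(res$full_fit)^2)
  expect_equal(res$statistic, 300 * log(rss0 / rss1), tolerance = 1e-8)
  # a planted slope difference of 4 standard errors is detected in at
  # least 90% of replicates (asymptotic power at 4 SE is about 98%; at
  # exactly 3 SE it is only ~85%)
  hits <- vapply(1:20, function(s) {
    set.seed(s)
    age <- runif(400, 70, 90)
    grp <- rep(c("A", "B"), 200)
    se_diff <- 0.5 * sqrt(2 / (200 * var(age)))
    slope <- ifelse(grp == "A", -0.2, -0.2 - 4 * se_diff)
    y <- 10 + slope * age + rnorm(400, 0, 0.5)
    lrt_trend_difference(y, age, grp)$p_value < 0.05
  }, TRUE)
  expect_gte(mean(hits), 0.9)
  expect_error(lrt_trend_difference(y, age, rep("A", 300)), "two groups")
})

make_pheno <- function(n, seed, effect = 0) {
  cfg <- sim_config(seed = seed, n_individuals = n,
                    planted_mtdna_effect = effect)
  gen_phenotypes(cfg)
}

test_that("fast permutation path reproduces fixed-smoothing gam refits", {
  ph <- make_pheno(300, 81)
  res <- permutation_gam_test(ph$grip_kg, ph$age, ph$weight_kg, ph$bmi,
                              ph$abdocirc_cm, ph$mtdna_cn, n_perm = 5,
                              seed = 3)
  dat <- data.frame(frailty = ph$grip_kg, age = ph$age,
                    weight = ph$weight_kg, bmi = ph$bmi,
                    abdocirc = ph$abdocirc_cm, somatic = ph$mtdna_cn)
  # reproduce the decoupling draw and the permutation stream
  draws <- wgsage:::with_seed(3, {
    perm0 <- sample.int(300)
    list(perm0 = perm0, perms = lapply(1:5, function(i) sample.int(300)))
  })
  refit_at <- function(d) mgcv::gam(frailty ~ s(age) + s(weight) +
                                      s(bmi) + s(abdocirc) + s(somatic),
                                    data = d, sp = res$sp_used)
  # observed deviance through the solver equals a full gam refit at the
  # decoupled smoothing parameters
  expect_equal(res$observed_deviance, deviance(refit_at(dat)),
               tolerance = 1e-6)
  # each permuted deviance equals the corresponding permuted refit
  for (i in 1:3) {
    dp <- dat
    dp$somatic <- dp$somatic[draws$perms[[i]]]
    expect_equal(res$permuted_deviances[i], deviance(refit_at(dp)),
                 tolerance = 1e-5)
  }
})

test_that("permutation p-hat follows the printed formula and its bounds", {
  ph <- make_pheno(250, 82)
  res <- permutation_gam_test(ph$grip_kg, ph$age, ph$weight_kg, ph$bmi,
                              ph$abdocirc_cm, ph$mtdna_cn, n_perm = 99,
                              seed = 4)
  expect_equal(res$p_value,
               (sum(res$permuted_deviances <= res$observed_deviance) + 0.5) /
                 (res$n_perm + 1))
  expect_gte(res$p_value, 0.5 / 100)
  expect_lte(res$p_value, 99.5 / 100)
  # a somatic column that is the frailty itself gives the formula floor
  res2 <- permutation_gam_test(ph$grip_kg, ph$age, ph$weight_kg, ph$bmi,
                               ph$abdocirc_cm,
                               ph$grip_kg + rnorm(250, 0, 1e-4),
                               n_perm = 50, seed = 5)
  expect_equal(res2$p_value, 0.5 / 51)
})

test_that("two-stage screen splits deterministically and thresholds at 0.2", {
  ph <- make_pheno(600, 83, effect = 6)
  tests <- data.frame(frailty = c("grip_kg", "gait_m_s"),
                      somatic = c("mtdna_cn", "mtdna_cn"),
                      sex = c("M", "all"), stringsAsFactors = FALSE)
  out <- two_stage_screen(ph, tests, n_perm = 99, seed = 11)
  idx <- attr(out, "screen_idx")
  expect_equal(length(idx), 150)
  out2 <- two_stage_screen(ph, tests, n_perm = 99, seed = 11)
  expect_identical(out$p_screen, out2$p_screen)
  expect_identical(idx, attr(out2, "screen_idx"))
  # screened-out tests carry no validation p
  expect_true(all(is.na(out$p_validate[out$p_screen >= 0.2])))
  passed <- !is.na(out$p_validate)
  if (any(passed))
    expect_equal(out$p_validate_holm[passed],
                 holm_correct(out$p_validate[passed]))
  expect_error(two_stage_screen(ph, tests[1, ]), "two candidate")
})

test_that("age-local quantile matches the brute-force double loop", {
  set.seed(91)
  n <- 300
  ages <- runif(n, 70, 90)
  vals <- rnorm(n)
  q <- age_local_quantile(vals, ages)
  brute <- vapply(seq_len(n), function(i) {
    nbr <- abs(round(ages) - round(ages[i])) <= 1
    mean(vals[nbr] <= vals[i])
  }, 0)
  expect_equal(q, brute)
  expect_true(all(q > 0 & q <= 1))
  # invariant to monotone transformation of the values
  expect_equal(age_local_quantile(exp(vals), ages), q)
  # all-equal values sit at the top of every neighbourhood
  expect_equal(age_local_quantile(rep(2, 20), rep(80, 20)), rep(1, 20))
  # strict minimum in its neighbourhood gets 1/m
  a <- c(80, 80, 80, 80)
  v <- c(-5, 1, 2, 3)
  expect_equal(age_local_quantile(v, a)[1], 1 / 4)
  expect_warning(age_local_quantile(c(1, 2), c(70, 90)), "singleton")
})

test_that("effective-age curve is zero at the median quantile and tracks a planted effect", {
  set.seed(92)
  n <- 1200
  age <- runif(n, 70, 90)
  q <- runif(n)
  # grip declines 0.5 kg/yr; q effect 4 kg across its range = 8 years
  grip <- 80 - 0.5 * age + 4 * (q - 0.5) + rnorm(n, 0, 2)
  ec <- effective_age_curve(grip, age, q, n_boot = 60, seed = 7,
                            q_grid = c(0.05, 0.5, 0.95))
  expect_equal(ec$curve$age_excess[ec$curve$q == 0.5], 0,
               tolerance = 1e-8)
  expect_equal(ec$beta_age, -0.5, tolerance = 0.05)
  # low quantile looks older, high quantile younger, roughly +/- 3.6 y
  lo <- ec$curve[ec$curve$q == 0.05, ]
  hi <- ec$curve[ec$curve$q == 0.95, ]
  expect_gt(lo$age_excess, 1)
  expect_lt(hi$age_excess, -1)
  expect_true(lo$lower <= lo$age_excess && lo$age_excess <= lo$upper)
  # HPD intervals are shortest-window: contained in the sample range
  expect_true(all(ec$curve$lower <= ec$curve$upper))
})

test_that("null effective-age curves cover zero", {
  set.seed(93)
  n <- 800
  age <- runif(n, 70, 90)
  q <- runif(n)
  grip <- 80 - 0.5 * age + rnorm(n, 0, 2)
  ec <- effective_age_curve(grip, age, q, n_boot = 80, seed = 8,
                            q_grid = c(0.1, 0.5, 0.9))
  covers <- ec$curve$lower <= 0 & ec$curve$upper >= 0
  expect_true(all(covers))
})

test_that("cohort intercept adjustment removes exactly a constant offset", {
  set.seed(94)
  n <- 400
  age <- runif(n, 70, 90)
  sex <- sample(c("M", "F"), n, replace = TRUE)
  cohort <- rep(c("REF", "OTHER"), each = n / 2)
  base <- 50 - 0.3 * age + 2 * (sex == "M")
  y <- base + 4 * (cohort == "OTHER")
  adj <- cohort_intercept_adjust(y, age, sex, cohort, reference = "REF")
  expect_lt(max(abs(adj - base)), 1e-6)
  # additive shift preserves within-cohort variance
  expect_equal(var(adj[cohort == "OTHER"]), var(y[cohort == "OTHER"]))
  # single-cohort data is returned unchanged
  one <- cohort_intercept_adjust(y[1:200], age[1:200], sex[1:200],
                                 rep("REF", 200), reference = "REF")
  expect_equal(as.numeric(one), y[1:200])
  expect_error(cohort_intercept_adjust(y, age, sex, cohort, "ABSENT"),
               "absent")
})

test_that("measure transforms invert on the data range", {
  tr <- measure_transform("power0.7")
  x <- c(5, 20, 45)
  expect_equal(tr$inverse(tr$transform(x)), x)
  expect_equal(measure_transform("log10")$inverse(2), 100)
})
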