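# Somatic-measure trend analysis, the frailty permutation procedure,
# age-local quantiles, effective-age curves and cohort intercept
# correction.

#' Measure transformations
#'
#' The somatic and frailty measures are modelled on transformed scales:
#' identity, `log10`, or a power transform with exponent 0.7 (used for
#' grip strength in kg).
#'
#' @param name One of `"identity"`, `"log10"`, `"power0.7"`.
#' @return A list with `transform` and `inverse` functions.
#' @export
measure_transform <- function(name = c("identity", "log10", "power0.7")) {
  name <- match.arg(name)
  switch(name,
         identity = list(transform = identity, inverse = identity),
         log10 = list(transform = log10, inverse = function(x) 10^x),
         power0.7 = list(transform = function(x) x^0.7,
                         inverse = function(x) x^(1 / 0.7)))
}

#' Linear age trend of a somatic measure
#'
#' Ordinary least squares of the (transformed) measure on age, with the
#' slope rescaled to change per decade and a 95% Wald confidence
#' interval.
#'
#' @param measure Numeric measure values.
#' @param age Ages in years.
#' @param transformation Transformation name (see [measure_transform()]).
#' @param conf_level Confidence level (default 0.95).
#' @return An object of class `trend_fit` with `slope_per_decade`,
#'   `conf_int`, `fit`.
#' @export
trend_fit <- function(measure, age, transformation = "identity",
                      conf_level = 0.95) {
  if (length(measure) < 3) stop("at least 3 observations required",
                                call. = FALSE)
  if (stats::sd(age) == 0) stop("age is constant", call. = FALSE)
  tr <- measure_transform(transformation)
  y <- tr$transform(measure)
  fit <- stats::lm(y ~ age)
  ci <- suppressWarnings(stats::confint(fit, "age", level = conf_level))
  structure(list(slope_per_decade = 10 * unname(stats::coef(fit)["age"]),
                 conf_int = 10 * unname(ci[1, ]),
                 transformation = transformation, fit = fit,
                 conf_level = conf_level),
            class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("Age trend (%s scale): %+.4g per decade, %g%% CI [%.4g, %.4g]\n",
              x$transformation, x$slope_per_decade, 100 * x$conf_level,
              x$conf_int[1], x$conf_int[2]))
  invisible(x)
}

#' Likelihood-ratio test for an inter-cohort trend difference
#'
#' Compares nested linear models of the (transformed) measure: a shared
#' age slope with per-group intercepts against per-group slopes. The test
#' statistic is `2 * (logLik_full - logLik_null)` on a chi-squared
#' reference with degrees of freedom equal to the parameter difference.
#'
#' @param measure,age Numeric vectors.
#' @param group Group labels (coerced to factor).
#' @param transformation Transformation name.
#' @return A list of class `trend_lrt` with `statistic`, `df`, `p_value`
#'   and the two fits.
#' @export
lrt_trend_difference <- function(measure, age, group,
                                 transformation = "identity") {
  tr <- measure_transform(transformation)
  y <- tr$transform(measure)
  g <- factor(group)
  if (nlevels(g) < 2) stop("at least two groups required", call. = FALSE)
  null_fit <- stats::lm(y ~ age + g)
  full_fit <- stats::lm(y ~ age * g)
  stat <- 2 * (as.numeric(stats::logLik(full_fit)) -
                 as.numeric(stats::logLik(null_fit)))
  df <- attr(stats::logLik(full_fit), "df") -
    attr(stats::logLik(null_fit), "df")
  structure(list(statistic = stat, df = df,
                 p_value = stats::pchisq(stat, df, lower.tail = FALSE),
                 null_fit = null_fit, full_fit = full_fit),
            class = "trend_lrt")
}

#' @export
print.trend_lrt <- function(x, ...) {
  cat(sprintf("Trend LRT: chi2 = %.3f, df = %d, p = %.4g\n", x$statistic,
              x$df, x$p_value))
  invisible(x)
}

# penalty-weighted design blocks of a fitted gaussian gam: model matrix,
# total penalty per column block, and the column range of a named term
gam_design <- function(fit, sp = fit$sp) {
  X <- stats::predict(fit, type = "lpmatrix")
  p <- ncol(X)
  S <- matrix(0, p, p)
  k <- 0
  for (sm in fit$smooth) {
    idx <- sm$first.para:sm$last.para
    for (j in seq_along(sm$S)) {
      k <- k + 1
      S[idx, idx] <- S[idx, idx] + sp[k] * sm$S[[j]]
    }
  }
  list(X = X, S = S)
}

#' Permutation test of a somatic measure's contribution to frailty
#'
#' Fits the additive model
#' `frailty ~ s(age) + s(weight) + s(bmi) + s(abdocirc) + s(somatic)`
#' (penalised thin-plate smooths, Gaussian error, identity link) and
#' compares its deviance `d` to the deviances `d_(i)` of `n_perm` refits
#' with the somatic column permuted. The p-value is
#' `(sum[d_(i) <= d] + 0.5) / (n_perm + 1)`. All refits (including the
#' observed one) share fixed smoothing parameters; to keep the comparison
#' exchangeable under the null these are selected on a decoupling fit in
#' which the somatic column has itself been randomly permuted, so the
#' smoothness choice carries no information about the observed pairing
#' (selecting it on the observed fit makes the test markedly
#' anticonservative). Set `refit_smoothing = TRUE` to re-select
#' smoothness in every permutation round via a full [mgcv::gam()] refit
#' instead.
#'
#' @param frailty,age,weight,bmi,abdocirc,somatic Numeric vectors;
#'   incomplete cases are dropped.
#' @param n_perm Number of permutations (default 10000).
#' @param seed Integer seed.
#' @param refit_smoothing Re-select smoothing parameters per permutation.
#' @return An object of class `permutation_test` with `p_value`,
#'   `observed_deviance`, `permuted_deviances`, `n_perm`, `seed`, `fit`.
#' @export
permutation_gam_test <- function(frailty, age, weight, bmi, abdocirc,
                                 somatic, n_perm = 10000L, seed = 1L,
                                 refit_smoothing = FALSE) {
  dat <- data.frame(frailty = frailty, age = age, weight = weight,
                    bmi = bmi, abdocirc = abdocirc, somatic = somatic)
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  n <- nrow(dat)
  fit <- mgcv::gam(frailty ~ s(age) + s(weight) + s(bmi) + s(abdocirc) +
                     s(somatic), data = dat)
  if (refit_smoothing) {
    d_perm <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
      dp <- dat
      dp$somatic <- dp$somatic[sample.int(n)]
      stats::deviance(mgcv::gam(frailty ~ s(age) + s(weight) + s(bmi) +
                                  s(abdocirc) + s(somatic), data = dp))
    }, 0))
    d_obs <- stats::deviance(fit)
  } else {
    # decoupling fit: smoothing parameters chosen with the somatic column
    # permuted, independent of the observed pairing
    draws <- with_seed(seed, {
      perm0 <- sample.int(n)
      perms <- lapply(seq_len(n_perm), function(i) sample.int(n))
      list(perm0 = perm0, perms = perms)
    })
    dat0 <- dat
    dat0$somatic <- dat0$somatic[draws$perm0]
    fit_sp <- mgcv::gam(frailty ~ s(age) + s(weight) + s(bmi) +
                          s(abdocirc) + s(somatic), data = dat0)
    des <- gam_design(fit, sp = fit_sp$sp)
    zcols <- NULL
    for (sm in fit$smooth)
      if (sm$term[1] == "somatic")
        zcols <- sm$first.para:sm$last.para
    stopifnot(!is.null(zcols))
    y <- dat$frailty
    X <- des$X
    Xf <- X[, -zcols, drop = FALSE]
    Z <- X[, zcols, drop = FALSE]
    S_ff <- des$S[-zcols, -zcols, drop = FALSE]
    S_zz <- des$S[zcols, zcols, drop = FALSE]
    A_ff <- crossprod(Xf) + S_ff
    A_zz <- crossprod(Z) + S_zz   # invariant under row permutation of Z
    b_f <- crossprod(Xf, y)
    pf <- ncol(Xf); pz <- ncol(Z)
    A <- matrix(0, pf + pz, pf + pz)
    A[seq_len(pf), seq_len(pf)] <- A_ff
    A[pf + seq_len(pz), pf + seq_len(pz)] <- A_zz
    dev_for <- function(Zp) {
      A_fz <- crossprod(Xf, Zp)
      A[seq_len(pf), pf + seq_len(pz)] <- A_fz
      A[pf + seq_len(pz), seq_len(pf)] <- t(A_fz)
      beta <- solve(A, c(b_f, crossprod(Zp, y)))
      r <- y - Xf %*% beta[seq_len(pf)] - Zp %*% beta[pf + seq_len(pz)]
      sum(r * r)
    }
    d_obs <- dev_for(Z)
    d_perm <- vapply(draws$perms, function(p)
      dev_for(Z[p, , drop = FALSE]), 0)
  }
  p_hat <- (sum(d_perm <= d_obs) + 0.5) / (n_perm + 1)
  structure(list(p_value = p_hat, observed_deviance = d_obs,
                 permuted_deviances = d_perm, n_perm = n_perm,
                 seed = seed, n = n, fit = fit,
                 sp_used = if (refit_smoothing) NULL else fit_sp$sp,
                 refit_smoothing = refit_smoothing),
            class = "permutation_test")
}

#' @export
print.permutation_test <- function(x, ...) {
  cat(sprintf(
    "Permutation test: deviance %.4g, p-hat = %.4g (%d permutations, n = %d)\n",
    x$observed_deviance, x$p_value, x$n_perm, x$n))
  invisible(x)
}

#' Two-stage screen-and-validate permutation testing
#'
#' Stage 1 runs every candidate test on a random `split` fraction of the
#' individuals; tests with screening p-value below `screen_threshold`
#' proceed to stage 2 on the complementary fraction, where p-values are
#' Holm-corrected.
#'
#' @param pheno Phenotype data.frame with columns `age`, `weight_kg`,
#'   `bmi`, `abdocirc_cm`, `sex`, the frailty columns and the somatic
#'   measure columns.
#' @param tests Data.frame with columns `frailty`, `somatic` (column
#'   names in `pheno`) and `sex` (`"all"` or a sex code restricting the
#'   test).
#' @param n_perm Permutations per test.
#' @param seed Integer seed (drives the split and every permutation run).
#' @param split Screening fraction (default 0.25).
#' @param screen_threshold Stage-1 p-value threshold (default 0.2).
#' @return A data.frame of tests with `p_screen`, `p_validate`,
#'   `p_validate_holm` (`NA` for tests that failed the screen).
#' @export
two_stage_screen <- function(pheno, tests, n_perm = 1000L, seed = 1L,
                             split = 0.25, screen_threshold = 0.2) {
  if (nrow(tests) < 2) stop("at least two candidate tests required",
                            call. = FALSE)
  n <- nrow(pheno)
  idx1 <- with_seed(seed, sort(sample.int(n, round(split * n))))
  idx2 <- setdiff(seq_len(n), idx1)
  run <- function(rows, test, s) {
    d <- pheno[rows, , drop = FALSE]
    if (test$sex != "all") d <- d[d$sex == test$sex, , drop = FALSE]
    permutation_gam_test(d[[test$frailty]], d$age, d$weight_kg, d$bmi,
                         d$abdocirc_cm, d[[test$somatic]],
                         n_perm = n_perm, seed = s)$p_value
  }
  out <- tests
  out$p_screen <- vapply(seq_len(nrow(tests)), function(i)
    run(idx1, tests[i, ], seed + i), 0)
  out$p_validate <- NA_real_
  pass <- which(out$p_screen < screen_threshold)
  if (length(pass)) {
    out$p_validate[pass] <- vapply(pass, function(i)
      run(idx2, tests[i, ], seed + 1000L + i), 0)
    out$p_validate_holm <- NA_real_
    out$p_validate_holm[pass] <- holm_correct(out$p_validate[pass])
  } else {
    message("none passed screen")
    out$p_validate_holm <- NA_real_
  }
  attr(out, "screen_idx") <- idx1
  out
}

#' Age-local quantile of a measure
#'
#' For each individual, the value's empirical quantile (fraction of
#' neighbourhood values at or below it, self included) among all
#' individuals whose integer-rounded age is within `window` years of the
#' individual's own.
#'
#' @param values Numeric measure (e.g. mitochondrial copy number).
#' @param ages Ages in years.
#' @param window Neighbourhood half-width in integer years (default 1).
#' @return Numeric vector of quantiles in `(0, 1]`. Singleton
#'   neighbourhoods yield 1 (with a warning).
#' @export
age_local_quantile <- function(values, ages, window = 1L) {
  stopifnot(length(values) == length(ages))
  a <- round(ages)
  q <- numeric(length(values))
  singles <- 0L
  for (lvl in unique(a)) {
    self <- which(a == lvl)
    nbr <- which(abs(a - lvl) <= window)
    if (length(nbr) == 1) singles <- singles + length(self)
    ecdf_vals <- vapply(values[self], function(v)
      mean(values[nbr] <= v), 0)
    q[self] <- ecdf_vals
  }
  if (singles) warning(singles, " singleton neighbourhood(s); quantile 1")
  q
}

# shortest interval containing a fraction `prob` of the sample
hpd_interval <- function(x, prob = 0.95) {
  x <- sort(x[is.finite(x)])
  n <- length(x)
  if (n == 0) return(c(NA_real_, NA_real_))
  k <- max(1L, ceiling(prob * n))
  if (k >= n) return(c(x[1], x[n]))
  w <- x[(k + 1):n] - x[seq_len(n - k)]
  i <- which.min(w)
  c(x[i], x[i + k])
}

#' Effective-age curve from an age-local quantile effect
#'
#' Fits `frailty ~ age + s(q)` and converts the predicted frailty at a
#' reference age across quantiles `q` into an age excess by inverting
#' through the linear age coefficient, relative to the median quantile
#' `q = 0.5`: `age_excess(q) = (pred(q) - pred(0.5)) / beta_age`.
#' Uncertainty comes from bootstrap resampling of individuals, summarised
#' as highest-posterior-density (shortest) intervals.
#'
#' @param frailty,age,q Numeric vectors (e.g. grip strength, age,
#'   age-local mtDNA quantile).
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Integer seed.
#' @param ref_age Reference age for prediction (default: median age).
#' @param q_grid Quantile grid for the curve.
#' @param conf_level HPD mass (default 0.95).
#' @return An object of class `effective_age_curve`: data.frame `curve`
#'   with `q`, `age_excess`, `lower`, `upper`, plus `beta_age`, `fit`.
#' @export
effective_age_curve <- function(frailty, age, q, n_boot = 1000L,
                                seed = 1L, ref_age = NULL,
                                q_grid = seq(0.05, 0.95, by = 0.05),
                                conf_level = 0.95) {
  dat <- data.frame(frailty = frailty, age = age, q = q)
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  if (is.null(ref_age)) ref_age <- stats::median(dat$age)
  curve_of <- function(d) {
    fit <- mgcv::gam(frailty ~ age + s(q), data = d)
    beta_age <- stats::coef(fit)["age"]
    pr <- stats::predict(fit, newdata = data.frame(
      age = ref_age, q = c(q_grid, 0.5)))
    ref <- pr[length(pr)]
    list(excess = (pr[seq_along(q_grid)] - ref) / beta_age,
         beta_age = unname(beta_age), fit = fit)
  }
  obs <- curve_of(dat)
  if (abs(obs$beta_age) < 1e-10)
    warning("age coefficient near zero; effective-age inversion unstable")
  boots <- with_seed(seed, {
    replicate(n_boot, {
      idx <- sample.int(nrow(dat), replace = TRUE)
      curve_of(dat[idx, , drop = FALSE])$excess
    })
  })
  hpd <- apply(boots, 1, hpd_interval, prob = conf_level)
  structure(list(curve = data.frame(q = q_grid,
                                    age_excess = unname(obs$excess),
                                    lower = hpd[1, ], upper = hpd[2, ]),
                 beta_age = obs$beta_age, ref_age = ref_age,
                 n_boot = n_boot, fit = obs$fit),
            class = "effective_age_curve")
}

#' @export
print.effective_age_curve <- function(x, ...) {
  cat(sprintf(
    "Effective-age curve at reference age %.0f (beta_age = %.3f/yr, %d bootstraps)\n",
    x$ref_age, x$beta_age, x$n_boot))
  print(utils::head(x$curve, 5))
  invisible(x)
}

#' @export
plot.effective_age_curve <- function(x, ...) {
  cv <- x$curve
  graphics::plot(cv$q, cv$age_excess, type = "l", lwd = 2,
                 ylim = range(c(cv$lower, cv$upper), na.rm = TRUE),
                 xlab = "age-local quantile", ylab = "age excess (years)",
                 ...)
  graphics::lines(cv$q, cv$lower, lty = 2)
  graphics::lines(cv$q, cv$upper, lty = 2)
  graphics::abline(h = 0, col = "grey")
  invisible(x)
}

#' Cohort intercept correction of a somatic measure
#'
#' Fits `measure ~ s(age, by = sex) + sex + cohort` (Gaussian additive
#' model) and shifts each individual's measure by the difference between
#' its cohort's intercept estimate and the reference cohort's:
#' `y' = y - s_C + s_ref`. Purely an additive shift: within-cohort
#' variance is preserved.
#'
#' @param measure,age Numeric vectors.
#' @param sex,cohort Factors (or coercible).
#' @param reference Name of the reference cohort.
#' @return Numeric vector of adjusted measures, with the per-cohort
#'   intercepts in attribute `intercepts`.
#' @export
cohort_intercept_adjust <- function(measure, age, sex, cohort, reference) {
  cohort <- factor(cohort)
  sex <- factor(sex)
  if (!reference %in% levels(cohort))
    stop("reference cohort absent", call. = FALSE)
  if (nlevels(cohort) == 1) {
    out <- measure
    attr(out, "intercepts") <- stats::setNames(0, levels(cohort))
    return(out)
  }
  dat <- data.frame(y = measure, age = age, sex = sex, cohort = cohort)
  fit <- if (nlevels(sex) > 1)
    mgcv::gam(y ~ s(age, by = sex) + sex + cohort, data = dat)
  else mgcv::gam(y ~ s(age) + cohort, data = dat)
  cf <- stats::coef(fit)
  s_c <- stats::setNames(numeric(nlevels(cohort)), levels(cohort))
  for (lvl in levels(cohort)[-1]) s_c[lvl] <- cf[paste0("cohort", lvl)]
  out <- measure - s_c[as.character(cohort)] + s_c[reference]
  attr(out, "intercepts") <- s_c
  names(out) <- NULL
  out
}
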