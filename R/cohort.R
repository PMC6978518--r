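# Cohort-level germline comparisons: Fisher carrier-burden and
# direction-of-effect tests, polygenic scores, the drift-aware bootstrap,
# and two-sample power curves.

#' Fisher carrier-burden test
#'
#' Exact test of carrier rates between two cohorts. The point estimate is
#' the cross-product odds ratio `(a d) / (b c)` (with a Haldane 0.5
#' continuity correction, reported, when a cell is zero); the p-value and
#' confidence interval come from the exact conditional test
#' ([stats::fisher.test()], i.e. inversion of the noncentral
#' hypergeometric distribution).
#'
#' @param a,b Carriers and non-carriers in cohort 1.
#' @param c,d Carriers and non-carriers in cohort 2.
#' @param conf_level Confidence level (default 0.95).
#' @return An object of class `carrier_fisher` with `odds_ratio`,
#'   `p_value`, `conf_int`, `table`, `haldane`.
#' @export
#' @examples
#' carrier_fisher(2, 715, 12, 257)  # odds ratio 0.060
carrier_fisher <- function(a, b, c, d, conf_level = 0.95) {
  tab <- matrix(c(a, b, c, d), 2, 2, byrow = TRUE,
                dimnames = list(c("cohort1", "cohort2"),
                                c("carrier", "non_carrier")))
  if (any(tab < 0)) stop("cell counts must be non-negative", call. = FALSE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("degenerate table: empty row or column", call. = FALSE)
  haldane <- any(tab == 0)
  t2 <- if (haldane) tab + 0.5 else tab
  if (haldane) message("zero cell: Haldane 0.5 correction applied")
  or <- (t2[1, 1] * t2[2, 2]) / (t2[1, 2] * t2[2, 1])
  ft <- stats::fisher.test(tab, conf.level = conf_level)
  structure(list(odds_ratio = or, p_value = ft$p.value,
                 conf_int = as.numeric(ft$conf.int), table = tab,
                 haldane = haldane, conf_level = conf_level),
            class = "carrier_fisher")
}

#' @export
print.carrier_fisher <- function(x, ...) {
  cat(sprintf(
    "Carrier burden: OR = %.3g, %g%% CI [%.3g, %.3g], exact p = %.3g%s\n",
    x$odds_ratio, 100 * x$conf_level, x$conf_int[1], x$conf_int[2],
    x$p_value, if (x$haldane) " (Haldane-corrected OR)" else ""))
  invisible(x)
}

#' Direction-of-effect allele-frequency bias test
#'
#' For a phenotype-associated variant set, cross-tabulates whether each
#' variant is enriched or depleted in cohort 1 against whether its effect
#' allele is a risk or protective allele, and applies Fisher's exact test.
#' Deviation from independence indicates a phenotype-specific allele
#' frequency bias between the cohorts. Variants with zero frequency
#' difference are dropped (count reported).
#'
#' @param freq1,freq2 Effect-allele frequencies per variant in the two
#'   cohorts.
#' @param effect_sign Trait direction of effect per variant: positive for
#'   risk alleles, negative for protective.
#' @return An object of class `carrier_fisher` (2x2 Fisher result) with an
#'   added `n_dropped`.
#' @export
direction_bias_test <- function(freq1, freq2, effect_sign) {
  stopifnot(length(freq1) == length(freq2),
            length(freq1) == length(effect_sign))
  diff <- freq1 - freq2
  keep <- diff != 0 & effect_sign != 0
  n_drop <- sum(!keep)
  if (n_drop) message(n_drop, " variant(s) with zero difference dropped")
  enriched <- diff[keep] > 0
  risk <- effect_sign[keep] > 0
  out <- carrier_fisher(sum(enriched & risk), sum(enriched & !risk),
                        sum(!enriched & risk), sum(!enriched & !risk))
  out$n_dropped <- n_drop
  out
}

#' Per-individual polygenic scores
#'
#' `S_i = sum_j beta_j d_ij` over the score loci, where dosages `d_ij` are
#' in `{0, 1, 2}`. Loci with a call rate below `min_call_rate` are removed
#' before scoring; remaining missing dosages are imputed as `2 f_j` using
#' the reference frequency of the score definition. A locus entirely
#' absent from the genotypes has call rate 0 and is removed (reported).
#'
#' @param dosages Numeric matrix, individuals x loci (column names are
#'   locus identifiers); `NA` for missing genotypes.
#' @param score_def Data.frame with columns `locus`, `beta`, `ref_freq`.
#' @param min_call_rate Call-rate threshold (default 0.97).
#' @return Numeric vector of per-individual scores, with the retained locus
#'   count in attribute `n_loci`.
#' @export
polygenic_score <- function(dosages, score_def, min_call_rate = 0.97) {
  dosages <- as.matrix(dosages)
  idx <- match(score_def$locus, colnames(dosages))
  absent <- is.na(idx)
  if (any(absent))
    message(sum(absent), " score locus/loci absent from genotypes removed")
  def <- score_def[!absent, , drop = FALSE]
  D <- dosages[, idx[!absent], drop = FALSE]
  call_rate <- colMeans(!is.na(D))
  keep <- call_rate >= min_call_rate
  def <- def[keep, , drop = FALSE]
  D <- D[, keep, drop = FALSE]
  for (j in seq_len(ncol(D))) {
    miss <- is.na(D[, j])
    if (any(miss)) D[miss, j] <- 2 * def$ref_freq[j]
  }
  structure(as.numeric(D %*% def$beta), n_loci = nrow(def))
}

#' Expected polygenic score of a cohort from allele frequencies
#'
#' `s_Cohort = (2 / n) * sum_j f_j beta_j` over the `n` score loci.
#'
#' @param freqs Data.frame with columns `locus`, `freq` (cohort
#'   effect-allele frequencies).
#' @param score_def Data.frame with columns `locus`, `beta`.
#' @return Scalar expected score.
#' @export
expected_cohort_score <- function(freqs, score_def) {
  idx <- match(score_def$locus, freqs$locus)
  if (anyNA(idx))
    stop("score locus missing from the frequency table (filter first)",
         call. = FALSE)
  (2 / nrow(score_def)) * sum(freqs$freq[idx] * score_def$beta)
}

#' Drift-aware bootstrap test of polygenic-score depletion
#'
#' Tests whether the expected polygenic score in the first cohort is
#' shifted relative to the second beyond what genetic drift explains.
#' Per-locus drift distances `d2 = (f_1 - f_2) / sqrt(f_2 (1 - f_2))` are
#' pooled over all well-genotyped loci (call rate at least
#' `min_call_rate` in both cohorts and absolute frequency difference below
#' `max_freq_diff`; score loci are included in the pool). Each bootstrap
#' round resamples `d2` with replacement per score locus, forms a
#' simulated reference cohort `f_ref = f_2 + d2 * sqrt(f_2 (1 - f_2))`
#' (clipped to `[0, 1]`; clip events counted), and records the depletion
#' statistic `s_1 - s_ref`. The two-sided p-value is
#' `(2 / (B + 1)) * (1/2 + min(#[s_1 < s_ref], #[s_1 > s_ref]))`.
#' Scores are normalised so the bootstrap reference-cohort scores have
#' mean 0 and standard deviation 1; confidence intervals are the 0.025 and
#' 0.975 quantiles of the normalised depletion.
#'
#' @param freq1,freq2 Cohort frequency tables (`locus`, `freq`,
#'   `call_rate`); `freq2` is the comparator whose drifted bootstrap
#'   replicates form the reference.
#' @param score_def Data.frame with columns `locus`, `beta`.
#' @param B Bootstrap rounds (default 1e5).
#' @param seed Integer seed.
#' @param min_call_rate Call-rate filter (default 0.97).
#' @param max_freq_diff Absolute frequency-difference filter (default
#'   0.04), applied to both the pool and the score loci.
#' @param filter_pool Apply the frequency-difference filter to the d2 pool
#'   as well as the score loci (default `TRUE`).
#' @return An object of class `drift_bootstrap`.
#' @export
drift_bootstrap <- function(freq1, freq2, score_def, B = 1e5L, seed = 1L,
                            min_call_rate = 0.97, max_freq_diff = 0.04,
                            filter_pool = TRUE) {
  m <- merge(freq1, freq2, by = "locus", suffixes = c("_1", "_2"))
  well <- m$call_rate_1 >= min_call_rate & m$call_rate_2 >= min_call_rate
  small <- abs(m$freq_1 - m$freq_2) < max_freq_diff
  pool_keep <- well & (!filter_pool | small)
  if (!any(pool_keep)) stop("empty d2 pool after filters", call. = FALSE)
  d2_pool <- (m$freq_1[pool_keep] - m$freq_2[pool_keep]) /
    sqrt(m$freq_2[pool_keep] * (1 - m$freq_2[pool_keep]))
  sc <- m[m$locus %in% score_def$locus & well & small, , drop = FALSE]
  def <- score_def[match(sc$locus, score_def$locus), , drop = FALSE]
  n_sc <- nrow(sc)
  if (n_sc == 0) stop("no score loci survive the filters", call. = FALSE)
  s1 <- (2 / n_sc) * sum(sc$freq_1 * def$beta)
  s2 <- (2 / n_sc) * sum(sc$freq_2 * def$beta)
  w <- sqrt(sc$freq_2 * (1 - sc$freq_2))
  clipped <- 0L
  s_ref <- with_seed(seed, {
    out <- numeric(B)
    chunk <- max(1L, min(B, as.integer(2e6 / n_sc)))
    done <- 0L
    while (done < B) {
      nb <- min(chunk, B - done)
      d2s <- matrix(sample(d2_pool, nb * n_sc, replace = TRUE), n_sc, nb)
      f_ref <- sc$freq_2 + d2s * w
      nclip <- sum(f_ref < 0 | f_ref > 1)
      if (nclip) {
        clipped <- clipped + nclip
        f_ref <- pmin(pmax(f_ref, 0), 1)
      }
      out[done + seq_len(nb)] <- (2 / n_sc) * colSums(f_ref * def$beta)
      done <- done + nb
    }
    out
  })
  n_less <- sum(s1 < s_ref)
  n_greater <- sum(s1 > s_ref)
  p <- (2 / (B + 1)) * (0.5 + min(n_less, n_greater))
  mu <- mean(s_ref); sdv <- stats::sd(s_ref)
  # degenerate reference distribution (e.g. an all-zero d2 pool): report
  # unnormalised zero shifts rather than 0/0
  delta_norm <- if (sdv > 0) (s1 - s_ref) / sdv else (s1 - s_ref) * 0
  structure(list(
    depletion = s1 - s2,
    depletion_normalised = mean(delta_norm),
    conf_int = unname(stats::quantile(delta_norm, c(0.025, 0.975))),
    p_value = p, B = as.integer(B), seed = seed,
    n_score_loci = n_sc, n_pool = length(d2_pool),
    n_less = n_less, n_greater = n_greater, clipped = clipped,
    s_cohort1 = s1, s_cohort2 = s2,
    ref_mean = mu, ref_sd = sdv), class = "drift_bootstrap")
}

#' @export
print.drift_bootstrap <- function(x, ...) {
  cat(sprintf(
    "Drift bootstrap (B = %d, %d score loci, pool %d):\n", x$B,
    x$n_score_loci, x$n_pool))
  cat(sprintf(
    "  depletion %.4g (normalised %.3f, 95%% CI [%.3f, %.3f]), p = %.4g\n",
    x$depletion, x$depletion_normalised, x$conf_int[1], x$conf_int[2],
    x$p_value))
  if (x$clipped)
    cat(sprintf("  %d bootstrap frequencies clipped to [0, 1]\n",
                x$clipped))
  invisible(x)
}

#' Analytic two-sample t power and sample-size curves
#'
#' Computes two-sample t-test power over a grid of per-group sample sizes
#' for a given mean shift and unit-sample standard deviation (via
#' [stats::power.t.test()], which root-finds the relevant noncentral t
#' distributions), and inverts the power-vs-n relationship by piecewise
#' linear interpolation to sample size vs power.
#'
#' @param shift Mean difference between groups.
#' @param sd1 Pooled standard deviation scaled to a sample size of 1.
#' @param n_grid Per-group sample sizes (default `2^(1:14)`).
#' @param alpha Significance level (default 0.05).
#' @param power_grid Power values at which to interpolate sample sizes.
#' @return A list of class `power_curve` with `power_by_n` and
#'   `n_by_power` data.frames. A zero shift gives power `alpha` at every
#'   `n`.
#' @export
power_curve <- function(shift, sd1, n_grid = 2^(1:14), alpha = 0.05,
                        power_grid = seq(0.1, 0.95, by = 0.05)) {
  power <- vapply(n_grid, function(n) {
    if (shift == 0) return(alpha)
    stats::power.t.test(n = n, delta = abs(shift), sd = sd1,
                        sig.level = alpha)$power
  }, 0)
  n_by_power <- if (shift == 0 || length(unique(power)) < 2) {
    data.frame(power = power_grid, n = NA_real_)
  } else {
    data.frame(power = power_grid,
               n = stats::approx(power, n_grid, xout = power_grid,
                                 ties = "ordered")$y)
  }
  structure(list(power_by_n = data.frame(n = n_grid, power = power),
                 n_by_power = n_by_power, shift = shift, sd1 = sd1,
                 alpha = alpha), class = "power_curve")
}

#' @export
print.power_curve <- function(x, ...) {
  cat(sprintf("Power curve: shift %.4g, unit-sample SD %.4g, alpha %g\n",
              x$shift, x$sd1, x$alpha))
  print(utils::head(x$power_by_n, 8))
  invisible(x)
}

#' Holm step-down multiple-testing correction
#'
#' @param p Vector of p-values.
#' @return Adjusted p-values (via [stats::p.adjust()]).
#' @export
holm_correct <- function(p) stats::p.adjust(p, method = "holm")
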