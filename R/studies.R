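# Desk-scale replication studies: seeded end-to-end exercises of each
# pipeline stage on synthetic cohorts, at sizes a laptop handles. Tests
# and the acceptance script consume the raw results these return.

#' Replication studies at desk scale
#'
#' Each `study_*` function runs one pipeline stage end-to-end on seeded
#' synthetic data under the package's reference study conditions and
#' returns the raw per-replicate results (estimates, selected
#' cardinalities, p-values, flags) for downstream summary.
#'
#' @param seed Integer base seed; replicate `i` uses `seed * 1000 + i`.
#' @name studies
NULL

#' @describeIn studies Subclonal CNV parameter recovery: for each planted
#'   clone fraction, simulate a genome of 8 contigs x 5000 het loci with a
#'   whole-contig (1, 0) deletion (5000 affected loci, depth about 38) and
#'   refit. Returns a data.frame with the planted and recovered fraction,
#'   whether the planted contig's ploidies were recovered exactly, and the
#'   CHIP flag.
#' @param f_values Planted clone fractions.
#' @param n_seeds Replicates per condition.
#' @export
study_cnv_recovery <- function(f_values = c(0.2, 0.3, 0.4), n_seeds = 20L,
                               seed = 1L) {
  seg <- data.frame(contig = "1", start = 1, end = 4e6, k1 = 1, k2 = 0)
  out <- expand.grid(f_true = f_values, rep = seq_len(n_seeds))
  out$f_hat <- NA_real_
  out$planted_exact <- NA
  out$chip <- NA
  for (i in seq_len(nrow(out))) {
    cfg <- sim_config(seed = seed * 1000L + i, n_loci = 40000L,
                      clone_fraction = out$f_true[i], segments = seg)
    x <- gen_cnv_sample(cfg, n_contigs = 8L)
    fit <- fit_cnv(x$loci)
    planted <- fit$segments[fit$segments$contig == "1", , drop = FALSE]
    out$f_hat[i] <- fit$f
    out$planted_exact[i] <- nrow(planted) > 0 &&
      all(planted$k1 == 0 & planted$k2 == 1)
    out$chip[i] <- cnv_chip_flag(fit)
  }
  out
}

#' @describeIn studies Null CNV study: diploid samples (4000 het loci over
#'   2 contigs); returns the per-seed CHIP flag, whose rate is the
#'   false-positive aneuploidy call rate.
#' @export
study_cnv_null <- function(n_seeds = 40L, seed = 1L) {
  vapply(seq_len(n_seeds), function(i) {
    cfg <- sim_config(seed = seed * 1000L + 500L + i, n_loci = 4000L,
                      clone_fraction = 0, segments = NULL)
    cnv_chip_flag(fit_cnv(gen_cnv_sample(cfg, n_contigs = 2L)$loci))
  }, TRUE)
}

#' @describeIn studies Planted three-signature mixture recovery: 200
#'   samples aged 60-95 with three signature activities following
#'   distinct age profiles (declining, rising, mid-life peak) of
#'   comparable magnitude, Poisson class counts. Returns per-seed the
#'   selected cardinality and the worst per-signature cosine of the k = 3
#'   fit against the planted profiles.
#' @export
study_nmf_recovery <- function(n_seeds = 20L, seed = 1L) {
  out <- data.frame(rep = seq_len(n_seeds), k = NA_integer_,
                    min_cosine = NA_real_)
  for (i in seq_len(n_seeds)) {
    s <- seed * 1000L + i
    sim <- with_seed(s, {
      W_true <- matrix(stats::rgamma(96 * 3, 0.5), 96, 3)
      W_true <- sweep(W_true, 2, colSums(W_true), "/")
      n <- 200
      ages <- sort(stats::runif(n, 60, 95))
      base <- cbind(260 * exp(-(ages - 60) / 12),
                    30 + 6 * (ages - 60),
                    230 * exp(-((ages - 77) / 8)^2))
      expo <- base * matrix(exp(stats::rnorm(n * 3, 0, 0.3)), n, 3)
      list(W = W_true, ages = ages,
           M = matrix(stats::rpois(96 * n, W_true %*% t(expo)), 96, n))
    })
    scan <- select_cardinality(sim$M, sim$ages, kmax = 10L,
                               restarts = 100L, seed = s)
    fit <- fit_signatures(sim$M, 3L, restarts = 100L, seed = s)
    out$k[i] <- scan$k
    out$min_cosine[i] <- min(match_signatures(fit$W, sim$W)$cosine)
  }
  out
}

#' @describeIn studies Drift-bootstrap null calibration: drifted cohort
#'   pairs with no planted score depletion; returns the per-seed
#'   bootstrap p-values.
#' @param B Bootstrap rounds.
#' @export
study_drift_null <- function(n_seeds = 100L, B = 10000L, seed = 1L) {
  vapply(seq_len(n_seeds), function(i) {
    cfg <- sim_config(seed = seed * 1000L + i, planted_beta_shift = 0)
    fr <- gen_cohort_freqs(cfg)
    drift_bootstrap(fr$freq_study, fr$freq_other, fr$score_def, B = B,
                    seed = seed * 1000L + i)$p_value
  }, 0)
}

#' @describeIn studies Drift-bootstrap power: cohorts with a planted
#'   depletion of the expected score (default 0.005 score units, several
#'   times the drift standard deviation, comparable to the strongest
#'   published longevity-score depletions); returns per-seed p-values.
#' @param shift Planted depletion in score units.
#' @export
study_drift_power <- function(n_seeds = 20L, B = 10000L, shift = 0.005,
                              seed = 1L) {
  vapply(seq_len(n_seeds), function(i) {
    cfg <- sim_config(seed = seed * 1000L + 200L + i,
                      planted_beta_shift = shift)
    fr <- gen_cohort_freqs(cfg)
    drift_bootstrap(fr$freq_study, fr$freq_other, fr$score_def, B = B,
                    seed = seed * 1000L + 200L + i)$p_value
  }, 0)
}

#' @describeIn studies Permutation-test type-I error: null phenotype
#'   simulations (no planted somatic effect) of `n` individuals; returns
#'   the per-simulation permutation p-values for grip strength against
#'   mitochondrial copy number.
#' @param n_sims Number of null simulations.
#' @param n Individuals per simulation.
#' @param n_perm Permutations per test.
#' @export
study_perm_type1 <- function(n_sims = 200L, n = 500L, n_perm = 1000L,
                             seed = 1L) {
  vapply(seq_len(n_sims), function(i) {
    cfg <- sim_config(seed = seed * 1000L + i, n_individuals = n,
                      planted_mtdna_effect = 0)
    ph <- gen_phenotypes(cfg)
    permutation_gam_test(ph$grip_kg, ph$age, ph$weight_kg, ph$bmi,
                         ph$abdocirc_cm, ph$mtdna_cn, n_perm = n_perm,
                         seed = seed * 1000L + i)$p_value
  }, 0)
}
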