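# Seeded generators for every input the pipeline consumes. Each generator is
# a pure function of its configuration: the seed lives in the config and the
# caller's RNG state is restored on exit.

with_seed <- function(seed, expr) {
  if (is.null(seed) || is.na(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulation configuration
#'
#' Bundles the parameters of the synthetic-data generators. Defaults are the
#' study conditions the pipeline targets: modal autosomal depth 38, base read
#' error rate 2e-3, expected somatic variant allele fraction 0.2, expected
#' heterozygous-locus rate 1e-4 and somatic-locus rate 5e-7 per locus, and an
#' aneuploid clone fraction of 0.2.
#'
#' @param seed Integer seed; every generator is deterministic given the config.
#' @param n_loci Number of loci to simulate.
#' @param mean_depth Mean (and modal) sequencing depth in reads.
#' @param depth_size Negative-binomial size of the per-locus depth model;
#'   the default 100 gives near-Poisson spread.
#' @param error_rate Per-read probability of a base error producing the
#'   counted alternate allele (epsilon).
#' @param het_rate Probability that a locus is a germline heterozygote.
#' @param somatic_vaf Variant allele fraction of planted somatic clones.
#' @param somatic_rate Probability that a reference-homozygous locus carries a
#'   planted somatic variant.
#' @param signature_weights Probability vector of length 96 over the mutation
#'   classes of planted somatic variants; must sum to 1.
#' @param clone_fraction Fraction f of aneuploid cells in CNV simulations,
#'   constrained to `[0, 0.5]` (background diploid majority).
#' @param segments `NULL`, or a data.frame with columns `contig`, `start`,
#'   `end`, `k1`, `k2` giving planted aneuploid segments (1-based inclusive
#'   genomic coordinates, non-negative integer chromatid ploidies).
#' @param gc_bias_amplitude Amplitude of the smooth multiplicative
#'   GC-dependent depth bias (on the log scale).
#' @param nb_size Negative-binomial size (overdispersion) of per-chromatid
#'   allele depths in CNV simulations.
#' @param drift_scale Scale of genetic drift between simulated cohorts:
#'   allele frequencies are perturbed by `drift_scale * sqrt(f(1-f)) * z`
#'   with standard normal z. The default 0.03 corresponds to a fixation
#'   index of about 1e-3, typical of closely related European-ancestry
#'   cohorts.
#' @param n_score_loci Number of polygenic-score loci.
#' @param n_pool_loci Number of genome-wide well-genotyped loci available for
#'   the drift pool (score loci are a subset).
#' @param beta_sd Standard deviation of simulated per-locus score
#'   coefficients (log-odds scale).
#' @param planted_beta_shift Planted depletion of the expected polygenic
#'   score in the first cohort, in score units; 0 plants nothing.
#' @param n_individuals Number of individuals in phenotype simulations.
#' @param age_range Two-element numeric age span in years.
#' @param planted_mtdna_effect Additive effect on grip strength (kg) across
#'   the full span of the age-local mtDNA copy-number quantile, planted in
#'   males only; 0 plants nothing.
#' @param pheno_noise_sd Residual standard deviation of grip strength in kg.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(seed = 1, n_loci = 1000)
#' tab <- gen_snv_sample(cfg)
#' table(tab$truth$status)
sim_config <- function(seed = 1L,
                       n_loci = 10000L,
                       mean_depth = 38,
                       depth_size = 100,
                       error_rate = 2e-3,
                       het_rate = 1e-4,
                       somatic_vaf = 0.2,
                       somatic_rate = 5e-7,
                       signature_weights = rep(1 / 96, 96),
                       clone_fraction = 0.2,
                       segments = NULL,
                       gc_bias_amplitude = 0.3,
                       nb_size = 100,
                       drift_scale = 0.03,
                       n_score_loci = 100L,
                       n_pool_loci = 20000L,
                       beta_sd = 0.15,
                       planted_beta_shift = 0,
                       n_individuals = 2000L,
                       age_range = c(75, 95),
                       planted_mtdna_effect = 0,
                       pheno_noise_sd = 5) {
  cfg <- list(seed = as.integer(seed), n_loci = as.integer(n_loci),
              mean_depth = mean_depth, depth_size = depth_size,
              error_rate = error_rate, het_rate = het_rate,
              somatic_vaf = somatic_vaf, somatic_rate = somatic_rate,
              signature_weights = signature_weights,
              clone_fraction = clone_fraction, segments = segments,
              gc_bias_amplitude = gc_bias_amplitude, nb_size = nb_size,
              drift_scale = drift_scale,
              n_score_loci = as.integer(n_score_loci),
              n_pool_loci = as.integer(n_pool_loci), beta_sd = beta_sd,
              planted_beta_shift = planted_beta_shift,
              n_individuals = as.integer(n_individuals),
              age_range = age_range,
              planted_mtdna_effect = planted_mtdna_effect,
              pheno_noise_sd = pheno_noise_sd)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  for (p in c("error_rate", "het_rate", "somatic_vaf", "somatic_rate"))
    stop_if_not_prob(cfg[[p]], p)
  if (cfg$mean_depth <= 0 || cfg$depth_size <= 0)
    stop("depth configuration must be positive", call. = FALSE)
  if (length(cfg$signature_weights) != 96 ||
      any(cfg$signature_weights < 0) ||
      abs(sum(cfg$signature_weights) - 1) > 1e-9)
    stop("signature_weights must be a 96-vector summing to 1", call. = FALSE)
  if (cfg$clone_fraction < 0 || cfg$clone_fraction > 0.5)
    stop("clone_fraction must lie in [0, 0.5]", call. = FALSE)
  if (!is.null(cfg$segments)) {
    seg <- cfg$segments
    need <- c("contig", "start", "end", "k1", "k2")
    if (!all(need %in% names(seg)))
      stop("segments must have columns contig, start, end, k1, k2",
           call. = FALSE)
    if (any(seg$k1 < 0) || any(seg$k2 < 0))
      stop("segment ploidies must be non-negative", call. = FALSE)
    for (ct in unique(seg$contig)) {
      s <- seg[seg$contig == ct, , drop = FALSE]
      s <- s[order(s$start), , drop = FALSE]
      if (nrow(s) > 1 && any(s$start[-1] <= s$end[-nrow(s)]))
        stop("segments must be non-overlapping within a contig",
             call. = FALSE)
    }
  }
  invisible(cfg)
}

#' Simulate a per-locus allele-count table for somatic SNV calling
#'
#' Each locus is labelled reference-homozygous, germline heterozygous, or
#' somatic. Total depth follows a negative-binomial model around
#' `mean_depth`; alternate-allele counts are binomial with success
#' probability `error_rate` (ref-hom), `1/2 + error_rate/3` (het), or
#' `(1 - 4*error_rate/3) * somatic_vaf + error_rate` (somatic) — the same
#' error model the calling thresholds assume. Somatic loci draw their
#' trinucleotide substitution class from `signature_weights`; background loci
#' are assigned classes uniformly.
#'
#' @param cfg A [sim_config()].
#' @return A list with `counts` (data.frame: contig, pos, ref, alt, n, n_A,
#'   triclass, blacklist) and `truth` (data.frame with the per-locus `status`
#'   label and alt-allele probability `p_alt`).
#' @export
gen_snv_sample <- function(cfg) {
  validate_sim_config(cfg)
  with_seed(cfg$seed, {
    n_loci <- cfg$n_loci
    eps <- cfg$error_rate
    u <- runif(n_loci)
    status <- ifelse(u < cfg$somatic_rate, "somatic",
                     ifelse(u < cfg$somatic_rate + cfg$het_rate,
                            "het", "ref_hom"))
    p_alt <- ifelse(status == "somatic",
                    (1 - 4 * eps / 3) * cfg$somatic_vaf + eps,
                    ifelse(status == "het", 0.5 + eps / 3, eps))
    n <- rnbinom(n_loci, mu = cfg$mean_depth, size = cfg$depth_size)
    n_A <- rbinom(n_loci, n, p_alt)
    classes <- mutation_classes96()
    cls <- sample(classes, n_loci, replace = TRUE)
    som <- status == "somatic"
    if (any(som))
      cls[som] <- sample(classes, sum(som), replace = TRUE,
                         prob = cfg$signature_weights)
    ref <- substr(cls, 3, 3)
    alt <- substr(cls, 5, 5)
    counts <- data.frame(contig = "1", pos = seq_len(n_loci), ref = ref,
                         alt = alt, n = n, n_A = n_A, triclass = cls,
                         blacklist = FALSE, stringsAsFactors = FALSE)
    truth <- data.frame(pos = seq_len(n_loci), status = status,
                        p_alt = p_alt, stringsAsFactors = FALSE)
    list(counts = counts, truth = truth)
  })
}

# smooth latent GC-bias surface used by gen_cnv_sample: a gentle unimodal
# (inverted-U) depth bias peaking near 45% GC, zero-mean over loci
gc_bias_field <- function(gc) {
  b <- -((gc - 0.45) / 0.15)^2
  b - mean(b)
}

#' Simulate het-locus allele depths with a planted aneuploid subclone
#'
#' Generates heterozygous loci on two contigs with per-chromatid read depths
#' drawn from a negative binomial around `c_i * p1` and `c_i * p2`, where
#' `p_j = f * k_j + (1 - f)` for planted segment ploidies `(k1, k2)` and
#' `c_i` is half the expected locus depth including a smooth GC-dependent
#' multiplier of amplitude `gc_bias_amplitude`. Phase is randomised with
#' probability 1/2, producing unphased reference/alternate depths.
#'
#' @param cfg A [sim_config()]; `cfg$segments` gives the planted aneuploid
#'   segments (absent or `NULL` for a fully diploid sample).
#' @param n_contigs Number of contigs the loci are spread over.
#' @return A list with `loci` (data.frame: contig, pos, d_R, d_A, b,
#'   gc100..gc800) and `truth` (clone fraction `f`, per-locus ploidies
#'   `k1`, `k2`, and the GC log-bias `h`).
#' @export
gen_cnv_sample <- function(cfg, n_contigs = 2L) {
  validate_sim_config(cfg)
  with_seed(cfg$seed, {
    n <- cfg$n_loci
    contig <- as.character(rep(seq_len(n_contigs), length.out = n))
    contig <- contig[order(as.integer(contig))]
    pos <- unlist(lapply(split(seq_len(n), contig), function(idx)
      cumsum(50L + rpois(length(idx), 550))), use.names = FALSE)
    # latent GC composition: a common locus GC level observed in 5 windows
    gc_core <- rbeta(n, 8, 10)            # centred near 0.44
    # nested windows around the same locus: tightly correlated observations
    # of the core GC level
    win <- c(100, 200, 400, 600, 800)
    g <- sapply(seq_along(win), function(j)
      pmin(pmax(gc_core + rnorm(n, 0, 0.008 * sqrt(j)), 0), 1))
    colnames(g) <- paste0("gc", win)
    b <- exp(rnorm(n, 0, 0.03))          # cohort baseline relative depth
    h <- if (cfg$gc_bias_amplitude > 0)
      cfg$gc_bias_amplitude * gc_bias_field(gc_core) else rep(0, n)
    c_i <- (cfg$mean_depth / 2) * b * exp(h)
    k1 <- rep(1L, n); k2 <- rep(1L, n)
    f <- cfg$clone_fraction
    if (!is.null(cfg$segments) && f > 0) {
      for (r in seq_len(nrow(cfg$segments))) {
        s <- cfg$segments[r, ]
        hit <- contig == as.character(s$contig) & pos >= s$start &
          pos <= s$end
        k1[hit] <- as.integer(s$k1); k2[hit] <- as.integer(s$k2)
      }
    }
    p1 <- f * k1 + (1 - f)
    p2 <- f * k2 + (1 - f)
    d1 <- rnbinom(n, mu = c_i * p1, size = cfg$nb_size)
    d2 <- rnbinom(n, mu = c_i * p2, size = cfg$nb_size)
    swap <- runif(n) < 0.5
    d_R <- ifelse(swap, d2, d1)
    d_A <- ifelse(swap, d1, d2)
    loci <- data.frame(contig = contig, pos = pos, d_R = d_R, d_A = d_A,
                       b = b, stringsAsFactors = FALSE)
    loci <- cbind(loci, as.data.frame(g))
    truth <- list(f = if (all(k1 == 1L & k2 == 1L)) 0 else f,
                  k1 = k1, k2 = k2, h = h, c = c_i, swap = swap)
    list(loci = loci, truth = truth)
  })
}

#' Simulate allele-frequency tables for two drifted cohorts plus a score
#'
#' Base effect-allele frequencies are drawn from Beta(2, 2); the second
#' cohort is perturbed by `drift_scale * sqrt(f(1-f)) * z`. A polygenic-score
#' definition over `n_score_loci` of the pool loci is generated with normal
#' coefficients, and an optional depletion of total magnitude
#' `planted_beta_shift` (in expected-score units) is planted in the first
#' cohort by moving score-locus frequencies against the coefficient signs.
#' Frequencies are clipped to `[1e-6, 1 - 1e-6]`; the number of clipped
#' values is recorded in the `clipped` attribute of each table.
#'
#' @param cfg A [sim_config()].
#' @return A list with `freq_study` and `freq_other` (data.frames: locus,
#'   freq, call_rate), and `score_def` (data.frame: locus, effect_allele,
#'   beta, ref_freq).
#' @export
gen_cohort_freqs <- function(cfg) {
  validate_sim_config(cfg)
  if (cfg$n_score_loci < 1) stop("n_score_loci must be >= 1", call. = FALSE)
  with_seed(cfg$seed, {
    n_pool <- max(cfg$n_pool_loci, cfg$n_score_loci)
    locus <- sprintf("L%06d", seq_len(n_pool))
    f_base <- rbeta(n_pool, 2, 2)
    z <- rnorm(n_pool)
    f1 <- f_base
    f2 <- f_base + cfg$drift_scale * sqrt(f_base * (1 - f_base)) * z
    score_idx <- sample.int(n_pool, cfg$n_score_loci)
    beta <- rnorm(cfg$n_score_loci, 0, cfg$beta_sd)
    if (cfg$planted_beta_shift > 0) {
      w <- sqrt(f2[score_idx] * (1 - f2[score_idx]))
      kappa <- cfg$planted_beta_shift * cfg$n_score_loci /
        (2 * sum(abs(beta) * w))
      f1[score_idx] <- f1[score_idx] - sign(beta) * kappa * w
    }
    clip <- function(f) {
      clipped <- sum(f < 1e-6 | f > 1 - 1e-6)
      structure(pmin(pmax(f, 1e-6), 1 - 1e-6), clipped = clipped)
    }
    f1 <- clip(f1); f2 <- clip(f2)
    call_rate1 <- rbeta(n_pool, 400, 2)
    call_rate2 <- rbeta(n_pool, 400, 2)
    mk <- function(f, cr) structure(
      data.frame(locus = locus, freq = as.numeric(f), call_rate = cr,
                 stringsAsFactors = FALSE),
      clipped = attr(f, "clipped"))
    list(freq_study = mk(f1, call_rate1),
         freq_other = mk(f2, call_rate2),
         score_def = data.frame(locus = locus[score_idx],
                                effect_allele = "A", beta = beta,
                                ref_freq = f_base[score_idx],
                                stringsAsFactors = FALSE))
  })
}

#' Simulate an elderly phenotype table with somatic measures
#'
#' Ages are uniform over `age_range`; grip strength declines linearly with
#' age with Gaussian noise, and an optional additive effect of the age-local
#' mitochondrial copy-number quantile is planted in males only, spanning
#' `planted_mtdna_effect` kg across the full quantile range. Gait speed,
#' weight, BMI and abdominal circumference are drawn with realistic elderly
#' means so that conditioning covariates are available.
#'
#' @param cfg A [sim_config()].
#' @return A data.frame with columns id, cohort, sex, age, weight_kg, bmi,
#'   abdocirc_cm, grip_kg, gait_m_s, mtdna_cn and the planted quantile
#'   `q_mtdna` used for truth checking.
#' @export
gen_phenotypes <- function(cfg) {
  validate_sim_config(cfg)
  if (diff(range(cfg$age_range)) < 10)
    stop("ages must span at least 10 years", call. = FALSE)
  with_seed(cfg$seed, {
    n <- cfg$n_individuals
    age <- runif(n, cfg$age_range[1], cfg$age_range[2])
    sex <- sample(c("M", "F"), n, replace = TRUE)
    mtdna_cn <- exp(rnorm(n, log(200) - 0.1 * (age - 80) / 10, 0.25))
    q <- age_local_quantile(mtdna_cn, age)
    male <- sex == "M"
    grip <- ifelse(male, 82, 64) - 0.5 * age +
      cfg$planted_mtdna_effect * (q - 0.5) * male +
      rnorm(n, 0, cfg$pheno_noise_sd)
    gait <- pmax(1.3 - 0.012 * (age - 70) +
                   rnorm(n, 0, 0.2 * cfg$pheno_noise_sd / 5), 0.1)
    data.frame(id = sprintf("S%05d", seq_len(n)), cohort = "SIM", sex = sex,
               age = age,
               weight_kg = ifelse(male, 78, 66) + rnorm(n, 0, 10),
               bmi = rnorm(n, 27, 4),
               abdocirc_cm = rnorm(n, 97, 11),
               grip_kg = grip, gait_m_s = gait,
               mtdna_cn = mtdna_cn, q_mtdna = q,
               stringsAsFactors = FALSE)
  })
}

#' Simulate contig read-count summaries with a planted mtDNA copy number
#'
#' Emulates the per-contig mapped-read summary (as reported by
#' `samtools idxstats`) for a sample with a given mitochondrial copy number
#' per nucleus and Y copy number, at a given autosomal depth. Read counts
#' are Poisson around the expected per-contig totals.
#'
#' @param copies_mt Mitochondrial genomes per nucleus.
#' @param copies_y Y chromosomes per nucleus (0 for females).
#' @param mean_depth Autosomal haploid-pair depth in reads.
#' @param read_length Read length in bp.
#' @param seed Integer seed.
#' @return A data.frame with columns contig, length, mapped.
#' @export
gen_contig_summary <- function(copies_mt = 300, copies_y = 1,
                               mean_depth = 38, read_length = 150,
                               seed = 1L) {
  with_seed(seed, {
    s_a <- 2.88e9; s_y <- 5.7e7; s_mt <- 16569
    lam_a <- s_a * mean_depth / read_length
    lam_y <- s_y * mean_depth / read_length * copies_y / 2
    lam_mt <- s_mt * mean_depth / read_length * copies_mt / 2
    data.frame(contig = c("autosomes", "Y", "MT"),
               length = c(s_a, s_y, s_mt),
               mapped = c(rpois(1, lam_a), rpois(1, lam_y),
                          rpois(1, lam_mt)),
               stringsAsFactors = FALSE)
  })
}

#' Simulate candidate mitochondrial variant records
#'
#' Emits one candidate record per mitochondrial position with at least two
#' alternate reads under a per-site error model, plus optional planted
#' heteroplasmic variants. The per-site error rate defaults to 0.001,
#' below the conservative fixed estimate (0.0025) used by the quality
#' score, reflecting that the score's error parameter is an upper bound.
#'
#' @param depth Total read depth at every site.
#' @param n_sites Number of mitochondrial positions simulated.
#' @param site_error Per-site per-read error rate.
#' @param heteroplasmies `NULL`, or data.frame with columns `pos` and `aaf`
#'   of planted heteroplasmic variants.
#' @param seed Integer seed.
#' @return A data.frame with columns pos, n_alt, N, aaf, strand_bias.
#' @export
gen_mito_variants <- function(depth = 3000, n_sites = 16569,
                              site_error = 0.001, heteroplasmies = NULL,
                              seed = 1L) {
  with_seed(seed, {
    n_alt <- rbinom(n_sites, depth, site_error)
    if (!is.null(heteroplasmies))
      n_alt[heteroplasmies$pos] <-
        rbinom(nrow(heteroplasmies), depth, heteroplasmies$aaf)
    keep <- which(n_alt >= 2)
    n_keep <- n_alt[keep]
    fwd <- rbinom(length(keep), n_keep, 0.5)
    sb <- pmax(fwd, n_keep - fwd) / pmax(n_keep, 1)
    data.frame(pos = keep, n_alt = n_keep, N = depth,
               aaf = n_keep / depth, strand_bias = sb)
  })
}
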