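test_that("error and heterozygote tails match direct summation", {
  expect_equal(pr_err(0, 40, 0.002), 1)
  expect_equal(pr_err(40, 40, 0.002), 0.002^40)
  expect_equal(pr_het(40, 40, 0.002), 1)
  expect_equal(pr_het(0, 40, 0.002), (0.5 - 0.002 / 3)^40)
  expect_equal(pr_err(3, 40, 0.002), oracle_binom_upper(3, 40, 0.002),
               tolerance = 1e-12)
  expect_equal(pr_het(10, 40, 0.002),
               oracle_binom_lower(10, 40, 0.5 + 0.002 / 3),
               tolerance = 1e-12)
  # monotonicity over the full support at several depths
  for (n in c(5, 23, 77)) {
    expect_true(all(diff(pr_err(0:n, n, 0.002)) <= 0))
    expect_true(all(diff(pr_het(0:n, n, 0.002)) >= 0))
  }
})

test_that("threshold optimiser agrees with the brute-force oracle", {
  p <- somatic_params()
  # depth 1 admits no pair with signal-to-noise >= 5
  t1 <- optimal_thresholds(1, p)
  expect_false(t1$feasible)
  expect_equal(t1$p_n, 0)
  expect_false(oracle_thresholds(1)$feasible)
  for (n in c(15, 38, 40, 63, 101)) {
    got <- optimal_thresholds(n, p)
    ora <- oracle_thresholds(n)
    expect_equal(got$feasible, ora$feasible, info = paste("n =", n))
    expect_equal(got$c_E, ora$c_E, info = paste("n =", n))
    expect_equal(got$c_H, ora$c_H, info = paste("n =", n))
    expect_equal(got$p_n, ora$p_n, tolerance = 1e-10,
                 info = paste("n =", n))
  }
})

test_that("unconstrained optimum is the full interval with p_n = r_RR", {
  p <- somatic_params(g_r = 1e-12)
  got <- optimal_thresholds(40, p)
  expect_equal(got$c_E, 0)
  expect_equal(got$c_H, 40)
  expect_equal(got$p_n, p$r_RR, tolerance = 1e-12)
})

test_that("sensitivity is monotone under widening and feasibility monotone in g_r", {
  p <- somatic_params()
  n <- 40
  pmf <- dbinom(0:n, n, p$p_A)
  win <- function(cE, cH) p$r_RR * sum(pmf[(cE + 1):(cH + 1)])
  t40 <- optimal_thresholds(n, p)
  expect_true(win(t40$c_E - 1, t40$c_H) >= t40$p_n)
  expect_true(win(t40$c_E, t40$c_H + 1) >= t40$p_n)
  # feasibility is monotone in g_r
  feas <- vapply(c(0.1, 1, 5, 50, 5000, 5e6),
                 function(g) optimal_thresholds(
                   n, somatic_params(g_r = g))$feasible, TRUE)
  expect_true(all(diff(as.integer(feas)) <= 0))
})

test_that("somatic calling respects thresholds and the blacklist", {
  p <- somatic_params()
  counts <- data.frame(contig = "1", pos = 1:4, ref = "C", alt = "A",
                       n = c(40, 40, 40, 40), n_A = c(0, 6, 6, 2),
                       triclass = "A[C>A]A",
                       blacklist = c(FALSE, FALSE, TRUE, FALSE))
  calls <- call_somatic(counts, p)
  expect_equal(calls$pos, 2L)  # 0 alt and 2 alt below c_E; blacklisted dropped
  # depths above the cap are truncated with a warning
  deep <- data.frame(n = 500, n_A = 6, blacklist = FALSE)
  expect_warning(call_somatic(deep, p), "depth cap")
})

test_that("planted-somatic recall matches the sensitivity formula", {
  p <- somatic_params()
  recalls <- sens <- numeric(20)
  n_som <- numeric(20)
  for (i in 1:20) {
    cfg <- sim_config(seed = 100 + i, n_loci = 20000, somatic_rate = 5e-3)
    sim <- gen_snv_sample(cfg)
    calls <- call_somatic(sim$counts, p)
    som <- sim$truth$status == "somatic"
    n_som[i] <- sum(som)
    recalls[i] <- sum(calls$pos %in% which(som)) / sum(som)
    tab <- threshold_table(p, 101)
    row <- match(pmin(sim$counts$n[som], 101), tab$n)
    sens[i] <- mean(ifelse(is.na(row), 0, tab$p_n[row])) / p$r_RR
  }
  expected <- mean(sens)
  se <- sqrt(expected * (1 - expected) / sum(n_som))
  expect_lt(abs(mean(recalls) - expected), 3 * se + 0.01)
})

test_that("null samples stay within the designed false-call budget", {
  p <- somatic_params()
  tab <- threshold_table(p, 101)
  total_calls <- 0
  total_budget <- 0
  for (s in 1:10) {
    cfg <- sim_config(seed = 300 + s, n_loci = 50000, somatic_rate = 0)
    sim <- gen_snv_sample(cfg)
    total_calls <- total_calls + nrow(call_somatic(sim$counts, p))
    row <- match(pmin(sim$counts$n, 101), tab$n)
    ok <- !is.na(row) & tab$feasible[row]
    total_budget <- total_budget + sum(
      p$r_RR * tab$alpha_E[row[ok]] + p$r_H * tab$alpha_H[row[ok]])
  }
  # expected false calls are a tiny fraction of a call; allow sampling
  # slack of a few events on half a million loci
  expect_lt(total_budget, 0.1)
  expect_lte(total_calls, 2)
})

test_that("normalised burden divides class calls by summed sensitivity", {
  p <- somatic_params()
  cls <- mutation_classes96()
  counts <- data.frame(n = rep(40, 6), n_A = c(6, 7, 0, 0, 1, 2),
                       triclass = c(rep(cls[1], 4), cls[2], cls[2]),
                       blacklist = FALSE)
  calls <- call_somatic(counts, p)
  burden <- normalized_burden(calls, counts, p)
  p40 <- optimal_thresholds(40, p)$p_n
  expect_equal(unname(burden[cls[1]]), 2 / (4 * p40))
  expect_equal(unname(burden[cls[2]]), 0)
  expect_true(all(is.na(burden[cls[3:96]])))  # flagged missing classes
  # no calls at all gives a zero (or missing) vector
  none <- normalized_burden(calls[0, ], counts, p)
  expect_equal(unname(none[cls[1]]), 0)
  expect_error(normalized_burden(calls, data.frame(n = 1, n_A = 0), p),
               "class annotation")
})

test_that("driver rules and the CHIP-by-SNV flag follow the filter cascade", {
  # VAF below 10% is excluded even if otherwise qualifying
  low_vaf <- driver_record(vaf = 0.09, cosmic_count = 500)
  expect_false(chip_driver_calls(low_vaf)$chip)
  # catalogue recurrence boundary is inclusive at 100
  at100 <- driver_record(cosmic_count = 100)
  expect_true(chip_driver_calls(at100)$chip)
  expect_false(chip_driver_calls(driver_record(cosmic_count = 99))$chip)
  # HIGH consequence on a canonical tumour-suppressor transcript
  tsg <- driver_record(consequence = "stop_gained", is_tsg = TRUE)
  expect_true(chip_driver_calls(tsg)$chip)
  # same consequence off the canonical transcript is not a driver
  off <- driver_record(consequence = "stop_gained", is_tsg = TRUE,
                       is_canonical = FALSE)
  expect_false(chip_driver_calls(off)$chip)
  # common, synonymous-like, or weakly supported records are filtered
  expect_false(chip_driver_calls(driver_record(pop_af = 0.002,
                                               cosmic_count = 500))$chip)
  expect_false(chip_driver_calls(driver_record(
    consequence = "synonymous_variant", cosmic_count = 500))$chip)
  expect_false(chip_driver_calls(driver_record(alt_reads = 2,
                                               cosmic_count = 500))$chip)
  # records with missing fields are skipped with a warning
  rec <- rbind(at100, driver_record(cosmic_count = NA))
  expect_warning(out <- chip_driver_calls(rec), "skipped")
  expect_true(out$chip)
})
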