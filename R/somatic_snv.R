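# Dynamic-threshold somatic SNV detection. A variant at a depth-n locus is
# called somatic when its alternate read count n_A lies in [c_E, c_H], with
# the integer thresholds chosen per depth to maximise detection sensitivity
# p_n subject to a minimum true/false positive ratio. The procedure yields a
# per-locus sensitivity estimate used to normalise burden across samples.

#' Somatic filter parameters
#'
#' Parameters of the dynamic-threshold somatic caller, with the defaults
#' tuned for sensitivity at standard (about 38x) sequencing depth:
#' `g_r = 5`, expected somatic VAF `f = 0.2`, base error rate
#' `epsilon = 2e-3`, heterozygous-locus rate `r_H = 1e-4`, and
#' somatic-locus rate `r_C = 5e-7`. Derived quantities:
#' `r_RR = (1 - r_H + sqrt(1 - 2 r_H)) / 2` (probability a locus is
#' reference-homozygous under Hardy-Weinberg) and
#' `p_A = (1 - 4 epsilon / 3) f + epsilon` (alternate-read probability at a
#' somatic locus).
#'
#' @param g_r Minimum acceptable ratio of true to false positive calls.
#' @param f Expected somatic variant allele fraction.
#' @param epsilon Base read error rate.
#' @param r_H Expected rate of heterozygous germline loci.
#' @param r_C Expected rate of somatic variant loci.
#' @return An object of class `somatic_params`.
#' @export
#' @examples
#' p <- somatic_params()
#' optimal_thresholds(40, p)
somatic_params <- function(g_r = 5, f = 0.2, epsilon = 2e-3, r_H = 1e-4,
                           r_C = 5e-7) {
  if (epsilon <= 0 || epsilon >= 1) stop("epsilon must be in (0, 1)")
  if (r_H < 0 || r_H >= 0.5) stop("r_H must be in [0, 0.5)")
  if (f <= 0 || f >= 1) stop("f must be in (0, 1)")
  r_RR <- 0.5 * (1 - r_H + sqrt(1 - 2 * r_H))
  p_A <- (1 - 4 * epsilon / 3) * f + epsilon
  structure(list(g_r = g_r, f = f, epsilon = epsilon, r_H = r_H, r_C = r_C,
                 r_RR = r_RR, p_A = p_A), class = "somatic_params")
}

#' @export
print.somatic_params <- function(x, ...) {
  cat("Somatic filter parameters:\n")
  cat(sprintf("  g_r = %g, f = %g, epsilon = %g, r_H = %g, r_C = %g\n",
              x$g_r, x$f, x$epsilon, x$r_H, x$r_C))
  cat(sprintf("  derived: r_RR = %.8f, p_A = %.8f\n", x$r_RR, x$p_A))
  invisible(x)
}

#' Tail probabilities of the error and heterozygote models
#'
#' `pr_err` is the upper binomial tail `P(X >= n_A)` for
#' `X ~ Binomial(n, epsilon)`: the probability that machine error alone
#' produces at least `n_A` alternate reads. `pr_het` is the lower tail
#' `P(X <= n_A)` for `X ~ Binomial(n, 1/2 + epsilon/3)`: the probability
#' that a heterozygous locus is sampled at or below `n_A` alternate reads.
#' Both are evaluated in log space via [stats::pbinom()].
#'
#' @param n_A Alternate-allele read count(s), `0 <= n_A <= n`.
#' @param n Total depth.
#' @param epsilon Base read error rate.
#' @return Probability vector.
#' @export
pr_err <- function(n_A, n, epsilon) {
  stopifnot(all(n_A >= 0), all(n_A <= n))
  stats::pbinom(n_A - 1, n, epsilon, lower.tail = FALSE)
}

#' @rdname pr_err
#' @export
pr_het <- function(n_A, n, epsilon) {
  stopifnot(all(n_A >= 0), all(n_A <= n))
  stats::pbinom(n_A, n, 0.5 + epsilon / 3)
}

#' Optimal somatic calling thresholds at one depth
#'
#' Enumerates all integer pairs `0 <= c_E <= c_H <= n` and returns the pair
#' maximising the detection sensitivity
#' `p_n = r_RR * P(c_E <= Binomial(n, p_A) <= c_H)` subject to the
#' signal-to-noise constraint
#' `(r_C / (1 - r_C)) * p_n / (r_RR * alpha_E + r_H * alpha_H) >= g_r`,
#' where `alpha_E = pr_err(c_E, n, epsilon)` and
#' `alpha_H = pr_het(c_H, n, epsilon)` are the sizes of the error and
#' heterozygote tests. When no pair satisfies the constraint the depth is
#' infeasible and `p_n = 0`. Ties in `p_n` are broken toward the smallest
#' `c_E`, then the largest `c_H`.
#'
#' @param n Total depth (single positive integer).
#' @param params A [somatic_params()].
#' @return A one-row data.frame with columns n, c_E, c_H, alpha_E, alpha_H,
#'   p_n, feasible.
#' @export
optimal_thresholds <- function(n, params = somatic_params()) {
  stopifnot(length(n) == 1, n >= 1)
  n <- as.integer(n)
  pmf <- stats::dbinom(0:n, n, params$p_A)
  cum <- c(0, cumsum(pmf))              # cum[i+1] = P(X <= i)
  aE <- pr_err(0:n, n, params$epsilon)  # alpha_E by c_E
  aH <- pr_het(0:n, n, params$epsilon)  # alpha_H by c_H
  # all pairs c_E <= c_H
  cE <- rep(0:n, times = (n + 1):1)
  cH <- unlist(lapply(0:n, function(a) a:n), use.names = FALSE)
  p_n <- params$r_RR * (cum[cH + 2] - cum[cE + 1])
  noise <- params$r_RR * aE[cE + 1] + params$r_H * aH[cH + 1]
  ratio <- (params$r_C / (1 - params$r_C)) * p_n / noise
  feas <- is.finite(ratio) & ratio >= params$g_r
  if (!any(feas)) {
    return(data.frame(n = n, c_E = NA_integer_, c_H = NA_integer_,
                      alpha_E = NA_real_, alpha_H = NA_real_, p_n = 0,
                      feasible = FALSE))
  }
  idx <- which(feas)
  # maximise p_n; ties: smallest c_E then largest c_H
  ord <- order(-p_n[idx], cE[idx], -cH[idx])
  best <- idx[ord[1]]
  data.frame(n = n, c_E = cE[best], c_H = cH[best],
             alpha_E = aE[cE[best] + 1], alpha_H = aH[cH[best] + 1],
             p_n = p_n[best], feasible = TRUE)
}

#' Threshold table over a range of depths
#'
#' @param params A [somatic_params()].
#' @param max_depth Largest depth to tabulate (default 101, the pileup
#'   depth cap).
#' @return A data.frame with one row per depth `1..max_depth`.
#' @export
threshold_table <- function(params = somatic_params(), max_depth = 101L) {
  do.call(rbind, lapply(seq_len(max_depth), optimal_thresholds,
                        params = params))
}

#' Call somatic SNVs from a locus count table
#'
#' A locus is called somatic when it is not blacklisted, its depth has
#' feasible thresholds, and `c_E <= n_A <= c_H`. Loci deeper than
#' `max_depth` are truncated to `max_depth` (with `n_A` capped accordingly)
#' and a warning is issued, mirroring a depth-capped pileup.
#'
#' @param counts Data.frame with columns `n`, `n_A`, and optionally
#'   `triclass`, `blacklist`, `contig`, `pos`.
#' @param params A [somatic_params()].
#' @param blacklist Optional logical vector overriding `counts$blacklist`.
#' @param max_depth Depth cap (default 101).
#' @return A data.frame of calls (subset of `counts` rows) with an added
#'   `p_n` sensitivity column; the full per-locus sensitivity vector is
#'   attached as attribute `sensitivity`.
#' @export
call_somatic <- function(counts, params = somatic_params(),
                         blacklist = NULL, max_depth = 101L) {
  stopifnot(all(c("n", "n_A") %in% names(counts)))
  bl <- blacklist %||% counts$blacklist %||% rep(FALSE, nrow(counts))
  n <- counts$n
  n_A <- counts$n_A
  if (any(n > max_depth)) {
    warning(sum(n > max_depth), " loci exceed the depth cap ", max_depth,
            "; depths truncated")
    n_A <- pmin(n_A, ifelse(n > max_depth, max_depth, n_A))
    n <- pmin(n, max_depth)
  }
  tab <- threshold_table(params, max_depth)
  row <- match(n, tab$n)
  p_n <- ifelse(is.na(row), 0, tab$p_n[row])
  feas <- !is.na(row) & tab$feasible[row]
  called <- feas & !bl & n_A >= tab$c_E[row] & n_A <= tab$c_H[row]
  called[is.na(called)] <- FALSE
  out <- counts[called, , drop = FALSE]
  out$p_n <- p_n[called]
  attr(out, "sensitivity") <- p_n
  out
}

#' Sensitivity-normalised 96-class somatic burden
#'
#' For each of the 96 trinucleotide substitution classes, the burden entry
#' is the number of somatic calls of that class divided by the sum of the
#' per-locus detection sensitivities `p_n` over all loci of that class.
#' Classes with zero total sensitivity get `NA` (flagged missing).
#'
#' @param calls Output of [call_somatic()].
#' @param counts The full locus count table the calls came from; must have a
#'   `triclass` column.
#' @param params A [somatic_params()].
#' @param drop_prefactor If `TRUE`, divide sensitivities by `r_RR` so the
#'   denominator is the somatic detection probability conditional on the
#'   locus being reference-homozygous.
#' @param max_depth Depth cap used during calling.
#' @return Named numeric vector of length 96.
#' @export
normalized_burden <- function(calls, counts, params = somatic_params(),
                              drop_prefactor = FALSE, max_depth = 101L) {
  if (is.null(counts$triclass)) stop("class annotation absent", call. = FALSE)
  classes <- mutation_classes96()
  sens <- attr(calls, "sensitivity")
  if (is.null(sens)) {
    tab <- threshold_table(params, max_depth)
    row <- match(pmin(counts$n, max_depth), tab$n)
    sens <- ifelse(is.na(row), 0, tab$p_n[row])
  }
  if (drop_prefactor) sens <- sens / params$r_RR
  denom <- vapply(classes, function(k) sum(sens[counts$triclass == k]), 0)
  num <- vapply(classes, function(k) sum(calls$triclass == k), 0)
  out <- ifelse(denom > 0, num / denom, NA_real_)
  names(out) <- classes
  out
}

#' Driver filtering and the CHIP-by-SNV rule
#'
#' Applies the incidental somatic driver rules: retain non-synonymous
#' records with population allele frequency below 0.1%, VAF of at least
#' 10%, and at least 3 supporting reads; a retained record is a driver if
#' it has a HIGH consequence on the canonical transcript of a tumour
#' suppressor gene, or a somatic-catalogue recurrence count of at least
#' 100. The individual is flagged CHIP-by-SNV if at least one driver
#' remains.
#'
#' @param records Data.frame with columns `consequence` (character),
#'   `is_tsg`, `is_canonical` (logical), `pop_af`, `vaf` (fractions),
#'   `cosmic_count`, `alt_reads` (counts). Records missing any field are
#'   skipped with a warning.
#' @return A list with `drivers` (the driver rows) and `chip` (logical).
#' @export
chip_driver_calls <- function(records) {
  need <- c("consequence", "is_tsg", "is_canonical", "pop_af",
            "cosmic_count", "vaf", "alt_reads")
  missing_col <- setdiff(need, names(records))
  if (length(missing_col))
    stop("records lack columns: ", paste(missing_col, collapse = ", "),
         call. = FALSE)
  ok <- stats::complete.cases(records[, need])
  if (any(!ok))
    warning(sum(!ok), " record(s) with missing annotation skipped")
  r <- records[ok, , drop = FALSE]
  nonsyn <- c("missense_variant", "splice_donor_variant",
              "splice_acceptor_variant", "start_lost", "stop_gained",
              "frameshift_variant", "inframe_insertion",
              "inframe_deletion")
  high <- c("transcript_ablation", "splice_acceptor_variant",
            "splice_donor_variant", "stop_gained", "frameshift_variant",
            "stop_lost", "start_lost")
  keep <- r$consequence %in% nonsyn & r$pop_af < 0.001 & r$vaf >= 0.10 &
    r$alt_reads >= 3
  r <- r[keep, , drop = FALSE]
  driver <- (r$consequence %in% high & r$is_canonical & r$is_tsg) |
    r$cosmic_count >= 100
  list(drivers = r[driver, , drop = FALSE], chip = any(driver))
}
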