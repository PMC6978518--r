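# Subclonal copy-number inference from unphased het-locus allele depths.
# A single aneuploid subclone at cell fraction f on a diploid background
# gives chromatid mean ploidies p_j = f*k_j + (1-f); allele depths are
# modelled as a phase-symmetric mixture of negative binomials around
# c_i*p_1 and c_i*p_2, with c_i a GC-corrected half-depth normaliser.

#' Select loci with highly stable sequencing characteristics
#'
#' Retains loci passing all of: cohort variant allele fraction in
#' `[0.05, 0.95]`, GC fraction of the surrounding 100 bp in `[0.30, 0.55]`,
#' mean relative depth in `[0.9, 1.1]` in both cohorts, and relative-depth
#' variance in `[0.025, 0.033]` in the first cohort and `[0.025, 0.040]`
#' in the second. Loci with missing statistics are dropped (count
#' reported).
#'
#' @param stats Data.frame with columns `vaf`, `gc100`, `mean_rel_1`,
#'   `mean_rel_2`, `var_rel_1`, `var_rel_2`.
#' @return Logical vector of retained loci.
#' @export
select_stable_loci <- function(stats) {
  need <- c("vaf", "gc100", "mean_rel_1", "mean_rel_2", "var_rel_1",
            "var_rel_2")
  stopifnot(all(need %in% names(stats)))
  cc <- stats::complete.cases(stats[, need])
  if (any(!cc))
    message(sum(!cc), " loci dropped for missing statistics")
  keep <- cc &
    stats$vaf >= 0.05 & stats$vaf <= 0.95 &
    stats$gc100 >= 0.30 & stats$gc100 <= 0.55 &
    stats$mean_rel_1 >= 0.9 & stats$mean_rel_1 <= 1.1 &
    stats$mean_rel_2 >= 0.9 & stats$mean_rel_2 <= 1.1 &
    stats$var_rel_1 >= 0.025 & stats$var_rel_1 <= 0.033 &
    stats$var_rel_2 >= 0.025 & stats$var_rel_2 <= 0.040
  keep & !is.na(keep)
}

#' Fit the sample-specific GC bias model
#'
#' Regresses the log ratio of observed relative depth to the cohort
#' baseline `b_i` on penalised smooths of the principal-component scores of
#' the 5-window GC fraction matrix, and returns the per-locus half-depth
#' normaliser `c_i = b_i * exp(h(g_i)) * D/2` with `D` the mean total
#' depth.
#'
#' @param loci Data.frame with columns `d_R`, `d_A`, `b` and the GC windows
#'   `gc100`, `gc200`, `gc400`, `gc600`, `gc800`.
#' @param min_loci Minimum number of loci required (default 1000).
#' @param max_fit_loci Smooth terms are estimated on at most this many
#'   evenly spaced loci (default 10000) and evaluated at all loci; the
#'   smooth is low-dimensional, so subsampling does not change it
#'   materially.
#' @return An object of class `gc_model` with elements `h` (fitted log
#'   bias per locus), `c` (half-depth normaliser per locus), `gam`,
#'   `n_pcs`.
#' @export
fit_gc_model <- function(loci, min_loci = 1000L, max_fit_loci = 10000L) {
  gcols <- paste0("gc", c(100, 200, 400, 600, 800))
  stopifnot(all(c("d_R", "d_A", "b", gcols) %in% names(loci)))
  if (nrow(loci) < min_loci)
    stop("at least ", min_loci, " het loci are required", call. = FALSE)
  total <- loci$d_R + loci$d_A
  rel <- total / mean(total)
  y <- log(pmax(rel, 1e-6) / loci$b)
  G <- as.matrix(loci[, gcols])
  sds <- apply(G, 2, stats::sd)
  usable <- sds > 1e-10
  if (!any(usable)) {
    h <- rep(mean(y), length(y))
    gam_fit <- NULL
    n_pcs <- 0L
  } else {
    pca <- stats::prcomp(G[, usable, drop = FALSE], center = TRUE,
                         scale. = TRUE)
    n_pcs <- sum(pca$sdev > 1e-8)
    if (n_pcs < sum(usable))
      message("rank-deficient GC matrix: using ", n_pcs,
              " principal components")
    R <- as.data.frame(pca$x[, seq_len(n_pcs), drop = FALSE])
    names(R) <- paste0("r", seq_len(n_pcs))
    dat <- cbind(data.frame(y = y), R)
    form <- stats::as.formula(paste(
      "y ~", paste(sprintf("s(%s)", names(R)), collapse = " + ")))
    fit_rows <- if (nrow(dat) > max_fit_loci)
      round(seq(1, nrow(dat), length.out = max_fit_loci)) else
        seq_len(nrow(dat))
    gam_fit <- mgcv::gam(form, data = dat[fit_rows, , drop = FALSE])
    h <- as.numeric(stats::predict(gam_fit, newdata = dat))
  }
  structure(list(h = h, c = loci$b * exp(h) * mean(total) / 2,
                 gam = gam_fit, n_pcs = n_pcs),
            class = "gc_model")
}

#' @export
print.gc_model <- function(x, ...) {
  cat(sprintf("GC bias model: %d PCs, mean |h| = %.4f\n", x$n_pcs,
              mean(abs(x$h))))
  invisible(x)
}

# asymptotic two-sample KS p-value (rank-based; ties handled by the ECDF
# definition, no jitter)
ks_p2 <- function(x, y) {
  suppressWarnings(stats::ks.test(x, y, exact = FALSE)$p.value)
}

# phase-symmetric KS p between two segments: compare the unordered pairs
# (min, max) of the normalised depths by two 1-D KS tests, Bonferroni x2
segment_ks_p <- function(lo1, hi1, lo2, hi2) {
  p <- 2 * min(ks_p2(lo1, lo2), ks_p2(hi1, hi2))
  min(p, 1)
}

#' Segment the genome by greedy Kolmogorov-Smirnov agglomeration
#'
#' Starts from blocks of `block` consecutive heterozygous loci (a remainder
#' shorter than `block / 2` at a contig end is attached to the previous
#' block) and repeatedly merges the adjacent pair with the highest
#' phase-symmetric two-sample KS p-value genome-wide while any p-value is
#' at least `p_threshold`. Segments never merge across contigs; a contig
#' with fewer than `block` loci forms a single segment.
#'
#' @param loci Data.frame with columns `contig`, `pos`, `d_R`, `d_A`,
#'   sorted by contig then position.
#' @param c Per-locus half-depth normaliser (e.g. from [fit_gc_model()]).
#' @param block Initial block size in loci (default 100).
#' @param p_threshold Stop merging when all adjacent KS p-values fall below
#'   this (default 0.01).
#' @return Data.frame with columns `contig`, `start_idx`, `end_idx`
#'   (row indices into `loci`), `n_loci`.
#' @export
segment_genome <- function(loci, c, block = 100L, p_threshold = 0.01) {
  stopifnot(length(c) == nrow(loci))
  u <- loci$d_R / c
  v <- loci$d_A / c
  lo <- pmin(u, v); hi <- pmax(u, v)
  segs <- list()
  for (ct in unique(loci$contig)) {
    idx <- which(loci$contig == ct)
    n <- length(idx)
    if (n < block) {
      segs[[length(segs) + 1L]] <- c(idx[1], idx[n])
      next
    }
    n_blocks <- n %/% block
    bounds <- seq(0, n_blocks * block, by = block)
    rem <- n - n_blocks * block
    if (rem >= block / 2) bounds <- c(bounds, n) else bounds[length(bounds)] <- n
    for (b in seq_len(length(bounds) - 1))
      segs[[length(segs) + 1L]] <-
        c(idx[bounds[b] + 1], idx[bounds[b + 1]])
  }
  start <- vapply(segs, `[`, 0, 1)
  end <- vapply(segs, `[`, 0, 2)
  contig <- loci$contig[start]
  pair_p <- function(i) {
    if (contig[i] != contig[i + 1]) return(-Inf)  # never merge across contigs
    r1 <- start[i]:end[i]; r2 <- start[i + 1]:end[i + 1]
    segment_ks_p(lo[r1], hi[r1], lo[r2], hi[r2])
  }
  pvals <- if (length(start) > 1)
    vapply(seq_len(length(start) - 1), pair_p, 0) else numeric(0)
  while (length(pvals) && max(pvals) >= p_threshold) {
    i <- which.max(pvals)
    end[i] <- end[i + 1]
    start <- start[-(i + 1)]; end <- end[-(i + 1)]
    contig <- contig[-(i + 1)]
    pvals <- pvals[-i]
    if (i > 1) pvals[i - 1] <- pair_p(i - 1)
    if (i <= length(pvals)) pvals[i] <- pair_p(i)
  }
  data.frame(contig = contig, start_idx = start, end_idx = end,
             n_loci = end - start + 1, stringsAsFactors = FALSE)
}

#' Phase-mixture negative-binomial segment log-likelihood
#'
#' Sum over segment loci of
#' `log(0.5 * NB(d_R; c p1, s) NB(d_A; c p2, s) +
#'      0.5 * NB(d_R; c p2, s) NB(d_A; c p1, s))`
#' with `p_j = f * k_j + (1 - f)`. The negative binomial is parameterised
#' by mean and size, `q = s / (s + mu)`.
#'
#' @param d_R,d_A Reference/alternate depths over the segment's loci.
#' @param c Half-depth normaliser per locus.
#' @param k1,k2 Chromatid ploidies (unordered; the likelihood is invariant
#'   to swapping).
#' @param f Aneuploid cell fraction.
#' @param s Negative-binomial size.
#' @return Scalar log-likelihood.
#' @export
segment_loglik <- function(d_R, d_A, c, k1, k2, f, s) {
  p1 <- f * k1 + (1 - f)
  p2 <- f * k2 + (1 - f)
  l11 <- stats::dnbinom(d_R, mu = c * p1, size = s, log = TRUE) +
    stats::dnbinom(d_A, mu = c * p2, size = s, log = TRUE)
  if (k1 == k2) return(sum(l11))
  l12 <- stats::dnbinom(d_R, mu = c * p2, size = s, log = TRUE) +
    stats::dnbinom(d_A, mu = c * p1, size = s, log = TRUE)
  sum(logaddexp(l11, l12)) - length(d_R) * log(2)
}

# unordered ploidy pairs up to k_max, diploid-preferred order:
# (1,1) first, then by distance from diploid (deterministic tie-break)
ploidy_pairs <- function(k_max) {
  pairs <- expand.grid(k1 = 0:k_max, k2 = 0:k_max)
  pairs <- pairs[pairs$k1 <= pairs$k2, , drop = FALSE]
  d <- abs(pairs$k1 - 1) + abs(pairs$k2 - 1)
  pairs[order(d, pairs$k1 + pairs$k2, pairs$k1), , drop = FALSE]
}

# fast NB log-pmf for integer counts with a cached lgamma(x + s) table;
# matches dnbinom(x, mu = mu, size = s, log = TRUE)
nb_logpmf_tab <- function(x, mu, s, lgam) {
  ls <- log(s + mu)
  out <- lgam[x + 1L] + s * (log(s) - ls)
  pos <- x > 0L
  out[pos] <- out[pos] + x[pos] * (log(mu[pos]) - ls[pos])
  out[x > 0L & mu == 0] <- -Inf
  out
}

# segment x pair log-likelihood table at (f, s); shares the per-ploidy
# NB densities across pairs
seg_pair_loglik <- function(d_R, d_A, c, seg_of, n_seg, pairs, f, s) {
  ks <- sort(unique(c(pairs$k1, pairs$k2)))
  xmax <- max(d_R, d_A)
  lgam <- lgamma(0:xmax + s) - lgamma(s) - lgamma(seq_len(xmax + 1))
  LR <- sapply(ks, function(k)
    nb_logpmf_tab(d_R, c * (f * k + 1 - f), s, lgam))
  LA <- sapply(ks, function(k)
    nb_logpmf_tab(d_A, c * (f * k + 1 - f), s, lgam))
  out <- matrix(NA_real_, n_seg, nrow(pairs))
  for (p in seq_len(nrow(pairs))) {
    i <- match(pairs$k1[p], ks); j <- match(pairs$k2[p], ks)
    ll <- if (i == j) LR[, i] + LA[, i]
    else {
      # fast two-term log-sum-exp; means are positive so terms are finite
      la <- LR[, i] + LA[, j]; lb <- LR[, j] + LA[, i]
      m <- pmax(la, lb)
      m + log1p(exp(-abs(la - lb))) - log(2)
    }
    out[, p] <- rowsum(ll, seg_of, reorder = TRUE)
  }
  out
}

#' Fit the subclonal CNV model to a sample
#'
#' Maximises the phase-mixture negative-binomial likelihood over the
#' aneuploid cell fraction `f` (grid `0, 0.01, ..., f_max` with local
#' polish), the dispersion `s` (log-spaced grid with polish) and
#' per-segment chromatid ploidies `(k1, k2) <= k_max`, with the maximum
#' allowable ploidy `k_max` chosen in an outer loop by BIC (parameters
#' counted as `f`, `s`, plus 2 per pre-merge segment). A final polish
#' merges adjacent segments assigned identical ploidies. A fit in which
#' every segment is diploid has unidentifiable `f`, reported as 0 by
#' convention.
#'
#' @param loci Data.frame of het loci (see [gen_cnv_sample()] for the
#'   columns).
#' @param c Optional per-locus half-depth normaliser; computed via
#'   [fit_gc_model()] when `NULL`.
#' @param segments Optional pre-computed segmentation from
#'   [segment_genome()].
#' @param k_max_cap Largest maximum ploidy tried (default 4).
#' @param f_max Largest clone fraction considered (default 0.5: the model
#'   assumes a background diploid majority).
#' @param f_step Grid step for `f` (default 0.01).
#' @param recalibrate Refine the depth normaliser after the BIC-best
#'   assignment (default `TRUE`): the sample-mean normalisation is itself
#'   biased by any aneuploid segment, so one pass rescales `c` by the
#'   likelihood-weighted observed/expected depth ratio and re-polishes
#'   `f` and `s`.
#' @return An object of class `cnv_fit` with elements `f`, `s`,
#'   `segments` (with `k1`, `k2` per segment), `loglik`, `BIC`, `k_max`,
#'   `n_loci`, plus the BIC trace over `k_max` candidates.
#' @export
fit_cnv <- function(loci, c = NULL, segments = NULL, k_max_cap = 4L,
                    f_max = 0.5, f_step = 0.01, recalibrate = TRUE) {
  if (is.null(c)) c <- fit_gc_model(loci)$c
  if (is.null(segments)) segments <- segment_genome(loci, c)
  d_R <- loci$d_R; d_A <- loci$d_A
  n <- length(d_R)
  n_seg <- nrow(segments)
  seg_of <- integer(n)
  for (i in seq_len(n_seg)) {
    seg_of[segments$start_idx[i]:segments$end_idx[i]] <- i
  }
  stopifnot(all(seg_of > 0))
  if (recalibrate) {
    # mean-based depth normalisation is biased by the aneuploid segment
    # itself; the median observed/expected ratio over loci is robust to an
    # aneuploid minority and fixes the global scale before fitting
    c <- c * stats::median((d_R + d_A) / (2 * c))
  }
  # initial NB size: per-segment moment estimates (with a segment-level
  # mean correction), combined by the median so aneuploid segments do not
  # deflate the starting dispersion
  s_seg <- vapply(seq_len(n_seg), function(i) {
    r <- segments$start_idx[i]:segments$end_idx[i]
    xs <- c(d_R[r], d_A[r]); ms <- c(c[r], c[r])
    ms <- ms * mean(xs) / mean(ms)
    ex <- mean((xs - ms)^2 - ms)
    if (ex <= 0) 1000 else min(max(mean(ms^2) / ex, 1), 1000)
  }, 0)
  s0 <- stats::median(s_seg)
  f_grid <- seq(0, f_max, by = f_step)
  all_pairs <- ploidy_pairs(k_max_cap)
  profile_f <- function(f, s, pairs, cc) {
    tab <- seg_pair_loglik(d_R, d_A, cc, seg_of, n_seg, pairs, f, s)
    best <- max.col(tab, ties.method = "first")
    list(loglik = sum(tab[cbind(seq_len(n_seg), best)]), assign = best)
  }
  # optimise (f, s, assignment) for a fixed pair set and normaliser;
  # grid_ll (optional) gives the profile log-likelihood over f_grid at
  # s_init. When the polished dispersion moves far from its starting
  # value the f grid is re-scanned at the new dispersion, since the
  # location of the global basin in f can depend on s.
  f_coarse <- unique(c(seq(0, f_max, by = 5 * f_step), f_max))
  optimise_pairs <- function(pairs, cc, grid_ll = NULL, s_init = s0,
                             grid = f_grid) {
    # log-likelihood at (f, s) with the per-segment ploidies held fixed
    seg_ll_fixed <- function(assign, f, s) {
      k1 <- pairs$k1[assign][seg_of]
      k2 <- pairs$k2[assign][seg_of]
      p1v <- f * k1 + (1 - f)
      p2v <- f * k2 + (1 - f)
      xmax <- max(d_R, d_A)
      lgam <- lgamma(0:xmax + s) - lgamma(s) - lgamma(seq_len(xmax + 1))
      l11 <- nb_logpmf_tab(d_R, cc * p1v, s, lgam) +
        nb_logpmf_tab(d_A, cc * p2v, s, lgam)
      same <- k1 == k2
      l12 <- nb_logpmf_tab(d_R, cc * p2v, s, lgam) +
        nb_logpmf_tab(d_A, cc * p1v, s, lgam)
      mix <- logaddexp(l11, l12) - log(2)
      sum(ifelse(same, l11, mix))
    }
    s_cur <- s_init
    f_hat <- NA_real_
    assign <- NULL
    for (pass in 1:2) {
      if (is.null(grid_ll))
        grid_ll <- vapply(grid, function(f)
          profile_f(f, s_cur, pairs, cc)$loglik, 0)
      f0 <- grid[which.max(grid_ll)]
      step <- max(diff(grid)[1], f_step)
      assign <- profile_f(f0, s_cur, pairs, cc)$assign
      opt_f <- stats::optimize(function(f) seg_ll_fixed(assign, f, s_cur),
                               lower = max(0, f0 - step),
                               upper = min(f_max, f0 + step),
                               maximum = TRUE, tol = 1e-4)
      f_hat <- if (opt_f$objective > max(grid_ll)) opt_f$maximum else f0
      opt_s <- stats::optimize(function(ls)
        seg_ll_fixed(assign, f_hat, exp(ls)),
        lower = log(1), upper = log(1000), maximum = TRUE, tol = 1e-3)
      s_hat <- exp(opt_s$maximum)
      if (pass == 1 && abs(log(s_hat / s_cur)) > 0.1) {
        s_cur <- s_hat
        grid_ll <- NULL   # re-scan f (coarsely) at the updated dispersion
        grid <- f_coarse
        next
      }
      s_cur <- s_hat
      break
    }
    # reassign ploidies at the polished (f, s); if that changes the
    # assignment, re-polish f once
    final <- profile_f(f_hat, s_cur, pairs, cc)
    if (!identical(final$assign, assign)) {
      assign <- final$assign
      opt_f2 <- stats::optimize(function(f) seg_ll_fixed(assign, f, s_cur),
                                lower = max(0, f_hat - 2 * f_step),
                                upper = min(f_max, f_hat + 2 * f_step),
                                maximum = TRUE, tol = 1e-4)
      if (opt_f2$objective >= final$loglik) f_hat <- opt_f2$maximum
      final <- profile_f(f_hat, s_cur, pairs, cc)
    }
    list(f = f_hat, s = s_cur, assign = final$assign,
         loglik = final$loglik)
  }
  # shared f-grid tables over the full pair set at s0, reused per k_max
  tabs <- lapply(f_grid, function(f)
    seg_pair_loglik(d_R, d_A, c, seg_of, n_seg, all_pairs, f, s0))
  # BIC over k_max from the shared grid profiles (every k_max carries the
  # same parameter count, so the comparison reduces to the profile
  # log-likelihood; ties resolve to the smallest k_max). Only the winner
  # is polished.
  n_par <- 2 + 2 * n_seg
  grids <- lapply(seq_len(k_max_cap), function(k_max) {
    sel <- which(all_pairs$k2 <= k_max)
    vapply(tabs, function(tb) {
      sub <- tb[, sel, drop = FALSE]
      sum(sub[cbind(seq_len(n_seg),
                    max.col(sub, ties.method = "first"))])
    }, 0)
  })
  bics <- vapply(grids, function(g) -2 * max(g) + n_par * log(n), 0)
  bics <- round(bics, 6)
  k_best <- which.min(bics)
  pairs <- all_pairs[all_pairs$k2 <= k_best, , drop = FALSE]
  best <- optimise_pairs(pairs, c, grids[[k_best]])
  best$k_max <- k_best
  best$BIC <- -2 * best$loglik + n_par * log(n)
  if (recalibrate) {
    p1 <- best$f * pairs$k1[best$assign][seg_of] + (1 - best$f)
    p2 <- best$f * pairs$k2[best$assign][seg_of] + (1 - best$f)
    gamma <- sum(d_R + d_A) / sum(c * (p1 + p2))
    res <- optimise_pairs(pairs, c * gamma, s_init = best$s,
                          grid = f_coarse)
    if (res$loglik >= best$loglik - 1e-6) {
      best$f <- res$f; best$s <- res$s
      best$assign <- res$assign; best$loglik <- res$loglik
      best$BIC <- -2 * res$loglik + n_par * log(n)
      c <- c * gamma
    }
  }
  seg_out <- segments
  seg_out$k1 <- pairs$k1[best$assign]
  seg_out$k2 <- pairs$k2[best$assign]
  # final polish: merge adjacent segments with identical ploidies
  i <- 1
  while (i < nrow(seg_out)) {
    if (seg_out$contig[i] == seg_out$contig[i + 1] &&
        seg_out$k1[i] == seg_out$k1[i + 1] &&
        seg_out$k2[i] == seg_out$k2[i + 1]) {
      seg_out$end_idx[i] <- seg_out$end_idx[i + 1]
      seg_out$n_loci[i] <- seg_out$end_idx[i] - seg_out$start_idx[i] + 1
      seg_out <- seg_out[-(i + 1), , drop = FALSE]
    } else i <- i + 1
  }
  rownames(seg_out) <- NULL
  diploid <- all(seg_out$k1 == 1 & seg_out$k2 == 1)
  f_out <- if (diploid) 0 else best$f
  structure(list(f = f_out, s = best$s, segments = seg_out,
                 loglik = best$loglik, BIC = best$BIC,
                 k_max = best$k_max, n_loci = n,
                 bic_trace = stats::setNames(bics, seq_along(bics)),
                 c = c),
            class = "cnv_fit")
}

#' @export
print.cnv_fit <- function(x, ...) {
  aneu <- sum(x$segments$k1 != 1 | x$segments$k2 != 1)
  cat(sprintf(
    "Subclonal CNV fit: f = %.3f, s = %.1f, k_max = %d (BIC %.1f)\n",
    x$f, x$s, x$k_max, x$BIC))
  cat(sprintf("  %d segment(s) over %d het loci; %d aneuploid\n",
              nrow(x$segments), x$n_loci, aneu))
  invisible(x)
}

#' @export
summary.cnv_fit <- function(object, ...) {
  print(object)
  print(object$segments)
  invisible(object)
}

#' @export
coef.cnv_fit <- function(object, ...) c(f = object$f, s = object$s)

#' @export
plot.cnv_fit <- function(x, ...) {
  seg <- x$segments
  graphics::plot(NULL, xlim = c(1, x$n_loci),
                 ylim = c(-0.2, max(seg$k2) + 0.2),
                 xlab = "het locus index", ylab = "chromatid ploidy",
                 main = sprintf("subclonal CNV fit (f = %.2f)", x$f), ...)
  for (i in seq_len(nrow(seg))) {
    graphics::segments(seg$start_idx[i], seg$k1[i], seg$end_idx[i],
                       seg$k1[i], col = "steelblue", lwd = 3)
    graphics::segments(seg$start_idx[i], seg$k2[i], seg$end_idx[i],
                       seg$k2[i], col = "firebrick", lwd = 3, lty = 2)
  }
  invisible(x)
}

#' CHIP flag from a subclonal CNV fit
#'
#' `TRUE` when the fit contains at least one non-diploid segment and the
#' aneuploid clone comprises at least `min_fraction` of cells.
#'
#' @param fit A [fit_cnv()] result.
#' @param min_fraction Minimum clone fraction (default 0.10).
#' @return Logical.
#' @export
cnv_chip_flag <- function(fit, min_fraction = 0.10) {
  any(fit$segments$k1 != 1 | fit$segments$k2 != 1) && fit$f >= min_fraction
}
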