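# Independent oracles used across the suite. These deliberately avoid the
# code paths of the implementation: tails are direct term-by-term
# summations in log space, threshold search is a plain double loop, and
# morphology is rasterised on logical vectors.

# upper binomial tail P(X >= k) by direct summation of log terms
oracle_binom_upper <- function(k, n, p) {
  if (k <= 0) return(1)
  i <- k:n
  lt <- lchoose(n, i) + i * log(p) + (n - i) * log1p(-p)
  m <- max(lt)
  exp(m) * sum(exp(lt - m))
}

# lower binomial tail P(X <= k) by direct summation
oracle_binom_lower <- function(k, n, p) {
  i <- 0:k
  lt <- lchoose(n, i) + i * log(p) + (n - i) * log1p(-p)
  m <- max(lt)
  exp(m) * sum(exp(lt - m))
}

# exhaustive search for the optimal somatic thresholds at one depth,
# mirroring the published objective and constraint definitions with
# independently built tails. For each c_E the c_H axis is vectorised; the
# cross-c_E comparison keeps the smallest c_E on ties and, within a c_E,
# the largest c_H.
oracle_thresholds <- function(n, g_r = 5, f = 0.2, eps = 2e-3,
                              r_H = 1e-4, r_C = 5e-7) {
  r_RR <- 0.5 * (1 - r_H + sqrt(1 - 2 * r_H))
  p_A <- (1 - 4 * eps / 3) * f + eps
  lp <- lchoose(n, 0:n) + (0:n) * log(p_A) + (n - (0:n)) * log1p(-p_A)
  pmf <- exp(lp)
  cum <- cumsum(pmf)
  aE <- vapply(0:n, oracle_binom_upper, 0, n = n, p = eps)
  aH <- vapply(0:n, oracle_binom_lower, 0, n = n, p = 0.5 + eps / 3)
  best <- list(p_n = -1, c_E = NA_integer_, c_H = NA_integer_,
               feasible = FALSE)
  for (cE in 0:n) {
    cH <- cE:n
    p_n <- r_RR * (cum[cH + 1] - if (cE == 0) 0 else cum[cE])
    ratio <- (r_C / (1 - r_C)) * p_n /
      (r_RR * aE[cE + 1] + r_H * aH[cH + 1])
    ok <- ratio >= g_r
    if (!any(ok)) next
    pmax_ok <- max(p_n[ok])
    cH_best <- max(cH[ok & p_n == pmax_ok])  # largest c_H within ties
    if (pmax_ok > best$p_n)                  # strict: smallest c_E wins ties
      best <- list(p_n = pmax_ok, c_E = cE, c_H = cH_best,
                   feasible = TRUE)
  }
  if (!best$feasible) best$p_n <- 0
  best
}

# rasterised morphology on a logical vector over positions 1..len
oracle_dilate <- function(mask, w) {
  r <- (w - 1) / 2
  out <- logical(length(mask))
  for (i in which(mask)) {
    lo <- max(1, i - r); hi <- min(length(mask), i + r)
    out[lo:hi] <- TRUE
  }
  out
}

oracle_erode <- function(mask, w, pad = (w - 1) / 2) {
  # treat positions outside the vector as background
  padded <- c(rep(FALSE, pad), mask, rep(FALSE, pad))
  out <- logical(length(mask))
  for (i in seq_along(mask)) {
    idx <- (i):(i + 2 * pad)
    out[i] <- all(padded[idx])
  }
  out
}

oracle_close_open <- function(mask, close_w, open_w) {
  # embed with background padding so dilation is never clamped at the
  # vector edges (morphology on the integer line)
  pad <- close_w + open_w
  work <- c(rep(FALSE, pad), mask, rep(FALSE, pad))
  closed <- oracle_erode(oracle_dilate(work, close_w), close_w)
  opened <- oracle_dilate(oracle_erode(closed, open_w), open_w)
  opened[pad + seq_along(mask)]
}

gr_to_mask <- function(gr, len) {
  mask <- logical(len)
  st <- GenomicRanges::start(gr); en <- GenomicRanges::end(gr)
  for (i in seq_along(gr)) {
    lo <- max(1, st[i]); hi <- min(len, en[i])
    if (lo <= hi) mask[lo:hi] <- TRUE
  }
  mask
}

mask_to_gr <- function(mask, contig = "1") {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  GenomicRanges::GRanges(contig,
                         IRanges::IRanges(starts[r$values], ends[r$values]))
}

# Holm adjustment straight from the definition
oracle_holm <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  running <- 0
  for (i in seq_len(m)) {
    running <- max(running, (m - i + 1) * p[ord[i]])
    adj[ord[i]] <- min(1, running)
  }
  adj
}

# driver-rule fixture builder
driver_record <- function(consequence = "missense_variant", is_tsg = FALSE,
                          is_canonical = TRUE, pop_af = 0, cosmic_count = 0,
                          vaf = 0.2, alt_reads = 10) {
  data.frame(consequence = consequence, is_tsg = is_tsg,
             is_canonical = is_canonical, pop_af = pop_af,
             cosmic_count = cosmic_count, vaf = vaf,
             alt_reads = alt_reads, stringsAsFactors = FALSE)
}
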