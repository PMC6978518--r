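# Genome accessibility tiering: per-sample depth bounds, cohort-level
# unusual-coverage regions with morphological smoothing, and tier assignment.
# Intervals are handled as GRanges; coordinates are 1-based inclusive
# internally, and converted from/to 0-based half-open BED on disk.

#' Per-sample depth bounds from a coverage histogram
#'
#' The expected-coverage bounds for a sample are the 0.001 and 0.999
#' quantiles of a Poisson distribution whose rate is the modal nonzero
#' autosomal coverage, with the lower bound floored at 15 reads (the depth
#' typically required for reliable genotyping). Ties in the modal depth are
#' broken toward the smaller depth.
#'
#' @param depth_histogram Named numeric vector of locus counts by depth
#'   (names are depths), or an unnamed vector counting depths `0, 1, 2, ...`.
#' @return A list of class `depth_bounds` with `modal_coverage`, `lower`
#'   and `upper`.
#' @export
#' @examples
#' h <- c(`0` = 10, `37` = 50, `38` = 80, `39` = 60)
#' sample_depth_bounds(h)
sample_depth_bounds <- function(depth_histogram) {
  depths <- if (!is.null(names(depth_histogram)))
    as.numeric(names(depth_histogram)) else seq_along(depth_histogram) - 1
  counts <- as.numeric(depth_histogram)
  nz <- depths > 0 & counts > 0
  if (!any(nz)) stop("no coverage: histogram has no nonzero-depth entries",
                     call. = FALSE)
  d <- depths[nz]; ct <- counts[nz]
  lambda <- min(d[ct == max(ct)])  # tie-break toward smaller depth
  lower <- max(15, qpois_left(0.001, lambda))
  upper <- qpois_left(0.999, lambda)
  structure(list(modal_coverage = lambda, lower = lower, upper = upper),
            class = "depth_bounds")
}

# left Poisson quantile: smallest k with CDF(k) >= p
qpois_left <- function(p, lambda) {
  k <- 0
  while (stats::ppois(k, lambda) < p) k <- k + 1
  k
}

#' @export
print.depth_bounds <- function(x, ...) {
  cat("Depth bounds: modal coverage", x$modal_coverage,
      "-> [", x$lower, ",", x$upper, "]\n")
  invisible(x)
}

intervals_to_gr <- function(df) {
  GenomicRanges::GRanges(df$contig,
                         IRanges::IRanges(df$start, df$end))
}

gr_normalise <- function(gr) GenomicRanges::reduce(GenomicRanges::sort(gr))

# Morphological dilation/erosion with a centred structuring element of odd
# width, exact on intervals (no rasterisation). Erosion of an interval of
# width < element width removes it.
interval_dilate <- function(gr, width) {
  stopifnot(width %% 2 == 1)
  r <- (width - 1) / 2
  if (length(gr) == 0 || r == 0) return(gr_normalise(gr))
  gr_normalise(GenomicRanges::resize(gr, GenomicRanges::width(gr) + 2 * r,
                                     fix = "center"))
}

interval_erode <- function(gr, width) {
  stopifnot(width %% 2 == 1)
  r <- (width - 1) / 2
  gr <- gr_normalise(gr)
  if (length(gr) == 0 || r == 0) return(gr)
  keep <- GenomicRanges::width(gr) >= width
  gr <- gr[keep]
  if (length(gr) == 0) return(gr)
  GenomicRanges::resize(gr, GenomicRanges::width(gr) - 2 * r, fix = "center")
}

#' Morphological closing then opening of an interval set
#'
#' Closing (dilate then erode) with a centred element of width
#' `close_width` fills gaps shorter than the element; opening (erode then
#' dilate) with width `open_width` removes runs shorter than the element.
#'
#' @param gr A `GRanges` of marked intervals.
#' @param close_width,open_width Odd structuring-element widths in bp
#'   (defaults 131 and 11).
#' @return A normalised `GRanges`.
#' @export
smooth_intervals <- function(gr, close_width = 131L, open_width = 11L) {
  closed <- interval_erode(interval_dilate(gr, close_width), close_width)
  interval_dilate(interval_erode(closed, open_width), open_width)
}

#' Cohort-level regions of unusual coverage
#'
#' Marks loci whose out-of-bound rate across samples strictly exceeds
#' `rate_threshold`, then applies morphological closing (width 131) and
#' opening (width 11) to the marked set.
#'
#' @param out_of_bound_masks A list of logical vectors (one per sample, all
#'   the same length) or a logical matrix with one column per sample;
#'   `TRUE` marks an out-of-bound locus. Positions are 1-based along a
#'   single contig.
#' @param contig Contig name for the returned intervals.
#' @param rate_threshold Out-of-bound rate above which a locus is marked.
#' @param close_width,open_width Structuring-element widths.
#' @return A `GRanges` of unusual-coverage intervals.
#' @export
cohort_unusual_regions <- function(out_of_bound_masks, contig = "1",
                                   rate_threshold = 0.05,
                                   close_width = 131L, open_width = 11L) {
  m <- if (is.list(out_of_bound_masks)) {
    len <- unique(lengths(out_of_bound_masks))
    if (length(len) != 1)
      stop("all masks must have the same length", call. = FALSE)
    do.call(cbind, out_of_bound_masks)
  } else as.matrix(out_of_bound_masks)
  if (ncol(m) == 0 || nrow(m) == 0) stop("empty cohort", call. = FALSE)
  rate <- rowMeans(m)
  marked <- rate > rate_threshold     # strictly exceeds
  gr <- logical_to_gr(marked, contig)
  smooth_intervals(gr, close_width, open_width)
}

logical_to_gr <- function(mask, contig = "1") {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values
  if (!any(keep)) return(GenomicRanges::GRanges())
  GenomicRanges::GRanges(contig, IRanges::IRanges(starts[keep], ends[keep]))
}

#' Assign locus confidence tiers
#'
#' Tier 3 comprises non-canonical contigs, the pseudoautosomal regions, and
#' all loci within `pad` bp of the union of the five poor-quality interval
#' sets (unusual coverage, repeats, low complexity, ENCODE excludable,
#' ENCODE non-unique). Remaining canonical loci are tier 1 if inside the
#' high-confidence genotyping regions, else tier 2.
#'
#' @param unusual,repeat_mask,low_complexity,encode_excludable,
#'   encode_nonunique `GRanges` of poor-quality regions (any may be empty).
#' @param giab_high_conf `GRanges` of high-confidence genotyping regions.
#' @param pseudoautosomal `GRanges` of pseudoautosomal regions; the default
#'   is the GRCh37 pair on X and Y.
#' @param canonical_contigs Character vector of canonical contig names.
#' @param contig_lengths Named integer vector of contig lengths covering at
#'   least the canonical contigs.
#' @param pad Padding in bp around poor-quality intervals (default 5).
#' @return A `GRanges` tiling the canonical contigs, with metadata column
#'   `tier` in `{1, 2, 3}`.
#' @export
assign_tiers <- function(unusual, repeat_mask, low_complexity,
                         encode_excludable, encode_nonunique,
                         giab_high_conf,
                         pseudoautosomal = par_regions_grch37(),
                         canonical_contigs = c(as.character(1:22), "X", "Y"),
                         contig_lengths, pad = 5L) {
  # the default pseudoautosomal regions cover X and Y; restrict them to
  # the contigs this genome actually has
  par_ct <- as.character(GenomicRanges::seqnames(pseudoautosomal))
  pseudoautosomal <- pseudoautosomal[par_ct %in% names(contig_lengths)]
  sets <- list(unusual = unusual, repeat_mask = repeat_mask,
               low_complexity = low_complexity,
               encode_excludable = encode_excludable,
               encode_nonunique = encode_nonunique,
               giab_high_conf = giab_high_conf,
               pseudoautosomal = pseudoautosomal)
  known <- names(contig_lengths)
  for (nm in names(sets)) {
    ct <- as.character(GenomicRanges::seqnames(sets[[nm]]))
    if (length(ct) && !all(ct %in% known))
      stop(sprintf("interval set '%s' uses unknown contig(s): %s", nm,
                   paste(setdiff(ct, known), collapse = ", ")),
           call. = FALSE)
  }
  genome <- GenomicRanges::GRanges(
    canonical_contigs,
    IRanges::IRanges(1, contig_lengths[canonical_contigs]))
  poor <- gr_normalise(c(unusual, repeat_mask, low_complexity,
                         encode_excludable, encode_nonunique))
  poor <- interval_dilate(poor, 2L * as.integer(pad) + 1L)
  tier3 <- gr_normalise(c(poor, pseudoautosomal))
  tier3 <- GenomicRanges::intersect(strip_gr(tier3), genome)
  rest <- GenomicRanges::setdiff(genome, tier3)
  tier1 <- GenomicRanges::intersect(rest, strip_gr(giab_high_conf))
  tier2 <- GenomicRanges::setdiff(rest, tier1)
  add_tier <- function(gr, t) {
    if (length(gr)) S4Vectors::mcols(gr)$tier <- t
    gr
  }
  out <- c(add_tier(tier3, 3L), add_tier(tier1, 1L), add_tier(tier2, 2L))
  GenomicRanges::sort(out)
}

# drop seqinfo/mcols so set operations do not complain about levels
strip_gr <- function(gr)
  GenomicRanges::GRanges(as.character(GenomicRanges::seqnames(gr)),
                         IRanges::ranges(gr))

#' GRCh37 pseudoautosomal regions
#'
#' @return A `GRanges` with the two pseudoautosomal regions on X and Y
#'   (1-based inclusive).
#' @export
par_regions_grch37 <- function() {
  GenomicRanges::GRanges(
    c("X", "X", "Y", "Y"),
    IRanges::IRanges(c(60001, 154931044, 10001, 59034050),
                     c(2699520, 155260560, 2649520, 59363566)))
}

#' Read / write BED interval sets
#'
#' Thin wrappers over [rtracklayer::import()] / [rtracklayer::export()];
#' BED is 0-based half-open on disk and the returned `GRanges` is 1-based
#' inclusive.
#'
#' @param path File path.
#' @param gr A `GRanges` to write.
#' @return `read_bed` returns a `GRanges`; `write_bed` returns `path`
#'   invisibly.
#' @export
read_bed <- function(path) rtracklayer::import(path, format = "BED")

#' @rdname read_bed
#' @export
write_bed <- function(gr, path) {
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}
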