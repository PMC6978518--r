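# Mitochondrial and Y copy number from contig read counts, and the
# mitochondrial low-frequency variant burden with its Phred-like q score.

#' Copy number per nucleus from contig read counts
#'
#' Estimates copies per nucleus of a target contig set (mitochondrial
#' genome or Y chromosome) as `2 * (R_num / S_num) / (R_A / S_A)`, i.e.
#' twice the ratio of per-bp read rates between the target and the
#' autosomes. Read counts are used as reported (no duplicate correction).
#'
#' @param R_num,S_num Mapped reads and total size (bp) of the target
#'   contig set.
#' @param R_A,S_A Mapped reads and total size of the autosomal contigs.
#' @return Copies per nucleus.
#' @export
#' @examples
#' copy_number(1000, 16569, 2e6, 2.88e9 / 16569 * 16569)
copy_number <- function(R_num, S_num, R_A, S_A) {
  if (any(R_A == 0)) stop("autosomal read count is zero", call. = FALSE)
  stopifnot(all(S_num > 0), all(S_A > 0), all(R_num >= 0))
  2 * (R_num / S_num) / (R_A / S_A)
}

#' Copy numbers from a contig read summary table
#'
#' @param idxstats Data.frame with columns `contig`, `length`, `mapped`
#'   (the samtools idxstats text layout), with rows for the autosomal,
#'   mitochondrial and (optionally) Y contig sets.
#' @param mt,y,autosomes Contig names (or name vectors) of each set.
#' @return Named numeric vector with `mt_copies` and (if Y present)
#'   `y_copies`.
#' @export
contig_copy_numbers <- function(idxstats, mt = "MT", y = "Y",
                                autosomes = setdiff(idxstats$contig,
                                                    c(mt, y, "X", "*"))) {
  pick <- function(ct) {
    rows <- idxstats$contig %in% ct
    list(R = sum(idxstats$mapped[rows]), S = sum(idxstats$length[rows]))
  }
  a <- pick(autosomes); m <- pick(mt)
  out <- c(mt_copies = copy_number(m$R, m$S, a$R, a$S))
  if (any(idxstats$contig %in% y)) {
    yy <- pick(y)
    out <- c(out, y_copies = copy_number(yy$R, yy$S, a$R, a$S))
  }
  out
}

#' Phred-like mitochondrial variant quality score
#'
#' `q = -10 log10(P(X > n_alt))` for `X ~ Binomial(N, p)` with a fixed,
#' deliberately conservative error-rate estimate `p = 0.0025`. The upper
#' tail is evaluated in log space; when it underflows double precision the
#' score is capped at `cap` (documented sentinel 990). A configuration
#' switch `inclusive = TRUE` uses `P(X >= n_alt)` instead.
#'
#' @param n_alt Alternate read count(s).
#' @param N Total depth(s).
#' @param p Error-rate estimate (default 0.0025).
#' @param cap Maximum reportable score (default 990).
#' @param inclusive Use the inclusive tail `P(X >= n_alt)`.
#' @return Numeric q score(s), `>= 0`.
#' @export
mito_q <- function(n_alt, N, p = 0.0025, cap = 990, inclusive = FALSE) {
  stopifnot(all(n_alt >= 0), all(n_alt <= N))
  k <- if (inclusive) n_alt - 1 else n_alt
  logtail <- stats::pbinom(k, N, p, lower.tail = FALSE, log.p = TRUE)
  q <- -10 * logtail / log(10)
  pmin(pmax(q, 0), cap)
}

#' Mitochondrial low-frequency variant burden
#'
#' Applies, in order: alternate reads `>= 10`; alternate allele fraction
#' `>= 0.001`; `q >= 30`; discard high-depth variants (`n_alt > 15`) with
#' strand bias `> 0.9`; discard positions in the hypervariable windows
#' MT:302-319 and MT:3105-3109. The burden is the number of surviving
#' variants with allele fraction below 0.01.
#'
#' @param variants Data.frame with columns `pos`, `n_alt`, `N`, and
#'   `strand_bias` (fraction of alternate reads on the majority strand);
#'   `aaf` is recomputed as `n_alt / N` if absent.
#' @param p Error rate for the q score.
#' @param q_min Minimum q (default 30).
#' @return A list of class `mito_burden` with `burden` (count), `passing`
#'   (the surviving low-frequency rows) and `filtered` (all survivors of
#'   the quality filters).
#' @export
mito_burden <- function(variants, p = 0.0025, q_min = 30) {
  v <- variants
  if (is.null(v$aaf)) v$aaf <- v$n_alt / v$N
  v <- v[v$n_alt >= 10, , drop = FALSE]
  v <- v[v$aaf >= 0.001, , drop = FALSE]
  if (nrow(v)) {
    v$q <- mito_q(v$n_alt, v$N, p = p)
    v <- v[v$q >= q_min, , drop = FALSE]
  }
  v <- v[!(v$n_alt > 15 & v$strand_bias > 0.9), , drop = FALSE]
  v <- v[!(v$pos >= 302 & v$pos <= 319) &
           !(v$pos >= 3105 & v$pos <= 3109), , drop = FALSE]
  low <- v[v$aaf < 0.01, , drop = FALSE]
  structure(list(burden = nrow(low), passing = low, filtered = v),
            class = "mito_burden")
}

#' @export
print.mito_burden <- function(x, ...) {
  cat(sprintf(
    "Mitochondrial variant burden: %d low-frequency variant(s) (%d passed filters)\n",
    x$burden, nrow(x$filtered)))
  invisible(x)
}

#' Read a samtools idxstats text file
#'
#' @param path Path to the 4-column idxstats output (contig, length,
#'   mapped, unmapped).
#' @param exclude_patterns Regular expressions of contigs to drop
#'   (defaults drop unplaced and patch contigs and the unmapped row).
#' @return Data.frame with columns `contig`, `length`, `mapped`.
#' @export
read_idxstats <- function(path,
                          exclude_patterns = c("^\\*$", "_patch$", "^GL",
                                               "^KI", "^NC_")) {
  tab <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                           col.names = c("contig", "length", "mapped",
                                         "unmapped"))
  drop <- Reduce(`|`, lapply(exclude_patterns, grepl, x = tab$contig))
  tab[!drop, c("contig", "length", "mapped")]
}
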