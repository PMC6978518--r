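#' @keywords internal
"_PACKAGE"

# pairwise log-sum-exp of two vectors
logaddexp <- function(la, lb) {
  m <- pmax(la, lb)
  out <- m + log1p(exp(pmin(la, lb) - m))
  # when both are -Inf the max trick yields NaN; the sum is -Inf
  out[is.infinite(la) & is.infinite(lb) & la < 0 & lb < 0] <- -Inf
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_prob <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stop(sprintf("'%s' must be a probability in [0, 1]", name), call. = FALSE)
  invisible(x)
}

#' The 96 single-base substitution classes
#'
#' Trinucleotide substitution classes in the pyrimidine-reference convention:
#' six substitutions (C>A, C>G, C>T, T>A, T>C, T>G) crossed with the 16
#' combinations of 5' and 3' flanking bases, written as e.g. `"A[C>T]G"`.
#' Ordering follows the conventional signature-catalogue layout
#' (substitution-major, then 5' base, then 3' base).
#'
#' @return Character vector of length 96.
#' @export
#' @examples
#' head(mutation_classes96())
mutation_classes96 <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  out <- character(0)
  for (s in subs)
    for (b5 in bases)
      for (b3 in bases)
        out <- c(out, paste0(b5, "[", s, "]", b3))
  out
}
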