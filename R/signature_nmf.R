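# Spectral denoising of 96-class burden matrices: non-negative matrix
# factorisation by multiplicative updates with multi-restart, an explained
# variance based cardinality selection over age-merged sample groups, and
# cosine-similarity matching to reference signature catalogues.

# One multiplicative-update (Lee-Seung, Frobenius) run from a random start.
nmf_run <- function(M, k, maxit = 500L, tol = 1e-7) {
  eps <- 1e-12
  nr <- nrow(M); nc <- ncol(M)
  W <- matrix(stats::runif(nr * k, 0, max(M) + eps), nr, k)
  H <- matrix(stats::runif(k * nc), k, nc)
  err_prev <- Inf
  converged <- FALSE
  for (it in seq_len(maxit)) {
    H <- H * (crossprod(W, M) / (crossprod(W) %*% H + eps))
    W <- W * (M %*% t(H)) / (W %*% tcrossprod(H) + eps)
    if (it %% 10 == 0 || it == maxit) {
      err <- sum((M - W %*% H)^2)
      if (is.finite(err_prev) &&
          err_prev - err <= tol * max(err_prev, eps)) {
        converged <- TRUE
        break
      }
      err_prev <- err
    }
  }
  list(W = W, H = H, error = sum((M - W %*% H)^2), converged = converged)
}

#' Fit a non-negative signature model
#'
#' Factorises a non-negative burden matrix `M` (96 classes x samples) as
#' `M ~ W H` by multiplicative updates minimising Frobenius error, keeping
#' the best of `restarts` random starts. Columns of `W` (signature
#' profiles) are normalised to sum to 1, with the scale absorbed into the
#' per-sample scores `H`.
#'
#' @param M Non-negative numeric matrix (classes x samples). Missing
#'   entries are imputed as 0 with a warning (conservative for burden).
#' @param k Factorisation cardinality (number of signatures).
#' @param restarts Number of random starts (default 100).
#' @param seed Integer seed.
#' @param maxit Iteration cap per run; non-convergent runs return the best
#'   iterate, flagged in `converged`.
#' @return An object of class `signature_model` with elements `W`, `H`,
#'   `k`, `error`, `explained_variance`, `best_restart`, `converged`.
#' @export
#' @examples
#' M <- matrix(rpois(96 * 8, 5), 96, 8)
#' fit <- fit_signatures(M, k = 2, restarts = 5, seed = 1)
#' fit
fit_signatures <- function(M, k, restarts = 100L, seed = 1L,
                           maxit = 500L) {
  stopifnot(k >= 1)
  M <- as.matrix(M)
  if (anyNA(M)) {
    warning(sum(is.na(M)), " missing burden entries imputed as 0")
    M[is.na(M)] <- 0
  }
  if (any(M < 0)) stop("burden matrix must be non-negative", call. = FALSE)
  with_seed(seed, {
    best <- NULL
    best_i <- NA_integer_
    for (i in seq_len(restarts)) {
      run <- nmf_run(M, k, maxit = maxit)
      if (is.null(best) || run$error < best$error) {
        best <- run
        best_i <- i
      }
    }
    scale <- colSums(best$W)
    scale[scale == 0] <- 1
    W <- sweep(best$W, 2, scale, "/")
    H <- best$H * scale
    structure(list(W = W, H = H, k = k, error = best$error,
                   explained_variance = explained_variance(M, W %*% H),
                   best_restart = best_i, converged = best$converged),
              class = "signature_model")
  })
}

#' @export
print.signature_model <- function(x, ...) {
  cat(sprintf(
    "Signature model: k = %d, %d samples, reconstruction error %.4g\n",
    x$k, ncol(x$H), x$error))
  cat(sprintf("  explained variance %.4f (best of restarts: #%d%s)\n",
              x$explained_variance, x$best_restart,
              if (x$converged) "" else ", iteration cap hit"))
  invisible(x)
}

#' Explained variance of a factorisation
#'
#' Defined as `1 - ||M - WH||_F^2 / ||M - mean(M)||_F^2` (mean-centred
#' denominator); set `centred = FALSE` for a raw `||M||_F^2` denominator.
#' A constant matrix has zero centred denominator and returns 1.
#'
#' @param M Data matrix.
#' @param WH Reconstruction.
#' @param centred Use the mean-centred denominator (default).
#' @return Scalar explained variance.
#' @export
explained_variance <- function(M, WH, centred = TRUE) {
  denom <- if (centred) sum((M - mean(M))^2) else sum(M^2)
  if (denom == 0) return(1)
  1 - sum((M - WH)^2) / denom
}

#' Select the factorisation cardinality
#'
#' Samples are sorted by age and merged into consecutive groups of 16 by
#' summing burden per class (a remainder group smaller than 16 is merged
#' into the last group). The reduced matrix is factorised at each
#' cardinality in `2..kmax` (with `k = 1` fitted to anchor the curve),
#' and the selected cardinality is the inflection of the
#' explained-variance curve: the smallest `k` at which the curve has
#' flattened, operationalised as the next marginal gain collapsing to
#' less than `gain_ratio` (default 0.2, a fivefold drop) of the gain
#' that reached `k`, or the curve being already flat at `k`. If no
#' cardinality satisfies the rule the `k` maximising the second
#' difference of explained variance is returned. `k_override` bypasses
#' the rule entirely.
#'
#' @param M Burden matrix (96 x samples).
#' @param ages Numeric vector of sample ages (length `ncol(M)`).
#' @param kmax Largest cardinality scanned (default 10).
#' @param restarts Random starts per cardinality (default 100).
#' @param seed Integer seed.
#' @param group_size Samples per merged group (default 16).
#' @param gain_ratio Relative marginal-gain collapse defining the elbow.
#' @param k_override Optional manual cardinality (returned as given).
#' @return A list of class `cardinality_scan` with `k` (selected), `ev`
#'   (explained variance by cardinality) and `grouped` (the reduced
#'   matrix).
#' @export
select_cardinality <- function(M, ages, kmax = 10L, restarts = 100L,
                               seed = 1L, group_size = 16L,
                               gain_ratio = 0.2, k_override = NULL) {
  M <- as.matrix(M)
  if (ncol(M) < 2 * group_size)
    stop("at least ", 2 * group_size, " samples with ages are required",
         call. = FALSE)
  stopifnot(length(ages) == ncol(M))
  ord <- order(ages)
  Ms <- M[, ord, drop = FALSE]
  n_groups <- ncol(Ms) %/% group_size
  grp <- pmin(ceiling(seq_len(ncol(Ms)) / group_size), n_groups)
  G <- sapply(seq_len(n_groups), function(g)
    rowSums(Ms[, grp == g, drop = FALSE]))
  ks <- seq_len(max(kmax, 3))
  ev <- vapply(ks, function(k) {
    fit <- fit_signatures(G, k, restarts = restarts, seed = seed + k,
                          maxit = 300L)
    fit$explained_variance
  }, 0)
  if (!is.null(k_override)) {
    return(structure(list(k = as.integer(k_override),
                          ev = stats::setNames(ev, ks), grouped = G),
                     class = "cardinality_scan"))
  }
  gains <- diff(ev)            # gains[k] = ev(k+1) - ev(k)
  cand <- 2:(length(ks) - 1)
  k_sel <- NA_integer_
  for (k in cand) {
    flat <- gains[k - 1] < 1e-6                 # curve already flat at k
    collapsed <- !flat && gains[k] < gain_ratio * gains[k - 1]
    if (flat || collapsed) {
      k_sel <- k
      break
    }
  }
  if (is.na(k_sel)) {
    curv <- (ev[cand] - ev[cand - 1]) - (ev[cand + 1] - ev[cand])
    k_sel <- cand[which.max(round(curv, 12))]
  }
  structure(list(k = k_sel, ev = stats::setNames(ev, ks), grouped = G),
            class = "cardinality_scan")
}

#' @export
print.cardinality_scan <- function(x, ...) {
  cat("Cardinality scan: selected k =", x$k, "\n")
  print(round(x$ev, 4))
  invisible(x)
}

#' Cosine similarity between signature profiles
#'
#' @param a,b Non-negative, non-zero numeric vectors of equal length.
#' @return Cosine similarity in `[0, 1]` for non-negative inputs.
#' @export
cosine_similarity <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("zero vector", call. = FALSE)
  sum(a * b) / (na * nb)
}

#' Match fitted signatures to reference profiles
#'
#' Greedy best-match assignment of each reference profile to a distinct
#' fitted signature by cosine similarity.
#'
#' @param W Fitted signature matrix (classes x k).
#' @param ref Reference matrix (classes x r).
#' @return Data.frame with columns `ref`, `matched` (column of `W`) and
#'   `cosine`.
#' @export
match_signatures <- function(W, ref) {
  W <- as.matrix(W); ref <- as.matrix(ref)
  sim <- matrix(NA_real_, ncol(ref), ncol(W))
  for (i in seq_len(ncol(ref)))
    for (j in seq_len(ncol(W)))
      sim[i, j] <- cosine_similarity(ref[, i], W[, j])
  out <- data.frame(ref = seq_len(ncol(ref)), matched = NA_integer_,
                    cosine = NA_real_)
  avail <- rep(TRUE, ncol(W))
  for (step in seq_len(min(ncol(ref), ncol(W)))) {
    s <- sim
    s[!is.na(out$matched), ] <- -Inf
    s[, !avail] <- -Inf
    ij <- arrayInd(which.max(s), dim(s))
    out$matched[ij[1]] <- ij[2]
    out$cosine[ij[1]] <- sim[ij[1], ij[2]]
    avail[ij[2]] <- FALSE
  }
  out
}
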