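#' Infomax independent component analysis
#'
#' Natural-gradient Infomax with a logistic nonlinearity, the standard
#' (non-extended) variant appropriate for super-Gaussian spatial sources.
#' The data are whitened internally; the unmixing matrix is updated with
#' the natural gradient `(I + (1 - 2y) u') W`, the learning rate is halved
#' whenever successive updates oscillate (negative cosine) or diverge, and
#' iteration stops when the weight-update norm drops below `tol`.
#'
#' Sources are returned with unit variance and with the sign fixed so that
#' each source's maximum-magnitude sample is positive, making runs
#' comparable for stability clustering.
#'
#' @param X data matrix, variables (rows) x samples (columns) — for
#'   spatial ICA, reduced components x voxels.
#' @param n_components number of sources (<= rank of X); defaults to
#'   `nrow(X)`.
#' @param seed integer seed for the random orthonormal initialisation.
#' @param lrate initial learning rate.
#' @param tol convergence tolerance on the Frobenius norm of the weight
#'   update.
#' @param max_iter maximum number of iterations (default 2000);
#'   non-convergence returns the best iterate with `converged = FALSE`
#'   and a warning.
#' @return object of class `"infomax_ica"`: `sources`
#'   (`n_components` x samples, unit variance), `unmixing`
#'   (`n_components` x nrow(X), including whitening), `mixing` (right
#'   inverse of `unmixing`), `center`, `iterations`, `converged`,
#'   `final_update`, `eigenvalues` of the data covariance.
#' @export
infomax_ica <- function(X, n_components = nrow(X), seed = 0L,
                        lrate = 0.01, tol = 1e-7, max_iter = 2000L) {
  X <- as.matrix(X)
  m <- nrow(X)
  n <- ncol(X)
  stopifnot(n_components >= 1, n_components <= m, n > m)
  ctr <- rowMeans(X)
  Xc <- X - ctr
  ## whitening via the eigendecomposition of the covariance
  Cv <- tcrossprod(Xc) / (n - 1)
  eg <- eigen(Cv, symmetric = TRUE)
  if (eg$values[n_components] < max(eg$values) * 1e-12)
    stop("n_components exceeds the rank of the data")
  Kw <- diag(1 / sqrt(eg$values[seq_len(n_components)]),
             n_components) %*% t(eg$vectors[, seq_len(n_components),
                                            drop = FALSE])
  Xw <- Kw %*% Xc

  k <- n_components
  W <- withr::with_seed(seed, {
    qr.Q(qr(matrix(stats::rnorm(k * k), k, k)))
  })
  I_k <- diag(k)
  prev_dW <- NULL
  best_W <- W
  best_change <- Inf
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    U <- W %*% Xw
    Y <- 1 / (1 + exp(-U))
    G <- (I_k + (1 - 2 * Y) %*% t(U) / n) %*% W
    dW <- lrate * G
    if (!all(is.finite(dW)) || max(abs(dW)) > 1e6) {
      lrate <- lrate / 2
      W <- best_W
      prev_dW <- NULL
      next
    }
    if (!is.null(prev_dW)) {
      cosang <- sum(dW * prev_dW) /
        sqrt(sum(dW^2) * sum(prev_dW^2) + 1e-300)
      if (cosang < 0) {
        lrate <- lrate * 0.5          # oscillation: halve
        dW <- lrate * G
      } else if (cosang < 0.866) {
        lrate <- lrate * 0.95         # direction drifting: anneal
      }
    }
    W <- W + dW
    change <- sqrt(sum(dW^2))
    if (change < best_change) {
      best_change <- change
      best_W <- W
    }
    prev_dW <- dW
    if (change < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("Infomax did not converge in ", max_iter,
            " iterations (final update ", signif(best_change, 3),
            "); returning best iterate")
    W <- best_W
  }
  ## symmetric decorrelation: for whitened data the optimal unmixing is
  ## orthogonal, so project onto the nearest rotation; sources then have
  ## exactly zero empirical correlation.
  sv <- svd(W)
  W <- sv$u %*% t(sv$v)

  S <- W %*% Xw
  ## unit-variance, sign-fixed sources
  sds <- apply(S, 1, stats::sd)
  sds[sds == 0] <- 1
  S <- S / sds
  signs <- vapply(seq_len(k), function(r) {
    v <- S[r, ]
    if (v[which.max(abs(v))] < 0) -1 else 1
  }, 0)
  S <- S * signs
  unmix <- (signs / sds) * (W %*% Kw)
  mixing <- t(unmix) %*% solve(tcrossprod(unmix))

  structure(list(sources = S, unmixing = unmix, mixing = mixing,
                 center = ctr, iterations = it, converged = converged,
                 final_update = best_change,
                 eigenvalues = eg$values), class = "infomax_ica")
}

#' @export
print.infomax_ica <- function(x, ...) {
  cat("Infomax ICA:", nrow(x$sources), "sources,", x$iterations,
      "iterations,", if (x$converged) "converged" else "NOT converged",
      sprintf("(final update %.2e)\n", x$final_update))
  invisible(x)
}

#' Match estimated components to reference components
#'
#' Greedy assignment by maximal absolute spatial correlation, the standard
#' way to resolve the permutation and sign ambiguity of ICA when comparing
#' against reference maps.
#'
#' @param est K x V matrix of estimated maps.
#' @param ref K_ref x V matrix of reference maps.
#' @return data.frame with one row per estimated component used:
#'   `est`, `ref`, `r` (signed correlation of the matched pair),
#'   `abs_r`.
#' @export
match_components <- function(est, ref) {
  cc <- stats::cor(t(est), t(ref))
  n <- min(nrow(est), nrow(ref))
  ac <- abs(cc)
  out <- data.frame(est = integer(n), ref = integer(n), r = numeric(n))
  for (j in seq_len(n)) {
    idx <- which(ac == max(ac), arr.ind = TRUE)[1L, ]
    out$est[j] <- idx[1L]
    out$ref[j] <- idx[2L]
    out$r[j] <- cc[idx[1L], idx[2L]]
    ac[idx[1L], ] <- -Inf
    ac[, idx[2L]] <- -Inf
  }
  out$abs_r <- abs(out$r)
  out[order(out$ref), ]
}
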