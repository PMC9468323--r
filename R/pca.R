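#' Two-stage PCA reduction for group spatial ICA
#'
#' Subject stage: each subject's voxel-centred T x V series is reduced to
#' the smallest number of temporal principal directions explaining at
#' least `variance_threshold` of its variance (capped at `subject_cap`).
#' Group stage: the subject-reduced data are concatenated along the
#' component dimension and reduced again to exactly `n_group_components`
#' directions, the matrix handed to the ICA unmixing.
#'
#' @param subject_series list of T x V matrices (V identical across
#'   subjects; T may vary).
#' @param n_group_components group-level dimension (default 20).
#' @param variance_threshold fraction of per-subject variance to retain at
#'   the subject stage (default 0.95).
#' @param subject_cap maximum per-subject dimension (default 30),
#'   preventing the variance rule from exploding on noisy data.
#' @return object of class `"pca_reduction"`: list with `group_reduced`
#'   (`n_group_components` x V), `group_basis`, `subject_bases` (per
#'   subject: directions, singular values, retained count and variance),
#'   `subject_dims`, `n_group_components`, `variance_threshold`.
#' @export
two_stage_pca <- function(subject_series, n_group_components = 20L,
                          variance_threshold = 0.95, subject_cap = 30L) {
  stopifnot(is.list(subject_series), length(subject_series) >= 2,
            n_group_components >= 1,
            variance_threshold > 0, variance_threshold <= 1)
  V <- ncol(subject_series[[1L]])
  if (!all(vapply(subject_series, ncol, 0L) == V))
    stop("all subjects must share the same voxel dimension")

  subject_bases <- vector("list", length(subject_series))
  reduced <- vector("list", length(subject_series))
  for (i in seq_along(subject_series)) {
    X <- as.matrix(subject_series[[i]])
    Xc <- sweep(X, 2, colMeans(X))          # centre each voxel series
    ## temporal PCA via the small T x T Gram matrix
    eg <- eigen(tcrossprod(Xc), symmetric = TRUE)
    ev <- pmax(eg$values, 0)
    cum <- cumsum(ev) / sum(ev)
    k <- which(cum >= variance_threshold)[1L]
    if (is.na(k)) k <- length(ev)
    k <- min(k, subject_cap, sum(ev > max(ev) * 1e-12))
    U <- eg$vectors[, seq_len(k), drop = FALSE]
    subject_bases[[i]] <- list(directions = U,
                               singular_values = sqrt(ev[seq_len(k)]),
                               retained = k,
                               retained_variance = cum[k])
    reduced[[i]] <- crossprod(U, Xc)
  }

  Y <- do.call(rbind, reduced)
  if (n_group_components > nrow(Y))
    stop("rank deficiency: requested ", n_group_components,
         " group components but only ", nrow(Y), " subject directions")
  G <- .top_left_singular(Y, n_group_components)
  structure(list(
    group_reduced = crossprod(G, Y),
    group_basis = G,
    subject_bases = subject_bases,
    subject_dims = vapply(subject_bases, `[[`, 0L, "retained"),
    n_group_components = as.integer(n_group_components),
    variance_threshold = variance_threshold
  ), class = "pca_reduction")
}

## Leading k left singular vectors of Y.  Exact for small problems;
## randomized subspace iteration (fixed internal seed, 8-column
## oversampling, 3 power iterations) for large ones, where only the
## leading subspace is needed.
.top_left_singular <- function(Y, k) {
  n <- nrow(Y)
  if (n <= 256L) {
    eg <- eigen(tcrossprod(Y), symmetric = TRUE)
    if (sum(eg$values > max(eg$values) * 1e-12) < k)
      stop("rank deficiency: concatenated data have rank ",
           sum(eg$values > max(eg$values) * 1e-12), " < ", k)
    return(eg$vectors[, seq_len(k), drop = FALSE])
  }
  p <- min(n, k + 8L)
  Om <- withr::with_seed(0L, matrix(stats::rnorm(ncol(Y) * p), ncol(Y), p))
  Q <- qr.Q(qr(Y %*% Om))
  for (it in 1:3)
    Q <- qr.Q(qr(Y %*% crossprod(Y, Q)))
  B <- crossprod(Q, Y)
  sb <- svd(B, nu = p, nv = 0)
  if (sum(sb$d > max(sb$d) * 1e-12) < k)
    stop("rank deficiency: concatenated data have rank below ", k)
  Q %*% sb$u[, seq_len(k), drop = FALSE]
}

#' @export
print.pca_reduction <- function(x, ...) {
  cat("Two-stage PCA reduction:", length(x$subject_bases), "subjects,",
      "subject dims", paste(range(x$subject_dims), collapse = "-"),
      "-> group dimension", x$n_group_components, "\n")
  invisible(x)
}
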