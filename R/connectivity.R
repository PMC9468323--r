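#' Post-process component or ROI time courses
#'
#' Standard cleanup applied to extracted time courses before connectivity
#' analysis: per-signal linear detrending, optional nuisance regression,
#' zero-phase band-pass filtering (2nd-order Butterworth, applied
#' forward-backward), and demeaning.  The default band of 0.01-0.08 Hz is
#' the conventional low-frequency BOLD band.
#'
#' @param tc T x K matrix of time courses.
#' @param tr repetition time in seconds per time point.
#' @param band length-2 numeric, pass band in Hz; must lie inside
#'   (0, Nyquist).  `NULL` skips filtering.
#' @param nuisance optional T x p matrix of nuisance regressors removed by
#'   least squares after detrending.
#' @return matrix of the same shape, zero-mean per column.
#' @export
postprocess_timecourses <- function(tc, tr, band = c(0.01, 0.08),
                                    nuisance = NULL) {
  tc <- as.matrix(tc)
  n_time <- nrow(tc)
  stopifnot(n_time >= 8, tr > 0)
  nyq <- 1 / (2 * tr)
  if (!is.null(band)) {
    stopifnot(length(band) == 2)
    if (band[1] <= 0 || band[2] <= band[1] || band[2] >= nyq)
      stop("invalid band: need 0 < low < high < Nyquist (", signif(nyq, 3),
           " Hz at tr = ", tr, " s)")
  }
  tt <- seq_len(n_time)
  X <- cbind(1, tt)
  out <- tc - X %*% solve(crossprod(X), crossprod(X, tc))
  if (!is.null(nuisance)) {
    Z <- cbind(1, as.matrix(nuisance))
    out <- out - Z %*% solve(crossprod(Z), crossprod(Z, out))
  }
  if (!is.null(band)) {
    bf <- signal::butter(2, band / nyq, type = "pass")
    out <- apply(out, 2, function(x) signal::filtfilt(bf, x))
  }
  sweep(out, 2, colMeans(out))
}

#' Sliding-window plan
#'
#' Defines the sliding-window segmentation of a length-`n_time` series:
#' `count = floor((n_time - width) / step) + 1` windows, window `j`
#' (0-based) covering the half-open interval `[j * step, j * step + width)`.
#' Defaults are a width of 50 TR and a step of 1 TR.
#'
#' @param n_time number of time points.
#' @param width window width in TR (>= 2).
#' @param step window step in TR (>= 1).
#' @return object of class `"window_plan"`: list with `width`, `step`,
#'   `count`, and 0-based `starts`.
#' @export
plan_windows <- function(n_time, width = 50L, step = 1L) {
  stopifnot(width >= 2, step >= 1)
  if (n_time < width)
    stop("series too short: n_time = ", n_time, " < width = ", width)
  count <- (n_time - width) %/% step + 1L
  structure(list(width = as.integer(width), step = as.integer(step),
                 count = as.integer(count),
                 starts = as.integer((seq_len(count) - 1L) * step)),
            class = "window_plan")
}

#' @export
print.window_plan <- function(x, ...) {
  cat("Sliding-window plan: width", x$width, "TR, step", x$step, "TR,",
      x$count, "windows\n")
  invisible(x)
}

## Pearson correlation matrix with constant-signal guard: entries involving
## a zero-variance column are set to 0 (diagonal stays 1) with a warning.
.safe_cor <- function(x, context = "segment") {
  sds <- apply(x, 2, stats::sd)
  flat <- sds == 0
  if (any(flat)) {
    warning("constant ", context, " in ", sum(flat),
            " signal(s); undefined correlations set to 0")
    x[, flat] <- 0
    sds[flat] <- 1
  }
  xs <- sweep(sweep(x, 2, colMeans(x)), 2, sds, "/")
  R <- crossprod(xs) / (nrow(x) - 1)
  R[flat, ] <- 0
  R[, flat] <- 0
  diag(R) <- 1
  R[R > 1] <- 1
  R[R < -1] <- -1
  (R + t(R)) / 2
}

#' Windowed Pearson correlation matrix
#'
#' Computes the K x K Pearson correlation matrix of one sliding window of
#' the time courses.  The sign of the correlation is kept as is (no
#' absolute value, no Fisher transform); the diagonal is exactly 1.  A
#' constant segment yields 0 entries with a warning so the sequence keeps
#' its alignment.
#'
#' @param tc T x K matrix of time courses.
#' @param plan a [plan_windows()] object.
#' @param j 0-based window index (`j < plan$count`).
#' @return K x K correlation matrix with attribute `window_index`.
#' @export
window_correlation <- function(tc, plan, j) {
  stopifnot(inherits(plan, "window_plan"), j >= 0, j < plan$count)
  s <- plan$starts[j + 1L]
  seg <- tc[(s + 1L):(s + plan$width), , drop = FALSE]
  R <- .safe_cor(seg, context = "window segment")
  attr(R, "window_index") <- as.integer(j)
  R
}

#' Vectorise the strict upper triangle of a symmetric matrix
#'
#' Returns the strictly-above-diagonal entries in row-major order
#' (pairs (1,2), (1,3), ..., (1,K), (2,3), ...), the canonical feature
#' order used throughout the package.  Length is `K * (K - 1) / 2`
#' (105 for K = 15, 6670 for K = 116).
#'
#' @param R symmetric K x K matrix.
#' @return numeric vector of length `K * (K - 1) / 2`.
#' @seealso [untriu_vector()] for the inverse.
#' @export
triu_vectorize <- function(R) {
  R <- as.matrix(R)
  stopifnot(nrow(R) == ncol(R))
  tR <- t(R)
  tR[lower.tri(tR)]
}

#' Rebuild a symmetric unit-diagonal matrix from its triu vector
#'
#' Inverse of [triu_vectorize()] for symmetric matrices with a known
#' diagonal.
#'
#' @param v triu feature vector of length `K * (K - 1) / 2`.
#' @param K matrix dimension.
#' @param diagonal diagonal value (default 1).
#' @return symmetric K x K matrix.
#' @export
untriu_vector <- function(v, K, diagonal = 1) {
  stopifnot(length(v) == K * (K - 1) / 2)
  tM <- matrix(0, K, K)
  tM[lower.tri(tM)] <- v
  M <- t(tM) + tM
  diag(M) <- diagonal
  M
}

#' Dynamic functional connectivity feature sequence
#'
#' Slides a window over the time courses and stacks the triu-vectorised
#' windowed correlation matrices into a d x w feature matrix
#' (d = K(K-1)/2), the input representation for the sequence classifier.
#'
#' @param tc T x K matrix of time courses.
#' @param plan a [plan_windows()] object.
#' @param subject_id optional identifier stored as an attribute.
#' @param level `"ica"` or `"roi"`, stored as an attribute.
#' @return d x w matrix of class `"feature_sequence"` with attributes
#'   `width`, `step`, `level`, `subject_id`.
#' @export
dfc_sequence <- function(tc, plan, subject_id = NULL, level = "ica") {
  tc <- as.matrix(tc)
  K <- ncol(tc)
  d <- K * (K - 1L) / 2L
  out <- .sliding_triu_cor(tc, plan)
  structure(out, class = c("feature_sequence", class(out)),
            width = plan$width, step = plan$step, level = level,
            subject_id = subject_id)
}

## All-window triu correlation features at once via cumulative sums:
## window sums of x, x^2 and x_p * x_q are differences of cumsums, so the
## whole d x w feature matrix costs O(T K^2) regardless of window count.
.sliding_triu_cor <- function(tc, plan) {
  n_time <- nrow(tc)
  K <- ncol(tc)
  w <- plan$count
  width <- plan$width
  lo <- plan$starts + 1L          # window start rows (1-based)
  hi <- plan$starts + width       # window end rows
  cs <- rbind(0, apply(tc, 2, cumsum))
  cs2 <- rbind(0, apply(tc^2, 2, cumsum))
  S1 <- cs[hi + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]    # w x K
  S2 <- cs2[hi + 1L, , drop = FALSE] - cs2[lo, , drop = FALSE]
  varn <- S2 - S1^2 / width       # width * variance
  flat <- varn <= 0
  if (any(flat))
    warning("constant window segment in ", sum(colSums(flat) > 0),
            " signal(s); undefined correlations set to 0")
  pq <- which(upper.tri(diag(K)), arr.ind = TRUE)
  pq <- pq[order(pq[, 1L], pq[, 2L]), , drop = FALSE]  # row-major order
  out <- matrix(0, nrow(pq), w)
  for (j in seq_len(nrow(pq))) {
    p <- pq[j, 1L]; q <- pq[j, 2L]
    cp <- cumsum(c(0, tc[, p] * tc[, q]))
    Spq <- cp[hi + 1L] - cp[lo]
    num <- Spq - S1[, p] * S1[, q] / width
    den <- sqrt(varn[, p] * varn[, q])
    r <- ifelse(den > 0, num / den, 0)
    out[j, ] <- pmin(1, pmax(-1, r))
  }
  out
}

#' Static functional connectivity vector
#'
#' Triu-vectorised Pearson correlation matrix of the entire time course —
#' the windowless counterpart of [dfc_sequence()] (identical to a single
#' window of width T).
#'
#' @param tc T x K matrix of time courses.
#' @param subject_id optional identifier stored as an attribute.
#' @return numeric vector of length `K * (K - 1) / 2`.
#' @export
static_fc <- function(tc, subject_id = NULL) {
  stopifnot(nrow(tc) >= 2)
  v <- triu_vectorize(.safe_cor(as.matrix(tc), context = "time course"))
  attr(v, "subject_id") <- subject_id
  v
}

#' Region-mean time courses from an atlas parcellation
#'
#' Averages the voxel time series within each atlas region, producing one
#' signal per region in ascending label order — the ROI-level counterpart
#' of the ICA component time courses (116 signals for the AAL atlas).
#'
#' @param voxel_series T x V matrix of voxel time series.
#' @param atlas_labels integer vector of per-voxel region labels
#'   (0 = background, excluded).
#' @param region_ids optional integer vector of required regions; an empty
#'   region raises an error naming it.
#' @return T x R matrix with region ids as column names and attribute
#'   `source = "roi"`.
#' @export
roi_mean_timecourses <- function(voxel_series, atlas_labels,
                                 region_ids = NULL) {
  voxel_series <- as.matrix(voxel_series)
  atlas_labels <- as.integer(atlas_labels)
  stopifnot(length(atlas_labels) == ncol(voxel_series))
  present <- sort(unique(atlas_labels[atlas_labels > 0L]))
  if (is.null(region_ids)) region_ids <- present
  missing_r <- setdiff(region_ids, present)
  if (length(missing_r))
    stop("atlas/mask mismatch: region(s) ",
         paste(missing_r, collapse = ", "), " contain no voxels")
  region_ids <- sort(region_ids)
  out <- vapply(region_ids, function(r)
    rowMeans(voxel_series[, atlas_labels == r, drop = FALSE]),
    numeric(nrow(voxel_series)))
  out <- matrix(out, nrow = nrow(voxel_series),
                dimnames = list(NULL, region_ids))
  attr(out, "source") <- "roi"
  out
}
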