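#' Back-reconstruction of subject components by dual regression
#'
#' Recovers subject-specific time courses and spatial maps from fixed
#' group maps in two least-squares stages, each with an intercept:
#' stage 1 regresses every time point's voxel vector on the group maps,
#' yielding T x K subject time courses; stage 2 regresses every voxel's
#' time series on those time courses, yielding K x V subject maps.
#' Time courses are returned zero-mean per component.
#'
#' Only the group maps and the subject's own data enter the computation,
#' so applying training-fold group maps to a held-out subject involves no
#' leakage.
#'
#' @param group_maps K x V matrix of group component maps (linearly
#'   independent rows).
#' @param subject_series T x V matrix for one subject.
#' @return object of class `"subject_components"`: `timecourses` (T x K,
#'   zero mean), `maps` (K x V), `kept` (component indices, initially
#'   `1:K`).
#' @export
back_reconstruct <- function(group_maps, subject_series) {
  group_maps <- as.matrix(group_maps)
  X <- as.matrix(subject_series)
  K <- nrow(group_maps)
  if (ncol(group_maps) != ncol(X))
    stop("voxel dimension mismatch between group maps and subject data")
  D1 <- cbind(1, t(group_maps))
  q1 <- qr(D1)
  if (q1$rank < K + 1L)
    stop("collinearity: group maps are not linearly independent")
  tc <- t(qr.coef(q1, t(X))[-1L, , drop = FALSE])
  D2 <- cbind(1, tc)
  maps <- qr.coef(qr(D2), X)[-1L, , drop = FALSE]
  tc <- sweep(tc, 2, colMeans(tc))
  structure(list(timecourses = tc, maps = maps, kept = seq_len(K)),
            class = "subject_components")
}

#' @export
print.subject_components <- function(x, ...) {
  cat("Subject components:", ncol(x$timecourses), "components,",
      nrow(x$timecourses), "time points (kept:",
      paste(range(x$kept), collapse = "-"), ")\n")
  invisible(x)
}

## Fraction of periodogram power above `cutoff_hz` for one signal.
.high_freq_fraction <- function(x, tr, cutoff_hz) {
  n <- length(x)
  x <- x - mean(x)
  pw <- Mod(stats::fft(x))^2
  freqs <- (seq_len(n) - 1) / (n * tr)
  half <- freqs <= 1 / (2 * tr)
  pw <- pw[half][-1L]          # drop the DC bin
  freqs <- freqs[half][-1L]
  if (sum(pw) == 0) return(0)
  sum(pw[freqs > cutoff_hz]) / sum(pw)
}

#' Restrict subject components to a kept subset
#'
#' Keeps an explicit list of components (the configuration-driven
#' replacement for manual noise-component labelling) or, optionally,
#' drops components flagged by a spectral heuristic: a component is
#' considered noise when more than `max_high_freq_fraction` of its
#' time-course spectral power lies above `cutoff_hz` (BOLD components
#' concentrate power in the low-frequency band).
#'
#' @param sc a [back_reconstruct()] result.
#' @param keep integer indices of components to keep (1-based, relative to
#'   the current components).  Mutually exclusive with `heuristic`.
#' @param heuristic optional list with `tr` (seconds), `cutoff_hz`
#'   (default 0.1), and `max_high_freq_fraction` (default 0.5).
#' @return `"subject_components"` object restricted to the kept
#'   components, with `kept` recording the original indices.
#' @export
select_components <- function(sc, keep = NULL, heuristic = NULL) {
  stopifnot(inherits(sc, "subject_components"),
            is.null(keep) || is.null(heuristic))
  K <- ncol(sc$timecourses)
  if (is.null(keep) && is.null(heuristic))
    stop("supply either `keep` or `heuristic`")
  if (!is.null(heuristic)) {
    stopifnot(!is.null(heuristic$tr))
    cutoff <- heuristic$cutoff_hz %||% 0.1
    maxfrac <- heuristic$max_high_freq_fraction %||% 0.5
    frac <- apply(sc$timecourses, 2, .high_freq_fraction,
                  tr = heuristic$tr, cutoff_hz = cutoff)
    keep <- which(frac <= maxfrac)
  }
  keep <- as.integer(keep)
  if (!length(keep))
    stop("invalid selection: empty keep set")
  if (any(keep < 1L | keep > K))
    stop("invalid selection: indices out of range 1..", K)
  structure(list(timecourses = sc$timecourses[, keep, drop = FALSE],
                 maps = sc$maps[keep, , drop = FALSE],
                 kept = sc$kept[keep]),
            class = "subject_components")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
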