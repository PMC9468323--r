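#' Gaussian-blob spatial component maps
#'
#' Places `n_components` Gaussian blobs at distinct locations on a 2-D or
#' 3-D voxel grid and returns them as a component-by-voxel loading matrix.
#' Maps are non-negative and row-normalised to unit maximum, and centres are
#' placed with a minimum mutual distance so that the pairwise spatial
#' correlation between any two maps stays below `max_pair_cor`.
#'
#' Voxels are ordered column-major (the first grid index varies fastest),
#' matching [load_nifti_series()].
#'
#' @param n_components number of spatial maps (>= 2).
#' @param grid_shape integer vector of 2 or 3 grid dimensions.
#' @param blob_sigma Gaussian kernel standard deviation, in voxels.
#' @param seed integer seed; the same call with the same seed is
#'   bit-reproducible.
#' @param max_pair_cor upper bound enforced on pairwise spatial correlation.
#' @return `n_components x prod(grid_shape)` matrix with attribute
#'   `centers` (component centres in voxel coordinates) and `grid_shape`.
#' @export
make_spatial_maps <- function(n_components, grid_shape, blob_sigma = 1.5,
                              seed = 0L, max_pair_cor = 0.3) {
  stopifnot(n_components >= 2, length(grid_shape) %in% c(2L, 3L),
            all(grid_shape >= 1), blob_sigma > 0)
  V <- prod(grid_shape)
  if (V < 4L * n_components)
    stop("infeasible geometry: grid volume ", V, " is too small for ",
         n_components, " distinct components (need >= ", 4L * n_components, ")")

  coords <- as.matrix(do.call(expand.grid, lapply(grid_shape, seq_len)))
  min_dist <- 2.5 * blob_sigma  # keeps blob overlap (hence correlation) low

  result <- withr::with_seed(seed, {
    maps_out <- NULL
    for (attempt in seq_len(50L)) {
      centers <- matrix(NA_real_, n_components, length(grid_shape))
      for (k in seq_len(n_components)) {
        best <- NULL
        best_d <- -Inf
        for (try in seq_len(200L)) {
          cand <- vapply(grid_shape, function(g) stats::runif(1, 1, g), 0)
          dmin <- if (k == 1L) Inf else
            min(sqrt(rowSums(sweep(centers[seq_len(k - 1L), , drop = FALSE],
                                   2, cand)^2)))
          if (dmin > best_d) {
            best <- cand
            best_d <- dmin
          }
          if (dmin >= min_dist) break
        }
        centers[k, ] <- best  # farthest candidate if the bound was not met
      }
      maps <- t(vapply(seq_len(n_components), function(k) {
        d2 <- rowSums(sweep(coords, 2, centers[k, ])^2)
        m <- exp(-d2 / (2 * blob_sigma^2))
        m / max(m)
      }, numeric(V)))
      cc <- stats::cor(t(maps))
      if (max(abs(cc[upper.tri(cc)])) < max_pair_cor) {
        attr(maps, "centers") <- centers
        attr(maps, "grid_shape") <- grid_shape
        maps_out <- maps
        break
      }
    }
    maps_out
  })
  if (is.null(result))
    stop("infeasible geometry: could not place ", n_components,
         " components with pairwise spatial correlation < ", max_pair_cor)
  result
}

#' Markov state sequence with controlled dwell time
#'
#' Samples a discrete hidden-state sequence from a Markov chain whose
#' self-transition probability is `1 - 1/mean_dwell` and whose off-diagonal
#' transitions are uniform, so run lengths are geometric with mean
#' `mean_dwell` time points.
#'
#' @param n_states number of states (>= 1).
#' @param n_time sequence length in time points.
#' @param mean_dwell expected dwell time per visit, in time points (>= 1).
#' @param seed integer seed.
#' @return integer vector of length `n_time` with 0-based state ids in
#'   `[0, n_states)`.
#' @export
sample_state_sequence <- function(n_states, n_time, mean_dwell, seed = 0L) {
  stopifnot(n_states >= 1, n_time >= 1, mean_dwell >= 1)
  if (n_states == 1L) return(integer(n_time))
  p_stay <- 1 - 1 / mean_dwell
  withr::with_seed(seed, {
    s <- integer(n_time)
    s[1L] <- sample.int(n_states, 1L) - 1L
    u <- stats::runif(n_time)
    jump <- sample.int(n_states - 1L, n_time, replace = TRUE)
    for (t in 2L:n_time) {
      if (u[t] < p_stay) {
        s[t] <- s[t - 1L]
      } else {
        # uniform over the other states
        cand <- jump[t] - 1L
        s[t] <- if (cand >= s[t - 1L]) cand + 1L else cand
      }
    }
    s
  })
}

#' Component time courses under state-switching covariance
#'
#' At each time point draws the K-vector of component amplitudes from a
#' zero-mean multivariate normal whose covariance is selected by the active
#' hidden state, optionally smoothed with a short moving-average kernel to
#' mimic the band-limited character of BOLD signals.
#'
#' @param states integer vector of 0-based state ids (length T).
#' @param covariances list of K x K positive-definite covariance matrices,
#'   one per state id (element `s + 1` serves state `s`).
#' @param seed integer seed.
#' @param smooth_len optional moving-average kernel length in time points
#'   (1 = no smoothing).  Smoothing is applied per component after sampling
#'   and does not change the within-state correlation structure.
#' @return T x K matrix of component time courses.
#' @export
sample_component_timecourses <- function(states, covariances, seed = 0L,
                                         smooth_len = 1L) {
  stopifnot(length(states) >= 1, smooth_len >= 1)
  ids <- sort(unique(states))
  if (min(ids) < 0L || max(ids) >= length(covariances))
    stop("every state id must index into `covariances`")
  K <- ncol(covariances[[1L]])
  chols <- lapply(covariances, function(C) {
    if (!isTRUE(all.equal(C, t(C), tolerance = 1e-8)))
      stop("covariance matrices must be symmetric")
    ch <- tryCatch(chol(C), error = function(e)
      stop("covariance matrix is not positive-definite"))
    ch
  })
  n_time <- length(states)
  withr::with_seed(seed, {
    z <- matrix(stats::rnorm(n_time * K), n_time, K)
    out <- matrix(0, n_time, K)
    for (s in ids) {
      idx <- which(states == s)
      out[idx, ] <- z[idx, , drop = FALSE] %*% chols[[s + 1L]]
    }
    if (smooth_len > 1L) {
      kern <- rep(1 / smooth_len, smooth_len)
      out <- apply(out, 2, function(x)
        stats::filter(x, kern, sides = 2, circular = TRUE))
    }
    out
  })
}

#' Mix component time courses into voxel data
#'
#' Forms `timecourses %*% maps` and adds i.i.d. Gaussian noise whose
#' standard deviation is set so that `sd(signal) / sd(noise) == snr`.
#' When the signal is identically zero the noise standard deviation
#' defaults to 1.
#'
#' @param maps K x V spatial map matrix.
#' @param timecourses T x K component time-course matrix.
#' @param snr signal-to-noise ratio (> 0), as a ratio of standard deviations.
#' @param seed integer seed.
#' @return T x V voxel time-series matrix.
#' @export
mix_to_voxels <- function(maps, timecourses, snr, seed = 0L) {
  stopifnot(ncol(timecourses) == nrow(maps), snr > 0)
  signal <- timecourses %*% maps
  s_sd <- stats::sd(as.vector(signal))
  noise_sd <- if (s_sd > 0) s_sd / snr else 1
  withr::with_seed(seed, {
    signal + matrix(stats::rnorm(length(signal), sd = noise_sd),
                    nrow(signal), ncol(signal))
  })
}

## Per-state covariance with unit diagonal built from disjoint correlated
## pairs; disjoint 2x2 blocks are positive-definite for any |r| < 1.
.pair_covariance <- function(K, pairs, r) {
  C <- diag(K)
  if (length(pairs)) {
    for (j in seq_along(pairs)) {
      p <- pairs[[j]]
      C[p[1L], p[2L]] <- C[p[2L], p[1L]] <- r[j]
    }
  }
  C
}

#' Synthetic multi-subject cohort with a planted group difference
#'
#' Generates a two-group (or multi-group) resting-state-like cohort with
#' full ground truth: shared spatial maps, per-subject hidden state
#' sequences, state-dependent inter-component covariance, and voxel data at
#' a configurable signal-to-noise ratio.  Dynamics come from a set of
#' disjoint "background" component pairs whose correlation flips sign
#' between states (+`background_r` in state 0, alternating sign across
#' states), identically in every group.  The group effect is planted by
#' shifting the correlation of each `effect_pairs` entry by `delta` in the
#' designated `effect_states` for every group after the first, relative to
#' the reference group.
#'
#' Defaults mirror a desk-scale resting-state cohort: K = 15 latent
#' networks, T = 130 time points, 2 hidden states with mean dwell 40 TR,
#' a 15 x 15 x 10 voxel grid, and snr = 2.
#'
#' @param n_per_group integer vector of group sizes (>= 2 groups).
#' @param K number of latent components.
#' @param n_time time points per subject.
#' @param grid_shape voxel grid dimensions.
#' @param n_states number of hidden connectivity states.
#' @param mean_dwell mean state dwell time (TR).
#' @param effect_pairs list of 1-based component index pairs carrying the
#'   group effect.
#' @param effect_states 0-based state ids in which the effect is planted;
#'   `NULL` (default) plants it in every state, making the group
#'   difference state-independent.  Supplying a subset (possibly with
#'   per-state `delta` signs) confines the effect to those states, the
#'   construction used to study dynamic-versus-static sensitivity.
#' @param delta correlation shift for the effect pairs; either a scalar or
#'   one value per element of `effect_states`.
#' @param snr signal-to-noise ratio of the voxel mixing step.
#' @param background_r magnitude of the state-switching background
#'   correlations.
#' @param blob_sigma spatial map width in voxels.
#' @param smooth_len moving-average kernel for time courses (1 = none).
#' @param group_names character vector of group labels.
#' @param seed integer seed controlling the whole cohort.
#' @return object of class `"dfc_cohort"`: a list with `maps`,
#'   `covariances` (per group, per state), `state_sequences`,
#'   `timecourses`, `voxels`, `labels` (data.frame subject_id, group),
#'   `effect_pairs`, `effect_states`, `delta`, `snr`, `grid_shape`, `seed`.
#' @export
make_cohort <- function(n_per_group = c(40L, 40L), K = 15L, n_time = 130L,
                        grid_shape = c(15L, 15L, 10L), n_states = 2L,
                        mean_dwell = 40L,
                        effect_pairs = list(c(1L, 2L)),
                        effect_states = NULL, delta = 0,
                        snr = 2, background_r = 0.5,
                        blob_sigma = 1.5, smooth_len = 1L,
                        group_names = LETTERS[seq_along(n_per_group)],
                        seed = 1L) {
  stopifnot(length(n_per_group) >= 2, all(n_per_group >= 1), K >= 2,
            n_states >= 1)
  if (is.null(effect_states)) effect_states <- seq_len(n_states) - 1L
  stopifnot(all(effect_states >= 0), all(effect_states < n_states))
  if (length(delta) == 1L) delta <- rep(delta, length(effect_states))
  stopifnot(length(delta) == length(effect_states))
  if (any(abs(delta) >= 1))
    stop("infeasible effect: |delta| must keep correlations inside (-1, 1)")

  eff_idx <- unique(unlist(effect_pairs))
  free <- setdiff(seq_len(K), eff_idx)
  n_bg <- length(free) %/% 2L
  background_pairs <- if (n_bg)
    lapply(seq_len(n_bg), function(j) free[c(2L * j - 1L, 2L * j)])
  else list()

  ## state s: background pairs at background_r * (-1)^s, effect pairs at 0
  base_cov <- lapply(seq_len(n_states) - 1L, function(s)
    .pair_covariance(K, background_pairs, rep(background_r * (-1)^s, n_bg)))

  n_groups <- length(n_per_group)
  covariances <- vector("list", n_groups)
  names(covariances) <- group_names
  covariances[[1L]] <- base_cov
  for (g in seq_len(n_groups)[-1L]) {
    cv <- base_cov
    for (j in seq_along(effect_states)) {
      s <- effect_states[j] + 1L
      for (p in effect_pairs) {
        newr <- cv[[s]][p[1L], p[2L]] + delta[j]
        if (abs(newr) >= 1)
          stop("infeasible effect: shifted correlation ", newr,
               " is outside (-1, 1)")
        cv[[s]][p[1L], p[2L]] <- cv[[s]][p[2L], p[1L]] <- newr
      }
    }
    ## disjoint-pair construction keeps blocks PD, but guard anyway
    for (s in seq_len(n_states))
      tryCatch(chol(cv[[s]]), error = function(e)
        stop("infeasible effect: shifted covariance is not positive-definite"))
    covariances[[g]] <- cv
  }

  maps <- make_spatial_maps(K, grid_shape, blob_sigma, seed = seed)
  n_total <- sum(n_per_group)
  group <- factor(rep(group_names, n_per_group), levels = group_names)
  subject_id <- sprintf("sub-%03d", seq_len(n_total))

  state_sequences <- vector("list", n_total)
  timecourses <- vector("list", n_total)
  voxels <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    sseed <- seed + i * 7L
    g <- as.integer(group[i])
    st <- sample_state_sequence(n_states, n_time, mean_dwell, seed = sseed)
    tc <- sample_component_timecourses(st, covariances[[g]],
                                       seed = sseed + 1L,
                                       smooth_len = smooth_len)
    state_sequences[[i]] <- st
    timecourses[[i]] <- tc
    voxels[[i]] <- mix_to_voxels(maps, tc, snr, seed = sseed + 2L)
  }
  names(state_sequences) <- names(timecourses) <- names(voxels) <- subject_id

  structure(list(
    maps = maps,
    covariances = covariances,
    state_sequences = state_sequences,
    timecourses = timecourses,
    voxels = voxels,
    labels = data.frame(subject_id = subject_id, group = group,
                        stringsAsFactors = FALSE),
    effect_pairs = effect_pairs,
    effect_states = effect_states,
    delta = delta,
    snr = snr,
    grid_shape = grid_shape,
    n_states = n_states,
    mean_dwell = mean_dwell,
    seed = seed
  ), class = "dfc_cohort")
}

#' @export
print.dfc_cohort <- function(x, ...) {
  cat("Synthetic rs-fMRI cohort:", nrow(x$labels), "subjects,",
      nrow(x$maps), "components,", nrow(x$timecourses[[1L]]), "time points,",
      prod(x$grid_shape), "voxels\n")
  print(table(x$labels$group))
  cat("states:", x$n_states, " effect pairs:",
      paste(vapply(x$effect_pairs, paste, "", collapse = "-"),
            collapse = ", "),
      " delta:", paste(x$delta, collapse = "/"),
      " snr:", x$snr, "\n")
  invisible(x)
}
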