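#' ICASSO-style stability assessment of an ICA decomposition
#'
#' Reruns Infomax `n_runs` times from distinct random initialisations,
#' measures the similarity between all pairs of estimated components as
#' the absolute Pearson correlation of their maps, clusters the pooled
#' components into `n_components` clusters by average-linkage agglomeration
#' on `1 - similarity`, and scores each cluster with the quality index
#' `Iq = mean intra-cluster similarity - mean extra-cluster similarity`.
#' The consensus map of a cluster is its centrotype, the member with the
#' highest total intra-cluster similarity.
#'
#' @param X data matrix, variables x samples (see [infomax_ica()]).
#' @param n_components number of sources per run.
#' @param n_runs number of ICA runs (>= 2, default 10).
#' @param seed base seed; run r uses `run_seeds[r]`.
#' @param run_seeds optional explicit per-run seeds (e.g. all equal to
#'   force identical runs); defaults to `seed + 0:(n_runs-1)`.
#' @param ... further arguments passed to [infomax_ica()].
#' @return object of class `"icasso_report"`: `iq` (per-cluster quality
#'   index), `consensus_maps` (`n_components` x samples centrotypes),
#'   `assignments` (data.frame run, component, cluster),
#'   `similarity` (pooled similarity matrix), `runs`, `stable`
#'   (all clusters contain one component from every run).
#' @export
icasso_stability <- function(X, n_components, n_runs = 10L, seed = 0L,
                             run_seeds = NULL, ...) {
  stopifnot(n_runs >= 2)
  if (is.null(run_seeds)) run_seeds <- seed + seq_len(n_runs) - 1L
  stopifnot(length(run_seeds) == n_runs)
  fits <- lapply(run_seeds, function(s)
    infomax_ica(X, n_components = n_components, seed = s, ...))
  pooled <- do.call(rbind, lapply(fits, `[[`, "sources"))
  run_of <- rep(seq_len(n_runs), each = n_components)
  comp_of <- rep(seq_len(n_components), times = n_runs)

  sim <- abs(stats::cor(t(pooled)))
  sim[!is.finite(sim)] <- 0
  diag(sim) <- 1
  d <- stats::as.dist(1 - sim)
  hc <- stats::hclust(d, method = "average")
  cl <- stats::cutree(hc, k = n_components)

  iq <- numeric(n_components)
  centro <- integer(n_components)
  for (c in seq_len(n_components)) {
    inside <- which(cl == c)
    outside <- which(cl != c)
    if (!length(inside)) {
      warning("degenerate clustering: cluster ", c, " is empty")
      iq[c] <- NA_real_
      next
    }
    intra <- if (length(inside) > 1L) {
      sm <- sim[inside, inside, drop = FALSE]
      mean(sm[upper.tri(sm)])
    } else 1
    extra <- if (length(outside))
      mean(sim[inside, outside, drop = FALSE]) else 0
    iq[c] <- intra - extra
    tot <- if (length(inside) > 1L)
      rowSums(sim[inside, inside, drop = FALSE]) else 1
    centro[c] <- inside[which.max(tot)]
  }

  sizes <- tabulate(cl, nbins = n_components)
  balanced <- all(sizes == n_runs) &&
    all(tapply(run_of, cl, function(r) !anyDuplicated(r)))
  if (!balanced)
    warning("unstable decomposition: cluster sizes ",
            paste(sizes, collapse = "/"),
            " differ from one component per run")

  structure(list(
    iq = iq,
    consensus_maps = pooled[centro, , drop = FALSE],
    centrotypes = centro,
    assignments = data.frame(run = run_of, component = comp_of,
                             cluster = cl),
    similarity = sim,
    runs = n_runs,
    stable = balanced
  ), class = "icasso_report")
}

#' @export
print.icasso_report <- function(x, ...) {
  cat("ICASSO stability report:", x$runs, "runs,",
      length(x$iq), "clusters;",
      sprintf("Iq min/median/max = %.3f/%.3f/%.3f;",
              min(x$iq, na.rm = TRUE), stats::median(x$iq, na.rm = TRUE),
              max(x$iq, na.rm = TRUE)),
      if (x$stable) "stable" else "UNSTABLE", "\n")
  invisible(x)
}
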