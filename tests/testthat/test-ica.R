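make_ica_fixture <- function(seed = 3) {
  co <- make_cohort(n_per_group = c(5, 5), K = 5, n_time = 130,
                    grid_shape = c(12, 12, 8), delta = 0, snr = 2,
                    seed = seed)
  list(cohort = co,
       reduction = two_stage_pca(co$voxels, n_group_components = 5))
}

test_that("two-stage PCA hits the configured group dimension", {
  fx <- make_ica_fixture()
  red <- fx$reduction
  expect_s3_class(red, "pca_reduction")
  expect_equal(nrow(red$group_reduced), 5L)
  expect_true(all(vapply(red$subject_bases, `[[`, 0,
                         "retained_variance") >= 0.95 |
                    red$subject_dims == 30L))

  ## default configuration yields a 20-dimensional group stage
  co <- make_cohort(n_per_group = c(6, 6), K = 15, n_time = 130,
                    grid_shape = c(10, 10, 6), seed = 5)
  red20 <- two_stage_pca(co$voxels)
  expect_equal(nrow(red20$group_reduced), 20L)
  expect_equal(red20$n_group_components, 20L)

  ## exactly low-rank data: subject stage keeps <= rank directions and
  ## reconstructs with negligible error
  set.seed(8)
  basis <- matrix(rnorm(3 * 200), 3, 200)
  series <- lapply(1:3, function(i) matrix(rnorm(40 * 3), 40, 3) %*% basis)
  red3 <- two_stage_pca(series, n_group_components = 3)
  expect_true(all(red3$subject_dims <= 3))
  sb <- red3$subject_bases[[1]]
  X <- series[[1]]
  Xc <- sweep(X, 2, colMeans(X))
  recon <- sb$directions %*% crossprod(sb$directions, Xc)
  expect_lt(max(abs(recon - Xc)), 1e-8)

  expect_error(two_stage_pca(series, n_group_components = 50),
               "rank deficiency")
})

test_that("Infomax recovers super-Gaussian sources", {
  set.seed(42)
  S <- matrix(rnorm(3 * 5000)^3, 3)
  A <- matrix(runif(9, 0.5, 1.5) * sign(rnorm(9)), 3)
  fit <- infomax_ica(A %*% S, 3, seed = 1)
  expect_lt(amari_distance(fit$unmixing %*% A), 0.05)
  ## sources: unit variance, sign convention, decorrelated
  expect_equal(unname(apply(fit$sources, 1, sd)), rep(1, 3))
  for (r in 1:3) {
    v <- fit$sources[r, ]
    expect_gt(v[which.max(abs(v))], 0)
  }
  cc <- cor(t(fit$sources))
  expect_lt(max(abs(cc[upper.tri(cc)])), 1e-8)
  ## unmixing and mixing are mutual inverses on the source space
  expect_equal(fit$unmixing %*% fit$mixing, diag(3), tolerance = 1e-8)

  expect_identical(fit$unmixing, infomax_ica(A %*% S, 3, seed = 1)$unmixing)

  ## the PCA rotation underlying whitening preserves total variance
  X <- A %*% S
  Xc <- X - rowMeans(X)
  Cv <- tcrossprod(Xc) / (ncol(X) - 1)
  expect_equal(sum(fit$eigenvalues), sum(diag(Cv)), tolerance = 1e-8)
})

test_that("ICASSO separates stable from unstable decompositions", {
  fx <- make_ica_fixture()
  X <- fx$reduction$group_reduced

  same <- suppressWarnings(
    icasso_stability(X, 5, n_runs = 3, run_seeds = rep(7L, 3)))
  expect_equal(same$iq, rep(1, 5), tolerance = 1e-8)

  stable <- suppressWarnings(icasso_stability(X, 5, n_runs = 10, seed = 1))
  expect_gt(min(stable$iq), 0.9)
  expect_true(stable$stable)
  expect_equal(nrow(stable$consensus_maps), 5L)

  noise <- withr::with_seed(99L, matrix(rnorm(5 * 600), 5, 600))
  noisy <- suppressWarnings(icasso_stability(noise, 5, n_runs = 6,
                                             seed = 2))
  expect_lt(mean(noisy$iq), mean(stable$iq))
})

test_that("dual regression recovers time courses and maps", {
  fx <- make_ica_fixture(seed = 13)
  co <- fx$cohort
  ## noiseless: time-course recovery is essentially exact
  clean <- co$timecourses[[1]] %*% co$maps
  sc <- back_reconstruct(co$maps, clean)
  r <- abs(diag(cor(sc$timecourses, co$timecourses[[1]])))
  expect_true(all(r > 0.999))

  ## least squares is invariant to rescaling a group map
  scaled <- co$maps
  scaled[2, ] <- scaled[2, ] * 7
  sc2 <- back_reconstruct(scaled, clean)
  expect_equal(abs(diag(cor(sc2$timecourses, co$timecourses[[1]]))), r,
               tolerance = 1e-6)

  ## noisy cohort: subject maps still match ground truth after matching
  sc3 <- back_reconstruct(co$maps, co$voxels[[1]])
  mt <- match_components(sc3$maps, co$maps)
  expect_gt(mean(mt$abs_r), 0.8)

  rankdef <- rbind(co$maps, co$maps[1, ])
  expect_error(back_reconstruct(rankdef, clean), "collinearity")
})

test_that("component selection keeps the requested subset", {
  fx <- make_ica_fixture(seed = 21)
  sc <- back_reconstruct(fx$cohort$maps, fx$cohort$voxels[[1]])
  kept <- select_components(sc, keep = c(1, 3, 5))
  expect_equal(kept$kept, c(1L, 3L, 5L))
  expect_equal(ncol(kept$timecourses), 3L)
  expect_equal(nrow(kept$maps), 3L)

  all_kept <- select_components(sc, keep = 1:5)
  expect_equal(all_kept$timecourses, sc$timecourses)

  expect_error(select_components(sc, keep = integer(0)),
               "empty keep set")
  expect_error(select_components(sc, keep = 9), "out of range")

  ## spectral heuristic: a 0.2 Hz carrier is flagged, a 0.03 Hz one kept
  tr <- 2.5
  tt <- seq_len(200) * tr
  sc_h <- structure(list(
    timecourses = cbind(sin(2 * pi * 0.2 * tt), sin(2 * pi * 0.03 * tt)),
    maps = matrix(rnorm(2 * 10), 2, 10), kept = 1:2),
    class = "subject_components")
  hk <- select_components(sc_h, heuristic = list(tr = tr))
  expect_equal(hk$kept, 2L)
})

test_that("group maps from the full pipeline match the generating maps", {
  co <- make_cohort(n_per_group = c(5, 5), K = 5, n_time = 130,
                    grid_shape = c(12, 12, 8), delta = 0, snr = 2,
                    seed = 31)
  red <- two_stage_pca(co$voxels, n_group_components = 5)
  fit <- suppressWarnings(infomax_ica(red$group_reduced, 5, seed = 7))
  mt <- match_components(fit$sources, co$maps)
  expect_gt(mean(mt$abs_r), 0.8)
})
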