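test_that("spatial maps are distinct, bounded in overlap, and seeded", {
  m <- make_spatial_maps(3, c(10, 10), blob_sigma = 1.5, seed = 0)
  expect_equal(dim(m), c(3, 100))
  expect_true(all(m >= 0))
  expect_equal(unname(apply(m, 1, max)), rep(1, 3))
  cc <- cor(t(m))
  expect_lt(max(abs(cc[upper.tri(cc)])), 0.3)

  expect_identical(m, make_spatial_maps(3, c(10, 10), 1.5, seed = 0))

  m1 <- make_spatial_maps(3, c(10, 10), 1.5, seed = 1)
  expect_false(identical(attr(m, "centers"), attr(m1, "centers")))
  cc1 <- cor(t(m1))
  expect_lt(max(abs(cc1[upper.tri(cc1)])), 0.3)

  expect_error(make_spatial_maps(5, c(4, 4), 1.5, seed = 0),
               "infeasible geometry")
})

test_that("state sequences have the requested dwell structure", {
  expect_identical(sample_state_sequence(1, 100, 10, seed = 3),
                   integer(100))
  s <- sample_state_sequence(2, 10000, 20, seed = 0)
  expect_true(all(s %in% c(0L, 1L)))
  expect_lt(abs(mean_dwell_of(s) - 20), 2)
  expect_identical(s, sample_state_sequence(2, 10000, 20, seed = 0))
})

test_that("time courses realise the per-state covariance", {
  K <- 4
  ident <- diag(K)
  tc <- sample_component_timecourses(integer(5000), list(ident), seed = 1)
  cc <- cor(tc)
  expect_lt(max(abs(cc[upper.tri(cc)])), 0.05)

  C <- diag(K)
  C[1, 2] <- C[2, 1] <- 0.8
  tc <- sample_component_timecourses(integer(5000), list(C), seed = 2)
  expect_gt(cor(tc[, 1], tc[, 2]), 0.75)
  expect_lt(cor(tc[, 1], tc[, 2]), 0.85)

  ## two states with opposite-sign coupling: whole-series correlation
  ## washes out, within-state correlation stays at +/- 0.8
  Cm <- diag(K); Cm[1, 2] <- Cm[2, 1] <- -0.8
  states <- rep(c(0L, 1L), each = 2500)
  tc <- sample_component_timecourses(states, list(C, Cm), seed = 3)
  expect_lt(abs(cor(tc[, 1], tc[, 2])), 0.15)
  expect_gt(cor(tc[states == 0L, 1], tc[states == 0L, 2]), 0.7)
  expect_lt(cor(tc[states == 1L, 1], tc[states == 1L, 2]), -0.7)

  bad <- diag(K); bad[1, 2] <- bad[2, 1] <- 1.5
  expect_error(sample_component_timecourses(integer(10), list(bad)),
               "positive-definite")
})

test_that("voxel mixing respects the signal-to-noise ratio", {
  maps <- make_spatial_maps(5, c(10, 10, 5), 1.5, seed = 4)
  tc <- make_test_tc(K = 5, seed = 5)
  recover <- function(X) {
    est <- t(qr.coef(qr(cbind(1, t(maps))), t(X))[-1, ])
    diag(cor(est, tc))
  }
  r_hi <- recover(mix_to_voxels(maps, tc, snr = 1e6, seed = 6))
  expect_true(all(r_hi > 0.99))
  r_lo <- recover(mix_to_voxels(maps, tc, snr = 1, seed = 6))
  expect_true(all(r_lo > 0.5))
  expect_lt(mean(r_lo), mean(r_hi))

  pure <- mix_to_voxels(maps, matrix(0, 120, 5), snr = 2, seed = 7)
  expect_lt(abs(mean(pure)), 0.01)
})

test_that("cohorts plant the requested group effect and are reproducible", {
  co <- make_cohort(n_per_group = c(6, 6), K = 8, n_time = 400,
                    grid_shape = c(10, 10, 6), delta = 0.6,
                    mean_dwell = 30, seed = 11)
  ## within the affected state, group-stratified correlation of the
  ## effect pair differs by about delta (tallied on ground truth)
  r_by_group <- vapply(c("A", "B"), function(g) {
    subj <- which(co$labels$group == g)
    vals <- unlist(lapply(subj, function(i) {
      in_state <- co$state_sequences[[i]] == co$effect_states[1]
      tc <- co$timecourses[[i]]
      cor(tc[in_state, co$effect_pairs[[1]][1]],
          tc[in_state, co$effect_pairs[[1]][2]])
    }))
    mean(vals)
  }, 0)
  expect_lt(abs((r_by_group["B"] - r_by_group["A"]) - 0.6), 0.1)

  co2 <- make_cohort(n_per_group = c(6, 6), K = 8, n_time = 400,
                     grid_shape = c(10, 10, 6), delta = 0.6,
                     mean_dwell = 30, seed = 11)
  expect_identical(co$voxels, co2$voxels)
  expect_identical(co$state_sequences, co2$state_sequences)

  ## delta = 0 gives exchangeable groups: identical generative covariances
  co0 <- make_cohort(n_per_group = c(3, 3), K = 6, n_time = 50,
                     grid_shape = c(8, 8, 4), delta = 0, seed = 1)
  expect_identical(co0$covariances[["A"]], co0$covariances[["B"]])

  expect_error(make_cohort(n_per_group = c(3, 3), K = 6, n_time = 50,
                           grid_shape = c(8, 8, 4), delta = 1.2,
                           seed = 1),
               "infeasible effect")
})
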