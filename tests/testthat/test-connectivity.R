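test_that("postprocessing removes trends and enforces the pass band", {
  tr <- 3
  n_time <- 200
  tt <- seq_len(n_time) * tr
  ## 0.04 Hz sinusoid is inside the 0.01-0.08 Hz band: amplitude kept
  x_in <- sin(2 * pi * 0.04 * tt)
  out <- postprocess_timecourses(cbind(x_in), tr = tr)
  amp <- function(x, f) {
    sp <- Mod(fft(x))
    freqs <- (seq_along(x) - 1) / (length(x) * tr)
    sp[which.min(abs(freqs - f))]
  }
  expect_gt(amp(out[, 1], 0.04) / amp(x_in, 0.04), 0.9)

  ## linear ramp is removed by detrending
  ramp <- seq(0, 10, length.out = n_time)
  out_r <- postprocess_timecourses(cbind(ramp), tr = tr, band = NULL)
  slope <- coef(lm(out_r[, 1] ~ seq_len(n_time)))[2]
  orig_slope <- coef(lm(ramp ~ seq_len(n_time)))[2]
  expect_lt(abs(slope), 1e-10 * abs(orig_slope))

  ## 0.2 Hz sinusoid at tr = 2.5 s sits above the band: > 90% attenuated
  tr2 <- 2.5
  tt2 <- seq_len(n_time) * tr2
  x_hi <- sin(2 * pi * 0.2 * tt2)
  out_h <- postprocess_timecourses(cbind(x_hi), tr = tr2)
  a2 <- function(x, f) {
    sp <- Mod(fft(x))
    freqs <- (seq_along(x) - 1) / (length(x) * tr2)
    sp[which.min(abs(freqs - f))]
  }
  expect_lt(a2(out_h[, 1], 0.2) / a2(x_hi, 0.2), 0.1)

  ## nuisance regression removes the supplied regressor
  nuis <- rnorm(n_time)
  y <- 2 * nuis + rnorm(n_time, sd = 0.1)
  out_n <- postprocess_timecourses(cbind(y), tr = tr, band = NULL,
                                   nuisance = cbind(nuis))
  expect_lt(abs(cor(out_n[, 1], nuis)), 1e-10)

  expect_error(postprocess_timecourses(cbind(x_in), tr = 3,
                                       band = c(0.01, 0.5)),
               "invalid band")
})

test_that("window plans count and place windows correctly", {
  expect_equal(plan_windows(50, 50, 1)$count, 1L)
  expect_equal(plan_windows(130, 50, 1)$count, 81L)
  expect_equal(plan_windows(54, 50, 2)$count, 3L)
  p <- plan_windows(54, 50, 2)
  expect_equal(p$starts, c(0L, 2L, 4L))
  expect_error(plan_windows(49, 50, 1), "too short")
})

test_that("windowed correlations match direct summation and keep sign", {
  tc <- make_test_tc(n_time = 130, K = 15, seed = 2)
  plan <- plan_windows(130, 50, 1)
  R <- window_correlation(tc, plan, 10)
  expect_equal(diag(R), rep(1, 15))
  expect_equal(R, t(R))
  seg <- tc[11:60, ]
  for (p in c(1, 3, 14)) {
    for (q in c(2, 9, 15)) {
      expect_equal(R[p, q], pearson_by_sums(seg[, p], seg[, q]),
                   tolerance = 1e-12)
    }
  }
  ## identical and negated segments
  two <- cbind(seg[, 1], seg[, 1], -seg[, 1])
  plan2 <- plan_windows(50, 50, 1)
  R2 <- window_correlation(two, plan2, 0)
  expect_equal(R2[1, 2], 1)
  expect_equal(R2[1, 3], -1)
  ## constant segment maps to 0 with a warning
  cst <- cbind(seg[, 1], rep(2, 50))
  expect_warning(R3 <- window_correlation(cst, plan2, 0), "constant")
  expect_equal(R3[1, 2], 0)
  expect_equal(diag(R3), rep(1, 2))
})

test_that("triu vectorisation is row-major and invertible", {
  expect_equal(triu_vectorize(matrix(c(1, 0.3, 0.3, 1), 2)), 0.3)
  M <- matrix(0, 4, 4)
  M[upper.tri(M)] <- 0  # fill explicitly below
  vals <- c(12, 13, 14, 23, 24, 34)
  k <- 0
  for (p in 1:3) for (q in (p + 1):4) {
    k <- k + 1
    M[p, q] <- M[q, p] <- vals[k]
  }
  diag(M) <- 1
  expect_equal(triu_vectorize(M), c(12, 13, 14, 23, 24, 34))

  expect_length(triu_vectorize(diag(15)), 105)
  expect_length(triu_vectorize(diag(116)), 6670)

  ## reconstruction identity for arbitrary symmetric unit-diagonal input
  set.seed(9)
  for (K in c(3, 8, 15)) {
    A <- matrix(rnorm(K * K), K)
    S <- (A + t(A)) / 2
    diag(S) <- 1
    expect_identical(untriu_vector(triu_vectorize(S), K), S)
  }
})

test_that("dfc sequences compose windows and reduce to static FC", {
  tc <- make_test_tc(n_time = 130, K = 15, seed = 4)
  plan <- plan_windows(130, 50, 1)
  fs <- dfc_sequence(tc, plan)
  expect_equal(dim(fs), c(105, 81))

  ## width = T collapses to the static vector
  plan_full <- plan_windows(130, 130, 1)
  one <- dfc_sequence(tc, plan_full)
  expect_equal(ncol(one), 1L)
  expect_equal(as.numeric(one[, 1]), as.numeric(static_fc(tc)),
               tolerance = 1e-12)

  ## static FC matches the summation oracle
  sv <- static_fc(tc)
  expect_equal(sv[1], pearson_by_sums(tc[, 1], tc[, 2]),
               tolerance = 1e-12)

  ## wider windows damp the window-to-window variance on stationary data
  tc_long <- make_test_tc(n_time = 400, K = 6, seed = 5)
  v30 <- apply(dfc_sequence(tc_long, plan_windows(400, 30, 1)), 1, var)
  v60 <- apply(dfc_sequence(tc_long, plan_windows(400, 60, 1)), 1, var)
  expect_lt(mean(v60), mean(v30))
})

test_that("ROI means average voxels within regions in label order", {
  X <- matrix(rnorm(50 * 6), 50, 6)
  ## one region covering everything = the global mean series
  g <- roi_mean_timecourses(X, rep(1L, 6))
  expect_equal(as.numeric(g), rowMeans(X))

  labels <- c(2L, 1L, 2L, 3L, 1L, 3L)
  tc <- roi_mean_timecourses(X, labels)
  expect_equal(colnames(tc), c("1", "2", "3"))
  expect_equal(tc[, "1"], (X[, 2] + X[, 5]) / 2)
  expect_equal(tc[, "2"], (X[, 1] + X[, 3]) / 2)

  expect_error(roi_mean_timecourses(X, labels, region_ids = 1:4),
               "region\\(s\\) 4")
})
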