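test_that("the cell matches hand evaluation of the gate equations", {
  ## all weights and biases zero: everything collapses to zero
  p0 <- lstm_params(2, 2, hidden = 3, fc = 2, seed = 1)
  for (nm in names(p0)) p0[[nm]] <- p0[[nm]] * 0
  st <- cell_step(p0, c(0.5, -1))
  expect_equal(st$h, matrix(0, 3, 1))
  expect_equal(st$C, matrix(0, 3, 1))

  ## zero weights, zero biases, C_prev = c: C_new = c/2, h = tanh(c/2)/2
  cprev <- c(0.4, -1.2, 2)
  st2 <- cell_step(p0, c(1, 1), prev = list(h = rep(0, 3), C = cprev))
  expect_equal(drop(st2$C), 0.5 * cprev)
  expect_equal(drop(st2$h), 0.5 * tanh(0.5 * cprev))

  ## scalar cell against the independent arithmetic oracle
  p1 <- lstm_params(1, 2, hidden = 1, fc = 1, seed = 2)
  p1$Wf[] <- c(0.3, -0.7);  p1$bf[] <- 0.1
  p1$Wi[] <- c(-0.2, 0.5);  p1$bi[] <- -0.3
  p1$Wc[] <- c(0.8, 0.4);   p1$bc[] <- 0.2
  p1$Wo[] <- c(0.1, -0.6);  p1$bo[] <- 0.4
  oracle <- scalar_cell_oracle(c(0.3, -0.7), 0.1, c(-0.2, 0.5), -0.3,
                               c(0.8, 0.4), 0.2, c(0.1, -0.6), 0.4,
                               x = 0.9, h_prev = -0.2, c_prev = 0.7)
  st3 <- cell_step(p1, 0.9, prev = list(h = -0.2, C = 0.7))
  expect_equal(drop(st3$h), oracle$h, tolerance = 1e-12)
  expect_equal(drop(st3$C), oracle$C, tolerance = 1e-12)
})

test_that("gate activations respect their ranges", {
  set.seed(4)
  p <- lstm_params(6, 2, hidden = 8, fc = 4, seed = 5)
  st <- list(h = matrix(0, 8, 20), C = matrix(0, 8, 20))
  for (t in 1:30) {
    st_new <- cell_step(p, matrix(rnorm(6 * 20, sd = 3), 6, 20),
                        prev = st)
    expect_true(all(st_new$f > 0 & st_new$f < 1))
    expect_true(all(st_new$i > 0 & st_new$i < 1))
    expect_true(all(st_new$o > 0 & st_new$o < 1))
    expect_true(all(abs(st_new$c_tilde) < 1))
    expect_true(all(abs(st_new$h) <= 1))
    st <- list(h = st_new$h, C = st_new$C)
  }
})

test_that("forward probabilities are a proper softmax", {
  p <- lstm_params(5, 3, hidden = 4, fc = 3, seed = 6)
  ## zero head: uniform probabilities
  p0 <- p
  p0$W1[] <- 0; p0$b1[] <- 0; p0$W2[] <- 0; p0$b2[] <- 0
  pr <- forward_sequence(p0, matrix(rnorm(5 * 7), 5, 7))
  expect_equal(unname(pr), rep(1 / 3, 3))

  set.seed(7)
  for (i in 1:100) {
    pr <- forward_sequence(p, matrix(rnorm(5 * 4), 5, 4))
    expect_true(all(pr >= 0))
    expect_equal(sum(pr), 1, tolerance = 1e-12)
  }
  expect_error(forward_sequence(p, matrix(numeric(0), 5, 0)),
               "empty sequence")

  ## permuting feature rows together with the matched input-weight
  ## columns leaves the output unchanged
  x <- matrix(rnorm(5 * 6), 5, 6)
  perm <- c(3, 1, 5, 2, 4)
  pp <- p
  H <- 4
  for (nm in c("Wf", "Wi", "Wc", "Wo"))
    pp[[nm]][, H + seq_len(5)] <- p[[nm]][, H + perm]
  expect_equal(forward_sequence(pp, x[perm, ]), forward_sequence(p, x),
               tolerance = 1e-12)
})

test_that("analytic gradients agree with finite differences", {
  set.seed(8)
  d <- 4; H <- 5; B <- 3
  p <- lstm_params(d, 2, hidden = H, fc = 3, seed = 9)
  X <- array(rnorm(d * 6 * B), c(d, 6, B))
  lens <- c(6L, 4L, 5L)
  y <- c(1L, 2L, 1L)
  for (ro in c("last", "mean")) {
    lg <- dfclstm:::.lstm_loss_grad(p, X, lens, y, readout = ro)
    worst <- 0
    for (nm in names(p)) {
      for (ii in seq_len(min(4, length(p[[nm]])))) {
        eps <- 1e-5
        p2 <- p
        p2[[nm]][ii] <- p2[[nm]][ii] + eps
        up <- dfclstm:::.lstm_loss_grad(p2, X, lens, y, readout = ro)$loss
        p2[[nm]][ii] <- p2[[nm]][ii] - 2 * eps
        dn <- dfclstm:::.lstm_loss_grad(p2, X, lens, y, readout = ro)$loss
        fd <- (up - dn) / (2 * eps)
        g <- lg$grads[[nm]][ii]
        worst <- max(worst, abs(fd - g) / max(1e-8, abs(fd) + abs(g)))
      }
    }
    expect_lt(worst, 1e-4)
  }
})

test_that("training fits separable sequences and is seed-deterministic", {
  set.seed(10)
  mkseq <- function(shift) {
    x <- matrix(rnorm(8 * 20), 8, 20)
    x[2, ] <- x[2, ] + shift
    x
  }
  seqs <- c(lapply(1:12, function(i) mkseq(0)),
            lapply(1:12, function(i) mkseq(2)))
  y <- factor(rep(c("ctl", "pat"), each = 12))
  m <- train_lstm(seqs, y, epochs = 150, seed = 1, min_loss = 0.02,
                  input_dropout = 0.2)
  expect_equal(mean(predict(m, seqs) == y), 1)

  m2 <- train_lstm(seqs, y, epochs = 150, seed = 1, min_loss = 0.02,
                   input_dropout = 0.2)
  expect_identical(m$params, m2$params)

  ## variable-length sequences are handled by last-valid-state readout
  seqs_var <- c(seqs[1:6], lapply(seqs[7:24], function(s)
    s[, 1:sample(10:20, 1), drop = FALSE]))
  m3 <- train_lstm(seqs_var, y, epochs = 40, seed = 2)
  expect_length(predict(m3, seqs_var), 24)

  expect_error(train_lstm(seqs[1:12], y[1:12]), "single class")
})

test_that("prediction breaks ties toward the lowest class index", {
  p <- lstm_params(3, 2, hidden = 2, fc = 2, seed = 11)
  p$W1[] <- 0; p$b1[] <- 0; p$W2[] <- 0; p$b2[] <- 0
  model <- structure(list(params = p, classes = c("a", "b"),
                          feat_mean = rep(0, 3), feat_sd = rep(1, 3),
                          readout = "last"),
                     class = "lstm_model")
  pred <- predict(model, matrix(rnorm(9), 3, 3))
  expect_equal(as.character(pred), "a")

  ## batch predict equals one-at-a-time predict
  seqs <- lapply(1:5, function(i) matrix(rnorm(3 * 4), 3, 4))
  pr_batch <- predict(model, seqs, type = "prob")
  pr_single <- do.call(rbind, lapply(seqs, function(s)
    predict(model, s, type = "prob")))
  expect_equal(pr_batch, pr_single, tolerance = 1e-12)

  expect_error(predict(model, matrix(rnorm(8), 4, 2)),
               "feature-space mismatch")
})

test_that("static baselines separate well-separated classes", {
  set.seed(12)
  x <- rbind(matrix(rnorm(30 * 10, mean = 0), 30, 10),
             matrix(rnorm(30 * 10, mean = 3), 30, 10))
  y <- factor(rep(c("A", "B"), each = 30))
  test_i <- c(1:10, 31:40)
  train_i <- setdiff(1:60, test_i)

  sv <- train_svm_baseline(x[train_i, ], y[train_i], seed = 1)
  expect_gt(mean(predict(sv, x[test_i, ]) == y[test_i]), 0.95)
  pr <- predict(sv, x[test_i, ], type = "prob")
  expect_equal(unname(rowSums(pr)), rep(1, 20), tolerance = 1e-6)

  rf <- train_rf_baseline(x[train_i, ], y[train_i], seed = 2)
  expect_gt(mean(predict(rf, x[test_i, ]) == y[test_i]), 0.95)
  rf2 <- train_rf_baseline(x[train_i, ], y[train_i], seed = 2)
  expect_identical(predict(rf, x[test_i, ], type = "prob"),
                   predict(rf2, x[test_i, ], type = "prob"))

  expect_error(train_svm_baseline(x[1:30, ], y[1:30]), "single class")
})

test_that("label-permuted static training stays near chance", {
  set.seed(13)
  x <- matrix(rnorm(60 * 20), 60, 20)
  x[31:60, 1] <- x[31:60, 1] + 3
  y_perm <- factor(sample(rep(c("A", "B"), each = 30)))  # broken labels
  folds <- stratified_kfold(y_perm, k = 5, seed = 3)
  acc <- numeric(5)
  for (f in 1:5) {
    te <- folds$folds[[f]]
    tr <- setdiff(1:60, te)
    m <- train_svm_baseline(x[tr, ], y_perm[tr], seed = f)
    acc[f] <- mean(predict(m, x[te, , drop = FALSE]) == y_perm[te])
  }
  ## 95% binomial band around chance for n = 60
  expect_gt(mean(acc), 0.5 - 1.96 * sqrt(0.25 / 60))
  expect_lt(mean(acc), 0.5 + 1.96 * sqrt(0.25 / 60))
})
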