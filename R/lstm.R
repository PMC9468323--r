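#' Initialise LSTM cell and classifier-head parameters
#'
#' The cell has four gate blocks (forget, input, candidate, output), each
#' an `H x (H + d)` weight matrix acting on the concatenation
#' `[h(t-1), x(t)]` plus a length-H bias.  The head is two fully connected
#' layers with a rectifier between them and softmax on the output.
#' Weights are drawn uniformly from `[-s, s]` with `s = 1/sqrt(H + d)`;
#' the forget-gate bias starts at 1 (the usual aid to early gradient
#' flow), all other biases at 0.
#'
#' @param d input feature dimension.
#' @param n_classes number of output classes.
#' @param hidden number of hidden cells H (default 30).
#' @param fc width of the intermediate fully connected layer (default 16).
#' @param seed integer seed.
#' @return list of class `"lstm_params"` with `Wf`, `Wi`, `Wc`, `Wo`,
#'   `bf`, `bi`, `bc`, `bo`, `W1`, `b1`, `W2`, `b2` and attributes `d`,
#'   `hidden`, `n_classes`.
#' @export
lstm_params <- function(d, n_classes, hidden = 30L, fc = 16L, seed = 0L) {
  stopifnot(d >= 1, n_classes >= 2, hidden >= 1, fc >= 1)
  H <- hidden
  s <- 1 / sqrt(H + d)
  withr::with_seed(seed, {
    rw <- function(r, c, sc) matrix(stats::runif(r * c, -sc, sc), r, c)
    p <- list(Wf = rw(H, H + d, s), Wi = rw(H, H + d, s),
              Wc = rw(H, H + d, s), Wo = rw(H, H + d, s),
              bf = rep(1, H), bi = rep(0, H), bc = rep(0, H),
              bo = rep(0, H),
              W1 = rw(fc, H, 1 / sqrt(H)), b1 = rep(0, fc),
              W2 = rw(n_classes, fc, 1 / sqrt(fc)), b2 = rep(0, n_classes))
    structure(p, d = d, hidden = H, n_classes = n_classes,
              class = "lstm_params")
  })
}

.sigmoid <- function(x) 1 / (1 + exp(-x))

#' One LSTM cell step
#'
#' Applies the gate equations of the cell to one input column (or a batch
#' of columns): forget and input gates are logistic, the candidate cell is
#' a tanh unit, the new cell state is `C(t-1) * f(t) + i(t) * Ctilde(t)`
#' elementwise, and the output is the output gate times the tanh of the
#' new cell state.
#'
#' @param params an [lstm_params()] object (head entries ignored).
#' @param x_t input: length-d vector or d x B matrix.
#' @param prev previous state, a list with `h` and `C` (each length-H
#'   vector or H x B matrix); `NULL` means the zero state.
#' @return list with `h`, `C`, and the gate activations `f`, `i`, `o`,
#'   `c_tilde`.
#' @export
cell_step <- function(params, x_t, prev = NULL) {
  H <- attr(params, "hidden")
  x_t <- as.matrix(x_t)
  if (nrow(x_t) != attr(params, "d"))
    stop("configuration error: input has ", nrow(x_t),
         " features, parameters expect ", attr(params, "d"))
  B <- ncol(x_t)
  if (is.null(prev)) prev <- list(h = matrix(0, H, B), C = matrix(0, H, B))
  h_prev <- matrix(prev$h, H, B)
  C_prev <- matrix(prev$C, H, B)
  z <- rbind(h_prev, x_t)
  f <- .sigmoid(params$Wf %*% z + params$bf)
  i <- .sigmoid(params$Wi %*% z + params$bi)
  g <- tanh(params$Wc %*% z + params$bc)
  o <- .sigmoid(params$Wo %*% z + params$bo)
  C_new <- C_prev * f + i * g
  h_new <- o * tanh(C_new)
  list(h = h_new, C = C_new, f = f, i = i, o = o, c_tilde = g)
}

#' Class probabilities for one feature sequence
#'
#' Iterates the LSTM cell over the columns of a d x w feature sequence
#' from the zero state, reads out the final hidden state (or the mean of
#' the per-step hidden states), applies the two fully connected layers
#' with the rectifier, and returns softmax probabilities.
#'
#' @param params an [lstm_params()] object.
#' @param seq d x w feature matrix (w >= 1).
#' @param readout `"last"` (final hidden state) or `"mean"` (average over
#'   steps).
#' @return named numeric vector of class probabilities (sums to 1).
#' @export
forward_sequence <- function(params, seq, readout = c("last", "mean")) {
  readout <- match.arg(readout)
  seq <- as.matrix(seq)
  if (ncol(seq) < 1L) stop("invalid input: empty sequence")
  fw <- .lstm_forward(params, array(seq, c(nrow(seq), ncol(seq), 1L)),
                      lens = ncol(seq), readout = readout)
  drop(fw$probs)
}

## Batched forward pass.  X: d x wmax x B array (padded with zeros beyond
## each sequence's length); lens: integer vector of valid lengths.
## The four gate blocks are fused into a single (4H) x (H+d) matrix so
## every step costs one GEMM.  Returns probabilities plus the cache
## needed for backpropagation.
.lstm_forward <- function(params, X, lens, readout = "last",
                          keep_cache = FALSE) {
  H <- attr(params, "hidden")
  d <- dim(X)[1L]
  wmax <- dim(X)[2L]
  B <- dim(X)[3L]
  Wall <- rbind(params$Wf, params$Wi, params$Wc, params$Wo)
  ball <- c(params$bf, params$bi, params$bc, params$bo)
  rf <- seq_len(H); ri <- H + rf; rc <- 2L * H + rf; ro <- 3L * H + rf
  h <- matrix(0, H, B)
  C <- matrix(0, H, B)
  hsum <- matrix(0, H, B)
  cache <- if (keep_cache) vector("list", wmax)
  for (t in seq_len(wmax)) {
    x_t <- matrix(X[, t, ], d, B)
    z <- rbind(h, x_t)
    pre <- Wall %*% z + ball
    f <- .sigmoid(pre[rf, , drop = FALSE])
    i <- .sigmoid(pre[ri, , drop = FALSE])
    g <- tanh(pre[rc, , drop = FALSE])
    o <- .sigmoid(pre[ro, , drop = FALSE])
    Cn <- C * f + i * g
    hn <- o * tanh(Cn)
    alive <- as.numeric(t <= lens)
    a <- matrix(alive, H, B, byrow = TRUE)
    h_new <- hn * a + h * (1 - a)
    C_new <- Cn * a + C * (1 - a)
    if (keep_cache)
      cache[[t]] <- list(z = z, f = f, i = i, o = o,
                         g = g, C_prev = C, Cn = Cn,
                         alive = alive)
    hsum <- hsum + hn * a
    h <- h_new
    C <- C_new
  }
  hL <- if (readout == "mean")
    sweep(hsum, 2, pmax(lens, 1L), "/") else h
  a1 <- params$W1 %*% hL + params$b1
  r <- pmax(a1, 0)
  logits <- params$W2 %*% r + params$b2
  lmax <- apply(logits, 2, max)
  el <- exp(sweep(logits, 2, lmax))
  probs <- sweep(el, 2, colSums(el), "/")
  list(probs = probs, hL = hL, a1 = a1, r = r, cache = cache)
}

## Cross-entropy loss and gradients for a padded batch.
## y_idx: integer class indices (1-based), length B.
.lstm_loss_grad <- function(params, X, lens, y_idx, readout = "last") {
  H <- attr(params, "hidden")
  d <- dim(X)[1L]
  wmax <- dim(X)[2L]
  B <- dim(X)[3L]
  fw <- .lstm_forward(params, X, lens, readout, keep_cache = TRUE)
  p <- fw$probs
  loss <- -mean(log(pmax(p[cbind(y_idx, seq_len(B))], 1e-12)))

  Y <- matrix(0, nrow(p), B)
  Y[cbind(y_idx, seq_len(B))] <- 1
  dlogits <- (p - Y) / B
  gW2 <- dlogits %*% t(fw$r)
  gb2 <- rowSums(dlogits)
  dr <- crossprod(params$W2, dlogits)
  da1 <- dr * (fw$a1 > 0)
  gW1 <- da1 %*% t(fw$hL)
  gb1 <- rowSums(da1)
  dhL <- crossprod(params$W1, da1)

  Wall <- rbind(params$Wf, params$Wi, params$Wc, params$Wo)
  rf <- seq_len(H); ri <- H + rf; rc <- 2L * H + rf; ro_ <- 3L * H + rf
  gWall <- matrix(0, 4L * H, H + d)
  gball <- numeric(4L * H)
  dh <- if (readout == "last") dhL else matrix(0, H, B)
  dC <- matrix(0, H, B)
  inv_len <- 1 / pmax(lens, 1L)
  dpre <- matrix(0, 4L * H, B)
  for (t in rev(seq_len(wmax))) {
    cc <- fw$cache[[t]]
    a <- matrix(cc$alive, H, B, byrow = TRUE)
    dh_t <- dh
    if (readout == "mean")
      dh_t <- dh_t + sweep(dhL, 2, inv_len, "*") * a
    dhn <- dh_t * a
    dh_carry <- dh_t * (1 - a)
    tC <- tanh(cc$Cn)
    dCn <- dC * a + dhn * cc$o * (1 - tC^2)
    dC <- dC * (1 - a) + dCn * cc$f
    dpre[rf, ] <- dCn * cc$C_prev * cc$f * (1 - cc$f)
    dpre[ri, ] <- dCn * cc$g * cc$i * (1 - cc$i)
    dpre[rc, ] <- dCn * cc$i * (1 - cc$g^2)
    dpre[ro_, ] <- dhn * tC * cc$o * (1 - cc$o)
    gWall <- gWall + dpre %*% t(cc$z)
    gball <- gball + rowSums(dpre)
    dz <- crossprod(Wall, dpre)
    dh <- dz[seq_len(H), , drop = FALSE] + dh_carry
  }
  list(loss = loss,
       grads = list(Wf = gWall[rf, , drop = FALSE],
                    Wi = gWall[ri, , drop = FALSE],
                    Wc = gWall[rc, , drop = FALSE],
                    Wo = gWall[ro_, , drop = FALSE],
                    bf = gball[rf], bi = gball[ri], bc = gball[rc],
                    bo = gball[ro_],
                    W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2))
}

## Pack a list of d x w matrices into a zero-padded d x wmax x B array.
.pack_sequences <- function(sequences) {
  d <- nrow(sequences[[1L]])
  lens <- vapply(sequences, ncol, 0L)
  wmax <- max(lens)
  X <- array(0, c(d, wmax, length(sequences)))
  for (b in seq_along(sequences))
    X[, seq_len(lens[b]), b] <- as.matrix(sequences[[b]])
  list(X = X, lens = lens)
}

#' Train the LSTM sequence classifier
#'
#' Minimises the softmax cross-entropy of the LSTM-plus-head architecture
#' over a set of dynamic-connectivity feature sequences by mini-batch
#' adaptive-moment (Adam) gradient descent with backpropagation through
#' time.  Sequences of unequal length are zero-padded and masked, with
#' the readout taken at each sequence's last valid step.  Features are
#' z-scored per dimension with statistics computed from the training set
#' only; the statistics are stored in the model and reapplied at
#' prediction time.  Training is deterministic given `seed`.
#'
#' @param sequences list of d x w feature matrices (w may vary).
#' @param labels factor (or vector) of class labels, one per sequence;
#'   at least two classes must be present.
#' @param hidden,fc architecture sizes (defaults 30 and 16).
#' @param lr Adam learning rate (default 1e-3).
#' @param epochs maximum training epochs (default 200).
#' @param batch_size mini-batch size (default 16).
#' @param patience epochs without loss improvement before early stop
#'   (default 25).
#' @param min_loss stop once the epoch cross-entropy falls below this
#'   value (default 0.05; training far past separation only memorises
#'   the training sequences).
#' @param weight_decay decoupled L2 penalty applied to the weight
#'   matrices (not biases) at each update (default 0).
#' @param input_dropout probability of dropping each input feature
#'   during training (default 0.4).  One mask per sequence per batch,
#'   shared across time steps (the variational convention, appropriate
#'   for heavily overlapping windows whose noise is temporally
#'   persistent); inputs are rescaled by `1/(1-p)` and dropout is off at
#'   prediction time.
#' @param feature_weight `"tstat"` (default) scales each standardised
#'   feature by its training-set group discriminability: for each
#'   feature, the absolute Welch t statistic (two classes) or the
#'   square root of the one-way F statistic (more classes) is computed
#'   for the two canonical subject-level summaries of a windowed
#'   feature — its mean level and its window-to-window standard
#'   deviation — and the larger of the two is kept, normalised to unit
#'   root-mean-square over features.  Connectivity sequences carry a
#'   handful of informative pairs among many noise pairs, informative
#'   either in level (state-independent effects) or in variability
#'   (state-confined effects); relevance weighting lets the gates
#'   concentrate on them while remaining leakage-free (statistics come
#'   from the training fold only, stored in the model, reapplied at
#'   prediction).  `"none"` disables it.
#' @param valid_frac fraction of the training sequences (stratified,
#'   seeded) held out as an internal validation set (default 0.2).
#'   Validation cross-entropy is monitored every epoch, `patience`
#'   applies to it, and the parameters of the best validation epoch are
#'   restored — gradient training on small cohorts otherwise runs past
#'   its generalisation peak.  Set to 0 to monitor training loss
#'   instead.
#' @param n_models ensemble size (default 1).  With `n_models > 1`,
#'   independent models are trained from different random
#'   initialisations (seeds `seed, seed + 1, ...`) and their predicted
#'   probabilities averaged — the standard remedy for the run-to-run
#'   variability of small-sample gradient training.
#' @param readout `"last"` or `"mean"` hidden-state readout.
#' @param standardize z-score features using training-set statistics
#'   (default TRUE).
#' @param seed integer seed controlling initialisation and batching.
#' @param verbose print per-epoch loss.
#' @return object of class `"lstm_model"`: `params`, `classes`,
#'   `feat_mean`, `feat_sd`, `readout`, `loss_history`, `config`.
#' @export
train_lstm <- function(sequences, labels, hidden = 30L, fc = 16L,
                       lr = 1e-3, epochs = 200L, batch_size = 16L,
                       patience = 25L, min_loss = 0.05,
                       weight_decay = 0, input_dropout = 0.4,
                       feature_weight = c("tstat", "none"),
                       valid_frac = 0.2, n_models = 1L,
                       readout = c("last", "mean"),
                       standardize = TRUE, seed = 1L, verbose = FALSE) {
  readout <- match.arg(readout)
  feature_weight <- match.arg(feature_weight)
  if (n_models > 1L) {
    members <- lapply(seq_len(n_models) - 1L, function(j)
      train_lstm(sequences, labels, hidden = hidden, fc = fc, lr = lr,
                 epochs = epochs, batch_size = batch_size,
                 patience = patience, min_loss = min_loss,
                 weight_decay = weight_decay,
                 input_dropout = input_dropout,
                 feature_weight = feature_weight,
                 valid_frac = valid_frac, n_models = 1L,
                 readout = readout, standardize = standardize,
                 seed = seed + j, verbose = verbose))
    return(structure(list(members = members,
                          classes = members[[1L]]$classes,
                          feat_mean = members[[1L]]$feat_mean,
                          feat_sd = members[[1L]]$feat_sd),
                     class = c("lstm_ensemble", "lstm_model")))
  }
  labels <- droplevels(as.factor(labels))
  stopifnot(length(sequences) == length(labels), epochs >= 1)
  if (nlevels(labels) < 2L)
    stop("degenerate labels: training set contains a single class")
  d <- nrow(sequences[[1L]])
  y_idx <- as.integer(labels)

  if (standardize) {
    all_cols <- do.call(cbind, lapply(sequences, as.matrix))
    feat_mean <- rowMeans(all_cols)
    feat_sd <- apply(all_cols, 1, stats::sd)
    feat_sd[feat_sd < 1e-12] <- 1
    sequences <- lapply(sequences, function(s) (s - feat_mean) / feat_sd)
  } else {
    feat_mean <- rep(0, d)
    feat_sd <- rep(1, d)
  }

  feat_weight <- rep(1, d)
  if (feature_weight == "tstat") {
    idx_by_class <- split(seq_along(labels), labels)
    group_stat <- function(summ) {   # summ: subjects x d
      if (nlevels(labels) == 2L) {
        a <- summ[idx_by_class[[1L]], , drop = FALSE]
        b <- summ[idx_by_class[[2L]], , drop = FALSE]
        va <- apply(a, 2, stats::var) / nrow(a)
        vb <- apply(b, 2, stats::var) / nrow(b)
        abs(colMeans(a) - colMeans(b)) / sqrt(va + vb)
      } else {
        gm <- colMeans(summ)
        ssb <- 0
        ssw <- 0
        for (ii in idx_by_class) {
          g <- summ[ii, , drop = FALSE]
          ssb <- ssb + nrow(g) * (colMeans(g) - gm)^2
          ssw <- ssw + colSums(sweep(g, 2, colMeans(g))^2)
        }
        msb <- ssb / (nlevels(labels) - 1L)
        msw <- ssw / (nrow(summ) - nlevels(labels))
        sqrt(msb / msw)
      }
    }
    sm <- t(vapply(sequences, rowMeans, numeric(d)))
    sv <- t(vapply(sequences, function(s) apply(s, 1, stats::sd),
                   numeric(d)))
    stat <- pmax(group_stat(sm), group_stat(sv))
    stat[!is.finite(stat)] <- 0
    rms <- sqrt(mean(stat^2))
    if (rms > 0) feat_weight <- stat / rms
    sequences <- lapply(sequences, function(s) s * feat_weight)
  }
  pk <- .pack_sequences(sequences)
  n <- length(sequences)

  params <- lstm_params(d, nlevels(labels), hidden, fc, seed = seed)
  m <- lapply(params, function(x) x * 0)
  v <- lapply(params, function(x) x * 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  step <- 0L
  loss_history <- numeric(0)
  val_history <- numeric(0)

  val_loss_of <- function(p, idx) {
    fw <- .lstm_forward(p, pk$X[, , idx, drop = FALSE], pk$lens[idx],
                        readout)
    -mean(log(pmax(fw$probs[cbind(y_idx[idx], seq_along(idx))], 1e-12)))
  }

  withr::with_seed(seed + 1L, {
    ## stratified internal validation split, if feasible
    val_idx <- integer(0)
    if (valid_frac > 0) {
      for (cl in seq_len(nlevels(labels))) {
        members <- which(y_idx == cl)
        n_val <- floor(length(members) * valid_frac)
        if (n_val >= 1 && length(members) - n_val >= 2)
          val_idx <- c(val_idx, sample(members, n_val))
      }
      if (length(val_idx) < 2 ||
          length(unique(y_idx[val_idx])) < nlevels(labels))
        val_idx <- integer(0)
    }
    fit_idx <- setdiff(seq_len(n), val_idx)
    monitor_val <- length(val_idx) > 0

    best <- Inf
    best_params <- params
    stall <- 0L
    for (ep in seq_len(epochs)) {
      ord <- sample(fit_idx)
      ep_loss <- 0
      nb <- 0L
      for (start in seq(1L, length(ord), by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1L, length(ord))]
        Xb <- pk$X[, , idx, drop = FALSE]
        if (input_dropout > 0) {
          keep <- array(stats::rbinom(d * length(idx), 1,
                                      1 - input_dropout) /
                          (1 - input_dropout),
                        c(d, 1L, length(idx)))
          Xb <- Xb * keep[, rep(1L, dim(Xb)[2L]), , drop = FALSE]
        }
        lg <- .lstm_loss_grad(params, Xb,
                              pk$lens[idx], y_idx[idx], readout)
        step <- step + 1L
        for (nm in names(params)) {
          g <- lg$grads[[nm]]
          m[[nm]] <- beta1 * m[[nm]] + (1 - beta1) * g
          v[[nm]] <- beta2 * v[[nm]] + (1 - beta2) * g^2
          mhat <- m[[nm]] / (1 - beta1^step)
          vhat <- v[[nm]] / (1 - beta2^step)
          params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
          if (weight_decay > 0 && startsWith(nm, "W"))
            params[[nm]] <- params[[nm]] * (1 - lr * weight_decay)
        }
        ep_loss <- ep_loss + lg$loss
        nb <- nb + 1L
      }
      ep_loss <- ep_loss / nb
      loss_history <- c(loss_history, ep_loss)
      crit <- if (monitor_val) val_loss_of(params, val_idx) else ep_loss
      if (monitor_val) val_history <- c(val_history, crit)
      if (verbose)
        message(sprintf("epoch %3d  loss %.5f  monitor %.5f", ep,
                        ep_loss, crit))
      if (crit < best - 1e-5) {
        best <- crit
        best_params <- params
        stall <- 0L
      } else {
        stall <- stall + 1L
      }
      if (stall >= patience || ep_loss < min_loss) break
    }
    params <- best_params
  })

  structure(list(params = params, classes = levels(labels),
                 feat_mean = feat_mean, feat_sd = feat_sd,
                 feat_weight = feat_weight,
                 readout = readout, loss_history = loss_history,
                 val_history = val_history,
                 config = list(hidden = hidden, fc = fc, lr = lr,
                               epochs = epochs, batch_size = batch_size,
                               patience = patience,
                               valid_frac = valid_frac, seed = seed)),
            class = "lstm_model")
}

#' Predict classes for feature sequences
#'
#' @param object an [train_lstm()] model.
#' @param newdata one d x w matrix or a list of them.
#' @param type `"class"` or `"prob"`.
#' @param ... unused.
#' @return factor of predicted classes (ties broken toward the lowest
#'   class index) or an n x n_classes probability matrix.
#' @export
predict.lstm_model <- function(object, newdata, type = c("class", "prob"),
                               ...) {
  type <- match.arg(type)
  if (inherits(object, "lstm_ensemble")) {
    probs <- Reduce(`+`, lapply(object$members, predict,
                                newdata = newdata, type = "prob")) /
      length(object$members)
    if (type == "prob") return(probs)
    return(factor(object$classes[max.col(probs, ties.method = "first")],
                  levels = object$classes))
  }
  if (is.matrix(newdata)) newdata <- list(newdata)
  d <- length(object$feat_mean)
  bad <- vapply(newdata, nrow, 0L) != d
  if (any(bad))
    stop("feature-space mismatch: sequences have ",
         paste(unique(vapply(newdata[bad], nrow, 0L)), collapse = "/"),
         " features, model expects ", d)
  fw <- object$feat_weight %||% rep(1, d)
  newdata <- lapply(newdata, function(s)
    ((as.matrix(s) - object$feat_mean) / object$feat_sd) * fw)
  pk <- .pack_sequences(newdata)
  fw <- .lstm_forward(object$params, pk$X, pk$lens, object$readout)
  probs <- t(fw$probs)
  colnames(probs) <- object$classes
  if (type == "prob") return(probs)
  factor(object$classes[max.col(probs, ties.method = "first")],
         levels = object$classes)
}

#' @export
print.lstm_model <- function(x, ...) {
  cat("LSTM sequence classifier:", length(x$feat_mean), "features,",
      x$config$hidden, "hidden cells,", length(x$classes), "classes;",
      length(x$loss_history), "epochs, final loss",
      sprintf("%.4f\n", utils::tail(x$loss_history, 1)))
  invisible(x)
}
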