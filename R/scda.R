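#' Architecture configuration for the sparse convolutional denoising
#' autoencoder
#'
#' The model is a 1-D convolutional autoencoder over the marker axis. The
#' seven-layer variant stacks six convolutions in an hourglass:
#' `conv(32) -> maxpool -> conv(64) -> maxpool -> conv(128) -> conv(128) ->
#' upsample -> conv(64) -> upsample -> conv(C, softmax)`, where `C` is the
#' number of genotype classes; the five-layer variant uses hidden kernel
#' counts (32, 64, 32) with a single pool/upsample pair. Every convolution
#' uses the same odd filter size, 'same' zero padding, and carries an L1
#' penalty `lambda * sum(|w|)` on its filter weights (biases excluded),
#' which drives many weights toward zero and keeps the model sparse.
#' Dropout is applied after each maxpooling stage during training.
#'
#' @param kernel_counts integer vector of hidden-layer kernel counts; the
#'   final layer always has `n_classes` kernels with a softmax over class
#'   channels. Defaults: `c(32, 64, 128, 128, 64)` for `seven_layer`,
#'   `c(32, 64, 32)` for `five_layer`.
#' @param filter_size odd convolution filter length >= 3; 5 is the default
#'   (the best-performing size in the 3..19 sweep).
#' @param l1_lambda L1 penalty weight, default `1e-4`.
#' @param dropout_p dropout (removal) probability in `[0, 1)`, default 0.25.
#' @param pool_size maxpool/upsample factor; fixed at 2.
#' @param hidden_activation `"relu"` (default) or `"sigmoid"` for hidden
#'   convolutions.
#' @param depth_variant `"seven_layer"` (default) or `"five_layer"`.
#' @return an object of class `scda_config`.
#' @export
scda_config <- function(kernel_counts = NULL, filter_size = 5L,
                        l1_lambda = 1e-4, dropout_p = 0.25, pool_size = 2L,
                        hidden_activation = c("relu", "sigmoid"),
                        depth_variant = c("seven_layer", "five_layer")) {
  depth_variant <- match.arg(depth_variant)
  hidden_activation <- match.arg(hidden_activation)
  if (is.null(kernel_counts))
    kernel_counts <- switch(depth_variant,
                            seven_layer = c(32L, 64L, 128L, 128L, 64L),
                            five_layer = c(32L, 64L, 32L))
  kernel_counts <- as.integer(kernel_counts)
  n_hidden <- switch(depth_variant, seven_layer = 5L, five_layer = 3L)
  if (length(kernel_counts) != n_hidden || any(kernel_counts < 1L))
    stop(sprintf("%s needs %d positive hidden kernel counts",
                 depth_variant, n_hidden))
  filter_size <- as.integer(filter_size)
  if (filter_size < 3L || filter_size %% 2L == 0L)
    stop("filter_size must be an odd integer >= 3")
  if (l1_lambda < 0) stop("l1_lambda must be >= 0")
  if (dropout_p < 0 || dropout_p >= 1) stop("dropout_p must be in [0, 1)")
  if (pool_size != 2L) stop("pool_size is fixed at 2")
  structure(
    list(kernel_counts = kernel_counts, filter_size = filter_size,
         l1_lambda = l1_lambda, dropout_p = dropout_p,
         pool_size = as.integer(pool_size),
         hidden_activation = hidden_activation,
         depth_variant = depth_variant),
    class = "scda_config")
}

#' Training configuration
#'
#' @param batch_size mini-batch size, default 32.
#' @param max_epochs maximum training epochs, default 1000 (early stopping
#'   usually halts far sooner).
#' @param learning_rate Adam step size, default 1e-3.
#' @param early_stop_patience epochs without validation-loss improvement
#'   before stopping (best-validation weights are restored), default 20.
#' @param optimizer only `"adam"` is implemented.
#' @param seed integer seed controlling shuffling and dropout.
#' @param verbose print one line per epoch.
#' @return an object of class `train_config`.
#' @export
train_config <- function(batch_size = 32L, max_epochs = 1000L,
                         learning_rate = 1e-3, early_stop_patience = 20L,
                         optimizer = "adam", seed = 1L, verbose = FALSE) {
  if (batch_size < 1L) stop("batch_size must be >= 1")
  if (max_epochs < 1L) stop("max_epochs must be >= 1")
  if (!identical(optimizer, "adam")) stop("only the adam optimizer is implemented")
  structure(
    list(batch_size = as.integer(batch_size),
         max_epochs = as.integer(max_epochs),
         learning_rate = learning_rate,
         early_stop_patience = as.integer(early_stop_patience),
         optimizer = optimizer, seed = as.integer(seed), verbose = verbose),
    class = "train_config")
}

# ---- convolution primitives ------------------------------------------------

# Stack shifted copies of A (rows = positions x samples, sample-major blocks
# of length L) so that convolution becomes one matrix product. Column block
# s in 1..k holds A shifted by u = s - (k+1)/2, zero-filled at sample
# boundaries; within a block the input channels are contiguous.
im2col <- function(A, L, B, k) {
  n <- nrow(A)
  C <- ncol(A)
  h <- (k - 1L) %/% 2L
  out <- matrix(0, n, k * C)
  pos <- rep.int(seq_len(L), B)
  for (s in seq_len(k)) {
    u <- s - h - 1L
    if (u == 0L) {
      out[, ((s - 1L) * C + 1L):(s * C)] <- A
    } else {
      rows <- which(pos + u >= 1L & pos + u <= L)
      out[rows, ((s - 1L) * C + 1L):(s * C)] <- A[rows + u, , drop = FALSE]
    }
  }
  out
}

# Adjoint of im2col: scatter-add column blocks back onto the input rows.
col2im <- function(dXcol, L, B, k, C) {
  n <- nrow(dXcol)
  h <- (k - 1L) %/% 2L
  dA <- matrix(0, n, C)
  pos <- rep.int(seq_len(L), B)
  for (s in seq_len(k)) {
    u <- s - h - 1L
    blk <- dXcol[, ((s - 1L) * C + 1L):(s * C), drop = FALSE]
    if (u == 0L) {
      dA <- dA + blk
    } else {
      rows <- which(pos + u >= 1L & pos + u <= L)
      dA[rows + u, ] <- dA[rows + u, , drop = FALSE] + blk[rows, , drop = FALSE]
    }
  }
  dA
}

#' 'Same'-padded 1-D multichannel convolution
#'
#' Computes, for every position `i` of the input sequence,
#' `out[i, m] = act(sum_u sum_d F[u, d, m] * in[i + u - (k+1)/2, d] + b[m])`
#' with zero padding outside the sequence, so the output length equals the
#' input length. This is the discrete convolution each network layer
#' applies, exposed directly so it can be checked against a brute-force
#' evaluation.
#'
#' @param input numeric matrix `[len, D]`: a length-`len` sequence with `D`
#'   channels.
#' @param filters numeric array `[k, D, n]` of `n` filters of odd length `k`.
#' @param biases numeric vector of length `n`.
#' @param activation function applied elementwise (default identity).
#' @return numeric matrix `[len, n]`.
#' @export
conv1d_same <- function(input, filters, biases = NULL,
                        activation = identity) {
  input <- as.matrix(input)
  stopifnot(is.array(filters), length(dim(filters)) == 3L)
  k <- dim(filters)[1L]
  D <- dim(filters)[2L]
  n <- dim(filters)[3L]
  if (k %% 2L == 0L) stop("filter length k must be odd")
  if (ncol(input) != D) stop("input channel count does not match filters")
  if (is.null(biases)) biases <- numeric(n)
  stopifnot(length(biases) == n)
  # weight matrix row order must match im2col blocks: channel fastest
  W <- matrix(aperm(filters, c(2L, 1L, 3L)), nrow = k * D, ncol = n)
  Z <- im2col(input, nrow(input), 1L, k) %*% W
  Z <- Z + rep(biases, each = nrow(Z))
  activation(Z)
}

# ---- model construction ----------------------------------------------------

#' Build an untrained SCDA model
#'
#' Assembles the layer plan for the configured depth variant and initializes
#' convolution weights (He-normal) reproducibly from `seed`. Input sequences
#' are zero-padded internally to a multiple of 4 (seven-layer; 2 for
#' five-layer) so the two pool/upsample stages invert exactly, and cropped
#' back on output; the pad region never contributes to the loss.
#'
#' @param config an [scda_config()].
#' @param n_markers input sequence length (>= 4).
#' @param n_classes number of genotype classes (output channels).
#' @param seed integer seed for weight initialization.
#' @return an object of class `scda_model`.
#' @export
build_scda <- function(config = scda_config(), n_markers, n_classes,
                       seed = 1L) {
  stopifnot(inherits(config, "scda_config"))
  if (n_markers < 4L) stop("n_markers must be >= 4")
  if (n_classes < 2L) stop("n_classes must be >= 2")
  kc <- config$kernel_counts
  hid <- config$hidden_activation
  if (config$depth_variant == "seven_layer") {
    plan <- list(
      list(type = "conv", layer = 1L, activation = hid),
      list(type = "pool"), list(type = "drop"),
      list(type = "conv", layer = 2L, activation = hid),
      list(type = "pool"), list(type = "drop"),
      list(type = "conv", layer = 3L, activation = hid),
      list(type = "conv", layer = 4L, activation = hid),
      list(type = "up"),
      list(type = "conv", layer = 5L, activation = hid),
      list(type = "up"),
      list(type = "conv", layer = 6L, activation = "softmax"))
    chain <- c(n_classes, kc, n_classes)
    pad_multiple <- 4L
  } else {
    plan <- list(
      list(type = "conv", layer = 1L, activation = hid),
      list(type = "pool"), list(type = "drop"),
      list(type = "conv", layer = 2L, activation = hid),
      list(type = "conv", layer = 3L, activation = hid),
      list(type = "up"),
      list(type = "conv", layer = 4L, activation = "softmax"))
    chain <- c(n_classes, kc, n_classes)
    pad_multiple <- 2L
  }
  k <- config$filter_size
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  layers <- vector("list", length(chain) - 1L)
  for (l in seq_along(layers)) {
    fan_in <- k * chain[l]
    layers[[l]] <- list(
      W = matrix(stats::rnorm(fan_in * chain[l + 1L], 0,
                              sqrt(2 / fan_in)),
                 nrow = fan_in, ncol = chain[l + 1L]),
      b = numeric(chain[l + 1L]),
      in_ch = chain[l], out_ch = chain[l + 1L])
  }
  L_pad <- as.integer(ceiling(n_markers / pad_multiple) * pad_multiple)
  structure(
    list(config = config, plan = plan, layers = layers,
         n_markers = as.integer(n_markers), n_classes = as.integer(n_classes),
         pad_multiple = pad_multiple, L_pad = L_pad,
         history = NULL, trained = FALSE),
    class = "scda_model")
}

#' Number of trainable parameters of an SCDA model
#'
#' Equals `sum over conv layers of (k * in_ch * out_ch + out_ch)`.
#'
#' @param model an `scda_model`.
#' @return integer parameter count.
#' @export
scda_parameter_count <- function(model) {
  stopifnot(inherits(model, "scda_model"))
  sum(vapply(model$layers, function(l) length(l$W) + length(l$b), numeric(1)))
}

#' @export
print.scda_model <- function(x, ...) {
  cat(sprintf(
    "scda_model (%s, k=%d): %d markers, %d classes, %d parameters%s\n",
    x$config$depth_variant, x$config$filter_size, x$n_markers, x$n_classes,
    scda_parameter_count(x),
    if (x$trained) sprintf(", trained (%d epochs)", nrow(x$history)) else
      ", untrained"))
  invisible(x)
}

#' L1 penalty of the model's convolution weights
#'
#' `lambda * sum(|w|)` over all convolution filter weights; biases are
#' excluded. Added to the reconstruction loss during training, this penalty
#' shrinks small weights toward zero.
#'
#' @param model an `scda_model`.
#' @param lambda penalty weight (defaults to the model's configured value).
#' @return the penalty value.
#' @export
l1_penalty <- function(model, lambda = model$config$l1_lambda) {
  stopifnot(inherits(model, "scda_model"), lambda >= 0)
  lambda * sum(vapply(model$layers, function(l) sum(abs(l$W)), numeric(1)))
}

#' Mean categorical cross-entropy reconstruction loss
#'
#' `mean(-log p[target class])` over all entries whose target class is
#' non-missing (code > 0); missing targets are excluded. Probabilities are
#' clipped at 1e-12 before the log.
#'
#' @param probabilities array `[n_samples, n_markers, n_classes]` of class
#'   probabilities (rows should sum to 1).
#' @param target a [genotype_matrix] or integer class matrix (0 = missing).
#' @return mean cross-entropy over scored entries.
#' @export
reconstruction_loss <- function(probabilities, target) {
  if (inherits(target, "genotype_matrix")) target <- target$values
  d <- dim(probabilities)
  stopifnot(length(d) == 3L, all(dim(target) == d[1:2]))
  idx <- which(target > 0L)
  if (!length(idx)) stop("target has no observed entries to score")
  rc <- arrayInd(idx, d[1:2])
  p <- probabilities[cbind(rc[, 1L], rc[, 2L], target[idx])]
  if (any(p < 1e-12)) p <- pmax(p, 1e-12)
  mean(-log(p))
}

# ---- forward / backward ----------------------------------------------------

# One-hot stack for a batch: rows = L_pad positions x B samples
# (sample-major), columns = class channels. Pad positions stay all-zero.
stack_onehot <- function(vals, L_pad, n_classes) {
  B <- nrow(vals)
  L0 <- ncol(vals)
  v <- matrix(0L, L_pad, B)
  v[seq_len(L0), ] <- t(vals)
  flat <- as.integer(v)
  X <- matrix(0, L_pad * B, n_classes)
  for (c in seq_len(n_classes)) {
    w <- which(flat == c)
    if (length(w)) X[w, c] <- 1
  }
  list(X = X, flat_classes = flat)
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1L, max)
  E <- exp(Z)
  E / rowSums(E)
}

scda_forward <- function(model, X, B, training = FALSE,
                         dropout_p = model$config$dropout_p) {
  A <- X
  caches <- vector("list", length(model$plan))
  for (i in seq_along(model$plan)) {
    op <- model$plan[[i]]
    if (op$type == "conv") {
      ly <- model$layers[[op$layer]]
      L <- nrow(A) %/% B
      k <- model$config$filter_size
      Xin <- A
      Z <- im2col(A, L, B, k) %*% ly$W
      Z <- Z + rep(ly$b, each = nrow(Z))
      A <- switch(op$activation,
                  relu = { Z[Z < 0] <- 0; Z },
                  sigmoid = 1 / (1 + exp(-Z)),
                  softmax = softmax_rows(Z))
      caches[[i]] <- list(input = Xin, output = A, L = L)
    } else if (op$type == "pool") {
      n <- nrow(A)
      odd <- seq.int(1L, n, 2L)
      A1 <- A[odd, , drop = FALSE]
      A2 <- A[odd + 1L, , drop = FALSE]
      M <- A1 >= A2
      A <- pmax(A1, A2)
      caches[[i]] <- list(mask = M)
    } else if (op$type == "drop") {
      if (training && dropout_p > 0) {
        keep <- matrix(stats::rbinom(length(A), 1L, 1 - dropout_p),
                       nrow(A), ncol(A)) / (1 - dropout_p)
        A <- A * keep
        caches[[i]] <- list(keep = keep)
      }
    } else if (op$type == "up") {
      A <- A[rep(seq_len(nrow(A)), each = 2L), , drop = FALSE]
    }
  }
  list(probs = A, caches = caches)
}

# Backward pass from dZ of the final (softmax) conv layer; returns per-layer
# weight and bias gradients. `fw` is the forward cache.
scda_backward <- function(model, fw, dZ_last, B) {
  k <- model$config$filter_size
  nl <- length(model$layers)
  gW <- vector("list", nl)
  gb <- vector("list", nl)
  grad <- NULL  # gradient wrt current op's output while walking backwards
  for (i in rev(seq_along(model$plan))) {
    op <- model$plan[[i]]
    if (op$type == "conv") {
      cache <- fw$caches[[i]]
      ly <- model$layers[[op$layer]]
      dZ <- if (op$activation == "softmax") dZ_last
            else if (op$activation == "relu") grad * (cache$output > 0)
            else grad * cache$output * (1 - cache$output)
      Xcol <- im2col(cache$input, cache$L, B, k)
      gW[[op$layer]] <- crossprod(Xcol, dZ)
      gb[[op$layer]] <- colSums(dZ)
      grad <- col2im(dZ %*% t(ly$W), cache$L, B, k, ly$in_ch)
    } else if (op$type == "pool") {
      M <- fw$caches[[i]]$mask
      n2 <- 2L * nrow(grad)
      dA <- matrix(0, n2, ncol(grad))
      odd <- seq.int(1L, n2, 2L)
      dA[odd, ] <- grad * M
      dA[odd + 1L, ] <- grad * !M
      grad <- dA
    } else if (op$type == "drop") {
      if (!is.null(fw$caches[[i]])) grad <- grad * fw$caches[[i]]$keep
    } else if (op$type == "up") {
      n <- nrow(grad)
      odd <- seq.int(1L, n, 2L)
      grad <- grad[odd, , drop = FALSE] + grad[odd + 1L, , drop = FALSE]
    }
  }
  list(gW = gW, gb = gb)
}

# Cross-entropy loss and softmax-input gradient for one batch.
# flat_classes: target class per stacked row (0 = missing or pad; excluded).
batch_loss_grad <- function(probs, flat_classes, n_classes) {
  counted <- which(flat_classes > 0L)
  n_c <- length(counted)
  Y <- matrix(0, nrow(probs), n_classes)
  Y[cbind(counted, flat_classes[counted])] <- 1
  p_true <- probs[cbind(counted, flat_classes[counted])]
  loss <- -sum(log(pmax(p_true, 1e-12))) / n_c
  dZ <- probs - Y
  uncounted <- flat_classes <= 0L
  if (any(uncounted)) dZ[uncounted, ] <- 0
  list(loss = loss, dZ = dZ / n_c, n = n_c)
}

# ---- training --------------------------------------------------------------

#' Train an SCDA model on corrupted/target genotype pairs
#'
#' Denoising setup: the network input is the corrupted matrix (masked
#' entries as all-zero one-hot vectors) and the target is the uncorrupted
#' matrix; the objective is the mean categorical cross-entropy over all
#' non-missing target entries plus the L1 penalty on convolution weights.
#' Optimized with Adam on shuffled mini-batches; training stops early when
#' the validation loss has not improved for `early_stop_patience` epochs and
#' the best-validation weights are restored.
#'
#' @param model an untrained (or previously trained) `scda_model`.
#' @param train_corrupt,train_target corrupted and clean training
#'   [genotype_matrix] objects of identical shape.
#' @param val_corrupt,val_target corrupted and clean validation matrices.
#' @param tcfg a [train_config()].
#' @return the trained `scda_model`; `$history` holds per-epoch
#'   `train_loss` (cross-entropy), `penalty`, `val_loss` and
#'   `val_masked_accuracy`.
#' @export
scda_train <- function(model, train_corrupt, train_target,
                       val_corrupt, val_target, tcfg = train_config()) {
  stopifnot(inherits(model, "scda_model"), inherits(tcfg, "train_config"))
  stopifnot(all(dim(train_corrupt$values) == dim(train_target$values)),
            all(dim(val_corrupt$values) == dim(val_target$values)),
            ncol(train_corrupt$values) == model$n_markers)
  C <- model$n_classes
  L_pad <- model$L_pad
  lambda <- model$config$l1_lambda
  lr <- tcfg$learning_rate
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8

  old <- local_seed(tcfg$seed)
  on.exit(restore_seed(old))

  nl <- length(model$layers)
  mW <- lapply(model$layers, function(l) l$W * 0)
  vW <- mW
  mb <- lapply(model$layers, function(l) l$b * 0)
  vb <- mb
  t_step <- 0L

  n_train <- nrow(train_corrupt$values)
  # validation coordinates for masked-entry accuracy: corrupted 0, truth > 0
  val_missing <- which(val_corrupt$values == 0L & val_target$values > 0L)

  hist <- list()
  best_val <- Inf
  best_layers <- model$layers
  stall <- 0L
  for (epoch in seq_len(tcfg$max_epochs)) {
    ord <- sample.int(n_train)
    batches <- split(ord, ceiling(seq_along(ord) / tcfg$batch_size))
    ep_loss <- 0; ep_n <- 0
    for (bi in batches) {
      B <- length(bi)
      xin <- stack_onehot(train_corrupt$values[bi, , drop = FALSE], L_pad, C)
      tgt <- stack_onehot(train_target$values[bi, , drop = FALSE], L_pad, C)
      fw <- scda_forward(model, xin$X, B, training = TRUE)
      lg <- batch_loss_grad(fw$probs, tgt$flat_classes, C)
      if (!is.finite(lg$loss))
        stop(sprintf("non-finite training loss at epoch %d; lower the learning rate",
                     epoch))
      ep_loss <- ep_loss + lg$loss * lg$n
      ep_n <- ep_n + lg$n
      gr <- scda_backward(model, fw, lg$dZ, B)
      t_step <- t_step + 1L
      corr1 <- 1 - beta1^t_step
      corr2 <- 1 - beta2^t_step
      for (l in seq_len(nl)) {
        # Adam step on the cross-entropy gradient, then the proximal
        # operator of the L1 penalty under Adam's diagonal metric
        # (soft-thresholding): small weights land exactly at zero, giving
        # the sparse filters the penalty is meant to produce.
        g <- gr$gW[[l]]
        mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * g
        vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * g * g
        denom <- sqrt(vW[[l]] / corr2) + eps
        W <- model$layers[[l]]$W - lr * (mW[[l]] / corr1) / denom
        if (lambda > 0) {
          thr <- lr * lambda / denom
          W <- sign(W) * pmax(abs(W) - thr, 0)
        }
        model$layers[[l]]$W <- W
        g <- gr$gb[[l]]
        mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * g
        vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * g * g
        model$layers[[l]]$b <- model$layers[[l]]$b -
          lr * (mb[[l]] / corr1) / (sqrt(vb[[l]] / corr2) + eps)
      }
    }
    val <- scda_evaluate(model, val_corrupt, val_target, tcfg$batch_size,
                         val_missing)
    hist[[epoch]] <- c(train_loss = ep_loss / ep_n,
                       penalty = l1_penalty(model),
                       val_loss = val$loss,
                       val_masked_accuracy = val$masked_accuracy)
    if (tcfg$verbose)
      message(sprintf(
        "epoch %3d  train_ce %.5f  penalty %.5f  val_ce %.5f  val_acc %s",
        epoch, ep_loss / ep_n, l1_penalty(model), val$loss,
        ifelse(is.na(val$masked_accuracy), "NA",
               sprintf("%.4f", val$masked_accuracy))))
    if (val$loss < best_val - 1e-7) {
      best_val <- val$loss
      best_layers <- model$layers
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= tcfg$early_stop_patience) break
    }
  }
  model$layers <- best_layers
  model$history <- as.data.frame(do.call(rbind, hist))
  model$history$epoch <- seq_len(nrow(model$history))
  model$trained <- TRUE
  model
}

# Validation-set cross-entropy (and masked accuracy) in inference mode.
scda_evaluate <- function(model, corrupt, target, batch_size, missing_idx) {
  C <- model$n_classes
  n <- nrow(corrupt$values)
  total <- 0; total_n <- 0; hits <- 0L
  rows_of <- arrayInd(missing_idx, dim(corrupt$values))
  for (start in seq(1L, n, by = batch_size)) {
    bi <- start:min(start + batch_size - 1L, n)
    B <- length(bi)
    xin <- stack_onehot(corrupt$values[bi, , drop = FALSE], model$L_pad, C)
    tgt <- stack_onehot(target$values[bi, , drop = FALSE], model$L_pad, C)
    fw <- scda_forward(model, xin$X, B, training = FALSE)
    lg <- batch_loss_grad(fw$probs, tgt$flat_classes, C)
    total <- total + lg$loss * lg$n
    total_n <- total_n + lg$n
    if (length(missing_idx)) {
      sel <- which(rows_of[, 1L] %in% bi)
      if (length(sel)) {
        srow <- match(rows_of[sel, 1L], bi)
        flat_rows <- (srow - 1L) * model$L_pad + rows_of[sel, 2L]
        pred <- max.col(fw$probs[flat_rows, , drop = FALSE],
                        ties.method = "first")
        hits <- hits + sum(pred == target$values[missing_idx[sel]])
      }
    }
  }
  list(loss = total / total_n,
       masked_accuracy = if (length(missing_idx))
         hits / length(missing_idx) else NA_real_)
}

#' Impute missing genotypes with a trained SCDA model
#'
#' Runs the network on the corrupted matrix and fills every missing entry
#' (code 0) with the argmax of the softmax class probabilities (ties broken
#' toward the lowest class index). Observed entries are never altered.
#'
#' @param model a trained `scda_model`.
#' @param corrupted a [genotype_matrix] with the model's marker count and
#'   class count.
#' @param batch_size forward-pass batch size.
#' @return an [imputation_result()] with per-entry class probabilities.
#' @export
scda_impute <- function(model, corrupted, batch_size = 32L) {
  stopifnot(inherits(model, "scda_model"),
            inherits(corrupted, "genotype_matrix"))
  if (corrupted$n_classes != model$n_classes)
    stop("n_classes mismatch between model and input")
  if (ncol(corrupted$values) != model$n_markers)
    stop("marker count mismatch between model and input")
  n <- nrow(corrupted$values)
  m <- model$n_markers
  C <- model$n_classes
  probs <- array(0, dim = c(n, m, C))
  for (start in seq(1L, n, by = batch_size)) {
    bi <- start:min(start + batch_size - 1L, n)
    B <- length(bi)
    xin <- stack_onehot(corrupted$values[bi, , drop = FALSE], model$L_pad, C)
    fw <- scda_forward(model, xin$X, B, training = FALSE)
    # unstack: rows are position-major within sample blocks of L_pad
    P <- array(fw$probs, dim = c(model$L_pad, B, C))
    probs[bi, , ] <- aperm(P[seq_len(m), , , drop = FALSE], c(2L, 1L, 3L))
  }
  pred <- decode_argmax(probs)
  completed <- corrupted
  miss <- corrupted$values == 0L
  completed$values[miss] <- pred[miss]
  imputation_result(completed, probabilities = probs, method = "scda",
                    info = list(history = model$history))
}
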