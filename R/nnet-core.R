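# Internal neural-network machinery: parameter packing, LSTM forward pass,
# exact backpropagation through time, and the Adam optimiser. All gradients
# are analytic; tests compare them against central finite differences.

GATE_I <- function(H) seq_len(H)
GATE_F <- function(H) H + seq_len(H)
GATE_G <- function(H) 2L * H + seq_len(H)
GATE_O <- function(H) 3L * H + seq_len(H)

sigm <- function(x) 1 / (1 + exp(-x))

# --- flat parameter vector <-> named shapes --------------------------------

make_skeleton <- function(subsets, H, B, ff_widths, n_inputs) {
  skel <- list()
  for (s in subsets) {
    skel[[paste0("lstm.", s, ".Wx")]] <- c(4L * H, B)
    skel[[paste0("lstm.", s, ".Wh")]] <- c(4L * H, H)
    skel[[paste0("lstm.", s, ".b")]]  <- c(4L * H, 1L)
    skel[[paste0("lstm.", s, ".v")]]  <- c(H, 1L)
    skel[[paste0("lstm.", s, ".c")]]  <- c(1L, 1L)
  }
  prev <- n_inputs
  for (l in seq_along(ff_widths)) {
    skel[[paste0("ff.W", l)]] <- c(ff_widths[l], prev)
    skel[[paste0("ff.b", l)]] <- c(ff_widths[l], 1L)
    prev <- ff_widths[l]
  }
  skel[["out.W"]] <- c(2L, prev); skel[["out.b"]] <- c(2L, 1L)
  skel
}

skeleton_sizes <- function(skel) vapply(skel, prod, numeric(1))

unpack_params <- function(theta, skel) {
  sizes <- skeleton_sizes(skel)
  stopifnot(length(theta) == sum(sizes))
  out <- vector("list", length(skel)); names(out) <- names(skel)
  pos <- 0L
  for (k in seq_along(skel)) {
    n <- sizes[[k]]
    out[[k]] <- matrix(theta[pos + seq_len(n)], skel[[k]][1], skel[[k]][2])
    pos <- pos + n
  }
  out
}

pack_params <- function(plist) unlist(lapply(plist, as.numeric), use.names = FALSE)

# index range of a component inside the flat vector
param_slices <- function(skel) {
  sizes <- skeleton_sizes(skel)
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1L
  data.frame(component = names(skel), start = starts, end = ends,
             row.names = NULL, stringsAsFactors = FALSE)
}

# --- forward ----------------------------------------------------------------

# Pads a samples-by-width block on the right with zeros to T*B columns and
# splits it into T consecutive blocks of length B (the recurrent sequence).
as_sequence <- function(x, B) {
  Tn <- max(1L, ceiling(ncol(x) / B))
  if (ncol(x) < Tn * B)
    x <- cbind(x, matrix(0, nrow(x), Tn * B - ncol(x)))
  lapply(seq_len(Tn), function(t) x[, (t - 1L) * B + seq_len(B), drop = FALSE])
}

# Forward pass. `inputs`: named list of samples-by-width matrices, one per
# subset branch. `drop_mask`: NULL (inference, dropout disabled) or a
# samples-by-n_inputs matrix of pre-scaled dropout multipliers.
nn_forward <- function(model, inputs, drop_mask = NULL, keep_cache = FALSE) {
  P <- unpack_params(model$theta, model$skel)
  H <- model$hidden_units; B <- model$block_length
  n <- nrow(inputs[[1]])
  S <- length(model$subsets)
  z <- matrix(0, n, S)
  cache <- list(branches = vector("list", S))
  for (si in seq_along(model$subsets)) {
    s <- model$subsets[[si]]
    if (!model$gates[[s]]) next  # switched off: contributes exact zeros
    xs <- inputs[[s]]
    if (is.null(xs)) stop(sprintf("missing input block for subset '%s'", s),
                          call. = FALSE)
    if (ncol(xs) != model$input_widths[[s]])
      stop(sprintf("input width mismatch for '%s': expected %d, got %d",
                   s, model$input_widths[[s]], ncol(xs)), call. = FALSE)
    seqs <- as_sequence(xs, B)
    Wx <- P[[paste0("lstm.", s, ".Wx")]]; Wh <- P[[paste0("lstm.", s, ".Wh")]]
    b <- as.numeric(P[[paste0("lstm.", s, ".b")]])
    v <- as.numeric(P[[paste0("lstm.", s, ".v")]])
    cc <- as.numeric(P[[paste0("lstm.", s, ".c")]])
    Hst <- matrix(0, n, H); Cst <- matrix(0, n, H)
    steps <- if (keep_cache) vector("list", length(seqs)) else NULL
    for (t in seq_along(seqs)) {
      Z <- seqs[[t]] %*% t(Wx) + Hst %*% t(Wh)
      Z <- sweep(Z, 2L, b, "+")
      gi <- sigm(Z[, GATE_I(H), drop = FALSE])
      gf <- sigm(Z[, GATE_F(H), drop = FALSE])
      gg <- tanh(Z[, GATE_G(H), drop = FALSE])
      go <- sigm(Z[, GATE_O(H), drop = FALSE])
      Cprev <- Cst
      Cst <- gf * Cprev + gi * gg
      tC <- tanh(Cst)
      Hprev <- Hst
      Hst <- go * tC
      if (keep_cache)
        steps[[t]] <- list(X = seqs[[t]], Hprev = Hprev, Cprev = Cprev,
                           i = gi, f = gf, g = gg, o = go, tC = tC)
    }
    u <- as.numeric(Hst %*% v + cc)
    z[, si] <- u
    if (keep_cache)
      cache$branches[[si]] <- list(steps = steps, H_T = Hst, n_steps = length(seqs))
  }
  zd <- if (is.null(drop_mask)) z else z * drop_mask
  L <- length(model$ff_widths)
  A <- vector("list", L + 1L)
  A[[1L]] <- zd
  for (l in seq_len(L)) {
    Sl <- sweep(A[[l]] %*% t(P[[paste0("ff.W", l)]]), 2L,
                as.numeric(P[[paste0("ff.b", l)]]), "+")
    A[[l + 1L]] <- sigm(sweep(Sl, 2L, model$act[[l]], "*"))
  }
  logits <- sweep(A[[L + 1L]] %*% t(P$out.W), 2L, as.numeric(P$out.b), "+")
  mx <- apply(logits, 1L, max)
  e <- exp(logits - mx)
  prob <- e / rowSums(e)
  if (keep_cache) {
    cache$z <- z; cache$zd <- zd; cache$drop_mask <- drop_mask
    cache$A <- A; cache$P <- P
  }
  list(logits = logits, prob = prob, cache = if (keep_cache) cache else NULL)
}

# Backward pass from d(objective)/d(logits); returns the flat gradient.
nn_backward <- function(model, inputs, cache, dlogits) {
  P <- cache$P
  H <- model$hidden_units; B <- model$block_length
  S <- length(model$subsets)
  G <- lapply(model$skel, function(d) matrix(0, d[1], d[2]))

  L <- length(model$ff_widths)
  A <- cache$A
  G$out.W <- t(dlogits) %*% A[[L + 1L]]
  G$out.b <- matrix(colSums(dlogits))
  dA <- dlogits %*% P$out.W
  for (l in rev(seq_len(L))) {
    Al <- A[[l + 1L]]
    dS <- sweep(dA * Al * (1 - Al), 2L, model$act[[l]], "*")
    G[[paste0("ff.W", l)]] <- t(dS) %*% A[[l]]
    G[[paste0("ff.b", l)]] <- matrix(colSums(dS))
    dA <- dS %*% P[[paste0("ff.W", l)]]
  }
  dz <- if (is.null(cache$drop_mask)) dA else dA * cache$drop_mask

  for (si in seq_len(S)) {
    s <- model$subsets[[si]]
    br <- cache$branches[[si]]
    if (is.null(br) || !model$gates[[s]]) next
    du <- dz[, si]
    v <- as.numeric(P[[paste0("lstm.", s, ".v")]])
    G[[paste0("lstm.", s, ".v")]] <- t(br$H_T) %*% matrix(du)
    G[[paste0("lstm.", s, ".c")]] <- matrix(sum(du))
    dH <- matrix(du) %*% t(matrix(v))
    dC <- matrix(0, nrow(dH), H)
    Wh <- P[[paste0("lstm.", s, ".Wh")]]
    dWx <- G[[paste0("lstm.", s, ".Wx")]]
    dWh <- G[[paste0("lstm.", s, ".Wh")]]
    db <- as.numeric(G[[paste0("lstm.", s, ".b")]])
    for (t in rev(seq_len(br$n_steps))) {
      st <- br$steps[[t]]
      dC <- dC + dH * st$o * (1 - st$tC^2)
      do_ <- dH * st$tC
      di <- dC * st$g
      dg <- dC * st$i
      df <- dC * st$Cprev
      dZt <- cbind(di * st$i * (1 - st$i),
                   df * st$f * (1 - st$f),
                   dg * (1 - st$g^2),
                   do_ * st$o * (1 - st$o))
      dWx <- dWx + t(dZt) %*% st$X
      dWh <- dWh + t(dZt) %*% st$Hprev
      db <- db + colSums(dZt)
      dH <- dZt %*% Wh
      dC <- dC * st$f
    }
    G[[paste0("lstm.", s, ".Wx")]] <- dWx
    G[[paste0("lstm.", s, ".Wh")]] <- dWh
    G[[paste0("lstm.", s, ".b")]] <- matrix(db)
  }
  pack_params(G)
}

# Mean cross-entropy and its gradient w.r.t. the logits.
softmax_xent <- function(logits, prob, labels) {
  n <- nrow(logits)
  Y <- cbind(1 - labels, labels)  # column 1 alive, column 2 dead (positive)
  p_true <- pmax(rowSums(prob * Y), .Machine$double.xmin)
  list(loss = -mean(log(p_true)), dlogits = (prob - Y) / n)
}

adam_init <- function(n) list(m = numeric(n), v = numeric(n), t = 0L)

adam_step <- function(theta, grad, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  list(theta = theta - lr * mhat / (sqrt(vhat) + eps), state = state)
}

slice_inputs <- function(inputs, idx)
  lapply(inputs, function(x) x[idx, , drop = FALSE])

model_accuracy <- function(model, inputs, labels) {
  p <- nn_forward(model, inputs)$prob[, 2L]
  mean(as.integer(p >= 0.5) == labels)
}

# Core training loop: Adam on minibatches with early stopping on held-out
# accuracy. Returns the updated model and a per-epoch log.
nn_train <- function(model, inputs, labels, config, val_idx = NULL,
                     train_idx = NULL) {
  n_all <- nrow(inputs[[1]])
  if (is.null(train_idx)) train_idx <- setdiff(seq_len(n_all), val_idx)
  tr_in <- slice_inputs(inputs, train_idx)
  tr_lab <- labels[train_idx]
  va_in <- if (length(val_idx)) slice_inputs(inputs, val_idx) else NULL
  va_lab <- labels[val_idx]
  S <- length(model$subsets)
  ntr <- length(train_idx)
  state <- adam_init(length(model$theta))
  rate <- config$dropout_rate
  log_rows <- vector("list", config$epochs)
  best <- list(acc = -Inf, theta = model$theta, epoch = 0L)
  wait <- 0L
  with_seed(model$train_seed, {
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(ntr)
      nb <- ceiling(ntr / config$batch_size)
      ep_loss <- 0
      for (bi in seq_len(nb)) {
        idx <- ord[((bi - 1L) * config$batch_size + 1L):min(bi * config$batch_size, ntr)]
        bin <- slice_inputs(tr_in, idx)
        blab <- tr_lab[idx]
        dmask <- if (rate > 0)
          matrix(stats::rbinom(length(idx) * S, 1L, 1 - rate) / (1 - rate),
                 length(idx), S)
        else NULL
        fw <- nn_forward(model, bin, drop_mask = dmask, keep_cache = TRUE)
        sx <- softmax_xent(fw$logits, fw$prob, blab)
        if (!is.finite(sx$loss))
          stop(sprintf("non-finite loss at epoch %d (learning rate %g)",
                       ep, config$learning_rate), call. = FALSE)
        grad <- nn_backward(model, bin, fw$cache, sx$dlogits)
        upd <- adam_step(model$theta, grad, state, config$learning_rate)
        model$theta <- upd$theta
        state <- upd$state
        ep_loss <- ep_loss + sx$loss * length(idx)
      }
      tr_acc <- model_accuracy(model, tr_in, tr_lab)
      va_acc <- if (!is.null(va_in)) model_accuracy(model, va_in, va_lab) else NA_real_
      log_rows[[ep]] <- data.frame(epoch = ep, train_loss = ep_loss / ntr,
                                   train_accuracy = tr_acc,
                                   validation_accuracy = va_acc)
      if (!is.null(va_in)) {
        if (va_acc > best$acc + 1e-12) {
          best <- list(acc = va_acc, theta = model$theta, epoch = ep)
          wait <- 0L
        } else {
          wait <- wait + 1L
          if (wait >= config$patience) break
        }
      }
    }
  })
  if (!is.null(va_in) && is.finite(best$acc)) model$theta <- best$theta
  list(model = model, log = do.call(rbind, log_rows[!vapply(log_rows, is.null, TRUE)]),
       best_epoch = if (!is.null(va_in)) best$epoch else NA_integer_)
}
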