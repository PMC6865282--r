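# Small text CNN: embedding -> parallel 1-d convolutions (widths 3/4/5) ->
# ReLU -> global max-pool -> softmax. Written against BLAS matmuls via an
# im2col layout: for width w the batch becomes a (B * P) x (w * d) matrix
# (P = positions), so the convolution is a single dense product. Trained
# with Adam and validation early stopping. Desk-scale by design (vocabulary
# a few thousand, d = 50): no GPU, one CPU core.

cnn_init <- function(vocab_size, h) {
  d <- h$d; f <- h$n_filters
  params <- list(E = matrix(rnorm(vocab_size * d, sd = 0.1), vocab_size, d))
  params$E[1L, ] <- 0  # pad embedding stays zero
  for (w in h$widths) {
    params[[paste0("W", w)]] <- matrix(rnorm(w * d * f, sd = sqrt(2 / (w * d))),
                                       w * d, f)
    params[[paste0("b", w)]] <- numeric(f)
  }
  params$Wo <- matrix(rnorm(length(h$widths) * f * 4L, sd = 0.05),
                      length(h$widths) * f, 4L)
  params$bo <- numeric(4L)
  params
}

# forward pass; returns logits and (optionally) the caches for backprop
cnn_forward <- function(params, ids, h, keep_cache = FALSE) {
  B <- nrow(ids); L <- ncol(ids); d <- h$d; f <- h$n_filters
  pooled <- vector("list", length(h$widths))
  caches <- if (keep_cache) vector("list", length(h$widths))
  for (wi in seq_along(h$widths)) {
    w <- h$widths[wi]
    P <- L - w + 1L
    X <- matrix(0, B * P, w * d)
    for (o in seq_len(w) - 1L) {
      tok <- ids[, (1L + o):(P + o), drop = FALSE]
      X[, o * d + seq_len(d)] <- params$E[as.vector(tok), , drop = FALSE]
    }
    Z <- X %*% params[[paste0("W", w)]]
    Z <- sweep(Z, 2L, params[[paste0("b", w)]], "+")
    Z[Z < 0] <- 0
    dim(Z) <- c(B, P, f)
    M <- Z[, 1L, ]
    if (B == 1L) M <- matrix(M, 1L, f)
    AM <- matrix(1L, B, f)
    if (P > 1L) for (p in 2L:P) {
      Zp <- Z[, p, ]
      if (B == 1L) Zp <- matrix(Zp, 1L, f)
      upd <- Zp > M
      M[upd] <- Zp[upd]
      AM[upd] <- p
    }
    pooled[[wi]] <- M
    if (keep_cache) caches[[wi]] <- list(X = X, AM = AM, M = M, P = P)
  }
  H <- do.call(cbind, pooled)
  logits <- sweep(H %*% params$Wo, 2L, params$bo, "+")
  if (keep_cache) list(logits = logits, H = H, caches = caches) else logits
}

cnn_backward <- function(params, ids, yi, fw, h) {
  B <- nrow(ids); d <- h$d; f <- h$n_filters
  # softmax cross-entropy gradient
  Z <- fw$logits - apply(fw$logits, 1L, max)
  P <- exp(Z); P <- P / rowSums(P)
  P[cbind(seq_len(B), yi)] <- P[cbind(seq_len(B), yi)] - 1
  dLogits <- P / B

  grads <- list()
  grads$Wo <- crossprod(fw$H, dLogits)
  grads$bo <- colSums(dLogits)
  dH <- dLogits %*% t(params$Wo)

  dE <- matrix(0, nrow(params$E), d)
  for (wi in seq_along(h$widths)) {
    w <- h$widths[wi]
    cache <- fw$caches[[wi]]
    Pn <- cache$P
    dPool <- dH[, (wi - 1L) * f + seq_len(f), drop = FALSE]
    dPool <- dPool * (cache$M > 0)  # ReLU gate at the pooled maximum
    # scatter gradient to the argmax positions in the (B * P) x f layout
    dZ <- matrix(0, B * Pn, f)
    rows <- (cache$AM - 1L) * B + row(cache$AM)
    dZ[cbind(as.vector(rows), as.vector(col(cache$AM)))] <- as.vector(dPool)
    grads[[paste0("W", w)]] <- crossprod(cache$X, dZ)
    grads[[paste0("b", w)]] <- colSums(dZ)
    dX <- dZ %*% t(params[[paste0("W", w)]])
    for (o in seq_len(w) - 1L) {
      tok <- as.vector(ids[, (1L + o):(Pn + o), drop = FALSE])
      blk <- dX[, o * d + seq_len(d), drop = FALSE]
      agg <- rowsum(blk, group = tok, reorder = FALSE)
      tgt <- as.integer(rownames(agg))
      dE[tgt, ] <- dE[tgt, , drop = FALSE] + agg
    }
  }
  grads$E <- dE
  grads
}

adam_step <- function(state, params, grads, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  params$E[1L, ] <- 0  # keep the pad row inert
  list(state = state, params = params)
}

fit_cnn <- function(ids, y, h, ids_val = NULL, y_val = NULL) {
  stopifnot(is.matrix(ids), ncol(ids) >= max(h$widths))
  yi <- as.integer(factor(y, levels = opi_labels()))
  vocab_size <- attr(ids, "vocab_size") %||% max(ids, 2L)
  params <- cnn_init(vocab_size, h)
  state <- list(m = lapply(params, function(p) p * 0),
                v = lapply(params, function(p) p * 0))
  n <- nrow(ids)
  best <- list(params = params, score = -Inf, epoch = 0L)
  have_val <- !is.null(ids_val) && !is.null(y_val)
  t_step <- 0L
  stall <- 0L
  for (ep in seq_len(h$epochs)) {
    ord <- sample.int(n)
    for (s in seq(1L, n, by = h$batch)) {
      idx <- ord[s:min(s + h$batch - 1L, n)]
      fw <- cnn_forward(params, ids[idx, , drop = FALSE], h,
                        keep_cache = TRUE)
      grads <- cnn_backward(params, ids[idx, , drop = FALSE], yi[idx], fw, h)
      t_step <- t_step + 1L
      up <- adam_step(state, params, grads, h$lr, t_step)
      state <- up$state; params <- up$params
    }
    if (have_val) {
      pv <- cnn_predict_idx(params, ids_val, h)
      score <- mean(opi_labels()[pv] == as.character(y_val))
      if (score > best$score + 1e-6) {
        best <- list(params = params, score = score, epoch = ep)
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= h$patience) break
      }
    } else {
      best <- list(params = params, score = NA_real_, epoch = ep)
    }
  }
  list(params = best$params, h = h, val_score = best$score,
       epochs_run = best$epoch)
}

cnn_predict_idx <- function(params, ids, h, batch = 512L) {
  n <- nrow(ids)
  out <- integer(n)
  for (s in seq(1L, n, by = batch)) {
    e <- min(s + batch - 1L, n)
    logits <- cnn_forward(params, ids[s:e, , drop = FALSE], h)
    out[s:e] <- max.col(logits, ties.method = "first")
  }
  out
}

predict_cnn <- function(fit, ids) {
  cnn_predict_idx(fit$params, ids, fit$h)
}
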