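# Minimal CNN engine on base-R matrices (BLAS-backed).
#
# Activation layout: a 2D feature map batch is a (H*W*B) x C matrix whose
# row index is h + (w-1)*H + (b-1)*H*W; a 1D batch uses W = 1. Convolutions
# are computed as sums of channel-mixing matrix products over shifted
# copies of the input (zero padding), which keeps every step vectorized.

.nn_idx_cache <- new.env(parent = emptyenv())

# Row indices of the (dy, dx)-shifted source for every target position;
# 0 marks out-of-bounds (zero padding).
shift_index <- function(h, w, b, dy, dx) {
  key <- paste(h, w, b, dy, dx, sep = ",")
  idx <- .nn_idx_cache[[key]]
  if (!is.null(idx)) return(idx)
  hh <- rep_len(seq_len(h), h * w)
  ww <- rep(seq_len(w), each = h)
  sh <- hh + dy; sw <- ww + dx
  ok <- sh >= 1L & sh <= h & sw >= 1L & sw <= w
  base <- ifelse(ok, sh + (sw - 1L) * h, 0L)
  idx <- as.integer(rep(base, b) +
                      rep((seq_len(b) - 1L) * h * w, each = h * w) * (base > 0L))
  .nn_idx_cache[[key]] <- idx
  idx
}

gather_rows <- function(x, idx) {
  out <- x[pmax(idx, 1L), , drop = FALSE]
  if (any(idx == 0L)) out[idx == 0L, ] <- 0
  out
}

conv_offsets <- function(kind) {
  if (kind == "2d") {
    off <- list(); k <- 0L
    for (dx in -1:1) for (dy in -1:1) { k <- k + 1L; off[[k]] <- c(dy, dx) }
    off
  } else lapply(-1:1, function(dy) c(dy, 0L))
}

# W: array (taps, Cin, Cout); bias: length Cout.
conv_forward <- function(x, W, bias, h, w, b, offsets) {
  cin <- dim(W)[2]; cout <- dim(W)[3]
  out <- matrix(rep(bias, each = nrow(x)), nrow(x), cout)
  for (k in seq_along(offsets)) {
    idx <- shift_index(h, w, b, offsets[[k]][1], offsets[[k]][2])
    out <- out + gather_rows(x, idx) %*% matrix(W[k, , ], cin, cout)
  }
  out
}

conv_backward <- function(x, dout, W, h, w, b, offsets) {
  taps <- dim(W)[1]; cin <- dim(W)[2]; cout <- dim(W)[3]
  dW <- array(0, dim(W))
  dx_ <- matrix(0, nrow(x), cin)
  for (k in seq_len(taps)) {
    o <- offsets[[k]]
    idx <- shift_index(h, w, b, o[1], o[2])
    dW[k, , ] <- crossprod(gather_rows(x, idx), dout)
    inv <- shift_index(h, w, b, -o[1], -o[2])
    dx_ <- dx_ + gather_rows(dout, inv) %*% t(matrix(W[k, , ], cin, cout))
  }
  list(dx = dx_, dW = dW, db = colSums(dout))
}

pool_index <- function(h, w, b, di, dj) {
  # target (ho, wo, batch) pulls input (2*ho-1+di, 2*wo-1+dj)
  ho <- h %/% 2L; wo <- max(w %/% 2L, 1L)
  key <- paste("p", h, w, b, di, dj, sep = ",")
  idx <- .nn_idx_cache[[key]]
  if (!is.null(idx)) return(idx)
  oh <- rep_len(seq_len(ho), ho * wo)
  ow <- rep(seq_len(wo), each = ho)
  sh <- 2L * oh - 1L + di
  sw <- if (w == 1L) ow else 2L * ow - 1L + dj
  base <- sh + (sw - 1L) * h
  idx <- as.integer(rep(base, b) + rep((seq_len(b) - 1L) * h * w, each = ho * wo))
  .nn_idx_cache[[key]] <- idx
  idx
}

maxpool_forward <- function(x, h, w, b) {
  taps <- if (w == 1L) list(c(0L, 0L), c(1L, 0L)) else
    list(c(0L, 0L), c(1L, 0L), c(0L, 1L), c(1L, 1L))
  parts <- lapply(taps, function(t) x[pool_index(h, w, b, t[1], t[2]), , drop = FALSE])
  out <- parts[[1]]
  for (k in 2:length(parts)) out <- pmax(out, parts[[k]])
  list(out = out, parts = parts, taps = taps)
}

maxpool_backward <- function(cache, dout, x, h, w, b) {
  dx_ <- matrix(0, nrow(x), ncol(x))
  claimed <- matrix(FALSE, nrow(dout), ncol(dout))
  for (k in seq_along(cache$parts)) {
    t <- cache$taps[[k]]
    idx <- pool_index(h, w, b, t[1], t[2])
    win <- (cache$parts[[k]] == cache$out) & !claimed
    claimed <- claimed | win
    dx_[idx, ] <- dx_[idx, ] + dout * win
  }
  dx_
}

bn_forward <- function(x, gamma, beta, rm, rv, training, momentum = 0.9,
                       eps = 1e-5) {
  if (training) {
    mu <- colMeans(x)
    xc <- sweep(x, 2L, mu)
    v <- colMeans(xc^2)
    rm_new <- momentum * rm + (1 - momentum) * mu
    rv_new <- momentum * rv + (1 - momentum) * v
  } else {
    mu <- rm; v <- rv
    xc <- sweep(x, 2L, mu)
    rm_new <- rm; rv_new <- rv
  }
  invstd <- 1 / sqrt(v + eps)
  xhat <- sweep(xc, 2L, invstd, `*`)
  out <- sweep(sweep(xhat, 2L, gamma, `*`), 2L, beta, `+`)
  list(out = out, xhat = xhat, invstd = invstd, rm = rm_new, rv = rv_new,
       training = training)
}

bn_backward <- function(cache, dout, gamma) {
  n <- nrow(dout)
  dxhat <- sweep(dout, 2L, gamma, `*`)
  s1 <- colSums(dxhat)
  s2 <- colSums(dxhat * cache$xhat)
  if (cache$training) {
    dx_ <- sweep(dxhat, 2L, s1 / n) - sweep(cache$xhat, 2L, s2 / n, `*`)
    dx_ <- sweep(dx_, 2L, cache$invstd, `*`)
  } else {
    # inference-mode batch norm is a fixed affine map
    dx_ <- sweep(dxhat, 2L, cache$invstd, `*`)
  }
  list(dx = dx_, dgamma = s2, dbeta = s1)
}

# (H*W*B) x C activation -> B x (H*W*C) per-image flatten (spatial-first).
flatten_batch <- function(x, hw, b) {
  a <- array(x, c(hw, b, ncol(x)))
  t(matrix(aperm(a, c(1, 3, 2)), hw * ncol(x), b))
}

unflatten_batch <- function(z, hw, b, c) {
  a <- array(t(z), c(hw, c, b))
  matrix(aperm(a, c(1, 3, 2)), hw * b, c)
}

softmax_rows <- function(s) {
  e <- exp(s - apply(s, 1L, max))
  e / rowSums(e)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}
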