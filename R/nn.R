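# Minimal CNN layer kit in base R matrix algebra: 3x3 same-padding
# convolution via im2col, batch normalization, ReLU, 2x2 max pooling, 2x2
# stride-2 transposed convolution, channel concatenation, softmax
# cross-entropy, and Adam. Activations are 4D arrays (H, W, N, C).

nn_offsets3 <- cbind(di = rep(0:2, times = 3), dj = rep(0:2, each = 3))

im2col3 <- function(x) {
  d <- dim(x)  # H, W, N, C
  xp <- array(0, dim = c(d[1] + 2, d[2] + 2, d[3], d[4]))
  xp[2:(d[1] + 1), 2:(d[2] + 1), , ] <- x
  blocks <- vector("list", 9)
  for (k in 1:9) {
    di <- nn_offsets3[k, 1]; dj <- nn_offsets3[k, 2]
    b <- xp[di + seq_len(d[1]), dj + seq_len(d[2]), , , drop = FALSE]
    dim(b) <- c(d[1] * d[2] * d[3], d[4])
    blocks[[k]] <- b
  }
  do.call(cbind, blocks)
}

conv3_forward <- function(x, W, b) {
  d <- dim(x)
  col <- im2col3(x)
  y <- col %*% W
  y <- sweep(y, 2, b, `+`)
  dim(y) <- c(d[1], d[2], d[3], ncol(W))
  list(y = y, col = col, in_dim = d)
}

conv3_backward <- function(dy, cache, W) {
  d <- cache$in_dim
  cin <- d[4]
  dim(dy) <- c(d[1] * d[2] * d[3], ncol(W))
  dW <- crossprod(cache$col, dy)
  db <- colSums(dy)
  dcol <- dy %*% t(W)
  dxp <- array(0, dim = c(d[1] + 2, d[2] + 2, d[3], cin))
  for (k in 1:9) {
    di <- nn_offsets3[k, 1]; dj <- nn_offsets3[k, 2]
    block <- dcol[, ((k - 1) * cin + 1):(k * cin), drop = FALSE]
    dim(block) <- c(d[1], d[2], d[3], cin)
    dxp[di + seq_len(d[1]), dj + seq_len(d[2]), , ] <-
      dxp[di + seq_len(d[1]), dj + seq_len(d[2]), , , drop = FALSE] + block
  }
  dx <- dxp[2:(d[1] + 1), 2:(d[2] + 1), , , drop = FALSE]
  list(dx = dx, dW = dW, db = db)
}

bn_forward <- function(x, gamma, beta, run_mean, run_var, training,
                       momentum = 0.9, eps = 1e-5) {
  d <- dim(x)
  m <- x
  dim(m) <- c(prod(d[1:3]), d[4])
  if (training) {
    mu <- colMeans(m)
    xc <- sweep(m, 2, mu)
    v <- colMeans(xc^2)
    run_mean <- momentum * run_mean + (1 - momentum) * mu
    run_var <- momentum * run_var + (1 - momentum) * v
  } else {
    mu <- run_mean
    v <- run_var
    xc <- sweep(m, 2, mu)
  }
  invstd <- 1 / sqrt(v + eps)
  xhat <- sweep(xc, 2, invstd, `*`)
  y <- sweep(sweep(xhat, 2, gamma, `*`), 2, beta, `+`)
  dim(y) <- d
  list(y = y, xhat = xhat, invstd = invstd, gamma = gamma, dims = d,
       run_mean = run_mean, run_var = run_var)
}

bn_backward <- function(dy, cache) {
  d <- cache$dims
  M <- prod(d[1:3])
  dym <- dy
  dim(dym) <- c(M, d[4])
  dgamma <- colSums(dym * cache$xhat)
  dbeta <- colSums(dym)
  dxhat <- sweep(dym, 2, cache$gamma, `*`)
  s1 <- colSums(dxhat)
  s2 <- colSums(dxhat * cache$xhat)
  dx <- sweep(dxhat, 2, s1 / M) - sweep(cache$xhat, 2, s2 / M, `*`)
  dx <- sweep(dx, 2, cache$invstd, `*`)
  dim(dx) <- d
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

relu_forward <- function(x) list(y = pmax(x, 0), mask = x > 0)
relu_backward <- function(dy, cache) dy * cache$mask

maxpool2_forward <- function(x) {
  d <- dim(x)
  o1 <- seq(1, d[1], 2); e1 <- o1 + 1
  o2 <- seq(1, d[2], 2); e2 <- o2 + 1
  a <- x[o1, o2, , , drop = FALSE]; b <- x[e1, o2, , , drop = FALSE]
  cc <- x[o1, e2, , , drop = FALSE]; dd <- x[e1, e2, , , drop = FALSE]
  y <- pmax(a, b, cc, dd)
  m1 <- a == y
  m2 <- (b == y) & !m1
  m3 <- (cc == y) & !m1 & !m2
  m4 <- !m1 & !m2 & !m3
  list(y = y, masks = list(m1, m2, m3, m4), in_dim = d)
}

maxpool2_backward <- function(dy, cache) {
  d <- cache$in_dim
  dx <- array(0, dim = d)
  o1 <- seq(1, d[1], 2); e1 <- o1 + 1
  o2 <- seq(1, d[2], 2); e2 <- o2 + 1
  dx[o1, o2, , ] <- dy * cache$masks[[1]]
  dx[e1, o2, , ] <- dy * cache$masks[[2]]
  dx[o1, e2, , ] <- dy * cache$masks[[3]]
  dx[e1, e2, , ] <- dy * cache$masks[[4]]
  dx
}

nn_offsets2 <- cbind(di = rep(1:2, times = 2), dj = rep(1:2, each = 2))

convt2_forward <- function(x, W, b) {
  d <- dim(x)  # H, W, N, Cin
  cout <- dim(W)[2]
  xm <- x
  dim(xm) <- c(prod(d[1:3]), d[4])
  y <- array(0, dim = c(2 * d[1], 2 * d[2], d[3], cout))
  for (k in 1:4) {
    yk <- sweep(xm %*% W[, , k], 2, b, `+`)
    dim(yk) <- c(d[1], d[2], d[3], cout)
    y[seq(nn_offsets2[k, 1], 2 * d[1], 2),
      seq(nn_offsets2[k, 2], 2 * d[2], 2), , ] <- yk
  }
  list(y = y, xm = xm, in_dim = d)
}

convt2_backward <- function(dy, cache, W) {
  d <- cache$in_dim
  cout <- dim(W)[2]
  dW <- array(0, dim = dim(W))
  db <- numeric(cout)
  dxm <- matrix(0, nrow = prod(d[1:3]), ncol = d[4])
  for (k in 1:4) {
    dyk <- dy[seq(nn_offsets2[k, 1], 2 * d[1], 2),
              seq(nn_offsets2[k, 2], 2 * d[2], 2), , , drop = FALSE]
    dim(dyk) <- c(prod(d[1:3]), cout)
    dW[, , k] <- crossprod(cache$xm, dyk)
    db <- db + colSums(dyk)
    dxm <- dxm + dyk %*% t(W[, , k])
  }
  dx <- dxm
  dim(dx) <- d
  list(dx = dx, dW = dW, db = db)
}

concat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  y <- array(0, dim = c(da[1], da[2], da[3], da[4] + db[4]))
  y[, , , seq_len(da[4])] <- a
  y[, , , da[4] + seq_len(db[4])] <- b
  y
}

# softmax cross-entropy; optional per-class weights counteract the severe
# background/structure pixel imbalance
softmax_ce <- function(logits, labels, class_weights = NULL) {
  d <- dim(logits)  # H, W, N, K
  M <- prod(d[1:3])
  m <- logits
  dim(m) <- c(M, d[4])
  rmax <- m[, 1]
  for (k in seq_len(d[4])[-1]) rmax <- pmax(rmax, m[, k])
  m <- m - rmax
  p <- exp(m)
  p <- p / rowSums(p)
  lab1 <- as.integer(labels) + 1L
  idx <- cbind(seq_len(M), lab1)
  w <- if (is.null(class_weights)) rep(1, M) else class_weights[lab1]
  wsum <- sum(w)
  loss <- -sum(w * log(pmax(p[idx], 1e-12))) / wsum
  dlogits <- p
  dlogits[idx] <- dlogits[idx] - 1
  dlogits <- dlogits * (w / wsum)
  dim(dlogits) <- d
  list(loss = loss, dlogits = dlogits, probs = p)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) array(0, dim = dim(p) %||% length(p))),
       v = lapply(params, function(p) array(0, dim = dim(p) %||% length(p))),
       t = 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
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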