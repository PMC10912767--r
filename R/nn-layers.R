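## Primitive tensor ops for the PlexusNet engine.
##
## Layout convention: activations are numeric arrays (N, H, W, C); dense
## activations are matrices (N, D). Convolution is evaluated via im2col +
## matrix multiplication; weights are stored as a (k*k*Cin, Cout) matrix so
## the same buffer serves forward, weight-gradient and input-gradient passes.
## Everything here is deterministic; randomness enters only through weight
## initialisation in the graph builder.

roundHalfUp <- function(x) floor(x + 0.5)

padZeros <- function(x, p) {
  if (p == 0L) return(x)
  d <- dim(x)
  out <- array(0, c(d[1], d[2] + 2 * p, d[3] + 2 * p, d[4]))
  out[, (p + 1):(p + d[2]), (p + 1):(p + d[3]), ] <- x
  out
}

## (N,H,W,C) -> (N*OH*OW, k*k*C); column blocks ordered by (ki, kj), each
## block C wide, rows ordered n fastest then oh then ow (R column-major).
im2col <- function(x, k, stride, pad) {
  xp <- padZeros(x, pad)
  d <- dim(xp); n <- d[1]; h <- d[2]; w <- d[3]; ch <- d[4]
  oh <- (h - k) %/% stride + 1L
  ow <- (w - k) %/% stride + 1L
  cols <- matrix(0, n * oh * ow, k * k * ch)
  for (ki in seq_len(k)) {
    ri <- seq.int(ki, by = stride, length.out = oh)
    for (kj in seq_len(k)) {
      cj <- seq.int(kj, by = stride, length.out = ow)
      blk <- ((ki - 1L) * k + (kj - 1L)) * ch
      cols[, (blk + 1L):(blk + ch)] <-
        matrix(xp[, ri, cj, , drop = FALSE], n * oh * ow, ch)
    }
  }
  list(cols = cols, n = n, oh = oh, ow = ow, ch = ch,
       h = dim(x)[2], w = dim(x)[3])
}

col2im <- function(dcols, k, stride, pad, n, h, w, ch, oh, ow) {
  hp <- h + 2L * pad; wp <- w + 2L * pad
  dxp <- array(0, c(n, hp, wp, ch))
  for (ki in seq_len(k)) {
    ri <- seq.int(ki, by = stride, length.out = oh)
    for (kj in seq_len(k)) {
      cj <- seq.int(kj, by = stride, length.out = ow)
      blk <- ((ki - 1L) * k + (kj - 1L)) * ch
      dxp[, ri, cj, ] <- dxp[, ri, cj, ] +
        array(dcols[, (blk + 1L):(blk + ch)], c(n, oh, ow, ch))
    }
  }
  if (pad > 0L) dxp[, (pad + 1L):(pad + h), (pad + 1L):(pad + w), ,
                    drop = FALSE] else dxp
}

convForward <- function(x, W, b, k, stride, pad) {
  ic <- im2col(x, k, stride, pad)
  out <- ic$cols %*% W
  out <- sweep(out, 2L, b, "+")
  list(out = array(out, c(ic$n, ic$oh, ic$ow, length(b))), cache = ic)
}

convBackward <- function(dout, cache, W, k, stride, pad) {
  d <- dim(dout)
  dmat <- matrix(dout, d[1] * d[2] * d[3], d[4])
  dW <- crossprod(cache$cols, dmat)
  db <- colSums(dmat)
  dcols <- tcrossprod(dmat, W)
  dx <- col2im(dcols, k, stride, pad, cache$n, cache$h, cache$w,
               cache$ch, cache$oh, cache$ow)
  list(dx = dx, dW = dW, db = db)
}

reluForward <- function(x) list(out = pmax(x, 0), cache = x > 0)
reluBackward <- function(dout, cache) dout * cache

sigmoidForward <- function(x) {
  s <- 1 / (1 + exp(-x)); list(out = s, cache = s)
}
sigmoidBackward <- function(dout, cache) dout * cache * (1 - cache)

## channelwise batch normalisation over (N, H, W)
bnForward <- function(x, gamma, beta, state, train, momentum = 0.9,
                      eps = 1e-5) {
  d <- dim(x); ch <- d[4]
  xm <- matrix(x, prod(d[1:3]), ch)
  if (train) {
    mu <- colMeans(xm)
    v <- colMeans(sweep(xm, 2L, mu)^2)
    state$mean <- momentum * state$mean + (1 - momentum) * mu
    state$var <- momentum * state$var + (1 - momentum) * v
  } else {
    mu <- state$mean; v <- state$var
  }
  istd <- 1 / sqrt(v + eps)
  xhat <- sweep(sweep(xm, 2L, mu), 2L, istd, "*")
  out <- sweep(sweep(xhat, 2L, gamma, "*"), 2L, beta, "+")
  list(out = array(out, d), cache = list(xhat = xhat, istd = istd, d = d),
       state = state)
}

bnBackward <- function(dout, cache, gamma) {
  d <- cache$d; m <- prod(d[1:3])
  dm <- matrix(dout, m, d[4])
  dgamma <- colSums(dm * cache$xhat)
  dbeta <- colSums(dm)
  t1 <- sweep(dm, 2L, colMeans(dm))
  t2 <- sweep(cache$xhat, 2L, colMeans(dm * cache$xhat), "*")
  dx <- sweep(t1 - t2, 2L, gamma * cache$istd, "*")
  list(dx = array(dx, d), dgamma = dgamma, dbeta = dbeta)
}

## per-sample layer normalisation over (H, W, C), channelwise affine
lnForward <- function(x, gamma, beta, eps = 1e-5) {
  d <- dim(x); m <- prod(d[2:4])
  xm <- matrix(aperm(x, c(2, 3, 4, 1)), m, d[1])   # features x samples
  mu <- colMeans(xm)
  v <- colMeans(sweep(xm, 2L, mu)^2)
  istd <- 1 / sqrt(v + eps)
  xhat <- sweep(sweep(xm, 2L, mu), 2L, istd, "*")
  xhat_a <- aperm(array(xhat, c(d[2], d[3], d[4], d[1])), c(4, 1, 2, 3))
  out <- sweep(sweep(xhat_a, 4L, gamma, "*"), 4L, beta, "+")
  list(out = out, cache = list(xhat = xhat, istd = istd, d = d))
}

lnBackward <- function(dout, cache, gamma) {
  d <- cache$d; m <- prod(d[2:4])
  dga <- sweep(dout, 4L, gamma, "*")
  dgm <- matrix(aperm(dga, c(2, 3, 4, 1)), m, d[1])
  xhat_a <- aperm(array(cache$xhat, c(d[2], d[3], d[4], d[1])), c(4, 1, 2, 3))
  dgamma <- apply(dout * xhat_a, 4L, sum)
  dbeta <- apply(dout, 4L, sum)
  t1 <- sweep(dgm, 2L, colMeans(dgm))
  t2 <- sweep(cache$xhat, 2L, colMeans(dgm * cache$xhat), "*")
  dxm <- sweep(t1 - t2, 2L, cache$istd, "*")
  dx <- aperm(array(dxm, c(d[2], d[3], d[4], d[1])), c(4, 1, 2, 3))
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

## 2x2 average pooling, stride 2 (odd trailing row/col dropped)
avgpoolForward <- function(x) {
  d <- dim(x)
  h2 <- d[2] %/% 2L; w2 <- d[3] %/% 2L
  i1 <- seq.int(1L, by = 2L, length.out = h2)
  j1 <- seq.int(1L, by = 2L, length.out = w2)
  out <- (x[, i1, j1, , drop = FALSE] + x[, i1 + 1L, j1, , drop = FALSE] +
          x[, i1, j1 + 1L, , drop = FALSE] +
          x[, i1 + 1L, j1 + 1L, , drop = FALSE]) / 4
  list(out = out, cache = d)
}

avgpoolBackward <- function(dout, cache) {
  d <- cache
  h2 <- d[2] %/% 2L; w2 <- d[3] %/% 2L
  dx <- array(0, d)
  i1 <- seq.int(1L, by = 2L, length.out = h2)
  j1 <- seq.int(1L, by = 2L, length.out = w2)
  q <- dout / 4
  dx[, i1, j1, ] <- q; dx[, i1 + 1L, j1, ] <- dx[, i1 + 1L, j1, ] + q
  dx[, i1, j1 + 1L, ] <- dx[, i1, j1 + 1L, ] + q
  dx[, i1 + 1L, j1 + 1L, ] <- dx[, i1 + 1L, j1 + 1L, ] + q
  dx
}

globalPoolForward <- function(x, kind) {
  d <- dim(x); n <- d[1]; ch <- d[4]
  xm <- matrix(aperm(x, c(2, 3, 1, 4)), d[2] * d[3], n * ch)
  if (kind == "avg") {
    out <- matrix(colMeans(xm), n, ch)
    cache <- list(kind = kind, d = d)
  } else {
    idx <- max.col(t(xm), ties.method = "first")
    out <- matrix(xm[cbind(idx, seq_along(idx))], n, ch)
    cache <- list(kind = kind, d = d, idx = idx)
  }
  list(out = out, cache = cache)
}

globalPoolBackward <- function(dout, cache) {
  d <- cache$d; n <- d[1]; ch <- d[4]; m <- d[2] * d[3]
  dxm <- matrix(0, m, n * ch)
  if (cache$kind == "avg") {
    dxm <- matrix(rep(as.vector(dout), each = m) / m, m, n * ch)
  } else {
    dxm[cbind(cache$idx, seq_len(n * ch))] <- as.vector(dout)
  }
  aperm(array(dxm, c(d[2], d[3], n, ch)), c(3, 1, 2, 4))
}

denseForward <- function(x, W, b) {
  list(out = sweep(x %*% W, 2L, b, "+"), cache = x)
}
denseBackward <- function(dout, cache, W) {
  list(dx = tcrossprod(dout, W), dW = crossprod(cache, dout),
       db = colSums(dout))
}

softmaxRows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

## multi-head self-attention encoder block, forward only:
## LN -> MHA -> residual -> LN -> FFN(C -> 2C -> C) -> residual
## x: (N, T, C) stored as 3-d array
transformerForward <- function(x, p, n_heads) {
  d <- dim(x); n <- d[1]; tt <- d[2]; ch <- d[3]
  hd <- ch %/% n_heads
  ln <- function(xx, g, b) {
    mu <- apply(xx, c(1, 2), mean)
    sdv <- sqrt(apply(xx, c(1, 2), function(v) mean((v - mean(v))^2)) + 1e-5)
    xh <- (xx - array(mu, d)) / array(sdv, d)
    sweep(sweep(xh, 3L, g, "*"), 3L, b, "+")
  }
  x1 <- ln(x, p$ln1_g, p$ln1_b)
  xm <- matrix(x1, n * tt, ch)
  q <- sweep(xm %*% p$Wq, 2L, p$bq, "+")
  k <- sweep(xm %*% p$Wk, 2L, p$bk, "+")
  v <- sweep(xm %*% p$Wv, 2L, p$bv, "+")
  att <- matrix(0, n * tt, ch)
  for (i in seq_len(n)) {
    ri <- seq.int(i, by = n, length.out = tt)     # rows of sample i
    for (h in seq_len(n_heads)) {
      cc <- ((h - 1L) * hd + 1L):(h * hd)
      qs <- q[ri, cc, drop = FALSE]
      ks <- k[ri, cc, drop = FALSE]
      vs <- v[ri, cc, drop = FALSE]
      a <- softmaxRows(tcrossprod(qs, ks) / sqrt(hd))
      att[ri, cc] <- a %*% vs
    }
  }
  o <- sweep(att %*% p$Wo, 2L, p$bo, "+")
  x2 <- x + array(o, d)
  x3 <- ln(x2, p$ln2_g, p$ln2_b)
  x3m <- matrix(x3, n * tt, ch)
  f <- pmax(sweep(x3m %*% p$W1, 2L, p$b1, "+"), 0)
  f2 <- sweep(f %*% p$W2, 2L, p$b2, "+")
  x2 + array(f2, d)
}
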