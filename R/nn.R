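## Minimal convolutional-network engine used by the fusion model:
## im2col-based 2-D convolution with explicit backward passes, nearest
## upsampling, 2x2 average pooling, global average pooling and a fully
## connected layer, plus an AdamW optimizer. Written against vectorised
## base-R matrix algebra; gradient correctness is verified by finite
## differences in the test suite.

.idxCache <- new.env(parent = emptyenv())

## Linear-index map for im2col on an (H, W, C) array with zero padding.
## Row order of the column matrix = output positions, column-major
## (y fastest); column order = kernel rows fastest, then kernel cols,
## then channel -- matching array(k, k, C) flattening.
.im2colIndex <- function(H, W, C, k, stride, pad) {
  key <- paste(H, W, C, k, stride, pad, sep = "_")
  hit <- .idxCache[[key]]
  if (!is.null(hit)) return(hit)
  Hp <- H + 2L * pad; Wp <- W + 2L * pad
  outH <- (Hp - k) %/% stride + 1L
  outW <- (Wp - k) %/% stride + 1L
  baseR <- rep(seq.int(1L, by = stride, length.out = outH), times = outW)
  baseC <- rep(seq.int(1L, by = stride, length.out = outW), each = outH)
  offR <- rep(0:(k - 1L), times = k * C)
  offC <- rep(rep(0:(k - 1L), each = k), times = C)
  offCh <- rep(seq_len(C), each = k * k)
  nQ <- k * k * C
  idx <- matrix(0L, outH * outW, nQ)
  for (q in seq_len(nQ)) {
    idx[, q] <- (baseR + offR[q]) + (baseC + offC[q] - 1L) * Hp +
      (offCh[q] - 1L) * Hp * Wp
  }
  out <- list(idx = idx, outH = outH, outW = outW, Hp = Hp, Wp = Wp,
              H = H, W = W, C = C, k = k, pad = pad)
  .idxCache[[key]] <- out
  out
}

.convForward <- function(x, p, stride, pad) {
  d <- dim(x)
  ii <- .im2colIndex(d[1L], d[2L], d[3L], p$k, stride, pad)
  if (pad > 0L) {
    xp <- array(0, c(ii$Hp, ii$Wp, d[3L]))
    xp[pad + seq_len(d[1L]), pad + seq_len(d[2L]), ] <- x
  } else xp <- x
  cols <- matrix(xp[ii$idx], nrow(ii$idx))
  y <- cols %*% p$W
  y <- y + matrix(p$b, nrow(y), length(p$b), byrow = TRUE)
  list(y = array(y, c(ii$outH, ii$outW, length(p$b))),
       cols = cols, ii = ii)
}

.convBackward <- function(dy, p, cache, needDx = TRUE) {
  ii <- cache$ii
  dY <- matrix(dy, nrow(ii$idx), length(p$b))
  dW <- crossprod(cache$cols, dY)
  db <- colSums(dY)
  dx <- NULL
  if (needDx) {
    dCols <- tcrossprod(dY, p$W)
    acc <- rowsum(as.vector(dCols), group = as.vector(ii$idx))
    dxp <- numeric(ii$Hp * ii$Wp * ii$C)
    dxp[as.integer(rownames(acc))] <- acc
    dxp <- array(dxp, c(ii$Hp, ii$Wp, ii$C))
    dx <- if (ii$pad > 0L)
      dxp[ii$pad + seq_len(ii$H), ii$pad + seq_len(ii$W), , drop = FALSE]
    else dxp
  }
  list(dW = dW, db = db, dx = dx)
}

.upsample2 <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1L]), each = 2L), rep(seq_len(d[2L]), each = 2L), ,
    drop = FALSE]
}

.upsample2Back <- function(dy) {
  d <- dim(dy)
  o1 <- seq(1L, d[1L], 2L); o2 <- seq(1L, d[2L], 2L)
  dy[o1, o2, , drop = FALSE] + dy[o1 + 1L, o2, , drop = FALSE] +
    dy[o1, o2 + 1L, , drop = FALSE] + dy[o1 + 1L, o2 + 1L, , drop = FALSE]
}

.avgpool2 <- function(x) {
  d <- dim(x)
  o1 <- seq(1L, d[1L], 2L); o2 <- seq(1L, d[2L], 2L)
  (x[o1, o2, , drop = FALSE] + x[o1 + 1L, o2, , drop = FALSE] +
     x[o1, o2 + 1L, , drop = FALSE] +
     x[o1 + 1L, o2 + 1L, , drop = FALSE]) / 4
}

.avgpool2Back <- function(dy) {
  d <- dim(dy)
  dx <- array(0, c(2L * d[1L], 2L * d[2L], d[3L]))
  q <- dy / 4
  o1 <- seq(1L, 2L * d[1L], 2L); o2 <- seq(1L, 2L * d[2L], 2L)
  dx[o1, o2, ] <- q; dx[o1 + 1L, o2, ] <- q
  dx[o1, o2 + 1L, ] <- q; dx[o1 + 1L, o2 + 1L, ] <- q
  dx
}

.convParam <- function(k, cin, cout, biasInit = 0) {
  fanIn <- k * k * cin
  list(W = matrix(stats::rnorm(fanIn * cout, 0, sqrt(2 / fanIn)),
                  fanIn, cout),
       b = rep(biasInit, cout), k = k, cin = cin, cout = cout)
}

## Sigmoid focal term and its derivative w.r.t. the logit.
## loss = -alphaT * (1 - u)^gamma * log(u), u = pt (clamped).
.focalGrad <- function(logits, targets, alphaT, gamma) {
  p <- stats::plogis(logits)
  u <- ifelse(targets == 1, p, 1 - p)
  u <- pmin(pmax(u, 1e-7), 1 - 1e-7)
  loss <- -alphaT * (1 - u)^gamma * log(u)
  dfdu <- alphaT * (gamma * (1 - u)^(pmax(gamma - 1, 0)) * log(u) -
                      (1 - u)^gamma / u)
  dudl <- (2 * targets - 1) * u * (1 - u)
  list(loss = loss, dlogit = dfdu * dudl)
}
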