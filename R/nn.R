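# Neural-network primitives in base R matrix algebra, each with an analytic
# backward pass. Shapes: token matrices are (n_tokens x dim); convolution
# feature maps are (rows, cols, channels) arrays.

softmax_rows <- function(m) {
  e <- exp(m - apply(m, 1, max))
  e / rowSums(e)
}

# backward of p = softmax_rows(m): given dp, return dm
softmax_rows_bwd <- function(p, dp) p * (dp - rowSums(dp * p))

gelu <- function(x) x * stats::pnorm(x)
gelu_grad <- function(x) stats::pnorm(x) + x * stats::dnorm(x)

dense_fwd <- function(x, W, b) {
  y <- x %*% W
  sweep(y, 2, b, "+")
}

dense_bwd <- function(x, W, dy) {
  list(dx = dy %*% t(W), dW = crossprod(x, dy), db = colSums(dy))
}

# --- layer normalization (per row, over the feature axis) -------------------

LN_EPS <- 1e-6

layernorm_fwd <- function(x, g, b) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + LN_EPS)
  xhat <- xc * inv
  y <- sweep(sweep(xhat, 2, g, "*"), 2, b, "+")
  list(y = y, xhat = xhat, inv = inv)
}

layernorm_bwd <- function(cache, g, dy) {
  xhat <- cache$xhat
  dxhat <- sweep(dy, 2, g, "*")
  dx <- cache$inv * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  list(dx = dx, dg = colSums(dy * xhat), db = colSums(dy))
}

# --- scaled dot-product attention -------------------------------------------

# q: (n x d), k, v: (m x d). Logits scaled by 1/sqrt(d); row softmax.
scaled_dot_attention <- function(q, k, v) {
  d <- ncol(q)
  s <- tcrossprod(q, k) / sqrt(d)
  p <- softmax_rows(s)
  list(out = p %*% v, weights = p)
}

scaled_dot_attention_bwd <- function(q, k, v, p, dout) {
  d <- ncol(q)
  dv <- crossprod(p, dout)
  dp <- tcrossprod(dout, v)
  ds <- softmax_rows_bwd(p, dp) / sqrt(d)
  list(dq = ds %*% k, dk = crossprod(ds, q), dv = dv)
}

# --- multi-head self-attention ----------------------------------------------

# x: (n x D); W = list(Wq, Wk, Wv, Wo each D x D, bq, bk, bv, bo length D)
msa_fwd <- function(x, W, n_heads) {
  D <- ncol(x); dh <- D %/% n_heads
  q <- dense_fwd(x, W$Wq, W$bq)
  k <- dense_fwd(x, W$Wk, W$bk)
  v <- dense_fwd(x, W$Wv, W$bv)
  o <- matrix(0, nrow(x), D)
  ps <- vector("list", n_heads)
  for (hh in seq_len(n_heads)) {
    cols <- (hh - 1L) * dh + seq_len(dh)
    at <- scaled_dot_attention(q[, cols, drop = FALSE], k[, cols, drop = FALSE],
                               v[, cols, drop = FALSE])
    o[, cols] <- at$out
    ps[[hh]] <- at$weights
  }
  y <- dense_fwd(o, W$Wo, W$bo)
  list(y = y, q = q, k = k, v = v, o = o, ps = ps)
}

msa_bwd <- function(x, W, cache, n_heads, dy) {
  D <- ncol(x); dh <- D %/% n_heads
  db <- dense_bwd(cache$o, W$Wo, dy)
  do <- db$dx
  dq <- matrix(0, nrow(x), D); dk <- dq; dv <- dq
  for (hh in seq_len(n_heads)) {
    cols <- (hh - 1L) * dh + seq_len(dh)
    g <- scaled_dot_attention_bwd(cache$q[, cols, drop = FALSE],
                                  cache$k[, cols, drop = FALSE],
                                  cache$v[, cols, drop = FALSE],
                                  cache$ps[[hh]], do[, cols, drop = FALSE])
    dq[, cols] <- g$dq; dk[, cols] <- g$dk; dv[, cols] <- g$dv
  }
  gq <- dense_bwd(x, W$Wq, dq)
  gk <- dense_bwd(x, W$Wk, dk)
  gv <- dense_bwd(x, W$Wv, dv)
  list(dx = gq$dx + gk$dx + gv$dx,
       dWq = gq$dW, dbq = gq$db, dWk = gk$dW, dbk = gk$db,
       dWv = gv$dW, dbv = gv$db, dWo = db$dW, dbo = db$db)
}

# --- 2-D convolution on (rows, cols, channels) arrays -----------------------

# "Same"-style padding for stride s: output is ceil(n/s) per axis.
conv_geom <- function(h, w, k, s) {
  ho <- ceiling(h / s); wo <- ceiling(w / s)
  ph <- max((ho - 1L) * s + k - h, 0L); pw <- max((wo - 1L) * s + k - w, 0L)
  list(ho = ho, wo = wo, pt = ph %/% 2L, pl = pw %/% 2L, ph = ph, pw = pw)
}

# im2col: rows = output positions (row-major), cols = k*k*cin. Padding is by
# edge replication (the package's convention throughout), so the gather
# indices point straight into the unpadded source; they depend only on the
# geometry and are cached. A constant feature map therefore stays constant
# under the convolution, with no border artifacts.
conv_idx_cache <- new.env(parent = emptyenv())

conv_indices <- function(h, w, cin, k, s, geom) {
  key <- sprintf("c_%d_%d_%d_%d_%d", h, w, cin, k, s)
  got <- conv_idx_cache[[key]]
  if (!is.null(got)) return(got)
  oi <- rep(seq_len(geom$ho), each = geom$wo)  # row-major positions
  oj <- rep(seq_len(geom$wo), times = geom$ho)
  ri <- (oi - 1L) * s - geom$pt; cj <- (oj - 1L) * s - geom$pl
  npos <- geom$ho * geom$wo
  idx <- matrix(0L, npos, k * k * cin)
  col <- 0L
  for (dj in seq_len(k)) for (di in seq_len(k)) for (ch in seq_len(cin)) {
    col <- col + 1L
    src_r <- pmin(pmax(ri + di, 1L), h)   # edge replication
    src_c <- pmin(pmax(cj + dj, 1L), w)
    idx[, col] <- src_r + h * (src_c - 1L) + h * w * (ch - 1L)
  }
  conv_idx_cache[[key]] <- idx
  idx
}

im2col <- function(a, k, s, geom) {
  idx <- conv_indices(dim(a)[1], dim(a)[2], dim(a)[3], k, s, geom)
  matrix(a[idx], nrow(idx), ncol(idx))
}

col2im <- function(dcols, h, w, cin, k, s, geom) {
  idx <- conv_indices(h, w, cin, k, s, geom)
  acc <- rowsum(as.vector(dcols), group = as.vector(idx))
  da <- array(0, c(h, w, cin))
  da[as.integer(rownames(acc))] <- acc[, 1]
  da
}

# W: matrix (k*k*cin x cout), b: length cout
conv2d_fwd <- function(a, W, b, k, s) {
  geom <- conv_geom(dim(a)[1], dim(a)[2], k, s)
  cols <- im2col(a, k, s, geom)
  y <- dense_fwd(cols, W, b)
  out <- array(0, c(geom$ho, geom$wo, ncol(W)))
  for (ch in seq_len(ncol(W)))
    out[, , ch] <- matrix(y[, ch], geom$ho, geom$wo, byrow = TRUE)
  list(out = out, cols = cols, geom = geom)
}

conv2d_bwd <- function(a, W, cache, k, s, dout) {
  geom <- cache$geom
  dy <- matrix(0, geom$ho * geom$wo, dim(dout)[3])
  for (ch in seq_len(dim(dout)[3]))
    dy[, ch] <- as.vector(t(dout[, , ch]))
  g <- dense_bwd(cache$cols, W, dy)
  da <- col2im(g$dx, dim(a)[1], dim(a)[2], dim(a)[3], k, s, geom)
  list(da = da, dW = g$dW, db = g$db)
}

# nearest-neighbor upsample of (ho, wo, c) to (h, w, c)
upsample_nn_fwd <- function(a, h, w) {
  ho <- dim(a)[1]; wo <- dim(a)[2]
  ri <- pmin(floor((seq_len(h) - 1L) * ho / h) + 1L, ho)
  cj <- pmin(floor((seq_len(w) - 1L) * wo / w) + 1L, wo)
  list(out = a[ri, cj, , drop = FALSE], ri = ri, cj = cj)
}

upsample_nn_bwd <- function(dout, ho, wo, cache) {
  da <- array(0, c(ho, wo, dim(dout)[3]))
  for (i in seq_along(cache$ri)) for (j in seq_along(cache$cj)) {
    da[cache$ri[i], cache$cj[j], ] <- da[cache$ri[i], cache$cj[j], ] +
      dout[i, j, ]
  }
  da
}

# inverted dropout; returns the mask so the backward pass reuses it
dropout_mask <- function(dimn, rate) {
  if (rate <= 0) return(NULL)
  matrix((stats::runif(prod(dimn)) >= rate) / (1 - rate), dimn[1], dimn[2])
}

# --- parameter initialization ----------------------------------------------

glorot <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
}
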