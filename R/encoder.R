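# Attention-gated patch encoder.
#
# Two patch streams enter: the tiled input patches and a "sliding box" query
# stream of 50%-overlap windows over the same (padded) image. Both are
# embedded to a fixed length; a gating attention scores the embedded queries
# against the embedded inputs (scaled dot product, row softmax) and the
# score-weighted values pass through two strided convolutions on the token
# grid and a final single-head attention layer.

#' Encoder configuration
#'
#' @param embed_dim token embedding length (default 64); must equal the
#'   transformer latent dimension downstream.
#' @param conv_filters integer pair of filter counts for the two convolution
#'   layers (default `c(32, 64)`); the second must equal `embed_dim` so the
#'   token dimension is preserved.
#' @param conv_kernel convolution kernel edge (default 3).
#' @param conv_stride convolution stride (default 3); the strided output is
#'   upsampled back to the token grid by nearest neighbor, so the token count
#'   never changes.
#' @return an object of class `encoder_config`.
#' @export
encoder_config <- function(embed_dim = 64L, conv_filters = c(32L, 64L),
                           conv_kernel = 3L, conv_stride = 3L) {
  cfg <- list(embed_dim = as.integer(embed_dim),
              conv_filters = as.integer(conv_filters),
              conv_kernel = as.integer(conv_kernel),
              conv_stride = as.integer(conv_stride),
              attention_heads = 1L)
  if (cfg$embed_dim < 1L || any(cfg$conv_filters < 1L))
    stop("embed_dim and conv_filters must be positive")
  if (length(cfg$conv_filters) != 2L)
    stop("conv_filters must be an integer pair")
  if (cfg$conv_filters[2] != cfg$embed_dim)
    stop("the second convolution filter count must equal embed_dim")
  class(cfg) <- "encoder_config"
  cfg
}

#' Sliding-box query stream for a patch grid
#'
#' Re-windows the (padded) image with 50% overlap (stride `patch_size/2`),
#' giving `(2*rows-1) * (2*cols-1)` windows in row-major order, then selects
#' `N = rows*cols` of them by nearest-index resampling of the flat window
#' sequence so the query stream aligns one-to-one with the input stream.
#'
#' @param grid a `patch_grid` from [extract_patches].
#' @return a `patch_grid`-like object whose `patches` are the selected query
#'   windows (`n_windows` records the pre-resampling count).
#' @export
sliding_box_queries <- function(grid) {
  stopifnot(inherits(grid, "patch_grid"))
  p <- grid$patch_size
  img <- assemble_patches(grid)
  stride <- max(1L, p %/% 2L)
  wr <- 2L * grid$grid_rows - 1L
  wc <- 2L * grid$grid_cols - 1L
  wins <- vector("list", wr * wc)
  t <- 0L
  for (i in seq_len(wr)) for (j in seq_len(wc)) {
    t <- t + 1L
    wins[[t]] <- img[(i - 1L) * stride + seq_len(p),
                     (j - 1L) * stride + seq_len(p), drop = FALSE]
  }
  n <- grid$grid_rows * grid$grid_cols
  sel <- round(seq(1, length(wins), length.out = n))
  structure(list(patches = wins[sel], grid_rows = grid$grid_rows,
                 grid_cols = grid$grid_cols, patch_size = p,
                 n_windows = length(wins)), class = "patch_grid")
}

# Patch-embedding initialization: a low-frequency 2-D cosine basis. Speckle
# is high-frequency multiplicative noise, while lesions and tissue bands are
# coarse intensity structure, so starting the embedding on smooth modes (the
# first one is the patch mean) gives training a speckle-robust signal from
# step one; a purely random projection buries that signal under the noise
# directions and stalls optimization at desk scale.
dct_embedding <- function(patch_size, e) {
  n_modes <- ceiling(sqrt(e))
  basis <- matrix(0, patch_size^2, n_modes^2)
  t <- (seq_len(patch_size) - 0.5) / patch_size
  col <- 0L
  for (u in 0:(n_modes - 1L)) for (v in 0:(n_modes - 1L)) {
    col <- col + 1L
    b2 <- outer(cos(pi * u * t), cos(pi * v * t))
    basis[, col] <- as.vector(b2) / sqrt(sum(b2^2))
  }
  # order modes by total frequency so truncation keeps the smoothest ones
  ord <- order(outer(0:(n_modes - 1L), 0:(n_modes - 1L), `+`))
  basis[, ord[seq_len(e)], drop = FALSE]
}

init_encoder_state <- function(cfg, patch_px) {
  e <- cfg$embed_dim; f1 <- cfg$conv_filters[1]; f2 <- cfg$conv_filters[2]
  k <- cfg$conv_kernel
  # The query/key maps of both attention stages start from the same weights,
  # so the initial logits are Gram matrices: diagonal-dominant, hence the
  # attention starts near a content-matching (identity-like) operator instead
  # of a uniform average. A uniform start would collapse every token onto the
  # patch mean and erase the spatial signal the box head has to learn from.
  ps <- round(sqrt(patch_px))
  emb <- if (ps * ps == patch_px) {
    dct_embedding(ps, e) + glorot(patch_px, e) * 0.1
  } else glorot(patch_px, e)
  wq <- glorot(e, e)
  # The value/output maps of the final attention start identity-biased so the
  # attention stage is token-preserving at step 0; the convolutions stay
  # fully random — with stride 3 every window tap contributes with its own
  # weights, which is what keeps all patch content recoverable downstream.
  eye <- function(n) diag(n) + glorot(n, n) * 0.1
  list(
    emb_in_W = emb, emb_in_b = numeric(e),
    emb_q_W = emb, emb_q_b = numeric(e),
    conv1_W = glorot(k * k * e, f1), conv1_b = numeric(f1),
    conv2_W = glorot(k * k * f1, f2), conv2_b = numeric(f2),
    att_Wq = wq, att_bq = numeric(e),
    att_Wk = wq, att_bk = numeric(e),
    att_Wv = eye(e), att_bv = numeric(e),
    att_Wo = eye(e), att_bo = numeric(e))
}

#' Attention-gated encoding of a patch grid
#'
#' @param inputs patch grid (or `N x P^2` matrix) of input patches.
#' @param queries matching query stream from [sliding_box_queries].
#' @param cfg an [encoder_config].
#' @param state encoder parameter list (see `init_encoder_state`).
#' @param grid_rows,grid_cols token grid shape (taken from `inputs` when it
#'   is a `patch_grid`).
#' @return list with `tokens` (`N x embed_dim`) and `attention_weights`
#'   (`N x N`, rows summing to 1) of class `encoded_patches`; `cache` holds
#'   intermediates for the backward pass.
#' @export
gated_attention <- function(inputs, queries, cfg, state,
                            grid_rows = NULL, grid_cols = NULL) {
  if (inherits(inputs, "patch_grid")) {
    grid_rows <- inputs$grid_rows; grid_cols <- inputs$grid_cols
    xin <- patches_matrix(inputs$patches, inputs$patch_size)
  } else xin <- as.matrix(inputs)
  xq <- if (inherits(queries, "patch_grid"))
    patches_matrix(queries$patches, queries$patch_size) else as.matrix(queries)
  if (nrow(xin) != nrow(xq) || ncol(xin) != ncol(xq))
    stop("input and query streams must have matching shapes")
  if (is.null(grid_rows) || is.null(grid_cols))
    stop("grid shape required when passing plain matrices")
  n <- nrow(xin); e <- cfg$embed_dim
  k <- cfg$conv_kernel; s <- cfg$conv_stride

  xe <- dense_fwd(xin, state$emb_in_W, state$emb_in_b)
  qe <- dense_fwd(xq, state$emb_q_W, state$emb_q_b)
  gate <- scaled_dot_attention(qe, xe, xe)          # scores queries vs inputs
  g <- gate$out                                     # N x e

  # row-major token layout -> (rows, cols, channels) array
  garr <- aperm(array(t(g), c(e, grid_cols, grid_rows)), c(3, 2, 1))
  c1 <- conv2d_fwd(garr, state$conv1_W, state$conv1_b, k, s)
  a1 <- gelu(c1$out)
  u1 <- upsample_nn_fwd(a1, grid_rows, grid_cols)
  c2 <- conv2d_fwd(u1$out, state$conv2_W, state$conv2_b, k, s)
  a2 <- gelu(c2$out)
  u2 <- upsample_nn_fwd(a2, grid_rows, grid_cols)
  tt <- t(matrix(aperm(u2$out, c(3, 2, 1)), e, n))  # back to token matrix

  aq <- dense_fwd(tt, state$att_Wq, state$att_bq)
  ak <- dense_fwd(tt, state$att_Wk, state$att_bk)
  av <- dense_fwd(tt, state$att_Wv, state$att_bv)
  at2 <- scaled_dot_attention(aq, ak, av)
  tokens <- dense_fwd(at2$out, state$att_Wo, state$att_bo)

  structure(list(tokens = tokens, attention_weights = at2$weights,
                 cache = list(xin = xin, xq = xq, xe = xe, qe = qe,
                              gate_p = gate$weights, g = g, garr = garr,
                              c1 = c1, a1_in = c1$out, u1 = u1,
                              c2 = c2, a2_in = c2$out, u2 = u2, tt = tt,
                              aq = aq, ak = ak, av = av, at2 = at2,
                              grid_rows = grid_rows, grid_cols = grid_cols)),
            class = "encoded_patches")
}

gated_attention_bwd <- function(enc, cfg, state, dtokens) {
  ca <- enc$cache
  e <- cfg$embed_dim; k <- cfg$conv_kernel; s <- cfg$conv_stride
  gr <- ca$grid_rows; gc <- ca$grid_cols
  gds <- list()

  go <- dense_bwd(ca$at2$out, state$att_Wo, dtokens)
  gds$att_Wo <- go$dW; gds$att_bo <- go$db
  ga <- scaled_dot_attention_bwd(ca$aq, ca$ak, ca$av, ca$at2$weights, go$dx)
  gq <- dense_bwd(ca$tt, state$att_Wq, ga$dq)
  gk <- dense_bwd(ca$tt, state$att_Wk, ga$dk)
  gv <- dense_bwd(ca$tt, state$att_Wv, ga$dv)
  gds$att_Wq <- gq$dW; gds$att_bq <- gq$db
  gds$att_Wk <- gk$dW; gds$att_bk <- gk$db
  gds$att_Wv <- gv$dW; gds$att_bv <- gv$db
  dtt <- gq$dx + gk$dx + gv$dx

  du2 <- aperm(array(t(dtt), c(e, gc, gr)), c(3, 2, 1))
  da2 <- upsample_nn_bwd(du2, dim(ca$a2_in)[1], dim(ca$a2_in)[2], ca$u2)
  dc2 <- da2 * gelu_grad(ca$a2_in)
  g2 <- conv2d_bwd(ca$u1$out, state$conv2_W, ca$c2, k, s, dc2)
  gds$conv2_W <- g2$dW; gds$conv2_b <- g2$db
  da1 <- upsample_nn_bwd(g2$da, dim(ca$a1_in)[1], dim(ca$a1_in)[2], ca$u1)
  dc1 <- da1 * gelu_grad(ca$a1_in)
  g1 <- conv2d_bwd(ca$garr, state$conv1_W, ca$c1, k, s, dc1)
  gds$conv1_W <- g1$dW; gds$conv1_b <- g1$db

  dg <- t(matrix(aperm(g1$da, c(3, 2, 1)), e, nrow(ca$g)))
  gg <- scaled_dot_attention_bwd(ca$qe, ca$xe, ca$xe, ca$gate_p, dg)
  dxe <- gg$dk + gg$dv
  gi <- dense_bwd(ca$xin, state$emb_in_W, dxe)
  gq2 <- dense_bwd(ca$xq, state$emb_q_W, gg$dq)
  gds$emb_in_W <- gi$dW; gds$emb_in_b <- gi$db
  gds$emb_q_W <- gq2$dW; gds$emb_q_b <- gq2$db
  gds
}
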