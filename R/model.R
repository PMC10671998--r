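# Detector trunk: positional embedding, pre-norm transformer blocks, and the
# box-regression head on the summary token.

#' Detector model configuration
#'
#' @param n_blocks number of transformer blocks (default 8).
#' @param n_heads attention heads per block (default 4); must divide
#'   `latent_dim`.
#' @param latent_dim token dimension D (default 64); must equal the encoder's
#'   `embed_dim`.
#' @param mlp_units hidden widths of the in-block MLP and of the box head
#'   (default `c(128, 64)`).
#' @param dropout dropout rate during training (default 0.1).
#' @param max_boxes box-array capacity K regressed per image (default 3).
#' @param patch_size patch edge in pixels (default 32).
#' @param image_height,image_width working resolution the detector expects;
#'   inputs of other sizes are resized. Default 250 x 250.
#' @param encoder an [encoder_config]; its `embed_dim` must equal
#'   `latent_dim`.
#' @param denoiser optional pre-processing hook, a function `matrix ->
#'   matrix` applied to the image before patching (identity by default);
#'   intended for plugging in an external denoiser.
#' @return an object of class `model_config`.
#' @export
model_config <- function(n_blocks = 8L, n_heads = 4L, latent_dim = 64L,
                         mlp_units = c(128L, 64L), dropout = 0.1,
                         max_boxes = 3L, patch_size = 32L,
                         image_height = 250L, image_width = 250L,
                         encoder = encoder_config(embed_dim = latent_dim),
                         denoiser = NULL) {
  cfg <- list(n_blocks = as.integer(n_blocks), n_heads = as.integer(n_heads),
              latent_dim = as.integer(latent_dim),
              mlp_units = as.integer(mlp_units), dropout = as.numeric(dropout),
              max_boxes = as.integer(max_boxes),
              patch_size = as.integer(patch_size),
              image_height = as.integer(image_height),
              image_width = as.integer(image_width),
              encoder = encoder, denoiser = denoiser)
  if (cfg$latent_dim %% cfg$n_heads != 0L)
    stop("latent_dim must be divisible by n_heads")
  if (cfg$max_boxes < 1L) stop("max_boxes must be >= 1")
  if (cfg$encoder$embed_dim != cfg$latent_dim)
    stop("encoder embed_dim must equal latent_dim")
  if (length(cfg$mlp_units) < 1L) stop("mlp_units must list at least one width")
  cfg$grid_rows <- ceiling(cfg$image_height / cfg$patch_size)
  cfg$grid_cols <- ceiling(cfg$image_width / cfg$patch_size)
  cfg$n_tokens <- cfg$grid_rows * cfg$grid_cols
  class(cfg) <- "model_config"
  cfg
}

#' Initialize detector parameters
#'
#' Glorot-uniform weights, zero biases, unit LayerNorm gains; the positional
#' table and summary token start as small Gaussian noise. Shapes are fully
#' determined by the configuration.
#'
#' @param cfg a [model_config].
#' @param seed integer RNG seed.
#' @return a named list of parameter arrays (the model state).
#' @export
init_model_state <- function(cfg, seed = 1L) {
  with_seed(seed, {
    d <- cfg$latent_dim
    n <- cfg$n_tokens
    patch_px <- cfg$patch_size^2
    st <- list(enc = init_encoder_state(cfg$encoder, patch_px),
               cls = matrix(stats::rnorm(d, sd = 0.02), 1, d),
               pos = matrix(stats::rnorm((n + 1) * d, sd = 0.02), n + 1, d))
    st$blocks <- lapply(seq_len(cfg$n_blocks), function(l) {
      widths <- c(d, cfg$mlp_units, d)
      mlp <- lapply(seq_len(length(widths) - 1L), function(i)
        list(W = glorot(widths[i], widths[i + 1]), b = numeric(widths[i + 1])))
      list(ln1_g = rep(1, d), ln1_b = numeric(d),
           att = list(Wq = glorot(d, d), bq = numeric(d),
                      Wk = glorot(d, d), bk = numeric(d),
                      Wv = glorot(d, d), bv = numeric(d),
                      Wo = glorot(d, d), bo = numeric(d)),
           ln2_g = rep(1, d), ln2_b = numeric(d),
           mlp = mlp)
    })
    st$ln_f_g <- rep(1, d); st$ln_f_b <- numeric(d)
    widths <- c(d, cfg$mlp_units, 4L * cfg$max_boxes)
    st$head <- lapply(seq_len(length(widths) - 1L), function(i)
      list(W = glorot(widths[i], widths[i + 1]), b = numeric(widths[i + 1])))
    st
  })
}

#' Prepend the summary token and add positional embeddings
#'
#' @param tokens `N x D` matrix of encoded patch tokens (or an
#'   `encoded_patches` object).
#' @param state model state (uses `state$cls` and `state$pos`).
#' @return `(N+1) x D` matrix `z0`.
#' @export
embed_with_positions <- function(tokens, state) {
  if (inherits(tokens, "encoded_patches")) tokens <- tokens$tokens
  if (ncol(tokens) != ncol(state$pos))
    stop("token dimension does not match the positional table")
  z <- rbind(state$cls, tokens)
  if (nrow(z) != nrow(state$pos))
    stop("token count does not match the positional table")
  z + state$pos
}

#' One pre-norm transformer block
#'
#' `z' = z + MSA(LN(z))`, `z_out = z' + MLP(LN(z'))` with GELU nonlinearity
#' in the MLP; dropout (when `train=TRUE`) on the MSA and MLP outputs.
#'
#' @param z `(N+1) x D` input tokens.
#' @param block one element of `state$blocks`.
#' @param cfg a [model_config].
#' @param train apply dropout draws from the current RNG.
#' @return list with `z` (output tokens) and `cache` for backprop.
#' @export
transformer_block <- function(z, block, cfg, train = FALSE) {
  ln1 <- layernorm_fwd(z, block$ln1_g, block$ln1_b)
  ms <- msa_fwd(ln1$y, block$att, cfg$n_heads)
  m1 <- if (train) dropout_mask(dim(ms$y), cfg$dropout) else NULL
  ato <- if (is.null(m1)) ms$y else ms$y * m1
  z1 <- z + ato
  ln2 <- layernorm_fwd(z1, block$ln2_g, block$ln2_b)
  hs <- list(); x <- ln2$y
  for (i in seq_along(block$mlp)) {
    pre <- dense_fwd(x, block$mlp[[i]]$W, block$mlp[[i]]$b)
    hs[[i]] <- list(x = x, pre = pre)
    x <- if (i < length(block$mlp)) gelu(pre) else pre
  }
  m2 <- if (train) dropout_mask(dim(x), cfg$dropout) else NULL
  mlpo <- if (is.null(m2)) x else x * m2
  list(z = z1 + mlpo,
       cache = list(ln1 = ln1, ms = ms, m1 = m1, z1 = z1, ln2 = ln2,
                    hs = hs, m2 = m2))
}

transformer_block_bwd <- function(block, cfg, cache, dz_out) {
  g <- list(mlp = vector("list", length(block$mlp)))
  dmlpo <- if (is.null(cache$m2)) dz_out else dz_out * cache$m2
  dx <- dmlpo
  for (i in rev(seq_along(block$mlp))) {
    if (i < length(block$mlp)) dx <- dx * gelu_grad(cache$hs[[i]]$pre)
    gb <- dense_bwd(cache$hs[[i]]$x, block$mlp[[i]]$W, dx)
    g$mlp[[i]] <- list(W = gb$dW, b = gb$db)
    dx <- gb$dx
  }
  ln2g <- layernorm_bwd(cache$ln2, block$ln2_g, dx)
  g$ln2_g <- ln2g$dg; g$ln2_b <- ln2g$db
  dz1 <- dz_out + ln2g$dx
  dato <- if (is.null(cache$m1)) dz1 else dz1 * cache$m1
  msg <- msa_bwd(cache$ln1$y, block$att, cache$ms, cfg$n_heads, dato)
  g$att <- list(Wq = msg$dWq, bq = msg$dbq, Wk = msg$dWk, bk = msg$dbk,
                Wv = msg$dWv, bv = msg$dbv, Wo = msg$dWo, bo = msg$dbo)
  ln1g <- layernorm_bwd(cache$ln1, block$ln1_g, msg$dx)
  g$ln1_g <- ln1g$dg; g$ln1_b <- ln1g$db
  g$dz <- dz1 + ln1g$dx
  g
}

# Full forward pass: image -> K x 4 box matrix (sigmoid coordinates, each
# box's coordinate pairs sorted so x_min <= x_max and y_min <= y_max).
# Returns the cache needed for backprop when train-time gradients are wanted.
detector_forward <- function(img, state, cfg, train = FALSE) {
  px <- if (inherits(img, "scan_image")) img$pixels else as.matrix(img)
  if (!is.null(cfg$denoiser)) px <- cfg$denoiser(px)
  if (nrow(px) != cfg$image_height || ncol(px) != cfg$image_width)
    px <- resize_image(scan_image(px), cfg$image_height, cfg$image_width)$pixels
  # per-image standardization: raw [0,1] patch vectors are dominated by their
  # shared mean component, which washes out the attention logits; zero-mean
  # unit-variance input conditions the encoder on image content immediately
  px <- (px - mean(px)) / (stats::sd(px) + 1e-8)
  grid <- extract_patches(px, cfg$patch_size)
  queries <- sliding_box_queries(grid)
  enc <- gated_attention(grid, queries, cfg$encoder, state$enc)
  z <- embed_with_positions(enc$tokens, state)
  bcaches <- vector("list", cfg$n_blocks)
  for (l in seq_len(cfg$n_blocks)) {
    tb <- transformer_block(z, state$blocks[[l]], cfg, train = train)
    z <- tb$z; bcaches[[l]] <- tb$cache
  }
  lnf <- layernorm_fwd(z, state$ln_f_g, state$ln_f_b)
  u <- lnf$y[1, , drop = FALSE]                       # summary token
  hs <- list(); x <- u
  for (i in seq_along(state$head)) {
    pre <- dense_fwd(x, state$head[[i]]$W, state$head[[i]]$b)
    hs[[i]] <- list(x = x, pre = pre)
    x <- if (i < length(state$head)) gelu(pre) else pre
  }
  p <- 1 / (1 + exp(-x))                              # sigmoid, 1 x 4K
  raw <- matrix(p, cfg$max_boxes, 4L, byrow = TRUE)   # (x1, y1, x2, y2)
  boxes <- cbind(pmin(raw[, 1], raw[, 3]), pmin(raw[, 2], raw[, 4]),
                 pmax(raw[, 1], raw[, 3]), pmax(raw[, 2], raw[, 4]))
  colnames(boxes) <- c("x_min", "y_min", "x_max", "y_max")
  list(boxes = boxes, raw = raw, p = as.vector(p),
       cache = list(enc = enc, bcaches = bcaches, lnf = lnf, hs = hs,
                    n_tokens = nrow(z) - 1L))
}

# Backward pass: dboxes is the K x 4 gradient in sorted-coordinate space.
# Returns a gradient structure parallel to `state`.
detector_backward <- function(state, cfg, fw, dboxes) {
  raw <- fw$raw
  draw <- matrix(0, nrow(raw), 4L)
  xflip <- raw[, 1] > raw[, 3]   # sort permutation per box
  yflip <- raw[, 2] > raw[, 4]
  draw[, 1] <- ifelse(xflip, dboxes[, 3], dboxes[, 1])
  draw[, 3] <- ifelse(xflip, dboxes[, 1], dboxes[, 3])
  draw[, 2] <- ifelse(yflip, dboxes[, 4], dboxes[, 2])
  draw[, 4] <- ifelse(yflip, dboxes[, 2], dboxes[, 4])
  dp <- as.vector(t(draw))                       # 4K, matches head output order
  p <- fw$p
  dx <- matrix(dp * p * (1 - p), 1)              # through the sigmoid

  g <- list(head = vector("list", length(state$head)))
  hs <- fw$cache$hs
  for (i in rev(seq_along(state$head))) {
    if (i < length(state$head)) dx <- dx * gelu_grad(hs[[i]]$pre)
    gb <- dense_bwd(hs[[i]]$x, state$head[[i]]$W, dx)
    g$head[[i]] <- list(W = gb$dW, b = gb$db)
    dx <- gb$dx
  }
  dlnf_y <- matrix(0, fw$cache$n_tokens + 1L, cfg$latent_dim)
  dlnf_y[1, ] <- dx
  lng <- layernorm_bwd(fw$cache$lnf, state$ln_f_g, dlnf_y)
  g$ln_f_g <- lng$dg; g$ln_f_b <- lng$db
  dz <- lng$dx
  g$blocks <- vector("list", cfg$n_blocks)
  for (l in rev(seq_len(cfg$n_blocks))) {
    bg <- transformer_block_bwd(state$blocks[[l]], cfg, fw$cache$bcaches[[l]], dz)
    dz <- bg$dz; bg$dz <- NULL
    g$blocks[[l]] <- bg
  }
  g$pos <- dz
  g$cls <- dz[1, , drop = FALSE]
  dtokens <- dz[-1, , drop = FALSE]
  g$enc <- gated_attention_bwd(fw$cache$enc, cfg$encoder, state$enc, dtokens)
  g
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single RDS file holding the configuration and all
#' parameter arrays; loading restores bit-identical inference.
#'
#' @param state model state (or an `octdetect` fit, whose state is taken).
#' @param cfg the [model_config] (ignored when `state` is a fit).
#' @param path destination file.
#' @export
save_checkpoint <- function(state, cfg, path) {
  if (inherits(state, "octdetect")) {
    cfg <- state$model; state <- state$state
  }
  cfg$denoiser <- NULL  # closures are not portable; rearm on load if needed
  saveRDS(list(format = "octdetect-checkpoint-1", config = unclass(cfg),
               state = state), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @return `load_checkpoint`: list with elements `state` and `config`.
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "octdetect-checkpoint-1"))
    stop("not an octdetect checkpoint: ", path)
  cfg <- obj$config
  class(cfg) <- "model_config"
  class(cfg$encoder) <- "encoder_config"
  list(state = obj$state, config = cfg)
}
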