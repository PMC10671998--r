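# Transformer trunk and box head.

test_that("positional embedding prepends the summary token", {
  cfg <- tiny_config()
  st <- init_model_state(cfg, seed = 2)
  n <- cfg$n_tokens
  tokens <- matrix(rnorm(n * 8), n, 8)
  z0 <- embed_with_positions(tokens, st)
  expect_equal(dim(z0), c(n + 1, 8))
  # zero positional table: z0 = [cls; tokens]
  st0 <- st; st0$pos <- st$pos * 0
  z00 <- embed_with_positions(tokens, st0)
  expect_equal(z00[1, ], as.vector(st$cls))
  expect_equal(z00[-1, ], tokens)
  expect_error(embed_with_positions(matrix(0, n + 5, 8), st), "token count")
  expect_error(embed_with_positions(matrix(0, n, 4), st), "dimension")
})

test_that("a zero-weight transformer block is the identity map", {
  cfg <- tiny_config()
  st <- init_model_state(cfg, seed = 3)
  blk <- octdetect:::map_params(st$blocks[[1]], f = function(p) p * 0)
  blk$ln1_g <- rep(1, 8); blk$ln2_g <- rep(1, 8)  # LN gains stay at 1
  z <- matrix(rnorm(5 * 8), 5, 8)
  # attention and MLP weights are zero, so both residual branches vanish
  out <- transformer_block(z, blk, cfg, train = FALSE)
  expect_equal(out$z, z, tolerance = 1e-12)
})

test_that("layer normalization standardizes every token", {
  z <- matrix(rnorm(6 * 8, mean = 3, sd = 2), 6, 8)
  ln <- octdetect:::layernorm_fwd(z, rep(1, 8), rep(0, 8))
  expect_equal(rowMeans(ln$y), rep(0, 6), tolerance = 1e-5)
  expect_equal(apply(ln$y, 1, function(r) mean(r^2)), rep(1, 6),
               tolerance = 1e-5)
})

test_that("a single-token single-head block matches straight-line arithmetic", {
  cfg <- model_config(n_blocks = 1, n_heads = 1, latent_dim = 2,
                      mlp_units = 2, dropout = 0, max_boxes = 1,
                      patch_size = 8, image_height = 8, image_width = 8,
                      encoder = encoder_config(embed_dim = 2, conv_filters = c(2, 2)))
  blk <- list(ln1_g = c(1, 1), ln1_b = c(0, 0),
              att = list(Wq = matrix(c(1, 0.5, -0.5, 1), 2, 2), bq = c(0, 0),
                         Wk = matrix(c(0.2, 0, 0, 0.2), 2, 2), bk = c(0, 0),
                         Wv = matrix(c(1, 2, 3, 4), 2, 2), bv = c(0, 0),
                         Wo = diag(2), bo = c(0, 0)),
              ln2_g = c(1, 1), ln2_b = c(0, 0),
              mlp = list(list(W = matrix(c(1, -1, 0.5, 0.5), 2, 2), b = c(0.1, -0.1)),
                         list(W = diag(2), b = c(0, 0))))
  z <- matrix(c(1.4, -0.6), 1, 2)
  out <- transformer_block(z, blk, cfg, train = FALSE)
  # by hand: LN of (1.4, -0.6) -> ~(1, -1) (mean 0.4, sd 1, ridge eps 1e-6)
  ln1 <- c(1, -1) / sqrt(1 + 1e-6)
  # single token: softmax over one logit = 1, so attention output = v
  v <- as.vector(ln1 %*% blk$att$Wv)          # (1*1 + -1*2, 1*3 + -1*4) = (-1, -1)
  z1 <- z + v %*% diag(2)
  mu <- mean(z1); sdv <- sqrt(mean((z1 - mu)^2) + 1e-6)
  ln2 <- (z1 - mu) / sdv
  h <- as.vector(ln2 %*% blk$mlp[[1]]$W) + c(0.1, -0.1)
  gelu_h <- h * pnorm(h)
  mlp_out <- gelu_h  # second layer is identity
  expect_equal(out$z, z1 + matrix(mlp_out, 1), tolerance = 1e-9)
})

test_that("the forward pass emits exactly K valid boxes, deterministically", {
  cfg <- tiny_config(max_boxes = 3)
  st <- init_model_state(cfg, seed = 4)
  set.seed(50)
  img <- matrix(runif(32 * 32), 32, 32)
  fw1 <- octdetect:::detector_forward(img, st, cfg)
  fw2 <- octdetect:::detector_forward(img, st, cfg)
  expect_equal(dim(fw1$boxes), c(3, 4))
  expect_true(all(fw1$boxes >= 0 & fw1$boxes <= 1))
  expect_true(all(fw1$boxes[, 1] <= fw1$boxes[, 3]))
  expect_true(all(fw1$boxes[, 2] <= fw1$boxes[, 4]))
  expect_identical(fw1$boxes, fw2$boxes)  # inference is pure
  # output responds to the input
  outs <- vapply(1:30, function(i) {
    octdetect:::detector_forward(matrix(runif(32 * 32), 32, 32), st, cfg)$boxes[1, 1]
  }, 0)
  expect_gt(stats::sd(outs), 0)
  # shape is invariant to content
  fw3 <- octdetect:::detector_forward(matrix(0, 32, 32), st, cfg)
  expect_equal(dim(fw3$boxes), dim(fw1$boxes))
})

test_that("the forward pass matches an independent straight-line
           re-implementation", {
  cfg <- tiny_config(n_blocks = 1, max_boxes = 1)
  st <- init_model_state(cfg, seed = 9)
  set.seed(60)
  img <- matrix(runif(32 * 32), 32, 32)
  fw <- octdetect:::detector_forward(img, st, cfg)

  # ---- plain array arithmetic, no shared helpers ----------------------------
  px <- (img - mean(img)) / sd(img)
  P <- 16; e <- 8
  # patches, row-major, column-major flattening inside each patch
  pats <- list(px[1:16, 1:16], px[1:16, 17:32], px[17:32, 1:16], px[17:32, 17:32])
  X <- do.call(rbind, lapply(pats, as.vector))
  # queries: 3x3 overlapping windows, flat row-major, nearest-index resample to 4
  wins <- list()
  for (i in 0:2) for (j in 0:2)
    wins[[length(wins) + 1]] <- px[i * 8 + 1:16, j * 8 + 1:16]
  sel <- round(seq(1, 9, length.out = 4))
  Q <- do.call(rbind, lapply(wins[sel], as.vector))
  es <- st$enc
  softmax <- function(r) { r <- exp(r - max(r)); r / sum(r) }
  Xe <- X %*% es$emb_in_W + matrix(es$emb_in_b, 4, e, byrow = TRUE)
  Qe <- Q %*% es$emb_q_W + matrix(es$emb_q_b, 4, e, byrow = TRUE)
  S <- Qe %*% t(Xe) / sqrt(e)
  Pw <- t(apply(S, 1, softmax))
  G <- Pw %*% Xe
  # conv stage: 2x2 token grid, 3x3 kernel stride 3 -> 1x1 output, pad to 3x3
  garr <- array(0, c(2, 2, e))
  for (ch in 1:e) garr[, , ch] <- matrix(G[, ch], 2, 2, byrow = TRUE)
  gelu_f <- function(x) x * pnorm(x)
  conv1x1 <- function(a, W, b, cin, cout) {
    # same padding for stride 3 on a 2x2 grid: one 3x3 window anchored at the
    # origin, one replicated row/column at the bottom/right (floor rule puts
    # the single pad after the data)
    padded <- array(0, c(3, 3, cin))
    for (ci in seq_len(cin))
      padded[, , ci] <- a[c(1, 2, 2), c(1, 2, 2), ci]
    out <- numeric(cout)
    for (co in 1:cout) {
      idx <- 0; acc <- 0
      for (dj in 1:3) for (di in 1:3) for (ci in 1:cin) {
        idx <- idx + 1
        acc <- acc + padded[di, dj, ci] * W[idx, co]
      }
      out[co] <- acc + b[co]
    }
    out
  }
  c1 <- gelu_f(conv1x1(garr, es$conv1_W, es$conv1_b, 8, 4))
  u1 <- array(rep(c1, each = 4), c(2, 2, 4))          # nearest upsample
  c2 <- gelu_f(conv1x1(u1, es$conv2_W, es$conv2_b, 4, 8))
  TT <- matrix(c2, 4, 8, byrow = TRUE)                # all tokens equal
  Aq <- TT %*% es$att_Wq + matrix(es$att_bq, 4, 8, byrow = TRUE)
  Ak <- TT %*% es$att_Wk + matrix(es$att_bk, 4, 8, byrow = TRUE)
  Av <- TT %*% es$att_Wv + matrix(es$att_bv, 4, 8, byrow = TRUE)
  S2 <- Aq %*% t(Ak) / sqrt(8)
  P2 <- t(apply(S2, 1, softmax))
  tokens <- P2 %*% Av %*% es$att_Wo + matrix(es$att_bo, 4, 8, byrow = TRUE)
  z <- rbind(st$cls, tokens) + st$pos
  lnorm <- function(zz, g, b) t(apply(zz, 1, function(r)
    (r - mean(r)) / sqrt(mean((r - mean(r))^2) + 1e-6))) *
    matrix(g, nrow(zz), length(g), byrow = TRUE) +
    matrix(b, nrow(zz), length(b), byrow = TRUE)
  blk <- st$blocks[[1]]
  a1 <- lnorm(z, blk$ln1_g, blk$ln1_b)
  qm <- a1 %*% blk$att$Wq + matrix(blk$att$bq, 5, 8, byrow = TRUE)
  km <- a1 %*% blk$att$Wk + matrix(blk$att$bk, 5, 8, byrow = TRUE)
  vm <- a1 %*% blk$att$Wv + matrix(blk$att$bv, 5, 8, byrow = TRUE)
  o <- matrix(0, 5, 8)
  for (hh in 1:2) {
    cols <- (hh - 1) * 4 + 1:4
    sh <- qm[, cols] %*% t(km[, cols]) / sqrt(4)
    ph <- t(apply(sh, 1, softmax))
    o[, cols] <- ph %*% vm[, cols]
  }
  z1 <- z + o %*% blk$att$Wo + matrix(blk$att$bo, 5, 8, byrow = TRUE)
  b1 <- lnorm(z1, blk$ln2_g, blk$ln2_b)
  h1 <- gelu_f(b1 %*% blk$mlp[[1]]$W + matrix(blk$mlp[[1]]$b, 5, 16, byrow = TRUE))
  h2 <- gelu_f(h1 %*% blk$mlp[[2]]$W + matrix(blk$mlp[[2]]$b, 5, 8, byrow = TRUE))
  z2 <- z1 + h2 %*% blk$mlp[[3]]$W + matrix(blk$mlp[[3]]$b, 5, 8, byrow = TRUE)
  zf <- lnorm(z2, st$ln_f_g, st$ln_f_b)
  u <- zf[1, , drop = FALSE]
  hh1 <- gelu_f(u %*% st$head[[1]]$W + st$head[[1]]$b)
  hh2 <- gelu_f(hh1 %*% st$head[[2]]$W + st$head[[2]]$b)
  oo <- hh2 %*% st$head[[3]]$W + st$head[[3]]$b
  pr <- 1 / (1 + exp(-as.vector(oo)))
  box <- c(min(pr[1], pr[3]), min(pr[2], pr[4]), max(pr[1], pr[3]), max(pr[2], pr[4]))
  # BLAS matmuls and scalar loops accumulate in different orders
  expect_equal(as.vector(fw$boxes[1, ]), box, tolerance = 1e-6)
})

test_that("backpropagated gradients match finite differences and are finite", {
  cfg <- tiny_config(n_blocks = 1, max_boxes = 1)
  st <- init_model_state(cfg, seed = 5)
  set.seed(70)
  img <- matrix(runif(32 * 32), 32, 32)
  act <- matrix(c(0.2, 0.3, 0.6, 0.7), 1, 4)
  fw <- octdetect:::detector_forward(img, st, cfg)
  dbox <- octdetect:::lloss_grad(fw$boxes, act)
  g <- octdetect:::detector_backward(st, cfg, fw, dbox)
  fl_s <- octdetect:::flatten_params(st)
  fl_g <- octdetect:::flatten_params(g)
  expect_setequal(names(fl_g), names(fl_s))
  expect_true(all(vapply(fl_g, function(x) all(is.finite(x)), TRUE)))
  lossfun <- function(state) {
    f <- octdetect:::detector_forward(img, state, cfg)
    lloss(f$boxes, act)$l_total
  }
  poke <- function(state, nm, e, val) {
    fl <- octdetect:::flatten_params(state)
    # walk the path and bump one element
    path <- strsplit(sub("^/", "", nm), "/", fixed = TRUE)[[1]]
    ref <- state
    expr <- "state"
    for (p in path) {
      key <- if (startsWith(p, "[")) as.integer(gsub("[][]", "", p)) else p
      expr <- if (is.character(key)) paste0(expr, "[[\"", key, "\"]]")
      else paste0(expr, "[[", key, "]]")
    }
    eval(parse(text = paste0(expr, "[", e, "] <- ", expr, "[", e, "] + ", val)))
    state
  }
  h <- 1e-5
  set.seed(71)
  picks <- sample(names(fl_s), 12)
  for (nm in picks) {
    e <- sample(length(fl_s[[nm]]), 1)
    fd <- (lossfun(poke(st, nm, e, h)) - lossfun(poke(st, nm, e, -h))) / (2 * h)
    expect_equal(fl_g[[nm]][e], fd, tolerance = 1e-3)
  }
})

test_that("checkpoints restore bit-identical inference", {
  cfg <- tiny_config(max_boxes = 2)
  st <- init_model_state(cfg, seed = 8)
  set.seed(80)
  img <- matrix(runif(32 * 32), 32, 32)
  before <- octdetect:::detector_forward(img, st, cfg)$boxes
  f <- tempfile(fileext = ".rds")
  save_checkpoint(st, cfg, f)
  ck <- load_checkpoint(f)
  after <- octdetect:::detector_forward(img, ck$state, ck$config)$boxes
  expect_identical(before, after)
  expect_error(load_checkpoint(system.file("DESCRIPTION", package = "octdetect")))
})
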