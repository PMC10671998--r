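# Composite training loss on matched box arrays:
#   total = mean(L_MSE, L_difference, L_IOU)
# where L_MSE is the coordinate mean squared error, L_difference is one minus
# the structural similarity of soft rasterized box masks, and L_IOU is one
# minus the mean intersection-over-union of index-aligned pairs.

# --- windowed SSIM (uniform 7x7 window, standard constants) -----------------

# Moving-average filter as a banded matrix product; rows within `pad` of the
# border use renormalized truncated windows, but those rows are cropped from
# the SSIM mean, so the statistic depends only on full windows.
uniform_filter_matrix <- function(n, win) {
  key <- sprintf("u_%d_%d", n, win)
  got <- blur_matrix_cache[[key]]
  if (!is.null(got)) return(got)
  r <- (win - 1L) %/% 2L
  B <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- max(1L, i - r):min(n, i + r)
    B[i, j] <- 1 / length(j)
  }
  blur_matrix_cache[[key]] <- B
  B
}

ufilt <- function(m, win) {
  uniform_filter_matrix(nrow(m), win) %*% m %*% t(uniform_filter_matrix(ncol(m), win))
}

#' Structural similarity index of two images
#'
#' Mean local SSIM with a uniform `win x win` window, constants
#' `C1 = (K1*L)^2`, `C2 = (K2*L)^2` with `K1 = 0.01`, `K2 = 0.03`, data range
#' `L = 1`, sample-covariance normalization, and a `(win-1)/2` border crop —
#' the standard formulation for unit-range images.
#'
#' @param x,y numeric matrices of equal size with values in `[0,1]`.
#' @param win odd window edge (default 7).
#' @return the mean SSIM (a number in `[-1, 1]`).
#' @export
ssim <- function(x, y, win = 7L) {
  stopifnot(all(dim(x) == dim(y)))
  if (min(dim(x)) < win) stop("image smaller than the SSIM window")
  C1 <- 0.01^2; C2 <- 0.03^2
  np <- win^2
  cov_norm <- np / (np - 1)
  ux <- ufilt(x, win); uy <- ufilt(y, win)
  vx <- cov_norm * (ufilt(x * x, win) - ux^2)
  vy <- cov_norm * (ufilt(y * y, win) - uy^2)
  vxy <- cov_norm * (ufilt(x * y, win) - ux * uy)
  S <- ((2 * ux * uy + C1) * (2 * vxy + C2)) /
    ((ux^2 + uy^2 + C1) * (vx + vy + C2))
  pad <- (win - 1L) %/% 2L
  mean(S[(pad + 1):(nrow(S) - pad), (pad + 1):(ncol(S) - pad)])
}

# --- soft rasterization of a box array --------------------------------------

# Exact per-pixel coverage of each box (piecewise linear in the coordinates),
# union by pixelwise max, then Gaussian blur (sigma in pixels). Smooth in the
# box coordinates, which makes the SSIM term usable as a training loss.
rasterize_boxes <- function(ba, h, w, sigma = 2) {
  ba <- unclass(ba)
  mask <- matrix(0, h, w)
  for (i in seq_len(nrow(ba))) {
    b <- ba[i, ]
    if (sum(abs(b)) == 0) next
    covx <- pmax(0, pmin(b[3], seq_len(w) / w) - pmax(b[1], (seq_len(w) - 1) / w)) * w
    covy <- pmax(0, pmin(b[4], seq_len(h) / h) - pmax(b[2], (seq_len(h) - 1) / h)) * h
    mask <- pmax(mask, outer(covy, covx))
  }
  if (sigma > 0) mask <- gauss_blur(mask, sigma)
  mask
}

#' Loss components on matched box arrays
#'
#' `loss_mse` is the mean squared coordinate difference over all `4K` slots
#' (sentinel padding included, so superfluous predictions are pulled toward
#' the zero box). `loss_iou` is one minus the mean IOU over index-aligned
#' pairs in which at least one side is non-sentinel (0 if every pair is
#' sentinel/sentinel). `loss_difference` is one minus the SSIM of the two
#' soft-rasterized box masks (Gaussian-smoothed exact-coverage union masks,
#' `sigma = 2` px), clipped into `[0,1]`; 0 when both arrays are empty.
#'
#' @param pred,actual box arrays (matrices `K x 4`) of equal length.
#' @param image_shape `c(height, width)` of the rasterization grid for the
#'   structural term.
#' @return a number.
#' @export
loss_mse <- function(pred, actual) {
  pred <- unclass(pred); actual <- unclass(actual)
  stopifnot(all(dim(pred) == dim(actual)))
  mean((pred - actual)^2)
}

# Sentinel equivalence inside the loss is a zero-area test with a small
# tolerance: the sigmoid head can shrink a superfluous box arbitrarily but
# never to exactly zero area, and a pair of (near-)sentinels carries no
# detection information. The cutoff matches the prediction-time sentinel
# threshold.
SENTINEL_AREA <- 1e-4

sentinel_like <- function(b) box_area(b) < SENTINEL_AREA

#' @rdname loss_mse
#' @export
loss_iou <- function(pred, actual) {
  pred <- unclass(pred); actual <- unclass(actual)
  stopifnot(all(dim(pred) == dim(actual)))
  act <- !(sentinel_like(pred) & sentinel_like(actual))
  if (!any(act)) return(0)
  ious <- vapply(which(act), function(i) box_iou(pred[i, ], actual[i, ]), 0)
  1 - mean(ious)
}

#' @rdname loss_mse
#' @export
loss_difference <- function(pred, actual, image_shape = c(64L, 64L)) {
  pred <- unclass(pred); actual <- unclass(actual)
  if (all(is_sentinel_box(pred)) && all(is_sentinel_box(actual))) return(0)
  h <- image_shape[1]; w <- image_shape[2]
  mp <- rasterize_boxes(pred, h, w)
  ma <- rasterize_boxes(actual, h, w)
  min(max(1 - ssim(mp, ma), 0), 1)
}

#' Composite detection loss
#'
#' @param pred,actual box arrays of equal capacity.
#' @param image_shape rasterization grid for the structural term.
#' @return an object of class `loss_breakdown`: list with `l_mse`,
#'   `l_difference`, `l_iou` and `l_total` (the mean of the three components,
#'   each bounded in `[0,1]` for normalized coordinates).
#' @examples
#' a <- box_array(c(0.2, 0.2, 0.4, 0.4), k = 1)
#' lloss(a, a)$l_total  # 0
#' @export
lloss <- function(pred, actual, image_shape = c(64L, 64L)) {
  lm <- loss_mse(pred, actual)
  ld <- loss_difference(pred, actual, image_shape)
  li <- loss_iou(pred, actual)
  structure(list(l_mse = lm, l_difference = ld, l_iou = li,
                 l_total = (lm + ld + li) / 3),
            class = "loss_breakdown")
}

#' @export
print.loss_breakdown <- function(x, ...) {
  cat(sprintf("LLoss %.5f  (mse %.5f | difference %.5f | iou %.5f)\n",
              x$l_total, x$l_mse, x$l_difference, x$l_iou))
  invisible(x)
}

# Gradient of the mean local SSIM with respect to the first image. `dS` is
# the upstream gradient on the mean (a scalar); returns a matrix like `x`.
# Derivation: S = (N1 N2)/(D1 D2) with N1 = 2 ux uy + C1, N2 = 2 vxy + C2,
# D1 = ux^2 + uy^2 + C1, D2 = vx + vy + C2; the filtered statistics are
# linear maps, so their adjoints are the transposed filter products.
ssim_grad_x <- function(x, y, win = 7L, dS = 1) {
  C1 <- 0.01^2; C2 <- 0.03^2
  np <- win^2; cn <- np / (np - 1)
  Uh <- uniform_filter_matrix(nrow(x), win)
  Uw <- uniform_filter_matrix(ncol(x), win)
  F  <- function(m) Uh %*% m %*% t(Uw)
  Ft <- function(m) crossprod(Uh, m %*% Uw)   # adjoint
  ux <- F(x); uy <- F(y)
  vx <- cn * (F(x * x) - ux^2)
  vy <- cn * (F(y * y) - uy^2)
  vxy <- cn * (F(x * y) - ux * uy)
  N1 <- 2 * ux * uy + C1; N2 <- 2 * vxy + C2
  D1 <- ux^2 + uy^2 + C1; D2 <- vx + vy + C2
  S <- (N1 * N2) / (D1 * D2)
  pad <- (win - 1L) %/% 2L
  ncrop <- (nrow(x) - 2L * pad) * (ncol(x) - 2L * pad)
  A <- matrix(0, nrow(x), ncol(x))
  A[(pad + 1):(nrow(x) - pad), (pad + 1):(ncol(x) - pad)] <- dS / ncrop
  dN1 <- A * N2 / (D1 * D2)
  dN2 <- A * N1 / (D1 * D2)
  dD1 <- -A * S / D1
  dD2 <- -A * S / D2
  # contributions to the filtered statistics
  dux <- 2 * uy * dN1 + 2 * ux * dD1 - 2 * cn * ux * dD2 - cn * uy * 2 * dN2
  dFxx <- cn * dD2          # through vx
  dFxy <- cn * 2 * dN2      # through vxy
  Ft(dux) + 2 * x * Ft(dFxx) + y * Ft(dFxy)
}

# Gradient of loss_difference with respect to the predicted coordinates:
# adjoint of the Gaussian blur takes the mask gradient back to the pre-blur
# coverage union; the union (pixelwise max) routes it to the covering box,
# and the coverage profile is piecewise linear in each coordinate, so the
# coordinate gradient concentrates on the pixel row/column containing that
# edge.
loss_difference_grad <- function(pred, actual, image_shape = c(64L, 64L),
                                 sigma = 2) {
  h <- image_shape[1]; w <- image_shape[2]
  k <- nrow(pred)
  g <- matrix(0, k, 4L)
  if (all(is_sentinel_box(pred)) && all(is_sentinel_box(actual))) return(g)
  ma <- rasterize_boxes(actual, h, w)
  # pre-blur coverage profiles per box, and the union
  covs <- vector("list", k)
  pre <- matrix(0, h, w)
  for (i in seq_len(k)) {
    b <- pred[i, ]
    if (sum(abs(b)) == 0) next
    covx <- pmax(0, pmin(b[3], seq_len(w) / w) - pmax(b[1], (seq_len(w) - 1) / w)) * w
    covy <- pmax(0, pmin(b[4], seq_len(h) / h) - pmax(b[2], (seq_len(h) - 1) / h)) * h
    covs[[i]] <- list(covx = covx, covy = covy, m = outer(covy, covx))
    pre <- pmax(pre, covs[[i]]$m)
  }
  mp <- if (sigma > 0) gauss_blur(pre, sigma) else pre
  ld <- 1 - ssim(mp, ma)
  if (ld <= 0 || ld >= 1) return(g)  # clipped region: flat
  dmask <- ssim_grad_x(mp, ma, dS = -1)  # d(1 - mssim)/d mp
  dpre <- if (sigma > 0) {
    Bh <- gauss_blur_matrix(h, sigma); Bw <- gauss_blur_matrix(w, sigma)
    crossprod(Bh, dmask %*% Bw)
  } else dmask
  for (i in seq_len(k)) {
    ci <- covs[[i]]
    if (is.null(ci)) next
    b <- pred[i, ]
    sel <- (ci$m >= pre - 1e-15) & (ci$m > 0)  # pixels this box governs
    gm <- dpre * sel
    jx0 <- min(max(ceiling(b[1] * w), 1L), w)  # column holding x_min
    jx1 <- min(max(ceiling(b[3] * w), 1L), w)
    jy0 <- min(max(ceiling(b[2] * h), 1L), h)
    jy1 <- min(max(ceiling(b[4] * h), 1L), h)
    g[i, 1] <- -w * sum(gm[, jx0] * ci$covy)
    g[i, 3] <-  w * sum(gm[, jx1] * ci$covy)
    g[i, 2] <- -h * sum(gm[jy0, ] * ci$covx)
    g[i, 4] <-  h * sum(gm[jy1, ] * ci$covx)
  }
  g
}

# Gradient of lloss$l_total with respect to the predicted coordinates.
# All three components are analytic (the IOU and coverage surfaces are
# piecewise smooth; subgradients are used on the measure-zero kinks).
lloss_grad <- function(pred, actual, image_shape = c(64L, 64L)) {
  pred <- unclass(pred); actual <- unclass(actual)
  k <- nrow(pred)
  g_mse <- 2 * (pred - actual) / (4 * k)
  act <- !(sentinel_like(pred) & sentinel_like(actual))
  g_iou <- matrix(0, k, 4L)
  if (any(act)) {
    na <- sum(act)
    for (i in which(act))
      g_iou[i, ] <- -box_iou_grad(pred[i, ], actual[i, ]) / na
  }
  g_dif <- loss_difference_grad(pred, actual, image_shape)
  (g_mse + g_iou + g_dif) / 3
}
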