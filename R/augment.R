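# Box-aware geometric augmentation and patch extraction.
#
# The augmentation transform is an affine map about the image center:
# optional left-right flip, rotation by an angle uniform in +/- (rotation
# factor x 360 degrees), and isotropic zoom with scale uniform in 1 +/- zoom
# factor. Images are resampled bilinearly through the inverse map with edge
# replication; boxes are pushed through the forward map as the axis-aligned
# hull of their four transformed corners, clipped to the unit square.

#' Augmentation parameters
#'
#' @param flip_horizontal allow a random left-right flip (probability 1/2).
#' @param rotation_factor rotation range as a fraction of a full turn
#'   (default 0.02, i.e. +/- 7.2 degrees); must lie in `[0, 0.5]`.
#' @param zoom_factor zoom range (default 0.2: scale drawn uniformly in
#'   `[0.8, 1.2]`, the same factor for width and height); in `[0, 0.9]`.
#' @param seed optional integer; when given, [augment] draws from a private
#'   stream seeded with it instead of the caller's RNG.
#' @return an object of class `augment_params`.
#' @export
augment_params <- function(flip_horizontal = TRUE, rotation_factor = 0.02,
                           zoom_factor = 0.2, seed = NULL) {
  if (rotation_factor < 0 || rotation_factor > 0.5)
    stop("rotation_factor must lie in [0, 0.5]")
  if (zoom_factor < 0 || zoom_factor > 0.9)
    stop("zoom_factor must lie in [0, 0.9]")
  structure(list(flip_horizontal = isTRUE(flip_horizontal),
                 rotation_factor = rotation_factor,
                 zoom_factor = zoom_factor, seed = seed),
            class = "augment_params")
}

# Forward affine map on pixel coordinates about the image center:
# flip, then rotate by theta, then scale by s.
affine_map <- function(x, y, w, h, flip, theta, s) {
  if (flip) x <- w - x
  cx <- w / 2; cy <- h / 2
  xr <- x - cx; yr <- y - cy
  ct <- cos(theta); st <- sin(theta)
  list(x = s * (ct * xr - st * yr) + cx,
       y = s * (st * xr + ct * yr) + cy)
}

#' Augment an annotated record
#'
#' Applies one random draw of the flip/rotate/zoom transform to the image and
#' maps every non-sentinel box through the same transform (axis-aligned hull
#' of the transformed corners, clipped to `[0,1]`). Boxes whose clipped area
#' drops below 10% of their original area are replaced by sentinels.
#'
#' @param record an [annotated_record].
#' @param params an [augment_params] object.
#' @param draws optional explicit draw `list(flip=, angle=, scale=)` (angle
#'   in radians); when `NULL` the draws are random. Zero angle, unit scale
#'   and no flip give the identity.
#' @return the augmented [annotated_record].
#' @export
augment <- function(record, params = augment_params(), draws = NULL) {
  stopifnot(inherits(record, "annotated_record"))
  if (is.null(draws)) {
    draw1 <- function() {
      list(flip = params$flip_horizontal && stats::runif(1) < 0.5,
           angle = stats::runif(1, -1, 1) * params$rotation_factor * 2 * pi,
           scale = 1 + stats::runif(1, -1, 1) * params$zoom_factor)
    }
    draws <- if (is.null(params$seed)) draw1() else with_seed(params$seed, draw1())
  }
  flip <- isTRUE(draws$flip); theta <- draws$angle; s <- draws$scale
  px <- record$image$pixels
  h <- nrow(px); w <- ncol(px)

  if (flip && theta == 0 && s == 1) {
    out_px <- px[, rev(seq_len(w)), drop = FALSE]  # exact column reversal
  } else if (!flip && theta == 0 && s == 1) {
    out_px <- px
  } else {
    # inverse map: unscale, unrotate, unflip; sample bilinearly
    gx <- matrix(seq_len(w) - 0.5, h, w, byrow = TRUE)
    gy <- matrix(seq_len(h) - 0.5, h, w)
    cx <- w / 2; cy <- h / 2
    xr <- (gx - cx) / s; yr <- (gy - cy) / s
    ct <- cos(-theta); st <- sin(-theta)
    sx <- ct * xr - st * yr + cx
    sy <- st * xr + ct * yr + cy
    if (flip) sx <- w - sx
    out_px <- matrix(bilinear_sample(px, sx, sy), h, w)
  }

  ba <- unclass(record$boxes)
  k <- nrow(ba)
  new_boxes <- NULL
  for (i in seq_len(k)) {
    b <- ba[i, ]
    if (sum(abs(b)) == 0) next
    cxs <- c(b[1], b[3], b[1], b[3]) * w
    cys <- c(b[2], b[2], b[4], b[4]) * h
    m <- affine_map(cxs, cys, w, h, flip, theta, s)
    nb <- c(min(m$x) / w, min(m$y) / h, max(m$x) / w, max(m$y) / h)
    clipped <- c(clamp01(nb[1:2]), clamp01(nb[3:4]))
    if (clipped[3] <= clipped[1] || clipped[4] <= clipped[2]) next
    if (box_area(clipped) < 0.1 * box_area(b)) next
    new_boxes <- rbind(new_boxes, clipped)
  }
  annotated_record(scan_image(out_px, id = record$image$id),
                   box_array(new_boxes, k = k))
}

#' Cut an image into non-overlapping fixed-size patches
#'
#' The image is first padded by edge replication up to the nearest multiple
#' of `patch_size` in each dimension, then tiled without overlap in row-major
#' order, so the patch count is `ceil(H/P) * ceil(W/P)`.
#'
#' @param img a [scan_image] (or plain matrix).
#' @param patch_size patch edge length in pixels (default 32).
#' @return an object of class `patch_grid`: list with `patches` (list of
#'   `patch_size x patch_size` matrices), `grid_rows`, `grid_cols`,
#'   `patch_size`.
#' @export
extract_patches <- function(img, patch_size = 32L) {
  px <- if (inherits(img, "scan_image")) img$pixels else as.matrix(img)
  patch_size <- as.integer(patch_size)
  if (length(px) == 0L) stop("empty image")
  h <- nrow(px); w <- ncol(px)
  gr <- ceiling(h / patch_size); gc <- ceiling(w / patch_size)
  ph <- gr * patch_size; pw <- gc * patch_size
  if (ph > h) px <- px[c(seq_len(h), rep(h, ph - h)), , drop = FALSE]
  if (pw > w) px <- px[, c(seq_len(w), rep(w, pw - w)), drop = FALSE]
  patches <- vector("list", gr * gc)
  t <- 0L
  for (i in seq_len(gr)) {
    rs <- (i - 1L) * patch_size + seq_len(patch_size)
    for (j in seq_len(gc)) {
      t <- t + 1L
      patches[[t]] <- px[rs, (j - 1L) * patch_size + seq_len(patch_size),
                         drop = FALSE]
    }
  }
  structure(list(patches = patches, grid_rows = gr, grid_cols = gc,
                 patch_size = patch_size), class = "patch_grid")
}

#' Reassemble a patch grid into its (padded) image
#'
#' Exact tiling inverse of [extract_patches] on the padded image.
#'
#' @param grid a `patch_grid`.
#' @return numeric matrix of size `grid_rows*P x grid_cols*P`.
#' @export
assemble_patches <- function(grid) {
  stopifnot(inherits(grid, "patch_grid"))
  p <- grid$patch_size
  out <- matrix(0, grid$grid_rows * p, grid$grid_cols * p)
  t <- 0L
  for (i in seq_len(grid$grid_rows)) for (j in seq_len(grid$grid_cols)) {
    t <- t + 1L
    out[(i - 1L) * p + seq_len(p), (j - 1L) * p + seq_len(p)] <- grid$patches[[t]]
  }
  out
}

# Flatten the patch list into an N x P^2 matrix (column-major within each
# patch; the same scheme is used for input and query streams).
patches_matrix <- function(patches, patch_size) {
  do.call(rbind, lapply(patches, as.vector))
}
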