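# Bounding boxes and fixed-length box arrays.
#
# Coordinate convention: normalized [0,1] corner format
# (x_min, y_min, x_max, y_max), origin at the top-left of the image, x
# rightward, y downward, continuous geometry (a box spans real intervals, not
# pixel index ranges). Files store pixel corner coordinates; conversion
# happens at the I/O boundary (see read_box_table/write_box_table).
#
# The sentinel box is (0,0,0,0): a zero-area placeholder padding a box array
# to its fixed capacity K. Any operation that must skip padding does so with
# a zero-area test.

#' Construct a fixed-length bounding-box array
#'
#' A box array is the unit the detector regresses: exactly `k` rows of
#' normalized corner-format boxes `(x_min, y_min, x_max, y_max)`, padded with
#' all-zero sentinel rows when fewer than `k` real boxes exist. Non-sentinel
#' rows are canonically sorted by `(y_min, x_min)` so that index-aligned
#' losses compare stable slots; sentinel rows always trail.
#'
#' @param boxes numeric matrix (or vector coercible to one) with 4 columns of
#'   normalized coordinates; `NULL` or a 0-row matrix gives an all-sentinel
#'   array.
#' @param k array capacity (number of slots).
#' @return a `k x 4` numeric matrix of class `box_array` with columns
#'   `x_min, y_min, x_max, y_max`.
#' @examples
#' box_array(c(0.1, 0.2, 0.3, 0.4), k = 3)
#' @export
box_array <- function(boxes = NULL, k = 3L) {
  k <- as.integer(k)
  if (k < 1L) stop("box array capacity 'k' must be >= 1")
  if (is.null(boxes)) boxes <- matrix(numeric(0), ncol = 4L)
  if (is.vector(boxes)) boxes <- matrix(boxes, ncol = 4L, byrow = TRUE)
  boxes <- as.matrix(boxes)
  if (ncol(boxes) != 4L) stop("boxes must have 4 columns")
  storage.mode(boxes) <- "double"
  real <- boxes[!is_sentinel_box(boxes), , drop = FALSE]
  if (nrow(real) > k)
    stop(sprintf("%d boxes exceed array capacity k=%d", nrow(real), k))
  bad <- real[, 1] > real[, 3] | real[, 2] > real[, 4] |
    apply(real < -1e-12 | real > 1 + 1e-12, 1, any)
  if (any(bad)) stop("invalid box: need 0 <= x_min <= x_max <= 1 and 0 <= y_min <= y_max <= 1")
  real <- clamp01(real)
  if (nrow(real) > 1L) real <- real[order(real[, 2], real[, 1]), , drop = FALSE]
  out <- rbind(real, matrix(0, k - nrow(real), 4L))
  dimnames(out) <- list(NULL, c("x_min", "y_min", "x_max", "y_max"))
  class(out) <- c("box_array", "matrix", "array")
  out
}

# Sentinel test, rowwise for a matrix or once for a length-4 vector.
is_sentinel_box <- function(b) {
  if (is.matrix(b)) rowSums(abs(b)) == 0 else sum(abs(b)) == 0
}

box_area <- function(b) {
  if (is.matrix(b)) pmax(b[, 3] - b[, 1], 0) * pmax(b[, 4] - b[, 2], 0)
  else max(b[3] - b[1], 0) * max(b[4] - b[2], 0)
}

n_real_boxes <- function(ba) sum(!is_sentinel_box(unclass(ba)))

#' Intersection over union of two axis-aligned boxes
#'
#' Continuous-geometry IOU: the area of intersection divided by the area of
#' union. Symmetric, bounded in `[0,1]`, equal to 1 only for identical
#' non-degenerate boxes. A pair of sentinel (or otherwise zero-area) boxes is
#' defined to have IOU 0.
#'
#' @param a,b length-4 numeric vectors `(x_min, y_min, x_max, y_max)` in
#'   normalized coordinates.
#' @return a number in `[0,1]`.
#' @examples
#' box_iou(c(0, 0, 0.5, 0.5), c(0, 0, 0.5, 0.5))  # 1
#' box_iou(c(0, 0, 0.2, 0.2), c(0.1, 0.1, 0.3, 0.3))  # 1/7
#' @export
box_iou <- function(a, b) {
  iw <- min(a[3], b[3]) - max(a[1], b[1])
  ih <- min(a[4], b[4]) - max(a[2], b[2])
  if (iw <= 0 || ih <= 0) return(0)
  inter <- iw * ih
  u <- box_area(a) + box_area(b) - inter
  if (u <= 0) return(0)
  inter / u
}

# Analytic gradient of box_iou with respect to the coordinates of `a`.
# Zero wherever the boxes do not overlap (the IOU surface is flat there).
box_iou_grad <- function(a, b) {
  g <- numeric(4)
  iw <- min(a[3], b[3]) - max(a[1], b[1])
  ih <- min(a[4], b[4]) - max(a[2], b[2])
  if (iw <= 0 || ih <= 0) return(g)
  inter <- iw * ih
  aw <- max(a[3] - a[1], 0); ah <- max(a[4] - a[2], 0)
  u <- aw * ah + box_area(b) - inter
  if (u <= 0) return(g)
  # d(inter)/d a
  dI <- c(if (a[1] > b[1]) -ih else 0,
          if (a[2] > b[2]) -iw else 0,
          if (a[3] < b[3])  ih else 0,
          if (a[4] < b[4])  iw else 0)
  dA <- c(-ah, -aw, ah, aw)
  dU <- dA - dI
  (dI * u - inter * dU) / u^2
}
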