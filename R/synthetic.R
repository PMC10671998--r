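# Synthetic speckled B-scan generator.
#
# Emulates the geometry of layered-tissue OCT B-scans: a stack of horizontal
# intensity bands with smooth wavy boundaries, multiplied by fully developed
# speckle (gamma noise with mean 1 and shape k, so the speckle contrast is
# 1/sqrt(k)), with one or more elliptical lesions of soft (Gaussian-blurred)
# edge added before the speckle. Every lesion's tight axis-aligned bounding
# box is returned as exact ground truth.

#' Parameters of the synthetic scan generator
#'
#' @param image_height,image_width scan size in pixels (both `>= 64`);
#'   defaults mirror the nominal B-scan geometry of 500 x 412 px.
#' @param n_layers number of horizontal tissue bands.
#' @param layer_intensity_range range the band intensities are drawn from
#'   (inside `[0,1]`).
#' @param speckle_shape gamma shape `k` of the multiplicative speckle
#'   (mean 1); smaller `k` means harsher speckle, contrast `1/sqrt(k)`.
#' @param lesion_count_range inclusive integer pair; the lesion count of each
#'   scan is uniform on this range. Default `c(1, 3)` (one to three lesions
#'   per image).
#' @param lesion_size_range lesion extent as a fraction of the smaller image
#'   dimension, within `(0, 0.5]`.
#' @param lesion_contrast signed intensity offset of a lesion against its
#'   background.
#' @param seed integer; together with the scan index it fully determines each
#'   scan.
#' @param k_slots capacity of the returned box arrays (must be at least
#'   `lesion_count_range[2]`).
#' @return an object of class `synthetic_params`.
#' @export
synthetic_params <- function(image_height = 412L, image_width = 500L,
                             n_layers = 6L,
                             layer_intensity_range = c(0.15, 0.75),
                             speckle_shape = 4,
                             lesion_count_range = c(1L, 3L),
                             lesion_size_range = c(0.08, 0.22),
                             lesion_contrast = 0.35,
                             seed = 1L, k_slots = 3L) {
  p <- list(image_height = as.integer(image_height),
            image_width = as.integer(image_width),
            n_layers = as.integer(n_layers),
            layer_intensity_range = as.numeric(layer_intensity_range),
            speckle_shape = as.numeric(speckle_shape),
            lesion_count_range = as.integer(lesion_count_range),
            lesion_size_range = as.numeric(lesion_size_range),
            lesion_contrast = as.numeric(lesion_contrast),
            seed = as.integer(seed), k_slots = as.integer(k_slots))
  if (p$image_height < 64L || p$image_width < 64L)
    stop("image dimensions must be >= 64 pixels")
  if (p$n_layers < 1L) stop("need at least one tissue layer")
  if (p$speckle_shape <= 0) stop("speckle_shape must be positive")
  if (any(p$lesion_count_range < 0L) ||
      p$lesion_count_range[1] > p$lesion_count_range[2])
    stop("lesion_count_range must be a nondecreasing pair of nonnegative integers")
  if (p$lesion_count_range[2] > p$k_slots)
    stop("lesion_count_range exceeds box-array capacity k_slots")
  if (p$lesion_size_range[1] <= 0 || p$lesion_size_range[2] > 0.5 ||
      p$lesion_size_range[1] > p$lesion_size_range[2])
    stop("lesion_size_range must lie within (0, 0.5]")
  if (any(p$layer_intensity_range < 0) || any(p$layer_intensity_range > 1) ||
      p$layer_intensity_range[1] > p$layer_intensity_range[2])
    stop("layer_intensity_range must be an ordered pair inside [0,1]")
  class(p) <- "synthetic_params"
  p
}

# Gaussian blur as banded row/column matrix products. Truncated at 4 sigma,
# border rows renormalized, so the operator is an exact linear map with no
# FFT wrap-around.
blur_matrix_cache <- new.env(parent = emptyenv())

gauss_blur_matrix <- function(n, sigma) {
  key <- sprintf("%d_%g", n, sigma)
  got <- blur_matrix_cache[[key]]
  if (!is.null(got)) return(got)
  r <- max(1L, ceiling(4 * sigma))
  kern <- stats::dnorm(-r:r, sd = sigma)
  B <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- (i - r):(i + r)
    ok <- j >= 1 & j <= n
    B[i, j[ok]] <- kern[ok] / sum(kern[ok])
  }
  blur_matrix_cache[[key]] <- B
  B
}

gauss_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  gauss_blur_matrix(nrow(m), sigma) %*% m %*% t(gauss_blur_matrix(ncol(m), sigma))
}

#' Generate one synthetic speckled scan with ground-truth boxes
#'
#' The scan is bit-reproducible: a given `(params, index)` pair always
#' produces the same image and boxes, independent of the caller's RNG state.
#'
#' @param params a [synthetic_params] object.
#' @param index scan index within the dataset (drives the per-scan RNG
#'   stream).
#' @param keep_masks attach the soft lesion masks as attribute
#'   `lesion_masks` (a list of matrices) for downstream validation.
#' @return an [annotated_record]; the box array holds the tight normalized
#'   box of every lesion, canonically sorted, sentinel-padded to `k_slots`.
#' @examples
#' rec <- generate_scan(synthetic_params(128, 128, seed = 7), index = 1)
#' @export
generate_scan <- function(params, index = 1L, keep_masks = FALSE) {
  stopifnot(inherits(params, "synthetic_params"))
  h <- params$image_height; w <- params$image_width
  with_seed(derive_seed(params$seed, index), {
    # layered background with smooth wavy boundaries
    nl <- params$n_layers
    ir <- params$layer_intensity_range
    intens <- stats::runif(nl, ir[1], ir[2])
    bg <- matrix(intens[1], h, w)
    if (nl > 1L) {
      base <- seq(0.12, 0.88, length.out = nl + 1)[2:nl] * h
      base <- sort(base + stats::runif(nl - 1L, -0.04, 0.04) * h)
      rowidx <- matrix(seq_len(h), h, w)
      xfrac <- (seq_len(w) - 0.5) / w
      for (kb in seq_len(nl - 1L)) {
        amp <- stats::runif(1, 0.01, 0.03) * h
        freq <- stats::runif(1, 1, 3)
        phase <- stats::runif(1, 0, 1)
        bound <- base[kb] + amp * sin(2 * pi * (freq * xfrac + phase))
        below <- rowidx > matrix(bound, h, w, byrow = TRUE)
        bg[below] <- intens[kb + 1L]
      }
      bg <- gauss_blur(bg, 1.5)  # smooth band transitions
    }
    # lesions: axis-aligned ellipses with soft edges
    n_les <- if (params$lesion_count_range[1] == params$lesion_count_range[2])
      params$lesion_count_range[1] else
      sample(params$lesion_count_range[1]:params$lesion_count_range[2], 1L)
    boxes <- NULL
    masks <- list()
    clean <- bg
    if (n_les > 0L) {
      mind <- min(h, w)
      centers <- matrix(numeric(0), 0, 2)
      yy <- matrix(seq_len(h) - 0.5, h, w)
      xx <- matrix(seq_len(w) - 0.5, h, w, byrow = TRUE)
      for (li in seq_len(n_les)) {
        for (try in 1:60) {
          a <- stats::runif(1, params$lesion_size_range[1],
                            params$lesion_size_range[2]) * mind / 2  # x semi-axis
          b <- stats::runif(1, params$lesion_size_range[1],
                            params$lesion_size_range[2]) * mind / 2
          margin <- 10  # blur halo must stay inside the image
          if (2 * a + 2 * margin >= w || 2 * b + 2 * margin >= h)
            stop("lesion_size_range too large for the image dimensions")
          cx <- stats::runif(1, a + margin, w - a - margin)
          cy <- stats::runif(1, b + margin, h - b - margin)
          far <- !nrow(centers) ||
            all(sqrt((centers[, 1] - cx)^2 + (centers[, 2] - cy)^2) >
                  (a + b) * 0.9)
          if (far || try == 60L) break
        }
        centers <- rbind(centers, c(cx, cy))
        inside <- ((xx - cx) / a)^2 + ((yy - cy) / b)^2 <= 1
        soft <- gauss_blur(inside * 1, 2)
        amp <- params$lesion_contrast * stats::runif(1, 0.85, 1.15)
        clean <- clean + amp * soft
        if (keep_masks) masks[[li]] <- soft
        # tight box of the perturbed pixels (threshold on the soft mask)
        hit <- which(soft > 0.1, arr.ind = TRUE)
        boxes <- rbind(boxes, c((min(hit[, 2]) - 1) / w, (min(hit[, 1]) - 1) / h,
                                max(hit[, 2]) / w, max(hit[, 1]) / h))
      }
    }
    speckle <- matrix(stats::rgamma(h * w, shape = params$speckle_shape,
                                    rate = params$speckle_shape), h, w)
    img <- clamp01(clean) * speckle
    rec <- annotated_record(scan_image(clamp01(img), id = sprintf("scan_%05d", index)),
                            box_array(boxes, k = params$k_slots))
    if (keep_masks) attr(rec, "lesion_masks") <- masks
    rec
  })
}

#' Generate a synthetic dataset
#'
#' @param params a [synthetic_params] object.
#' @param n_images number of scans (`>= 1`); scan `i` is
#'   `generate_scan(params, i)`.
#' @return list of [annotated_record]s.
#' @export
generate_dataset <- function(params, n_images) {
  n_images <- as.integer(n_images)
  if (n_images < 1L) stop("n_images must be >= 1")
  lapply(seq_len(n_images), function(i) generate_scan(params, i))
}

#' Write a generated dataset to disk
#'
#' Layout: `images/<id>.png` (8-bit grayscale), `annotations.csv` (pixel-
#' coordinate box table) and `manifest.txt` recording the generator
#' parameters and seed.
#'
#' @param records list of [annotated_record]s.
#' @param dir destination directory (created if needed).
#' @param params optional [synthetic_params] recorded in the manifest.
#' @export
write_scan_dataset <- function(records, dir, params = NULL) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  for (r in records)
    save_image(r$image, file.path(dir, "images", paste0(r$image$id, ".png")))
  write_box_table(records, file.path(dir, "annotations.csv"))
  if (!is.null(params)) {
    lines <- vapply(names(unclass(params)), function(nm)
      sprintf("%s=%s", nm, paste(params[[nm]], collapse = ",")), "")
    writeLines(lines, file.path(dir, "manifest.txt"))
  }
  invisible(dir)
}

#' Read a dataset written by [write_scan_dataset]
#'
#' @param dir dataset directory.
#' @param k box-array capacity.
#' @return list of [annotated_record]s (images lexicographic by file name).
#' @export
read_scan_dataset <- function(dir, k = 3L) {
  files <- sort(list.files(file.path(dir, "images"), pattern = "\\.(png|tif|tiff)$",
                           full.names = TRUE))
  boxes <- read_box_table(file.path(dir, "annotations.csv"), k = k)
  lapply(files, function(f) {
    img <- load_image(f)
    annotated_record(img, boxes[[img$id]] %||% box_array(NULL, k = k))
  })
}
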