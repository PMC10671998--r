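# Image and annotation I/O, plus the dataset split.

#' Construct a scan image
#'
#' A single-channel 2-D intensity image. Intensities are clamped to `[0,1]`.
#'
#' @param pixels numeric matrix, rows = image rows (y), columns = x.
#' @param id image identifier (defaults to `"scan"`).
#' @return an object of class `scan_image` with fields `id`, `pixels`,
#'   `height`, `width`.
#' @export
scan_image <- function(pixels, id = "scan") {
  pixels <- as.matrix(pixels)
  if (length(pixels) == 0L) stop("zero-sized image")
  storage.mode(pixels) <- "double"
  pixels <- clamp01(pixels)
  structure(list(id = as.character(id), pixels = pixels,
                 height = nrow(pixels), width = ncol(pixels)),
            class = "scan_image")
}

#' @export
print.scan_image <- function(x, ...) {
  cat(sprintf("<scan_image '%s' %dx%d px, intensity [%.3f, %.3f]>\n",
              x$id, x$height, x$width, min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Pair an image with its ground-truth box array
#'
#' @param image a [scan_image].
#' @param boxes a [box_array] (or a matrix/vector coercible to one).
#' @param k box-array capacity used when coercing `boxes`.
#' @return an object of class `annotated_record`.
#' @export
annotated_record <- function(image, boxes, k = 3L) {
  if (!inherits(image, "scan_image")) image <- scan_image(image)
  if (!inherits(boxes, "box_array")) boxes <- box_array(boxes, k = k)
  structure(list(image = image, boxes = boxes), class = "annotated_record")
}

#' Load a grayscale scan from PNG or TIFF
#'
#' Intensities are rescaled to `[0,1]` (the png and tiff readers already
#' return that scale for 8- and 16-bit data); RGB input is collapsed to
#' grayscale by the unweighted channel mean. The image id is the file stem.
#'
#' @param path path to a `.png`, `.tif` or `.tiff` file.
#' @return a [scan_image].
#' @export
load_image <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format '", ext, "' (need PNG or TIFF)"))
  if (length(dim(px)) == 3L) {
    nch <- dim(px)[3]
    if (nch >= 3L) px <- (px[, , 1] + px[, , 2] + px[, , 3]) / 3
    else px <- px[, , 1]
  }
  if (length(px) == 0L) stop("zero-sized image: ", path)
  scan_image(px, id = tools::file_path_sans_ext(basename(path)))
}

#' Write a scan image to PNG (8-bit grayscale)
#'
#' @param img a [scan_image].
#' @param path destination path.
#' @export
save_image <- function(img, path) {
  png::writePNG(img$pixels, target = path)
  invisible(path)
}

# Bilinear sample of matrix `px` at continuous coordinates (xs, ys), where
# pixel (i, j) has its center at (j - 0.5, i - 0.5). Coordinates outside the
# image are clamped to the border (edge replication).
bilinear_sample <- function(px, xs, ys) {
  h <- nrow(px); w <- ncol(px)
  cx <- pmin(pmax(xs - 0.5, 0), w - 1)  # in [0, w-1], units of column index - 1
  cy <- pmin(pmax(ys - 0.5, 0), h - 1)
  x0 <- pmin(floor(cx), w - 1); y0 <- pmin(floor(cy), h - 1)
  fx <- cx - x0; fy <- cy - y0
  x1 <- pmin(x0 + 1, w - 1); y1 <- pmin(y0 + 1, h - 1)
  i00 <- y0 + 1 + x0 * h; i01 <- y0 + 1 + x1 * h
  i10 <- y1 + 1 + x0 * h; i11 <- y1 + 1 + x1 * h
  v <- px[i00] * (1 - fx) * (1 - fy) + px[i01] * fx * (1 - fy) +
    px[i10] * (1 - fx) * fy + px[i11] * fx * fy
  v
}

#' Resize a scan by bilinear interpolation
#'
#' Sampling is at output pixel centers mapped affinely onto the input grid,
#' so resizing an image to its own size reproduces it exactly and a constant
#' image stays constant. Boxes live in normalized coordinates and are
#' unaffected by resizing.
#'
#' @param img a [scan_image].
#' @param height,width target size in pixels (both `>= 8`).
#' @return the resized [scan_image] (same id).
#' @export
resize_image <- function(img, height, width) {
  height <- as.integer(height); width <- as.integer(width)
  if (height < 8L || width < 8L) stop("target dimensions must be >= 8 pixels")
  h0 <- img$height; w0 <- img$width
  if (height == h0 && width == w0) return(img)
  xs <- ((seq_len(width) - 0.5) * w0) / width
  ys <- ((seq_len(height) - 0.5) * h0) / height
  grid_x <- matrix(xs, height, width, byrow = TRUE)
  grid_y <- matrix(ys, height, width)
  out <- matrix(bilinear_sample(img$pixels, grid_x, grid_y), height, width)
  scan_image(out, id = img$id)
}

#' Read a CSV bounding-box table
#'
#' The file schema is
#' `image_id,x_min,y_min,x_max,y_max,width,height` with box coordinates in
#' pixels; `width`/`height` are the image dimensions used to convert to the
#' normalized coordinates the package works in. Rows sharing an `image_id`
#' accumulate into one box array.
#'
#' @param path CSV file path.
#' @param k box-array capacity for every image.
#' @return named list mapping `image_id` to a [box_array].
#' @export
read_box_table <- function(path, k = 3L) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("image_id", "x_min", "y_min", "x_max", "y_max", "width", "height")
  if (!all(need %in% names(tab)))
    stop("malformed box table: need columns ", paste(need, collapse = ","))
  if (nrow(tab) == 0L) return(structure(list(), names = character(0)))
  if (any(tab$x_max < tab$x_min) || any(tab$y_max < tab$y_min))
    stop("malformed row: x_max < x_min or y_max < y_min")
  if (any(tab$x_min < 0) || any(tab$y_min < 0) ||
      any(tab$x_max > tab$width) || any(tab$y_max > tab$height))
    stop("box outside image bounds")
  norm <- cbind(tab$x_min / tab$width, tab$y_min / tab$height,
                tab$x_max / tab$width, tab$y_max / tab$height)
  out <- lapply(split(seq_len(nrow(tab)), tab$image_id),
                function(i) box_array(norm[i, , drop = FALSE], k = k))
  out[unique(tab$image_id)]
}

#' Write a CSV bounding-box table
#'
#' Inverse of [read_box_table]: normalized boxes are written as pixel
#' coordinates at full double precision, so a write/read round trip
#' reproduces the normalized boxes to well below 1e-9. Sentinel rows are not
#' written.
#'
#' @param records named list of [box_array] objects, or a list of
#'   [annotated_record]s (image ids and sizes are then taken from the images).
#' @param path destination CSV path.
#' @param width,height image dimensions in pixels used for the conversion
#'   when `records` is a plain list of box arrays.
#' @export
write_box_table <- function(records, path, width = NULL, height = NULL) {
  rows <- list()
  push <- function(id, ba, w, h) {
    ba <- unclass(ba)
    for (i in seq_len(nrow(ba))) {
      b <- ba[i, ]
      if (sum(abs(b)) == 0) next
      rows[[length(rows) + 1L]] <<- data.frame(
        image_id = id, x_min = b[1] * w, y_min = b[2] * h,
        x_max = b[3] * w, y_max = b[4] * h, width = w, height = h,
        stringsAsFactors = FALSE)
    }
  }
  if (length(records) && inherits(records[[1]], "annotated_record")) {
    for (r in records) push(r$image$id, r$boxes, r$image$width, r$image$height)
  } else {
    if (is.null(width) || is.null(height))
      stop("width/height required when writing plain box arrays")
    ids <- names(records)
    for (i in seq_along(records)) push(ids[i], records[[i]], width, height)
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(image_id = character(0), x_min = numeric(0), y_min = numeric(0),
               x_max = numeric(0), y_max = numeric(0), width = numeric(0),
               height = numeric(0))
  # full precision so normalized coordinates round-trip exactly
  for (cl in c("x_min", "y_min", "x_max", "y_max"))
    tab[[cl]] <- formatC(tab[[cl]], digits = 17, format = "g")
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read or write COCO-style annotations
#'
#' A minimal COCO detection dialect: `images` (id, file_name, width, height),
#' `annotations` (id, image_id, category_id, bbox as pixel `[x, y, w, h]`)
#' and a single category `lesion` (id 1).
#'
#' @param path JSON file path.
#' @param k box-array capacity per image.
#' @return `read_coco`: named list mapping image file stem to [box_array].
#' @export
read_coco <- function(path, k = 3L) {
  doc <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  imgs <- doc$images
  if (is.null(imgs) || nrow(imgs) == 0L) return(structure(list(), names = character(0)))
  ann <- doc$annotations
  out <- list()
  for (i in seq_len(nrow(imgs))) {
    im <- imgs[i, ]
    id <- tools::file_path_sans_ext(im$file_name)
    rows <- if (is.null(ann) || nrow(ann) == 0L) integer(0) else
      which(ann$image_id == im$id)
    if (length(rows)) {
      # jsonlite may simplify bbox to a matrix or keep a list of vectors
      bb <- if (is.matrix(ann$bbox)) ann$bbox[rows, , drop = FALSE] else
        do.call(rbind, ann$bbox[rows])  # [x, y, w, h] in pixels
      norm <- cbind(bb[, 1] / im$width, bb[, 2] / im$height,
                    (bb[, 1] + bb[, 3]) / im$width,
                    (bb[, 2] + bb[, 4]) / im$height)
    } else norm <- NULL
    out[[id]] <- box_array(norm, k = k)
  }
  out
}

#' @rdname read_coco
#' @param records list of [annotated_record]s to export.
#' @export
write_coco <- function(records, path) {
  images <- list(); annotations <- list(); aid <- 0L
  for (i in seq_along(records)) {
    r <- records[[i]]
    images[[i]] <- list(id = i, file_name = paste0(r$image$id, ".png"),
                        width = r$image$width, height = r$image$height)
    ba <- unclass(r$boxes)
    for (j in seq_len(nrow(ba))) {
      b <- ba[j, ]
      if (sum(abs(b)) == 0) next
      aid <- aid + 1L
      annotations[[aid]] <- list(
        id = aid, image_id = i, category_id = 1L,
        bbox = c(b[1] * r$image$width, b[2] * r$image$height,
                 (b[3] - b[1]) * r$image$width, (b[4] - b[2]) * r$image$height))
    }
  }
  doc <- list(images = images, annotations = annotations,
              categories = list(list(id = 1L, name = "lesion")))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Random train/validation/test split
#'
#' Shuffles the records under the given seed and allocates counts by
#' flooring `n * fraction`; remainder records go to the training split (the
#' largest split absorbs rounding). The three parts are disjoint and
#' exhaustive.
#'
#' @param records a list (any element type).
#' @param fractions length-3 numeric summing to 1; default `c(0.6, 0.1, 0.3)`.
#' @param seed integer RNG seed for the shuffle.
#' @return list with elements `train`, `validation`, `test`.
#' @examples
#' sp <- split_dataset(as.list(1:100), seed = 1)
#' lengths(sp)  # 60 10 30
#' @export
split_dataset <- function(records, fractions = c(0.6, 0.1, 0.3), seed = 1L) {
  n <- length(records)
  if (n < 3L) stop("need at least 3 records to split")
  if (length(fractions) != 3L || abs(sum(fractions) - 1) > 1e-9)
    stop("fractions must be three numbers summing to 1")
  idx <- with_seed(seed, sample.int(n))
  n_val <- floor(n * fractions[2]); n_test <- floor(n * fractions[3])
  n_train <- n - n_val - n_test
  list(train = records[idx[seq_len(n_train)]],
       validation = records[idx[n_train + seq_len(n_val)]],
       test = records[idx[n_train + n_val + seq_len(n_test)]])
}
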