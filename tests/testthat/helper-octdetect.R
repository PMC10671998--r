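# Shared fixtures: everything is generated in code at test time.

# A desk-scale model configuration (tiny token count, shallow trunk) used by
# unit tests that only need shapes and determinism, not detection quality.
tiny_config <- function(n_blocks = 1L, max_boxes = 1L, dropout = 0) {
  model_config(n_blocks = n_blocks, n_heads = 2L, latent_dim = 8L,
               mlp_units = c(16L, 8L), dropout = dropout,
               max_boxes = max_boxes, patch_size = 16L,
               image_height = 32L, image_width = 32L,
               encoder = encoder_config(embed_dim = 8L, conv_filters = c(4L, 8L)))
}

# Independent IOU oracle: rasterize both boxes on an n x n grid and count
# cells whose centers fall inside (pure integer counting, no shared code
# with box_iou).
iou_raster_oracle <- function(a, b, n = 1000L) {
  centers <- (seq_len(n) - 0.5) / n
  ax <- sum(centers > a[1] & centers < a[3]); ay <- sum(centers > a[2] & centers < a[4])
  bx <- sum(centers > b[1] & centers < b[3]); by <- sum(centers > b[2] & centers < b[4])
  ix <- sum(centers > max(a[1], b[1]) & centers < min(a[3], b[3]))
  iy <- sum(centers > max(a[2], b[2]) & centers < min(a[4], b[4]))
  inter <- ix * iy
  un <- ax * ay + bx * by - inter
  if (un == 0) 0 else inter / un
}

random_box <- function(min_side = 0.05) {
  repeat {
    x <- sort(stats::runif(2)); y <- sort(stats::runif(2))
    if (x[2] - x[1] > min_side && y[2] - y[1] > min_side)
      return(c(x[1], y[1], x[2], y[2]))
  }
}

# Small single-lesion synthetic records shared by pipeline tests.
tiny_records <- function(n, seed = 5L, size = 64L) {
  p <- synthetic_params(size, size, lesion_count_range = c(1L, 1L),
                        lesion_size_range = c(0.15, 0.3), seed = seed)
  generate_dataset(p, n)
}
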