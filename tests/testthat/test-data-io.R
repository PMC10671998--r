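# Image and annotation I/O, coordinate conversion, dataset split.

test_that("PNG and TIFF round trips rescale intensities into [0,1]", {
  td <- tempfile(); dir.create(td)
  ones <- matrix(1, 10, 12)
  png::writePNG(ones, file.path(td, "white.png"))
  img <- load_image(file.path(td, "white.png"))
  expect_true(all(img$pixels == 1))
  expect_equal(img$id, "white")
  expect_equal(c(img$height, img$width), c(10, 12))

  tiff::writeTIFF(matrix(0, 8, 8), file.path(td, "zero.tif"), bits.per.sample = 16L)
  img0 <- load_image(file.path(td, "zero.tif"))
  expect_true(all(img0$pixels == 0))

  # RGB -> grayscale by unweighted channel mean
  rgb <- array(0, c(6, 6, 3))
  rgb[, , 1] <- 0.9; rgb[, , 2] <- 0.3; rgb[, , 3] <- 0.3
  png::writePNG(rgb, file.path(td, "rgb.png"))
  imgc <- load_image(file.path(td, "rgb.png"))
  expect_equal(dim(imgc$pixels), c(6, 6))
  expect_equal(imgc$pixels[1, 1], 0.5, tolerance = 1 / 255)

  expect_error(load_image(file.path(td, "missing.png")), "not found")
})

test_that("bilinear resize honors target shape, identity and constants", {
  set.seed(2)
  img <- scan_image(matrix(runif(500 * 412), 412, 500), id = "bscan")
  small <- resize_image(img, 250, 250)
  expect_equal(c(small$height, small$width), c(250, 250))
  expect_identical(resize_image(img, 412, 500)$pixels, img$pixels)
  const <- resize_image(scan_image(matrix(0.37, 64, 64)), 40, 96)
  expect_equal(range(const$pixels), c(0.37, 0.37))
  expect_error(resize_image(img, 4, 100), ">= 8")
})

test_that("CSV box tables normalize by image size and round-trip exactly", {
  td <- tempfile(); dir.create(td)
  f <- file.path(td, "boxes.csv")
  writeLines(c("image_id,x_min,y_min,x_max,y_max,width,height",
               "img1,10,20,30,40,100,100"), f)
  tab <- read_box_table(f, k = 3)
  expect_equal(unclass(tab$img1)[1, ], c(x_min = 0.10, y_min = 0.20,
                                         x_max = 0.30, y_max = 0.40))
  # empty table
  writeLines("image_id,x_min,y_min,x_max,y_max,width,height", f)
  expect_length(read_box_table(f), 0)
  # malformed rows are rejected
  writeLines(c("image_id,x_min,y_min,x_max,y_max,width,height",
               "img1,30,20,10,40,100,100"), f)
  expect_error(read_box_table(f), "malformed")
  writeLines(c("image_id,x_min,y_min,x_max,y_max,width,height",
               "img1,10,20,30,400,100,100"), f)
  expect_error(read_box_table(f), "outside")

  # write -> read reproduces a 3-box record to 1e-9
  set.seed(8)
  ba <- box_array(rbind(random_box(), random_box(), random_box()), k = 3)
  write_box_table(list(scan7 = ba), f, width = 500, height = 412)
  back <- read_box_table(f, k = 3)
  expect_lt(max(abs(unclass(back$scan7) - unclass(ba))), 1e-9)
})

test_that("COCO-style annotations round-trip through JSON", {
  td <- tempfile(); dir.create(td)
  set.seed(9)
  recs <- tiny_records(2, seed = 9)
  f <- file.path(td, "ann.json")
  write_coco(recs, f)
  doc <- jsonlite::fromJSON(f)
  expect_equal(doc$categories$name, "lesion")
  back <- read_coco(f, k = 3)
  for (r in recs)
    expect_equal(unclass(back[[r$image$id]]), unclass(r$boxes),
                 tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("split_dataset produces the 60/10/30 partition", {
  sp <- split_dataset(as.list(1:100), seed = 4)
  expect_equal(lengths(sp), c(train = 60, validation = 10, test = 30))
  sp10 <- split_dataset(as.list(1:10), seed = 4)
  expect_equal(lengths(sp10), c(train = 6, validation = 1, test = 3))
  # disjoint and exhaustive
  all_ids <- sort(unname(unlist(sp)))
  expect_equal(all_ids, 1:100)
  # reproducible
  sp2 <- split_dataset(as.list(1:100), seed = 4)
  expect_identical(sp, sp2)
  sp3 <- split_dataset(as.list(1:100), seed = 5)
  expect_false(identical(sp, sp3))
  expect_error(split_dataset(as.list(1:2), seed = 1), "at least 3")
  expect_error(split_dataset(as.list(1:10), fractions = c(0.5, 0.2, 0.2)),
               "summing to 1")
})

test_that("synthetic datasets survive a disk round trip", {
  td <- tempfile(); dir.create(td)
  p <- synthetic_params(64, 64, lesion_count_range = c(1, 2),
                        lesion_size_range = c(0.15, 0.3), seed = 21)
  recs <- generate_dataset(p, 3)
  write_scan_dataset(recs, td, params = p)
  expect_true(file.exists(file.path(td, "manifest.txt")))
  back <- read_scan_dataset(td, k = 3)
  expect_length(back, 3)
  for (i in 1:3) {
    expect_equal(back[[i]]$image$id, recs[[i]]$image$id)
    # PNG quantizes to 8 bits
    expect_lt(max(abs(back[[i]]$image$pixels - recs[[i]]$image$pixels)), 1 / 255)
    expect_equal(unclass(back[[i]]$boxes), unclass(recs[[i]]$boxes),
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
})
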