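# Box geometry and the composite loss.

test_that("box_iou matches exact and rasterized values", {
  expect_equal(box_iou(c(0, 0, 0.5, 0.5), c(0, 0, 0.5, 0.5)), 1)
  expect_equal(box_iou(c(0, 0, 0.2, 0.2), c(0.5, 0.5, 0.7, 0.7)), 0)
  # worked pair: intersection 0.01, union 0.07
  expect_equal(box_iou(c(0, 0, 0.2, 0.2), c(0.1, 0.1, 0.3, 0.3)), 1 / 7,
               tolerance = 1e-12)
  expect_equal(box_iou(c(0, 0, 0, 0), c(0, 0, 0, 0)), 0)
  set.seed(31)
  for (i in 1:50) {
    # grid-aligned boxes: the counting oracle is exact there (see the
    # acceptance test for the rationale)
    a <- round(random_box() * 1000) / 1000
    b <- round(random_box() * 1000) / 1000
    expect_equal(box_iou(a, b), box_iou(b, a))   # symmetric
    expect_lt(abs(box_iou(a, b) - iou_raster_oracle(a, b)), 2e-3)
    expect_gte(box_iou(a, b), 0); expect_lte(box_iou(a, b), 1)
  }
})

test_that("loss_mse is the coordinate mean square with hand-checked value", {
  a <- box_array(c(0.2, 0.2, 0.4, 0.4), k = 1)
  z <- box_array(NULL, k = 1)
  expect_equal(loss_mse(a, a), 0)
  expect_equal(loss_mse(z, a), (0.04 + 0.04 + 0.16 + 0.16) / 4)  # 0.10
  expect_equal(loss_mse(z, a), loss_mse(a, z))                   # symmetric
})

test_that("loss_iou follows the worked pair and sentinel exclusion rules", {
  b1 <- box_array(c(0, 0, 0.2, 0.2), k = 3)
  b2 <- box_array(c(0.1, 0.1, 0.3, 0.3), k = 3)
  expect_equal(loss_iou(b1, b1), 0)
  expect_equal(loss_iou(b1, b2), 6 / 7, tolerance = 1e-12)
  disj <- box_array(c(0.6, 0.6, 0.8, 0.8), k = 3)
  expect_equal(loss_iou(b1, disj), 1)
  z <- box_array(NULL, k = 3)
  expect_equal(loss_iou(z, z), 0)  # all-sentinel pairs excluded
})

test_that("loss_difference is zero on identity, bounded, and matches the
           reference SSIM implementation", {
  a <- box_array(c(0.3, 0.3, 0.6, 0.6), k = 1)
  expect_equal(loss_difference(a, a, c(64, 64)), 0)
  b <- box_array(c(0.55, 0.55, 0.85, 0.85), k = 1)  # shifted by half image
  ld <- loss_difference(a, b, c(64, 64))
  expect_gte(ld, 0); expect_lte(ld, 1); expect_gt(ld, 0.01)
  z <- box_array(NULL, k = 1)
  expect_equal(loss_difference(z, z, c(64, 64)), 0)
})

test_that("windowed SSIM agrees with scikit-image on a small fixture", {
  skip_if_not(nzchar(Sys.which("python")), "python not on PATH")
  set.seed(7)
  x <- matrix(runif(40 * 40), 40, 40)
  y <- pmin(pmax(x + matrix(rnorm(40 * 40, sd = 0.1), 40, 40), 0), 1)
  td <- tempfile(); dir.create(td)
  write.csv(x, file.path(td, "x.csv"), row.names = FALSE)
  write.csv(y, file.path(td, "y.csv"), row.names = FALSE)
  script <- file.path(td, "ssim.py")
  writeLines(c(
    "import numpy as np",
    "from skimage.metrics import structural_similarity",
    sprintf("x = np.loadtxt(r'%s', delimiter=',', skiprows=1)", file.path(td, "x.csv")),
    sprintf("y = np.loadtxt(r'%s', delimiter=',', skiprows=1)", file.path(td, "y.csv")),
    "s = structural_similarity(x, y, win_size=7, data_range=1.0)",
    "print(repr(float(s)))"), script)
  out <- suppressWarnings(system2("python", script, stdout = TRUE))
  skip_if(length(out) == 0 || is.na(suppressWarnings(as.numeric(out[length(out)]))),
          "scikit-image unavailable")
  ref <- as.numeric(out[length(out)])
  expect_equal(ssim(x, y), ref, tolerance = 1e-6)
})

test_that("lloss composes its components and vanishes only at identity", {
  a <- box_array(c(0.2, 0.2, 0.4, 0.4), k = 1)
  lb <- lloss(a, a)
  expect_s3_class(lb, "loss_breakdown")
  expect_equal(lb$l_total, 0)
  z <- box_array(NULL, k = 1)
  lb2 <- lloss(z, a)
  expect_equal(lb2$l_total, (lb2$l_mse + lb2$l_difference + lb2$l_iou) / 3)
  expect_equal(lb2$l_mse, 0.10)
  expect_equal(lb2$l_iou, 1)
  expect_gt(lb2$l_total, 0)
  set.seed(41)
  for (i in 1:10) {
    p <- box_array(random_box(), k = 2)
    q <- box_array(random_box(), k = 2)
    lt <- lloss(p, q)$l_total
    expect_gte(lt, 0); expect_lte(lt, 1)
  }
})

test_that("lloss decreases monotonically as a disjoint box translates onto
           the target", {
  target <- matrix(c(0.6, 0.6, 0.8, 0.8), 1)
  start <- c(0.05, 0.05, 0.25, 0.25)
  shift <- c(0.55, 0.55, 0.55, 0.55)
  vals <- sapply(seq(0, 1, length.out = 20), function(t)
    lloss(matrix(start + t * shift, 1), target, c(64, 64))$l_total)
  expect_true(all(diff(vals) < 1e-8))
  expect_equal(vals[20], 0, tolerance = 1e-12)
})

test_that("analytic loss gradient matches finite differences", {
  set.seed(13)
  h <- 1e-5
  for (rep in 1:4) {
    pred <- rbind(random_box(), random_box())
    act <- rbind(random_box(), c(0, 0, 0, 0))
    ga <- octdetect:::lloss_grad(pred, act)
    for (i in 1:2) for (j in 1:4) {
      p1 <- pred; p1[i, j] <- p1[i, j] + h
      p2 <- pred; p2[i, j] <- p2[i, j] - h
      fd <- (lloss(p1, act)$l_total - lloss(p2, act)$l_total) / (2 * h)
      expect_equal(ga[i, j], fd, tolerance = 1e-4)
    }
  }
})
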