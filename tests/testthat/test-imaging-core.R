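test_that("image_grid validates pixels, spacing and origin", {
  expect_s3_class(image_grid(matrix(0, 4, 4)), "image_grid")
  expect_error(image_grid(matrix(c(1, NA, 1, 1), 2, 2)), "finite")
  expect_error(image_grid(matrix(0, 4, 4), spacing = c(1, -1)), "positive")
  expect_error(image_grid(array(0, c(2, 2, 2))), "matrix")
})

test_that("warping with the identity transform is a no-op", {
  set.seed(1)
  img <- image_grid(matrix(runif(256), 16, 16))
  for (interp in c("bilinear", "nearest")) {
    out <- warp_image(img, transform_identity(c(16, 16)), interp)
    expect_identical(out$pixels, img$pixels)
  }
})

test_that("constant integer shift matches an index-shift oracle", {
  set.seed(2)
  img <- image_grid(matrix(runif(256), 16, 16))
  shift <- transform_dense(deformation_field(matrix(3, 16, 16),
                                             matrix(0, 16, 16)))
  out <- warp_image(img, shift, "nearest", "edge")
  # backward warping: output row r samples input row r + 3
  expect_equal(out$pixels[1:13, ], img$pixels[4:16, ])
  # edge clamp: rows beyond the border repeat the last input row
  expect_equal(out$pixels[14:16, ],
               img$pixels[c(16, 16, 16), ])
})

test_that("zero images stay zero under any transform and boundary", {
  img <- image_grid(matrix(0, 12, 12))
  f <- generate_deformation(deformation_spec(max_displacement_px = 3,
                                             smoothness_sigma_px = 2,
                                             seed = 4), c(12, 12))
  for (b in c("edge", "zero")) {
    out <- warp_image(img, transform_dense(f), "bilinear", b)
    expect_true(all(out$pixels == 0))
  }
})

test_that("warp rejects mismatched shapes and non-finite fields", {
  img <- image_grid(matrix(0, 8, 8))
  expect_error(warp_image(img, transform_identity(c(9, 8))),
               "does not match")
  bad <- deformation_field(matrix(0, 8, 8), matrix(0, 8, 8))
  bad$dy[1, 1] <- Inf
  expect_error(warp_image(img, transform_dense(bad)), "finite")
})

test_that("transform_points converts pixel displacements to mm", {
  img <- image_grid(matrix(0, 32, 32), spacing = c(0.5, 0.5))
  lm <- landmark_set(rbind(c(5, 5), c(10, 3)), c("a", "b"), image = img)
  # identity leaves points untouched
  same <- transform_points(lm, transform_identity(c(32, 32)), img)
  expect_equal(same$points, lm$points)
  # uniform (1, 2) px shift at 0.5 mm spacing moves every point (0.5, 1) mm
  shift <- transform_dense(deformation_field(matrix(1, 32, 32),
                                             matrix(2, 32, 32),
                                             c(0.5, 0.5)))
  moved <- transform_points(lm, shift, img)
  expect_equal(moved$points, lm$points + rep(c(0.5, 1), each = 2))
})

test_that("transform_points matches a per-point bilinear oracle", {
  img <- image_grid(matrix(0, 64, 64), spacing = c(0.7, 0.7))
  f <- generate_deformation(deformation_spec(max_displacement_px = 4,
                                             smoothness_sigma_px = 6,
                                             seed = 9), c(64, 64))
  set.seed(10)
  px <- cbind(runif(10, 2, 60), runif(10, 2, 60))
  lm <- landmark_set(px * 0.7, image = img)
  moved <- transform_points(lm, transform_dense(f), img)
  bilin1 <- function(m, y, x) {
    y0 <- floor(y); x0 <- floor(x); fy <- y - y0; fx <- x - x0
    (1 - fy) * (1 - fx) * m[y0 + 1, x0 + 1] + fy * (1 - fx) * m[y0 + 2, x0 + 1] +
      (1 - fy) * fx * m[y0 + 1, x0 + 2] + fy * fx * m[y0 + 2, x0 + 2]
  }
  for (i in 1:10) {
    dy <- bilin1(f$dy, px[i, 1], px[i, 2])
    dx <- bilin1(f$dx, px[i, 1], px[i, 2])
    expect_equal(unname(moved$points[i, ]),
                 c((px[i, 1] + dy) * 0.7, (px[i, 2] + dx) * 0.7),
                 tolerance = 1e-12)
  }
})

test_that("out-of-domain landmarks are excluded with a warning", {
  img <- image_grid(matrix(0, 16, 16))
  lm <- landmark_set(rbind(c(3, 3), c(40, 3)), c("in", "out"))
  expect_warning(out <- transform_points(lm, transform_identity(c(16, 16)),
                                         img), "out")
  expect_equal(out$labels, "in")
  expect_equal(attr(out, "dropped"), "out")
})

test_that("16-bit TIFF round trip is bit-identical", {
  set.seed(3)
  img <- image_grid(matrix(sample(0:65535, 64) / 65535, 8, 8),
                    spacing = c(1, 1))
  path <- withr::local_tempfile(fileext = ".tif")
  write_image(img, path)
  back <- suppressWarnings(read_image(path, spacing = c(1, 1)))
  expect_identical(back$pixels, img$pixels)
})

test_that("NIfTI round trip preserves pixels and spacing", {
  set.seed(4)
  img <- image_grid(matrix(rnorm(96), 12, 8), spacing = c(0.3, 0.3))
  path <- withr::local_tempfile(fileext = ".nii.gz")
  write_image(img, path)
  back <- read_image(path)
  expect_equal(back$pixels, img$pixels, tolerance = 1e-12)
  expect_equal(back$spacing, img$spacing, tolerance = 1e-6)
})

test_that("PNG without spacing warns and defaults to 1 mm", {
  img <- image_grid(matrix(runif(64), 8, 8))
  path <- withr::local_tempfile(fileext = ".png")
  write_image(img, path)
  expect_warning(back <- read_image(path), "spacing")
  expect_equal(back$spacing, c(1, 1))
})

test_that("3D NIfTI volumes are rejected with the offending shape", {
  arr <- array(runif(4 * 4 * 3), c(4, 4, 3))
  path <- withr::local_tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(arr), path)
  expect_error(read_image(path), "4 x 4 x 3")
})

test_that("landmark CSV and field NIfTI round trips are lossless", {
  lm <- landmark_set(rbind(c(1.25, 3.5), c(7, 2)), c("T1", "T2"))
  lp <- withr::local_tempfile(fileext = ".csv")
  write_landmarks(lm, lp)
  expect_equal(read_landmarks(lp)$points, lm$points)
  f <- generate_deformation(deformation_spec(seed = 2), c(16, 16),
                            c(0.5, 0.5))
  fp <- withr::local_tempfile(fileext = ".nii.gz")
  write_field(f, fp)
  back <- read_field(fp)
  expect_equal(back$dy, f$dy, tolerance = 1e-6)
  expect_equal(back$dx, f$dx, tolerance = 1e-6)
  expect_equal(back$spacing, c(0.5, 0.5))
})

test_that("invert_field composes with the field to near-identity", {
  f <- generate_deformation(deformation_spec(max_displacement_px = 5,
                                             smoothness_sigma_px = 16,
                                             seed = 6), c(96, 96))
  inv <- invert_field(f)
  # u(x) + d(x + u(x)) should vanish
  yy <- rep(0:95, times = 96); xx <- rep(0:95, each = 96)
  sy <- cosreg:::bilinear_sample(f$dy, yy + as.vector(inv$dy),
                                 xx + as.vector(inv$dx))
  resid <- abs(as.vector(inv$dy) + sy)
  expect_lt(mean(resid), 0.05)
})
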