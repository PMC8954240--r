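test_that("target registration error is the per-label distance in mm", {
  a <- landmark_set(rbind(c(0, 0), c(2, 1)), c("T1", "T2"))
  expect_equal(tre(a, a)$per_target, c(T1 = 0, T2 = 0))
  b <- landmark_set(rbind(c(3, 4), c(2, 1)), c("T1", "T2"))
  got <- tre(a, b)
  expect_equal(unname(got$per_target), c(5, 0))
  expect_equal(got$mean, 2.5)
  # matching is by label, not order
  b_swapped <- landmark_set(rbind(c(2, 1), c(3, 4)), c("T2", "T1"))
  expect_equal(tre(a, b_swapped)$per_target, got$per_target)
  expect_error(tre(a, landmark_set(rbind(c(0, 0)), "T1")), "T2")
  set.seed(1)
  pa <- matrix(runif(20), 10, 2); pb <- matrix(runif(20), 10, 2)
  la <- landmark_set(pa); lb <- landmark_set(pb)
  expect_equal(unname(tre(la, lb)$per_target),
               sqrt(rowSums((pa - pb)^2)), tolerance = 1e-12)
})

test_that("displacement RMSE converts residual vectors to mm", {
  f0 <- deformation_field(matrix(0, 8, 8), matrix(0, 8, 8))
  gt <- deformation_field(matrix(3, 8, 8), matrix(4, 8, 8))
  expect_identical(displacement_rmse(gt, gt), 0)
  expect_equal(displacement_rmse(gt, f0, spacing = c(1, 1)), 5)
  set.seed(2)
  a <- deformation_field(matrix(rnorm(64), 8, 8), matrix(rnorm(64), 8, 8))
  b <- deformation_field(matrix(rnorm(64), 8, 8), matrix(rnorm(64), 8, 8))
  oracle <- sqrt(mean(((a$dy - b$dy) * 0.5)^2 + ((a$dx - b$dx) * 0.7)^2))
  expect_equal(displacement_rmse(a, b, spacing = c(0.5, 0.7)), oracle,
               tolerance = 1e-12)
  expect_error(displacement_rmse(a, b, mask = matrix(FALSE, 8, 8)), "mask")
})

test_that("HD95 matches brute force and is bounded by the maximum HD", {
  expect_equal(as.numeric(hausdorff95(rbind(c(0, 0)), rbind(c(0, 0)))), 0)
  one <- hausdorff95(rbind(c(0, 0)), rbind(c(3, 4)))
  expect_equal(as.numeric(one), 5)
  expect_equal(attr(one, "hd_max"), 5)
  set.seed(3)
  A <- matrix(runif(100, 0, 10), 50, 2)
  B <- matrix(runif(100, 0, 10), 50, 2)
  d <- as.matrix(dist(rbind(A, B)))[1:50, 51:100]
  dab <- apply(d, 1, min); dba <- apply(d, 2, min)
  oracle <- max(quantile(dab, 0.95, type = 7), quantile(dba, 0.95, type = 7))
  got <- hausdorff95(A, B)
  expect_equal(as.numeric(got), unname(oracle), tolerance = 1e-12)
  expect_lte(as.numeric(got), attr(got, "hd_max"))
  # invariance under a common rigid translation
  shift <- c(2.5, -1)
  shifted <- hausdorff95(sweep(A, 2, shift, "+"), sweep(B, 2, shift, "+"))
  expect_equal(as.numeric(shifted), as.numeric(got), tolerance = 1e-12)
  expect_error(hausdorff95(A[0, ], B), "non-empty")
})

test_that("mask boundaries are the 4-connectivity rim in mm", {
  m <- matrix(FALSE, 6, 6); m[2:5, 2:5] <- TRUE
  b <- mask_boundary_points(m, c(2, 2))
  expect_equal(nrow(b), 12)   # 4x4 block: all but the 2x2 interior
  expect_true(all(b[, 1] %in% ((1:4) * 2)))
})

test_that("evaluate_run reports zero for a perfect no-deformation run", {
  ph <- small_phantom()
  zero <- deformation_field(matrix(0, 128, 128), matrix(0, 128, 128),
                            c(1.25, 1.25))
  gt <- list(field = zero, landmarks = ph$landmarks, mask = ph$vessel_mask)
  ev <- evaluate_run(gt, transform_identity(c(128, 128)), ph$mr)
  expect_equal(ev$rmse_mm, 0)
  expect_equal(ev$tre_mm, 0)
  expect_equal(ev$hd95_mm, 0)
})

test_that("identity evaluation equals the deformation's own statistics", {
  ph <- small_phantom()
  f <- generate_deformation(deformation_spec(max_displacement_px = 4,
                                             smoothness_sigma_px = 12,
                                             seed = 41), c(128, 128),
                            c(1.25, 1.25))
  inv <- invert_field(f)
  gt <- list(field = f, inv_field = inv, landmarks = ph$landmarks,
             mask = ph$vessel_mask)
  ev <- evaluate_run(gt, transform_identity(c(128, 128)), ph$mr)
  expect_equal(ev$rmse_mm,
               sqrt(mean((inv$dy * 1.25)^2 + (inv$dx * 1.25)^2)),
               tolerance = 1e-12)
  lm_px <- cosreg:::landmarks_to_px(ph$landmarks, ph$mr)
  uy <- cosreg:::bilinear_sample(inv$dy, lm_px[, 1], lm_px[, 2])
  ux <- cosreg:::bilinear_sample(inv$dx, lm_px[, 1], lm_px[, 2])
  expect_equal(ev$tre_mm, mean(sqrt((uy * 1.25)^2 + (ux * 1.25)^2)),
               tolerance = 1e-12)
})

test_that("report aggregation reproduces hand-computed mean and sd", {
  rows <- list(
    list(rmse_mm = 1, tre_mm = 2, tre_per_target = c(a = 2), hd95_mm = 3,
         method = "M"),
    list(rmse_mm = 2, tre_mm = 4, tre_per_target = c(a = 4), hd95_mm = 5,
         method = "M"),
    list(rmse_mm = 3, tre_mm = 6, tre_per_target = c(a = 6), hd95_mm = 7,
         method = "M"))
  rep <- eval_report(rows)
  expect_equal(rep$rmse_mean, 2)
  expect_equal(rep$rmse_sd, 1)
  expect_equal(rep$tre_mean, 4)
  expect_equal(rep$tre_sd, 2)
  expect_equal(rep$hd95_mean, 5)
  expect_equal(rep$n_runs, 3)
  single <- eval_report(rows[1])
  expect_true(is.na(single$rmse_sd))
})
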