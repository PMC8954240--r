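test_that("NMI matches its definition and degenerate conventions", {
  set.seed(1)
  img <- image_grid(matrix(runif(256), 16, 16))
  expect_equal(nmi_metric(img, img, 32), 2, tolerance = 1e-9)
  # brute-force histogram/entropy oracle on a random pair
  a <- image_grid(matrix(runif(256), 16, 16))
  b <- image_grid(matrix(runif(256), 16, 16))
  bin_of <- function(v, bins) {
    r <- range(v)
    pmin(pmax(floor((v - r[1]) / diff(r) * bins) + 1L, 1L), bins)
  }
  ia <- bin_of(as.vector(a$pixels), 16); ib <- bin_of(as.vector(b$pixels), 16)
  H <- function(cnt) { p <- cnt[cnt > 0] / sum(cnt); -sum(p * log(p)) }
  oracle <- (H(table(ia)) + H(table(ib))) / H(table(paste(ia, ib)))
  expect_equal(nmi_metric(a, b, 16), oracle, tolerance = 1e-12)
  # constant conventions
  flat <- image_grid(matrix(1, 16, 16))
  expect_identical(nmi_metric(flat, flat), 2)
  expect_warning(v <- nmi_metric(flat, a), "constant")
  expect_true(is.na(v))
})

test_that("NMI of independent noise approaches 1", {
  for (s in 1:5) {
    set.seed(100 + s)
    a <- image_grid(matrix(runif(256 * 256), 256, 256))
    b <- image_grid(matrix(runif(256 * 256), 256, 256))
    expect_lt(abs(nmi_metric(a, b, 32) - 1), 0.02)
  }
})

test_that("coupled cost matches an independent recomputation", {
  ph <- small_phantom()
  ops <- small_operators()
  cfg <- registration_config(pyramid_levels = 1)
  centers <- cbind(y = c(20, 40, 60, 80, 100), x = c(30, 50, 64, 70, 90))
  nu <- 1000
  for (s in 1:5) {
    f <- generate_deformation(deformation_spec(max_displacement_px = 3,
                                               smoothness_sigma_px = 8,
                                               seed = s), c(128, 128))
    tf <- transform_dense(f)
    got <- coupled_cost(ph$mr, ph$pa, tf, ops, centers, cfg, nu)
    O_s <- rbind(unclass(ops$op_a), unclass(ops$op_b))
    cc <- function(P) sweep(P, 2, colMeans(P))
    B <- O_s %*% cc(patch_at(ph$mr, centers, 7))
    moved <- cbind(centers[, 1] + f$dy[centers + 1],
                   centers[, 2] + f$dx[centers + 1])
    M <- O_s %*% cc(patch_at(ph$pa, moved, 7))
    sb <- log1p(nu * B^2); sm <- log1p(nu * M^2)
    cb <- sweep(sb, 2, colMeans(sb)); cm <- sweep(sm, 2, colMeans(sm))
    oracle <- mean(-colSums(cb * cm) /
                     (sqrt(colSums(cb^2)) * sqrt(colSums(cm^2)) + 1e-9))
    expect_equal(as.numeric(got), oracle, tolerance = 1e-10)
  }
})

test_that("self-registration cost is lowest at the identity", {
  ph <- small_phantom()
  ops <- mono_small_operators()
  cfg <- registration_config(pyramid_levels = 1)
  centers <- cosreg:::level_centers(c(128, 128), cfg)
  id_cost <- coupled_cost(ph$mr, ph$mr, transform_identity(c(128, 128)),
                          ops, centers, cfg)
  for (s in 1:10) {
    f <- generate_deformation(deformation_spec(max_displacement_px = 2,
                                               smoothness_sigma_px = 10,
                                               seed = s), c(128, 128))
    perturbed <- coupled_cost(ph$mr, ph$mr, transform_dense(f), ops,
                              centers, cfg)
    expect_gt(as.numeric(perturbed), as.numeric(id_cost))
  }
})

test_that("a constant metric leaves the initialization unchanged", {
  ph <- small_phantom()
  flat_factory <- function(ref_l, flo_l, centers, f) {
    list(cost_full = function(dy, dx) 1,
         cost_sub = function(idx, dys, dxs) 1,
         commit = function(dy, dx) invisible(NULL))
  }
  res <- cosreg:::register_deformable(ph$mr, ph$pa, flat_factory,
                                      registration_config(pyramid_levels = 1,
                                                          max_iter_per_level = 3),
                                      "flat")
  expect_true(all(res$transform$control_y == 0))
  expect_true(all(res$transform$control_x == 0))
})

test_that("registering an image to itself returns the identity", {
  ph <- study_phantom()
  res <- register_jacsm(ph$mr, ph$mr, mono_operators(),
                        registration_config(max_iter_per_level = 5))
  fld <- as_deformation_field(res$transform)
  expect_lt(mean(sqrt(fld$dy^2 + fld$dx^2)), 0.05)
  rn <- register_nmi(ph$mr, ph$mr, registration_config(max_iter_per_level = 5))
  fn <- as_deformation_field(rn$transform)
  expect_lt(mean(sqrt(fn$dy^2 + fn$dx^2)), 0.05)
})

test_that("cost traces never increase and share the pyramid structure", {
  ph <- small_phantom()
  f <- generate_deformation(deformation_spec(max_displacement_px = 4,
                                             smoothness_sigma_px = 16,
                                             seed = 31), c(128, 128),
                            c(1.25, 1.25))
  pa_def <- warp_image(ph$pa, transform_dense(f))
  cfg <- registration_config(pyramid_levels = 2, max_iter_per_level = 4)
  rj <- register_jacsm(ph$mr, pa_def, small_operators(), cfg)
  rn <- register_nmi(ph$mr, pa_def, cfg)
  for (res in list(rj, rn)) {
    expect_true(res$converged)
    for (tr in res$cost_trace) expect_true(all(diff(tr) <= 0))
  }
  # metric swap changes no plumbing: same pyramid depth and transform space
  expect_identical(length(rj$cost_trace), length(rn$cost_trace))
  expect_identical(dim(rj$transform$control_y), dim(rn$transform$control_y))
})

test_that("NMI recovers a mono-modal deformation", {
  ph <- small_phantom()
  red <- vapply(33:35, function(s) {
    f <- generate_deformation(deformation_spec(max_displacement_px = 8,
                                               smoothness_sigma_px = 32,
                                               seed = s), c(128, 128),
                              c(1.25, 1.25))
    mr_def <- warp_image(ph$mr, transform_dense(f))
    gt <- list(field = f, landmarks = ph$landmarks, mask = ph$vessel_mask)
    un <- evaluate_run(gt, transform_identity(c(128, 128)), ph$mr)
    ev <- evaluate_run(gt, register_nmi(ph$mr, mr_def,
                                        registration_config()), ph$mr)
    1 - ev$tre_mm / un$tre_mm
  }, numeric(1))
  expect_gte(median(red), 0.5)
})
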