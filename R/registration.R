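#' Deformable registration settings
#'
#' Both registrars (JACSM and NMI) share this configuration and the same
#' optimization scaffold: a coarse-to-fine image pyramid, a cubic B-spline
#' free-form deformation whose control grid is defined once on the
#' full-resolution domain, central finite-difference gradients on the control
#' displacements, and a backtracking line search that guarantees a
#' non-increasing cost trace.
#'
#' @param transform_model currently \code{"bspline"} (cubic FFD).
#' @param grid_spacing_px FFD knot spacing in full-resolution pixels; must be
#'   at least the patch size.
#' @param pyramid_levels number of pyramid levels (level L is downsampled by
#'   2^(L-1)). Two levels by default: the simulated vessels are 2-3 px wide
#'   at full resolution, so a third (x4) level retains no vessel structure
#'   to steer the coarse solution.
#' @param sample_centers \code{"grid"} places cost-sample centres on a regular
#'   grid with stride \code{center_stride_px}; \code{"random"} samples
#'   \code{n_cost_patches} centres uniformly.
#' @param center_stride_px grid stride between cost-sample centres (pixels).
#'   Strides below the patch size give overlapping windows, which constrain
#'   the metric: a false local match cannot satisfy many overlapping windows
#'   at once, while the true deformation can.
#' @param max_control_disp_px box bound on the control-point displacements
#'   (pixels); encodes the a-priori magnitude of the deformation being
#'   recovered (brain shift is bounded). \code{Inf} disables.
#' @param n_cost_patches number of random centres (only for
#'   \code{sample_centers = "random"}).
#' @param max_iter_per_level descent iterations per pyramid level.
#' @param step_init initial line-search step, expressed as the largest control
#'   displacement change in pixels.
#' @param step_shrink line-search backtracking factor in (0, 1).
#' @param tol_rel stop a level when the relative cost decrease of an
#'   iteration falls below this.
#' @param fd_step_px central finite-difference step on control displacements
#'   (pixels).
#' @param bins histogram bins for the NMI metric.
#' @param patch_size patch edge used for cost sampling (must match the
#'   operators for JACSM).
#' @param smooth_sigma_px Gaussian prefilter applied to both images at every
#'   pyramid level before metric evaluation (pixels). Suppresses the pixel
#'   noise floor so that the interpolation smoothing inherent in off-grid
#'   sampling does not bias the metric toward fractional displacements; 0
#'   disables.
#' @param reg_weight weight of the bending-energy penalty on the control
#'   grid (mean squared second differences of the control displacements, in
#'   px^2); discourages physically implausible wiggles that over-fit a
#'   sampled metric. 0 disables.
#' @param center_mask_quantile keep only the cost-sample centres whose
#'   reference patch standard deviation exceeds this quantile of all centres
#'   (0 keeps all). Structureless reference windows carry no alignment
#'   information but let a sampled metric be gamed by sliding them onto
#'   arbitrary float content; masking is computed on the fixed reference, so
#'   it cannot be exploited by the optimizer.
#' @param grad_smooth_knots Gaussian smoothing of the finite-difference
#'   gradient over the control grid, in knots; confines updates to
#'   deformation modes at least as smooth as the knot spacing. 0 disables.
#' @param seed seed for random centre sampling.
#' @return A list of class \code{registration_config}.
#' @export
registration_config <- function(transform_model = "bspline",
                                grid_spacing_px = 16, pyramid_levels = 2,
                                sample_centers = c("grid", "random"),
                                n_cost_patches = 1500,
                                max_iter_per_level = 20, step_init = 2,
                                step_shrink = 0.5, tol_rel = 1e-4,
                                fd_step_px = 0.5, bins = 32, patch_size = 7,
                                smooth_sigma_px = 1, reg_weight = 2e-4,
                                grad_smooth_knots = 1,
                                center_mask_quantile = 0.75,
                                center_stride_px = 5,
                                max_control_disp_px = 12,
                                sampling = c("bilinear", "kernel"),
                                seed = 1L) {
  sampling = match.arg(sampling)
  sample_centers <- match.arg(sample_centers)
  if (pyramid_levels < 1) stop("pyramid_levels must be >= 1")
  if (grid_spacing_px < patch_size)
    stop("grid_spacing_px must be at least the patch size")
  structure(list(transform_model = match.arg(transform_model, "bspline"),
                 grid_spacing_px = grid_spacing_px,
                 pyramid_levels = as.integer(pyramid_levels),
                 sample_centers = sample_centers,
                 n_cost_patches = as.integer(n_cost_patches),
                 max_iter_per_level = as.integer(max_iter_per_level),
                 step_init = step_init, step_shrink = step_shrink,
                 tol_rel = tol_rel, fd_step_px = fd_step_px,
                 bins = as.integer(bins), patch_size = as.integer(patch_size),
                 smooth_sigma_px = smooth_sigma_px,
                 reg_weight = reg_weight,
                 grad_smooth_knots = grad_smooth_knots,
                 center_mask_quantile = center_mask_quantile,
                 center_stride_px = center_stride_px,
                 max_control_disp_px = max_control_disp_px,
                 sampling = sampling,
                 seed = as.integer(seed)),
            class = "registration_config")
}

downsample2 <- function(pixels) {
  ny <- nrow(pixels) %/% 2L * 2L; nx <- ncol(pixels) %/% 2L * 2L
  p <- pixels[seq_len(ny), seq_len(nx)]
  (p[seq(1, ny, 2), seq(1, nx, 2)] + p[seq(2, ny, 2), seq(1, nx, 2)] +
     p[seq(1, ny, 2), seq(2, nx, 2)] + p[seq(2, ny, 2), seq(2, nx, 2)]) / 4
}

downsample_image <- function(image, factor) {
  p <- image$pixels
  f <- factor
  while (f > 1) { p <- downsample2(p); f <- f / 2 }
  image_grid(p, image$spacing * factor, image$modality, image$origin)
}

level_centers <- function(shape, cfg) {
  h <- (cfg$patch_size - 1) %/% 2
  stride <- if (is.null(cfg$center_stride_px)) cfg$patch_size else
    cfg$center_stride_px
  ys <- seq(h, shape[1] - 1 - h, by = stride)
  xs <- seq(h, shape[2] - 1 - h, by = stride)
  if (cfg$sample_centers == "grid") {
    cbind(y = rep(ys, times = length(xs)), x = rep(xs, each = length(ys)))
  } else {
    set.seed(cfg$seed)
    cbind(y = stats::runif(cfg$n_cost_patches, h, shape[1] - 1 - h),
          x = stats::runif(cfg$n_cost_patches, h, shape[2] - 1 - h))
  }
}

# Dense FFD weight matrix mapping control displacements (full-resolution px)
# to displacements at the given full-resolution coordinates; also returns the
# per-control-point lists of affected rows (the local FD support).
ffd_weight_matrix <- function(y_full, x_full, grid_spacing_px, gdim) {
  ncp <- gdim[1] * gdim[2]
  nc <- length(y_full)
  cy <- bspline_cells(y_full, grid_spacing_px)
  cx <- bspline_cells(x_full, grid_spacing_px)
  W <- matrix(0, nc, ncp)
  rows <- seq_len(nc)
  for (l in 0:3) {
    iy <- pmin(pmax(cy$i + l + 1, 1), gdim[1])
    for (m in 0:3) {
      ix <- pmin(pmax(cx$i + m + 1, 1), gdim[2])
      col <- (ix - 1) * gdim[1] + iy
      idx <- cbind(rows, col)
      W[idx] <- W[idx] + cy$w[, l + 1] * cx$w[, m + 1]
    }
  }
  support <- lapply(seq_len(ncp), function(p) which(W[, p] != 0))
  list(W = W, support = support)
}

# Bending energy of a control-displacement grid (mean squared second
# differences, including the mixed term twice), and its gradient.
bending_energy <- function(m) {
  n <- nrow(m); k <- ncol(m)
  dyy <- m[1:(n - 2), , drop = FALSE] - 2 * m[2:(n - 1), , drop = FALSE] +
    m[3:n, , drop = FALSE]
  dxx <- m[, 1:(k - 2), drop = FALSE] - 2 * m[, 2:(k - 1), drop = FALSE] +
    m[, 3:k, drop = FALSE]
  dxy <- m[2:n, 2:k, drop = FALSE] - m[1:(n - 1), 2:k, drop = FALSE] -
    m[2:n, 1:(k - 1), drop = FALSE] + m[1:(n - 1), 1:(k - 1), drop = FALSE]
  (sum(dyy^2) + sum(dxx^2) + 2 * sum(dxy^2)) / length(m)
}

bending_gradient <- function(m) {
  n <- nrow(m); k <- ncol(m)
  g <- matrix(0, n, k)
  dyy <- m[1:(n - 2), , drop = FALSE] - 2 * m[2:(n - 1), , drop = FALSE] +
    m[3:n, , drop = FALSE]
  g[1:(n - 2), ] <- g[1:(n - 2), ] + dyy
  g[2:(n - 1), ] <- g[2:(n - 1), ] - 2 * dyy
  g[3:n, ] <- g[3:n, ] + dyy
  dxx <- m[, 1:(k - 2), drop = FALSE] - 2 * m[, 2:(k - 1), drop = FALSE] +
    m[, 3:k, drop = FALSE]
  g[, 1:(k - 2)] <- g[, 1:(k - 2)] + dxx
  g[, 2:(k - 1)] <- g[, 2:(k - 1)] - 2 * dxx
  g[, 3:k] <- g[, 3:k] + dxx
  dxy <- m[2:n, 2:k, drop = FALSE] - m[1:(n - 1), 2:k, drop = FALSE] -
    m[2:n, 1:(k - 1), drop = FALSE] + m[1:(n - 1), 1:(k - 1), drop = FALSE]
  g[2:n, 2:k] <- g[2:n, 2:k] + 2 * dxy
  g[1:(n - 1), 2:k] <- g[1:(n - 1), 2:k] - 2 * dxy
  g[2:n, 1:(k - 1)] <- g[2:n, 1:(k - 1)] - 2 * dxy
  g[1:(n - 1), 1:(k - 1)] <- g[1:(n - 1), 1:(k - 1)] + 2 * dxy
  2 * g / length(m)
}

# Shared coarse-to-fine FFD optimizer. `metric_factory(ref_l, float_l,
# centers, level_factor)` must return a state list with:
#   cost_full(dy, dx)          full cost at centre displacements (level px)
#   cost_sub(idx, dy_s, dx_s)  cost with displacements replaced on a subset
#   commit(dy, dx)             refresh internal caches at accepted iterates
register_deformable <- function(reference, float_img, metric_factory, cfg,
                                method_label) {
  stopifnot_image(reference); stopifnot_image(float_img)
  if (!all(img_shape(reference) == img_shape(float_img)))
    stop("reference and float images must share a shape")
  if (any(abs(reference$spacing - float_img$spacing) > 1e-9))
    warning("reference and float spacing differ; proceeding in pixel units")
  sh <- img_shape(reference)
  gdim <- ffd_grid_dim(sh, cfg$grid_spacing_px)
  ncp <- gdim[1] * gdim[2]
  phi_y <- numeric(ncp); phi_x <- numeric(ncp)
  factors <- 2^((cfg$pyramid_levels - 1):0)
  traces <- vector("list", length(factors))
  h_fd <- cfg$fd_step_px
  for (li in seq_along(factors)) {
    f <- factors[li]
    ref_l <- downsample_image(reference, f)
    flo_l <- downsample_image(float_img, f)
    if (cfg$smooth_sigma_px > 0) {
      ref_l$pixels <- gaussian_smooth(ref_l$pixels, cfg$smooth_sigma_px)
      flo_l$pixels <- gaussian_smooth(flo_l$pixels, cfg$smooth_sigma_px)
    }
    sh_l <- img_shape(ref_l)
    centers <- level_centers(sh_l, cfg)
    if (cfg$center_mask_quantile > 0) {
      psd <- apply(patch_at_kernel(ref_l$pixels, centers, cfg$patch_size), 2,
                   stats::sd)
      keep <- psd >= stats::quantile(psd, cfg$center_mask_quantile,
                                     names = FALSE)
      if (sum(keep) >= 8) centers <- centers[keep, , drop = FALSE]
    }
    # block-mean pixel (i) at level f sits at full-res coordinate i*f+(f-1)/2
    yf <- centers[, 1] * f + (f - 1) / 2
    xf <- centers[, 2] * f + (f - 1) / 2
    wm <- ffd_weight_matrix(yf, xf, cfg$grid_spacing_px, gdim)
    W <- wm$W
    state <- metric_factory(ref_l, flo_l, centers, f)
    reg_of <- function(py, px) {
      if (cfg$reg_weight == 0) return(0)
      cfg$reg_weight * (bending_energy(matrix(py, gdim[1], gdim[2])) +
                          bending_energy(matrix(px, gdim[1], gdim[2])))
    }
    dy <- as.vector(W %*% phi_y) / f
    dx <- as.vector(W %*% phi_x) / f
    cost <- state$cost_full(dy, dx) + reg_of(phi_y, phi_x)
    if (!is.finite(cost))
      stop("non-finite cost at initialization: check operator/patch ",
           "compatibility with the images")
    state$commit(dy, dx)
    trace <- cost
    step_px <- cfg$step_init
    for (it in seq_len(cfg$max_iter_per_level)) {
      grad <- numeric(2 * ncp)
      for (p in seq_len(ncp)) {
        idx <- wm$support[[p]]
        if (length(idx) == 0) next
        wv <- W[idx, p] / f
        grad[p] <- (state$cost_sub(idx, dy[idx] + h_fd * wv, dx[idx]) -
                      state$cost_sub(idx, dy[idx] - h_fd * wv, dx[idx])) /
          (2 * h_fd)
        grad[ncp + p] <- (state$cost_sub(idx, dy[idx], dx[idx] + h_fd * wv) -
                            state$cost_sub(idx, dy[idx],
                                           dx[idx] - h_fd * wv)) / (2 * h_fd)
      }
      if (cfg$reg_weight > 0) {
        grad[seq_len(ncp)] <- grad[seq_len(ncp)] + cfg$reg_weight *
          as.vector(bending_gradient(matrix(phi_y, gdim[1], gdim[2])))
        grad[ncp + seq_len(ncp)] <- grad[ncp + seq_len(ncp)] +
          cfg$reg_weight *
          as.vector(bending_gradient(matrix(phi_x, gdim[1], gdim[2])))
      }
      if (cfg$grad_smooth_knots > 0) {
        grad[seq_len(ncp)] <- as.vector(gaussian_smooth(
          matrix(grad[seq_len(ncp)], gdim[1], gdim[2]),
          cfg$grad_smooth_knots))
        grad[ncp + seq_len(ncp)] <- as.vector(gaussian_smooth(
          matrix(grad[ncp + seq_len(ncp)], gdim[1], gdim[2]),
          cfg$grad_smooth_knots))
      }
      gmax <- max(abs(grad))
      if (gmax == 0) break
      dir <- -grad / gmax          # largest control change = 1 px
      cap <- cfg$max_control_disp_px
      accepted <- FALSE
      for (bt in 1:10) {
        py <- pmin(pmax(phi_y + step_px * dir[seq_len(ncp)], -cap), cap)
        px <- pmin(pmax(phi_x + step_px * dir[ncp + seq_len(ncp)], -cap), cap)
        dyn <- as.vector(W %*% py) / f
        dxn <- as.vector(W %*% px) / f
        cn <- state$cost_full(dyn, dxn) + reg_of(py, px)
        if (is.finite(cn) && cn < cost) {
          rel <- (cost - cn) / max(abs(cost), 1e-12)
          phi_y <- py; phi_x <- px; dy <- dyn; dx <- dxn
          cost <- cn
          state$commit(dy, dx)
          trace <- c(trace, cost)
          step_px <- min(step_px * 2, 4 * cfg$step_init)
          accepted <- TRUE
          break
        }
        step_px <- step_px * cfg$step_shrink
      }
      if (!accepted) break
      if (rel < cfg$tol_rel) break
    }
    traces[[li]] <- trace
  }
  transform <- transform_bspline(matrix(phi_y, gdim[1], gdim[2]),
                                 matrix(phi_x, gdim[1], gdim[2]),
                                 cfg$grid_spacing_px, sh)
  warped <- warp_image(float_img, transform, "bilinear", "edge")
  converged <- all(vapply(traces, function(tr)
    tr[length(tr)] <= tr[1], logical(1)))
  structure(list(transform = transform, warped_float = warped,
                 cost_trace = traces, converged = converged,
                 metadata = list(method = method_label, config = cfg)),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  final <- vapply(x$cost_trace, function(tr) tr[length(tr)], numeric(1))
  cat(sprintf("<registration_result> %s; %d level(s), final costs: %s\n",
              x$metadata$method, length(x$cost_trace),
              paste(signif(final, 5), collapse = ", ")))
  invisible(x)
}

# zero-mean columns
center_cols <- function(X) sweep(X, 2, colMeans(X))

make_jacsm_metric <- function(ops, nu, patch_size,
                              sampling = "bilinear") {
  psample <- if (sampling == "kernel") patch_at_kernel else patch_at_bilinear
  # both learned operators are applied to BOTH patches: responses of matched
  # patches then activate the same rows of the stacked operator, so the
  # coupling rewards same-geometry matches only, independent of how the two
  # modality-specific operators happen to order their rows
  O_s <- rbind(unclass(ops$op_a), unclass(ops$op_b))
  function(ref_l, flo_l, centers, f) {
    # reference responses are fixed; the float image is sampled at the
    # transform-mapped centres (backward-warping convention); both sides use
    # the fixed-width kernel sampler so their smoothing matches
    B <- O_s %*% center_cols(psample(ref_l$pixels, centers, patch_size))
    env <- new.env(parent = emptyenv())
    N <- nrow(centers)
    terms_at <- function(idx, dys, dxs) {
      cy <- centers[idx, 1] + dys
      cx <- centers[idx, 2] + dxs
      # sampling is edge-clamped: windows that drift past the border see
      # duplicated edge rows rather than dropping out, so the cost stays
      # continuous in the displacements
      P <- center_cols(psample(flo_l$pixels, cbind(cy, cx), patch_size))
      M <- O_s %*% P
      # soft co-support indicators of the two patches, correlated across
      # operator rows: the term is -1 when the patches activate exactly the
      # same rows (maximal co-support intersection) and ~0 for unrelated
      # structure; being scale-free, it cannot be improved by inflating or
      # suppressing response magnitudes
      sb <- log1p(nu * B[, idx, drop = FALSE]^2)
      sm <- log1p(nu * M^2)
      cb <- sweep(sb, 2, colMeans(sb))
      cm <- sweep(sm, 2, colMeans(sm))
      -colSums(cb * cm) /
        (sqrt(colSums(cb^2)) * sqrt(colSums(cm^2)) + 1e-9)
    }
    list(
      # cost_full is side-effect free: line-search trials must not disturb
      # the cache that cost_sub's incremental updates rely on
      cost_full = function(dy, dx) mean(terms_at(seq_len(N), dy, dx)),
      cost_sub = function(idx, dys, dxs) {
        (sum(env$terms) - sum(env$terms[idx]) +
           sum(terms_at(idx, dys, dxs))) / N
      },
      commit = function(dy, dx) {
        env$terms <- terms_at(seq_len(N), dy, dx)
        invisible(NULL)
      })
  }
}

entropy_nats <- function(counts) {
  p <- counts[counts > 0]
  p <- p / sum(counts)
  -sum(p * log(p))
}

make_nmi_metric <- function(bins, patch_size, sampling = "bilinear") {
  psample <- if (sampling == "kernel") patch_at_kernel else patch_at_bilinear
  function(ref_l, flo_l, centers, f) {
    off <- patch_offsets(patch_size)
    n_off <- length(off$dy)
    vr <- as.vector(psample(ref_l$pixels, centers, patch_size))
    rng_r <- range(vr); rng_f <- range(flo_l$pixels)
    bin_of <- function(v, rng) {
      if (diff(rng) == 0) return(rep(1L, length(v)))
      pmin(pmax(floor((v - rng[1]) / diff(rng) * bins) + 1L, 1L), bins)
    }
    ia <- bin_of(vr, rng_r)                # fixed reference marginal
    sample_float_bins <- function(idx, dys, dxs) {
      yy <- outer(off$dy, centers[idx, 1] + dys, "+")
      xx <- outer(off$dx, centers[idx, 2] + dxs, "+")
      v <- if (sampling == "kernel")
        kernel_sample(flo_l$pixels, as.vector(yy), as.vector(xx))
      else bilinear_sample(flo_l$pixels, as.vector(yy), as.vector(xx), "edge")
      bin_of(v, rng_f)
    }
    sample_rows <- function(idx)
      as.vector(outer(seq_len(n_off), (idx - 1) * n_off, "+"))
    env <- new.env(parent = emptyenv())
    joint_counts <- function(ii, ib)
      tabulate((ib - 1L) * bins + ii, nbins = bins * bins)
    neg_nmi_from <- function(jc) {
      jm <- matrix(jc, bins, bins)
      ha <- entropy_nats(rowSums(jm)); hb <- entropy_nats(colSums(jm))
      hab <- entropy_nats(jc)
      if (hab == 0) return(-2)     # both marginals constant: perfect overlap
      -(ha + hb) / hab
    }
    list(
      # side-effect free; see the note in the co-sparse metric
      cost_full = function(dy, dx)
        neg_nmi_from(joint_counts(ia, sample_float_bins(
          seq_len(nrow(centers)), dy, dx))),
      cost_sub = function(idx, dys, dxs) {
        rows <- sample_rows(idx)
        ib_new <- sample_float_bins(idx, dys, dxs)
        jc <- env$jc
        dec <- tabulate((env$ib[rows] - 1L) * bins + ia[rows],
                        nbins = bins * bins)
        inc <- tabulate((ib_new - 1L) * bins + ia[rows], nbins = bins * bins)
        neg_nmi_from(jc - dec + inc)
      },
      commit = function(dy, dx) {
        ib <- sample_float_bins(seq_len(nrow(centers)), dy, dx)
        env$ib <- ib
        env$jc <- joint_counts(ia, ib)
        invisible(NULL)
      })
  }
}

#' Coupled co-sparsity registration cost
#'
#' Evaluates the registration data term at a given transform: the mean, over
#' sample centres, of the joint co-sparsity excess of reference patches at
#' the centres and float patches at the transform-mapped centres,
#' \deqn{-(1/N) \sum_i \sum_k \log(1 + \min(q_{ik}, r_{ik}))}
#' where \eqn{q_{ik} = \nu (\Omega_{ref} P_{ref}(x_i))_k^2} and
#' \eqn{r_{ik} = \nu (\Omega_{float} P_{float}(x_i + u(x_i)))_k^2}, with
#' patches zero-mean normalized as in training and sampled through the
#' fixed-width Gaussian kernel. Each term is non-positive and most negative
#' where the two modalities are co-activated on the same operator rows — a
#' shared co-support; it is zero when either side is structureless and flat
#' once the float response reaches the reference's, so the cost neither
#' rewards parking sample windows on flat image regions nor inflating float
#' responses beyond the reference's, and perfect alignment of a mono-modal
#' pair is exactly stationary. Centres whose transform-mapped window leaves
#' the image domain are dropped and N adjusted; the number kept is attached
#' as attribute \code{"n_used"}.
#'
#' @param reference reference \code{\link{image_grid}} (sampled at the
#'   centres).
#' @param float_img float \code{\link{image_grid}} (sampled at
#'   transform-mapped positions).
#' @param transform a \code{reg_transform} on the shared domain.
#' @param ops operator pair: \code{op_a} applies to the float image,
#'   \code{op_b} to the reference.
#' @param centers optional N x 2 matrix of 0-based centres; defaults to the
#'   grid of \code{cfg}.
#' @param cfg a \code{\link{registration_config}}.
#' @param nu log-square weight (must match the learning configuration).
#' @return Scalar cost.
#' @export
coupled_cost <- function(reference, float_img, transform, ops, centers = NULL,
                         cfg = registration_config(), nu = 1000) {
  if (is.null(centers)) centers <- level_centers(img_shape(reference), cfg)
  ps <- cfg$patch_size
  h <- (ps - 1) / 2
  sh <- img_shape(reference)
  O_s <- rbind(unclass(ops$op_a), unclass(ops$op_b))
  psample <- if (cfg$sampling == "kernel") patch_at_kernel else
    patch_at_bilinear
  B <- O_s %*% center_cols(psample(reference$pixels, centers, ps))
  d <- displacement_at(transform, centers[, 1], centers[, 2])
  cy <- centers[, 1] + d$dy; cx <- centers[, 2] + d$dx
  valid <- cy >= h & cy <= sh[1] - 1 - h & cx >= h & cx <= sh[2] - 1 - h
  if (!any(valid)) stop("all cost-sample centres left the domain")
  M <- O_s %*% center_cols(psample(float_img$pixels, cbind(cy, cx), ps))
  sb <- log1p(nu * B^2); sm <- log1p(nu * M^2)
  cb <- sweep(sb, 2, colMeans(sb)); cm <- sweep(sm, 2, colMeans(sm))
  terms <- -colSums(cb * cm) /
    (sqrt(colSums(cb^2)) * sqrt(colSums(cm^2)) + 1e-9)
  structure(mean(terms), n_used = sum(valid))
}

#' Register a float image to a reference with the JACSM cost
#'
#' Deformable registration by minimizing the coupled co-sparsity cost with a
#' fixed learned operator pair, over a cubic B-spline free-form deformation
#' optimized coarse-to-fine with finite-difference descent and backtracking
#' line search. In the brain-shift workflow the reference is the
#' pre-deformation MR image and the float is the deformed PA image.
#'
#' @param reference,float_img \code{\link{image_grid}}s of the same shape.
#' @param ops learned operator pair (\code{op_a} float-side, \code{op_b}
#'   reference-side), from \code{\link{learn_operators}}.
#' @param cfg a \code{\link{registration_config}}.
#' @param nu log-square weight used in the cost (match the learning value).
#' @return A \code{registration_result}: the recovered transform, the warped
#'   float image, the per-level cost traces (non-increasing by construction)
#'   and a convergence flag.
#' @export
register_jacsm <- function(reference, float_img, ops,
                           cfg = registration_config(), nu = 1000) {
  if (ncol(ops$op_a) != cfg$patch_size^2)
    stop("operator patch dimension ", ncol(ops$op_a),
         " does not match cfg patch_size^2 = ", cfg$patch_size^2)
  register_deformable(reference, float_img,
                      make_jacsm_metric(ops, nu, cfg$patch_size,
                                        cfg$sampling), cfg,
                      "JACSM")
}

#' Register a float image to a reference by normalized mutual information
#'
#' Baseline registrar sharing the full optimization scaffold of
#' \code{\link{register_jacsm}} (same pyramid, same sample centres, same FFD
#' and line search) but maximizing the normalized mutual information of the
#' sampled intensity pairs, so that a JACSM-vs-NMI comparison isolates the
#' similarity measure.
#'
#' @inheritParams register_jacsm
#' @return A \code{registration_result}.
#' @export
register_nmi <- function(reference, float_img, cfg = registration_config()) {
  register_deformable(reference, float_img,
                      make_nmi_metric(cfg$bins, cfg$patch_size,
                                      cfg$sampling), cfg, "NMI")
}

#' Normalized mutual information of two images
#'
#' \code{NMI = (H(A) + H(B)) / H(A, B)} from a joint histogram with
#' equal-width bins over each image's intensity range; natural-log entropies.
#' NMI lies in [1, 2], reaching 2 for identical images (up to binning) and 1
#' for independent ones. If both images are constant the overlap is perfect
#' by convention (2); if exactly one is constant the measure is degenerate
#' and \code{NA} is returned with a warning.
#'
#' @param a,b \code{\link{image_grid}}s of identical shape.
#' @param bins number of histogram bins per axis (>= 8).
#' @param mask optional logical matrix restricting the evaluation.
#' @return Scalar NMI.
#' @export
nmi_metric <- function(a, b, bins = 32L, mask = NULL) {
  stopifnot_image(a); stopifnot_image(b)
  if (!all(img_shape(a) == img_shape(b)))
    stop("images must have identical shape")
  if (bins < 8) stop("bins must be >= 8")
  va <- as.vector(a$pixels); vb <- as.vector(b$pixels)
  if (!is.null(mask)) { va <- va[mask]; vb <- vb[mask] }
  ca <- diff(range(va)) == 0; cb <- diff(range(vb)) == 0
  if (ca && cb) return(2)
  if (ca || cb) {
    warning("one image is constant: NMI is degenerate")
    return(NA_real_)
  }
  bin_of <- function(v) {
    rng <- range(v)
    pmin(pmax(floor((v - rng[1]) / diff(rng) * bins) + 1L, 1L), bins)
  }
  jc <- tabulate((bin_of(vb) - 1L) * bins + bin_of(va), nbins = bins * bins)
  jm <- matrix(jc, bins, bins)
  (entropy_nats(rowSums(jm)) + entropy_nats(colSums(jm))) / entropy_nats(jc)
}
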