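patch_offsets <- function(patch_size) {
  h <- (patch_size - 1L) %/% 2L
  # row-major vectorization: row offset varies slowest, column fastest
  list(dy = rep(-h:h, each = patch_size), dx = rep(-h:h, times = patch_size),
       half = h)
}

#' Extract co-located patch pairs from two aligned images
#'
#' Samples \code{count} patch centres uniformly at random from all positions
#' at least \code{floor(patch_size/2)} pixels from the border, and returns the
#' vectorized patches of both images at the same centres as the columns of two
#' n x N matrices (n = patch_size^2, row-major vectorization). These ensembles
#' are the training signals for analysis-operator learning.
#'
#' Sampling is without replacement whenever \code{count} does not exceed the
#' number of valid centres, and with replacement (with a warning) otherwise.
#'
#' @param img_a,img_b \code{\link{image_grid}}s of identical shape.
#' @param patch_size odd patch edge length in pixels (default 7).
#' @param count number of patch pairs.
#' @param seed integer RNG seed.
#' @param normalization \code{"zero_mean"} (default) subtracts each patch's
#'   own mean, so operators respond to structure rather than brightness;
#'   \code{"none"} keeps raw intensities.
#' @return A list of class \code{patch_ensemble_pair} with elements
#'   \code{X_a}, \code{X_b} (n x N matrices), \code{centers} (N x 2 matrix of
#'   0-based (y, x) pixel coordinates), \code{patch_size},
#'   \code{normalization}.
#' @export
extract_patch_pairs <- function(img_a, img_b, patch_size = 7L, count = 2000L,
                                seed = 1L,
                                normalization = c("zero_mean", "none")) {
  stopifnot_image(img_a); stopifnot_image(img_b)
  normalization <- match.arg(normalization)
  if (!all(img_shape(img_a) == img_shape(img_b)))
    stop("images must have identical shape; got ",
         paste(img_shape(img_a), collapse = "x"), " vs ",
         paste(img_shape(img_b), collapse = "x"))
  patch_size <- as.integer(patch_size)
  if (patch_size %% 2L == 0L)
    stop("patch_size must be odd (even sizes have no centre pixel)")
  if (count < 1) stop("count must be >= 1")
  sh <- img_shape(img_a)
  h <- (patch_size - 1L) %/% 2L
  vy <- (h):(sh[1] - 1L - h); vx <- (h):(sh[2] - 1L - h)
  if (length(vy) < 1 || length(vx) < 1)
    stop("patch_size too large for image")
  n_valid <- length(vy) * length(vx)
  set.seed(seed)
  if (count <= n_valid) {
    lin <- sample.int(n_valid, count)
  } else {
    warning("count exceeds number of valid centres (", n_valid,
            "); sampling with replacement")
    lin <- sample.int(n_valid, count, replace = TRUE)
  }
  cy <- vy[(lin - 1L) %% length(vy) + 1L]
  cx <- vx[(lin - 1L) %/% length(vy) + 1L]
  centers <- cbind(y = cy, x = cx)
  gather <- function(pixels) {
    off <- patch_offsets(patch_size)
    ny <- nrow(pixels)
    X <- matrix(0, patch_size^2, count)
    for (j in seq_along(off$dy))
      X[j, ] <- pixels[(cx + off$dx[j]) * ny + (cy + off$dy[j]) + 1L]
    X
  }
  X_a <- gather(img_a$pixels); X_b <- gather(img_b$pixels)
  if (normalization == "zero_mean") {
    X_a <- sweep(X_a, 2, colMeans(X_a))
    X_b <- sweep(X_b, 2, colMeans(X_b))
  }
  structure(list(X_a = X_a, X_b = X_b, centers = centers,
                 patch_size = patch_size, normalization = normalization),
            class = "patch_ensemble_pair")
}

#' @export
print.patch_ensemble_pair <- function(x, ...) {
  cat(sprintf("<patch_ensemble_pair> %d x %d (patch %d x %d, %s)\n",
              nrow(x$X_a), ncol(x$X_a), x$patch_size, x$patch_size,
              x$normalization))
  invisible(x)
}

#' Vectorize the patch around an integer pixel centre
#'
#' @param image an \code{\link{image_grid}}.
#' @param center 0-based (y, x) integer pixel coordinates.
#' @param patch_size odd patch edge length.
#' @return A numeric vector of length patch_size^2 (row-major order).
#' @export
vectorize_patch <- function(image, center, patch_size = 7L) {
  stopifnot_image(image)
  sh <- img_shape(image)
  h <- (patch_size - 1L) %/% 2L
  cy <- center[1]; cx <- center[2]
  if (cy < h || cy > sh[1] - 1 - h || cx < h || cx > sh[2] - 1 - h)
    stop("patch centre (", cy, ", ", cx, ") too close to the border")
  off <- patch_offsets(patch_size)
  image$pixels[(cx + off$dx) * sh[1] + (cy + off$dy) + 1]
}

#' Sample patches at (possibly off-grid) centres by bilinear interpolation
#'
#' The window is translated rigidly to the given centre and every pixel of the
#' window is sampled bilinearly; this is the patch sampler used by the
#' registration cost, which evaluates reference-image patches at
#' transform-mapped coordinates.
#'
#' @param image an \code{\link{image_grid}}.
#' @param centers N x 2 matrix of 0-based (y, x) coordinates, possibly
#'   fractional.
#' @param patch_size odd patch edge length.
#' @param boundary passed to the bilinear sampler (\code{"edge"} or
#'   \code{"zero"}).
#' @return An n x N matrix of vectorized patches (row-major order).
#' @export
patch_at <- function(image, centers, patch_size = 7L, boundary = "edge") {
  stopifnot_image(image)
  centers <- matrix(centers, ncol = 2)
  off <- patch_offsets(patch_size)
  n <- patch_size^2; N <- nrow(centers)
  yy <- outer(off$dy, centers[, 1], "+")
  xx <- outer(off$dx, centers[, 2], "+")
  matrix(bilinear_sample(image$pixels, as.vector(yy), as.vector(xx),
                         boundary), n, N)
}

# patch sampler on the fixed-width Gaussian kernel (see kernel_sample); used
# by the registration metrics so that on- and off-grid patches carry the same
# effective smoothing
patch_at_kernel <- function(pixels, centers, patch_size, sigma = 0.85) {
  off <- patch_offsets(patch_size)
  centers <- matrix(centers, ncol = 2)
  yy <- outer(off$dy, centers[, 1], "+")
  xx <- outer(off$dx, centers[, 2], "+")
  matrix(kernel_sample(pixels, as.vector(yy), as.vector(xx), sigma),
         patch_size^2, nrow(centers))
}

# fast bilinear patch sampler on a raw pixel matrix
patch_at_bilinear <- function(pixels, centers, patch_size) {
  off <- patch_offsets(patch_size)
  centers <- matrix(centers, ncol = 2)
  yy <- outer(off$dy, centers[, 1], "+")
  xx <- outer(off$dx, centers[, 2], "+")
  matrix(bilinear_sample(pixels, as.vector(yy), as.vector(xx), "edge"),
         patch_size^2, nrow(centers))
}
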