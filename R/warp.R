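# Interpolated sampling of a matrix at fractional 0-based (y, x) coordinates.
# boundary = "edge" clamps coordinates to the domain; "zero" returns 0 outside.
bilinear_sample <- function(pixels, y, x, boundary = c("edge", "zero")) {
  boundary <- match.arg(boundary)
  ny <- nrow(pixels); nx <- ncol(pixels)
  if (boundary == "zero") {
    inside <- y >= 0 & y <= ny - 1 & x >= 0 & x <= nx - 1
  }
  y <- pmin(pmax(y, 0), ny - 1)
  x <- pmin(pmax(x, 0), nx - 1)
  y0 <- floor(y); x0 <- floor(x)
  y0 <- pmin(y0, ny - 2); x0 <- pmin(x0, nx - 2)
  y0[ny == 1] <- 0; x0[nx == 1] <- 0   # degenerate single row/col
  fy <- y - y0; fx <- x - x0
  i00 <- x0 * ny + y0 + 1
  v <- (1 - fy) * (1 - fx) * pixels[i00] +
    fy * (1 - fx) * pixels[i00 + 1] +
    (1 - fy) * fx * pixels[i00 + ny] +
    fy * fx * pixels[i00 + ny + 1]
  if (boundary == "zero") v[!inside] <- 0
  v
}

# Fixed-width Gaussian interpolation: value(p) = sum_q G(p - q) I(q) over the
# (2 radius + 1)^2 integer neighbourhood, weights renormalized. Unlike
# bilinear interpolation, the effective smoothing is (nearly) independent of
# the fractional part of the coordinate, so a registration metric built on
# this sampler is not biased toward off-grid displacements by
# interpolation-induced noise smoothing.
kernel_sample <- function(pixels, y, x, sigma = 0.85, radius = 2L) {
  ny <- nrow(pixels); nx <- ncol(pixels)
  y <- pmin(pmax(y, 0), ny - 1)
  x <- pmin(pmax(x, 0), nx - 1)
  y0 <- round(y); x0 <- round(x)
  acc <- numeric(length(y)); wsum <- numeric(length(y))
  for (di in -radius:radius) {
    yi <- y0 + di
    wy2 <- (y - yi)^2
    yi <- pmin(pmax(yi, 0), ny - 1)
    for (dj in -radius:radius) {
      xj <- x0 + dj
      w <- exp(-(wy2 + (x - xj)^2) / (2 * sigma^2))
      xj <- pmin(pmax(xj, 0), nx - 1)
      acc <- acc + w * pixels[xj * ny + yi + 1]
      wsum <- wsum + w
    }
  }
  acc / wsum
}

nearest_sample <- function(pixels, y, x, boundary = c("edge", "zero")) {
  boundary <- match.arg(boundary)
  ny <- nrow(pixels); nx <- ncol(pixels)
  if (boundary == "zero") {
    inside <- y >= -0.5 & y < ny - 0.5 & x >= -0.5 & x < nx - 0.5
  }
  yi <- pmin(pmax(round(y), 0), ny - 1)
  xi <- pmin(pmax(round(x), 0), nx - 1)
  v <- pixels[xi * ny + yi + 1]
  if (boundary == "zero") v[!inside] <- 0
  v
}

#' Warp an image by a transform (backward mapping)
#'
#' Resamples the input image at transform-mapped coordinates: the output at
#' pixel \code{(y, x)} is the input sampled at \code{(y + dy, x + dx)}, where
#' \code{(dy, dx)} is the transform's displacement at \code{(y, x)}. This is
#' the package-wide backward-warping convention; the displacement therefore
#' maps output (reference-frame) coordinates into the input (float) image.
#'
#' @param image an \code{\link{image_grid}}.
#' @param transform a \code{reg_transform} whose domain matches the image
#'   shape.
#' @param interpolation \code{"bilinear"} (default) or \code{"nearest"}.
#' @param boundary out-of-domain handling: \code{"edge"} clamps to the nearest
#'   edge pixel (default, avoids artificial gradients during registration);
#'   \code{"zero"} pads with zeros.
#' @return An \code{image_grid} with the same shape, spacing and modality.
#' @examples
#' img <- image_grid(matrix(runif(64), 8, 8))
#' out <- warp_image(img, transform_identity(c(8, 8)))
#' all.equal(out$pixels, img$pixels)
#' @export
warp_image <- function(image, transform,
                       interpolation = c("bilinear", "nearest"),
                       boundary = c("edge", "zero")) {
  stopifnot_image(image)
  interpolation <- match.arg(interpolation)
  boundary <- match.arg(boundary)
  sh <- img_shape(image)
  if (!all(transform$domain_shape == sh))
    stop("transform domain ", paste(transform$domain_shape, collapse = " x "),
         " does not match image shape ", paste(sh, collapse = " x "))
  if (transform$kind == "identity" ||
      (transform$kind == "dense" && all(transform$field$dy == 0) &&
       all(transform$field$dx == 0)))
    return(image)
  field <- as_deformation_field(transform, image$spacing)
  if (any(!is.finite(field$dy)) || any(!is.finite(field$dx)))
    stop("displacement field contains non-finite values")
  yy <- rep(0:(sh[1] - 1), times = sh[2]) + as.vector(field$dy)
  xx <- rep(0:(sh[2] - 1), each = sh[1]) + as.vector(field$dx)
  v <- if (interpolation == "bilinear")
    bilinear_sample(image$pixels, yy, xx, boundary)
  else nearest_sample(image$pixels, yy, xx, boundary)
  image_grid(matrix(v, sh[1], sh[2]), image$spacing, image$modality,
             image$origin)
}

#' Apply a transform to landmark points
#'
#' Moves each landmark by the displacement interpolated at its location,
#' consistently with the backward-warping convention of
#' \code{\link{warp_image}}: a point at reference-frame position p maps to
#' float-frame position \code{p + u(p)}. Points outside the image domain are
#' excluded with a warning and recorded in the \code{"dropped"} attribute.
#'
#' @param landmarks a \code{\link{landmark_set}} (positions in mm).
#' @param transform a \code{reg_transform} on the image's pixel domain.
#' @param image the \code{\link{image_grid}} defining the mm-to-pixel mapping.
#' @return A \code{landmark_set} with transformed positions (mm); attribute
#'   \code{"convention"} documents the mapping direction.
#' @export
transform_points <- function(landmarks, transform, image) {
  stopifnot_image(image)
  px <- landmarks_to_px(landmarks, image)
  sh <- img_shape(image)
  inside <- px[, 1] >= 0 & px[, 1] <= sh[1] - 1 &
    px[, 2] >= 0 & px[, 2] <= sh[2] - 1
  if (!any(inside)) stop("all landmarks fall outside the image domain")
  if (!all(inside))
    warning("excluding landmarks outside image domain: ",
            paste(landmarks$labels[!inside], collapse = ", "))
  px_in <- px[inside, , drop = FALSE]
  d <- displacement_at(transform, px_in[, 1], px_in[, 2])
  moved_px <- cbind(px_in[, 1] + d$dy, px_in[, 2] + d$dx)
  out <- landmark_set(px_to_mm(moved_px, image),
                      labels = landmarks$labels[inside])
  attr(out, "dropped") <- landmarks$labels[!inside]
  attr(out, "convention") <- "reference-to-float (p + u(p)), backward warping"
  out
}
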