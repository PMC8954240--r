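MODALITIES <- c("MR", "PA", "US", "OTHER")

#' 2D image on a regular grid with physical pixel spacing
#'
#' The basic image container used throughout the package: a 2D matrix of
#' intensities together with the pixel spacing in millimetres, a modality tag
#' and a physical origin. The coordinate convention is fixed package-wide:
#' 0-based pixel indices, \code{(row = y, col = x)} ordering, pixel centres at
#' integer coordinates, and physical position \code{mm = index * spacing +
#' origin}.
#'
#' @param pixels numeric matrix of intensities (rows = y, columns = x).
#' @param spacing length-2 numeric, \code{(dy, dx)} in mm per pixel; strictly
#'   positive.
#' @param modality one of \code{"MR"}, \code{"PA"}, \code{"US"}, \code{"OTHER"}.
#' @param origin length-2 numeric, physical position of pixel (0, 0) in mm.
#' @return An object of class \code{image_grid}.
#' @examples
#' img <- image_grid(matrix(0, 8, 8), spacing = c(0.6, 0.6), modality = "MR")
#' dim(img$pixels)
#' @export
image_grid <- function(pixels, spacing = c(1, 1), modality = "OTHER",
                       origin = c(0, 0)) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("'pixels' must be a numeric matrix (2D image); got dimensions: ",
         paste(dim(pixels), collapse = " x "))
  if (any(!is.finite(pixels)))
    stop("'pixels' must be finite (no NA/NaN/Inf)")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 2 || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must be two strictly positive finite numbers (dy, dx) in mm")
  modality <- match.arg(modality, MODALITIES)
  origin <- as.numeric(origin)
  if (length(origin) != 2 || any(!is.finite(origin)))
    stop("'origin' must be two finite numbers (y0, x0) in mm")
  structure(list(pixels = pixels, spacing = spacing, modality = modality,
                 origin = origin),
            class = "image_grid")
}

#' @export
print.image_grid <- function(x, ...) {
  cat(sprintf("<image_grid> %d x %d px, spacing (%.4g, %.4g) mm, modality %s\n",
              nrow(x$pixels), ncol(x$pixels), x$spacing[1], x$spacing[2],
              x$modality))
  cat(sprintf("  intensity range [%.4g, %.4g], origin (%.4g, %.4g) mm\n",
              min(x$pixels), max(x$pixels), x$origin[1], x$origin[2]))
  invisible(x)
}

img_shape <- function(image) dim(image$pixels)

stopifnot_image <- function(image) {
  if (!inherits(image, "image_grid")) stop("expected an 'image_grid' object")
  invisible(image)
}

#' Dense displacement field
#'
#' Per-pixel displacement in pixels, stored as two matrices (dy, dx) matching
#' the spatial shape of the grid it deforms. Displacements follow the backward
#' warping convention: the warped image samples the source at
#' \code{(y + dy, x + dx)}.
#'
#' @param dy,dx numeric matrices of identical shape; displacement components in
#'   pixels.
#' @param spacing length-2 numeric, mm per pixel of the target grid.
#' @return An object of class \code{deformation_field}.
#' @export
deformation_field <- function(dy, dx, spacing = c(1, 1)) {
  if (!is.matrix(dy) || !is.matrix(dx) || !all(dim(dy) == dim(dx)))
    stop("'dy' and 'dx' must be matrices of identical shape")
  if (any(!is.finite(dy)) || any(!is.finite(dx)))
    stop("displacement field must be finite everywhere")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 2 || any(spacing <= 0))
    stop("'spacing' must be two positive numbers (dy, dx) in mm")
  structure(list(dy = dy, dx = dx, spacing = spacing),
            class = "deformation_field")
}

#' @export
print.deformation_field <- function(x, ...) {
  mag <- sqrt(x$dy^2 + x$dx^2)
  cat(sprintf("<deformation_field> %d x %d px, |u| max %.4g px, mean %.4g px\n",
              nrow(x$dy), ncol(x$dy), max(mag), mean(mag)))
  invisible(x)
}

field_magnitude <- function(field) sqrt(field$dy^2 + field$dx^2)

#' Landmark set in physical coordinates
#'
#' Named points in millimetres, used as registration targets for the target
#' registration error. Labels must be unique. When an image is supplied the
#' points are checked against its physical bounds.
#'
#' @param points numeric matrix with two columns \code{(y_mm, x_mm)}.
#' @param labels character vector of unique labels, one per point.
#' @param image optional \code{image_grid}; points are validated to lie within
#'   its physical extent.
#' @return An object of class \code{landmark_set}.
#' @export
landmark_set <- function(points, labels = NULL, image = NULL) {
  points <- as.matrix(points)
  if (ncol(points) != 2 || !is.numeric(points) || any(!is.finite(points)))
    stop("'points' must be a finite numeric matrix with columns (y_mm, x_mm)")
  if (is.null(labels)) labels <- paste0("T", seq_len(nrow(points)))
  labels <- as.character(labels)
  if (length(labels) != nrow(points)) stop("one label per point required")
  if (anyDuplicated(labels)) stop("landmark labels must be unique")
  colnames(points) <- c("y_mm", "x_mm")
  rownames(points) <- labels
  if (!is.null(image)) {
    stopifnot_image(image)
    lo <- image$origin
    hi <- image$origin + (img_shape(image) - 1) * image$spacing
    out <- points[, 1] < lo[1] | points[, 1] > hi[1] |
      points[, 2] < lo[2] | points[, 2] > hi[2]
    if (any(out))
      stop("landmarks outside image physical bounds: ",
           paste(labels[out], collapse = ", "))
  }
  structure(list(points = points, labels = labels), class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("<landmark_set> %d points (mm):\n", nrow(x$points)))
  print(round(x$points, 3))
  invisible(x)
}

landmarks_to_px <- function(landmarks, image) {
  sweep(sweep(landmarks$points, 2, image$origin, "-"), 2, image$spacing, "/")
}

px_to_mm <- function(px, image) {
  sweep(sweep(px, 2, image$spacing, "*"), 2, image$origin, "+")
}
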