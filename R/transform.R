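#' Spatial transforms
#'
#' A transform maps output-grid pixel coordinates to input-grid coordinates
#' (backward warping). Three parameterizations are supported: the identity, a
#' dense displacement field, and a cubic B-spline free-form deformation (FFD)
#' with control points on a regular grid. All transforms can be converted to a
#' dense \code{\link{deformation_field}} on their domain.
#'
#' @param domain_shape integer length-2, (ny, nx) of the pixel domain.
#' @return An object of class \code{reg_transform}.
#' @rdname reg_transform
#' @export
transform_identity <- function(domain_shape) {
  domain_shape <- as.integer(domain_shape)
  structure(list(kind = "identity", domain_shape = domain_shape),
            class = "reg_transform")
}

#' @param field a \code{\link{deformation_field}}.
#' @rdname reg_transform
#' @export
transform_dense <- function(field) {
  if (!inherits(field, "deformation_field"))
    stop("'field' must be a deformation_field")
  structure(list(kind = "dense", field = field,
                 domain_shape = dim(field$dy)),
            class = "reg_transform")
}

#' @param control_y,control_x matrices of control-point displacements (pixels,
#'   full-resolution units) on the FFD knot grid; see
#'   \code{\link{ffd_grid_dim}} for the required shape.
#' @param grid_spacing_px knot spacing in pixels.
#' @rdname reg_transform
#' @export
transform_bspline <- function(control_y, control_x, grid_spacing_px,
                              domain_shape) {
  domain_shape <- as.integer(domain_shape)
  gdim <- ffd_grid_dim(domain_shape, grid_spacing_px)
  if (!all(dim(control_y) == gdim) || !all(dim(control_x) == gdim))
    stop("control grids must have shape ", paste(gdim, collapse = " x "),
         " for domain ", paste(domain_shape, collapse = " x "),
         " and spacing ", grid_spacing_px)
  structure(list(kind = "bspline", control_y = control_y,
                 control_x = control_x, grid_spacing_px = grid_spacing_px,
                 domain_shape = domain_shape),
            class = "reg_transform")
}

#' @export
print.reg_transform <- function(x, ...) {
  cat(sprintf("<reg_transform> kind=%s, domain %s\n", x$kind,
              paste(x$domain_shape, collapse = " x ")))
  invisible(x)
}

#' FFD control grid dimensions for a pixel domain
#'
#' Cubic B-spline support requires one knot row/column before the domain and
#' two beyond it; for a domain of n pixels with knot spacing d the grid has
#' \code{floor((n - 1) / d) + 4} knots per axis.
#'
#' @param domain_shape integer (ny, nx).
#' @param grid_spacing_px knot spacing in pixels.
#' @return integer length-2 control grid shape.
#' @export
ffd_grid_dim <- function(domain_shape, grid_spacing_px) {
  as.integer(floor((domain_shape - 1) / grid_spacing_px) + 4)
}

# cubic B-spline basis weights at fractional position u in [0,1)
bspline_basis <- function(u) {
  u2 <- u * u; u3 <- u2 * u
  cbind((1 - u)^3 / 6,
        (3 * u3 - 6 * u2 + 4) / 6,
        (-3 * u3 + 3 * u2 + 3 * u + 1) / 6,
        u3 / 6)
}

# knot cell index (0-based) and basis weights for 0-based pixel coords
bspline_cells <- function(coord, grid_spacing_px) {
  t <- coord / grid_spacing_px
  i <- floor(t)
  list(i = i, w = bspline_basis(t - i))
}

# Evaluate FFD displacement at arbitrary 0-based (y, x) coordinate vectors.
# Control array index for knot j (j from -1) is j + 2 in 1-based R.
ffd_displacement_at <- function(transform, y, x) {
  cy <- bspline_cells(y, transform$grid_spacing_px)
  cx <- bspline_cells(x, transform$grid_spacing_px)
  gdim <- dim(transform$control_y)
  dy <- numeric(length(y)); dx <- numeric(length(y))
  for (l in 0:3) {
    iy <- pmin(pmax(cy$i + l + 1, 1), gdim[1])
    wy <- cy$w[, l + 1]
    for (m in 0:3) {
      ix <- pmin(pmax(cx$i + m + 1, 1), gdim[2])
      w <- wy * cx$w[, m + 1]
      idx <- cbind(iy, ix)
      dy <- dy + w * transform$control_y[idx]
      dx <- dx + w * transform$control_x[idx]
    }
  }
  list(dy = dy, dx = dx)
}

#' Convert a transform to a dense displacement field
#'
#' @param transform a \code{reg_transform}.
#' @param spacing mm per pixel recorded on the output field.
#' @return A \code{\link{deformation_field}} on the transform's domain; the
#'   identity converts to an all-zero field.
#' @export
as_deformation_field <- function(transform, spacing = c(1, 1)) {
  if (!inherits(transform, "reg_transform"))
    stop("'transform' must be a reg_transform")
  sh <- transform$domain_shape
  switch(transform$kind,
    identity = deformation_field(matrix(0, sh[1], sh[2]),
                                 matrix(0, sh[1], sh[2]), spacing),
    dense = transform$field,
    bspline = {
      yy <- rep(0:(sh[1] - 1), times = sh[2])
      xx <- rep(0:(sh[2] - 1), each = sh[1])
      d <- ffd_displacement_at(transform, yy, xx)
      deformation_field(matrix(d$dy, sh[1], sh[2]),
                        matrix(d$dx, sh[1], sh[2]), spacing)
    },
    stop("unknown transform kind: ", transform$kind))
}

# displacement (in pixels) interpolated at arbitrary 0-based coordinates
displacement_at <- function(transform, y, x) {
  switch(transform$kind,
    identity = list(dy = numeric(length(y)), dx = numeric(length(y))),
    bspline = ffd_displacement_at(transform, y, x),
    dense = list(
      dy = bilinear_sample(transform$field$dy, y, x, boundary = "edge"),
      dx = bilinear_sample(transform$field$dx, y, x, boundary = "edge")),
    stop("unknown transform kind: ", transform$kind))
}

#' Approximate inverse of a displacement field
#'
#' Fixed-point inversion: finds u such that \code{u(p) = -d(p + u(p))}, so that
#' backward-warping by u undoes backward-warping by d up to the smoothness of
#' the field. Converges when the field's Jacobian perturbation is a
#' contraction, which holds for the smooth simulated brain-shift fields used
#' here.
#'
#' @param field a \code{\link{deformation_field}} (d).
#' @param iterations maximum fixed-point sweeps.
#' @param tol stop when the maximum update falls below this (pixels).
#' @return A \code{deformation_field} holding the approximate inverse.
#' @export
invert_field <- function(field, iterations = 50, tol = 1e-6) {
  sh <- dim(field$dy)
  yy <- rep(0:(sh[1] - 1), times = sh[2])
  xx <- rep(0:(sh[2] - 1), each = sh[1])
  uy <- numeric(length(yy)); ux <- numeric(length(yy))
  for (it in seq_len(iterations)) {
    sy <- bilinear_sample(field$dy, yy + uy, xx + ux, boundary = "edge")
    sx <- bilinear_sample(field$dx, yy + uy, xx + ux, boundary = "edge")
    step <- max(abs(-sy - uy), abs(-sx - ux))
    uy <- -sy; ux <- -sx
    if (step < tol) break
  }
  deformation_field(matrix(uy, sh[1], sh[2]), matrix(ux, sh[1], sh[2]),
                    field$spacing)
}
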