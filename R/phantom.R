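# Separable Gaussian smoothing via banded convolution matrices; kernel is
# truncated at 3 sigma and renormalized per row, so edges keep unit gain.
gaussian_smooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  smat <- function(n) {
    r <- max(1L, ceiling(3 * sigma))
    d <- outer(seq_len(n), seq_len(n), "-")
    k <- exp(-d^2 / (2 * sigma^2))
    k[abs(d) > r] <- 0
    k / rowSums(k)
  }
  smat(nrow(m)) %*% m %*% t(smat(ncol(m)))
}

#' Specification of the brain-mimicking phantom
#'
#' Describes a tissue slab with a curved (head-like) top surface and embedded
#' tubular vessels, rendered in three modality-specific contrast models. The
#' default geometry is a 150 x 40 mm body with two vessels of 1.2 and 1.4 mm
#' inside diameter. Contrast models are simple analytic renderings: MR is
#' tissue-dominant with mild vessel contrast, PA is vessel-dominant with
#' multiplicative optical depth attenuation exp(-rate * depth_mm), and US is
#' tissue speckle with weak vessel contrast.
#'
#' @param body_width_mm,body_height_mm body dimensions in mm.
#' @param vessel_diameters_mm inside diameters of the simulated vessels (mm);
#'   recycled to \code{vessel_count}.
#' @param vessel_count number of vessels.
#' @param curved_top if \code{TRUE} the top surface is a half-elliptic dome.
#' @param noise_sigma named additive/multiplicative noise levels per modality
#'   (\code{mr}, \code{pa} additive Gaussian on [0,1]-scaled intensities;
#'   \code{us} multiplicative speckle strength).
#' @param pa_attenuation_per_mm effective optical attenuation rate for the PA
#'   rendering (1/mm).
#' @param seed integer RNG seed; the same spec reproduces bit-identical output.
#' @return A list of class \code{phantom_spec}.
#' @export
phantom_spec <- function(body_width_mm = 150, body_height_mm = 40,
                         vessel_diameters_mm = c(1.2, 1.4), vessel_count = 2,
                         curved_top = TRUE,
                         noise_sigma = c(mr = 0.02, pa = 0.02, us = 0.4),
                         pa_attenuation_per_mm = 0.1, seed = 1L) {
  if (any(vessel_diameters_mm <= 0)) stop("vessel diameters must be positive")
  if (body_width_mm <= 0 || body_height_mm <= 0)
    stop("body dimensions must be positive")
  if (pa_attenuation_per_mm < 0) stop("attenuation rate must be >= 0")
  ns <- c(mr = 0.02, pa = 0.02, us = 0.4)
  noise_sigma <- unlist(noise_sigma)
  ns[names(noise_sigma)] <- noise_sigma
  structure(list(body_width_mm = body_width_mm,
                 body_height_mm = body_height_mm,
                 vessel_diameters_mm = rep_len(vessel_diameters_mm,
                                               vessel_count),
                 vessel_count = as.integer(vessel_count),
                 curved_top = isTRUE(curved_top), noise_sigma = ns,
                 pa_attenuation_per_mm = pa_attenuation_per_mm,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate a paired MR / PA / US phantom with ground truth
#'
#' Builds the body geometry, places vessels as gently curved near-horizontal
#' tubes inside the body, renders the three modalities, and places landmarks
#' on vessel centrelines. All randomness is governed by \code{spec$seed}.
#'
#' The PA rendering multiplies both tissue and vessel response by
#' exp(-rate * depth_mm), depth measured from the top surface, so vessel
#' pixels are strictly brighter than tissue at any depth before noise.
#'
#' @param spec a \code{\link{phantom_spec}}.
#' @param shape_px canvas size (ny, nx) in pixels.
#' @param spacing_mm pixel spacing (dy, dx) in mm.
#' @param n_landmarks number of vessel-centreline landmarks (>= 3).
#' @return A list with elements \code{mr}, \code{pa}, \code{us}
#'   (\code{\link{image_grid}}s), \code{landmarks}
#'   (\code{\link{landmark_set}}), \code{vessel_mask} (logical matrix) and
#'   \code{spec}.
#' @export
generate_phantom <- function(spec, shape_px = c(256, 256),
                             spacing_mm = c(0.6, 0.6), n_landmarks = 5L) {
  stopifnot(inherits(spec, "phantom_spec"))
  ny <- shape_px[1]; nx <- shape_px[2]
  dy <- spacing_mm[1]; dx <- spacing_mm[2]
  w_px <- spec$body_width_mm / dx
  h_px <- spec$body_height_mm / dy
  if (w_px > nx - 4 || h_px > ny - 4)
    stop("canvas too small: body needs ", ceiling(w_px), " x ",
         ceiling(h_px), " px plus margins")
  set.seed(spec$seed)
  cx <- (nx - 1) / 2
  base_row <- (ny - 1) / 2 + h_px / 2          # body vertically centred
  xs <- 0:(nx - 1)
  rel <- (xs - cx) / (w_px / 2)
  prof <- ifelse(abs(rel) <= 1,
                 if (spec$curved_top) sqrt(pmax(0, 1 - rel^2)) else 1, 0)
  top_row <- base_row - h_px * prof            # top surface per column
  rows <- matrix(0:(ny - 1), ny, nx)
  toprow_m <- matrix(top_row, ny, nx, byrow = TRUE)
  body <- sweep(rows, 2, top_row, ">=") & rows <= base_row &
    matrix(prof > 0, ny, nx, byrow = TRUE)
  depth_mm <- matrix(pmax(0, rows - toprow_m) * dy, ny, nx)

  # vessels: near-horizontal sinusoidal centrelines at a random depth fraction
  vessel_mask <- matrix(FALSE, ny, nx)
  centrelines <- vector("list", spec$vessel_count)
  for (v in seq_len(spec$vessel_count)) {
    r_mm <- spec$vessel_diameters_mm[v] / 2
    placed <- FALSE
    for (try in 1:50) {
      frac <- stats::runif(1, 0.25, 0.7)
      amp <- stats::runif(1, 2, 5)
      wav <- stats::runif(1, 80, 160)
      phase <- stats::runif(1, 0, 2 * pi)
      cl <- base_row - frac * h_px * prof + amp * sin(2 * pi * xs / wav + phase)
      margin <- r_mm / dy + 2
      ok <- prof > 0 & cl > top_row + margin & cl < base_row - margin
      if (sum(ok) > 0.5 * sum(prof > 0)) { placed <- TRUE; break }
    }
    if (!placed) stop("could not place vessel ", v, " inside the body")
    cl[!ok] <- NA
    centrelines[[v]] <- cl
    dist_v <- abs(rows - matrix(cl, ny, nx, byrow = TRUE)) * dy
    vm <- !is.na(dist_v) & dist_v <= r_mm
    vessel_mask <- vessel_mask | vm
  }

  # landmarks on vessel centrelines, spread along the valid extent
  lm_px <- NULL
  n_lm <- max(3L, as.integer(n_landmarks))
  per <- ceiling(n_lm / spec$vessel_count)
  for (v in seq_len(spec$vessel_count)) {
    valid_x <- which(!is.na(centrelines[[v]]))
    picks <- valid_x[round(seq(0.2, 0.8, length.out = per) * length(valid_x))]
    lm_px <- rbind(lm_px, cbind(round(centrelines[[v]][picks]), picks - 1))
  }
  lm_px <- lm_px[seq_len(n_lm), , drop = FALSE]

  tissue_tex <- gaussian_smooth(matrix(stats::rnorm(ny * nx), ny, nx), 12)
  tissue_tex <- tissue_tex / stats::sd(tissue_tex)
  psf <- function(m) gaussian_smooth(m, 0.8)

  # homogeneous gel body with contrast-filled tubes: vessels enhance strongly
  mr_clean <- matrix(0.02, ny, nx)
  mr_clean[body] <- 0.6 + 0.05 * tissue_tex[body]
  mr_clean[vessel_mask] <- 1
  mr <- psf(mr_clean) + spec$noise_sigma["mr"] * matrix(stats::rnorm(ny * nx),
                                                        ny, nx)

  att <- exp(-spec$pa_attenuation_per_mm * depth_mm)
  pa_clean <- matrix(0, ny, nx)
  pa_clean[body] <- 0.05
  pa_clean[vessel_mask] <- 1
  pa_clean <- pa_clean * att
  pa <- psf(pa_clean) + spec$noise_sigma["pa"] * matrix(stats::rnorm(ny * nx),
                                                        ny, nx)

  us_clean <- matrix(0.02, ny, nx)
  us_clean[body] <- 0.5 + 0.04 * tissue_tex[body]
  us_clean[vessel_mask] <- 0.62
  k_sp <- 1 / max(spec$noise_sigma["us"], 1e-6)^2
  speckle <- matrix(stats::rgamma(ny * nx, shape = k_sp, rate = k_sp), ny, nx)
  us <- psf(us_clean * speckle)

  mk <- function(p, mod) image_grid(p, spacing_mm, mod)
  img_mr <- mk(mr, "MR")
  landmarks <- landmark_set(px_to_mm(lm_px, img_mr), image = img_mr)
  list(mr = img_mr, pa = mk(pa, "PA"), us = mk(us, "US"),
       landmarks = landmarks, vessel_mask = vessel_mask,
       pa_clean = mk(pa_clean, "PA"), body_mask = body,
       depth_mm = depth_mm, spec = spec)
}

#' Specification of a smooth random deformation
#'
#' A parametric stand-in for intra-operative brain shift: independent Gaussian
#' noise per displacement channel, smoothed with a Gaussian of the stated
#' correlation length, then rescaled so the maximum displacement magnitude
#' equals \code{max_displacement_px} exactly.
#'
#' @param max_displacement_px maximum displacement magnitude (pixels).
#' @param smoothness_sigma_px Gaussian correlation length (pixels, >= 1).
#' @param seed integer RNG seed.
#' @return A list of class \code{deformation_spec}.
#' @export
deformation_spec <- function(max_displacement_px = 8,
                             smoothness_sigma_px = 32, seed = 1L) {
  if (max_displacement_px < 0) stop("max_displacement_px must be >= 0")
  if (smoothness_sigma_px < 1) stop("smoothness_sigma_px must be >= 1")
  structure(list(max_displacement_px = max_displacement_px,
                 smoothness_sigma_px = smoothness_sigma_px,
                 seed = as.integer(seed)),
            class = "deformation_spec")
}

#' Generate a smooth random deformation field
#'
#' @param spec a \code{\link{deformation_spec}}.
#' @param shape_px field shape (ny, nx).
#' @param spacing_mm pixel spacing recorded on the field.
#' @return A \code{\link{deformation_field}} whose maximum displacement
#'   magnitude equals \code{spec$max_displacement_px} (to 1e-9) and whose mean
#'   is near zero.
#' @export
generate_deformation <- function(spec, shape_px = c(256, 256),
                                 spacing_mm = c(1, 1)) {
  stopifnot(inherits(spec, "deformation_spec"))
  ny <- shape_px[1]; nx <- shape_px[2]
  if (spec$max_displacement_px == 0)
    return(deformation_field(matrix(0, ny, nx), matrix(0, ny, nx),
                             spacing_mm))
  set.seed(spec$seed)
  dy <- gaussian_smooth(matrix(stats::rnorm(ny * nx), ny, nx),
                        spec$smoothness_sigma_px)
  dx <- gaussian_smooth(matrix(stats::rnorm(ny * nx), ny, nx),
                        spec$smoothness_sigma_px)
  mag <- sqrt(dy^2 + dx^2)
  s <- spec$max_displacement_px / max(mag)
  deformation_field(dy * s, dx * s, spacing_mm)
}
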