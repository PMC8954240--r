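#' Target registration error
#'
#' Euclidean distance in mm between matched landmarks (matched by label) of a
#' ground-truth set and a recovered set.
#'
#' @param gt_targets,recovered_targets \code{\link{landmark_set}}s with
#'   matching labels.
#' @return A list with \code{per_target} (named distances, mm) and
#'   \code{mean}.
#' @examples
#' a <- landmark_set(rbind(c(0, 0)), "T1")
#' b <- landmark_set(rbind(c(3, 4)), "T1")
#' tre(a, b)$mean   # 5
#' @export
tre <- function(gt_targets, recovered_targets) {
  missing <- setdiff(gt_targets$labels, recovered_targets$labels)
  if (length(missing) > 0)
    stop("labels missing from recovered set: ",
         paste(missing, collapse = ", "))
  rec <- recovered_targets$points[gt_targets$labels, , drop = FALSE]
  d <- sqrt(rowSums((gt_targets$points - rec)^2))
  names(d) <- gt_targets$labels
  list(per_target = d, mean = mean(d))
}

#' Displacement-field RMSE in mm
#'
#' Root-mean-square of the residual displacement-vector error between a
#' ground-truth and a recovered field, converted to mm through the pixel
#' spacing: \code{sqrt(mean ||(gt - rec) * spacing||^2)} over the mask.
#'
#' @param gt_field,recovered_field \code{\link{deformation_field}}s of the
#'   same shape (displacements in pixels).
#' @param mask optional logical matrix; defaults to all pixels.
#' @param spacing (dy, dx) mm per pixel; defaults to the ground-truth field's
#'   spacing.
#' @return Scalar RMSE in mm; 0 iff the fields agree on the mask.
#' @export
displacement_rmse <- function(gt_field, recovered_field, mask = NULL,
                              spacing = NULL) {
  if (!all(dim(gt_field$dy) == dim(recovered_field$dy)))
    stop("fields must have the same shape")
  if (is.null(spacing)) spacing <- gt_field$spacing
  if (is.null(mask)) mask <- matrix(TRUE, nrow(gt_field$dy),
                                    ncol(gt_field$dy))
  if (!any(mask)) stop("mask is empty")
  ry <- (gt_field$dy - recovered_field$dy)[mask] * spacing[1]
  rx <- (gt_field$dx - recovered_field$dx)[mask] * spacing[2]
  sqrt(mean(ry^2 + rx^2))
}

directed_nn_dist <- function(a, b) {
  # nearest-neighbour Euclidean distance from each row of a to the set b,
  # chunked to bound memory on large boundary sets
  n <- nrow(a)
  out <- numeric(n)
  chunk <- max(1L, floor(2e6 / nrow(b)))
  for (s in seq(1, n, by = chunk)) {
    idx <- s:min(s + chunk - 1, n)
    d2 <- outer(a[idx, 1], b[, 1], "-")^2 + outer(a[idx, 2], b[, 2], "-")^2
    out[idx] <- sqrt(apply(d2, 1, min))
  }
  out
}

#' Hausdorff distance (95th percentile and maximum)
#'
#' Directed nearest-neighbour Euclidean distances are computed from every
#' point of A to the set B and vice versa; the robust variant replaces the
#' directed maxima with the 95th percentile of each directed distance
#' distribution (linear interpolation between order statistics) before taking
#' the outer maximum: \code{HD95 = max(P95 d(a, B), P95 d(b, A))}. The
#' classical maximum Hausdorff distance is attached as attribute
#' \code{"hd_max"}; HD95 never exceeds it.
#'
#' @param points_a,points_b non-empty numeric matrices with columns (y, x) in
#'   mm.
#' @param probs percentile in (0, 1]; 0.95 by default.
#' @return Scalar HD95 in mm, with attribute \code{hd_max}.
#' @examples
#' hausdorff95(rbind(c(0, 0)), rbind(c(3, 4)))   # 5
#' @export
hausdorff95 <- function(points_a, points_b, probs = 0.95) {
  points_a <- matrix(points_a, ncol = 2)
  points_b <- matrix(points_b, ncol = 2)
  if (nrow(points_a) == 0 || nrow(points_b) == 0)
    stop("point sets must be non-empty")
  dab <- directed_nn_dist(points_a, points_b)
  dba <- directed_nn_dist(points_b, points_a)
  hd95 <- max(stats::quantile(dab, probs, type = 7, names = FALSE),
              stats::quantile(dba, probs, type = 7, names = FALSE))
  structure(hd95, hd_max = max(max(dab), max(dba)))
}

#' Boundary points of a binary mask, in mm
#'
#' A pixel is a boundary pixel when it is inside the mask and at least one of
#' its 4-neighbours (or the image border) is outside.
#'
#' @param mask logical matrix.
#' @param spacing (dy, dx) mm per pixel.
#' @return Matrix of boundary pixel centres (y_mm, x_mm).
#' @export
mask_boundary_points <- function(mask, spacing = c(1, 1)) {
  ny <- nrow(mask); nx <- ncol(mask)
  pad <- matrix(FALSE, ny + 2, nx + 2)
  pad[2:(ny + 1), 2:(nx + 1)] <- mask
  interior <- pad[1:ny, 2:(nx + 1)] & pad[3:(ny + 2), 2:(nx + 1)] &
    pad[2:(ny + 1), 1:nx] & pad[2:(ny + 1), 3:(nx + 2)]
  b <- which(mask & !interior, arr.ind = TRUE)
  cbind(y_mm = (b[, 1] - 1) * spacing[1], x_mm = (b[, 2] - 1) * spacing[2])
}

#' Evaluate one registration run against simulated ground truth
#'
#' Computes the three report metrics for a registration result:
#' \itemize{
#'   \item RMSE: displacement-field RMSE (mm) between the recovered field and
#'     the ground-truth correspondence field (the inverse of the applied
#'     deformation, so that both map reference coordinates into the float
#'     image);
#'   \item TRE: mean distance (mm) between transform-mapped landmarks and
#'     their true positions in the float image;
#'   \item HD95: 95th-percentile Hausdorff distance (mm) between the vessel
#'     boundary of the reference mask and the boundary of the
#'     registration-compensated float mask.
#' }
#' Passing \code{transform_identity} gives the pre-registration (unregistered)
#' error level of the same quantities.
#'
#' @param gt list with \code{field} (the \code{\link{deformation_field}}
#'   applied to the float image), \code{landmarks}
#'   (\code{\link{landmark_set}}, reference frame), \code{mask} (logical
#'   vessel mask on the aligned images), and optionally \code{inv_field} (the
#'   precomputed inverse; computed here otherwise).
#' @param result a \code{registration_result}, or a bare \code{reg_transform}.
#' @param reference the reference \code{\link{image_grid}} (for spacing and
#'   mm conversion).
#' @return A list: \code{rmse_mm}, \code{tre_mm}, \code{tre_per_target},
#'   \code{hd95_mm}, \code{method}.
#' @export
evaluate_run <- function(gt, result, reference) {
  transform <- if (inherits(result, "registration_result")) result$transform
    else result
  method <- if (inherits(result, "registration_result"))
    result$metadata$method else "identity"
  spacing <- reference$spacing
  inv <- if (!is.null(gt$inv_field)) gt$inv_field else invert_field(gt$field)
  rec <- as_deformation_field(transform, spacing)
  rec$spacing <- spacing
  inv$spacing <- spacing
  rmse <- displacement_rmse(inv, rec, mask = NULL, spacing = spacing)

  lm_px <- landmarks_to_px(gt$landmarks, reference)
  d_rec <- displacement_at(transform, lm_px[, 1], lm_px[, 2])
  mapped <- cbind(lm_px[, 1] + d_rec$dy, lm_px[, 2] + d_rec$dx)
  d_true <- list(dy = bilinear_sample(inv$dy, lm_px[, 1], lm_px[, 2], "edge"),
                 dx = bilinear_sample(inv$dx, lm_px[, 1], lm_px[, 2], "edge"))
  truth <- cbind(lm_px[, 1] + d_true$dy, lm_px[, 2] + d_true$dx)
  dist_mm <- sqrt(((mapped[, 1] - truth[, 1]) * spacing[1])^2 +
                    ((mapped[, 2] - truth[, 2]) * spacing[2])^2)
  names(dist_mm) <- gt$landmarks$labels

  mask_img <- image_grid(gt$mask + 0, spacing)
  deformed_mask <- warp_image(mask_img, transform_dense(gt$field), "nearest",
                              "zero")
  compensated <- warp_image(deformed_mask, transform, "nearest", "zero")
  hd <- hausdorff95(mask_boundary_points(gt$mask, spacing),
                    mask_boundary_points(compensated$pixels > 0.5, spacing))

  list(rmse_mm = rmse, tre_mm = mean(dist_mm), tre_per_target = dist_mm,
       hd95_mm = as.numeric(hd), method = method)
}

#' Aggregate run metrics into a Table-1-style report
#'
#' @param rows list of \code{\link{evaluate_run}} outputs (one per run).
#' @return A data frame of class \code{eval_report} with one row per method:
#'   mean and (for more than one run) standard deviation of RMSE, TRE and
#'   HD95 in mm, plus run and target counts.
#' @export
eval_report <- function(rows) {
  methods <- unique(vapply(rows, `[[`, character(1), "method"))
  agg <- lapply(methods, function(m) {
    rs <- Filter(function(r) r$method == m, rows)
    col <- function(name) vapply(rs, `[[`, numeric(1), name)
    n <- length(rs)
    sdv <- function(v) if (n > 1) stats::sd(v) else NA_real_
    data.frame(method = m,
               rmse_mean = mean(col("rmse_mm")), rmse_sd = sdv(col("rmse_mm")),
               tre_mean = mean(col("tre_mm")), tre_sd = sdv(col("tre_mm")),
               hd95_mean = mean(col("hd95_mm")), hd95_sd = sdv(col("hd95_mm")),
               n_runs = n,
               n_targets = length(rs[[1]]$tre_per_target))
  })
  out <- do.call(rbind, agg)
  class(out) <- c("eval_report", "data.frame")
  out
}

#' @export
print.eval_report <- function(x, ...) {
  fmt <- function(m, s) ifelse(is.na(s), sprintf("%.3f", m),
                               sprintf("%.3f ± %.3f", m, s))
  cat("Registration evaluation (mm):\n")
  print(data.frame(method = x$method,
                   RMSE = fmt(x$rmse_mean, x$rmse_sd),
                   TRE = fmt(x$tre_mean, x$tre_sd),
                   HD95 = fmt(x$hd95_mean, x$hd95_sd),
                   runs = x$n_runs), row.names = FALSE)
  invisible(x)
}
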