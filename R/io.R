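infer_format <- function(path) {
  low <- tolower(path)
  if (grepl("\\.png$", low)) return("png")
  if (grepl("\\.tiff?$", low)) return("tiff")
  if (grepl("\\.nii(\\.gz)?$", low)) return("nifti")
  stop("cannot infer image format from path: ", path)
}

#' Read / write 2D images (PNG, TIFF, NIfTI)
#'
#' PNG and TIFF carry no physical spacing; unless \code{spacing} is supplied
#' they default to (1, 1) mm with a warning. NIfTI spacing is taken from (and
#' written to) the header \code{pixdim}. Multi-channel PNG/TIFF input is
#' reduced to the channel mean with a warning; a genuinely 3D NIfTI volume is
#' an error, since the pipeline is 2D.
#'
#' @param path file path; format inferred from the extension unless \code{fmt}
#'   is given.
#' @param fmt \code{"png"}, \code{"tiff"} or \code{"nifti"}.
#' @param spacing optional (dy, dx) mm override.
#' @param modality modality tag for the returned \code{\link{image_grid}}.
#' @return \code{read_image}: an \code{image_grid}. \code{write_image}:
#'   the path, invisibly.
#' @export
read_image <- function(path, fmt = NULL, spacing = NULL, modality = "OTHER") {
  if (!file.exists(path)) stop("file not found: ", path)
  fmt <- if (is.null(fmt)) infer_format(path) else
    match.arg(fmt, c("png", "tiff", "nifti"))
  if (fmt == "nifti") {
    nii <- RNifti::readNifti(path)
    arr <- as.array(nii)
    d <- dim(arr)
    keep <- d > 1
    if (sum(keep) > 2)
      stop("expected a 2D image but got a volume of shape ",
           paste(d, collapse = " x "), " (", sum(keep), " non-singleton axes)")
    arr <- array(arr, d[keep])
    if (length(dim(arr)) != 2)
      stop("expected a 2D image but got shape ", paste(d, collapse = " x "))
    sp <- if (!is.null(spacing)) spacing else RNifti::pixdim(nii)[1:2]
    return(image_grid(matrix(as.numeric(arr), nrow(arr), ncol(arr)),
                      spacing = sp, modality = modality))
  }
  arr <- if (fmt == "png") png::readPNG(path) else tiff::readTIFF(path)
  if (length(dim(arr)) == 3) {
    if (dim(arr)[3] > 4)
      stop("expected a 2D image but got shape ",
           paste(dim(arr), collapse = " x "))
    warning("multi-channel image reduced to channel mean")
    arr <- apply(arr, c(1, 2), mean)
  }
  if (is.null(spacing)) {
    warning(toupper(fmt), " carries no physical spacing; defaulting to 1 mm")
    spacing <- c(1, 1)
  }
  image_grid(arr, spacing = spacing, modality = modality)
}

#' @param image an \code{\link{image_grid}}. For PNG/TIFF the intensities must
#'   already lie in [0, 1]; NIfTI stores raw values.
#' @param bits bit depth for TIFF (8 or 16).
#' @rdname read_image
#' @export
write_image <- function(image, path, fmt = NULL, bits = 16L) {
  stopifnot_image(image)
  fmt <- if (is.null(fmt)) infer_format(path) else
    match.arg(fmt, c("png", "tiff", "nifti"))
  if (fmt == "nifti") {
    nii <- RNifti::asNifti(image$pixels)
    RNifti::pixdim(nii) <- image$spacing
    RNifti::writeNifti(nii, path)
    return(invisible(path))
  }
  p <- image$pixels
  if (min(p) < 0 || max(p) > 1)
    stop("PNG/TIFF output requires intensities in [0, 1]; rescale first")
  if (fmt == "png") png::writePNG(p, path)
  else tiff::writeTIFF(p, path, bits.per.sample = as.integer(bits))
  invisible(path)
}

#' Read / write landmark CSV files
#'
#' Plain CSV with header \code{label,y_mm,x_mm}.
#'
#' @param path CSV path.
#' @param landmarks a \code{\link{landmark_set}}.
#' @return \code{read_landmarks}: a \code{landmark_set}.
#' @export
read_landmarks <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "y_mm", "x_mm")
  if (!all(need %in% names(df)))
    stop("landmark CSV must have columns: ", paste(need, collapse = ", "))
  landmark_set(cbind(df$y_mm, df$x_mm), labels = df$label)
}

#' @rdname read_landmarks
#' @export
write_landmarks <- function(landmarks, path) {
  df <- data.frame(label = landmarks$labels,
                   y_mm = landmarks$points[, 1],
                   x_mm = landmarks$points[, 2])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write displacement fields as two-volume NIfTI
#'
#' The field is stored as an (ny, nx, 2) NIfTI array, channel 1 = dy, channel
#' 2 = dx, displacements in pixels; a JSON sidecar records the backward-warping
#' convention, units and spacing.
#'
#' @param field a \code{\link{deformation_field}}.
#' @param path output path (.nii or .nii.gz); the sidecar gets \code{.json}
#'   appended.
#' @return \code{read_field}: a \code{deformation_field}.
#' @export
write_field <- function(field, path) {
  arr <- array(c(field$dy, field$dx), c(dim(field$dy), 2))
  nii <- RNifti::asNifti(arr)
  RNifti::pixdim(nii) <- c(field$spacing, 1)
  RNifti::writeNifti(nii, path)
  jsonlite::write_json(
    list(convention = "backward warping: output(y,x) = input(y+dy, x+dx)",
         units = "pixels", channels = c("dy", "dx"),
         spacing_mm = field$spacing),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_field
#' @export
read_field <- function(path) {
  arr <- as.array(RNifti::readNifti(path))
  if (length(dim(arr)) != 3 || dim(arr)[3] != 2)
    stop("expected an (ny, nx, 2) field volume; got shape ",
         paste(dim(arr), collapse = " x "))
  spacing <- c(1, 1)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(meta$spacing_mm)) spacing <- as.numeric(meta$spacing_mm)
  }
  deformation_field(arr[, , 1], arr[, , 2], spacing)
}
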