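# Readers and writers for the supported on-disk formats: NIfTI volumes
# (spacing-aware) and PNG images/masks.

#' Read an image or volume
#'
#' NIfTI files (`.nii`, `.nii.gz`) are read with their header spacing; PNG
#' files are read as intensities in `[0, 1]` with unit spacing.
#'
#' @param path file path.
#' @return list with `data` (numeric array) and `spacing` (mm per axis).
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lp <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lp)) {
    v <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("corrupt or unreadable NIfTI file: ",
                                           path, call. = FALSE))
    sp <- RNifti::pixdim(v)
    a <- as.array(v)
    data <- array(as.numeric(a), dim = dim(a))  # strip header attributes
    return(list(data = data, spacing = as.numeric(sp)))
  }
  if (grepl("\\.png$", lp)) {
    a <- tryCatch(png::readPNG(path),
                  error = function(e) stop("corrupt or unreadable PNG file: ",
                                           path, call. = FALSE))
    return(list(data = as.array(a), spacing = rep(1, 2)))
  }
  stop("unsupported format (expected .nii, .nii.gz or .png): ", path)
}

#' Write an integer label mask
#'
#' PNG output stores labels in an 8-bit grayscale channel (labels must be
#' < 256); NIfTI output preserves spacing. `read(write(x))` recovers the
#' labels exactly.
#'
#' @param mask integer matrix (or 3D array for NIfTI).
#' @param path output path ending in `.png`, `.nii` or `.nii.gz`.
#' @param spacing spacing stored in NIfTI headers.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path, spacing = c(1, 1)) {
  lp <- tolower(path)
  if (grepl("\\.png$", lp)) {
    if (max(mask) > 255) stop("PNG masks support at most 256 labels")
    png::writePNG(mask / 255, path)
  } else if (grepl("\\.nii(\\.gz)?$", lp)) {
    RNifti::writeNifti(nifti_with_spacing(mask, spacing), path)
  } else {
    stop("unsupported mask format (expected .png, .nii or .nii.gz): ", path)
  }
  invisible(path)
}

#' Read a label mask written by [write_mask()]
#'
#' @param path mask path.
#' @return integer matrix/array of labels.
#' @export
read_mask <- function(path) {
  v <- read_volume(path)
  x <- v$data
  if (grepl("\\.png$", tolower(path))) x <- x * 255
  r <- round(x)
  storage.mode(r) <- "integer"
  r
}

nifti_with_spacing <- function(x, spacing) {
  img <- RNifti::asNifti(x)
  RNifti::pixdim(img) <- spacing
  img
}
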