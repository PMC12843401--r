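# Synthetic phantom generator. Emulates the qualitative difficulties of
# abdominal CT slices -- several "organ-like" targets of very different
# sizes, smooth irregular outlines, low-contrast class pairs, and a noisy
# background -- so that training, loss and metric code paths can be
# exercised without any dataset download. It does not emulate real anatomy,
# scanner physics, or inter-slice correlation.

#' Generate a synthetic multi-class phantom
#'
#' Draws `n_classes - 1` organ-like blobs (randomly deformed ellipses) on a
#' noisy background. Blob areas are log-spaced from large (> 10% of the
#' canvas) to small (< 1%), each blob has a distinct mean intensity, and two
#' of the intensities are deliberately close (a low-contrast pair). The mask
#' matches the blob geometry exactly and every label is present. Fully
#' deterministic per seed.
#'
#' @param seed RNG seed.
#' @param size canvas side in pixels (>= 32).
#' @param n_classes class count including background (>= 2).
#' @param noise_sd standard deviation of the additive Gaussian image noise;
#'   set 0 for noise-free blobs whose interior mean equals the assigned
#'   intensity exactly.
#' @param spacing pixel spacing in mm recorded in the sample.
#' @return a `segmentation_sample`: list with `image` (matrix in `[0, 1]`),
#'   `mask` (integer matrix), `spacing`, `source`.
#' @examples
#' s <- generate_phantom(seed = 7, size = 64, n_classes = 4)
#' table(s$mask)
#' @export
generate_phantom <- function(seed = 1L, size = 224L, n_classes = 9L,
                             noise_sd = 0.03, spacing = c(1, 1)) {
  if (n_classes < 2) stop("n_classes must be at least 2")
  if (size < 32) stop("size must be at least 32")
  n_blobs <- n_classes - 1L
  if (n_blobs > floor((size / 8)^2 / 4))
    stop("too many classes for the canvas size")
  withr::with_seed(seed, {
    H <- size; W <- size
    # blob "radii": areas log-spaced between ~16% and ~0.5% of the canvas
    r_big <- sqrt(0.16 / pi) * size
    r_small <- sqrt(0.005 / pi) * size
    radii <- exp(seq(log(r_big), log(r_small), length.out = max(n_blobs, 2)))
    radii <- radii[seq_len(n_blobs)]
    # distinct mean intensities in (0.25, 0.95); make the last two a
    # low-contrast pair when there are >= 3 blobs
    vals <- seq(0.3, 0.9, length.out = n_blobs)
    if (n_blobs >= 3) vals[n_blobs] <- vals[n_blobs - 1] + 0.05
    vals <- vals[sample.int(n_blobs)]
    mask <- matrix(0L, H, W)
    img <- matrix(0.15, H, W)
    # slow background intensity drift
    gx <- matrix(rep(seq(-0.5, 0.5, length.out = W), each = H), H, W)
    img <- img + 0.05 * gx * stats::runif(1, -1, 1)
    yy <- matrix(rep(seq_len(H), times = W), H, W)
    xx <- matrix(rep(seq_len(W), each = H), H, W)
    for (k in seq_len(n_blobs)) {
      r <- radii[k]
      placed <- FALSE
      for (try in 1:200) {
        cy <- stats::runif(1, r + 2, H - r - 2)
        cx <- stats::runif(1, r + 2, W - r - 2)
        ar <- stats::runif(1, 0.7, 1.4)          # axis ratio
        th <- stats::runif(1, 0, pi)             # orientation
        nharm <- 3L
        amp <- stats::runif(nharm, 0, 0.15)
        ph <- stats::runif(nharm, 0, 2 * pi)
        dy <- yy - cy; dx <- xx - cx
        u <- dx * cos(th) + dy * sin(th)
        v <- -dx * sin(th) + dy * cos(th)
        ang <- atan2(v, u * ar)
        rad <- sqrt((u * ar)^2 + v^2)
        wig <- rep(1, length(ang))
        for (hh in seq_len(nharm))
          wig <- wig + amp[hh] * cos(hh * ang + ph[hh])
        inside <- rad <= r * wig
        dim(inside) <- c(H, W)
        # keep blobs from erasing earlier (larger) classes entirely
        overlap <- sum(inside & mask != 0) / max(sum(inside), 1)
        if (sum(inside) >= 4 && overlap < 0.5) {
          mask[inside] <- k
          img[inside] <- vals[k]
          placed <- TRUE
          break
        }
      }
      if (!placed) stop("could not place all blobs; too many classes for the canvas")
    }
    if (any(tabulate(mask + 1L, nbins = n_classes) == 0))
      stop("could not place all blobs; too many classes for the canvas")
    if (noise_sd > 0)
      img <- img + matrix(stats::rnorm(H * W, 0, noise_sd), H, W)
    img <- pmin(pmax(img, 0), 1)
    segmentation_sample(image = img, mask = mask, spacing = spacing,
                        source = sprintf("phantom-seed%d", seed))
  })
}

#' Construct a segmentation sample
#'
#' A lightweight container pairing an image with its integer label mask,
#' pixel spacing and provenance.
#'
#' @param image numeric matrix `(H, W)` or array `(H, W, 3)`.
#' @param mask integer matrix `(H, W)`, labels in `0 .. C-1`.
#' @param spacing physical pixel size in mm per axis.
#' @param source free-form provenance string.
#' @return a `segmentation_sample` list.
#' @export
segmentation_sample <- function(image, mask, spacing = c(1, 1),
                                source = "unknown") {
  di <- dim(image)[1:2]
  dm <- dim(mask)[1:2]
  if (!identical(di, dm)) stop("image and mask must be spatially congruent")
  if (any(mask < 0)) stop("mask labels must be nonnegative")
  structure(list(image = image, mask = matrix(as.integer(mask), dm[1], dm[2]),
                 spacing = spacing, source = source),
            class = "segmentation_sample")
}

#' @export
print.segmentation_sample <- function(x, ...) {
  cat(sprintf("<segmentation_sample> %dx%d, %d labels, spacing %s mm (%s)\n",
              nrow(x$mask), ncol(x$mask), length(unique(as.vector(x$mask))),
              paste(signif(x$spacing, 3), collapse = "x"), x$source))
  invisible(x)
}

#' Generate a phantom dataset on disk
#'
#' Writes `n` phantom samples as uncompressed NIfTI image/mask pairs plus a
#' CSV manifest (id, file names, per-sample seed, class count, size).
#' Regeneration with the same seed reproduces identical arrays.
#'
#' @param n number of samples (>= 1).
#' @param seed master seed; per-sample seeds are derived deterministically.
#' @param out_dir output directory (created if missing).
#' @param size,n_classes,noise_sd forwarded to [generate_phantom()].
#' @return the manifest as a tibble (also written to `manifest.csv`).
#' @export
generate_dataset <- function(n, seed = 1L, out_dir, size = 224L,
                             n_classes = 9L, noise_sd = 0.03) {
  if (n < 1) stop("n must be at least 1")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  rows <- lapply(seq_len(n), function(i) {
    si <- (as.numeric(seed) * 1009 + i * 7919) %% 2147483647
    s <- generate_phantom(seed = as.integer(si), size = size,
                          n_classes = n_classes, noise_sd = noise_sd)
    id <- sprintf("phantom_%03d", i)
    img_f <- file.path(out_dir, paste0(id, "_img.nii"))
    msk_f <- file.path(out_dir, paste0(id, "_msk.nii"))
    RNifti::writeNifti(nifti_with_spacing(s$image, s$spacing), img_f)
    RNifti::writeNifti(nifti_with_spacing(s$mask, s$spacing), msk_f)
    tibble::tibble(id = id, image = basename(img_f), mask = basename(msk_f),
                   seed = as.integer(si), n_classes = n_classes, size = size)
  })
  manifest <- dplyr::bind_rows(rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  manifest
}

#' Load a dataset written by [generate_dataset()]
#'
#' @param dir dataset directory containing `manifest.csv`.
#' @return list of `segmentation_sample` objects.
#' @export
load_dataset <- function(dir) {
  mf <- file.path(dir, "manifest.csv")
  if (!file.exists(mf)) stop("no manifest.csv in ", dir)
  manifest <- utils::read.csv(mf, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(manifest)), function(i) {
    img <- read_volume(file.path(dir, manifest$image[i]))
    msk <- read_volume(file.path(dir, manifest$mask[i]))
    segmentation_sample(image = img$data, mask = round(msk$data),
                        spacing = img$spacing[1:2], source = manifest$id[i])
  })
}
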