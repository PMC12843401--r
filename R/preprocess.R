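# CT preprocessing and the on-the-fly augmentation policy.

#' Clip and normalize CT intensities
#'
#' Hounsfield-unit values are truncated to the soft-tissue window
#' `[lo, hi] = [-125, 275]` HU and mapped affinely to `[0, 1]`. The mapping
#' is monotone non-decreasing; values below/above the window saturate at
#' 0/1.
#'
#' @param volume numeric array of HU values (any shape).
#' @param lo,hi window bounds in HU.
#' @return array of the same shape with values in `[0, 1]`.
#' @examples
#' clip_normalize_ct(c(-1000, -125, 75, 275, 2000))
#' @export
clip_normalize_ct <- function(volume, lo = -125, hi = 275) {
  if (lo >= hi) stop("lo must be strictly below hi")
  (pmin(pmax(volume, lo), hi) - lo) / (hi - lo)
}

#' Resize an image/mask pair to a uniform resolution
#'
#' The image is resized bilinearly; the mask with nearest-neighbor sampling,
#' so no new labels can appear.
#'
#' @param sample a `segmentation_sample`.
#' @param size target side in pixels (default 224).
#' @return resized `segmentation_sample` (spacing rescaled accordingly).
#' @export
resize_pair <- function(sample, size = 224L) {
  if (size <= 0) stop("size must be positive")
  d <- dim(sample$mask)
  if (all(d == size)) return(sample)
  img <- resize_image(sample$image, size, bilinear = TRUE)
  msk <- resize_image(sample$mask, size, bilinear = FALSE)
  segmentation_sample(image = img, mask = round(msk),
                      spacing = sample$spacing * d[1:2] / size,
                      source = sample$source)
}

resize_image <- function(x, size, bilinear = TRUE) {
  filt <- if (bilinear) "bilinear" else "none"
  y <- EBImage::resize(x, w = size, h = size, filter = filt)
  as.array(y)
}

#' Augmentation policy
#'
#' Parameters of the on-the-fly training augmentation. Geometric transforms
#' (flip, rotation, translation, scaling, elastic deformation) are applied
#' jointly to image and mask -- bilinear resampling for the image, nearest
#' neighbor for the mask so labels stay crisp. Intensity transforms
#' (brightness/contrast, Gaussian noise, CLAHE) and occlusion affect the
#' image only. Each optional transform fires with probability 0.5; flip
#' probability and rotation limit follow the training protocol, remaining
#' magnitudes are conservative defaults.
#'
#' @param flip_prob horizontal flip probability (0.5).
#' @param rotate_limit rotation limit in degrees (20, i.e. +/- 20).
#' @param translate_frac maximum translation as a fraction of the side (0.1).
#' @param scale_range multiplicative scale range (c(0.9, 1.1)).
#' @param elastic_alpha,elastic_sigma elastic displacement magnitude and
#'   Gaussian smoothing, in pixels (30, 5); `elastic_alpha = 0` disables.
#' @param occlusion_holes,occlusion_size max random occlusion holes and hole
#'   side in pixels (2, 16).
#' @param brightness_limit,contrast_limit additive/multiplicative intensity
#'   limits (0.2, 0.2).
#' @param noise_sd max Gaussian noise standard deviation (0.02).
#' @param clahe_clip CLAHE clip limit (2); 0 disables.
#' @param seed master seed combined with the per-draw seed for
#'   reproducibility.
#' @return an `augmentation_policy` list.
#' @export
augmentation_policy <- function(flip_prob = 0.5, rotate_limit = 20,
                                translate_frac = 0.1,
                                scale_range = c(0.9, 1.1),
                                elastic_alpha = 30, elastic_sigma = 5,
                                occlusion_holes = 2L, occlusion_size = 16L,
                                brightness_limit = 0.2, contrast_limit = 0.2,
                                noise_sd = 0.02, clahe_clip = 2,
                                seed = 1L) {
  stopifnot(flip_prob >= 0, flip_prob <= 1)
  structure(list(flip_prob = flip_prob, rotate_limit = rotate_limit,
                 translate_frac = translate_frac, scale_range = scale_range,
                 elastic_alpha = elastic_alpha, elastic_sigma = elastic_sigma,
                 occlusion_holes = occlusion_holes,
                 occlusion_size = occlusion_size,
                 brightness_limit = brightness_limit,
                 contrast_limit = contrast_limit,
                 noise_sd = noise_sd, clahe_clip = clahe_clip, seed = seed),
            class = "augmentation_policy")
}

#' Apply one stochastic augmentation draw
#'
#' Reproducible given `(policy$seed, draw_seed)`. The transform draws are
#' recorded in the `"draws"` attribute of the result (e.g. whether the flip
#' fired), which the Monte-Carlo policy tests rely on.
#'
#' @param sample a `segmentation_sample`.
#' @param policy an [augmentation_policy()].
#' @param draw_seed per-draw seed (e.g. the training iteration).
#' @return augmented `segmentation_sample` with attribute `"draws"`.
#' @export
augment <- function(sample, policy = augmentation_policy(), draw_seed = 1L) {
  seed <- (as.numeric(policy$seed) * 100003 + as.numeric(draw_seed)) %% 2147483647
  withr::with_seed(as.integer(seed), augment_impl(sample, policy))
}

augment_impl <- function(sample, policy) {
  img <- sample$image
  msk <- sample$mask
  d <- dim(msk)
  H <- d[1]; W <- d[2]
  draws <- list()
  # ---- joint geometric transform (inverse map from output to source) ----
  draws$flip <- stats::runif(1) < policy$flip_prob
  ang <- stats::runif(1, -policy$rotate_limit, policy$rotate_limit) * pi / 180
  draws$angle_deg <- ang * 180 / pi
  tr <- stats::runif(2, -policy$translate_frac, policy$translate_frac) * c(H, W)
  sc <- stats::runif(1, policy$scale_range[1], policy$scale_range[2])
  draws$scale <- sc
  cy <- (H - 1) / 2; cx <- (W - 1) / 2
  or <- matrix(rep(seq_len(H) - 1, times = W), H, W)
  oc <- matrix(rep(seq_len(W) - 1, each = H), H, W)
  ocf <- if (draws$flip) (W - 1) - oc else oc
  # inverse affine: undo translation, then rotation/scale about the center
  ry <- or - cy - tr[1]
  rx <- ocf - cx - tr[2]
  mapr <- cy + (cos(-ang) * ry - sin(-ang) * rx) / sc
  mapc <- cx + (sin(-ang) * ry + cos(-ang) * rx) / sc
  draws$elastic <- policy$elastic_alpha > 0 && stats::runif(1) < 0.5
  if (draws$elastic) {
    fy <- matrix(stats::runif(H * W, -1, 1), H, W)
    fx <- matrix(stats::runif(H * W, -1, 1), H, W)
    fy <- as.array(EBImage::gblur(fy, sigma = policy$elastic_sigma))
    fx <- as.array(EBImage::gblur(fx, sigma = policy$elastic_sigma))
    fy <- fy / max(abs(fy), 1e-12) * policy$elastic_alpha / 10
    fx <- fx / max(abs(fx), 1e-12) * policy$elastic_alpha / 10
    mapr <- mapr + fy
    mapc <- mapc + fx
  }
  img3 <- if (is.matrix(img)) array(img, c(H, W, 1L)) else img
  wi <- cpp_warp(img3, mapr, mapc, 0L)
  wm <- cpp_warp(array(msk, c(H, W, 1L)), mapr, mapc, 1L)
  img <- if (is.matrix(img)) wi[, , 1] else wi
  msk <- matrix(as.integer(round(wm[, , 1])), H, W)
  # ---- occlusion (image only) ----
  draws$occlusion <- policy$occlusion_holes > 0 && stats::runif(1) < 0.5
  if (draws$occlusion) {
    nh <- sample.int(policy$occlusion_holes, 1)
    for (k in seq_len(nh)) {
      hs <- sample.int(policy$occlusion_size, 1)
      r0 <- sample.int(max(H - hs, 1), 1)
      c0 <- sample.int(max(W - hs, 1), 1)
      if (is.matrix(img)) img[r0:(r0 + hs - 1), c0:(c0 + hs - 1)] <- 0
      else img[r0:(r0 + hs - 1), c0:(c0 + hs - 1), ] <- 0
    }
  }
  # ---- intensity (image only) ----
  draws$brightness_contrast <- stats::runif(1) < 0.5
  if (draws$brightness_contrast) {
    a <- stats::runif(1, -policy$contrast_limit, policy$contrast_limit)
    bb <- stats::runif(1, -policy$brightness_limit, policy$brightness_limit)
    img <- img * (1 + a) + bb
  }
  draws$noise <- policy$noise_sd > 0 && stats::runif(1) < 0.5
  if (draws$noise) {
    sdv <- stats::runif(1, 0, policy$noise_sd)
    img <- img + array(stats::rnorm(length(img), 0, sdv), dim(img))
  }
  draws$clahe <- policy$clahe_clip > 0 && stats::runif(1) < 0.5
  if (draws$clahe) {
    img <- pmin(pmax(img, 0), 1)
    img <- tryCatch(as.array(EBImage::clahe(img, limit = policy$clahe_clip)),
                    error = function(e) img)
  }
  img <- pmin(pmax(img, 0), 1)
  out <- segmentation_sample(image = img, mask = msk,
                             spacing = sample$spacing, source = sample$source)
  attr(out, "draws") <- draws
  out
}
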