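test_that("CT windowing maps the HU window onto [0,1] monotonically", {
  expect_equal(clip_normalize_ct(-125), 0)
  expect_equal(clip_normalize_ct(275), 1)
  expect_equal(clip_normalize_ct(75), 0.5)
  expect_equal(clip_normalize_ct(-1000), 0)
  expect_equal(clip_normalize_ct(3000), 1)
  hu <- sort(stats::runif(100, -1200, 2000))
  expect_true(all(diff(clip_normalize_ct(hu)) >= 0))
  expect_error(clip_normalize_ct(0, lo = 10, hi = 10), "strictly below")
})

test_that("pair resizing keeps masks label-exact", {
  withr::with_seed(2, {
    img <- matrix(stats::runif(512 * 512), 512, 512)
    msk <- matrix(0L, 512, 512)
    msk[100:300, 150:350] <- 1L
    msk[400:450, 40:90] <- 2L
  })
  s <- segmentation_sample(img, msk)
  r <- resize_pair(s, 224)
  expect_equal(dim(r$image), c(224, 224))
  expect_equal(dim(r$mask), c(224, 224))
  expect_true(all(r$mask %in% c(0L, 1L, 2L)))
  # binary stays binary
  sb <- segmentation_sample(img, (msk > 0) + 0L)
  expect_true(all(resize_pair(sb, 100)$mask %in% c(0L, 1L)))
  # identity at the target size
  s224 <- resize_pair(s, 224)
  expect_identical(resize_pair(s224, 224), s224)
  expect_error(resize_pair(s, 0), "positive")
})

test_that("phantoms are deterministic, complete and multi-scale", {
  a <- generate_phantom(seed = 11, size = 64, n_classes = 4)
  b <- generate_phantom(seed = 11, size = 64, n_classes = 4)
  expect_identical(a$image, b$image)
  expect_identical(a$mask, b$mask)
  expect_false(identical(a$mask, generate_phantom(seed = 12, size = 64,
                                                  n_classes = 4)$mask))
  # every label present; multi-scale areas over many seeds
  areas_small <- logical(0); areas_big <- logical(0)
  for (sd in 1:100) {
    s <- generate_phantom(seed = sd, size = 64, n_classes = 4, noise_sd = 0)
    expect_setequal(unique(as.vector(s$mask)), 0:3)
    ar <- tabulate(s$mask, nbins = 3) / length(s$mask)
    areas_small <- c(areas_small, any(ar < 0.01))
    areas_big <- c(areas_big, any(ar > 0.10))
  }
  expect_true(all(areas_small))
  expect_true(all(areas_big))
})

test_that("noise-free blob interiors equal their assigned intensity", {
  s <- generate_phantom(seed = 5, size = 64, n_classes = 5, noise_sd = 0)
  for (cl in 1:4) {
    vals <- s$image[s$mask == cl]
    expect_equal(stats::sd(vals), 0, tolerance = 1e-12)
    expect_equal(mean(vals), vals[1])
  }
  expect_error(generate_phantom(seed = 1, size = 32, n_classes = 40),
               "too many classes")
})

test_that("augmentation is reproducible and label-safe", {
  s <- generate_phantom(seed = 3, size = 64, n_classes = 4)
  pol <- augmentation_policy(seed = 9)
  a1 <- augment(s, pol, draw_seed = 42)
  a2 <- augment(s, pol, draw_seed = 42)
  expect_identical(a1$image, a2$image)
  expect_identical(a1$mask, a2$mask)
  expect_false(identical(a1$mask, augment(s, pol, draw_seed = 43)$mask))
  for (d in 1:20) {
    aa <- augment(s, pol, draw_seed = d)
    expect_true(is.integer(aa$mask))
    expect_true(all(aa$mask %in% unique(as.vector(s$mask))))
    expect_true(all(aa$image >= 0 & aa$image <= 1))
  }
})

test_that("horizontal flips occur at the configured frequency", {
  s <- generate_phantom(seed = 3, size = 32, n_classes = 3)
  pol <- augmentation_policy(seed = 1, elastic_alpha = 0, clahe_clip = 0,
                             noise_sd = 0, occlusion_holes = 0L)
  flips <- vapply(1:2000, function(d)
    attr(augment(s, pol, draw_seed = d), "draws")$flip, logical(1))
  expect_gt(mean(flips), 0.47)
  expect_lt(mean(flips), 0.53)
})

test_that("image and mask undergo the same geometric displacement", {
  # a distinctive mask pixel and a bright image dot at the same location
  # must land on the same place after the joint transform
  img <- matrix(0, 64, 64); msk <- matrix(0L, 64, 64)
  img[40, 22] <- 1; msk[40, 22] <- 1L
  s <- segmentation_sample(img, msk)
  pol <- augmentation_policy(seed = 5, elastic_alpha = 30, clahe_clip = 0,
                             noise_sd = 0, occlusion_holes = 0L,
                             brightness_limit = 0, contrast_limit = 0)
  hits <- 0L
  for (d in 1:10) {
    a <- augment(s, pol, draw_seed = d)
    if (!any(a$mask == 1L)) next
    mpos <- which(a$mask == 1L, arr.ind = TRUE)
    ipos <- which(a$image == max(a$image), arr.ind = TRUE)
    dmin <- min(sqrt((mpos[, 1] - ipos[1, 1])^2 + (mpos[, 2] - ipos[1, 2])^2))
    expect_lt(dmin, 2)
    hits <- hits + 1L
  }
  expect_gt(hits, 5L)
})

test_that("masks and volumes round-trip through PNG and NIfTI", {
  withr::with_seed(4, msk <- matrix(sample(0:8, 64 * 64, TRUE), 64, 64))
  fp <- withr::local_tempfile(fileext = ".png")
  write_mask(msk, fp)
  expect_identical(read_mask(fp), msk)
  fn <- withr::local_tempfile(fileext = ".nii.gz")
  write_mask(msk, fn, spacing = c(0.8, 0.8))
  expect_equal(unname(read_mask(fn)), unname(msk))
  v <- read_volume(fn)
  expect_equal(v$spacing[1:2], c(0.8, 0.8), tolerance = 1e-6)
  # spacing survives a 3D round trip
  vol <- array(stats::runif(4 * 4 * 3), c(4, 4, 3))
  f3 <- withr::local_tempfile(fileext = ".nii")
  v3 <- RNifti::asNifti(vol); RNifti::pixdim(v3) <- c(0.8, 0.8, 3.0); RNifti::writeNifti(v3, f3)
  expect_equal(read_volume(f3)$spacing[1:3], c(0.8, 0.8, 3.0),
               tolerance = 1e-6)
  # unknown / corrupt formats
  ft <- withr::local_tempfile(fileext = ".txt")
  writeLines("not an image", ft)
  expect_error(read_volume(ft), "unsupported")
  fbad <- withr::local_tempfile(fileext = ".png")
  writeLines("not a png", fbad)
  expect_error(read_volume(fbad), "PNG")
})

test_that("dataset generation writes a complete reproducible manifest", {
  d1 <- withr::local_tempdir()
  man <- generate_dataset(8, seed = 7, out_dir = d1, size = 32, n_classes = 3)
  expect_equal(nrow(man), 8L)
  expect_false(any(duplicated(man$id)))
  expect_true(all(file.exists(file.path(d1, man$image))))
  samples <- load_dataset(d1)
  expect_length(samples, 8L)
  d2 <- withr::local_tempdir()
  generate_dataset(8, seed = 7, out_dir = d2, size = 32, n_classes = 3)
  s1 <- load_dataset(d1); s2 <- load_dataset(d2)
  for (i in 1:8) {
    expect_identical(s1[[i]]$mask, s2[[i]]$mask)
    expect_equal(s1[[i]]$image, s2[[i]]$image)
  }
  expect_error(generate_dataset(0, out_dir = d1), "at least 1")
})
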