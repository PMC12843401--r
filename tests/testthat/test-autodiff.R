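# The in-package reverse-mode engine against finite differences.

ns <- asNamespace("m3seg")

grad_of <- function(build, x) {
  ns$ag_tape_start()
  xn <- ns$ag_leaf(x, "x")
  l <- build(xn)
  ns$ag_backward(l)
  g <- xn$g
  ns$ag_tape_stop()
  g
}

test_that("convolution gradients match finite differences", {
  x <- rand_grid(5, 5, 3, seed = 2)
  w <- rand_grid(3, 3, 3, seed = 3)[, , 1:3, drop = FALSE]
  w <- array(w * 0.3, c(3, 3, 3, 2))[, , , 1:2]
  w <- array(stats::rnorm(3 * 3 * 3 * 2, 0, 0.3), c(3, 3, 3, 2))
  b <- c(0.1, -0.2)
  wt <- rand_grid(5, 5, 2, seed = 4)
  g <- grad_of(function(xn) ns$ag_sum(ns$ag_mul(
    ns$ag_conv2d(xn, w, b, stride = 1L, pad = 1L, groups = 1L), wt)), x)
  fn <- function(xx) sum(ns$cpp_conv2d(array(xx, dim(x)), as.numeric(w), b,
                                       TRUE, 3, 3, 3, 2, 1, 1, 1) * wt)
  expect_lt(max(abs(g - num_grad(fn, x))), 1e-6)
})

test_that("grouped and depthwise convolution gradients are exact", {
  x <- rand_grid(4, 4, 6, seed = 5)
  w <- array(stats::rnorm(3 * 3 * 1 * 6, 0, 0.3), c(3, 3, 1, 6))
  g <- grad_of(function(xn) ns$ag_sum(
    ns$ag_conv2d(xn, w, NULL, stride = 1L, pad = 1L, groups = 6L)), x)
  fn <- function(xx) sum(ns$cpp_conv2d(array(xx, dim(x)), as.numeric(w),
                                       numeric(1), FALSE, 3, 3, 1, 6, 1, 1, 6))
  expect_lt(max(abs(g - num_grad(fn, x))), 1e-6)
})

test_that("normalization and attention op gradients match finite differences", {
  X <- matrix(stats::rnorm(6 * 8), 6, 8)
  gam <- runif(8, 0.5, 1.5); bet <- stats::rnorm(8)
  wt <- matrix(stats::rnorm(6 * 8), 6, 8)
  ref_ln <- function(M) {
    mu <- rowMeans(M); xc <- M - mu; v <- rowMeans(xc^2)
    sweep(sweep(xc / sqrt(v + 1e-5), 2, gam, `*`), 2, bet, `+`)
  }
  g <- grad_of(function(xn) ns$ag_sum(ns$ag_mul(
    ns$ag_layernorm(xn, gam, bet), wt)), X)
  gn <- num_grad(function(xx) sum(ref_ln(matrix(xx, 6, 8)) * wt), X)
  expect_lt(max(abs(g - gn)), 1e-6)

  ref_gn <- function(M, groups = 2) {
    C <- ncol(M); cg <- C / groups; out <- M
    for (g0 in seq_len(groups)) {
      idx <- ((g0 - 1) * cg + 1):(g0 * cg)
      blk <- M[, idx]; mu <- mean(blk); v <- mean((blk - mu)^2)
      out[, idx] <- (blk - mu) / sqrt(v + 1e-5)
    }
    sweep(sweep(out, 2, gam, `*`), 2, bet, `+`)
  }
  g2 <- grad_of(function(xn) ns$ag_sum(ns$ag_mul(
    ns$ag_groupnorm(xn, 2, gam, bet), wt)), X)
  gn2 <- num_grad(function(xx) sum(ref_gn(matrix(xx, 6, 8)) * wt), X)
  expect_lt(max(abs(g2 - gn2)), 1e-6)

  A <- matrix(stats::rnorm(5 * 4), 5, 4)
  wt2 <- matrix(stats::rnorm(5 * 4), 5, 4)
  ref_sm <- function(M) t(apply(M, 1, function(r) {
    e <- exp(r - max(r)); e / sum(e)
  }))
  g3 <- grad_of(function(xn) ns$ag_sum(ns$ag_mul(
    ns$ag_softmax_rows(xn), wt2)), A)
  gn3 <- num_grad(function(xx) sum(ref_sm(matrix(xx, 5, 4)) * wt2), A)
  expect_lt(max(abs(g3 - gn3)), 1e-6)
})

test_that("compound loss gradient from logits matches finite differences", {
  L <- matrix(stats::rnorm(12 * 3), 12, 3)
  y <- m3seg::to_onehot(matrix(sample(0:2, 12, TRUE), 4, 3), 3)
  ns$ag_tape_start()
  Ln <- ns$ag_leaf(L, "L")
  tot <- ns$ag_total_loss(Ln, y)
  ns$ag_backward(tot$total)
  g <- Ln$g
  ns$ag_tape_stop()
  ref <- function(xx) {
    M <- matrix(xx, 12, 3)
    p <- t(apply(M, 1, function(r) { e <- exp(r - max(r)); e / sum(e) }))
    ce <- -sum(y * log(p)) / 12
    dice <- 1 - mean(((2 * colSums(p * y) + 1e-5) /
                        (colSums(p) + colSums(y) + 1e-5))[2:3])
    0.5 * ce + 0.5 * dice
  }
  expect_lt(max(abs(g - matrix(num_grad(ref, L), 12, 3))), 1e-6)
})

test_that("bilinear upsampling is linear and gradient-exact", {
  x <- rand_grid(3, 3, 2, seed = 7)
  wt <- rand_grid(6, 6, 2, seed = 8)
  g <- grad_of(function(xn) ns$ag_sum(ns$ag_mul(ns$ag_upsample2(xn), wt)), x)
  fn <- function(xx) sum(ns$cpp_upsample2(array(xx, dim(x))) * wt)
  expect_lt(max(abs(g - num_grad(fn, x))), 1e-6)
  # linearity
  y1 <- ns$cpp_upsample2(x)
  y2 <- ns$cpp_upsample2(2 * x)
  expect_equal(y2, 2 * y1)
})
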