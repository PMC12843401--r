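# Decoder: multi-scale selective attention (MSSA) with linear-complexity
# Performer attention, and the merge-augment-upsample stage.

# Positive softmax-kernel random feature map. Rows are scaled by d^(-1/4) so
# that phi(Q) phi(K)' approximates exp(Q K' / sqrt(d)) in expectation; a
# shared max-subtraction keeps the exponentials finite and cancels in the
# row normalization. The exponent is proj - ||x||^2/2 per row.
performer_exponent <- function(tokens, W) {
  sc <- ncol(vof(tokens))^(-0.25)
  xh <- ag_scale(tokens, sc)
  proj <- ag_matmul(xh, ag_t(W))
  sq <- ag_scale(ag_rowsums(ag_mul(xh, xh)), 0.5)
  ag_sub(proj, replicate_cols(sq, ncol(vof(proj))))
}

# broadcast a length-N vector across m columns (differentiable)
replicate_cols <- function(v, m) {
  vv <- vof(v)
  emit(matrix(vv, length(vv), m), list(v), function(g) list(rowSums(g)))
}

# Kernel-approximated softmax attention (Performer / FAVOR):
# out = D^{-1} phi(Q) (phi(K)' V),  D = diag(phi(Q) phi(K)' 1).
ag_performer <- function(Q, K, V, W, eps = 1e-12) {
  m <- nrow(vof(W))
  eq <- performer_exponent(Q, W)
  ek <- performer_exponent(K, W)
  shift <- max(max(vof(eq)), max(vof(ek)))
  phiQ <- ag_scale(ag_exp(ag_sub(eq, shift)), 1 / sqrt(m))
  phiK <- ag_scale(ag_exp(ag_sub(ek, shift)), 1 / sqrt(m))
  kv <- ag_matmul(ag_t(phiK), V)                     # m x d
  num <- ag_matmul(phiQ, kv)                         # N x d
  ksum <- ag_colsums(phiK)                           # m
  den <- ag_matmul(phiQ, ag_reshape(ksum, c(m, 1L))) # N x 1
  denv <- ag_add(ag_reshape(den, nrow(vof(num))), eps)
  ag_scale_rows(num, ag_div(1, denv))
}

#' Linear-complexity kernel-approximated attention
#'
#' Approximates softmax attention `Softmax(Q K' / sqrt(d)) V` with the
#' positive random-feature map of the Performer:
#' `out = D^-1 (phi(Q) (phi(K)' V))`, `D = diag(phi(Q) phi(K)' 1)`, at cost
#' `O(N m d)` without ever materializing the `N x N` attention matrix. The
#' implied attention weights are non-negative and row-normalized by
#' construction.
#'
#' @param Q,K,V `N x d` matrices.
#' @param m random feature count (ignored when `features` is given).
#' @param features optional precomputed `m x d` Gaussian projection matrix;
#'   supply this to share one draw across calls.
#' @param seed RNG seed for the feature draw when `features` is `NULL`.
#' @return `N x d` output matrix.
#' @examples
#' Q <- matrix(rnorm(32), 8, 4)
#' out <- performer_attention(Q, Q, Q, m = 64, seed = 1)
#' @export
performer_attention <- function(Q, K, V, m = 256L, features = NULL, seed = 1L) {
  stopifnot(ncol(Q) == ncol(K), nrow(K) == nrow(V))
  if (is.null(features)) {
    if (m < 1) stop("m must be at least 1")
    features <- draw_performer_features(ncol(Q), m, seed)
  }
  out <- ag_performer(Q, K, V, features)
  if (any(!is.finite(vof(out))))
    stop("performer_attention: degenerate feature map (non-finite output)")
  out
}

#' @rdname performer_attention
#' @param d head dimension.
#' @export
draw_performer_features <- function(d, m, seed = 1L) {
  withr::with_seed(seed, matrix(stats::rnorm(m * d), m, d))
}

# ---- MSSA ------------------------------------------------------------------

# Multi-scale selective attention: four depthwise-separable branches
# (kernels 3/5/7/9, ReLU then SE each), concatenated and fused to C channels,
# refined by Performer attention over the spatial tokens, recombined with the
# fused features and projected back to C channels; residual to the input.
init_mssa <- function(b, name, C, m_features = 64L, feature_seed = 1L) {
  ks <- c(3L, 5L, 7L, 9L)
  branches <- lapply(seq_along(ks), function(i) {
    k <- ks[i]
    dw <- layer_conv(b, sprintf("%s.br%d.dw", name, i), C, C, k, groups = C,
                     bias = FALSE)
    pw <- layer_conv(b, sprintf("%s.br%d.pw", name, i), C, C, 1L, pad = 0L)
    se <- layer_se(b, sprintf("%s.br%d.se", name, i), C)
    list(dw = dw, pw = pw, se = se)
  })
  fuse <- layer_conv(b, paste0(name, ".fuse"), 4L * C, C, 1L, pad = 0L)
  wq <- layer_linear(b, paste0(name, ".q"), C, C)
  wk <- layer_linear(b, paste0(name, ".k"), C, C)
  wv <- layer_linear(b, paste0(name, ".v"), C, C)
  recomb <- layer_conv(b, paste0(name, ".recomb"), 2L * C, C, 1L, pad = 0L)
  Wf <- draw_performer_features(C, m_features, feature_seed)
  function(P, x) {
    d <- dim(vof(x))
    if (d[1] < 1 || d[2] < 1) stop("MSSA requires a nonempty spatial extent")
    bouts <- lapply(branches, function(br)
      br$se(P, ag_relu(br$pw(P, br$dw(P, x)))))
    fms <- ag_concat_c(bouts)
    fin <- fuse(P, fms)
    tk <- ag_grid_to_tokens(fin)
    attn <- ag_performer(wq(P, tk), wk(P, tk), wv(P, tk), Wf)
    ag_grid <- ag_tokens_to_grid(attn, d[1], d[2])
    y <- recomb(P, ag_concat_c(list(ag_grid, fin)))
    ag_add(x, y)
  }
}

#' Multi-scale selective attention (MSSA)
#'
#' Functional wrapper around a freshly initialized (or supplied) MSSA
#' decoder-refinement module. Output shape equals input shape; the random
#' features of the internal linear attention are drawn once at construction,
#' so repeated forward passes are deterministic.
#'
#' @param x `(H, W, C)` feature grid.
#' @param module optional module from [new_mssa()].
#' @param m random feature count of the linear attention.
#' @param seed RNG seed when `module` is `NULL`.
#' @return refined grid, same shape as `x`.
#' @export
mssa <- function(x, module = NULL, m = 64L, seed = 1L) {
  if (is.null(module)) module <- new_mssa(dim(x)[3], m = m, seed = seed)
  module$forward(x)
}

#' @rdname mssa
#' @param channels input channel count C.
#' @export
new_mssa <- function(channels, m = 64L, seed = 1L) {
  b <- new_builder()
  fwd <- withr::with_seed(seed,
    init_mssa(b, "mssa", channels, m_features = m, feature_seed = seed))
  list(params = b$params, names = b$names, fwd = fwd,
       forward = function(x, train = FALSE) fwd(b$params, x))
}

# ---- decoder stage ---------------------------------------------------------

# Merge-augment-upsample: 2x bilinear upsample of the deep features,
# concatenation with the MKGAG-gated skip (when present), 3x3 fusion
# convolution + BN + ReLU, then MSSA refinement. Stages without a skip are a
# pure upsample + convolution path.
init_decoder_stage <- function(b, name, cin, cskip, cout, m_features,
                               feature_seed) {
  has_skip <- cskip > 0L
  gate <- if (has_skip) init_mkgag(b, paste0(name, ".gate"), cskip) else NULL
  fuse <- layer_conv(b, paste0(name, ".fuse"), cin + cskip, cout, 3L)
  bn <- layer_instnorm(b, paste0(name, ".bn"), cout)
  refine <- if (has_skip)
    init_mssa(b, paste0(name, ".mssa"), cout, m_features, feature_seed)
  else NULL
  function(P, deep, skip = NULL, train = FALSE) {
    up <- ag_upsample2(deep)
    if (has_skip) {
      du <- dim(vof(up))
      if (is.null(skip)) stop("this decoder stage requires a skip feature")
      ds <- dim(vof(skip))
      if (du[1] != ds[1] || du[2] != ds[2])
        stop(sprintf("skip feature must be %dx%d, got %s", du[1], du[2],
                     paste(ds[1:2], collapse = "x")))
      g <- gate(P, skip, train = train)
      up <- ag_concat_c(list(up, g))
    }
    y <- ag_relu(bn(P, fuse(P, up), train = train))
    if (has_skip) y <- refine(P, y)
    y
  }
}

# 1x1 convolution to class logits
init_head <- function(b, name, cin, classes) {
  layer_conv(b, name, cin, classes, 1L, pad = 0L)
}
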