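# Multi-kernel group attention gate (MKGAG) on skip connections.
#
# Three independent 3x3 group-convolution + batch-norm branches are summed,
# passed through ReLU6, compressed to a single channel by a 1x1 convolution
# and squashed by a sigmoid; the resulting (0,1) spatial map re-weights every
# input channel identically: Y = X (*) A.

init_mkgag <- function(b, name, C, groups = NULL) {
  if (is.null(groups)) groups <- gcd(4L, C)
  if (C %% groups != 0)
    stop(sprintf("MKGAG channels (%d) not divisible by group count (%d)",
                 C, groups))
  convs <- list(); bns <- list()
  for (k in 1:3) {
    convs[[k]] <- layer_conv(b, sprintf("%s.br%d.conv", name, k), C, C, 3L,
                             groups = groups, bias = FALSE)
    bns[[k]] <- layer_bn(b, sprintf("%s.br%d.bn", name, k), C)
  }
  squeeze <- layer_conv(b, paste0(name, ".squeeze"), C, 1L, 1L, pad = 0L)
  function(P, x, train = FALSE, return_gate = FALSE) {
    hs <- lapply(1:3, function(k) bns[[k]](P, convs[[k]](P, x), train = train))
    s <- ag_add(ag_add(hs[[1]], hs[[2]]), hs[[3]])
    A <- ag_sigmoid(squeeze(P, ag_relu6(s)))
    d <- dim(vof(x))
    y <- ag_mul_cmap(x, ag_reshape(A, c(d[1], d[2])))
    if (return_gate) attr(y, "gate") <- vof(A)
    y
  }
}

#' Multi-kernel group attention gate (MKGAG)
#'
#' Applies a freshly initialized (or supplied) skip-connection gate to a
#' feature grid. The attention map has a single channel with entries strictly
#' in (0, 1), so all channels are modulated identically and the output never
#' exceeds the input in absolute value.
#'
#' @param x `(H, W, C)` feature grid.
#' @param module optional module from [new_mkgag()].
#' @param seed RNG seed when `module` is `NULL`.
#' @param train use batch (TRUE) or running (FALSE) normalization statistics.
#' @param return_gate attach the `(H, W, 1)` attention map as attribute
#'   `"gate"`.
#' @return gated grid, same shape as `x`.
#' @export
mkgag <- function(x, module = NULL, seed = 1L, train = FALSE,
                  return_gate = FALSE) {
  if (is.null(module)) module <- new_mkgag(dim(x)[3], seed = seed)
  module$forward(x, train = train, return_gate = return_gate)
}

#' @rdname mkgag
#' @param channels input channel count C.
#' @param groups group count of the 3x3 group convolutions
#'   (default `gcd(4, channels)`).
#' @export
new_mkgag <- function(channels, groups = NULL, seed = 1L) {
  b <- new_builder()
  fwd <- withr::with_seed(seed, init_mkgag(b, "mkgag", channels, groups))
  list(params = b$params, buffers = b$buffers, names = b$names, fwd = fwd,
       forward = function(x, train = FALSE, return_gate = FALSE)
         fwd(b$params, x, train = train, return_gate = return_gate))
}
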