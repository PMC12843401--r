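#' Normalized Manhattan distance matrix of a token grid
#'
#' Tokens are enumerated row-major from the top-left with 0-based
#' coordinates; for tokens i, j at (x_i, y_i), (x_j, y_j) the entry is
#' `(|x_i - x_j| + |y_i - y_j|) / (Hf + Wf)`. The matrix is symmetric with a
#' zero diagonal and entries strictly below 1; subtracted (scaled by a
#' learnable per-head factor) from attention logits it acts as a soft
#' locality prior.
#'
#' @param Hf,Wf token grid height and width.
#' @return an `N x N` matrix, `N = Hf * Wf`.
#' @examples
#' manhattan_bias(2, 2)
#' @export
manhattan_bias <- function(Hf, Wf) {
  stopifnot(Hf >= 1, Wf >= 1)
  r <- rep(seq_len(Hf) - 1L, each = Wf)
  c <- rep(seq_len(Wf) - 1L, times = Hf)
  (abs(outer(r, r, `-`)) + abs(outer(c, c, `-`))) / (Hf + Wf)
}

#' Flatten a feature grid into a token sequence
#'
#' Converts an `(Hf, Wf, C)` feature grid into an `N x D` token matrix
#' (`N = Hf * Wf`, row-major token order), optionally applying a linear
#' projection `C -> D`. The inverse operation is [tokens_to_grid()].
#'
#' @param grid array `(Hf, Wf, C)`.
#' @param proj optional `C x D` projection matrix (`NULL` keeps `D = C`).
#' @return `N x D` matrix with attribute `grid_shape = c(Hf, Wf)`.
#' @export
hybrid_embed <- function(grid, proj = NULL) {
  d <- dim(grid)
  if (length(d) != 3) stop("grid must be an (H, W, C) array")
  tk <- ag_grid_to_tokens(grid)
  if (!is.null(proj)) {
    if (nrow(proj) != d[3])
      stop(sprintf("projection expects %d input channels, grid has %d",
                   nrow(proj), d[3]))
    tk <- tk %*% proj
  }
  attr(tk, "grid_shape") <- c(d[1], d[2])
  tk
}

#' @rdname hybrid_embed
#' @param tokens `N x D` token matrix.
#' @param Hf,Wf grid shape (defaults to the `grid_shape` attribute).
#' @export
tokens_to_grid <- function(tokens, Hf = NULL, Wf = NULL) {
  gs <- attr(tokens, "grid_shape")
  if (is.null(Hf)) Hf <- gs[1]
  if (is.null(Wf)) Wf <- gs[2]
  if (Hf * Wf != nrow(tokens))
    stop("grid shape does not match the token count")
  ag_tokens_to_grid(unname_attr(tokens), Hf, Wf)
}

unname_attr <- function(x) {
  attr(x, "grid_shape") <- NULL
  x
}

# ---- ME-MSA ----------------------------------------------------------------

# Multi-head self-attention with a per-head learnable Manhattan-distance
# penalty on the logits: Softmax(Q K' / sqrt(d_k) - lambda_h * D) V.
# When every lambda is exactly zero the bias term is short-circuited and the
# computation is the vanilla attention path.
init_memsa <- function(b, name, D, heads, lambda_init = 1.0) {
  wq <- layer_linear(b, paste0(name, ".q"), D, D)
  wk <- layer_linear(b, paste0(name, ".k"), D, D)
  wv <- layer_linear(b, paste0(name, ".v"), D, D)
  wo <- layer_linear(b, paste0(name, ".o"), D, D)
  add_param(b, paste0(name, ".lambda"), rep(lambda_init, heads))
  ln <- paste0(name, ".lambda")
  dk <- D %/% heads
  function(P, x, Dmat, return_attn = FALSE) {
    Q <- wq(P, x); K <- wk(P, x); V <- wv(P, x)
    lam <- P[[ln]]
    lamv <- vof(lam)
    use_bias <- !(all(lamv == 0) && !is_node(lam))
    outs <- vector("list", heads)
    attns <- if (return_attn) vector("list", heads) else NULL
    for (h in seq_len(heads)) {
      idx <- ((h - 1) * dk + 1):(h * dk)
      Qh <- ag_cols(Q, idx); Kh <- ag_cols(K, idx); Vh <- ag_cols(V, idx)
      logits <- ag_scale(ag_matmul(Qh, ag_t(Kh)), 1 / sqrt(dk))
      if (use_bias) {
        lh <- ag_subset(lam, h)
        logits <- ag_sub(logits, ag_mul(lh, Dmat))
      }
      A <- ag_softmax_rows(logits)
      if (return_attn) attns[[h]] <- vof(A)
      outs[[h]] <- ag_matmul(A, Vh)
    }
    out <- Reduce(function(a, z) cbind2_ag(a, z), outs)
    out <- wo(P, out)
    if (return_attn) attr(out, "attn") <- attns
    out
  }
}

# column-bind two token matrices (differentiable)
cbind2_ag <- function(a, b) {
  av <- vof(a); bv <- vof(b)
  na <- ncol(av)
  emit(cbind(av, bv), list(a, b), function(g) {
    list(g[, seq_len(na), drop = FALSE], g[, -seq_len(na), drop = FALSE])
  })
}

#' Manhattan-biased multi-head self-attention over a token sequence
#'
#' Standalone functional form of the ME-MSA operation: per head,
#' `Softmax(Q K' / sqrt(d_k) - lambda_h * D) V`, heads concatenated and
#' linearly projected. With `lambda = 0` this is exactly vanilla multi-head
#' softmax attention.
#'
#' @param tokens `N x D` matrix.
#' @param grid_shape `c(Hf, Wf)` with `Hf * Wf = N` (used to build the
#'   distance matrix; ignored if `bias` is supplied).
#' @param num_heads head count (must divide D).
#' @param lambda per-head bias strength; scalar values are recycled.
#' @param weights attention weights as produced by
#'   [init_attention_weights()]; drawn from `seed` when `NULL`.
#' @param bias optional precomputed `N x N` distance matrix.
#' @param seed RNG seed for weight initialization when `weights` is `NULL`.
#' @param return_attn if `TRUE`, attach the per-head attention matrices
#'   (each row-stochastic) as attribute `"attn"`.
#' @return `N x D` output matrix.
#' @export
me_msa <- function(tokens, grid_shape, num_heads = 4L, lambda = 1.0,
                   weights = NULL, bias = NULL, seed = 1L,
                   return_attn = FALSE) {
  D <- ncol(tokens)
  if (D %% num_heads != 0) stop("num_heads must divide the token dimension")
  if (is.null(weights))
    weights <- init_attention_weights(D, num_heads, seed = seed,
                                      lambda_init = lambda[1])
  P <- weights$params
  lam <- rep_len(lambda, num_heads)
  assign(paste0(weights$name, ".lambda"), lam, envir = P)
  if (is.null(bias)) {
    if (nrow(tokens) != prod(grid_shape))
      stop("grid_shape does not match the token count")
    bias <- manhattan_bias(grid_shape[1], grid_shape[2])
  }
  if (nrow(bias) != nrow(tokens)) stop("bias side must equal the token count")
  weights$fwd(P, tokens, bias, return_attn = return_attn)
}

#' @rdname me_msa
#' @param dim token dimension D.
#' @param lambda_init initial per-head bias strength.
#' @export
init_attention_weights <- function(dim, num_heads, seed = 1L, lambda_init = 1.0) {
  b <- new_builder()
  fwd <- withr::with_seed(seed,
    init_memsa(b, "attn", dim, num_heads, lambda_init = lambda_init))
  list(params = b$params, names = b$names, fwd = fwd, name = "attn",
       dim = dim, num_heads = num_heads)
}

# ---- MSGA ------------------------------------------------------------------

# Multi-scale gate attention. The input grid is split into G channel
# subgroups; each subgroup is modulated by (i) a depthwise 3x3 path gated by
# a coordinate-attention style spatial map built from directional avg/max
# pooling, and (ii) a cross-spatial interaction producing a final sigmoid
# re-weighting of the raw subgroup.
init_msga <- function(b, name, C, G) {
  if (C %% G != 0)
    stop(sprintf("MSGA channels (%d) not divisible by groups (%d)", C, G))
  c_g <- C %/% G
  gn_groups <- gcd(G, c_g)
  dws <- list(); pools <- list(); gns <- list()
  for (g in seq_len(G)) {
    dws[[g]] <- layer_conv(b, sprintf("%s.g%d.dw", name, g), c_g, c_g, 3L,
                           groups = c_g)
    # shared 1x1 reduction of the concatenated avg/max strips (both axes)
    pools[[g]] <- layer_linear(b, sprintf("%s.g%d.pool", name, g), 2L * c_g, 1L)
    add_param(b, sprintf("%s.g%d.gn.gamma", name, g), rep(1, c_g))
    add_param(b, sprintf("%s.g%d.gn.beta", name, g), numeric(c_g))
  }
  function(P, x) {
    d <- dim(vof(x))
    H <- d[1]; W <- d[2]
    outs <- vector("list", G)
    for (g in seq_len(G)) {
      idx0 <- (g - 1) * c_g
      Xg <- ag_slice_c(x, idx0 + 1, idx0 + c_g)
      Fdw <- dws[[g]](P, Xg)
      # directional pooling of the raw subgroup (coordinate attention style)
      hstrip <- cbind2_ag(ag_pool_w_avg(Xg), ag_pool_w_max(Xg))  # H x 2c
      wstrip <- cbind2_ag(ag_pool_h_avg(Xg), ag_pool_h_max(Xg))  # W x 2c
      sh <- pools[[g]](P, hstrip)                                # H x 1
      sw <- pools[[g]](P, wstrip)                                # W x 1
      Msp <- ag_sigmoid(ag_outer_add(ag_reshape(sh, H), ag_reshape(sw, W)))
      Fg <- ag_mul_cmap(Fdw, Msp)
      # cross-spatial interaction
      Tg <- ag_grid_to_tokens(Fg)                                # N x c
      Gn <- ag_groupnorm(Tg, gn_groups,
                         P[[sprintf("%s.g%d.gn.gamma", name, g)]],
                         P[[sprintf("%s.g%d.gn.beta", name, g)]])
      d1 <- ag_softmax_rows(ag_reshape(ag_scale(ag_colsums(Tg), 1 / (H * W)),
                                       c(1L, c_g)))
      d2 <- ag_softmax_rows(ag_reshape(ag_scale(ag_colsums(Gn), 1 / (H * W)),
                                       c(1L, c_g)))
      map1 <- ag_matmul(d1, ag_t(Gn))                            # 1 x N
      map2 <- ag_matmul(d2, ag_t(Tg))                            # 1 x N
      fused <- ag_sigmoid(ag_add(map1, map2))
      fmap <- ag_tokens_to_grid(ag_t(fused), H, W)               # H x W x 1
      outs[[g]] <- ag_mul_cmap(Xg, ag_reshape(fmap, c(H, W)))
    }
    ag_concat_c(outs)
  }
}

gcd <- function(a, b) if (b == 0) a else gcd(b, a %% b)

#' Multi-scale gate attention (MSGA)
#'
#' Functional wrapper around a freshly initialized (or supplied) MSGA module;
#' primarily useful for inspection and testing. Inside the network the module
#' is applied to the token grid at the start of every encoder block. The
#' final gate is a sigmoid, so the output can attenuate but never amplify the
#' input: `|Y| <= |X|` elementwise.
#'
#' @param x `(H, W, C)` feature grid.
#' @param groups channel subgroup count G (must divide C).
#' @param module optional module from [new_msga()].
#' @param seed RNG seed when `module` is `NULL`.
#' @return gated grid, same shape as `x`.
#' @export
msga <- function(x, groups = 4L, module = NULL, seed = 1L) {
  if (is.null(module)) module <- new_msga(dim(x)[3], groups, seed = seed)
  module$forward(x)
}

#' @rdname msga
#' @param channels input channel count C.
#' @export
new_msga <- function(channels, groups = 4L, seed = 1L) {
  b <- new_builder()
  fwd <- withr::with_seed(seed, init_msga(b, "msga", channels, groups))
  mod <- list(params = b$params, names = b$names,
              forward = function(x, train = FALSE) fwd(b$params, x))
  mod$fwd <- fwd
  mod
}

# ---- encoder block ---------------------------------------------------------

# One encoder layer: tokens -> grid -> MSGA -> tokens -> LN -> ME-MSA,
# residual from the block input; then LN -> MLP with a second residual.
init_encoder_block <- function(b, name, cfg, grid_hw) {
  D <- cfg$hidden_dim
  msga_f <- init_msga(b, paste0(name, ".msga"), D, cfg$msga_groups)
  ln1 <- layer_layernorm(b, paste0(name, ".ln1"), D)
  attn <- init_memsa(b, paste0(name, ".attn"), D, cfg$num_heads,
                     lambda_init = cfg$lambda_init)
  ln2 <- layer_layernorm(b, paste0(name, ".ln2"), D)
  fc1 <- layer_linear(b, paste0(name, ".mlp1"), D, cfg$mlp_dim)
  fc2 <- layer_linear(b, paste0(name, ".mlp2"), cfg$mlp_dim, D)
  Dmat <- manhattan_bias(grid_hw[1], grid_hw[2])
  function(P, x) {
    g <- ag_tokens_to_grid(x, grid_hw[1], grid_hw[2])
    m <- ag_grid_to_tokens(msga_f(P, g))
    y1 <- ag_add(x, attn(P, ln1(P, m), Dmat))
    h <- fc2(P, ag_gelu(fc1(P, ln2(P, y1))))
    ag_add(y1, h)
  }
}
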