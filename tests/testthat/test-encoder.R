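ns <- asNamespace("m3seg")

test_that("manhattan bias has the stated geometry", {
  D2 <- manhattan_bias(2, 2)
  expect_equal(D2[1, 4], 0.5)  # corners (0,0) -> (1,1): 2/4
  expect_equal(diag(D2), rep(0, 4))
  expect_equal(D2, t(D2))
  D14 <- manhattan_bias(14, 14)
  expect_equal(max(D14), 26 / 28)
  expect_true(all(D14 >= 0 & D14 < 1))
})

test_that("manhattan bias is translation-consistent", {
  Hf <- 5; Wf <- 7
  D <- manhattan_bias(Hf, Wf)
  tok <- function(r, c) r * Wf + c + 1  # 0-based coords, row-major
  withr::with_seed(42, {
    for (k in 1:50) {
      a <- c(sample(0:(Hf - 2), 1), sample(0:(Wf - 2), 1))
      b <- c(sample(0:(Hf - 2), 1), sample(0:(Wf - 2), 1))
      expect_equal(D[tok(a[1], a[2]), tok(b[1], b[2])],
                   D[tok(a[1] + 1, a[2] + 1), tok(b[1] + 1, b[2] + 1)])
    }
  })
})

test_that("hybrid embedding flattens and round-trips losslessly", {
  g <- rand_grid(8, 8, 64, seed = 11)
  tk <- hybrid_embed(g)
  expect_equal(dim(tk), c(64L, 64L))
  expect_equal(attr(tk, "grid_shape"), c(8, 8))
  expect_equal(tokens_to_grid(tk), g)
  # row-major enumeration: token 2 is grid position (row 1, col 2)
  expect_equal(unname(tk[2, ]), g[1, 2, ])
  # with projection
  proj <- matrix(stats::rnorm(64 * 16), 64, 16)
  expect_equal(dim(hybrid_embed(g, proj)), c(64L, 16L))
  expect_error(hybrid_embed(g, matrix(0, 32, 16)), "channels")
  big <- rand_grid(14, 14, 768, seed = 12)
  expect_equal(dim(hybrid_embed(big)), c(196L, 768L))
})

test_that("ME-MSA with lambda = 0 equals vanilla multi-head attention", {
  withr::with_seed(5, {
    N <- 196; D <- 768; heads <- 12
    X <- matrix(stats::rnorm(N * D, 0, 0.5), N, D)
  })
  w <- init_attention_weights(D, heads, seed = 9)
  out <- me_msa(X, grid_shape = c(14, 14), num_heads = heads, lambda = 0,
                weights = w)
  P <- w$params
  ref <- ref_multihead_attention(
    X,
    get("attn.q.w", P), get("attn.q.b", P),
    get("attn.k.w", P), get("attn.k.b", P),
    get("attn.v.w", P), get("attn.v.b", P),
    get("attn.o.w", P), get("attn.o.b", P), heads)
  expect_lt(max(abs(out - ref)), 1e-6)
})

test_that("attention weights are row-stochastic and N = 1 passes through V", {
  X <- matrix(stats::rnorm(16 * 8), 16, 8)
  w <- init_attention_weights(8, 2, seed = 3)
  out <- me_msa(X, grid_shape = c(4, 4), num_heads = 2, lambda = 1,
                weights = w, return_attn = TRUE)
  for (A in attr(out, "attn")) {
    expect_true(all(abs(rowSums(A) - 1) < 1e-6))
    expect_true(all(A >= 0))
  }
  # single token: softmax of a scalar is 1, output = W_o(W_v x)
  x1 <- matrix(stats::rnorm(8), 1, 8)
  w1 <- init_attention_weights(8, 2, seed = 4)
  P <- w1$params
  out1 <- me_msa(x1, grid_shape = c(1, 1), num_heads = 2, lambda = 1,
                 weights = w1)
  v1 <- sweep(x1 %*% get("attn.v.w", P), 2, get("attn.v.b", P), `+`)
  ref1 <- sweep(v1 %*% get("attn.o.w", P), 2, get("attn.o.b", P), `+`)
  expect_equal(out1, ref1, tolerance = 1e-12)
})

test_that("a large lambda concentrates attention on the self token", {
  withr::with_seed(8, {
    N <- 25; D <- 16
    X <- matrix(stats::rnorm(N * D, 0, 0.1), N, D)
  })
  w <- init_attention_weights(D, 1, seed = 2)
  out <- me_msa(X, grid_shape = c(5, 5), num_heads = 1, lambda = 1e4,
                weights = w, return_attn = TRUE)
  A <- attr(out, "attn")[[1]]
  expect_true(all(diag(A) > 0.999))
})

test_that("MSGA gates: zero input maps to zero, and it never amplifies", {
  mod <- new_msga(8, groups = 2, seed = 1)
  z <- array(0, c(4, 4, 8))
  expect_equal(mod$forward(z), z)
  withr::with_seed(21, {
    for (k in 1:20) {
      x <- array(stats::rnorm(6 * 6 * 8), c(6, 6, 8))
      y <- mod$forward(x)
      expect_equal(dim(y), dim(x))
      expect_true(all(abs(y) <= abs(x) + 1e-12))
    }
  })
  expect_error(new_msga(8, groups = 3), "divisible")
})

test_that("MSGA with forced weights matches a hand-computed gate", {
  # one group, 2 channels, 3x3 grid; depthwise kernel = identity (center 1),
  # pooling projection zeroed with bias 0 -> Msp = sigmoid(0) = 0.5
  mod <- new_msga(2, groups = 1, seed = 1)
  P <- mod$params
  wdw <- array(0, c(3, 3, 1, 2)); wdw[2, 2, 1, ] <- 1
  assign("msga.g1.dw.w", wdw, P)
  assign("msga.g1.dw.b", c(0, 0), P)
  assign("msga.g1.pool.w", matrix(0, 4, 1), P)
  assign("msga.g1.pool.b", 0, P)
  x <- rand_grid(3, 3, 2, seed = 33)
  y <- mod$forward(x)
  # reproduce the cross-spatial arithmetic by hand
  Fg <- x * 0.5                       # identity depthwise, gate 0.5
  tk <- t(apply(Fg, 3, function(s) as.vector(t(s))))  # 2 x 9 (c x N)
  gam <- get("msga.g1.gn.gamma", P); bet <- get("msga.g1.gn.beta", P)
  mu <- mean(tk); v <- mean((tk - mu)^2)
  gn <- (tk - mu) / sqrt(v + 1e-5) * gam + bet        # single GN group
  sm <- function(z) { e <- exp(z - max(z)); e / sum(e) }
  d1 <- sm(rowMeans(tk)); d2 <- sm(rowMeans(gn))
  fused <- 1 / (1 + exp(-(d1 %*% gn + d2 %*% tk)))
  map <- t(matrix(fused, 3, 3))       # token order back to (row, col)
  expect_equal(y, x * array(rep(map, 2), c(3, 3, 2)), tolerance = 1e-10)
})

test_that("encoder blocks preserve sequence shape through a deep stack", {
  cfg <- model_config("tiny")
  b <- ns$new_builder()
  blocks <- withr::with_seed(1, lapply(1:3, function(i)
    ns$init_encoder_block(b, paste0("e", i), cfg, c(4, 4))))
  X <- matrix(stats::rnorm(16 * 64), 16, 64)
  h <- X
  for (blk in blocks) h <- blk(b$params, h)
  expect_equal(dim(h), dim(X))
  expect_true(all(is.finite(h)))
})

test_that("both residual paths are wired from the block input", {
  # zeroing the output projections of the attention and the MLP must reduce
  # the block to the identity: Y = X + 0 + 0
  cfg <- model_config("tiny")
  b <- ns$new_builder()
  blk <- withr::with_seed(2, ns$init_encoder_block(b, "e1", cfg, c(4, 4)))
  P <- b$params
  assign("e1.mlp2.w", matrix(0, cfg$mlp_dim, cfg$hidden_dim), P)
  assign("e1.mlp2.b", numeric(cfg$hidden_dim), P)
  assign("e1.attn.o.w", matrix(0, cfg$hidden_dim, cfg$hidden_dim), P)
  assign("e1.attn.o.b", numeric(cfg$hidden_dim), P)
  X <- matrix(stats::rnorm(16 * 64), 16, 64)
  expect_equal(blk(P, X), X, tolerance = 1e-12)
})
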