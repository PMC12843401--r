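# Shared fixtures and independent reference implementations used as oracles.

# Plain vanilla multi-head softmax attention, written directly from the
# definition (independent of the package's attention code path).
ref_multihead_attention <- function(X, Wq, bq, Wk, bk, Wv, bv, Wo, bo, heads) {
  D <- ncol(X)
  dk <- D / heads
  Q <- sweep(X %*% Wq, 2, bq, `+`)
  K <- sweep(X %*% Wk, 2, bk, `+`)
  V <- sweep(X %*% Wv, 2, bv, `+`)
  outs <- lapply(seq_len(heads), function(h) {
    idx <- ((h - 1) * dk + 1):(h * dk)
    L <- Q[, idx, drop = FALSE] %*% t(K[, idx, drop = FALSE]) / sqrt(dk)
    A <- t(apply(L, 1, function(r) { e <- exp(r - max(r)); e / sum(e) }))
    A %*% V[, idx, drop = FALSE]
  })
  sweep(do.call(cbind, outs) %*% Wo, 2, bo, `+`)
}

# Exact softmax attention (single head), the oracle for the kernel
# approximation.
ref_softmax_attention <- function(Q, K, V) {
  L <- Q %*% t(K) / sqrt(ncol(Q))
  A <- t(apply(L, 1, function(r) { e <- exp(r - max(r)); e / sum(e) }))
  A %*% V
}

# Exhaustive pairwise-distance HD95 oracle: boundary voxels by definition
# (foreground with a background face neighbor, outside counts as
# background), all pairwise distances by double loop.
ref_hd95 <- function(P, G, spacing = c(1, 1), q = 0.95) {
  bpts <- function(M) {
    d <- dim(M)
    out <- NULL
    idx <- which(M != 0, arr.ind = TRUE)
    for (r in seq_len(nrow(idx))) {
      co <- idx[r, ]
      on_bd <- FALSE
      for (ax in seq_along(d)) {
        for (dlt in c(-1L, 1L)) {
          nb <- co
          nb[ax] <- nb[ax] + dlt
          if (nb[ax] < 1 || nb[ax] > d[ax] ||
              M[matrix(nb, 1)] == 0) { on_bd <- TRUE; break }
        }
        if (on_bd) break
      }
      if (on_bd) out <- rbind(out, co)
    }
    out
  }
  A <- bpts(P); B <- bpts(G)
  dists <- function(U, W) {
    sapply(seq_len(nrow(U)), function(i) {
      min(sapply(seq_len(nrow(W)), function(j)
        sqrt(sum(((U[i, ] - W[j, ]) * spacing)^2))))
    })
  }
  stats::quantile(c(dists(A, B), dists(B, A)), q, names = FALSE)
}

# finite-difference gradient
num_grad <- function(f, x, eps = 1e-5) {
  g <- x
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

# tiny deterministic grid
rand_grid <- function(H, W, C, seed = 1) {
  withr::with_seed(seed, array(stats::rnorm(H * W * C), c(H, W, C)))
}

# four phantoms matching the tiny preset, used by the training tests
tiny_phantoms <- function(n = 4, size = 64, n_classes = 4, seed_base = 100) {
  lapply(seq_len(n), function(i)
    m3seg::generate_phantom(seed = seed_base + i, size = size,
                            n_classes = n_classes))
}
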