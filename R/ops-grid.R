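# Differentiable ops on feature grids (arrays dim = c(H, W, C)).

as_grid <- function(x, H, W, C) array(x, dim = c(H, W, C))

# 2D convolution. w: array (kh, kw, cin/groups, cout); b: length-cout vector
# or NULL. Zero padding, square stride.
ag_conv2d <- function(x, w, b = NULL, stride = 1L, pad = 0L, groups = 1L) {
  xv <- vof(x); wv <- vof(w); bv <- if (is.null(b)) NULL else vof(b)
  dw <- dim(wv)
  kh <- dw[1]; kw <- dw[2]; cin_g <- dw[3]; cout <- dw[4]
  has_b <- !is.null(bv)
  y <- cpp_conv2d(xv, as.numeric(wv), if (has_b) bv else numeric(1), has_b,
                  kh, kw, cin_g, cout, stride, pad, groups)
  ins <- if (is.null(b)) list(x, w) else list(x, w, b)
  emit(y, ins, function(g) {
    bw <- cpp_conv2d_bw(xv, as.numeric(wv), g, has_b,
                        kh, kw, cin_g, cout, stride, pad, groups)
    gw <- array(bw$dw, dim = dw)
    if (is.null(b)) list(bw$dx, gw) else list(bw$dx, gw, as.numeric(bw$db))
  })
}

ag_upsample2 <- function(x) {
  xv <- vof(x)
  emit(cpp_upsample2(xv), list(x), function(g) list(cpp_upsample2_bw(g)))
}

ag_concat_c <- function(xs) {
  vals <- lapply(xs, vof)
  d <- dim(vals[[1]])
  cs <- vapply(vals, function(v) dim(v)[3], numeric(1))
  y <- array(unlist(vals, use.names = FALSE), dim = c(d[1], d[2], sum(cs)))
  emit(y, xs, function(g) {
    out <- vector("list", length(xs))
    at <- 0L
    for (i in seq_along(xs)) {
      out[[i]] <- g[, , (at + 1):(at + cs[i]), drop = FALSE]
      at <- at + cs[i]
    }
    out
  })
}

ag_slice_c <- function(x, from, to) {
  xv <- vof(x)
  emit(xv[, , from:to, drop = FALSE], list(x), function(g) {
    gx <- array(0, dim(xv))
    gx[, , from:to] <- g
    list(gx)
  })
}

# grid (H,W,C) * map (H,W), broadcast over channels
ag_mul_cmap <- function(x, m) {
  xv <- vof(x); mv <- vof(m)
  d <- dim(xv)
  mb <- array(mv, dim = d)  # recycles the H*W map across channels
  emit(xv * mb, list(x, m), function(g) {
    gm <- rowSums(g * xv, dims = 2L)
    dim(gm) <- dim(mv)
    list(g * mb, gm)
  })
}

# grid * per-channel vector (length C)
ag_mul_cvec <- function(x, s) {
  xv <- vof(x); sv <- vof(s)
  d <- dim(xv)
  sb <- rep(sv, each = d[1] * d[2])
  emit(xv * sb, list(x, s), function(g) {
    list(g * sb, colSums(g * xv, dims = 2L))
  })
}

ag_add_cvec <- function(x, b) {
  xv <- vof(x); bv <- vof(b)
  d <- dim(xv)
  bb <- rep(bv, each = d[1] * d[2])
  emit(xv + bb, list(x, b), function(g) {
    list(g, colSums(g, dims = 2L))
  })
}

# grid -> token matrix (N x C), token index t = (row-1)*W + col
ag_grid_to_tokens <- function(x) {
  xv <- vof(x)
  d <- dim(xv)
  tk <- aperm(xv, c(2, 1, 3))
  dim(tk) <- c(d[1] * d[2], d[3])
  emit(tk, list(x), function(g) {
    dim(g) <- c(d[2], d[1], d[3])
    list(aperm(g, c(2, 1, 3)))
  })
}

ag_tokens_to_grid <- function(tk, H, W) {
  tv <- vof(tk)
  C <- ncol(tv)
  gv <- tv
  dim(gv) <- c(W, H, C)
  y <- aperm(gv, c(2, 1, 3))
  emit(y, list(tk), function(g) {
    gt <- aperm(g, c(2, 1, 3))
    dim(gt) <- c(H * W, C)
    list(gt)
  })
}

# ---- pooling ---------------------------------------------------------------

# Average over width -> (H, C)
ag_pool_w_avg <- function(x) {
  xv <- vof(x)
  d <- dim(xv)
  y <- colMeans(aperm(xv, c(2, 1, 3)), dims = 1L)
  emit(y, list(x), function(g) {
    gx <- aperm(array(as.vector(g) / d[2], dim = c(d[1], d[3], d[2])), c(1, 3, 2))
    list(gx)
  })
}

# Average over height -> (W, C)
ag_pool_h_avg <- function(x) {
  xv <- vof(x)
  d <- dim(xv)
  y <- colMeans(xv, dims = 1L)
  emit(y, list(x), function(g) {
    gx <- aperm(array(as.vector(g) / d[1], dim = c(d[2], d[3], d[1])), c(3, 1, 2))
    list(gx)
  })
}

# Max over width -> (H, C), exact argmax backward
ag_pool_w_max <- function(x) {
  xv <- vof(x)
  d <- dim(xv)
  m <- matrix(aperm(xv, c(2, 1, 3)), d[2], d[1] * d[3])
  idx <- apply(m, 2L, which.max)
  y <- m[cbind(idx, seq_along(idx))]
  dim(y) <- c(d[1], d[3])
  emit(y, list(x), function(g) {
    gm <- matrix(0, d[2], d[1] * d[3])
    gm[cbind(idx, seq_along(idx))] <- as.vector(g)
    dim(gm) <- c(d[2], d[1], d[3])
    list(aperm(gm, c(2, 1, 3)))
  })
}

# Max over height -> (W, C)
ag_pool_h_max <- function(x) {
  xv <- vof(x)
  d <- dim(xv)
  m <- matrix(xv, d[1], d[2] * d[3])
  idx <- apply(m, 2L, which.max)
  y <- m[cbind(idx, seq_along(idx))]
  dim(y) <- c(d[2], d[3])
  emit(y, list(x), function(g) {
    gm <- matrix(0, d[1], d[2] * d[3])
    gm[cbind(idx, seq_along(idx))] <- as.vector(g)
    dim(gm) <- c(d[1], d[2], d[3])
    list(array(gm, dim = d))
  })
}

# Global average pool -> length-C vector
ag_gap <- function(x) {
  xv <- vof(x)
  d <- dim(xv)
  emit(colMeans(xv, dims = 2L), list(x), function(g) {
    list(array(rep(g / (d[1] * d[2]), each = d[1] * d[2]), dim = d))
  })
}

# Outer additive broadcast: a (length H), b (length W) -> (H, W) map
ag_outer_add <- function(a, b) {
  av <- vof(a); bv <- vof(b)
  emit(outer(av, bv, `+`), list(a, b), function(g) {
    list(rowSums(g), colSums(g))
  })
}

# Fused per-channel normalization on a grid. In training mode the statistics
# are computed over the spatial extent; in inference mode fixed running
# statistics are used. Affine transform included.
ag_bn_grid <- function(x, gamma, beta, mu = NULL, va = NULL, eps = 1e-5) {
  xv <- vof(x); gv <- vof(gamma); bv <- vof(beta)
  d <- dim(xv)
  hw <- d[1] * d[2]
  fixed <- !is.null(mu)
  if (!fixed) {
    mu <- colMeans(xv, dims = 2L)
    va <- colMeans(xv * xv, dims = 2L) - mu^2
    va[va < 0] <- 0
  }
  istd <- 1 / sqrt(va + eps)
  xhat <- (xv - rep(mu, each = hw)) * rep(istd, each = hw)
  y <- xhat * rep(gv, each = hw) + rep(bv, each = hw)
  emit(y, list(x, gamma, beta), function(g) {
    dxhat <- g * rep(gv, each = hw)
    if (fixed) {
      dx <- dxhat * rep(istd, each = hw)
    } else {
      mg <- colMeans(dxhat, dims = 2L)
      mgx <- colMeans(dxhat * xhat, dims = 2L)
      dx <- (dxhat - rep(mg, each = hw) - xhat * rep(mgx, each = hw)) *
        rep(istd, each = hw)
    }
    list(dx, colSums(g * xhat, dims = 2L), colSums(g, dims = 2L))
  })
}
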