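# Differentiable primitives. Shapes follow two conventions:
#   grids   : arrays dim = c(H, W, C)
#   tokens  : matrices N x D, token t = (row-1)*W + col (row-major, 0-based
#             coordinates from the top-left)
# Scalar broadcasting is supported where noted; anything else must match.

scalar_like <- function(x) length(vof(x)) == 1L

row_max <- function(m) {
  out <- m[, 1L]
  nc <- ncol(m)
  if (nc > 1L) for (j in 2:nc) out <- pmax(out, m[, j])
  out
}

ag_add <- function(a, b) {
  av <- vof(a); bv <- vof(b)
  emit(av + bv, list(a, b), function(g) {
    ga <- if (length(av) == 1L && length(bv) > 1L) sum(g) else g
    gb <- if (length(bv) == 1L && length(av) > 1L) sum(g) else g
    list(ga, gb)
  })
}

ag_sub <- function(a, b) {
  av <- vof(a); bv <- vof(b)
  emit(av - bv, list(a, b), function(g) {
    ga <- if (length(av) == 1L && length(bv) > 1L) sum(g) else g
    gb <- if (length(bv) == 1L && length(av) > 1L) -sum(g) else -g
    list(ga, gb)
  })
}

ag_mul <- function(a, b) {
  av <- vof(a); bv <- vof(b)
  emit(av * bv, list(a, b), function(g) {
    ga <- g * bv; gb <- g * av
    if (length(av) == 1L && length(bv) > 1L) ga <- sum(ga)
    if (length(bv) == 1L && length(av) > 1L) gb <- sum(gb)
    list(ga, gb)
  })
}

ag_div <- function(a, b) {
  av <- vof(a); bv <- vof(b)
  emit(av / bv, list(a, b), function(g) {
    ga <- g / bv; gb <- -g * av / (bv * bv)
    if (length(av) == 1L && length(bv) > 1L) ga <- sum(ga)
    if (length(bv) == 1L && length(av) > 1L) gb <- sum(gb)
    list(ga, gb)
  })
}

ag_scale <- function(a, k) {  # k: plain constant
  emit(vof(a) * k, list(a), function(g) list(g * k))
}

ag_exp <- function(a) {
  y <- exp(vof(a))
  emit(y, list(a), function(g) list(g * y))
}

ag_log <- function(a) {
  av <- vof(a)
  emit(log(av), list(a), function(g) list(g / av))
}

ag_sigmoid <- function(a) {
  y <- 1 / (1 + exp(-vof(a)))
  emit(y, list(a), function(g) list(g * y * (1 - y)))
}

ag_relu <- function(a) {
  av <- vof(a)
  emit(pmax(av, 0), list(a), function(g) list(g * (av > 0)))
}

ag_relu6 <- function(a) {
  av <- vof(a)
  emit(pmin(pmax(av, 0), 6), list(a), function(g) list(g * (av > 0 & av < 6)))
}

ag_gelu <- function(a) {
  av <- vof(a)
  emit(av * stats::pnorm(av), list(a), function(g) {
    list(g * (stats::pnorm(av) + av * stats::dnorm(av)))
  })
}

ag_sum <- function(a) {
  av <- vof(a)
  emit(sum(av), list(a), function(g) {
    gr <- rep(g, length(av))
    if (!is.null(dim(av))) dim(gr) <- dim(av)
    list(gr)
  })
}

ag_mean <- function(a) {
  av <- vof(a)
  emit(mean(av), list(a), function(g) {
    gr <- rep(g / length(av), length(av))
    if (!is.null(dim(av))) dim(gr) <- dim(av)
    list(gr)
  })
}

# ---- matrix ops ------------------------------------------------------------

ag_matmul <- function(a, b) {
  av <- vof(a); bv <- vof(b)
  emit(av %*% bv, list(a, b), function(g) {
    list(g %*% t(bv), t(av) %*% g)
  })
}

ag_t <- function(a) {
  emit(t(vof(a)), list(a), function(g) list(t(g)))
}

ag_softmax_rows <- function(a) {
  av <- vof(a)
  m <- row_max(av)
  e <- exp(av - m)
  y <- e / rowSums(e)
  emit(y, list(a), function(g) {
    list((g - rowSums(g * y)) * y)
  })
}

ag_rowsums <- function(a) {
  av <- vof(a)
  emit(rowSums(av), list(a), function(g) {
    list(matrix(g, nrow(av), ncol(av)))
  })
}

ag_colsums <- function(a) {
  av <- vof(a)
  emit(colSums(av), list(a), function(g) {
    list(matrix(g, nrow(av), ncol(av), byrow = TRUE))
  })
}

# X * s[row], s a length-nrow vector
ag_scale_rows <- function(a, s) {
  av <- vof(a); sv <- as.vector(vof(s))
  emit(av * sv, list(a, s), function(g) {
    list(g * sv, rowSums(g * av))
  })
}

# Row-wise layer normalization with affine parameters (gamma, beta: length D).
ag_layernorm <- function(a, gamma, beta, eps = 1e-5) {
  av <- vof(a); gv <- vof(gamma); bv <- vof(beta)
  mu <- rowMeans(av)
  xc <- av - mu
  v <- rowMeans(xc * xc)
  istd <- 1 / sqrt(v + eps)
  xhat <- xc * istd
  y <- sweep(xhat, 2L, gv, `*`)
  y <- sweep(y, 2L, bv, `+`)
  emit(y, list(a, gamma, beta), function(g) {
    dxhat <- sweep(g, 2L, gv, `*`)
    dx <- (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) * istd
    list(dx, colSums(g * xhat), colSums(g))
  })
}

# Column-wise standardization (used for per-channel batch statistics on the
# token matrix of a single sample). Returns standardized matrix; the affine
# transform is applied by the caller.
ag_colnorm <- function(a, eps = 1e-5, mu = NULL, va = NULL) {
  av <- vof(a)
  n <- nrow(av)
  if (is.null(mu)) mu <- colMeans(av)
  xc <- sweep(av, 2L, mu, `-`)
  if (is.null(va)) va <- colMeans(xc * xc)
  istd <- 1 / sqrt(va + eps)
  xhat <- sweep(xc, 2L, istd, `*`)
  emit(xhat, list(a), function(g) {
    # standard batch-norm backward:
    # dx = istd * (g - mean_col(g) - xhat * mean_col(g * xhat))
    dx <- sweep(g, 2L, colMeans(g), `-`) -
      xhat * matrix(colMeans(g * xhat), n, ncol(av), byrow = TRUE)
    dx <- sweep(dx, 2L, istd, `*`)
    list(dx)
  })
}

# Column-wise standardization against fixed statistics (inference-mode BN).
ag_colnorm_fixed <- function(a, mu, va, eps = 1e-5) {
  av <- vof(a)
  istd <- 1 / sqrt(va + eps)
  xhat <- sweep(sweep(av, 2L, mu, `-`), 2L, istd, `*`)
  emit(xhat, list(a), function(g) list(sweep(g, 2L, istd, `*`)))
}

# Group normalization over a token matrix (N x C): channels are split into
# `groups` consecutive blocks; each block is standardized over all N x (C/g)
# entries jointly, then affine-transformed per channel.
ag_groupnorm <- function(a, groups, gamma, beta, eps = 1e-5) {
  av <- vof(a); gv <- vof(gamma); bv <- vof(beta)
  n <- nrow(av); C <- ncol(av)
  cg <- C / groups
  xhat <- av
  istds <- numeric(groups)
  for (g0 in seq_len(groups)) {
    idx <- ((g0 - 1) * cg + 1):(g0 * cg)
    blk <- av[, idx, drop = FALSE]
    mu <- mean(blk)
    va <- mean((blk - mu)^2)
    istds[g0] <- 1 / sqrt(va + eps)
    xhat[, idx] <- (blk - mu) * istds[g0]
  }
  y <- sweep(xhat, 2L, gv, `*`)
  y <- sweep(y, 2L, bv, `+`)
  emit(y, list(a, gamma, beta), function(g) {
    dxhat <- sweep(g, 2L, gv, `*`)
    dx <- dxhat
    for (g0 in seq_len(groups)) {
      idx <- ((g0 - 1) * cg + 1):(g0 * cg)
      dh <- dxhat[, idx, drop = FALSE]
      xh <- xhat[, idx, drop = FALSE]
      dx[, idx] <- (dh - mean(dh) - xh * mean(dh * xh)) * istds[g0]
    }
    list(dx, colSums(g * xhat), colSums(g))
  })
}

# Fused cross-entropy from logits (numerically stable log-softmax).
# logits: N x C, y_onehot: N x C. Value equals
# -(1/N) sum_i sum_c y_ic log softmax(logits)_ic.
ag_ce_logits <- function(logits, y_onehot) {
  lv <- vof(logits)
  m <- row_max(lv)
  e <- exp(lv - m)
  p <- e / rowSums(e)
  n <- nrow(lv)
  val <- -sum(y_onehot * (lv - m - log(rowSums(e)))) / n
  emit(val, list(logits), function(g) {
    list(g * (p - y_onehot) / n)
  })
}

# X + b[col] broadcast down rows (bias on a token matrix)
ag_add_rowvec <- function(a, b) {
  av <- vof(a); bv <- vof(b)
  emit(sweep(av, 2L, bv, `+`), list(a, b), function(g) {
    list(g, colSums(g))
  })
}

ag_cols <- function(a, idx) {
  av <- vof(a)
  emit(av[, idx, drop = FALSE], list(a), function(g) {
    gx <- matrix(0, nrow(av), ncol(av))
    gx[, idx] <- g
    list(gx)
  })
}

ag_subset <- function(a, idx) {
  av <- vof(a)
  emit(av[idx], list(a), function(g) {
    gx <- numeric(length(av))
    gx[idx] <- g
    list(gx)
  })
}

ag_reshape <- function(a, dims) {
  av <- vof(a)
  d0 <- dim(av)
  y <- av
  dim(y) <- dims
  emit(y, list(a), function(g) {
    dim(g) <- d0
    list(g)
  })
}
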