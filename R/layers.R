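# Layer constructors. A "builder" collects named parameter arrays and
# persistent buffers (batch-norm running statistics); constructors return
# forward closures with signature (P, x, train) where P maps parameter names
# to plain arrays (inference) or tape leaves (training).

new_builder <- function() {
  b <- new.env(parent = emptyenv())
  b$params <- new.env(parent = emptyenv())
  b$buffers <- new.env(parent = emptyenv())
  b$names <- character()
  b
}

add_param <- function(b, name, value) {
  assign(name, value, envir = b$params)
  b$names <- c(b$names, name)
  invisible(value)
}

# He-normal init for conv kernels, Xavier-ish for linear maps
init_conv_w <- function(kh, kw, cin_g, cout) {
  sd <- sqrt(2 / (kh * kw * cin_g))
  array(stats::rnorm(kh * kw * cin_g * cout, 0, sd), dim = c(kh, kw, cin_g, cout))
}

init_linear_w <- function(din, dout) {
  sd <- sqrt(1 / din)
  matrix(stats::rnorm(din * dout, 0, sd), din, dout)
}

layer_conv <- function(b, name, cin, cout, k, stride = 1L, pad = (k - 1L) %/% 2L,
                       groups = 1L, bias = TRUE) {
  if (cin %% groups != 0 || cout %% groups != 0)
    stop(sprintf("channels (%d -> %d) not divisible by groups (%d) in %s",
                 cin, cout, groups, name))
  wn <- paste0(name, ".w"); bn <- paste0(name, ".b")
  add_param(b, wn, init_conv_w(k, k, cin %/% groups, cout))
  if (bias) add_param(b, bn, numeric(cout))
  function(P, x) {
    ag_conv2d(x, P[[wn]], if (bias) P[[bn]] else NULL,
              stride = stride, pad = pad, groups = groups)
  }
}

layer_linear <- function(b, name, din, dout, bias = TRUE) {
  wn <- paste0(name, ".w"); bn <- paste0(name, ".b")
  add_param(b, wn, init_linear_w(din, dout))
  if (bias) add_param(b, bn, numeric(dout))
  function(P, x) {
    y <- ag_matmul(x, P[[wn]])
    if (bias) y <- ag_add_rowvec(y, P[[bn]]) else y
  }
}

# Batch normalization over the spatial extent of a single sample; running
# statistics (momentum 0.1) are used at inference time.
layer_bn <- function(b, name, C, momentum = 0.1, eps = 1e-5) {
  gn <- paste0(name, ".gamma"); be <- paste0(name, ".beta")
  mn <- paste0(name, ".rmean"); vn <- paste0(name, ".rvar")
  add_param(b, gn, rep(1, C))
  add_param(b, be, numeric(C))
  assign(mn, numeric(C), envir = b$buffers)
  assign(vn, rep(1, C), envir = b$buffers)
  buf <- b$buffers
  function(P, x, train = FALSE) {
    if (train) {
      xv <- vof(x)
      mu <- colMeans(xv, dims = 2L)
      va <- colMeans(xv * xv, dims = 2L) - mu^2
      va[va < 0] <- 0
      assign(mn, (1 - momentum) * get(mn, buf) + momentum * mu, envir = buf)
      assign(vn, (1 - momentum) * get(vn, buf) + momentum * va, envir = buf)
      ag_bn_grid(x, P[[gn]], P[[be]], eps = eps)
    } else {
      ag_bn_grid(x, P[[gn]], P[[be]], mu = get(mn, buf), va = get(vn, buf),
                 eps = eps)
    }
  }
}

# Instance normalization: per-channel spatial statistics of the current
# sample, at training and inference alike (batch-size independent, the usual
# choice for small-batch medical segmentation backbones).
layer_instnorm <- function(b, name, C, eps = 1e-5) {
  gn <- paste0(name, ".gamma"); be <- paste0(name, ".beta")
  add_param(b, gn, rep(1, C))
  add_param(b, be, numeric(C))
  function(P, x, train = FALSE) ag_bn_grid(x, P[[gn]], P[[be]], eps = eps)
}

layer_layernorm <- function(b, name, D, eps = 1e-5) {
  gn <- paste0(name, ".gamma"); be <- paste0(name, ".beta")
  add_param(b, gn, rep(1, D))
  add_param(b, be, numeric(D))
  function(P, x) ag_layernorm(x, P[[gn]], P[[be]], eps = eps)
}

# Squeeze-and-excitation: global pooled descriptor -> bottleneck -> sigmoid
# per-channel recalibration.
layer_se <- function(b, name, C, reduction = 16L) {
  r <- max(4L, C %/% reduction)
  f1 <- layer_linear(b, paste0(name, ".fc1"), C, r)
  f2 <- layer_linear(b, paste0(name, ".fc2"), r, C)
  function(P, x) {
    s <- ag_gap(x)
    s <- ag_reshape(s, c(1L, length(vof(s))))
    s <- ag_relu(f1(P, s))
    s <- ag_sigmoid(f2(P, s))
    ag_mul_cvec(x, ag_reshape(s, ncol(vof(s))))
  }
}

# Wrap a module's parameters as tape leaves for a training step.
wrap_params <- function(params, names) {
  P <- new.env(parent = emptyenv())
  for (nm in names) assign(nm, ag_leaf(get(nm, envir = params), nm), envir = P)
  P
}

collect_grads <- function(P, names) {
  out <- vector("list", length(names))
  names(out) <- names
  for (nm in names) {
    nd <- get(nm, envir = P)
    out[[nm]] <- if (is_node(nd)) nd$g else NULL
  }
  out
}
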