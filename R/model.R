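# Whole-model assembly: residual CNN stem -> patch embedding -> encoder
# block stack -> gated skips -> merge-augment-upsample decoder -> 1x1 head.

# Residual convolutional stem with three downsampling stages emitting skip
# features at 1/2, 1/4 and 1/8 resolution.
init_stem <- function(b, name, cin, widths) {
  stages <- list()
  prev <- cin
  for (i in seq_along(widths)) {
    w <- widths[i]
    pre <- paste0(name, ".s", i)
    down <- layer_conv(b, paste0(pre, ".down"), prev, w, 3L, stride = 2L,
                       bias = FALSE)
    bn0 <- layer_instnorm(b, paste0(pre, ".bn0"), w)
    c1 <- layer_conv(b, paste0(pre, ".c1"), w, w, 3L, bias = FALSE)
    bn1 <- layer_instnorm(b, paste0(pre, ".bn1"), w)
    c2 <- layer_conv(b, paste0(pre, ".c2"), w, w, 3L, bias = FALSE)
    bn2 <- layer_instnorm(b, paste0(pre, ".bn2"), w)
    stages[[i]] <- local({
      down <- down; bn0 <- bn0; c1 <- c1; bn1 <- bn1; c2 <- c2; bn2 <- bn2
      function(P, x, train) {
        h <- ag_relu(bn0(P, down(P, x), train = train))
        r <- bn2(P, c2(P, ag_relu(bn1(P, c1(P, h), train = train))),
                 train = train)
        ag_relu(ag_add(h, r))
      }
    })
  }
  function(P, x, train = FALSE) {
    skips <- vector("list", length(stages))
    h <- x
    for (i in seq_along(stages)) {
      h <- stages[[i]](P, h, train)
      skips[[i]] <- h
    }
    skips
  }
}

#' Build the segmentation network
#'
#' Assembles the full hybrid model described by a [model_config()]: a
#' three-stage residual CNN stem (skip features at 1/2, 1/4, 1/8 resolution),
#' a strided patch-embedding convolution to the token grid, `depth` encoder
#' blocks (MSGA + Manhattan-biased attention + MLP), MKGAG-gated skip
#' connections, a cascade of merge-augment-upsample decoder stages with MSSA
#' refinement, and a 1x1 segmentation head.
#'
#' @param config an `m3_config`.
#' @param seed RNG seed controlling parameter initialization and the linear
#'   attention feature draws; forward passes are deterministic given the
#'   built model.
#' @return an object of class `m3_model`.
#' @examples
#' m <- build_model(model_config("tiny"), seed = 1)
#' count_parameters(m)
#' @export
build_model <- function(config, seed = 1L) {
  config <- validate_config(config)
  b <- new_builder()
  S <- config$input_size
  grid <- S %/% config$patch_size
  n_up <- as.integer(round(log2(config$patch_size)))
  sc <- config$stem_channels
  withr::with_seed(seed, {
    stem <- init_stem(b, "stem", config$in_channels, sc)
    # patch embedding: strided conv on the 1/8-resolution stem features
    es <- config$patch_size %/% 8L
    embed <- layer_conv(b, "embed", sc[3], config$hidden_dim, es, stride = es,
                        pad = 0L)
    blocks <- lapply(seq_len(config$depth), function(i)
      init_encoder_block(b, sprintf("enc%d", i), config, c(grid, grid)))
    enc_ln <- layer_layernorm(b, "enc.ln", config$hidden_dim)
    # decoder stages, deepest first; skips pair with stem stages 3, 2, 1
    dec <- config$decoder_channels
    # stage i emits resolution S / 2^(n_up - i); it can fuse the stem stage
    # at the same resolution (stem stage j lives at S / 2^j)
    skip_ch <- integer(n_up)
    stem_for_stage <- n_up - seq_len(n_up)
    applied <- 0L
    for (i in seq_len(n_up)) {
      j <- stem_for_stage[i]
      if (j >= 1L && j <= 3L && applied < config$num_skips) {
        skip_ch[i] <- sc[j]
        applied <- applied + 1L
      }
    }
    cin <- c(config$hidden_dim, dec[-length(dec)])
    stages <- lapply(seq_len(n_up), function(i)
      init_decoder_stage(b, sprintf("dec%d", i), cin[i], skip_ch[i], dec[i],
                         config$performer_features,
                         feature_seed = seed + i))
    head <- init_head(b, "head", dec[n_up], config$num_classes)
  })
  submodule_of <- function(nm) {
    if (grepl("\\.msga\\.", nm)) "msga"
    else if (grepl("\\.attn\\.", nm)) "me_msa"
    else if (grepl("\\.gate\\.", nm)) "mkgag"
    else if (grepl("\\.mssa\\.", nm)) "mssa"
    else if (grepl("^head", nm)) "head"
    else if (grepl("^stem", nm)) "stem"
    else "other"
  }
  fwd <- function(P, image, train = FALSE) {
    d <- dim(vof(image))
    if (d[1] != S || d[2] != S)
      stop(sprintf("input must be %dx%d, got %dx%d", S, S, d[1], d[2]))
    skips <- stem(P, image, train = train)
    tk <- ag_grid_to_tokens(embed(P, skips[[3]]))
    for (blk in blocks) tk <- blk(P, tk)
    tk <- enc_ln(P, tk)
    h <- ag_tokens_to_grid(tk, grid, grid)
    for (i in seq_len(n_up)) {
      sk <- if (skip_ch[i] > 0L) skips[[stem_for_stage[i]]] else NULL
      h <- stages[[i]](P, h, sk, train = train)
    }
    head(P, h)
  }
  structure(list(config = config, params = b$params, buffers = b$buffers,
                 names = b$names, fwd = fwd, seed = seed,
                 submodule_of = submodule_of),
            class = "m3_model")
}

#' @export
print.m3_model <- function(x, ...) {
  cat(sprintf("<m3_model> preset '%s', %s trainable parameters\n",
              x$config$preset, format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

#' Forward pass of a segmentation model
#'
#' Maps an `(S, S)` or `(S, S, channels)` image to per-pixel class logits.
#' Deterministic given the built model (the linear-attention random features
#' are fixed at construction).
#'
#' @param model an `m3_model`.
#' @param image numeric array; a 2D matrix is treated as single-channel.
#' @param train use batch statistics in the normalization layers and update
#'   their running averages (training mode).
#' @return logits array `(S, S, num_classes)`.
#' @export
model_forward <- function(model, image, train = FALSE) {
  image <- ensure_channels(image, model$config$in_channels)
  model$fwd(model$params, image, train = train)
}

ensure_channels <- function(image, cin) {
  if (is.matrix(image)) image <- array(image, dim = c(dim(image), 1L))
  d <- dim(image)
  if (length(d) != 3) stop("image must be (H, W) or (H, W, channels)")
  if (d[3] != cin)
    stop(sprintf("model expects %d channel(s), image has %d", cin, d[3]))
  image
}

#' Count trainable parameters
#'
#' @param model an `m3_model` (or any object with a `params` environment and
#'   `names` vector).
#' @param by_submodule if `TRUE`, return a tibble of counts per named
#'   submodule family (stem, msga, me_msa, mkgag, mssa, head, other).
#' @return integer count, or a tibble.
#' @export
count_parameters <- function(model, by_submodule = FALSE) {
  sizes <- vapply(model$names,
                  function(nm) length(get(nm, envir = model$params)),
                  numeric(1))
  if (!by_submodule) return(sum(sizes))
  fam <- vapply(model$names, model$submodule_of, character(1))
  tibble::tibble(submodule = fam, n = sizes) |>
    dplyr::group_by(.data$submodule) |>
    dplyr::summarise(parameters = sum(.data$n), .groups = "drop")
}

# Predicted label map from a logits grid
logits_to_mask <- function(logits) {
  lv <- vof(logits)
  d <- dim(lv)
  m <- matrix(lv, d[1] * d[2], d[3])
  mask <- max.col(m, ties.method = "first") - 1L
  matrix(mask, d[1], d[2])
}
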