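#' Architecture configuration
#'
#' Collects every hyperparameter of the hybrid CNN-Transformer segmentation
#' network. Three presets are provided: `"tiny"` (a CPU-trainable
#' configuration used throughout the tests and examples), `"base"`
#' (hidden dimension 768, 12 encoder layers) and `"large"` (1024, 24).
#'
#' @param preset one of `"tiny"`, `"base"`, `"large"`.
#' @param ... named overrides for any configuration field, e.g.
#'   `num_classes = 4` or `input_size = 64`.
#'
#' @details Fields (with the `base` defaults):
#' * `input_size` (224): square input side S in pixels.
#' * `in_channels` (1): image channels (1 grayscale, 3 RGB).
#' * `patch_size` (16): token patch side P; the encoder token grid is
#'   (S/P) x (S/P). Must divide `input_size` and be a multiple of 8
#'   (the CNN stem downsamples by 8 before patch embedding).
#' * `hidden_dim` (768): transformer width D, divisible by `num_heads`
#'   and `msga_groups`.
#' * `depth` (12): number of encoder blocks.
#' * `mlp_dim` (4*D): transformer MLP width.
#' * `num_heads` (12): attention heads.
#' * `msga_groups` (8): channel subgroups G of the multi-scale gate.
#' * `stem_channels` (c(64, 128, 256)): CNN stem widths at 1/2, 1/4, 1/8
#'   resolution; the 1/8 features feed the patch embedding, all three feed
#'   the gated skip connections.
#' * `decoder_channels` (c(256, 128, 64, 16)): output channels of the
#'   up-stages; length must equal log2(`patch_size`).
#' * `num_classes` (9): segmentation classes including background.
#' * `num_skips` (3): gated skip connections used (<= number of up-stages
#'   with an available stem feature).
#' * `performer_features` (256): random feature count m of the linear
#'   attention in the decoder.
#' * `lambda_init` (1.0): initial value of the learnable per-head Manhattan
#'   bias strength.
#'
#' @return an object of class `m3_config` (a named list).
#' @examples
#' cfg <- model_config("tiny", num_classes = 4)
#' cfg$hidden_dim
#' @export
model_config <- function(preset = c("base", "tiny", "large"), ...) {
  preset <- match.arg(preset)
  cfg <- switch(preset,
    base = list(
      input_size = 224L, in_channels = 1L, patch_size = 16L,
      hidden_dim = 768L, depth = 12L, mlp_dim = 3072L, num_heads = 12L,
      msga_groups = 8L, stem_channels = c(64L, 128L, 256L),
      decoder_channels = c(256L, 128L, 64L, 16L),
      num_classes = 9L, num_skips = 3L,
      performer_features = 256L, lambda_init = 1.0
    ),
    large = list(
      input_size = 224L, in_channels = 1L, patch_size = 16L,
      hidden_dim = 1024L, depth = 24L, mlp_dim = 4096L, num_heads = 16L,
      msga_groups = 8L, stem_channels = c(64L, 128L, 256L),
      decoder_channels = c(256L, 128L, 64L, 16L),
      num_classes = 9L, num_skips = 3L,
      performer_features = 256L, lambda_init = 1.0
    ),
    tiny = list(
      input_size = 64L, in_channels = 1L, patch_size = 16L,
      hidden_dim = 64L, depth = 2L, mlp_dim = 128L, num_heads = 4L,
      msga_groups = 4L, stem_channels = c(8L, 16L, 32L),
      decoder_channels = c(32L, 16L, 8L, 8L),
      num_classes = 4L, num_skips = 3L,
      performer_features = 64L, lambda_init = 1.0
    )
  )
  cfg$preset <- preset
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(cfg))
    if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
    cfg[names(dots)] <- dots
  }
  cfg <- validate_config(cfg)
  class(cfg) <- "m3_config"
  cfg
}

validate_config <- function(cfg) {
  if (cfg$input_size %% cfg$patch_size != 0)
    stop(sprintf("input_size (%d) is not divisible by patch_size (%d)",
                 cfg$input_size, cfg$patch_size))
  if (cfg$patch_size %% 8 != 0)
    stop(sprintf("patch_size (%d) must be a multiple of 8 (CNN stem stride)",
                 cfg$patch_size))
  if (cfg$hidden_dim %% cfg$num_heads != 0)
    stop(sprintf("hidden_dim (%d) is not divisible by num_heads (%d)",
                 cfg$hidden_dim, cfg$num_heads))
  if (cfg$hidden_dim %% cfg$msga_groups != 0)
    stop(sprintf("hidden_dim (%d) is not divisible by msga_groups (%d)",
                 cfg$hidden_dim, cfg$msga_groups))
  n_up <- as.integer(round(log2(cfg$patch_size)))
  if (length(cfg$decoder_channels) != n_up)
    stop(sprintf("decoder_channels must have length log2(patch_size) = %d", n_up))
  if (cfg$num_skips > min(3L, n_up))
    stop(sprintf("num_skips (%d) exceeds the available up-stages with skips (%d)",
                 cfg$num_skips, min(3L, n_up)))
  if (cfg$num_classes < 2) stop("num_classes must be at least 2")
  cfg
}

#' @export
print.m3_config <- function(x, ...) {
  cat(sprintf("<m3_config '%s'> S=%d P=%d D=%d depth=%d heads=%d G=%d classes=%d\n",
              x$preset, x$input_size, x$patch_size, x$hidden_dim, x$depth,
              x$num_heads, x$msga_groups, x$num_classes))
  invisible(x)
}

#' Token sequence length of the encoder
#'
#' Number of tokens produced when a square input of side `input_size` is
#' split into non-overlapping patches of side `patch_size`:
#' `(input_size / patch_size)^2`.
#'
#' @param input_size input side in pixels.
#' @param patch_size patch side in pixels.
#' @return integer token count.
#' @examples
#' sequence_length(224, 16)  # 196
#' @export
sequence_length <- function(input_size, patch_size) {
  if (patch_size <= 0 || input_size <= 0)
    stop("input_size and patch_size must be positive")
  if (input_size %% patch_size != 0)
    stop(sprintf("input_size (%d) is not divisible by patch_size (%d)",
                 input_size, patch_size))
  as.integer((input_size / patch_size)^2)
}

#' Read / write a model configuration as YAML
#'
#' @param path file path.
#' @return `read_model_config()` returns an `m3_config`;
#'   `write_model_config()` returns `path` invisibly.
#' @export
read_model_config <- function(path) {
  y <- yaml::read_yaml(path)
  preset <- y$preset %||% "base"
  y$preset <- NULL
  for (f in c("stem_channels", "decoder_channels"))
    if (!is.null(y[[f]])) y[[f]] <- as.integer(y[[f]])
  do.call(model_config, c(list(preset = preset), y))
}

#' @rdname read_model_config
#' @param cfg an `m3_config`.
#' @export
write_model_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
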