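# Training loop: SGD with momentum and weight decay, polynomial learning-rate
# decay, per-iteration logging of the compound loss, checkpointing and exact
# resume. All randomness (batch sampling, augmentation draws) is derived
# from the master seed and the iteration index, so a resumed run reproduces
# an uninterrupted one bitwise.

#' Training configuration
#'
#' Defaults follow the reference optimization protocol: SGD with initial
#' learning rate 0.01, momentum 0.9, weight decay 1e-4, batch size 24,
#' 20,000 iterations, polynomial decay with power 0.9. Desk-scale runs
#' shrink `batch_size` and `max_iterations`.
#'
#' @param lr initial learning rate (> 0).
#' @param momentum SGD momentum.
#' @param weight_decay L2 weight decay.
#' @param batch_size samples per iteration (>= 1).
#' @param max_iterations total iterations of the schedule.
#' @param lr_power polynomial decay power: `lr * (1 - it/max)^power`.
#' @param seed master seed for sampling/augmentation/initialized state.
#' @param eval_every compute training-set DSC every this many iterations
#'   (0 disables).
#' @param target_dsc stop early once the mean foreground training DSC
#'   reaches this value (`NULL` disables).
#' @param augment optional [augmentation_policy()] applied to every drawn
#'   training sample (training phase only).
#' @param checkpoint_every write a checkpoint every this many iterations
#'   (0 disables); requires `checkpoint_path`.
#' @param checkpoint_path file path for checkpoints.
#' @return a `train_config` list.
#' @export
train_config <- function(lr = 0.01, momentum = 0.9, weight_decay = 1e-4,
                         batch_size = 24L, max_iterations = 20000L,
                         lr_power = 0.9, seed = 1L, eval_every = 0L,
                         target_dsc = NULL, augment = NULL,
                         checkpoint_every = 0L, checkpoint_path = NULL) {
  if (lr <= 0) stop("lr must be positive")
  if (batch_size < 1) stop("batch_size must be at least 1")
  structure(list(lr = lr, momentum = momentum, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 max_iterations = as.integer(max_iterations),
                 lr_power = lr_power, seed = seed,
                 eval_every = as.integer(eval_every), target_dsc = target_dsc,
                 augment = augment,
                 checkpoint_every = as.integer(checkpoint_every),
                 checkpoint_path = checkpoint_path),
            class = "train_config")
}

poly_lr <- function(lr0, it, max_it, power) lr0 * (1 - (it - 1) / max_it)^power

#' Fit the segmentation network
#'
#' Minimizes the compound loss `0.5 * CE + 0.5 * Dice` over the supplied
#' samples with momentum SGD. Each iteration draws `batch_size` samples
#' (uniformly, seeded by iteration), optionally augments them, accumulates
#' gradients over the batch and applies one update. The run log records the
#' total/CE/Dice losses for every iteration.
#'
#' @param model an `m3_model` from [build_model()].
#' @param samples list of `segmentation_sample` objects whose masks use
#'   labels `0 .. num_classes - 1` and whose size equals the model input.
#' @param config a [train_config()].
#' @param loss a [loss_config()].
#' @param start_iteration first iteration index (used when resuming).
#' @param opt_state momentum buffers from a checkpoint (internal).
#' @param log existing run log to append to (internal).
#' @param quiet suppress progress messages.
#' @return an `m3_fit`: list with `model`, `log` (tibble), `config`,
#'   `iterations`, `final_dsc`.
#' @export
fit_segmentation <- function(model, samples, config = train_config(),
                             loss = loss_config(), start_iteration = 1L,
                             opt_state = NULL, log = NULL, quiet = TRUE) {
  stopifnot(inherits(model, "m3_model"))
  C <- model$config$num_classes
  S <- model$config$input_size
  for (s in samples) {
    if (!all(dim(s$mask) == S))
      stop("sample size does not match the model input size")
    if (max(s$mask) >= C)
      stop("sample labels exceed the model class count")
  }
  vel <- opt_state %||% new.env(parent = emptyenv())
  logs <- if (is.null(log)) list() else list(log)
  final_dsc <- NA_real_
  it <- start_iteration - 1L
  while (it < config$max_iterations) {
    it <- it + 1L
    lr <- poly_lr(config$lr, it, config$max_iterations, config$lr_power)
    batch <- withr::with_seed(iter_seed(config$seed, it), {
      idx <- sample.int(length(samples), config$batch_size, replace = TRUE)
      lapply(seq_along(idx), function(j) {
        s <- samples[[idx[j]]]
        if (!is.null(config$augment))
          s <- augment(s, config$augment,
                       draw_seed = it * 131L + j)
        s
      })
    })
    gacc <- NULL
    ce_v <- 0; di_v <- 0
    for (s in batch) {
      ag_tape_start()
      P <- wrap_params(model$params, model$names)
      logits <- model$fwd(P, ensure_channels(s$image, model$config$in_channels),
                          train = TRUE)
      ltk <- ag_grid_to_tokens(logits)
      yh <- to_onehot(s$mask, C)
      l <- ag_total_loss(ltk, yh, loss)
      ag_backward(l$total)
      g <- collect_grads(P, model$names)
      ag_tape_stop()
      ce_v <- ce_v + l$ce
      di_v <- di_v + l$dice
      if (is.null(gacc)) gacc <- g
      else for (nm in model$names)
        if (!is.null(g[[nm]])) gacc[[nm]] <- (gacc[[nm]] %||% 0) + g[[nm]]
    }
    nb <- length(batch)
    ce_v <- ce_v / nb; di_v <- di_v / nb
    sgd_step(model, gacc, nb, lr, config$momentum, config$weight_decay, vel)
    logs[[length(logs) + 1L]] <- tibble::tibble(
      iteration = it, lr = lr,
      loss_ce = ce_v, loss_dice = di_v,
      loss_total = loss$lambda_ce * ce_v + loss$lambda_dice * di_v,
      train_dsc = NA_real_)
    if (config$eval_every > 0 && (it %% config$eval_every == 0 ||
                                  it == config$max_iterations)) {
      final_dsc <- mean_train_dsc(model, samples)
      logs[[length(logs)]]$train_dsc <- final_dsc
      if (!quiet)
        message(sprintf("iter %d  loss %.4f  train DSC %.3f", it,
                        logs[[length(logs)]]$loss_total, final_dsc))
      if (!is.null(config$target_dsc) && final_dsc >= config$target_dsc) break
    }
    if (config$checkpoint_every > 0 && !is.null(config$checkpoint_path) &&
        it %% config$checkpoint_every == 0)
      save_checkpoint(model, config$checkpoint_path, iteration = it,
                      opt_state = vel, log = dplyr::bind_rows(logs))
  }
  fit <- structure(list(model = model, log = dplyr::bind_rows(logs),
                        config = config, loss = loss, iterations = it,
                        final_dsc = final_dsc),
                   class = "m3_fit")
  fit
}

iter_seed <- function(seed, it) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(it) * 16807) %% 2147483647)
}

sgd_step <- function(model, grads, nb, lr, momentum, wd, vel) {
  for (nm in model$names) {
    g <- grads[[nm]]
    if (is.null(g)) next
    w <- get(nm, envir = model$params)
    g <- g / nb + wd * w
    v0 <- if (exists(nm, envir = vel, inherits = FALSE))
      get(nm, envir = vel) else 0
    v <- momentum * v0 + g
    assign(nm, v, envir = vel)
    assign(nm, w - lr * v, envir = model$params)
  }
}

mean_train_dsc <- function(model, samples) {
  per <- vapply(samples, function(s) {
    pred <- logits_to_mask(model_forward(model, s$image))
    cls <- setdiff(sort(unique(as.vector(s$mask))), 0L)
    if (!length(cls)) return(NA_real_)
    mean(vapply(cls, function(cl) dsc(pred == cl, s$mask == cl) / 100,
                numeric(1)))
  }, numeric(1))
  mean(per, na.rm = TRUE)
}

#' @export
print.m3_fit <- function(x, ...) {
  cat(sprintf("<m3_fit> %d iterations, final total loss %.4f%s\n",
              x$iterations, utils::tail(x$log$loss_total, 1),
              if (is.na(x$final_dsc)) ""
              else sprintf(", train DSC %.3f", x$final_dsc)))
  invisible(x)
}

# ---- checkpoints -----------------------------------------------------------

#' Save / load / resume from a checkpoint
#'
#' A checkpoint is a single RDS archive of the parameters, normalization
#' buffers, optimizer momentum state, iteration counter, run log and a hash
#' of the architecture configuration (verified on load).
#'
#' @param model an `m3_model`.
#' @param path checkpoint file path.
#' @param iteration iteration at which the checkpoint is taken.
#' @param opt_state momentum buffer environment.
#' @param log run-log tibble.
#' @return `save_checkpoint()` returns `path` invisibly.
#' @export
save_checkpoint <- function(model, path, iteration = 0L, opt_state = NULL,
                            log = NULL) {
  ck <- list(
    params = as.list(model$params),
    buffers = as.list(model$buffers),
    opt_state = if (is.null(opt_state)) list() else as.list(opt_state),
    iteration = iteration,
    config = model$config,
    config_hash = config_hash(model$config),
    seed = model$seed,
    log = log
  )
  saveRDS(ck, path)
  invisible(path)
}

config_hash <- function(cfg) {
  paste(vapply(unclass(cfg), function(x) paste(x, collapse = ","),
               character(1)), collapse = "|")
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  model <- build_model(ck$config, seed = ck$seed)
  if (config_hash(model$config) != ck$config_hash)
    stop("checkpoint configuration hash mismatch")
  for (nm in names(ck$params)) assign(nm, ck$params[[nm]], envir = model$params)
  for (nm in names(ck$buffers)) assign(nm, ck$buffers[[nm]], envir = model$buffers)
  list(model = model, iteration = ck$iteration, opt_state = ck$opt_state,
       log = ck$log, config = ck$config)
}

#' @rdname save_checkpoint
#' @param samples,config,loss as in [fit_segmentation()].
#' @export
resume_training <- function(path, samples, config = NULL,
                            loss = loss_config()) {
  ck <- load_checkpoint(path)
  if (is.null(config)) stop("resume_training needs the train_config")
  vel <- new.env(parent = emptyenv())
  for (nm in names(ck$opt_state)) assign(nm, ck$opt_state[[nm]], envir = vel)
  fit_segmentation(ck$model, samples, config = config, loss = loss,
                   start_iteration = ck$iteration + 1L, opt_state = vel,
                   log = ck$log)
}

# ---- prediction and evaluation --------------------------------------------

#' Predict a label mask for an image
#'
#' Images whose size differs from the model input are resized bilinearly,
#' predicted, and the mask is restored to the original size with
#' nearest-neighbor sampling. No stochastic transform is applied: repeated
#' calls give identical masks.
#'
#' @param model an `m3_model`.
#' @param image numeric matrix/array.
#' @return integer label matrix of the same spatial size as `image`.
#' @export
predict_mask <- function(model, image) {
  S <- model$config$input_size
  d0 <- dim(image)[1:2]
  x <- image
  if (!all(d0 == S)) x <- resize_image(image, S, bilinear = TRUE)
  logits <- model_forward(model, x)
  mask <- logits_to_mask(logits)
  if (!all(d0 == S)) {
    mask <- resize_to(mask, d0, bilinear = FALSE)
    mask <- matrix(as.integer(round(mask)), d0[1], d0[2])
  }
  mask
}

resize_to <- function(x, d, bilinear = TRUE) {
  filt <- if (bilinear) "bilinear" else "none"
  as.array(EBImage::resize(x, w = d[1], h = d[2], filter = filt))
}

#' Evaluate a model on a set of samples
#'
#' Predicts every sample and computes the per-class metric report. In
#' `"3d"` mode the slice predictions of each case are stacked and evaluated
#' volumetrically (HD95 uses the 3-axis spacing); in `"2d"` mode each slice
#' is a case. On single-slice cases the two modes agree.
#'
#' @param model an `m3_model`.
#' @param samples list of `segmentation_sample`s.
#' @param mode `"2d"` or `"3d"`.
#' @param slice_spacing out-of-plane spacing (mm) used in `"3d"` mode.
#' @return an `m3_metrics` tibble with attribute `"summary"`.
#' @export
evaluate_model <- function(model, samples, mode = c("2d", "3d"),
                           slice_spacing = 1) {
  mode <- match.arg(mode)
  C <- model$config$num_classes
  preds <- lapply(samples, function(s) predict_mask(model, s$image))
  if (mode == "2d") {
    reports <- lapply(seq_along(samples), function(i)
      evaluate_masks(preds[[i]], samples[[i]]$mask, num_classes = C,
                     spacing = samples[[i]]$spacing,
                     case = samples[[i]]$source))
    rep <- dplyr::bind_rows(reports)
  } else {
    d <- dim(samples[[1]]$mask)
    pv <- array(unlist(preds), dim = c(d, length(preds)))
    gv <- array(unlist(lapply(samples, `[[`, "mask")),
                dim = c(d, length(samples)))
    if (length(preds) == 1L) {
      pv <- array(pv, dim = d); gv <- array(gv, dim = d)
      sp <- samples[[1]]$spacing
    } else sp <- c(samples[[1]]$spacing, slice_spacing)
    rep <- evaluate_masks(pv, gv, num_classes = C, spacing = sp,
                          case = "volume")
  }
  class(rep) <- c("m3_metrics", setdiff(class(rep), "m3_metrics"))
  attr(rep, "summary") <- summarize_metrics(rep)
  rep
}
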