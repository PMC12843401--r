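# broom-style tidiers and ggplot2 autoplot methods.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a training run
#'
#' One row per iteration with the learning rate and the total/CE/Dice loss
#' components (and the training DSC where it was evaluated).
#'
#' @param x an `m3_fit`.
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.m3_fit <- function(x, ...) x$log

#' @rdname tidy.m3_fit
#' @export
glance.m3_fit <- function(x, ...) {
  tibble::tibble(
    iterations = x$iterations,
    final_loss = utils::tail(x$log$loss_total, 1),
    final_ce = utils::tail(x$log$loss_ce, 1),
    final_dice = utils::tail(x$log$loss_dice, 1),
    train_dsc = x$final_dsc,
    parameters = count_parameters(x$model)
  )
}

#' Plot the loss curves of a training run
#'
#' @param object an `m3_fit`.
#' @param ... unused.
#' @return a ggplot of the total, cross-entropy and Dice losses.
#' @export
autoplot.m3_fit <- function(object, ...) {
  df <- object$log |>
    dplyr::select("iteration", Total = "loss_total", CE = "loss_ce",
                  Dice = "loss_dice") |>
    tidyr_longer()
  ggplot2::ggplot(df, ggplot2::aes(.data$iteration, .data$value,
                                   colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "iteration", y = "loss", colour = NULL) +
    ggplot2::theme_minimal()
}

# minimal pivot to avoid a tidyr dependency
tidyr_longer <- function(df) {
  comps <- setdiff(names(df), "iteration")
  dplyr::bind_rows(lapply(comps, function(cp)
    tibble::tibble(iteration = df$iteration, component = cp,
                   value = df[[cp]])))
}

#' Plot a per-class metric report
#'
#' @param object an `m3_metrics` tibble from [evaluate_masks()] or
#'   [evaluate_model()].
#' @param metric which metric to plot.
#' @param ... unused.
#' @return a ggplot bar chart per class.
#' @export
autoplot.m3_metrics <- function(object, metric = c("dsc", "iou", "hd95"),
                                ...) {
  metric <- match.arg(metric)
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(factor(.data$class), .data[[metric]])) +
    ggplot2::stat_summary(fun = mean, geom = "col") +
    ggplot2::labs(x = "class", y = toupper(metric)) +
    ggplot2::theme_minimal()
}

#' @export
glance.m3_metrics <- function(x, ...) summarize_metrics(x)
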