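# Evaluation metrics: Dice similarity coefficient (reported as a percent),
# 95th-percentile Hausdorff distance over boundary surface distances (mm),
# and intersection-over-union.

#' Dice similarity coefficient
#'
#' `2 |P n G| / (|P| + |G|) * 100`. Two empty masks score 100 by convention.
#'
#' @param P,G logical/0-1 arrays of identical shape (any dimensionality).
#' @return percentage in `[0, 100]`.
#' @examples
#' dsc(matrix(c(1, 1, 0, 0), 2), matrix(c(1, 0, 1, 0), 2))  # 50
#' @export
dsc <- function(P, G) {
  check_same_shape(P, G)
  p <- as.logical(P); g <- as.logical(G)
  sp <- sum(p); sg <- sum(g)
  if (sp + sg == 0) return(100)
  200 * sum(p & g) / (sp + sg)
}

#' Intersection over union
#'
#' `|P n G| / |P u G|`. Two empty masks score 1 by convention.
#'
#' @inheritParams dsc
#' @return value in `[0, 1]`.
#' @export
iou <- function(P, G) {
  check_same_shape(P, G)
  p <- as.logical(P); g <- as.logical(G)
  u <- sum(p | g)
  if (u == 0) return(1)
  sum(p & g) / u
}

check_same_shape <- function(P, G) {
  if (!identical(dim(P) %||% length(P), dim(G) %||% length(G)))
    stop("masks must have identical shape")
}

# Boundary voxels: foreground with at least one background face-neighbor
# (out-of-bounds counts as background). Works for 2D and 3D masks.
boundary_points <- function(mask) {
  m <- as.array(mask) != 0
  d <- dim(m)
  nd <- length(d)
  interior <- rep(TRUE, length(m))
  dim(interior) <- d
  for (ax in seq_len(nd)) {
    lo <- shift_arr(m, ax, 1L)
    hi <- shift_arr(m, ax, -1L)
    interior <- interior & lo & hi
  }
  which(m & !interior, arr.ind = TRUE)
}

# shift along axis `ax` by `by`, padding with FALSE
shift_arr <- function(m, ax, by) {
  d <- dim(m)
  out <- array(FALSE, d)
  idx_src <- lapply(d, seq_len)
  idx_dst <- idx_src
  n <- d[ax]
  if (by >= n || -by >= n) return(out)
  if (by > 0) {
    idx_dst[[ax]] <- (by + 1):n
    idx_src[[ax]] <- 1:(n - by)
  } else if (by < 0) {
    idx_dst[[ax]] <- 1:(n + by)
    idx_src[[ax]] <- (1 - by):n
  }
  do.call(`[<-`, c(list(out), idx_dst, list(do.call(`[`, c(list(m), idx_src)))))
}

#' 95th-percentile Hausdorff distance between mask boundaries
#'
#' Boundary voxels (foreground with a background face-neighbor) of each mask
#' are extracted, scaled by the physical `spacing`, and the directed
#' point-to-set distances are computed in both directions; the statistic is
#' the 95th percentile of the pooled bidirectional distance set. `P == G`
#' gives 0. If either mask is empty the distance is undefined and `NA` is
#' returned with attribute `undefined = TRUE`; dataset summaries exclude and
#' count such cases.
#'
#' @inheritParams dsc
#' @param spacing physical size of a voxel along each axis (mm); recycled to
#'   the mask dimensionality.
#' @param percentile percentile of the pooled surface distances (95).
#' @return distance in mm, or flagged `NA`.
#' @export
hd95 <- function(P, G, spacing = NULL, percentile = 95) {
  check_same_shape(P, G)
  nd <- length(dim(as.array(P)))
  if (is.null(spacing)) spacing <- rep(1, nd)
  spacing <- rep_len(spacing, nd)
  if (sum(P != 0) == 0 || sum(G != 0) == 0)
    return(structure(NA_real_, undefined = TRUE))
  bp <- boundary_points(P)
  bg <- boundary_points(G)
  A <- sweep(bp, 2L, spacing, `*`)
  B <- sweep(bg, 2L, spacing, `*`)
  pooled <- c(cpp_min_dists(A, B), cpp_min_dists(B, A))
  unname(stats::quantile(pooled, percentile / 100))
}

#' Per-class metric report for one case
#'
#' Computes DSC, HD95 and IOU for every foreground class of a predicted
#' integer mask against the ground truth. Classes empty in both masks score
#' the both-empty conventions (DSC 100, IOU 1) with undefined HD95.
#'
#' @param pred,truth integer label masks (2D, or 3D stacks of slices) with
#'   labels in `0 .. num_classes - 1`.
#' @param num_classes class count including background (default: deduced
#'   from `truth`).
#' @param spacing voxel spacing in mm.
#' @param case case identifier recorded in the report.
#' @return a tibble of class `m3_metrics`, one row per foreground class:
#'   `case`, `class`, `dsc`, `hd95`, `iou`, `hd95_defined`.
#' @export
evaluate_masks <- function(pred, truth, num_classes = NULL, spacing = NULL,
                           case = "case") {
  check_same_shape(pred, truth)
  if (is.null(num_classes)) num_classes <- max(truth, pred) + 1L
  rows <- lapply(seq_len(num_classes - 1L), function(cl) {
    Pc <- pred == cl
    Gc <- truth == cl
    h <- hd95(Pc, Gc, spacing)
    tibble::tibble(case = case, class = cl,
                   dsc = dsc(Pc, Gc), hd95 = as.numeric(h), iou = iou(Pc, Gc),
                   hd95_defined = !isTRUE(attr(h, "undefined")))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("m3_metrics", class(out))
  out
}

#' Summarize a metric report
#'
#' Means over foreground classes (and cases); undefined HD95 entries are
#' excluded from the HD95 mean and counted.
#'
#' @param report an `m3_metrics` tibble (rows from one or more cases).
#' @return one-row tibble: `mean_dsc`, `mean_hd95`, `mean_iou`, `n_classes`,
#'   `n_hd95_undefined`.
#' @export
summarize_metrics <- function(report) {
  tibble::tibble(
    mean_dsc = mean(report$dsc),
    mean_hd95 = if (any(report$hd95_defined))
      mean(report$hd95[report$hd95_defined]) else NA_real_,
    mean_iou = mean(report$iou),
    n_classes = nrow(report),
    n_hd95_undefined = sum(!report$hd95_defined)
  )
}

#' Write a metric report as CSV plus a JSON summary
#'
#' @param report an `m3_metrics` tibble.
#' @param csv_path,json_path output paths (`NULL` skips either file).
#' @return the summary tibble, invisibly.
#' @export
write_metric_report <- function(report, csv_path = NULL, json_path = NULL) {
  s <- summarize_metrics(report)
  if (!is.null(csv_path)) utils::write.csv(report, csv_path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(as.list(s), json_path, auto_unbox = TRUE, digits = NA)
  invisible(s)
}
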