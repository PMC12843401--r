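# Reverse-mode automatic differentiation over plain R arrays.
#
# A "tape" records every differentiable operation in creation order, which is
# a valid topological order, so backpropagation is a single reverse sweep.
# Ops are dual-mode: with no active tape (or only plain-array inputs) they
# compute values and return plain arrays, so the same forward code serves
# training and inference.

the <- new.env(parent = emptyenv())
the$tape <- NULL

is_node <- function(x) inherits(x, "ag_node")

#' @noRd
vof <- function(x) if (is_node(x)) x$v else x

ag_tape_start <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- vector("list", 1024L)
  t$n <- 0L
  the$tape <- t
  invisible(t)
}

ag_tape_stop <- function() {
  the$tape <- NULL
  invisible(NULL)
}

# Record a computed value as a node if a tape is active and at least one
# input is itself a node. `bf(g)` must return a list of gradients aligned
# with `ins` (NULL entries allowed for non-differentiable inputs).
emit <- function(value, ins, bf) {
  t <- the$tape
  if (is.null(t)) return(value)
  hit <- FALSE
  for (x in ins) if (inherits(x, "ag_node")) { hit <- TRUE; break }
  if (!hit) return(value)
  nd <- new.env(parent = emptyenv())
  nd$v <- value
  nd$g <- NULL
  nd$ins <- ins
  nd$bf <- bf
  class(nd) <- "ag_node"
  n <- t$n + 1L
  if (n > length(t$nodes)) t$nodes <- c(t$nodes, vector("list", length(t$nodes)))
  t$nodes[[n]] <- nd
  t$n <- n
  nd
}

# A leaf (trainable parameter). Always recorded when a tape is active so its
# gradient can be collected after the backward sweep.
ag_leaf <- function(value, name = NULL) {
  t <- the$tape
  if (is.null(t)) return(value)
  nd <- new.env(parent = emptyenv())
  nd$v <- value
  nd$g <- NULL
  nd$ins <- list()
  nd$bf <- NULL
  nd$name <- name
  class(nd) <- "ag_node"
  n <- t$n + 1L
  if (n > length(t$nodes)) t$nodes <- c(t$nodes, vector("list", length(t$nodes)))
  t$nodes[[n]] <- nd
  t$n <- n
  nd
}

# Backward sweep from a scalar loss node. After the call every node reached
# by the chain rule carries its gradient in `$g`.
ag_backward <- function(loss) {
  stopifnot(is_node(loss))
  t <- the$tape
  if (is.null(t)) stop("no active tape")
  loss$g <- 1
  for (i in seq.int(t$n, 1L)) {
    nd <- t$nodes[[i]]
    if (is.null(nd$g) || is.null(nd$bf)) next
    gs <- nd$bf(nd$g)
    ins <- nd$ins
    for (j in seq_along(ins)) {
      p <- ins[[j]]
      if (is_node(p) && !is.null(gs[[j]])) {
        p$g <- if (is.null(p$g)) gs[[j]] else p$g + gs[[j]]
      }
    }
  }
  invisible(loss)
}
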