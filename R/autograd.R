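## Minimal reverse-mode automatic differentiation over 4-D feature arrays.
##
## A feature block is an R array with dim c(H, W, C, N) (height, width,
## channels, batch). Graph nodes are environments; a tape (list of ops in
## execution order) is replayed in reverse to accumulate gradients.
## Coarse-grained ops (whole convolutions) keep the tape short, so plain R
## closures are fast enough: all heavy lifting happens in the C++ kernels.

#' Create an autograd tape
#'
#' A tape records every differentiable operation executed with it as the
#' `tape` argument. Passing `tape = NULL` to the same ops runs them in pure
#' inference mode with no recording.
#'
#' @return an environment of class `ag_tape`
#' @keywords internal
#' @export
ag_tape <- function() {
  e <- new.env(parent = emptyenv())
  e$ops <- vector("list", 64L)
  e$n <- 0L
  class(e) <- "ag_tape"
  e
}

#' @keywords internal
#' @export
ag_node <- function(value) {
  e <- new.env(parent = emptyenv())
  e$v <- value
  e$g <- NULL
  class(e) <- "ag_node"
  e
}

#' @keywords internal
#' @keywords internal
#' @export
ag_value <- function(x) if (inherits(x, "ag_node")) x$v else x

ag_record <- function(tape, out, inputs, backward) {
  if (is.null(tape)) return(invisible(out))
  n <- tape$n + 1L
  if (n > length(tape$ops)) tape$ops <- c(tape$ops, vector("list", length(tape$ops)))
  tape$ops[[n]] <- list(out = out, inputs = inputs, backward = backward)
  tape$n <- n
  invisible(out)
}

ag_accum <- function(node, g) {
  if (is.null(node$g)) node$g <- g else node$g <- node$g + g
}

#' Run the backward pass over a tape
#'
#' Seeds the gradient of `loss` with 1 and propagates to every recorded
#' input. Parameter gradients are afterwards available through
#' [param_grad()].
#'
#' @param tape an [ag_tape()] that recorded the forward pass
#' @param loss the scalar output node
#' @keywords internal
#' @keywords internal
#' @export
ag_backward <- function(tape, loss) {
  stopifnot(inherits(tape, "ag_tape"), inherits(loss, "ag_node"))
  loss$g <- 1
  for (i in seq(tape$n, 1L)) {
    op <- tape$ops[[i]]
    g <- op$out$g
    if (is.null(g)) next
    gs <- op$backward(g)
    for (j in seq_along(op$inputs)) {
      inp <- op$inputs[[j]]
      if (inherits(inp, "ag_node") && !is.null(gs[[j]])) ag_accum(inp, gs[[j]])
    }
  }
  invisible(NULL)
}

## ---- parameters -----------------------------------------------------------

#' Create a trainable parameter
#'
#' Parameters are persistent environments holding the value, the gradient
#' accumulator and the Adam moment estimates.
#'
#' @param value initial numeric array
#' @param name human-readable identifier used in audit breakdowns
#' @keywords internal
#' @keywords internal
#' @export
new_param <- function(value, name = "") {
  e <- new.env(parent = emptyenv())
  e$v <- value
  e$g <- NULL
  e$m <- NULL
  e$u <- NULL
  e$name <- name
  class(e) <- "ag_param"
  e
}

param_grad <- function(p) p$g

## Wrap a parameter as a graph node; after ag_backward the node gradient is
## pushed into the parameter's accumulator (summing over reuse, which is how
## weight tying across applications works).
ag_use_param <- function(tape, p) {
  n <- ag_node(p$v)
  ag_record(tape, n, list(), function(g) list())
  if (!is.null(tape)) {
    n_idx <- tape$n
    tape$ops[[n_idx]]$backward <- function(g) {
      if (is.null(p$g)) p$g <- g else p$g <- p$g + g
      list()
    }
    tape$ops[[n_idx]]$inputs <- list()
  }
  n
}

## Collect every ag_param reachable in a nested list structure, with
## dotted-path names.
#' @keywords internal
#' @export
collect_params <- function(x, prefix = "") {
  if (inherits(x, "ag_param")) {
    out <- list(x)
    names(out) <- prefix
    return(out)
  }
  if (is.list(x)) {
    out <- list()
    nms <- names(x)
    for (i in seq_along(x)) {
      nm <- if (!is.null(nms) && nzchar(nms[i])) nms[i] else as.character(i)
      p <- if (nzchar(prefix)) paste0(prefix, ".", nm) else nm
      out <- c(out, collect_params(x[[i]], p))
    }
    return(out)
  }
  list()
}

#' @keywords internal
#' @export
zero_grads <- function(params) {
  for (p in params) p$g <- NULL
  invisible(NULL)
}

## ---- elementwise / structural ops ----------------------------------------

#' @keywords internal
#' @export
ag_lift <- function(x) if (inherits(x, "ag_node")) x else ag_node(x)

#' @keywords internal
#' @export
op_add <- function(tape, a, b) {
  a <- ag_lift(a); b <- ag_lift(b)
  out <- ag_node(a$v + b$v)
  ag_record(tape, out, list(a, b), function(g) list(g, g))
  out
}

#' @keywords internal
#' @export
op_sub <- function(tape, a, b) {
  a <- ag_lift(a); b <- ag_lift(b)
  out <- ag_node(a$v - b$v)
  ag_record(tape, out, list(a, b), function(g) list(g, -g))
  out
}

#' @keywords internal
#' @export
op_scale <- function(tape, a, k) {
  a <- ag_lift(a)
  out <- ag_node(a$v * k)
  ag_record(tape, out, list(a), function(g) list(g * k))
  out
}

#' @keywords internal
#' @export
op_concat_c <- function(tape, xs) {
  xs <- lapply(xs, ag_lift)
  dims <- lapply(xs, function(x) dim(x$v))
  cs <- vapply(dims, function(d) d[3], numeric(1))
  d0 <- dims[[1]]
  for (d in dims) stopifnot(all(d[c(1, 2, 4)] == d0[c(1, 2, 4)]))
  val <- array(0, dim = c(d0[1], d0[2], sum(cs), d0[4]))
  at <- 0L
  for (i in seq_along(xs)) {
    val[, , at + seq_len(cs[i]), ] <- xs[[i]]$v
    at <- at + cs[i]
  }
  out <- ag_node(val)
  ag_record(tape, out, xs, function(g) {
    at <- 0L
    gs <- vector("list", length(xs))
    for (i in seq_along(xs)) {
      gi <- g[, , at + seq_len(cs[i]), , drop = FALSE]
      dim(gi) <- dims[[i]]
      gs[[i]] <- gi
      at <- at + cs[i]
    }
    gs
  })
  out
}

#' @keywords internal
#' @export
op_prelu <- function(tape, x, slope_param) {
  x <- ag_lift(x)
  s <- ag_use_param(tape, slope_param)
  sv <- as.numeric(s$v)[1]
  neg <- !is.na(x$v) & x$v < 0 # NaN activations pass through unchanged
  val <- x$v
  val[neg] <- val[neg] * sv
  out <- ag_node(val)
  ag_record(tape, out, list(x, s), function(g) {
    gx <- g
    gx[neg] <- gx[neg] * sv
    gs <- sum(g[neg] * x$v[neg])
    list(gx, gs)
  })
  out
}

#' @keywords internal
#' @export
op_sigmoid <- function(tape, x) {
  x <- ag_lift(x)
  val <- 1 / (1 + exp(-x$v))
  out <- ag_node(val)
  ag_record(tape, out, list(x), function(g) list(g * val * (1 - val)))
  out
}

## global average pool over H,W -> (1,1,C,N)
#' @keywords internal
#' @export
op_gap <- function(tape, x) {
  x <- ag_lift(x)
  d <- dim(x$v)
  val <- apply(x$v, c(3, 4), mean)
  val <- array(val, dim = c(1, 1, d[3], d[4]))
  out <- ag_node(val)
  ag_record(tape, out, list(x), function(g) {
    gper <- g / (d[1] * d[2])
    list(array(rep(gper, each = d[1] * d[2]), dim = d))
  })
  out
}

## multiply x (H,W,C,N) by per-channel gates (1,1,C,N)
#' @keywords internal
#' @export
op_chanmul <- function(tape, x, gate) {
  x <- ag_lift(x); gate <- ag_lift(gate)
  d <- dim(x$v)
  gx <- array(rep(gate$v, each = d[1] * d[2]), dim = d)
  out <- ag_node(x$v * gx)
  ag_record(tape, out, list(x, gate), function(g) {
    dgate <- apply(g * x$v, c(3, 4), sum)
    list(g * gx, array(dgate, dim = dim(gate$v)))
  })
  out
}

## mean absolute error against a constant target
#' @keywords internal
#' @export
op_l1_loss <- function(tape, pred, target) {
  pred <- ag_lift(pred)
  if (length(target) != length(pred$v)) stop("op_l1_loss: size mismatch")
  if (!is.null(dim(pred$v))) dim(target) <- dim(pred$v)
  diff <- pred$v - target
  val <- mean(abs(diff))
  out <- ag_node(val)
  n <- length(diff)
  ag_record(tape, out, list(pred), function(g) list(g * sign(diff) / n))
  out
}

## ---- convolution ops ------------------------------------------------------

#' @keywords internal
#' @export
op_conv2d <- function(tape, x, wp, bp, k, stride, pad) {
  x <- ag_lift(x)
  w <- ag_use_param(tape, wp)
  b <- ag_use_param(tape, bp)
  xd <- dim(x$v)
  y <- cpp_conv2d_fwd(x$v, as.integer(xd), w$v, b$v, k, stride, pad)
  out <- ag_node(y)
  yd <- dim(y)
  ag_record(tape, out, list(x, w, b), function(g) {
    r <- cpp_conv2d_bwd(x$v, as.integer(xd), w$v, g, as.integer(yd),
                        k, stride, pad, TRUE)
    list(r$dx, r$dw, r$db)
  })
  out
}

#' @keywords internal
#' @export
op_convt2d <- function(tape, x, wp, bp, k, stride, pad) {
  x <- ag_lift(x)
  w <- ag_use_param(tape, wp)
  b <- ag_use_param(tape, bp)
  xd <- dim(x$v)
  y <- cpp_convt2d_fwd(x$v, as.integer(xd), w$v, b$v, k, stride, pad)
  out <- ag_node(y)
  yd <- dim(y)
  ag_record(tape, out, list(x, w, b), function(g) {
    r <- cpp_convt2d_bwd(x$v, as.integer(xd), w$v, g, as.integer(yd),
                         k, stride, pad, TRUE)
    list(r$dx, r$dw, r$db)
  })
  out
}
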