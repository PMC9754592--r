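## Core architectural primitives: per-scale resampling geometry, conv /
## transposed-conv layers with PReLU activations, residual groups, and the
## structural audit (parameter counting).

#' Per-scale resampling geometry
#'
#' Returns the kernel/stride/pad triple that realises an exact `x scale`
#' up-sampling with a transposed convolution (and an exact `/ scale`
#' down-sampling with a strided convolution). The four supported triples all
#' satisfy `kernel - 2 * pad == stride == scale`, which makes the transposed
#' convolution output exactly `scale * input` pixels.
#'
#' @param scale integer scale factor, one of 1, 2, 3, 4
#' @return an object of class `scale_config` with fields `scale`, `kernel`,
#'   `stride`, `pad`
#' @examples
#' make_scale_config(4) # kernel 8, stride 4, pad 2
#' @export
make_scale_config <- function(scale) {
  cfgs <- list(
    `1` = c(kernel = 3L, stride = 1L, pad = 1L),
    `2` = c(kernel = 6L, stride = 2L, pad = 2L),
    `3` = c(kernel = 7L, stride = 3L, pad = 2L),
    `4` = c(kernel = 8L, stride = 4L, pad = 2L)
  )
  key <- as.character(scale)
  if (length(scale) != 1L || is.na(scale) || !key %in% names(cfgs)) {
    stop("unsupported scale ", deparse(substitute(scale)), " = ",
         paste(scale, collapse = ","), "; allowed scales are 1, 2, 3, 4")
  }
  cfg <- cfgs[[key]]
  structure(list(scale = as.integer(scale), kernel = cfg[["kernel"]],
                 stride = cfg[["stride"]], pad = cfg[["pad"]]),
            class = "scale_config")
}

#' @export
print.scale_config <- function(x, ...) {
  cat(sprintf("scale_config: x%d (kernel %d, stride %d, pad %d)\n",
              x$scale, x$kernel, x$stride, x$pad))
  invisible(x)
}

## ---- layers ---------------------------------------------------------------

## Kaiming fan-in init, gain for PReLU(0.25). Draws from the current RNG
## state so builds are seedable with set.seed().
kaiming_init <- function(dims, fan_in, act) {
  gain <- if (act) sqrt(2 / (1 + 0.25^2)) else 1
  array(stats::rnorm(prod(dims), sd = gain / sqrt(fan_in)), dim = dims)
}

#' Construct a convolution layer
#'
#' @param cin,cout channel counts
#' @param k,stride,pad kernel geometry
#' @param act logical, apply a PReLU (one learned slope per layer) after the
#'   convolution
#' @param transpose logical, build a transposed (up-sampling) convolution
#' @keywords internal
#' @export
layer_conv <- function(cin, cout, k, stride = 1L, pad = (k - 1L) %/% 2L,
                       act = TRUE, transpose = FALSE, name = "conv") {
  wd <- if (transpose) c(k, k, cout, cin) else c(k, k, cin, cout)
  l <- list(
    type = if (transpose) "deconv" else "conv",
    k = as.integer(k), stride = as.integer(stride), pad = as.integer(pad),
    cin = cin, cout = cout, act = act,
    w = new_param(kaiming_init(wd, cin * k * k, act), paste0(name, ".w")),
    b = new_param(numeric(cout), paste0(name, ".b"))
  )
  if (act) l$slope <- new_param(0.25, paste0(name, ".prelu"))
  class(l) <- "ag_layer"
  l
}

## Forward application of a layer. `probe_linear = TRUE` skips the
## activation (used by linearity/oracle tests).
#' @export
fwd_layer <- function(tape, l, x, probe_linear = FALSE) {
  y <- if (l$type == "deconv") {
    op_convt2d(tape, x, l$w, l$b, l$k, l$stride, l$pad)
  } else {
    op_conv2d(tape, x, l$w, l$b, l$k, l$stride, l$pad)
  }
  if (l$act && !probe_linear) y <- op_prelu(tape, y, l$slope)
  y
}

#' Learned up-sampling layer
#'
#' Transposed convolution (plus PReLU) whose geometry multiplies the spatial
#' dimensions exactly by `cfg$scale`.
#'
#' @param x a feature array `dim c(H, W, C, N)` or an autograd node
#' @param layer a layer built with [make_upsample_layer()]
#' @param tape optional autograd tape
#' @return feature array (or node) with spatial dims scaled up
#' @export
upsample_layer <- function(x, layer, tape = NULL) {
  stopifnot(identical(layer$type, "deconv"))
  xv <- ag_value(x)
  if (any(!is.finite(xv))) stop("upsample_layer: non-finite input")
  out <- fwd_layer(tape, layer, x)
  if (is.null(tape) && !inherits(x, "ag_node")) ag_value(out) else out
}

#' Learned down-sampling layer
#'
#' Strided convolution (plus PReLU); input spatial dims must be divisible by
#' the scale.
#'
#' @inheritParams upsample_layer
#' @export
downsample_layer <- function(x, layer, tape = NULL) {
  stopifnot(identical(layer$type, "conv"))
  xv <- ag_value(x)
  d <- dim(xv)
  s <- layer$stride
  if (d[1] %% s != 0 || d[2] %% s != 0) {
    stop(sprintf("downsample_layer: spatial dims %dx%d not divisible by scale %d; pad first",
                 d[1], d[2], s))
  }
  out <- fwd_layer(tape, layer, x)
  if (is.null(tape) && !inherits(x, "ag_node")) ag_value(out) else out
}

#' @rdname upsample_layer
#' @param channels channel count (preserved)
#' @param cfg a [make_scale_config()]
#' @export
make_upsample_layer <- function(cfg, channels = 64L, act = TRUE) {
  layer_conv(channels, channels, cfg$kernel, cfg$stride, cfg$pad,
             act = act, transpose = TRUE, name = sprintf("up%dx", cfg$scale))
}

#' @rdname downsample_layer
#' @inheritParams make_upsample_layer
#' @export
make_downsample_layer <- function(cfg, channels = 64L, act = TRUE) {
  layer_conv(channels, channels, cfg$kernel, cfg$stride, cfg$pad,
             act = act, transpose = FALSE, name = sprintf("down%dx", cfg$scale))
}

#' Residual group
#'
#' Two 3x3 convolutions (PReLU after the first) with an identity skip:
#' `x + f(x)`. Zero-initialised weights make it an exact identity.
#'
#' @export
make_residual_group <- function(channels = 64L, name = "rg") {
  l <- list(
    conv1 = layer_conv(channels, channels, 3L, 1L, 1L, act = TRUE,
                       name = paste0(name, ".conv1")),
    conv2 = layer_conv(channels, channels, 3L, 1L, 1L, act = FALSE,
                       name = paste0(name, ".conv2"))
  )
  class(l) <- c("residual_group", "ag_module")
  l
}

#' @rdname make_residual_group
#' @param x feature array or node
#' @param group a `residual_group`
#' @param tape optional autograd tape
#' @export
residual_group <- function(x, group, tape = NULL) {
  h <- fwd_layer(tape, group$conv1, x)
  h <- fwd_layer(tape, group$conv2, h)
  out <- op_add(tape, ag_lift(x), h)
  if (is.null(tape) && !inherits(x, "ag_node")) ag_value(out) else out
}

## ---- audit ----------------------------------------------------------------

#' Count trainable parameters of a model
#'
#' Walks the model structure, counting every weight, bias and activation
#' slope exactly once (weight-tied layers are stored once and therefore
#' counted once). Returns totals, a per-module breakdown keyed by the first
#' path component, the total rounded to the nearest thousand, and the
#' model's depth (conv/deconv layers on the longest input-to-output path,
#' taken from the model's own metadata when available).
#'
#' @param model a built model (e.g. [build_msbpn()] / [build_msbfan()]), or
#'   any nested list containing parameters
#' @return an object of class `audit_report`
#' @export
count_parameters <- function(model) {
  ps <- collect_params(model)
  sizes <- vapply(ps, function(p) length(p$v), numeric(1))
  top <- vapply(strsplit(names(ps), ".", fixed = TRUE), `[[`, "", 1L)
  per <- tapply(sizes, top, sum)
  total <- sum(sizes)
  depth <- if (is.list(model) && !is.null(model$meta$depth)) model$meta$depth else NA_integer_
  structure(list(
    total_params = as.integer(total),
    params_K = as.integer(round(total / 1000)),
    per_module_params = as.list(as.integer(per) |> stats::setNames(names(per))),
    depth = depth
  ), class = "audit_report")
}

#' @export
print.audit_report <- function(x, ...) {
  cat(sprintf("audit_report: %s parameters (%sK), depth %s\n",
              format(x$total_params, big.mark = ","),
              format(x$params_K, big.mark = ","),
              ifelse(is.na(x$depth), "NA", x$depth)))
  for (nm in names(x$per_module_params)) {
    cat(sprintf("  %-12s %s\n", nm,
                format(x$per_module_params[[nm]], big.mark = ",")))
  }
  invisible(x)
}

#' Serialise an audit report as JSON
#'
#' @param report an `audit_report`
#' @param path optional file path; if missing the JSON string is returned
#' @export
audit_json <- function(report, path = NULL) {
  js <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    invisible(js)
  } else {
    js
  }
}
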