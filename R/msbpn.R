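## MSBPN: the single-image multi-scale back-projection network.
##
## A shared shallow feature is refined in parallel scale branches. A branch
## of scale s stacks (m + 1) projection stages; every stage runs n
## weight-tied back-projection pairs. One pair owns a single up-layer U and
## a single down-layer D (kernel geometry from make_scale_config(s)) and
## applies an up-projection followed by a down-projection with those two
## operators, so each pair contributes exactly two parameterised layers.
## Branches emit refined LR-domain features ("synthesized LR features");
## channel selection fuses them at LR resolution, a shared target-scale
## up-layer maps to the HR domain, and a 3x3 convolution reconstructs the
## image, to which a parameter-free bicubic skip of the input is added.

#' MSBPN configuration
#'
#' @param scales integer vector of branch scales; the default `1:target`
#'   uses one branch per scale up to the SR factor
#' @param m number of densely connected refinement stages (each branch has
#'   `m + 1` projection stages in total)
#' @param n back-projection pairs per stage
#' @param dense logical; reuse all preceding stage outputs (additive dense
#'   connections) as the input of each refinement stage
#' @param channels feature width (64 in the reference configuration)
#' @param in_channels input image channels (1 for grayscale MR)
#' @param validate enforce the `scales == 1:target` invariant; disable to
#'   build the single-scale ablation variant (e.g. `scales = c(4,4,4,4)`)
#' @return an object of class `projection_spec`
#' @export
projection_spec <- function(scales = 1:4, m = 1L, n = 1L, dense = TRUE,
                            channels = 64L, in_channels = 1L,
                            validate = TRUE) {
  scales <- as.integer(scales)
  stopifnot(length(scales) >= 1, m >= 1, n >= 1, channels >= 1)
  for (s in scales) make_scale_config(s) # validates membership in 1..4
  if (validate && !identical(sort(scales), seq_len(max(scales)))) {
    stop("scales must be exactly 1..target factor (got ",
         paste(scales, collapse = ","), "); use validate = FALSE for ",
         "single-scale ablation variants")
  }
  structure(list(scales = scales, m = as.integer(m), n = as.integer(n),
                 dense = isTRUE(dense), channels = as.integer(channels),
                 in_channels = as.integer(in_channels)),
            class = "projection_spec")
}

## ---- projection primitives ------------------------------------------------

#' Back-projection refinement operators
#'
#' `up_projection` maps an LR-domain feature to the HR domain with residual
#' refinement: `H0 = U(L); e = D(H0) - L; H = H0 + U(e)`. `down_projection`
#' is the mirror image: `L0 = D(H); e = U(L0) - H; L = L0 + D(e)`. Both use
#' one up-layer and one down-layer; the up (down) operator is reused for the
#' refinement term, which is what makes a full back-projection pair cost two
#' parameterised layers.
#'
#' @param x feature array or autograd node (LR domain for `up_projection`,
#'   HR domain for `down_projection`)
#' @param up,down layers from [make_upsample_layer()] /
#'   [make_downsample_layer()] sharing one [make_scale_config()]
#' @param tape optional autograd tape
#' @param probe_linear skip activations (linear probe for oracle tests)
#' @export
up_projection <- function(x, up, down, tape = NULL, probe_linear = FALSE) {
  xn <- ag_lift(x)
  h0 <- fwd_layer(tape, up, xn, probe_linear)
  e <- op_sub(tape, fwd_layer(tape, down, h0, probe_linear), xn)
  h <- op_add(tape, h0, fwd_layer(tape, up, e, probe_linear))
  if (is.null(tape) && !inherits(x, "ag_node")) ag_value(h) else h
}

#' @rdname up_projection
#' @export
down_projection <- function(x, up, down, tape = NULL, probe_linear = FALSE) {
  xn <- ag_lift(x)
  l0 <- fwd_layer(tape, down, xn, probe_linear)
  e <- op_sub(tape, fwd_layer(tape, up, l0, probe_linear), xn)
  l <- op_add(tape, l0, fwd_layer(tape, down, e, probe_linear))
  if (is.null(tape) && !inherits(x, "ag_node")) ag_value(l) else l
}

bp_pair_forward <- function(tape, pair, x, probe_linear = FALSE) {
  h <- up_projection(x, pair$up, pair$down, tape, probe_linear)
  down_projection(h, pair$up, pair$down, tape, probe_linear)
}

## ---- concat + 1x1 utilities ----------------------------------------------

#' Dense feature compression
#'
#' Concatenates same-shape feature blocks along channels and applies a
#' learned 1x1 convolution back to `channels`. With a single input and
#' identity-initialised weights this is an exact identity. The reference
#' MSBPN uses parameter-free additive dense connections (see the methods
#' vignette); this op backs the optional concatenation dense mode.
#'
#' @param features list of feature arrays/nodes with identical shapes
#' @param layer a layer from [make_dense_compress()]
#' @param tape optional autograd tape
#' @export
dense_compress <- function(features, layer, tape = NULL) {
  stopifnot(length(features) >= 1)
  cat_in <- if (length(features) == 1L) ag_lift(features[[1]]) else
    op_concat_c(tape, features)
  out <- fwd_layer(tape, layer, cat_in)
  if (is.null(tape) && !inherits(features[[1]], "ag_node")) ag_value(out) else out
}

#' @rdname dense_compress
#' @param k number of concatenated inputs
#' @param channels feature width
#' @param identity_init initialise as the averaging identity over the k
#'   inputs instead of random weights
#' @export
make_dense_compress <- function(k, channels = 64L, identity_init = FALSE) {
  l <- layer_conv(k * channels, channels, 1L, 1L, 0L, act = FALSE,
                  name = "compress")
  if (identity_init) {
    w <- array(0, dim = c(1, 1, k * channels, channels))
    for (i in seq_len(k)) {
      for (c in seq_len(channels)) w[1, 1, (i - 1) * channels + c, c] <- 1 / k
    }
    l$w$v <- w
    l$b$v <- numeric(channels)
  }
  l
}

#' Channel selection over per-branch features
#'
#' Concatenates the per-scale branch outputs along channels and applies a
#' learned 1x1 selection convolution back to `channels` (with PReLU).
#'
#' @param features list of same-shape per-branch feature blocks
#' @param layer layer from [make_channel_selection()]
#' @param tape optional autograd tape
#' @export
channel_selection <- function(features, layer, tape = NULL) {
  stopifnot(length(features) >= 1)
  cat_in <- if (length(features) == 1L) ag_lift(features[[1]]) else
    op_concat_c(tape, features)
  out <- fwd_layer(tape, layer, cat_in)
  if (is.null(tape) && !inherits(features[[1]], "ag_node")) ag_value(out) else out
}

#' @rdname channel_selection
#' @param n_branches number of branches feeding the selection
#' @param channels feature width
#' @param act apply PReLU after the 1x1 convolution
#' @export
make_channel_selection <- function(n_branches, channels = 64L, act = TRUE) {
  layer_conv(n_branches * channels, channels, 1L, 1L, 0L, act = act,
             name = "select")
}

## ---- model construction ---------------------------------------------------

build_scale_branch <- function(scale, spec) {
  cfg <- make_scale_config(scale)
  stages <- vector("list", spec$m + 1L)
  for (j in seq_along(stages)) {
    pairs <- vector("list", spec$n)
    for (p in seq_along(pairs)) {
      pairs[[p]] <- list(
        up = make_upsample_layer(cfg, spec$channels),
        down = make_downsample_layer(cfg, spec$channels)
      )
    }
    stages[[j]] <- list(pairs = pairs)
  }
  list(scale = scale, cfg = cfg, stages = stages)
}

#' Build an MSBPN model
#'
#' @param spec a [projection_spec()]
#' @param target_scale SR factor; defaults to `max(spec$scales)`
#' @param seed optional integer seed for weight initialisation
#' @param global_residual add a parameter-free bicubic skip of the input to
#'   the reconstruction (default TRUE; see the methods vignette)
#' @param zero_init_head zero-initialise the reconstruction convolution so
#'   that, with the bicubic skip, the untrained model reproduces the
#'   bicubic baseline exactly (default TRUE)
#' @return an object of class `msbp_model`
#' @export
build_msbpn <- function(spec, target_scale = max(spec$scales), seed = NULL,
                        global_residual = TRUE, zero_init_head = TRUE) {
  stopifnot(inherits(spec, "projection_spec"))
  if (!is.null(seed)) set.seed(seed)
  tcfg <- make_scale_config(target_scale)
  c <- spec$channels
  model <- list(
    feat = layer_conv(spec$in_channels, c, 3L, 1L, 1L, act = TRUE, name = "feat"),
    branches = lapply(spec$scales, build_scale_branch, spec = spec),
    select = make_channel_selection(length(spec$scales), c),
    up_final = make_upsample_layer(tcfg, c),
    recon = {
      l <- layer_conv(c, 1L, 3L, 1L, 1L, act = FALSE, name = "recon")
      if (isTRUE(zero_init_head)) l$w$v[] <- 0
      l
    },
    meta = list(
      spec = spec, target_scale = as.integer(target_scale),
      global_residual = isTRUE(global_residual),
      # depth: total up/down layer count across branches (the convention
      # that reproduces the printed depth column; see vignette)
      depth = 2L * spec$n * (spec$m + 1L) * length(spec$scales)
    )
  )
  class(model) <- c("msbp_model", "ag_module")
  model
}

#' Run one scale branch
#'
#' Applies the branch's `m + 1` projection stages to the shared shallow
#' feature `S`, with additive dense reuse of all preceding stage outputs
#' when the spec requests it, and returns the refined LR-domain feature.
#'
#' @param S shallow feature array or node
#' @param branch one element of `model$branches`
#' @param dense logical, dense connections on
#' @param tape optional autograd tape
#' @param probe_linear skip activations
#' @export
scale_branch_forward <- function(S, branch, dense = TRUE, tape = NULL,
                                 probe_linear = FALSE) {
  s0 <- ag_lift(S)
  outs <- list()
  inp <- s0
  for (stage in branch$stages) {
    if (length(outs) > 0) {
      inp <- if (dense) {
        acc <- s0
        for (o in outs) acc <- op_add(tape, acc, o)
        acc
      } else {
        outs[[length(outs)]]
      }
    }
    x <- inp
    for (pair in stage$pairs) x <- bp_pair_forward(tape, pair, x, probe_linear)
    outs[[length(outs) + 1L]] <- x
  }
  out <- outs[[length(outs)]]
  if (is.null(tape) && !inherits(S, "ag_node")) ag_value(out) else out
}

as_hwcn <- function(img) {
  if (is.matrix(img)) {
    dim(img) <- c(dim(img), 1L, 1L)
  } else if (length(dim(img)) == 3L) {
    dim(img) <- c(dim(img), 1L)
  }
  stopifnot(length(dim(img)) == 4L)
  img
}

## core forward shared by training (tape) and inference
msbpn_forward_node <- function(model, x, tape = NULL, probe_linear = FALSE) {
  spec <- model$meta$spec
  s0 <- fwd_layer(tape, model$feat, ag_lift(x), probe_linear)
  branch_outs <- lapply(model$branches, function(br)
    scale_branch_forward(s0, br, dense = spec$dense, tape = tape,
                         probe_linear = probe_linear))
  sel <- if (length(branch_outs) == 1L) {
    fwd_layer(tape, model$select, branch_outs[[1]], probe_linear)
  } else {
    fwd_layer(tape, model$select, op_concat_c(tape, branch_outs), probe_linear)
  }
  hr <- fwd_layer(tape, model$up_final, sel, probe_linear)
  fwd_layer(tape, model$recon, hr, probe_linear)
}

#' Super-resolve with an MSBPN model
#'
#' @param model a built `msbp_model`
#' @param lr_image LR input: matrix `(H, W)` or array `(H, W, 1, N)`,
#'   intensities in `[0, 1]`
#' @param tape optional autograd tape (training)
#' @param probe_linear skip activations (oracle tests)
#' @return SR output with spatial dims `target_scale` times the input, same
#'   container shape as the input
#' @export
msbpn_forward <- function(model, lr_image, tape = NULL, probe_linear = FALSE) {
  was_matrix <- is.matrix(lr_image)
  x <- as_hwcn(lr_image)
  out <- msbpn_forward_node(model, x, tape, probe_linear)
  if (model$meta$global_residual) {
    mid <- (dim(x)[3] + 1L) %/% 2L # centre channel when slices are stacked
    up <- resize_bicubic_4d(x[, , mid, , drop = FALSE], model$meta$target_scale)
    out <- op_add(tape, out, ag_node(up))
  }
  if (!is.null(tape)) return(out)
  v <- ag_value(out)
  if (was_matrix) v <- v[, , 1, 1]
  v
}

#' @export
predict.msbp_model <- function(object, newdata, ...) {
  msbpn_forward(object, newdata)
}

#' @export
print.msbp_model <- function(x, ...) {
  s <- x$meta$spec
  cat(sprintf("msbp_model: x%d SR, scales [%s], m=%d, n=%d, dense=%s, %d channels\n",
              x$meta$target_scale, paste(s$scales, collapse = ","),
              s$m, s$n, s$dense, s$channels))
  print(count_parameters(x))
  invisible(x)
}
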