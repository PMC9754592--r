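## MSBFAN: bidirectional recurrent spatio-temporal fusion attention network.
##
## One STAM iteration = temporal exploration (TEB, residual groups over a
## target/neighbour pair feature), spatial exploration (SEB, the MSBPN
## backbone), spatio-temporal fusion attention (STAB, channel attention over
## the concatenated streams), and a downsampling block (DB) that returns the
## fused HR feature to the LR domain as the next recurrent state. All STAM
## weights are shared across iterations; neighbours are consumed
## nearest-first, alternating past/future. The reconstruction convolution
## concatenates every STAM's HR output (its width is fixed at build time).

#' Build an MSBFAN model
#'
#' @param seq_len slice-sequence length the model is built for (default 7:
#'   target + 3 past + 3 future); the reconstruction width is
#'   `max(1, n_neighbours) * channels`
#' @param target_scale SR factor (2, 3 or 4)
#' @param spec [projection_spec()] for the SEB backbone; default
#'   `(m = 2, n = 1)` — the single-slice-equivalent MSBPN configuration
#' @param teb_groups residual groups in the TEB (reference uses 9)
#' @param attention_reduction bottleneck reduction r of the fusion attention
#' @param direction "both" (bidirectional), "forward" (past neighbours
#'   only) or "backward" (future only) — the stream ablations
#' @param stab_mode "attention" (squeeze-excitation fusion attention,
#'   default) or "residual" (plain residual fusion: a 3x3 convolution over
#'   the concatenated streams, the fusion-ablation variant)
#' @param seed optional init seed
#' @param global_residual add the bicubic skip of the target slice
#' @param zero_init_head zero-initialise the reconstruction convolution (the
#'   untrained model then starts at the bicubic baseline)
#' @return object of class `msbfan_model`
#' @export
build_msbfan <- function(seq_len = 7L, target_scale = 4L,
                         spec = projection_spec(scales = seq_len_scales(target_scale),
                                                m = 2L, n = 1L),
                         teb_groups = 9L, attention_reduction = 16L,
                         direction = c("both", "forward", "backward"),
                         stab_mode = c("attention", "residual"),
                         seed = NULL, global_residual = TRUE,
                         zero_init_head = TRUE) {
  direction <- match.arg(direction)
  stab_mode <- match.arg(stab_mode)
  stopifnot(seq_len >= 1L)
  if (!is.null(seed)) set.seed(seed)
  tcfg <- make_scale_config(target_scale)
  c <- spec$channels
  n_nb <- n_neighbours_for(seq_len, direction)
  slots <- max(1L, n_nb)
  r <- max(1L, as.integer(attention_reduction))
  model <- list(
    feat_t = layer_conv(1L, c, 3L, 1L, 1L, act = TRUE, name = "feat_t"),
    feat_p = layer_conv(2L, c, 3L, 1L, 1L, act = TRUE, name = "feat_p"),
    teb = lapply(seq_len(teb_groups), function(i)
      make_residual_group(c, name = sprintf("teb.rg%d", i))),
    teb_up = make_upsample_layer(tcfg, c),
    seb = list(
      branches = lapply(spec$scales, build_scale_branch, spec = spec),
      select = make_channel_selection(length(spec$scales), c),
      up_final = make_upsample_layer(tcfg, c)
    ),
    stab = if (stab_mode == "attention") {
      list(
        fc1 = layer_conv(2L * c, max(1L, (2L * c) %/% r), 1L, 1L, 0L,
                         act = TRUE, name = "stab.fc1"),
        fc2 = layer_conv(max(1L, (2L * c) %/% r), 2L * c, 1L, 1L, 0L,
                         act = FALSE, name = "stab.fc2"),
        fuse = layer_conv(2L * c, c, 1L, 1L, 0L, act = TRUE, name = "stab.fuse")
      )
    } else {
      list(fuse3 = layer_conv(2L * c, c, 3L, 1L, 1L, act = TRUE,
                              name = "stab.fuse3"))
    },
    db = make_downsample_layer(tcfg, c),
    recon = {
      l <- layer_conv(slots * c, 1L, 3L, 1L, 1L, act = FALSE, name = "recon")
      if (isTRUE(zero_init_head)) l$w$v[] <- 0
      l
    },
    meta = list(seq_len = as.integer(seq_len), target_scale = as.integer(target_scale),
                spec = spec, teb_groups = as.integer(teb_groups),
                attention_reduction = r, direction = direction,
                stab_mode = stab_mode, slots = slots,
                global_residual = isTRUE(global_residual))
  )
  class(model) <- c("msbfan_model", "ag_module")
  model
}

seq_len_scales <- function(target_scale) seq_len(target_scale)

n_neighbours_for <- function(seq_len, direction) {
  total <- seq_len - 1L
  if (direction == "both") total else total %/% 2L
}

## ---- shallow extraction ---------------------------------------------------

#' Shallow feature extraction
#'
#' `extract_shallow_target` embeds the target slice (3x3 conv, 1 -> c
#' channels). `extract_shallow_pair` channel-concatenates the target with a
#' neighbour slice and embeds the ordered pair (3x3 conv, 2 -> c).
#'
#' @param model a built `msbfan_model`
#' @param I_t,I_k grayscale slices (matrices or `(H,W,1,N)` arrays)
#' @param tape optional autograd tape
#' @export
extract_shallow_target <- function(model, I_t, tape = NULL) {
  out <- fwd_layer(tape, model$feat_t, ag_lift(as_hwcn(I_t)))
  if (is.null(tape)) ag_value(out) else out
}

#' @rdname extract_shallow_target
#' @export
extract_shallow_pair <- function(model, I_t, I_k, tape = NULL) {
  a <- as_hwcn(I_t); b <- as_hwcn(I_k)
  stopifnot(identical(dim(a), dim(b)))
  pair <- op_concat_c(tape, list(ag_lift(a), ag_lift(b)))
  out <- fwd_layer(tape, model$feat_p, pair)
  if (is.null(tape)) ag_value(out) else out
}

## ---- STAM components ------------------------------------------------------

#' Temporal exploration block
#'
#' Applies the shared stack of residual groups to a shallow pair feature;
#' shape preserved.
#' @param T_feat feature array or node
#' @inheritParams extract_shallow_target
#' @export
teb_forward <- function(model, T_feat, tape = NULL) {
  x <- ag_lift(T_feat)
  for (g in model$teb) x <- residual_group(x, g, tape)
  if (is.null(tape) && !inherits(T_feat, "ag_node")) ag_value(x) else x
}

#' Spatial exploration block
#'
#' The MSBPN backbone (scale branches + channel selection + target-scale
#' up-layer) applied to the current recurrent LR feature; returns an
#' HR-domain feature with `channels` maps.
#' @param S_feat LR-domain feature array or node
#' @inheritParams extract_shallow_target
#' @export
seb_forward <- function(model, S_feat, tape = NULL) {
  spec <- model$meta$spec
  s0 <- ag_lift(S_feat)
  branch_outs <- lapply(model$seb$branches, function(br)
    scale_branch_forward(s0, br, dense = spec$dense, tape = tape))
  sel <- if (length(branch_outs) == 1L) {
    fwd_layer(tape, model$seb$select, branch_outs[[1]])
  } else {
    fwd_layer(tape, model$seb$select, op_concat_c(tape, branch_outs))
  }
  out <- fwd_layer(tape, model$seb$up_final, sel)
  if (is.null(tape) && !inherits(S_feat, "ag_node")) ag_value(out) else out
}

#' Spatio-temporal fusion attention (STAB)
#'
#' Concatenates the HR temporal and spatial features, applies
#' squeeze-excitation channel attention (global average pool, bottleneck,
#' sigmoid gates in (0,1), channel rescale) and fuses with a 1x1
#' convolution back to `channels` maps.
#'
#' @param temporal,spatial same-shape HR feature blocks
#' @param gates_identity force all attention gates to 1 (reduces the block
#'   to concatenation + 1x1 fusion; used by tests)
#' @inheritParams extract_shallow_target
#' @export
stab_fuse <- function(model, temporal, spatial, tape = NULL,
                      gates_identity = FALSE) {
  tn <- ag_lift(temporal); sn <- ag_lift(spatial)
  stopifnot(identical(dim(tn$v), dim(sn$v)))
  cat_in <- op_concat_c(tape, list(tn, sn))
  if (!is.null(model$stab$fuse3)) { # residual fusion ablation variant
    out <- fwd_layer(tape, model$stab$fuse3, cat_in)
    return(if (is.null(tape) && !inherits(temporal, "ag_node")) ag_value(out) else out)
  }
  if (gates_identity) {
    gated <- cat_in
  } else {
    g <- op_gap(tape, cat_in)
    g <- fwd_layer(tape, model$stab$fc1, g)
    g <- fwd_layer(tape, model$stab$fc2, g)
    g <- op_sigmoid(tape, g)
    gated <- op_chanmul(tape, cat_in, g)
  }
  out <- fwd_layer(tape, model$stab$fuse, gated)
  if (is.null(tape) && !inherits(temporal, "ag_node")) ag_value(out) else out
}

#' Downsampling block (DB)
#'
#' One shared strided convolution maps the fused HR feature back to the LR
#' domain; the forward- and backward-stream states it emits are the same
#' feature by construction, so the returned pair is identical.
#'
#' @param H HR feature block (dims divisible by the target scale)
#' @inheritParams extract_shallow_target
#' @return list with components `s_f` and `s_b` (identical)
#' @export
db_downsample <- function(model, H, tape = NULL) {
  s <- downsample_layer(ag_lift(H), model$db, tape)
  out <- list(s_f = s, s_b = s)
  if (is.null(tape) && !inherits(H, "ag_node")) {
    list(s_f = ag_value(s), s_b = ag_value(s))
  } else {
    out
  }
}

#' Reconstruction from STAM HR features
#'
#' Channel-concatenates the collected HR features and applies the single
#' 3x3 reconstruction convolution to one output channel.
#'
#' @param hr_list list of same-shape HR feature blocks
#' @inheritParams extract_shallow_target
#' @export
reconstruct <- function(model, hr_list, tape = NULL) {
  stopifnot(length(hr_list) >= 1)
  cat_in <- if (length(hr_list) == 1L) ag_lift(hr_list[[1]]) else
    op_concat_c(tape, lapply(hr_list, ag_lift))
  out <- fwd_layer(tape, model$recon, cat_in)
  if (is.null(tape) && !inherits(hr_list[[1]], "ag_node")) ag_value(out) else out
}

## ---- recurrence -----------------------------------------------------------

## Neighbour processing order: nearest-first, alternating past/future
## (past first on ties), filtered by the model's stream direction.
neighbour_order <- function(offsets, direction) {
  offs <- offsets[offsets != 0L]
  offs <- offs[order(abs(offs), offs)] # -1, +1, -2, +2, ...
  switch(direction,
         forward = offs[offs < 0L],
         backward = offs[offs > 0L],
         both = offs)
}

#' Super-resolve a target slice from its sequence
#'
#' Iterates the shared STAM over the sequence's neighbour slices in
#' nearest-first alternating order; every iteration emits an HR feature and
#' the DB output becomes the next recurrent LR state. The reconstruction
#' layer consumes all emitted HR features (the model's slot count is fixed
#' at build time: if the sequence offers fewer neighbours than slots the
#' last HR feature is replicated, extra neighbours are ignored).
#'
#' @param model a built `msbfan_model`
#' @param seq a [slice_sequence()]
#' @param tape optional autograd tape
#' @return SR image of the target slice (matrix `(H*s, W*s)`, or a node
#'   when a tape is given)
#' @export
msbfan_forward <- function(model, seq, tape = NULL) {
  stopifnot(inherits(seq, "slice_sequence"))
  I_t <- seq$slices[[seq$target_index]]
  s_state <- fwd_layer(tape, model$feat_t, ag_lift(as_hwcn(I_t)))
  offs <- neighbour_order(seq$offsets, model$meta$direction)
  hr_list <- list()
  if (length(offs) == 0L) {
    hr_list[[1L]] <- seb_forward(model, s_state, tape)
  } else {
    for (k in offs) {
      I_k <- seq$slices[[seq$target_index + k]]
      t_feat <- extract_shallow_pair(model, I_t, I_k, tape)
      t_feat <- teb_forward(model, t_feat, tape)
      t_hr <- fwd_layer(tape, model$teb_up, ag_lift(t_feat))
      s_hr <- seb_forward(model, s_state, tape)
      h <- stab_fuse(model, t_hr, s_hr, tape)
      s_state <- db_downsample(model, h, tape)$s_f
      hr_list[[length(hr_list) + 1L]] <- h
      if (length(hr_list) == model$meta$slots) break
    }
  }
  while (length(hr_list) < model$meta$slots) {
    hr_list[[length(hr_list) + 1L]] <- hr_list[[length(hr_list)]]
  }
  out <- reconstruct(model, hr_list, tape)
  if (model$meta$global_residual) {
    up <- resize_bicubic_4d(as_hwcn(I_t), model$meta$target_scale)
    out <- op_add(tape, ag_lift(out), ag_node(up))
  }
  if (!is.null(tape)) return(out)
  ag_value(out)[, , 1, 1]
}

#' @export
predict.msbfan_model <- function(object, newdata, ...) {
  msbfan_forward(object, newdata)
}

#' @export
print.msbfan_model <- function(x, ...) {
  cat(sprintf("msbfan_model: x%d SR, seq_len %d (%s), SEB m=%d n=%d, %d channels\n",
              x$meta$target_scale, x$meta$seq_len, x$meta$direction,
              x$meta$spec$m, x$meta$spec$n, x$meta$spec$channels))
  print(count_parameters(x))
  invisible(x)
}
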