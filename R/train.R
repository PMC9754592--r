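## Training loop (L1 + Adam with the halved-schedule), checkpointing, and
## evaluation against HR ground truth.

#' Training hyper-parameters
#'
#' Defaults follow the reference protocol: L1 loss, Adam
#' (beta1 0.9, beta2 0.999, eps 1e-8), learning rate 1e-4 decayed by a
#' factor of 10 at half of the 100 epochs, 48x48 LR patches.
#'
#' @param loss only `"L1"` is supported
#' @param lr_init initial learning rate
#' @param lr_decay_factor decay factor applied at `decay_at`
#' @param total_epochs schedule length
#' @param decay_at epoch (0-based) at which the decay applies; defaults to
#'   half the schedule
#' @param adam_beta1,adam_beta2,adam_eps Adam moments
#' @param patch LR patch side
#' @param batch_size minibatch size
#' @param seed RNG seed for sampling and shuffling
#' @return object of class `train_config`
#' @export
train_config <- function(loss = "L1", lr_init = 1e-4, lr_decay_factor = 10,
                         total_epochs = 100L, decay_at = total_epochs %/% 2L,
                         adam_beta1 = 0.9, adam_beta2 = 0.999,
                         adam_eps = 1e-8, patch = 48L, batch_size = 16L,
                         seed = 1L) {
  stopifnot(identical(loss, "L1"), lr_init > 0, lr_decay_factor >= 1,
            total_epochs >= 1, decay_at >= 0)
  structure(list(loss = loss, lr_init = lr_init,
                 lr_decay_factor = lr_decay_factor,
                 total_epochs = as.integer(total_epochs),
                 decay_at = as.integer(decay_at),
                 adam_beta1 = adam_beta1, adam_beta2 = adam_beta2,
                 adam_eps = adam_eps, patch = as.integer(patch),
                 batch_size = as.integer(batch_size), seed = as.integer(seed)),
            class = "train_config")
}

#' Step learning-rate schedule
#'
#' `lr_init` before `decay_at`, `lr_init / lr_decay_factor` from `decay_at`
#' onwards.
#'
#' @param epoch 0-based epoch index in `[0, total_epochs)`
#' @param cfg a [train_config()]
#' @export
lr_schedule <- function(epoch, cfg) {
  if (epoch < 0 || epoch >= cfg$total_epochs) {
    stop("lr_schedule: epoch ", epoch, " outside [0, ", cfg$total_epochs, ")")
  }
  if (epoch < cfg$decay_at) cfg$lr_init else cfg$lr_init / cfg$lr_decay_factor
}

adam_step <- function(params, lr, cfg, t) {
  b1 <- cfg$adam_beta1; b2 <- cfg$adam_beta2; eps <- cfg$adam_eps
  for (p in params) {
    if (is.null(p$g)) next
    if (is.null(p$m)) { p$m <- p$g * 0; p$u <- p$g * 0 }
    p$m <- b1 * p$m + (1 - b1) * p$g
    p$u <- b2 * p$u + (1 - b2) * p$g^2
    mhat <- p$m / (1 - b1^t)
    uhat <- p$u / (1 - b2^t)
    p$v <- p$v - lr * mhat / (sqrt(uhat) + eps)
  }
  invisible(NULL)
}

forward_loss <- function(model, sample, tape) {
  if (inherits(model, "msbp_model")) {
    pred <- msbpn_forward(model, sample$lr, tape)
    op_l1_loss(tape, pred, sample$hr)
  } else {
    pred <- msbfan_forward(model, sample$seq, tape)
    op_l1_loss(tape, pred, as_hwcn(sample$hr))
  }
}

#' Train a model
#'
#' Minimises the mean absolute error between the SR output and the HR
#' target with Adam under the step learning-rate schedule. Deterministic
#' for a fixed `cfg$seed`. Aborts with a diagnostic on a non-finite loss.
#'
#' @param model a `msbp_model` or `msbfan_model`
#' @param dataset list of samples. For MSBPN: elements with `$lr` (LR
#'   array `(H,W,1,B)` or matrix) and `$hr`; for MSBFAN: elements with
#'   `$seq` (a [slice_sequence()] of LR slices) and `$hr` (HR target
#'   matrix)
#' @param cfg a [train_config()]
#' @param steps number of optimisation steps; each step draws one sample
#'   (or one minibatch, when the dataset elements carry batched arrays)
#'   uniformly at random
#' @param log_every record the loss every this many steps
#' @return list with the trained `model` and a data.frame `log`
#'   (step, loss, lr)
#' @export
train <- function(model, dataset, cfg, steps = 300L, log_every = 1L) {
  stopifnot(length(dataset) >= 1)
  params <- collect_params(model)
  set.seed(cfg$seed)
  steps_per_epoch <- max(1L, length(dataset) %/% max(1L, cfg$batch_size))
  logs <- vector("list", steps %/% log_every + 1L)
  li <- 0L
  for (step in seq_len(steps)) {
    epoch <- min(cfg$total_epochs - 1L, (step - 1L) %/% steps_per_epoch)
    lr <- lr_schedule(epoch, cfg)
    sample_i <- dataset[[sample.int(length(dataset), 1L)]]
    tape <- ag_tape()
    zero_grads(params)
    loss <- forward_loss(model, sample_i, tape)
    if (!is.finite(loss$v)) {
      stop(sprintf("train: non-finite loss at step %d (lr %.2e); lower the learning rate",
                   step, lr))
    }
    ag_backward(tape, loss)
    adam_step(params, lr, cfg, step)
    if (step %% log_every == 0L) {
      li <- li + 1L
      logs[[li]] <- data.frame(step = step, loss = loss$v, lr = lr)
    }
  }
  list(model = model, log = do.call(rbind, logs[seq_len(li)]))
}

## ---- checkpointing --------------------------------------------------------

#' Save / load model weights
#'
#' Checkpoints store every parameter value keyed by its path in the model
#' structure, plus the model metadata; loading restores the weights into a
#' structurally identical model in place.
#'
#' @param model a built model
#' @param path checkpoint file (RDS)
#' @export
save_checkpoint <- function(model, path) {
  ps <- collect_params(model)
  saveRDS(list(values = lapply(ps, function(p) p$v),
               class = class(model), meta = model$meta), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(model, path) {
  ck <- readRDS(path)
  ps <- collect_params(model)
  if (!identical(sort(names(ps)), sort(names(ck$values)))) {
    stop("load_checkpoint: parameter structure mismatch")
  }
  for (nm in names(ps)) {
    if (!identical(dim(ps[[nm]]$v) %||% length(ps[[nm]]$v),
                   dim(ck$values[[nm]]) %||% length(ck$values[[nm]]))) {
      stop("load_checkpoint: shape mismatch for ", nm)
    }
    ps[[nm]]$v <- ck$values[[nm]]
  }
  invisible(model)
}

## ---- evaluation -----------------------------------------------------------

#' Centre-crop to dimensions divisible by `d` / crop an evaluation border
#'
#' @param img numeric matrix
#' @param d divisor (12 covers every supported scale factor)
#' @param b border width in pixels
#' @export
crop_divisible <- function(img, d) {
  h <- (nrow(img) %/% d) * d
  w <- (ncol(img) %/% d) * d
  oi <- (nrow(img) - h) %/% 2L
  oj <- (ncol(img) - w) %/% 2L
  img[oi + seq_len(h), oj + seq_len(w), drop = FALSE]
}

#' @rdname crop_divisible
#' @export
crop_border <- function(img, b) {
  if (b <= 0) return(img)
  img[(b + 1L):(nrow(img) - b), (b + 1L):(ncol(img) - b), drop = FALSE]
}

#' Evaluate a model (or the bicubic baseline) on HR volumes
#'
#' Each slice is centre-cropped to dimensions divisible by 12 (so all
#' scale factors share one HR reference), degraded bicubically to form the
#' LR input, super-resolved, and compared to the HR slice with PSNR and
#' SSIM after excluding a border of `scale` pixels (the usual SR
#' convention).
#'
#' @param model a trained model, or `NULL` for the bicubic-upsampling
#'   baseline
#' @param volumes list of [volume_record()]s (or one record)
#' @param scale SR factor
#' @param slices optional integer vector restricting which slices of each
#'   volume are evaluated
#' @param seq_len sequence length for `msbfan_model`s (defaults to the
#'   model's build length)
#' @return object of class `metric_result`: mean `psnr_db`, mean `ssim`,
#'   `n_images`, and the per-slice values
#' @export
evaluate <- function(model, volumes, scale, slices = NULL, seq_len = NULL) {
  if (inherits(volumes, "volume_record")) volumes <- list(volumes)
  is_seq <- inherits(model, "msbfan_model")
  if (is_seq && is.null(seq_len)) seq_len <- model$meta$seq_len
  ps <- c(); ss <- c()
  for (vol in volumes) {
    vox <- vol$voxels
    depth <- dim(vox)[3]
    idx <- if (is.null(slices)) seq_len(depth) else slices
    lr_slices <- NULL
    if (is_seq) {
      lr_slices <- lapply(seq_len(depth), function(k)
        degrade_bicubic(crop_divisible(vox[, , k], 12L), scale))
    }
    for (k in idx) {
      hr <- crop_divisible(vox[, , k], 12L)
      lr <- degrade_bicubic(hr, scale)
      sr <- if (is.null(model)) {
        resize_bicubic(lr, nrow(hr), ncol(hr), antialias = FALSE)
      } else if (is_seq) {
        half <- (seq_len - 1L) %/% 2L
        nb_idx <- pmin(pmax(k + (-half):(seq_len - 1L - half), 1L), depth)
        seqk <- slice_sequence(lr_slices[nb_idx], half + 1L)
        msbfan_forward(model, seqk)
      } else {
        msbpn_forward(model, lr)
      }
      sr <- pmin(pmax(sr, 0), 1)
      a <- crop_border(hr, scale); b <- crop_border(sr, scale)
      ps <- c(ps, psnr(a, b))
      ss <- c(ss, ssim(a, b))
    }
  }
  structure(list(psnr_db = mean(ps), ssim = mean(ss), n_images = length(ps),
                 per_slice_psnr = ps, per_slice_ssim = ss),
            class = "metric_result")
}

#' @export
print.metric_result <- function(x, ...) {
  cat(sprintf("metric_result: PSNR %.2f dB / SSIM %.4f over %d slices\n",
              x$psnr_db, x$ssim, x$n_images))
  invisible(x)
}

## ---- dataset preparation --------------------------------------------------

#' Build LR/HR training samples from volumes
#'
#' Degrades every slice bicubically and samples `per_slice` aligned patch
#' pairs with random dihedral augmentation.
#'
#' @param volumes list of [volume_record()]s
#' @param scale SR factor
#' @param patch LR patch side (capped at the slice size)
#' @param per_slice patch pairs per slice
#' @return list of samples with `$lr`, `$hr` (arrays) for [train()]
#' @export
make_pair_dataset <- function(volumes, scale, patch = 48L, per_slice = 1L) {
  if (inherits(volumes, "volume_record")) volumes <- list(volumes)
  out <- list()
  for (vol in volumes) {
    vox <- vol$voxels
    for (k in seq_len(dim(vox)[3])) {
      hr <- crop_divisible(vox[, , k], 12L)
      lr <- degrade_bicubic(hr, scale)
      sz <- min(patch, nrow(lr), ncol(lr))
      for (i in seq_len(per_slice)) {
        pp <- sample_patch_pair(lr, hr, scale, size = sz,
                                augment_id = sample.int(8L, 1L) - 1L,
                                provenance = list(volume = vol$source_id,
                                                  slice = k))
        out[[length(out) + 1L]] <- list(lr = pp$lr_patch, hr = pp$hr_patch,
                                        provenance = pp$provenance)
      }
    }
  }
  out
}

#' Build slice-sequence training samples from volumes
#'
#' LR sequences (degraded slice-wise) paired with the HR target slice.
#'
#' @inheritParams make_pair_dataset
#' @param seq_len sequence length
#' @export
make_sequence_dataset <- function(volumes, scale, seq_len = 7L) {
  if (inherits(volumes, "volume_record")) volumes <- list(volumes)
  out <- list()
  for (vol in volumes) {
    vox <- vol$voxels
    depth <- dim(vox)[3]
    hr_slices <- lapply(seq_len(depth), function(k)
      crop_divisible(vox[, , k], 12L))
    lr_slices <- lapply(hr_slices, degrade_bicubic, s = scale)
    tgt <- (seq_len + 1L) %/% 2L
    for (d0 in seq_len(max(0L, depth - seq_len + 1L))) {
      seqk <- slice_sequence(lr_slices[d0:(d0 + seq_len - 1L)], tgt)
      out[[length(out) + 1L]] <- list(seq = seqk,
                                      hr = hr_slices[[d0 + tgt - 1L]])
    }
  }
  out
}
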