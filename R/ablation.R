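## Ablation harness: rebuilds the published ablation designs at reduced
## scale on synthetic phantoms. The emitted tables reproduce the structure
## (rows, columns, variants, parameter counts); absolute PSNR/SSIM values
## at toy scale are NOT comparable with full-scale training.

#' Reduced-scale ablation configuration
#'
#' @param channels feature width for toy models
#' @param scale SR factor
#' @param steps optimisation steps per variant
#' @param seq_len sequence length for sequence-model grids
#' @param n_volumes,height,width,depth phantom dataset geometry
#' @param teb_groups TEB depth for toy sequence models
#' @param seed master seed
#' @export
ablation_config <- function(channels = 8L, scale = 2L, steps = 10L,
                            seq_len = 5L, n_volumes = 2L, height = 48L,
                            width = 48L, depth = 10L, teb_groups = 2L,
                            seed = 7L) {
  structure(list(channels = as.integer(channels), scale = as.integer(scale),
                 steps = as.integer(steps), seq_len = as.integer(seq_len),
                 n_volumes = as.integer(n_volumes), height = as.integer(height),
                 width = as.integer(width), depth = as.integer(depth),
                 teb_groups = as.integer(teb_groups), seed = as.integer(seed)),
            class = "ablation_config")
}

ablation_volumes <- function(cfg) {
  lapply(seq_len(cfg$n_volumes + 1L), function(i)
    generate_volume(phantom_params(height = cfg$height, width = cfg$width,
                                   depth = cfg$depth,
                                   n_structures = 12L,
                                   seed = cfg$seed * 100L + i)))
}

ablation_train_eval <- function(model, vols, cfg, sequence = FALSE) {
  train_vols <- vols[seq_len(length(vols) - 1L)]
  test_vol <- vols[[length(vols)]]
  tc <- train_config(batch_size = 1L, seed = cfg$seed)
  ds <- if (sequence) {
    make_sequence_dataset(train_vols, cfg$scale, model$meta$seq_len)
  } else {
    make_pair_dataset(train_vols, cfg$scale,
                      patch = min(24L, cfg$height %/% cfg$scale))
  }
  fit <- train(model, ds, tc, steps = cfg$steps)
  mid <- (dim(test_vol$voxels)[3] + 1L) %/% 2L
  res <- evaluate(fit$model, test_vol, cfg$scale,
                  slices = mid + (-1L):1L)
  list(model = fit$model, psnr = res$psnr_db, ssim = res$ssim)
}

row_of <- function(variant, r, model, extra = list()) {
  c(list(variant = variant, psnr = round(r$psnr, 2), ssim = round(r$ssim, 4),
         params_K = count_parameters(model)$params_K), extra)
}

#' Run an ablation grid
#'
#' Builds, trains (at reduced scale, on synthetic phantoms) and evaluates
#' the variants of one published ablation design:
#' \describe{
#'   \item{dense}{dense vs plain connections at n = 1..3 (2 x 3 table)}
#'   \item{multiscale}{multi-scale vs single-scale branches at n = 1..3,
#'     with parameter counts}
#'   \item{baselines}{SEB(1 slice), SEB(all slices concatenated),
#'     forward-only, backward-only, full bidirectional}
#'   \item{slice_order}{P / F / PF train-by-test 3x3 matrix}
#'   \item{slice_length}{sequence lengths 1..4 with parameter audit}
#'   \item{fusion}{fusion attention vs plain residual fusion}
#' }
#'
#' @param grid_name one of the names above
#' @param cfg an [ablation_config()]
#' @return data.frame; structure mirrors the corresponding published table
#' @export
run_ablation <- function(grid_name, cfg = ablation_config()) {
  grids <- c("dense", "multiscale", "baselines", "slice_order",
             "slice_length", "fusion")
  if (!grid_name %in% grids) {
    stop("unknown ablation grid '", grid_name, "'; expected one of ",
         paste(grids, collapse = ", "))
  }
  vols <- ablation_volumes(cfg)
  sc <- seq_len(cfg$scale)
  rows <- list()
  add <- function(r) rows[[length(rows) + 1L]] <<- as.data.frame(r)

  if (grid_name == "dense") {
    for (dense in c(TRUE, FALSE)) for (n in 1:3) {
      spec <- projection_spec(sc, m = 1L, n = n, dense = dense,
                              channels = cfg$channels)
      model <- build_msbpn(spec, seed = cfg$seed)
      r <- ablation_train_eval(model, vols, cfg)
      add(row_of(sprintf("M_m1_n%d", n), r, model,
                 list(dense = ifelse(dense, "w/", "w/o"))))
    }
  } else if (grid_name == "multiscale") {
    for (ms in c(TRUE, FALSE)) for (n in 1:3) {
      spec <- if (ms) {
        projection_spec(sc, m = 1L, n = n, channels = cfg$channels)
      } else {
        projection_spec(rep(cfg$scale, cfg$scale), m = 1L, n = n,
                        channels = cfg$channels, validate = FALSE)
      }
      model <- build_msbpn(spec, target_scale = cfg$scale, seed = cfg$seed)
      r <- ablation_train_eval(model, vols, cfg)
      add(row_of(sprintf("M_m1_n%d", n), r, model,
                 list(multiscale = ifelse(ms, "w/", "w/o"))))
    }
  } else if (grid_name == "baselines") {
    spec1 <- projection_spec(sc, m = 2L, n = 1L, channels = cfg$channels)
    seb1 <- build_msbpn(spec1, seed = cfg$seed)
    r <- ablation_train_eval(seb1, vols, cfg)
    add(row_of("SEB (1 slice)", r, seb1))
    # all slices concatenated as input channels of the SEB
    specN <- projection_spec(sc, m = 2L, n = 1L, channels = cfg$channels,
                             in_channels = cfg$seq_len)
    sebN <- build_msbpn(specN, seed = cfg$seed)
    r <- ablation_train_eval_stack(sebN, vols, cfg)
    add(row_of(sprintf("SEB (%d slices)", cfg$seq_len), r, sebN))
    for (dir in c("forward", "backward", "both")) {
      m <- build_msbfan(seq_len = cfg$seq_len, target_scale = cfg$scale,
                        spec = projection_spec(sc, m = 2L, n = 1L,
                                               channels = cfg$channels),
                        teb_groups = cfg$teb_groups, attention_reduction = 4L,
                        direction = dir, seed = cfg$seed)
      r <- ablation_train_eval(m, vols, cfg, sequence = TRUE)
      add(row_of(sprintf("MSBFAN (%s)", ifelse(dir == "both", "full", dir)),
                 r, m))
    }
  } else if (grid_name == "slice_order") {
    modes <- list(P = c(-2L, -1L), F = c(1L, 2L), PF = c(-1L, 1L))
    models <- list()
    for (tr in names(modes)) {
      m <- build_msbfan(seq_len = 3L, target_scale = cfg$scale,
                        spec = projection_spec(sc, m = 1L, n = 1L,
                                               channels = cfg$channels),
                        teb_groups = cfg$teb_groups, attention_reduction = 4L,
                        seed = cfg$seed)
      ds <- make_order_dataset(vols[seq_len(length(vols) - 1L)], cfg$scale,
                               modes[[tr]])
      fit <- train(m, ds, train_config(batch_size = 1L, seed = cfg$seed),
                   steps = cfg$steps)
      models[[tr]] <- fit$model
    }
    for (te in names(modes)) for (tr in names(modes)) {
      res <- evaluate_order(models[[tr]], vols[[length(vols)]], cfg$scale,
                            modes[[te]])
      add(list(test = te, train = tr, psnr = round(res$psnr_db, 2),
               ssim = round(res$ssim, 4),
               params_K = count_parameters(models[[tr]])$params_K))
    }
  } else if (grid_name == "slice_length") {
    for (len in 1:4) {
      m <- build_msbfan(seq_len = len, target_scale = cfg$scale,
                        spec = projection_spec(sc, m = 1L, n = 1L,
                                               channels = cfg$channels),
                        teb_groups = cfg$teb_groups, attention_reduction = 4L,
                        seed = cfg$seed)
      r <- ablation_train_eval(m, vols, cfg, sequence = TRUE)
      recon_params <- length(m$recon$w$v) + length(m$recon$b$v)
      add(row_of(sprintf("MSBFAN/%d", len), r, m,
                 list(params_minus_recon =
                        count_parameters(m)$total_params - recon_params)))
    }
  } else if (grid_name == "fusion") {
    for (mode in c("attention", "residual")) {
      m <- build_msbfan(seq_len = cfg$seq_len, target_scale = cfg$scale,
                        spec = projection_spec(sc, m = 1L, n = 1L,
                                               channels = cfg$channels),
                        teb_groups = cfg$teb_groups, attention_reduction = 4L,
                        stab_mode = mode, seed = cfg$seed)
      r <- ablation_train_eval(m, vols, cfg, sequence = TRUE)
      add(row_of(ifelse(mode == "attention", "FA", "FA->RL"), r, m))
    }
  }
  do.call(rbind, rows)
}

## SEB-with-stacked-slices variant: the whole LR sequence enters as input
## channels, the HR target is the centre slice.
ablation_train_eval_stack <- function(model, vols, cfg) {
  train_vols <- vols[seq_len(length(vols) - 1L)]
  test_vol <- vols[[length(vols)]]
  ds <- lapply(make_sequence_dataset(train_vols, cfg$scale, cfg$seq_len),
               stack_sample)
  fit <- train(model, ds, train_config(batch_size = 1L, seed = cfg$seed),
               steps = cfg$steps)
  tests <- lapply(make_sequence_dataset(list(test_vol), cfg$scale, cfg$seq_len),
                  stack_sample)
  mid <- tests[[(length(tests) + 1L) %/% 2L]]
  sr <- pmin(pmax(msbpn_forward(fit$model, mid$lr)[, , 1, 1], 0), 1)
  a <- crop_border(mid$hr, cfg$scale)
  b <- crop_border(sr, cfg$scale)
  list(model = fit$model, psnr = psnr(a, b), ssim = ssim(a, b))
}

stack_sample <- function(s) {
  d <- dim(s$seq$slices[[1]])
  lr <- array(unlist(s$seq$slices), dim = c(d, length(s$seq$slices), 1L))
  list(lr = lr, hr = s$hr)
}

## fixed-offset sequences (P / F / PF designs)
make_order_dataset <- function(volumes, scale, offsets) {
  out <- list()
  for (vol in volumes) {
    vox <- vol$voxels
    depth <- dim(vox)[3]
    hr_slices <- lapply(seq_len(depth), function(k)
      crop_divisible(vox[, , k], 12L))
    lr_slices <- lapply(hr_slices, degrade_bicubic, s = scale)
    for (k in seq_len(depth)) {
      idx <- sort(unique(c(k, pmin(pmax(k + offsets, 1L), depth))))
      seqk <- slice_sequence(lr_slices[idx], which(idx == k)[1])
      out[[length(out) + 1L]] <- list(seq = seqk, hr = hr_slices[[k]])
    }
  }
  out
}

evaluate_order <- function(model, vol, scale, offsets) {
  ds <- make_order_dataset(list(vol), scale, offsets)
  mid <- ds[[(length(ds) + 1L) %/% 2L]]
  sr <- pmin(pmax(msbfan_forward(model, mid$seq), 0), 1)
  a <- crop_border(mid$hr, scale)
  b <- crop_border(sr, scale)
  list(psnr_db = psnr(a, b), ssim = ssim(a, b))
}
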