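## Seedable MR-like phantom volumes: sums of randomly posed 3-D ellipsoids
## with tissue-class intensities, smoothed in-plane, plus optional noise.
## Ellipsoids extend smoothly through the slice axis, which gives the
## volumes the high adjacent-slice correlation (decaying with distance)
## that the sequence network exploits.

#' Phantom generator parameters
#'
#' @param height,width,depth volume dimensions (>= 16 in-plane; tests use
#'   reduced sizes, the reference data this emulates is 240 x 240 x 91)
#' @param n_structures number of random ellipsoids
#' @param intensity_classes mean intensities in (0, 1) emulating tissue
#'   classes (defaults roughly CSF / grey / white / lesion contrast)
#' @param smoothness in-plane Gaussian blur sigma in pixels
#' @param noise_sd noise scale (see `noise_model`)
#' @param noise_model "gaussian" (default) or "rician" (magnitude MR noise)
#' @param seed integer seed; the volume is fully determined by it
#' @return object of class `phantom_params`
#' @export
phantom_params <- function(height = 96L, width = 96L, depth = 16L,
                           n_structures = 25L,
                           intensity_classes = c(0.35, 0.55, 0.75, 0.95),
                           smoothness = 1.5, noise_sd = 0.01,
                           noise_model = c("gaussian", "rician"),
                           seed = 1L) {
  noise_model <- match.arg(noise_model)
  stopifnot(height >= 16, width >= 16, depth >= 1, n_structures >= 0,
            noise_sd >= 0, all(intensity_classes > 0 & intensity_classes < 1))
  structure(list(height = as.integer(height), width = as.integer(width),
                 depth = as.integer(depth),
                 n_structures = as.integer(n_structures),
                 intensity_classes = intensity_classes,
                 smoothness = smoothness, noise_sd = noise_sd,
                 noise_model = noise_model, seed = as.integer(seed)),
            class = "phantom_params")
}

gaussian_blur_matrix <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    idx <- pmin(pmax(i + (-r):r, 1L), n)
    for (j in seq_along(idx)) W[i, idx[j]] <- W[i, idx[j]] + k[j]
  }
  W
}

#' Generate one phantom volume
#'
#' Deterministic given `params$seed`: a background ramp plus
#' `n_structures` rotated ellipsoids with class intensities, blurred
#' in-plane, plus noise, min-max normalised to `[0, 1]`.
#'
#' @param params a [phantom_params()]
#' @return a [volume_record()]
#' @export
generate_volume <- function(params) {
  stopifnot(inherits(params, "phantom_params"))
  h <- params$height; w <- params$width; d <- params$depth
  set.seed(params$seed)
  vox <- array(0.08, dim = c(h, w, d)) # dim background
  if (params$n_structures > 0) {
    xs <- (seq_len(h) - 0.5) / h
    ys <- (seq_len(w) - 0.5) / w
    zs <- (seq_len(d) - 0.5) / d
    grid_x <- array(rep(xs, times = w * d), dim = c(h, w, d))
    grid_y <- array(rep(rep(ys, each = h), times = d), dim = c(h, w, d))
    grid_z <- array(rep(zs, each = h * w), dim = c(h, w, d))
    for (i in seq_len(params$n_structures)) {
      ctr <- stats::runif(3, c(0.15, 0.15, 0.1), c(0.85, 0.85, 0.9))
      ax <- stats::runif(3, c(0.05, 0.05, 0.15), c(0.25, 0.25, 0.6))
      th <- stats::runif(1, 0, pi) # in-plane rotation
      cls <- params$intensity_classes[
        1L + (i - 1L) %% length(params$intensity_classes)]
      amp <- cls * stats::runif(1, 0.8, 1.2)
      dx <- grid_x - ctr[1]; dy <- grid_y - ctr[2]; dz <- grid_z - ctr[3]
      rx <- cos(th) * dx - sin(th) * dy
      ry <- sin(th) * dx + cos(th) * dy
      q <- (rx / ax[1])^2 + (ry / ax[2])^2 + (dz / ax[3])^2
      inside <- q <= 1
      # soft-ish edge: intensity falls with q to avoid hard aliasing
      vox[inside] <- vox[inside] * 0.35 + amp * (1 - 0.3 * q[inside])
    }
  }
  if (params$smoothness > 0) {
    Wh <- gaussian_blur_matrix(h, params$smoothness)
    Ww <- gaussian_blur_matrix(w, params$smoothness)
    for (k in seq_len(d)) vox[, , k] <- Wh %*% vox[, , k] %*% t(Ww)
  }
  if (params$noise_sd > 0) {
    if (params$noise_model == "rician") {
      n1 <- array(stats::rnorm(length(vox), sd = params$noise_sd), dim = dim(vox))
      n2 <- array(stats::rnorm(length(vox), sd = params$noise_sd), dim = dim(vox))
      vox <- sqrt((vox + n1)^2 + n2^2)
    } else {
      vox <- vox + array(stats::rnorm(length(vox), sd = params$noise_sd),
                         dim = dim(vox))
    }
  }
  vox <- normalize_01(vox)
  volume_record(vox, source_id = sprintf("phantom-seed%d", params$seed))
}

#' Generate a phantom dataset on disk
#'
#' Writes `n_volumes` NIfTI volumes plus a JSON manifest. Per-volume seeds
#' are derived deterministically from the master seed and are pairwise
#' distinct, so regeneration is byte-for-byte reproducible.
#'
#' @param n_volumes number of volumes
#' @param params template [phantom_params()]; its `seed` is the master seed
#' @param out_dir writable output directory
#' @return the manifest (invisibly written to `manifest.json`)
#' @export
generate_dataset <- function(n_volumes, params, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- params$seed * 1000L + seq_len(n_volumes)
  entries <- vector("list", n_volumes)
  for (i in seq_len(n_volumes)) {
    p <- params
    p$seed <- seeds[i]
    vol <- generate_volume(p)
    fn <- sprintf("phantom_%03d.nii", i)
    write_nifti(vol, file.path(out_dir, fn))
    entries[[i]] <- list(id = sprintf("phantom_%03d", i), file = fn,
                         seed = seeds[i],
                         dims = c(p$height, p$width, p$depth))
  }
  manifest <- list(master_seed = params$seed, n_volumes = n_volumes,
                   params = unclass(params)[c("height", "width", "depth",
                                              "n_structures", "smoothness",
                                              "noise_sd", "noise_model")],
                   volumes = entries)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Mean adjacent-slice correlation at a given slice distance
#'
#' @param vox 3-D array or [volume_record()]
#' @param dist slice distance
#' @keywords internal
#' @export
slice_correlation <- function(vox, dist = 1L) {
  if (inherits(vox, "volume_record")) vox <- vox$voxels
  d <- dim(vox)[3]
  stopifnot(dist < d)
  cors <- vapply(seq_len(d - dist), function(k) {
    a <- as.numeric(vox[, , k]); b <- as.numeric(vox[, , k + dist])
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
    stats::cor(a, b)
  }, numeric(1))
  mean(cors, na.rm = TRUE)
}
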