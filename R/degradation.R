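## Bicubic degradation, dihedral augmentation, patch and sequence sampling.
##
## Bicubic dialect: Catmull-Rom kernel (a = -0.5), half-pixel centre
## alignment, edge clamping, and antialiasing (kernel widened by the scale
## factor) when downscaling. Resizing is expressed as two 1-D weight
## matrices, so constants are reproduced exactly and degree-1 ramps are
## reproduced away from the clamped border.

cubic_kernel <- function(x, a = -0.5) {
  x <- abs(x)
  w <- numeric(length(x))
  i1 <- x <= 1
  i2 <- x > 1 & x < 2
  w[i1] <- (a + 2) * x[i1]^3 - (a + 3) * x[i1]^2 + 1
  w[i2] <- a * x[i2]^3 - 5 * a * x[i2]^2 + 8 * a * x[i2] - 4 * a
  w
}

## (n_out x n_in) row-stochastic resampling matrix
resize_weights <- function(n_in, n_out, antialias = TRUE) {
  scale <- n_in / n_out
  fs <- if (antialias && scale > 1) scale else 1
  supp <- 2 * fs
  W <- matrix(0, n_out, n_in)
  for (i in seq_len(n_out)) {
    center <- (i - 0.5) * scale - 0.5 # 0-based input coordinate
    lo <- floor(center - supp + 1e-9)
    hi <- ceiling(center + supp - 1e-9)
    idx <- lo:hi
    w <- cubic_kernel((idx - center) / fs)
    keep <- w != 0
    idx <- idx[keep]; w <- w[keep]
    w <- w / sum(w)
    idx_cl <- pmin(pmax(idx, 0L), n_in - 1L) + 1L # clamp to edge
    for (j in seq_along(idx_cl)) W[i, idx_cl[j]] <- W[i, idx_cl[j]] + w[j]
  }
  W
}

#' Bicubic resampling of a 2-D image
#'
#' @param img numeric matrix
#' @param h_out,w_out output dimensions
#' @param antialias widen the kernel when downscaling (recommended)
#' @return resampled matrix (not clipped)
#' @export
resize_bicubic <- function(img, h_out, w_out, antialias = TRUE) {
  stopifnot(is.matrix(img))
  Wh <- resize_weights(nrow(img), h_out, antialias)
  Ww <- resize_weights(ncol(img), w_out, antialias)
  Wh %*% img %*% t(Ww)
}

## bicubic x`scale` upsampling of a (H,W,C,N) block, per channel/sample
resize_bicubic_4d <- function(x, scale) {
  d <- dim(x)
  Wh <- resize_weights(d[1], d[1] * scale, antialias = FALSE)
  Ww <- resize_weights(d[2], d[2] * scale, antialias = FALSE)
  out <- array(0, dim = c(d[1] * scale, d[2] * scale, d[3], d[4]))
  for (n in seq_len(d[4])) for (c in seq_len(d[3])) {
    out[, , c, n] <- Wh %*% x[, , c, n] %*% t(Ww)
  }
  out
}

#' Bicubic degradation of an HR image
#'
#' Crops the image to the largest region divisible by `s`, then downscales
#' by the integer factor `s` with the antialiased bicubic kernel and clips
#' to `[0, 1]`.
#'
#' @param hr numeric matrix with intensities in `[0, 1]`
#' @param s integer scale factor >= 2
#' @return LR matrix with dims `floor(dim(hr) / s)`
#' @export
degrade_bicubic <- function(hr, s) {
  s <- as.integer(s)
  if (is.na(s) || s < 2) stop("degrade_bicubic: scale factor must be >= 2")
  h <- (nrow(hr) %/% s) * s
  w <- (ncol(hr) %/% s) * s
  hr <- hr[seq_len(h), seq_len(w), drop = FALSE]
  lr <- resize_bicubic(hr, h %/% s, w %/% s, antialias = TRUE)
  pmin(pmax(lr, 0), 1)
}

#' Dihedral augmentation
#'
#' Applies one of the 8 dihedral transforms (4 rotations x optional
#' horizontal flip). `op_id %% 4` counts 90-degree counter-clockwise
#' rotations; `op_id %/% 4` selects the flip.
#'
#' @param img numeric matrix
#' @param op_id integer in 0..7
#' @export
augment <- function(img, op_id) {
  if (length(op_id) != 1L || is.na(op_id) || op_id < 0 || op_id > 7) {
    stop("augment: op_id must be an integer in 0..7")
  }
  op_id <- as.integer(op_id)
  rot90 <- function(m) t(m)[ncol(m):1, , drop = FALSE]
  for (i in seq_len(op_id %% 4L)) img <- rot90(img)
  if (op_id %/% 4L == 1L) img <- img[, ncol(img):1, drop = FALSE]
  img
}

#' Compose two dihedral ops
#'
#' Returns the op id equivalent to applying `op1` then `op2` (used to check
#' group closure).
#' @keywords internal
augment_compose <- function(op1, op2) {
  probe <- matrix(seq_len(12), 3, 4) # asymmetric probe identifies each op
  target <- augment(augment(probe, op1), op2)
  for (k in 0:7) if (identical(augment(probe, k), target)) return(k)
  stop("dihedral composition fell outside the group") # unreachable
}

#' Sample an aligned LR/HR patch pair
#'
#' The LR crop origin is uniform over all valid positions; the HR crop
#' starts at `s * origin` with side `s * size`, so the pair stays on the
#' scale lattice. Reproducible under `set.seed()`.
#'
#' @param lr,hr aligned LR and HR matrices (`dim(hr) == s * dim(lr)`)
#' @param s scale factor
#' @param size LR patch side (default 48)
#' @param augment_id optional dihedral op applied to both members
#' @param provenance optional list carried through (volume id, slice, ...)
#' @return an object of class `train_sample_pair`
#' @export
sample_patch_pair <- function(lr, hr, s, size = 48L, augment_id = NULL,
                              provenance = list()) {
  stopifnot(all(dim(hr) == s * dim(lr)))
  if (nrow(lr) < size || ncol(lr) < size) {
    stop(sprintf("sample_patch_pair: LR source %dx%d smaller than patch %d",
                 nrow(lr), ncol(lr), size))
  }
  oi <- sample.int(nrow(lr) - size + 1L, 1L) - 1L
  oj <- sample.int(ncol(lr) - size + 1L, 1L) - 1L
  lp <- lr[oi + seq_len(size), oj + seq_len(size), drop = FALSE]
  hp <- hr[s * oi + seq_len(s * size), s * oj + seq_len(s * size), drop = FALSE]
  if (!is.null(augment_id)) {
    lp <- augment(lp, augment_id)
    hp <- augment(hp, augment_id)
  }
  structure(list(lr_patch = lp, hr_patch = hp, scale = as.integer(s),
                 provenance = c(provenance,
                                list(origin = c(oi, oj),
                                     aug = if (is.null(augment_id)) NA_integer_
                                           else as.integer(augment_id)))),
            class = "train_sample_pair")
}

#' Ordered slice sequence with a designated target
#'
#' @param slices list of same-shape grayscale matrices
#' @param target_index 1-based index of the target slice
#' @return object of class `slice_sequence`
#' @export
slice_sequence <- function(slices, target_index) {
  stopifnot(length(slices) >= 1,
            target_index >= 1, target_index <= length(slices))
  d <- dim(slices[[1]])
  for (s in slices) stopifnot(identical(dim(s), d))
  structure(list(slices = slices, target_index = as.integer(target_index),
                 offsets = seq_along(slices) - as.integer(target_index)),
            class = "slice_sequence")
}

#' Sliding-window slice sequences from a volume
#'
#' Yields one centred sequence per window of `seq_len` consecutive slices
#' along the depth axis (the reference protocol treats 7 slices as one
#' training sample).
#'
#' @param vol a [volume_record()] or a 3-D array `(H, W, D)`
#' @param seq_len window length (odd for a centred target)
#' @return list of [slice_sequence()] objects (empty, with a warning, when
#'   the volume is shallower than `seq_len`)
#' @export
make_sequence_samples <- function(vol, seq_len = 7L) {
  vox <- if (inherits(vol, "volume_record")) vol$voxels else vol
  stopifnot(length(dim(vox)) == 3L, seq_len >= 1L)
  depth <- dim(vox)[3]
  if (depth < seq_len) {
    warning("volume depth ", depth, " < seq_len ", seq_len,
            "; returning no samples")
    return(list())
  }
  lapply(seq_len(depth - seq_len + 1L), function(d0) {
    slices <- lapply(seq_len(seq_len), function(i) vox[, , d0 + i - 1L])
    slice_sequence(slices, target_index = (seq_len + 1L) %/% 2L)
  })
}
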