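## PSNR and SSIM, the two quantitative SR metrics.

#' Peak signal-to-noise ratio
#'
#' `10 * log10(peak^2 / MSE)` in dB; identical inputs report the
#' documented 100 dB cap.
#'
#' @param a,b same-shape numeric arrays with values in `[0, peak]`
#' @param peak signal peak (1.0 for normalised MR slices)
#' @param cap value reported for zero MSE
#' @export
psnr <- function(a, b, peak = 1.0, cap = 100) {
  if (!identical(dim(a) %||% length(a), dim(b) %||% length(b))) {
    stop("psnr: shape mismatch")
  }
  mse <- mean((a - b)^2)
  if (mse == 0) return(cap)
  min(cap, 10 * log10(peak^2 / mse))
}

## separable "valid" Gaussian filtering matrix: (n - win + 1) x n
ssim_filter_matrix <- function(n, win, sigma) {
  g <- exp(-((seq_len(win) - (win + 1) / 2)^2) / (2 * sigma^2))
  g <- g / sum(g)
  n_out <- n - win + 1L
  W <- matrix(0, n_out, n)
  for (i in seq_len(n_out)) W[i, i:(i + win - 1L)] <- g
  W
}

#' Structural similarity index
#'
#' Mean local SSIM with the standard 11x11 Gaussian window (sigma 1.5),
#' K1 = 0.01, K2 = 0.03, computed on valid windows only.
#'
#' @param a,b same-shape numeric matrices in `[0, peak]`
#' @param peak dynamic range
#' @param win window size
#' @param sigma Gaussian window sigma
#' @export
ssim <- function(a, b, peak = 1.0, win = 11L, sigma = 1.5) {
  stopifnot(is.matrix(a), identical(dim(a), dim(b)))
  if (nrow(a) < win || ncol(a) < win) {
    stop("ssim: image smaller than the ", win, "x", win, " window")
  }
  c1 <- (0.01 * peak)^2
  c2 <- (0.03 * peak)^2
  Wr <- ssim_filter_matrix(nrow(a), win, sigma)
  Wc <- t(ssim_filter_matrix(ncol(a), win, sigma))
  f <- function(x) Wr %*% x %*% Wc
  mu_a <- f(a); mu_b <- f(b)
  va <- f(a * a) - mu_a^2
  vb <- f(b * b) - mu_b^2
  cab <- f(a * b) - mu_a * mu_b
  smap <- ((2 * mu_a * mu_b + c1) * (2 * cab + c2)) /
    ((mu_a^2 + mu_b^2 + c1) * (va + vb + c2))
  mean(smap)
}
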