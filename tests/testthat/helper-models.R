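# Shared tiny-model builders and fixtures (all generated in code).

tiny_msbpn <- function(scales = 1:2, m = 1L, n = 1L, channels = 4L,
                       seed = 42L, ...) {
  build_msbpn(projection_spec(scales, m = m, n = n, channels = channels),
              seed = seed, ...)
}

tiny_msbfan <- function(seq_len = 3L, scale = 2L, channels = 4L,
                        seed = 42L, ...) {
  build_msbfan(seq_len = seq_len, target_scale = scale,
               spec = projection_spec(seq_len(scale), m = 1L, n = 1L,
                                      channels = channels),
               teb_groups = 2L, attention_reduction = 2L, seed = seed, ...)
}

# scalar 1-channel 1x1 linear layers for the back-projection oracles
scalar_layer <- function(weight, transpose = FALSE) {
  l <- layer_conv(1L, 1L, 1L, 1L, 0L, act = TRUE, transpose = transpose)
  l$w$v[] <- weight
  l$b$v[] <- 0
  l
}

rand_img <- function(h, w, seed = 1) {
  set.seed(seed)
  matrix(stats::runif(h * w), h, w)
}

tiny_volume <- function(seed = 1L, h = 48L, w = 48L, d = 8L) {
  generate_volume(phantom_params(height = h, width = w, depth = d,
                                 n_structures = 10L, seed = seed))
}

# independent analytic parameter-count oracle for the MSBPN family
msbpn_expected_params <- function(scales, m, n, channels = 64L,
                                  in_channels = 1L) {
  ks <- vapply(scales, function(s) make_scale_config(s)$kernel, numeric(1))
  per_layer <- channels^2 * ks^2 + channels + 1   # w + b + PReLU slope
  branches <- 2 * n * (m + 1) * sum(per_layer)
  feat <- in_channels * channels * 9 + channels + 1
  select <- length(scales) * channels^2 + channels + 1
  k_t <- make_scale_config(max(scales))$kernel
  up_final <- channels^2 * k_t^2 + channels + 1
  recon <- channels * 9 + 1
  branches + feat + select + up_final + recon
}

# independent dihedral composition oracle: find the single op matching
# op1-then-op2 on an asymmetric probe, or NA if the group is not closed
augment_compose_ref <- function(op1, op2) {
  probe <- matrix(seq_len(35), 5, 7)
  target <- augment(augment(probe, op1), op2)
  for (k in 0:7) if (identical(augment(probe, k), target)) return(k)
  NA_integer_
}
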