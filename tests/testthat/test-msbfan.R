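test_that("shallow extraction: shapes, degenerate pair, order sensitivity", {
  model <- tiny_msbfan(channels = 6L, seed = 5)
  a <- rand_img(12, 12, 1); b <- rand_img(12, 12, 2)
  st <- extract_shallow_target(model, a)
  expect_identical(dim(st), c(12L, 12L, 6L, 1L))
  # pairing the target with itself must not crash (k = 0 degenerate)
  expect_identical(dim(extract_shallow_pair(model, a, a)), c(12L, 12L, 6L, 1L))
  # concatenation is ordered: swapping the pair changes the output
  p1 <- extract_shallow_pair(model, a, b)
  p2 <- extract_shallow_pair(model, b, a)
  expect_gt(max(abs(p1 - p2)), 1e-6)
})

test_that("TEB preserves shape and is the identity when zero-initialised", {
  model <- tiny_msbfan(channels = 4L, seed = 6)
  x <- array(stats::rnorm(10 * 10 * 4), c(10, 10, 4, 1))
  expect_identical(dim(teb_forward(model, x)), dim(x))
  for (g in model$teb) {
    g$conv1$w$v[] <- 0; g$conv1$b$v[] <- 0
    g$conv2$w$v[] <- 0; g$conv2$b$v[] <- 0
  }
  expect_equal(teb_forward(model, x), x, tolerance = 1e-14)
  # reference TEB conv cost: 9 residual groups = 9 * 73,856
  teb64 <- lapply(1:9, function(i) make_residual_group(64L))
  conv_cost <- sum(vapply(teb64, function(g)
    length(g$conv1$w$v) + length(g$conv1$b$v) +
      length(g$conv2$w$v) + length(g$conv2$b$v), numeric(1)))
  expect_identical(conv_cost, 9 * 73856)
})

test_that("SEB maps LR features to target-resolution HR features", {
  model <- tiny_msbfan(channels = 4L, scale = 2L, seed = 7)
  s <- array(stats::rnorm(10 * 10 * 4), c(10, 10, 4, 1))
  out <- seb_forward(model, s)
  expect_identical(dim(out), c(20L, 20L, 4L, 1L))
})

test_that("STAB: gate range, identity-gate reduction, output shape", {
  model <- tiny_msbfan(channels = 4L, seed = 8)
  tm <- array(stats::rnorm(8 * 8 * 4), c(8, 8, 4, 1))
  sp <- array(stats::rnorm(8 * 8 * 4), c(8, 8, 4, 1))
  out <- stab_fuse(model, tm, sp)
  expect_identical(dim(out), c(8L, 8L, 4L, 1L))
  # sigmoid gates are strictly inside (0,1) for finite inputs
  g <- op_gap(NULL, ag_node(op_concat_c(NULL, list(ag_node(tm), ag_node(sp)))$v))
  g <- fwd_layer(NULL, model$stab$fc1, g)
  g <- fwd_layer(NULL, model$stab$fc2, g)
  gates <- ag_value(op_sigmoid(NULL, g))
  expect_true(all(gates > 0 & gates < 1))
  # forcing gates to 1 reduces to concatenation + 1x1 fusion
  cat_in <- op_concat_c(NULL, list(ag_node(tm), ag_node(sp)))
  manual <- ag_value(fwd_layer(NULL, model$stab$fuse, cat_in))
  expect_equal(stab_fuse(model, tm, sp, gates_identity = TRUE), manual,
               tolerance = 1e-14)
})

test_that("DB emits a bitwise-identical forward/backward state pair", {
  model <- tiny_msbfan(channels = 4L, scale = 2L, seed = 9)
  H <- array(stats::rnorm(16 * 16 * 4), c(16, 16, 4, 1))
  out <- db_downsample(model, H)
  expect_identical(out$s_f, out$s_b)
  expect_identical(dim(out$s_f), c(8L, 8L, 4L, 1L))
  # one shared down layer: parameter cost counted once
  expect_identical(sum(grepl("^db", names(count_parameters(model)$per_module_params))), 1L)
})

test_that("msbfan_forward: geometry, determinism, sequence-length 1 equals SEB path", {
  model <- tiny_msbfan(seq_len = 3L, channels = 4L, scale = 2L, seed = 10)
  slices <- lapply(1:3, function(i) rand_img(12, 12, i))
  seq3 <- slice_sequence(slices, 2L)
  sr <- msbfan_forward(model, seq3)
  expect_identical(dim(sr), c(24L, 24L))
  expect_identical(msbfan_forward(model, seq3), sr)
  # single-slice model: extract -> SEB -> reconstruct (+ bicubic skip)
  m1 <- tiny_msbfan(seq_len = 1L, channels = 4L, scale = 2L, seed = 10)
  I <- slices[[1]]
  manual <- {
    s0 <- fwd_layer(NULL, m1$feat_t, ag_node(array(I, c(12, 12, 1, 1))))
    h <- seb_forward(m1, s0)
    out <- reconstruct(m1, list(h))
    ag_value(out)[, , 1, 1] + resize_bicubic(I, 24, 24, antialias = FALSE)
  }
  expect_equal(msbfan_forward(m1, slice_sequence(list(I), 1L)), manual,
               tolerance = 1e-12)
})

test_that("reversing the neighbour order changes the output", {
  # random head: with the zero-initialised default the output is the
  # bicubic skip alone and order sensitivity would be vacuous
  model <- tiny_msbfan(seq_len = 5L, channels = 4L, scale = 2L, seed = 11,
                       zero_init_head = FALSE)
  slices <- lapply(1:5, function(i) rand_img(12, 12, i + 20))
  fwd <- msbfan_forward(model, slice_sequence(slices, 3L))
  rev <- msbfan_forward(model, slice_sequence(rev(slices), 3L))
  expect_gt(max(abs(fwd - rev)), 1e-8)
})

test_that("forward-only and backward-only ablations build and have equal counts", {
  mf <- tiny_msbfan(seq_len = 5L, channels = 4L, seed = 12, direction = "forward")
  mb <- tiny_msbfan(seq_len = 5L, channels = 4L, seed = 12, direction = "backward")
  expect_identical(count_parameters(mf)$total_params,
                   count_parameters(mb)$total_params)
  slices <- lapply(1:5, function(i) rand_img(12, 12, i))
  s5 <- slice_sequence(slices, 3L)
  expect_identical(dim(msbfan_forward(mf, s5)), c(24L, 24L))
  expect_identical(dim(msbfan_forward(mb, s5)), c(24L, 24L))
})

test_that("zero temporal paths make the output independent of the neighbours", {
  model <- tiny_msbfan(seq_len = 3L, channels = 4L, scale = 2L, seed = 13,
                       zero_init_head = FALSE)
  # silence the temporal stream: zero TEB residual branches, attention
  # bottleneck (gates become the constant sigmoid(0)), and the temporal
  # half of the fusion weights
  for (g in model$teb) { g$conv2$w$v[] <- 0; g$conv2$b$v[] <- 0 }
  model$stab$fc2$w$v[] <- 0; model$stab$fc2$b$v[] <- 0
  model$stab$fuse$w$v[, , 1:4, ] <- 0 # temporal channels are 1..c in the concat
  tgt <- rand_img(12, 12, 30)
  nb1 <- lapply(1:3, function(i) if (i == 2) tgt else rand_img(12, 12, i + 40))
  nb2 <- lapply(1:3, function(i) if (i == 2) tgt else rand_img(12, 12, i + 50))
  o1 <- msbfan_forward(model, slice_sequence(nb1, 2L))
  o2 <- msbfan_forward(model, slice_sequence(nb2, 2L))
  expect_equal(o1, o2, tolerance = 1e-12)
})

test_that("parameters are constant across sequence lengths up to the recon layer", {
  totals <- vapply(c(3L, 5L, 7L), function(len) {
    m <- tiny_msbfan(seq_len = len, channels = 4L, seed = 14)
    recon <- length(m$recon$w$v) + length(m$recon$b$v)
    count_parameters(m)$total_params - recon
  }, numeric(1))
  expect_identical(totals, rep(totals[1], 3))
})

test_that("7-slice reconstruction cost and MSBFAN < MSBPN(m=1,n=3) ordering", {
  fan <- build_msbfan(seq_len = 7L, target_scale = 4L, seed = 1)
  # 6 HR features x 64 channels -> 3x3 conv to 1 channel
  expect_identical(length(fan$recon$w$v) + length(fan$recon$b$v), 3457L)
  big <- msbpn_expected_params(1:4, m = 1L, n = 3L)
  expect_lt(count_parameters(fan)$total_params, big)
})

test_that("msbfan training reduces the loss through the recurrent graph", {
  model <- tiny_msbfan(seq_len = 3L, channels = 4L, scale = 2L, seed = 15,
                       zero_init_head = FALSE)
  vol <- tiny_volume(seed = 31, h = 24L, w = 24L, d = 6L)
  ds <- make_sequence_dataset(list(vol), 2L, 3L)
  fit <- train(model, ds, train_config(batch_size = 1L, seed = 15), steps = 25L)
  expect_lt(mean(tail(fit$log$loss, 5)), mean(head(fit$log$loss, 5)))
  expect_true(all(is.finite(fit$log$loss)))
})
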