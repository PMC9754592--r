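test_that("scale configs reproduce the printed kernel/stride/pad triples", {
  expect_equal(unclass(make_scale_config(1))[c("kernel", "stride", "pad")],
               list(kernel = 3L, stride = 1L, pad = 1L))
  expect_equal(unclass(make_scale_config(2))[c("kernel", "stride", "pad")],
               list(kernel = 6L, stride = 2L, pad = 2L))
  expect_equal(unclass(make_scale_config(3))[c("kernel", "stride", "pad")],
               list(kernel = 7L, stride = 3L, pad = 2L))
  expect_equal(unclass(make_scale_config(4))[c("kernel", "stride", "pad")],
               list(kernel = 8L, stride = 4L, pad = 2L))
  for (s in 1:4) {
    cfg <- make_scale_config(s)
    expect_identical(cfg$kernel - 2L * cfg$pad, cfg$stride)
    expect_identical(cfg$stride, cfg$scale)
  }
  expect_error(make_scale_config(5), "allowed scales")
  expect_error(make_scale_config(0), "allowed scales")
})

test_that("transposed-conv output-size identity holds for x3 over in = 1..64", {
  cfg <- make_scale_config(3)
  for (n_in in 1:64) {
    expect_identical((n_in - 1L) * cfg$stride - 2L * cfg$pad + cfg$kernel,
                     3L * n_in)
  }
})

test_that("up/down layers scale spatial dims exactly and round-trip", {
  set.seed(1)
  for (s in 1:4) {
    cfg <- make_scale_config(s)
    up <- make_upsample_layer(cfg, 3L)
    dn <- make_downsample_layer(cfg, 3L)
    for (sz in c(8L, 13L, 33L, 64L)) {
      x <- array(stats::rnorm(sz * sz * 3), c(sz, sz, 3, 1))
      u <- upsample_layer(x, up)
      expect_identical(dim(u)[1:2], c(s * sz, s * sz))
      expect_identical(dim(u)[3], 3L)
      d <- downsample_layer(u, dn)
      expect_identical(dim(d)[1:2], dim(x)[1:2])
      expect_true(all(is.finite(d)))
    }
  }
})

test_that("downsample rejects non-divisible inputs; upsample rejects non-finite", {
  cfg <- make_scale_config(4)
  dn <- make_downsample_layer(cfg, 2L)
  x <- array(0, c(47, 47, 2, 1))
  expect_error(downsample_layer(x, dn), "not divisible")
  up <- make_upsample_layer(cfg, 2L)
  bad <- array(NaN, c(8, 8, 2, 1))
  expect_error(upsample_layer(bad, up), "non-finite")
})

test_that("zero input with zero bias stays zero through up/down layers", {
  cfg <- make_scale_config(2)
  up <- make_upsample_layer(cfg, 2L)
  up$b$v[] <- 0
  z <- upsample_layer(array(0, c(8, 8, 2, 1)), up)
  expect_true(all(z == 0))
})

test_that("layers are linear in probe mode: doubling input doubles output", {
  set.seed(2)
  for (transpose in c(FALSE, TRUE)) {
    l <- layer_conv(2L, 3L, 6L, 2L, 2L, act = TRUE, transpose = transpose)
    l$b$v[] <- 0
    x <- array(stats::rnorm(12 * 12 * 2), c(12, 12, 2, 1))
    y1 <- ag_value(fwd_layer(NULL, l, ag_node(x), probe_linear = TRUE))
    y2 <- ag_value(fwd_layer(NULL, l, ag_node(2 * x), probe_linear = TRUE))
    expect_equal(y2, 2 * y1, tolerance = 1e-12)
  }
})

test_that("residual group: zero-initialised branch is the identity; costs match", {
  g <- make_residual_group(64L)
  g$conv1$w$v[] <- 0; g$conv1$b$v[] <- 0
  g$conv2$w$v[] <- 0; g$conv2$b$v[] <- 0
  x <- array(stats::rnorm(9 * 9 * 64), c(9, 9, 64, 1))
  expect_equal(residual_group(x, g), x, tolerance = 1e-14)
  # conv weight+bias cost per group (excluding the PReLU slope)
  conv_cost <- length(g$conv1$w$v) + length(g$conv1$b$v) +
    length(g$conv2$w$v) + length(g$conv2$b$v)
  expect_identical(conv_cost, 2L * (64L * 64L * 9L + 64L))
  expect_identical(conv_cost, 73856L)
  # shape preserved
  g2 <- make_residual_group(4L)
  x2 <- array(0.5, c(60, 60, 4, 1))
  expect_identical(dim(residual_group(x2, g2)), dim(x2))
})

test_that("count_parameters matches hand counts and the analytic oracle", {
  conv <- layer_conv(64L, 64L, 3L, 1L, 1L, act = FALSE)
  expect_identical(count_parameters(list(conv))$total_params, 36928L)
  deconv <- layer_conv(64L, 64L, 8L, 4L, 2L, act = FALSE, transpose = TRUE)
  expect_identical(count_parameters(list(deconv))$total_params, 262208L)
  # full models against the independent analytic formula
  for (cfg in list(list(1:4, 1L, 1L), list(1:4, 2L, 3L), list(1:2, 1L, 2L))) {
    model <- build_msbpn(projection_spec(cfg[[1]], m = cfg[[2]], n = cfg[[3]]),
                         seed = 1)
    a <- count_parameters(model)
    expect_identical(a$total_params,
                     as.integer(msbpn_expected_params(cfg[[1]], cfg[[2]], cfg[[3]])))
    expect_identical(a$params_K, as.integer(round(a$total_params / 1000)))
    expect_identical(sum(unlist(a$per_module_params)), a$total_params)
  }
})

test_that("audit depth equals the total up/down layer count 2n(m+1) per branch", {
  # the convention that reproduces the printed depth column 16/32/48/24/48/72
  expected <- c("1,1" = 16L, "1,2" = 32L, "1,3" = 48L,
                "2,1" = 24L, "2,2" = 48L, "2,3" = 72L)
  for (key in names(expected)) {
    mn <- as.integer(strsplit(key, ",")[[1]])
    model <- build_msbpn(projection_spec(1:4, m = mn[1], n = mn[2],
                                         channels = 2L), seed = 1)
    expect_identical(count_parameters(model)$depth, expected[[key]])
  }
})

test_that("audit JSON serialises the report fields", {
  model <- tiny_msbpn()
  js <- jsonlite::fromJSON(audit_json(count_parameters(model)))
  expect_named(js, c("total_params", "params_K", "per_module_params", "depth"),
               ignore.order = TRUE)
  expect_identical(js$total_params, count_parameters(model)$total_params)
})
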