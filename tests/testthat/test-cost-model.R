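test_that("shape inference follows the padding conventions", {
  net <- resnet50v2_template(240, 2)
  shp <- infer_shapes(net)
  stem_conv <- shp[shp$kind == "conv", ][1, ]
  expect_equal(c(stem_conv$height, stem_conv$width), c(120, 120))
  # the four stages end at sides 60, 30, 15, 8
  last_of_stage <- function(stage) {
    rows <- shp[grepl(paste0(stage, "_b"), shp$id) & shp$kind == "add", ]
    rows[nrow(rows), ]
  }
  sides <- vapply(paste0("stage", 1:4),
                  function(s) last_of_stage(s)$height, numeric(1))
  expect_equal(unname(sides), c(60, 30, 15, 8))
  # identity-kind layers leave the shape unchanged
  expect_equal(shp$channels[shp$kind == "batchnorm"][1],
               shp$channels[shp$kind == "conv"][1])
})

test_that("valid padding windows are floor((in - k)/stride) + 1", {
  net <- tiny_net(input_side = 10, k1 = 3, padding = "valid")
  shp <- infer_shapes(net)
  expect_equal(shp$height[shp$kind == "conv"][1], 8)
  expect_error(infer_shapes(tiny_net(input_side = 2, k1 = 3, padding = "valid")),
               "does not fit")
})

test_that("merge layers check their operand shapes", {
  net <- resnet50v2_template(240, 2)
  # an identity shortcut cannot bridge the 64 -> 256 channel expansion
  broken <- net
  broken$stages[[1]]$block$shortcut <- "identity"
  expect_error(infer_shapes(broken), "add")
  # and a stride in one inception branch breaks the concat alignment
  inc <- inception_v4_template(240, 2)
  inc$stages[[1]]$block$branches[[2]][[1]]$stride <- c(2, 2)
  expect_error(infer_shapes(inc), "concat")
})

test_that("convolution FLOPs follow 2 x Cin x K x K x out-shape", {
  l7 <- layer_spec("conv", kernel = 7, filters = 64)
  expect_equal(conv_flops(l7, c(240, 240, 3), c(120, 120, 64)), 270950400)
  l1 <- layer_spec("conv", kernel = 1, filters = 8)
  expect_equal(conv_flops(l1, c(10, 10, 3), c(10, 10, 8)), 4800)
  lu <- layer_spec("conv", kernel = 1, filters = 1)
  expect_equal(conv_flops(lu, c(1, 1, 1), c(1, 1, 1)), 2)
})

test_that("dense FLOPs follow 2 x in x out", {
  expect_equal(dense_flops(2048, 2), 8192)
  expect_equal(dense_flops(1, 1), 2)
  expect_error(dense_flops(0, 2), "positive")
})

test_that("parameter counting matches its stated conventions", {
  # dense with bias
  head_only <- network_spec("d", c(1, 1, 2048),
    stem = list(layer_spec("input")),
    stages = list(),
    head = list(layer_spec("dense", filters = 2, bias = TRUE)),
    n_classes = 2, min_input = 1)
  expect_equal(count_params(head_only), 4098)
  # batchnorm contributes 4 per channel
  bn_net <- network_spec("b", c(4, 4, 6),
    stem = list(layer_spec("input"), layer_spec("batchnorm")),
    stages = list(),
    head = list(layer_spec("global_pool"),
                layer_spec("dense", filters = 2, bias = TRUE)),
    n_classes = 2, min_input = 1)
  expect_equal(count_params(bn_net), 4 * 6 + 6 * 2 + 2)
})

test_that("small-network costs agree with literal-loop enumeration", {
  cases <- expand.grid(side = c(7, 10), k1 = c(1, 3), f1 = c(2, 4),
                       padding = c("same", "valid"),
                       stringsAsFactors = FALSE)
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    net <- tiny_net(input_side = cs$side, k1 = cs$k1, f1 = cs$f1,
                    k2 = 1, f2 = 8, padding = cs$padding)
    rep <- cost_report(net)
    s1 <- if (cs$padding == "same") cs$side else cs$side - cs$k1 + 1
    expected_flops <-
      brute_conv_flops(c(cs$side, cs$side, 3), cs$k1, cs$f1,
                       padding = cs$padding) +
      brute_conv_flops(c(s1, s1, cs$f1), 1, 8, padding = cs$padding) +
      2 * 8 * 2
    expect_equal(rep$total_flops, expected_flops)
    expect_equal(rep$total_params,
                 brute_tiny_params(cs$side, cs$k1, cs$f1, 1, 8))
  }
})

test_that("report totals equal their per-layer sums and stay positive", {
  nets <- list(resnet50v2_template(240, 2),
               inception_v4_template(240, 2),
               compound_reduce(resnet50v2_template(240, 2),
                               scaling_coefficients(phi = 2)))
  for (net in nets) {
    rep <- cost_report(net)
    expect_equal(rep$total_flops, sum(rep$per_layer$flops))
    expect_equal(rep$total_params, sum(rep$per_layer$params))
    expect_gt(rep$total_flops, 0)
    expect_gt(rep$total_params, 0)
    expect_true(all(rep$per_layer$flops[!rep$per_layer$kind %in%
                                          c("conv", "dense")] == 0))
  }
})

test_that("reduced networks cost strictly less than their originals", {
  for (tmpl in list(resnet50v2_template(240, 2), inception_v4_template(240, 2))) {
    orig <- cost_report(tmpl)
    red <- cost_report(compound_reduce(tmpl, scaling_coefficients(phi = 1)))
    expect_lt(red$total_flops, orig$total_flops)
    expect_lt(red$total_params, orig$total_params)
  }
})
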