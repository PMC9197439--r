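test_that("reduction factors are the negative powers of the bases", {
  expect_equal(reduction_factors(scaling_coefficients(phi = 0)),
               c(d = 1, w = 1, r = 1))
  f <- reduction_factors(scaling_coefficients(1.2, 1.1, 1.15, phi = 1))
  expect_equal(unname(f), c(1 / 1.2, 1 / 1.1, 1 / 1.15))
  f2 <- reduction_factors(scaling_coefficients(1.2, 1.1, 1.15, phi = 2))
  expect_equal(unname(f2[["w"]]), 1.1^-2)
})

test_that("scale_count rounds to nearest with ties-to-even and clamps at 1", {
  expect_equal(scale_count(256, 1.1^-2), 212)
  expect_equal(scale_count(3, 1.2^-1), 2)    # tie 2.5 resolves to even
  expect_equal(scale_count(1, 0.5), 1)       # clamp floor
  expect_equal(scale_count(240, 1.15^-3), 158)  # 157.8 rounds up
  expect_error(scale_count(0, 0.5), ">= 1")
  expect_error(scale_count(10, 1.5), "factor")
})

test_that("compound reduction reproduces the published reduced stages", {
  net <- resnet50v2_template(240, 2)
  r1 <- compound_reduce(net, scaling_coefficients(phi = 1))
  expect_equal(vapply(r1$stages, function(s) s$repeats, numeric(1)),
               c(2, 3, 5, 2))
  expect_equal(r1$input[1:2], c(209, 209))
  r3 <- compound_reduce(net, scaling_coefficients(phi = 3))
  expect_equal(r3$stages[[4]]$base_width, 385)
  # 4x expansion follows the base width: 385 -> 1540
  shp <- infer_shapes(r3)
  expect_true(any(shp$channels == 1540))
})

test_that("zero exponent is the identity, bit-for-bit through serialization", {
  for (net in list(resnet50v2_template(240, 2), inception_v4_template(240, 2))) {
    same <- compound_reduce(net, scaling_coefficients(phi = 0))
    expect_identical(network_to_json(same), network_to_json(net))
    same_ir <- input_reduce(net, scaling_coefficients(phi = 0))
    expect_identical(network_to_json(same_ir), network_to_json(net))
  }
})

test_that("compound reduction never alters ratios, stem, or classes", {
  net <- resnet50v2_template(240, 2)
  for (phi in 1:3) {
    red <- compound_reduce(net, scaling_coefficients(phi = phi))
    for (k in seq_along(red$stages))
      expect_equal(width_ratios(red$stages[[k]]$block),
                   width_ratios(net$stages[[k]]$block))
    stem_conv <- Filter(function(l) l$kind == "conv", red$stem)[[1]]
    expect_equal(stem_conv$filters, 64)
    expect_equal(red$n_classes, net$n_classes)
    expect_equal(red$input[3], 3)
  }
})

test_that("input reduction scales only the image", {
  net <- resnet50v2_template(240, 2)
  ir1 <- input_reduce(net, scaling_coefficients(phi = 1))
  expect_equal(ir1$input[1:2], c(209, 209))
  expect_equal(vapply(ir1$stages, function(s) s$repeats, numeric(1)),
               vapply(net$stages, function(s) s$repeats, numeric(1)))
  expect_identical(count_params(ir1), count_params(net))
  ir6 <- input_reduce(net, scaling_coefficients(phi = 6))
  expect_equal(ir6$input[1:2], c(104, 104))
  # below the architecture minimum the reduction is rejected
  small <- resnet50v2_template(48, 2)
  expect_error(input_reduce(small, scaling_coefficients(phi = 6)), "minimum")
})

test_that("the balance constraint is checked with its published value", {
  chk <- check_constraint(scaling_coefficients(1.2, 1.1, 1.15))
  expect_equal(chk$value, 1.2 * 1.1^2 * 1.15^2)
  expect_equal(round(chk$value, 4), 1.9203)
  expect_true(chk$ok)
  expect_true(check_constraint(scaling_coefficients(2, 1, 1))$ok)
  expect_false(check_constraint(scaling_coefficients(1, 1, 1))$ok)
})

test_that("the theoretical reduction halves cost per unit exponent", {
  expect_equal(theoretical_ratio(0), 1)
  expect_equal(theoretical_ratio(1), 0.5)
  expect_equal(theoretical_ratio(3), 0.125)
  expect_error(theoretical_ratio(-1), "non-negative")
})

test_that("budget-driven exponent selection matches exhaustive enumeration", {
  net <- resnet50v2_template(240, 2)
  coef <- scaling_coefficients()
  costs <- suppressWarnings(vapply(0:6, function(phi)
    cost_report(compound_reduce(net, scaling_coefficients(phi = phi)))$total_flops,
    numeric(1)))
  oracle <- function(budget) which(costs <= budget)[1] - 1
  for (budget in c(costs[1] * 2, 3.0e9, 2.0e9, costs[7]))
    expect_equal(suppressWarnings(choose_phi_for_budget(net, coef, budget)),
                 oracle(budget))
  expect_equal(choose_phi_for_budget(net, coef, costs[1] * 2), 0)
  expect_error(suppressWarnings(choose_phi_for_budget(net, coef, costs[7] / 2)),
               "unattainable")
})

test_that("cost and parameters are non-increasing in the exponent", {
  for (tmpl in list(resnet50v2_template(240, 2), inception_v4_template(240, 2))) {
    reports <- suppressWarnings(lapply(0:6, function(phi)
      cost_report(compound_reduce(tmpl, scaling_coefficients(phi = phi)))))
    flops <- vapply(reports, `[[`, numeric(1), "total_flops")
    params <- vapply(reports, `[[`, numeric(1), "total_params")
    expect_true(all(diff(flops) <= 0))
    expect_true(all(diff(params) <= 0))
  }
})
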