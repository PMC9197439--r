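test_that("materialized parameter tensors match the analytic count", {
  for (net in list(tiny_net(), toy_cnn_template(32),
                   toy_cnn_template(48, widths = c(4, 8, 12)))) {
    m <- materialize(net, seed = 1)
    expect_identical(n_params(m), count_params(net))
  }
})

test_that("training configuration carries the published protocol defaults", {
  cfg <- train_config()
  expect_equal(cfg$epochs, 50L)
  expect_equal(cfg$learning_rate, 5e-4)
  expect_equal(cfg$weight_decay, 5e-4)
  expect_error(train_config(epochs = 0))
})

test_that("the runtime's convolution agrees with direct summation", {
  # one 3x3 valid conv on a known input, checked against a literal loop
  net <- network_spec("conv1", c(5, 5, 2),
    stem = list(layer_spec("input"),
                layer_spec("conv", kernel = 3, filters = 3, padding = "valid",
                           bias = TRUE)),
    stages = list(),
    head = list(layer_spec("global_pool"),
                layer_spec("dense", filters = 2, bias = TRUE)),
    n_classes = 2, min_input = 3)
  m <- materialize(net, seed = 4)
  x <- array(stats::rnorm(5 * 5 * 2), dim = c(5, 5, 2, 1))
  fwd <- narcnn:::forward_pass(m, x)
  conv_id <- vapply(m$nodes, `[[`, character(1), "id")[
    vapply(m$nodes, `[[`, character(1), "kind") == "conv"]
  got <- fwd$acts[[conv_id]]
  W <- m$params[[conv_id]]$W; b <- m$params[[conv_id]]$b
  for (i in 1:3) for (j in 1:3) for (co in 1:3) {
    want <- b[co]
    for (ki in 1:3) for (kj in 1:3) for (ci in 1:2)
      want <- want + x[i + ki - 1, j + kj - 1, ci, 1] * W[ki, kj, ci, co]
    expect_equal(got[i, j, co, 1], want)
  }
})

test_that("analytic gradients match finite differences on a tiny model", {
  net <- tiny_net(input_side = 6, k1 = 3, f1 = 2, k2 = 1, f2 = 3)
  m <- materialize(net, seed = 2)
  x <- with_seed_test(3, array(stats::runif(6 * 6 * 3 * 2), dim = c(6, 6, 3, 2)))
  y1 <- c(1L, 2L)
  loss_at <- function(model) {
    fwd <- narcnn:::forward_pass(model, x, train = FALSE)
    narcnn:::softmax_loss(fwd$out, y1)$loss
  }
  fwd <- narcnn:::forward_pass(m, x, train = FALSE, keep = TRUE)
  sl <- narcnn:::softmax_loss(fwd$out, y1)
  grads <- narcnn:::backward_pass(m, fwd, sl$dlogits)
  eps <- 1e-5
  for (id in names(grads)) for (nm in names(grads[[id]])) {
    p <- m$params[[id]][[nm]]
    for (k in unique(c(1, ceiling(length(p) / 2), length(p)))) {
      mp <- m; mp$params[[id]][[nm]][k] <- p[k] + eps
      mm <- m; mm$params[[id]][[nm]][k] <- p[k] - eps
      fd <- (loss_at(mp) - loss_at(mm)) / (2 * eps)
      g <- grads[[id]][[nm]][k]
      expect_lt(abs(fd - g), 1e-4 * max(1, abs(g)))
    }
  }
})

test_that("a short run learns the synthetic task and is seed-reproducible", {
  sets <- synth_sets()
  small <- list(x = sets$train$x[1:80], y = sets$train$y[1:80])
  cfg <- train_config(epochs = 2, batch_size = 16, seed = 0)
  m <- materialize(toy_cnn_template(32), seed = 0)
  fit1 <- train(m, small, cfg)
  expect_length(fit1$history, 2)
  expect_lt(fit1$history[2], fit1$history[1])
  fit2 <- train(m, small, cfg)
  expect_identical(fit1$history, fit2$history)
  expect_identical(fit1$params, fit2$params)
})

test_that("training rejects a dataset whose images mismatch the input", {
  m <- materialize(toy_cnn_template(32), seed = 0)
  bad <- list(x = array(0.5, dim = c(16, 16, 3, 4)), y = c(0, 1, 0, 1))
  expect_error(train(m, bad, train_config(epochs = 1)), "expects")
})

test_that("rank-based AUC matches its definition and an independent oracle", {
  expect_equal(evaluate_auc(c(.9, .8, .3, .2), c(1, 1, 0, 0))$auc_mean, 1)
  expect_equal(evaluate_auc(c(.9, .8, .3, .2), c(0, 0, 1, 1))$auc_mean, 0)
  expect_error(evaluate_auc(c(.1, .2), c(1, 1)), "single class")
  # independent scores hover at chance level
  perm <- with_seed_test(42, {
    list(s = stats::runif(10000), y = stats::rbinom(10000, 1, 0.5))
  })
  expect_equal(evaluate_auc(perm$s, perm$y)$auc_mean, 0.5, tolerance = 0.02)
  # cross-check against the ROC reference implementation
  skip_if_not_installed("pROC")
  ex <- with_seed_test(7, list(s = stats::runif(200), y = stats::rbinom(200, 1, 0.4)))
  ref <- as.numeric(pROC::auc(pROC::roc(ex$y, ex$s, quiet = TRUE,
                                        direction = "<")))
  expect_equal(evaluate_auc(ex$s, ex$y)$auc_mean, ref, tolerance = 1e-12)
})

test_that("multi-run evaluation averages per-run AUCs", {
  runs <- list(c(.9, .8, .3, .2), c(.2, .8, .3, .9), c(.6, .7, .4, .5))
  ev <- evaluate_auc(runs, c(1, 1, 0, 0))
  expect_equal(ev$n_runs, 3)
  expect_equal(ev$auc_mean, mean(ev$auc_runs))
  expect_true(all(ev$auc_runs >= 0 & ev$auc_runs <= 1))
})
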