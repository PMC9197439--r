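# Shared fixtures and independent oracles, built in code at test time.

# A minimal sequential network: input -> conv -> conv -> global pool -> dense.
tiny_net <- function(input_side = 10, k1 = 3, f1 = 4, k2 = 1, f2 = 8,
                     n_classes = 2, padding = "same", bias1 = TRUE) {
  network_spec(
    name = "tiny",
    input = c(input_side, input_side, 3),
    stem = list(
      layer_spec("input"),
      layer_spec("conv", kernel = k1, filters = f1, padding = padding,
                 bias = bias1),
      layer_spec("conv", kernel = k2, filters = f2, padding = padding)),
    stages = list(),
    head = list(layer_spec("global_pool"),
                layer_spec("dense", filters = n_classes, bias = TRUE)),
    n_classes = n_classes,
    min_input = 4)
}

# Literal-loop FLOPs oracle for one convolution: walks every output
# element and kernel tap, counting one multiply and one add each.
brute_conv_flops <- function(in_shape, kernel, filters, stride = 1,
                             padding = "same") {
  ho <- if (padding == "same") ceiling(in_shape[1] / stride)
        else floor((in_shape[1] - kernel) / stride) + 1
  wo <- if (padding == "same") ceiling(in_shape[2] / stride)
        else floor((in_shape[2] - kernel) / stride) + 1
  flops <- 0
  for (i in seq_len(ho)) for (j in seq_len(wo)) for (co in seq_len(filters))
    for (ci in seq_len(in_shape[3])) for (ki in seq_len(kernel))
      for (kj in seq_len(kernel))
        flops <- flops + 2
  flops
}

# Literal weight-tensor enumeration for the tiny network above.
brute_tiny_params <- function(input_side = 10, k1 = 3, f1 = 4, k2 = 1,
                              f2 = 8, n_classes = 2, bias1 = TRUE) {
  n <- 0
  n <- n + k1 * k1 * 3 * f1 + if (bias1) f1 else 0   # conv1
  n <- n + k2 * k2 * f1 * f2                          # conv2 (no bias)
  n <- n + f2 * n_classes + n_classes                 # dense
  n
}

# Published reduced-architecture cells driven by (1.2, 1.1, 1.15): each row
# is (original count, factor, expected). The ambiguous stage-2 width pair at
# phi 1/2 — whose printed values are mutually swapped relative to the
# formula — is excluded.
published_cells <- function() {
  rbind(
    # stage repeats at phi = 1..3 (alpha = 1.2)
    expand.grid(n = c(3, 4, 6), phi = 1:3, kind = "depth"),
    # stage base widths at phi = 1..3 (beta = 1.1), stage 2 only at phi = 3
    expand.grid(n = c(64, 256, 512), phi = 1:3, kind = "width"),
    expand.grid(n = 128, phi = 3, kind = "width"),
    # input sides at phi = 1..6 (gamma = 1.15)
    expand.grid(n = 240, phi = 1:6, kind = "res"))
}

published_expected <- local({
  e <- new.env()
  e$depth <- list(`3` = c(2, 2, 2), `4` = c(3, 3, 2), `6` = c(5, 4, 3))
  e$width <- list(`64` = c(58, 53, 48), `256` = c(233, 212, 192),
                  `512` = c(465, 423, 385), `128` = c(NA, NA, 96))
  e$res <- list(`240` = c(209, 181, 158, 137, 119, 104))
  e
})

with_seed_test <- function(seed, code) withr::with_seed(seed, code)

# Small shared synthetic dataset (generated once per test session).
synth_sets <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      tr_dir <- file.path(tempdir(), "narcnn_train")
      te_dir <- file.path(tempdir(), "narcnn_test")
      tr <- make_manifest(200, 0.5, 64, tr_dir, seed = 11)
      te <- make_manifest(100, 0.5, 64, te_dir, seed = 99)
      cache <<- list(train = load_manifest(tr), test = load_manifest(te))
    }
    cache
  }
})
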