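# Analytic cost model: shape inference through the compiled graph plus
# FLOPs and parameter accounting. FLOPs are counted as 2 x multiply-
# accumulates over convolutional and dense layers only; batch
# normalisation, pooling, activations and shortcut additions contribute
# zero, and no bias-add term is included, matching the published counting
# convention. Parameters count every stored weight, including the four
# batch-normalisation statistics per channel (scale, shift, moving mean,
# moving variance).

#' Tensor shape
#'
#' @param height,width,channels Strictly positive integers.
#' @return Named numeric vector `c(height, width, channels)` of class
#'   `nar_shape`.
#' @export
tensor_shape <- function(height, width, channels) {
  s <- c(height = as.numeric(height), width = as.numeric(width),
         channels = as.numeric(channels))
  if (any(s < 1) || any(s != floor(s)))
    stop("tensor dimensions must be strictly positive integers")
  structure(s, class = "nar_shape")
}

out_side <- function(side, kernel, stride, padding) {
  if (padding == "same") return(ceiling(side / stride))
  o <- floor((side - kernel) / stride) + 1
  if (o < 1) stop("valid-padding window ", kernel, " does not fit input side ", side)
  o
}

infer_shapes_nodes <- function(nodes, input) {
  shapes <- list()
  get1 <- function(node) {
    if (length(node$inputs) != 1)
      stop("layer ", node$id, " expects exactly one input")
    shapes[[node$inputs]]
  }
  for (node in nodes) {
    s <- switch(node$kind,
      input = input,
      conv = {
        i <- get1(node)
        c(out_side(i[1], node$kernel[1], node$stride[1], node$padding),
          out_side(i[2], node$kernel[2], node$stride[2], node$padding),
          node$filters)
      },
      pool_max = ,
      pool_avg = {
        i <- get1(node)
        c(out_side(i[1], node$kernel[1], node$stride[1], node$padding),
          out_side(i[2], node$kernel[2], node$stride[2], node$padding),
          i[3])
      },
      global_pool = c(1, 1, get1(node)[3]),
      flatten = { i <- get1(node); c(1, 1, prod(i)) },
      dense = c(1, 1, node$filters),
      batchnorm = ,
      activation = get1(node),
      add = {
        ins <- shapes[node$inputs]
        for (k in seq_along(ins)[-1])
          if (!identical(ins[[1]], ins[[k]]))
            stop("shape mismatch at add layer ", node$id, ": ",
                 paste(ins[[1]], collapse = "x"), " vs ",
                 paste(ins[[k]], collapse = "x"))
        ins[[1]]
      },
      concat = {
        ins <- shapes[node$inputs]
        for (k in seq_along(ins)[-1])
          if (!identical(ins[[1]][1:2], ins[[k]][1:2]))
            stop("spatial mismatch at concat layer ", node$id)
        c(ins[[1]][1:2], sum(vapply(ins, function(x) x[3], numeric(1))))
      },
      stop("unknown layer kind ", node$kind, " at ", node$id))
    shapes[[node$id]] <- s
  }
  shapes
}

#' Infer the output shape of every layer
#'
#' Walks the compiled layer graph. `"same"`-padded windows produce
#' `ceiling(side / stride)` outputs; `"valid"` windows produce
#' `floor((side - kernel) / stride) + 1`.
#'
#' @param net A `nar_network`.
#' @return A data frame with one row per layer: `id`, `kind`, `height`,
#'   `width`, `channels`.
#' @examples
#' shp <- infer_shapes(resnet50v2_template(240, 2))
#' head(shp)
#' @export
infer_shapes <- function(net) {
  nodes <- compile_network(net)
  shapes <- infer_shapes_nodes(nodes, net$input)
  data.frame(
    id = vapply(nodes, `[[`, character(1), "id"),
    kind = vapply(nodes, `[[`, character(1), "kind"),
    height = vapply(nodes, function(n) shapes[[n$id]][1], numeric(1)),
    width = vapply(nodes, function(n) shapes[[n$id]][2], numeric(1)),
    channels = vapply(nodes, function(n) shapes[[n$id]][3], numeric(1)),
    stringsAsFactors = FALSE)
}

#' Convolution FLOPs
#'
#' `2 * C_in * K_h * K_w * H_out * W_out * C_out`: two floating-point
#' operations per multiply-accumulate, no bias-add term.
#'
#' @param layer A conv [layer_spec()] (its kernel is used).
#' @param in_shape,out_shape Shapes `c(height, width, channels)`.
#' @return FLOPs count.
#' @examples
#' conv_flops(layer_spec("conv", kernel = 7, filters = 64),
#'            c(240, 240, 3), c(120, 120, 64))
#' @export
conv_flops <- function(layer, in_shape, out_shape) {
  if (any(c(layer$kernel, in_shape[3], out_shape[3]) < 1))
    stop("kernel and channel counts must be positive")
  2 * in_shape[3] * layer$kernel[1] * layer$kernel[2] *
    out_shape[1] * out_shape[2] * out_shape[3]
}

#' Dense-layer FLOPs
#'
#' `2 * in_size * out_size`.
#'
#' @param in_size,out_size Positive input/output widths.
#' @return FLOPs count.
#' @export
dense_flops <- function(in_size, out_size) {
  if (in_size < 1 || out_size < 1) stop("sizes must be positive")
  2 * in_size * out_size
}

node_params <- function(node, in_shape) {
  switch(node$kind,
    conv = node$kernel[1] * node$kernel[2] * in_shape[3] * node$filters +
      if (node$bias) node$filters else 0,
    dense = prod(in_shape) * node$filters + if (node$bias) node$filters else 0,
    batchnorm = 4 * in_shape[3],
    0)
}

#' Count network parameters
#'
#' Convolutions contribute `K_h * K_w * C_in * C_out` (+ `C_out` when
#' biased), dense layers `in * out + out`, batch normalisation `4 * C`
#' (scale, shift, moving mean, moving variance); all other layer kinds are
#' parameter-free.
#'
#' @param net A `nar_network`.
#' @return Total parameter count.
#' @examples
#' count_params(resnet50v2_template(240, 2))  # 23568898
#' @export
count_params <- function(net) {
  nodes <- compile_network(net)
  shapes <- infer_shapes_nodes(nodes, net$input)
  tot <- 0
  for (node in nodes) {
    ins <- if (length(node$inputs)) shapes[[node$inputs[1]]] else net$input
    tot <- tot + node_params(node, ins)
  }
  tot
}

#' Per-layer and total cost report
#'
#' Runs shape inference and accumulates FLOPs (conv + dense only) and
#' parameters for every layer.
#'
#' @param net A `nar_network`.
#' @return A `nar_cost_report`: list with `per_layer` (data frame: `id`,
#'   `kind`, `height`, `width`, `channels`, `flops`, `params`),
#'   `total_flops`, `total_params`, and `gflops` (`total_flops / 1e9`
#'   rounded half-up to 2 decimals).
#' @examples
#' cost_report(resnet50v2_template(240, 2))
#' @export
cost_report <- function(net) {
  nodes <- compile_network(net)
  shapes <- infer_shapes_nodes(nodes, net$input)
  n <- length(nodes)
  flops <- params <- numeric(n)
  for (k in seq_len(n)) {
    node <- nodes[[k]]
    out <- shapes[[node$id]]
    ins <- if (length(node$inputs)) shapes[[node$inputs[1]]] else net$input
    params[k] <- node_params(node, ins)
    flops[k] <- switch(node$kind,
      conv = conv_flops(list(kernel = node$kernel), ins, out),
      dense = dense_flops(prod(ins), node$filters),
      0)
  }
  per_layer <- data.frame(
    id = vapply(nodes, `[[`, character(1), "id"),
    kind = vapply(nodes, `[[`, character(1), "kind"),
    height = vapply(nodes, function(nd) shapes[[nd$id]][1], numeric(1)),
    width = vapply(nodes, function(nd) shapes[[nd$id]][2], numeric(1)),
    channels = vapply(nodes, function(nd) shapes[[nd$id]][3], numeric(1)),
    flops = flops, params = params, stringsAsFactors = FALSE)
  structure(list(network = net$name, input = net$input,
                 per_layer = per_layer,
                 total_flops = sum(flops), total_params = sum(params),
                 gflops = round_half_up(sum(flops) / 1e9, 2)),
            class = "nar_cost_report")
}

#' @export
print.nar_cost_report <- function(x, ...) {
  cat(sprintf("<nar_cost_report> %s  input %gx%gx%g\n", x$network,
              x$input[1], x$input[2], x$input[3]))
  cat(sprintf("  layers: %d   total FLOPs: %s (%.2f GFLOPs)   params: %s\n",
              nrow(x$per_layer), format(x$total_flops, big.mark = ","),
              x$gflops, format(x$total_params, big.mark = ",")))
  invisible(x)
}

# Continuous-relaxation cost: evaluates the conv/dense FLOPs total with
# real-valued spatial sides, real-valued widths and fractional repeat
# weights instead of rounded integers. Used to study the scaling law
# FLOPs(phi)/FLOPs(0) ~ d * w^2 * r^2 free of integer-rounding noise.
continuous_cost <- function(net, coefficients) {
  f <- reduction_factors(coefficients)
  nodes <- compile_network(net)
  rep_weight <- function(node) {
    st <- Filter(function(s) identical(s$name, node$stage), net$stages)
    if (length(st) == 0 || !st[[1]]$depth_scalable || is.na(node$instance))
      return(1)
    L <- st[[1]]$repeats
    if (node$instance == 1 || L == 1) return(1)
    max(f[["d"]] * L - 1, 0) / (L - 1)
  }
  w_of <- function(node) {
    st <- Filter(function(s) identical(s$name, node$stage), net$stages)
    if (length(st) == 0) 1 else f[["w"]]
  }
  shapes <- list()
  tot <- 0
  for (node in nodes) {
    ins <- if (length(node$inputs)) shapes[[node$inputs[1]]] else NULL
    s <- switch(node$kind,
      input = c(net$input[1] * f[["r"]], net$input[2] * f[["r"]], net$input[3]),
      conv = c(ins[1] / node$stride[1], ins[2] / node$stride[2],
               node$filters * w_of(node)),
      pool_max = ,
      pool_avg = c(ins[1] / node$stride[1], ins[2] / node$stride[2], ins[3]),
      global_pool = c(1, 1, ins[3]),
      flatten = c(1, 1, prod(ins)),
      dense = c(1, 1, node$filters),
      concat = {
        insl <- shapes[node$inputs]
        c(insl[[1]][1:2], sum(vapply(insl, function(x) x[3], numeric(1))))
      },
      ins)
    shapes[[node$id]] <- s
    if (node$kind == "conv")
      tot <- tot + rep_weight(node) *
        2 * ins[3] * node$kernel[1] * node$kernel[2] * s[1] * s[2] * s[3]
    if (node$kind == "dense")
      tot <- tot + 2 * prod(ins) * node$filters
  }
  tot
}
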