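# Intermediate representation of block-based CNN architectures.
#
# A network is described symbolically: a stem (ordered layers, possibly
# branched blocks), a list of stages (a block template repeated `repeats`
# times around a stage base width), and a head. Widths inside a block are
# expressed as rational multiples of the stage base width so that compound
# reduction rescales every convolution while preserving the block's internal
# proportions (e.g. the 1:1:4 bottleneck expansion).

LAYER_KINDS <- c("input", "conv", "dense", "batchnorm", "activation",
                 "pool_max", "pool_avg", "global_pool", "add", "concat",
                 "flatten")

#' Describe a single layer
#'
#' Layers are the leaves of the architecture representation. Convolutions
#' either carry an absolute filter count (`filters`, fixed under width
#' scaling, e.g. a stem convolution) or a `width_ratio` relative to the
#' enclosing stage's base width (rescaled by compound reduction).
#'
#' @param kind One of `"input"`, `"conv"`, `"dense"`, `"batchnorm"`,
#'   `"activation"`, `"pool_max"`, `"pool_avg"`, `"global_pool"`, `"add"`,
#'   `"concat"`, `"flatten"`.
#' @param kernel Length-2 numeric `(h, w)` kernel for conv/pool layers.
#' @param filters Absolute output channels (conv) or units (dense); mutually
#'   exclusive with `width_ratio` for convolutions.
#' @param width_ratio Output channels as a multiple of the stage base width.
#' @param stride Length-2 numeric `(h, w)` stride.
#' @param padding `"same"` or `"valid"`.
#' @param bias Whether the layer carries an additive bias term.
#' @param takes_stride Marks the convolution that receives a block's
#'   downsampling stride when the block instance downsamples.
#' @return A `nar_layer` object.
#' @export
layer_spec <- function(kind, kernel = NULL, filters = NULL, width_ratio = NULL,
                       stride = c(1, 1), padding = "same", bias = FALSE,
                       takes_stride = FALSE) {
  kind <- match.arg(kind, LAYER_KINDS)
  if (!is.null(kernel)) {
    kernel <- as.numeric(kernel)
    if (length(kernel) == 1) kernel <- c(kernel, kernel)
    if (any(kernel < 1)) stop("kernel dimensions must be positive")
  }
  stride <- as.numeric(stride)
  if (length(stride) == 1) stride <- c(stride, stride)
  if (any(stride < 1)) stop("stride must be positive")
  if (!is.null(filters)) {
    filters <- as.numeric(filters)
    if (filters < 1) stop("filters must be positive when present")
  }
  if (!kind %in% c("conv", "dense") && (!is.null(filters) || !is.null(width_ratio)))
    stop("non-parametric layer kinds carry no filters")
  if (kind == "conv" && is.null(filters) && is.null(width_ratio))
    stop("conv layers need either filters or width_ratio")
  padding <- match.arg(padding, c("same", "valid"))
  structure(list(kind = kind, kernel = kernel, filters = filters,
                 width_ratio = if (!is.null(width_ratio)) as.numeric(width_ratio),
                 stride = stride, padding = padding, bias = isTRUE(bias),
                 takes_stride = isTRUE(takes_stride)),
            class = "nar_layer")
}

#' Describe a block of layers
#'
#' A block is either a straight sequence (`layers`), optionally closed by a
#' residual shortcut (`merge = "add"`), or a set of parallel `branches`
#' merged by channel concatenation (`merge = "concat"`). Branch elements may
#' themselves be `block_spec`s, which covers architectures whose branches
#' split again (e.g. the final Inception group).
#'
#' @param name Block label.
#' @param layers Ordered list of [layer_spec()]s (sequential form).
#' @param branches List of branches, each an ordered list of layers/blocks.
#' @param merge `"none"`, `"add"` (residual) or `"concat"`.
#' @param shortcut Shortcut policy for residual blocks: `"none"`,
#'   `"identity"`, or `"projection"` (a 1x1 convolution; instantiated in the
#'   first repeat of a stage, later repeats fall back to identity).
#' @return A `nar_block` object.
#' @export
block_spec <- function(name, layers = NULL, branches = NULL,
                       merge = c("none", "add", "concat"),
                       shortcut = c("none", "identity", "projection")) {
  merge <- match.arg(merge)
  shortcut <- match.arg(shortcut)
  if (is.null(layers) == is.null(branches))
    stop("exactly one of layers/branches must be given")
  if (merge == "concat" && is.null(branches))
    stop("concat blocks need branches")
  structure(list(name = name, layers = layers, branches = branches,
                 merge = merge, shortcut = shortcut),
            class = "nar_block")
}

#' Per-layer width ratios of a block
#'
#' Returns the width ratios of every width-scalable convolution in the block,
#' in traversal order (branches in order, depth first).
#'
#' @param block A `nar_block`.
#' @return Numeric vector of ratios.
#' @export
width_ratios <- function(block) {
  collect <- function(el) {
    if (inherits(el, "nar_layer"))
      return(if (el$kind == "conv" && !is.null(el$width_ratio)) el$width_ratio else numeric())
    els <- if (!is.null(el$layers)) el$layers else unlist(el$branches, recursive = FALSE)
    unlist(lapply(els, collect))
  }
  collect(block)
}

#' Describe a repeated stage
#'
#' @param name Stage label.
#' @param block The [block_spec()] template repeated in this stage.
#' @param repeats Number of block repetitions (>= 1).
#' @param base_width Stage base width; scalable convolutions inside the block
#'   resolve to `round(base_width * width_ratio)`.
#' @param depth_scalable Whether compound reduction may change `repeats`.
#' @param downsample `"none"` or `"start"`: whether the first block instance
#'   halves the spatial resolution (stride 2 on its marked convolution and
#'   shortcut).
#' @param transition Optional [block_spec()] executed once after the repeats
#'   (e.g. an Inception reduction block); never removed by depth scaling.
#' @return A `nar_stage` object.
#' @export
stage_spec <- function(name, block, repeats, base_width, depth_scalable = TRUE,
                       downsample = c("none", "start"), transition = NULL) {
  repeats <- as.numeric(repeats)
  base_width <- as.numeric(base_width)
  if (repeats < 1) stop("repeats must be >= 1")
  if (base_width < 1) stop("base_width must be >= 1")
  structure(list(name = name, block = block, repeats = repeats,
                 base_width = base_width, depth_scalable = isTRUE(depth_scalable),
                 downsample = match.arg(downsample), transition = transition),
            class = "nar_stage")
}

#' Describe a full network
#'
#' @param name Network label.
#' @param input Length-3 numeric `(height, width, channels)`.
#' @param stem Ordered list of layers/blocks applied before the stages; the
#'   first element must be the (single) input layer.
#' @param stages List of [stage_spec()]s.
#' @param head Ordered list of layers applied after the stages (typically a
#'   global pool and the dense classifier).
#' @param n_classes Number of output classes (>= 2).
#' @param min_input Smallest input side the topology supports.
#' @return A `nar_network` object.
#' @export
network_spec <- function(name, input, stem, stages, head, n_classes,
                         min_input = 32) {
  input <- as.numeric(input)
  if (length(input) != 3 || any(input < 1))
    stop("input must be three positive integers (height, width, channels)")
  structure(list(name = name, input = input, stem = stem, stages = stages,
                 head = head, n_classes = as.numeric(n_classes),
                 min_input = as.numeric(min_input)),
            class = "nar_network")
}

#' @export
print.nar_network <- function(x, ...) {
  cat(sprintf("<nar_network> %s  input %gx%gx%g  %g classes\n", x$name,
              x$input[1], x$input[2], x$input[3], x$n_classes))
  for (st in x$stages)
    cat(sprintf("  stage %-14s width %4g x %g repeats%s\n", st$name,
                st$base_width, st$repeats,
                if (!is.null(st$transition)) " + transition" else ""))
  invisible(x)
}

# conv + batchnorm + activation triple used throughout the Inception template
conv_bn <- function(kernel, width_ratio = NULL, filters = NULL,
                    stride = c(1, 1), padding = "same") {
  list(layer_spec("conv", kernel = kernel, width_ratio = width_ratio,
                  filters = filters, stride = stride, padding = padding,
                  bias = FALSE),
       layer_spec("batchnorm"),
       layer_spec("activation"))
}

#' ResNet50 V2 template
#'
#' Pre-activation bottleneck ResNet with stage base widths 64/128/256/512,
#' 1:1:4 width ratios, repeats 3/4/6/3, and downsampling at the start of
#' stages 2-4 (stride 2 on the 3x3 convolution and the projection shortcut).
#' Batch normalisation and activation precede each convolution; biases follow
#' the convention that reproduces the published 23,568,898 parameter total
#' for a 2-class head: stem convolution, final 1x1 of each bottleneck,
#' projection shortcuts and the dense classifier carry biases, the first two
#' bottleneck convolutions do not.
#'
#' @param input_side Input image side in pixels (>= 32).
#' @param n_classes Number of output classes (>= 2).
#' @return A `nar_network`.
#' @examples
#' net <- resnet50v2_template(240, 2)
#' vapply(net$stages, function(s) s$repeats, numeric(1))
#' @export
resnet50v2_template <- function(input_side, n_classes = 2) {
  input_side <- as.numeric(input_side)
  if (input_side < 32)
    stop("input_side ", input_side, " is below the minimum of 32 needed for ",
         "the template's five downsamplings")
  if (n_classes < 2) stop("n_classes must be >= 2")

  bottleneck <- block_spec(
    "bottleneck_v2",
    layers = list(
      layer_spec("batchnorm"), layer_spec("activation"),
      layer_spec("conv", kernel = 1, width_ratio = 1, bias = FALSE),
      layer_spec("batchnorm"), layer_spec("activation"),
      layer_spec("conv", kernel = 3, width_ratio = 1, bias = FALSE,
                 takes_stride = TRUE),
      layer_spec("batchnorm"), layer_spec("activation"),
      layer_spec("conv", kernel = 1, width_ratio = 4, bias = TRUE)),
    merge = "add", shortcut = "projection")

  stage <- function(name, width, repeats, downsample)
    stage_spec(name, bottleneck, repeats, width, depth_scalable = TRUE,
               downsample = downsample)

  network_spec(
    name = "resnet50v2",
    input = c(input_side, input_side, 3),
    stem = list(
      layer_spec("input"),
      layer_spec("conv", kernel = 7, filters = 64, stride = 2,
                 padding = "same", bias = TRUE),
      layer_spec("pool_max", kernel = 3, stride = 2, padding = "same")),
    stages = list(
      stage("stage1", 64, 3, "none"),
      stage("stage2", 128, 4, "start"),
      stage("stage3", 256, 6, "start"),
      stage("stage4", 512, 3, "start")),
    head = list(
      layer_spec("batchnorm"), layer_spec("activation"),
      layer_spec("global_pool"),
      layer_spec("dense", filters = n_classes, bias = TRUE)),
    n_classes = n_classes,
    min_input = 32)
}

#' Inception V4 template
#'
#' The canonical Inception V4 topology: a valid-padding stem with three
#' branched mixing blocks, four Inception-A blocks, a Reduction-A block,
#' seven Inception-B blocks, a Reduction-B block, three Inception-C blocks,
#' global average pooling and a dense classifier. The A/B/C groups are
#' depth-scalable; the reduction blocks are stage transitions and are never
#' removed. Branch widths are expressed as rational multiples of each
#' group's base width (96 for A, 256 for B and C) so that width scaling
#' preserves the branch proportions.
#'
#' @param input_side Input image side in pixels (>= 96).
#' @param n_classes Number of output classes (>= 2).
#' @return A `nar_network`.
#' @export
inception_v4_template <- function(input_side, n_classes = 2) {
  input_side <- as.numeric(input_side)
  if (input_side < 96)
    stop("input_side ", input_side, " is below the minimum of 96 for the ",
         "valid-padding Inception V4 stem")
  if (n_classes < 2) stop("n_classes must be >= 2")

  br <- function(...) c(...)  # branch = flat list of layers

  stem <- flatten_elements(list(
    layer_spec("input"),
    conv_bn(3, filters = 32, stride = 2, padding = "valid"),
    conv_bn(3, filters = 32, padding = "valid"),
    conv_bn(3, filters = 64),
    block_spec("stem_mixed3a", branches = list(
      list(layer_spec("pool_max", kernel = 3, stride = 2, padding = "valid")),
      br(conv_bn(3, filters = 96, stride = 2, padding = "valid"))),
      merge = "concat"),
    block_spec("stem_mixed4a", branches = list(
      br(conv_bn(1, filters = 64), conv_bn(3, filters = 96, padding = "valid")),
      br(conv_bn(1, filters = 64), conv_bn(c(7, 1), filters = 64),
         conv_bn(c(1, 7), filters = 64), conv_bn(3, filters = 96, padding = "valid"))),
      merge = "concat"),
    block_spec("stem_mixed5a", branches = list(
      br(conv_bn(3, filters = 192, stride = 2, padding = "valid")),
      list(layer_spec("pool_max", kernel = 3, stride = 2, padding = "valid"))),
      merge = "concat")))

  inception_a <- block_spec("inception_a", branches = list(
    br(list(layer_spec("pool_avg", kernel = 3)), conv_bn(1, 1)),
    br(conv_bn(1, 1)),
    br(conv_bn(1, 2 / 3), conv_bn(3, 1)),
    br(conv_bn(1, 2 / 3), conv_bn(3, 1), conv_bn(3, 1))),
    merge = "concat")
  reduction_a <- block_spec("reduction_a", branches = list(
    list(layer_spec("pool_max", kernel = 3, stride = 2, padding = "valid")),
    br(conv_bn(3, 4, stride = 2, padding = "valid")),
    br(conv_bn(1, 2), conv_bn(3, 7 / 3), conv_bn(3, 8 / 3, stride = 2,
                                                 padding = "valid"))),
    merge = "concat")
  inception_b <- block_spec("inception_b", branches = list(
    br(list(layer_spec("pool_avg", kernel = 3)), conv_bn(1, 1 / 2)),
    br(conv_bn(1, 3 / 2)),
    br(conv_bn(1, 3 / 4), conv_bn(c(1, 7), 7 / 8), conv_bn(c(7, 1), 1)),
    br(conv_bn(1, 3 / 4), conv_bn(c(1, 7), 3 / 4), conv_bn(c(7, 1), 7 / 8),
       conv_bn(c(1, 7), 7 / 8), conv_bn(c(7, 1), 1))),
    merge = "concat")
  reduction_b <- block_spec("reduction_b", branches = list(
    list(layer_spec("pool_max", kernel = 3, stride = 2, padding = "valid")),
    br(conv_bn(1, 3 / 4), conv_bn(3, 3 / 4, stride = 2, padding = "valid")),
    br(conv_bn(1, 1), conv_bn(c(1, 7), 1), conv_bn(c(7, 1), 5 / 4),
       conv_bn(3, 5 / 4, stride = 2, padding = "valid"))),
    merge = "concat")
  inception_c <- block_spec("inception_c", branches = list(
    br(list(layer_spec("pool_avg", kernel = 3)), conv_bn(1, 1)),
    br(conv_bn(1, 1)),
    br(conv_bn(1, 3 / 2),
       list(block_spec("c_split_a", branches = list(
         br(conv_bn(c(1, 3), 1)), br(conv_bn(c(3, 1), 1))), merge = "concat"))),
    br(conv_bn(1, 3 / 2), conv_bn(c(1, 3), 7 / 4), conv_bn(c(3, 1), 2),
       list(block_spec("c_split_b", branches = list(
         br(conv_bn(c(3, 1), 1)), br(conv_bn(c(1, 3), 1))), merge = "concat")))),
    merge = "concat")

  network_spec(
    name = "inceptionv4",
    input = c(input_side, input_side, 3),
    stem = stem,
    stages = list(
      stage_spec("inception_a", inception_a, 4, 96, transition = reduction_a),
      stage_spec("inception_b", inception_b, 7, 256, transition = reduction_b),
      stage_spec("inception_c", inception_c, 3, 256)),
    head = list(
      layer_spec("global_pool"),
      layer_spec("dense", filters = n_classes, bias = TRUE)),
    n_classes = n_classes,
    min_input = 96)
}

# Flatten nested lists of elements while keeping nar_layer/nar_block leaves
flatten_elements <- function(els) {
  out <- list()
  for (el in els) {
    if (inherits(el, "nar_layer") || inherits(el, "nar_block"))
      out[[length(out) + 1]] <- el
    else if (is.list(el))
      out <- c(out, flatten_elements(el))
    else stop("unexpected element in layer list")
  }
  out
}

#' Validate a network description
#'
#' Checks the structural invariants of every layer, block and stage and runs
#' shape inference end to end. Problems are returned as data, not raised.
#'
#' @param net A `nar_network`.
#' @return Character vector of issues; empty when the network is valid.
#' @examples
#' validate_network(resnet50v2_template(240, 2))
#' @export
validate_network <- function(net) {
  issues <- character()
  say <- function(...) issues <<- c(issues, sprintf(...))
  if (!inherits(net, "nar_network")) return("not a nar_network object")
  if (length(net$input) != 3 || any(net$input < 1))
    say("input shape must be three positive integers")
  n_input <- 0
  check_layer <- function(l, where) {
    if (!l$kind %in% LAYER_KINDS) say("%s: unknown layer kind '%s'", where, l$kind)
    if (l$kind == "input") n_input <<- n_input + 1
    if (!is.null(l$kernel) && any(l$kernel < 1)) say("%s: non-positive kernel", where)
    if (any(l$stride < 1)) say("%s: non-positive stride", where)
    if (!is.null(l$filters) && l$filters < 1) say("%s: non-positive filters", where)
    if (l$kind == "conv" && is.null(l$filters) && is.null(l$width_ratio))
      say("%s: conv with no width", where)
  }
  check_block <- function(b, where) {
    els <- if (!is.null(b$layers)) list(b$layers) else b$branches
    for (branch in els) for (el in branch) {
      if (inherits(el, "nar_block")) check_block(el, paste0(where, "/", el$name))
      else check_layer(el, where)
    }
  }
  for (el in net$stem) {
    if (inherits(el, "nar_block")) check_block(el, paste0("stem/", el$name))
    else check_layer(el, "stem")
  }
  for (st in net$stages) {
    if (st$repeats < 1) say("stage %s: repeats must be >= 1", st$name)
    if (st$base_width < 1) say("stage %s: base_width must be >= 1", st$name)
    check_block(st$block, st$name)
    if (!is.null(st$transition)) check_block(st$transition, paste0(st$name, "/transition"))
  }
  for (el in net$head) check_layer(el, "head")
  if (n_input != 1) say("network must contain exactly one input layer (found %d)", n_input)
  dense <- Filter(function(l) l$kind == "dense", net$head)
  if (length(dense) == 0) say("head has no dense classifier")
  else if (dense[[length(dense)]]$filters != net$n_classes)
    say("dense classifier output (%d) does not equal n_classes (%d)",
        dense[[length(dense)]]$filters, net$n_classes)
  if (length(issues) == 0) {
    shp <- tryCatch(infer_shapes(net), error = function(e) e)
    if (inherits(shp, "error")) say("shape inference failed: %s", conditionMessage(shp))
  }
  issues
}

#' Serialize a network to JSON
#'
#' The document is self-contained: every count is explicit and
#' `network_from_json(network_to_json(net))` is structurally identical to
#' `net`.
#'
#' @param net A `nar_network`.
#' @param path Optional file to write to.
#' @return The JSON text, invisibly when `path` is given.
#' @export
network_to_json <- function(net, path = NULL) {
  enc_layer <- function(l) c(list(node = "layer"), Filter(Negate(is.null), unclass(l)))
  enc_block <- function(b) {
    out <- list(node = "block", name = b$name, merge = b$merge, shortcut = b$shortcut)
    if (!is.null(b$layers)) out$layers <- lapply(b$layers, enc_el)
    if (!is.null(b$branches))
      out$branches <- lapply(b$branches, function(br) lapply(br, enc_el))
    out
  }
  enc_el <- function(el) if (inherits(el, "nar_block")) enc_block(el) else enc_layer(el)
  enc_stage <- function(st) {
    out <- list(name = st$name, block = enc_block(st$block), repeats = st$repeats,
                base_width = st$base_width, depth_scalable = st$depth_scalable,
                downsample = st$downsample)
    if (!is.null(st$transition)) out$transition <- enc_block(st$transition)
    out
  }
  doc <- list(format = "narcnn/network", version = 1, name = net$name,
              input = net$input, n_classes = net$n_classes,
              min_input = net$min_input,
              stem = lapply(net$stem, enc_el),
              stages = lapply(net$stages, enc_stage),
              head = lapply(net$head, enc_el))
  txt <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(as.character(txt)))
  }
  as.character(txt)
}

#' Deserialize a network from JSON
#'
#' @param text JSON text, or a path to a JSON file.
#' @return A `nar_network`.
#' @export
network_from_json <- function(text) {
  if (length(text) == 1 && !grepl("[{]", text) && file.exists(text))
    text <- paste(readLines(text, warn = FALSE), collapse = "\n")
  doc <- tryCatch(
    jsonlite::fromJSON(text, simplifyVector = FALSE),
    error = function(e) stop("malformed network document: ", conditionMessage(e)))
  if (is.null(doc$format) || doc$format != "narcnn/network")
    stop("malformed network document: missing format tag 'narcnn/network'")
  dec_layer <- function(l)
    layer_spec(l$kind, kernel = unlist(l$kernel), filters = l$filters,
               width_ratio = l$width_ratio,
               stride = unlist(l$stride), padding = l$padding,
               bias = isTRUE(l$bias), takes_stride = isTRUE(l$takes_stride))
  dec_el <- function(el) {
    if (is.null(el$node)) stop("malformed network document: element without node tag")
    if (el$node == "block") dec_block(el) else dec_layer(el)
  }
  dec_block <- function(b)
    block_spec(b$name,
               layers = if (!is.null(b$layers)) lapply(b$layers, dec_el),
               branches = if (!is.null(b$branches))
                 lapply(b$branches, function(br) lapply(br, dec_el)),
               merge = b$merge, shortcut = b$shortcut)
  dec_stage <- function(st)
    stage_spec(st$name, dec_block(st$block), st$repeats, st$base_width,
               depth_scalable = isTRUE(st$depth_scalable),
               downsample = st$downsample,
               transition = if (!is.null(st$transition)) dec_block(st$transition))
  network_spec(doc$name, unlist(doc$input), lapply(doc$stem, dec_el),
               lapply(doc$stages, dec_stage), lapply(doc$head, dec_el),
               doc$n_classes, doc$min_input)
}
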