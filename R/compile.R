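# Compilation of the symbolic architecture description into a flat,
# topologically ordered node graph. Every consumer of a network — shape
# inference, the cost model, materialization — works on this graph, so the
# stage/block instantiation rules (projection shortcut in the first repeat,
# stride on the marked convolution of a downsampling instance, transitions
# after the repeats) live in exactly one place.

compile_network <- function(net) {
  nodes <- list()
  n_id <- 0
  emit <- function(prefix, kind, inputs, kernel = NULL, stride = c(1, 1),
                   padding = "same", filters = NULL, bias = FALSE,
                   stage = NA_character_, instance = NA_real_) {
    n_id <<- n_id + 1
    id <- sprintf("%03d_%s_%s", n_id, prefix, kind)
    nodes[[id]] <<- list(id = id, kind = kind, inputs = inputs,
                         kernel = kernel, stride = stride, padding = padding,
                         filters = filters, bias = bias,
                         stage = stage, instance = instance)
    id
  }
  resolve_width <- function(l, base) {
    if (!is.null(l$filters)) return(l$filters)
    max(1, round_half_even(base * l$width_ratio))
  }
  emit_layer <- function(l, cur, base, prefix, block_stride = 1,
                         stage = NA_character_, instance = NA_real_) {
    stride <- l$stride
    if (isTRUE(l$takes_stride) && block_stride > 1) stride <- c(block_stride, block_stride)
    filters <- if (l$kind %in% c("conv", "dense")) resolve_width(l, base)
    emit(prefix, l$kind, cur, kernel = l$kernel, stride = stride,
         padding = l$padding, filters = filters, bias = l$bias,
         stage = stage, instance = instance)
  }
  emit_seq <- function(els, cur, base, prefix, block_stride = 1,
                       stage = NA_character_, instance = NA_real_) {
    for (el in els) {
      cur <- if (inherits(el, "nar_block"))
        emit_block(el, cur, base, paste0(prefix, ".", el$name), 1, "none",
                   stage, instance)
      else emit_layer(el, cur, base, prefix, block_stride, stage, instance)
    }
    cur
  }
  emit_block <- function(b, cur, base, prefix, block_stride = 1,
                         shortcut = b$shortcut, stage = NA_character_,
                         instance = NA_real_) {
    if (b$merge == "concat") {
      ends <- character()
      for (i in seq_along(b$branches))
        ends[i] <- emit_seq(b$branches[[i]], cur, base,
                            sprintf("%s_br%d", prefix, i), 1, stage, instance)
      return(emit(prefix, "concat", ends, stage = stage, instance = instance))
    }
    body_end <- emit_seq(b$layers, cur, base, prefix, block_stride, stage, instance)
    if (b$merge == "none") return(body_end)
    # residual merge
    sc_end <- cur
    if (shortcut == "projection") {
      convs <- Filter(function(l) inherits(l, "nar_layer") && l$kind == "conv", b$layers)
      out_w <- resolve_width(convs[[length(convs)]], base)
      sc_end <- emit(paste0(prefix, "_sc"), "conv", cur, kernel = c(1, 1),
                     stride = c(block_stride, block_stride), padding = "same",
                     filters = out_w, bias = TRUE, stage = stage, instance = instance)
    } else if (block_stride > 1) {
      # parameter-free spatial alignment of the identity path
      sc_end <- emit(paste0(prefix, "_sc"), "pool_max", cur, kernel = c(1, 1),
                     stride = c(block_stride, block_stride), padding = "same",
                     stage = stage, instance = instance)
    }
    emit(prefix, "add", c(body_end, sc_end), stage = stage, instance = instance)
  }

  cur <- emit_seq(net$stem, character(), 1, "stem")
  for (st in net$stages) {
    for (i in seq_len(st$repeats)) {
      stride_i <- if (st$downsample == "start" && i == 1) 2 else 1
      shortcut_i <- if (i == 1) st$block$shortcut
                    else if (st$block$shortcut == "none") "none" else "identity"
      cur <- emit_block(st$block, cur, st$base_width,
                        sprintf("%s_b%d", st$name, i), stride_i, shortcut_i,
                        stage = st$name, instance = i)
    }
    if (!is.null(st$transition))
      cur <- emit_block(st$transition, cur, st$base_width,
                        paste0(st$name, "_tr"), 1, "none",
                        stage = st$name, instance = NA_real_)
  }
  emit_seq(net$head, cur, 1, "head")
  unname(nodes)
}
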