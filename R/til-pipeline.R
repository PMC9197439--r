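# Prediction-phase pipeline: tile a slide image into patches of fixed
# physical size, classify each patch, and assemble a lymphocyte map.

#' Slide metadata
#'
#' @param width,height Slide dimensions in pixels.
#' @param mpp Microns per pixel (0.25 at 40x magnification, 0.5 at 20x).
#' @return A `slide_meta` object.
#' @export
slide_meta <- function(width, height, mpp) {
  if (mpp <= 0) stop("mpp must be positive")
  if (width < 1 || height < 1) stop("slide dimensions must be positive")
  structure(list(width = as.numeric(width), height = as.numeric(height),
                 mpp = as.numeric(mpp)),
            class = "slide_meta")
}

#' Patch grid over a slide
#'
#' Partitions the slide into non-overlapping square patches covering
#' `patch_microns` x `patch_microns` of tissue (50 x 50 microns by
#' default), so the physical patch size — and hence the number of patches
#' per slide — is independent of the scan resolution. Coordinates are
#' 0-based half-open pixel boxes, row-major from the top-left; trailing
#' partial patches are dropped.
#'
#' @param meta A [slide_meta()].
#' @param patch_microns Physical patch side in microns.
#' @return Data frame with columns `row`, `col` (0-based grid indices),
#'   `x`, `y` (top-left pixel), `side_px`. Zero rows when the slide is
#'   smaller than one patch.
#' @examples
#' patch_grid(slide_meta(1000, 1000, 0.5))  # 10 x 10 patches of 100 px
#' @export
patch_grid <- function(meta, patch_microns = 50) {
  side_px <- round(patch_microns / meta$mpp)
  n_col <- floor(meta$width / side_px)
  n_row <- floor(meta$height / side_px)
  if (n_col < 1 || n_row < 1)
    return(data.frame(row = integer(), col = integer(), x = integer(),
                      y = integer(), side_px = integer()))
  g <- expand.grid(col = seq_len(n_col) - 1, row = seq_len(n_row) - 1)
  data.frame(row = g$row, col = g$col,
             x = g$col * side_px, y = g$row * side_px,
             side_px = side_px)
}

#' Classify every patch of an image
#'
#' Crops each patch box, resizes it from its physical size to the
#' classifier's input side (bilinear), and scores it. The patch grid — and
#' therefore the work per slide — is the same whatever input size the
#' model expects.
#'
#' @param model A `nar_model`, or any function mapping a list of
#'   `[side, side, 3]` arrays to a numeric score vector (useful for
#'   stubs).
#' @param image Slide image as an `[H, W, 3]` array in `[0, 1]`.
#' @param patches Patch data frame from [patch_grid()].
#' @param input_side Classifier input side; defaults to the model's.
#' @param batch_size Patches scored per forward pass.
#' @return Numeric score vector, one per patch, in `patches` order.
#' @export
classify_patches <- function(model, image, patches, input_side = NULL,
                             batch_size = 64) {
  d <- dim(image)
  bad <- patches$x < 0 | patches$y < 0 |
    patches$x + patches$side_px > d[2] | patches$y + patches$side_px > d[1]
  if (any(bad))
    stop("patch (row ", patches$row[which(bad)[1]], ", col ",
         patches$col[which(bad)[1]], ") lies outside the image")
  if (is.null(input_side))
    input_side <- if (inherits(model, "nar_model")) model$input[1]
                  else patches$side_px[1]
  crops <- lapply(seq_len(nrow(patches)), function(i) {
    p <- patches[i, ]
    resize_image(image[p$y + seq_len(p$side_px), p$x + seq_len(p$side_px), ,
                       drop = FALSE],
                 input_side)
  })
  if (!inherits(model, "nar_model")) return(as.numeric(model(crops)))
  scores <- numeric(length(crops))
  for (start in seq(1, length(crops), by = batch_size)) {
    take <- start:min(start + batch_size - 1, length(crops))
    scores[take] <- predict_scores(model, crops[take])
  }
  scores
}

#' Assemble a TIL map
#'
#' @param scores Per-patch scores from [classify_patches()].
#' @param patches Patch data frame from [patch_grid()].
#' @param meta The [slide_meta()].
#' @param threshold Probability threshold; a patch is labelled positive iff
#'   its score is >= `threshold`.
#' @return A `til_map`: score and label matrices (rows = grid rows), the
#'   slide metadata and the threshold.
#' @export
build_til_map <- function(scores, patches, meta, threshold = 0.5) {
  if (length(scores) != nrow(patches))
    stop("scores (", length(scores), ") and patches (", nrow(patches),
         ") are misaligned")
  n_row <- max(patches$row) + 1; n_col <- max(patches$col) + 1
  sc <- matrix(NA_real_, n_row, n_col)
  sc[cbind(patches$row + 1, patches$col + 1)] <- scores
  structure(list(scores = sc, labels = sc >= threshold, meta = meta,
                 threshold = threshold, side_px = patches$side_px[1]),
            class = "til_map")
}

#' @export
print.til_map <- function(x, ...) {
  cat(sprintf("<til_map> %dx%d patches, %d positive (threshold %.2f)\n",
              nrow(x$scores), ncol(x$scores), sum(x$labels), x$threshold))
  invisible(x)
}

#' Write / read a TIL map as CSV
#'
#' Columns `row`, `col`, `score`, `label`; labels survive the round trip
#' exactly.
#'
#' @param map A `til_map`.
#' @param path CSV file path.
#' @return `write_til_map` returns `path` invisibly; `read_til_map`
#'   returns a `til_map`.
#' @export
write_til_map <- function(map, path) {
  idx <- which(!is.na(map$scores), arr.ind = TRUE)
  df <- data.frame(row = idx[, 1] - 1, col = idx[, 2] - 1,
                   score = map$scores[idx],
                   label = as.integer(map$labels[idx]))
  df <- df[order(df$row, df$col), ]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_til_map
#' @param meta,threshold Slide metadata and threshold to attach on read.
#' @export
read_til_map <- function(path, meta = NULL, threshold = 0.5) {
  df <- utils::read.csv(path)
  sc <- matrix(NA_real_, max(df$row) + 1, max(df$col) + 1)
  sc[cbind(df$row + 1, df$col + 1)] <- df$score
  structure(list(scores = sc, labels = sc >= threshold, meta = meta,
                 threshold = threshold, side_px = NA_real_),
            class = "til_map")
}

#' Render a TIL map as a PNG
#'
#' Positive patches are drawn red on a blue tissue background.
#'
#' @param map A `til_map`.
#' @param path Output PNG path.
#' @param cell_px Pixels drawn per patch cell.
#' @return `path`, invisibly.
#' @export
render_til_map <- function(map, path, cell_px = 8) {
  lab <- map$labels
  h <- nrow(lab) * cell_px; w <- ncol(lab) * cell_px
  img <- array(0, dim = c(h, w, 3))
  big <- lab[rep(seq_len(nrow(lab)), each = cell_px),
             rep(seq_len(ncol(lab)), each = cell_px)]
  big[is.na(big)] <- FALSE
  img[, , 1] <- big            # red where positive
  img[, , 3] <- !big           # blue background
  png::writePNG(img, path)
  invisible(path)
}

#' Read a raster image
#'
#' PNG or TIFF, returned as an `[H, W, 3]` array in `[0, 1]` (grayscale is
#' replicated across channels, alpha dropped).
#'
#' @param path Image file.
#' @return Numeric array `[H, W, 3]`.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("reading TIFF requires the 'tiff' package")
      tiff::readTIFF(path)
    },
    stop("unsupported image format: .", ext))
  if (length(dim(img)) == 2) img <- array(rep(img, 3), dim = c(dim(img), 3))
  if (dim(img)[3] > 3) img <- img[, , 1:3, drop = FALSE]
  img
}

# Bilinear resize to a square side; images are [H, W, C] arrays.
resize_image <- function(img, side) {
  d <- dim(img)
  if (d[1] == side && d[2] == side) return(img)
  out <- EBImage::resize(img, w = side, h = side)
  array(out, dim = c(side, side, d[3]))
}
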