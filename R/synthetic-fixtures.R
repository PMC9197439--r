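# Deterministic synthetic fixtures emulating the binary
# lymphocyte-positive / lymphocyte-negative patch task: pink
# eosin-like tissue texture with small dark-purple nuclear blobs.
# Positive patches are blob-dense (>= 20 blobs), negative patches carry
# at most 2. The class signal is therefore blob density rather than a
# single colour shift, so reducing the input resolution degrades the
# task gradually instead of switching it off.

PATCH_BG <- c(0.91, 0.73, 0.83)    # eosin-pink base
BLOB_COL <- c(0.36, 0.20, 0.52)    # hematoxylin-purple nuclei

#' Generate one synthetic tissue patch
#'
#' @param label 1 for a lymphocyte-rich (positive) patch, 0 for negative.
#' @param side_px Patch side in pixels (>= 32).
#' @param seed Integer seed; the same `(label, side_px, seed)` triple
#'   always produces identical pixels.
#' @return `[side_px, side_px, 3]` array in `[0, 1]`, with the generator's
#'   own blob mask attached as attribute `"mask"` (logical matrix).
#' @examples
#' p <- make_patch(1, 64, seed = 1)
#' sum(attr(p, "mask")) > 0
#' @export
make_patch <- function(label, side_px, seed) {
  if (side_px < 32) stop("side_px must be >= 32")
  with_seed(seed, {
    s <- side_px
    # mottled pink background
    img <- array(0, dim = c(s, s, 3))
    rc <- expand.grid(r = seq_len(s), c = seq_len(s))
    mottle <- 0.02 * sin(rc$r / s * 2 * pi * stats::runif(1, 1, 3) +
                           stats::runif(1, 0, 2 * pi)) +
              0.02 * sin(rc$c / s * 2 * pi * stats::runif(1, 1, 3) +
                           stats::runif(1, 0, 2 * pi))
    for (ch in 1:3)
      img[, , ch] <- PATCH_BG[ch] + mottle +
        stats::rnorm(s * s, sd = 0.025)
    # nuclear blobs
    n_blobs <- if (label >= 1) 20 + sample.int(16, 1) - 1 else sample(0:2, 1)
    mask <- matrix(FALSE, s, s)
    radius <- max(2, round(s / 28))
    min_d2 <- (2 * 1.3 * radius + 1)^2  # keep blobs disjoint when room allows
    centers <- matrix(numeric(), ncol = 2)
    place <- function() {
      for (try in 1:50) {
        cand <- c(sample.int(s, 1), sample.int(s, 1))
        if (nrow(centers) == 0 ||
            min((centers[, 1] - cand[1])^2 + (centers[, 2] - cand[2])^2) >= min_d2)
          return(cand)
      }
      cand
    }
    for (b in seq_len(n_blobs)) {
      ctr <- place()
      centers <- rbind(centers, ctr)
      cy <- ctr[1]; cx <- ctr[2]
      ry <- radius * stats::runif(1, 0.7, 1.3)
      rx <- radius * stats::runif(1, 0.7, 1.3)
      th <- stats::runif(1, 0, pi)
      yy <- pmax(1, cy - ceiling(2 * radius)):pmin(s, cy + ceiling(2 * radius))
      xx <- pmax(1, cx - ceiling(2 * radius)):pmin(s, cx + ceiling(2 * radius))
      gy <- outer(yy - cy, rep(1, length(xx)))
      gx <- outer(rep(1, length(yy)), xx - cx)
      u <- gy * cos(th) + gx * sin(th)
      v <- -gy * sin(th) + gx * cos(th)
      hit <- (u / ry)^2 + (v / rx)^2 <= 1
      mask[yy, xx] <- mask[yy, xx] | hit
    }
    shade <- stats::runif(1, 0.9, 1.1)
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[mask] <- BLOB_COL[ch] * shade + stats::rnorm(sum(mask), sd = 0.02)
      img[, , ch] <- plane
    }
    img[img < 0] <- 0; img[img > 1] <- 1
    attr(img, "mask") <- mask
    img
  })
}

#' Generate a synthetic slide with ground truth
#'
#' Draws a per-patch label grid (independent Bernoulli with the requested
#' positive fraction), renders every patch with [make_patch()], and
#' mosaics them into one slide image.
#'
#' @param dims_px Length-2 `c(width, height)` of the slide in pixels.
#' @param mpp Microns per pixel.
#' @param positive_fraction Probability that a patch is positive.
#' @param seed Integer seed.
#' @param patch_microns Physical patch side in microns.
#' @return A `synthetic_slide`: `image` (`[H, W, 3]`), `meta`
#'   ([slide_meta()]), `truth` (binary matrix matching the patch grid),
#'   `positive_fraction`, `seed`.
#' @export
make_slide <- function(dims_px, mpp, positive_fraction, seed,
                       patch_microns = 50) {
  if (positive_fraction < 0 || positive_fraction > 1)
    stop("positive_fraction must be in [0, 1]")
  meta <- slide_meta(dims_px[1], dims_px[2], mpp)
  grid <- patch_grid(meta, patch_microns)
  truth <- matrix(0L, max(grid$row, -1) + 1, max(grid$col, -1) + 1)
  img <- array(rep(PATCH_BG, each = meta$height * meta$width),
               dim = c(meta$height, meta$width, 3))
  labels <- with_seed(seed,
    stats::rbinom(nrow(grid), 1, positive_fraction))
  for (i in seq_len(nrow(grid))) {
    p <- grid[i, ]
    truth[p$row + 1, p$col + 1] <- labels[i]
    patch <- make_patch(labels[i], p$side_px,
                        seed = (seed + 7919 * i) %% 2147483647)
    img[p$y + seq_len(p$side_px), p$x + seq_len(p$side_px), ] <- patch
  }
  structure(list(image = img, meta = meta, truth = truth,
                 positive_fraction = positive_fraction, seed = seed),
            class = "synthetic_slide")
}

#' Write a labelled synthetic patch set with a manifest
#'
#' Emulates, at desk scale, the labelled patch sets used to train and test
#' the patch classifier. Patches are written as PNG files with a CSV
#' manifest of `path`, `label` and `mpp`, directly loadable by [train()].
#'
#' @param n_patches Number of patches (>= 2).
#' @param positive_fraction Probability that a patch is positive; when
#'   `both_classes` is `TRUE` it must leave room for both classes.
#' @param side_px Patch side in pixels.
#' @param out_dir Output directory (created if missing).
#' @param seed Integer seed.
#' @param mpp Microns per pixel recorded in the manifest.
#' @param both_classes Guarantee at least one patch of each class (the
#'   trained head needs both); a request with `positive_fraction` 0 or 1
#'   is then an error.
#' @return Path of the manifest CSV, with the manifest data frame as
#'   attribute `"manifest"`.
#' @export
make_manifest <- function(n_patches, positive_fraction, side_px, out_dir,
                          seed, mpp = 0.5, both_classes = TRUE) {
  if (n_patches < 2) stop("n_patches must be >= 2")
  if (both_classes && positive_fraction %in% c(0, 1))
    stop("positive_fraction ", positive_fraction,
         " cannot produce both classes")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  labels <- with_seed(seed, stats::rbinom(n_patches, 1, positive_fraction))
  if (both_classes && length(unique(labels)) == 1)
    labels[1] <- 1 - labels[1]
  paths <- file.path(out_dir, sprintf("patch_%04d.png", seq_len(n_patches)))
  for (i in seq_len(n_patches)) {
    patch <- make_patch(labels[i], side_px,
                        seed = (seed + 104729 * i) %% 2147483647)
    png::writePNG(patch, paths[i])
  }
  manifest <- data.frame(path = paths, label = labels, mpp = mpp)
  csv <- file.path(out_dir, "manifest.csv")
  utils::write.csv(manifest, csv, row.names = FALSE)
  attr(csv, "manifest") <- manifest
  csv
}

#' Load a manifest into an in-memory dataset
#'
#' @param manifest_csv Path to a manifest written by [make_manifest()].
#' @return List with `x` (list of image arrays) and `y` (0/1 labels).
#' @export
load_manifest <- function(manifest_csv) {
  df <- utils::read.csv(manifest_csv)
  list(x = lapply(df$path, read_image), y = as.numeric(df$label))
}
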