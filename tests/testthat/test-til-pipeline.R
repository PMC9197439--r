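test_that("the patch grid covers 50-micron squares at any scan resolution", {
  expect_equal(patch_grid(slide_meta(1000, 1000, 0.25))$side_px[1], 200)
  g <- patch_grid(slide_meta(1000, 1000, 0.5))
  expect_equal(g$side_px[1], 100)
  expect_equal(nrow(g), 100)
  expect_equal(max(g$row), 9)
  # slides smaller than one patch give an empty grid, not an error
  expect_equal(nrow(patch_grid(slide_meta(80, 80, 0.5))), 0)
})

test_that("grids depend only on physical dimensions", {
  g40x <- patch_grid(slide_meta(2000, 1600, 0.25))
  g20x <- patch_grid(slide_meta(1000, 800, 0.5))
  expect_equal(max(g40x$row), max(g20x$row))
  expect_equal(max(g40x$col), max(g20x$col))
  expect_equal(nrow(g40x), nrow(g20x))
})

test_that("patches tile without overlap or gaps", {
  meta <- slide_meta(730, 520, 0.5)  # trailing partial patches dropped
  g <- patch_grid(meta)
  expect_equal(nrow(g), 7 * 5)
  covered <- matrix(0, meta$height, meta$width)
  for (i in seq_len(nrow(g)))
    covered[g$y[i] + seq_len(g$side_px[i]), g$x[i] + seq_len(g$side_px[i])] <-
      covered[g$y[i] + seq_len(g$side_px[i]), g$x[i] + seq_len(g$side_px[i])] + 1
  expect_true(all(covered <= 1))
  expect_equal(sum(covered), nrow(g) * g$side_px[1]^2)
})

test_that("patch scoring preserves order and is grid-size invariant", {
  slide <- make_slide(c(500, 400), 0.5, 0.4, seed = 3)
  g <- patch_grid(slide$meta)
  # a constant stub scores every patch identically
  stub <- function(crops) rep(0.25, length(crops))
  s <- classify_patches(stub, slide$image, g, input_side = 32)
  expect_equal(s, rep(0.25, nrow(g)))
  # the patch count does not depend on the classifier's input size
  mean_side <- function(crops) vapply(crops, function(c) dim(c)[1], numeric(1))
  sides240 <- classify_patches(mean_side, slide$image, g, input_side = 48)
  sides119 <- classify_patches(mean_side, slide$image, g, input_side = 24)
  expect_length(sides240, nrow(g))
  expect_length(sides119, nrow(g))
  expect_true(all(sides240 == 48) && all(sides119 == 24))
  # out-of-bounds patches are rejected by name
  bad <- g; bad$x[3] <- bad$x[3] + 10000
  expect_error(classify_patches(stub, slide$image, bad), "col")
})

test_that("the map grid reflects scores against the threshold", {
  meta <- slide_meta(300, 200, 0.5)
  g <- patch_grid(meta)  # 3 x 2
  expect_error(build_til_map(c(1, 0), g, meta), "misaligned")
  scores <- c(0.9, 0.4, 0.6, 0.5, 0.1, 0.8)
  map <- build_til_map(scores, g, meta, threshold = 0.5)
  expect_equal(dim(map$scores), c(2, 3))
  expect_equal(sum(map$labels), sum(scores >= 0.5))
  all_pos <- build_til_map(rep(1, 6), g, meta)
  expect_true(all(all_pos$labels))
  two <- build_til_map(c(0.4, 0.6, 0, 0, 0, 0), g, meta, 0.5)
  expect_equal(sum(two$labels), 1)
})

test_that("a map written to CSV and PNG reads back with identical labels", {
  meta <- slide_meta(400, 400, 0.5)
  g <- patch_grid(meta)
  scores <- with_seed_test(5, stats::runif(nrow(g)))
  map <- build_til_map(scores, g, meta)
  csv <- withr::local_tempfile(fileext = ".csv")
  png_path <- withr::local_tempfile(fileext = ".png")
  write_til_map(map, csv)
  back <- read_til_map(csv, meta)
  expect_equal(back$labels, map$labels)
  expect_equal(back$scores, map$scores, tolerance = 1e-12)
  render_til_map(map, png_path)
  img <- png::readPNG(png_path)
  cell <- 8
  centers_r <- (seq_len(nrow(map$labels)) - 1) * cell + 4
  centers_c <- (seq_len(ncol(map$labels)) - 1) * cell + 4
  red <- img[centers_r, centers_c, 1] > 0.5
  expect_equal(red, unname(map$labels))
})

test_that("an end-to-end slide run recovers the planted truth", {
  sets <- synth_sets()
  m <- materialize(toy_cnn_template(32), seed = 1)
  fit <- train(m, sets$train, train_config(epochs = 3, batch_size = 32, seed = 1))
  slide <- make_slide(c(640, 640), 0.5, 0.4, seed = 21, patch_microns = 32)
  g <- patch_grid(slide$meta, patch_microns = 32)
  scores <- classify_patches(fit, slide$image, g)
  truth <- slide$truth[cbind(g$row + 1, g$col + 1)]
  expect_gte(evaluate_auc(scores, truth)$auc_mean, 0.9)
})
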