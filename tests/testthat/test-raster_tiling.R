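test_that("padding arithmetic matches the full-scan geometry", {
  g <- pad_geometry(10200, 14039, 512)
  expect_equal(g$pad_bottom, 40L)
  expect_equal(g$pad_right, 297L)
  expect_equal(g$height, 10240L)
  expect_equal(g$width, 14336L)
  expect_equal(tile_count(g$height, g$width, 512, 512), 560L)
  # identity and degenerate cases
  expect_equal(pad_geometry(512, 512, 512)[c("pad_bottom", "pad_right")],
               list(pad_bottom = 0L, pad_right = 0L))
  expect_equal(pad_geometry(1, 1, 512)[c("height", "width")],
               list(height = 512L, width = 512L))
  expect_error(pad_geometry(10, 10, 0), "multiple")
})

test_that("pad_to_multiple zero-fills bottom/right only", {
  img <- array(sample(0:255, 5 * 7 * 3, TRUE), c(5, 7, 3))
  p <- pad_to_multiple(img, 4)
  expect_equal(dim(p$image), c(8L, 8L, 3L))
  expect_equal(p$pad_bottom, 3L)
  expect_equal(p$pad_right, 1L)
  expect_equal(p$image[1:5, 1:7, ], img)
  expect_true(all(p$image[6:8, , ] == 0))
  expect_true(all(p$image[, 8, ] == 0))
  # 1x1 forced case: everything except (1,1) is zero
  q <- pad_to_multiple(matrix(9), 16)
  expect_equal(dim(q$image), c(16L, 16L))
  expect_equal(sum(q$image), 9)
})

test_that("tile counts follow the sliding-window formula", {
  expect_equal(tile_count(1024, 1024, 512, 256), 9L)
  grid <- split_tiles(array(0, c(1024, 1024, 1)), 512, 256)
  expect_length(grid$tiles, 9L)
  expect_error(split_tiles(array(0, c(512, 512, 1)), 256, 512), "gaps")
  one <- split_tiles(array(1:512^2 %% 7, c(512, 512, 1)), 512)
  expect_length(one$tiles, 1L)
  expect_equal(one$tiles[[1]]$data[, , 1], array(1:512^2 %% 7, c(512, 512)))
})

test_that("pad -> split -> stitch -> crop is the identity for random shapes", {
  set.seed(41)
  for (i in 1:12) {
    h <- sample(1:300, 1); w <- sample(1:300, 1)
    tile <- sample(c(16L, 32L, 64L), 1)
    stride <- sample(c(tile, tile %/% 2), 1)
    img <- array(runif(h * w * 2), c(h, w, 2))
    p <- pad_to_multiple(img, tile)
    grid <- split_tiles(p$image, tile, stride, orig_dim = c(h, w))
    out <- stitch_tiles(grid)
    expect_equal(out, img, tolerance = 0)
  }
  # one case at the network tile size and above 1000 px
  img <- array(runif(1300 * 701), c(1300, 701, 1))
  p <- pad_to_multiple(img, 512)
  out <- stitch_tiles(split_tiles(p$image, 512L, orig_dim = c(1300, 701)))
  expect_equal(out, img, tolerance = 0)
})

test_that("stitching averages scores in overlapping regions", {
  # all-constant tiles stay constant under overlap averaging
  img <- array(3.5, c(64, 64, 1))
  grid <- split_tiles(img, 32, 16)
  expect_equal(stitch_tiles(grid), img, tolerance = 0)
  # two tiles disagreeing 0 vs 1 average to 0.5 in the overlap
  g2 <- split_tiles(array(0, c(32, 48, 1)), 32, 16)
  for (k in seq_along(g2$tiles)) g2$tiles[[k]]$data[] <- g2$tiles[[k]]$col %% 2
  st <- stitch_tiles(g2)
  expect_true(all(st[, 17:32, 1] == 0.5))
  # a missing tile is an integrity error
  g2$tiles <- g2$tiles[-2]
  expect_error(stitch_tiles(g2), "tile")
})

test_that("images and masks survive the PNM round trip bit-exactly", {
  d <- withr::local_tempdir()
  img <- array(sample(0:255, 31 * 17 * 3, TRUE), c(31L, 17L, 3L))
  write_raster(img, file.path(d, "x.ppm"))
  expect_identical(read_raster(file.path(d, "x.ppm")), img)
  mask <- matrix(sample(0:1, 40 * 25, TRUE), 40L, 25L)
  write_mask(mask, file.path(d, "m.pgm"))
  expect_identical(read_mask(file.path(d, "m.pgm")), matrix(as.integer(mask), 40L))
  expect_error(write_mask(matrix(2L, 2, 2), file.path(d, "bad.pgm")), "binary")
})
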