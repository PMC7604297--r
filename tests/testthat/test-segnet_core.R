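test_that("bilinear upsampling interpolates constants, centers, and random grids", {
  expect_equal(bilinear_upsample(array(5, c(3, 3, 1)), 4),
               array(5, c(12, 12, 1)))
  # symmetry: the four samples straddling the centre of a 2x2 grid average to
  # the mean of the corners (the value at the geometric centre)
  up <- bilinear_upsample(matrix(c(0, 4, 2, 6), 2, 2), 2)
  expect_equal(mean(up[2:3, 2:3]), mean(c(0, 4, 2, 6)))
  set.seed(5)
  for (i in 1:6) {
    x <- array(rnorm(5 * 7 * 2), c(5, 7, 2))
    f <- sample(2:4, 1)
    got <- bilinear_upsample(x, f)
    expect_equal(got, bilinear_oracle(x, f), tolerance = 1e-6)
    # convex combination: output extrema within input extrema
    expect_gte(min(got), min(x) - 1e-12)
    expect_lte(max(got), max(x) + 1e-12)
  }
  expect_error(bilinear_upsample(matrix(0, 2, 2), 0), "factor")
})

test_that("pixel_shuffle matches the index-map oracle and conserves values", {
  # hand-enumerated case
  expect_equal(pixel_shuffle(array(1:4, c(1, 1, 4)), 2)[, , 1],
               matrix(c(1, 3, 2, 4), 2, 2))
  expect_identical(pixel_shuffle(array(1:6, c(2, 3, 1)), 1),
                   array(1:6, c(2, 3, 1)))
  set.seed(9)
  for (i in 1:25) {
    r <- sample(1:3, 1)
    H <- sample(1:5, 1); W <- sample(1:5, 1); C <- sample(1:3, 1)
    x <- array(rnorm(H * W * C * r * r), c(H, W, C * r * r))
    y <- pixel_shuffle(x, r)
    expect_equal(dim(y), c(H * r, W * r, C))
    expect_equal(y, pixel_shuffle_oracle(x, r))
    expect_equal(sort(as.vector(y)), sort(as.vector(x)))   # permutation
    expect_equal(pixel_unshuffle(y, r), x)                 # inverse
    expect_equal(pixel_shuffle(pixel_unshuffle(y, r), r), y)  # two-sided
  }
  expect_error(pixel_shuffle(array(0, c(2, 2, 3)), 2), "divisible")
  expect_error(pixel_unshuffle(array(0, c(3, 4, 1)), 2), "divisible")
})

test_that("the model maps tiles to per-pixel scores at input resolution", {
  m <- build_model(tiny_spec(), seed = 1)
  sc <- generate_scene(scene_params(canvas_height = 64L, canvas_width = 64L, seed = 2L))
  out <- forward_model(m, sc$image)
  expect_equal(dim(out), c(64L, 64L, 2L))
  expect_true(all(is.finite(out)))
  # softmax over classes sums to 1 per pixel
  pr <- forward_proba(m, sc$image)
  expect_equal(apply(pr, c(1, 2), sum), matrix(1, 64, 64), tolerance = 1e-5)
  # all-zero tile: finite scores
  expect_true(all(is.finite(forward_model(m, array(0L, c(64, 64, 3))))))
  # non-conforming input errors at forward time
  expect_error(forward_model(m, array(0, c(60, 64, 3))), "divisible")
})

test_that("the encoder reduces each spatial dimension exactly 16-fold", {
  m <- build_model(tiny_spec(input_size = 96L), seed = 1)
  for (side in c(64L, 96L)) {
    enc <- encoder_features(m, array(runif(side * side * 3), c(side, side, 3)))
    expect_equal(dim(enc)[1:2], c(side, side) / 16L)
  }
})

test_that("the two heads share identical encoder/ASPP/decoder parameter counts", {
  msp <- build_model(tiny_spec("subpixel"), seed = 1)
  mbl <- build_model(tiny_spec("bilinear"), seed = 1)
  csp <- n_parameters(msp, by_component = TRUE)
  cbl <- n_parameters(mbl, by_component = TRUE)
  expect_equal(csp[["enc"]], cbl[["enc"]])
  expect_equal(csp[["aspp"]], cbl[["aspp"]])
  expect_equal(csp[["dec"]], cbl[["dec"]])
  expect_gt(csp[["head"]], cbl[["head"]])  # learned upsampling has parameters
  # only head parameter names differ
  pn <- function(m) setdiff(names(m$params), grep("^head", names(m$params), value = TRUE))
  expect_identical(pn(msp), pn(mbl))
})

test_that("a depthwise-separable block can reproduce a dense convolution", {
  # 1 input channel, pointwise initialised to identity: depthwise 3x3 + 1x1
  # equals the dense 3x3 with the same spatial kernel
  x <- array(rnorm(9 * 11), c(9, 11, 1))
  k <- array(rnorm(9), c(3, 3, 1, 1))
  dense <- rootseg:::.conv2d_fwd(x, k, 0, 1L, 1L, 1L)
  dw <- rootseg:::.conv2d_fwd(x, k, 0, 1L, 1L, 1L)          # depthwise, groups = C = 1
  pw <- rootseg:::.conv2d_fwd(dw, array(1, c(1, 1, 1, 1)), 0, 1L, 1L, 1L)
  expect_equal(pw, dense, tolerance = 1e-12)
})

test_that("forward_tiles preserves keys, order, and determinism", {
  m <- build_model(tiny_spec(), seed = 3)
  img <- generate_scene(scene_params(canvas_height = 128L, canvas_width = 64L,
                                     seed = 4L))$image
  grid <- split_tiles(rootseg:::.norm_tile(img), 64L)
  s1 <- forward_tiles(m, grid)
  s2 <- forward_tiles(m, grid)
  expect_length(s1$tiles, length(grid$tiles))
  expect_identical(lapply(s1$tiles, function(t) t[c("row", "col")]),
                   lapply(grid$tiles, function(t) t[c("row", "col")]))
  expect_identical(s1$tiles, s2$tiles)
  bad <- grid; bad$tiles[[1]]$data <- bad$tiles[[1]]$data[1:32, 1:32, , drop = FALSE]
  expect_error(forward_tiles(m, bad), "mismatch")
})

test_that("checkpoints round-trip through save/load", {
  d <- withr::local_tempdir()
  m <- build_model(tiny_spec(), seed = 5)
  save_model(m, file.path(d, "ck.rds"))
  m2 <- load_model(file.path(d, "ck.rds"))
  expect_equal(m2$params, m$params)
  x <- array(runif(64 * 64 * 3), c(64, 64, 3))
  expect_equal(forward_model(m2, x), forward_model(m, x))
  saveRDS(list(format = "other"), file.path(d, "bad.rds"))
  expect_error(load_model(file.path(d, "bad.rds")), "checkpoint")
})
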