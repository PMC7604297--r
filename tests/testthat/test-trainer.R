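test_that("cross-entropy matches closed forms and the per-pixel oracle", {
  # probability 1 for the true class everywhere -> loss 0
  mask <- matrix(c(0L, 1L, 1L, 0L), 2, 2)
  sure <- array(0, c(2, 2, 2))
  sure[, , 1] <- 50 * (mask == 0); sure[, , 2] <- 50 * (mask == 1)
  expect_equal(cross_entropy_loss(sure, mask), 0, tolerance = 1e-12)
  # uniform scores, K = 2 -> ln 2
  expect_equal(cross_entropy_loss(array(0, c(3, 3, 2)), matrix(0L, 3, 3)),
               log(2), tolerance = 1e-12)
  # random case vs brute-force oracle, unweighted and weighted
  set.seed(21)
  for (i in 1:5) {
    sc <- array(rnorm(4 * 4 * 3), c(4, 4, 3))
    mk <- matrix(sample(0:2, 16, TRUE), 4, 4)
    expect_equal(cross_entropy_loss(sc, mk), ce_oracle(sc, mk), tolerance = 1e-6)
    w <- runif(3, 0.5, 2)
    expect_equal(cross_entropy_loss(sc, mk, w), ce_oracle(sc, mk, w),
                 tolerance = 1e-6)
    # softmax shift invariance
    expect_equal(cross_entropy_loss(sc + 7, mk), cross_entropy_loss(sc, mk),
                 tolerance = 1e-9)
  }
  expect_error(cross_entropy_loss(array(NaN, c(2, 2, 2)), matrix(0L, 2, 2)),
               "finite")
  expect_error(cross_entropy_loss(array(0, c(2, 2, 2)), matrix(5L, 2, 2)), "< K")
})

test_that("splits are seeded, disjoint, and exhaustive", {
  s1 <- make_splits(1:100, 0.05, seed = 1)
  s2 <- make_splits(1:100, 0.05, seed = 1)
  expect_identical(s1, s2)
  expect_length(s1$val, 5L)
  expect_length(s1$train, 95L)
  expect_setequal(c(s1$train, s1$val), 1:100)
  expect_length(intersect(s1$train, s1$val), 0L)
  expect_false(identical(make_splits(1:100, 0.05, seed = 2)$val, s1$val))
  s3 <- make_splits(1:2, 0.5, seed = 1)
  expect_length(s3$train, 1L)
  expect_length(s3$val, 1L)
  expect_error(make_splits(1:10, 0.01, seed = 1), "empty")
  expect_error(make_splits(integer(0), 0.5, seed = 1), "empty")
})

test_that("a zero learning rate with zero weight decay leaves parameters unchanged", {
  scenes <- thin_scenes(4L, 9000L)
  m <- build_model(tiny_spec(), seed = 8)
  fit <- fit_rootseg(scenes, model = m,
                     control = train_spec(learning_rate = 1e-30, weight_decay = 0,
                                          epochs = 1L, batch_size = 2L,
                                          val_fraction = 0.25, seed = 1))
  expect_equal(fit$model$params, m$params, tolerance = 1e-12)
})

test_that("training runs exactly the configured epochs and is seed-reproducible", {
  scenes <- thin_scenes(6L, 7000L)
  ctl <- train_spec(epochs = 3L, batch_size = 3L, val_fraction = 0.2, seed = 4)
  f1 <- fit_rootseg(scenes, spec = tiny_spec(), control = ctl)
  f2 <- fit_rootseg(scenes, spec = tiny_spec(), control = ctl)
  expect_equal(nrow(f1$history), 3L)
  expect_identical(f1$history, f2$history)
  expect_equal(f1$model$params, f2$model$params, tolerance = 1e-12)
  expect_true(all(f1$history$train_loss >= 0))
  ok <- function(v) all(v >= 0 & v <= 1)
  expect_true(ok(f1$history$val_f1) && ok(f1$history$val_precision) &&
              ok(f1$history$val_recall))
  # a different seed gives a different trajectory
  f3 <- fit_rootseg(scenes, spec = tiny_spec(),
                    control = train_spec(epochs = 3L, batch_size = 3L,
                                         val_fraction = 0.2, seed = 5))
  expect_false(identical(f3$history$train_loss, f1$history$train_loss))
})

test_that("train spec presets and validation catch bad configurations", {
  desk <- train_spec()
  expect_equal(desk$batch_size, 8L)
  expect_equal(desk$epochs, 20L)
  paper <- train_spec(preset = "paper")
  expect_equal(paper$batch_size, 24L)
  expect_equal(paper$epochs, 80L)
  expect_equal(paper$learning_rate, 7e-4)
  expect_equal(paper$beta1, 0.9)
  expect_equal(paper$beta2, 0.999)
  expect_equal(paper$epsilon, 1e-8)
  expect_equal(paper$weight_decay, 1e-6)
  expect_error(train_spec(learning_rate = 0), "positive")
  expect_error(train_spec(val_fraction = 1), "val_fraction")
})
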