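# Training: pixel-wise cross-entropy on fixed-size tiles with Adam at the
# published hyperparameters (lr 7e-4, beta1 0.9, beta2 0.999, eps 1e-8,
# weight decay 1e-6 as classic coupled L2). Constant learning rate, a fixed
# epoch budget with no early stopping, seeded shuffling and splits, and
# per-epoch validation precision/recall/F1.

#' Training configuration
#'
#' Defaults are the desk-scale preset (batch 8, 20 epochs) suited to CPU
#' training; `preset = "paper"` switches to the published GPU-scale recipe
#' (batch 24, 80 epochs). Optimiser constants default to the published
#' values and are deliberately not scheduled: only the initial rate is
#' specified, and Adam's adaptivity does the rest.
#'
#' @param learning_rate Adam step size (constant; default 7e-4).
#' @param beta1,beta2,epsilon Adam moment decay rates and stabiliser.
#' @param weight_decay L2 coefficient folded into the gradient (classic
#'   coupled Adam + L2, not decoupled decay).
#' @param batch_size tiles per optimiser step.
#' @param epochs fixed number of passes; no early stopping.
#' @param val_fraction fraction of tiles held out for per-epoch validation.
#' @param seed integer; drives splits, shuffling and any augmentation.
#' @param class_weights optional length-K per-class loss weights (default
#'   uniform; roots cover few pixels, so inverse-frequency weights are a
#'   sensible option, but unweighted is the faithful default).
#' @param preset `"desk"` or `"paper"`; presets only change `batch_size` and
#'   `epochs`.
#' @return object of class `train_spec`.
#' @export
train_spec <- function(learning_rate = 7e-4, beta1 = 0.9, beta2 = 0.999,
                       epsilon = 1e-8, weight_decay = 1e-6,
                       batch_size = NULL, epochs = NULL,
                       val_fraction = 0.05, seed = 1L,
                       class_weights = NULL,
                       preset = c("desk", "paper")) {
  preset <- match.arg(preset)
  if (is.null(batch_size)) batch_size <- if (preset == "paper") 24L else 8L
  if (is.null(epochs)) epochs <- if (preset == "paper") 80L else 20L
  if (learning_rate <= 0 || beta1 <= 0 || beta2 <= 0 || epsilon <= 0)
    stop("optimiser rates must be positive", call. = FALSE)
  if (weight_decay < 0) stop("`weight_decay` must be >= 0", call. = FALSE)
  if (batch_size < 1) stop("`batch_size` must be >= 1", call. = FALSE)
  if (epochs < 1) stop("`epochs` must be >= 1", call. = FALSE)
  if (val_fraction <= 0 || val_fraction >= 1)
    stop("`val_fraction` must be in (0, 1)", call. = FALSE)
  structure(list(learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
                 epsilon = epsilon, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 val_fraction = val_fraction, seed = as.integer(seed),
                 class_weights = class_weights, preset = preset),
            class = "train_spec")
}

#' Split a manifest into train and validation sets
#'
#' Seed-deterministic, disjoint and exhaustive partition at the tile level.
#'
#' @param manifest data.frame (one row per tile/scene) or a vector of ids.
#' @param val_fraction fraction assigned to validation; both sides must end
#'   up non-empty.
#' @param seed integer seed.
#' @return list with `train` and `val` (same type as `manifest`).
#' @export
make_splits <- function(manifest, val_fraction = 0.05, seed = 1L) {
  n <- if (is.data.frame(manifest)) nrow(manifest) else length(manifest)
  if (n < 1L) stop("`manifest` is empty", call. = FALSE)
  n_val <- round(n * val_fraction)
  if (n_val < 1L || n_val >= n)
    stop(sprintf("val_fraction %.3f yields an empty split side for %d tiles",
                 val_fraction, n), call. = FALSE)
  idx <- with_seed(seed, sample.int(n, n_val))
  pick <- function(m, i) if (is.data.frame(m)) m[i, , drop = FALSE] else m[i]
  list(train = pick(manifest, setdiff(seq_len(n), idx)),
       val = pick(manifest, sort(idx)))
}

#' Mean pixel-wise cross-entropy of class scores against a mask
#'
#' Softmax cross-entropy averaged over pixels: `-mean(log p[true class])`,
#' optionally weighted per class (weighted mean). Invariant to adding a
#' constant to all class scores at a pixel.
#'
#' @param scores numeric array H x W x K of class scores (logits).
#' @param mask integer matrix H x W with values in `0..K-1`.
#' @param weights optional length-K class weights.
#' @return scalar loss (>= 0).
#' @export
cross_entropy_loss <- function(scores, mask, weights = NULL) {
  d <- dim(scores)
  if (length(d) != 3L) stop("`scores` must be H x W x K", call. = FALSE)
  if (any(d[1:2] != dim(mask))) stop("`scores`/`mask` dims differ", call. = FALSE)
  if (any(!is.finite(scores))) stop("non-finite values in `scores`", call. = FALSE)
  if (any(mask < 0 | mask >= d[3])) stop("mask values must be < K", call. = FALSE)
  ag_softmax_ce(ag_leaf(scores), mask, weights)$value
}

# One Adam step over the parameter list. st holds m, v, t.
.adam_step <- function(params, grads, st, ts) {
  st$t <- st$t + 1L
  bc1 <- 1 - ts$beta1^st$t
  bc2 <- 1 - ts$beta2^st$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    if (ts$weight_decay > 0) g <- g + ts$weight_decay * params[[nm]]
    st$m[[nm]] <- ts$beta1 * st$m[[nm]] + (1 - ts$beta1) * g
    st$v[[nm]] <- ts$beta2 * st$v[[nm]] + (1 - ts$beta2) * g^2
    params[[nm]] <- params[[nm]] -
      ts$learning_rate * (st$m[[nm]] / bc1) /
      (sqrt(st$v[[nm]] / bc2) + ts$epsilon)
  }
  params
}

# tiles: list of list(image, mask). Returns list(model, history).
.train_loop <- function(model, train_tiles, val_tiles, ts, verbose = FALSE) {
  if (!length(train_tiles)) stop("empty training split", call. = FALSE)
  params <- model$params
  st <- new.env(parent = emptyenv())
  st$t <- 0L
  st$m <- lapply(params, function(p) p * 0)  # zero buffers, shapes preserved
  st$v <- st$m
  history <- vector("list", ts$epochs)
  best <- list(f1 = -Inf, params = params, epoch = 0L)
  xs <- lapply(train_tiles, function(t) .norm_tile(t$image))
  ms <- lapply(train_tiles, function(t) t$mask)

  for (epoch in seq_len(ts$epochs)) {
    ord <- with_seed(ts$seed * 10000L + epoch, sample(seq_along(xs)))
    losses <- numeric(0)
    b0 <- 1L
    while (b0 <= length(ord)) {
      batch <- ord[b0:min(b0 + ts$batch_size - 1L, length(ord))]
      b0 <- b0 + ts$batch_size
      gacc <- NULL
      bl <- 0
      for (i in batch) {
        pn <- lapply(params, ag_leaf)
        out <- .forward_graph(model$spec, pn, xs[[i]])
        lnode <- ag_softmax_ce(out$scores, ms[[i]], ts$class_weights)
        if (!is.finite(lnode$value))
          stop(sprintf("non-finite loss at epoch %d; training aborted", epoch),
               call. = FALSE)
        ag_backward(lnode)
        bl <- bl + lnode$value
        g <- lapply(pn, function(n) n$grad)
        gacc <- if (is.null(gacc)) g else
          Map(function(a, b) if (is.null(b)) a else a + b, gacc, g)
      }
      nb <- length(batch)
      gacc <- lapply(gacc, function(g) if (is.null(g)) NULL else g / nb)
      params <- .adam_step(params, gacc, st, ts)
      losses <- c(losses, bl / nb)
    }
    m <- model; m$params <- params
    vm <- .validate(m, val_tiles)
    history[[epoch]] <- data.frame(epoch = epoch,
                                   train_loss = mean(losses),
                                   val_accuracy = unname(vm["accuracy"]),
                                   val_precision = unname(vm["precision"]),
                                   val_recall = unname(vm["recall"]),
                                   val_f1 = unname(vm["f1"]))
    if (is.finite(vm["f1"]) && vm["f1"] > best$f1)
      best <- list(f1 = vm["f1"], params = params, epoch = epoch)
    if (verbose)
      message(sprintf("epoch %2d  loss %.4f  val F1 %.4f",
                      epoch, mean(losses), vm["f1"]))
  }
  model$params <- params
  hist <- do.call(rbind, history)
  rownames(hist) <- NULL
  list(model = model, history = hist, best = best)
}

.validate <- function(model, val_tiles) {
  if (!length(val_tiles))
    return(c(accuracy = NA_real_, precision = NA_real_,
             recall = NA_real_, f1 = NA_real_))
  counts <- c(TP = 0, FP = 0, FN = 0, TN = 0)
  for (t in val_tiles) {
    sc <- forward_model(model, t$image)
    pred <- .scores_to_mask(sc)
    cc <- confusion(pred, t$mask)
    counts <- counts + unlist(cc[c("TP", "FP", "FN", "TN")])
  }
  mr <- metrics_from_counts(as_confusion(counts))
  c(accuracy = mr$accuracy, precision = mr$precision,
    recall = mr$recall, f1 = mr$f1)
}

#' Fit the root segmentation network
#'
#' The single fitting entry point: takes scenes (in memory or as a dataset
#' manifest of image/mask files), makes a seeded train/validation split,
#' trains for exactly `control$epochs` epochs, and returns a fitted-model
#' object with the per-epoch training record. The best-validation-F1
#' parameters are retained alongside the final ones.
#'
#' @param data either a list of `scene` objects / `list(image, mask)` pairs,
#'   or a data.frame manifest with `image_path`/`mask_path` columns (as
#'   written by [generate_dataset()]).
#' @param spec a [model_spec()]; tile dims must be divisible by 16.
#' @param control a [train_spec()].
#' @param model optional pre-built [build_model()] to continue training;
#'   overrides `spec`.
#' @param verbose print per-epoch progress.
#' @return object of class `rootseg_fit`: `model` (final), `best_params`,
#'   `best_epoch`, `history` (data.frame of epoch records), `control`, `spec`.
#' @export
fit_rootseg <- function(data, spec = model_spec(), control = train_spec(),
                        model = NULL, verbose = FALSE) {
  tiles <- .as_tiles(data)
  if (is.null(model)) model <- build_model(spec, seed = control$seed)
  sp <- make_splits(seq_along(tiles), control$val_fraction, control$seed)
  res <- .train_loop(model, tiles[sp$train], tiles[sp$val], control,
                     verbose = verbose)
  structure(list(model = res$model, best_params = res$best$params,
                 best_epoch = res$best$epoch, history = res$history,
                 control = control, spec = res$model$spec,
                 n_train = length(sp$train), n_val = length(sp$val)),
            class = "rootseg_fit")
}

.as_tiles <- function(data) {
  if (is.data.frame(data)) {
    missing <- !file.exists(data$image_path) | !file.exists(data$mask_path)
    if (any(missing))
      stop(sprintf("missing dataset files: %s",
                   paste(data$image_path[missing], collapse = ", ")), call. = FALSE)
    return(lapply(seq_len(nrow(data)), function(i)
      list(image = read_raster(data$image_path[i]),
           mask = read_mask(data$mask_path[i]))))
  }
  if (is.list(data) && length(data) &&
      all(vapply(data, function(d) !is.null(d$image) && !is.null(d$mask), logical(1))))
    return(lapply(data, function(d) list(image = d$image, mask = d$mask)))
  stop("`data` must be a manifest data.frame or a list of image/mask pairs",
       call. = FALSE)
}

#' @export
print.rootseg_fit <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  cat(sprintf(paste0("rootseg_fit: %d epochs on %d train / %d val tiles\n",
                     "  final: train loss %.4f, val F1 %.4f (P %.4f, R %.4f)\n",
                     "  best val F1 %.4f at epoch %d\n"),
              nrow(x$history), x$n_train, x$n_val,
              last$train_loss, last$val_f1, last$val_precision,
              last$val_recall, max(x$history$val_f1), x$best_epoch))
  invisible(x)
}

#' @export
summary.rootseg_fit <- function(object, ...) {
  print(object)
  cat("\nTraining history:\n")
  print(object$history, row.names = FALSE, digits = 4)
  invisible(object$history)
}

#' @export
plot.rootseg_fit <- function(x, ...) {
  h <- x$history
  op <- par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(par(op))
  plot(h$epoch, h$train_loss, type = "b", pch = 16, xlab = "epoch",
       ylab = "mean pixel cross-entropy", main = "Training loss", ...)
  plot(h$epoch, h$val_f1, type = "b", pch = 16, ylim = c(0, 1),
       xlab = "epoch", ylab = "score", main = "Validation metrics")
  lines(h$epoch, h$val_precision, type = "b", pch = 1, lty = 2)
  lines(h$epoch, h$val_recall, type = "b", pch = 2, lty = 3)
  legend("bottomright", c("F1", "precision", "recall"),
         pch = c(16, 1, 2), lty = 1:3, bty = "n")
  invisible(x)
}

#' Predict with a fitted model
#'
#' @param object a `rootseg_fit`.
#' @param image image array or path (see [predict.rootseg_model()]).
#' @param which `"final"` (last-epoch parameters) or `"best"`
#'   (best-validation-F1 checkpoint).
#' @param ... passed to [predict.rootseg_model()].
#' @return mask matrix or score array.
#' @export
predict.rootseg_fit <- function(object, image, which = c("final", "best"), ...) {
  which <- match.arg(which)
  m <- object$model
  if (which == "best") m$params <- object$best_params
  predict(m, image, ...)
}
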