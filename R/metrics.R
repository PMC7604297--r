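# Pixel-level evaluation. Root = positive class. precision = TP/(TP+FP),
# recall = TP/(TP+FN), F1 = 2PR/(P+R), dice = 2TP/(2TP+FP+FN) (algebraically
# identical to F1 from the same counts), accuracy = (TP+TN)/total. Background
# dominates (~97% of pixels), so accuracy is reported but never used as a
# headline number. Degenerate denominators yield 0 with a flag, never NaN.

#' Pixel confusion counts between a predicted and a true mask
#'
#' @param pred,truth binary 0/1 matrices of identical dims; 1 = root.
#' @return object of class `confusion_counts`: list with `TP`, `FP`, `FN`,
#'   `TN` (doubles, to avoid integer overflow on gigapixel tallies).
#' @export
confusion <- function(pred, truth) {
  .check_binary_mask(pred, "pred")
  .check_binary_mask(truth, "truth")
  if (any(dim(pred) != dim(truth)))
    stop("`pred` and `truth` dims differ", call. = FALSE)
  p <- as.logical(pred); t <- as.logical(truth)
  as_confusion(c(TP = sum(p & t), FP = sum(p & !t),
                 FN = sum(!p & t), TN = sum(!p & !t)))
}

#' Construct confusion counts directly
#'
#' @param x named numeric vector or list with `TP`, `FP`, `FN`, `TN` (all
#'   >= 0).
#' @return object of class `confusion_counts`.
#' @export
as_confusion <- function(x) {
  x <- as.list(x)
  need <- c("TP", "FP", "FN", "TN")
  if (!all(need %in% names(x))) stop("need TP, FP, FN, TN", call. = FALSE)
  x <- lapply(x[need], as.numeric)
  if (any(unlist(x) < 0)) stop("counts must be >= 0", call. = FALSE)
  structure(x, class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("confusion: TP %g  FP %g  FN %g  TN %g (total %g)\n",
              x$TP, x$FP, x$FN, x$TN, x$TP + x$FP + x$FN + x$TN))
  invisible(x)
}

#' Harmonic-mean F1 from precision and recall
#'
#' `F1 = 2 P R / (P + R)`; 0 (flagged degenerate upstream) when both are 0.
#'
#' @param precision,recall values in \[0, 1\].
#' @return F1 in \[0, 1\].
#' @examples
#' f1_score(0.9702, 0.9847)  # 0.9773 to 4 d.p.
#' @export
f1_score <- function(precision, recall) {
  ifelse(precision + recall > 0, 2 * precision * recall / (precision + recall), 0)
}

#' Segmentation metrics from confusion counts
#'
#' @param counts a `confusion_counts` object (or anything [as_confusion()]
#'   accepts).
#' @return object of class `metrics_report`: list with `accuracy`,
#'   `precision`, `recall`, `f1`, `dice`, `counts`, and `degenerate` (names of
#'   metrics whose denominator was 0 and which were set to 0).
#' @export
metrics_from_counts <- function(counts) {
  counts <- as_confusion(counts)
  total <- counts$TP + counts$FP + counts$FN + counts$TN
  degen <- character(0)
  div <- function(num, den, nm) {
    if (den <= 0) { degen <<- c(degen, nm); return(0) }
    num / den
  }
  precision <- div(counts$TP, counts$TP + counts$FP, "precision")
  recall <- div(counts$TP, counts$TP + counts$FN, "recall")
  f1 <- if (precision + recall > 0) f1_score(precision, recall)
        else { degen <- c(degen, "f1"); 0 }
  dice <- div(2 * counts$TP, 2 * counts$TP + counts$FP + counts$FN, "dice")
  accuracy <- div(counts$TP + counts$TN, total, "accuracy")
  structure(list(accuracy = accuracy, precision = precision, recall = recall,
                 f1 = f1, dice = dice, counts = counts, degenerate = degen),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("accuracy %.4f  precision %.4f  recall %.4f  F1 %.4f  dice %.4f\n",
              x$accuracy, x$precision, x$recall, x$f1, x$dice))
  if (length(x$degenerate))
    cat("  (degenerate, set to 0:", paste(x$degenerate, collapse = ", "), ")\n")
  invisible(x)
}

#' Evaluate a model over a dataset manifest
#'
#' Runs the full pad/tile/forward/stitch/argmax path per image and aggregates
#' either pooled pixel counts (`micro`, the default) or the mean of per-image
#' metrics (`macro`).
#'
#' @param model a `rootseg_model` or `rootseg_fit`.
#' @param manifest data.frame with `image_path` and `mask_path` columns, or a
#'   list of scenes.
#' @param aggregation `"micro"` or `"macro"`.
#' @return a `metrics_report` (micro) or list with `mean` metrics and
#'   `per_image` data.frame (macro). Both carry the `per_image` table in
#'   attribute/slot `per_image`.
#' @export
evaluate_model <- function(model, manifest, aggregation = c("micro", "macro")) {
  aggregation <- match.arg(aggregation)
  if (inherits(model, "rootseg_fit")) model <- model$model
  tiles <- .as_tiles(manifest)
  rows <- vector("list", length(tiles))
  tot <- c(TP = 0, FP = 0, FN = 0, TN = 0)
  for (i in seq_along(tiles)) {
    pred <- predict(model, tiles[[i]]$image)
    cc <- confusion(pred, tiles[[i]]$mask)
    mr <- metrics_from_counts(cc)
    rows[[i]] <- data.frame(image = i, TP = cc$TP, FP = cc$FP, FN = cc$FN,
                            TN = cc$TN, precision = mr$precision,
                            recall = mr$recall, f1 = mr$f1, dice = mr$dice)
    tot <- tot + unlist(cc[c("TP", "FP", "FN", "TN")])
  }
  per_image <- do.call(rbind, rows)
  if (aggregation == "micro") {
    out <- metrics_from_counts(as_confusion(tot))
    out$n_images <- length(tiles)
    out$aggregation <- "micro"
    attr(out, "per_image") <- per_image
    return(out)
  }
  means <- colMeans(per_image[, c("precision", "recall", "f1", "dice")])
  structure(list(aggregation = "macro", n_images = length(tiles),
                 precision = means[["precision"]], recall = means[["recall"]],
                 f1 = means[["f1"]], dice = means[["dice"]],
                 per_image = per_image),
            class = "metrics_macro")
}

#' @export
print.metrics_macro <- function(x, ...) {
  cat(sprintf("macro over %d images: precision %.4f  recall %.4f  F1 %.4f  dice %.4f\n",
              x$n_images, x$precision, x$recall, x$f1, x$dice))
  invisible(x)
}

#' Side-by-side comparison of upsampling heads
#'
#' Evaluates two (or more) checkpoints on the same manifest and reports
#' per-model micro metrics plus per-image dice deltas relative to the first
#' model. No significance claims are made.
#'
#' @param manifest dataset manifest or scene list.
#' @param models named list of `rootseg_model`/`rootseg_fit` objects (e.g.
#'   `list(bilinear = ..., subpixel = ...)`).
#' @return list with `summary` (one row per model: precision, recall, f1,
#'   dice) and `per_image` (long data.frame with a `model` column and a
#'   `dice_delta` vs the first model).
#' @export
compare_heads <- function(manifest, models) {
  if (length(models) < 2L || is.null(names(models)))
    stop("`models` must be a named list of >= 2 models", call. = FALSE)
  specs <- lapply(models, function(m)
    if (inherits(m, "rootseg_fit")) m$spec else m$spec)
  is0 <- specs[[1]]$input_size
  if (any(vapply(specs, function(s) s$input_size, integer(1)) != is0))
    warning("models have differing input sizes; comparison may not be like-for-like")
  evals <- lapply(models, evaluate_model, manifest = manifest)
  summary <- do.call(rbind, lapply(names(evals), function(nm) {
    e <- evals[[nm]]
    data.frame(model = nm, precision = e$precision, recall = e$recall,
               f1 = e$f1, dice = e$dice)
  }))
  per <- do.call(rbind, lapply(names(evals), function(nm) {
    pi <- attr(evals[[nm]], "per_image")
    pi$model <- nm
    pi
  }))
  base <- attr(evals[[1]], "per_image")$dice
  per$dice_delta <- per$dice - base[per$image]
  list(summary = summary, per_image = per)
}

# --- skeleton length --------------------------------------------------------

# One pass of Zhang-Suen thinning (vectorised over the whole image).
.thin_pass <- function(m, step) {
  h <- nrow(m); w <- ncol(m)
  pad <- matrix(FALSE, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- m
  sh <- function(dy, dx) pad[(2 + dy):(h + 1 + dy), (2 + dx):(w + 1 + dx)]
  p2 <- sh(-1, 0); p3 <- sh(-1, 1); p4 <- sh(0, 1); p5 <- sh(1, 1)
  p6 <- sh(1, 0); p7 <- sh(1, -1); p8 <- sh(0, -1); p9 <- sh(-1, -1)
  B <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
  seqn <- list(p2, p3, p4, p5, p6, p7, p8, p9, p2)
  A <- matrix(0L, h, w)
  for (k in 1:8) A <- A + (!seqn[[k]] & seqn[[k + 1]])
  cond <- m & B >= 2 & B <= 6 & A == 1L
  if (step == 1L) cond <- cond & !(p2 & p4 & p6) & !(p4 & p6 & p8)
  else cond <- cond & !(p2 & p4 & p8) & !(p2 & p6 & p8)
  m & !cond
}

#' Morphological skeleton of a binary mask (Zhang–Suen thinning)
#'
#' @param mask binary 0/1 matrix.
#' @return logical matrix of the one-pixel-wide skeleton.
#' @export
skeletonize <- function(mask) {
  .check_binary_mask(mask)
  m <- mask == 1
  repeat {
    m1 <- .thin_pass(m, 1L)
    m2 <- .thin_pass(m1, 2L)
    if (identical(m2, m)) break
    m <- m2
  }
  m
}

# Remove skeleton spurs: branches of < min_len pixels that run from an
# endpoint into a junction. These are thinning artifacts of boundary bumps,
# not root branches, and bias length upward.
.prune_spurs <- function(sk, min_len) {
  if (min_len < 1 || !any(sk)) return(sk)
  h <- nrow(sk)
  noff <- c(-1L, 1L, -h, h, -h - 1L, -h + 1L, h - 1L, h + 1L)
  deg <- function(s) {
    pad <- matrix(FALSE, h + 2, ncol(s) + 2)
    pad[2:(h + 1), 2:(ncol(s) + 1)] <- s
    d <- matrix(0L, h, ncol(s))
    for (dy in -1:1) for (dx in -1:1) if (dy || dx)
      d <- d + pad[(2 + dy):(h + 1 + dy), (2 + dx):(ncol(s) + 1 + dx)]
    d
  }
  # guard ring so linear-index neighbour offsets cannot wrap
  sk[1, ] <- FALSE; sk[h, ] <- FALSE; sk[, 1] <- FALSE; sk[, ncol(sk)] <- FALSE
  repeat {
    d <- deg(sk)
    ends <- which(sk & d == 1L)
    removed <- FALSE
    for (e in ends) {
      if (!sk[e]) next
      path <- e
      cur <- e; prev <- -1L
      repeat {
        nb <- cur + noff
        nb <- nb[sk[nb]]
        nb <- nb[nb != prev & !(nb %in% path)]
        if (!length(nb)) { path <- integer(0); break }      # isolated segment
        if (length(nb) > 1L || d[nb[1]] >= 3L) {            # reached junction
          break
        }
        prev <- cur; cur <- nb[1]; path <- c(path, cur)
        if (length(path) >= min_len) { path <- integer(0); break }
      }
      if (length(path) && length(path) < min_len) {
        sk[path] <- FALSE
        removed <- TRUE
      }
    }
    if (!removed) break
  }
  sk
}

#' Root length estimate from a binary mask
#'
#' Skeletonises the mask (Zhang-Suen thinning, then pruning of spurs shorter
#' than `prune` pixels) and sums inter-pixel links along the skeleton:
#' orthogonal neighbours contribute 1 px, diagonal neighbours sqrt(2) px, and
#' a diagonal link is skipped when either of its two orthogonal "corner"
#' pixels is present (so an L-step is not double counted). A straight
#' horizontal run of n pixels therefore measures n - 1.
#'
#' @param mask binary 0/1 matrix.
#' @param prune spurs shorter than this many pixels are removed before
#'   measuring (thinning artifacts of boundary bumps); branches ending free of
#'   a junction are never pruned.
#' @return length in pixels (0 for an empty mask).
#' @export
estimate_root_length <- function(mask, prune = 5L) {
  sk <- .prune_spurs(skeletonize(mask), prune)
  h <- nrow(sk); w <- ncol(sk)
  if (!any(sk)) return(0)
  horiz <- sum(sk[, -w] & sk[, -1])
  vert <- sum(sk[-h, ] & sk[-1, ])
  se <- sk[-h, -w] & sk[-1, -1] & !(sk[-h, -1] | sk[-1, -w])
  ne <- sk[-1, -w] & sk[-h, -1] & !(sk[-h, -w] | sk[-1, -1])
  horiz + vert + sqrt(2) * (sum(se) + sum(ne))
}
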