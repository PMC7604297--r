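# Pad / tile / stitch: the mechanism by which scans far larger than the
# network input (up to ~10,200 x 14,039 px) pass through a fixed 512 x 512
# model. Padding is zeros, bottom/right only, so original pixel coordinates
# are unchanged; tiles are row-major; stitching averages scores where tiles
# overlap and crops the padding off. Coordinates are 0-based.

#' Padding geometry without allocating the image
#'
#' @param h,w current height and width in pixels.
#' @param multiple target divisor (e.g. 512).
#' @return list with `height`, `width` (padded dims), `pad_bottom`, `pad_right`.
#' @examples
#' pad_geometry(10200, 14039, 512)  # pads 40 and 297 -> 10240 x 14336
#' @export
pad_geometry <- function(h, w, multiple) {
  if (!is.numeric(multiple) || length(multiple) != 1L || multiple < 1)
    stop("`multiple` must be a positive integer", call. = FALSE)
  ph <- as.integer(ceiling(h / multiple) * multiple)
  pw <- as.integer(ceiling(w / multiple) * multiple)
  list(height = ph, width = pw, pad_bottom = ph - as.integer(h),
       pad_right = pw - as.integer(w))
}

#' Zero-pad an image so its dimensions are divisible by `multiple`
#'
#' Padding is appended on the bottom and right only; the original content
#' occupies the top-left block unchanged.
#'
#' @param image matrix or H x W x C array.
#' @param multiple target divisor of both output dimensions.
#' @return list with `image` (padded), `pad_bottom`, `pad_right`.
#' @export
pad_to_multiple <- function(image, multiple) {
  was2d <- length(dim(image)) == 2L
  image <- .as3d(image)
  d <- dim(image)
  g <- pad_geometry(d[1], d[2], multiple)
  out <- array(0, dim = c(g$height, g$width, d[3]))
  storage.mode(out) <- storage.mode(image)
  out[seq_len(d[1]), seq_len(d[2]), ] <- image
  if (was2d) out <- out[, , 1]
  list(image = out, pad_bottom = g$pad_bottom, pad_right = g$pad_right)
}

#' Number of tiles produced by a sliding tiling
#'
#' @param h,w padded image dims; `(h - tile_size)` and `(w - tile_size)` must
#'   be divisible by `stride`.
#' @param tile_size tile side length in pixels.
#' @param stride step between tile origins; `stride <= tile_size`.
#' @return integer tile count `((h-t)/s + 1) * ((w-t)/s + 1)`.
#' @examples
#' tile_count(10240, 14336, 512, 512)  # 20 * 28 = 560
#' @export
tile_count <- function(h, w, tile_size, stride = tile_size) {
  .check_tiling(h, w, tile_size, stride)
  as.integer(((h - tile_size) / stride + 1) * ((w - tile_size) / stride + 1))
}

.check_tiling <- function(h, w, tile_size, stride) {
  if (stride > tile_size)
    stop("`stride` greater than `tile_size` leaves coverage gaps", call. = FALSE)
  if (stride < 1 || tile_size < 1) stop("non-positive tiling parameters", call. = FALSE)
  if (h < tile_size || w < tile_size)
    stop("image smaller than tile; pad first", call. = FALSE)
  if ((h - tile_size) %% stride != 0 || (w - tile_size) %% stride != 0)
    stop("image dims incompatible with tile/stride; pad first", call. = FALSE)
  invisible(TRUE)
}

#' Split a padded image into fixed-size tiles
#'
#' @param image matrix or H x W x C array, already padded so the tiling covers
#'   it exactly (see [pad_to_multiple()]).
#' @param tile_size tile side in pixels (default 512, the network input).
#' @param stride step between tile origins; defaults to `tile_size`
#'   (non-overlapping). Smaller strides give overlapping tiles whose scores
#'   are averaged at stitch time.
#' @param orig_dim length-2 integer, the pre-padding dims recorded for the
#'   final crop; defaults to the input dims (no padding).
#' @return a `tile_grid`: list with `tile_size`, `stride`, `orig_height`,
#'   `orig_width`, `pad_bottom`, `pad_right`, `nrow_tiles`, `ncol_tiles`, and
#'   `tiles`, a row-major list of `list(row, col, data)` with 0-based indices.
#' @export
split_tiles <- function(image, tile_size = 512L, stride = tile_size,
                        orig_dim = NULL) {
  was2d <- length(dim(image)) == 2L
  image <- .as3d(image)
  d <- dim(image)
  .check_tiling(d[1], d[2], tile_size, stride)
  if (is.null(orig_dim)) orig_dim <- d[1:2]
  nr <- (d[1] - tile_size) / stride + 1
  nc <- (d[2] - tile_size) / stride + 1
  tiles <- vector("list", nr * nc)
  k <- 0L
  for (i in seq_len(nr) - 1L) {
    for (j in seq_len(nc) - 1L) {
      k <- k + 1L
      dat <- image[i * stride + seq_len(tile_size),
                   j * stride + seq_len(tile_size), , drop = FALSE]
      if (was2d) dat <- dat[, , 1]
      tiles[[k]] <- list(row = i, col = j, data = dat)
    }
  }
  structure(list(tile_size = as.integer(tile_size), stride = as.integer(stride),
                 orig_height = as.integer(orig_dim[1]),
                 orig_width = as.integer(orig_dim[2]),
                 pad_bottom = as.integer(d[1] - orig_dim[1]),
                 pad_right = as.integer(d[2] - orig_dim[2]),
                 nrow_tiles = as.integer(nr), ncol_tiles = as.integer(nc),
                 tiles = tiles),
            class = "tile_grid")
}

#' @export
print.tile_grid <- function(x, ...) {
  cat(sprintf("tile_grid: %d x %d tiles of %d px (stride %d), original %d x %d, pads (%d, %d)\n",
              x$nrow_tiles, x$ncol_tiles, x$tile_size, x$stride,
              x$orig_height, x$orig_width, x$pad_bottom, x$pad_right))
  invisible(x)
}

#' Reassemble tiles into a full-size raster
#'
#' Inverse of [split_tiles()]: places each tile at its origin, averages
#' pixel-wise where tiles overlap (mean of scores, so stitch-then-argmax
#' avoids seam artifacts), then crops away the padding so the output has the
#' original dimensions.
#'
#' @param grid a `tile_grid` whose `data` entries are matrices or H x W x C
#'   arrays (e.g. per-pixel class scores).
#' @return matrix or array of the original (pre-padding) dimensions.
#' @export
stitch_tiles <- function(grid) {
  if (!inherits(grid, "tile_grid")) stop("`grid` must be a tile_grid", call. = FALSE)
  expected <- grid$nrow_tiles * grid$ncol_tiles
  if (length(grid$tiles) != expected)
    stop(sprintf("incomplete tile grid: %d of %d tiles", length(grid$tiles), expected),
         call. = FALSE)
  t0 <- .as3d(grid$tiles[[1]]$data)
  was2d <- length(dim(grid$tiles[[1]]$data)) == 2L
  ch <- dim(t0)[3]
  ts <- grid$tile_size; s <- grid$stride
  H <- (grid$nrow_tiles - 1L) * s + ts
  W <- (grid$ncol_tiles - 1L) * s + ts
  acc <- array(0, dim = c(H, W, ch))
  cnt <- matrix(0, H, W)
  seen <- matrix(FALSE, grid$nrow_tiles, grid$ncol_tiles)
  for (t in grid$tiles) {
    if (is.null(t$data)) stop("missing tile data", call. = FALSE)
    seen[t$row + 1L, t$col + 1L] <- TRUE
    ri <- t$row * s + seq_len(ts)
    ci <- t$col * s + seq_len(ts)
    acc[ri, ci, ] <- acc[ri, ci, , drop = FALSE] + .as3d(t$data)
    cnt[ri, ci] <- cnt[ri, ci] + 1
  }
  if (!all(seen)) stop("missing tiles in grid", call. = FALSE)
  for (c in seq_len(ch)) acc[, , c] <- acc[, , c] / cnt
  out <- acc[seq_len(grid$orig_height), seq_len(grid$orig_width), , drop = FALSE]
  if (was2d) out <- out[, , 1]
  out
}
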