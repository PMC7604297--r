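#' Bilinear upsampling of a raster by an integer factor
#'
#' Two-stage linear interpolation over the four nearest input samples: first
#' along x to obtain the intermediate values \eqn{f(R_1)}, \eqn{f(R_2)} at the
#' query column, then along y between them. The grid convention is
#' corner-aligned: the output corner samples coincide with the input corner
#' samples, so the source coordinate of output row \eqn{i} is
#' \eqn{i\,(H-1)/(fH-1)}. Every output value is a convex combination of input
#' values, hence the output extrema never exceed the input extrema — the
#' low-pass behaviour that motivates replacing this stage with learned
#' sub-pixel convolution in the segmentation head.
#'
#' @param x numeric matrix (H x W) or array (H x W x C).
#' @param factor integer upscaling factor, >= 1.
#' @return array of dimension (factor*H) x (factor*W) x C (matrix in, matrix
#'   out).
#' @examples
#' bilinear_upsample(matrix(c(0, 4, 2, 6), 2, 2), 2)
#' @export
bilinear_upsample <- function(x, factor) {
  if (!is.numeric(factor) || length(factor) != 1L || factor < 1 ||
      factor != as.integer(factor))
    stop("`factor` must be a single integer >= 1", call. = FALSE)
  was2d <- length(dim(x)) == 2L
  x <- .as3d(x)
  d <- dim(x)
  out <- .bilinear_resize_fwd(x, as.integer(d[1] * factor), as.integer(d[2] * factor))
  if (was2d) out <- out[, , 1]
  out
}

#' Periodic shuffling (sub-pixel rearrangement) of channel blocks into space
#'
#' Rearranges an H x W x (C*r^2) tensor into an rH x rW x C tensor without any
#' arithmetic on the values: `out[y, x, c] = in[floor(y/r), floor(x/r),
#' c*r^2 + (y mod r)*r + (x mod r)]` (0-based indices). This is the PS operator
#' of sub-pixel convolution: a preceding convolution produces r^2 channel
#' phases per output channel, and the shuffle interleaves them into a finer
#' grid, letting the network *learn* its upsampling filter instead of fixing a
#' bilinear one. The channel-major phase order (`c*r^2 + dy*r + dx`) follows
#' the originating super-resolution formulation.
#'
#' @param x numeric array H x W x (C*r^2).
#' @param r integer upscaling factor >= 1.
#' @return numeric array rH x rW x C; a pure permutation of `x`'s values.
#' @seealso [pixel_unshuffle()] for the exact inverse.
#' @examples
#' pixel_shuffle(array(1:4, c(1, 1, 4)), 2)[, , 1]  # [[1,2],[3,4]]
#' @export
pixel_shuffle <- function(x, r) {
  r <- as.integer(r)
  if (length(r) != 1L || is.na(r) || r < 1L)
    stop("`r` must be a single integer >= 1", call. = FALSE)
  d <- dim(x)
  if (length(d) != 3L) stop("`x` must be an H x W x C array", call. = FALSE)
  if (d[3] %% (r * r) != 0L)
    stop(sprintf("channel count %d not divisible by r^2 = %d", d[3], r * r),
         call. = FALSE)
  if (r == 1L) return(x)
  H <- d[1]; W <- d[2]; C <- d[3] %/% (r * r)
  oy <- rep(seq_len(H * r) - 1L, times = W * r * C)
  ox <- rep(rep(seq_len(W * r) - 1L, each = H * r), times = C)
  oc <- rep(seq_len(C) - 1L, each = H * r * W * r)
  iy <- oy %/% r
  ix <- ox %/% r
  ic <- oc * r * r + (oy %% r) * r + (ox %% r)
  out <- x[1L + iy + H * ix + H * W * ic]
  dim(out) <- c(H * r, W * r, C)
  out
}

#' Inverse periodic shuffling
#'
#' Exact inverse of [pixel_shuffle()]: folds an rH x rW x C tensor back into
#' H x W x (C*r^2) under the same channel-major phase convention.
#'
#' @inheritParams pixel_shuffle
#' @param x numeric array rH x rW x C with both spatial dims divisible by `r`.
#' @return numeric array H x W x (C*r^2).
#' @export
pixel_unshuffle <- function(x, r) {
  r <- as.integer(r)
  if (length(r) != 1L || is.na(r) || r < 1L)
    stop("`r` must be a single integer >= 1", call. = FALSE)
  d <- dim(x)
  if (length(d) != 3L) stop("`x` must be an H x W x C array", call. = FALSE)
  if (d[1] %% r != 0L || d[2] %% r != 0L)
    stop("spatial dims must be divisible by `r`", call. = FALSE)
  if (r == 1L) return(x)
  H <- d[1] %/% r; W <- d[2] %/% r; C <- d[3]
  # out[h, w, c*r^2 + dy*r + dx] = x[h*r + dy, w*r + dx, c]
  oh <- rep(seq_len(H) - 1L, times = W * C * r * r)
  ow <- rep(rep(seq_len(W) - 1L, each = H), times = C * r * r)
  occ <- rep(seq_len(C * r * r) - 1L, each = H * W)
  c0 <- occ %/% (r * r)
  dy <- (occ %% (r * r)) %/% r
  dx <- occ %% r
  out <- x[1L + (oh * r + dy) + d[1] * (ow * r + dx) + d[1] * d[2] * c0]
  dim(out) <- c(H, W, C * r * r)
  out
}
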