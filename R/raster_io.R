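# Raster I/O. The package reads and writes binary PNM: P6 (RGB, maxval 255)
# for images and P5 (grayscale) for masks. PNM is lossless and bit-exact on
# round trip, which the mask contract requires; ASCII variants (P2/P3) are
# accepted on read. Masks follow the annotation convention: root pixels white
# (255), background black (0), mapped to {1, 0} in memory.

#' Read a raster image (binary or ASCII PNM)
#'
#' @param path file path to a `.ppm`/`.pgm`/`.pnm` file.
#' @return integer array H x W x 3 (RGB) or H x W x 1 (grayscale), values
#'   0..255, row-major origin top-left.
#' @export
read_raster <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 2L))
  if (!magic %in% c("P2", "P3", "P5", "P6"))
    stop(sprintf("'%s' is not a supported PNM file (magic '%s')", path, magic),
         call. = FALSE)
  hdr <- .pnm_header_ints(con, 3L)
  w <- hdr[1]; h <- hdr[2]; maxval <- hdr[3]
  if (maxval > 255L) stop("16-bit PNM not supported", call. = FALSE)
  nch <- if (magic %in% c("P3", "P6")) 3L else 1L
  n <- w * h * nch
  vals <- if (magic %in% c("P5", "P6")) {
    as.integer(readBin(con, "raw", n))
  } else {
    scan(con, what = integer(), n = n, quiet = TRUE)
  }
  if (length(vals) != n) stop("truncated PNM payload", call. = FALSE)
  # file order: row-major, channels interleaved -> H x W x C array
  arr <- array(0L, dim = c(h, w, nch))
  for (c in seq_len(nch))
    arr[, , c] <- matrix(vals[seq(c, n, by = nch)], nrow = h, ncol = w, byrow = TRUE)
  arr
}

.pnm_header_ints <- function(con, k) {
  out <- integer(0)
  tok <- character(0)
  repeat {
    ch <- rawToChar(readBin(con, "raw", 1L))
    if (length(ch) == 0L || ch == "") stop("truncated PNM header", call. = FALSE)
    if (ch == "#") {  # comment to end of line
      repeat {
        ch <- rawToChar(readBin(con, "raw", 1L))
        if (ch %in% c("\n", "\r", "")) break
      }
      next
    }
    if (grepl("[[:space:]]", ch)) {
      if (length(tok)) { out <- c(out, as.integer(paste(tok, collapse = ""))); tok <- character(0) }
      if (length(out) == k) return(out)
    } else tok <- c(tok, ch)
  }
}

#' Write a raster image as binary PNM
#'
#' RGB arrays (H x W x 3) are written as P6, single-channel as P5. Values are
#' clamped to 0..255 and rounded; the round trip through [read_raster()] is
#' bit-exact for integer input.
#'
#' @param image numeric/integer array H x W x 3, H x W x 1, or H x W matrix.
#' @param path output path (conventionally `.ppm` for RGB, `.pgm` for gray).
#' @return `path`, invisibly.
#' @export
write_raster <- function(image, path) {
  image <- .as3d(image)
  d <- dim(image)
  if (!d[3] %in% c(1L, 3L)) stop("image must have 1 or 3 channels", call. = FALSE)
  v <- pmin(pmax(round(image), 0), 255)
  magic <- if (d[3] == 3L) "P6" else "P5"
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(sprintf("%s\n%d %d\n255\n", magic, d[2], d[1]), con, eos = NULL)
  # aperm to C x W x H; as.vector then runs channel fastest, then column,
  # then row = interleaved row-major, the PNM payload order
  flat <- as.vector(aperm(v, c(3L, 2L, 1L)))
  writeBin(as.raw(as.integer(flat)), con)
  invisible(path)
}

#' Read a binary mask
#'
#' Reads a grayscale PNM mask written with the white-root/black-background
#' convention and maps it to a 0/1 integer matrix (threshold at 128).
#'
#' @param path path to a `.pgm` mask file.
#' @return integer matrix H x W with values in \{0, 1\}.
#' @export
read_mask <- function(path) {
  arr <- read_raster(path)
  m <- arr[, , 1]
  matrix(as.integer(m >= 128L), nrow = dim(arr)[1])
}

#' Write a binary mask
#'
#' Writes a 0/1 matrix as a grayscale PNM with roots white (255) and
#' background black (0). The write/read round trip preserves the mask exactly.
#'
#' @param mask integer/logical matrix H x W, values in \{0, 1\}.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  .check_binary_mask(mask, "mask")
  write_raster(matrix(as.integer(mask) * 255L, nrow = nrow(mask)), path)
}

.check_binary_mask <- function(mask, name = "mask") {
  if (is.null(dim(mask)) || length(dim(mask)) != 2L)
    stop(sprintf("`%s` must be a matrix", name), call. = FALSE)
  if (!all(mask %in% c(0L, 1L, FALSE, TRUE)))
    stop(sprintf("`%s` must be strictly binary (0/1)", name), call. = FALSE)
  invisible(TRUE)
}
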