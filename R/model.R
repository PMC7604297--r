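# The segmentation network. Encoder: a stack of strided depthwise-separable
# blocks to output stride 16, then atrous spatial pyramid pooling (parallel
# 1x1, three dilated 3x3 branches at rates 6/12/18, and image-level pooling)
# concatenated and compressed by a 1x1 convolution. Decoder: 4x bilinear
# upsample to OS=4, concat with 1x1-reduced low-level features, 3x3 fusion,
# then a final 4x stage that is either one bilinear upsample (standard head)
# or two cascaded sub-pixel stages (3x3 conv quadrupling channels followed by
# PixelShuffle r=2), and a 1x1 classifier at full resolution. Sub-pixel stages
# therefore operate on features, not logits.

#' Architecture configuration for the segmentation network
#'
#' @param backbone `"lite"` (one depthwise-separable block per downsampling
#'   stage; CPU-trainable) or `"xception"` (adds a second, non-strided
#'   separable block per stage — a deeper Xception-flavoured stack).
#' @param output_stride fixed at 16: the encoder feature map is 16x smaller
#'   than the input in each spatial dimension.
#' @param aspp_rates strictly increasing dilation rates of the three atrous
#'   branches (default 6, 12, 18).
#' @param aspp_out_channels channels after the ASPP 1x1 compression.
#' @param lowlevel_channels channels after the 1x1 reduction of the skip
#'   (low-level, OS=4) features.
#' @param decoder_channels channels of the 3x3 decoder fusion output.
#' @param upsampling_mode final 4x stage: `"bilinear"` or `"subpixel"`.
#' @param subpixel_r per-stage upscaling factor of the sub-pixel head; the
#'   default 2 is applied twice (two cascaded stages) to total 4x.
#' @param num_classes output classes (2: background, root).
#' @param input_size nominal tile side in px; must be divisible by
#'   `output_stride`.
#' @param backbone_widths channel widths of the four encoder stages
#'   (OS 2, 4, 8, 16).
#' @param aspp_1x1,aspp_pool include the 1x1 and image-pooling ASPP branches
#'   (standard composition; both on by default).
#' @return object of class `rootseg_spec`.
#' @export
model_spec <- function(backbone = c("lite", "xception"),
                       output_stride = 16L,
                       aspp_rates = c(6L, 12L, 18L),
                       aspp_out_channels = 256L,
                       lowlevel_channels = 48L,
                       decoder_channels = 256L,
                       upsampling_mode = c("subpixel", "bilinear"),
                       subpixel_r = 2L,
                       num_classes = 2L,
                       input_size = 512L,
                       backbone_widths = c(32L, 64L, 128L, 256L),
                       aspp_1x1 = TRUE, aspp_pool = TRUE) {
  backbone <- match.arg(backbone)
  upsampling_mode <- match.arg(upsampling_mode)
  if (output_stride != 16L) stop("`output_stride` is fixed at 16", call. = FALSE)
  if (length(aspp_rates) != 3L || any(aspp_rates <= 0) ||
      any(diff(aspp_rates) <= 0))
    stop("`aspp_rates` must be three strictly increasing positive rates", call. = FALSE)
  if (subpixel_r < 1L) stop("`subpixel_r` must be >= 1", call. = FALSE)
  if (input_size %% output_stride != 0L)
    stop("`input_size` must be divisible by `output_stride`", call. = FALSE)
  if (length(backbone_widths) != 4L || any(backbone_widths < 1))
    stop("`backbone_widths` must be four positive widths", call. = FALSE)
  structure(list(backbone = backbone, output_stride = as.integer(output_stride),
                 aspp_rates = as.integer(aspp_rates),
                 aspp_out_channels = as.integer(aspp_out_channels),
                 lowlevel_channels = as.integer(lowlevel_channels),
                 decoder_channels = as.integer(decoder_channels),
                 upsampling_mode = upsampling_mode,
                 subpixel_r = as.integer(subpixel_r),
                 num_classes = as.integer(num_classes),
                 input_size = as.integer(input_size),
                 backbone_widths = as.integer(backbone_widths),
                 aspp_1x1 = isTRUE(aspp_1x1), aspp_pool = isTRUE(aspp_pool)),
            class = "rootseg_spec")
}

#' @export
print.rootseg_spec <- function(x, ...) {
  cat(sprintf(paste0("rootseg_spec: %s backbone (widths %s), OS=%d, ASPP rates %s -> %d ch,\n",
                     "  low-level %d ch, decoder %d ch, head: %s, %d classes, input %d px\n"),
              x$backbone, paste(x$backbone_widths, collapse = "/"),
              x$output_stride, paste(x$aspp_rates, collapse = "/"),
              x$aspp_out_channels, x$lowlevel_channels, x$decoder_channels,
              if (x$upsampling_mode == "subpixel")
                sprintf("sub-pixel (2 stages, r=%d)", x$subpixel_r)
              else "bilinear 4x",
              x$num_classes, x$input_size))
  invisible(x)
}

# He-normal initialised conv weight kh x kw x inC_per_group x outC (+ zero bias)
.init_conv <- function(kh, kw, cin_g, cout, fan_groups = 1L) {
  fan_in <- kh * kw * cin_g
  w <- array(rnorm(kh * kw * cin_g * cout, 0, sqrt(2 / fan_in)),
             dim = c(kh, kw, cin_g, cout))
  list(w = w, b = numeric(cout))
}

#' Build a segmentation model
#'
#' Initialises all parameters (He-normal weights, zero biases) under the given
#' seed and returns an untrained model. No pretrained weights are used
#' anywhere; the network is designed to train from scratch.
#'
#' @param spec a [model_spec()].
#' @param seed integer seed for weight initialisation.
#' @return object of class `rootseg_model`: list with `spec`, `params` (named
#'   list of arrays), `seed`.
#' @export
build_model <- function(spec = model_spec(), seed = 1L) {
  if (!inherits(spec, "rootseg_spec")) stop("`spec` must come from model_spec()", call. = FALSE)
  w <- spec$backbone_widths
  params <- list()
  add <- function(name, kh, kw, cin_g, cout) {
    p <- .init_conv(kh, kw, cin_g, cout)
    params[[paste0(name, ".w")]] <<- p$w
    params[[paste0(name, ".b")]] <<- p$b
  }
  with_seed(seed, {
    # encoder: stem (dense conv) + 3 separable downsampling stages
    add("enc.stem", 3, 3, 3, w[1])                        # OS 2
    add("enc.b2.dw", 3, 3, 1, w[1]); add("enc.b2.pw", 1, 1, w[1], w[2])  # OS 4
    add("enc.b3.dw", 3, 3, 1, w[2]); add("enc.b3.pw", 1, 1, w[2], w[3])  # OS 8
    add("enc.b4.dw", 3, 3, 1, w[3]); add("enc.b4.pw", 1, 1, w[3], w[4])  # OS 16
    if (spec$backbone == "xception") {
      # extra non-strided separable block per stage
      add("enc.b2x.dw", 3, 3, 1, w[2]); add("enc.b2x.pw", 1, 1, w[2], w[2])
      add("enc.b3x.dw", 3, 3, 1, w[3]); add("enc.b3x.pw", 1, 1, w[3], w[3])
      add("enc.b4x.dw", 3, 3, 1, w[4]); add("enc.b4x.pw", 1, 1, w[4], w[4])
    }
    A <- spec$aspp_out_channels
    if (spec$aspp_1x1) add("aspp.b0", 1, 1, w[4], A)
    for (k in 1:3) {  # separable atrous branches
      add(sprintf("aspp.b%d.dw", k), 3, 3, 1, w[4])
      add(sprintf("aspp.b%d.pw", k), 1, 1, w[4], A)
    }
    if (spec$aspp_pool) add("aspp.pool", 1, 1, w[4], A)
    nb <- 3L + spec$aspp_1x1 + spec$aspp_pool
    add("aspp.proj", 1, 1, nb * A, A)
    add("dec.low", 1, 1, w[2], spec$lowlevel_channels)
    add("dec.fuse", 3, 3, A + spec$lowlevel_channels, spec$decoder_channels)
    D <- spec$decoder_channels
    if (spec$upsampling_mode == "subpixel") {
      r2 <- spec$subpixel_r^2
      add("head.sp1", 3, 3, D, D * r2)
      add("head.sp2", 3, 3, D, D * r2)
    }
    add("head.cls", 1, 1, D, spec$num_classes)
  })
  structure(list(spec = spec, params = params, seed = as.integer(seed)),
            class = "rootseg_model")
}

#' @export
print.rootseg_model <- function(x, ...) {
  cat(sprintf("rootseg_model: %s parameters in %d tensors (seed %d)\n",
              format(n_parameters(x), big.mark = ","),
              length(x$params), x$seed))
  print(x$spec)
  invisible(x)
}

#' Total (or per-component) parameter count
#'
#' @param model a `rootseg_model`.
#' @param by_component if `TRUE`, return a named vector of counts per
#'   component prefix (`enc`, `aspp`, `dec`, `head`).
#' @return integer count or named vector.
#' @export
n_parameters <- function(model, by_component = FALSE) {
  n <- vapply(model$params, length, integer(1))
  if (!by_component) return(sum(n))
  comp <- sub("\\..*$", "", names(n))
  tapply(n, comp, sum)
}

# Shared forward graph. `pn` is the named list of parameter ag-nodes; x is
# H x W x 3 in [0, 1]. Returns list(scores = node, encoder = plain array).
.forward_graph <- function(spec, pn, x) {
  sep <- function(node, name, stride = 1L, dilation = 1L) {
    cin <- dim(node$value)[3]
    h <- ag_conv(node, pn[[paste0(name, ".dw.w")]], pn[[paste0(name, ".dw.b")]],
                 stride = stride, dilation = dilation, groups = cin)
    h <- ag_relu(h)
    h <- ag_conv(h, pn[[paste0(name, ".pw.w")]], pn[[paste0(name, ".pw.b")]])
    ag_relu(h)
  }
  cv <- function(node, name, stride = 1L, dilation = 1L, act = TRUE) {
    h <- ag_conv(node, pn[[paste0(name, ".w")]], pn[[paste0(name, ".b")]],
                 stride = stride, dilation = dilation)
    if (act) ag_relu(h) else h
  }
  xin <- ag_leaf(x - 0.5)
  h <- cv(xin, "enc.stem", stride = 2L)            # OS 2
  h <- sep(h, "enc.b2", stride = 2L)               # OS 4
  if (spec$backbone == "xception") h <- sep(h, "enc.b2x")
  low <- h
  h <- sep(h, "enc.b3", stride = 2L)               # OS 8
  if (spec$backbone == "xception") h <- sep(h, "enc.b3x")
  h <- sep(h, "enc.b4", stride = 2L)               # OS 16
  if (spec$backbone == "xception") h <- sep(h, "enc.b4x")

  d16 <- dim(h$value)
  branches <- list()
  if (spec$aspp_1x1) branches <- c(branches, list(cv(h, "aspp.b0")))
  for (k in 1:3)
    branches <- c(branches, list(sep(h, sprintf("aspp.b%d", k),
                                     dilation = spec$aspp_rates[k])))
  if (spec$aspp_pool) {
    g <- ag_gap(h)
    g <- cv(g, "aspp.pool")
    branches <- c(branches, list(ag_broadcast(g, d16[1], d16[2])))
  }
  a <- ag_concat(branches)
  a <- cv(a, "aspp.proj")                          # 1x1 channel compression

  # decoder: 4x bilinear to OS 4, skip concat, 3x3 fusion
  d4 <- dim(low$value)
  u <- ag_bilinear(a, d4[1], d4[2])
  lo <- cv(low, "dec.low")
  f <- cv(ag_concat(list(u, lo)), "dec.fuse")

  # final 4x stage
  if (spec$upsampling_mode == "subpixel") {
    s <- cv(f, "head.sp1", act = FALSE)
    s <- ag_relu(ag_pixel_shuffle(s, spec$subpixel_r))
    s <- cv(s, "head.sp2", act = FALSE)
    s <- ag_relu(ag_pixel_shuffle(s, spec$subpixel_r))
  } else {
    df <- dim(f$value)
    s <- ag_bilinear(f, df[1] * 4L, df[2] * 4L)
  }
  scores <- cv(s, "head.cls", act = FALSE)
  list(scores = scores, encoder = h)
}

.check_input_dims <- function(spec, d) {
  if (d[1] %% spec$output_stride != 0L || d[2] %% spec$output_stride != 0L)
    stop(sprintf("input dims %d x %d not divisible by output stride %d",
                 d[1], d[2], spec$output_stride), call. = FALSE)
}

# Normalise an image tile (integer 0..255 or double) to [0, 1] H x W x 3.
.norm_tile <- function(x) {
  x <- .as3d(x)
  if (dim(x)[3] == 1L) x <- array(rep(x, 3L), dim = c(dim(x)[1:2], 3L))
  storage.mode(x) <- "double"
  if (max(x) > 1.5) x <- x / 255
  x
}

#' Run the network on one tile
#'
#' @param model a `rootseg_model`.
#' @param x image tile, H x W x 3 (integer 0–255 or double in \[0,1\]); H and
#'   W must be divisible by the output stride.
#' @return numeric array H x W x num_classes of per-pixel class scores
#'   (logits).
#' @export
forward_model <- function(model, x) {
  x <- .norm_tile(x)
  .check_input_dims(model$spec, dim(x))
  pn <- lapply(model$params, ag_leaf)
  .forward_graph(model$spec, pn, x)$scores$value
}

#' Encoder feature map for an input tile
#'
#' Exposes the output-stride-16 feature map, e.g. to verify the spatial
#' reduction contract (a 512 x 512 input yields a 32 x 32 map).
#'
#' @inheritParams forward_model
#' @return numeric array (H/16) x (W/16) x C.
#' @export
encoder_features <- function(model, x) {
  x <- .norm_tile(x)
  .check_input_dims(model$spec, dim(x))
  pn <- lapply(model$params, ag_leaf)
  .forward_graph(model$spec, pn, x)$encoder$value
}

#' Per-pixel class probabilities (softmax over the score channels)
#'
#' @inheritParams forward_model
#' @return array H x W x num_classes summing to 1 over classes at each pixel.
#' @export
forward_proba <- function(model, x) {
  sc <- forward_model(model, x)
  .softmax3 <- function(s) {
    m <- apply(s, c(1, 2), max)
    e <- exp(sweep(s, c(1, 2), m))
    sweep(e, c(1, 2), apply(e, c(1, 2), sum), "/")
  }
  .softmax3(sc)
}

#' Run the network over every tile of a grid
#'
#' @param model a `rootseg_model`.
#' @param grid a `tile_grid` of image tiles sized to the model input.
#' @return a `tile_grid` of score tiles (H x W x num_classes), same keys and
#'   order.
#' @export
forward_tiles <- function(model, grid) {
  if (!inherits(grid, "tile_grid")) stop("`grid` must be a tile_grid", call. = FALSE)
  out <- grid
  for (k in seq_along(grid$tiles)) {
    t <- grid$tiles[[k]]
    d <- dim(.as3d(t$data))
    if (d[1] != grid$tile_size || d[2] != grid$tile_size)
      stop("tile size mismatch with grid metadata", call. = FALSE)
    out$tiles[[k]]$data <- forward_model(model, t$data)
  }
  out
}

#' Segment a full-size image
#'
#' The end-to-end inference path: zero-pad to a tile multiple, split into
#' tiles, run the network on each, stitch the score maps (averaging overlaps),
#' crop to the original dims, and take the per-pixel argmax.
#'
#' @param object a `rootseg_model`.
#' @param image H x W x 3 image (any size), or a file path readable by
#'   [read_raster()].
#' @param stride tile stride; defaults to the tile size (non-overlapping).
#' @param type `"mask"` (0/1 integer matrix) or `"scores"` (stitched logits).
#' @param ... unused.
#' @return mask matrix or score array at the original image dims.
#' @export
predict.rootseg_model <- function(object, image, stride = NULL, type = c("mask", "scores"), ...) {
  type <- match.arg(type)
  if (is.character(image)) image <- read_raster(image)
  ts <- object$spec$input_size
  if (is.null(stride)) stride <- ts
  img <- .norm_tile(image)
  orig <- dim(img)[1:2]
  pad <- pad_to_multiple(img, ts)
  grid <- split_tiles(pad$image, tile_size = ts, stride = stride, orig_dim = orig)
  scores <- stitch_tiles(forward_tiles(object, grid))
  if (type == "scores") return(scores)
  .scores_to_mask(scores)
}

.scores_to_mask <- function(scores) {
  # argmax over classes; class 2 (index 2) is root
  matrix(as.integer(scores[, , 2] > scores[, , 1]), nrow = dim(scores)[1])
}

#' Save / load a model checkpoint
#'
#' Checkpoints are single-file serialised parameter sets with the embedded
#' spec and a format version tag.
#'
#' @param model a `rootseg_model` (or `rootseg_fit`, whose final model is
#'   saved).
#' @param path checkpoint file path.
#' @return `path` invisibly (`save_model`); the model (`load_model`).
#' @export
save_model <- function(model, path) {
  if (inherits(model, "rootseg_fit")) model <- model$model
  obj <- list(format = "rootseg-ckpt-1", spec = model$spec,
              params = model$params, seed = model$seed)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e)
    stop(sprintf("cannot read checkpoint '%s': %s", path, conditionMessage(e)),
         call. = FALSE))
  if (!identical(obj$format, "rootseg-ckpt-1"))
    stop(sprintf("'%s' is not a rootseg checkpoint", path), call. = FALSE)
  structure(list(spec = obj$spec, params = obj$params, seed = obj$seed),
            class = "rootseg_model")
}
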