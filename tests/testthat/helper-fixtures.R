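# Shared fixtures. Everything is generated in code; model/tile sizes are kept
# small so the whole suite trains real networks within a CPU test budget.

# A deliberately tiny architecture for shape/contract tests.
tiny_spec <- function(head = "subpixel", input_size = 64L) {
  model_spec(input_size = input_size,
             backbone_widths = c(6L, 8L, 12L, 16L),
             aspp_out_channels = 16L, lowlevel_channels = 8L,
             decoder_channels = 12L, upsampling_mode = head)
}

# The capacity used for learning tests (needs headroom to actually fit).
desk_spec <- function(head = "subpixel", input_size = 96L) {
  model_spec(input_size = input_size,
             backbone_widths = c(12L, 16L, 24L, 32L),
             aspp_out_channels = 32L, lowlevel_channels = 16L,
             decoder_channels = 24L, upsampling_mode = head)
}

# Scaled-down "easy" world: default high-contrast appearance on a 96 px
# canvas, root count scaled so coverage matches the 512-canvas default.
smoke_scenes <- function(n, seed0 = 100L) {
  lapply(seq_len(n), function(i)
    generate_scene(scene_params(canvas_height = 96L, canvas_width = 96L,
                                n_roots = 2L, contrast_regime = "high",
                                seed = seed0 + i)))
}

# Thin-structure benchmark world: fine roots of 1-3 px with heavy branching.
thin_scenes <- function(n, seed0) {
  lapply(seq_len(n), function(i)
    generate_scene(scene_params(canvas_height = 64L, canvas_width = 64L,
                                n_roots = 3L, main_width_range = c(2, 4),
                                fine_width_range = c(1, 3),
                                branch_probability = 0.5,
                                contrast_regime = "high", seed = seed0 + i)))
}

# Scalar two-stage interpolation oracle (corner-aligned), evaluated per pixel.
bilinear_oracle <- function(x, factor) {
  H <- dim(x)[1]; W <- dim(x)[2]; C <- dim(x)[3]
  oh <- H * factor; ow <- W * factor
  out <- array(0, c(oh, ow, C))
  for (c in seq_len(C)) for (oy in seq_len(oh)) for (ox in seq_len(ow)) {
    fy <- if (oh > 1 && H > 1) (oy - 1) * (H - 1) / (oh - 1) else 0
    fx <- if (ow > 1 && W > 1) (ox - 1) * (W - 1) / (ow - 1) else 0
    y1 <- floor(fy); y2 <- min(y1 + 1, H - 1)
    x1 <- floor(fx); x2 <- min(x1 + 1, W - 1)
    q11 <- x[y1 + 1, x1 + 1, c]; q21 <- x[y1 + 1, x2 + 1, c]
    q12 <- x[y2 + 1, x1 + 1, c]; q22 <- x[y2 + 1, x2 + 1, c]
    tx <- if (x2 > x1) fx - x1 else 0
    fr1 <- (1 - tx) * q11 + tx * q21   # f(R1), interpolate along x at y1
    fr2 <- (1 - tx) * q12 + tx * q22   # f(R2), along x at y2
    ty <- if (y2 > y1) fy - y1 else 0
    out[oy, ox, c] <- (1 - ty) * fr1 + ty * fr2  # f(P), along y
  }
  out
}

# Explicit index-map oracle for the periodic shuffle.
pixel_shuffle_oracle <- function(x, r) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3] / (r * r)
  out <- array(0, c(H * r, W * r, C))
  for (c0 in seq_len(C) - 1) for (y in seq_len(H * r) - 1) for (x2 in seq_len(W * r) - 1)
    out[y + 1, x2 + 1, c0 + 1] <-
      x[y %/% r + 1, x2 %/% r + 1, c0 * r * r + (y %% r) * r + (x2 %% r) + 1]
  out
}

# Brute-force per-pixel cross-entropy oracle.
ce_oracle <- function(scores, mask, weights = NULL) {
  K <- dim(scores)[3]
  if (is.null(weights)) weights <- rep(1, K)
  tot <- 0; wsum <- 0
  for (i in seq_len(nrow(mask))) for (j in seq_len(ncol(mask))) {
    s <- scores[i, j, ]
    p <- exp(s - max(s)); p <- p / sum(p)
    k <- mask[i, j] + 1
    tot <- tot + weights[k] * (-log(p[k]))
    wsum <- wsum + weights[k]
  }
  tot / wsum
}

random_counts <- function() {
  as_confusion(c(TP = sample(0:500, 1), FP = sample(0:200, 1),
                 FN = sample(0:200, 1), TN = sample(0:5000, 1)))
}
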