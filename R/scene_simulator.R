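# Synthetic minirhizotron scenes. The generator stands in for field scans,
# which are rarely redistributable: curvilinear roots of tapering width on a
# textured brown soil background, with the two documented failure sources as distractors —
# bright stone/highlight ellipses (false-positive bait) and low-contrast brown
# strokes (false-negative bait) — neither of which enters the ground-truth
# mask. Everything is driven by one integer seed; identical parameters give
# bit-identical scenes.

#' Parameters of a synthetic root scene
#'
#' Defaults describe the "desk" canvas: one 512 x 512 network input with a
#' handful of main roots plus fine laterals, soil at mean grey 90 with
#' mixed-frequency texture, and a realistic sprinkle of bright stones. The
#' `contrast_regime` chooses the root tint band: `"high"` renders roots well
#' above the soil intensity (easy to separate), `"low"` compresses the
#' root-vs-soil gap to emulate washed-out brown roots.
#'
#' @param canvas_height,canvas_width canvas dims in pixels (>= 64).
#' @param n_roots number of main root trajectories.
#' @param main_width_range min/max starting width (px) of main roots.
#' @param fine_width_range min/max width (px) of lateral branches.
#' @param branch_probability probability of spawning a lateral at each anchor
#'   point (every ~14 path steps).
#' @param root_intensity_range min/max 8-bit root intensity; `NULL` picks the
#'   regime default (high: 170–240, low: 105–140).
#' @param soil_mean mean 8-bit soil intensity.
#' @param soil_noise_sd SD of the soil texture (applied at two spatial
#'   frequencies).
#' @param stone_density expected bright stones per megapixel.
#' @param stone_intensity_range min/max 8-bit stone intensity.
#' @param n_distractors number of low-contrast brown strokes drawn into the
#'   image but *not* the mask (false-negative bait).
#' @param contrast_regime `"high"` or `"low"`.
#' @param seed integer; fully determines the scene.
#' @return object of class `scene_params`.
#' @export
scene_params <- function(canvas_height = 512L, canvas_width = 512L,
                         n_roots = 5L,
                         main_width_range = c(5, 12),
                         fine_width_range = c(1, 3),
                         branch_probability = 0.25,
                         root_intensity_range = NULL,
                         soil_mean = 90,
                         soil_noise_sd = 12,
                         stone_density = 8,
                         stone_intensity_range = c(200, 255),
                         n_distractors = 2L,
                         contrast_regime = c("high", "low"),
                         seed = 1L) {
  contrast_regime <- match.arg(contrast_regime)
  if (is.null(root_intensity_range))
    root_intensity_range <- if (contrast_regime == "high") c(170, 240) else c(105, 140)
  p <- list(canvas_height = as.integer(canvas_height),
            canvas_width = as.integer(canvas_width),
            n_roots = as.integer(n_roots),
            main_width_range = as.numeric(main_width_range),
            fine_width_range = as.numeric(fine_width_range),
            branch_probability = as.numeric(branch_probability),
            root_intensity_range = as.numeric(root_intensity_range),
            soil_mean = as.numeric(soil_mean),
            soil_noise_sd = as.numeric(soil_noise_sd),
            stone_density = as.numeric(stone_density),
            stone_intensity_range = as.numeric(stone_intensity_range),
            n_distractors = as.integer(n_distractors),
            contrast_regime = contrast_regime,
            seed = as.integer(seed))
  class(p) <- "scene_params"
  validate_scene_params(p)
  p
}

validate_scene_params <- function(p) {
  chk_range <- function(r, nm) {
    if (length(r) != 2L || any(!is.finite(r)) || r[1] > r[2])
      stop(sprintf("invalid `%s`: need finite (min, max) with min <= max", nm),
           call. = FALSE)
  }
  if (is.na(p$canvas_height) || p$canvas_height < 64L)
    stop("invalid `canvas_height`: must be >= 64", call. = FALSE)
  if (is.na(p$canvas_width) || p$canvas_width < 64L)
    stop("invalid `canvas_width`: must be >= 64", call. = FALSE)
  if (is.na(p$n_roots) || p$n_roots < 0L)
    stop("invalid `n_roots`: must be >= 0", call. = FALSE)
  chk_range(p$main_width_range, "main_width_range")
  chk_range(p$fine_width_range, "fine_width_range")
  chk_range(p$root_intensity_range, "root_intensity_range")
  chk_range(p$stone_intensity_range, "stone_intensity_range")
  if (p$branch_probability < 0 || p$branch_probability > 1)
    stop("invalid `branch_probability`: must be in [0, 1]", call. = FALSE)
  if (p$soil_noise_sd < 0) stop("invalid `soil_noise_sd`: must be >= 0", call. = FALSE)
  if (p$stone_density < 0) stop("invalid `stone_density`: must be >= 0", call. = FALSE)
  if (p$n_distractors < 0L) stop("invalid `n_distractors`: must be >= 0", call. = FALSE)
  if (is.na(p$seed)) stop("invalid `seed`", call. = FALSE)
  invisible(p)
}

# Run code under a private RNG stream, restoring the caller's state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# Disc offsets within integer radius r of the origin (cached).
.disc_cache <- new.env(parent = emptyenv())
.disc_offsets <- function(r) {
  key <- as.character(r)
  if (!is.null(.disc_cache[[key]])) return(.disc_cache[[key]])
  s <- seq(-r, r)
  g <- expand.grid(dy = s, dx = s)
  g <- g[g$dy^2 + g$dx^2 <= r^2 + 0.25, ]
  .disc_cache[[key]] <- g
  g
}

# Draw one smoothed-random-walk stroke with linear width taper.
# Covered pixels are accumulated as linear indices and stamped once.
# Returns list(mask = logical matrix of covered pixels, length = centreline
# length in px, anchors = list of candidate branch points).
.draw_stroke <- function(h, w, y0, x0, heading, w_start, w_end, max_steps,
                         step = 1.5, wobble = 0.14) {
  y <- y0; x <- x0
  len <- 0
  anchors <- list()
  n <- max(2L, as.integer(max_steps))
  idx <- vector("list", n)
  for (i in seq_len(n)) {
    frac <- (i - 1) / (n - 1)
    wid <- w_start + (w_end - w_start) * frac
    off <- .disc_offsets(max(0L, as.integer(round(wid / 2))))
    yy <- as.integer(round(y)) + off$dy
    xx <- as.integer(round(x)) + off$dx
    ok <- yy >= 1L & yy <= h & xx >= 1L & xx <= w
    idx[[i]] <- yy[ok] + h * (xx[ok] - 1L)
    heading <- heading + rnorm(1, 0, wobble)
    y2 <- y + step * sin(heading)
    x2 <- x + step * cos(heading)
    inside <- y2 >= 1 && y2 <= h && x2 >= 1 && x2 <= w
    if (!inside) break
    len <- len + step
    y <- y2; x <- x2
    if (i %% 14L == 0L)
      anchors[[length(anchors) + 1L]] <-
        list(y = y, x = x, heading = heading, frac = frac)
  }
  m <- matrix(FALSE, h, w)
  m[unique(unlist(idx))] <- TRUE
  list(mask = m, length = len, anchors = anchors)
}

# Filled rotated ellipse as a logical matrix stamp.
.draw_ellipse <- function(h, w, cy, cx, a, b, theta) {
  r <- ceiling(max(a, b))
  ys <- max(1, floor(cy - r)):min(h, ceiling(cy + r))
  xs <- max(1, floor(cx - r)):min(w, ceiling(cx + r))
  if (!length(ys) || !length(xs)) return(NULL)
  g <- expand.grid(y = ys, x = xs)
  dy <- g$y - cy; dx <- g$x - cx
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  g[(u / a)^2 + (v / b)^2 <= 1, ]
}

#' Generate one synthetic root scene
#'
#' Draws `n_roots` smoothed random-walk trajectories with linearly tapering
#' width (optionally branching into fine laterals), renders them in a
#' brown-to-white tint band over a textured soil background, adds bright
#' elliptical stones and low-contrast distractor strokes to the image only,
#' and returns the exact pixel mask of the drawn roots.
#'
#' @param params a [scene_params()] object.
#' @return object of class `scene`: list with `image` (integer H x W x 3,
#'   0–255), `mask` (integer 0/1 matrix), `params`, `root_pixel_fraction`, and
#'   `extras` (`stone_mask`, `distractor_mask` logical matrices and
#'   `centerline_length`, the analytic length in px of all drawn root
#'   centrelines).
#' @export
generate_scene <- function(params) {
  if (!inherits(params, "scene_params")) stop("`params` must come from scene_params()", call. = FALSE)
  validate_scene_params(params)
  with_seed(params$seed, .generate_scene_impl(params))
}

.generate_scene_impl <- function(p) {
  h <- p$canvas_height; w <- p$canvas_width
  mask <- matrix(FALSE, h, w)
  total_len <- 0

  # --- root strokes ---------------------------------------------------------
  for (i in seq_len(p$n_roots)) {
    edge <- sample.int(4L, 1L)  # 1 top, 2 right, 3 bottom, 4 left
    if (edge == 1L) { y0 <- 1; x0 <- runif(1, 1, w); heading <- pi / 2 }
    else if (edge == 2L) { y0 <- runif(1, 1, h); x0 <- w; heading <- pi }
    else if (edge == 3L) { y0 <- h; x0 <- runif(1, 1, w); heading <- -pi / 2 }
    else { y0 <- runif(1, 1, h); x0 <- 1; heading <- 0 }
    heading <- heading + rnorm(1, 0, 0.3)
    w0 <- runif(1, p$main_width_range[1], p$main_width_range[2])
    st <- .draw_stroke(h, w, y0, x0, heading, w0, pmax(1, 0.3 * w0),
                       max_steps = 0.7 * (h + w))
    mask <- mask | st$mask
    total_len <- total_len + st$length
    for (a in st$anchors) {
      if (runif(1) < p$branch_probability) {
        bw <- runif(1, p$fine_width_range[1], p$fine_width_range[2])
        bh <- a$heading + sample(c(-1, 1), 1) * runif(1, 0.5, 1.2)
        br <- .draw_stroke(h, w, a$y, a$x, bh, bw, pmax(0.8, 0.5 * bw),
                           max_steps = 0.25 * (h + w) * (1 - a$frac) + 10)
        mask <- mask | br$mask
        total_len <- total_len + br$length
      }
    }
  }

  # --- soil background ------------------------------------------------------
  # two-frequency texture: a coarse field upsampled bilinearly plus fine grain
  ch <- max(2L, ceiling(h / 32)); cw <- max(2L, ceiling(w / 32))
  coarse <- matrix(rnorm(ch * cw, 0, 1.6 * p$soil_noise_sd), ch, cw)
  lowfreq <- .bilinear_resize_fwd(array(coarse, c(ch, cw, 1L)), h, w)[, , 1]
  base <- p$soil_mean + lowfreq + matrix(rnorm(h * w, 0, p$soil_noise_sd), h, w)
  img <- array(0, dim = c(h, w, 3L))
  img[, , 1] <- base * 1.10   # brown tint
  img[, , 2] <- base * 0.95
  img[, , 3] <- base * 0.75

  # --- distractor strokes (image only; false-negative bait) -----------------
  distractor <- matrix(FALSE, h, w)
  for (i in seq_len(p$n_distractors)) {
    y0 <- runif(1, 1, h); x0 <- runif(1, 1, w)
    dw <- runif(1, p$fine_width_range[1], p$main_width_range[2] * 0.6)
    st <- .draw_stroke(h, w, y0, x0, runif(1, 0, 2 * pi), dw, pmax(0.8, 0.4 * dw),
                       max_steps = 0.2 * (h + w))
    distractor <- distractor | st$mask
  }
  didx <- which(distractor)
  if (length(didx)) {
    # a shade brighter than soil but well below the root band
    lvl <- p$soil_mean + 0.35 * (mean(p$root_intensity_range) - p$soil_mean)
    jit <- rnorm(length(didx), 0, 3)
    img[didx] <- lvl * 1.08 + jit
    img[didx + h * w] <- lvl * 0.92 + jit
    img[didx + 2 * h * w] <- lvl * 0.68 + jit
  }

  # --- roots ----------------------------------------------------------------
  ridx <- which(mask)
  if (length(ridx)) {
    inten <- runif(1, p$root_intensity_range[1], p$root_intensity_range[2]) +
      rnorm(length(ridx), 0, 4)
    # brown-to-white tint: whiter as intensity approaches 255
    tfrac <- pmin(pmax(inten / 255, 0), 1)
    tint_r <- 1.05 - 0.05 * tfrac
    tint_g <- 0.88 + 0.12 * tfrac
    tint_b <- 0.70 + 0.30 * tfrac
    img[ridx] <- inten * tint_r
    img[ridx + h * w] <- inten * tint_g
    img[ridx + 2 * h * w] <- inten * tint_b
  }

  # --- stones (image only; false-positive bait) -----------------------------
  stone <- matrix(FALSE, h, w)
  n_stones <- rpois(1, p$stone_density * h * w / 1e6)
  for (i in seq_len(n_stones)) {
    px <- .draw_ellipse(h, w, runif(1, 1, h), runif(1, 1, w),
                        a = runif(1, 3, 14), b = runif(1, 2, 9),
                        theta = runif(1, 0, pi))
    if (is.null(px) || !nrow(px)) next
    keep <- !mask[cbind(px$y, px$x)]  # roots occlude stones
    px <- px[keep, ]
    if (!nrow(px)) next
    stone[cbind(px$y, px$x)] <- TRUE
    si <- runif(1, p$stone_intensity_range[1], p$stone_intensity_range[2]) +
      rnorm(nrow(px), 0, 5)
    ii <- (px$x - 1L) * h + px$y
    img[ii] <- si
    img[ii + h * w] <- si * 0.97
    img[ii + 2 * h * w] <- si * 0.90
  }

  img <- array(as.integer(pmin(pmax(round(img), 0), 255)), dim = dim(img))
  mask_int <- matrix(as.integer(mask), h, w)
  structure(list(image = img, mask = mask_int, params = p,
                 root_pixel_fraction = mean(mask_int),
                 extras = list(stone_mask = stone, distractor_mask = distractor,
                               centerline_length = total_len)),
            class = "scene")
}

#' @export
print.scene <- function(x, ...) {
  cat(sprintf("scene: %d x %d, %d root(s), %.2f%% root pixels, %s contrast, seed %d\n",
              nrow(x$mask), ncol(x$mask), x$params$n_roots,
              100 * x$root_pixel_fraction, x$params$contrast_regime,
              x$params$seed))
  invisible(x)
}

#' Generate a dataset of scenes on disk
#'
#' Writes `n_scenes` image/mask pairs (seed varied deterministically as
#' `seed + i - 1`) plus a CSV manifest with per-scene root pixel fractions.
#' Regenerating with the same parameters yields identical files.
#'
#' @param params a [scene_params()] object; `params$seed` seeds scene 1.
#' @param n_scenes number of scenes (>= 1).
#' @param out_dir output directory (created if needed).
#' @return data.frame manifest with columns `image_path`, `mask_path`, `seed`,
#'   `root_pixel_fraction`, also written to `manifest.csv` in `out_dir`.
#' @export
generate_dataset <- function(params, n_scenes, out_dir) {
  if (!inherits(params, "scene_params")) stop("`params` must come from scene_params()", call. = FALSE)
  if (n_scenes < 1) stop("`n_scenes` must be >= 1", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop(sprintf("cannot create '%s'", out_dir), call. = FALSE)
  rows <- vector("list", n_scenes)
  for (i in seq_len(n_scenes)) {
    p <- params
    p$seed <- params$seed + i - 1L
    sc <- generate_scene(p)
    ip <- file.path(out_dir, sprintf("scene_%04d.ppm", i))
    mp <- file.path(out_dir, sprintf("scene_%04d_mask.pgm", i))
    write_raster(sc$image, ip)
    write_mask(sc$mask, mp)
    rows[[i]] <- data.frame(image_path = ip, mask_path = mp, seed = p$seed,
                            root_pixel_fraction = sc$root_pixel_fraction,
                            stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  manifest
}
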