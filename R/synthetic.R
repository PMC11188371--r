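#' Sample growth-stage dependent rosette parameters
#'
#' Maps a growth stage in `[0, 1]` (transplant to harvest) to the geometry of
#' a synthetic rosette. Radius and leaf count grow deterministically and
#' monotonically with stage; leaf shape, orientation jitter and hue are drawn
#' from the current RNG stream, so a fixed seed reproduces identical
#' parameters.
#'
#' @param stage growth stage in `[0, 1]`
#' @param seed optional integer; when given, draws are made under this seed
#'   without disturbing the caller's RNG stream
#' @param config list of generator bounds: `radius_range` (px),
#'   `leaf_count_range`, `leaf_aspect_range`, `angle_jitter_max` (radians),
#'   `hue_range` (degrees)
#' @return an object of class `fw_plant_params`
#' @export
sample_plant_params <- function(stage, seed = NULL, config = synth_config()) {
  if (!is.numeric(stage) || length(stage) != 1 || is.na(stage) ||
      stage < 0 || stage > 1)
    fw_domain_error("stage must be a single value in [0, 1]")
  with_seed(seed, {
    r <- config$radius_range
    lc <- config$leaf_count_range
    structure(list(
      leaf_count = as.integer(round(lc[1] + stage * (lc[2] - lc[1]))),
      rosette_radius_px = r[1] + stage * (r[2] - r[1]),
      leaf_aspect = runif(1, config$leaf_aspect_range[1], config$leaf_aspect_range[2]),
      leaf_angle_jitter = runif(1, 0, config$angle_jitter_max),
      hue_center = runif(1, config$hue_range[1], config$hue_range[2]),
      density = max(-2, min(2, rnorm(1))),
      stage = stage
    ), class = "fw_plant_params")
  })
}

#' Default synthetic-generator configuration
#'
#' Bounds for the rosette generator: radii span a freshly transplanted
#' seedling (~28 px at the 820x616 working resolution, i.e. ~45 mm diameter
#' at 0.8 mm/px) to a harvest-ready head (~170 px, ~270 mm diameter).
#'
#' @param radius_range rosette radius at stage 0 and 1, pixels
#' @param leaf_count_range leaf count at stage 0 and 1
#' @param leaf_aspect_range width/length ratio range of individual leaves
#' @param angle_jitter_max maximum angular jitter of leaf placement, radians
#' @param hue_range leaf hue range, degrees (green is ~120)
#' @param canvas_h,canvas_w canvas size in pixels (the working resolution)
#' @param distractor_intensity 0 disables pot-rim/bed distractors; 1 is full
#' @export
synth_config <- function(radius_range = c(28, 170),
                         leaf_count_range = c(5, 14),
                         leaf_aspect_range = c(0.35, 0.5),
                         angle_jitter_max = 0.25,
                         hue_range = c(100, 130),
                         canvas_h = 616, canvas_w = 820,
                         distractor_intensity = 0.5) {
  list(radius_range = radius_range, leaf_count_range = leaf_count_range,
       leaf_aspect_range = leaf_aspect_range, angle_jitter_max = angle_jitter_max,
       hue_range = hue_range, canvas_h = canvas_h, canvas_w = canvas_w,
       distractor_intensity = distractor_intensity)
}

#' @export
print.fw_plant_params <- function(x, ...) {
  cat(sprintf("Rosette params: %d leaves, radius %.1f px, aspect %.2f, stage %.2f\n",
              x$leaf_count, x$rosette_radius_px, x$leaf_aspect, x$stage))
  invisible(x)
}

# numeric hsv -> rgb (h in degrees, s,v in [0,1]); returns length-3 vector
hsv_to_rgb <- function(h, s, v) {
  h <- (h %% 360) / 60
  i <- floor(h); f <- h - i
  p <- v * (1 - s); q <- v * (1 - s * f); t <- v * (1 - s * (1 - f))
  switch(as.character(i %% 6),
         "0" = c(v, t, p), "1" = c(q, v, p), "2" = c(p, v, t),
         "3" = c(p, q, v), "4" = c(t, p, v), "5" = c(v, p, q))
}

# paint one rotated ellipse into mask/image layers; returns updated pixels
ellipse_pixels <- function(h, w, cx, cy, a, b, theta) {
  # bounding box of the rotated ellipse
  ux <- sqrt((a * cos(theta))^2 + (b * sin(theta))^2)
  uy <- sqrt((a * sin(theta))^2 + (b * cos(theta))^2)
  xs <- max(1, floor(cx - ux)):min(w, ceiling(cx + ux))
  ys <- max(1, floor(cy - uy)):min(h, ceiling(cy + uy))
  if (!length(xs) || !length(ys)) return(NULL)
  dx <- outer(rep(1, length(ys)), xs - cx)
  dy <- outer(ys - cy, rep(1, length(xs)))
  u <- (dx * cos(theta) + dy * sin(theta)) / a
  v <- (-dx * sin(theta) + dy * cos(theta)) / b
  inside <- u * u + v * v <= 1
  if (!any(inside)) return(NULL)
  idx <- which(inside, arr.ind = TRUE)
  cbind(y = ys[idx[, 1]], x = xs[idx[, 2]],
        radial = sqrt(dx[inside]^2 + dy[inside]^2))
}

#' Render a synthetic top-view rosette image with its ground-truth mask
#'
#' Draws a single green rosette on a dark hydroponic-bed background:
#' overlapping leaf ellipses radiating from a common centre, a brighter core,
#' per-pixel sensor noise, and (optionally) a grey pot rim plus bed texture
#' that a segmenter must reject. The truth mask is the union of the leaf
#' ellipses and is a single connected component by construction.
#'
#' @param params an `fw_plant_params` from [sample_plant_params()]
#' @param canvas_h,canvas_w canvas size in pixels
#' @param distractor_intensity 0--1; strength of pot-rim/bed-texture clutter
#' @param seed optional integer seed for reproducible rendering
#' @return list with `image` (canvas_h x canvas_w x 3 array in `[0,1]`) and
#'   `truth_mask` (logical matrix of the same height/width)
#' @export
render_plant <- function(params, canvas_h = 616, canvas_w = 820,
                         distractor_intensity = 0.5, seed = NULL) {
  if (!inherits(params, "fw_plant_params")) fw_domain_error("params must be fw_plant_params")
  r <- params$rosette_radius_px
  if (2 * r > min(canvas_h, canvas_w) - 20)
    fw_config_error("rosette (radius %.0f px) too large for %dx%d canvas",
                    r, canvas_h, canvas_w)
  with_seed(seed, {
    h <- canvas_h; w <- canvas_w
    # background: dark bed with mild texture
    img <- array(0, dim = c(h, w, 3))
    base <- c(0.16, 0.13, 0.11)
    noise <- matrix(rnorm(h * w, 0, 0.015), h, w)
    stripe <- 0.012 * sin(outer(seq_len(h), rep(1, w)) / 17) *
      distractor_intensity
    for (ch in 1:3) img[, , ch] <- pmin(pmax(base[ch] + noise + stripe, 0), 1)

    cx <- w / 2 + runif(1, -15, 15)
    cy <- h / 2 + runif(1, -15, 15)

    if (distractor_intensity > 0) {
      # grey pot rim: annulus around the plant
      rim <- ellipse_pixels(h, w, cx, cy, 1.35 * r + 8, 1.35 * r + 8, 0)
      if (!is.null(rim)) {
        keep <- rim[, "radial"] >= 1.35 * r
        rim <- rim[keep, , drop = FALSE]
        rim_col <- c(0.33, 0.31, 0.29) * distractor_intensity +
          base * (1 - distractor_intensity)
        for (ch in 1:3) img[cbind(rim[, 1], rim[, 2], ch)] <- rim_col[ch]
      }
      # dark bed holes on a lattice (other planting positions)
      for (hx in seq(80, w - 40, by = 200)) for (hy in seq(60, h - 40, by = 200)) {
        if (sqrt((hx - cx)^2 + (hy - cy)^2) < 1.7 * r + 30) next
        hole <- ellipse_pixels(h, w, hx, hy, 22, 22, 0)
        if (!is.null(hole))
          for (ch in 1:3) img[cbind(hole[, 1], hole[, 2], ch)] <-
            base[ch] * 0.4 * distractor_intensity +
            img[cbind(hole[, 1], hole[, 2], ch)] * (1 - distractor_intensity)
      }
    }

    mask <- matrix(FALSE, h, w)
    bright <- 1 + 0.18 * tanh(params$density %||% 0)
    k <- params$leaf_count
    angles <- 2 * pi * seq_len(k) / k +
      rnorm(k, 0, params$leaf_angle_jitter)
    lengths <- r * ifelse(seq_len(k) %% 2 == 0, runif(k, 0.85, 1), runif(k, 0.6, 0.8))
    # draw longer (outer) leaves first so inner leaves overlap them
    for (i in order(lengths, decreasing = TRUE)) {
      len <- lengths[i]; th <- angles[i]
      a <- len / 2
      b <- max(2, len * params$leaf_aspect / 2)
      lcx <- cx + a * cos(th); lcy <- cy + a * sin(th)
      px <- ellipse_pixels(h, w, lcx, lcy, a, b, th)
      if (is.null(px)) next
      mask[px[, 1:2, drop = FALSE]] <- TRUE
      hue <- params$hue_center + rnorm(1, 0, 5)
      sat <- runif(1, 0.55, 0.75)
      # darker toward the tip; denser plants render brighter overall
      val <- bright * (0.52 - 0.22 * (px[, "radial"] / max(px[, "radial"], 1)))
      colbase <- hsv_to_rgb(hue, sat, 1)
      pn <- rnorm(nrow(px), 0, 0.02)
      for (ch in 1:3) img[cbind(px[, 1], px[, 2], ch)] <-
        pmin(pmax(colbase[ch] * (val + pn), 0), 1)
    }
    # bright core disk ties all leaves into one component
    core <- ellipse_pixels(h, w, cx, cy, max(3, 0.15 * r), max(3, 0.15 * r), 0)
    if (!is.null(core)) {
      mask[core[, 1:2, drop = FALSE]] <- TRUE
      cb <- hsv_to_rgb(params$hue_center - 8, 0.45, 1)
      for (ch in 1:3) img[cbind(core[, 1], core[, 2], ch)] <-
        pmin(pmax(cb[ch] * 0.55 * bright + rnorm(nrow(core), 0, 0.02), 0), 1)
    }
    list(image = img, truth_mask = mask)
  })
}

#' Generate a labelled synthetic dataset
#'
#' Produces `n` top-view rosette images with ground-truth masks, assigns each
#' a fresh weight through the allometric law applied to the truth-mask area,
#' and records truth morphometrics (area, perimeter, ellipse axes, measured
#' on the truth mask) in a manifest. Stages are drawn uniformly on `[0, 1]`,
#' emulating a corpus collected evenly from transplant to harvest. With a
#' fixed seed the whole dataset (images, masks, manifest) is bit-identical
#' across runs.
#'
#' @param n number of samples (>= 1)
#' @param law an [allometric_law()]
#' @param seed integer seed controlling all randomness
#' @param out_dir optional directory; when given, writes `images/*.png`,
#'   `masks/*.png` and `manifest.csv` there
#' @param config generator bounds, see [synth_config()]
#' @return invisibly, a list with `manifest` (data.frame) and `samples`
#'   (list of `image`/`truth_mask` pairs; dropped when `out_dir` is given)
#' @export
generate_dataset <- function(n, law = allometric_law(), seed = 1,
                             out_dir = NULL, config = synth_config()) {
  if (!is.numeric(n) || n < 1) fw_domain_error("n must be >= 1")
  n <- as.integer(n)
  keep <- is.null(out_dir)
  if (!is.null(out_dir)) {
    dir.create(file.path(out_dir, "images"), recursive = TRUE, showWarnings = FALSE)
    dir.create(file.path(out_dir, "masks"), recursive = TRUE, showWarnings = FALSE)
    if (!dir.exists(out_dir)) fw_stop("fw_io_error", "cannot create %s", out_dir)
  }
  samples <- if (keep) vector("list", n)
  rows <- vector("list", n)
  with_seed(seed, {
    stages <- runif(n)
    for (i in seq_len(n)) {
      id <- sprintf("sample_%04d", i)
      params <- sample_plant_params(stages[i], config = config)
      sc <- render_plant(params, config$canvas_h, config$canvas_w,
                         config$distractor_intensity)
      feats <- extract_features(sc$truth_mask)
      lob <- feats[["perimeter_px"]] / (2 * sqrt(pi * feats[["area_px"]]))
      wt <- allometric_weight(feats[["area_px"]], law,
                              density = params$density, lobedness = lob)
      rows[[i]] <- data.frame(sample_id = id, weight_g = wt, stage = stages[i],
                              area_px = feats[["area_px"]],
                              perimeter_px = feats[["perimeter_px"]],
                              major_px = feats[["major_px"]],
                              minor_px = feats[["minor_px"]])
      if (keep) {
        samples[[i]] <- list(sample_id = id, image = sc$image,
                             truth_mask = sc$truth_mask, weight_g = wt,
                             stage = stages[i])
      } else {
        png::writePNG(sc$image, file.path(out_dir, "images", paste0(id, ".png")))
        png::writePNG(sc$truth_mask * 1, file.path(out_dir, "masks",
                                                   paste0(id, "_mask.png")))
      }
    }
  })
  manifest <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  }
  invisible(list(manifest = manifest, samples = if (keep) samples))
}
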