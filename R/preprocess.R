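# conversions between row-major (y, x) arrays and EBImage's (x, y) layout
to_ebi <- function(mat) EBImage::Image(t(mat))
from_ebi <- function(img) t(EBImage::imageData(img))

#' Resize an RGB image to the working resolution
#'
#' All downstream stages operate at 820 (wide) x 616 (high), a 4:1 downscale
#' of an 8-megapixel 3280 x 2464 capture. Portrait inputs are transposed to
#' landscape first. Integer-factor downscales use exact block (area)
#' averaging; other scale changes use bilinear resampling.
#'
#' @param image numeric array h x w x 3 with values in `[0, 1]`
#' @param target_h,target_w working resolution (height, width)
#' @return array `target_h x target_w x 3`
#' @export
resize_to_standard <- function(image, target_h = 616, target_w = 820) {
  if (length(dim(image)) != 3 || dim(image)[3] != 3 || any(dim(image)[1:2] == 0))
    fw_domain_error("image must be a non-empty h x w x 3 array")
  h <- dim(image)[1]; w <- dim(image)[2]
  if (h > w) {  # portrait: transpose to landscape
    image <- aperm(image, c(2, 1, 3))
    h <- dim(image)[1]; w <- dim(image)[2]
  }
  if (h == target_h && w == target_w) return(image)
  fy <- h / target_h; fx <- w / target_w
  out <- array(0, dim = c(target_h, target_w, 3))
  if (fy == fx && fy == round(fy) && fy >= 1) {
    f <- as.integer(fy)
    for (ch in 1:3) out[, , ch] <- block_mean(image[, , ch], f)
  } else {
    for (ch in 1:3) {
      r <- EBImage::resize(to_ebi(image[, , ch]), w = target_w, h = target_h)
      out[, , ch] <- from_ebi(r)
    }
  }
  out
}

# exact f x f block averaging (area interpolation for integer downscales)
block_mean <- function(mat, f) {
  h <- nrow(mat); w <- ncol(mat)
  tmp <- matrix(colMeans(matrix(mat, nrow = f)), nrow = h / f)
  t(matrix(colMeans(matrix(t(tmp), nrow = f)), nrow = w / f))
}

# excess-green index G - (R+B)/2, the marker source for plant/soil scenes
excess_green <- function(image) {
  image[, , 2] - (image[, , 1] + image[, , 3]) / 2
}

#' Segment the plant from the background
#'
#' Reproduces the refinement chain used for factory scenes: an excess-green
#' transform thresholded by Otsu provides candidate foreground; watershed
#' labelling of its distance map yields marker regions; their dilated
#' bounding box initialises an iterative GrabCut (Gaussian-mixture colour
#' models + graph cut); the binary mask is then cleaned with a median
#' filter. The result is deterministic for a fixed image and configuration.
#'
#' @param image array h x w x 3 at the working resolution, values in `[0,1]`
#' @param grabcut_iters GrabCut refinement iterations
#' @param median_kernel odd side length of the median filter window applied
#'   to the mask (set 0 to disable)
#' @param filter_image_first apply the median filter to the image before
#'   segmentation instead of to the mask after (alternative reading of the
#'   refinement order)
#' @param gamma contrast-sensitive smoothness strength of the graph cut
#' @return object of class `fw_segmentation`: list with `mask` (logical
#'   matrix), `component_count`, `provenance = "grabcut"`
#' @export
segment_plant <- function(image, grabcut_iters = 5, median_kernel = 5,
                          filter_image_first = FALSE, gamma = 50) {
  if (length(dim(image)) != 3) fw_domain_error("image must be h x w x 3")
  if (median_kernel > 0 && median_kernel %% 2 != 1)
    fw_config_error("median_kernel must be odd")
  with_seed(760309L, {  # internal seed: kmeans init inside GrabCut
    if (filter_image_first && median_kernel > 1) {
      r <- (median_kernel - 1) / 2
      for (ch in 1:3) image[, , ch] <-
        from_ebi(EBImage::medianFilter(to_ebi(image[, , ch]), r))
    }
    exg <- excess_green(image)
    exg01 <- pmin(pmax((exg + 1) / 2, 0), 1)
    thr <- EBImage::otsu(to_ebi(exg01), range = c(0, 1))
    binary <- exg01 > thr
    # guard against Otsu splitting a plant-free scene's background noise:
    # require markers to be meaningfully green
    if (!any(binary) || max(exg[binary]) < 0.08) fw_segmentation_empty()
    # watershed labelling of the distance map -> foreground marker regions
    dm <- EBImage::distmap(to_ebi(binary))
    ws <- EBImage::watershed(dm)
    labels <- from_ebi(ws)
    fg_marker <- labels > 0
    ys <- which(rowSums(fg_marker) > 0); xs <- which(colSums(fg_marker) > 0)
    rect <- c(y0 = max(1, min(ys) - 10), y1 = min(nrow(binary), max(ys) + 10),
              x0 = max(1, min(xs) - 10), x1 = min(ncol(binary), max(xs) + 10))
    mask <- grabcut(image, rect, iters = grabcut_iters, gamma = gamma)
    if (!any(mask)) mask <- binary  # colour models collapsed; keep markers
    if (!filter_image_first && median_kernel > 1) {
      r <- (median_kernel - 1) / 2
      mask <- from_ebi(EBImage::medianFilter(to_ebi(mask * 1), r)) > 0.5
    }
    if (!any(mask)) fw_segmentation_empty()
    structure(list(mask = mask,
                   component_count = count_components(mask),
                   provenance = "grabcut"),
              class = "fw_segmentation")
  })
}

#' @export
print.fw_segmentation <- function(x, ...) {
  cat(sprintf("Segmentation (%s): %d x %d, %d component(s), %d fg px\n",
              x$provenance, nrow(x$mask), ncol(x$mask), x$component_count,
              sum(x$mask)))
  invisible(x)
}

count_components <- function(mask) {
  if (!any(mask)) return(0L)
  max(EBImage::bwlabel(to_ebi(mask)))
}

#' GrabCut segmentation with a rectangle initialisation
#'
#' Iterative foreground extraction: pixels outside the rectangle are fixed
#' background; inside, foreground/background Gaussian-mixture colour models
#' (5 full-covariance components each) are alternated with a min-cut on the
#' 8-connected pixel grid whose terminal weights are the mixture
#' negative log-likelihoods and whose neighbour weights are
#' contrast-sensitive. Computation is restricted to a margin around the
#' rectangle for speed.
#'
#' @param image array h x w x 3 in `[0,1]`
#' @param rect named vector `y0, y1, x0, x1` (inclusive pixel bounds of the
#'   probable-foreground region)
#' @param iters refinement iterations
#' @param gamma smoothness strength
#' @param n_components mixture components per class
#' @return logical h x w mask
#' @export
grabcut <- function(image, rect, iters = 5, gamma = 50, n_components = 5) {
  h <- dim(image)[1]; w <- dim(image)[2]
  my <- round((rect["y1"] - rect["y0"]) * 0.25) + 20
  mx <- round((rect["x1"] - rect["x0"]) * 0.25) + 20
  ry <- max(1, rect["y0"] - my):min(h, rect["y1"] + my)
  rx <- max(1, rect["x0"] - mx):min(w, rect["x1"] + mx)
  rh <- length(ry); rw <- length(rx)
  Z <- cbind(as.vector(image[ry, rx, 1]),
             as.vector(image[ry, rx, 2]),
             as.vector(image[ry, rx, 3]))
  inrect <- matrix(FALSE, rh, rw)
  inrect[ry >= rect["y0"] & ry <= rect["y1"],
         rx >= rect["x0"] & rx <= rect["x1"]] <- TRUE
  hard_bg <- !as.vector(inrect)
  alpha <- !hard_bg   # initial: rectangle = foreground

  # contrast-sensitive neighbour weights (shared across iterations)
  idx <- matrix(seq_len(rh * rw), rh, rw)
  sqd <- function(a, b) rowSums((Z[a, , drop = FALSE] - Z[b, , drop = FALSE])^2)
  pair_down  <- cbind(as.vector(idx[-rh, ]), as.vector(idx[-1, ]))
  pair_right <- cbind(as.vector(idx[, -rw]), as.vector(idx[, -1]))
  pair_dr    <- cbind(as.vector(idx[-rh, -rw]), as.vector(idx[-1, -1]))
  pair_ur    <- cbind(as.vector(idx[-1, -rw]), as.vector(idx[-rh, -1]))
  d2 <- c(sqd(pair_down[, 1], pair_down[, 2]), sqd(pair_right[, 1], pair_right[, 2]),
          sqd(pair_dr[, 1], pair_dr[, 2]), sqd(pair_ur[, 1], pair_ur[, 2]))
  beta <- 1 / (2 * max(mean(d2), 1e-8))
  wts <- function(pairs, diag) {
    v <- gamma * exp(-beta * sqd(pairs[, 1], pairs[, 2]))
    if (diag) v / sqrt(2) else v
  }
  full <- function(pairs, vals) {
    out <- numeric(rh * rw); out[pairs[, 1]] <- vals; out
  }
  cap_down  <- full(pair_down, wts(pair_down, FALSE))
  cap_right <- full(pair_right, wts(pair_right, FALSE))
  cap_dr    <- full(pair_dr, wts(pair_dr, TRUE))
  cap_ur    <- cbind_ur_caps(pair_ur, wts(pair_ur, TRUE), rh * rw)
  BIG <- 9 * gamma + 1

  comp_fg <- NULL; comp_bg <- NULL
  for (it in seq_len(iters)) {
    if (!any(alpha) || !any(!alpha)) break
    gmm_fg <- fit_gmm(Z[alpha, , drop = FALSE], n_components, comp_fg)
    gmm_bg <- fit_gmm(Z[!alpha, , drop = FALSE], n_components, comp_bg)
    if (is.null(gmm_fg) || is.null(gmm_bg)) break
    D_fg <- -gmm_loglik(gmm_fg, Z)
    D_bg <- -gmm_loglik(gmm_bg, Z)
    src <- D_bg; snk <- D_fg
    src[hard_bg] <- 0; snk[hard_bg] <- BIG
    fg <- .grid_mincut_cpp(rh, rw, src, snk, cap_down, cap_right, cap_dr, cap_ur)
    fg[hard_bg] <- FALSE
    if (identical(fg, alpha)) { alpha <- fg; break }
    alpha <- fg
    comp_fg <- gmm_fg; comp_bg <- gmm_bg
  }
  mask <- matrix(FALSE, h, w)
  mask[ry, rx] <- matrix(alpha, rh, rw)
  mask
}

# up-right caps are indexed by the lower (source) pixel of each pair
cbind_ur_caps <- function(pairs, vals, n) {
  out <- numeric(n); out[pairs[, 1]] <- vals; out
}

# weighted full-covariance GMM; init by kmeans, refit by likelihood
# assignment when previous parameters are available
fit_gmm <- function(Z, k, prev = NULL) {
  n <- nrow(Z)
  if (n < 2 * k) return(NULL)
  if (is.null(prev)) {
    sub <- if (n > 4000) Z[seq(1, n, length.out = 4000), , drop = FALSE] else Z
    km <- suppressWarnings(kmeans(sub, centers = min(k, nrow(unique(sub))),
                                  iter.max = 30, nstart = 1))
    centers <- km$centers
    assign <- max.col(-outer_dist2(Z, centers))
  } else {
    ll <- comp_loglik(prev, Z)
    assign <- max.col(ll)
  }
  comps <- lapply(seq_len(max(assign)), function(j) {
    Zi <- Z[assign == j, , drop = FALSE]
    if (nrow(Zi) < 4) return(NULL)
    list(w = nrow(Zi) / n, mu = colMeans(Zi),
         cov = stats::cov(Zi) + diag(1e-5, 3))
  })
  comps <- comps[!vapply(comps, is.null, logical(1))]
  if (!length(comps)) return(NULL)
  tot <- sum(vapply(comps, `[[`, numeric(1), "w"))
  for (j in seq_along(comps)) comps[[j]]$w <- comps[[j]]$w / tot
  comps
}

outer_dist2 <- function(Z, centers) {
  d <- matrix(0, nrow(Z), nrow(centers))
  for (j in seq_len(nrow(centers)))
    d[, j] <- rowSums(sweep(Z, 2, centers[j, ])^2)
  d
}

# per-component log(weight * density) matrix
comp_loglik <- function(comps, Z) {
  out <- matrix(-Inf, nrow(Z), length(comps))
  for (j in seq_along(comps)) {
    cp <- comps[[j]]
    R <- chol(cp$cov)
    q <- colSums(backsolve(R, t(Z) - cp$mu, transpose = TRUE)^2)
    out[, j] <- log(cp$w) - 0.5 * q - sum(log(diag(R))) - 1.5 * log(2 * pi)
  }
  out
}

gmm_loglik <- function(comps, Z) {
  ll <- comp_loglik(comps, Z)
  m <- apply(ll, 1, max)
  m + log(rowSums(exp(ll - m)))
}

#' Keep only the largest connected component
#'
#' Retains the component of largest pixel area; ties are broken by smallest
#' centroid row, then smallest centroid column.
#'
#' @param mask logical matrix, or an `fw_segmentation`
#' @return same type as the input, with a single component
#' @export
select_target_component <- function(mask) {
  seg <- NULL
  if (inherits(mask, "fw_segmentation")) { seg <- mask; mask <- seg$mask }
  mask <- mask_as_logical(mask)
  if (!any(mask)) fw_segmentation_empty()
  labels <- from_ebi(EBImage::bwlabel(to_ebi(mask)))
  nlab <- max(labels)
  if (nlab > 1) {
    areas <- tabulate(labels[labels > 0], nbins = nlab)
    cand <- which(areas == max(areas))
    if (length(cand) > 1) {
      cy <- vapply(cand, function(l) mean(which(labels == l, arr.ind = TRUE)[, 1]),
                   numeric(1))
      cand <- cand[cy == min(cy)]
      if (length(cand) > 1) {
        cx <- vapply(cand, function(l) mean(which(labels == l, arr.ind = TRUE)[, 2]),
                     numeric(1))
        cand <- cand[which.min(cx)]
      }
    }
    mask <- labels == cand[1]
  }
  if (is.null(seg)) return(mask)
  seg$mask <- mask
  seg$component_count <- 1L
  seg
}

#' Intersection-over-union of two masks
#' @param a,b logical matrices of equal size
#' @return IoU in `[0, 1]`
#' @export
mask_iou <- function(a, b) {
  a <- mask_as_logical(a); b <- mask_as_logical(b)
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}
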