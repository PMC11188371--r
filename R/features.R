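# 8-connected neighbour offsets in clockwise order (dy, dx), starting east
MOORE <- matrix(c(0, 1,  1, 1,  1, 0,  1, -1,  0, -1,  -1, -1,  -1, 0,  -1, 1),
                ncol = 2, byrow = TRUE)

#' Trace the outer contour of a mask
#'
#' Moore-neighbour boundary tracing with 8-connectivity. Returns the ordered
#' closed boundary of the component containing the first foreground pixel in
#' column-major scan order (for a single-component mask, the outer contour).
#' Interior holes are ignored: only the outer boundary is walked.
#'
#' @param mask logical or 0/1 matrix (rows = y, columns = x)
#' @return integer matrix with columns `x`, `y`; the polygon is implicitly
#'   closed (last vertex connects to the first)
#' @export
extract_contour <- function(mask) {
  mask <- mask_as_logical(mask)
  start <- which(mask)[1]
  if (is.na(start)) fw_segmentation_empty()
  h <- nrow(mask); w <- ncol(mask)
  sy <- (start - 1) %% h + 1
  sx <- (start - 1) %/% h + 1
  inside <- function(y, x) y >= 1 && y <= h && x >= 1 && x <= w && mask[y, x]
  # single isolated pixel
  if (!any(vapply(seq_len(8), function(k)
    inside(sy + MOORE[k, 1], sx + MOORE[k, 2]), logical(1))))
    return(cbind(x = sx, y = sy))
  # Moore tracing: from the current pixel p, scan neighbours clockwise
  # starting just after the backtrack (background) pixel b; the first
  # foreground pixel becomes the new p, the neighbour scanned before it the
  # new b. Stop when the (p, b) state recurs (Jacob's criterion).
  pts_x <- integer(0); pts_y <- integer(0)
  py <- sy; px <- sx
  by <- sy; bx <- sx - 1L   # west neighbour is background: sx is minimal x
  state0 <- NULL
  maxit <- 4L * h * w
  repeat {
    pts_x <- c(pts_x, px); pts_y <- c(pts_y, py)
    bdir <- which(MOORE[, 1] == by - py & MOORE[, 2] == bx - px)
    prev_y <- by; prev_x <- bx
    found <- FALSE
    for (step in 1:8) {
      k <- (bdir - 1L + step) %% 8L + 1L
      ny <- py + MOORE[k, 1]; nx <- px + MOORE[k, 2]
      if (inside(ny, nx)) {
        by <- prev_y; bx <- prev_x
        py <- ny; px <- nx
        found <- TRUE
        break
      }
      prev_y <- ny; prev_x <- nx
    }
    if (!found) break
    st <- c(py, px, by, bx)
    if (is.null(state0)) state0 <- st
    else if (all(st == state0)) break
    if (length(pts_x) > maxit) break
  }
  n <- length(pts_x)
  if (n > 1 && pts_x[n] == pts_x[1] && pts_y[n] == pts_y[1]) {
    pts_x <- pts_x[-n]; pts_y <- pts_y[-n]  # drop duplicated closing vertex
  }
  cbind(x = pts_x, y = pts_y)
}

mask_as_logical <- function(mask) {
  if (is.logical(mask)) return(mask)
  if (is.numeric(mask) && is.matrix(mask)) return(mask > 0)
  fw_domain_error("mask must be a logical or numeric matrix")
}

#' Area enclosed by a pixel contour
#'
#' Surveyor's (shoelace) area of the closed boundary polygon with the
#' lattice-polygon (Pick) correction `+ n/2 + 1`, so that on rasterised
#' shapes the value approximates the enclosed pixel count. Interior holes do
#' not reduce the area (the contour is the outer boundary only). A one- or
#' two-pixel contour yields a small positive value rather than an error.
#'
#' @param contour matrix with columns `x`, `y` as from [extract_contour()]
#' @return area in pixels^2
#' @export
contour_area <- function(contour) {
  contour <- check_contour(contour)
  n <- nrow(contour)
  x <- contour[, 1]; y <- contour[, 2]
  j <- if (n == 1) 1 else c(2:n, 1)
  shoelace <- abs(sum(x * y[j] - x[j] * y)) / 2
  shoelace + n / 2 + 1
}

#' Length of a closed pixel contour
#'
#' Sum of Euclidean segment lengths around the closed polygon (diagonal
#' steps count sqrt(2)). Invariant under traversal direction.
#'
#' @inheritParams contour_area
#' @return perimeter in pixels
#' @export
contour_perimeter <- function(contour) {
  contour <- check_contour(contour)
  n <- nrow(contour)
  if (n == 1) return(0)
  j <- c(2:n, 1)
  sum(sqrt((contour[j, 1] - contour[, 1])^2 + (contour[j, 2] - contour[, 2])^2))
}

check_contour <- function(contour) {
  if (is.null(dim(contour)) || ncol(contour) < 2 || nrow(contour) < 1)
    fw_domain_error("contour must be a matrix with columns x, y")
  contour
}

#' Axis lengths of the least-squares fitted ellipse
#'
#' Direct least-squares conic fit (constrained so the solution is an
#' ellipse), computed on centred and scaled coordinates for numerical
#' stability. Returns full axis lengths (diameters), so a circle of radius r
#' gives roughly (2r, 2r).
#'
#' @inheritParams contour_area
#' @return named numeric: `major_px`, `minor_px` (major >= minor)
#' @export
fit_ellipse_axes <- function(contour) {
  contour <- check_contour(contour)
  if (nrow(contour) < 5)
    fw_feature_undefined("ellipse fit needs >= 5 contour points, got %d", nrow(contour))
  x0 <- contour[, 1]; y0 <- contour[, 2]
  mx <- mean(x0); my <- mean(y0)
  sc <- sqrt(mean((x0 - mx)^2 + (y0 - my)^2))
  if (sc <= 0) fw_feature_undefined("degenerate contour")
  x <- (x0 - mx) / sc; y <- (y0 - my) / sc
  D1 <- cbind(x^2, x * y, y^2)
  D2 <- cbind(x, y, 1)
  S1 <- crossprod(D1); S2 <- crossprod(D1, D2); S3 <- crossprod(D2)
  Tm <- tryCatch(-solve(S3, t(S2)), error = function(e) NULL)
  if (is.null(Tm)) fw_feature_undefined("singular scatter in ellipse fit")
  M <- S1 + S2 %*% Tm
  M2 <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  eg <- eigen(M2)
  ok <- which(abs(Im(eg$values)) < 1e-8 &
                4 * Re(eg$vectors[1, ]) * Re(eg$vectors[3, ]) -
                Re(eg$vectors[2, ])^2 > 0)
  if (!length(ok)) fw_feature_undefined("no elliptical solution")
  a1 <- Re(eg$vectors[, ok[1]])
  coefs <- c(a1, as.vector(Tm %*% a1))  # A B C D E F
  A <- coefs[1]; B <- coefs[2]; C <- coefs[3]
  D <- coefs[4]; E <- coefs[5]; F <- coefs[6]
  den <- B^2 - 4 * A * C
  cx <- (2 * C * D - B * E) / den
  cy <- (2 * A * E - B * D) / den
  Fc <- A * cx^2 + B * cx * cy + C * cy^2 + D * cx + E * cy + F
  Mc <- matrix(c(A, B / 2, B / 2, C), 2)
  lam <- eigen(Mc, symmetric = TRUE)$values
  if (any(-Fc / lam <= 0)) fw_feature_undefined("degenerate ellipse")
  semis <- sqrt(-Fc / lam) * sc
  c(major_px = 2 * max(semis), minor_px = 2 * min(semis))
}

#' Extract the four manual morphometric features from a mask
#'
#' Composes [extract_contour()], [contour_area()], [contour_perimeter()] and
#' [fit_ellipse_axes()] into the feature vector used by all manual-feature
#' weight models: projected area (A), boundary perimeter (P), and the
#' fitted-ellipse major (MA) and minor (MI) axis lengths, all in pixel units.
#'
#' @param mask logical or 0/1 matrix, expected to hold a single connected
#'   component (see [select_target_component()])
#' @return named numeric vector `area_px`, `perimeter_px`, `major_px`,
#'   `minor_px`
#' @export
extract_features <- function(mask) {
  contour <- extract_contour(mask)
  axes <- fit_ellipse_axes(contour)
  c(area_px = contour_area(contour),
    perimeter_px = contour_perimeter(contour),
    axes)
}

#' Batch feature extraction over masks
#'
#' Applies [extract_features()] to each mask; samples whose features are
#' undefined (e.g. too few contour points for the ellipse fit) are dropped
#' with a warning, mirroring the exclusion of unusable images from a real
#' corpus.
#'
#' @param masks list of masks
#' @param ids sample identifiers (same length)
#' @return data.frame `sample_id`, `area_px`, `perimeter_px`, `major_px`,
#'   `minor_px`
#' @export
extract_features_batch <- function(masks, ids = names(masks)) {
  if (is.null(ids)) ids <- sprintf("sample_%04d", seq_along(masks))
  rows <- lapply(seq_along(masks), function(i) {
    f <- tryCatch(extract_features(masks[[i]]),
                  fw_feature_undefined = function(e) NULL,
                  fw_segmentation_empty = function(e) NULL)
    if (is.null(f)) return(NULL)
    data.frame(sample_id = ids[[i]], area_px = f[["area_px"]],
               perimeter_px = f[["perimeter_px"]], major_px = f[["major_px"]],
               minor_px = f[["minor_px"]])
  })
  dropped <- sum(vapply(rows, is.null, logical(1)))
  if (dropped > 0)
    warning(sprintf("%d sample(s) dropped: features undefined", dropped))
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}
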