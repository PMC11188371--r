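#' The 15 feature subsets of the model grid
#'
#' All non-empty subsets of the four manual features A (area), P (perimeter),
#' MA (major axis), MI (minor axis), in the conventional printed order:
#' the four singletons, then pairs, triples and the full set.
#'
#' @return list of 15 character vectors
#' @export
enumerate_feature_subsets <- function() {
  list(c("A"), c("P"), c("MA"), c("MI"),
       c("A", "P"), c("A", "MA"), c("A", "MI"), c("P", "MA"), c("P", "MI"),
       c("MA", "MI"),
       c("A", "P", "MA"), c("A", "P", "MI"), c("A", "MA", "MI"),
       c("P", "MA", "MI"),
       c("A", "P", "MA", "MI"))
}

# all exponent vectors with 1 <= total degree <= m over v variables,
# ordered by total degree then lexicographically
poly_exponents <- function(v, m, interactions = TRUE) {
  grid <- as.matrix(expand.grid(rep(list(0:m), v)))[, v:1, drop = FALSE]
  tot <- rowSums(grid)
  keep <- tot >= 1 & tot <= m
  if (!interactions) keep <- keep & rowSums(grid > 0) <= 1
  grid <- grid[keep, , drop = FALSE]
  # graded ordering: total degree, then earlier variables lead
  keys <- c(list(rowSums(grid)), lapply(seq_len(v), function(i) -grid[, i]))
  grid[do.call(order, keys), , drop = FALSE]
}

#' Polynomial design matrix of total degree m
#'
#' Expands the columns of `features` into the full polynomial basis of total
#' degree `<= m` (all monomials, including cross terms), preceded by an
#' intercept column. With `interactions = FALSE` only pure powers are kept.
#' Degree 1 reproduces the plain multiple-linear-regression design exactly.
#'
#' @param features numeric matrix (rows = samples)
#' @param degree_m polynomial degree, one of 1, 2, 3
#' @param interactions include cross terms (default) or pure powers only
#' @return design matrix with `choose(m + v, v)` columns when interactions
#'   are included
#' @export
expand_polynomial_basis <- function(features, degree_m, interactions = TRUE) {
  if (!degree_m %in% 1:3) fw_domain_error("degree_m must be 1, 2 or 3")
  features <- as.matrix(features)
  v <- ncol(features)
  ex <- poly_exponents(v, degree_m, interactions)
  out <- matrix(1, nrow(features), 1 + nrow(ex))
  nms <- "(Intercept)"
  vn <- colnames(features) %||% paste0("x", seq_len(v))
  for (j in seq_len(nrow(ex))) {
    col <- rep(1, nrow(features))
    for (i in seq_len(v)) if (ex[j, i] > 0) col <- col * features[, i]^ex[j, i]
    out[, j + 1] <- col
    nms <- c(nms, paste(ifelse(ex[j, ] > 0,
                               paste0(vn, ifelse(ex[j, ] > 1,
                                                 paste0("^", ex[j, ]), "")), ""),
                        collapse = "")[1])
  }
  colnames(out) <- nms
  out
}

#' Ordinary least squares on a design matrix
#'
#' QR-based OLS returning the coefficient vector that minimises the residual
#' sum of squares. Rank-deficient designs produce a warning and the
#' minimum-norm solution (via the pseudoinverse).
#'
#' @param design design matrix (n x p, n >= p expected)
#' @param response numeric response vector
#' @return numeric coefficient vector of length p
#' @export
fit_ols <- function(design, response) {
  design <- as.matrix(design)
  if (nrow(design) < ncol(design))
    fw_domain_error("need at least as many rows as columns (%d < %d)",
                    nrow(design), ncol(design))
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    warning("rank-deficient design; returning minimum-norm solution")
    sv <- svd(design)
    pos <- sv$d > max(sv$d) * 1e-10
    beta <- sv$v[, pos, drop = FALSE] %*%
      ((t(sv$u[, pos, drop = FALSE]) %*% response) / sv$d[pos])
    return(as.vector(beta))
  }
  as.vector(qr.coef(qrd, response))
}

#' Fit a polynomial fresh-weight regression
#'
#' The conventional manual-feature model: features of the chosen subset are
#' min-max scaled (fit on the training data), the response is standardised,
#' the scaled features are expanded into a total-degree polynomial basis and
#' fitted by ordinary least squares. `degree = 1` gives simple (one feature)
#' or multiple linear regression; degrees 2 and 3 give quadratic and cubic
#' polynomial regressions.
#'
#' @param data data.frame holding the subset's feature columns (`area_px`,
#'   `perimeter_px`, `major_px`, `minor_px`) and the response `weight_g`
#' @param subset character vector over `c("A","P","MA","MI")`
#' @param degree polynomial degree, 1, 2 or 3
#' @param interactions include cross terms in multivariate bases
#' @return object of class `fw_polyreg`
#' @seealso [predict.fw_polyreg()], [fit_regression_grid()]
#' @examples
#' d <- data.frame(area_px = 1:20, weight_g = 3 + 2 * (1:20))
#' m <- fw_polyreg(d, "A", degree = 1)
#' predict(m, d[1:3, , drop = FALSE])
#' @export
fw_polyreg <- function(data, subset, degree = 1, interactions = TRUE) {
  cols <- feature_columns(subset)
  miss <- setdiff(cols, names(data))
  if (length(miss)) fw_domain_error("missing columns: %s", paste(miss, collapse = ", "))
  if (!"weight_g" %in% names(data)) fw_domain_error("missing column: weight_g")
  X <- as.matrix(data[, cols, drop = FALSE])
  y <- data$weight_g
  fs <- scale_features_minmax(X)
  ts <- scale_target_standard(y)
  design <- expand_polynomial_basis(fs$train, degree, interactions)
  beta <- fit_ols(design, ts$train)
  fitted_std <- as.vector(design %*% beta)
  structure(list(
    subset = subset, degree = degree, interactions = interactions,
    coefficients = stats::setNames(beta, colnames(design)),
    feature_scaler = fs$scaler, target_scaler = ts$scaler,
    n_train = nrow(X),
    train_r2 = r_squared(y, standard_inverse(ts$scaler, fitted_std)),
    call = match.call()
  ), class = "fw_polyreg")
}

#' Predict fresh weight from manual features
#'
#' Applies the fitted min-max feature scaling, the polynomial basis
#' expansion and the coefficients, then inverts the response
#' standardisation, returning grams.
#'
#' @param object an [fw_polyreg()] model
#' @param newdata data.frame with the model's feature columns
#' @param ... unused
#' @return numeric vector of predicted weights, grams
#' @export
predict.fw_polyreg <- function(object, newdata, ...) {
  cols <- feature_columns(object$subset)
  miss <- setdiff(cols, names(newdata))
  if (length(miss)) fw_domain_error("missing columns: %s", paste(miss, collapse = ", "))
  X <- minmax_transform(object$feature_scaler,
                        as.matrix(newdata[, cols, drop = FALSE]))
  design <- expand_polynomial_basis(X, object$degree, object$interactions)
  standard_inverse(object$target_scaler, as.vector(design %*% object$coefficients))
}

#' @export
print.fw_polyreg <- function(x, ...) {
  cat(sprintf("Polynomial weight regression: degree %d on (%s)\n",
              x$degree, paste(x$subset, collapse = ", ")))
  cat(sprintf("  %d terms, n = %d, training R^2 = %.3f\n",
              length(x$coefficients), x$n_train, x$train_r2))
  invisible(x)
}

#' @export
coef.fw_polyreg <- function(object, ...) object$coefficients

#' @export
summary.fw_polyreg <- function(object, ...) {
  print(object)
  cat("Coefficients (scaled feature space, standardised response):\n")
  print(round(object$coefficients, 4))
  invisible(object)
}

#' Fit the full conventional model grid
#'
#' Trains all 45 conventional models -- the 15 feature subsets crossed with
#' polynomial degrees 1 (linear), 2 and 3 -- on the training split and
#' evaluates R^2 and RMSE (grams) on the test split, mirroring the canonical
#' layout of published model-comparison tables: 4 simple linear, 11 multiple
#' linear, 8 simple polynomial and 22 multivariate polynomial fits.
#'
#' @param train,test data.frames with feature columns and `weight_g`
#' @param degrees degrees to sweep (default 1:3)
#' @param interactions include cross terms in multivariate bases
#' @return object of class `fw_reggrid`: list with `results` (data.frame
#'   `subset`, `degree`, `r2`, `rmse_g`) and `models`
#' @export
fit_regression_grid <- function(train, test, degrees = 1:3, interactions = TRUE) {
  subsets <- enumerate_feature_subsets()
  rows <- list(); models <- list()
  for (deg in degrees) {
    for (ss in subsets) {
      key <- paste0(paste(ss, collapse = "+"), "|d", deg)
      m <- fw_polyreg(train, ss, deg, interactions)
      pred <- predict(m, test)
      rows[[key]] <- data.frame(subset = paste(ss, collapse = ","),
                                degree = deg,
                                r2 = r_squared(test$weight_g, pred),
                                rmse_g = rmse(test$weight_g, pred))
      models[[key]] <- m
    }
  }
  structure(list(results = do.call(rbind, c(rows, list(make.row.names = FALSE))),
                 models = models,
                 n_train = nrow(train), n_test = nrow(test)),
            class = "fw_reggrid")
}

#' @export
print.fw_reggrid <- function(x, ...) {
  cat(sprintf("Conventional regression grid: %d models (train %d / test %d)\n",
              nrow(x$results), x$n_train, x$n_test))
  best <- x$results[which.max(x$results$r2), ]
  cat(sprintf("  best: degree %d on (%s), R^2 = %.3f, RMSE = %.2f g\n",
              best$degree, best$subset, best$r2, best$rmse_g))
  invisible(x)
}
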