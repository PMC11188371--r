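#' Shuffled train/test split
#'
#' Single seeded shuffle split. The training size is `round(train_fraction
#' * n)`; train and test are disjoint and exhaustive.
#'
#' @param n number of samples (>= 2), or a data.frame whose rows are split
#' @param train_fraction fraction assigned to training (default 0.7)
#' @param seed integer seed for the shuffle
#' @return list with integer index vectors `train` and `test`
#' @export
split_dataset <- function(n, train_fraction = 0.7, seed = 1) {
  if (is.data.frame(n)) n <- nrow(n)
  if (!is.numeric(n) || n < 2) fw_domain_error("need at least 2 samples")
  n <- as.integer(n)
  idx <- with_seed(seed, sample.int(n))
  k <- round(train_fraction * n)
  list(train = sort(idx[seq_len(k)]), test = sort(idx[-seq_len(k)]))
}

#' Pearson correlation matrix of features and weight
#'
#' Pairwise Pearson correlation over the given columns; the input for the
#' correlation heatmap used to screen candidate model inputs.
#'
#' @param data data.frame; defaults to the four manual features plus weight
#' @param columns columns to correlate
#' @return symmetric correlation matrix with unit diagonal
#' @export
pearson_corr_matrix <- function(data,
                                columns = c(unname(FEATURE_NAMES), "weight_g")) {
  columns <- intersect(columns, names(data))
  if (nrow(data) < 3) fw_domain_error("need >= 3 rows")
  m <- as.matrix(data[, columns, drop = FALSE])
  sds <- apply(m, 2, sd)
  if (any(sds == 0 | !is.finite(sds)))
    fw_domain_error("constant column(s): %s",
                    paste(columns[sds == 0 | !is.finite(sds)], collapse = ", "))
  cor(m)
}

#' Coefficient of determination
#'
#' `1 - SSR/SST`: one minus the ratio of residual to total sum of squares.
#' Can be negative for predictors worse than the mean.
#'
#' @param true_g,predicted_g equal-length numeric vectors
#' @return dimensionless R^2
#' @export
r_squared <- function(true_g, predicted_g) {
  check_paired(true_g, predicted_g)
  sst <- sum((true_g - mean(true_g))^2)
  if (sst <= 0) fw_domain_error("true values have zero variance")
  1 - sum((true_g - predicted_g)^2) / sst
}

#' Root mean square error
#'
#' Square root of the mean squared prediction error, in the units of the
#' response (grams for fresh weight).
#'
#' @inheritParams r_squared
#' @return RMSE in grams
#' @export
rmse <- function(true_g, predicted_g) {
  check_paired(true_g, predicted_g)
  sqrt(mean((true_g - predicted_g)^2))
}

check_paired <- function(a, b) {
  if (length(a) != length(b)) fw_domain_error("length mismatch (%d vs %d)",
                                              length(a), length(b))
  if (length(a) < 1) fw_domain_error("empty vectors")
  invisible(NULL)
}

#' Gaussian kernel density estimate of a weight sample
#'
#' Density curve used for the predicted-versus-true weight overlays;
#' bandwidth follows Scott's rule by default.
#'
#' @param values_g numeric sample (>= 2 distinct values)
#' @param grid evaluation points; defaults to 512 points spanning the data
#'   plus three bandwidths
#' @param bw bandwidth, or the name of a rule (`"scott"`)
#' @return data.frame with `x` (grams) and `density`
#' @export
kde_curve <- function(values_g, grid = NULL, bw = "scott") {
  if (length(values_g) < 2 || sd(values_g) == 0)
    fw_degenerate_scale("need >= 2 distinct values for a density estimate")
  if (identical(bw, "scott"))
    bw <- sd(values_g) * length(values_g)^(-1 / 5)
  if (is.null(grid)) {
    d <- density(values_g, bw = bw, n = 512,
                 from = min(values_g) - 3 * bw, to = max(values_g) + 3 * bw)
  } else {
    d <- density(values_g, bw = bw, n = length(grid),
                 from = min(grid), to = max(grid))
  }
  data.frame(x = d$x, density = d$y)
}
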