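#' Min-max feature scaling fitted on a training split
#'
#' Maps each training column linearly onto `[0, 1]`. The fitted transform is
#' applied unchanged to new data (values outside the training range map
#' outside `[0, 1]`; no clipping), and is exactly invertible.
#'
#' @param train numeric matrix or data.frame (rows = samples)
#' @param newdata optional matrix to transform with the fitted parameters
#' @return list with `train` (scaled), `newdata` (scaled, or NULL) and
#'   `scaler` (class `fw_minmax_scaler`)
#' @export
scale_features_minmax <- function(train, newdata = NULL) {
  train <- as.matrix(train)
  mins <- apply(train, 2, min)
  maxs <- apply(train, 2, max)
  if (any(maxs - mins <= 0))
    fw_degenerate_scale("constant feature column(s): %s",
                        paste(colnames(train)[maxs - mins <= 0], collapse = ", "))
  scaler <- structure(list(min = mins, max = maxs), class = "fw_minmax_scaler")
  list(train = minmax_transform(scaler, train),
       newdata = if (!is.null(newdata)) minmax_transform(scaler, as.matrix(newdata)),
       scaler = scaler)
}

minmax_transform <- function(scaler, x) {
  sweep(sweep(as.matrix(x), 2, scaler$min), 2, scaler$max - scaler$min, "/")
}

minmax_inverse <- function(scaler, x) {
  sweep(sweep(as.matrix(x), 2, scaler$max - scaler$min, "*"), 2, scaler$min, "+")
}

#' Standardisation of the response fitted on a training split
#'
#' Centres and scales the training weights to mean 0, standard deviation 1;
#' exactly invertible.
#'
#' @param train_weights numeric vector (>= 2 distinct values)
#' @return list with `train` (standardised) and `scaler`
#'   (class `fw_standard_scaler`)
#' @export
scale_target_standard <- function(train_weights) {
  m <- mean(train_weights); s <- sd(train_weights)
  if (!is.finite(s) || s <= 0)
    fw_degenerate_scale("response has zero variance")
  scaler <- structure(list(mean = m, sd = s), class = "fw_standard_scaler")
  list(train = (train_weights - m) / s, scaler = scaler)
}

standard_transform <- function(scaler, x) (x - scaler$mean) / scaler$sd
standard_inverse <- function(scaler, x) x * scaler$sd + scaler$mean
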