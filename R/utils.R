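#' @useDynLib freshwt, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats coef cor density kmeans predict quantile rnorm runif sd
#' @importFrom utils read.csv write.csv head tail
NULL

# classed conditions so callers can distinguish failure modes
fw_stop <- function(class, msg, ...) {
  stop(structure(
    list(message = sprintf(msg, ...), call = sys.call(-1)),
    class = c(class, "fw_error", "error", "condition")))
}

fw_domain_error       <- function(msg, ...) fw_stop("fw_domain_error", msg, ...)
fw_config_error       <- function(msg, ...) fw_stop("fw_config_error", msg, ...)
fw_segmentation_empty <- function(msg = "no foreground found", ...) {
  fw_stop("fw_segmentation_empty", msg, ...)
}
fw_feature_undefined  <- function(msg, ...) fw_stop("fw_feature_undefined", msg, ...)
fw_degenerate_scale   <- function(msg, ...) fw_stop("fw_degenerate_scale", msg, ...)
fw_dependency_error   <- function(msg, ...) fw_stop("fw_dependency_error", msg, ...)

# run code under a fixed RNG state without disturbing the caller's stream
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# derive a reproducible child seed from a master seed and a stage label
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.double(seed) * 7919 + h) %% .Machine$integer.max)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# canonical feature names and their manifest column names
FEATURE_NAMES <- c(A = "area_px", P = "perimeter_px", MA = "major_px", MI = "minor_px")

feature_columns <- function(subset) {
  bad <- setdiff(subset, names(FEATURE_NAMES))
  if (length(bad)) fw_domain_error("unknown feature(s): %s", paste(bad, collapse = ", "))
  unname(FEATURE_NAMES[subset])
}
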