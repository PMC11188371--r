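#' Architecture of the manual-feature perceptron (MLP_1)
#'
#' Three fully connected layers of 32, 15 and 1 nodes. The 32- and 15-node
#' layers use ReLU; dropout (rate 0.5) follows the 15-node layer; the output
#' node is also ReLU-capped, clamping predictions at 0 g.
#'
#' @return object of class `fw_nn_spec`
#' @export
build_mlp_manual <- function() {
  layers <- list(
    list(type = "dense", n_in = 4, n_out = 32), list(type = "relu"),
    list(type = "dense", n_in = 32, n_out = 15), list(type = "relu"),
    list(type = "dropout", rate = 0.5),
    list(type = "dense", n_in = 15, n_out = 1), list(type = "relu"))
  nn_spec("MLP_1", layers, input = "features", input_dim = 4)
}

#' Architecture of the flattened-image perceptron (MLP_2)
#'
#' Takes the 28 x 28 single-channel image flattened to a 784-vector through
#' fully connected layers of 1568, 392 and 1 nodes (ReLU, ReLU + dropout
#' 0.5, ReLU output).
#'
#' @return object of class `fw_nn_spec`
#' @export
build_mlp_image <- function() {
  layers <- list(
    list(type = "dense", n_in = 784, n_out = 1568), list(type = "relu"),
    list(type = "dense", n_in = 1568, n_out = 392), list(type = "relu"),
    list(type = "dropout", rate = 0.5),
    list(type = "dense", n_in = 392, n_out = 1), list(type = "relu"))
  nn_spec("MLP_2", layers, input = "image", input_dim = 784)
}

#' Architecture of the convolutional regressor
#'
#' Four 3 x 3 stride-1 zero-padded convolution stages of 64, 128, 256 and
#' 512 channels, each ReLU-activated; max pooling (2) after the 128- and
#' 256-channel stages takes the 28 x 28 input to 7 x 7; global average
#' pooling then yields a 512-vector fed to a single linear output node (no
#' activation). With `residual = TRUE` identity skip connections are added
#' around consecutive convolution pairs of equal channel width -- in this
#' four-stage stack every stage changes width, so the printed architecture
#' has no eligible pair and the residual flag leaves it structurally
#' unchanged; the flag matters for custom stacks built with [nn_spec()].
#'
#' @param residual add identity skips around equal-width convolution pairs
#' @return object of class `fw_nn_spec`
#' @export
build_cnn <- function(residual = TRUE) {
  layers <- list(
    list(type = "conv", n_in = 1, n_out = 64), list(type = "relu"),
    list(type = "conv", n_in = 64, n_out = 128), list(type = "relu"),
    list(type = "maxpool2"),
    list(type = "conv", n_in = 128, n_out = 256), list(type = "relu"),
    list(type = "maxpool2"),
    list(type = "conv", n_in = 256, n_out = 512), list(type = "relu"),
    list(type = "gavgpool"),
    list(type = "dense", n_in = 512, n_out = 1))
  if (residual) layers <- add_residual_skips(layers)
  nn_spec("CNN", layers, input = "image", input_dim = 784,
          img_h = 28, img_w = 28, residual = residual)
}

# wrap save/addfrom around consecutive equal-width conv(+relu) pairs
add_residual_skips <- function(layers) {
  out <- list(); slot <- 0L; i <- 1L
  while (i <= length(layers)) {
    ly <- layers[[i]]
    nxt_conv <- if (i + 2 <= length(layers) &&
                    identical(layers[[i + 1]]$type, "relu"))
      layers[[i + 2]] else NULL
    if (identical(ly$type, "conv") && !is.null(nxt_conv) &&
        identical(nxt_conv$type, "conv") &&
        identical(ly$n_in, ly$n_out) && identical(nxt_conv$n_in, nxt_conv$n_out) &&
        identical(ly$n_out, nxt_conv$n_out)) {
      slot <- slot + 1L
      out <- c(out, list(list(type = "save", slot = slot)),
               layers[i:(i + 2)],
               list(list(type = "addfrom", slot = slot)))
      i <- i + 3L
    } else {
      out <- c(out, list(ly))
      i <- i + 1L
    }
  }
  out
}

#' Construct a neural model specification
#'
#' Low-level constructor for custom layer stacks; the three standard
#' architectures are available through [build_mlp_manual()],
#' [build_mlp_image()] and [build_cnn()].
#'
#' @param name model label
#' @param layers list of layer descriptors (`type` one of `dense`, `conv`,
#'   `relu`, `dropout`, `maxpool2`, `gavgpool`, `save`, `addfrom`)
#' @param input `"features"` or `"image"`
#' @param input_dim flattened input length
#' @param img_h,img_w image dimensions (image input only)
#' @param residual whether skip connections were requested
#' @return object of class `fw_nn_spec`
#' @export
nn_spec <- function(name, layers, input = c("features", "image"),
                    input_dim, img_h = 28, img_w = 28, residual = FALSE) {
  input <- match.arg(input)
  structure(list(name = name, layers = layers, input = input,
                 input_dim = input_dim, img_h = img_h, img_w = img_w,
                 residual = residual),
            class = "fw_nn_spec")
}

#' @export
print.fw_nn_spec <- function(x, ...) {
  cat(sprintf("Neural spec %s: %s input (%d), %d layers, %s parameters\n",
              x$name, x$input, x$input_dim, length(x$layers),
              format(nn_param_count(x), big.mark = ",")))
  invisible(x)
}

#' Number of trainable parameters in a specification
#' @param spec an `fw_nn_spec`
#' @return parameter count (weights + biases)
#' @export
nn_param_count <- function(spec) {
  .nn_param_count_cpp(spec$layers, spec$input_dim, spec$img_h, spec$img_w)
}

#' Training configuration for the neural regressors
#'
#' Defaults follow the common protocol for all three models: MSE loss, Adam
#' with learning rate 0.001, batch size 512 (one optimiser step per epoch
#' whenever the training set is smaller than a batch), targets scaled by
#' 0.01, and random horizontal/vertical flip augmentation for image models.
#' Default epoch counts are the per-model convergence points of the training
#' loss: 400 (MLP_1), 500 (MLP_2), 300 (CNN).
#'
#' @param model `"MLP_1"`, `"MLP_2"` or `"CNN"` (sets the default epochs)
#' @param epochs training epochs; `NULL` uses the per-model default
#' @param lr Adam learning rate
#' @param batch_size minibatch size
#' @param seed integer seed for initialisation, dropout and augmentation
#' @param augment random flips (image models; ignored for feature input)
#' @param weight_scale multiplicative target scaling
#' @param chunk internal forward/backward chunk size (memory/speed knob;
#'   does not affect results beyond float summation order)
#' @return list of class `fw_train_config`
#' @export
train_config <- function(model = c("MLP_1", "MLP_2", "CNN"), epochs = NULL,
                         lr = 0.001, batch_size = 512, seed = 1,
                         augment = TRUE, weight_scale = 0.01, chunk = 8) {
  model <- match.arg(model)
  if (is.null(epochs))
    epochs <- c(MLP_1 = 400, MLP_2 = 500, CNN = 300)[[model]]
  structure(list(model = model, epochs = as.integer(epochs), lr = lr,
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 augment = augment, weight_scale = weight_scale,
                 chunk = as.integer(chunk)),
            class = "fw_train_config")
}

#' Optimiser steps per epoch
#'
#' One step per full pass: `ceiling(n_train / batch_size)`; with the
#' standard batch of 512 and a training set smaller than one batch this is
#' exactly one step per epoch.
#'
#' @param n_train training-set size
#' @param batch_size minibatch size
#' @return integer number of optimiser iterations per epoch
#' @export
iterations_per_epoch <- function(n_train, batch_size = 512) {
  if (n_train < 1 || batch_size < 1) fw_domain_error("sizes must be >= 1")
  as.integer(ceiling(n_train / batch_size))
}

#' Scale a weight for training
#'
#' Targets are multiplied by 0.01 before training for optimisation
#' stability; [inverse_weight_scale()] maps predictions back to grams.
#'
#' @param weight_g weights in grams (>= 0)
#' @param weight_scale scale factor
#' @return scaled targets
#' @export
scale_weight_for_training <- function(weight_g, weight_scale = 0.01) {
  if (any(weight_g < 0)) fw_domain_error("weights must be >= 0")
  weight_g * weight_scale
}

#' @rdname scale_weight_for_training
#' @param scaled scaled targets
#' @export
inverse_weight_scale <- function(scaled, weight_scale = 0.01) {
  scaled / weight_scale
}

#' Convert an RGB image to the 28 x 28 single-channel network input
#'
#' Luminance grayscale conversion (Rec. 601 weights), bilinear resize to
#' 28 x 28 and intensity in `[0, 1]`. With `augment = TRUE` the image is
#' flipped horizontally and/or vertically, each with probability 0.5, drawn
#' from the current RNG stream.
#'
#' @param image h x w x 3 array in `[0,1]`
#' @param augment apply random flips
#' @param size output side length
#' @return `size` x `size` matrix
#' @export
prepare_image_input <- function(image, augment = FALSE, size = 28) {
  if (length(dim(image)) != 3 || any(dim(image)[1:2] == 0))
    fw_domain_error("image must be a non-empty h x w x 3 array")
  gray <- 0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
  small <- from_ebi(EBImage::resize(to_ebi(gray), w = size, h = size))
  small <- pmin(pmax(small, 0), 1)
  if (augment) {
    if (runif(1) < 0.5) small <- small[, rev(seq_len(ncol(small)))]
    if (runif(1) < 0.5) small <- small[rev(seq_len(nrow(small))), ]
  }
  small
}

# stack a list of 28x28 matrices (or an n x 784 matrix) into engine layout
as_image_matrix <- function(images, size = 28) {
  if (is.matrix(images) && ncol(images) == size * size) return(t(images))
  if (is.list(images))
    return(vapply(images, function(m) as.vector(m), numeric(size * size)))
  fw_domain_error("images must be a list of matrices or an n x %d matrix",
                  size * size)
}

#' Train a neural fresh-weight regressor
#'
#' Trains the given architecture with MSE loss and Adam on scaled targets.
#' Feature-input models receive min-max scaled features (fitted on the
#' training data); image models receive prepared 28 x 28 inputs and optional
#' flip augmentation applied epoch-wise inside the training loop. With a
#' fixed seed the loss series and weights are reproducible.
#'
#' @param spec an `fw_nn_spec`
#' @param x training inputs: data.frame of features (for `MLP_1`-style
#'   specs) or a list of 28 x 28 matrices / n x 784 matrix (image specs)
#' @param weight_g training weights in grams
#' @param config an [train_config()]
#' @return object of class `fw_nn` with the trained weights and the
#'   per-epoch training loss series
#' @export
fw_nn <- function(spec, x, weight_g, config = train_config(spec$name)) {
  if (!inherits(spec, "fw_nn_spec")) fw_domain_error("spec must be fw_nn_spec")
  if (length(weight_g) < 1) fw_domain_error("empty training set")
  y <- scale_weight_for_training(weight_g, config$weight_scale)
  feature_scaler <- NULL
  if (spec$input == "features") {
    X <- as.matrix(if (is.data.frame(x)) x[, unname(FEATURE_NAMES)] else x)
    fs <- scale_features_minmax(X)
    feature_scaler <- fs$scaler
    Xin <- t(fs$train)
  } else {
    Xin <- as_image_matrix(x, spec$img_h)
  }
  if (ncol(Xin) != length(y))
    fw_domain_error("inputs (%d) and weights (%d) differ", ncol(Xin), length(y))
  cfg <- list(lr = config$lr, epochs = config$epochs,
              batch_size = config$batch_size, seed = config$seed,
              augment = isTRUE(config$augment) && spec$input == "image",
              image_input = spec$input == "image",
              img_h = spec$img_h, img_w = spec$img_w, chunk = config$chunk,
              head_bias = mean(y))  # output-bias init at the target mean
  fit <- .nn_train_cpp(spec$layers, Xin, y, cfg)
  structure(list(spec = spec, weights = fit$weights, biases = fit$biases,
                 loss = as.numeric(fit$loss), config = config,
                 feature_scaler = feature_scaler,
                 n_train = length(y)),
            class = "fw_nn")
}

#' Predict fresh weight with a trained neural model
#'
#' Deterministic inference (dropout inactive); returns grams.
#'
#' @param object an [fw_nn()] model
#' @param newdata features or images, in the same form used for training
#' @param ... unused
#' @return numeric vector of predicted weights, grams
#' @export
predict.fw_nn <- function(object, newdata, ...) {
  spec <- object$spec
  if (spec$input == "features") {
    X <- as.matrix(if (is.data.frame(newdata))
      newdata[, unname(FEATURE_NAMES)] else newdata)
    Xin <- t(minmax_transform(object$feature_scaler, X))
  } else {
    Xin <- as_image_matrix(newdata, spec$img_h)
  }
  cfg <- list(image_input = spec$input == "image",
              img_h = spec$img_h, img_w = spec$img_w,
              chunk = object$config$chunk)
  out <- .nn_predict_cpp(spec$layers, object$weights, object$biases, Xin, cfg)
  inverse_weight_scale(as.numeric(out), object$config$weight_scale)
}

#' @export
print.fw_nn <- function(x, ...) {
  cat(sprintf("Trained %s: %d epochs, final training MSE %.5f (scaled targets), n = %d\n",
              x$spec$name, length(x$loss), tail(x$loss, 1), x$n_train))
  invisible(x)
}

#' @export
summary.fw_nn <- function(object, ...) {
  print(object)
  cat(sprintf("  parameters: %s; lr %.4g, batch %d, seed %d\n",
              format(nn_param_count(object$spec), big.mark = ","),
              object$config$lr, object$config$batch_size, object$config$seed))
  invisible(object)
}

#' Per-image inference latency
#'
#' Median wall-clock milliseconds per image over repeated single-image
#' forward passes. Reported for model comparison only; absolute values are
#' hardware-bound.
#'
#' @param model an `fw_nn` (or `fw_polyreg`) model
#' @param inputs a non-empty list/matrix of inputs as accepted by `predict`
#' @param repetitions number of timed repetitions (>= 1)
#' @return milliseconds per image (median over repetitions)
#' @export
measure_inference_time <- function(model, inputs, repetitions = 10) {
  if (repetitions < 1) fw_domain_error("repetitions must be >= 1")
  single <- if (is.data.frame(inputs) || is.matrix(inputs)) {
    if (!nrow(inputs)) fw_domain_error("empty inputs")
    inputs[1, , drop = FALSE]
  } else if (is.list(inputs)) {
    if (!length(inputs)) fw_domain_error("empty input list")
    inputs[1]
  } else fw_domain_error("unsupported input container")
  times <- vapply(seq_len(repetitions), function(i) {
    t0 <- proc.time()[["elapsed"]]
    predict(model, single)
    (proc.time()[["elapsed"]] - t0) * 1000
  }, numeric(1))
  stats::median(times)
}
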