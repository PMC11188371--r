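test_that("architectures have the printed shapes and parameter counts", {
  m1 <- build_mlp_manual()
  expect_equal(m1$input_dim, 4)
  # 4*32+32 + 32*15+15 + 15*1+1, counted by hand
  expect_equal(nn_param_count(m1), 671)
  m2 <- build_mlp_image()
  expect_equal(m2$input_dim, 784)  # flattened 1 x 28 x 28
  expect_equal(nn_param_count(m2),
               784 * 1568 + 1568 + 1568 * 392 + 392 + 392 + 1)
  cnn <- build_cnn()
  expect_equal(nn_param_count(cnn),
               1 * 9 * 64 + 64 + 64 * 9 * 128 + 128 + 128 * 9 * 256 + 256 +
                 256 * 9 * 512 + 512 + 512 + 1)
  # residual flag leaves the printed four-stage stack structurally unchanged
  expect_equal(nn_param_count(build_cnn(residual = FALSE)),
               nn_param_count(cnn))
})

test_that("all three models map their input shape to one scalar per sample", {
  set.seed(7)
  feats <- data.frame(area_px = runif(9, 1000, 9000),
                      perimeter_px = runif(9, 100, 500),
                      major_px = runif(9, 50, 250), minor_px = runif(9, 40, 200))
  w <- runif(9, 5, 80)
  f1 <- fw_nn(build_mlp_manual(), feats, w, train_config("MLP_1", epochs = 3))
  expect_length(predict(f1, feats), 9)
  imgs <- lapply(1:7, function(i) matrix(runif(784), 28, 28))
  f2 <- fw_nn(build_mlp_image(), imgs, runif(7, 5, 80),
              train_config("MLP_2", epochs = 2))
  expect_length(predict(f2, imgs), 7)   # batch of 7 -> 7 scalars
  f3 <- fw_nn(build_cnn(), imgs, runif(7, 5, 80),
              train_config("CNN", epochs = 2))
  p3 <- predict(f3, imgs)
  expect_length(p3, 7)
  expect_true(all(is.finite(p3)))
  # dropout inactive at inference: repeated prediction identical
  expect_identical(predict(f1, feats), predict(f1, feats))
  # zero input still yields a finite scalar
  expect_true(is.finite(predict(f2, list(matrix(0, 28, 28)))))
})

test_that("identity skips wrap equal-width conv pairs and preserve shape", {
  stack <- list(
    list(type = "conv", n_in = 1, n_out = 8), list(type = "relu"),
    list(type = "conv", n_in = 8, n_out = 8), list(type = "relu"),
    list(type = "conv", n_in = 8, n_out = 8), list(type = "relu"),
    list(type = "gavgpool"),
    list(type = "dense", n_in = 8, n_out = 1))
  wrapped <- freshwt:::add_residual_skips(stack)
  types <- vapply(wrapped, `[[`, "", "type")
  expect_true("save" %in% types && "addfrom" %in% types)
  spec_res <- nn_spec("toy_res", wrapped, "image", 784)
  spec_plain <- nn_spec("toy", stack, "image", 784)
  expect_equal(nn_param_count(spec_res), nn_param_count(spec_plain))
  imgs <- lapply(1:5, function(i) matrix(runif(784), 28, 28))
  w <- runif(5, 10, 50)
  fit <- fw_nn(spec_res, imgs, w, train_config("CNN", epochs = 3))
  expect_length(predict(fit, imgs), 5)
})

test_that("image preparation is deterministic and flips are involutions", {
  img <- array(runif(90 * 120 * 3), dim = c(90, 120, 3))
  a <- prepare_image_input(img)
  b <- prepare_image_input(img)
  expect_identical(a, b)
  expect_equal(dim(a), c(28, 28))
  expect_true(all(a >= 0 & a <= 1))
  # flipping twice restores the original
  flipped <- a[, 28:1]
  expect_identical(flipped[, 28:1], a)
  # constant image maps to a constant tensor
  const <- prepare_image_input(array(0.5, dim = c(50, 60, 3)))
  expect_equal(max(const) - min(const), 0)
  expect_error(prepare_image_input(array(0, dim = c(0, 5, 3))),
               class = "fw_domain_error")
})

test_that("weight scaling follows the 0.01 protocol exactly", {
  expect_equal(scale_weight_for_training(34), 0.34)
  expect_equal(scale_weight_for_training(0), 0)
  w <- runif(20, 0, 150)
  expect_identical(inverse_weight_scale(scale_weight_for_training(w)), w)
  expect_error(scale_weight_for_training(-1), class = "fw_domain_error")
})

test_that("one optimiser step per epoch when the batch holds the train set", {
  expect_equal(iterations_per_epoch(263, 512), 1L)
  expect_equal(iterations_per_epoch(1000, 512), 2L)
  expect_equal(iterations_per_epoch(512, 512), 1L)
  expect_equal(iterations_per_epoch(513, 512), 2L)
})

test_that("training is seed-reproducible and the loss series shrinks", {
  ds <- fixture_dataset(60, seed = 5)
  mf <- ds$manifest
  cfg <- train_config("MLP_1", epochs = 150, seed = 4)
  f1 <- fw_nn(build_mlp_manual(), mf, mf$weight_g, cfg)
  f2 <- fw_nn(build_mlp_manual(), mf, mf$weight_g, cfg)
  expect_identical(f1$loss, f2$loss)
  expect_identical(f1$weights, f2$weights)
  expect_lt(tail(f1$loss, 1), f1$loss[1])
  expect_length(f1$loss, 150)
  # a different seed changes the trajectory
  f3 <- fw_nn(build_mlp_manual(), mf, mf$weight_g,
              train_config("MLP_1", epochs = 150, seed = 5))
  expect_false(identical(f1$loss, f3$loss))
})

test_that("a small conv net learns on synthetic images", {
  ds <- fixture_dataset(60, seed = 5)
  imgs <- memo("imgs60", lapply(ds$samples, function(s) prepare_image_input(s$image)))
  toy <- nn_spec("toy_cnn", list(
    list(type = "conv", n_in = 1, n_out = 8), list(type = "relu"),
    list(type = "maxpool2"),
    list(type = "conv", n_in = 8, n_out = 16), list(type = "relu"),
    list(type = "maxpool2"),
    list(type = "gavgpool"),
    list(type = "dense", n_in = 16, n_out = 1)), "image", 784)
  fit <- fw_nn(toy, imgs, ds$manifest$weight_g,
               train_config("CNN", epochs = 60, seed = 9))
  expect_lt(tail(fit$loss, 1), fit$loss[1])
  p <- predict(fit, imgs)
  expect_gt(cor(p, ds$manifest$weight_g), 0.7)
})

test_that("inference timing returns positive latencies for any repetitions", {
  ds <- fixture_dataset(60, seed = 5)
  mf <- ds$manifest
  fit <- fw_nn(build_mlp_manual(), mf, mf$weight_g,
               train_config("MLP_1", epochs = 5))
  t1 <- measure_inference_time(fit, mf, repetitions = 1)
  t2 <- measure_inference_time(fit, mf, repetitions = 20)
  expect_gte(t1, 0); expect_gte(t2, 0)
  expect_true(is.finite(t1) && is.finite(t2))
  expect_error(measure_inference_time(fit, list(), 5), class = "fw_domain_error")
})
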