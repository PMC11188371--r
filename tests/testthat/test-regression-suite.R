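test_that("the subset grid enumerates all 15 combinations in printed order", {
  ss <- enumerate_feature_subsets()
  expect_length(ss, 15)
  sizes <- lengths(ss)
  expect_equal(sum(sizes == 1), 4)   # simple models
  expect_equal(sum(sizes > 1), 11)   # multivariate models
  expect_equal(ss[[1]], "A")
  expect_equal(ss[[5]], c("A", "P"))
  expect_equal(ss[[15]], c("A", "P", "MA", "MI"))
  expect_false(any(duplicated(vapply(ss, paste, "", collapse = ","))))
})

minmax_inverse_for_test <- function(scaler, x)
  sweep(sweep(as.matrix(x), 2, scaler$max - scaler$min, "*"), 2, scaler$min, "+")

test_that("min-max scaling maps the training range onto [0, 1] invertibly", {
  sc <- scale_features_minmax(matrix(c(2, 4, 6), ncol = 1))
  expect_equal(as.vector(sc$train), c(0, 0.5, 1))
  X <- matrix(runif(40, 5, 50), 20, 2)
  sc2 <- scale_features_minmax(X)
  back <- minmax_inverse_for_test(sc2$scaler, sc2$train)
  expect_lt(max(abs(back - X)), 1e-9)
  # values above the training max extrapolate beyond 1 (no clipping)
  out <- scale_features_minmax(matrix(1:5, ncol = 1),
                               newdata = matrix(10, 1, 1))
  expect_gt(out$newdata[1, 1], 1)
  expect_error(scale_features_minmax(matrix(3, 5, 1)),
               class = "fw_degenerate_scale")
})

test_that("target standardisation yields mean 0 / sd 1 and inverts exactly", {
  st <- scale_target_standard(c(10, 20, 30))
  expect_equal(mean(st$train), 0)
  expect_equal(sd(st$train), 1)
  w <- runif(50, 1, 100)
  st2 <- scale_target_standard(w)
  expect_lt(max(abs(st2$train * st2$scaler$sd + st2$scaler$mean - w)), 1e-9)
  expect_error(scale_target_standard(rep(7, 10)),
               class = "fw_degenerate_scale")
})

test_that("polynomial bases have the combinatorially expected columns", {
  x1 <- matrix(seq_len(6), ncol = 1, dimnames = list(NULL, "x"))
  b3 <- expand_polynomial_basis(x1, 3)
  expect_equal(ncol(b3), 4)                       # 1, x, x^2, x^3
  expect_equal(b3[, 4], as.numeric((1:6)^3))
  X2 <- matrix(runif(12), 6, 2)
  expect_equal(ncol(expand_polynomial_basis(X2, 2)), choose(2 + 2, 2))  # 6
  X4 <- matrix(runif(40), 10, 4)
  expect_equal(ncol(expand_polynomial_basis(X4, 3)), choose(3 + 4, 4))  # 35
  # degree 1 is exactly the linear design
  b1 <- expand_polynomial_basis(X2, 1)
  expect_equal(unname(b1), unname(cbind(1, X2)))
  # powers-only mode drops cross terms
  expect_equal(ncol(expand_polynomial_basis(X2, 2, interactions = FALSE)), 5)
  expect_error(expand_polynomial_basis(X2, 4), class = "fw_domain_error")
})

test_that("OLS matches the normal-equations oracle on random systems", {
  for (seed in 1:5) {
    set.seed(seed)
    A <- matrix(rnorm(60), 20, 3)
    y <- rnorm(20)
    beta <- fit_ols(A, y)
    oracle <- solve(crossprod(A), crossprod(A, y))
    expect_lt(max(abs(beta - as.vector(oracle))), 1e-8)
  }
  # exact fits are recovered to numerical precision
  x <- seq(0, 1, length.out = 30)
  expect_equal(fit_ols(cbind(1, x), 1 + 2 * x), c(1, 2), tolerance = 1e-9)
  b <- fit_ols(expand_polynomial_basis(matrix(x, ncol = 1), 2), x^2)
  expect_equal(unname(b), c(0, 0, 1), tolerance = 1e-6)
  # rank deficiency: warning plus minimum-norm solution
  Ad <- cbind(1, x, 2 * x)
  expect_warning(bd <- fit_ols(Ad, 3 * x), "rank-deficient")
  expect_lt(max(abs(Ad %*% bd - 3 * x)), 1e-8)
  expect_error(fit_ols(matrix(1, 2, 3), 1:2), class = "fw_domain_error")
})

test_that("the fitted pipeline reproduces exact linear truths end to end", {
  d <- data.frame(area_px = seq(100, 3000, length.out = 40))
  d$weight_g <- 3 + 0.02 * d$area_px
  m <- fw_polyreg(d, "A", degree = 1)
  expect_lt(max(abs(predict(m, d) - d$weight_g)), 1e-6)
  expect_equal(m$train_r2, 1, tolerance = 1e-9)
  # noiseless allometric truth with k = 1 is linear in area
  law <- allometric_law(exponent_k = 1, noise_sd = 0, density_gain = 0)
  d2 <- data.frame(area_px = seq(500, 40000, length.out = 60))
  d2$weight_g <- allometric_weight(d2$area_px, law)
  m2 <- fw_polyreg(d2[1:40, ], "A", degree = 1)
  held <- d2[41:60, ]
  expect_gt(r_squared(held$weight_g, predict(m2, held)), 0.999999)
  expect_error(predict(m2, data.frame(perimeter_px = 1)),
               class = "fw_domain_error")
})

test_that("training R^2 never decreases with polynomial degree (nested OLS)", {
  ds <- fixture_dataset(60, seed = 5)
  mf <- ds$manifest
  for (ss in list("A", c("A", "P"), c("P", "MA", "MI"))) {
    r2s <- vapply(1:3, function(deg)
      fw_polyreg(mf, ss, deg)$train_r2, numeric(1))
    expect_true(all(diff(r2s) >= -1e-10))
  }
})

test_that("the grid holds 45 models and reapplication is deterministic", {
  ds <- fixture_dataset(60, seed = 5)
  mf <- ds$manifest
  sp <- split_dataset(nrow(mf), seed = 3)
  g1 <- fit_regression_grid(mf[sp$train, ], mf[sp$test, ])
  expect_equal(nrow(g1$results), 45)
  expect_equal(sum(g1$results$degree == 1 & !grepl(",", g1$results$subset)), 4)
  expect_equal(sum(g1$results$degree == 1 & grepl(",", g1$results$subset)), 11)
  expect_equal(sum(g1$results$degree > 1 & !grepl(",", g1$results$subset)), 8)
  expect_equal(sum(g1$results$degree > 1 & grepl(",", g1$results$subset)), 22)
  g2 <- fit_regression_grid(mf[sp$train, ], mf[sp$test, ])
  expect_identical(g1$results, g2$results)
  # lower residual sum of squares means higher R^2 and lower RMSE together
  ord_r2 <- order(g1$results$r2)
  expect_equal(ord_r2, order(g1$results$rmse_g, decreasing = TRUE))
})
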