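test_that("the shuffled split has the documented sizes and determinism", {
  sp <- split_dataset(376, seed = 1)
  expect_length(sp$train, 263)          # round(0.7 * 376)
  expect_length(sp$test, 113)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), 1:376)
  sp10 <- split_dataset(10, seed = 2)
  expect_length(sp10$train, 7)
  expect_length(sp10$test, 3)
  expect_identical(split_dataset(100, seed = 9), split_dataset(100, seed = 9))
  expect_false(identical(split_dataset(100, seed = 9)$train,
                         split_dataset(100, seed = 10)$train))
  expect_error(split_dataset(1), class = "fw_domain_error")
})

test_that("Pearson correlations match the closed form and its edge cases", {
  x <- rnorm(30)
  d <- data.frame(a = x, b = -x, c = x + rnorm(30, 0, 0.5))
  m <- pearson_corr_matrix(d, columns = c("a", "b", "c"))
  expect_equal(diag(m), c(a = 1, b = 1, c = 1))
  expect_equal(m["a", "b"], -1)
  expect_equal(m, t(m))
  expect_true(all(m >= -1 & m <= 1))
  # frozen scalar oracle for the 5-point table
  d5 <- data.frame(x = 1:5, y = c(2, 4, 5, 4, 5))
  m5 <- pearson_corr_matrix(d5, columns = c("x", "y"))
  expect_equal(m5["x", "y"], 0.7745966692, tolerance = 1e-9)
  expect_error(pearson_corr_matrix(data.frame(x = 1:5, y = rep(2, 5)),
                                   columns = c("x", "y")),
               class = "fw_domain_error")
})

test_that("R^2 and RMSE match hand-computed values", {
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(r_squared(c(1, 2, 3), rep(2, 3)), 0)
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 4)), 0.5)
  y <- runif(20); bad <- rev(sort(y))
  expect_lte(r_squared(y, bad), 1)
  expect_equal(rmse(c(1, 2), c(1, 2)), 0)
  expect_equal(rmse(c(0, 0), c(3, 4)), sqrt(12.5))
  # translation invariance
  expect_equal(rmse(y + 5, bad + 5), rmse(y, bad))
  expect_error(rmse(1:3, 1:4), class = "fw_domain_error")
  expect_error(r_squared(rep(1, 5), rep(1, 5)), class = "fw_domain_error")
})

test_that("the KDE integrates to one and matches the normal density", {
  set.seed(2)
  z <- rnorm(10000)
  k <- kde_curve(z)
  expect_true(all(k$density >= 0))
  dx <- diff(k$x[1:2])
  expect_lt(abs(sum(k$density) * dx - 1), 0.01)
  at0 <- k$density[which.min(abs(k$x))]
  expect_lt(abs(at0 - 1 / sqrt(2 * pi)) / (1 / sqrt(2 * pi)), 0.1)
  # doubling the sample shifts the support accordingly
  k2 <- kde_curve(2 * z)
  expect_equal(max(k2$x), 2 * max(k$x), tolerance = 0.05)
  expect_error(kde_curve(5), class = "fw_degenerate_scale")
  # identical inputs produce identical curves (perfect-model overlay)
  expect_identical(kde_curve(z), kde_curve(z))
})

test_that("the comparison report bundles grids, deep models and figures", {
  ds <- fixture_dataset(60, seed = 5)
  mf <- ds$manifest
  sp <- split_dataset(nrow(mf), seed = 3)
  grid <- fit_regression_grid(mf[sp$train, ], mf[sp$test, ])
  te <- mf[sp$test, ]
  set.seed(1)
  deep <- list(
    eval_report("MLP_1", te$weight_g, te$weight_g * runif(nrow(te), 0.8, 1.2), 0.1),
    eval_report("MLP_2", te$weight_g, te$weight_g * runif(nrow(te), 0.9, 1.1), 0.1),
    eval_report("CNN", te$weight_g, te$weight_g * runif(nrow(te), 0.95, 1.05), 0.5))
  corr <- pearson_corr_matrix(mf)
  td <- withr::local_tempdir()
  rep1 <- build_comparison_report(grid, deep, corr, out_dir = td)
  expect_equal(nrow(rep1$conventional), 45)
  expect_equal(nrow(rep1$deep), 3)
  expect_true(file.exists(file.path(td, "report.json")))
  expect_true(file.exists(file.path(td, "regression_results.csv")))
  expect_true(file.exists(file.path(td, "heatmap.png")))
  expect_true(file.exists(file.path(td, "kde_CNN.png")))
  # byte-identical JSON on rerun
  td2 <- withr::local_tempdir()
  build_comparison_report(grid, deep, corr, out_dir = td2)
  expect_identical(readLines(file.path(td, "report.json")),
                   readLines(file.path(td2, "report.json")))
  # missing correlation matrix: heatmap omitted with a notice
  expect_message(rep2 <- build_comparison_report(grid, deep, NULL),
                 "heatmap omitted")
  expect_null(rep2$correlation)
})
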