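test_that("growth-stage parameters respect boundaries and are reproducible", {
  cfg <- synth_config()
  p0 <- sample_plant_params(0, seed = 1)
  expect_equal(p0$leaf_count, cfg$leaf_count_range[1])
  expect_equal(p0$rosette_radius_px, cfg$radius_range[1])
  p1 <- sample_plant_params(1, seed = 1)
  expect_equal(p1$rosette_radius_px, cfg$radius_range[2])
  expect_gte(p1$leaf_count, p0$leaf_count)
  # determinism under a fixed seed
  expect_identical(sample_plant_params(0.5, seed = 7),
                   sample_plant_params(0.5, seed = 7))
  expect_error(sample_plant_params(1.2), class = "fw_domain_error")
  expect_error(sample_plant_params(-0.1), class = "fw_domain_error")
})

test_that("radius and leaf count are nondecreasing in stage", {
  stages <- seq(0, 1, by = 0.1)
  ps <- lapply(stages, sample_plant_params, seed = 3)
  radii <- vapply(ps, `[[`, numeric(1), "rosette_radius_px")
  leaves <- vapply(ps, `[[`, integer(1), "leaf_count")
  expect_true(all(diff(radii) >= 0))
  expect_true(all(diff(leaves) >= 0))
})

test_that("rendering produces a connected green rosette with matching mask", {
  p <- sample_plant_params(0.7, seed = 3)
  sc <- render_plant(p, seed = 4)
  expect_equal(dim(sc$truth_mask), dim(sc$image)[1:2])
  expect_equal(count_components_for_test(sc$truth_mask), 1L)
  # foreground is green-dominant, background dark
  exg <- sc$image[, , 2] - (sc$image[, , 1] + sc$image[, , 3]) / 2
  expect_gt(mean(exg[sc$truth_mask]), mean(exg[!sc$truth_mask]) + 0.1)
  # identical params + seed give identical bytes
  expect_identical(sc, render_plant(p, seed = 4))
  # oversize rosette is a configuration error
  big <- sample_plant_params(1, seed = 1)
  expect_error(render_plant(big, canvas_h = 100, canvas_w = 100),
               class = "fw_config_error")
})

test_that("truth-mask area scales like the squared rosette radius", {
  area_at <- function(stage) {
    p <- sample_plant_params(stage, seed = 9)
    sum(render_plant(p, seed = 9)$truth_mask)
  }
  r <- synth_config()$radius_range
  a1 <- area_at(0.25); a2 <- area_at(0.85)
  ratio_r2 <- ((r[1] + 0.85 * diff(r)) / (r[1] + 0.25 * diff(r)))^2
  expect_gt(a2 / a1, 0.5 * ratio_r2)
  expect_lt(a2 / a1, 2.0 * ratio_r2)
})

test_that("allometric law follows the stated power form", {
  # identity law: 10 mm^2 -> 10 g
  expect_equal(allometric_weight(10, allometric_law(1, 1, 0, 1)), 10)
  # frozen scalar oracle: 0.002 * 5000^1.3 computed independently
  expect_equal(allometric_weight(5000, allometric_law(0.002, 1.3, 0, 1)),
               128.733329, tolerance = 1e-6)
  # strict monotonicity without noise
  law0 <- allometric_law(noise_sd = 0)
  a <- seq(500, 50000, length.out = 25)
  expect_true(all(diff(allometric_weight(a, law0)) > 0))
  expect_error(allometric_weight(-5, law0), class = "fw_domain_error")
  expect_error(allometric_law(coefficient_c = -1), class = "fw_domain_error")
})

test_that("dataset generation is deterministic and writes a full manifest", {
  d1 <- generate_dataset(6, seed = 3)
  d2 <- generate_dataset(6, seed = 3)
  expect_identical(d1$manifest, d2$manifest)
  expect_identical(d1$samples[[4]]$image, d2$samples[[4]]$image)
  expect_equal(nrow(d1$manifest), 6)
  expect_named(d1$manifest, c("sample_id", "weight_g", "stage", "area_px",
                              "perimeter_px", "major_px", "minor_px"))
  expect_true(all(d1$manifest$weight_g > 0))
  # on-disk round trip: identical CSV bytes for identical seeds
  td1 <- withr::local_tempdir(); td2 <- withr::local_tempdir()
  generate_dataset(4, seed = 8, out_dir = td1)
  generate_dataset(4, seed = 8, out_dir = td2)
  expect_identical(unname(tools::md5sum(file.path(td1, "manifest.csv"))),
                   unname(tools::md5sum(file.path(td2, "manifest.csv"))))
  expect_length(list.files(file.path(td1, "images")), 4)
  expect_length(list.files(file.path(td1, "masks")), 4)
})

test_that("generator calibration ties weight tightly to area", {
  ds <- fixture_dataset(60, seed = 5)
  mf <- ds$manifest
  expect_gt(cor(mf$area_px, mf$weight_g), 0.8)
  # every feature correlates positively with weight
  for (col in c("area_px", "perimeter_px", "major_px", "minor_px"))
    expect_gt(cor(mf[[col]], mf$weight_g), 0)
})
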