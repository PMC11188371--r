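test_that("contours are closed boundaries with holes ignored", {
  sq <- square_mask(10)
  ct <- extract_contour(sq)
  expect_equal(ncol(ct), 2)
  expect_equal(nrow(ct), 4 * 9)  # 8-connected boundary of a 10x10 square
  d <- disk_mask(50)
  ctd <- extract_contour(d)
  expect_gt(nrow(ctd), 0)
  # boundary pixels only, all on the mask
  expect_true(all(d[cbind(ctd[, "y"], ctd[, "x"])]))
  # interior hole does not change the outer boundary
  dh <- d; dh[50:70, 50:70] <- FALSE
  expect_identical(extract_contour(dh), ctd)
  expect_error(extract_contour(matrix(FALSE, 4, 4)),
               class = "fw_segmentation_empty")
})

test_that("contour area matches brute-force pixel counts", {
  sq <- square_mask(100)
  a <- contour_area(extract_contour(sq))
  expect_lt(abs(a - 100^2) / 100^2, 0.02)
  for (r in c(20, 50, 80)) {
    d <- disk_mask(r)
    a <- contour_area(extract_contour(d))
    expect_lt(abs(a - sum(d)) / sum(d), 0.02)        # vs rasterised pixel count
    expect_lt(abs(a - pi * r^2) / (pi * r^2), 0.02)  # vs ideal disk
  }
  # single pixel: small positive value, not an error
  single <- matrix(FALSE, 5, 5); single[3, 3] <- TRUE
  expect_gt(contour_area(extract_contour(single)), 0)
})

test_that("contour perimeter matches ideal arc lengths within tolerance", {
  sq <- extract_contour(square_mask(100))
  expect_lt(abs(contour_perimeter(sq) - 400) / 400, 0.02)
  d <- extract_contour(disk_mask(50))
  expect_lt(abs(contour_perimeter(d) - 2 * pi * 50) / (2 * pi * 50), 0.05)
  # orientation invariance
  expect_equal(contour_perimeter(d), contour_perimeter(d[rev(seq_len(nrow(d))), ]))
})

test_that("ellipse fitting recovers generator axes and is rotation invariant", {
  ax <- fit_ellipse_axes(extract_contour(ellipse_mask(60, 30)))
  expect_lt(abs(ax[["major_px"]] - 120) / 120, 0.03)
  expect_lt(abs(ax[["minor_px"]] - 60) / 60, 0.03)
  # circle: both axes equal the diameter
  axd <- fit_ellipse_axes(extract_contour(disk_mask(50)))
  expect_lt(abs(axd[["major_px"]] - 100) / 100, 0.03)
  expect_lt(abs(axd[["minor_px"]] - 100) / 100, 0.03)
  # rotation by 37 degrees changes axes by < 1%
  axr <- fit_ellipse_axes(extract_contour(ellipse_mask(60, 30, theta = 37 * pi / 180)))
  expect_lt(abs(axr[["major_px"]] - ax[["major_px"]]) / ax[["major_px"]], 0.01)
  expect_lt(abs(axr[["minor_px"]] - ax[["minor_px"]]) / ax[["minor_px"]], 0.01)
  # fewer than 5 contour points cannot define an ellipse
  tiny <- matrix(FALSE, 6, 6); tiny[3, 3:4] <- TRUE
  expect_error(fit_ellipse_axes(extract_contour(tiny)),
               class = "fw_feature_undefined")
})

test_that("the composed feature vector satisfies its invariants", {
  for (mask in list(disk_mask(40), ellipse_mask(50, 25),
                    ellipse_mask(45, 40, theta = 1))) {
    f <- extract_features(mask)
    expect_named(f, c("area_px", "perimeter_px", "major_px", "minor_px"))
    expect_true(all(f > 0))
    expect_gte(f[["major_px"]], f[["minor_px"]])
    # isoperimetric inequality with rasterisation slack
    expect_gte(f[["perimeter_px"]]^2 * 1.01, 4 * pi * f[["area_px"]])
  }
  expect_error(extract_features(matrix(FALSE, 3, 3)),
               class = "fw_segmentation_empty")
})

test_that("features scale correctly with mask magnification", {
  base <- extract_features(disk_mask(30))
  for (s in c(2, 3)) {
    f <- extract_features(disk_mask(30 * s))
    expect_lt(abs(f[["area_px"]] / base[["area_px"]] - s^2) / s^2, 0.03)
    expect_lt(abs(f[["perimeter_px"]] / base[["perimeter_px"]] - s) / s, 0.03)
    expect_lt(abs(f[["major_px"]] / base[["major_px"]] - s) / s, 0.03)
    expect_lt(abs(f[["minor_px"]] / base[["minor_px"]] - s) / s, 0.03)
  }
})

test_that("segmentation-derived features agree with truth morphometrics", {
  ds <- fixture_dataset(60, seed = 5)
  idx <- c(10, 25, 40)
  for (i in idx) {
    s <- ds$samples[[i]]
    seg <- select_target_component(segment_plant(s$image))
    f <- extract_features(seg$mask)
    truth <- unlist(ds$manifest[i, c("area_px", "perimeter_px", "major_px",
                                     "minor_px")])
    # perimeter is boundary-length: median filtering smooths lobe concavities,
    # so it gets a wider band than the area/axis features
    tol <- c(area_px = 0.05, perimeter_px = 0.10, major_px = 0.05,
             minor_px = 0.05)
    for (k in names(f))
      expect_lt(abs(f[[k]] - truth[[k]]) / truth[[k]], tol[[k]])
  }
})

test_that("batch extraction drops undefined samples with a warning", {
  good <- disk_mask(20)
  bad <- matrix(FALSE, 8, 8); bad[4, 4] <- TRUE
  expect_warning(out <- extract_features_batch(list(a = good, b = bad)),
                 "dropped")
  expect_equal(out$sample_id, "a")
})
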