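test_that("resize reaches the working resolution from typical captures", {
  full <- array(runif(2464 * 3280 * 3), dim = c(2464, 3280, 3)) # 4:1 scale
  out <- resize_to_standard(full)
  expect_equal(dim(out), c(616, 820, 3))
  # exact block average on the 4:1 path
  expect_equal(out[1, 1, 1], mean(full[1:4, 1:4, 1]), tolerance = 1e-12)
  # identity on target size
  at_target <- array(runif(616 * 820 * 3), dim = c(616, 820, 3))
  expect_identical(resize_to_standard(at_target), at_target)
  # aspect-preserving 2:1 downscale
  half <- resize_to_standard(array(runif(1232 * 1640 * 3), dim = c(1232, 1640, 3)))
  expect_equal(dim(half), c(616, 820, 3))
  # portrait input is brought to landscape before scaling
  portrait <- resize_to_standard(array(runif(3280 * 2464 * 3), dim = c(3280, 2464, 3)))
  expect_equal(dim(portrait), c(616, 820, 3))
  expect_error(resize_to_standard(array(0, dim = c(0, 10, 3))),
               class = "fw_domain_error")
})

test_that("a pure green disk on black is segmented to its pixel area", {
  img <- array(0, dim = c(200, 200, 3))
  d <- disk_mask(60, pad = 40)[1:200, 1:200]
  img[, , 2][d] <- 0.8
  seg <- segment_plant(img)
  expect_s3_class(seg, "fw_segmentation")
  expect_lt(abs(sum(seg$mask) - sum(d)) / sum(d), 0.03)
  expect_equal(seg$component_count, 1L)
})

test_that("an all-background image raises the empty-segmentation signal", {
  set.seed(4)
  bg <- array(0.15 + rnorm(300 * 400 * 3, 0, 0.01), dim = c(300, 400, 3))
  expect_error(segment_plant(bg), class = "fw_segmentation_empty")
  expect_error(select_target_component(matrix(FALSE, 5, 5)),
               class = "fw_segmentation_empty")
})

test_that("segmentation is deterministic and recovers synthetic rosettes", {
  p <- sample_plant_params(0.6, seed = 21)
  sc <- render_plant(p, seed = 22)
  seg1 <- segment_plant(sc$image)
  seg2 <- segment_plant(sc$image)
  expect_identical(seg1$mask, seg2$mask)
  tgt <- select_target_component(seg1)
  expect_gte(mask_iou(tgt$mask, sc$truth_mask), 0.9)
  # distractors off: still accurate
  sc0 <- render_plant(p, distractor_intensity = 0, seed = 22)
  tgt0 <- select_target_component(segment_plant(sc0$image))
  expect_gte(mask_iou(tgt0$mask, sc0$truth_mask), 0.9)
})

test_that("largest-component selection follows the documented tie-breaks", {
  m <- matrix(FALSE, 120, 120)
  m[10:39, 10:39] <- TRUE      # 900 px
  m[80:99, 80:99] <- TRUE      # 400 px
  kept <- select_target_component(m)
  expect_true(all(kept[10:39, 10:39]))
  expect_false(any(kept[80:99, 80:99]))
  # single component: identity
  single <- matrix(FALSE, 50, 50); single[10:20, 10:20] <- TRUE
  expect_identical(select_target_component(single), single)
  # equal areas: smallest centroid row wins
  tie <- matrix(FALSE, 200, 60)
  tie[5:24, 20:39] <- TRUE     # centroid row ~14
  tie[95:114, 20:39] <- TRUE   # centroid row ~104
  kept2 <- select_target_component(tie)
  expect_true(all(kept2[5:24, 20:39]))
  expect_false(any(kept2[95:114, 20:39]))
  # idempotence
  expect_identical(select_target_component(kept2), kept2)
})

test_that("median filtering the mask does not fragment the target", {
  p <- sample_plant_params(0.5, seed = 31)
  sc <- render_plant(p, seed = 32)
  seg_nofilter <- segment_plant(sc$image, median_kernel = 0)
  seg_filter <- segment_plant(sc$image, median_kernel = 5)
  expect_lte(seg_filter$component_count, seg_nofilter$component_count)
  # the alternative order (filter the image first) also yields a good mask
  seg_alt <- select_target_component(
    segment_plant(sc$image, filter_image_first = TRUE))
  expect_gte(mask_iou(seg_alt$mask, sc$truth_mask), 0.85)
})
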