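test_that("lung segmentation overlaps the truth and avoids the border", {
  fx <- default_phantom()
  seg <- fx$lung$data
  union <- fx$ph$truth$lung$data | fx$ph$truth$airway$data
  dice <- 2 * sum(seg & union) / (sum(seg) + sum(union))
  expect_gte(dice, 0.99)
  d <- dim(seg)
  expect_identical(sum(seg[c(1, d[1]), , ]) + sum(seg[, c(1, d[2]), ]) +
                     sum(seg[, , c(1, d[3])]), 0L)
})

test_that("segmentation of an airless volume raises a no-lung error", {
  flat <- ct_volume(array(40, c(10, 10, 10)), c(1, 1, 1))
  expect_error(segment_lungs(flat), class = "fl_degenerate_error")
})

test_that("airway region growing recovers the lumen without contaminating lung", {
  fx <- default_phantom()
  aw <- fx$airway$data
  truth <- fx$ph$truth$airway$data
  expect_gte(sum(aw & truth) / sum(truth), 0.99)
  expect_lte(sum(aw & fx$ph$truth$lung$data) / sum(fx$ph$truth$lung$data),
             0.01)
})

test_that("a seed in soft tissue violates the growth precondition", {
  fx <- default_phantom()
  d <- dim(fx$ph$volume$data)
  ctr <- round(d / 2)
  # midline between the lungs is mediastinal soft tissue
  expect_gt(fx$ph$volume$data[ctr[1], ctr[2], ctr[3]], -320)
  expect_error(segment_airways(fx$ph$volume, seed_voxel = ctr),
               class = "fl_input_error")
  expect_error(segment_airways(fx$ph$volume, seed_voxel = c(-1, 5, 5)),
               class = "fl_input_error")
})

test_that("leak control halts growth at a wall breach and keeps the pre-leak region", {
  # straight lumen through soft tissue, breached into an emphysema-like
  # chamber that only becomes reachable once the threshold relaxes
  v <- array(40, c(40, 40, 40))
  v[20, 20, 10:40] <- -1000                    # lumen, opens at the top
  v[5:35, 5:35, 3:8] <- -930                   # chamber below
  v[20, 20, 9] <- -930                         # one-voxel breach
  vol <- ct_volume(v, c(1, 1, 1))
  lumen_n <- sum(v == -1000)
  aw <- segment_airways(vol, seed_voxel = c(20, 20, 40),
                        grow_threshold = -950, leak_factor = 2)
  expect_true(attr(aw, "leak_detected"))
  expect_identical(sum(aw$data), lumen_n)
  expect_lte(sum(aw$data), 2 * lumen_n)
})

test_that("mask refinement fills cavities, stays disjoint, and is idempotent", {
  lung <- array(FALSE, c(20, 20, 20))
  lung[5:15, 5:15, 5:15] <- TRUE
  lung[9:11, 9:11, 9:11] <- FALSE              # interior cavity
  airway <- array(FALSE, c(20, 20, 20))
  airway[7, 7, 5:15] <- TRUE                   # airway inside the lung
  ref <- refine_lung_mask(binary_mask(lung, "lung", c(1, 1, 1)),
                          binary_mask(airway, "airway", c(1, 1, 1)),
                          close_radius_mm = 0)
  expect_true(all(ref$data[9:11, 9:11, 9:11]))  # cavity filled
  expect_false(any(ref$data & airway))          # disjoint from airway
  # radius 0 is exactly hole-filled(lung - airway) minus airway
  expect_identical(ref$data, fill_holes(lung & !airway) & !airway)
  expect_error(refine_lung_mask(binary_mask(lung),
                                binary_mask(array(FALSE, c(5, 5, 5)))),
               class = "fl_input_error")

  fx <- default_phantom()
  again <- refine_lung_mask(fx$refined, fx$airway, 2, fx$ph$volume$spacing)
  expect_identical(again$data, fx$refined$data)
})

test_that("the %LAA profile tracks the truth-mask computation", {
  fx <- default_phantom()
  prof <- laa_profile(fx$ph$volume, fx$refined)
  hu <- fx$ph$volume$data[fx$ph$truth$lung$data]
  for (i in seq_len(nrow(prof))) {
    truth_pct <- 100 * mean(hu <= prof$threshold_hu[i])
    expect_lt(abs(prof$percent[i] - truth_pct), 1.0)
  }
  expect_true(all(diff(prof$percent) >= 0))
})

test_that("an emphysema-free lung has essentially no voxels below -950", {
  ph <- make_ct_phantom(phantom_spec(shape = c(64L, 64L, 64L),
                                     emphysema_fraction = 0, seed = 3L))
  prof <- laa_profile(ph$volume, ph$truth$lung)
  expect_lt(prof$percent[prof$threshold_hu == -950], 0.1)
})

test_that("laa_profile rejects an empty mask and mismatched shapes", {
  ph <- make_ct_phantom(phantom_spec(shape = c(24L, 24L, 24L)))
  empty <- binary_mask(array(FALSE, dim(ph$volume$data)))
  expect_error(laa_profile(ph$volume, empty), class = "fl_degenerate_error")
  wrong <- binary_mask(array(TRUE, c(4, 4, 4)))
  expect_error(laa_profile(ph$volume, wrong), class = "fl_input_error")
})

test_that("%LAA is invariant to axis relabelling", {
  ph <- make_ct_phantom(phantom_spec(shape = c(40L, 44L, 48L),
                                     emphysema_fraction = 0.3, seed = 2L))
  p1 <- laa_profile(ph$volume, ph$truth$lung)
  perm <- c(3, 1, 2)
  vol2 <- ct_volume(aperm(ph$volume$data, perm), ph$volume$spacing[perm])
  p2 <- laa_profile(vol2, binary_mask(aperm(ph$truth$lung$data, perm)))
  expect_identical(p1$percent, p2$percent)
})

test_that("the emphysema-function slope recovers constructed relationships", {
  # two-point line: (0.8, 5%) and (0.6, 15%) -> slope -50 %/unit ratio
  rec <- data.frame(subject = c("a", "b"), threshold_hu = -900,
                    percent = c(5, 15), fev_ratio = c(0.8, 0.6))
  fit <- laa_function_slope(rec)
  expect_equal(fit$slope, -50, tolerance = 1e-12)

  # constant %LAA gives slope 0
  flat <- data.frame(subject = letters[1:4], threshold_hu = -900,
                     percent = 7, fev_ratio = c(0.5, 0.6, 0.7, 0.8))
  expect_equal(laa_function_slope(flat)$slope, 0, tolerance = 1e-12)

  # noisy linear truth recovered within 3 SE
  set.seed(1)
  ratio <- runif(20, 0.4, 0.9)
  pct <- 40 - 45 * ratio + rnorm(20, 0, 0.5)
  rec2 <- data.frame(subject = sprintf("s%02d", 1:20), threshold_hu = -870,
                     percent = pct, fev_ratio = ratio)
  fit2 <- laa_function_slope(rec2)
  se <- summary(lm(pct ~ ratio))$coefficients[2, 2]
  expect_lt(abs(fit2$slope + 45), 3 * se)
  expect_gt(fit2$r_squared, 0.9)
})

test_that("degenerate emphysema-function designs are rejected", {
  one <- data.frame(subject = "a", threshold_hu = -900, percent = 5,
                    fev_ratio = 0.8)
  expect_error(laa_function_slope(one), class = "fl_degenerate_error")
  same <- data.frame(subject = c("a", "b"), threshold_hu = -900,
                     percent = c(5, 10), fev_ratio = c(0.7, 0.7))
  expect_error(laa_function_slope(same), class = "fl_degenerate_error")
  expect_error(laa_function_slope(data.frame(subject = "a")),
               class = "fl_input_error")
})
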