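# Sequential-labeling + HSI pipeline: hue+intensity thresholding, two-pass
# labeling, region selection, hole closing, masking, and the composed
# segmenter including its documented lip failure modes.

test_that("threshold_hue_intensity applies both the hue window and the intensity floor", {
  h <- matrix(c(0, 0, 90, NA), 2, 2)          # raw hue; shifted: 180, 180, 270, NA
  i <- matrix(c(0.05, 0.6, 0.6, 0.6), 2, 2)
  hsi <- structure(list(h = h, s = matrix(1, 2, 2), i = i), class = "hsi_image")
  got <- threshold_hue_intensity(hsi, seq_params(intensity_min = 0.15))
  expect_equal(got, matrix(c(FALSE, TRUE, FALSE, FALSE), 2, 2))
})

test_that("the dark boundary band separates tongue and lip into two components", {
  sc <- make_scene(scene_spec(noise_sigma = 0))
  f1 <- threshold_hue_intensity(rgb_to_hsi(sc$image), seq_params())
  lab <- oracle_label(f1, 4)
  expect_equal(max(lab), 2)                    # tongue and lip, nothing else
})

test_that("sequential_label matches the flood-fill oracle", {
  # diagonal adjacency distinguishes the connectivities
  m <- matrix(FALSE, 3, 3); m[1, 1] <- TRUE; m[2, 2] <- TRUE
  expect_equal(length(sequential_label(m, 4)$sizes), 2L)
  expect_equal(length(sequential_label(m, 8)$sizes), 1L)

  expect_equal(length(sequential_label(matrix(FALSE, 4, 4), 4)$sizes), 0L)

  full <- matrix(TRUE, 10, 10)
  lr <- sequential_label(full, 4)
  expect_equal(lr$sizes, 100L)

  set.seed(23)
  for (k in 1:25) {
    m <- random_mask(32, 32)
    for (conn in c(4L, 8L)) {
      lr <- sequential_label(m, conn)
      expect_equal(lr$labels, oracle_label(m, conn))
      expect_equal(sum(lr$sizes), sum(m))
      if (length(lr$sizes) > 0)
        expect_equal(sort(unique(lr$labels[lr$labels > 0])),
                     seq_along(lr$sizes))   # consecutive labels 1..K
    }
  }
})

test_that("select_region picks the largest region with deterministic tie-breaks", {
  m <- matrix(FALSE, 10, 10)
  m[1:4, 1:5] <- TRUE   # label 1, 20 px
  m[7:9, 1:3] <- TRUE   # label 2, 9 px
  lr <- sequential_label(m, 4)
  sel <- select_region(lr)
  expect_equal(sum(sel), 20)

  # equal sizes: smallest label (earliest in raster order) wins
  m2 <- matrix(FALSE, 10, 10)
  m2[1:2, 1:2] <- TRUE; m2[8:9, 8:9] <- TRUE
  sel2 <- select_region(sequential_label(m2, 4))
  expect_true(all(sel2[1:2, 1:2])); expect_false(any(sel2[8:9, 8:9]))

  expect_error(select_region(sequential_label(matrix(FALSE, 5, 5), 4)),
               class = "tongueseg_no_foreground")
})

test_that("select_region picks the lip when it outgrows the tongue substance", {
  # a heavily coated tongue: the in-window substance is only a thin ring,
  # smaller than the lip crescent -> the lip is selected (documented
  # failure mode of pure color thresholding)
  sc <- make_scene(scene_spec(coating_rgb = c(0.84, 0.84, 0.86),
                              coating_fraction = 0.75,
                              tongue_axes_frac = c(0.20, 0.17),
                              lip_outer_scale = 1.8, noise_sigma = 0))
  f1 <- threshold_hue_intensity(rgb_to_hsi(sc$image), seq_params())
  sel <- select_region(sequential_label(f1, 4))
  expect_equal(sum(sel & sc$truth), 0)        # selected region misses the tongue
  expect_gt(sum(sel), 0)
})

test_that("close_holes is extensive, idempotent, and fills small holes", {
  m <- matrix(FALSE, 30, 30); m[8:22, 8:22] <- TRUE
  m[14:16, 14:16] <- FALSE
  p <- seq_params(se_radius = 5)
  out <- close_holes(m, p)
  expect_true(all(out[14:16, 14:16]))         # hole filled
  expect_true(all(out[m]))                    # output superset of input
  expect_equal(close_holes(out, p), out)      # idempotent

  solid <- matrix(FALSE, 40, 40); solid[12:28, 12:28] <- TRUE
  expect_equal(close_holes(solid, p), solid)
  expect_equal(close_holes(matrix(FALSE, 10, 10), p), matrix(FALSE, 10, 10))
})

test_that("apply_mask conserves foreground values exactly and blanks background", {
  set.seed(3)
  img <- rgb_image(array(runif(8 * 8 * 3), c(8, 8, 3)))
  all_on <- matrix(TRUE, 8, 8)
  expect_equal(unclass(apply_mask(img, all_on)), unclass(img))
  expect_true(all(unclass(apply_mask(img, !all_on)) == 0))

  half <- matrix(rep(c(TRUE, FALSE), each = 32), 8, 8)
  out <- unclass(apply_mask(img, half))
  for (ch in 1:3) {
    expect_identical(out[, , ch][half], unclass(img)[, , ch][half])
    expect_true(all(out[, , ch][!half] == 0))
  }
  expect_error(apply_mask(img, matrix(TRUE, 4, 4)), class = "tongueseg_shape_error")
})

test_that("segment_sequential_hsi extracts uncoated tongues accurately", {
  for (nm in c("light_red", "deep_red")) {
    sc <- preset_scene(nm, rng_seed = 5)
    mt <- seg_metrics(confusion(segment_sequential_hsi(sc$image), sc$truth))
    expect_gte(mt$recognition, 0.9)
    expect_lte(mt$error, 0.05)
  }
})

test_that("a bright lip bridge makes the sequential mask leak into the lip", {
  sc <- preset_scene("thick_yellow_coating", rng_seed = 5, lip_bridge = TRUE)
  mt <- seg_metrics(confusion(segment_sequential_hsi(sc$image), sc$truth))
  expect_gt(mt$error, 0.2)                     # heavy false-positive leak
})

test_that("segment_sequential_hsi signals no-foreground on a tongue-free scene", {
  sc <- make_scene(scene_spec(tongue = FALSE, noise_sigma = 0))
  expect_error(segment_sequential_hsi(sc$image),
               class = "tongueseg_no_foreground")
})
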