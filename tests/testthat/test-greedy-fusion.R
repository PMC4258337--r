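# Greedy color/space fusion: predicates, seed selection, candidate ordering,
# region growth, and the composed segmenter with its structural invariants.

# hsi_image built directly from matrices (raw hue scale).
hsi_from <- function(h, s, i) structure(list(h = h, s = s, i = i),
                                        class = "hsi_image")

test_that("is_substance fuses hue window, saturation and intensity", {
  p <- fusion_params()
  expect_true(is_substance(0, 0.8, 0.5, p))        # shifted hue 180, bright
  expect_false(is_substance(270, 0.8, 0.5, p))     # shifted hue 90: yellow side
  expect_false(is_substance(NA, 0.8, 0.5, p))      # undefined hue
  expect_false(is_substance(0, 0.8, 0.1, p))       # too dark
  expect_false(is_substance(0, 0.05, 0.5, p))      # too desaturated
  # vectorized
  expect_equal(is_substance(c(0, 270, NA), c(0.8, 0.8, 0.8), c(0.5, 0.5, 0.5), p),
               c(TRUE, FALSE, FALSE))
})

test_that("is_coating_admissible requires color, intensity and enclosure", {
  p <- fusion_params(enclosure_min_neighbors = 2)
  h <- matrix(NA_real_, 5, 5); s <- matrix(0.05, 5, 5); i <- matrix(0.8, 5, 5)
  hsi <- hsi_from(h, s, i)

  lone <- greedy_state(matrix(0L, 5, 5))
  expect_false(is_coating_admissible(c(3, 3), hsi, lone, p))  # 0 accepted neighbors

  flags <- matrix(0L, 5, 5); flags[2, 2:4] <- 1L               # 3 substance neighbors
  st <- greedy_state(flags)
  expect_true(is_coating_admissible(c(3, 3), hsi, st, p))

  # dark crevice: intensity floor fails even with enclosure
  i2 <- i; i2[3, 3] <- 0.05
  expect_false(is_coating_admissible(c(3, 3), hsi_from(h, s, i2), st, p))

  # yellow-band coating pixel (raw hue 60 -> shifted 240)
  h3 <- h; h3[3, 3] <- 60
  s3 <- s; s3[3, 3] <- 0.6                                     # not white-like
  expect_true(is_coating_admissible(c(3, 3), hsi_from(h3, s3, i), st, p))
  # outside both coating rules
  h4 <- h3; h4[3, 3] <- 150
  expect_false(is_coating_admissible(c(3, 3), hsi_from(h4, s3, i), st, p))
})

test_that("best_candidate minimizes hue distance with insertion-order ties", {
  h <- matrix(c(3, 40, 3, NA), 2, 2) - 180    # shifted hues 3, 40, 3, NA
  h <- (h + 360) %% 360                        # back to raw scale
  hsi <- hsi_from(h, matrix(1, 2, 2), matrix(1, 2, 2))
  st <- greedy_state(matrix(0L, 2, 2),
                     frontier = rbind(c(1, 1), c(2, 1), c(1, 2), c(2, 2)),
                     hue_mean = 0)
  expect_equal(best_candidate(st, hsi), c(1, 1))   # dist 3 beats 40; first wins tie

  one <- greedy_state(matrix(0L, 2, 2), frontier = rbind(c(2, 2)), hue_mean = 0)
  expect_equal(best_candidate(one, hsi), c(2, 2))  # singleton, undefined hue still returned

  empty <- greedy_state(matrix(0L, 2, 2), hue_mean = 0)
  expect_error(best_candidate(empty, hsi), class = "tongueseg_empty_frontier")
})

test_that("select_seed validates explicit seeds and finds automatic ones", {
  sc <- preset_scene("red", rng_seed = 9)
  hsi <- rgb_to_hsi(sc$image)

  bright <- which(sc$truth & !sc$coating, arr.ind = TRUE)[200, ]
  expect_equal(select_seed(hsi, fusion_params(seed = bright)), unname(bright))

  dark <- c(1, 1)   # face corner: not substance
  expect_error(select_seed(hsi, fusion_params(seed = dark)),
               class = "tongueseg_seed_failure")

  auto <- select_seed(hsi, fusion_params())
  expect_true(sc$truth[auto[1], auto[2]])           # lands inside the tongue

  # no red region anywhere: seed failure
  flat <- rgb_to_hsi(rgb_image(array(rep(c(0.2, 0.8, 0.3), each = 400), c(20, 20, 3))))
  expect_error(select_seed(flat, fusion_params()),
               class = "tongueseg_seed_failure")
})

test_that("grow_region floods a uniformly red image completely", {
  img <- rgb_image(array(rep(c(0.8, 0.3, 0.35), each = 100), c(10, 10, 3)))
  hsi <- rgb_to_hsi(img)
  mask <- grow_region(hsi, c(5, 5), fusion_params())
  expect_true(all(mask))
  expect_true(all(attr(mask, "flags") == 1L))       # everything is substance
})

test_that("grow_region recovers a red disk and stops at the background", {
  r <- matrix(seq_len(40), 40, 40); c_ <- t(r)
  disk <- (r - 20)^2 + (c_ - 20)^2 <= 12^2
  img <- array(rep(c(0.2, 0.7, 0.3), each = 1600), c(40, 40, 3))  # green background
  for (ch in 1:3) { pl <- img[, , ch]; pl[disk] <- c(0.8, 0.3, 0.35)[ch]; img[, , ch] <- pl }
  mask <- grow_region(rgb_to_hsi(rgb_image(img)), c(20, 20), fusion_params())
  expect_equal(matrix(as.logical(mask), 40, 40), disk)
})

test_that("grow_region absorbs an enclosed white coating disk (annulus case)", {
  r <- matrix(seq_len(50), 50, 50); c_ <- t(r)
  d2 <- (r - 25)^2 + (c_ - 25)^2
  annulus <- d2 <= 18^2 & d2 > 9^2
  core <- d2 <= 9^2
  img <- array(rep(c(0.2, 0.7, 0.3), each = 2500), c(50, 50, 3))
  for (ch in 1:3) {
    pl <- img[, , ch]
    pl[annulus] <- c(0.8, 0.3, 0.35)[ch]     # red substance ring
    pl[core] <- c(0.85, 0.85, 0.87)[ch]      # bright white coating
    img[, , ch] <- pl
  }
  mask <- grow_region(rgb_to_hsi(rgb_image(img)), c(25, 10), fusion_params())
  expect_equal(matrix(as.logical(mask), 50, 50), annulus | core)
  flags <- attr(mask, "flags")
  expect_true(all(flags[annulus] == 1L))            # ring justified as substance
  expect_true(all(flags[core] %in% 2:3))            # core as coating or enclosed fill
  expect_false(any(mask & !(annulus | core)))       # rejected pixels never return
})

test_that("grow_region rejects a seed that violates the start conditions", {
  sc <- preset_scene("red", rng_seed = 1)
  hsi <- rgb_to_hsi(sc$image)
  expect_error(grow_region(hsi, c(1, 1), fusion_params()),
               class = "tongueseg_seed_failure")
})

test_that("greedy segmentation is accurate on every preset and structurally sound", {
  for (nm in names(tongue_presets())) {
    sc <- preset_scene(nm, rng_seed = 13)
    mask <- segment_greedy_fusion(sc$image)
    mt <- seg_metrics(confusion(mask, sc$truth))
    expect_gte(mt$recognition, 0.9)
    expect_lte(mt$error, 0.05)

    # one connected component containing the seed
    plain <- matrix(as.logical(mask), nrow(mask), ncol(mask))
    lr <- sequential_label(plain, 8)
    expect_equal(length(lr$sizes), 1L)
    seed <- attr(mask, "seed")
    expect_true(plain[seed[1], seed[2]])

    # audit trail: accepted pixels carry a justification flag, nothing else does
    flags <- attr(mask, "flags")
    expect_true(all(flags[plain] %in% 1:3))
    expect_true(all(flags[!plain] == 0L))
    # substance-flagged pixels genuinely satisfy the substance predicate
    hsi <- rgb_to_hsi(sc$image)
    sub <- flags == 1L
    expect_true(all(is_substance(hsi$h[sub], hsi$s[sub], hsi$i[sub], fusion_params())))
  }
})

test_that("the coating submask ends up inside the greedy mask", {
  sc <- preset_scene("thick_white_coating", rng_seed = 21)
  mask <- segment_greedy_fusion(sc$image)
  expect_true(all(mask[sc$coating]))
})

test_that("greedy growth excludes a lip separated by a dark boundary", {
  sc <- preset_scene("red", rng_seed = 17)
  mask <- segment_greedy_fusion(sc$image)
  hsi <- rgb_to_hsi(sc$image)
  # lip zone pixels: same hue as the tongue, bright, but unreachable
  lip <- !sc$truth & binarize_by_hue(hsi, morph_params()) &
    hsi$i >= fusion_params()$intensity_min
  expect_gt(sum(lip), 100)              # the decoy exists
  expect_equal(sum(mask & lip), 0)      # and is fully excluded
})

test_that("greedy segmentation is bit-reproducible and monotone-bounded", {
  sc <- preset_scene("thick_yellow_coating", rng_seed = 31)
  m1 <- segment_greedy_fusion(sc$image)
  m2 <- segment_greedy_fusion(sc$image)
  expect_identical(m1, m2)
  n <- length(sc$truth)
  expect_lte(attr(m1, "accepted"), n)
  expect_lte(attr(m1, "rejected"), n)
})
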