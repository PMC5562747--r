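test_that("blank channels segment to nothing, with a warning", {
  expect_warning(seg <- segment_channel(matrix(0, 32, 32)), "blank")
  expect_equal(nrow(seg$objects), 0)
})

test_that("a single bright disk yields one object of the right area", {
  img <- matrix(0, 64, 64)
  for (i in 1:64) for (j in 1:64)
    if ((i - 32)^2 + (j - 32)^2 <= 16) img[i, j] <- 200   # r = 4 disk
  seg <- segment_channel(img, viability_params(min_object_px = 10))
  expect_equal(nrow(seg$objects), 1)
  expect_equal(seg$objects$area, sum(img > 0))
  expect_equal(seg$objects$y, 31, tolerance = 0.05)   # 0-based centroid
})

test_that("labeling is 8-connected", {
  img <- matrix(0, 20, 20)
  img[3:6, 3:6] <- 200
  img[7:10, 7:10] <- 200     # touches the first block only diagonally
  p <- viability_params(min_object_px = 4,
                        channel_threshold_mode = "fixed",
                        fixed_thresholds = c(green = 100, red = 100))
  seg <- segment_channel(img, p)
  expect_equal(nrow(seg$objects), 1)
})

test_that("generated disks are counted exactly on clean renders", {
  gen <- generate_livedead_image(image_truth(30, 0, seed = 4))
  seg <- segment_channel(gen$img$green)
  expect_equal(nrow(seg$objects), 30)

  gen2 <- generate_livedead_image(image_truth(80, 20, seed = 5))
  res <- count_live_dead(gen2$img)
  expect_equal(res$live_count, 80)
  expect_equal(res$dead_count, 20)
  expect_equal(res$viability_pct, 80.0)
})

test_that("viability of an all-dead image is zero", {
  gen <- generate_livedead_image(image_truth(0, 10, seed = 6))
  expect_warning(res <- count_live_dead(gen$img), "blank")
  expect_equal(res$live_count, 0)
  expect_equal(res$dead_count, 10)
  expect_equal(res$viability_pct, 0)
})

test_that("dual-positive objects are counted once, as dead by default", {
  img <- matrix(0, 64, 64)
  for (i in 1:64) for (j in 1:64) {
    if ((i - 20)^2 + (j - 20)^2 <= 25) img[i, j] <- 200
  }
  g <- img
  for (i in 1:64) for (j in 1:64)
    if ((i - 45)^2 + (j - 45)^2 <= 25) g[i, j] <- 200   # extra green-only cell
  r <- img                                              # red matches cell 1
  p <- viability_params(min_object_px = 10,
                        channel_threshold_mode = "fixed",
                        fixed_thresholds = c(green = 100, red = 100))
  res <- count_live_dead(two_channel_image(g, r), p)
  expect_equal(res$n_dual, 1)
  expect_equal(res$live_count, 1)
  expect_equal(res$dead_count, 1)
  expect_equal(res$live_count + res$dead_count, 2)   # distinct physical cells

  p_live <- viability_params(min_object_px = 10,
                             channel_threshold_mode = "fixed",
                             fixed_thresholds = c(green = 100, red = 100),
                             dual_positive = "live")
  res2 <- count_live_dead(two_channel_image(g, r), p_live)
  expect_equal(res2$live_count, 2)
  expect_equal(res2$dead_count, 0)
})

test_that("adding a red-only cell never increases viability", {
  base <- count_live_dead(generate_livedead_image(
    image_truth(40, 10, seed = 9))$img)
  more_dead <- count_live_dead(generate_livedead_image(
    image_truth(40, 11, seed = 9))$img)
  expect_lte(more_dead$viability_pct, base$viability_pct)
})

test_that("channel-swap symmetry: swapping twice restores the result", {
  gen <- generate_livedead_image(image_truth(25, 15, blur_sigma_px = 1,
                                             noise_sd = 3, seed = 12))
  r1 <- count_live_dead(gen$img)
  swapped <- two_channel_image(gen$img$red, gen$img$green)
  reswapped <- two_channel_image(swapped$red, swapped$green)
  r2 <- count_live_dead(reswapped)
  expect_equal(r1$viability_pct, r2$viability_pct)
  expect_equal(r1$live_count, r2$live_count)
})
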