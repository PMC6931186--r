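test_that("soft Dice matches hand-counted values and handles degenerate input", {
  r <- array(0, c(4, 4)); r[1:2, 1] <- 1
  # perfect overlap
  expect_equal(soft_dice(r, r), 1, tolerance = 1e-6)
  # TP=2, FP=1, FN=1 -> 4/6 (counted by hand; equals the Eq-style value)
  p <- array(0, c(4, 4)); p[1, 1] <- 1; p[3, 1] <- 1; p[2, 2] <- 1
  r2 <- array(0, c(4, 4)); r2[1, 1] <- 1; r2[3, 1] <- 1; r2[4, 4] <- 1
  expect_equal(soft_dice(p, r2), 4 / 6, tolerance = 1e-6)
  # empty prediction scores zero against a nonempty target
  expect_equal(soft_dice(array(0, c(4, 4)), r), 0)
  expect_error(soft_dice(array(0, c(3, 3)), r), "differ")
})

test_that("soft Dice equals the counting Dice on binary input (randomized oracle)", {
  set.seed(42)
  for (rep in 1:25) {
    sh <- sample(3:8, 3, replace = TRUE)
    p <- random_mask(sh, p = runif(1, 0.05, 0.6))
    r <- random_mask(sh, p = runif(1, 0.05, 0.6))
    if (sum(p) + sum(r) == 0) next
    expect_equal(soft_dice(p, r), brute_dice(p, r), tolerance = 1e-5)
  }
})

test_that("two-channel loss spans [0,2] with the expected endpoints", {
  r <- random_mask(c(6, 6, 6), p = 0.3, seed = 9)
  expect_lt(two_channel_loss(list(p = r, q = 1 - r), r), 1e-5)
  expect_gt(two_channel_loss(list(p = 1 - r, q = r), r), 2 - 1e-5)
  # p = 0.5 everywhere against a direct summation oracle
  p <- array(0.5, dim(r))
  n <- length(r); f <- sum(r)
  d1 <- 2 * 0.5 * f / (n * 0.25 + f + 1e-7)
  d2 <- 2 * 0.5 * (n - f) / (n * 0.25 + (n - f) + 1e-7)
  expect_equal(two_channel_loss(p, r), 2 - d1 - d2, tolerance = 1e-10)
  # strictly decreasing toward the truth along convex combinations
  losses <- vapply(seq(0, 1, by = 0.25), function(a) {
    two_channel_loss(a * r + (1 - a) * (1 - r), r)
  }, numeric(1))
  expect_true(all(diff(losses) < 0))
})

test_that("dice_coefficient counts overlap per the 2TP/(2TP+FP+FN) rule", {
  m1 <- random_mask(c(5, 5, 5), seed = 1)
  expect_equal(dice_coefficient(m1, m1)$dice, 1)
  a <- array(0, c(3, 3, 3)); a[1, 1, 1] <- 1
  b <- array(0, c(3, 3, 3)); b[3, 3, 3] <- 1
  expect_equal(dice_coefficient(a, b)$dice, 0)
  # TP=3, FP=1, FN=2 -> 6/9
  p <- array(0, c(4, 4, 4)); p[1:4, 1, 1] <- 1
  t <- array(0, c(4, 4, 4)); t[1:3, 1, 1] <- 1; t[1:2, 2, 1] <- 1
  dr <- dice_coefficient(p, t)
  expect_equal(c(dr$TP, dr$FP, dr$FN), c(3, 1, 2))
  expect_equal(dr$dice, 6 / 9)
  # empty vs empty agrees perfectly on absence
  z <- array(0, c(3, 3, 3))
  expect_equal(dice_coefficient(z, z)$dice, 1)
  expect_error(dice_coefficient(array(0.5, c(3, 3, 3)), z), "binary")
  # symmetry
  expect_equal(dice_coefficient(m1, random_mask(c(5, 5, 5), seed = 2))$dice,
               dice_coefficient(random_mask(c(5, 5, 5), seed = 2), m1)$dice)
})

test_that("lesion size classification applies the 20x20x25 mm bounding-box rule", {
  mk <- function(ext) { # ext in voxels as (IS, PA, LR)
    m <- array(0, c(40, 40, 40))
    m[seq_len(ext[1]), seq_len(ext[2]), seq_len(ext[3])] <- 1
    lesion_mask(m)
  }
  # extents (x,y,z) = (19,19,24) mm -> small (z is the IS axis)
  expect_equal(classify_lesion_size(mk(c(24, 19, 19))), "small")
  # one axis over threshold -> large
  expect_equal(classify_lesion_size(mk(c(24, 19, 21))), "large")
  # boundary equality counts as large
  expect_equal(classify_lesion_size(mk(c(25, 19, 19))), "large")
  expect_equal(classify_lesion_size(mk(c(24, 20, 19))), "large")
  # single voxel at 1 mm spacing is small
  one <- array(0, c(16, 16, 16)); one[8, 8, 8] <- 1
  expect_equal(classify_lesion_size(lesion_mask(one)), "small")
  # spacing scales the extents: 7 voxels at 3 mm IS spacing = 21 mm < 25
  m <- array(0, c(16, 16, 16)); m[1:7, 1, 1] <- 1
  expect_equal(classify_lesion_size(lesion_mask(m, spacing = c(3, 1, 1))), "small")
  m[1:9, 1, 1] <- 1 # 27 mm -> large
  expect_equal(classify_lesion_size(lesion_mask(m, spacing = c(3, 1, 1))), "large")
  expect_error(classify_lesion_size(lesion_mask(array(0, c(4, 4, 4)))), "empty")
})

test_that("wilcoxon_rank_sum matches exact enumeration for tie-free small samples", {
  # x = {1,2}, y = {3,4}: all mass in one tail of C(4,2)=6 assignments
  expect_equal(wilcoxon_rank_sum(c(1, 2), c(3, 4)), 2 / 6, tolerance = 1e-12)
  set.seed(7)
  for (rep in 1:20) {
    nx <- sample(2:6, 1); ny <- sample(2:6, 1)
    x <- sample(seq_len(50), nx); y <- sample(seq(51, 120), ny)
    y <- sample(c(x + 0.5, y), ny) # interleave, keep tie-free
    expect_equal(wilcoxon_rank_sum(x, y), enum_wilcoxon(x, y),
                 tolerance = 1e-9)
  }
  # symmetry under swapping the samples
  x <- c(0.3, 1.8, 2.2); y <- c(1.1, 2.9, 4.4)
  expect_equal(wilcoxon_rank_sum(x, y), wilcoxon_rank_sum(y, x))
  # identical samples are not distinguishable
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_error(wilcoxon_rank_sum(numeric(0), 1), "nonempty")
})

test_that("the exact and approximate rank-sum p-values agree closely at n = 6 + 6", {
  set.seed(11)
  for (rep in 1:10) {
    x <- rnorm(6); y <- rnorm(6, mean = runif(1, 0, 1.5))
    exact <- wilcoxon_rank_sum(x, y) # n = 12 tie-free -> exact branch
    approx <- suppressWarnings(
      stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value)
    expect_lt(abs(exact - approx), 0.02)
  }
})
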