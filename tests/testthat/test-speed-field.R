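test_that("speed_at returns the region speeds prescribed by the disc geometry", {
  pat <- speed_pattern(0.4, 1.2, 1, R = 10, delta = 3,
                       disc_center = c(30, 30))
  L <- 60
  # strictly inside the fast half, regardless of delta
  expect_equal(speed_at(pat, c(30 + 5, 30), L), 1.2)
  # mirror point on the slow side
  expect_equal(speed_at(pat, c(30 - 5, 30), L), 0.4)
  # background at twice the disc radius
  expect_equal(speed_at(pat, c(30, 30 + 20), L), 1)
  # tie-breaking: dividing diameter belongs to the slow half, the rim is
  # inside the disc
  expect_equal(speed_at(pat, c(30, 30 + 5), L), 0.4)
  expect_equal(speed_at(pat, c(30, 30 + 10), L), 0.4)
  # minimum image: the disc wraps across the periodic boundary
  pat2 <- speed_pattern(0.4, 1.2, 1, R = 10, disc_center = c(1, 1))
  expect_equal(speed_at(pat2, c(59, 59), L), 0.4)
  expect_equal(speed_at(pat2, c(4, 1), L), 1.2)
})

test_that("speed_at rejects non-finite points and invalid patterns", {
  pat <- speed_pattern(0.4, 1.2, 1, R = 10)
  expect_error(speed_at(pat, c(NA, 1), 60), "non-finite")
  expect_error(speed_pattern(1.2, 0.4, 1, R = 10), "v_minus")
  expect_error(speed_pattern(-1, 1, 1, R = 10), ">= 0")
  expect_error(speed_pattern(0.4, 1.2, 1, R = -1), "R must be")
})

test_that("region classification is exhaustive, exclusive, and has the right areas", {
  set.seed(42)
  L <- 60
  pat <- speed_pattern(0.4, 1.2, 1, R = 10, delta = -2,
                       disc_center = c(25, 35))
  n <- 1e5
  pts <- cbind(runif(n, 0, L), runif(n, 0, L))
  lab <- region_at(pat, pts, L)
  counts <- table(factor(lab, levels = c("slow", "fast", "background")))
  expect_equal(sum(counts), n)
  # Monte-Carlo half-disc areas: pi R^2 / 2 each, within 4 sd of the
  # binomial sampling error
  p_half <- pi * pat$R^2 / 2 / L^2
  tol <- 4 * sqrt(n * p_half * (1 - p_half))
  expect_lt(abs(counts[["slow"]] - n * p_half), tol)
  expect_lt(abs(counts[["fast"]] - n * p_half), tol)
})

test_that("swapping v- and v+ is the mirror image of negating the axis", {
  set.seed(7)
  L <- 40
  pts <- cbind(runif(500, 0, L), runif(500, 0, L))
  a <- speed_pattern(0.4, 1.2, 1, R = 8, disc_center = c(20, 20),
                     axis = c(1, 0))
  b <- speed_pattern(0.4, 1.2, 1, R = 8, disc_center = c(20, 20),
                     axis = c(-1, 0))
  va <- speed_at(a, pts, L)
  vb <- speed_at(b, pts, L)
  swap <- function(v) ifelse(v == 0.4, 1.2, ifelse(v == 1.2, 0.4, v))
  # off the dividing diameter (measure zero for random points) the swapped
  # speeds match the mirrored pattern
  expect_equal(vb, swap(va))
})

test_that("update_disc locks the bead at offset delta and is idempotent", {
  L <- 60
  pat <- speed_pattern(0.4, 1.2, 1, R = 10, delta = 0)
  p1 <- update_disc(pat, c(0, 0), L)
  expect_equal(p1$disc_center, c(0, 0))
  # delta = -8a puts the disc centre 8a ahead of the bead along the axis
  a <- 1.25
  pat2 <- speed_pattern(0.4, 1.2, 1, R = 8 * a, delta = -8 * a)
  p2 <- update_disc(pat2, c(0, 0), L)
  expect_equal(p2$disc_center, c(8 * a, 0))
  # the bead then sits on the rim: the slow/background interface
  expect_equal(region_at(p2, c(0, 0), L), "slow")
  expect_equal(region_at(p2, c(-1e-9, 0), L), "background")
  # idempotent for a fixed bead position
  expect_identical(update_disc(p2, c(0, 0), L), p2)
})

test_that("intensity calibration interpolates the anchor measurements", {
  cal <- intensity_calibration()
  expect_equal(intensity_to_speed(cal, 0.9), 19)
  expect_equal(intensity_to_speed(cal, 0.1), 7)
  expect_equal(intensity_to_speed(cal, 0.7), 17)
  # monotone piecewise-linear in between
  expect_equal(intensity_to_speed(cal, 0.4), 12)
  expect_error(intensity_to_speed(cal, 1.5), "outside")
  expect_error(intensity_calibration(data.frame(intensity = c(0.1, 0.9),
                                                speed = c(19, 7))),
               "non-decreasing")
})
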