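test_that("kinetic energy follows 0.5 v^2 with the earlier-frame convention", {
  tr <- data.frame(frame = 0:3, x = c(0, 0.3, 0.6, 0.9),
                   y = c(0, 0.4, 0.8, 1.2))
  ke <- kinetic_energy(tr, dt = 1)
  expect_equal(length(ke), 3L)               # one shorter than the track
  expect_equal(ke$values, rep(0.125, 3))     # speed 0.5 -> KE 1/8
  expect_equal(ke$frames, 0:2)

  still <- data.frame(frame = 0:5, x = rep(2, 6), y = rep(-1, 6))
  expect_equal(kinetic_energy(still)$values, rep(0, 5))

  two <- data.frame(frame = 0:1, x = c(0, 1), y = c(0, 0))
  expect_equal(length(kinetic_energy(two, dt = 1)), 1L)
})

test_that("kinetic energy is invariant under translation and rotation", {
  set.seed(11)
  for (rep in 1:5) {
    n <- 40
    tr <- data.frame(frame = seq_len(n), x = cumsum(rnorm(n)),
                     y = cumsum(rnorm(n)))
    th <- runif(1, 0, 2 * pi)
    sh <- runif(2, -50, 50)
    tr2 <- data.frame(
      frame = tr$frame,
      x = cos(th) * tr$x - sin(th) * tr$y + sh[1],
      y = sin(th) * tr$x + cos(th) * tr$y + sh[2])
    expect_equal(kinetic_energy(tr2)$values, kinetic_energy(tr)$values,
                 tolerance = 1e-10)
  }
})

test_that("non-uniform frame spacing is rejected with the first gap named", {
  tr <- data.frame(frame = c(0, 1, 3, 4), x = rnorm(4), y = rnorm(4))
  expect_error(kinetic_energy(tr), "frames 1 and 3")
})

test_that("log_resample keeps every stride-th sample and guards zeros", {
  s <- cell_series(1L, 0:14999, runif(15000, 0, 4))
  r <- log_resample(s, stride = 5L)
  expect_equal(length(r), 3000L)             # 15000 frames -> 3000 samples
  expect_true(r$transformed)
  expect_equal(r$stride, 5L)

  r1 <- log_resample(s, stride = 1L)
  expect_equal(length(r1), length(s))        # stride 1 leaves count unchanged

  z <- cell_series(2L, 0:99, c(0, runif(99, 0.5, 2)))
  rz <- log_resample(z, stride = 1L)
  expect_true(all(is.finite(rz$values)))     # zero KE maps to finite log
})

test_that("phase terciles partition any lifetime and the remainder goes last", {
  s300 <- cell_series(1L, 0:299, runif(300))
  seg <- segment_phases(s300, window_samples = 100L)
  expect_equal(seg$early, c(1L, 100L))
  expect_equal(seg$middle, c(101L, 200L))
  expect_equal(seg$last, c(201L, 300L))

  s301 <- cell_series(1L, 0:300, runif(301))
  seg1 <- segment_phases(s301, window_samples = 100L)
  expect_equal(seg1$last[2] - seg1$last[1] + 1L, 101L)  # extra sample lands last

  set.seed(3)
  for (n in sample(3:500, 25)) {
    s <- cell_series(1L, seq_len(n), runif(n))
    sg <- segment_phases(s, window_samples = min(10L, n))
    covered <- c(seq(sg$early[1], sg$early[2]),
                 seq(sg$middle[1], sg$middle[2]),
                 seq(sg$last[1], sg$last[2]))
    expect_equal(covered, seq_len(n))        # disjoint cover, no overlap
  }
})

test_that("the central window is centered and clips with a warning", {
  s <- cell_series(1L, 0:2999, runif(3000))
  seg <- segment_phases(s, window_samples = 3000L)
  expect_equal(seg$central_window, c(1L, 3000L))  # window = whole lifetime
  expect_false(seg$clipped)

  expect_warning(seg2 <- segment_phases(s, window_samples = 4000L),
                 "clipped")
  expect_true(seg2$clipped)
})

test_that("mean_field averages contemporaries and drops the focal", {
  mk <- function(id, vals) cell_series(id, seq_along(vals), vals,
                                       transformed = TRUE)
  two <- list(`1` = mk(1, c(1, 2, 3)), `2` = mk(2, c(5, 6, 7)))
  ctx <- mean_field(two, 1L)
  expect_equal(ctx$values, c(5, 6, 7))       # N = 2: context is the sibling

  three <- c(two, list(`3` = mk(3, c(1, 0, -1))))
  ctx3 <- mean_field(three, 1L)
  expect_equal(ctx3$values, c(3, 3, 3))      # mean of 5,1 / 6,0 / 7,-1

  expect_error(mean_field(list(`1` = mk(1, 1:3)), 1L), "contemporar")
})

test_that("mean_field commutes with relabeling of sibling ids", {
  set.seed(5)
  mk <- function(id, vals) cell_series(id, seq_along(vals), vals,
                                       transformed = TRUE)
  vals <- replicate(4, rnorm(20), simplify = FALSE)
  a <- list(`1` = mk(1, vals[[1]]), `2` = mk(2, vals[[2]]),
            `3` = mk(3, vals[[3]]), `4` = mk(4, vals[[4]]))
  b <- list(`1` = mk(1, vals[[1]]), `9` = mk(9, vals[[4]]),
            `5` = mk(5, vals[[3]]), `7` = mk(7, vals[[2]]))
  expect_equal(mean_field(a, 1L)$values, mean_field(b, 1L)$values)
})

test_that("coarse_grain averages blocks, drops the tail, and composes", {
  s <- cell_series(1L, 1:4, c(1, 2, 3, 4), transformed = TRUE)
  expect_equal(coarse_grain(s, 2L)$values, c(1.5, 3.5))
  expect_identical(coarse_grain(s, 1L), s)

  s11 <- cell_series(1L, 1:11, as.numeric(1:11), transformed = TRUE)
  expect_equal(length(coarse_grain(s11, 5L)), 2L)   # trailing 1 dropped
  expect_error(coarse_grain(s11, 12L), "exceeds")

  set.seed(7)
  s60 <- cell_series(1L, 1:60, rnorm(60), transformed = TRUE)
  expect_equal(coarse_grain(coarse_grain(s60, 2L), 3L)$values,
               coarse_grain(s60, 6L)$values)
  dt6 <- coarse_grain(s60, 6L)
  expect_equal(dt6$stride, 6L)               # effective sampling interval scales
})
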