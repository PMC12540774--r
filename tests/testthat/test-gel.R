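test_that("background subtraction flattens offsets and preserves band areas", {
  flat <- lane_profile(1:100, rep(50, 100))
  expect_equal(subtract_background(flat)$intensity, rep(0, 100),
               tolerance = 1e-4)
  # single Gaussian band on a constant offset: area recovered within 2%
  s <- gen_gel_lane(seed = 1, extended_yields = numeric(0), baseline = 10,
                    noise_sd = 0, total_signal = 1000)
  sub <- subtract_background(s$profile)
  expect_equal(sum(sub$intensity), 1000, tolerance = 0.02)
  # linear ramp under two bands: band-area ratio preserved within 3%
  pos <- 1:300
  ramp <- 5 + 0.05 * pos
  two <- ramp + 700 * dnorm(pos, 80, 6) + 300 * dnorm(pos, 220, 6)
  lane <- subtract_background(lane_profile(pos, two))
  a1 <- sum(lane$intensity[pos >= 56 & pos <= 104])
  a2 <- sum(lane$intensity[pos >= 196 & pos <= 244])
  expect_equal(a1 / a2, 700 / 300, tolerance = 0.03)
  # the rolling-minimum alternative handles flat offsets too, but its
  # window must fit inside the profile
  expect_equal(subtract_background(flat, method = "rollmin")$intensity,
               rep(0, 100))
  expect_error(subtract_background(flat, method = "rollmin",
                                   band_width = 40), "window")
})

test_that("band quantification computes yield fractions", {
  pos <- 1:200
  y <- 10 + 900 * dnorm(pos, 60, 5) + 100 * dnorm(pos, 150, 5)
  p <- lane_profile(pos, y)
  q <- quantify_bands(p, list(unextended = c(130, 170),
                              extended_1 = c(40, 80)))
  # first window is whichever species list names it; extended defaults to
  # all but the first entry
  expect_equal(q$yield_fraction, 0.9, tolerance = 0.01)
  expect_equal(sum(q$band_fractions), 1)
  # all signal unextended
  y0 <- 10 + 1000 * dnorm(pos, 60, 5)
  q0 <- quantify_bands(lane_profile(pos, y0),
                       list(un = c(40, 80), ext = c(130, 170)))
  expect_equal(q0$yield_fraction, 0, tolerance = 0.005)
  expect_error(quantify_bands(p, list(c(40, 80), c(70, 120))), "overlap")
})

test_that("planted lane yields are recovered within 2 points under noise", {
  for (seed in c(2, 5)) {
    s <- gen_gel_lane(seed = seed, extended_yields = c(0.1, 0.2, 0.3),
                      noise_sd = 0.5)
    q <- quantify_bands(s$profile, s$windows)
    expect_equal(q$yield_fraction, 0.6, tolerance = 0.02 / 0.6)
  }
})

test_that("yields are invariant under profile scaling and windows are additive", {
  s <- gen_gel_lane(seed = 3)
  q1 <- quantify_bands(s$profile, s$windows)
  scaled <- s$profile
  scaled$intensity <- scaled$intensity * 17
  q2 <- quantify_bands(scaled, s$windows)
  expect_equal(q2$yield_fraction, q1$yield_fraction, tolerance = 1e-9)
  # splitting one window into two contiguous halves conserves intensity
  w <- s$windows[[2]]
  mid <- floor(mean(w))
  split_wins <- c(s$windows[-2], list(a = c(w[1], mid), b = c(mid + 1, w[2])))
  q3 <- quantify_bands(s$profile, split_wins)
  expect_equal(sum(q3$band_intensities[c("a", "b")]),
               unname(q1$band_intensities[2]), tolerance = 1e-12)
})

test_that("time courses keep lane order by timepoint", {
  lanes <- lapply(list(c(0.1, 1), c(0.5, 3), c(0.9, 24)), function(yt) {
    gen_gel_lane(seed = 7, extended_yields = yt[1], timepoint = yt[2])$profile
  })
  wins <- gen_gel_lane(seed = 7, extended_yields = 0.1)$windows[1:2]
  tc <- timecourse(lanes[c(3, 1, 2)], wins)
  expect_equal(tc$timepoint, c(1, 3, 24))
  expect_true(all(diff(tc$yield_fraction) > 0))
  dup <- lanes[c(1, 1)]
  expect_warning(timecourse(dup, wins), "duplicate")
  # identical lanes give identical yields
  tc2 <- suppressWarnings(timecourse(dup, wins))
  expect_equal(tc2$yield_fraction[1], tc2$yield_fraction[2])
})
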