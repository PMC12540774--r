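mk_two_beads <- function(d, sigma = c(0.5, 0.5), box = c(10, 10, 10)) {
  cg_frame(data.frame(chain = c("a", "b"), type = "U", sigma = sigma,
                      x = c(1, 1 + d), y = 1, z = 1,
                      stringsAsFactors = FALSE), box)
}

test_that("CG contact cutoff is 0.5(sigma_i + sigma_j) + 0.1 nm, strict", {
  expect_equal(nrow(cg_contact_pairs(mk_two_beads(0.55))), 1L)
  expect_equal(nrow(cg_contact_pairs(mk_two_beads(0.60))), 0L)
  # asymmetric sigmas: cutoff 0.5(0.3 + 0.7) + 0.1 = 0.6
  expect_equal(nrow(cg_contact_pairs(mk_two_beads(0.59, c(0.3, 0.7)))), 1L)
  expect_equal(nrow(cg_contact_pairs(mk_two_beads(0.61, c(0.3, 0.7)))), 0L)
})

test_that("missing sigma raises an error naming the bead type", {
  b <- data.frame(chain = "a", type = "Q", sigma = NA_real_,
                  x = 1, y = 1, z = 1, stringsAsFactors = FALSE)
  expect_error(cg_frame(b, c(5, 5, 5)), "Q")
})

test_that("contacts use the minimum image and bonded neighbours are excluded", {
  # beads near opposite box faces are neighbours through the boundary
  b <- data.frame(chain = c("a", "b"), type = "U", sigma = 0.5,
                  x = c(0.1, 9.9), y = 1, z = 1, stringsAsFactors = FALSE)
  expect_equal(nrow(cg_contact_pairs(cg_frame(b, c(10, 10, 10)))), 1L)
  # consecutive beads of one chain are bonded and skipped by default
  b2 <- data.frame(chain = "a", type = "U", sigma = 0.5,
                   x = c(1, 1.3, 1.55), y = 1, z = 1,
                   stringsAsFactors = FALSE)
  fr2 <- cg_frame(b2, c(10, 10, 10))
  got <- cg_contact_pairs(fr2)
  expect_equal(nrow(got), 1L)          # only the 1-3 pair
  expect_equal(c(got$i, got$j), c(1L, 3L))
  expect_equal(nrow(cg_contact_pairs(fr2, exclude_bonded = FALSE)), 3L)
})

test_that("CG pairs equal O(N^2) brute force and respect box translations", {
  set.seed(31)
  for (rep in 1:3) {
    n <- 60
    b <- data.frame(chain = paste0("c", rep(1:12, each = 5)), type = "U",
                    sigma = runif(n, 0.3, 0.7),
                    x = runif(n, 0, 6), y = runif(n, 0, 6),
                    z = runif(n, 0, 6), stringsAsFactors = FALSE)
    fr <- cg_frame(b, c(6, 6, 6))
    got <- cg_contact_pairs(fr)
    keys <- if (nrow(got)) sort(paste(got$i, got$j, sep = "|")) else character(0)
    expect_identical(keys, oracle_cg_pairs(fr))
    # translate through the periodic box: identical pair set
    b2 <- b
    b2$x <- (b2$x + 2.5) %% 6
    got2 <- cg_contact_pairs(cg_frame(b2, c(6, 6, 6)))
    keys2 <- if (nrow(got2)) sort(paste(got2$i, got2$j, sep = "|")) else character(0)
    expect_identical(keys2, keys)
  }
})

test_that("density profile integrates to the bead count and finds the phases", {
  s <- gen_cg_slab(seed = 2, box = c(24, 16, 16))
  prof <- slab_density_profile(s$frame, "x", n_bins = 60)
  expect_equal(sum(prof$count), nrow(s$frame$beads))
  # plateau means recover the planted densities within 5%
  L <- s$frame$box[1]
  half_w <- s$truth$slab_fraction * L / 2
  inner <- abs(prof$center - L / 2) < 0.7 * half_w
  outer <- abs(prof$center - L / 2) > 1.4 * half_w
  expect_equal(mean(prof$density[inner]), s$truth$rho_dense, tolerance = 0.05)
  expect_equal(mean(prof$density[outer]), s$truth$rho_dilute, tolerance = 0.3)
  # all beads in the central third: outer bins empty
  b <- s$frame$beads[abs(s$frame$beads$x - L / 2) < L / 6, ]
  prof2 <- slab_density_profile(cg_frame(b, s$frame$box), "x",
                                n_bins = 30, recenter = FALSE)
  expect_true(all(prof2$count[prof2$center < L / 6] == 0))
  expect_true(all(prof2$count[prof2$center > 5 * L / 6] == 0))
})

test_that("uniform beads give a flat profile within counting error", {
  s <- gen_cg_slab(seed = 6, rho_dense = 0.8, rho_dilute = 0.8)
  prof <- slab_density_profile(s$frame, "x", n_bins = 12)
  expect_lt(stats::sd(prof$count) / mean(prof$count), 0.25)
  expect_error(slab_density_profile(s$frame, "x", n_bins = 5), "n_bins")
})
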