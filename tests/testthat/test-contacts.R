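# small hand-built frames for boundary geometry
mini_frame <- function(df, box = NULL) md_frame(df, box = box)

hbond_probe_frame <- function(r, along = c(1, 0, 0), h_at = c(0.1, 0, 0)) {
  # donor N (ARG side chain) and acceptor O (nucleotide phosphate oxygen)
  mini_frame(data.frame(
    atom_name = c("NH1", "HH11", "OP1"),
    element = c("N", "H", "O"),
    resname = c("ARG", "ARG", "DA"),
    resid = c(1L, 1L, 2L),
    chain = c("P", "P", "N"),
    x = c(0, h_at[1], r * along[1]),
    y = c(0, h_at[2], r * along[2]),
    z = c(0, h_at[3], r * along[3]),
    stringsAsFactors = FALSE))
}

test_that("hydrogen-bond cone accepts ideal linear geometry and is strict at the cutoff", {
  hb <- detect_hbonds(hbond_probe_frame(0.29))
  expect_equal(nrow(hb), 1L)
  expect_equal(hb$donor_atom, "NH1")
  expect_equal(hb$acceptor_atom, "OP1")
  expect_equal(hb$angle, 0, tolerance = 1e-9)
  # r = 0.33 at theta = 0: strictly outside
  expect_equal(nrow(detect_hbonds(hbond_probe_frame(0.33))), 0L)
  # r = 0.30 at theta = 30: cutoff shrinks to 0.2904
  th <- 30 * pi / 180
  fr <- hbond_probe_frame(0.30, along = c(cos(th), sin(th), 0))
  expect_equal(nrow(detect_hbonds(fr)), 0L)
  # same distance back at theta ~ 0 is accepted
  expect_equal(nrow(detect_hbonds(hbond_probe_frame(0.30))), 1L)
})

test_that("frames without hydrogens are rejected for hydrogen bonding", {
  fr <- mini_frame(data.frame(
    atom_name = c("NH1", "OP1"), element = c("N", "O"),
    resname = c("ARG", "DA"), resid = 1:2, chain = c("P", "N"),
    x = c(0, 0.29), y = 0, z = 0, stringsAsFactors = FALSE))
  expect_error(detect_hbonds(fr), "no hydrogens")
})

ionic_probe_frame <- function(d_op1, d_op2 = d_op1 + 0.04) {
  mini_frame(data.frame(
    atom_name = c("CZ", "OP1", "OP2"),
    element = c("C", "O", "O"),
    resname = c("ARG", "DA", "DA"),
    resid = c(1L, 2L, 2L),
    chain = c("P", "N", "N"),
    x = c(0, d_op1, 0), y = c(0, 0, d_op2), z = 0,
    stringsAsFactors = FALSE))
}

test_that("ionic contacts use min(CZ-OP1, CZ-OP2) < 0.6 nm, strictly", {
  ev <- detect_ionic(ionic_probe_frame(0.59))
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$distance, 0.59)
  expect_equal(nrow(detect_ionic(ionic_probe_frame(0.61, 0.65))), 0L)
  expect_equal(nrow(detect_ionic(ionic_probe_frame(0.60, 0.60))), 0L)
})

test_that("a hydrogen bond between the residues suppresses the ionic contact", {
  fr <- ionic_probe_frame(0.40)
  hb <- data.frame(donor_chain = "P", donor_resid = 1L,
                   acceptor_chain = "N", acceptor_resid = 2L)
  expect_equal(nrow(detect_ionic(fr, hb)), 0L)
  expect_equal(nrow(detect_ionic(fr)), 1L)
})

test_that("arginines missing CZ are skipped with a warning", {
  fr <- mini_frame(data.frame(
    atom_name = c("NE", "OP1"), element = c("N", "O"),
    resname = c("ARG", "DA"), resid = 1:2, chain = c("P", "N"),
    x = c(0, 0.3), y = 0, z = 0, stringsAsFactors = FALSE))
  expect_warning(ev <- detect_ionic(fr), "without CZ")
  expect_equal(nrow(ev), 0L)
})

test_that("total-least-squares plane fit is correct and rotation-equivariant", {
  sq <- rbind(c(1, 1, 0), c(1, -1, 0), c(-1, 1, 0), c(-1, -1, 0))
  p <- fit_plane(sq)
  expect_equal(p$centroid, c(0, 0, 0))
  expect_equal(abs(p$unit_normal), c(0, 0, 1), tolerance = 1e-12)
  # rotate: normal follows the rotation (up to sign)
  th <- 0.7
  R <- rbind(c(1, 0, 0), c(0, cos(th), -sin(th)), c(0, sin(th), cos(th)))
  p2 <- fit_plane(sq %*% t(R))
  expect_equal(abs(sum(p2$unit_normal * (R %*% c(0, 0, 1)))), 1,
               tolerance = 1e-9)
  # noisy planar hexagon: recovered normal within 1 degree
  set.seed(5)
  hex <- cbind(0.14 * cos(0:5 * pi / 3), 0.14 * sin(0:5 * pi / 3), 0)
  hex <- hex %*% t(R) + matrix(rnorm(18, 0, 0.001), 6)
  p3 <- fit_plane(hex)
  ang <- acos(min(1, abs(sum(p3$unit_normal * (R %*% c(0, 0, 1)))))) * 180 / pi
  expect_lt(ang, 1)
  expect_error(fit_plane(cbind(1:4, 2 * (1:4), 3 * (1:4))), "collinear")
})

stack_probe_frame <- function(height, tilt_deg = 0) {
  g <- data.frame(
    atom_name = c("NE", "CZ", "NH1", "NH2"),
    element = c("N", "C", "N", "N"),
    x = c(-0.133, 0, 0.067, 0.067),
    y = c(0, 0, 0.116, -0.116), z = 0, stringsAsFactors = FALSE)
  th <- tilt_deg * pi / 180
  R <- rbind(c(1, 0, 0), c(0, cos(th), -sin(th)), c(0, sin(th), cos(th)))
  gx <- as.matrix(g[c("x", "y", "z")]) %*% t(R)
  ring <- data.frame(
    atom_name = c("N1", "C2", "N3", "C4", "C5", "C6"),
    element = c("N", "C", "N", "C", "C", "C"),
    x = 0.139 * cos(0:5 * pi / 3), y = 0.139 * sin(0:5 * pi / 3), z = 0,
    stringsAsFactors = FALSE)
  at <- rbind(
    data.frame(atom_name = g$atom_name, element = g$element,
               resname = "ARG", resid = 1L, chain = "P",
               x = gx[, 1], y = gx[, 2], z = gx[, 3] + height,
               stringsAsFactors = FALSE),
    data.frame(atom_name = ring$atom_name, element = ring$element,
               resname = "DC", resid = 2L, chain = "N",
               x = ring$x, y = ring$y, z = ring$z,
               stringsAsFactors = FALSE))
  mini_frame(at)
}

test_that("stacking requires a close centroid and near-parallel planes", {
  ev <- detect_stacking(stack_probe_frame(0.38))
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$angle, 0, tolerance = 1e-6)
  expect_equal(ev$distance, 0.38, tolerance = 1e-12)
  # perpendicular planes rejected even when close
  expect_equal(nrow(detect_stacking(stack_probe_frame(0.35, 90))), 0L)
  # tilt brackets the 30-degree limit
  expect_equal(nrow(detect_stacking(stack_probe_frame(0.38, 29.9))), 1L)
  expect_equal(nrow(detect_stacking(stack_probe_frame(0.38, 30.1))), 0L)
  # distance gate
  expect_equal(nrow(detect_stacking(stack_probe_frame(0.50))), 0L)
})

test_that("unknown phosphate-bearing residues are rejected by name", {
  fr <- mini_frame(data.frame(
    atom_name = c("CZ", "OP1"), element = c("C", "O"),
    resname = c("ARG", "XNA"), resid = 1:2, chain = c("P", "N"),
    x = c(0, 0.4), y = 0, z = 0, stringsAsFactors = FALSE))
  expect_error(detect_stacking(fr), "XNA")
})

test_that("generic chain contacts are strict at 0.45 nm and match brute force", {
  two <- function(d) mini_frame(data.frame(
    atom_name = c("C1", "C2"), element = "C", resname = "DA",
    resid = 1:2, chain = c("A", "B"), x = c(0, d), y = 0, z = 0,
    stringsAsFactors = FALSE))
  expect_equal(nrow(generic_contacts(two(0.44))), 1L)
  expect_equal(nrow(generic_contacts(two(0.45))), 0L)
  set.seed(9)
  for (i in 1:5) {
    at <- data.frame(
      atom_name = "C", element = sample(c("C", "H"), 50, TRUE),
      resname = "DA", resid = 1:50,
      chain = sample(c("A", "B", "C"), 50, TRUE),
      x = runif(50, 0, 2), y = runif(50, 0, 2), z = runif(50, 0, 2),
      stringsAsFactors = FALSE)
    fr <- mini_frame(at)
    got <- generic_contacts(fr)
    got_keys <- if (nrow(got))
      sort(paste(got$chain_a, got$chain_b, sep = "|")) else character(0)
    expect_identical(got_keys, oracle_generic(fr))
  }
})

test_that("classification matches planted truth and the brute-force oracle", {
  for (seed in 1:10) {
    g <- gen_frame(seed, n_hbond = 2, n_ionic = 2, n_stacking = 2,
                   n_decoys = 4)
    keys <- classify_keys(g$frame)
    expect_identical(keys, truth_keys(g$truth))
    expect_identical(keys, oracle_classify(g$frame))
  }
})

test_that("classification is invariant under rigid motions", {
  g <- gen_frame(seed = 21)
  ref <- classify_keys(g$frame)
  for (s in 1:5)
    expect_identical(classify_keys(rigid_transform(g$frame, seed = s)), ref)
})

test_that("enlarging a cutoff never removes events of that mode", {
  for (seed in c(3, 14)) {
    g <- gen_frame(seed)
    tight <- detect_ionic(g$frame, detect_hbonds(g$frame), cutoff = 0.6)
    loose <- detect_ionic(g$frame, detect_hbonds(g$frame), cutoff = 0.8)
    tk <- paste(tight$arg_resid, tight$nt_resid)
    lk <- paste(loose$arg_resid, loose$nt_resid)
    expect_true(all(tk %in% lk))
    st <- detect_stacking(g$frame, centroid_cutoff = 0.45)
    sl <- detect_stacking(g$frame, centroid_cutoff = 0.6)
    expect_true(all(paste(st$arg_resid, st$nt_resid) %in%
                      paste(sl$arg_resid, sl$nt_resid)))
  }
})

test_that("per-nucleotide rates normalise by frames and nucleotides", {
  # 2 planted ionic pairs among 8 nucleotide residues, repeated in 10 frames
  g <- gen_frame(seed = 4, n_hbond = 0, n_ionic = 2, n_stacking = 0,
                 n_decoys = 6)
  traj <- md_trajectory(rep(list(g$frame), 10))
  s <- per_nucleotide_rates(traj)
  expect_equal(unname(s$per_mode_rate["ionic"]), 2 / 8)
  expect_equal(unname(s$per_mode_rate["hbond"]), 0)
  expect_equal(s$total_rate, sum(s$per_mode_rate))
  expect_equal(s$n_nucleotides, 8L)
  # frame order does not matter
  g2 <- gen_frame(seed = 5, n_hbond = 1, n_ionic = 1, n_stacking = 1,
                  n_decoys = 2)
  frames <- list(g$frame, g2$frame, g$frame)
  s1 <- per_nucleotide_rates(md_trajectory(frames))
  s2 <- per_nucleotide_rates(md_trajectory(rev(frames)))
  expect_equal(s1$per_mode_rate, s2$per_mode_rate)
  expect_error(per_nucleotide_rates(traj, window = 99), "window")
})

test_that("rates are additive over disjoint frame windows", {
  frames <- lapply(1:6, function(s)
    gen_frame(s, n_hbond = s %% 3, n_ionic = 1, n_stacking = s %% 2,
              n_decoys = 2)$frame)
  # pad frames to a common nucleotide count is unnecessary: rates are per
  # frame, so compare weighted combination of window rates to the full run
  traj <- md_trajectory(frames)
  all6 <- per_nucleotide_rates(traj)
  a <- per_nucleotide_rates(traj, window = 1:3)
  b <- per_nucleotide_rates(traj, window = 4:6)
  n_a <- a$n_nucleotides * 3; n_b <- b$n_nucleotides * 3
  expect_equal(all6$per_mode_rate * all6$n_nucleotides * 6,
               a$per_mode_rate * n_a + b$per_mode_rate * n_b,
               tolerance = 1e-12)
})

test_that("excess peptide counts chains with no nucleic contact", {
  # hbond and stacking units have heavy-atom pairs under 0.45 nm; the
  # ionic unit's closest heavy atoms sit at 0.55 nm, so its peptide is
  # unbound under the generic-contact rule
  g <- gen_frame(seed = 8, n_hbond = 1, n_ionic = 1, n_stacking = 1,
                 n_decoys = 0)
  at <- g$frame$atoms
  # add two isolated arginine chains far from everything
  pch <- at$chain[at$resname == "ARG"][1]
  iso <- do.call(rbind, lapply(1:2, function(i) {
    a <- at[at$chain == pch, ]
    a$chain <- paste0("F", i)
    a$resid <- 500L + i
    a$x <- a$x + 50 + 10 * i
    a
  }))
  fr <- md_frame(rbind(at, iso))
  ex <- excess_peptide(md_trajectory(list(fr, fr)))
  expect_equal(ex$mean, 3)   # two isolated chains + the ionic unit's peptide
  expect_equal(ex$sd, 0)
  ex0 <- excess_peptide(md_trajectory(list(g$frame)))
  expect_equal(ex0$mean, 1)
  # enlarging the contact cutoff binds the ionic peptide too
  ex1 <- excess_peptide(md_trajectory(list(g$frame)), cutoff = 0.58)
  expect_equal(ex1$mean, 0)
})

test_that("replicate aggregation reports mean and sample SD per mode", {
  mk <- function(h, i, s) structure(
    list(per_mode_rate = c(hbond = h, ionic = i, stacking = s),
         total_rate = h + i + s), class = "contact_summary")
  agg <- replicate_aggregate(list(mk(1, 1, 1), mk(1, 1, 1), mk(1, 1, 1),
                                  mk(1, 1, 1), mk(1, 1, 1)))
  expect_equal(unname(agg$mean["total"]), 3)
  expect_equal(unname(agg$sd["total"]), 0)
  agg2 <- replicate_aggregate(list(mk(1, 0, 0), mk(3, 0, 0)))
  expect_equal(unname(agg2$mean["hbond"]), 2)
  expect_equal(unname(agg2$sd["hbond"]), sqrt(2))
  bad <- structure(list(per_mode_rate = c(hbond = 1), total_rate = 1),
                   class = "contact_summary")
  expect_error(replicate_aggregate(list(mk(1, 1, 1), bad)), "mismatched")
})
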