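# Seeded synthetic-data generators. Every generator plants a known ground
# truth and returns it alongside the data, so each analysis stage has a
# parameter-recovery test surface. All randomness flows from the explicit
# `seed` argument of each call; the global RNG state is left untouched.

#' Generate a synthetic NaCl turbidity titration
#'
#' Emulates a plate-reader titration of a coacervate sample with a
#' concentrated NaCl stock: turbidity follows a logistic dissolution curve
#' \eqn{T(c) = T_0 / (1 + e^{k (c - c_0)})}, which is converted back to
#' absorbances through the inverse turbidity relation, with Gaussian noise
#' on the turbidity. The ground-truth tangent-intercept CSC of the logistic
#' is \eqn{c_0 + 2/k}.
#'
#' Defaults mirror a typical well: 100 uL starting volume titrated with a
#' 5 M stock from 0 to 800 mM (within a 20\% maximum dilution), 100
#' readings, plateau turbidity 90\% and noise of 1\% of the plateau.
#'
#' @param seed integer seed.
#' @param k logistic steepness (/mM), > 0.
#' @param c0 logistic midpoint (mM).
#' @param t0 plateau turbidity (percent, < 100).
#' @param n_points number of readings (>= 2).
#' @param noise_sd Gaussian noise SD on turbidity (percentage points).
#' @param initial_volume,titrant_stock,initial_salt,blank well parameters.
#' @param c_max final NaCl concentration reached (mM, < titrant_stock).
#' @param label sample label.
#' @return list: \code{record} (a [titration_record()]) and \code{truth}
#'   (\code{csc = c0 + 2/k}, \code{k}, \code{c0}, \code{t0}).
#' @export
gen_titration <- function(seed, k = 0.1, c0 = 200, t0 = 90, n_points = 100L,
                          noise_sd = 0.9, initial_volume = 100,
                          titrant_stock = 5000, initial_salt = 0,
                          c_max = 800, blank = 0.05, label = "synthetic") {
  stopifnot(k > 0, t0 < 100, n_points >= 2, c_max < titrant_stock)
  if (noise_sd >= t0)
    warning("noise SD is as large as the plateau turbidity", call. = FALSE)
  conc <- seq(initial_salt, c_max, length.out = n_points)
  # cumulative stock volume producing each target concentration
  s_cum <- initial_volume * (conc - initial_salt) / (titrant_stock - conc)
  additions <- diff(s_cum)
  turb <- t0 / (1 + exp(k * (conc - c0)))
  turb <- withr::with_seed(seed, turb + stats::rnorm(n_points, 0, noise_sd))
  turb <- pmin(turb, 99.9)
  absorb <- turbidity_to_absorbance(turb, blank)
  rec <- titration_record(initial_volume, initial_salt, titrant_stock,
                          additions, absorb, blank, label = label)
  list(record = rec,
       truth = list(csc = c0 + 2 / k, k = k, c0 = c0, t0 = t0))
}

#' Generate a CSC-versus-peptide-length series
#'
#' Plants the linear relation \eqn{CSC = m / N + c} whose zero crossing
#' defines the minimal peptide length \eqn{N_{min} = -m/c}. Default slope
#' and intercept are anchored to a mixed-sequence DNA octamer series (CSC
#' 99.3 mM at N = 4, \eqn{N_{min}} 3.5). Noise is multiplicative Gaussian.
#'
#' @param seed integer seed.
#' @param m slope (mM residues).
#' @param c intercept (mM).
#' @param lengths peptide lengths N.
#' @param noise_sd relative noise per point (default 0.02 = 2\%).
#' @return list: \code{peptide_lengths}, \code{csc_values}, \code{truth}
#'   (\code{n_min = -m/c}, \code{m}, \code{c}).
#' @export
gen_length_series <- function(seed, m = -2780.4, c = 794.4,
                              lengths = c(4, 6, 8, 10), noise_sd = 0.02) {
  csc <- m / lengths + c
  csc <- withr::with_seed(seed,
    csc * (1 + stats::rnorm(length(lengths), 0, noise_sd)))
  list(peptide_lengths = lengths, csc_values = csc,
       truth = list(n_min = -m / c, m = m, c = c))
}

#' Generate a synthetic FRAP trace
#'
#' Pre-bleach frames at normalised intensity 1, then a single-exponential
#' recovery \eqn{I(t') = P - (P - B) e^{-t'/\tau}} with Gaussian noise.
#'
#' @param seed integer seed.
#' @param tau recovery time (s), > 0.
#' @param bleach_depth intensity immediately after the bleach (normalised).
#' @param plateau recovery plateau (normalised; < 1 models incomplete
#'   recovery).
#' @param n_pre,n_post numbers of pre- and post-bleach frames.
#' @param dt frame interval (s), > 0; default the confocal frame time
#'   1.117 s.
#' @param noise_sd Gaussian noise SD (normalised units).
#' @param droplet_id label.
#' @return list: \code{trace} (a normalised [frap_trace()]) and
#'   \code{truth} (\code{tau}, \code{bleach_depth}, \code{plateau},
#'   \code{mobile_fraction}).
#' @export
gen_frap <- function(seed, tau = 10, bleach_depth = 0.2, plateau = 0.8,
                     n_pre = 10L, n_post = 100L, dt = 1.117,
                     noise_sd = 0.02, droplet_id = "synthetic") {
  stopifnot(tau > 0, n_pre >= 1, n_post >= 5)
  if (dt <= 0) stop("dt must be > 0", call. = FALSE)
  times <- (seq_len(n_pre + n_post) - 1) * dt
  tp <- (seq_len(n_post) - 1) * dt
  clean <- c(rep(1, n_pre),
             plateau - (plateau - bleach_depth) * exp(-tp / tau))
  y <- withr::with_seed(seed,
    clean + stats::rnorm(length(clean), 0, noise_sd))
  tr <- frap_trace(times, y, n_prebleach = n_pre, droplet_id = droplet_id,
                   normalized = noise_sd == 0)
  list(trace = tr,
       truth = list(tau = tau, bleach_depth = bleach_depth,
                    plateau = plateau,
                    mobile_fraction = (plateau - bleach_depth) /
                      (1 - bleach_depth)))
}

#' Generate a droplet micrograph with a planted partition coefficient
#'
#' Disks of intensity \eqn{I_{dark} + K_p (I_{bg} - I_{dark})} on a uniform
#' dilute-phase background, plus a matching fluorophore-free dark frame;
#' Gaussian noise on both.
#'
#' @param seed integer seed.
#' @param kp planted partition coefficient, > 0.
#' @param n_droplets number of non-overlapping disks.
#' @param radius_range min/max disk radius (px).
#' @param background dilute-phase intensity (AU).
#' @param dark dark-field intensity (AU).
#' @param noise_sd Gaussian noise SD (AU).
#' @param shape image dimensions (px).
#' @return list: \code{image}, \code{dark} (matrices) and \code{truth}
#'   (\code{kp}, droplet \code{centers}, \code{radii},
#'   \code{droplet_intensity}).
#' @export
gen_droplet_image <- function(seed, kp = 8, n_droplets = 5L,
                              radius_range = c(5, 12), background = 20,
                              dark = 10, noise_sd = 1,
                              shape = c(128L, 128L)) {
  if (kp <= 0) stop("kp must be > 0", call. = FALSE)
  i_drop <- dark + kp * (background - dark)
  withr::with_seed(seed, {
    centers <- matrix(NA_real_, 0, 2)
    radii <- numeric(0)
    tries <- 0
    while (length(radii) < n_droplets) {
      tries <- tries + 1
      if (tries > 1000 * max(1, n_droplets))
        stop("could not place droplets without overlap; frame overcrowded",
             call. = FALSE)
      r <- stats::runif(1, radius_range[1], radius_range[2])
      cx <- stats::runif(1, r + 2, shape[1] - r - 1)
      cy <- stats::runif(1, r + 2, shape[2] - r - 1)
      if (nrow(centers) == 0 ||
          all(sqrt((centers[, 1] - cx)^2 + (centers[, 2] - cy)^2) >
                radii + r + 4)) {
        centers <- rbind(centers, c(cx, cy))
        radii <- c(radii, r)
      }
    }
    img <- matrix(background, shape[1], shape[2])
    xs <- row(img); ys <- col(img)
    for (i in seq_along(radii))
      img[(xs - centers[i, 1])^2 + (ys - centers[i, 2])^2 <= radii[i]^2] <-
        i_drop
    img <- img + matrix(stats::rnorm(length(img), 0, noise_sd),
                        shape[1], shape[2])
    drk <- dark + matrix(stats::rnorm(prod(shape), 0, noise_sd),
                         shape[1], shape[2])
    list(image = pmax(img, 0), dark = pmax(drk, 0),
         truth = list(kp = kp, centers = centers, radii = radii,
                      droplet_intensity = i_drop, background = background,
                      dark = dark))
  })
}

#' Generate a gel lane with planted band yields
#'
#' Gaussian bands (one per species, first = unextended primer) whose areas
#' are proportional to the planted fractions, on a constant baseline with
#' Gaussian noise. The planted yield is the summed fraction of the extended
#' species.
#'
#' @param seed integer seed.
#' @param extended_yields fractions of the extended species (sum < 1); the
#'   unextended primer carries the remainder.
#' @param centers band centres (px); default evenly spaced.
#' @param widths band Gaussian SDs (px).
#' @param baseline constant background level (AU).
#' @param noise_sd Gaussian noise SD (AU).
#' @param total_signal summed band intensity (AU).
#' @param n_points profile length (px).
#' @param timepoint reaction time (h), recorded on the profile.
#' @return list: \code{profile} (a [lane_profile()]), \code{windows}
#'   (suggested band windows at centres +/- 4 widths) and \code{truth}
#'   (\code{yield_fraction}, \code{fractions}).
#' @export
gen_gel_lane <- function(seed, extended_yields = c(0.1, 0.2, 0.3),
                         centers = NULL, widths = NULL, baseline = 10,
                         noise_sd = 0.5, total_signal = 5000,
                         n_points = 400L, timepoint = NA_real_) {
  stopifnot(all(extended_yields >= 0), sum(extended_yields) <= 1)
  fractions <- c(1 - sum(extended_yields), extended_yields)
  n_sp <- length(fractions)
  if (is.null(centers))
    centers <- seq(n_points * 0.15, n_points * 0.85, length.out = n_sp)
  if (is.null(widths)) widths <- rep(6, n_sp)
  stopifnot(length(centers) == n_sp, length(widths) == n_sp,
            all(centers > 0 & centers < n_points))
  if (n_sp > 1 && any(diff(sort(centers)) < 4 * max(widths)))
    warning("bands overlap beyond tolerance", call. = FALSE)
  pos <- seq_len(n_points)
  y <- rep(baseline, n_points)
  for (i in seq_len(n_sp))
    y <- y + total_signal * fractions[i] *
      stats::dnorm(pos, centers[i], widths[i])
  y <- withr::with_seed(seed, y + stats::rnorm(n_points, 0, noise_sd))
  prof <- lane_profile(pos, pmax(y, 0), label = "synthetic",
                       timepoint = timepoint)
  windows <- lapply(seq_len(n_sp), function(i)
    c(max(1, centers[i] - 4 * widths[i]),
      min(n_points, centers[i] + 4 * widths[i])))
  names(windows) <- c("unextended",
                      if (n_sp > 1) paste0("extended_", seq_len(n_sp - 1)))
  list(profile = prof, windows = windows,
       truth = list(yield_fraction = sum(extended_yields),
                    fractions = fractions, centers = centers,
                    widths = widths))
}

#' Generate a coarse-grained direct-coexistence slab
#'
#' Places beads uniformly at a high density inside a central slab along x
#' and at a low density outside it, emulating the coexisting dense and
#' dilute phases of a slab simulation (scaled down from production box
#' sizes).
#'
#' @param seed integer seed.
#' @param rho_dense,rho_dilute number densities (beads/nm^3).
#' @param slab_fraction fraction of the x length occupied by the dense slab.
#' @param box box lengths (nm).
#' @param sigma bead diameter parameter (nm).
#' @param bead_type bead type label.
#' @return list: \code{frame} (a [cg_frame()]) and \code{truth}
#'   (\code{rho_dense}, \code{rho_dilute}, \code{slab_fraction}).
#' @export
gen_cg_slab <- function(seed, rho_dense = 2, rho_dilute = 0.05,
                        slab_fraction = 0.3, box = c(24, 8, 8),
                        sigma = 0.5, bead_type = "U") {
  stopifnot(rho_dense >= rho_dilute, slab_fraction > 0, slab_fraction < 1)
  L <- box[1]; area <- box[2] * box[3]
  lo <- L * (0.5 - slab_fraction / 2)
  hi <- L * (0.5 + slab_fraction / 2)
  n_dense <- round(rho_dense * (hi - lo) * area)
  n_dilute <- round(rho_dilute * (L - (hi - lo)) * area)
  withr::with_seed(seed, {
    xd <- stats::runif(n_dense, lo, hi)
    xl <- stats::runif(n_dilute, 0, L - (hi - lo))
    xl <- ifelse(xl < lo, xl, xl + (hi - lo))
    x <- c(xd, xl)
    n <- length(x)
    beads <- data.frame(chain = paste0("c", seq_len(n)), type = bead_type,
                        sigma = sigma,
                        x = x,
                        y = stats::runif(n, 0, box[2]),
                        z = stats::runif(n, 0, box[3]),
                        stringsAsFactors = FALSE)
    list(frame = cg_frame(beads, box),
         truth = list(rho_dense = rho_dense, rho_dilute = rho_dilute,
                      slab_fraction = slab_fraction,
                      n_dense = n_dense, n_dilute = n_dilute))
  })
}

# ---- idealised residue geometry templates (coordinates in nm) ------------

# planar guanidinium group of the arginine sidechain, plane z = 0, with
# in-plane hydrogens (N-H ~0.10 nm)
guanidinium_template <- function() {
  data.frame(
    atom_name = c("NE", "CZ", "NH1", "NH2", "HE",
                  "HH11", "HH12", "HH21", "HH22"),
    element = c("N", "C", "N", "N", "H", "H", "H", "H", "H"),
    x = c(0, 0.133, 0.200, 0.200, -0.050, 0.165, 0.298, 0.165, 0.298),
    y = c(0, 0, 0.116, -0.116, 0.087, 0.205, 0.120, -0.205, -0.120),
    z = 0,
    stringsAsFactors = FALSE)
}

# phosphate fragment: P with the two non-bridging oxygens, plane z = 0
phosphate_template <- function() {
  data.frame(atom_name = c("P", "OP1", "OP2"),
             element = c("P", "O", "O"),
             x = c(0, 0.148, -0.074),
             y = c(0, 0, 0.128),
             z = 0, stringsAsFactors = FALSE)
}

# nucleobase ring template, plane z = 0, centroid at origin for the six-ring
base_ring_template <- function(resname) {
  ang <- (0:5) * pi / 3
  hex <- data.frame(atom_name = c("N1", "C2", "N3", "C4", "C5", "C6"),
                    element = c("N", "C", "N", "C", "C", "C"),
                    x = 0.139 * cos(ang), y = 0.139 * sin(ang), z = 0,
                    stringsAsFactors = FALSE)
  if (resname %in% PURINE_RESNAMES) {
    five <- data.frame(atom_name = c("N9", "C8", "N7"),
                       element = c("N", "C", "N"),
                       x = c(-0.270, -0.300, -0.170),
                       y = c(-0.020, -0.160, -0.220),
                       z = 0, stringsAsFactors = FALSE)
    hex <- rbind(hex, five)
  }
  hex
}

random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# assemble one (arginine, nucleotide) unit in local coordinates for a given
# planting kind, returning the two atom tables
plant_unit <- function(kind, resname = "DC") {
  g <- guanidinium_template()
  gxyz <- as.matrix(g[c("x", "y", "z")])
  cz <- as.numeric(gxyz[g$atom_name == "CZ", ])
  nt <- NULL
  if (kind == "ionic" || kind == "ionic_decoy") {
    d <- if (kind == "ionic") 0.55 else 0.62
    ph <- phosphate_template()
    # OP1 perpendicular to the guanidinium plane, out of hydrogen reach
    shift <- c(cz[1] - 0.148, cz[2], cz[3] + d)
    ph[c("x", "y", "z")] <- sweep(as.matrix(ph[c("x", "y", "z")]), 2,
                                  -shift)
    nt <- ph
  } else if (kind == "hbond") {
    # acceptor OP1 along the NH1-HH12 direction at r = 0.29, theta = 0;
    # P and OP2 continue away from the guanidinium so nothing overlaps
    nh1 <- as.numeric(gxyz[g$atom_name == "NH1", ])
    h <- as.numeric(gxyz[g$atom_name == "HH12", ])
    u <- (h - nh1) / sqrt(sum((h - nh1)^2))
    acc <- nh1 + 0.29 * u
    v <- c(-u[2], u[1], 0)   # in-plane perpendicular
    nt <- data.frame(atom_name = c("P", "OP1", "OP2"),
                     element = c("P", "O", "O"),
                     stringsAsFactors = FALSE)
    p_pos <- acc + 0.148 * u
    op2 <- p_pos + 0.148 * (0.5 * u + 0.866 * v)
    xyz <- rbind(p_pos, acc, op2)
    nt$x <- xyz[, 1]; nt$y <- xyz[, 2]; nt$z <- xyz[, 3]
  } else if (kind == "hbond_decoy") {
    # ring nitrogen N1 at r = 0.35 from NH1 (outside the cone even at
    # theta = 0), ring plane perpendicular: no hbond, no stacking, no OP
    nh1 <- as.numeric(gxyz[g$atom_name == "NH1", ])
    h <- as.numeric(gxyz[g$atom_name == "HH12", ])
    u <- (h - nh1) / sqrt(sum((h - nh1)^2))
    acc <- nh1 + 0.35 * u
    ring <- base_ring_template(resname)
    rxyz <- as.matrix(ring[c("x", "y", "z")])
    rxyz <- rxyz[, c(3, 2, 1)]           # rotate ring into the xz... yz plane
    rxyz <- sweep(rxyz, 2, as.numeric(rxyz[1, ]))  # N1 to origin
    rxyz <- sweep(rxyz, 2, -acc)         # N1 at the acceptor position
    ring[c("x", "y", "z")] <- rxyz
    nt <- ring
  } else if (kind == "stacking" || kind == "stack_dist_decoy" ||
             kind == "stack_angle_decoy") {
    ring <- base_ring_template(resname)
    h <- switch(kind, stacking = 0.38, stack_dist_decoy = 0.50,
                stack_angle_decoy = 0.40)
    if (kind == "stack_angle_decoy") {
      # guanidinium plane perpendicular to the ring plane (90 degrees)
      gxyz <- gxyz[, c(3, 2, 1)]
    }
    # place CZ directly above the ring centroid (six-ring centroid = origin)
    czr <- as.numeric(gxyz[g$atom_name == "CZ", ])
    gxyz <- sweep(gxyz, 2, czr - c(0, 0, h))
    g[c("x", "y", "z")] <- gxyz
    nt <- ring
  } else stop("unknown plant kind: ", kind)
  list(arg = g, nt = nt,
       nt_resname = if (any(nt$atom_name == "P")) "DA" else resname)
}

#' Generate a synthetic frame with planted contacts
#'
#' Places idealised guanidinium groups and nucleotide fragments (phosphate
#' and base-ring templates) on a sparse 3-D grid, each pair in its own cell
#' with a random rigid orientation. Planted units satisfy exactly one
#' contact criterion; decoy units sit just outside a cutoff (ionic at
#' 0.62 nm, hydrogen bond at 0.29 nm... 0.35 nm donor-acceptor, stacking at
#' 0.50 nm or tilted to 90 degrees), so a correct classifier reports the
#' planted events and nothing else. The hydrogen-bond plants use phosphate
#' oxygens as acceptors with the CZ atom within 0.6 nm, exercising the rule
#' that hydrogen-bonded pairs are not double-counted as ionic.
#'
#' @param seed integer seed.
#' @param n_hbond,n_ionic,n_stacking planted event counts per mode.
#' @param n_decoys number of decoy units (cycled over the decoy kinds).
#' @param box optional periodic box (nm); must hold the grid, else an
#'   overcrowding error is raised.
#' @param spacing grid cell spacing (nm), default 3.
#' @return list: \code{frame} (an [md_frame()]) and \code{truth}
#'   (data.frame of planted events: arg chain/resid, nt chain/resid, mode).
#' @export
gen_frame <- function(seed, n_hbond = 3L, n_ionic = 2L, n_stacking = 1L,
                      n_decoys = 5L, box = NULL, spacing = 3) {
  kinds <- c(rep("hbond", n_hbond), rep("ionic", n_ionic),
             rep("stacking", n_stacking))
  decoy_kinds <- c("ionic_decoy", "hbond_decoy", "stack_dist_decoy",
                   "stack_angle_decoy")
  if (n_decoys > 0)
    kinds <- c(kinds, decoy_kinds[((seq_len(n_decoys) - 1) %% 4) + 1])
  n_units <- length(kinds)
  if (n_units == 0) stop("nothing to generate", call. = FALSE)
  side <- ceiling(n_units^(1 / 3))
  if (!is.null(box) && any(side * spacing > box))
    stop("placement failure: box too small for ", n_units,
         " units at ", spacing, " nm spacing", call. = FALSE)
  ring_names <- c("C", "U", "DC", "DT", "A", "G", "DA", "DG")
  withr::with_seed(seed, {
    kinds <- sample(kinds)   # shuffle cell assignment
    atoms <- list()
    truth <- list()
    for (u in seq_len(n_units)) {
      cell <- c((u - 1) %% side,
                ((u - 1) %/% side) %% side,
                (u - 1) %/% side^2)
      centre <- (cell + 0.5) * spacing
      rot <- random_rotation()
      resname <- sample(ring_names, 1)
      unit <- plant_unit(kinds[u], resname = resname)
      place <- function(df, resname, chain, resid) {
        xyz <- as.matrix(df[c("x", "y", "z")]) %*% t(rot)
        xyz <- sweep(xyz, 2, -centre)
        data.frame(atom_name = df$atom_name, element = df$element,
                   resname = resname, resid = resid, chain = chain,
                   x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                   stringsAsFactors = FALSE)
      }
      atoms[[2 * u - 1]] <- place(unit$arg, "ARG", paste0("P", u), u)
      atoms[[2 * u]] <- place(unit$nt, unit$nt_resname, paste0("N", u),
                              1000L + u)
      if (kinds[u] %in% c("hbond", "ionic", "stacking"))
        truth[[length(truth) + 1L]] <- data.frame(
          arg_chain = paste0("P", u), arg_resid = u,
          nt_chain = paste0("N", u), nt_resid = 1000L + u,
          mode = kinds[u], stringsAsFactors = FALSE)
    }
    truth <- if (length(truth)) do.call(rbind, truth) else
      data.frame(arg_chain = character(), arg_resid = integer(),
                 nt_chain = character(), nt_resid = integer(),
                 mode = character(), stringsAsFactors = FALSE)
    list(frame = md_frame(do.call(rbind, atoms), box = box), truth = truth)
  })
}

#' Apply a random rigid transform to a frame
#'
#' Utility for invariance testing: rotates and translates all coordinates
#' by a common rigid motion (box, if any, is dropped since an arbitrary
#' rotation does not preserve an orthorhombic box).
#'
#' @param frame an [md_frame()].
#' @param seed integer seed.
#' @param max_shift translation range (nm).
#' @return the transformed \code{md_frame} (no box).
#' @export
rigid_transform <- function(frame, seed, max_shift = 5) {
  stopifnot(inherits(frame, "md_frame"))
  withr::with_seed(seed, {
    rot <- random_rotation()
    shift <- stats::runif(3, -max_shift, max_shift)
    xyz <- as.matrix(frame$atoms[c("x", "y", "z")]) %*% t(rot)
    xyz <- sweep(xyz, 2, -shift)
    at <- frame$atoms
    at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
    md_frame(at, box = NULL, time = frame$time)
  })
}
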