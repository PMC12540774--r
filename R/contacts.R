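# Atomistic contact classification: arginine-nucleotide hydrogen bonds,
# ionic contacts and guanidinium-nucleobase stacking, from geometric rules.

NUCLEOTIDE_RESNAMES <- c("A", "C", "G", "U", "DA", "DC", "DG", "DT")
PURINE_RESNAMES <- c("A", "G", "DA", "DG")

# ring atom templates; purines default to the full 9-atom fused ring
ring_atom_names <- function(resname, purine_ring = "nine") {
  if (resname %in% PURINE_RESNAMES) {
    if (purine_ring == "nine")
      c("N9", "C8", "N7", "C5", "C6", "N1", "C2", "N3", "C4")
    else c("N1", "C2", "N3", "C4", "C5", "C6")
  } else if (resname %in% NUCLEOTIDE_RESNAMES) {
    c("N1", "C2", "N3", "C4", "C5", "C6")
  } else {
    stop("unsupported residue: ", resname, call. = FALSE)
  }
}

#' Construct an atomistic frame
#'
#' A frame is a table of atom records with coordinates in nanometres plus an
#' optional orthorhombic periodic box. Distances are computed with the
#' minimum-image convention whenever a box is present; frames without a box
#' use raw distances.
#'
#' @param atoms data.frame with columns \code{atom_name}, \code{resname},
#'   \code{resid}, \code{chain}, \code{x}, \code{y}, \code{z} (nm) and
#'   optionally \code{element} (inferred from the first letter of
#'   \code{atom_name} when absent).
#' @param box orthorhombic box lengths, numeric length 3 (nm), or NULL.
#' @param time frame time (ns), optional.
#' @return object of class \code{"md_frame"}.
#' @export
md_frame <- function(atoms, box = NULL, time = NA_real_) {
  need <- c("atom_name", "resname", "resid", "chain", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss))
    stop("atoms table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!all(is.finite(as.matrix(atoms[c("x", "y", "z")]))))
    stop("non-finite coordinates", call. = FALSE)
  if (is.null(atoms$element))
    atoms$element <- toupper(substr(gsub("[0-9]", "", atoms$atom_name), 1, 1))
  if (!is.null(box)) {
    stopifnot(length(box) == 3, all(box > 0))
    box <- as.numeric(box)
  }
  structure(list(atoms = atoms, box = box, time = time), class = "md_frame")
}

#' @export
print.md_frame <- function(x, ...) {
  cat(sprintf("md_frame: %d atoms, %d residues, %d chains%s\n",
              nrow(x$atoms),
              length(unique(paste(x$atoms$chain, x$atoms$resid))),
              length(unique(x$atoms$chain)),
              if (is.null(x$box)) "" else
                sprintf(", box %.1f x %.1f x %.1f nm",
                        x$box[1], x$box[2], x$box[3])))
  invisible(x)
}

#' Bundle frames into a trajectory
#' @param frames list of [md_frame()] objects.
#' @return object of class \code{"md_trajectory"}.
#' @export
md_trajectory <- function(frames) {
  stopifnot(length(frames) >= 1,
            all(vapply(frames, inherits, logical(1), "md_frame")))
  structure(list(frames = frames), class = "md_trajectory")
}

#' @export
length.md_trajectory <- function(x) length(x$frames)

# pairwise distance matrix between coordinate sets, minimum image if boxed
pair_dist_matrix <- function(a, b, box = NULL) {
  a <- as.matrix(a); b <- as.matrix(b)
  d2 <- matrix(0, nrow(a), nrow(b))
  for (k in 1:3) {
    dk <- outer(a[, k], b[, k], "-")
    if (!is.null(box)) dk <- dk - box[k] * round(dk / box[k])
    d2 <- d2 + dk^2
  }
  sqrt(d2)
}

# minimum-image displacement vectors from a single point to rows of b
mi_disp <- function(p, b, box = NULL) {
  b <- matrix(as.numeric(b), ncol = 3)
  d <- sweep(b, 2, as.numeric(p))
  if (!is.null(box))
    for (k in 1:3) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
  d
}

res_key <- function(chain, resid) paste(chain, resid, sep = "/")

# unordered residue-pair keys, for hbond/ionic mutual exclusion
pair_key <- function(k1, k2) {
  paste(pmin(k1, k2), pmax(k1, k2), sep = "--")
}

#' Detect hydrogen bonds (Wernet-Nilsson criterion)
#'
#' A donor-H...acceptor triple is a hydrogen bond when the donor-acceptor
#' distance \eqn{r} (nm) satisfies \eqn{r < 0.33 - 0.000044\,\theta^2}, with
#' \eqn{\theta} the H-donor-acceptor angle in degrees (strict inequality).
#' Donors are N/O atoms with a covalently bound hydrogen (H within 0.12 nm);
#' acceptors are N/O atoms of a different residue. The criterion is
#' angle-dependent, so frames without hydrogens are rejected outright rather
#' than silently degrading to a heavy-atom rule.
#'
#' @param frame an [md_frame()] with explicit hydrogens.
#' @return data.frame, one row per donor-H/acceptor bond: donor and acceptor
#'   chain/resid/resname/atom, hydrogen name, \code{distance} (nm),
#'   \code{angle} (degrees).
#' @export
detect_hbonds <- function(frame) {
  stopifnot(inherits(frame, "md_frame"))
  at <- frame$atoms
  box <- frame$box
  h_idx <- which(at$element == "H")
  if (!length(h_idx))
    stop("frame has no hydrogens; the hydrogen-bond criterion is angle-dependent and cannot be evaluated",
         call. = FALSE)
  no_idx <- which(at$element %in% c("N", "O"))
  if (!length(no_idx)) return(empty_hbond_table())
  xyz <- as.matrix(at[c("x", "y", "z")])
  # covalent donor for each hydrogen: nearest N/O within 0.12 nm
  dh <- pair_dist_matrix(xyz[h_idx, , drop = FALSE],
                         xyz[no_idx, , drop = FALSE], box)
  rows <- list()
  for (i in seq_along(h_idx)) {
    j <- which.min(dh[i, ])
    if (dh[i, j] >= 0.12) next
    d <- no_idx[j]           # donor heavy atom
    h <- h_idx[i]
    dkey <- res_key(at$chain[d], at$resid[d])
    acc <- no_idx[no_idx != d &
                    res_key(at$chain[no_idx], at$resid[no_idx]) != dkey]
    if (!length(acc)) next
    r <- as.numeric(pair_dist_matrix(xyz[d, , drop = FALSE],
                                     xyz[acc, , drop = FALSE], box))
    vh <- mi_disp(xyz[d, ], xyz[h, , drop = FALSE], box)[1, ]
    va <- mi_disp(xyz[d, ], xyz[acc, , drop = FALSE], box)
    cosang <- (va %*% vh) / (sqrt(sum(vh^2)) * sqrt(rowSums(va^2)))
    theta <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
    ok <- which(r < 0.33 - 0.000044 * theta^2)
    for (m in ok) {
      a <- acc[m]
      rows[[length(rows) + 1L]] <- data.frame(
        donor_chain = at$chain[d], donor_resid = at$resid[d],
        donor_resname = at$resname[d], donor_atom = at$atom_name[d],
        hydrogen = at$atom_name[h],
        acceptor_chain = at$chain[a], acceptor_resid = at$resid[a],
        acceptor_resname = at$resname[a], acceptor_atom = at$atom_name[a],
        distance = r[m], angle = theta[m], stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty_hbond_table())
  do.call(rbind, rows)
}

empty_hbond_table <- function() {
  data.frame(donor_chain = character(), donor_resid = integer(),
             donor_resname = character(), donor_atom = character(),
             hydrogen = character(),
             acceptor_chain = character(), acceptor_resid = integer(),
             acceptor_resname = character(), acceptor_atom = character(),
             distance = numeric(), angle = numeric(),
             stringsAsFactors = FALSE)
}

# residue-pair keys that carry at least one hydrogen bond
hbond_pair_keys <- function(hb) {
  if (!nrow(hb)) return(character())
  unique(pair_key(res_key(hb$donor_chain, hb$donor_resid),
                  res_key(hb$acceptor_chain, hb$acceptor_resid)))
}

#' Detect ionic arginine-phosphate contacts
#'
#' An ionic contact exists between an arginine residue and a nucleotide when
#' the guanidinium carbon CZ approaches either non-bridging phosphate oxygen
#' (OP1 or OP2) closer than 0.6 nm, provided no hydrogen bond links the two
#' residues in the same frame (hydrogen-bonded pairs are counted as hydrogen
#' bonds only). One event per residue pair.
#'
#' @param frame an [md_frame()].
#' @param hbonds hydrogen-bond table from [detect_hbonds()] for the same
#'   frame (may be an empty table when the mutual-exclusion rule is not
#'   needed, e.g. hydrogen-free test frames).
#' @param cutoff CZ-OP distance cutoff (nm), default 0.6.
#' @return event data.frame: arg and nucleotide chain/resid, \code{mode}
#'   ("ionic"), \code{distance} (min CZ-OP1/OP2, nm), \code{angle} (NA).
#' @export
detect_ionic <- function(frame, hbonds = empty_hbond_table(), cutoff = 0.6) {
  stopifnot(inherits(frame, "md_frame"))
  at <- frame$atoms
  arg_res <- unique(at[at$resname == "ARG", c("chain", "resid")])
  cz <- at[at$resname == "ARG" & at$atom_name == "CZ", ]
  # warn on arginines missing the CZ atom
  if (nrow(arg_res)) {
    have <- res_key(cz$chain, cz$resid)
    missing_cz <- setdiff(res_key(arg_res$chain, arg_res$resid), have)
    if (length(missing_cz))
      warning("ARG residue(s) without CZ skipped: ",
              paste(missing_cz, collapse = ", "), call. = FALSE)
  }
  op <- at[at$resname %in% NUCLEOTIDE_RESNAMES &
             at$atom_name %in% c("OP1", "OP2"), ]
  if (!nrow(cz) || !nrow(op)) return(empty_event_table())
  d <- pair_dist_matrix(cz[c("x", "y", "z")], op[c("x", "y", "z")], frame$box)
  hb_keys <- hbond_pair_keys(hbonds)
  rows <- list()
  op_key <- res_key(op$chain, op$resid)
  for (i in seq_len(nrow(cz))) {
    ck <- res_key(cz$chain[i], cz$resid[i])
    for (nk in unique(op_key)) {
      dmin <- min(d[i, op_key == nk])
      if (dmin < cutoff && !(pair_key(ck, nk) %in% hb_keys)) {
        nt <- op[match(nk, op_key), ]
        rows[[length(rows) + 1L]] <- data.frame(
          arg_chain = cz$chain[i], arg_resid = cz$resid[i],
          nt_chain = nt$chain, nt_resid = nt$resid, nt_resname = nt$resname,
          mode = "ionic", distance = dmin, angle = NA_real_,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) return(empty_event_table())
  do.call(rbind, rows)
}

empty_event_table <- function() {
  data.frame(arg_chain = character(), arg_resid = integer(),
             nt_chain = character(), nt_resid = integer(),
             nt_resname = character(), mode = character(),
             distance = numeric(), angle = numeric(),
             stringsAsFactors = FALSE)
}

#' Total-least-squares plane through a set of atoms
#'
#' Centroid plus the unit normal along the direction of smallest coordinate
#' variance (smallest eigenvector of the centred covariance). The normal's
#' sign is canonicalised to the +z hemisphere (+x, then +y, on ties).
#'
#' @param xyz numeric matrix (n x 3), n >= 3 non-collinear points (nm).
#' @return list: \code{centroid} (nm), \code{unit_normal}, \code{atoms_used}.
#' @export
fit_plane <- function(xyz) {
  xyz <- as.matrix(xyz)
  if (nrow(xyz) < 3) stop("need >= 3 atoms to fit a plane", call. = FALSE)
  centroid <- colMeans(xyz)
  centred <- sweep(xyz, 2, centroid)
  e <- eigen(crossprod(centred), symmetric = TRUE)
  # collinear: only one direction with appreciable variance
  if (e$values[2] < 1e-12 * max(e$values[1], 1e-300))
    stop("degenerate geometry: atoms are collinear", call. = FALSE)
  n <- e$vectors[, 3]
  s <- sign(n[3])
  if (s == 0) s <- sign(n[1])
  if (s == 0) s <- sign(n[2])
  if (s < 0) n <- -n
  list(centroid = centroid, unit_normal = n, atoms_used = nrow(xyz))
}

# angle between two planes via their normals, folded into [0, 90] degrees
plane_angle <- function(n1, n2) {
  c12 <- abs(sum(n1 * n2)) / (sqrt(sum(n1^2)) * sqrt(sum(n2^2)))
  acos(min(1, c12)) * 180 / pi
}

#' Detect guanidinium-nucleobase stacking
#'
#' A stacking (cation-pi / pi-pi) contact exists when the arginine CZ atom
#' lies within \code{centroid_cutoff} of the centre of geometry of a
#' nucleobase ring and the angle between the guanidinium plane (NE, CZ, NH1,
#' NH2, total least squares) and the ring plane, folded into [0, 90]
#' degrees, is strictly below \code{max_angle}.
#'
#' The angle criterion follows the published rule; the distance gate is not
#' stated there, so it defaults to the generic 0.45 nm heavy-atom contact
#' cutoff and is exposed as a parameter. Purine rings use all nine ring
#' atoms by default (\code{purine_ring = "six"} selects the pyrimidine-like
#' six-ring instead).
#'
#' @param frame an [md_frame()].
#' @param centroid_cutoff CZ-to-ring-centroid cutoff (nm), default 0.45.
#' @param max_angle inter-plane angle limit (degrees), default 30.
#' @param purine_ring "nine" (default) or "six".
#' @return event data.frame with \code{mode = "stacking"}, \code{distance}
#'   (CZ-centroid, nm) and \code{angle} (degrees).
#' @export
detect_stacking <- function(frame, centroid_cutoff = 0.45, max_angle = 30,
                            purine_ring = c("nine", "six")) {
  stopifnot(inherits(frame, "md_frame"))
  purine_ring <- match.arg(purine_ring)
  at <- frame$atoms
  box <- frame$box
  # any residue carrying a phosphate must have a recognised base name
  phos_res <- unique(at$resname[at$atom_name %in% c("OP1", "OP2")])
  unknown <- setdiff(phos_res, NUCLEOTIDE_RESNAMES)
  if (length(unknown))
    stop("unsupported residue: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  arg_key <- res_key(at$chain, at$resid)
  args <- unique(arg_key[at$resname == "ARG"])
  nts <- unique(at[at$resname %in% NUCLEOTIDE_RESNAMES, c("chain", "resid", "resname")])
  if (!length(args) || !nrow(nts)) return(empty_event_table())
  rows <- list()
  for (ak in args) {
    sel <- at[arg_key == ak & at$atom_name %in% c("NE", "CZ", "NH1", "NH2"), ]
    if (nrow(sel) < 4) {
      warning("ARG ", ak, " lacks complete guanidinium atoms; skipped",
              call. = FALSE)
      next
    }
    gplane <- fit_plane(sel[c("x", "y", "z")])
    cz <- as.numeric(sel[sel$atom_name == "CZ", c("x", "y", "z")])
    for (j in seq_len(nrow(nts))) {
      rn <- ring_atom_names(nts$resname[j], purine_ring)
      ring <- at[at$chain == nts$chain[j] & at$resid == nts$resid[j] &
                   at$atom_name %in% rn, ]
      if (nrow(ring) < 3) next
      rxyz <- as.matrix(ring[c("x", "y", "z")])
      centroid <- colMeans(rxyz)
      dvec <- mi_disp(cz, matrix(centroid, 1), box)[1, ]
      dist <- sqrt(sum(dvec^2))
      if (dist >= centroid_cutoff) next
      rplane <- fit_plane(rxyz)
      ang <- plane_angle(gplane$unit_normal, rplane$unit_normal)
      if (ang < max_angle) {
        parts <- strsplit(ak, "/")[[1]]
        rows[[length(rows) + 1L]] <- data.frame(
          arg_chain = parts[1], arg_resid = as.integer(parts[2]),
          nt_chain = nts$chain[j], nt_resid = nts$resid[j],
          nt_resname = nts$resname[j], mode = "stacking",
          distance = dist, angle = ang, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) return(empty_event_table())
  do.call(rbind, rows)
}

#' Generic inter-chain heavy-atom contacts
#'
#' Two chains are in contact when any pair of heavy atoms (element other
#' than H) across them lies strictly closer than \code{cutoff}.
#'
#' @param frame an [md_frame()].
#' @param cutoff heavy-atom distance cutoff (nm), default 0.45.
#' @return data.frame of chain pairs in contact with the minimum cross-chain
#'   heavy-atom distance and the number of atom pairs under the cutoff.
#' @export
generic_contacts <- function(frame, cutoff = 0.45) {
  stopifnot(inherits(frame, "md_frame"))
  at <- frame$atoms[frame$atoms$element != "H", ]
  chains <- unique(at$chain)
  rows <- list()
  if (length(chains) >= 2) {
    for (i in seq_len(length(chains) - 1)) {
      a <- at[at$chain == chains[i], c("x", "y", "z")]
      for (j in (i + 1):length(chains)) {
        b <- at[at$chain == chains[j], c("x", "y", "z")]
        d <- pair_dist_matrix(a, b, frame$box)
        if (min(d) < cutoff)
          rows[[length(rows) + 1L]] <- data.frame(
            chain_a = chains[i], chain_b = chains[j],
            min_distance = min(d), n_pairs = sum(d < cutoff),
            stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows))
    return(data.frame(chain_a = character(), chain_b = character(),
                      min_distance = numeric(), n_pairs = integer(),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Classify all arginine-nucleotide contacts in a frame
#'
#' Runs the hydrogen-bond, ionic and stacking detectors and reduces events
#' to residue-pair granularity: one event per (arginine residue, nucleotide
#' residue) pair per mode. Hydrogen bonds are kept only for pairs where one
#' side is an arginine and the other a nucleotide, matching the
#' peptide-oligonucleotide interaction bookkeeping. Ionic and hydrogen-bond
#' events are mutually exclusive per residue pair by construction.
#'
#' @param frame an [md_frame()] (hydrogens required when "hbond" is among
#'   \code{modes}).
#' @param modes subset of c("hbond", "ionic", "stacking").
#' @param centroid_cutoff,max_angle,purine_ring passed to [detect_stacking()].
#' @param ionic_cutoff passed to [detect_ionic()].
#' @return event data.frame (arg chain/resid, nt chain/resid, mode,
#'   distance, angle).
#' @export
classify_contacts <- function(frame,
                              modes = c("hbond", "ionic", "stacking"),
                              ionic_cutoff = 0.6, centroid_cutoff = 0.45,
                              max_angle = 30, purine_ring = "nine") {
  at <- frame$atoms
  is_arg <- at$resname == "ARG"
  is_nt <- at$resname %in% NUCLEOTIDE_RESNAMES
  events <- list()
  hb <- if (any(c("hbond", "ionic") %in% modes)) detect_hbonds(frame)
        else empty_hbond_table()
  if ("hbond" %in% modes && nrow(hb)) {
    d_arg <- hb$donor_resname == "ARG" &
      hb$acceptor_resname %in% NUCLEOTIDE_RESNAMES
    a_arg <- hb$acceptor_resname == "ARG" &
      hb$donor_resname %in% NUCLEOTIDE_RESNAMES
    keep <- hb[d_arg | a_arg, ]
    if (nrow(keep)) {
      arg_side <- ifelse(keep$donor_resname == "ARG", "donor", "acceptor")
      ev <- data.frame(
        arg_chain = ifelse(arg_side == "donor", keep$donor_chain, keep$acceptor_chain),
        arg_resid = ifelse(arg_side == "donor", keep$donor_resid, keep$acceptor_resid),
        nt_chain = ifelse(arg_side == "donor", keep$acceptor_chain, keep$donor_chain),
        nt_resid = ifelse(arg_side == "donor", keep$acceptor_resid, keep$donor_resid),
        nt_resname = ifelse(arg_side == "donor", keep$acceptor_resname, keep$donor_resname),
        mode = "hbond", distance = keep$distance, angle = keep$angle,
        stringsAsFactors = FALSE)
      ev <- ev[!duplicated(ev[c("arg_chain", "arg_resid", "nt_chain", "nt_resid")]), ]
      events$hbond <- ev
    }
  }
  if ("ionic" %in% modes)
    events$ionic <- detect_ionic(frame, hb, cutoff = ionic_cutoff)
  if ("stacking" %in% modes)
    events$stacking <- detect_stacking(frame, centroid_cutoff = centroid_cutoff,
                                       max_angle = max_angle,
                                       purine_ring = purine_ring)
  events <- events[vapply(events, function(e) nrow(e) > 0, logical(1))]
  if (!length(events)) return(empty_event_table())
  out <- do.call(rbind, events)
  rownames(out) <- NULL
  out
}

resolve_window <- function(n_frames, window) {
  if (is.null(window)) return(seq_len(n_frames))
  if (is.character(window) && grepl("^last:[0-9]+$", window)) {
    k <- min(as.integer(sub("last:", "", window)), n_frames)
    return((n_frames - k + 1L):n_frames)
  }
  window <- as.integer(window)
  if (!length(window) || any(window < 1 | window > n_frames))
    stop("window outside trajectory", call. = FALSE)
  window
}

#' Per-frame per-nucleotide contact rates
#'
#' Counts classified residue-pair events in each frame of the analysis
#' window and normalises by (number of frames x number of nucleotide
#' residues), giving contacts per frame per nucleotide for each interaction
#' mode, the statistic used to compare peptide binding to DNA versus RNA.
#'
#' @param traj an [md_trajectory()].
#' @param window frame selection: NULL (all), an index vector, or
#'   \code{"last:n"} for the final n frames.
#' @param modes interaction modes to count.
#' @param ... passed to [classify_contacts()].
#' @return object of class \code{"contact_summary"}: \code{per_mode_rate},
#'   \code{total_rate}, \code{n_frames}, \code{n_nucleotides},
#'   \code{per_frame_counts} (frames x modes matrix).
#' @export
per_nucleotide_rates <- function(traj, window = NULL,
                                 modes = c("hbond", "ionic", "stacking"),
                                 ...) {
  stopifnot(inherits(traj, "md_trajectory"))
  idx <- resolve_window(length(traj$frames), window)
  if (!length(idx)) stop("empty analysis window", call. = FALSE)
  at1 <- traj$frames[[idx[1]]]$atoms
  nt_res <- unique(at1[at1$resname %in% NUCLEOTIDE_RESNAMES,
                       c("chain", "resid")])
  n_nt <- nrow(nt_res)
  if (!n_nt) stop("no nucleotide residues in frame", call. = FALSE)
  counts <- matrix(0, length(idx), length(modes),
                   dimnames = list(NULL, modes))
  for (fi in seq_along(idx)) {
    ev <- classify_contacts(traj$frames[[idx[fi]]], modes = modes, ...)
    if (nrow(ev)) {
      tab <- table(factor(ev$mode, levels = modes))
      counts[fi, ] <- as.numeric(tab)
    }
  }
  rate <- colSums(counts) / (length(idx) * n_nt)
  structure(list(per_mode_rate = rate, total_rate = sum(rate),
                 n_frames = length(idx), n_nucleotides = n_nt,
                 per_frame_counts = counts),
            class = "contact_summary")
}

#' @export
print.contact_summary <- function(x, ...) {
  cat("Contact summary (per frame, per nucleotide)\n")
  if (!is.null(x$per_mode_rate))
    for (m in names(x$per_mode_rate))
      cat(sprintf("  %-9s %.4f\n", m, x$per_mode_rate[m]))
  cat(sprintf("  total     %.4f\n", x$total_rate))
  if (!is.null(x$sd)) {
    cat(sprintf("  replicates: n = %d, sd(total) = %.4f\n",
                x$n_replicates, x$sd["total"]))
  } else {
    cat(sprintf("  frames: %d, nucleotides: %d\n", x$n_frames,
                x$n_nucleotides))
  }
  invisible(x)
}

#' Excess unbound peptide in a trajectory window
#'
#' Counts, in each frame, the peptide chains that make no generic
#' heavy-atom contact (< \code{cutoff}) with any nucleic-acid chain — the
#' peptide remaining free in the box at equilibrium — and averages the count
#' over the window.
#'
#' @param traj an [md_trajectory()].
#' @param window frame selection, as in [per_nucleotide_rates()].
#' @param cutoff heavy-atom contact cutoff (nm), default 0.45.
#' @return list: \code{mean}, \code{sd} (over frames), \code{per_frame}.
#' @export
excess_peptide <- function(traj, window = NULL, cutoff = 0.45) {
  stopifnot(inherits(traj, "md_trajectory"))
  idx <- resolve_window(length(traj$frames), window)
  per_frame <- vapply(idx, function(fi) {
    fr <- traj$frames[[fi]]
    at <- fr$atoms
    roles <- chain_roles(at)
    pep <- names(roles)[roles == "peptide"]
    nuc <- names(roles)[roles == "nucleic"]
    if (!length(pep)) stop("no peptide chains in frame", call. = FALSE)
    gc <- generic_contacts(fr, cutoff = cutoff)
    bound <- unique(c(gc$chain_a[gc$chain_b %in% nuc],
                      gc$chain_b[gc$chain_a %in% nuc]))
    sum(!(pep %in% bound))
  }, numeric(1))
  list(mean = mean(per_frame),
       sd = if (length(per_frame) > 1) stats::sd(per_frame) else 0,
       per_frame = per_frame)
}

# label chains as peptide / nucleic / other from their residue names
chain_roles <- function(atoms) {
  chains <- unique(atoms$chain)
  roles <- vapply(chains, function(ch) {
    rn <- unique(atoms$resname[atoms$chain == ch])
    if (any(rn %in% NUCLEOTIDE_RESNAMES)) "nucleic"
    else if (any(rn == "ARG")) "peptide"
    else "other"
  }, character(1))
  names(roles) <- chains
  roles
}

#' Aggregate contact summaries across replicates
#'
#' @param summaries list of \code{contact_summary} objects from independent
#'   replicate trajectories (>= 2, identical mode sets).
#' @return \code{contact_summary} with per-replicate rates plus mean and
#'   sample SD per mode and for the total.
#' @export
replicate_aggregate <- function(summaries) {
  stopifnot(length(summaries) >= 2,
            all(vapply(summaries, inherits, logical(1), "contact_summary")))
  modes <- names(summaries[[1]]$per_mode_rate)
  for (s in summaries)
    if (!identical(names(s$per_mode_rate), modes))
      stop("replicates have mismatched interaction modes", call. = FALSE)
  mat <- t(vapply(summaries, function(s)
    c(s$per_mode_rate, total = s$total_rate), numeric(length(modes) + 1)))
  structure(list(per_mode_rate = colMeans(mat)[modes],
                 total_rate = mean(mat[, "total"]),
                 mean = colMeans(mat),
                 sd = apply(mat, 2, stats::sd),
                 per_replicate = mat,
                 n_replicates = length(summaries)),
            class = "contact_summary")
}
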