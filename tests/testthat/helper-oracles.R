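# Independent brute-force oracles: naive loops re-implementing each
# geometric criterion from scratch, kept deliberately separate from the
# package's vectorised code paths. Oracles assume unboxed frames (the
# synthetic generator's default) except where noted.

euclid <- function(a, b) sqrt(sum((a - b)^2))

NT_NAMES <- c("A", "C", "G", "U", "DA", "DC", "DG", "DT")

# event keys at residue-pair granularity: "arg_resid|nt_resid|mode"
# (resids are globally unique in generated frames)
oracle_classify <- function(frame, ionic_cutoff = 0.6,
                            centroid_cutoff = 0.45, max_angle = 30) {
  at <- frame$atoms
  xyz <- as.matrix(at[c("x", "y", "z")])
  n <- nrow(at)
  keys <- character(0)
  rk <- paste(at$chain, at$resid)

  # --- hydrogen bonds (Wernet-Nilsson cone), arg-nt pairs only ---
  hb_pairs <- character(0)  # "resid_i|resid_j" unordered, all residue kinds
  for (d in seq_len(n)) {
    if (!(at$element[d] %in% c("N", "O"))) next
    hs <- integer(0)
    for (h in seq_len(n))
      if (at$element[h] == "H" && euclid(xyz[h, ], xyz[d, ]) < 0.12)
        hs <- c(hs, h)
    # keep hydrogens whose nearest heavy N/O is this donor
    hs <- Filter(function(h) {
      best <- Inf; bi <- 0
      for (a in seq_len(n))
        if (at$element[a] %in% c("N", "O")) {
          dd <- euclid(xyz[h, ], xyz[a, ])
          if (dd < best) { best <- dd; bi <- a }
        }
      bi == d
    }, hs)
    if (!length(hs)) next
    for (a in seq_len(n)) {
      if (a == d || !(at$element[a] %in% c("N", "O"))) next
      if (rk[a] == rk[d]) next
      r <- euclid(xyz[d, ], xyz[a, ])
      for (h in hs) {
        vh <- xyz[h, ] - xyz[d, ]
        va <- xyz[a, ] - xyz[d, ]
        th <- acos(min(1, max(-1, sum(vh * va) /
                                (sqrt(sum(vh^2)) * sqrt(sum(va^2)))))) * 180 / pi
        if (r < 0.33 - 0.000044 * th^2) {
          hb_pairs <- c(hb_pairs, paste(sort(c(at$resid[d], at$resid[a])),
                                        collapse = "|"))
          if (at$resname[d] == "ARG" && at$resname[a] %in% NT_NAMES)
            keys <- c(keys, paste(at$resid[d], at$resid[a], "hbond", sep = "|"))
          if (at$resname[a] == "ARG" && at$resname[d] %in% NT_NAMES)
            keys <- c(keys, paste(at$resid[a], at$resid[d], "hbond", sep = "|"))
        }
      }
    }
  }
  hb_pairs <- unique(hb_pairs)

  # --- ionic: CZ vs OP1/OP2 without an hbond between the residues ---
  for (i in seq_len(n)) {
    if (at$resname[i] != "ARG" || at$atom_name[i] != "CZ") next
    for (j in seq_len(n)) {
      if (!(at$resname[j] %in% NT_NAMES) ||
          !(at$atom_name[j] %in% c("OP1", "OP2"))) next
      if (euclid(xyz[i, ], xyz[j, ]) < ionic_cutoff) {
        pk <- paste(sort(c(at$resid[i], at$resid[j])), collapse = "|")
        if (!(pk %in% hb_pairs))
          keys <- c(keys, paste(at$resid[i], at$resid[j], "ionic", sep = "|"))
      }
    }
  }

  # --- stacking: CZ near ring centroid, planes within 30 degrees ---
  svd_normal <- function(m) {
    c <- sweep(m, 2, colMeans(m))
    svd(c)$v[, 3]
  }
  arg_res <- unique(at$resid[at$resname == "ARG"])
  nt_res <- unique(at$resid[at$resname %in% NT_NAMES])
  for (ar in arg_res) {
    g <- at$resid == ar & at$atom_name %in% c("NE", "CZ", "NH1", "NH2")
    if (sum(g) < 4) next
    ng <- svd_normal(xyz[g, , drop = FALSE])
    cz <- xyz[at$resid == ar & at$atom_name == "CZ", ]
    for (nr in nt_res) {
      resname <- at$resname[at$resid == nr][1]
      rn <- if (resname %in% c("A", "G", "DA", "DG"))
        c("N9", "C8", "N7", "C5", "C6", "N1", "C2", "N3", "C4")
      else c("N1", "C2", "N3", "C4", "C5", "C6")
      sel <- at$resid == nr & at$atom_name %in% rn
      if (sum(sel) < 3) next
      rxyz <- xyz[sel, , drop = FALSE]
      cen <- colMeans(rxyz)
      if (euclid(cz, cen) >= centroid_cutoff) next
      nr_ <- svd_normal(rxyz)
      ang <- acos(min(1, abs(sum(ng * nr_)))) * 180 / pi
      if (ang < max_angle)
        keys <- c(keys, paste(ar, nr, "stacking", sep = "|"))
    }
  }
  sort(unique(keys))
}

# package classification reduced to the same key set
classify_keys <- function(frame, ...) {
  ev <- classify_contacts(frame, ...)
  if (!nrow(ev)) return(character(0))
  sort(unique(paste(ev$arg_resid, ev$nt_resid, ev$mode, sep = "|")))
}

truth_keys <- function(truth) {
  if (!nrow(truth)) return(character(0))
  sort(unique(paste(truth$arg_resid, truth$nt_resid, truth$mode, sep = "|")))
}

# brute-force generic chain contacts
oracle_generic <- function(frame, cutoff = 0.45) {
  at <- frame$atoms[frame$atoms$element != "H", ]
  xyz <- as.matrix(at[c("x", "y", "z")])
  chains <- unique(at$chain)
  out <- character(0)
  for (ci in seq_along(chains)) for (cj in seq_along(chains)) {
    if (cj <= ci) next
    ia <- which(at$chain == chains[ci]); ib <- which(at$chain == chains[cj])
    hit <- FALSE
    for (i in ia) for (j in ib)
      if (euclid(xyz[i, ], xyz[j, ]) < cutoff) { hit <- TRUE; break }
    if (hit) out <- c(out, paste(chains[ci], chains[cj], sep = "|"))
  }
  sort(out)
}

# brute-force CG contact pairs with minimum image (row-by-row enumeration;
# the per-row arithmetic is vectorised only for speed)
oracle_cg_pairs <- function(frame, exclude_bonded = TRUE) {
  b <- frame$beads
  box <- frame$box
  n <- nrow(b)
  out <- character(0)
  for (i in seq_len(n - 1)) {
    j <- (i + 1):n
    dx <- b$x[i] - b$x[j]; dx <- dx - box[1] * round(dx / box[1])
    dy <- b$y[i] - b$y[j]; dy <- dy - box[2] * round(dy / box[2])
    dz <- b$z[i] - b$z[j]; dz <- dz - box[3] * round(dz / box[3])
    dist <- sqrt(dx^2 + dy^2 + dz^2)
    cut <- 0.5 * (b$sigma[i] + b$sigma[j]) + 0.1
    hit <- j[dist < cut]
    if (exclude_bonded)
      hit <- hit[!(b$chain[i] == b$chain[hit] & hit - i == 1L)]
    if (length(hit)) out <- c(out, paste(i, hit, sep = "|"))
  }
  sort(out)
}

# exhaustive enumeration of 3-point OLS fits via lm()
oracle_steepest <- function(x, y, window = 3) {
  best <- NULL
  for (i in seq_len(length(x) - window + 1)) {
    idx <- i:(i + window - 1)
    f <- stats::lm(y[idx] ~ x[idx])
    s <- unname(coef(f)[2])
    if (is.null(best) || abs(s) > abs(best$slope))
      best <- list(slope = s, intercept = unname(coef(f)[1]), start = i)
  }
  best
}
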