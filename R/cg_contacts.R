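# Coarse-grained bead contacts and slab-coexistence density profiles.

#' Construct a coarse-grained frame
#'
#' One-bead-per-residue configurations from direct-coexistence slab
#' simulations. Beads within a chain are assumed to be stored in chain order
#' (bonded neighbours are consecutive rows of the same chain).
#'
#' @param beads data.frame with columns \code{chain}, \code{type},
#'   \code{sigma} (nm, > 0), \code{x}, \code{y}, \code{z} (nm).
#' @param box box lengths (nm), numeric length 3.
#' @return object of class \code{"cg_frame"}.
#' @export
cg_frame <- function(beads, box) {
  need <- c("chain", "type", "sigma", "x", "y", "z")
  miss <- setdiff(need, names(beads))
  if (length(miss))
    stop("beads table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  bad <- unique(beads$type[!is.finite(beads$sigma) | beads$sigma <= 0])
  if (length(bad))
    stop("missing or invalid sigma for bead type(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  stopifnot(length(box) == 3, all(box > 0))
  structure(list(beads = beads, box = as.numeric(box)), class = "cg_frame")
}

#' Coarse-grained contact pairs
#'
#' Beads i and j are in contact when their minimum-image distance is
#' strictly below \eqn{0.5(\sigma_i + \sigma_j) + 0.1} nm. Bonded
#' nearest-neighbour pairs (consecutive beads of the same chain) are
#' excluded, so the count reflects cohesive rather than covalent proximity;
#' set \code{exclude_bonded = FALSE} to keep them.
#'
#' @param frame a [cg_frame()].
#' @param exclude_bonded drop intra-chain nearest neighbours (default TRUE).
#' @return data.frame of contacts: bead indices \code{i < j}, their types,
#'   \code{distance} and the pair \code{cutoff} (nm).
#' @export
cg_contact_pairs <- function(frame, exclude_bonded = TRUE) {
  stopifnot(inherits(frame, "cg_frame"))
  b <- frame$beads
  n <- nrow(b)
  if (n < 2)
    return(data.frame(i = integer(), j = integer(), type_i = character(),
                      type_j = character(), distance = numeric(),
                      cutoff = numeric(), stringsAsFactors = FALSE))
  xyz <- as.matrix(b[c("x", "y", "z")])
  d <- pair_dist_matrix(xyz, xyz, frame$box)
  cut <- outer(b$sigma, b$sigma, function(si, sj) 0.5 * (si + sj) + 0.1)
  hit <- which(d < cut & upper.tri(d), arr.ind = TRUE)
  if (nrow(hit) && exclude_bonded) {
    same_chain <- b$chain[hit[, 1]] == b$chain[hit[, 2]]
    adjacent <- abs(hit[, 1] - hit[, 2]) == 1L
    hit <- hit[!(same_chain & adjacent), , drop = FALSE]
  }
  data.frame(i = hit[, 1], j = hit[, 2],
             type_i = b$type[hit[, 1]], type_j = b$type[hit[, 2]],
             distance = d[hit], cutoff = cut[hit],
             stringsAsFactors = FALSE)
}

#' Slab density profile along a box axis
#'
#' Bins bead counts along one axis of the periodic box and normalises by bin
#' volume, yielding a number-density profile (beads/nm^3) that exposes the
#' coexisting dense and dilute phases of a direct-coexistence slab. With
#' \code{recenter = TRUE} the profile is shifted so that the periodic centre
#' of mass (circular mean along the axis) sits at the box centre, which makes
#' profiles from drifting slabs comparable.
#'
#' @param frame a [cg_frame()].
#' @param axis "x", "y" or "z".
#' @param n_bins number of bins (>= 10).
#' @param recenter recentre on the dense slab's periodic centre of mass.
#' @return data.frame: bin \code{center} (nm), \code{density} (beads/nm^3),
#'   \code{count}.
#' @export
slab_density_profile <- function(frame, axis = c("x", "y", "z"),
                                 n_bins = 100L, recenter = TRUE) {
  stopifnot(inherits(frame, "cg_frame"))
  axis <- match.arg(axis)
  if (n_bins < 10) stop("n_bins must be >= 10", call. = FALSE)
  if (!nrow(frame$beads)) stop("empty frame", call. = FALSE)
  k <- match(axis, c("x", "y", "z"))
  L <- frame$box[k]
  pos <- frame$beads[[axis]] %% L
  if (recenter) {
    theta <- 2 * pi * pos / L
    com <- atan2(mean(sin(theta)), mean(cos(theta))) * L / (2 * pi)
    pos <- (pos - com + L / 2) %% L
  }
  edges <- seq(0, L, length.out = n_bins + 1L)
  counts <- as.numeric(table(cut(pos, edges, include.lowest = TRUE,
                                 labels = FALSE)))
  counts_full <- numeric(n_bins)
  idx <- as.integer(names(table(cut(pos, edges, include.lowest = TRUE,
                                    labels = FALSE))))
  counts_full[idx] <- counts
  bin_vol <- (L / n_bins) * prod(frame$box[-k])
  data.frame(center = (edges[-1] + edges[-length(edges)]) / 2,
             density = counts_full / bin_vol,
             count = counts_full)
}
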