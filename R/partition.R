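# Image-based partition coefficients for fluorescent clients in droplets.

#' Partition coefficient from the three intensity components
#'
#' \deqn{K_p = (I_{droplet} - I_{dark}) / (I_{dilute} - I_{dark})}
#'
#' The dark intensity (a field with no fluorophore, same laser power)
#' removes the detector offset, which makes \eqn{K_p} invariant under affine
#' intensity transforms applied jointly to all three inputs.
#'
#' @param i_droplet mean intensity over droplet pixels (AU).
#' @param i_dilute mean intensity of the dilute phase (AU).
#' @param i_dark mean dark-field intensity (AU).
#' @return the dimensionless partition coefficient.
#' @examples
#' compute_kp(110, 20, 10)  # 10
#' @export
compute_kp <- function(i_droplet, i_dilute, i_dark) {
  stopifnot(is.finite(i_droplet), is.finite(i_dilute), is.finite(i_dark))
  if (i_dilute <= i_dark)
    stop("undefined Kp: dilute-phase intensity does not exceed dark level",
         call. = FALSE)
  (i_droplet - i_dark) / (i_dilute - i_dark)
}

#' Segment droplets in a fluorescence micrograph
#'
#' Global threshold (Otsu's method scaled by \code{factor}; the default 0.8
#' is a deliberately low threshold so droplet pixels are not underestimated)
#' followed by connected-component labelling. Components smaller than
#' \code{min_px} pixels are discarded; droplets touching the border are
#' kept.
#'
#' @param img numeric intensity matrix (at least 16 x 16 pixels).
#' @param factor multiplier on the Otsu threshold (default 0.8).
#' @param min_px minimum component area in pixels (default 4).
#' @return integer label matrix (0 = background) with attribute
#'   \code{"n_droplets"}; all-zero with \code{n_droplets = 0} when nothing
#'   is found.
#' @export
segment_droplets <- function(img, factor = 0.8, min_px = 4L) {
  img <- as.matrix(img)
  if (any(dim(img) < 16)) stop("image smaller than 16x16 px", call. = FALSE)
  if (any(!is.finite(img)) || any(img < 0))
    stop("intensities must be finite and non-negative", call. = FALSE)
  rng <- range(img)
  if (diff(rng) == 0) {
    lab <- matrix(0L, nrow(img), ncol(img))
    attr(lab, "n_droplets") <- 0L
    return(lab)
  }
  scaled <- (img - rng[1]) / diff(rng)
  thr <- factor * EBImage::otsu(EBImage::Image(scaled), range = c(0, 1))
  mask <- scaled > thr
  lab <- EBImage::bwlabel(EBImage::Image(mask))
  lab <- EBImage::imageData(lab)
  if (max(lab) > 0) {
    sizes <- tabulate(lab[lab > 0])
    drop_small <- which(sizes < min_px)
    if (length(drop_small)) lab[lab %in% drop_small] <- 0L
    # relabel consecutively
    kept <- sort(unique(lab[lab > 0]))
    lab[] <- match(lab, kept, nomatch = 0L) * (lab > 0)
  }
  lab <- matrix(as.integer(lab), nrow(img), ncol(img))
  attr(lab, "n_droplets") <- length(unique(lab[lab > 0]))
  lab
}

#' Partition coefficient from a micrograph and a dark frame
#'
#' Segments droplets, pools all droplet pixels for \eqn{I_{droplet}},
#' averages the field of view outside a one-pixel dilation of the droplet
#' mask for \eqn{I_{dilute}} (the dilation keeps droplet-edge halos out of
#' the dilute estimate), takes the dark frame's mean for \eqn{I_{dark}},
#' and applies [compute_kp()].
#'
#' @param img intensity matrix of the sample field of view.
#' @param dark intensity matrix of the fluorophore-free dark field (same
#'   shape).
#' @param factor,min_px passed to [segment_droplets()].
#' @return object of class \code{"partition_result"}: \code{kp},
#'   \code{i_droplet}, \code{i_dilute}, \code{i_dark}, \code{n_droplets},
#'   \code{mask_coverage} (fraction of FOV inside droplets), \code{labels}.
#' @export
kp_from_images <- function(img, dark, factor = 0.8, min_px = 4L) {
  img <- as.matrix(img); dark <- as.matrix(dark)
  if (!identical(dim(img), dim(dark)))
    stop("sample and dark images must have the same shape", call. = FALSE)
  lab <- segment_droplets(img, factor = factor, min_px = min_px)
  n <- attr(lab, "n_droplets")
  if (n == 0) {
    out <- structure(list(kp = NA_real_, i_droplet = NA_real_,
                          i_dilute = mean(img), i_dark = mean(dark),
                          n_droplets = 0L, mask_coverage = 0,
                          labels = lab),
                     class = "partition_result")
    attr(out, "no_droplets") <- TRUE
    return(out)
  }
  mask <- lab > 0
  dil <- EBImage::imageData(EBImage::dilate(EBImage::Image(mask),
                                            EBImage::makeBrush(3, "box"))) > 0
  if (all(dil)) stop("droplet mask covers the whole field of view", call. = FALSE)
  i_droplet <- mean(img[mask])
  i_dilute <- mean(img[!dil])
  i_dark <- mean(dark)
  structure(list(kp = compute_kp(i_droplet, i_dilute, i_dark),
                 i_droplet = i_droplet, i_dilute = i_dilute, i_dark = i_dark,
                 n_droplets = n, mask_coverage = mean(mask), labels = lab),
            class = "partition_result")
}

#' @export
print.partition_result <- function(x, ...) {
  if (x$n_droplets == 0) {
    cat("Partition result: no droplets detected\n")
  } else {
    cat(sprintf("Partition coefficient Kp = %.3f\n", x$kp))
    cat(sprintf("  I_droplet = %.2f, I_dilute = %.2f, I_dark = %.2f\n",
                x$i_droplet, x$i_dilute, x$i_dark))
    cat(sprintf("  %d droplets, %.1f%% of FOV\n", x$n_droplets,
                100 * x$mask_coverage))
  }
  invisible(x)
}
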