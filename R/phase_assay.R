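#' Convert 600-nm absorbance to percent turbidity
#'
#' Plate readers report absorbance; droplet-containing samples scatter light,
#' so turbidity is derived from the transmittance relative to a blank well:
#' \deqn{Turbidity = 100 - Transmittance\% = 100 (1 - 10^{Abs_{blank} - Abs})}
#'
#' Values can be slightly negative when a well reads below the blank; these
#' are retained (and flagged via attribute \code{"negative"}) rather than
#' clamped, so that least-squares tangent fits near the blank level are not
#' biased.
#'
#' @param abs absorbance at 600 nm (AU), vector allowed.
#' @param blank blank-well absorbance (AU), scalar or vector recycled.
#' @return numeric vector of turbidity in percent, with logical attribute
#'   \code{"negative"} marking entries below zero.
#' @examples
#' absorbance_to_turbidity(1.2, 0.2)  # 90
#' @export
absorbance_to_turbidity <- function(abs, blank) {
  if (!all(is.finite(abs)) || !all(is.finite(blank)))
    stop("absorbance_to_turbidity: non-finite input", call. = FALSE)
  turb <- 100 * (1 - 10^(blank - abs))
  attr(turb, "negative") <- turb < 0
  turb
}

# inverse of the turbidity relation; used by the synthetic generator
turbidity_to_absorbance <- function(turbidity, blank) {
  if (any(turbidity >= 100))
    stop("turbidity >= 100% has no finite absorbance", call. = FALSE)
  blank - log10(1 - turbidity / 100)
}

#' Construct a titration record
#'
#' One well's NaCl titration: the starting condition plus the volume added at
#' each step and the absorbance read before the first addition and after each
#' subsequent one.
#'
#' @param initial_volume starting well volume (uL).
#' @param initial_salt NaCl concentration before titration (mM).
#' @param titrant_stock NaCl stock concentration (mM); concentrated stocks
#'   (1-5 M) keep the total dilution small.
#' @param addition_volumes volume added at each step (uL).
#' @param absorbances absorbance at 600 nm; length must be
#'   \code{length(addition_volumes) + 1}, first value pre-titration.
#' @param blank_absorbance blank-well absorbance (AU).
#' @param label free-text sample label, e.g. \code{"R4/RNA8 4:1"}.
#' @return an object of class \code{"titration_record"}.
#' @export
titration_record <- function(initial_volume, initial_salt, titrant_stock,
                             addition_volumes, absorbances,
                             blank_absorbance, label = "") {
  stopifnot(is.numeric(initial_volume), initial_volume > 0,
            is.numeric(initial_salt), initial_salt >= 0,
            is.numeric(titrant_stock), titrant_stock > 0)
  if (length(addition_volumes) && any(addition_volumes <= 0))
    stop("all addition volumes must be > 0", call. = FALSE)
  if (length(absorbances) != length(addition_volumes) + 1L)
    stop("need length(absorbances) == length(addition_volumes) + 1",
         call. = FALSE)
  structure(list(initial_volume   = as.numeric(initial_volume),
                 initial_salt     = as.numeric(initial_salt),
                 titrant_stock    = as.numeric(titrant_stock),
                 addition_volumes = as.numeric(addition_volumes),
                 absorbances      = as.numeric(absorbances),
                 blank_absorbance = as.numeric(blank_absorbance),
                 label            = label),
            class = "titration_record")
}

#' @export
print.titration_record <- function(x, ...) {
  cat("Titration record", if (nzchar(x$label)) paste0("[", x$label, "]"), "\n")
  cat(sprintf("  %d additions, V0 = %g uL, stock = %g mM NaCl\n",
              length(x$addition_volumes), x$initial_volume, x$titrant_stock))
  invisible(x)
}

#' Cumulative NaCl concentration along a titration
#'
#' Accounts for the growing total volume in the well:
#' \eqn{c_i = (c_0 V_0 + c_{stock} \sum \Delta v) / (V_0 + \sum \Delta v)}.
#' The first element (no addition) equals the initial salt concentration.
#'
#' @param rec a [titration_record()].
#' @return numeric vector (mM), one value per absorbance reading.
#' @export
salt_series <- function(rec) {
  stopifnot(inherits(rec, "titration_record"))
  added <- c(0, cumsum(rec$addition_volumes))
  total <- rec$initial_volume + added
  if (any(total <= 0)) stop("zero total volume", call. = FALSE)
  (rec$initial_salt * rec$initial_volume + rec$titrant_stock * added) / total
}

#' Build a turbidity curve from a titration record
#'
#' @param rec a [titration_record()].
#' @return a \code{data.frame} of class \code{"turbidity_curve"} with columns
#'   \code{salt_conc} (mM, strictly increasing) and \code{turbidity} (percent).
#' @export
turbidity_curve <- function(rec) {
  conc <- salt_series(rec)
  if (any(diff(conc) <= 0))
    stop("salt series is not strictly increasing; check stock vs initial salt",
         call. = FALSE)
  turb <- absorbance_to_turbidity(rec$absorbances, rec$blank_absorbance)
  out <- data.frame(salt_conc = conc, turbidity = as.numeric(turb))
  class(out) <- c("turbidity_curve", "data.frame")
  out
}

#' Steepest sliding-window tangent of a turbidity curve
#'
#' Fits an ordinary-least-squares line to every window of \code{window}
#' consecutive points and returns the fit with the largest absolute slope,
#' which serves as the tangent at the inflection point of the sigmoidal
#' titration curve. Ties on |slope| are broken by the lowest window start.
#'
#' @param curve a \code{turbidity_curve}, or any data.frame with
#'   \code{salt_conc} and \code{turbidity} columns (other x/y data may be
#'   passed via \code{x}, \code{y}).
#' @param window number of consecutive points per fit (default 3).
#' @param x,y optional raw vectors overriding \code{curve}.
#' @return list of class \code{"tangent_fit"}: \code{slope} (%/mM),
#'   \code{intercept} (%), \code{window_start_index} (1-based),
#'   \code{r_squared}.
#' @export
steepest_tangent <- function(curve = NULL, window = 3L, x = NULL, y = NULL) {
  if (is.null(x)) {
    x <- curve$salt_conc
    y <- curve$turbidity
  }
  n <- length(x)
  window <- as.integer(window)
  if (window < 2L) stop("window must be >= 2", call. = FALSE)
  if (n < window)
    stop(sprintf("need at least %d points, got %d", window, n), call. = FALSE)
  best <- NULL
  for (i in seq_len(n - window + 1L)) {
    idx <- i:(i + window - 1L)
    fit <- stats::lm.fit(cbind(1, x[idx]), y[idx])
    slope <- fit$coefficients[2]
    # ties (within fp tolerance) keep the earliest window
    if (is.null(best) ||
        abs(slope) > abs(best$slope) + 1e-12 + 1e-9 * abs(best$slope)) {
      ss_res <- sum(fit$residuals^2)
      ss_tot <- sum((y[idx] - mean(y[idx]))^2)
      r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
      best <- list(slope = unname(slope),
                   intercept = unname(fit$coefficients[1]),
                   window_start_index = i,
                   r_squared = r2,
                   window = window)
    }
  }
  structure(best, class = "tangent_fit")
}

#' @export
print.tangent_fit <- function(x, ...) {
  cat(sprintf("Tangent fit: slope %.4g %%/mM, intercept %.4g %%, window at %d, R2 %.4f\n",
              x$slope, x$intercept, x$window_start_index, x$r_squared))
  invisible(x)
}

#' Critical salt concentration from a tangent line
#'
#' The CSC is the x-intercept of the tangent \eqn{y = a x + b} at the
#' inflection of the turbidity decay: \eqn{CSC = -b/a}.
#'
#' @param t a \code{tangent_fit}.
#' @return CSC (mM).
#' @export
csc_from_tangent <- function(t) {
  stopifnot(inherits(t, "tangent_fit"))
  if (t$slope == 0) stop("degenerate tangent: slope is zero", call. = FALSE)
  -t$intercept / t$slope
}

#' Extract the critical salt concentration from a titration
#'
#' Full pipeline: dilution-corrected salt series, absorbance-to-turbidity
#' conversion, steepest three-point tangent, and \eqn{CSC = -b/a}. The CSC is
#' the highest NaCl concentration tolerated before complete droplet
#' dissolution. A warning flag is attached when the final turbidity exceeds
#' 5\% of the initial plateau (dissolution apparently incomplete), and when
#' the intercept falls outside the sampled salt range (extrapolated).
#'
#' @param rec a [titration_record()] or a \code{turbidity_curve}.
#' @param window tangent window size (default 3 points).
#' @return object of class \code{"csc_fit"}: \code{csc} (mM),
#'   \code{tangent}, \code{curve}, logical flags \code{extrapolated} and
#'   \code{incomplete_dissolution}, and \code{label}.
#' @examples
#' sim <- gen_titration(seed = 1, noise_sd = 0)
#' fit <- extract_csc(sim$record)
#' fit$csc          # close to sim$truth$csc
#' @export
extract_csc <- function(rec, window = 3L) {
  curve <- if (inherits(rec, "turbidity_curve")) rec else turbidity_curve(rec)
  turb <- curve$turbidity
  if (max(turb) < 1)
    stop("insufficient signal: curve never rises above 1% turbidity",
         call. = FALSE)
  tang <- steepest_tangent(curve, window = window)
  csc <- csc_from_tangent(tang)
  plateau <- max(turb)
  incomplete <- turb[length(turb)] > 0.05 * plateau
  if (incomplete)
    warning("final turbidity exceeds 5% of the plateau; dissolution may be incomplete",
            call. = FALSE)
  extrap <- csc < min(curve$salt_conc) || csc > max(curve$salt_conc)
  structure(list(csc = csc, tangent = tang, curve = curve,
                 extrapolated = extrap,
                 incomplete_dissolution = incomplete,
                 label = if (inherits(rec, "titration_record")) rec$label else ""),
            class = "csc_fit")
}

#' @export
print.csc_fit <- function(x, ...) {
  cat("Critical salt concentration",
      if (nzchar(x$label)) paste0("[", x$label, "]"), "\n")
  cat(sprintf("  CSC = %.1f mM NaCl%s\n", x$csc,
              if (x$extrapolated) " (extrapolated beyond sampled range)" else ""))
  cat(sprintf("  tangent: slope %.4g %%/mM over %d points from index %d\n",
              x$tangent$slope, x$tangent$window, x$tangent$window_start_index))
  invisible(x)
}

#' @export
coef.csc_fit <- function(object, ...) {
  c(csc = object$csc, slope = object$tangent$slope,
    intercept = object$tangent$intercept)
}

#' @export
plot.csc_fit <- function(x, ...) {
  plot(x$curve$salt_conc, x$curve$turbidity, xlab = "NaCl (mM)",
       ylab = "Turbidity (%)", main = x$label, ...)
  graphics::abline(a = x$tangent$intercept, b = x$tangent$slope, lty = 2)
  graphics::abline(v = x$csc, col = "red")
  invisible(x)
}

#' Coacervation onset concentration
#'
#' The onset is defined as the first measured concentration at which
#' turbidity strictly exceeds 20\%. No interpolation is performed: the rule
#' is a threshold on measured points, not a fit.
#'
#' @param conc increasing concentration vector (mM amino acid).
#' @param turbidity percent turbidity, same length.
#' @param threshold onset threshold in percent (default 20).
#' @return the onset concentration (mM), or \code{NA_real_} with attribute
#'   \code{"no_onset" = TRUE} when the threshold is never exceeded.
#' @export
onset_concentration <- function(conc, turbidity, threshold = 20) {
  stopifnot(length(conc) == length(turbidity))
  if (any(diff(conc) <= 0)) stop("conc must be strictly increasing", call. = FALSE)
  hit <- which(turbidity > threshold)
  if (!length(hit)) {
    out <- NA_real_
    attr(out, "no_onset") <- TRUE
    return(out)
  }
  conc[hit[1]]
}

#' Minimal complex concentration for coacervation
#'
#' For a dilution series in which turbidity rises sigmoidally with total
#' complex concentration, the minimal concentration required for coacervation
#' is the x-intercept of the tangent at the inflection point of the rising
#' curve (steepest positive-slope window).
#'
#' @param conc concentration vector (any concentration unit; the result is in
#'   the same unit), increasing.
#' @param turbidity percent turbidity, rising with concentration.
#' @param window tangent window size (default 3).
#' @return the x-intercept concentration.
#' @export
minimal_complex_concentration <- function(conc, turbidity, window = 3L) {
  stopifnot(length(conc) == length(turbidity))
  tang <- steepest_tangent(x = conc, y = turbidity, window = window)
  if (tang$slope <= 0)
    stop("no rising region: steepest tangent has non-positive slope",
         call. = FALSE)
  -tang$intercept / tang$slope
}

#' Fit the minimal peptide length N_min from a CSC-vs-length series
#'
#' Coacervate salt stability grows with peptide length N following a linear
#' relation between CSC and 1/N: \eqn{CSC = m / N + c}. The fitted line
#' crosses CSC = 0 at \eqn{N_{min} = -m / c}, the shortest peptide predicted
#' to support coacervation with the given oligonucleotide.
#'
#' @param peptide_lengths integer vector of peptide lengths N (>= 2 distinct
#'   values, each >= 2).
#' @param csc_values CSC per length (mM).
#' @return object of class \code{"nmin_fit"}: \code{slope} (mM*N),
#'   \code{intercept} (mM), \code{n_min} (residues), \code{r_squared}, and
#'   \code{non_physical} flag (TRUE when the line never crosses zero for
#'   positive N).
#' @examples
#' fit <- fit_nmin(c(4, 8), c(100, 250))
#' fit$n_min  # 3
#' @export
fit_nmin <- function(peptide_lengths, csc_values) {
  n <- peptide_lengths
  if (length(n) < 2 || anyDuplicated(n))
    stop("need >= 2 distinct peptide lengths", call. = FALSE)
  if (any(n < 2)) stop("peptide lengths must be >= 2", call. = FALSE)
  stopifnot(length(csc_values) == length(n))
  inv_n <- 1 / n
  fit <- stats::lm(csc_values ~ inv_n)
  m <- unname(stats::coef(fit)[2])
  c0 <- unname(stats::coef(fit)[1])
  if (c0 == 0) stop("zero intercept: N_min undefined", call. = FALSE)
  r2 <- if (length(n) > 2) {
    ss_res <- sum(stats::residuals(fit)^2)
    ss_tot <- sum((csc_values - mean(csc_values))^2)
    if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  } else 1
  non_physical <- sign(m) == sign(c0)
  if (non_physical)
    warning("slope and intercept share sign: fitted line never crosses CSC = 0 for positive N",
            call. = FALSE)
  structure(list(slope = m, intercept = c0, n_min = -m / c0,
                 r_squared = r2, non_physical = non_physical,
                 peptide_lengths = n, csc_values = csc_values, lm = fit),
            class = "nmin_fit")
}

#' @export
print.nmin_fit <- function(x, ...) {
  cat("Minimal peptide length fit: CSC = m/N + c\n")
  cat(sprintf("  m = %.4g mM*N, c = %.4g mM, R2 = %.3f\n",
              x$slope, x$intercept, x$r_squared))
  cat(sprintf("  N_min = %.2f residues%s\n", x$n_min,
              if (x$non_physical) " (non-physical fit)" else ""))
  invisible(x)
}

#' @export
coef.nmin_fit <- function(object, ...) {
  c(slope = object$slope, intercept = object$intercept, n_min = object$n_min)
}

#' @export
predict.nmin_fit <- function(object, peptide_lengths, ...) {
  object$slope / peptide_lengths + object$intercept
}

#' @export
plot.nmin_fit <- function(x, ...) {
  plot(1 / x$peptide_lengths, x$csc_values, xlab = "1/N",
       ylab = "CSC (mM)", ...)
  graphics::abline(a = x$intercept, b = x$slope, lty = 2)
  invisible(x)
}
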