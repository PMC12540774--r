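# FRAP trace normalisation and exponential recovery-time fitting.

#' Construct a FRAP trace
#'
#' Region-of-interest intensity over time for one bleached droplet. The
#' first \code{n_prebleach} points are pre-bleach frames; the bleach happens
#' between indices \code{n_prebleach} and \code{n_prebleach + 1}.
#'
#' @param times acquisition times (s), strictly increasing.
#' @param intensities ROI intensities (AU), same length.
#' @param n_prebleach number of pre-bleach frames (>= 1, < length).
#' @param droplet_id identifier, free text.
#' @param normalized logical; TRUE after [normalize_trace()].
#' @return object of class \code{"frap_trace"}.
#' @export
frap_trace <- function(times, intensities, n_prebleach, droplet_id = "",
                       normalized = FALSE) {
  stopifnot(length(times) == length(intensities),
            n_prebleach >= 1, n_prebleach < length(times))
  if (any(diff(times) <= 0))
    stop("times must be strictly increasing", call. = FALSE)
  structure(list(times = as.numeric(times),
                 intensities = as.numeric(intensities),
                 n_prebleach = as.integer(n_prebleach),
                 droplet_id = droplet_id, normalized = normalized),
            class = "frap_trace")
}

#' @export
print.frap_trace <- function(x, ...) {
  cat(sprintf("FRAP trace %s: %d frames (%d pre-bleach)%s\n",
              x$droplet_id, length(x$times), x$n_prebleach,
              if (x$normalized) ", normalized" else ""))
  invisible(x)
}

#' Normalise a FRAP trace to its pre-bleach intensity
#'
#' Divides the whole trace by the mean of the pre-bleach frames, so the
#' pre-bleach level is 1 by construction and traces from different droplets
#' and laser powers are comparable. The operation is invariant to any
#' positive rescaling of the raw intensities.
#'
#' @param t a [frap_trace()].
#' @return the normalised trace.
#' @export
normalize_trace <- function(t) {
  stopifnot(inherits(t, "frap_trace"))
  pre <- mean(t$intensities[seq_len(t$n_prebleach)])
  if (!is.finite(pre) || pre == 0)
    stop("pre-bleach mean is zero; cannot normalise", call. = FALSE)
  t$intensities <- t$intensities / pre
  t$normalized <- TRUE
  t
}

#' Fit a single-exponential FRAP recovery
#'
#' Fits \eqn{I(t') = P - (P - B) e^{-t'/\tau}} to the post-bleach portion of
#' a normalised trace, with \eqn{t' = 0} at the first post-bleach frame.
#' By default all three parameters are free ("freeB"); \code{model =
#' "fixedB"} anchors the bleach depth \eqn{B} to the first post-bleach
#' intensity instead. The free-\eqn{B} fit is preferred because anchoring
#' \eqn{B} to a single noisy reading propagates that reading's error into
#' \eqn{\tau}. The mobile fraction
#' is \eqn{(P - B)/(1 - B)}; incomplete recovery (\eqn{P < 1}) is common for
#' strongly partitioned probes and leaves \eqn{\tau} unaffected.
#'
#' @param t a normalised [frap_trace()] (raw traces are normalised first)
#'   with at least 5 post-bleach points.
#' @param model "freeB" (default) or "fixedB".
#' @return object of class \code{"frap_fit"}: \code{tau} (s),
#'   \code{bleach_depth}, \code{plateau}, \code{mobile_fraction},
#'   \code{r_squared}, \code{model}, plus the post-bleach data used.
#' @examples
#' tr <- gen_frap(seed = 1, noise_sd = 0)
#' fit_recovery(tr$trace)$tau  # recovers the planted tau
#' @export
fit_recovery <- function(t, model = c("freeB", "fixedB")) {
  stopifnot(inherits(t, "frap_trace"))
  model <- match.arg(model)
  if (!t$normalized) t <- normalize_trace(t)
  post <- (t$n_prebleach + 1L):length(t$times)
  if (length(post) < 5)
    stop("need at least 5 post-bleach points", call. = FALSE)
  tp <- t$times[post] - t$times[post[1]]
  y <- t$intensities[post]
  B0 <- y[1]
  P0 <- mean(y[tp >= stats::quantile(tp, 0.9)])
  if (P0 <= B0) P0 <- B0 + max(1e-3, diff(range(y)))
  # initial tau: time to reach half of the estimated recovery amplitude
  half <- B0 + (P0 - B0) / 2
  above <- which(y >= half)
  tau0 <- if (length(above)) max(tp[above[1]], tp[2]) else max(tp) / 3
  dat <- data.frame(tp = tp, y = y)
  fit <- tryCatch({
    if (model == "fixedB")
      minpack.lm::nlsLM(y ~ P - (P - B0) * exp(-tp / tau), data = dat,
                        start = list(P = P0, tau = tau0),
                        control = minpack.lm::nls.lm.control(maxiter = 500))
    else
      minpack.lm::nlsLM(y ~ P - (P - B) * exp(-tp / tau), data = dat,
                        start = list(P = P0, B = B0, tau = tau0),
                        control = minpack.lm::nls.lm.control(maxiter = 500))
  }, error = function(e)
    stop("recovery fit failed: ", conditionMessage(e), call. = FALSE))
  cf <- stats::coef(fit)
  tau <- unname(cf["tau"])
  if (tau <= 0) stop("rejected fit: non-positive tau", call. = FALSE)
  B <- if (model == "fixedB") B0 else unname(cf["B"])
  P <- unname(cf["P"])
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  mobile <- if (B < 1) (P - B) / (1 - B) else NA_real_
  structure(list(tau = tau, bleach_depth = B, plateau = P,
                 mobile_fraction = mobile,
                 r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else 1,
                 model = model, times = tp, intensities = y, nls = fit),
            class = "frap_fit")
}

#' @export
print.frap_fit <- function(x, ...) {
  cat("FRAP exponential recovery fit\n")
  cat(sprintf("  tau = %.3g s, plateau = %.3f, bleach depth = %.3f (%s)\n",
              x$tau, x$plateau, x$bleach_depth, x$model))
  cat(sprintf("  mobile fraction = %.3f%s, R2 = %.4f\n",
              x$mobile_fraction,
              if (is.finite(x$mobile_fraction) && x$mobile_fraction > 1)
                " (>1, flagged)" else "",
              x$r_squared))
  invisible(x)
}

#' @export
coef.frap_fit <- function(object, ...) {
  c(tau = object$tau, plateau = object$plateau,
    bleach_depth = object$bleach_depth,
    mobile_fraction = object$mobile_fraction)
}

#' @export
predict.frap_fit <- function(object, times = object$times, ...) {
  object$plateau - (object$plateau - object$bleach_depth) *
    exp(-times / object$tau)
}

#' @export
plot.frap_fit <- function(x, ...) {
  plot(x$times, x$intensities, xlab = "time post-bleach (s)",
       ylab = "normalised intensity", ...)
  graphics::lines(x$times, predict(x), col = "red")
  invisible(x)
}

#' Average several droplets' recovery curves and fit the mean
#'
#' Normalises each trace, resamples all traces onto the time grid of the
#' first by linear interpolation (post-bleach times measured from the first
#' post-bleach frame), averages pointwise, and fits the mean curve. This is
#' the standard protocol of bleaching several droplets in different fields
#' of view and fitting their averaged recovery.
#'
#' @param traces list of [frap_trace()] objects (a single trace passes
#'   through with a warning); all must share the same number of pre-bleach
#'   frames and have overlapping post-bleach time ranges.
#' @param model passed to [fit_recovery()].
#' @return list: \code{trace} (the averaged \code{frap_trace}) and
#'   \code{fit} (its \code{frap_fit}).
#' @export
average_recovery <- function(traces, model = "freeB") {
  stopifnot(length(traces) >= 1,
            all(vapply(traces, inherits, logical(1), "frap_trace")))
  traces <- lapply(traces, normalize_trace)
  if (length(traces) == 1) {
    warning("single trace: averaging is a passthrough", call. = FALSE)
    return(list(trace = traces[[1]], fit = fit_recovery(traces[[1]], model)))
  }
  npre <- traces[[1]]$n_prebleach
  ref <- traces[[1]]
  # common post-bleach grid relative to each trace's first post-bleach frame
  rel <- lapply(traces, function(t) {
    post <- (t$n_prebleach + 1L):length(t$times)
    list(tp = t$times[post] - t$times[post[1]], y = t$intensities[post])
  })
  tmax <- min(vapply(rel, function(r) max(r$tp), numeric(1)))
  if (tmax <= 0) stop("non-overlapping post-bleach time ranges", call. = FALSE)
  grid <- rel[[1]]$tp[rel[[1]]$tp <= tmax + 1e-9]
  ymat <- vapply(rel, function(r)
    stats::approx(r$tp, r$y, xout = grid, rule = 2)$y,
    numeric(length(grid)))
  ymean <- rowMeans(ymat)
  pre_t <- ref$times[seq_len(npre)]
  pre_y <- rowMeans(vapply(traces, function(t)
    t$intensities[seq_len(t$n_prebleach)][seq_len(npre)], numeric(npre)))
  post_t0 <- ref$times[npre + 1L]
  avg <- frap_trace(c(pre_t, post_t0 + grid), c(pre_y, ymean),
                    n_prebleach = npre, droplet_id = "average",
                    normalized = TRUE)
  list(trace = avg, fit = fit_recovery(avg, model))
}
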