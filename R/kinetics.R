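#' Per-frame beat-pattern series
#'
#' Scalar time series derived from flow fields: either the mean speed
#' magnitude V(t) of consecutive-pair flows, or the mean displacement
#' magnitude U(t) relative to a reference frame.
#'
#' @param values Nonnegative numeric vector, one value per analyzed frame.
#' @param fps Frames per second.
#' @param kind \code{"velocity"} or \code{"displacement"}.
#' @return Object of class \code{beat_pattern}.
#' @export
beat_pattern <- function(values, fps = 10, kind = c("velocity", "displacement")) {
  kind <- match.arg(kind)
  if (any(values < 0, na.rm = TRUE)) stop("beat_pattern: values must be >= 0")
  structure(list(values = values, fps = fps, kind = kind), class = "beat_pattern")
}

#' @export
print.beat_pattern <- function(x, ...) {
  cat(sprintf("Beat pattern (%s): %d frames @ %g fps, range [%g, %g]\n",
              x$kind, length(x$values), x$fps,
              min(x$values, na.rm = TRUE), max(x$values, na.rm = TRUE)))
  invisible(x)
}

# last index of the run of values equal to signal[i] starting at i; used to
# push rest references to the deepest point of a quantized relaxation plateau
.plateau_end <- function(signal, i) {
  while (i < length(signal) && signal[i + 1] == signal[i]) i <- i + 1L
  as.integer(i)
}

# mean magnitude over valid nodes of one flow grid; NA when none valid
.mean_speed <- function(flow) {
  m <- sqrt(flow$ux^2 + flow$uy^2)
  if (!any(flow$valid)) return(NA_real_)
  mean(m[flow$valid])
}

# linearly interpolate missing entries of a scalar trace
.fill_na <- function(v) {
  if (!anyNA(v)) return(v)
  if (all(is.na(v))) stop("trace is entirely missing (no valid flow nodes)")
  stats::approx(seq_along(v)[!is.na(v)], v[!is.na(v)], xout = seq_along(v),
                rule = 2)$y
}

#' Average motility trace V(t)
#'
#' Spatial average of the speed magnitudes of consecutive-pair flow fields,
#' \eqn{V(t) = \langle |v(t,x)| \rangle_x}. Frames with no valid node are
#' flagged missing and linearly interpolated.
#'
#' @param flows List of [flow_grid()]s from consecutive frame pairs.
#' @param fps Frames per second.
#' @return A \code{"velocity"} [beat_pattern()].
#' @export
velocity_trace <- function(flows, fps = 10) {
  v <- vapply(flows, .mean_speed, numeric(1))
  beat_pattern(.fill_na(v), fps = fps, kind = "velocity")
}

#' Alternating prominent extrema of a noisy signal
#'
#' Assigns an alternating sequence of minima and maxima
#' (\eqn{t_k^{min} < t_k^{max} < t_{k+1}^{min}}) such that every retained
#' maximum is the absolute maximum between its flanking minima (and vice
#' versa), each maximum exceeds the preceding retained minimum by at least
#' \code{delta}, and each minimum lies at least \code{delta} below the
#' preceding maximum. Plateaus report their earliest frame. A signal with no
#' delta-prominent excursion yields an empty sequence.
#'
#' @param signal Numeric vector, length >= 3.
#' @param delta Positive prominence threshold (signal units).
#' @return Object of class \code{extrema_sequence}: list with integer frame
#'   vectors \code{minima}, \code{maxima} (1-based) and \code{delta}.
#' @export
find_extrema <- function(signal, delta) {
  stopifnot(is.numeric(signal), length(signal) >= 3, delta > 0)
  minima <- integer(0); maxima <- integer(0)
  run_min_v <- signal[1]; run_min_i <- 1L
  run_max_v <- signal[1]; run_max_i <- 1L
  mode <- "none"
  for (t in 2:length(signal)) {
    v <- signal[t]
    if (mode == "none") {
      if (v < run_min_v) { run_min_v <- v; run_min_i <- t }
      if (v > run_max_v) { run_max_v <- v; run_max_i <- t }
      if (v >= run_min_v + delta) {
        minima <- c(minima, run_min_i); mode <- "max"
        run_max_v <- v; run_max_i <- t
      } else if (v <= run_max_v - delta) {
        # dropped first: the sequence must start with a minimum, so discard
        # the leading maximum and seek the first minimum
        mode <- "min"; run_min_v <- v; run_min_i <- t
      }
    } else if (mode == "max") {
      if (v > run_max_v) { run_max_v <- v; run_max_i <- t }
      if (v <= run_max_v - delta) {
        maxima <- c(maxima, run_max_i); mode <- "min"
        run_min_v <- v; run_min_i <- t
      }
    } else {
      if (v < run_min_v) { run_min_v <- v; run_min_i <- t }
      if (v >= run_min_v + delta) {
        minima <- c(minima, run_min_i); mode <- "max"
        run_max_v <- v; run_max_i <- t
      }
    }
  }
  # a maximum still rising at the end of the recording is unconfirmed (it
  # never dropped by delta) and is not reported; a trailing minimum is kept
  # when it satisfies the drop condition
  if (mode == "min" && length(maxima) > 0 &&
      run_min_v <= signal[maxima[length(maxima)]] - delta) {
    minima <- c(minima, run_min_i)
  }
  if (length(maxima) == 0) minima <- integer(0)  # no oscillation: empty sequence
  structure(list(minima = minima, maxima = maxima, delta = delta),
            class = "extrema_sequence")
}

#' @export
print.extrema_sequence <- function(x, ...) {
  cat(sprintf("Extrema: %d minima, %d maxima (delta = %g)\n",
              length(x$minima), length(x$maxima), x$delta))
  invisible(x)
}

#' Displacement flows and trace relative to a reference frame
#'
#' Optical flow of every frame against the reference frame \code{t*}:
#' \eqn{u_{t*}(t,x)}, and the average displacement trace
#' \eqn{U_{t*}(t) = \langle |u_{t*}(t,x)| \rangle_x}. By construction
#' \eqn{U_{t*}(t^*) = 0}.
#'
#' @param stack An [image_stack()].
#' @param reference_index Reference frame (1-based), typically a minimum of
#'   V(t).
#' @param config A [piv_config()].
#' @return List with \code{flows} (per-frame [flow_grid()]) and
#'   \code{pattern} (a \code{"displacement"} [beat_pattern()]).
#' @export
reference_displacement <- function(stack, reference_index, config = piv_config()) {
  stopifnot(inherits(stack, "image_stack"))
  nf <- n_frames(stack)
  if (reference_index < 1 || reference_index > nf)
    stop("reference_displacement: reference_index outside the stack")
  ref <- get_frame(stack, reference_index)
  flows <- lapply(seq_len(nf), function(t)
    two_pass_flow(ref, get_frame(stack, t), config))
  u <- vapply(flows, .mean_speed, numeric(1))
  list(flows = flows,
       pattern = beat_pattern(.fill_na(u), fps = stack$fps, kind = "displacement"))
}

#' Re-reference a displacement field without re-running PIV
#'
#' Computational shortcut
#' \eqn{u_T(t,x) \approx u_{t*}(t,x) - u_{t*}(T,x)}: the displacement of
#' frame \code{t} relative to frame \code{T}, from the flows of both against
#' the common reference \code{t*}. Exact for rigid motion. Nodes invalid in
#' either operand are invalid in the result.
#'
#' @param flow_t,flow_T [flow_grid()]s of frames t and T against the same
#'   reference.
#' @return A [flow_grid()].
#' @export
approximate_reference_switch <- function(flow_t, flow_T) {
  stopifnot(inherits(flow_t, "flow_grid"), inherits(flow_T, "flow_grid"),
            identical(flow_t$x, flow_T$x), identical(flow_t$y, flow_T$y))
  valid <- flow_t$valid & flow_T$valid
  flow_grid(flow_t$ux - flow_T$ux, flow_t$uy - flow_T$uy,
            flow_t$x, flow_t$y, flow_t$spacing, valid = valid)
}

#' Synthesize the beat pattern U(t) from a stack
#'
#' Bootstrap: compute V(t) from consecutive flows; take its global minimum
#' as the working reference \code{t*}; compute \eqn{U_{t*}(t)}; take the
#' delta-prominent minima of \eqn{U_{t*}} as the reference set
#' \eqn{t_k^{min}}; return the pointwise minimum
#' \eqn{U(t) = \min_k U_{t_k^{min}}(t)}, whose inter-beat baseline is ~0.
#'
#' When \code{length(references) * n_frames} exceeds \code{budget}, the
#' re-referenced series are formed by [approximate_reference_switch()]
#' instead of fresh PIV per reference (exact for rigid motion, and accurate
#' while displacements stay within the fine search range).
#'
#' If no delta-prominent minimum exists (e.g. a static recording) the working
#' reference alone is used, with a warning advising a longer recording or a
#' smaller delta.
#'
#' @param stack An [image_stack()].
#' @param config A [piv_config()].
#' @param delta Prominence threshold; default 20% of the interdecile range of
#'   \eqn{U_{t*}}.
#' @param budget Maximum number of (reference x frame) PIV evaluations before
#'   switching to the approximation. Default \code{Inf} (always exact).
#' @return List of class \code{beat_analysis}: \code{U} (the synthesized
#'   [beat_pattern()]), \code{V}, \code{U_ref} (the working-reference trace),
#'   \code{references} (frame indices), \code{t_star}, \code{flows}
#'   (per-frame flows against \code{t*}) and \code{delta}.
#' @export
synthesize_beat_pattern <- function(stack, config = piv_config(), delta = NULL,
                                    budget = Inf) {
  stopifnot(inherits(stack, "image_stack"))
  nf <- n_frames(stack)
  if (nf < 3) stop("synthesize_beat_pattern: need at least 3 frames")
  cons <- lapply(seq_len(nf - 1), function(t)
    two_pass_flow(get_frame(stack, t), get_frame(stack, t + 1), config))
  V <- velocity_trace(cons, fps = stack$fps)
  # among equally minimal frames, the latest of the plateau is the deepest
  # point of the (exponential) relaxation and hence the best rest reference
  t_star <- .plateau_end(V$values, which.min(V$values))
  refd <- reference_displacement(stack, t_star, config)
  Ur <- refd$pattern
  if (is.null(delta)) {
    idr <- diff(quantile(Ur$values, c(0.1, 0.9), names = FALSE))
    delta <- if (idr > 0) 0.2 * idr else .Machine$double.eps
  }
  ex <- find_extrema(Ur$values, delta)
  refs <- unique(vapply(ex$minima, function(m) .plateau_end(Ur$values, m), integer(1)))
  if (length(refs) == 0) {
    warning("synthesize_beat_pattern: no delta-prominent minima; using the V(t) ",
            "reference only. Consider a longer recording or a smaller delta.")
    refs <- t_star
  }
  exact <- length(refs) * nf <= budget
  Umat <- vapply(refs, function(Tref) {
    if (Tref == t_star) return(Ur$values)
    if (exact) {
      reference_displacement(stack, Tref, config)$pattern$values
    } else {
      vapply(seq_len(nf), function(t) .mean_speed(
        approximate_reference_switch(refd$flows[[t]], refd$flows[[Tref]])),
        numeric(1))
    }
  }, numeric(nf))
  Umat <- matrix(Umat, nrow = nf)
  U <- apply(Umat, 1, min, na.rm = TRUE)
  structure(list(U = beat_pattern(.fill_na(U), fps = stack$fps, kind = "displacement"),
                 V = V, U_ref = Ur, references = refs, t_star = t_star,
                 flows = refd$flows, delta = delta, exact = exact),
            class = "beat_analysis")
}

#' Beat frequency from a beat pattern
#'
#' Mean period between consecutive delta-prominent maxima, reported in beats
#' per minute. At a 10 frames/s capture rate frequencies above 120 bpm
#' (fewer than 5 frames per beat) are under-resolved and flagged unreliable;
#' the same frames-per-beat limit is applied at other frame rates.
#'
#' @param pattern A [beat_pattern()].
#' @param delta Prominence threshold; default 20% of the interdecile range.
#' @return List with \code{bpm}, \code{period_s}, \code{maxima} (frame
#'   indices) and logical \code{unreliable}.
#' @export
beat_frequency <- function(pattern, delta = NULL) {
  stopifnot(inherits(pattern, "beat_pattern"))
  if (is.null(delta)) {
    idr <- diff(quantile(pattern$values, c(0.1, 0.9), names = FALSE))
    delta <- if (idr > 0) 0.2 * idr else .Machine$double.eps
  }
  ex <- find_extrema(pattern$values, delta)
  if (length(ex$maxima) < 2)
    stop("beat_frequency: fewer than 2 maxima; cannot estimate a period")
  period_frames <- mean(diff(ex$maxima))
  period_s <- period_frames / pattern$fps
  bpm <- 60 / period_s
  list(bpm = bpm, period_s = period_s, maxima = ex$maxima,
       unreliable = period_frames <= 5)
}
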