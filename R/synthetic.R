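#' Beat waveform: swift contraction, exponential relaxation
#'
#' Periodic activation in \[0, 1\]: a linear rise over
#' \code{contraction_rise} seconds to full activation, followed by
#' exponential relaxation with time constant \code{relaxation_tau} — the
#' asymmetry characteristic of myocardial contraction cycles.
#'
#' @param period Beat period (seconds).
#' @param contraction_rise Rise time (seconds, short).
#' @param relaxation_tau Relaxation decay constant (seconds);
#'   \code{contraction_rise < relaxation_tau < period}.
#' @param amplitude Dimensionless scale applied to the active stress.
#' @return Object of class \code{beat_waveform}.
#' @export
beat_waveform <- function(period = 1, contraction_rise = 0.1,
                          relaxation_tau = 0.25, amplitude = 1) {
  if (!(contraction_rise < relaxation_tau && relaxation_tau < period))
    stop("beat_waveform: need contraction_rise < relaxation_tau < period")
  if (amplitude <= 0) stop("beat_waveform: amplitude must be > 0")
  structure(list(period = period, contraction_rise = contraction_rise,
                 relaxation_tau = relaxation_tau, amplitude = amplitude),
            class = "beat_waveform")
}

#' Waveform activation at time t
#'
#' @param w A [beat_waveform()].
#' @param t Time(s) in seconds, \code{>= 0}.
#' @return Activation value(s) in \[0, 1\] (amplitude is applied by the
#'   movie generator, not here).
#' @export
waveform_value <- function(w, t) {
  stopifnot(inherits(w, "beat_waveform"), all(t >= -1e-12))
  phase <- t %% w$period
  ifelse(phase < w$contraction_rise,
         phase / w$contraction_rise,
         exp(-(phase - w$contraction_rise) / w$relaxation_tau))
}

#' Band-limited random texture
#'
#' Reproducible pseudo-random texture with a tunable correlation length:
#' white noise smoothed by a separable Gaussian kernel and rescaled to an
#' 8-bit-like intensity range, providing local contrast for PIV everywhere
#' except designated blank (cell-free) regions, which are set flat.
#'
#' @param seed Integer RNG seed.
#' @param size Image side in pixels (>= 64) or length-2 \code{c(H, W)}.
#' @param correlation_length Gaussian sigma of the smoothing kernel (px).
#' @param blank Optional list of blank rectangles, each
#'   \code{c(x0, x1, y0, y1)} in pixel coordinates.
#' @return Numeric image matrix in \[0, 255\].
#' @export
generate_texture <- function(seed, size, correlation_length = 1.2, blank = NULL) {
  if (length(size) == 1) size <- c(size, size)
  if (any(size < 64)) stop("generate_texture: size must be >= 64")
  set.seed(as.integer(seed))
  m <- matrix(rnorm(prod(size)), size[1], size[2])
  ksz <- max(3L, as.integer(ceiling(3 * correlation_length)))
  k <- stats::dnorm(seq(-ksz, ksz), sd = correlation_length)
  k <- k / sum(k)
  m <- apply(m, 2, function(col) stats::filter(col, k, circular = TRUE))
  m <- t(apply(m, 1, function(row) stats::filter(row, k, circular = TRUE)))
  m <- (m - min(m)) / (max(m) - min(m)) * 215 + 20
  for (b in blank) m[b[3]:b[4], b[1]:b[2]] <- 128
  m
}

#' Warp an image by a displacement field (inverse mapping)
#'
#' Output pixel at \code{x} samples the texture at \code{x - u(x)} with
#' bilinear interpolation (pull-back; forward splatting would leave holes).
#' A zero field returns the input unchanged; integer uniform fields are
#' exact pixel shifts.
#'
#' @param texture Numeric image matrix.
#' @param ux,uy Per-pixel displacement matrices (same shape as
#'   \code{texture}), in pixels.
#' @return Warped image matrix.
#' @export
warp_frame <- function(texture, ux, uy) {
  stopifnot(is.matrix(texture), identical(dim(texture), dim(ux)),
            identical(dim(texture), dim(uy)))
  H <- nrow(texture); W <- ncol(texture)
  px <- rep(seq_len(W), each = H)
  py <- rep(seq_len(H), times = W)
  sx <- pmin(pmax(px - as.vector(ux), 1), W)
  sy <- pmin(pmax(py - as.vector(uy), 1), H)
  x0 <- pmin(floor(sx), W - 1L); y0 <- pmin(floor(sy), H - 1L)
  wx <- sx - x0; wy <- sy - y0
  v <- texture[cbind(y0, x0)] * (1 - wx) * (1 - wy) +
       texture[cbind(y0, x0 + 1)] * wx * (1 - wy) +
       texture[cbind(y0 + 1, x0)] * (1 - wx) * wy +
       texture[cbind(y0 + 1, x0 + 1)] * wx * wy
  matrix(v, H, W)
}

#' Specification of a synthetic beating-monolayer scene
#'
#' @param size Image side in pixels (or \code{c(H, W)}).
#' @param centers List of contractile centers; each a list with
#'   \code{position} (pixel \code{c(x, y)}), \code{params} (a
#'   [sheet_params()] in pixel units, \code{k > 0}), \code{waveform} (a
#'   [beat_waveform()]), \code{phase} (seconds) and
#'   \code{peak_displacement} (px, maximum |u| at full activation; kept
#'   small so superposition of centers stays in the linear regime).
#' @param texture_seed RNG seed for the background texture.
#' @param noise_sd Additive Gaussian read-noise SD (intensity units).
#' @param blank Optional blank (cell-free) rectangles, see
#'   [generate_texture()].
#' @param debris Logical: animate drifting bright blobs inside blank
#'   regions (convective debris artifact).
#' @param fps Frames per second.
#' @param correlation_length Texture correlation length (px).
#' @return Object of class \code{scene_spec}.
#' @export
scene_spec <- function(size = 256, centers, texture_seed = 1L, noise_sd = 1,
                       blank = NULL, debris = FALSE, fps = 10,
                       correlation_length = 1.2) {
  if (length(size) == 1) size <- c(size, size)
  stopifnot(fps > 0, length(centers) >= 1)
  for (ctr in centers) {
    stopifnot(inherits(ctr$params, "sheet_params"), inherits(ctr$waveform, "beat_waveform"))
    if (ctr$position[1] < 1 || ctr$position[1] > size[2] ||
        ctr$position[2] < 1 || ctr$position[2] > size[1])
      stop("scene_spec: center outside the frame")
    pk <- if (is.null(ctr$peak_displacement)) 6 else ctr$peak_displacement
    if (pk > 8) stop("scene_spec: peak_displacement must be <= 8 px (linear regime)")
  }
  structure(list(size = size, centers = centers, texture_seed = texture_seed,
                 noise_sd = noise_sd, blank = blank, debris = isTRUE(debris),
                 fps = fps, correlation_length = correlation_length),
            class = "scene_spec")
}

# static unit displacement field (max |u| = 1) and matching convergence map
# of one center, evaluated on the full pixel lattice
.center_unit_field <- function(ctr, size) {
  sol <- solve_uniform_core(ctr$params)
  H <- size[1]; W <- size[2]
  dx <- outer(rep(1, H), seq_len(W) - ctr$position[1])
  dy <- outer(seq_len(H) - ctr$position[2], rep(1, W))
  r <- sqrt(dx^2 + dy^2)
  r[r < 1e-9] <- 1e-9
  ur <- sol$u(r)
  sc <- max(abs(ur))
  pk <- if (is.null(ctr$peak_displacement)) 6 else ctr$peak_displacement
  f <- pk / sc
  list(ux = f * ur * dx / r, uy = f * ur * dy / r,
       C = f * sol$C(r), scale = f, sol = sol)
}

#' Generate a ground-truth-annotated beating-monolayer movie
#'
#' Per frame, each center's equilibrium displacement field (from the elastic
#' sheet model) is scaled by its waveform activation and amplitude, the
#' fields are superposed, and the seeded background texture is warped by the
#' resulting field; Gaussian read noise (and optional drifting debris in
#' blank regions) is added. Fully deterministic given (spec, seed).
#'
#' @param spec A [scene_spec()].
#' @param n_frames Number of frames.
#' @param seed RNG seed for noise and debris (texture has its own seed).
#' @return List of class \code{synthetic_movie}: \code{stack}
#'   ([image_stack()]), and \code{truth} with per-center unit fields
#'   (\code{ux}, \code{uy}, \code{C} at full activation), per-frame
#'   activation matrix \code{activation} (frames x centers), per-frame
#'   ground-truth accessors [truth_displacement()] / [truth_convergence()],
#'   center positions and beat (activation peak) times.
#' @export
generate_movie <- function(spec, n_frames, seed = 1L) {
  stopifnot(inherits(spec, "scene_spec"), n_frames >= 1)
  H <- spec$size[1]; W <- spec$size[2]
  tex <- generate_texture(spec$texture_seed, spec$size,
                          correlation_length = spec$correlation_length,
                          blank = spec$blank)
  units <- lapply(spec$centers, .center_unit_field, size = spec$size)
  tvec <- (seq_len(n_frames) - 1) / spec$fps
  act <- vapply(seq_along(spec$centers), function(i) {
    ctr <- spec$centers[[i]]
    ph <- if (is.null(ctr$phase)) 0 else ctr$phase
    ctr$waveform$amplitude *
      waveform_value(ctr$waveform, (tvec - ph) %% ctr$waveform$period)
  }, numeric(n_frames))
  act <- matrix(act, nrow = n_frames)
  set.seed(as.integer(seed))
  frames <- array(0, dim = c(H, W, n_frames))
  ndeb <- 0L
  deb <- NULL
  if (spec$debris && length(spec$blank)) {
    ndeb <- 2L * length(spec$blank)
    deb <- lapply(seq_len(ndeb), function(i) {
      b <- spec$blank[[((i - 1L) %% length(spec$blank)) + 1L]]
      list(box = b,
           x = runif(1, b[1], b[2]), y = runif(1, b[3], b[4]),
           vx = runif(1, -1.5, 1.5), vy = runif(1, -1.5, 1.5),
           sigma = runif(1, 2, 4), amp = runif(1, 30, 60))
    })
  }
  for (t in seq_len(n_frames)) {
    ux <- matrix(0, H, W); uy <- matrix(0, H, W)
    for (i in seq_along(units)) {
      ux <- ux + act[t, i] * units[[i]]$ux
      uy <- uy + act[t, i] * units[[i]]$uy
    }
    fr <- warp_frame(tex, ux, uy)
    if (ndeb > 0L) {
      for (d in deb) {
        cx <- d$box[1] + (d$x - d$box[1] + d$vx * (t - 1)) %% (d$box[2] - d$box[1])
        cy <- d$box[3] + (d$y - d$box[3] + d$vy * (t - 1)) %% (d$box[4] - d$box[3])
        xs <- max(1, floor(cx - 3 * d$sigma)):min(W, ceiling(cx + 3 * d$sigma))
        ys <- max(1, floor(cy - 3 * d$sigma)):min(H, ceiling(cy + 3 * d$sigma))
        blob <- d$amp * outer(exp(-(ys - cy)^2 / (2 * d$sigma^2)),
                              exp(-(xs - cx)^2 / (2 * d$sigma^2)))
        fr[ys, xs] <- fr[ys, xs] + blob
      }
    }
    if (spec$noise_sd > 0) fr <- fr + rnorm(H * W, sd = spec$noise_sd)
    frames[, , t] <- fr
  }
  truth <- list(units = units, activation = act,
                centers = lapply(spec$centers, `[[`, "position"),
                beat_times = lapply(spec$centers, function(ctr) {
                  ph <- if (is.null(ctr$phase)) 0 else ctr$phase
                  pk <- ph + ctr$waveform$contraction_rise
                  pk + ctr$waveform$period *
                    (0:ceiling(max(tvec) / ctr$waveform$period))
                }),
                fps = spec$fps, seed = seed)
  structure(list(stack = image_stack(frames, fps = spec$fps), truth = truth,
                 spec = spec),
            class = "synthetic_movie")
}

#' Ground-truth displacement field of a synthetic movie at one frame
#' @param movie A \code{synthetic_movie} from [generate_movie()].
#' @param t Frame index (1-based).
#' @return List with per-pixel matrices \code{ux}, \code{uy}.
#' @export
truth_displacement <- function(movie, t) {
  u <- movie$truth$units
  act <- movie$truth$activation
  ux <- Reduce(`+`, lapply(seq_along(u), function(i) act[t, i] * u[[i]]$ux))
  uy <- Reduce(`+`, lapply(seq_along(u), function(i) act[t, i] * u[[i]]$uy))
  list(ux = ux, uy = uy)
}

#' Ground-truth convergence map of a synthetic movie at one frame
#' @inheritParams truth_displacement
#' @return Per-pixel convergence matrix (model C scaled by the activation).
#' @export
truth_convergence <- function(movie, t) {
  u <- movie$truth$units
  act <- movie$truth$activation
  Reduce(`+`, lapply(seq_along(u), function(i) act[t, i] * u[[i]]$C))
}
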