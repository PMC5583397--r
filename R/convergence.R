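#' Scalar field on a flow-grid lattice
#'
#' @param values Numeric matrix (rows = y nodes, cols = x nodes).
#' @param x,y Node pixel coordinates.
#' @param spacing Grid spacing d (pixels).
#' @param kind One of \code{"convergence"}, \code{"contractility"},
#'   \code{"weight"}, \code{"generic"}.
#' @param border Optional logical matrix flagging nodes computed with
#'   one-sided differences (or otherwise less trustworthy).
#' @return Object of class \code{scalar_map}.
#' @export
scalar_map <- function(values, x, y, spacing,
                       kind = c("generic", "convergence", "contractility", "weight"),
                       border = NULL) {
  kind <- match.arg(kind)
  stopifnot(is.matrix(values), nrow(values) == length(y), ncol(values) == length(x),
            spacing > 0)
  if (kind == "contractility" && any(values < 0, na.rm = TRUE))
    stop("scalar_map: contractility must be >= 0")
  if (kind == "weight" && (any(values < 0, na.rm = TRUE) || any(values > 1, na.rm = TRUE)))
    stop("scalar_map: weights must lie in [0, 1]")
  structure(list(values = values, x = x, y = y, spacing = spacing,
                 kind = kind, border = border),
            class = "scalar_map")
}

#' @export
print.scalar_map <- function(x, ...) {
  cat(sprintf("Scalar map (%s): %d x %d nodes, spacing %g px, range [%g, %g]\n",
              x$kind, length(x$y), length(x$x), x$spacing,
              min(x$values, na.rm = TRUE), max(x$values, na.rm = TRUE)))
  invisible(x)
}

.same_lattice <- function(a, b)
  identical(a$x, b$x) && identical(a$y, b$y)

#' Convergence of a displacement field by finite differences
#'
#' \eqn{C = -\nabla\cdot u}, estimated by central differences with the grid
#' spacing d at interior nodes,
#' \eqn{C \approx [u_x(x-d,y) - u_x(x+d,y)]/2d + [u_y(x,y-d) - u_y(x,y+d)]/2d};
#' border nodes use one-sided differences and are flagged in \code{border}.
#'
#' @param flow A [flow_grid()] with at least 3 nodes per axis.
#' @return A \code{"convergence"} [scalar_map()]. Nodes with missing
#'   neighbors are NA.
#' @export
finite_difference_convergence <- function(flow) {
  stopifnot(inherits(flow, "flow_grid"))
  ny <- length(flow$y); nx <- length(flow$x)
  if (ny < 3 || nx < 3)
    stop("finite_difference_convergence: need >= 3 nodes along each axis")
  d <- flow$spacing
  ux <- flow$ux; uy <- flow$uy
  dux <- matrix(NA_real_, ny, nx)   # d(ux)/dx
  duy <- matrix(NA_real_, ny, nx)   # d(uy)/dy
  dux[, 2:(nx - 1)] <- (ux[, 3:nx] - ux[, 1:(nx - 2)]) / (2 * d)
  dux[, 1] <- (ux[, 2] - ux[, 1]) / d
  dux[, nx] <- (ux[, nx] - ux[, nx - 1]) / d
  duy[2:(ny - 1), ] <- (uy[3:ny, ] - uy[1:(ny - 2), ]) / (2 * d)
  duy[1, ] <- (uy[2, ] - uy[1, ]) / d
  duy[ny, ] <- (uy[ny, ] - uy[ny - 1, ]) / d
  border <- matrix(FALSE, ny, nx)
  border[c(1, ny), ] <- TRUE
  border[, c(1, nx)] <- TRUE
  scalar_map(-(dux + duy), flow$x, flow$y, d, kind = "convergence", border = border)
}

#' Spatial median filter on a scalar map
#'
#' Replaces each node by the median over its \eqn{(2 radius + 1)^2}
#' neighborhood (truncated at the borders, missing values ignored). Reduces
#' impulsive noise while preserving spatial gradients; idempotent on
#' piecewise-constant maps and leaves step edges in place.
#'
#' @param map A [scalar_map()].
#' @param radius Neighborhood radius in nodes (default 1: adjacent grid
#'   points, a 3 x 3 window).
#' @return A filtered [scalar_map()].
#' @export
median_filter_map <- function(map, radius = 1L) {
  stopifnot(inherits(map, "scalar_map"), radius >= 1L)
  v <- map$values
  ny <- nrow(v); nx <- ncol(v)
  out <- v
  for (i in seq_len(ny)) {
    ri <- max(1, i - radius):min(ny, i + radius)
    for (j in seq_len(nx)) {
      rj <- max(1, j - radius):min(nx, j + radius)
      w <- v[ri, rj]
      out[i, j] <- if (all(is.na(w))) NA_real_ else median(w, na.rm = TRUE)
    }
  }
  scalar_map(out, map$x, map$y, map$spacing, kind = map$kind, border = map$border)
}

#' Temporal high-pass filter (leaky differentiator with mean restoration)
#'
#' Per-node recursion
#' \deqn{C'(r,t) = q\,[C'(r,t-1) + C(r,t) - C(r,t-1)] + (1-q)\,M(r)}
#' with \eqn{M(r)} the temporal mean of the unfiltered sequence and
#' initialization \eqn{C'(r,0) = M(r)}, \eqn{C(r,0) := M(r)} (so a constant
#' series is a fixed point from the first step). The filter passes
#' fast beats, removes slow drift (a linear ramp converges to
#' \eqn{M + \beta q/(1-q)}), and maintains the average of a stationary
#' sequence.
#'
#' @param series Numeric vector (one node), matrix (\code{nodes x time}) or
#'   3-D array (\code{ny x nx x time}).
#' @param q Forgetting factor in (0, 1); default 0.9 (cut-off ~0.17 Hz at
#'   10 fps, well below beat frequencies).
#' @return Filtered object of the same shape.
#' @export
high_pass_filter <- function(series, q = 0.9) {
  if (q <= 0 || q >= 1) stop("high_pass_filter: q must be inside (0, 1)")
  dims <- dim(series)
  x <- if (is.null(dims)) matrix(series, nrow = 1)
       else if (length(dims) == 2) series
       else matrix(series, nrow = dims[1] * dims[2])
  if (ncol(x) < 2) stop("high_pass_filter: series length must be >= 2")
  M <- rowMeans(x, na.rm = TRUE)
  out <- x
  prev_f <- M   # C'(t = 0)
  prev_c <- M   # C (t = 0), defined as M
  for (t in seq_len(ncol(x))) {
    ct <- x[, t]
    ct[is.na(ct)] <- prev_c[is.na(ct)]
    f <- q * (prev_f + ct - prev_c) + (1 - q) * M
    out[, t] <- f
    prev_f <- f
    prev_c <- ct
  }
  if (is.null(dims)) as.vector(out)
  else if (length(dims) == 2) out
  else array(out, dim = dims)
}

#' Local image contrast on the flow lattice
#'
#' Standard deviation of image brightness within a square window (default
#' 16 x 16 px) centered on each node's pixel position, optionally rescaled
#' to \[0, 1\] by a normalization constant (by default the maximum windowed
#' SD of the frame; for a movie pass the stack-wide maximum via
#' \code{norm}). Cell-free areas have low contrast and get weights near 0.
#'
#' @param frame Numeric image matrix.
#' @param x,y Node pixel coordinates (1-based).
#' @param window Window width in pixels (>= 2), default 16.
#' @param spacing Lattice spacing of the node grid (pixels).
#' @param norm Normalization constant; \code{NULL} uses the frame maximum;
#'   \code{NA} returns the raw windowed SD (kind \code{"generic"}).
#' @return A [scalar_map()] of kind \code{"weight"} (or \code{"generic"}
#'   when \code{norm = NA}).
#' @export
local_contrast <- function(frame, x, y, window = 16L, spacing = NULL, norm = NULL) {
  stopifnot(is.matrix(frame), window >= 2)
  half <- as.integer(window) %/% 2L
  H <- nrow(frame); W <- ncol(frame)
  v <- matrix(NA_real_, length(y), length(x))
  for (i in seq_along(y)) {
    ri <- max(1, y[i] - half):min(H, y[i] + half - 1L)
    for (j in seq_along(x)) {
      rj <- max(1, x[j] - half):min(W, x[j] + half - 1L)
      v[i, j] <- stats::sd(frame[ri, rj])
    }
  }
  if (is.null(spacing)) spacing <- if (length(x) > 1) diff(x[1:2]) else 1
  if (length(norm) == 1 && is.na(norm))
    return(scalar_map(v, x, y, spacing, kind = "generic"))
  if (is.null(norm)) norm <- max(v, na.rm = TRUE)
  w <- if (norm > 0) pmin(v / norm, 1) else v * 0
  scalar_map(w, x, y, spacing, kind = "weight")
}

#' Contrast-weight a convergence map
#'
#' Pointwise product \eqn{C'(r,t) = C(r,t)\, w(r,t)}; suppresses spurious
#' flow signals from areas devoid of cells.
#'
#' @param map A [scalar_map()] (e.g. convergence).
#' @param weight A \code{"weight"} [scalar_map()] on the same lattice.
#' @return A [scalar_map()] of the same kind as \code{map}.
#' @export
contrast_weight <- function(map, weight) {
  stopifnot(inherits(map, "scalar_map"), inherits(weight, "scalar_map"))
  if (!.same_lattice(map, weight)) stop("contrast_weight: lattice mismatch")
  scalar_map(map$values * weight$values, map$x, map$y, map$spacing,
             kind = map$kind, border = map$border)
}

#' Thresholded contractility s*
#'
#' \eqn{s^*(r) = C(r)} where \eqn{C(r) > 0}, else 0. Missing nodes map to 0
#' (no evidence of contraction). Idempotent; output nonnegative.
#'
#' @param C A (filtered) convergence [scalar_map()].
#' @return A \code{"contractility"} [scalar_map()].
#' @export
threshold_contractility <- function(C) {
  stopifnot(inherits(C, "scalar_map"))
  v <- C$values
  v[is.na(v) | v <= 0] <- 0
  scalar_map(v, C$x, C$y, C$spacing, kind = "contractility", border = C$border)
}

#' Full contractility pipeline: stack to per-frame s* maps
#'
#' Composition, in order: displacement flows (relative to automatically
#' chosen reference frames) -> finite-difference convergence -> spatial
#' median filter -> temporal high-pass filter -> contrast weighting ->
#' thresholding. The median filter runs first to remove impulsive PIV
#' outliers before they enter the temporal recursion.
#'
#' @param stack An [image_stack()] with >= 2 frames.
#' @param config A [piv_config()].
#' @param q High-pass forgetting factor (default 0.9).
#' @param median_radius Median window radius in nodes (default 1).
#' @param contrast_window Contrast window in pixels (default 16).
#' @param delta Extrema prominence threshold for the reference bootstrap
#'   (default: automatic, see [synthesize_beat_pattern()]).
#' @param budget Re-referencing PIV budget, see [synthesize_beat_pattern()].
#' @param flows Either \code{"displacement"} (default: per-frame flows
#'   against the bootstrap reference) or \code{"velocity"}
#'   (consecutive-pair flows), or a precomputed list of [flow_grid()]s.
#' @return List of class \code{contractility_result}: \code{s} (per-frame
#'   \code{"contractility"} [scalar_map()]s), \code{C_raw}, \code{weights},
#'   \code{flows}, \code{M} (per-node temporal mean), and the beat analysis
#'   (\code{beats}) when displacement flows were computed.
#' @export
contractility_pipeline <- function(stack, config = piv_config(), q = 0.9,
                                   median_radius = 1L, contrast_window = 16L,
                                   delta = NULL, budget = Inf,
                                   flows = c("displacement", "velocity")) {
  stopifnot(inherits(stack, "image_stack"))
  if (n_frames(stack) < 2) stop("contractility_pipeline: need >= 2 frames")
  beats <- NULL
  if (is.character(flows)) {
    flows <- match.arg(flows)
    if (flows == "displacement") {
      beats <- synthesize_beat_pattern(stack, config, delta = delta, budget = budget)
      flow_list <- beats$flows
    } else {
      flow_list <- lapply(seq_len(n_frames(stack) - 1), function(t)
        two_pass_flow(get_frame(stack, t), get_frame(stack, t + 1), config))
    }
  } else {
    flow_list <- flows
  }
  Cmaps <- lapply(flow_list, function(f)
    tryCatch(median_filter_map(finite_difference_convergence(f), radius = median_radius),
             error = function(e) stop("contractility_pipeline [convergence stage]: ",
                                      conditionMessage(e))))
  proto <- Cmaps[[1]]
  arr <- array(unlist(lapply(Cmaps, `[[`, "values")),
               dim = c(length(proto$y), length(proto$x), length(Cmaps)))
  filt <- high_pass_filter(arr, q = q)
  M <- apply(arr, c(1, 2), mean, na.rm = TRUE)
  # stack-wide contrast normalization
  raw_sd <- lapply(seq_along(Cmaps), function(t)
    local_contrast(get_frame(stack, min(t, n_frames(stack))), proto$x, proto$y,
                   window = contrast_window, spacing = proto$spacing, norm = NA))
  gmax <- max(vapply(raw_sd, function(m) max(m$values, na.rm = TRUE), numeric(1)))
  weights <- lapply(raw_sd, function(m)
    scalar_map(if (gmax > 0) pmin(m$values / gmax, 1) else m$values * 0,
               m$x, m$y, m$spacing, kind = "weight"))
  s <- lapply(seq_along(Cmaps), function(t) {
    cm <- scalar_map(filt[, , t], proto$x, proto$y, proto$spacing,
                     kind = "convergence", border = proto$border)
    threshold_contractility(contrast_weight(cm, weights[[t]]))
  })
  structure(list(s = s, C_raw = Cmaps, weights = weights, flows = flow_list,
                 M = M, beats = beats, q = q),
            class = "contractility_result")
}

#' Tile-wise paired totals of a map and an image
#'
#' Distributes a node map and a pixel image covering the same field of view
#' into non-overlapping square tiles (remainder tiles dropped) and returns
#' the total of each within every tile — the quantitation used to correlate
#' convergence-derived contractility with immunofluorescence intensity.
#'
#' @param map_a A [scalar_map()] (nodes carry 1-based pixel coordinates).
#' @param image_b Numeric matrix covering the same field of view.
#' @param tile Tile width in pixels.
#' @return data.frame with \code{tile_row}, \code{tile_col}, \code{sum_map},
#'   \code{sum_image}.
#' @export
tile_aggregate <- function(map_a, image_b, tile) {
  stopifnot(inherits(map_a, "scalar_map"), is.matrix(image_b), tile >= 1)
  H <- nrow(image_b); W <- ncol(image_b)
  if (tile > H || tile > W) stop("tile_aggregate: tile larger than the field of view")
  nty <- H %/% tile; ntx <- W %/% tile
  res <- expand.grid(tile_row = seq_len(nty), tile_col = seq_len(ntx))
  node_ty <- ceiling(map_a$y / tile)
  node_tx <- ceiling(map_a$x / tile)
  res$sum_map <- mapply(function(tr, tc) {
    iy <- which(node_ty == tr); ix <- which(node_tx == tc)
    if (length(iy) == 0 || length(ix) == 0) 0
    else sum(map_a$values[iy, ix, drop = FALSE], na.rm = TRUE)
  }, res$tile_row, res$tile_col)
  res$sum_image <- mapply(function(tr, tc)
    sum(image_b[((tr - 1) * tile + 1):(tr * tile),
                ((tc - 1) * tile + 1):(tc * tile)]),
    res$tile_row, res$tile_col)
  res
}

#' Radial profile of a scalar map
#'
#' Mean of node values within concentric annuli around a center, as used to
#' compare measured convergence/displacement maps with the radially
#' symmetric model solutions.
#'
#' @param map A [scalar_map()].
#' @param center Length-2 pixel coordinates \code{c(x, y)}.
#' @param bin_width Annulus width in pixels.
#' @return data.frame with \code{radius} (bin centers), \code{value} (NA for
#'   empty annuli) and \code{n} (nodes per annulus).
#' @export
radial_profile <- function(map, center, bin_width) {
  stopifnot(inherits(map, "scalar_map"), length(center) == 2, bin_width > 0)
  if (center[1] < min(map$x) - map$spacing || center[1] > max(map$x) + map$spacing ||
      center[2] < min(map$y) - map$spacing || center[2] > max(map$y) + map$spacing)
    stop("radial_profile: center outside the field")
  r <- sqrt(outer(map$y - center[2], map$x - center[1], function(a, b) a^2 + b^2))
  bin <- floor(r / bin_width)
  nb <- max(bin) + 1
  val <- vapply(0:(nb - 1), function(b) {
    v <- map$values[bin == b]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, numeric(1))
  n <- vapply(0:(nb - 1), function(b) sum(bin == b & !is.na(map$values)), numeric(1))
  data.frame(radius = (0:(nb - 1) + 0.5) * bin_width, value = val, n = n)
}
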