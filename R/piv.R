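#' PIV configuration
#'
#' Parameters of the two-pass block-matching optical flow. The first pass
#' scans 64-pixel tiles over a wide (+/- 32 px) search area; a thin-plate
#' spline fit of the resulting sparse vectors gives a smooth coarse field,
#' which the second pass refines with 32-pixel tiles over a +/- 4 px search
#' centered on the coarse prediction.
#'
#' @param coarse_tile,coarse_search First-pass tile width and search radius
#'   (pixels).
#' @param fine_tile,fine_search Second-pass tile width and search radius
#'   (pixels); must satisfy \code{fine_tile < coarse_tile} and
#'   \code{fine_search < coarse_search}.
#' @param overlap Tile overlap fraction in \[0, 1); node spacing is
#'   \code{tile * (1 - overlap)}.
#' @param spline_smoothing Nonnegative thin-plate-spline regularization
#'   weight (on unit-normalized node coordinates). The default attenuates a
#'   single 8 px outlier in an 8 x 8 uniform field below 2 px.
#' @param score Correlation score variant: \code{"zero_mean"} (default;
#'   mean-subtracted sum of products), \code{"raw"} (the plain sum of
#'   products, sensitive to uneven illumination), or \code{"ncc"}
#'   (normalized cross-correlation; robust on smooth, low-frequency
#'   textures where the unnormalized scores are biased toward
#'   high-variance windows).
#' @return Object of class \code{piv_config}.
#' @export
piv_config <- function(coarse_tile = 64L, coarse_search = 32L,
                       fine_tile = 32L, fine_search = 4L,
                       overlap = 0.5, spline_smoothing = 1,
                       score = c("zero_mean", "raw", "ncc")) {
  score <- match.arg(score)
  coarse_tile <- as.integer(coarse_tile); coarse_search <- as.integer(coarse_search)
  fine_tile <- as.integer(fine_tile); fine_search <- as.integer(fine_search)
  if (any(c(coarse_tile, coarse_search, fine_tile, fine_search) <= 0L))
    stop("piv_config: tile and search sizes must be positive integers")
  if (fine_tile >= coarse_tile) stop("piv_config: fine_tile must be < coarse_tile")
  if (fine_search >= coarse_search) stop("piv_config: fine_search must be < coarse_search")
  if (overlap < 0 || overlap >= 1) stop("piv_config: overlap must be in [0, 1)")
  if (spline_smoothing < 0) stop("piv_config: spline_smoothing must be >= 0")
  structure(list(coarse_tile = coarse_tile, coarse_search = coarse_search,
                 fine_tile = fine_tile, fine_search = fine_search,
                 overlap = overlap, spline_smoothing = spline_smoothing,
                 score = score),
            class = "piv_config")
}

#' Cross-correlation similarity of two image tiles
#'
#' The pixel-by-pixel sum of the brightness products
#' \eqn{\sum_x h_1(x) h_2(x)}. With \code{zero_mean = TRUE} both tiles are
#' mean-subtracted first.
#'
#' @param tile_a,tile_b Numeric matrices of identical shape.
#' @param zero_mean Subtract each tile's mean before multiplying.
#' @return A single numeric score.
#' @examples
#' cross_correlation_score(matrix(1, 4, 4), matrix(1, 4, 4))  # 16
#' @export
cross_correlation_score <- function(tile_a, tile_b, zero_mean = FALSE) {
  if (!identical(dim(tile_a), dim(tile_b)))
    stop("cross_correlation_score: incompatible tiles (shape mismatch)")
  if (zero_mean) {
    tile_a <- tile_a - mean(tile_a)
    tile_b <- tile_b - mean(tile_b)
  }
  sum(tile_a * tile_b)
}

#' Best-matching integer displacement of one tile
#'
#' Exhaustively scores every integer shift within \code{predicted +/-
#' search_radius} and returns the shift maximizing the cross-correlation
#' score. Ties are broken by smallest shift magnitude, then row-major scan
#' order. The node is masked (not an error) when the tile or the full search
#' window leaves either frame, or when the tile has zero contrast.
#'
#' @param frame_a,frame_b Numeric matrices (rows = y, columns = x).
#' @param center Length-2 pixel coordinates \code{c(x, y)}, 1-based.
#' @param tile_size Tile width (pixels).
#' @param search_radius Maximum deviation from \code{predicted} (pixels).
#' @param predicted Length-2 predicted displacement \code{c(ux, uy)}.
#' @param score Score variant, see [piv_config()].
#' @return List with \code{ux}, \code{uy} (NA when masked) and \code{valid}.
#' @export
best_match_displacement <- function(frame_a, frame_b, center, tile_size,
                                    search_radius, predicted = c(0L, 0L),
                                    score = c("zero_mean", "raw", "ncc")) {
  stopifnot(is.matrix(frame_a), is.matrix(frame_b),
            identical(dim(frame_a), dim(frame_b)), length(center) == 2)
  m <- match_blocks(frame_a, frame_b,
                    as.integer(center[2] - 1L), as.integer(center[1] - 1L),
                    as.integer(tile_size), as.integer(search_radius),
                    as.integer(round(predicted[2])), as.integer(round(predicted[1])),
                    .score_mode(match.arg(score)))
  list(ux = m[1, 1], uy = m[1, 2], valid = m[1, 3] == 1L)
}

# node centers (1-based pixel coords) at which a tile of width `tile` fits
# inside a dimension of `n` pixels, spaced by tile * (1 - overlap)
.tile_nodes <- function(n, tile, overlap) {
  half <- tile %/% 2L
  step <- max(1L, as.integer(round(tile * (1 - overlap))))
  lo <- half + 1L
  hi <- n - (tile - half) + 1L
  if (hi < lo) integer(0) else seq.int(lo, hi, by = step)
}

#' Construct a flow grid
#'
#' @param ux,uy Displacement component matrices (rows = y nodes, cols = x
#'   nodes), pixels.
#' @param x,y Node pixel coordinates (1-based).
#' @param spacing Grid spacing d (pixels).
#' @param valid Logical matrix of node validity.
#' @return Object of class \code{flow_grid}.
#' @export
flow_grid <- function(ux, uy, x, y, spacing, valid = NULL) {
  stopifnot(is.matrix(ux), identical(dim(ux), dim(uy)),
            nrow(ux) == length(y), ncol(ux) == length(x), spacing > 0)
  if (is.null(valid)) valid <- !is.na(ux) & !is.na(uy)
  ux[!valid] <- NA_real_; uy[!valid] <- NA_real_
  structure(list(ux = ux, uy = uy, x = x, y = y,
                 spacing = spacing, valid = valid),
            class = "flow_grid")
}

#' @export
print.flow_grid <- function(x, ...) {
  cat(sprintf("Flow grid: %d x %d nodes, spacing %g px, %d/%d valid\n",
              length(x$y), length(x$x), x$spacing, sum(x$valid), length(x$valid)))
  invisible(x)
}

# thin-plate spline solver on normalized coordinates;
# returns a predict(px, py) closure. U(r) = r^2 log r.
.tps_solve <- function(x, y, v, lambda) {
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sc <- sqrt(mean((x - mx)^2 + (y - my)^2))
  if (sc == 0) stop("thin_plate_spline_fit: degenerate node set")
  xs <- (x - mx) / sc; ys <- (y - my) / sc
  U <- function(r) ifelse(r > 0, r^2 * log(r), 0)
  K <- U(sqrt(outer(xs, xs, "-")^2 + outer(ys, ys, "-")^2))
  P <- cbind(1, xs, ys)
  A <- rbind(cbind(K + lambda * diag(n), P),
             cbind(t(P), matrix(0, 3, 3)))
  sol <- tryCatch(solve(A, c(v, 0, 0, 0)),
                  error = function(e) stop("thin_plate_spline_fit: insufficient support (",
                                           conditionMessage(e), ")"))
  w <- sol[1:n]; a <- sol[n + 1:3]
  function(px, py) {
    pxs <- (px - mx) / sc; pys <- (py - my) / sc
    Kp <- U(sqrt(outer(pxs, xs, "-")^2 + outer(pys, ys, "-")^2))
    a[1] + a[2] * pxs + a[3] * pys + as.vector(Kp %*% w)
  }
}

#' Thin-plate spline fit of a sparse displacement field
#'
#' Interpolates/denoises each displacement component of a sparse flow grid by
#' a thin-plate spline and evaluates it on a target lattice. With smoothing 0
#' the spline interpolates the valid nodes exactly; positive smoothing trades
#' fidelity for stiffness, attenuating isolated outliers. Affine fields
#' (uniform and linear) are reproduced exactly for any smoothing.
#'
#' @param sparse_flow A [flow_grid()] with at least 3 non-collinear valid
#'   nodes.
#' @param target_x,target_y Pixel coordinates of the output lattice; default
#'   the input lattice.
#' @param smoothing Nonnegative regularization weight.
#' @return A [flow_grid()] on the target lattice (all nodes valid).
#' @export
thin_plate_spline_fit <- function(sparse_flow, target_x = NULL, target_y = NULL,
                                  smoothing = 0) {
  stopifnot(inherits(sparse_flow, "flow_grid"), smoothing >= 0)
  if (is.null(target_x)) target_x <- sparse_flow$x
  if (is.null(target_y)) target_y <- sparse_flow$y
  ok <- which(sparse_flow$valid, arr.ind = TRUE)
  if (nrow(ok) < 3) stop("thin_plate_spline_fit: insufficient support (< 3 valid nodes)")
  nx <- sparse_flow$x[ok[, 2]]
  ny <- sparse_flow$y[ok[, 1]]
  if (qr(cbind(1, nx, ny))$rank < 3)
    stop("thin_plate_spline_fit: insufficient support (collinear nodes)")
  fx <- .tps_solve(nx, ny, sparse_flow$ux[ok], smoothing)
  fy <- .tps_solve(nx, ny, sparse_flow$uy[ok], smoothing)
  gx <- rep(target_x, each = length(target_y))
  gy <- rep(target_y, times = length(target_x))
  flow_grid(matrix(fx(gx, gy), length(target_y), length(target_x)),
            matrix(fy(gx, gy), length(target_y), length(target_x)),
            target_x, target_y,
            spacing = if (length(target_x) > 1) diff(target_x[1:2]) else 1,
            valid = matrix(TRUE, length(target_y), length(target_x)))
}

# run one block-matching pass over a node lattice; pred_* matrices (or 0)
.score_mode <- function(score)
  c(raw = 0L, zero_mean = 1L, ncc = 2L)[[score]]

.match_pass <- function(frame_a, frame_b, xs, ys, tile, search,
                        pred_ux = NULL, pred_uy = NULL, score = "zero_mean") {
  gx <- rep(xs, each = length(ys))
  gy <- rep(ys, times = length(xs))
  zx <- if (is.null(pred_ux)) integer(length(gx)) else as.integer(round(pred_ux))
  zy <- if (is.null(pred_uy)) integer(length(gy)) else as.integer(round(pred_uy))
  m <- match_blocks(frame_a, frame_b, as.integer(gy - 1L), as.integer(gx - 1L),
                    as.integer(tile), as.integer(search), zy, zx, .score_mode(score))
  step <- if (length(xs) > 1) diff(xs[1:2]) else tile
  flow_grid(matrix(as.numeric(m[, 1]), length(ys), length(xs)),
            matrix(as.numeric(m[, 2]), length(ys), length(xs)),
            xs, ys, spacing = step,
            valid = matrix(m[, 3] == 1L, length(ys), length(xs)))
}

#' Two-pass block-matching optical flow between an image pair
#'
#' Pass 1 matches coarse tiles over the wide search range; the sparse result
#' is smoothed by a thin-plate spline and evaluated at the fine lattice as
#' the displacement prediction; pass 2 matches fine tiles over the small
#' search range around each prediction. Displacement components therefore
#' never exceed \code{coarse_search + fine_search} in magnitude. If fewer
#' than 3 valid non-collinear coarse nodes exist, the componentwise mean of
#' the valid coarse vectors (or zero) is used as a constant prediction.
#'
#' @param frame_a,frame_b Numeric matrices of equal shape, each dimension
#'   larger than \code{coarse_tile + 2 * coarse_search}.
#' @param config A [piv_config()].
#' @return A [flow_grid()] on the fine lattice; nodes whose tile/search
#'   window leaves the frame are masked.
#' @export
two_pass_flow <- function(frame_a, frame_b, config = piv_config()) {
  stopifnot(inherits(config, "piv_config"), is.matrix(frame_a), is.matrix(frame_b))
  if (!identical(dim(frame_a), dim(frame_b)))
    stop("two_pass_flow: frames must have identical shape")
  need <- config$coarse_tile + 2L * config$coarse_search
  if (nrow(frame_a) <= need || ncol(frame_a) <= need)
    stop(sprintf(paste0("two_pass_flow: frame (%d x %d) too small; both dimensions must ",
                        "exceed coarse_tile + 2*coarse_search = %d"),
                 nrow(frame_a), ncol(frame_a), need))
  cxs <- .tile_nodes(ncol(frame_a), config$coarse_tile, config$overlap)
  cys <- .tile_nodes(nrow(frame_a), config$coarse_tile, config$overlap)
  coarse <- .match_pass(frame_a, frame_b, cxs, cys,
                        config$coarse_tile, config$coarse_search,
                        score = config$score)
  fxs <- .tile_nodes(ncol(frame_a), config$fine_tile, config$overlap)
  fys <- .tile_nodes(nrow(frame_a), config$fine_tile, config$overlap)
  pred <- tryCatch(
    thin_plate_spline_fit(coarse, fxs, fys, smoothing = config$spline_smoothing),
    error = function(e) {
      mux <- mean(coarse$ux[coarse$valid])
      muy <- mean(coarse$uy[coarse$valid])
      if (!is.finite(mux)) mux <- 0
      if (!is.finite(muy)) muy <- 0
      flow_grid(matrix(mux, length(fys), length(fxs)),
                matrix(muy, length(fys), length(fxs)),
                fxs, fys, spacing = 1)
    })
  cs <- config$coarse_search
  .match_pass(frame_a, frame_b, fxs, fys, config$fine_tile, config$fine_search,
              pred_ux = pmin(pmax(pred$ux, -cs), cs),
              pred_uy = pmin(pmax(pred$uy, -cs), cs),
              score = config$score)
}
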