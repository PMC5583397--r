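#' Parameters of the contractile elastic sheet model
#'
#' The cell monolayer is modelled as an isotropic linear elastic plate with
#' Hooke's law \eqn{\sigma = c_1 \varepsilon + c_2 I\,\mathrm{Tr}\varepsilon},
#' carrying a uniform isotropic active stress \eqn{\sigma^* I} inside a
#' circular core of radius \code{r0}, and (optionally) tethered to the rigid
#' substrate by an elastic drag of spring constant \code{k} per unit area.
#' The drag introduces the decay length
#' \eqn{\lambda = \sqrt{(c_1+c_2)/k}}, beyond which deformations die off
#' exponentially.
#'
#' @param c1,c2 Elastic moduli (stress units) of the sheet. Requires
#'   \code{c1 > 0} and \code{c1 + 2*c2 > 0} (positive compressional stiffness).
#' @param k Substrate drag spring constant (stress / length^2), \code{>= 0}.
#'   \code{k = 0} is the freely floating sheet.
#' @param sigma_star Magnitude of the active contractile stress inside the
#'   core (stress units). Positive values contract.
#' @param r0 Radius of the uniformly contracting core (length units).
#' @return An object of class \code{sheet_params}: a list with the validated
#'   fields plus \code{lambda} (\code{Inf} when \code{k = 0}).
#' @examples
#' p <- sheet_params(c1 = 1, c2 = 1, k = 1, sigma_star = 1, r0 = 1)
#' p$lambda  # sqrt(2)
#' @export
sheet_params <- function(c1 = 1, c2 = 1, k = 0, sigma_star = 1, r0 = 1) {
  stopifnot(is.numeric(c1), is.numeric(c2), is.numeric(k),
            is.numeric(sigma_star), is.numeric(r0))
  if (c1 <= 0) stop("sheet_params: c1 must be > 0")
  if (c1 + 2 * c2 <= 0) stop("sheet_params: c1 + 2*c2 must be > 0 (compressional stiffness)")
  if (c1 + c2 <= 0) stop("sheet_params: c1 + c2 must be > 0")
  if (k < 0) stop("sheet_params: k must be >= 0")
  if (r0 <= 0) stop("sheet_params: r0 must be > 0")
  structure(list(c1 = c1, c2 = c2, k = k, sigma_star = sigma_star, r0 = r0,
                 lambda = if (k > 0) sqrt((c1 + c2) / k) else Inf),
            class = "sheet_params")
}

#' @export
print.sheet_params <- function(x, ...) {
  cat(sprintf("Elastic sheet: c1=%g c2=%g k=%g sigma*=%g r0=%g lambda=%g\n",
              x$c1, x$c2, x$k, x$sigma_star, x$r0, x$lambda))
  invisible(x)
}

#' Strain tensor of a radially symmetric displacement field, in polar components
#'
#' For a rotation-invariant field \eqn{u_r = u(r)}, \eqn{u_\phi = 0} the
#' infinitesimal strain tensor has \eqn{\varepsilon_{rr} = du/dr},
#' \eqn{\varepsilon_{\phi\phi} = u/r} and a shear component that vanishes
#' identically, \eqn{\varepsilon_{r\phi} = 0}.
#'
#' @param u Radial displacement: a function of \code{r}, or a
#'   \code{radial_solution} (whose analytic derivative is then used).
#' @param r Radii at which to evaluate (all \code{> 0}).
#' @param du Optional derivative \eqn{du/dr} as a function of \code{r}. When
#'   missing (and \code{u} is a plain function) a fourth-order central
#'   difference is used.
#' @return A list with numeric vectors \code{err}, \code{ephiphi},
#'   \code{erphi} (the last is exactly zero) and \code{r}.
#' @export
strain_polar <- function(u, r, du = NULL) {
  if (inherits(u, "radial_solution")) {
    du <- u$du
    u <- u$u
  }
  stopifnot(is.function(u), is.numeric(r))
  if (any(r <= 0)) stop("strain_polar: r must be > 0 (use the inner-solution limit at r = 0)")
  if (is.null(du)) {
    dudr <- vapply(r, function(ri) {
      h <- 1e-5 * max(1, abs(ri))
      (-u(ri + 2 * h) + 8 * u(ri + h) - 8 * u(ri - h) + u(ri - 2 * h)) / (12 * h)
    }, numeric(1))
  } else {
    dudr <- du(r)
  }
  list(err = dudr, ephiphi = u(r) / r, erphi = rep(0, length(r)), r = r)
}

#' Hooke's law for an isotropic elastic sheet, polar components
#'
#' \eqn{\sigma_{rr} = c_1\varepsilon_{rr} + c_2(\varepsilon_{rr}+\varepsilon_{\phi\phi})},
#' \eqn{\sigma_{\phi\phi} = c_1\varepsilon_{\phi\phi} + c_2(\varepsilon_{rr}+\varepsilon_{\phi\phi})},
#' \eqn{\sigma_{r\phi} = c_1\varepsilon_{r\phi}}. The trace identity
#' \eqn{\mathrm{Tr}\,\sigma = (c_1+2c_2)\mathrm{Tr}\,\varepsilon} follows.
#'
#' @param strain A strain list as produced by [strain_polar()].
#' @param c1,c2 Elastic moduli.
#' @return A list with \code{srr}, \code{sphiphi}, \code{srphi} and the traces
#'   \code{tr_strain}, \code{tr_stress}.
#' @export
hooke_stress <- function(strain, c1, c2) {
  tr <- strain$err + strain$ephiphi
  list(srr = c1 * strain$err + c2 * tr,
       sphiphi = c1 * strain$ephiphi + c2 * tr,
       srphi = c1 * strain$erphi,
       tr_strain = tr,
       tr_stress = (c1 + 2 * c2) * tr)
}

#' Equilibrium displacement of a uniformly contracting core
#'
#' Solves the radial force balance of the sheet for a single contractile
#' center of radius \code{r0}. Without substrate drag (\code{k = 0}) the
#' solution is the classical piecewise form \eqn{u = b r} inside and
#' \eqn{u = a/r} outside, with the outer region exactly divergence-free.
#' With drag (\code{k > 0}) the radial equation becomes the modified Bessel
#' equation of order one: \eqn{u = A I_1(r/\lambda)} inside and
#' \eqn{u = B K_1(r/\lambda)} outside, the prefactors fixed by matching at
#' \code{r0}.
#'
#' Two matching conventions are available for \code{k = 0}:
#' \describe{
#'   \item{\code{"stress-free-core"}}{inner coefficient
#'     \eqn{b = -\sigma^*/(c_1+2c_2)} (total stress vanishes inside the
#'     core) plus displacement continuity; the inner convergence plateau is
#'     the classical \eqn{2\sigma^*/(c_1+2c_2)}.}
#'   \item{\code{"traction"}}{displacement \emph{and} total radial traction
#'     \eqn{\sigma_{rr}+\sigma^*_{rr}} continuous across \code{r0}, giving
#'     \eqn{b = -\sigma^*/(2(c_1+c_2))}. This is the \eqn{k \to 0} limit of
#'     the Bessel branch, which always uses both conditions.}
#' }
#' See the methods vignette for why the two disagree.
#'
#' @param params A [sheet_params()] object.
#' @param matching Matching convention for the \code{k = 0} branch.
#' @return An object of class \code{radial_solution}: list with vectorized
#'   functions \code{u(r)}, \code{du(r)} (exact derivative) and \code{C(r)}
#'   (convergence \eqn{-\nabla\cdot u}), the coefficients (\code{a}, \code{b}
#'   for \code{k = 0}; \code{A}, \code{B} for \code{k > 0}), and the params.
#' @examples
#' sol <- solve_uniform_core(sheet_params(c1 = 1, c2 = 1, k = 0, sigma_star = 1))
#' sol$C(0.5)   # inner plateau 2*sigma*/(c1+2c2)
#' sol$C(2)     # exactly 0 outside the core
#' @export
solve_uniform_core <- function(params, matching = c("stress-free-core", "traction")) {
  stopifnot(inherits(params, "sheet_params"))
  matching <- match.arg(matching)
  c1 <- params$c1; c2 <- params$c2; k <- params$k
  s <- params$sigma_star; r0 <- params$r0

  if (k == 0) {
    b <- if (matching == "stress-free-core") -s / (c1 + 2 * c2) else -s / (2 * (c1 + c2))
    a <- b * r0^2                      # displacement continuity at r0
    ufun <- function(r) ifelse(r <= r0, b * r, a / r)
    dufun <- function(r) ifelse(r <= r0, b, -a / r^2)
    Cfun <- function(r) ifelse(r < r0, -2 * b, 0)
    coef <- list(a = a, b = b)
  } else {
    lam <- params$lambda
    x0 <- r0 / lam
    I1 <- besselI(x0, 1); K1 <- besselK(x0, 1)
    dI1 <- besselI(x0, 0) - I1 / x0    # I1'(x) = I0 - I1/x
    dK1 <- -besselK(x0, 0) - K1 / x0   # K1'(x) = -K0 - K1/x
    # rows: u continuity; total radial traction continuity
    M <- rbind(c(I1, -K1),
               c((c1 + c2) * dI1 / lam + c2 * I1 / r0,
                 -((c1 + c2) * dK1 / lam + c2 * K1 / r0)))
    rhs <- c(0, -s)
    AB <- solve(M, rhs)
    A <- AB[1]; B <- AB[2]
    ufun <- function(r) {
      x <- r / lam
      ifelse(r <= r0, A * besselI(x, 1), B * besselK(x, 1))
    }
    dufun <- function(r) {
      x <- r / lam
      ifelse(r <= r0,
             A * (besselI(x, 0) - besselI(x, 1) / x) / lam,
             B * (-besselK(x, 0) - besselK(x, 1) / x) / lam)
    }
    # C = -(1/r) d(r u)/dr : d(x I1)/dx = x I0, d(x K1)/dx = -x K0
    Cfun <- function(r) {
      x <- r / lam
      ifelse(r < r0, -A * besselI(x, 0) / lam, B * besselK(x, 0) / lam)
    }
    coef <- list(A = A, B = B)
  }
  structure(c(list(u = ufun, du = dufun, C = Cfun,
                   params = params, matching = matching), coef),
            class = "radial_solution")
}

#' @export
print.radial_solution <- function(x, ...) {
  cat("Radial sheet solution (", if (x$params$k == 0) "k = 0 closed form" else
      "modified Bessel branch", ", matching = ", x$matching, ")\n", sep = "")
  if (x$params$k == 0) cat(sprintf("  b = %.6g, a = %.6g\n", x$b, x$a))
  else cat(sprintf("  A = %.6g, B = %.6g, lambda = %.6g\n", x$A, x$B, x$params$lambda))
  invisible(x)
}

#' Point response kernel relating contractility to convergence
#'
#' For spatially varying contractility the convergence field is the
#' convolution of \eqn{\sigma^*} with a radially symmetric response kernel.
#' Two forms are provided:
#' \describe{
#'   \item{\code{"printed"}}{\eqn{g(r) = \frac{1}{2\lambda}[K_1(r/\lambda) -
#'     K_2(r/\lambda)]}; negative for every \code{r > 0}.}
#'   \item{\code{"consistent"}}{the smooth part of the actual negative
#'     divergence of the \eqn{K_1} displacement kernel,
#'     \eqn{-K_0(r/\lambda)/(2\pi\lambda^2)}. The full response additionally
#'     carries a local (delta) term \eqn{\sigma^*(r)/(c_1+c_2)}, which
#'     [convergence_from_contractility()] adds analytically.}
#' }
#' The two differ; only \code{"consistent"} is mutually consistent with
#' [displacement_from_contractility()] (see the methods vignette).
#'
#' @param r Radii, all \code{> 0} (the kernel diverges at 0).
#' @param lambda Decay length, \code{> 0}.
#' @param form Kernel variant.
#' @return Kernel values \code{g(r)}.
#' @export
response_kernel <- function(r, lambda, form = c("printed", "consistent")) {
  form <- match.arg(form)
  stopifnot(is.numeric(r), is.numeric(lambda), lambda > 0)
  if (any(r <= 0)) stop("response_kernel: kernel is singular at r = 0; r must be > 0")
  x <- r / lambda
  switch(form,
         printed = (besselK(x, 1) - besselK(x, 2)) / (2 * lambda),
         consistent = -besselK(x, 0) / (2 * pi * lambda^2))
}

#' Contractility field on a lattice
#'
#' A scalar, nonnegative active-stress amplitude \eqn{\sigma^*(r')} sampled on
#' a regular lattice, used as the source term of the convolution solutions.
#'
#' @param values Matrix of \eqn{\sigma^*} values (rows index \code{y}).
#' @param x,y Lattice coordinates (strictly increasing, uniform spacing).
#' @return Object of class \code{contractility_field}.
#' @export
contractility_field <- function(values, x, y) {
  stopifnot(is.matrix(values), length(y) == nrow(values), length(x) == ncol(values))
  if (any(values < 0)) stop("contractility_field: sigma* must be nonnegative")
  hx <- diff(x); hy <- diff(y)
  if (length(hx) < 1 || length(hy) < 1 ||
      max(abs(hx - hx[1])) > 1e-9 * abs(hx[1]) ||
      max(abs(hy - hy[1])) > 1e-9 * abs(hy[1]))
    stop("contractility_field: lattice must be uniform")
  structure(list(values = values, x = x, y = y, hx = hx[1], hy = hy[1]),
            class = "contractility_field")
}

#' Gaussian contractility profile
#'
#' @param amplitude Peak \eqn{\sigma^*}.
#' @param width Gaussian standard deviation (length units).
#' @param center Numeric length-2 center \code{(x, y)}.
#' @param x,y Lattice coordinates.
#' @return A [contractility_field()].
#' @export
gaussian_contractility <- function(amplitude, width, center, x, y) {
  g <- outer(y, x, function(yy, xx)
    amplitude * exp(-((xx - center[1])^2 + (yy - center[2])^2) / (2 * width^2)))
  contractility_field(g, x, y)
}

#' Uniform-core contractility profile (sharp disk)
#'
#' Boundary lattice cells are weighted by their approximate disk coverage so
#' the discretized source integrates to \eqn{\sigma^* \pi r_0^2} more
#' accurately than naive in/out sampling.
#'
#' @param amplitude Core \eqn{\sigma^*}.
#' @param r0 Core radius.
#' @param center Numeric length-2 center \code{(x, y)}.
#' @param x,y Lattice coordinates.
#' @param antialias Subsample factor for edge-cell coverage (integer >= 1).
#' @return A [contractility_field()].
#' @export
disk_contractility <- function(amplitude, r0, center, x, y, antialias = 4L) {
  h <- x[2] - x[1]
  rr <- outer(y - center[2], x - center[1], function(yy, xx) sqrt(xx^2 + yy^2))
  vals <- matrix(0, nrow(rr), ncol(rr))
  vals[rr <= r0 - h] <- amplitude
  edge <- which(rr > r0 - h & rr < r0 + h, arr.ind = TRUE)
  if (nrow(edge) > 0 && antialias >= 1L) {
    off <- (seq_len(antialias) - 0.5) / antialias - 0.5
    for (i in seq_len(nrow(edge))) {
      cx <- x[edge[i, 2]] - center[1]
      cy <- y[edge[i, 1]] - center[2]
      sub <- outer(cy + off * h, cx + off * h, function(a, b) sqrt(a^2 + b^2))
      vals[edge[i, 1], edge[i, 2]] <- amplitude * mean(sub <= r0)
    }
  }
  contractility_field(vals, x, y)
}

# Pairwise distances from eval points (n x 2) to source nodes; used by the
# quadrature routines below. Returns n x m matrix.
.pairwise_dist <- function(px, py, sx, sy) {
  dx <- outer(px, sx, "-")
  dy <- outer(py, sy, "-")
  list(dx = dx, dy = dy, d = sqrt(dx^2 + dy^2))
}

# apply FUN to blocks of rows of pts (n x 2 matrix) and rbind the results;
# keeps the n_eval x n_source quadrature matrices memory-bounded
.by_chunk <- function(pts, chunk, FUN) {
  n <- nrow(pts)
  idx <- split(seq_len(n), ceiling(seq_len(n) / chunk))
  do.call(rbind, lapply(idx, function(i) FUN(pts[i, , drop = FALSE])))
}

.field_nodes <- function(field) {
  sx <- rep(field$x, each = length(field$y))
  sy <- rep(field$y, times = length(field$x))
  list(sx = sx, sy = sy, w = as.vector(field$values), area = field$hx * field$hy)
}

#' Displacement field generated by an arbitrary contractility distribution
#'
#' Superposes the point response \eqn{u \propto -K_1(|r-r'|/\lambda)\,\hat s}
#' over the source lattice (direct quadrature):
#' \deqn{u(r) = -\frac{1}{2\pi(c_1+c_2)\lambda}\int \sigma^*(r')
#'   K_1\!\left(\frac{|r-r'|}{\lambda}\right)\frac{r-r'}{|r-r'|}\,dr'.}
#' Valid for \code{k > 0} (finite \eqn{\lambda}); the kernel's integrable
#' singularity is handled by dropping the (symmetric, self-cancelling)
#' contribution of the source cell containing the evaluation point.
#'
#' @param field A [contractility_field()].
#' @param params [sheet_params()] with \code{k > 0}.
#' @param points Evaluation points: matrix/data.frame with columns \code{x},
#'   \code{y}.
#' @return A data.frame with \code{x}, \code{y}, \code{ux}, \code{uy}.
#' @export
displacement_from_contractility <- function(field, params, points) {
  stopifnot(inherits(field, "contractility_field"), inherits(params, "sheet_params"))
  if (!is.finite(params$lambda))
    stop("displacement_from_contractility: k = 0 has no finite lambda; use solve_uniform_core")
  pts <- as.matrix(as.data.frame(points)[, c("x", "y")])
  nd <- .field_nodes(field)
  lam <- params$lambda
  pref <- -1 / (2 * pi * (params$c1 + params$c2) * lam)
  hnear <- max(field$hx, field$hy) / 2
  uv <- .by_chunk(pts, max(1, floor(2e6 / length(nd$w))), function(p) {
    D <- .pairwise_dist(p[, 1], p[, 2], nd$sx, nd$sy)
    K <- matrix(0, nrow(D$d), ncol(D$d))
    ok <- D$d > hnear                            # self cell: symmetric, drop
    K[ok] <- besselK(D$d[ok] / lam, 1) / D$d[ok] # K1(d/lam)/d for unit vector
    cbind(pref * nd$area * as.vector((K * D$dx) %*% nd$w),
          pref * nd$area * as.vector((K * D$dy) %*% nd$w))
  })
  data.frame(x = pts[, 1], y = pts[, 2], ux = uv[, 1], uy = uv[, 2])
}

#' Convergence field generated by an arbitrary contractility distribution
#'
#' Convolution of \eqn{\sigma^*} with the consistent response kernel: a local
#' term \eqn{\sigma^*(r)/(c_1+c_2)} plus the smooth tail
#' \eqn{-K_0(|r-r'|/\lambda)/(2\pi\lambda^2(c_1+c_2))}. The logarithmic
#' singularity of \eqn{K_0} is integrable; the source cell under each
#' evaluation point is integrated analytically over an equal-area disk
#' (\eqn{\int_0^X x K_0\,dx = 1 - X K_1(X)}).
#'
#' @inheritParams displacement_from_contractility
#' @param kernel \code{"consistent"} (default; matches
#'   [displacement_from_contractility()] and [solve_uniform_core()]) or
#'   \code{"printed"} for the verbatim \eqn{(K_1-K_2)/2\lambda} kernel with no
#'   local term (illustrative only).
#' @return A data.frame with \code{x}, \code{y}, \code{C}.
#' @export
convergence_from_contractility <- function(field, params, points,
                                           kernel = c("consistent", "printed")) {
  stopifnot(inherits(field, "contractility_field"), inherits(params, "sheet_params"))
  kernel <- match.arg(kernel)
  if (!is.finite(params$lambda))
    stop("convergence_from_contractility: k = 0 has no finite lambda; use solve_uniform_core")
  pts <- as.matrix(as.data.frame(points)[, c("x", "y")])
  nd <- .field_nodes(field)
  lam <- params$lambda
  h <- max(field$hx, field$hy)
  chunk <- max(1, floor(2e6 / length(nd$w)))
  if (kernel == "printed") {
    Cv <- .by_chunk(pts, chunk, function(p) {
      D <- .pairwise_dist(p[, 1], p[, 2], nd$sx, nd$sy)$d
      G <- matrix(0, nrow(D), ncol(D))
      far <- D > h / 2
      G[far] <- response_kernel(D[far], lam, form = "printed")
      cbind(nd$area * as.vector(G %*% nd$w))
    })
    return(data.frame(x = pts[, 1], y = pts[, 2], C = as.vector(Cv)))
  }
  # analytic patch for the self cell: equal-area disk of radius R
  R <- sqrt(nd$area / pi)
  patch <- -(1 - (R / lam) * besselK(R / lam, 1))  # integral of the K0 tail over the disk
  Cv <- .by_chunk(pts, chunk, function(p) {
    D <- .pairwise_dist(p[, 1], p[, 2], nd$sx, nd$sy)$d
    near <- D <= h / 2
    G <- matrix(0, nrow(D), ncol(D))
    G[!near] <- -besselK(D[!near] / lam, 0) / (2 * pi * lam^2)
    v <- nd$area * as.vector(G %*% nd$w)
    selfw <- as.vector(near %*% nd$w)              # sigma* at (cells under) the point
    nnear <- pmax(1, as.vector(near %*% rep(1, length(nd$w))))
    cbind(v + patch * selfw / nnear)
  })
  # local delta term sigma*(r): interpolate source at the evaluation point
  sig_at <- .bilinear_lattice(field$values, field$x, field$y, pts[, 1], pts[, 2])
  data.frame(x = pts[, 1], y = pts[, 2],
             C = (as.vector(Cv) + sig_at) / (params$c1 + params$c2))
}

# bilinear interpolation of a matrix sampled on (x, y) at query points
.bilinear_lattice <- function(values, x, y, qx, qy) {
  nx <- length(x); ny <- length(y)
  fx <- (qx - x[1]) / (x[2] - x[1]) + 1
  fy <- (qy - y[1]) / (y[2] - y[1]) + 1
  fx <- pmin(pmax(fx, 1), nx); fy <- pmin(pmax(fy, 1), ny)
  ix <- pmin(floor(fx), nx - 1); iy <- pmin(floor(fy), ny - 1)
  wx <- fx - ix; wy <- fy - iy
  v00 <- values[cbind(iy, ix)];     v01 <- values[cbind(iy, ix + 1)]
  v10 <- values[cbind(iy + 1, ix)]; v11 <- values[cbind(iy + 1, ix + 1)]
  v00 * (1 - wx) * (1 - wy) + v01 * wx * (1 - wy) +
    v10 * (1 - wx) * wy + v11 * wx * wy
}
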