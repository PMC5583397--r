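test_that("strain_polar gives (du/dr, u/r, 0) with a vanishing shear component", {
  b <- 0.3; a <- 2
  st <- strain_polar(function(r) b * r, c(0.5, 1, 3), du = function(r) rep(b, 3))
  expect_equal(st$err, rep(b, 3))
  expect_equal(st$ephiphi, rep(b, 3))
  expect_identical(st$erphi, rep(0, 3))
  st2 <- strain_polar(function(r) a / r, c(0.5, 1, 3), du = function(r) -a / r^2)
  expect_equal(st2$err, -a / c(0.5, 1, 3)^2)
  expect_equal(st2$ephiphi, a / c(0.5, 1, 3)^2)
  expect_equal(st2$err + st2$ephiphi, rep(0, 3))   # traceless outer solution
  # numeric differentiation fallback: u = r^2 at r = 2 -> (4, 2, 0)
  st3 <- strain_polar(function(r) r^2, 2)
  expect_equal(st3$err, 4, tolerance = 1e-8)
  expect_equal(st3$ephiphi, 2)
  expect_error(strain_polar(function(r) r, 0), "r must be > 0")
})

test_that("hooke_stress components, shear and trace identity", {
  st <- list(err = 1, ephiphi = 1, erphi = 0)   # epsilon = b I with b = 1
  ss <- hooke_stress(st, c1 = 1, c2 = 1)
  expect_equal(c(ss$srr, ss$sphiphi, ss$srphi), c(3, 3, 0))
  # outer solution scale: eps = (-1, 1, 0) -> sigma = (-c1, c1, 0), traceless
  so <- hooke_stress(list(err = -1, ephiphi = 1, erphi = 0), c1 = 2.5, c2 = 7)
  expect_equal(c(so$srr, so$sphiphi, so$srphi), c(-2.5, 2.5, 0))
  expect_equal(so$tr_stress, 0)
  expect_equal(hooke_stress(list(err = 0, ephiphi = 0, erphi = 0), 1, 1)$srr, 0)
  # trace law over random draws
  set.seed(4)
  for (i in 1:20) {
    c1 <- runif(1, 0.1, 5); c2 <- runif(1, -c1 / 2 + 0.05, 5)
    e <- list(err = rnorm(1), ephiphi = rnorm(1), erphi = 0)
    h <- hooke_stress(e, c1, c2)
    expect_equal(h$tr_stress, (c1 + 2 * c2) * h$tr_strain, tolerance = 1e-12)
  }
})

test_that("k = 0 closed form: inner plateau, outer divergence-free, Cauchy-Euler residual", {
  set.seed(8)
  for (i in 1:5) {
    c1 <- runif(1, 0.2, 3); c2 <- runif(1, 0.1, 3); s <- runif(1, 0.5, 2)
    p <- sheet_params(c1 = c1, c2 = c2, k = 0, sigma_star = s, r0 = 1)
    sol <- solve_uniform_core(p)
    expect_equal(sol$C(c(0.2, 0.5, 0.9)), rep(2 * s / (c1 + 2 * c2), 3))
    expect_equal(sol$C(c(1.5, 2, 5, 10)), rep(0, 4))
    expect_equal(sol$b, -s / (c1 + 2 * c2))
    # displacement continuity at r0
    expect_equal(sol$u(1 - 1e-10), sol$u(1 + 1e-10), tolerance = 1e-6)
    # Cauchy-Euler residual u'' + u'/r - u/r^2 = 0 on both branches
    for (r in c(0.4, 2.7)) {
      h <- 1e-4
      upp <- (sol$u(r + h) - 2 * sol$u(r) + sol$u(r - h)) / h^2
      up <- (sol$u(r + h) - sol$u(r - h)) / (2 * h)
      expect_lt(abs(upp + up / r - sol$u(r) / r^2), 1e-5)
    }
  }
})

test_that("k > 0 Bessel branch: boundary conditions, residual, halo, asymptotics", {
  p <- sheet_params(c1 = 1, c2 = 1, k = 1, sigma_star = 1, r0 = 1)
  sol <- solve_uniform_core(p)
  lam <- p$lambda
  expect_equal(sol$u(1e-8), 0, tolerance = 1e-7)          # u(0) = 0
  expect_lt(abs(sol$u(30)), 1e-8)                          # decays at infinity
  expect_equal(sol$u(1 - 1e-10), sol$u(1 + 1e-10), tolerance = 1e-6)
  # total radial traction continuity (the second matching condition)
  tr_tot <- function(r, inside) {
    st <- strain_polar(sol, r)
    hooke_stress(st, p$c1, p$c2)$srr + if (inside) p$sigma_star else 0
  }
  expect_equal(tr_tot(1 - 1e-7, TRUE), tr_tot(1 + 1e-7, FALSE), tolerance = 1e-5)
  # modified Bessel residual rho^2 u'' + rho u' - (rho^2 + 1) u = 0
  for (rho in c(0.3, 0.6, 1.5, 4)) {
    r <- rho * lam; h <- 1e-4 * lam
    upp <- (sol$u(r + h) - 2 * sol$u(r) + sol$u(r - h)) / h^2
    up <- (sol$u(r + h) - sol$u(r - h)) / (2 * h)
    res <- rho^2 * upp * lam^2 + rho * up * lam - (rho^2 + 1) * sol$u(r)
    expect_lt(abs(res), 1e-5)
  }
  # divergent halo outside the core, deepening with k
  halo <- vapply(c(0.5, 1, 5), function(k) {
    s <- solve_uniform_core(sheet_params(c1 = 1, c2 = 1, k = k, sigma_star = 1, r0 = 1))
    min(s$C(seq(1.01, 8, by = 0.01)))
  }, numeric(1))
  expect_true(all(halo < 0))
  expect_true(all(diff(halo) < 0))
  # K1 asymptotics (and hence outer C ~ -sqrt(pi/2 rho) e^-rho up to a constant)
  rho <- seq(8, 12, by = 0.5)
  ratio <- sol$C(rho * lam) / (-sqrt(pi / (2 * rho)) * exp(-rho))
  expect_lt(max(ratio) / min(ratio) - 1, 0.01)
  dev <- abs(besselK(c(5, 10, 20, 40), 1) / (sqrt(pi / (2 * c(5, 10, 20, 40))) *
                                               exp(-c(5, 10, 20, 40))) - 1)
  expect_true(all(diff(dev) < 0))          # ratio -> 1 as rho grows
  expect_lt(dev[4], 0.01)
})

test_that("k -> 0 limit of the Bessel branch approaches the traction-matched closed form", {
  p0 <- sheet_params(c1 = 1, c2 = 0.5, k = 0, sigma_star = 1, r0 = 1)
  ref <- solve_uniform_core(p0, matching = "traction")
  r <- seq(0.2, 3, by = 0.2)
  errs <- vapply(c(1e-2, 1e-4), function(k) {
    s <- solve_uniform_core(sheet_params(c1 = 1, c2 = 0.5, k = k, sigma_star = 1, r0 = 1))
    max(abs(s$u(r) - ref$u(r)))
  }, numeric(1))
  expect_lt(errs[2], 1e-3)
  expect_lt(errs[2], errs[1])
})

test_that("response_kernel forms, scale invariance and signs", {
  expect_equal(response_kernel(1, 1, form = "printed"),
               (besselK(1, 1) - besselK(1, 2)) / 2)
  expect_true(all(response_kernel(c(0.1, 1, 10), 1, form = "printed") < 0))
  expect_true(all(response_kernel(c(0.1, 1, 10), 1, form = "consistent") < 0))
  # scale invariance g(r; lambda) = g(r/lambda; 1)/lambda for the printed form
  expect_equal(response_kernel(3, 2, form = "printed"),
               response_kernel(1.5, 1, form = "printed") / 2)
  expect_error(response_kernel(0, 1), "singular")
  # the consistent smooth tail equals the negative divergence of the K1
  # displacement kernel (numeric differentiation oracle)
  lam <- 1.3
  f <- function(s) -besselK(s / lam, 1) / (2 * pi * lam)   # u kernel magnitude, c1+c2 = 1
  s0 <- 2.1; h <- 1e-6
  div_num <- (f(s0 + h) - f(s0 - h)) / (2 * h) + f(s0) / s0
  expect_equal(-div_num, response_kernel(s0, lam, form = "consistent"), tolerance = 1e-6)
})

test_that("convolution solutions match the closed form and each other", {
  p <- sheet_params(c1 = 1, c2 = 1, k = 1, sigma_star = 1, r0 = 1)
  sol <- solve_uniform_core(p)
  h <- 0.02
  grid <- seq(-1.5, 1.5, by = h)
  fld <- disk_contractility(1, 1, c(0, 0), grid, grid)
  rho <- seq(0.2, 5, by = 0.2)
  pts <- data.frame(x = rho * p$lambda, y = 0)
  Cc <- convergence_from_contractility(fld, p, pts)$C
  expect_lt(max(abs(Cc - sol$C(rho * p$lambda))) / max(abs(sol$C(rho * p$lambda))), 0.02)
  # displacement route agrees too, and zero source gives zero response
  u <- displacement_from_contractility(fld, p, pts)
  expect_lt(max(abs(u$ux - sol$u(rho * p$lambda))), 5e-3)
  expect_equal(u$uy, rep(0, length(rho)), tolerance = 1e-12)
  z <- contractility_field(matrix(0, 11, 11), 1:11, 1:11)
  expect_equal(displacement_from_contractility(z, p, pts)$ux, rep(0, length(rho)))
  expect_equal(convergence_from_contractility(z, p, pts)$C, rep(0, length(rho)))
})

test_that("finite-difference divergence of convolved displacements converges at second order", {
  p <- sheet_params(c1 = 1, c2 = 1, k = 1, sigma_star = 1, r0 = 1)
  src <- gaussian_contractility(1, 0.6, c(0, 0), seq(-3, 3, by = 0.05),
                                seq(-3, 3, by = 0.05))
  fd_err <- function(hh) {
    g <- seq(-2.4, 2.4, by = hh)
    pts <- expand.grid(x = g, y = g)
    u <- displacement_from_contractility(src, p, pts)
    n <- length(g)
    UX <- matrix(u$ux, n, n); UY <- matrix(u$uy, n, n)   # [x, y]
    ii <- 2:(n - 1)
    Cfd <- -((UX[ii + 1, ii] - UX[ii - 1, ii]) + (UY[ii, ii + 1] - UY[ii, ii - 1])) / (2 * hh)
    Cd <- convergence_from_contractility(src, p, expand.grid(x = g[ii], y = g[ii]))
    max(abs(Cfd - matrix(Cd$C, n - 2, n - 2)))
  }
  e1 <- fd_err(0.3); e2 <- fd_err(0.15)
  expect_gt(e1 / e2, 2.5)   # ~4 expected for a second-order scheme
  expect_lt(e1 / e2, 6)
})

test_that("sheet_params validates moduli and k = 0 refuses the convolution route", {
  expect_error(sheet_params(c1 = -1), "c1")
  expect_error(sheet_params(c1 = 1, c2 = -0.6), "c1 \\+ 2\\*c2")
  expect_error(sheet_params(k = -1), "k")
  p0 <- sheet_params(k = 0)
  z <- contractility_field(matrix(1, 5, 5), 1:5, 1:5)
  expect_error(displacement_from_contractility(z, p0, data.frame(x = 1, y = 0)),
               "solve_uniform_core")
})
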