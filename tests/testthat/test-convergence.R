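grid_flow <- function(fux, fuy, xs = seq(10, 90, by = 10), ys = xs, d = 10) {
  ux <- outer(ys, xs, fux); uy <- outer(ys, xs, fuy)
  flow_grid(ux, uy, xs, ys, d)
}

test_that("finite_difference_convergence: rigid motion zero, linear radial field exact", {
  fl <- grid_flow(function(y, x) 2 + 0 * x, function(y, x) -1 + 0 * x)
  C <- finite_difference_convergence(fl)
  expect_equal(max(abs(C$values)), 0)
  # inward radial u = -alpha r: C = 2 alpha, exact under central differences
  alpha <- 0.1
  fl2 <- grid_flow(function(y, x) -alpha * (x - 50), function(y, x) -alpha * (y - 50))
  C2 <- finite_difference_convergence(fl2)
  expect_equal(C2$values[!C2$border], rep(2 * alpha, sum(!C2$border)))
  expect_true(all(C2$border[1, ]))
  # border uses one-sided differences: still exact for a linear field
  expect_equal(max(abs(C2$values - 2 * alpha)), 0)
  expect_error(finite_difference_convergence(
    flow_grid(matrix(0, 2, 2), matrix(0, 2, 2), c(1, 2), c(1, 2), 1)), ">= 3")
})

test_that("central differences of the outer free-sheet field vanish at second order", {
  # u = a/r is divergence-free; discretization error must shrink ~d^2
  a <- 5
  err <- vapply(c(4, 2, 1), function(d) {
    xs <- seq(100, 180, by = d)
    fl <- grid_flow(function(y, x) a * (x - 50) / ((x - 50)^2 + (y - 50)^2),
                    function(y, x) a * (y - 50) / ((x - 50)^2 + (y - 50)^2),
                    xs = xs, ys = xs, d = d)
    C <- finite_difference_convergence(fl)
    max(abs(C$values[!C$border]))
  }, numeric(1))
  expect_gt(err[1] / err[2], 3)
  expect_gt(err[2] / err[3], 3)
})

test_that("median filter: constants, spikes, step edges, idempotence", {
  xs <- seq(10, 90, by = 10)
  con <- scalar_map(matrix(3, 9, 9), xs, xs, 10)
  expect_equal(median_filter_map(con)$values, con$values)
  spike <- matrix(0, 9, 9); spike[5, 5] <- 100
  sp <- scalar_map(spike, xs, xs, 10)
  expect_equal(median_filter_map(sp)$values[5, 5], 0)
  step <- scalar_map(cbind(matrix(0, 9, 4), matrix(1, 9, 5)), xs, xs, 10)
  once <- median_filter_map(step)
  expect_equal(once$values, step$values)          # edge preserved exactly
  expect_equal(median_filter_map(once)$values, once$values)  # idempotent here
})

test_that("high_pass_filter: fixed point, drift removal, impulse decay, mean preservation", {
  # constant series is a fixed point for any q
  expect_equal(high_pass_filter(rep(4.2, 50), q = 0.7), rep(4.2, 50))
  # linear drift converges to M + beta q/(1-q)
  beta <- 0.3; q <- 0.5
  x <- beta * (1:200)
  f <- high_pass_filter(x, q = q)
  expect_equal(f[200], mean(x) + beta * q / (1 - q), tolerance = 1e-10)
  expect_lt(abs(f[200] - f[150]), 1e-10)          # slope removed
  # unit impulse response decays as q^n
  imp <- c(rep(0, 5), 1, rep(0, 30))
  imp <- imp - mean(imp)                          # zero-mean series
  fi <- high_pass_filter(imp + 0, q = 0.8)
  tail_idx <- 8:20
  expect_equal(fi[tail_idx] - mean(imp), (fi[8] - mean(imp)) * 0.8^(tail_idx - 8),
               tolerance = 1e-10)
  # stationary periodic series: mean over whole periods equals M to 1e-12
  per <- sin(2 * pi * (0:9) / 10)
  x2 <- rep(per, 80) + 2
  f2 <- high_pass_filter(x2, q = 0.9)
  late <- f2[401:800]                             # transient fully decayed
  expect_lt(abs(mean(late) - mean(x2)), 1e-12)
  expect_error(high_pass_filter(1:10, q = 1), "q must be")
  expect_error(high_pass_filter(1:10, q = 0), "q must be")
})

test_that("local_contrast: flat zero, checkerboard saturates, blank half low", {
  xs <- c(24, 48, 72, 96)
  flat <- matrix(5, 120, 120)
  w <- local_contrast(flat, xs, xs)
  expect_equal(max(w$values), 0)
  chk <- outer(1:120, 1:120, function(i, j) ((i + j) %% 2) * 255)
  wc <- local_contrast(chk, xs, xs)
  expect_equal(max(wc$values), 1)
  half <- cbind(matrix(128, 120, 60), make_texture(2, 120)[, 1:60])
  wh <- local_contrast(half, xs, xs)
  expect_true(all(wh$values[, xs <= 60] < 0.05))
  expect_true(all(wh$values[, xs > 60] > 0.5))
})

test_that("contrast_weight is a guarded pointwise product", {
  xs <- c(10, 20, 30)
  m <- scalar_map(matrix(2, 3, 3), xs, xs, 10)
  w1 <- scalar_map(matrix(1, 3, 3), xs, xs, 10, kind = "weight")
  w0 <- scalar_map(matrix(0, 3, 3), xs, xs, 10, kind = "weight")
  expect_equal(contrast_weight(m, w1)$values, m$values)
  expect_equal(max(abs(contrast_weight(m, w0)$values)), 0)
  wl <- scalar_map(matrix(0.05, 3, 3), xs, xs, 10, kind = "weight")
  expect_equal(contrast_weight(m, wl)$values[1, 1], 0.1)
  other <- scalar_map(matrix(1, 3, 3), xs + 5, xs, 10, kind = "weight")
  expect_error(contrast_weight(m, other), "lattice mismatch")
})

test_that("threshold_contractility definition, idempotence, nonnegativity", {
  xs <- c(10, 20, 30)
  C <- scalar_map(matrix(c(-1, 0, 2, NA, -5, 1, 0.5, -0.1, 0), 3, 3), xs, xs, 10)
  s1 <- threshold_contractility(C)
  expect_equal(as.vector(s1$values), c(0, 0, 2, 0, 0, 1, 0.5, 0, 0))
  expect_true(all(s1$values >= 0))
  s2 <- threshold_contractility(s1)
  expect_equal(s2$values, s1$values)
  neg <- scalar_map(matrix(-abs(rnorm(9)), 3, 3), xs, xs, 10)
  expect_equal(max(threshold_contractility(neg)$values), 0)
})

test_that("tile_aggregate totals and correlation behavior", {
  xs <- 1:4
  m <- scalar_map(matrix(1, 4, 4), xs, xs, 1)
  img <- matrix(1, 4, 4)
  ta <- tile_aggregate(m, img, 2)
  expect_equal(nrow(ta), 4)
  expect_equal(ta$sum_map, rep(4, 4))
  expect_equal(ta$sum_image, rep(4, 4))
  expect_error(tile_aggregate(m, img, 8), "larger than")
  # proportional maps correlate perfectly
  set.seed(10)
  xs2 <- 1:20
  v <- matrix(rexp(400), 20, 20)
  ma <- scalar_map(v, xs2, xs2, 1)
  ta2 <- tile_aggregate(ma, 3 * v, 5)
  expect_equal(cor(ta2$sum_map, ta2$sum_image), 1)
  # independent maps: near-zero correlation (permutation baseline)
  cors <- vapply(1:20, function(i) {
    set.seed(i)
    a <- scalar_map(matrix(rnorm(400), 20, 20), xs2, xs2, 1)
    b <- matrix(rnorm(400), 20, 20)
    ta <- tile_aggregate(a, b, 2)     # 100 tiles
    cor(ta$sum_map, ta$sum_image)
  }, numeric(1))
  expect_gt(mean(abs(cors) < 0.3), 0.9)
})

test_that("radial_profile recovers radial functions and flags empty annuli", {
  xs <- seq(2, 198, by = 4)
  r <- sqrt(outer(xs - 100, rep(1, length(xs)))^2 +
            outer(rep(1, length(xs)), xs - 100)^2)
  m <- scalar_map(exp(-r / 30), xs, xs, 4, kind = "generic")
  pr <- radial_profile(m, c(100, 100), 8)
  ok <- pr$n > 0 & pr$radius < 90
  expect_lt(max(abs(pr$value[ok] - exp(-pr$radius[ok] / 30))), 0.05)
  flat <- scalar_map(matrix(7, length(xs), length(xs)), xs, xs, 4)
  pf <- radial_profile(flat, c(100, 100), 8)
  expect_true(all(abs(pf$value[pf$n > 0] - 7) < 1e-12))
  expect_error(radial_profile(m, c(500, 500), 8), "outside")
})

test_that("free-sheet radial profile of convergence is a positive plateau then zero", {
  p <- sheet_params(c1 = 1, c2 = 1, k = 0, sigma_star = 1, r0 = 30)
  sol <- solve_uniform_core(p)
  xs <- seq(2, 198, by = 4)
  r <- sqrt(outer(xs - 100, rep(1, length(xs)))^2 +
            outer(rep(1, length(xs)), xs - 100)^2)
  C <- scalar_map(sol$C(pmax(r, 1e-9)), xs, xs, 4, kind = "convergence")
  pr <- radial_profile(C, c(100, 100), 6)
  inner <- pr$radius < 24; outer <- pr$radius > 36 & pr$radius < 90
  expect_true(all(abs(pr$value[inner] - 2 / 3) < 1e-9))  # 2 sigma*/(c1+2c2)
  expect_true(all(abs(pr$value[outer]) < 1e-12))
})
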