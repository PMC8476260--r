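test_that("cubic B-spline basis takes its printed values", {
  expect_equal(bspline_basis(0, 0), 1 / 6, tolerance = 1e-15)
  expect_equal(bspline_basis(1, 0), 4 / 6, tolerance = 1e-15)
  expect_equal(bspline_basis(2, 0), 1 / 6, tolerance = 1e-15)
  expect_equal(bspline_basis(3, 0), 0, tolerance = 1e-15)
  expect_equal(bspline_basis(3, 1 - 1e-12), 1 / 6, tolerance = 1e-9)
  for (u in c(0, 0.25, 0.5, 0.99))
    expect_equal(sum(bspline_basis(0:3, rep(u, 4))), 1, tolerance = 1e-12)
  expect_error(bspline_basis(4, 0.5), "0..3")
})

test_that("FFD displacement reduces to constants under uniform control points", {
  g <- bspline_transform(grid_origin = c(-5, -5, -5), grid_spacing = c(5, 5, 5),
                         grid_shape = c(8, 8, 8))
  pts <- matrix(stats::runif(30, 0, 20), ncol = 3)
  expect_equal(max(abs(bspline_displacement(g, pts))), 0)
  g$displacements[, , , 1] <- 1.5
  g$displacements[, , , 2] <- -2
  g$displacements[, , , 3] <- 0.25
  d <- bspline_displacement(g, pts)
  expect_lt(max(abs(sweep(d, 2, c(1.5, -2, 0.25)))), 1e-12)
})

test_that("FFD displacement matches a triple-loop tensor-product oracle", {
  set.seed(7)
  g <- bspline_transform(grid_origin = c(-4, -5, -6), grid_spacing = c(4, 5, 6),
                         grid_shape = c(9, 8, 7),
                         displacements = array(stats::rnorm(9 * 8 * 7 * 3),
                                               c(9, 8, 7, 3)))
  pts <- cbind(stats::runif(100, 0, 20), stats::runif(100, 0, 14),
               stats::runif(100, 0, 10))
  got <- bspline_displacement(g, pts)
  for (i in 1:100)
    expect_lt(max(abs(got[i, ] - oracle_bspline_disp(g, pts[i, ]))), 1e-10)
})

test_that("FFD displacement is linear in the control displacements", {
  set.seed(8)
  shp <- c(7, 7, 7)
  d1 <- array(stats::rnorm(prod(shp) * 3), c(shp, 3))
  d2 <- array(stats::rnorm(prod(shp) * 3), c(shp, 3))
  mk <- function(d) bspline_transform(c(-5, -5, -5), c(5, 5, 5), shp, d)
  pts <- matrix(stats::runif(60, 0, 15), ncol = 3)
  a <- 0.3; b <- -1.7
  lhs <- bspline_displacement(mk(a * d1 + b * d2), pts)
  rhs <- a * bspline_displacement(mk(d1), pts) +
    b * bspline_displacement(mk(d2), pts)
  expect_lt(max(abs(lhs - rhs)), 1e-10)
})

test_that("out-of-support points raise a domain error in strict mode", {
  g <- bspline_transform(c(-5, -5, -5), c(5, 5, 5), c(6, 6, 6))
  expect_error(bspline_displacement(g, c(100, 0, 0)), "domain")
  expect_silent(bspline_displacement(g, c(100, 0, 0), strict = FALSE))
})

test_that("transform chains compose as documented", {
  pts <- matrix(stats::runif(30, 0, 10), ncol = 3)
  expect_equal(apply_transform(transform_chain(), pts), pts)
  aff <- affine_transform(matrix = diag(c(1.1, 0.9, 1)),
                          translation = c(1, -2, 0.5), center = c(5, 5, 5))
  got <- apply_transform(aff, pts)
  want <- t(apply(pts, 1, function(p)
    aff$matrix %*% (p - aff$center) + aff$center + aff$translation))
  expect_lt(max(abs(got - want)), 1e-12)
  # [affine, bspline]: the FFD displacement is evaluated at the fixed point
  g <- bspline_transform(c(-6, -6, -6), c(6, 6, 6), c(6, 6, 6),
                         displacements = array(0.5, c(6, 6, 6, 3)))
  ch <- transform_chain(aff, g)
  expect_lt(max(abs(apply_transform(ch, pts) - (want + 0.5))), 1e-10)
})

test_that("transforms survive a JSON round trip", {
  aff <- affine_transform(matrix(c(1, 0.01, 0, 0, 1, 0, 0, 0, 1), 3, 3),
                          c(4, -3, 2), c(16, 16, 16))
  set.seed(12)
  g <- bspline_transform(c(-5, -5, -5), c(5, 5, 5), c(6, 6, 6),
                         array(stats::rnorm(6^3 * 3), c(6, 6, 6, 3)),
                         frame_origin = c(1, 2, 3))
  ch <- transform_chain(aff, g)
  f <- tempfile(fileext = ".json")
  write_transform(ch, f)
  ch2 <- read_transform(f)
  pts <- matrix(stats::runif(30, 2, 12), ncol = 3)
  expect_equal(apply_transform(ch2, pts), apply_transform(ch, pts),
               tolerance = 1e-12)
  unlink(f)
})
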