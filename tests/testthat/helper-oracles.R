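# Independent brute-force oracles. These deliberately use plain R loops and
# never call the package's vectorized/compiled paths they are checking.

# Pearson-style normalized cross-correlation, scalar accumulation
oracle_ncc <- function(a, b) {
  a <- as.vector(a); b <- as.vector(b)
  ma <- sum(a) / length(a)
  mb <- sum(b) / length(b)
  num <- 0; da <- 0; db <- 0
  for (i in seq_along(a)) {
    num <- num + (a[i] - ma) * (b[i] - mb)
    da <- da + (a[i] - ma)^2
    db <- db + (b[i] - mb)^2
  }
  num / (sqrt(da) * sqrt(db))
}

# cubic B-spline basis polynomials, written out directly
oracle_basis <- function(m, u) {
  switch(m + 1L,
         (1 - u)^3 / 6,
         (3 * u^3 - 6 * u^2 + 4) / 6,
         (-3 * u^3 + 3 * u^2 + 3 * u + 1) / 6,
         u^3 / 6)
}

# triple-loop tensor-product FFD displacement at one aligned-frame point
oracle_bspline_disp <- function(t, pt) {
  out <- c(0, 0, 0)
  r <- (pt - t$grid_origin) / t$grid_spacing
  i0 <- floor(r) - 1
  u <- r - floor(r)
  for (m in 0:3) for (n in 0:3) for (l in 0:3) {
    w <- oracle_basis(m, u[1]) * oracle_basis(n, u[2]) * oracle_basis(l, u[3])
    cp <- t$displacements[i0[1] + m + 1, i0[2] + n + 1, i0[3] + l + 1, ]
    out <- out + w * cp
  }
  out
}

# exhaustive 6-neighbor surface scan (0-based indices out)
oracle_surface_idx <- function(mask) {
  d <- dim(mask)
  out <- NULL
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (mask[i, j, k] != 1) next
    nb <- list(c(i - 1, j, k), c(i + 1, j, k), c(i, j - 1, k),
               c(i, j + 1, k), c(i, j, k - 1), c(i, j, k + 1))
    on_surface <- FALSE
    for (p in nb) {
      if (any(p < 1) || any(p > d) || mask[p[1], p[2], p[3]] == 0) {
        on_surface <- TRUE
        break
      }
    }
    if (on_surface) out <- rbind(out, c(i, j, k) - 1)
  }
  out
}

# all-pairs directed nearest distances
oracle_min_dists <- function(A, B) {
  apply(A, 1, function(a) min(sqrt(colSums((t(B) - a)^2))))
}

oracle_hausdorff <- function(A, B) {
  max(max(oracle_min_dists(A, B)), max(oracle_min_dists(B, A)))
}

oracle_asd <- function(A, B) {
  (sum(oracle_min_dists(A, B)) + sum(oracle_min_dists(B, A))) /
    (nrow(A) + nrow(B))
}

oracle_hd95 <- function(A, B) {
  # sort-based linear-interpolation percentile (quantile type 7 definition)
  x <- sort(c(oracle_min_dists(A, B), oracle_min_dists(B, A)))
  h <- (length(x) - 1) * 0.95 + 1
  lo <- floor(h)
  x[lo] + (h - lo) * (x[min(lo + 1, length(x))] - x[lo])
}

# trilinear interpolation at one continuous 0-based voxel index
oracle_trilinear <- function(arr, p) {
  i0 <- pmin(pmax(floor(p), 0), dim(arr) - 2)
  f <- p - i0
  v <- 0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) f[1] else 1 - f[1]) * (if (dy) f[2] else 1 - f[2]) *
      (if (dz) f[3] else 1 - f[3])
    v <- v + w * arr[i0[1] + dx + 1, i0[2] + dy + 1, i0[3] + dz + 1]
  }
  v
}

# random binary blob mask on a small grid
random_mask <- function(d, p = 0.2) {
  array(as.integer(stats::runif(prod(d)) < p), d)
}

# small noisy test volume
tiny_volume <- function(d = c(8, 9, 7), spacing = c(1, 1, 1), seed = 1) {
  set.seed(seed)
  volume(array(stats::rnorm(prod(d)), d), spacing = spacing)
}

# phantom spec scaled down to a 32^3 grid (15.5 mm extent)
small_spec <- function(seed = 1)
  phantom_spec(shape = c(32, 32, 32), shell_radii = c(6.5, 5.5, 4.5),
               shell_thickness = 2, foramen_radius = c(1, 1), seed = seed)

# smoothed-noise texture helper (wraps the package's internal smoother)
cpp_smooth_for_tests <- function(arr, sigma = c(2, 2, 2))
  atlasseg:::cpp_gauss_smooth(as.vector(arr), dim(arr), sigma)
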