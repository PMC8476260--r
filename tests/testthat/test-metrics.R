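test_that("dice matches its defining arithmetic", {
  a <- labelmap(array(0L, c(6, 6, 6)))
  a$voxels[2:3, 2:3, 2:3] <- 1L            # 8 voxels
  expect_equal(dice(a, a), 1)
  b <- labelmap(array(0L, c(6, 6, 6)))
  b$voxels[3:4, 2:3, 2:3] <- 1L            # 8 voxels, overlap 4
  expect_equal(dice(a, b), 0.5)
  disj <- labelmap(array(0L, c(6, 6, 6)))
  disj$voxels[5:6, 5:6, 5:6] <- 1L
  expect_equal(dice(a, disj), 0)
  expect_warning(d0 <- dice(labelmap(array(0L, c(3, 3, 3))),
                            labelmap(array(0L, c(3, 3, 3)))), "empty")
  expect_equal(d0, 1)
  expect_error(dice(a, labelmap(array(0L, c(5, 5, 5)))), "same grid")
})

test_that("surface extraction matches an exhaustive 6-neighbor scan", {
  single <- labelmap(array(0L, c(5, 5, 5)))
  single$voxels[3, 3, 3] <- 1L
  s <- extract_surface(single)
  expect_equal(nrow(s), 1)
  expect_equal(as.numeric(s), c(2, 2, 2))
  cube <- labelmap(array(0L, c(8, 8, 8)))
  cube$voxels[3:6, 3:6, 3:6] <- 1L
  expect_equal(nrow(extract_surface(cube)), 4^3 - 2^3)  # 56 shell voxels
  set.seed(17)
  for (rep in 1:5) {
    m <- random_mask(c(7, 8, 6), p = 0.3)
    if (!any(m == 1)) next
    lab <- labelmap(m, spacing = c(0.5, 0.5, 0.5))
    got <- extract_surface(lab)
    want <- oracle_surface_idx(m) * 0.5
    expect_equal(got[order(got[, 1], got[, 2], got[, 3]), , drop = FALSE],
                 unname(want[order(want[, 1], want[, 2], want[, 3]), ,
                             drop = FALSE]),
                 ignore_attr = TRUE)
  }
  expect_error(extract_surface(labelmap(array(0L, c(3, 3, 3)))), "empty")
})

test_that("hausdorff on singletons is the axis distance in mm", {
  a <- labelmap(array(0L, c(12, 4, 4)), spacing = c(0.5, 0.5, 0.5))
  a$voxels[2, 2, 2] <- 1L
  b <- labelmap(array(0L, c(12, 4, 4)), spacing = c(0.5, 0.5, 0.5))
  b$voxels[9, 2, 2] <- 1L                   # 7 voxels apart along x
  expect_equal(hausdorff(a, b), 3.5)
  expect_equal(asd(a, b), 3.5)
  expect_equal(hd95(a, b), 3.5)
  expect_equal(hausdorff(a, a), 0)
})

test_that("asd between parallel plates equals their separation", {
  a <- labelmap(array(0L, c(10, 10, 12)), spacing = c(1, 1, 1))
  a$voxels[3:8, 3:8, 4] <- 1L
  b <- labelmap(array(0L, c(10, 10, 12)), spacing = c(1, 1, 1))
  b$voxels[3:8, 3:8, 7] <- 1L               # 3 mm below
  expect_equal(asd(a, b), 3)
})

test_that("hd95 follows the linear-interpolation percentile rule", {
  # surfaces constructed so the pooled nearest-neighbor multiset is exactly
  # {1 mm x19, 10 mm x1}: nine isolated point pairs 1 mm apart (18 distances),
  # one extra B point 1 mm from an A point, one outlier B point 10 mm away
  A <- t(sapply(1:9, function(i) c(0, i * 100, 0)))
  B <- rbind(t(sapply(1:9, function(i) c(1, i * 100, 0))),
             c(0, 900, 1),    # 19th distance: 1 mm from A9
             c(0, 900, 10))   # 20th distance: 10 mm from A9
  # frozen value from the sort-based oracle formula:
  # h = 0.95*(20-1)+1 = 19.05 -> 1 + 0.05*(10-1) = 1.45
  expect_equal(oracle_hd95(A, B), 1.45, tolerance = 1e-12)
  expect_equal(hd95(A, B), 1.45, tolerance = 1e-12)
  expect_equal(hausdorff(A, B), 10, tolerance = 1e-12)
})

test_that("distance metrics agree with brute-force all-pairs oracles", {
  set.seed(23)
  for (rep in 1:12) {
    d <- sample(8:20, 3, replace = TRUE)
    sp <- stats::runif(1, 0.4, 1.2)
    m1 <- random_mask(d, 0.15); m2 <- random_mask(d, 0.15)
    if (!any(m1 == 1) || !any(m2 == 1)) next
    A <- labelmap(m1, spacing = rep(sp, 3))
    B <- labelmap(m2, spacing = rep(sp, 3))
    sa <- extract_surface(A); sb <- extract_surface(B)
    expect_equal(hausdorff(A, B), oracle_hausdorff(sa, sb), tolerance = 1e-9)
    expect_equal(asd(A, B), oracle_asd(sa, sb), tolerance = 1e-9)
    expect_equal(hd95(A, B), oracle_hd95(sa, sb), tolerance = 1e-9)
    expect_lte(hd95(A, B), hausdorff(A, B) + 1e-12)
    # symmetry
    expect_equal(hausdorff(A, B), hausdorff(B, A), tolerance = 1e-12)
    expect_equal(asd(A, B), asd(B, A), tolerance = 1e-12)
    expect_equal(hd95(A, B), hd95(B, A), tolerance = 1e-12)
  }
})

test_that("metrics are translation-invariant and scale with spacing", {
  set.seed(29)
  m1 <- random_mask(c(10, 10, 10), 0.2)
  m2 <- random_mask(c(10, 10, 10), 0.2)
  A <- labelmap(m1); B <- labelmap(m2)
  # common integer-voxel translation: realized by shifting both origins
  A2 <- labelmap(m1, origin = c(3, -2, 5)); B2 <- labelmap(m2, origin = c(3, -2, 5))
  expect_equal(dice(A, B), dice(A2, B2))
  expect_equal(hausdorff(A, B), hausdorff(A2, B2), tolerance = 1e-12)
  expect_equal(asd(A, B), asd(A2, B2), tolerance = 1e-12)
  # doubling spacing doubles every distance exactly
  Ad <- labelmap(m1, spacing = c(2, 2, 2)); Bd <- labelmap(m2, spacing = c(2, 2, 2))
  expect_equal(hausdorff(Ad, Bd), 2 * hausdorff(A, B), tolerance = 1e-12)
  expect_equal(asd(Ad, Bd), 2 * asd(A, B), tolerance = 1e-12)
  expect_equal(hd95(Ad, Bd), 2 * hd95(A, B), tolerance = 1e-12)
})

test_that("evaluate reports the empty-prediction error state", {
  truth <- labelmap(array(0L, c(6, 6, 6)))
  truth$voxels[2:4, 2:4, 2:4] <- 1L
  ev <- evaluate(truth, truth)
  expect_equal(unlist(ev[c("dice", "hd95_mm", "asd_mm")]),
               c(dice = 1, hd95_mm = 0, asd_mm = 0))
  empty <- labelmap(array(0L, c(6, 6, 6)))
  ev2 <- evaluate(empty, truth)
  expect_equal(ev2$dice, 0)
  expect_true(is.na(ev2$hd95_mm) && is.na(ev2$asd_mm))
  expect_true(ev2$empty_prediction)
})
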