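test_that("volume and labelmap constructors enforce their invariants", {
  expect_error(volume(array(1, c(2, 2, 2)), spacing = c(1, -1, 1)),
               "strictly positive")
  expect_error(volume(array(1, c(2, 2, 2)), direction = matrix(1, 3, 3)),
               "orthonormal")
  expect_error(labelmap(array(2, c(2, 2, 2))), "0 or 1")
  lab <- labelmap(array(0L, c(2, 2, 2)))
  expect_s3_class(lab, "labelmap")
  expect_error(atlas("a", volume(array(1, c(2, 2, 2))),
                     labelmap(array(0L, c(3, 3, 3)))),
               "identical geometry")
})

test_that("NIfTI round trip preserves voxels and geometry", {
  R <- cbind(c(0, 1, 0), c(-1, 0, 0), c(0, 0, 1))  # 90 deg rotation
  v <- volume(array(sample(0:255, 3 * 4 * 5, TRUE), c(3, 4, 5)),
              spacing = c(0.5, 0.7, 0.9), origin = c(1.5, -2, 3),
              direction = R)
  for (ext in c(".nii", ".nii.gz")) {
    f <- tempfile(fileext = ext)
    write_volume(v, f)
    v2 <- read_volume(f)
    expect_identical(v2$voxels, v$voxels)
    expect_lt(max(abs(v2$spacing - v$spacing)), 1e-6)
    expect_lt(max(abs(v2$origin - v$origin)), 1e-6)
    expect_lt(max(abs(v2$direction - v$direction)), 1e-6)
    unlink(f)
  }
})

test_that("MetaImage round trip preserves voxels and geometry", {
  R <- cbind(c(0, 0, 1), c(1, 0, 0), c(0, 1, 0))
  v <- volume(array(stats::rnorm(60), c(3, 4, 5)), spacing = c(1.1, 0.4, 2),
              origin = c(-7, 0.25, 11), direction = R)
  f <- tempfile(fileext = ".mha")
  write_volume(v, f)
  v2 <- read_volume(f)
  expect_equal(v2$voxels, v$voxels, tolerance = 1e-12)
  expect_lt(max(abs(v2$spacing - v$spacing)), 1e-9)
  expect_lt(max(abs(v2$origin - v$origin)), 1e-9)
  expect_lt(max(abs(v2$direction - v$direction)), 1e-9)
  unlink(f)
})

test_that("a phantom written to disk keeps its stated spacing", {
  ph <- make_phantom(small_spec())
  f <- tempfile(fileext = ".nii.gz")
  write_volume(ph$gray, f)
  v <- read_volume(f)
  expect_equal(v$spacing, c(0.5, 0.5, 0.5), tolerance = 1e-6)
  expect_equal(v$voxels, ph$gray$voxels, tolerance = 1e-6)
  unlink(f)
})

test_that("unreadable or unsupported files give format errors", {
  txt <- tempfile(fileext = ".txt")
  writeLines("not an image", txt)
  expect_error(read_volume(txt), "unsupported")
  bad <- tempfile(fileext = ".nii")
  writeLines("still not an image", bad)
  expect_error(read_volume(bad), "unreadable|NIfTI")
  expect_error(read_volume(tempfile(fileext = ".nii")), "not found")
  unlink(c(txt, bad))
})

test_that("label maps are validated on read, never thresholded", {
  lab <- labelmap(array(c(0L, 1L), c(4, 4, 4)))
  f <- tempfile(fileext = ".nii.gz")
  write_labelmap(lab, f)
  expect_identical(read_labelmap(f)$voxels, lab$voxels)
  # zeros-only file
  f0 <- tempfile(fileext = ".nii.gz")
  write_labelmap(labelmap(array(0L, c(3, 3, 3))), f0)
  expect_equal(sum(read_labelmap(f0)$voxels), 0)
  # a gray file with value 2 must be rejected with the offending value listed
  v2 <- volume(array(c(0, 1, 2), c(3, 3, 3)))
  f2 <- tempfile(fileext = ".nii.gz")
  write_volume(v2, f2, datatype = "uint8")
  expect_error(read_labelmap(f2), "2")
  unlink(c(f, f0, f2))
})

test_that("resampling onto the same grid is the identity for all interpolators", {
  v <- tiny_volume(c(10, 11, 12), spacing = c(0.7, 1, 1.3), seed = 4)
  for (interp in c("nearest", "linear", "cubic-bspline")) {
    r <- resample_to_reference(v, v, interp)
    expect_lt(max(abs(r$voxels - v$voxels)), 1e-6)
  }
  expect_error(resample_to_reference(v, v, "sinc"), "unknown interpolation")
})

test_that("constant volumes stay constant under resampling to any grid", {
  v <- volume(array(3.25, c(8, 8, 8)), spacing = c(1, 1, 1))
  ref <- volume(array(0, c(5, 6, 7)), spacing = c(0.8, 0.9, 0.6),
                origin = c(0.3, 0.4, 0.2))
  for (interp in c("nearest", "linear", "cubic-bspline")) {
    r <- resample_to_reference(v, ref, interp)
    expect_lt(max(abs(r$voxels - 3.25)), 1e-6)
  }
})

test_that("linear resampling of a ramp gives exact midpoints at half-voxel offsets", {
  d <- c(12, 6, 6)
  ramp <- volume(array(rep(0:(d[1] - 1), times = prod(d[2:3])), d),
                 spacing = c(0.5, 0.5, 0.5))
  ref <- volume(array(0, d - c(1, 0, 0)), spacing = c(0.5, 0.5, 0.5),
                origin = c(0.25, 0, 0))  # half-voxel shift along the ramp
  r <- resample_to_reference(ramp, ref, "linear")
  expected <- rep(0:(d[1] - 2) + 0.5, times = prod(d[2:3]))
  expect_lt(max(abs(as.vector(r$voxels) - expected)), 1e-12)
})

test_that("nearest-neighbor resampling of a label map yields only input values", {
  set.seed(9)
  lab <- labelmap(random_mask(c(9, 9, 9)), spacing = c(1, 1, 1))
  ref <- volume(array(0, c(14, 14, 14)), spacing = c(0.6, 0.6, 0.6),
                origin = c(-0.4, 0.2, 0.1))
  r <- resample_to_reference(lab, ref, "nearest")
  expect_true(all(r$voxels %in% c(0, 1)))
  expect_s3_class(r, "labelmap")
})
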