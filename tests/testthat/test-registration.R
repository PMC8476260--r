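# registration tests share one phantom (64^3 @ 0.5 mm, the desk scale)
ph <- make_phantom(phantom_spec())
fixed <- ph$gray
cfg <- registration_config("desk")

test_that("self-registration stays at the identity", {
  aff <- register_affine(fixed, fixed, cfg)
  expect_lt(sqrt(sum(aff$translation^2)), 0.25)          # 0.5 voxel
  expect_lt(norm(aff$matrix - diag(3), "F"), 0.05)
  ffd <- register_bspline(fixed, fixed, aff, cfg)
  # the recovered deformation field stays sub-voxel over the whole domain
  # (stochastic optimization leaves noise-level jitter, nothing systematic)
  pts <- voxel_to_world(fixed, atlasseg:::grid_indices(dim(fixed$voxels)))
  D <- bspline_displacement(ffd, pts, strict = FALSE)
  expect_lt(max(sqrt(rowSums(D^2))), mean(fixed$spacing))        # < 1 voxel
  expect_lt(mean(sqrt(rowSums(D^2))), 0.2 * mean(fixed$spacing))
})

test_that("a known rotation is recovered within a degree", {
  # textured volume (smoothed noise): rotation is observable everywhere,
  # unlike on the near-ellipsoidal phantom where shear can alias it
  set.seed(10)
  arr <- array(stats::rnorm(64^3), c(64, 64, 64))
  arr <- array(cpp_smooth_for_tests(arr), c(64, 64, 64))
  tex <- volume(arr * 300, spacing = c(0.5, 0.5, 0.5))
  th <- 5 * pi / 180
  Rz <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  ctr <- atlasseg:::domain_center(tex)
  # true fixed-to-moving map = +5 degree rotation about z
  moving <- warp(tex, affine_transform(matrix = solve(Rz), center = ctr),
                 tex, interpolation = "linear")
  aff <- register_affine(tex, moving, cfg)
  ang <- atan2(aff$matrix[2, 1], aff$matrix[1, 1]) * 180 / pi
  expect_lt(abs(ang - 5), 1)
  expect_lt(sqrt(sum(aff$translation^2)), 0.25)
})

test_that("warping is exact for identity and integer-shift chains", {
  w <- warp(fixed, transform_chain(), fixed, "linear")
  expect_lt(max(abs(w$voxels - fixed$voxels)), 1e-6)
  # pure +1 voxel translation with nearest neighbor = array shift
  sh <- affine_transform(translation = c(fixed$spacing[1], 0, 0))
  w2 <- warp(fixed, sh, fixed, "nearest")
  d <- dim(fixed$voxels)
  expect_equal(w2$voxels[1:(d[1] - 1), , ], fixed$voxels[2:d[1], , ])
})

test_that("warp agrees with an independent per-voxel evaluation", {
  aff <- affine_transform(matrix = diag(c(1.03, 0.97, 1)) %*%
                            rbind(c(1, 0.02, 0), c(-0.02, 1, 0), c(0, 0, 1)),
                          translation = c(1.2, -0.7, 0.4),
                          center = c(10, 10, 10))
  ch <- transform_chain(aff)
  w <- warp(fixed, ch, fixed, "linear")
  set.seed(13)
  d <- dim(fixed$voxels)
  for (rep in 1:100) {
    idx <- c(sample(4:(d[1] - 4), 1), sample(4:(d[2] - 4), 1),
             sample(4:(d[3] - 4), 1))
    p <- voxel_to_world(fixed, idx)
    q <- aff$matrix %*% (as.numeric(p) - aff$center) + aff$center +
      aff$translation
    cidx <- as.numeric(world_to_voxel(fixed, as.numeric(q)))
    want <- if (all(cidx >= 0) && all(cidx <= d - 1))
      oracle_trilinear(fixed$voxels, cidx) else min(fixed$voxels)
    expect_lt(abs(w$voxels[idx[1] + 1, idx[2] + 1, idx[3] + 1] - want), 1e-9)
  }
})

test_that("label propagation stays binary and preserves integer shifts", {
  lab <- ph$left
  w <- warp_label(lab, transform_chain(), fixed)
  expect_identical(w$voxels, lab$voxels)
  sh <- affine_transform(translation = c(0, 2 * fixed$spacing[2], 0))
  w2 <- warp_label(lab, sh, fixed)
  expect_true(all(w2$voxels %in% c(0L, 1L)))
  expect_equal(sum(w2$voxels), sum(lab$voxels))  # structure is interior
  co <- cohort_spec()
  ffd <- random_deformation(co, fixed, seed = 3)
  w3 <- warp_label(lab, transform_chain(ffd), fixed)
  expect_true(all(w3$voxels %in% c(0L, 1L)))
})

test_that("registration is bit-reproducible under a fixed seed", {
  co <- cohort_spec()
  ffd <- random_deformation(co, fixed, seed = 5)
  moving <- warp(fixed, ffd, fixed, interpolation = "linear")
  a1 <- register_affine(fixed, moving, cfg)
  a2 <- register_affine(fixed, moving, cfg)
  expect_identical(a1$matrix, a2$matrix)
  expect_identical(a1$translation, a2$translation)
  b1 <- register_bspline(fixed, moving, a1, cfg)
  b2 <- register_bspline(fixed, moving, a2, cfg)
  expect_identical(b1$displacements, b2$displacements)
})

test_that("registration reduces deformation error and improves the metric", {
  # ten seeded pairs; errors measured over the bone shell, where the
  # deformation is observable from image structure
  co <- cohort_spec()
  base <- atlasseg:::phantom_clean(phantom_spec())
  bone <- which(as.vector(base$gray$voxels > 500))
  idx_all <- atlasseg:::grid_indices(dim(fixed$voxels))
  pre <- post <- numeric(10)
  nmi_gain <- logical(10)
  for (sd in 1:10) {
    ffd <- random_deformation(co, fixed, seed = 100 + sd)
    moving <- warp(fixed, ffd, fixed, interpolation = "linear")
    aff <- register_affine(fixed, moving, cfg)
    rec <- register_bspline(fixed, moving, aff, cfg)
    chain <- transform_chain(aff, rec)
    set.seed(1)
    pts <- voxel_to_world(fixed, idx_all[sample(bone, 1500), ])
    y <- pts
    for (k in 1:30) y <- pts - bspline_displacement(ffd, y, strict = FALSE)
    mapped <- apply_transform(chain, pts)
    pre[sd] <- mean(sqrt(rowSums((pts - y)^2)))
    post[sd] <- mean(sqrt(rowSums((mapped - y)^2)))
    nmi_gain[sd] <-
      nmi(fixed, moving, chain, samples = 4000, seed = 77) >=
      nmi(fixed, moving, NULL, samples = 4000, seed = 77)
  }
  expect_lt(median(post), median(pre))
  expect_true(all(nmi_gain))
})
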