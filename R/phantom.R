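#' Specification of a synthetic skull-base phantom
#'
#' The phantom emulates the kind of data this pipeline targets: a bright
#' ellipsoidal bone shell (skull base) on a soft-tissue/air background,
#' pierced by two oblique cylindrical low-intensity channels a few mm wide
#' (the left and right foramen-like canals), with acquisition noise added
#' before a slight Gaussian smoothing. Ground-truth labels mark each canal
#' where it passes through bone.
#'
#' @param shape voxels per axis (default 64^3).
#' @param spacing mm per voxel (default 0.5 isotropic).
#' @param shell_radii outer ellipsoid radii in mm.
#' @param shell_thickness bone shell thickness in mm.
#' @param foramen_radius canal radius in mm, length 2 (left, right).
#' @param intensity list with `air`, `soft`, `bone` levels (CT-like arbitrary
#'   units) and Gaussian `noise_sd`.
#' @param smoothing_sigma post-noise Gaussian smoothing in mm.
#' @param seed RNG seed; the phantom is a pure function of spec + seed.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(64, 64, 64), spacing = c(0.5, 0.5, 0.5),
                         shell_radii = c(13, 11, 9), shell_thickness = 3,
                         foramen_radius = c(1.5, 1.5),
                         intensity = list(air = -1000, soft = 40, bone = 1200,
                                          noise_sd = 40),
                         smoothing_sigma = 0.5, seed = 1L) {
  spec <- list(shape = as.integer(shape), spacing = as.numeric(spacing),
               shell_radii = as.numeric(shell_radii),
               shell_thickness = shell_thickness,
               foramen_radius = rep_len(as.numeric(foramen_radius), 2L),
               intensity = intensity, smoothing_sigma = smoothing_sigma,
               seed = as.integer(seed))
  if (any(spec$shell_radii <= spec$shell_thickness))
    stop("shell radii must exceed the shell thickness", call. = FALSE)
  class(spec) <- "phantom_spec"
  spec
}

# geometry only, no noise/smoothing: gray + left/right truth labels
phantom_clean <- function(spec) {
  d <- spec$shape
  sp <- spec$spacing
  ax <- lapply(1:3, function(k) (0:(d[k] - 1)) * sp[k])
  ctr <- vapply(1:3, function(k) (d[k] - 1) * sp[k] / 2, numeric(1))
  X <- array(rep(ax[[1]] - ctr[1], times = d[2] * d[3]), d)
  Y <- array(rep(rep(ax[[2]] - ctr[2], each = d[1]), times = d[3]), d)
  Z <- array(rep(ax[[3]] - ctr[3], each = d[1] * d[2]), d)
  router <- spec$shell_radii
  rinner <- router - spec$shell_thickness
  outer <- (X / router[1])^2 + (Y / router[2])^2 + (Z / router[3])^2 <= 1
  inner <- (X / rinner[1])^2 + (Y / rinner[2])^2 + (Z / rinner[3])^2 <= 1
  band <- outer & !inner
  channel <- function(w, v, radius) {
    w <- w / sqrt(sum(w^2))
    v <- v / sqrt(sum(v^2))
    rmid <- router - spec$shell_thickness / 2
    s <- 1 / sqrt(sum((w / rmid)^2))  # radial scale to the mid-shell surface
    p <- w * s
    dx <- X - p[1]; dy <- Y - p[2]; dz <- Z - p[3]
    t <- dx * v[1] + dy * v[2] + dz * v[3]
    r2 <- (dx - t * v[1])^2 + (dy - t * v[2])^2 + (dz - t * v[3])^2
    list(hole = r2 <= radius^2 & abs(t) <= 2 * spec$shell_thickness,
         canal = r2 <= radius^2 & abs(t) <= 1.5 * spec$shell_thickness)
  }
  chL <- channel(c(-0.55, 0.15, -0.80), c(-0.45, 0.05, -0.89),
                 spec$foramen_radius[1])
  chR <- channel(c(0.55, 0.20, -0.80), c(0.48, 0.10, -0.87),
                 spec$foramen_radius[2])
  hole <- chL$hole | chR$hole
  gray <- array(spec$intensity$air, d)
  gray[inner] <- spec$intensity$soft
  gray[band & !hole] <- spec$intensity$bone
  gray[band & hole] <- spec$intensity$soft
  labL <- (chL$canal & band) * 1L
  labR <- (chR$canal & band) * 1L
  if (any(labL & labR))
    stop("phantom spec error: left and right foramina overlap", call. = FALSE)
  for (lab in list(labL, labR)) {
    n <- sum(lab)
    if (n < 20)
      stop("phantom spec error: foramen label has ", n, " voxels (< 20)",
           call. = FALSE)
    idx <- which(lab == 1L, arr.ind = TRUE)
    if (any(idx == 1L) || any(sweep(idx, 2, d, `>=`)))
      stop("phantom spec error: foramen touches the volume boundary",
           call. = FALSE)
  }
  g <- volume(gray, spacing = sp)
  list(gray = g,
       left = labelmap(labL, like = g),
       right = labelmap(labR, like = g))
}

# acquisition noise then slight smoothing (processing order of the emulated
# atlas preparation: smoothing is applied last)
phantom_finish <- function(gray, spec) {
  v <- gray$voxels + stats::rnorm(length(gray$voxels), 0,
                                  spec$intensity$noise_sd)
  sigma_vox <- spec$smoothing_sigma / gray$spacing
  v <- array(cpp_gauss_smooth(as.vector(v), dim(v), sigma_vox), dim(v))
  volume(v, spacing = gray$spacing, origin = gray$origin,
         direction = gray$direction)
}

#' Generate a synthetic skull-base phantom
#'
#' @param spec a [phantom_spec()].
#' @return List with `gray` ([volume()]) and `left`, `right` truth
#'   [labelmap()]s. Bitwise deterministic for a given spec + seed.
#' @export
make_phantom <- function(spec = phantom_spec()) {
  base <- phantom_clean(spec)
  with_seed(spec$seed, {
    base$gray <- phantom_finish(base$gray, spec)
  })
  base
}

#' Specification of a phantom cohort
#'
#' Mirrors the study design the toolkit targets: a pool of atlases plus a
#' held-out test set (default 20 + 10), each member a smooth random B-spline
#' deformation of a common base anatomy with fresh acquisition noise.
#'
#' @param n_atlases,n_tests cohort sizes (defaults 20 and 10).
#' @param def_grid_spacing control-grid spacing (mm) of the random
#'   deformations.
#' @param def_max_disp max control-point displacement (mm); must stay below
#'   `0.4 * def_grid_spacing` so deformations remain invertibility-safe.
#' @param seed cohort seed.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_atlases = 20L, n_tests = 10L,
                        def_grid_spacing = 10, def_max_disp = 3,
                        seed = 42L) {
  if (n_atlases < 1) stop("n_atlases must be >= 1", call. = FALSE)
  if (def_max_disp < 0 || def_max_disp >= 0.4 * def_grid_spacing)
    stop("def_max_disp must satisfy 0 <= max < 0.4 * grid spacing",
         call. = FALSE)
  structure(list(n_atlases = as.integer(n_atlases),
                 n_tests = as.integer(n_tests),
                 def_grid_spacing = def_grid_spacing,
                 def_max_disp = def_max_disp, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Random smooth B-spline deformation
#'
#' Control-point displacements drawn i.i.d. uniform in
#' `[-def_max_disp, def_max_disp]` on a grid covering the reference domain.
#'
#' @param cohort a [cohort_spec()] providing grid spacing and magnitude.
#' @param reference a [volume()] whose physical domain the grid must cover.
#' @param seed RNG seed (deterministic per seed).
#' @return A [bspline_transform()].
#' @export
random_deformation <- function(cohort, reference, seed) {
  g <- bspline_grid_for(reference, cohort$def_grid_spacing)
  with_seed(seed, {
    g$displacements <- array(
      stats::runif(prod(g$grid_shape) * 3, -cohort$def_max_disp,
                   cohort$def_max_disp),
      dim = c(g$grid_shape, 3L))
  })
  g
}

#' Generate a phantom cohort on disk
#'
#' Writes `n_atlases` atlas members and `n_tests` test members as NIfTI
#' files (`<role>_<nn>_gray.nii.gz`, `_label_left.nii.gz`,
#' `_label_right.nii.gz`) plus a `manifest.csv` listing ids, seeds and
#' deformation magnitudes. Each member is the base phantom warped by its own
#' random free-form deformation, with fresh noise. Members whose warped truth
#' labels are not single 6-connected components are regenerated with a new
#' derived seed (logged via `message()`).
#'
#' @param cohort a [cohort_spec()].
#' @param spec a [phantom_spec()] for the base anatomy.
#' @param out_dir output directory (created if needed).
#' @return The manifest data.frame, invisibly.
#' @export
make_cohort <- function(cohort = cohort_spec(), spec = phantom_spec(),
                        out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  base <- phantom_clean(spec)
  roles <- c(rep("atlas", cohort$n_atlases), rep("test", cohort$n_tests))
  nums <- c(seq_len(cohort$n_atlases), seq_len(cohort$n_tests))
  rows <- vector("list", length(roles))
  for (i in seq_along(roles)) {
    id <- sprintf("%s_%02d", roles[i], nums[i])
    mseed <- (cohort$seed %% 100000L) * 10000L + i
    member <- NULL
    for (try in 0:4) {
      s <- mseed + try * 97L
      ffd <- random_deformation(cohort, base$gray, seed = s)
      gray <- warp(base$gray, ffd, base$gray, interpolation = "linear")
      labL <- warp_label(base$left, ffd, base$gray)
      labR <- warp_label(base$right, ffd, base$gray)
      if (is_connected6(labL$voxels) && is_connected6(labR$voxels) &&
          sum(labL$voxels) >= 20 && sum(labR$voxels) >= 20) {
        member <- list(ffd = ffd, gray = gray, labL = labL, labR = labR,
                       seed = s)
        break
      }
      message("cohort member ", id,
              ": warped label not a single 6-connected component; ",
              "regenerating with a new derived seed")
    }
    if (is.null(member))
      stop("could not generate a valid cohort member for ", id, call. = FALSE)
    gray <- with_seed(member$seed + 1L, phantom_finish(member$gray, spec))
    files <- paste0(id, c("_gray.nii.gz", "_label_left.nii.gz",
                          "_label_right.nii.gz"))
    write_volume(gray, file.path(out_dir, files[1]))
    write_labelmap(member$labL, file.path(out_dir, files[2]))
    write_labelmap(member$labR, file.path(out_dir, files[3]))
    cpn <- sqrt(rowSums(matrix(member$ffd$displacements, ncol = 3)^2))
    rows[[i]] <- data.frame(id = id, role = roles[i], seed = member$seed,
                            mean_disp_mm = mean(cpn),
                            max_disp_mm = max(cpn),
                            gray = files[1], label_left = files[2],
                            label_right = files[3],
                            stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

# is the foreground of a binary array one 6-connected component?
is_connected6 <- function(mask) {
  mask <- mask == 1L
  n <- sum(mask)
  if (n == 0) return(TRUE)
  comp <- array(FALSE, dim(mask))
  comp[which(mask)[1]] <- TRUE
  repeat {
    grown <- dilate6(comp, 1L) & mask
    if (sum(grown) == sum(comp)) break
    comp <- grown
  }
  sum(comp) == n
}

#' Simulate independent raters from a ground-truth mask
#'
#' Each rater misses a true foreground voxel with probability `1 - p`
#' (sensitivity) and falsely marks a background voxel with probability
#' `1 - q` (specificity), independently per voxel and rater.
#'
#' @param truth a [labelmap()].
#' @param p,q sensitivity and specificity, in (0, 1].
#' @param R number of raters.
#' @param seed RNG seed.
#' @return A [decision_stack()] of R simulated segmentations.
#' @export
simulate_raters <- function(truth, p, q, R, seed = 1L) {
  stopifnot(inherits(truth, "labelmap"))
  if (p <= 0 || p > 1 || q <= 0 || q > 1)
    stop("'p' and 'q' must be in (0, 1]", call. = FALSE)
  if (R < 1) stop("'R' must be >= 1", call. = FALSE)
  t <- as.vector(truth$voxels) == 1L
  with_seed(seed, {
    labels <- lapply(seq_len(R), function(j) {
      u <- stats::runif(length(t))
      v <- ifelse(t, u <= p, u > q) * 1L
      labelmap(array(v, dim(truth$voxels)), like = truth)
    })
    decision_stack(labels)
  })
}
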