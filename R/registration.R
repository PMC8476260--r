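#' Registration configuration and presets
#'
#' The `"paper"` preset follows the published parameterization of the
#' pipeline: a factor-2 Gaussian pyramid, 2000 random metric samples per
#' iteration, gradient ascent on sampled NMI, 4 affine levels x 1000
#' iterations, 5 B-spline levels x 3000 iterations with a 5 mm finest control
#' grid. The `"desk"` preset (default) keeps the same structure at a size
#' that registers a 64^3 volume in seconds: 2 affine levels x 100 iterations
#' and 3 B-spline levels x 200 iterations.
#'
#' @param preset `"desk"` or `"paper"`.
#' @param affine_levels,affine_iters_per_level affine pyramid schedule.
#' @param bspline_levels,bspline_iters_per_level FFD pyramid schedule.
#' @param grid_spacing_mm finest control-point spacing in mm (coarser levels
#'   double it per level).
#' @param pyramid_factor integer downsampling factor between levels.
#' @param metric_samples random voxels drawn per iteration for the NMI metric.
#' @param histogram_bins joint-histogram bins per image.
#' @param step_a,step_A,step_alpha gradient-ascent step schedule
#'   `a / (A + t)^alpha` (mm-scale step lengths).
#' @param grad_subset number of control-point components per iteration in the
#'   FFD finite-difference gradient; 0 (default) differentiates every
#'   component with support among the iteration's samples.
#' @param fd_eps_voxels finite-difference perturbation, as a fraction of the
#'   current level's voxel size (binned intensities make the sampled metric
#'   piecewise constant, so the perturbation must be large enough to move
#'   samples across bins).
#' @param rng_seed seed controlling the stochastic sampling; registrations
#'   are bit-reproducible for a fixed seed.
#' @return A list of class `registration_config`.
#' @export
registration_config <- function(preset = c("desk", "paper"),
                                affine_levels = NULL,
                                affine_iters_per_level = NULL,
                                bspline_levels = NULL,
                                bspline_iters_per_level = NULL,
                                grid_spacing_mm = 5,
                                pyramid_factor = 2L,
                                metric_samples = 2000L,
                                histogram_bins = 32L,
                                step_a = 1.0, step_A = 50, step_alpha = 0.602,
                                grad_subset = 0L, fd_eps_voxels = 0.5,
                                rng_seed = 1L) {
  preset <- match.arg(preset)
  def <- if (preset == "paper")
    list(al = 4L, ai = 1000L, bl = 5L, bi = 3000L)
  else
    list(al = 2L, ai = 100L, bl = 3L, bi = 200L)
  cfg <- list(preset = preset,
              affine_levels = as.integer(affine_levels %||% def$al),
              affine_iters_per_level = as.integer(affine_iters_per_level %||% def$ai),
              bspline_levels = as.integer(bspline_levels %||% def$bl),
              bspline_iters_per_level = as.integer(bspline_iters_per_level %||% def$bi),
              grid_spacing_mm = grid_spacing_mm,
              pyramid_factor = as.integer(pyramid_factor),
              metric_samples = as.integer(metric_samples),
              histogram_bins = as.integer(histogram_bins),
              step_a = step_a, step_A = step_A, step_alpha = step_alpha,
              grad_subset = as.integer(grad_subset),
              fd_eps_voxels = fd_eps_voxels,
              rng_seed = as.integer(rng_seed))
  counts <- unlist(cfg[c("affine_levels", "affine_iters_per_level",
                         "bspline_levels", "bspline_iters_per_level",
                         "pyramid_factor", "metric_samples",
                         "histogram_bins")])
  if (any(counts < 1)) stop("all counts must be >= 1", call. = FALSE)
  if (grid_spacing_mm <= 0) stop("grid_spacing_mm must be > 0", call. = FALSE)
  class(cfg) <- "registration_config"
  cfg
}

domain_center <- function(vol) {
  as.numeric(voxel_to_world(vol, (dim(vol$voxels) - 1) / 2))
}

#' Multiresolution affine registration
#'
#' Coarse-to-fine stochastic gradient ascent on sampled normalized mutual
#' information: at each pyramid level a fresh random voxel sample is drawn
#' every iteration, the metric gradient is taken by central finite differences
#' on the 12 affine parameters, and a normalized step of decaying length
#' `a/(A+t)^alpha` is applied. Deterministic for a fixed `rng_seed`.
#'
#' @param fixed,moving `volume`s (fixed = the image to be segmented).
#' @param cfg a [registration_config()].
#' @return An `affine_transform` mapping fixed to moving physical points, with
#'   the per-level metric trajectory in `attr(, "trace")`.
#' @export
register_affine <- function(fixed, moving, cfg = registration_config()) {
  stopifnot(inherits(fixed, "volume"), inherits(moving, "volume"))
  center <- domain_center(fixed)
  with_seed(cfg$rng_seed, {
    suppressWarnings({
      pf <- gaussian_pyramid(fixed, cfg$affine_levels, cfg$pyramid_factor)
      pm <- gaussian_pyramid(moving, cfg$affine_levels, cfg$pyramid_factor)
    })
    nl <- min(length(pf), length(pm))
    pf <- pf[seq_len(nl)]; pm <- pm[seq_len(nl)]
    theta <- c(as.vector(diag(3)), 0, 0, 0)
    trace <- list()
    radius <- mean((dim(fixed$voxels) - 1) * fixed$spacing) / 2
    for (L in seq_len(nl)) {
      f <- pf[[L]]; m <- pm[[L]]
      fiw <- index_to_world_map(f)
      mwi <- world_to_index_map(m)
      eps_t <- cfg$fd_eps_voxels * mean(f$spacing)
      eps <- c(rep(eps_t / radius, 9), rep(eps_t, 3))
      scales <- c(rep(1 / radius, 9), rep(1, 3))
      res <- cpp_register_affine_level(
        as.vector(f$voxels), dim(f$voxels), as.vector(m$voxels),
        dim(m$voxels), fiw$M, fiw$o, mwi$M, mwi$o, center, theta,
        cfg$affine_iters_per_level, cfg$metric_samples, cfg$histogram_bins,
        min(f$voxels), max(f$voxels), min(m$voxels), max(m$voxels),
        cfg$step_a, cfg$step_A, cfg$step_alpha, eps, scales)
      theta <- res$theta
      if (any(!is.finite(theta)))
        stop("affine optimization diverged (non-finite parameters) at level ",
             L, call. = FALSE)
      trace[[L]] <- data.frame(level = L,
                               iter = seq_along(res$trace),
                               nmi = as.numeric(res$trace))
    }
    out <- affine_transform(matrix(theta[1:9], 3, 3), theta[10:12], center)
    attr(out, "trace") <- do.call(rbind, trace)
    out
  })
}

#' Multiresolution B-spline free-form deformation registration
#'
#' Optimizes the displacements of a cubic B-spline control grid composed
#' after an affine initialization (`T(x) = A(x) + D(x)`), coarse to fine:
#' the control-point spacing starts at `grid_spacing_mm * 2^(levels-1)` and
#' halves per level down to `grid_spacing_mm`, while the images move up the
#' Gaussian pyramid. The metric gradient is taken by central finite
#' differences on a random subset of control-point components per iteration
#' (each perturbation only touches the metric samples inside that control
#' point's 4x4x4 support).
#'
#' @param fixed,moving `volume`s.
#' @param init affine initialization (e.g. from [register_affine()]).
#' @param cfg a [registration_config()].
#' @return A `bspline_transform` (finest grid), with the metric trajectory in
#'   `attr(, "trace")`.
#' @export
register_bspline <- function(fixed, moving, init = affine_transform(),
                             cfg = registration_config()) {
  stopifnot(inherits(fixed, "volume"), inherits(moving, "volume"),
            inherits(init, "affine_transform"))
  with_seed(cfg$rng_seed + 1L, {
    suppressWarnings({
      pf <- gaussian_pyramid(fixed, cfg$bspline_levels, cfg$pyramid_factor)
      pm <- gaussian_pyramid(moving, cfg$bspline_levels, cfg$pyramid_factor)
    })
    nl <- min(length(pf), length(pm))
    pf <- pf[seq_len(nl)]; pm <- pm[seq_len(nl)]
    theta <- c(as.vector(init$matrix), init$translation)
    grid <- NULL
    trace <- list()
    for (L in seq_len(nl)) {
      spacing_mm <- cfg$grid_spacing_mm * 2^(nl - L)
      newgrid <- bspline_grid_for(fixed, spacing_mm)
      if (!is.null(grid)) {
        # initialize the refined grid from the coarse field (evaluation-based)
        cp <- grid_indices(newgrid$grid_shape)
        aligned <- sweep(cp %*% diag(newgrid$grid_spacing, 3), 2,
                         newgrid$grid_origin, `+`)
        d <- cpp_bspline_disp(as.vector(grid$displacements), grid$grid_shape,
                              grid$grid_origin, grid$grid_spacing, aligned)$disp
        newgrid$displacements <- array(d, dim = c(newgrid$grid_shape, 3L))
      }
      grid <- newgrid
      f <- pf[[L]]; m <- pm[[L]]
      fiw <- index_to_world_map(f)
      mwi <- world_to_index_map(m)
      res <- cpp_register_bspline_level(
        as.vector(f$voxels), dim(f$voxels), f$spacing,
        as.vector(m$voxels), dim(m$voxels),
        fiw$M, fiw$o, mwi$M, mwi$o,
        theta, init$center, mwi$M %*% fixed$direction,
        grid$grid_origin, grid$grid_spacing, grid$grid_shape,
        as.vector(grid$displacements),
        cfg$bspline_iters_per_level, cfg$metric_samples, cfg$grad_subset,
        cfg$histogram_bins,
        min(f$voxels), max(f$voxels), min(m$voxels), max(m$voxels),
        cfg$step_a, cfg$step_A, cfg$step_alpha,
        cfg$fd_eps_voxels * mean(f$spacing))
      if (any(!is.finite(res$disp)))
        stop("B-spline optimization diverged (non-finite displacements) ",
             "at level ", L, call. = FALSE)
      grid$displacements <- array(res$disp, dim = c(grid$grid_shape, 3L))
      trace[[L]] <- data.frame(level = L, iter = seq_along(res$trace),
                               nmi = as.numeric(res$trace))
    }
    attr(grid, "trace") <- do.call(rbind, trace)
    grid
  })
}

#' Warp a volume through a transform chain
#'
#' Produces the volume on `reference`'s grid: each reference voxel is mapped
#' through the chain into the input volume's space and interpolated there.
#' Gray volumes default to cubic B-spline interpolation (the final-result
#' convention); use linear inside optimization loops.
#'
#' @param vol the volume to warp (the moving/atlas image).
#' @param chain transform or [transform_chain()] mapping reference (fixed)
#'   points to `vol`'s (moving) points.
#' @param reference [volume()] supplying the output grid.
#' @param interpolation `"nearest"`, `"linear"` or `"cubic-bspline"`.
#' @param background out-of-domain fill (defaults as in
#'   [resample_to_reference()]).
#' @return A [volume()] on the reference grid.
#' @export
warp <- function(vol, chain, reference, interpolation = "cubic-bspline",
                 background = NULL) {
  stopifnot(inherits(vol, "volume"), inherits(reference, "volume"))
  if (inherits(chain, c("affine_transform", "bspline_transform")))
    chain <- transform_chain(chain)
  if (is.null(background))
    background <- if (inherits(vol, "labelmap")) 0 else min(vol$voxels)
  pts <- voxel_to_world(reference, grid_indices(dim(reference$voxels)))
  mapped <- apply_transform(chain, pts)
  res <- interp_at(vol, world_to_voxel(vol, mapped), interpolation,
                   background)
  arr <- array(res$values, dim = dim(reference$voxels))
  if (inherits(vol, "labelmap") && interpolation == "nearest")
    labelmap(arr, like = reference)
  else
    volume(arr, spacing = reference$spacing, origin = reference$origin,
           direction = reference$direction)
}

#' Propagate a binary label map through a transform chain
#'
#' Nearest-neighbor interpolation; the output is binary on the reference grid.
#'
#' @inheritParams warp
#' @param label a [labelmap()].
#' @return A [labelmap()] on the reference grid.
#' @export
warp_label <- function(label, chain, reference) {
  stopifnot(inherits(label, "labelmap"))
  warp(label, chain, reference, interpolation = "nearest", background = 0)
}
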