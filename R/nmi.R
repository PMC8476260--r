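#' Sampled normalized mutual information
#'
#' Studholme's normalized form \eqn{(H_1 + H_2)/H_{12}} of the joint intensity
#' histogram: voxels of the fixed grid are drawn uniformly at random, mapped
#' through the transform chain, the moving image is interpolated linearly at
#' the mapped points, and a `bins` x `bins` joint histogram is built from
#' min-max scaled intensities (per image, full-volume range). Identical images
#' under the identity give 2; independent images approach 1.
#'
#' @param fixed,moving `volume`s.
#' @param chain a [transform_chain()] (or single transform) mapping fixed to
#'   moving physical points; `NULL` for the identity.
#' @param samples number of random fixed-grid voxels; `Inf` (or anything not
#'   smaller than the voxel count) uses every voxel.
#' @param bins histogram bins per image (default 32).
#' @param seed optional RNG seed for the voxel sample.
#' @return A single numeric score (ranges over about `[1, 2]`).
#' @export
nmi <- function(fixed, moving, chain = NULL, samples = 2000, bins = 32,
                seed = NULL) {
  stopifnot(inherits(fixed, "volume"), inherits(moving, "volume"))
  if (samples < bins) stop("'samples' must be >= 'bins'", call. = FALSE)
  n <- length(fixed$voxels)
  with_seed(seed, {
    if (!is.finite(samples) || samples >= n) {
      pick <- seq_len(n)
    } else {
      pick <- sample.int(n, samples, replace = TRUE)
    }
    idx <- arrayInd(pick, dim(fixed$voxels)) - 1L
    fv <- fixed$voxels[pick]
    pts <- voxel_to_world(fixed, idx)
    if (!is.null(chain)) pts <- apply_transform(chain, pts)
    res <- interp_at(moving, world_to_voxel(moving, pts), "linear", NA)
    keep <- res$indomain
    if (mean(keep) < 0.5)
      stop("insufficient overlap: fewer than 50% of metric samples map ",
           "inside the moving image", call. = FALSE)
    fb <- intensity_bin(fv[keep], range(fixed$voxels), bins)
    mb <- intensity_bin(res$values[keep], range(moving$voxels), bins)
    joint <- tabulate(fb * bins + mb + 1L, nbins = bins * bins)
    Hj <- entropy_counts(joint)
    Hf <- entropy_counts(tabulate(fb + 1L, nbins = bins))
    Hm <- entropy_counts(tabulate(mb + 1L, nbins = bins))
    if (Hj <= 1e-12) 2 else (Hf + Hm) / Hj
  })
}

intensity_bin <- function(v, rng, bins) {
  if (diff(rng) <= 0) return(rep(0L, length(v)))
  pmin(pmax(as.integer(floor((v - rng[1]) / diff(rng) * bins)), 0L),
       bins - 1L)
}

entropy_counts <- function(counts) {
  n <- sum(counts)
  p <- counts[counts > 0] / n
  -sum(p * log(p))
}
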