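#' Gaussian image pyramid (coarse to fine)
#'
#' Each coarser level is produced by Gaussian anti-alias smoothing
#' (sigma = factor/2 voxels) followed by decimation by `factor`; spacing is
#' scaled so the physical extent is preserved within one voxel. Levels whose
#' coarsest axis would fall below 4 voxels are dropped with a warning.
#'
#' @param vol a [volume()].
#' @param levels number of levels requested (>= 1).
#' @param factor integer downsampling factor per level (default 2).
#' @return List of volumes, coarsest first, finest (= `vol`) last.
#' @export
gaussian_pyramid <- function(vol, levels, factor = 2L) {
  stopifnot(inherits(vol, "volume"), levels >= 1, factor >= 2)
  feasible <- 1L + max(0L, floor(log(min(dim(vol$voxels)) / 4) / log(factor)))
  if (levels > feasible) {
    warning("pyramid clamped to ", feasible,
            " level(s); coarser levels would go below 4 voxels per axis",
            call. = FALSE)
    levels <- feasible
  }
  out <- vector("list", levels)
  out[[levels]] <- vol
  cur <- vol
  if (levels > 1) for (L in (levels - 1):1) {
    sm <- cpp_gauss_smooth(as.vector(cur$voxels), dim(cur$voxels),
                           rep(factor / 2, 3))
    sm <- array(sm, dim = dim(cur$voxels))
    keep <- lapply(dim(sm), function(n) seq(1L, n, by = factor))
    dec <- sm[keep[[1]], keep[[2]], keep[[3]], drop = FALSE]
    cur <- volume(dec, spacing = cur$spacing * factor, origin = cur$origin,
                  direction = cur$direction)
    out[[L]] <- cur
  }
  out
}
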