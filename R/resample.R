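interp_code <- function(interpolation) {
  switch(interpolation,
         nearest = 0L, linear = 1L, `cubic-bspline` = 3L,
         stop("unknown interpolation '", interpolation,
              "' (expected nearest, linear or cubic-bspline)", call. = FALSE))
}

# Interpolate a volume at continuous 0-based voxel indices (n x 3).
# For cubic-bspline the array is prefiltered so that the reconstruction
# interpolates the original samples exactly.
interp_at <- function(vol, idx, interpolation = "linear", background = 0) {
  code <- interp_code(interpolation)
  arr <- vol$voxels
  storage.mode(arr) <- "double"
  if (code == 3L) arr <- cpp_bspline_prefilter(arr, dim(vol$voxels))
  cpp_interp(as.vector(arr), dim(vol$voxels), rbind3(idx), code,
             as.double(background))
}

#' Resample a volume onto a reference grid
#'
#' Sampling is done in physical space: every voxel center of `ref` is mapped
#' to world coordinates and the input volume is interpolated there. Points
#' falling outside the input's domain are filled with `background`.
#'
#' @param vol input [volume()] or [labelmap()].
#' @param ref reference [volume()] supplying the output grid.
#' @param interpolation one of `"nearest"`, `"linear"`, `"cubic-bspline"`.
#' @param background fill value for out-of-domain voxels. Defaults to the
#'   input's minimum intensity for gray volumes and 0 for label maps.
#' @return A [volume()] on `ref`'s grid (a [labelmap()] when the input is a
#'   label map and interpolation is nearest-neighbor).
#' @export
resample_to_reference <- function(vol, ref, interpolation = "linear",
                                  background = NULL) {
  stopifnot(inherits(vol, "volume"), inherits(ref, "volume"))
  is_label <- inherits(vol, "labelmap")
  if (is.null(background))
    background <- if (is_label) 0 else min(vol$voxels)
  pts <- voxel_to_world(ref, grid_indices(dim(ref$voxels)))
  idx <- world_to_voxel(vol, pts)
  res <- interp_at(vol, idx, interpolation, background)
  arr <- array(res$values, dim = dim(ref$voxels))
  if (is_label && interpolation == "nearest")
    labelmap(arr, like = ref)
  else
    volume(arr, spacing = ref$spacing, origin = ref$origin,
           direction = ref$direction)
}

# Resample onto the reference grid, additionally returning which reference
# voxels were inside the input's domain (used by atlas selection).
resample_with_mask <- function(vol, ref, interpolation = "linear",
                               background = NULL) {
  if (is.null(background))
    background <- if (inherits(vol, "labelmap")) 0 else min(vol$voxels)
  pts <- voxel_to_world(ref, grid_indices(dim(ref$voxels)))
  idx <- world_to_voxel(vol, pts)
  res <- interp_at(vol, idx, interpolation, background)
  list(vol = volume(array(res$values, dim = dim(ref$voxels)),
                    spacing = ref$spacing, origin = ref$origin,
                    direction = ref$direction),
       indomain = array(res$indomain, dim = dim(ref$voxels)))
}
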