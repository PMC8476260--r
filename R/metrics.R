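#' Dice overlap coefficient
#'
#' \eqn{\mathrm{Dice}(A,B) = 2|A \cap B| / (|A| + |B|)} by voxel counts, in
#' `[0, 1]`. Two empty masks are defined as Dice 1 (identical emptiness),
#' with a warning.
#'
#' @param A,B [labelmap()]s on the same grid.
#' @param warn warn when both masks are empty.
#' @return A single numeric value in `[0, 1]`.
#' @export
dice <- function(A, B, warn = TRUE) {
  stopifnot(inherits(A, "labelmap"), inherits(B, "labelmap"))
  if (!same_geometry(A, B))
    stop("dice requires masks on the same grid", call. = FALSE)
  na <- sum(A$voxels)
  nb <- sum(B$voxels)
  if (na + nb == 0) {
    if (warn) warning("both masks are empty; Dice defined as 1", call. = FALSE)
    return(1)
  }
  2 * sum(A$voxels & B$voxels) / (na + nb)
}

#' Extract the surface voxels of a mask
#'
#' A foreground voxel belongs to the surface iff at least one of its six
#' face-adjacent neighbors is background or outside the volume.
#'
#' @param mask a non-empty [labelmap()].
#' @return An n x 3 matrix of surface voxel centers in physical mm
#'   (class `surface_set`).
#' @export
extract_surface <- function(mask) {
  stopifnot(inherits(mask, "labelmap"))
  m <- mask$voxels == 1L
  if (!any(m)) stop("cannot extract the surface of an empty mask",
                    call. = FALSE)
  d <- dim(m)
  # a voxel is interior iff all six face neighbors are foreground
  interior <- array(TRUE, d)
  shift_and <- function(interior, ax, dir) {
    pad <- array(FALSE, d)
    idx_to <- lapply(d, seq_len)
    idx_from <- idx_to
    if (dir > 0) { idx_to[[ax]] <- 1:(d[ax] - 1); idx_from[[ax]] <- 2:d[ax] }
    else { idx_to[[ax]] <- 2:d[ax]; idx_from[[ax]] <- 1:(d[ax] - 1) }
    pad[idx_to[[1]], idx_to[[2]], idx_to[[3]]] <-
      m[idx_from[[1]], idx_from[[2]], idx_from[[3]]]
    interior & pad
  }
  for (ax in 1:3) for (dir in c(-1, 1))
    interior <- shift_and(interior, ax, dir)
  surf <- m & !interior
  idx <- which(surf, arr.ind = TRUE) - 1L
  pts <- voxel_to_world(mask, idx)
  structure(pts, class = c("surface_set", class(pts)))
}

as_surface <- function(x) {
  if (inherits(x, "labelmap")) extract_surface(x)
  else rbind3(unclass(x))
}

#' Hausdorff distance between two surfaces
#'
#' \eqn{H(A,B) = \max(h(A,B), h(B,A))} with
#' \eqn{h(A,B) = \max_{a \in A} \min_{b \in B} \lVert a-b \rVert}, Euclidean
#' in mm between voxel centers.
#'
#' @param A,B `surface_set`s (or [labelmap()]s, whose surfaces are
#'   extracted first).
#' @return Distance in mm.
#' @export
hausdorff <- function(A, B) {
  a <- as_surface(A)
  b <- as_surface(B)
  if (!nrow(a) || !nrow(b)) stop("empty surface set", call. = FALSE)
  max(max(cpp_min_dists(a, b)), max(cpp_min_dists(b, a)))
}

#' 95% Hausdorff distance
#'
#' The 95th percentile (linear-interpolation percentile definition,
#' [stats::quantile()] type 7) of the pooled nearest-neighbor surface
#' distances of both directions — a robust variant of [hausdorff()]. Set
#' `pooled = FALSE` for the max of the two per-direction 95th percentiles.
#'
#' @inheritParams hausdorff
#' @param pooled pool both directions before taking the percentile (default).
#' @return Distance in mm; never exceeds the exact Hausdorff distance.
#' @export
hd95 <- function(A, B, pooled = TRUE) {
  a <- as_surface(A)
  b <- as_surface(B)
  if (!nrow(a) || !nrow(b)) stop("empty surface set", call. = FALSE)
  dab <- cpp_min_dists(a, b)
  dba <- cpp_min_dists(b, a)
  if (pooled)
    unname(stats::quantile(c(dab, dba), 0.95, type = 7))
  else
    max(stats::quantile(dab, 0.95, type = 7),
        stats::quantile(dba, 0.95, type = 7))
}

#' Average symmetric surface distance
#'
#' \deqn{\mathrm{ASD} = \frac{1}{|S(A)|+|S(B)|}\Big(\sum_{a \in S(A)}
#'   \min_b \lVert a-b \rVert + \sum_{b \in S(B)} \min_a \lVert b-a
#'   \rVert\Big)} in mm.
#'
#' @inheritParams hausdorff
#' @return Distance in mm.
#' @export
asd <- function(A, B) {
  a <- as_surface(A)
  b <- as_surface(B)
  if (!nrow(a) || !nrow(b)) stop("empty surface set", call. = FALSE)
  (sum(cpp_min_dists(a, b)) + sum(cpp_min_dists(b, a))) / (nrow(a) + nrow(b))
}

#' Evaluate a predicted segmentation against a reference
#'
#' @param pred,truth [labelmap()]s on the same grid.
#' @return A one-row data.frame with `dice`, `hd95_mm`, `asd_mm`, and an
#'   `empty_prediction` flag; the distance metrics are `NA` when exactly one
#'   of the masks is empty.
#' @export
evaluate <- function(pred, truth) {
  stopifnot(inherits(pred, "labelmap"), inherits(truth, "labelmap"))
  if (!same_geometry(pred, truth))
    stop("prediction and truth must share the same grid", call. = FALSE)
  np <- sum(pred$voxels)
  nt <- sum(truth$voxels)
  d <- dice(pred, truth, warn = FALSE)
  if (np == 0 || nt == 0) {
    data.frame(dice = if (np + nt == 0) 1 else 0, hd95_mm = NA_real_,
               asd_mm = NA_real_, empty_prediction = np == 0)
  } else {
    data.frame(dice = d, hd95_mm = hd95(pred, truth),
               asd_mm = asd(pred, truth), empty_prediction = FALSE)
  }
}
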