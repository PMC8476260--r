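#' Normalized cross-correlation between two volumes on a common grid
#'
#' The mean-centered, variance-normalized correlation
#' \deqn{\mathrm{NCC} = \frac{\sum_i (T_i - \bar T)(F_i - \bar F)}
#'   {\sqrt{\sum_i (T_i - \bar T)^2}\sqrt{\sum_i (F_i - \bar F)^2}}}
#' over the \eqn{n} compared voxels, bounded in \eqn{[-1, 1]} and invariant to
#' positive affine intensity changes — which makes it robust to nonstandard
#' intensity scales between scanners and hence suitable as an atlas-selection
#' criterion.
#'
#' @param fixed,moving `volume`s already resampled to a common grid.
#' @param mask optional logical array restricting the comparison (e.g. to the
#'   voxels inside both image domains).
#' @return A single numeric score in `[-1, 1]`.
#' @export
ncc <- function(fixed, moving, mask = NULL) {
  stopifnot(inherits(fixed, "volume"), inherits(moving, "volume"))
  if (!all(dim(fixed$voxels) == dim(moving$voxels)))
    stop("ncc requires volumes on a common grid (resample first)",
         call. = FALSE)
  a <- as.vector(fixed$voxels)
  b <- as.vector(moving$voxels)
  if (!is.null(mask)) {
    keep <- as.vector(mask)
    a <- a[keep]
    b <- b[keep]
  }
  if (length(a) < 2L)
    stop("ncc needs at least 2 compared voxels", call. = FALSE)
  a <- a - mean(a)
  b <- b - mean(b)
  da <- sqrt(sum(a^2))
  db <- sqrt(sum(b^2))
  if (da == 0 || db == 0)
    stop("ncc is undefined for a constant image (zero variance)",
         call. = FALSE)
  max(-1, min(1, sum(a * b) / (da * db)))
}

#' Rank atlases by similarity to the fixed image
#'
#' Each atlas gray image is resampled directly onto the fixed grid (identity
#' alignment, linear interpolation) and scored by [ncc()] over the voxels
#' inside both image domains; atlases are returned in descending score order,
#' ties broken by atlas id.
#'
#' @param fixed the target [volume()].
#' @param atlases list of [atlas()] objects.
#' @return A data.frame with columns `atlas_id`, `ncc`, in rank order.
#' @export
rank_atlases <- function(fixed, atlases) {
  if (!length(atlases)) stop("empty atlas list", call. = FALSE)
  ids <- vapply(atlases, function(a) a$id, character(1))
  scores <- vapply(atlases, function(a) {
    r <- resample_with_mask(a$gray, fixed, "linear")
    ncc(fixed, r$vol, mask = r$indomain)
  }, numeric(1))
  ord <- order(-scores, ids)
  data.frame(atlas_id = ids[ord], ncc = scores[ord],
             stringsAsFactors = FALSE)
}

#' Select the top-k ranked atlases
#'
#' @param ranked data.frame from [rank_atlases()].
#' @param k number of atlases to keep (default 10). When fewer are available,
#'   all are kept with a warning.
#' @return Character vector of atlas ids, best first.
#' @export
select_top_k <- function(ranked, k = 10) {
  if (!is.numeric(k) || length(k) != 1L || k < 1)
    stop("'k' must be a count >= 1", call. = FALSE)
  if (k > nrow(ranked))
    warning("requested k = ", k, " but only ", nrow(ranked),
            " atlases are available; keeping all", call. = FALSE)
  ranked$atlas_id[seq_len(min(k, nrow(ranked)))]
}
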