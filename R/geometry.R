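#' 3-D scalar volume with physical geometry
#'
#' A `volume` is a 3-D numeric array plus the physical metadata needed to place
#' every voxel in space: per-axis spacing (mm), the world position of voxel
#' `(0,0,0)` (mm), and a 3x3 orthonormal direction-cosine matrix. The world
#' position of 0-based voxel index `i` is
#' `origin + direction %*% (spacing * i)`; all distances in this package are
#' computed in physical millimetres.
#'
#' @param voxels 3-D numeric array of intensities (CT-like, arbitrary units).
#' @param spacing numeric length-3, mm per voxel along each axis; must be
#'   strictly positive.
#' @param origin numeric length-3, world coordinates (mm) of voxel (0,0,0).
#' @param direction 3x3 orthonormal direction-cosine matrix
#'   (`abs(det) == 1` within 1e-6).
#' @return An object of class `volume`.
#' @export
volume <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                   direction = diag(3)) {
  voxels <- as.array(voxels)
  if (length(dim(voxels)) != 3L || length(voxels) == 0L)
    stop("'voxels' must be a non-empty 3-D array", call. = FALSE)
  voxels <- array(as.double(voxels), dim = dim(voxels))  # strip foreign attrs
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  direction <- as.matrix(direction)
  check_geometry(spacing, origin, direction)
  structure(list(voxels = voxels, spacing = spacing, origin = origin,
                 direction = direction),
            class = "volume")
}

check_geometry <- function(spacing, origin, direction) {
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must be 3 strictly positive finite values (mm)",
         call. = FALSE)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("'origin' must be 3 finite values (mm)", call. = FALSE)
  if (!all(dim(direction) == c(3L, 3L)) ||
      max(abs(crossprod(direction) - diag(3))) > 1e-6 ||
      abs(abs(det(direction)) - 1) > 1e-6)
    stop("'direction' must be a 3x3 orthonormal matrix", call. = FALSE)
  invisible(TRUE)
}

#' Binary label map sharing a volume's geometry
#'
#' @param voxels 3-D array with values restricted to {0, 1}.
#' @param spacing,origin,direction geometry, as for [volume()]. Ignored when
#'   `like` is supplied.
#' @param like optional `volume` (or `labelmap`) whose geometry is copied.
#' @return An object of class `labelmap` (which also inherits the geometry
#'   contract of `volume`).
#' @export
labelmap <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                     direction = diag(3), like = NULL) {
  voxels <- as.array(voxels)
  if (length(dim(voxels)) != 3L || length(voxels) == 0L)
    stop("'voxels' must be a non-empty 3-D array", call. = FALSE)
  bad <- unique(voxels[!(voxels %in% c(0, 1))])
  if (length(bad))
    stop("label values must be 0 or 1; found: ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  voxels <- array(as.integer(voxels), dim = dim(voxels))  # strip foreign attrs
  if (!is.null(like)) {
    spacing <- like$spacing
    origin <- like$origin
    direction <- like$direction
    if (!all(dim(voxels) == dim(like$voxels)))
      stop("label array shape must match the reference volume", call. = FALSE)
  }
  check_geometry(spacing, origin, as.matrix(direction))
  structure(list(voxels = voxels, spacing = as.numeric(spacing),
                 origin = as.numeric(origin),
                 direction = as.matrix(direction)),
            class = c("labelmap", "volume"))
}

#' Paired gray volume and expert label map
#'
#' @param id character atlas identifier.
#' @param gray a `volume`.
#' @param label a `labelmap` with geometry and shape identical to `gray`.
#' @return An object of class `atlas`.
#' @export
atlas <- function(id, gray, label) {
  stopifnot(is.character(id), length(id) == 1L)
  if (!inherits(gray, "volume")) stop("'gray' must be a volume", call. = FALSE)
  if (!inherits(label, "labelmap")) stop("'label' must be a labelmap", call. = FALSE)
  if (!same_geometry(gray, label) || !all(dim(gray$voxels) == dim(label$voxels)))
    stop("atlas gray and label must share identical geometry and shape",
         call. = FALSE)
  structure(list(id = id, gray = gray, label = label), class = "atlas")
}

#' Do two images share the same grid?
#'
#' @param a,b `volume` objects.
#' @param tol absolute tolerance (mm) on geometry fields.
#' @return `TRUE` if shapes match and geometry agrees within `tol`.
#' @export
same_geometry <- function(a, b, tol = 1e-6) {
  all(dim(a$voxels) == dim(b$voxels)) &&
    max(abs(a$spacing - b$spacing)) <= tol &&
    max(abs(a$origin - b$origin)) <= tol &&
    max(abs(a$direction - b$direction)) <= tol
}

#' Map 0-based voxel indices to world coordinates (mm)
#'
#' @param x a `volume`.
#' @param idx n x 3 matrix (or length-3 vector) of 0-based, possibly
#'   fractional, voxel indices.
#' @return n x 3 matrix of world coordinates in mm.
#' @export
voxel_to_world <- function(x, idx) {
  idx <- rbind3(idx)
  sweep(idx %*% (t(x$direction) * x$spacing), 2, x$origin, `+`)
}

#' Map world coordinates (mm) to continuous 0-based voxel indices
#'
#' @param x a `volume`.
#' @param pts n x 3 matrix (or length-3 vector) of world coordinates in mm.
#' @return n x 3 matrix of continuous voxel indices.
#' @export
world_to_voxel <- function(x, pts) {
  pts <- rbind3(pts)
  sweep(sweep(pts, 2, x$origin, `-`) %*% x$direction, 2, x$spacing, `/`)
}

rbind3 <- function(p) {
  if (is.null(dim(p))) p <- matrix(p, ncol = 3L)
  storage.mode(p) <- "double"
  p
}

# index -> world as matrix/offset pair (used by the compiled optimizers)
index_to_world_map <- function(x) {
  list(M = x$direction %*% diag(x$spacing, 3L), o = x$origin)
}

# world -> index
world_to_index_map <- function(x) {
  Minv <- diag(1 / x$spacing, 3L) %*% t(x$direction)
  list(M = Minv, o = as.numeric(-Minv %*% x$origin))
}

# all voxel centers of a grid as 0-based index triplets (n x 3)
grid_indices <- function(d) {
  as.matrix(expand.grid(x = 0:(d[1] - 1), y = 0:(d[2] - 1), z = 0:(d[3] - 1),
                        KEEP.OUT.ATTRS = FALSE))
}

#' @export
print.volume <- function(x, ...) {
  cat(sprintf("<%s> %s voxels, spacing %s mm, origin (%s) mm\n",
              class(x)[1], paste(dim(x$voxels), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              paste(signif(x$origin, 4), collapse = ", ")))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' @export
print.atlas <- function(x, ...) {
  cat(sprintf("<atlas '%s'> %s voxels, %d foreground label voxels\n", x$id,
              paste(dim(x$gray$voxels), collapse = "x"), sum(x$label$voxels)))
  invisible(x)
}
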