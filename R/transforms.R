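#' Affine spatial transform
#'
#' Maps fixed-image physical points to moving-image physical points
#' (resampling convention): `y = M (x - c) + c + t`.
#'
#' @param matrix 3x3 invertible linear part.
#' @param translation length-3 translation in mm.
#' @param center length-3 rotation center in mm.
#' @return An object of class `affine_transform`.
#' @export
affine_transform <- function(matrix = diag(3), translation = c(0, 0, 0),
                             center = c(0, 0, 0)) {
  matrix <- as.matrix(matrix)
  stopifnot(all(dim(matrix) == c(3L, 3L)))
  if (abs(det(matrix)) <= 1e-9)
    stop("affine matrix must be invertible", call. = FALSE)
  structure(list(matrix = matrix, translation = as.numeric(translation),
                 center = as.numeric(center)),
            class = "affine_transform")
}

#' Cubic B-spline free-form deformation
#'
#' A displacement field parameterized by a regular control-point grid. The
#' grid lives in the fixed image's axis-aligned frame (coordinates
#' `t(direction) %*% (x - frame_origin)`); the displacement at a point is the
#' tensor-product sum over the 4x4x4 nearest control points with the uniform
#' cubic B-spline weights of [bspline_basis()].
#'
#' @param grid_origin length-3, mm position of control point (0,0,0) in the
#'   aligned frame.
#' @param grid_spacing length-3, control-point spacing in mm (must be > 0).
#' @param grid_shape length-3 integer control-point counts (>= 4 each).
#' @param displacements array of dim `c(grid_shape, 3)` of mm displacement
#'   vectors, or `NULL` for the identity.
#' @param frame_origin,frame_direction anchor of the aligned frame (the fixed
#'   image's origin and direction).
#' @return An object of class `bspline_transform`.
#' @export
bspline_transform <- function(grid_origin, grid_spacing, grid_shape,
                              displacements = NULL,
                              frame_origin = c(0, 0, 0),
                              frame_direction = diag(3)) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, length(grid_origin) == 3L,
            length(grid_spacing) == 3L)
  if (any(grid_spacing <= 0)) stop("grid_spacing must be > 0", call. = FALSE)
  if (any(grid_shape < 4L))
    stop("grid_shape must be >= 4 along each axis (cubic support)",
         call. = FALSE)
  if (is.null(displacements))
    displacements <- array(0, dim = c(grid_shape, 3L))
  displacements <- as.array(displacements)
  if (!all(dim(displacements) == c(grid_shape, 3L)))
    stop("displacements must have dim c(grid_shape, 3)", call. = FALSE)
  storage.mode(displacements) <- "double"
  structure(list(grid_origin = as.numeric(grid_origin),
                 grid_spacing = as.numeric(grid_spacing),
                 grid_shape = grid_shape,
                 displacements = displacements,
                 order = 3L,
                 frame_origin = as.numeric(frame_origin),
                 frame_direction = as.matrix(frame_direction)),
            class = "bspline_transform")
}

# control grid covering `fixed`'s physical domain plus a one-control-point
# margin on each side, so every interior point has its full 4x4x4 support
bspline_grid_for <- function(fixed, spacing_mm) {
  extent <- (dim(fixed$voxels) - 1) * fixed$spacing
  spacing_mm <- rep_len(spacing_mm, 3L)
  shape <- as.integer(ceiling(extent / spacing_mm - 1e-9)) + 4L
  bspline_transform(grid_origin = -spacing_mm, grid_spacing = spacing_mm,
                    grid_shape = shape,
                    frame_origin = fixed$origin,
                    frame_direction = fixed$direction)
}

#' Uniform cubic B-spline basis functions
#'
#' The four cubic polynomials that weight the influence of each control point
#' according to its distance from the evaluation point:
#' \deqn{B_0(u) = (1-u)^3/6,\; B_1(u) = (3u^3-6u^2+4)/6,}
#' \deqn{B_2(u) = (-3u^3+3u^2+3u+1)/6,\; B_3(u) = u^3/6,\quad 0 \le u < 1.}
#' They form a partition of unity: \eqn{\sum_m B_m(u) = 1}.
#'
#' @param m basis index, 0..3 (vectorized).
#' @param u relative grid position in `[0, 1)` (vectorized).
#' @return Numeric weights.
#' @export
bspline_basis <- function(m, u) {
  if (any(!(m %in% 0:3))) stop("'m' must be in 0..3", call. = FALSE)
  n <- max(length(m), length(u))
  m <- rep_len(m, n)
  u <- rep_len(u, n)
  w <- numeric(n)
  w[m == 0] <- (1 - u[m == 0])^3 / 6
  w[m == 1] <- (3 * u[m == 1]^3 - 6 * u[m == 1]^2 + 4) / 6
  w[m == 2] <- (-3 * u[m == 2]^3 + 3 * u[m == 2]^2 + 3 * u[m == 2] + 1) / 6
  w[m == 3] <- u[m == 3]^3 / 6
  w
}

#' Evaluate a free-form deformation's displacement
#'
#' @param t a [bspline_transform()].
#' @param points n x 3 matrix (or length-3 vector) of world coordinates (mm).
#' @param strict error if a point lies outside the grid's supported domain
#'   (default); with `strict = FALSE` such points get zero displacement.
#' @return n x 3 matrix of mm displacement vectors (in world coordinates).
#' @export
bspline_displacement <- function(t, points, strict = TRUE) {
  stopifnot(inherits(t, "bspline_transform"))
  points <- rbind3(points)
  aligned <- sweep(points, 2, t$frame_origin, `-`) %*% t$frame_direction
  res <- cpp_bspline_disp(as.vector(t$displacements), t$grid_shape,
                          t$grid_origin, t$grid_spacing, aligned)
  if (strict && !all(res$indomain))
    stop(sum(!res$indomain),
         " point(s) outside the B-spline grid's supported domain",
         call. = FALSE)
  res$disp %*% t(t$frame_direction)
}

#' Ordered chain of spatial transforms
#'
#' Maps fixed-image points to moving-image points. Affine members transform
#' the running point; B-spline members add their displacement evaluated at
#' the original fixed-image point (so a `[affine, bspline]` chain realizes
#' `T(x) = A(x) + D(x)` with the deformation grid anchored on the fixed
#' domain). An empty chain is the identity.
#'
#' @param ... transforms, applied in order.
#' @return An object of class `transform_chain`.
#' @export
transform_chain <- function(...) {
  xs <- list(...)
  if (length(xs) == 1L && is.list(xs[[1]]) && !inherits(xs[[1]], c("affine_transform", "bspline_transform")))
    xs <- xs[[1]]
  ok <- vapply(xs, function(x)
    inherits(x, c("affine_transform", "bspline_transform")), logical(1))
  if (!all(ok)) stop("chain members must be transforms", call. = FALSE)
  structure(list(transforms = xs), class = "transform_chain")
}

#' Apply a transform or chain to world points
#'
#' @param transform an `affine_transform`, `bspline_transform`, or
#'   `transform_chain`.
#' @param points n x 3 matrix (or length-3 vector) of world coordinates (mm).
#' @return n x 3 matrix of mapped world coordinates.
#' @export
apply_transform <- function(transform, points) {
  points <- rbind3(points)
  if (inherits(transform, "affine_transform")) {
    q <- sweep(points, 2, transform$center, `-`)
    return(sweep(q %*% t(transform$matrix), 2,
                 transform$center + transform$translation, `+`))
  }
  if (inherits(transform, "bspline_transform"))
    return(points + bspline_displacement(transform, points, strict = FALSE))
  if (inherits(transform, "transform_chain")) {
    out <- points
    for (t in transform$transforms) {
      if (inherits(t, "bspline_transform"))
        out <- out + bspline_displacement(t, points, strict = FALSE)
      else
        out <- apply_transform(t, out)
    }
    return(out)
  }
  stop("not a transform", call. = FALSE)
}

#' Serialize a transform (or chain) to JSON
#'
#' @param x transform or chain.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_transform <- function(x, path) {
  jsonlite::write_json(transform_to_list(x), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

transform_to_list <- function(x) {
  if (inherits(x, "affine_transform"))
    list(type = "affine", matrix = as.vector(x$matrix),
         translation = x$translation, center = x$center)
  else if (inherits(x, "bspline_transform"))
    list(type = "bspline", grid_origin = x$grid_origin,
         grid_spacing = x$grid_spacing, grid_shape = x$grid_shape,
         displacements = as.vector(x$displacements),
         frame_origin = x$frame_origin,
         frame_direction = as.vector(x$frame_direction))
  else if (inherits(x, "transform_chain"))
    list(type = "chain", transforms = lapply(x$transforms, transform_to_list))
  else stop("not a transform", call. = FALSE)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  transform_from_list(jsonlite::read_json(path, simplifyVector = FALSE))
}

transform_from_list <- function(l) {
  num <- function(x) as.numeric(unlist(x))
  switch(l$type,
         affine = affine_transform(matrix(num(l$matrix), 3, 3),
                                   num(l$translation), num(l$center)),
         bspline = {
           shape <- as.integer(num(l$grid_shape))
           bspline_transform(num(l$grid_origin), num(l$grid_spacing), shape,
                             array(num(l$displacements), c(shape, 3L)),
                             num(l$frame_origin),
                             matrix(num(l$frame_direction), 3, 3))
         },
         chain = transform_chain(lapply(l$transforms, transform_from_list)),
         stop("unknown transform type: ", l$type, call. = FALSE))
}
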