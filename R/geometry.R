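#' @useDynLib retrack, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Shared grid conventions
# -----------------------
# Every volumetric object carries an isotropic `voxel_size` (mm) and an
# `origin`: the world-mm position of the corner of voxel (1,1,1).  The center
# of 1-based voxel (i,j,k) is therefore origin + (c(i,j,k) - 0.5) * voxel_size,
# and all streamline/centerline points live in world mm.

#' Grid geometry descriptor
#'
#' @param dim integer vector of length 3, grid size in voxels.
#' @param voxel_size isotropic voxel edge length in mm.
#' @param origin world-mm position of the corner of the first voxel.
#' @return A `grid_geometry` list with elements `dim`, `voxel_size`, `origin`.
#' @export
grid_geometry <- function(dim, voxel_size = 2, origin = c(0, 0, 0)) {
  dim <- as.integer(dim)
  stopifnot(length(dim) == 3, all(dim >= 1), voxel_size > 0,
            length(origin) == 3, all(is.finite(origin)))
  structure(list(dim = dim, voxel_size = as.numeric(voxel_size),
                 origin = as.numeric(origin)),
            class = "grid_geometry")
}

geometry_of <- function(x) {
  if (inherits(x, "grid_geometry")) return(x)
  d <- if (!is.null(x$dim)) x$dim
  else if (!is.null(x$grid)) dim(x$grid)[1:3]
  else if (!is.null(x$coef)) dim(x$coef)[1:3]
  else if (!is.null(x$signals)) dim(x$signals)[1:3]
  else stop("cannot infer grid geometry")
  grid_geometry(d, x$voxel_size, x$origin)
}

same_grid <- function(a, b) {
  ga <- geometry_of(a); gb <- geometry_of(b)
  identical(ga$dim, gb$dim) &&
    isTRUE(all.equal(ga$voxel_size, gb$voxel_size)) &&
    isTRUE(all.equal(ga$origin, gb$origin))
}

#' Convert world points to 1-based voxel indices
#'
#' @param p numeric matrix (n x 3) or length-3 vector of world-mm points.
#' @param geom a `grid_geometry` (or any object carrying one).
#' @return Integer matrix (n x 3) of 1-based voxel indices; points outside the
#'   grid yield indices outside `1..dim`.
#' @export
world_to_voxel <- function(p, geom) {
  geom <- geometry_of(geom)
  p <- rbind(p)
  idx <- floor(sweep(sweep(p, 2, geom$origin), 2, geom$voxel_size, "/")) + 1
  storage.mode(idx) <- "integer"
  idx
}

#' Convert 1-based voxel indices to world coordinates of voxel centers
#'
#' @param idx integer matrix (n x 3) or length-3 vector of 1-based indices.
#' @param geom a `grid_geometry` (or any object carrying one).
#' @return Numeric matrix (n x 3) of world-mm voxel centers.
#' @export
voxel_to_world <- function(idx, geom) {
  geom <- geometry_of(geom)
  idx <- rbind(idx)
  sweep(sweep(idx - 0.5, 2, geom$voxel_size, "*"), 2, geom$origin, "+")
}

# value of `grid` at the voxel containing each world point; 0 outside
lookup_points <- function(grid, geom, p) {
  geom <- geometry_of(geom)
  idx <- world_to_voxel(p, geom)
  ok <- idx[, 1] >= 1 & idx[, 2] >= 1 & idx[, 3] >= 1 &
    idx[, 1] <= geom$dim[1] & idx[, 2] <= geom$dim[2] & idx[, 3] <= geom$dim[3]
  out <- numeric(nrow(idx))
  if (any(ok)) out[ok] <- grid[idx[ok, , drop = FALSE]]
  out
}

#' Binary mask volume
#'
#' @param grid 3D array coercible to 0/1.
#' @param voxel_size,origin grid geometry (see package conventions).
#' @return A `binary_mask` object.
#' @export
binary_mask <- function(grid, voxel_size = 2, origin = c(0, 0, 0)) {
  stopifnot(length(dim(grid)) == 3)
  g <- array(as.integer(grid != 0), dim = dim(grid))
  structure(list(grid = g, voxel_size = as.numeric(voxel_size),
                 origin = as.numeric(origin)),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %s @ %g mm, %d voxels set\n",
              paste(dim(x$grid), collapse = "x"), x$voxel_size, sum(x$grid)))
  invisible(x)
}

#' Visitation-count mask
#'
#' Integer grid of per-voxel visitation counts across `n_regions` repeated
#' tracking results (values 0..n_regions).
#'
#' @param grid 3D integer array of counts.
#' @param n_regions number of accumulated per-region binary masks.
#' @param voxel_size,origin grid geometry.
#' @return A `count_mask` object.
#' @export
count_mask <- function(grid, n_regions, voxel_size = 2, origin = c(0, 0, 0)) {
  stopifnot(length(dim(grid)) == 3, n_regions >= 1,
            min(grid) >= 0, max(grid) <= n_regions)
  structure(list(grid = array(as.integer(grid), dim = dim(grid)),
                 n_regions = as.integer(n_regions),
                 voxel_size = as.numeric(voxel_size),
                 origin = as.numeric(origin)),
            class = "count_mask")
}

#' @export
print.count_mask <- function(x, ...) {
  cat(sprintf("<count_mask> %s @ %g mm, n_regions=%d, max count=%d\n",
              paste(dim(x$grid), collapse = "x"), x$voxel_size,
              x$n_regions, max(x$grid)))
  invisible(x)
}

#' Streamline bundle
#'
#' @param streamlines list of n x 3 numeric matrices of world-mm points.
#' @param provenance label of the generating seed region.
#' @return A `streamline_bundle` object.
#' @export
streamline_bundle <- function(streamlines, provenance = NA_character_) {
  stopifnot(is.list(streamlines))
  structure(list(streamlines = streamlines, provenance = provenance),
            class = "streamline_bundle")
}

#' @export
print.streamline_bundle <- function(x, ...) {
  np <- vapply(x$streamlines, nrow, 1L)
  cat(sprintf("<streamline_bundle> %d streamlines, %d points total\n",
              length(x$streamlines), sum(np)))
  invisible(x)
}

#' @export
length.streamline_bundle <- function(x) length(x$streamlines)
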