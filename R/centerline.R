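# Bundle centerline extraction and generation of scaled planar seed regions
# along it.

#' Resample a streamline to n equally spaced points
#'
#' Points are equally spaced by arc length from the first to the last vertex
#' (endpoints included), with linear interpolation between original vertices.
#'
#' @param s n x 3 matrix of world-mm points (>= 2 rows).
#' @param n number of output samples (>= 2).
#' @return n x 3 matrix.
#' @export
resample_streamline <- function(s, n) {
  s <- rbind(s)
  if (nrow(s) < 2) stop("cannot resample a single-point streamline")
  stopifnot(n >= 2)
  seg <- sqrt(rowSums((s[-1, , drop = FALSE] - s[-nrow(s), , drop = FALSE])^2))
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  if (total == 0) return(matrix(rep(s[1, ], each = n), n, 3))
  target <- seq(0, total, length.out = n)
  out <- cbind(stats::approx(cum, s[, 1], xout = target, ties = "ordered")$y,
               stats::approx(cum, s[, 2], xout = target, ties = "ordered")$y,
               stats::approx(cum, s[, 3], xout = target, ties = "ordered")$y)
  out
}

# arc length of a polyline
polyline_length <- function(s) {
  if (nrow(s) < 2) return(0)
  sum(sqrt(rowSums((s[-1, , drop = FALSE] - s[-nrow(s), , drop = FALSE])^2)))
}

#' Compute the centerline of a streamline bundle
#'
#' Each streamline is orientation-aligned with a reference streamline (the
#' longest in the bundle; a streamline is flipped when its endpoints match
#' the reversed reference better), resampled to `n` points, and the
#' centerline is the point-wise average.
#'
#' @param bundle a `streamline_bundle`.
#' @param n number of centerline samples (default 129, which makes every
#'   seed-region count of the form 2^k + 1 an exact equally spaced subset).
#' @return A `centerline`: list with `points` (n x 3 matrix) and `n`.
#' @export
compute_centerline <- function(bundle, n = 129) {
  stopifnot(inherits(bundle, "streamline_bundle"))
  lines <- Filter(function(s) nrow(s) >= 2, bundle$streamlines)
  if (length(lines) == 0) stop("empty bundle: no streamlines with >= 2 points")
  lens <- vapply(lines, polyline_length, 1.0)
  ref <- lines[[which.max(lens)]]
  a <- ref[1, ]; b <- ref[nrow(ref), ]
  acc <- matrix(0, n, 3)
  for (s in lines) {
    p <- s[1, ]; q <- s[nrow(s), ]
    straight <- sum((p - a)^2) + sum((q - b)^2)
    flipped <- sum((p - b)^2) + sum((q - a)^2)
    if (flipped < straight) s <- s[rev(seq_len(nrow(s))), , drop = FALSE]
    acc <- acc + resample_streamline(s, n)
  }
  pts <- acc / length(lines)
  structure(list(points = pts, n = as.integer(n)), class = "centerline")
}

#' @export
print.centerline <- function(x, ...) {
  cat(sprintf("<centerline> %d points, length %.1f mm\n", x$n,
              polyline_length(x$points)))
  invisible(x)
}

#' Perpendicular plane frame at a centerline point
#'
#' The plane normal is the local centerline direction given by two
#' consecutive centerline points (the last point reuses the preceding
#' segment); the in-plane basis `u, v` is built deterministically by crossing
#' the normal with the coordinate axis of its smallest absolute component, so
#' that `{u, v, normal}` is orthonormal and right-handed.
#'
#' @param c a `centerline`.
#' @param i index in `1..n`.
#' @return A `plane_frame`: list with `origin`, `normal`, `u`, `v`.
#' @export
plane_at <- function(c, i) {
  stopifnot(inherits(c, "centerline"), i >= 1, i <= c$n)
  pts <- c$points
  n <- c$n
  j <- if (i < n) i + 1L else i - 1L
  d <- pts[max(i, j), ] - pts[min(i, j), ]
  # coincident consecutive points: search outward for the nearest distinct one
  k <- 1L
  while (sum(d^2) == 0 && (i - k >= 1 || i + k <= n)) {
    lo <- max(i - k, 1L); hi <- min(i + k, n)
    d <- pts[hi, ] - pts[lo, ]
    k <- k + 1L
  }
  if (sum(d^2) == 0) stop("degenerate centerline: all points coincide")
  normal <- d / sqrt(sum(d^2))
  ax <- diag(3)[, which.min(abs(normal))]
  u <- pracma_cross(ax, normal)
  u <- u / sqrt(sum(u^2))
  v <- pracma_cross(normal, u)
  structure(list(origin = pts[i, ], normal = normal, u = u, v = v),
            class = "plane_frame")
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Trace the tract-mask contour in a plane by ray casting
#'
#' Equally distributed rays are sent out from the plane origin and sampled at
#' equally spaced points; the first sample of each ray outside the masked
#' tract volume (nearest-voxel lookup; leaving the grid counts as outside)
#' defines that ray's contour radius.  A closed periodic cubic spline through
#' the contour points gives the region outline.
#'
#' @param plane a `plane_frame` with its origin inside `tract_mask`.
#' @param tract_mask a `binary_mask` of the tracked bundle.
#' @param n_rays number of rays (equal angular spacing).
#' @param ray_step_mm radial sampling step in mm.
#' @param max_radius_mm radius cap; rays still inside at the cap are clamped
#'   there and flagged via the `capped` field.
#' @param n_spline number of dense spline samples on the closed outline.
#' @return A `contour`: list with `plane`, `ray_angles`, `radii`,
#'   `spline_samples` (closed (n+1) x 2 in-plane polyline), `capped`.
#' @export
trace_contour <- function(plane, tract_mask, n_rays = 36, ray_step_mm = 0.5,
                          max_radius_mm = 30, n_spline = 128) {
  stopifnot(inherits(plane, "plane_frame"), inherits(tract_mask, "binary_mask"),
            n_rays >= 4, ray_step_mm > 0, max_radius_mm > ray_step_mm)
  if (lookup_points(tract_mask$grid, tract_mask, rbind(plane$origin)) == 0)
    stop("plane origin lies outside the tract mask")
  angles <- 2 * pi * (seq_len(n_rays) - 1) / n_rays
  rr <- seq(ray_step_mm, max_radius_mm, by = ray_step_mm)
  # sample all rays x all radii at once
  dirs <- outer(cos(angles), plane$u) + outer(sin(angles), plane$v)  # n_rays x 3
  pts <- matrix(rep(plane$origin, each = n_rays * length(rr)),
                n_rays * length(rr), 3) +
    dirs[rep(seq_len(n_rays), times = length(rr)), ] *
    rep(rr, each = n_rays)
  inside <- matrix(lookup_points(tract_mask$grid, tract_mask, pts) != 0,
                   n_rays, length(rr))
  first_out <- apply(inside, 1, function(row) {
    w <- which(!row)
    if (length(w) == 0) NA_integer_ else w[1]
  })
  capped <- is.na(first_out)
  radii <- ifelse(capped, max_radius_mm, rr[ifelse(capped, 1L, first_out)])
  contour_from_radii(plane, angles, radii, capped, n_spline)
}

# fit the closed periodic spline through polar contour points
contour_from_radii <- function(plane, angles, radii, capped, n_spline = 128) {
  x <- radii * cos(angles)
  y <- radii * sin(angles)
  th <- c(angles, 2 * pi)
  sx <- stats::spline(th, c(x, x[1]), method = "periodic", n = n_spline + 1)
  sy <- stats::spline(th, c(y, y[1]), method = "periodic", n = n_spline + 1)
  samples <- cbind(sx$y, sy$y)
  samples[nrow(samples), ] <- samples[1, ]  # numerically exact closure
  structure(list(plane = plane, ray_angles = angles, radii = radii,
                 spline_samples = samples, capped = capped),
            class = "contour")
}

#' @export
print.contour <- function(x, ...) {
  cat(sprintf("<contour> %d rays, radii %.1f-%.1f mm%s\n",
              length(x$ray_angles), min(x$radii), max(x$radii),
              if (any(x$capped)) sprintf(" (%d capped)", sum(x$capped)) else ""))
  invisible(x)
}

#' Scale a contour outward
#'
#' Moves every contour point outward along its ray by `scaling_mm` (the
#' SCALING variable) and refits the spline outline.
#'
#' @param ctr a `contour`.
#' @param scaling_mm outward offset in mm (>= 0).
#' @return The scaled `contour`.
#' @export
scale_contour <- function(ctr, scaling_mm) {
  stopifnot(inherits(ctr, "contour"), scaling_mm >= 0)
  if (scaling_mm == 0) return(ctr)
  contour_from_radii(ctr$plane, ctr$ray_angles, ctr$radii + scaling_mm,
                     ctr$capped, nrow(ctr$spline_samples) - 1)
}

#' Seed points inside a contour
#'
#' A regular 2D grid of spacing `spacing_mm` on the contour plane, clipped by
#' point-in-polygon against the spline outline and mapped to world
#' coordinates; the plane origin is always included.
#'
#' @param ctr a `contour`.
#' @param spacing_mm in-plane grid spacing in mm.
#' @return n x 3 matrix of world-mm seed points.
#' @export
seed_points_in_contour <- function(ctr, spacing_mm = 1) {
  stopifnot(inherits(ctr, "contour"), spacing_mm > 0)
  bnd <- ctr$spline_samples
  rx <- range(bnd[, 1]); ry <- range(bnd[, 2])
  gx <- seq(floor(rx[1] / spacing_mm), ceiling(rx[2] / spacing_mm)) * spacing_mm
  gy <- seq(floor(ry[1] / spacing_mm), ceiling(ry[2] / spacing_mm)) * spacing_mm
  grid2 <- as.matrix(expand.grid(x = gx, y = gy))
  keep <- mgcv::in.out(bnd, grid2)
  pts2 <- grid2[keep, , drop = FALSE]
  if (!any(pts2[, 1] == 0 & pts2[, 2] == 0))
    pts2 <- rbind(c(0, 0), pts2)        # the plane origin is always a seed
  plane <- ctr$plane
  matrix(rep(plane$origin, each = nrow(pts2)), nrow(pts2), 3) +
    outer(pts2[, 1], plane$u) + outer(pts2[, 2], plane$v)
}

#' Equally spaced centerline indices for the seed planes
#'
#' `n_seeds` indices equally spaced over `1..n_centerline` (endpoints
#' included), rounded to the nearest integer and strictly increasing.
#'
#' @param n_centerline number of centerline samples.
#' @param n_seeds number of seed regions (SEEDS variable, >= 2).
#' @return Integer vector of 1-based indices.
#' @export
select_plane_indices <- function(n_centerline, n_seeds) {
  stopifnot(n_seeds >= 2)
  if (n_seeds > n_centerline)
    stop("n_seeds exceeds the number of centerline samples")
  idx <- round(seq(0, n_centerline - 1, length.out = n_seeds)) + 1L
  as.integer(idx)
}
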