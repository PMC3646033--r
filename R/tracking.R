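# Deterministic tensor-deflection (TEND) streamline propagation.

#' Tracking parameters
#'
#' Controls TEND streamline propagation.  The deflection blend follows the
#' classical formulation `v_out = f*e1 + (1-f)*((1-g)*v_in + g*D*v_in)`; the
#' defaults `f = 0, g = 1` give pure tensor deflection `v_out ~ D v_in`, the
#' variant most widely deployed in clinical tractography.  The tensor is
#' normalized by its largest eigenvalue before deflection so step geometry is
#' independent of the diffusivity scale.
#'
#' @param step_mm integration step length in mm.
#' @param fa_threshold stop when local FA falls below this value.
#' @param max_angle_deg stop when the per-step turning angle exceeds this.
#' @param max_steps maximum steps per propagation direction.
#' @param f,g deflection blend weights in `[0, 1]`.
#' @param method `"euler"` (default, era-typical) or `"rk4"`.
#' @return A `tracking_params` list.
#' @export
tracking_params <- function(step_mm = 1.0, fa_threshold = 0.15,
                            max_angle_deg = 45, max_steps = 600,
                            f = 0, g = 1, method = c("euler", "rk4")) {
  method <- match.arg(method)
  stopifnot(step_mm > 0, fa_threshold >= 0, fa_threshold <= 1,
            max_angle_deg > 0, max_angle_deg <= 90, max_steps >= 1,
            f >= 0, f <= 1, g >= 0, g <= 1)
  structure(list(step_mm = step_mm, fa_threshold = fa_threshold,
                 max_angle_deg = max_angle_deg,
                 max_steps = as.integer(max_steps),
                 f = f, g = g, method = method),
            class = "tracking_params")
}

#' TEND deflection of an incoming direction
#'
#' `v_out = normalize(f*e1 + (1-f)*((1-g)*v_in + g*Dhat*v_in))` with
#' `Dhat = D / lambda1`, sign-aligned with `v_in` so the streamline never
#' backtracks.  A zero tensor returns `v_in` unchanged.
#'
#' @param t 3x3 symmetric tensor or length-6 coefficient vector.
#' @param v_in unit direction vector.
#' @param params a [tracking_params()].
#' @return Unit 3-vector.
#' @export
tend_deflect <- function(t, v_in, params = tracking_params()) {
  stopifnot(length(v_in) == 3)
  n <- sqrt(sum(v_in^2))
  stopifnot(n > 0)
  .cpp_tend_deflect(as_coef6(t), as.numeric(v_in) / n, params$f, params$g)
}

#' Propagate a single streamline from a seed point
#'
#' Euler (or RK4) integration in both directions from the seed, starting
#' along the positive and negative principal eigenvector at the seed.  Each
#' step interpolates the tensor, deflects the incoming direction and advances
#' `step_mm`; propagation stops when the FA falls below threshold, the turn
#' angle exceeds the limit, the streamline leaves the volume, or `max_steps`
#' is reached.  The two half-tracks are concatenated with the seed appearing
#' once.  A seed in sub-threshold FA yields a single-point streamline.
#'
#' @param field a `tensor_field`.
#' @param seed world-mm point.
#' @param params a [tracking_params()].
#' @return n x 3 matrix of world-mm points.
#' @export
propagate_streamline <- function(field, seed, params = tracking_params()) {
  track_streamlines(field, rbind(as.numeric(seed)), params)$streamlines[[1]]
}

#' Track streamlines from a set of seed points
#'
#' Vectorized front end to the compiled propagation kernel; see
#' [propagate_streamline()] for the per-seed behavior.
#'
#' @param field a `tensor_field`.
#' @param seeds n x 3 matrix of world-mm seed points.
#' @param params a [tracking_params()].
#' @param provenance optional label stored on the returned bundle.
#' @return A `streamline_bundle`.
#' @export
track_streamlines <- function(field, seeds, params = tracking_params(),
                              provenance = NA_character_) {
  stopifnot(inherits(field, "tensor_field"))
  seeds <- rbind(seeds)
  stopifnot(ncol(seeds) == 3, nrow(seeds) >= 1)
  lines <- .cpp_track_seeds(field$coef, dim(field$coef)[1:3],
                            field$voxel_size, field$origin, seeds,
                            params$step_mm, params$fa_threshold,
                            params$max_angle_deg, params$max_steps,
                            params$f, params$g, params$method == "rk4")
  streamline_bundle(lines, provenance = provenance)
}

#' Seed points from a binary ROI mask
#'
#' For `density = 1`, one seed per ROI voxel at its center; for `density = k`,
#' a regular k^3 sub-grid per voxel.
#'
#' @param roi a `binary_mask`.
#' @param density seeds per voxel axis (integer >= 1).
#' @return n x 3 matrix of world-mm seed points.
#' @export
seeds_from_mask <- function(roi, density = 1) {
  stopifnot(inherits(roi, "binary_mask"), density >= 1)
  density <- as.integer(density)
  idx <- which(roi$grid != 0, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("empty ROI: no voxels to seed")
  centers <- voxel_to_world(idx, roi)
  if (density == 1) return(centers)
  off1 <- (seq_len(density) - (density + 1) / 2) / density * roi$voxel_size
  off <- as.matrix(expand.grid(off1, off1, off1))
  out <- matrix(0, nrow(centers) * nrow(off), 3)
  for (i in seq_len(nrow(off))) {
    out[((i - 1) * nrow(centers) + 1):(i * nrow(centers)), ] <-
      sweep(centers, 2, off[i, ], "+")
  }
  out
}

#' Filter a bundle by include regions
#'
#' A streamline is kept iff at least one ROI contains one of its points
#' (`mode = "any"`) or every ROI contains at least one of its points
#' (`mode = "all"`).  Point-in-ROI membership uses nearest-voxel lookup.
#'
#' @param bundle a `streamline_bundle`.
#' @param rois list of `binary_mask` objects on a shared grid.
#' @param mode `"any"` or `"all"`.
#' @return The filtered `streamline_bundle`.
#' @export
filter_by_include <- function(bundle, rois, mode = c("any", "all")) {
  mode <- match.arg(mode)
  stopifnot(inherits(bundle, "streamline_bundle"), is.list(rois))
  if (length(rois) == 0) stop("empty include-ROI list")
  for (r in rois) stopifnot(inherits(r, "binary_mask"))
  if (length(rois) > 1) {
    for (r in rois[-1]) {
      if (!same_grid(rois[[1]], r)) stop("include ROIs are on different grids")
    }
  }
  touches <- vapply(bundle$streamlines, function(s) {
    vapply(rois, function(r) any(lookup_points(r$grid, r, s) != 0), TRUE)
  }, logical(length(rois)))
  touches <- matrix(touches, nrow = length(rois))
  keep <- if (mode == "any") colSums(touches) >= 1 else
    colSums(touches) == length(rois)
  streamline_bundle(bundle$streamlines[keep], provenance = bundle$provenance)
}
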