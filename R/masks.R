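# Binary fiber masks, visitation-count accumulation and FBM thresholding.

#' Rasterize a streamline bundle to a binary mask
#'
#' Each streamline segment is super-sampled at steps of at most a quarter
#' voxel and every voxel containing a sample point is set to 1 ("crossed or
#' touched by a fiber").
#'
#' @param bundle a `streamline_bundle`.
#' @param grid_spec a `grid_geometry` (or any object carrying one, e.g. the
#'   tensor field) defining the output grid.
#' @param sample_mm supersampling step along segments (default: a quarter
#'   voxel).
#' @return A `binary_mask` (all-zero for an empty bundle).
#' @export
streamlines_to_mask <- function(bundle, grid_spec, sample_mm = NULL) {
  stopifnot(inherits(bundle, "streamline_bundle"))
  geom <- geometry_of(grid_spec)
  if (is.null(sample_mm)) sample_mm <- geom$voxel_size / 4
  stopifnot(sample_mm > 0)
  grid <- .cpp_rasterize_streamlines(bundle$streamlines, geom$dim,
                                     geom$voxel_size, geom$origin,
                                     sample_mm)
  binary_mask(array(grid, dim = geom$dim), geom$voxel_size, geom$origin)
}

#' Accumulate per-region binary masks into a visitation-count mask
#'
#' @param masks non-empty list of `binary_mask` objects on a shared grid.
#' @return A `count_mask` with `n_regions = length(masks)`.
#' @export
accumulate <- function(masks) {
  if (!is.list(masks) || length(masks) == 0) stop("empty mask list")
  for (m in masks) stopifnot(inherits(m, "binary_mask"))
  g1 <- masks[[1]]
  for (m in masks[-1]) if (!same_grid(g1, m)) stop("mask grids do not match")
  total <- Reduce(`+`, lapply(masks, `[[`, "grid"))
  count_mask(total, n_regions = length(masks),
             voxel_size = g1$voxel_size, origin = g1$origin)
}

#' Threshold a count mask at a fiber-bundle-membership level
#'
#' A voxel is kept iff it is covered by at least `fbm_percent`% of the
#' accumulated reconstructions: `count >= ceiling(fbm_percent/100 *
#' n_regions)` (so FBM 90 keeps voxels included in 90% *or more* of the
#' reconstructions; ties at exact multiples are kept).
#'
#' @param cm a `count_mask`.
#' @param fbm_percent membership level in (0, 100].
#' @return A `binary_mask`.
#' @export
fbm_threshold <- function(cm, fbm_percent) {
  stopifnot(inherits(cm, "count_mask"), fbm_percent > 0, fbm_percent <= 100)
  thr <- ceiling(fbm_percent / 100 * cm$n_regions)
  binary_mask(cm$grid >= thr, cm$voxel_size, cm$origin)
}

#' Seed plan for repeated tracking
#'
#' @param n_seeds number of generated seed regions (SEEDS variable, >= 2).
#' @param scaling_mm outward contour offset in mm (SCALING variable, >= 0).
#' @return A `seed_plan` list.
#' @export
seed_plan <- function(n_seeds, scaling_mm) {
  stopifnot(n_seeds >= 2, scaling_mm >= 0)
  structure(list(n_seeds = as.integer(n_seeds),
                 scaling_mm = as.numeric(scaling_mm)),
            class = "seed_plan")
}

#' Classical two-ROI deterministic tractography
#'
#' Tracks from every voxel center of the seed ROI and keeps only streamlines
#' that reach the include (target) ROI, rasterized to a binary mask.
#'
#' @param field a `tensor_field`.
#' @param seed_roi,include_roi `binary_mask` ROIs on the field grid.
#' @param tparams a [tracking_params()].
#' @param density seeds per ROI-voxel axis.
#' @return A list: `mask` (`binary_mask`), `bundle` (kept streamlines).
#' @export
run_two_roi <- function(field, seed_roi, include_roi,
                        tparams = tracking_params(), density = 1) {
  bundle <- track_streamlines(field, seeds_from_mask(seed_roi, density),
                              tparams, provenance = "two_roi")
  kept <- filter_by_include(bundle, list(include_roi), mode = "all")
  list(mask = streamlines_to_mask(kept, field), bundle = kept)
}

#' Whole-volume tractography baseline
#'
#' Seeds every voxel of `seed_volume` (the FA-suprathreshold volume for the
#' original variant, or the union of the generated seed regions for the
#' re-seeded variant), keeps streamlines touching *both* ROIs (AND include),
#' and rasterizes.
#'
#' @param field a `tensor_field`.
#' @param seed_volume a non-empty `binary_mask` of seed voxels.
#' @param roi_a,roi_b combined include ROIs.
#' @param tparams a [tracking_params()].
#' @return A list: `mask`, `bundle`.
#' @export
run_whole_brain <- function(field, seed_volume, roi_a, roi_b,
                            tparams = tracking_params()) {
  if (sum(seed_volume$grid) == 0) stop("empty seed volume")
  bundle <- track_streamlines(field, seeds_from_mask(seed_volume, 1),
                              tparams, provenance = "whole_brain")
  kept <- filter_by_include(bundle, list(roi_a, roi_b), mode = "all")
  list(mask = streamlines_to_mask(kept, field), bundle = kept)
}

#' Repeated deterministic streamline tracking
#'
#' The full re-seeding pipeline: (1) initial two-ROI tracking and fiber-mask
#' generation; (2) centerline extraction (`n_centerline` samples); (3) for
#' each of `plan$n_seeds` equally spaced centerline points, a perpendicular
#' plane, a ray-cast contour of the initial mask scaled outward by
#' `plan$scaling_mm`, and an in-plane seed grid; (4) tracking from every
#' generated region, filtered with the initial seed and include ROIs as
#' *alternative* (ANY) include regions; (5) per-region binary masks
#' accumulated into the visitation-count mask.  The initial result does not
#' enter the count: the count denominator is the number of generated seed
#' regions.
#'
#' @param field a `tensor_field`.
#' @param seed_roi,include_roi initial `binary_mask` ROIs.
#' @param plan a [seed_plan()].
#' @param tparams a [tracking_params()].
#' @param n_centerline number of centerline samples (default 129).
#' @param seed_spacing_mm in-plane seed-grid spacing (default 1, half the
#'   2 mm acquisition voxel).
#' @return A `repeated_result`: list with `count_mask`, `per_region_masks`,
#'   `centerline`, `seed_plan`, `initial` (two-ROI result), `params`.
#' @export
run_repeated_tracking <- function(field, seed_roi, include_roi, plan,
                                  tparams = tracking_params(),
                                  n_centerline = 129, seed_spacing_mm = 1) {
  stopifnot(inherits(plan, "seed_plan"))
  initial <- run_two_roi(field, seed_roi, include_roi, tparams)
  if (length(initial$bundle) == 0) stop("initial reconstruction empty")
  ctr_line <- compute_centerline(initial$bundle, n = n_centerline)
  idx <- select_plane_indices(n_centerline, plan$n_seeds)
  geom <- geometry_of(field)
  rois <- list(seed_roi, include_roi)
  region_masks <- vector("list", length(idx))
  region_seeds <- vector("list", length(idx))
  for (r in seq_along(idx)) {
    plane <- plane_at(ctr_line, idx[r])
    plane <- anchor_plane(plane, initial$mask)
    seeds <- if (is.null(plane)) {
      rbind(ctr_line$points[idx[r], ])   # degenerate region: origin only
    } else {
      ctr <- trace_contour(plane, initial$mask)
      ctr <- scale_contour(ctr, plan$scaling_mm)
      seed_points_in_contour(ctr, seed_spacing_mm)
    }
    region_seeds[[r]] <- seeds
    bundle <- track_streamlines(field, seeds, tparams,
                                provenance = sprintf("region_%03d", r))
    kept <- filter_by_include(bundle, rois, mode = "any")
    region_masks[[r]] <- streamlines_to_mask(kept, geom)
  }
  cm <- accumulate(region_masks)
  structure(list(count_mask = cm, per_region_masks = region_masks,
                 region_seeds = region_seeds, centerline = ctr_line,
                 seed_plan = plan, initial = initial, params = tparams),
            class = "repeated_result")
}

# centerline points sit on the streamline average and can fall a voxel
# outside the rasterized mask; re-anchor the plane origin on the nearest
# in-mask voxel center within a 2-voxel radius (NULL when none exists)
anchor_plane <- function(plane, mask) {
  if (lookup_points(mask$grid, mask, rbind(plane$origin)) != 0) return(plane)
  geom <- geometry_of(mask)
  idx0 <- world_to_voxel(plane$origin, geom)[1, ]
  off <- as.matrix(expand.grid(-2:2, -2:2, -2:2))
  cand <- sweep(off, 2, idx0, "+")
  ok <- cand[, 1] >= 1 & cand[, 2] >= 1 & cand[, 3] >= 1 &
    cand[, 1] <= geom$dim[1] & cand[, 2] <= geom$dim[2] & cand[, 3] <= geom$dim[3]
  cand <- cand[ok, , drop = FALSE]
  inmask <- mask$grid[cand] != 0
  if (!any(inmask)) return(NULL)
  cand <- cand[inmask, , drop = FALSE]
  ctrs <- voxel_to_world(cand, geom)
  d2 <- rowSums(sweep(ctrs, 2, plane$origin)^2)
  plane$origin <- ctrs[which.min(d2), ]
  plane
}

#' @export
print.repeated_result <- function(x, ...) {
  cat(sprintf("<repeated_result> %d seed regions, scaling %g mm, max count %d\n",
              x$seed_plan$n_seeds, x$seed_plan$scaling_mm, max(x$count_mask$grid)))
  invisible(x)
}
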