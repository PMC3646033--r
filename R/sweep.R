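# Dice evaluation, the full factorial parameter sweep and descriptive group
# statistics.

#' Dice similarity coefficient
#'
#' `DSC = 2 |A intersect B| / (|A| + |B|)`: 1 is a perfect match, 0 means no
#' overlap.  Two empty masks compare as 1 by convention (flagged with a
#' warning).
#'
#' @param a,b `binary_mask` objects on the same grid.
#' @return Fraction in `[0, 1]`.
#' @export
dice <- function(a, b) {
  stopifnot(inherits(a, "binary_mask"), inherits(b, "binary_mask"))
  if (!same_grid(a, b)) stop("mask grids do not match")
  na <- sum(a$grid); nb <- sum(b$grid)
  if (na + nb == 0) {
    warning("both masks empty: DSC defined as 1 by convention")
    return(1)
  }
  2 * sum(a$grid & b$grid) / (na + nb)
}

#' Full factorial parameter grid
#'
#' Cartesian product of the four study variables: NOISE {0,1,2} x SEEDS
#' {2,3,5,9,17,33,65,129} x SCALING {0..5} mm x FBM {10..100 step 10} %,
#' i.e. 1440 parameterizations.
#'
#' @param noise,seeds,scaling,fbm optional restricted value sets (defaults:
#'   the full study grid).
#' @return Data frame with columns `noise`, `seeds`, `scaling`, `fbm`.
#' @export
build_parameter_grid <- function(noise = 0:2,
                                 seeds = c(2, 3, 5, 9, 17, 33, 65, 129),
                                 scaling = 0:5,
                                 fbm = seq(10, 100, by = 10)) {
  stopifnot(all(noise %in% 0:2), all(seeds >= 2), all(scaling >= 0),
            all(fbm > 0 & fbm <= 100))
  expand.grid(noise = noise, seeds = seeds, scaling = scaling, fbm = fbm,
              KEEP.OUT.ATTRS = FALSE)
}

#' Run the parameter sweep
#'
#' For each (noise, seeds, scaling) combination one repeated-tracking run is
#' executed (and shared across the FBM levels of that combination, which
#' only re-threshold its count mask); each record is the DSC of the
#' FBM-thresholded mask against the ground-truth bundle.
#'
#' @param phantoms named list, one entry per noise level appearing in `grid`
#'   (names "0", "1", "2"), each a list with elements `field` (fitted
#'   `tensor_field`) and `truth` (with `bundle_mask`, `seed_roi`,
#'   `include_roi`).
#' @param grid a parameter grid from [build_parameter_grid()].
#' @param tparams a [tracking_params()].
#' @param verbose print progress lines.
#' @return `grid` with an added `dsc` column (fractions in `[0, 1]`).
#' @export
run_sweep <- function(phantoms, grid = build_parameter_grid(),
                      tparams = tracking_params(), verbose = FALSE) {
  stopifnot(all(as.character(unique(grid$noise)) %in% names(phantoms)))
  grid$dsc <- NA_real_
  combos <- unique(grid[, c("noise", "seeds", "scaling")])
  for (ci in seq_len(nrow(combos))) {
    nz <- combos$noise[ci]; ns <- combos$seeds[ci]; sc <- combos$scaling[ci]
    ph <- phantoms[[as.character(nz)]]
    if (verbose)
      message(sprintf("sweep: noise=%d seeds=%d scaling=%g", nz, ns, sc))
    res <- run_repeated_tracking(ph$field, ph$truth$seed_roi,
                                 ph$truth$include_roi,
                                 seed_plan(ns, sc), tparams)
    rows <- which(grid$noise == nz & grid$seeds == ns & grid$scaling == sc)
    for (r in rows) {
      seg <- fbm_threshold(res$count_mask, grid$fbm[r])
      grid$dsc[r] <- dice(seg, ph$truth$bundle_mask)
    }
  }
  grid
}

#' Descriptive statistics of DSC by grouping variable
#'
#' One row per distinct value of `variable` with the group size and the mean,
#' sample standard deviation (n-1 denominator), minimum and maximum DSC in
#' percent.
#'
#' @param records a sweep data frame with a `dsc` column (fractions).
#' @param variable one of `"noise"`, `"seeds"`, `"scaling"`, `"fbm"`.
#' @return Data frame with columns `variable`, `group`, `n`, `mean_dsc`,
#'   `sd_dsc`, `min_dsc`, `max_dsc` (all DSC columns in percent).
#' @export
group_summary <- function(records, variable) {
  stopifnot(is.data.frame(records), nrow(records) > 0,
            variable %in% names(records), "dsc" %in% names(records))
  vals <- sort(unique(records[[variable]]))
  out <- do.call(rbind, lapply(vals, function(v) {
    d <- 100 * records$dsc[records[[variable]] == v]
    data.frame(variable = variable, group = v, n = length(d),
               mean_dsc = mean(d),
               sd_dsc = if (length(d) > 1) stats::sd(d) else 0,
               min_dsc = min(d), max_dsc = max(d))
  }))
  rownames(out) <- NULL
  out
}

#' Mean DSC over the preferred parameter band
#'
#' The band found to perform best in the study design this package
#' implements: SCALING 1-5 mm, SEEDS > 2 and FBM 30-50%, restricted to the
#' rows present in `records`.
#'
#' @param records a sweep data frame with a `dsc` column.
#' @param noise optional noise level to restrict to.
#' @return Mean DSC (fraction) over the band.
#' @export
best_band_mean <- function(records, noise = NULL) {
  keep <- records$scaling >= 1 & records$scaling <= 5 &
    records$seeds > 2 & records$fbm >= 30 & records$fbm <= 50
  if (!is.null(noise)) keep <- keep & records$noise == noise
  if (!any(keep)) stop("no records in the requested band")
  mean(records$dsc[keep])
}
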