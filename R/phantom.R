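# Synthetic tensor phantom: a curved (or straight) fiber bundle embedded in an
# isotropic background, with simulated diffusion-weighted signals and Rician
# noise at configurable SNR.  Serves as the ground-truthed test bed for the
# repeated-tracking pipeline.

#' Phantom configuration
#'
#' Describes a synthetic fiber-bundle phantom: a tube swept along a
#' quarter-circle arc (emulating the bend of the corticospinal tract) or along
#' a straight axis, embedded in an isotropic background.  The tube may taper
#' toward the seed end (`taper < 1`), emulating a bundle that fans out from a
#' compact anatomical waist such as the cerebral peduncle; the seed ROI is the
#' narrow end-cap, which is what makes classical end-cap-seeded two-ROI
#' tracking underestimate the spatial extent of the bundle.
#'
#' @param grid_shape integer 3-vector, grid size in voxels.
#' @param voxel_size isotropic voxel size in mm.
#' @param arc_radius radius (mm) of the quarter-circle centerline arc; for
#'   `shape = "straight"` the tube length is `arc_radius * pi / 2` so both
#'   shapes have the same centerline length.
#' @param tube_radius tube radius (mm) at the wide (include-ROI) end.
#' @param taper tube radius at the seed end as a fraction of `tube_radius`
#'   (1 = constant-radius tube); the radius grows linearly along the arc.
#' @param shape `"arc"` (quarter circle in the x-z plane) or `"straight"`
#'   (tube along x).
#' @param bundle_eigenvalues three descending diffusivities (mm^2/s) of the
#'   prolate bundle tensor.
#' @param background_diffusivity isotropic background diffusivity (mm^2/s).
#' @param s0 baseline (b=0) signal, unitless.
#' @param noise_level 0 (noise-free), 1 (SNR ~ 65) or 2 (SNR ~ 32).
#' @param rng_seed integer seed controlling the noise realization.
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(grid_shape = c(64, 64, 64), voxel_size = 2,
                           arc_radius = 30, tube_radius = 6, taper = 0.5,
                           shape = c("arc", "straight"),
                           bundle_eigenvalues = c(1.7, 0.3, 0.3) * 1e-3,
                           background_diffusivity = 2.0e-3,
                           s0 = 1000, noise_level = 0, rng_seed = 1L) {
  shape <- match.arg(shape)
  stopifnot(length(grid_shape) == 3, all(grid_shape >= 8), voxel_size > 0,
            arc_radius > 0, tube_radius > 0, taper > 0, taper <= 1,
            length(bundle_eigenvalues) == 3,
            all(diff(bundle_eigenvalues) <= 0),
            all(bundle_eigenvalues > 0),
            background_diffusivity > 0, s0 > 0,
            noise_level %in% 0:2)
  structure(list(grid_shape = as.integer(grid_shape),
                 voxel_size = as.numeric(voxel_size),
                 arc_radius = as.numeric(arc_radius),
                 tube_radius = as.numeric(tube_radius),
                 taper = as.numeric(taper), shape = shape,
                 bundle_eigenvalues = as.numeric(bundle_eigenvalues),
                 background_diffusivity = as.numeric(background_diffusivity),
                 s0 = as.numeric(s0), noise_level = as.integer(noise_level),
                 rng_seed = as.integer(rng_seed)),
            class = "phantom_config")
}

#' Single-shell gradient scheme
#'
#' One b=0 entry plus `n_directions` unit vectors from a fixed quasi-uniform
#' (golden-spiral hemisphere) point set shipped as a text fixture, for
#' bit-reproducibility.
#'
#' @param b_value diffusion weighting in s/mm^2 (single shell).
#' @param n_directions number of diffusion-encoding directions (max 30 from
#'   the embedded set).
#' @return A `gradient_scheme` data frame with columns `bval`, `gx`, `gy`,
#'   `gz`; the first row is the b=0 entry.
#' @export
gradient_scheme <- function(b_value = 1000, n_directions = 30) {
  stopifnot(b_value > 0, n_directions >= 6, n_directions <= 30)
  path <- system.file("extdata", "gradients30.txt", package = "retrack",
                      mustWork = TRUE)
  g <- as.matrix(utils::read.table(path))
  g <- g[seq_len(n_directions), , drop = FALSE]
  g <- g / sqrt(rowSums(g^2))
  out <- data.frame(bval = c(0, rep(b_value, n_directions)),
                    gx = c(0, g[, 1]), gy = c(0, g[, 2]), gz = c(0, g[, 3]))
  class(out) <- c("gradient_scheme", "data.frame")
  out
}

# signed distance to the capped tube surface, local radius and arc-length
# coordinate for a matrix of world points; used by both the tensor builder
# and the ground-truth masks
phantom_surface <- function(cfg, p) {
  extent <- cfg$grid_shape * cfg$voxel_size
  ctr <- extent / 2
  L <- cfg$arc_radius * pi / 2
  if (cfg$shape == "arc") {
    # circle center placed so the arc's bounding square is centered
    C <- c(ctr[1] - cfg$arc_radius / 2, ctr[2], ctr[3] - cfg$arc_radius / 2)
    qx <- p[, 1] - C[1]; qy <- p[, 2] - C[2]; qz <- p[, 3] - C[3]
    theta <- atan2(qz, qx)
    th_cl <- pmin(pmax(theta, 0), pi / 2)
    ax <- C[1] + cfg$arc_radius * cos(th_cl)
    az <- C[3] + cfg$arc_radius * sin(th_cl)
    dx <- p[, 1] - ax; dy <- qy; dz <- p[, 3] - az
    tx <- -sin(th_cl); tz <- cos(th_cl)
    a <- abs(dx * tx + dz * tz)            # axial overshoot beyond the caps
    a[a < 1e-9] <- 0                       # within the span it is zero up to rounding
    d2 <- dx^2 + dy^2 + dz^2
    d_perp <- sqrt(pmax(d2 - a^2, 0))      # distance to the local axis
    s <- th_cl * cfg$arc_radius
    tangent <- cbind(tx, 0, tz)
  } else {
    x0 <- ctr[1] - L / 2
    s_raw <- p[, 1] - x0
    s <- pmin(pmax(s_raw, 0), L)
    a <- abs(s_raw - s)
    d_perp <- sqrt((p[, 2] - ctr[2])^2 + (p[, 3] - ctr[3])^2)
    theta <- NULL
    tangent <- cbind(rep(1, nrow(p)), 0, 0)
  }
  r_loc <- cfg$tube_radius * (cfg$taper + (1 - cfg$taper) * s / L)
  inside <- a == 0 & d_perp <= r_loc
  dr <- pmax(d_perp - r_loc, 0)
  sd <- ifelse(inside, d_perp - r_loc, sqrt(dr^2 + a^2))
  list(sd = sd, s = s, inside = inside, tangent = tangent, r_loc = r_loc,
       length = L)
}

#' Build the phantom tensor field and ground truth
#'
#' Voxels whose center lies inside the tube receive a prolate tensor with
#' `bundle_eigenvalues` and principal axis along the local centerline tangent;
#' background voxels receive an isotropic tensor; voxels within one voxel of
#' the tube surface (on either side) receive a linear blend of the two — the
#' partial-volume model responsible for the anisotropy drop at the bundle
#' border.  The ground truth comprises the tube-interior mask and one-voxel
#' -thick end-cap ROIs (the seed ROI at the narrow end).
#'
#' @param cfg a [phantom_config()].
#' @return A list with elements `field` (a `tensor_field`) and `truth` (a list
#'   of `binary_mask` objects: `bundle_mask`, `seed_roi`, `include_roi`).
#' @export
build_tensor_field <- function(cfg) {
  stopifnot(inherits(cfg, "phantom_config"))
  dimv <- cfg$grid_shape
  vox <- cfg$voxel_size
  extent <- dimv * vox
  margin <- cfg$tube_radius + vox       # tube plus partial-volume shell
  L <- cfg$arc_radius * pi / 2
  need <- if (cfg$shape == "arc") {
    c(cfg$arc_radius + 2 * margin, 2 * margin, cfg$arc_radius + 2 * margin)
  } else {
    c(L + 2 * vox, 2 * margin, 2 * margin)
  }
  over <- which(need > extent)
  if (length(over) > 0) {
    stop(sprintf("tube exceeds grid bounds along axis %s (needs %.1f mm, grid %.1f mm)",
                 paste(c("x", "y", "z")[over], collapse = ","),
                 max(need[over]), min(extent[over])))
  }

  idx <- as.matrix(expand.grid(i = seq_len(dimv[1]), j = seq_len(dimv[2]),
                               k = seq_len(dimv[3])))
  geom <- grid_geometry(dimv, vox)
  p <- voxel_to_world(idx, geom)
  surf <- phantom_surface(cfg, p)

  w <- pmin(pmax((vox - surf$sd) / (2 * vox), 0), 1)  # 1 deep inside .. 0 outside
  lam <- cfg$bundle_eigenvalues
  dbg <- cfg$background_diffusivity
  tx <- surf$tangent[, 1]; tz <- surf$tangent[, 3]
  # prolate tensor with axes {tangent, in-plane radial, y}
  bxx <- lam[1] * tx^2 + lam[2] * tz^2
  bxz <- (lam[1] - lam[2]) * tx * tz
  bzz <- lam[1] * tz^2 + lam[2] * tx^2
  byy <- rep(lam[3], length(tx))
  coef <- array(0, dim = c(dimv, 6))
  coef[, , , 1] <- array(w * bxx + (1 - w) * dbg, dim = dimv)
  coef[, , , 3] <- array(w * bxz, dim = dimv)
  coef[, , , 4] <- array(w * byy + (1 - w) * dbg, dim = dimv)
  coef[, , , 6] <- array(w * bzz + (1 - w) * dbg, dim = dimv)

  field <- tensor_field(coef, voxel_size = vox, origin = geom$origin)

  bundle <- array(as.integer(surf$inside), dim = dimv)
  seed <- array(as.integer(surf$inside & surf$s <= vox), dim = dimv)
  incl <- array(as.integer(surf$inside & surf$s >= surf$length - vox), dim = dimv)
  truth <- list(bundle_mask = binary_mask(bundle, vox, geom$origin),
                seed_roi = binary_mask(seed, vox, geom$origin),
                include_roi = binary_mask(incl, vox, geom$origin))
  stopifnot(sum(truth$seed_roi$grid) > 0, sum(truth$include_roi$grid) > 0)
  list(field = field, truth = truth)
}

#' Simulate diffusion-weighted signals from a tensor field
#'
#' Computes `S_k = s0 * exp(-b_k * g_k' D g_k)` per voxel and scheme entry
#' (the Stejskal-Tanner signal equation); b=0 entries give `s0` everywhere.
#'
#' @param field a `tensor_field`.
#' @param scheme a [gradient_scheme()].
#' @param s0 baseline signal.
#' @return A `dwi_volume`: list with `signals` (4D array), `scheme`,
#'   `voxel_size`, `origin`.
#' @export
simulate_dwi <- function(field, scheme, s0 = 1000) {
  stopifnot(inherits(field, "tensor_field"), s0 > 0)
  if (any(scheme$bval < 0)) stop("negative b-value in gradient scheme")
  dimv <- dim(field$coef)[1:3]
  nk <- nrow(scheme)
  signals <- array(s0, dim = c(dimv, nk))
  for (k in seq_len(nk)) {
    b <- scheme$bval[k]
    if (b == 0) next
    g <- c(scheme$gx[k], scheme$gy[k], scheme$gz[k])
    q <- g[1]^2 * field$coef[, , , 1] + 2 * g[1] * g[2] * field$coef[, , , 2] +
      2 * g[1] * g[3] * field$coef[, , , 3] + g[2]^2 * field$coef[, , , 4] +
      2 * g[2] * g[3] * field$coef[, , , 5] + g[3]^2 * field$coef[, , , 6]
    signals[, , , k] <- s0 * exp(-b * q)
  }
  structure(list(signals = signals, scheme = scheme,
                 voxel_size = field$voxel_size, origin = field$origin),
            class = "dwi_volume")
}

#' @export
print.dwi_volume <- function(x, ...) {
  d <- dim(x$signals)
  cat(sprintf("<dwi_volume> %s, %d volumes @ %g mm\n",
              paste(d[1:3], collapse = "x"), d[4], x$voxel_size))
  invisible(x)
}

# run `expr` under a private RNG stream, leaving the caller's RNG untouched
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Add complex Gaussian (Rician magnitude) noise to a DWI volume
#'
#' Each signal s is replaced by `|s + n_r + i n_i|` with independent zero-mean
#' Gaussians of standard deviation `sigma` on the real and imaginary channel —
#' the magnitude-reconstruction noise model of MRI.  Deterministic given
#' `seed`; the caller's RNG state is preserved.
#'
#' @param dwi a `dwi_volume`.
#' @param sigma per-channel Gaussian standard deviation (>= 0).
#' @param seed integer seed for the noise realization.
#' @return A `dwi_volume` with noisy magnitudes.
#' @export
add_complex_gaussian_noise <- function(dwi, sigma, seed = 1L) {
  stopifnot(inherits(dwi, "dwi_volume"), sigma >= 0)
  if (sigma == 0) return(dwi)
  n <- length(dwi$signals)
  noisy <- with_seed(seed, {
    nr <- stats::rnorm(n, sd = sigma)
    ni <- stats::rnorm(n, sd = sigma)
    sqrt((as.vector(dwi$signals) + nr)^2 + ni^2)
  })
  dwi$signals <- array(noisy, dim = dim(dwi$signals))
  dwi
}

#' Per-channel noise standard deviation for a named noise level
#'
#' SNR is defined as the mean noise-free b=0 signal inside the bundle divided
#' by the per-channel Gaussian sigma; levels 1 and 2 target SNR 65 and 32.
#'
#' @param s0 baseline signal.
#' @param noise_level 0, 1 or 2.
#' @return sigma (0 for level 0).
#' @export
noise_sigma <- function(s0, noise_level) {
  stopifnot(noise_level %in% 0:2)
  c(0, s0 / 65, s0 / 32)[noise_level + 1]
}

#' Generate a complete phantom data set
#'
#' Builds the tensor field and ground truth, simulates the DWI signals, and
#' adds Rician noise according to `cfg$noise_level`.
#'
#' @param cfg a [phantom_config()].
#' @param scheme a [gradient_scheme()] (default: 30 directions at b=1000).
#' @return A `phantom` list: `cfg`, `scheme`, `field` (noise-free generating
#'   tensors), `truth`, `dwi` (noisy if requested), `sigma`.
#' @export
make_phantom <- function(cfg, scheme = gradient_scheme()) {
  built <- build_tensor_field(cfg)
  dwi <- simulate_dwi(built$field, scheme, s0 = cfg$s0)
  sigma <- noise_sigma(cfg$s0, cfg$noise_level)
  if (sigma > 0) dwi <- add_complex_gaussian_noise(dwi, sigma, cfg$rng_seed)
  structure(list(cfg = cfg, scheme = scheme, field = built$field,
                 truth = built$truth, dwi = dwi, sigma = sigma),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom> %s %s @ %g mm, noise level %d (sigma=%.2f)\n",
              x$cfg$shape, paste(x$cfg$grid_shape, collapse = "x"),
              x$cfg$voxel_size, x$cfg$noise_level, x$sigma))
  invisible(x)
}
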