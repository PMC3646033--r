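# Shared fixtures, built lazily and cached for the whole test run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) assign(name, builder(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# compact quarter-arc phantom (tapered, like the study phantom but smaller)
small_arc_cfg <- function(noise_level = 0, taper = 0.5, rng_seed = 42L) {
  phantom_config(grid_shape = c(32, 32, 32), voxel_size = 2, arc_radius = 16,
                 tube_radius = 5, taper = taper, noise_level = noise_level,
                 rng_seed = rng_seed)
}

small_arc_phantom <- function() {
  fixture("small_arc", function() make_phantom(small_arc_cfg()))
}

# constant-radius straight tube (symmetric in x)
straight_cfg <- function(tube_radius = 5) {
  phantom_config(grid_shape = c(32, 24, 24), voxel_size = 2, arc_radius = 16,
                 tube_radius = tube_radius, taper = 1, shape = "straight")
}

straight_phantom <- function() {
  fixture("straight", function() make_phantom(straight_cfg()))
}

# homogeneous prolate field aligned with +x
homogeneous_field <- function(dim = c(24, 16, 16), voxel = 2,
                              lam = c(1.7, 0.3, 0.3) * 1e-3) {
  coef <- array(0, dim = c(dim, 6))
  coef[, , , 1] <- lam[1]
  coef[, , , 4] <- lam[2]
  coef[, , , 6] <- lam[3]
  tensor_field(coef, voxel_size = voxel)
}

# fully isotropic field
isotropic_field <- function(dim = c(12, 12, 12), voxel = 2, d = 1e-3) {
  coef <- array(0, dim = c(dim, 6))
  coef[, , , 1] <- d
  coef[, , , 4] <- d
  coef[, , , 6] <- d
  tensor_field(coef, voxel_size = voxel)
}

# random symmetric positive-definite tensor coefficient vector
random_spd6 <- function() {
  A <- matrix(stats::rnorm(9), 3)
  D <- crossprod(A) * 1e-3
  c(D[1, 1], D[1, 2], D[1, 3], D[2, 2], D[2, 3], D[3, 3])
}

# random rotation matrix (QR of a Gaussian matrix, det +1)
random_rotation <- function() {
  Q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# analytic geometry of the arc phantom centerline, mirroring the generator's
# placement rule (circle center such that the arc bounding square is centered)
arc_center <- function(cfg) {
  ctr <- cfg$grid_shape * cfg$voxel_size / 2
  c(ctr[1] - cfg$arc_radius / 2, ctr[2], ctr[3] - cfg$arc_radius / 2)
}

# distance from world points to the (clamped) analytic arc segment
dist_to_arc <- function(p, cfg) {
  C <- arc_center(cfg)
  qx <- p[, 1] - C[1]; qz <- p[, 3] - C[3]
  th <- pmin(pmax(atan2(qz, qx), 0), pi / 2)
  ax <- C[1] + cfg$arc_radius * cos(th)
  az <- C[3] + cfg$arc_radius * sin(th)
  sqrt((p[, 1] - ax)^2 + (p[, 2] - C[2])^2 + (p[, 3] - az)^2)
}

# shoelace area of a closed 2D polygon
polygon_area <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  n <- nrow(xy)
  abs(sum(x[-n] * y[-1] - x[-1] * y[-n])) / 2
}
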