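test_that("bundle mask volume matches the analytic tube volume", {
  # independent membership oracle: dense search over the arc parameter
  # (argmin at an arc endpoint means the point lies beyond the flat cap)
  oracle_count <- function(cfg) {
    geom <- grid_geometry(cfg$grid_shape, cfg$voxel_size)
    idx <- as.matrix(expand.grid(seq_len(cfg$grid_shape[1]),
                                 seq_len(cfg$grid_shape[2]),
                                 seq_len(cfg$grid_shape[3])))
    p <- voxel_to_world(idx, geom)
    C <- arc_center(cfg)
    th <- seq(0, pi / 2, length.out = 2001)
    ax <- C[1] + cfg$arc_radius * cos(th)
    az <- C[3] + cfg$arc_radius * sin(th)
    # restrict to the tube bounding box to keep the search affordable
    r1 <- cfg$tube_radius + 1
    cand <- which(abs(p[, 2] - C[2]) <= r1 &
                    p[, 1] >= C[1] - r1 & p[, 1] <= C[1] + cfg$arc_radius + r1 &
                    p[, 3] >= C[3] - r1 & p[, 3] <= C[3] + cfg$arc_radius + r1)
    d2 <- outer(p[cand, 1], ax, "-")^2 + outer(p[cand, 3], az, "-")^2
    j <- max.col(-d2, ties.method = "first")
    dist <- sqrt(d2[cbind(seq_along(cand), j)] + (p[cand, 2] - C[2])^2)
    # axial component at the argmin separates in-span points (~0 up to the
    # theta discretization) from points beyond the flat caps
    axial <- abs((p[cand, 1] - ax[j]) * (-sin(th[j])) +
                   (p[cand, 3] - az[j]) * cos(th[j]))
    sum(dist <= cfg$tube_radius & axial <= 0.02)
  }
  cfg2 <- phantom_config(grid_shape = c(64, 64, 64), voxel_size = 2,
                         arc_radius = 30, tube_radius = 6, taper = 1)
  built2 <- build_tensor_field(cfg2)
  expect_equal(sum(built2$truth$bundle_mask$grid), oracle_count(cfg2))
  # at 1 mm voxels the count converges onto the analytic volume pi r^2 L
  cfg1 <- phantom_config(grid_shape = c(128, 128, 128), voxel_size = 1,
                         arc_radius = 30, tube_radius = 6, taper = 1)
  built1 <- build_tensor_field(cfg1)
  L <- cfg1$arc_radius * pi / 2
  analytic <- pi * cfg1$tube_radius^2 * L / cfg1$voxel_size^3
  measured <- sum(built1$truth$bundle_mask$grid)
  expect_lt(abs(measured - analytic) / analytic, 0.05)
})

test_that("interior bundle voxels carry the prolate tensor, background is isotropic", {
  ph <- small_arc_phantom()
  cfg <- ph$cfg
  fam <- fa_map(ph$field)
  # a voxel well inside the tube: eigenvalues equal the configured ones
  idx <- which(ph$truth$bundle_mask$grid == 1, arr.ind = TRUE)
  ctrs <- voxel_to_world(idx, ph$truth$bundle_mask)
  deep <- which.max(-dist_to_arc(ctrs, cfg))  # closest to the centerline
  d6 <- ph$field$coef[idx[deep, 1], idx[deep, 2], idx[deep, 3], ]
  D <- matrix(c(d6[1], d6[2], d6[3], d6[2], d6[4], d6[5], d6[3], d6[5], d6[6]), 3)
  ev <- sort(eigen(D, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  expect_equal(ev, cfg$bundle_eigenvalues, tolerance = 1e-12)
  # FA oracle evaluated directly from the eigenvalue formula
  lam <- cfg$bundle_eigenvalues
  fa_oracle <- sqrt(3 / 2) * sqrt(sum((lam - mean(lam))^2)) / sqrt(sum(lam^2))
  expect_equal(fractional_anisotropy(d6), fa_oracle, tolerance = 1e-12)
  expect_equal(fa_oracle, 0.799, tolerance = 1e-3)
  # background corner voxel: FA exactly 0
  expect_equal(fam[1, 1, 1], 0)
})

test_that("ROIs are one voxel thick, sit at the tube ends and intersect the bundle", {
  ph <- small_arc_phantom()
  tr <- ph$truth
  expect_gt(sum(tr$seed_roi$grid), 0)
  expect_gt(sum(tr$include_roi$grid), 0)
  expect_true(all(tr$bundle_mask$grid[tr$seed_roi$grid == 1] == 1))
  expect_true(all(tr$bundle_mask$grid[tr$include_roi$grid == 1] == 1))
  # the tapered seed end is narrower than the include end
  expect_lt(sum(tr$seed_roi$grid), sum(tr$include_roi$grid))
  # disks are far apart (opposite arc ends)
  sc <- voxel_to_world(which(tr$seed_roi$grid == 1, arr.ind = TRUE), tr$seed_roi)
  ic <- voxel_to_world(which(tr$include_roi$grid == 1, arr.ind = TRUE), tr$include_roi)
  gap <- sqrt(sum((colMeans(sc) - colMeans(ic))^2))
  expect_gt(gap, ph$cfg$arc_radius)
})

test_that("a tube too large for the grid errors naming the overflowing axis", {
  expect_error(build_tensor_field(
    phantom_config(grid_shape = c(16, 16, 16), voxel_size = 2,
                   arc_radius = 30, tube_radius = 6)),
    "axis")
})

test_that("simulated signals follow the Stejskal-Tanner relation", {
  ph <- small_arc_phantom()
  scheme <- ph$scheme
  # b=0 entry equals s0 everywhere
  expect_true(all(ph$dwi$signals[, , , 1] == ph$cfg$s0))
  # isotropic voxel: identical signal in every direction, s0*exp(-b*d)
  sig_bg <- ph$dwi$signals[1, 1, 1, -1]
  expect_equal(unname(sig_bg),
               rep(ph$cfg$s0 * exp(-1000 * ph$cfg$background_diffusivity), 30),
               tolerance = 1e-12)
  # diagonal tensor with gradient along x: s0*exp(-b*Dxx)
  coef <- array(0, dim = c(1, 1, 1, 6))
  coef[1, 1, 1, ] <- c(1.7e-3, 0, 0, 0.3e-3, 0, 0.3e-3)
  f1 <- tensor_field(coef, voxel_size = 2)
  sch <- data.frame(bval = c(0, 1000), gx = c(0, 1), gy = c(0, 0), gz = c(0, 0))
  class(sch) <- c("gradient_scheme", "data.frame")
  dwi1 <- simulate_dwi(f1, sch, s0 = 1000)
  expect_equal(dwi1$signals[1, 1, 1, 2], 1000 * exp(-1.7), tolerance = 1e-12)
  # negative b rejected
  sch$bval[2] <- -10
  expect_error(simulate_dwi(f1, sch), "negative b")
})

test_that("complex Gaussian noise has the Rician magnitude distribution", {
  ph <- small_arc_phantom()
  # sigma = 0 is the identity
  expect_identical(add_complex_gaussian_noise(ph$dwi, 0), ph$dwi)
  # zero signal: mean magnitude is sigma*sqrt(pi/2) (Rayleigh closed form)
  zero <- ph$dwi
  zero$signals <- array(0, dim = c(100, 100, 100, 1))
  noisy <- add_complex_gaussian_noise(zero, 10, seed = 99)
  expect_lt(abs(mean(noisy$signals) - 10 * sqrt(pi / 2)) / (10 * sqrt(pi / 2)),
            0.01)
  # determinism: same seed gives bit-identical output
  n1 <- add_complex_gaussian_noise(ph$dwi, 5, seed = 3)
  n2 <- add_complex_gaussian_noise(ph$dwi, 5, seed = 3)
  expect_identical(n1$signals, n2$signals)
  n3 <- add_complex_gaussian_noise(ph$dwi, 5, seed = 4)
  expect_false(identical(n1$signals, n3$signals))
})

test_that("generated noise levels hit the target SNR within 10%", {
  for (spec in list(c(1, 65), c(2, 32))) {
    cfg <- small_arc_cfg(noise_level = spec[1])
    ph <- make_phantom(cfg)
    b0 <- ph$dwi$signals[, , , 1]
    snr <- mean(b0[ph$truth$bundle_mask$grid == 1]) / ph$sigma
    expect_lt(abs(snr - spec[2]) / spec[2], 0.10)
  }
})

test_that("phantom generation is reproducible from config and seed", {
  cfg <- small_arc_cfg(noise_level = 2, rng_seed = 11L)
  p1 <- make_phantom(cfg)
  p2 <- make_phantom(cfg)
  expect_identical(p1$truth$bundle_mask$grid, p2$truth$bundle_mask$grid)
  expect_identical(p1$truth$seed_roi$grid, p2$truth$seed_roi$grid)
  expect_identical(p1$truth$include_roi$grid, p2$truth$include_roi$grid)
  expect_identical(p1$dwi$signals, p2$dwi$signals)
})

test_that("the embedded gradient table is quasi-uniform and unit length", {
  scheme <- gradient_scheme()
  expect_equal(nrow(scheme), 31)
  expect_equal(scheme$bval[1], 0)
  g <- as.matrix(scheme[-1, c("gx", "gy", "gz")])
  expect_equal(unname(rowSums(g^2)), rep(1, 30), tolerance = 1e-12)
  # well-conditioned tensor design (non-collinear requirement)
  B <- cbind(g[, 1]^2, 2 * g[, 1] * g[, 2], 2 * g[, 1] * g[, 3],
             g[, 2]^2, 2 * g[, 2] * g[, 3], g[, 3]^2)
  expect_equal(qr(B)$rank, 6)
})
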