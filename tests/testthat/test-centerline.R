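test_that("arc-length resampling is uniform, idempotent and endpoint-preserving", {
  seg <- rbind(c(0, 0, 0), c(10, 0, 0))
  r <- resample_streamline(seg, 5)
  expect_equal(r[, 1], c(0, 2.5, 5, 7.5, 10))
  expect_equal(r[, 2], rep(0, 5))
  # n = original count on an equally spaced line reproduces it
  line <- cbind(seq(0, 10, by = 2), 1, -1)
  expect_equal(resample_streamline(line, nrow(line)), unname(line))
  # L-shaped polyline, n = 2: endpoints only
  L <- rbind(c(0, 0, 0), c(3, 0, 0), c(3, 4, 0))
  expect_equal(resample_streamline(L, 2), rbind(c(0, 0, 0), c(3, 4, 0)))
  expect_error(resample_streamline(rbind(c(0, 0, 0)), 5), "single-point")
})

test_that("the centerline averages aligned streamlines", {
  # two parallel lines at y = +d / -d average onto y = 0
  l1 <- cbind(seq(0, 20, by = 1), 3, 0)
  l2 <- cbind(seq(0, 20, by = 1), -3, 0)
  c1 <- compute_centerline(streamline_bundle(list(l1, l2)), n = 11)
  expect_lt(max(abs(c1$points[, 2])), 1e-9)
  expect_equal(c1$points[, 1], seq(0, 20, length.out = 11))
  # orientation alignment: a reversed copy must not cancel the average
  c2 <- compute_centerline(streamline_bundle(
    list(l1, l2[rev(seq_len(nrow(l2))), ])), n = 11)
  expect_equal(c2$points, c1$points, tolerance = 1e-9)
  # single streamline: its own resampling
  c3 <- compute_centerline(streamline_bundle(list(l1)), n = 21)
  expect_equal(c3$points, unname(l1))
  expect_error(compute_centerline(streamline_bundle(list())), "empty bundle")
})

test_that("centerline of jittered arcs matches the direct averaging oracle", {
  set.seed(31)
  n_pts <- 129
  th <- seq(0, pi / 2, length.out = n_pts)
  arc <- cbind(30 * cos(th), 0, 30 * sin(th))
  sigma <- 0.5
  copies <- replicate(100, arc + matrix(stats::rnorm(3 * n_pts, sd = sigma),
                                        n_pts, 3), simplify = FALSE)
  ctr <- compute_centerline(streamline_bundle(copies), n = n_pts)
  # independent oracle, written out in full: flip toward the reference
  # orientation, resample by cumulated chord length, then average point-wise
  oracle_resample <- function(s, n) {
    cum <- c(0, cumsum(sqrt(rowSums(diff(s)^2))))
    tgt <- seq(0, cum[length(cum)], length.out = n)
    apply(s, 2, function(col) stats::approx(cum, col, xout = tgt)$y)
  }
  oracle <- Reduce(`+`, lapply(copies, oracle_resample, n = n_pts)) /
    length(copies)
  expect_lt(max(abs(ctr$points - oracle)), 1e-9)
  # Monte-Carlo concentration: the average stays near the true arc on the
  # 3*sigma/sqrt(n_copies) scale
  d <- sqrt(rowSums((ctr$points - arc)^2))
  expect_lt(max(d), 3 * sigma / sqrt(100) * 4)
})

test_that("plane frames are orthonormal and follow the local direction", {
  line <- cbind(seq(0, 20, by = 2), 0, 0)
  ctr <- structure(list(points = line, n = nrow(line)), class = "centerline")
  for (i in c(1, 5, nrow(line))) {  # includes the endpoint fallback rule
    pf <- plane_at(ctr, i)
    expect_equal(pf$normal, c(1, 0, 0))
    M <- cbind(pf$u, pf$v, pf$normal)
    expect_equal(crossprod(M), diag(3), tolerance = 1e-12)
    expect_equal(det(M), 1, tolerance = 1e-12)
  }
  # quarter arc: numerical normal within one discretization step of the tangent
  th <- seq(0, pi / 2, length.out = 65)
  arc <- cbind(30 * cos(th), 0, 30 * sin(th))
  actr <- structure(list(points = arc, n = 65L), class = "centerline")
  dth <- pi / 2 / 64
  for (i in c(1, 20, 40, 65)) {
    pf <- plane_at(actr, i)
    tan_i <- c(-sin(th[i]), 0, cos(th[i]))
    ang <- acos(pmin(abs(sum(pf$normal * tan_i)), 1))
    expect_lt(ang, dth)
  }
  # coincident consecutive points fall back to the nearest distinct neighbor
  dup <- rbind(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0))
  dctr <- structure(list(points = dup, n = 3L), class = "centerline")
  expect_equal(plane_at(dctr, 1)$normal, c(1, 0, 0))
  allsame <- structure(list(points = matrix(1, 3, 3), n = 3L),
                       class = "centerline")
  expect_error(plane_at(allsame, 2), "degenerate")
})

test_that("ray-cast contours recover a spherical cross-section", {
  # sphere of radius 5 mm on a 1 mm grid
  dimv <- c(16, 16, 16)
  idx <- as.matrix(expand.grid(1:16, 1:16, 1:16))
  ctrs <- idx - 0.5
  center <- c(8, 8, 8)
  inside <- sqrt(rowSums(sweep(ctrs, 2, center)^2)) <= 5
  mask <- binary_mask(array(as.integer(inside), dimv), voxel_size = 1)
  plane <- structure(list(origin = center, normal = c(0, 0, 1),
                          u = c(1, 0, 0), v = c(0, 1, 0)),
                     class = "plane_frame")
  ctr <- trace_contour(plane, mask, n_rays = 36, ray_step_mm = 0.5)
  expect_equal(length(ctr$radii), 36)
  expect_equal(diff(ctr$ray_angles), rep(2 * pi / 36, 35), tolerance = 1e-12)
  diag3 <- sqrt(3)  # voxelization tolerance on a 1 mm grid
  expect_true(all(ctr$radii >= 5 - diag3 & ctr$radii <= 5 + 0.5 + diag3))
  # coefficient of variation below the voxelization bound
  expect_lt(stats::sd(ctr$radii) / mean(ctr$radii), 0.15)
  expect_false(any(ctr$capped))
  # spline outline is closed
  ns <- nrow(ctr$spline_samples)
  expect_equal(ctr$spline_samples[1, ], ctr$spline_samples[ns, ])
  # single-voxel mask: minimal radii
  one <- array(0L, dimv); one[8, 8, 8] <- 1L
  m1 <- binary_mask(one, 1)
  p1 <- plane; p1$origin <- c(7.5, 7.5, 7.5)
  c1 <- trace_contour(p1, m1, n_rays = 12, ray_step_mm = 0.25)
  expect_true(all(c1$radii <= sqrt(3) + 0.25))
  # origin outside the mask errors
  pout <- plane; pout$origin <- c(1, 1, 1)
  expect_error(trace_contour(pout, mask), "outside")
})

test_that("contour scaling moves radii outward and grows the enclosed area", {
  angles <- 2 * pi * (0:35) / 36
  ctr <- retrack:::contour_from_radii(
    structure(list(origin = c(0, 0, 0), normal = c(0, 0, 1),
                   u = c(1, 0, 0), v = c(0, 1, 0)), class = "plane_frame"),
    angles, rep(5, 36), rep(FALSE, 36))
  expect_identical(scale_contour(ctr, 0), ctr)
  s1 <- scale_contour(ctr, 1)
  expect_equal(s1$radii, rep(6, 36))
  # enclosed spline area strictly increases with scaling
  areas <- vapply(0:5, function(sc)
    polygon_area(scale_contour(ctr, sc)$spline_samples), 1.0)
  expect_true(all(diff(areas) > 0))
  expect_equal(areas[1], pi * 25, tolerance = 0.01 * pi * 25)
})

test_that("in-contour seed grids fill the region and stay on the plane", {
  plane <- structure(list(origin = c(3, 4, 5),
                          normal = c(0, 1, 1) / sqrt(2),
                          u = c(1, 0, 0),
                          v = c(0, 1, -1) / sqrt(2)), class = "plane_frame")
  angles <- 2 * pi * (0:35) / 36
  ctr <- retrack:::contour_from_radii(plane, angles, rep(5, 36), rep(FALSE, 36))
  # spacing chosen so no grid point falls exactly on the circle boundary
  seeds <- seed_points_in_contour(ctr, 0.9)
  expect_lt(abs(nrow(seeds) - pi * 25 / 0.81) / (pi * 25 / 0.81), 0.10)
  offs <- sweep(seeds, 2, plane$origin)
  expect_lt(max(abs(offs %*% plane$normal)), 1e-9)
  expect_true(any(rowSums(offs^2) < 1e-18))  # origin included
  # degenerate near-zero contour: exactly the origin
  tiny <- retrack:::contour_from_radii(plane, angles, rep(1e-6, 36),
                                       rep(FALSE, 36))
  st <- seed_points_in_contour(tiny, 1)
  expect_equal(nrow(st), 1)
  expect_equal(st[1, ], plane$origin)
})

test_that("seed-plane indices are equally spaced with endpoints included", {
  expect_equal(select_plane_indices(129, 5), c(0, 32, 64, 96, 128) + 1)
  expect_equal(select_plane_indices(129, 2), c(1, 129))
  expect_equal(select_plane_indices(129, 129), 1:129)
  expect_equal(select_plane_indices(129, 3), c(1, 65, 129))
  expect_error(select_plane_indices(10, 11), "exceeds")
  for (ns in c(2, 3, 5, 9, 17, 33, 65, 129)) {
    idx <- select_plane_indices(129, ns)
    expect_length(idx, ns)
    expect_true(all(diff(idx) > 0))
  }
})
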