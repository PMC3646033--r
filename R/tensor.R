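# Diffusion tensor estimation and per-tensor scalar measures.

#' Diffusion tensor field
#'
#' @param coef 4D array (nx, ny, nz, 6) of unique tensor coefficients in the
#'   order Dxx, Dxy, Dxz, Dyy, Dyz, Dzz (mm^2/s).
#' @param voxel_size,origin grid geometry (see package conventions).
#' @param n_clamped number of voxels whose negative eigenvalues were clamped
#'   during fitting (0 for synthetic fields).
#' @return A `tensor_field` object.
#' @export
tensor_field <- function(coef, voxel_size = 2, origin = c(0, 0, 0),
                         n_clamped = 0L) {
  stopifnot(length(dim(coef)) == 4, dim(coef)[4] == 6)
  structure(list(coef = coef, voxel_size = as.numeric(voxel_size),
                 origin = as.numeric(origin), n_clamped = as.integer(n_clamped)),
            class = "tensor_field")
}

#' @export
print.tensor_field <- function(x, ...) {
  cat(sprintf("<tensor_field> %s @ %g mm%s\n",
              paste(dim(x$coef)[1:3], collapse = "x"), x$voxel_size,
              if (x$n_clamped > 0) sprintf(" (%d voxels clamped)", x$n_clamped)
              else ""))
  invisible(x)
}

# accept a 3x3 symmetric matrix or a length-6 coefficient vector
as_coef6 <- function(t) {
  if (is.matrix(t)) {
    stopifnot(nrow(t) == 3, ncol(t) == 3,
              isTRUE(all.equal(t, (t + base::t(t)) / 2, tolerance = 1e-8)))
    c(t[1, 1], t[1, 2], t[1, 3], t[2, 2], t[2, 3], t[3, 3])
  } else {
    stopifnot(length(t) == 6)
    as.numeric(t)
  }
}

coef6_to_matrix <- function(d) {
  matrix(c(d[1], d[2], d[3],
           d[2], d[4], d[5],
           d[3], d[5], d[6]), 3, 3)
}

#' Log-linear least-squares tensor fit
#'
#' Per voxel, ordinary least squares on `log(S_k / S0) = -b g_k' D g_k` over
#' all diffusion-weighted entries of the scheme, with `S0` taken as the mean
#' of the b=0 entries.  Requires at least 6 non-collinear directions plus a
#' b=0 image.  Negative eigenvalues (from noise) are clamped to zero and the
#' affected voxel count recorded in `n_clamped`.
#'
#' @param dwi a `dwi_volume`.
#' @param weighted use weighted least squares with weights `S_k^2` (the
#'   standard first-order variance correction for log-transformed signals).
#' @param clamp clamp negative eigenvalues to zero (default TRUE).
#' @return A `tensor_field`.
#' @export
fit_tensor_loglinear <- function(dwi, weighted = FALSE, clamp = TRUE) {
  stopifnot(inherits(dwi, "dwi_volume"))
  scheme <- dwi$scheme
  is_b0 <- scheme$bval == 0
  if (!any(is_b0)) stop("gradient scheme has no b=0 entry")
  if (sum(!is_b0) < 6) stop("need at least 6 diffusion-weighted directions")
  dimv <- dim(dwi$signals)[1:3]
  nvox <- prod(dimv)
  sig <- matrix(dwi$signals, nrow = nvox)        # voxels x entries
  eps <- .Machine$double.eps * max(sig)
  s0 <- rowMeans(sig[, is_b0, drop = FALSE])
  s0 <- pmax(s0, eps)

  g <- as.matrix(scheme[!is_b0, c("gx", "gy", "gz")])
  b <- scheme$bval[!is_b0]
  # design matrix for the 6 unique coefficients
  B <- cbind(g[, 1]^2, 2 * g[, 1] * g[, 2], 2 * g[, 1] * g[, 3],
             g[, 2]^2, 2 * g[, 2] * g[, 3], g[, 3]^2) * b
  if (qr(B)$rank < 6) stop("rank-deficient design matrix: gradient directions are collinear")

  sk <- pmax(sig[, !is_b0, drop = FALSE], eps)
  Y <- -log(sk / s0)                              # voxels x directions
  if (!weighted) {
    # one shared normal-equation solve for all voxels
    coef <- Y %*% B %*% solve(crossprod(B))       # voxels x 6
  } else {
    coef <- matrix(0, nvox, 6)
    W <- sk^2
    for (v in seq_len(nvox)) {
      BW <- B * W[v, ]
      coef[v, ] <- solve(crossprod(B, BW), crossprod(BW, Y[v, ]))
    }
  }
  coef <- array(coef, dim = c(dimv, 6))
  n_clamped <- 0L
  if (clamp) {
    cl <- .cpp_clamp_tensors(coef, as.integer(dimv))
    coef <- array(cl$coef, dim = c(dimv, 6))
    n_clamped <- as.integer(cl$n_clamped)
  }
  tensor_field(coef, voxel_size = dwi$voxel_size, origin = dwi$origin,
               n_clamped = n_clamped)
}

#' Principal eigenvector of a diffusion tensor
#'
#' Unit eigenvector of the largest eigenvalue, with a fixed sign convention
#' (nonnegative x component; ties broken on y, then z).  Degenerate tensors
#' (all eigenvalues equal) still return a valid unit vector, flagged via the
#' `degenerate` attribute.
#'
#' @param t 3x3 symmetric matrix or length-6 coefficient vector.
#' @return Unit 3-vector with attributes `lambda1` and `degenerate`.
#' @export
principal_eigenvector <- function(t) {
  d <- as_coef6(t)
  v <- .cpp_principal_eigenvector(d)
  ev <- eigen(coef6_to_matrix(d), symmetric = TRUE, only.values = TRUE)$values
  attr(v, "degenerate") <- isTRUE(all.equal(ev[1], ev[3])) ||
    (ev[1] - ev[2]) <= 1e-12 * max(abs(ev[1]), 1e-300)
  v
}

#' Fractional anisotropy
#'
#' `FA = sqrt(3/2) * ||lambda - mean(lambda)|| / ||lambda||`, computed from
#' rotation-invariant tensor norms; 0 for the zero tensor by convention.
#'
#' @param t 3x3 symmetric matrix or length-6 coefficient vector.
#' @return Scalar in `[0, 1]`.
#' @export
fractional_anisotropy <- function(t) {
  as.numeric(.cpp_fa6(matrix(as_coef6(t), nrow = 1)))
}

#' Voxel-wise fractional anisotropy map
#'
#' @param field a `tensor_field`.
#' @return 3D array of FA values.
#' @export
fa_map <- function(field) {
  stopifnot(inherits(field, "tensor_field"))
  dimv <- dim(field$coef)[1:3]
  array(.cpp_fa6(matrix(field$coef, ncol = 6)), dim = dimv)
}

#' Interpolate the tensor field at a world point
#'
#' Component-wise trilinear interpolation of the 6 coefficients (interpolating
#' coefficients rather than eigenvectors avoids sign-flip artifacts).
#'
#' @param field a `tensor_field`.
#' @param p world-mm point (length 3).
#' @return Length-6 coefficient vector, or `NULL` when `p` lies outside the
#'   field bounding box (the tracking-termination signal).
#' @export
interpolate_tensor <- function(field, p) {
  stopifnot(inherits(field, "tensor_field"), length(p) == 3)
  out <- .cpp_interp_tensor(field$coef, dim(field$coef)[1:3],
                            field$voxel_size, field$origin, as.numeric(p))
  if (anyNA(out)) return(NULL)
  out
}
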