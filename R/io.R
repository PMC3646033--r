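# File input/output: NIfTI volumes, FSL bval/bvec tables, TrackVis TRK
# streamlines, JSON-lines debug streamlines and provenance records.
#
# Only axis-aligned NIfTI geometries are supported: the method is
# geometry-light and oblique/sheared affines are rejected with a clear
# message rather than silently mishandled.

#' Write a 3D/4D volume as NIfTI-1
#'
#' @param grid 3D or 4D array.
#' @param geometry a `grid_geometry` (or object carrying one).
#' @param path output path (`.nii` or `.nii.gz`).
#' @param datatype storage type passed to RNifti (e.g. "uint8", "int16",
#'   "float"); default chooses "float" for numeric, "uint8" for 0/1 integer.
#' @return `path`, invisibly.
#' @export
write_volume <- function(grid, geometry, path, datatype = NULL) {
  geom <- geometry_of(geometry)
  if (is.null(datatype)) {
    datatype <- if (is.integer(grid) && max(grid) <= 255 && min(grid) >= 0)
      "uint8" else "float"
  }
  img <- RNifti::asNifti(grid)
  vs <- geom$voxel_size
  aff <- rbind(cbind(diag(vs, 3), geom$origin + vs / 2), c(0, 0, 0, 1))
  RNifti::`qform<-`(img, structure(aff, code = 2L)) -> img
  RNifti::pixdim(img) <- c(rep(vs, 3), rep(1, length(dim(grid)) - 3))
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Read a NIfTI-1 volume with axis-aligned geometry
#'
#' @param path NIfTI file.
#' @return List with `grid` (array), `voxel_size`, `origin` (corner of the
#'   first voxel, package convention).
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  x <- RNifti::xform(img)
  if (max(abs(x[1:3, 1:3] - diag(diag(x[1:3, 1:3])))) > 1e-4 ||
      any(diag(x[1:3, 1:3]) < 0))
    stop("unsupported geometry: only axis-aligned, positively oriented NIfTI volumes are handled")
  vs <- diag(x[1:3, 1:3])
  if (max(abs(vs - vs[1])) > 1e-4 * vs[1])
    stop("unsupported geometry: anisotropic voxels")
  grid <- array(as.vector(img), dim = dim(img))
  list(grid = grid, voxel_size = vs[1], origin = as.numeric(x[1:3, 4]) - vs[1] / 2)
}

#' Read a binary mask volume
#'
#' @param path NIfTI file.
#' @return A `binary_mask`.
#' @export
read_mask <- function(path) {
  v <- read_volume(path)
  binary_mask(v$grid, v$voxel_size, v$origin)
}

#' Write/read FSL-style gradient tables
#'
#' `.bval` holds one row of b-values, `.bvec` three rows (x, y, z) of unit
#' direction components, one column per volume.
#'
#' @param scheme a [gradient_scheme()].
#' @param bval_path,bvec_path output paths.
#' @return Paths, invisibly.
#' @export
write_bvals_bvecs <- function(scheme, bval_path, bvec_path) {
  writeLines(paste(format(scheme$bval, trim = TRUE), collapse = " "), bval_path)
  writeLines(c(paste(format(scheme$gx, digits = 17, trim = TRUE), collapse = " "),
               paste(format(scheme$gy, digits = 17, trim = TRUE), collapse = " "),
               paste(format(scheme$gz, digits = 17, trim = TRUE), collapse = " ")),
             bvec_path)
  invisible(c(bval_path, bvec_path))
}

#' @rdname write_bvals_bvecs
#' @return For the reader: a `gradient_scheme` data frame.
#' @export
read_bvals_bvecs <- function(bval_path, bvec_path) {
  bval <- scan(bval_path, quiet = TRUE)
  bvec <- as.matrix(utils::read.table(bvec_path))
  if (nrow(bvec) != 3) stop("bvec file must have 3 rows")
  if (ncol(bvec) != length(bval))
    stop(sprintf("bvec entry count (%d) does not match bval count (%d)",
                 ncol(bvec), length(bval)))
  out <- data.frame(bval = bval, gx = bvec[1, ], gy = bvec[2, ], gz = bvec[3, ])
  class(out) <- c("gradient_scheme", "data.frame")
  out
}

#' Read a DWI data set (NIfTI + bval/bvec)
#'
#' @param dwi_path 4D NIfTI file.
#' @param bval_path,bvec_path gradient table files.
#' @return A `dwi_volume`.
#' @export
read_dwi <- function(dwi_path, bval_path, bvec_path) {
  v <- read_volume(dwi_path)
  if (length(dim(v$grid)) != 4) stop("DWI volume must be 4D")
  scheme <- read_bvals_bvecs(bval_path, bvec_path)
  if (dim(v$grid)[4] != nrow(scheme))
    stop(sprintf("DWI has %d volumes but the gradient table has %d entries",
                 dim(v$grid)[4], nrow(scheme)))
  structure(list(signals = v$grid, scheme = scheme,
                 voxel_size = v$voxel_size, origin = v$origin),
            class = "dwi_volume")
}

#' Write a tensor field as NIfTI (plus optional FA map)
#'
#' The 4th dimension holds the 6 unique coefficients in the order Dxx, Dxy,
#' Dxz, Dyy, Dyz, Dzz.
#'
#' @param field a `tensor_field`.
#' @param path output NIfTI path.
#' @param fa_path optional FA map output path.
#' @return `path`, invisibly.
#' @export
write_tensor_field <- function(field, path, fa_path = NULL) {
  write_volume(field$coef, field, path, datatype = "double")
  if (!is.null(fa_path)) write_volume(fa_map(field), field, fa_path)
  invisible(path)
}

#' Read a tensor field written by [write_tensor_field()]
#'
#' @param path NIfTI path (4D, 6 components).
#' @return A `tensor_field`.
#' @export
read_tensor_field <- function(path) {
  v <- read_volume(path)
  if (length(dim(v$grid)) != 4 || dim(v$grid)[4] != 6)
    stop("tensor volume must be 4D with 6 components")
  tensor_field(v$grid, v$voxel_size, v$origin)
}

# ---------------------------------------------------------------------------
# TrackVis TRK streamline format (little-endian, 1000-byte header, version 2).
# Points are stored in the format's voxel-mm frame, i.e. world mm relative to
# the grid corner; the reader restores world coordinates from the header.

trk_pad <- function(n) raw(n)

#' Write streamlines as a TrackVis TRK file
#'
#' @param bundle a `streamline_bundle`.
#' @param path output `.trk` path.
#' @param geometry a `grid_geometry` (or carrier) supplying the header's
#'   dimensions, voxel size and origin.
#' @return `path`, invisibly.
#' @export
write_trk <- function(bundle, path, geometry) {
  stopifnot(inherits(bundle, "streamline_bundle"))
  geom <- geometry_of(geometry)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(charToRaw("TRACK"), as.raw(0)), con)
  writeBin(as.integer(geom$dim), con, size = 2, endian = "little")
  writeBin(rep(geom$voxel_size, 3), con, size = 4, endian = "little")
  writeBin(as.numeric(geom$origin), con, size = 4, endian = "little")
  writeBin(0L, con, size = 2, endian = "little")       # n_scalars
  writeBin(trk_pad(200), con)
  writeBin(0L, con, size = 2, endian = "little")       # n_properties
  writeBin(trk_pad(200), con)
  vox2ras <- rbind(cbind(diag(1, 3), as.numeric(geom$origin)), c(0, 0, 0, 1))
  writeBin(as.numeric(t(vox2ras)), con, size = 4, endian = "little")
  writeBin(trk_pad(444), con)                          # reserved
  writeBin(c(charToRaw("RAS"), as.raw(0)), con)        # voxel_order
  writeBin(trk_pad(4), con)                            # pad2
  writeBin(as.numeric(c(1, 0, 0, 0, 1, 0)), con, size = 4, endian = "little")
  writeBin(trk_pad(2), con)                            # pad1
  writeBin(trk_pad(6), con)                            # invert/swap flags
  writeBin(length(bundle$streamlines), con, size = 4, endian = "little")
  writeBin(2L, con, size = 4, endian = "little")       # version
  writeBin(1000L, con, size = 4, endian = "little")    # hdr_size
  for (s in bundle$streamlines) {
    writeBin(nrow(s), con, size = 4, endian = "little")
    pts <- sweep(s, 2, geom$origin)                    # world -> voxel-mm
    writeBin(as.numeric(t(pts)), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read a TrackVis TRK file
#'
#' @param path `.trk` path.
#' @return A list: `bundle` (`streamline_bundle` in world mm), `dim`,
#'   `voxel_size`, `origin`.
#' @export
read_trk <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  id <- readBin(con, "raw", 6)
  if (!identical(rawToChar(id[1:5]), "TRACK")) stop("malformed TRK header: bad id string")
  dimv <- readBin(con, "integer", 3, size = 2, endian = "little")
  vox <- readBin(con, "numeric", 3, size = 4, endian = "little")
  origin <- readBin(con, "numeric", 3, size = 4, endian = "little")
  n_scalars <- readBin(con, "integer", 1, size = 2, endian = "little")
  invisible(readBin(con, "raw", 200))
  n_props <- readBin(con, "integer", 1, size = 2, endian = "little")
  invisible(readBin(con, "raw", 200))
  invisible(readBin(con, "numeric", 16, size = 4, endian = "little"))
  invisible(readBin(con, "raw", 444 + 4 + 4))
  invisible(readBin(con, "numeric", 6, size = 4, endian = "little"))
  invisible(readBin(con, "raw", 2 + 6))
  n_count <- readBin(con, "integer", 1, size = 4, endian = "little")
  version <- readBin(con, "integer", 1, size = 4, endian = "little")
  hdr_size <- readBin(con, "integer", 1, size = 4, endian = "little")
  if (hdr_size != 1000) stop("malformed TRK header: hdr_size != 1000")
  lines <- vector("list", n_count)
  for (i in seq_len(n_count)) {
    np <- readBin(con, "integer", 1, size = 4, endian = "little")
    dat <- readBin(con, "numeric", np * (3 + n_scalars), size = 4,
                   endian = "little")
    m <- matrix(dat, ncol = 3 + n_scalars, byrow = TRUE)[, 1:3, drop = FALSE]
    if (n_props > 0) invisible(readBin(con, "numeric", n_props, size = 4,
                                       endian = "little"))
    lines[[i]] <- sweep(m, 2, origin, "+")             # voxel-mm -> world
  }
  list(bundle = streamline_bundle(lines), dim = dimv, voxel_size = vox[1],
       origin = origin)
}

#' Write/read streamlines as JSON lines (debug format)
#'
#' One streamline per line, each a JSON array of `[x, y, z]` world-mm points.
#'
#' @param bundle a `streamline_bundle`.
#' @param path output path.
#' @return Paths/bundles, invisibly for the writer.
#' @export
write_streamlines_json <- function(bundle, path) {
  lines <- vapply(bundle$streamlines, function(s)
    as.character(jsonlite::toJSON(unname(s), digits = NA)), "")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_streamlines_json
#' @export
read_streamlines_json <- function(path) {
  lines <- readLines(path)
  streamline_bundle(lapply(lines, function(l) {
    m <- jsonlite::fromJSON(l)
    matrix(as.numeric(m), ncol = 3)
  }))
}

#' Write a provenance record
#'
#' Every pipeline run records its full configuration (including defaulted
#' parameters), the package version, the RNG seed and the coordinate
#' convention as JSON next to its outputs.
#'
#' @param path output JSON path.
#' @param config named list of parameters.
#' @param seed RNG seed used (or NA).
#' @return `path`, invisibly.
#' @export
write_provenance <- function(path, config, seed = NA_integer_) {
  rec <- list(
    package = "retrack",
    version = as.character(utils::packageVersion("retrack")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    rng_seed = seed,
    coordinates = "world mm; voxel centers at origin + (index - 0.5) * voxel_size, 1-based indices",
    config = config)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(path)
}
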