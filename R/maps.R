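# ESP map container and MRC/CCP4 (mode 2) input/output.
#
# A cryo-EM map is a 3-D scalar field of electrostatic potential (ESP);
# values are conventionally interpreted in units of the map standard
# deviation (sigma) after rescaling.

#' Construct an ESP map object
#'
#' @param grid 3-D numeric array, x index fastest (axis order x, y, z).
#' @param voxel_size Voxel edge length(s) in Angstrom; length 1 or 3.
#' @param origin Cartesian position (Angstrom) of grid node (1,1,1).
#' @param rescaled Logical; `TRUE` if values are in map-sigma units
#'   (mean 0, sd 1).
#' @return An `esp_map` object: list with `grid`, `voxel_size`, `origin`,
#'   `mean`, `sigma` (population sd), `rescaled`.
#' @export
esp_map <- function(grid, voxel_size, origin = c(0, 0, 0), rescaled = FALSE) {
  stopifnot(is.array(grid), length(dim(grid)) == 3L)
  voxel_size <- rep_len(as.numeric(voxel_size), 3L)
  if (any(!is.finite(voxel_size)) || any(voxel_size <= 0))
    stop("voxel_size must be positive and finite")
  origin <- rep_len(as.numeric(origin), 3L)
  m <- mean(grid)
  s <- sqrt(mean((grid - m)^2))   # population sd: cryo-EM map-sigma convention
  obj <- structure(
    list(grid = grid, voxel_size = voxel_size, origin = origin,
         mean = m, sigma = s, rescaled = isTRUE(rescaled)),
    class = "esp_map")
  if (obj$rescaled && (abs(m) > 1e-6 || abs(s - 1) > 1e-6))
    stop("map flagged rescaled but mean/sigma are not 0/1")
  obj
}

#' @export
print.esp_map <- function(x, ...) {
  d <- dim(x$grid)
  cat(sprintf("esp_map: %d x %d x %d voxels, voxel %.3g/%.3g/%.3g A, origin (%.3g, %.3g, %.3g)\n",
              d[1], d[2], d[3], x$voxel_size[1], x$voxel_size[2], x$voxel_size[3],
              x$origin[1], x$origin[2], x$origin[3]))
  cat(sprintf("  mean %.4g  sigma %.4g  rescaled %s\n", x$mean, x$sigma, x$rescaled))
  invisible(x)
}

#' Rescale a map to sigma units
#'
#' Transforms values to `(v - mean) / sigma` so the result has mean 0 and
#' standard deviation 1; contour levels on the result are in map-sigma units.
#' Idempotent on already-rescaled input.
#'
#' @param map An `esp_map`.
#' @return A rescaled `esp_map`.
#' @export
rescale_map <- function(map) {
  stopifnot(inherits(map, "esp_map"))
  if (map$sigma <= 0) stop("cannot rescale a constant map (sigma = 0)")
  esp_map((map$grid - map$mean) / map$sigma, map$voxel_size, map$origin,
          rescaled = TRUE)
}

#' Sample a map by trilinear interpolation
#'
#' Interpolates grid values at arbitrary Cartesian points. Points must lie
#' inside the grid extent; the map is treated as a non-periodic box, so
#' out-of-box sampling is an error rather than a wrap.
#'
#' @param map An `esp_map`.
#' @param points n x 3 matrix (or length-3 vector) of Cartesian coordinates
#'   in Angstrom.
#' @return Numeric vector of interpolated values, length n.
#' @export
sample_map <- function(map, points) {
  stopifnot(inherits(map, "esp_map"))
  p <- rbind(points)
  if (ncol(p) != 3L) stop("points must be n x 3")
  d <- dim(map$grid)
  # fractional grid coordinates, 0-based
  f <- sweep(sweep(p, 2, map$origin), 2, map$voxel_size, "/")
  eps <- 1e-9
  bad <- f[, 1] < -eps | f[, 1] > d[1] - 1 + eps |
         f[, 2] < -eps | f[, 2] > d[2] - 1 + eps |
         f[, 3] < -eps | f[, 3] > d[3] - 1 + eps
  if (any(bad))
    stop(sprintf("sample_map: %d point(s) outside map extent (first: %.3f, %.3f, %.3f)",
                 sum(bad), p[which(bad)[1], 1], p[which(bad)[1], 2], p[which(bad)[1], 3]))
  f <- pmin(pmax(f, 0), matrix(d - 1, nrow(f), 3, byrow = TRUE))
  i0 <- pmin(floor(f), matrix(d - 2, nrow(f), 3, byrow = TRUE))
  i0 <- pmax(i0, 0)
  w <- f - i0
  g <- map$grid
  idx <- function(dx, dy, dz)
    g[cbind(i0[, 1] + dx + 1, i0[, 2] + dy + 1, i0[, 3] + dz + 1)]
  v000 <- idx(0, 0, 0); v100 <- idx(1, 0, 0)
  v010 <- idx(0, 1, 0); v110 <- idx(1, 1, 0)
  v001 <- idx(0, 0, 1); v101 <- idx(1, 0, 1)
  v011 <- idx(0, 1, 1); v111 <- idx(1, 1, 1)
  wx <- w[, 1]; wy <- w[, 2]; wz <- w[, 3]
  c00 <- v000 * (1 - wx) + v100 * wx
  c10 <- v010 * (1 - wx) + v110 * wx
  c01 <- v001 * (1 - wx) + v101 * wx
  c11 <- v011 * (1 - wx) + v111 * wx
  c0 <- c00 * (1 - wy) + c10 * wy
  c1 <- c01 * (1 - wy) + c11 * wy
  as.vector(c0 * (1 - wz) + c1 * wz)
}

# ---------------------------------------------------------------------------
# MRC/CCP4 format (MRC2014, mode 2 = 32-bit float), little-endian.
# Axis order is fixed to mapc,mapr,maps = 1,2,3 (x fastest); maps with a
# permuted axis order are rejected rather than silently reordered.

#' Read an MRC/CCP4 map
#'
#' Reads a mode-2 (32-bit float) MRC/CCP4 file. Origin precedence follows
#' the MRC2014 convention used by most cryo-EM software: the ORIGIN header
#' field if any component is nonzero, otherwise `nstart * voxel`.
#'
#' @param path Path to the map file.
#' @return An `esp_map`.
#' @export
read_map <- function(path) {
  if (!file.exists(path)) stop("map file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_int <- readBin(con, "integer", n = 256, size = 4, endian = "little")
  seek(con, 0)
  hdr_num <- readBin(con, "numeric", n = 256, size = 4, endian = "little")
  nxyz <- hdr_int[1:3]
  mode <- hdr_int[4]
  nstart <- hdr_int[5:7]
  mxyz <- hdr_int[8:10]
  cella <- hdr_num[11:13]
  mapcrs <- hdr_int[17:19]
  orig <- hdr_num[50:52]
  if (mode != 2L) stop("read_map: only mode 2 (float32) supported, got mode ", mode)
  if (any(nxyz <= 0) || any(mxyz <= 0))
    stop("read_map: invalid header dimensions")
  if (!identical(mapcrs, c(1L, 2L, 3L)))
    stop("read_map: unsupported axis order (mapc,mapr,maps = ",
         paste(mapcrs, collapse = ","), ")")
  nsymbt <- hdr_int[24]
  nvox <- prod(nxyz)
  expected <- 1024 + nsymbt + 4 * nvox
  if (file.size(path) < expected)
    stop(sprintf("read_map: file truncated (%d bytes, expected >= %d)",
                 file.size(path), expected))
  seek(con, 1024 + nsymbt)
  vals <- readBin(con, "numeric", n = nvox, size = 4, endian = "little")
  if (length(vals) != nvox) stop("read_map: data block shorter than header claims")
  voxel <- cella / mxyz
  origin <- if (any(abs(orig) > 0)) orig else nstart * voxel
  esp_map(array(vals, dim = nxyz), voxel_size = voxel, origin = origin)
}

#' Write an MRC/CCP4 map
#'
#' Writes a mode-2 MRC2014 file with the map origin stored in the ORIGIN
#' header field.
#'
#' @param map An `esp_map`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_map <- function(map, path) {
  stopifnot(inherits(map, "esp_map"))
  d <- dim(map$grid)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  vals <- as.vector(map$grid)
  wi(d)                       # nx ny nz
  wi(2)                       # mode 2 float
  wi(c(0, 0, 0))              # nstart
  wi(d)                       # mx my mz (sampling = grid)
  wf(d * map$voxel_size)      # cella
  wf(c(90, 90, 90))           # cellb
  wi(c(1, 2, 3))              # mapc mapr maps
  wf(c(min(vals), max(vals), mean(vals)))  # dmin dmax dmean
  wi(1)                       # ispg (P1)
  wi(0)                       # nsymbt
  wi(rep(0L, 25))             # extra words 26-49
  wf(map$origin)              # origin x y z (words 50-52)
  writeChar("MAP ", con, nchars = 4, eos = NULL)          # word 53
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)        # machine stamp
  wf(sqrt(mean((vals - mean(vals))^2)))                   # rms
  wi(1)                       # nlabl
  lab <- formatC("chlfscan synthetic/processed ESP map", width = -80)
  writeChar(lab, con, nchars = 80, eos = NULL)
  writeChar(strrep(" ", 80 * 9), con, nchars = 720, eos = NULL)
  wf(vals)
  invisible(path)
}
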