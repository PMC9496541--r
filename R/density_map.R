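#' Cryo-EM density map
#'
#' A minimal in-memory representation of a cryo-EM density map: a 3D array
#' of density values on a regular grid, together with the voxel size and
#' the Cartesian position (in Angstrom) of grid index (1,1,1).
#'
#' @param values 3D numeric array of density values (arbitrary map units).
#' @param voxel_size numeric length-1 or length-3, Angstrom per grid step.
#' @param origin numeric length-3, Angstrom offset of grid index (1,1,1).
#' @param name free-text identifier.
#' @return An object of class `density_map`.
#' @export
density_map <- function(values, voxel_size, origin = c(0, 0, 0), name = "") {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array")
  if (any(dim(values) < 2L))
    stop("grid must have at least 2 points along each axis")
  if (!all(is.finite(values)))
    stop("density values must be finite")
  voxel_size <- rep_len(as.numeric(voxel_size), 3L)
  if (any(voxel_size <= 0))
    stop("voxel_size components must be > 0")
  structure(
    list(values = values, voxel_size = voxel_size,
         origin = as.numeric(origin), name = as.character(name)[1]),
    class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<density_map '%s'> %d x %d x %d voxels, %.3g x %.3g x %.3g A/voxel\n",
              x$name, d[1], d[2], d[3],
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  cat(sprintf("  origin (A): %.2f %.2f %.2f; density range [%.3g, %.3g]\n",
              x$origin[1], x$origin[2], x$origin[3],
              min(x$values), max(x$values)))
  invisible(x)
}

#' Cartesian coordinates of grid indices
#'
#' @param map a `density_map`.
#' @param ijk integer matrix of 1-based grid indices (n x 3).
#' @return n x 3 matrix of Angstrom coordinates in the map frame.
#' @export
grid_to_xyz <- function(map, ijk) {
  ijk <- matrix(as.numeric(ijk), ncol = 3L)
  sweep(sweep(ijk - 1, 2L, map$voxel_size, "*"), 2L, map$origin, "+")
}

# ---- MRC/CCP4 I/O ------------------------------------------------------
# Minimal mode-2 (float32) reader/writer. Honors the axis-order words
# (mapc/mapr/maps) and the origin / nxstart header fields.

#' Read an MRC/CCP4 density map (mode 2)
#'
#' @param path file path.
#' @param name identifier stored on the returned map (defaults to the file
#'   name).
#' @return a [density_map()].
#' @export
read_mrc <- function(path, name = basename(path)) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_int <- readBin(con, "integer", n = 256L, size = 4L, endian = "little")
  seek(con, 0L)
  hdr_num <- readBin(con, "numeric", n = 256L, size = 4L, endian = "little")
  nxyz <- hdr_int[1:3]
  mode <- hdr_int[4]
  if (mode != 2L)
    stop("only MRC mode 2 (float32) is supported; got mode ", mode)
  nstart <- hdr_int[5:7]
  mxyz <- hdr_int[8:10]
  cella <- hdr_num[11:13]
  axis_order <- hdr_int[17:19]            # mapc, mapr, maps
  origin <- hdr_num[50:52]                # MRC2014 origin, Angstrom
  nsymbt <- hdr_int[24]
  seek(con, 1024L + nsymbt)
  vals <- readBin(con, "numeric", n = prod(nxyz), size = 4L, endian = "little")
  arr <- array(vals, dim = nxyz)
  voxel <- cella / mxyz
  if (!all(axis_order == 1:3)) {
    perm <- order(axis_order)              # file axis -> xyz axis
    arr <- aperm(arr, perm)
    nstart <- nstart[perm]                 # cella/mxyz are already in xyz
  }
  if (all(origin == 0) && any(nstart != 0))
    origin <- nstart * voxel
  density_map(arr, voxel_size = voxel, origin = origin, name = name)
}

#' Write a density map as MRC mode 2
#'
#' @param map a [density_map()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_mrc <- function(map, path) {
  d <- dim(map$values)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  wi(d); wi(2L)                      # nx ny nz, mode
  wi(c(0L, 0L, 0L)); wi(d)           # nstart, mx my mz
  wf(d * map$voxel_size)             # cella
  wf(c(90, 90, 90))                  # cellb
  wi(1:3)                            # mapc mapr maps
  wf(c(min(map$values), max(map$values), mean(map$values)))
  wi(c(1L, 0L))                      # ispg, nsymbt
  wi(rep(0L, 25L))                   # extra
  wf(map$origin)                     # origin
  writeChar("MAP ", con, nchars = 4L, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # machst, little-endian
  wf(stats::sd(map$values))
  wi(0L)                             # nlabl
  writeBin(raw(800L), con)           # labels
  writeBin(as.numeric(map$values), con, size = 4L, endian = "little")
  invisible(path)
}
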