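#' Write a volume or image as an MRC2014 mode-2 file
#'
#' Little-endian float32 data with the voxel size carried in the header
#' cell fields (Angstrom, per the MRC standard). Accepts a
#' [density_map()], `tomogram`, 2-D matrix or plain 3-D array.
#'
#' @param x the data to write.
#' @param path output path.
#' @param voxel_size_nm voxel size; taken from the object when it carries
#'   one.
#' @return `path`, invisibly.
#' @export
write_mrc <- function(x, path, voxel_size_nm = NULL) {
  if (inherits(x, c("density_map", "tomogram"))) {
    voxel_size_nm <- x$voxel_size_nm
    data <- x$data
  } else {
    data <- x
  }
  if (is.null(voxel_size_nm)) stop("voxel_size_nm required for bare arrays")
  if (is.matrix(data)) data <- array(data, c(dim(data), 1L))
  stopifnot(length(dim(data)) == 3)
  d <- dim(data)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(v) writeBin(as.integer(v), con, size = 4, endian = "little")
  wf <- function(v) writeBin(as.numeric(v), con, size = 4, endian = "little")
  wi(d)                          # nx ny nz
  wi(2L)                         # mode 2 = float32
  wi(c(0L, 0L, 0L))              # nxstart
  wi(d)                          # mx my mz
  wf(d * voxel_size_nm * 10)     # cella (Angstrom)
  wf(c(90, 90, 90))              # cellb
  wi(c(1L, 2L, 3L))              # mapc mapr maps
  wf(c(min(data), max(data), mean(data)))
  wi(c(0L, 0L))                  # ispg, nsymbt
  writeBin(raw(8), con)          # extra words 25-26
  writeChar("MRCO", con, nchars = 4, eos = NULL)  # exttyp
  wi(20140L)                     # nversion
  writeBin(raw(84), con)         # remaining extra space
  wf(c(0, 0, 0))                 # origin
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # machst little-endian
  wf(stats::sd(as.vector(data)))
  wi(0L)                         # nlabl
  writeBin(raw(800), con)        # labels
  writeBin(as.numeric(data), con, size = 4, endian = "little")
  invisible(path)
}

#' Read an MRC2014 mode-2 file
#'
#' Only mode 2 (float32) is supported; other modes raise an error naming
#' the mode, and truncated files raise an error reporting the byte
#' offset/shortfall.
#'
#' @param path file path.
#' @return a [density_map()] (or a 2-D matrix with attributes when
#'   nz = 1).
#' @export
read_mrc <- function(path) {
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 1024)
    stop(sprintf("truncated MRC file: %s bytes, header needs 1024", sz))
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(n) readBin(con, "integer", n, size = 4, endian = "little")
  rf <- function(n) readBin(con, "numeric", n, size = 4, endian = "little")
  d <- ri(3)
  mode <- ri(1)
  if (mode != 2)
    stop(sprintf("unsupported MRC mode %d (only mode 2, float32, is supported)", mode))
  ri(3)                          # nxstart
  m <- ri(3)                     # mx my mz
  cella <- rf(3)
  seek(con, 1024)
  expected <- 1024 + 4 * prod(d)
  if (sz < expected)
    stop(sprintf("truncated MRC file: %d bytes, expected %d (data short by %d at offset %d)",
                 sz, expected, expected - sz, sz))
  data <- array(readBin(con, "numeric", prod(d), size = 4, endian = "little"), d)
  voxel <- cella[1] / (10 * m[1])
  if (d[3] == 1L) {
    out <- data[, , 1]
    attr(out, "voxel_size_nm") <- voxel
    return(out)
  }
  density_map(data, voxel)
}

#' Write tilt angles as a plain-text .tlt file
#'
#' One angle per line, the dialect tomography packages exchange.
#'
#' @param angles_deg numeric tilt angles or a `tilt_series`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tlt <- function(angles_deg, path) {
  if (inherits(angles_deg, "tilt_series")) angles_deg <- angles_deg$angles_deg
  writeLines(sprintf("%.2f", angles_deg), path)
  invisible(path)
}

#' Read a plain-text .tlt tilt-angle file
#'
#' @param path file path.
#' @return numeric vector of angles in degrees.
#' @export
read_tlt <- function(path) as.numeric(readLines(path))

#' Export a tube model as PDB
#'
#' Coarse mode writes one pseudo-atom (CA) per subunit; atomic mode
#' replicates a supplied heterodimer template (principal axis aligned to
#' the tube axis) at every dimer position. One chain per protofilament,
#' occupancy 1.00, and the B-factor column encodes the subunit identity
#' (A = 10.0, B = 20.0). Files exceeding the 99,999-atom PDB limit are
#' split with a warning.
#'
#' @param model a `tube_model` (types assigned).
#' @param path output path (`.pdb`).
#' @param template optional path to a PDB file holding one straightened
#'   heterodimer for atomic mode.
#' @return character vector of the file(s) written, invisibly.
#' @export
write_model_pdb <- function(model, path, template = NULL) {
  stopifnot(inherits(model, "tube_model"))
  pl <- model$placements
  if (is.null(template)) {
    xyz <- cbind(pl$x, pl$y, pl$z) * 10          # nm -> Angstrom
    chain <- LETTERS[(pl$pf %% 26) + 1]
    b <- ifelse(pl$type == "A", 10, 20)
    resno <- pl$axial + 1L
  } else {
    tmpl <- bio3d::read.pdb(template)
    txyz <- matrix(tmpl$xyz, ncol = 3, byrow = TRUE)
    txyz <- scale(txyz, scale = FALSE)           # center
    pc <- svd(txyz)$v
    if (det(pc) < 0) pc[, 3] <- -pc[, 3]
    ## principal axis -> z
    txyz <- txyz %*% pc[, c(2, 3, 1)]
    dimers <- pl[pl$axial %% 2L == 0L, ]
    n_t <- nrow(txyz)
    xyz <- matrix(0, nrow(dimers) * n_t, 3)
    chain <- character(nrow(dimers) * n_t)
    b <- numeric(nrow(dimers) * n_t)
    resno <- integer(nrow(dimers) * n_t)
    for (i in seq_len(nrow(dimers))) {
      phi <- atan2(dimers$y[i], dimers$x[i])
      ## dimer center sits one monomer rise above the A subunit position
      zc <- dimers$z[i] + model$spec$monomer_rise_nm / 2
      rows <- ((i - 1) * n_t + 1):(i * n_t)
      xyz[rows, ] <- txyz %*% t(rot_z(phi)) +
        matrix(c(dimers$x[i], dimers$y[i], zc) * 10, n_t, 3, byrow = TRUE)
      chain[rows] <- LETTERS[(dimers$pf[i] %% 26) + 1]
      b[rows] <- ifelse(dimers$type[i] == "A", 10, 20)
      resno[rows] <- dimers$axial[i] %/% 2L + 1L
    }
  }
  n_atoms <- nrow(xyz)
  max_atoms <- 99999L
  n_files <- ceiling(n_atoms / max_atoms)
  paths <- character(n_files)
  if (n_files > 1)
    warning(sprintf("%d atoms exceed the PDB limit; splitting into %d files",
                    n_atoms, n_files))
  for (k in seq_len(n_files)) {
    idx <- ((k - 1) * max_atoms + 1):min(k * max_atoms, n_atoms)
    pk <- if (n_files == 1) path else sub("\\.pdb$", sprintf("_part%d.pdb", k), path)
    ni <- length(idx)
    bio3d::write.pdb(file = pk,
                     xyz = as.numeric(t(xyz[idx, , drop = FALSE])),
                     resno = resno[idx],
                     resid = rep("ALA", ni),
                     eleno = seq_len(ni),
                     elety = rep("CA", ni),
                     chain = chain[idx],
                     o = rep(1, ni),
                     b = b[idx])
    paths[k] <- pk
  }
  invisible(paths)
}

#' Export a lattice report as JSON
#'
#' @param report a `lattice_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_lattice_report_json <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
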