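# Topology and trajectory ingestion. PDB and DCD go through bio3d; GRO is
# parsed here (no installed R package reads it). All coordinates are converted
# to Angstrom on ingest; GRO files (nm) are scaled by 10.

#' Read a molecular topology
#'
#' Reads a PDB or GRO file into a [Topology-class]. Elements missing from the
#' file are inferred from the leading characters of the atom name; masses are
#' assigned from standard atomic weights. GRO files carry no chain identifier:
#' chains are assigned alphabetically, starting a new chain whenever the
#' residue number decreases.
#'
#' @param path file path
#' @param format `"auto"` (by extension), `"pdb"` or `"gro"`
#' @return a [Topology-class]
#' @examples
#' gro <- tempfile(fileext = ".gro")
#' sys <- generateTrajectory(fourBlockSpec(nframes = 2))
#' writeGRO(sys$topology, frameCoords(sys$trajectory, 1), gro)
#' readTopology(gro)
#' @export
readTopology <- function(path, format = c("auto", "pdb", "gro")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("input error: file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, pdb = "pdb", ent = "pdb", gro = "gro",
                     stop("cannot infer topology format from extension '", ext, "'"))
  }
  switch(format, pdb = .readPDBTopology(path), gro = .readGROTopology(path))
}

.readPDBTopology <- function(path) {
  lines <- readLines(path, warn = FALSE)
  atomLines <- grep("^(ATOM  |HETATM)", lines)
  if (length(atomLines) == 0L) stop("format error: no ATOM records in ", path)
  # duplicate-serial check within the first model only
  firstEnd <- grep("^(ENDMDL|END($|\\s))", lines)
  scope <- if (length(firstEnd)) atomLines[atomLines < firstEnd[1L]] else atomLines
  serials <- suppressWarnings(as.integer(substr(lines[scope], 7L, 11L)))
  dup <- which(duplicated(serials) & !is.na(serials))
  if (length(dup))
    stop(sprintf("format error: duplicate atom serial %d at line %d",
                 serials[dup[1L]], scope[dup[1L]]))
  pdb <- bio3d::read.pdb(path, verbose = FALSE, multi = FALSE)
  a <- pdb$atom
  element <- a$elesy
  missing <- is.na(element) | trimws(element) == ""
  element[missing] <- .elementFromName(a$elety[missing])
  element <- toupper(trimws(element))
  chain <- a$chain
  chain[is.na(chain) | chain == ""] <- "A"
  newTopology(data.frame(
    serial = a$eleno, name = trimws(a$elety), element = element,
    mass = .massFromElement(element), resno = a$resno,
    resname = trimws(a$resid), chain = chain, stringsAsFactors = FALSE))
}

.readGROTopology <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3L) stop("format error: GRO file too short: ", path)
  natoms <- suppressWarnings(as.integer(trimws(lines[2L])))
  if (is.na(natoms) || natoms < 1L) stop("format error: bad atom count in ", path)
  if (length(lines) < 2L + natoms) stop("format error: truncated GRO file: ", path)
  al <- lines[3L:(2L + natoms)]
  resno <- as.integer(substr(al, 1L, 5L))
  resname <- trimws(substr(al, 6L, 10L))
  name <- trimws(substr(al, 11L, 15L))
  serial <- as.integer(substr(al, 16L, 20L))
  if (any(is.na(resno)) || any(is.na(serial)))
    stop("format error: unparseable GRO atom line in ", path)
  # chains from residue-number monotonicity: a decrease starts a new chain
  brk <- c(FALSE, diff(resno) < 0)
  chain <- LETTERS[cumsum(brk) + 1L]
  element <- .elementFromName(name)
  newTopology(data.frame(
    serial = serial, name = name, element = element,
    mass = .massFromElement(element), resno = resno, resname = resname,
    chain = chain, stringsAsFactors = FALSE))
}

#' Construct a topology from an atom table
#'
#' @param atoms data.frame with columns `serial`, `name`, `element`, `mass`,
#'   `resno`, `resname`, `chain` (element/mass filled in when absent)
#' @return a [Topology-class]
#' @export
newTopology <- function(atoms) {
  if (is.null(atoms$element)) atoms$element <- .elementFromName(atoms$name)
  if (is.null(atoms$mass)) atoms$mass <- .massFromElement(atoms$element)
  if (is.null(atoms$serial)) atoms$serial <- seq_len(nrow(atoms))
  rownames(atoms) <- NULL
  new("Topology", atoms = atoms)
}

#' Read a coordinate trajectory
#'
#' Reads a DCD or multi-model PDB trajectory over a given topology, optionally
#' subsampling by `stride`. Coordinates are stored in Angstrom. Neither format
#' carries physical time, so frame times are synthesized as
#' `startNs + (i - 1) * stride * dtNs` for retained frames.
#'
#' @param topology the [Topology-class] the file must match
#' @param path file path
#' @param format `"auto"` (by extension), `"dcd"` or `"pdb"` (multi-model)
#' @param stride keep every `stride`-th frame (positive integer)
#' @param dtNs time between *stored* frames in ns (default 1)
#' @param startNs time of the first frame in ns (default 0)
#' @return a [Trajectory-class]
#' @export
readTrajectory <- function(topology, path, format = c("auto", "dcd", "pdb"),
                           stride = 1L, dtNs = 1, startNs = 0) {
  stopifnot(is(topology, "Topology"))
  format <- match.arg(format)
  if (!file.exists(path)) stop("input error: file not found: ", path)
  stride <- as.integer(stride)
  if (is.na(stride) || stride < 1L) stop("stride must be a positive integer")
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, dcd = "dcd", pdb = "pdb", ent = "pdb",
                     stop("cannot infer trajectory format from extension '", ext, "'"))
  }
  xyz <- switch(format,
    dcd = unclass(bio3d::read.dcd(path, verbose = FALSE)),
    pdb = {
      pdb <- bio3d::read.pdb(path, verbose = FALSE, multi = TRUE)
      unclass(pdb$xyz)
    })
  xyz <- as.matrix(xyz)
  if (nrow(xyz) == 0L) stop("input error: trajectory has zero frames")
  na <- nAtoms(topology)
  if (ncol(xyz) != 3L * na)
    stop(sprintf("topology/trajectory mismatch: file has %d atoms, topology has %d",
                 ncol(xyz) %/% 3L, na))
  keep <- seq(1L, nrow(xyz), by = stride)
  xyz <- xyz[keep, , drop = FALSE]
  times <- startNs + (seq_along(keep) - 1L) * stride * dtNs
  new("Trajectory", topology = topology, xyz = xyz, times = times)
}

#' Construct a trajectory from coordinates in memory
#'
#' @param topology a [Topology-class]
#' @param xyz frames x (3 * natoms) matrix, Angstrom
#' @param times frame times in ns (default `0, dtNs, ...`)
#' @param dtNs frame spacing used when `times` is missing
#' @return a [Trajectory-class]
#' @export
newTrajectory <- function(topology, xyz, times = NULL, dtNs = 1) {
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  if (is.null(times)) times <- (seq_len(nrow(xyz)) - 1L) * dtNs
  new("Trajectory", topology = topology, xyz = xyz, times = as.numeric(times))
}

#' Extract a sub-trajectory by frame indices
#'
#' @param traj a [Trajectory-class]
#' @param frames integer frame indices to keep (in increasing order)
#' @return a [Trajectory-class]
#' @export
subTrajectory <- function(traj, frames) {
  stopifnot(is(traj, "Trajectory"), all(frames >= 1L), all(frames <= nFrames(traj)))
  new("Trajectory", topology = traj@topology,
      xyz = traj@xyz[frames, , drop = FALSE], times = traj@times[frames])
}

#' Write a GRO coordinate file
#'
#' Writes one frame in GROMACS GRO format (positions in nm). GRO has no chain
#' field; chain identity is recoverable on re-read only through the
#' residue-number convention described in [readTopology()].
#'
#' @param topology a [Topology-class]
#' @param coords natoms x 3 matrix in Angstrom
#' @param path output file
#' @param title title line
#' @return invisibly, the path
#' @export
writeGRO <- function(topology, coords, path, title = "synthetic system") {
  a <- topology@atoms
  stopifnot(nrow(coords) == nrow(a), ncol(coords) == 3L)
  nm <- coords / 10  # Angstrom -> nm
  lines <- c(title, sprintf("%5d", nrow(a)),
             sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                     a$resno %% 100000L, substr(a$resname, 1L, 5L),
                     substr(a$name, 1L, 5L), a$serial %% 100000L,
                     nm[, 1L], nm[, 2L], nm[, 3L]),
             sprintf("%10.5f%10.5f%10.5f", 100, 100, 100))
  writeLines(lines, path)
  invisible(path)
}

#' Write a (multi-model) PDB trajectory
#'
#' Each frame becomes one MODEL record. With a single frame a plain PDB file
#' is produced.
#'
#' @param traj a [Trajectory-class]
#' @param path output file
#' @return invisibly, the path
#' @export
writeMultiModelPDB <- function(traj, path) {
  a <- traj@topology@atoms
  con <- file(path, "w")
  on.exit(close(con))
  nf <- nFrames(traj)
  nameFmt <- ifelse(nchar(a$name) >= 4L, substr(a$name, 1L, 4L),
                    sprintf(" %-3s", a$name))
  for (f in seq_len(nf)) {
    if (nf > 1L) writeLines(sprintf("MODEL     %4d", f), con)
    m <- .rowToXYZ(traj@xyz[f, ])
    writeLines(sprintf("ATOM  %5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                       a$serial %% 100000L, nameFmt, substr(a$resname, 1L, 3L),
                       a$chain, a$resno %% 10000L, m[, 1L], m[, 2L], m[, 3L],
                       1, 0, a$element), con)
    if (nf > 1L) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Write a DCD trajectory
#'
#' Writes a CHARMM-flavour binary DCD file (single precision, no unit cell)
#' readable by standard MD tooling. Coordinates are written in Angstrom.
#'
#' @param traj a [Trajectory-class]
#' @param path output file
#' @return invisibly, the path
#' @export
writeDCD <- function(traj, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  nf <- nFrames(traj)
  na <- nAtoms(traj)
  icntrl <- integer(20L)
  icntrl[1L] <- nf      # frames
  icntrl[2L] <- 1L      # first step
  icntrl[3L] <- 1L      # save interval
  icntrl[4L] <- nf      # total steps
  icntrl[20L] <- 24L    # CHARMM version flag
  writeBin(84L, con, size = 4L)
  writeChar("CORD", con, nchars = 4L, eos = NULL)
  writeBin(icntrl, con, size = 4L)
  writeBin(84L, con, size = 4L)
  title <- formatC("generated by trajnet", width = -80L)
  writeBin(4L + 80L, con, size = 4L)
  writeBin(1L, con, size = 4L)
  writeChar(title, con, nchars = 80L, eos = NULL)
  writeBin(4L + 80L, con, size = 4L)
  writeBin(4L, con, size = 4L)
  writeBin(na, con, size = 4L)
  writeBin(4L, con, size = 4L)
  reclen <- 4L * na
  for (f in seq_len(nf)) {
    m <- .rowToXYZ(traj@xyz[f, ])
    for (k in 1:3) {
      writeBin(reclen, con, size = 4L)
      writeBin(as.numeric(m[, k]), con, size = 4L)
      writeBin(reclen, con, size = 4L)
    }
  }
  invisible(path)
}
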