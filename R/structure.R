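#' Molecular structure container
#'
#' A `Structure` couples per-atom metadata (atom name, residue name and
#' number, chain, element symbol) with Cartesian coordinates in Angstrom.
#' It is the common currency of every analysis stage: generators emit it,
#' the conformer/hydration/deuteration operations consume it.
#'
#' @param atoms data.frame with columns `name`, `resname`, `resno`, `chain`,
#'   and optionally `element` (derived from `name` when absent).
#' @param coords numeric matrix, one row per atom, columns x/y/z in Angstrom.
#' @return object of class `Structure`: a list with elements `atoms`
#'   (data.frame) and `coords` (n x 3 matrix).
#' @examples
#' w <- water_template()
#' nrow(w$atoms)
#' @export
Structure <- function(atoms, coords) {
  stopifnot(is.data.frame(atoms))
  coords <- as.matrix(coords)
  if (!is.numeric(coords) || ncol(coords) != 3L)
    stop("coords must be an n x 3 numeric matrix")
  if (nrow(atoms) != nrow(coords))
    stop("atom count (", nrow(atoms), ") != coordinate count (", nrow(coords), ")")
  if (nrow(coords) > 0L && !all(is.finite(coords)))
    stop("coordinates must be finite")
  need <- c("name", "resname", "resno", "chain")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atoms is missing column(s): ", paste(miss, collapse = ", "))
  if (is.null(atoms$element)) atoms$element <- element_from_name(atoms$name)
  atoms$name <- as.character(atoms$name)
  atoms$resname <- as.character(atoms$resname)
  atoms$resno <- as.integer(atoms$resno)
  atoms$chain <- as.character(atoms$chain)
  atoms$element <- as.character(atoms$element)
  rownames(atoms) <- NULL
  dimnames(coords) <- NULL
  structure(list(atoms = atoms, coords = coords), class = "Structure")
}

#' @export
print.Structure <- function(x, ...) {
  cat("Structure:", nrow(x$atoms), "atoms,",
      length(unique(paste(x$atoms$chain, x$atoms$resno))), "residues\n")
  invisible(x)
}

#' Number of atoms in a Structure or Trajectory topology
#' @param x a `Structure` or `Trajectory`
#' @return integer atom count
#' @export
n_atoms <- function(x) {
  if (inherits(x, "Trajectory")) x <- x$topology
  nrow(x$atoms)
}

#' Multi-frame trajectory sharing one topology
#'
#' @param topology a [Structure] providing atom metadata (frame 1 reference).
#' @param frames list of n x 3 coordinate matrices, all with the topology's
#'   atom count; frame order is meaningful and preserved on file round-trip.
#' @return object of class `Trajectory`
#' @export
Trajectory <- function(topology, frames) {
  stopifnot(inherits(topology, "Structure"), is.list(frames), length(frames) >= 1L)
  na <- nrow(topology$atoms)
  for (i in seq_along(frames)) {
    f <- as.matrix(frames[[i]])
    if (nrow(f) != na)
      stop("frame ", i, " has ", nrow(f), " atoms; topology has ", na)
    if (!all(is.finite(f))) stop("frame ", i, " has non-finite coordinates")
    dimnames(f) <- NULL
    frames[[i]] <- f
  }
  structure(list(topology = topology, frames = frames), class = "Trajectory")
}

#' @export
print.Trajectory <- function(x, ...) {
  cat("Trajectory:", length(x$frames), "frames x", nrow(x$topology$atoms), "atoms\n")
  invisible(x)
}

#' Number of frames
#' @param traj a `Trajectory`
#' @return integer frame count
#' @export
n_frames <- function(traj) length(traj$frames)

#' Frame as a Structure
#' @param traj a `Trajectory`
#' @param i frame index (1-based)
#' @return `Structure` with the topology's metadata and frame `i` coordinates
#' @export
get_frame <- function(traj, i) {
  stopifnot(i >= 1L, i <= length(traj$frames))
  Structure(traj$topology$atoms, traj$frames[[i]])
}

#' Select atoms by metadata predicates
#'
#' All supplied predicates are combined with AND. `resno` may be a vector of
#' residue numbers or a length-2 range given as `range = c(lo, hi)`.
#'
#' @param s a [Structure] (or [Trajectory]; its topology is used)
#' @param name,resname,element,chain character vectors; atom matches if its
#'   value is in the vector
#' @param resno integer vector of residue numbers
#' @param range length-2 numeric, inclusive residue-number range
#' @return sorted integer vector of (1-based) atom indices
#' @export
select_atoms <- function(s, name = NULL, resname = NULL, resno = NULL,
                         range = NULL, element = NULL, chain = NULL) {
  if (inherits(s, "Trajectory")) s <- s$topology
  a <- s$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(name))    keep <- keep & a$name %in% name
  if (!is.null(resname)) keep <- keep & a$resname %in% resname
  if (!is.null(resno))   keep <- keep & a$resno %in% resno
  if (!is.null(range))   keep <- keep & a$resno >= range[1L] & a$resno <= range[2L]
  if (!is.null(element)) keep <- keep & a$element %in% element
  if (!is.null(chain))   keep <- keep & a$chain %in% chain
  sort(which(keep))
}

#' Resolve a site string to one atom index
#'
#' Sites are written either as a bare atom name (unique in the structure,
#' e.g. `"N2"` on the ligand) or as `"<RESNAME><resno>:<ATOM>"`
#' (e.g. `"THR190:OG1"`, `"ASP186:O"`). Matching is case-insensitive.
#'
#' @param s a [Structure]
#' @param site site string
#' @return single integer atom index
#' @export
resolve_site <- function(s, site) {
  if (inherits(s, "Trajectory")) s <- s$topology
  a <- s$atoms
  site <- trimws(site)
  if (grepl(":", site, fixed = TRUE)) {
    parts <- strsplit(site, ":", fixed = TRUE)[[1L]]
    m <- regmatches(parts[1L], regexec("^([A-Za-z]+)([0-9]+)$", parts[1L]))[[1L]]
    if (length(m) != 3L) stop("cannot parse site '", site, "'")
    idx <- which(toupper(a$resname) == toupper(m[2L]) &
                 a$resno == as.integer(m[3L]) &
                 toupper(a$name) == toupper(parts[2L]))
  } else {
    idx <- which(toupper(a$name) == toupper(site))
  }
  if (length(idx) == 0L) stop("site '", site, "' does not resolve to any atom")
  if (length(idx) > 1L) stop("site '", site, "' is ambiguous (", length(idx), " atoms)")
  idx
}

## ---- file I/O ------------------------------------------------------------

standard_water_names <- c("HOH", "WAT", "TIP3", "SOL")

bio3d_to_structure <- function(pdb) {
  a <- pdb$atom
  element <- a$elesy
  bad <- is.na(element) | element == "" | !grepl("^[A-Za-z]+$", element)
  element[bad] <- element_from_name(a$elety[bad])
  chain <- a$chain
  chain[is.na(chain)] <- "A"
  atoms <- data.frame(name = a$elety, resname = a$resid, resno = a$resno,
                      chain = chain, element = toupper(element),
                      stringsAsFactors = FALSE)
  Structure(atoms, cbind(a$x, a$y, a$z))
}

read_xyz_block <- function(lines, start, path) {
  n <- suppressWarnings(as.integer(trimws(lines[start])))
  if (is.na(n) || n <= 0L)
    stop("parse error in '", path, "' line ", start, ": expected atom count")
  if (start + 1L + n > length(lines))
    stop("parse error in '", path, "': truncated frame starting at line ", start)
  rows <- lines[(start + 2L):(start + 1L + n)]
  toks <- strsplit(trimws(rows), "[[:space:]]+")
  bad <- which(vapply(toks, length, 1L) < 4L)
  if (length(bad))
    stop("parse error in '", path, "' line ", start + 1L + bad[1L],
         ": expected 'element x y z'")
  el <- vapply(toks, `[[`, "", 1L)
  xyz <- t(vapply(toks, function(t) {
    v <- suppressWarnings(as.numeric(t[2:4]))
    v
  }, numeric(3L)))
  badrow <- which(!apply(is.finite(xyz), 1L, all))
  if (length(badrow))
    stop("parse error in '", path, "' line ", start + 1L + badrow[1L],
         ": non-numeric coordinate")
  list(elements = el, xyz = xyz, next_line = start + 2L + n)
}

#' Read a molecular structure from PDB or XYZ
#'
#' PDB parsing is delegated to \pkg{bio3d}; XYZ files (element + three
#' coordinates per row) yield a single synthetic residue `UNK`. For
#' multi-model files only the first frame is returned (see
#' [read_trajectory]).
#'
#' @param path file path
#' @param format `"pdb"` or `"xyz"`; default guessed from the extension
#' @return a [Structure]
#' @export
read_structure <- function(path, format = c("auto", "pdb", "xyz")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.xyz$", path, ignore.case = TRUE)) "xyz" else "pdb"
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "pdb") {
    pdb <- bio3d::read.pdb(path, verbose = FALSE)
    return(bio3d_to_structure(pdb))
  }
  lines <- readLines(path)
  blk <- read_xyz_block(lines, 1L, path)
  el <- element_from_name(blk$elements)
  atoms <- data.frame(name = blk$elements, resname = "UNK", resno = 1L,
                      chain = "A", element = el, stringsAsFactors = FALSE)
  Structure(atoms, blk$xyz)
}

#' Write a structure to PDB or XYZ
#'
#' PDB output uses wwPDB fixed columns with three-decimal coordinates,
#' occupancy 1.00 and B-factor 0.00. Zero-atom structures are refused.
#'
#' @param s a [Structure]
#' @param path output file path
#' @param format `"pdb"` or `"xyz"` (default from extension)
#' @return invisibly, `path`
#' @export
write_structure <- function(s, path, format = c("auto", "pdb", "xyz")) {
  stopifnot(inherits(s, "Structure"))
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.xyz$", path, ignore.case = TRUE)) "xyz" else "pdb"
  if (nrow(s$atoms) == 0L) stop("refusing to write a zero-atom structure")
  if (format == "pdb") {
    het <- s$atoms$resname %in% c(standard_water_names, "HSM", "LIG", "UNK", "UNL")
    bio3d::write.pdb(file = path,
                     xyz = as.numeric(t(s$coords)),
                     type = ifelse(het, "HETATM", "ATOM"),
                     resno = s$atoms$resno,
                     resid = s$atoms$resname,
                     eleno = seq_len(nrow(s$atoms)),
                     elety = s$atoms$name,
                     chain = s$atoms$chain,
                     o = rep(1, nrow(s$atoms)), b = rep(0, nrow(s$atoms)),
                     elesy = s$atoms$element)
  } else {
    con <- file(path, "w"); on.exit(close(con))
    writeLines(as.character(nrow(s$atoms)), con)
    writeLines("generated by deutbind", con)
    writeLines(sprintf("%-2s %12.6f %12.6f %12.6f", s$atoms$element,
                       s$coords[, 1L], s$coords[, 2L], s$coords[, 3L]), con)
  }
  invisible(path)
}

#' Read a multi-frame trajectory (multi-model PDB or concatenated XYZ)
#'
#' Every frame must share the first frame's atom count; a mismatch is an
#' error naming the offending frame.
#'
#' @param path file path
#' @param format `"pdb"` or `"xyz"` (default from extension)
#' @return a [Trajectory]
#' @export
read_trajectory <- function(path, format = c("auto", "pdb", "xyz")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.xyz$", path, ignore.case = TRUE)) "xyz" else "pdb"
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "pdb") {
    lines <- readLines(path)
    starts <- grep("^MODEL", lines)
    if (length(starts) > 1L) {
      ends <- grep("^ENDMDL", lines)
      if (length(ends) != length(starts)) stop("unbalanced MODEL/ENDMDL in ", path)
      counts <- vapply(seq_along(starts), function(i)
        sum(grepl("^(ATOM|HETATM)", lines[starts[i]:ends[i]])), 1L)
      if (any(counts != counts[1L])) {
        bad <- which(counts != counts[1L])[1L]
        stop("frame ", bad, " has ", counts[bad],
             " atoms; frame 1 has ", counts[1L])
      }
    }
    pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
    topo <- bio3d_to_structure(pdb)
    nf <- nrow(pdb$xyz)
    frames <- lapply(seq_len(nf), function(i)
      matrix(pdb$xyz[i, ], ncol = 3L, byrow = TRUE))
    return(Trajectory(topo, frames))
  }
  lines <- readLines(path)
  pos <- 1L
  frames <- list(); el0 <- NULL
  while (pos <= length(lines) && nzchar(trimws(lines[pos]))) {
    blk <- read_xyz_block(lines, pos, path)
    if (is.null(el0)) el0 <- blk$elements
    if (length(blk$elements) != length(el0))
      stop("frame ", length(frames) + 1L, " has ", length(blk$elements),
           " atoms; frame 1 has ", length(el0))
    frames[[length(frames) + 1L]] <- blk$xyz
    pos <- blk$next_line
  }
  if (!length(frames)) stop("no frames in ", path)
  atoms <- data.frame(name = el0, resname = "UNK", resno = 1L, chain = "A",
                      element = element_from_name(el0), stringsAsFactors = FALSE)
  Trajectory(Structure(atoms, frames[[1L]]), frames)
}

#' Write a trajectory as multi-model PDB or concatenated XYZ
#'
#' @param traj a [Trajectory]
#' @param path output file path
#' @param format `"pdb"` or `"xyz"` (default from extension)
#' @return invisibly, `path`
#' @export
write_trajectory <- function(traj, path, format = c("auto", "pdb", "xyz")) {
  stopifnot(inherits(traj, "Trajectory"))
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.xyz$", path, ignore.case = TRUE)) "xyz" else "pdb"
  s <- traj$topology
  if (nrow(s$atoms) == 0L) stop("refusing to write a zero-atom trajectory")
  if (format == "pdb") {
    xyz <- do.call(rbind, lapply(traj$frames, function(f) as.numeric(t(f))))
    het <- s$atoms$resname %in% c(standard_water_names, "HSM", "LIG", "UNK", "UNL")
    bio3d::write.pdb(file = path, xyz = xyz,
                     type = ifelse(het, "HETATM", "ATOM"),
                     resno = s$atoms$resno, resid = s$atoms$resname,
                     eleno = seq_len(nrow(s$atoms)), elety = s$atoms$name,
                     chain = s$atoms$chain,
                     o = rep(1, nrow(s$atoms)), b = rep(0, nrow(s$atoms)),
                     elesy = s$atoms$element)
  } else {
    con <- file(path, "w"); on.exit(close(con))
    for (f in traj$frames) {
      writeLines(as.character(nrow(s$atoms)), con)
      writeLines("generated by deutbind", con)
      writeLines(sprintf("%-2s %12.6f %12.6f %12.6f", s$atoms$element,
                         f[, 1L], f[, 2L], f[, 3L]), con)
    }
  }
  invisible(path)
}
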