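#' @useDynLib conformscape, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats runif rnorm optim uniroot setNames
#' @importFrom utils head tail read.delim write.table
NULL

# ---------------------------------------------------------------------------
# Domain containers.
#
# A Structure is a single conformation: an ordered atom table (chain,
# residue number in author numbering -- negatives allowed for appendage
# residues -- residue name, atom name, element) plus an n x 3 coordinate
# matrix in Angstrom.  A Trajectory shares one atom table (its "topology")
# across an n_atoms x 3 x n_frames coordinate array with a fixed frame
# spacing in picoseconds.
# ---------------------------------------------------------------------------

#' Construct a Structure
#'
#' @param atoms data.frame with columns `chain`, `resid` (integer, author
#'   numbering, may be negative), `resname`, `atom`, `element`.
#' @param coords numeric matrix, `nrow(atoms)` x 3, coordinates in Angstrom.
#' @param label free-text label carried through analyses.
#' @return An object of class `Structure`.
#' @export
new_structure <- function(atoms, coords, label = "") {
  stopifnot(is.data.frame(atoms), nrow(atoms) >= 1L)
  coords <- as.matrix(coords)
  if (!is.numeric(coords) || ncol(coords) != 3L || nrow(coords) != nrow(atoms))
    stop("coords must be a numeric nrow(atoms) x 3 matrix")
  if (!all(is.finite(coords)))
    stop("coordinates must be finite")
  need <- c("chain", "resid", "resname", "atom", "element")
  miss <- setdiff(need, names(atoms))
  if (length(miss))
    stop("atoms is missing columns: ", paste(miss, collapse = ", "))
  atoms$resid <- as.integer(atoms$resid)
  key <- paste(atoms$chain, atoms$resid, atoms$atom)
  if (anyDuplicated(key))
    stop("duplicate (chain, residue, atom) keys in structure")
  rownames(atoms) <- NULL
  dimnames(coords) <- NULL
  structure(list(atoms = atoms, coords = coords, label = label),
            class = "Structure")
}

#' Construct a Trajectory
#'
#' @param topology a [Structure] giving atom identities (its own coordinates
#'   are frame 1 by convention, but the array below is authoritative).
#' @param coords numeric array `n_atoms x 3 x n_frames`.
#' @param frame_spacing_ps time between saved frames, picoseconds.
#' @return An object of class `Trajectory`.
#' @export
new_trajectory <- function(topology, coords, frame_spacing_ps = 50) {
  stopifnot(inherits(topology, "Structure"))
  if (length(dim(coords)) != 3L)
    stop("coords must be an n_atoms x 3 x n_frames array")
  if (dim(coords)[1] != n_atoms(topology) || dim(coords)[2] != 3L)
    stop("inconsistent atom counts between topology and coordinate array")
  if (dim(coords)[3] < 1L) stop("trajectory needs at least one frame")
  if (!is.numeric(frame_spacing_ps) || frame_spacing_ps <= 0)
    stop("frame_spacing_ps must be positive")
  dimnames(coords) <- NULL
  structure(list(topology = topology, coords = coords,
                 frame_spacing_ps = as.numeric(frame_spacing_ps)),
            class = "Trajectory")
}

#' @export
print.Structure <- function(x, ...) {
  cat(sprintf("<Structure '%s': %d atoms, %d residues, chains %s>\n",
              x$label, n_atoms(x), length(unique(paste(x$atoms$chain, x$atoms$resid))),
              paste(unique(x$atoms$chain), collapse = ",")))
  invisible(x)
}

#' @export
print.Trajectory <- function(x, ...) {
  cat(sprintf("<Trajectory: %d frames x %d atoms, dt = %g ps>\n",
              n_frames(x), n_atoms(x$topology), x$frame_spacing_ps))
  invisible(x)
}

#' Number of atoms in a Structure (or a Trajectory's topology)
#' @param x Structure or Trajectory.
#' @export
n_atoms <- function(x) {
  if (inherits(x, "Trajectory")) return(nrow(x$topology$atoms))
  nrow(x$atoms)
}

#' Number of frames in a Trajectory
#' @param x Trajectory.
#' @export
n_frames <- function(x) {
  stopifnot(inherits(x, "Trajectory"))
  dim(x$coords)[3]
}

#' Frame times of a Trajectory in picoseconds
#'
#' Frame 1 is at t = 0 by convention.
#' @param traj Trajectory.
#' @export
frame_times <- function(traj) {
  (seq_len(n_frames(traj)) - 1L) * traj$frame_spacing_ps
}

#' Extract one frame of a Trajectory as a Structure
#' @param traj Trajectory.
#' @param i frame index (1-based).
#' @export
get_frame <- function(traj, i) {
  stopifnot(inherits(traj, "Trajectory"))
  i <- as.integer(i)
  if (i < 1L || i > n_frames(traj)) stop("frame index out of range: ", i)
  new_structure(traj$topology$atoms, traj$coords[, , i],
                label = sprintf("%s[frame %d]", traj$topology$label, i))
}

# ---------------------------------------------------------------------------
# Selections
# ---------------------------------------------------------------------------

#' Atom selection by residue ranges and atom names
#'
#' A selection combines inclusive residue-number ranges per chain with a set
#' of atom names.  The conventional reference frame for the kinase core is
#' helices E and F, native residues 140-160 and 217-233.
#'
#' @param ranges either a data.frame with columns `chain`, `start`, `end`,
#'   or a compact string such as `"A:140-160,A:217-233"`; `NULL` selects all
#'   residues.
#' @param atom_names character vector of atom names to keep, e.g. `"CA"` or
#'   `c("N","CA","C","O")` (backbone); `NULL` keeps all atom names.
#' @return An object of class `Selection`.
#' @export
selection <- function(ranges = NULL, atom_names = "CA") {
  if (is.character(ranges) && length(ranges) == 1L) ranges <- parse_ranges(ranges)
  if (!is.null(ranges)) {
    stopifnot(is.data.frame(ranges), all(c("chain", "start", "end") %in% names(ranges)))
    ranges$start <- as.integer(ranges$start)
    ranges$end <- as.integer(ranges$end)
    if (any(ranges$start > ranges$end))
      stop("selection range with start > end")
  }
  structure(list(ranges = ranges, atom_names = atom_names), class = "Selection")
}

parse_ranges <- function(txt) {
  parts <- strsplit(txt, ",", fixed = TRUE)[[1]]
  parts <- trimws(parts[nzchar(trimws(parts))])
  rows <- lapply(parts, function(p) {
    m <- regmatches(p, regexec("^([A-Za-z0-9]+):(-?[0-9]+)-(-?[0-9]+)$", p))[[1]]
    if (length(m) != 4L) stop("cannot parse selection range: '", p, "'")
    data.frame(chain = m[2], start = as.integer(m[3]), end = as.integer(m[4]))
  })
  do.call(rbind, rows)
}

#' Helix E/F core fit selection (native numbering)
#'
#' The immobile large-lobe anchor helices: E = 140-160, F = 217-233.
#' @param chain chain identifier, default `"A"`.
#' @param atom_names atom names, default backbone `{N, CA, C, O}`.
#' @export
core_fit_selection <- function(chain = "A", atom_names = c("N", "CA", "C", "O")) {
  selection(data.frame(chain = chain, start = c(140L, 217L), end = c(160L, 233L)),
            atom_names = atom_names)
}

#' Resolve a Selection to atom indices
#'
#' @param s Structure (or Trajectory; the topology is used).
#' @param sel Selection.
#' @return Integer vector of row indices into the atom table, ordered by
#'   (chain, residue number, canonical atom-name order N, CA, C, O, then
#'   alphabetical).
#' @export
select_indices <- function(s, sel) {
  if (inherits(s, "Trajectory")) s <- s$topology
  stopifnot(inherits(s, "Structure"), inherits(sel, "Selection"))
  at <- s$atoms
  keep <- rep(FALSE, nrow(at))
  if (is.null(sel$ranges)) {
    keep[] <- TRUE
  } else {
    for (r in seq_len(nrow(sel$ranges))) {
      hit <- at$chain == sel$ranges$chain[r] &
        at$resid >= sel$ranges$start[r] & at$resid <= sel$ranges$end[r]
      if (!any(hit))
        stop(sprintf("selection resolves no atoms for range %s:%d-%d",
                     sel$ranges$chain[r], sel$ranges$start[r], sel$ranges$end[r]))
      keep <- keep | hit
    }
  }
  if (!is.null(sel$atom_names)) keep <- keep & at$atom %in% sel$atom_names
  idx <- which(keep)
  if (!length(idx)) stop("selection resolves no atoms")
  canon <- c("N", "CA", "C", "O")
  arank <- match(at$atom[idx], canon)
  arank[is.na(arank)] <- length(canon) + rank(at$atom[idx][is.na(arank)])
  idx[order(at$chain[idx], at$resid[idx], arank)]
}

#' Resolve a Selection to atom records
#'
#' @inheritParams select_indices
#' @return data.frame of atom records (with `x`, `y`, `z` columns appended)
#'   in canonical order.
#' @export
select_atoms <- function(s, sel) {
  if (inherits(s, "Trajectory")) s <- s$topology
  idx <- select_indices(s, sel)
  out <- s$atoms[idx, , drop = FALSE]
  out$x <- s$coords[idx, 1]
  out$y <- s$coords[idx, 2]
  out$z <- s$coords[idx, 3]
  rownames(out) <- NULL
  out
}

# ---------------------------------------------------------------------------
# Residue numbering map
# ---------------------------------------------------------------------------

#' Numbering map between native-extended and chimera author numbering
#'
#' The fusion kinase is crystallographically numbered 1..n ("chimera"
#' numbering) while comparative analyses use native kinase numbering with
#' the appendage residues negative.  The two published anchor pairs
#' (native 10 = chimera 65, native 15 = chimera 70) fix a +55 offset.
#'
#' @param offset integer added to a native residue number to obtain the
#'   chimera number; default 55.
#' @param native_range inclusive native-numbering range over which the map
#'   is defined; default -69..350.
#' @param notes free text.
#' @export
numbering_map <- function(offset = 55L, native_range = c(-69L, 350L), notes = "") {
  stopifnot(length(native_range) == 2L, native_range[1] <= native_range[2])
  structure(list(offset = as.integer(offset),
                 native_range = as.integer(native_range), notes = notes),
            class = "NumberingMap")
}

#' Map a residue number between numbering schemes
#'
#' @param n residue number(s) in the source scheme.
#' @param map a [numbering_map()].
#' @param direction `"native_to_chimera"` or `"chimera_to_native"`.
#' @return Integer vector of mapped residue numbers.
#' @export
map_residue <- function(n, map = numbering_map(),
                        direction = c("native_to_chimera", "chimera_to_native")) {
  direction <- match.arg(direction)
  n <- as.integer(n)
  native <- if (direction == "native_to_chimera") n else n - map$offset
  bad <- native < map$native_range[1] | native > map$native_range[2]
  if (any(bad))
    stop("residue(s) outside mapped native range: ",
         paste(n[bad], collapse = ", "))
  if (direction == "native_to_chimera") n + map$offset else n - map$offset
}

# ---------------------------------------------------------------------------
# PDB input / output
#
# Only ATOM/HETATM/MODEL/ENDMDL records are interpreted.  Alternate
# locations are resolved by keeping the highest-occupancy altloc (first on
# ties).  Coordinates are fixed-format %8.3f so a read/write round trip is
# exact to 3 decimals.
# ---------------------------------------------------------------------------

#' Read a (multi-model) PDB file
#'
#' @param path path to a PDB file.
#' @param model `"all"` to read every MODEL into a [Trajectory] (single
#'   model files yield a [Structure]), or an integer model index.
#' @param frame_spacing_ps frame spacing attached when a Trajectory is
#'   produced; default 50 ps, the conventional MD snapshot stride.
#' @return A [Structure] (one model) or [Trajectory] (several models, the
#'   topology taken from model 1).
#' @export
read_pdb <- function(path, model = "all", frame_spacing_ps = 50) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  keep <- rec %in% c("ATOM  ", "HETATM", "MODEL ", "ENDMDL")
  lines <- lines[keep]
  rec <- rec[keep]
  if (!length(lines)) stop("no ATOM/HETATM records in ", path)

  model_id <- integer(length(lines))
  cur <- 1L; seen_model <- FALSE
  for (i in seq_along(lines)) {
    if (rec[i] == "MODEL ") {
      if (seen_model) cur <- cur + 1L
      seen_model <- TRUE
    } else if (rec[i] == "ENDMDL") {
      # boundary handled by next MODEL record
    } else model_id[i] <- cur
  }
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  lines <- lines[is_atom]; model_id <- model_id[is_atom]

  parse_model <- function(ml) {
    if (any(nchar(ml) < 54)) stop("malformed ATOM record (line too short)")
    atom <- trimws(substr(ml, 13, 16))
    altloc <- substr(ml, 17, 17)
    resname <- trimws(substr(ml, 18, 20))
    chain <- trimws(substr(ml, 22, 22))
    chain[!nzchar(chain)] <- "A"   # unnamed chain defaults to A
    resid <- suppressWarnings(as.integer(trimws(substr(ml, 23, 26))))
    x <- suppressWarnings(as.numeric(substr(ml, 31, 38)))
    y <- suppressWarnings(as.numeric(substr(ml, 39, 46)))
    z <- suppressWarnings(as.numeric(substr(ml, 47, 54)))
    occ <- suppressWarnings(as.numeric(substr(ml, 55, 60)))
    occ[is.na(occ)] <- 1
    elem <- if (all(nchar(ml) >= 78)) trimws(substr(ml, 77, 78)) else rep("", length(ml))
    guess <- substr(gsub("[0-9']", "", atom), 1, 1)
    elem[!nzchar(elem)] <- guess[!nzchar(elem)]
    if (anyNA(resid) || anyNA(x) || anyNA(y) || anyNA(z))
      stop("malformed ATOM record (unparseable field)")
    df <- data.frame(chain = chain, resid = resid, resname = resname,
                     atom = atom, element = elem, altloc = altloc,
                     occ = occ, x = x, y = y, z = z)
    # altloc: keep highest occupancy, first wins ties (stable order)
    key <- paste(df$chain, df$resid, df$atom)
    if (anyDuplicated(key)) {
      ord <- order(match(key, unique(key)), -df$occ,
                   seq_len(nrow(df)))
      df <- df[ord, ][!duplicated(key[ord]), ]
      df <- df[order(match(paste(df$chain, df$resid, df$atom), unique(key))), ]
    }
    df
  }

  models <- sort(unique(model_id))
  first <- parse_model(lines[model_id == models[1]])
  atoms <- first[c("chain", "resid", "resname", "atom", "element")]
  lab <- basename(path)

  if (!identical(model, "all")) {
    mi <- as.integer(model)
    if (!(mi %in% models)) stop("model index not present in file: ", mi)
    df <- parse_model(lines[model_id == mi])
    return(new_structure(df[c("chain", "resid", "resname", "atom", "element")],
                         cbind(df$x, df$y, df$z), label = lab))
  }
  if (length(models) == 1L)
    return(new_structure(atoms, cbind(first$x, first$y, first$z), label = lab))

  co <- array(NA_real_, dim = c(nrow(atoms), 3L, length(models)))
  co[, , 1] <- cbind(first$x, first$y, first$z)
  for (k in seq_along(models)[-1]) {
    df <- parse_model(lines[model_id == models[k]])
    if (nrow(df) != nrow(atoms))
      stop(sprintf("inconsistent atom counts across models: model %d has %d atoms, model 1 has %d",
                   models[k], nrow(df), nrow(atoms)))
    co[, , k] <- cbind(df$x, df$y, df$z)
  }
  topo <- new_structure(atoms, co[, , 1], label = lab)
  new_trajectory(topo, co, frame_spacing_ps = frame_spacing_ps)
}

fmt_atom_line <- function(i, at, xyz) {
  elem <- at$element
  name <- at$atom
  # PDB atom-name column convention: 1/2-char element names start col 14
  namefield <- if (nchar(name) >= 4L) substr(name, 1, 4) else sprintf(" %-3s", name)
  sprintf("ATOM  %5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          i %% 100000L, namefield, substr(at$resname, 1, 3), substr(at$chain, 1, 1),
          at$resid, xyz[1], xyz[2], xyz[3], 1, 0, substr(elem, 1, 2))
}

#' Write a Structure or Trajectory as a PDB file
#'
#' Trajectories are written as MODEL/ENDMDL blocks; coordinates are rounded
#' to the PDB precision of 3 decimals.
#'
#' @param x Structure or Trajectory.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  emit_model <- function(atoms, coords) {
    for (i in seq_len(nrow(atoms)))
      writeLines(fmt_atom_line(i, atoms[i, ], coords[i, ]), con)
  }
  if (inherits(x, "Structure")) {
    emit_model(x$atoms, x$coords)
  } else if (inherits(x, "Trajectory")) {
    for (k in seq_len(n_frames(x))) {
      writeLines(sprintf("MODEL     %4d", k), con)
      emit_model(x$topology$atoms, x$coords[, , k])
      writeLines("ENDMDL", con)
    }
  } else stop("x must be a Structure or Trajectory")
  writeLines("END", con)
  invisible(path)
}

#' Coordinates of one residue's named atom
#'
#' Convenience accessor used by the angle descriptor; errors name the
#' residue when it cannot be resolved.
#' @param s Structure.
#' @param resid residue number (author numbering as stored in `s`).
#' @param atom atom name, default `"CA"`.
#' @param chain chain id, default `"A"`.
#' @return Numeric length-3 position.
#' @export
residue_xyz <- function(s, resid, atom = "CA", chain = "A") {
  hit <- which(s$atoms$chain == chain & s$atoms$resid == resid & s$atoms$atom == atom)
  if (length(hit) != 1L)
    stop(sprintf("cannot resolve atom %s of residue %d (chain %s)", atom, resid, chain))
  s$coords[hit, ]
}
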