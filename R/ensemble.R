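#' Construct a coordinate ensemble
#'
#' An ensemble holds F frames of A atoms in nanometres together with the atom
#' roster shared by every frame. It is the object every analysis stage
#' consumes; frames typically come from a molecular dynamics trajectory
#' exported as multi-model PDB, or from the synthetic generators in this
#' package.
#'
#' @param coords Numeric array `F x A x 3` (nm), or an `A x 3` matrix for a
#'   single frame.
#' @param atoms Data frame with one row per atom and columns `serial`,
#'   `name`, `element`, `resname`, `resno`, `chain`, and optionally
#'   `occupancy`, `bfactor`.
#' @param times Optional numeric vector of frame times in ps (length F).
#' @param label Free-text label carried through to results (e.g.
#'   `"ALASdChA-300K"`).
#'
#' @return An object of class `ensemble`: a list with elements `coords`
#'   (F x A x 3 array, nm), `atoms` (tibble), `times`, `label`.
#' @export
ensemble <- function(coords, atoms, times = NULL, label = "ensemble") {
  if (is.matrix(coords)) coords <- array(coords, dim = c(1L, dim(coords)))
  stopifnot(length(dim(coords)) == 3L, dim(coords)[3L] == 3L)
  atoms <- tibble::as_tibble(atoms)
  needed <- c("serial", "name", "element", "resname", "resno", "chain")
  missing_cols <- setdiff(needed, names(atoms))
  if (length(missing_cols)) {
    stop("ensemble(): atoms table lacks column(s): ",
      paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"occupancy" %in% names(atoms)) atoms$occupancy <- 1
  if (!"bfactor" %in% names(atoms)) atoms$bfactor <- 0
  if (dim(coords)[2L] != nrow(atoms)) {
    stop("ensemble(): coords have ", dim(coords)[2L], " atoms but roster has ",
      nrow(atoms), call. = FALSE)
  }
  if (any(!is.finite(coords))) stop("ensemble(): non-finite coordinates", call. = FALSE)
  if (any(atoms$resno < 1L)) stop("ensemble(): residue numbers must be >= 1", call. = FALSE)
  if (any(!nzchar(atoms$name))) stop("ensemble(): empty atom name", call. = FALSE)
  key <- paste(atoms$chain, atoms$resno, atoms$name)
  if (anyDuplicated(key)) {
    stop("ensemble(): duplicate (chain, residue, atom name): ",
      key[duplicated(key)][1L], call. = FALSE)
  }
  if (!is.null(times) && length(times) != dim(coords)[1L]) {
    stop("ensemble(): times length must equal frame count", call. = FALSE)
  }
  structure(
    list(coords = coords, atoms = atoms, times = times, label = label),
    class = "ensemble"
  )
}

#' @export
print.ensemble <- function(x, ...) {
  cat("<ensemble> ", x$label, ": ", n_frames(x), " frame(s), ", n_atoms(x),
    " atoms, chains ", paste(unique(x$atoms$chain), collapse = ","), "\n", sep = "")
  invisible(x)
}

#' Number of frames in an ensemble
#' @param x An `ensemble`.
#' @export
n_frames <- function(x) dim(x$coords)[1L]

#' Number of atoms in an ensemble
#' @param x An `ensemble`.
#' @export
n_atoms <- function(x) dim(x$coords)[2L]

#' Extract one frame as an A x 3 coordinate matrix (nm)
#' @param x An `ensemble`.
#' @param i Frame index.
#' @export
frame_coords <- function(x, i = 1L) {
  stopifnot(i >= 1L, i <= n_frames(x))
  matrix(x$coords[i, , ], ncol = 3L,
    dimnames = list(NULL, c("x", "y", "z")))
}

# --- multi-model PDB I/O (fixed columns; coordinates Angstrom on disk, nm in memory) ---

#' Read a multi-model PDB file into an ensemble
#'
#' `MODEL`/`ENDMDL` records delimit frames; a file without `MODEL` records is
#' read as a single frame. Coordinates are converted from Angstrom to nm.
#' Alternate locations other than `' '`/`'A'` are dropped; insertion codes
#' are rejected. Parsing is delegated to [bio3d::read.pdb()] after a
#' validation pass that enforces a constant atom roster across models.
#'
#' @param path Path to a PDB file.
#' @param label Ensemble label; defaults to the file name.
#' @return An [ensemble()].
#' @export
read_multimodel_pdb <- function(path, label = basename(path)) {
  if (!file.exists(path)) stop("read_multimodel_pdb(): file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  is_atom <- startsWith(lines, "ATOM  ") | startsWith(lines, "HETATM")
  atom_idx <- which(is_atom)
  if (length(atom_idx) == 0L) stop("read_multimodel_pdb(): no ATOM records in ", path, call. = FALSE)
  # validation pass: fixed-width fields, model boundaries, constant roster
  for (i in atom_idx) {
    ln <- lines[i]
    if (nchar(ln) < 54L) {
      stop("read_multimodel_pdb(): truncated ATOM record at line ", i, call. = FALSE)
    }
    coords_txt <- c(substr(ln, 31, 38), substr(ln, 39, 46), substr(ln, 47, 54))
    if (anyNA(suppressWarnings(as.numeric(coords_txt)))) {
      stop("read_multimodel_pdb(): unparseable coordinates at line ", i, call. = FALSE)
    }
    if (is.na(suppressWarnings(as.integer(substr(ln, 23, 26))))) {
      stop("read_multimodel_pdb(): unparseable residue number at line ", i, call. = FALSE)
    }
    if (substr(ln, 27, 27) != " ") {
      stop("read_multimodel_pdb(): insertion codes are not supported (line ", i, ")",
        call. = FALSE)
    }
  }
  model_starts <- which(startsWith(lines, "MODEL"))
  if (length(model_starts) > 1L) {
    model_of <- findInterval(atom_idx, model_starts)
    kept <- substr(lines[atom_idx], 17, 17) %in% c(" ", "A")
    counts <- table(model_of[kept])
    if (length(unique(as.integer(counts))) > 1L) {
      bad <- names(counts)[which(as.integer(counts) != as.integer(counts)[1L])[1L]]
      stop("read_multimodel_pdb(): atom count mismatch in MODEL #", bad,
        " (", counts[[bad]], " vs ", counts[[1L]], " atoms)", call. = FALSE)
    }
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, rm.alt = TRUE, verbose = FALSE)
  nf <- nrow(pdb$xyz)
  na_ <- nrow(pdb$atom)
  atoms <- tibble::tibble(
    serial = as.integer(pdb$atom$eleno),
    name = trimws(pdb$atom$elety),
    element = ifelse(is.na(pdb$atom$elesy) | !nzchar(trimws(pdb$atom$elesy)),
      substr(trimws(pdb$atom$elety), 1L, 1L), trimws(pdb$atom$elesy)),
    resname = trimws(pdb$atom$resid),
    resno = as.integer(pdb$atom$resno),
    chain = ifelse(is.na(pdb$atom$chain), " ", pdb$atom$chain),
    occupancy = ifelse(is.na(pdb$atom$o), 1, pdb$atom$o),
    bfactor = ifelse(is.na(pdb$atom$b), 0, pdb$atom$b)
  )
  coords <- array(NA_real_, dim = c(nf, na_, 3L))
  for (f in seq_len(nf)) {
    m <- matrix(pdb$xyz[f, ], ncol = 3L, byrow = TRUE)
    coords[f, , ] <- m / 10 # Angstrom -> nm
  }
  ensemble(coords, atoms, label = label)
}

#' Write an ensemble as a multi-model PDB file
#'
#' One `MODEL`/`ENDMDL` block per frame; coordinates are emitted in Angstrom
#' with three decimals, so a read/write round trip preserves coordinates to
#' 1e-4 nm.
#'
#' @param x An [ensemble()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_multimodel_pdb <- function(x, path) {
  stopifnot(inherits(x, "ensemble"))
  ang <- x$coords * 10
  if (any(ang >= 1e4) || any(ang <= -1e3)) {
    stop("write_multimodel_pdb(): coordinate exceeds the fixed-width PDB field ",
      "(must lie in (-100, 1000) nm)", call. = FALSE)
  }
  # bio3d expects rows of (x1, y1, z1, x2, ...) per frame
  xyz <- t(apply(x$coords, 1L, function(fr) as.vector(t(fr * 10))))
  if (n_frames(x) == 1L) xyz <- matrix(xyz, nrow = 1L)
  bio3d::write.pdb(
    file = path, xyz = xyz,
    type = rep("ATOM", n_atoms(x)),
    eleno = x$atoms$serial, elety = x$atoms$name,
    resid = x$atoms$resname, chain = x$atoms$chain, resno = x$atoms$resno,
    o = x$atoms$occupancy, b = x$atoms$bfactor, elesy = x$atoms$element
  )
  invisible(path)
}

# canonical within-residue atom order used by select_atoms()
.canonical_atom_rank <- function(name) {
  rank <- match(name, c("N", "CA", "C", "O", "H"))
  ifelse(is.na(rank), 6L, rank)
}

#' Resolve a named region into atom indices
#'
#' Selects the requested atom names for every residue a region covers,
#' ordered by chain, residue number, then the canonical backbone order
#' N, CA, C, O, H (remaining names alphabetically). The residue count of the
#' selection is attached as attribute `n_residues`.
#'
#' @param x An [ensemble()].
#' @param regions A [region_set()].
#' @param region_name Name of the region to select.
#' @param atom_names Character vector of atom names (default backbone
#'   `N`, `CA`, `C`).
#' @return Integer vector of atom indices into the ensemble roster.
#' @export
select_atoms <- function(x, regions, region_name, atom_names = c("N", "CA", "C")) {
  stopifnot(inherits(x, "ensemble"))
  res <- region_residues(regions, region_name)
  at <- x$atoms
  at$idx <- seq_len(nrow(at))
  covered <- dplyr::inner_join(at, res, by = c("chain", "resno"))
  if (nrow(covered) == 0L) {
    stop("select_atoms(): region '", region_name, "' selects no atoms", call. = FALSE)
  }
  sel <- covered[covered$name %in% atom_names, , drop = FALSE]
  if (nrow(sel) == 0L) {
    stop("select_atoms(): region '", region_name, "' selects no atoms named ",
      paste(atom_names, collapse = "/"), call. = FALSE)
  }
  # every covered residue must carry every requested atom name
  have <- dplyr::summarise(
    dplyr::group_by(covered, .data$chain, .data$resno),
    n_named = sum(unique(atom_names) %in% .data$name), .groups = "drop"
  )
  incomplete <- have[have$n_named < length(unique(atom_names)), , drop = FALSE]
  if (nrow(incomplete) > 0L) {
    stop("select_atoms(): requested atom name(s) missing in residue(s): ",
      paste(paste0(incomplete$chain, ":", incomplete$resno), collapse = ", "),
      call. = FALSE)
  }
  ord <- order(sel$chain, sel$resno, .canonical_atom_rank(sel$name), sel$name)
  idx <- sel$idx[ord]
  attr(idx, "n_residues") <- nrow(have)
  idx
}

#' Build a uniformly sampled time axis
#'
#' @param duration_ns Total duration in ns (> 0).
#' @param interval_ps Sampling interval in ps (> 0); must divide the duration.
#' @return Numeric vector of frame times in ps, from 0 to the duration
#'   inclusive; a 100 ns run sampled every 100 ps yields 1001 times.
#' @export
build_time_axis <- function(duration_ns, interval_ps) {
  stopifnot(duration_ns > 0, interval_ps > 0)
  duration_ps <- duration_ns * 1000
  n <- duration_ps / interval_ps
  if (abs(n - round(n)) > 1e-9) {
    stop("build_time_axis(): interval does not divide the duration", call. = FALSE)
  }
  seq(0, duration_ps, by = interval_ps)
}
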