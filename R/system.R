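#' Construct a molecular system
#'
#' A `molecular_system` bundles an atom table, optional Lennard-Jones
#' pair-coefficient tables, and an optional snapshot ensemble of
#' coordinates.  It is the container every unit scheme and energy
#' computation operates on.
#'
#' @param atoms data frame with one row per atom and columns `atom_id`
#'   (integer, unique), `name` (PDB atom name), `element` (symbol),
#'   `chain`, `resname`, `resid` (residue sequence number), `charge`
#'   (partial charge, elementary-charge units) and, for Lennard-Jones
#'   combining, `rmin_half` (Angstrom) and `epsilon` (kcal/mol).
#' @param coords optional coordinates: either an `n_atoms x 3` matrix
#'   (single snapshot) or an `n_atoms x 3 x n_frames` array.
#' @param times optional numeric vector of snapshot times (ps), strictly
#'   increasing, one per frame.
#' @param lj_pairs optional tabulated per-pair Lennard-Jones
#'   coefficients: a list with `type_index` (integer per atom), `acoef`
#'   and `bcoef` (symmetric `n_types x n_types` matrices of C12 and C6).
#'   When present these take precedence over combining `rmin_half` /
#'   `epsilon`.
#'
#' @return An object of class `molecular_system`.
#' @export
molecular_system <- function(atoms, coords = NULL, times = NULL, lj_pairs = NULL) {
  required <- c("atom_id", "name", "element", "chain", "resname", "resid", "charge")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols) > 0)
    stop("atoms table is missing columns: ", paste(missing_cols, collapse = ", "))
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  if (anyDuplicated(atoms$atom_id))
    stop("atom_id values must be unique")
  if (any(!is.finite(atoms$charge)))
    stop("all atomic charges must be finite")
  if (!is.null(atoms$rmin_half) && any(atoms$rmin_half < 0, na.rm = TRUE))
    stop("rmin_half must be non-negative")
  if (!is.null(atoms$epsilon) && any(atoms$epsilon < 0, na.rm = TRUE))
    stop("epsilon must be non-negative")
  key <- paste(atoms$chain, atoms$resname, atoms$resid)
  dup <- vapply(split(atoms$name, key), anyDuplicated, 0L)
  if (any(dup > 0))
    stop("duplicate atom name within residue: ", names(dup)[dup > 0][1])
  atoms$is_heavy <- toupper(atoms$element) != "H"

  if (!is.null(coords)) {
    if (length(dim(coords)) == 2) coords <- array(coords, c(nrow(coords), 3, 1))
    if (dim(coords)[1] != nrow(atoms))
      stop("coords have ", dim(coords)[1], " atoms but the atom table has ", nrow(atoms))
    if (dim(coords)[2] != 3) stop("coords must have 3 spatial columns")
    if (is.null(times)) times <- seq_len(dim(coords)[3]) - 1
    if (length(times) != dim(coords)[3])
      stop("times must have one entry per snapshot")
    if (any(diff(times) <= 0)) stop("snapshot times must be strictly increasing")
  }
  structure(
    list(atoms = atoms, coords = coords, times = times, lj_pairs = lj_pairs),
    class = "molecular_system"
  )
}

#' @export
print.molecular_system <- function(x, ...) {
  nf <- n_frames(x)
  cat("molecular_system:", nrow(x$atoms), "atoms,",
      length(unique(paste(x$atoms$chain, x$atoms$resid))), "residues,",
      nf, "snapshot(s)\n")
  invisible(x)
}

#' Number of snapshots held by a system
#' @param system a [molecular_system()]
#' @return integer frame count (0 when no coordinates are attached)
#' @export
n_frames <- function(system) {
  if (is.null(system$coords)) 0L else dim(system$coords)[3]
}

#' Extract one snapshot's coordinate matrix
#' @param system a [molecular_system()]
#' @param frame frame index (1-based)
#' @return `n_atoms x 3` numeric matrix
#' @export
snapshot_coords <- function(system, frame = 1L) {
  if (is.null(system$coords)) stop("system has no coordinates")
  if (frame < 1 || frame > n_frames(system))
    stop("frame ", frame, " out of range 1..", n_frames(system))
  system$coords[, , frame, drop = TRUE]
}

residue_keys <- function(atoms) paste(atoms$chain, atoms$resname, atoms$resid, sep = "|")

#' Read a (multi-model) PDB file into a molecular system
#'
#' Models of a multi-model PDB become the snapshot ensemble.  Charges
#' and Lennard-Jones parameters are not present in PDB files; supply a
#' topology (see [read_topology_json()] or [read_parm7()]) to attach
#' them, or leave them zero for geometry-only work.  The first alternate
#' location of each atom is kept; insertion codes are folded into the
#' residue id.  Legacy `O1P`/`O2P` phosphate names are canonicalised to
#' `OP1`/`OP2`.
#'
#' @param file path to a PDB file
#' @param topology optional list as returned by [read_topology_json()] or
#'   [read_parm7()]; its charges/LJ parameters are matched by atom order.
#' @param times optional snapshot times (ps); defaults to 0, 1, ... frames.
#' @return a [molecular_system()]
#' @export
read_pdb_system <- function(file, topology = NULL, times = NULL) {
  pdb <- bio3d::read.pdb(file, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  keep <- at$alt %in% c("", " ", NA, "A")
  at <- at[keep, , drop = FALSE]
  name <- trimws(at$elety)
  name[name == "O1P"] <- "OP1"
  name[name == "O2P"] <- "OP2"
  insert <- ifelse(is.na(at$insert) | at$insert %in% c("", " "), "", at$insert)
  elem <- trimws(at$elesy)
  no_elem <- is.na(elem) | elem == ""
  elem[no_elem] <- substr(gsub("[0-9']", "", name[no_elem]), 1, 1)
  atoms <- data.frame(
    atom_id = seq_along(name),
    name = name,
    element = elem,
    chain = ifelse(is.na(at$chain), "A", at$chain),
    resname = trimws(at$resid),
    resid = paste0(at$resno, insert),
    charge = 0,
    stringsAsFactors = FALSE
  )
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  nf <- nrow(xyz)
  coords <- array(NA_real_, c(nrow(atoms), 3, nf))
  idx <- which(keep)
  for (f in seq_len(nf)) {
    m <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
    coords[, , f] <- m[idx, , drop = FALSE]
  }
  sys <- molecular_system(atoms, coords, times = times)
  if (!is.null(topology)) sys <- attach_topology(sys, topology)
  sys
}

#' Attach topology parameters (charges, LJ) to a system
#'
#' Matching is positional: the topology must describe the same atoms in
#' the same order as the system.
#'
#' @param system a [molecular_system()]
#' @param topology list from [read_topology_json()] or [read_parm7()]
#' @return the system with charges/LJ parameters filled in
#' @export
attach_topology <- function(system, topology) {
  ta <- topology$atoms
  if (nrow(ta) != nrow(system$atoms))
    stop("topology has ", nrow(ta), " atoms but system has ", nrow(system$atoms))
  if (any(trimws(ta$name) != system$atoms$name))
    warning("topology atom names do not all match system atom names; positional matching used")
  system$atoms$charge <- ta$charge
  if (!is.null(ta$rmin_half)) system$atoms$rmin_half <- ta$rmin_half
  if (!is.null(ta$epsilon)) system$atoms$epsilon <- ta$epsilon
  system$lj_pairs <- topology$lj_pairs
  system
}

#' Read a JSON topology
#'
#' The JSON topology is the package's documented interchange format for
#' synthetic and toy systems.  Schema (all energies kcal/mol, lengths
#' Angstrom, charges elementary units):
#'
#' ```
#' {
#'   "atoms": [{"atom_id": 1, "name": "P", "element": "P",
#'              "chain": "A", "resname": "DG", "resid": "1",
#'              "charge": 1.1, "rmin_half": 2.1, "epsilon": 0.2}, ...],
#'   "exclusions": [[1,2], [1,3], ...],
#'   "scaled14":   [[1,5], ...],
#'   "scee": 1.2,
#'   "scnb": 2.0
#' }
#' ```
#'
#' `exclusions` are fully excluded (1-2/1-3) atom-id pairs; `scaled14`
#' pairs are scaled by `1/scee` (electrostatics) and `1/scnb` (van der
#' Waals).
#'
#' @param file path to the JSON topology
#' @return list with elements `atoms` (data frame), `rules`
#'   (a [nonbonded_rules()]) and `lj_pairs` (`NULL` for this format)
#' @export
read_topology_json <- function(file) {
  top <- jsonlite::fromJSON(file, simplifyDataFrame = TRUE)
  atoms <- as.data.frame(top$atoms, stringsAsFactors = FALSE)
  atoms$resid <- as.character(atoms$resid)
  to_mat <- function(x) {
    if (is.null(x) || length(x) == 0) return(matrix(integer(), ncol = 2))
    m <- if (is.matrix(x)) x else do.call(rbind, x)
    storage.mode(m) <- "integer"
    m
  }
  rules <- nonbonded_rules(
    excluded = to_mat(top$exclusions),
    scaled14 = to_mat(top$scaled14),
    scee = if (is.null(top$scee)) 1.2 else top$scee,
    scnb = if (is.null(top$scnb)) 2.0 else top$scnb
  )
  list(atoms = atoms, rules = rules, lj_pairs = NULL)
}

#' Write a JSON topology
#'
#' Inverse of [read_topology_json()]; used by the synthetic-data
#' generator so the same files the real pipeline consumes can be
#' produced from code.
#'
#' @param atoms atom data frame (see [molecular_system()])
#' @param rules a [nonbonded_rules()]
#' @param file output path
#' @return `file`, invisibly
#' @export
write_topology_json <- function(atoms, rules, file) {
  cols <- intersect(c("atom_id", "name", "element", "chain", "resname", "resid",
                      "charge", "rmin_half", "epsilon"), names(atoms))
  obj <- list(
    atoms = atoms[, cols],
    exclusions = unname(apply(rules$excluded, 1, function(r) as.integer(r), simplify = FALSE)),
    scaled14 = unname(apply(rules$scaled14, 1, function(r) as.integer(r), simplify = FALSE)),
    scee = rules$scee,
    scnb = rules$scnb
  )
  jsonlite::write_json(obj, file, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(file)
}

## ---- AMBER parm7 -----------------------------------------------------------

parm7_sections <- function(lines) {
  flags <- grep("^%FLAG", lines)
  names <- trimws(sub("^%FLAG", "", lines[flags]))
  ends <- c(flags[-1] - 1L, length(lines))
  out <- list()
  for (k in seq_along(flags)) {
    body <- lines[(flags[k] + 1L):ends[k]]
    body <- body[!grepl("^%", body)]
    out[[names[k]]] <- body
  }
  out
}

parm7_numeric <- function(section) {
  if (is.null(section)) return(numeric())
  as.numeric(unlist(strsplit(trimws(paste(section, collapse = " ")), "\\s+")))
}

parm7_names <- function(section, width = 4L) {
  txt <- paste(section, collapse = "")
  n <- nchar(txt) %/% width
  out <- trimws(substring(txt, (seq_len(n) - 1L) * width + 1L, seq_len(n) * width))
  out[out != ""]
}

#' Read an AMBER parm7 (prmtop) topology
#'
#' Parses the plain-text `%FLAG` sections needed for pairwise nonbonded
#' energies: atom names, charges (converted from AMBER internal units by
#' dividing by 18.2223), atomic numbers, residue labels/pointers,
#' Lennard-Jones A/B coefficient tables with atom type indices, the
#' excluded-atoms list, the `SCEE`/`SCNB` 1-4 scale factors, and the 1-4
#' pairs implied by the dihedral lists (fourth atom of each dihedral
#' whose third index is non-negative).  Bonded force-field terms are not
#' read.
#'
#' @param file path to a parm7 file
#' @return list with `atoms` (data frame), `rules` (a
#'   [nonbonded_rules()]; excluded = excluded-atoms list minus 1-4
#'   pairs) and `lj_pairs` (tabulated A/B coefficients)
#' @export
read_parm7 <- function(file) {
  lines <- readLines(file)
  sec <- parm7_sections(lines)
  pointers <- parm7_numeric(sec$POINTERS)
  natom <- as.integer(pointers[1])
  ntypes <- as.integer(pointers[2])
  name <- parm7_names(sec$ATOM_NAME)[seq_len(natom)]
  name[name == "O1P"] <- "OP1"
  name[name == "O2P"] <- "OP2"
  charge <- parm7_numeric(sec$CHARGE)[seq_len(natom)] / 18.2223
  atnum <- as.integer(parm7_numeric(sec$ATOMIC_NUMBER))[seq_len(natom)]
  element <- element_from_z(atnum)
  reslab <- parm7_names(sec$RESIDUE_LABEL)
  resptr <- as.integer(parm7_numeric(sec$RESIDUE_POINTER))
  res_of <- findInterval(seq_len(natom), resptr)
  atoms <- data.frame(
    atom_id = seq_len(natom), name = name, element = element,
    chain = "A", resname = reslab[res_of], resid = as.character(res_of),
    charge = charge, stringsAsFactors = FALSE
  )
  type_index <- as.integer(parm7_numeric(sec$ATOM_TYPE_INDEX))[seq_len(natom)]
  nbidx <- as.integer(parm7_numeric(sec$NONBONDED_PARM_INDEX))
  acoef_flat <- parm7_numeric(sec$LENNARD_JONES_ACOEF)
  bcoef_flat <- parm7_numeric(sec$LENNARD_JONES_BCOEF)
  acoef <- matrix(0, ntypes, ntypes)
  bcoef <- matrix(0, ntypes, ntypes)
  for (i in seq_len(ntypes)) for (j in seq_len(ntypes)) {
    k <- nbidx[ntypes * (i - 1L) + j]
    if (k > 0) { acoef[i, j] <- acoef_flat[k]; bcoef[i, j] <- bcoef_flat[k] }
  }
  # 1-4 pairs: outer atoms of dihedrals; negative 3rd index marks improper
  # or already-counted multi-term dihedrals (no 1-4 interaction).
  dihed <- c(parm7_numeric(sec$DIHEDRALS_INC_HYDROGEN),
             parm7_numeric(sec$DIHEDRALS_WITHOUT_HYDROGEN))
  s14 <- matrix(integer(), ncol = 2)
  if (length(dihed) > 0) {
    d <- matrix(as.integer(dihed), ncol = 5, byrow = TRUE)
    ok <- d[, 3] >= 0 & d[, 4] >= 0
    if (any(ok)) {
      a <- abs(d[ok, 1]) %/% 3L + 1L
      l <- abs(d[ok, 4]) %/% 3L + 1L
      s14 <- unique(cbind(pmin(a, l), pmax(a, l)))
    }
  }
  nexc <- as.integer(parm7_numeric(sec$NUMBER_EXCLUDED_ATOMS))
  exc_list <- as.integer(parm7_numeric(sec$EXCLUDED_ATOMS_LIST))
  exc <- matrix(integer(), ncol = 2)
  if (length(exc_list) > 0) {
    owner <- rep(seq_len(natom), nexc)
    keep <- exc_list > 0  # 0 entries pad atoms with no exclusions
    exc <- cbind(pmin(owner[keep], exc_list[keep]),
                 pmax(owner[keep], exc_list[keep]))
    exc <- unique(exc)
  }
  # excluded list includes 1-4 partners; separate them out
  key <- function(m) paste(m[, 1], m[, 2])
  exc <- exc[!(key(exc) %in% key(s14)), , drop = FALSE]
  scee <- parm7_numeric(sec$SCEE_SCALE_FACTOR)
  scnb <- parm7_numeric(sec$SCNB_SCALE_FACTOR)
  rules <- nonbonded_rules(
    excluded = exc, scaled14 = s14,
    scee = if (length(scee)) scee[1] else 1.2,
    scnb = if (length(scnb)) scnb[1] else 2.0
  )
  list(atoms = atoms, rules = rules,
       lj_pairs = list(type_index = type_index, acoef = acoef, bcoef = bcoef))
}

element_from_z <- function(z) {
  tab <- c("H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne",
           "Na", "Mg", "Al", "Si", "P", "S", "Cl", "Ar", "K", "Ca")
  out <- rep("X", length(z))
  ok <- !is.na(z) & z >= 1 & z <= length(tab)
  out[ok] <- tab[z[ok]]
  out
}

#' Export unit-scheme assignments as TSV
#'
#' Writes one row per atom with its segment unit, fragment unit and
#' backbone/functional subunit label, the flat format used to audit
#' scheme construction.
#'
#' @param system a [molecular_system()]
#' @param segments segment [unit_scheme()]
#' @param fragments fragment [unit_scheme()] (optional)
#' @param labeling a subunit labeling from [label_subunits()] (optional)
#' @param file output path
#' @return `file`, invisibly
#' @export
write_scheme_tsv <- function(system, segments, fragments = NULL, labeling = NULL, file) {
  at <- system$atoms
  df <- data.frame(
    atom_id = at$atom_id, atom_name = at$name,
    residue = paste0(at$chain, ":", at$resname, at$resid),
    unit_segment = segments$units$label[match(segments$unit_of, segments$units$unit_id)],
    stringsAsFactors = FALSE
  )
  if (!is.null(fragments))
    df$unit_fragment <- fragments$units$label[match(fragments$unit_of, fragments$units$unit_id)]
  if (!is.null(labeling)) df$subunit <- unclass(labeling)
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
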