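#' Default residue dictionary
#'
#' Maps residue names to a category (`"nuc"` or `"aa"`) and a formal
#' charge.  Nucleotides carry -1 (anionic phosphate), Asp/Glu -1,
#' Lys/Arg +1, histidine is configurable (neutral by default; `HIP`
#' is always +1).  Users may extend the table for non-standard
#' residues.
#'
#' @param his_charge formal charge assigned to `HIS`/`HID`/`HIE`
#' @param extra optional data frame with columns `resname`, `category`,
#'   `formal_charge` appended to (and overriding) the defaults
#' @return data frame with columns `resname`, `category`, `formal_charge`
#' @export
default_residue_dict <- function(his_charge = 0L, extra = NULL) {
  nuc <- c("DA", "DT", "DG", "DC", "DU", "A", "T", "G", "C", "U",
           "DA5", "DT5", "DG5", "DC5", "DA3", "DT3", "DG3", "DC3")
  aa0 <- c("ALA", "ASN", "CYS", "CYX", "GLN", "GLY", "ILE", "LEU", "MET",
           "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL", "ASH", "GLH", "LYN")
  dict <- rbind(
    data.frame(resname = nuc, category = "nuc", formal_charge = -1L),
    data.frame(resname = aa0, category = "aa", formal_charge = 0L),
    data.frame(resname = c("ASP", "GLU"), category = "aa", formal_charge = -1L),
    data.frame(resname = c("LYS", "ARG"), category = "aa", formal_charge = 1L),
    data.frame(resname = c("HIS", "HID", "HIE"), category = "aa",
               formal_charge = as.integer(his_charge)),
    data.frame(resname = "HIP", category = "aa", formal_charge = 1L)
  )
  if (!is.null(extra)) {
    dict <- dict[!(dict$resname %in% extra$resname), ]
    dict <- rbind(dict, extra[, c("resname", "category", "formal_charge")])
  }
  dict
}

new_unit_scheme <- function(scheme_name, unit_of, units, covalent_pairs) {
  structure(list(scheme_name = scheme_name, unit_of = unit_of,
                 units = units, covalent_pairs = covalent_pairs),
            class = "unit_scheme")
}

#' @export
print.unit_scheme <- function(x, ...) {
  cat("unit_scheme (", x$scheme_name, "): ", nrow(x$units), " units (",
      sum(x$units$category == "nuc"), " nuc, ", sum(x$units$category == "aa"),
      " aa), ", nrow(x$covalent_pairs), " covalent pairs\n", sep = "")
  invisible(x)
}

unit_display_label <- function(resname, resid, category) {
  base <- sub("^D", "", resname)
  base <- sub("[53]$", "", base)
  ifelse(category == "nuc",
         paste0(base, resid),
         paste0(substr(resname, 1, 1), tolower(substr(resname, 2, 3)), resid))
}

#' Partition a system into segments (conventional residues)
#'
#' One unit per PDB residue: the segment scheme used for partition
#' analysis and force-field pair energies.  Categories and formal
#' charges come from the residue dictionary; covalent pairs are all
#' sequence-adjacent same-chain residue pairs.
#'
#' @param system a [molecular_system()]
#' @param residue_dict residue dictionary, see [default_residue_dict()]
#' @return a `unit_scheme` with `scheme_name = "segment"`
#' @export
assign_segments <- function(system, residue_dict = default_residue_dict()) {
  at <- system$atoms
  key <- residue_keys(at)
  first <- !duplicated(key)
  ukey <- key[first]
  # a residue key reappearing after other residues means a duplicate id
  runs <- rle(key)$values
  if (anyDuplicated(runs))
    stop("duplicate residue key: ", runs[duplicated(runs)][1])
  units <- data.frame(
    unit_id = seq_along(ukey),
    chain = at$chain[first], resname = at$resname[first],
    resid = as.character(at$resid[first]),
    stringsAsFactors = FALSE
  )
  m <- match(units$resname, residue_dict$resname)
  if (anyNA(m))
    stop("unrecognized residue name: ",
         paste(unique(units$resname[is.na(m)]), collapse = ", "),
         " (extend the residue dictionary)")
  units$category <- residue_dict$category[m]
  units$formal_charge <- residue_dict$formal_charge[m]
  units$label <- unit_display_label(units$resname, units$resid, units$category)
  unit_of <- match(key, ukey)
  cov <- do.call(rbind, lapply(split(units$unit_id, units$chain), function(ids) {
    if (length(ids) < 2) return(NULL)
    cbind(ids[-length(ids)], ids[-1])
  }))
  if (is.null(cov)) cov <- matrix(integer(), ncol = 2)
  rownames(cov) <- NULL
  new_unit_scheme("segment", unit_of, units, cov)
}

chain_unit_order <- function(scheme) {
  split(scheme$units$unit_id, scheme$units$chain)
}

#' Shift segments to FMO-style fragments
#'
#' Fragments have the same atom count per unit as residues but a
#' shifted boundary: for every non-C-terminal amino acid, its carbonyl
#' atoms \{C, O\} move to the next residue's fragment; for every
#' non-5'-terminal nucleotide, its phosphate atoms \{P, OP1, OP2\} move
#' to the previous residue's fragment.  Bridging O3'/O5' atoms stay
#' with their sugars.  Terminal residues are never shifted.  Atom count,
#' per-chain atom sets and total charge are conserved; unit labels are
#' unchanged.
#'
#' @param segments a segment [unit_scheme()] from [assign_segments()]
#' @param system the [molecular_system()] the scheme was built from
#' @param inverse if `TRUE`, undo the shift (fragments back to segments)
#' @return a `unit_scheme` with `scheme_name = "fragment"` (or
#'   `"segment"` when `inverse = TRUE`)
#' @export
shift_to_fragments <- function(segments, system, inverse = FALSE) {
  at <- system$atoms
  unit_of <- segments$unit_of
  units <- segments$units
  for (ids in chain_unit_order(segments)) {
    if (length(ids) < 2) next
    for (k in seq_along(ids)) {
      u <- ids[k]
      cat_u <- units$category[units$unit_id == u]
      if (cat_u == "aa" && k < length(ids)) {
        sel <- which(residue_unit(segments, at) == u & at$name %in% c("C", "O"))
        if (length(sel) < 2)
          stop("residue ", units$label[units$unit_id == u],
               " is missing backbone atom ",
               paste(setdiff(c("C", "O"), at$name[sel]), collapse = "/"))
        unit_of[sel] <- if (inverse) u else ids[k + 1]
      }
      if (cat_u == "nuc" && k > 1) {
        phos <- c("P", "OP1", "OP2", "O1P", "O2P")
        sel <- which(residue_unit(segments, at) == u & at$name %in% phos)
        if (length(sel) < 3)
          stop("nucleotide ", units$label[units$unit_id == u],
               " is missing phosphate atoms (found ",
               paste(at$name[sel], collapse = ","), ")")
        unit_of[sel] <- if (inverse) u else ids[k - 1]
      }
    }
  }
  new_unit_scheme(if (inverse) "segment" else "fragment",
                  unit_of, units, segments$covalent_pairs)
}

# unit each atom's own residue maps to (independent of any shift applied)
residue_unit <- function(scheme, atoms) {
  key <- paste(atoms$chain, atoms$resid)
  ukey <- paste(scheme$units$chain, scheme$units$resid)
  scheme$units$unit_id[match(key, ukey)]
}

#' Label atoms as backbone (b) or functional (f) subunits
#'
#' Amino acids: backbone is the peptide main chain (N, CA, C, O, OXT
#' and their hydrogens H/H1-H3/HA/HA2/HA3); everything else is the side
#' chain (functional).  Glycine has an empty functional set.
#' Nucleotides: backbone is the phosphate + pentose (any atom whose
#' name contains a prime, plus P/OP1/OP2 and dialect variants); the
#' remaining atoms form the base (functional).  Splitting is defined
#' for segment schemes only.
#'
#' @param system a [molecular_system()]
#' @param scheme a segment [unit_scheme()]
#' @return character vector (one of `"b"`, `"f"` per atom) of class
#'   `subunit_labeling`
#' @export
label_subunits <- function(system, scheme) {
  if (scheme$scheme_name != "segment")
    stop("backbone/functional splitting is defined for segment schemes only")
  at <- system$atoms
  cat_of <- scheme$units$category[match(scheme$unit_of, scheme$units$unit_id)]
  lab <- rep(NA_character_, nrow(at))
  aa_bb <- c("N", "CA", "C", "O", "OXT", "H", "H1", "H2", "H3", "HA", "HA2", "HA3")
  nuc_bb <- c("P", "OP1", "OP2", "O1P", "O2P", "OP3", "H5T", "H3T")
  is_aa <- cat_of == "aa"
  is_nuc <- cat_of == "nuc"
  lab[is_aa] <- ifelse(at$name[is_aa] %in% aa_bb, "b", "f")
  lab[is_nuc] <- ifelse(grepl("'", at$name[is_nuc]) | at$name[is_nuc] %in% nuc_bb,
                        "b", "f")
  if (anyNA(lab))
    stop("atoms in units of unknown category cannot be labeled: ",
         paste(utils::head(at$name[is.na(lab)], 5), collapse = ", "))
  structure(lab, scheme_name = scheme$scheme_name, class = "subunit_labeling")
}

#' Construct a functional-group scheme for a base pair
#'
#' A group scheme names the hydrogen bonds, CO...H contacts and weak
#' electrostatic (ES) contacts between the two bases of a pair, giving
#' for each bond the (disjoint) atom-name sets on either base used for
#' energy decomposition and a pair of heavy probe atoms used for bond
#' length statistics.
#'
#' @param pair_type two base letters, e.g. `c("A", "T")`
#' @param groups named list: bond label -> list with one character
#'   vector of atom names per base letter
#' @param probes data frame with columns `bond`, `atom_a`, `atom_b`
#' @return object of class `group_scheme`
#' @export
group_scheme <- function(pair_type, groups, probes) {
  stopifnot(length(pair_type) == 2)
  for (base in pair_type) {
    all_atoms <- unlist(lapply(groups, function(g) g[[base]]))
    if (anyDuplicated(all_atoms))
      stop("group atom sets must be disjoint within base ", base, ": ",
           all_atoms[duplicated(all_atoms)][1], " appears twice")
  }
  structure(list(pair_type = pair_type, groups = groups,
                 probes = as.data.frame(probes, stringsAsFactors = FALSE)),
            class = "group_scheme")
}

#' Default functional-group schemes for base pairs
#'
#' Supported pair types: A:T and C:G (Watson-Crick) and the G:T wobble
#' mismatch.  Hydrogen-bond groups and probe atoms follow the standard
#' pairing geometry; the weak-ES group memberships are provisional
#' defaults and can be overridden via `es_groups`.  A:T has two
#' hydrogen bonds plus a CO...H contact, C:G has three hydrogen bonds,
#' G:T (wobble) has two hydrogen bonds plus CO...H and ES contacts.
#'
#' @param pair_type `c("A","T")`, `c("C","G")` or `c("G","T")`
#' @param es_groups optional named list overriding/extending the weak-ES
#'   bond groups (same structure as `groups` in [group_scheme()])
#' @return a [group_scheme()]
#' @export
default_group_scheme <- function(pair_type, es_groups = NULL) {
  key <- paste(pair_type, collapse = ":")
  defs <- list(
    "A:T" = list(
      groups = list(
        HB1     = list(A = "N6", T = "O4"),
        HB2     = list(A = "N1", T = "N3"),
        "CO..H" = list(A = "C2", T = "O2")
      ),
      probes = data.frame(
        bond = c("HB1", "HB2", "CO..H"),
        atom_a = c("N6", "N1", "C2"),
        atom_b = c("O4", "N3", "O2"))
    ),
    "C:G" = list(
      groups = list(
        HB1 = list(C = "N3", G = "N1"),
        HB2 = list(C = "N4", G = "O6"),
        HB3 = list(C = "O2", G = "N2"),
        ES1 = list(C = "C2", G = "C2"),
        ES2 = list(C = "C4", G = "C6")
      ),
      probes = data.frame(
        bond = c("HB1", "HB2", "HB3"),
        atom_a = c("N1", "O6", "O2"),
        atom_b = c("N3", "N4", "N2"))
    ),
    "G:T" = list(
      groups = list(
        HB1     = list(G = "N1", T = "O4"),
        HB2     = list(G = "N2", T = "N3"),
        "CO..H" = list(G = "O6", T = "C7"),
        ES1     = list(G = "N3", T = "O2")
      ),
      probes = data.frame(
        bond = c("HB1", "HB2", "CO..H"),
        atom_a = c("O4", "O4", "C7"),
        atom_b = c("N1", "N2", "O6"))
    )
  )
  if (!key %in% names(defs))
    stop("unsupported base-pair type: ", key,
         " (supported: A:T, C:G, G:T)")
  d <- defs[[key]]
  if (!is.null(es_groups)) {
    for (nm in names(es_groups)) d$groups[[nm]] <- es_groups[[nm]]
  }
  group_scheme(pair_type, d$groups, d$probes)
}

#' Atom indices belonging to a unit
#' @param scheme a [unit_scheme()]
#' @param unit a unit id or display label
#' @return integer vector of atom row indices
#' @export
unit_atoms <- function(scheme, unit) {
  if (is.character(unit)) {
    m <- match(unit, scheme$units$label)
    if (is.na(m)) stop("unknown unit label: ", unit)
    unit <- scheme$units$unit_id[m]
  }
  which(scheme$unit_of == unit)
}

#' Formal-charge and totality checks for a unit scheme
#'
#' @param scheme a [unit_scheme()]
#' @param system the matching [molecular_system()]
#' @return `TRUE` invisibly; errors describe any violated invariant
#' @export
validate_scheme <- function(scheme, system) {
  if (length(scheme$unit_of) != nrow(system$atoms))
    stop("scheme does not cover all atoms")
  if (anyNA(scheme$unit_of))
    stop("some atoms are not assigned to any unit")
  if (!all(scheme$unit_of %in% scheme$units$unit_id))
    stop("unit_of refers to unknown unit ids")
  invisible(TRUE)
}
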