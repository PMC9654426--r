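#' Nonbonded interaction rules
#'
#' Holds the bookkeeping a force field imposes on pairwise sums:
#' fully excluded (1-2/1-3) atom pairs, 1-4 pairs scaled by `1/scee`
#' (electrostatics) and `1/scnb` (van der Waals), the dielectric
#' constant, and the Coulomb conversion constant.
#'
#' @param excluded two-column integer matrix of excluded atom-id pairs
#' @param scaled14 two-column integer matrix of 1-4 atom-id pairs
#' @param dielectric relative permittivity (dimensionless, > 0);
#'   electrostatic energies scale as its inverse
#' @param coulomb_constant conversion constant in kcal A / (mol e^2);
#'   the AMBER convention value by default
#' @param scee,scnb 1-4 scale divisors for electrostatics and van der
#'   Waals (AMBER defaults 1.2 and 2.0)
#' @return object of class `nonbonded_rules`
#' @export
nonbonded_rules <- function(excluded = matrix(integer(), ncol = 2),
                            scaled14 = matrix(integer(), ncol = 2),
                            dielectric = 1,
                            coulomb_constant = 332.0522173,
                            scee = 1.2, scnb = 2.0) {
  excluded <- pair_matrix(excluded)
  scaled14 <- pair_matrix(scaled14)
  if (dielectric <= 0) stop("dielectric constant must be positive")
  if (nrow(excluded) > 0 && nrow(scaled14) > 0) {
    overlap <- intersect(pair_key(excluded), pair_key(scaled14))
    if (length(overlap) > 0)
      stop("excluded and 1-4 scaled pair sets must be disjoint (",
           overlap[1], ")")
  }
  structure(list(excluded = excluded, scaled14 = scaled14,
                 dielectric = dielectric,
                 coulomb_constant = coulomb_constant,
                 scee = scee, scnb = scnb),
            class = "nonbonded_rules")
}

pair_matrix <- function(m) {
  if (is.null(m) || length(m) == 0) return(matrix(integer(), ncol = 2))
  m <- matrix(as.integer(m), ncol = 2)
  unique(cbind(pmin(m[, 1], m[, 2]), pmax(m[, 1], m[, 2])))
}

pair_key <- function(m) paste(m[, 1], m[, 2], sep = "-")

# n x n weight matrices for elec and vdw sums: 1 everywhere off-diagonal,
# 0 on excluded pairs and the diagonal, 1/scee or 1/scnb on 1-4 pairs
weight_matrices <- function(n, rules) {
  w_elec <- matrix(1, n, n)
  diag(w_elec) <- 0
  w_vdw <- w_elec
  if (nrow(rules$excluded) > 0) {
    idx <- rbind(rules$excluded, rules$excluded[, 2:1, drop = FALSE])
    w_elec[idx] <- 0
    w_vdw[idx] <- 0
  }
  if (nrow(rules$scaled14) > 0) {
    idx <- rbind(rules$scaled14, rules$scaled14[, 2:1, drop = FALSE])
    w_elec[idx] <- 1 / rules$scee
    w_vdw[idx] <- 1 / rules$scnb
  }
  list(elec = w_elec, vdw = w_vdw)
}

distance_matrix <- function(coords) {
  d2 <- outer(rowSums(coords^2), rowSums(coords^2), "+") - 2 * tcrossprod(coords)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

lj_coefficients <- function(system) {
  n <- nrow(system$atoms)
  if (!is.null(system$lj_pairs)) {
    ti <- system$lj_pairs$type_index
    list(A = system$lj_pairs$acoef[ti, ti, drop = FALSE],
         B = system$lj_pairs$bcoef[ti, ti, drop = FALSE])
  } else {
    rh <- system$atoms$rmin_half
    ep <- system$atoms$epsilon
    if (is.null(rh) || is.null(ep))
      stop("system has neither tabulated LJ pair coefficients nor ",
           "per-atom rmin_half/epsilon parameters")
    rmin <- outer(rh, rh, "+")                 # Lorentz-Berthelot arithmetic
    eps <- sqrt(outer(ep, ep))                 # geometric well depth
    list(A = eps * rmin^12, B = 2 * eps * rmin^6)
  }
}

#' Atom-level pairwise energy matrices for one snapshot
#'
#' Computes the full `n x n` electrostatic and van der Waals energy
#' matrices (kcal/mol) with exclusions and 1-4 weights applied:
#' `elec[A,B] = w_AB * k * Q_A * Q_B / (eps * R_AB)` and
#' `vdw[A,B] = w_AB * (C12_AB / R_AB^12 - C6_AB / R_AB^6)`.
#' Unit pair energies are block sums over these matrices.
#'
#' @param system a [molecular_system()] with charges (and LJ parameters)
#' @param rules a [nonbonded_rules()]
#' @param frame snapshot index
#' @param coords optional explicit `n x 3` coordinate matrix overriding
#'   `frame`
#' @return list with matrices `elec` and `vdw`
#' @export
pair_energy_matrices <- function(system, rules = nonbonded_rules(),
                                 frame = 1L, coords = NULL) {
  if (is.null(coords)) coords <- snapshot_coords(system, frame)
  n <- nrow(system$atoms)
  r <- distance_matrix(coords)
  w <- weight_matrices(n, rules)
  active <- (w$elec > 0) | (w$vdw > 0)
  if (any(r[active] == 0 & row(r)[active] != col(r)[active]))
    stop("coincident atoms: zero interatomic distance between distinct atoms")
  rinv <- r
  diag(rinv) <- 1  # dummy; diagonal weights are zero
  rinv <- 1 / rinv
  q <- system$atoms$charge
  elec <- (rules$coulomb_constant / rules$dielectric) * tcrossprod(q) * rinv * w$elec
  lj <- lj_coefficients(system)
  r6 <- rinv^6
  vdw <- (lj$A * r6^2 - lj$B * r6) * w$vdw
  diag(elec) <- 0
  diag(vdw) <- 0
  list(elec = elec, vdw = vdw)
}

#' Electrostatic interaction energy between two atom sets
#'
#' Coulomb sum `k * Q_A * Q_B / (eps * R_AB)` over all non-excluded
#' atom pairs (A in i, B in j), with 1-4 pairs weighted by `1/scee`.
#' Exactly linear in the inverse dielectric constant.
#'
#' @param system a [molecular_system()]
#' @param atoms_i,atoms_j integer atom row indices of the two sets
#' @param rules a [nonbonded_rules()]
#' @param frame snapshot index
#' @param coords optional explicit coordinates
#' @return energy in kcal/mol
#' @export
elec_energy <- function(system, atoms_i, atoms_j, rules = nonbonded_rules(),
                        frame = 1L, coords = NULL) {
  m <- pair_energy_matrices(system, rules, frame, coords)
  sum(m$elec[atoms_i, atoms_j])
}

#' Lennard-Jones interaction energy between two atom sets
#'
#' `C12_AB / R^12 - C6_AB / R^6` summed over non-excluded atom pairs,
#' with 1-4 pairs weighted by `1/scnb`.  Pair coefficients come from
#' tabulated A/B matrices when the system carries them, otherwise from
#' Lorentz-Berthelot combining of per-atom `rmin_half`/`epsilon`.
#'
#' @inheritParams elec_energy
#' @return energy in kcal/mol
#' @export
vdw_energy <- function(system, atoms_i, atoms_j, rules = nonbonded_rules(),
                       frame = 1L, coords = NULL) {
  m <- pair_energy_matrices(system, rules, frame, coords)
  sum(m$vdw[atoms_i, atoms_j])
}

#' Pairwise interaction-energy table between units
#'
#' For every unit pair (i < j) and every requested snapshot, the
#' electrostatic and van der Waals interaction energies and their sum,
#' with covalently adjacent unit pairs flagged.  Intra-unit energies
#' are not pair quantities and are not included.  Block sums over the
#' atom-level matrices make this exactly equal to the naive double loop
#' over atom pairs.
#'
#' @param system a [molecular_system()] with coordinates
#' @param scheme a [unit_scheme()]
#' @param rules a [nonbonded_rules()]
#' @param frames snapshot indices (default: all)
#' @param cutoff optional distance cutoff (Angstrom): pairs whose
#'   closest atom-atom distance exceeds it are dropped.  Default `NULL`
#'   keeps all pairs.
#' @return data frame with columns `unit_i`, `unit_j`, `snapshot`,
#'   `level` (`"MM"`), `scheme`, `elec`, `vdw`, `total`, `is_covalent`
#' @export
unit_pair_table <- function(system, scheme, rules = nonbonded_rules(),
                            frames = NULL, cutoff = NULL) {
  validate_scheme(scheme, system)
  if (is.null(frames)) frames <- seq_len(max(1L, n_frames(system)))
  nu <- nrow(scheme$units)
  uids <- scheme$units$unit_id
  ind <- matrix(0, nrow(system$atoms), nu)
  ind[cbind(seq_len(nrow(system$atoms)), match(scheme$unit_of, uids))] <- 1
  ut <- which(upper.tri(matrix(0, nu, nu)), arr.ind = TRUE)
  cov_keys <- pair_key(pair_matrix(scheme$covalent_pairs))
  out <- vector("list", length(frames))
  for (k in seq_along(frames)) {
    f <- frames[k]
    m <- pair_energy_matrices(system, rules, frame = f)
    e_units <- t(ind) %*% m$elec %*% ind
    v_units <- t(ind) %*% m$vdw %*% ind
    df <- data.frame(
      unit_i = uids[ut[, 1]], unit_j = uids[ut[, 2]],
      snapshot = f, level = "MM", scheme = scheme$scheme_name,
      elec = e_units[ut], vdw = v_units[ut],
      stringsAsFactors = FALSE
    )
    if (!is.null(cutoff)) {
      r <- distance_matrix(snapshot_coords(system, f))
      keep <- vapply(seq_len(nrow(ut)), function(p) {
        ai <- which(ind[, ut[p, 1]] > 0); aj <- which(ind[, ut[p, 2]] > 0)
        min(r[ai, aj]) <= cutoff
      }, logical(1))
      df <- df[keep, , drop = FALSE]
    }
    out[[k]] <- df
  }
  res <- do.call(rbind, out)
  res$total <- res$elec + res$vdw
  res$is_covalent <- pair_key(cbind(pmin(res$unit_i, res$unit_j),
                                    pmax(res$unit_i, res$unit_j))) %in% cov_keys
  rownames(res) <- NULL
  res
}

#' Atom-resolved energy matrix for one unit pair
#'
#' The elec/vdw submatrices between the atoms of two units, the
#' resolution at which backbone/functional and functional-group
#' decompositions operate.
#'
#' @param system a [molecular_system()]
#' @param scheme a [unit_scheme()]
#' @param pair two unit ids or display labels
#' @param rules a [nonbonded_rules()]
#' @param frame snapshot index
#' @return object of class `atom_pair_energy`: atom indices `atoms_i`,
#'   `atoms_j` and matrices `elec`, `vdw`, `total`
#' @export
atom_pair_matrix <- function(system, scheme, pair, rules = nonbonded_rules(),
                             frame = 1L) {
  ai <- unit_atoms(scheme, pair[[1]])
  aj <- unit_atoms(scheme, pair[[2]])
  m <- pair_energy_matrices(system, rules, frame)
  structure(list(
    atoms_i = ai, atoms_j = aj,
    names_i = system$atoms$name[ai], names_j = system$atoms$name[aj],
    elec = m$elec[ai, aj, drop = FALSE],
    vdw = m$vdw[ai, aj, drop = FALSE],
    total = m$elec[ai, aj, drop = FALSE] + m$vdw[ai, aj, drop = FALSE]
  ), class = "atom_pair_energy")
}

#' Backbone/functional decomposition of a unit-pair energy
#'
#' Splits a pair energy into the four subunit blocks bb, bf, fb and ff,
#' where the first letter refers to the first unit (e.g. `bf` is the
#' backbone of unit i with the functional unit of j).  The four blocks
#' partition the total exactly.  Blocks involving an empty functional
#' set (glycine has no side chain) are reported as `NA` (absent), not
#' zero.
#'
#' @param apm an [atom_pair_matrix()]
#' @param labeling a [label_subunits()] labeling
#' @param component which energy component to decompose
#' @return named numeric vector `c(bb, bf, fb, ff)`
#' @export
subunit_decompose <- function(apm, labeling,
                              component = c("total", "elec", "vdw")) {
  component <- match.arg(component)
  m <- apm[[component]]
  li <- unclass(labeling)[apm$atoms_i]
  lj <- unclass(labeling)[apm$atoms_j]
  block <- function(a, b) {
    if (!any(li == a) && a == "f") return(NA_real_)
    if (!any(lj == b) && b == "f") return(NA_real_)
    sum(m[li == a, lj == b])
  }
  c(bb = block("b", "b"), bf = block("b", "f"),
    fb = block("f", "b"), ff = block("f", "f"))
}

#' Functional-group (per-bond) decomposition of a unit-pair energy
#'
#' Splits the functional-functional (base-base) part of a pair energy
#' into named bond contributions (hydrogen bonds, CO...H, weak ES) plus
#' a `rest` term so that `sum(named) + rest` equals the ff total
#' exactly.
#'
#' @param apm an [atom_pair_matrix()] (first unit must match the first
#'   base letter of the group scheme)
#' @param groups a [group_scheme()]
#' @param labeling a [label_subunits()] labeling (defines the ff block)
#' @param component energy component to decompose
#' @return named numeric vector of bond energies, including `rest` and
#'   `ff_total`
#' @export
group_decompose <- function(apm, groups, labeling,
                            component = c("total", "elec", "vdw")) {
  component <- match.arg(component)
  m <- apm[[component]]
  li <- unclass(labeling)[apm$atoms_i]
  lj <- unclass(labeling)[apm$atoms_j]
  ff_total <- sum(m[li == "f", lj == "f"])
  base_i <- groups$pair_type[1]
  base_j <- groups$pair_type[2]
  vals <- vapply(names(groups$groups), function(bond) {
    g <- groups$groups[[bond]]
    sel_i <- match(g[[base_i]], apm$names_i)
    sel_j <- match(g[[base_j]], apm$names_j)
    if (anyNA(sel_i))
      stop("group ", bond, ": atom ", g[[base_i]][is.na(sel_i)][1],
           " not found in first unit")
    if (anyNA(sel_j))
      stop("group ", bond, ": atom ", g[[base_j]][is.na(sel_j)][1],
           " not found in second unit")
    sum(m[sel_i, sel_j, drop = FALSE])
  }, numeric(1))
  c(vals, rest = ff_total - sum(vals), ff_total = ff_total)
}

#' Ensemble table of backbone/functional decompositions
#'
#' Convenience wrapper: [subunit_decompose()] for each listed pair and
#' snapshot, returned as a long data frame ready for
#' [ensemble_mean_std()].
#'
#' @param system,scheme,rules,frames as in [unit_pair_table()]
#' @param labeling a [label_subunits()] labeling
#' @param pairs two-column matrix (or list of length-2 vectors) of unit
#'   ids/labels; default: all unit pairs
#' @return data frame with columns `unit_i`, `unit_j`, `snapshot`,
#'   `bb`, `bf`, `fb`, `ff`
#' @export
subunit_pair_table <- function(system, scheme, labeling,
                               rules = nonbonded_rules(),
                               frames = NULL, pairs = NULL) {
  if (is.null(frames)) frames <- seq_len(max(1L, n_frames(system)))
  if (is.null(pairs)) {
    nu <- scheme$units$unit_id
    ut <- which(upper.tri(matrix(0, length(nu), length(nu))), arr.ind = TRUE)
    pairs <- cbind(nu[ut[, 1]], nu[ut[, 2]])
  }
  if (is.list(pairs)) pairs <- do.call(rbind, pairs)
  lab <- unclass(labeling)
  rows <- list()
  for (f in frames) {
    m <- pair_energy_matrices(system, rules, frame = f)
    tot <- m$elec + m$vdw
    for (p in seq_len(nrow(pairs))) {
      ai <- unit_atoms(scheme, pairs[p, 1][[1]])
      aj <- unit_atoms(scheme, pairs[p, 2][[1]])
      li <- lab[ai]; lj <- lab[aj]
      sub <- tot[ai, aj, drop = FALSE]
      block <- function(a, b) {
        if ((a == "f" && !any(li == "f")) || (b == "f" && !any(lj == "f")))
          return(NA_real_)
        sum(sub[li == a, lj == b])
      }
      rows[[length(rows) + 1L]] <- data.frame(
        unit_i = pairs[p, 1], unit_j = pairs[p, 2], snapshot = f,
        bb = block("b", "b"), bf = block("b", "f"),
        fb = block("f", "b"), ff = block("f", "f"),
        row.names = NULL, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
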