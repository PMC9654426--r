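#' Configuration for the synthetic-data generators
#'
#' The defaults encode the study conditions the generators emulate:
#' 100-snapshot ensembles, hydrogen-bond heavy-atom contacts near
#' 2.95 Angstrom, coordinate jitter giving pair-energy standard
#' deviations of a few percent of the means, QM electrostatics
#' tracking MM electrostatics with a slope slightly below one,
#' strong (near-total, but sub-unity) solvent screening opposing the
#' electrostatics of charged pairs, dispersion decoupled from the
#' force-field van der Waals term, and fractional unit charges
#' deviating a few percent from the formal integers.
#'
#' @param n_nuc_pairs number of base pairs in the toy duplex
#' @param n_aa number of amino acid residues in the toy protein chain
#' @param n_snapshots ensemble size
#' @param jitter_sigma Gaussian coordinate jitter per snapshot (Angstrom)
#' @param ct_scale charge-transfer scale: fractional charges deviate
#'   from formal by about this fraction
#' @param alpha slope of generated QM electrostatics on MM
#'   electrostatics (0 < alpha <= 1.2)
#' @param beta screening fraction for charged pairs (0 <= beta <= 1):
#'   generated `solv = -beta * es + noise`
#' @param decouple_dispersion draw dispersion independently of the
#'   van der Waals term
#' @param es_noise,solv_noise,di_noise Gaussian noise scales (kcal/mol)
#'   for the generated components
#' @param seed RNG seed; identical seeds give bit-identical output
#' @return object of class `generator_config`
#' @export
generator_config <- function(n_nuc_pairs = 4, n_aa = 6, n_snapshots = 100,
                             jitter_sigma = 0.1, ct_scale = 0.05,
                             alpha = 0.95, beta = 0.95,
                             decouple_dispersion = TRUE,
                             es_noise = 0.3, solv_noise = 0.3,
                             di_noise = 0.1, seed = 1L) {
  if (jitter_sigma < 0) stop("jitter_sigma must be >= 0")
  if (alpha <= 0 || alpha > 1.2) stop("alpha must be in (0, 1.2]")
  if (beta < 0 || beta > 1) stop("beta must be in [0, 1]")
  if (n_nuc_pairs < 1 || n_aa < 0 || n_snapshots < 1)
    stop("invalid generator sizes")
  structure(as.list(environment()), class = "generator_config")
}

# base templates: atom name, offset inward from the pairing edge (dx),
# lateral offset (dy), partial charge.  Edge atoms (dx = 0) sit at
# dy = -1.8/0/+1.8 so that paired edges meet at 2.95 A contacts with
# complementary charge signs (hydrogen-bond-like dipolar attraction).
# Charges sum to -0.2 per base; the backbone sums to -0.8.
toy_base_templates <- function() {
  list(
    A = data.frame(
      name = c("N6", "N1", "C2", "C6", "N3", "C5", "C4", "N7", "C8", "N9"),
      dx = c(0, 0, 0, 1.2, 1.2, 2.4, 2.4, 3.4, 4.2, 3.8),
      dy = c(-1.8, 0, 1.8, -0.9, 0.9, -0.9, 0.9, -1.6, -0.6, 0.8),
      charge = c(0.35, -0.45, 0.10, 0.20, -0.20, 0, 0.10, -0.30, 0.10, -0.10)),
    T = data.frame(
      name = c("O4", "N3", "O2", "C4", "C2", "C5", "N1", "C7", "C6"),
      dx = c(0, 0, 0, 1.2, 1.2, 2.4, 2.4, 3.2, 3.4),
      dy = c(-1.8, 0, 1.8, -0.9, 0.9, -0.9, 0.9, -1.8, 0),
      charge = c(-0.45, 0.35, -0.40, 0.25, 0.30, 0, -0.10, -0.25, 0.10)),
    G = data.frame(
      name = c("O6", "N1", "N2", "C6", "C2", "C5", "N3", "N7", "C8", "C4", "N9"),
      dx = c(0, 0, 0, 1.2, 1.2, 2.4, 2.4, 3.4, 4.2, 3.2, 3.8),
      dy = c(-1.8, 0, 1.8, -0.9, 0.9, -0.9, 0.9, -1.6, -0.6, 0.3, 1.2),
      charge = c(-0.45, 0.35, 0.30, 0.25, 0.20, 0, -0.35, -0.35, 0.15, 0.10, -0.40)),
    C = data.frame(
      name = c("N4", "N3", "O2", "C4", "C2", "C5", "N1", "C6"),
      dx = c(0, 0, 0, 1.2, 1.2, 2.4, 2.4, 3.4),
      dy = c(-1.8, 0, 1.8, -0.9, 0.9, -0.9, 0.9, 0),
      charge = c(0.35, -0.45, -0.40, 0.20, 0.35, 0, -0.10, -0.15))
  )
}

toy_backbone_template <- function() {
  data.frame(
    name = c("C1'", "C2'", "O4'", "C3'", "C4'", "O3'", "C5'", "O5'", "P", "OP1", "OP2"),
    dx = c(5.2, 5.8, 6.3, 6.6, 7.0, 7.2, 7.8, 8.6, 9.6, 10.4, 10.4),
    dy = c(0.6, -0.5, 1.2, -1.0, 0.3, -2.0, 0.0, 0.5, 0.0, 1.0, -1.0),
    charge = c(0.40, 0.10, -0.30, 0.10, 0.10, -0.40, 0.10, -0.40, 1.10, -0.80, -0.80)
  )
}

# amino acid templates: backbone (neutral) + side chain; dx is measured
# from the residue anchor toward +x (away from the DNA; negative dx
# points the side chain at the duplex).
toy_aa_templates <- function() {
  bb <- data.frame(
    name = c("N", "H", "CA", "HA", "C", "O"),
    dx = c(0, 0, 1.0, 1.2, 2.0, 2.2),
    dy = c(0, 0.9, -0.5, -1.4, 0.3, 1.4),
    charge = c(-0.40, 0.25, 0.10, 0.05, 0.55, -0.55))
  side <- list(
    LYS = data.frame(name = c("CB", "CG", "CD", "NZ"),
                     dx = c(-1.0, -2.0, -3.0, -4.0),
                     dy = c(0.3, -0.3, 0.3, -0.3),
                     charge = c(0, 0, 0.2, 0.8)),
    ASP = data.frame(name = c("CB", "CG", "OD1", "OD2"),
                     dx = c(-1.0, -2.0, -2.8, -2.8),
                     dy = c(0.3, -0.3, 0.6, -1.2),
                     charge = c(0, 0.4, -0.7, -0.7)),
    GLY = data.frame(name = character(), dx = numeric(), dy = numeric(),
                     charge = numeric()),
    SER = data.frame(name = c("CB", "OG"),
                     dx = c(-1.0, -2.0), dy = c(0.3, -0.3),
                     charge = c(0.2, -0.2)),
    ALA = data.frame(name = "CB", dx = -1.0, dy = 0.3, charge = 0),
    ARG = data.frame(name = c("CB", "CG", "CD", "NE", "CZ", "NH1", "NH2"),
                     dx = c(-1.0, -2.0, -3.0, -3.8, -4.6, -5.4, -4.8),
                     dy = c(0.3, -0.3, 0.3, -0.3, 0.4, -0.2, 1.3),
                     charge = c(0, 0, 0.2, -0.4, 0.6, 0.5, 0.1)),
    PHE = data.frame(name = c("CB", "CG", "CD1", "CD2"),
                     dx = c(-1.0, -2.0, -3.0, -2.4),
                     dy = c(0.3, -0.3, 0.3, -1.4),
                     charge = c(0, 0.1, -0.05, -0.05))
  )
  list(bb = bb, side = side)
}

toy_lj <- function(element) {
  rmin <- c(H = 0.6, C = 1.90, N = 1.82, O = 1.66, P = 2.10)
  eps <- c(H = 0.015, C = 0.086, N = 0.17, O = 0.21, P = 0.20)
  list(rmin_half = unname(rmin[element]), epsilon = unname(eps[element]))
}

#' Generate a toy duplex-plus-protein complex
#'
#' Builds a schematic (non-helical) DNA-like duplex of alternating G:C
#' and A:T pairs flanked by a short protein chain, with a seeded
#' Gaussian-jitter snapshot ensemble.  The geometry is deliberately
#' schematic: what matters downstream is that atom names follow PDB
#' conventions, every nucleotide's charges sum to exactly -1 (backbone
#' -0.8, base -0.2), paired base edges meet at hydrogen-bond-like
#' 2.95 Angstrom heavy-atom contacts with complementary partial
#' charges, phosphates face away from the pairing interface, and a
#' cationic (Lys) and an anionic (Asp) side chain sit near the duplex.
#'
#' @param config a [generator_config()]
#' @return list with `system` (a [molecular_system()]), `rules`
#'   (a [nonbonded_rules()] carrying the toy exclusions/1-4 pairs),
#'   `segments`, `fragments` (unit schemes) and `labeling`
#' @export
generate_toy_complex <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  bases <- toy_base_templates()
  bb <- toy_backbone_template()
  aa <- toy_aa_templates()
  rise <- 3.6
  edge <- 1.475  # paired edge atoms meet at 2 * edge = 2.95 A
  rows <- list()
  add_atoms <- function(df) rows[[length(rows) + 1L]] <<- df

  pair_seq <- rep(c("GC", "AT"), length.out = config$n_nuc_pairs)
  for (i in seq_len(config$n_nuc_pairs)) {
    b1 <- substr(pair_seq[i], 1, 1)
    b2 <- substr(pair_seq[i], 2, 2)
    z <- rise * i
    for (strand in 1:2) {
      b <- if (strand == 1) b1 else b2
      sgn <- if (strand == 1) -1 else 1
      tmpl <- rbind(bases[[b]], bb)
      add_atoms(data.frame(
        name = tmpl$name, element = substr(gsub("[0-9']", "", tmpl$name), 1, 1),
        chain = c("A", "B")[strand], resname = paste0("D", b),
        resid = as.character(i),
        charge = tmpl$charge,
        x = sgn * (edge + tmpl$dx), y = tmpl$dy, z = z,
        stringsAsFactors = FALSE))
    }
  }
  # DNA-binding interfaces are Arg/Lys-rich; two cations give the toy the
  # paper-like population of long-range ionic contacts with the duplex
  aa_names <- rep(c("LYS", "ASP", "GLY", "ARG", "ALA", "PHE"),
                  length.out = config$n_aa)
  aa_x0 <- edge + max(bb$dx) + 7.0  # anchor outside strand B's phosphates
  for (j in seq_len(config$n_aa)) {
    rn <- aa_names[j]
    tmpl <- rbind(aa$bb, aa$side[[rn]])
    z <- rise * ((j - 1) %% config$n_nuc_pairs + 1) + 1.8
    add_atoms(data.frame(
      name = tmpl$name, element = substr(gsub("[0-9]", "", tmpl$name), 1, 1),
      chain = "P", resname = rn, resid = as.character(j),
      charge = tmpl$charge,
      x = aa_x0 + tmpl$dx + 8.0 * ((j - 1) %/% config$n_nuc_pairs),
      y = tmpl$dy + 1.2 * ((j - 1) %/% config$n_nuc_pairs), z = z,
      stringsAsFactors = FALSE))
  }
  at <- do.call(rbind, rows)
  at$atom_id <- seq_len(nrow(at))
  lj <- toy_lj(at$element)
  at$rmin_half <- lj$rmin_half
  at$epsilon <- lj$epsilon

  ideal <- as.matrix(at[, c("x", "y", "z")])
  nf <- config$n_snapshots
  coords <- array(rep(ideal, nf), c(nrow(at), 3, nf))
  if (config$jitter_sigma > 0)
    coords <- coords + array(rnorm(length(coords), 0, config$jitter_sigma),
                             dim(coords))
  times <- 300 * (seq_len(nf) - 1)

  sys <- molecular_system(
    at[, c("atom_id", "name", "element", "chain", "resname", "resid",
           "charge", "rmin_half", "epsilon")],
    coords, times = times)
  rules <- toy_rules(sys)
  segments <- assign_segments(sys)
  fragments <- shift_to_fragments(segments, sys)
  labeling <- label_subunits(sys, segments)
  list(system = sys, rules = rules, segments = segments,
       fragments = fragments, labeling = labeling, config = config)
}

# inter-residue exclusions / 1-4 pairs across the covalent links of the
# toy chains (O3'-P in DNA, C-N in protein)
toy_rules <- function(sys) {
  at <- sys$atoms
  find_atom <- function(chain, resid, name) {
    hit <- which(at$chain == chain & at$resid == as.character(resid) & at$name == name)
    if (length(hit) == 1) hit else NA_integer_
  }
  excl <- list(); s14 <- list()
  link <- function(pairs, kind) {
    pairs <- pairs[!is.na(pairs[, 1]) & !is.na(pairs[, 2]), , drop = FALSE]
    if (kind == "excl") excl[[length(excl) + 1L]] <<- pairs
    else s14[[length(s14) + 1L]] <<- pairs
  }
  for (chain in c("A", "B")) {
    ids <- unique(at$resid[at$chain == chain])
    for (k in seq_along(ids)[-1]) {
      i <- ids[k - 1]; j <- ids[k]
      link(cbind(find_atom(chain, i, "O3'"),
                 c(find_atom(chain, j, "P"), find_atom(chain, j, "OP1"),
                   find_atom(chain, j, "OP2"), find_atom(chain, j, "O5'"))), "excl")
      link(cbind(find_atom(chain, i, "C3'"), find_atom(chain, j, "P")), "excl")
      link(cbind(find_atom(chain, i, "C3'"),
                 c(find_atom(chain, j, "OP1"), find_atom(chain, j, "OP2"),
                   find_atom(chain, j, "O5'"))), "s14")
      link(cbind(find_atom(chain, i, "O3'"), find_atom(chain, j, "C5'")), "s14")
      link(cbind(c(find_atom(chain, i, "C4'"), find_atom(chain, i, "C2'")),
                 find_atom(chain, j, "P")), "s14")
    }
  }
  ids <- unique(at$resid[at$chain == "P"])
  for (k in seq_along(ids)[-1]) {
    i <- ids[k - 1]; j <- ids[k]
    link(cbind(find_atom("P", i, "C"),
               c(find_atom("P", j, "N"), find_atom("P", j, "CA"),
                 find_atom("P", j, "H"))), "excl")
    link(cbind(c(find_atom("P", i, "O"), find_atom("P", i, "CA")),
               find_atom("P", j, "N")), "excl")
    link(cbind(find_atom("P", i, "O"),
               c(find_atom("P", j, "CA"), find_atom("P", j, "H"))), "s14")
    link(cbind(find_atom("P", i, "CA"),
               c(find_atom("P", j, "CA"), find_atom("P", j, "H"))), "s14")
    link(cbind(find_atom("P", i, "C"),
               c(find_atom("P", j, "HA"), find_atom("P", j, "C"),
                 find_atom("P", j, "CB"))), "s14")
  }
  to_m <- function(l) if (length(l)) do.call(rbind, l) else matrix(integer(), ncol = 2)
  nonbonded_rules(excluded = to_m(excl), scaled14 = to_m(s14))
}

#' Generate synthetic QM component tables from an MM pair table
#'
#' Produces partition-analysis (`PA`) and `FMO` pair-component rows and
#' a fractional unit-charge table with the controlled statistical
#' structure of the generator configuration: QM electrostatics
#' `es = alpha * elec + noise`; dispersion drawn independently of the
#' van der Waals term (one stable value per pair plus snapshot noise)
#' when `decouple_dispersion` is set; solvent screening
#' `solv = -beta * es + noise` for pairs involving a formally charged
#' unit and small otherwise; `FMO` rows add a large negative 0-body
#' term for covalently bonded pairs (the fragment-boundary artifact)
#' and small `e0`/`ctes` elsewhere; unit charges deviate from their
#' formal integers by about `ct_scale`.  Ground-truth parameters are
#' returned alongside the tables.
#'
#' @param mm_table per-snapshot MM pair table from [unit_pair_table()]
#' @param scheme the [unit_scheme()] the table was computed under
#'   (categories and formal charges)
#' @param config a [generator_config()]
#' @return list with data frames `pa`, `fmo`, `charges` and the
#'   ground-truth parameter list `truth`
#' @export
generate_qm_tables <- function(mm_table, scheme, config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed + 1L)
  units <- scheme$units
  fc <- setNames(units$formal_charge, units$unit_id)
  key <- paste(pmin(mm_table$unit_i, mm_table$unit_j),
               pmax(mm_table$unit_i, mm_table$unit_j), sep = "|")
  upairs <- unique(key)
  # stable per-pair dispersion baseline: a contact property (dispersion
  # decays as r^-6, so non-contact pairs get none), but with magnitudes
  # drawn independently of the vdW values among contacting pairs
  pair_vdw <- tapply(abs(mm_table$vdw), key, mean)
  contact <- setNames(as.numeric(pair_vdw[upairs] > 0.3), upairs)
  di_base <- if (config$decouple_dispersion)
    setNames(contact * rnorm(length(upairs), -2.5, 1), upairs)
  n <- nrow(mm_table)
  charged <- fc[as.character(mm_table$unit_i)] != 0 |
    fc[as.character(mm_table$unit_j)] != 0
  es <- config$alpha * mm_table$elec + rnorm(n, 0, config$es_noise)
  di <- if (config$decouple_dispersion)
    di_base[key] + rnorm(n, 0, config$di_noise)
  else 1.05 * mm_table$vdw + rnorm(n, 0, config$di_noise)
  solv <- ifelse(charged,
                 -config$beta * es + rnorm(n, 0, config$solv_noise),
                 rnorm(n, 0, 0.1))
  pa <- data.frame(
    unit_i = mm_table$unit_i, unit_j = mm_table$unit_j,
    snapshot = mm_table$snapshot, level = "PA", scheme = mm_table$scheme,
    es = es, di = unname(di), solv = solv,
    is_covalent = mm_table$is_covalent, stringsAsFactors = FALSE)
  fmo <- data.frame(
    unit_i = mm_table$unit_i, unit_j = mm_table$unit_j,
    snapshot = mm_table$snapshot, level = "FMO", scheme = mm_table$scheme,
    es = es + rnorm(n, 0, 0.2),
    e0 = ifelse(mm_table$is_covalent, -300 + rnorm(n, 0, 5), rnorm(n, 0, 0.3)),
    ctes = rnorm(n, 0, 0.1),
    di = unname(di) + rnorm(n, 0, 0.05),
    solv = solv + rnorm(n, 0, 0.2),
    is_covalent = mm_table$is_covalent, stringsAsFactors = FALSE)

  snaps <- sort(unique(mm_table$snapshot))
  # unit-level charge-transfer offset, stable across snapshots
  ct_u <- setNames(config$ct_scale * stats::runif(nrow(units), 0.5, 1.5),
                   units$unit_id)
  ch <- do.call(rbind, lapply(snaps, function(s) {
    total <- ifelse(units$formal_charge != 0,
                    units$formal_charge * (1 - ct_u[as.character(units$unit_id)]),
                    rnorm(nrow(units), 0, 0.01)) + rnorm(nrow(units), 0, 0.02)
    functional <- ifelse(units$category == "nuc",
                         -0.2 + rnorm(nrow(units), 0, 0.02),
                         ifelse(units$formal_charge != 0,
                                units$formal_charge * 0.97 + rnorm(nrow(units), 0, 0.02),
                                rnorm(nrow(units), 0, 0.02)))
    functional[units$resname == "GLY"] <- NA_real_
    data.frame(unit_id = units$unit_id, label = units$label,
               residue_type = ifelse(units$category == "nuc",
                                     sub("^D", "", units$resname), units$resname),
               snapshot = s, formal_charge = units$formal_charge,
               total_charge = total, functional_charge = functional,
               stringsAsFactors = FALSE)
  }))
  list(pa = pa, fmo = fmo, charges = ch,
       truth = list(alpha = config$alpha, beta = config$beta,
                    ct_scale = config$ct_scale,
                    decouple_dispersion = config$decouple_dispersion))
}
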