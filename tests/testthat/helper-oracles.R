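# Independent brute-force oracle for pairwise nonbonded energies:
# a scalar double loop over atom pairs applying the Coulomb and
# Lennard-Jones formulas directly.  Deliberately shares no code with
# the package's block-sum implementation.
oracle_pair_energy <- function(system, atoms_i, atoms_j, rules, coords) {
  q <- system$atoms$charge
  rh <- system$atoms$rmin_half
  ep <- system$atoms$epsilon
  ti <- if (!is.null(system$lj_pairs)) system$lj_pairs$type_index
  pk <- function(a, b) paste(min(a, b), max(a, b))
  ek <- if (nrow(rules$excluded)) apply(rules$excluded, 1, function(r) pk(r[1], r[2])) else character()
  sk <- if (nrow(rules$scaled14)) apply(rules$scaled14, 1, function(r) pk(r[1], r[2])) else character()
  elec <- 0; vdw <- 0
  for (a in atoms_i) for (b in atoms_j) {
    if (a == b) next
    key <- pk(a, b)
    if (key %in% ek) next
    we <- 1; wv <- 1
    if (key %in% sk) { we <- 1 / rules$scee; wv <- 1 / rules$scnb }
    r <- sqrt(sum((coords[a, ] - coords[b, ])^2))
    elec <- elec + we * rules$coulomb_constant * q[a] * q[b] / (rules$dielectric * r)
    if (is.null(ti)) {
      rmin <- rh[a] + rh[b]
      eps <- sqrt(ep[a] * ep[b])
      A <- eps * rmin^12
      B <- 2 * eps * rmin^6
    } else {
      A <- system$lj_pairs$acoef[ti[a], ti[b]]
      B <- system$lj_pairs$bcoef[ti[a], ti[b]]
    }
    vdw <- vdw + wv * (A / r^12 - B / r^6)
  }
  list(elec = elec, vdw = vdw, total = elec + vdw)
}

# random small multi-unit system with optional random exclusions and
# 1-4 pairs; atoms placed on a jittered grid so no two coincide
random_system <- function(n_atoms = 40, n_units = 4, seed = 1,
                          with_rules = TRUE, n_frames = 1) {
  set.seed(seed)
  side <- ceiling(n_atoms^(1 / 3)) + 1
  grid <- expand.grid(x = seq_len(side), y = seq_len(side), z = seq_len(side)) * 3
  grid <- as.matrix(grid[sample(nrow(grid), n_atoms), ])
  unit <- sort(rep_len(seq_len(n_units), n_atoms))
  atoms <- data.frame(
    atom_id = seq_len(n_atoms),
    name = paste0("X", seq_len(n_atoms)),
    element = sample(c("C", "N", "O", "H"), n_atoms, replace = TRUE),
    chain = "A", resname = "ALA", resid = as.character(unit),
    charge = round(runif(n_atoms, -0.8, 0.8), 3),
    rmin_half = runif(n_atoms, 0.6, 2.1),
    epsilon = runif(n_atoms, 0.01, 0.25),
    stringsAsFactors = FALSE
  )
  coords <- array(rep(grid, n_frames), c(n_atoms, 3, n_frames)) +
    array(rnorm(n_atoms * 3 * n_frames, 0, 0.2), c(n_atoms, 3, n_frames))
  sys <- molecular_system(atoms, coords)
  rules <- nonbonded_rules()
  if (with_rules) {
    inter <- which(outer(unit, unit, "!=") & upper.tri(diag(n_atoms)), arr.ind = TRUE)
    picked <- inter[sample(nrow(inter), min(8, nrow(inter))), , drop = FALSE]
    half <- seq_len(nrow(picked) %/% 2)
    rules <- nonbonded_rules(excluded = picked[half, , drop = FALSE],
                             scaled14 = picked[-half, , drop = FALSE])
  }
  list(system = sys, rules = rules, unit = unit,
       scheme = assign_segments(sys))
}

# small peptide-like system built by hand: n_res alanine-style residues
tiny_protein <- function(n_res = 4, resnames = rep("ALA", n_res)) {
  rows <- lapply(seq_len(n_res), function(i) {
    data.frame(
      name = c("N", "CA", "C", "O", if (resnames[i] != "GLY") "CB"),
      element = c("N", "C", "C", "O", if (resnames[i] != "GLY") "C"),
      chain = "A", resname = resnames[i], resid = as.character(i),
      charge = 0, rmin_half = 1.7, epsilon = 0.1,
      stringsAsFactors = FALSE)
  })
  at <- do.call(rbind, rows)
  at$atom_id <- seq_len(nrow(at))
  at$charge <- round(seq(-0.4, 0.4, length.out = nrow(at)), 3)
  coords <- cbind(seq_len(nrow(at)) * 2.5, 0, 0)
  molecular_system(at, coords)
}
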