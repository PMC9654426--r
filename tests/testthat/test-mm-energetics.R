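two_atom_system <- function(q1, q2, r, rmin_half = 1.5, epsilon = 0.1) {
  atoms <- data.frame(
    atom_id = 1:2, name = c("X1", "X2"), element = "C", chain = "A",
    resname = c("ALA", "GLY"), resid = c("1", "2"),
    charge = c(q1, q2), rmin_half = rmin_half, epsilon = epsilon,
    stringsAsFactors = FALSE)
  molecular_system(atoms, cbind(c(0, r), 0, 0))
}

test_that("electrostatics follows Coulomb's law with the configured constant", {
  rules <- nonbonded_rules()
  # all charges zero
  s0 <- two_atom_system(0, 0, 3)
  expect_equal(elec_energy(s0, 1, 2, rules), 0)
  # R chosen so k/R = 100 -> opposite unit charges give exactly -100
  r <- rules$coulomb_constant / 100
  s1 <- two_atom_system(1, -1, r)
  expect_equal(elec_energy(s1, 1, 2, rules), -100, tolerance = 1e-12)
  # exact 1/dielectric linearity
  rules2 <- nonbonded_rules(dielectric = 2)
  expect_equal(elec_energy(s1, 1, 2, rules2), -50, tolerance = 1e-12)
  rules5 <- nonbonded_rules(dielectric = 5)
  expect_equal(elec_energy(s1, 1, 2, rules5) * 5,
               elec_energy(s1, 1, 2, rules), tolerance = 1e-12)
})

test_that("Lennard-Jones energy has its zero crossing and matches the closed form", {
  rules <- nonbonded_rules()
  s0 <- two_atom_system(0, 0, 3, epsilon = 0)  # C12 = C6 = 0
  expect_equal(vdw_energy(s0, 1, 2, rules), 0)
  # zero crossing where C12/R^12 = C6/R^6, i.e. R = Rmin / 2^(1/6)
  rmin <- 2 * 1.5
  s1 <- two_atom_system(0, 0, rmin / 2^(1 / 6))
  expect_equal(vdw_energy(s1, 1, 2, rules), 0, tolerance = 1e-12)
  # direct scalar evaluation at an arbitrary distance
  r <- 3.3
  s2 <- two_atom_system(0.2, -0.1, r, rmin_half = 1.6, epsilon = 0.12)
  A <- 0.12 * (3.2)^12
  B <- 2 * 0.12 * (3.2)^6
  expect_equal(vdw_energy(s2, 1, 2, rules), A / r^12 - B / r^6,
               tolerance = 1e-12)
  # vdW is invariant under the dielectric constant
  expect_equal(vdw_energy(s2, 1, 2, nonbonded_rules(dielectric = 7)),
               vdw_energy(s2, 1, 2, rules), tolerance = 1e-15)
})

test_that("coincident atoms are rejected", {
  s <- two_atom_system(1, 1, 0)
  expect_error(elec_energy(s, 1, 2, nonbonded_rules()), "[Cc]oincident")
})

test_that("unit pair table equals the atom-set energies and flags covalent pairs", {
  rs <- random_system(24, 2, seed = 11)
  tab <- unit_pair_table(rs$system, rs$scheme, rs$rules)
  ai <- which(rs$unit == 1); aj <- which(rs$unit == 2)
  expect_equal(tab$elec, elec_energy(rs$system, ai, aj, rs$rules), tolerance = 1e-12)
  expect_equal(tab$vdw, vdw_energy(rs$system, ai, aj, rs$rules), tolerance = 1e-12)
  expect_equal(tab$total, tab$elec + tab$vdw)
  expect_true(tab$is_covalent)  # residues 1 and 2 are sequence-adjacent
})

test_that("disabling exclusions changes the electrostatics of a linked pair", {
  rs <- random_system(24, 2, seed = 12)
  with_rules <- unit_pair_table(rs$system, rs$scheme, rs$rules)
  no_rules <- unit_pair_table(rs$system, rs$scheme, nonbonded_rules())
  expect_false(isTRUE(all.equal(with_rules$elec, no_rules$elec)))
})

test_that("block sums match the brute-force double loop on random systems", {
  for (seed in 1:10) {
    rs <- random_system(n_atoms = sample(15:40, 1), n_units = sample(2:4, 1),
                        seed = seed)
    tab <- unit_pair_table(rs$system, rs$scheme, rs$rules)
    coords <- snapshot_coords(rs$system, 1)
    for (p in seq_len(nrow(tab))) {
      ora <- oracle_pair_energy(rs$system,
                                which(rs$unit == tab$unit_i[p]),
                                which(rs$unit == tab$unit_j[p]),
                                rs$rules, coords)
      expect_equal(tab$elec[p], ora$elec, tolerance = 1e-10)
      expect_equal(tab$vdw[p], ora$vdw, tolerance = 1e-10)
    }
  }
})

test_that("tabulated per-pair LJ coefficients take precedence over combining", {
  rs <- random_system(12, 2, seed = 21, with_rules = FALSE)
  ti <- rep(1:2, length.out = 12)
  rs$system$lj_pairs <- list(type_index = ti,
                             acoef = matrix(c(1e5, 2e5, 2e5, 3e5), 2),
                             bcoef = matrix(c(50, 80, 80, 120), 2))
  tab <- unit_pair_table(rs$system, rs$scheme, nonbonded_rules())
  ora <- oracle_pair_energy(rs$system, which(rs$unit == 1), which(rs$unit == 2),
                            nonbonded_rules(), snapshot_coords(rs$system, 1))
  expect_equal(tab$vdw, ora$vdw, tolerance = 1e-10)
})

test_that("subunit decomposition partitions the pair energy exactly", {
  toy <- generate_toy_complex(generator_config(n_snapshots = 1, seed = 6))
  seg <- toy$segments
  lab <- toy$labeling
  # a nucleotide pair: all four blocks defined, sum equals total
  u <- seg$units$unit_id[seg$units$chain == "A"][1]
  v <- seg$units$unit_id[seg$units$chain == "B"][1]
  apm <- atom_pair_matrix(toy$system, seg, c(u, v), toy$rules)
  d <- subunit_decompose(apm, lab)
  expect_equal(unname(sum(d)), sum(apm$total), tolerance = 1e-10)
  # brute-force re-summation by label agrees block by block
  li <- unclass(lab)[apm$atoms_i]; lj <- unclass(lab)[apm$atoms_j]
  expect_equal(unname(d["bf"]), sum(apm$total[li == "b", lj == "f"]),
               tolerance = 1e-12)
  expect_equal(unname(d["fb"]), sum(apm$total[li == "f", lj == "b"]),
               tolerance = 1e-12)
})

test_that("all-backbone labelings put the whole energy in bb", {
  rs <- random_system(16, 2, seed = 31)
  lab <- structure(rep("b", 16), class = "subunit_labeling")
  apm <- atom_pair_matrix(rs$system, rs$scheme, c(1, 2), rs$rules)
  d <- subunit_decompose(apm, lab)
  expect_equal(unname(d["bb"]), sum(apm$total), tolerance = 1e-12)
  expect_true(is.na(d["bf"]) && is.na(d["fb"]) && is.na(d["ff"]))
})

test_that("glycine pairs report absent (NA) functional blocks, not zeros", {
  toy <- generate_toy_complex(generator_config(n_snapshots = 1, seed = 6))
  seg <- toy$segments
  gly <- seg$units$unit_id[seg$units$resname == "GLY"][1]
  other <- seg$units$unit_id[seg$units$resname == "PHE"][1]
  apm <- atom_pair_matrix(toy$system, seg, c(gly, other), toy$rules)
  d <- subunit_decompose(apm, toy$labeling)
  expect_false(is.na(d["bb"]))
  expect_false(is.na(d["bf"]))  # glycine backbone vs PHE side chain
  expect_true(is.na(d["fb"]))
  expect_true(is.na(d["ff"]))
})

test_that("group decomposition re-sums to the ff total exactly", {
  toy <- generate_toy_complex(generator_config(n_snapshots = 1, seed = 8))
  seg <- toy$segments
  # first G:C pair across the strands
  g <- seg$units$unit_id[seg$units$chain == "A" & seg$units$resname == "DG"][1]
  c_ <- seg$units$unit_id[seg$units$chain == "B" & seg$units$resname == "DC"][1]
  apm <- atom_pair_matrix(toy$system, seg, c(g, c_), toy$rules)
  # pair type order must match the unit order (G first)
  gs <- group_scheme(c("G", "C"),
                     groups = list(HB1 = list(G = "N1", C = "N3"),
                                   HB2 = list(G = "O6", C = "N4"),
                                   HB3 = list(G = "N2", C = "O2")),
                     probes = data.frame(bond = c("HB1", "HB2", "HB3"),
                                         atom_a = c("N1", "O6", "O2"),
                                         atom_b = c("N3", "N4", "N2")))
  d <- group_decompose(apm, gs, toy$labeling)
  expect_equal(unname(sum(d[c("HB1", "HB2", "HB3", "rest")])),
               unname(d["ff_total"]), tolerance = 1e-10)
  # brute-force selective sum for one group
  sel_i <- match("N1", apm$names_i); sel_j <- match("N3", apm$names_j)
  expect_equal(unname(d["HB1"]), apm$total[sel_i, sel_j], tolerance = 1e-12)
  # empty scheme: everything is rest
  empty <- group_scheme(c("G", "C"), groups = list(),
                        probes = data.frame(bond = character(),
                                            atom_a = character(),
                                            atom_b = character()))
  d0 <- group_decompose(apm, empty, toy$labeling)
  expect_equal(unname(d0["rest"]), unname(d0["ff_total"]), tolerance = 1e-12)
  # unknown atoms are reported with the group name
  bad <- group_scheme(c("G", "C"),
                      groups = list(HBX = list(G = "N1", C = "QZ")),
                      probes = data.frame(bond = "HBX", atom_a = "N1",
                                          atom_b = "QZ"))
  expect_error(group_decompose(apm, bad, toy$labeling), "HBX.*QZ")
})

test_that("excluded and scaled pair sets must be disjoint", {
  expect_error(nonbonded_rules(excluded = rbind(c(1L, 2L)),
                               scaled14 = rbind(c(2L, 1L))),
               "disjoint")
  expect_error(nonbonded_rules(dielectric = 0), "positive")
})
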