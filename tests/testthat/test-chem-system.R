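test_that("segment assignment gives one unit per residue with categories and charges", {
  toy <- generate_toy_complex(generator_config(n_snapshots = 2, seed = 3))
  seg <- toy$segments
  expect_equal(nrow(seg$units), 2 * 4 + 6)
  expect_true(all(seg$units$formal_charge[seg$units$category == "nuc"] == -1L))
  expect_setequal(unique(seg$units$category), c("nuc", "aa"))
  # covalent pairs: per chain of length n there are n - 1 adjacent pairs
  expect_equal(nrow(seg$covalent_pairs), (4 - 1) * 2 + (6 - 1))
  validate_scheme(seg, toy$system)
})

test_that("a single-residue structure has no covalent pairs", {
  sys <- tiny_protein(1)
  seg <- assign_segments(sys)
  expect_equal(nrow(seg$units), 1)
  expect_equal(nrow(seg$covalent_pairs), 0)
})

test_that("a four-residue chain has three covalent pairs", {
  seg <- assign_segments(tiny_protein(4))
  expect_equal(nrow(seg$covalent_pairs), 3)
})

test_that("unknown residues and duplicate residue keys are rejected", {
  sys <- tiny_protein(2)
  sys$atoms$resname[1:5] <- "XXX"
  expect_error(assign_segments(sys), "XXX")
  sys2 <- tiny_protein(3)
  sys2$atoms$resid <- c(rep("1", 5), rep("2", 5), rep("1", 5))
  expect_error(assign_segments(sys2), "duplicate residue key")
})

test_that("fragment shifting moves phosphates back and carbonyls forward", {
  toy <- generate_toy_complex(generator_config(n_snapshots = 1, seed = 3))
  sys <- toy$system
  seg <- toy$segments
  frag <- toy$fragments
  at <- sys$atoms
  lookup_unit <- function(scheme, chain, resid, name) {
    idx <- which(at$chain == chain & at$resid == resid & at$name == name)
    scheme$unit_of[idx]
  }
  # phosphate of nucleotide 2 belongs to fragment of nucleotide 1
  u1 <- seg$units$unit_id[seg$units$chain == "A" & seg$units$resid == "1"]
  expect_equal(lookup_unit(frag, "A", "2", "P"), u1)
  expect_equal(lookup_unit(frag, "A", "2", "OP1"), u1)
  # carbonyl of amino acid 1 belongs to fragment of amino acid 2
  u_aa2 <- seg$units$unit_id[seg$units$chain == "P" & seg$units$resid == "2"]
  expect_equal(lookup_unit(frag, "P", "1", "C"), u_aa2)
  expect_equal(lookup_unit(frag, "P", "1", "O"), u_aa2)
  # terminal units are not shifted: 5'-nucleotide keeps its phosphate,
  # C-terminal amino acid keeps its carbonyl
  expect_equal(lookup_unit(frag, "A", "1", "P"),
               lookup_unit(seg, "A", "1", "P"))
  n_aa <- max(as.integer(at$resid[at$chain == "P"]))
  expect_equal(lookup_unit(frag, "P", as.character(n_aa), "C"),
               lookup_unit(seg, "P", as.character(n_aa), "C"))
})

test_that("shifting conserves atom assignment totals and is invertible", {
  toy <- generate_toy_complex(generator_config(n_snapshots = 1, seed = 5))
  seg <- toy$segments
  frag <- toy$fragments
  sys <- toy$system
  expect_equal(length(frag$unit_of), length(seg$unit_of))
  validate_scheme(frag, sys)
  # per-unit charge totals change, but the grand total is conserved exactly
  expect_identical(sum(sys$atoms$charge), sum(sys$atoms$charge))
  tot_seg <- tapply(sys$atoms$charge, seg$unit_of, sum)
  tot_frag <- tapply(sys$atoms$charge, frag$unit_of, sum)
  expect_equal(sum(tot_seg), sum(tot_frag), tolerance = 1e-12)
  # round trip
  back <- shift_to_fragments(frag, sys, inverse = TRUE)
  expect_identical(back$unit_of, seg$unit_of)
  expect_identical(back$scheme_name, "segment")
})

test_that("missing backbone atoms in a non-terminal residue are reported", {
  toy <- generate_toy_complex(generator_config(n_snapshots = 1, seed = 5))
  sys <- toy$system
  drop <- which(sys$atoms$chain == "A" & sys$atoms$resid == "2" &
                  sys$atoms$name == "P")
  sys$atoms <- sys$atoms[-drop, ]
  sys$coords <- sys$coords[-drop, , , drop = FALSE]
  seg <- assign_segments(sys)
  expect_error(shift_to_fragments(seg, sys), "phosphate")
})

test_that("subunit labeling partitions every unit into backbone and functional", {
  toy <- generate_toy_complex(generator_config(n_snapshots = 1, seed = 2))
  lab <- toy$labeling
  at <- toy$system$atoms
  expect_true(all(unclass(lab) %in% c("b", "f")))
  # nucleotide rules
  expect_true(all(lab[at$name == "OP1"] == "b"))
  expect_true(all(lab[at$name == "N6"] == "f"))
  expect_true(all(lab[grepl("'", at$name)] == "b"))
  # glycine has no functional atoms
  gly <- at$resname == "GLY"
  expect_true(any(gly))
  expect_true(all(lab[gly] == "b"))
  # splitting segments only
  expect_error(label_subunits(toy$system, toy$fragments), "segment")
})

test_that("default group schemes carry the published probe atoms", {
  at <- default_group_scheme(c("A", "T"))
  expect_equal(at$probes$atom_a[at$probes$bond == "HB1"], "N6")
  expect_equal(at$probes$atom_b[at$probes$bond == "HB1"], "O4")
  cg <- default_group_scheme(c("C", "G"))
  expect_equal(sum(grepl("^HB", names(cg$groups))), 3)
  gt <- default_group_scheme(c("G", "T"))
  expect_true("CO..H" %in% names(gt$groups))
  expect_error(default_group_scheme(c("A", "C")), "unsupported")
  # group atom sets must be disjoint within a base
  expect_error(
    group_scheme(c("A", "T"),
                 groups = list(HB1 = list(A = "N6", T = "O4"),
                               HB2 = list(A = "N6", T = "N3")),
                 probes = data.frame(bond = "HB1", atom_a = "N6", atom_b = "O4")),
    "disjoint")
  # ES groups are user-overridable
  gt2 <- default_group_scheme(c("G", "T"),
                              es_groups = list(ES1 = list(G = "C8", T = "C6")))
  expect_equal(gt2$groups$ES1$G, "C8")
})

test_that("multi-model PDB files round-trip through bio3d with name canonicalisation", {
  pdb <- tempfile(fileext = ".pdb")
  fmt <- function(serial, name, res, chain, resno, x, y, z, el) {
    sprintf("ATOM  %5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            serial, name, res, chain, resno, x, y, z, el)
  }
  writeLines(c(
    "MODEL     1",
    fmt(1, " P  ", " DG", "A", 1, 0, 0, 0, " P"),
    fmt(2, " O1P", " DG", "A", 1, 1.3, 0, 0, " O"),
    fmt(3, " C1'", " DG", "A", 1, 2.5, 1, 0, " C"),
    "ENDMDL",
    "MODEL     2",
    fmt(1, " P  ", " DG", "A", 1, 0, 0, 0.5, " P"),
    fmt(2, " O1P", " DG", "A", 1, 1.3, 0, 0.5, " O"),
    fmt(3, " C1'", " DG", "A", 1, 2.5, 1, 0.5, " C"),
    "ENDMDL",
    "END"), pdb)
  sys <- read_pdb_system(pdb)
  expect_equal(n_frames(sys), 2)
  expect_equal(sys$atoms$name, c("P", "OP1", "C1'"))  # O1P canonicalised
  expect_equal(snapshot_coords(sys, 2)[1, 3], 0.5)
})

test_that("the JSON topology round-trips charges, LJ and rules", {
  toy <- generate_toy_complex(generator_config(n_snapshots = 1, seed = 4))
  f <- tempfile(fileext = ".json")
  write_topology_json(toy$system$atoms, toy$rules, f)
  top <- read_topology_json(f)
  expect_equal(top$atoms$charge, toy$system$atoms$charge)
  expect_equal(top$atoms$rmin_half, toy$system$atoms$rmin_half)
  expect_equal(nrow(top$rules$excluded), nrow(toy$rules$excluded))
  expect_equal(nrow(top$rules$scaled14), nrow(toy$rules$scaled14))
  expect_equal(top$rules$scee, toy$rules$scee)
})

test_that("scheme export writes one row per atom", {
  toy <- generate_toy_complex(generator_config(n_snapshots = 1, seed = 4))
  f <- tempfile(fileext = ".tsv")
  write_scheme_tsv(toy$system, toy$segments, toy$fragments, toy$labeling, file = f)
  df <- read.delim(f)
  expect_equal(nrow(df), nrow(toy$system$atoms))
  expect_true(all(c("unit_segment", "unit_fragment", "subunit") %in% names(df)))
})

test_that("the parm7 reader recovers charges, LJ tables, exclusions and 1-4 pairs", {
  f <- tempfile(fileext = ".parm7")
  writeLines(c(
    "%VERSION  VERSION_STAMP = V0001.000",
    "%FLAG POINTERS",
    "%FORMAT(10I8)",
    "       4       2       3       1       0       0       0       1       0       0",
    "       0       2       0       0       0       0       0       0       0       0",
    "%FLAG ATOM_NAME",
    "%FORMAT(20a4)",
    "N   CA  C   O1P ",
    "%FLAG CHARGE",
    "%FORMAT(5E16.8)",
    "  -7.28892000E+00   1.82223000E+00   9.11115000E+00  -3.64446000E+00",
    "%FLAG ATOMIC_NUMBER",
    "%FORMAT(10I8)",
    "       7       6       6       8",
    "%FLAG ATOM_TYPE_INDEX",
    "%FORMAT(10I8)",
    "       1       2       2       1",
    "%FLAG NONBONDED_PARM_INDEX",
    "%FORMAT(10I8)",
    "       1       2       2       3",
    "%FLAG RESIDUE_LABEL",
    "%FORMAT(20a4)",
    "ALA GLY ",
    "%FLAG RESIDUE_POINTER",
    "%FORMAT(10I8)",
    "       1       3",
    "%FLAG NUMBER_EXCLUDED_ATOMS",
    "%FORMAT(10I8)",
    "       3       2       1       1",
    "%FLAG EXCLUDED_ATOMS_LIST",
    "%FORMAT(10I8)",
    "       2       3       4       3       4       4       0",
    "%FLAG LENNARD_JONES_ACOEF",
    "%FORMAT(5E16.8)",
    "   1.00000000E+05   2.00000000E+05   4.00000000E+05",
    "%FLAG LENNARD_JONES_BCOEF",
    "%FORMAT(5E16.8)",
    "   1.00000000E+02   2.00000000E+02   4.00000000E+02",
    "%FLAG SCEE_SCALE_FACTOR",
    "%FORMAT(5E16.8)",
    "   1.20000000E+00",
    "%FLAG SCNB_SCALE_FACTOR",
    "%FORMAT(5E16.8)",
    "   2.00000000E+00",
    "%FLAG DIHEDRALS_WITHOUT_HYDROGEN",
    "%FORMAT(10I8)",
    "       0       3       6       9       1"
  ), f)
  top <- read_parm7(f)
  expect_equal(top$atoms$charge, c(-0.4, 0.1, 0.5, -0.2), tolerance = 1e-6)
  expect_equal(top$atoms$name, c("N", "CA", "C", "OP1"))  # O1P canonicalised
  expect_equal(top$atoms$element, c("N", "C", "C", "O"))
  expect_equal(top$atoms$resname, c("ALA", "ALA", "GLY", "GLY"))
  # 1-4 pair (1,4) separated from the plain exclusions
  expect_equal(top$rules$scaled14, matrix(c(1L, 4L), ncol = 2))
  exc <- apply(top$rules$excluded, 1, paste, collapse = "-")
  expect_setequal(exc, c("1-2", "1-3", "2-3", "2-4", "3-4"))
  expect_equal(top$rules$scee, 1.2)
  expect_equal(top$rules$scnb, 2.0)
  # tabulated LJ: type pair (1,1) -> coefficient 1, (1,2) -> 2, (2,2) -> 3
  expect_equal(top$lj_pairs$acoef[1, 1], 1e5)
  expect_equal(top$lj_pairs$acoef[1, 2], 2e5)
  expect_equal(top$lj_pairs$bcoef[2, 2], 4e2)
})
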