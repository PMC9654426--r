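---
title: "Pair interaction energies, decompositions, and interaction-network comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pair interaction energies, decompositions, and interaction-network comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pienet)
```

# The problem

How much does each residue of a protein, and each nucleotide of a DNA
duplex, contribute to the binding of a protein–DNA complex — and how
much of that contribution comes from the backbone rather than the side
chain or the base?  Force-field (molecular-mechanics, MM) pair
energies answer this cheaply but without solvent screening or charge
transfer; quantum-chemical fragment methods (FMO/DFTB with a continuum
solvent) deliver screened, polarized interaction energies but at much
higher cost and under a slightly different unit convention.  `pienet`
implements the bookkeeping that makes the two comparable on equal
footing over an ensemble of molecular-dynamics snapshots, and the
statistics used to compare the resulting residue interaction networks.

# Units of analysis

*Segments* are conventional residues: every atom belongs to the
residue its PDB record names.  *Fragments* are the computational units
of fragment-based QM: identical atom counts, but each amino acid's
carbonyl \{C, O\} is assigned to the next fragment and each
nucleotide's phosphate \{P, OP1, OP2\} to the previous one.
`assign_segments()` and `shift_to_fragments()` construct both; the
shift is exactly invertible and conserves atom count and total charge.
Two deliberate choices where conventions are unwritten: the shifted
atom sets are fixed to \{C, O\} and \{P, OP1, OP2\} (bridging O3'/O5'
oxygens stay with their sugars, preserving the equality of atomic
composition between residue and fragment), and chain-terminal residues
are never shifted because no adjacent unit exists to receive or donate
the group.

Within a segment, `label_subunits()` splits atoms into *backbone* (b)
— peptide main chain, or phosphate + pentose — and *functional* (f)
units — side chain or nucleobase.  Glycine's functional set is empty,
and every downstream decomposition reports its f-blocks as absent
(`NA`), never as zero.  `default_group_scheme()` further splits the
Watson–Crick edge of a base into named hydrogen bonds (HB1, HB2, HB3),
CO⋯H contacts and weak electrostatic (ES) contacts, each with a pair
of heavy probe atoms for bond-length statistics.  The hydrogen-bond
memberships and probes follow the standard pairing geometry for A:T,
C:G and the G:T wobble mismatch; the ES-group memberships are
provisional defaults and are user-overridable
(`es_groups =` argument), since no universal convention exists.
Probe names are resolved in whichever unit of the pair carries them,
because published probe tables do not order atoms consistently by
unit and both bases of a pair usually contain atoms named N1 or N3.

# Force-field pair energies

For units $i \ne j$ the MM interaction energy is
$\Delta E_{ij} = \Delta E^{elec}_{ij} + \Delta E^{vdW}_{ij}$ with

$$\Delta E^{elec}_{ij} = \sum_{A\in i}\sum_{B\in j} w_{AB}\,
\frac{k\,Q_A Q_B}{\varepsilon R_{AB}}, \qquad
\Delta E^{vdW}_{ij} = \sum_{A\in i}\sum_{B\in j} w_{AB}'
\left(\frac{C^{12}_{AB}}{R_{AB}^{12}} - \frac{C^{6}_{AB}}{R_{AB}^{6}}\right),$$

where $w_{AB}$ implements the force-field bookkeeping: 0 for excluded
(1–2/1–3) pairs, $1/1.2$ (electrostatics) and $1/2.0$ (van der Waals)
for 1–4 pairs — read from the topology's `SCEE`/`SCNB` when present —
and 1 otherwise.  Numerical conventions, each configurable:

* Coulomb constant $k = 332.0522173$ kcal Å mol⁻¹ e⁻², the AMBER
  convention.
* $\varepsilon = 1$ (vacuum form); electrostatics is exactly linear in
  $1/\varepsilon$ and the van der Waals term is independent of it.
* No distance cutoff and no periodic images: the per-pair analysis
  concerns a single non-periodic complex.  A cutoff is available as an
  option.
* Lennard-Jones coefficients come from tabulated per-type-pair A/B
  matrices when a parm7 topology supplies them, otherwise from
  Lorentz–Berthelot combining of per-atom `rmin_half`/`epsilon`.
* Intra-unit energies are not pair quantities and are never included;
  inter-unit exclusions only matter for covalently adjacent units,
  which are flagged `is_covalent` so correlation analyses can drop
  them.

`unit_pair_table()` evaluates all unit pairs per snapshot as block
sums over the atom-level energy matrices, which is algebraically
identical to the naive double loop; the test suite asserts agreement
with an independent scalar double-loop oracle to $10^{-10}$ relative
over 100 randomized systems.  `subunit_decompose()` (bb/bf/fb/ff,
first letter = first unit) and `group_decompose()` (named bonds +
`rest`) re-sum to their parent totals exactly, and the suite asserts
this closure at $10^{-10}$.

# QM component tables

No quantum chemistry is computed here.  `pienet` ingests pair
interaction energy components from CSV at three levels: `MM`
(`elec`, `vdw`), partition analysis `PA` (`es`, `di`, `solv`), and
`FMO` (`es`, `e0`, `ctes`, `di`, `solv`); schema validation rejects
rows whose components do not match their level.  `solute_pie()` (ES +
DI) and `solution_pie()` (all components) give the solvent-free and
screened energies; their difference is exactly `solv` for PA rows.
Covalently bonded fragment pairs carry a large boundary 0-body term
(order −300 kcal mol⁻¹ for DFTB) and must stay flagged so regressions
exclude them.  Charge-transfer bookkeeping: `charge_deviation()`
reports percent deviation from the formal integer for charged units
and absolute deviation (in e) for neutral ones, where a percentage is
undefined.

# Ensemble statistics

`select_snapshots()` uses a half-open window $[t_0, t_1)$ with
nearest-frame matching: the documented production policy — 10 ps
frames, window 20–50 ns, stride 300 ps — then yields exactly 100
snapshots (a closed window would give 101).  `rmsd_series()` computes
heavy-atom RMSD against a reference frame, by default after
least-squares rigid-body superposition (the standard trajectory
practice; both switchable), delegating the Kabsch fit to `bio3d`.
`ensemble_mean_std()` reports the population (divisor $n$) standard
deviation by default — a documented choice, switchable to the sample
estimator — and propagates absent (`NA`) decomposition cells as
absent.  The histogram modality flag counts local maxima above a
height threshold, merging maxima not separated by a valley below half
the smaller peak, so a jagged single basin stays unimodal.

# Residue interaction networks and their comparison

`build_prn()` keeps an undirected edge wherever the ensemble-mean
interaction is attractive and at least as strong as a threshold
$E_{lim}$ (−1 kcal mol⁻¹ by convention), weighted by that energy.  Two
graphs over the same node universe are compared by
`joint_weight_histogram()` + `mutual_information()`:

* the pair universe is the union of pairs with an edge in either
  graph, optionally restricted to nuc–nuc / nuc–aa / aa–aa;
* the energy axis has `n_bins` (default 40) left-closed bins spanning
  [min weight over both graphs, $E_{lim}$], plus a dedicated no-edge
  bin per axis for pairs absent from one graph;
* MI uses natural logarithms by default (configurable base); the
  coefficients of constraint are $C(1|2) = MI/H_1$ and
  $C(2|1) = MI/H_2$, with the label convention switchable since the
  literature is not uniform about which marginal normalizes which
  coefficient;
* per-snapshot graph pairs can be compared and averaged
  (`compare_prn_series()`), the convention for ensemble-level
  comparison.

The binning domain and the no-edge-bin handling are this package's
decisions (recorded in the comparison object); absolute MI values are
therefore comparable only within one convention.  The identities
$MI(G,G) = H(G)$, $MI = 0$ for product histograms, symmetry,
$0 \le C \le 1$ and the no-increase-under-bin-merging property are
asserted in the test suite at $10^{-12}$.

# The synthetic-data generator

The generator exists so every pipeline stage is testable without the
original MD/QM archives.  `generate_toy_complex()` builds a schematic
ladder duplex — alternating G:C and A:T pairs, 3.6 Å rise, no helical
twist — flanked by a short protein chain, with defaults chosen once to
match the study conditions the pipeline is meant to face:

* **100 snapshots** of Gaussian coordinate jitter, $\sigma = 0.1$ Å,
  which makes the standard deviations of strong non-covalent pair
  energies a few percent of their means.
* **Exact charges**: every nucleotide's atomic charges sum to exactly
  −1, split −0.8 (phosphate + pentose) / −0.2 (base); the paired base
  edges carry complementary dipolar partial charges and meet at
  2.95 Å heavy-atom contacts, so base–base attraction coexists with
  net anionic repulsion.
* **Protein composition**: Lys, Asp, Gly, Arg, Ala, Phe.  Two cations
  among six residues is deliberate — DNA-binding interfaces are
  Arg/Lys-rich, and the cation–phosphate contacts give the unscreened
  MM network its characteristic excess of long-range ionic nuc–aa
  edges over the screened network.
* **QM structure** (`generate_qm_tables()`): ES $= \alpha\,$elec +
  noise with $\alpha = 0.95$ (MM overestimates QM electrostatics by a
  few percent); screening solv $= -\beta\,$ES + noise for pairs
  involving a formally charged unit, with $\beta = 0.95$; dispersion
  gets one stable per-pair baseline (−2.5 ± 1 kcal mol⁻¹) drawn
  independently of the vdW values but gated on contact, since
  dispersion decays as $r^{-6}$ and a non-contact pair has none;
  fractional unit charges deviate from their formal integers by about
  the charge-transfer scale (5%).
* $\beta$ is capped at 1 although screened continuum results for
  anionic base pairs behave as if solv slightly over-compensates ES;
  keeping $\beta < 1$ keeps the solute/solution algebra well posed,
  and the ionic sign flip (solute repulsive, solution attractive)
  still emerges because the dispersion baseline outweighs the
  unscreened ES residue.  This flip, the recovery of $\alpha$ and
  $\beta$ within their 95% confidence intervals, and the
  dispersion–vdW decorrelation ($R^2 < 0.2$ with covalent pairs
  excluded) are asserted by the acceptance tests.

What the generator does **not** emulate: realistic sugar rings or
helical geometry, base stacking energetics, explicit hydrogens on
bases, polarization response, or the absolute magnitudes of any
published system's energies.  Passing tests on generator output
demonstrate the correctness of the bookkeeping and the statistical
machinery under controlled ground truth — not force-field accuracy on
real complexes.

# The bundled reference dataset

`mutsdna_tables()` ships ensemble-averaged (100 snapshots) reference
tables for a MutS–DNA mismatch-recognition complex (PDB 2o8b, 3763
atoms): pair interaction energies under five method/unit conventions,
MM and PA components, bb/bf/fb/ff decompositions, per-hydrogen-bond
energies for an A:T, a C:G and the G:T wobble pair, fractional unit
charges, and mean heavy-atom bond lengths.  The package's statistics
reproduce the dataset's published summary values — e.g. $R^2 = 0.993$
between MM and QM solute energies over the 14 non-covalent pairs, the
bb regression slope 0.852, the maximum charge deviation of 7.9% (Asp108),
and the per-bond sums −8.8 / −21.7 / −13.8 kcal mol⁻¹ — all recomputed
from the tables by `scripts/acceptance.R` and the test suite.

# Problem sizes and runtime

The test suite runs the toy complex at its default size (~215 atoms,
14 units, 91 pairs) with 100 snapshots for parameter recovery and
smaller ensembles (5–40 snapshots) elsewhere; the oracle-equivalence
suite uses 100 randomized systems of 20–60 atoms.  These sizes were
chosen so that the whole suite completes in well under a minute while
leaving every statistical assertion comfortably powered.

# Known limitations

* No bonded terms, no PME/Ewald, no free-energy estimators: strictly
  pairwise nonbonded interaction analysis.
* The quantum engine is out of scope; `FMO`/`PA` rows are ingested,
  never computed, and parsing raw GAMESS output is not implemented —
  the documented CSV schema is the interchange format.
* The damped DFTB electrostatics (γ/Γ functions) is documented
  conceptually but never evaluated; its parameters are not public in
  the source material.
* parm7 reading covers the sections needed for nonbonded pair
  energies (charges, LJ tables, exclusions, scale factors, dihedral-
  derived 1–4 pairs); chain identifiers are not present in parm7 and
  are set to a single chain.
* Alternate locations: the first altloc is kept; insertion codes are
  folded into the residue identifier.
* Histidine's formal charge defaults to 0 and is configurable through
  the residue dictionary (`HIP` is +1).
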