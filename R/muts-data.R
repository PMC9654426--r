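#' Reference interaction tables for the MutS-DNA complex
#'
#' Ensemble-averaged (100 MD snapshots) interaction-energy, charge and
#' bond-length tables for a truncated MutS mismatch-repair enzyme bound
#' to a 15-bp DNA duplex containing a G:T mismatch (PDB 2o8b; 3763
#' atoms).  Energies were obtained with the Amber force field
#' (ff14SB/Parmbsc1) and with FMO2-DFTB3/PCM quantum chemistry under
#' two unit conventions (conventional residues vs shifted FMO
#' fragments); charges are DFTB Mulliken charges.  These tables are the
#' package's worked reference dataset: the regression, decomposition
#' and charge-bookkeeping utilities reproduce their published summary
#' statistics exactly.
#'
#' @param which one of `"pie"` (pair interaction energies by method),
#'   `"components"` (MM elec/vdW and PA ES/DI/solv components),
#'   `"subunits"` (backbone/functional bb/bf/fb/ff decomposition under
#'   three methods; empty cells are `NA` — glycine has no side chain),
#'   `"charges"` (formal, MM and fractional QM unit charges, total and
#'   functional), `"groups"` (per-hydrogen-bond energy decomposition of
#'   three base pairs) or `"bonds"` (mean heavy-atom bond lengths of
#'   the named hydrogen bonds).
#' @return data frame; energies kcal/mol, charges elementary units,
#'   lengths Angstrom.  `<col>` and `<col>_sd` hold ensemble mean and
#'   standard deviation.
#' @export
#' @examples
#' pie <- mutsdna_tables("pie")
#' nc <- pie[!pie$is_covalent, ]
#' regress(nc$mm_solute_res, nc$pa_solute_res, keys = nc$pair)
mutsdna_tables <- function(which = c("pie", "components", "subunits",
                                     "charges", "groups", "bonds")) {
  which <- match.arg(which)
  file <- system.file("extdata", paste0("mutsdna_", which, ".csv"),
                      package = "pienet", mustWork = TRUE)
  read.csv(file, stringsAsFactors = FALSE)
}
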