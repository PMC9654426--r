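#' Interaction-energy component schema by level
#'
#' `MM` rows carry force-field components (`elec`, `vdw`); `PA` rows
#' carry the partition-analysis components electrostatic (`es`),
#' dispersion (`di`) and solvent screening (`solv`); `FMO` rows add the
#' 0-body exchange/repulsion term (`e0`) and the charge-transfer
#' coupling to ES (`ctes`).
#'
#' @param level `"MM"`, `"PA"` or `"FMO"`
#' @return character vector of required component column names
#' @export
level_components <- function(level) {
  switch(level,
    MM = c("elec", "vdw"),
    PA = c("es", "di", "solv"),
    FMO = c("es", "e0", "ctes", "di", "solv"),
    stop("unknown level: ", level, " (expected MM, PA or FMO)")
  )
}

#' Validate a pair-component table
#'
#' Checks that every row carries finite values for exactly the
#' components its level requires (extra component columns must be `NA`
#' for rows of a level that does not define them).
#'
#' @param df data frame with columns `unit_i`, `unit_j`, `snapshot`,
#'   `level`, `scheme`, `is_covalent` and component columns
#' @return `df`, invisibly
#' @export
validate_pair_components <- function(df) {
  required <- c("unit_i", "unit_j", "snapshot", "level", "scheme", "is_covalent")
  miss <- setdiff(required, names(df))
  if (length(miss) > 0)
    stop("pair-component table is missing columns: ", paste(miss, collapse = ", "))
  all_comp <- c("elec", "vdw", "es", "e0", "ctes", "di", "solv")
  for (lv in unique(df$level)) {
    need <- level_components(lv)
    rows <- df$level == lv
    for (comp in need) {
      if (is.null(df[[comp]]) || any(!is.finite(df[[comp]][rows])))
        stop("level ", lv, " rows must carry finite '", comp, "' values")
    }
    for (comp in setdiff(intersect(all_comp, names(df)), need)) {
      if (any(!is.na(df[[comp]][rows])))
        stop("level ", lv, " rows must not carry '", comp, "' values")
    }
  }
  invisible(df)
}

#' Solute pair interaction energy
#'
#' The solvent-free part of a pair interaction energy: `es + di` for
#' partition-analysis (`PA`) rows, `elec + vdw` for `MM` rows, and
#' `es + e0 + ctes + di` for `FMO` rows.
#'
#' @param records validated pair-component data frame (single level)
#' @return numeric vector of solute energies (kcal/mol), one per row
#' @export
solute_pie <- function(records) {
  lv <- unique(records$level)
  if (length(lv) != 1) stop("records must all share one level")
  comps <- setdiff(level_components(lv), "solv")
  for (comp in comps)
    if (is.null(records[[comp]]) || any(!is.finite(records[[comp]])))
      stop("missing component '", comp, "' for level ", lv)
  rowSums(records[, comps, drop = FALSE])
}

#' Pair interaction energy in solution
#'
#' The full pair interaction energy including solvent screening:
#' `es + di + solv` for `PA`, `es + e0 + ctes + di + solv` for `FMO`.
#' For `MM` rows (which carry no screening term) this equals the
#' solute value.
#'
#' @inheritParams solute_pie
#' @return numeric vector of solution energies (kcal/mol)
#' @export
solution_pie <- function(records) {
  lv <- unique(records$level)
  if (length(lv) != 1) stop("records must all share one level")
  comps <- level_components(lv)
  for (comp in comps)
    if (is.null(records[[comp]]) || any(!is.finite(records[[comp]])))
      stop("missing component '", comp, "' for level ", lv)
  rowSums(records[, comps, drop = FALSE])
}

#' Deviation of an actual unit charge from its formal charge
#'
#' Charge transfer makes actual (QM) unit charges fractional.  For
#' charged units the deviation is reported in percent of the formal
#' charge, `100 * |total - formal| / |formal|`; for neutral units a
#' percentage is undefined and the absolute deviation (in elementary
#' charges) is reported instead.
#'
#' @param total actual (fractional) unit charge, elementary units
#' @param formal integer formal charge
#' @param mode `"percent"` (formal != 0 only) or `"absolute"`
#' @return numeric deviation(s)
#' @export
charge_deviation <- function(total, formal, mode = c("percent", "absolute")) {
  mode <- match.arg(mode)
  if (mode == "percent") {
    if (any(formal == 0))
      stop("percent deviation is undefined for formal charge 0; ",
           "use mode = \"absolute\" for neutral units")
    100 * abs(total - formal) / abs(formal)
  } else {
    abs(total - formal)
  }
}

#' Mean functional-unit charge for a residue type
#'
#' Averages the functional (base or side-chain) charge over all units
#' of one residue type, e.g. the mean base charge of all guanines.
#'
#' @param charges data frame with columns `residue_type` and
#'   `functional_charge` (one row per unit, ensemble-averaged)
#' @param residue_type type to average over (e.g. `"G"`)
#' @return mean functional charge (elementary units)
#' @export
per_type_functional_charge <- function(charges, residue_type) {
  rows <- charges$residue_type == residue_type
  if (!any(rows)) stop("no units of residue type ", residue_type)
  mean(charges$functional_charge[rows])
}

#' Read / write pair-component CSV tables
#'
#' Strict-header UTF-8 CSV with `.` decimal separator; columns
#' `unit_i`, `unit_j`, `snapshot`, `level`, `scheme`, `is_covalent` and
#' the component columns of [level_components()].  Reading validates
#' the schema.
#'
#' @param file path
#' @return `read_pair_components`: validated data frame
#' @export
read_pair_components <- function(file) {
  df <- read.csv(file, stringsAsFactors = FALSE)
  df$is_covalent <- as.logical(df$is_covalent)
  validate_pair_components(df)
  df
}

#' @rdname read_pair_components
#' @param df pair-component data frame
#' @return `write_pair_components`: `file`, invisibly
#' @export
write_pair_components <- function(df, file) {
  validate_pair_components(df)
  write.csv(df, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Read / write unit-charge CSV tables
#'
#' Columns `unit_id`, `label`, `residue_type`, `snapshot` (optional for
#' ensemble-averaged tables), `formal_charge`, `total_charge`,
#' `functional_charge`.  A sanity check requires actual charges to lie
#' within 0.5 e of the formal charge.
#'
#' @param file path
#' @return `read_unit_charges`: data frame
#' @export
read_unit_charges <- function(file) {
  df <- read.csv(file, stringsAsFactors = FALSE)
  need <- c("unit_id", "formal_charge", "total_charge")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("unit-charge table is missing columns: ", paste(miss, collapse = ", "))
  off <- abs(df$total_charge - df$formal_charge) >= 0.5
  if (any(off))
    stop("unit ", df$unit_id[off][1],
         ": total charge deviates from formal by >= 0.5 e")
  df
}

#' @rdname read_unit_charges
#' @param df unit-charge data frame
#' @return `write_unit_charges`: `file`, invisibly
#' @export
write_unit_charges <- function(df, file) {
  write.csv(df, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}
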