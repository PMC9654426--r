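#' Pipeline configuration
#'
#' Declarative configuration for [run_pipeline()].  Defaults mirror the
#' conventional analysis settings: vacuum dielectric, an edge threshold
#' of -1 kcal/mol, 40 histogram bins.  The snapshot window defaults to
#' the full trajectory; set `start`/`end`/`stride` for production-part
#' selection.
#'
#' @param generator a [generator_config()] (synthetic input), or `NULL`
#'   when `system`/`rules` are supplied directly to [run_pipeline()]
#' @param dielectric relative permittivity for MM electrostatics
#' @param e_lim network edge threshold (kcal/mol, negative)
#' @param n_bins histogram bins for graph comparison
#' @param start,end,stride snapshot selection window (ps); `NULL` keeps
#'   every frame
#' @param out_dir output directory (created if needed); `NULL` disables
#'   file output
#' @param digits rounding for rendered report tables
#' @return object of class `pipeline_config`
#' @export
pipeline_config <- function(generator = generator_config(),
                            dielectric = 1, e_lim = -1, n_bins = 40,
                            start = NULL, end = NULL, stride = NULL,
                            out_dir = NULL, digits = 1) {
  if (e_lim >= 0) stop("e_lim must be negative")
  structure(as.list(environment()), class = "pipeline_config")
}

#' Hash of the scientific parameters of a pipeline configuration
#'
#' Output-location settings are excluded so reruns into different
#' directories share a hash.
#'
#' @param config a [pipeline_config()]
#' @return md5 string
#' @export
config_hash <- function(config) {
  sci <- unclass(config)
  sci$out_dir <- NULL
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(sci, tmp, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(tmp))
}

#' Run the full analysis pipeline
#'
#' Orchestrates the stages end to end: snapshot selection, MM pair
#' energies, synthetic QM tables (for generator input),
#' backbone/functional decomposition, ensemble averaging, MM-QM
#' correlations, residue-network construction for the MM and PA
#' energy sets, and their mutual-information comparison.  Deterministic
#' for a fixed configuration; every written artifact carries the
#' configuration hash.
#'
#' @param config a [pipeline_config()]
#' @param system,rules optionally, a prepared [molecular_system()] and
#'   [nonbonded_rules()] instead of the synthetic generator
#' @param verbose print per-stage progress
#' @return list with `mm` (per-snapshot pair table), `qm` (synthetic or
#'   ingested component tables), `ensemble_mm`, `ensemble_pa`,
#'   `subunits`, `correlations`, `prn` (MM and PA graphs), `comparison`,
#'   `config_hash`, and `files` (paths written, if any)
#' @export
run_pipeline <- function(config = pipeline_config(), system = NULL,
                         rules = NULL, verbose = FALSE) {
  say <- function(...) if (verbose) message("[pienet] ", ...)
  t0 <- Sys.time()
  hash <- config_hash(config)
  if (is.null(system)) {
    say("stage simulate: generating toy complex")
    toy <- generate_toy_complex(config$generator)
    system <- toy$system
    rules <- toy$rules
    segments <- toy$segments
    labeling <- toy$labeling
  } else {
    if (is.null(rules)) rules <- nonbonded_rules()
    segments <- assign_segments(system)
    labeling <- label_subunits(system, segments)
  }
  rules$dielectric <- config$dielectric

  say("stage select")
  frames <- if (is.null(config$start)) seq_len(n_frames(system))
  else select_snapshots(system$times, config$start, config$end, config$stride)

  say("stage mm-energies: ", length(frames), " frames")
  mm <- unit_pair_table(system, segments, rules, frames = frames)

  say("stage qm-tables")
  qm <- generate_qm_tables(mm, segments, config$generator)
  qm$pa$total <- solution_pie(qm$pa)
  qm$pa$solute <- solute_pie(qm$pa)

  say("stage decompose")
  subunits <- subunit_pair_table(system, segments, labeling, rules,
                                 frames = frames[1])

  say("stage average")
  key <- c("unit_i", "unit_j")
  ens_mm <- ensemble_mean_std(mm, c("elec", "vdw", "total"), key)
  ens_pa <- ensemble_mean_std(qm$pa, c("es", "di", "solv", "total", "solute"), key)

  say("stage correlate")
  mm_mean <- ens_mm
  names(mm_mean)[names(mm_mean) == "elec_mean"] <- "elec"
  names(mm_mean)[names(mm_mean) == "vdw_mean"] <- "vdw"
  pa_mean <- ens_pa
  names(pa_mean)[names(pa_mean) == "es_mean"] <- "es"
  names(pa_mean)[names(pa_mean) == "di_mean"] <- "di"
  cov_key <- paste(mm$unit_i, mm$unit_j)[mm$is_covalent]
  mm_mean$is_covalent <- paste(mm_mean$unit_i, mm_mean$unit_j) %in% cov_key
  pa_mean$is_covalent <- mm_mean$is_covalent
  correlations <- component_correlation(mm_mean, pa_mean)

  say("stage prn + compare")
  g_mm <- build_prn(ens_mm, segments$units, config$e_lim, weight_col = "total_mean")
  g_pa <- build_prn(ens_pa, segments$units, config$e_lim, weight_col = "total_mean")
  comparison <- compare_prn(g_mm, g_pa, n_bins = config$n_bins)

  files <- character()
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    meta <- c(config_hash = hash,
              package_version = as.character(utils::packageVersion("pienet")))
    p <- function(f) file.path(config$out_dir, f)
    write_pair_components(mm, p("mm_pairs.csv"))
    write_pair_components(qm$pa[, setdiff(names(qm$pa), c("total", "solute"))],
                          p("pa_pairs.csv"))
    write_unit_charges(qm$charges, p("unit_charges.csv"))
    make_report(ens_mm, p("ensemble_mm.csv"), c("elec", "vdw", "total"),
                digits = config$digits, metadata = meta)
    make_report(ens_pa, p("ensemble_pa.csv"),
                c("es", "di", "solv", "total", "solute"),
                digits = config$digits, metadata = meta)
    write_prn(g_mm, p("prn_mm.tsv"), "edgelist")
    write_prn(g_pa, p("prn_pa.tsv"), "edgelist")
    jsonlite::write_json(
      list(metadata = as.list(meta),
           correlations = lapply(correlations, function(r)
             r[c("slope", "intercept", "r_squared", "n")]),
           comparison = unclass(comparison)[c("mi", "h1", "h2", "c12", "c21",
                                              "n", "n_bins", "category")]),
      p("report.json"), auto_unbox = TRUE, digits = NA)
    files <- file.path(config$out_dir,
                       c("mm_pairs.csv", "pa_pairs.csv", "unit_charges.csv",
                         "ensemble_mm.csv", "ensemble_pa.csv",
                         "prn_mm.tsv", "prn_pa.tsv", "report.json"))
  }
  say("done in ", format(Sys.time() - t0))
  list(mm = mm, qm = qm, ensemble_mm = ens_mm, ensemble_pa = ens_pa,
       subunits = subunits, correlations = correlations,
       prn = list(mm = g_mm, pa = g_pa), comparison = comparison,
       config_hash = hash, files = files)
}
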