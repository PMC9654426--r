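#' Ordinary least squares between two matched energy sets
#'
#' Regresses `y` on `x` after dropping excluded keys and any pair with
#' a missing value in either set (listwise deletion, e.g. glycine
#' blanks).  R-squared is the squared Pearson correlation.
#'
#' @param x,y numeric vectors of matched values
#' @param keys optional identifiers (e.g. pair labels), used for
#'   exclusions and reporting
#' @param exclude keys (or logical/integer index) to drop, with the
#'   conventional use being covalently bonded pairs
#' @return object of class `regression_result`: list with `slope`,
#'   `intercept`, `r_squared`, `n`, `excluded`
#' @export
regress <- function(x, y, keys = NULL, exclude = NULL) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (is.null(keys)) keys <- as.character(seq_along(x))
  drop <- rep(FALSE, length(x))
  if (!is.null(exclude)) {
    if (is.logical(exclude) || is.numeric(exclude)) {
      drop[exclude] <- TRUE
    } else {
      drop <- keys %in% exclude
    }
  }
  excluded <- data.frame(key = keys[drop],
                         reason = rep("excluded", sum(drop)),
                         stringsAsFactors = FALSE)
  miss <- !drop & (is.na(x) | is.na(y))
  if (any(miss))
    excluded <- rbind(excluded,
                      data.frame(key = keys[miss], reason = "missing value"))
  keep <- !drop & !miss
  if (sum(keep) < 2) stop("fewer than 2 pairs remain after exclusions")
  fit <- lm(y[keep] ~ x[keep])
  structure(list(
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    r_squared = cor(x[keep], y[keep])^2,
    n = sum(keep),
    excluded = excluded
  ), class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("OLS (n = %d): slope %.3f, intercept %.3f, R2 %.3f",
              x$n, x$slope, x$intercept, x$r_squared))
  if (nrow(x$excluded) > 0)
    cat("  [excluded: ", paste(x$excluded$key, collapse = ", "), "]", sep = "")
  cat("\n")
  invisible(x)
}

#' Componentwise MM-QM correlations
#'
#' Regressions of the matched physically analogous components: QM
#' electrostatics (`es`) on MM electrostatics (`elec`), and QM
#' dispersion (`di`) on MM van der Waals (`vdw`).  Tables are matched
#' on (`unit_i`, `unit_j`); covalently bonded pairs are excluded by
#' default.
#'
#' @param mm_table data frame with `unit_i`, `unit_j`, `elec`, `vdw`
#'   (+ `is_covalent`)
#' @param qm_table data frame with `unit_i`, `unit_j`, `es`, `di`
#'   (+ `is_covalent`)
#' @param exclude_covalent drop pairs flagged covalent in either table
#' @return list of two [regress()] results: `elec_es` and `vdw_di`
#' @export
component_correlation <- function(mm_table, qm_table, exclude_covalent = TRUE) {
  key <- function(df) paste(pmin(df$unit_i, df$unit_j),
                            pmax(df$unit_i, df$unit_j), sep = "|")
  km <- key(mm_table); kq <- key(qm_table)
  common <- intersect(km, kq)
  if (length(common) < 2) stop("fewer than 2 matched pairs between tables")
  im <- match(common, km); iq <- match(common, kq)
  excl <- NULL
  if (exclude_covalent) {
    cov <- (mm_table$is_covalent[im] %in% TRUE) | (qm_table$is_covalent[iq] %in% TRUE)
    excl <- common[cov]
  }
  list(
    elec_es = regress(mm_table$elec[im], qm_table$es[iq], keys = common, exclude = excl),
    vdw_di = regress(mm_table$vdw[im], qm_table$di[iq], keys = common, exclude = excl)
  )
}

#' Bond-length statistics for the named bonds of a base pair
#'
#' Distance between the two heavy probe atoms of each named bond,
#' per snapshot, summarised as ensemble mean and standard deviation.
#' Probe atom names are resolved in whichever unit of the pair carries
#' them (published probe tables do not consistently order the atoms by
#' unit).
#'
#' @param system a [molecular_system()] with coordinates
#' @param scheme a [unit_scheme()]
#' @param pair two unit ids or display labels
#' @param groups a [group_scheme()] providing the probe table
#' @param frames snapshot indices (default: all)
#' @param population population standard deviation (see
#'   [ensemble_mean_std()])
#' @return data frame with columns `bond`, `atom_a`, `atom_b`, `mean`,
#'   `sd`, `n`
#' @export
bond_distance_stats <- function(system, scheme, pair, groups,
                                frames = NULL, population = TRUE) {
  if (is.null(frames)) frames <- seq_len(max(1L, n_frames(system)))
  ai <- unit_atoms(scheme, pair[[1]])
  aj <- unit_atoms(scheme, pair[[2]])
  find_in <- function(atom, idx) {
    hit <- idx[system$atoms$name[idx] == atom & system$atoms$is_heavy[idx]]
    if (length(hit)) hit[1] else NA_integer_
  }
  # the two probes must sit in different units; base rings share many
  # atom names (N1, N3, ...) so orientation is decided per bond
  resolve_pair <- function(a, b) {
    a_i <- find_in(a, ai); b_j <- find_in(b, aj)
    if (!is.na(a_i) && !is.na(b_j)) return(c(a_i, b_j))
    a_j <- find_in(a, aj); b_i <- find_in(b, ai)
    if (!is.na(a_j) && !is.na(b_i)) return(c(a_j, b_i))
    missing <- if (is.na(a_i) && is.na(a_j)) a else b
    stop("probe atom ", missing, " not found (or not heavy) in the pair")
  }
  out <- lapply(seq_len(nrow(groups$probes)), function(b) {
    probes <- resolve_pair(groups$probes$atom_a[b], groups$probes$atom_b[b])
    a1 <- probes[1]
    a2 <- probes[2]
    d <- vapply(frames, function(f) {
      xyz <- snapshot_coords(system, f)
      sqrt(sum((xyz[a1, ] - xyz[a2, ])^2))
    }, numeric(1))
    s <- if (length(d) > 1) stats::sd(d) else 0
    if (population && length(d) > 1) s <- s * sqrt((length(d) - 1) / length(d))
    data.frame(bond = groups$probes$bond[b],
               atom_a = groups$probes$atom_a[b],
               atom_b = groups$probes$atom_b[b],
               mean = mean(d), sd = s, n = length(d),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Round and format mean +/- sd table cells
#'
#' Formats ensemble statistics the way interaction-energy tables are
#' conventionally printed: one decimal place, `mean+/-sd`, empty cells
#' for absent (NA) values.  Rendering is deterministic.
#'
#' @param mean,sd numeric vectors
#' @param digits decimal places
#' @return character vector
#' @export
format_mean_sd <- function(mean, sd = NULL, digits = 1) {
  fmt <- function(v) formatC(round(v, digits), format = "f", digits = digits)
  out <- ifelse(is.na(mean), "",
                if (is.null(sd)) fmt(mean)
                else paste0(fmt(mean), "±", fmt(sd)))
  ifelse(is.na(mean), "", out)
}

#' Render an ensemble table as a publication-style CSV
#'
#' Writes a wide table with `mean+/-sd` cells rounded to `digits`
#' decimals, leaving absent decomposition cells empty.  A metadata
#' header line (key=value pairs, `#`-prefixed) records provenance.
#'
#' @param table data frame from [ensemble_mean_std()]
#' @param file output path
#' @param value_cols base names of the value columns (without
#'   `_mean`/`_sd`)
#' @param digits decimal places (energies are conventionally printed
#'   with one)
#' @param metadata named character vector written as a comment header
#' @return `file`, invisibly
#' @export
make_report <- function(table, file, value_cols, digits = 1, metadata = NULL) {
  keys <- setdiff(names(table),
                  c(paste0(value_cols, "_mean"), paste0(value_cols, "_sd")))
  out <- table[, keys, drop = FALSE]
  for (col in value_cols) {
    out[[col]] <- format_mean_sd(table[[paste0(col, "_mean")]],
                                 table[[paste0(col, "_sd")]], digits)
  }
  con <- file(file, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(metadata))
    writeLines(paste0("# ", names(metadata), "=", metadata), con)
  write.csv(out, con, row.names = FALSE, quote = FALSE)
  invisible(file)
}
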