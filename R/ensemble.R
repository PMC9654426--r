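#' Snapshot selection policy
#'
#' Frames are selected from a half-open time window `[start, end)` at a
#' fixed stride, with nearest-frame matching: the frame closest to each
#' target time `start, start + stride, ...` is taken, provided it lies
#' within half the typical frame spacing of the target.  The half-open
#' window makes a 20-50 ns window with a 300 ps stride over 10 ps
#' frames yield exactly 100 snapshots.
#'
#' @param times numeric vector of frame times (ps), increasing
#' @param start,end window bounds (ps), `start < end`
#' @param stride selection stride (ps), > 0
#' @return integer vector of selected frame indices
#' @export
select_snapshots <- function(times, start, end, stride) {
  if (start >= end) stop("window start must be before end")
  if (stride <= 0) stop("stride must be positive")
  if (any(diff(times) <= 0)) stop("frame times must be strictly increasing")
  targets <- seq(start, end - stride * 1e-9, by = stride)
  targets <- targets[targets < end]
  spacing <- if (length(times) > 1) stats::median(diff(times)) else stride
  idx <- vapply(targets, function(t) {
    k <- which.min(abs(times - t))
    if (abs(times[k] - t) <= spacing / 2 && times[k] >= start && times[k] < end)
      k else NA_integer_
  }, integer(1))
  idx <- unique(idx[!is.na(idx)])
  if (length(idx) == 0)
    stop("no frames fall inside the selection window [", start, ", ", end, ")")
  idx
}

#' RMSD of each snapshot relative to a reference frame
#'
#' Root-mean-square deviation over the selected atoms, optionally after
#' an optimal rigid-body (Kabsch) superposition onto the reference.
#' Superposition defaults to on, the standard practice for trajectory
#' stability analysis; heavy atoms only by default.
#'
#' @param system a [molecular_system()] with >= 1 snapshot
#' @param reference reference frame index
#' @param heavy_only restrict to non-hydrogen atoms
#' @param superpose apply least-squares rigid-body fitting first
#' @return numeric vector of per-frame RMSD values (Angstrom)
#' @export
rmsd_series <- function(system, reference = 1L, heavy_only = TRUE,
                        superpose = TRUE) {
  nf <- n_frames(system)
  if (nf == 0) stop("system has no coordinates")
  sel <- if (heavy_only) which(system$atoms$is_heavy) else seq_len(nrow(system$atoms))
  if (length(sel) == 0) stop("no atoms selected for RMSD")
  ref <- snapshot_coords(system, reference)[sel, , drop = FALSE]
  ref_xyz <- as.numeric(t(ref))
  vapply(seq_len(nf), function(f) {
    frm <- snapshot_coords(system, f)[sel, , drop = FALSE]
    bio3d::rmsd(ref_xyz, as.numeric(t(frm)), fit = superpose)
  }, numeric(1))
}

#' Histogram of an RMSD series with a modality flag
#'
#' Bins the series and counts local maxima whose height exceeds
#' `peak_frac` of the largest bin: 1 for a unimodal distribution
#' (a single dominant conformational basin), 2+ when distinct basins
#' coexist.
#'
#' @param series numeric vector (e.g. from [rmsd_series()])
#' @param n_bins number of histogram bins
#' @param peak_frac fraction of the maximum count a local maximum must
#'   reach to count as a mode
#' @return list with `breaks`, `counts`, `mids` and `modality`
#' @export
rmsd_histogram <- function(series, n_bins = 30, peak_frac = 0.2) {
  h <- graphics::hist(series, breaks = n_bins, plot = FALSE)
  counts <- h$counts
  thresh <- peak_frac * max(counts)
  n <- length(counts)
  # candidate modes: local maxima above the height threshold
  cand <- which(vapply(seq_len(n), function(k) {
    left <- if (k == 1) -1 else counts[k - 1]
    right <- if (k == n) -1 else counts[k + 1]
    counts[k] > thresh && counts[k] >= left && counts[k] >= right
  }, logical(1)))
  # merge candidates not separated by a genuine valley (below half the
  # smaller of the two maxima): jagged single basins stay unimodal
  peaks <- 0L
  if (length(cand) > 0) {
    peaks <- 1L
    last <- cand[1]
    for (k in cand[-1]) {
      valley <- min(counts[last:k])
      if (valley < 0.5 * min(counts[last], counts[k])) {
        peaks <- peaks + 1L
        last <- k
      } else if (counts[k] > counts[last]) last <- k
    }
  }
  list(breaks = h$breaks, counts = counts, mids = h$mids, modality = peaks)
}

#' Ensemble mean and standard deviation by group
#'
#' Arithmetic mean and standard deviation of per-snapshot values,
#' grouped by key columns (pair, subunit pair, bond, unit, ...).  The
#' population standard deviation (divisor n) is the default; set
#' `population = FALSE` for the sample estimator (divisor n - 1).
#' `NA` cells (absent decomposition blocks such as glycine ff) stay
#' absent: a group whose values are all `NA` yields `NA`.
#'
#' @param df data frame of per-snapshot records
#' @param value_cols names of the numeric columns to average
#' @param by names of the grouping key columns
#' @param population use the population (n) standard deviation
#' @return data frame with the key columns and, per value column,
#'   `<col>_mean`, `<col>_sd`, plus the snapshot count `n`
#' @export
ensemble_mean_std <- function(df, value_cols, by, population = TRUE) {
  key <- interaction(df[by], drop = TRUE, lex.order = TRUE)
  groups <- split(seq_len(nrow(df)), key)
  out <- do.call(rbind, lapply(groups, function(rows) {
    res <- df[rows[1], by, drop = FALSE]
    res$n <- length(rows)
    for (col in value_cols) {
      v <- df[[col]][rows]
      if (all(is.na(v))) {
        res[[paste0(col, "_mean")]] <- NA_real_
        res[[paste0(col, "_sd")]] <- NA_real_
      } else {
        m <- mean(v)
        s <- if (length(v) > 1) stats::sd(v) else 0
        if (population && length(v) > 1) s <- s * sqrt((length(v) - 1) / length(v))
        res[[paste0(col, "_mean")]] <- m
        res[[paste0(col, "_sd")]] <- s
      }
    }
    res
  }))
  rownames(out) <- NULL
  out
}
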