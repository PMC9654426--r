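#' Build a residue interaction network graph
#'
#' Nodes are units (residues/nucleotides); an undirected edge joins two
#' units whenever their ensemble-mean interaction energy is attractive
#' and at least as strong as the threshold `e_lim` (i.e. mean energy
#' `<= e_lim < 0`), weighted by that energy.
#'
#' @param table data frame with columns `unit_i`, `unit_j` and an
#'   energy column (`mean` by default)
#' @param units data frame describing the node universe, with columns
#'   `unit_id`, `label`, `category` (e.g. `scheme$units`)
#' @param e_lim edge-inclusion threshold, kcal/mol, strictly negative
#' @param weight_col name of the energy column in `table`
#' @return an [igraph::graph] of class `c("prn_graph", "igraph")` with
#'   vertex attributes `name` (unit id), `label`, `category`, edge
#'   attribute `weight`, and graph attribute `e_lim`
#' @export
build_prn <- function(table, units, e_lim = -1, weight_col = "mean") {
  if (e_lim >= 0) stop("e_lim must be negative (attractive threshold)")
  w <- table[[weight_col]]
  if (is.null(w)) stop("no column '", weight_col, "' in table")
  keep <- !is.na(w) & w <= e_lim
  edges <- table[keep, c("unit_i", "unit_j"), drop = FALSE]
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = as.character(edges$unit_i),
                   to = as.character(edges$unit_j),
                   weight = w[keep]),
    directed = FALSE,
    vertices = data.frame(name = as.character(units$unit_id),
                          label = units$label,
                          category = units$category)
  )
  g <- igraph::set_graph_attr(g, "e_lim", e_lim)
  class(g) <- c("prn_graph", class(g))
  g
}

#' Category of a unit pair
#'
#' Classifies a pair by the categories of its two units:
#' `"nuc-nuc"`, `"nuc-aa"` or `"aa-aa"`.
#'
#' @param cat_i,cat_j unit categories (`"nuc"` or `"aa"`)
#' @return character vector of pair categories
#' @export
pair_category <- function(cat_i, cat_j) {
  a <- pmin(cat_i, cat_j)  # "aa" < "nuc" lexically
  b <- pmax(cat_i, cat_j)
  ifelse(a == "nuc", "nuc-nuc", ifelse(b == "nuc", "nuc-aa", "aa-aa"))
}

prn_edge_weights <- function(g) {
  el <- igraph::as_edgelist(g)
  if (nrow(el) == 0)
    return(setNames(numeric(), character()))
  key <- paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]), sep = "|")
  setNames(igraph::E(g)$weight, key)
}

#' Joint edge-weight histogram of two interaction graphs
#'
#' Over the union of unit pairs carrying an edge in either graph
#' (optionally restricted to one pair category), each pair contributes
#' one count at (bin of its weight in graph 1, bin of its weight in
#' graph 2).  The energy axis is divided into `n_bins` left-closed bins
#' spanning `[min weight over both graphs, e_lim]`; a pair with no edge
#' in one graph (interaction weaker than `e_lim` there) falls into a
#' dedicated no-edge bin on that axis, so the count matrix is
#' `(n_bins + 1) x (n_bins + 1)`.
#'
#' @param g1,g2 [build_prn()] graphs over the same node universe
#' @param n_bins number of energy bins
#' @param category `"all"`, `"nuc-nuc"`, `"nuc-aa"` or `"aa-aa"`
#' @return list with `counts` (matrix, last row/column = no-edge bin),
#'   `breaks`, `n_bins`, `category` and `e_lim`
#' @export
joint_weight_histogram <- function(g1, g2, n_bins = 40,
                                   category = c("all", "nuc-nuc", "nuc-aa", "aa-aa")) {
  category <- match.arg(category)
  v1 <- sort(igraph::V(g1)$name)
  v2 <- sort(igraph::V(g2)$name)
  if (!identical(v1, v2))
    stop("the two graphs must share the same node universe")
  e_lim <- igraph::graph_attr(g1, "e_lim")
  w1 <- prn_edge_weights(g1)
  w2 <- prn_edge_weights(g2)
  pairs <- union(names(w1), names(w2))
  if (category != "all" && length(pairs) > 0) {
    cat_of <- setNames(igraph::V(g1)$category, igraph::V(g1)$name)
    parts <- strsplit(pairs, "|", fixed = TRUE)
    pc <- vapply(parts, function(p) pair_category(cat_of[p[1]], cat_of[p[2]]),
                 character(1))
    pairs <- pairs[pc == category]
  }
  lo <- min(c(w1, w2, e_lim))
  breaks <- seq(lo, e_lim, length.out = n_bins + 1)
  bin_of <- function(w, key) {
    if (!key %in% names(w)) return(n_bins + 1L)  # no-edge bin
    x <- w[[key]]
    b <- findInterval(x, breaks, rightmost.closed = TRUE, left.open = FALSE)
    min(max(b, 1L), n_bins)
  }
  counts <- matrix(0L, n_bins + 1L, n_bins + 1L)
  for (key in pairs) {
    i <- bin_of(w1, key)
    j <- bin_of(w2, key)
    counts[i, j] <- counts[i, j] + 1L
  }
  list(counts = counts, breaks = breaks, n_bins = n_bins,
       category = category, e_lim = e_lim)
}

#' Mutual information and coefficients of constraint of a joint histogram
#'
#' Treats the normalised joint histogram as a discrete joint
#' distribution `p(x, y)` and computes the mutual information
#' `MI = sum p log(p / (p_x p_y))` (with `0 log 0 := 0`), the marginal
#' entropies `H1`, `H2`, and the coefficients of constraint
#' `C(1|2) = MI / H1` and `C(2|1) = MI / H2`, which equal 1 when one
#' graph's edge weights fully determine the other's.
#'
#' @param hist result of [joint_weight_histogram()], or any
#'   non-negative count matrix (then supplied as `list(counts = m)` or
#'   a bare matrix)
#' @param base logarithm base (`exp(1)` for nats, 2 for bits)
#' @return object of class `graph_comparison`: list with `mi`, `h1`,
#'   `h2`, `c12`, `c21`, `n`, `n_bins`, `category`, `e_lim`
#' @export
mutual_information <- function(hist, base = exp(1)) {
  counts <- if (is.matrix(hist)) hist else hist$counts
  if (any(counts < 0)) stop("histogram counts must be non-negative")
  n <- sum(counts)
  if (n == 0) stop("all-zero histogram: no pairs to compare")
  p <- counts / n
  px <- rowSums(p)
  py <- colSums(p)
  lg <- function(x) log(x, base = base)
  ent <- function(q) { q <- q[q > 0]; -sum(q * lg(q)) }
  pp <- outer(px, py)
  nz <- p > 0
  mi <- sum(p[nz] * lg(p[nz] / pp[nz]))
  mi <- max(mi, 0)  # guard against tiny negative rounding
  h1 <- ent(px)
  h2 <- ent(py)
  structure(list(
    mi = mi, h1 = h1, h2 = h2,
    c12 = if (h1 > 0) mi / h1 else NA_real_,
    c21 = if (h2 > 0) mi / h2 else NA_real_,
    n = n,
    n_bins = if (is.matrix(hist)) nrow(counts) else hist$n_bins,
    category = if (is.matrix(hist)) NA_character_ else hist$category,
    e_lim = if (is.matrix(hist)) NA_real_ else hist$e_lim
  ), class = "graph_comparison")
}

#' @export
print.graph_comparison <- function(x, ...) {
  cat(sprintf("graph comparison (%s, %d pairs): MI = %.4f, H1 = %.4f, H2 = %.4f, C(1|2) = %.4f, C(2|1) = %.4f\n",
              ifelse(is.na(x$category), "?", x$category), x$n,
              x$mi, x$h1, x$h2, x$c12, x$c21))
  invisible(x)
}

#' Compare two residue interaction networks
#'
#' Convenience wrapper: joint histogram plus mutual-information
#' statistics in one call.
#'
#' @inheritParams joint_weight_histogram
#' @param base logarithm base
#' @return a [mutual_information()] `graph_comparison`
#' @export
compare_prn <- function(g1, g2, n_bins = 40,
                        category = c("all", "nuc-nuc", "nuc-aa", "aa-aa"),
                        base = exp(1)) {
  mutual_information(joint_weight_histogram(g1, g2, n_bins, category), base = base)
}

#' Average graph comparison over per-snapshot graph pairs
#'
#' Builds a graph per snapshot from each of two per-snapshot energy
#' tables, compares matched snapshots, and averages the statistics,
#' the convention for ensemble-level network comparison.
#'
#' @param tables1,tables2 data frames of per-snapshot pair energies
#'   (columns `unit_i`, `unit_j`, `snapshot` and the weight column)
#' @param units node-universe data frame (see [build_prn()])
#' @param e_lim edge threshold
#' @param n_bins,category,base as in [compare_prn()]
#' @param weight_col energy column name
#' @return list with the mean `mi`, `h1`, `h2`, `c12`, `c21` and the
#'   number of snapshots `n_snapshots`
#' @export
compare_prn_series <- function(tables1, tables2, units, e_lim = -1,
                               n_bins = 40, category = "all",
                               base = exp(1), weight_col = "total") {
  snaps <- sort(intersect(unique(tables1$snapshot), unique(tables2$snapshot)))
  if (length(snaps) == 0) stop("no common snapshots between the two tables")
  stats <- lapply(snaps, function(s) {
    g1 <- build_prn(tables1[tables1$snapshot == s, ], units, e_lim, weight_col)
    g2 <- build_prn(tables2[tables2$snapshot == s, ], units, e_lim, weight_col)
    cmp <- compare_prn(g1, g2, n_bins, category, base)
    c(mi = cmp$mi, h1 = cmp$h1, h2 = cmp$h2, c12 = cmp$c12, c21 = cmp$c21)
  })
  m <- colMeans(do.call(rbind, stats))
  c(as.list(m), n_snapshots = length(snaps))
}

#' Export a residue interaction network
#'
#' Writes GraphML (via igraph) or a three-column edge list
#' (`unit_i`, `unit_j`, `weight`, tab-separated).
#'
#' @param g a [build_prn()] graph
#' @param file output path
#' @param format `"graphml"` or `"edgelist"`
#' @return `file`, invisibly
#' @export
write_prn <- function(g, file, format = c("graphml", "edgelist")) {
  format <- match.arg(format)
  if (format == "graphml") {
    cls <- class(g)
    class(g) <- setdiff(cls, "prn_graph")
    igraph::write_graph(g, file, format = "graphml")
  } else {
    el <- igraph::as_edgelist(g)
    df <- data.frame(unit_i = el[, 1], unit_j = el[, 2],
                     weight = igraph::E(g)$weight)
    write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(file)
}
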