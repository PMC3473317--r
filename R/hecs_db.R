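# Construction of highly expressed cell-specific (HECS) signature databases
# from an expression atlas, plus the statistics used to characterize them
# (signature sizes, cumulative uniqueness, pairwise sharing).

new_hecs_db <- function(species, threshold, signatures, universe,
                        entrez_to_symbol) {
  universe <- sort(unique(universe))
  stray <- setdiff(unique(unlist(signatures, use.names = FALSE)), universe)
  if (length(stray) > 0L) {
    stop("signature genes outside the universe: ",
         paste(utils::head(stray, 3L), collapse = ", "), call. = FALSE)
  }
  sym <- entrez_to_symbol[universe]
  names(sym) <- universe
  s2e <- stats::setNames(universe, toupper(sym))
  s2e <- s2e[!is.na(names(s2e)) & !duplicated(names(s2e))]
  structure(list(species = species,
                 threshold = threshold,
                 signatures = signatures,
                 universe = universe,
                 entrez_to_symbol = sym,
                 symbol_to_entrez = s2e),
            class = "hecs_db")
}

#' @export
print.hecs_db <- function(x, ...) {
  sizes <- lengths(x$signatures)
  cat("HECS database (", x$species, "), threshold ", x$threshold, "x median\n",
      "  ", length(x$signatures), " cell types, universe of ",
      length(x$universe), " genes\n",
      "  signature sizes: min ", min(sizes), ", mean ",
      round(mean(sizes), 1), ", max ", max(sizes), "\n", sep = "")
  invisible(x)
}

#' Number of cell types in a HECS database
#' @param db A `hecs_db` object.
#' @return Integer count.
#' @export
n_cell_types <- function(db) {
  stopifnot(inherits(db, "hecs_db"))
  length(db$signatures)
}

#' Average an atlas over biological replicates
#'
#' Collapses the probes x samples matrix to probes x cell types by taking the
#' arithmetic mean of each probe's values over every sample of a cell type.
#' Columns are ordered by sorted cell-type label.
#'
#' @param atlas An [expression_atlas].
#' @return Numeric matrix, probes x cell types.
#' @export
average_replicates <- function(atlas) {
  stopifnot(inherits(atlas, "expression_atlas"))
  cts <- sort(unique(atlas$sample_cell_type))
  out <- vapply(cts, function(ct) {
    cols <- names(atlas$sample_cell_type)[atlas$sample_cell_type == ct]
    rowMeans(atlas$values[, cols, drop = FALSE])
  }, numeric(nrow(atlas$values)))
  # vapply drops to a vector for a single-probe atlas
  if (is.null(dim(out))) out <- matrix(out, nrow = 1L, dimnames = list(NULL, cts))
  rownames(out) <- rownames(atlas$values)
  out
}

#' Assign HECS genes and build a signature database
#'
#' A probe is flagged for a cell type when its replicate-averaged expression
#' there is at least `threshold` times the probe's median expression across
#' all cell types, provided that median is positive. (A zero median would make
#' the criterion vacuous and flag the probe wherever it has any signal, so
#' such probes are excluded.) A gene becomes a HECS gene of a cell type when
#' any of its probes is flagged there; genes reached through several probes
#' are listed once per cell type. The gene universe is every annotated gene on
#' the array, flagged or not — it is the enrichment background.
#'
#' @param cell_matrix Probes x cell types matrix from [average_replicates()].
#' @param annotation Probe annotation data frame (`probe_id`, `entrez_id`,
#'   `symbol`); probes with `NA` Entrez ids never yield signature genes.
#' @param threshold Fold threshold `t > 1`. The reference atlases in this
#'   field use 15 (mouse) and 10 (human).
#' @param species Species label recorded on the database.
#' @return A `hecs_db` object.
#' @export
assign_hecs <- function(cell_matrix, annotation, threshold,
                        species = "synthetic") {
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 1) {
    stop("threshold must be a single number > 1", call. = FALSE)
  }
  stopifnot(is.matrix(cell_matrix), !is.null(rownames(cell_matrix)))
  idx <- match(rownames(cell_matrix), annotation$probe_id)
  entrez <- annotation$entrez_id[idx]
  symbol <- annotation$symbol[idx]
  annotated <- !is.na(entrez)
  if (!any(annotated)) {
    stop("no annotated probes: cannot build a HECS database", call. = FALSE)
  }

  med <- apply(cell_matrix, 1L, stats::median)
  flags <- sweep(cell_matrix, 1L, threshold * med, ">=") & med > 0

  universe <- sort(unique(entrez[annotated]))
  first <- !duplicated(entrez[annotated])
  entrez_to_symbol <- stats::setNames(symbol[annotated][first],
                                      entrez[annotated][first])

  cts <- colnames(cell_matrix)
  signatures <- stats::setNames(lapply(cts, function(ct) {
    sort(unique(entrez[annotated & flags[, ct]]))
  }), cts)

  new_hecs_db(species, threshold, signatures, universe, entrez_to_symbol)
}

#' Per-cell-type signature sizes and their mean
#'
#' @param db A `hecs_db`.
#' @return A list with `sizes` (named integer vector, one entry per cell type,
#'   empty signatures counted as 0) and `mean_size` (unrounded arithmetic
#'   mean).
#' @export
hecs_count_stats <- function(db) {
  stopifnot(inherits(db, "hecs_db"))
  sizes <- lengths(db$signatures)
  list(sizes = sizes, mean_size = mean(sizes))
}

#' Cumulative uniqueness curve of a signature database
#'
#' For each `n` from 1 to the number of cell types, the percentage of distinct
#' signature genes assigned to `n` or fewer cell types. The curve is
#' nondecreasing and reaches 100 at the last `n`; a database where every gene
#' belongs to exactly one cell type is 100% unique already at `n = 1`.
#'
#' @param db A `hecs_db` with at least one signature gene.
#' @return A data frame with columns `n` and `cumulative_pct`.
#' @export
cumulative_uniqueness <- function(db) {
  stopifnot(inherits(db, "hecs_db"))
  genes <- unlist(db$signatures, use.names = FALSE)
  if (length(genes) == 0L) {
    stop("database has no HECS genes; uniqueness is undefined", call. = FALSE)
  }
  counts <- table(genes)  # gene -> number of cell types it is assigned to
  total <- length(counts)
  ns <- seq_len(length(db$signatures))
  cum <- vapply(ns, function(n) 100 * sum(counts <= n) / total, 0)
  data.frame(n = ns, cumulative_pct = cum)
}

#' Pairwise signature sharing between cell types
#'
#' Percentage of HECS genes shared by each pair of cell types. With the
#' `overlap` coefficient the denominator is the smaller signature,
#' `100 * |A n B| / min(|A|, |B|)`; with `jaccard` it is the union. Any pair
#' involving an empty signature scores 0.
#'
#' @param db A `hecs_db`.
#' @param method `"overlap"` (default) or `"jaccard"`.
#' @return A symmetric matrix (cell types x cell types, sorted labels) with
#'   entries in `[0, 100]`, diagonal 100 for non-empty signatures, and
#'   attributes `method` and `mean_offdiag` (mean of the off-diagonal
#'   entries).
#' @export
pairwise_sharing <- function(db, method = c("overlap", "jaccard")) {
  stopifnot(inherits(db, "hecs_db"))
  method <- match.arg(method)
  cts <- sort(names(db$signatures))
  k <- length(cts)
  m <- matrix(0, k, k, dimnames = list(cts, cts))
  for (i in seq_len(k)) {
    a <- db$signatures[[cts[i]]]
    for (j in i:k) {
      b <- db$signatures[[cts[j]]]
      if (length(a) == 0L || length(b) == 0L) {
        v <- 0
      } else {
        inter <- length(intersect(a, b))
        denom <- if (method == "overlap") min(length(a), length(b))
                 else length(union(a, b))
        v <- 100 * inter / denom
      }
      m[i, j] <- m[j, i] <- v
    }
  }
  attr(m, "method") <- method
  attr(m, "mean_offdiag") <- if (k > 1L) mean(m[upper.tri(m)]) else NA_real_
  m
}
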