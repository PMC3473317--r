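# Weighted ranking of enrichment results across multiple gene lists.
# Because Fisher p-values depend strongly on list size, scores from lists of
# different length are not directly comparable; scaling each list's top
# scores by that list's maximum puts all lists on a common [0, 1] axis.

#' Weighted-rank matrix for multi-list comparison
#'
#' For each list: keep the `top_m` highest-scoring cell types (ties at the
#' boundary resolved by cell-type label, so exactly `top_m` survive), drop any
#' with score below `min_score`, then divide the surviving scores by the
#' list's overall maximum score. The rows are assembled into a union matrix:
#' entries for cell types excluded from a list are `NA` (serialized as empty
#' fields, never 0, so consumers can tell "excluded" from "score 0"). A list
#' whose every score falls below `min_score` keeps an all-`NA` row.
#'
#' @param results A list of [enrich()] results (a single result is accepted).
#' @param top_m Number of top cell types retained per list (default 10).
#' @param min_score Minimum enrichment score retained (default 2, i.e.
#'   adjusted p below 0.01).
#' @return An object of class `weighted_rank_matrix`: a numeric matrix, rows =
#'   list names, columns = the union of selected cell types ordered by
#'   descending column maximum then label, entries in `(0, 1]` or `NA`;
#'   attributes `top_m` and `min_score`.
#' @export
weighted_rank <- function(results, top_m = 10L, min_score = 2) {
  if (inherits(results, "enrichment_result")) results <- list(results)
  stopifnot(length(results) >= 1L,
            all(vapply(results, inherits, TRUE, "enrichment_result")))
  selected <- lapply(results, function(res) {
    ord <- order(-res$score, res$cell_type)
    top <- res[ord, , drop = FALSE][seq_len(min(top_m, nrow(res))), ]
    top <- top[top$score >= min_score, , drop = FALSE]
    if (nrow(top) == 0L) return(stats::setNames(numeric(0), character(0)))
    stats::setNames(top$score / max(res$score), top$cell_type)
  })
  list_names <- vapply(results, attr, "", "list_name")
  cols <- sort(unique(unlist(lapply(selected, names))))
  m <- matrix(NA_real_, nrow = length(results), ncol = length(cols),
              dimnames = list(list_names, cols))
  for (i in seq_along(selected)) {
    m[i, names(selected[[i]])] <- selected[[i]]
  }
  if (ncol(m) > 1L) {
    colmax <- apply(m, 2L, max, na.rm = TRUE)
    m <- m[, order(-colmax, colnames(m)), drop = FALSE]
  }
  structure(m, top_m = top_m, min_score = min_score,
            class = c("weighted_rank_matrix", class(m)))
}

#' @export
print.weighted_rank_matrix <- function(x, ...) {
  cat("Weighted-rank matrix: ", nrow(x), " list(s) x ", ncol(x),
      " cell type(s) (top ", attr(x, "top_m"), ", min score ",
      attr(x, "min_score"), ")\n", sep = "")
  y <- x
  attributes(y) <- attributes(y)[c("dim", "dimnames")]
  print(round(y, 3))
  invisible(x)
}

#' Write a weighted-rank matrix as TSV (heatmap-ready)
#'
#' Excluded entries are written as empty fields.
#'
#' @param wrm A `weighted_rank_matrix`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_weighted_rank <- function(wrm, path) {
  stopifnot(inherits(wrm, "weighted_rank_matrix"))
  df <- data.frame(list = rownames(wrm), as.data.frame(unclass(wrm)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_report(df, path,
                   header = c(paste0("top_m: ", attr(wrm, "top_m")),
                              paste0("min_score: ", attr(wrm, "min_score"))))
}
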