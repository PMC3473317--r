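# Scoring a gene list against every cell type of a HECS database:
# one-sided Fisher's exact (hypergeometric tail) test, Benjamini-Hochberg
# adjustment across cell types, enrichment score = -log10(adjusted p).

# Largest representable score: -log10 of the smallest positive double is
# about 323.6; adjusted p-values that underflow to 0 are capped here so that
# scores stay finite and sortable.
SCORE_CAP <- 320

#' Upper tail of the hypergeometric distribution
#'
#' `P(X >= k)` where `X` counts the signature genes in a uniform draw of `n`
#' genes from a universe of `N` containing `K` signature genes — the p-value
#' of the one-sided Fisher's exact test for enrichment. Computed through the
#' numerically stable distribution-function routine of [stats::phyper()];
#' `k = 0` spans the whole support and returns exactly 1.
#'
#' @param k Overlap count(s), `|list ∩ signature|`.
#' @param K Signature size(s) within the universe.
#' @param n Mapped list size(s).
#' @param N Universe size(s).
#' @return Probability vector, same length as the recycled arguments.
#' @export
hypergeom_tail <- function(k, K, n, N) {
  arg <- cbind(k = k, K = K, n = n, N = N)  # recycles to common length
  k <- arg[, "k"]; K <- arg[, "K"]; n <- arg[, "n"]; N <- arg[, "N"]
  if (any(k < 0 | K < 0 | n < 0 | N < 0)) {
    stop("contingency counts must be non-negative", call. = FALSE)
  }
  if (any(K > N) || any(n > N)) {
    stop("signature and list sizes cannot exceed the universe", call. = FALSE)
  }
  if (any(k > pmin(K, n))) {
    stop("overlap k cannot exceed min(K, n)", call. = FALSE)
  }
  unname(ifelse(k == 0, 1,
                stats::phyper(k - 1, m = K, n = N - K, k = n,
                              lower.tail = FALSE)))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Classic step-up false discovery rate control:
#' `adj_(i) = min(1, min_{j >= i} p_(j) * m / j)` over the ascending order
#' statistics, mapped back to the input order.
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Enrichment of a gene list across every cell type of a database
#'
#' The list is first restricted to the database's gene universe (symbol lists
#' are translated through the database's annotation). For each cell type a
#' 2x2 contingency table is formed from the overlap `k` between the mapped
#' list (size `n`) and the signature (size `K`) against the universe (size
#' `N`); the one-sided Fisher p-value is [hypergeom_tail()]; adjustment is
#' Benjamini-Hochberg across the cell types of this list only — multi-list
#' sessions never pool p-values. The enrichment score is `-log10(p_adj)`,
#' capped at 320 when the adjusted p-value underflows to zero.
#'
#' @param gl A [gene_list()].
#' @param db A `hecs_db`.
#' @return An object of class `enrichment_result`: a data frame with one row
#'   per cell type, columns `cell_type`, `k`, `K`, `n`, `N`, `p_raw`, `p_adj`,
#'   `score`, sorted by score descending with ties broken by cell-type label;
#'   attributes `list_name` and `n_mapped`.
#' @export
enrich <- function(gl, db) {
  stopifnot(inherits(gl, "gene_list"), inherits(db, "hecs_db"))
  mapped <- map_list_to_universe(gl, db)
  if (length(mapped) == 0L) {
    stop("No genes found in the database (list '", gl$name, "')",
         call. = FALSE)
  }
  N <- length(db$universe)
  n <- length(mapped)
  cts <- names(db$signatures)
  K <- lengths(db$signatures)
  k <- vapply(db$signatures, function(sig) sum(mapped %in% sig), 1L)
  p_raw <- hypergeom_tail(k, K, n, N)
  p_adj <- bh_adjust(p_raw)
  score <- ifelse(p_adj > 0, pmin(-log10(p_adj), SCORE_CAP), SCORE_CAP)
  out <- data.frame(cell_type = cts, k = unname(k), K = unname(K),
                    n = n, N = N, p_raw = unname(p_raw),
                    p_adj = unname(p_adj), score = unname(score),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$cell_type), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, list_name = gl$name, n_mapped = n,
            class = c("enrichment_result", "data.frame"))
}

#' @export
print.enrichment_result <- function(x, n = 10L, ...) {
  cat("Enrichment of list '", attr(x, "list_name"), "' (",
      attr(x, "n_mapped"), " genes mapped, universe ", x$N[1L], ")\n",
      sep = "")
  print.data.frame(utils::head(as.data.frame(x), n), digits = 4)
  if (nrow(x) > n) cat("... and", nrow(x) - n, "more cell types\n")
  invisible(x)
}

#' Write an enrichment result as a TSV table
#'
#' @param result An `enrichment_result`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_enrichment <- function(result, path) {
  stopifnot(inherits(result, "enrichment_result"))
  write_tsv_report(as.data.frame(result), path,
                   header = c(paste0("list: ", attr(result, "list_name")),
                              paste0("n_mapped: ", attr(result, "n_mapped"))))
}
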