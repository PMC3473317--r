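# Independent oracles and in-code fixtures shared across the suite.
# Oracles deliberately use different code paths from the package:
# closed-form combinatorics, literal draw enumeration, and per-instance
# classification loops.

# Hypergeometric upper tail by summing the pmf written straight from the
# counting formula: P(X >= k) = sum_j C(K,j) C(N-K,n-j) / C(N,n).
oracle_hyper_tail <- function(k, K, n, N) {
  js <- seq.int(k, min(K, n))
  if (k > min(K, n)) return(0)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# The same tail by literally enumerating every size-n draw from an urn of N
# balls of which the first K are "signature", and counting draws with >= k
# signature balls. Only feasible for small N.
oracle_hyper_tail_enum <- function(k, K, n, N) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)
  mean(hits >= k)
}

# Benjamini-Hochberg step-up written directly from the formula:
# adj_(i) = min(1, min_{j >= i} p_(j) * m / j) over ascending order.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  p_sorted <- p[ord]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[i] <- min(1, min(p_sorted[i:m] * m / (i:m)))
  }
  out <- numeric(m)
  out[ord] <- adj
  out
}

# ROC rates by classifying every (list, cell type) instance at every cutoff
# in an explicit double loop.
oracle_roc_rates <- function(scores, positive, thresholds) {
  tpr <- fpr <- numeric(length(thresholds))
  for (t in seq_along(thresholds)) {
    tp <- fp <- fn <- tn <- 0L
    for (i in seq_len(nrow(scores))) {
      for (j in seq_len(ncol(scores))) {
        pred <- scores[i, j] >= thresholds[t]
        if (positive[i, j] && pred) tp <- tp + 1L
        if (positive[i, j] && !pred) fn <- fn + 1L
        if (!positive[i, j] && pred) fp <- fp + 1L
        if (!positive[i, j] && !pred) tn <- tn + 1L
      }
    }
    tpr[t] <- tp / (tp + fn)
    fpr[t] <- fp / (fp + tn)
  }
  list(tpr = tpr, fpr = fpr)
}

# A hand-written 3-probe x 4-sample atlas: 2 cell types x 2 replicates.
tiny_atlas <- function() {
  values <- matrix(c(40, 44, 2, 2,
                     3, 5, 3, 5,
                     1, 1, 30, 34),
                   nrow = 3, byrow = TRUE,
                   dimnames = list(c("P1", "P2", "P3"),
                                   c("A_R1", "A_R2", "B_R1", "B_R2")))
  ann <- data.frame(probe_id = c("P1", "P2", "P3"),
                    entrez_id = c("101", "102", "103"),
                    symbol = c("GA", "GB", "GC"),
                    stringsAsFactors = FALSE)
  sct <- c(A_R1 = "A", A_R2 = "A", B_R1 = "B", B_R2 = "B")
  expression_atlas(values, sct, ann, "synthetic")
}

# Build a database with prescribed signatures and universe by writing the
# on-disk format and reading it back (also exercises the serialization).
db_from_signatures <- function(signatures, universe,
                               species = "synthetic", threshold = 15) {
  path <- tempfile(fileext = ".tsv")
  on.exit(unlink(path))
  header <- c(paste0("# species: ", species),
              paste0("# threshold: ", threshold),
              paste0("# universe_size: ", length(universe)),
              paste0("# cell_types: ", paste(names(signatures), collapse = "|")))
  rows <- character(0)
  for (ct in names(signatures)) {
    for (g in signatures[[ct]]) rows <- c(rows, paste(ct, g, paste0("G", g), sep = "\t"))
  }
  for (g in setdiff(universe, unlist(signatures))) {
    rows <- c(rows, paste("", g, paste0("G", g), sep = "\t"))
  }
  writeLines(c(header, "cell_type\tentrez_id\tsymbol", rows), path)
  read_hecs_db(path)
}

# Entrez-typed labelled list for rank evaluation / ROC fixtures.
labelled_list <- function(name, ids, truth) {
  gl <- gene_list(name, ids, "entrez")
  attr(gl, "truth") <- truth
  gl
}
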