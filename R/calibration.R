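# Validation machinery: expression-ranked test lists with known truth, rank
# evaluation, ROC curves over (list, cell type) instances with bootstrap
# confidence intervals, robustness sweeps over the signature threshold, and
# gamma-based null calibration from random gene lists.

#' Build labelled test lists from the top k% most highly expressed probes
#'
#' For each requested cell type and percentage `k`, ranks all probes by that
#' cell type's replicate-averaged expression (descending; ties broken by
#' probe id), takes the top `ceiling(k/100 * n_probes)` probes, maps them to
#' Entrez ids through the annotation and deduplicates. Unannotated probes
#' compete for the top slots but contribute no gene, so the final list can be
#' smaller than the probe count. The generating cell type is recorded as the
#' list's truth label.
#'
#' @param cell_matrix Probes x cell types matrix from [average_replicates()].
#' @param annotation Probe annotation data frame.
#' @param percents Numeric vector of percentages `k`, each in `(0, 100)`.
#' @param cell_types Cell types to build lists for; default all columns.
#' @return A list of [gene_list()] objects (Entrez-typed) named
#'   `"<cell_type>_top<k>"`, each with attributes `truth` and `percent`.
#' @export
make_test_lists <- function(cell_matrix, annotation, percents = 5,
                            cell_types = NULL) {
  stopifnot(is.matrix(cell_matrix))
  if (any(percents <= 0 | percents >= 100)) {
    stop("percents must lie strictly between 0 and 100", call. = FALSE)
  }
  if (is.null(cell_types)) cell_types <- colnames(cell_matrix)
  stopifnot(all(cell_types %in% colnames(cell_matrix)))
  idx <- match(rownames(cell_matrix), annotation$probe_id)
  entrez <- annotation$entrez_id[idx]
  np <- nrow(cell_matrix)
  out <- list()
  for (ct in cell_types) {
    ord <- order(-cell_matrix[, ct], rownames(cell_matrix))
    for (k in percents) {
      n_top <- ceiling(k / 100 * np)
      ids <- entrez[ord[seq_len(n_top)]]
      ids <- unique(ids[!is.na(ids)])
      gl <- gene_list(sprintf("%s_top%g", ct, k), ids, id_type = "entrez")
      attr(gl, "truth") <- ct
      attr(gl, "percent") <- k
      out[[gl$name]] <- gl
    }
  }
  out
}

#' Evaluate whether enrichment ranks each test list's true cell type first
#'
#' Runs [enrich()] on every labelled test list and reports the top `r` cell
#' types per list plus a hit indicator: whether the truth label (or any
#' member of its truth group, when `truth_group` is supplied — useful when a
#' cell type's stimulation states should count as correct) holds rank 1.
#'
#' @param test_lists Labelled lists from [make_test_lists()] (each must carry
#'   a `truth` attribute).
#' @param db A `hecs_db`.
#' @param r Number of top cell types reported per list (default 3; truncated
#'   to the number of cell types).
#' @param truth_group Optional named list mapping a truth label to the set of
#'   cell-type labels accepted as correct; default exact match.
#' @return A list of class `rank_evaluation`: `ranks` (long data frame with
#'   columns `list_name`, `truth`, `rank`, `cell_type`, `score`) and `hits`
#'   (data frame with columns `list_name`, `truth`, `top1`, `hit`), plus the
#'   overall `hit_rate`.
#' @export
rank_evaluation <- function(test_lists, db, r = 3L, truth_group = NULL) {
  stopifnot(length(test_lists) >= 1L)
  ranks <- list()
  hits <- list()
  for (gl in test_lists) {
    truth <- attr(gl, "truth")
    if (is.null(truth)) stop("test list '", gl$name, "' has no truth label",
                             call. = FALSE)
    res <- enrich(gl, db)
    rr <- min(r, nrow(res))
    top <- res[seq_len(rr), ]
    ranks[[gl$name]] <- data.frame(list_name = gl$name, truth = truth,
                                   rank = seq_len(rr),
                                   cell_type = top$cell_type,
                                   score = top$score,
                                   stringsAsFactors = FALSE)
    accepted <- if (!is.null(truth_group) && truth %in% names(truth_group)) {
      truth_group[[truth]]
    } else {
      truth
    }
    hits[[gl$name]] <- data.frame(list_name = gl$name, truth = truth,
                                  top1 = top$cell_type[1L],
                                  hit = top$cell_type[1L] %in% accepted,
                                  stringsAsFactors = FALSE)
  }
  ranks <- do.call(rbind, ranks)
  hits <- do.call(rbind, hits)
  rownames(ranks) <- rownames(hits) <- NULL
  structure(list(ranks = ranks, hits = hits, hit_rate = mean(hits$hit)),
            class = "rank_evaluation")
}

#' @export
print.rank_evaluation <- function(x, ...) {
  cat("Rank evaluation: ", nrow(x$hits), " lists, truth ranked first in ",
      sum(x$hits$hit), " (", round(100 * x$hit_rate, 1), "%)\n", sep = "")
  invisible(x)
}

#' Score matrix for a set of labelled test lists
#'
#' Runs [enrich()] on every list and gathers the scores into a lists x cell
#' types matrix together with the per-list truth labels — the input shape
#' [roc_curve()] and [bootstrap_ci()] consume.
#'
#' @param test_lists Labelled lists (each carrying a `truth` attribute).
#' @param db A `hecs_db`.
#' @return A list with `scores` (numeric matrix, rows named by list) and
#'   `truth` (named character vector).
#' @export
score_table <- function(test_lists, db) {
  cts <- names(db$signatures)
  m <- matrix(NA_real_, length(test_lists), length(cts),
              dimnames = list(vapply(test_lists, function(g) g$name, ""), cts))
  truth <- character(length(test_lists))
  for (i in seq_along(test_lists)) {
    res <- enrich(test_lists[[i]], db)
    m[i, res$cell_type] <- res$score
    truth[i] <- attr(test_lists[[i]], "truth")
  }
  names(truth) <- rownames(m)
  list(scores = m, truth = truth)
}

#' ROC curve over (list, cell type) instances
#'
#' Every (list, cell type) pair is an instance; it is positive when the cell
#' type matches the list's truth label (or lies in its truth group). At each
#' score cutoff `s` an instance is predicted positive when its enrichment
#' score is at least `s`. TPR and FPR are computed per cutoff and the AUC by
#' the trapezoidal rule over the (FPR, TPR) points anchored at (0,0) and
#' (1,1).
#'
#' @param scores Numeric matrix, lists x cell types, of enrichment scores.
#' @param truth Named character vector (names = list names) of truth labels,
#'   or a named list of accepted label sets per list.
#' @param thresholds Score cutoffs; evaluated in descending order.
#' @return An object of class `roc_result`: list with `thresholds` (sorted
#'   descending), `tpr`, `fpr`, `auc` and `ci` (`NULL` until
#'   [bootstrap_ci()] is attached).
#' @export
roc_curve <- function(scores, truth,
                      thresholds = c(0, 0.5, 1, 1.5, 2, 3, 5, 7, 10, 15, 20,
                                     25, 30, 40, 50, 75, 100, 150, 200, 320)) {
  pos <- positive_matrix(scores, truth)
  thresholds <- sort(unique(thresholds), decreasing = TRUE)
  rates <- roc_rates(scores, pos, thresholds)
  auc <- roc_auc(rates$fpr, rates$tpr)
  structure(list(thresholds = thresholds, tpr = rates$tpr, fpr = rates$fpr,
                 auc = auc, ci = NULL),
            class = "roc_result")
}

# Logical lists x cell types matrix marking positive instances.
positive_matrix <- function(scores, truth) {
  if (is.character(truth)) truth <- as.list(truth)
  if (is.null(names(truth))) {
    stop("truth must be named by list", call. = FALSE)
  }
  truth <- truth[rownames(scores)]
  labs <- unique(unlist(truth))
  missing <- setdiff(labs, colnames(scores))
  if (length(missing) > 0L) {
    stop("truth label(s) absent from score columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  pos <- matrix(FALSE, nrow(scores), ncol(scores),
                dimnames = dimnames(scores))
  for (i in seq_len(nrow(scores))) {
    pos[i, truth[[i]]] <- TRUE
  }
  pos
}

roc_rates <- function(scores, pos, thresholds) {
  np <- sum(pos)
  nn <- sum(!pos)
  tpr <- fpr <- numeric(length(thresholds))
  for (i in seq_along(thresholds)) {
    pred <- scores >= thresholds[i]
    tpr[i] <- if (np > 0L) sum(pred & pos) / np else NA_real_
    fpr[i] <- if (nn > 0L) sum(pred & !pos) / nn else NA_real_
  }
  list(tpr = tpr, fpr = fpr)
}

roc_auc <- function(fpr, tpr) {
  x <- c(0, fpr, 1)
  y <- c(0, tpr, 1)
  ord <- order(x, y)
  x <- x[ord]; y <- y[ord]
  sum(diff(x) * (utils::head(y, -1L) + utils::tail(y, -1L)) / 2)
}

#' @export
print.roc_result <- function(x, ...) {
  cat("ROC over ", length(x$thresholds), " cutoffs: AUC = ",
      round(x$auc, 4), "\n", sep = "")
  invisible(x)
}

#' Percentile bootstrap confidence intervals for an ROC curve
#'
#' Resamples the lists (rows) with replacement — not the individual
#' instances, which are dependent within a list — recomputes TPR and FPR at
#' every cutoff, and takes the 2.5/97.5 percentiles. Deterministic given the
#' seed.
#'
#' @inheritParams roc_curve
#' @param B Number of bootstrap resamples (at least 100).
#' @param seed RNG seed.
#' @param level Confidence level (default 0.95).
#' @return A data frame with columns `threshold`, `tpr_lo`, `tpr_hi`,
#'   `fpr_lo`, `fpr_hi`.
#' @export
bootstrap_ci <- function(scores, truth, thresholds, B = 1000L, seed = 1L,
                         level = 0.95) {
  if (B < 100L) stop("B must be at least 100", call. = FALSE)
  if (nrow(scores) < 2L) {
    stop("bootstrap needs at least 2 lists", call. = FALSE)
  }
  pos <- positive_matrix(scores, truth)
  thresholds <- sort(unique(thresholds), decreasing = TRUE)
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  with_seed(seed, {
    tprs <- fprs <- matrix(NA_real_, B, length(thresholds))
    for (b in seq_len(B)) {
      rows <- sample.int(nrow(scores), replace = TRUE)
      r <- roc_rates(scores[rows, , drop = FALSE],
                     pos[rows, , drop = FALSE], thresholds)
      tprs[b, ] <- r$tpr
      fprs[b, ] <- r$fpr
    }
    data.frame(threshold = thresholds,
               tpr_lo = apply(tprs, 2L, stats::quantile, probs[1L], na.rm = TRUE),
               tpr_hi = apply(tprs, 2L, stats::quantile, probs[2L], na.rm = TRUE),
               fpr_lo = apply(fprs, 2L, stats::quantile, probs[1L], na.rm = TRUE),
               fpr_hi = apply(fprs, 2L, stats::quantile, probs[2L], na.rm = TRUE))
  })
}

#' Robustness of enrichment performance to the signature threshold
#'
#' Rebuilds the signature database at each requested threshold, generates
#' sampled test lists from the top `percent`% most highly expressed genes of
#' every cell type (list sizes drawn uniformly from `size_range`, capped at
#' the pool size, `n_repeats` lists per cell type), and computes an ROC per
#' threshold. A threshold too strict to yield any signature surfaces as an
#' error entry for that threshold rather than aborting the sweep.
#'
#' @param atlas An [expression_atlas].
#' @param thresholds Fold thresholds to rebuild the database at (each > 1).
#' @param percent Top-expression percentage defining each cell type's gene
#'   pool (default 10).
#' @param n_repeats Sampled lists per cell type (default 3).
#' @param size_range Range of sampled list sizes (default 500 to 4000; capped
#'   at the pool size).
#' @param score_cutoffs Score cutoffs handed to [roc_curve()].
#' @param seed RNG seed for the list sampling.
#' @return A named list (one element per threshold, names `"t<threshold>"`),
#'   each either an `roc_result` or a `condition` captured for that
#'   threshold; class `threshold_sweep`.
#' @export
threshold_sweep <- function(atlas, thresholds, percent = 10, n_repeats = 3L,
                            size_range = c(500L, 4000L),
                            score_cutoffs = c(0, 0.5, 1, 1.5, 2, 3, 5, 7, 10,
                                              15, 20, 25, 30, 40, 50, 75, 100,
                                              150, 200, 320),
                            seed = 1L) {
  stopifnot(inherits(atlas, "expression_atlas"))
  if (any(thresholds <= 1)) stop("all thresholds must exceed 1", call. = FALSE)
  cm <- average_replicates(atlas)
  ann <- atlas$probe_annotation

  # one pool of candidate genes per cell type: top percent% probes, mapped
  pools <- make_test_lists(cm, ann, percents = percent)
  out <- stats::setNames(vector("list", length(thresholds)),
                         paste0("t", thresholds))
  with_seed(seed, {
    lists <- list()
    for (pool in pools) {
      sizes <- size_range[1L] - 1L +
        sample.int(size_range[2L] - size_range[1L] + 1L, n_repeats,
                   replace = TRUE)
      sizes <- pmin(sizes, length(pool$ids))
      for (j in seq_len(n_repeats)) {
        gl <- gene_list(sprintf("%s_s%d", pool$name, j),
                        sample(pool$ids, sizes[j]), id_type = "entrez")
        attr(gl, "truth") <- attr(pool, "truth")
        lists[[gl$name]] <- gl
      }
    }
    for (i in seq_along(thresholds)) {
      out[[i]] <- tryCatch({
        db <- assign_hecs(cm, ann, thresholds[i], species = atlas$species)
        if (all(lengths(db$signatures) == 0L)) {
          stop("empty database: no HECS genes at threshold ", thresholds[i],
               call. = FALSE)
        }
        st <- score_table(lists, db)
        roc_curve(st$scores, st$truth, score_cutoffs)
      }, error = function(e) e)
    }
  })
  structure(out, class = "threshold_sweep")
}

#' @export
print.threshold_sweep <- function(x, ...) {
  for (nm in names(x)) {
    if (inherits(x[[nm]], "roc_result")) {
      cat(nm, ": AUC = ", round(x[[nm]]$auc, 4), "\n", sep = "")
    } else {
      cat(nm, ": error: ", conditionMessage(x[[nm]]), "\n", sep = "")
    }
  }
  invisible(x)
}

#' Quantile of the zero-inflated gamma null score distribution
#'
#' The null enrichment-score distribution is modelled as a point mass at zero
#' (fraction `zero_fraction`) mixed with a gamma on the positive scores. The
#' returned score `q` solves
#' `zero_fraction + (1 - zero_fraction) * F_gamma(q) = alpha`; when the atom
#' alone already reaches `alpha`, the quantile is 0.
#'
#' @param shape,scale Gamma parameters (shape-scale parameterization).
#' @param zero_fraction Proportion of null scores exactly zero.
#' @param alpha Target cumulative probability (default 0.95).
#' @return Non-negative score quantile.
#' @export
null_score_quantile <- function(shape, scale, zero_fraction = 0,
                                alpha = 0.95) {
  stopifnot(shape > 0, scale > 0, zero_fraction >= 0, zero_fraction <= 1,
            alpha > 0, alpha < 1)
  if (zero_fraction >= alpha) return(0)
  stats::qgamma((alpha - zero_fraction) / (1 - zero_fraction),
                shape = shape, scale = scale)
}

#' Calibrate the null distribution of enrichment scores with random lists
#'
#' Draws `n_lists` random gene lists from the database universe (sizes
#' uniform in `size_range`), scores each against every cell type, and pools
#' all resulting enrichment scores. The pooled scores are summarized by the
#' fraction that are exactly zero and a gamma distribution fit by maximum
#' likelihood to the strictly positive scores; zeros are folded back in
#' through the mixture quantile [null_score_quantile()], giving the score a
#' random list exceeds with probability `1 - alpha`.
#'
#' @param db A `hecs_db`.
#' @param n_lists Number of random lists (default 150).
#' @param size_range List size range (default 100 to 400).
#' @param alpha Cumulative probability for the calibrated score cutoff
#'   (default 0.95).
#' @param seed RNG seed.
#' @return An object of class `null_calibration`: list with `shape`, `scale`,
#'   `zero_fraction`, `score_at_alpha`, `alpha`, `n_scores`, `seed`. When
#'   every pooled score is zero the gamma fit is skipped (parameters `NA`)
#'   with a warning and `score_at_alpha` is 0.
#' @export
null_calibration <- function(db, n_lists = 150L, size_range = c(100L, 400L),
                             alpha = 0.95, seed = 1L) {
  stopifnot(inherits(db, "hecs_db"))
  if (size_range[2L] > length(db$universe)) {
    stop("size_range exceeds the universe size", call. = FALSE)
  }
  lists <- generate_random_lists(db$universe, n_lists, size_range, seed = seed)
  scores <- unlist(lapply(lists, function(gl) enrich(gl, db)$score),
                   use.names = FALSE)
  zero_fraction <- mean(scores == 0)
  pos <- scores[scores > 0]
  if (length(pos) == 0L) {
    warning("all pooled null scores are zero; no gamma fit performed")
    return(structure(list(shape = NA_real_, scale = NA_real_,
                          zero_fraction = 1, score_at_alpha = 0,
                          alpha = alpha, n_scores = length(scores),
                          seed = seed),
                     class = "null_calibration"))
  }
  fit <- fit_gamma_mle(pos)
  q <- null_score_quantile(fit$shape, fit$scale, zero_fraction, alpha)
  structure(list(shape = fit$shape, scale = fit$scale,
                 zero_fraction = zero_fraction, score_at_alpha = q,
                 alpha = alpha, n_scores = length(scores), seed = seed),
            class = "null_calibration")
}

# Gamma MLE (shape/scale) via MASS::fitdistr, started from the method of
# moments; falls back to the moment estimates if the optimizer fails.
fit_gamma_mle <- function(x) {
  stopifnot(all(x > 0))
  m <- mean(x); v <- stats::var(x)
  start <- list(shape = max(m^2 / v, 1e-3), rate = max(m / v, 1e-3))
  fit <- tryCatch(
    MASS::fitdistr(x, "gamma", start = start, lower = c(1e-8, 1e-8)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(list(shape = start$shape, scale = 1 / start$rate))
  }
  est <- fit$estimate
  list(shape = unname(est["shape"]), scale = 1 / unname(est["rate"]))
}

#' @export
print.null_calibration <- function(x, ...) {
  cat("Null calibration over ", x$n_scores, " scores: ",
      round(100 * x$zero_fraction, 1), "% zeros; gamma(shape ",
      signif(x$shape, 4), ", scale ", signif(x$scale, 4), "); score at alpha ",
      x$alpha, " = ", signif(x$score_at_alpha, 4), "\n", sep = "")
  invisible(x)
}
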