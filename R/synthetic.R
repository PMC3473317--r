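# Synthetic expression atlases with planted cell-type signatures.
# The generator emulates the structure of the public expression atlases the
# signature databases are built from: a log-normal baseline intensity per
# probe, a small set of probes per cell type raised by a known fold, a few
# biological replicates per cell type with multiplicative noise, genes
# represented by more than one probe, and probes with no gene annotation.
# Ground truth (which gene belongs to which cell type) is returned alongside,
# so every downstream step can be tested for exact recovery.

# Run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards. All stochastic functions in the package route
# their randomness through this, so results are reproducible given a seed
# without clobbering the user's RNG.
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}

#' Specification of a synthetic atlas
#'
#' Defaults describe a compact but structurally faithful atlas: 10 cell types
#' with 2 biological replicates each, 5,000 probes, 100 signature probes per
#' cell type planted at 50-fold over baseline, 10% replicate noise (as a
#' coefficient of variation), 10% of genes carried by two probes and 10% of
#' probes unannotated.
#'
#' @param n_cell_types Number of cell types.
#' @param n_probes Number of probes on the array.
#' @param n_replicates Biological replicates per cell type.
#' @param n_signature_probes_per_cell Probes planted as the signature of each
#'   cell type; `n_signature_probes_per_cell * n_cell_types` must not exceed
#'   `n_probes`.
#' @param signal_fold Planted fold `f > 1` over the probe's baseline.
#' @param baseline_log_mean,baseline_log_sd Log-normal parameters of the
#'   baseline intensity (natural-log scale).
#' @param replicate_noise_cv Coefficient of variation of the multiplicative
#'   (log-normal, mean 1) replicate noise; 0 for a noiseless atlas.
#' @param multi_probe_gene_fraction Fraction of genes represented by two
#'   probes.
#' @param unannotated_fraction Fraction of probes with no gene annotation
#'   (drawn from the non-signature probes).
#' @param shared_signature_fraction Fraction of each cell type's signature
#'   probes also planted in its designated partner (cell types are paired
#'   1-2, 3-4, ...); 0 for fully disjoint signatures.
#' @param seed RNG seed; the generator is fully deterministic given the spec.
#' @return An object of class `synthetic_atlas_spec`.
#' @export
synthetic_atlas_spec <- function(n_cell_types = 10L,
                                 n_probes = 5000L,
                                 n_replicates = 2L,
                                 n_signature_probes_per_cell = 100L,
                                 signal_fold = 50,
                                 baseline_log_mean = log(100),
                                 baseline_log_sd = 1,
                                 replicate_noise_cv = 0.1,
                                 multi_probe_gene_fraction = 0.1,
                                 unannotated_fraction = 0.1,
                                 shared_signature_fraction = 0,
                                 seed = 1L) {
  stopifnot(n_cell_types >= 1L, n_probes >= 1L, n_replicates >= 1L,
            n_signature_probes_per_cell >= 0L,
            signal_fold > 1,
            baseline_log_sd >= 0, replicate_noise_cv >= 0,
            multi_probe_gene_fraction >= 0, multi_probe_gene_fraction <= 1,
            unannotated_fraction >= 0, unannotated_fraction <= 1,
            shared_signature_fraction >= 0, shared_signature_fraction <= 1)
  if (n_signature_probes_per_cell * n_cell_types > n_probes) {
    stop("infeasible: n_signature_probes_per_cell * n_cell_types exceeds ",
         "n_probes", call. = FALSE)
  }
  structure(as.list(environment()), class = "synthetic_atlas_spec")
}

#' Generate a synthetic atlas with planted signatures
#'
#' Baseline intensities are drawn log-normal per probe; each cell type's
#' signature probes are multiplied by `signal_fold` in that cell type's
#' samples (and in the partner cell type's samples for shared probes);
#' replicate noise is multiplicative log-normal with the requested CV and
#' unit mean. The annotation assigns synthetic Entrez-style ids (all-digit
#' strings) and symbols `G<id>`; multi-probe genes pair probes within the
#' same cell type's signature (or within the baseline pool), so the planted
#' gene-level truth is unambiguous. Unannotated probes are drawn from the
#' baseline pool only — planted probes are always annotated.
#'
#' @param spec A [synthetic_atlas_spec()].
#' @return A list with components `atlas` (an [expression_atlas]) and `truth`
#'   (class `ground_truth`: `planted`, a named list mapping each cell type to
#'   its signature gene ids; `probe_gene`, the annotation data frame; `fold`,
#'   the per-probe planted fold).
#' @export
generate_atlas <- function(spec) {
  stopifnot(inherits(spec, "synthetic_atlas_spec"))
  with_seed(spec$seed, {
    nct <- spec$n_cell_types
    np <- spec$n_probes
    nsig <- spec$n_signature_probes_per_cell
    probes <- sprintf("P%05d", seq_len(np))
    cts <- sprintf("CT%02d", seq_len(nct))

    # partition a random draw of probes into per-cell-type signatures
    sig_idx <- if (nsig > 0L) sample.int(np, nsig * nct) else integer(0)
    sig_of <- stats::setNames(
      lapply(seq_len(nct), function(i) sig_idx[seq_len(nsig) + (i - 1L) * nsig]),
      cts)
    baseline_idx <- setdiff(seq_len(np), sig_idx)

    # per-probe x per-cell-type planted fold
    fold <- matrix(1, np, nct, dimnames = list(probes, cts))
    for (ct in cts) fold[sig_of[[ct]], ct] <- spec$signal_fold
    n_shared <- round(spec$shared_signature_fraction * nsig)
    if (n_shared > 0L && nct >= 2L) {
      for (i in seq(1L, nct - 1L, by = 2L)) {
        a <- cts[i]; b <- cts[i + 1L]
        fold[sig_of[[a]][seq_len(n_shared)], b] <- spec$signal_fold
        fold[sig_of[[b]][seq_len(n_shared)], a] <- spec$signal_fold
      }
    }

    baseline <- stats::rlnorm(np, spec$baseline_log_mean, spec$baseline_log_sd)
    means <- baseline * fold  # probes x cell types

    cv <- spec$replicate_noise_cv
    sdlog <- sqrt(log1p(cv^2))
    sample_ids <- as.vector(t(outer(cts, seq_len(spec$n_replicates),
                                    function(c, r) sprintf("%s_R%d", c, r))))
    sample_ct <- rep(cts, each = spec$n_replicates)
    values <- matrix(0, np, length(sample_ids),
                     dimnames = list(probes, sample_ids))
    for (j in seq_along(sample_ids)) {
      noise <- if (cv > 0) stats::rlnorm(np, -sdlog^2 / 2, sdlog) else 1
      values[, j] <- means[, sample_ct[j]] * noise
    }

    # annotation: unannotated probes come from the baseline pool
    n_unann <- round(spec$unannotated_fraction * np)
    if (n_unann > length(baseline_idx)) {
      stop("infeasible: unannotated_fraction leaves too few baseline probes",
           call. = FALSE)
    }
    unann_idx <- if (n_unann > 0L) sample(baseline_idx, n_unann) else integer(0)

    # gene assignment per stratum (each signature, then the baseline pool):
    # with multi-probe fraction g, d two-probe genes among m probes satisfies
    # d = round(g * m / (1 + g)), leaving m - d genes in the stratum
    gene_of <- rep(NA_character_, np)
    next_id <- 100001L
    assign_genes <- function(idx) {
      m <- length(idx)
      if (m == 0L) return(invisible())
      d <- round(spec$multi_probe_gene_fraction * m / (1 + spec$multi_probe_gene_fraction))
      d <- min(d, m %/% 2L)
      n_genes <- m - d
      ids <- as.character(seq(next_id, length.out = n_genes))
      next_id <<- next_id + n_genes
      assignment <- c(seq_len(n_genes), seq_len(d))  # first d genes get 2 probes
      gene_of[idx] <<- ids[assignment]
      invisible()
    }
    for (ct in cts) assign_genes(sig_of[[ct]])
    assign_genes(setdiff(baseline_idx, unann_idx))

    ann <- data.frame(probe_id = probes,
                      entrez_id = gene_of,
                      symbol = ifelse(is.na(gene_of), NA_character_,
                                      paste0("G", gene_of)),
                      stringsAsFactors = FALSE)

    sct <- stats::setNames(sample_ct, sample_ids)
    atlas <- expression_atlas(values, sct, ann, species = "synthetic")

    planted <- stats::setNames(lapply(cts, function(ct) {
      sort(unique(gene_of[which(fold[, ct] > 1)]))
    }), cts)
    truth <- structure(list(planted = planted,
                            probe_gene = ann,
                            fold = fold),
                       class = "ground_truth")
    list(atlas = atlas, truth = truth)
  })
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("Ground truth: ", length(x$planted), " cell types, ",
      length(unique(unlist(x$planted))), " planted genes\n", sep = "")
  invisible(x)
}

#' Write ground truth as a TSV table
#'
#' Long format, columns `cell_type`, `entrez_id`.
#'
#' @param truth A `ground_truth` object.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  df <- do.call(rbind, lapply(names(truth$planted), function(ct) {
    g <- truth$planted[[ct]]
    if (length(g) == 0L) return(NULL)
    data.frame(cell_type = ct, entrez_id = g, stringsAsFactors = FALSE)
  }))
  write_tsv_report(df, path)
}

#' Random gene lists drawn from a universe
#'
#' Each list samples its size uniformly within `size_range` and then draws
#' that many ids from `universe` uniformly without replacement. Used for null
#' calibration and false-positive-rate assessment.
#'
#' @param universe Character vector of Entrez ids to draw from.
#' @param n_lists Number of lists.
#' @param size_range Length-2 integer vector `(min, max)` of list sizes;
#'   `max` must not exceed the universe size.
#' @param seed RNG seed.
#' @return A list of [gene_list()] objects (Entrez-typed) named
#'   `"random001"`, `"random002"`, ...
#' @export
generate_random_lists <- function(universe, n_lists, size_range = c(100L, 400L),
                                  seed = 1L) {
  stopifnot(length(size_range) == 2L, size_range[1L] >= 1L,
            size_range[1L] <= size_range[2L])
  if (size_range[2L] > length(universe)) {
    stop("size_range exceeds the universe size", call. = FALSE)
  }
  with_seed(seed, {
    sizes <- size_range[1L] - 1L +
      sample.int(size_range[2L] - size_range[1L] + 1L, n_lists, replace = TRUE)
    lapply(seq_len(n_lists), function(i) {
      gene_list(sprintf("random%03d", i), sample(universe, sizes[i]),
                id_type = "entrez")
    })
  })
}
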