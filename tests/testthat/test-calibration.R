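# Test-list construction, rank evaluation, ROC machinery, threshold sweeps
# and the gamma null calibration.

test_that("top-k% test lists take ceil(k% of probes) before gene mapping", {
  g <- generate_atlas(synthetic_atlas_spec(n_cell_types = 2L, n_probes = 1000L,
                                           n_signature_probes_per_cell = 20L,
                                           multi_probe_gene_fraction = 0,
                                           unannotated_fraction = 0, seed = 3L))
  cm <- average_replicates(g$atlas)
  ann <- g$atlas$probe_annotation
  tl <- make_test_lists(cm, ann, percents = 5, cell_types = "CT01")
  # all probes annotated, one gene per probe: list size equals probe count
  expect_length(tl[[1]]$ids, 50L)
  expect_identical(attr(tl[[1]], "truth"), "CT01")
  expect_identical(attr(tl[[1]], "percent"), 5)

  # 2 cell types x percents 2..10 -> 18 lists; 10 cell types would give 90
  tl9 <- make_test_lists(cm, ann, percents = 2:10)
  expect_length(tl9, 18L)

  # multi-probe genes shrink the list after mapping
  g2 <- generate_atlas(synthetic_atlas_spec(n_cell_types = 2L,
                                            n_probes = 1000L,
                                            n_signature_probes_per_cell = 20L,
                                            multi_probe_gene_fraction = 0.5,
                                            unannotated_fraction = 0,
                                            seed = 3L))
  cm2 <- average_replicates(g2$atlas)
  tl2 <- make_test_lists(cm2, g2$atlas$probe_annotation, percents = 5,
                         cell_types = "CT01")
  expect_lt(length(tl2[[1]]$ids), 50L)

  expect_error(make_test_lists(cm, ann, percents = 0), "strictly between")
  expect_error(make_test_lists(cm, ann, percents = 100), "strictly between")
})

test_that("test-list sizes are nonincreasing as the percentile shrinks", {
  g <- generate_atlas(synthetic_atlas_spec(n_cell_types = 3L, n_probes = 500L,
                                           n_signature_probes_per_cell = 15L,
                                           seed = 17L))
  cm <- average_replicates(g$atlas)
  tl <- make_test_lists(cm, g$atlas$probe_annotation, percents = c(10, 5, 2),
                        cell_types = "CT02")
  sizes <- lengths(lapply(tl, `[[`, "ids"))
  expect_true(all(diff(unname(sizes[c("CT02_top2", "CT02_top5",
                                      "CT02_top10")])) >= 0))
  # no randomness: regenerating gives identical lists
  tl_again <- make_test_lists(cm, g$atlas$probe_annotation,
                              percents = c(10, 5, 2), cell_types = "CT02")
  expect_identical(tl, tl_again)
})

test_that("rank evaluation finds planted signatures and honours truth groups", {
  db <- db_from_signatures(list(A = as.character(1:20),
                                B = as.character(21:40),
                                B_stim = as.character(21:45)),
                           universe = as.character(1:200))
  lists <- list(labelled_list("la", as.character(1:20), "A"),
                labelled_list("lb", as.character(21:40), "B"))
  re <- rank_evaluation(lists, db, r = 2L)
  expect_identical(re$hits$top1[re$hits$list_name == "la"], "A")
  expect_true(re$hits$hit[1])

  # lb's exact signature also sits inside B_stim; whichever state ranks
  # first, the truth group accepts both
  reg <- rank_evaluation(lists, db, r = 2L,
                         truth_group = list(B = c("B", "B_stim")))
  expect_true(all(reg$hits$hit))
  expect_equal(reg$hit_rate, 1)

  # r beyond the number of cell types returns all of them
  r_all <- rank_evaluation(lists[1], db, r = 10L)
  expect_identical(nrow(r_all$ranks), 3L)
})

test_that("ROC separates the separable case and matches the brute-force oracle", {
  scores <- matrix(c(30, 1, 1,
                     1, 30, 1,
                     1, 1, 30,
                     30, 1, 1), nrow = 4, byrow = TRUE,
                   dimnames = list(paste0("l", 1:4), c("A", "B", "C")))
  truth <- c(l1 = "A", l2 = "B", l3 = "C", l4 = "A")
  cuts <- c(0, 0.5, 2, 10, 25, 40)
  r <- roc_curve(scores, truth, cuts)
  expect_equal(r$auc, 1)
  i10 <- which(r$thresholds == 10)
  expect_equal(r$tpr[i10], 1)
  expect_equal(r$fpr[i10], 0)
  # cutoff above the global maximum predicts nothing
  i40 <- which(r$thresholds == 40)
  expect_equal(r$tpr[i40], 0)
  expect_equal(r$fpr[i40], 0)
  # lowering the cutoff never decreases either rate
  expect_true(all(diff(r$tpr) >= 0) && all(diff(r$fpr) >= 0))

  set.seed(55)
  noisy <- matrix(stats::runif(60, 0, 30), nrow = 10,
                  dimnames = list(paste0("l", 1:10), paste0("C", 1:6)))
  truth_n <- stats::setNames(sample(colnames(noisy), 10, replace = TRUE),
                             rownames(noisy))
  cuts_n <- c(0, 1, 2, 5, 10, 15, 20, 25, 30)
  rn <- roc_curve(noisy, truth_n, cuts_n)
  pos <- matrix(FALSE, 10, 6, dimnames = dimnames(noisy))
  for (i in 1:10) pos[i, truth_n[i]] <- TRUE
  orc <- oracle_roc_rates(noisy, pos, sort(cuts_n, decreasing = TRUE))
  expect_equal(rn$tpr, orc$tpr, tolerance = 1e-12)
  expect_equal(rn$fpr, orc$fpr, tolerance = 1e-12)

  expect_error(roc_curve(scores, c(l1 = "D", l2 = "B", l3 = "C", l4 = "A")),
               "absent from score columns")
})

test_that("scores independent of the truth give near-chance AUC", {
  aucs <- vapply(1:5, function(s) {
    set.seed(s)
    scores <- matrix(stats::runif(40 * 20, 0, 10), nrow = 40,
                     dimnames = list(paste0("l", 1:40), paste0("C", 1:20)))
    truth <- stats::setNames(sample(colnames(scores), 40, replace = TRUE),
                             rownames(scores))
    roc_curve(scores, truth, seq(0, 10, by = 0.5))$auc
  }, 0)
  expect_lt(abs(mean(aucs) - 0.5), 0.1)
})

test_that("bootstrap intervals are seed-deterministic and bracket the point", {
  set.seed(202)
  scores <- matrix(stats::runif(15 * 5, 0, 30), nrow = 15,
                   dimnames = list(paste0("l", 1:15), paste0("C", 1:5)))
  truth <- stats::setNames(sample(colnames(scores), 15, replace = TRUE),
                           rownames(scores))
  cuts <- c(0, 2, 10, 20)
  ci1 <- bootstrap_ci(scores, truth, cuts, B = 200L, seed = 31L)
  ci2 <- bootstrap_ci(scores, truth, cuts, B = 200L, seed = 31L)
  expect_identical(ci1, ci2)
  r <- roc_curve(scores, truth, cuts)
  expect_true(all(ci1$tpr_lo - 1e-12 <= r$tpr & r$tpr <= ci1$tpr_hi + 1e-12))
  expect_true(all(ci1$fpr_lo - 1e-12 <= r$fpr & r$fpr <= ci1$fpr_hi + 1e-12))

  # a table whose rows are all identical has zero-width intervals
  flat <- matrix(rep(c(10, 1, 1), each = 6), nrow = 6,
                 dimnames = list(paste0("l", 1:6), c("A", "B", "C")))
  truth_f <- stats::setNames(rep("A", 6), rownames(flat))
  cif <- bootstrap_ci(flat, truth_f, cuts, B = 150L, seed = 1L)
  expect_true(all(cif$tpr_hi - cif$tpr_lo == 0))
  expect_true(all(cif$fpr_hi - cif$fpr_lo == 0))

  expect_error(bootstrap_ci(scores, truth, cuts, B = 50L), "at least 100")
  expect_error(bootstrap_ci(scores[1, , drop = FALSE], truth[1], cuts,
                            B = 200L), "at least 2 lists")
})

test_that("threshold sweeps share lists across thresholds and flag empties", {
  g <- generate_atlas(synthetic_atlas_spec(n_cell_types = 4L, n_probes = 800L,
                                           n_signature_probes_per_cell = 25L,
                                           seed = 41L))
  sw <- threshold_sweep(g$atlas, c(10, 15), percent = 10, n_repeats = 2L,
                        size_range = c(20L, 60L), seed = 77L)
  expect_named(sw, c("t10", "t15"))
  expect_s3_class(sw$t15, "roc_result")

  # a single-threshold sweep under the same seed reproduces the same ROC
  solo <- threshold_sweep(g$atlas, 15, percent = 10, n_repeats = 2L,
                          size_range = c(20L, 60L), seed = 77L)
  expect_equal(solo$t15$auc, sw$t15$auc)
  expect_equal(solo$t15$tpr, sw$t15$tpr)

  # a threshold above the planted fold leaves no signatures; the sweep
  # surfaces the error for that threshold without aborting the others
  sw2 <- threshold_sweep(g$atlas, c(15, 200), percent = 10, n_repeats = 2L,
                         size_range = c(20L, 60L), seed = 77L)
  expect_s3_class(sw2$t15, "roc_result")
  expect_s3_class(sw2$t200, "error")
  expect_error(threshold_sweep(g$atlas, c(1, 15)), "exceed 1")
})

test_that("the mixture quantile solves the zero-inflated gamma equation", {
  # exponential special case: qgamma(.95, 1, 1) = -ln(0.05)
  expect_equal(null_score_quantile(1, 1, 0, 0.95), -log(0.05),
               tolerance = 1e-12)
  expect_equal(null_score_quantile(2, 0.5, 0.96, 0.95), 0)
  q <- null_score_quantile(2, 0.5, 0.4, 0.9)
  expect_equal(0.4 + 0.6 * stats::pgamma(q, 2, scale = 0.5), 0.9,
               tolerance = 1e-10)
  # nondecreasing in alpha
  alphas <- c(0.5, 0.8, 0.9, 0.95, 0.99)
  qs <- vapply(alphas, function(a) null_score_quantile(2, 0.5, 0.3, a), 0)
  expect_true(all(diff(qs) >= 0))
})

test_that("null calibration is reproducible and degenerates gracefully", {
  g <- generate_atlas(synthetic_atlas_spec(n_cell_types = 5L, n_probes = 2000L,
                                           n_signature_probes_per_cell = 40L,
                                           seed = 19L))
  cm <- average_replicates(g$atlas)
  db <- assign_hecs(cm, g$atlas$probe_annotation, 15)
  nc1 <- null_calibration(db, n_lists = 40L, size_range = c(50L, 150L),
                          seed = 13L)
  nc2 <- null_calibration(db, n_lists = 40L, size_range = c(50L, 150L),
                          seed = 13L)
  expect_identical(nc1, nc2)
  expect_gt(nc1$shape, 0)
  expect_gt(nc1$scale, 0)
  expect_gte(nc1$score_at_alpha, 0)
  expect_identical(nc1$n_scores, 40L * 5L)

  expect_error(null_calibration(db, size_range = c(100L, 1e6L)),
               "exceeds the universe")
})
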