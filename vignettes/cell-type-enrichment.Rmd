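---
title: "Cell-type enrichment with highly expressed cell-specific gene signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cell-type enrichment with highly expressed cell-specific gene signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellsig)
```

## The problem

Gene expression measured in tissue sampled *in vivo* mixes two very
different signals. A gene's transcript count can rise because cells are
transcribing it more — or because cells that constitutively express it at a
high level have migrated into the sample. In immunological settings this is
the rule rather than the exception: infiltrating lymphocytes and macrophages
carry their own characteristic RNA complements, and a differential-expression
analysis that ignores the changing cell demographics will misread cell
migration as transcriptional regulation.

`cellsig` addresses this by asking, for any user-supplied gene list, whether
the list contains more *highly expressed cell-specific* (HECS) genes of some
cell type than expected by chance. A strong enrichment for one cell type's
signature is evidence that the list reflects that cell type's presence (or
change in abundance) rather than in-situ regulation.

## The signature database

The raw material is an expression atlas: a probes × samples intensity matrix
spanning many purified cell types and tissues, with a small number of
biological replicates per cell type, plus a probe → (Entrez id, symbol)
annotation. Database construction is deliberately simple:

1. **Average replicates.** Each probe's values are averaged over the
   replicates of each cell type, giving a probes × cell-types matrix.
2. **Threshold rule.** Probe $p$ is flagged for cell type $c$ when
   $$x_{pc} \ge t \cdot \operatorname{median}_{c'} x_{pc'},$$
   with the median taken across *all* cell types. The comparison is
   inclusive ("at least $t$-fold") and the boundary case is tested
   explicitly. $t$ is the database's one tunable parameter (dimensionless
   fold); the reference microarray atlases in this field use $t = 15$
   (mouse) and $t = 10$ (human), a balance between signature size and
   signature uniqueness.
3. **Gene mapping.** A gene is a HECS gene of $c$ if *any* of its probes is
   flagged for $c$; a gene reached through several probes is listed once per
   cell type. Genes are keyed by Entrez id; symbols are display metadata.
4. **Universe.** Every annotated gene on the array — flagged or not — forms
   the gene universe, the background of the enrichment test.

Two numerical guards: probes whose median across cell types is zero are
excluded from flagging ($t \times 0 = 0$ would otherwise flag them wherever
they have any signal), and the median over an even number of cell types is
the usual interior median (mean of the two central order statistics).

The database is characterized by its per-cell-type signature sizes, the
cumulative-uniqueness curve (fraction of signature genes assigned to at most
$n$ cell types), and the pairwise sharing matrix. The sharing denominator is
genuinely underdetermined in the literature this design comes from; we
default to the overlap coefficient
$100\,|A \cap B| / \min(|A|, |B|)$ — which best matches reported sharing
levels between closely related immune-cell states — and expose Jaccard as an
alternative, recording the method in the output.

## The enrichment score

For a gene list restricted to the universe (size $n$), each cell type with
signature size $K$ in a universe of size $N$ and overlap $k$ is scored with
the one-sided Fisher's exact test for enrichment, i.e. the hypergeometric
upper tail $P(X \ge k)$. P-values are Benjamini–Hochberg adjusted across the
cell types *of that list only* — lists of different sizes have incomparable
p-values, so multi-list sessions never pool. The enrichment score is
$-\log_{10}(p_{\mathrm{adj}})$, capped at 320 when the adjusted p-value
underflows to zero (just inside $-\log_{10}$ of the smallest positive
double), keeping scores finite and sortable. Ties in the ranking are broken
by cell-type label so results are reproducible.

The score is a ranking device more than a strict statistic: Fisher p-values
are very sensitive to list size, but the *ordering* of cell types is robust.
For cross-list comparison the **weighted ranking** takes, per list, the 10
most enriched cell types, drops those scoring below 2, and scales the
survivors by the list's maximum score, producing a lists × cell-types matrix
in $(0, 1]$. Excluded entries serialize as empty fields rather than zeros so
a heatmap consumer can distinguish "excluded" from "score 0". The scaling
maximum is the maximum over all cell types (equivalently the top-10
maximum). `top_m = 10` and `min_score = 2` are configurable defaults.

## Validation machinery

* **Test lists.** For each cell type and percentage $k$, the top
  $\lceil k/100 \cdot \text{probes} \rceil$ most highly expressed probes
  (ties broken by probe id) are mapped to genes and deduplicated, giving a
  labelled list whose true cell type is known. The ceiling guarantees a
  non-empty list on small atlases.
* **Rank evaluation** scores each test list and asks whether the true cell
  type ranks first. An optional truth-group map accepts, say, a cell type's
  stimulation states as correct.
* **ROC.** Instances are all (list, cell type) pairs — the only reading
  under which a false-positive rate across many lists and many cell types
  is meaningful. An instance is predicted positive at cutoff $s$ when its
  score is $\ge s$; the AUC is the trapezoid over the (FPR, TPR) points
  anchored at (0,0) and (1,1). Confidence intervals come from a percentile
  bootstrap over *lists* (not instances, which are dependent within a
  list); the resampling is seed-deterministic.
* **Threshold sweep.** The database is rebuilt at several $t$; test lists
  are subsamples (3 per cell type, sizes uniform between 500 and 4000) of
  each cell type's top-10% gene pool, shared across all thresholds so the
  comparison isolates $t$. On the desk-scale synthetic atlas the per-cell
  pool (~450 genes) is smaller than the nominal size range, so sampled
  sizes are capped at the pool size.
* **Null calibration.** Random lists (150 lists of 100–400 ids drawn
  uniformly without replacement from the universe) are scored and all
  cell-type scores pooled. Pooled scores are summarized as a point mass at
  zero (fraction $z$) plus a gamma fitted by maximum likelihood to the
  strictly positive scores (method-of-moments start); the calibrated score
  cutoff solves $z + (1 - z) F_{\Gamma}(q) = \alpha$, with $q = 0$ when the
  atom alone reaches $\alpha$. Pooling all cell-type scores (rather than
  each list's maximum) is a design choice; excluding exact zeros from the
  gamma fit and folding them back through the mixture quantile avoids
  fitting a continuous density to an atom.

## The synthetic atlas generator

Every claim above is testable without external data because the generator
plants known structure: a log-normal baseline intensity per probe
(`meanlog = log 100`, `sdlog = 1`, a realistic several-decade intensity
spread); per cell type, a block of signature probes multiplied by a known
fold; multiplicative log-normal replicate noise with unit mean and a chosen
coefficient of variation (multiplicative so non-negativity is structural);
a fraction of genes carried by two probes (probes of one gene stay within
one cell type's signature stratum, keeping gene-level truth unambiguous);
a fraction of unannotated probes (drawn from non-signature probes, so
planted truth remains recoverable); and optionally a fraction of signature
probes shared between designated cell-type pairs.

The reference conditions — the generator defaults used throughout the tests
and the acceptance script — are 10 cell types × 2 replicates, 5,000 probes,
100 signature probes per cell type at 50-fold, noise CV 0.1, 10% two-probe
genes, 10% unannotated probes. Gene ids are synthetic digit strings (so they
pass Entrez validation) with symbols `G<id>`.

What the generator does *not* emulate: microarray physics (probe affinity,
background correction, normalization artifacts), correlated noise between
probes, realistic signature-size heterogeneity, or the annotation ambiguity
of real platforms (a symbol maps to exactly one synthetic gene). Passing
tests therefore demonstrate correctness of the algorithms under the planted
model, not performance on any particular public atlas.

One structural caveat worth knowing: because the threshold rule is
median-based, a probe planted in $m$ of $C$ cell types stops being
flaggable once $m$ approaches $C/2$ (the median itself rises). With shared
signatures this matters for small $C$ — a probe shared by a designated pair
is only recoverable when $C \ge 6$ or so — and it is the mechanism by which
the rule enforces cell-specificity in the first place.

## Choices made where the design was open

* **Sharing denominator**: overlap coefficient by default, Jaccard
  selectable; neither claims to reproduce any externally reported sharing
  figure exactly.
* **Multi-list upload dialects**: a `long` (list-name, id) and a `wide`
  (one column per list) format with configurable separator; blank cells in
  the wide format are skipped, matching spreadsheet paste-in behaviour.
  A historical 20-list session cap from the original web deployment is not
  enforced — it was a server constraint, not a method constraint.
* **Symbol matching** is case-insensitive (upper-cased on both sides);
  Entrez ids must be all-digit strings and match exactly.
* **Plain hypergeometric tails** (no mid-p correction) — the standard
  Fisher test.
* **Exit codes** in the command-line front end: 0 success, 2
  usage/parameter, 3 data/format, 4 empty-result conditions.

## Problem sizes

The test suite and the acceptance script run entirely on synthetic atlases
of the reference size (5,000 probes, 10 cell types) or smaller; the
exhaustive hypergeometric check covers every instance with universe size
≤ 25 against a combinatorial oracle; bootstrap checks use a few hundred
resamples. These sizes were chosen so that a complete verification run
finishes in well under a minute while still exercising every code path at
meaningful scale.

## Limitations

* Identifier translation is limited to the supplied annotation table; there
  is no symbol ↔ Entrez service, and platform files (CEL, vendor CSVs) are
  out of scope — users supply extracted matrices.
* Enrichment is one-sided (enrichment only); depletion is not scored.
* The enrichment score should be read as a ranking; its absolute value
  depends strongly on list size. The null calibration gives a principled
  minimum score for a given false-positive tolerance, and a score of 2 is a
  reasonable floor for lists of a few hundred genes.
```
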