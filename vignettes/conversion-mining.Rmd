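---
title: "Mining direct cell-conversion transcriptomes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining direct cell-conversion transcriptomes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(convmine)
```

## The problem

Direct conversion (transdifferentiation) experiments reprogram one somatic
cell type into another by forced transcription-factor expression. Public
repositories hold many small, heterogeneous expression series for such
conversions — often one to four datasets per conversion, sometimes with a
single sample per group. `convmine` implements a meta-analysis recipe for
this situation: score each dataset separately, then let *agreement across
independent datasets*, rather than any per-dataset statistic, carry the
inferential weight. Its outputs are the gene lists and networks such studies
report: a common signature shared by all conversions from one origin cell, a
conversion-specific signature per target cell type, the differentially
expressed transcription factors (DE-TFs) whose binding targets are
over-represented among the differential genes, a directed gene regulatory
network (GRN) per conversion with hub TFs ranked by out-degree, ontology-term
enrichment, and uncentered-correlation clustergrams.

## Per-dataset differential expression

Each dataset is a genes × samples matrix of pre-normalized linear-scale
intensities with an origin/target group label per sample. For each gene:

* **fold change** — ratio of the target-group mean to the origin-group mean
  on the linear scale. Group means are floored at a pseudocount of
  $10^{-6}\times$ the global matrix median so that ratios stay finite on
  sparse input; the floor is far below any realistic intensity and never
  binds on well-behaved data.
* **p-value** — Welch's unequal-variance two-sample $t$ test on $\log_2$
  intensities. Welch is the least-assumption two-group default: it does not
  require equal variances, and on log scale the multiplicative microarray
  noise model becomes approximately additive Gaussian. No per-dataset
  multiple-testing correction is applied; the raw 0.05 threshold is
  deliberately permissive because cross-dataset voting (below) is the
  robustness mechanism, and correcting per dataset would starve the vote.
* **direction call** — `up` if $p \le 0.05$ and the fold change is above 1,
  `down` if below, otherwise `none`.

Several real conversion series have one sample per group, where no $t$ test
exists. Such genes are flagged untestable, and the default
`single_sample_mode = "fc_only"` calls direction by fold-change magnitude
$\ge$ 1.5 alone (the `strict` mode refuses to call them at all). A
fold-change-only path must exist because single-sample series are a real and
common part of these study designs; the mode is explicit in the thresholds
object so the choice is always visible.

Direction calls are invariant to positive rescaling of the matrix, and
swapping the group labels inverts fold changes and calls while leaving
p-values unchanged — both enforced by tests.

## Consensus voting

All downstream analysis operates on the *direction table*: genes × datasets
matrix of `up`/`down`/`none` calls, with a parallel fold-change matrix.
A vote rule has three parts: `min_same` (how many datasets must agree),
`forbid_opposite` (whether a single opposite call vetoes), and an optional
`fc_min` gate that every *supporting* dataset must pass. Non-supporting
datasets are exempt from the gate — the closest reading of "differential in
at least $m$ of $n$ datasets with fold change more than 1.5".

Two standing rules:

* **within-conversion merge** — $(n-1)$-of-$n$ with the opposite-call veto
  (so 2-of-3 and 3-of-4 for the usual replicate counts); single-dataset
  conversions pass their calls through.
* **common signature** — $(n-1)$-of-$n$ across *all* datasets of the study
  (8-of-9 for the canonical nine-dataset fibroblast panel), plus a strict
  tier that additionally applies `fc_min = 1.5` to every supporter.

The opposite-call veto defaults to on for the common vote as well. The
alternative (tolerating one opposite call) admits genes that are strongly
*specific* to a single-dataset conversion — up at home, down in the eight
other datasets — into the "common" list, which contradicts both the
biological reading of a shared initiation signature and the generator's
ground truth, where common and specific sets are disjoint. The veto-free
variant remains one flag away (`common_forbid_opposite = FALSE`) for
sensitivity analysis.

When `min_same` is small enough that both directions could qualify, the gene
is returned as `none`: a tie is evidence of inconsistency, not of either
direction.

## Conversion-specific signatures

A gene is *specific* to a conversion when it is in that conversion's merged
DEG list, shows the **opposite** direction in at least `min_opposite` of the
other conversions' datasets, and shows the **identical** direction in at most
`max_identical = 2` of them — the exception tolerance that absorbs
cross-hybridizing probes and borderline calls without abandoning
exclusivity. `none` calls count toward neither bound, since both bounds are
phrased as counts of expressed patterns. By default `min_opposite` resolves
to (number of other datasets − 2). Note `max_identical` is an allowance, not
a requirement, so feasibility only requires `min_opposite` ≤ the number of
other datasets; the canonical rule (7 opposite, up to 2 identical, 8–9
others) is legal under this reading. The home conversion's supporting
datasets must each pass the 1.5 fold-change gate.

Two properties follow and are enforced by tests: specific lists of different
conversions are pairwise disjoint whenever `max_identical < min_opposite`,
and the lists respond monotonically to both knobs.

## TF regulons, GRNs and hub ranking

Given a TF → bound-targets database (a ChIP-derived regulon collection,
carried as GMT), each conversion's DEG list is tested per TF with the
one-sided (over-representation) hypergeometric tail
$P(X \ge \text{overlap})$ over the universe of database genes intersected
with the measured genes. One-sided is the right test here: a regulon's
*depletion* among DEGs is not evidence that the TF drives the conversion.
TFs with raw $p < 0.05$ whose own conversion-level fold change (geometric
mean across the conversion's datasets) has magnitude $\ge 1.5$ are the
DE-TFs. A Holm-adjusted column is emitted alongside for the user, but the
flag follows the raw threshold, mirroring the permissive-per-stage /
consensus-across-stages philosophy. The TF's own direction (up or down) is
kept as a node annotation — down-regulated regulators are first-class
citizens — but does not affect edge construction.

The GRN has an edge from every DE-TF to each of its regulon members in the
DEG list (self-loops only when the TF is itself a DEG); the *core network*
restricts edges to DE-TF → DE-TF pairs, exposing the hierarchy among the
regulators. Hubs are ranked by out-degree — the number of regulated DEG
targets — with alphabetical tie-breaking for determinism; the headline
reporting convention is the top five. Cross-study agreement of a TF's
targets (e.g. human vs mouse versions of a conversion) is summarized as the
fraction of targets called in both studies that agree in direction.

## Ontology enrichment

Term enrichment uses the **two-sided** hypergeometric test in the
twice-the-smaller-tail convention,
$p = \min(1,\, 2\min(P(X \ge k), P(X \le k)))$, with the
minimum-likelihood-sum alternative behind `method = "minlik"` for
sensitivity checks. Across all terms of a database queried with one gene
list, p-values receive Holm's step-down correction (via
`stats::p.adjust(method = "holm")`), and terms are flagged at adjusted
$p < 0.05$: a correction is named, so the significance call uses the
corrected value; the raw column is also reported.

## Clustering

Clustergrams use the classic microarray recipe: similarity is the
**uncentered correlation** $\sum x_i y_i / (\lVert x\rVert\,\lVert y\rVert)$
(cosine form, no mean-centering — the absolute up/down pattern matters, and
a flat profile is perfectly self-similar), distance $1 - s$, and
agglomerative **average linkage** (the common default of the classic
clustering tools; single and complete are available). Ties in the minimum
distance are broken toward the smallest cluster-index pair, so results are
bit-reproducible. The clustered input is the genes × datasets $\log_2$
fold-change matrix of the common signature — matching the red/green
up-down display convention — and results export as CDT/GTR file pairs for
TreeView-style viewers. All-zero rows are rejected (no direction to
compare); join heights are recorded as computed, without enforcing
monotonicity, although average linkage on these distances cannot invert.

## The synthetic study generator

The generator is first-class, tested code: it defines the study conditions
under which the pipeline is validated. Defaults emulate a nine-dataset,
five-conversion fibroblast panel:

| parameter | default | meaning |
|---|---|---|
| `n_genes` | 5000 | genes per dataset |
| `conversions` | 5 with 1/1/3/1/3 datasets | nine datasets total |
| `replicates_per_group` | 3 | per origin/target group |
| `common_up` / `common_down` | 20 / 25 | shared signature, same sign everywhere |
| `specific_per_conversion` | 15 | home sign at home, opposite sign elsewhere |
| `effect_log2` | 2.0 | planted \|log2 FC\| |
| `noise_sd_log2` | 0.5 | per-sample Gaussian noise, log2 scale |
| `baseline_log2_mean/sd` | 7 / 2 | baseline expression distribution |
| TF regulons | 1 master/conversion, size 80, half from the DEG pool | plus 15 decoy TFs with neutral regulons |

Noise is i.i.d. Gaussian on the log2 scale (log-normal intensities), the
standard microarray error model. Specific genes are planted with the
*opposite* sign away from home — not flat — so the specificity rule's
opposite-pattern branch is genuinely exercised. Master TFs are planted
up-regulated in their home conversion only; decoy TFs and decoy ontology
terms are drawn independently of the truth so that enrichment gates face
realistic negatives. Identical seeds give bit-identical studies; the
generator restores the caller's RNG state.

What the generator does **not** emulate: batch effects, probe saturation,
platform-specific intensity distributions, correlated noise between genes,
and annotation noise across species. Passing tests therefore demonstrate
that the algorithms recover what they are designed to recover under the
stated noise model — not that any particular real GEO series would yield
the same lists.

In the noiseless limit every stage recovers the planted truth exactly (a
test asserts F1 = 1.0 end to end). Under the default noise, per-dataset
detection power of a planted gene is about 0.88, so the 8-of-9 common vote
retains roughly 72–78% of the shared signature with essentially perfect
precision (F1 ≈ 0.84–0.88 across seeds) — an inherent property of stacking
nine ~0.88 Bernoulli gates, discussed honestly rather than patched by
inflating the planted effect. Specific signatures (which need agreement in
fewer places) land at F1 ≈ 0.89–0.97, DE-TF recovery is near-perfect, and
planted master regulators top the out-degree ranking.

## Numerical and interface choices

* Gene symbols are uppercased on ingest so mouse and human symbols unify;
  duplicate symbols (multi-probe genes) collapse by row mean with a logged
  warning — the collapse policy is a documented choice, as no standard
  exists.
* Zero-variance genes in the Welch test take the limit values ($p = 1$ for
  equal means, $p = 0$ otherwise), which is what makes the noiseless limit
  exact rather than undefined.
* The enrichment universe defaults to the regulon/term database universe
  intersected with the measured genes, configurable.
* Writers sort everything they emit (GMT sets and members, SIF edges,
  manifest paths), so outputs are byte-stable and reruns with the same
  configuration and seed produce identical checksums (`tools::md5sum` over
  every artifact, recorded in a JSON manifest).
* Problem sizes used by the test suite: exhaustive hypergeometric sweeps to
  universe size 12, exhaustive vote enumeration to 6 datasets, brute-force
  clustering oracles at 4–6 items × 100 instances, and synthetic studies at
  400–5000 genes — sizes at which exhaustive oracles are exact and the whole
  suite runs in well under a minute per file.

## Known limitations

* P-values from 1-vs-1 datasets do not exist; the fold-change-only fallback
  is a pragmatic, clearly-flagged substitute, not a statistical test.
* No effect-size meta-analysis (random-effects pooling, Fisher's method):
  voting is the design, by intent, and fold-change heterogeneity between
  platforms is only addressed by the per-dataset gates.
* The per-dataset raw $p < 0.05$ stage is anti-conservative in isolation;
  single-dataset conversions therefore carry more false positives into
  their (unvoted) DEG lists than multi-dataset ones. This mirrors the
  study design being modeled; treat single-dataset DEG lists accordingly.
* Ontology analysis is a plain two-sided hypergeometric per term: no GO
  graph topology, term fusion, or kappa grouping.
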