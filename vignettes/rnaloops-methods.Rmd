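---
title: "Regulatory loop inference from drug-response transcriptomics: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regulatory loop inference from drug-response transcriptomics: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnaloops)
library(data.table)
```

## The analysis in one paragraph

`rnaloops` implements a systems-level workflow for asking how a
perturbation — in the motivating application, temozolomide chemotherapy of
glioblastoma stem-like cells — reorganizes regulatory relationships among
transcription factors (TFs), miRNAs, mRNAs and long non-coding RNAs
(lncRNAs). Public regulator–target catalogs (ChIP-seq derived TF–target
tables, CLIP-derived miRNA–target tables, predicted miRNA–lncRNA pairs) are
merged into one large directed background network, the *RNA interactome*.
Per-condition differential-expression (DE) calls are thresholded by biotype
and mapped onto this background; the induced subgraph over DE genes is the
condition-specific subnetwork. Within each subnetwork the package
enumerates three-node feed-forward loops (FFLs), derives shared-miRNA
competing-endogenous-RNA (ceRNA) candidates, and prioritizes
loop-associated lncRNAs by expression presence, co-expression
guilt-by-association with pathway over-representation, and a median-split
log-rank survival screen.

## The background interactome

Associations arrive as five tab-separated edge classes — TF→mRNA,
TF→lncRNA, TF→miRNA, miRNA→mRNA, miRNA→lncRNA — each row a binary
"regulates" statement with a source-database label. Assembly
(`build_interactome()`) deduplicates on the (source, target) pair and keeps
the union of evidence databases per edge; regulations are treated as
unweighted, because the upstream catalogs make binary claims and the
downstream motif logic is purely structural.

Two conventions matter:

* **TF registry relabeling.** TF-coding genes appear in gene-level tables
  as ordinary mRNA targets. Any id listed in the TF registry is relabeled
  to biotype TF wherever it occurs, which is what turns miRNA→mRNA records
  into the miRNA→TF edges required by miRNA-mediated and mixed loops. A
  registry id that an edge file declares to be a lncRNA or miRNA is a hard
  error rather than a silent overwrite.
* **Opaque identifiers.** Ids are namespaced strings; no cross-database
  identifier mapping is attempted. Reconciling RefSeq/miRBase/Ensembl
  annotation is upstream curation, not part of this method.

## Differential-expression thresholds

A record enters a condition's DE set when `fdr < fdr_max` and the absolute
fold change strictly exceeds the biotype threshold: by default 2 for
mRNAs/TFs and 1.5 for miRNAs and lncRNAs, with `fdr_max = 0.05`. Both
inequalities are strict, so a record sitting exactly at a threshold is
excluded. The `fc_scale` option states whether the thresholds are compared
on the log2 scale (`|log2FC| > t`, the default) or on the linear scale
(`2^|log2FC| > t`): published descriptions of such filters alternate
between "fold change > 2" and "log FC > 2", and a single configuration
flag is the honest way to support both readings without guessing which
one a given input table intends.

## Subnetworks, loops and ceRNA triples

The subnetwork of a condition is the induced subgraph: background edges
with both endpoints DE, plus every DE gene as a node even when isolated.
Extraction is deliberately *pure* — an optional expression-correlation
filter on edges exists (`corr_min`), but it is off by default because
dropping edges on an unstated correlation threshold would silently change
every downstream count. Edge signs (stimulatory/inhibitory) are annotated
from the Pearson correlation of endpoint expression when a matrix is
supplied; miRNA-source edges without expression default to inhibitory,
reflecting the repressive mechanism of miRNA regulation.

`enumerate_ffls()` classifies each (TF, miRNA, target) triple with both
regulator→target edges present:

| type | regulator connection |
|---|---|
| `tf_mediated` | TF→miRNA only |
| `mirna_mediated` | miRNA→TF only |
| `mixed` | TF→miRNA and miRNA→TF |

Classification is **exclusive** by default: a mutually regulated pair
yields one `mixed` motif per target and is not additionally counted under
the one-way types, so the three type counts partition the motif set — the
natural reading of reports that quote the three counts side by side. The
alternative (a mutual triple also reported under both one-way types) is
available with `exclusive = FALSE`. Targets are restricted to mRNA and
lncRNA biotypes, which also guarantees the three motif nodes are distinct.
The implementation is a join over co-targeting pairs; its correctness is
established in the test suite against an independent brute-force triple
scan over hundreds of random typed graphs.

ceRNA candidates (`find_cerna()`) are structural: every (miRNA, lncRNA,
mRNA) with both miRNA→lncRNA and miRNA→mRNA edges in the subnetwork,
restricted by default to miRNAs that participate in FFLs. No
expression-correlation requirement is imposed on the lncRNA–mRNA pair —
the sponging hypothesis here rests on shared interactions — but the pair
correlation is attached as an annotation column when a matrix is supplied.

## Prioritizing lncRNAs

* `expressed_in_all()` keeps candidates detected (above `min_value`, by
  default 0) in every sample.
* `correlate_lncrna_mrna()` ranks mRNAs per lncRNA by `|r|` (Pearson by
  default, Spearman available). The default selection is the top 200
  mRNAs; no principled universal threshold exists for "associated", so the
  rule is a documented, configurable default rather than a hidden
  constant.
* `hypergeometric_ora()` computes the exact one-sided hypergeometric tail
  for each gene set and applies Benjamini–Hochberg correction across sets;
  BH is the standard choice where the multiple-testing procedure is
  otherwise unspecified. The top 10 pathways per lncRNA are reported.
* `survival_screen()` splits a cohort at the median expression of a gene
  (ties to the low group, a fixed deterministic policy), runs the log-rank
  test via `survival::survdiff`, and reports the observed/expected
  hazard-ratio approximation `HR = (O_hi/E_hi)/(O_lo/E_lo)`. This matches
  the log-rank + hazard-ratio reporting style of median-split
  Kaplan–Meier screens without introducing a Cox regression model; it is a
  screen, not an adjusted effect estimate.

## The synthetic-data generator

The generator exists so the entire pipeline can be exercised, validated
and benchmarked with known ground truth and no external data. Its default
configuration reproduces the study conditions of the motivating analysis:

* a node universe of 107 TFs, 1851 miRNAs, 10,970 lncRNAs and 18,812
  mRNAs;
* a uniform per-class edge density of 0.0196, chosen once so the expected
  background is ≈ 1.15 million regulations over that universe
  (58.5 million possible pairs across the five classes);
* two conditions emulating a strongly responding line (DE fractions
  0.0326/0.0276/0.0188 for mRNA/miRNA/lncRNA — about 614, 51 and 206
  genes at the default universe) and a minimally responding one
  (0.0013/0.0065/0.0001 — about 25, 12 and 1);
* DE statistics drawn to separate cleanly at the module thresholds: DE
  genes get FDR ~ U(0, 0.05) and |log2FC| = threshold + |N(0, 1)|,
  non-DE genes get FDR ~ U(0.05, 1);
* expression as baseline 8 plus unit Gaussian noise, with planted ceRNA
  partners loading (weight 2) on a shared latent factor, giving an
  expected pair correlation of 0.8 at the default noise; values are
  floored at zero, which at these settings is a ~4σ event per cell;
* survival cohorts of 600 with exponential event times (baseline hazard
  0.1 per time unit, censoring uniform on (0, 15), i.e. roughly "months"
  with ~60% event rate) and a default hazard ratio of 2 on the
  high-expression half of effect genes — a typical effect size for a
  prognostic biomarker screen.

Within each edge class, random edges are independent Bernoulli draws
(Erdős–Rényi within the class bipartite structure), sampled exactly as a
binomial edge count followed by uniform distinct pairs. Degree-sequence or
scale-free nulls are out of scope; the generator's job is biotype
structure, not topology realism.

**Planting.** Ground-truth FFLs and ceRNA triples are added on top of the
random background, and their nodes are forced into the first condition's
DE set. Two safeguards make planted loops *stably typed* under exclusive
classification: each planted loop receives its own (TF, miRNA) regulator
pair, and the random draw is pruned of the single reverse regulator edge
that would upgrade a planted one-way loop to mixed. Planted ceRNA miRNAs
are drawn from the planted-loop miRNAs so the triples survive the
loop-miRNA restriction downstream. miRNA→TF regulations — planted or
random — are emitted inside the miRNA→mRNA table with registry ids as
targets, so the TF-relabeling path is exercised by every run.

**What the generator does not emulate.** Counts and read-level noise
(DE statistics are drawn directly, not computed from a count model);
annotation mismatches between databases; correlated DE across conditions;
degree heterogeneity and hub structure of real regulatory catalogs;
confounding between expression and survival beyond the planted effect.
Passing tests on synthetic data therefore demonstrate the *correctness of
the graph and statistical machinery* and recoverability of planted
structure — not robustness to the biological messiness of real catalogs.

## Determinism and numerical choices

Every generator stage derives its RNG stream from the master seed (offsets
0–3), so equal seeds give byte-identical output files. All analysis
outputs are deterministically ordered (edges by ids, motifs by
(tf, mirna, target), hubs by out-degree with lexicographic tie-break).
Constant expression rows are excluded from correlations with a warning
rather than propagating `NA`. A median-split group with zero events is a
degenerate input: the single-gene screen refuses it with an error naming
the gene, and the multi-gene screen reports `NA` with a warning. ORA
p-values use `phyper` tails; equality with explicit combinatorial
enumeration is asserted in tests for universes up to 30.

## Validation problem sizes

The test suite validates motif enumeration against the brute-force scan on
100 random graphs of up to ~50 nodes at mixed densities; planted recovery
on a 135-node universe with 60 planted loops and 10 planted triples;
full-scale generation and assembly once at the default 31,740-node,
~1.15M-edge configuration; log-rank calibration on 500 null cohorts of
n = 60; and effect recovery at n = 400 with hazard ratio 4. These sizes
were chosen as the smallest that make each property's failure modes
visible.

## Limitations

* The interactome is only as good as the association catalogs; the
  package deliberately performs no identifier mapping or lift-over.
* Motif enumeration is restricted to the three 3-node FFL classes; longer
  loops and motif significance testing against degree-preserving
  randomizations are out of scope.
* The ceRNA derivation is structural; it does not model binding-site
  competition or expression stoichiometry.
* The survival screen is univariate and unadjusted; it ranks candidates,
  it does not establish independent prognostic value.
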