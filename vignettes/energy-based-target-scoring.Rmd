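---
title: "Energy-based scoring of microRNA target sites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Energy-based scoring of microRNA target sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirddg)
```

## The model

mirddg treats miRNA-mediated repression as a two-step thermodynamic
process. A stretch of the 3'UTR must first become single-stranded; the
free-energy cost of opening the local mRNA secondary structure is the
*disruption energy*, ΔG_open ≤ 0 (closer to zero = more accessible).
The miRNA then base-pairs with the open site; the free-energy gain of
that binding is the *hybridization energy*, ΔG_H. The overall
favorability of stepwise duplex formation is their difference,

ΔΔG = ΔG_H − ΔG_open,

and lower ΔΔG means a better target. Working with continuous energies
rather than a fixed seed-match rule lets the same score rank canonical
and non-canonical sites on one scale, with no conservation requirement.

### Candidate sites

Scoring every UTR position is too expensive, so candidates are anchored
at a minimal pairing *nucleus*: a perfect 4-nt Watson-Crick match to the
miRNA seed region (positions 2–8; nucleus starts at positions 2–5). G-U
wobbles are treated as mismatches both here and in seed typing — the
point of the nucleus is a committed, maximally stable initiation stretch.
For hybridization the UTR context around the 4-mer is extended by twice
the length of each remaining miRNA arm (mapped antisense, so the miRNA
5' remainder faces the downstream flank), optionally reaching into the
upstream CDS; longer contexts would only accumulate intramolecular
structure that does not describe the binding event. Cofolding is
constrained so the nucleus stays paired; if a backend returns a
structure with nucleus bases unpaired or intramolecular pairs, the
structure is repaired (nucleus enforced, intramolecular pairs removed,
other intermolecular pairs kept) and re-evaluated. Overlapping 4-mer
registers describing the same region are collapsed to the best-ΔΔG
representative, grouping by transitive closure of interval overlap with
deterministic position-order tie-breaks.

### Accessibility

ΔG_open comes from local unpaired probabilities: for every placement of
a u-length open region containing the 4-mer nucleus (17 placements for
an interior site at u = 20), a window of exactly W nt centered on the
region is folded and ΔG_open = RT·ln(P_unpaired) is averaged over
placements. The log is taken before averaging — the expectation of a log
is not the log of an expectation — and the window is extracted at
exactly W nt (shifted inward at sequence ends, shrunk only when the
whole sequence is shorter) so the backend reports the exact open
probability of that single window. Defaults W = 80, L = 40 (maximum
pairing span), u = 20, RT = 0.6163 kcal/mol (37 °C), all exposed in
`thermo_config()`. Whether the open regions should instead slide over
the whole extracted site span is genuinely ambiguous; both readings are
implemented (`windows_over`), with the nucleus reading as default since
the match site is defined by its 4-mer. P_unpaired is floored at 1e-12
before the log; a zero probability is a backend artifact, not physics.

### Seed taxonomy

Each site is also labelled by maximal seed complementarity, in priority
order 8mer > 7mer-A > 7mer > 6mer > 7in8 > 6in8 > 5mer > 5in8 > 4mer:
consecutive Watson-Crick runs within positions 2–8 define the k-mer
classes, 7mer-A is a 7mer plus an adenine opposite position 1, and the
k-in-8 classes count pairs anywhere in positions 1–8 with an adenine
opposite position 1 counted as a pair. Labels feed the stringency
filters (`6mer` keeps canonical classes, `6in8` adds the two relaxed
ones, `4mer` keeps all). UTR positions beyond the sequence ends are
scored as mismatches rather than raising errors, so sites at UTR
boundaries remain classifiable.

## Engines

All folding goes through a three-function engine contract
(`constrained_cofold`, `evaluate`, `unpaired_probability`), so the
energetics backend is pluggable:

* `vienna_engine()` adapts the ViennaRNA executables (RNAcofold with
  hard pair constraints, RNAeval, RNAplfold run at `-W` equal to the
  window length).
* `toy_engine()` is a deterministic pair-counting model: −1.0 kcal/mol
  per intermolecular Watson-Crick pair, −0.5 per G-U, no intramolecular
  structure, constant unpaired probability. It makes every pipeline
  value exactly predictable by hand, which is what the test suite needs.
  Two options extend it for fixtures: `accessibility = "au"` makes
  P_unpaired a deterministic function of the open region's AU content
  (unstructured AU-rich regions are more accessible), and a small
  `position_weight` deepens pairs toward the miRNA 3' end so toy
  energies are not quantized to half-kcal steps.

## The linear expression-change model

Per miRNA–UTR pair, sites collapse into 14 features: best and
second-best ΔΔG, ΔG_H and ΔG_open (best = most favorable, i.e. maximum
for ΔG_open), ΔG_H and ΔG_open at the two best-ΔΔG sites, the three
energy sums, and the UTR length. Genes without sites (or a second site)
get zeros for the affected energy features so every gene stays scorable.

`energy_model()` fits ordinary least squares of observed log2 fold
change on these features, training only on pairs at or below a cutoff
(default 0, i.e. observed down-regulation; −0.1 discards weakly changed
genes that are mostly noise), inside a k-fold cross-validation whose
folds are disjoint at the gene level and pooled across miRNAs. Held-out
performance is summarized by Spearman rank correlation, and predictions
are the per-gene median over the k fold models — the classic
`print`/`summary`/`coef`/`predict`/`residuals`/`plot`/`simulate`
methods all operate on the fitted object.

One property of this feature set deserves emphasis: because
ΔΔG = ΔG_H − ΔG_open holds at every site, three features are exact
linear combinations of the others (`dG_open_at_best_ddG =
dG_H_at_best_ddG − best_ddG`, the same at the second site, and
`sum_dG_open = sum_dG_H − sum_ddG`; see `dependent_feature_names()`).
The design matrix over all 14 features is therefore always
rank-deficient, individual weights for that triple are not identifiable,
and a plain `lm()` fit reports them as aliased. `fit_ols()` keeps all 14
columns, warns, and resolves the degeneracy through the singular-value
pseudoinverse (minimum-norm solution), which leaves *predictions* —
the identifiable quantity — exactly determined. Model comparisons or
coefficient interpretation should use the 11 identifiable features.

## Controls

Null sites come from dinucleotide-shuffled miRNAs: the start base is
drawn from the mononucleotide frequencies, the sequence is extended by a
first-order Markov walk that consumes the input's dinucleotide multiset,
and an attempt is accepted only if the walk placed at least 85% of the
length before leftover bases are inserted at random positions. The walk
additionally tracks a remaining-mononucleotide pool (a dinucleotide is
only consumable while its second base is still available), which is
what guarantees exact composition conservation in every accepted
shuffle; without it, a walk started on a base other than the input's
first base can finish with a different composition. Shuffles whose
positions 2–8 equal a known miRNA seed, or whose positions 1–8 contain
a poly-A motif (AAAAAA, AAUAAA), are rejected and redrawn; "overlap"
with known seeds is read as exact heptamer identity (a stricter
hexamer mode is available via `strict_6mer`). Each accepted shuffle is
paired with UTRs sampled without replacement — 10 shuffles × 10 UTRs
per input miRNA by default — and one match site per control pair is
sampled uniformly as the control site.

## Evaluation

`roc_auc()` sweeps all distinct values as cutoffs; its AUC is the
normalized Mann-Whitney U statistic with ties counted one half.
`rank_sum_test()` is the two-sided Wilcoxon rank-sum with normal
approximation and tie correction. `enrichment_curve()` ranks genes
ascending by score and reports, for top sets growing in 50-gene
increments (final partial set truncated, ties broken by gene id), the
fraction of bona fide targets (observed log2FC at or below a cutoff)
relative to their prevalence; 1 = random, and at N = all genes the
curve is exactly 1 by construction. `seed_baseline_enrichment()` gives
the constant comparator of a canonical 6-mer search, which equals 1 on
a gene set restricted to 6-mer-carrying genes.

## The synthetic-data generator

`synthetic_study()` emulates the statistical structure of a miRNA
transfection experiment at desk scale: log-normal UTR lengths (meanlog
log 800, sdlog 0.6, clamped to 60–4000 nt — the scale of mammalian
3'UTRs), slightly AU-rich base composition (30/20/20/30), target sites
of chosen seed types planted into 30% of genes (plus whatever
background 4-mer matches arise by chance — roughly a dozen per
kilobase), energies from the deterministic toy engine, and expression
change exactly linear in the 14 features plus Gaussian noise
(sd 0.2 log2 units). Planted windows are written so that
`assign_seed_type()` provably returns the requested label, with
mismatch bases chosen to exclude accidental upgrades; every plant is
re-verified in a closed loop. The generating coefficients
(`default_true_coefficients()`) follow the expected directions —
positive on ΔΔG/ΔG_H features, negative on ΔG_open features and UTR
length — with zeros on the structurally dependent triple.

What the generator deliberately does *not* emulate: real folding
thermodynamics (the toy engine is pair counting), indirect and
off-target expression effects, measurement error structure beyond
i.i.d. Gaussian noise, isoform mixtures, and the fact that in real
data most genes with sites show no repression. Passing tests therefore
demonstrate that the machinery is correct and internally consistent —
scanner, energetics, features, fitting, ranking — not that the model
attains any particular accuracy on biological data.

## Problem sizes and numerical choices

The test suite and the acceptance script run the study at 150–2000
genes and a single miRNA (the acceptance script uses 1200), sizes at
which ordinary least squares on 14 features is extremely
well-conditioned and the whole pipeline completes in minutes on one
core. Cross-validation uses k = 5; fold assignment, shuffling, control
pairing and noise all flow from a single integer seed, and two runs
from one seed are byte-identical. Energies are computed in double
precision and serialized at 2 decimals in site tables; model JSON is
written at 17 significant digits so a reloaded model predicts
bit-identically. In the acceptance script bona fide targets are defined
as the most strongly down-regulated decile of the simulated
distribution, mirroring the practice of choosing a stringent
expression-change cutoff on the dataset at hand.
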