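---
title: "Methods: inferring blood-synovium ligand-receptor crosstalk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: inferring blood-synovium ligand-receptor crosstalk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lrtalk)
```

## Scope and model

`lrtalk` infers candidate molecular communication between two tissue
compartments — peripheral blood mononuclear cells (`BL`) and synovial
fibroblasts (`SY`) in case/control osteoarthritis cohorts — from bulk
expression matrices. The inference is deliberately simple and transparent:
a gene is a candidate *sender* in a tissue if it is a differentially
expressed ligand there, a candidate *receiver* if it is a differentially
expressed receptor, and a curated ligand→receptor pair database supplies the
wiring. For every ordered tissue pair (A, B) ∈ {BL, SY}² and every database
pair (L, R),

> edge (A, L) → (B, R) exists ⟺ L is a differential ligand of A and R is a
> differential receptor of B,

yielding the four direction classes `BL->BL`, `BL->SY`, `SY->BL`, `SY->SY`.
Within-tissue classes are first-class outputs, not a by-product: autocrine
and paracrine signaling inside a compartment is as interpretable as the
between-tissue chords. The procedure is presence/absence on DEG status only.
Expression level, fold-change magnitude and direction concordance are *not*
filters — each gene's up/down direction is carried as an annotation so a
reader can post-filter, but the map itself imposes no concordance
requirement. A gene annotated in both database roles participates in both.
This is a hypothesis-generating screen: an edge asserts co-occurrence of
differential expression compatible with signaling, not causal signal flow.

## Differential expression

The screen needs a per-gene two-group test; the package offers two.

**Welch's t (default).** For gene *g*, with group means and variances
computed per group, `t = (mean_OA − mean_HC)/sqrt(s²_HC/n_HC + s²_OA/n_OA)`
on Welch–Satterthwaite degrees of freedom, two-sided p from Student's t.
Welch is assumption-light (no equal-variance assumption) and behaves well at
the very unbalanced blood design (33 vs 108). Genes with zero variance in
both groups and equal means are reported as t = 0, p = 1 rather than
dropped, so the gene universe — and therefore every enrichment background —
is stable.

**Empirical-Bayes moderated t.** Microarray cohorts of this size per gene
benefit from variance moderation, and the original analyses of such data
conventionally used moderated statistics. Per-gene pooled variances s² with
residual df are modeled as draws from a scaled inverse-chi-square prior
(d₀, s₀²); the fit is method-of-moments on log s²: the spread of log s² in
excess of the sampling component `trigamma(df/2)` identifies d₀ through the
trigamma function (inverted by Newton iteration), and the mean identifies
s₀² through the digamma function. The posterior variance
`(d₀·s₀² + df·s²)/(d₀ + df)` feeds a pooled-variance t on df + d₀ degrees of
freedom. Two degenerate regimes are handled explicitly: when the observed
log-variance spread is below the sampling minimum, d₀ = ∞ and every gene
shares s₀²; when all input variances are literally identical, s₀² is that
common value. The implementation is validated in the tests against an
independent established moderated-statistics fit on the same data.

**Thresholding.** DEGs are genes with p strictly below α (default 0.05); the
strict inequality is deliberate — a p-value exactly at the threshold is not
below it. A stricter variant filters on BH-adjusted p (`use_adjusted = TRUE`);
with these cohort sizes it typically leaves too few ligand-receptor pairs
for a meaningful map, which is exactly why the raw-p screen is the default.
BH adjustment is step-up `q_(i) = min_{j≥i}(p_(j)·m/j)` capped at 1. No
fold-change cutoff is applied, and log2fc is defined OA − HC so that "up"
always means higher in OA.

## Preprocessing and QC

The package accepts expression matrices, not raw array files; probe-level
preprocessing (e.g. RMA on CEL files) is out of scope. The documented
stand-in is: optional `log2(x + offset)` for intensity-scale input, then
classic quantile normalization (rank, replace by the across-sample mean of
each rank, ties receiving the mean of the spanned reference values). Probe
tables are collapsed to gene symbols by the plain arithmetic mean of a
gene's probe rows — the common convention for symbol-level reanalysis;
median or max-IQR alternatives are intentionally not offered. Unmapped
probes are dropped and counted, never imputed. Gene symbols are uppercased
and whitespace-stripped at every ingestion point, because case mismatch
between platform annotations and pair databases silently empties
intersections.

QC outputs mirror standard array practice: per-sample five-number summaries
(type-7 linear-interpolation quartiles, so different implementations agree
to machine precision) and sample PCA. PCA centers features but does not
unit-scale them by default (`scale. = TRUE` exposes the correlation
variant — tools differ on this default, so it is a flag rather than a
hidden choice). A deterministic sign convention — the largest-magnitude
loading of each component is positive — makes scores reproducible across
runs and gene orderings.

## Over-representation analysis

Differential ligands are tested per annotation term with the exact
hypergeometric upper tail P(X ≥ k), X ~ Hypergeom(N, K, n), via the stable
distribution-function implementation (no factorial overflow). Choices that
change numbers, made explicit:

* **Background** = the measured gene universe of the tissue's expression
  matrix after collapsing, not the genome. Term members outside the
  background are discarded before counting, so unmeasured genes can never
  affect a count.
* **One-sided over-representation only** — the screen reports enrichment,
  not depletion.
* **Terms with zero query hits are excluded** from testing and from the BH
  denominator m; with many annotation terms and small queries this makes
  adjusted values noticeably smaller than an all-terms m, which is the
  convention of mainstream ORA tools.
* **BH within each GO category** (BP/MF/CC) by default, matching how dot
  plots are grouped; `per_category = FALSE` adjusts globally.

## The synthetic study generator

The generator exists so that every downstream stage is testable offline with
known ground truth. It emulates the *shape* of the two target cohorts:
blood with 33 HC and 108 OA samples, synovium with 11 and 11, a shared gene
universe in which disjoint minorities are labeled ligands (`LIG####`) and
receptors (`REC####`), and a directed pair database drawn uniformly without
replacement from the ligand × receptor cross product. Expression for gene g,
sample s is

```
x_gs = baseline_g + effect_log2 · d_g · 1[s ∈ OA] + ε,   ε ~ N(0, sigma²)
```

with d_g ∈ {+1, −1} for genes planted up/down (chosen per tissue at the
configured fractions) and 0 otherwise, and baselines uniform on
`baseline_range`. Defaults, chosen once: `n_genes = 2000` (large enough to
preserve the multiple-testing structure, small enough for fast tests; real
universes are an order of magnitude larger), `n_ligands = n_receptors = 150`
and `n_pairs = 400` (a minority of the universe, pair density comparable to
curated catalogues relative to universe size), `frac_de_* = 0.3/0.3/0.05`
(ligand/receptor/background), `effect_log2 = 1` and `sigma = 0.5` (a
moderate, realistic log2 effect at array-like noise; at these values the
blood design has essentially full power per gene and the 11-vs-11 synovium
design ~99%), `baseline_range = (4, 12)` (the span of RMA-scale
intensities). All randomness flows from one explicit integer seed; each
operation uses a private RNG stream and restores the caller's RNG state.

What the generator does *not* emulate — and what passing tests therefore do
not certify about real data: probe-level effects, batch structure,
correlated co-expression modules, heavy-tailed or intensity-dependent noise,
ligand/receptor symbol overlap (the synthetic universes are disjoint so
truth recovery is unambiguous; overlap handling is exercised separately with
hand-built fixtures), and any relationship between the two tissues' planted
gene sets beyond chance.

## Numerical and serialization choices

* Strict `<` at every significance threshold; ties at the threshold are
  excluded.
* Volcano labeling: the `top_n/2` smallest-p up- and down-regulated genes
  (default 20 total), ties broken by |log2fc| descending then symbol
  ascending; sides short of genes are clamped.
* Direction labels `up`/`down` follow the sign of log2fc; an exactly-zero
  fold change gets `NA` direction.
* All writers emit fully sorted rows (edges by direction class, ligand,
  receptor; chord segments by tissue, role, symbol), UTF-8, LF, tab
  delimiters, so repeated runs are byte-identical — determinism is tested at
  the file level, not just the object level.
* The communication map serializes to an edge TSV, a GraphML network with
  nodes keyed `<tissue>:<symbol>`, and a chord-segment JSON (per tissue,
  ligand segments then receptor segments, edges indexed by segment) that a
  circos-style renderer can consume directly; the package itself draws only
  ggplot2 summaries.
* `run_crosstalk_pipeline()` writes every stage's table to disk such that any
  later stage can be re-run in isolation from the files alone; the run
  summary JSON contains the per-tissue DEG/ligand/receptor counts and the
  four direction-class edge counts that are the analysis' headline numbers.

## Test and validation sizes

The test suite validates each operation against independent oracles —
exhaustive hypergeometric enumeration for all backgrounds N ≤ 25, brute-force
BH on all permutations of up to six p-values, a scalar triple-loop edge
oracle on 200 random map instances up to 10⁴ database pairs, reference
t-test and moderated-fit implementations, and simulation-based checks: null
calibration on a 2000-gene study (DEG rate inside the binomial 99% interval
around 0.05; ORA family-wise discovery rate over 500 random queries),
planted-signal sensitivity > 0.9 over 20 seeds at effect 1.0/σ 0.5, and
complete planted-pair edge recovery at effect 2.0, where per-gene detection
is essentially certain even in the 11-vs-11 design. These sizes were chosen
as the smallest at which the statistical assertions are stable.

## Limitations

The map is a screen over curated pairs: it cannot see unannotated
interactions, secreted intermediates, or cell-type composition effects
(bulk profiles mix cell types; a DEG may reflect composition, not
regulation). Presence/absence on p < 0.05 makes the edge set sensitive to
cohort power — the two tissues' very different sample sizes mean BL and SY
DEG sets are not comparable in stringency. No expression-weighted or
specificity-scored variant is provided, and no attempt is made to infer
directionality of effect along an edge beyond the recorded up/down
annotations.
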