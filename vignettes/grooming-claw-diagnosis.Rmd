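---
title: "Diagnosing grooming claws and placing fossils: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diagnosing grooming claws and placing fossils: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(unguis)
```

## The scientific problem

Extant strepsirrhines and tarsiers carry a grooming claw on the second
pedal digit; most anthropoids carry a nail. Whether Eocene adapiform
primates had grooming claws bears directly on where they attach to the
primate tree, so the diagnosis must be quantitative: the bony distal
phalanx under a grooming claw differs from one under a nail in shape, not
in any single presence/absence trait. This package implements three
linked analyses around that question:

1. **Distal-phalanx shape morphometrics.** Nine measurements per ungual
   (eight linear, in mm, plus the facet-shaft angle FSA in degrees) are
   size-standardized and compared across the four unguis-form groups —
   nails (ungulae), grooming claws, claws (falculae) and the claw-like
   tegulae of callitrichines.
2. **Pedal proportions.** Ratios among metatarsal and phalanx lengths
   separate prosimian-grade from anthropoid-grade feet; discriminant
   analysis assigns whole feet to family-level groups.
3. **Ordered-character maximum parsimony.** A small taxon-by-character
   matrix is searched exhaustively for the most parsimonious trees, with
   the ensemble statistics (TL, CI, HI, RI, RC) and consensus trees used
   to summarize the result.

## Size standardization and shape variables

Linear measurements are divided by the specimen's geometric mean
\(GM = (\prod_{i=1}^{8} x_i)^{1/8}\), computed in the log domain. The
standardized vector has unit product by construction, and every
downstream statistic is invariant under uniform scaling of the specimen —
a property the test suite asserts directly. FSA is an angle and is never
standardized. Three simpler indices are carried alongside: VFL/TPL
(relative volar-process length — how far the apical pad extends), the
tapering index SH14/SH34 (proximal over distal shaft height), and
SW34/TPL (relative apical-tuft width).

## The single-specimen t-test

A fossil is a sample of one. Comparing it to an extant group summarized
by \((\bar y, s^2, n)\) uses
\[ t = \frac{x - \bar y}{s\sqrt{(n+1)/n}}, \qquad df = n - 1 , \]
the prediction-interval pivot, which is exactly t-distributed under
normality — the calibration test in the suite confirms the nominal 5%
type-I error over 1000 seeded null replicates. The reference summaries
ship as a packaged fixture (`fixtures("table5")`), with group sizes
ungular 21, grooming 10, tegular 4, falcular 7. Classification of a
fossil (`classify_fossil()`) runs this test per variable against the
ungular and grooming baselines and takes the nearest group by minimum
|t|. The combined verdict requires agreement on all three of FSA,
VFL/TPL and SH14/SH34 — it is the *combination* of a dorsally canted,
strongly tapering shaft with a short volar process that marks a grooming
claw; tuft width is reported but excluded from the verdict because it
tracks the nail condition even in otherwise grooming-like fossils.
Significance flags default to a Bonferroni-adjusted alpha of
0.05/12 ≈ 0.0042 (twelve sequential comparisons); the foot-ratio
analyses use 0.0125 (four) and 0.025 (two).

## Multigroup statistics

One-way ANOVA, Kruskal–Wallis, Tukey HSD, Welch and Mann–Whitney tests
are delegated to their standard implementations in `stats`. Two
procedures are implemented here because no installed package provides
them in the needed form:

* **Tamhane's T2** is realized as pairwise Welch t-tests with
  Satterthwaite degrees of freedom and a Šidák multiplicity adjustment
  \(p_{adj} = 1 - (1-p)^m\) over the \(m\) pairs. Published
  implementations differ in the exact critical-value multiplier, so
  adjusted p-values agree with other software to roughly two decimals,
  not machine precision.
* **Pairwise Hotelling T²** uses the pooled two-group covariance with the
  usual F conversion. If the pooled covariance is numerically singular
  (more variables than specimens), a fixed diagonal ridge of
  \(10^{-8}\,\mathrm{tr}(S)/p\) is added and a warning raised; results in
  that regime should be read qualitatively.

PCA runs on the correlation matrix, so the nine eigenvalues sum to 9 and
"percent variance" is eigenvalue/9. Loadings are reported as Pearson
correlations between variables and component scores, and component signs
are anchored so the loading of BH/GM on component 1 is positive. By
default the PCA is fit on all supplied specimens (fossils included); a
caller who prefers to project fossils post hoc can fit on the extant
subset and use the returned loadings — the fit-on-all choice mirrors how
the published ordination was plotted, and with four fossils among ~50
specimens the two differ negligibly.

## Foot proportions

Six ratios are computed: pp4/mt4 (prehensility), mt1/mt2 (hallux
hypertrophy), mt3/mt4 (foot axis), mt4/mt5, pp2/pp5 (digit II
reduction) and pp3/pp4. Discriminant analyses use `MASS::lda` behind
`lda_fit()`/`lda_classify()` with **equal priors**: group sizes in
museum collections are sampling artifacts, and equal priors make the
posterior probabilities comparable across groups. Jackknife
(leave-one-out) success (`loo_cv()`) refits the model once per record —
the refit counter is part of the return value so the n-refits contract is
checkable. The phalanx-only analysis uses seven variables: the eight
phalangeal lengths minus pp1. The hallucal proximal phalanx is the one
element whose proportions are dominated by hallux grasping rather than
by the digit II–V grasp pattern the analysis targets, and dropping it is
the only reading consistent with a seven-variable design; the function
logs this choice each time it runs.

The conservative fourth-metatarsal estimator (`estimate_mt4()`)
addresses a fossil whose published mt4 length is implausibly short: the
point estimate is the *smaller* of mt3 × min(mt4/mt3) and
mt5 × min(mt4/mt5) over the extant sample — the shortest mt4 that any
sampled primate's proportions would imply — with the full ratio-based
predictive interval returned alongside. Because the estimator is a
minimum statistic, its lower tail across simulation replicates is
unbounded; tests therefore assert the plausible band for the bulk and
median of seeded replicates rather than for every draw.

## The parsimony engine

Characters are small-integer states; cells may be single states,
ambiguity/polymorphism sets (`"02"`), or missing (`"?"`). Ordered
characters pay \(|i-j|\) per change (Wagner); unordered pay 1 (Fitch).
Tree length uses Farris interval dynamic programming for ordered
characters and Fitch set operations for unordered ones, both vectorized
across characters; ambiguity enters as the spanning interval (ordered)
or the state set (unordered), and missing cells are unconstrained. The
suite verifies the engine against a brute-force enumerator of all
ancestral-state assignments (100/100 seeded matrices) and against an
independent library implementation of Fitch length.

Two costing conventions exist for polymorphic terminals. The default
treats `"0/1"` as *uncertainty* (cheapest resolution). The
`polymorphism = "polymorphism"` flag instead charges each polymorphic
terminal the internal span of its set (ordered: max − min; unordered:
set size − 1) in addition to the connection cost — an approximation of
the convention in classic parsimony software, adequate for the small
matrices this engine targets and documented here because the two
conventions can change printed tree lengths.

`exhaustive_search()` enumerates all \((2n-5)!!\) unrooted binary
topologies by stepwise leaf insertion (the count is returned and tested:
3 topologies at n = 4, 105 at n = 6, 10,395 at n = 8) and refuses above
11 taxa, where the count reaches 34,459,425. `branch_and_bound()` uses
the monotonicity of parsimony length under leaf addition to prune
partial trees longer than the incumbent; it provably returns the same
MP set, which the suite checks on 50 seeded matrices. With
`collect_trees = FALSE` only the minimum length and one witness tree are
kept, allowing equal-length pruning — the right mode for large tie sets,
e.g. recovery experiments. MP trees are emitted in a canonical order:
each tree is serialized rooted on the outgroup with sibling subtrees
sorted lexicographically, and the set is sorted by that string, so
results are reproducible across runs.

Per-character bounds give the ensemble indices: \(m_j\) (minimum steps
on any tree: state range for ordered characters, minimum hitting set
minus one for unordered) and \(g_j\) (steps on the star tree under the
best central state). Then CI = Σm/Σs, HI = 1 − CI,
RI = (Σg − Σs)/(Σg − Σm) (defined as 1 when Σg = Σm), RC = CI·RI. By
default all characters are included (the common software default);
`tree_stats(x, exclude_uninformative = TRUE)` recomputes without
parsimony-uninformative characters. Consensus trees
(`consensus_trees()`) count clades with trees rooted on the common
outgroup: strict keeps frequency-1 clades, majority keeps clades above
the threshold (default 0.5), and per-clade support frequencies are
returned and verified against direct bipartition counting.

NEXUS input/output covers the subset these matrices use — DATA/CHARACTERS
blocks, `(..)`/`{..}` ambiguity, `?` missing, ASSUMPTIONS typesets
(`ord`/`unord` with index ranges), and an OUTGROUP declaration — and
round-trips losslessly; `write_nexus(parse_nexus(x))` is a fixed point.
The published revisions to the 8-taxon primate matrix ship as a packaged
edit list (`fixtures("matrix_corrections")`,
`fixtures("matrix_additions")`): recodings to three-state ordered
characters, cell corrections, and nine added characters with their
codings for the 10-taxon set. The *base* matrix itself was published only
in a supplementary document and is not redistributed here; the pipeline
`parse_nexus() |> apply_edits() |> exhaustive_search()` runs end to end
as soon as a transcription is supplied under `inst/extdata/`.

## Synthetic data: what it emulates and what it does not

The generators reproduce the *statistical frame* of the analyses — not
real anatomy.

* `gen_phalanx_dataset()` draws shape first and size second. The
  directly drawn quantities are the six standardized variables BH/GM,
  BW/GM, TPL/GM, SH14/GM, SW14/GM, SW34/GM, the two ratios VFL/TPL and
  SH14/SH34, and FSA, each from its group's published mean and variance;
  VFL/GM and SH34/GM are derived so every record is internally
  consistent, and raw measurements are recovered by multiplying by a
  log-normal size. This parameterization was chosen over drawing all
  eight standardized variables independently because a ratio of
  independent normals has an inflated mean (a ~1% Jensen effect at
  these parameter values) and, worse, enforcing the anatomical bound
  VFL ≤ TPL by naive rejection would *deflate* the ratio mean by ~4%.
  VFL/TPL is instead drawn from a truncated normal whose location is
  solved analytically so the realized mean equals the published one.
  Variables are independent by default (only marginal summaries were
  published); an exchangeable-correlation mode exists for robustness
  checks. Consequences to keep in mind: derived quantities (e.g. VFL/GM)
  match their published means to ~1–2%, not exactly, and no
  between-variable covariance structure of real unguals is represented.
* `gen_foot_dataset()` draws the six target ratios from their group
  normals and builds 13 element lengths consistent with them; elements no
  ratio constrains are anchored to the articulated fossil skeleton's
  proportions with mild log-normal noise. Ratio distributions therefore
  match the specifications exactly in expectation; absolute lengths are
  only plausible, not data.
* `gen_character_matrix()` evolves characters on a random unrooted
  binary topology: per edge, a change occurs with the stated
  probability — one ±1 step for ordered characters (reflecting at the
  bounds), a uniform jump for unordered — with missing cells and
  two-state polymorphism injected afterwards. Passing recovery tests on
  these matrices shows the *search* is correct in a low-homoplasy
  regime; it says nothing about parsimony's behaviour on real, highly
  homoplastic data.

All generators are deterministic functions of (spec, seed).

## The recovery experiment

The packaged parameter-recovery experiment uses 8 taxa and 25 ordered
five-state characters with per-edge change probability 0.01. The rate
was set from a design calculation, not by trial: the generating tree can
only be *beaten* (rather than tied) when homoplasy arises, i.e. when two
changes of the same character collide in state. With 13 edges, the
expected number of multi-change characters per matrix is
\(25\binom{13}{2}p^2 \approx 0.44\) at p = 0.05 but ≈ 0.02 at p = 0.01,
and roughly half of such pairs collide. At p = 0.05 the collision load
is high enough that measured recovery is only ~60%; at p = 0.01 the
expected number of convergent events per matrix is well below one and
measured recovery is 96–99% across independent seed sets. The experiment
asserts ≥ 95/100. Recovery is decided by length equality
(`tree_length(true_tree) == TL_min`), which is exactly membership of the
MP set and avoids materializing the large tie sets that low rates
produce.

## Problem sizes and numerical choices

The test suite runs exhaustive searches to 8 taxa (10,395 topologies),
branch-and-bound to 10, brute-force oracles at 6–7 taxa, and
1000-replicate calibration loops — sizes chosen so the full suite
completes in a few minutes while every loop still has enough replicates
for exact binomial interval checks. Other fixed choices: hull-edge
tolerance 1e-9 in score units; the singularity ridge above; nearest-group
ties broken toward the first group in input order and flagged;
display rounding of t-values and ratios to two decimals with full
precision retained internally; all p-values two-tailed.

## Known limitations

* The extant raw measurement matrices behind the published group
  summaries were never deposited; everything fossil-facing runs off the
  printed summaries, and group-level analyses are validated in
  simulation mode at those parameter values. Published figures that
  require the raw data (the 97.1% discriminant success rate, specific
  eigenvalues, fossil posterior probabilities) are covered by
  property-based analogues only.
* The published per-variable reference sample sizes may differ from the
  whole-group counts used here (several specimens contribute more than
  one phalanx); recomputed t-values agree with the printed ones within
  printed-summary rounding (≤ ~7% relative for |t| ≥ 0.5, sign-exact),
  which is consistent with that uncertainty.
* The supplementary NEXUS matrices are not redistributed; the parsimony
  reproduction of the printed TL/CI values requires supplying their
  transcription (see above).
* Tamhane T2 adjusted p-values are implementation-dependent in the
  second decimal; conclusions at the 0.0042 threshold in this package's
  tests are insensitive to that.
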