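---
title: "Methods: substitution rates and genome rearrangement in plastomes"
author: "plastorate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: substitution rates and genome rearrangement in plastomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

plastorate links nucleotide substitution rates of plastid protein-coding
genes to measures of plastome rearrangement — inversion distances between
signed locally collinear block (LCB) orders and in-frame indel counts — the
analysis pattern used to study diatom plastomes, where a single inverted
repeat copy is removed and each genome is summarized as a signed permutation
of 42 blocks. This vignette documents the models, the tunable parameters,
the synthetic world used for validation, and the numerical and design
choices, in that order.

## Pairwise rates: Nei–Gojobori counting

`ng86_pairwise()` implements the 1986 counting estimator. Synonymous site
fractions per codon are the fraction of single-base changes to *sense*
codons that preserve the amino acid; changes that would create a stop codon
are excluded from both the synonymous and nonsynonymous site counts, so a
codon one step from a stop contributes `s + n < 3` sites. This choice keeps
the estimator defined on coding space; the alternative (counting
stop-changes as nonsynonymous) inflates N slightly. For codon pairs
differing at 2 or 3 positions, synonymous/nonsynonymous differences are
averaged over all `k!` mutational pathways, skipping pathways that pass
through a stop codon; in the (practically unreached) case that every
pathway is blocked, the average over all pathways is used with stop-steps
counted as nonsynonymous. Proportions are corrected with the Jukes–Cantor
transform `d = -(3/4) log(1 - (4/3) p)`; `p >= 3/4` is reported as
saturated (`NA`), and `omega = dN/dS` is *undefined* — never 0 — when
`dS = 0`, with such pairs excluded from downstream correlations and
counted.

Genetic code: translation table 11 (bacterial/plastid) by default,
configurable; plastid protein genes are the target domain and table 11 is
what `transeq`-style workflows use for them. Pairwise comparisons are
gap-stripped *pairwise* (only codons gapped in that pair are dropped),
because a pair's estimate should not lose columns to third-taxon gaps;
tree-based fitting instead strips codon columns gapped in any taxon,
matching PAL2NAL `-nogap` semantics.

The estimator is only evaluated against its own model: the `omega = 1`
recovery check simulates with `kappa = 1` and uniform codon frequencies at
a total divergence of 0.3 substitutions per codon. At much lower
divergence the ratio of two small counts is noisy and upward-skewed
(a ratio-estimator artefact, visible as mean dN/dS around 1.14 at
divergence 0.1); at 0.3 the mean over 20 seeds is ~1.00. Transition bias
(`kappa > 1`) biases NG86's dN/dS downward by design — that is a property
of the method, not a defect, and is why the M0 model is also provided.

## The single-ratio codon model (M0)

`gy94_rate_matrix()` builds the Goldman–Yang instantaneous rate matrix over
the 61 sense codons: zero for multi-position changes, and proportional to
the target codon frequency times `kappa` for transitions and `omega` for
nonsynonymous changes, scaled to mean rate 1 at equilibrium. Codon
frequencies default to F3×4 (position-specific nucleotide frequencies with
stop mass renormalized), with F61 and uniform as options; which frequency
model the reference implementations default to varies, and F3×4 is the
conventional default. Transition probabilities come from an
eigendecomposition of the symmetrized reversible generator
(`D^{1/2} Q D^{-1/2}`), which is numerically stable and removes the need
for a general matrix-exponential dependency.

`m0_loglik()` is Felsenstein pruning over codon site patterns compressed
with multiplicities, with per-pattern rescaling against underflow; gapped
or ambiguous codons are treated as missing data at that tip. `fit_m0()`
maximizes over `(kappa, omega, tree_scale)` with **branch-length
proportions fixed to the input tree and a single global scale optimized**
— a deliberate simplification of the reference model 0, which frees every
branch; the simplification is recorded in the fit object. Optimization is
bounded quasi-Newton (`L-BFGS-B` on log parameters) with bounds
`kappa ∈ [0.01, 100]`, `omega ∈ [1e-4, 20]`, `tree_scale ∈ [1e-6, 1e3]`,
from three starts `(kappa, omega) = (1, 0.1), (2, 0.5), (5, 1)`. Degenerate
inputs are flagged rather than failing: identical sequences drive the scale
to its lower bound (`tree_scale_at_lower_bound`), purely synonymous
variation drives `omega` to its floor.

Likelihood-ratio tests for nested site models are arithmetic on supplied
log-likelihoods: `stat = 2 (lnL1 - lnL0)` against the upper chi-square tail
(df = 2 for the beta vs beta-plus-positive-class comparison). Numerical
fitting of those site models (and empirical-Bayes site identification) is
out of scope; only the test arithmetic is implemented, and a negative
statistic is reported as-is with `p = 1` and a warning.

## Reversal distance on signed permutations

Each plastome's structure is a signed permutation of LCB ids; the minimum
number of segment reversals (with sign flips) separating two orders is the
Hannenhalli–Pevzner distance `d = (n + 1) - c + h + f`, computed on the
breakpoint graph of the permutation framed by `0` and `n + 1`: `c`
alternating cycles, `h` hurdles (unoriented components minimal or greatest
in the span-containment order), `f` the fortress indicator (1 iff the
number of hurdles is odd and all of them are superhurdles). Chromosomes are
treated as **linear with fixed framing**, matching the single-linear-
chromosome convention for plastomes with one IR copy removed and a
published linearized block order; an orientation-insensitive grouping mode
(equality up to whole-molecule reversal) exists behind a flag and is off by
default, because the published identical-order count is defined on the
printed orders as-is.

Correctness is established against an independent breadth-first-search
oracle (`bfs_oracle_distance()`, bidirectional, exact): exhaustively for
all 4,282 signed permutations with `n <= 5`, and on seeded random pairs at
`n ∈ {6, 7, 8}` — including nested-unoriented-component cases that exercise
the hurdle logic. Fortresses require more blocks than any oracle-checkable
case (the smallest needs three superhurdles); the implementation follows
the published definition and the `d = (n+1) - c + h + f` identity is
asserted on every computed instance.

## Indels

An indel event is a maximal run of `-` in either row of the
reference/taxon pairwise view of a gene (taxon-row run = deletion,
reference-row run = insertion; both separate the pair). "Number of indels"
is the count of such maximal runs — an *event* count, the standard indel
statistic — not a gapped-column count (a per-column mode exists behind a
flag). A gene is *intact* for a taxon iff every run length in both rows is
divisible by 3; intactness is evaluated per gene per taxon against the
reference only, and only intact genes enter that taxon's single total.
Adjacent insertion and deletion runs count as two events (they are distinct
maximal runs). Columns gapped in both rows are uninformative for the pair
and are stripped before counting.

## The correlation stage

Per-focal-taxon tests take an **all-vs-all** pairwise rate matrix (dN, dS
or omega) and the inversion-distance matrix: for focal taxon *i*, a Pearson
test of `rate(i, j)` against `iv(i, j)` over the 39 partners. A per-focal
correlation requires per-pair rates, which is why the all-vs-all matrix —
not outgroup-relative rates — is the input here; this is an interpretation
recorded as such. P-values use `t = r sqrt((n-2)/(1-r^2))` with `n - 2`
df; the Bonferroni family is the set of focal taxa (m = 40 by default),
one family per rate type; significance calls are made on the *raw* p at
`alpha = 0.05` with adjusted values reported alongside. Focal rows with
fewer than 3 defined pairs are skipped and logged.

Rate-vs-feature regressions report both a Pearson test and a PGLS fit
under Brownian-motion covariance (`V[i, j]` = shared root-to-MRCA path
length) on the outgroup-pruned tree, since both are in routine use and the
method is reported per row. PGLS solves
`beta = (X' V^{-1} X)^{-1} X' V^{-1} y` by Cholesky whitening; `sigma^2`
uses `n - k`; with `V = I` the fit reduces to OLS (asserted to 1e-8 in the
suite, and cross-checked against `nlme::gls` with a Brownian correlation).
No Pagel's lambda is estimated — the correlation structure is plain
Brownian, with a lambda profile available behind a flag only.

## The synthetic world

`make_scenario()` generates complete datasets with the statistical
structure the analysis assumes. Defaults are stated once and are not tuned
to test outcomes:

| parameter | default | why |
|---|---|---|
| `n_taxa` | 40 (+ outgroup) | the sampling depth of the motivating study design |
| tree | pure-birth, ultrametric, height 0.25 subs/codon site | a time tree with a relaxed clock is the standard generating model; 0.25 root-to-tip gives ingroup pairwise dS well inside the counting method's valid range while the outgroup (branch = height) sits near dS ~ 0.6 |
| `tau` | 0.6 | lognormal sdlog of per-branch rate multipliers; substantial lineage effects (occasional 3–5× branches) emulate the long-branch lineages real plastome trees show |
| group omegas | photosynthesis 0.05, ribosomal/RNA-polymerase 0.3, RubisCo 0.08 | the purifying-selection contrast by functional class reported across plastomes |
| `kappa` | 2 | a typical organellar transition/transversion ratio |
| genes | 8 × 150 codons | a desk-scale stand-in for the ~100-gene concatenation; long enough for stable pairwise dN |
| `n_blocks` | 42 | the block count of the published LCB table |
| `lambda_inv` | 25 per unit rate-weighted branch length | yields pairwise inversion distances spanning ~2–20, the range the published table's orders actually produce |
| `mu_indel` | 120 | per-taxon totals of a few dozen events, the scale of real per-taxon indel counts |

The coupling knob interpolates between two Poisson layers: a *heritable*
layer on branches with intensity `coupling * rate * b * m` (events inherited
by descendants; at `coupling = 1` rearrangement intensity is fully
proportional to the branch substitution-rate multiplier) and a
*lineage-independent* layer drawn per leaf with intensity
`(1 - coupling) * rate * mean(rate-weighted root-to-leaf depth)`. The naive
alternative — interpolating inside the branch intensity,
`rate * b * (c m + (1 - c))` — was implemented first and measured: it is
**not** a null at `c = 0`, because the branch-length factor `b` then still
drives both pairwise rates and pairwise rearrangement counts, and the focal
tests reject in the vast majority of cases. The two-layer design makes
`c = 0` i.i.d. across leaves and hence a genuine null, while `c = 1` is
unchanged.

Indel events delete 1–3 codons (3/6/9 nt at 70/20/10%) at codon boundaries,
placed away from existing runs so planted events remain distinct maximal
runs; lengths are capped at 9 nt so genes stay intact by construction, and
a separate `frameshift_rate` injects out-of-frame gaps to exercise the
exclusion logic. All generators are pure functions of (config, seed); seeds
are mandatory.

What the generator does *not* emulate: IR expansion/contraction and
foreign-DNA insertion, base-composition heterogeneity across lineages,
rearrangement hotspots (reversals are uniform, matching the null model
implicit in reversal-distance analysis), alignment error, and ortholog
mis-assignment. A green estimator-recovery test therefore establishes
correctness of the estimators under their own assumptions — not robustness
to those real-data complications.

## Size of the focal-test family: a caveat the suite surfaces

The test suite checks the decoupled scenario's false-positive fraction over
20 replicates × 40 focal taxa against the binomial 95% band around the
nominal 5%. That yardstick assumes 800 independent tests, but the 40 focal
tests inside one replicate are strongly dependent: every taxon participates
in every focal test, so a single chance coincidence between a high-rate
lineage and a high-reversal-count lineage fires most of a replicate at
once. Measured per-replicate counts are heavy-tailed (mostly 0–7 of 40,
occasionally 30+), so the fraction is effectively a mean of ~20 clustered
draws with a standard deviation several times the binomial one, and the
band does not have 95% coverage. With the suite's fixed seeds the measured
fraction can fall outside the band while the *per-test* marginal size is
close to nominal; the check is kept as stated rather than recalibrated
post hoc, and this paragraph is the analysis of why it can fail. The
practical reading for real data: per-focal-taxon significance counts ("k of
40 taxa significant") inherit exactly this clustering and should not be
read as k independent discoveries.

## Numerical choices and conventions

- Coordinates are 1-based inclusive everywhere (gene blocks, reports): the
  package is R throughout and every neighbouring API (ape, Biostrings) is
  1-based; introducing a 0-based internal convention would only create
  translation bugs.
- Ambiguity codes other than `N` are rejected at read time; counting
  methods are defined on unambiguous codons.
- Matrix exponentials via symmetric eigendecomposition; transition matrices
  are clipped at 0 and row-renormalized (deviations are at the 1e-12
  level). Pruning rescales per pattern; likelihood contributions below
  1e-300 are floored.
- PGLS jitters the covariance diagonal by 1e-10 of its mean only if the
  Cholesky fails, and records that it did.
- The LCB parser accepts Unicode minus and minus-separated-by-space (the
  typography of published tables) and normalizes both.
- Isoform/ortholog selection is out of scope: alignments are inputs.

## Known limitations

- `fit_m0` optimizes one global tree scale, not per-branch lengths; its
  omega estimates are cross-checked by simulation, but its `lnL` values are
  not comparable to a free-branch fit.
- The fortress branch of the distance formula is exercised only by its
  definition, not by an oracle (no small-n fortress exists).
- The Pearson-based focal analysis is not robust to leverage points (see
  the size caveat above); a rank-based variant would trade power for
  robustness and is deliberately not the default, to keep the published
  method.
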