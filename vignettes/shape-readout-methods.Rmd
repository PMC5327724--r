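---
title: "Modeling TF-DNA binding specificity with DNA shape features: methods"
author: "selexshape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling TF-DNA binding specificity with DNA shape features: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(selexshape)
```

## The problem

Transcription factors (TFs) recognize their binding sites through two
complementary mechanisms: *base readout* (direct contacts with base
functional groups, well captured by independent per-position nucleotide
models) and *shape readout* (recognition of the sequence-dependent
three-dimensional conformation of the double helix). HT-SELEX — iterated
rounds of in vitro selection of a random oligonucleotide pool by a TF,
with sequencing of each round — yields quantitative relative binding
affinities for millions of sequences. `selexshape` implements the full
path from per-round read pools to position-resolved statements about
where along a binding site shape readout contributes, together with a
ground-truth simulator so every stage is testable without any external
download.

## From reads to M-word scores

An **M-word** is an aligned core-motif match plus a fixed number of
flanking bases on each side; it is the unit to which binding scores are
assigned.

**Core motifs** are IUPAC consensus strings. Degenerate symbols are
discounted when measuring a core: the weight of a symbol is
1/(number of nucleotides it denotes), so `CANNTG` has weighted length
$4 \cdot 1 + 2 \cdot 0.25 = 4.5$. The mismatch budget is
$\lfloor(\mathrm{weighted\ length} - 4)/2\rfloor + 1$ (clamped at 0 below
weighted length 4, where the formula would go negative): two mismatches
for `ATAAAA`, one for `CANNTG`. A core may be extracted from a longer
published seed by sliding family-catalogue motifs over it
(`select_core_from_catalog()`): positions are scored by the fraction of
aligned IUPAC *sets* that agree (`score1`), ties broken by exact symbol
identity (`score2`).

**Scanning** (`scan_pool()`) examines both strands. A read is discarded
when two or more distinct intervals match at the *stricter* threshold of
one mismatch fewer (multiple binding sites — possible cooperative
binding), when no window matches, or when the best hit cannot supply the
required flanks. Two tie-break rules are our own choices where the
policy only resolves unequal match counts: equally good best hits on
opposite strands of the same interval are discarded
(`ambiguous_strand`) rather than oriented arbitrarily, and equally good
hits at different intervals are discarded as multiple binding modes.
Reads containing non-ACGT characters are skipped and tallied. Retained
M-words are re-oriented so the core reads in motif orientation.

**Scores.** Identical oligonucleotides are counted once (PCR
de-duplication, keyed on the full read). For round $i$ (rounds $\ge 3$;
earlier rounds show little enrichment),

$$\mathrm{score}(w) = \left(\frac{freq_i(w)}{est\_freq_0(w)}\right)^{1/i},$$

where $freq_i$ is the word's frequency among retained reads and
$est\_freq_0$ its estimated initial-pool frequency under a fifth-order
Markov model of the round-0 pool (marginal hexamer distribution times
conditional next-base probabilities; pseudocount 1 per hexamer cell
guarantees positivity; the background is trained on the read strand
only). Under geometric per-round enrichment the score is proportional
to relative binding affinity; the i-th root removes the dependence on
the selected round. Note the two denominators live on different
supports: $freq_i$ is normalized over retained core-matched words while
$est\_freq_0$ is a distribution over all $4^M$ words, so scores carry an
arbitrary common scale factor; all downstream uses (regression,
percentile spreads, ranks) are invariant to it.

**Flank lengths.** The initial flank is
$\lfloor(10-\mathrm{core\ length})/2\rfloor$ (literal length; flanks are
physical positions), guaranteeing $M \ge 10$ and at least six
shape-predictable positions. The maximum flank is the largest for which
the dataset keeps $\ge 1000$ M-words with count $> 8$ *and* a maximum
count $\ge 100$; datasets are emitted for every flank from initial to
maximum.

## Quality control

Stage 1 (`qc_stage1()`): drop M-words with count $\le 8$; fail the
dataset if fewer than 1000 distinct words remain, if the 90th-percentile
score does not exceed the 10th percentile by at least 0.2 (percentiles
by linear interpolation; the method is configurable), or if the maximum
count is below 100. Stage 2 (`qc_stage2()`): a model using a superset of
features should not underperform its subset by more than 3% — read as
relative to the subset's cross-validated $R^2$, with an
absolute-difference switch, since the percentage base is ambiguous; and
datasets whose best model has $R^2 < 0.5$ are excluded. Cross-validated
(not training) $R^2$ enters the screen because only cross-validated
performance is reported anywhere. Per TF, the dataset with the highest
best-model $R^2$ wins; exact ties go to the earliest round, then the
smallest flank.

## DNA shape features

Shape is predicted from a pentamer query table (`predict_shape()`):
minor groove width (MGW, Å) and propeller twist (ProT, degrees) describe
the central base pair of each pentamer; roll and helix twist (degrees)
describe its two central base-pair steps. Sliding the 5-bp window leaves
the two positions at each end undefined. Step features are indexed by
the step's *right* base pair and averaged over the two covering
pentamers, so the bundle attributed to base position $i$ contains the
two steps flanking it. First-order features are normalized as
$(x - \min)/\mathrm{sd}$ with the minimum over all 1024 pentamers and
the standard deviation over the encoded dataset (per dataset, per
feature kind — pooling across datasets would leak information between
experiments). Second-order features are products of adjacent
first-order features, scaled by the standard deviation of the products
in the dataset; products touching an undefined neighbor are omitted, not
imputed.

The per-position bundle $shape_i$ holds 12 features: MGW$_i$, ProT$_i$,
Roll$_i$, Roll$_{i+1}$, HelT$_i$, HelT$_{i+1}$ and the six second-order
terms MGW$^2_i$, MGW$^2_{i+1}$, ProT$^2_i$, ProT$^2_{i+1}$, Roll$^2_i$,
HelT$^2_i$. A 1mer+shape model therefore needs 12 features per interior
position versus 84 for 1mer+2mer+3mer and 64 for 3mer alone:

```{r}
per_position_feature_count(c("1mer", "shape"))
per_position_feature_count(c("1mer", "2mer", "3mer"))
per_position_feature_count("3mer")
```

Because no experimentally derived query table ships with the package,
`gen_shape_table()` draws a synthetic one within plausible physical
ranges (MGW 3.0–6.5 Å, ProT −17–0°, Roll −8–9°, HelT 30–40°), by default
tied across reverse-complement pentamer pairs so profiles obey strand
symmetry. Any real table in the same TSV layout can be dropped in via
`load_shape_table()`. Two negative controls are built in: column-wise
shuffling of the pentamer assignment (`shuffle_shape_table()`, preserving
each column's value multiset) and replacement of encoded shape columns
by moment-matched Gaussian noise (`gaussian_random_features()`).

## Models

`fit_ridge()` is L2-regularized multiple linear regression with 10-fold
cross-validation, via glmnet with $\alpha = 0$. Numerical choices: the
intercept is unpenalized; columns are *not* re-standardized (encodings
are already one-hot or sd-normalized); $\lambda$ is chosen per training
fold by 5-fold inner cross-validation over a logarithmic grid
$10^{3}, \ldots, 10^{-4}$ (8 points); reported $cv\_R^2$ is the squared
Pearson correlation between pooled out-of-fold predictions and observed
scores (pooling is more stable than averaging per-fold $R^2$ at small
$n$; a variance-explained option exists). Fold assignment is seeded and
shared across all model specs of a dataset so comparisons are paired.
Zero-variance responses are refused rather than reported as $R^2 = 0$.

k-mer features are one-hot indicators per start position
(lexicographic A<C<G<T order); `E2`/`NoE2` variants keep or remove k-mer
windows overlapping the two terminal positions at each end — read as
*window overlap* because those features act as a proxy for the shape
values undefined exactly there; the window set is configurable since
an anchored-at-terminal reading is also defensible. For palindromic
cores each feature row is averaged with the encoding of the
reverse-complement word.

In unregularized regression a 3mer model spans the same space as
1mer+2mer+3mer; `map_3mer_equivalence()` implements the explicit weight
mapping (with its boundary term at the last window) and the test suite
verifies prediction identity to $10^{-10}$ on random weights and words.
With regularization the two are only approximately equivalent, asserted
as $|\Delta R^2| < 0.05$ on synthetic data.

## Feature selection and logos

* **Red heat map** — add $shape_i$ to the 1mer baseline:
  $(R^2_{1mer+shape_i} - R^2_{1mer}) / R^2_{1mer}$ per position.
* **Blue heat map** — remove $shape_i$ from the shape-only model:
  $(R^2_{shape} - R^2_{shape-i}) / R^2_{shape}$.
* **Combined** — the cell-by-cell minimum, suppressing the red map's
  false positives and tolerating the blue map's false negatives, both of
  which arise because adjacent positions share pentamer context.

Values are kept signed; renderers may clip at zero. Cells where the
reference $R^2$ is non-positive are masked. `feature_delta_matrix()`
refines the analysis to single (position, feature-kind) pairs by adding
only that kind's first-order columns at that position (for the step
features, the two steps flanking the position) to the 1mer baseline.
The resulting $\Delta R^2$ matrix *is* the shape-logo PSSM: letter
heights (H = HelT, M = MGW, P = ProT, R = Roll) equal the
$\Delta R^2$ entries exactly, floored at zero for display, with empty
stacks at the undefined terminal positions. Sequence logos use base
frequencies of the top 200 scoring M-words converted to
information-content heights ($2 - $ entropy, bits).

`pca_families()` performs covariance PCA (no column scaling beyond the
encoding's own normalization) of per-TF feature vectors — each TF
represented by its top-scoring word — and summarizes family separation
as the difference between median inter- and intra-family distances in
the first two components.

## The simulator and what passing tests mean

`simulate_experiment()` realizes the generative model the scoring
assumes: round 0 plants one random realization of the IUPAC core per
read at a uniform offset leaving full flanks in uniform background;
each round multiplies read frequencies by
$\mathrm{affinity}(w) = \exp(\text{sequence energies} + \beta \cdot
\text{shape features})$ (single-copy occupancy, linear in affinity —
saturation and cooperativity deliberately excluded so the i-th-root
identity holds), renormalizes, resamples multinomially and injects PCR
duplicates at a configured rate. Identical seeds give byte-identical
pools, and an exact (noiseless) mode propagates frequencies in closed
form.

Study conditions fixed in the defaults: pools of 30,000 reads (20,000
in the fast fixture suite) of length 16, four selection rounds, PCR
duplication rate 0.05, a hexamer core with flank 2 ($M = 10$), a planted
MGW readout of $\beta = 0.5$ at the first shape-defined position, and
weak ($\mathrm{sd}\ 0.25$) 1mer energies on the 3′ flank so the sequence
baseline has signal. The effect sizes were chosen so that enrichment is
strong enough for a clear readout signal while round-4 pools keep their
word diversity and score spreads comparable to deep-sequenced
experiments; recovery tests use 20 seeded replicates and require the
red-heat-map and logo argmax within ±1 position of the plant (adjacent
positions share pentamer context, so off-by-one calls are expected).

What the simulator does **not** emulate: sequencer errors, synthesis
and PCR sequence bias, TF concentration and washing kinetics, binding
saturation, cooperative multi-site occupancy (present only as the
deliberate contamination fixture), and real pentamer shape values.
Passing tests therefore demonstrate that the pipeline's inference is
correct *under its own generative assumptions*, not that any particular
biological TF uses shape readout.

## Known limitations

* Scores carry a dataset-level scale factor (normalization mismatch
  described above); only relative statements are meaningful.
* With a synthetic shape table, absolute shape values are arbitrary;
  all shape results are relative to the table supplied.
* Heat maps inherit the false-positive/false-negative structure of
  add/remove feature selection under feature redundancy; the combined
  map mitigates but does not eliminate it.
* The regression family is linear by design (interpretability);
  non-linear readout is out of scope.
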