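---
title: "Models and methods behind idrscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind idrscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`idrscreen` implements the computational phase of a pooled growth-selection
screen for functional disordered peptides — the kind of assay in which a
library of short inserts (random 60-nt oligos, or designed variants of known
transactivation domains, TADs) is fused to a truncated transcription factor,
cells carrying functional inserts survive selective growth, and the library
is sequenced at several time points. This vignette explains the models, the
tunable parameters, and the choices made where the design was genuinely
open.

## The screen model

Each library member $i$ is a clone whose abundance grows exponentially,
$a_i(t) = a_i(0)\,e^{r_i t}$, over sampling days $t \in \{0, 2, 4, 6, 8\}$.
Sequencing a sample of depth $D$ at time $t$ draws read counts from a
multinomial over the clone proportions $p_i(t) = a_i(t) / \sum_j a_j(t)$.
The analysis works on proportions, so a clone's observed trajectory reflects
its growth rate *relative to the population mean-field*: a moderately
functional clone can show a declining normalized count simply because
faster-growing clones dilute it. This is why classification is calibrated on
an internal null (stop-codon inserts) rather than on the sign of the slope.

### Growth estimation

Counts are filtered (total raw reads $\ge 3$), then normalized in three
steps: day-0 zeros are set to one raw read when the trajectory is alive
later (a division-by-zero guard); every count is divided by the total reads
of its (time point, replicate) sample; and each replicate trajectory is
divided by its day-0 value so $y(0) = 1$. The growth estimate is the slope
$\beta$ of a robust linear regression of $y - 1$ on $t$ through the origin,
pooling the points of all replicates. The robust fit is a Huber M-estimator
(tuning constant 1.345, at most 50 IWLS iterations); when the residual scale
is exactly zero (a noiseless fixture), ordinary least squares is used and
the fit is marked converged. Fits are kept when the sequence was seen in at
least two replicates, had at least 10 raw reads, and the fit converged.

Estimates are rounded to two decimal places (halves away from zero) before
classification: at realistic depths the third decimal is regression noise.
The two printed reference thresholds in this assay family (−0.13, −0.15)
carry two decimals, which is why "two significant figures" is implemented
as two decimal places.

### Stop-codon calibration

Inserts that begin with a stop codon encode no peptide and form an
empirical null for the growth estimate. Two calibration modes are
provided. For designed libraries carrying exactly three stop variants, the
threshold is the highest of their estimates (`design_max_stop`). For random
libraries with thousands of stop-led inserts, `target_fpr` scans the
observed stop estimates and returns the smallest threshold whose in-sample
exceedance is at most the target (default 0.006, the operating point at
which this assay family reports a 0.6% stop-control FPR). Classification
uses a strict inequality, so a stop variant that defines the threshold is
itself nonfunctional. In the end-to-end driver the stop set is split in
half: one half calibrates, the other half is a held-out null on which the
realized FPR can be measured. With ~120 controls on each side the realized
held-out FPR is itself a binomial draw; checks against the target must
allow that sampling noise.

## The synthetic screen

The simulator generates the data structures the analysis assumes, with a
planted ground truth so that label and parameter recovery can be tested —
something real screen data cannot provide.

* **Random library**: uniform-random 60-nt inserts (peptides ≤ 20 aa after
  stop truncation). About 3/64 of inserts begin with a stop codon, yielding
  the stop-control null for free.
* **Design library**: A/G/P/K/R scans of wild-type TAD peptides (identity
  substitutions skipped), plus three stop controls (TAA/TGA/TAG first
  codon), all back-translated with a fixed most-frequent-codon table —
  codon identity is irrelevant downstream except for stops. Replicate
  barcodes are 8-nt with pairwise Levenshtein distance ≥ 4, found by
  seeded rejection sampling.
* **Planted rule**: a peptide is functional iff it has ≥ 2 acidic (D/E)
  residues, ≥ 1 aromatic (F/W/Y), and no positively charged (K/R/H)
  residues. The rule mirrors the acidic-plus-aromatic, positive-depleted
  signature of transactivation domains, so the feature-importance stage has
  a known answer to recover. Under this rule roughly 1% of random 60-nt
  inserts are functional.
* **Planted rates**: +0.4/day (functional) and −0.4/day (nonfunctional).
  These were chosen once as a plausible survival-versus-death contrast over
  an 8-day selection: nonfunctional clones decay to ~4% of their initial
  abundance by day 8, giving normalized-slope nulls near −0.1, in the same
  range as the reference thresholds above, while functional clones separate
  by an order of magnitude.
* **Initial abundances** are uniform by default (log-normal optional);
  library skew is a free parameter because real screens do not report it.
* **Read emission** (optional) produces single already-merged reads
  (barcode + insert + stop tail `TAATTAATTAA` + 21-nt adaptor) with
  i.i.d. substitution errors at constant Phred quality. Indel handling is
  exercised through constructed fixtures in the pair-merging tests instead.

What the simulator does *not* emulate: PCR amplification bias, chimeras,
position-dependent quality profiles, replicate-specific abundance drift.
Passing tests therefore demonstrate correctness of the estimation and
learning machinery under the stated statistical model, not robustness to
every artifact of real sequencing.

## Read processing

The processing stage mirrors amplicon pipelines: overlap merging of read
pairs (accept only merges of exactly the construct length with ≤ 2
alignment gaps; disagreements resolved toward the higher-quality base),
expected-error filtering ($\sum_b 10^{-Q_b/10} \le 1$), prefix-anchored
barcode demultiplexing (≤ 2 edits within an 8-nt barcode; equidistant ties
unassigned), adaptor trimming (≤ 10% edits in a 21-nt adaptor; reads
without a locatable adaptor are dropped), dereplication (count ≥ 2),
abundance-ordered greedy clustering, and mapping of all reads to the
closest centroid (identity ≥ 0.90 de novo, ≥ 0.80 against a designed
reference).

Sequence identity needed a concrete definition because the original
external tools leave it version-dependent: here it is matching columns
over all alignment columns (terminal gaps included) of a global alignment
scored match +1, mismatch −1, gap −2. Clustering order ties are broken
lexicographically so reruns are bit-identical. Singletons are removed
before clustering.

## The feature framework

Features are encode → view → aggregate triples: an encoding maps residues
to numbers (a scale, a group membership, or a pattern), a view selects the
full sequence or sliding windows, and an aggregator reduces the values
(count, sum, mean, max, min, presence). The default catalog has exactly
146 features in eight sets:

| set | features | content |
|---|---|---|
| aa_composition | 20 | residue fractions, order IVLAFWYGSPKRHDETQNCM |
| group_composition | 11 | aliphatic, aromatic, branching, charged, negative, phosphorylatable, polar, hydrophobic, positive, sulfur, tiny |
| minimotif | 100 | 25 ordered pairs of {negative, positive, aromatic, polar, nonpolar} × gap ranges {0–3, 0–10} × {presence, count} |
| ninetad | 1 | presence of the 9aaTAD motif |
| disorder | 5 | TOP-IDP scale: full-sequence mean + window-5/9 extrema |
| helicity | 5 | helix-propensity scale, same views |
| general | 3 | length, molecular weight, hydrophobic fraction |
| pi | 1 | isoelectric point |

The catalog is this package's own documented enumeration of the
146-feature design: the same total, the same eight sets, and the same
always-kept legacy features (length, pI, hydrophobicity, disorder,
helicity, 9aaTAD) that earlier TAD work singled out.

Notable numerical choices:

* **Mini-motif counts** enumerate ordered residue pairs whose gap lies in
  the range; all overlapping occurrences count ("DFDF" has three
  negative→aromatic pairs). Presence uses the generated regular
  expression. Regex engines disagree on overlapping-match counting, so the
  pair-enumeration contract is explicit and oracle-tested.
* **pI** is solved by bisection on the Henderson–Hasselbalch net-charge
  curve with the EMBOSS pKa set, to |net charge| < 1e−4 within 100
  iterations. pI values always depend on the pKa table; the table is fixed
  and recorded here.
* **Disorder and helicity** are scale-based proxies (TOP-IDP; Pace–Scholtz
  helix propensities inverted and min–max normalized so higher = more
  helical). They stand in for external disorder/helicity programs, which
  are deliberately out of scope; the catalog metadata flags them so users
  can substitute external predictions.
* **9aaTAD patterns** ship as a data file of four regular expressions
  reconstructed from the published positional preferences of the motif
  (the original resource is not redistributable); the file is named
  `_synthetic` and can be replaced. A missing pattern file is a hard
  error, not a silently absent feature.
* **Zero-count smoothing** in amino-acid enrichment adds 0.5 to every raw
  count before frequencies, keeping log2 ratios finite.
* **Rank-sum comparisons** use the exact null for small tie-free samples
  and the tie-corrected normal approximation otherwise, matching both the
  exact-enumeration oracle at small n and standard practice at scale.

## Machine learning

Labels from a growth screen are heavily imbalanced (~1% functional), so the
pipeline is built around precision–recall evaluation and training-side
subsampling:

* **Pruning** (fit once per dataset): near-zero-variance features
  (frequency ratio > 95/5), exact linear combinations (iterative QR), and
  correlation clusters (components of the |r| ≥ 0.75 graph, keeping the
  member least correlated to the rest; legacy features always retained).
* **Splits**: a stratified 75/25 train/test split; 10 × 5-fold
  cross-validation (50 splits) on the training side, stratified by label so
  every fold sees positives. For designed libraries, group k-fold keeps all
  variants of a TAD set on one side of every split (13 groups partition
  into folds of {3,3,3,2,2}).
* **Leak control**: subsampling to the minority class, centering/scaling,
  and all pruning statistics are fitted on training rows only; validation
  and test rows are transformed with the frozen parameters.
* **Models**: lasso and ridge logistic regression over 50 evenly spaced
  lambda values on [1e−5, 0.1] ("evenly interspersed" read as a linear
  grid; log spacing is available as an option), and gradient-boosted trees
  over the 32-point grid eta {0.1, 0.3} × depth {2, 4} × subsample
  {0.5, 0.75} × rounds {30, 100} × min-child-weight {0.5, 1}.
* **Selection**: the one-standard-error rule over the 50-split PR-AUC,
  with complexity ordered as fewest boosting rounds then shallowest trees,
  and strongest penalty first for the penalized models.
* **Stacking**: a logistic meta-learner on the base models' out-of-fold
  probabilities, its weights averaged over 50 bootstrap resamples with
  minority subsampling on the in-bag side. Base-model weights are
  constrained non-negative (lightly ridge-regularized): base probabilities
  are strongly collinear, and an unconstrained fit can assign a negative
  weight to a good model and invert its ranking.
* **PR-AUC** uses step-wise (achievable-precision) interpolation — linear
  interpolation overestimates PR-AUC; ROC AUC uses the rank formulation.
  The random baseline reported alongside PR-AUC is the positive-class
  prevalence.
* **Importance**: penalized models report |standardized coefficient|
  rescaled to percentages per method with the coefficient sign as
  direction; boosted trees report gain percentages with direction from the
  class-conditional mean difference (trees carry no sign); the stacked
  table combines base importances with normalized absolute stack weights.

## Tolerance analysis

For designed variant libraries, the tolerance of a TAD set is the fraction
of its labeled variants that are functional (`missing` variants — pairs
never detected in the library — are excluded from both numerator and
denominator, matching "empty tiles", and are never treated as zeros). The
pooled substitution matrix reports, for each (wild-type residue,
substituted-into residue) pair, the functional fraction across all TADs
(raw pooling, not per-TAD weighting), with rows and columns ordered by
decreasing mean observed tolerance. Variant notations such as `W30R` are
parsed with a configurable position offset because such notations are
written sometimes in protein and sometimes in domain coordinates.

## Problem sizes and reproducibility

The bundled end-to-end demonstrations use a 5,000-member random library at
a per-sample depth of 10⁴ reads with three replicates, and depth series of
10³–10⁵ on a 200-member library for slope-recovery measurements; these
sizes were chosen so a complete run takes a few minutes on one CPU while
keeping ~120 stop-codon controls on each side of the calibration/holdout
split. Every stochastic stage takes an explicit seed and restores the
global RNG state, so reruns with the same configuration are bit-identical.
The realized held-out FPR and the stacked model's PR-AUC remain stochastic
quantities: they fluctuate across seeds within the binomial and resampling
noise discussed above.

## Known limitations

* Growth estimation ignores bottlenecks, dilution events, and
  per-time-point variance structure; the slope is a relative-fitness proxy,
  not an absolute growth rate.
* The correct-mapping guarantee of greedy clustering relies on random
  60-mers being far apart; dense designed libraries are mapped against
  their reference instead (identity 0.80), as in the original protocols.
* Disorder/helicity proxies are composition-scale averages; they rank
  sequences sensibly but are not substitutes for context-aware predictors.
* The ML stage evaluates against screen-derived labels; at low prevalence,
  label noise from threshold calibration bounds achievable PR-AUC.
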