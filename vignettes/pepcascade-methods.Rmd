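---
title: "Methods: cascaded prediction of MHC-I binding peptides"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cascaded prediction of MHC-I binding peptides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Cytotoxic T cells survey cells through short peptides presented on MHC
class I proteins. For the murine reference allomorph H-2Kb the presented
peptides are predominantly octamers, and binding is classically summarized
by the canonical sequence motif 3[Y]-5[Y,F]-8[L,M,I,V]: an aromatic main
anchor at position 5, an aliphatic C-terminal anchor at position 8, and a
secondary tyrosine anchor at position 3. Motif rules are coarse, however —
many binders violate them and many motif-compliant peptides do not bind.
`pepcascade` implements a cascaded (stacked-generalization) machine-learning
model that learns finer-grained patterns from labeled binder/non-binder
octapeptide sets, together with the two analyses used to interrogate such a
model: wildcard fragment-library dissection of a reference epitope (for
H-2Kb, the ovalbumin epitope SIINFEKL), and analysis of thermal-shift
(differential scanning fluorimetry) assays that measure direct
peptide-MHC binding.

## Peptide descriptors

Every classifier consumes one of six numeric encodings of a peptide of
length $L$:

* **AAFREQ** (20): integer amino-acid counts in the fixed alphabet order
  A, R, N, D, C, Q, E, G, H, I, L, K, M, F, P, S, T, W, Y, V.
* **BINPEP** ($5L$): each residue's identity as five bits. Any injective
  code works for a learner; we use the binary representation of the
  residue's index in the fixed alphabet order, which makes the encoding
  trivially invertible (`decode_binpep()`).
* **BINAATYPE** ($6L$): each residue as six bits flagging its side-chain
  pharmacophore features (lipophilic, aromatic, H-bond acceptor, H-bond
  donor, positively ionizable, negatively ionizable).
* **PEPCATS** (147, length-independent): a topological pharmacophore pair
  descriptor. For every residue pair at sequence separation $d \in [1, 7]$,
  each cross-product of the two residues' features increments the bin of
  the unordered feature-pair type (21 types) at distance $d$. Each bin is
  then divided by the total count of its pair type, so the seven bins of
  every occupied pair type sum to 1. The lower distance bound is
  configurable (`min_dist = 0` also counts intra-residue pairs); the
  default of 1 reflects that the descriptor is defined on residue *pairs*,
  for which a self-pair at separation 0 is degenerate.
* **PPCA** ($19L$): each residue as 19 principal-component scores of a
  large amino-acid property-scale matrix (below).
* **PPCALI** ($19 \times (\text{max lag}+1) = 152$): the length-invariant
  auto-correlation of PPCA — for every lag $d \in [0,7]$ and score
  dimension $k$, $\sum_i x_{i,k}\, x_{i+d,k}$.

The pharmacophore assignment table is a package default (aromatic F, W, Y,
H; lipophilic A, V, L, I, M, F, W, P, C; donor S, T, Y, N, Q, W, K, R, H;
acceptor S, T, Y, N, Q, D, E, H; positive K, R, H; negative D, E) and can
be replaced wholesale through a plain-text config
(`read_pharmacophore_table()`); the architecture, not the particular
table, carries the method.

The property scales behind PPCA default to all 531 complete (NA-free)
scales of the AAindex collection shipped with \pkg{seqinr}, exposed
through the same 20-row CSV interface as any custom matrix
(`read_property_scales()`). A centered 20-row matrix has rank at most 19,
so the first 19 principal components capture essentially 100% of the
variance; scores are rescaled to unit variance per component. Because the
bundled scale collection is a design choice, absolute PPCA score values
are not comparable across scale collections — all structural properties
(19 components, unit variance, reconstruction) are.

Peptides containing non-canonical codes (X, B, Z, U, ...) are rejected,
never imputed: training data are curated to canonical residues, and an
imputed residue would silently distort every downstream descriptor.

## The cascade

```{r}
library(pepcascade)
data <- curate_peptides(read_peptide_table("peptides.csv"))
model <- cascade_fit(data, seed = 1)
predict(model, "SIINFEKL")
```

**Curation** keeps canonical octapeptides, collapses exact duplicates with
consistent labels, and drops *all* records of any sequence observed with
conflicting labels (no majority vote — an ambiguous measurement is
evidence against both labels).

**Splitting** is 4:1 into a cross-validation portion (10 folds) and an
external validation set, stratified by label. The external set is never
touched during model selection. Stratification is near-neutral on a
balanced core set but costs nothing and protects unbalanced inputs.

**First stage.** Each of up to 12 base slots (6 descriptors × 2 learning
schemes) is trained per outer fold. Hyperparameters are chosen by inner
5-fold cross-validation on the Matthews correlation coefficient (MCC),
the same index used for outer selection. The SVM grid spans cost
$C \in [0.5, 8]$ over linear, polynomial ($d \in \{1,2,3\}$), radial and
sigmoid kernels with $\gamma \in \{0.01, 0.05, 0.10\}$ and
$\mathrm{coef0} \in \{0, 3, 6\}$. The neural networks are single-hidden-
layer perceptrons with $h \in [2, 10]$ hidden units and logistic outputs,
trained by quasi-Newton optimization (BFGS, as implemented in \pkg{nnet})
with weight decay $\in \{0.01, 0.1, 1\}$; decay takes the role a
learning-rate/momentum pair plays under online backpropagation. All grid
steps are configurable (`grid_spec()`), and `reduced_grid_spec()` is the
documented desk-scale grid used by the package's own validation runs.

SVM scores are mapped into $[0,1)$ by Platt-style calibration — a
binomial GLM on the training decision values — rather than libsvm's
internal cross-validated probability machinery, which is not
deterministic under an external seed. Scores of exactly 1 are clamped to
the largest representable value below 1 to honor the $[0,1)$ contract.

**Second stage.** Base-classifier scores feed a small "jury" feed-forward
network (3 hidden units by default). Every member subset of the base
slots is enumerated — $2^{12} = 4096$ juries for the full architecture,
with the empty subset recorded as degenerate — and each jury is scored by
pooled cross-validated MCC and by external-set MCC. By default the jury
trains on the bases' scores on *their own training data*, a deliberately
optimistic stacking choice that mirrors the original workflow;
`stacking = "cv"` substitutes leak-free out-of-fold scores for users who
prefer the conservative variant.

**Selection** uses a compromise rule: rank by
$\min(\mathrm{MCC}_{cv}, \mathrm{MCC}_{ext})$, tie-break by the mean,
then by fewer members. The rule is symmetric in the two estimates, guards
against a jury that excels on only one of them, and prefers parsimony.
The winner is retrained on the entire core set. Random elements (fold
shuffles, network initializations) all derive from one pipeline seed via
a counter-based map (`child_seed()`), so per-subset jury seeds depend on
the member mask, not on enumeration order, and adding a stage never
reshuffles earlier stages.

## Synthetic data: what it emulates and what it does not

`generate_peptides(motif_spec())` draws balanced binder/non-binder
octapeptide sets with planted anchors. Defaults — chosen once as the
package's study conditions — are the canonical H-2Kb motif positions
(3[Y], 5[Y,F], 8[L,M,I,V]), per-anchor enrichment 0.9, uniform background,
label noise 0.05, and 500 peptides per class. Non-binders accidentally
matching *all* anchors are rejected and redrawn. Under these conditions
the Bayes-optimal rule ("at least two anchors match") reaches MCC ≈ 0.84
against the noisy labels, so a well-implemented learner should land near
0.8 — which is what the package's validation runs require. The generator
emulates positional preferences and label noise only; it does not emulate
positional correlations, length variation, assay-specific biases, or the
redundancy structure of real epitope databases, so passing the recovery
tests demonstrates correctness of the machinery, not real-data accuracy.
Published performance on curated epitope-database snapshots is not
reproducible without those snapshots and is out of scope.

The package's validation runs use a reduced desk-scale configuration: the
three position-resolved descriptors (BINAATYPE, BINPEP, PPCA) × both
schemes (6 slots, exhaustive $2^6$ jury search), `reduced_grid_spec()`,
1,000 training peptides, and 1,000 freshly generated evaluation peptides;
the permutation-null run uses the BINPEP pair of slots. These sizes keep a
full recovery run in the minutes range on a single CPU while preserving
every structural element of the full architecture, whose combinatorics
($6 \times 2 = 12$ slots, $2^{12} = 4096$ juries) are verified separately.

## Epitope dissection and proteome scanning

`fragment_patterns()` enumerates every contiguous fragment (default:
length ≥ 3) of a reference octapeptide, pinned at its original register
with `x` (any residue) elsewhere — for SIINFEKL, 20 patterns from
`xIINFEKL` and `SIINFEKx` (20 peptides each) down to the tripeptide
groups ($20^5$ peptides). Groups with at most four wildcards
($20^4 = 160{,}000$, the default cap) are enumerated exhaustively; larger
groups are uniformly sampled at the cap with a recorded seed, since
scoring $20^5$ peptides per group exceeds a sensible interactive budget.
Groups are summarized by median and quartiles, matching how score
distributions of such libraries are reported. Only same-register
fragments form a group — a shifted fragment occupies different binding
pockets and is a different hypothesis.

`position_effect_profile()` scores, for each position, the group with
only that position randomized and reports the median's drop against the
reference's own score; planted (or real) anchor positions show the
largest drops. `scan_proteome()` slides the scoring window over protein
sequences (1-based inclusive coordinates, forward sequence only — proteins
have no strand), skips and counts windows containing non-canonical
residues, and reports the fraction of windows at or above a confidence
threshold (default 0.99).

## Thermal-shift analysis

Melting curves (temperature vs fluorescence, about 25-99 °C) are min-max
normalized, smoothed with a centered moving average (default 5 points —
wide enough to suppress single-point reader noise at a 0.5 °C sampling
interval, narrow enough not to bias a 2-3 °C-wide transition), and
differentiated numerically. The melting point is the most prominent
interior local extremum of dF/dT within the analysis segment (default
35-90 °C, bracketing the unfolding transition of the peptide-binding
superdomain while excluding early-ramp and post-aggregation artifacts;
configurable). The analyzed readout descends through the transition, so
the extremum is a *minimum* by default; `extremum = "max"` serves
ascending dye-gain readouts, which the simulator can also produce
(including a post-transition dye-quench decay). Two safeguards avoid
false melting points: candidates must lie within 10% of the segment's
deepest derivative value (numerical ripple in flat regions never
qualifies), and extrema pinned at the segment boundary are flagged
(`boundary-minimum`) rather than reported. A parabola through the
extremum and its neighbours interpolates Tm off the sampling grid, so a
symmetric transition is recovered exactly rather than to half a grid
step.

Relative binding maps replicate melting points linearly onto the control
span: the no-ligand control mean defines 0%, the positive reference mean
100%. A Tm-linear mapping is the simplest monotone choice consistent with
that anchoring; area- or fit-based alternatives would need raw-curve
access and are not implemented. Significance per ligand is a one-sided
Welch test (unequal variances, Welch-Satterthwaite degrees of freedom)
against the no-ligand control, with p = 1 by convention when both groups
are constant and equal. Replicates default to quadruplicates.

## Numerical choices and degenerate inputs

* MCC with any zero denominator factor is defined as 0; the empty
  confusion table is an error.
* Grid ties resolve to the first configuration in grid order; jury ties
  resolve by the selection rule's parsimony step.
* Non-converging hyperparameter configurations are skipped with a
  warning, never silently ranked.
* Constant property-scale columns are dropped with a warning before the
  PCA; a matrix with fewer than 20 informative scales, or identical rows,
  is an error.
* Constant-fluorescence curves, segments outside the curve range, and
  conflicting control means are errors, not NAs.

## Known limitations

* Absolute PPCA scores depend on the bundled property-scale collection.
* The faithful stacking default is optimistic by construction; use
  `stacking = "cv"` for unbiased jury training inputs.
* One model handles one allele and one peptide length; the length is
  fixed at training time and enforced at prediction.
* Tri- and tetrapeptide fragment groups are sampled, not exhausted, above
  the enumeration cap.
* The Tm-linear relative-binding mapping is an interpretation; panels
  whose curves lack a detectable transition are excluded by the
  no-minimum/boundary flags rather than extrapolated.
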