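---
title: "Screening bone-proteome biomarkers for late postmortem interval classes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening bone-proteome biomarkers for late postmortem interval classes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pmiscreen)
library(dplyr)
```

## The problem

Estimating how long a person has been dead (the postmortem interval,
PMI) from skeletal remains is notoriously hard once soft tissue is gone,
and essentially unstandardized for intervals beyond five years ("late
PMI"). Bone proteomes degrade slowly and unevenly: blood-derived and
cytoplasmic proteins disappear within the first years, while proteins
bound to the mineralized matrix — collagens, proteoglycans — persist for
decades. Label-free quantification (LFQ) of bone protein extracts
therefore carries a usable temporal signal, but at forensic sample sizes
(a handful of donors per PMI class) classical statistics cannot exploit
it. `pmiscreen` implements a protocol for that regime: build
per-condition proteomes from an LFQ abundance table, profile them
biochemically, explore them by unsupervised ordination, and then screen
for a minimal panel of proteins whose abundances let a random-forest
classifier separate PMI classes with sustained performance under
resampling.

## The data model

The package's interchange unit is a wide abundance table: one row per
sample, one column per protein, intensities from MS1-based label-free
quantification. A protein not identified in a sample is an explicit
missing value (`NA`), never a zero: whether and how to impute is a
modeling decision, and the package makes it visibly (zero-filling, the
conventional below-detection stand-in, is applied inside the ordination
and modeling steps, not in the data).

A sample annotation table assigns each sample a PMI class (`PMI1`,
`PMI15`, `PMI20`), a bone type (`rib`, `tibia`), a search type
(`tryptic` or `semitryptic`, i.e. whether the upstream database search
allowed peptides cleaved canonically at only one terminus — degradation
products that matter in old samples), and a replicate index. A
*condition* is a (PMI class, bone) pair with five biological replicates.

## Proteome sets and biochemical profiles

The *consistent proteome* of a condition is the set of proteins
identified in **all** of its replicates (`consistent_proteome()`); this
consistency filter trades diversity for reliability, which is the right
trade for a forensic tool. The *representative set* of a search type is
the union of the per-condition consistent proteomes
(`representative_set()`), and `intersection_counts()` tabulates every
membership signature across conditions, UpSet-style.

`biochem_profile()` computes, from supplied FASTA sequences, the average
molecular weight (sum of average residue masses plus one water,
18.0153 Da) and the acidic (D, E) and basic (K, R, H) residue
percentages. Histidine is only weakly basic at physiological pH, so its
inclusion is a flag (`include_histidine`). `early_late_contrast()`
compares the proteins seen early but in no late condition against the
late-persistent set, using a Shapiro–Wilk-gated two-group test
(`compare_groups()`: equal-variance t-test when both groups look normal
at `alpha = 0.05`, otherwise a Mann–Whitney U test — both two-sided;
groups of fewer than three proteins are reported without a test). The
expectation from bone chemistry is that late-persistent proteins are
heavier and more acidic: acidic side chains bind the amphoteric
hydroxyapatite surface, which protects them from proteolysis.

## Ordination

`standardize_abundance()` zero-fills and then standardizes each protein
column to mean zero and *population* standard deviation one, matching
the common machine-learning scaler convention, and drops constant
columns with a warning. `pca_abundance()` is plain PCA of the
standardized matrix; explained-variance ratios are eigenvalue shares.
`kmeans_components()` clusters ordination scores with Lloyd's algorithm
under k-means++ seeding, keeping the best of 25 restarts by
within-cluster sum of squares; base R's `kmeans()` supplies the Lloyd
iterations but not the seeding, so the initialization is implemented
here. `mca_presence()` performs multiple correspondence analysis of the
presence/absence matrix via the complete disjunctive table: two
indicator columns per protein, SVD of the standardized residual matrix
$D_r^{-1/2}(P - rc^\top)D_c^{-1/2}$, principal row coordinates, and
per-dimension inertia shares. Single-state proteins are dropped with a
warning; identical samples give zero inertia and a degenerate flag.

In bone data the dominant abundance contrast is anatomical, not
temporal: tibia (compact, poorly vascularized) retains matrix proteins
that ribs lose. The ordinations are therefore expected to cluster by
bone type rather than PMI — which is precisely why the supervised
protocol below exists.

## The random-forest protocol

The classifier is a probability random forest (`ranger`), configured by
`rf_config()` with the scikit-learn-style field names the protocol was
defined in: `n_estimators`, `max_depth`, `min_samples_split`,
`min_samples_leaf`, `max_features = "sqrt"`. The randomized search
(`hyperparameter_search()`) samples configurations from the declared
grid (`rf_grid()`: 100–499 trees, depth in {5, 10, 15, 20}, split/leaf
minima fixed at 2), holds out a stratified 40% of samples, and scores
each candidate by stratified 3-fold cross-validated accuracy on the
remaining 60% — 3 folds being the largest feasible at ten samples.
`rf_preset()` ships the published per-stratum selections; the
448-tree/depth-15 configuration is the default for tibia models.

`resampled_evaluation()` is the protocol's backbone: `n_iter` (default
100) iterations, each drawing a stratified 80/20 train/test split with
seed `base_seed + i` (also the forest seed, making the whole trace
reproducible), recording test accuracy, macro-averaged F1, normalized
Mean-Decrease-in-Gini importances, and exact per-class SHAP values for
the test samples. Stratification matters: with five samples per class an
unstratified 80/20 split can produce single-class training sets. After
the planned iterations every sample must have appeared at least once in
a training and once in a test set; if not, extra iterations are appended
and logged. Macro-averaged F1 equals weighted F1 here because classes
are balanced by design.

### Exact SHAP values

No SHAP library exists in this package's R dependency set, so the
attribution engine is implemented in C++ (`treeshap_ranger()`): for each
tree, the conditional expectation $v(S)$ descends the tree, following
splits on features in $S$ and averaging children by in-bag cover
otherwise, and Shapley values over the features the tree actually uses
are computed by direct subset enumeration. At ten samples with leaf size
two a tree has at most three internal splits, so enumeration is exact
and fast; the engine refuses trees using more than 25 features. Forest
values average over trees, giving local accuracy by construction:
`base + sum(shap) = predicted class probability`, asserted to `1e-6` in
the test suite and verified against an independent R implementation
built on `ranger::treeInfo()`.

### Feature scale

Models run on `log10(1 + x)` features by default (`feature_scale`).
Trees are invariant to monotone transforms except for one detail that
matters greatly here: split thresholds are midpoints between training
values, and on the raw intensity scale a midpoint between $10^{9.97}$
and $10^{7.16}$ lies at $\sim 10^{9.67}$ — just below the higher group.
A legitimately low draw from the high class then lands on the wrong side
of the threshold even though the class ranges are separated by orders of
magnitude, which corrupts attributions (and, in larger panels, votes).
On the log scale the threshold falls mid-gap, several standard
deviations from both classes. The raw scale remains available.

## Variable screening

`minimal_biomarker_search()` iterates toward a minimal panel:

1. **Round 0** evaluates the full representative set.
2. **Round 1** keeps proteins whose mean importance share strictly
   exceeds `threshold` (default 4%), applied once, up front.
3. Each later round drops up to `batch` (default 2) proteins selected by
   the SHAP rule and retrains; the loop stops when no protein qualifies
   or only one would remain.

The SHAP rule works on per-class summaries pooled over each class's
*own* test samples (`shap_summary()`). That pooling choice is load
bearing: pooled over all test samples, every informative protein's
median vanishes by symmetry in a balanced two-class design (equal and
opposite attributions on the two classes), and no median-based rule can
work. Restricted to own-class samples, a genuine marker shows a large
positive median and a nonnegative lower tail, while an uninformative or
chance-correlated protein hovers near zero and dips negative whenever it
misleads the model. A protein qualifies for elimination when (a) in
every class its pooled |median| is within `epsilon` (default 0.75) of
zero relative to the largest absolute pooled value, and (b) its pooled
5% lower-tail quantile is negative in at least one class. The tail
quantile, not the raw minimum, carries the decision: the minimum of
hundreds of pooled values flags one-off events. The `epsilon` band is
deliberately permissive — it only shields proteins whose attributions
sit at the very top of the observed range — because the negative-tail
condition is the sharp criterion. Qualifying proteins are removed
deepest tail first, at most `batch` per round, and the survivors are
re-assessed on the retrained model: a spurious competitor poisons the
attributions of genuine markers, so its removal must precede any verdict
on them.

Termination reports the best-performing round (performance first, then
the smaller panel). If that panel meets the `target` (default 1.0, i.e.
100% mean *and* minimum accuracy and F1), a leave-one-out check
certifies whether any single remaining protein could be removed without
falling below target. The certificate is reported (`loo_minimal`) but
does not prune by default: a panel of mutually redundant markers — each
individually sufficient, as planted markers with disjoint class ranges
necessarily are — fails the strict certificate while being exactly the
panel the screening rules support. `prune_loo = TRUE` enables
certificate-driven pruning (drops tagged `leave-one-out`) for users who
want the smallest sufficient set instead.

## The synthetic study generator

`synthetic_spec_default()` encodes the reference design: five conditions
(PMI1 rib; PMI15 and PMI20, rib and tibia) with five replicates each —
25 samples — over the 21-protein semitryptic panel. Intensities are
log10-normal (`sd` 0.3 on the log scale; LFQ intensities are positive
and heavy-tailed), and three planted biomarkers (PGS1, K1C13, CO3A1)
receive class-conditional means separated by 2.5–3 log units — more than
six standard deviations, so their intensity ranges cannot overlap
between PMI classes, an arithmetic property `validate_synthetic_spec()`
checks up front. Non-planted proteins carry no PMI signal in their means
but suffer PMI-dependent identification dropout (detection probability
0.95 / 0.80 / 0.65 for PMI1 / PMI15 / PMI20), emulating proteome decay;
the collagen family gets a +0.8 log10 bone effect in tibia. These
defaults were fixed once as the package's reference conditions.

What the generator does *not* emulate is worth stating plainly: no
correlated protein modules (real collagens co-vary; here non-planted
proteins are independent), no shared-run batch effects, no
intensity-dependent missingness, no peptide-level noise, and planted
markers are cleanly separable by construction. Consequently a passing
test suite shows that the protocol recovers signal of the planted kind
under realistic noise and dropout — not that three proteins suffice in
real casework. Two emergent properties of the small-sample regime are
faithfully reproduced, and the screening rules are designed around them:
with ten fixed samples, some "noise" protein orders the two classes
perfectly by chance in roughly one study in ten (18 independent proteins
at $2 \cdot 5!\,5!/10! \approx 0.8\%$ each), and such a protein is
genuinely indistinguishable from a planted marker within that dataset;
and label-permuted data yield per-dataset accuracies far from 0.5 in
either direction, because the resampled iterations share one fixed
geometry — the chance-level check in the tests therefore averages over
independent permuted datasets rather than trusting a binomial band on
dependent predictions.

## Problem sizes and numerical choices

The test suite exercises the protocol at the study's own scale: 100
resampling iterations for the headline performance and recovery checks,
20 independently seeded studies for the recovery rate, 15 permuted
datasets of 20 iterations for the null, and brute-force oracles at
$n \le 12$ (exhaustive 2-partitions for k-means, dense eigen/SVD
recomputation for PCA/MCA, subset-enumeration Shapley values per tree).
Determinism is part of the contract: every stochastic step derives its
seed from a base seed, and reruns are bit-identical.

Other numerical choices: population (not sample) standard deviation in
the scaler; explained-variance ratios over all eigenvalues so they sum
to one at full rank; class-probability ties broken toward the first
factor level; importances normalized to shares (all-zero when no forest
split); Shapiro–Wilk inapplicable to constant groups, which are treated
as non-normal; FASTA I/O via `seqinr`.

## Limitations

The protocol certifies internal resampling performance only. With five
samples per class, a no-free-lunch caveat applies to any selection
procedure: panels that include a chance-perfect competitor are expected
in a minority of datasets, and only external validation can remove them.
The leave-one-out certificate is deliberately strict and will rarely
hold for redundant marker panels; read `sustained` and `loo_minimal`
together. Nothing in the package fetches sequences or intensities from
external services; all inputs are files or generated objects.
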