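---
title: "ISE models for ligand-based screening: methods and design notes"
author: "isescreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ISE models for ligand-based screening: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isescreen)
```

## The model

An ISE classification model is an ensemble of *filters*. Each filter is a
conjunction of exactly five closed value ranges on five distinct 2D
molecular descriptors; a molecule passes iff all five of its values lie
inside the ranges. Filters are scored on a learning set of actives diluted
with property-matched decoys (typically 100 decoys per active; 1000:1
better approximates real screening odds when compute affords it) by the
Matthews correlation coefficient,
$$\mathrm{MCC} = \frac{TP \cdot TN - FP \cdot FN}
{\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}},$$
the appropriate measure at extreme class imbalance. Any zero factor under
the root yields MCC = 0 by convention.

A screened molecule is scored by every filter: with weight $w_f$ it gains
$+w_f$ on a pass and $-w_f$ on a fail, and the normalized sum
$$\mathrm{index} = \frac{\sum_f w_f(\delta_{\mathrm{pass}} -
\delta_{\mathrm{fail}})}{\sum_f w_f} \in [-1, +1]$$
ranks the library. Unit weights are the default reading (the index is then
exactly (passes − fails)/n); MCC and F-score weighting are provided
because the scoring prose of the source protocol invokes both without
fixing one — the choice is recorded in the model and its JSON
serialization.

## The search

The candidate space per descriptor is built from quantile bins of the
active-class distribution: `n_bins` bins (default 8) give
`n_bins (n_bins + 1) / 2` contiguous-union candidate ranges. Actives
define the relevant region of each property, and contiguous unions keep
the space enumerable; each candidate carries its single-descriptor MCC.
With $d$ descriptors the filter count is the degree-5 elementary symmetric
polynomial of the per-descriptor range counts — about $10^{12}$ for 20
descriptors at the default binning — so enumeration must be preceded by
elimination:

1. Sample `sample_size_t` filters uniformly (five distinct descriptors,
   one surviving range each; default 10^5 per iteration) and record each
   filter's MCC.
2. For every range, accumulate its observation count, the mean MCC of
   filters containing it, and its share of appearances in the top and
   bottom deciles of the sampled score distribution.
3. Eliminate ranges observed at least `min_observations` times (default
   30) whose mean MCC falls strictly below the `elim_fraction` quantile
   (default 0.2) of eliminable ranges *and* that are over-represented in
   the bottom decile (share > 0.1) while under-represented in the top
   decile (share < 0.1). A tie at the quantile cut never splits: tied
   ranges are all kept.
4. Repeat until fewer than `exhaustive_threshold` (10^6) combinations
   remain, then enumerate all of them and retain the top
   min(`max_filters` = 1000, `retain_fraction` = 20%) by MCC.

Two safeguards keep the loop sound. A descriptor is never reduced below
`min_ranges_per_descriptor` surviving ranges (default 1), so the catalog
cannot collapse; and the elimination quantile is computed over ranges that
are actually eliminable — otherwise the search deadlocks once weak
descriptors are pinned at the floor while strong descriptors hold all the
surviving ranges. If an iteration still eliminates nothing, it is retried
with the decile condition relaxed (mean-MCC criterion alone), which
guarantees progress; the decile condition is a conservative protection for
under-sampled ranges, not the engine of the search.

### Robust bin edges

Bin edges are placed on the active values after discarding points outside
median ± 3.5 MAD (per descriptor; values outside the fence are still
*scored*, only ignored for edge placement). The motivation is label noise:
a few decoys mislabelled as active otherwise stretch the outermost
quantiles across the whole decoy support, and no candidate range can then
express a compact active-property box. For a unimodal active class the
fence is wider than the class support, so with clean labels the edges are
the plain active quantiles. `mad_fence = NULL` disables it.

### Determinism and tie-breaks

All stochastic steps consume R's RNG, seeded once from the configuration,
so identical inputs and seed reproduce a model bit-for-bit (the JSON
serialization uses 17 significant digits and round-trips exactly; it
deliberately carries no wall-clock field). Descriptors are ordered
lexicographically (C locale) and ranges by (low, high); exhaustive
enumeration follows that order, and the final sort by MCC is stable, so
ties resolve lexicographically on (descriptor names, low, high)
everywhere. Intervals are closed on both ends.

## The surrounding protocol

**Curation.** Activity records (agonists with EC50, antagonists with IC50
or Ki, values in nM) pass a fixed rule sequence: flagged database comments;
non-"=" qualifiers; potency above 100 µM; confidence not above 7; an
explicit exclusion list (e.g. approved drugs, to keep external validation
honest); duplicates collapsed to the *worst* (largest) value; and a small
structural-alert list for reactive/mutagenic groups (configurable off).
The source protocol lists these criteria without an order; the order here
is fixed so the audit — one first-matching rule per dropped record — is
reproducible. An optional highly-active threshold (10 or 100 nM) is
exposed but off by default, since the protocol applies it only to unnamed
models.

**Decoys.** The applicability domain is the per-property mean ± 2 SD box
over the actives' MW, clogP, HBA and HBD; SD is the sample (n − 1) form.
Decoys are drawn uniformly without replacement from the eligible pool; a
short pool returns everything eligible with a shortfall flag rather than
an error, so small demonstration pools work.

**Cross-validation.** Stratified k-fold (default 5) deals each class
cyclically after shuffling, so per-fold class counts are within one
molecule of exact stratification; below 20 actives the scheme switches to
leave-one-out over actives with decoys dealt evenly alongside. Per fold, a
model is built on the remaining folds (fold-derived seeds) and the
held-out fold scored. The report gives the mean training top-filter MCC
across folds (a top-5 variant is also computed), the pooled AUC over raw
held-out indices (rank-normalizing per fold was the alternative; raw
indices are comparable because the index is already normalized to
[−1, 1]), TPR/TNR at index > 0, and the EF of the pooled top fraction.

**Validation nulls.** Y-randomization places the observed number of
interactions uniformly at random (without replacement within a replicate)
in the drug × target frame and measures how many land on
predicted-positive cells; the mean converges to the predicted-positive
density. Diversity is reported as mean pairwise Tanimoto similarity of
atom-pair fingerprint sets, with Tc < 0.7 flagged as diverse; two empty
fingerprints give Tc = 0 by convention.

## The descriptor panel

The shipped 2D panel (58 descriptors) covers the seven families used to
characterize such models: physical properties (MW, logP, TPSA, MR, HBA,
HBD via OpenBabel), atom/bond counts, pharmacophore feature counts (SMARTS
definitions), Gasteiger partial-charge statistics, charge-binned
approximate atomic surface areas, adjacency/distance-matrix indices
(Wiener, Balaban J, Zagreb, eccentricity/Petitjean), and Kier–Hall
connectivity and shape indices (χ⁰, χ¹, valence variants, κ₁–κ₃). It is an
open-source approximation *by family*: no attempt is made to reproduce any
proprietary descriptor panel numerically, and the family map ships as a
CSV so models can be profiled by family occupancy. Constant descriptors
and one member of every pair with |Pearson r| > 0.9 (the later-listed
column, deterministically) are pruned before modeling.

Standardization keeps the largest carbon-containing component of
multi-component SMILES and assigns the dominant protonation state at pH
7.4 (aliphatic amines protonated, carboxylic acids deprotonated) before
canonicalization. Tautomer enumeration, 3D descriptors and conformers are
out of scope. One caveat: components are split textually at ".", so the
rare legal SMILES whose ring closure spans a dot is not supported.

## The synthetic generator

`generatePlantedFixture()` emulates the actives-vs-decoys structure of a
curated learning set with known ground truth: decoy descriptors are
uniform on a broad support ([0, 100]), each planted box is a
five-descriptor range of width 16 on its own descriptor quintet, actives
are drawn as truncated Gaussians (σ = width/6) inside *every* planted box,
and decoys falling inside any box are resampled. Multiple boxes therefore
model redundant signal — each planted filter alone separates the classes
perfectly — rather than subpopulations; this is what makes "top filter
MCC = 1.0" a well-defined recovery target with more than one box. Label
noise swaps `round(noise_rate · n_actives)` active labels with as many
decoy labels: flips at a fixed fraction of *all* labels would swamp the
minority class at 100:1 dilution, while the balanced swap preserves class
sizes and keeps the planted boxes the geometrically correct classifiers.
At the reference conditions (100 actives, 10,000 decoys, 20 descriptors,
5% noise) the planted filter's attainable MCC is ≈ 0.95.

What passing these fixtures does *not* show: real descriptor distributions
are correlated, heavy-tailed and discrete in places, real activity is not
a single axis-aligned box, and real decoys are only presumed inactive.
The planted geometry validates the search and the scoring machinery, not
chemical generalization; the toy SMILES generator (arylpiperazine-like
actives vs small fragments) exercises the chemistry path end to end but is
deliberately easy.

## Problem sizes used by the tests and the acceptance script

Planted-recovery runs use the reference 100 + 10,000 molecule fixtures
with the per-iteration sample reduced to 3 × 10⁴ (at 20 descriptors every
range is still observed ≈ 200 times per iteration, comfortably above the
`min_observations` floor of 30, and recovery is unchanged). Oracle
comparisons run on 6-descriptor/2-bin catalogs (1458 combinations) where
full brute-force enumeration in plain R is itself cheap; cross-validation
checks use 2-bin catalogs so each fold enumerates ≈ 6 × 10⁴ filters
exhaustively. The shuffled-label null is asserted on the mean pooled AUC
over seeds: a single-seed null AUC at these set sizes has standard
deviation ≈ 0.03, so the mean is the quantity with a stable expectation.

## Known limitations

- The descriptor panel approximates commercial panels by family only;
  models built on different panels are not comparable filter-for-filter.
- The elimination statistic (mean MCC plus decile representation) is one
  reasonable reading of "eliminate values with bad scores at the extremes
  of the score histogram"; the source protocol does not specify the
  statistic, the per-iteration sample size, or the discretization, and all
  are configurable.
- Whether the 20% retention applies before or after the 1000-filter cap is
  ambiguous in the protocol; the implementation takes the minimum of the
  two.
- Index-based ranking produces heavy ties on small models; downstream
  rank statistics treat ties as one half.
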