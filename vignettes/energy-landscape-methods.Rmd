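---
title: "Energy-landscape analysis of binarized brain-network dynamics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Energy-landscape analysis of binarized brain-network dynamics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(statescape)
```

# The model

`statescape` characterizes the dynamics of K interacting systems (in the
reference application, seven large-scale brain networks: DMN, SMN, auditory,
FPN, salience, attention, visual) whose continuous activity has been reduced
to binary states $\sigma_i^t \in \{-1, +1\}$ (+1 active). The probability of
observing an activity pattern $V = (\sigma_1, \ldots, \sigma_K)$ is modelled
by the pairwise maximum-entropy (Ising) model

$$P(V) = \frac{e^{-E(V)}}{\sum_W e^{-E(W)}}, \qquad
  E(V) = -\sum_i h_i \sigma_i - \tfrac12 \sum_{i \ne j} J_{ij} \sigma_i \sigma_j ,$$

the least-structured distribution that reproduces the observed activation
rates $\langle\sigma_i\rangle$ and pairwise co-activations
$\langle\sigma_i\sigma_j\rangle$. "Energy" here is a statistical index —
the negative log unnormalized probability — with no biological meaning:
low-energy patterns are frequent and stable. The $\tfrac12$ in front of the
coupling sum is a convention; because the fit adapts $J$ to the data, every
probability-level output (and hence the whole landscape analysis) is
invariant to it.

Assumptions worth keeping in mind: stationarity over the recording (one set
of $h, J$ per participant or group), binarization at the per-network
temporal mean (which roughly balances active/inactive states), and no
higher-than-pairwise interactions.

# Preprocessing

`average_network_activity()` collapses region-level series to per-network
means; `binarize_mean_threshold()` thresholds each network at its own
temporal mean, strictly above → +1, otherwise −1. The tie rule (a value
exactly at the mean is inactive) matters only for degenerate discrete data
— it is measure-zero for continuous signals — but a deterministic choice is
required for reproducibility. Constant columns binarize to all −1 with a
warning rather than an error, so a degenerate network does not silently
change sign conventions. Binarization is per participant and per network
*before* any concatenation; group-level model fits concatenate the
participants' binary series in roster order.

`binary_similarity()` is the fraction of time points on which two binary
series agree (computed in 1/0 coding; equal to 1 − Hamming/N), used to
justify collapsing similar systems into one network.
`split_dmn_by_seed()` implements the seed-based split of the default-mode
network for the finer 8-network parcellation: per-ROI correlations with the
two seeds, Fisher z-transformed (atanh with |r| clamped at $1-10^{-12}$),
averaged across participants, assigned by the larger mean z.

# Model fitting

`fit_mem()` performs moment-matching gradient ascent from zero
initialization:

$$h_i \mathrel{+}= \eta\,(\langle\sigma_i\rangle - \langle\sigma_i\rangle_m),
\qquad
J_{ij} \mathrel{+}= \eta\,(\langle\sigma_i\sigma_j\rangle -
\langle\sigma_i\sigma_j\rangle_m),$$

with the model moments computed by exact enumeration over the $2^K$
patterns (K is capped at 20; everything here is $O(2^K)$, and K = 7 means
128 patterns). The log-likelihood is concave, so the fixed point is unique
and the outcome is independent of the learning rate within its stability
range — a property the test suite asserts directly. Defaults: $\eta = 0.2$
applied as $0.2/K$, tolerance $10^{-5}$ on the maximum absolute moment
discrepancy, at most $10^6$ iterations (non-convergence is flagged on the
report, not an error). These are package choices; they reproduce the
empirical pattern probabilities to r > 0.99 at the sample sizes used here.

Goodness of fit (`fit_accuracy()`) is quantified two ways: the Pearson
correlation between the model and empirical appearance probabilities over
all patterns, and the proportion of the first-order model's
Kullback–Leibler divergence that the pairwise model removes,
$(D_1 - D_2)/D_1$, where the first-order model is the independent-network
fit ($J \equiv 0$, $h_i = \operatorname{atanh}\langle\sigma_i\rangle$).
Zero-probability empirical patterns contribute nothing to either KL term.
If the data carry no pairwise structure, $D_1 \approx 0$ and the accuracy
is flagged undefined rather than reported as a ratio of noise.

# The energy landscape

`build_landscape()` enumerates all $2^K$ energies. Patterns form a
hypercube graph (adjacent iff Hamming distance 1). A **local minimum** has
energy strictly below all K neighbours; on a perfectly flat landscape the
strict inequality yields none. **Basins** (`assign_basins()`) come from
steepest descent — move to the lowest-energy neighbour while one is lower —
with exact ties broken toward the lower pattern code (again measure-zero
but deterministic); a descent that stalls on an exact plateau is an error
naming the tied patterns, never a silent guess. Basin sizes are fractions
of the $2^K$ patterns.

The **disconnectivity graph** (`build_disconnectivity_graph()`) encodes at
what threshold energy two minima disconnect when all patterns at or above
the threshold are removed. The merge energy of two minima equals the
minimax barrier — the smallest over connecting paths of the largest energy
on the path — and is computed by a single ascending sweep with union–find,
which is equivalent to the descending-threshold procedure but runs in
near-linear time. Tests verify the equivalence against an independent
bottleneck-path oracle on random landscapes. Adding a constant to all
energies shifts merge heights by that constant and changes nothing else.

**Brain states** (`define_brain_states()`): the four canonical states are
two major states (each typically a pair of deep minima on one branch of the
tree) and two minor states, jointly the *intermediate state*. The grouping
of minima into states is explicit by default — in the reference analysis it
came from inspecting the hierarchy. The automatic mode cuts the tree at a
barrier level: minima merging below the cut share a state, and clusters are
ranked major/minor by total basin size. The default cut sits in the widest
gap of the sorted merge energies among cuts producing two to four clusters.
This rule was chosen over "always cut into four clusters" because a fitted
landscape may lose a shallow minimum to sampling noise; a fixed-k cut then
splits a true major pair, whereas the gap rule simply reports the lost
minor state as empty. A user-set `auto_cut` overrides the heuristic.

# Dynamics

`metropolis_walk()` simulates the Metropolis–Hastings chain: propose one of
the K neighbours uniformly, accept with $\min(1, e^{E_{cur} - E_{prop}})$.
Rejected proposals repeat the current pattern and the step count advances —
without counting stays the chain would not have the Boltzmann distribution
as its stationary law. Detailed balance is verified analytically over the
full $128 \times 128$ kernel in the tests. Defaults follow the reference
procedure: $10^5$ steps, the first 100 discarded, a uniformly random start,
and a mandatory seed (the caller's RNG state is untouched).

Trajectories map to state sequences through the basin partition — the same
code path serves simulated walks and empirical binarized volumes ("direct
counting"). Transition semantics (`classify_transitions()`):

* a **direct** transition is a single-step change between the two major
  states;
* an **indirect** transition is a *completed* passage
  major$_a$ → intermediate$^+$ → major$_b$, $b \ne a$. Excursions into the
  intermediate state that return to the same major state, and trajectories
  ending inside the intermediate state, count nothing. This is the
  strictest reading of a transition "via" the intermediate state; since
  both groups are scored identically, a looser reading would shift levels,
  not contrasts.

Transition frequencies are reported both per retained step and per label
change, since either normalization is defensible. `summarize_dynamics()`
adds per-state appearance percentages and major-state dwell times (lengths
of maximal constant runs in either major state).

`running_cv()` quantifies whether the two simulated indices (indirect
frequency, mean major duration) have settled: cumulative estimates at
checkpoints within a run, CV = sd/mean over the checkpoint window, averaged
over independent runs. This operationalization is the package's own
practical diagnostic; at the default $10^5$ steps the CVs of both indices
are of order $10^{-2}$ on the planted landscapes.

# Functional coordination

`network_fc()` computes pairwise Pearson correlations of the continuous
network series with clamped Fisher z transforms.
`segregation_strength()` is the mean z over within-module pairs minus the
mean over across-module pairs, for a two-module split of the networks. The
within-module mean pools both modules' internal pairs unweighted (the
alternative — weighting the two modules equally — differs only when module
sizes are very unequal; pooling is the simpler convention and is what the
formula "the average of within-module FC" suggests). The canonical module
splits ship as `planted_module_specs()`: the intermediate-state split
(DMN/SMN/AUD vs FPN/SAN/ATN/VIS) and the major-state split (DMN/VIS vs the
rest).

# Group statistics

`compare_groups()` uses the pooled-variance two-sample t (reported df
$n_1 + n_2 - 2$, matching how the reference results are quoted), a
label-shuffling permutation test with the two-sided add-one rule
$p = (\#\{|t^*| \ge |t|\} + 1)/(n_{perm} + 1)$ (default $10^4$
permutations, mandatory seed), and Cohen's d with pooled SD.
`chi2_residual_test()` is the Pearson chi-squared test with post hoc
adjusted standardized residuals
$(O - E)/\sqrt{E(1 - p_{row})(1 - p_{col})}$ and Bonferroni-corrected
flags; the correction factor is always passed by the caller, never guessed.
`correlate()` gives Pearson or residual-based partial correlations on
$n - 2 - k$ df. `two_way_anova()` fits the fixed-effects factorial model
with Type II sums of squares; the designs used here are balanced or nearly
so, where Type I and Type II coincide (asserted in the tests). One-sided
alternatives are never used; all permutation rules are two-sided.

# Diagnosis prediction

The univariate rule thresholds one dynamics index at
$(\min \mathrm{TD} + \max \mathrm{ASD})/2$ — the midpoint of the two group
extremes that face each other when the index is lower in the clinical
group. The side classified as ASD is derived from the training means
rather than hard-coded, so an index with the opposite polarity is handled
correctly. The bivariate rule is a soft-margin linear SVM on
(intermediate-state frequency, indirect-transition frequency), cost fixed
at 1 (configurable) and no feature scaling — both features are percentages
of comparable magnitude. Evaluation (`evaluate_classifier()`) treats ASD
as the positive class and *refuses to score the training cohort* unless
explicitly overridden, mirroring the train-on-one-site, test-on-other-sites
design. Individual-level landscapes for test participants use the same fit
defaults; a warning flags fit accuracies below 0.9, since individual fits
are known to be markedly less accurate than group fits.

# The synthetic cohort generator

Because the original fMRI recordings are out of scope, every pipeline stage
is validated against planted ground truth. The generator stores three ±1
patterns Hopfield-style in $J$: two overlapping "major" patterns (DMN+VIS
active; DMN+SMN+FPN+VIS active) at Hamming distance 2, whose wells form the
two-minimum branch of each major state (a pattern pair at distance 1 can
never be two strict minima), and one "minor" pattern (DMN+SMN+AUD active,
anticorrelated with the FPN/SAN/ATN/VIS module) whose well and its global
flip are the two minor states. A frozen random symmetric perturbation
breaks the exact degeneracies of the pure outer-product construction, and a
common inverse-temperature factor of 1.6 sets well depths so that walk
dwell times are in a realistic range. The accepted parameter set was found
by bounded search over the block magnitudes and ships frozen
(`planted_params()`); the tests assert its structure rather than re-derive
it.

The TD-like variant has six local minima with minor basins of 14/128
(≈10.9%) each. The ASD-like variant keeps the *same six minima* but raises
the minor wells (basins 4/128 and 2/128) and slightly strengthens the major
couplings. The second knob exists because weakening the minor coupling
alone raises the major minima relative to the direct saddle between the two
major basins and so *increases* direct transitions; with the compensation,
the exact stationary direct-crossing flux (computable from the Boltzmann
distribution and the kernel) matches between the variants to within 0.3%,
reproducing the reference phenotype — fewer indirect transitions, smaller
intermediate state, longer major dwell times, direct transitions unchanged.

Cohort defaults mirror the study conditions: 26 TD-like and 24 ASD-like
participants, 240 volumes each (an ~8-minute scan at a 2 s repetition
time), per-participant Gaussian jitter on $h$ (sd 0.05) and $J$ (sd 0.03)
for individual variability, and a continuous lift $\sigma_i^t +$ N(0,
0.3²) whose mean-threshold binarization recovers the binary series with
<5% error. Behavioural scores use the demographic table's means and SDs
(ADOS 1.2 ± 1.4 TD / 12.8 ± 3.6 ASD; FIQ 112.6 ± 12.0 / 109.9 ± 14.2) with
planted correlations to each participant's *ground-truth* indices: ADOS ~
indirect −0.47 (ASD), FIQ ~ indirect +0.46 (TD), FIQ ~ major-state duration
+0.55 (ASD). The score noise is orthogonalized against the index within
each group, so the planted correlation is exact in the generated sample —
attenuation observed downstream is then attributable entirely to
estimation error, which makes it testable.

Binary series are drawn i.i.d. from the exact categorical Boltzmann
distribution by default (possible because $2^7 = 128$; it removes burn-in
concerns from unit tests). A `markov` mode records Metropolis steps
instead, adding temporal autocorrelation closer to fMRI. The choice
matters for interpretation: i.i.d. sampling preserves pattern
*occupancies* (state sizes, intermediate-state frequency) but destroys
temporal persistence, so empirical per-participant transition and dwell
indices counted on i.i.d. series are occupancy-driven — empirical direct
transitions, for example, then differ between groups simply because major
occupancies differ, and empirical behavioural correlations are strongly
attenuated at T = 240. The pipeline therefore evaluates the dynamics
contrasts on the simulated walks of the fitted landscapes (as the
reference analysis did) and uses the empirical counts for occupancy
indices. What passing tests show about real data: the *method* recovers
planted structure and contrasts through the full chain
(binarize → fit → landscape → dynamics → statistics); they do not show
robustness to hemodynamics, scanner noise, motion artefacts or
non-stationarity, none of which the generator emulates.

# Numerical choices and degenerate inputs

* Boltzmann weights are exponentiated after subtracting the minimum energy;
  all outputs are invariant to constant energy offsets.
* Fisher z uses atanh with |r| clamped to $1 - 10^{-12}$.
* Steepest-descent and threshold ties are broken deterministically (lower
  pattern code); exact plateaus abort with a diagnostic.
* Exhaustive operations refuse K > 20.
* Every stochastic routine takes an explicit seed and restores the
  caller's RNG state; cohorts are bit-reproducible from
  (master seed, participant index).
* Degenerate statistics (zero pooled variance, constant correlates,
  $D_1 \approx 0$ accuracy, flat probability vectors) are flagged or raised
  as errors rather than returned as numbers.

# Problem sizes

The test-suite and acceptance runs use the sizes the analysis itself uses:
$2^7$-pattern landscapes, group fits on ~6,000 concatenated volumes,
$10^5$-step walks for dynamics indices (with $10^6$-step walks for the
Boltzmann-convergence check), $10^4$ permutations for the group tests, 20
master seeds for the contrast-recovery check, and $10^3$ replicates for the
type-I-error calibration. These run in a few minutes on one CPU.

# Known limitations

* All landscape operations are exhaustive; K beyond ~20 needs approximate
  minima search and pseudo-likelihood fitting, which are out of scope.
* The automatic state grouping assumes the two-major / up-to-two-minor
  structure; landscapes with more than four barrier-separated clusters at
  every cut level are rejected rather than forced into four states.
* The generator plants linear behavioural effects with Gaussian noise;
  real symptom scores are discrete, skewed and bounded.
* Empirical transition indices on i.i.d. synthetic series are
  occupancy-driven, as discussed above; use `series_mode = "markov"` when
  temporal realism matters.
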