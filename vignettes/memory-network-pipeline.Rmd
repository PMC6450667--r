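---
title: "Modelling memory quality and cortico-hippocampal connectivity with epiconn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling memory quality and cortico-hippocampal connectivity with epiconn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epiconn)
```

# The scientific problem

Continuous-report memory experiments ask participants to reproduce a
feature of a studied event on a circular space — a color wheel, or a
position in a 360° panorama scene — so that memory is measured as a graded
angular error rather than a binary hit/miss. When such a task is combined
with fMRI, two families of questions open up: behaviourally, whether the
different features of one event (its color, its spatial location, its
emotional association) are bound together or forgotten independently, and
neurally, how the hippocampus and the posterior-medial (PM) and
anterior-temporal (AT) cortical systems reconfigure their communication
when events are retrieved, and whether that communication tracks how much
and how precisely is remembered.

`epiconn` implements the full analysis chain for this paradigm: a circular
mixture model of response errors, trial scoring and a composite
memory-quality score, feature-binding dependency statistics, background
functional connectivity with graph metrics, and memory-modulated gPPI
effective connectivity — together with a synthetic-data generator that
plants known ground truth in every stage, so the entire chain is testable
without access to scanner data.

# The behavioural model

## Mixture model of angular errors

A response error $e$ (wrapped to $(-180°, 180°]$) is modelled as a mixture
of memory and guessing:

$$p(e) = (1-\gamma)\,\phi_\kappa(e) + \gamma \frac{1}{2\pi},$$

where $\phi_\kappa$ is the von Mises density with mean zero and
concentration $\kappa$ (higher $\kappa$ = more precise memory) and
$\gamma$ is the proportion of uniform guesses. `fit_mixture()` maximizes
the log-likelihood with L-BFGS-B from a 4 × 3 grid of starting values
($\kappa \in \{1,4,16,64\}$, $\gamma \in \{0.1,0.5,0.9\}$), because the
surface can be multimodal for small samples; $\kappa$ is bounded to
$[0.01, 500]$. The fit is deterministic given the data. Degenerate inputs
(all-identical errors) drive $\kappa$ into its upper bound and are flagged
with `boundary = TRUE` rather than erroring.

Angles are handled in degrees throughout the user-facing API and wrapped
to $(-180°, 180°]$ with a half-open convention (an error of exactly half
a circle is $+180°$); radians appear only inside density evaluation.
Under uniform guessing the expected absolute error is exactly 90°, the
chance level used for subject exclusion.

## Success thresholds and trial scoring

Given a fitted mixture, the posterior probability that an error came from
the memory component is

$$P(\text{memory} \mid e) =
  \frac{(1-\gamma)\phi_\kappa(e)}{(1-\gamma)\phi_\kappa(e) + \gamma/2\pi},$$

and `success_threshold()` solves $P = 0.5$ in closed form,
$\cos e^* = \log[\gamma I_0(\kappa)/(1-\gamma)]/\kappa$, falling back to
0° or 180° when the posterior never crosses one half. Ties at exactly 0.5
classify as correct. With the generator's default parameters the derived
thresholds are ±57° for color and ±28° for scene errors. Aggregate
("group") fits pool wrapped errors across all included subjects, and
exclusion (mean |error| ≥ 75° on either feature, the boundary inclusive)
is applied *before* aggregate fitting, so chance-level subjects cannot
distort the thresholds.

Per trial, each feature then receives: a binary success flag (inclusive
threshold), a precision (reversed absolute error, $180 - |e|$, defined
only on successful trials), and a contribution to the composite quality
score. The quality score sums the emotion score (0 incorrect / 0.5
low-confidence correct / 1 high-confidence correct) and, for each visual
feature, $1 - |e|/\text{threshold}$ on successful trials and 0 otherwise,
giving a 0–3 scale where 3 means everything remembered with perfect
precision.

*Design choice.* The scaling of precision into the quality score was
genuinely open: normalizing by the threshold (our default) makes the
score continuous at the success boundary, whereas normalizing by 180°
would leave a jump from $1 - \text{thr}/180$ to 0 at the threshold. Both
are implemented (`scaling = "threshold"` / `"half_circle"`); analyses in
this package use the continuous variant. Missing responses are scored
unsuccessful rather than dropped, which keeps trial counts intact for the
fMRI modulators.

## Dependency and precision correlations

For two binary success vectors, the observed dependency is
$P_{AB} + P_{A'B'}$ (proportion of trials remembered or forgotten
together) and the independent-model expectation is
$P_A P_B + P_{A'} P_{B'}$; `corrected_dependency()` reports their
difference. The statistic is symmetric under jointly relabeling
correct/incorrect and is still defined when a margin is degenerate (it is
then exactly zero). Precision relations are Pearson correlations, Fisher
z-transformed with $r$ clipped to $\pm(1-10^{-7})$; the
precision–precision correlation is restricted to trials where *both*
features were successfully recalled. Emotion counts as successful for
dependency whenever the response was correct, at any confidence.

# The connectivity models

## Background connectivity

Analyses are ROI-based: 12 bilateral regions assigned to PM (ANG, PREC,
PCC, RSC, PHC), AT (PRC, AMYG, FUS, ITC, OFC) and hippocampus (aHIPP,
pHIPP). Each run is denoised by a single least-squares projection:
intercept, linear trend, a discrete-cosine high-pass basis (cutoff 1/128
Hz — chosen over FFT filtering because it composes into one projection),
nuisance regressors, and — for background connectivity — all task and
memory regressors (HRF-convolved 6-s boxcars for encoding and remember
events, plus five mean-centred modulators per condition: emotion memory,
color/scene success centred over all condition trials, color/scene
precision centred over correct trials only and zero elsewhere). Residuals
therefore reflect covariation independent of evoked activity. If a
modulator is exactly collinear on a degenerate run (e.g. all trials
correct), it is dropped from that run's projection with a warning; rank
deficiency among base regressors is an error.

Connectivity per condition is the HRF-weighted Pearson correlation:
weights are the condition's HRF-convolved boxcar, negative lobes clipped
to zero, normalized to sum one — so scans acquired while the condition's
evoked response was present dominate the estimate. Matrices are
thresholded at $r \ge 0.25$ (sub-threshold entries set to zero, surviving
weights retained), and two metrics are derived per subject and condition:
Louvain modularity $Q$ (100 restarts from seeded RNG states, best
partition, resolution 1 — the algorithm is order-dependent, so restarts
are part of the contract) and within/between-network density. Density
means *include* thresholded zeros, so they respond both to how many
connections survive and to how strong they are; a surviving-edges-only
variant was considered and rejected because it confounds the count and
strength changes the task contrast is about. Negative correlations are
zeroed by any cut ≥ 0; there is no absolute-value option.

Group comparisons are within-subject: a paired t on modularity and
1-df contrasts for the 2 (task) × 2 (within/between) density design,
where each $F = t^2$ of the corresponding contrast.

## Memory-modulated connectivity (gPPI)

For gPPI the series are denoised with nuisance-only projections (task
structure must stay in the data) and each target ROI is regressed on:
per-run intercepts, the task regressors, the psychological regressors,
the seed series, and the seed × psychological interactions, formed in
BOLD space as the elementwise product of the observed seed and the
HRF-convolved modulator. No neural-level deconvolution is attempted — at
TR 1.5 s it is under-determined, and the BOLD-space convention matches
the established toolboxes for this analysis. The remember-event main
effect is kept in the model alongside the quality modulator, so the
interaction captures modulation beyond mere retrieval.

Model 1 uses the composite quality score, mean-centred across remember
events. Model 2 enters all five feature modulators and their five
interactions jointly, so each beta is that feature's *unique*
contribution. The interaction coefficients form an asymmetric seed ×
target matrix, summarized as means over the nine directed network pairs
(with aHIPP↔pHIPP as the within-hippocampus cell) and tested with
one-tailed one-sample t tests (better memory is predicted to increase,
not decrease, coupling) under Benjamini–Hochberg FDR within the nine-cell
family (all seed-target cells for feature analyses). An emotion-moderation
analysis fits split models on negative-only vs neutral-only trials
(centering within the subset) and contrasts the betas with a paired test;
split models were chosen over a three-way valence × modulator interaction
term because they match how the modulators are constructed. A univariate
variant (`activity_glm()`) tests which ROIs' mean activity tracks the
quality modulator.

# The synthetic-data generator

The generator is first-class, tested code; its defaults *are* the study
conditions every claim in this package is evaluated under.

**Behaviour.** 28 subjects × 6 blocks × 24 trials. Within a block each of
six panorama scenes hosts four trials whose target colors and locations
are pairwise ≥ 45° apart (rejection sampling; infeasible geometries
error), and valence is balanced. Responses follow the mixture model with
color $\kappa = 5.4$, $\gamma = 0.33$ and scene $\kappa = 27$,
$\gamma = 0.36$; emotion is correct with probability 0.76. These values
match the empirical regime of the paradigm. Feature dependency is planted
through a per-trial Bernoulli(0.5) latent memory state that shifts each
feature's retrieval probability by ±`dependency_strength` (default 0.15,
a mid-range value chosen once; the empirical magnitude is not published),
leaving marginal guess rates at $\gamma$ and never coupling precision
across features — so the dependency stage is falsifiable: success
dependency must appear, precision dependency must not. Emotion confidence
is a binary high/low attribute (p = 0.7 high among correct responses; the
acquisition protocol for confidence is not specified in the paradigm, so
the simplest attribute that supports the 0/0.5/1 coding was used.)

**Time series.** TR 1.5 s, 466 scans per run, six runs; encoding events
early in each run, remember events later, non-overlapping. ROI signals
sum a network-structured latent process, evoked responses (canonical
double-gamma HRF: gamma(6,1) response minus gamma(16,1)/6 undershoot,
unit peak — the standard kernel, as none is prescribed by the paradigm),
slow nuisance components with random loadings, white noise, and planted
interaction terms. The latent covariance uses a shared network signal
(within-network covariance 0.9), a global signal (between, 0.1), and a
remember-locked shared signal (`between_boost_remember = 2.5`) whose
amplitude follows the HRF-convolved remember regressor. With unit noise
these values put encoding within-network correlations near 0.47 and
retrieval between-network correlations near 0.43 — a regime in which the
planted retrieval reconfiguration (lower Q, disproportionate between-
network density increase) sits above every examined threshold up to
r = 0.3, as it does in real data of this kind. A homogeneous block model
cannot simultaneously match the *magnitude* of published between-network
densities (~0.15) and keep the signature above an r = 0.3 cut; we
prioritize the direction-and-robustness property, which is what the test
suite checks.

**Planted coupling.** Memory-modulated interactions are added as
$\beta \cdot x_{\text{seed}} \cdot m(t)$ with $m$ the centred,
HRF-convolved modulator, computed from a snapshot of the base signals so
each planted coefficient keeps its nominal value regardless of how many
pairs are planted. The default cohort plants $\beta = 0.25$ from PRC/PHC
onto both hippocampal ROIs plus the within-hippocampus pair; cortical
seeds are never targets, keeping their observed series clean. The
coefficient is deliberately modest: planting 0.5 on six pairs adds enough
remember-locked variance to the hippocampal ROIs to distort their
background correlations, and the default cohort is meant to exhibit the
behavioural, background-connectivity and gPPI phenomena *jointly*.
Recovery claims (planted 0.5 recovered within ±0.1) use a dedicated
single-pair scenario at the study-scale geometry — at the reduced test
geometry (16 trials, 240 scans) run-local denoising projections bias the
interaction estimate by up to ~25%, which is a property of that geometry,
not of the estimator.

**What the generator does not emulate.** No volumetric images, no motion
or physiological noise, no BOLD autocorrelation, no hemispheric or
voxel-level structure, homogeneous within-network covariance, and
independent white measurement noise. Passing tests therefore demonstrate
the *statistical machinery* — estimator correctness, calibration,
specificity, direction of planted effects — not robustness to realistic
fMRI artifacts. Two further honest caveats: (i) in the default cohort the
color- and scene-precision gPPI matrices are *positively* correlated,
because the planted coupling is the shared composite quality score that
both precisions feed; dissociation (near-zero pattern similarity)
appears, as it should, only when disjoint feature-specific couplings are
planted. (ii) In the joint five-modulator model the two precision
interaction regressors are mildly correlated, so their estimation errors
correlate slightly negatively (pattern similarity near −0.1 rather than
exactly 0 in the dissociation scenario).

# Problem sizes and numerical choices

The packaged analyses run at the study scale: 28 subjects, 144 trials
each, 6 runs × 466 scans × 12 ROIs (~2 minutes end to end including both
gPPI models). The test suite uses the `"small"` profile (4 subjects,
2 runs × 120 scans, 7 ROIs, 16 trials) for mechanics and the full profile
for all substantive claims: mixture recovery at n = 3000 × 20 replicates,
dependency calibration over 200 cohorts × 28 subjects, threshold
robustness over 20 cohorts × 5 cuts, gPPI recovery over 20 study-scale
simulations. Every stochastic operation takes an explicit integer seed;
per-subject seeds derive deterministically from the master seed
(`subject_seed()`), so identical configurations produce byte-identical
result bundles. Convergence tolerance for the mixture MLE is 1e-8 on the
log-likelihood; Louvain ties resolve to the first maximal-Q restart;
Fisher transforms clip $r$ at $\pm(1-10^{-7})$.

# Orchestration

`run_pipeline(run_config(...))` executes simulate → exclude →
aggregate-fit → thresholds → score → dependency → connectivity → gPPI and
returns (optionally writes) the full results bundle with a manifest. The
numbered scripts under `analysis/` run the same stages as a stepwise
narrative, writing tidy tables under `results/`; they are the intended
command-line surface of the package, with `scripts/acceptance.R`
recomputing the headline quantities as JSON.

# Known limitations

Beyond the generator caveats above: the mixture model has no swap
(misbinding) component and no bias parameter, matching the paradigm's
model; density and modularity are computed on a 12-node graph where
single-subject Louvain partitions are coarse; the gPPI leak between
correlated same-network seeds (a seed correlated with a planted seed
inherits part of its interaction) is inherent to regression on observed
seeds and is why specificity claims are phrased at the network-cell
level, not the single-pair level.
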