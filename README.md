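# epiconn

Analysis pipeline for continuous-report episodic memory experiments with
fMRI: circular mixture modelling of reconstruction errors, feature-binding
dependency, a composite memory-quality score, background functional
connectivity of cortico-hippocampal networks, and memory-modulated gPPI
effective connectivity — with a synthetic-data generator that plants known
ground truth in every stage.

## The problem

In a continuous-report memory paradigm, participants study objects with a
color drawn from a 360° spectrum, a location in a 360° panorama scene, and
an emotionally negative or neutral sound, then later reconstruct each
feature by moving around the circular space. Memory is measured as a
wrapped angular error (response − target), which separates *whether*
a feature was retrieved from *how precisely*. Combined with ROI time
series from the hippocampus and the posterior-medial (PM) and
anterior-temporal (AT) cortical systems, this supports three analyses:

1. **Behaviour.** Errors are modelled as a von Mises + uniform mixture,

   p(e) = (1 − γ) φ_κ(e) + γ / 2π,

   where κ is memory precision and γ the guess rate. The posterior
   probability that an error came from the von Mises component yields a
   success threshold (the |error| where the posterior crosses 0.5), trial
   scoring, precision (180 − |error| on correct trials), and a 0–3
   memory-quality score per trial. Feature binding is quantified by
   corrected dependency, (P_AB + P_A'B') − (P_A·P_B + P_A'·P_B').
2. **Background connectivity.** After projecting out task, memory and
   nuisance structure per run, HRF-weighted ROI correlations are computed
   separately for encoding and retrieval, thresholded at r ≥ 0.25, and
   summarized by Louvain modularity Q and within/between-network density,
   compared within subject across tasks.
3. **gPPI.** Each target ROI is regressed on per-run intercepts, task
   regressors, a memory modulator, the seed series, and the seed ×
   modulator interaction; the interaction betas form an asymmetric
   seed → target matrix whose network-pair means are tested one-tailed
   with BH-FDR.

The package is aimed at cognitive-neuroscience researchers who want these
stages as tested, seedable building blocks, and at methodologists who want
a generator with planted ground truth for validating estimators of this
kind.

## Worked example

The numbered scripts under `analysis/` run the full study-scale analysis
(28 subjects, 6 blocks × 24 trials, 6 runs × 466 scans at TR 1.5 s) on
simulated data:

```sh
Rscript analysis/01_simulate.R 42     # cohort with planted ground truth
Rscript analysis/02_fit_behavior.R    # exclusion, mixture fits, scoring
Rscript analysis/03_dependency.R      # feature-binding statistics
Rscript analysis/04_connectivity.R    # background connectivity + graphs
Rscript analysis/05_gppi.R            # memory-modulated connectivity
```

`02_fit_behavior.R` prints:

```
28 of 28 subjects included (chance-level exclusions: 0).
color: kappa 5.32, gamma 0.34 -> success threshold +/-57 deg
scene: kappa 27.37, gamma 0.36 -> success threshold +/-28 deg
Success rates: emotion 0.77, color 0.74, scene 0.68; mean quality 1.60 / 3
```

The aggregate fits recover the generating parameters (κ = 5.4 / 27,
γ = 0.33 / 0.36), and the derived success thresholds — the |error| at
which an observation is as likely to be memory as guess — land at ±57°
(color) and ±28° (scene). `03_dependency.R` then shows binding of the
gist but not of precision:

```
  dependency_emotion-color     mean +0.026, t(27) =   5.80, p = 0.0000
  dependency_emotion-scene     mean +0.032, t(27) =   5.36, p = 0.0000
  dependency_color-scene       mean +0.016, t(27) =   2.66, p = 0.0131
  colorPrec_sceneSucc          mean -0.004, t(27) =  -0.21, p = 0.8346
  scenePrec_colorSucc          mean +0.024, t(27) =   1.10, p = 0.2825
  colorPrec_scenePrec          mean -0.010, t(27) =  -0.48, p = 0.6368
```

Retrieval success is dependent across every feature pair (the planted
latent memory state), while precision is uncoupled — exactly the planted
structure. `04_connectivity.R` finds the retrieval reconfiguration
(modularity drops, t(27) = −264.8; between-network density rises
disproportionately, interaction F = 1198, direction stable across cuts
0–0.3), and `05_gppi.R` localizes the planted memory-quality coupling to
the hippocampal cells of the network matrix (PM→HIPP and AT→HIPP means
0.46, FDR-significant; all purely cortical cells null), with hippocampal
ROI activity tracking memory quality.

The same chain is callable in R:

```r
library(epiconn)
res <- run_pipeline(run_config(profile = "full", seed = 42))
res$thresholds          # derived success thresholds (deg)
res$dependency$group    # group dependency tests
res$connectivity$group  # encoding-vs-retrieval contrasts
res$gppi$network_inference
```

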