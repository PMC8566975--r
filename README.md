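# neurodep

Discovery of depression subnetworks from heterogeneous multi-subject
intracranial EEG (iEEG).

## The problem

Semi-chronic iEEG gives direct, millisecond-resolution recordings of
cortical and subcortical activity, but every patient carries electrodes
at different, clinically chosen sites. That heterogeneity defeats naive
group analyses. `neurodep` implements the full analysis chain that makes
such cohorts comparable and relates their network physiology to
depression status (PHQ-9 ≥ 10 depressed, ≤ 5 control):

1. **Preprocessing** — 2–250 Hz band-pass, 60/120/180/240 Hz notches,
   512 Hz resampling, common-average reference; 60 s blocks screened by
   Pearson kurtosis (≤ 10) and sampled across daytime hours.
2. **Correlational whole-brain model** — per-subject Fisher-z
   correlation matrices, radial-basis-function expansion to the global
   electrode set (`w = exp(−d²/width²)`, width 20 mm), evidence-weighted
   population averaging, and kriging reconstruction of unsampled sites,
   `ŷ_u = K_uo (K_oo + εI)⁻¹ y_o`, validated leave-one-patient-out
   against a shuffled-model chance control.
3. **Parcellation** — Louvain maximization of resolution-weighted
   Newman–Girvan modularity `Q = Σ_{ij∈same} (K_ij − γ k_i k_j / 2W)`,
   allegiance over repeated runs, a γ-sweep (0.5–2.1) selecting the
   atlas-similarity peak with fewest modules, participation coefficients
   `y_i = 1 − Σ_c (k_i(c)/k_i)²`, and provincial/connector hub tables.
4. **Spectral-spatial features** — 6-cycle Morlet power in 30 s windows
   across six bands (δ 1–4, θ 5–8, α 9–12, β 13–30, low-γ 31–70,
   high-γ 71–150 Hz), relative power, z-scored per electrode-band and
   averaged per module: 6 bands × 6 modules = 36 features per subject.
5. **Classification** — leave-one-out cross-validated PCA (4
   components) + L1 logistic regression with balanced accuracy, a
   1000-permutation label null, alternate models (L1/L2/elastic-net/
   random forest) and a line-length epileptiform control.
6. **Network expression patterns (NEPs)** — back-projection of the
   classifier to per-subject per-feature log-odds impacts (loading
   threshold 0.2, impact threshold 0.15), Ward biclustering into two
   NEPs and subject groups, and withhold-one-NEP sensitivity analysis
   attributing classification probability to each pattern.
7. **Connectivity contrast** — group correlational models, Cohen's *d*
   of edge-correlation distributions per module pair (depressed −
   control), permutation significance at p < 0.001.

A synthetic-cohort generator with planted ground truth (block
correlation structure, two planted NEPs, group connectivity shifts,
artifact bursts) makes every stage testable without clinical data.

## Worked example

```r
library(neurodep)
res <- run_all(list(n_subjects = 10, n_global_electrodes = 30,
                    duration = 60, electrodes_per_subject = c(12, 18),
                    artifact_rate = 0, connectivity_perms = 200,
                    allegiance_runs = 10, seed = 7))
res$parcellation
res$classifier
head(res$neps$sensitivity, 4)
```

Output from this exact call:

```
Parcellation: 6 modules at gamma=0.5 (Q=75.74)
LOOCV PCA + L1-logistic: balanced accuracy 91.7% (n=10)
  subject    p_full        NEP1        NEP2     profile
1     S01 0.9901096  0.24718428 -0.00335452 NEP1-driven
2     S02 0.9208269 -0.05150627  0.43180946 NEP2-driven
3     S03 0.9508892  0.12192858  0.04329236 NEP1-driven
4     S04 0.8669263  0.18716877 -0.06129596 NEP1-driven
```

Reading it: the γ-sweep parcellated the population correlation model
into 6 modules, matching the planted 6-module structure (the planted
blocks are so clean here that atlas similarity is flat across the γ
grid, hence the sweep's global-maximum warning); the LOOCV classifier
separated depressed from control subjects at 91.7% balanced accuracy,
well above the 50% chance level of its permutation null (the planted
band effects are strong at this desk scale); and the sensitivity table attributes each
subject's classification probability (`p_full`) to the two NEPs — a
positive contribution pushes that subject toward a depression
classification, and the `profile` tag says which pattern (if any)
dominates by more than the 0.05 probability margin. All artifacts
(features.csv, parcellation.tsv, connectivity.csv, neps.tsv,
classifier.json, manifest.json) are written to `res$out_dir`.

A command-line entry point covers simulation and the full pipeline:

```sh
Rscript inst/cli/neurodep.R simulate --out cohort/ --seed 1 --subjects 12
Rscript inst/cli/neurodep.R run --out artifacts/ --seed 1
```

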