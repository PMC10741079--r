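---
title: "Methods: tumor-cell-restricted marker scoring for multiplex IHC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tumor-cell-restricted marker scoring for multiplex IHC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mfihc)
```

## The problem

RNA-based prognostic panels in breast cancer read a bulk signal from a
tissue fragment whose tumor purity is unknown: admixed benign glands,
stroma and immune cells dilute or distort the measurement. Multiplex
fluorescence immunohistochemistry (mfIHC) measures protein markers cell by
cell, so the analysis can be restricted to malignant cells — provided the
malignant cells can be identified automatically. In breast tissue the
discriminating feature is anatomical: benign glands are wrapped in a layer
of myosin-positive myoepithelial cells, while invasive carcinoma has lost
that layer.

This package implements the full chain as testable components:

1. a **synthetic tissue-microarray (TMA) generator** producing 0.6 mm spot
   cell tables with complete ground truth;
2. an optional **raster front-end** (render cells to a multichannel image,
   re-detect them with classical operators);
3. **benign/malignant classification** combining a nearest-myoepithelial
   distance rule with a gland-level rule;
4. **marker quantification** restricted to malignant cells (the mfIHC
   score);
5. **prognosis statistics** (dichotomization, five-marker score,
   Kaplan–Meier, log-rank, Cox, time-dependent AUC, chi-square
   association);
6. **marker-interplay analytics** (Spearman matrix, Ward clustering).

## Classification model

For every PanCK-positive (epithelial) cell the Euclidean distance to the
nearest Myosin-positive (myoepithelial) cell of the same spot is computed
with a grid-bucket index that is contractually equal to the brute-force
minimum. *Approach 1* labels a cell benign iff that distance is at most
25 µm — the boundary is inclusive because the rule is stated as "≤ 25 µm".
*Approach 2* groups epithelial cells into glands (single-linkage connected
components at a 20 µm linkage radius, a transparent, oracle-checkable
substitute for a learned gland detector) and labels a gland benign iff at
least half of its members are within 25 µm of myoepithelium; the tie at
exactly 0.5 resolves to benign, the conservative direction when the goal is
to *exclude* benign cells from tumor scoring. The default fusion rule,
`benign-if-either`, maximizes that exclusion; all four fusion rules
(`benign-if-either`, `benign-if-both`, `cell-priority`, `gland-priority`)
are implemented and the chosen rule is recorded in the run manifest,
because the optimal fusion of the two approaches is a genuinely open design
choice. Performance is reported as accuracy/sensitivity/specificity with
Wilson score 95% intervals (the interval method is a declared choice;
positive class = malignant), at cell or gland level — both units are
supported since headline accuracies of such classifiers are conventionally
quoted at gland level.

## The mfIHC score

Raw intensities live on the 0–255 measurement scale. Within each spot every
channel is divided by the spot's mean PanCK intensity over a reference cell
set. Two reference sets are available: all PanCK-positive cells (the
textbook definition, function default) and PanCK-positive *final-malignant*
cells, which is what `run_pipeline()` uses. The tumor-restricted reference
is a deliberate design decision: with it, adding benign glands or stroma to
a spot cannot move the normalization factor, so every per-patient marker
summary is bit-identical under such admixture — the package's testable form
of the tumor-purity-robustness claim. With the all-PanCK reference that
invariance would be impossible, since benign epithelium is PanCK-positive.

Per patient and marker, over final-malignant cells only:

* `positive_fraction` — positive tumor cells / all tumor cells;
* `mean_pos_intensity` — mean normalized intensity over positive tumor
  cells, defined as 0 when no tumor cell is positive so the score degrades
  gracefully to the fraction component;
* `mfihc_score` — min–max scaled (0–50) fraction plus min–max scaled
  (0–50) mean intensity, scaling performed across the *analyzed* cohort
  (post-exclusion, whole cohort rather than per-TMA — a declared choice)
  so the score lies in [0, 100] and each component's cohort argmax attains
  exactly 50;
* `labeling_index` — 100 × positive fraction, conventionally reported for
  the proliferation markers Ki67 and TOP2A.

Patients whose spot contains no final-malignant cell are excluded and
recorded with a reason (`n_input = n_analyzed + n_excluded` always holds).
Per-cell positivity is thresholded on normalized intensity; the default
thresholds are derived from the generator's bimodal intensity model (the
geometric-mean valley between the two log-normal components, divided by the
expected PanCK mean). On real data there is no substitute for user-supplied
thresholds — thresholding replaces trained per-marker classifiers and this
is a documented limitation.

## Prognosis statistics

Marker dichotomization follows a "highest slope" rule: the automatic
cutpoint is the location of maximum |d/dx| of a Gaussian KDE (Silverman
bandwidth) of the cohort score distribution, searched between the 10th and
90th percentiles; a manual override is first-class and recorded as
`method = "manual"`, mirroring the visually-corrected practice of
pathology scoring. A score exactly at the cutpoint is low (strict `>` for
high — the convention is declared because "> c vs < c" leaves equality
unstated). The five-marker prognosis score is the integer sum (0–5) of the
high flags of PR, ER, AR, GATA3 and PD-L1; missing flags are an error, not
an imputation.

Survival machinery goes through the `survival` package: Kaplan–Meier
product-limit curves, the k-group log-rank test, and Cox proportional
hazards with Breslow tie handling (tie rule declared; simplest to check
against the two-sample exponential closed form). Time-dependent AUC is the
cumulative-case/dynamic-control estimator with inverse-probability-of-
censoring weights from the Kaplan–Meier estimate of the censoring
distribution; it is written in the package (no suitable estimator package
is a dependency) and verified against brute-force case–control pair
enumeration. Association with clinical categories uses the r×c chi-square
test without continuity correction, alongside a descriptive mean ± SD table
and a Kruskal–Wallis alternative for the continuous score — the package
deliberately offers both since published tables of this kind rarely state
which test produced each p-value. p-values are unadjusted by default; users
can apply `p.adjust` downstream. Clustering standardizes the
patients × markers matrix (mfIHC scores; labeling indices for Ki67/TOP2A),
uses Euclidean distance with Ward (`ward.D2`) linkage, cuts at k = 3, and
relabels clusters `a`, `b`, `c` by descending hormone-block mean so labels
are stable; linkage/distance/standardization are declared choices, not
inferences.

## The synthetic generator

The generator is first-class, tested code, and its defaults define the
study conditions for every benchmark in the test suite.

**Geometry.** A 0.6 mm diameter spot. Benign glands are epithelial annuli
(outer radius 40 µm, lumen fraction 0.6) wrapped in a discrete
myoepithelial ring at +5 µm offset, 8 µm arc spacing and ±1.5 µm radial
jitter; this guarantees every benign epithelial cell is within 25 µm of a
ring cell, i.e., the geometry the distance rule assumes. Malignant nests
are truncated-Gaussian clusters (σ 18 µm, hard radius 40 µm) placed so that
no malignant cell comes within 50 µm of any myoepithelial cell. Structures
are packed by rejection sampling with a 25 µm inter-structure margin (so
distinct glands never single-link at 20 µm); infeasible packings raise an
error rather than silently truncating. Background stroma (800/mm²) and
immune cells (300/mm²) fill the disc; epithelial packing is 10 000/mm².
Defaults of 3 glands + 3 nests per spot are stand-ins — the source cohorts
for such analyses never publish spot composition — and all are
configurable.

**Intensities.** Per marker, a two-component clamped log-normal on
[0, 255]: negatives around 12 (σ_log 0.5), positives around 150
(σ_log 0.25); PanCK ≈ 120 on epithelial cells, Myosin ≈ 140 on
myoepithelial cells, DAPI ≈ 180 everywhere. The positivity truth flag is
recorded at draw time, which is what lets threshold calling be scored
against truth. Patient-high tumors shift the positive component by +0.3
log units and carry a patient-level ±0.1 log-unit batch jitter.

**Correlation structure.** Patient-level marker-high status comes from a
latent hormone factor loading 0.8 on PR/ER/AR/GATA3 (prevalence 0.6), a
proliferation factor loading 0.8 on Ki67/TOP2A (prevalence 0.3),
independent TROP2/PD-L1/HER2 (0.70/0.25/0.15), and an
HER2→TOP2A coamplification rule: HER2-high patients acquire TOP2A-high
status with probability 0.40, reflecting the known co-location of the two
genes on 17q. Clinical covariates (pT, pN, M, grade) derive from an
aggressiveness latent that loads −0.6 on the hormone factor and +0.7 on
the proliferation factor, cut to realistic category frequencies.

**Survival.** Exponential proportional hazards: baseline 0.010
events/month, protective log-hazards for PR (−0.45), ER (−0.35), AR
(−0.45), GATA3 (−0.35), PD-L1 (−0.35), zero otherwise; censoring is a
0.012/month exponential plus a 120-month administrative cut, giving
roughly 40–50% censoring — typical of a contemporary surgical cohort.
`simulate_patient_profiles()` exposes this layer without cells so that
large-n parameter-recovery checks (Cox at n = 2000, null AUC at n = 1000)
run in seconds.

**What it does not emulate.** No staining chemistry, bleaching,
autofluorescence or registration error (flat Gaussian noise in the
renderer is the only imaging artifact); no intratumoral heterogeneity
beyond per-cell Bernoulli positivity; immune cells carry no PD-L1 signal.
Passing benchmarks on this generator demonstrates internal correctness of
the algorithms under the stated geometry and noise model — not clinical
performance on real slides.

## The raster front-end

`render_spot()` stamps each cell as a uniform 3 µm-radius disc in every
channel (amplitude = raw intensity), blurs with a 1 µm Gaussian PSF at
1 µm/px, adds noise, and clamps to [0, 255]. `segment_cells()` smooths
DAPI, thresholds by Otsu, splits touching nuclei with a distance-transform
watershed (tolerance 0.2) and measures per-cell channel means on the
nuclear mask dilated by 3 µm — the cytoplasmic expansion radius is a
declared stand-in, as the measurement compartment of production systems is
rarely published. Detected counts track truth within ~5% only for sparse
preparations (≲ 500 cells/mm² without tightly packed glandular rings, at
1 µm/px); denser tissue merges genuinely overlapping nuclei and the count
becomes a lower bound. Measurement is linear in amplitude in the
noise-free limit. PanCK/Myosin phenotype flags can be re-derived from
measured means by per-channel Otsu thresholds. Table-level pipelines may
bypass this module entirely.

## Numerical choices and degenerate inputs

* All randomness flows from one root seed; stage seeds are derived
  deterministically, so identical (config, seed) reproduces cell tables,
  CSVs and manifest checksums bit-for-bit.
* Nearest-neighbour queries: grid-bucket ring search, exact; `Inf`
  sentinel when a spot has no myoepithelium (such cells classify as
  malignant).
* Min–max scaling of a constant cohort maps to the range minimum with a
  warning; a constant score vector is an error for cutpoint placement.
* Cox non-convergence and all-constant designs raise errors;
  `chisq.test` is called without continuity correction so toy tables match
  the closed form exactly.
* Problem sizes used by the shipped checks: the classification benchmark
  uses 100 spots (~600–850 glands, ~65 000 cells); parameter recovery uses
  n = 2000 patient profiles; the end-to-end survival-ordering check uses
  150 patients. These sizes give stable statistics at interactive runtimes.

## Worked example

```{r example, eval = FALSE}
cfg <- sim_config()
res <- run_pipeline(cfg, n_patients = 60, seed = 11)
print(res)
summary(res)
plot(res)    # Kaplan-Meier curves by five-marker score
```

## Known limitations

The gland rule is a coverage heuristic, not a learned morphology model; it
inherits the generator's assumption that benign glands present complete
rings. Positivity thresholds must be supplied by the user on real data.
The highest-slope cutpoint estimator is sensitive to KDE bandwidth for
weakly bimodal scores (rare markers with noisy intensity components can
dichotomize poorly — the manual override exists for exactly this case).
Survival simulation is exponential; no competing risks.
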