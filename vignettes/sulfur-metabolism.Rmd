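---
title: "Methods: community secretion potentials and longitudinal sulfur-metabolome statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: community secretion potentials and longitudinal sulfur-metabolome statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of its models and of the design
choices that were genuinely open. It states no empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## 1. The community model

A strain reconstruction is a stoichiometric matrix with flux bounds, a
biomass reaction producing a strain biomass metabolite, and exchange
reactions written `met →` with coefficient −1, so that negative flux is
uptake and positive flux secretion (the COBRA convention). Flux units are
mmol·person⁻¹·day⁻¹; biomass flux is day⁻¹. The native format is a small
JSON dialect — desk-scale, dependency-light and diffable — rather than SBML;
SBML import/export is a non-goal. Reversible reactions default to bounds
±1000, irreversible to [0, 1000], the conventional "unconstrained" defaults
for genome-scale reconstructions.

`build_community()` assembles per-subject models the way community FBA
pipelines do: each detected strain's reactions are copied with
strain-prefixed identifiers into a private compartment; each strain exchange
becomes a transporter between the strain compartment and a shared lumen
(`[lu]`); every lumen metabolite receives one diet exchange
(`Diet_EX_<met>[d]`, bounds [−diet, 0]) and one fecal exchange
(`EX_<met>[fe]`, bounds [0, 1000]); and a community biomass reaction consumes
each strain's biomass metabolite with stoichiometric coefficient equal to its
relative abundance, bounded to [0.4, 1] day⁻¹ (fecal excretion between every
third day and daily). Strains with zero abundance are omitted entirely, which
the tests show leaves all flux results unchanged.

Two open points were decided as follows. First, biomass–flux *coupling
constraints* (tying each strain's flux magnitudes to its biomass production)
are **not** implemented: only the community biomass bounds above are
enforced. The builder is written so a coupling hook could be added, but
nothing in the package relies on one. A consequence worth knowing: secretion
potentials respond to strain *presence/absence* (the 0.1 coverage detection
threshold) and to the diet, not to continuous abundance variation. Second,
relative abundances come from genome coverage by thresholding at 0.1 and
renormalising to sum 1; an all-below-threshold subject is an "empty
community" error, not a silent empty model.

## 2. Net maximal secretion potentials

For each metabolite with both diet and fecal exchanges we solve one LP
maximising the fecal exchange, then read the net value
|v_fe + v_diet| — maximal secretion minus the diet uptake magnitude (the
diet flux is ≤ 0). A pure pass-through metabolite (diet in, feces out, no
synthesis) therefore scores 0. Because the diet flux at the fecal optimum
can be non-unique, a second, lexicographic LP minimises total absolute flux
with the fecal exchange pinned at its optimum; this makes every reported
potential deterministic. A metabolite that no present strain can transport
has no exchanges in that subject's model; the community cannot secrete it
and the screen records 0 with a log entry (missing values are reserved for
genuine LP failures).

The LP engine is a bounded-variable two-phase primal simplex with Bland's
rule (termination on the degenerate bases metabolic networks produce),
pivot-updated basis inverses with periodic refactorisation, feasibility
tolerance 1e−6 and entering tolerance 1e−9. No installed package provides a
reliable general LP solver, so the engine is part of the package; its
correctness is established in the tests against (a) a dense brute-force
vertex enumerator on small fixtures and (b) an independent simplex
implementation on community-sized models, both to 1e−6.

## 3. Synthetic data: what it emulates, and what it does not

The generators define the study conditions for all calibration experiments.

* **Strain panel.** Two keystone archetypes carry all sulfur chemistry: a
  mucin-degrader with the aspartate → homoserine → cystathionine →
  methionine chain, cysteine desulfhydration to H₂S, assimilatory sulfite
  reductase (EC 1.8.2.2) and asparagine synthesis; and a taurine respirer
  with bile-salt hydrolase, taurine dissimilation to sulfite and sulfite
  respiration to H₂S. Background strains are plain glucose fermenters with
  randomised biomass yields. Every generated strain is self-checked to grow
  on the built-in toy European diet (glucose 10, aspartate 5, cysteine 2,
  sulfite 2, taurocholate 2 mmol·person⁻¹·day⁻¹).
* **Abundances.** Dirichlet draws with concentration 50 × base proportions;
  keystone base proportion 0.3% each (anchored at the reported keystone
  abundance scale), background uniform. In cases the expected keystone
  proportion is multiplied by (1 + shift); the default shift 0.7 mirrors the
  0.20% → 0.34% case-control contrast used as an anchor. At this
  concentration the keystone draws are strongly right-skewed; a detection
  test at n = 200/200 succeeds in about 91% of seeds, and one module test
  that needs a tight abundance distribution uses concentration 2000 as an
  explicit fixture choice.
* **Longitudinal metabolome.** Log-concentrations follow
  y = μ + u_subject + covariates + template(group, wave) + interactions + ε
  with subject SD = residual SD = 0.3 on the log scale (the cohort's
  variance components are not published; these are calibration choices,
  recorded in the config). Trajectory types are coefficient templates on
  (group, group×FU1, group×FU2): type 1 = (δ, 0, 0), type 2 = (0, δ, 2δ),
  type 3 = (δ, −δ, −2δ), δ = 0.4 — the testable encoding of the three
  verbal trajectory shapes. Pairwise interaction effects add
  (b₀ + β·group)·y_B to a target metabolite A with base slope b₀ = 0.5.
  Levodopa dosing: no intake at baseline (drug-naive design); 55% / 80% of
  cases take levodopa at the follow-ups; the log 3-OMD elevation is
  slope × dose with slope 0.614 per 100 mg/day and doses drawn so the
  fold-change is log-uniform on [10, 600] — both the classification margin
  and the change-on-change slope therefore follow from one mechanism.
* **Survival.** Standard-normal exposure, exponential event times with
  log-hazard = log(HR)·exposure + small covariate terms (age, sex, BMI,
  smoking, CRP), administrative censoring at 0.7–1 × 24 years, and the
  baseline hazard solved numerically so the expected event count hits the
  target (157 events in 10,034 subjects by default).

Not emulated: mass-spectrometry batch drift and limits of detection,
phylogenetic covariance between strain abundances, informative censoring,
and real dietary variation. Passing recovery tests therefore demonstrates
estimator correctness under the stated generative model, not robustness to
those real-data features.

## 4. Statistical estimators

* **Mixed models.** Random-intercept linear models fitted by REML (`lme4`);
  among the estimators consistent with "generalized least squares with
  heteroscedasticity-robust standard errors", REML is our documented choice. Cluster-robust (sandwich) covariance is
  computed in-package from the compound-symmetry GLS representation
  (bread Σ XᵢᵀVᵢ⁻¹Xᵢ, meat Σ XᵢᵀVᵢ⁻¹rᵢrᵢᵀVᵢ⁻¹Xᵢ, CR1-style m/(m−1)
  factor), because no installed package provides cluster-robust vcov for
  mixed fits. The 3-df global Wald test uses this robust covariance for the
  components and the joint test alike.
* **Trajectory classification** applies an FDR gate on the global test, then
  nominal α = 0.05 component tests: type 1 requires a significant group
  main effect (from a refit without interactions) with non-significant
  interactions; type 2 a non-significant baseline difference with jointly
  significant positive interactions; type 3 a significant positive baseline
  difference with jointly significant negative interactions.
* **Medication models.** Change-on-change: Δ log-concentration between
  consecutive waves on Δ dose with age, sex, disease length and interval as
  covariates. Because everyone is drug-naive at baseline, "dose + dose×wave"
  adjustment is structurally collinear; the package parametrises medication
  adjustment as one dose slope per wave, dropping structurally zero columns.
  Observations with missing doses are dropped, never the subject.
* **Fractional regressions** are quasi-binomial logit fits (log odds
  ratios) with nonparametric subject bootstrap (percentile CIs, normal
  approximation p on the bootstrap SE; 2000 replications by default).
  Zero potentials are offset by half the smallest positive value before
  logs; the handling is logged.
* **Fractional polynomials.** Degree ≤ 2, powers from
  {−2, −1, −0.5, 0 (log), 0.5, 1, 2, 3}, repeated powers taking an extra
  log factor. Raw deviance always prefers the nested degree-2 model, so
  selection uses the conventional closed test: degree 2 is kept only when
  it beats the best degree-1 model by a 2-df F-test at 0.05.
* **Cox models** use Efron tie handling, the field default. Exposure preprocessing follows the stated order log →
  winsorise (5 SD) → standardise, per batch. Fixed-effect meta-analysis is
  inverse-variance pooling with Cochran's Q, cross-checked against an
  independent implementation in the tests.
* **Matching.** The deviation score sums the age KS statistic, the BMI KS
  statistic (the statistic, not its p-value — scale-free) and per-flag
  normalised counts; sex matching is a hard constraint maintained by a
  feasibility check on every removal. Inside the optimizer the flag counts
  are normalised by the fixed target size so their scale does not drift
  during elimination. Ties are broken by lowest subject id. Greedy
  elimination is myopic: on tiny selections (KS granularity 1/4 at 4-vs-4)
  it can exceed the exhaustive optimum and the score trace need not fall
  monotonically; the tests pin fixtures where the intended behaviour is
  provable (flag-dominated scores) or observed.

## 5. Multiple testing

`bh_fdr()` implements the step-up procedure with a *declared* family size
that may exceed the number of tests actually run, so a family whose members
were skipped (degenerate pairs, all-zero potentials) is still corrected at
full size. Family sizes mirror the analysis design: all ordered metabolite
pairs for the interaction screen, the metabolite count for trajectory and
medication families, the tested secretion set, and the bile-acid panel for
the incidence analysis.

## 6. Problem sizes and reproducibility

Calibration experiments use 200 replicate cohorts of 30 cases + 30 controls
× 3 waves for interaction and medication recovery, 100 replicates of
10,034 subjects (~157 events) for Cox recovery, and 500 arithmetic
simulations for FDR control; the demonstration pipeline runs 5 strains,
30 model subjects, an 8-metabolite cohort and a 4,000-subject survival arm.
These sizes keep every Monte-Carlo standard error well below the recovery
tolerances (±0.05 on interaction coefficients, ±0.06 on the dosage slope,
±0.03 on the hazard ratio). All randomness flows from explicit integer
seeds; one global seed is split into per-module seeds by `derive_seed()`, so
each stage is reproducible in isolation and identical configurations yield
byte-identical outputs.

## 7. Known limitations

Without coupling constraints, secretion potentials are insensitive to
continuous abundance variation (presence/absence and diet drive them); the
toy reconstructions track carbon and sulfur but not energy or redox
balance; ordered-logistic UPDRS models use proportional odds without a
random intercept (the discrete subscales are short and the approximation is
flagged); and the matcher is a greedy heuristic, not an exact optimizer —
an integer-programming formulation is a deliberate non-goal.
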