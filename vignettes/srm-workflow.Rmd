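---
title: "Methods: multiplexed SRM design, scheduling and quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multiplexed SRM design, scheduling and quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the models and procedures it
implements, the parameters that matter, the numerical conventions, and the
limits of what the synthetic-data tests demonstrate.

## The measurement model

Selected reaction monitoring measures predefined precursor→fragment ion
pairs (*transitions*) on a triple quadrupole. For each target peptide the
endogenous ("light") form is monitored together with a spiked-in synthetic
twin carrying a heavy C-terminal label, which co-elutes and fragments
identically; the heavy trace verifies identity (co-elution, matching
relative fragment intensities) while quantification uses the light peak
areas. A protein is represented by several proteotypic peptides, each by
several transitions, so one protein-level quantity is estimated from a
block of correlated measurements per run.

The quantification stage models, per protein, the log2 peak areas of all
retained transitions:

\[
y_{f,r} \;=\; \mu + C_{c(r)} + F_f + R_r + \varepsilon_{f,r},
\qquad R_r \sim N(0, \sigma_{\mathrm{run}}^2),\;
\varepsilon \sim N(0, \sigma^2),
\]

with condition \(C\) and feature \(F\) (a peptide × charge × transition
combination) fixed and the run \(R\) random. The reported log2 fold-change
is the condition contrast against the control, with its standard error,
Satterthwaite degrees of freedom, t statistic and two-sided p-value;
p-values are then Benjamini–Hochberg adjusted **across proteins within one
condition-vs-control comparison** (not pooled across all conditions, which
mirrors per-comparison reporting practice) and called significant at an
adjusted 0.05.

Assumptions worth stating: feature effects are additive on the log2 scale
(constant fragment-intensity proportions across conditions), residual
variance is shared across features, and the run effect captures all
between-replicate correlation. On balanced complete data the fixed-effect
contrast reduces to the difference of group means — a closed form the test
suite checks to 1e-6. When the run-variance estimate is singular, or only
one feature exists, the fit degrades to the fixed-effects two-way model
with residual degrees of freedom; if the residual variance itself is zero
(condition literally duplicating control) the p-value is defined as 1 for
a zero estimate.

## Filtering, imputation, detection calls

* **Peak-group filter.** A peptide's peak group in a run is retained iff
  its *top transition* — defined as the transition with the highest light
  peak area in that run, the convention peak-picking software uses — has
  S/N strictly greater than 3. Retention is decided for the whole group,
  never per transition, and every input row lands in exactly one of the
  retained set or the rejection log.
* **Imputation.** A transition whose area falls strictly below its
  transition-specific background is assigned one-third of that background.
  Both thresholds are strict inequalities; the boundary cases (S/N exactly
  3 → rejected; area equal to background → unchanged) are documented
  decisions, and the imputation is idempotent.
* **Detection calls.** A peptide is "detected" in a replicate iff its peak
  group survived the filter there (a single surviving replicate suffices
  to make a protein *detectable* — the workflow's reading of an ambiguous
  rule, flagged here). A protein is *quantifiable* in a condition when ≥2
  distinct peptides are each detected in ≥3 biological replicates;
  *detectable* when something was detected but that rule is unmet;
  *not detected* otherwise. A comparison is attempted when either side is
  quantifiable. Calls are monotone: adding a detected peptide-replicate
  can never demote a protein.

Peptide abundances (for plots and correlation, not for the model) are the
median of the peptide's transition log2 areas per run; protein abundances
are the median of peptide abundances; condition summaries show the median
with a t-interval about the mean.

## Assay design conventions

* Digestion is fully tryptic: cleave after K/R, suppressed before proline
  (configurable), 0 missed cleavages by default — dual LysC+trypsin
  digestion converges to the same peptide set in silico.
* Candidate peptides are kept at 7–25 residues, the usual SRM
  detectability window.
* Proteotypic = occurring in exactly one proteome entry; a peptide absent
  from the proteome is *not* proteotypic (specificity is defined with
  respect to the reference, so a target must exist there).
* Masses are monoisotopic throughout (proton 1.007276 Da, water
  18.010565 Da), with fixed carbamidomethyl-C (+57.021464 Da) and no
  variable modifications: synthetic reference peptides do not reproduce
  post-translational modifications, so the assay targets unmodified
  backbones. The heavy label (+8.014199 K / +10.008269 R) shifts the
  precursor and all y ions, never b ions. An independently coded
  elemental-composition oracle agrees with these tables to 1e-4 Th in the
  tests, and b/y complementarity holds to 1e-6.
* Fragment enumeration keeps the 20 most probable singly/doubly charged
  b/y fragments per precursor charge, by library rank; ties break
  deterministically (y before b, lower index, lower fragment charge).
  Ranking is per precursor charge — whether pooled-ranking was intended is
  unknowable from the method description, so the per-precursor choice is
  declared. The final panel keeps one precursor charge per peptide (the
  one with the best summed ranks).
* Panels enforce 2–8 peptides per protein and 4–10 transitions per
  peptide; proteins failing the minimum are excluded with a reason rather
  than silently dropped (the fate of a marker with no proteotypic tryptic
  peptides).

## Scheduling

RT windows of fixed width (default 4 min) are centred on the RT predicted
from an ordinary-least-squares iRT calibration and **clipped** — not
shifted — at the gradient boundaries, preserving centre ordering. Light
and heavy twins co-elute by construction and share one window. Concurrency
is counted by an endpoint sweep over half-open intervals \([s, e)\), so
touching windows do not overlap; a brute-force time-grid oracle confirms
the sweep in the tests. The effective cycle time is
`concurrency × (dwell + interscan overhead)`; the overhead default is 0
because a 170-transition worst case at 10 ms dwell matching a 1.7-s cycle
implies negligible overhead, and it is configurable where that does not
hold.

The shipped default panel is deliberately dense (ten proteins × six
peptides × up to ten transitions, light + heavy = 786 transitions); at a
4-min window on a 30-min gradient its worst-case concurrency of 184 pushes
the effective cycle to 1.84 s, so the feasibility check reports it
infeasible against a 1.7-s budget. That is the check working as intended —
a leaner validated panel (fewer peptides or transitions) fits comfortably.

## qPCR and correlation

ΔCt is computed against the **mean of two housekeeping genes** with the
sign convention `mean(HK) − Ct(target)`, so induction plots upward; the
sign is configurable because the convention is not universal. Replicate
summaries are means with t-intervals. Profiles are z-scaled (mean 0,
sample SD 1) for display on a common axis; Pearson correlation is
affine-invariant, so pairwise r and p are identical on raw and scaled
series — the per-pair p-value uses the exact t transform
\(t = r\sqrt{(n-2)/(1-r^2)}\), two-sided, with no multiplicity correction
across correlogram cells. Profile clustering is agglomerative with
Euclidean distance and average linkage (the heatmap's method is otherwise
unstated); rows are sorted by label first so the tree is invariant to
input order.

## The synthetic time course

The generator emulates exactly the structure the model fits: per-protein
piecewise-linear log2 trajectories over the differentiation time course
(control NSC plus four differentiation time points, four biological
replicates), per-peptide digestion-efficiency offsets
(SD 0.5 log2 units), fixed per-peptide fragment-intensity fractions
(geometric in library rank, summing to 1), a shared run random effect
(SD 0.1), residual noise (SD 0.2), transition-specific backgrounds
(log2 mean 4, SD 0.5), constant heavy spike-ins, and S/N reported as
area/background — a declared proxy, since real S/N comes from the peak
picker upstream. Signals falling below background are replaced by
noise-floor draws so the imputation rule is genuinely exercised. Matched
Ct values couple linearly to the protein trajectory with negative slope
(higher protein → lower Ct → higher ΔCt), plus constant-level
housekeeping genes.

Default trajectories encode the qualitative biology of BDNF/GDNF-driven
neuronal differentiation: neuronal markers rise (the DCX-like trajectory
ends +3 log2 units over control), stem-cell markers fall, S100B dips then
recovers, OCT4 sits below the detection limit, GFAP is borderline, and
oligodendrocyte markers stay flat. Magnitudes are choices, not
measurements — the generator makes no attempt to reproduce any measured
abundance table.

What passing tests therefore show: the pipeline recovers known
fold-changes, controls false positives, and applies every filtering rule
exactly, *on data satisfying the model's assumptions*. What they cannot
show: robustness to real-data pathologies — interfering transitions,
retention-time drift, non-Gaussian tails, fragment-ratio changes from
modifications, batch structure beyond a single run effect.

## Numerical and statistical notes

* Problem sizes in the checks are chosen to give stable statistics at
  interactive runtimes: 200 simulated fold-change recoveries (20
  simulations × 10 proteins, fold-changes uniform on ±3) for coverage and
  bias, 500 all-null fits (50 × 10, reduced 2-peptide × 3-transition
  panels) for the type-I proxy, 1000 random peptides for the mass oracle,
  100 random window sets and 500 random p-vectors for the scheduling and
  FDR oracles.
* Because all proteins in a simulation share its realised run effects,
  interval misses cluster by simulation; coverage estimates over pooled
  protein instances therefore fluctuate more than binomial noise suggests.
* Below-background imputation inflates the residual-variance estimate for
  low-abundance proteins, which widens their intervals: measured coverage
  sits in the upper half of the accepted 90–98% band. The intervals are
  conservative, not anti-conservative.
* Degenerate inputs are defined, not crashed on: empty filter input
  returns empty output plus an empty log, a single replicate yields a
  median without an interval, constant profiles refuse z-scaling with a
  clear error, and a comparison with only one run in total is a singular
  design error.

## Known limitations

* The default panel's sequences, iRTs and fragment ranks are synthetic;
  m/z coordinates do not correspond to real assays and must be replaced
  with library values for real use.
* Quantification is relative (log2 fold-change vs control); no absolute
  amounts. Light/heavy ratio-based quantification exists
  (`ratio_to_heavy = TRUE`) but is off by default, and the default is the
  documented mode.
* S/N is consumed from the input, never recomputed — peak integration is
  upstream of this package.
* The mixed model assumes equal feature variance and no transition
  interference beyond what the dot-product co-elution check catches.
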