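---
title: "Ultrasound grading and integrated ACR/EULAR + US classification for Sjögren's syndrome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ultrasound grading and integrated ACR/EULAR + US classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sgusdx)
```

## The problem

Sjögren's syndrome (SS) has no laboratory gold standard: in practice the
diagnosis is made by experienced rheumatologists weighing serology, histology,
gland-function tests and imaging. Consensus classification criteria (AECG,
ACR, and the weighted 2016 ACR/EULAR score) approximate that judgement but
disagree with it in a substantial minority of patients. Gray-scale
ultrasonography (US) of the major salivary glands sees the parenchymal damage
SS causes — hypoechoic areas, hyperechoic bands, irregular gland borders — and
is cheap, radiation-free and repeatable, which makes it a natural candidate
item to add to a criteria score.

`sgusdx` implements one complete realisation of that idea: a per-gland
logistic probability model over binary US findings, an ordinal US grade 0–4
for the patient, and an *integrated* score in which a US-derived score is
added to the ACR/EULAR item score before thresholding. It also implements the
machinery needed to evaluate such a system honestly: confusion metrics,
exhaustive threshold sweeps, and k-fold cross-validation with per-fold
threshold selection.

## The per-gland model

Each of the four glands (left/right parotid, left/right submandibular) is
read for binary findings. For gland $g$ with finding indicators $x_1, \dots,
x_m$ the model is an ordinary logistic regression fitted per gland type, with
the gland (not the patient) as the unit and left/right glands pooled:

$$
P_L(g) = \beta_0 + \sum_j \beta_j x_j, \qquad
p(g) = \frac{1}{1 + e^{-P_L(g)}} .
$$

Two fixed coefficient sets are built in, one per diagnostic basis used to
label the glands during fitting:

| basis | gland | intercept | hypo | band | irreg |
|-------|-------|-----------|------|------|-------|
| AECG | parotid | −0.33 | 1.65 | 0.52 | — |
| AECG | submandibular | −1.23 | 1.91 | 0.69 | 0.89 |
| ACR | parotid | −0.51 | 2.20 | — | — |
| ACR | submandibular | −1.61 | 1.98 | 0.65 | 1.36 |

A dash means the finding is not scored for that gland type (an irregular
border recorded for a parotid gland is carried through I/O but never enters
any score). All scored coefficients are positive, so flipping any scored
finding from 0 to 1 strictly increases the gland probability and can never
decrease a patient's score sum, probability or grade — a property the test
suite checks exhaustively.

The patient-level quantities are

* **score sum** — the count of positive scored findings over the 4 glands
  (maximum 10 under AECG, 8 under ACR);
* **probability** — the arithmetic mean of the 4 gland probabilities;
* **grade 0–4** — fixed score-sum intervals: AECG
  $\{0\},\{1\text{–}2\},\{3\text{–}5\},\{6\text{–}8\},\{9\text{–}10\}$, ACR
  $\{0\},\{1\text{–}2\},\{3\text{–}5\},\{6\text{–}7\},\{8\}$;
* **risk of SS per grade** — the empirical fraction
  $100 \cdot n_{SS} / (n_{SS} + n_{nonSS})$ within the grade.

The logit here is the standard $\log[p/(1-p)]$. A variant sometimes written
in clinical summaries, $\log[1/(1-p)]$, is inconsistent with the probability
equation above and with every published numeric value of this system, so the
standard form is used throughout.

### Numerical conventions

* The printed two-decimal coefficients are the canonical constants. Analytic
  reproductions of published probabilities therefore use a tolerance of
  ±0.002, which absorbs the rounding of the coefficients before printing
  (e.g. the all-positive ACR patient evaluates to 0.8798 against a printed
  0.879).
* Risks and cross-validated accuracies are rounded half away from zero to one
  decimal (49/53 → 92.5); sensitivity/specificity/accuracy are displayed as
  integers but always retained unrounded.
* An empty grade has *missing* risk, never 0.

### The enumeration oracle

`enumerate_configurations()` brute-forces every patient-level finding
configuration (4·4·8·8 = 1024 under AECG; 2·2·8·8 = 256 under ACR) and tables
score sum, grade and probability for each. This is the reference against
which the scoring path is checked: the theoretical per-grade probability
intervals must bracket published observed ranges, and the extremes must equal
the closed-form all-negative and all-positive values. Note the published
per-grade ranges are *observed-cohort* ranges, not theoretical extremes, so
containment (not equality) is the correct check for the interior grades.

## The integrated ACR/EULAR + US score

The ACR/EULAR item score is $3 \cdot \text{anti-SSA} + 3 \cdot \text{biopsy}
+ \text{ocular} + \text{Schirmer} + \text{flow} \in [0, 9]$, with SS declared
at ≥ 4. The integrated system adds an assigned US score $s \in \{1,2,3\}$
when the US grade reaches a threshold $g_0$:

$$
\text{integrated} = \text{ACR/EULAR} + s \cdot \mathbb{1}[\text{grade} \ge g_0],
\qquad \text{SS} \iff \text{integrated} \ge t .
$$

The recommended configuration is $(g_0, s, t) = (\ge 2, 3, \ge 5)$
(`recommended_config()`). With $t = 5$ and $s = 3$ a patient still needs
either a weight-3 item or US evidence plus two minor items, preserving the
face validity of the original criteria (a patient cannot reach threshold on
minor items alone). The methods text mentions assigned scores "1 to 4" in one
sentence; the evaluated grids cap at 3, so `integrated_config()` accepts 4
only with a warning.

Two degeneracies are worth knowing: with $s = 0$ the integrated classifier
reduces exactly to the ACR/EULAR classifier at the same threshold, and any
patient with ACR/EULAR score ≥ 5 is SS at $t = 5$ regardless of US. Both are
asserted as tests.

## Evaluation and cross-validation

`sweep_configurations()` evaluates, against a chosen truth label, 57
configurations per basis: ACR/EULAR alone (threshold 4), US alone (grade
threshold 1–4), the simple conjunction (4 points), and the integrated grid
(4 grade thresholds × 3 assigned scores × 4 integrated thresholds 4–7).

For cross-validation the published description does not state what "training"
estimates. We interpret it as *per-fold selection of the family's free
thresholds by training-set accuracy* — for the ACR/EULAR family the score
threshold is searched over 1–9, for US the grade threshold over 1–4, and for
the integrated family the full grid — because fixed thresholds would make
training vacuous and could not produce cross-validated accuracies that differ
from the apparent ones. US model coefficients are held fixed throughout (the
per-fold refit variant is deliberately not the default; the gland models were
developed on a larger cohort than the evaluation subset). Ties in
training accuracy are broken by the lexicographically smallest configuration,
making the procedure fully deterministic given the fold seed. Folds are a
seeded uniform shuffle into sizes differing by at most one — not stratified,
since stratification is nowhere described. Held-out predictions are pooled
over folds into a single accuracy (per-fold averaging would be undefined for
single-class folds).

## The synthetic cohort generator

No patient-level data accompany the published system, so the package ships a
generator (`generate_cohort()`) that emulates the *statistical structure* the
scoring system assumes, for use in tests and simulation studies:

1. clinical SS status ~ Bernoulli(prevalence);
2. for each gland type, the left gland's findings are independent Bernoulli
   draws with per-status occurrence probabilities; the right gland copies the
   left *exactly* with probability `lr_concordance`, else is drawn
   independently — the simplest mechanism consistent with the clinical
   observation that disease severity matches between the left and right
   glands of the same type;
3. the five ACR/EULAR items are drawn from their sensitivity (SS patients)
   or 1 − specificity (non-SS);
4. AECG and ACR labels are the clinical status flipped independently with a
   small probability (`label_noise`), reflecting that criteria-based and
   clinical diagnoses concord well but not perfectly.

`reference_cohort_params()` fixes defaults chosen once to emulate the
development cohort: prevalence 133/213; left–right concordance 0.9; finding
occurrence probabilities of roughly 0.6–0.8 (SS) versus 0.06–0.22 (non-SS),
chosen so that non-SS patients commonly reach grades 1–2 while most SS
patients reach grades 3–4 and the per-grade risk rises strictly from a few
percent to above 90% at grade 4 in cohorts of a few thousand; item
sensitivities of 0.52–0.68 and specificities of 0.62–0.88, realistic for
these tests against a clinical gold standard and giving the ACR/EULAR
classifier alone an accuracy around 80%, which the integrated system then
improves on. Per-status occurrence rates of the individual findings were
never published alongside the coefficient sets, so this calibration is
qualitative by design.

What the generator deliberately does **not** model: within-gland correlation
of findings beyond status (findings are independent given status — a
documented extension point), a continuous severity scale (real SS severity is
graded, which is why real cohorts show more SS patients at *low* grades than
this generator produces), longitudinal change, and reader disagreement.
Consequently, passing tests demonstrate the internal consistency and the
qualitative behaviour of the scoring machinery under a favourable,
well-specified data-generating process — not clinical performance on real
patients.

## Refitting and the grade-wise comparison

`refit_us_model()` re-derives the model from any labeled cohort: univariate
screening per finding (closed-form 2×2 odds ratio with Wald CI, chi-square
test, and a single-predictor logistic fit; the candidate gate is the logistic
p-value at 0.05, falling back to the chi-square p-value when separation
collapses the Wald statistic), then a multivariable logistic fit per gland
type (IRLS, tolerance 1e-8, at most 100 iterations, Wald inference).
Complete separation is flagged, never fatal. If screening selects a finding
set with a different maximum score sum than the built-in basis model, grade
intervals are rebuilt as $\{0\}$ plus four near-equal bins — the built-in
intervals are otherwise reused.

`steel_dwass()` performs the all-pairs nonparametric comparison used to
verify that fitted probabilities differ between grades: for each pair of
groups the tie-corrected standardized rank-sum statistic $z$ is referred to
the studentized range distribution via $\sqrt{2}\,|z|$ with $k$ groups and
infinite degrees of freedom. A permutation mode estimates the pairwise null
directly and is used in the tests to validate the approximation at small
sample sizes. Pairs involving a group of fewer than 2 observations are
reported as not testable.

## Problem sizes used in the test suite

Desk-scale checks run on the closed forms and the 256/1024-row enumerations.
Simulation-based properties use cohorts of 62 (evaluation-subset scale), 213
(development scale), 5 000 (grade-risk calibration) and 20 000 patients
(marginal-frequency convergence); parameter-recovery checks use 4 000 glands
per seed over 40 seeds, and the cross-validation ordering check uses 50
cohorts of 62 patients. The full suite completes in well under a minute.

## Known limitations

* The built-in coefficients are reproduced to the two printed decimals; the
  original fit cannot be recovered beyond that precision.
* The published 62-patient sensitivity/specificity/accuracy tables and
  cross-validated accuracies depend on an undeposited cohort and are treated
  as qualitative targets only (ordering and dominance relations), never as
  numeric assertions.
* The cross-validation "training" interpretation above is an interpretation;
  alternatives (e.g. per-fold coefficient refits) are exposed through the
  API (`refit_us_model()` plus `cross_validate(grid = ...)`) but are not the
  default.
* Records with ACR/EULAR exclusion conditions are classified as given; the
  original criteria's exclusion handling is out of scope.
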