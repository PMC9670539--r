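---
title: "Modelling graded-estimates beads-task data: ideal observers, deviation scores, and population-averaged inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling graded-estimates beads-task data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beadstask)
```

## The task and the statistic

In the graded-estimates (GE) variant of the beads task, a participant watches
a fixed sequence of ten draws that apparently come from one of two mirrored
containers — jar A, mostly one colour, and jar B, mostly the other — and
after every draw rates on a continuous slider how sure they are about the
source. Because the draw sequence is fixed, the exact Bayesian answer is
available at every position, and each rating can be scored by its distance
from that answer. This *deviation from the normative model* is the package's
central statistic: it indexes how far a responder's probability estimates
drift from ideal evidence integration, the quantity of interest in studies of
the jumping-to-conclusions (JtC) reasoning style associated with delusions in
schizophrenia.

The canonical design built by `build_canonical_task()` crosses two
manipulations within participant:

* **Jar ratio** — the containers hold their majority colour in proportion
  0.8 ("easy") or 0.6 ("ambiguous"); each ratio forms a block of five
  series (one at jar A's composition, one at jar B's, one 100:0, one 0:100,
  one 50:50), 10 draws each, 200 trials in total.
* **Content** — a neutral version with coloured beads and an emotional
  version in which each bead is replaced by a facial expression under the
  fixed map red→happy, green→angry, with draw sequences identical
  position-by-position to the neutral block.

Seven distinct series compositions exist across the two blocks and are
indexed 1–7 (1 = 60:40, 2 = 100:0, 3 = 50:50, 4 = 40:60, 5 = 0:100,
6 = 80:20, 7 = 20:80). The assignment of ids 2 and 3 is a convention of this
package and can be overridden via `series_map`; the ids of the four
ratio-specific series (1, 4, 6, 7) are pinned down by how results are
conventionally reported (series 6/7 belong to the 80:20 block, 1/4 to
60:40). Within-series draw *orders* are generated pseudo-randomly from the
task seed and stored verbatim in the task file, making every downstream
computation order-explicit; the ideal observer is order-invariant, so this
choice affects only the trial-by-trial trajectory shapes, not terminal
posteriors. The same shared compositions (100:0, 0:100, 50:50) receive
independent orders in the two blocks.

## The ideal observer

With mirrored jars of majority proportion $p$ and a prior $\pi$ on jar B,
the posterior after observing $n_B$ jar-B-dominant and $n_A$ jar-A-dominant
draws is

$$
P(B \mid n_B, n_A) \;=\;
\operatorname{logistic}\!\Big( \operatorname{logit}(\pi) +
  (n_B - n_A)\,\ln\tfrac{p}{1-p} \Big),
$$

which equals the explicit Bayes ratio
$p^{n_B} q^{n_A} \pi \,/\, (p^{n_B} q^{n_A} \pi + q^{n_B} p^{n_A} (1-\pi))$,
$q = 1-p$. The package implements the logistic form
(`posterior_jar_b()`, `trajectory()`) and the test-suite checks it against
the brute-force ratio to $10^{-12}$ over every count combination up to ten
draws. The prior is fixed at $\pi = 0.5$ by default — two containers, no
base-rate information — and is exposed as an argument for sensitivity
analyses. Order invariance, colour-swap antisymmetry
($P \mapsto 1-P$ under relabelling) and monotonicity in the evidence follow
from the closed form and are enforced as test invariants.

Responses are expressed on a 0–10 scale ($Y$), with 10 anchored at
"completely sure jar B" to match the posterior's reference
(`rescale_response()` flips the affine map when the slider is drawn with jar
B on the left; the anchoring is documented in the data dictionary because
raw files do not carry it). The deviation score is the unsigned distance

$$ D \;=\; \lvert Y - 10\,P(B)\rvert \in [0, 10], $$

computed per trial by `deviation_table()`. The unsigned form is used
throughout the analysis layer — group comparisons in this literature are
reported as magnitudes of departure — while the signed difference is kept as
an auxiliary column for direction analyses. $Y$ is treated as continuous;
no rounding is applied before analysis.

## The biased responder (generative model)

Real GE data for this design are not publicly deposited, so the package
ships a first-class generative model rather than a fixture. A responder is
described by four parameters (`observer_params()`): at cumulative log-odds
$\Lambda_k$ the mean response is $10\,\operatorname{logistic}(w \Lambda_k + b)$, with

* $w \ge 0$ — evidence weight: $w = 1$ is normative, $w < 1$ produces
  conservative, under-adjusted estimates (the behaviour that makes ambiguous
  60:40 evidence especially costly), $w > 1$ over-adjustment;
* $b$ — additive prior bias on the log-odds scale;
* $\sigma$ — Gaussian response noise on the 0–10 scale, applied after the
  logistic and clipped to the slider range, so that $\sigma$ is directly
  interpretable in deviation units;
* a lapse rate mixing in uniform responses.

Identity parameters reproduce the ideal observer exactly (a test invariant).
Because the task keeps all previous draws visible — a design feature meant
to neutralise memory load — the model deliberately contains no memory-decay
parameter: deviations are driven by $w$, $b$, $\sigma$ and lapses only.

For this model the expected deviation has a closed form:
`expected_abs_deviation()` evaluates
$E\,\lvert \mathrm{clip}(m + \varepsilon, 0, 10) - 10P \rvert$ exactly
(folded-normal segments plus the probability mass clipped onto the slider
ends), and `expected_deviation_profile()` maps it over a whole task. These
expressions are the *independent oracle* against which simulation-based
checks of the scoring and analysis layers are run; they are never used in
the pipeline itself.

## The synthetic cohort

`cohort_config()` / `generate_cohort()` emulate a 62-participant
case-control study: 30 patients (age 37.0 ± 14.2, 46.7% male) and 32
controls (32.3 ± 10.9, 43.8% male). Patients carry clinical scores drawn
from truncated normals within instrument ranges with the published group
means and SDs (PANSS subscales, PSYRATS delusions and hallucinations
totals, chlorpromazine-equivalent dose, illness duration). Two item-level
marginals are not published for this design and were fixed once at values
plausible for an acute inpatient sample experiencing delusions: PANSS-P1
(delusions item, range 1–7) mean 4.5, SD 1.2; PSYRATS-D6 (disruption to
life, range 0–4) mean 3.0, SD 1.0.

The generative levers are:

* **Group effect** — patients' evidence weight is centred at $w = 0.6$
  (SD 0.15) against $0.9$ (SD 0.08) in controls, with $\sigma = 1$ in both
  groups. Under-weighting was chosen as the primary lever because it
  produces over-conservative estimates precisely under ambiguity, so the
  simulated cohorts show larger deviations at 60:40 than 80:20 — the
  pattern the design is meant to detect. Prior bias and noise are secondary
  levers, all configurable.
* **Content effect** — in the emotional condition *both* groups receive a
  small decrement to $w$ (0.02) and an increment to $\sigma$ (0.75).
  The noise increment is the dominant component by design: processing
  emotional faces competes for the resources used by the probability
  estimate, which degrades precision for everyone, and because noise
  inflates measured deviation more for responders whose deterministic
  deviation is small, it moves controls disproportionately — narrowing the
  group contrast in the easy (80:20) emotional cells, the qualitative
  signature the generator is built to reproduce. A pure $w$ decrement would
  have the opposite effect (it costs low-$w$ patients more than controls),
  which is why the decrement is kept small.
* **Symptom linkage** — patients' latent
  $(w_{\text{neutral}}, w_{\text{emotional}}, \text{PANSS-P1},
  \text{PSYRATS-D6})$ vector is drawn from a Gaussian copula: correlated
  standard normals mapped through the truncated-normal quantile functions.
  This preserves the clinical marginals exactly while hitting the latent
  correlations in expectation. Defaults: $r(\text{P1}, w_n) = -0.40$,
  $r(\text{D6}, w_e) = -0.39$ (negative, so higher symptom load means more
  deviation), $r(w_n, w_e) = 0.6$, $r(\text{P1}, \text{D6}) = 0.3$; the
  two cross-terms are set to the products implied by the chain through $w$,
  keeping the matrix coherent. An infeasible matrix fails at configuration
  time via its Cholesky factorisation. Mild truncation attenuates the
  realised correlation by well under 0.01 at these settings.

What the generator does *not* emulate: response times, within-series
serial dependence of errors beyond what participant-level parameters induce,
learning or fatigue across blocks, medication effects, and any non-Gaussian
features of real slider behaviour (end-anchoring habits, discretisation).
Passing simulation-based tests therefore demonstrates that the pipeline
recovers effects from data with the *assumed* structure, not that the
assumed structure is true of patients; the exchangeable working-correlation
choice below is robust to part, not all, of this gap.

## The analysis layer

`fit_marginal_model()` fits a population-averaged linear model of the
deviation score separately per jar ratio, on Group, Series (categorical),
Content and Position (numeric 1–10, centred at 5.5), with all two- and
three-way interactions involving Group, clustered by participant. The
estimating equations use an exchangeable working correlation, solved by
iterated generalised least squares with a moment estimator for the
intra-cluster correlation $\alpha$, and all inference uses the robust
sandwich covariance, so conclusions do not hinge on the working-correlation
choice (the package reports $\alpha$ and convergence diagnostics; the
working structure can be switched to independence). Factors use sum-to-zero
contrasts, making the Group term the balanced average group effect; each
term is reported with a robust Wald $\chi^2$, its df and p. For the
exchangeable structure the cluster inverse
$R^{-1} = \frac{1}{1-\alpha}\big[I - \frac{\alpha}{1+(m-1)\alpha} J\big]$
reduces all cluster algebra to column sums, which keeps the 500-replicate
simulations used in the tests inexpensive. With independence weighting the
solver reproduces OLS with cluster-robust (HC0) covariance exactly, which
the test-suite verifies against an external sandwich-covariance
implementation.

Numerical choices: the coefficient iteration stops at a relative step below
$10^{-10}$ (cap 50 iterations; balanced designs converge in one step because
identical within-cluster regressor blocks make GLS coincide with OLS);
$\alpha$ is clamped to $[-1/(m_{\max}-1) + 10^{-6},\, 0.99]$ to keep
$R$ invertible; a zero-variance outcome or fewer than two clusters per group
aborts with a usage error rather than a degenerate fit.

`ls_means_contrasts()` produces model-based means per Group × Series ×
Content cell with Position at its midpoint, and control-minus-patient
differences with robust SEs, two-sided normal p-values and 95% CIs, so a CI
excludes zero exactly when $p < 0.05$. No multiplicity adjustment is applied
by default, matching the unadjusted reporting convention of this literature;
a Holm flag is available. `symptom_correlations()` runs the Pearson battery
(patients only, two-sided, pairwise-complete, $n \ge 3$, zero-variance cells
flagged) over the four aggregate levels produced by
`aggregate_deviations()`: per-condition global means, per-series means,
last-position scores, and the mirror-pair averages of the two jar-ratio
series of each block (1+4, 6+7). `demographics_tests()` uses the Pearson
chi-squared without continuity correction for sex and the Welch
unequal-variance t (reported control minus patient) for age; both match
their textbook closed forms, which is checked to $10^{-10}$.

## Reproducibility and problem sizes

Every stochastic stage draws from a seed derived from the master seed and
the stage name (`derive_seed()`), so the pipeline is a pure function of
(config, seed), stages can be re-run in isolation, and `run_pipeline()`
emits a manifest with per-file checksums that is byte-reproducible across
runs. The simulation-based checks in the test-suite use 500 replicates for
the size of the Group test (empirical rejection rate expected in a
[0.03, 0.08] band at $\alpha = 0.05$ with 62 clusters — sandwich covariances
run slightly liberal at this cluster count), 200 replicates for power and
gap recovery (the recovered 60:40 group gap is compared with the
closed-form expectation integrated over the $w$ distributions by 120-point
quantile quadrature), 500 replicates of 30-patient cohorts against a
3000-patient oracle for the symptom-linkage recovery, and 300 replicates
for the qualitative content-effect pattern. These sizes were chosen so
Monte-Carlo error is small against each tolerance while a full test run
stays comfortable on a single CPU.

## Known limitations

* The package analyses deviation magnitudes; it does not model
  draws-to-decision data or fit the biased-observer parameters to real
  participants (the generative model is for synthesis and oracles, not
  estimation).
* The exchangeable working correlation is a modelling default, not an
  empirical fact about real beads-task data; robust SEs protect validity,
  not efficiency.
* Series ids 2/3 (100:0 vs 50:50) and the within-series draw orders are
  package conventions where the design leaves them open; both are
  configurable and recorded in the task file.
* The LS-means grid weights Series and Content cells equally and fixes
  Position at 5.5; with the interactions included this is a definition of
  the reported means, not an approximation.
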