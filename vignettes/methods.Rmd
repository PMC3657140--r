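---
title: "Methods: the generative model, inversion scheme and synthetic cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the generative model, inversion scheme and synthetic cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the modelling choices in `emoconn`: the task
design, the forward (generative) model, the priors and variational
inversion, the model space and selection scheme, the
psychophysiological-interaction (PPI) analysis, and the scope of the
synthetic-data generator. Code chunks are illustrative and not
evaluated when the vignette is built.

## Task design

The paradigm is a blocked faces design over five conditions: neutral
(N), happy (H), sad (S), fearful (F) faces and rest (R). Each block
lasts 21 s and presents six faces for 3 s each with 0.5 s gaps
(6 × 3.5 s = 21 s). The default order,
`"NHNSNFNRSNHNFNRFNSNHNR"`, has 22 blocks and a total duration of
462 s (7 min 42 s), sampled with a TR of 2.1 s into 218 volumes.

```r
design <- parse_block_order("NHNSNFNRSNHNFNRFNSNHNR")
```

Condition boxcars are built on a microtime grid (default 16 bins per
TR) so that neural dynamics are integrated well below the sampling
rate. A `faces` input is the union of the four face conditions and
drives the network; the emotion inputs act as modulators only.

## Generative model

Neural states $x \in \mathbb{R}^4$ over regions V1, FG, AMY, OFC follow
the bilinear equation

$$\dot x = \Big(A + \sum_j u_j(t)\, B_j\Big) x + C\, u(t),$$

where $A$ holds intrinsic connections (off-diagonal) and self-decay
(diagonal), $B_j$ the modulation of connections by input $j$, and $C$
the driving input weights (faces into V1). Self-connections are
parametrised as $A_{ii} = -\exp(\theta_i)$ so they remain negative.

Each region's neural activity enters a balloon–windkessel hemodynamic
model (signal, flow, volume $v$, deoxyhemoglobin $q$), and BOLD is read
out as

$$y = 100\, V_0 \left[ k_1 (1 - q) + k_2 (1 - q/v) + k_3 (1 - v) \right]$$

with 1.5 T constants $k_1 = 7E_0$, $k_2 = 2$, $k_3 = 2E_0 - 0.2$,
$V_0 = 0.02$, $E_0 = 0.4$. Integration uses a fixed-step scheme on the
microtime grid in compiled code; stability of every draw is checked via
the eigenvalues of $A + \sum_j B_j$ over the attainable input
combinations.

## Model space

Stage one compares seven structural architectures, all driven by faces
into V1, from serial feedforward chains to the fully interconnected
model (both directions for every FG/AMY/OFC pair plus V1–FG both
ways), which is the designated winner. Stage two fixes that winner and
compares 21 patterns of emotion-specific modulation over the six
directed FG/AMY/OFC interconnections, partitioned into 7 families by
pattern type: Family 1 contains the six single-edge models (Model 2 =
FG→OFC, Model 5 = OFC→FG); Family 7 contains the three two-pair
bidirectional models, with Model 21 modulating OFC↔AMY and OFC↔FG. The
space is table-driven (`inst/extdata/model_space.yaml`) and the loader
validates all of these invariants.

## Priors and inversion

Inversion is variational Laplace: a Gaussian posterior over parameters
$\theta$ and a pooled log-precision $\lambda$ for observation noise,
optimising the free energy (an evidence lower bound that equals the
exact log marginal likelihood for linear-Gaussian models, which is how
the implementation is validated). Priors are zero-mean Gaussians:
variance 0.25 for intrinsic, modulatory and driving parameters, 1/16
for the log self-decay scale, and $\lambda \sim N(0, 16)$.
Hemodynamic constants are pinned by default.

Numerical choices worth recording:

- The Jacobian of the forward model is obtained by one-sided finite
  differences (step $10^{-3}$) and parameter updates are
  Levenberg-damped Gauss–Newton steps; $\lambda$ is updated by a
  backtracked Newton step.
- The Laplace complexity term $-\tfrac12 \log |H|$ depends on the
  Jacobian at the expansion point. The objective is therefore
  re-baselined whenever the Jacobian is refreshed, and step acceptance
  always compares free energies computed with the *same* Jacobian.
  Without this, stale comparisons can silently stall the optimiser far
  from the optimum. The accepted-step trace is exactly monotone for
  linear models and monotone between refreshes otherwise.
- Convergence requires both the achieved and the Gauss–Newton-predicted
  improvement to fall below the tolerance, so a rejected step does not
  masquerade as convergence.
- Low-frequency discrete-cosine confounds (cutoff twice the longest
  same-condition onset spacing) and the mean are projected out of data
  and prediction, with the effective number of observations reduced
  accordingly.

When the data contain modulations by more than one emotion, fitting one
emotion's model space alone is misspecified: the unmodelled modulation
leaks into intrinsic estimates and biases model comparison. The
pipeline's `fit_mode = "joint"` therefore adds the other emotion as a
*saturated* nuisance modulator (all six interconnections free) to every
candidate. Because the nuisance structure is identical across
candidates and agnostic to any particular pattern, it absorbs the
other emotion's signal without informing the comparison.

## Model selection

Subject-level free energies enter fixed-effects (summed log evidence)
or random-effects (variational Dirichlet over model frequencies)
selection. Families receive equal priors, split equally among members,
so family size does not bias family-level posteriors; the winning model
is selected within the winning family after renormalisation.

## PPI

The psychological vector is +1 on the emotion's volumes, −1 on neutral,
0 elsewhere; the interaction regressor is its elementwise product with
the amygdala seed series. The target (FG or OFC) is regressed on the
interaction with both main effects and an intercept and linear drift
partialled out. Group differences use Welch t tests with Bonferroni
correction over the two targets; symptom correlations are
product-moment with exact t-based p values.

## Synthetic cohorts: scope and ground truth

`cohort_spec()` defines each cohort by a ground-truth model id per
emotion. Defaults encode the group-by-valence reversal: HC have happy →
Model 5 and sad → Model 21; rMDD have happy → Model 21 and sad →
Model 2. Subject couplings are drawn around population means
(intrinsic 0.2, self −1.0, modulatory 0.4, driving 0.8 Hz; SD 0.08),
rejected until bilinearly stable. Noise SD is set from the requested
SNR relative to the noiseless signal SD; Legendre drift and a
half-normal symptom score are added, and a weak-OFC subtype (couplings
into OFC attenuated ×0.1) exercises the subject-inclusion rule.

The generator is deliberately *well-specified with respect to the
fitted model family*: the same bilinear + balloon forward model
produces and fits the data. It is therefore evidence about the
correctness and power of the inference machinery, not about
hemodynamic model misspecification, physiological noise structure, or
motion — none of which are simulated.

## Limitations

- Free energies are lower bounds from a Laplace–Gaussian family; model
  comparison inherits any bound slack that differs between models.
- At SNR 1 a single-edge modulation (e.g. Model 5's OFC→FG during
  happy blocks) carries little information per subject, so model-level
  (as opposed to family-level) identification at small group sizes
  operates close to its power limit by design.
- The hemodynamics are pinned at canonical 1.5 T constants during
  inversion; regional hemodynamic variability is representable in the
  interface (`prior_spec(hemo_var = ...)`) but is not part of the
  default analysis.
- PPI is a descriptive regression at sampling resolution; it is used
  here as a complementary check on the DCM results, not as a
  deconvolution-based estimator of neural-level interactions.
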