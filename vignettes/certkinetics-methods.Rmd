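---
title: "Kinetic models, Bayesian calibration and model comparison for TGN ceramide-transfer signaling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetic models, Bayesian calibration and model comparison for TGN ceramide-transfer signaling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(certkinetics)
```

## The biological system and the two competing models

Secretory vesicle formation at the trans-Golgi network (TGN) depends on a
phosphorylation circuit of three proteins: protein kinase D (PKD), the lipid
kinase PI4KIII&beta;, and the ceramide transfer protein CERT.  Active,
DAG-bound PKD (`PKDpDAG`) phosphorylates PI4KIII&beta; (activating PI4P
production, which recruits CERT to the TGN) and CERT itself (detaching CERT
from the TGN).  CERT-mediated ceramide delivery in turn feeds back on PKD
activation, because ceramide is converted at the TGN into sphingomyelin plus
DAG, and DAG recruits and activates PKD.

The two model variants encode the two mechanistic hypotheses for CERT
transport:

* **Variant A (shuttle).** CERT stays anchored to the ER; PKD
  phosphorylation only detaches it from the TGN.  States: `PKD`, `PKDpDAG`,
  `PI4K`, `PI4Kp`, `CERTpER`, `CERTaER`, `CERTaTGN`.  The overall feedback
  loop between transfer activity and PKD is positive.
* **Variant B (neck-swinging).** Phosphorylation detaches CERT from both
  membranes, so only unphosphorylated CERT is transfer-active.  States:
  `CERTp`, `CERTa`, `CERTaERTGN` replace the three CERT forms.  PKD activity
  directly depletes the transfer-active pool: a negative loop.  Variant B
  carries one additional parameter, `k_phos_free`, a PKD-dependent
  phosphorylation of free CERT (`PKDpDAG * CERTa` mass action), which is how
  we realize the "one parameter more" difference between the variants.

Both variants have 7 state variables; A has 26 and B has 27 parameters.
Units are fixed throughout: molecules/cell for amounts, hours for time,
molecules/(cell h) for synthesis rates and maximal rates, 1/h for
first-order rates.

## Rate laws

Regulated (catalysed) reactions use a double-saturating form

$$v = v_{max}\; \frac{E}{K_E + E} \; \frac{S}{K_S + S},$$

with regulator $E$ and substrate $S$.  This form is bounded by $v_{max}$, so
every regulation has a well-defined *operating point* $v / v_{max} \in
[0, 1)$: values far below one mean the coupling is unsaturated and highly
responsive to changes in the regulator.  The regulated reactions are
PI4KIII&beta; phosphorylation (regulator `PKDpDAG`), CERT phosphorylation
(regulator `PKDpDAG`), and CERT recruitment to the TGN (regulator `PI4Kp`,
lumping PI4P production into the recruitment term).

The ceramide transfer flux is linear in the TGN-delivering CERT form,
$J = k_{10}\,\mathrm{CERT_{TGN}}$ (molecules/h).  Ceramide itself is not a
state variable; $J$ is a pure output flux.  Its feedback on PKD activation
(lumping SMS-driven DAG production, recruitment and activation) is a single
saturating channel $v_{max,cer}\, J/(K_{cer}+J)$.  This channel is
deliberately substrate-independent — that keeps the parameter count at
26/27 — with a hard guard that it vanishes when PKD is exhausted, so
trajectories cannot be driven negative.  Its half-saturation constant
$K_{cer}$ consequently has units of molecules/h.

PI4P and DAG are never explicit states: their production and action are
lumped into the regulated recruitment and activation terms.

Turnover: each protein has one synthesis rate (into the unphosphorylated /
ER-side form) and one first-order degradation rate applied equally to all
of its forms.  Per-form degradation rates are not identifiable from the
available observables, and a shared rate keeps the parameter counts at
26/27.

## Experimental inputs

Four step inputs, each piecewise constant in time:

| input | meaning | mechanism in the model |
|-------|---------|------------------------|
| `u1` | PDBu (PKD activator) | extra activation channel `u1 * k_pdbu * PKD` |
| `u2` | kb-NB142-70 (PKD inhibitor) | divides PKD-catalysed `vmax` terms and the basal/PDBu activation channels by `1 + k_inh * u2` |
| `u3` | ectopic PI4KIII&beta; expression | constant extra synthesis `u3 * s_ect_PI4K` |
| `u4` | ectopic CERT expression | constant extra synthesis `u4 * s_ect_CERT` |

PDBu acts upstream of PKD (so it is an activation channel on inactive PKD);
the inhibitor blocks PKD kinase activity, including the autophosphorylation
that the pS910 blot readout reports, which is why it divides both the
catalytic `vmax` terms and the activation channels.  The inhibition
strength `k_inh` is a counted model parameter rather than a separate input
amplitude.  Ectopic (tagged) protein is assumed kinetically identical to
endogenous protein and pooled into the same species, with constant synthesis
from transfection at $t = 0$.  Every protocol starts from the endogenous
steady state (all inputs off), because cells are unperturbed before
transfection.

## Observation model

Blot observables map to states as: `pPKD` (y4) &rarr; `PKDpDAG`, `pPI4K`
(y5) &rarr; `PI4Kp`, `pCERT` (y6) &rarr; the phosphorylated CERT form
(`CERTpER` in A, `CERTp` in B); `*_total` observables are sums over all
forms of a protein and are absolute (molecules/cell).

Relative phospho time courses carry an unknown per-course gain (antibody
affinity, exposure).  Under the Gaussian noise model the maximum-likelihood
gain has a closed form,

$$\hat s = \frac{\sum_i x_i d_i / \sigma_i^2}{\sum_i x_i^2 / \sigma_i^2},
\qquad \hat s \ge 0,$$

and is profiled out inside the likelihood rather than sampled.  Profiling
was chosen over fixed-point normalization (e.g. dividing by the $t=0$
band) because early bands can sit near background; it is exact under the
noise model and adds no dimensions to the posterior.  Negative profiled
gains are clipped to zero (a blot signal cannot invert), and an all-zero
model course gets gain zero by convention.

The likelihood is independent Gaussian per record with the measured
(replicate-derived) standard deviations — noise variances are taken from
the data, not estimated.  Failed simulations map to `-Inf` log-likelihood
instead of raising, so samplers and optimizers reject such proposals
gracefully.

## Priors and MAP estimation

All parameters get independent log-uniform priors: a box of ±3 log10 units
around a central parameterization (normally the best multistart MAP
estimate), with two literature-style caps: degradation rates are confined
to protein half-lives of 1–100 h, and endogenous synthesis rates to the
range that keeps steady-state totals between 10^3 and 10^9 molecules/cell
at the corresponding turnover bounds.  MAP estimation runs repeated
L-BFGS-B maximizations from log-uniform starting points
(`multistart_map()`), ranked by posterior value.

## Parallel-tempering MCMC

`pt_sample()` runs Metropolis random walks in log10 parameter space on a
ladder of inverse temperatures $\beta_0 = 0 < \dots < \beta_{L-1} = 1$
(tempered density $p(\theta)\,L(\theta)^{\beta}$), with one random
adjacent-pair swap attempt per iteration (acceptance
$\min\{1, \exp[(\beta_i-\beta_j)(\log L_j - \log L_i)]\}$).  Step sizes are
adapted toward a 20–30% acceptance rate during burn-in (default: the first
half) and frozen afterwards, so the post-burn-in kernel is a valid MCMC
kernel for the tempered targets.  Runs are bit-reproducible given the seed.
Convergence is checked across independent runs with the Gelman–Rubin
potential scale reduction
$\hat R = \sqrt{((N{-}1)/N \cdot W + B/N)/W}$ (pass: all $\hat R < 1.1$);
degenerate (zero-variance) chains are flagged.  A representative posterior
subsample (`subsample_posterior()`: burn-in discard, uniform thinning,
seeded random subsample) feeds all prediction functions.

The ladder uses the power-law schedule $\beta_i = (i/(L-1))^p$.  The
package default is $p = 5$, which concentrates rungs near $\beta = 0$
where the thermodynamic-integration integrand is steep.

## Evidence and model comparison

The log marginal likelihood is computed by thermodynamic integration,
$\log Z = \int_0^1 E_\beta[\log L]\, d\beta$, with trapezoidal quadrature
over the ladder and per-rung expectations taken from the post-burn-in
chains (`-Inf` draws from failed simulations are excluded and counted).
The uncertainty attached to $\log Z$ is the spread over independent
repeated sampling runs.  Bayes factors are reported as
$2\log K = 2(\log Z_A - \log Z_B)$ with uncertainties combined in
quadrature and categorized on the Kass–Raftery scale ((0,2] barely worth
mentioning, (2,6] positive, (6,10] strong, >10 very strong).

A practical warning that shapes the package defaults: with wide
(±3 log10) priors the integrand $E_\beta[\log L]$ is on the order of
$-10^7$ at $\beta = 0$ and extremely heavy-tailed, while the posterior-end
values are $O(-10^2)$.  A coarse ladder therefore puts enormous,
noise-dominated weight on the first trapezoid panel.  With few rungs the
first rung must sit very deep: for 4-level desk-scale runs we use
$p = 10$ (first rung $\beta_1 \approx 1.7\times10^{-5}$, the same depth as
a 10-level $p=5$ ladder), which we found necessary for the run-to-run
spread of $2\log K$ to be small compared to its value; $p = 5$ at 4 levels
leaves $|2\log K|$ estimates that are pure first-panel noise (spreads in
the thousands).  Evidence values from coarse ladders remain biased (the
bias largely cancels in model comparisons on the same ladder and data);
dense ladders (10+ levels) are the configuration of record for evidence
numbers.

## Predictions

`endogenous_distributions()` maps each posterior draw to the steady state
with all inputs off, all reaction fluxes (molecules/h) and all operating
points, and summarizes each quantity by its expectation and the
[0.5, 99.5] percentile band (99% central mass — percentiles, not
mean±SD, because amount posteriors are skewed on the linear scale; they are
displayed on a log axis).  Draws whose steady state fails to converge are
dropped and counted; more than 10% dropped raises an error.

`perturbation_response()` implements three scenarios per draw:

* `feedback_knockout` — the transfer&rarr;PKD activation channel is
  removed (`vmax_cer = 0`); reported is the % change of steady-state
  `PKDpDAG`.  We report the change *upon removing* the feedback; the
  complementary direction (what the feedback contributes) is the signflip
  of the same number to first order.
* `transfer_up_10` — `k10` is scaled by 1-D root finding (relative
  tolerance 1e-6) until steady-state $J$ is up by exactly 10%; reported is
  the % change of `PKDpDAG`.
* `pkd_up_10` — the basal activation rate `k_act` is scaled until
  steady-state `PKDpDAG` is up by 10%; reported is the % change of $J$.
  Scaling the basal channel (not the CERT-dependent one) mirrors how a
  PDBu-like stimulus acts upstream of PKD.

Reported percentages are posterior expectations of the per-draw relative
change (not the relative change of posterior expectations); the per-draw
distribution is returned so either summary can be formed.

## Absolute quantification

`fit_standard_curve()` is ordinary least squares of band intensity on
molecule number with an intercept (blot backgrounds shift intensities;
image-level background correction is upstream of this package).
`inverse_predict()` inverts the curve for an unknown intensity with a
delta-method standard error that propagates the residual noise of the new
measurement and the coefficient covariance; the delta method was chosen
over Fieller intervals because abundances are reported at
coefficient-of-variation precision.  `endogenous_abundance()` converts an
endogenous/ectopic signal ratio into molecules per cell, combining input
CVs in quadrature.

## The synthetic-data generator

`generate_dataset()` emulates the statistical structure of the calibration
data: endogenous absolute quantification (steady-state totals) with a
30% CV by default (admissible 25–40%, the blot-quantification range), in
3 replicates; relative phospho courses with additive Gaussian noise of SD
equal to 10% of each course's noise-free maximum; and the five experiment
families E1–E5 (ectopic expression ramps over 24 h in culture, PDBu
activation, kb-NB142-70 inhibition, early/long-time refinement courses,
and a validation point at 25.25 h).  Exact intermediate sampling grids for
the time courses are fixture choices covering the experimental ranges.
The long-time refinement horizon after PDBu defaults to 6 h and is
configurable.  Absolute replicates are truncated at zero, while the
recorded SD stays at the pre-truncation value so the Gaussian likelihood
stays consistent with the generating distribution.

The shipped ground-truth parameter files are documented synthetic
fixtures, chosen once so that: endogenous totals sit near the measured
orders of magnitude (PI4KIII&beta; ~2·10^6, PKD and CERT ~5·10^5
molecules/cell); most PKD and PI4KIII&beta; is unphosphorylated at rest
while most CERT is transfer-active; the basal PKD activation flux is about
two orders of magnitude above the transfer-dependent channel; protein
half-lives are ~14 h; and the variant-specific feedback signs hold (in A,
+10% active PKD raises transfer by a few percent, removing the feedback
costs PKD less than 1%; in B, raising PKD activity lowers transfer).  They
are not estimates of any real posterior.

What the generator does *not* emulate: antibody saturation and blot
nonlinearity, correlated lane noise, image-processing artifacts, biological
cell-to-cell variability, or model error (data are generated from the same
model family that is fitted).  Passing calibration and coverage tests on
these data therefore validates the inference machinery, not the biological
adequacy of either model for real lysates.  (Coverage checks compare
noise-free observables to the posterior *predictive* band, i.e. parameter
uncertainty plus the Gaussian noise model, as is standard.)

## Numerical choices

* Integration: `deSolve::lsoda`, relative tolerance 1e-8 (absolute 1e-4
  molecules), restarted at every input switch so discontinuities are never
  stepped across.  Inside the likelihood the step budget per integration is
  capped (5000); parameter corners that exhaust it count as failed
  simulations (`-Inf`), which slightly disfavors pathologically stiff
  corners of the prior box.
* Steady states: integration over ten times the slowest turnover timescale
  from a turnover-balanced start, then damped Newton polishing to a
  max-norm residual of 1e-6 molecules/(cell h).  Inside iterative code the
  previous solution warm-starts the Newton step.  States are clipped at
  zero during flux evaluation so integrator micro-undershoots cannot
  produce negative fluxes.
* Determinism: every stochastic routine takes an explicit seed and restores
  the caller's RNG state; chains, datasets and subsamples are
  bit-reproducible.
* Desk-scale defaults (used by the test-suite's end-to-end checks and the
  acceptance script): 4 temperature levels, 6000–20000 iterations, 2–3
  runs, ~100-draw posterior subsamples, ~46-record datasets.  The
  study-scale configuration (10 levels, 5·10^5 iterations, 3 runs) is
  available through `pipeline_config()`.

## Known limitations

* **Variant B nests variant A.**  Setting `k_phos_free = 0` in B and
  relabeling the CERT states (`CERTp`&harr;`CERTpER`,
  `CERTa`&harr;`CERTaER`, `CERTaERTGN`&harr;`CERTaTGN`) reproduces
  variant A exactly.  Empirically, the best-fit log-likelihoods of the two
  variants agree to a fraction of a nat on data generated from *either*
  variant.  Bayes factors between them on such data therefore measure only
  the Occam penalty of the extra, weakly constrained `k_phos_free`
  dimension — O(1) on the 2 log K scale — and tend to favor the smaller
  model A regardless of which variant generated the data.  Identifying the
  generating variant by the sign of 2 log K is consequently not a reliable
  operation for this model pair at desk scale; discriminating the two
  transport mechanisms requires rate structures (or observables) in which
  the variants are not nested.
* The transfer&rarr;PKD activation channel is substrate-independent by
  construction; at parameter corners where PKD is nearly exhausted its
  hard positivity guard makes the right-hand side discontinuous.
* Evidence estimates from coarse ladders are biased (see above); only
  their comparison on a common ladder is meaningful at desk scale.
* With ~46 records, many of the 26/27 parameters are weakly identified;
  coverage statements are therefore restricted to parameters flagged
  identifiable by the posterior-width criterion (95% interval narrower
  than 60% of the prior box).
* The Gaussian additive noise model is an idealization of blot
  densitometry; the generator and likelihood share it by design.
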