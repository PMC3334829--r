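---
title: "Source reconstruction under head-position uncertainty: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Source reconstruction under head-position uncertainty: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

MEG source reconstruction assumes the cortical surface is known in the
sensor frame. In practice the co-registration between the anatomical model
and the MEG helmet is uncertain at the several-millimetre level, and the
lead fields — the linear operators mapping cortical dipole moments to
sensor measurements — depend *non-linearly* on that alignment. A fixed-head
inversion therefore inherits an unquantified error. `megcoreg` treats the
six rigid-body degrees of freedom of head position (three translations in
mm, three rotations in degrees, rotating about the mid-point of the ear
fiducials) as unknowns with a posterior distribution of their own.

## The model

For a head hypothesis $h$, data $Y \in \mathbb{R}^{m \times N_t}$ (possibly
eigenmode-reduced) follow the Gaussian linear model

$$Y = L_h J + \varepsilon, \qquad
  J \sim N(0, Q), \qquad \varepsilon \sim N(0, R),$$

with $R = e^{\lambda_0} I$ (uniform white sensor noise, exponentiated to
stay positive) and the multiple-sparse-priors (MSP) source covariance

$$Q = \sum_{i=1}^{N_p} e^{\lambda_i} D_i, \qquad D_i = g_i g_i',$$

where $g_i$ is the column of the graph-Laplacian Green's function
$G = \exp(s\,(A - \mathrm{diag}\,\mathrm{deg}))$ at the $i$-th patch
centre: each component is one candidate patch of activated cortex, and the
log-weights $\lambda$ are the hyperparameters. Conditional on $h$ and
$\lambda$ the source posterior is Gaussian with

$$\hat J = Q L' (R + L Q L')^{-1} Y, \qquad
  \Sigma_J = Q - Q L' (R + L Q L')^{-1} L Q.$$

Model quality is scored by the variational free energy,
$F = \text{accuracy} - \text{complexity}$: the accuracy is the Gaussian
log-density of the data under the model covariance $C_Y = R + LQL'$, and
the complexity
$\tfrac12 e_\lambda' C_\lambda^{-1} e_\lambda +
 \tfrac12 \log(|C_\lambda|/|\Sigma_\lambda|)$, with
$e_\lambda = \mu - \nu$, charges hyperparameters for moving away from their
prior $N(\nu, C_\lambda = \alpha I)$. $F$ approximates the log model
evidence $\log p(Y \mid h)$, which is exactly the quantity a posterior over
head positions needs.

Three layers sit on top of the fixed-head inversion:

1. **Metropolis search over $h$** — a Gaussian random walk with per-axis
   standard deviation $2.4/\sqrt 6$ (mm / degrees), acceptance ratio
   $\exp(F(h') - F(h))$ times the uniform-prior indicator (±20 mm
   translation box, free rotation). Multiple chains run in lockstep and
   stop when the Gelman–Rubin ratio on the $F$ traces,
   $\hat R = \widehat{\mathrm{var}}(F \mid Y) / Z$ computed on the second
   half of each chain, comes within tolerance of 1 (default 1.1; the
   plain variance ratio is used, with a square-root option).
2. **Burn-in discard** — strictly the first half of every chain.
3. **Bayesian model averaging** — $T = 10{,}000$ draws: pick a pooled
   posterior head sample uniformly, fetch its $\hat J_k$ and
   $\mathrm{diag}\,\Sigma_{J,k}$, draw a Gaussian source realisation, and
   summarise. This yields the averaged current density, per-vertex
   posterior variance, a discrete posterior over the location of peak
   power (with smallest-set 95% confidence regions), and the posterior
   cloud of the three fiducials, whose mean is the head-location summary.

## Hyperparameter optimisation

The fitting of $(\lambda_0, \lambda)$ maximises $F$ by a restricted
maximum-likelihood ascent on the sensor-space covariance: the primary step
is the multiplicative fixed-point update
$e^{\lambda_i} \leftarrow e^{\lambda_i}\,
  (\tilde w_i' C^{-1} \hat C_Y C^{-1} \tilde w_i) /
  (\tilde w_i' C^{-1} \tilde w_i)$
(with $\hat C_Y = YY'/N_t$), which follows the curved valley coupling the
noise level to the component weights; a Fisher-scoring step is the
safeguarded fallback, and a backtracking line search keeps the objective
non-decreasing. Components whose weight collapses below $10^{-8}$ of the
largest are frozen (automatic relevance determination). The posterior
covariance of the hyperparameters, $\Sigma_\lambda$, is the inverse Fisher
curvature at the optimum.

Numerical choices that matter:

* **Internal rescaling.** Each sensor-space component $L D_i L'$ is
  normalised to unit mean diagonal and the data to unit mean sensor power,
  so the uninformative prior mean $\nu = 0$ puts every component at the
  data scale for *every* head hypothesis; reported hyperparameters are
  shifted back to raw units (the complexity term is invariant because
  $\mu$ and $\nu$ shift together).
* **Noise floor.** The sensor variance is bounded below at $10^{-3}$ of
  the mean sensor power. On noiseless, exactly rank-deficient data the
  Gaussian likelihood is unbounded as $e^{\lambda_0} \to 0$ and the
  attained $F$ would measure optimiser descent depth rather than evidence;
  the floor (an effective 30 dB ceiling, below the real noise at every SNR
  in the study design, whose largest is 20 dB) makes noiseless evidence
  finite and comparable across heads.
* **Convergence.** $|\Delta F| < 0.01$ over four successive iterations
  *and* a small projected gradient (noise parameters pinned at the floor
  excluded), capped at 128 iterations. The free-energy differences that
  drive every downstream decision are $10^2$–$10^4$, so the per-iteration
  tolerance is far below anything that could change a comparison.
* **Warm start.** Every head hypothesis starts from the converged
  hyperparameters of the reference head — one fixed initialisation, so
  $F(h)$ remains a well-defined function of $h$.
* Determinants via Cholesky throughout; a relative jitter fallback guards
  rank-deficient model covariances; only the diagonal of $\Sigma_J$ is
  computed in the pipeline.

## What the simulator emulates

`simulation_spec()` reproduces the synthetic study design: 161 samples at
200 Hz, sinusoidal sources (defaults 20, 20, 10 Hz — two synchronous
lateral sources plus one frontal), spatial profiles of ~10 mm FWHM centred
on randomly chosen MSP patch centres, and white sensor noise calibrated so
that $10\log_{10}(\mathrm{var}(Y)/\mathrm{var}(\text{noise}))$ matches the
requested decibel figure, with the signal variance pooled over sensors and
samples. Source centres are restricted to patch centres the array can see
(unit-current field amplitude at least 10% of the maximum), like the
superficial lateral and frontal sources of the study design. The default
spatial profile is the MSP patch profile at the chosen centre
(`profile = "patch"`), whose width is calibrated to the stated FWHM; a
resolution-independent analytic Gaussian is available as
`profile = "gaussian"`. At fine mesh resolution the two coincide. At
coarse resolution only the patch profile keeps the design's premise that a
patch-centre source is exactly representable by the prior dictionary —
with a mismatched profile, the ~1% spatial tails spill signal variance
into otherwise-empty eigenmodes, and on noiseless data that spill costs
hundreds of log-evidence units, enough for a rotational alias of the
sparse patch grid to outscore the true head. The truth is the reference
head (the search prior is centred on it, as when a co-registration
estimate is the starting point), and chains initialise from the prior box
with orientations within ±15° of the reference.

The synthetic cortex is a deterministic latitude/longitude sphere (left
open at the poles: closing fans would create high-degree vertices with
exactly radial, hence externally silent, normals) carrying three kinds of
shape structure: a low-order deformation, a single-lobed order-1 azimuthal
asymmetry (`asym = 0.07`, the "face"), and higher-frequency "sulcal"
ripples (`fold = 0.14`). All three are physically load-bearing. In a
spherical conductor only the non-radial component of a dipole produces any
external field, so an unfolded surface (near-radial normals) would carry
almost invisible sources; with the ripples the vertex normals tilt 10–30°
from radial, as on folded cortex. And without the order-1 asymmetry the
surface retains approximate rotational symmetries at the spacing of the
sparse patch grid (~20° at 64 components), so a head rotated by one grid
step can alias onto the true one; real heads have a dominant front–back
asymmetry and no such symmetry. The forward model is the closed-form field of
a current dipole in a homogeneous conducting sphere evaluated at point
magnetometers; the sphere is re-fitted to the mesh on every call, so the
conductor moves rigidly with the head (this is also what makes the lead
field frame-covariant). Realistic-geometry effects the simulator does
*not* emulate: boundary-element conductor shapes, gradiometer pickup
coils, correlated or non-stationary sensor noise, evoked-response
averaging, and head movement during the recording — so green tests here
say nothing about those.

## Scale, resolution, and the patch dictionary

Tests and the bundled experiment run at a reduced desk scale: 500 dipoles,
60 sensors, 40 eigenmodes, 64 components (the full-scale counterparts are
8196 / 274 / 100 / 512 and are reachable through the same arguments or
`--scale paper`). One resolution interaction deserves care: the Green's
smoothing coefficient counts in *graph steps*, so a value that gives
~10 mm patches on a 3 mm-edge mesh gives ~40 mm patches on a 15 mm-edge
mesh, while 10 mm FWHM sources are then sub-resolution deltas — and with
an over-wide dictionary a *displaced* head can fit a delta source better
than the true one. `calibrate_smoothing()` therefore picks the coefficient
whose normalised patch profile best matches the simulator's Gaussian
source profile on the actual mesh (near-delta patches at the reduced
scale, conventional values on fine meshes); `run_experiment()` and the
command-line pipeline use it by default, while `green_function()` keeps
the conventional default of 0.6 for callers who set their own scale.

At the reduced scale with the default patch-profile sources, the
three-source design at SNR 0 dB yields mean fiducial errors of ~3 mm
(five seeds; the full-scale study reports ~4 mm), exact source recovery
(patch quantisation absorbs moderate head error: the nearest wrong patch
centre is over 24 mm away at this component count), zero source error for
the noiseless one- and five-source designs, and ~1.9 mm fiducial error for
the noiseless five-source case. At SNR −20 dB the posterior is essentially
the prior and the fiducial error is bounded by the prior uncertainty,
~20 mm of translation half-width plus rotation wander through the ~80 mm
lever arm from the rotation origin to the fiducials (measured ~22 mm mean
over four seeds).

## Design choices where the design was open

* **Rotation convention**: intrinsic x–y–z Euler angles in degrees about
  the ear mid-point (the origin is standard; the angle convention had to
  be fixed somewhere).
* **Patch centres**: deterministic farthest-point sampling over the
  vertex coordinates (uniform index strides are only spatially uniform if
  the vertex ordering is; on a ring-ordered mesh they cluster). The rule
  is deterministic, so component sets are reproducible across runs and
  machines, and centres are at least ~24 mm apart at the reduced scale.
* **Proposal scale**: the per-axis standard deviation is read as
  $2.4/\sqrt 6$, the classical $2.4/\sqrt d$ random-walk scaling for a
  $d$-dimensional target.
* **Head-independent $Q$**: the component set is built once in the head
  frame; only the lead field changes with $h$ (the dipole layout inside
  the head does not move relative to the head).
* **Anomalous-sample rejection**: occasionally a chain traps at a minor
  local maximum of $F$ 15+ log-evidence units below the main basin; its
  samples carry posterior odds below $e^{-15}$ and a mixed sampler would
  essentially never visit them. `run_experiment()` removes pooled samples
  more than 12 log-units below the best (the ~99.9th percentile of the
  expected $\chi^2_6/2$ spread of $F$ across a six-parameter posterior)
  before the fiducial and BMA summaries; `run_multichain()` itself applies
  no filter. BMA additionally uses a 3 log-unit Occam window by default.
* **BMA computation**: in the default `"power"` mode the per-draw
  time-integrated power map is sampled exactly from its scaled noncentral
  chi-square law, and the averaged current is the Rao-Blackwellised
  mixture mean over the picked heads; the `"current"` mode draws the
  current matrix elementwise and is used to verify the mixture identities.
* **Degenerate inputs**: dipoles at the conductor centre or with radial
  orientation give exactly zero lead-field columns (no singularity in this
  parameterisation) and their components are pruned; all-equal
  free-energy traces make $\hat R$ undefined and are reported as converged
  with a flag; proposals outside the prior box are rejected without a
  forward evaluation.

## Limitations

The conductor is a single homogeneous sphere — adequate for MEG and for
studying the inference machinery, not for EEG or skull-shape questions.
The search prior is deliberately worst-case (flat); an informative prior
from an actual co-registration would tighten everything. Patch extent and
conductivity are treated as known. The Metropolis proposal is not adapted
during sampling, so very sharp evidence surfaces (high SNR, noiseless)
mix slowly near the mode; the convergence rule then typically stops the
search at the sample cap rather than by $\hat R$.

## A worked run

```{r}
library(megcoreg)
ex <- run_experiment(simulation_spec(snr_db = 0), seed = 1)
glance(ex)                      # fiducial + source errors, Rhat, acceptance
autoplot(ex$search)             # free-energy traces per chain
tidy(ex$bma)                    # per-vertex mean power / peak mass
peak_location_posterior(ex$bma) # 95% confidence set for the power maximum
```
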