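---
title: "Methods: spectral DCM for resting-state networks across the lifespan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spectral DCM for resting-state networks across the lifespan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(specdcm)
```

`specdcm` estimates directed (effective) connectivity among resting-state
fMRI networks from the complex cross-spectral density (CSD) of their BOLD
time courses, and relates the estimated parameters to age and cognition.
This vignette is the package's account of the model, the estimation
machinery, the synthetic cohort used to validate it, and the numerical and
design choices behind each — including what the validation does and does
not demonstrate.

## The generative model

Neural activity in $n$ nodes (here: three networks, or the nodes of one
network) follows a linear stochastic differential equation,

$$\dot x(t) = A\,x(t) + v(t),$$

where $A$ is the $n \times n$ effective-connectivity matrix in Hz. Entry
$A_{ij}$ ($i \neq j$) is the directed influence of node $j$ on node $i$.
Diagonal entries are not free rates: each self-connection is
$A_{ii} = -0.5\,e^{a_{ii}}$, a log-scaling of a $-0.5$ Hz reference decay.
This keeps the diagonal negative for any real $a_{ii}$, so "stronger
self-inhibition" is a single signed scalar and unconstrained optimization
cannot produce a node that excites itself. Stability of the network
requires every eigenvalue of $A$ to have negative real part;
`stability_check()` tests exactly that.

The endogenous fluctuations $v(t)$ driving each node are specified in the
frequency domain by a two-parameter power law,
$g_v(\omega) = e^{\alpha_v}\,\omega^{-\beta_v}$ (with $\omega$ in rad/s),
i.e. a log-amplitude and a spectral exponent per node. The same form with
a single global amplitude/exponent pair, scaled by a fixed reference level,
describes the observation (channel) noise.

Neural states are observed through a hemodynamic model per node: a
vasodilatory signal with decay rate $\kappa = 0.64\,e^{\mathrm{decay}}$
s$^{-1}$ and autoregulation $\gamma = 0.32$ s$^{-1}$ drives blood inflow;
venous volume follows with transit time $\tau = 2\,e^{\mathrm{transit}}$ s
and Grubb exponent $0.32$; deoxyhemoglobin dilutes and washes out; and the
BOLD read-out mixes volume and deoxyhemoglobin terms with an
intravascular/extravascular ratio $\varepsilon = e^{\epsilon}$. The three
free hemodynamic parameters per subject (transit and decay per node,
$\varepsilon$ global) are log-scalings of those reference values, so all
physical rates stay positive. Whether $\varepsilon$ should vary per node
is genuinely open; it is implemented as a global scalar, switchable in
principle by treating it as an extra per-node parameter family.

Because the model is fitted in a narrow band (0.008–0.1 Hz) where the
balloon dynamics are effectively linear, the observation model is the
first-order transfer function $K(\omega)$ of the balloon system linearized
about its resting fixed point. `hemodynamic_kernel()` returns it per node;
the linearization is also available in closed form, used by the compiled
fast path and cross-checked in the tests against Runge–Kutta integration
of the same ODEs (agreement to ~$10^{-8}$ relative L2 error, i.e. exact up
to integration error). The read-out is in percent signal change
($V_0 = 4$); with all log-parameters at zero this puts the in-band
signal-to-noise ratio near 10 against the observation-noise reference
level (`noise_ref = 100` in `balloon_constants()`), which is the regime
the default priors assume.

Putting the pieces together, the predicted CSD is

$$G_y(\omega) = K(\omega)\,(i\omega I - A)^{-1}\, G_v(\omega)\,
  (i\omega I - A)^{-H}\,K(\omega)^H + G_e(\omega),$$

with diagonal $K$, $G_v$, $G_e$. `predicted_csd()` evaluates this on a
grid of 32 linearly spaced frequencies from $1/(T\,\mathrm{TR})$ to
0.1 Hz. All interfaces take Hz; the rad/s conversion happens once,
internally. A single-node sanity anchor: with $A = -0.5$, white
unit-amplitude input and an identity kernel, the predicted spectrum is the
Lorentzian $1/(\omega^2 + 0.25)$, which the implementation reproduces to
machine precision.

## Simulating BOLD data

`simulate_bold()` synthesizes series directly in the frequency domain:
independent complex Gaussian Fourier coefficients at each DFT frequency
are scaled by a Hermitian matrix square root of the predicted CSD and
inverse transformed. The population cross-spectrum of the output therefore
equals `predicted_csd()` *exactly* — no integration error, no transient —
which is why it is the default simulator; a time-domain SDE integrator
appears only as a test oracle (for the stability contract). The
scaling convention ($E[X_k X_k^H] = (N/\Delta)\,S(f_k)$ for a two-sided
per-Hz density $S$) is the one the MAR estimator inverts, and the
long-run consistency tests (Welch and MAR oracles against
`predicted_csd()`) pin it down.

## Estimating cross-spectra from data

`estimate_csd()` fits a vector autoregression (MAR) of order 8 by least
squares to the (linearly detrended) series and evaluates its implied
spectral matrix on the analysis grid. Order 8 is a standard choice for
smooth band-limited spectra at these series lengths and is configurable.
Detrending replaces the confound regression that, for real recordings,
happens upstream of this package. The series are *not* standardized by
default: the absolute spectral scale carries the information that
identifies the fluctuation-amplitude parameters, and standardizing would
break the exact correspondence between generator and estimator;
`standardize = TRUE` remains available for data whose units are
arbitrary.

Two properties of this estimator matter downstream. First, its sampling
variance per entry scales with $S_{ii} S_{jj}$ (the leading complex-Wishart
term), spanning several orders of magnitude across the band. Second, a
split-half contrast — the same MAR fitted to each half of the recording —
gives an honest estimate of the estimator's own noise level, which
`estimate_csd()` attaches to its output (`noise_level`). Both feed the
inversion below.

`fisher_fc()` computes the functional-connectivity baseline: Fisher
$z = \mathrm{atanh}(r)$ of the pairwise Pearson correlations.
`svd_timeseries()` extracts a region's representative time course as the
first principal component of its voxel matrix (first left singular vector
scaled by its singular value, sign-aligned with the voxel mean).

## Variational-Laplace inversion

`invert()` estimates the posterior over the packed parameter vector
(couplings switched on by the model's adjacency, self log-scalings,
fluctuation and noise log-parameters, hemodynamic log-scalings — 24
parameters for a full 3-node model) by Gauss–Newton ascent on the
variational free energy

$$F = \langle \log p(y \mid \theta) \rangle_q - KL(q \,\|\, p_0),$$

with a Gaussian likelihood on the stacked real and imaginary parts of the
observed CSD and a Gaussian posterior $q$ (the Laplace assumption).
Numerical Jacobians use central differences with step $10^{-4}$; a
compiled path evaluates the forward model and Jacobian, and the tests hold
it to the plain-R reference at $10^{-12}$ relative error. Candidate steps
are Levenberg–Marquardt damped and kept only if they increase $F$, so the
accepted-step $F$ sequence is non-decreasing by construction (asserted in
every fit). Convergence requires $|\Delta F| < 0.01$ nats on four
consecutive accepted steps, with a cap of 128 iterations; a capped fit is
returned with `converged = FALSE` rather than discarded, and subjects are
flagged for exclusion from group statistics only below 10% variance
explained.

Two refinements to the error model proved necessary rather than optional:

* **Whitening.** Residuals are scaled by $1/\sqrt{S_{ii} S_{jj}}$,
  computed once from the observed spectrum and shared by every candidate
  model. Without it the likelihood is dominated by the largest
  low-frequency diagonal entries; fits stall on near-critical spectra and
  model comparison rewards whichever model happens to bend toward those
  entries.
* **A hyperprior on the error log-precision.** The single estimated
  log-precision $\lambda$ gets a Gaussian hyperprior
  ($\mathrm{var} = 1/128$) centered on the split-half noise level of the
  spectral estimate. Without it $\lambda$ is unbounded as a fit approaches
  the data, and free-energy differences between models degenerate into
  numerical noise of hundreds of nats. The split-half centering makes the
  assumed noise level an empirical quantity rather than a tuning constant;
  in simulation it tracks the true estimator error variance closely.

Priors are independent Gaussians: off-diagonal couplings
$\mathcal N(0, 1/64)$, self log-scalings $\mathcal N(0, 1/256)$,
fluctuation and noise log-parameters $\mathcal N(0, 1/64)$, hemodynamic
log-scalings $\mathcal N(0, 1/256)$, all overridable. A coupling switched
off by the model's adjacency is simply absent from the free vector and is
restored as an exact zero with zero variance (`expand_fit()`), which is
what lets fits of different models be averaged on a common support.

## Model space

`enumerate_full(3)` produces all $2^{3\times3} = 512$ binary coupling
patterns; requiring every self-connection and no isolated node
(`plausibility_rules()`) leaves 54 biologically plausible connected
models, matching the inclusion–exclusion count $2^6 - (3\cdot4 - 3 + 1)$.
"Connected" is read as *no node is isolated* — the weakest reading — since
for three nodes only this reading reproduces 54; weak and strong graph
connectivity are available as options. Laterality-aware rules (sagittal
symmetry, homotopic pairs bidirectional-or-absent, required and forbidden
links) support within-network spaces whose nodes carry left/right labels;
their cardinalities are logged, not asserted, because no stated rule set
reproduces the within-network counts exactly (an open ambiguity recorded
as such). `to_prior()` turns any member into a prior specification by
switching couplings off.

## Model selection and averaging

`fixed_effects_bms()` is the softmax of free energies summed over
subjects. `random_effects_bms()` — the pipeline default, since exceedance
probabilities are the quantity displayed — implements the variational
Dirichlet scheme: iterate
$u_{nk} \propto \exp(F_{nk} + \psi(\alpha_k) - \psi(\sum_j \alpha_j))$,
$\alpha_k = \alpha_0 + \sum_n u_{nk}$ with $\alpha_0 = 1$, then estimate
exceedance probabilities by Monte-Carlo sampling from the fitted Dirichlet
($10^6$ draws by default; the $K = 2$ case is held to the Beta-tail
quadrature in the tests). `bma()` averages each subject's per-model
posteriors by moment matching
($\bar\mu = \sum_m w_m \mu_m$,
$\bar\sigma^2 = \sum_m w_m(\sigma_m^2 + \mu_m^2) - \bar\mu^2$),
deterministic by design; an Occam window (default: include everything)
drops negligible models with renormalization.

## Group statistics

`age_regression()` regresses standardized age on standardized parameters
plus covariates (OLS), reporting the multiple correlation and per-term 95%
confidence intervals. `cca()` computes canonical weights from the SVD of
the whitened cross-covariance, with ridge regularization only on rank
deficiency. The orientation convention: the X-set weights get their
largest-magnitude element positive, and the Y-set weights then take the
sign that keeps the realized first canonical correlation non-negative —
orienting the two sets independently would randomize the sign of the
moderation interaction downstream. `structure_correlations()` reports each
variable's correlation with its own set's first variate, flagging
$|r| < 0.3$ as low-contribution. Significance is by row permutation of one
set (default 1000 permutations, $p = (1 + \#\{r^* \ge r\})/(1 + B)$), with
Bartlett's $\chi^2$ approximation reported alongside; the two agree within
0.05 at moderate $n$ in the tests, and the permutation $p$ is uniform
under the null (KS-checked).

`moderation()` fits
$W_1 \sim \mathrm{age} + V_1 + \mathrm{age}\times V_1 + \mathrm{covariates}$
on standardized variables, where $V_1$ and $W_1$ are the first canonical
pair (connectivity and cognitive profiles). Age and $V_1$ are standardized
*before* forming the product. Tertile simple slopes are returned for
plotting; tertiles, because the alternative decile-based grouping of the
emulated study is internally inconsistent with three equal groups.
`fdr_correct()` applies Benjamini–Hochberg across the family of
multivariate analyses (both the effective-connectivity and the
functional-connectivity branches). Covariates enter the age regression and
the moderation model, not the CCA itself. All analyses are complete-case,
with dropped rows logged.

`fc_reanalysis()` is literally `run_group_stats()` on Fisher-z values —
one code path, relabeled — so the effective-vs-functional connectivity
contrast cannot be confounded by implementation differences.

## The synthetic cohort

No public deposition of the emulated cohort exists, so validation runs on
a seeded generator (`simulate_cohort()`) that reproduces the study's
*conditions*: 602 subjects available by configuration (200 by default, for
runtime), ages uniform on 18–88, one 255-volume recording per subject at
TR = 1.97 s, a 3-node network. Per-subject generative parameters drift
linearly with age — stronger self-inhibition (+0.004/yr on each
$a_{ii}$) and slower vasodilatory decay (+0.003/yr on each decay
log-scaling) in all nodes, an increased fluctuation exponent in node 1,
decreased amplitude in node 2, and two small opposing coupling drifts —
with between-subject scatter (SD 0.08–0.10 per family) around the trend.
Draws must satisfy a stability margin (all eigenvalues of $A$ below
$-0.125$ Hz), not bare stability: near-critical systems have diverging
low-frequency power and are not representative of resting-state dynamics.
Covariates are independent of age except head motion, which gets a small
positive age slope. Six cognitive scores follow

$$y_k = w_k\,p\,(1 + \lambda z(a)) + \beta_k z(a) + e_k,$$

where $p$ is the standardized connectivity profile (negated mean
self-inhibition: stronger inhibition, lower profile), $z(a)$ the age
z-score against the configured uniform distribution (so the construction
is deterministic given the config), $\lambda = 0.3$ the moderation
strength, $w_k \in [0.2, 0.5]$ the profile loadings, $\beta_k < 0$ the
direct age declines, and unit-SD noise — per-score profile correlations
around 0.2–0.4, which is what cognitive test batteries typically show
against a latent factor. The cognitive-score residual covariance is
diagonal by default and exposed as configuration, since the real
covariance is not publicly stated.

What the generator does *not* emulate: volumetric images, motion or
despiking artifacts, scanner drifts beyond a linear trend, network
definition (node identities are taken as given labels), or non-stationary
coupling. Passing tests therefore demonstrate internal consistency of the
estimation machinery under the stated generative assumptions — not
robustness to the preprocessing realities of raw fMRI.

## What the validation shows, and what it does not

Problem sizes were chosen so the full suite runs in minutes on one CPU:
parameter recovery uses 20 single-subject replicates at the study's
recording length (plus 10 at 4x length), the variance-explained
diagnostic uses the default 200-subject cohort, model recovery uses 10
replicates of 20 subjects over a deterministic 8-model subset of the
54-model space, and the statistical calibrations use cohorts of 400.

* **Parameter recovery.** At 255 volumes the correlation between true and
  estimated off-diagonal couplings averages ~0.8–0.9 across replicates,
  and the mean absolute error roughly halves at 4x the recording length.
  Median variance explained across the default cohort is ~84%, above the
  75% diagnostic benchmark, with no subject below the 10% exclusion
  floor.
* **Model recovery is the known limitation.** Group BMS reliably rejects
  models *missing* true couplings and grossly over-parameterized
  non-nested alternatives, but cannot reliably reject the immediate
  supersets of a sparse generating model: each spurious free coupling
  recovers ~0.5–1 nats of accuracy from the spectral-estimation error —
  whose correlation across frequencies the single-precision iid likelihood
  cannot represent — against a complexity penalty of ~0.3–0.5 nats. In the
  randomized-generator confusion design the generating model therefore
  tops the exceedance ranking only in a minority of replicates (~20%),
  winning mainly when it is dense. This was traced specifically to
  error-mode structure: it survives changes of MAR order (4–32), grid
  density (12–32 frequencies), jackknife bias correction of the
  estimator, and optimizer patience, and disappears when fitting
  noiseless model spectra. Resolving it would require a correlated error
  model across frequencies, which is outside the present error model's
  scope. Conclusions that depend only on model-averaged parameters (all
  of the group statistics here) are insulated by design: averaging over a
  space whose members share the estimated parameters is robust to
  evidence ties among near-equivalent models.
* **Statistical calibration.** CCA permutation p-values are uniform under
  the null; the moderation test detects the generator's $\lambda = 0.3$
  interaction in 100% of 400-subject cohorts when fitted on the generating
  profiles, with a ~5% false-positive rate at $\lambda = 0$. Through the
  full pipeline (fit, BMA, CCA) the interaction *estimate* is positive in
  ~90% of runs, but single-recording measurement noise in the per-subject
  profile attenuates it: at 200 subjects only ~30% of runs reach
  $p < 0.05$. Detecting the moderation reliably needs either the full
  cohort size (602, ~1.7x the z-statistic) or longer recordings — a
  realistic power observation worth knowing before designing a study
  around this pipeline.

## Numerical choices and degenerate inputs

Hermitian symmetrization is applied after every spectral assembly, with a
hard error if the input is far from Hermitian; PSD is enforced by
eigenvalue clipping at zero in the simulator and checked (floor
$-10^{-8} \times$ trace) on estimator output. Perfectly correlated or
constant channels are errors in `fisher_fc()`, not infinities.
Ill-conditioned MAR regressions (condition number $> 10^{12}$) abort with
the condition number. The MAP update of the error log-precision is a
safeguarded Newton iteration (steps clamped to $\pm 4$). Variance
explained is clipped to $[0, 1]$ with a warning when negative. Model-space
filtering is deterministic (lexicographic order) and idempotent. All
randomness descends from one root seed through named substreams
(`substream_seed()`), and a cohort is reproducible bit-for-bit from its
configuration.
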