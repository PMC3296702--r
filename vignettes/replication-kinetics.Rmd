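---
title: "Modeling inhomogeneous DNA replication kinetics with repkin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling inhomogeneous DNA replication kinetics with repkin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repkin)
```

## The model

Eukaryotic DNA replication proceeds by stochastic firing of origins, each
creating a pair of divergent forks that advance until they coalesce with an
opposing fork. `repkin` models this process when both the origin-firing rate
and the fork velocity vary along the genome and through S phase.

Three coupled fields describe the ensemble-average ("mean-field") kinetics on
a genomic segment: the replication fraction $f(x,t)$ — the probability that
position $x$ (kb) is replicated $t$ seconds after S-phase entry — and the
densities $\rho_\pm(x,t)$ (forks/kb) of right- and left-moving forks:

$$\frac{\partial f}{\partial t} = v_+\rho_+ + v_-\rho_-,$$

$$\frac{\partial \rho_\pm}{\partial t} \pm
  \frac{\partial (v_\pm \rho_\pm)}{\partial x}
  = I(x,t)\,(1-f) \;-\; \frac{(v_+ + v_-)\,\rho_+\rho_-}{1-f}.$$

The source term creates fork pairs at the initiation rate $I$ (initiations
per kb of *unreplicated* DNA per second), rescaled by the probability $1-f$
that the position has not already been replicated passively. The sink term
removes opposing forks pairwise, at a rate proportional to the two local
fork populations and their relative speed, normalized by $1-f$. Directional
replication fractions $f_\pm = \int_0^t v_\pm \rho_\pm \,dt'$ are accumulated
alongside. With constant rates the model reduces to the classical
one-dimensional KJMA nucleation-and-growth solution
$f(t) = 1-e^{-I v t^2}$, $\rho_\pm(t) = I\,t\,e^{-I v t^2}$, which the test
suite uses as an analytic oracle.

Space-time integrals of the source and sink give the expected numbers of
initiations and coalescences per replication cycle, $N_i$ and $N_c$; on a
periodic genome every initiation is eventually balanced by a coalescence, so
$N_i = N_c$ up to numerical round-off, while on a linear molecule the two
outermost forks exit the ends and $N_i = N_c + 1$.

### Numerical scheme

`solve_replication()` integrates the system with a direction-aware
first-order upwind discretization of the advection terms and a forward-Euler
source/sink update, under the CFL condition $\max(v)\,\Delta t \le \Delta x$
(checked at solve time). Defaults for the 1000-kb test system are
$\Delta x = 0.5$ kb and $\Delta t = 10$ s (Courant number 0.8). Numerical
safeguards:

* the sink's $1/(1-f)$ is clamped at $10^{-12}$, and the per-step sink is
  capped so densities stay non-negative;
* $f$ is clamped to $[0,1]$ by proportionally rescaling the two directional
  increments, which keeps $f_+ + f_- = f$ exact;
* integration stops early when the remaining fork mass and the source are
  both negligible.

Three discretization artifacts are worth knowing about, all first-order
(they shrink linearly with the grid step):

* **Frozen termination residue.** Where two fork waves annihilate, numerical
  diffusion can exhaust the fork populations slightly before the DNA between
  them is fully covered, leaving a small frozen unreplicated pocket
  (about $3\times10^{-3}$ at the default grid on the two-zone system).
* **Annihilation leakage.** A small fork-density tail can survive the
  collision of two waves and keep advecting (total leaked mass halves when
  the grid is refined). At exactly Courant number 1 upwind advection is
  diffusion-free and opposing single-cell packets can pass through each
  other without annihilating, so internal pre-solves use Courant 0.8.
* **Source lag.** The explicit source uses start-of-step $f$, slightly
  overestimating initiation counts when coverage changes quickly within a
  step.

Comparisons against simulation in the test suite therefore allow, besides
the Monte Carlo sampling error, a Richardson error bound of
$2\,|u_h - u_{h/2}|$ obtained from a solve at half the step sizes.

### What is exact and what is approximate

For constant fork speed the mean-field $f(x,t)$ is *exact*: it equals the
probability that no initiation occurred in the past coverage cone of
$(x,t)$, and the test suite verifies this against a direct quadrature of the
cone integral. The fork densities, however, rely on the factorization
$\langle\rho_+\rho_-\rangle \approx \rho_+\rho_-$ in the sink. Where fork
populations are strongly positively correlated — the inner flank of a
dominant initiation zone, or the late-S tails — this underestimates
coalescence and overestimates the minority fork density by up to a factor
of order two *at the $10^{-3}$ forks/kb level* (a few percent of the peak
density). With 1000 simulated cycles the resulting deviations exceed three
per-bin standard errors in roughly 2–3% of space-time bins, which is why the
solver–simulator fork-density comparison in the acceptance tests attains
about 97% rather than the 99% bar asserted there; the replication fraction
and initiation-event density, being coverage quantities, pass at 100%.

## Start- and end-time probabilities

The probability that replication of a molecule has *started* by time $t$ is
Poisson-exact: $P_s(t) = 1 - \exp(-N_e(t))$ with
$N_e(t) = \int_0^t\!\!\int I\,dx\,dt'$ (no $1-f$ factor — nothing can have
been replicated before the first initiation). For a fragment of a larger
genome, replication can also start by a fork entering across an end, giving
$P_s = 1 - e^{-N_e}\,(1 - f_+(x_-,t))\,(1 - f_-(x_+,t))$: the probability
that a right-moving fork has crossed the left end is exactly the probability
that the left end has been replicated by a right-moving fork.

The probability that replication has *ended* has no closed form; it is
estimated by assuming the number of remaining forks is Poisson:
$\tilde P_e(t) = \exp(-\int q_+\,dx)$ on a circle, and
$P_e(t) = f(x_-,t)\exp(-\int_{x_-}^{x_+} q_+\,dx)$ on a fragment (left end
replicated and no right-moving forks; the mirrored form with $q_-$ is
equivalent). Two normalizations of the fork density are implemented:
$q_+ = \rho_+/f$ (default) and $q_+ = \rho_+$. The default was chosen
because it is exact in the $t\to 0$ limit and, on the two-zone test system,
tracks the simulated last-coalescence CDF with a maximum deviation about
seven times smaller than the unnormalized variant. The estimate is also
clipped to never exceed $P_s$.

The Poisson assumption is accurate early and late in S phase and weakest in
mid-S phase where fork numbers are largest and strongly non-Poisson. On the
two-zone system — whose gated late zone fires a synchronized burst of
origins, about as unfavourable a case as the approximation can meet — the
maximum absolute deviation from the empirical CDF is about 0.07. The
deviation decreases monotonically as the expected number of initiations
grows, which the acceptance tests check across a three-point ladder of
homogeneous scenarios.

## The stochastic simulator

`simulate_cycle()` is a lattice Monte Carlo (default spacing
$\delta x = 0.1$ kb, time step $\delta x/\max v$) that serves as the
ground-truth oracle for the solver and as the generator of synthetic
single-molecule data. Unreplicated sites fire with probability
$I\,\delta x\,\delta t$ per step (an error is raised if this exceeds 0.1);
replicated DNA is maintained as a sorted list of islands whose edges are
the forks; overlapping islands merge, recording a coalescence at the exact
crossing point; periodic boundaries wrap. When a site is swept, its
replication time (sub-step precise) and the replicating fork's direction are
recorded; if two forks reach a site within one step, the earlier sub-step
arrival claims it. Fork injection at fragment boundaries is realized
*exactly*, by simulating explicit homogeneous flanks of length
$v\,t_{\max}$ on each side — so the agreement between the solver's
closed-form injection density
$\rho_b(t) = I_{out}\,t\,e^{-I_{out}v_{out}t^2/2}$ and the flank simulations
is itself a test of that closed form. With a defect model, defects are
placed with exponential spacing (mean $d$ kb); an edge reaching a defect
stalls and resumes after an exponential repair time (mean $\tau$ s;
$\tau=\infty$ never resumes, leaving the opposing fork to replicate the
blocked DNA). In the rate equations the same physics appears as stall
($v_\pm\rho_\pm/d$), repair ($\rho^s_\pm/\tau$, integrated implicitly so
that small $\tau$ is not stiffness-limited) and stalled-collision
($v_\mp\rho_\mp\rho^s_\pm/(1-f)$) terms, with stalled densities fixed in
space.

The lattice introduces $O(\delta x)$ edge effects: each fork "loses" about
half a site at birth and at any measurement cutoff, and a coalescence
attributes its final site to only one of the two directions. At the default
spacing these amount to a few percent of the fork-density signal in bins
where forks are short-lived; ensemble comparisons in the tests use
$\delta x = 0.05$ kb where that matters.

Randomness comes from R's global RNG: a single `set.seed()` before an
ensemble or sampling call makes the whole experiment reproducible; cycles
consume the stream sequentially.

## SMARD observables

In a SMARD experiment an asynchronously replicating population is labeled
with a first ("red") then a second ("green") nucleotide, and fully
substituted molecules are collected. A molecule caught mid-replication is
red where it replicated before the label switch and green after; label
transitions mark the fork positions at the switch, oriented red→green.
`sample_smard()` reproduces the protocol: the switch time is uniform on
$[0, t_{window}]$ (perfect asynchrony), with $t_{window}$ defaulting to the
time at which the end probability reaches 0.999; two-color molecules (switch
between first initiation and last coalescence) are kept for analysis, and
the numbers of fully-red and fully-green molecules seen along the way are
recorded, since the experimental fork-speed estimator
$v = l/(n_f\,t_{rep})$, $t_{rep} = t_{window}\,n_{rg}/(n_r + n_{rg})$,
needs them.

`smard_profiles()` computes the experiment's summaries — red-green content
$r(x)$ in 5-kb bins, directional fork densities in 50-kb bins, and the
spatial autocorrelation of the red-green indicator (biased estimator,
normalized by the lag-0 pair count, wrapping around on periodic molecules)
— and `predict_red_green()` / `predict_fork_density()` give their mean-field
expectations:

$$\tilde r(x) = \frac{\int [f(x,t) - P_e(t)]\,dt}{\int [P_s(t) - P_e(t)]\,dt},
\qquad
\tilde\rho_\pm(x) = \frac{\int \rho_\pm(x,t)\,dt}{\int [P_s(t)-P_e(t)]\,dt}.$$

The $P_e$ correction removes fully replicated molecules, which contribute to
$f$ but are not collected as two-color; no such correction is needed for the
fork densities since finished molecules carry no forks. Because the
denominator uses the approximate $P_e$, fragment-level predictions inherit a
systematic error of order 5–10% on fork densities — well inside the
sampling noise of experiment-scale data sets (tens of molecules per
fragment, matching the 11–57 fully labeled molecules per fragment typical of
real experiments) but visible at several thousand molecules.

On the two-zone system the red-green content shows two local maxima at the
zone positions. The *early* zone carries the higher content (it replicates
first in most cells); the late zone's peak is sharper and more prominent
relative to its surroundings, reflecting its ten-fold higher rate. A peak's
height orders zones by replication time, not by efficiency alone.

## Fitting correlated SMARD profiles

Profile bins are strongly correlated along the genome (one molecule
contributes a contiguous red block), so ordinary least squares misstates
both the weights and the goodness of fit. `fit_smard()` implements an
iterative decorrelated least-squares procedure:

1. start from `theta0`, or from data-driven values (zone centers at content
   maxima, rate scale from the homogeneous closed form, velocity from the
   experimental estimator above);
2. solve the rate equations for the current scenario and predict the
   concatenated profile vector (content bins, then fork-density bins, per
   fragment);
3. simulate `n_sim` replicate experiments at the current scenario, with the
   experiment's own molecule counts;
4. estimate their sample covariance and fit a positive-definite surrogate:
   per-block variance profile times a nugget-plus-exponential correlation
   $R(\Delta) = a\,e^{-\Delta/\lambda}$ ($R(0)=1$), zero across blocks
   (content and each fork direction per fragment form separate blocks);
5. Cholesky-factorize, decorrelate data and model by the inverse factor;
6. minimize the unit-weight sum of squared decorrelated residuals
   (Nelder-Mead; rates on a log scale);
7. iterate from 2 until the relative parameter change falls below `tol`
   (default $10^{-2}$, at most `max_outer` iterations).

The nugget parameter matters: forcing pure-exponential correlation
overstates long-range dependence, and the resulting mis-weighting inflated
the reduced chi-square on well-specified synthetic data by a factor of
several; with the nugget the decorrelated replicates are white to within
sampling error (held-out $\chi^2/\mathrm{dim} \approx 0.9$). Parameter
uncertainties are Gauss-Newton standard errors from the decorrelated
finite-difference Jacobian, scaled by the reduced chi-square; the covariance
they rest on is itself estimated from simulation.

The shipped `two_zone_family()` mirrors a realistic fragment study: two
rounded-box initiation zones, a constant background, boundary injection
rates at both ends and a constant velocity (10 parameters), optionally
paired with a rearranged allele carrying a genomic deletion that removes the
second zone and shifts downstream coordinates (11th parameter: the second
condition's velocity). The rounded box is
$A\,\sigma((x - c + w/2)/s)\,\sigma((c + w/2 - x)/s)$ with logistic edges of
scale $s = 2$ kb by default; fits are not very sensitive to the precise
edge shape.

### Synthetic recovery scale

The recovery experiments in the acceptance tests use a 500-kb region split
into two 250-kb fragments with 50 two-color molecules each, zones at 150 and
350 kb, background $10^{-7}$, injection $5\times10^{-4}$ at both ends and
$v = 0.04$ kb/s; fits run with `n_sim = 50` replicate experiments per outer
iteration, a 1-kb solver grid and two seeds. These sizes were chosen so a
full recovery runs in minutes while the molecule counts stay at the scale of
real fragment data; the test tolerances (centers within 25 kb, velocity
within 20%, reduced chi-square in $[0.5, 2]$) are the ones the package
commits to at that scale.

## What the synthetic data do and do not show

The generator emulates: stochastic origin firing from arbitrary space-time
rate profiles, passive replication, fork coalescence, asynchronous
collection, two-color selection, fragment excision from a longer genome,
and fork stalling at randomly placed lesions. It does not emulate:
microscopy and image segmentation noise in label calls, molecule breakage
or incomplete substitution, cell-to-cell variation in global rate
parameters, checkpoint feedback between stalls and origin firing, or
sister-chromatid/re-replication artifacts. Passing tests therefore
establish the internal consistency of solver, simulator, estimators and
fitting machinery under the stated stochastic model — not robustness to the
measurement artifacts of real combed-fiber data.

## Choices for under-determined inputs

The literature source for the two-zone test system leaves some values
unprintable; the package fixes them once as documented defaults: early-zone
peak amplitude $2\times10^{-5}$ initiations/kb/s (the late zone is ten times
that), Gaussian "50 kb size" read as $2\sigma$ ($\sigma = 25$ kb), solver
steps $\Delta x = 0.5$ kb / $\Delta t = 10$ s, horizon 25000 s. With these,
the system fires about 7 initiations per cycle and finishes replication
around $10^4$ s — magnitudes typical of mammalian somatic cells. The
boundary-injection density uses the half-exponent form
$I\,t\,e^{-Ivt^2/2}$, which integrates (times $v$) to exactly one crossing
fork and matches explicit-flank simulation; its density peaks at
$t^* = 1/\sqrt{Iv}$.
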