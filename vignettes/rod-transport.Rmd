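---
title: "Models and methods: thick-rod transport in cross-linked networks"
author: "rodnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: thick-rod transport in cross-linked networks}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

A rigid rodlike particle whose diameter $d$ is comparable to the mesh size
$a_x$ of a cross-linked macromolecular network (bacteria in mucus, nanorods
in hydrogels) moves through a free-energy landscape set almost entirely by
entropy: network strands must pay a conformational penalty wherever the rod
excludes them. The resulting dynamics falls into distinct regimes --
Brownian, *sliding* (fast, Fickian but non-Gaussian), *hopping* (rare
cell-to-cell jumps) and *trapped* -- and which regime a rod occupies depends
on the commensuration of its length $L$ with $a_x$: rods with $L \approx n
a_x$ experience a much lower barrier and diffuse anomalously fast.

`rodnet` implements the full computational apparatus for this problem:

1. a DPD simulator (network + solvent + rigid rod),
2. the trajectory statistics that diagnose the regimes,
3. a partition-function theory of the entropic barrier $U_b$ with the
   $U_b = k_BT$ phase boundary, and
4. closed-form continuous-time random-walk (CTRW) displacement
   distributions for the three mobile regimes, plus a seeded trajectory
   sampler used as the package's fixture generator.

# Dissipative particle dynamics

Beads interact within a cutoff $r_c$ (the length unit) through the standard
soft conservative force $F^C = a_{ij}(1 - r/r_c)\hat r$, a pairwise
dissipative force $F^D = -\gamma (1-r/r_c)^2 (\hat r \cdot v_{ij})\hat r$
and a random force $F^R = \sigma (1-r/r_c)\,\theta_{ij}\hat r/\sqrt{\Delta
t}$, with $\sigma^2 = 2\gamma k_BT$ enforced at construction
(`dpd_params()` rejects any other $\sigma$). All three are pairwise
antisymmetric, so momentum is conserved locally and hydrodynamics emerges.
Defaults: $a_{ii} = 25$, $\gamma = 4.5$, $\Delta t = 0.02\,\tau$, $\rho =
3\,r_c^{-3}$, $k_BT = m = r_c = 1$. The pair noise $\theta_{ij}$ is uniform
on $[-\sqrt3, \sqrt3]$ (zero mean, unit variance), drawn once per pair per
step so the antisymmetry is exact; with this choice the total momentum
drifts only by round-off ($\sim 10^{-13}$ over $10^3$ steps in the tests).

Integration uses the modified velocity-Verlet scheme with one force
evaluation per step and velocity-prediction factor $\lambda = 0.65$
(configurable). The measured stationary temperature of the default fluid is
$1.00\,k_BT$ within 1--2%, the expected residual discretisation effect at
$\Delta t = 0.02$.

The rod is a rigid body: the net force and torque about its centre of mass
drive the COM velocity and the angular momentum; the orientation quaternion
is advanced with the half-step angular velocity and renormalised every
step, and bead coordinates are *regenerated* from the pose, so intra-rod
distances are exact by construction rather than maintained by constraints.
Angular-momentum components about axes with near-zero inertia (degenerate
bead layouts) are ignored. DPD dissipative and random forces act on
rod-bead pairs like on any others; there is no separate rod thermostat.

Degenerate inputs have documented conventions: coincident beads are pushed
apart along a seeded random direction at an effective separation of
$10^{-6} r_c$; a bead displacing more than $r_c/2$ in one step, a bond
stretched beyond half the box, or a non-finite coordinate is a hard error.

# Network and rod construction

The network is hexa-functional: crosslinks on a simple-cubic lattice of
spacing $a_x = 3.35\,r_c$ (functionality 6 under periodic closure), each
lattice edge realised as a chain of harmonically bonded beads
(`bond_k = 100`, `bond_r0 = 0.7`, 7 beads per strand by default -- a strand
contour of $1.67\,a_x$, i.e. moderately slack chains, a realistic choice
for a swollen gel). These bonded-interaction values are conventional
choices exposed in the configuration, not quantities the physics is
sensitive to at the k_BT scale probed here.

Mesh polydispersity is controlled by the coefficient of variation CV of
strand rest lengths. Per-strand bead counts are drawn from a rounded
lognormal whose log-SD is calibrated *deterministically* against the
rounded distribution's pmf (`uniroot` on the analytic CV of the rounded
draw), so the realised rest-length CV matches the target to $\pm 0.02$ at
$10^4$ strands; CV = 0.3--0.8 covers the biologically observed range.

The rod is a volume-filled spherocylinder: beads on a cubic grid of pitch
$\le 0.5\,r_c$ clipped to the capped cylinder, which prevents strands from
threading through the soft-core body. Inertia is computed by direct
summation and the body frame rotated to principal axes (long axis along
$z$). `place_rod()` deletes solvent within $0.5\,r_c$ of the rod, restores
the global density to $\rho$ exactly (bookkeeping over solvent far from the
rod), and refuses poses that put a crosslink strictly inside the hard core.

# Trajectory observables and regime classification

The axial displacement projects COM increments on the *instantaneous* rod
axis, $z(t_k) = \sum_{j<k} \Delta r_j \cdot \hat u_j$, with the axis
sign-aligned frame to frame (it is a nematic director); this measures
displacement along the rod contour and is robust to slow reorientation. The MSD $\langle \Delta z^2 \rangle$ is time-averaged over
all origins on log-spaced lags; local exponents come from central
differences, and a windowed regression (about a third of a decade) provides
the noise-robust version used in decisions. $G_s(z,t)$ is the normalised
displacement histogram; $\alpha_1 = \tfrac13 \langle \Delta z^4\rangle /
\langle \Delta z^2\rangle^2 - 1$.

The diffusion coefficient is fitted only when a *Fickian window* exists
(local exponent in $[0.9, 1.1]$ over at least half a decade); the fit is an
origin-constrained weighted least squares of $\langle\Delta z^2\rangle =
2Dt$ with weights $1/t^3$, the inverse of the time-averaged MSD's noise
variance. Without a window the result is an explicit "no estimate", never
a number.

Hop detection uses Haar multiresolution denoising with the universal
threshold $\hat\sigma\sqrt{2\ln n}$ ($\hat\sigma$ from the MAD of the
finest detail coefficients), followed by a local two-level change-point
refinement of each candidate step on the raw signal. A numerical floor of
$10^{-7}$ of the signal range suppresses round-off dust on noiseless
input.

The classifier applies, in precedence order trapped > hopping >
sliding > Brownian:

* **trapped** -- terminal-decade exponent $< 0.1$ and total excursion
  $< 0.8\,a_x$;
* **hopping** -- an intermediate plateau (exponent $< 0.25$ over at least
  half a decade, outside any Fickian window) together with a $G_s$ comb
  spaced within $[0.8, 1.2]\,a_x$;
* **sliding** -- a Fickian window, no plateau, and non-Gaussianity (peak
  $\alpha_1 \ge 0.3$, or a multi-peaked $G_s$);
* **Brownian** -- a Fickian window, no plateau, near-Gaussian $G_s$.

Two implementation details matter in practice and are deliberate: a
Fickian window only counts if the MSD is still growing at the terminal lags
(otherwise the short-time diffusive stretch of a confined particle
masquerades as Fickian), and the $\alpha_1$ summary uses only lags with at
least 100 independent increments, median-smoothed over neighbouring lags
(the raw kurtosis estimator at the longest lags is noisy enough to push a
Gaussian series over any threshold). The numerical thresholds (0.1, 0.25,
$[0.9,1.1]$, 0.3) are conventions exposed in `classifier_config()`; 0.3
for $\alpha_1$ was calibrated on the package's own CTRW sampler.

# Entropic free-energy theory

The rod-network free energy is $F = -k_BT \ln Z$ with $Z$ the partition
function of endpoint-pinned Gaussian chains in the presence of a hard-core
cylinder (length $L$, diameter $d$, axis along a lattice direction through
the cell centres). Each strand of $N$ bonds and Kuhn length $b$
($a_x = b\sqrt N$ is the unit length) is sampled as a discrete Gaussian
bridge (steps of per-dimension variance $b^2/3$, standard bridge
construction); a sample is rejected if any vertex falls inside the
cylinder, so $-\ln(\text{acceptance})$ is that strand's confinement free
energy and the strand sum gives $F(\tilde z)$. The barrier is
$U_b = \max \Delta F - \min \Delta F$ over one period.

Numerical design:

* **Common random numbers.** The radial part of the rejection test does
  not depend on the rod centre $\tilde z$, so each offending vertex excludes
  an *interval* of rod centres; one sample set is evaluated against the
  whole $\tilde z$ grid simultaneously. This is exact CRN across the grid
  and suppresses the sampling noise in the profile differences that set
  $U_b$.
* **Interaction shell.** Strands with both endpoints farther than
  $L/2 + d/2 + \text{shell}\cdot a_x$ from the rod axis segment are skipped;
  bridge excursions are $\sim b\sqrt N/2 \approx 0.3\,a_x$, so the default
  shell of a few $a_x$ is conservative.
* **Crosslink integration.** The partition function integrates over
  crosslink positions; this is approximated by independent Gaussian
  smearing of strand endpoints with SD $a_x/4$. Smearing is on by default --
  a quenched lattice is geometrically impossible for $d/a_x > \sqrt2$
  (lattice points would sit inside the rod) -- and `crosslink_smear = 0`
  recovers the quenched model.
* **Discretisation.** $N = 32$ by default. A convergence study at
  $d/a_x = 1.4$ gave $U_b(L/a_x = 2.0) = 1.00 \to 0.78 \to \approx 0.6$ and
  $U_b(L/a_x = 1.5) = 5.7 \to 6.2 \to 6.9$ for $N = 16 \to 32 \to 64$: the
  coarser chain under-resolves the vertex-only hard-core test, and $N = 32$
  is within Monte Carlo noise of $N = 64$ at half the cost. The
  valley/ridge topology of the landscape is insensitive to this choice.

With these defaults the theory reproduces the physics that motivates it:
at $d/a_x = 1.4$ the noncommensurate rod ($L/a_x = 1.5$) faces
$U_b \approx 6\,k_BT$ with the maximum at the cell centre, while the
commensurate rod ($L/a_x = 2.0$) faces $U_b \approx 0.8\,k_BT$; across the
$(d/a_x, L/a_x)$ plane, valleys of sub-$k_BT$ barriers run along integer
$L/a_x$ and the $U_b = k_BT$ contour separates them from the hopping
ridges. Quantitative $U_b$ values carry the $O(1)$ uncertainty of the
independent-strand and vertex-discretisation approximations; the
qualitative topology and the commensurate/noncommensurate inequality are
the robust content.

# CTRW displacement distributions

For barriers above $k_BT$ the displacement distribution is a delta comb on
lattice sites $\pm n a_x$ under a Gaussian envelope of variance
$2 a_x^2 t/\tau_{hop}$, each site weighted by the stationary Boltzmann
factor $C P(n)$, $P(n) = e^{-4\beta U_0 n^2}$, $\sum_{n\ge0} C P(n) = 1$.
Two conventions are explicit: the raw envelope-times-comb product is
asymptotic, so the discrete weights are renormalised to unit total; and
the weight of each $n \ge 1$ is split evenly between the two signs (the
normalisation runs over $n \ge 0$ only).

For $0 < U_b < k_BT$ the sliding propagator is the exponential-tailed
Bessel integral; at $t = 0$ it reduces exactly to the Laplace density
$e^{-2|z|/a_x}$ (whose $\alpha_1 = 1$), and quadrature confirms it stays
normalised at all $t$. Evaluation uses exponentially scaled $I_0$ with the
growth factors folded into one exponent, so no overflow occurs. For
$U_b = 0$ the propagator is Gaussian with variance $2a_x^2 t/\tau_0$.

`montroll_weiss()` evaluates $S(k,s) = (1-\tilde\psi)/(s[1 -
\hat\phi\tilde\psi])$ with validity guards, and `mw_invert()` performs
fixed-Talbot Laplace inversion per wavenumber followed by an inverse
Fourier integral -- over the first Brillouin zone for lattice (comb) jump
distributions, returning site masses.

`solve_fokker_planck()` integrates the Smoluchowski (drift--diffusion)
form of the generalized Fokker-Planck equation at $\alpha = 1$ -- the only
case exercised in this problem; fractional exponents are rejected -- with
conservative finite volumes and Scharfetter-Gummel exponential edge
fluxes on a periodic grid. The discrete stationary state is then *exactly*
Boltzmann, and probability is conserved to round-off per step; explicit
sub-steps obey an internal CFL bound. Against the free Gaussian the
solution is accurate to $\sim 10^{-4}$ in $L^1$ at a grid of 128 points
per $a_x$.

# The synthetic trajectory generator

`sample_ctrw()` is first-class, tested code: it generates the labelled
fixtures on which the analysis stack and the classifier are validated.
Frozen study conditions (32768 frames per series, $a_x = 1$):

* **Brownian**: i.i.d. Gaussian increments at the barrier-free variance
  rate ($\tau_0 = 50$ frames).
* **Hopping**: Ornstein-Uhlenbeck in-cell confinement (SD $0.2\,a_x$,
  relaxation 4 frames) plus $\pm a_x$ jumps with exponential waits of mean
  2500 frames -- rare events, as the regime requires; this produces the
  intermediate MSD plateau and the $a_x$-spaced comb.
* **Trapped**: the confinement alone, SD $0.10\,a_x$ (the classifier's
  excursion metric is measured from the starting point, which nearly
  doubles the apparent range, hence the conservative SD).
* **Sliding**: a Poisson jump kernel (rate $1/100$ per frame) with
  two-sided exponential jump lengths of scale $a_x/2$ -- the
  trajectory-level counterpart of the analytic sliding propagator, whose
  $t = 0$ form has exactly these tails. A smooth sub-$k_BT$ Langevin path
  was evaluated and rejected for this role: once in-cell positions are
  averaged over, its displacement distribution is Gaussian to
  $\alpha_1 \approx 0.04$ and *no* statistic separates it from Brownian
  motion; the regime's defining "anomalous yet Brownian" character lives
  in the master-equation jump picture.

What the generator does emulate: the regime-defining structure of $z(t)$
(plateaus, combs, saturation, Fickian-but-non-Gaussian statistics) under
stationary, homogeneous conditions. What it does not: inertia (no
ballistic regime -- CTRW paths are rough at all scales), coupling between
rod orientation and translation, strand-relaxation memory, and spatial
heterogeneity of real networks. Classifier performance on these fixtures
(98.5% recovery over 200 series) therefore validates the decision logic,
not the full difficulty of experimental data.

# Problem sizes used by the tests and the acceptance script

Production-scale systems for quantitative transport coefficients (a
$42.76^3\,r_c^3$ box, $\approx 2.3\times10^5$ beads, multi-$10^7$ steps)
are far beyond a desk check. The package's own validation uses scaled systems chosen so each
check exercises the genuine pipeline: pure-solvent thermostat checks at
$10^3$ beads and $2\times10^4$ steps; rod-in-network runs at $3^3$ or
$4^3$ mesh cells ($\approx 3\,800$ / $7\,200$ beads) with $10^3$--$10^4$
step productions, which resolve the ballistic window and the short-time
crossover; theory profiles at 1500--4000 bridges per strand. Slow-physics
observables (Fickian windows of thick rods, hopping statistics, the
trapped-onset sweep) need $10^2$--$10^4\times$ longer runs; the
corresponding end-to-end checks run the same protocol at probe scale and
report honestly against the full-physics expectations.

# Known limitations

* Rod orientations in the theory are lattice-aligned; rotational dynamics
  and its waiting-time statistics are out of scope (negligible for the
  thick, long rods considered).
* The theory treats strands as independent endpoint-pinned bridges with
  smeared crosslinks; collective network elasticity is not propagated, so
  $U_b$ is quantitative only to $O(1)$.
* The fractional-calculus case $\alpha \ne 1$ of the generalized
  Fokker-Planck operator is not implemented.
* Electrostatics, explicit hydrodynamic solvers beyond DPD, pressure
  coupling and non-orthorhombic boxes are out of scope.
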