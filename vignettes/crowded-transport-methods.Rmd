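---
title: "Transport and interaction analysis in crowded protein solutions: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transport and interaction analysis in crowded protein solutions: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crowdflow)
```

# Scope and units

`crowdflow` analyzes equilibrium simulations of concentrated macromolecular
solutions: shear viscosity from pressure-tensor fluctuations, translational
and rotational diffusion with periodic-box and water-model corrections,
contact/cluster kinetics, and colloid-theory interaction strength
(second virial coefficient, Baxter stickiness, dissociation constants).
It does not run molecular dynamics; it consumes trajectories and stress
series, and it ships generators that produce statistically faithful
surrogates with known ground truth so that every estimator can be
validated by parameter recovery.

All quantities live in one working unit system: Angstrom, nanosecond,
centipoise, Kelvin, bar. The derived energy unit is cP A^3/ns = 1e-24 J,
chosen so that the Stokes-Einstein expression
$D_t = k_BT / (6\pi\eta R_h)$ evaluates directly to A^2/ns when $\eta$ is
in cP and $R_h$ in A. Every conversion constant lives in `crowd_units`;
no formula carries hidden factors. Only cubic periodic boxes are
supported, because every finite-size correction used here is
parameterized by a single edge length $L$; non-cubic input is rejected
rather than silently approximated.

# Green-Kubo viscosity

The zero-shear viscosity is the time integral of the equilibrium stress
autocorrelation,
$$\eta = \frac{V}{k_B T}\int_0^\infty \langle P_{\alpha\beta}(0)\,
P_{\alpha\beta}(t)\rangle\, dt,$$
estimated from many short replicate runs. Per replica we average raw
(not mean-removed) autocorrelations over all supplied off-diagonal /
deviatoric channels; a nonzero mean stress is a data-quality problem and
is reported as a warning, never silently subtracted. The running
integral $\eta(\tau)$ is accumulated by the trapezoid rule, and the
cross-replica standard deviation $\sigma(\tau)$ is summarized by a power
law $\sigma(\tau) = A\tau^b$ (diffusive noise growth gives $b \approx
0.5$). A double exponential saturation
$$\eta(\tau) = \eta_\infty\left[\alpha(1 - e^{-\tau/\tau_1}) +
(1-\alpha)(1 - e^{-\tau/\tau_2})\right]$$
is then fitted to the replica-mean integral with weights $1/\sigma(\tau)$
to extrapolate $\tau \to \infty$. The integration cutoff $\tau_{max}$ is
chosen by scanning an increasing candidate grid (default 25-200 ps) and
taking the smallest value whose estimate agrees with the next one within
combined uncertainties; if no candidate stabilizes, the result is
flagged unconverged rather than reported silently. Uncertainty on
$\eta_\infty$ comes from a seeded bootstrap over replicas (the fit is
re-run on resampled replica means; $\sigma(\tau)$ weights are held
fixed, which is conservative and much cheaper).

Numerical choices: the $\sigma$ weights are floored at $10^{-3}$ of
their maximum because $\sigma(\tau) \to 0$ at small $\tau$ would
otherwise dominate the fit; for noiseless (identical-replica) input the
weights fall back to uniform; the fitted grid is thinned to at most 1200
points, which changes nothing for these smooth curves.

# Translational diffusion

$D_{t,PBC}$ comes from a weighted linear fit $MSD = 6Dt + c$ of the
all-time-origin mean-square displacement over a lag window (default
2-10 ns). The intercept is free: it absorbs short-time anomalous
behavior so that the slope reflects the long-time diffusive regime.
Because MSD values at neighboring lags are strongly correlated, the
standard error is taken from the scatter of per-molecule slopes, not
from the ordinary regression formula. A second, later window is a
standard consistency diagnostic: on Brownian data the two windows agree
within combined errors, while subdiffusive input produces a flagged
discrepancy.

The periodic-box correction adds
$\xi\, k_BT / (6\pi\eta L)$ with the cubic-lattice constant
$\xi = 2.837297$. Only this leading term is applied by default; a
higher-order term in the particle radius is available behind a
default-off flag, and the correction's inputs are recorded in an
append-only ledger on the estimate so the final number can be replayed
from its history (`replay_ledger()`). For crowded systems the system's
own computed viscosity enters the correction; effectively dilute systems
use the salt-water reference 0.347 cP. Final values are rescaled by
$\eta_{model}/\eta_{exp}$ (default 0.334/0.89) to compensate the
underestimated solvent viscosity of the simulation water model; the
pipeline order is correct-then-rescale.

# Rotational diffusion

Following the random-vector protocol, unit vectors rigidly attached to
the molecule are tracked (either directly from the rotational-walk
generator, or by applying the least-squares rigid-body rotation that
superposes the molecule's C-alpha set onto a reference frame), and
$C(t) = \langle P_2(\hat v(0)\cdot\hat v(t))\rangle$ is fitted over
0-20 ns by a double exponential with amplitude constrained to $[0,1]$.
The overall relaxation time is the amplitude-weighted mean
$\tau = a\tau_a + (1-a)\tau_b$, which equals the time integral of the
normalized fitted correlation function, and $D_r = 1/(6\tau)$. This
assumes an isotropic diffusion tensor while resolving fast and slow
relaxation; anisotropic tensor fitting is out of scope. The
finite-size correction adds $k_BT/(6\eta L^3)$ (leading order; the
prefactor is an exposed argument), and the same water-model rescaling
applies.

# Contacts, clusters, and survival kinetics

Two molecules are in contact when their minimum heavy-atom distance is
below 5 A (surrogate mode for spherical particles: surface-to-surface
distance below the cutoff); residue-resolved profiles count crowder
heavy atoms within 7 A of each C-alpha. Per-frame contact graphs give
connected components; the probe's direct degree and its component size
minus one are the "direct" and "in cluster" counts, with components
labeled by their lowest molecule index for determinism. Cluster-size
distributions are deliberately not reported — with tens of molecules
per box they are not statistically meaningful; only probe-centric
counts are.

The contact autocorrelation pools all pairs:
$$C(\Delta t) = \frac{\sum_p \langle\delta_p(t)\delta_p(t+\Delta t)
\rangle_t}{\sum_p \langle\delta_p(t)^2\rangle_t},$$
with the *intermittent* convention — a contact may break and reform
within $\Delta t$ — because the defining sum has no history condition;
the continuous-survival convention is a different observable and is not
the default. $C$ is evaluated on a logarithmic lag grid (24
points/decade): three decay scales spanning sub-ns to hundreds of ns
cannot be resolved on a linear grid. The survival model
$w_1 e^{-t/\tau_1} + w_2 e^{-t/\tau_2} + w_3 e^{-t/\tau_3} (+ c_0)$ is
fitted by multi-start Levenberg-Marquardt in log-$\tau$; the optional
constant $c_0$ absorbs the long-time plateau of the intermittent ACF
(the stationary contact probability). Fits are weighted $1/\mathrm{SEM}^2$
when replicate errors exist, since long-lag noise otherwise dominates.
Nearly flat input raises an error — never a silent finite answer — and
unresolved neighboring scales are flagged degenerate.

Stationarity is judged by the window Z-score
$Z(t) = |a_w(t) - a_{max}(t)| / (\mathrm{SEM}_w + \mathrm{SEM}_{max})$
comparing a short-window mean against the remaining-run mean, with SEMs
across replicates when available and by block averaging (block =
window/10) otherwise; $Z \lesssim 1$ indicates the two agree within one
standard error. Downstream analyses accept a burn-in argument, and the
pipeline always emits the Z-score report so the burn-in choice can be
justified.

# Colloid-theory interaction strength

Center-of-mass radial distribution functions use minimum-image
distances and finite-N normalization by the actual pair density
$N_{pairs}/V$ — material when a box holds only a handful of molecules.
The second virial coefficient is
$B_2 = -2\pi\int_0^{r_{max}}(g(r)-1) r^2 dr$; the upper limit is a
required, recorded per-pair input (first minimum after the contact
peak), not an automatic detection. The adhesive-hard-sphere map gives
the Baxter stickiness $\tau_B = 1/(4 - B_2/V_{HS})$, with
$B_2 \ge 4V_{HS}$ rejected as the repulsive limit, and the dissociation
constant $K_D = \tau_B/V_{HS}$ (in A^-3, converted to mM via Avogadro's
number). For probe-crowder pairs the probe's own sphere volume enters
the $K_D$ conversion so that different crowders are compared on the
probe's scale. Independently, the quadratic coefficient of the
relative-viscosity expansion maps to stickiness via
$b = 5.9 + 1.9/\tau_B$.

# Concentration-dependence models

Volume fractions and mass concentrations interconvert by the linear map
$c\,[\mathrm{g/L}] = 1430\,\phi$, a protein-density-like calibration
that is a few-percent approximation for individual systems. Relative
viscosity models: Einstein $1 + 2.5\phi$; quadratic
$1 + 2.5\phi + b\phi^2$ (the Einstein term is held fixed so $b$ is
comparable across datasets, conventionally fitted up to ~250 g/L);
Mooney $\exp(S\phi/(1-K\phi))$ with intrinsic viscosity $S$ (2.5 for
rigid spheres) and self-crowding factor $K$. All are constrained
through $\eta_r(0) = 1$ exactly. Diffusion vs concentration is fitted
by $D(\phi) = D_0\, \eta_r(\phi)^{-1} (1+\zeta\phi)^{-p}$, where
$1+\zeta\phi$ is an effective cluster size. The exponents default to
$p_t = 1/3$ and $p_r = 1$: for a compact cluster of $1+\zeta\phi$
molecules, $R_h \propto \mathrm{size}^{1/3}$, and $D_t \propto R_h^{-1}$
while $D_r \propto R_h^{-3}$. Both exponents are explicit arguments and
are reported with the fit. $\zeta$ is bounded below at zero and hitting
the bound is reported, since "no clustering" is a scientifically
meaningful outcome. The generalized Stokes-Einstein diagnostic
$(D/D_0)/(\eta_0/\eta)$ equals 1 when diffusion slows exactly as
viscosity grows; values below 1 indicate excess slow-down from
transient clusters.

# What the generators emulate — and what they do not

The generators reproduce the *statistical structure* the estimators
assume, not protein physics:

* `simulate_brownian_crowd`: overdamped spheres with a smoothed
  square-well potential (harmonic core, flat well, cosine edge over a
  smoothing band that keeps Euler-Maruyama integration stable) in a
  periodic cubic box. Ground-truth stickiness is the $B_2$ of the
  *actual smoothed potential*, computed by quadrature — not the nominal
  well depth — so recovery tests compare against the generator's own
  truth. The generator also applies the periodic-box self-mobility
  reduction implied by its nominal Stokes viscosity
  ($D_{eff} = D_0 - \xi k_BT/(6\pi\eta_{nom}L)$), so the analysis
  pipeline's finite-size correction is exercised non-trivially and
  restores $D_0$ exactly in expectation. There are no hydrodynamic
  interactions, no solvent, and no molecular shape beyond spheres:
  passing recovery tests validates the estimators, not force fields.
  The interacting path runs in compiled code with R's RNG stream, so
  seeded runs are bit-reproducible.
* `simulate_rotational_walk`: isotropic rotational Brownian motion by
  axis-angle composition (no Euler angles, hence no gimbal artifacts);
  $\langle P_2\rangle$ decays as $e^{-6D_r t}$ exactly.
* `simulate_stress_ou`: five independent stationary Ornstein-Uhlenbeck
  channels per replica with covariance
  $\eta^* k_BT/(V\tau_c)\,e^{-t/\tau_c}$, so the Green-Kubo integral
  equals $\eta^*$ in closed form; exact OU discretization, stationary
  from the first sample. Five channels exercise the channel-averaging
  code path.
* `simulate_contact_timeline`: an alternating renewal process per pair.
  The (weights, times) parameters describe the exponential-mixture decay
  of the *survival correlation function* — the observable the analysis
  fits — so on-durations are drawn from the length-debiased mixture with
  component probabilities proportional to $w_i/\tau_i$. Drawing
  durations from the raw mixture instead would length-bias the
  correlation amplitudes to $w_i\tau_i/\sum_j w_j\tau_j$, burying fast
  components (for weights 0.5/0.3/0.2 at 100/5/0.3 ns the fast
  amplitude would be about 0.1%, unrecoverable at any realistic scale).
  The process is sampled at frame times after a burn-in of several
  maximal survival times, so the recorded state is stationary and free
  of duration-rounding bias. The default recovery conditions use
  occupancy 0.2: transient crowding contacts are minority-occupancy,
  and a modest occupancy keeps reformation correlations subdominant to
  the survival decay being measured.

# Validation design and problem sizes

Each estimator is validated three ways: closed-form cases (exact
algebra), independent oracles (direct $O(NK)$ autocorrelation sums,
union-find connected components, brute-force minimum distances), and
end-to-end parameter recovery from the generators. The suite uses
desk-scale problem sizes chosen so each recovery test resolves its
parameters with comfortable margin: 150 x 1 ns OU replicas for the
viscosity protocol (recovers 0.35 cP within ~1%), a 30-sphere crowd
with $10^5$ steps for translational recovery, $2\times10^5$ rotational
steps, and $10^4$ pairs x 1000 ns for the three-scale survival mixture.

Two validation choices deserve explanation:

* The RDF-to-$B_2$ consistency check pools the RDF over five seeds of a
  dilute sticky crowd before integrating. Per-seed $B_2$ estimates are a
  small difference of large core and well terms and are dominated by
  bound-pair shot noise (a handful of bound pairs fluctuating with
  ~ns correlation times); the identity $g \approx e^{-u/k_BT}$ itself
  additionally requires $\rho|B_2| \ll 1$, which fixes the usable
  density. The pooled comparison tests the estimator's correctness; the
  per-seed scatter is a property of the observable, not the code.
* The generalized Stokes-Einstein mechanism check compares sticky
  ($\epsilon = 3\,k_BT$) against hard-core crowds using the
  *concentration-only* suspension viscosity (quadratic law with the
  hard-sphere coefficient $b = 5.9$) in the ratio. Using the
  colloid-theory $\eta_r(\tau_B)$ of the sticky potential would insert
  the same cluster physics into both numerator and denominator and
  force the ratio toward 1 by construction; with the concentration-only
  reference, excess slow-down from clustering is isolated, and only the
  sticky crowds drop below unity. The free-diffusion recovery test uses
  non-interacting tracers, because with an excluded-volume core at
  $\phi = 0.1$ the long-time diffusivity is *physically* reduced by
  roughly $(1 - 2\phi)$ — an interaction effect, not an estimator bias.

# Known limitations

* Cubic boxes and a single probe convention; no triclinic cells, no
  constant-pressure box dynamics.
* Finite-size corrections are leading-order; constants are exposed
  rather than hidden, and the higher-order translational term is off by
  default.
* The rotational analysis assumes an isotropic diffusion tensor.
* The contact ACF pools pairs; for strongly heterogeneous pair classes
  the pooled decay mixes class kinetics (the difference vanishes for
  exchangeable pairs, as in the generators).
* The bootstrap holds $\sigma(\tau)$ weights fixed across resamples.
* BD integration is Euler-Maruyama; near-core statistics carry an
  $O(D k\, dt)$ discretization bias, which is why stability guards
  (RMS step below a tenth of the radius) are enforced at configuration
  time and why ground truth is defined by quadrature over the actual
  smoothed potential.
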