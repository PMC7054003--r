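---
title: "A constrained-diffusion model of myosin V stepping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A constrained-diffusion model of myosin V stepping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(myovstep)
```

## The model

Myosin V walks hand-over-hand along filamentous actin: one actin-binding
head stays bound while the other, at the end of a stiff lever arm, performs
a diffusive search for the next binding site. `myovstep` implements a
semi-analytical model of this search and of the kinetic network built on
top of it, together with two simulators (an equilibrium Metropolis sampler
and a Brownian-dynamics integrator) of the same underlying bead-chain
Hamiltonian that cross-validate the analytics.

### Geometry

F-actin is a two-start helix with 13 subunits per strand per 72 nm repeat.
Binding sites are indexed by an integer $n$, with positions

$$\mathbf r_n = \big(R(\cos\phi_n - 1),\; R\sin\phi_n,\; n\,\Delta z/2\big),
\qquad \phi_n = -\tfrac{12\pi n}{13},$$

where $R = 5.5$ nm and $\Delta z = 72/13$ nm. The bound head occupies
$n = 0$; the half-helical sites $n = \pm 13$ sit at $z = \pm 36$ nm and the
full-helical sites $n = \pm 26$ at $z = \pm 72$ nm. Each site carries an
outward normal with azimuth $\phi_n$; binding requires the free leg to
point anti-parallel to that normal within a half-width
$\delta\phi_{ac}$ (55.6&deg; by default, a ~111&deg; acceptance region).

### The free-head density

Each "leg" (head plus lever arm) is a semiflexible chain of contour length
$L$ (35 nm for the wild type, 25/45 nm for the 4IQ/8IQ constructs) and
persistence length $l_p = 350$ nm, i.e. deep in the stiff regime
$\kappa = L/l_p \le 0.13$. In the stiff mean-field limit each leg's
end-to-end (chord) vector factorizes into

* a sharply peaked radial density
  $f(\ell) \propto (1-(\ell/L)^2)^{-9/2}
  \exp[-\tfrac{9\kappa}{8}/(1-(\ell/L)^2)]$, and
* an orientational weight.

For the bound leg the post-power-stroke constraint
$\mathcal H_c = \tfrac12 \nu_c k_BT (\hat u_0 - \hat u_c)^2$ on the anchor
tangent combines with the chain's tangent-to-chord response ($20/(7\kappa)$
in concentration units) into a von Mises--Fisher weight
$\exp(\mathcal T\, \hat u_c\!\cdot\!\hat u_1)$ on the chord direction, with
power-stroke effectiveness
$\mathcal T = 1 + 20\nu_c/(20 + 7\kappa\nu_c)$. A load $\mathbf F$ applied
at the joint adds $\beta \mathbf F \cdot \mathbf r_J \approx
\beta F L\, \hat F\!\cdot\!\hat u_1$, which is absorbed exactly into a
renormalized direction and strength,

$$\hat u_c' = \frac{\mathcal T \hat u_c + \beta F L \hat F}{\mathcal T'},
\qquad
\mathcal T' = \sqrt{\mathcal T^2 + (\beta F L)^2
  + 2\mathcal T \beta F L\, \hat F\!\cdot\!\hat u_c}.$$

The free leg's chord is isotropic. Two further couplings close the model:
the inter-leg joint potential
$\mathcal H_J = \mu_c k_BT [1 - \cos(\theta_J - \theta_p)]$ acting on the
angle $\theta_J$ between the two arm chords (preferred angle
$\theta_p = 83^\circ$, strength $\mu_c = 5\,k_BT$), and an effective
head--head exclusion $\mathcal H_V = k_BT (d_V/r)^6$ with $d_V$ = 20, 27.5,
35 nm for the 4/6/8IQ constructs. `free_head_density()` evaluates the
resulting normalized density $\mathcal P(\mathbf r)$; with $\mu_c = 0$ its
$z$-$x$ projection is a single crescent, while $\mu_c \gtrsim 3$ produces
the experimentally observed bimodal, compass-like contour.

Numerically, every pointwise evaluation is an exact three-dimensional
integral over the joint position written in two-center coordinates
$(\ell_1, \ell_2, \varphi)$ — the distances to the bound head and to the
evaluation point, and the azimuth about the axis joining them. This puts
both sharply peaked radial factors on explicit quadrature axes (the chord
shells are only ~0.2 nm wide) and turns the azimuthal acceptance window
into a plain interval of $\varphi$ nodes. Site densities change by less
than 0.1% when all node counts are doubled; the defaults are 14 radial
nodes per leg, 64 (256 when windowed) azimuth nodes and a 128-node
normalization rule.

### First passage and the kinetic network

The mean first-passage time to site $n$ is diffusion-limited capture at
radius $a$,
$t_{fp}^n = [4\pi a D_h\, \mathcal P(\mathbf r_n, \text{window})]^{-1}$,
using the joint density of position and acceptance-window orientation
($a = 0.4$ nm, $D_h = 5.7\times 10^4$ nm$^2$/ms). Sites whose joint density
falls below $10^{-12}$ nm$^{-3}$ are treated as unreachable.

Five pathways compete from the two-heads-bound waiting state. Trailing-head
detachment (rate $t_{d1}^{-1} = 12\,$s$^{-1}$) starts a search gated by ATP
hydrolysis ($t_h^{-1} = 750\,$s$^{-1}$); binding behind the bound head is
penalized by $b = 0.045$ because the recovery stroke orients the head for
forward binding. Leading-head detachment is slower
($t_{d2}^{-1} = 1.5\,$s$^{-1}$, gating ratio $g = t_{d2}/t_{d1} = 8$),
skips hydrolysis, and penalizes forward rebinding instead. The bound head
detaches throughout at $t_{d1}^{-1}$, terminating the run. Per-site
probabilities are

$$\mathcal P_T^n = \frac{b_n t_{d1}^2}
 {t_{fp}^n (1 + r_T t_{d1})(t_{d1} + t_h)}, \qquad
 r_T = \sum_n b_n (t_{fp}^n)^{-1},$$

with the leading-leg analogue obtained by $b_n \to b_{-n}$, $t_h \to 0$,
$r_T \to r_L$; termination is the exact complement, so the network
conserves probability to machine precision by construction. Mean binding
times are $t_T = r_T^{-1} + t_h$ and $t_L = r_L^{-1}$.

Step-size distributions follow by convolution: the standing head-separation
distribution $\mathcal P_{dist}^n$ (renormalized over $n > 0$) convolved
with the per-site binding distribution of the stepping head, mixed over the
two branches with weights $g/(1+g)$ and $1/(1+g)$. Forward-step
distributions for comparison with stepping assays zero backward binding
before convolving, add 1 nm Gaussian localization noise and are binned
(5 nm by default; the experimental bin width is not recoverable from the
published text, so it is exposed as a parameter). Run statistics use

$$z_{run} = \frac{\tfrac12 \sum_n z_n \mathcal P(z_n)}
 {\mathcal P_t (1 - \mathcal P_t)},$$

with $\mathcal P(z_n)$ carrying its raw branch mass $1 - \mathcal P_t$ (the
factor $\tfrac12$ converts head displacement to center-of-mass motion, and
the mean number of steps per run is $1/\mathcal P_t$), and the analogous
time expression with the waiting time $g\,t_{d1}/(1+g)$ between
detachments.

## What the package reproduces

With the default (wild-type) parameter set and no further adjustment the
pipeline gives, as computed by `scripts/acceptance.R` and the test suite:
a trailing binding time of 1.61 ms at zero load rising to a 25.6 ms peak
near 1.8 pN; equality of backward and forward stepping at 1.89 pN,
coinciding with the zero of the run length (the stall force); a zero-load
run length of 1.32 um and velocity of ~430 nm/s; a forward-step mode at
72 nm shifting backward by one actin subunit under 1 pN; and a worst-case
run-length loss of ~14% when a 1 pN load is rotated to a polar angle near
20--25 degrees in the motility plane, with purely sideways loads always
lengthening runs.

## Design choices and numerical conventions

* **Thermal energy.** $k_BT = 4.1$ pN nm (about 297 K); all energies are in
  $k_BT$, lengths in nm, times in ms, forces in pN.
* **Orientation weight under load.** Two forms are implemented
  (`density_model(form = )`). The default `"vmf"` uses the renormalized
  von Mises--Fisher weight above, which reproduces the published load
  response of the binding times, the step ratio and the stall force. The
  alternative `"gauss"` replaces the vMF angular energy by a Gaussian in
  the chord rotation angle with concentration $\mathcal T - 1$ and the
  exact load arm $\ell_1$: this is the bent-cantilever response, whose
  restoring torque keeps growing at large rotations instead of saturating.
  The bead-chain oracle sides with `"gauss"` under strong loads (2 pN;
  see the limitations below) while both forms agree at zero load.
* **Joint angle.** $\theta_J$ is measured between the two arm chords
  (joint-to-head vectors). For legs this stiff the chord and the local
  tangent at the joint differ by a few degrees at most; defining the
  constraint on chords keeps the mean field and both simulators exactly
  comparable.
* **Exclusion.** $\mathcal H_V$ reweights the joint head-pair density as a
  function of the head--head distance and the normalization is recomputed;
  it suppresses separations below ~0.7 $d_V$ essentially completely, which
  is why nearest-neighbour stomps do not occur.
* **Density floor and window quadrature.** Windowed site evaluations use
  four times the azimuthal node count because the acceptance indicator is
  discontinuous; the acceptance window may be asymmetric
  (`delta1`/`delta2`) but defaults to symmetric.
* **Stall-force bracketing.** The run-length root is bisected to
  $10^{-3}$ pN inside [0.5, 3] pN.
* **Simulators.** The Metropolis oracle samples unit-tangent chains (rigid
  bonds) with single-tangent pivots plus rigid whole-leg rotations (the
  collective move is what equilibrates the slow compass-arc mode), one
  bead per 5 nm of contour by default and 2.5 nm segments when used as a
  continuum reference. The BD integrator uses harmonic bonds
  (30 $k_BT$/nm$^2$, ~0.18 nm fluctuations), discrete worm-like-chain
  bending, the same constraint terms, free-draining beads with the head's
  diffusivity, and a 0.085 ns default time step chosen to keep the average
  per-component displacement below 0.1 nm; a binding attempt fires when
  the head is within $a$ of a site with the free leg inside the *conical*
  acceptance region (the analytic theory's azimuthal window is its
  tractable approximation). A cone miss is re-checked while the head stays
  within the capture radius; a penalty rejection blocks that site until
  the head leaves, making $b$ the per-excursion acceptance probability.
* **Effective exclusion length.** `estimate_dV()` fits the
  $(d_V/r)^6$ form to the suppression of the head--head distance
  distribution induced by explicit leg--leg bead exclusion, on the
  shoulder of the repulsion (suppression between $e^{-3}$ and
  $e^{-0.05}$) with count-based weights. The bead--bead contact distance
  is fixed once at 5 nm — the size of one head/IQ structural unit — and
  with it the fitted exclusion lengths come out near 21, 26 and 31 nm for
  the 4IQ, 6IQ and 8IQ constructs, inside the published ±15% bands. The fitted form is an
  effective description; its residuals (20--70% of the signal spread) are
  reported and a warning is raised above 20%.
* **Fitting.** The step-distribution objective is the summed KL divergence
  of the supplied histograms from the model's binned forward-step law
  (equal weights across mutants; empty bins get $10^{-6}$ pseudo-mass),
  minimized by Nelder--Mead on logit-transformed box coordinates with
  optional Latin-hypercube restarts; $(l_p, \nu_c)$ move along curves of
  constant $\mathcal T$. The force-response fit adjusts $(\mathcal T, b)$
  (optionally $a$) to hit a stall force of 1.9 pN and a 1.3 um zero-load
  run length; an alternating refinement loop runs three cycles by default.

## The synthetic-data generator

`generate_fixture_histograms()` draws forward steps from the model's own
forward-only distribution, adds 1 nm Gaussian localization noise and bins
at 2.5 nm — the conditions of the stepping assays the model describes
(several hundred steps per construct, ~1 nm localization accuracy; the
bins resolve the 2.77 nm half-subunit spacing of the lattice, which is
what makes the joint angle identifiable at these sample sizes). It emulates localization error and
finite sampling but none of the instrument-specific artifacts of real
recordings (drift, missed short steps, the unresolved large steps of long
lever arms), so passing parameter-recovery tests demonstrates statistical
identifiability under the model, not robustness to real-data pathologies.
At 500 steps per construct the joint objective is visibly noise-limited:
single-seed estimates of $\theta_p$ scatter by several degrees (the
objective surface is shallow along a $\theta_c$--$\theta_p$ valley), and
it is the multi-seed average that pins the generating values.

## Known limitations

* The mean field factorizes radial and orientational fluctuations of each
  leg and treats the load as a rigid reorientation (the `"vmf"` form).
  Against the bead-chain Metropolis oracle the density agrees to
  KL < 0.05 (nats, 3 nm cells) at zero load for all constraint strengths
  tested, but disagrees at the 0.1 nats level under a 2 pN backward load,
  where the chain is stiffer against over-rotation than the saturating vMF
  torque. The `"gauss"` cantilever form closes that gap at the cost of
  moving the load-dependent observables away from the published values;
  reconciling the two regimes would need the next order of the stiff-limit
  expansion.
* The computed narrowing of the forward-step width with joint-constraint
  strength is about 0.05 nm per $k_BT$ (0.04--0.07 across preferred
  angles), roughly half the published 0.1 nm per $k_BT$, although every
  qualitative feature (monotone narrowing, near-independence of
  $\theta_p$, the flat/decreasing/increasing binding-time trends at
  $\theta_p$ = 83/65/95 degrees) reproduces.
* Super-stall behavior (power-stroke reversal above roughly 4 pN), cargo
  and label hydrodynamics, and actin fluctuations, rafts or branching are
  outside the model's scope; the low-ATP backward-velocity comparison at
  3 pN is already at the edge of validity and comes out at about
  -56 nm/s against a measured ~-90 nm/s.
* Problem sizes used by the shipped tests: densities on 2.5--4 nm grids,
  oracle comparisons with 3-5 x 10^5 Metropolis samples on 3 nm cells, 200
  Brownian-dynamics search trajectories, 300-400 kinetic Monte-Carlo runs,
  and ten 500-step-per-construct recovery fits at reduced quadrature.
  These sizes keep every comparison's statistical error well inside the
  tolerances being asserted.

## Reproducing the headline numbers

```r
params <- motor_params()        # wild-type, Table-style defaults
rates  <- kinetic_rates()
kin    <- myov_kinetics(params, load_force(0), rates)
dist   <- step_distribution(kin$pp, mode = "combined")
run_statistics(kin$pp, dist, kin$bt, rates)
stall_force(params, rates)
```

`scripts/acceptance.R` recomputes all headline quantities from scratch and
writes them as JSON; see the README for the exact invocation.
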