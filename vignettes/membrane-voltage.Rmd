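---
title: "Close-contact electrostatics of apposed bilayers: model, numerics and synthetic data"
author: "memvolt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Close-contact electrostatics of apposed bilayers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memvolt)
```

## The physical picture

When a synaptic vesicle docks at the presynaptic membrane, the two bilayers
are pulled to within a few nanometres of each other. Both membranes carry
anionic lipid (POPS at a few to fifteen mole percent, PIP2 at -5 e in some
systems), and the thin film of cytosol left between them holds only part of
the potassium counter-charge that neutralized each membrane when they were
far apart. Locally, each membrane therefore sits in an asymmetric charge
environment, and a voltage appears across each bilayer. Below a critical
separation this voltage reaches the electroporation range (of order one
volt) and a transient water channel -- a fusion pore -- opens through the
membrane. Ion flow through the pore then neutralizes the imbalance and the
pore reseals, unless lateral membrane tension stabilizes or dilates it.

`memvolt` implements this picture three ways, each checking the others:

1. **a closed-form five-layer slab model** of the potential and the
   transmembrane voltages,
2. **a numerical 1-D Poisson route** from particle configurations through
   binned charge-density profiles, and
3. **a synthetic configuration generator** that realizes the layered system
   as particles, with plantable pores, so the whole detection and
   classification pipeline can be exercised and validated without any
   molecular-dynamics input.

## The five-layer model

The geometry is a stack of five slabs along the membrane normal Z, with
Z = 0 at the mid-plane of the inter-membrane region: the inter-membrane
cytosol R2 of thickness $D$ spans $[-D/2, D/2]$; the vesicle membrane (m1,
thickness $H_m$) and the vesicle lumen R1 (thickness $H_L$) lie above; the
presynaptic membrane (m2) and the interstitial fluid R3 mirror below.
Charge density is uniform within each slab. Electro-neutrality reads

$$\rho_1 H_L + \rho_3 H_L + \rho_2 D + \rho_{m1} H_m + \rho_{m2} H_m = 0 ,$$

and the potential solves the one-dimensional Poisson equation
$\Phi'' = -\rho/(\varepsilon_r \varepsilon_0)$, making $\Phi$ piecewise
quadratic with continuous value and slope at the four interfaces (there are
no charge sheets in the continuum model). Two gauge choices matter and are
worth stating precisely:

* **Field gauge.** We impose $E = 0$ outside the slab system -- the physical
  boundary condition for an isolated, overall-neutral stack. For a
  mirror-symmetric stack this coincides with the "double integral from the
  symmetry axis" construction, because the field also vanishes at Z = 0
  there. For asymmetric neutral stacks the two constructions differ by a
  constant field; only the zero-external-field choice makes the closed-form
  voltages below hold for every neutral stack, which we verified against
  brute-force quadrature before freezing the convention.
* **Potential reference.** $\Phi(0) = 0$ at the mid-plane; this is an
  additive constant and affects no voltage.

With that gauge the voltages across the two membranes are

$$\Delta V_1 = -\frac{H_m}{\varepsilon_r\varepsilon_0}\left(\tfrac12\rho_{m1}H_m +
\rho_{m2}H_m + \rho_2 D + \rho_3 H_L\right), \qquad
\Delta V_2 = -\frac{H_m}{\varepsilon_r\varepsilon_0}\left(\tfrac12\rho_{m2}H_m +
\rho_{m1}H_m + \rho_2 D + \rho_1 H_L\right),$$

with the sign convention $\Delta V_k = \Phi(\text{outer face}) -
\Phi(\text{inner face})$. For the symmetric case
($\rho_1=\rho_3$, $\rho_{m1}=\rho_{m2}=\rho_m$) both reduce to
$\Delta V = -(\rho_m H_m + \rho_2 D)\,H_m/(2\varepsilon_r\varepsilon_0)$:
linear in $D$, vanishing when the inter-membrane counter-charge exactly
balances a membrane's charge, and growing as the membranes approach. Only
voltage magnitudes are physically compared anywhere in the package; the
absolute sign is a convention.

The model is deliberately *not* Poisson–Boltzmann: ion densities are fixed
uniform per layer, with dielectric screening carried entirely by the single
relative permittivity $\varepsilon_r = 3$ (an experimentally measured
effective value for the hydrated membrane environment). Boltzmann-relaxed
ion profiles, image charges and curvature are out of scope.

## Parameters and defaults

| parameter | default | units | why |
|---|---|---|---|
| $\varepsilon_r$ | 3 | -- | measured effective permittivity used by the model |
| $H_m$ | 4 | nm | typical phospholipid bilayer thickness |
| $H_L$ | 4 | nm | outer aqueous slabs; box of five layers ~20 nm tall |
| area per lipid | 0.65 | nm$^2$ | fluid-phase phosphatidylcholine value |
| lateral box | 23 | nm | the simulated patch cross-section |
| scan grid | 6 nm down, 0.5 nm steps | nm | the stepped-approach protocol |
| observation window | 20 | ns | pore-formation window |
| POPS charge | -1, PIP2 -5 | e | headgroup charges |

The slab thicknesses and area per lipid are not uniquely fixed by the
modelled system; they were chosen once, before any testing, and are
config-overridable. A useful consistency check fell out of them: with
counter-ions distributed uniformly over the three aqueous regions
([build_stack_params()]), the implied potassium concentration across the
4.5--15% POPS composition family spans ~0.04--0.15 mol/L, exactly the
physiological window the simulated systems report.

```{r concentrations}
for (p in c(0.045, 0.15)) {
  cfg <- build_configuration(build_stack_params(lipid_mix_pops(p), D = 4),
                             box_xy = 23, seed = 1)
  conc <- ion_concentration(cfg)
  cat(sprintf("POPS %4.1f%%: %.3f mol/L\n", 100 * p,
              conc$mol_per_L[conc$region == "aqueous"]))
}
```

## Distance scans and the two charge-closure policies

A distance scan needs a rule for what happens to the charges as $D$
changes. Two closures are implemented ([voltage_vs_distance()]):

* `fixed_rho2` (default): the counter-ion *density* between the membranes
  is held constant and the outer regions re-neutralize the stack. This
  matches the stepped-approach protocol in which each distance is an
  independently built system at the same ion concentration, and it yields
  the exactly affine $\Delta V(D)$ with slope
  $-\rho_2 H_m/(2\varepsilon_r\varepsilon_0)$.
* `fixed_counter_charge`: the total counter-charge per area $Q_2=\rho_2 D$
  is held fixed, as if the R2 ions were trapped while the membranes
  approach. Under the slab algebra this makes $\Delta V$ independent of
  $D$ -- there is then no critical distance, which is why this closure is
  *not* the default even though "trapped ions" sounds like the more
  literal picture of a single approaching system. The choice is recorded
  in every scan's metadata.

[critical_distance()] inverts $|\Delta V(D)| = \Delta V_{critical}$ on the
close-contact branch -- the branch where the magnitude grows as the
membranes approach. (Extrapolating the affine relation far beyond the
template distance produces a second, unphysical crossing where the
overcompensating counter-charge dominates; the inversion explicitly
excludes it.) Closed form under `fixed_rho2`; bisection to $10^{-9}$ nm
otherwise; default bracket 0.5--10 nm.

```{r scan}
sc <- distance_scan(lipid_mix_pops(0.15), dv_critical = 1.0)
sc
```

## The numerical route

The particle-based route mirrors how transmembrane potentials are measured
in simulation trajectories: bin the per-particle charges into a 1-D profile
$\rho(Z)$ averaged over the membrane plane ([bin_charge_density()],
default 0.1 nm bins), double-integrate the Poisson equation
([integrate_potential()]) and read the voltage off the membrane faces
([measure_voltage()], linear interpolation). Numerical choices: the field
integral accumulates the piecewise-constant bin densities exactly; the
potential integral is trapezoidal over bin edges, which is exact for the
resulting piecewise-linear field; so the only discretization error is in
how the binning represents the charge distribution (first-order in bin
width at unaligned layer faces, exact at aligned ones). Voltages are
gauge-invariant by construction and the reference position is arbitrary.

## What the synthetic generator does and does not emulate

[build_configuration()] realizes a stack as particles: headgroup charges
distributed through each membrane slab, integer unit-charge ions placed
uniformly in the three aqueous regions, and exact electro-neutrality. Two
constructions deserve comment:

* **Volumetric headgroups (default).** Placing headgroup charge as discrete
  sheets at the slab faces is geometrically appealing, but a 0.1 nm binning
  of a face-aligned charge sheet smears it one bin into the slab and biases
  the measured voltage by $\sim\sigma h/2\varepsilon$ (~0.07 V for the 15%
  POPS system) -- a systematic error larger than the construction's
  statistical noise. Distributing the charge uniformly through the slab
  matches the analytic model in expectation at every bin width. The sheet
  style remains available (`head_style = "sheet"`) and is what the
  face-detection route expects sheet-like data to look like.
* **Integer-count neutrality.** Ion counts are apportioned across the three
  regions by largest remainder so that they cancel the (integer) headgroup
  charge exactly; no localized compensating charge is needed, which would
  otherwise bias the measured voltage by ~0.05 V at the default box size.

[build_trajectory()] adds zero-charge water markers (jittered lattice at
33 nm$^{-3}$, the density of water) and, past the schedule opening time, a
dense cylindrical column of markers through each membrane at the scheduled
radius (0.1 nm fill lattice, kept at or below the detection cell so a
planted channel is never missed by sampling accident). Radius schedules
`reseal_fast`, `reseal_slow` and `dilate` mirror the three observed
tension regimes (20.6, 24.9, 32.6 pN/nm): closure within the 20 ns window,
slow shrinkage that outlives the window, and monotone growth. The
schedules are *prescribed*, not simulated: the generator makes no kinetic
claim, and the trajectory mode of [distance_scan()] couples voltage to
opening time by an explicit threshold stub
($t_{open} = w\,(\Delta V_{crit}/|\Delta V|)^2$), documented as such.

What passing tests on this data does **not** show: real lipid packing,
water polarization, pore nucleation kinetics, line tension, or hemifusion
intermediates. The generator validates the *analysis chain* -- binning,
integration, detection, sizing, timing, classification -- not membrane
physics.

## Pore detection, sizing and fate

[detect_pores()] tiles the membrane plane into 0.2 nm cells and calls a
cell open when water occupancy is continuous across the slab (every 0.2 nm
Z sub-bin occupied). Open cells are grouped by 4-connectivity with
periodic wrap in X and Y (hand-rolled breadth-first labelling, since
standard image labellers do not wrap); pore size is reported as the
equivalent circular diameter $2\sqrt{A/\pi}$, the natural scalar for the
"1--2 nm diameter" language of the field. Planted radii of 0.5--1.0 nm are
recovered within two grid cells, with zero false positives on intact
frames, because an intact slab contains no water markers at all.

[pore_size_distribution()] fits a Gaussian to the diameter histogram by
least squares, weighted by inverse bin count (the counting-noise variance);
at least 10 observations are required, below which only the histogram is
returned. [classify_fate()] labels a series `RESEAL_FAST` on closure
within the window, `DILATE` on $\ge 25\%$ growth with a non-decreasing
fitted trend over the last third (net fitted decline up to one cell
tolerated -- a per-step test proved fragile under one-cell detection
noise), `RESEAL_SLOW` otherwise; a closure time is recorded only when
closure was observed.

## Tension

Lateral tension is $\Gamma = L_Z\,(P_Z - P_{Lat})$ with the bar-nm to
pN/nm factor (0.1) derived from SI definitions at run time
([membrane_tension()]). The 20.6 pN/nm regime at a 20 nm box corresponds
to a 10.3 bar pressure gap, and the identity round-trips to machine
precision.

## Problem sizes and verification

The validation suite runs entirely on synthetic data: 20 random neutral
stacks against a $10^{-4}$ nm quadrature oracle; particle systems at the
full 23 nm cross-section for the voltage pipeline (8 replicate
configurations to estimate counting noise); 8--10 nm boxes for the pore
round-trip, 50-frame false-positive screen and fate classification, where
the cross-section only dilutes the statistics and the full box adds
nothing. These sizes were chosen so the whole suite completes in well
under a minute while every tolerance is met with margin.

## Known limitations

* The slab model's voltages are only as meaningful as the uniform-density
  assumption; real counter-ion profiles relax toward the membranes.
* `fixed_counter_charge` scans are provided for completeness but carry no
  distance dependence in this algebra.
* The critical distance depends on $H_L$, $H_m$ and the area per lipid,
  none of which are sharply fixed; compare trends (composition
  monotonicity, linearity) rather than absolute distances.
* Detection assumes pores are water-filled cylinders spanning the slab;
  tilted or hourglass channels would be undersized.
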