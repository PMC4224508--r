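---
title: "Modelling sinoatrial and atrioventricular nodal conduction at desk scale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling sinoatrial and atrioventricular nodal conduction at desk scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

nodalsim simulates the electrophysiology of the right atrium and its
conduction system -- sinoatrial node (SAN), atrial muscle, the
atrioventricular (AVN) pathways (inferior nodal extension, transitional
zone, penetrating bundle) and the passive block zone -- on voxel label
volumes at 60 µm resolution. Two engines share one geometry, protocol and
measurement surface: a modified FitzHugh–Nagumo (FHN) reaction–diffusion
model integrated by explicit finite differences, and a three-state
cellular automaton (CA). This vignette documents the model equations, the
calibration of their free parameters, the design decisions behind the
synthetic geometries and protocols, the numerical choices, and what the
package's tests do and do not establish about real tissue.

## Reaction kinetics

Every excitable tissue class uses the Rogers-type modified FHN system on
the normalized potential $u$ (0 = rest, 1 = overshoot) and recovery
variable $v$:

$$\frac{\partial u}{\partial t} = c_1 u (u - \alpha)(1 - u) - c_2 u v
  + \nabla \cdot (\mathbf{D} \nabla u), \qquad
  \frac{dv}{dt} = b (d\,u - v).$$

$(D, c_1, c_2, b, d)$ per tissue are the published set
(`tissue_params()`); they are preserved verbatim and never re-fit. Two
points deserve comment:

* **Recovery form.** With the atrial coefficients, the textbook recovery
  $dv/dt = b(u - d v)$ saturates at $v = u/d \approx 0.40$, below the
  repolarization knee $\;(c_1/c_2)\,((1-\alpha)/2)^2 \approx 1.3$ of any
  propagating $\alpha$: the plateau would never end. The form
  $b(d\,u - v)$ reaches the knee and, with $\alpha \approx 0.24$,
  reproduces the published atrial APD90 of 75 ms almost exactly. It is
  therefore the recovery used throughout.
* **Pacemaking (SAN).** The nodal variant keeps the cubic but couples the
  recovery additively and carries a constant pacemaker current $J$:
  $du/dt = c_1 u(u-\alpha)(1-u) - c_2 v + J$, with $\alpha < 0$. The
  multiplicative coupling cannot pace usefully: $u = 0$ stays an exact
  equilibrium, so after each beat the trajectory collapses exponentially
  toward it and either sticks at a depolarized fixed point
  ($|\alpha| \gtrsim 0.2$) or needs more than a second to re-fire. The
  additive form rebounds through a brief hyperpolarization, giving a
  finite diastolic depolarization rate, and $J$ (the classic applied
  current of the original FHN oscillator) sets its slope.

The block zone is passive tissue, $du/dt = -u/R_b$ plus diffusion, with
$R_b = 0.5$; it has no recovery variable and can never regenerate an
upstroke, which suffices to extinguish incident waves.

The SAN periphery is an idealized border band, 4 elements (0.24 mm) wide:
within it $c_1$ grades linearly with lattice distance from the nearest
atrial element, from the nodal value at the band's inner edge to the
atrial value at the atrium. The threshold grades with the same weight
toward a small positive edge value (+0.05) and the pacemaker current
fades to zero: the border loses automaticity toward the atrium but keeps
a low threshold. That combination matters: a border graded all the way to
atrial threshold is a current sink that blocks nodal exit on a 2D sheet
(exit block), while a border that kept the nodal threshold and the
atrial-scale $c_1$ would out-pace the centre. The shipped rule makes the
periphery an excitable amplifier, so the impulse leaves the node against
the atrial load and the leading pacemaker site stays central.

## Units, diffusion and the calibrated constants

Space is the 60 µm lattice (`dx = 0.06` mm), time is milliseconds. The
published diffusion coefficients are dimensionless; one table unit is
`diffusion_unit` mm²/ms. Anisotropic tissues (SAN, crista terminalis,
roof bundle, main branch) get a fiber tensor
$\mathbf{D} = D_t I + (D_l - D_t) f f^T$ with $D_l/D_t = 10$ applied
geometric-mean preserving ($D_l = D\sqrt{10}$, $D_t = D/\sqrt{10}$),
which yields the published conduction-velocity anisotropy of
$\sqrt{10} \approx 3.2$. Characterization strands are isotropic.

The published table omits $\alpha$, $J$ and the diffusion unit. They were
fixed once by `scripts/calibrate.R` against the published strand table
and are frozen in the package defaults:

| quantity | value | fixed against |
|---|---|---|
| `diffusion_unit` | 0.02407 mm²/ms | atrial strand CV 0.5333 m/s |
| `alpha` atrial | 0.2385 | atrial strand APD90 75.05 ms (jointly with the unit) |
| `alpha` INE | 0.1605 | INE strand CV 0.0949 m/s |
| `alpha` PB | 0.2310 | PB strand CV 0.1413 m/s |
| `alpha` SAN, `j` SAN | −0.12, 0.16 | cycle length 330 ms, strand APD90 185 ms, refractory period 283 ms (joint grid) |

One threshold per tissue cannot fit four measurements, so the rest of the
strand table is a genuine validation surface. Where it validates and
where it does not:

* Atrial CV and APD90 match to a fraction of a percent; SAN cycle length
  (+4%), APD90 (+7%) and refractory period (−8%) land within tolerance;
  INE and PB conduction velocities are matched exactly; the
  conduction-velocity anisotropy ratio and the $\sqrt{D}$ scaling of CV
  are reproduced within a few percent.
* INE APD90 saturates near 34 ms (published 93.7) and PB near 82 ms
  (published 118): in the canonical cubic the plateau ends at the knee
  $(c_1/c_2)((1-\alpha)/2)^2$, and the $\alpha$ that reproduces the slow
  conduction of these tissues fixes a low knee. No admissible $\alpha$
  reaches both (the APD would demand $\alpha < 0$, which un-stabilizes
  rest and triples the CV). The published modification of the excitation
  equation evidently reshapes the plateau in a way the canonical family
  cannot express.
* Functional (propagated) refractory periods run long for the
  fast-recovering tissues (atrial 123 ms vs 82): recovery decays with
  time constant $1/b$, and a premature wave needs a sizable margin below
  the knee before it stops being decremental over 47 layers. The SAN
  value, by contrast, is dominated by its long cycle and lands in band.
* Maximum upstroke velocity trades off against CV through the same
  $\alpha$; the shipped calibration favours CV/APD, leaving upstrokes
  30–50% low. The engine reports them; they bound nothing else.

## Strand measurement conventions

`strand_measurements()` encodes the characterization protocol: 50×5×5
elements, the first three layers stimulated (1 ms voltage clamp),
conduction velocity as the mean first-activation time difference between
layers 10 and 40 (1.8 mm), APD90 from the mid-strand trace (onset at the
upstroke foot, end at 90% return to the pre-upstroke baseline, linearly
interpolated), maximum upstroke as the largest discrete $du/dt$, and the
refractory period as the shortest S1–S2 coupling that still propagates to
the far probe, found by bisection at 1 ms (identical to an exhaustive
sweep because propagation success is monotone in the interval; a test
verifies the identity against a sweep oracle).

The pacemaking strand needs two conventions of its own, both consequences
of physiology rather than implementation. A free-running uniform nodal
strand fires as a *phase wave* -- nearly synchronously -- so there is no
propagating wave to time: conduction velocity and refractory period are
therefore read from a premature (S1–S2) wave coupled to the strand's own
spontaneous beat, with CV measured at the shortest fully propagating
interval (the refractory period itself, the slowest wave the tissue
supports). Cycle length, APD90 and upstroke come from the steady
spontaneous beat. Nodal CV carries strong restitution (0.078 m/s at the
refractory limit rising to 0.18 m/s late in diastole), so this
convention, which we state explicitly, is the single largest contributor
to the +18% deviation of the nodal strand CV from the published 0.0673
m/s.

## The cellular automaton

Each node is resting, excited or refractory. A resting node accumulates
an excitation counter by `gain` per currently excited 6-connected
neighbour per step and fires at `theta`; excited nodes excite neighbours
for `E` steps, are refractory for `R` steps, then rest (counters reset on
firing and on leaving refractoriness). All updates are synchronous; a
brute-force reference automaton written independently in the test suite
must match the engine state-for-state on random heterogeneous lattices.

Conduction speed is controlled by multi-step accumulation: with unit
gain, `theta = k` delays each node $k$ steps, so CV $= dx/(k\,dt)$. At
the 60 µm lattice the automaton step is 0.1 ms (a 1 ms step would cap CV
at 0.06 m/s, below every published value). Defaults encode the published
automaton table: CV 0.30 / 0.10 / 0.15 / 0.10 m/s and refractory periods
81 / 94 / 134 / 154 ms for atrial muscle, inferior nodal extension,
transitional zone and penetrating bundle, plus a nodal row carrying the
283 ms nodal refractory period for the fibrillation scenario. The excited
phase is kept short (~1.5 ms, just beyond the slowest accumulation
delay), with the refractory phase carrying the rest of the period: long
excited phases re-fire short-refractory nodes across heterogeneous tissue
borders -- discovered here as a spurious ring oscillator and worth a
warning to anyone re-parameterizing the automaton.

## Synthetic geometries

All geometries are generated by code, deterministically.

* `make_strand()` -- the characterization strand.
* `make_single_cell()` -- an isolated voxel for point kinetics.
* `make_anisotropic_slab()` -- uniform fibrous slab; the default tissue
  is the crista terminalis because the self-depolarizing node cannot
  carry a clean test wave (its background drift contaminates the front).
* `make_idealized_right_atrium()` -- a 2D sheet preserving the topology
  that drives the nodal behaviours: caval orifice, SAN with graded
  periphery lying against the crista terminalis (and wrapped, except for
  a crista-facing exit window, in an insulating connective-tissue collar
  excluded from the domain: without it the sheet's diffusive load pins
  the weak nodal source at a stable sub-threshold equilibrium after its
  first beat), a passive block zone
  interposed between node and septum (the straight node-to-septum path
  crosses passive tissue only, forcing the septal detour), an intercaval
  line of block at the cranial orifice pole, and an AVN chain -- slow
  pathway (INE), fast pathway (transitional zone, reached from the
  septal side) and penetrating bundle joined at a compact-node junction
  insulated from the atrium everywhere else. The default 9 mm sheet
  serves sinus-rhythm runs; fibrillation-like runs use the enlarged
  variant (`300, 300, svc_radius = 100`) so the caval circuit exceeds
  the automaton wavelength. The roof bundle and main branch of the full
  anatomy have no 2D counterpart and are absent by construction.
* `make_dual_pathway_ring()` -- fast (TZ) and slow (INE) limbs joined
  caudally at a junction continuing into a bundle stub, cranially by an
  atrial bar; the slow limb is routed as the longer path so that a beat
  blocked in the fast limb and conducted retrogradely up the slow limb
  finds the fast limb recovered on return.

What these geometries emulate is connectivity and the ordering of
conduction delays and refractory periods; what they do not emulate is
real fiber architecture, wall thickness, or absolute activation times of
the anatomical model. Passing scenario tests therefore establishes the
mechanisms (detour, dual entry, entrance block, filtering, echo), not
anatomical timing.

## Protocols

`run_sinus()` seeds the diastolic potential only in the central third of
the node, so the leading pacemaker site is central; activation must reach
the crista first, detour around the block zone to the septum, and enter
the AVN by both routes with the septal route downstream.

`run_af()` produces the fibrillation-like state. An honest negative
result shaped this protocol: with a single uniform atrial refractory
period and no conduction-velocity restitution, the automaton's vulnerable
window for a lone premature stimulus is empty -- the recovery front
travels at exactly the wavefront speed, so a broken premature front
glides behind it and its two arms annihilate after at most one lap around
the orifice (verified by direct simulation over wide stimulus-timing and
geometry scans). Sustained reentry in the published anatomy rides on its
refractory-period dispersion, which the idealized sheet deliberately
lacks. The default driver therefore follows the premature caval beat with
a rapid planar burst at the caval band (95 ms interval, just above the
atrial refractory period), reproducing the high-rate atrial input whose
nodal filtering is the point of the scenario: the node centre follows at
an integer fraction (entrance block, ≥ 3:1 with the shipped numbers,
alternating when the rates are incommensurate) and the distal penetrating
bundle at 2:1 (Wenckebach-type filtering). `induce = "s2"` runs the
single-premature-beat protocol and reports whether reentry was induced as
an outcome.

`run_echo()` runs S1–S2 at the bundle stub of the ring. The echo window
measured by `echo_window()` is a single contiguous interval bounded by
the two limb refractory periods (94–134 ms): below it both limbs block,
inside it the fast limb blocks while the slow limb conducts retrogradely
and the impulse reenters the fast limb anterogradely (one echo, the loop
dying on its second lap because the loop time is shorter than the slow
limb's refractory period), above it both limbs conduct and collide. One
deviation was forced: the published bundle refractory period (154 ms)
exceeds the whole window, so no premature ventricular-side beat could
ever re-enter through a stub carrying it; the stimulus stub recovers in
60 ms while both limbs keep their published values.

## Numerics

Forward Euler with `dt = 0.005` ms by default; when no explicit `dt` is
given the step is reduced to 95% of the diffusion stability bound
$1/(2\,\mathrm{max}\sum_i D_{ii}/dx^2)$ (the anisotropic crista tensor is
the binding case at ~0.003 ms). An explicit `dt` is honoured and guarded:
divergence (|u| > 10) aborts with a stability error naming the step.
Halving `dt` moves strand CV by under 1% (tested). Diffusion is a
conservative face-flux form -- face tensors are arithmetic means, mixed
(off-diagonal) terms use face-centred tangential gradients, fluxes are
applied antisymmetrically -- so total $u$ is conserved to round-off with
reaction off, no-flux at every outer and tissue/hole boundary by
construction; holes (label 0) are excluded entirely. Activation detection
is the upward crossing of u = 0.5 (configurable), linearly interpolated
between steps.

Problem sizes were chosen so the whole test suite and the acceptance
script run in minutes on one CPU: 1,250-voxel strands, a 220-voxel-long
heat-kernel fiber, 130–150 voxel sinus sheets, the 300-voxel
fibrillation sheet (automaton), and the ~75×63 ring.

## Limitations

The kinetics are caricatures: no biophysical currents, no
rate-dependent APD restitution beyond what the cubic produces, and the
canonical-form shortfalls listed above (slow-tissue APD, functional
refractory periods, upstroke magnitudes). The idealized 2D sheet cannot
sustain single-stimulus reentry and the fibrillation-like state is
driven, not self-sustained; dominant frequencies of the full-anatomy
arrhythmia are out of reach at desk scale. Fiber fields in the bundled
geometries are axis-aligned; arbitrary fiber angles exercise the mixed
stencil but with first-order accuracy only. The display voltage map
(−80 to +20 mV) affects no dynamics.
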