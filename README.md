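# nodalsim

Desk-scale simulation of the cardiac conduction system of the right
atrium: the sinoatrial node (SAN, the heart's pacemaker), atrial muscle,
the atrioventricular (AVN) pathways — inferior nodal extension (slow),
transitional zone (fast), penetrating bundle — and the passive block zone
that forces sinus activation to detour toward the interatrial septum.
The package is for electrophysiology modellers who want the classical
nodal behaviours (sinus activation sequence, SAN entrance block during
fibrillation, AVN Wenckebach-type filtering, ventricular echo beats)
reproducible from code on a laptop, without the full anatomical model.

Two engines share one geometry / protocol / measurement surface:

* a **modified FitzHugh–Nagumo reaction–diffusion model** on a 60 µm
  voxel lattice, per tissue class

  $$\partial_t u = c_1 u (u-\alpha)(1-u) - c_2 u v
    + \nabla\!\cdot(\mathbf{D}\nabla u), \qquad
    \dot v = b(d\,u - v),$$

  with an additive-coupling pacemaking variant
  ($-c_2 v + J$, $\alpha<0$) for the SAN, a passive block zone
  ($\dot u = -u/R_b$), a graded SAN periphery band, and fiber-based
  anisotropic diffusion tensors
  $\mathbf{D} = D_t I + (D_l - D_t)ff^T$ with $D_l/D_t = 10$
  (conduction-velocity anisotropy $\approx\sqrt{10}$);

* a **three-state cellular automaton** (resting / excited / refractory,
  excitation counters against a threshold) whose per-tissue delays and
  refractory periods encode the published automaton behaviour.

Geometries (strand, anisotropic slab, idealized 2D right atrium,
dual-pathway ring) are generated by code; measurements (conduction
velocity, APD90, maximum upstroke, S1–S2 refractory period, cycle
length, conduction-block ratios) return tibbles and work on either
engine. See the methods vignette (`vignettes/nodal-conduction.Rmd`) for
the model details, the calibration of the free parameters, and known
limitations.

## Worked example

Characterize atrial muscle on the 50×5×5 strand and measure a sinus beat
on the idealized atrium:

```r
library(nodalsim)

strand_measurements("atrial", rp = FALSE)
#> # A tibble: 1 × 6
#>   tissue cv_m_s apd90_ms upstroke_per_ms rp_ms cycle_ms
#>   <chr>   <dbl>    <dbl>           <dbl> <dbl>    <dbl>
#> 1 atrial  0.533     75.0           0.820    NA       NA

g <- make_idealized_right_atrium()
s <- run_sinus(g, duration = 220)
dplyr::filter(tidy(s), site %in%
  c("san_centre", "crista", "septum", "junction", "pb_distal"))
#> # A tibble: 5 × 3
#>   site       t_activation n_events
#>   <chr>             <dbl>    <int>
#> 1 san_centre         2.20        1
#> 2 crista             6.21        1
#> 3 septum            29.5         1
#> 4 junction          20.8         1
#> 5 pb_distal         29.2         1
```

The strand conduction velocity (0.533 m/s) and APD90 (75.0 ms) are the
published atrial values; in the sinus beat the impulse starts centrally
in the node, reaches the crista terminalis at ~6 ms, detours around the
passive block zone to the septum (~29 ms), enters the AVN junction via
the fast septal route (~21 ms) and conducts anterogradely down the
penetrating bundle (~29 ms). `plot_activation(s)` draws the isochrone map;
`autoplot(s)` the probe traces.

The fibrillation-like and echo-beat scenarios:

```r
ga <- make_idealized_right_atrium(300, 300, svc_radius = 100)
r <- run_af(ga)
r$san_ratio   # conduction ratio 4:1 -- SAN entrance block
r$avn_ratio   # conduction ratio 2:1 -- AVN filtering

ring <- make_dual_pathway_ring()
run_echo(ring, s1_s2_interval = 114)$echo   # TRUE: one reentrant echo
echo_window(ring)                           # the window = the two limb RPs
```

A thin command-line front end ships in `inst/cli/nodalsim`
(`generate-geometry`, `run`, `measure`).

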