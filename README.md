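# activedrift

Agent-based simulation of colloidal transport in a bacterial bath whose
swimming speed is patterned by light, plus the pressure-field analyses that
explain the transport.

## The problem

Suspensions of motile bacteria exert mechanical pressure on immersed
objects. When the swimming speed is made *spatially non-uniform* — here by
projecting light onto photokinetic *E. coli*, whose speed follows the local
intensity — regions of different activity coexist: slow regions grow dense
(for a dilute run-and-tumble gas the stationary state satisfies
`rho v = const`), fast regions grow dilute. A passive colloid placed at the
interface between a slow and a fast region then feels unequal pressures on
its two sides and drifts — surprisingly, *toward the fast side*: the dense
slow side, compressed by a surrounding layer of polarized swimmers,
develops an interaction (virial) pressure that exceeds the swim pressure of
the fast side. In the experiments this drive transports 10 um beads at
about 1% of the fast swimming speed, with a light pattern that follows each
bead through a feedback loop.

`activedrift` is for people who want to simulate and dissect this
mechanism: it integrates N run-and-tumble spherocylindrical rods (length
`ell = 1`, thickness `sigma = 1/2`, tumble rate `alpha = 0.1`) with steric
pair forces and one passive bead in a periodic box, imposes the
feedback-locked speed pattern (`v_minus` / `v_plus` inside a disc of radius
`R = 8a`, `v_zero` outside), and measures:

* `p_W(theta)` — mechanical wall pressure resolved along the bead contour;
* `p_D(r)` — direct (virial) pressure, localized by midpoint-binned pair
  virials, and its value on an annulus just outside the bead;
* `p_S = p_W - p_D` — the empirical swim-pressure remainder on the contour;
* `m(r)`, `f_S = gamma v m` — polarization and swim-force-density fields,
  and the no-current momentum balance `gamma v m = grad p_D`;
* bead drift speed (least-squares slope of the unwrapped track) and region
  density ratios, with ensemble standard errors;
* closed-form ideal active-gas oracles (`gamma rho v^2 tau / 2`,
  `rho v = const`, encounter time `a/v`) used to validate everything.

## Worked example

Hold the bead fixed, fully embedded in the slow half-disc, and measure the
pressure decomposition on its contour (reduced geometry `a = 1.25`,
`R = 10`, `L = 30`, packing fraction 0.38, two seeds kept short for the
example):

```r
library(activedrift)
pr <- pressure_protocol("slow", seeds = 1:2, n_steps = 6e4)
cat(sprintf("p_W = %.3f +/- %.3f, p_D = %.3f, p_S = %.3f\n",
            pr$mean_p_w, pr$sem_p_w, pr$mean_p_d, pr$mean_p_s))
#> p_W = 0.460 +/- 0.032, p_D = 0.384, p_S = 0.077
```

The wall pressure on the slow side is essentially all direct (interaction)
pressure: `p_D/p_W ~ 0.84`, and the swim remainder `p_S` is small — the
signature that the slow, crowded region pushes via compression, not via
propulsion. The same protocol with `side = "fast"` gives a roughly twofold
smaller `p_W` of which barely 60% is direct pressure. Releasing the bead
turns the imbalance into motion:

```r
dr <- drift_protocol(seeds = 1:6, n_steps = 1.5e5)
dr
#> drift_estimate: v = 0.030187 +/- 0.00106 (n = 6 runs)
```

a drift of ~2.7% of the fast speed `v_plus = 19/17`, directed from the slow
toward the fast half (positive axis), with the run-to-run standard error.

The numbered drivers under `analysis/` reproduce the full study at the
reduced scale and write CSV tables under `results/`:
`01_pressure_maps.R` (contour profiles and `p_D` maps for the slow, fast
and interface bead positions), `02_drift_vs_density.R` (drift versus
packing fraction with and without rod-rod interactions),
`03_drift_vs_offset.R` (drift versus the bead offset `Delta`, including the
sign reversal at the disc rim), `04_background_speed.R` (density ratios and
drift versus the background speed `v0`).

## Notes on scales and conventions

All quantities are in reduced units (`ell = v0 = gamma = 1`; 2D pressure in
`gamma v0 / ell`). The shipped protocols use a half-scale geometry
(`a = 1.25`, `R = 10`, `L = 30`) so ensembles finish quickly;
`reference_geometry("full")` restores the experimental aspect ratio. See
the methods vignette (`vignettes/active-pressure-transport.Rmd`) for the
model details, parameter rationale — including the calibrated bead drag —
estimator design, and known limitations.
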