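# cuttleflow

Analysis of liquid–gas interface motion in paired millimetric channels
inspired by the wavy pillar walls of the cuttlebone — the chambered shell
cuttlefish use for buoyancy control. When a hydrostatic head
ΔP = ρ g ΔH pulls two air–water fronts through nominally identical
channels, the fronts do not stay together: the Darcy feedback through the
shrinking air column (a leading front sees less resistance and
accelerates) amplifies any small lead, and wall waviness modulates the
local mobility, so the separation D(t) = |S₁(t) − S₂(t)| grows roughly
exponentially. The package is built around that statistic:

* **Pressure budget and dimensionless numbers** — ρUL/μ, ρgΔH, 2γ/R,
  μLU/h², μU/h — establishing that the hydrostatic head dominates the
  dynamic pressure drops by 2–4 orders of magnitude, so the two channels
  are identically driven.
* **Capillary rise** — integration of the momentum balance
  ρ d(z ż)/dt = 2σcosθ/w − μz ż/w², with its early linear regime
  z = U₀t and late Washburn regime z = √(4σcosθ·w·t/μ), and a log–log
  exponent fit.
* **Front-separation Lyapunov exponents** — D(t) → masked log D → local
  slope over 7-sample windows by a degree-4 Savitzky–Golay
  differentiator → per-run 75th percentile λ₇₅ → trends of λ₇₅ against
  head ΔH and wall amplitude A.
* **A seeded stochastic simulator** of two wavy-wall channels under
  Darcy's law, a synthetic top-view frame renderer, and a sub-pixel front
  tracker that closes the loop from image stacks back to displacement
  traces.

It is written for people studying confined two-phase flows and
biomimetic microfluidics who want the full chain — physics sanity checks,
trace analysis, synthetic benchmarks and imaging round trips — as tested,
reusable functions rather than one-off scripts.

## Worked example

```r
library(cuttleflow)
water <- fluid_properties()   # 997 kg/m3, 1e-3 Pa s, 0.072 N/m, theta = 0

# Which forces matter at the nominal operating point?
pressure_budget(water, height_difference = 1.33e-2,
                radius_of_curvature = 0.375e-3,
                filled_length = 0.039, speed = 1e-3, gap = 0.75e-3)
#> Pressure budget (Pa):
#>   hydrostatic          130.1
#>   capillary              384
#>   viscous            0.06933
#>   contact line      0.001333
#>   head (gauge)        -514.1
#>   viscous/hydrostatic  0.000533
#>   contact-line/viscous 0.0192

# One simulated dual-channel run and its separation statistic
geom <- channel_geometry(amplitude = 0.188e-3)       # 0.188 mm wavy walls
cfg  <- simulation_config(head_height = 1.33e-2, seed = 42)
run  <- simulate_dual_channel(geom, geom, water, cfg)
lam  <- local_log_slope(separation(run), window = 7, degree = 4)
percentile_summary(lam)
#> lambda (q = 0.75): 227 1/s over 165 local exponents
crossing_count(run)
#> [1] 8

# A small ensemble over the experimental condition grid
base <- simulation_config(head_height = 0, seed = 1)
grid <- simulate_ensemble(water, heads = head_presets(),
                          amplitudes = amplitude_presets(),
                          n_seeds = 5, base_config = base)
res <- report(grid, plots = FALSE)
res$by_head
#>   head_m mean_lambda se_lambda  n
#> 1 0.0057    73.36362  7.355154 20
#> 2 0.0114   136.64993 12.030612 20
#> 3 0.0133   161.83598 17.324391 20
```

The budget shows the hierarchy that makes the experiment clean: the
hydrostatic driving (130 Pa) towers over the viscous (0.07 Pa) and
contact-line (0.001 Pa) drops, and the capillary pressure, though large,
is identical in the two channels. The single run yields 165 local
exponents with λ₇₅ ≈ 227 s⁻¹ and 8 front crossings. In the ensemble the
mean λ₇₅ rises with the head (73 → 137 → 162 s⁻¹ across 0.57, 1.14 and
1.33 cm), and `res$by_amplitude` shows the same monotone rise with wall
amplitude — straighter channels separate their fronts more slowly, the
pattern that matches the straight, parallel pillars found where the real
cuttlebone actually pumps water.

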