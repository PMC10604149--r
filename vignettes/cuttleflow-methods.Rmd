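---
title: "Interface separation in cuttlebone-inspired dual channels: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interface separation in cuttlebone-inspired dual channels: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cuttleflow)
```

## The system

The cuttlebone keeps a cuttlefish neutrally buoyant by exchanging liquid
and gas through a chambered shell whose chambers are supported by
corrugated ("wavy") vertical pillars. Near the ventral membrane, where
water actually moves in and out, the pillars straighten and align. A
natural question is whether that local straightening is functional: does
wall waviness destabilize the liquid–gas interface that travels through
the inter-pillar gaps?

cuttleflow models the desk-scale analogue of that question: two
millimetric channels (nominally 39 mm long, 0.75 mm wide, in three
segments) moulded side by side in PDMS, connected to a common reservoir
whose bath is lowered by a height $\Delta H$, so that a hydrostatic
pressure $\rho g \Delta H$ pulls the two air–water fronts along the
channels. The walls are either straight or sinusoidally corrugated with
amplitude $A \in \{0, 0.0625, 0.188, 0.25\}$ mm. The measurement is the
pair of front displacements $S_1(t), S_2(t)$, and the question is how
fast the two fronts separate.

## Which forces matter

`pressure_budget()` assembles the relevant pressures at an operating
point. For water ($\rho \approx 997$ kg/m$^3$, $\mu \approx 10^{-3}$
Pa\,s) moving at $U \sim 0.2$–$2$ mm/s through $h = 0.75$ mm channels:

* hydrostatic driving $\rho g \Delta H \sim 10$–$10^2$ Pa,
* capillary pressure $2\gamma/R$ — large ($\sim$400 Pa at
  $R \approx h/2$) but *identical* in the two channels, since the menisci
  share the same radius of curvature, so it contributes no differential
  driving,
* viscous drop $\sim \mu L U / h^2 \sim 10^{-2}$–$10^{-1}$ Pa,
* contact-line drop $\sim \mu U / h \sim 10^{-3}$–$10^{-2}$ Pa.

The hierarchy hydrostatic $\gg$ viscous $\gg$ contact line (tested as a
property across the whole operating range) is what justifies treating the
two channels as identically driven: any separation of the fronts must
come from geometry and randomness, not from the static pressure budget.
The Reynolds number $\rho U L/\mu$ is $\sim 3\times 10^{-2}$ at
cuttlebone scales. One wrinkle worth recording: at channel scale the
formula gives $0.15$–$1.5$ over $U \in [0.2, 2]$ mm/s with $L = 0.75$ mm,
while the published estimate brackets the range as
$1.5\times10^{-2}$–$1.5\times10^{-1}$; only the low-speed end of the
printed range is consistent with $\rho U L / \mu$. We compute the formula
faithfully and note both readings rather than silently repairing either.

## Capillary rise in a single gap

The momentum balance for a liquid column of height $z$ rising in a gap of
width $w$ is integrated exactly as written,

$$\rho \,\frac{d(z\dot z)}{dt} = \frac{2\sigma\cos\theta}{w} -
  \frac{\mu z}{w^2}\,\dot z ,$$

using the momentum variable $y = z\dot z$, which is regular at $z = 0$
(the physical initial condition), with $z^2 = z(0)^2 + 2\int y\,dt$
recovered alongside. In $y$ the balance is linear, so an exact closed
form exists; the package nevertheless integrates numerically (deSolve,
`lsoda`, absolute tolerance $10^{-12}$ on $y$) so that the viscous
prefactor can be changed, and the closed form serves as an independent
oracle in the test suite. The `poiseuille_factor` argument (default 1,
i.e. the balance exactly as above) lets users insert the parallel-plate
convention 12.

Two regimes bracket the solution: inertia–surface-tension balance gives
linear growth $z = U_0 t$ with $U_0 = \sqrt{2\sigma\cos\theta/(\rho w)}$,
and the viscous–surface-tension balance gives the Washburn law
$z = \sqrt{4\sigma\cos\theta\, w t/\mu}$. The crossover time is
$t_c = \rho w^2/\mu$, the only timescale the two balances share; the
asymptote tests probe $t \le t_c/20$ and $t \ge 100\,t_c$, where the
respective approximations are good to better than 1%.
`fit_rise_exponent()` (log–log least squares) returns 1 and 1/2 on the
pure regimes and a value strictly between on windows straddling $t_c$ —
the "between $t$ and $t^{1/2}$" signature of measured penetration curves.
Surface tension 0.072 N/m and contact angle 0 (complete wetting on
glass/PDMS) are defaults, not measurements, and are overridable.

## The separation statistic

The headline statistic is built in three steps, each a separate function
so every link can be tested against an exact fixture:

1. **Separation.** $D(t) = |S_1(t) - S_2(t)|$; the absolute value removes
   any bias toward one channel. Samples with $D$ below a floor
   $\varepsilon$ are masked: at crossings $\log D$ diverges, and
   sub-resolution separations are noise. The floor defaults to one pixel
   of the synthetic rendering (25 µm); for real data it should be the
   spatial resolution of the tracking.
2. **Local exponent.** The exponent $\lambda$ in $D(t) = e^{\lambda t}$
   is estimated locally, because any single choice of $t$ in
   $\log D(t)/t$ is arbitrary: over every fully valid centred window of
   7 samples a degree-4 polynomial is least-squares fitted to $\log D$
   (a Savitzky–Golay sliding-window differentiator) and its derivative at
   the centre, divided by the sample spacing, is the local exponent.
   Truncated edge windows are *not* used — exponents exist only at
   full-window centres — which keeps the window-count law exact (a fully
   valid series of length $N$ yields exactly $N - 6$ exponents) and
   avoids asymmetric bias where the front starts and stops. Window and
   degree are parameters with defaults (7, 4).
3. **Summary.** A run is summarized by the 75th percentile of its local
   exponents (linear interpolation between order statistics — stated
   explicitly because quantile conventions differ), capturing the fastest
   separation phases. Whether to use all exponents or only positive ones
   is genuinely open; the default uses all values, and
   `positive_only = TRUE` covers the other reading.

Summaries are computed per experiment first and only then compared across
conditions (`lambda_trend()`, ordinary least squares of $\lambda_{75}$
against head or amplitude); raw exponents are never pooled across runs.
The chain is exact in exact arithmetic: for noiseless
$D = D_0 e^{\lambda_0 t}$ it returns $\lambda_0$ to $10^{-9}$ relative
for every admissible window, which the suite asserts for
$\lambda_0 \in \{0.01, 0.1, 1\}\ \mathrm{s}^{-1}$.

## The stochastic dual-channel simulator

The simulator stands in for the physical experiments. Each front advances
by Darcy's law through the remaining air column,

$$\frac{dS_i}{dt} = \frac{h_i(S_i)^2}{12\mu}\;
  \frac{P_i(S_i)}{L - S_i + L_{\mathrm{ref}}}\;\xi_i(t),$$

with $h_i(x) = h_0 + A\sin(2\pi x/\lambda_w + \phi)$ the local wall
profile (unconstricted inside the three inter-segment gaps),
$h^2/(12\mu)$ the parallel-plate mobility, and
$L_{\mathrm{ref}} = 14$ mm — the hydraulic length of the rectangular head
the channels discharge into — regularizing the endpoint so the velocity
stays finite at arrival. The $1/(L - S)$ factor is the instability
mechanism: a leading front sees a shorter air column, so it accelerates,
and any small lead grows exponentially. This is assertable directly: with
noise off and a small initial offset in straight channels, $D(t)$ grows
monotonically.

**Driving pressure.** $P_i = \rho g \Delta H$ by default. We considered
and rejected two alternatives. Adding the full front capillary suction
$2\sigma\cos\theta/h_i(S_i)$ introduces a $\approx 192$ Pa constant that
is common to both channels and to all heads; it merely compresses the
relative contrast between heads (1.14 cm versus 1.33 cm drops from 17%
to 6%) and contradicts the budget argument above, under which static
capillary jumps at the two menisci cancel. Keeping only the wavy-wall
*modulation* $2\sigma\cos\theta\,(1/h_i - 1/h_0)$ is more defensible
physically, but its gradient scales as $1/\Delta H$ relative to the
driving, making the separation exponent nearly independent of head —
again contrary to the observed phenomenology of faster separation at
larger pressure drops. With pure head driving, every rate in the system
is proportional to $\Delta H$, and waviness acts through the mobility
$h(S)^2$, whose logarithmic gradient is proportional to $A$. The
modulation term remains available via
`simulation_config(capillary_coupling = )` for exploration; negative net
driving clamps a front rather than retreating it.

**Noise.** Roughness and moulding imperfections are represented by
multiplicative lognormal noise on the velocity, median 1, log-scale
`roughness_sigma`, drawn independently per channel and per output time
step (and held across internal substeps, so the noise process does not
depend on the integrator refinement). Multiplicative noise was chosen
over additive because it cannot make a front retreat. The scale is the
one free parameter of the generator; it was calibrated once, by scanning
$\sigma \in \{0.05, \dots, 0.25\}$ against three phenomenological
requirements — occasional front crossings in straight-channel runs,
persistent separation at high amplitude, and per-run exponent counts in
the 150–300 band — together with the requirement that 20-replicate
ensembles resolve the mean-$\lambda_{75}$ ordering across heads and
amplitudes. $\sigma = 0.05$ and $0.10$ both satisfied all four;
$\sigma = 0.10$ is the default for its stronger crossing phenomenology.

**Sampling.** The output interval defaults to 1/230 of the expected
traverse time of the run's head (computed from the separable closed form
of the straight noiseless channel), emulating an experimenter choosing a
recording frame rate per run. This keeps each run's exponent count near
the 150–300 per-experiment band across all heads, which a fixed interval
cannot do, since traverse time scales as $1/\Delta H$. A fixed
`time_step` can be supplied instead.

**Numerics.** Fronts advance by explicit midpoint (second-order) substeps
bounded so no substep moves a front more than $\lambda_w/20$, resolving
the wall corrugation. Against the closed-form straight-channel solution
this is accurate to $\sim 2\times10^{-6}$ of the channel length (a
first-order Euler substep at the same bound leaves a $2\times10^{-3}$
relative error, which is why midpoint was adopted). The corrugation
wavelength (1.3 mm, about 30 periods per channel) and the relative wall
phase (0: the two channels are identical, so roughness noise is the only
symmetry breaker) are free parameters not fixed by the experiments; both
are config-overridable. Ensembles derive per-run seeds from a documented
stable hash of (head, amplitude, replicate) and a base seed, so every
grid is exactly reproducible and cells are independent.

## Rendering and tracking

`render_frames()` draws each time sample as a top-view grayscale frame:
channel interiors bounded by the wavy silhouette, dry interior light, wet
interior ($x < S_i$) dark, PDMS background light. `track_fronts()`
inverts this: rows of a per-channel ROI are averaged into an intensity
profile, normalized per frame to guard against illumination drift, and
the front is the largest column crossing a 0.5 threshold, refined to
sub-pixel by linear interpolation (parabolic refinement was rejected as
needless for a 1-pixel contract). Featureless frames are classified by
their absolute level (fully dry reads 0, fully wet reads the channel
length); frames that lose the front carry the previous position forward
and are flagged, with more than 20% flagged frames a hard failure. A
width-3 running median then removes single-frame outliers, and fronts are
made monotone by a running maximum, since a physical front cannot
retreat. The round-trip contract — track(render(trace)) within one pixel
of the truth, uniformly over frames and for every amplitude preset — is
the only validation the tracker has, and is asserted in the suite; the
ROI/threshold scheme has not been exercised against real video.

## What the synthetic data do and do not show

The generator reproduces the *structure* of the experiments: paired
monotone displacement traces on a uniform grid, head- and
amplitude-dependent separation statistics with run-to-run variability,
occasional crossings, and image stacks consistent with the traces. It
does not reproduce absolute traverse times (21–140 s in the physical
channels, set by unmeasured hydraulic resistances that the desk-scale
model deliberately omits) nor the numerical values of experimental
$\lambda_{75}$, and fronts are scalar positions — there is no
Saffman–Taylor fingering morphology, droplet breakup, or meniscus shape.
Passing trend tests therefore demonstrates that the analysis chain
recovers the qualitative physics from data with this structure, not that
the simulator is a quantitative model of any particular channel.

## Problem sizes

The test suite and acceptance script use 20 replicates per condition cell
(3 heads at $A = 0.188$ mm; 4 amplitudes at $\Delta H = 1.33$ cm), runs
of roughly 180–280 samples each, rendering at 50 µm per pixel with every
8th sample rendered, and capillary-rise grids of a few hundred points.
These sizes were chosen so each property is measured well away from its
decision boundary while a full run of the suite stays comfortable on a
single CPU.
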