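---
title: "The runtumble model: from a signalling cascade to population accumulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The runtumble model: from a signalling cascade to population accumulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(runtumble)
```

`runtumble` is an agent-based simulator of *Escherichia coli* chemotaxis.
Each simulated cell carries a deterministic model of its intracellular
signalling cascade; stochasticity enters only through initial conditions and
the per-step run/tumble decision. This vignette explains the model layer by
layer, the choices behind every default, and what the package's tests do and
do not demonstrate.

## The five-stage loop

Time advances in steps of `dt = 0.0144` s (50,000 steps make a ~12-minute
experiment). Each step, every cell:

1. reads the ligand concentration(s) at its current position;
2. integrates its signalling cascade over `dt` with those concentrations
   frozen (quasi-static ligand: the cell moves much less than a gradient
   length scale per step);
3. converts its CheY-P level to a clockwise (tumble) bias;
4. draws a uniform number `r` and tumbles exactly when `bias > r`
   (ties run); a tumble rotates the heading by a random angle, a run leaves
   it unchanged; either way the cell then translates at the swim speed for
   the full step;
5. has its position corrected by the boundary rule (solid clamp by default,
   periodic wrap optionally).

## Ligand fields

Fields are static, immutable functions of position: no diffusion,
degradation, or consumption (MeAsp is non-metabolisable; serine consumption
is neglected on the experiment's timescale). The exponential hump

$$[L](x, y) = s\,\bigl(l_0 + e^{-((x-c_x)^2 + (y-c_y)^2)/d}\bigr)$$

has peak $s\,(l_0 + 1)$ at its center; `d` controls steepness (10 shallow, 1
intermediate, 0.1 steep) and the scaling `s` plays the role of the MeAsp and
serine multipliers (`omega`, `upsilon`) in the two-attractant arena, where
the MeAsp hump is centred at $(-1, 0)$ and the serine hump at $(1, 0)$.

## The signalling cascade

Receptors are modelled as mixed Monod–Wyman–Changeux signalling teams of
`n_cluster = 24` dimer units, 9 Tar (MeAsp-binding) and 15 Tsr
(serine-binding) — a team size in the range inferred for adapted receptor
clusters, with the Tsr-heavy composition reflecting the measured Tsr:Tar
abundance ratio. The team is active with probability
$\Phi = 1/(1 + e^{F})$, where

$$F = n\Bigl[f_m(m) + a_{\mathrm{Tar}}
      \ln\frac{1 + [L_a]/K_\mathrm{off}^\mathrm{Tar}}
              {1 + [L_a]/K_\mathrm{on}^\mathrm{Tar}}
      + a_{\mathrm{Tsr}}
      \ln\frac{1 + [L_s]/K_\mathrm{off}^\mathrm{Tsr}}
              {1 + [L_s]/K_\mathrm{on}^\mathrm{Tsr}}\Bigr],
\qquad f_m(m) = 1 - 0.5\,m .$$

Dissociation constants are `K_tar = 0.02/0.5` mM (MeAsp on Tar) and
`K_tsr = 0.001/1.0` mM (serine on Tsr; micromolar inactive-state affinity,
as measured for serine sensing). The low-affinity binding of MeAsp to Tsr is
neglected, appropriate at the concentrations simulated. The methylation
level is clamped to `[0, 10]`; at a clamp boundary an outward `dm/dt` is
zeroed.

Activity drives four ordinary differential equations (concentrations in uM,
totals written `[X]_T`):

$$\begin{aligned}
\dot m   &= k_R [R]_T (1-\Phi) - k_B B_p \Phi\\
\dot A_p &= k_A \Phi ([A]_T - A_p) - k_y A_p ([Y]_T - Y_p)
            - k_b A_p ([B]_T - B_p)\\
\dot Y_p &= k_y A_p ([Y]_T - Y_p) - k_z [Z]_T Y_p - \gamma_Y Y_p\\
\dot B_p &= k_b A_p ([B]_T - B_p) - \gamma_B B_p
\end{aligned}$$

CheR methylates inactive receptors and phosphorylated CheB demethylates
active ones. Because the `m`-nullcline fixes the steady activity $\Phi^*$
independently of the ambient ligand level, the pathway adapts perfectly:
after any step the phosphorylated concentrations return exactly to their
pre-step values (only `m` shifts), as long as `m` stays inside its range.
Both a CheZ-mediated (`k_z`) and a spontaneous (`gamma_Y`)
dephosphorylation route are provided; either can be zeroed.

### The default parameter set

No single published constant set pins down this model family, so the
package ships its own set, fully replaceable through configuration (every
coefficient is a config key; see `load_config()`):

| quantity | value | why |
|---|---|---|
| totals A, B, R, Y, Z | 5, 2, 0.3, 9.7, 1.1 uM | literature-scale copy numbers |
| `k_A` | 16 /s | sub-second kinase excitation |
| `k_y`, `k_b` | 5, 1.5 /(uM s) | fast phosphotransfer |
| `k_z`, `g_Y`, `g_B` | 5 /(uM s), 0.1 /s, 1 /s | CheY-P lifetime ~0.2 s |
| `k_R`, `k_B` | 0.2, 0.10070 /(uM s) | see below |

`k_R` and `k_B` were calibrated once, jointly, so that the unstimulated
steady state at the 0.1 mM MeAsp background gives the reference CheY-P
level $[Y_p]^* = 4.043$ uM and an adaptation time of ~8 s at `beta = 1` for
a 0.1 to 0.2 mM step (the known seconds-scale of *E. coli* adaptation).
These two anchors fix the ratio and the magnitude of the pair; nothing else
was adjusted afterwards.

Cell-to-cell variation in protein expression is modelled by multiplying all
five totals by a common factor `beta`
(`scale_protein_totals()`); operon structure keeps the ratios of the
chemotaxis proteins approximately constant, which is why one scalar
suffices. Across the ladder `beta = 1/4 ... 10` the model yields strictly
monotone single-cell read-outs: the steady phosphorylated fractions and the
adaptation time decrease with `beta`, and the step-response amplitude (in
uM) increases, saturating. The direction of the amplitude trend is a
structural property of this four-equation cascade — the steady CheY-P
concentration is an increasing, saturating function of `beta` for any
positive rate set — so parameter sets with a different internal structure
can reverse it; the package treats monotonicity itself as the model
invariant.

## Motor and kinematics

CheY-P sets the clockwise bias through the sigmoid

$$\mathrm{Bias} = \frac{1}{1 + 3.7\,([Y_p]^*/[Y_p])^{5.5}},$$

where $[Y_p]^*$ is the cell's own unstimulated steady-state CheY-P — so
every cell has unstimulated bias $1/4.7 \approx 0.21$ and the curve shifts
with each cell's protein content. The printed form of this law is
typographically ambiguous in its source material; this orientation is the
only one that is increasing in CheY-P with a plausible unstimulated bias
(the alternative readings give a decreasing curve or a bias of ~5e-4).
Both constants are configurable.

Runs move the cell by $(c\sin\theta, c\cos\theta)\,dt$ (heading measured
clockwise from +y, forced by that component convention); tumbles first add
a turning angle of random sign, uniform on 18–98 degrees (mean absolute
turn 58 degrees), then translate for the full step — tumbles are brief in
reality, so they are folded into one reorient-and-move step rather than
given a duration of their own. After a solid-wall clamp the heading is left
unchanged (the next tumble re-randomises it); this is the minimal rule
consistent with a clamp-to-boundary wall.

### Units: the one genuinely open choice

The swim speed is quoted in um/s (29), but the domain $[-2,2]^2$ carries no
stated physical size. The package fixes one domain unit = 0.2 mm (an
800 um arena, `kinematic_spec(domain_unit_mm=)`), chosen so that the
*unstimulated* run-and-tumble walk — 29 um/s with ~70 ms runs, diffusivity
$D \approx v^2\tau_p/2$ — explores the whole domain within the 12-minute
experiment ($\sqrt{4DT} \approx$ the domain half-width). This is the
largest arena in which population accumulation can equilibrate on that
timescale; with a millimetre-per-unit reading, cells would move ~0.3 mm in
12 minutes and no parameter set could produce the reference behaviour
(equilibrated accumulation at the peak). The choice is exposed in
configuration and affects only the um/s-to-domain-unit conversion.

## Population experiments and read-outs

`run_beta_sweep()` simulates one mixed-`beta` population per gradient
steepness and reports the final mean distance to the peak per
subpopulation: fast adapters (large `beta`) terminate runs quickly and
localise tightly in steep gradients; slow adapters (`beta = 1/4`) respond
sluggishly everywhere and behave almost identically across gradients.
`run_two_ligand_grid()` crosses MeAsp and serine scalings, classifies each
cell by the sign of its final `x` (threshold 0, the midpoint between the
peaks at -1 and +1 — a threshold at `x = 1` would sit on one peak, which we
take to be a typographical slip in one source description; the threshold is
configurable), and `hill_fit()` summarises attraction against `upsilon`
with a least-squares Hill curve, multi-started over a log-spaced grid of
`K` because the scalings span five decades.

```{r example, eval = FALSE}
cfg <- preset_config("fig7_steep", seed = 1)
sweep <- run_beta_sweep(cfg, d = c(10, 1, 0.1))
sweep$summary
```

## Numerical choices

* **Inside the ABM loop** the cascade is advanced by classic fixed-step
  RK4 with the ligand term frozen; the substep count per cell is chosen
  from an upper bound on the fastest linearised rate of its `beta`-scaled
  cascade (`h * lambda <= 0.5`), so stiff large-`beta` cells take more
  substeps (1–2 at `beta <= 1`, ~16 at `beta = 10`). State bounds
  (`0 <= X_p <= [X]_T`, the methylation range) are clamped after every
  substep.
* **Outside the loop** (`integrate_cascade()`, `step_response()`) the
  stiff-capable adaptive `deSolve::lsoda` is used with `rtol 1e-8`; the
  test suite checks one engine step against a 100x-finer RK4 reference to
  1e-6 relative.
* **Steady states** are computed by integrating ten times the slowest
  configured timescale and Newton-polishing to an absolute derivative
  tolerance of 1e-9. Population initialisation exploits perfect
  adaptation: the steady state is solved once per `beta` and shifted to
  each cell's local concentrations in closed form (the methylation level is
  linear in the ligand log-occupancy terms).
* **Random numbers**: one PCG32 stream per cell, derived from the master
  seed, consumed in a fixed order (3 initialisation draws, then per step:
  decision; on tumbles, sign and angle). The pure-R reference engine
  consumes the identical streams, and the suite checks the two engines
  produce identical trajectories; `rng_uniforms()` exposes the streams.
* **Adaptation time** is read off the CheY-P trajectory as the first
  return, after the post-step extremum, to within 10% of the gap between
  extremum and final level; a zero-amplitude step returns 0.
* **Sensitivity** $S = -\partial\ln\Phi/\partial\ln[L]$ is a central
  difference on the log axis at the locally adapted methylation level.

## What the tests show — and what they do not

The simulated conditions mirror the reference experiments but at reduced
scale, the package's own choice to keep the default suite fast: the
protein-scaling sweep uses 20 cells per `beta` over 10,000 steps (~2.4
simulated minutes) and three seeds, and the two-attractant ladder uses 20
cells over the full 50,000 steps at three `upsilon` values. At these sizes
the qualitative orderings (steep-gradient separation by `beta`, the rise of
serine attraction with `upsilon`) are stable across seeds, but individual
mean distances carry sampling noise of order 0.1 domain units, and 2.4
minutes is far from the equilibrated 12-minute state — the full-scale
presets (`fig7_*`, 100 cells, 50,000 steps) remain a few minutes' work on
one core.

The generator emulates: uniform initial positions and headings, pre-adapted
cells (each cell starts at the cascade steady state for its local
concentration; a `background`-adapted switch exists, and matters only for
transients shorter than an adaptation time), static fields, and a constant
swim speed (the measured spread, 29 +/- 6 um/s, is available as optional
per-cell jitter, off by default because speed variation convolves with the
protein-scaling effect under study). It does not emulate: rotational
diffusion during runs, tumble durations, cell growth/division, ligand
consumption, cell–cell interactions, three-dimensional swimming, or
stochastic chemical kinetics in the cascade. Passing tests therefore
demonstrate the internal consistency of this model and the robustness of
its population-level orderings — not quantitative agreement with any wet
experiment.

## Known limitations

* The default cascade is a calibrated stand-in with the canonical
  four-state structure; quantitative read-outs (e.g. the exact `upsilon`
  crossover of the serine/MeAsp competition) shift with the receptor
  constants, and the step-response amplitude trend with `beta` is
  structure-dependent (see above).
* The per-step Bernoulli motor model yields ~70 ms unstimulated runs —
  shorter than measured run durations; the bias curve, not the run-length
  distribution, is the calibrated object.
* Solid walls clamp position but preserve heading, so cells can slide
  along walls between tumbles; with strong gradients near a boundary this
  mildly inflates wall occupancy.
* Methylation clamping means very large steps (far outside the sensitive
  range of both receptor arms) are not perfectly adapted.
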