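---
title: "Modeling global methylation dynamics across the maternal-to-zygotic transition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling global methylation dynamics across the maternal-to-zygotic transition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mztdyn)
library(dplyr)
```

## The model

`mztdyn` simulates how the genome-wide DNA-methylation level of an embryo
changes from fertilization to gamete formation in a species with separate
sexes, and how that level is transmitted — and perturbed — across
generations. The simulation is deterministic and discrete in time: one
step is one cell division.

Three mutually exclusive CpG states are tracked as genome-wide
proportions: homomethylated $X$ (both strands methylated), hemimethylated
$Y$ (one strand) and unmethylated $Z$, with $X + Y + Z = 1$. Each division
applies three sub-steps in order:

1. **Replication** (semiconservative): $X \to 0$, $Y \to X + Y/2$,
   $Z \to Z + Y/2$. Replication alone is a demethylating force.
2. **Repair / maintenance**: hemimethylated sites are re-methylated at
   rate $\alpha$ or demethylated at rate $\rho_c\,\delta$; unmethylated
   sites gain de novo methylation at rate $\beta$:
   $X' = \alpha Y + \beta Z$, $Y' = (1 - \alpha - \rho_c\delta)Y$,
   $Z' = (1-\beta)Z + \rho_c\delta Y$.
3. **Active demethylation**: $X' = (1-\zeta)X$, $Z' = Z + \zeta X$.

Each sub-step is a linear redistribution of mass, so the total is
conserved exactly; the suite checks this to $10^{-12}$ on random states.

The developmental clock is set by embryo growth. The cell count follows
discrete logistic growth $N \leftarrow N + \mu N (1 - N/K)$ with realized
rate $\mu = (1 + \rho)r$: a maternally/paternally loaded repressor $\rho$
doubles the earliest division rate when $\rho_0 = 1$ and decays
geometrically, $\rho \leftarrow (1 - \rho_{deg})\rho$. The
nucleocytoplasmic ratio is $\nu = 1/N$ under a conserved embryo volume.
Zygotic genome activation (ZGA) is modeled as a smooth switch of each rate
from its pre-ZGA to its post-ZGA value along a logistic in the repressor
ratio, with midpoint where $\rho_{power}\,\rho_0/\rho = 1/\nu_t$. Pre-ZGA
rates are pinned at perfect maintenance ($\alpha_0 = 1$, $\beta_0 =
\delta_0 = \zeta_0 = 0$), which holds the methylation level $X + Y$ exactly
constant through cleavage; post-ZGA rates are sex-specific and define the
gametic target level.

A generation is $D$ divisions; at its end, fertilization averages the two
parental compositions component-wise into the next zygote, the embryo
resets ($N$ to $N_0$, $\rho$ to $\rho_0$), and — optionally — the post-ZGA
$\alpha$ and $\delta$ of either or both sexes drift by uniform draws from
configured intervals, modeling environmental variation carried through
the gametes.

## Default parameterization

The canonical scenario (`scenario_preset("table1_default")`) uses
$D = 250$, $r = 0.1$, $K = 1024$, $\rho_0 = 1$, $\rho_{deg} = 0.1$,
$\rho_{power} = 1$, $\nu_t = 0.01$, transition slope $Q = 100$ for all
four rates, zygotes starting fully homomethylated, and post-ZGA rates
$\alpha_1 = 0.99$, $\delta_1 = 0.01$, $\zeta_1 = 0$ with $\beta_1 = 0.04$
(male) and $\beta_1 = 0.1$ (female). With $\zeta = 0$ and
$\alpha + \delta = 1$ the per-division map collapses the hemimethylated
pool every division and the equilibrium is the closed form

$$X^* = \frac{\beta}{1 - \alpha + \beta},$$

giving 0.80 and 0.909 for the two sexes — the gametic methylation levels
reported for zebrafish oocytes and sperm. The `"human"` (0.54 / 0.48) and
`"hypothetical_low"` (0.30) presets pin $\beta_1$ by inverting that
relation at the same $\alpha_1, \delta_1$.

```{r}
fixed_point(0.99, 0.04, 0.01)
sim <- run_simulation(scenario_preset("table1_default"))
summarize_simulation(sim)
```

## Numerical and design choices

Several points are under-determined by the verbal description of the
process; the package resolves them as follows.

* **Order within a division.** The repressor effect $\rho_c$ and the four
  instantaneous rates are evaluated from $\rho$ (and $\nu$) *entering* the
  division; the three methylation sub-steps are applied; only then are
  $N$ and $\rho$ advanced. Methylation at division $d$ thus depends on
  the division-$d$ repressor, matching the way the recurrences are
  indexed.
* **Logistic saturation.** At a generation start the transition exponent
  is $\approx Q(1/\nu_t - 1) = 9900$ at defaults, which overflows a naive
  exponential. The argument is clamped to $\pm 700$, so rates saturate to
  their pre/post values instead of producing `Inf`.
* **No repressor loaded ($\rho_0 = 0$).** The repressor ratio is
  undefined, so the switch falls back to the nucleocytoplasmic trigger
  itself: pre-ZGA rates while $\nu > \nu_t$, post-ZGA once
  $\nu \le \nu_t$. This preserves the ratio-threshold reading of ZGA when
  the repressor-based trigger has no meaning.
* **Real-valued cell counts.** Growth is a deterministic mean-field
  recurrence; $N$ is not rounded. The zygote starts at $N_0 = 1$, so
  $\nu$ starts at 1 and crosses $\nu_t = 0.01$ at 100 cells.
* **ZGA onset** is operationalized as the first division whose entering
  repressor satisfies $\rho_{power}\rho_0/\rho \ge 1/\nu_t$ — the
  logistic midpoint. At defaults ($\rho = 0.9^{d-1}$) this is division
  45 of every generation.
* **Equilibrium detection.** `divisions_to_equilibrium()` reports the
  first division at which $X$ enters, and thereafter stays within, a
  half-width `tol` band around a target level. Levels are reported at an
  accuracy of 0.01 throughout, so the canonical target is the fixed point
  rounded to two decimals with `tol = 0.005` — the division at which the
  trajectory's level *rounds* to the equilibrium. Under that rule the
  default two-generation run settles at divisions 67 (level 0.91) and 91
  (level 0.80) of generation 2, i.e. 22 and 46 divisions after ZGA
  onset. Using the unrounded fixed point as the target instead shifts
  the faster sex to division 65; the rounded-target rule is the one that
  corresponds to levels reported at two decimals.
* **Rate-space exploration.** `explore_parameter_space()` evaluates
  equilibria analytically on the $(\alpha, \beta, \delta)$ grid (with
  $\zeta = 0$, late-development $\rho_c = 1$) by solving the stationarity
  conditions of the affine per-division map, rather than by simulation;
  settling times are then simulated only for retained triples, from a
  standard zygotic level of 0.854545 (the two-generation averaged zygote
  of the canonical run; configurable). The degenerate neutral map
  $\alpha = 1, \beta = \delta = 0$, whose equilibrium is not unique, is
  never retained.
* **Environmental drift** applies only to post-ZGA $\alpha$ and $\delta$
  (pre-ZGA rates are structurally fixed to keep the cleavage plateau).
  By default perturbations accumulate across generations (a random walk
  on the current rates); `env_model(accumulate = FALSE)` instead draws
  around the fixed base rates each generation. Draws that would leave the
  feasible set ($\alpha + \delta \le 1$ after clamping to $[0,1]$) are
  redrawn, up to 100 times, to avoid the bias silent clamping would
  introduce. A `"directional"` mode applies a constant per-generation
  shift whose magnitude is a configuration value.
* **Fertilization timing** is gated on completing the $D$ divisions of
  the generation; triggering it at methylation equilibrium instead is a
  straightforward variant but is not the default.

## What the simulator does and does not capture

The model is mean-field and deterministic: it describes average
genome-wide proportions, not per-cell or per-locus stochasticity, and a
fixed-seed run reproduces bit-identical trajectories. Passing tests
therefore demonstrate the internal consistency of the kinetic scheme —
conservation, convergence to the analytic equilibria, trigger timing —
not agreement with any particular methylome data set. Locus-resolved
dynamics, enzyme kinetics, selection on methylation states, and inference
of rates from bisulfite data are out of scope.

Two quantitative limitations are worth knowing. First, generations
approach their steady transgenerational cycle geometrically rather than
reaching it: with the default male kinetics the contraction per
generation is $(\alpha-\beta)^{D - \text{onset}} \approx 3\times10^{-5}$,
so successive generation records differ at the $10^{-6}$–$10^{-10}$
level rather than being identical. Second, and for the same reason, when
only one sex's rates drift the other sex's *final* level is constant
only to about $3\times10^{-5}$ times the drift of the shared zygote
(order $10^{-6}$ at defaults) — its rates and equilibrium, however, are
exactly untouched, which is the sense in which transmission of
environmental effects is sex-specific ("cis").

## Problem sizes used in the test suite

The suite runs the canonical $2 \times 250$-division scenario in full,
ten-generation runs for drift experiments, $10^4$ random states for the
conservation property, $10^3$ random rate draws for the
closed-form-versus-simulation check, and explorer grids at steps 0.05
(with settling times) and 0.01–0.02 (equilibria only) — sizes at which
every check is exact or converged while the whole suite stays fast on a
single core.
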