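---
title: "Methods: branching-process analysis of abortive and clonogenic colonies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: branching-process analysis of abortive and clonogenic colonies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gwcolony)
```

## The model and its assumptions

`gwcolony` treats the progeny of one plated cell as a synchronized binary
Galton–Watson branching process. At each generation $g$ a proliferative
cell undergoes reproductive cell death (RCD) with probability $P_1(g)$, or
divides into two generation-$g{+}1$ daughters with probability
$1 - P_1(g)$. RCD cells persist physically (they are counted in the colony
size) but never divide again. A colony is *abortive* when every lineage
has died; its final size $n$ then corresponds to a full binary tree with
$n$ leaves (RCD events) and $n-1$ internal nodes (divisions).

The model's assumptions, all deliberate simplifications of real colony
growth, are:

* **synchrony** — all cells divide on a common clock (one doubling time),
  with no cell-cycle variability;
* **symmetry** — divisions always yield two daughters of the next
  generation, both subject to the same $P_1(g)$;
* **generation dependence only** — the death probability depends on the
  number of divisions since plating, not on time, position, or colony
  size (the lattice simulator adds the spatial constraint back in);
* **independence** — all fate draws are independent across cells.

For constant $P_1 = p$ the abortive size law has the Catalan closed form
$f_n = C_{n-1} p^n (1-p)^{n-1}$ (the number of binary tree shapes with $n$
leaves times the probability of each), with total abortive mass
$\min(1, p/(1-p))$. `pmf_constant()` evaluates this in log space so large
$n$ neither overflows nor underflows. For a schedule, `pmf_schedule()`
uses the size-convolution recursion
$q_g(n) = P_1(g)[n{=}1] + (1-P_1(g)) \sum_k q_{g+1}(k)\, q_{g+1}(n-k)$.

### Tail semantics of a finite schedule

A schedule stores $P_1(g)$ only up to a horizon $g_{\max}$ (default 16,
matching the $\le 16$ divisions possible in a 13-day assay at a 20 h
doubling time). Two interpretations of "beyond the horizon" are
implemented:

* `tail = "constant"` (default): $P_1$ stays at $P_1(g_{\max})$
  indefinitely. The level-$g_{\max}$ distribution is then exactly the
  constant-$p$ closed form, so the recursion is exact at every size, a
  constant schedule reproduces `pmf_constant()` identically, and the total
  abortive mass converges to the Galton–Watson extinction probability.
* `tail = "truncate"`: lineages still proliferative at the horizon are
  scored as non-abortive and contribute no mass, mimicking colonies fixed
  at a finite assay time.

Constant continuation is the default because the truncated total is
dominated by horizon effects near criticality: a critical lineage
($P_1 = 0.5$) survives to generation $g$ with probability $\sim 2/g$, so
at $g_{\max} = 30$ about 6.5% of the abortive mass has not yet resolved.
All closed-form identities used for validation (and `survivor_mass()`,
computed from the extinction fixed point
$x_g = P_1(g) + (1-P_1(g)) x_{g+1}^2$ anchored at $\min(1, p/(1-p))$)
assume the constant continuation. The truncated variant remains available
for matching fixed-time scoring exactly.

## Estimating the 1-cell class

Single cells are not scored experimentally. Under the tree model
$f_1 = p$ and $f_2 = (1-p)p^2$ share the same first-generation $p$, so the
1-cell frequency is recovered from the 2-cell class as a root of
$(1-p)p^2 = f_2$. The cubic has two roots in $[0,1]$ merging at $p = 2/3$
(where $f_2$ peaks at $4/27$); `estimate_f1_from_f2()` reports both and
selects the smaller by default, consistent with observed 1-cell
frequencies well below 50%. An `f2` above $4/27$ is a model violation and
is rejected rather than clamped.

## Regression smoothing

Both families are ordinary least squares on base-10 log frequencies:
`log_linear` ($\log_{10} y = a n + b$, exponential decay) and `log_log`
($\log_{10} y = a \log_{10} n + b$, power-law decay). Base 10 matches the
decadic plotting convention under which the published slope/intercept
values for such data are quoted. The AIC is the least-squares form
$N \ln(\mathrm{RSS}/N) + 2K$ with $K = 3$; the inferred 1-cell point may
enter the fit but never the AIC, which compares families on observed data
only (absolute AIC values therefore depend on $N$ and on this convention;
only differences within one observation set are meaningful, and
`aic_compare()` refuses to compare fits over different point sets).
Confidence limits are mean-response bands from the $t$ distribution with
$N-2$ degrees of freedom, back-transformed; prediction bands are not
distinguished because the downstream use is smoothing, not forecasting.

A caution established by the package's own test suite: for constant $P_1$
the log-linear fit of $f_2..f_{15}$ is only approximately linear —
$R^2$ falls to 0.92 at $P_1 = 0.5$, where the size law is the pure power
$n^{-3/2}$, and rises to ${\sim}0.97$ toward $P_1 = 0.3$ or $0.7$. Visual
linearity on a log plot is a weaker statement than any fixed $R^2$
threshold.

## Inverting for P1(g)

`invert_p1()` matches the branching model to the smoothed frequencies on
sizes 1–15, solving for the schedule head $P_1(0..5)$ with the tail held
constant at $P_1(5)$ during inversion. Sizes above 15 are too sparse in
abortive-colony data to constrain deeper generations; $P_1(5)$ itself is
informed only by the largest classes and is flagged as high-uncertainty.

Design choices that were genuinely open:

* **joint vs sequential.** The default solves all six probabilities
  jointly by box-constrained least squares on $\log_{10}$ frequencies (15
  equations, 6 unknowns) — it uses all the information and degrades
  gracefully when the data are not exactly model-consistent. A
  `"sequential"` mode (solve $f_1$ for $P_1(0)$, then $f_2$ for $P_1(1)$,
  ...) is provided; on model-consistent data the two agree.
* **parameterization.** The optimizer works on the logit scale (BFGS with
  a Nelder–Mead polish), which enforces $[0,1]$ smoothly and avoids
  box-boundary line-search failures.
* **normalization.** Smoothed frequencies are treated as percentages of
  *all* colonies (including the inferred 1-cell class) and divided by 100;
  the resulting sub-probability needs no renormalization because the
  model's abortive mass is itself below 1. This is configurable
  (`normalize = "none"`).
* **uncertainty propagation.** 95% limits are obtained by re-running the
  inversion on the lower and upper confidence-limit curves of the
  regression band — the construction mirrors how dotted-limit curves are
  propagated graphically — rather than by bootstrap, which would add
  sampling machinery without data to resample.
* **excess sign.** The radiation-induced excess is defined as irradiated
  minus unirradiated, so that a dose that increases RCD gives positive
  excess; limits combine by interval arithmetic.

Round-trip behaviour (verified in the test suite at 50,000 sampled
colonies): heads in $[0.05, 0.6]$ are recovered within $\pm 0.02$ for
$g \le 3$ and $\pm 0.05$ for $g = 4, 5$ from noiseless frequencies; the
full generate–fit–invert pipeline, which adds the log-log smoothing and
the 1-cell inference, recovers within about $\pm 0.04$.

## The tail parameter c

Generations beyond 5 cannot be estimated from abortive sizes $\le 15$, so
the schedule is completed with a one-parameter linear model:
$P_1(g_{\max}) = (1-c) P_1(5)$ with linear interpolation between
generations 5 and $g_{\max}$. $c = 0$ keeps the generation-5 death rate
forever; $c = 1$ lets RCD decay to zero by the horizon. $c$ is the single
knob connecting the abortive distribution to clonogenic survival, and the
package's sensitivity analysis (acceptance suite) shows the surviving
fraction responds to $c$ much more strongly than the 2–15-cell size bins
do.

## The lattice simulator

Clonogenic colonies involve thousands of cells and contact inhibition, so
the analytic model no longer applies; `run_batch()` grows each colony on
a 2D square lattice instead.

| parameter | default | units | rationale |
|---|---|---|---|
| `pitch` | 31.6 | µm | one fibroblast footprint (1,000 µm²) per site |
| `grid_side` | 201 | sites | odd, centre inoculation; a 16-step colony cannot reach the edge |
| `dt_hours` | 20 | h | measured fibroblast doubling time; one step = one doubling |
| `horizon_days` | 13 | days | assay duration; 15.6 doublings, capped at `g_max = 16` steps |
| `p_move` | 0.25 | — | movement exists but its rate is not constrained by the data; see below |
| `rcd_when_blocked` | `FALSE` | — | blocked cells defer their fate; see below |

Rules, in order, per step: every proliferative cell (uniformly random
order, to avoid spatial update bias) with at least one free 8-neighbour
draws a fate — RCD with probability $P_1(g)$, which is absorbing, or
division, placing one daughter on a uniformly random free neighbour.
Both the stationary and the placed daughter carry generation $g+1$,
matching the lineage-tree semantics in which the internal node *is* the
division. A cell with no free neighbour is contact-inhibited: by default
it draws no fate at all that step, because fates are tied to doublings
and a blocked cell does not double (set `rcd_when_blocked = TRUE` to let
blocked cells still die). After the division phase, every cell with a
free neighbour relocates to one with probability `p_move`.

The movement rate is the one simulator parameter fixed by judgement
rather than measurement: `p_move = 0.25` gives visible rearrangement
without turning colonies into gas. Because small colonies (where the
analytic cross-check applies) have free space everywhere, the size
distribution of colonies up to ~8 cells is insensitive to `p_move`, and
the test suite verifies the simulator against the Catalan law there.

Determinism: all randomness flows through R's RNG; `run_batch()` derives
one seed per simulation set from the master seed, so any result is
bit-reproducible from `(inputs, seed, config)`.

## Synthetic data generator

`generate_synthetic_counts()` emulates the *structure* of scored assay
data: `n_colonies` plated cells, sizes drawn either multinomially from
the analytic pmf (sizes 1–49, all remaining mass — large abortive
colonies plus surviving clones — pooled in the `n = 50` clonogenic class)
or from full lattice runs. Frequencies are percentages of all plated
colonies. The generator reproduces the sampling noise of a
50,000-colony experiment, which is what the estimation pipeline is
validated against.

It does **not** emulate: plating-efficiency variation between dishes,
colony merging or miscounting at high density, dose–response structure
(each table is generated from one schedule), or scorer truncation
effects. Passing tests therefore demonstrate statistical correctness of
the method under the branching model's own sampling assumptions, not
robustness to those experimental artefacts.

## Numerical choices

* Catalan probabilities via `lchoose` in log space; self-convolutions via
  FFT (`stats::convolve`) with negative round-off clamped at zero.
* The deep-horizon validation sums the pmf to $n = 10^6$: near
  criticality the size law tail is $\sim n^{-3/2}/(2\sqrt{\pi})$, so the
  unsummed mass at $10^6$ is below $6\times10^{-4}$, inside the $10^{-3}$
  check tolerance.
* Flat data (zero log-variance) take the $R^2 = 0$ convention.
* Exact AIC ties select the first family in caller order and are flagged.
* SQD bins with zero observed frequency are an error unless the caller
  opts into skipping them; the chi-square test treats simulated
  proportions as fixed (simulation totals are ~50× the observed counts)
  with `bins - 1` degrees of freedom.

## Problem sizes used in validation

The shipped test suite runs, per execution: the tree-enumeration oracle
to size 7; 10,000-inoculum lattice batches at three constant $P_1$ values
for the analytic cross-check; a 50,000-colony generate–fit–invert
recovery; and 2,000-inoculum batches for the $c$-sensitivity contrast.
These sizes were chosen as the smallest that keep Monte Carlo error well
inside the assertion tolerances (binomial standard errors enter the
checks explicitly).

## Known limitations

* The branching process is synchronous and symmetric; cell-cycle
  dispersion, asymmetric division and time-dependent (rather than
  generation-dependent) death are out of scope.
* $P_1(4)$ and especially $P_1(5)$ are weakly identified from sizes
  $\le 15$; treat their confidence limits as optimistic.
* The lattice is 2D (appropriate for monolayer fibroblast colonies) with
  one cell per site and no mechanics; colony shapes are diffusion-like
  rather than mechanically realistic.
* Dose enters only through the estimated schedules; the package fits no
  dose–response model (no LQ/target-theory fitting).
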