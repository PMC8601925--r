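---
title: "Methods: two-locus hitchhiking with recurrent beneficial mutation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-locus hitchhiking with recurrent beneficial mutation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hitchsweep)
```

## The model and its assumptions

The package implements a diploid two-locus, two-allele model with additive
fitness. Locus 1 carries alleles `A`/`a` and is the *linked* site whose
variation we track; locus 2 carries `B`/`b`, where `B` is strongly
beneficial (selection coefficient `s2 > 0`). The four gametes
`AB, aB, Ab, ab` have frequencies `x1..x4`. Forces, all per generation and
all assumed small:

* additive selection: `s1` (signed) at locus 1, `s2` at locus 2, with
  `|s1|` assumed much smaller than `s2` (a warning is emitted otherwise);
* mutation: two-way at locus 1 (`mu_A`: `a -> A`, `mu_Abar`: `A -> a`),
  one-way at locus 2 (`mu_B`: `b -> B`). Back mutation `B -> b` is fixed at
  zero by construction so that the beneficial allele fixes at the end of a
  sweep; constructing parameters with `mu_Bbar != 0` is an error rather
  than a silent reinterpretation of the dynamics;
* recombination at fraction `r`, acting only through the linkage
  disequilibrium `D = x1 x4 - x2 x3`.

Since the selection terms enter as marginal-fitness excesses, the gamete
rates sum to zero exactly; `x4` is therefore never integrated
independently but defined as `1 - x1 - x2 - x3`, which keeps the simplex
constraint exact in floating point.

The analysis coordinates are `x = x1 + x2` (frequency of `B`),
`p1 = x1 / x` and `p2 = x3 / (1 - x)` (frequency of `A` on the `B` and `b`
backgrounds). This chart is singular at `x = 0` and `x = 1`; all
transformed-coordinate operations reject `x <= 1e-12` or
`x >= 1 - 1e-12`. The transformed system is the *exact* image of the
gamete system — no approximation is introduced by the coordinate change —
and the test suite verifies the equivalence of the two right-hand sides to
below `1e-10` over a thousand random states and parameter sets. This
check also settles how the typeset equations group their factors: the
admissible reading is the one in which `(1 - x)` multiplies the whole
bracket of the `dx/dt` equation,

```
dx/dt = [ (s1 (p1 - p2) + s2) x + mu_B ] (1 - x) .
```

The deterministic treatment is valid only above a threshold frequency
`x0`; by default `x0 = 5 / alpha` with `alpha = 2 N s2`, the standard
convention for where a sweep trajectory leaves the drift-dominated zone.
Below `x0` the package switches to diffusion moments (see below).

## Closed-form regimes and their accuracy

`integrate_sweep()` handles the general model with an adaptive solver
(`lsoda`-family with root finding, `rtol = 1e-10`, `atol = 1e-12` by
default; the solver switches to a stiff method on its own if needed,
although with all rates far below one the problem is non-stiff in
practice). Integration stops by event detection when `x` reaches
`stop_at_x`; if the cap is reached first, a `sweep_incomplete` condition
carrying the partial trajectory is raised. The closed forms refuse
parameters outside their stated regime instead of extrapolating silently.

**Recurrent mutation only** (`r = 0`, `mu_A = mu_Abar = 0`, `s1 = 0`):
the background difference obeys
`p1 - p2 = C (s2 x + mu_B) / x` with
`C = x0 (p10 - p20) / (s2 x0 + mu_B)`, `p2` is constant, and
`x(t) = (K e^{gamma t} - mu_B) / (s2 + K e^{gamma t})` with
`gamma = s2 + mu_B`, `K = (s2 x0 + mu_B)/(1 - x0)`. These solve their
ODEs exactly; the suite checks them against `rtol = 1e-12` integration at
the `1e-8` level. With `p10 = p20` the ratio `x1/x` is constant through
the entire sweep: once the initial phase has fixed the background
composition, mutation no longer matters.

**Mutation plus recombination** (`s1 = 0`, `mu_A = mu_Abar = 0`): with
`rho = r / (s2 + mu_B)`,
`p1 - p2 = C~ (1 - x)^rho (s2 x + mu_B)^{1 - rho} / x` is again an exact
solution. The accompanying
`p2 ~ p20 - r C~ [log(1 - x) - log(1 - x0)]` is first order in `rho`
(measured error `4e-6` at `rho = 1e-3`, `4e-4` at `rho = 1e-2`, well
inside the `5 rho` documentation band); a warning fires when
`rho > 0.1`. The integration constant is retained so that `p2(x0) = p20`
holds exactly; the conventional form without it is recovered as
`x0 -> 0`.

**Mutation–selection balance at the linked locus** (`mu_B = 0`,
`mu_A > 0`, `s1 < 0`): allele `A` is deleterious and starts at its
equilibrium frequency. The printed equilibrium `mu_A / s1` is implemented
as `p20 = mu_A / |s1|` — a frequency cannot be negative — and the sweep
starts from `p10 = 0` (the beneficial mutation lands on an `a` chromosome
with high probability since `p20` is small). The closed forms for
`x(tau)`, `p1 - p2` and `p1` assume `|s1|, r << s2` *and* replace the
logistic factor `(1 - x(tau))` by a constant in the recombination-influx
integral. That second replacement is the dominant error: when
`(mu_A + r) tau_hat << 1` the true influx integrates `(1 - x)` over the
sweep, which by logistic symmetry contributes about half of the constant
approximation, so the closed-form `p1(tau_hat)` overshoots by roughly half
the recombination term. Measured against full integration at
`s2 = 0.05`, `s1 = -0.001`, `r = 5e-4`, `mu_A = 1e-5` the relative error
in `p1(tau_hat)` is 17%, and it is *not* reduced by halving `|s1|` and `r`
jointly — the relative weight `r/(|s1| + r)` of the offending term is
scale-invariant. The error does vanish as `r -> 0` (0.1% at `r = 0`) and
shrinks when `|s1|/s2` grows at fixed `r`. For this reason the numeric
mode of `het_ratio_after_sweep()` (direct integration plus
`H = 2p(1 - p)`) is authoritative whenever the two modes disagree; the
closed form is provided as the interpretable reconstruction

```
H(tau_hat)/H(0) ~ (1 - X) + r/(mu_A + r) * X * (1 - Y),
X = exp(s1 tau_hat),  Y = exp(-(mu_A + r) tau_hat),
```

the unique parse of the flattened printed expression that is consistent
with the `p1(tau)` solution evaluated at `tau_hat` and with the headline
inequality below. In the neutral limit it collapses to the classical
`1 - x0^{2r/s2}`.

**Sweep duration.** Both the printed logistic-symmetry form
`tau_hat = -(2/s2) log x0` (default) and the exact
`(2/s2) log((1 - x0)/x0)` are available; they differ by `O(x0)` and the
choice is a `form` argument everywhere it matters.

**Headline property.** Across `r` in {0, 1e-4, 1e-3, 1e-2} at
`s2 = 0.01`, `x0 = 0.005`, the numerically computed heterozygosity ratio
with purifying selection (`s1 = -0.001`, `p20 = 0.01`) is at least the
neutral ratio at the same `r` — mutation keeps restoring the deleterious
allele and purifying selection anchors its equilibrium, so the relative
sweep signature is weaker than for a neutral polymorphism. The ratio is
monotone non-decreasing in `r` and approaches 1 for `r >> s2`.

## The stochastic initial phase

Below `x0` the frequency of `B` is treated by a diffusion with drift
`alpha z + theta/2` and diffusion coefficient `z`, in time units of `2N`
generations (`alpha = 2 N s2`, `theta = 4 N mu_B`). Only the first two
moments are used — the moment hierarchy closes because both coefficients
are linear in `z` — and no attempt is made to solve for the density
itself; the Wright–Fisher simulator supplies distributional checks
instead. The closed moments are

```
m1(t) = theta/(2 alpha) (e^{alpha t} - 1),   var(t) = m1(t)^2 / theta,
```

so the coefficient of variation is `1/sqrt(theta)` — about 7 for
`theta = 0.02`. The initial phase is *strongly* stochastic even though its
mean is simple; every consumer of these moments carries that caveat.

For the `AB` gamete the mutational input is thinned by the decaying `A`
background, `sigma(t) = x3* exp(-m1(t))`, giving
`m1_x1(t) = x3* m1(t)` under an integrand approximation that is accurate
for `t <= 2 tbar0` in the intended range (`alpha > 100`,
`theta > 0.005`); outside the window a warning is attached. Numerical
integration of the exact moment ODEs agrees with the closed `x` moments to
`1e-12` and with the approximate `x1` moments to 0.02% inside the window.

`tbar0 = (1/alpha) log(1 + 2 alpha x0 / theta)` inverts the mean
trajectory exactly (`m1(tbar0) = x0` to machine precision). The
deterministic phase is then started at `t0 = 2N tbar0` generations — the
single place where the `2N` conversion happens; every trajectory carries
an explicit `time_scale` tag — with `p10 = p20 = x3*`, the frequency of
`A` at the onset of selection. The predicted coefficient of variation of
`p10`, `sqrt(1/(theta x3*))`, is attached to the initial conditions: the
moment prediction of `p10` is poor in any single population, which is
exactly why `sampled_init` mode exists. That mode draws one Wright–Fisher
path and hands the state at the *first generation* with `x >= x0` to the
integrator — no sub-generation interpolation is invented; the overshoot is
recorded instead.

### What the mean-trajectory time is, and is not

`tbar0` is the time at which the *unconditional mean* of the diffusion
reaches `x0`. It is not a mean first-passage time, and for small `theta`
the two differ by an order of magnitude: the mean is carried by the small
fraction of populations in which an establishing mutation appeared early,
while the typical population is still waiting (the waiting time for an
establishing mutation is roughly `1/(2 N mu_B * 2 s2)` generations, about
1000 for `N = 5000`, `s2 = 0.05`, `mu_B = 1e-6`, versus
`2N tbar0 = 124`). The package therefore exposes both quantities —
`mean_time_to_threshold()` for the mean-trajectory prediction and
`hitting_times()` for the simulated first-passage ensemble — and the
acceptance checks report the measured ratio rather than pretending the
two coincide. For the same reason the closed moments track the
Wright–Fisher ensemble tightly at `tbar0/2` but overpredict the variance
at `tbar0`, where the rare early-established paths have already left the
linear regime and saturate; the linear-drift diffusion has no such
ceiling.

## The Wright–Fisher simulator

One generation applies the full deterministic right-hand side as an Euler
step (selection, mutation and recombination jointly — the rates in scope
are at most a few percent, so operator-splitting differences are second
order), clips to the simplex, and resamples `2N` gametes multinomially.
Expected frequencies leaving the simplex by more than `1e-6` raise an
error: that indicates rates too large for the one-generation Euler life
cycle rather than a state to be silently repaired. The engine is validated
independently of any sweep theory by the classical neutral checks: the
one-generation sampling variance `x(1-x)/(2N)` and the per-generation
heterozygosity decay factor `1 - 1/(2N)` over a drift ensemble.

Sweep bookkeeping: the hitting time is the first generation with
`x >= x0`, completion the first generation with `x >= 1 - x0` (matching
`tau_hat`, and avoiding the long neutral tail to absolute fixation), and
at completion the outcome is classified `multiple_origin_soft` if both
`x1 > epsilon` and `x2 > epsilon` (default `epsilon = 0.05`, the
conventional 5% detection threshold, configurable), `hard` if exactly one
background exceeds it. With two backgrounds there are exactly two origin
classes, so no infinite-alleles bookkeeping is needed.

Randomness: a seed is mandatory in every `sim_config`; replicate
substreams are derived deterministically from `(seed, replicate index)`,
so `(seed, config)` fully determines every output, bit for bit.

`softness_scan()` varies `kappa = mu_B / s2` through `mu_B` at fixed `s2`
(so `theta` co-varies with `kappa`, as it must when the mutation rate is
the moving part), and a second axis varies `s2` at fixed `mu_B`. The two
axes behave differently, and deliberately so: the soft-sweep proportion
rises steeply along the `kappa`/`theta` axis (measured 0.03 / 0.22 / 0.84
at `kappa` = 5e-5 / 5e-4 / 5e-3, `N = 2000`, `s2 = 0.05`, 500
replicates), while along the `s2` axis at fixed `mu_B` it is close to flat
(~0.22 across `s2` = 0.02–0.1). Under sweep-end classification the clock
that brings the second origin and the clock that ends the sweep both scale
with `s2`, so the scaled mutation supply `theta` is what decides softness;
a strong negative `s2` effect appears in protocols that census at a fixed
generation rather than at sweep completion, which this package does not
emulate.

## Numerical and design choices

* Solver tolerances default to `rtol = 1e-10`, `atol = 1e-12`
  (`1e-12`/`1e-14` in oracle comparisons); event detection by root
  finding, never by grid inspection.
* `p1`, `p2` are clamped to `[0, 1]` at solver-roundoff level after
  integration; trajectories are tabulated with derived columns
  (`D`, `p_A`, `H`) and written as TSV at 10 significant digits.
* Boundary guard `1e-12` on `x` for all transformed-coordinate
  operations; `to_haplo` refuses states with `x1 + x2` at 0 or 1.
* The `kappa = 0` control in scans needs a starting beneficial copy to
  produce any sweeps; classification can then only be `hard` — the
  simulator enforces that no second origin class can appear without
  mutation.
* Problem sizes used by the test suite and acceptance script — a
  thousand random states for the equivalence property, twenty parameter
  draws for the closed-form oracle, 2000 Wright–Fisher replicates at
  `N = 5000` for the diffusion comparison, and 500 replicates per grid
  point for the scans — were chosen so that Monte-Carlo error is small
  against the effects being measured while a full run completes in a few
  minutes on one CPU.

## What the simulator does and does not emulate

The Wright–Fisher engine generates the study conditions themselves
(constant `N`, non-overlapping generations, multinomial resampling, the
stated mutation scheme); it makes no attempt to model demography,
dominance, haploid or fluctuating effective sizes, more than two loci, or
an infinite-alleles mutation structure. Passing tests therefore show that
the analytical results describe *this* model faithfully at the stated
parameter ranges — not that real populations satisfy them; in data,
demography and background selection can mimic or mask every signature
discussed here.

## Known limitations

* The case-3 closed forms carry an irreducible error of order half the
  recombination term (see above); use the numeric mode for quantitative
  work with `r > 0`.
* The diffusion moments describe the unconditional law of the initial
  phase; they are not conditioned on eventual sweep and their variance is
  only trustworthy while the linear regime holds (`t` up to about
  `tbar0/2` for small `theta`).
* The `x1` moment formulas inherit the `t <= 2 tbar0` window; beyond it
  they are flagged, not fixed.
* Fixation probabilities, competing-sweep (traffic) dynamics and
  coalescent signatures of sweeps are out of scope.
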