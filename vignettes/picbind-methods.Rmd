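---
title: "Models and methods behind picbind"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind picbind}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(picbind)
```

# The binding network

The assays this package analyzes probe a three-component system: 40S
ribosomal subunits saturated with eIF1 and eIF1A (denoted R), the
eIF2•GTP•Met-tRNA_i ternary complex (T, carrying the radiolabel), and eIF3
(E). Four reversible steps connect them:

* T + R ⇌ RT, dissociation constant `K1` — TC binding the PIC without eIF3;
* E + RT ⇌ RTE, `K2` — eIF3 binding the 43S PIC;
* T + RE ⇌ RTE, `K3` — TC binding the 40S•eIF3 complex;
* E + R ⇌ RE, `K4` — eIF3 binding the free 40S subunit.

Because the two routes from (R, T, E) to the ternary species RTE must release
the same free energy, the cycle closes: `K1·K2 = K3·K4`. No direct
measurement of eIF3 binding to the free subunit exists in this assay format,
so `K4` is *defined* by closure (`derive_fourth_constant()`), and
`equilibrium_constants()` refuses constant sets that violate it beyond 1e-9
relative. All concentrations are nM and all times minutes throughout, matching
how these experiments are designed and reported.

# The equilibrium solver

`solve_equilibrium()` computes the unique non-negative species state for
given totals. Writing `t = T_free`, `e = E_free`, the free-R concentration is
eliminated exactly through R's conservation law,

```
r(t, e) = R_total / (1 + t/K1 + e/K4 + t·e/(K1·K2)),
```

leaving two residual equations (conservation of T and of E) in two unknowns.
Each residual is strictly monotone in its own variable with guaranteed sign
changes at the ends of `[0, T_total]` and `[0, E_total]`, so a solution
always exists in the box and nested bisection is unconditionally convergent.
The implementation first runs a damped Newton iteration (finite-difference
Jacobian, step halving, iterates clamped to the box; iteration cap 200) and
falls back to nested bisection whenever Newton fails to reach tolerance;
non-convergence after the fallback raises an error carrying the residuals
rather than returning silently. Convergence is declared at residuals below
1e-10 relative to each component's total — several orders below measurement
noise, and tight enough that round-trip tests at 1e-8 pass with margin. The
complex concentrations are reconstructed from mass action (`RT = r·t/K1`
etc.), so the four equilibrium relations hold to machine rounding by
construction.

Mixtures with a zero total are not sent through the general solver: they
collapse analytically to at most one two-species reaction, whose bound
complex is the stable small root `2ab/(s + sqrt(s² − 4ab))`, `s = a + b + K`,
of the usual quadratic. This avoids spurious divisions and documents the
limiting cases the tests rely on.

The solver is validated against an independently written nested-bisection
oracle on random instances, and by exchange symmetry: relabelling T↔E with
K1↔K4, K2↔K3 maps solutions onto each other.

# The free-eIF3 correction

At 30 nM 40S — at or below `K1` — much of the 40S pool is free and competes
for eIF3, so total eIF3 overstates the free concentration. All
tracer-containing species are resolved on the gel, which makes the
eIF3-containing species reconstructable lane by lane:

* `RTE = frac_43S_eIF3 · T_total` (measured directly),
* `T_free = frac_free · T_total` (measured directly),
* `RE = K3 · RTE / T_free` (mass action of T + RE ⇌ RTE, using the
  separately measured `K3` of that variant),
* `E_free = E_total − RTE − RE`.

`correct_titration()` applies this per lane and the resulting curve of
supershift fraction against free eIF3 is what the isotherms are fit to. The
correctness property is exact inversion: for band fractions produced by the
equilibrium model with the same `K3`, the recovered `E_free` equals the
solver's to solver tolerance. When `K3` is misspecified the error is largest
in the first lanes and decays to nothing as eIF3 exceeds everything it can
bind, which is why the titrations extend well past the 40S capacity.

With noisy fractions the subtraction can go slightly negative in early
lanes; such lanes are floored at zero and *flagged*, never silently dropped,
so replicate structure stays intact and the issue is visible in the run log.

For 40S titrations of TC binding no correction is applied: the tracer is at
1–2 nM, at least five-fold below the smallest dissociation constant fit, so
total 40S stands in for free 40S. This tracer-limit approximation
contributes under +1 nM of bias at the constants of interest (visible in the
noiseless recovery tests) and is documented rather than corrected.

# Isotherm fitting, model choice, censoring

Binding curves are fit by bounded Levenberg–Marquardt least squares
(`minpack.lm::nlsLM`) with five deterministic starts, K log-spaced across the
observed x range. A fixed start grid was chosen over randomized jitter so a
fit is a pure function of its inputs; five starts are ample for
two/three-parameter isotherms. Parameters and bounds:

* amplitude `A ∈ [0, 1.05]` — free, not pinned to 1, because endpoints are
  condition-dependent and themselves reported; the 5% headroom absorbs
  quantification slack;
* `K ∈ [x_min/10, x_max·10]` — an estimate pinned at either bound means the
  curve contains no affinity information (saturated or flat) and is returned
  as a *fit failure*, not a number;
* Hill coefficient `n ∈ [0.5, 6]`, reported in the half-saturation
  parameterization so `K_app` is directly in nM.

`compare_isotherms()` selects between Langmuir (2 parameters) and Hill (3) by
AICc computed from residual sums of squares — an explicit, automatable
criterion where visual comparison would otherwise be used; a failed Langmuir
fit auto-selects Hill. The Hill model with `n` fixed at 1 reproduces the
Langmuir fit exactly (nesting), which the tests assert to 1e-9 in rss.

Censoring implements the assay-resolution caveat: when the fitted apparent
K_D is at or below the limiting 40S concentration (30 nM in the standard
design; boundary inclusive), the titration is essentially stoichiometric and
the fit measures the capacity of the reaction, not the affinity. Such values
are flagged `censored` with the limit recorded and are reported as upper
limits. On the *total*-eIF3 axis the apparent K_D of a much-tighter-than-30 nM
interaction concentrates near half the 40S concentration — the quantitative
form of the caveat — while on the corrected free-eIF3 axis it is smaller
still; both behaviours are asserted in tests.

One bias deserves explicit statement. The corrected curve's response is the
supershift fraction `RTE/T_total`. When `K1 > K3` (eIF3 stabilizes TC
binding), rising eIF3 also recruits additional TC into the PIC, so the
curve's amplitude grows along the titration and its half-saturation point
sits systematically above the true `K2` — this is part of why these apparent
affinities are "apparent". When `K1 = K3` (no coupling) the supershift
fraction is exactly `f·e/(K2+e)` and the apparent K_D is unbiased. Recovery
scoring in the test suite therefore generates its ground-truth bundles in
the uncoupled regime; analyses of coupled systems should read `K_app` as an
apparent, upper-bounded quantity, exactly as the censoring machinery
assumes.

Replicates are always fit individually and summarized as mean ± SEM
(sample SD/√n) by `aggregate_replicates()`; curves are never pooled into one
fit, and a single replicate reports its SEM as undefined rather than zero.

# Recruitment kinetics

`fit_single_exponential()` fits `y(t) = A·(1 − e^(−kt))` with the intercept
fixed at zero: recruitment reactions are initiated by simultaneous addition
of mRNA and ATP, so there is no burst phase to model, and the single
exponential is the stated rate law of the assay. Fits are unweighted least
squares (no weighting scheme is defined for these quantifications) with the
same deterministic multi-start policy (six rate starts spanning
`0.05/t_max` to `10/t_min`).

A reaction complete before the first quenched sample carries no rate
information. The operational rule: if the fitted curve at the earliest
positive time point already exceeds 90% of the fitted amplitude
(`k·t₁ > ln 10`), the fit returns `rate_resolved = FALSE`; the endpoint is
still reported but the rate is not, and `rate_ratio()` refuses unresolved
inputs, directing the caller to report a bound instead. The 90% threshold is
a package choice: it cleanly separates, at typical first samples of
15–30 s, rates around the fastest measurable (~0.2 s⁻¹) from those the
assay resolves.

Endpoint-only designs (reactions run 2 h to completion) bypass the kinetic
model entirely: `extent_at_completion()` aggregates terminal fractions as
mean ± SEM.

# The synthetic-data generator

`simulate_titration()` and `simulate_timecourse()` generate exactly the
tables the readers consume. Band fractions come from the equilibrium solver
(or the exponential law) at the design's true parameters; noise is additive
Gaussian per band fraction, clipped to [0, 1] and renormalized to the lane's
pre-noise total — emulating that phosphorimager lane quantifications are
normalized shares of a lane's signal. Defaults are the standard assay
designs: eIF3 titrated 30–500 nM (7 log-spaced points) into 30 nM 40S with
2 nM tracer TC; 40S titrated 10–320 nM in two-fold steps against 1 nM
tracer; time courses of 8 log-spaced points within 120 min; two replicates.
The default `sigma = 0.02` on band fractions was chosen once to make
replicate SEMs comparable in scale to those reported for such assays; it is
a free knob of the generator, not a fitted quantity.

Reproducibility contract: one master seed expands into per-replicate
substreams (`seed + 7919·i`, reduced mod 2³¹), so generation is
bit-reproducible, replicates differ only by their noise stream, and
conditions in a `variant_panel()` get disjoint streams. What the generator
does *not* emulate: gel-cage dissociation during electrophoresis, correlated
lane artifacts, pipetting error on totals, and counting statistics — so
passing recovery tests demonstrate correctness of the estimators under the
stated noise model, not robustness to every failure mode of real gels.

# Pipeline and problem sizes

The `run_*` functions orchestrate the stages over delimited tables with a
single declarative `run_config()`; every threshold (censor limit, recovery
tolerance, noise, seeds, model policy) lives in the config with documented
defaults. Runs are deterministic: identical config and seed give
byte-identical output tables. The run log records every flagged lane, failed
fit and model choice, and each summary value is traceable to per-replicate
rows in the detail table. `run_recover()` scores recovered against true
parameters and passes a condition either on relative error or — when the
truth lies at or below the censor limit — on correct censoring, since an
upper limit cannot be scored as a point estimate.

Validation problem sizes were chosen to keep the full suite under a minute
on one CPU while leaving estimator variance well below the tolerances
asserted: 2000 random mixtures for conservation/nonnegativity, 100 instances
for oracle equivalence, 200–500 simulated curves for the fitting and
kinetics recovery studies, and 8-replicate designs for the headline
parameter-recovery checks.

# Known limitations

* The free-eIF3 correction propagates no uncertainty from `K3` into the
  fitted `K2`; a delta-method extension would be straightforward.
* No global multi-curve (shared-parameter) fitting; replicates are fit
  individually by design, to match how means and SEMs are defined here.
* The Hill coefficient is a descriptive measure of apparent cooperativity;
  no molecular mechanism is implied, and none is fit.
* Kinetics are strictly single-exponential; lag or multi-phase behaviour is
  out of scope and will surface as structured residuals, not as a warning.
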