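---
title: "Methods: thermodynamic life-history optimisation and footprint estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: thermodynamic life-history optimisation and footprint estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermofoot)
```

## The model

`thermofoot` models an ectotherm pest whose juveniles acquire energy
reserves $M$ at a per-unit mortality cost $c$, so that survival to maturity
is $(1-c)^M$. Reserves are allocated with fraction $p$ to catalytic capacity
(enzymes that speed constrained reactions at cold temperature), fraction $q$
to cellular maintenance (molecular chaperones that stabilise proteins at hot
temperature), and the residual $M(1-p-q)$ to growth and reproduction with
allometric exponent $b$:

$$ B = [M(1-p-q)]^b. $$

Productivity follows Arrhenius kinetics with activation energy $E_{a,B}$ and
a rate scale proportional to catalytic allocation, $A_B = a_B\,pM$. Failure
is modelled through reversible two-state protein unfolding: the equilibrium
constant

$$ K_u(T) = \exp\!\big(-\Delta G_u(T)/RT\big), \qquad
   \Delta G_u(T) = \Delta H_m\Big(1-\tfrac{T}{T_m}\Big)
   - \Delta C_p\big[(T_m - T) + T\ln(T/T_m)\big] $$

crosses 1 at the midpoint $T_m$, and the proportion of properly folded
protein is

$$ S(T) = \frac{1}{1 + \dfrac{\kappa_D}{qM}\,K_u(T)}, $$

so maintenance investment $qM$ directly buys stability ($A_D \propto
(qM)^{-1}$). Population growth rate is the product

$$ r'(T) = (1-c)^M \cdot B \cdot a_B\,pM\,e^{-E_{a,B}/RT} \cdot S(T), $$

and the agricultural impact of a strategy is $M\,r'$, per-capita host
consumption being taken proportional to acquired reserves.

This unfolding parameterisation is a declared stand-in for a
temperature-dependent failure activation energy: the exact constants behind
the original graphical illustration of this model family are not published,
so the package exposes a standard, fully configurable two-state
thermodynamic form ($\Delta C_p = 0$ by default, giving a log-linear
stability cliff) and treats the qualitative behaviour of the optimum as the
contract. All proportionality constants are absorbed into `a_B` and
`kappa_D`; outputs are in relative units, and users are expected to read
curves after `relative_response()` scaling.

Acute-cold lethality is deliberately not modelled. Temperatures are degrees
Celsius at every user interface and Kelvin internally.

## Parameters that matter

Defaults ship in `inst/extdata/default_config.json`, not in code:

| parameter | default | units | why |
|---|---|---|---|
| `Ea_B` | 65 000 | J/mol | ≈ 0.67 eV, the canonical metabolic-rate activation energy range |
| `dH_m` | 300 000 | J/mol | unfolding enthalpy of a moderately sized protein; sets cliff steepness |
| `T_m` | 315 | K | midpoint ≈ 42 °C, so failure bites just above the 35 °C hot regime |
| `dCp` | 0 | J/(mol·K) | no curvature by default; configurable |
| `kappa_D` | 5 | — | failure scale before division by $qM$ |
| `c` | 0.1 | — | per-unit acquisition mortality; survival $0.9^M$ |
| `b` | 0.75 | — | the standard metabolic allometric exponent |
| `a_B` | 1 | — | absorbed scale; outputs are relative |

With these defaults the optimised model reproduces, and the test suite
asserts, the qualitative contract: optimal acquisition $M^*$ increases with
temperature (23 < 29 < 35 °C) and decreases with feeding cost $c$;
maintenance $q^*$ at 35 °C exceeds $q^*$ at 29 °C; cheaper feeding widens
thermal niche breadth; hot-adapted strategies outgrow cold-adapted ones at
the hot end of the curve; and the impact curve $M^* r'$ peaks at a
temperature at or above the growth-rate peak (37.5 vs 36 °C on a 0.5 °C
grid).

One deliberate constraint: `M_bounds` defaults to (0.5, 30) — a
physiological cap on reserves. For very cheap feeding ($c \le 0.05$) the
optimum sits on the cap, so $M^*(c)$ has ties at the bound; the
monotonicity contract (non-increasing in $c$) still holds.

## Optimisation

The optimiser maximises $r'$ over $M \in$ `M_bounds`, $p, q \ge 0$,
$p + q \le 1$ in two stages: a simplex-constrained coarse grid (41 points
per axis; lexicographic tie-breaking on $M$, then $p$, then $q$ for
reproducibility), then Nelder–Mead refinement in an unconstrained logistic
reparameterisation, restarted once from its own solution, plus seeded
jittered restarts. Because the logistic map saturates when the optimum sits
on a bound, a final coordinate polish runs golden-section searches on the
natural scale and evaluates the exact interval endpoints. The test suite
checks the result against a dense 201-points-per-axis brute-force grid
(within $10^{-6}$ relative). Boundary strategies ($p = 0$, $q = 0$,
$p + q = 1$) evaluate to $r' = 0$ rather than erroring so the optimiser can
probe them. An all-zero objective returns a flagged non-converged result.

"Adapted populations" are a single strategy frozen at the adaptation
temperature (no plasticity). Thermal niche breadth is the total temperature
span where $r'$ is at least 50% of the curve maximum (the threshold is a
package choice — breadth has no canonical numeric definition), with linear
interpolation at crossings.

## Footprint estimation

Two independent per-line footprint metrics, in mg host per day:

$$ \varphi_1 = C_m\,\omega\,M/d_1, \qquad \varphi_2 = \psi\,C_E/d_2, $$

with $\omega$ lifetime offspring per female, $M$ adult mass at emergence,
$d_1$ egg-to-adult development time, $\psi$ early (16 h) fecundity, $d_2$
the fastest per-dish development time. $C_m$ (mg host per mg beetle,
temperature-specific) is the slope of corrected host loss on beetle mass
produced, regressed through the origin — a dish that produces no beetle
mass consumes essentially nothing; an intercept variant is available behind
a flag since the original treatment is not stated. $C_E$ (mg host per egg)
is a pooled ratio estimator, robust to low-egg dishes.

Two ancestor-relative contrasts are reported by `footprint_estimates()`:

* `rel_phi1`: percent change versus the line's own geographic ancestor at
  29 °C — the common scaling that puts plasticity and evolution on one
  axis. Because $C_m$ itself is temperature-specific, this contrast carries
  the $C_m(T)/C_m(29)$ ratio.
* `evo_rel_phi1`: percent change versus the respective ancestor at the
  *same* assay temperature — the pure evolution effect. Headline statements
  of the form "hot-adapted lines leave an 80% larger footprint at 35 °C"
  are this contrast, and per-generation rates divide it by the number of
  generations elapsed (reported to one decimal).

References are always the line's own geographic ancestor, never a pooled
one.

**Parametric bootstrap.** Each trait is drawn independently from
Normal(mean, SE); the original analysis does not state whether draws were
correlated across traits measured on the same individuals, so independence
is assumed and documented here. Strictly positive traits ($M$, $d_1$) are
floored at $10^{-6}$ of their mean (truncations counted); intervals are
percentile 2.5/97.5; the point estimate is the noise-free plug-in from the
trait means, not the bootstrap mean. Identical seeds give bit-identical
intervals. A coverage simulation in the acceptance suite shows ≥ 93%
empirical coverage of the generating footprint over 1000 replicates.

## Consumption variance decomposition

`lifehistory_variance_explained()` fits ordinary least squares of corrected
host loss on nested predictor sets — eggs; eggs + survivors; eggs +
survivors + adult mass (main effects only) — and returns the three $R^2$
values, which are non-decreasing by construction. Control correction
subtracts the temperature-matched mean beetle-free drift and floors
negative results at zero with a count.

## Expression trade-off analytics

Post-differential-expression only (alignment, count generation and DE
testing are out of scope). `overlap_stats()` gives the independence
expectation $n_A n_B / N$, the 2×2 chi-squared (df = 1, no continuity
correction by default; Yates behind a flag) and the hypergeometric upper
tail. The chi-squared printed in the motivating study (37.5) is not
reproducible from its printed marginals under either standard variant
(41.38 uncorrected, 40.61 Yates, both asserted against
`stats::chisq.test` as oracle); the package computes the standard forms and
documents the discrepancy rather than guessing the original construction.

`classify_directions()` calls a gene antagonistic when its two log-fold
changes have opposite signs, excluding exact zeros with a logged count (tie
handling is unstated upstream), and runs the exact binomial sign test.
Trade-off scores are plain dot products of log-fold changes with the
sample's normalized counts, taken as provided (no internal re-normalization
— upstream TMM-style normalization is out of scope). The trade-off axis is
the leading eigenvector of the centred 2-D score cloud, with sign fixed so
the positive direction loads positively on the heat-stress score (the
maintenance pole), making projections comparable across runs.

## What the synthetic generators emulate — and what they do not

The generators are first-class, tested code, deterministic per seed, and
emit their full parameterisation as metadata. The stated world:

* **Design**: 3 origins × 2 regimes × 2 replicate lines + 3 ancestors,
  assayed at 23/29/35 °C; one expression library per line × temperature and
  two per ancestor (54 libraries).
* **Traits**: truth = baseline(T) × regime multiplier × origin scale, with
  a shared lognormal line-level scale (SD 0.08) on the reproductive traits
  (this shared acquisition variation is what makes $\varphi_1$ and
  $\varphi_2$ correlate, r ≈ 0.9 at the default 5% trait CV), and 5%
  multiplicative noise doubling as the reported SE. The default hot-regime
  bundle at 35 °C multiplies $\omega M/d_1$ by exactly 1.8 (+80% evolution
  contrast) and the cold bundle at 23 °C by exactly 1.076 (+7.6%).
* **Consumption**: eggs are lognormal-overdispersed Poisson (log-SD 0.4) —
  homogeneous dishes would understate the between-dish signal that real
  assays show, and with them the 3-predictor $R^2$ would sit near 0.80
  rather than the ≥ 0.90 the 5%-residual world is supposed to give;
  survivors are Binomial(eggs, 0.85); host loss is
  $C_m(T)\,\times$ survivors × mass + drift + Gaussian residual with SD 5%
  of mean consumption; $C_m$ truth is 3.17/3.66/3.55 at 23/29/35 °C.
  Per-egg consumption is *implied* ($C_m \cdot$ survival $\cdot$ mass), not
  an independent dial, and is reported in generator metadata.
* **Expression**: 21 up-mating/down-heat + 113 down-mating/up-heat
  antagonistic genes + 3 concordant; antagonistic heat responses mirror the
  mating response up to lognormal noise (SD 0.15; 0 gives exact
  antisymmetry and score correlation −1); negative-binomial counts
  (dispersion 0.05) with 35 °C libraries shifted along the heat direction.

Features of real data deliberately not emulated: ancestral plasticity of
the footprint (baselines are chosen so the ancestor's $\omega M/d_1$ is
flat across temperatures, so configured multipliers map exactly onto
ancestor-relative changes; real ancestors show 0–45% plastic reductions
away from 29 °C), trait-trait correlation structure beyond the shared
acquisition scale, library-size variation and batch effects in counts, and
any within-dish individual variation. A green test therefore establishes
that the estimators recover the effects this world encodes at the stated
noise — not that the defaults describe any particular real population.

`generate_model_truth()` bridges the two halves: strategies are optimised
at each regime's evolution temperature and frozen; mass maps linearly to
$M^*$, offspring production to $r'$, development time is constant, with
mapping constants anchored to the ancestor at 29 °C and recorded in
metadata. Under this mapping $\omega M/d_1$ is exactly proportional to the
model impact $M^* r'$, so the footprint pipeline can be run on model-implied
data and checked for internal consistency.

## Numerical choices

* Optimiser tolerance: relative $10^{-8}$ (Nelder–Mead), coordinate polish
  at $10^{-10}$ of the interval; determinism is bit-exact for a fixed
  config and seed.
* Component-product identity of $r'$ holds to $10^{-12}$ relative and is
  property-tested on random inputs.
* $q = 0$ (and $p = 0$) return $r' = 0$, not an error; $K_u$ underflow at
  extreme cold combined with $q = 0$ is guarded explicitly.
* Bootstrap seeds are derived per table row (`seed + i`), keeping any
  derived seed far below $2^{31}$.
* All RNG use goes through a private stream that restores the caller's
  `.Random.seed`.

## Known limitations

* The stability formulation is phenomenological; it does not model enzyme
  populations, oxygen limitation or reactive-oxygen damage, and the
  supplement-level constants of the original model were not available to
  calibrate against.
* Footprint SEs enter through independent Normal draws; correlated trait
  errors would widen or narrow intervals in ways the package cannot know
  from summary tables.
* The variance-decomposition contract (final $R^2 \ge 0.9$) is a property
  of the generator's stated world, not a claim about arbitrary data.
* Trait means/SEs are consumed as given; mixed-model estimation of those
  summaries is out of scope.
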