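---
title: "Volumetric and acoustic thermodynamics of solutes in mixed aqueous solvents"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Volumetric and acoustic thermodynamics of solutes in mixed aqueous solvents}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(solvatherm)
```

## The measurement problem

A vibrating-tube densimeter with an integrated ultrasonic cell measures the
density $\rho$ and speed of sound $u$ of a solution. For a solute A (an
amino acid or small peptide) dissolved at molality $m_A$ in a solvent that
may itself be a mixture (water plus a co-solvent B such as an ionic liquid
at molality $m_B$), two derived per-measurement properties carry the
thermodynamic signal:

* the **apparent molar volume**
  $$V_\phi = \frac{M}{\rho} - \frac{\rho - \rho_0}{m_A\,\rho\,\rho_0},$$
  where $M$ is the solute molar mass and $\rho_0$ the density of the
  *solvent* (the water + co-solvent mixture, measured at $m_A = 0$);

* the **apparent molar isentropic compressibility**
  $$K_{\phi,s} = \frac{M K_s}{\rho} + \frac{K_s \rho_0 - K_{s,0}\,\rho}{m_A\,\rho\,\rho_0},
  \qquad K_s = \frac{1}{u^2 \rho} \;\text{(Newton--Laplace)}.$$

Both formulas are algebraically identical to "total property of the
solution containing 1 kg of solvent, minus the solvent's property, per
mole of solute": $V_\phi = [(1 + m_A M)/\rho - 1/\rho_0]/m_A$ and
$K_{\phi,s} = [(1 + m_A M)K_s/\rho - K_{s,0}/\rho_0]/m_A$. The test suite
pins the implementation to these total-property identities on thousands of
random inputs, which removes any ambiguity between equivalent published
renderings of the defining equations.

The baseline $(\rho_0, u_0)$ of each $(m_B, T)$ group is always the
*measured* $m_A = 0$ row of that group, never a water correlation: in a
ternary design the reference solvent is the co-solvent mixture itself.

## From raw tables to interaction coefficients

The pipeline (`analyze()`) proceeds in the order the quantities are
defined:

1. **Limiting values.** At fixed $(\text{solute}, m_B, T)$ the apparent
   property is close to linear in $m_A$ for zwitterionic non-electrolytes,
   so $Y(m_A) = Y^0 + S\,m_A$ is fitted by least squares
   (`fit_limiting()`); the intercept is the limiting (infinite-dilution)
   value $V^0_\phi$ or $K^0_{\phi,s}$, which isolates solute--solvent
   interactions, and $S$ is the experimental slope carrying solute--solute
   information. The linear (rather than $\sqrt{m_A}$ Masson) form matches
   the single-slope convention of the reference data and the
   non-electrolyte character of amino acids near neutral pH.
2. **Transfer functions.** $\Delta Y^0(m_B) = Y^0(\text{in mixed solvent})
   - Y^0(\text{in water})$ (`transfer_all()`), defined only between
   limiting fits. Positive transfer volumes and compressions signal
   dominant ion--hydrophilic co-sphere overlap.
3. **Temperature dependence.** $V^0_\phi(T) = a + b(T - T_{\rm ref}) +
   c(T - T_{\rm ref})^2$ with $T_{\rm ref} = 298.15$ K
   (`fit_temperature_model()`). The limiting apparent molar expansibility
   is $E^0_\phi = b + 2c(T - T_{\rm ref})$ and its temperature derivative
   is the constant $2c$. **Hepler's criterion** classifies the solute from
   the sign of $2c$: positive means structure-maker (kosmotrope), negative
   structure-breaker. The default classification dead-band is the
   propagated standard error of $2c$, so noise is not over-interpreted.
4. **Pair/triplet coefficients.** The McMillan--Mayer / Friedman--Krishnan
   expansion $\Delta Y^0 = 2\,Y_{AB}\,m_B + 3\,Y_{ABB}\,m_B^2$ is fitted
   with zero intercept (`fit_pair_triplet()`), both coefficients jointly:
   the transfer is identically zero at $m_B = 0$, and the expansion has no
   constant term.

Units are strict SI everywhere inside the package (m$^3$ mol$^{-1}$,
Pa$^{-1}$, mol kg$^{-1}$); the journal scales ($\times 10^6$ m$^3$
mol$^{-1}$, m$^3$ mol$^{-1}$ GPa$^{-1}$) are applied only on input/output
(`si_to_report()`, `report_to_si()`). Mixing scale factors mid-pipeline is
the single most common source of order-of-magnitude errors in this
literature, so the boundary is kept hard.

## Why the reference temperature is 298.15 K

The reference tables shipped with the package do not state $T_{\rm ref}$
explicitly, but it is identifiable from the tables themselves: for every
one of the ten $(\text{solute}, m_B)$ rows, the tabulated expansibility at
298.15 K equals the coefficient $b$ exactly, which happens only when
$T_{\rm ref} = 298.15$ K. The acceptance tests assert this identity row by
row.

Similarly, the published coefficient table prints $|c|$ while the
expansibility trend of the dipeptide at $m_B \le 0.2$ mol kg$^{-1}$
requires $c < 0$; the shipped coefficient table therefore carries signed
$c$, with the sign resolved from the temperature trend of the
corresponding expansibility row, and comparisons against printed
derivative columns are made on magnitudes.

## The error model, and which fit to use when

The instrument's expanded uncertainties (coverage factor 2) are
$\pm 0.1$ kg m$^{-3}$ and $\pm 0.8$ m s$^{-1}$; the package's default
standard uncertainties are half of those, $\sigma_\rho = 0.05$ kg m$^{-3}$
and $\sigma_u = 0.4$ m s$^{-1}$. First-order propagation
(`propagate_uncertainty()`, checked against a finite-difference Jacobian)
gives

$$\sigma_{V_\phi} \approx \frac{(1 + m_A M)}{m_A \rho^2}\,\sigma_\rho
\;\;\propto\; \frac{1}{m_A},$$

with $\rho$--$u$ covariance neglected (none is published for this class of
instrument). Two structural consequences matter for fitting:

* the per-point error of an apparent property grows like $1/m_A$ towards
  infinite dilution, so the points that matter most for the intercept are
  the noisiest; and
* all points of a dilution series share one measured baseline
  $(\rho_0, u_0)$, so their errors are *correlated* through it.

Unweighted OLS (`method = "ols"`, the default) reproduces the conventional
single-slope reporting of published tables, but its standard errors ignore
both effects: in simulation at the instrument noise level its nominal 2-se
intercept interval covers the truth in well under 70% of replicates. For
parameter-recovery and coverage work the package therefore provides
`method = "gls"`, which uses the propagated per-point variances plus the
rank-one (volume) or rank-two (compressibility) shared-baseline covariance
and takes standard errors from $(X^\top \Sigma^{-1} X)^{-1}$ with
$\Sigma$ known. Its 2-se intervals are close to nominal ($\approx 95\%$
coverage in the package's own recovery tests). This is a deliberate design
choice: the default mirrors the field's reporting convention, the GLS
option is the statistically calibrated estimator, and the two must not be
conflated when quoting uncertainties.

## The synthetic-data generator

`generate_dataset()` emulates the study design rather than the instrument
hardware. A `ground_truth()` object fixes:

* the design: 2 solutes, co-solvent molalities 0.00--0.40 mol kg$^{-1}$ in
  steps of 0.10, temperatures 288.15/298.15/308.15/318.15 K, eight solute
  molalities equally spaced in 0.05--0.40 mol kg$^{-1}$;
* true limiting volumes built from the per-solute quadratic temperature
  model in water plus a pair/triplet co-solvent dependence
  $V^0_\phi(m_B,T) = V^0_{\phi,\rm w}(T) + 2 V_{AB} m_B + 3 V_{ABB} m_B^2$,
  so the transfer functions generated downstream obey the interaction
  expansion *exactly* and end-to-end coefficient recovery is well defined;
  limiting compressions are tabulated per temperature with the analogous
  pair/triplet term;
* water-like solvent baselines ($\rho_0 \approx 997$ kg m$^{-3}$,
  $u_0 \approx 1497$ m s$^{-1}$ near 298 K, with mild linear temperature
  and co-solvent trends) stored as constants -- no equation of state is
  embedded, and baselines are never interpolated;
* instrument noise $\sigma_\rho = 0.05$ kg m$^{-3}$,
  $\sigma_u = 0.4$ m s$^{-1}$, applied to baseline rows too.

Generation inverts the defining equations exactly
(`invert_density()`, `invert_sound_speed()`) and then adds Gaussian noise
from per-row substreams keyed by the measurement identity, so one seed
fully determines the table and the output is independent of row iteration
order. In the zero-noise limit the full pipeline is the identity on the
ground truth to better than $10^{-9}$ relative -- the core verification
property of the package.

What the generator does **not** emulate: instrument drift and hysteresis,
temperature-dependent noise, solute-dependent deviations from linear
$Y(m_A)$, and any real-solution curvature beyond the quadratic transfer
expansion. Passing recovery tests therefore demonstrates correctness of
the analysis chain, not the adequacy of the linear/quadratic models for
any particular real system.

## Numerical choices and degenerate inputs

* Limiting fits require $\ge 2$ distinct positive molalities (point
  estimates) and $\ge 3$ for standard errors; a single-molality group is a
  singular design and is reported in the skipped-group table, never
  silently dropped.
* The temperature model requires $\ge 3$ distinct temperatures; duplicated
  temperatures are rejected. With exactly 3 points the residual standard
  deviation has zero degrees of freedom and is flagged `NA` rather than
  reported as 0. Both fit-quality metrics (residual SD with $n-3$ degrees
  of freedom, and mean absolute relative deviation) are computed, because
  published "$\sigma$" columns in this literature are ambiguous between
  the two.
* All group-wise operations sort on their keys first, so results are
  invariant to input row order; result CSVs are written with fixed column
  order and `%.15g` formatting, making repeated runs byte-identical. The
  run manifest records a config hash and the seed, and no timestamps.
* Molar masses default to 0.11912 kg mol$^{-1}$ (l-threonine, C4H9NO3)
  and 0.17617 kg mol$^{-1}$ (glycyl-l-threonine, C6H12N2O4).

## Known limitations

* The published pair/triplet *compressibility* coefficients for these
  systems are not recoverable from the published transfer table under the
  quadratic expansion at the stated scales: refitting yields coefficients
  roughly an order of magnitude smaller (e.g. $\approx 11$ vs a printed
  $113.89$ for the l-threonine pair term at 298.15 K). The package
  documents this internal inconsistency and asserts its stability in a
  test instead of guessing a hidden convention; the volume coefficients
  are affected by the analogous ambiguity and are likewise not treated as
  recovery targets.
* Published standard errors on limiting compressions depend on the raw
  supplementary data and cannot be re-derived from the printed derived
  layer; consistency checks compare central values only.
* Problem sizes in the test suite are chosen for desk-scale verification:
  500-instance property sweeps for the least-squares oracles, 200
  replicates for coverage and Monte-Carlo/SE comparisons, 1000-point
  sweeps for the algebraic identities. These are the package's standard
  verification sizes and complete in well under a minute.

## Reproducing the consistency layer

```{r, eval = FALSE}
v <- validate_consistency(
  coefficients    = ref_temp_coefficients(),
  expansibilities = ref_expansibilities(),
  limiting        = ref_limiting_compressions(),
  transfers       = ref_transfer_compressions()
)
all(v$pass) # TRUE: 82 row-level checks
```
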