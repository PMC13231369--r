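# solvatherm

Volumetric and acoustic thermodynamics of amino acids and small peptides
in water and in mixed aqueous solvents (e.g. aqueous ionic liquids), from
raw vibrating-tube-densimeter tables to interaction coefficients.

Solution chemists probing how a co-solvent reshapes the hydration shell of
a biomolecule measure density ρ and speed of sound *u* of dilution series
and reduce them to a standard ladder of derived quantities. `solvatherm`
implements that ladder as a tested, reusable pipeline:

| stage | quantity | model |
|---|---|---|
| per measurement | apparent molar volume | V<sub>φ</sub> = M/ρ − (ρ − ρ₀)/(m<sub>A</sub> ρ ρ₀) |
| per measurement | apparent molar isentropic compressibility | K<sub>φ,s</sub> = M·K<sub>s</sub>/ρ + (K<sub>s</sub>ρ₀ − K<sub>s,0</sub>ρ)/(m<sub>A</sub> ρ ρ₀), with K<sub>s</sub> = 1/(u²ρ) (Newton–Laplace) |
| per (solute, m<sub>B</sub>, T) | limiting value and experimental slope | Y(m<sub>A</sub>) = Y⁰ + S·m<sub>A</sub>, least squares |
| per (solute, m<sub>B</sub> > 0, T) | transfer function | ΔY⁰ = Y⁰(mixed solvent) − Y⁰(water) |
| per (solute, m<sub>B</sub>) | temperature model, expansibility, Hepler classification | V⁰<sub>φ</sub>(T) = a + b(T − T<sub>ref</sub>) + c(T − T<sub>ref</sub>)², E⁰<sub>φ</sub> = b + 2c(T − T<sub>ref</sub>), sign of 2c |
| per (solute, T) | McMillan–Mayer pair/triplet coefficients | ΔY⁰ = 2Y<sub>AB</sub>m<sub>B</sub> + 3Y<sub>ABB</sub>m<sub>B</sub>² (zero intercept) |

It also ships a seeded synthetic-data generator that inverts the defining
equations exactly, so the whole chain is verifiable by parameter recovery,
plus reference derived-property tables for l-threonine and
glycyl-l-threonine in aqueous 1-octyl-3-methylimidazolium bromide
(288.15–318.15 K) and consistency checkers that re-derive each published
table from the layer beneath it.

Internally everything is strict SI; journal scales (×10⁶ m³ mol⁻¹,
m³ mol⁻¹ GPa⁻¹) are applied only at input/output via `si_to_report()` /
`report_to_si()`.

## Worked example

Simulate a full study at instrument noise (σ<sub>ρ</sub> = 0.05 kg m⁻³,
σ<sub>u</sub> = 0.4 m s⁻¹) and recover the limiting volume of l-threonine
in water at 298.15 K:

```r
library(solvatherm)

truth <- ground_truth()                      # 2 solutes x 5 m_B x 4 T x 8 m_A
dat   <- generate_dataset(truth, seed = 42)  # 340-row measurement table
res   <- analyze(dat)

f <- res$limiting$fits
f[f$solute == "l-threonine" & f$property == "volume" &
  f$T == 298.15 & f$m_B == 0, ]
#>       solute m_B      T property   intercept      slope se_intercept
#>  l-threonine   0 298.15   volume 7.75069e-05 7.8717e-07  2.75732e-07
```

On the reporting scale that is V⁰<sub>φ</sub> = 77.51 (± 0.28) ×10⁻⁶
m³ mol⁻¹ against a generating truth of 77.70: the intercept of the
dilution series, i.e. the solute's partial molar volume at infinite
dilution, recovered within one standard error. `res` also contains the
transfer functions, temperature models with Hepler classifications, and
pair/triplet interaction fits for every group, plus skipped-group reports.

Re-deriving one published table from another (transfer compressions from
limiting compressions):

```r
v <- validate_consistency(limiting  = ref_limiting_compressions(),
                          transfers = ref_transfer_compressions())
head(v[, c("solute", "m_B", "T", "computed", "printed", "pass")], 4)
#>       solute m_B      T computed printed pass
#>  l-threonine 0.1 288.15   8.9569  8.9570 TRUE
#>  l-threonine 0.1 298.15   2.3203  2.3203 TRUE
#>  l-threonine 0.1 308.15   0.3927  0.3927 TRUE
#>  l-threonine 0.1 318.15   0.8405  0.8405 TRUE
all(v$pass)   # TRUE, 32 of 32 cells within print rounding (2e-4)
```

Every computed cell is the difference of two limiting compressions
(in 10⁻⁶ m³ mol⁻¹ GPa⁻¹); positive values mean the solute's hydration
shell becomes more compressible on transfer into the ionic-liquid medium.

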