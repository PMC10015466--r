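# fetiron

Speciation, NMR relaxometry and dissociation kinetics of the
Fe(III)-Tiron system in aqueous solution.

Tiron (4,5-dihydroxy-1,3-benzenedisulfonate) binds Fe³⁺ through its
catecholate oxygens and forms, depending on pH and ligand excess, the
complexes [Fe(Tiron)(H₂O)₄]⁻, [Fe(Tiron)₂(H₂O)₂]⁵⁻ and [Fe(Tiron)₃]⁹⁻.
These high-spin d⁵ species are strong water-proton relaxation agents, which
makes them attractive model systems for iron-based MRI contrast agents —
but their characterization requires combining several techniques whose
analyses share parameters. `fetiron` provides that combined machinery for
R users working in paramagnetic relaxometry and solution coordination
chemistry:

* **Speciation** — a mass-balance equilibrium solver over the species
  L/HL/H₂L, Fe³⁺, FeL, FeL₂, FeL₃ and FeL₂H₋₁, species-distribution
  diagrams, simulation of spectrophotometric and potentiometric titrations,
  and least-squares refinement of the equilibrium constants.
* **Relaxometry** — forward model of the relaxivity r₁(ν, T) as the sum of
  inner-sphere (Solomon–Bloembergen–Morgan), second-sphere and outer-sphere
  (Freed translational diffusion) contributions, with transient-ZFS
  (Bloembergen–Morgan) electron relaxation for S = 5/2 and the standard
  temperature laws.
* **¹⁷O exchange** — Swift–Connick reduced transverse relaxation rates and
  shifts versus temperature, scalar-dominated bound-site relaxation, and an
  exchange-regime classifier.
* **Global fitting** — simultaneous weighted least squares over NMRD
  profiles and ¹⁷O datasets sharing one parameter vector, with bounds,
  deterministic multi-start, fixed-parameter masks and 1σ uncertainties.
* **Kinetics** — mono-exponential trace fitting and the pathway-weighted
  rate law of the CDTA-mediated transchelation,
  k_d = x(FeL₃)·k₀ + x(FeL₂)·(k₁[H⁺] + k₄[H⁺][CDTA]),
  with refinement of the rate constants and half-life prediction.
* **Synthetic data** — seeded generators for every dataset kind, built on
  the forward models, so all fitting routes are testable with known ground
  truth.

The tabulated parameter sets of the Fe(III)-Tiron study (equilibrium
constants, per-complex relaxation parameters, rate constants) ship as
fixtures: `tiron_constants()`, `tiron_relax_params()`, `tiron_o17_params()`,
`tiron_rate_constants()`.

## Worked example

Where is the iron at a given pH, and what relaxivity does a 1:50
Fe:Tiron solution show?

```r
library(fetiron)

distribution_curve(tiron_constants(), 2e-4, 9e-3, c(2, 4.3, 7.4))[, 1:6]
#>    pH     Fe    FeL   FeL2   FeL3 FeL2Hm1
#> 1 2.0 0.0039 0.9957 0.0004 0.0000  0.0000
#> 2 4.3 0.0000 0.0640 0.9354 0.0003  0.0003
#> 3 7.4 0.0000 0.0000 0.0038 0.9949  0.0013
```

The mono complex dominates in acid, the bis complex around pH 4–5, the
tris complex above pH 6.5. The forward relaxivity model with the tabulated
bis-complex parameters gives the component breakdown (mM⁻¹s⁻¹ at 298 K):

```r
total_r1(tiron_relax_params("FeL2"), c(32, 60, 120))
#>   nu_MHz    IS    SS    OS    r1 IS_pct
#> 1     32 2.955 0.712 1.000 4.666   63.3
#> 2     60 3.763 0.710 0.948 5.422   69.4
#> 3    120 4.730 0.762 1.009 6.501   72.8
```

so at 60 MHz the model reproduces the measured 5.4 mM⁻¹s⁻¹ and shows that
the two bound waters carry ~70% of the relaxivity. Combining both modules
predicts the relaxivity-versus-pH profile of the 1:50 solution at 32 MHz
(measured: 3.5 at pH 2, 5.0 at pH 4, ~2.9 above pH 6.5):

```r
r1_ph_profile(tiron_constants(), total_Fe = 1.88e-3, total_L = 94e-3,
              pH = c(2.0, 4.0, 7.4), nu_MHz = 32)[, c("pH", "r1")]
#>    pH    r1
#> 1 2.0 3.469
#> 2 4.0 4.634
#> 3 7.4 2.582
```

How inert is the system near physiological pH?

```r
kd <- observed_kd(tiron_rate_constants(), tiron_constants(),
                  pH = 7.4, total_Fe = 1e-4, total_L = 5e-4, CDTA = 0)
c(kd = kd, t_half_h = half_life(kd))
#>       kd t_half_h
#> 0.000107     1.79
```

A dissociation half-life of ~1.8 h at pH 7.4 — about 37 times more labile
than Fe(EDTA)⁻ under the same conditions.

A thin command-line wrapper over the same functions is installed with the
package (`inst/exec/fetiron`), exposing the tasks `speciate`,
`simulate-nmrd`, `simulate-o17`, `synth-traces`, `fit-global`, `fit-o17`,
`fit-kinetics`, `predict-r1` and `predict-kd`.

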