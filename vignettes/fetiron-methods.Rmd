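---
title: "Models and methods: speciation, relaxometry, 17O exchange and kinetics of Fe(III)-Tiron"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: speciation, relaxometry, 17O exchange and kinetics of Fe(III)-Tiron}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fetiron)
```

# Scope

`fetiron` implements the complete computational chain needed to characterize
the Fe(III)-Tiron system (Tiron = 4,5-dihydroxy-1,3-benzenedisulfonate) in
aqueous solution: equilibrium speciation versus pH, forward modeling and
global fitting of water-proton relaxivity (NMRD) profiles together with
variable-temperature ¹⁷O NMR data, and pseudo-first-order analysis of
CDTA-mediated transchelation kinetics. A synthetic-data generator produces
every dataset type from known ground truth, so each fitting route is testable
end to end without measured data.

This vignette records the models, the conventions, and the design decisions
taken where the choices were genuinely open.

# Speciation model

The solution chemistry is described by eight species: the free ligand forms
L⁴⁻, HL³⁻, H₂L²⁻ (the two protonations occur at the phenolate oxygens;
the sulfonates stay deprotonated), free Fe³⁺, the stepwise complexes FeL,
FeL₂, FeL₃, and the mixed hydroxo complex FeL₂H₋₁ in which one bound water
is replaced by hydroxide. Constants are decadic-log concentration constants
at 0.15 M ionic strength and 25 °C:

* protonation: $K_i^H = [\mathrm{H}_iL]/([\mathrm{H}_{i-1}L][\mathrm{H}^+])$,
  with $\log K_1^H = 12.40$, $\log K_2^H = 7.46$;
* stepwise stability: $K_{\mathrm{FeL}_x} =
  [\mathrm{FeL}_x]/([\mathrm{FeL}_{x-1}][L])$, with logs 20.32, 14.49, 9.83;
* hydroxo species: $K = [\mathrm{FeL}_2]/([\mathrm{FeL}_2\mathrm{H}_{-1}]
  [\mathrm{H}^+])$, $\log K = 7.86$, so the hydroxo form grows above
  pH ≈ 7.9 — the direction consistent with the base-consuming processes
  observed between pH 6 and 9 at low ligand excess.

No activity corrections are applied (the constants are concentration
constants at fixed ionic strength), and no polynuclear or hydrolyzed iron
species beyond the five listed are modeled; distribution diagrams computed
outside roughly pH 0–12, or for iron in large excess over ligand where
Fe(OH)ₓ chemistry would intervene, should therefore be read with care.

## Solving the mass balance

At a stated pH the free hydrogen-ion concentration is fixed
($[\mathrm{H}^+] = 10^{-\mathrm{pH}}$; pH-stat assumption). The two coupled
mass balances in the unknown free concentrations $x = [L^{4-}]$ and
$y = [\mathrm{Fe}^{3+}]$ are reduced exactly to one equation: $y$ is
eliminated analytically from the iron balance,

$$y(x) = \frac{\mathrm{Fe}_t}{1 + \beta_1 x + (\beta_2 + \beta_{OH}) x^2 +
\beta_3 x^3},$$

and the remaining ligand-balance residual is strictly increasing in $x$,
so the root is unique and bracketable. It is found by Brent's method on
$\log_{10} x$ (guaranteeing positivity) with a `tol = 1e-14` bracket and a
final Newton polish; solved states close both mass balances to better than
$10^{-10}$ relative, which the test suite verifies on a totals × pH grid.
This replaces the more common damped two-dimensional Newton iteration:
the 1-D reduction cannot diverge and needs no damping heuristics.

The full proton balance (with $pK_w = 13.77$) is used only when simulating
base-volume titrations, where the titratable proton content
$[\mathrm{H}^+] - [\mathrm{OH}^-] + [\mathrm{HL}] + 2[\mathrm{H}_2L] -
[\mathrm{FeL}_2\mathrm{H}_{-1}]$ is balanced against the added base,
including dilution by the titrant. Electrode readings are emulated as
$\mathrm{pH}_{read} = \mathrm{pH}_{true} + pA$ with $pA = 0.02$ by default.

```{r speciation}
st <- solve_speciation(species_model(),
                       solution_conditions(1.88e-3, 94.0e-3, 4.3))
round(st$fe_fractions, 4)
```

## Constant refinement

`refine_constants()` refines any subset of the equilibrium constants (and
optionally the molar absorptivities) against absorbance-pH and/or
base-volume datasets by Levenberg-Marquardt least squares, reporting
1σ uncertainties from the Jacobian-based covariance at the optimum. A
pseudo-inverse keeps poorly determined directions finite, and a rank check
flags under-determined free sets instead of failing. On noiseless synthetic
data the free constants are recovered to better than $10^{-3}$ log units
(tested); on data with absorbance noise of 0.005 the replicate spread is
consistent with the reported curvature uncertainties (also tested).

# Relaxivity model

The observed relaxivity is the sum of three contributions,
$r_1 = r_1^{IS} + r_1^{SS} + r_1^{OS}$.

**Inner sphere.** $r_1^{IS} = P_m/(T_{1M} + \tau_M)$ with
$P_m = q\,[\mathrm{1\ mM}]/55.6\,\mathrm{M}$. The bound-proton relaxation is
purely dipolar (the scalar contribution to ¹H relaxation is negligible for
these complexes and is omitted):

$$\frac{1}{T_{1M}} = \frac{2}{15}\left(\frac{\mu_0}{4\pi}\right)^2
\frac{\gamma_I^2 g^2 \mu_B^2 S(S+1)}{r^6}
\left[\frac{3\tau_{d1}}{1+\omega_I^2\tau_{d1}^2} +
\frac{7\tau_{d2}}{1+\omega_S^2\tau_{d2}^2}\right],
\qquad \frac{1}{\tau_{di}} = \frac{1}{\tau_R} + \frac{1}{\tau_M} +
\frac{1}{T_{ie}}.$$

**Second sphere.** The same functional form with the second-sphere
parameters ($q^{SS}$, $r^{SS}$, $\tau_R^{SS}$) and a fixed residence time
$\tau_M^{SS} = 1$ ns. The full exchange denominator is kept rather than the
fast-exchange simplification; at 1 ns the two differ by well under 1%.
Electron relaxation enters the second-sphere correlation times exactly as
in the inner sphere.

**Outer sphere.** The Freed hard-sphere translational-diffusion model with
finite electron relaxation,

$$J(\omega, T_{je}) = \mathrm{Re}\frac{1 + z/4}{1 + z + 4z^2/9 + z^3/9},
\qquad z = \sqrt{i\omega\tau_D + \tau_D/T_{je}}, \qquad \tau_D = a^2/D,$$

with $r_1^{OS} \propto [3J(\omega_I, T_{1e}) + 7J(\omega_S, T_{2e})]
/(aD)$ per mM of complex.

**Electron relaxation.** The tabulated parameters are the mean-square
transient zero-field-splitting energy Δ² and its correlation time τ_v.
Several closed forms circulate in the literature; this package adopts the
standard Bloembergen–Morgan/McLachlan transient-ZFS expressions for
S = 5/2:

$$\frac{1}{T_{1e}} = \frac{\Delta^2\tau_v}{25}[4S(S+1)-3]
\left[\frac{1}{1+\omega_S^2\tau_v^2} + \frac{4}{1+4\omega_S^2\tau_v^2}\right],
\qquad
\frac{1}{T_{2e}} = \frac{\Delta^2\tau_v}{50}[4S(S+1)-3]
\left[3 + \frac{5}{1+\omega_S^2\tau_v^2} +
\frac{2}{1+4\omega_S^2\tau_v^2}\right].$$

The two rates coincide at zero field. This choice was validated against the
alternative convention with half these rates: with the tabulated parameter
sets the form above reproduces the printed 60/120 MHz relaxivities of all
three Tiron complexes within ~5%, while the halved-rate convention misses
the bis complex by +15%. The one visible consequence of the remaining
model-form freedom is the low-field split between the second- and
outer-sphere contributions of the tris complex: the package computes a
profile-averaged second-sphere share of ~61% where the original analysis
quotes 65–70%, although the total relaxivities agree closely. Omitting
electron relaxation from the second-sphere correlation time would raise
that share to ~75% but degrades the total-relaxivity agreement, so it was
not adopted.

**Conventions.** Frequencies are proton Larmor frequencies in MHz;
$\omega_I = 2\pi\nu \cdot 10^6$ and $\omega_S = 658.21\,\omega_I$ (the
g-ratio folded once). "298 K" reference values mean 298.15 K everywhere.
The tabulated diffusion coefficient is used as
$D = 2.24\times10^{-5}\ \mathrm{cm^2\,s^{-1}}$, the standard aqueous value
(the positive exponent sometimes seen in print is a typographical slip).
Temperature dependences: correlation times and Δ² follow
$x(T) = x_{298}\exp[E/R(1/T - 1/298.15)]$ (growing on cooling), diffusion
the inverse law, and the water residence time the Eyring form
$k_{ex}(T) = k_{ex}^{298}(T/298.15)\exp[\Delta H_M/R(1/298.15 - 1/T)]$.

```{r relax}
total_r1(tiron_relax_params("FeL2"), c(32, 60, 120))[, c("nu_MHz", "IS", "SS", "OS", "r1")]
```

# ¹⁷O observables

Reduced (per mole fraction of bound water) transverse relaxation rates and
shifts follow the Swift-Connick equations with a scalar-dominated bound-site
relaxation:

$$\frac{1}{T_{2m}} = \frac{S(S+1)}{3}\left(\frac{A_O}{\hbar}\right)^2
\tau_{s1}, \qquad \frac{1}{\tau_{s1}} = \frac{1}{\tau_M} + \frac{1}{T_{1e}},$$

with $T_{1e}$ from the shared electron-relaxation model evaluated at the
electron Larmor frequency of the 11.74 T field. The ¹⁷O dipolar term is
omitted (it is orders of magnitude below the scalar term at these coupling
constants). The bound shift is the Fermi-contact expression
$\Delta\omega_m = g\mu_B S(S+1) B_0 (A_O/\hbar) / (3 k_B T)$. The empirical
outer-sphere coefficient $C_{os}$ is interpreted as adding
$C_{os}\Delta\omega_m$ to the reduced shift only — it does not touch the
reduced rate. This convention reproduces the role of the small tabulated
values (0.04–0.05) but is an interpretation; the quantity is never defined
operationally in the source analyses.

The exchange-regime classifier compares $\tau_M$ with $T_{2m}$: ratios
above 10 are labeled slow, below 0.1 fast, the band between intermediate.
With the tabulated parameters the mono complex (τ_M = 18 μs) stays in slow
exchange across 278–350 K, and the bis complex (τ_M = 272 ns) shows the
slow/intermediate signature of reduced rates that fall on cooling.

# Global fitting

`fit_global()` minimizes the weighted sum of squared residuals over any
mixture of NMRD and ¹⁷O datasets sharing one parameter vector. Because the
relative weighting of ¹H and ¹⁷O residuals used in the original analyses is
unstated, each residual series (relaxivity, reduced rate, reduced shift) is
normalized by its mean observed magnitude by default so the datasets
contribute comparably; the weights are user-configurable.

Optimization is bounded Levenberg-Marquardt from a deterministic
multi-start scheme (default 8 starts: the supplied initial values plus
log-uniform draws within the bounds, seeded), because a single-start fit
is not reproducible across starting guesses. Uncertainties come from the
Jacobian-based covariance at the optimum. An identifiability guard warns
when exchange/hyperfine parameters (τ_M, A_O/ħ) are freed for a q = 0
problem without ¹⁷O data. Temperature-dependent Δ²(T) enters identically
in the ¹H and ¹⁷O branches.

# Transchelation kinetics

Single traces follow $A_t = A_p + (A_0 - A_p)e^{-k_d t}$, with both
endpoints fittable by default (endpoint drift) or freezable. The observed
rate constant is modeled by the pathway-weighted law

$$k_d = x_{\mathrm{FeL}_3} k_0 + x_{\mathrm{FeL}_2}
\left(k_1[\mathrm{H}^+] + k_4[\mathrm{H}^+][\mathrm{CDTA}]\right),$$

where the FeL₃/FeL₂ partition comes from the kinetically determined
stability constant ($\log K = 9.20$) and the free ligand concentration
delivered by the speciation solver; the minor hydroxo species is neglected
in the kinetic model. The exact algebra of the saturation terms for the
protonated and ternary intermediates is not available in the main source,
so the law is linear in [CDTA] over the 20–80-fold excess range studied
and is isolated behind `observed_kd()` for easy replacement. With the
tabulated constants this law reproduces the reference dissociation rate at
pH 7.4 ($1.07\times10^{-4}$ vs $1.1\times10^{-4}$ s⁻¹, −2.3%):

```{r kinetics}
kd <- observed_kd(tiron_rate_constants(), tiron_constants(),
                  pH = 7.4, total_Fe = 1e-4, total_L = 5e-4, CDTA = 0)
c(kd = kd, t_half_h = half_life(kd))
```

The hydroxide-assisted law $k_0 + k_{OH}[\mathrm{OH}^-] +
k_{OH^2}[\mathrm{OH}^-]^2$ is provided (`hydroxide_kd()`) only for the
comparative inertness ordering against the polyaminocarboxylate reference
complexes; half-life comparisons near physiological pH use the printed
reference rate constants directly.

# Synthetic data: what it does and does not emulate

The generator mirrors the measurement designs of the study: NMRD profiles
on 30 log-spaced frequencies over 0.01–500 MHz at 283/288/298/310 K; ¹⁷O
data over 278–350 K at 11.74 T; absorbance titrations at 0.19 mM Fe with a
~50-fold Tiron excess over pH 2–10; mono-exponential traces at 0.1 mM
complex. Noise is Gaussian — relative 1% for relaxation rates (matching the
stated instrumental reproducibility) or absolute for absorbance — seeded
through R's generator, so every dataset is bit-reproducible. Real
measurements additionally carry baseline drift, temperature-calibration
error and correlated residuals that the generator does not emulate:
passing parameter-recovery tests therefore demonstrates the correctness
and identifiability of the fitting machinery under the stated noise model,
not robustness to instrumental artifacts.

# Numerical choices and problem sizes

* Speciation root bracketing on $\log_{10}[L^{4-}] \in [-45, \log_{10} L_t + 1]$;
  Brent tolerance $10^{-14}$, Newton polish; residuals verified to
  $10^{-10}$ relative.
* The grid+bisection reference solver used in the tests scans $2\times10^5$
  grid points per instance and bisects to a $10^{-14}$ bracket.
* LM fits run up to 200–300 iterations; rate constants are refined on a log
  scale to preserve positivity; kinetic residuals are relative so that
  conditions spanning decades of $k_d$ weigh equally.
* Test problem sizes were chosen to exercise every code path at interactive
  runtimes: 12-frequency × 4-temperature NMRD grids and 9-temperature ¹⁷O
  sets for the global-fit recovery studies, 12-replicate Monte-Carlo sets
  for the refinement calibration checks, and 50–100 random instances for
  each oracle-equivalence sweep.

# Known limitations

* Static-ZFS electron relaxation, Curie relaxation, cross-correlation
  effects and $r_2$ are outside the model, as are activity-coefficient
  corrections and redox chemistry.
* The second-/outer-sphere split at low field depends on the (unprinted)
  electron-relaxation closed form, as discussed above.
* The kinetic law does not saturate in [CDTA]; extrapolation far beyond the
  80-fold excess regime is not supported.
* Reported uncertainties are curvature (linearization) estimates; strongly
  correlated parameter pairs (e.g. Δ² and τ_v) can make individual 1σ
  values optimistic even when the fit is excellent.
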