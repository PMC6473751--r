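# stiffsim

Diffusion–reaction modelling of enzyme-mediated hydrogel stiffening.

Dynamically stiffening hydrogels are a standard tool for studying how
tissue mechanics (e.g. tumor stiffening) drives cell behavior. One widely
used chemistry crosslinks an 8-arm PEG-norbornene macromer with a
bis-cysteine, bis-tyrosine peptide (CYGGGYC); the enzyme tyrosinase then
diffuses into the cell-laden gel and oxidizes the network-bound tyrosine
residues into DOPA, whose dimers form secondary crosslinks that stiffen the
gel in place. Whether, where, and how fast stiffening occurs is a coupled
transport–reaction question, and `stiffsim` answers it quantitatively for
the people who design such gels: biomaterials and tissue-engineering
researchers choosing enzyme doses, incubation times and gel geometries.

## The model

The package chains four layers, each exposed as plain functions:

1. **Network structure** — mass swelling ratio `q = m_swollen/m_dry`;
   volumetric ratio `Q = 1 + (ρ_PEG/ρ_H2O)(q − 1)`; molecular weight
   between crosslinks `M̄c = 2(MW_A/f_A + MW_B/f_B)`; mesh size
   `ξ = Q^(1/3) · ℓ · sqrt(3 C_n M̄c / M_r)`; Lustig–Peppas in-gel
   diffusivity `D_gel = D_sol (1 − R_E/ξ) exp(−Y/(Q − 1))`.
2. **Transport** — Fick's second law `∂C_E/∂t = ∂x(D ∂x C_E)` across a
   1 mm slab with both faces at the bath concentration, solved by the
   analytic Fourier series (constant D) and by a conservative
   Crank–Nicolson finite-difference scheme (general D).
3. **Kinetics** — Michaelis–Menten `V_P = k_cat C_E C_S/(K_M + C_S)`,
   optional substrate inhibition `… + C_S²/K_i`, nonlinear least-squares
   fitting (`fit_kinetics()`), initial-rate extraction from assay time
   courses, and the integrated rate law
   `t = [K_M ln(C_S0/C_S) + (C_S0 − C_S)]/(k_cat C_E)`.
4. **Coupling** — per position, the immobilized substrate follows
   `C_S(x,t) = K_M · W(f)` with
   `f = (C_S0/K_M) exp[(C_S0 − k_cat X(x,t))/K_M]`, where `W` is the
   Lambert W function and `X` the enzyme exposure; an independent
   stiff-ODE oracle (`numeric_reference()`) validates the closed form.

A power-law analysis module (`fit_power_law()`, `ideality_assessment()`)
fits `G′ = a · ν_2s^b` on log-log axes to assess network ideality (rubber
elasticity predicts b = 1), and seeded generators
(`simulate_velocities()`, `simulate_timecourse()`, `simulate_profile()`,
`simulate_modulus_swelling()`, `simulate_swelling()`) produce all test
data synthetically. See the methods vignette
(`vignettes/stiffening-model.Rmd`) for assumptions, numerical choices and
limitations.

## Worked example

Structure of a stiff (~5 kPa) gel and the headline conversion-time
estimate:

```r
library(stiffsim)

Mc <- mw_between_crosslinks(macromer_spec(), crosslinker_spec("CYGGGYC"))
gel_state(Q = 18, Mc = Mc, G_prime_kPa = 5)
#> Gel structural state
#>   q = 16.5, Q = 18, nu_2s = 0.05556
#>   Mc = 5722 g/mol
#>   mesh size = 15.2 nm
#>   G' = 5 kPa

# well-mixed estimate: 99% conversion of 10 mM substrate at 3 uM enzyme
integrated_mm_time(tyrosinase_kinetics("cygggyc"), 3, 10, 0.99) / 3600
#> [1] 1.939969
```

The 15.2 nm mesh is more than three times the enzyme's 4.5 nm
hydrodynamic radius, so even the stiffened network barely hinders
transport, and a 3 µM enzyme bath converts 10 mM of substrate in about
two hours *if* enzyme is everywhere. The full simulation couples the two
processes:

```r
consts <- stiffsim_constants()
slab <- slab_problem(consts$slab_thickness_m, consts$D_gel_stiff,
                     consts$enzyme_conc_uM)
prob <- dr_problem(slab, tyrosinase_kinetics("cygggyc"), 10,
                   grid1d(dx = 2e-5, dt = 10, horizon = 8 * 3600))
sol <- closed_form_fields(prob)
sol
#> Diffusion-reaction solution (closed_form, exposure integrated)
#>   51 nodes x 49 times up to 8 h
#>   final conversion: 100.0% (center), 100.0% (slab mean)

stiffening_summary(sol, 0.95)$completion_s / 3600
#> [1] 2.671977
```

With transport included, the slab midplane — the last place the enzyme
reaches — passes 95 % conversion only at ~2.7 h: product formation lags
enzyme arrival, and the whole 1 mm slab completes comfortably within the
6–8 h incubation used experimentally.

A command-line interface wraps the same functions
(`inst/cli/stiffsim`): `mesh`, `diffuse`, `kinetics-fit`, `simulate`
(YAML config), `stiffen-fit`, and `synth` for seeded synthetic datasets.

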