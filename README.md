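# pmfassoc

Association thermodynamics of carboxylic acids in nonpolar solvents from
one-dimensional free-energy profiles.

Amphiphilic additives such as fatty acids dimerize in oils: two headgroups
pair through one hydrogen bond (*open* dimer) or two (*closed* dimer), and
trace water competes by hydrating the monomer. The monomer concentration —
which sets the additive's chemical potential and hence its adsorption —
follows from the dimer dissociation constant *K*<sub>d</sub> = *M*²/*D* and
the hydrate heterodissociation constant *K*<sub>h</sub> =
*M·W*<sub>free</sub>/*MW*, both temperature dependent. `pmfassoc`
implements the computational chain that turns a potential of mean force
(PMF) *W*(*r*) along the headgroup separation into these quantities:

1. **Synthetic umbrella sampling** — Metropolis Monte Carlo windows on a
   parametric two-well model landscape (closed dimer at 3.8 Å, open dimer
   at 4.6 Å, zero plateau beyond 10 Å), with the standard protocol as
   default: 0.5 Å window spacing, 6 kcal/(mol Å²) harmonic bias, 20,000
   stored samples per window.
2. **WHAM** — the weighted histogram analysis method, iterated to
   self-consistency, with neighbor-overlap diagnostics, trajectory-
   truncation convergence checks, and Monte Carlo bootstrap uncertainty.
3. **Well integration** — the bound-state integral
   *Q* = ∫ 4π*r*² e^(−*W*(*r*)/*k*T) d*r* over [*r*₀, *r*₁] (defaults
   3.9–5.3 Å), giving Δ<sub>d</sub>*G* = *k*T ln(*Q*/*V*<sub>ref</sub>)
   and *K*<sub>d</sub> = *c*° e^(−Δ<sub>d</sub>*G*/*RT*) under a 1 M or a
   solvent-mole-fraction standard state, plus open/closed sub-well
   decomposition and secondary-minimum analysis.
4. **Van't Hoff fitting** — ln *K*<sub>d</sub> linear in 1/*T* with
   Δ<sub>d</sub>*H* = −*R*·slope, and the reference constant
   *K*<sub>d0</sub> at 298 K by enthalpy-consistent extrapolation.
5. **Speciation** — closed-form monomer/dimer equilibria and a damped-
   Newton solver for the coupled monomer/dimer/hydrate system with exact
   mass balances.

The synthetic generator is first-class: because the generating landscape
is known analytically, every estimator in the chain is tested against
exact ground truth and independent oracles (likelihood-maximization WHAM,
sample-based MBAR, adaptive quadrature, nested bisection).

## Worked example

```r
library(pmfassoc)

pmf <- make_default_pmf()
ds  <- run_schedule(pmf, r_start = 15, r_end = 3.5, spacing = 0.5,
                    spring = 6, temperature = 300,
                    config = sampler_config(seed = 1))
prof <- solve_wham(ds)
prof
#> PMF profile: 262 bins of 0.05 A at 300 K; W in [ -28.49 , 0.4639 ] kJ/mol
#>   zero-referenced over [ 10 , 16.475 ] A

find_minima(prof, depth_threshold = 1)
#>          r          W
#> 1 3.815872 -28.505383
#> 2 4.585259 -23.962238

integrate_association(prof)
#> Association over [3.90, 5.30] A at 300 K (molar_1M):
#>   dG_dissociation = 17.520 kJ/mol, K_d = 0.89 mM

oc <- open_closed_decomposition(prof, boundary = 4.2)
sprintf("open fraction %.2f, closed %.2f", oc$fraction_open, oc$fraction_closed)
#> [1] "open fraction 0.60, closed 0.40"
```

The reconstructed profile recovers the generating landscape (minima at
3.8/4.6 Å, well depth ≈28.5 kJ/mol) and integrates to a dissociation free
energy of 17.5 kJ/mol at 300 K, i.e. *K*<sub>d</sub> ≈ 0.9 mM under the
1 M standard state. Fitting published dissociation constants for the
acid–water complex across 300–345 K:

```r
fit <- vant_hoff_fit(c(300, 323, 345), c(0.249, 0.705, 1.741), T0 = 298)
fit
#> Van't Hoff fit (lnK_regression, K_d0 by extrapolate_from_nearest_T):
#>   dH = 37.16 kJ/mol, K_d0 = 0.2253 mM at T0 = 298 K
#>   ln-space residuals:  0.00000 -0.02025  0.00128
```

i.e. a dissociation enthalpy of 37.2 kJ/mol and 0.225 mM at 25 °C.
Speciation with both dimerization and hydration active:

```r
solve_speciation(C_total = 1, W_total = 5,
                 equilibrium_constants(K_d = 0.249, K_h = 1.5,
                                       temperature = 300))
#> Speciation (C_eq_M_plus_D): M = 0.209782, D = 0.176741,
#>   MW = 0.613476, W_free = 4.38652 mM
```

so at 1 mM total acid with 5 mM water, only ~21 % of the acid remains as
free monomer. `run_pipeline(pipeline_config(...), out_dir)` chains all
stages and writes CSV/JSON artifacts plus a hash manifest; identical
configuration and seed reproduce identical outputs.

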