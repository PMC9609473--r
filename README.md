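# revkin

Reversible first-order kinetics of ionic drug binding and release from
nanoparticle coronas.

## The problem

Protonated doxorubicin binds electrostatically to the carboxylate groups
of acrylic-acid residues in the hydrophilic corona of self-assembled
N-vinyl-2-pyrrolidone/acrylic-acid amphiphilic copolymer nanoparticles.
In a dialysis release experiment the free-drug fraction climbs to an
equilibrium plateau rather than to complete release, because binding is
reversible. `revkin` is for researchers in nanoparticle drug delivery
who want to turn such release time series into physically meaningful
constants: separate release and binding rate constants, an equilibrium
constant, activation energies, and the standard thermodynamic functions
of the release reaction.

## The model

Free drug (concentration C_DOX) and ionically immobilized drug (C_IDOX)
interconvert by a reversible first-order reaction,

    dC_DOX/dt = k1 * C_IDOX - k-1 * C_DOX,      k-1 = k-1' * C_COOH,

where k1 (1/h) is the release constant, k-1 the pseudo-first-order
binding constant absorbing the carboxyl concentration C_COOH, and k-1'
the second-order binding constant. With the release conversion
ξ = C_DOX / C_DOX_max, the solution from a fully bound start is

    ξ(t) = ξ∞ (1 - exp(-(k1 + k-1) t)),   ξ∞ = K / (1 + K),
    K = k1 / k-1 = ξ∞ / (1 - ξ∞),

so ln(ξ∞ - ξ) is linear in t with slope -(k1 + k-1): the equilibrium
conversion fixes K, the decay rate fixes the sum k1 + k-1, and the two
constants separate as k1 = kK/(1+K), k-1 = k/(1+K). Temperature series
of the constants then give activation energies (Arrhenius, ln k vs 1/T),
the standard release enthalpy (van't Hoff, ln K vs 1/T), the Gibbs
energy ΔG°(T) = -RT ln K and the entropy ΔS° = (ΔH° - ΔG°)/T.

## Worked example

Simulate one noisy dialysis experiment at the neutral-pH reference
constants (k1 = 0.0165, k-1 = 0.153 1/h) and refit it:

```r
library(revkin)
spec  <- synthetic_spec(rate_constants(0.0165, 0.153),
                        noise_sd = 0.002, seed = 42)
fit   <- fit_release(simulate_release(spec))
summary(fit)
#> Reversible first-order release fit (nonlinear)
#> Reversible release rate constants (1/h):
#>   k1 (release) = 0.01711,  k-1 (binding) = 0.1589,  k1 + k-1 = 0.176
#>   K = k1/k-1 = 0.1077   (equilibrium conversion 0.09724)
#> Equilibrium conversion xi_inf = 0.097238 (nonlinear; plateau sd 0.00331)
#> Bound fraction at equilibrium 1/(1+K) = 0.9028
#> Model adequacy (semilog linearization):
#>   Semilog fit: slope -0.098618 1/h, intercept -3.1929 (gap to ln xi_inf -0.862)
#>   r^2 = 0.66562 over 20 points (5 excluded at xi >= xi_inf)
#> Residual sd on conversion: 0.00257 over 25 points
```

Both generating constants are recovered within a few percent; about 90%
of the drug stays bound at equilibrium. The semilog diagnostic
illustrates why the joint nonlinear fit is the default on noisy data:
the log transform magnifies noise near the plateau.

A temperature series of fitted constants yields the full thermodynamic
chain:

```r
thermo_report(c(278, 298, 310, 323),
              c(2.80e-3, 1.27e-2, 1.65e-2, 3.52e-2),   # k1  (1/h)
              c(0.119, 0.137, 0.153, 0.166))           # k-1 (1/h)
#> Thermodynamics of reversible drug release
#>   release  : Arrhenius fit (4 points): Ea = 40.8 kJ/mol, ln A = 11.848, r^2 = 0.9752
#>   binding  : Arrhenius fit (4 points): Ea = 5.6 kJ/mol, ln A = 0.285, r^2 = 0.9946
#>   van't Hoff: van't Hoff fit (4 points): dH = 35.2 kJ/mol, r^2 = 0.9628
#>  temperature     k1 k_minus1          K dG_kJ_mol dS_J_mol_K
#>          278 0.0028    0.119 0.02352941       8.7       95.3
#>          298 0.0127    0.137 0.09270073       5.9       98.3
#>          310 0.0165    0.153 0.10784314       5.7       94.9
#>          323 0.0352    0.166 0.21204819       4.2       96.0
```

Release is strongly temperature-activated (about 41 kJ/mol) while
binding is nearly diffusion-controlled (about 6 kJ/mol); release is
endothermic (ΔH° ≈ 35 kJ/mol) and entropy-driven (ΔS° ≈ 98 J/mol/K), so
the bound state loosens as temperature rises.

A command-line wrapper chaining these stages
(`simulate`/`fit`/`thermo`/`recover`/`report`) is installed at
`system.file("cli", "revkin", package = "revkin")`; see `?rk_cli`.

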