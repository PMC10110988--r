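# methanobatch

Coupled modeling of hydrogenotrophic methanogen growth and gas–liquid
mass transfer in sealed pressurized batch reactors — the laboratory
workhorse for screening underground hydrogen storage sites for microbial
H₂ loss.

Methanogenic archaea run the Sabatier reaction, CO₂ + 4 H₂ → CH₄ + 2 H₂O,
which removes five moles of gas per mole of CH₄ formed. In a closed
bottle reactor charged with 80/20 H₂/CO₂ over growth medium, microbial
activity therefore shows up as a pressure decline of several hundred
mBar, and that pressure trace (plus a few microscopy cell counts) is the
data from which growth kinetics must be inferred.

The model couples, in both phases (moles `N_n` of H₂/CO₂/CH₄ in gas and
water, total cells `X`):

- **dual-substrate Monod growth** in the liquid,
  `μ = μmax · C_H2/(K_H2+C_H2) · C_CO2/(K_CO2+C_CO2)`,
  with lag ramp `λ(t)` and decay `b`: `dX/dt = λX(μ − b)`;
- **Sabatier stoichiometry** via `ζ = (−1, −¼, +¼)` and the hydrogen
  yield `Y_H2`: reaction term `ζ_n·λμX/Y_H2` per component;
- **two-film gas–liquid transfer** toward Henry equilibrium with the
  current partial pressure, `J_n = k_gw·(H_n·p_n − C_n)/C_ref`, gas
  phase `−J`, liquid `+J`;
- **ideal-gas pressure closure** `P = N_tot·R·T/V_gas`.

On top of the forward model: a calibration workflow (initialization →
lag heuristics → bounded Levenberg–Marquardt fitting of `μmax`, `Y_H2`,
`k_gw`, … in log10 space, with multistart identifiability diagnostics),
sequential per-cycle calibration of refill experiments, a synthetic
observation generator for simulate-then-recover validation, and the
specific-contact-area upscaling of `k_gw` to water-wet porous media.

## Worked example

Simulate the thermophilic-strain experiment (600 mBar, 65 °C, 132.5 ml
reactor, 47 ml medium) with its matched parameters, generate noise-free
observations from it, and recover the parameters from the base-case
starting values:

```r
library(methanobatch)

scn <- table1_scenarios()$series_1_1
traj <- integrate_scenario(scn)
traj
#> <reactor_trajectory> 251 points over 1.5e+05 s; pressure 600 -> 173.4 mBar;
#>   peak 1.43e+08 cells/ml

gen <- generate_observations(scn, noise = noise_model(0, 0, seed = 1))
fit <- fit_scenario(scn, gen$observations,
                    calibration_spec(free = c("mu_max", "yield_Y_H2", "k_gw"),
                                     species = 1, multistart_count = 1))
fit
#> <calibration_result>
#>   fitted:
#>     mu_max                 0.00017
#>     yield_Y_H2             4.1e+12
#>     k_gw                   0.08
#>   objective: 1.12526e-16
```

The pressure falls from 600 to 173 mBar through a lag plateau and a
sigmoidal decline — hydrogen is the limiting substrate (<1% of it
remains at the plateau, against ~46% of the CO₂) — and the fit returns
the generating values `μmax = 1.7e-4 1/s`, `Y_H2 = 4.1e12 cells/mol`,
`k_gw = 8e-2 mol/s` to machine precision. Dropping the three cell-count
observations makes the yield/inoculum pair non-identifiable, which the
multistart diagnostic reports (`uniqueness_flag = FALSE`).

A thin command-line front end wraps the same functions
(`inst/scripts/methanobatch.R`; subcommands `simulate`, `generate`,
`suite`, `fit`, `fit-refill`, `porous`; YAML configs in laboratory units
— see `inst/extdata/example_config.yaml`).

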