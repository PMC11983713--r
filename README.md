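# aquann

A flexible 3-site water force field in R whose atomic partial charges and
intermolecular charge transfer (CT) are predicted on the fly by small dense
neural networks from radial, interaction-classified descriptors of each
atom's local environment — polarization without iterative charge
equilibration.  The package is aimed at molecular-simulation method
developers who want a fully inspectable, tested reference implementation of
the dynamic-charge water model idea: descriptors with analytic Jacobians,
exact chain-rule forces, Ewald electrostatics, an MD engine, a fixed-charge
SPC/FW baseline, analysis observables, and a synthetic surrogate-label
generator so the complete train → predict → simulate loop runs without any
quantum-chemistry data.

## The model

The potential energy of `N` flexible water molecules is

    U = Σ_I [ k_b ((r_OH1 − r0)² + (r_OH2 − r0)²) + k_a (θ_I − θ0)² ]   (intra)
      + Σ_{i<j} [ A_ij / r_ij⁹ − B_ij / r_ij⁶ ]                         (9–6 vdW)
      + k_e Σ_{i<j} q_i q_j / r_ij                                      (Coulomb)
      − k_c Σ_{IJ} δq_IJ² / (δq_IJ² + 3 δq0²)                           (CT)

with intramolecular nonbonded pairs excluded, direct sums for clusters and
Ewald summation for orthorhombic cells.  The charges `q_i` come from
element-specific networks fed with 24 interaction-classified functions
(ICFs) `Σ_j exp(−k_f r_ij)·s_c(r_ij)` of the atom's environment inside
4.4 Å; the per-pair CT `δq_IJ` comes from a third network over 36 pair ICFs
inside 5.5 Å, antisymmetrized so `δq_IJ = −δq_JI` holds by construction.
Charges are re-neutralized each evaluation (`Δq = Σ q_i / N`), and forces are
fully analytic, including the network chain rule and the neutralization
shift.  See the methods vignette (`vignettes/water-model-methods.Rmd`) for
conventions, derivations and design rationale.

## Worked example

Gas-phase benchmarks of the SPC/FW baseline (published parameters):

```r
library(aquann)
spcfw_monomer_dipole()      # 2.193 D
optimize_dimer(spcfw_params())
#> water dimer minimum: r_OO = 2.730 A, theta_A = 21.7 deg,
#>   E_int = -7.139 kcal/mol, mu = 3.594 D (max|F| = 6.81e-07)
```

`r_OO` is the O–O distance at the dimer minimum, `theta_A` the angle between
the acceptor's HOH bisector and the O–O axis, `E_int` the supermolecular
interaction energy (monomer deformation excluded), and `mu` the total
point-charge dipole of the complex.

The full dynamic-charge loop on synthetic labels:

```r
ds  <- make_training_set(40, 8, surrogate_params(sigma_noise = 0), seed = 2)
tr  <- train_charge_model(ds, hidden = c(16, 16, 16, 16), epochs = 30,
                          batch = 128, lr = 2e-3, seed = 2)
model <- chargenn_model(tr$net_O, tr$net_H, tr$net_CT)
be  <- energy_backend("chargenn", nn = model)

cfg <- minimize(build_water_cluster(8, seed = 9), be, tol = 1e-3)$config
ev  <- total_energy_and_gradient(cfg, model)
#> U_total = -108.676 kcal/mol (intra 16.955, vdw 67.034,
#>                              coul -192.652, ct -0.0124)
sum(ev$charges)             # 0 (neutralized; shift was -0.00095 e)

traj <- run_md(cfg, be, ensemble = "NVT", T_K = 298.15, dt = 0.5,
               steps = 400, stride = 100, seed = 1)
tail(traj$energy[, c("time", "U_total", "KE", "T_inst")], 3)
#>   time U_total     KE  T_inst
#> 3  100 -98.708 12.267 171.478
#> 4  150 -96.634 11.780 164.661
#> 5  200 -96.159 12.299 171.917
```

Observables (`radial_distribution()`, `ir_spectrum()`, `self_diffusion()`,
`tetrahedral_order()`, `molecular_dipole()`, `layer_statistics()`) consume
trajectories or configurations and emit plain data frames / TSV tables.
A command-line wrapper (`inst/cli/aquann`) exposes `gen-data`, `train`,
`predict`, `optimize`, `md` and `analyze` over flat key–value config files.

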