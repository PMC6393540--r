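# tabiophys

Quantitative biophysics of bacterial toxin–antitoxin (TA) autoregulation,
for structural biologists and biophysicists studying repressor–operator
systems in which a *flexible* protein segment controls DNA binding.

The package implements three connected analyses:

1. **Cooperative operator binding by ITC.** The antitoxin dimer A₂ binds
   its operator duplex D as two dimers in one concerted step,

   2 A₂ + D ⇌ A₄D,  K_A = [A₄D] / ([A₂]²[D])  (M⁻²),

   with no singly-bound intermediate. The module solves the tri-molecular
   speciation (unique root of K_A(A−2C)²(D−C) = C), simulates closed-cell
   duplex-into-dimer titrations with perfusion dilution, fits
   (log₁₀K_A, ΔH, offset) by multi-start Levenberg–Marquardt, and provides
   the sequential two-site contrast model whose cooperative limit
   (K₂ ≫ K₁) converges to the concerted one.
2. **SAXS disorder analysis.** Guinier fitting with an iterative
   q·Rg-window, the dimensionless Kratky plot (qRg)²I(q)/I(0) with its
   analytic references — globular x²·exp(−x²/3), maximum 3/e ≈ 1.104 at
   √3; Debye coil 2(e^(−x²)−1+x²)/x², asymptote 2 — peak detection and
   foldedness classification, coarse-grained Debye profiles,
   self-avoiding flexible-tail conformer generation, MultiFoXS-style
   multi-state (≤ 4 states) ensemble fitting with weighted Rg
   distributions, and Porod volume / molecular-weight estimates.
3. **Rigid-body structure metrics.** A minimal PDB reader, Kabsch
   superposition (proper rotations guaranteed), backbone RMSD with
   residue maps, centre-of-mass separations, inter-domain rotation
   angles, Shrake–Rupley SASA, buried surface areas, and sequence net
   charge.

A synthetic-data module generates every input — noisy isotherms, bead
bodies and tail ensembles with scattering curves, toy structures with
exact known transforms, and the operator-variant FASTA — each with a
ground-truth JSON sidecar, so the entire pipeline is testable offline.

See `vignettes/tabiophys-methods.Rmd` for the models, assumptions,
defaults and limitations.

## Worked example

Simulate a wild-type-operator titration (K_A = 3.0×10¹³ M⁻²,
ΔH = −19.0 kcal/mol, 1% noise) at a fittable steepness and refit it:

```r
library(tabiophys)

protocol <- titration_protocol(cell_volume = 200, cell_conc = 1.8e-6,
                               syringe_conc = 8e-6,
                               injection_volumes = rep(2, 25))
truth <- binding_parameters(K_A = 3.0e13, dH = -19.0)
sim <- simulate_isotherm(truth, protocol, noise_sd = 0.19, seed = 7)
fit_isotherm(sim)
#> Cooperative fit (25 injections)
#>   K_A    = 3.03e+13 M^-2  (log10 = 13.482 +/- 0.030)
#>   dG     = -18.39 kcal/mol
#>   dH     = -19.15 +/- 0.16 kcal/mol
#>   offset = 0.150 kcal/mol, residual rms = 0.212
```

The fitted constant is within 1% of the generating value on the log scale;
ΔG = −RT ln K_A at 25 °C. In the stoichiometric limit the operator
saturates at exactly two dimers per duplex:

```r
sc <- speciation_curve(K_A = 1e20, duplex_total = 5e-6,
                       dimer_ratios = seq(0, 4, by = 0.1))
min(sc$ratio[sc$bound_fraction >= 0.99])
#> [1] 2
```

A partially disordered particle — rigid body plus 22-residue flexible
tail, "measured" as a 0.7/0.3 two-conformer mixture with 1% noise — is
recovered by the multi-state fitter:

```r
sys <- make_rigid_plus_tail_system(seed = 1)
multistate_enumerate(sys$pool_profiles, sys$experiment, max_states = 2)
#>   k = 1: chi2 = 1.871, members = {1}, weights = {1.000}
#>   k = 2: chi2 = 0.7017, members = {1,2}, weights = {0.698,0.302}
#>   best k = 2
```

The two-state model finds the generating conformers with weights
0.698/0.302 (truth 0.7/0.3) and halves χ² relative to the best single
state. The same curve classifies as globular on the dimensionless Kratky
plot — the disordered tail is only ~10% of the particle, which is exactly
why ensemble fitting, not the Kratky peak, is the sensitive diagnostic:

```r
g <- guinier_fit(sys$experiment)
pk <- find_kratky_maximum(dimensionless_kratky(sys$experiment, g$Rg, g$I0))
classify_foldedness(pk)
#> [1] "globular"
```

## Command line

```sh
Rscript inst/cli/tabiophys.R itc simulate --ka 3e13 --dh -19 \
    --cell-conc 1.8e-6 --syringe-conc 8e-6 --noise 0.19 --seed 7 -o iso.csv
Rscript inst/cli/tabiophys.R itc fit iso.csv -o fit.json
Rscript inst/cli/tabiophys.R saxs guinier curve.dat
Rscript inst/cli/tabiophys.R struct charge MRHIQGQVFY...
```

(after installation, the launcher is at
`system.file("cli/tabiophys.R", package = "tabiophys")`).

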