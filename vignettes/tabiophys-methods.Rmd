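---
title: "Models and methods behind tabiophys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind tabiophys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tabiophys)
```

# Scope

`tabiophys` packages the three quantitative arguments used to characterise
a bacterial toxin–antitoxin (TA) autoregulation module in which the
*toxin*, not the antitoxin, carries the flexible regulatory element:

1. an isothermal titration calorimetry (ITC) model in which the antitoxin
   dimer binds its operator DNA as **two dimers in one concerted
   (tri-molecular) step**;
2. small-angle X-ray scattering (SAXS) analysis of intrinsic disorder via
   the dimensionless Kratky plot and multi-state ensemble fitting of a
   rigid body with a flexible N-terminal tail;
3. rigid-body structural comparison metrics (superposition RMSD,
   centre-of-mass separations, inter-domain rotations, buried surface
   area, sequence net charge).

Everything runs on synthetic data produced by the package's own
generators, so the full pipeline is testable without downloads.

# The cooperative binding model

## Tri-molecular equilibrium

Electrophoretic mobility, size-exclusion and native-MS data for this class
of repressor show only free dimer, free operator duplex, and a saturated
2:1 complex — no singly-bound intermediate. The minimal model is the
concerted reaction

$$2\,A_2 + D \rightleftharpoons A_4D, \qquad
K_A = \frac{[A_4D]}{[A_2]^2[D]} \quad (\mathrm{M}^{-2}),$$

whose mass balance reduces to one equation in the complex concentration
$C$:

$$K_A\,(A_\mathrm{tot}-2C)^2\,(D_\mathrm{tot}-C) = C .$$

The left side minus the right side is strictly decreasing in $C$ on
$[0, \min(A_\mathrm{tot}/2, D_\mathrm{tot})]$, so the physical root is
unique. `solve_trimolecular_equilibrium()` brackets it by bisection (200
iterations on the guaranteed sign change) and polishes with a few Newton
steps; this is slower than the closed-form cubic but immune to the
catastrophic cancellation the cubic suffers near saturation
($K_A \sim 10^{20}$ M$^{-2}$ is routinely used as the stoichiometric
limit). Tests cross-check against both a `polyroot` solution and a
brute-force grid scan.

A consequence of the concerted stoichiometry is that, in the
effectively-infinite-$K$ limit, the smallest dimer:duplex ratio giving
$\ge 99\%$ bound duplex on a 0.1-ratio grid is exactly **2.0** — the
saturation behaviour seen in gel-shift titrations.

## The sequential contrast model

`sequential_two_site_speciation()` implements the stepwise alternative
($A_2 + D \rightleftharpoons A_2D$, $K_1$;
$A_2D + A_2 \rightleftharpoons A_4D$, $K_2$; $K_1K_2$ in M$^{-2}$). As
$K_2/K_1 \to \infty$ at fixed product, the intermediate population
vanishes monotonically and the speciation converges to the tri-molecular
model (sup-norm difference $<10^{-3}$ by $K_2/K_1 = 10^6$). This is the
quantitative sense in which "highly cooperative" and "tri-molecular" are
operationally the same hypothesis.

## ITC simulation

Titration direction is **duplex into dimer**, matching the stated
experiments, so the equivalence point on the injectant:cell molar-ratio
axis falls at 0.5 (two dimers consumed per duplex) — not at 2. The
closed-cell perfusion model is the standard displaced-volume bookkeeping:
injection $i$ of volume $dv$ scales all existing cell totals by
$(1-dv/V_0)$ and adds $dv\,c_\mathrm{syr}/V_0$ of injectant; the heat is

$$q_i = V_0\,\Delta H\,\bigl(C_i - C_{i-1}(1-dv_i/V_0)\bigr),$$

normalized per mole of injected duplex, plus a constant offset and
(optionally) seeded Gaussian noise. A `perfusion = "trapezoid"` flag
enables mid-injection averaging of the injectant term; the instrument's
exact correction is not documented for the source data, so the simple
variant is the default. $\Delta H$ is in kcal per mole of duplex
incorporated (one duplex per complex); "per mole of added ligand" is read
as per mole of injected duplex.

## Fitting

`fit_isotherm()` minimises the residual sum of squares over
$(\log_{10} K_A, \Delta H, \mathrm{offset})$. Optimising $\log_{10} K_A$
(clamped to $[-5, 30]$ decades during search) conditions a parameter that
spans $10^9$–$10^{15}$ M$^{-2}$ across operator variants. Three starts
spanning $\pm 2$ decades guard against the local minima of steep
isotherms; each start runs a small Levenberg–Marquardt with numeric
Jacobians (chosen over Nelder–Mead because zero-residual self-consistency
fits must converge to 6 significant digits). Standard errors come from
$s^2 (J^\top J)^{-1}$ at the optimum; $\Delta G_A = -RT\ln K_A$ is
reported at 25 °C. A fit whose $\mathrm{se}(\log_{10}K_A) > 2$ (or whose
information matrix is singular) sets `k_lower_bound`: the isotherm is flat
and only bounds $K_A$ from below.

The fittable regime is set by the dimensionless steepness
$K_A A^2$ (cell dimer concentration $A$): between roughly 10 and $10^3$
the isotherm has curvature that determines all three parameters. The
recovery experiments therefore scale concentrations so
$K_A A^2 \approx 10^2$, exactly as a calorimetrist picks a c-value.

# SAXS disorder analysis

## Guinier and dimensionless Kratky

`guinier_fit()` fits $\ln I$ vs $q^2$ with an iteratively shrinking
window until $q_\mathrm{max} R_g \le 1.3$ (the classical globular cutoff,
configurable). A non-negative low-$q$ slope raises a "no Guinier region"
error rather than returning a meaningless $R_g$. For Gaussian-coil-like
curves the Guinier regime is narrower; the tests use
`qrg_limit = 1.0` there, common practice for disordered proteins (with
the 1.3 window a coil of $R_g = 20$ Å fits to 18.7 Å).

The dimensionless Kratky transform $y = (qR_g)^2 I(q)/I(0)$ vs
$x = qR_g$ removes size so that *shape class* is what remains:

* globular (Guinier-law) reference: $y = x^2 e^{-x^2/3}$, maximum
  $3/e \approx 1.104$ at $x = \sqrt 3$;
* ideal-coil (Debye-law) reference:
  $y = 2\,(e^{-x^2} - 1 + x^2)/x^2$, monotone with asymptote 2.

The Debye transform is implemented with the standard $+e^{-x^2}$
numerator of the Debye function; printed versions of the formula
sometimes carry a sign slip that would make the function negative at
small $x$.

`find_kratky_maximum()` smooths with a local-polynomial
(Savitzky–Golay-type) filter — default window 7 points, order 2 — finds
the maximum for $x \le 4$, refines it parabolically, and returns `NULL`
for curves still rising at the boundary (the coil signature).
`classify_foldedness()` calls a peak at $(x^* \le 1.9, y^* \le 1.17)$
globular; the thresholds sit midway between the analytic globular peak
$(\sqrt 3, 1.104)$ and the $(2.0, 1.22)$ peak observed for a partially
disordered toxin, and are configurable.

## Coarse-grained profiles and ensembles

`debye_profile()` evaluates the Debye double sum over one-bead-per-residue
models with unit form factors. That is accurate for the low-$q$
($q \lesssim 0.3$ Å$^{-1}$) disorder diagnostics targeted here and is
*not* an atomic profile calculator (no hydration layer, no atomic form
factors). Above $6.5\times10^4$ pairs the sum is compressed to a
pair-distance histogram ($2^{14}$ bins, per-bin weight-averaged distance),
which is exact for singly occupied bins and second-order accurate
otherwise; a 2000-bead uniform sphere matches the analytic sphere form
factor within 2% out to $qR = 3$.

`generate_tail_conformers()` grows a self-avoiding chain of
fixed-bond-length (3.8 Å) beads from an anchor on the rigid body:
uniform random directions, rejection of any bead within the clash radius
(2.0 Å) of the rigid body or earlier tail beads, bounded per-bead retries
with whole-chain restarts. With clash checks off it reproduces the ideal
freely jointed chain ($\langle R^2\rangle = n b^2$), and with them on the
measured excluded-volume expansion is the standard sanity check.

`multistate_enumerate()` fits sparse weighted mixtures: for each number
of states $k$, the best member subset by non-negative least squares on
$\sigma$-weighted intensities (Lawson–Hanson, $k \le 4$ columns), weights
normalised from the NNLS coefficients, overall scale refit analytically.
Subsets are enumerated exactly while $\binom{P}{k}$ stays under the
enumeration bound (default 25 000), otherwise a beam search seeded by the
best $(k-1)$-state models; either way $\chi^2$ is non-increasing in $k$
because every $(k-1)$ optimum survives as a candidate with a zero
coefficient. `best_k` applies a 1% parsimony rule (smallest $k$ within 1%
of the minimal $\chi^2$) so noise is not over-fitted with extra states.
The deposited-data $\chi^2$ values of the original MultiFoXS analyses are
reproduced only as an *ordering* (flexible-tail ensemble strictly better
than a rigid folded-tail model); the third-party fit metric is not
documented, so numerical equality is out of scope.

`porod_mw_estimates()` computes the Porod invariant
$Q = \int q^2 I\,\mathrm dq$ by trapezoid with three standard
completions: Guinier extension below $q_\mathrm{min}$, a flat background
$B$ and plateau $K_p$ fitted on the Porod scale
($q^4 I = K_p + Bq^4$ over the top 30% of the range), and the
$K_p/q_\mathrm{max}$ tail. Then $V_p = 2\pi^2 I_0/Q$ and
$\mathrm{MW} \approx V_p/1.66$ Å$^3$/Da. The "Fisher" molecular-weight
method sometimes named alongside $I_0$/Porod estimates has no published
definition we could locate and is omitted.

# Structural metrics

`read_structure()` is a minimal fixed-column PDB reader (one model,
altloc policy "blank or A", waters always excluded, HETATM optional);
no R PDB parser exists in the dependency set and the needed subset is
small. Superposition is Kabsch via SVD with the determinant guard that
keeps rotations proper even for mirror-degenerate inputs; tests agree
with an independent quaternion (Horn) implementation to $10^{-6}$ Å.
`relative_rotation()` aligns two complexes on one subunit pair and
reports the residual rotation angle $\arccos((\mathrm{tr}R-1)/2)$ and
centroid displacement of the measured subunit — the construction behind
"toxin rotated by 25° with a 6.8 Å COM shift" comparisons, validated here
on synthetic two-domain fixtures built with exactly those transforms.

SASA is Shrake–Rupley with a deterministic golden-spiral point set (960
points, probe 1.4 Å, Bondi radii), so results are bit-reproducible
without an RNG; buried surface area is
$\mathrm{SASA}(A) + \mathrm{SASA}(B) - \mathrm{SASA}(AB)$. Centre-of-mass
distances default to uniform weighting over selected atoms (the source
analyses do not state their weighting; mass weighting is a flag).
Residue correspondence for cross-homolog RMSDs is supplied as an explicit
residue map rather than computed by built-in alignment, keeping RMSD
deterministic.

# The synthetic-data world

The generators state, once, the world the tests live in:

* **ITC fixtures** use the published experimental geometry (200 µL cell,
  2 µL injections) and the published parameter sets
  ($K_A = 3.0\times10^{13}$ M$^{-2}$, $\Delta H = -19.0$ kcal/mol for
  the wild-type operator; $K_A = 2.3\times10^{15}$ M$^{-2}$ for the
  truncated-toxin complex at its quoted 0.9 µM-into-0.2 µM protocol).
  Noise is additive Gaussian on normalized heats at 1% of $|\Delta H|$ —
  the paper states no noise model; this magnitude resembles a
  well-behaved iTC200 baseline. Cell concentrations for recovery
  experiments are scaled so $K_A A^2 \approx 10^2$ (see above).
* **SAXS fixtures**: globular bodies are uniform bead-filled spheres;
  partially disordered particles are a 200-bead body (≈ the globular
  TA-complex core) with a 22-bead self-avoiding tail, the length of the
  disordered toxin N-terminus. "Experimental" curves are designated
  mixtures (default 0.7/0.3) of pool-member profiles with
  $\sigma(q) = a + b\,I(q)$, $a = 10^{-4} I(0)$, $b = 0.01$. Pools
  default to 50 conformers, not 10 000, to keep desk-scale runtime; the
  enumeration code paths (exact and beam) are both exercised regardless.
* **Toy structures** are built with exact known transforms (30 Å helix
  separation, 25° domain rotation + 6.8 Å displacement, 37° rigid
  copies), so the structural metrics are tested against constructed
  truth, with ground-truth JSON sidecars alongside every file.

What a green test does *not* establish: real ITC baselines drift and
their integration errors are correlated, real SAXS noise is
detector-specific and buffer-subtraction-limited, and real conformer
pools have atomic detail the bead model lacks. The synthetic world
validates the estimators' correctness, not instrument realism.

Member *identity* in a multi-state fit is only identifiable when pool
profiles differ by more than the noise: near-degenerate tail conformers
(the scattering is body-dominated) can swap for an equivalent neighbour,
while mixture weights remain stable. The across-seed recovery property is
therefore asserted on a pool of mutually distinguishable shapes.

# Numerical choices

* Root finding: bisection to a relative bracket of $10^{-12}$, then
  Newton polish; residuals $<10^{-10}\max(1, D_\mathrm{tot})$.
* Optimizer: Levenberg–Marquardt, relative SSR tolerance $10^{-12}$,
  numeric forward-difference Jacobians ($h = \max(10^{-7},
  10^{-7}|\theta|)$).
* PDB files carry 0.001 Å coordinate precision; file round-trip tests
  use that, in-memory tests use $10^{-9}$.
* Degenerate inputs: zero $K_A$/duplex return exact zeros; empty
  selections, overlapping BSA parts, non-monotone $q$, missing metadata
  keys all raise named errors rather than propagating NaN.
* All stochastic operations take a seed and restore the caller's RNG
  state (`with_seed`), so regeneration is byte-identical.

# Known limitations

* The ITC module fits single experiments; no global fitting across
  operator variants, no raw-thermogram integration.
* The SAXS module is coarse-grained by design: no atomic form factors,
  hydration layer, or real-space $P(r)$ inversion.
* The structure module reads PDB only (no mmCIF) and computes no
  electrostatics.
* Acceptance comparisons against deposited crystal/SAXS entries require
  those third-party files locally (`inst/extdata/deposited/`); they are
  not shipped and the package never downloads.
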