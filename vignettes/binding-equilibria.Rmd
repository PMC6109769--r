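---
title: "Multi-equilibrium analysis of calmodulin-peptide titrations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-equilibrium analysis of calmodulin-peptide titrations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(calbind)
```

## The system and the model

Calmodulin (CaM) is a 148-residue Ca²⁺ sensor with two lobes, each
carrying two EF-hand Ca²⁺ sites; targets bind in hydrophobic,
methionine-rich pockets that open upon Ca²⁺ loading.  This package
analyses CaM binding to two peptide ligands — a *Drosophila*
cryptochrome C-terminal peptide (dCRY₄₉₀₋₅₁₆, species `A`) and an INAD
peptide containing the TMAKINKR motif (INAD₂₃₀₋₂₄₃, species `B`) — and
to both at once, as measured by isothermal titration calorimetry (ITC)
and ¹⁵N-HSQC chemical shift titrations.

The core object is a *binding scheme*: a declarative network of free
species and complexes, each complex formed along an ordered path of
elementary association steps.  Five schemes cover the experimental
designs:

| scheme | complexes | steps |
|--------|-----------|-------|
| S1 | MA, MA₂ | K1 (high-affinity, HA), K2 (low-affinity, LA) |
| S2 | MA | K1 (apo-CaM, single site) |
| S3 | MB | KB (INAD single site) |
| S4 | MA, MA₂, MB | K1, K2, KB (competition, no ternary complex) |
| S5 | MA, MA₂, MB, MAB | S4 + K3 (CaM–INAD–dCRY ternary complex) |

Stepwise constants are macroscopic stoichiometric constants exactly as
the schemes state them; no statistical-factor conversion to microscopic
site constants is applied.  The alternative "independent ligand-site"
parameterization is not implemented — for well-separated events it
yields equivalent fits, and the stoichiometric form is the one the
bundled reference constants refer to.  A complex's cumulative constant
is the product of its path's stepwise constants, and its cumulative
enthalpy the sum of the step enthalpies.

## Speciation

Given total concentrations and stepwise constants, free and complex
concentrations satisfy mass action and mass balance,

$$[c] = \beta_c \prod_s [s]^{\nu_{cs}}, \qquad
T_s = [s] + \sum_c \nu_{cs}\,[c].$$

The solver works in log-free-concentration space with damped Newton
iterations (positivity is automatic, and conditioning is acceptable even
though the cumulative constants span 10³–10¹¹ M⁻¹), with a backtracking
line search on the scaled residual norm.  Convergence demands a maximum
relative mass-balance residual below 10⁻¹⁰ (configurable), with an
iteration cap of 200.  If Newton stalls, a nested-bisection fallback is
used: for any scheme in which every complex contains exactly one
receptor — true for all bundled schemes — the free receptor
concentration is an explicit function of the free ligands, and each
ligand balance is monotone in its own free concentration, so bisection
over free `A` with an inner bisection over free `B` brackets the unique
solution.  Complexes whose cumulative constant is zero (or that require
an absent species) are pruned before solving, which makes a reduced
scheme (e.g. S5 with K3 = 0) solve with arithmetic identical to its
smaller counterpart (S4) — bit for bit, not merely to tolerance.

```{r speciation}
st <- solve_speciation(binding_scheme("S2"), c(K1 = 1e6),
                       c(M = 1e-6, A = 1e-6))
st
```

## The ITC heat model

A `titration_protocol()` describes a perfusion-cell experiment: active
cell volume $V_0$ (default 1.4 mL, the standard VP-ITC cell), an
injection schedule (default 25 × 10 µL, within the 5–10 µL range such
experiments use), cell and syringe compositions in molar units.
Concentrations expressed in µM/mM are converted at the boundary
(`umol()`, `mmol()`); everything internal is molar and calories.

Each injection displaces a fraction $dV/V_0$ of the cell contents:
$C \leftarrow C\,(1 - dV/V_0) + C_{syr}\,dV/V_0$.  With the heat
content density $H_i = \sum_c \Delta H_c [c]_i$ (cal/L) at equilibrium
after injection $i$, the measured heat is

$$q_i = V_0\,(H_i - H_{i-1}) + dV_i\,\frac{H_i + H_{i-1}}{2}
      + Q_{dil}\,C_{syr}\,dV_i,$$

the middle term being the midpoint correction for the displaced volume
and $Q_{dil}$ a per-mole-of-injectant heat-of-dilution offset.  (The
alternative exponential dilution convention differs by <0.5% at
$dV/V_0 < 1\%$.)  Heats are reported per mole of injectant added, and
the nominal cell receptor concentration is scaled by the nuisance
parameter $r_M$ before the first injection.  A small priming injection,
customarily discarded from analysis, is simulated and flagged
`excluded`; flagged injections never enter any fit.

```{r isotherm}
pro <- titration_protocol(cell = c(M = umol(40)),
                          syringe = c(A = mmol(0.8)))
iso <- simulate_isotherm(binding_scheme("S1"),
                         ka = c(K1 = 1.71e7, K2 = 2.31e4),
                         dh = c(K1 = -3730, K2 = -4600), pro)
plot(iso)
```

A note on shape: with the reference constants the low-affinity event
has $c = K_{a2} M_t \approx 0.9$ at 40 µM cell concentration, so its
contribution is a broad tail rather than a distinct second step; the
smoothed second derivative of the model curve (see
`count_inflections()`) changes sign once, at the high-affinity
equivalence point.  A clearly resolved second inflection would require
cell concentrations an order of magnitude higher than such experiments
use.

## Fitting

`itc_fit()` estimates stepwise constants and enthalpies, plus $r_M$ and
$Q_{dil}$ per dataset, by bounded Levenberg–Marquardt least squares on
the molar heats (`minpack.lm`).  Association constants are optimized as
log₁₀(Ka) — positivity plus scale-invariance — with default bounds
log₁₀ Ka ∈ [0, 12] and $r_M$ ∈ [0.5, 2].  Several datasets may be fit
globally: step parameters are shared through their step labels, the
nuisance parameters stay per-dataset, and any parameter may be fixed
(e.g. `r_m = 1` when an isotherm lacks the sigmoidicity to determine
the stoichiometry, the usual treatment for weak binders).

Standard errors come from the linearized covariance (residual variance
times the inverse approximate Hessian at the optimum), with the delta
method mapping log₁₀ Ka errors to the natural scale; they are
approximate in the usual nonlinear-regression sense.  A fit is flagged
`degenerate` when there is no signal or when some parameter correlation
exceeds 0.999 (e.g. two equal association constants, which are not
separable by any fit).  Fit quality is summarized by

$$\mathrm{GoF} = 100\sqrt{\max(0,\,1 - \mathrm{SSR}/\mathrm{SST})},$$

a normalized percentage (100 = perfect, 0 = no better than the data
mean; undefined for constant data).  Commercial packages report a
goodness-of-fit percentage whose exact definition is unpublished, so
printed GoF values from the literature are treated as qualitative
ordering evidence, never as numeric targets.

```{r fit}
s2 <- binding_scheme("S2")
g <- gen_itc(reference_scenario("dcry_apo"), seed = 1)
fit <- itc_fit(g$dataset, start = c(ka_K1 = 1e4, dh_K1 = -1000),
               fixed = c(r_m_S2 = 1, q_dil_S2 = 0))
summary(fit)
```

## Thermodynamic conversions

$\Delta G = -RT\ln K_a$ with $R = 1.9872$ cal mol⁻¹ K⁻¹ and $T = 298$ K
exactly (not 298.15 — the convention the reference constants were
derived with), and $\Delta S = (\Delta H - \Delta G)/T$;
$K_d = 1/K_a$.  Derived quantities are reported to three significant
figures (`report_signif()`), matching how dissociation constants and
entropies are customarily quoted.

```{r thermo}
thermo_summary(ka = 1.71e7, dh = -3730)
```

## Chemical shift perturbations

For a titration followed by ¹⁵N-HSQC, the combined amide perturbation
of each residue between the reference (apo) and a bound-state point is

$$\mathrm{CSP} = \sqrt{\frac{\Delta\delta_H^2 +
  (0.14\,\Delta\delta_N)^2}{d}},$$

with nitrogen weight 0.14 and divisor $d = 2$ by default.  Both the
$d = 2$ and $d = 1$ conventions are in circulation, so $d$ is
configurable rather than hard-coded; the default follows the common
root-mean-square form.  Residues are called significant when their CSP
strictly exceeds the mean plus one standard deviation of the observed
CSPs (multiplier configurable).  Peaks missing from either list —
broadened beyond detection in slow/intermediate exchange — are carried
as `NA` and excluded from the mean/SD, never silently dropped.
`lobe_sums()` aggregates CSPs over the N-terminal lobe (residues 1–76)
and C-terminal lobe (81–148) by default, leaving the interdomain linker
(77–80) unassigned; the boundaries are configurable since lobe
definitions vary by a few residues across studies.  The perturbation is
computed final-point-minus-apo; intermediate points serve trajectory
plots, not the statistic.  Exchange-regime classification is not
automated: absent peaks are simply unobservable.

## Synthetic data

The generators exist so that every pipeline stage is testable offline,
and their defaults are the study conditions of the titrations they
emulate: 20–40 µM CaM in the cell, 0.4–0.8 mM peptide in the syringe,
5–10 µL injections (`reference_scenario()` bundles the exact designs
with the published best-fit constants).  ITC noise is i.i.d. Gaussian
on the integrated molar heats with a default standard deviation of 2%
of the maximum absolute model heat — a typical integrated-heat
signal-to-noise level; no published noise model exists for these
experiments.  All randomness flows through a single integer seed
(R's default Mersenne–Twister), recorded in the truth record, and equal
seeds give byte-identical output.

The NMR generator emulates fast exchange: observed shifts are
population-weighted averages of free and bound states with the bound
fraction from the 1:1 equilibrium, optionally with designated
slow-exchange residues rendered missing at bound fractions between 0.1
and 0.9.  The `inad_csp` scenario is a *synthetic* fixture whose
bound-state offsets are designed by a deterministic formula so that
exactly the 16 residues reported as significantly perturbed in the
INAD titration carry the largest perturbations and the C-terminal lobe
dominates — it emulates the published perturbation pattern
qualitatively and is never presented as measured data.

What passing tests on these generators do *not* show: real isotherms
carry correlated baseline drift, integration artifacts and
concentration errors beyond the scalar $r_M$; real spectra suffer
peak overlap and intermediate-exchange broadening.  Conclusions about
the estimators' behavior on such data require the usual caution.

## Numerical and design choices

* Speciation tolerance 10⁻¹⁰ relative (cap 200 iterations), both
  configurable; results are independent of starting point by
  construction (cold start at free = total).
* Fits are deterministic given identical data and starting values.
* Problem sizes in the validation suite: oracle agreement is checked
  over 500–1000 random draws; stochastic fit properties (model
  selection between the ternary and no-ternary schemes, Ka/ΔH
  recovery) use 20 seeded replicates of 25-injection isotherms at 2%
  noise, which characterizes the estimator while keeping the suite
  quick to run.
* Model selection between nested schemes is by SSR comparison at equal
  data; the ternary scheme contains the no-ternary scheme (K3 → 0), so
  a well-converged ternary fit can never do worse — failures of that
  ordering would indicate optimizer trouble, which is what the check
  guards against.

## Known limitations

* Kinetics (on/off rates), ionic strength and pH corrections, and
  explicit Ca²⁺ binding are out of scope; Ca²⁺ saturation is implicit
  in which scheme and constants apply.
* Heat-capacity (ΔCp) and temperature dependence are not modeled.
* Kd fitting from NMR shift trajectories is deliberately absent — in
  the fast-to-intermediate exchange regime with µM affinities such
  fits are unreliable.
* Uncertainties are linearized; no bootstrap or Bayesian treatment.
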