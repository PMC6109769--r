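# calbind

Multi-equilibrium binding analysis of calmodulin–peptide titrations by
isothermal titration calorimetry (ITC) and NMR.

## What it is for

Calmodulin (CaM) binds short amphipathic peptides from its target
proteins through Ca²⁺-exposed hydrophobic pockets.  When two ligands
compete — here a *Drosophila* cryptochrome C-terminal peptide (dCRY)
and an INAD scaffold peptide — a single titration curve is the
superposition of several coupled equilibria: sequential binding of two
dCRY peptides to the high-affinity (HA) and low-affinity (LA) sites,
single-site INAD binding, competitive displacement, and formation of a
CaM–INAD–dCRY ternary complex.  `calbind` is for researchers who need
to model and fit such isotherms, decide between competing reaction
schemes, and corroborate the picture with NMR chemical-shift
perturbations (CSPs).

The package provides:

* **Binding schemes** (`binding_scheme()`, `make_scheme()`): declarative
  reaction networks; five bundled schemes S1–S5 covering the designs
  above (species `M` = CaM, `A` = dCRY, `B` = INAD).
* **Speciation** (`solve_speciation()`, `species_distribution()`): the
  coupled mass-balance equations
  `[c] = βc Πs [s]^νcs`, `Ts = [s] + Σc νcs [c]`
  solved by damped Newton iteration in log-concentration space, with a
  nested-bisection fallback; residuals below 10⁻¹⁰ relative.
* **ITC model** (`titration_protocol()`, `simulate_isotherm()`):
  per-injection heats with perfusion-cell dilution bookkeeping,
  midpoint volume correction, heat-of-dilution offset `Q_dil` and
  receptor-concentration scale `r_M`:
  `q_i = V0 (H_i − H_{i−1}) + dV_i (H_i + H_{i−1})/2 + Q_dil C_syr dV_i`,
  with `H_i = Σc ΔHc [c]_i`.
* **Fitting** (`itc_fit()`): bounded Levenberg–Marquardt least squares
  on log₁₀ Ka, ΔH, `r_M`, `Q_dil`; single isotherms or global fits with
  step parameters shared across datasets; standard errors, goodness of
  fit `GoF = 100·sqrt(1 − SSR/SST)`, convergence and degeneracy
  diagnostics; `print`/`summary`/`coef`/`vcov`/`residuals`/`fitted`/
  `predict`/`plot`/`simulate` methods.
* **Thermodynamics** (`thermo_summary()`, `delta_g()`, `delta_s()`,
  `kd()`): ΔG = −RT ln Ka (R = 1.9872 cal mol⁻¹ K⁻¹, T = 298 K),
  ΔG = ΔH − TΔS, Kd = 1/Ka.
* **CSP analysis** (`combined_csp()`, `csp_profile()`, `lobe_sums()`):
  combined amide perturbations
  `sqrt((Δδ_H² + (0.14 Δδ_N)²)/2)`, significance at mean + 1 SD
  (strict), per-lobe aggregation (N: 1–76, C: 81–148 by default).
* **Synthetic data** (`gen_itc()`, `gen_nmr_titration()`,
  `reference_scenario()`): seeded generators emulating VP-ITC
  titrations (20–40 µM CaM, 0.4–0.8 mM peptide, 5–10 µL injections)
  and fast-exchange ¹⁵N-HSQC titrations of a 148-residue protein, with
  truth records for recovery studies.
* **I/O** (`read_isotherm_csv()`, `read_peaklist()` for CSV and
  Sparky-style lists, `write_fit_json()`, `write_csp_csv()`).

## Worked example

Generate a noisy synthetic two-site dCRY titration at the reference
constants (Ka₁ = 1.71×10⁷ M⁻¹, Ka₂ = 2.31×10⁴ M⁻¹, ΔH₁ = −3730,
ΔH₂ = −4600 cal/mol; 0.8 mM dCRY into 40 µM CaM, 25 × 10 µL) and fit
it:

```r
library(calbind)
g <- gen_itc(reference_scenario("dcry_ca"), seed = 1)
fit <- itc_fit(g$dataset,
               start = c(ka_K1 = 1e6, ka_K2 = 1e4,
                         dh_K1 = -2000, dh_K2 = -2000),
               fixed = c(r_m_S1 = 1, q_dil_S1 = 0))
summary(fit)
```

```
ITC fit: 1 dataset(s), schemes S1
Estimates:
   ka_K1    ka_K2    dh_K1    dh_K2
20840000    23580    -3722    -4503
SSR = 1.185e+05   GoF = 99.9%   (25 points, 4 free par.)

Coefficients (free parameters):
      estimate std_error
ka_K1 20840000 1.086e+07
ka_K2    23580 2.573e+03
dh_K1    -3722 3.474e+01
dh_K2    -4503 2.016e+02

Per-step thermodynamics (T = 298 K; cal, mol, M):
 step       ka        kd    dg    dh     ds
   K1 20839991 4.798e-08 -9980 -3722 21.000
   K2    23577 4.241e-05 -5962 -4503  4.896
```

Reading this: the HA-site constant is recovered to 0.09 log₁₀ units
(2.1×10⁷ vs 1.71×10⁷ M⁻¹, i.e. Kd 48 vs 58 nM — the HA constant is the
hardest parameter at this noise level, as its large standard error
shows), the LA constant to 2%, and both enthalpies to ~2%.  The derived
ΔS (+21.0 and +4.9 cal mol⁻¹ K⁻¹) matches the entropies published for
the two dCRY events (+20.6, +4.53).  `plot(fit)` overlays the fitted
curve on the points; `predict(fit)` returns the model isotherm.

Speciation along a competition titration (the concentration
distribution of CaM complexes as dCRY is titrated into CaM + INAD,
ternary scheme S5):

```r
ka <- c(K1 = 1.04e7, K2 = 1.02e4, KB = 9.95e3, K3 = 5.6e6)
traj <- data.frame(M = 40e-6, A = seq(0, 1.5e-4, length.out = 50),
                   B = 160e-6)
dist <- species_distribution(binding_scheme("S5"), ka, traj)
matplot(traj$A * 1e6, dist[, c("MA", "MA2", "MB", "MAB")] * 1e6,
        type = "l", xlab = "total dCRY (uM)", ylab = "complex (uM)")
```

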