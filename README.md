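# petpbpk

Whole-body physiologically based pharmacokinetic (PBPK) analysis of
dynamic mouse PET time-activity curves.

## What it is for

A 60-minute dynamic PET scan of a mouse yields time-activity curves
(TACs) for blood, liver, gallbladder + intestine, kidneys and peripheral
tissue. From these, `petpbpk` estimates organ-level pharmacokinetics:
hepatobiliary clearance CL_H, renal clearance CL_R, hepatic extraction
ratio E_H = CL_H/Q_P,H, the tissue/plasma distribution coefficient
D_Tissue, and plasma kinetics (CL = λ_z·V_z, t_1/2 = ln2/λ_z) — and
compares treatment groups (e.g. with vs without a transporter inhibitor
such as cyclosporine) by homoscedastic t-tests. It is aimed at
radiotracer developers and PK modellers who want a reproducible,
physiologically bounded whole-body compartment analysis rather than a
single-organ simplified model.

## The model

Nine first-order compartments (amounts, kBq): plasma B; hepatic H1
(reversible) → H2 (irreversible) → gallbladder/intestine G, with
enterohepatic reabsorption G → H1; renal R1 (adjacent to plasma,
excreting to urine U) ⇌ R2; two parallel tissue pools T1, T2; input is a
10-s zero-order infusion of the dose into B. Fitting minimises the
weighted sum of squared residuals of all regional amount curves
(early plasma/liver/kidney frames ×5) by bounded multistart
Levenberg–Marquardt, with uptake rates capped by plasma flow over plasma
volume. Clearances are functionals of the fitted rate constants, e.g.

    CL_H = k_BH1 · k_H1H2/(k_H1B + k_H1H2) · V_Plasma,
    V_Plasma = v_blood · (1 − hct) · BW.

The plasma curve is additionally fitted with the closed-form
two-compartment infusion model C(t) parameterised by (V_1, V_z, λ_1, λ_z).
A synthetic-scan generator (compartment simulation + observation model +
multiplicative lognormal noise) makes every stage testable without raw
images; see the methods vignette (`vignettes/pbpk-methods.Rmd`) for the
full model, assumptions and known identifiability limits.

## Worked example

```r
library(petpbpk)
phys <- physiology_constants()

# 1. synthetic control-like scan (CL_H 35, CL_R 11.9 µl/min truth; 5% noise)
scn <- scenario_presets(noise_cv = 0.05, seed = 7)$mt107_control_like
g <- generate_scan(scn, phys)

# 2. prepare curves, fit plasma model and whole-body model, derive PK
prep <- prepare_scan(g$scan, phys)
pfit <- fit_plasma(prep$c_plasma, g$scan, seed = 7)
fit  <- multistart_fit(prep, fit_config(n_starts = 16, seed = 7), phys)
derive_all(fit$best_params, g$scan, phys)
```

which prints (exact output of this seed):

```
CL_H 36.1 ul/min, CL_R 0.901 ul/min, CL 37 ul/min
E_H 0.036, CL_R/GFR 0.0056, CL_H/CL_R 40, D_Tissue 0.13
```

Read against the generating truth (CL_H 35.0, CL_R 11.9, D_Tissue 0.100):
CL_H and D_Tissue are recovered well; CL_R illustrates the documented
identifiability limit — at 5% noise a degenerate renal-exchange basin
fits the 60-min data better than the truth while implying a far smaller
steady-state CL_R. Noise-free, the same protocol recovers all three
within optimizer precision (see `tests/testthat/test-acceptance.R`).
Group studies (`run_study()`, `refine_and_refit()`) aggregate per-scan
results into a summary table with t-tests; the ~2-fold CL_H difference
between the two presets is detected at n = 4 per group in ≥ 8/10 seeded
repetitions.

## Command line

```sh
Rscript inst/cli/petpbpk-cli.R simulate-scan --preset mt107_control_like \
        --seed 1 --out scans/
Rscript inst/cli/petpbpk-cli.R fit-pbpk scans/mt107-control-like.csv --starts 32
Rscript inst/cli/petpbpk-cli.R run scans/*.csv --out report/ --seed 1
```

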