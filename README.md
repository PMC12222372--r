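# hepaflow

Hepatic blood flow (HBF) quantification from dynamic [¹⁵O]-water PET.

## The problem

The liver receives blood from two sources: the hepatic artery (the
minority share) and the portal vein (the majority). The standard
single-input one-tissue compartment model used for perfusion PET,

> dC_T/dt = f·C_A(t−Δt₁) − k·C_T(t),  C_PET = (1−V_B)·C_T + V_B·C_A,

sees only the arterial input C_A and therefore *systematically
underestimates* total liver perfusion. `hepaflow` implements a dual-input
model in which the portal input is **measured** from the image (a
portal-vein volume of interest) rather than modelled:

> dC_T/dt = f_A·C_A(t−Δt₁) + f_P·C_PV(t−Δt₂) − k·C_T(t),
> C_PET = (1−V_B)·C_T + V_B·(f_A·C_A + f_P·C_PV)/f,   f = f_A + f_P,

alongside two classical dual-input variants that replace the measured
portal curve with a notional dispersed compartment (one with a
spleen-calibrated arterial delay and a portosystemic shunting fraction E,
one with a single delay), so the four models can be compared on equal
footing with MRE, MSE and AIC on the original 24 acquisition frames.

Flows f, f_A, f_P are in mL/min/mL, washout k in 1/min, V_B is the
vascular volume fraction, delays are integer seconds. Derived quantities
are total flow f, the water partition coefficient V_T = f/k, and the
portal fraction f_P/f.

Fitting is unweighted least squares on a 1-s interpolated grid:
a Newton-type inner optimiser (`stats::nlm`) with constraint transforms
(absolute value for positive parameters, logit for fractions) and a
Levenberg–Marquardt polish, inside an exhaustive integer delay grid
search (default 0..65 s, two-dimensional for the two-delay models).
Everything else — TAC I/O, NIfTI VOI extraction with
largest-connected-component filtering and the 90th-percentile rule for
thin vessels, cohort statistics, and a synthetic-data generator — is
included so the full pipeline runs without patient data.

## Worked example

Simulate one subject at the default ground truth (f_A = 0.299,
f_P = 0.930, k = 1.603, V_B = 0.095, Δt₁ = 18 s, Δt₂ = 23 s; total flow
0.299 + 0.930 = 1.229 mL/min/mL) with 5% frame noise, then fit the
measured-portal-input model and the one-tissue baseline:

```r
library(hepaflow)
sub <- generate_subject(subject_spec(noise_fraction = 0.05, seed = 42L))
fit <- fit_hbf("new_dual_input", sub$tacs$liver, sub$tacs$aorta,
               pv = sub$tacs$portal_vein,
               config = fit_config(delay_min = 10, delay_max = 30))
fit
#> <hbf_fit 'new_dual_input': sse = 2.74181e+06>
#> <new_dual_input params: f_A=0.2613, f_P=1.017, k=1.646, V_B=0.1078, dt1=19, dt2=23>
#>   f_total = 1.278 mL/min/mL, V_T = 0.7765, portal fraction = 0.796
#>   MRE = 0.362, MSE = 0.03063 (kBq/mL)^2, AIC = -71.65

fit1 <- fit_hbf("1tcm", sub$tacs$liver, sub$tacs$aorta,
                config = fit_config(delay_min = 10, delay_max = 30))
fit1
#> <hbf_fit '1tcm': sse = 6.69987e+07>
#> <1tcm params: f=0.5336, k=0.6336, V_B=0.044, dt1=25>
#>   f_total = 0.5336 mL/min/mL, V_T = 0.8423, portal fraction = NA
#>   MRE = 0.882, MSE = 0.3231 (kBq/mL)^2, AIC = -19.12
```

The dual-input fit recovers the generating total flow within 4%
(1.278 vs 1.229) and the delays within 1 s, while the one-tissue model
underestimates total flow by more than half (0.534) with a far worse MSE
and AIC — the qualitative behaviour the model comparison machinery is
built to measure. (Both fits warn that one early near-zero frame is
excluded from the MRE; that is expected.)

VOI extraction from images works the same way end to end:

```r
ph <- generate_phantom_image(sub)   # small 4D phantom with a cold-rimmed PV box
tacs <- extract_study_tacs(ph$pet, ph$masks, ph$schedule)
fit_img <- fit_hbf("new_dual_input", tacs$liver, tacs$aorta,
                   pv = tacs$portal_vein,
                   config = fit_config(delay_min = 10, delay_max = 30))
```

A command-line interface with `fit`, `extract` and `simulate` subcommands
ships in `inst/cli/hepaflow.R`; see the vignette
(`vignettes/hepatic-blood-flow-modelling.Rmd`) for the model equations,
unit conventions, numerical choices, and the documented loop-closure
tolerances (2% on clean 1-s curves; 5% / ±2 s at frame level, where the
frame-averaging observation operator has a small systematic half-sample
distortion).

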