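# dragtag

Quantifying the energetic burden of externally attached telemetry tags on
anguilliform swimmers.

Eels migrate thousands of kilometres on an exceptionally efficient
whole-body undulatory swimming mode — which makes them exceptionally
sensitive to the hydrodynamic drag of externally attached tags (e.g.
pop-up satellite archival tags). `dragtag` is an R package for biologists
who design, evaluate or re-evaluate such tagging studies. It implements the
complete swim-tunnel workflow for measuring tag effects with calibrated
spherical drag dummies, and the resulting evaluation tool for predicting a
tag's burden in the field from two numbers: its drag force and its
attachment site.

## What it computes

**Drag physics.** Spherical dummies are sized from the sphere drag law
`F_D = ½ ρ V² c_D π (d/2)²` at a reference speed (0.65 m s⁻¹, the optimal
swimming speed of untagged silver eels), and empirical calibrations are fit
as through-origin polynomials `F(V) = αV² + βV`.

**Swimming energetics.** Oxygen-uptake rates (MO₂) from O₂-decline slopes
in a sealed swim tunnel, the exponential metabolic model
`MO₂ = SMR·e^(cU)`, and its closed-form endpoints: optimal swimming speed
`U_opt = 1/c` and minimum cost of transport `COT_min = SMR·c·e/3.6`
(mgO₂ kg⁻¹ km⁻¹). Tunnel speeds can be corrected for the solid blocking
effect, `U_F = U_T(1 + τλ(A_O/A_T)^{3/2})`.

**Critical swimming speed.** The Brett formula
`U_crit = U_i + ΔU·(T_i/ΔT)` over stepwise fatigue protocols.

**Kinematics.** Tail-beat frequency (cycle counting), peak-to-peak
amplitudes, body-wave speed (cross-correlation phase lag between
landmarks), the Strouhal number `St = a·f/U`, and their linear speed
regressions.

**The evaluation tool.** Per-individual percent effects against control
fit a through-origin quadratic in added drag, `E = a·F_D + b·F_D²`, one
curve per endpoint (%U_crit reduction: a = 102.8, b = 527.7; %COT_min
increase: a = −8.92, b = 2687), plus additive attachment-site penalties for
tags placed at the centre of mass.

**Synthetic cohorts.** A seeded generator (`simulate_swim_study()`)
produces complete virtual studies — O₂ traces, fatigue logs, landmark
trajectories, truth tables — with the published study conditions as
defaults, so the entire pipeline is verifiable end to end without animal
data.

## Worked example

Size the three standard drag dummies:

```r
library(dragtag)
round(100 * size_sphere(c(0.05, 0.1, 0.2)), 2)
#> [1] 2.56 3.62 5.12
```

Fit the metabolic model to oxygen-uptake samples and read off the
energetic endpoints:

```r
u <- seq(0.3, 0.9, 0.1)
m <- fit_metabolic_model(u, 40.58 * exp(u / 0.68))
m
#> Exponential metabolic model  MO2 = SMR * exp(c U)
#>   SMR = 40.58 mgO2 kg^-1 h^-1, c = 1.4706 s m^-1 (r^2 = 1.000, n = 7)
#>   Uopt = 0.680 m s^-1, COTmin = 45.06 mgO2 kg^-1 km^-1
```

SMR is the model's extrapolation to zero speed; `U_opt` is the speed with
the cheapest transport, and `COT_min` the cost there.

Evaluate a commercial satellite tag (0.159 N of drag) attached at the
traditional centre-of-mass site:

```r
ev <- evaluate_tag(tag_scenario(0.159, site = "B"))
ev$ucrit$total    # percent reduction of critical swimming speed
#> [1] 44.68598
ev$cotmin$total   # percent increase of minimum cost of transport
#> [1] 129.5118
```

The drag alone costs 29.7% of `U_crit` and raises `COT_min` by 66.5%; the
centre-of-mass placement adds another 15 and 63 percentage points. Such an
eel swims at roughly half its critical speed for nearly 2.3× the minimum
transport cost — the case for smaller tags at the anterior attachment site
(0.125 body lengths from the snout).

Run the whole pipeline on a simulated study:

```r
simulate_swim_study(cohort_config(seed = 1), out_dir = "study/")
report <- run_pipeline(run_config(min_r2 = 0.85), "study/")
report$impairment$ucrit   # fitted through-origin quadratic
```

A thin command-line wrapper with the same operations lives in
`inst/scripts/dragtag.R`.

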