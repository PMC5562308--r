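---
title: "Modelling the aging of copper added to soils"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the aging of copper added to soils}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cuaging)
```

## The problem

When water-soluble Cu is added to a soil — as a salt spike, a contamination
event, or a dosing treatment — it first partitions rapidly between the solid
and solution phases, and then its *lability* declines for years. Lability
here means the isotopically exchangeable pool (the E value), measured by
stable-isotope dilution: the fraction of the added Cu that still exchanges
freely with an enriched ^65^Cu spike. Risk assessments that use total Cu
overstate exposure in aged soils; a model of the lability decline lets
toxicity thresholds be corrected for time, soil chemistry and climate.

`cuaging` predicts `E_add`, the labile fraction of *added* Cu, from four
covariates: soil pH (measured in 0.01 M CaCl~2~), total organic carbon
(% w/w), absolute temperature, and time since addition.

## The model

Aging is decomposed into three loss channels,

$$E_{add} = 1 - Y_1 - Y_2 - Y_3,$$

which the model evaluates in the equivalent product form

$$E_{add} = e^{x}\,\mathrm{erfc}\sqrt{x}\;
  \Bigl[\,1 - \frac{B}{10^{pK^\circ - pH} + 1}\,t^{C/t}
          - F\,\frac{C_{org}}{100}\,t^{G/t}\Bigr],
  \qquad x = N e^{K/T} t .$$

* **Precipitation/nucleation** ($Y_1$): a fast loss proportional to the
  CuOH^+^ fraction of dissolved Cu, $1/(10^{pK^\circ-pH}+1)$, which rises
  with pH. The kinetic factor $t^{C/t}$ approaches 1 as $C \to 0$; the
  reference fit has $C = 0$, i.e. the process is complete within days and
  contributes a time-independent offset.
* **Occlusion** ($Y_2$): entrapment within soil organic matter, linear in
  organic carbon, with its own kinetic factor $t^{G/t}$ (reference $G = 0$).
* **Diffusion** ($Y_3$): slow migration of Cu into micropores and
  mesopores, modelled as diffusion in a plane sheet from a stirred solution
  of limited volume. The surviving (still-labile) fraction is
  $S(x) = e^{x}\mathrm{erfc}\sqrt{x}$. Its two limits connect the earlier
  single-regime descriptions: for small $x$, $1 - S(x) \approx
  2\sqrt{x/\pi}$ (square-root-of-time kinetics, the short-term limit); for
  large $x$, $S(x) \approx 1/\sqrt{\pi x}$, a slow decay that tracks
  logarithmic-in-time aging over practical windows. The temperature enters
  through an Arrhenius factor folded into $x$.

### Parameters

| Symbol | Meaning | Unit | Reference value |
|---|---|---|---|
| `B` | precipitation/nucleation coefficient | – | 1.14 |
| `C` | fast-process kinetic scale | day | 0 |
| `N` | diffusion pre-factor $D_0/\alpha^2 l^2$ | day^-1^ | 214.91 |
| `F` | occlusion coefficient | – | 2.85 |
| `G` | occlusion kinetic scale | day | 0 |
| `K` | $-E_a/R$ | K | −4330 |
| `pK0` | first hydrolysis constant of Cu | – | 7.7 |

`K = -4330` corresponds to an activation energy of 36 kJ/mol
(`round(arrhenius_k(36))`). The mechanistic constants $D_0$, $E_a$, $\alpha$
and $l$ are *not* separately identifiable from E-value data; only the
composites `N` and `K` are modelled, deliberately. `pK0` is fixed at the
bulk-solution value 7.7 by default; freeing it (see below) typically lands
near 6.65, consistent with soil surfaces promoting hydrolysis.

## Conventions and numerical choices

* **Time unit** is days throughout; readers accept a `time_years` column
  and convert at 365 d/y (leap-day precision is far below model error).
* **t = 0** returns `E_add = 1` exactly — nothing has aged. For $t \to 0^+$
  with $C > 0$ the kinetic factor $t^{C/t}$ tends to 0, which is the limit
  used if it is ever evaluated there.
* **Clamping.** With the reference `B` and `F`, high-pH organic-rich soils
  can drive the bracket $1 - Y_1 - Y_2$ negative; it is clamped to
  $[0, 1]$, the row is flagged in the `clamped` column, and a single
  warning summarises the count. `E_add` is a fraction and stays in
  $[0, 1]$ always.
* **Scaled erfc.** $S(x)$ is computed through the exponentially scaled
  complementary error function, never as a literal product (exp overflows
  past $x \approx 700$). `pracma::erfcx` is used for $\sqrt{x} \le 20$ and
  a 10-term Laplace asymptotic series beyond; the branches agree to
  ~1e-15 at the crossover and the whole range $x \in [10^{-8}, 10^8]$ is
  verified in the tests against adaptive quadrature of the defining
  integral to better than 1e-9 relative.
* **Temperature for outdoor aging** is the arithmetic mean over the aging
  period: the occlusion/diffusion response is nearly linear in
  temperature over 253–323 K, so the mean is an adequate summary.

## Fitting

`fit_aging_model()` minimises the weighted residual sum of squares of
observed minus predicted `E_add` under box constraints
(`B, C, N, F, G >= 0`, `K <= 0`, `pK0` in [3, 10]), with `K` and `pK0`
fixed by default. The optimiser is bounded Levenberg–Marquardt
(`minpack.lm::nls.lm`, ftol = ptol = 1e-10) with a quasi-Newton polish
(`stats::nlminb`, rel.tol = 1e-15) and a final LM restart: the polish
matters because finite-difference LM alone stalls ~1e-4 above the optimum
in the flat valley around the solution, and with it all multi-starts agree
to ~1e-15. Multi-start (default 10, seeded) draws `B, F` uniform on
[0, 3], `C, G` uniform on [0, 10], `N` log-uniform on [10^-2^, 10^4^], and
`pK0` uniform on [3, 10] when free.

**Trend anchors.** Incubation datasets rarely extend beyond a year, so the
extrapolation to decades is controlled by pseudo-observations at 3600 and
7200 days whose target E values come from an external long-horizon model.
Anchors enter the objective with their own weights (default 1) but are
excluded from the reported R² and RMSE, which describe the real
observations only. Hard-constraint anchoring was considered and rejected:
pseudo-observations keep the objective smooth, let the user weight the
anchors' reliability, and reduce to the unanchored fit when absent.

**Goodness of fit.** `R² = 1 − SSres/SStot` on the pooled observations and
`RMSE = sqrt(SSres/n)` with denominator `n` (not `n − p`); both choices
are the simplest readings of a single reported statistic and are recorded
here so comparisons are interpretable.

**Free pK°.** `fit_free_pk()` adds `pK0` to the free set. With `B` fixed
at 0 the precipitation term vanishes and `pK0` is unidentifiable; the
function warns in that case.

## Isotope dilution

`e_value()` implements the dilution equation
$E = R\,\frac{AM(Cu_{nat})}{AM(^{65}Cu)}
\frac{IR_{sp}-IR_{meas}}{IR_{meas}-IR_{nat}}(IR_{nat}+1)$ with
`IR_sp = 0.5/99.5` and a default natural ratio `IR_nat = 2.2435`,
overridable per measurement since the natural ratio may be determined
per soil solution. E is strictly *increasing* in `IR_meas` on
(`IR_sp`, `IR_nat`): more exchange dilutes the spike further toward the
natural ratio, and the equation diverges as `IR_meas` approaches
`IR_nat` (no dilution detected — an error, not a number).
`added_e_fraction()` converts paired spiked/control E values to the labile
fraction of the addition; out-of-range fractions are flagged but kept
unclamped so raw measurements survive for quality control.

## The synthetic-data harness

`generate_soils()` draws pH, organic carbon and temperature uniformly and
independently over the study ranges (pH 2.98–7.52, C~org~ 0.41–23.32 %
w/w, 278–298 K — temperate annual means) and time log-uniformly over
1–30000 days so both aging regimes are populated.
`simulate_observations()` adds Gaussian noise on the E fraction, clipped
to [0, 1] with the clip count reported; additive noise at sd ≈ 0.02–0.11
matches the dispersion seen in incubation E values. What the generator
does **not** emulate: pH–organic-carbon correlation (real soils have
some), weather-driven temperature variation, moisture effects, microbial
activity, and measurement error in the covariates. Passing recovery tests
therefore demonstrate that the estimator is consistent under the model's
own assumptions — not that field data are this clean.

`recovery_experiment()` wraps generate → simulate → fit and reports bias,
relative RMSE and boundary hits per parameter. At the harness conditions
used in the tests and the acceptance script (n = 200 soils, noise sd
0.02, multi-start 6), `B`, `N` and `F` come back within a few percent and
`C`, `G` pile at their zero boundary when the truth has `C = G = 0`.
These problem sizes keep the full suite under a minute while leaving the
recovery tolerances comfortably slack.

The long-term *refit* exercised by the tests runs on a synthetic
stand-in: 200 observations confined to a 1–360 day outdoor-style window
plus 3600/7200-day anchors computed from the reference parameters. It
validates the refit *procedure* (constraints, anchor plumbing, fixed
`K`/`pK0`) by parameter recovery, not by matching any published fit
statistic — those depend on the original incubation measurements, which
this package does not ship.

## Field validation

`field_soils()` returns 20 field-contaminated European soils (Hygum,
Woburn, Wageningen, Italy, Hungary; 8–78 years of aging under ambient
conditions) with measured labile fractions; the file is checksum-pinned.
`validate_field()` compares reference-parameter predictions with the
measurements:

```{r field}
v <- validate_field()
v$mae        # mean absolute error on the E fraction
v$pearson_r  # correlation of predicted with measured
```

The bar is deliberately coarse (MAE < 0.15, positive correlation): the
field soils carry uncontrolled moisture, microbial and temperature
histories, and several sites have total Cu far above the dosing level the
model was calibrated for.

## Known limitations

* Only water-soluble Cu additions: sludge, manure or organic-fertiliser
  Cu ages through different reactions and is out of scope.
* Moisture, microbial activity and plant uptake are not modelled.
* Speciation is the two-species Cu^2+^/CuOH^+^ partition only.
* No uncertainty quantification on fitted parameters (point estimates
  with convergence and KKT diagnostics only).
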