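---
title: "Assessing heavy-metal contaminated soils: indices, exposure doses and multi-organ hazard"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing heavy-metal contaminated soils}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soilhmrisk)
```

## The problem

Karst-region agricultural topsoil carries naturally elevated heavy-metal
loads, augmented by mining and smelting. Given a soil survey — one composite
sample per site with pH and total As, Cd, Cr, Hg and Pb (mg/kg) — the
questions a public-health assessor asks are, in order: how contaminated is
the soil relative to regulatory and geochemical baselines; how much risk
does it pose to the ecosystem; and how much hazard and cancer risk does it
pose to people, deterministically, probabilistically, and organ by organ.
`soilhmrisk` implements that chain end to end, with all reference constants
shipped as editable CSV tables rather than hard-coded in formulas.

## Pollution indices

For a sample with concentration $C_i$ and the screening value $S_i$ of its
pH class, the single-factor index is $PI_i = C_i / S_i$. Screening values
come from the Chinese soil environmental quality standard GB 15618-2018 and
depend on the pH class; the class intervals are right-closed exactly as the
standard prints them ($\mathrm{pH} \le 5.5$, $5.5 < \mathrm{pH} \le 6.5$,
$6.5 < \mathrm{pH} \le 7.5$, $\mathrm{pH} > 7.5$), so a sample at pH 5.5
belongs to the most acidic class. The Nemerow composite
$$P_N = \sqrt{\tfrac{1}{2}\left(\overline{PI}^2 + PI_{max}^2\right)}$$
emphasises the worst pollutant. The geoaccumulation index
$I_{geo} = \log_2\!\left(C_i / (1.5\,B_i)\right)$ compares against the
geochemical background $B_i$, with the conventional factor 1.5 absorbing
natural lithogenic variation; it isolates anthropogenic enrichment.

The scope of $\overline{PI}$ and $PI_{max}$ is ambiguous in survey work:
some studies compute $P_N$ per sample across metals, others once for the
whole survey from per-metal mean PIs. `assess_pollution()` reports both,
labelled `nemerow` (per sample) and `survey_pn`, because the two answer
different questions and a single survey-level figure hides the upper tail
of the per-sample distribution.

Exceedance rates are reported against both baselines — screening values
(pH-class dependent, per class and overall) and background values — since
survey reports use both comparisons and they differ by an order of
magnitude for metals, such as Hg, whose background is far below the
screening level. Summary SD uses the $n-1$ denominator by default
(conventional for survey statistics) and is switchable to $n$.

## Ecological risk

Hakanson's per-metal risk $E_r = T_i \cdot C_i / S_i$ weighs the
concentration ratio by a toxic response factor
($T$: As 10, Cd 30, Cr 2, Hg 40, Pb 5), and $RI = \sum E_r$. The reference
denominator is a genuine design fork: the risk equation is often printed
with the screening value $S_i$, while classical Hakanson practice uses the
background $B_i$. The package defaults to the screening value, the printed
form of the equation it implements, and exposes
`ecological_risk(denominator = "background")` for the classical choice;
neither ordering of survey-level mean $E_r$ should be over-interpreted,
since per-sample distributions dominate it. RI below 80 is classified low
risk; band tables for all five indices ship as data and are editable.

## Deterministic exposure and risk

Average daily doses for ingestion, inhalation and dermal contact follow the
USEPA equations (see `?add_ingestion`), with the exposure profiles for
adults and children bundled as `exposure_parameters.csv` (soil ingestion
rate 100/200 mg/d, inhalation 14.5/7.5 m$^3$/d, exposure frequency 350
d/yr, body weight 64.3/19.2 kg, skin area 5700/2800 cm$^2$, adherence
0.07/0.2 mg/(cm$^2$ d), dermal absorption fraction 0.001, particle emission
factor 1.36·10$^9$ m$^3$/kg). Per-metal, per-pathway reference doses and
slope factors live in `toxicity_reference.csv`. Hazard quotients are
$HI = \sum_{pathways} ADD/RfD$ and cancer risks $CR = \sum ADD \times SF$;
totals THI and TCR are exact sums over metals.

Two conventions deserve explicit statement:

* **Averaging time.** The bundled profiles set the carcinogenic averaging
  time equal to the non-carcinogenic one, AT = ED × 365 d. The usual
  USEPA alternative (lifetime averaging for carcinogens) is a one-line
  change in the exposure table; the bundled choice is the one under which
  the bundled toxicity tables reproduce the reference risk table this
  package is calibrated against.
* **Absent parameters.** Several metal/pathway cells genuinely lack an RfD
  or SF (no inhalation RfD for Hg or Pb, no slope factors at all for Hg,
  no dermal SF for Cd or Pb). Absence is an explicit `NA` in the table,
  never a zero; absent cells contribute exactly zero to aggregates, are
  reported as `NA` in outputs, and the skipped set is printed once per
  run.

```{r}
conc <- c(As = 9.08, Cd = 0.36, Cr = 73.06, Hg = 0.13, Pb = 28.14)
risk <- deterministic_risk(conc, quiet = TRUE)
risk$totals[, c("population", "THI", "TCR")]
```

All risks are linear in concentration, children's risks exceed adults' for
every metal under the bundled profiles, and results are carried at full
precision (rounding only at presentation).

## Probabilistic (Monte Carlo) risk

`run_monte_carlo()` replaces point inputs by distributions and pushes
10,000 joint draws (the default; the draw count is an argument) through the
same dose kernel as the deterministic path, so degenerate point-mass
specifications reproduce deterministic results to machine precision — a
property the test suite asserts rather than assumes.

Distribution choices, made once and documented here:

* **Concentrations**: truncated lognormal per metal, moment-matched to the
  bundled survey's mean/SD and truncated at its observed min/max. The
  matching targets the moments of the *truncated* law (a Nelder–Mead
  search from the closed-form untruncated start), because matching the
  parent law and then truncating visibly biases the mean — about −3% for
  Cr with these bounds.
* **Soil ingestion rate**: lognormal with CV 0.6, the variability scale
  tracer studies report for soil ingestion; no truncation (positive
  support already).
* **Body weight**: truncated normal (adults 64.3 ± 10.5 kg on [40, 100];
  children 19.2 ± 3.2 kg on [10, 35]), CV ≈ 0.16 as in exposure-factor
  handbooks.
* **Everything else**: point values. Parameters for which no defensible
  variability estimate exists are not given token distributions.
* Draws are independent: no credible correlation structure among exposure
  parameters is available, and imposing one without data would be
  decorative.

Sampling is by inverse CDF with the CDF rescaled to the truncation
interval, so bounds are honoured exactly (no accept–reject loops) and a
seed fixes the entire draw matrix bit-for-bit. Exceedance probabilities use
strict inequality; at $10^4$ draws the boundary mass is negligible.
Contribution shares are ratios of mean HIs and sum to 100% by construction.

Survey-level exceedance probabilities (e.g. the fraction of draws with
THI > 1) depend strongly on the concentration distribution; with only
summary moments available they are reproducible in direction and order of
magnitude, not digit-for-digit, and the package treats them accordingly.

## Target-organ toxicity dose (TTD) hazard

Traditional HI uses one critical-effect RfD per metal; real mixtures injure
several organ systems at once, so the TTD refinement computes
$HI_{TTD}(i,k) = ADD_{ing}(i) / TTD(i,k)$ per metal $i$ and organ $k$ and
sums dose-additively within each of five systems (neurological, renal,
cardiovascular, hematological, testicular). Only ingestion feeds the
default assessment — it dominates the dose — and other pathways can be
switched on. Hg is absent from the endpoint table (organ-specific endpoint
data for it are sparse) and is excluded with a warning.

The bundled endpoint file `ttd_endpoints_calibrated.csv` is, as its name
says, *calibrated*: organ-level toxicity endpoints are scattered across
agency mixture profiles and are not reproduced here verbatim; instead the
table is constructed to be consistent with the reference survey's published
per-metal and per-organ cumulative hazards and with the documented organ
sensitivities (As → neurological/cardiovascular, Pb → renal,
Cr → hematological/testicular, Cd → renal). Every endpoint is at or below
the corresponding chronic RfD, so the per-metal multi-organ hazard is
always at least the single-endpoint ingestion HI; users with preferred
agency endpoints should substitute their own file. The grand total
$THI_{TTD}$ is identical whether accumulated metal-first or organ-first,
and the package tests that conservation on random tables.

## The synthetic survey generator

No per-sample field data ship with the package; `generate_survey()` stands
in for them. It emulates:

* per-metal truncated-lognormal concentrations whose truncated moments
  match the bundled 740-sample survey's min/max/mean/SD (lognormal because
  trace-element surveys are positive and right-skewed, with CVs of 29–59%
  here; a truncated-normal law is a fallback and a switch);
* truncated-normal pH (6.14 ± 0.96 on [3.84, 8.06]);
* a negative pH–Cd dependence via a Gaussian copula on ranks, default
  correlation −0.3 — the direction is well-established (Cd is more soluble,
  hence more retained in the exchangeable pool, in acid soils) while the
  magnitude is a documented calibration knob, chosen so the Cd exceedance
  gradient across pH classes is qualitatively reproduced;
* prefecture labels drawn with the reference survey's sampling weights,
  and unit-square coordinates, optionally rank-coupled to total load so a
  smooth hotspot appears.

What it does **not** emulate: real geography or spatial autocorrelation
(coordinates are synthetic), inter-metal correlations beyond the pH–Cd
pair, analytical error, or the true (unknown) marginal shapes — only the
first two moments and the support are matched. Passing tests therefore
demonstrate correctness of the computational chain under a realistic but
idealised data-generating process, not agreement with any particular field
campaign beyond its summary table. `fit_generator()` inverts the process
(moment-matching a spec to an arbitrary survey, with a slight 2% padding of
the observed range for feasibility), and generate → fit → generate is a
fixed point up to sampling error.

## Numerical choices and degenerate inputs

* Truncated-moment matching solves a two-parameter system by Nelder–Mead
  (relative tolerance 10⁻¹⁴ on the objective, acceptance at 10⁻⁵ on each
  moment) and fails loudly — with the achieved moments in the message —
  when the target is infeasible, e.g. an SD larger than the truncation
  interval can support, or a mean outside the bounds.
* Zero concentrations are valid dose inputs (zero dose); zero or negative
  exposure parameters are domain errors naming the parameter.
* Zero-variance columns in `fit_generator()` become point distributions,
  with a warning.
* Classification at band boundaries is right-closed (a value equal to an
  upper bound takes the lower band's label), matching how the regulatory
  tables print their inequalities.
* All survey I/O parses numbers with base R's correctly-rounded reader, so
  write → read round-trips are bit-identical.

## Problem sizes used by the shipped checks

The test-suite and reproduction scripts run the generator at n = 740 (the
reference survey size) and n = 10⁵ for convergence checks, and the Monte
Carlo engine at 10⁴ draws (default) with the package's documented default
seed 20170740. These sizes make every moment-recovery and
stochastic-tolerance assertion comfortably stable while keeping a full run
in seconds.

## Known limitations

* Bioavailability is not modelled; doses use total concentrations, which
  overstates absorbed dose in most soils.
* No formal sensitivity analysis (Sobol, rank-correlation tornado) is
  included; the Monte Carlo engine exposes its draw matrices so one can be
  layered on.
* The Er survey-level ordering and the probabilistic exceedance
  probabilities are distribution-sensitive and only qualitatively
  reproducible from summary moments.
* Regional labels are carried as metadata only; no computation is
  stratified by region.
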