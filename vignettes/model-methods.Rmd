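---
title: "Model methods: dual-engine cost-effectiveness of sac-TMT versus chemotherapy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model methods: dual-engine cost-effectiveness of sac-TMT versus chemotherapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psmarkov)
```

## The decision problem

`psmarkov` models the cost-effectiveness, from the Chinese healthcare-system
perspective, of sacituzumab tirumotecan (sac-TMT, a Trop-2-directed
antibody-drug conjugate) against platinum-based chemotherapy as second-line
treatment for advanced EGFR-mutant non-squamous NSCLC after EGFR-TKI
failure.  A simulated cohort moves through three mutually exclusive health
states — progression-free (PFS), progressed disease (PD), and death — and
accrues direct medical costs (2025 USD) and quality-adjusted life years.
The same decision problem is evaluated by two engines so that structural
uncertainty from model choice is visible rather than hidden:

* a **partitioned survival model (PSM)**, in which state occupancy is read
  directly off the parametric PFS and OS curves
  (`share_pfs = min(S_PFS, S_OS)`, `share_pd = max(0, S_OS - S_PFS)`,
  `share_dead = 1 - S_OS`), and
* a **Markov cohort model**, in which occupancy evolves through per-cycle
  transition probabilities derived from the same curves.

Both engines share one clock: 28-day cycles over a 10-year horizon (130
full cycles), with costs and outcomes discounted at 5% per year and
half-cycle-corrected (trapezoidal) state membership.  The willingness-to-pay
threshold is three times 2025 per-capita GDP, \$41,811/QALY.

## Survival inputs

Survival is parametric, on a month axis (1 month = 365.25/12 days).  The
base case uses the best-fitting families for each arm and endpoint:

| Arm | Endpoint | Family | Parameters |
|---|---|---|---|
| sac-TMT | OS | log-logistic | shape 1.538, scale 27.354 |
| sac-TMT | PFS | log-normal | meanlog 2.20, sdlog 0.999 |
| Chemotherapy | OS | Weibull (PH) | shape 1.599, rate 0.007 |
| Chemotherapy | PFS | log-logistic | shape 2.420, scale 4.590 |

The shape/scale reading of these printed parameter pairs is a deliberate
choice: it reproduces the trial's observed medians.  The log-logistic
median equals its scale, so sac-TMT median OS is 27.4 months (consistent
with a median "not yet reached" at data cutoff), chemotherapy median OS is
$(\ln 2 / 0.007)^{1/1.599} = 17.7$ months against an observed 17.4, and
chemotherapy median PFS is 4.59 months — all plausible only on a month
scale, which fixes the time unit.  The parameterization is a constructor
argument (`surv_dist()`), so alternatives can be explored.

The fitting path (`fit_parsurv()`, `select_best_fit()`) maximizes the
right-censored log-likelihood for all seven candidate families
(exponential, Weibull-PH, Gompertz, log-logistic, log-normal, gamma,
generalized gamma) via `flexsurv`, and selects by lowest AIC, with BIC
breaking exact ties and AIC governing (with a logged message) when the two
criteria disagree.

Pseudo individual-patient data can be rebuilt from digitized
Kaplan–Meier coordinates plus numbers at risk (`reconstruct_ipd()`),
inverting the product-limit construction interval by interval in the
Guyot style.  Digitization jitter that makes survival rise by at most
0.005 is removed by an isotonic pass (logged); larger rises are treated
as data errors.  Without a total-event count the final interval assumes
no censoring before end of follow-up; with one, events are proportionally
rescaled in a final pass.

## The Markov transition schedule

The study text fixes only one transition directly: PFS→death equals the
background mortality, a crude annual rate of 8.04‰ converted to a 28-day
probability through the rate scale ($r=-\ln(1-p)$,
$p_{28}=1-e^{-28r/365}$, giving $6.19\times10^{-4}$).  The remaining
construction is our concrete, auditable reading:

* PFS exit per cycle is the interval probability of the PFS curve,
  $1 - S_{PFS}(t+\Delta)/S_{PFS}(t)$; the background probability is capped
  at that exit and PFS→PD takes the remainder (the floor prevents a
  negative PFS→PD in early cycles).
* PD→death *closes the OS curve*: each cycle it supplies exactly the
  deaths needed to keep cumulative cohort mortality on $1-S_{OS}$, net of
  deaths out of PFS, divided by the running PD occupancy and clamped to
  $[0,1]$.

A literal per-cycle version of that closure (allocating only the current
cycle's OS-curve deaths, and only from PD) cannot track the OS curve: at
cycle 0 the PD state is empty, so the first cycle's deaths would be lost
permanently.  We therefore target *cumulative* mortality and, when PD
occupancy cannot absorb the requirement (notably the start-up cycles),
route the overflow through PFS→death beyond the background floor, capped
at the total PFS exit probability.  Both clamping and overflow are counted
in the run log.  With this closure the cohort death share tracks
$1-S_{OS}$ to within $7\times10^{-4}$ on the base-case curves, and the two
engines coincide to machine precision for exponential curves on a common
time grid — a useful structural check, since memorylessness makes the two
formulations mathematically identical there.

**Curve-time grid.**  The schedule can read the fitted month-scaled curves
either at the true cycle length (0.9199 months per 28-day cycle;
`markov_grid = "calendar"`) or at integer cycle indices
(`markov_grid = "cycle"`, the default), i.e. treating one cycle as one
month of curve time while calendar time (discounting, accrual) stays on
the 28-day clock.  The cycle-index grid is the convention we recover from
the original analysis's printed Markov results (it reproduces the sac-TMT
Markov QALY total to within 0.003, where the calendar grid misses the
printed incremental QALYs by more than its own reporting precision); it is
also the natural behaviour of stage-indexed transition formulas in common
decision-tree software.  The calendar grid remains available and is used
by the engine-equivalence checks.  The PSM always uses calendar time.

## Economic inputs

Resource use is computed for a reference patient of 65 kg, 1.72 m² body
surface area and creatinine clearance 70 mL/min.

**Dosing.**  sac-TMT 5 mg/kg on days 1 and 15 of each 28-day cycle
(325 mg, two administrations per cycle).  Chemotherapy: pemetrexed
500 mg/m² (860 mg) plus carboplatin at AUC 5 by the Calvert formula
(5 × (70 + 25) = 475 mg) on day 1 of each 21-day cycle for four induction
cycles (84 days = exactly three model cycles), then pemetrexed
maintenance.  The 21-day regimen is converted to a daily rate and accrued
per 28-day model cycle, keeping a single model clock.  Drug costs accrue
only while progression-free (treatment to progression).

**Vial arithmetic.**  `vial_strategy = "exact"` (dose-proportional cost)
is the default; `"round_up"` (whole vials, no sharing) is available.  The
exact strategy is not a guess: the original analysis's own base-case and
reimbursement-scenario totals differ by 46.97 × (price difference per
200 mg), which equals the discounted PFS time multiplied by 3.25 fractional
200-mg units per cycle — exactly the dose-proportional cost of 2 × 325/200
units, and inconsistent with whole-vial rounding (4 vials per cycle).

**Follow-up bundle** (per PFS cycle; the itemization is a documented
default, as the original frequencies are unpublished): one consultation,
complete blood count, blood biochemistry and urinalysis per cycle; CT
every 2 cycles and MRI every 3 cycles as per-cycle averages; injection +
preparation fees and one nursing + bed day per administration.

**Progressed disease.**  BSC at \$436.19 per cycle, plus a per-strategy
subsequent-treatment mix over pemetrexed and osimertinib.  The published
report does not print the subsequent-therapy proportions, so the mix is
the calibration knob for the otherwise-undetermined PD costs.  The
committed values — sac-TMT arm 100% BSC; chemotherapy arm BSC plus an 18%
osimertinib weight (≈\$117/cycle) — minimize the squared deviation of the
four base-case total costs (two engines × two arms) from the published
table, and are fixed in `base_case_spec()`.  Backing PD costs out of the
published sac-TMT totals gives ≈\$430 per PD cycle, which is why the
follow-up bundle is not additionally charged in PD.

**Adverse events.**  Only grade ≥3 treatment-related events with ≥5%
incidence enter: anaemia, leukopenia, neutropenia, thrombocytopenia.  Both
the management cost and the disutility are applied once, at model entry,
as incidence-weighted expectations (e.g. sac-TMT arm cost
0.11×448.56 + 0.28×421.40 + 0.40×406.56 + 0.02×2937.46 = \$388.71).  The
disutility expectation (sac-TMT −0.1478, chemotherapy −0.1506) is applied
as a one-off *absolute* QALY decrement (`ae_disutility_once = TRUE`): the
published QALY totals are reproduced to <0.01 QALY under this accounting
and miss by ~0.15 QALY if the decrement is scaled by one cycle length, so
we adopt the former as the original study's convention.  Scaling by one
cycle is available as the alternative setting.

## Discounting and accrual conventions

Per-cycle accrual multiplies the trapezoidal membership
$\tfrac12(m_k + m_{k+1})$ by the state utility (or cost), the cycle length
in years (28/365.25), and a continuous-in-cycle discount factor
$(1.05)^{-t_{mid}/12}$ evaluated at the interval midpoint in months.  The
half-cycle correction is applied in *both* engines — the symmetric
treatment avoids manufacturing a spurious engine discrepancy — and
`accrual = "start"` is available for sensitivity.  Halving the cycle
length moves base-case QALY totals by <0.5%, so discretization error is
immaterial at 28 days.

## Uncertainty analysis

**One-way (tornado).**  Every tabulated parameter is varied alone over its
range (published ranges where stated, ±20% otherwise; discount rate 0–8%)
and the ICER recomputed deterministically; entries are sorted by spread,
and variations producing non-positive incremental effect are flagged
rather than dropped.  In the base case the largest spreads belong to the
PD utility, the sac-TMT vial price, the PFS utility, the discount rate,
and the sac-TMT-arm neutropenia incidence, and no tested variation brings
the ICER below the \$41,811 threshold.

**Probabilistic.**  A second-order Monte Carlo draws cost parameters from
Gamma and utility/disutility/probability parameters from Beta
distributions, moment-matched to mean = base and sd = (high − low)/3.92
(ranges read as 95% intervals; the original report states ranges but not
SDs).  Disutilities are drawn as Beta on the magnitude and negated.
Survival-curve parameters carry no published distribution and are held at
base — a logged limitation; curve-level uncertainty is reachable through
scenarios instead.  Draws are made parameter-by-parameter in the fixed
`param_table()` row order from one seeded generator, so the full run is
bit-reproducible from (spec, n, seed).  Infeasible Beta moments fall back
to uniform(low, high) with a warning.

**A known reproduction gap.**  The original report states that the
probability of cost-effectiveness is 0% at thresholds up to \$70,155 and
100% at \$96,180–\$100,380.  That step-function CEAC implies essentially
zero dispersion in the ICER draws, which is incompatible with the
published utility ranges (PD utility 0.031–0.473 alone gives the
incremental QALYs a standard deviation near 0.09) under the range/3.92
reading — or any standard reading — of the input table.  Our seeded PSA
reproduces the 0% statement at \$41,811 but yields ≈80%, not 100%, at the
Beijing threshold; the acceptance suite asserts the published value and
records the failure openly rather than tuning the dispersion away.

## Scenarios

* **Reimbursement price**: the sac-TMT price is replaced by the
  NRDL-negotiated \$637 per 200 mg, all else at base.  Price-only
  overrides leave QALYs bit-identical by construction.
* **GDP-multiple thresholds**: 1×/2×/3× per-capita GDP
  (\$13,937/\$27,874/\$41,811, derived from the published 3× figure).
* **Regional thresholds**: three times regional per-capita GDP — Beijing
  \$100,380, Shanghai \$96,180, Jiangsu \$70,155, Zhejiang \$59,532 —
  evaluated on the base-case PSA sample.

## The synthetic-data generator

`sim_spec()`/`simulate_ipd()` emulate the *structure* of the source trial
without claiming its data: 188 subjects per arm (one arm of a 376-patient
1:1 randomization), event times drawn by inverse-CDF from the base-case
fitted families, administrative censoring at a 24-month cutoff and 5%
uniform dropout (both package choices, stated here because the trial's
censoring pattern is unpublished).  PFS and OS are coupled comonotonically
(one shared uniform rank per subject) and PFS is capped at OS, so
progression never follows death — the structural requirement of the PSM.
`make_digitized_fixture()` samples the resulting KM step function on a
grid with optional bounded jitter (emulating manual curve digitization)
and counts exact numbers at risk.

What passing the synthetic round trips does *not* show: the generator has
no delayed treatment effects, no non-proportional or crossing hazards
beyond what the chosen families imply, no covariate structure, and no
AE-time or cost micro-data.  Agreement on synthetic data validates the
pipeline's internal consistency, not the clinical fidelity of any
particular extrapolation.

## Problem sizes and runtimes

The test suite exercises parameter recovery at n = 5000 per family,
reconstruction round trips at n = 200, and seeded PSAs of 10–1,000
iterations; a full deterministic engine run is ~10 ms and the
1,000-iteration PSA completes in a few seconds on one core.  These sizes
were chosen to make Monte-Carlo tolerances (10% parameter recovery,
±0.03 survival in round trips) comfortably attainable while keeping the
default check fast.

## Known limitations

* The PD→death closure is one consistent reading of an under-specified
  construction; alternatives (e.g. PD mortality from the OS interval
  hazard without cohort closure) do not track the OS curve and were
  rejected on that ground.
* Subsequent-therapy proportions, follow-up frequencies and the
  osimertinib pack size are unpublished; they are explicit configuration
  knobs, and the committed calibration absorbs their joint effect.
* Survival uncertainty is excluded from the PSA (no published
  distributions), so the CEAC understates total decision uncertainty.
* The published step-function CEAC cannot be reproduced from the published
  ranges (see above).
* No tunnel states, time-in-state utilities, individual-level simulation,
  or societal costs.
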