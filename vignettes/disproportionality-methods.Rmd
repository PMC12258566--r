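---
title: "Disproportionality signal detection on spontaneous reports: models, conventions and validation"
author: "faersignal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality signal detection on spontaneous reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faersignal)
```

## The problem

Spontaneous adverse-event reporting systems such as FAERS collect
unsolicited reports of suspected drug harms. They have no denominator —
nobody knows how many patients took the drug without an event — so the
only available signal-detection strategy is *disproportionality*: is a
particular adverse event reported more often **with** the drug of
interest than would be expected from its share among **all other**
reports (the case/non-case design)?

Every statistic in this package derives from the per-event 2x2 table

|            | event of interest | all other events |
|------------|-------------------|------------------|
| target drug reports | `a` | `b` |
| all other reports   | `c` | `d` |

with `n = a+b+c+d`, `Cx = a+b`, `Cy = a+c`. The counting unit is the
unique (report, Preferred Term) pair: one report listing three PTs
contributes three pairs. At System Organ Class level a report
contributes once per *distinct PT* it carries, which is why a drug's
SOC-level "case reports" can exceed its number of reports. This pair
convention is the only one under which published SOC tables for drugs
with multi-PT reports reconcile with their report counts, and it is the
package default throughout.

## The four algorithms

* **ROR** (reporting odds ratio): `ad/bc`, Wald CI
  `exp(ln ROR ± 1.96·sqrt(1/a+1/b+1/c+1/d))`. Undefined when `b` or `c`
  is zero; the package returns an explicit reason rather than `NaN`,
  and applies no Haldane continuity correction by default.
* **PRR** (proportional reporting ratio): `[a/(a+b)]/[c/(c+d)]` with an
  analogous log-scale CI, accompanied by the chi-square statistic.
  `prr_stats()` computes the Yates continuity-corrected form, clamped
  at 0 when the correction overshoots (`|ad−bc| < n/2`); the
  uncorrected Pearson form is available via `correct = FALSE` (see
  *Validation* below for why that option matters).
* **BCPNN IC** (information component):
  `E(IC) = log2 [(Cxy+γ11)(C+α)(C+β)] / [(C+γ)(Cx+α1)(Cy+β1)]` with
  defaults `α1=β1=γ11=1`, `α=β=2` and
  `γ = γ11(C+α)(C+β)/[(Cx+α1)(Cy+β1)]`, plus the standard three-term
  variance and the conservative bound `IC − 2·sqrt(V(IC))`.
* **MGPS / EBGM**: DuMouchel's two-component gamma-Poisson mixture
  fitted by maximum marginal likelihood across all events of a run;
  `EBGM = exp E[ln λ | a]` and `EBGM05` its posterior 5th percentile.

Signal criteria are conjunctions, each gated on `a ≥ 3`: ROR ≥ 2 with
CI lower bound > 1; PRR ≥ 2 with chi-square ≥ 4; IC − 2SD > 0; and (for
MGPS, where the literature criterion is standard but often left
unstated) EBGM05 ≥ 2. Flags are columns in the output, never row
filters, so sub-threshold rows remain inspectable.

## Two IC estimators, and why both exist

With the default hyperparameters and the derived `γ`, the prior is
centred on independence: a perfectly independent table gives
`E(IC) = 0` *exactly* (for `a=b=c=d` the numerator and denominator are
equal integers). This canonical, shrunk estimator is the package
default. It has a structural property worth knowing: because the
posterior joint probability cannot exceed roughly `(a+1)` pseudo-counts
of mass, `2^IC` is bounded near `a`, so extremely large
observed/expected ratios are strongly compressed.

Published FAERS signal tables, however, frequently contain IC values
far above that bound (an IC of 12.8 at `a = 148` is impossible for the
shrunk estimator, whose ceiling there is about 7.2). Such tables are
internally consistent with the *unsmoothed* maximum-likelihood
component `IC = log2(a·n / (Cx·Cy))` — together with `EBGM = 2^IC` and
the same variance formula evaluated at zero pseudo-counts.
`bcpnn_hyperparams(smoothing = FALSE)` selects exactly that variant;
the validation workflow below uses it, and the estimator in use is
always explicit in the call.

Two caveats on the smoothed estimator, established empirically during
development and covered by the property tests:

* shrinkage direction is guaranteed only away from the null — within
  about ±0.35 bits of independence the ±1 pseudo-counts can nudge
  `2^IC` marginally past the raw ratio;
* `EBGM05` from `2^(IC − 1.645·SD)` and the MGPS posterior percentile
  are different quantities; `signal_stats()` labels which source filled
  the column (`ebgm05_source`).

## MGPS numerics

The mixture prior is fitted on the log/logit scale with `L-BFGS-B`
inside a ±12 box from DuMouchel's conventional start
`(0.2, 0.1, 2, 4, 1/3)`. A mixing weight collapsing to 0 or 1 simply
means one gamma component suffices and is accepted; a *weighted*
component pinned at the box boundary means the prior is unidentifiable
(the classic case: a single extreme event among nulls, whose "signal
component" degenerates to a point mass), and the fit falls back — with
a warning and an explicit `estimator = "ic-fallback"` label — to the
unsmoothed estimator. `EBGM05` solves the posterior mixture CDF by
bisection to `1e-10`.

## Reconstructing 2x2 tables from published rows

Published tables print `(a, ROR, PRR, χ²)` per event but not the cells,
so any statistic they do *not* print cannot be checked directly.
`reconstruct_table()` recovers `(b, c, d)`:

1. `PRR = (a + ROR·b)/(a + b)` — an identity obtained by eliminating
   `c` and `d` — gives `b` in closed form:
   `b = a(PRR−1)/(ROR−PRR)`.
2. With `d = ROR·b·c/a` enforcing the ROR, the chi-square becomes a
   monotone function of `c` alone, solved by 1-D root finding on the
   log scale. This replaces a generic 3-D derivative-free search: it is
   deterministic, exact when a root exists, and conditions the problem
   properly.
3. Cells are rounded to integers and all three statistics recomputed;
   the result is accepted only if every relative residual is within
   0.5%.

Two numerical facts about this inverse problem matter in practice:

* **The chi-square flavour is identifiable from integers.** For a
  large-ROR row, no integer table matching the printed ROR and PRR has
  a *Yates-corrected* chi-square within 0.5% of the printed value,
  while the uncorrected Pearson statistic matches to ~1e-3%. Printed
  FAERS tables therefore typically contain the Pearson statistic even
  when the corrected formula is stated alongside, and
  `reconstruct_table()` defaults to `chisq_type = "pearson"`.
* **`c` can be weakly identified.** When the printed chi-square sits at
  or above its large-`c` asymptote (a consequence of two-decimal
  rounding), `c` is only bounded below; the solver then returns the
  closest point and flags it in the `note` attribute. The statistics
  of interest (IC, EBGM, CI bounds) have converged in that regime, so
  the reconstruction remains a valid cross-check even though `c` itself
  is not unique.

The package ships the published aducanumab reference rows it validates
against in `inst/extdata/published_reference_rows.csv`; the
reconstruction reproduces the printed IC (2.93 and 12.81 bits), EBGM
(7.62) and ROR CI lower bound (14.19) to the printed precision.

## Descriptive conventions

`summarize_characteristics()` follows the conventions that make
published characteristics tables reproduce exactly from their counts:

* demographic variables use the known-sex reports as the universe
  (unknown-sex reports are excluded; both counts are kept as
  attributes);
* outcome percentages are per outcome *record* (a report with two
  outcomes counts twice in the denominator);
* time-to-onset is `event date − earliest target-drug therapy start`
  in whole days — the conventional choice, since reporting systems do
  not define it — with half-open buckets `[0,7)`, `[7,28)`, `[28,60)`,
  `[60,∞)`; its denominator is the set of reports carrying a
  target-drug therapy record, with missing or sub-day-precision dates
  tabulated as `Unknown`;
* age bins are half-open left-closed (`[45,65)`, `[65,75)`, `≥75`),
  resolving the overlap that "45~65 / 65~75" labels would otherwise
  have; weight likewise (`<60`, `[60,80)`, `≥80` kg);
* percentages are rounded half-up to two decimals at presentation only.

Dates are parsed at their stated precision (`YYYYMMDD`, `YYYYMM`,
`YYYY`); a partial date participates in keep-latest ordering at its
precision but is treated as absent for day-level arithmetic.
Deduplication keeps, per `caseid`, the record with the latest FDA
receipt date, ties broken by the larger numeric `primaryid` — the
standard FAERS revision rule.

## What the synthetic generator does and does not emulate

`generate_reports()` emulates the structural features the pipeline
exercises: per-report demographics drawn from realistic categorical
distributions (the defaults mirror a published anti-amyloid antibody
safety profile: ~53% female, a third aged 75+, >90% US reports, ~0.6
outcome records per report, onset predominantly beyond 60 days);
one-or-more drug records with role codes; one-or-more PTs per report
(independent per-PT Bernoulli draws, so the PT count is approximately
truncated-Poisson with mean ~1.3); therapy start dates consistent with
a chosen onset-delay mixture; and case revisions at a configurable
duplicate rate.

Signals are injected multiplicatively: for reports carrying the signal
drug, the PT probability is multiplied by the relative reporting rate
`RR` (clamped to 1). In the rare-event limit both ROR and PRR estimate
`RR`, which keeps recovery tests analytic; `expected_table()` gives the
closed-form expected cells (neglecting the two rare forcing
corrections — reports that draw no drug receive the highest-marginal
drug, reports that draw no PT receive one marginal draw — and signal
leakage through non-primary-suspect carriers; all are second-order at
the default settings).

The generator does **not** model reporting-delay dynamics, drug-drug
interactions, masking (signal dilution by other strong signals),
duplicate reports that change content between revisions, or MedDRA
coding noise. Passing calibration tests on synthetic data therefore
demonstrates correctness of the counting and statistics, not robustness
to those real-data pathologies.

Default scales used by the test suite and calibration runs: null
calibration uses 50 replicates of 4,000 reports; signal-recovery uses
20 replicates of 20,000 reports with `RR = 20` (expected `a ≈ 40`);
the whole suite runs in well under a minute on one core. All
randomness flows from the single config seed, and identical config plus
seed yields byte-identical output files.

## Worked example

```{r example, eval = FALSE}
cfg <- synthetic_config(n_reports = 20000, seed = 1)
g <- generate_reports(cfg)
map <- pt_soc_map(cfg$event_catalog$pt, cfg$event_catalog$soc)
res <- run_full_analysis(run_config(g$tables, pt_soc_map = map,
                                    out_dir = "results"))
subset(res$pt_signals, ror_signal)
```

The run writes `characteristics.csv`, `soc_signals.csv`,
`pt_signals.csv` (descending case count, top 30, minimum count 3) and a
`manifest.json` reconciling parsed, skipped and deduplicated row
counts.

## Known limitations

* The background is "all other reports"; no active-comparator or
  drug-class restriction is implemented.
* PT→SOC mapping is single-level (no HLT/HLGT/SMQ groupings) and must
  be supplied by the user, since MedDRA is licensed.
* No multiple-comparison layer beyond MGPS shrinkage; no time-scan
  statistics; no causality assessment — disproportionality measures
  reporting association only.
* The legacy (pre-2012) LAERS file schema is not parsed.
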