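---
title: "Methods: six-model occupational health risk assessment and its verification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: six-model occupational health risk assessment and its verification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ohra)
```

## The problem

Workplaces that handle chemical toxicants are assessed with a patchwork of
occupational health risk assessment (OHRA) models. Six are in wide use — the
EPA inhalation hazard-quotient model, COSHH Essentials control banding, the
Singaporean semi-quantitative method, and the ICMM, Australian and Romanian
risk matrices — and they routinely disagree on the same workplace, because
they weigh toxicity, measured exposure and evaluator judgment differently.
`ohra` implements all six engines behind one record interface, converts
their incommensurable ordinal outputs onto a common risk-ratio scale, and
provides the statistical machinery to ask which model's risk ordering
tracks an external reference ("inherent risk") across industries and
chemicals.

## The scoring models

All engines consume an exposure record — industry, job/location, hazard,
airborne time-weighted concentration `ca` (mg/m³), exposure pattern (`et`
h/d, `ef` d/y, `ed` y), worker count — plus the chemical's hazard profile
from the registry.

**EPA (quantitative).** The exposure concentration averages the intake over
the full averaging time,

$$EC = \frac{CA \times ET \times EF \times ED}{AT}, \qquad
  AT = ED \times 365 \times 24,$$

with `CA` converted to µg/m³. `ED` cancels, so `EC` depends only on `CA`,
`ET`, `EF`; continuous exposure gives `EC = CA`. The hazard quotient is
`HQ = EC/RfC` with both sides in µg/m³ — where an RfC is quoted in mg/m³
the factor of 1,000 µg/mg is exactly this unit conversion, and HQ is
dimensionless. A literal extra factor of 1,000 would push every assessment
to the top band, which is dimensionally and practically absurd; we treat it
as the unit conversion. HQ is banded to levels 1–5 at cut points 0.1, 0.5,
1.0 and 2.0. Chemicals without an RfC cannot be EPA-scored and are skipped
with a logged reason rather than defaulted.

**Singaporean (semi-quantitative).** `Risk = sqrt(HR × ER)`, rounded *up*
to the next integer (the method's conservative convention) and capped at 5.
The hazard rating HR comes from an explicit per-chemical override when the
registry carries one, else from carcinogenicity class (IARC 1/2A → 5,
2B → 4), else from acute-toxicity bands on LD50/LC50. The exposure rating
ER bands the concentration ratio `CR = ca/OEL` at the same 0.1/0.5/1/2 cut
points.

**COSHH (control banding).** Risk phrases map to hazard bands A–E;
dustiness (solids) or volatility (liquids; gases count as highly volatile)
crossed with the quantity band gives an exposure-potential level EP1–EP4; a
matrix yields control strategies CS1–CS4, which align with levels 2–5 of
the common scale. COSHH deliberately ignores the measured concentration.

**ICMM, Australian, Romanian (matrix/calculator).** These methods are
evaluator-driven; their rating tables are not standardized numerical
objects. The package ships editable default tables — a monotone 5×5
likelihood × consequence grid (ICMM, with an exposure-time weight shifting
likelihood one step), a 125-cell calculator table
`level = 1 + 4·log(L·F·S)/log(125)` rounded to one decimal (Australian,
fractional levels attainable), and a monotone 7×6 severity × probability
grid (Romanian). Reproducibility of a subjective method requires freezing
the evaluator's table: every result row embeds the MD5 checksum of the full
method configuration, and per-(industry, location, hazard) rating overrides
can be supplied in `config$ratings`. When run unattended, consequence/
severity ratings reuse the Singaporean HR, probability/likelihood ratings
band the concentration ratio, and the Australian frequency rating bands
`ef` (days/year) at 13/53/105/201.

All band lookups in the package are left-closed, right-open, top band
closed above — one tie-break convention everywhere, tested against
brute-force interval oracles.

## Harmonization: the risk ratio

A method's level is divided by its scale maximum: `RR = level/max_level`,
in (0, 1]. EPA, Singaporean, ICMM and Australian use five levels; COSHH
attains 2–5; the Romanian scale has seven levels. For the Romanian
denominator the package defaults to 10, not 7: with 10 the Romanian ratios
land on the same one-decimal grid as the five-level methods (4 → 0.4,
6 → 0.6), which is how mixed-model comparison tables are conventionally
printed; the literal `level/7` definition is available via
`romanian_denominator = 7`. Ratios are kept at full precision internally
and rounded half-up to one decimal only for display.

## Statistics

Risk ratios take at most seven distinct values, so ties are massive and
everything is rank-based: Kruskal–Wallis (midranks, tie correction) across
more than two groups, Mann–Whitney between two, Spearman correlation
between method columns and against CR. Two choices the source methods leave
open were fixed as follows and are reported, not asserted as canonical:
tests are two-sided at α = 0.05 with raw p-values (Holm adjustment
available, off by default), and the Mann–Whitney p switches to exact
enumeration of group assignments when both samples have ≤ 8 observations —
the usual exact formulae are invalid under ties, whereas enumeration of the
permutation null is exact regardless. Method columns are compared
pairwise-complete: the EPA column simply has no entries where the RfC is
absent (deletion, not imputation). Correlation cells with fewer than three
complete pairs are `NA`, never zero.

## Verification against inherent risk

Inherent risk (IR) of an industry is its catalog tier (severe / medium /
low, ranks 1–3); the five bundled industries span the three tiers. IR of a
chemical ranks RfC ascending (smaller RfC, more severe inherent
consequence), with the exposure side arbitrating near-ties: two chemicals
whose RfCs lie within one order of magnitude *and* whose CR ranges overlap
are tied. The "≈" relation between two aromatic solvents with RfCs 30 and
100 µg/m³ and overlapping CRs is exactly this rule; the rule is ours, since
no formal definition exists for it.

"Consistent with the IR sequence" is operationalized as two separately
reported components: (a) group medians weakly decreasing across tiers —
no group in a lower-IR tier exceeds any group in a higher tier, with
within-tier differences allowed; and (b) every cross-pair between adjacent
tiers separating at p < α. `consistent` is their conjunction;
`distinguishes_all` asks instead that *every* pairwise comparison
separates. Whether a published consistency judgment used significance or
raw ordering is typically unstated, which is why both components are
exposed.

## The synthetic exposure generator

No field dataset ships with the package. The generator emulates the
structure of a published-style survey table: per (industry, location,
hazard) a record count `n`, a mean and a min–max range in mg/m³.
Airborne occupational concentrations are canonically lognormal, so each
stratum is fitted as:

* `sigma` from quantile matching: the printed range is read as the expected
  extreme span of `n` draws, `ln(max/min) = 2 z σ` with
  `z = Φ⁻¹((n − 0.5)/n)`;
* `mu` from the mean equation *of the range-clipped distribution*,
  `E[min(max, max(min, X))] = mean`, solved numerically (closed form for
  the clipped mean + `uniroot`). Clipping must enter this equation: for the
  widest strata (σ > 2) nearly half the unclipped mean mass lies beyond the
  printed maximum, and matching the unclipped mean would bias generated
  means low by tens of percent.

Draws are stratified inverse-CDF samples — one draw per probability
stratum, order shuffled — clipped to the range. Stratification keeps a
stratum of a few dozen records close to its design mean (an i.i.d. sampler
would have a ~25% standard error on the mean for the heavy-tailed strata,
making the generated table a poor emulation of its own design summary at
realistic `n`). Determinism: one global seed; each stratum's seed is
derived from it and a stable polynomial hash of (industry, location,
hazard), so adding a stratum never perturbs the draws of another, and
output is bit-identical for a fixed seed. Degenerate single-value strata
are point masses.

The bundled design (`default_exposure_spec()`) covers five industries over
three IR tiers, thirteen hazards including four focal toxicants (manganese
and inorganic compounds, benzene, xylene, ethyl acetate), and 1,519 records
(148/97/989/85/200 per industry). Published per-industry totals do not
decompose exactly into location counts when a location measures several
hazards, so the design reconciles: the ferrous-casting location with two
co-measured hazards splits its 20 locations 10/10, one ship-repair stratum
carries two extra records and one equipment-repair stratum one fewer, so
the per-industry totals hold exactly.

What the emulation does *not* reproduce: real within-worker correlation,
ET/EF/ED variation (all records carry the full-shift default 8 h/d,
250 d/y, 25 y), seasonal or enterprise-level structure, and any
dataset-dependent statistic of the original survey (medians per industry,
cross-method correlations). Tests that pass on this design therefore
validate the pipeline's arithmetic, orderings and invariants — not claims
about any particular field dataset.

## Defaults and registry caveats

Concentrations are mg/m³ at every interface; µg/m³ appears only inside the
EPA arithmetic, and RfC is stored in µg/m³. CR uses the China PC-TWA by
default (`oel_source = "acgih"` switches). The bundled registry's limit and
acute-toxicity values are standard-order defaults for the bundled hazards;
entries whose `notes` flag them as placeholders are reported at load and
should be confirmed against GBZ 2.1 / ACGIH documentation before any
regulatory use. Nuisance dusts carry an explicit low-toxicity HR override
(HR 1) so the rating-based engines can score them; remove the override to
have them skipped instead.

## Problem sizes in the test suite

The suite exercises the full 1,519-record design once (shared across test
files), exhaustive grids for every matrix engine (75, 125 and 42 cells),
n = 10,000 draws for generator mean recovery, and small hand-enumerable
samples for the rank statistics. The whole suite runs in well under a
minute on one core.

## Known limitations

* The ICMM/Australian/Romanian defaults are reconstructions in the spirit
  of the source methods, not transcriptions of any official table; results
  from them are only comparable across runs sharing a config checksum.
* COSHH hazard banding requires risk phrases; chemicals without phrases are
  skipped for COSHH.
* The EPA pathway covers non-carcinogenic inhalation risk only; the
  carcinogenic (unit-risk) pathway and dermal/ingestion routes are out of
  scope, and `iur` is stored but unused.
* `consistent`/`distinguishes_all` are relative-accuracy descriptors
  against a catalog reference, not a claim that any model is correct.
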