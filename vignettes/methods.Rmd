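---
title: "Estimating epibiont nematode loads from ordinal skin-scrape surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating epibiont nematode loads from ordinal skin-scrape surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nemacensus)
```

## The problem

Florida manatees (*Trichechus manatus latirostris*) carry a community of
diplogastrid nematodes — *Cutidiplogaster manati* and two further
morphospecies nicknamed LT (long tail) and ST (short tail) — living in the
biofilm and sloughing dead-skin layer of their epidermis. Field surveys of
this fauna are necessarily semi-quantitative: during a health assessment a
5 × 5 cm patch of dorsal tail skin is scraped onto a water-agar plate, and
each morphospecies on the plate is scored on an ordinal visible-count scale
(`0`, `+`, `++`, `+++`). `nemacensus` turns such ordinal survey tables into
per-species skin densities, community composition, prevalence, and — via a
geometric model of the dorsal surface — whole-animal load estimates with a
depth-sampling correction.

## From ordinal scores to densities

Each ordinal level is replaced by a representative count per plate. The
default mapping is the one used in the published manatee census:

| level | symbol | visible-count range | representative count |
|------:|:------:|:-------------------:|---------------------:|
| 0 | `0`   | 0       | 0   |
| 1 | `+`   | 1–20    | 10  |
| 2 | `++`  | 21–99   | 50  |
| 3 | `+++` | ≥ 100   | 100 |

(The field protocol and the published table captions disagree slightly on
the `+`/`++` boundary — 1–20/21–99 versus 1–15/15–99. The caption ranges
overlap at 15, so the package uses the non-overlapping protocol ranges
wherever ranges matter, i.e. in the simulator's binning; the mapping to
representative counts is unaffected.)

The density estimator is **two-stage**: for each host, mapped counts are
divided by plate area (25 cm²) and averaged over that host's included
plates; the host means are then averaged **without weighting**, so a host
sampled with nine plates counts no more than one sampled with four. The
published 2018 density means (2.26, 3.19, 2.76 nematodes/cm²) are
reproduced exactly by this estimator and *not* by flat pooling over plates
(which gives ≈ 2.25/3.16/3.10); the package's brute-force oracle tests pin
this down. Host-level means are the natural unit here because plates within
a host are pseudoreplicates, not independent samples.

**Sample inclusion.** Resample plates — the same skin patch scraped again
with more pressure — measure depth, not new area, and are excluded from the
density estimate by the default `"nonsequential"` rule. First passes of
sequentially sampled areas are kept. Alternative rules (`"first_pass"`,
`"all"`, a custom predicate, and host exclusion) are exposed as
configuration. For the 2019 survey the published means (2.64/2.65/2.65)
could not be reconciled with any single inclusion rule we tried (all
passes, first passes only, adults only, and combinations), so the package
computes a 2019 census under whatever rule the user selects but makes no
claim of reproducing those three numbers; `reproduce_paper(2019)` produces
the report without printed-value checks.

```{r}
est <- population_mean_density(load_fixture(2018))
est
```

## Prevalence and depth structure

A species is *present* on a host if any plate scores `+` or higher.
Sequential resampling of one patch indexes depth into the biofouling
layer: the per-host **depth-yield multiplier** is the total mapped count
over all passes divided by the first-pass count (species summed within a
pass). In the 2019 survey this ratio is about 3–4 for the richly colonised
hosts, the anchor for the load-range multipliers below; hosts whose first
pass yields nothing have an undefined ratio and are flagged rather than
summarised.

```{r}
depth_yield(load_fixture(2019))
```

## The dorsal surface model

Two field measurements drive the geometry: umbilicus girth *G* (body
circumference at the navel) and curvilinear total length *L*, both in cm.
The girth sets a radius *r* = *G*/2π. The tail dorsum is modelled as a
circle of that radius (area *G*²/4π) and the body dorsum as an ellipse
with semi-minor axis *a* = *r* and semi-major axis *b* = *L*/2 (area
π·*a*·*b* = *G·L*/4); the total is exactly their sum. Both figures are
taken at full (not half) area: the published per-sex component and total
means (15,320 + 3,730 = 19,050 cm² female; 16,136 + 3,435 = 19,571 cm²
male) are additive and of the magnitude this reading implies. Whether an
ellipse-minus-overlap variant was intended cannot be settled from the
source text; a `scale` argument supports sensitivity analysis. Tail length
(printed means 64/66 cm) is carried in the data model but enters no area
formula, mirroring the stated method.

Areas are computed **per individual and then averaged** within sex — mean
of areas, not area of mean measurements — because both formulas are
nonlinear in girth (Jensen's inequality makes the orderings differ; a
property test checks mean tail area ≥ tail area of the mean girth). The
packaged morphometrics fixture holds the per-sex printed summary only;
per-individual girths were published in supplementary material that the
package does not ship, so exact reproduction of the printed area means
from raw measurements is out of scope and the census consumes the printed
means directly.

## Loads and depth-adjusted ranges

The baseline load on a surface is total density × area. With the 2018
total density *D* ≈ 8.213 nematodes/cm² this gives ≈ 30,633/28,211
nematodes on the female/male tail dorsum and ≈ 156,452/160,731 on the full
dorsum, matching the published 30,636/28,211 and 156,452/160,727 within
0.1 % (the residual comes from the whole-cm² rounding of the published
area means). For the depth-adjusted range the baseline is first rounded to
a reporting quantum of 10,000 nematodes — the convention that reproduces
the published endpoints — then multiplied by the low and high depth
multipliers. The default preset `c(3, 4)` encodes the deeper-sampling
yield; `"wide"` (= `c(1, 4)`) spans from the superficial baseline itself
(≈ 30,000 on the tail) to the deep extreme, giving the headline
30,000–120,000 (tail) and 160,000–640,000 (dorsum) figures. Both the
quantum and the multipliers are arguments, not constants.

```{r}
cs <- nematode_census(load_fixture(2018), load_fixture("morphometrics"))
cs
```

## The survey simulator

`simulate_survey()` generates ground-truthed synthetic surveys so every
stage is testable without field data. Its defaults emulate the 2018 adult
survey shape: 7 hosts, 4–9 pseudoreplicate plates each, one superficial
pass, three morphospecies. Per host, a latent density per species is drawn
from a lognormal across hosts (default medians 2.0/2.8/2.4 nematodes/cm²
with sdlog 0.6, chosen so typical plates land in the `++`/`+++` classes as
the real tables do); each plate's count is negative-binomial with mean
density × 25 cm² × availability and size *k* = 5 (clustered, overdispersed
counts; *k* = ∞ gives Poisson), then binned on the protocol scale.
Morphometrics are bivariate-normal (length, girth) per sex, truncated
positive, means 262/310 cm (printed lengths) and 217/208 cm girth — the
paper prints no girth, so the defaults are back-calculated from the
printed tail areas via *G* = √(4π·A\_tail) — sd 15 cm and correlation 0.7,
values we consider realistic for an adult winter cohort. Depth structure
is a per-species availability profile by pass; `depth_profile()` encodes
the qualitative published pattern of a species absent from the superficial
biofilm but present in deeper dead-skin passes (no quantitative
availability values exist, so the profile is illustrative by design).
Juvenile hosts (off by default) attenuate all densities by a factor
(default 0.1), emulating the sparse fauna of the one sampled calf.

What the simulator does **not** emulate: spatial autocorrelation across
the host's surface, between-year dynamics, observer variation in scoring,
and any real relationship between morphometrics and nematode density.
Passing recovery tests therefore validates the estimator's arithmetic and
its behaviour under ordinal censoring — not the field protocol itself.

**Ground truth for recovery.** Binning a count into an ordinal class and
replacing the class with a fixed representative count is inherently biased
for the latent mean (severely so when plates saturate at `+++`). The
recovery harness therefore compares the replicate mean of the estimator
with the estimator's *own expectation* under the simulator, computed
numerically (`expected_mapped_density()`: the negative-binomial bin
probabilities are integrated over the lognormal host-density law with
`stats::integrate`, rel.tol 1e-9). Bias relative to the latent mean is
reported alongside, as information only.

## Numerical conventions and degenerate inputs

* Reporting uses half-up rounding (densities to 2 d.p., composition to
  whole percent, loads to whole nematodes, baselines to the 10,000
  quantum); all internal arithmetic is unrounded.
* All-zero surveys yield zero loads and an explicitly undefined
  composition (error on request, `NA` in the fitted object).
* A host with no plates left after inclusion filtering is an error, not a
  silent drop; hosts named in `exclude_hosts` are dropped before
  estimation.
* Depth multipliers with a zero first-pass count are flagged undefined and
  excluded from the min/median/max summary.
* Fixture ambiguity: some renderings of the source tables run `++` glyphs
  together; the shipped 2018 transcription is the one validated by
  reproducing the published density means to 2 d.p. (the package's
  "fixture audit" test). No equivalent printed check pins every 2019 cell;
  the 2019 fixture follows the same reading.

## Problem sizes in the test-suite

The suite runs the full fixtures (46 and 31 plates), 100 randomised small
surveys (≤ 5 hosts × ≤ 6 plates) against a brute-force oracle at 1e-12,
and a 200-replicate recovery experiment at the 2018 survey shape, judged
at four Monte-Carlo standard errors of the replicate mean — sizes chosen
to make the statistical checks sharp while keeping the default suite fast.

## Known limitations

* Representative-count conversion is a convention, not an estimate; no
  occupancy/detection model or interval estimation beyond the multiplier
  range is attempted (none exists in the source analysis).
* The geometry is a flat two-figure projection; no 3-D body model, no
  ventral surface.
* The 2019 density means are unresolved (above), and the depth multipliers
  are treated as a qualitative 3–4× anchor rather than a fitted quantity.
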