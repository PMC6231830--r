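---
title: "Spatial exposure, dominance and mediation in a rural surveillance site: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial exposure, dominance and mediation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hdssgeo)
```

## The problem

Rural demographic surveillance platforms in settings without postal codes or
cadastral records must build their own georeferenced frame: villages
subdivided into road-bounded *sectors*, sectors into *land parcels*, each
parcel carrying a hierarchical location identifier, and households and
individuals nested inside. Once that frame exists, two classes of question
follow. First, *environmental exposure*: how close do households live to
solid waste mounds and stagnant liquid puddles, and how does sector-level
waste density vary with the social composition of the sector? Second,
*data quality*: how should the mapped geometry be audited in the field, and
when should a batch of digitised parcels be sent back for re-mapping?

hdssgeo implements the full chain: a synthetic settlement generator with a
known structural model, the spatial indicators, the sector dominance
classifier, rank-based association tests, regression-based mediation with a
cluster bootstrap, and the audit designs. Because the real survey data of
such platforms are not public, the generator is the package's reference
instrument: every estimator is validated by parameter recovery against the
structure the generator is known to contain.

## Identifiers

Parcel identifiers are 19-digit strings concatenating zero-padded codes for
country, state, district, block, village, sector and parcel sequence, with
digit widths 3-2-3-2-3-2-4. The widths are not dictated by the identifier
concept itself — any split summing to 19 works — so they are configurable
(`uid_widths()`), validated to sum to 19, and default to the magnitudes of
Indian administrative census codes. Sector labels are alphabetic in the
field ("A", "B", …) and map to the 2-digit numeric code inside the
identifier. Individual identifiers are uniform random 9-digit strings and
deliberately carry *no* location information, so that people can move
without being renumbered; `allocate_individual_uid()` guarantees
collision-free draws.

All coordinates are planar metres. No geodesic computation appears anywhere
in the package: at village scale (hundreds of metres) the error of a local
projected grid is far below the positional error of digitised parcels.

## The synthetic settlement model

`synth_config()` fixes the generative model; its defaults are the study
conditions the analyses assume:

* **Village sizes.** Parcel counts are lognormal with median ≈ 587 and
  roughly unit coefficient of variation, clamped to 25–3279, across 51
  villages — a wide, right-skewed size distribution.
* **Morphology.** Four point processes realise the settlement typology:
  a Thomas process (uniform parents, Gaussian offspring, σ = 10 m) for
  clustered villages, an elongated band for linear, an annulus for
  circular, a jittered square lattice for regular. The default mix is
  0.58/0.20/0.20/0.02, which makes essentially all villages register as
  clustered on the nearest-neighbour index with a rare regular outlier.
  A Thomas process was preferred over a Matérn cluster process because its
  offspring spread σ maps smoothly onto the index, making calibration
  transparent.
* **Parcels and sectors.** Parcels are 15 m squares centred on the
  generated centroids; they are not clipped against each other, because
  every downstream computation uses only centroids and areas. Sectors are
  a spatial k-means partition of the parcel centroids with a target of
  ~70 parcels per core sector (cap 500, small clusters ≤ 50 acting as
  outer sectors); oversized clusters are split recursively. Seventy was
  chosen so that a full-scale site yields on the order of 650–700
  inhabited sectors, the granularity at which dominance classification is
  meaningful. Sector hulls double as the road skeleton.
* **Use classes.** Residential/nonresidential/mixed at
  56.08/38.54/5.38 % — the composition of a mature rural cadastre in this
  setting.
* **Social structure.** Each sector draws a caste profile from a
  Dirichlet distribution centred on site shares (General/OBC/SC-ST =
  0.35/0.45/0.20) with concentration 5; household caste is multinomial in
  that profile. Low concentration means segregated sectors. Household SES
  (rich/middle/poor) comes from an ordinal logit shifted by caste (OBC
  +0.7, SC/ST +1.3 toward poorer) plus a sector-level wealth effect
  (SD 0.8 on the latent scale) — without that sector effect, SES-dominant
  sectors would be far rarer than caste-dominant ones, contrary to the
  observed pattern. With these defaults roughly 60 % of inhabited sectors
  have a dominant caste and ~35 % a dominant SES class at the 1.5× rule.
* **Waste.** Spot counts per sector are Poisson with log-intensity
  `gamma0 + gamma1 * lowSES_share + gamma2 * SCST_share` per hectare
  (defaults log 15, 0.6, 0.9), locations uniform in the sector hull,
  diameters lognormal with ~70 % at or above the 1 m qualifying
  threshold, 14 % solid mounds. The intensity acts at sector level, not
  household level, mirroring the sector-level density indicator. The
  defaults put the median sector density near 2 qualifying spots per 100
  residents.
* **Households per parcel** are `1 + Poisson(0.2)` (≈ 1.2 households per
  residential parcel) and household size is `1 + Poisson(5.1)` (≈ 6
  members), so a full-scale site carries ≈ 33,000 households and
  ≈ 200,000 individuals.

The manifest attached to every generated site records the exact structural
parameters used, so recovery tests never have to re-derive them.

What the generator does *not* emulate: irregular cadastral geometry,
terrain, within-sector social gradients, temporal census waves, and any
form of measurement error in the coordinates. Passing tests therefore
demonstrate that the estimators recover the structure *this* model
contains; they cannot certify behaviour under real-world geometry errors,
which is precisely what the audit module is for.

## Spatial indicators

**Nearest-neighbour index.** `nearest_neighbor_index()` is the classic
Clark–Evans ratio: observed mean nearest-neighbour distance over
`0.5 / sqrt(n / area)`. No edge correction is applied — the basic form is
what the settlement-typology tables in this field use — and the area
defaults to the convex hull of the points (bounding box and user-supplied
area are options; the choice matters and is the caller's). A perfect
square lattice gives exactly 2, complete spatial randomness 1 in
expectation, and a Thomas process with small σ drives the index well below
0.5. Classification rounds the index half-up to one decimal first — the
published class bounds (0–0.5, 0.6–0.9, 1.0, > 1.0) only tile the line at
that granularity.

**Exposure indicators.** Sector waste density is qualifying spots per 100
residents (threshold 1.0 m, *inclusive* — the sources alternate between
"> 1 m" and "≥ 1 m"; inclusive is configurable). Household proximity is
the planar distance to the nearest qualifying spot of either kind,
searched across the *whole site*, not the household's own sector: the
indicator is defined on the household, and the nearest hazard may sit just
across a sector boundary. The search uses a hand-rolled uniform-grid index
with an expanding-ring stopping rule; the test suite asserts exact
equality with a brute-force scan, so the index is an optimisation, never
an approximation.

**Built-up concentration.** Per village the core built-up region is the
convex hull of constructed-parcel centroids (default). A convex hull
contains all its generating points, so the in-core parcel share is 100 %
by construction and only the area share is informative; a grid-based
concave alternative (`hull_method = "grid"`, occupied 50 m cells) can
exclude outlying parcels at the cost of a resolution parameter. No
alpha-shape engine is available, and for compact rural clusters the
convex hull is an adequate core description.

## Dominance

A sector is *dominant* for a class when its household-weighted prevalence
of that class is at least 1.5× the site-wide prevalence. Decisions that
the rule statement leaves open, fixed here: the boundary is inclusive
(with a 1e-9 numerical slack so exact ratios like 0.30/0.20 qualify);
when several classes qualify the one with the largest ratio wins, ties
broken lexicographically, and all qualifying classes are reported;
prevalence is household-weighted, not person-weighted, because caste and
SES are recorded per household; uninhabited sectors are excluded from
denominators rather than treated as errors. Raising the threshold can
only shrink the dominant set, and a site-uniform composition has no
dominant sectors at any threshold above 1 — both are property-tested.

## Association and mediation

**Kruskal–Wallis.** Implemented from the rank formula with the standard
tie correction `1 − Σ(t³−t)/(N³−N)` and a χ² reference on k−1 degrees of
freedom, so the tie-correction factor is visible in the result; the test
suite checks exact agreement with `stats::kruskal.test` across enumerated
small-group layouts and verifies null p-value uniformity by simulation.
When every observation is identical the statistic is defined as 0 with
p = 1.

**Path analysis.** The mediation question — does household caste affect
proximity to waste *through* sector composition? — is answered with
regression-based path analysis (product of coefficients), not
latent-variable structural equation modelling: every arrow is an explicit,
testable regression. The outcome is log nearest-waste distance by default
(the raw distance is strongly right-skewed; a raw-scale option remains).
Caste enters as indicator contrasts with General as reference; SES is
coded ordinally 1–3. Continuous mediators (waste density) use linear
models; binary mediators (dominance indicators) use a logistic link, in
which case the product-of-coefficients value mixes scales and the
total = direct + indirect identity — exact for all-linear paths, and
asserted to 1e-8 in the tests — no longer holds. Confidence intervals come
from a nonparametric bootstrap that resamples *sectors*, not households:
the mediators are sector-level, so household resampling would pretend the
mediator was measured independently for every household and understate its
variance. Degenerate replicates (a resample in which a dominance indicator
is constant, say) are dropped and counted. Marginal models per mediator
and a joint model are both expressible through `path_model_spec()`, since
the field convention does not settle whether the dominance indicators are
exogenous.

The estimator is validated on `simulate_path_data()`: caste-homogeneous
sectors (the sharpest form of segregation the settlement generator
produces), a sector mediator `a·X + noise`, and a household outcome
`c'·X + b·M + covariates + noise`, so the true indirect effect is exactly
`a·b`. The acceptance suite runs 100 replicates at ≈ 5,000 households and
250 sectors with 500 bootstrap draws each and requires ≥ 90 % interval
coverage of the truth. On full synthetic sites, where the implied
household-level indirect effect has no closed form, the sign of the
density-mediated caste effect is checked instead.

## Quality audit

The audit design has four pieces. (1) Pilot villages: a stratified draw of
two large-linear, two large-circular, one small-linear and one
small-circular village. (2) Parcel samples per village:
`max(30, ceiling(0.051 · n))` capped at n, allocated across use classes by
largest-remainder apportionment. (3) Field checks: ceiling(10 %) per
task stratum. (4) Lot quality assurance: accept a lot when defects in a
sample of n are at most d. Since no published (n, d) exists for this
design, `lqas_plan()` derives the smallest n admitting a d that satisfies
both binomial bounds — producer risk ≤ α at the acceptable quality level
and consumer risk ≤ β at the rejectable level (defaults 5 %/20 % at
10 %/10 %, giving n = 30, d = 3 territory). The closed-form operating
characteristic is verified against Monte Carlo to within 1 %.
`error_rate_report()` turns per-parcel audit flags into the half-up
percentage style used throughout (a parcel may carry several flags;
categories are not exclusive).

## Numerical and reporting choices

* Percentages are rounded *half-up* at the printed precision
  (`ratio_report()`); base R's round-half-even would disagree with the
  reporting convention on exact halves.
* GeoJSON coordinates are written at micro-metre precision, which makes
  write → read → write byte-identical and bounds round-trip error at
  1e-6 m.
* k-means sector tiling jitters coordinates by ≤ 1 mm to avoid duplicate
  centres in perfectly coincident clustered points; sector numbering is
  re-ordered by centroid position so generation is deterministic under a
  seed.
* Degenerate inputs fail loudly and specifically: fewer than two points
  for the index, zero area, empty sectors (excluded, not errored, in
  dominance), no qualifying spots, zero-variance mediators (named
  singularity error), infeasible sampling strata (named stratum).

## Problem sizes

The default test suite generates sites of 4–8 villages with ~250 parcels
each (a few thousand parcels, a few hundred sectors across tests), runs
the 100-replicate mediation coverage study at B = 500, the 200-seed CSR
calibration at n = 500, and the 1,000 × 300 index-versus-brute-force
check; the whole suite completes in well under five minutes on one core.
The acceptance script additionally generates one full-scale site (51
villages, ≈ 47,000 parcels, ≈ 33,000 households) in under a minute. These
sizes were chosen so the sampling error of each check sits an order of
magnitude below the property being asserted.

## Known limitations

* Parcels overlap when centroids sit closer than the parcel side; areas
  are per-parcel constants, not a tessellation.
* The convex-hull core makes the in-core parcel share uninformative
  (always 100 %); use the grid method when that share matters.
* Logistic-mediator indirect effects are scale-mixed products, reported
  without a causal-scale translation.
* The generator's dominance fractions are emergent, not dialled: they
  respond jointly to segregation concentration, sector size and household
  counts, and are only approximately positioned at the study's observed
  shares.
* Road layers are a skeleton (sector hulls with sampled typology), rich
  enough for density arithmetic and IO round-trips, not for network
  analysis.
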