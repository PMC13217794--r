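---
title: "From marker detections to breeding values: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From marker detections to breeding values: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`litterebv` turns raw fiducial-marker (ArUco) detections of group-housed
laying hens into estimated breeding values (EBVs) for litter-area
behaviour. This vignette explains the models the package implements, the
choices made where the design was genuinely open, and what the
simulation-based checks do and do not establish about real data.

## The measurement chain

A ceiling camera films the litter area of each pen at 20 frames per
second; a detector reports, per frame, each visible marker's identity
code and its four corner pixel coordinates. The package takes over from
there:

1. **Tracking** (`read_detections()`, `attach_identities()`,
   `filter_pipeline()`): parse the per-frame stream, attach each bird's
   unique wingtag through the backpack-placement roster (marker numbers
   repeat across pens, so the join is pen-wise), and clean the stream.
2. **Behaviour** (`segment_runs()`, `detect_dles()`,
   `hourly_time_budget()`, `assemble_phenotypes()`): segment detection
   runs, classify detection-loss events (DLEs) by zone, build time
   budgets and derive the three hourly traits.
3. **Genomics** (`snp_qc()`, `grm_vanraden1()`, `pen_relatedness()`):
   SNP quality control and the genomic relationship matrix (GRM).
4. **Mixed models** (`reml_univariate()`, `reml_trivariate()`,
   `blup_fixed_varcomps()`, `lrt_genetic_variance()`): variance
   components, EBVs and their reliabilities.
5. **Summaries and validation** (`genetic_parameters()`,
   `leave_one_pen_out()`, `validation_regression()`,
   `crossval_accuracy()`): heritabilities, repeatability, the
   coefficient of genetic variation, and leave-one-pen-out accuracy.

A synthetic-data module (`sim_design()`, `sim_truth()`,
`simulate_genotypes()`, `simulate_genetic_effects()`,
`simulate_hourly_phenotypes()`, `simulate_tracking_stream()`) generates
both levels of data — hourly phenotypes obeying the genetic model, and
the frame-level stream with ground truth retained — so the whole chain
is exercisable and auditable at desk scale.

## Filtering the raw stream

`filter_pipeline()` applies, within each pen and in order:

1. drop detections whose centre (mean of the four corners) lies inside
   the **exclusion polygon** bounding the ramp and upper levels;
2. drop **unregistered markers** — codes never documented at backpack
   placement (worn or bent backpacks produce phantom codes);
3. drop rows whose shoelace **marker area** exceeds the per-pen upper
   quantile (default 0.999) of the empirical area distribution —
   corner-like patterns at opposite ends of the pen read as one
   impossibly large marker;
4. drop all rows of any (pen, marker, millisecond) observed at more than
   one distinct position — one physical marker cannot be in two places;
5. drop whole per-bird 10-second **distance windows** whose summed
   displacement exceeds the per-pen upper quantile (default 0.999) —
   tracking artifacts and identity swaps produce teleport-like jumps;
6. drop pens whose coordinates exceed the expected frame size (a pen
   recorded at a different resolution lives in a different pixel space).

Two choices deserve comment. The original protocol chose the area and
distance cut-offs by visual inspection of histograms; we replace
inspection with configurable upper quantiles and persist the realized
cut-offs in the report, so the decision is reproducible and auditable.
The cut-offs are realized order statistics (type-1 quantiles): on a
stream whose upper tail is unremarkable the cut-off coincides with the
observed maximum and nothing is removed, which keeps the filter
conservative on clean data; re-running with frozen cut-offs removes
nothing. The distance rule uses non-overlapping (tumbling) 10-s windows
and removes offending windows wholesale — removing single rows would
keep half of a teleport. The row accounting is exact by construction:
`rows_in - sum(removed per step) = rows_out`, always.

## Runs, detection-loss events and zones

Two thresholds govern the event logic, both expressed in frames at
20 fps:

* **Run segmentation** bridges gaps of fewer than `gap_tolerance`
  *missing frames* (default 70): a dropout shorter than a qualifying
  loss event does not break a run. Strict per-frame continuity is
  available with `gap_tolerance = 1`.
* A **detection-loss event** qualifies when the frame-index difference
  between the last sighting and the re-detection is at least
  `min_gap_frames` (default 70, i.e. 3.5 s — a bird last seen in frame
  5 and re-found in frame 75 was lost for (75-5)/20 = 3.5 s) *and* the
  preceding run contains at least `min_prior_run_frames` detected
  frames (default 1200, one minute).

The two conventions differ by one frame at the boundary (a gap with
exactly 69 missing frames is bridged, so the shortest observable
inter-run gap spans 71 frame indices under the defaults); both follow
the respective worked definitions, and the boundary case never surfaces
under the default tolerances.

The recordable litter area is partitioned into three zones (central
**focal** — optimal detection, losses attributed to occlusion or
detector limits; peripheral **yellow** — lens distortion and distance;
**green** near the exits — true absences). Classification tests the
polygons in the priority order focal, yellow, green, so ties at shared
borders resolve deterministically. Point-in-polygon testing is even-odd
ray casting (via `mgcv::in.out()`). A gap is **Away** when neither
endpoint lies in the focal zone, **Focal** when both do, **Uncertain**
otherwise.

For hourly time budgets *every* inter-detection gap is
endpoint-classified, so the non-detected time partitions into Away /
Uncertain / Focal, plus an explicit `unclassified` bucket for edge time
(before the first and after the last detection of the hour) — nothing is
silently reallocated and the five shares sum to one exactly. The DLE
*event list* and the hourly focal-loss rates, by contrast, use the
qualification thresholds above. Records belong to the wall-clock hour of
their timestamp; runs spanning an hour boundary are split there.

## The three hourly traits

For every bird, day and hour:

* `dh01` — 1 if some run within the hour holds at least 1200 detected
  frames (one continuous minute), else 0;
* `mdh` — square root of the minutes detected, with minutes = detected
  frames / (20 x 60);
* `wsh` — square root of the average walking speed in cm/min: Euclidean
  step distances between successive detections are summed, steps
  spanning a gap of 70+ frames are excluded (the displacement across a
  loss event is not walking), the sum is converted at 8 px/cm and
  divided by the *raw* minutes detected. Dividing by raw minutes (not by
  the square-root-transformed trait) is what gives cm/min units.

When `dh01 = 0` the other two traits are coded missing: the hour carries
no usable track. Step exclusion applies to every 70+-frame gap whether
or not the prior-run condition holds — a teleport after a short run is
still a teleport.

## Genomic relationships

`grm_vanraden1()` computes the first VanRaden relationship matrix,
`G = ZZ' / (2 sum p(1-p))` with `Z` the genotype matrix centred by twice
the per-SNP sample allele frequency. Missing genotypes are mean-imputed
per SNP before centring, which preserves the exact row-sum-zero
identity. Because allele frequencies come from the sample itself, G is
expressed relative to the current population: off-diagonal entries
average slightly below zero, and the mean within-pen relatedness of a
randomized population is slightly negative — that is a property of the
centring, not missing signal. QC (`snp_qc()`) keeps autosomal SNPs with
minor allele frequency above 0.01 and call rate above 0.90; a SNP
failing several rules is attributed to the first failing rule in the
fixed order non-autosomal, MAF, call rate, so report counts add up.

## The repeated-records animal model

Each trait's hourly records follow

y = Xb + Za + Vc + Wd + e,

with fixed pen, day and hour-of-day effects (reference-level coding),
random breeding values a ~ N(0, G sigma2_a), a random pen-day-hour
interaction c ~ N(0, I sigma2_c) shared by all birds of a pen in one
specific hour of one day, a permanent-environment effect d ~ N(0, I
sigma2_d) constant across a bird's records, and residuals with a
separate variance per pen-hour group (activity differs along the day and
between pens). The trivariate model stacks the three traits with
unstructured 3x3 covariance matrices for a, c and d; traits of the same
bird-day-hour record also correlate residually.

### Estimation

`reml_univariate()` and `reml_trivariate()` maximize the restricted
likelihood with the average-information (AI) algorithm on the
mixed-model equations; the restricted log-likelihood is evaluated
through the standard identity
`log|V| + log|X'V^-1 X| = log|R| + sum log|Sigma_t (x) K_t| + log|C|`
and reported up to an additive constant. Each AI proposal is checked
against the likelihood; proposals that leave the parameter space or
decrease the likelihood are retried with Levenberg-style damping and
step halving, and an EM step is the final fallback, so iterations never
diverge. Standard errors come from the inverse AI matrix at convergence
(a pseudo-inverse when a parameter sits on the boundary).

Numerical choices: variances are kept non-negative by projection, with
covariance matrices clipped to the positive cone using a relative
eigenvalue floor (1e-6 of the mean diagonal) — correlations cannot reach
exactly +/-1, which keeps the prior inverse and the likelihood stable
near boundaries; the GRM receives a 1e-6 diagonal bump (configurable)
before inversion; convergence requires a relative likelihood change
below 1e-8 and a relative parameter change below 1e-6, within 200
iterations by default; the first two iterations are plain EM to
stabilize poor start values.

### The trivariate constraint protocol

Because `mdh` and `wsh` are only observed when `dh01 = 1`, the data
contain no information on residual covariances with the binary trait —
any non-zero estimate is an artefact of fixed-effect estimation. The
trivariate fit therefore proceeds in two stages: stage 1 estimates all
covariance matrices freely with a homogeneous residual (the pen-hour
heterogeneous residual is dropped in the multi-trait model); stage 2
refits with the residual variances and the `mdh`-`wsh` residual
covariance fixed at their stage-1 estimates and the residual covariances
involving `dh01` fixed to zero, re-estimating everything else.
Constrained entries are reproduced exactly in the returned components.

### Derived parameters

With mean residual variance averaged (unweighted) over pen-hour groups,

* hourly heritability: sigma2_a / (sigma2_a + sigma2_c + sigma2_d +
  mean sigma2_e) — phenotypic variance is the sum of *all* modelled
  random components, because the pen-day-hour variance would otherwise
  be absorbed by the residual and end up in the denominator anyway;
* daily heritability divides the transient components (sigma2_c and the
  residual) by the average number of recorded hours per pen-day —
  computed from the data by default (10.5 in the design the package
  emulates) rather than hard-coded;
* repeatability: (sigma2_a + sigma2_d) / sigma2_P;
* GCV: sqrt(sigma2_a) / trait mean, on the analysed (transformed) scale;
* reported EBV accuracy: the mean over individuals of
  sqrt((sigma2_a - SE_i^2)/sigma2_a), SE_i the prediction-error SE from
  the mixed-model equations; negative radicands are clipped to zero and
  counted.

Values are kept at full precision internally; rounding (2 dp in the
summaries above) happens only at report time. The binary trait is
analysed on the linear scale: with a population mean near 0.6, a linear
mixed model approximates a threshold model closely, and linear and
threshold EBVs for such traits are known to correlate very highly.

The likelihood-ratio test for genetic variance compares the full model
with one in which the animal term is removed. The null value lies on the
boundary, so the default reference is the 50:50 mixture of a point mass
at zero and chi-square(1); a plain chi-square(1) is available.

## Leave-one-pen-out validation

`leave_one_pen_out()` masks one pen at a time and solves BLUP with *all*
variance parameters frozen at the full-data estimates, collecting the
masked individuals' EBVs (EBVMP) and reported reliabilities.
`validation_regression()` pools all masked-pen records in one model,
`y = pen + hour + day + beta * EBVMP + pdh + pe + e` (a single slope per
trait), re-estimating the environmental components; `beta = 1` means
correctly dispersed EBVs. `crossval_accuracy()` converts the explained
variance into an accuracy by dividing by the square root of the hourly
heritability of the full-data fit; values above one are reported with a
warning, not clipped. The EBVMP variance entering the formula is that
among the phenotyped masked individuals (each pen's birds take their
EBVMP from the fold that masked them). A regression on an EBVMP set with
numerically zero variance (a collapsed genetic-variance estimate) is
refused rather than returning an astronomically large, meaningless
slope.

## What the generator emulates — and what it does not

`simulate_hourly_phenotypes()` draws records exactly from the model
above: matrix-normal breeding values with row covariance G
(`vec(A) ~ N(0, Sigma_a (x) G)`), i.i.d. permanent-environment and
pen-day-hour effects, pen/day/hour fixed effects, and residuals with a
per-pen-hour variance spread multiplicatively (default +/-30%) around
the trait means. The default variance structure uses additive,
pen-day-hour, permanent-environment and mean residual variances of
(0.01, 0.11, 0.67), (0.01, 0.06, 0.51), (0.05, 0.24, 2.26) and
(0.16, 0.85, 8.56) for the three traits, genetic correlations
(0.73, -0.28, -0.72), and trait means (0.60, 2.7, 16.17) — the scale of
the study population this package is built around (10 pens x ~113 hens,
7 days, a mean of 10.5 recorded hours per pen-day). `simulate_genotypes()`
can produce paternal half-sib families (`n_sires`), mirroring a
crossbred population from pooled semen; family structure is what lets
masked pens borrow information through the GRM at desk scale.

`simulate_tracking_stream()` is a stand-in for the physical recording
chain, not a model of hen dynamics: a correlated Gaussian random walk
with reflecting boundaries (step scale chosen so the raw walking speed
is a few hundred cm/min), alternating-exponential absence episodes,
exponential occlusion episodes, per-frame flicker, extra dropout in the
yellow zone, and injected artifacts (giant markers, same-millisecond
duplicates, unregistered codes, teleports) at configurable rates, all
flagged in the retained ground truth. Default loss rates put the
detected share of time near the observed 37/63 split. Emitted marker
squares are axis-aligned (centre and shoelace area are
rotation-invariant, so downstream maths is unaffected) and coordinates
are clamped to the frame, as a pixel detector's must be.

Passing simulation checks therefore demonstrates that the pipeline's
*arithmetic and inference are correct under the stated model*; they do
not certify the model against real footage, where occlusion is social
rather than Poisson, absences follow daily rhythms, and detection failure
may correlate with behaviour. One consequence deserves emphasis: on data
simulated from a correctly specified model, the model-based (reported)
accuracy of masked-pen EBVs and the cross-validated accuracy estimate
the *same* quantity, so the real-data observation that reported
accuracies are roughly twice the cross-validated ones cannot be
reproduced by this generator — that gap is a signature of model
misspecification and of the limits of theoretical reliability formulas
on real data, not of the estimation machinery.

## Problem sizes used by the checks

The test suite and the acceptance script run the whole chain at reduced
scale, chosen as the smallest designs at which each quantity is
identifiable: tracking fixtures use a handful of birds and a few
recorded minutes per hour; univariate parameter recovery uses 300
genotyped birds in 4 pens with 2 days x 4 hours and 20 seeded
replicates; the trivariate correlation-recovery fixture uses 240 birds
with genetic variances inflated eightfold so a correlation of -0.7 is
identifiable at that size; the cross-validation calibration uses 300
half-sib birds (15 sires) in 4 pens with 15 records each over 10
replicates. Every stochastic step takes an explicit seed, and one master
seed fans out to sub-seeds through a fixed counter scheme, so all
replicates are reproducible.

## Known limitations

* Zone polygons are configuration inputs; no camera calibration or
  undistortion is attempted, and the pixel-to-cm factor is a single
  constant per camera view (rank-preserving within pen).
* How non-event non-detection time should be apportioned among the
  Away/Uncertain/Focal causes is not uniquely defined; the
  endpoint-classified partition with an explicit `unclassified` bucket
  is one consistent reading.
* The distance filter examines tumbling, not sliding, 10-s windows; a
  jump straddling a window boundary contributes to one window only.
* The movement and loss processes of the stream simulator are
  convenience distributions and must not be read as estimates of real
  birds' dynamics.
* Heteroskedasticity across days and threshold-model analysis of the
  binary trait are out of scope by design.
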