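---
title: "Habitat suitability from CRW null models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Habitat suitability from CRW null models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The estimation problem

A lactating otariid is a central-place forager: between nursing bouts on
a rookery island she makes at-sea trips of a few days, and her habitat
choice is confounded with the simple fact that she must start from, and
return to, one fixed point. Presence-only telemetry therefore cannot be
contrasted with uniform background points — most of the ocean was never
*available* to her. The approach implemented here builds availability
from the movement itself: for every observed trip phase we simulate
correlated random walks (CRWs) that keep the trip's step lengths and
per-step durations but randomize its headings. Locations along retained
CRWs are pseudoabsences: places the animal could plausibly have gone,
at the times she was at sea, had she moved indifferent to the
environment.

The pipeline is: daily regularization and trip segmentation; CRW
simulation, weighting and filtering per trip phase; environmental
matchup by box means; a binomial additive mixed model; and gridded
suitability prediction. Each stage is an exported function; the
`analysis/` scripts chain them over the packaged synthetic study.

# Track processing

Raw positions pass an iterative speed filter (default `vmax` = 3 m/s, a
sustained swimming speed for this size of otariid; positions violating
the limit against every remaining neighbour are removed worst-first).
Tracks are then linearly interpolated to 00:00 UTC daily epochs —
interpolation never bridges gaps wider than 3 days, and interpolated
positions falling on land are dropped. A daily position is a haul-out
state when it is within 5 km of the colony or on land; maximal at-sea
runs bounded by haul-outs on both sides are foraging trips (runs
touching the start or end of a record are incomplete and discarded). The
5 km radius sits below the smallest maximum-trip-distance in the
packaged 72-trip reference table (5.02 km), so no genuine trip can be
swallowed by the haul-out zone. Each trip splits at its apex — the
position farthest from the colony, earliest index on ties — into an
outgoing and an incoming phase that share the apex.

Utilization distributions use a bivariate Gaussian kernel on a planar
equirectangular projection about the data centroid, with the reference
bandwidth `0.5 * (sd_x + sd_y) * n^(-1/6)`; contour levels are the
smallest regions holding 50% and 95% of the probability mass.

# The CRW null model and the similarity weight

For a phase with positions `p_1..p_n` the observed step series is the
sequence of great-circle step lengths (haversine, radius 6371 km) and
turning angles (wrapped heading differences in (-180, 180], negative =
left). Each simulation starts at `p_1` with a uniform initial heading;
subsequent headings turn by draws from a wrapped normal with the
phase's circular mean and circular SD — the source method says only
that angles are "sampled from a normal distribution", and fitting the
phase's own angular statistics preserves its directional persistence.
Step lengths and durations are replayed exactly. A step that lands on
land is resampled — a replacement length drawn with replacement from
the phase's step-length pool plus a fresh heading — up to 100 times,
then the simulation restarts (up to 20 times) before being flagged.

Each simulation is scored against its phase by

    weight = 2 * (d_track - d_crw) / d_track + |angle_track - angle_crw| / 90

where `d` is the net-displacement distance (start to end) and `angle`
the start-to-end initial bearing, the difference wrapped into [0, 180]
degrees. Three readings of this formula are defensible; the package
implements the literal one — the factor 2 binds to the distance term
only, and the distance difference is signed (a null that travels
*farther* than the track lowers the weight) — and exposes
`scale_whole_sum` and `absolute_distance` switches for the
alternatives. "Net angular displacement" is operationalized as the
start-to-end initial bearing: the /90 normalization implies degrees,
and wrapping the difference to [0, 180] keeps the angular term in
[0, 2]. Per trip, land-flagged simulations are dropped and then those
above the 75th weight percentile (linear-interpolation quantile,
computed within the trip's own simulation set, as the weighting is
defined per trip). Retained outgoing and incoming simulations are
paired index-wise; dropping the incoming sim's duplicated first
position makes a paired null trip with exactly the source trip's
position count, which is what yields the exact 1:1 class balance later.

# Environmental matchup

Every daily position — presence or pseudoabsence alike — is joined to
each covariate by the mean over grid cells whose centres lie in the
half-open 1° x 1° box centred on the position (half-open so edge cells
are counted once, reproducibly), at the time slice nearest the position
date within the variable's native resolution window (1 day for SST,
SLA, currents and wind; 8 days for chlorophyll and the SD layers). Eddy
kinetic energy is `(u^2 + v^2) / 2` in cm^2/s^2, computed from the
box-averaged geostrophic components. Chlorophyll-a and EKE are log10
transformed and bathymetry SD square-root transformed (the transforms
that make these right-skewed quantities roughly symmetric); bathymetry
stays in negative metres below sea level. Log base 10 follows
ocean-colour convention. Records with a non-positive value in a log
domain, or any missing covariate, are excluded and counted; losing more
than half the records aborts the matchup as a coverage mismatch.
Covariates are a pure function of position and date — never of the
presence label.

# The habitat model

For each individual, the trip with the most daily locations (ties:
longer span, then smallest trip id) contributes its presence records,
paired with the records of one retained null of that trip selected
uniformly at random — a 1:1 design with one trip and one null per
individual, avoiding pseudoreplication. The model is an additive
logistic regression fitted with `mgcv`: penalized cubic regression
splines (`bs = "cr"`, basis dimension 4) per covariate plus a
per-individual random intercept (`bs = "re"`), smoothing parameters by
REML. Basis dimension 4 keeps every smooth's effective degrees of
freedom at or below 3.9 while still allowing a hump-shaped response;
the non-shrinkage basis is deliberate — shrinkage bases zero out weak
terms entirely, which makes the reported edf floor of 1.0 unreachable
and collapses shared signal onto a single member of a correlated pair.
Candidate covariate sets are screened with generalized variance
inflation factors (flag at `GVIF^(1/(2 df)) > 2`) and ranked by AIC;
when the AIC-best candidate is not also AUC-best the conflict is
reported and AIC wins. AUC is computed in sample as the Mann-Whitney
normalization with ties counted half. Model variability is quantified
by refitting 40 times, re-drawing the null per trip each time, and
tallying per-covariate significance at p < 0.001 together with the
mean (min-max) of edf, chi-square, AIC, AUC and deviance explained
(reported as mgcv's adjusted deviance explained — the R^2 flavour of
the source is not recoverable, and this analogue is documented as
such). Deviance explained and the significance tally come straight
from `mgcv::summary.gam`'s Wald chi-square tests.

Daily suitability surfaces evaluate the fitted model on a 0.25° grid:
covariates are extracted at cell centres with the *same* box-mean
operator and transforms as training (train/predict consistency), the
random intercept is set to its population mean, and the predicted
probability — already in [0, 1] — is the suitability (an optional
min-max rescale is behind a flag; probability is the default because
it is reproducible and monotone-equivalent). Land and missing-covariate
cells are masked. Seasonal composites are cellwise means with
SE = SD / sqrt(n days).

# The synthetic study system

Because no telemetry or satellite archive ships with the package, a
generator supplies both with known ground truth.

**Fields.** The domain is an 8.5° x 8° winter eastern-boundary domain
on a 0.25° grid with a straight meridional coastline (land east), an
exponential shelf reaching a 4000 m abyss (e-folding 60 km; depth
monotone non-increasing offshore), and a single-cell offshore island —
the rookery. SST is a convex combination of a 12 °C inshore and an
18 °C offshore endmember: the weight has a cross-shore upwelling
profile (e-folding 120 km), along-shore filament bands (wavelength
2.5° latitude) whose amplitude *grows* offshore and whose phase drifts
slowly through the season, and a mild seasonal modulation. Noise-free
SST is therefore always inside [12, 18] °C. The filament structure is
load-bearing: without it SST is a deterministic function of depth and
no model could attribute effects between the two; the slow phase drift
keeps a cool patch in place for the length of a trip while
decorrelating patches across trips. log10 chlorophyll is linear in SST
(slope -0.15 per °C: cool water is greener). SLA is a superposition of
six drifting Gaussian eddies (amplitude ~8 cm, radius 40-80 km,
westward drift 1.5 km/day); u and v are the geostrophic velocities of
the analytic anomaly gradient, so EKE is exactly zero only where the
gradient vanishes and the no-eddy scenario has identically zero SLA
and EKE. SST SD and SLA SD are 3x3-cell local SDs; bathymetry SD is
the local SD of the depth surface (high at the shelf break). Gaussian
noise (SST 0.3 °C, log-chl 0.1, SLA 0.5 cm, wind 1 m/s) is added per
cell and day. All randomness descends from one integer seed through a
documented splitting scheme (`split_seed`), so field sets are
bit-reproducible.

**Tracks.** Individuals alternate 2-day haul-outs at the rookery with
trips whose durations are gamma draws (mean 8.4, SD 3.6 days, clipped
to 2-23 days — the scale of the packaged reference table). A trip
first picks a foraging destination: a sea cell in an annulus around
the colony (reach set by the trip's step budget), drawn with
probability proportional to `exp(eta)` where `eta` is the ground-truth
preference — under a null preference this is uniform over the annulus.
The animal then commutes with a biased random walk: at each 6-hour
step, 16 candidate headings at a lognormal step length (mean 18-25 km)
are scored by the truth preference at the candidate plus a drift term
toward the current target (the destination outbound, the rookery over
the final half, ramping up), candidates on land or within 7 km of the
colony are excluded, and one is drawn by softmax. The last step snaps
to the rookery. The commute-to-patch structure matters: a pure
per-step preference walk expresses so little habitat selection that
even the *true* preference separates tracks from similarity-filtered
CRWs at an AUC of only ~0.7; destination choice is also how commuting
central-place foragers actually behave.

**What the generator does not emulate.** ARGOS error classes and
heavy-tailed location error (only optional Gaussian jitter); tidal and
diel rhythms in haul-out; short near-colony trips (the annulus floor
under-represents trips below ~50 km, while the reference table has
trips down to 5 km); prey fields distinct from the environmental
proxies; and any feedback of foraging success on movement. Tests that
pass on this generator therefore validate the *pipeline's estimators*,
not the biological fidelity of any one dataset.

# Packaged study conditions and what they show

`study_conditions("strong")` is the recovery condition: 10 individuals,
3 trips each, preferring cool (-2.5 logit/°C) and shallow
(+0.002 logit/m) water; 20 CRWs per phase. `study_conditions("null")`
is the calibration condition: no preference, 20 individuals with 3
trips (the larger sample keeps one realization's accidental spatial
clustering from masquerading as selection). Both pin their environment
and track seeds (101, 202) so every analysis refers to the same
synthetic world — they are fixtures — while CRW simulation, null
selection and ensemble resampling follow the run-time seed.

Two identifiability facts shape how recovery is scored, and both are
measured by the package itself:

* With two active covariates whose realized values correlate at
  |r| ~ 0.6 and ~230 modeling records, the *individual* partial
  responses are not identified — across null re-draws the weaker
  covariate's fitted shape flips sign while the joint fit barely
  changes. Recovery is therefore scored on what is identified: the
  Spearman correlation between the fitted environmental linear
  predictor and the truth preference evaluated on the covariates the
  model observes (the box-mean scale), averaged over five replicate
  null draws (`evaluate_recovery`). Mean values are ~0.92 with
  in-sample AUC ~0.83-0.85. The single-covariate case, where the
  partial response is identified, recovers its truth with rank
  correlation 1.0 and a monotone central response, and is tested as
  such.

* In-sample AUC of a flexible additive model does not go to 0.5 under
  exchangeability: label-permutation refits at the null condition's
  sample size measure a floor of ~0.59-0.60. The null condition's
  observed mean AUC (~0.61) sits ~0.01 above that floor — the
  pseudoabsence design leaks almost nothing — but a 0.5 +/- 0.05 band
  on the in-sample statistic is unattainable by construction, and the
  corresponding check is expected to stay red. The per-covariate
  significance tally is the calibrated quantity: at alpha = 0.001, no
  covariate exceeds 2-3 spurious detections in 40 runs.

# Numerical choices and degenerate inputs

Haversine distances use radius 6371.0 km everywhere; a zero
displacement has bearing 0 by convention, and `crw_weight` refuses a
zero track displacement (a degenerate trip). Apex ties break to the
earliest index; trip-choice ties to the longer span, then the smallest
trip id; candidate-model ties to declaration order. Quantiles are R's
default linear-interpolation type 7. Box membership uses half-open
intervals so a position on a cell-centre boundary counts once. The
wrapped-normal sampler degenerates cleanly: zero circular SD replays
the mean angle, giving straight-line simulations for straight phases.
`EKE = 0` cells are excluded from the log transform (and floored at
1e-3 cm^2/s^2 only inside the generator's preference lookup, where a
finite value is needed). Problem sizes throughout — a 35 x 33 x 61
field set, 10-20 individuals, 10-20 CRWs per phase, 40 ensemble runs —
were chosen so the full synthetic pipeline completes in well under ten
minutes on a single core.

# Known limitations

The speed filter plus linear interpolation stands in for state-space
filtering of ARGOS error; it is documented, simple and testable, but
it does not model observation error. The quartile weight filter keeps
75% of non-land nulls regardless of their absolute similarity, so
pseudoabsence quality degrades for highly tortuous phases. In-sample
AUC overstates discrimination at small n (quantified above). The
distance-from-colony candidate model often beats the environmental one
on AIC in synthetic data — central-place geometry is a strong
predictor — so conclusions about *why* a region is suitable should
rest on the environmental model's partial responses, jointly, not on
single-covariate attribution when covariates are collinear.
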