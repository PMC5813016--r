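---
title: "Quantifying beta-arrestin membrane recruitment and receptor pharmacology: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying beta-arrestin membrane recruitment and receptor pharmacology: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tirfpharm)
```

## The scientific problem

Agonist activation of a G-protein-coupled receptor such as the D1 dopamine
receptor triggers two distinguishable downstream events: G~s/olf~-mediated
stimulation of adenylyl cyclase (measured as a rise in intracellular cAMP) and
recruitment of beta-arrestin to the phosphorylated receptor at the plasma
membrane, which drives desensitization of the cAMP response. Under total
internal reflection fluorescence (TIRF) microscopy, arrestin recruitment is
visible as bright, sub-resolution puncta appearing on the cell footprint.
Comparing agonist classes therefore requires three quantitative layers, all
implemented here:

1. an image-analysis chain that turns a raw 16-bit TIRF field into per-cell
   puncta endpoints (count and integrated intensity, both adjusted for cell
   area);
2. a statistical layer comparing those endpoints across treatment groups; and
3. receptor-pharmacology calculations linking in vitro potency and binding to
   projected in vivo receptor occupancy: 4PL dose-response fits, percent
   desensitization, potency shifts at mutant receptors, Cheng-Prusoff Ki,
   apparent Kb, and the occupancy projection
   RO(%) = 100·C~b,u~/(C~b,u~ + K~i~).

Because the raw microscopy and assay data behind these analyses are not
publicly deposited, the package ships a ground-truthed synthetic generator for
each data type; every pipeline stage is validated against data whose truth is
known by construction.

## The puncta pipeline

The operator chain, with defaults:

| step | operator | parameters (default) |
|---|---|---|
| 1 | square-root transform to 8-bit | `v8 = min(255, floor(sqrt(v16)))` |
| 2 | Gaussian smoothing | half-width 2 px, sigma 1 |
| 3 | top-hat, background removal | disk radius 30 px |
| 4 | top-hat, signal enhancement | disk radius 5 px |
| 5 | non-maximal suppression | radius 3 px, threshold 20 (8-bit) |
| 6 | marker-controlled watershed | peaks as foreground markers |
| 7 | measurement | on the step-1 image, not the processed one |
| 8 | Otsu cell segmentation | hole filling + largest 8-connected component |

Numerical choices the operator names do not pin down, and how this
implementation resolves them:

* **Square-root mapping.** `floor(sqrt(v))` with a clip at 255 maps the full
  16-bit range onto [0, 255] with integer output and compresses bright puncta
  of widely varying intensity onto a common scale.
* **`h = 2 px` of the smoothing kernel** is read as the truncation half-width
  of a sigma = 1 Gaussian (a 5x5 kernel), normalized after truncation so a
  constant image maps to itself; borders use edge replication for the same
  reason.
* **Structuring elements** are discrete disks: offsets (dr, dc) with
  dr^2 + dc^2 <= r^2, centre included. Erosion/dilation ignore out-of-image
  pixels, which keeps the white top-hat nonnegative and offset-invariant.
* **NMS neighbourhood** uses Chebyshev distance (a (2r+1)^2 window) with an
  inclusive threshold. Equal-valued plateaus of candidate pixels (8-connected)
  are collapsed to their lexicographically smallest (row, col) member, so the
  peak set is unique and deterministic.
* **Watershed markers.** Foreground markers are the NMS peaks; the background
  marker is every pixel of the enhanced image below the NMS threshold (the
  natural "not a punctum" evidence at hand; the alternative of a separate
  background level is configurable only through the threshold itself).
  Flooding is by priority queue on the negated enhanced image with
  8-connectivity; at equal elevation the foreground basin wins ties against
  the background, so an isolated blob's region is exactly its
  above-threshold support, and FIFO ordering makes the result deterministic.
* **Coordinates are 1-based (row, col)** throughout, R's native convention; a
  0-based convention in R invites off-by-one defects with no compensating
  benefit.
* **Border policy:** puncta regions touching the image border are retained.
* **Which image feeds Otsu** is not dictated by the operator chain; the
  default is the smoothed 8-bit image (cleaner bimodal histogram), with the
  raw square-root image available via `pipeline_config(cell_image = "sqrt")`.
* **Gates** (`gate_min_area_px`, `gate_min_mean_intensity`) default to off.
  The tests verify the gating robustness property: raising the intensity gate
  preserves the direction and significance of a true group difference.

Endpoints: puncta whose centroid pixel falls outside the cell mask are
discarded; the per-field count and integrated intensity (sum over regions of
mean intensity x area, measured on the unprocessed square-root image) are each
divided by the field's normalization factor, defined as its cell foreground
area divided by the median foreground area pooled across the experiment.

## Group statistics

Per-cell endpoint values are square-root transformed (variance stabilization
for count-like data; for Poisson counts the transformed variance is
approximately 1/4 regardless of the mean), then averaged within each batch of
cells recorded together. **The batch mean is the analysis unit** - using
per-cell values would treat cells within a well as independent replicates and
pseudo-replicate the design. Homogeneity of variances is checked with
Bartlett's test; the treatment effect with a one-way ANOVA; comparisons
against the control group with two-sided Dunnett tests; and any remaining
p-value families with Benjamini-Hochberg adjustment. All tests are two-tailed
at the 5% level.

No Dunnett implementation is available in this toolchain, so adjusted
p values are computed by Monte-Carlo integration of the max-|t| null: group
means are simulated from their null normal distributions together with a
shared pooled-variance chi-square draw, and the adjusted p value is the tail
probability of the observed |t| under the maximum across comparisons. The
integration uses a fixed internal seed (deterministic output) and 10^5 draws
by default, giving Monte-Carlo error well below 0.005; tests compare the k = 2
reduction against the exact two-sided t test and the k = 3 case against an
independent raw-data simulation.

## Dose-response and receptor math

The 4PL model `r = bottom + (top - bottom)/(1 + (EC50/c)^hill)` is fitted on
log10 concentration by bounded least squares (L-BFGS-B with a Nelder-Mead
polish). Initialization is deterministic - bottom = min, top = max, EC50 = the
concentration whose response is nearest the half-range, hill = 1 - and the
Hill slope is constrained to [0.1, 10]. Flat curves are flagged
`no_response` rather than fitted. Percent efficacy is the fitted top asymptote
relative to the plate's saturating positive control (5 uM dopamine in the
assay emulated here). The HTRF standard curve is itself a monotone 4PL of
ratio against log concentration, inverted analytically; ratios outside the
calibrated range are flagged, never silently extrapolated.

Percent desensitization is the percent decrease in challenge-evoked cAMP
relative to vehicle pretreatment; sensitization (negative values) is
preserved. Basal subtraction is off by default - the normalization is to the
vehicle-pretreated challenge response only - and can be applied upstream by
the caller if desired. The closed forms Ki = IC50/(1 + L/Kd),
Kb = IC50/(1 + [A]/EC50) and RO = 100·C/(C + Ki) are implemented directly with
input validation, and the occupancy profile couples them to the PK generator
through C~b,u~ = C~b,total~ x f~u,b~. `match_occupancy()` finds the dose
scaler equating two compounds' mean occupancy over a dosing interval - the
normalization used to compare a catechol and a non-catechol agonist at
matched central D1R occupancy.

## Hierarchical Bayesian binding model

Saturation binding counts are modelled per group g and day d as

  y ~ LogNormal(log mu, sigma),  mu = Bmax~g~ · exp(u~g,d~) · L/(L + Kd~g~)

with day effects u~g,d~ ~ Normal(0, tau) on Bmax only (the day-to-day
variation in these assays is dominated by tissue amount, which scales the
asymptote, not the affinity; a Kd day effect is not identified by 9
concentrations x 3 days). Priors are weakly informative: Normal(log MLE, 1.5)
on log Kd and log Bmax (centred on the per-group least-squares fit, sd 1.5 on
the log scale spans more than two orders of magnitude), half-Normal(0.5) on
tau and on sigma. The error model is proportional (lognormal), matching how
counting noise scales in these assays; nonpositive specific counts cannot
enter a lognormal likelihood and are dropped with a message.

The sampler is component-wise random-walk Metropolis with Robbins-Monro scale
adaptation toward 0.44 acceptance during burn-in only (so retained draws come
from a fixed kernel). The default schedule reproduces the published analysis
design - three chains with 50,000 total iterations and 25,000 total burn-in,
read as totals across chains - and any sampler reproducing that schedule and
passing the coverage tests would be equally valid. Convergence is assessed by
the split-chain scale-reduction statistic on the group-level and variance
parameters with tolerance 1.01; results always carry the diagnostic and a
`converged` flag, and non-convergence warns rather than fails. Tests and the
acceptance suite run reduced iteration counts (1.5-6k iterations), which the
design anticipates; at those lengths the R-hat flag frequently trips while
interval coverage is already calibrated, which is exactly why the flag is a
warning, not an error.

Classification of inhibitor groups against the inhibitor-free reference uses
95% credible intervals as the operational reading of "larger than the
experimental noise": **competitive** if the group's Bmax interval overlaps the
reference's while its Kd interval lies wholly above; **mixed** if the Bmax
interval lies wholly below the reference's; **indeterminate** otherwise (in
particular, a duplicate of the reference is indeterminate - there is no Kd
shift to detect).

## What the synthetic generator does and does not emulate

A synthetic field is `background + smooth gradient + elliptical cell plateaus
+ isotropic Gaussian puncta (truncated at 4 sigma)`, then Poisson shot noise
on the expected signal, additive Gaussian read noise, rounding, and clipping
to 16 bits. The constant plateau over each elliptical footprint gives Otsu the
bimodal histogram a real TIRF cell footprint produces; the background
non-uniformity is a Gaussian blob with spatial scale of order the field size,
which exercises the radius-30 top-hat. Acquisition noise statistics and pixel
size are not published for the emulated instrument, so the defaults are free
parameters chosen once to be realistic rather than estimates: baseline 400
counts, gradient amplitude 300, cell plateau 2500, puncta amplitudes
15,000-50,000 with sigma 1.5 px, shot noise on, read sd 100 counts. With
these, a punctum's enhanced-image peak height is roughly 60-80 8-bit units -
at least three times the detection threshold of 20 - and puncta are separated
by at least 8 px, beyond twice the NMS radius. A green detection test
therefore establishes that the chain is correct and robust to the stated
noise, not that it would meet any particular sensitivity on a real
instrument; no optics (PSF, TIRF evanescent-field depth profile), photobleaching,
or time-lapse dynamics are simulated.

One consistency note on the background-invariance property: the added
low-frequency background is sized at 20% of the dynamic range *of the
puncta-free field* (baseline + gradient + cell plateau). Under the square-root
transform, an additive background worth 20% of the full range including the
brightest puncta would perturb measured intensities by tens of percent for any
implementation of this chain, so the property is only internally consistent
under the puncta-free reading; counts are invariant under either reading.

Assay-side generators reproduce their closed forms exactly when noise is off
(4PL curve, one-site binding with the Cheng-Prusoff Kd shift for competitive
inhibitors and the asymptote scaling for non-competitive ones, one-compartment
superposition PK), which the tests exploit as oracles.

## Known limitations

* The watershed assigns every above-threshold pixel to some peak's basin;
  faint blobs that contain no NMS peak are absorbed by a neighbouring basin or
  the background rather than reported separately.
* The Dunnett adjustment is Monte-Carlo and hence carries ~10^-3 p-value
  noise; it is deterministic for given data but not a quadrature-exact value.
* The binding sampler is a random-walk Metropolis; long correlated chains are
  needed for tight posteriors, and the day-effect/asymptote trade-off mixes
  slowly on short runs (the split R-hat diagnostic reports this honestly).
* The PK module is a deliberate one-compartment surrogate for unpublished
  compartmental models; occupancy projections inherit that simplification.
* The TIFF codec covers exactly the single-channel uncompressed 16-bit
  baseline variant the pipeline emits; anything else is rejected explicitly.
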