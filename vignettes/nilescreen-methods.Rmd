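---
title: "Methods: GFP-normalised Nile Red screening analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: GFP-normalised Nile Red screening analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nilescreen)
```

# The assay and its single statistic

`nilescreen` analyses a phenotypic anti-obesity screen in *C. elegans*
run in 96-well plates. Each well holds a population of roughly 250
age-synchronised worms carrying a body-wall-muscle GFP reporter
(*myo-3::gfp*), grown from L1 to L4 in the presence of the lipophilic
dye Nile Red and, in compound wells, a test compound (10 µM in 0.5%
DMSO). A plate reader records two fluorescence channels per well: Nile
Red (ex 528 / em 580 nm), which tracks stored fat, and GFP (ex 482 /
em 515 nm), which tracks the number of worms that actually ended up in
the well.

Everything downstream rests on one statistic, the **fat score**

$$s = \frac{F_{\mathrm{NileRed}}}{F_{\mathrm{GFP}}},$$

computed per well by `normalize_well()`. Because both channels scale
with worm count, the count cancels: in a noiseless model with
$F_{\mathrm{NR}} = c \cdot \mathrm{fat} \cdot n$ and
$F_{\mathrm{GFP}} = g \cdot n$, the score is
$c \cdot \mathrm{fat} / g$ for any $n$, and the package tests assert
this invariance *exactly* for $n \in \{125, 250, 500\}$. The ratio is a
per-worm fat proxy in arbitrary units; only comparisons between wells
are meaningful.

Two guards surround the ratio. Wells whose GFP falls below a floor
(default 5% of the plate's median vehicle-well GFP) are marked invalid
with reason `gfp_below_floor` rather than producing a wild ratio from
an empty or dead well; the floor is configurable because it is a
data-hygiene device, not a biological constant. An optional per-plate
rescaling of GFP by the vehicle-well median (`rescale_gfp`, off by
default) makes scores comparable across plates; the plain per-well
ratio is the primary definition and the default.

# Controls and plate design

Each screening plate carries four replicate wells of four control
conditions (16 control wells, leaving 80 compound wells):

* **vehicle** — wild-type reporter worms in DMSO only; defines the null
  score distribution;
* **positive control** — the AMPK activator AICAR at 0.1 mM, which
  reduces worm fat;
* **fat control** — the *nhr-49* mutant crossed into the reporter
  (strain HBC02), fatter than wild type; *nhr-49* acts in the
  PPAR-signalling pathway;
* **thin control** — the *cebp-1* mutant cross (HBC04), thinner than
  wild type.

The package's layout fixtures and simulator place the control block in
columns 11–12 (vehicle and AICAR in 11, fat and thin in 12); real
layouts are supplied as TSV/JSON files and may put controls anywhere.
Compounds are screened blind, in duplicate, with the two wells of a
compound on two separate plates; the duplicate structure is always
recorded explicitly in the library map, never inferred from position.

# Plate quality control: the Z′ factor

`compute_zprime()` implements the standard assay-quality statistic

$$Z' = 1 - \frac{3(\sigma_{+} + \sigma_{-})}{|\mu_{+} - \mu_{-}|}$$

on a positive/negative control pair, with sample standard deviations
($n-1$ denominator, as everywhere in the package). Banding follows the
usual convention: **excellent** for $0.5 \le Z' \le 1$, **marginal**
for $0 < Z' < 0.5$, **poor** for $Z' \le 0$; $Z' = 1$ is only reached
in the noiseless limit. Two pairs are evaluated per plate by
`plate_qc()`: vehicle vs AICAR (a small dynamic range, typically
marginal) and AICAR vs the fat mutant (a large range, typically
excellent). Plates are *gated* on the AICAR-vs-fat pair at
marginal-or-better by default — screens of this type proceed on a
marginal assay, so the default gate must not be stricter than that
practice; both the gating pair and the minimum band are configurable.
Equal control means are a zero-dynamic-range error rather than a
$-\infty$ score.

# Outlier trimming and group statistics

Confirmation experiments combine replicate wells per condition and trim
them before statistics (`trim_values()`):

1. remove exactly one maximal and one minimal value (one instance each
   under ties — the rule removes *a* max and *a* min, not all tied
   copies);
2. iteratively apply a two-sided Grubbs test at $\alpha = 0.05$
   (configurable), removing the most extreme remaining point while
   significant, stopping at $n = 3$.

The Grubbs critical value is the closed-form t-quantile expression
$G_{\mathrm{crit}} = \frac{n-1}{\sqrt{n}}
\sqrt{t^2_{\alpha/(2n),\,n-2} / (n - 2 + t^2)}$. Trimming is applied
per condition (per compound or control group), not across a plate.
Inputs with fewer than four values skip trimming with a logged
warning, since removing min and max from three values would leave too
little to test. Every removal is logged with its reason; an analysis
that silently deletes points is not auditable.

`summarize_group()` reports $n$, mean, sd and $\mathrm{sem} =
\mathrm{sd}/\sqrt{n}$.

# Calling compounds

## Primary/secondary screen call rule

A screen of this design never states per-compound p-values; a compound
is called from its two blinded duplicate wells against the vehicle
wells of the plates those duplicates sit on (pooled). The package uses
a **concordant-duplicate threshold rule** (`call_compound_screen()`):

* `decrease` if *every* duplicate score is below
  $\mu_{\mathrm{veh}} - k\,\sigma_{\mathrm{veh}}$;
* `increase` if every duplicate is above
  $\mu_{\mathrm{veh}} + k\,\sigma_{\mathrm{veh}}$;
* `no_effect` otherwise (discordant duplicates are no-effect);
* `no_data` if no valid duplicate remains.

$k = 2$ by default. Under a Gaussian null, one well crosses the lower
cut with probability ≈ 0.023, so a null compound is called a decreaser
at ≈ $5 \times 10^{-4}$ — the regime that produces the familiar low
single-digit hit rates at realistic library sizes. The rule, and $k$,
are configurable; a t-test mode (`screen_calls(mode = "ttest")`) is
exposed for secondary screens run with more replicates.

## Confirmation statistics

`confirm_compound()` applies a two-tailed two-sample **Welch** t-test
(unequal variances — the safer default with small, possibly unequal
replicate counts) and maps p to the tier ladder `*` p < 0.05, `**`
p < 0.025, `***` p < 0.001. Direction is the sign of the mean
difference *only when* the test is significant; a lower mean with
p ≥ 0.05 stays `no_effect`. Two zero-variance groups with equal means
give p = 1 (no evidence), with unequal means p = 0 (degenerate perfect
separation); `t.test` itself is undefined there. No multiple-testing
correction is applied anywhere: the cascade's secondary confirmation
is its false-positive control, and per-compound p-values are reported
so users can apply their own correction if they repurpose the
functions.

## The cascade and deselection

`triage_cascade()` builds the secondary roster: all primary decreasers
and increasers plus a seeded random sample (default 26) of no-effect
compounds as a negative arm. The sample seed is recorded in the result
so the roster is reproducible. `confirm_hits()` intersects the two
screens by direction — confirmed sets are by construction subsets of
the primary sets. The package always reports arithmetically consistent
roster counts (decrease + increase + sampled no-effect = roster size);
published summaries of such cascades occasionally carry small
bookkeeping inconsistencies between stages, and the pipeline makes no
attempt to reproduce those.

After unblinding (`unblind()`), `deselect()` removes confirmed hits
flagged `anthelminthic`, `cytotoxic`, `antibiotic`, `contraceptive`,
`unavailable` or `known_anti_obesity` (a repurposing screen wants
novel candidates), logging each removal; unannotated compounds are
retained and flagged rather than silently kept or dropped.

## Hit-rate rendering

Screen summary tables print positive hit rates truncated toward zero,
to one decimal below 10% and to a whole percent at or above 10% (two
significant figures over the range screens produce): 12/160 → 7.5%,
92/1200 → 7.6% (not 7.7), 29/160 → 18% (not 18.1). `hit_rate()`
implements exactly this convention and `format_hit_rate()` drops the
trailing `.0` of whole percentages.

## Mutant-background comparison

`compare_backgrounds()` takes the four groups wt ± compound and
fat-mutant ± compound and reports three Welch tests: the wild-type
effect, the mutant effect, and treated-mutant vs treated-wild-type.
A treated mutant that remains significantly fatter than treated wild
type (`residual_elevation`) suggests the compound acts through the
PPAR pathway the *nhr-49* lesion disrupts; a treated mutant pushed
significantly below both its own control and the wild-type control
(`below_control_reduction`) indicates a pathway-independent reduction.

# Image quantification

The plate-reader readout is corroborated by micrographs of individual
worms. `place_roi()` re-implements the manual box protocol: images are
2584 × 1936 px RGB (other sizes accepted with a warning), the
anatomical landmark is the pharyngeal grinder, and the default
1000 × 1000 box is placed with its **left edge at the landmark's
x-coordinate, vertically centred on the landmark**, clamped (with a
warning) at image borders. "One side touching the grinder" admits
several geometries; the anterior-anchored left-edge reading is used
because the quantified anatomy lies posterior to the grinder, and the
placement must above all be deterministic — identical image and
landmark always give the identical box. Coordinates are 0-based,
origin top-left, x rightward, y downward.

`roi_mean_red()` is the plain arithmetic mean of the red channel
(channel 1 of the stored array — the RGB-stack split, not a
colour-space transform) over the box: permutation-invariant inside
the box, blind to everything outside it. The mean is used as the
box summary; median or integrated-density variants would be easy to
add but are not what the protocol describes. `quantify_group()`
reduces n ≥ 2 images to per-worm values and group statistics, and
accepts lazy sources (paths or closures) because one full-size RGB
image is ~120 MB as doubles; holding 20 in memory at once is
unnecessary when each reduces to a scalar.

# The synthetic-data generator

No raw plate data for such screens are publicly deposited, so the
package ships a generator (`simulate_screen()`, `simulate_well()`,
`generate_worm_image()`) that emulates the *readout*, with full ground
truth, for operating-characteristic testing. Per well:

$$n \sim \mathrm{round}\,\mathcal{N}(250,\ (0.05 \cdot 250)^2),\quad
F_{\mathrm{GFP}} = g\,n\,(1+\varepsilon_1),\quad
F_{\mathrm{NR}} = c\,m_{\mathrm{strain}}\,m_{\mathrm{cpd}}\,
  n\,(1+\varepsilon_2)\,\pi_{\mathrm{plate}}$$

with $\varepsilon_i \sim \mathcal{N}(0, 0.05^2)$ independent,
truncation at zero, and $\pi_{\mathrm{plate}}$ a lognormal
(sdlog 0.05) staining factor applied to Nile Red only — emulating the
staining-batch variation that GFP normalisation cannot remove, which
is why duplicates live on separate plates. Defaults
(`sim_params()`): 250 worms/well; count cv 5% (liquid-handling
dispersion of age-synchronised L1s); per-worm yields $g = c = 100$ AU
so the wild-type vehicle score is 1; well noise cv 5% per channel
(bench plate-reader repeatability); strain multipliers 1.6 (fat
*nhr-49*) and 0.6 (thin *cebp-1*); AICAR multiplier 0.6. The strain
and AICAR multipliers are chosen to reproduce the qualitative control
ordering (fat > wt > AICAR ≈ thin) with the separations that put the
vehicle-vs-AICAR Z′ in the marginal band and AICAR-vs-fat in the
excellent band — the operating regime the assay reports — rather than
fitted to any quantitative measurement. Ground truth
(`screen_truth()`) defaults to 7.5% decreasers at multiplier 0.6 and
4% increasers at 1.5, the scale of effect prevalence a repurposing
library shows at these screens' pre-screen stage.

What the generator does **not** model: Nile Red uptake kinetics,
growth/starvation, edge effects or any spatial plate structure,
compound toxicity, dose–response (a single concentration, as in the
assay), or correlated channel noise. Passing recovery tests therefore
show the *pipeline logic* is correct under the stated noise model —
they are not evidence about biological variability beyond it. The
image generator draws an elliptical worm with Gaussian lipid-droplet
blobs, rescales the red channel so the box mean lands on the requested
value, quantises to 8-bit, and records the exact post-quantisation box
mean as ground truth by direct pixel summation at creation time.

# Numerical choices and degenerate inputs

* Sample sd ($n-1$) everywhere; sem = sd/√n.
* Score of a well with GFP below floor: invalid with reason, never an
  exception or an Inf.
* Trimming ties: one instance each of min and max.
* Welch test on two constant equal groups: p = 1; constant unequal:
  p = 0.
* Z′ with equal means: error (zero dynamic range).
* Hit rates: truncation toward zero as above; 0 hits → 0.
* ROI at borders: clamped, warned, never silently cropped.
* All seeds are explicit; stage seeds are derived from one master seed
  via `sample.int(2^31 - 2, k)` so they stay valid 32-bit integers;
  two runs with the same configuration are byte-identical on the same
  platform.

# Problem sizes

The shipped tests run the full cascade at the real library size
(1200 compounds, ~32 plates) — the simulation is cheap because each
plate is 96 wells — plus a 10⁴-replicate null calibration of the
confirmation test, a 10⁴-compound null calling experiment against a
Monte-Carlo oracle, and image checks on a small number of full-size
2584 × 1936 micrographs with reduced-size images for geometry unit
tests. These sizes were chosen to match the screen being modelled
while keeping the suite comfortably interactive.

# Known limitations

* The threshold call rule assumes approximately Gaussian vehicle
  scores; heavy-tailed plate artefacts would inflate the effective
  false-call rate (no B-score or spatial correction is applied, and
  none is offered).
* Vehicle statistics pool the two plates of a duplicate pair; a strong
  plate effect is partially absorbed but not removed per-plate.
* The Grubbs test is exact only under normality; with n = 4–8
  replicates it is a pragmatic outlier guard, not a formal test of
  the data-generating process.
* `unblind()` resolves identities by blinded id; it does not attempt
  fuzzy name matching across annotation sources.
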