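---
title: "Fingerprints and single-marker quantitation: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fingerprints and single-marker quantitation: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qamsfp)
```

This vignette is the package's account of the science it implements: the
models, their assumptions, the tunable parameters, and the design
choices made where the underlying methodology leaves the implementer
free. The setting is quality control of multi-herb liquid preparations
(here, an eleven-herb antiviral mixture with seven quantified marker
compounds, detected by UPLC at 254 nm over a 58-minute gradient), but
nothing in the code is specific to that preparation.

## 1. Why a single marker

Multi-compound quality control by the external standard method (ESM)
needs one certified reference standard per analyte, re-run with every
calibration. Quantitative analysis of multi-components by a single
marker (QAMS) replaces all but one standard with pre-established
*relative correction factors* (RCFs). For compound $x$ against the
marker (forsythoside A by default):

$$ f_x = \frac{C_x \, A_{ref}}{C_{ref} \, A_x} $$

measured from runs in which both concentrations are known, and inverted
for unknowns as $C_x = f_x \, C_{ref} \, A_x / A_{ref}$. Two structural
properties carry the method:

* **Slope-ratio identity.** If detector response is linear with zero
  intercept, $A = a C$, then $f_x = a_{ref}/a_x$, and QAMS contents equal
  ESM contents identically — any disagreement measures nonlinearity,
  intercepts, or integration error, which is why the relative error
  $\mathrm{RE} = (C_{QAMS} - C_{ESM})/C_{ESM} \times 100\%$ is the
  acceptance statistic (the field's working threshold is $|RE| < 5\%$).
* **Run-scale invariance.** $f_x$ is a ratio of areas from the *same*
  run, so any factor multiplying the whole run (injection volume,
  detector gain) cancels exactly. This is the mechanism behind the very
  low RSDs of RCFs across injection volumes, and the reason RCFs
  transfer across instruments and columns far better than absolute
  response factors.

`qams()` estimates each $f_x$ as the mean of the per-level ratios over
the calibration series; with zero intercepts every level gives the same
number, and the per-level RSD (reported by `summary()`) is a built-in
diagnostic for intercept or carry-over problems.

Peak location across instruments uses the *relative retention time*
$t = rt_x / rt_{ref}$, which is far more stable than absolute retention
(`locate_peak_by_relative_rt()`, acceptance window 0.02 by default, ties
resolved toward the larger peak).

## 2. Calibration, LOD and LOQ

`fit_calibration()` is ordinary least squares of area on concentration —
the response model the field actually uses, with $R^2$ reported and the
calibration range recorded as the linear range. Detection and
quantitation limits follow the signal-to-noise definition: LOD and LOQ
are the concentrations at which the *predicted peak height* reaches
$3\sigma_{noise}$ and $10\sigma_{noise}$. Since the curve predicts areas,
height is derived through a shape factor (`height_per_area`,
$1/(\sigma\sqrt{2\pi})$ for a Gaussian of width $\sigma$); the
dilute-until-S/N procedure used at the bench is equivalent for linear
responses but needs data the curve already contains.

## 3. Fingerprint model

Batch consistency is evaluated on the *common peaks* — peaks present at a
consistent relative retention time in (by default) every batch.

**Alignment.** One batch is the template (the field's convention is the
first batch, S1). Every sample's peaks are mapped to relative retention
time against the marker peak — located as the largest peak near its
expected position — and matched to the template's peaks by greedy
nearest-neighbour assignment within `rel_rt_tolerance` (default 0.02,
i.e. 2% of the marker's retention time; ties go to the smaller rel-RT
distance, then the larger area). Template slots are restricted to
reference peaks with S/N $\ge$ 10, the quantifiability (LOQ) criterion:
a "common peak" that is not quantifiable in the reference run is not a
useful fingerprint feature, and — more practically — a low-S/N noise
excursion adjacent to a genuine slot can otherwise capture other
samples' peaks under one-to-one matching. Sample peaks of any S/N may
still match, so minor constituents are not discarded, only prevented
from defining the template.

**Similarity.** Each batch's common-peak area vector is compared to the
reference fingerprint — the element-wise *mean* pattern, not the template
batch itself (the two roles are deliberately distinct) — by the vector
cosine. The cosine is scale-invariant, so a stronger or weaker injection
does not move similarity; what moves it is a change in *proportions*.
Non-common peak area percentage complements it: cosine on common peaks
cannot see constituents that fall outside the common set. Whether the
original similarity software works on peak vectors or whole curves is
not public; both modes are provided (`similarity_report()` on aligned
areas, `trace_cosine()` on resampled traces), with the peak-vector mode
as the default.

**Clustering.** `cluster_heatmap()` reproduces the field's batch-quality
view: $\log_2$(area + 1), agglomerative clustering (average linkage,
Euclidean distance — the upstream tools do not document their defaults)
and a $k$-cut of the dendrogram. The offset of one area unit guards
$\log_2 0$ and is negligible against areas of order $10^8$. On the
synthetic design the $k=2$ cut recovers the planted S1–S10 vs S11–S15
split, mirroring the elevated liquiritin / glycyrrhizic acid pattern the
published heatmap shows.

## 4. Peak processing

The detector model is additive: smooth baseline + peaks + white noise.
Choices, in order of appearance:

* **Baseline**: morphological opening (rolling minimum then maximum over
  a 2-minute window) removes structures narrower than the window —
  i.e. peaks — while following drift; a rolling mean of the same width
  smooths the staircase. The window must exceed the widest peak
  (defaults: 2 min vs. peak $\sigma \approx 0.05$ min). The envelope of
  a noisy trace sits a few noise SDs low, so the baseline is re-centred
  to give zero-median detrended noise over the peak-free region.
* **Noise**: estimated from first differences of the signal (slow drift
  cancels; white noise keeps $\sqrt2$ times its SD), after masking
  regions where the detrended signal exceeds $3\sigma$ (dilated
  outwards by 0.15 min) so peak flanks do not inflate the estimate.
* **Detection**: candidate regions where the lightly smoothed signal
  (5-point boxcar, used only for region and valley finding) exceeds
  twice the smoothed noise; local maxima qualify if the *raw* height
  passes `min_snr` $\times$ noise (default 3, the LOD criterion reused
  as the detection floor) and `min_height_frac` of the tallest peak
  (default 0.001 — the fingerprint spans about three decades of peak
  height, so the floor must sit below 0.1% of the dominant peak). With
  zero noise the S/N threshold degenerates gracefully to an absolute
  height floor.
* **Integration**: trapezoidal, on the raw baseline-subtracted signal,
  between valley-to-valley bounds; co-eluting maxima are split at the
  deepest intervening valley, with no curve fitting. Heights are raw
  apex values, so smoothing never biases them.

These are desk-scale reimplementations of what instrument software does;
none of the vendors document their parameters, so all constants here are
this package's own defaults, chosen so that closed-form oracles (a unit
Gaussian integrates to $\sigma\sqrt{2\pi}$ within 1%) and the synthetic
ground truth validate them.

## 5. The synthetic study design

`sim_config()` defaults encode the study conditions the pipeline is
meant to handle: 15 batches sharing 49 common peaks (7 named targets
with the published response slopes, stock concentrations and a 58-minute
gradient's retention times; 42 seeded filler compounds at least 0.55 min
apart), a six-level mixed-standard series diluted 3.5–112x (a 32x
span — the published linear ranges imply 32x even though the text of the
source study once says 64x), and herb-deficiency negative samples that
share jitter and noise bit-for-bit with their positive counterparts so
exclusion is the *only* difference.

Values the underlying methodology does not state were fixed once at
what practitioners would call realistic and are not tuned: Gaussian
peaks ($\sigma$ 0.04–0.07 min; analytically integrable, co-elution by
summation), total retention-time jitter SD 0.05 min split 80/20 in
variance between a batch-level shift and per-peak jitter (well inside
the 2% alignment tolerance), white detector noise SD $5\times10^6$
(chosen so the published LODs of ~0.1 ug/mL correspond to 3:1 S/N at
the published slopes), a low-order polynomial baseline hump of amplitude
$10^7$, 6% lognormal per-batch concentration variation plus a 3%
whole-run scale factor (giving batch similarities around 0.99,
consistent with the 0.95–0.99 the field reports), and cluster
multipliers of 1.5 (liquiritin) and 1.9 (glycyrrhizic acid) for batches
11–15, matching the contrast visible in the published batch contents.
One top-level seed fans out deterministically to per-purpose substreams,
so outputs are bit-identical under a fixed seed and negative samples
stay aligned with positives.

What the generator deliberately does **not** emulate: tailing or
fronting peak shapes, retention drift correlated with gradient
composition, heteroscedastic or correlated detector noise, saturation,
and real co-elution structure beyond Gaussian summation. Passing tests
therefore demonstrate correctness of the *computations* under a clean
detector model, not robustness to every chromatographic pathology.

## 6. Numerical and API choices

* RSDs use the sample (n−1) standard deviation throughout; this is what
  reproduces the published robustness summaries. Report rounding (means
  to 4 decimals, RSDs to 2) lives only in print methods; stored values
  keep full precision.
* The sample dilution factor (default 2, the study's sample
  preparation) is applied symmetrically to ESM and QAMS, so RE is
  dilution-invariant.
* `esm_content()` warns (class `qamsfp_extrapolation`) outside the
  calibration range rather than refusing: fingerprint batches
  legitimately stray slightly outside standards.
* Missing marker or target peaks raise classed errors
  (`qamsfp_marker_error`, `qamsfp_peak_not_found`) so pipelines can
  reject a sample without string-matching messages.
* Annotation (`annotate_features()`) implements exactly the two public
  acceptance criteria — |mass error| < 5 ppm and isotope-ratio
  difference < 10% — with candidates ranked by |ppm|. Proprietary
  MS/MS library scores are out of scope; a placeholder column can carry
  external scores. Isotope ratios are supplied per library entry
  (a helper computes M+1/M from element counts); there is no formula
  parser.
* The mzML reader handles chromatogram lists (64/32-bit floats,
  uncompressed or zlib) and converts second-based time axes to minutes;
  writing mzML is out of scope.

## 7. Problem sizes used by the test suite

The suite exercises the full render–detect–align–quantify pipeline at
the study's native size (15 batches x 49 peaks, 5801-point traces) a few
times, and uses the generator's exact-area contract view
(`truth_peak_tables()`) for replicate studies: 100 seeded replicates for
the two-cluster recovery rate and for the 1%-area-noise content
recovery. These sizes keep the whole suite under half a minute while
leaving every statistical check at full design size.

## 8. Known limitations

* Strongly co-eluting peaks (< ~2$\sigma$ apart) are split at the
  valley, biasing both areas; no deconvolution is attempted.
* The greedy alignment is one-to-one against a single template; a
  consensus template from several batches would be more robust but is
  not what the field's software does.
* LOD/LOQ inherit the calibration intercept; a large positive intercept
  can produce negative limits, which are reported as-is for the analyst
  to flag.
* The published similarity values of the source study cannot be
  reproduced here because the raw chromatograms are not public; the
  package instead validates similarity on synthetic data with known
  truth.
```{r session, echo=FALSE}
sessionInfo()
```
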