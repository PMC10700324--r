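---
title: "Methods: CorrTF longitudinal connectivity screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CorrTF longitudinal connectivity screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(corrtf)
```

This vignette is the package's own account of the analysis it implements:
the connectivity statistic, the longitudinal screening procedure, the
synthetic cohort the tests run on, and the design choices made where the
design was genuinely open.

## The CorrTF statistic

For two region-of-interest (ROI) mean time series, the correlation transfer
function treats one region as the input and the other as the output of a
linear time-invariant system. In the frequency domain, an LTI system obeys
Y(f) = X(f)·H(f), so the empirical transfer-function magnitude at each
discrete frequency bin is

|H(f)| = |F(ROI_out)(f)| / |F(ROI_in)(f)|,

with F the discrete Fourier transform. `corrtf_spectrum()` returns this
per-bin ratio over the one-sided spectrum; `corrtf_value()` reduces it to a
scalar per ordered pair; `corrtf_matrix()` assembles the full R×R directed
matrix (13,340 off-diagonal entries at R = 116). The matrix entry (i, j)
has region j in the denominator, so it quantifies the connection directed
*from* j *to* i; `connectivity_edges()` uses that convention for its
`source`/`target` columns.

Three numerical choices deserve explicit statement:

* **Scalar reduction.** The transfer function is defined per frequency but
  the screen needs one value per connection. The default is the mean ratio
  over the DFT bins inside the analysis band (0.01–0.08 Hz), the same band
  the series were filtered to; `median` and `max` reductions are
  selectable via `aggregate`. The DC bin is always excluded: it lies
  outside the band and carries no fluctuation information after
  filtering.
* **Denominator regularization.** Bins whose denominator magnitude is at
  or below `eps_rel` (default 1e-12) times the largest in-band denominator
  magnitude are *excluded* from the mean rather than clipped; clipping
  would turn near-empty denominator bins into arbitrarily large ratios and
  dominate the average. If every in-band bin is excluded the connection is
  reported as a degenerate-connection error naming the pair.
* **No taper or detrending.** The series reaching the DFT have already
  been band-pass filtered; applying a window on top would change the
  statistic, so none is applied.

The comparison arm computes the Pearson correlation matrix per
subject-visit and its Fisher z-transform (`atanh`), the conventional
undirected functional-connectivity feature.

## Signal preparation

Real acquisitions enter as preprocessed, MNI-normalized 4D volumes (the
package deliberately performs no slice timing, realignment, normalization
or smoothing — those belong to SPM-class tooling upstream) plus an integer
label atlas aligned to the same grid. The pipeline discards the first 10
volumes (magnetization equilibrium), averages voxels per label per time
point, and band-pass filters each region's series.

The filter is a Butterworth band-pass of design order 4 applied forward
and backward, giving zero phase and an effective order of 8. The band
edges (0.01–0.08 Hz at TR = 3 s, Nyquist 1/6 Hz) are the standard
resting-state BOLD band. Because 130-point series are short, edge handling
matters: each series is extended by odd reflection at both ends by three
filter lengths (27 samples at order 4) before the forward–backward pass,
and each pass starts from the DC steady state of its edge sample (past
inputs held at that level, past outputs zero, since the band-pass has zero
DC gain). This suppresses the step transient that otherwise leaks a
constant offset into the output. The test suite pins the contract: a
0.04 Hz sinusoid is retained within 10% amplitude, DC and a 0.15 Hz
component are attenuated by at least 20 dB, the filter is linear, and the
cross-correlation peak with a passband input sits at lag 0.

## The longitudinal screen

Subjects are measured at baseline and two follow-ups. Per group and per
connection, the procedure is:

1. a paired t-test on baseline → visit 1,
2. a paired t-test on visit 1 → visit 2,
3. a one-way ANOVA over the three visit samples,

and a connection is flagged significant only when **all three** p-values
fall below α (default 0.05). The intersection is deliberately stricter
than any single test. The sign pattern of the two t statistics
(`positive_to_negative`, `negative_to_positive`, `same_sign_*`) classifies
the temporal profile — a rise-then-fall coupling produces
positive→negative. Exact zero statistics take the sign of their nonzero
partner; a double zero is classified `same_sign_positive` by convention.

Choices made where the design was open:

* **Paired by default.** The same subjects are measured at every visit, so
  the paired t-test is the natural choice; Welch's independent test is
  selectable (`paired = FALSE`).
* **ANOVA flavor.** A one-way F over visits-as-groups. A repeated-measures
  ANOVA would model the subject pairing too; it is out of scope here, and
  the paired t-tests already carry the within-subject information.
* **Normalization.** A sum-of-squares normalization step is often attached
  to this procedure, but its axis is ambiguous, and the axis matters:
  * *per connection* (each visit's cross-subject vector scaled to unit
    sum of squares) removes exactly the cross-visit rescaling the screen
    is meant to detect — after scaling, only changes in the
    coefficient of variation remain detectable, a mean shift of size δ is
    attenuated by roughly σ²/(μ²+σ²), and the shared norm couples the
    subjects, making the t-test conservative;
  * *per subject* (each subject-visit's whole connection vector scaled to
    unit sum of squares) is useful on real data, where it removes
    session-scale amplitude differences, but it couples all connections
    through the shared norm: a strong change in a few connections shifts
    every other connection's normalized values, so untouched connections
    no longer behave like nulls.
  Because either axis breaks a property the package commits to (power
  against injected effects, or null behavior of untouched connections),
  the default is `normalize = "none"`: the screen tests the connection
  values as computed. Both axes remain one switch away and are the
  right choice in settings their caveats do not touch.
* **No multiplicity correction by default.** The screen is an uncorrected
  p < 0.05 sweep over 13,340 connections — a screening design whose
  expected false-positive floor is nonzero and visible in any null group.
  A Benjamini–Hochberg option (`correction = "BH"`) tightens the
  threshold for users who want FDR control; reported p-values stay
  unadjusted either way.
* **Degenerate data.** Connections with zero-variance paired differences
  or zero within-visit variance are reported with NA statistics,
  `significant = FALSE` and `degenerate = TRUE` — flagged, never silently
  dropped.

The heavy per-group sweep runs through `screen_visits()`, a vectorized
closed-form implementation (t, F and their distribution tails via
`pt`/`pf`). Its agreement with per-connection recomputation by
`paired_ttest()`/`oneway_anova()` and with `stats::t.test` /
`stats::oneway.test` is asserted in the test suite on random samples, so
the fast path and the textbook path cannot drift apart.

## Region table and networks

The packaged table (`inst/extdata/aal116_regions.tsv`) lists the 116 AAL
regions in the standard atlas ordering — odd index left, even index right
for the 45 paired cerebral and 9 paired cerebellar regions, eight midline
vermis subdivisions at the end — with the abbreviations in common use
(PreCG, SFGdor, …, Vermis10; `.L`/`.R` suffixes mark hemisphere).

Each region carries one of six functional-network labels: sensorimotor
cortex (SMC), executive attention network (EAN), visual cortex (VC),
cerebellum (Cereb), default-mode network (DMN) and subcortical nuclei
(SN). **This mapping is a documented reconstruction**: no complete
standard assignment of all 116 AAL regions to these six networks exists,
so the table anchors the regions with well-established memberships
(cerebellum and vermis → Cereb; calcarine and occipital cortex → VC;
pre/postcentral, paracentral lobule, Heschl, superior parietal and
superior temporal → SMC; hippocampus, temporal poles' middle part and the
basal ganglia → SN; rectus and medial prefrontal → DMN; superior temporal
pole and lateral prefrontal → EAN) and fills the remainder from
conventional AAL groupings. Any region can be reassigned through a YAML or
TSV override (`load_region_table(mapping_override = ...)`); network-level
results should be read with the mapping's reconstructed status in mind.

## The synthetic cohort generator

`generate_cohort()` emulates the statistical structure the screen assumes,
not BOLD physiology:

* Each region's latent signal is a sum of 5 sinusoids with frequencies
  drawn uniformly in 0.01–0.08 Hz, random phases, random amplitudes,
  rescaled to unit standard deviation — band-limited content without any
  hemodynamic model.
* Latents are drawn once per subject and held fixed across visits;
  Gaussian white noise (default SD 0.5, a moderate signal-to-noise
  condition) is redrawn per visit. Under no injected effects, a
  connection's values are therefore exchangeable across visits — the
  basis of the null calibration tests.
* An `effect_spec(group, source, target, visit_gains)` adds the source
  region's *latent* (not its noisy observation) to the target's series,
  scaled by a per-visit gain. Because the coupling acts on the latent,
  the induced connectivity change is monotone in the gain in expectation,
  which the tests verify by Monte-Carlo. Note that an injected coupling
  changes the target region's entire spectrum, so every connection
  touching the target responds — the set of truly affected connections is
  much larger than the set of injected pairs, and significant counts in a
  demonstration run reflect that.
* The default layout reproduces the study scale: groups NC 29, EMCI 23,
  LMCI 24, AD 23; three visits; 116 regions × 130 time points at TR = 3 s.
  `default_effects()` adds a deliberately scaled-down longitudinal effect
  structure (none in NC; 12 effects in EMCI sourced from Vermis_3 and the
  left calcarine; 8 in LMCI from the left Cerebelum_10 and right
  hippocampus; 5 in AD from the left superior temporal pole with
  rise-then-fall gains and one from the right superior temporal gyrus with
  the opposite pattern), so a default run shows group counts ordered
  EMCI > LMCI > AD > NC above the uncorrected screen's null floor.

What the generator does **not** emulate: hemodynamic response shapes,
head motion, physiological (cardiac/respiratory) noise, scanner drift,
spatial autocorrelation between neighboring regions, or session-scale
amplitude differences. Tests passing on this generator therefore certify
the pipeline's statistical and numerical behavior — calibration under
exchangeable nulls, power against planted directed couplings, conservation
identities of the summaries — not robustness to those real-data artifacts.

`generate_labeled_volume_fixture()` builds small 4D volumes whose labeled
voxel blocks carry known region series (with a background margin of label
0), used to verify NIfTI ingestion and ROI-mean extraction exactly.

## Monte-Carlo designs and problem sizes

The calibration and power properties are verified at sizes chosen to make
the checks sharp yet quick:

* **Null calibration**: 12 independent null cohorts of 15 regions and 29
  subjects give 2,520 directed connections. Connections within one cohort
  share regions and are correlated; independence across cohorts keeps the
  empirical rejection rate near its binomial concentration, which is what
  the acceptance band assumes. The single paired t-test is expected near
  its nominal 5% level (slightly conservative, as the in-band mean-ratio
  values are heavy-tailed), and the three-test intersection stays below
  1%.
* **Power**: 200 replicate cohorts of 10 regions and 25 subjects with one
  injected effect (gains 0 → 3 → 0), chosen to realize a standardized
  per-transition shift of at least 1 on the tested connection — the test
  verifies the realized shift before asserting recovery in at least 80%
  of replicates, and that connections touching neither effect region stay
  at the null rate. The region count does not change the per-connection
  statistic; it only sets how many pure-null connections ride along.
* **End to end**: the default synthetic run (99 subjects × 3 visits,
  116 × 130, CorrTF and Pearson arms, 13,340 directed connections per
  group) is executed twice and must produce byte-identical result files;
  it completes in well under a minute per run on one CPU.

## Limitations

* The region→network mapping is a reconstruction (above); network-level
  summaries inherit its uncertainty.
* The screen models no covariates (age, sex, scanner); it is a per-group
  marginal analysis.
* The uncorrected default implies a known false-positive floor across
  13,340 connections; use `correction = "BH"` when an FDR-controlled set
  is wanted.
* CorrTF is a magnitude-ratio feature: it carries no phase information,
  and its directionality is an interpretation of which series sits in the
  denominator, not a causal claim.
* Real-data mode expects fully preprocessed, atlas-aligned inputs; no
  spatial preprocessing is performed or checked beyond grid agreement.
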