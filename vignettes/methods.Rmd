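---
title: "Directed EEG connectivity and smartphone sentiment: models and methods"
author: "rpdcnet authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Directed EEG connectivity and smartphone sentiment: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rpdcnet)
```

## Scope

`rpdcnet` implements an analysis chain for resting-state EEG effective
connectivity and its association with clinical and digital-phenotyping
outcomes: (1) multivariate autoregressive (MVAR) modelling of
source-level time series and renormalized partial directed coherence
(rPDC); (2) projection of source-space connectivity onto an anatomical
atlas by Gaussian dipole-density weighting, with a node-retention rule;
(3) cluster-mass permutation tests of group differences on the directed
connectivity graph; (4) reconstruction and sentiment labelling of
smartphone keystroke logs; and (5) outcome regressions linking selected
connectivity edges to follow-up symptom scores and person-level negative
sentiment. Synthetic-data generators with known ground truth make every
stage testable end to end; the pipeline deliberately starts at source
time series plus dipole coordinates (artifact rejection, ICA
decomposition and dipole fitting are upstream concerns).

## The MVAR model and rPDC

Each recording is modelled as a stationary vector autoregression

$$x_t = \sum_{r=1}^{p} A_r x_{t-r} + \varepsilon_t,
  \qquad \varepsilon_t \sim (0, \Sigma),$$

fitted by least squares after per-channel mean removal. The 3-minute
recording is fitted as one continuous series: rPDC's renormalization
consumes the coefficient-estimator covariance, and an unsegmented fit
maximises its precision. `order = "auto"` minimises BIC over orders up
to 20.

For an ordered pair (target $i \leftarrow$ source $j$) the Fourier
transform of the cross-coefficients is
$\bar A_{ij}(\omega) = \sum_r a_{ij,r}\, e^{-2\pi i \omega r / f_s}$,
stacked as $X_{ij}(\omega) = (\mathrm{Re}, \mathrm{Im})^\top$. Its
$2\times2$ covariance $V_{ij}(\omega)$ propagates the asymptotic
coefficient covariance $\Sigma_{ii}\,[R^{-1}]_{jj}/N$ (the lag block of
source $j$ in the inverse regressor covariance, the standard Kronecker
form; a bootstrap covariance could be swapped in) through the
cosine/sine weights. The statistic

$$\lambda_{ij}(\omega) = \frac{1}{N}\, X_{ij}(\omega)^\top
  V_{ij}(\omega)^{-1} X_{ij}(\omega)$$

is the renormalized partial directed coherence: $N\lambda$ is
asymptotically $\chi^2(2)$ when the influence $j \to i$ is absent,
making values comparable across pairs and frequencies. The suite checks
this calibration directly (mean $\approx 2$ at the null, KS agreement
with $\chi^2(2)$, empirical type-I rate of the 5% threshold).

Two numerical consequences shaped the design:

* **Order 2 has no frequency resolution.** With $p$ lags the
  renormalization multiplies a $2 \times p$ trigonometric matrix; for
  $p \le 2$ it is square, so $\lambda$ is *exactly* constant in
  $\omega$. `computeRpdc()` therefore refuses $p < 2$ (singular
  covariance), and band-specific structure requires $p > 2$.
* **Band structure lives at long lags at high sampling rates.** At
  500 Hz, distinguishing 2 Hz from 10 Hz requires tens of lags. The
  generator defaults emulate the study recordings (500 Hz, 180 s,
  stated below), but demonstrations, calibrations and the test suite
  generate at 100 Hz — comfortably above twice the highest band edge
  (40 Hz) — where one oscillation period spans ~9 samples and modest
  model orders resolve the bands.

Band averages are arithmetic means of $\lambda$ over grid frequencies
(default 1–40 Hz in 0.5-Hz steps, resolving the narrowest band with
six points) in delta [1, 4), theta [4, 8), alpha [8, 14), beta [14, 30)
and gamma [30, 40] Hz; intervals are left-closed/right-open with gamma
right-closed. The natural log is applied only at the statistics and
association stages, never before band averaging.

## The synthetic MVAR cohort

Each source channel is an AR(2) oscillator with pole angle
$2\pi f_c/f_s$ at its band's centre frequency and pole modulus 0.95 — a
clear spectral peak inside the band. A planted coupling adds
cross-coefficients from source to target shaped as a damped cosine at
the band centre spanning roughly one oscillation period
(`round(fs / fc)` lags, capped at 48), normalised so `strength` is the
peak transfer gain in [0, 1). A single-lag coupling was rejected
because rPDC renders it frequency-flat (above), which would make
planted "band-specific" differences appear in every band. Group 2 adds
`groupDelta` to flagged couplings and differs in nothing else. Every
generated model is verified stationary (companion spectral radius
< 1); a violating spec is rejected naming the offending coupling.
Dipole coordinates are drawn isotropically (default sd 6 mm) around the
assigned atlas node centres so the density projection is exercised
nontrivially. Defaults mirror the study conditions: 500 Hz sampling and
180 s of eyes-closed rest.

What the generator does *not* emulate: volume conduction, blinks and
line noise, non-stationarity, and realistic language content (the
keystroke generator draws from three disjoint word lists). Passing
tests therefore demonstrate correctness of the estimators and decision
procedures under the stated model, not robustness to EEG artifacts.

## Atlas projection and node retention

Each dipole is convolved with an isotropic 3-D Gaussian kernel
(FWHM 20 mm, $\sigma = \mathrm{FWHM}/(2\sqrt{2\ln 2}) \approx 8.49$ mm)
and the kernel mass falling on each node's support (a deterministic
5-mm grid clipped to the node sphere) is normalised by the total mass
over the whole atlas support. Source-level connectivity is projected to
node pairs as a *weighted mean* — each IC pair (source $s$, target $t$,
$s \neq t$) weighted by $w_s(\mathrm{ROI}_A)\,w_t(\mathrm{ROI}_B)$ and
the sum divided by the total weight. A plain weighted sum would
conflate dipole count with connectivity strength. Self-pairs (one IC as
both source and target) are always excluded so an IC spanning two nodes
cannot manufacture flow between them; node pairs with zero weight are
missing, not zero.

"Contributes at least one cortical dipole" is operationalised as the
dipole's maximal-weight node: a node is retained when at least 65% of
participants contribute, and the report includes the fraction of total
dipole-density mass captured by retained nodes. Retention is monotone
in the threshold. The bundled `toyAtlas()` (ten 15-mm spheres) is a
test and demo surface, not an anatomical reference; a delimited
node-table reader accepts real atlases.

## Cluster-mass permutation testing

Per directed edge and band, groups are compared with pooled two-sample
t statistics on log connectivity (47 retained nodes give 1081 node
pairs per band, each carrying two directed values). Edges with
uncorrected two-sided $p$ below the cluster-forming threshold (default
$10^{-4}$) are clustered by band-local adjacency — two directed edges
are adjacent iff they share a node and belong to the same band — with
positive and negative differences clustered separately (two-tailed
behaviour). The adjacency rule is the simplest line-graph choice and is
isolated in one function, deliberately swappable. A cluster's mass is
its summed $F = t^2$; significance compares observed masses to
`nPerm = 2000` full label reshuffles, with corrected
$p = (1 + \#\{\text{null} \ge m\})/(n_{\mathrm{perm}} + 1)$, never
below $1/(n_{\mathrm{perm}}+1)$. Both the conservative max-cluster null
(default) and the second-largest-cluster null are available; on any
dataset the max-cluster corrected p is at least the second-largest one,
and the suite asserts this. Missing edges are excluded from clustering
rather than imputed.

The family-wise error calibration (`estimateFwer()`) uses 500 replicate
global-null cohorts of 20 + 20 participants, 10 nodes, 20-s recordings
at 100 Hz, order-4 fits and 200 shuffles. The permutation test's
validity rests on group exchangeability alone, so the shorter
recordings and fixed order affect power, not level.

## Keystroke reconstruction and sentiment metrics

Messages are reconstructed by replaying keypresses: backspace deletes
the last buffered character (no-op when empty), and a buffer is emitted
at a pause $\ge$ 5 s, an app switch, or an enter key. A secondary
logger-style segmentation rule (<50% longest-common-prefix overlap
starts a new message; larger overlaps merge as revisions) is available
behind a flag, off by default. Partial or redundant strings — a message
wholly contained in the next one, same app, within 60 s — are dropped
in a single left-to-right pass. Deduplication runs *before* the length
filter (reconstruct → dedupe → retain), so a partial fragment cannot
survive by being shortened first. Retained messages have more than one
character, or are a single emoji.

Cleaning removes URLs and @-mentions, collapses runs of three or more
identical letters to one ("noooo" → "no"; the rule can over-collapse,
e.g. "soooon" → "son"), normalises whitespace, and preserves
punctuation, case, emojis and hashtags. Cleaning is idempotent. The
bundled classifier is a deterministic lexicon stub (majority of matched
positive vs negative tokens, ties neutral) standing behind the same
interface a transformer model would use: any function from text to
one of three labels can be plugged in.

Daily negative/positive proportions are computed per calendar day (UTC
midnight boundaries by default; the zone is a parameter) and averaged
*unweighted* over valid days — days with at least 3 messages — within
the first 180 days of observation; participants with fewer than 7 valid
days are flagged excluded. Sub-threshold days are excluded from the
person-level average as well as from inclusion; a flag can revisit
this, since weighting by message count is equally defensible.

The keystroke generator separates genuine messages by at least 90 s so
the 60-s deduplication window can only fire on the partial-duplicate
artifacts it injects deliberately; this makes the ground truth exactly
recoverable and the round-trip test exact.

## Association models

The symptom model is a negative-binomial regression (log link) of the
follow-up clinical score on a baseline connectivity edge (log-rPDC),
adjusting for baseline score, age, sex and site, with sandwich
standard errors. The instrument's total ranges from 17 to 113, so the
model applies to the excess above the floor of 17; the synthetic
outcome generator draws `17 + NB(mu, size)` accordingly (intercept 2.5
on the log-mean scale, a mean excess of ~12 points). A repeated-measures
GEE formulation with a single follow-up outcome adjusted for baseline
collapses to exactly this single-equation model, which is why the
robust-SE negative-binomial regression is the implementation. The
sentiment model is a linear regression of mean daily negative-sentiment
proportion on the edge, adjusting for positive sentiment (to absorb
overall expressivity), age, sex, site and phone type — deliberately
*not* baseline depression, preserving behavioural variance in
linguistic expression. Sex, site and phone type are 0/1 indicators.

Standardized effects use the t-to-d conversion $d = 2t/\sqrt{df}$
(robust z for the negative-binomial family), which is invariant to
predictor rescaling; this is the package's documented choice where no
canonical d exists for such coefficients. A McFadden pseudo-R² is the
natural companion for the count model but no claim is made that it
matches any particular R² convention. Per-band p-values are reported
unadjusted, with a supplementary Benjamini–Hochberg report
(`fdrAcrossBands()`) alongside.

## Orchestration and reproducibility

`runConfig()` collects every threshold with the reference defaults
(20 mm, 0.65, 2000 shuffles, $10^{-4}$, 5 s, 60 s, 3 messages, 7 days,
180 days) in one auditable object that is echoed into every manifest.
`runPipeline()` executes stages in dependency order on a synthetic
cohort, derives one sub-seed per stage from the master seed, logs stage
counts (nodes retained, edges tested, clusters found, messages
included), and writes md5 hashes of all outputs; identical configs
reproduce identical hashes. A thin command-line wrapper
(`inst/scripts/rpdcnet-cli.R`) exposes the stages as subcommands.

## Problem sizes used by the validation suite

The test suite and the acceptance script use these scales, chosen so
each check's Monte-Carlo error is small relative to its tolerance:
family-wise error, 500 replicate null cohorts (10 nodes, 20 + 20
participants, 20 s at 100 Hz, 200 shuffles); chi-squared calibration,
20 batches of 30 uncoupled recordings (100 s at 100 Hz); directionality
recovery, 100 seeded recordings; regression recovery, 100 seeds at
n = 300 per model plus 500 null seeds for the type-I rate. Parameter
recovery targets (95% CI coverage in at least 90% of seeds, type-I rate
in [0.02, 0.09]) follow binomial error bounds at those counts.

## Known limitations

Source separation quality, dipole localisation error and volume
conduction are out of scope; the atlas projection inherits whatever
spatial error the upstream dipole fits carry. The lexicon classifier is
a stub: its labels are exact on generated text but are no statement
about natural language. The elongation rule follows its single
documented example and can over-collapse. The permutation test controls
the family-wise error weakly (any-cluster level), not per-cluster
strongly. rPDC inherits MVAR assumptions — linearity and stationarity
over the fitted window.
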