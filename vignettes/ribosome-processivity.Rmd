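---
title: "Quantifying ribosome processivity with the ribosome density index"
author: "riboRDI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying ribosome processivity with the ribosome density index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riboRDI)
```

## The problem and the model

A translating ribosome must stay bound to its mRNA over hundreds of
catalytic cycles. When processivity fails, ribosomes drop off before the
stop codon, and ribosome-profiling coverage becomes 5′-skewed: initiation
keeps loading ribosomes at the start, but fewer and fewer survive to
distal codons. riboRDI summarizes that skew per transcript with the
**ribosome density index**,

$$\mathrm{RDI} \;=\; \frac{\sum_{i=1}^{n} i \, d_i}{n \sum_{i=1}^{n} d_i},$$

where $d_i$ is the (TPM-normalized) ribosome-protected-fragment depth at
codon $i$ (1-based) and $n$ the ORF length in codons, stop codon
excluded. RDI is the density-weighted mean codon position expressed as a
fraction of the ORF. Its properties drive everything downstream:

* a uniform profile gives $\mathrm{RDI} = (n+1)/(2n) \approx 0.5$;
* all density on codon 1 gives $1/n$, all on codon $n$ gives 1, and every
  non-zero profile lies in $[1/n,\,1]$;
* RDI is invariant to rescaling the profile (so raw counts and
  TPM-normalized densities give the same value);
* reversing a profile maps RDI to $(n+1)/n - \mathrm{RDI}$.

Under per-codon drop-off with survival probability $r = 1 - p$ per
elongation step, expected occupancy is geometric, $d_i = r^{i-1}$, and
RDI has the closed form implemented in `rdiGeometricClosedForm()`:

$$\mathrm{RDI}(n, r) = \frac{1 - (n+1)r^n + n r^{n+1}}{n(1-r)(1-r^n)}.$$

This analytic oracle anchors the simulator tests: the deterministic
drop-off simulator must match it to $10^{-10}$, and stochastic occupancy
must match the geometric expectation within Monte-Carlo error. When
$n(1-p)$ cancellation would degrade the analytic ratio (roughly
$n\,p < 1$), the function evaluates the finite sums directly instead;
both branches are exact finite-sum expressions, not simulations.

## Two failure modes, two density shapes

The package models the two elongation pathologies that profiling data
can confuse:

* **Drop-off** (processivity failure): each elongation event aborts with
  probability $p$ (`applyDropoff()`, `per_codon` mode; the default,
  matching "1 abort per 40 elongation events" at $p = 1/40$). A
  `per_transit` variant lets a fraction $p$ of ribosomes abort once, at
  a uniformly random codon, giving a linear rather than geometric decay.
  Both interpretations are implemented because the phrase "translation
  events" is ambiguous; the geometric one is the default.
* **Stalling**: one stall site per transcript with `fold`-times higher
  density 5′ of the site than 3′ of it (`applyStall()`; default the
  literal region model, with a local-window variant for a queued-ribosome
  picture). Stall sites are drawn from the central 90% of codons so both
  regions are non-empty.

Averaged over random stall positions, stalling moves the pool mean RDI
moderately below the uniform value, while drop-off at the same nominal
rate collapses it far more — drop-off compounds per codon, stalling does
not. The package asserts only this *ordering* (drop-off < stalling <
uniform): the absolute simulated means depend on unstated details of the
generative model (e.g. whether pools reuse empirical per-transcript
densities), so they are not treated as fixed-point targets.

## The analysis pipeline

1. **Profiles** — `readDepth()` ingests transcript-coordinate bedGraph
   (0-based, half-open; gaps are zero) or a per-codon TSV;
   `sumDepthToCodons()` sums nucleotide triplets, dropping a partial
   trailing codon with a warning. No P-site offset is applied by default
   (an `offset` argument exists because published practice varies).
2. **Normalization** — `computeTPM()` (standard TPM) and
   `normalizeProfiles()` divide RPF counts by matched total-mRNA TPM.
3. **Filtering** — `filterTranslated()` removes a transcript when *any*
   single replicate has strictly more than 25% zero-density codons. The
   zero test is exact equality: zeros are identical before and after
   normalization, so applying the rule post-normalization (as done here)
   removes the same set either way.
4. **RDI** — `computeRdiSet()` computes per-replicate RDIs and averages
   them per condition (pooling replicate counts first is available but
   not the default; with balanced replicates the two choices differ
   negligibly and the averaging convention is stated rather than
   guessed). `binRdiByCovariate()` (rank deciles, ties broken by
   transcript id, Spearman correlation) serves the ORF-length and
   codon-optimality analyses; `pairedRdiComparison()` counts the paired
   scatter halves and tests the two value sets with a Mann-Whitney U.
5. **Codon optimality** — `relativeAdaptiveness()` and `computeCai()`
   implement the Sharp–Li codon adaptation index: $w$ is abundance over
   the synonymous-family maximum (zero-abundance codons get
   pseudo-abundance 0.5), CAI the log-space geometric mean of $w$ over
   sense codons, trailing stop excluded, internal stops an error.
6. **Metagene curves** — `metageneLengthNorm()` (codon centers
   $(i-0.5)/n$ into equal-width fraction bins) and `metagenePerCodon()`
   (absolute codons, default window 5–105 because read mapping at the
   start codon is unreliable; shorter transcripts are excluded, not
   padded). Per-transcript profiles are first divided by their own mean
   (default) or maximum. Means carry 99% percentile-bootstrap CIs
   (B = 1000, seeded).
7. **Statistics** — `mannWhitneyU()` (exact permutation distribution for
   small tie-free samples, full enumeration with midranks for small tied
   ones, tie-corrected normal approximation with continuity correction
   otherwise), `perRegionTests()` (each bin/codon tested independently;
   BH adjustment opt-in, off by default to report raw per-region
   p-values), and `empiricalPvalue()` (Monte-Carlo subsampling:
   N = 10,000 random same-size transcript sets from all records, one
   sided with larger control-minus-treated loss as extreme, and the
   never-zero estimator $p = (k+1)/(N+1)$).

## What the synthetic study emulates

`generateFixtures()` produces a fully synthetic two-condition,
two-replicate study whose defaults encode the conditions of the kind of
mTORC1-inhibition experiment it emulates, rather than tunable knobs:

* ORF lengths log-normal with median 500 codons and log-sd 0.3 — the
  log-normal matching both the ~500-codon median and the ~520-codon mean
  of the filtered translatome it emulates
  ($500\,e^{0.3^2/2} \approx 523$); bounded below at 60 codons so the
  early analysis window always fits.
* Baseline 30 expected footprints per codon with independent Poisson
  noise per replicate.
* A baseline per-codon drop-off hazard of $5\times10^{-4}$ in the
  control condition, chosen analytically so the genome mean RDI sits
  near 0.48 for 500-codon ORFs.
* In the treated condition, an *additional* hazard confined to codons
  15–55: 0.02 on a designated 10% target subset (driving the target-set
  mean toward ~0.44, a loss of ~0.04) and 0.009 on the remaining
  transcripts (the genome-wide component, ~2–4% mean RDI loss). Setting
  both excesses to zero yields an exact null construction.

Two consequences matter for interpreting the per-codon metagene on this
construction. First, with *mean* normalization an early-window density
loss inflates the normalized values of every other codon (the
per-transcript normalizer shrinks), so the treated curve separates
everywhere; *max* normalization anchors both conditions at their
(pre-window) maximum and is the right lens for asking *where* divergence
begins. Second, a persistent level offset remains 3′ of the window under
any normalization — only the *growth* of the gap is confined to codons
15–55, and after codon 55 the curves run parallel. The package's checks
therefore assert: no divergence before the window, strong per-region
significance inside it, and a stable (non-growing) gap after it.

## Numerical and design choices

* **Seeds.** Every stochastic routine accepts a seed and evaluates under
  a temporary RNG state, leaving the caller's stream untouched;
  simulation configs carry their seed, so identical configs give
  byte-identical fixture files.
* **Equality tolerances.** "Equal RDI" in the paired comparison means
  $|\Delta| < 10^{-12}$; the zero-codon filter uses exact equality.
* **Degenerate inputs.** All-zero profiles make RDI undefined and raise
  errors naming the transcript; an all-identical covariate makes rank
  binning and Spearman degenerate and is rejected; empty samples,
  all-zero libraries, overlapping bedGraph intervals and ragged TSV rows
  are errors with positions.
* **CI method.** The percentile bootstrap of the mean was chosen because
  only a confidence level, not a method, is stated for the metagene
  error bars.
* **Problem sizes.** The shipped checks run the simulators at 1000
  transcripts, the synthetic study at 200 transcripts × ~500 codons,
  Mann-Whitney enumeration up to $n_1+n_2 = 8$, and the null-calibration
  of the empirical test at N = 999 with 200 repetitions; these sizes
  give stable statistics in seconds while exercising every code path.

## Limitations

The generators are density-shape models, not elongation kinetics: no
codon-specific dwell times, collisions, or initiation dynamics, and the
length model is narrower than a real transcriptome's. Poisson noise
understates overdispersion of real footprint counts. Passing the
synthetic-study checks therefore shows that the pipeline recovers the
signatures its own generative model plants — early-window drop-off
lowering RDI, confined divergence onset, paired-scatter asymmetry — not
that any particular biological dataset will show them. CAI values on
real data are additionally reproducible only up to the choice of codon
usage table; the table shipped under `inst/extdata/` is synthetic and
for testing and examples only.
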