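# riboRDI

Quantifying **ribosome processivity** from ribosome-profiling data.

During elongation the ribosome must stay mRNA-bound over hundreds of
catalytic cycles. When it drops off early, ribosome-protected-fragment
(RPF) coverage becomes 5′-skewed: density is high near the start codon
and tapers toward the stop. riboRDI condenses that skew into one number
per transcript, the **ribosome density index (RDI)**:

```
        Σᵢ i · dᵢ
RDI = ─────────────        i = 1..n (codons), dᵢ = normalized RPF depth
        n · Σᵢ dᵢ
```

RDI is the density-weighted mean codon position as a fraction of the ORF
length `n` (stop codon excluded). Evenly covered ORFs give
`(n+1)/(2n) ≈ 0.5`; progressive drop-off pushes RDI below 0.5; every
non-zero profile lies in `[1/n, 1]`. The package is aimed at anyone with
per-codon (or per-nucleotide) Ribo-seq depth over coding regions —
from bulk MEF experiments down to small synthetic benchmarks — who wants
to ask whether a treatment, a gene set, or a sequence feature changes
ribosome processivity.

Besides the metric itself, the package provides the full supporting
pipeline: depth → codon summation, TPM normalization, the
">25% zero-density codons in any replicate" translation filter, the
Sharp–Li codon adaptation index (CAI), length-normalized and per-codon
metagene curves with 99% bootstrap confidence intervals, per-region
Mann-Whitney tests, Monte-Carlo subsampling empirical p-values for
target gene sets, and generative simulators of ribosome **drop-off**
(geometric decay; 1 abort per 40 elongation events as the reference
setting) and **stalling** (fold-elevated density 5′ of a stall site).

## Worked example

A fully synthetic two-condition study: a control with a small baseline
drop-off hazard everywhere, and a treatment adding extra drop-off inside
codons 15–55 — strongly on a 10% "target" subset, weakly genome-wide.

```r
library(riboRDI)

computeRdi(c(3, 2, 1, 0))            # 5'-skewed toy profile
#> [1] 0.4166667
rdiGeometricClosedForm(500, 1 - 1/40) # expected RDI, p = 1/40 drop-off
#> [1] 0.07999682

fx  <- generateFixtures(fixtureConfig(seed = 7))
set <- filterTranslated(fx$profiles)      # >25%-zero-codon rule
set
#> CodonProfileSet with 800 profile(s): 200 transcript(s),
#>   conditions { control, treated }, replicates { r1, r2 }

tab <- computeRdiSet(set)                 # per-transcript RDI table
round(c(control = mean(tab$mean_control),
        treated = mean(tab$mean_treated)), 3)
#> control treated
#>   0.478   0.462

cmp <- pairedRdiComparison(tab, "control", "treated")
cmp[c("nHigherA", "nHigherB", "p")]      # paired scatter halves
#> $nHigherA [1] 200   $nHigherB [1] 0   $p [1] 1.41e-56

targets <- fx$truth$transcript_id[fx$truth$is_target]
empiricalPvalue(deltaRdi(tab, "control", "treated"), targets,
                N = 10000, seed = 8)
#> EmpiricalTest: observed mean ΔRDI = 0.03369 over 20 targets;
#>   0 of 10000 null subsamples >= observed; one-sided p = 9.999e-05
```

Reading: the treatment lowers the genome mean RDI from 0.478 to 0.462
(reduced early processivity on most transcripts — every one of the 200
transcripts sits above the diagonal of the paired scatter), and the
target set's mean RDI loss of 0.034 is larger than that of any of
10,000 random 20-transcript sets (empirical p ≈ 1e-4, the estimator's
minimum at N = 10,000).

Metagene views localize the effect: `metagenePerCodon(set,
normalization = "max")` shows the two conditions overlapping before
codon ~15, diverging through codons 15–55, and running parallel after;
`perRegionTests()` returns the per-codon Mann-Whitney p-values.

Real data enter through `readDepth()` (transcript-coordinate bedGraph or
per-codon TSV), `computeTPM()` + `normalizeProfiles()` for RPF/TPM
densities, and `readCdsFasta()` + `readCodonUsage()` +
`relativeAdaptiveness()` + `computeCai()` for codon-optimality analyses
(`binRdiByCovariate()` bins RDI by CAI deciles or log ORF length). A
small **synthetic** usage table ships in `inst/extdata/` for examples.

## Command line

A thin CLI over the same functions lives at
`inst/scripts/rdi-tools.R` (subcommands `build`, `filter`, `rdi`, `cai`,
`simulate`, `fixtures`, `metagene`, `compare`, `test-empirical`):

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts/rdi-tools.R", package="riboRDI"))')" \
    fixtures --n 200 --seed 7 --out-prefix study
Rscript ... rdi --profiles study_profiles.tsv --out study_rdi.tsv
```

All output tables are TSV with `#`-prefixed provenance headers (package
version, parameters, seed); identical seeds give byte-identical files.
Exit codes: 0 success, 2 validation failure, 3 I/O failure.

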