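#' CodonProfileSet: per-codon RPF depth profiles
#'
#' Container for per-codon ribosome-protected-fragment (RPF) depth
#' profiles across transcripts, conditions and replicates. Each row of the
#' underlying [S4Vectors::DataFrame] holds one profile: a transcript
#' identifier, a condition label, a replicate label and an
#' [IRanges::NumericList] element of length `n` (the ORF length in codons,
#' stop codon excluded) with non-negative per-codon depth. After
#' [normalizeProfiles()] the table additionally carries the matched
#' total-mRNA TPM and the per-codon densities (counts / TPM).
#'
#' Validity requires unique (transcript, condition, replicate) keys,
#' non-negative depths, and a single codon length per transcript across
#' all its profiles.
#'
#' @slot data A `DataFrame` with columns `transcript_id`, `condition`,
#'   `replicate`, `counts` (`NumericList`), and optionally `tpm`
#'   (`numeric`) and `densities` (`NumericList`).
#' @slot removalLog A `DataFrame` recording transcripts removed by
#'   [filterTranslated()] (columns `transcript_id`, `condition`,
#'   `replicate`, `zero_fraction`).
#'
#' @seealso [CodonProfileSet()] for construction from plain lists.
#' @export
setClass("CodonProfileSet",
         slots = c(data = "DataFrame", removalLog = "DataFrame"))

setValidity("CodonProfileSet", function(object) {
  d <- object@data
  need <- c("transcript_id", "condition", "replicate", "counts")
  if (!all(need %in% colnames(d)))
    return(paste0("missing column(s): ",
                  paste(setdiff(need, colnames(d)), collapse = ", ")))
  if (nrow(d) == 0L) return(TRUE)
  if (!is(d$counts, "NumericList"))
    return("'counts' must be a NumericList")
  key <- paste(d$transcript_id, d$condition, d$replicate, sep = "\r")
  if (anyDuplicated(key))
    return("duplicated (transcript_id, condition, replicate) keys")
  n <- lengths(d$counts)
  if (any(n < 1L)) return("every profile must have at least one codon")
  if (any(unlist(d$counts, use.names = FALSE) < 0))
    return("negative per-codon depth")
  byTx <- tapply(n, d$transcript_id, function(x) length(unique(x)))
  if (any(byTx > 1L))
    return(paste0("codon length differs across profiles of transcript(s): ",
                  paste(names(byTx)[byTx > 1L], collapse = ", ")))
  if ("densities" %in% colnames(d)) {
    if (!is(d$densities, "NumericList") ||
        !identical(unname(lengths(d$densities)), unname(n)))
      return("'densities' must be a NumericList matching 'counts' lengths")
    if (!"tpm" %in% colnames(d) || any(!is.na(d$tpm) & d$tpm <= 0))
      return("normalized profiles require tpm > 0")
  }
  TRUE
})

#' CodonUsageTable: codon abundances and relative adaptiveness
#'
#' Holds a 64-codon abundance table (counts or frequency per thousand) and
#' the derived relative adaptiveness `w` for the 61 sense codons of the
#' standard genetic code: within each synonymous family,
#' `w = f / max(f)`, so the most abundant codon of each family has
#' `w = 1`. Stop codons carry no `w`. Built by [relativeAdaptiveness()].
#'
#' @slot abundance Named numeric: codon (DNA triplet) to abundance.
#' @slot w Named numeric over the 61 sense codons, each in (0, 1].
#'
#' @export
setClass("CodonUsageTable",
         slots = c(abundance = "numeric", w = "numeric"))

setValidity("CodonUsageTable", function(object) {
  sense <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
  if (!setequal(names(object@w), sense))
    return("'w' must cover exactly the 61 sense codons")
  if (any(object@w <= 0 | object@w > 1))
    return("'w' values must lie in (0, 1]")
  aa <- Biostrings::GENETIC_CODE[names(object@w)]
  mx <- tapply(object@w, aa, max)
  if (any(abs(mx - 1) > 1e-9))
    return("each synonymous family must contain w == 1")
  TRUE
})

#' SimulationConfig: parameters of the ribosome-flow simulators
#'
#' Bundles every knob of the generative models: pool size, ORF-length
#' model (fixed lengths, or log-normal with a given median and log-sd,
#' bounded), the uniform baseline ribosome load per codon, the per-codon
#' drop-off probability and its interpretation, the stall fold-change and
#' placement policy, the count-noise model, and the RNG seed that makes
#' every simulation reproducible.
#'
#' @slot nTranscripts Number of mRNAs in the simulated pool.
#' @slot lengthModel `"lognormal"` or `"fixed"`.
#' @slot fixedLengths Codon lengths used when `lengthModel == "fixed"`.
#' @slot medianLength Median ORF length in codons (log-normal model).
#' @slot sdlog Log-scale standard deviation of the length model.
#' @slot minLength,maxLength Bounds applied to drawn lengths (codons).
#' @slot baselineRibosomes Uniform per-codon depth (and, stochastically,
#'   the number of initiating ribosomes per transcript).
#' @slot pDropoff Probability that a ribosome aborts per elongation event.
#' @slot dropoffMode `"per_codon"` (abort hazard at every elongation step)
#'   or `"per_transit"` (a fraction of ribosomes abort once, at a uniform
#'   random codon).
#' @slot stallFold Density fold-change 5' of a stall site (>= 1).
#' @slot stallPolicy `"uniform"` (random site within the central 90% of
#'   codons) or `"fixed"`.
#' @slot stallCodon Stall codon used when `stallPolicy == "fixed"`.
#' @slot noise `"none"` or `"poisson"`.
#' @slot seed Integer RNG seed.
#'
#' @seealso [simulationConfig()], [fixtureConfig()]
#' @export
setClass("SimulationConfig",
         slots = c(nTranscripts = "integer", lengthModel = "character",
                   fixedLengths = "integer", medianLength = "numeric",
                   sdlog = "numeric", minLength = "integer",
                   maxLength = "integer", baselineRibosomes = "numeric",
                   pDropoff = "numeric", dropoffMode = "character",
                   stallFold = "numeric", stallPolicy = "character",
                   stallCodon = "integer", noise = "character",
                   seed = "integer"))

setValidity("SimulationConfig", function(object) {
  if (object@nTranscripts < 1L) return("nTranscripts must be >= 1")
  if (!object@lengthModel %in% c("lognormal", "fixed"))
    return("lengthModel must be 'lognormal' or 'fixed'")
  if (object@lengthModel == "fixed" && length(object@fixedLengths) == 0L)
    return("fixed length model requires fixedLengths")
  if (length(object@fixedLengths) && any(object@fixedLengths < 1L))
    return("lengths must be >= 1 codon")
  if (object@minLength < 1L || object@maxLength < object@minLength)
    return("invalid length bounds")
  if (object@baselineRibosomes <= 0) return("baselineRibosomes must be > 0")
  if (object@pDropoff < 0 || object@pDropoff > 1)
    return("pDropoff must lie in [0, 1]")
  if (!object@dropoffMode %in% c("per_codon", "per_transit"))
    return("dropoffMode must be 'per_codon' or 'per_transit'")
  if (object@stallFold < 1) return("stallFold must be >= 1")
  if (!object@stallPolicy %in% c("uniform", "fixed"))
    return("stallPolicy must be 'uniform' or 'fixed'")
  if (!object@noise %in% c("none", "poisson"))
    return("noise must be 'none' or 'poisson'")
  TRUE
})

#' MetageneCurve: averaged density profiles on a shared axis
#'
#' Result of [metageneLengthNorm()] or [metagenePerCodon()]: per-condition
#' mean normalized ribosome density along a shared axis (ORF-fraction bins
#' or absolute codon indices), with percentile-bootstrap confidence
#' intervals and the per-transcript samples the means were taken over
#' (used by [perRegionTests()]).
#'
#' @slot axisType `"fraction"` or `"codon"`.
#' @slot axis Numeric axis values (bin centers, or codon indices).
#' @slot stats `DataFrame` with columns `condition`, `axis`, `mean`,
#'   `ciLow`, `ciHigh`, `n`.
#' @slot samples Named list (one element per condition) of matrices,
#'   transcripts x axis positions, of per-transcript normalized densities
#'   (`NA` where a transcript contributes nothing to a bin).
#' @slot normalization `"mean"` or `"max"` (per-transcript normalizer).
#' @slot level Confidence level of the intervals.
#'
#' @export
setClass("MetageneCurve",
         slots = c(axisType = "character", axis = "numeric",
                   stats = "DataFrame", samples = "list",
                   normalization = "character", level = "numeric"))

setValidity("MetageneCurve", function(object) {
  st <- object@stats
  need <- c("condition", "axis", "mean", "ciLow", "ciHigh", "n")
  if (!all(need %in% colnames(st))) return("malformed stats table")
  ok <- is.na(st$mean) |
    (st$ciLow <= st$mean + 1e-9 & st$mean <= st$ciHigh + 1e-9)
  if (!all(ok)) return("CI bounds must bracket the mean")
  if (!all(vapply(object@samples, ncol, 1L) == length(object@axis)))
    return("sample matrices must have one column per axis position")
  TRUE
})

#' EmpiricalTest: Monte-Carlo subsampling test result
#'
#' Result of [empiricalPvalue()]: the observed target-set statistic (mean
#' RDI difference, control minus treated), the number of null subsamples,
#' the count of null statistics at least as extreme, and the empirical
#' p-value `(k + 1) / (N + 1)`, which is never zero and never below
#' `1 / (N + 1)`.
#'
#' @slot observed Observed mean difference over the target set.
#' @slot N Number of random subsamples drawn.
#' @slot k Number of null statistics `>=` observed.
#' @slot p One-sided empirical p-value.
#' @slot nTargets Size of the target set.
#' @slot seed Seed used (`NA` if the session RNG stream was used).
#'
#' @export
setClass("EmpiricalTest",
         slots = c(observed = "numeric", N = "integer", k = "integer",
                   p = "numeric", nTargets = "integer", seed = "integer"))

setValidity("EmpiricalTest", function(object) {
  if (object@N < 1L) return("N must be >= 1")
  lo <- 1 / (object@N + 1)
  if (object@p < lo - 1e-12 || object@p > 1 + 1e-12)
    return("p must lie in [1/(N+1), 1]")
  TRUE
})
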