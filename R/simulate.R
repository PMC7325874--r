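#' Build a simulation configuration
#'
#' Constructor with the study's default conditions: a 1000-mRNA pool with
#' log-normal ORF lengths (median 500 codons, log-sd 0.3 -- giving a pool
#' mean near 520 codons, bounded to
#' [30, 5000]), uniform baseline density of 50 ribosome footprints per
#' codon, per-codon drop-off at 1 in 40 elongation events, a 10-fold
#' stall, no count noise.
#'
#' @param nTranscripts Pool size.
#' @param lengthModel `"lognormal"` or `"fixed"`.
#' @param fixedLengths Codon lengths for the fixed model.
#' @param medianLength,sdlog,minLength,maxLength Log-normal length model
#'   parameters (codons).
#' @param baselineRibosomes Uniform per-codon depth.
#' @param pDropoff Per-elongation-event abort probability.
#' @param dropoffMode `"per_codon"` or `"per_transit"`.
#' @param stallFold 5'-side density fold-change at a stall (>= 1).
#' @param stallPolicy `"uniform"` or `"fixed"`.
#' @param stallCodon Stall codon for the fixed policy.
#' @param noise `"none"` or `"poisson"`.
#' @param seed Integer RNG seed.
#' @return A [SimulationConfig].
#' @export
simulationConfig <- function(nTranscripts = 1000L,
                             lengthModel = c("lognormal", "fixed"),
                             fixedLengths = integer(0),
                             medianLength = 500, sdlog = 0.3,
                             minLength = 30L, maxLength = 5000L,
                             baselineRibosomes = 50,
                             pDropoff = 1 / 40,
                             dropoffMode = c("per_codon", "per_transit"),
                             stallFold = 10,
                             stallPolicy = c("uniform", "fixed"),
                             stallCodon = NA_integer_,
                             noise = c("none", "poisson"),
                             seed = 1L) {
  lengthModel <- match.arg(lengthModel)
  if (lengthModel == "fixed" && length(fixedLengths))
    nTranscripts <- length(fixedLengths)
  new("SimulationConfig",
      nTranscripts = as.integer(nTranscripts),
      lengthModel = lengthModel,
      fixedLengths = as.integer(fixedLengths),
      medianLength = medianLength, sdlog = sdlog,
      minLength = as.integer(minLength), maxLength = as.integer(maxLength),
      baselineRibosomes = baselineRibosomes, pDropoff = pDropoff,
      dropoffMode = match.arg(dropoffMode), stallFold = stallFold,
      stallPolicy = match.arg(stallPolicy),
      stallCodon = as.integer(stallCodon),
      noise = match.arg(noise), seed = as.integer(seed))
}

#' @rdname SimulationConfig-class
#' @param object A `SimulationConfig`.
#' @export
setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig:", object@nTranscripts, "transcript(s),",
      object@lengthModel, "lengths, baseline",
      object@baselineRibosomes, "per codon, p(dropoff)",
      object@pDropoff, paste0("(", object@dropoffMode, "),"),
      "stall fold", object@stallFold, ", noise", object@noise,
      ", seed", object@seed, "\n")
  invisible(NULL)
})

.drawLengths <- function(config) {
  if (config@lengthModel == "fixed") return(config@fixedLengths)
  n <- round(stats::rlnorm(config@nTranscripts,
                           meanlog = log(config@medianLength),
                           sdlog = config@sdlog))
  as.integer(pmin(pmax(n, config@minLength), config@maxLength))
}

#' Build a pool of mRNAs with uniform ribosome density
#'
#' Creates `nTranscripts` profiles with constant per-codon depth equal to
#' `baselineRibosomes` (plus Poisson noise if configured). All randomness
#' (lengths, noise) flows from the config seed, so identical configs give
#' identical pools.
#'
#' @param config A [SimulationConfig].
#' @param condition,replicate Labels for the generated profiles.
#' @return A [CodonProfileSet].
#' @export
buildUniformPool <- function(config, condition = "sim", replicate = "1") {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  .withSeed(config@seed, {
    lens <- .drawLengths(config)
    ids <- sprintf("tx%05d", seq_along(lens))
    counts <- lapply(lens, function(n) {
      v <- rep(config@baselineRibosomes, n)
      if (config@noise == "poisson") v <- stats::rpois(n, v)
      as.numeric(v)
    })
    CodonProfileSet(counts, ids, condition = condition,
                    replicate = replicate)
  })
}

# Survival-curve multiplier of per-codon drop-off with hazard vector q
# (q[j] = abort probability after elongation step j): occupancy at codon i
# is prod_{j<i}(1 - q_j).
.dropoffSurvival <- function(q) {
  cumprod(c(1, 1 - q[-length(q)]))
}

#' Apply ribosome drop-off to a pool
#'
#' Models spontaneous abortion of translation. In `per_codon` mode each
#' initiating ribosome advances codon by codon and aborts after each
#' elongation step with probability `p`, so expected occupancy decays
#' geometrically: `baseline * (1 - p)^(i - 1)`. In `per_transit` mode a
#' fraction `p` of ribosomes abort once, at a uniformly random codon, and
#' the rest complete, giving the linear expectation
#' `baseline * (1 - p * (i - 1) / n)`. With `deterministic = TRUE` the
#' expectation replaces sampling (profiles are multiplied by the exact
#' survival curve); otherwise individual ribosomes are simulated and
#' occupancy counts accumulated.
#'
#' @param pool A [CodonProfileSet] (typically from [buildUniformPool()]).
#' @param p Abort probability in \[0, 1\].
#' @param mode `"per_codon"` or `"per_transit"`.
#' @param deterministic Replace sampling with the expectation.
#' @param nRibosomes Initiating ribosomes per transcript for stochastic
#'   sampling (default: the profile's first-codon depth, rounded).
#' @param seed Optional seed for the stochastic modes.
#' @return A `CodonProfileSet` with drop-off applied.
#' @examples
#' pool <- CodonProfileSet(list(rep(8, 3)), "tx1")
#' profileCounts(applyDropoff(pool, 0.5, deterministic = TRUE))
#' @export
applyDropoff <- function(pool, p, mode = c("per_codon", "per_transit"),
                         deterministic = FALSE, nRibosomes = NULL,
                         seed = NULL) {
  mode <- match.arg(mode)
  if (p < 0 || p > 1) stop("p must lie in [0, 1]")
  d <- pool@data
  if (p == 0) return(pool)
  .withSeed(seed, {
    newCounts <- lapply(seq_len(nrow(d)), function(j) {
      v <- as.numeric(d$counts[[j]])
      n <- length(v)
      if (deterministic) {
        if (mode == "per_codon") v * (1 - p)^(seq_len(n) - 1)
        else v * (1 - p * (seq_len(n) - 1) / n)
      } else {
        B <- if (is.null(nRibosomes)) max(1L, round(v[1L]))
        else as.integer(nRibosomes)
        if (B < 1L) stop("need at least one initiating ribosome")
        if (mode == "per_codon") {
          reached <- pmin(1L + stats::rgeom(B, p), n)
          occ <- rev(cumsum(rev(tabulate(reached, nbins = n))))
        } else {
          nAbort <- stats::rbinom(1L, B, p)
          occ <- rep(B - nAbort, n)
          if (nAbort > 0L) {
            at <- sample.int(n, nAbort, replace = TRUE)
            occ <- occ + rev(cumsum(rev(tabulate(at, nbins = n))))
          }
        }
        as.numeric(occ)
      }
    })
    d$counts <- IRanges::NumericList(newCounts)
    initialize(pool, data = d)
  })
}

#' Apply ribosome stalling to a pool
#'
#' Places one stall site per transcript and elevates density 5' of it by
#' `fold` relative to the 3' side. The default `"region"` model raises the
#' whole 5' region `[1, s]`; the `"window"` variant raises only the
#' `windowWidth` codons immediately 5' of the stall (a queued-ribosome
#' picture). Under the `"uniform"` policy the stall codon is drawn
#' uniformly from the central codons `[0.05 n, 0.95 n]`, keeping both
#' sides non-empty.
#'
#' @param pool A [CodonProfileSet].
#' @param fold Density fold-change (>= 1).
#' @param policy `"uniform"` or `"fixed"`.
#' @param stallCodon Stall codon for the fixed policy (single value or
#'   one per profile).
#' @param model `"region"` or `"window"`.
#' @param windowWidth Width of the elevated window (codons).
#' @param seed Optional seed for the uniform policy.
#' @return A `CodonProfileSet` with stalling applied.
#' @export
applyStall <- function(pool, fold, policy = c("uniform", "fixed"),
                       stallCodon = NULL, model = c("region", "window"),
                       windowWidth = 10L, seed = NULL) {
  policy <- match.arg(policy)
  model <- match.arg(model)
  if (fold < 1) stop("fold must be >= 1")
  d <- pool@data
  if (fold == 1) return(pool)
  if (policy == "fixed") {
    if (is.null(stallCodon)) stop("fixed policy requires stallCodon")
    stallCodon <- rep_len(as.integer(stallCodon), nrow(d))
  }
  .withSeed(seed, {
    newCounts <- lapply(seq_len(nrow(d)), function(j) {
      v <- as.numeric(d$counts[[j]])
      n <- length(v)
      s <- if (policy == "fixed") stallCodon[j] else {
        lo <- max(1L, ceiling(0.05 * n))
        hi <- max(lo, floor(0.95 * n))
        if (lo >= hi) lo else lo + sample.int(hi - lo + 1L, 1L) - 1L
      }
      if (s < 1L || s > n)
        stop("stall codon ", s, " outside ORF of length ", n)
      from <- if (model == "region") 1L else max(1L, s - windowWidth + 1L)
      v[from:s] <- v[from:s] * fold
      v
    })
    d$counts <- IRanges::NumericList(newCounts)
    initialize(pool, data = d)
  })
}

#' Configuration of the synthetic two-condition study
#'
#' Convenience constructor for [generateFixtures()] with the emulated
#' study's conditions: 200 mRNAs, log-normal ORF lengths with median 500
#' codons (bounded below at 60 so the early analysis window always fits),
#' baseline 30 footprints per codon, a baseline per-codon drop-off hazard
#' of 5e-4 (giving a genome mean RDI near 0.48 at 500-codon ORFs), and
#' Poisson count noise per replicate.
#'
#' @param seed Integer RNG seed.
#' @param nTranscripts,baselineRibosomes,pDropoff,medianLength,sdlog,minLength
#'   Overrides of the study defaults.
#' @param ... Further arguments to [simulationConfig()].
#' @return A [SimulationConfig].
#' @export
fixtureConfig <- function(seed = 1L, nTranscripts = 200L,
                          baselineRibosomes = 30, pDropoff = 5e-4,
                          medianLength = 500, sdlog = 0.3,
                          minLength = 60L, ...) {
  simulationConfig(nTranscripts = nTranscripts,
                   baselineRibosomes = baselineRibosomes,
                   pDropoff = pDropoff, medianLength = medianLength,
                   sdlog = sdlog, minLength = minLength,
                   noise = "poisson", seed = seed, ...)
}

#' Generate a synthetic two-condition, two-replicate study
#'
#' Emulates the structure of an mTORC1-inhibition ribosome-profiling
#' experiment: a "control" condition with the baseline per-codon drop-off
#' hazard everywhere, and a "treated" condition with an additional
#' drop-off hazard confined to an early window of codons (default 15-55)
#' -- `excessDropoff` on a designated target subset of transcripts and
#' `genomeExcess` on the remaining transcripts (the genome-wide component
#' of the effect; set it to 0 for a target-only construction). Two
#' replicates per condition receive independent Poisson noise around the
#' expected occupancy when the config requests Poisson noise. Everything
#' is deterministic given the config seed.
#'
#' @param config A [SimulationConfig] (see [fixtureConfig()]).
#' @param targetFraction Fraction of transcripts designated as targets.
#' @param earlyWindow Integer vector `c(first, last)` codon of the excess
#'   drop-off window; must fit within the shortest ORF.
#' @param excessDropoff Additional per-codon abort hazard inside the
#'   window on target transcripts (treated condition).
#' @param genomeExcess Additional in-window hazard on non-target
#'   transcripts (treated condition).
#' @param replicates Replicate labels (default `c("r1", "r2")`).
#' @return A list: `profiles` (a [CodonProfileSet] with conditions
#'   `control` and `treated`) and `truth` (a `DataFrame` with
#'   `transcript_id`, `is_target`, `n`).
#' @export
generateFixtures <- function(config, targetFraction = 0.1,
                             earlyWindow = c(15L, 55L),
                             excessDropoff = 0.02, genomeExcess = 0.009,
                             replicates = c("r1", "r2")) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  if (targetFraction < 0 || targetFraction > 1)
    stop("targetFraction must lie in [0, 1]")
  if (length(earlyWindow) != 2L || earlyWindow[1L] < 1L ||
      earlyWindow[2L] < earlyWindow[1L])
    stop("earlyWindow must be c(first, last) with 1 <= first <= last")
  if (excessDropoff < 0 || excessDropoff > 1 ||
      genomeExcess < 0 || genomeExcess > 1)
    stop("excess hazards must lie in [0, 1]")
  .withSeed(config@seed, {
    lens <- .drawLengths(config)
    if (min(lens) < earlyWindow[2L])
      stop("early window [", earlyWindow[1L], ", ", earlyWindow[2L],
           "] extends beyond the shortest ORF (", min(lens), " codons)")
    ids <- sprintf("tx%05d", seq_along(lens))
    nTargets <- round(targetFraction * length(ids))
    targets <- sort(sample(ids, nTargets))
    b <- config@baselineRibosomes
    p <- config@pDropoff

    rows <- vector("list", length(ids) * 2L * length(replicates))
    k <- 0L
    txCol <- condCol <- repCol <- character(length(rows))
    for (j in seq_along(ids)) {
      n <- lens[j]
      inWin <- seq_len(n) >= earlyWindow[1L] & seq_len(n) <= earlyWindow[2L]
      qCtrl <- rep(p, n)
      extra <- if (ids[j] %in% targets) excessDropoff else genomeExcess
      qTrt <- qCtrl + extra * inWin
      expCtrl <- b * .dropoffSurvival(qCtrl)
      expTrt <- b * .dropoffSurvival(qTrt)
      for (cond in c("control", "treated")) {
        e <- if (cond == "control") expCtrl else expTrt
        for (rep in replicates) {
          k <- k + 1L
          rows[[k]] <- if (config@noise == "poisson")
            as.numeric(stats::rpois(n, e)) else e
          txCol[k] <- ids[j]; condCol[k] <- cond; repCol[k] <- rep
        }
      }
    }
    d <- S4Vectors::DataFrame(transcript_id = txCol, condition = condCol,
                              replicate = repCol,
                              counts = IRanges::NumericList(rows))
    ord <- order(match(condCol, c("control", "treated")))
    set <- new("CodonProfileSet", data = d[ord, , drop = FALSE],
               removalLog = .emptyRemovalLog())
    truth <- S4Vectors::DataFrame(transcript_id = ids,
                                  is_target = ids %in% targets,
                                  n = lens)
    list(profiles = set, truth = truth)
  })
}
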