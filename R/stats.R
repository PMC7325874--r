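#' Mann-Whitney U test
#'
#' Two-sample rank test. The statistic is the classic
#' \eqn{U_1 = \#\{(i,j): a_i > b_j\}} counting ties as 1/2 (computed via
#' midranks). The exact method evaluates the permutation distribution of
#' U -- through the exact Wilcoxon distribution when there are no ties,
#' by full enumeration of labelings otherwise -- and is selected
#' automatically when `n1 + n2 <= 12` with no ties. The normal method
#' uses the tie-corrected normal approximation with continuity
#' correction. Two-sided p-values are `2 * min(P(U <= u), P(U >= u))`
#' capped at 1.
#'
#' @param a,b Non-empty numeric samples.
#' @param method `"auto"`, `"exact"` or `"normal"`.
#' @return A list: `U` (for sample `a`), `p` (two-sided), `n1`, `n2`,
#'   `method` (the method actually used).
#' @examples
#' mannWhitneyU(c(1, 2, 3), c(4, 5, 6))$p   # 0.1
#' @export
mannWhitneyU <- function(a, b, method = c("auto", "exact", "normal")) {
  method <- match.arg(method)
  if (!length(a) || !length(b)) stop("both samples must be non-empty")
  if (anyNA(a) || anyNA(b)) stop("samples must not contain NA")
  n1 <- length(a); n2 <- length(b); N <- n1 + n2
  r <- rank(c(a, b))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(c(a, b)) > 0L
  if (method == "auto")
    method <- if (N <= 12L && !ties) "exact" else "normal"

  if (method == "exact") {
    if (!ties) {
      pl <- stats::pwilcox(u, n1, n2)
      pg <- 1 - stats::pwilcox(u - 1, n1, n2)
      p <- min(1, 2 * min(pl, pg))
    } else {
      # enumeration of all C(N, n1) labelings on the midranks
      combs <- utils::combn(N, n1)
      us <- colSums(matrix(r[combs], nrow = n1)) - n1 * (n1 + 1) / 2
      eps <- 1e-9
      pl <- mean(us <= u + eps)
      pg <- mean(us >= u - eps)
      p <- min(1, 2 * min(pl, pg))
    }
  } else {
    mu <- n1 * n2 / 2
    nt <- table(r)
    sigma2 <- (n1 * n2 / 12) *
      ((N + 1) - sum(nt^3 - nt) / (N * (N - 1)))
    z <- u - mu
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- z - sign(z) * 0.5          # continuity correction
      p <- min(1, 2 * stats::pnorm(-abs(z) / sqrt(sigma2)))
    }
  }
  list(U = u, p = p, n1 = n1, n2 = n2, method = method)
}

#' Monte-Carlo subsampling empirical p-value for a target gene set
#'
#' Tests whether a target set's mean RDI difference (control minus
#' treated) is larger than expected for a random set of the same size.
#' The null is built by drawing `N` uniformly random subsets of
#' `|targets|` transcripts (without replacement within a draw) from all
#' records and recording each subset's mean difference; the one-sided
#' p-value is `(k + 1) / (N + 1)` with `k` the number of null statistics
#' `>=` the observed one, so a larger control-minus-treated drop is "more
#' extreme" and the estimate is never zero.
#'
#' @param delta Named numeric vector of per-transcript RDI differences
#'   (see [deltaRdi()]).
#' @param targetIds Character vector of target transcript identifiers;
#'   must be a subset of `names(delta)` of size >= 2.
#' @param N Number of subsamples (default 10000).
#' @param seed Optional integer seed.
#' @return An [EmpiricalTest].
#' @export
empiricalPvalue <- function(delta, targetIds, N = 10000L, seed = NULL) {
  if (N < 1L) stop("N must be >= 1")
  if (is.null(names(delta))) stop("'delta' must be named by transcript")
  targetIds <- unique(targetIds)
  miss <- setdiff(targetIds, names(delta))
  if (length(miss))
    stop("target id(s) absent from records: ",
         paste(utils::head(miss, 5L), collapse = ", "))
  m <- length(targetIds)
  if (m < 2L) stop("need at least 2 target transcripts")
  M <- length(delta)
  if (m > M) stop("target set larger than the record set")
  observed <- mean(delta[targetIds])
  null <- .withSeed(seed, {
    idx <- matrix(0L, nrow = m, ncol = N)
    for (j in seq_len(N)) idx[, j] <- sample.int(M, m)
    colMeans(matrix(delta[idx], nrow = m))
  })
  k <- sum(null >= observed)
  new("EmpiricalTest", observed = observed, N = as.integer(N),
      k = as.integer(k), p = (k + 1) / (N + 1),
      nTargets = as.integer(m),
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}

#' @rdname EmpiricalTest-class
#' @param object An `EmpiricalTest`.
#' @export
setMethod("show", "EmpiricalTest", function(object) {
  cat(sprintf(paste0("EmpiricalTest: observed mean ΔRDI = %.4g over %d",
                     " targets; %d of %d null subsamples >= observed;",
                     " one-sided p = %.4g\n"),
              object@observed, object@nTargets, object@k, object@N,
              object@p))
  invisible(NULL)
})

#' Percentile bootstrap confidence interval of the mean
#'
#' Resamples the data with replacement `B` times and returns the
#' percentile interval of the bootstrap means at the requested level.
#' Deterministic given `seed`.
#'
#' @param x Non-empty numeric sample.
#' @param level Confidence level (default 0.99).
#' @param B Number of bootstrap resamples (default 1000, minimum 100).
#' @param seed Optional integer seed.
#' @return Numeric `c(low, high)`.
#' @export
bootstrapCiMean <- function(x, level = 0.99, B = 1000L, seed = NULL) {
  if (!length(x)) stop("empty sample")
  if (B < 100L) stop("B must be >= 100")
  if (level <= 0 || level >= 1) stop("level must lie in (0, 1)")
  n <- length(x)
  means <- .withSeed(seed, {
    colMeans(matrix(x[sample.int(n, n * B, replace = TRUE)], nrow = n))
  })
  alpha <- (1 - level) / 2
  unname(stats::quantile(means, c(alpha, 1 - alpha)))
}

# Shared metagene assembly: given per-condition matrices of
# per-transcript values (transcripts x axis positions, NA allowed),
# compute means and bootstrap CIs.
.metageneFromSamples <- function(samples, axis, axisType, normalization,
                                 level, B, seed) {
  rows <- list()
  .withSeed(seed, {
    for (cond in names(samples)) {
      M <- samples[[cond]]
      for (j in seq_along(axis)) {
        v <- M[, j]
        v <- v[!is.na(v)]
        if (!length(v)) {
          rows[[length(rows) + 1L]] <- S4Vectors::DataFrame(
            condition = cond, axis = axis[j], mean = NA_real_,
            ciLow = NA_real_, ciHigh = NA_real_, n = 0L)
          next
        }
        ci <- bootstrapCiMean(v, level = level, B = B)
        rows[[length(rows) + 1L]] <- S4Vectors::DataFrame(
          condition = cond, axis = axis[j], mean = mean(v),
          ciLow = min(ci[1L], mean(v)), ciHigh = max(ci[2L], mean(v)),
          n = length(v))
      }
    }
  })
  new("MetageneCurve", axisType = axisType, axis = axis,
      stats = do.call(rbind, rows), samples = samples,
      normalization = normalization, level = level)
}

#' Length-normalized metagene curve
#'
#' Maps every codon `i` of an `n`-codon transcript to the fractional
#' position `(i - 0.5) / n`, assigns it to one of `nBins` equal-width
#' bins (half-open `[k/B, (k+1)/B)`, last bin closed), and averages
#' per-transcript normalized densities within bins. Each transcript is
#' first divided by its own mean density (default) or by its maximum
#' density; replicates are averaged per condition before normalization.
#' Per-bin means across transcripts carry percentile-bootstrap confidence
#' intervals.
#'
#' @param set A [CodonProfileSet].
#' @param nBins Number of ORF-fraction bins (default 100).
#' @param normalization `"mean"` or `"max"` per-transcript normalizer.
#' @param level CI level (default 0.99).
#' @param B Bootstrap resamples per bin (default 1000).
#' @param seed Optional integer seed for the bootstrap.
#' @return A [MetageneCurve] with one set of curves per condition.
#' @export
metageneLengthNorm <- function(set, nBins = 100L,
                               normalization = c("mean", "max"),
                               level = 0.99, B = 1000L, seed = NULL) {
  normalization <- match.arg(normalization)
  if (nBins < 2L) stop("nBins must be >= 2")
  prof <- .conditionMeanProfiles(set)
  samples <- lapply(prof, function(byTx) {
    M <- matrix(NA_real_, nrow = length(byTx), ncol = nBins,
                dimnames = list(names(byTx), NULL))
    for (tx in names(byTx)) {
      v <- .normalizeVec(byTx[[tx]], normalization, tx)
      n <- length(v)
      bin <- pmin(floor((seq_len(n) - 0.5) / n * nBins) + 1L, nBins)
      agg <- tapply(v, bin, mean)
      M[tx, as.integer(names(agg))] <- agg
    }
    M
  })
  axis <- (seq_len(nBins) - 0.5) / nBins
  .metageneFromSamples(samples, axis, "fraction", normalization,
                       level, B, seed)
}

#' Per-codon metagene curve over an absolute window
#'
#' Averages normalized densities codon by codon over a window of absolute
#' codon indices (default codons 5 to 105; the first codons are excluded
#' because read mapping at the start codon is unreliable). Only
#' transcripts at least `stop` codons long contribute; the per-transcript
#' normalizer (mean or max) is computed over the full transcript before
#' windowing.
#'
#' @param set A [CodonProfileSet].
#' @param start,stop First and last codon of the window.
#' @inheritParams metageneLengthNorm
#' @return A [MetageneCurve].
#' @export
metagenePerCodon <- function(set, start = 5L, stop = 105L,
                             normalization = c("mean", "max"),
                             level = 0.99, B = 1000L, seed = NULL) {
  normalization <- match.arg(normalization)
  if (start < 1L || stop <= start)
    stop("need 1 <= start < stop")
  prof <- .conditionMeanProfiles(set)
  axis <- as.numeric(seq.int(start, stop))
  samples <- lapply(prof, function(byTx) {
    keep <- names(byTx)[vapply(byTx, length, 1L) >= stop]
    if (!length(keep))
      stop("no transcript of at least ", stop, " codons")
    M <- matrix(NA_real_, nrow = length(keep), ncol = length(axis),
                dimnames = list(keep, NULL))
    for (tx in keep) {
      v <- .normalizeVec(byTx[[tx]], normalization, tx)
      M[tx, ] <- v[start:stop]
    }
    M
  })
  .metageneFromSamples(samples, axis, "codon", normalization,
                       level, B, seed)
}

#' @rdname MetageneCurve-class
#' @export
setMethod("show", "MetageneCurve", function(object) {
  cat("MetageneCurve (", object@axisType, " axis, ",
      length(object@axis), " position(s), ", object@normalization,
      "-normalized, ", object@level * 100, "% CIs) over condition(s): ",
      paste(names(object@samples), collapse = ", "), "\n", sep = "")
  invisible(NULL)
})

.curveSamples <- function(curve, condition) {
  if (is.null(condition)) {
    if (length(curve@samples) != 1L)
      stop("curve holds several conditions; name one")
    curve@samples[[1L]]
  } else {
    if (!condition %in% names(curve@samples))
      stop("condition '", condition, "' not present in curve")
    curve@samples[[condition]]
  }
}

#' Region-by-region Mann-Whitney tests between two conditions
#'
#' At every axis position (length-fraction bin or codon) of a metagene
#' curve, compares the two conditions' per-transcript normalized
#' densities with [mannWhitneyU()]. Each region is treated independently;
#' no multiple-testing correction is applied unless `adjust = TRUE`
#' (Benjamini-Hochberg).
#'
#' @param x A [MetageneCurve] holding both conditions, or the first of
#'   two curves built on identical axes.
#' @param y Optional second `MetageneCurve` (same axis as `x`).
#' @param conditionA,conditionB Condition names (defaulting to the two
#'   conditions of `x` when `y` is absent, or to the sole condition of
#'   each curve).
#' @param adjust Add a BH-adjusted `padj` column.
#' @param method Passed to [mannWhitneyU()].
#' @return A `DataFrame`: `region`, `U`, `p`, `n1`, `n2` (and `padj`).
#' @export
perRegionTests <- function(x, y = NULL, conditionA = NULL,
                           conditionB = NULL, adjust = FALSE,
                           method = "auto") {
  stopifnot(is(x, "MetageneCurve"))
  if (is.null(y)) {
    if (is.null(conditionA) || is.null(conditionB)) {
      if (length(x@samples) != 2L)
        stop("curve must hold exactly two conditions, or name them")
      conditionA <- names(x@samples)[1L]
      conditionB <- names(x@samples)[2L]
    }
    A <- .curveSamples(x, conditionA)
    Bm <- .curveSamples(x, conditionB)
    axis <- x@axis
  } else {
    stopifnot(is(y, "MetageneCurve"))
    if (!identical(x@axis, y@axis))
      stop("axis mismatch between the two curves")
    A <- .curveSamples(x, conditionA)
    Bm <- .curveSamples(y, conditionB)
    axis <- x@axis
  }
  rows <- lapply(seq_along(axis), function(j) {
    a <- A[, j]; a <- a[!is.na(a)]
    b <- Bm[, j]; b <- b[!is.na(b)]
    if (!length(a) || !length(b))
      return(S4Vectors::DataFrame(region = axis[j], U = NA_real_,
                                  p = NA_real_, n1 = length(a),
                                  n2 = length(b)))
    mw <- mannWhitneyU(a, b, method = method)
    S4Vectors::DataFrame(region = axis[j], U = mw$U, p = mw$p,
                         n1 = mw$n1, n2 = mw$n2)
  })
  out <- do.call(rbind, rows)
  if (adjust) out$padj <- stats::p.adjust(out$p, method = "BH")
  out
}
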