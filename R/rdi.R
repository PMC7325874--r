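#' @rdname computeRdi
#' @export
setMethod("computeRdi", "numeric", function(x, ...) {
  if (length(x) < 1L) stop("empty profile")
  if (any(x < 0)) stop("negative density")
  s <- sum(x)
  if (s <= 0) stop("RDI undefined for zero-density profile")
  sum(seq_along(x) * x) / (length(x) * s)
})

#' @rdname computeRdi
#' @export
setMethod("computeRdi", "CodonProfileSet", function(x, ...) {
  vals <- .profileValues(x)
  vapply(names(vals), function(k) {
    v <- vals[[k]]
    if (sum(v) <= 0)
      stop("RDI undefined for zero-density profile '", k, "'")
    sum(seq_along(v) * v) / (length(v) * sum(v))
  }, numeric(1))
})

#' Per-transcript RDI table across conditions and replicates
#'
#' Computes one RDI per profile and assembles a wide per-transcript table.
#' Per-condition RDI is the mean of per-replicate RDIs by default;
#' `replicateHandling = "pool"` instead sums replicate profiles before
#' computing a single per-condition RDI. When the set has exactly two
#' conditions, a `delta` column holds the first-condition mean minus the
#' second (conditions in declared order, e.g. control - treated).
#'
#' @param set A [CodonProfileSet].
#' @param replicateHandling `"average"` (default) or `"pool"`.
#' @return A [S4Vectors::DataFrame] with columns `transcript_id`, `n`,
#'   `rdi_<condition>_<replicate>` (averaging mode only),
#'   `mean_<condition>`, and `delta` for two-condition sets.
#' @export
computeRdiSet <- function(set, replicateHandling = c("average", "pool")) {
  replicateHandling <- match.arg(replicateHandling)
  d <- set@data
  if (nrow(d) == 0L) stop("empty profile set")
  vals <- .profileValues(set)
  conds <- conditionNames(set)
  txs <- transcriptIds(set)
  n <- nCodons(set)[txs]
  out <- S4Vectors::DataFrame(transcript_id = txs, n = unname(n))

  if (replicateHandling == "average") {
    rdi <- vapply(seq_along(vals), function(j) {
      v <- vals[[j]]
      if (sum(v) <= 0)
        stop("RDI undefined for zero-density profile of transcript '",
             d$transcript_id[j], "'")
      sum(seq_along(v) * v) / (length(v) * sum(v))
    }, numeric(1))
    for (cond in conds) {
      for (rep in unique(d$replicate[d$condition == cond])) {
        sel <- d$condition == cond & d$replicate == rep
        col <- stats::setNames(rdi[sel], d$transcript_id[sel])
        out[[paste("rdi", cond, rep, sep = "_")]] <- unname(col[txs])
      }
      sel <- d$condition == cond
      cm <- tapply(rdi[sel], d$transcript_id[sel], mean)
      out[[paste0("mean_", cond)]] <- unname(cm[txs])
    }
  } else {
    for (cond in conds) {
      cm <- vapply(txs, function(tx) {
        idx <- which(d$transcript_id == tx & d$condition == cond)
        if (!length(idx)) return(NA_real_)
        v <- vals[[idx[1L]]]
        if (length(idx) > 1L) for (j in idx[-1L]) v <- v + vals[[j]]
        if (sum(v) <= 0)
          stop("RDI undefined for zero-density profile of transcript '",
               tx, "'")
        sum(seq_along(v) * v) / (length(v) * sum(v))
      }, numeric(1))
      out[[paste0("mean_", cond)]] <- unname(cm)
    }
  }
  if (length(conds) == 2L)
    out$delta <- out[[paste0("mean_", conds[1L])]] -
      out[[paste0("mean_", conds[2L])]]
  out
}

#' Closed-form RDI of a geometric density profile
#'
#' Analytic RDI of the profile \eqn{d_i = r^{i-1}} (the expected occupancy
#' under per-codon ribosome drop-off with survival probability `r` per
#' elongation step), from the exact finite geometric sums:
#' \deqn{RDI(n, r) = \frac{1 - (n+1) r^n + n r^{n+1}}{n (1 - r)(1 - r^n)}}
#' with the uniform limit \eqn{(n+1)/(2n)} at \eqn{r = 1}. Serves as the
#' independent oracle for [applyDropoff()].
#'
#' @param n ORF length in codons (positive integer, vectorized).
#' @param r Per-step survival probability in (0, 1].
#' @return RDI value(s).
#' @examples
#' rdiGeometricClosedForm(10, 1)     # 0.55
#' rdiGeometricClosedForm(4, 0.5)    # 3.25 / 7.5
#' @export
rdiGeometricClosedForm <- function(n, r) {
  if (any(n < 1)) stop("n must be >= 1")
  if (any(r <= 0 | r > 1)) stop("r must lie in (0, 1]")
  k <- max(length(n), length(r))
  n <- rep_len(n, k)
  r <- rep_len(r, k)
  vapply(seq_len(k), function(j) {
    if (abs(1 - r[j]) < 1e-12) return((n[j] + 1) / (2 * n[j]))
    # the analytic ratio cancels catastrophically when n (1 - r) is
    # small; fall back to the explicit finite sums there
    if (n[j] * (1 - r[j]) < 1) {
      d <- r[j]^(seq_len(n[j]) - 1)
      return(sum(seq_len(n[j]) * d) / (n[j] * sum(d)))
    }
    rn <- r[j]^n[j]
    (1 - (n[j] + 1) * rn + n[j] * r[j] * rn) /
      (n[j] * (1 - r[j]) * (1 - rn))
  }, numeric(1))
}

#' Bin transcripts by a covariate and summarize RDI per bin
#'
#' Sorts transcripts by a covariate (e.g. CAI, or log ORF length), splits
#' them into `nBins` equal-count rank bins (sizes differing by at most
#' one, remainder assigned to the lowest bins; ties broken by transcript
#' identifier), and summarizes RDI within each bin. Also reports the
#' Spearman rank correlation between covariate and RDI across all
#' transcripts.
#'
#' @param rdi Named numeric vector of per-transcript RDI values.
#' @param covariate Named numeric vector covering every transcript in
#'   `rdi`.
#' @param nBins Number of rank bins (default 10 deciles).
#' @return A list with `bins` (a `DataFrame`: bin, n, covariate range,
#'   RDI median and quartiles), `assignment` (named bin index per
#'   transcript), `rho` and `rhoP` (Spearman correlation and p-value).
#' @export
binRdiByCovariate <- function(rdi, covariate, nBins = 10L) {
  if (nBins < 2L) stop("nBins must be >= 2")
  if (is.null(names(rdi)) || is.null(names(covariate)))
    stop("'rdi' and 'covariate' must be named by transcript")
  miss <- setdiff(names(rdi), names(covariate))
  if (length(miss))
    stop("missing covariate for transcript(s): ",
         paste(miss, collapse = ", "))
  m <- length(rdi)
  if (m < nBins) stop("fewer transcripts than bins")
  cov <- covariate[names(rdi)]
  if (length(unique(cov)) == 1L)
    stop("covariate is identical for all transcripts; ",
         "rank binning and Spearman correlation are degenerate")
  ord <- order(cov, names(rdi))
  base <- m %/% nBins
  rem <- m %% nBins
  sizes <- rep(base, nBins) + c(rep(1L, rem), rep(0L, nBins - rem))
  bin <- rep(seq_len(nBins), times = sizes)
  assignment <- stats::setNames(integer(m), names(rdi))
  assignment[ord] <- bin
  rows <- lapply(seq_len(nBins), function(b) {
    ids <- names(assignment)[assignment == b]
    q <- stats::quantile(rdi[ids], c(0.25, 0.5, 0.75), names = FALSE)
    S4Vectors::DataFrame(bin = b, n = length(ids),
                         cov_min = min(cov[ids]), cov_max = max(cov[ids]),
                         rdi_q1 = q[1], rdi_median = q[2], rdi_q3 = q[3])
  })
  ct <- suppressWarnings(
    stats::cor.test(cov, rdi, method = "spearman", exact = FALSE))
  list(bins = do.call(rbind, rows), assignment = assignment,
       rho = unname(ct$estimate), rhoP = ct$p.value)
}

#' Paired per-transcript RDI comparison between two conditions
#'
#' Counts how many transcripts have higher condition-mean RDI in `A` than
#' in `B` (the "above the diagonal" count of a paired scatter), how many
#' the reverse, and how many are equal (|difference| < `tol`), and tests
#' the two RDI value sets with a Mann-Whitney U-test, as in a genome-wide
#' two-condition comparison. Transcripts missing either condition are
#' excluded with a warning.
#'
#' @param rdiTable Output of [computeRdiSet()].
#' @param conditionA,conditionB Condition labels (must match
#'   `mean_<condition>` columns of `rdiTable`).
#' @param tol Equality tolerance on the RDI difference (default 1e-12).
#' @return A list: `nHigherA`, `nHigherB`, `nEqual`, `U`, `p`, `nUsed`,
#'   `nExcluded`.
#' @export
pairedRdiComparison <- function(rdiTable, conditionA, conditionB,
                                tol = 1e-12) {
  ca <- paste0("mean_", conditionA)
  cb <- paste0("mean_", conditionB)
  if (!all(c(ca, cb) %in% colnames(rdiTable)))
    stop("rdiTable lacks condition mean column(s) for '", conditionA,
         "' / '", conditionB, "'")
  a <- rdiTable[[ca]]
  b <- rdiTable[[cb]]
  ok <- !is.na(a) & !is.na(b)
  if (any(!ok))
    warning(sum(!ok), " transcript(s) missing one condition; excluded")
  a <- a[ok]; b <- b[ok]
  if (!length(a)) stop("no transcript with both conditions")
  d <- a - b
  mw <- mannWhitneyU(a, b, method = "auto")
  list(nHigherA = sum(d > tol), nHigherB = sum(d < -tol),
       nEqual = sum(abs(d) <= tol), U = mw$U, p = mw$p,
       nUsed = length(a), nExcluded = sum(!ok))
}

#' Condition-difference RDI vector
#'
#' Convenience extractor: per-transcript RDI difference
#' `conditionA - conditionB` (e.g. control minus treated) as a named
#' vector, the input of [empiricalPvalue()].
#'
#' @inheritParams pairedRdiComparison
#' @param dropNA Drop transcripts missing either condition (default TRUE).
#' @return Named numeric vector of RDI differences.
#' @export
deltaRdi <- function(rdiTable, conditionA, conditionB, dropNA = TRUE) {
  ca <- paste0("mean_", conditionA)
  cb <- paste0("mean_", conditionB)
  if (!all(c(ca, cb) %in% colnames(rdiTable)))
    stop("rdiTable lacks condition mean column(s)")
  d <- stats::setNames(rdiTable[[ca]] - rdiTable[[cb]],
                       rdiTable$transcript_id)
  if (dropNA) d <- d[!is.na(d)]
  d
}
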