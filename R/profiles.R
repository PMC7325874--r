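#' Construct a CodonProfileSet
#'
#' Builds a [CodonProfileSet] from plain R objects. `counts` supplies one
#' per-codon depth vector per profile; `transcriptId`, `condition` and
#' `replicate` are recycled to the number of profiles. Input depth is
#' expected to cover the CDS without the stop codon, so `n` (codons per
#' transcript) excludes the stop.
#'
#' @param counts A list of non-negative numeric vectors (or a single
#'   vector for one profile), one element per profile.
#' @param transcriptId Character vector of transcript identifiers.
#' @param condition,replicate Character labels, recycled.
#' @return A `CodonProfileSet`.
#' @examples
#' ps <- CodonProfileSet(list(c(2, 3, 1), c(4, 0, 1)),
#'                       transcriptId = c("txA", "txB"))
#' nCodons(ps)
#' @export
CodonProfileSet <- function(counts, transcriptId,
                            condition = "control", replicate = "1") {
  if (is.numeric(counts)) counts <- list(counts)
  m <- length(counts)
  d <- S4Vectors::DataFrame(
    transcript_id = rep_len(as.character(transcriptId), m),
    condition = rep_len(as.character(condition), m),
    replicate = rep_len(as.character(replicate), m),
    counts = IRanges::NumericList(lapply(counts, as.numeric)))
  new("CodonProfileSet", data = d, removalLog = .emptyRemovalLog())
}

#' @rdname CodonProfileSet-class
#' @export
setMethod("transcriptIds", "CodonProfileSet",
          function(x) unique(x@data$transcript_id))

#' @rdname CodonProfileSet-class
#' @export
setMethod("conditionNames", "CodonProfileSet",
          function(x) unique(x@data$condition))

#' @rdname CodonProfileSet-class
#' @export
setMethod("replicateNames", "CodonProfileSet",
          function(x) unique(x@data$replicate))

#' @rdname CodonProfileSet-class
#' @export
setMethod("nCodons", "CodonProfileSet", function(x) {
  d <- x@data
  n <- lengths(d$counts)
  first <- !duplicated(d$transcript_id)
  stats::setNames(as.integer(n[first]), d$transcript_id[first])
})

#' @rdname CodonProfileSet-class
#' @export
setMethod("profileCounts", "CodonProfileSet", function(x) {
  out <- as.list(x@data$counts)
  names(out) <- paste(x@data$transcript_id, x@data$condition,
                      x@data$replicate, sep = "|")
  out
})

#' @rdname CodonProfileSet-class
#' @export
setMethod("profileDensities", "CodonProfileSet", function(x) {
  if (!isNormalized(x))
    stop("profile set has not been normalized; call normalizeProfiles()")
  out <- as.list(x@data$densities)
  names(out) <- paste(x@data$transcript_id, x@data$condition,
                      x@data$replicate, sep = "|")
  out
})

#' @rdname CodonProfileSet-class
#' @export
setMethod("isNormalized", "CodonProfileSet",
          function(x) "densities" %in% colnames(x@data))

#' @rdname CodonProfileSet-class
#' @export
setMethod("removalLog", "CodonProfileSet", function(x) x@removalLog)

#' @rdname CodonProfileSet-class
#' @export
setMethod("length", "CodonProfileSet", function(x) nrow(x@data))

#' @rdname CodonProfileSet-class
#' @param i Row (profile) index: numeric, logical or character-free.
#' @export
setMethod("[", "CodonProfileSet", function(x, i) {
  initialize(x, data = x@data[i, , drop = FALSE],
             removalLog = .emptyRemovalLog())
})

#' @rdname CodonProfileSet-class
#' @export
setMethod("show", "CodonProfileSet", function(object) {
  d <- object@data
  cat("CodonProfileSet with", nrow(d), "profile(s):",
      length(unique(d$transcript_id)), "transcript(s),",
      "conditions {", paste(unique(d$condition), collapse = ", "), "},",
      "replicates {", paste(unique(d$replicate), collapse = ", "), "}\n")
  if (isNormalized(object)) cat("  normalized (RPF / TPM densities)\n")
  if (nrow(object@removalLog))
    cat("  removal log:", nrow(object@removalLog), "transcript(s)\n")
  invisible(NULL)
})

#' Keep a subset of transcripts
#'
#' @param set A [CodonProfileSet].
#' @param ids Transcript identifiers to retain.
#' @return A `CodonProfileSet` restricted to `ids`.
#' @export
keepTranscripts <- function(set, ids) {
  set[set@data$transcript_id %in% ids]
}

#' Sum per-nucleotide depth into per-codon counts
#'
#' Collapses a per-nucleotide RPF depth vector over a CDS into per-codon
#' counts by summing consecutive nucleotide triplets, optionally after
#' skipping `offset` nucleotides (a P-site offset; published practice
#' varies and the default applies none). A trailing partial codon is
#' dropped with a warning, never padded.
#'
#' @param ntDepth Non-empty numeric vector of non-negative per-nucleotide
#'   depths, covering the CDS without the stop codon.
#' @param offset Number of leading nucleotides to skip (default 0).
#' @param transcript Transcript name used in error messages.
#' @return Numeric vector of `floor((length - offset) / 3)` codon counts.
#' @examples
#' sumDepthToCodons(c(1, 1, 1, 2, 2, 2))   # c(3, 6)
#' @export
sumDepthToCodons <- function(ntDepth, offset = 0L, transcript = "<unnamed>") {
  if (length(ntDepth) == 0L)
    stop("empty nucleotide depth for transcript '", transcript, "'")
  if (any(ntDepth < 0))
    stop("negative depth for transcript '", transcript, "'")
  if (offset < 0L || offset >= length(ntDepth))
    stop("invalid offset for transcript '", transcript, "'")
  usable <- length(ntDepth) - offset
  if (usable < 3L)
    stop("offset leaves fewer than one codon for transcript '",
         transcript, "'")
  nc <- usable %/% 3L
  rest <- usable %% 3L
  if (rest > 0L)
    warning("dropping ", rest, " trailing nucleotide(s) of transcript '",
            transcript, "' (partial codon)")
  x <- ntDepth[(offset + 1L):(offset + 3L * nc)]
  as.numeric(colSums(matrix(x, nrow = 3L)))
}

#' Transcripts-per-million normalization
#'
#' Standard TPM: per-transcript read rate per kilobase, rescaled so the
#' library sums to one million.
#'
#' @param readCounts Named non-negative numeric vector of total-mRNA read
#'   counts per transcript.
#' @param lengthsNt Named positive numeric vector of transcript lengths in
#'   nucleotides; must cover every transcript in `readCounts`.
#' @return Named numeric vector of TPM values summing to 1e6.
#' @examples
#' computeTPM(c(A = 10, B = 10), c(A = 1000, B = 2000))
#' @export
computeTPM <- function(readCounts, lengthsNt) {
  miss <- setdiff(names(readCounts), names(lengthsNt))
  if (length(miss))
    stop("no length for transcript(s): ", paste(miss, collapse = ", "))
  if (any(readCounts < 0)) stop("negative read counts")
  if (all(readCounts == 0))
    stop("all-zero read counts: no library to normalize")
  len <- lengthsNt[names(readCounts)]
  if (any(len <= 0)) stop("non-positive transcript length")
  rate <- readCounts / (len / 1000)
  rate / sum(rate) * 1e6
}

#' Normalize RPF counts by matched mRNA abundance
#'
#' Divides each per-codon RPF count vector by the transcript's total-mRNA
#' TPM, yielding ribosome densities comparable across transcripts.
#'
#' @param set A [CodonProfileSet].
#' @param tpm Named numeric vector of TPM values (one per transcript; all
#'   transcripts of `set` must be present with `tpm > 0`).
#' @return The set with `tpm` and `densities` columns added.
#' @export
normalizeProfiles <- function(set, tpm) {
  d <- set@data
  miss <- setdiff(unique(d$transcript_id), names(tpm))
  if (length(miss))
    stop("no TPM for transcript(s): ", paste(miss, collapse = ", "))
  t <- unname(tpm[d$transcript_id])
  bad <- unique(d$transcript_id[is.na(t) | t <= 0])
  if (length(bad))
    stop("non-positive TPM for transcript(s): ",
         paste(bad, collapse = ", "))
  d$tpm <- t
  d$densities <- d$counts / t
  initialize(set, data = d)
}

#' Filter lowly translated mRNAs
#'
#' Removes every transcript for which, in at least one replicate of at
#' least one condition, the fraction of codons with zero ribosome density
#' is strictly greater than `maxZeroFraction` (default 0.25, i.e. the
#' ">25% zero codons in any one biological replicate" rule). The zero test
#' is exact equality: densities derive from counts, so zeros are identical
#' before and after TPM normalization.
#'
#' @param set A [CodonProfileSet].
#' @param maxZeroFraction Threshold in \[0, 1\].
#' @return The filtered set; `removalLog(set)` lists each removed
#'   transcript with its worst offending replicate and zero fraction.
#' @export
filterTranslated <- function(set, maxZeroFraction = 0.25) {
  if (length(set) == 0L) stop("empty profile set")
  if (maxZeroFraction < 0 || maxZeroFraction > 1)
    stop("maxZeroFraction must lie in [0, 1]")
  d <- set@data
  vals <- .profileValues(set)
  zf <- vapply(vals, function(v) mean(v == 0), numeric(1))
  worst <- tapply(seq_along(zf), d$transcript_id, function(idx)
    idx[which.max(zf[idx])])
  offending <- worst[zf[worst] > maxZeroFraction]
  removed <- names(offending)
  log <- if (length(offending)) {
    o <- unname(offending)
    S4Vectors::DataFrame(transcript_id = d$transcript_id[o],
                         condition = d$condition[o],
                         replicate = d$replicate[o],
                         zero_fraction = unname(zf[o]))
  } else .emptyRemovalLog()
  keep <- !(d$transcript_id %in% removed)
  initialize(set, data = d[keep, , drop = FALSE], removalLog = log)
}
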