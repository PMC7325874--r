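# Interchange formats. The canonical depth input is a bedGraph dialect in
# TRANSCRIPT coordinates (the alignment reference is the transcriptome):
# transcript_id <tab> start <tab> end <tab> depth, 0-based half-open.
# The per-codon fixture format ("codon_tsv") is:
# transcript_id <tab> condition <tab> replicate <tab> c1,c2,...,cn

.readLinesNoComments <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  list(lines = lines[keep], lineNo = which(keep))
}

#' Read per-codon or per-nucleotide depth into a CodonProfileSet
#'
#' Reads ribosome footprint depth in either supported dialect. bedGraph
#' intervals (transcript coordinates, 0-based half-open) are expanded to
#' per-nucleotide depth -- uncovered positions are zero -- and summed into
#' codons with [sumDepthToCodons()]; the depth is expected to cover the
#' CDS without the stop codon. `codon_tsv` rows carry condition and
#' replicate labels and comma-separated per-codon counts and are passed
#' through. The dialect is sniffed from the first data line when
#' `dialect = "auto"`.
#'
#' @param path Input file.
#' @param dialect `"auto"`, `"bedgraph"` or `"codon_tsv"`.
#' @param condition,replicate Labels applied to bedGraph input (the
#'   codon_tsv dialect carries its own).
#' @param offset P-site offset in nucleotides for bedGraph input.
#' @return A [CodonProfileSet] (empty, with a warning, for an empty
#'   file).
#' @export
readDepth <- function(path, dialect = c("auto", "bedgraph", "codon_tsv"),
                      condition = "control", replicate = "1",
                      offset = 0L) {
  dialect <- match.arg(dialect)
  parsed <- .readLinesNoComments(path)
  if (!length(parsed$lines)) {
    warning("no data lines in ", path, "; returning an empty profile set")
    return(new("CodonProfileSet",
               data = S4Vectors::DataFrame(
                 transcript_id = character(0), condition = character(0),
                 replicate = character(0),
                 counts = IRanges::NumericList()),
               removalLog = .emptyRemovalLog()))
  }
  if (dialect == "auto") {
    f <- strsplit(parsed$lines[1L], "\t", fixed = TRUE)[[1L]]
    dialect <- if (length(f) == 4L &&
                   !is.na(suppressWarnings(as.numeric(f[2L]))) &&
                   !is.na(suppressWarnings(as.numeric(f[3L]))))
      "bedgraph" else "codon_tsv"
  }
  if (dialect == "bedgraph")
    .readBedgraph(parsed, path, condition, replicate, offset)
  else
    .readCodonTsv(parsed, path)
}

.readBedgraph <- function(parsed, path, condition, replicate, offset) {
  fields <- strsplit(parsed$lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 4L)
  if (length(bad))
    stop("malformed bedGraph line(s) in ", path, ": ",
         paste(utils::head(parsed$lineNo[bad], 5L), collapse = ", "))
  tx <- vapply(fields, `[[`, "", 1L)
  start <- as.numeric(vapply(fields, `[[`, "", 2L))
  end <- as.numeric(vapply(fields, `[[`, "", 3L))
  depth <- as.numeric(vapply(fields, `[[`, "", 4L))
  if (anyNA(start) || anyNA(end) || anyNA(depth))
    stop("non-numeric bedGraph field in ", path)
  if (any(start < 0) || any(end <= start))
    stop("invalid interval (need 0 <= start < end) in ", path)
  if (any(depth < 0)) stop("negative depth in ", path)
  counts <- list(); ids <- character(0)
  for (t in unique(tx)) {
    sel <- which(tx == t)
    o <- sel[order(start[sel])]
    if (any(start[o][-1L] < end[o][-length(o)]))
      stop("overlapping intervals for transcript '", t, "' in ", path)
    nt <- numeric(max(end[o]))
    for (j in o) nt[(start[j] + 1L):end[j]] <- depth[j]
    ids <- c(ids, t)
    counts[[length(counts) + 1L]] <-
      sumDepthToCodons(nt, offset = offset, transcript = t)
  }
  CodonProfileSet(counts, ids, condition = condition,
                  replicate = replicate)
}

.readCodonTsv <- function(parsed, path) {
  fields <- strsplit(parsed$lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 4L)
  if (length(bad))
    stop("ragged codon_tsv row(s) in ", path, " at line(s): ",
         paste(utils::head(parsed$lineNo[bad], 5L), collapse = ", "))
  counts <- lapply(seq_along(fields), function(j) {
    v <- suppressWarnings(
      as.numeric(strsplit(fields[[j]][4L], ",", fixed = TRUE)[[1L]]))
    if (anyNA(v))
      stop("non-numeric count in ", path, " at line ", parsed$lineNo[j])
    v
  })
  CodonProfileSet(counts,
                  transcriptId = vapply(fields, `[[`, "", 1L),
                  condition = vapply(fields, `[[`, "", 2L),
                  replicate = vapply(fields, `[[`, "", 3L))
}

# '#'-prefixed provenance header: package version plus caller-supplied
# key = value parameters. No timestamps, so identical runs give
# byte-identical files.
.provenanceHeader <- function(params = list()) {
  c(paste0("# riboRDI v", as.character(utils::packageVersion("riboRDI"))),
    vapply(names(params), function(k)
      paste0("# ", k, " = ", paste(format(params[[k]]), collapse = ",")),
      character(1)))
}

#' Write a CodonProfileSet in the codon_tsv format
#'
#' One row per profile: `transcript_id`, `condition`, `replicate`, and
#' the comma-separated per-codon counts, preceded by a `#`-prefixed
#' provenance header. Integer counts round-trip bit-exactly through
#' [readDepth()].
#'
#' @param set A [CodonProfileSet].
#' @param path Output file.
#' @param params Named list recorded in the header (seed, parameters).
#' @return Invisibly, `path`.
#' @export
writeProfileSet <- function(set, path, params = list()) {
  d <- set@data
  body <- vapply(seq_len(nrow(d)), function(j)
    paste(d$transcript_id[j], d$condition[j], d$replicate[j],
          paste(as.character(d$counts[[j]]), collapse = ","),
          sep = "\t"), character(1))
  writeLines(c(.provenanceHeader(params), body), path)
  invisible(path)
}

#' Write a result table as TSV with a provenance header
#'
#' @param df A data.frame-like table ([S4Vectors::DataFrame] accepted).
#' @param path Output file.
#' @param params Named list recorded in the `#`-prefixed header.
#' @return Invisibly, `path`.
#' @export
writeResultTsv <- function(df, path, params = list()) {
  df <- as.data.frame(df)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.provenanceHeader(params), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a gene list (one identifier per line)
#'
#' `#` comments and blank lines are skipped; duplicates are dropped with
#' a warning, preserving first-seen order.
#'
#' @param path Input file.
#' @return Character vector of unique identifiers.
#' @export
readGeneList <- function(path) {
  parsed <- .readLinesNoComments(path)
  ids <- trimws(sub("#.*$", "", parsed$lines))
  ids <- ids[nzchar(ids)]
  if (!length(ids)) stop("no identifiers in ", path)
  dup <- duplicated(ids)
  if (any(dup))
    warning(sum(dup), " duplicate identifier(s) in ", path, " dropped")
  ids[!dup]
}

#' Read a transcript -> read-count TSV
#'
#' Two columns: transcript identifier, non-negative read count.
#'
#' @param path Input file.
#' @return Named numeric vector.
#' @export
readCounts <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.table(path, header = FALSE, comment.char = "#",
                           col.names = c("transcript_id", "count"),
                           colClasses = c("character", "numeric"))
  if (any(tab$count < 0)) stop("negative read count in ", path)
  stats::setNames(tab$count, tab$transcript_id)
}

#' Transcript lengths from a CDS FASTA
#'
#' Reads a FASTA of coding sequences ([Biostrings::readDNAStringSet])
#' and returns nucleotide lengths named by the first whitespace-separated
#' token of each record header (matching the transcript identifiers used
#' in depth files).
#'
#' @param path FASTA file.
#' @return Named numeric vector of lengths (nt).
#' @export
readLengthsFromFasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  s <- Biostrings::readDNAStringSet(path)
  ids <- vapply(strsplit(names(s), "\\s+"), `[[`, "", 1L)
  stats::setNames(as.numeric(Biostrings::width(s)), ids)
}

#' Read CDS sequences from FASTA
#'
#' @param path FASTA file.
#' @return A [Biostrings::DNAStringSet] named by the first header token.
#' @export
readCdsFasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  s <- Biostrings::readDNAStringSet(path)
  names(s) <- vapply(strsplit(names(s), "\\s+"), `[[`, "", 1L)
  s
}
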