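# Codon adaptation index (Sharp & Li 1987): relative adaptiveness w per
# sense codon from a genome usage table, CAI as the geometric mean of w
# over a CDS.

.senseCodons <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc != "*"]
}

.stopCodons <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc == "*"]
}

.normalizeCodonNames <- function(x) {
  x <- toupper(x)
  gsub("U", "T", x, fixed = TRUE)
}

#' Relative adaptiveness from a codon-usage table
#'
#' Converts raw codon abundances (counts or frequency per thousand) into
#' relative adaptiveness values: within each synonymous family of the
#' standard genetic code, `w = f / max(f)`. Zero-abundance codons receive
#' a pseudo-abundance of 0.5 before division (standard CAI practice), so
#' every `w` is strictly positive. Single-codon families (ATG, TGG) get
#' `w = 1`; stop codons carry no `w`.
#'
#' @param abundance Named non-negative numeric vector; names are DNA or
#'   RNA codons (case-insensitive), covering all 61 sense codons. Stop
#'   codon rows are allowed and ignored for `w`.
#' @return A [CodonUsageTable].
#' @examples
#' tab <- relativeAdaptiveness(setNames(rep(1, 61), names(
#'   Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]))
#' codonW(tab)[["ATG"]]
#' @export
relativeAdaptiveness <- function(abundance) {
  names(abundance) <- .normalizeCodonNames(names(abundance))
  if (anyDuplicated(names(abundance)))
    stop("duplicated codon(s) in usage table")
  if (any(abundance < 0)) stop("negative codon abundance")
  sense <- .senseCodons()
  miss <- setdiff(sense, names(abundance))
  if (length(miss))
    stop("missing sense codon(s): ", paste(miss, collapse = ", "))
  f <- abundance[sense]
  aa <- Biostrings::GENETIC_CODE[sense]
  famMax <- tapply(f, aa, max)
  dead <- sort(unique(aa[famMax[aa] == 0]))
  if (length(dead))
    stop("all-zero synonymous family(ies): ",
         paste(dead, collapse = ", "))
  f[f == 0] <- 0.5
  w <- as.numeric(f) / as.numeric(tapply(f, aa, max)[aa])
  new("CodonUsageTable", abundance = abundance,
      w = stats::setNames(w, sense))
}

#' @rdname CodonUsageTable-class
#' @export
setMethod("codonW", "CodonUsageTable", function(x) x@w)

#' @rdname CodonUsageTable-class
#' @export
setMethod("codonAbundance", "CodonUsageTable", function(x) x@abundance)

#' @rdname CodonUsageTable-class
#' @export
setMethod("show", "CodonUsageTable", function(object) {
  cat("CodonUsageTable: 61 sense codons,",
      sum(abs(object@w - 1) < 1e-12), "family-optimal codon(s)\n")
  invisible(NULL)
})

#' Read a codon-usage table from TSV
#'
#' Two tab- or whitespace-separated columns: codon, abundance. Codons are
#' case-insensitive, DNA (T) and RNA (U) alphabets both accepted; lines
#' starting with `#` are comments.
#'
#' @param path Path to the table.
#' @return Named numeric abundance vector (DNA codons).
#' @export
readCodonUsage <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.table(path, header = FALSE, comment.char = "#",
                           col.names = c("codon", "abundance"),
                           colClasses = c("character", "numeric"))
  stats::setNames(tab$abundance, .normalizeCodonNames(tab$codon))
}

.splitCodons <- function(seq, id) {
  s <- .normalizeCodonNames(seq)
  L <- nchar(s)
  if (L == 0L) stop("empty CDS for '", id, "'")
  if (L %% 3L != 0L)
    stop("CDS length ", L, " of '", id, "' is not a multiple of 3")
  codons <- substring(s, seq(1L, L - 2L, by = 3L), seq(3L, L, by = 3L))
  badPos <- grep("[^ACGT]", codons)
  if (length(badPos))
    stop("ambiguous or non-DNA base in '", id, "' at codon ", badPos[1L],
         " (", codons[badPos[1L]], ")")
  codons
}

#' Codon adaptation index of coding sequences
#'
#' CAI is the geometric mean of the relative adaptiveness `w` over all
#' sense codons of a CDS, computed in log space:
#' \eqn{CAI = \exp(\frac{1}{L}\sum_i \log w_i)}. A trailing stop codon is
#' permitted and excluded from `L`; an internal stop codon or an ambiguous
#' base is an error reporting its codon position.
#'
#' @param cds A character vector of DNA/RNA sequences (named by
#'   transcript), or a [Biostrings::DNAStringSet].
#' @param table A [CodonUsageTable].
#' @return Named numeric vector of CAI values in (0, 1].
#' @examples
#' tab <- relativeAdaptiveness(setNames(rep(1, 61), names(
#'   Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]))
#' computeCai(c(tx1 = "ATGGCTAAA"), tab)
#' @export
computeCai <- function(cds, table) {
  stopifnot(is(table, "CodonUsageTable"))
  if (is(cds, "DNAStringSet") || is(cds, "RNAStringSet"))
    cds <- stats::setNames(as.character(cds), names(cds))
  if (!is.character(cds)) stop("'cds' must be character or DNAStringSet")
  ids <- if (is.null(names(cds))) as.character(seq_along(cds)) else names(cds)
  w <- codonW(table)
  stops <- .stopCodons()
  out <- vapply(seq_along(cds), function(j) {
    codons <- .splitCodons(cds[[j]], ids[j])
    if (length(codons) > 1L && codons[length(codons)] %in% stops)
      codons <- codons[-length(codons)]
    internal <- which(codons %in% stops)
    if (length(internal))
      stop("internal stop codon in '", ids[j], "' at codon ",
           internal[1L])
    if (!length(codons)) stop("no sense codons in '", ids[j], "'")
    exp(mean(log(w[codons])))
  }, numeric(1))
  stats::setNames(out, ids)
}
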