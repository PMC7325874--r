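# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`; the
# caller's RNG stream is untouched. seed = NULL evaluates as-is.
.withSeed <- function(seed, code) {
  if (is.null(seed) || (length(seed) == 1L && is.na(seed)))
    return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L)
    stop("'seed' must be a single number or NULL")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

# Per-profile value vectors: densities when normalized, counts otherwise.
.profileValues <- function(set) {
  d <- set@data
  v <- if ("densities" %in% colnames(d)) d$densities else d$counts
  out <- as.list(v)
  names(out) <- paste(d$transcript_id, d$condition, d$replicate, sep = "|")
  out
}

.emptyRemovalLog <- function() {
  S4Vectors::DataFrame(transcript_id = character(0),
                       condition = character(0),
                       replicate = character(0),
                       zero_fraction = numeric(0))
}

# Per-(transcript, condition) replicate-averaged value vectors:
# list(condition -> named list(transcript -> numeric)).
.conditionMeanProfiles <- function(set) {
  d <- set@data
  vals <- .profileValues(set)
  out <- list()
  for (cond in conditionNames(set)) {
    sel <- which(d$condition == cond)
    byTx <- split(sel, d$transcript_id[sel])
    out[[cond]] <- lapply(byTx, function(idx) {
      m <- vals[[idx[1L]]]
      if (length(idx) > 1L)
        for (j in idx[-1L]) m <- m + vals[[j]]
      m / length(idx)
    })
  }
  out
}

.normalizeVec <- function(v, normalization, tx) {
  s <- switch(normalization, mean = mean(v), max = max(v),
              stop("unknown normalization '", normalization, "'"))
  if (s <= 0)
    stop("cannot normalize zero-density transcript '", tx, "'")
  v / s
}
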