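test_that("codon summation collapses nucleotide triplets and drops partial tails", {
  expect_equal(sumDepthToCodons(c(1, 1, 1, 2, 2, 2)), c(3, 6))
  expect_equal(sumDepthToCodons(c(0, 0, 0, 0, 0, 0)), c(0, 0))
  expect_warning(out <- sumDepthToCodons(c(1, 1, 1, 5), transcript = "tx"),
                 "partial codon")
  expect_equal(out, 3)
  # offset shifts the frame
  expect_warning(expect_equal(
    sumDepthToCodons(c(9, 1, 1, 1, 2, 2, 2), offset = 1), c(3, 6)), NA)
  expect_error(sumDepthToCodons(numeric(0), transcript = "txE"), "txE")
  expect_error(sumDepthToCodons(c(1, -1, 1), transcript = "txN"), "txN")
  expect_error(sumDepthToCodons(c(1, 1, 1), offset = 2, transcript = "txO"),
               "txO")
})

test_that("codon summation conserves total depth over consumed nucleotides", {
  set.seed(7)
  for (rep in 1:20) {
    len <- sample(3:60, 1)
    nt <- sample(0:20, len, replace = TRUE)
    off <- sample(0:min(3, len - 3), 1)
    nc <- (len - off) %/% 3
    cod <- suppressWarnings(sumDepthToCodons(nt, offset = off))
    expect_identical(sum(cod), as.numeric(sum(nt[(off + 1):(off + 3 * nc)])))
  }
})

test_that("TPM normalization matches hand arithmetic and always sums to 1e6", {
  expect_equal(unname(computeTPM(c(A = 7), c(A = 300))), 1e6)
  tpm <- computeTPM(c(A = 10, B = 10), c(A = 1000, B = 2000))
  expect_equal(unname(tpm), c(2e6 / 3, 1e6 / 3), tolerance = 1e-9)
  tpm0 <- computeTPM(c(A = 10, B = 0), c(A = 300, B = 300))
  expect_equal(unname(tpm0), c(1e6, 0))
  expect_error(computeTPM(c(A = 0, B = 0), c(A = 10, B = 10)), "all-zero")
  expect_error(computeTPM(c(A = 1, B = 1), c(A = 10)), "B")
  set.seed(11)
  for (rep in 1:10) {
    k <- sample(2:30, 1)
    rc <- setNames(rpois(k, 50), paste0("t", seq_len(k)))
    rc[1] <- rc[1] + 1   # guarantee a nonzero library
    ln <- setNames(sample(100:5000, k), names(rc))
    expect_equal(sum(computeTPM(rc, ln)), 1e6, tolerance = 1e-6)
  }
})

test_that("density normalization divides counts by TPM and is consistent under rescaling", {
  ps <- CodonProfileSet(list(c(2, 4), c(0, 0, 0)), c("txA", "txB"))
  ns <- normalizeProfiles(ps, c(txA = 2, txB = 5))
  expect_true(isNormalized(ns))
  expect_equal(unname(profileDensities(ns)[[1]]), c(1, 2))
  expect_equal(unname(profileDensities(ns)[[2]]), c(0, 0, 0))
  # counts * k with tpm * k gives identical densities
  ps2 <- CodonProfileSet(list(c(2, 4) * 3), "txA")
  ns2 <- normalizeProfiles(ps2, c(txA = 2 * 3))
  expect_equal(profileDensities(ns2)[[1]], profileDensities(ns)[[1]])
  expect_error(normalizeProfiles(ps, c(txA = 0, txB = 5)), "txA")
  expect_error(normalizeProfiles(ps, c(txA = 2)), "txB")
})

test_that("translated-mRNA filter applies the strict >25% zero rule per replicate", {
  counts <- list(
    c(1, 2, 3, 0), c(1, 1, 1, 1),   # txKeep: worst zero fraction 0.25
    c(1, 0, 0, 1), c(1, 1, 1, 1),   # txDrop: 0.50 in one replicate
    c(2, 2, 2, 2), c(3, 3, 3, 3))   # txFull: no zeros
  ps <- CodonProfileSet(counts,
                        transcriptId = rep(c("txKeep", "txDrop", "txFull"),
                                           each = 2),
                        condition = "control",
                        replicate = rep(c("r1", "r2"), 3))
  out <- filterTranslated(ps, 0.25)
  expect_setequal(transcriptIds(out), c("txKeep", "txFull"))
  log <- removalLog(out)
  expect_equal(log$transcript_id, "txDrop")
  expect_equal(log$replicate, "r1")
  expect_equal(log$zero_fraction, 0.5)
  # threshold 1 removes nothing; threshold 0 removes any transcript with a zero
  expect_length(transcriptIds(filterTranslated(ps, 1)), 3)
  expect_setequal(transcriptIds(filterTranslated(ps, 0)), "txFull")
})

test_that("profile set enforces its invariants", {
  expect_error(CodonProfileSet(list(c(1, -2)), "tx"), "negative")
  expect_error(CodonProfileSet(list(1:3, 1:4), c("tx", "tx"),
                               replicate = c("r1", "r2")),
               "codon length")
  expect_error(CodonProfileSet(list(1:3, 1:3), c("tx", "tx")),
               "duplicated")
  ps <- tinyStudySet()
  expect_equal(length(ps), 8L)
  expect_equal(unname(nCodons(ps)), c(4L, 4L))
  expect_setequal(conditionNames(ps), c("control", "treated"))
  sub <- keepTranscripts(ps, "txA")
  expect_equal(transcriptIds(sub), "txA")
  expect_equal(length(sub), 4L)
})
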