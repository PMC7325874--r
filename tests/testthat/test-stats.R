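test_that("Mann-Whitney U matches hand-derived examples", {
  mw <- mannWhitneyU(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$U, 0)
  expect_equal(mw$p, 0.1)
  expect_equal(mw$method, "exact")
  tie <- mannWhitneyU(c(5, 5), c(5, 5))
  expect_equal(tie$p, 1)
  expect_equal(tie$U, 2)       # all four pairs tie, 1/2 each
  mw2 <- mannWhitneyU(c(1, 3), c(2, 4))
  oracle <- bruteMannWhitney(c(1, 3), c(2, 4))
  expect_equal(mw2$U, oracle$U)
  expect_equal(mw2$p, oracle$p)   # 2/3 from the 6 labelings
  expect_equal(oracle$p, 2 / 3)
  expect_error(mannWhitneyU(numeric(0), 1:3), "non-empty")
})

test_that("exact Mann-Whitney agrees with full enumeration on small samples", {
  set.seed(31)
  for (rep in 1:40) {
    n1 <- sample(1:4, 1); n2 <- sample(1:4, 1)
    a <- rnorm(n1); b <- rnorm(n2)
    mw <- mannWhitneyU(a, b, method = "exact")
    oracle <- bruteMannWhitney(a, b)
    expect_equal(mw$U, oracle$U)
    expect_equal(mw$p, oracle$p, tolerance = 1e-12)
  }
  # tied data go through the enumeration path and still match
  for (rep in 1:15) {
    a <- sample(1:3, sample(2:4, 1), replace = TRUE)
    b <- sample(1:3, sample(2:4, 1), replace = TRUE)
    mw <- mannWhitneyU(a, b, method = "exact")
    oracle <- bruteMannWhitney(a, b)
    expect_equal(mw$U, oracle$U)
    expect_equal(mw$p, oracle$p, tolerance = 1e-12)
  }
})

test_that("Mann-Whitney agrees with the base-R implementation", {
  set.seed(41)
  a <- rnorm(8); b <- rnorm(7) + 0.5
  mw <- mannWhitneyU(a, b, method = "exact")
  ref <- wilcox.test(a, b, exact = TRUE)
  expect_equal(mw$U, unname(ref$statistic))
  expect_equal(mw$p, ref$p.value, tolerance = 1e-12)
  a2 <- rnorm(30); b2 <- rnorm(25) + 0.3
  mwN <- mannWhitneyU(a2, b2, method = "normal")
  refN <- wilcox.test(a2, b2, exact = FALSE, correct = TRUE)
  expect_equal(mwN$p, refN$p.value, tolerance = 1e-9)
  # tie-corrected normal path
  a3 <- sample(1:5, 20, replace = TRUE)
  b3 <- sample(2:6, 20, replace = TRUE)
  expect_equal(mannWhitneyU(a3, b3)$p,
               suppressWarnings(wilcox.test(a3, b3, exact = FALSE,
                                            correct = TRUE)$p.value),
               tolerance = 1e-9)
})

test_that("empirical p-value uses the (k+1)/(N+1) estimator and its bounds", {
  set.seed(3)
  delta <- setNames(c(5, 6, rnorm(198, sd = 0.01)), paste0("t", 1:200))
  et <- empiricalPvalue(delta, c("t1", "t2"), N = 500, seed = 1)
  # only a null draw of exactly {t1, t2} (1 in choose(200, 2)) can reach
  # the observed mean, so k stays at 0 or barely above
  expect_lte(et@p, 3 / 501)
  expect_gte(et@p, 1 / 501)
  expect_equal(et@p, (et@k + 1) / (et@N + 1))
  expect_error(empiricalPvalue(delta, "t1"), "at least 2")
  expect_error(empiricalPvalue(delta, c("t1", "missing")), "absent")
  expect_error(empiricalPvalue(delta, c("t1", "t2"), N = 0), ">= 1")
  expect_identical(empiricalPvalue(delta, c("t3", "t4"), N = 200,
                                   seed = 8)@p,
                   empiricalPvalue(delta, c("t3", "t4"), N = 200,
                                   seed = 8)@p)
})

test_that("bootstrap percentile CI brackets the mean and is seed-stable", {
  expect_equal(bootstrapCiMean(rep(3.2, 10), seed = 1), c(3.2, 3.2))
  set.seed(17)
  x <- rnorm(40)
  ci <- bootstrapCiMean(x, level = 0.99, B = 1000, seed = 4)
  expect_lte(ci[1], mean(x))
  expect_gte(ci[2], mean(x))
  expect_identical(ci, bootstrapCiMean(x, level = 0.99, B = 1000, seed = 4))
  expect_error(bootstrapCiMean(numeric(0)), "empty")
  expect_error(bootstrapCiMean(x, B = 10), ">= 100")
})

test_that("length-normalized metagene is flat for uniform data and scale-free", {
  ps <- CodonProfileSet(list(rep(2, 200), rep(4, 300)), c("t1", "t2"))
  mg <- metageneLengthNorm(ps, nBins = 20, seed = 1)
  st <- mg@stats
  expect_equal(st$mean, rep(1, 20))
  expect_equal(st$ciLow, rep(1, 20))
  expect_equal(st$ciHigh, rep(1, 20))
  # per-transcript rescaling changes nothing under mean normalization
  ps2 <- CodonProfileSet(list(rep(2, 200) * 50, rep(4, 300) / 7),
                         c("t1", "t2"))
  mg2 <- metageneLengthNorm(ps2, nBins = 20, seed = 1)
  expect_equal(mg2@stats$mean, st$mean)
  expect_error(metageneLengthNorm(
    CodonProfileSet(list(rep(0, 10)), "tz")), "tz")
})

test_that("codon positions map to the documented ORF-fraction bins", {
  # codon 200 of a 1000-codon ORF sits at 19.95%, i.e. bin 20 of 100
  v <- rep(1, 1000); v[200] <- 1001
  ps <- CodonProfileSet(list(v), "tx")
  mg <- metageneLengthNorm(ps, nBins = 100, seed = 1)
  st <- mg@stats
  expect_equal(st$axis[which.max(st$mean)], 0.195)
  expect_equal(which.max(st$mean), 20)
})

test_that("per-codon metagene honors its window and tracks drop-off decay", {
  pool <- buildUniformPool(simulationConfig(
    nTranscripts = 12, lengthModel = "fixed",
    fixedLengths = c(rep(200, 10), 80, 50), baselineRibosomes = 10,
    seed = 6))
  dec <- applyDropoff(pool, 0.02, deterministic = TRUE)
  mg <- metagenePerCodon(dec, start = 5, stop = 105, seed = 2)
  st <- mg@stats
  expect_equal(nrow(st), 101)
  expect_equal(st$axis, as.numeric(5:105))
  expect_true(all(st$n == 10))      # the 80- and 50-codon ORFs excluded
  expect_true(all(diff(st$mean) < 0))
  expect_error(metagenePerCodon(pool, start = 5, stop = 300), "300")
  # uniform pool gives a flat curve
  mgU <- metagenePerCodon(pool, seed = 3)
  expect_equal(var(mgU@stats$mean), 0)
})

test_that("per-region tests flag only genuinely shifted regions", {
  set.seed(55)
  m <- 20; L <- 12
  mk <- function(shift) lapply(seq_len(m), function(i) {
    v <- 1 + abs(rnorm(L, sd = 0.05))
    if (shift) v[6] <- v[6] * 0.4
    v
  })
  ps <- CodonProfileSet(c(mk(FALSE), mk(TRUE)),
                        transcriptId = rep(paste0("t", 1:m), 2),
                        condition = rep(c("A", "B"), each = m))
  # max normalization: lowering one codon leaves the other codons'
  # normalized values untouched (the transcript maximum is elsewhere),
  # so only the shifted region should light up
  mg <- metagenePerCodon(ps, start = 2, stop = 11, normalization = "max",
                         seed = 9)
  tests <- perRegionTests(mg, conditionA = "A", conditionB = "B")
  expect_equal(nrow(tests), 10)
  atShift <- tests$p[tests$region == 6]
  expect_lt(atShift, 0.01)
  # the shifted codon dominates; null codons have uniform p, so allow
  # the occasional nominal hit but nothing extreme
  expect_equal(tests$region[which.min(tests$p)], 6)
  expect_gte(sum(tests$p[tests$region != 6] > 0.05), 8)
  expect_true(all(tests$p[tests$region != 6] > 0.001))
  # identical data give p = 1 under the tie handling
  same <- perRegionTests(mg, conditionA = "A", conditionB = "A")
  expect_true(all(same$p == 1))
  # axis mismatch between two curves is an error
  mgShort <- metagenePerCodon(ps, start = 2, stop = 10, seed = 9)
  expect_error(perRegionTests(mg, mgShort, conditionA = "A",
                              conditionB = "B"), "axis mismatch")
  withBH <- perRegionTests(mg, conditionA = "A", conditionB = "B",
                           adjust = TRUE)
  expect_true("padj" %in% colnames(withBH))
  expect_true(all(withBH$padj >= withBH$p - 1e-12))
})

test_that("empirical p-values are calibrated under a null target set", {
  set.seed(42)
  delta <- setNames(rnorm(100), paste0("t", 1:100))
  hits <- 0L
  reps <- 200L
  for (i in seq_len(reps)) {
    targets <- sample(names(delta), 10)
    p <- empiricalPvalue(delta, targets, N = 999)@p
    if (p <= 0.05) hits <- hits + 1L
  }
  expect_gte(hits / reps, 0.01)
  expect_lte(hits / reps, 0.09)
})
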