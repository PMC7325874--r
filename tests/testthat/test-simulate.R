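test_that("uniform pools are flat, deterministic, and have the uniform RDI", {
  cfg <- simulationConfig(nTranscripts = 3, lengthModel = "fixed",
                          fixedLengths = c(4, 4, 4),
                          baselineRibosomes = 2, seed = 9)
  pool <- buildUniformPool(cfg)
  expect_equal(unname(profileCounts(pool)), rep(list(rep(2, 4)), 3))
  expect_equal(unname(computeRdi(pool)), rep(5 / 8, 3))
  cfgL <- simulationConfig(nTranscripts = 25, seed = 33)
  p1 <- buildUniformPool(cfgL)
  p2 <- buildUniformPool(cfgL)
  expect_identical(profileCounts(p1), profileCounts(p2))
  ns <- nCodons(p1)
  expect_true(all(ns >= 30 & ns <= 5000))
  expect_equal(unname(computeRdi(p1)), (ns + 1) / (2 * ns),
               ignore_attr = TRUE)
})

test_that("deterministic drop-off gives the geometric expectation", {
  pool <- CodonProfileSet(list(rep(8, 3)), "tx1")
  out <- applyDropoff(pool, 0.5, deterministic = TRUE)
  expect_equal(unname(profileCounts(out))[[1]], c(8, 4, 2))
  expect_equal(unname(computeRdi(out)), 22 / 42)
  expect_identical(profileCounts(applyDropoff(pool, 0)),
                   profileCounts(pool))
  # expectation equals the closed form across p and n
  for (p in c(0.005, 0.01, 0.025, 0.05)) {
    for (n in c(100, 520, 2000)) {
      det <- applyDropoff(CodonProfileSet(list(rep(10, n)), "tx"), p,
                          deterministic = TRUE)
      expect_equal(unname(computeRdi(det)),
                   rdiGeometricClosedForm(n, 1 - p), tolerance = 1e-10)
    }
  }
  expect_error(applyDropoff(pool, -0.1), "0, 1")
  expect_error(applyDropoff(pool, 1.1), "0, 1")
})

test_that("deterministic per-transit drop-off decays linearly", {
  pool <- CodonProfileSet(list(rep(10, 5)), "tx1")
  out <- applyDropoff(pool, 0.5, mode = "per_transit",
                      deterministic = TRUE)
  expect_equal(unname(profileCounts(out))[[1]],
               10 * (1 - 0.5 * (0:4) / 5))
})

test_that("stochastic drop-off occupancy matches its expectation", {
  n <- 50
  pool <- CodonProfileSet(list(rep(1, n)), "tx1")
  B <- 10000
  occ <- unname(profileCounts(
    applyDropoff(pool, 0.02, nRibosomes = B, seed = 101)))[[1]]
  q <- 0.98^(seq_len(n) - 1)
  se <- sqrt(B * q * (1 - q))
  z <- (occ - B * q) / pmax(se, 1e-9)
  expect_true(all(abs(z[c(2, 5, 10, 25, 50)]) <= 3))
  expect_true(all(abs(z[-1]) <= 5))
  expect_equal(occ[1], B)    # every ribosome occupies codon 1
  # p = 1: everything aborts after the first codon
  occ1 <- unname(profileCounts(
    applyDropoff(pool, 1, nRibosomes = 100, seed = 5)))[[1]]
  expect_equal(occ1, c(100, rep(0, n - 1)))
  expect_equal(computeRdi(occ1), 1 / n)
  # per-transit stochastic mean: linear decay
  occT <- unname(profileCounts(
    applyDropoff(pool, 0.5, mode = "per_transit", nRibosomes = B,
                 seed = 7)))[[1]]
  eT <- B * (1 - 0.5 * (seq_len(n) - 1) / n)
  expect_true(all(abs(occT - eT) <= 3 * sqrt(B) + 5))
})

test_that("RDI decreases strictly with the drop-off probability", {
  n <- 520
  grid <- c(0, 0.005, 0.01, 0.025, 0.05)
  rdis <- vapply(grid, function(p) {
    unname(computeRdi(applyDropoff(CodonProfileSet(list(rep(5, n)), "tx"),
                                   p, deterministic = TRUE)))
  }, numeric(1))
  expect_true(all(diff(rdis) < 0))
})

test_that("stalling elevates the 5' side and respects its policies", {
  pool <- CodonProfileSet(list(rep(1, 4)), "tx1")
  out <- applyStall(pool, 10, policy = "fixed", stallCodon = 2)
  expect_equal(unname(profileCounts(out))[[1]], c(10, 10, 1, 1))
  expect_equal(unname(computeRdi(out)), 37 / 88)
  expect_identical(profileCounts(applyStall(pool, 1)),
                   profileCounts(pool))
  # stall at the last codon: uniform profile scaled, RDI unchanged
  outN <- applyStall(pool, 10, policy = "fixed", stallCodon = 4)
  expect_equal(unname(computeRdi(outN)), 5 / 8)
  # local-window variant only elevates the window
  outW <- applyStall(CodonProfileSet(list(rep(1, 10)), "tx"), 10,
                     policy = "fixed", stallCodon = 6, model = "window",
                     windowWidth = 2)
  expect_equal(unname(profileCounts(outW))[[1]],
               c(1, 1, 1, 1, 10, 10, 1, 1, 1, 1))
  # uniform policy keeps stall sites within the central 90% of codons
  big <- buildUniformPool(simulationConfig(nTranscripts = 40,
                                           lengthModel = "fixed",
                                           fixedLengths = rep(100, 40),
                                           baselineRibosomes = 1,
                                           seed = 2))
  st <- applyStall(big, 10, seed = 3)
  firstLow <- vapply(unname(profileCounts(st)), function(v)
    which(v == 1)[1], numeric(1))
  expect_true(all(firstLow - 1 >= 5 & firstLow - 1 <= 95))
  expect_error(applyStall(pool, 0.5), ">= 1")
})

test_that("fixture generator is seed-deterministic and recovers its own construction", {
  cfg <- fixtureConfig(seed = 11, nTranscripts = 60)
  fx1 <- generateFixtures(cfg)
  fx2 <- generateFixtures(cfg)
  expect_identical(profileCounts(fx1$profiles), profileCounts(fx2$profiles))
  expect_identical(fx1$truth$is_target, fx2$truth$is_target)
  set <- fx1$profiles
  expect_setequal(conditionNames(set), c("control", "treated"))
  expect_setequal(replicateNames(set), c("r1", "r2"))
  expect_equal(length(set), 60 * 4)
  # written fixture files are byte-identical for the same seed
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  writeProfileSet(fx1$profiles, f1, params = list(seed = 11))
  writeProfileSet(fx2$profiles, f2, params = list(seed = 11))
  expect_identical(readLines(f1), readLines(f2))
  # targets lose RDI in the treated condition
  tab <- computeRdiSet(set)
  targets <- fx1$truth$transcript_id[fx1$truth$is_target]
  dTar <- deltaRdi(tab, "control", "treated")[targets]
  expect_gt(mean(dTar), 0.02)
})

test_that("a null fixture construction leaves the two conditions statistically identical", {
  cfg <- fixtureConfig(seed = 21, nTranscripts = 80)
  fx <- generateFixtures(cfg, excessDropoff = 0, genomeExcess = 0)
  cmp <- pairedRdiComparison(computeRdiSet(fx$profiles),
                             "control", "treated")
  # noise-only split: no condition should dominate
  expect_gt(cmp$p, 0.05)
  expect_lt(abs(cmp$nHigherA - cmp$nHigherB), 0.5 * cmp$nUsed)
})

test_that("fixture generation rejects windows that do not fit the shortest ORF", {
  cfg <- fixtureConfig(seed = 3, nTranscripts = 10, minLength = 30,
                       medianLength = 35, sdlog = 0.05)
  expect_error(generateFixtures(cfg), "shortest ORF")
})
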