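test_that("pathway seed sampling is uniform-without-replacement and reproducible", {
  net <- plantedFixture(21)
  members <- pathwayMembers(net)$PW1
  s1 <- sampleSeedGenes(net, "PW1", 5, seed = 7)
  s2 <- sampleSeedGenes(net, "PW1", 5, seed = 7)
  expect_identical(seedGenes(s1), seedGenes(s2))
  expect_length(seedGenes(s1), 5)
  expect_true(all(seedGenes(s1) %in% members))
  whole <- sampleSeedGenes(net, "PW1", length(members), seed = 1)
  expect_setequal(seedGenes(whole), members)
  expect_error(sampleSeedGenes(net, "PW1", length(members) + 1), "only")
  expect_error(sampleSeedGenes(net, "NOPE", 2), "unknown pathway")
})

test_that("recovery rates follow their set-algebra definitions", {
  # network genes: P = {p1..p4}, others = {o1..o3}; seeds = {p1}
  net <- makeNet(data.frame(a = c("p1", "p2", "p3", "o1", "o2"),
                            b = c("p2", "p3", "p4", "o2", "o3")))
  seeds <- seedsOf(net, "p1")
  P <- c("p1", "p2", "p3", "p4")
  unl <- setdiff(geneNames(net), "p1")

  # S = P \ seeds exactly -> (1, 0)
  st <- sigTable(unl, ifelse(unl %in% c("p2", "p3", "p4"), 0.01, 1))
  expect_equal(recoveryRates(st, seeds, P, net, 0.05, useAdjusted = FALSE),
               c(in_rate = 1, out_rate = 0))
  # S empty -> (0, 0)
  st0 <- sigTable(unl, rep(1, length(unl)))
  expect_equal(recoveryRates(st0, seeds, P, net, 0.05, useAdjusted = FALSE),
               c(in_rate = 0, out_rate = 0))
  # S = all non-pathway nodes -> out_rate 1
  stO <- sigTable(unl, ifelse(unl %in% c("o1", "o2", "o3"), 0.01, 1))
  expect_equal(recoveryRates(stO, seeds, P, net, 0.05, useAdjusted = FALSE),
               c(in_rate = 0, out_rate = 1))
  # every pathway gene a seed -> in_rate undefined
  expect_warning(
    rr <- recoveryRates(st, seedsOf(net, P), c("p1", "p2"), net, 0.05,
                        useAdjusted = FALSE),
    "in_rate undefined")
  expect_true(is.na(rr["in_rate"]))
  expect_error(recoveryRates(st, seeds, P, net, 0), "threshold")
})

test_that("recovery rates re-derive from raw sets on a real run", {
  net <- plantedFixture(22)
  seeds <- sampleSeedGenes(net, "PW2", 5, seed = 2)
  st <- empiricalPvalues(net, seeds, t = 5,
                         spec = randomizationSpec(nRandom = 39L, seed = 3))
  tb <- significanceTable(st)
  P <- pathwayMembers(net)$PW2
  for (th in c(0.05, 0.2, 1)) {
    rr <- recoveryRates(st, seeds, P, net, th, useAdjusted = FALSE)
    S <- tb$gene[tb$p <= th]
    expect_equal(rr[["in_rate"]],
                 length(setdiff(intersect(S, P), seedGenes(seeds))) /
                   length(setdiff(P, seedGenes(seeds))))
    expect_equal(rr[["out_rate"]],
                 length(setdiff(S, P)) /
                   length(setdiff(geneNames(net), P)))
  }
  # curves are monotone as the threshold loosens
  cv <- recoveryCurve(st, seeds, P, net, useAdjusted = FALSE)
  expect_true(all(diff(cv$in_rate) >= 0))
  expect_true(all(diff(cv$out_rate) >= 0))
  expect_equal(cv$in_rate[cv$threshold == 1], 1)
  expect_equal(cv$out_rate[cv$threshold == 1], 1)
})

test_that("recovery area summarizes curves sensibly", {
  perfect <- data.frame(in_rate = c(1, 1), out_rate = c(0, 1),
                        threshold = c(0.05, 1))
  expect_equal(recoveryArea(perfect), 1)
  diag <- data.frame(in_rate = c(0.5, 1), out_rate = c(0.5, 1),
                     threshold = c(0.05, 1))
  expect_equal(recoveryArea(diag), 0.5)
  better <- data.frame(in_rate = c(0.8, 1), out_rate = c(0.1, 1),
                       threshold = c(0.05, 1))
  expect_gt(recoveryArea(better), recoveryArea(diag))
})

test_that("a degenerate iteration sweep reduces to a single recovery curve", {
  net <- plantedFixture(23)
  sw <- iterationSweep(net, "PW1", sizes = 5L, tValues = 10L, reps = 1L,
                       spec = randomizationSpec(nRandom = 19L), seed = 5)
  grid <- defaultThresholdGrid()
  expect_equal(nrow(sw$runs), length(grid))
  expect_equal(nrow(sw$means), length(grid))
  expect_equal(sw$means$in_rate, sw$runs$in_rate[order(sw$runs$threshold)])
  expect_equal(sw$means$out_rate,
               sw$runs$out_rate[order(sw$runs$threshold)])
})

test_that("sweep outputs have the factorial shape and are seed-reproducible", {
  net <- plantedFixture(24)
  sw <- iterationSweep(net, c("PW1", "PW2"), sizes = c(4L, 6L),
                       tValues = c(5L, 10L), reps = 2L,
                       spec = randomizationSpec(nRandom = 9L), seed = 6)
  grid <- defaultThresholdGrid()
  expect_equal(nrow(sw$runs), 2 * 2 * 2 * 2 * length(grid))
  expect_equal(nrow(sw$means), 2 * length(grid))
  sw2 <- iterationSweep(net, c("PW1", "PW2"), sizes = c(4L, 6L),
                        tValues = c(5L, 10L), reps = 2L,
                        spec = randomizationSpec(nRandom = 9L), seed = 6)
  expect_identical(sw$runs, sw2$runs)
})

test_that("perturbation sweep preserves degrees and tracks its fractions", {
  net <- plantedFixture(25)
  sw <- perturbationSweep(net, "PW1", fractions = c(0.02, 0.3), reps = 1L,
                          spec = randomizationSpec(nRandom = 9L), seed = 7)
  expect_setequal(unique(sw$runs$fraction), c(0.02, 0.3))
  expect_equal(nrow(sw$means), 2 * length(defaultThresholdGrid()))
})

test_that("stability matrices are symmetric with unit diagonal", {
  net <- plantedFixture(26)
  sets <- list(a = seedGenes(sampleSeedGenes(net, "PW1", 4, seed = 1)),
               b = seedGenes(sampleSeedGenes(net, "PW2", 4, seed = 2)),
               c = seedGenes(sampleSeedGenes(net, "PW3", 4, seed = 3)))
  # tiny ensembles can give degenerate (zero-variance) dendrograms, which
  # correlate as NA with a warning; only the matrix shape is under test
  m <- suppressWarnings(
    stabilityAcrossT(net, sets, tValues = c(5L, 10L),
                     spec = randomizationSpec(nRandom = 19L), seed = 8))
  expect_equal(dim(m), c(2, 2))
  expect_equal(diag(m), c(`5` = 1, `10` = 1))
  expect_equal(m, t(m))
  expect_error(stabilityAcrossT(net, sets[1:2]), "at least 3")
})
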