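# Directional system partitions, partitioned TPMs, and phi_s.

test_that("direction labelings collapse to the distinct cut-sets", {
  expect_length(systemPartitions(2, dedupe = FALSE), 9L)
  p2 <- systemPartitions(2)
  expect_length(p2, 3L)
  cuts <- sapply(p2, function(p) paste(which(p$cut), collapse = ","))
  expect_length(unique(cuts), 3L)

  # 3 units: sum over set partitions with k in {2, 3} of 3^k labelings
  expect_length(systemPartitions(3, dedupe = FALSE), 54L)
  # dedup is consistent with the raw labelings' distinct cut matrices
  raw <- systemPartitions(3, dedupe = FALSE)
  rawCuts <- unique(sapply(raw, function(p) paste(which(p$cut), collapse = ",")))
  expect_length(systemPartitions(3), length(rawCuts))
})

test_that("a single-unit system has exactly one (complete) partition", {
  p <- systemPartitions(1)
  expect_length(p, 1L)
  expect_identical(p[[1]]$X, list(1L))
  expect_equal(p[[1]]$norm, 1)
})

test_that("partitioned TPMs match brute-force causal marginalization", {
  for (seed in c(6, 19)) {
    net <- rProductNetwork(3, seed = seed)
    sys <- conditionSystem(net, 1:3)
    sSizes <- rep(2L, 3)
    st <- oStateTable(sSizes)
    for (p in systemPartitions(3)[c(1, 5, 9)]) {
      ptTe <- partitionedTpm(sys, p, "effect")
      # oracle: per unit, per conditioning row
      for (row in c(1L, 4L, 8L)) for (j in 1:3) {
        i <- which(sapply(p$parts, function(b) j %in% b))
        manual <- oPartitionedUnit(effectTpm(sys), sSizes, j, p$X[[i]],
                                   st[row, ], 2L)
        pj <- sum(ptTe[row, st[, j] == 2L])
        expect_equal(pj, manual, tolerance = 1e-10)
      }
    }
  }
})

test_that("partitions leave independent units untouched", {
  # two unconstrained-coupled... two units with no mutual connections:
  # each holds itself; partition cutting between them changes nothing
  w <- matrix(0, 2, 2); w[1, 1] <- 1; w[2, 2] <- 1
  net <- logisticNetwork(w, k = 4, state = "Ab")
  sys <- conditionSystem(net, 1:2)
  for (p in systemPartitions(2)) {
    expect_equal(partitionedTpm(sys, p, "effect"), effectTpm(sys),
                 tolerance = 1e-14)
  }
  res <- systemPhi(sys)
  expect_identical(res@phi, 0)
  expect_true(res@reducible)
})

test_that("cutting a reciprocal copy pair noises the severed factors to 0.5", {
  w <- matrix(0, 2, 2); w[2, 1] <- 1; w[1, 2] <- 1
  net <- logisticNetwork(w, k = 4, state = "Ab")
  sys <- conditionSystem(net, 1:2)
  both <- Filter(function(p) all(lengths(p$X) == 1L), systemPartitions(2))
  expect_length(both, 1L)
  pt <- partitionedTpm(sys, both[[1]], "effect")
  expect_equal(pt, matrix(0.25, 4, 4), tolerance = 1e-12)
})

test_that("phi_s never exceeds the partition normalization", {
  for (seed in 1:8) {
    net <- makeRandomLogistic(3, k = 4, seed = seed)
    sys <- conditionSystem(net, 1:3)
    ces <- maximalCauseEffectState(sys)
    if (is.na(ces@effectState) || is.na(ces@causeState)) next
    for (p in systemPartitions(3)) {
      pe <- phiDirectional(sys, p, "effect", ces@effectState)
      pc <- phiDirectional(sys, p, "cause", ces@causeState)
      expect_lte(min(pe, pc), p$norm + 1e-9)
      expect_gte(pe, 0)
      expect_gte(pc, 0)
    }
  }
})

test_that("the 6-unit copy cycle has the closed-form phi_s", {
  net <- makeDirectedCycle(6, k = 4, state = "Abcdef")
  res <- systemPhi(net)
  # MIP severs two cycle connections; each costs log2(sigma / 0.5) at
  # selectivity sigma^6 (derived by direct evaluation of the partitioned
  # factors: a noised copy unit drops from sigma to 1/2)
  sg <- 1 / (1 + exp(-4))
  expect_equal(res@phi, sg^6 * 2 * log2(sg / 0.5), tolerance = 1e-9)
  expect_false(res@reducible)
  expect_equal(res@phiCause, res@phiEffect, tolerance = 1e-9)
})

test_that("feed-forward systems are exactly reducible", {
  net <- makeRandomFeedforward(3, seed = 1)
  res <- systemPhi(net)
  expect_identical(res@phi, 0)
  # feed-forward chain with deterministic units
  chain <- copyChainNet()
  resC <- systemPhi(chain)
  expect_identical(resC@phi, 0)
})

test_that("deduplicated search equals the naive full-labeling search", {
  for (seed in c(2, 5, 12)) {
    n <- 2L + (seed %% 3L)
    net <- makeRandomLogistic(n, k = 4, seed = seed,
                              state = rep(c(1L, 2L), length.out = n))
    sys <- conditionSystem(net, seq_len(n))
    expect_equal(systemPhi(sys)@phi, oSystemPhi(sys), tolerance = 1e-9)
  }
})
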