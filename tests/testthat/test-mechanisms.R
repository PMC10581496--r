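# Mechanism-level repertoires, intrinsic information, disintegrating
# partitions, phi_d, maximal purviews, and distinctions.

test_that("effect repertoires match the brute-force marginalization oracle", {
  for (seed in c(5, 14, 27)) {
    net <- rProductNetwork(3, seed = seed)
    sys <- conditionSystem(net, 1:3)
    for (Mset in list(1L, c(1L, 2L), c(2L, 3L))) {
      for (Zset in list(2L, c(1L, 3L), 1:3)) {
        rep_ <- effectRepertoire(sys, Mset, Zset)
        oracle <- oEffectRepertoire(effectTpm(sys), rep(2L, 3),
                                    Mset, currentState(net)[Mset], Zset)
        expect_equal(rep_$table, oracle, tolerance = 1e-10)
      }
    }
  }
})

test_that("a full deterministic mechanism points at its successor substate", {
  net <- permutationNetwork(c(2L, 3L, 4L, 1L), 2, state = c(1L, 1L))
  sys <- conditionSystem(net, 1:2)
  rep_ <- effectRepertoire(sys, 1:2, 1:2)
  expect_equal(rep_$table, c(0, 1, 0, 0), tolerance = 1e-12)  # successor
})

test_that("an empty mechanism gives the fully unconstrained product", {
  net <- rProductNetwork(3, seed = 2)
  sys <- conditionSystem(net, 1:3)
  rep_ <- effectRepertoire(sys, integer(0), 1:3)
  # product of per-unit grand marginals, assembled independently
  Te <- effectTpm(sys)
  st <- oStateTable(rep(2L, 3))
  perUnit <- lapply(1:3, function(j) sapply(1:2, function(a)
    mean(sapply(1:8, function(si) sum(Te[si, st[, j] == a])))))
  manual <- sapply(1:8, function(v)
    perUnit[[1]][st[v, 1]] * perUnit[[2]][st[v, 2]] * perUnit[[3]][st[v, 3]])
  expect_equal(rep_$table, manual, tolerance = 1e-12)
})

test_that("cause repertoires reduce correctly and flag impossible states", {
  net <- rProductNetwork(3, seed = 9)
  sys <- conditionSystem(net, 1:3)
  # single-unit mechanism: product equals the bare unit factor
  rep1 <- causeRepertoire(sys, 2L, c(1L, 3L))
  mk <- phistruct:::margDist(sys, "c", 2L, phistruct:::maskOf(c(1L, 3L)))
  expect_equal(rep1$table, mk[, systemState(sys)[2]], tolerance = 1e-12)
  expect_false(rep1$causeless)
  # a mechanism state impossible under every purview state is causeless
  tp <- matrix(0, 4, 4); tp[, 4] <- 1      # B always switches ON
  netD <- Network(tp, units = c("A", "B"), state = c(2L, 2L))
  sysD <- conditionSystem(netD, 1:2)
  repBad <- causeRepertoire(sysD, 2L, 1L, mechanismState = 1L)  # B OFF now
  expect_true(repBad$causeless)
  # and phi_c treats it as causeless (0), not an error
  expect_equal(distinctionPhi(sysD, 2L, 1L, "cause", mechanismState = 1L)$phi, 0)
})

test_that("mechanism intrinsic information has the textbook values", {
  # deterministic copy A -> B: mechanism {A} over purview {B}, effect side
  net <- copyChainNet()
  sys <- conditionSystem(net, 1:3)
  ii <- mechanismIi(sys, 1L, 2L, "effect")
  expect_equal(ii$max, 1, tolerance = 1e-12)          # 1 * log2(2)
  # unconstrained mechanism-purview pair: zero
  w <- matrix(0, 2, 2); w[1, 1] <- 1                  # B has no inputs
  netU <- logisticNetwork(w, k = 4, state = "Ab")
  sysU <- conditionSystem(netU, 1:2)
  iiU <- mechanismIi(sysU, 1L, 2L, "effect")
  expect_equal(iiU$max, 0, tolerance = 1e-12)
})

test_that("cycle mechanisms match direct evaluation over candidate purviews", {
  net <- makeDirectedCycle(6, k = 4, state = "Abcdef")
  sys <- conditionSystem(net, 1:6)
  sg <- 1 / (1 + exp(-4))
  # mechanism {A} (ON) over its successor {B}: p_e(B on | A on) = sigma,
  # unconstrained = 1/2
  ii <- mechanismIi(sys, 1L, 2L, "effect")
  expect_equal(ii$max, sg * log2(2 * sg), tolerance = 1e-10)
  expect_equal(ii$states, 2L)    # B ON
  # over a non-input purview {D}: A exerts no constraint
  iiD <- mechanismIi(sys, 1L, 4L, "effect")
  expect_equal(iiD$max, 0, tolerance = 1e-10)
})

test_that("disintegrating partitions enumerate per the constraint set", {
  # |M| = 1, |Z| = 1: the single full severing
  p11 <- mechanismPartitions(1L, 1L)
  expect_length(p11, 1L)
  expect_length(p11[[1]], 2L)
  # counts match an independent brute-force enumeration
  expect_length(mechanismPartitions(1:2, 1L), oDisintegrationCount(2, 1))
  expect_length(mechanismPartitions(1:2, 1:2), oDisintegrationCount(2, 2))
  expect_length(mechanismPartitions(1L, 1:3), oDisintegrationCount(1, 3))
  # the whole pair (M, Z) alone is never a partition
  for (p in mechanismPartitions(1:2, 1:2)) {
    expect_gte(length(p), 2L)
    expect_false(any(vapply(p, function(pr)
      length(pr[[1]]) == 2L && length(pr[[2]]) > 0L, logical(1))))
  }
})

test_that("mechanism phi is zero without mechanism-purview connections", {
  net <- makeDirectedCycle(6, k = 4, state = "Abcdef")
  sys <- conditionSystem(net, 1:6)
  expect_equal(distinctionPhi(sys, 1L, 4L, "effect")$phi, 0)
  # first-order mechanism over its successor: phi equals the direct value
  sg <- 1 / (1 + exp(-4))
  r <- distinctionPhi(sys, 1L, 2L, "effect")
  expect_equal(r$phi, sg * log2(2 * sg), tolerance = 1e-10)
})

test_that("maximal purviews pick the wired neighbours in a copy chain", {
  net <- copyChainNet()
  sys <- conditionSystem(net, 1:3)
  pe <- maximalPurview(sys, 2L, "effect")   # B's effect lands on C
  expect_identical(pe$units, 3L)
  pc <- maximalPurview(sys, 2L, "cause")    # B's cause is A
  expect_identical(pc$units, 1L)
  # a mechanism with no cause-effect power has a null purview
  w <- matrix(0, 2, 2); w[1, 1] <- 1
  netU <- logisticNetwork(w, k = 4, state = "Ab")
  sysU <- conditionSystem(netU, 1:2)
  expect_null(maximalPurview(sysU, 2L, "effect")$units)
})

test_that("symmetric purviews tie exactly and the scan is deterministic", {
  # A feeds B and C identically; the single-unit purviews {B} and {C} tie,
  # and the joint purview {B, C} dominates both (for a single-unit mechanism
  # every disintegration severs all connections, so expansion wins over
  # dilution for fully driven purview units)
  w <- matrix(0, 3, 3)
  w[1, 2] <- 1; w[1, 3] <- 1; w[2, 1] <- 0.5; w[3, 1] <- 0.5
  net <- logisticNetwork(w, k = 4, state = "Abc")
  sys <- conditionSystem(net, 1:3)
  phiB <- distinctionPhi(sys, 1L, 2L, "effect")$phi
  phiC <- distinctionPhi(sys, 1L, 3L, "effect")$phi
  expect_equal(phiB, phiC, tolerance = 1e-12)
  sg <- 1 / (1 + exp(-4))
  p1 <- maximalPurview(sys, 1L, "effect")
  p2 <- maximalPurview(sys, 1L, "effect")
  expect_identical(p1$units, p2$units)   # repeated scans agree
  expect_identical(p1$units, c(2L, 3L))
  expect_equal(p1$phi, sg^2 * 2 * log2(2 * sg), tolerance = 1e-10)
})

test_that("distinctions of the copy cycle are first-order and congruent", {
  net <- makeDirectedCycle(4, k = 4, state = "Abcd")
  sys <- conditionSystem(net, 1:4)
  res <- systemPhi(sys)
  D <- computeDistinctions(sys, res@ces)
  expect_identical(attr(D, "nCandidates"), 15L)
  expect_true(all(vapply(D, function(d) length(d@mechanism), integer(1)) == 1L))
  expect_length(D, 4L)
  # phi_d never exceeds the intrinsic information on either side
  for (d in D) {
    iiE <- mechanismIi(sys, d@mechanism, d@effectUnits, "effect")$max
    iiC <- mechanismIi(sys, d@mechanism, d@causeUnits, "cause")$max
    expect_lte(d@phiEffect, iiE + 1e-9)
    expect_lte(d@phiCause, iiC + 1e-9)
  }
})

test_that("the congruence filter excludes purview states off the system state", {
  net <- makeDirectedCycle(4, k = 4, state = "Abcd")
  sys <- conditionSystem(net, 1:4)
  res <- systemPhi(sys)
  D <- computeDistinctions(sys, res@ces)
  # swapping the system's effect state makes every distinction incongruent
  fake <- new("CauseEffectState",
              causeState = res@ces@causeState,
              effectState = (res@ces@effectState %% 16L) + 1L,
              iiCause = res@ces@iiCause, iiEffect = res@ces@iiEffect)
  Dfake <- computeDistinctions(sys, fake)
  expect_lt(length(Dfake), length(D))
})

test_that("an interacting deterministic pair supports a second-order effect", {
  # A' = A xor B, B' = not B: every disintegration perturbs the product
  net <- permutationNetwork(c(3L, 4L, 2L, 1L), 2, state = c(1L, 1L))
  sys <- conditionSystem(net, 1:2)
  r <- distinctionPhi(sys, 1:2, 1:2, "effect")
  expect_gt(r$phi, 0)
})
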