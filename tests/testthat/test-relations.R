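# Congruent overlaps, relation faces, and relation integrated information.

test_that("congruent overlap intersects unit-state tuples", {
  p1 <- substate(2L, 1L)                       # {b-}
  p2 <- substate(c(1L, 2L), c(1L, 1L))         # {a-, b-}
  p3 <- substate(c(2L, 3L), c(1L, 1L))         # {b-, c-}
  ov <- congruentOverlap(list(p1, p2, p3))
  expect_identical(ov$units, 2L)
  expect_identical(ov$states, 1L)
  # same unit in different states never overlaps
  ovBad <- congruentOverlap(list(substate(2L, 1L), substate(2L, 2L)))
  expect_length(ovBad$units, 0L)
})

test_that("random overlap sets agree with the set-algebra oracle", {
  for (seed in 1:10) {
    sets <- localSeed(seed, lapply(1:3, function(i) {
      u <- sort(sample(1:5, sample(1:4, 1)))
      substate(u, sample(1:2, length(u), replace = TRUE))
    }))
    ov <- congruentOverlap(sets)
    oracle <- oCommonOverlap(lapply(sets, function(s) oTuples(s$units, s$states)))
    expect_setequal(oTuples(ov$units, ov$states), oracle)
  }
})

test_that("face counts follow the shared-unit geometry", {
  # all four purviews share one congruent unit: all 3^2 = 9 faces exist
  d1 <- synthDistinction(cu = c(1L, 4L), cs = c(1L, 1L),
                         eu = c(1L, 5L), es = c(1L, 2L), mech = 7L)
  d2 <- synthDistinction(cu = c(1L, 6L), cs = c(1L, 2L),
                         eu = 1L, es = 1L, mech = 8L)
  expect_length(enumerateFaces(list(d1, d2)), 9L)

  # overlap only cause-to-cause: exactly one face
  d3 <- synthDistinction(cu = 1L, cs = 1L, eu = 2L, es = 1L, mech = 7L)
  d4 <- synthDistinction(cu = 1L, cs = 1L, eu = 3L, es = 1L, mech = 8L)
  expect_length(enumerateFaces(list(d3, d4)), 1L)
  expect_identical(enumerateFaces(list(d3, d4))[[1]]$selection,
                   c("cause", "cause"))

  # no congruent overlap anywhere: no faces, relation nonexistent
  d5 <- synthDistinction(cu = 1L, cs = 1L, eu = 2L, es = 1L, mech = 7L)
  d6 <- synthDistinction(cu = 3L, cs = 1L, eu = 4L, es = 1L, mech = 8L)
  expect_length(enumerateFaces(list(d5, d6)), 0L)
  expect_length(computeRelations(list(d5, d6)), 2L - 2L)
})

test_that("self-relation faces require a congruent cause-effect overlap", {
  dSelf <- synthDistinction(cu = c(1L, 2L), cs = c(1L, 1L),
                            eu = c(2L, 3L), es = c(1L, 1L), mech = 5L)
  f <- enumerateFaces(list(dSelf))
  expect_length(f, 1L)
  expect_identical(f[[1]]$units, 2L)
  dNo <- synthDistinction(cu = 1L, cs = 1L, eu = 2L, es = 1L, mech = 5L)
  expect_length(enumerateFaces(list(dNo)), 0L)
})

test_that("relation phi follows the per-unit weakest-link formula", {
  # full mutual overlap: phi_r = min phi_d
  dA <- synthDistinction(cu = 1:2, cs = c(1L, 1L), eu = 1:2, es = c(1L, 1L),
                         phi = 0.8, mech = 5L)
  dB <- synthDistinction(cu = 1:2, cs = c(1L, 1L), eu = 1:2, es = c(1L, 1L),
                         phi = 0.3, mech = 6L)
  r <- relationPhi(list(dA, dB))
  expect_equal(r$phi, 0.3, tolerance = 1e-12)

  # hand-evaluated partial overlap: dA spans {1-,2-} (cause = effect), dC
  # overlaps on unit 2 only; per-unit shares 0.8/2 and 0.6/3; joint = {2-}
  dC <- synthDistinction(cu = c(2L, 3L), cs = c(1L, 1L),
                         eu = c(3L, 4L), es = c(1L, 1L), phi = 0.6, mech = 6L)
  r2 <- relationPhi(list(dA, dC))
  expect_equal(r2$phi, min(0.8 / 2, 0.6 / 3) * 1, tolerance = 1e-12)

  # a zero-phi distinction nullifies the relation
  dZ <- synthDistinction(cu = 1:2, cs = c(1L, 1L), eu = 1:2, es = c(1L, 1L),
                         phi = 0, mech = 7L)
  expect_equal(relationPhi(list(dA, dZ))$phi, 0, tolerance = 1e-12)
  # only dA's self-relation survives: the pair and dZ's self-relation are 0
  expect_length(computeRelations(list(dA, dZ)), 1L)
})

test_that("congruent cause and effect units count as one in the divisor", {
  # cause {1-}, effect {1-}: union over tuples has a single element
  d <- synthDistinction(cu = 1L, cs = 1L, eu = 1L, es = 1L, phi = 0.5,
                        mech = 3L)
  r <- relationPhi(list(d))
  expect_equal(r$phi, 0.5, tolerance = 1e-12)   # (0.5 / 1) * 1
})

test_that("schematic effect-purview families give the published counts", {
  # effect purviews {a}, {b}, {c}, {ab}, {bc}, {abc}, all state-congruent
  eff <- list(1L, 2L, 3L, c(1L, 2L), c(2L, 3L), 1:3)
  subsets <- function(k) utils::combn(6, k, simplify = FALSE)
  nOverlap <- function(k) sum(vapply(subsets(k), function(ix) {
    ov <- congruentOverlap(lapply(eff[ix], function(u)
      substate(u, rep(1L, length(u)))))
    length(ov$units) > 0L
  }, logical(1)))
  expect_identical(nOverlap(2), 10L)
  expect_identical(nOverlap(3), 6L)
  expect_identical(nOverlap(4), 1L)

  # the same counts surface as relation degrees when causes cannot overlap
  D <- lapply(seq_along(eff), function(i)
    synthDistinction(cu = 10L + i, cs = 1L, eu = eff[[i]],
                     es = rep(1L, length(eff[[i]])), phi = 1, mech = 20L + i))
  R <- computeRelations(D)
  degs <- vapply(R, function(r) length(r@members), integer(1))
  expect_identical(sum(degs == 2L), 10L)
  expect_identical(sum(degs == 3L), 6L)
  expect_identical(sum(degs == 4L), 1L)
  expect_identical(sum(degs >= 5L), 0L)
})

test_that("pruned enumeration equals the unpruned oracle", {
  for (seed in 1:6) {
    D <- localSeed(seed, lapply(1:5, function(i) {
      cu <- sort(sample(1:4, sample(1:2, 1)))
      eu <- sort(sample(1:4, sample(1:2, 1)))
      synthDistinction(cu = cu, cs = rep(1L, length(cu)),
                       eu = eu, es = rep(1L, length(eu)),
                       phi = runif(1, 0.1, 1), mech = 10L + i)
    }))
    R <- computeRelations(D)
    O <- oRelationsUnpruned(D)
    key <- function(m) paste(m, collapse = ",")
    expect_setequal(vapply(R, function(r) key(r@members), character(1)),
                    vapply(O, function(o) key(o$members), character(1)))
    phiR <- sort(vapply(R, function(r) r@phi, numeric(1)))
    phiO <- sort(vapply(O, function(o) o$phi, numeric(1)))
    expect_equal(phiR, phiO, tolerance = 1e-10)
  }
})

test_that("phi_r never exceeds the weakest distinction", {
  for (seed in 7:9) {
    D <- localSeed(seed, lapply(1:4, function(i) {
      u <- sort(sample(1:3, sample(1:2, 1)))
      synthDistinction(cu = u, cs = rep(1L, length(u)),
                       eu = u, es = rep(1L, length(u)),
                       phi = runif(1, 0.1, 1), mech = 10L + i)
    }))
    for (r in computeRelations(D)) {
      expect_lte(r@phi,
                 min(vapply(D[r@members], function(d) d@phi, numeric(1))) + 1e-12)
    }
  }
})

test_that("the all-congruent closed-form count matches the enumeration", {
  # every purview is the same congruent substate: all subsets are related
  for (nD in 2:5) {
    D <- lapply(seq_len(nD), function(i)
      synthDistinction(cu = 1L, cs = 1L, eu = 1L, es = 1L, phi = 0.5,
                       mech = i + 10L))
    R <- computeRelations(D)
    expect_length(R, allCongruentRelationCount(nD))
  }
  expect_equal(maxRelationCount(2), 2^3 - 1)
  expect_equal(maxRelationCount(6), 2^63 - 1)
})

test_that("the relation enumeration cap raises a capacity error", {
  D <- lapply(1:25, function(i)
    synthDistinction(cu = 1L, cs = 1L, eu = 1L, es = 1L, mech = i + 30L))
  expect_error(computeRelations(D), "cap")
})
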