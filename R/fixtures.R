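# Fixture generators: the example network families (directed cycle, modular
# pairs, bottleneck, specialized lattice, feed-forward counter) and seeded
# random logistic networks for property testing. All weight matrices obey
# the column-normalization constraint of the logistic builder; families whose
# published weights appear only in figure diagrams are parameterized and
# carry no claims about the figures' printed phi values.

#' Directed cycle of logistic units
#'
#' Unit \eqn{i} receives weight 1.0 from unit \eqn{i - 1} (mod n): each unit
#' copies its predecessor with determinism set by \code{k}.
#'
#' @param n number of units (>= 2).
#' @param k logistic slope.
#' @param state state specification; default: first unit ON, rest OFF.
#' @return a [Network-class].
#' @examples
#' net <- makeDirectedCycle(6, k = 4)   # the "Abcdef" copy cycle
#' @export
makeDirectedCycle <- function(n = 6L, k = 4, state = NULL) {
  n <- as.integer(n)
  stopifnot(n >= 2L)
  w <- matrix(0, n, n)
  for (i in seq_len(n)) w[if (i == 1L) n else i - 1L, i] <- 1
  if (is.null(state)) state <- c(2L, rep(1L, n - 1L))
  logisticNetwork(w, k = k, state = state)
}

#' Modular network of strongly coupled pairs
#'
#' \code{nPairs} two-unit modules with strong reciprocal intra-module
#' weights and weak directed inter-module links arranged in a ring of
#' modules (fault lines between the modules). With \code{wInter = 0} the
#' modules are fully disconnected.
#'
#' @param nPairs number of two-unit modules.
#' @param k logistic slope.
#' @param wInter weight of the inter-module link (subtracted from the
#'   intra-module weight so columns still sum to 1).
#' @param state state specification; default: first unit ON, rest OFF.
#' @return a [Network-class].
#' @export
makeModularPairs <- function(nPairs = 3L, k = 4, wInter = 0.1, state = NULL) {
  nPairs <- as.integer(nPairs)
  stopifnot(nPairs >= 1L, wInter >= 0, wInter < 1)
  n <- 2L * nPairs
  w <- matrix(0, n, n)
  for (p in seq_len(nPairs)) {
    a <- 2L * p - 1L; b <- 2L * p
    w[b, a] <- 1 - wInter            # a listens mostly to its partner
    w[a, b] <- 1                     # b listens only to its partner
    if (wInter > 0) {
      prevB <- 2L * ((p - 2L) %% nPairs + 1L)  # second unit of prev module
      w[prevB, a] <- w[prevB, a] + wInter
    }
  }
  if (is.null(state)) state <- c(2L, rep(1L, n - 1L))
  logisticNetwork(w, k = k, state = state)
}

#' Bottleneck (degenerate) network
#'
#' Unit A receives equal weights from all other units and feeds every other
#' unit with weight 1: a hub with redundant inputs and outputs, high
#' degeneracy.
#'
#' @param n number of units.
#' @param k logistic slope.
#' @param state state specification; default: A ON, rest OFF.
#' @return a [Network-class].
#' @export
makeBottleneck <- function(n = 6L, k = 4, state = NULL) {
  n <- as.integer(n)
  stopifnot(n >= 2L)
  w <- matrix(0, n, n)
  w[2:n, 1] <- 1 / (n - 1)
  w[1, 2:n] <- 1
  if (is.null(state)) state <- c(2L, rep(1L, n - 1L))
  logisticNetwork(w, k = k, state = state)
}

#' Specialized lattice network
#'
#' Heterogeneously connected units with partially overlapping inputs and
#' outputs: each unit draws weights from a seeded random sparse pattern over
#' its neighbourhood, column-normalized. This reproduces the topology class
#' of the published lattice examples with parameterized weights.
#'
#' @param n number of units.
#' @param k logistic slope.
#' @param seed integer seed (the family is deterministic given the seed).
#' @param state state specification; default: first unit ON, rest OFF.
#' @return a [Network-class].
#' @export
makeSpecializedLattice <- function(n = 6L, k = 4, seed = 1L, state = NULL) {
  n <- as.integer(n)
  stopifnot(n >= 2L)
  w <- withr_seed(seed, {
    w <- matrix(0, n, n)
    for (i in seq_len(n)) {
      # neighbourhood: previous two and next unit on a ring, plus self
      nb <- unique(c((i - 2L - 1L) %% n + 1L, (i - 1L - 1L) %% n + 1L,
                     i %% n + 1L, i))
      raw <- stats::runif(length(nb), 0.2, 1)
      w[nb, i] <- raw / sum(raw)
    }
    w
  })
  if (is.null(state)) state <- c(2L, rep(1L, n - 1L))
  logisticNetwork(w, k = k, state = state)
}

# evaluate expr under a local RNG seed without disturbing the global stream
#' @noRd
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Deterministic feed-forward counter
#'
#' Three deterministic binary units with only feed-forward cross-connections
#' from A to B and C (\eqn{A' = A \oplus I}, \eqn{B' = B \oplus A},
#' \eqn{C' = C \oplus A}, with \eqn{\oplus} on \eqn{\{-1,+1\}} as negated sign
#' product), driven by an input unit I that holds its own state and acts as
#' a frozen background condition. The three-unit system is not strongly
#' connected, hence reducible (\eqn{\varphi_s = 0}); each unit alone is a
#' deterministic self-conditioned complex, so the triad condenses into three
#' single-unit complexes.
#'
#' @param input state of the input unit I: \code{1} (counting) or \code{-1}.
#' @param state state specification for A, B, C; default \code{"Abc"}.
#' @return a 4-unit [Network-class] with units A, B, C, I; analyse members
#'   \code{c("A", "B", "C")} with I as background.
#' @export
makeFeedforwardCounter <- function(input = 1, state = NULL) {
  units <- c("A", "B", "C", "I")
  sizes <- rep(2L, 4L)
  st <- stateTable(sizes)
  sgn <- (st == 2L) * 2 - 1          # {-1, +1} values
  # xor on {-1,+1} is the negated product: -x*y is +1 iff exactly one is ON
  nxt <- cbind(A = -sgn[, 1] * sgn[, 4],  # A' = A xor I (toggles while I ON)
               B = -sgn[, 2] * sgn[, 1],  # B' = B xor A
               C = -sgn[, 3] * sgn[, 1],  # C' = C xor A
               I = sgn[, 4])              # I holds
  factors <- lapply(1:4, function(i) {
    on <- as.numeric(nxt[, i] > 0)
    cbind(1 - on, on)
  })
  tpmFull <- expandRows(factors)
  if (is.null(state)) state <- c(2L, 1L, 1L, if (input > 0) 2L else 1L)
  else state <- c(parseStateSpec(state, units[1:3],
                                 rep(list(c("-1", "1")), 3)),
                  if (input > 0) 2L else 1L)
  Network(tpmFull, units = units, state = state)
}

#' Five-unit excitatory/inhibitory motif
#'
#' Binary logistic units on a ring with a strong excitatory connection from
#' each unit's predecessor and a weaker inhibitory connection from the unit
#' two steps ahead, so each incoming-weight column still sums to 1. This
#' reproduces the topology class of mixed excitatory/inhibitory example
#' networks with parameterized weights; it carries no claims about any
#' published phi values, which depend on diagram-only weight settings.
#'
#' @param k logistic slope.
#' @param wInhib magnitude of the inhibitory weight (the excitatory weight
#'   is \code{1 + wInhib}).
#' @param state state specification; default \code{"ABcdE"}.
#' @return a 5-unit [Network-class].
#' @export
makeExcitatoryInhibitory <- function(k = 4, wInhib = 0.4, state = NULL) {
  stopifnot(wInhib >= 0, wInhib < 1)
  n <- 5L
  w <- matrix(0, n, n)
  for (i in seq_len(n)) {
    prev <- if (i == 1L) n else i - 1L
    ahead <- (i + 1L) %% n + 1L
    w[prev, i] <- 1 + wInhib
    w[ahead, i] <- -wInhib
  }
  if (is.null(state)) state <- c(2L, 2L, 1L, 1L, 2L)
  logisticNetwork(w, k = k, state = state)
}

#' Random column-normalized logistic network
#'
#' Seeded random weights: each unit receives inputs from a random non-empty
#' subset of units (density controlled by \code{sparsity}), with positive
#' weights normalized to sum 1. Identical (n, k, seed, sparsity) yield a
#' bit-identical network.
#'
#' @param n number of units.
#' @param k logistic slope.
#' @param seed integer seed.
#' @param sparsity probability that a potential connection is absent.
#' @param state state specification; default: all OFF.
#' @return a [Network-class].
#' @export
makeRandomLogistic <- function(n, k = 4, seed = 1L, sparsity = 0.3,
                               state = NULL) {
  n <- as.integer(n)
  stopifnot(n >= 1L)
  w <- withr_seed(seed, {
    w <- matrix(stats::runif(n * n), n, n)
    w[stats::runif(n * n) < sparsity] <- 0
    for (i in seq_len(n)) {
      if (sum(w[, i]) == 0) w[sample.int(n, 1L), i] <- 1
      w[, i] <- w[, i] / sum(w[, i])
    }
    w
  })
  if (is.null(state)) state <- rep(1L, n)
  logisticNetwork(w, k = k, state = state)
}

#' Random feed-forward (DAG) logistic network
#'
#' Like [makeRandomLogistic()] but connections only run from lower-index to
#' strictly higher-index units, so the interaction digraph is acyclic and the
#' full system is reducible (\eqn{\varphi_s = 0}). Source units without
#' inputs are unconstrained coin-flip units.
#'
#' @inheritParams makeRandomLogistic
#' @return a [Network-class].
#' @export
makeRandomFeedforward <- function(n, k = 4, seed = 1L, sparsity = 0.3,
                                  state = NULL) {
  n <- as.integer(n)
  stopifnot(n >= 2L)
  w <- withr_seed(seed, {
    w <- matrix(0, n, n)
    for (i in 2:n) {
      src <- seq_len(i - 1L)
      raw <- stats::runif(length(src))
      raw[stats::runif(length(src)) < sparsity] <- 0
      if (sum(raw) == 0) raw[sample.int(length(src), 1L)] <- 1
      w[src, i] <- raw / sum(raw)
    }
    w
  })
  if (is.null(state)) state <- rep(1L, n)
  logisticNetwork(w, k = k, state = state)
}
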