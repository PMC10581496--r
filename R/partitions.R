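# Directional system partitions, partitioned TPMs, and system integrated
# information phi_s over the normalized minimum partition.
#
# A partition divides the system into k >= 2 parts, each labeled with a
# direction: inputs cut ("input"), outputs cut ("output"), or both ("both").
# The induced cut is summarized per part by the set X^(i) of units whose
# inputs to that part are severed; severed connections are causally
# marginalized (replaced by independent noise). Distinct labelings inducing
# the same cut-set are deduplicated, since phi depends on the cut-set only.
# The normalization sum_i |S^(i)| |X^(i)| is the maximal number of pairwise
# interactions a partition can affect, i.e. the largest value phi_s(theta)
# could take over arbitrary TPMs.

# all set partitions of 1..n into >= minBlocks non-empty blocks,
# in a canonical (restricted-growth) order
#' @noRd
setPartitionsInt <- function(n, minBlocks = 1L) {
  out <- list()
  rec <- function(i, blocks) {
    if (i > n) {
      if (length(blocks) >= minBlocks) out[[length(out) + 1L]] <<- blocks
      return(invisible(NULL))
    }
    for (b in seq_along(blocks)) {
      nb <- blocks
      nb[[b]] <- c(nb[[b]], i)
      rec(i + 1L, nb)
    }
    rec(i + 1L, c(blocks, list(i)))
  }
  rec(2L, list(1L))
  if (n == 0L) return(list())
  out
}

#' Enumerate directional system partitions
#'
#' All set partitions of the member units into \eqn{k \ge 2} parts, combined
#' with all per-part direction labels (inputs / outputs / both cut), reduced
#' to distinct induced cut-sets. For a single-unit system the partition set
#' is the single complete noising of the unit's own input.
#'
#' @param n number of member units (or a [ConditionedSystem-class]).
#' @param dedupe collapse direction labelings that induce the same cut-set
#'   (default TRUE; with FALSE all raw labelings are returned, e.g. 9 for two
#'   units, 54 for three).
#' @return list of partitions; each has \code{parts} (list of local unit
#'   index vectors), \code{dirs} (direction per part), \code{X} (per part,
#'   the units whose inputs to the part are severed), \code{norm}
#'   (\eqn{\sum_i |S^{(i)}||X^{(i)}|}), and \code{cut} (logical matrix,
#'   \code{cut[x, u]} = input from x to u severed).
#' @export
systemPartitions <- function(n, dedupe = TRUE) {
  if (is(n, "ConditionedSystem")) n <- length(n@members)
  n <- as.integer(n)
  if (n < 1L) stop("a partition needs at least one unit")
  if (n == 1L) {
    cut <- matrix(TRUE, 1L, 1L)
    return(list(list(parts = list(1L), dirs = "both", X = list(1L),
                     norm = 1, cut = cut)))
  }
  dirLabels <- c("input", "output", "both")
  base <- setPartitionsInt(n, minBlocks = 2L)
  out <- list()
  seen <- new.env(parent = emptyenv())
  for (blocks in base) {
    k <- length(blocks)
    dirGrid <- as.matrix(expand.grid(rep(list(1:3), k)))
    for (r in seq_len(nrow(dirGrid))) {
      dirs <- dirLabels[dirGrid[r, ]]
      X <- vector("list", k)
      for (i in seq_len(k)) {
        if (dirs[i] %in% c("input", "both")) {
          X[[i]] <- sort(setdiff(seq_len(n), blocks[[i]]))
        } else {
          src <- integer(0)
          for (j in seq_len(k)) {
            if (j != i && dirs[j] %in% c("output", "both"))
              src <- c(src, blocks[[j]])
          }
          X[[i]] <- sort(src)
        }
      }
      cut <- matrix(FALSE, n, n)
      for (i in seq_len(k)) {
        if (length(X[[i]])) cut[X[[i]], blocks[[i]]] <- TRUE
      }
      p <- list(parts = blocks, dirs = dirs, X = X,
                norm = sum(cut), cut = cut)
      if (dedupe) {
        key <- paste(which(cut), collapse = ",")
        if (!is.null(seen[[key]])) next
        seen[[key]] <- TRUE
      }
      out[[length(out) + 1L]] <- p
    }
  }
  out
}

#' Partitioned transition probability matrix
#'
#' Recomputes the per-unit conditional probabilities with the inputs severed
#' by a partition causally marginalized (uniform over the cut sources'
#' states, intact inputs held at their actual state), then recombines the
#' units by product.
#'
#' @param sys a [ConditionedSystem-class].
#' @param partition a partition as returned by [systemPartitions()].
#' @param side \code{"effect"} or \code{"cause"}.
#' @return the partitioned TPM (same shape as [effectTpm()] / [causeTpm()]).
#' @export
partitionedTpm <- function(sys, partition, side = c("effect", "cause")) {
  side <- match.arg(side)
  s <- if (side == "effect") "e" else "c"
  ns <- length(sys@members)
  full <- bitwShiftL(1L, ns) - 1L
  mats <- vector("list", ns)
  for (i in seq_along(partition$parts)) {
    keepMask <- bitwAnd(full, bitwNot(maskOf(partition$X[[i]])))
    g <- groupOf(sys, keepMask)
    for (j in partition$parts[[i]]) {
      M <- margDist(sys, s, j, keepMask)
      mats[[j]] <- M[g, , drop = FALSE]
    }
  }
  expandRows(mats)
}

#' Directional integrated information for a given partition
#'
#' Effect side (cause analogous): \eqn{\varphi_e(\theta) =
#' p_e(s'_e \mid s)\,|\log_2(p_e(s'_e \mid s) / p_e^\theta(s'_e \mid s))|^+},
#' the selectivity-weighted positive part of the probability loss the
#' partition inflicts on the maximal state.
#'
#' @param sys a [ConditionedSystem-class].
#' @param partition a partition from [systemPartitions()].
#' @param side \code{"effect"} or \code{"cause"}.
#' @param stateIdx index of the maximal state on that side.
#' @return phi in ibits (non-negative).
#' @export
phiDirectional <- function(sys, partition, side = c("effect", "cause"),
                           stateIdx) {
  side <- match.arg(side)
  ns <- length(sys@members)
  sizes <- sys@cache$sizes
  full <- bitwShiftL(1L, ns) - 1L
  sIdx <- stateToIndex(sys@state, sizes)
  prime <- indexToState(stateIdx, sizes)
  if (side == "effect") {
    sel <- sys@Te[sIdx, stateIdx]
    if (sel <= 0) return(0)
    intact <- sel
    condState <- sys@state      # conditioning states: current
    targetState <- prime        # target: effect state per unit
  } else {
    col <- causeTpm(sys)[, sIdx]
    tot <- sum(col)
    if (tot <= 0) stop("unreachable current state")
    sel <- col[stateIdx] / tot
    intact <- col[stateIdx]
    if (intact <= 0) return(0)
    condState <- prime          # conditioning states: prior (cause) state
    targetState <- sys@state    # target: current state per unit
  }
  sflag <- if (side == "effect") "e" else "c"
  ptheta <- 1
  for (i in seq_along(partition$parts)) {
    keepMask <- bitwAnd(full, bitwNot(maskOf(partition$X[[i]])))
    row <- subIndex(sys, condState, keepMask)
    for (j in partition$parts[[i]]) {
      ptheta <- ptheta * margDist(sys, sflag, j, keepMask)[row, targetState[j]]
    }
  }
  if (ptheta <= 0) return(Inf)   # intact > 0 but partition forbids the state
  sel * max(0, log2(intact / ptheta))
}

#' System integrated information over the minimum partition
#'
#' Computes the maximal cause-effect state, evaluates
#' \eqn{\varphi_s(\theta) = \min(\varphi_c(\theta), \varphi_e(\theta))} for
#' every distinct directional partition, and selects the minimum partition
#' (MIP) as the minimizer of \eqn{\varphi_s(\theta)} relative to its maximal
#' attainable value \eqn{\sum_i |S^{(i)}||X^{(i)}|}. Ties on the normalized
#' value resolve to the largest unnormalized \eqn{\varphi_s}; residual ties
#' to the first partition in canonical enumeration order. The returned phi is
#' the unnormalized value at the MIP (the absolute loss of intrinsic
#' information).
#'
#' @param x a [ConditionedSystem-class], or a [Network-class] (with
#'   \code{members}).
#' @param members when \code{x} is a network: unit names/indices of the
#'   candidate system (default: all units).
#' @return a [SystemPhiResult-class].
#' @examples
#' net <- makeDirectedCycle(6, k = 4, state = "Abcdef")
#' res <- systemPhi(net)
#' phiValue(res)   # 1.7465 ibits
#' @export
systemPhi <- function(x, members = NULL) {
  sys <- if (is(x, "ConditionedSystem")) x else
    conditionSystem(x, if (is.null(members)) seq_along(x@units) else members)
  ns <- length(sys@members)
  if (ns > maxUnitsCap())
    stop(sprintf("system has %d units; exhaustive partition search is capped at %d (option phistruct.maxUnits)",
                 ns, maxUnitsCap()))
  tol <- phiTol()
  ces <- maximalCauseEffectState(sys)
  zero <- function(reducible) methods::new(
    "SystemPhiResult", phi = 0, phiCause = 0, phiEffect = 0,
    normalized = 0, mip = list(), ces = ces,
    members = sys@members, state = sys@state,
    nPartitions = 0L, reducible = reducible)
  if (is.na(ces@causeState) || is.na(ces@effectState)) return(zero(TRUE))
  parts <- systemPartitions(ns)
  best <- NULL; bestR <- Inf; bestPhi <- -Inf; bestC <- 0; bestE <- 0
  for (p in parts) {
    pc <- phiDirectional(sys, p, "cause", ces@causeState)
    pe <- phiDirectional(sys, p, "effect", ces@effectState)
    ph <- min(pc, pe)
    r <- ph / p$norm
    if (r < bestR - tol || (abs(r - bestR) <= tol && ph > bestPhi + tol)) {
      bestR <- r; bestPhi <- ph; best <- p; bestC <- pc; bestE <- pe
    }
    if (ph <= 0) { bestR <- 0; bestPhi <- 0; best <- p
                   bestC <- pc; bestE <- pe; break }
  }
  methods::new("SystemPhiResult",
               phi = bestPhi, phiCause = bestC, phiEffect = bestE,
               normalized = bestR, mip = best, ces = ces,
               members = sys@members, state = sys@state,
               nPartitions = length(parts),
               reducible = bestPhi <= tol)
}

#' @rdname phistruct-generics
#' @export
setMethod("phiValue", "SystemPhiResult", function(x) x@phi)

#' @rdname phistruct-generics
#' @export
setMethod("members", "SystemPhiResult", function(x) x@members)

setMethod("show", "SystemPhiResult", function(object) {
  cat(sprintf("System phi: %.6g ibits (phi_c = %.6g, phi_e = %.6g)\n",
              object@phi, object@phiCause, object@phiEffect))
  cat(sprintf("  reducible: %s; partitions evaluated: %d\n",
              object@reducible, object@nPartitions))
  if (length(object@mip)) {
    lab <- vapply(seq_along(object@mip$parts), function(i)
      sprintf("{%s}%s", paste(object@mip$parts[[i]], collapse = ","),
              switch(object@mip$dirs[i], input = "<-",
                     output = "->", both = "<->")),
      character(1))
    cat(sprintf("  MIP: %s (normalization %d)\n",
                paste(lab, collapse = " / "), object@mip$norm))
  }
  invisible(object)
})
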