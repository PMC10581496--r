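# Mechanism-level analysis: repertoires over purviews, intrinsic
# information, disintegrating partitions, integrated information phi_d,
# maximal purviews, and the congruence-filtered set of causal distinctions.
#
# All probabilities are product probabilities over individual units: other
# system units are causally marginalized (uniform interventional
# distribution), which keeps the units conditionally independent and
# discounts correlations that are not due to the mechanism itself.

#' @noRd
resolveMemberUnits <- function(sys, units) {
  if (is.character(units)) {
    g <- match(units, sys@network@units)
    if (anyNA(g)) stop("unknown unit name")
  } else g <- as.integer(units)
  loc <- match(g, sys@members)
  if (anyNA(loc)) stop("units must be members of the system")
  sort(loc)
}

#' Effect repertoire of a mechanism over a purview
#'
#' Per-unit effect probabilities \eqn{p_e(z_i \mid m)} obtained by causally
#' marginalizing the non-mechanism units uniformly, combined as a product
#' over the purview units. Also returns the unconstrained repertoire
#' \eqn{\pi_e(z; M)} (average over all mechanism states).
#'
#' @param sys a [ConditionedSystem-class].
#' @param mechanism member units of the mechanism \eqn{M} (names or network
#'   indices).
#' @param purview member units of the purview \eqn{Z} (non-empty).
#' @param mechanismState optional state indices for \eqn{m} (default: the
#'   system state restricted to the mechanism).
#' @return list with \code{purview} (local unit indices), \code{table}
#'   (\eqn{\pi_e(z \mid m)} over purview states, little-endian),
#'   \code{unconstrained} (\eqn{\pi_e(z; M)}), and \code{factors}.
#' @export
effectRepertoire <- function(sys, mechanism, purview, mechanismState = NULL) {
  Z <- resolveMemberUnits(sys, purview)
  if (length(Z) == 0L) stop("purview must be non-empty")
  M <- if (length(mechanism)) resolveMemberUnits(sys, mechanism) else integer(0)
  m <- if (is.null(mechanismState)) sys@state[M] else as.integer(mechanismState)
  maskM <- maskOf(M)
  sizes <- sys@cache$sizes
  mats <- lapply(Z, function(j) margDist(sys, "e", j, maskM))
  Tm <- expandRows(mats)                  # |Omega_M| x |Omega_Z|
  mIdx <- stateToIndex(m, sizes[M])
  list(purview = Z, mechanism = M, mechanismState = m,
       table = Tm[mIdx, ],
       unconstrained = colMeans(Tm),
       factors = lapply(mats, function(x) x[mIdx, ]))
}

#' Cause repertoire of a mechanism over a purview
#'
#' Per-unit cause probabilities \eqn{p_c(m_i \mid z)} (non-purview prior
#' units causally marginalized uniformly) combined as a product over the
#' mechanism units, as a function of the purview state \eqn{z}; the backward
#' table is obtained by Bayes' rule over the product distribution with a
#' uniform prior over purview states. A mechanism state that is impossible
#' under every purview state has an undefined backward table and is flagged
#' \code{causeless}.
#'
#' @inheritParams effectRepertoire
#' @return list with \code{table} (\eqn{\pi_c(m \mid z)} over purview
#'   states), \code{backward} (\eqn{\pi_{c\leftarrow}(z \mid m)}),
#'   \code{unconstrained} (\eqn{\pi_c(m; Z)}, scalar), and \code{causeless}.
#' @export
causeRepertoire <- function(sys, mechanism, purview, mechanismState = NULL) {
  Z <- resolveMemberUnits(sys, purview)
  if (length(Z) == 0L) stop("purview must be non-empty")
  M <- resolveMemberUnits(sys, mechanism)
  if (length(M) == 0L) stop("mechanism must be non-empty on the cause side")
  m <- if (is.null(mechanismState)) sys@state[M] else as.integer(mechanismState)
  maskZ <- maskOf(Z)
  tab <- rep(1, prod(sys@cache$sizes[Z]))
  for (k in seq_along(M)) {
    Mk <- margDist(sys, "c", M[k], maskZ)
    tab <- tab * Mk[, m[k]]
  }
  tot <- sum(tab)
  list(purview = Z, mechanism = M, mechanismState = m,
       table = tab,
       backward = if (tot > 0) tab / tot else rep(NA_real_, length(tab)),
       unconstrained = mean(tab),
       causeless = tot <= 0)
}

#' Intrinsic information of a mechanism over a purview
#'
#' Effect side: \eqn{ii_e(m, z) = \pi_e(z \mid m)\,\log_2(\pi_e(z \mid m) /
#' \pi_e(z; M))}; cause side: \eqn{ii_c(m, z) = \pi_{c\leftarrow}(z \mid m)\,
#' \log_2(\pi_c(m \mid z) / \pi_c(m; Z))}. Returns the ii values over all
#' purview states and the maximal state(s).
#'
#' @inheritParams effectRepertoire
#' @param side \code{"effect"} or \code{"cause"}.
#' @return list with \code{ii} (vector over purview states), \code{max},
#'   \code{states} (indices tied for the maximum, within tolerance).
#' @export
mechanismIi <- function(sys, mechanism, purview,
                        side = c("effect", "cause"), mechanismState = NULL) {
  side <- match.arg(side)
  tol <- phiTol()
  if (side == "effect") {
    rep_ <- effectRepertoire(sys, mechanism, purview, mechanismState)
    p <- rep_$table; unc <- rep_$unconstrained
    ii <- numeric(length(p))
    pos <- p > 0
    ii[pos] <- p[pos] * log2(p[pos] / unc[pos])
  } else {
    rep_ <- causeRepertoire(sys, mechanism, purview, mechanismState)
    if (rep_$causeless) {
      return(list(ii = rep(0, length(rep_$table)), max = 0,
                  states = integer(0), repertoire = rep_))
    }
    p <- rep_$table; unc <- rep_$unconstrained
    ii <- numeric(length(p))
    pos <- p > 0
    ii[pos] <- rep_$backward[pos] * log2(p[pos] / unc)
  }
  top <- max(ii)
  states <- if (top > tol) which(ii >= top - tol) else integer(0)
  list(ii = ii, max = max(top, 0), states = states, repertoire = rep_)
}

# --- disintegrating partitions --------------------------------------------

# Visit every disintegrating partition of (M, Z): sets of pairs
# {(M^(i), Z^(i))} where the non-empty M parts partition M, the non-empty
# Z parts partition Z, parts may be empty, at least two pairs exist, and no
# pair has M^(i) = M with a non-empty purview part. `fun(pairs)` is called
# per partition and returns FALSE to stop early.
#' @noRd
forEachDisintegration <- function(M, Z, fun, collapseTrivial = FALSE) {
  pm <- setPartitionsInt(length(M), 1L)
  pz <- setPartitionsInt(length(Z), 1L)
  # visit coarse partitions first: zeros (reducibility) are typically proven
  # by 2-block cuts, allowing early termination before the combinatorial bulk
  combos <- expand.grid(i = seq_along(pm), j = seq_along(pz))
  p <- lengths(pm)[combos$i]; q <- lengths(pz)[combos$j]
  combos <- combos[order(p + q, pmax(p, q)), , drop = FALSE]
  for (r in seq_len(nrow(combos))) {
    PM <- pm[[combos$i[r]]]
    PZ <- pz[[combos$j[r]]]
    # with the mechanism in a single (whole) block, every refinement of Z
    # yields the same fully-severed probability and normalization: visit the
    # single-block form only, when the caller just minimizes over phi
    if (collapseTrivial && length(PM) == 1L && length(PZ) > 1L) next
    blocksM <- lapply(PM, function(b) M[b])
    blocksZ <- lapply(PZ, function(b) Z[b])
    cont <- visitMatchings(blocksM, blocksZ, length(PM) == 1L, fun)
    if (!cont) return(invisible(FALSE))
  }
  invisible(TRUE)
}

#' @noRd
visitMatchings <- function(blocksM, blocksZ, mechWhole, fun) {
  p <- length(blocksM); q <- length(blocksZ)
  usedZ <- logical(q)
  rec <- function(i, pairs) {
    if (i > p) {
      for (zb in which(!usedZ))
        pairs[[length(pairs) + 1L]] <- list(integer(0), blocksZ[[zb]])
      return(fun(pairs))
    }
    # the M-block stays unmatched (empty purview part)
    if (!rec(i + 1L, c(pairs, list(list(blocksM[[i]], integer(0))))))
      return(FALSE)
    # or takes one unused Z-block -- forbidden when the block is all of M
    if (!mechWhole) {
      for (zb in which(!usedZ)) {
        usedZ[zb] <<- TRUE
        ok <- rec(i + 1L, c(pairs, list(list(blocksM[[i]], blocksZ[[zb]]))))
        usedZ[zb] <<- FALSE
        if (!ok) return(FALSE)
      }
    }
    TRUE
  }
  rec(1L, list())
}

#' Enumerate the disintegrating partitions of a mechanism-purview pair
#'
#' All partitions \eqn{\{(M^{(i)}, Z^{(i)})\}} with parts drawn from the
#' power sets of \eqn{M} and \eqn{Z} (possibly empty), the non-empty parts
#' partitioning \eqn{M} and \eqn{Z}, at least two pairs, and no pair pairing
#' the whole mechanism with a non-empty purview part. For \eqn{|M| = 1}
#' every disintegration severs all mechanism-purview connections.
#'
#' @param mechanism,purview integer vectors (disjoint identities are not
#'   required; they are treated as labels).
#' @return list of partitions; each partition is a list of pairs
#'   \code{list(M_i, Z_i)}.
#' @export
mechanismPartitions <- function(mechanism, purview) {
  out <- list()
  forEachDisintegration(as.integer(mechanism), as.integer(purview),
                        function(pairs) {
                          out[[length(out) + 1L]] <<- pairs
                          TRUE
                        })
  out
}

# --- integrated information of a mechanism over a purview -----------------

# phi for mechanism m over purview Z at purview state zprime, minimized over
# disintegrating partitions relative to the number of severed
# mechanism-purview unit pairs |M||Z| - sum_i |M_i||Z_i|. Exact early
# termination at phi(theta) = 0.
#' @noRd
phiMechanismSide <- function(sys, M, m, Z, zprime, side) {
  tol <- phiTol()
  sizes <- sys@cache$sizes
  if (side == "effect") {
    sel <- 1
    for (k in seq_along(Z)) {
      sel <- sel * margDist(sys, "e", Z[k], maskOf(M))[
        stateToIndex(m, sizes[M]), zprime[k]]
    }
    intact <- sel
  } else {
    crep <- causeRepertoire(sys, sys@members[M], sys@members[Z], m)
    if (crep$causeless) return(list(phi = 0, mip = NULL, selectivity = 0))
    zIdx <- stateToIndex(zprime, sizes[Z])
    intact <- crep$table[zIdx]
    sel <- crep$backward[zIdx]
    if (intact <= 0) return(list(phi = 0, mip = NULL, selectivity = sel))
  }
  if (sel <= 0) return(list(phi = 0, mip = NULL, selectivity = sel))

  sflag <- if (side == "effect") "e" else "c"
  memo <- new.env(parent = emptyenv())
  # partitioned factor of target unit j conditioned on a sub-part
  getVal <- function(condUnits, j) {
    cm <- maskOf(condUnits)
    key <- paste0(cm, ".", j)
    v <- memo[[key]]
    if (!is.null(v)) return(v)
    if (side == "effect") {
      row <- stateToIndex(m[match(condUnits, M)], sizes[condUnits])
      v <- margDist(sys, "e", j, cm)[row, zprime[match(j, Z)]]
    } else {
      row <- stateToIndex(zprime[match(condUnits, Z)], sizes[condUnits])
      v <- margDist(sys, "c", j, cm)[row, m[match(j, M)]]
    }
    memo[[key]] <- v
    v
  }
  nMZ <- length(M) * length(Z)
  best <- new.env(parent = emptyenv())
  best$r <- Inf; best$phi <- -Inf; best$mip <- NULL
  forEachDisintegration(M, Z, function(pairs) {
    ptheta <- 1
    kept <- 0L
    for (pr in pairs) {
      Mi <- pr[[1L]]; Zi <- pr[[2L]]
      kept <- kept + length(Mi) * length(Zi)
      targets <- if (side == "effect") Zi else Mi
      conds <- if (side == "effect") Mi else Zi
      for (j in targets) ptheta <- ptheta * getVal(conds, j)
    }
    norm <- nMZ - kept
    ph <- if (ptheta <= 0) Inf else sel * max(0, log2(intact / ptheta))
    r <- ph / norm
    if (r < best$r - tol ||
        (abs(r - best$r) <= tol && ph > best$phi + tol)) {
      best$r <- r; best$phi <- ph; best$mip <- pairs
    }
    ph > 0   # FALSE stops the enumeration: reducible
  }, collapseTrivial = TRUE)
  list(phi = if (best$phi <= tol) 0 else best$phi,
       mip = best$mip, selectivity = sel)
}

#' Integrated information of a mechanism over a given purview
#'
#' Determines the maximal purview state by intrinsic information, then
#' minimizes the selectivity-weighted positive log-ratio of intact versus
#' partitioned product probability over all disintegrating partitions,
#' normalized by the number of severed mechanism-purview connections. State
#' ties resolve to the state with maximal phi, then the smallest state index.
#'
#' @inheritParams mechanismIi
#' @return list with \code{phi} (ibits), \code{state} (purview state
#'   indices), \code{stateIdx}, \code{ii}, and \code{mip}.
#' @export
distinctionPhi <- function(sys, mechanism, purview,
                           side = c("effect", "cause"),
                           mechanismState = NULL) {
  side <- match.arg(side)
  M <- resolveMemberUnits(sys, mechanism)
  Z <- resolveMemberUnits(sys, purview)
  m <- if (is.null(mechanismState)) sys@state[M] else as.integer(mechanismState)
  sizes <- sys@cache$sizes
  ii <- mechanismIi(sys, sys@members[M], sys@members[Z], side, m)
  if (length(ii$states) == 0L)
    return(list(phi = 0, state = NULL, stateIdx = NA_integer_,
                ii = 0, mip = NULL))
  tol <- phiTol()
  bestPhi <- -Inf; bestState <- NA_integer_; bestMip <- NULL
  for (stIdx in ii$states) {
    zprime <- indexToState(stIdx, sizes[Z])
    r <- phiMechanismSide(sys, M, m, Z, zprime, side)
    if (r$phi > bestPhi + tol) {
      bestPhi <- r$phi; bestState <- stIdx; bestMip <- r$mip
    }
  }
  list(phi = max(bestPhi, 0),
       state = indexToState(bestState, sizes[Z]),
       stateIdx = as.integer(bestState),
       ii = ii$max, mip = bestMip)
}

#' Maximally irreducible purview of a mechanism
#'
#' Scans every non-empty purview \eqn{Z \subseteq S} and returns the purview
#' (with its maximal state) attaining the maximum integrated information.
#' Ties resolve to the larger purview, then the lexicographically smallest
#' unit set.
#'
#' @inheritParams mechanismIi
#' @return list with \code{units} (network unit indices, or \code{NULL} when
#'   every purview has phi = 0), \code{states}, \code{phi}, \code{mip}.
#' @export
maximalPurview <- function(sys, mechanism, side = c("effect", "cause"),
                           mechanismState = NULL) {
  side <- match.arg(side)
  M <- resolveMemberUnits(sys, mechanism)
  ns <- length(sys@members)
  tol <- phiTol()
  best <- list(units = NULL, states = NULL, phi = 0, mip = NULL)
  bestLocal <- NULL
  for (mask in seq_len(2^ns - 1L)) {
    Z <- bitsOf(mask, ns)
    r <- distinctionPhi(sys, sys@members[M], sys@members[Z], side,
                        mechanismState)
    if (r$phi <= tol) next
    better <- FALSE
    if (r$phi > best$phi + tol) better <- TRUE
    else if (abs(r$phi - best$phi) <= tol && !is.null(bestLocal)) {
      if (length(Z) > length(bestLocal)) better <- TRUE
      else if (length(Z) == length(bestLocal) &&
               paste(Z, collapse = ",") < paste(bestLocal, collapse = ","))
        better <- TRUE
    }
    if (better) {
      best <- list(units = sys@members[Z], states = r$state,
                   phi = r$phi, mip = r$mip)
      bestLocal <- Z
    }
  }
  best
}

#' Compute the congruent causal distinctions of a system
#'
#' Iterates over all \eqn{2^{|S|} - 1} candidate mechanisms, finds each
#' mechanism's maximally irreducible cause and effect purviews, keeps
#' candidates with \eqn{\varphi_d = \min(\varphi_c, \varphi_e) > 0}, and
#' filters for congruence with the system's maximal cause-effect state
#' (purview states must be sub-states of \eqn{s'_c} and \eqn{s'_e},
#' compared as (unit, state) tuples).
#'
#' @param sys a [ConditionedSystem-class].
#' @param ces the system's [CauseEffectState-class] (e.g. from
#'   [systemPhi()]); computed on the fly when missing.
#' @return list of [Distinction-class] objects, with attributes
#'   \code{nCandidates} (mechanisms evaluated) and \code{nPositivePhi}
#'   (candidates with \eqn{\varphi_d > 0} before the congruence filter).
#' @export
computeDistinctions <- function(sys, ces = NULL) {
  if (is.null(ces)) ces <- maximalCauseEffectState(sys)
  ns <- length(sys@members)
  sizes <- sys@cache$sizes
  tol <- phiTol()
  out <- list()
  nCand <- as.integer(2^ns - 1)
  nPos <- 0L
  if (is.na(ces@causeState) || is.na(ces@effectState)) {
    # a system without a maximal cause-effect state specifies no distinctions
    attr(out, "nCandidates") <- nCand
    attr(out, "nPositivePhi") <- 0L
    return(out)
  }
  sc <- indexToState(ces@causeState, sizes)
  se <- indexToState(ces@effectState, sizes)
  for (mask in seq_len(2^ns - 1L)) {
    M <- bitsOf(mask, ns)
    pc <- maximalPurview(sys, sys@members[M], "cause")
    if (pc$phi <= tol) next
    pe <- maximalPurview(sys, sys@members[M], "effect")
    if (pe$phi <= tol) next
    nPos <- nPos + 1L
    cLoc <- match(pc$units, sys@members)
    eLoc <- match(pe$units, sys@members)
    congruent <- all(pc$states == sc[cLoc]) && all(pe$states == se[eLoc])
    if (!congruent) next
    out[[length(out) + 1L]] <- methods::new(
      "Distinction",
      mechanism = sys@members[M],
      mechanismState = sys@state[M],
      causeUnits = as.integer(pc$units), causeStates = as.integer(pc$states),
      effectUnits = as.integer(pe$units), effectStates = as.integer(pe$states),
      phiCause = pc$phi, phiEffect = pe$phi,
      phi = min(pc$phi, pe$phi),
      congruent = TRUE)
  }
  attr(out, "nCandidates") <- nCand
  attr(out, "nPositivePhi") <- nPos
  out
}

#' @rdname phistruct-generics
#' @export
setMethod("phiValue", "Distinction", function(x) x@phi)

setMethod("show", "Distinction", function(object) {
  cat(sprintf(
    "Distinction: mechanism {%s} -> cause {%s} / effect {%s}, phi_d = %.6g\n",
    paste(object@mechanism, collapse = ","),
    paste(sprintf("%d=%d", object@causeUnits, object@causeStates),
          collapse = ","),
    paste(sprintf("%d=%d", object@effectUnits, object@effectStates),
          collapse = ","),
    object@phi))
  invisible(object)
})
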