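# Background conditioning: effect and cause TPMs of a candidate system.
#
# Effect side: the background W = U \ S is clamped at its current state w, so
# p_e(sbar | s) = p(sbar | s, w).
#
# Cause side: each unit factor is a mixture over prior background states
# wbar, weighted by the posterior probability of wbar given the full current
# universe state u under a uniform prior over prior universe states:
#   p_c(s_i | sbar) = sum_wbar p(s_i | sbar, wbar) *
#                     sum_shat p(u | shat, wbar) / sum_uhat p(u | uhat)
# Factors are recombined by product, which renders the background causally
# inert and keeps the unit factorization intact.

#' Condition a network on background units to obtain a candidate system
#'
#' Restricts a [Network-class] to a candidate system, producing the effect
#' TPM (background clamped at its current state) and the cause TPM
#' (background mixed over its posterior prior-state distribution given the
#' current universe state).
#'
#' @param net a [Network-class] with its current state set.
#' @param members unit names or integer indices of the candidate system
#'   (non-empty subset of the network's units).
#' @param computeCause compute the cause TPM as well (default TRUE). The
#'   cause TPM requires the current state to be reachable
#'   (\eqn{\sum_{\hat u} p(u \mid \hat u) > 0}); an unreachable state is an
#'   error.
#' @return a [ConditionedSystem-class].
#' @examples
#' net <- makeDirectedCycle(3, k = 4, state = "Abc")
#' sys <- conditionSystem(net, c("A", "B"))
#' effectTpm(sys)
#' @export
conditionSystem <- function(net, members, computeCause = TRUE) {
  stopifnot(is(net, "Network"))
  members <- resolveUnits(net, members)
  if (length(members) == 0L) stop("members must be a non-empty unit set")
  sizes <- netSizes(net)
  n <- length(sizes)
  background <- setdiff(seq_len(n), members)
  stU <- stateTable(sizes)
  FU <- unitFactorsU(net)
  sSizes <- sizes[members]
  Ds <- prod(sSizes)

  # rows of the full state table compatible with the background at w;
  # their natural order is exactly the little-endian order of system states
  if (length(background)) {
    keep <- rowSums(stU[, background, drop = FALSE] !=
                    matrix(net@state[background], nrow(stU),
                           length(background), byrow = TRUE)) == 0L
    sel <- which(keep)
  } else {
    sel <- seq_len(nrow(stU))
  }
  eFactors <- lapply(members, function(i) FU[[i]][sel, , drop = FALSE])
  Te <- expandRows(eFactors)

  cFactors <- list()
  Tc <- matrix(numeric(0), 0, 0)
  if (computeCause) {
    uIdx <- stateToIndex(net@state, sizes)
    colU <- net@tpm[, uIdx]
    denom <- sum(colU)
    if (denom <= 0)
      stop("current state is unreachable (sum_uhat p(u | uhat) = 0); the cause TPM is undefined")
    # posterior weight of each prior full state's background pattern
    if (length(background)) {
      bSizes <- sizes[background]
      bGroup <- integer(nrow(stU))
      mult <- cumprod(c(1, bSizes[-length(bSizes)]))
      for (k in seq_along(background)) {
        bGroup <- bGroup + (stU[, background[k]] - 1L) * mult[k]
      }
      bGroup <- bGroup + 1L
      wWeight <- as.vector(rowsum(colU, bGroup))   # sum_shat p(u | shat, wbar)
      wvec <- wWeight[bGroup] / denom              # beta(wbar) spread back
    } else {
      wvec <- rep(1, nrow(stU))                    # mixture collapses
    }
    # group prior full states by their system pattern
    sGroup <- integer(nrow(stU))
    mult <- cumprod(c(1, sSizes[-length(sSizes)]))
    for (k in seq_along(members)) {
      sGroup <- sGroup + (stU[, members[k]] - 1L) * mult[k]
    }
    sGroup <- sGroup + 1L
    cFactors <- lapply(members, function(i) {
      m <- rowsum(FU[[i]] * wvec, sGroup)
      dimnames(m) <- NULL
      m
    })
    Tc <- expandRows(cFactors)
  }

  cache <- new.env(parent = emptyenv())
  cache$stateTable <- stateTable(sSizes)
  cache$sizes <- sSizes
  sys <- methods::new("ConditionedSystem",
                      network = net,
                      members = as.integer(members),
                      state = net@state[members],
                      Te = Te, Tc = Tc,
                      eFactors = eFactors, cFactors = cFactors,
                      cache = cache)
  sys
}

#' @noRd
resolveUnits <- function(net, units) {
  if (is.character(units)) {
    idx <- match(units, net@units)
    if (anyNA(idx)) stop(sprintf("unknown unit: %s",
                                 paste(units[is.na(idx)], collapse = ", ")))
  } else {
    idx <- as.integer(units)
    if (any(idx < 1L | idx > length(net@units))) stop("unit index out of range")
  }
  sort(unique(idx))
}

# --- marginalization cache -------------------------------------------------

# Grouping of system states by the pattern of a subset of member units
# (little-endian within the subset), memoized per system.
#' @noRd
groupOf <- function(sys, mask) {
  env <- sys@cache
  if (is.null(env$gList)) env$gList <- vector("list", 2^length(env$sizes))
  g <- env$gList[[mask + 1L]]
  if (!is.null(g)) return(g)
  st <- env$stateTable
  sizes <- env$sizes
  units <- bitsOf(mask, length(sizes))
  if (length(units) == 0L) {
    g <- rep(1L, nrow(st))
  } else {
    sub <- sizes[units]
    mult <- cumprod(c(1, sub[-length(sub)]))
    g <- integer(nrow(st))
    for (k in seq_along(units)) g <- g + (st[, units[k]] - 1L) * mult[k]
    g <- g + 1L
  }
  env$gList[[mask + 1L]] <- g
  g
}

# p(target unit j | units in `mask` at each of their joint states), with all
# other member units causally marginalized (uniform average). side "e":
# rows of the result are current-system-state patterns of `mask`; side "c":
# prior-state patterns. Returns |Omega_mask| x |A_j| matrix.
#' @noRd
margDist <- function(sys, side, j, mask) {
  env <- sys@cache
  store <- if (side == "e") "eM" else "cM"
  tab <- env[[store]]
  if (is.null(tab)) {
    ns <- length(env$sizes)
    tab <- lapply(seq_len(ns), function(i) vector("list", 2^ns))
    env[[store]] <- tab
  }
  M <- env[[store]][[j]][[mask + 1L]]
  if (!is.null(M)) return(M)
  F <- if (side == "e") sys@eFactors[[j]] else sys@cFactors[[j]]
  full <- bitwShiftL(1L, length(env$sizes)) - 1L
  if (mask == full) {
    M <- F
  } else {
    g <- groupOf(sys, mask)
    cnt <- nrow(F) / max(g)
    M <- rowsum(F, g) / cnt
    dimnames(M) <- NULL
  }
  env[[store]][[j]][[mask + 1L]] <- M
  M
}

# index of a state restricted to the units of `mask` (local member indices)
#' @noRd
subIndex <- function(sys, state, mask) {
  sizes <- sys@cache$sizes
  units <- bitsOf(mask, length(sizes))
  stateToIndex(state[units], sizes[units])
}

#' @rdname phistruct-generics
#' @export
setMethod("members", "ConditionedSystem", function(x) x@members)

#' @rdname phistruct-generics
#' @export
setMethod("systemState", "ConditionedSystem", function(x) x@state)

#' @rdname phistruct-generics
#' @export
setMethod("effectTpm", "ConditionedSystem", function(x) x@Te)

#' @rdname phistruct-generics
#' @export
setMethod("causeTpm", "ConditionedSystem", function(x) {
  if (nrow(x@Tc) == 0L) stop("cause TPM was not computed for this system")
  x@Tc
})

#' @rdname phistruct-generics
#' @export
setMethod("unitNames", "ConditionedSystem",
          function(x) x@network@units[x@members])

#' Background units of a conditioned system
#' @param x a [ConditionedSystem-class].
#' @return integer indices of the background units W = U \ S.
#' @export
backgroundUnits <- function(x) setdiff(seq_along(x@network@units), x@members)

setMethod("show", "ConditionedSystem", function(object) {
  cat(sprintf("ConditionedSystem over %s (state %s)\n",
              paste(unitNames(object), collapse = ""),
              stateLabel(object@network, object@state, object@members)))
  bg <- backgroundUnits(object)
  if (length(bg)) {
    cat(sprintf("  background: %s at %s\n",
                paste(object@network@units[bg], collapse = ""),
                stateLabel(object@network, object@network@state[bg], bg)))
  } else {
    cat("  background: none (system = universe)\n")
  }
  invisible(object)
})

#' Interaction digraph of a conditioned system
#'
#' Edge j -> i when the effect factor of unit i varies with the state of
#' member unit j (holding all other member units fixed), i.e. when j is an
#' actual input of i within the background-conditioned system.
#'
#' @param x a [ConditionedSystem-class].
#' @return logical adjacency matrix over the member units.
#' @export
interactionGraph <- function(x) {
  ns <- length(x@members)
  full <- bitwShiftL(1L, ns) - 1L
  adj <- matrix(FALSE, ns, ns,
                dimnames = list(unitNames(x), unitNames(x)))
  for (i in seq_len(ns)) {
    Fi <- x@eFactors[[i]]
    for (j in seq_len(ns)) {
      without <- bitwAnd(full, bitwNot(bitwShiftL(1L, j - 1L)))
      avg <- margDist(x, "e", i, without)
      g <- groupOf(x, without)
      adj[j, i] <- max(abs(Fi - avg[g, , drop = FALSE])) > phiTol()
    }
  }
  adj
}

#' Is the system's interaction digraph strongly connected?
#'
#' A system that is not strongly connected is reducible
#' (\eqn{\varphi_s = 0}): some directional partition severs no effective
#' connection. This diagnostic never substitutes for the partition search.
#'
#' @param x a [ConditionedSystem-class].
#' @return logical scalar.
#' @export
isStronglyConnected <- function(x) {
  adj <- interactionGraph(x)
  if (nrow(adj) == 1L) return(TRUE)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "directed")
  igraph::is_connected(g, mode = "strong")
}
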