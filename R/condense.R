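# Exclusion: identifying maximal substrates (complexes) and recursively
# condensing a universe into a disjoint, exhaustive set of complexes.

#' @noRd
allSubsetMasks <- function(pool) {
  # all non-empty subsets of the units in `pool`, as sorted index vectors,
  # in deterministic bitmask order
  n <- length(pool)
  out <- vector("list", 2^n - 1L)
  for (m in seq_len(2^n - 1L)) out[[m]] <- pool[bitsOf(m, n)]
  out
}

# evaluate phi_s for every candidate subset of `pool` (all other units,
# including previously extracted complexes, act as background conditions)
#' @noRd
scanCandidates <- function(net, pool) {
  cands <- allSubsetMasks(pool)
  res <- vector("list", length(cands))
  phi <- numeric(length(cands))
  for (i in seq_along(cands)) {
    r <- systemPhi(conditionSystem(net, cands[[i]]))
    res[[i]] <- r
    phi[i] <- r@phi
  }
  list(members = cands, phi = phi, results = res)
}

# deterministic comparator: larger first, then lexicographically smaller
#' @noRd
preferredCandidate <- function(sets) {
  best <- 1L
  for (i in seq_along(sets)[-1L]) {
    a <- sets[[i]]; b <- sets[[best]]
    if (length(a) > length(b)) { best <- i; next }
    if (length(a) < length(b)) next
    cmp <- paste(a, collapse = ","); ref <- paste(b, collapse = ",")
    if (cmp < ref) best <- i
  }
  best
}

#' Find the first complex of a network
#'
#' Exhaustively scans all non-empty unit subsets (the rest acting as
#' background conditions) and returns the candidate with maximal system
#' integrated information \eqn{\varphi_s^*}. Ties among overlapping
#' candidates fall to the next-best unique level; residual ties prefer the
#' larger, then lexicographically smallest, system.
#'
#' @param net a [Network-class] with its state set.
#' @return a [Complex-class], or \code{NULL} when no subset has
#'   \eqn{\varphi_s > 0}.
#' @export
findFirstComplex <- function(net) {
  cs <- condense(net, maxComplexes = 1L)
  if (length(cs) == 0L) NULL else cs[[1L]]
}

#' Condense a network into its disjoint complexes
#'
#' Iteratively extracts maximal substrates: the candidate with maximal
#' \eqn{\varphi_s} becomes a complex, its units leave the candidate pool but
#' keep serving as background conditions, and the scan repeats over the
#' remaining units until none are left or no candidate is integrated.
#'
#' @param x a [Network-class].
#' @param maxComplexes stop after this many extraction rounds (default: all).
#' @param ... unused.
#' @return list of [Complex-class] objects (possibly empty), pairwise
#'   disjoint, in extraction order.
#' @rdname condense-method
#' @export
setMethod("condense", "Network", function(x, maxComplexes = Inf, ...) {
  net <- x
  n <- length(net@units)
  if (n > maxUnitsCap())
    stop(sprintf("universe has %d units; the exhaustive subset scan is capped at %d (option phistruct.maxUnits)",
                 n, maxUnitsCap()))
  tol <- phiTol()
  scan <- scanCandidates(net, seq_len(n))
  keyOf <- function(u) paste(u, collapse = ",")
  phiBy <- stats::setNames(scan$phi, vapply(scan$members, keyOf, character(1)))
  resBy <- stats::setNames(scan$results, names(phiBy))
  pool <- seq_len(n)
  complexes <- list()
  rank <- 1L
  while (length(pool) > 0L && length(complexes) < maxComplexes) {
    cands <- allSubsetMasks(pool)
    phi <- phiBy[vapply(cands, keyOf, character(1))]
    if (max(phi) <= tol) break
    chosen <- integer(0)
    # walk phi levels downward until one yields a unique or disjoint set
    levels <- sort(unique(round(phi / tol) * tol), decreasing = TRUE)
    for (lev in levels) {
      if (lev <= tol) break
      at <- which(phi >= lev - tol & phi <= lev + tol)
      if (length(at) == 1L) { chosen <- at; break }
      sets <- cands[at]
      overlap <- FALSE
      for (a in seq_along(sets)) for (b in seq_along(sets)) {
        if (a < b && length(intersect(sets[[a]], sets[[b]]))) overlap <- TRUE
      }
      if (!overlap) { chosen <- at; break }
    }
    if (length(chosen) == 0L) {
      # every level is tied-and-overlapping: fall back to the deterministic
      # preference among the top tied candidates
      top <- which(phi >= max(phi) - tol)
      chosen <- top[preferredCandidate(cands[top])]
    }
    for (i in chosen) {
      mem <- cands[[i]]
      complexes[[length(complexes) + 1L]] <- methods::new(
        "Complex", members = as.integer(mem), state = net@state[mem],
        phi = unname(phi[i]), rank = rank,
        result = resBy[[keyOf(mem)]], network = net)
      pool <- setdiff(pool, mem)
      rank <- rank + 1L
    }
  }
  complexes
})

#' @rdname phistruct-generics
#' @export
setMethod("phiValue", "Complex", function(x) x@phi)

#' @rdname phistruct-generics
#' @export
setMethod("members", "Complex", function(x) x@members)

#' @rdname phistruct-generics
#' @export
setMethod("unitNames", "Complex", function(x) x@network@units[x@members])

setMethod("show", "Complex", function(object) {
  cat(sprintf("Complex %d: %s (state %s), phi_s* = %.6g ibits\n",
              object@rank,
              paste(unitNames(object), collapse = ""),
              stateLabel(object@network, object@state, object@members),
              object@phi))
  invisible(object)
})
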