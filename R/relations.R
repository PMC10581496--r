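# Causal relations: congruent overlaps among distinction purviews, relation
# faces, and relation integrated information phi_r.
#
# Purviews are sets of (unit, state) tuples; every intersection and union in
# this module operates on the tuples, so the same unit in incongruent states
# never overlaps, while congruent cause and effect occurrences of a unit
# count as one.

#' Construct a sub-state (set of unit-state tuples)
#'
#' @param units integer unit indices.
#' @param states integer state indices, same length.
#' @return object of class \code{"substate"}: a list with sorted
#'   \code{units} and matching \code{states}.
#' @export
substate <- function(units, states) {
  units <- as.integer(units); states <- as.integer(states)
  stopifnot(length(units) == length(states))
  o <- order(units)
  structure(list(units = units[o], states = states[o]), class = "substate")
}

#' @export
print.substate <- function(x, ...) {
  cat(sprintf("substate: {%s}\n",
              paste(sprintf("%d=%d", x$units, x$states), collapse = ", ")))
  invisible(x)
}

#' @noRd
tupleCodes <- function(units, states, radix = 64L) units * radix + states

#' @noRd
codesToSubstate <- function(codes, radix = 64L) {
  codes <- sort(codes)
  substate(codes %/% radix, codes %% radix)
}

# cause / effect purviews of a Distinction as tuple-code sets
#' @noRd
distinctionCodes <- function(d) {
  list(cause = tupleCodes(d@causeUnits, d@causeStates),
       effect = tupleCodes(d@effectUnits, d@effectStates))
}

#' Congruent overlap of a set of purviews
#'
#' Intersection over (unit, state) tuples: units overlap only when they are
#' in the same state in every purview. An empty result signals that the
#' purviews support no relation face.
#'
#' @param purviews a list of \code{substate} objects (at least 2), or of
#'   [Distinction-class] purviews extracted by the caller.
#' @return a \code{substate} (possibly empty).
#' @export
congruentOverlap <- function(purviews) {
  stopifnot(length(purviews) >= 2L)
  codes <- lapply(purviews, function(p) tupleCodes(p$units, p$states))
  codesToSubstate(Reduce(intersect, codes))
}

#' Enumerate the faces of a candidate relation
#'
#' A face selects, for every distinction in the set, its cause purview, its
#' effect purview, or both; the face exists when the selected purviews share
#' a non-empty congruent intersection (the face purview). A single
#' distinction admits only the self-relation face over its own cause and
#' effect. A set of h distinctions has at most \eqn{3^h} faces.
#'
#' @param dlist list of [Distinction-class] objects.
#' @return list of faces, each a list with \code{selection} (per
#'   distinction: "cause", "effect" or "both"), \code{units}, \code{states}
#'   (the face purview).
#' @export
enumerateFaces <- function(dlist) {
  h <- length(dlist)
  stopifnot(h >= 1L)
  codes <- lapply(dlist, distinctionCodes)
  choices <- c("cause", "effect", "both")
  grid <- as.matrix(expand.grid(rep(list(1:3), h)))
  faces <- list()
  for (r in seq_len(nrow(grid))) {
    selIdx <- grid[r, ]
    nPurviews <- sum(ifelse(selIdx == 3L, 2L, 1L))
    if (nPurviews < 2L) next      # |z| > 1 required
    sets <- list()
    for (i in seq_len(h)) {
      if (selIdx[i] %in% c(1L, 3L)) sets <- c(sets, list(codes[[i]]$cause))
      if (selIdx[i] %in% c(2L, 3L)) sets <- c(sets, list(codes[[i]]$effect))
    }
    ov <- Reduce(intersect, sets)
    if (length(ov) == 0L) next
    ss <- codesToSubstate(ov)
    faces[[length(faces) + 1L]] <- list(selection = choices[selIdx],
                                        units = ss$units,
                                        states = ss$states)
  }
  faces
}

#' Relation integrated information
#'
#' \eqn{\varphi_r(\mathbf d) = \min_{d}\, \varphi_d /
#' |z^*_c(d) \cup z^*_e(d)| \times |\bigcup_f o^*_f|}: the smallest
#' per-purview-unit integrated information among the related distinctions,
#' scaled by the number of distinct (unit, state) tuples across all face
#' purviews (the joint purview).
#'
#' @param dlist list of [Distinction-class] objects.
#' @param faces faces from [enumerateFaces()]; computed when missing.
#' @return list with \code{phi}, \code{faces}, \code{purview} (joint purview
#'   as a \code{substate}).
#' @export
relationPhi <- function(dlist, faces = NULL) {
  if (is.null(faces)) faces <- enumerateFaces(dlist)
  if (length(faces) == 0L)
    return(list(phi = 0, faces = faces, purview = substate(integer(0),
                                                           integer(0))))
  joint <- sort(unique(unlist(lapply(faces, function(f)
    tupleCodes(f$units, f$states)))))
  perUnit <- vapply(dlist, function(d) {
    cd <- distinctionCodes(d)
    d@phi / length(union(cd$cause, cd$effect))
  }, numeric(1))
  list(phi = min(perUnit) * length(joint),
       faces = faces,
       purview = codesToSubstate(joint))
}

#' Compute all relations among a set of distinctions
#'
#' Enumerates the subsets \eqn{\mathbf d \subseteq D} with \eqn{|\mathbf d|
#' \ge 1} and \eqn{\varphi_r > 0}. Self-relations (a single distinction
#' whose cause and effect overlap congruently) are included. The enumeration
#' is pruned by downward closure: a subset whose purviews share no congruent
#' overlap cannot support a face in any superset, so supersets of face-less
#' sets are skipped.
#'
#' @param D list of [Distinction-class] objects (e.g. from
#'   [computeDistinctions()]).
#' @param maxDistinctions capacity guard for the exponential enumeration
#'   (default \code{getOption("phistruct.maxDistinctions", 20)}); larger
#'   distinction sets raise an error suggesting to analyse folds instead.
#' @return list of [Relation-class] objects.
#' @export
computeRelations <- function(D,
                             maxDistinctions =
                               getOption("phistruct.maxDistinctions", 20L)) {
  nD <- length(D)
  if (nD == 0L) return(list())
  if (nD > maxDistinctions)
    stop(sprintf(
      "%d distinctions exceed the relation-enumeration cap of %d; raise option phistruct.maxDistinctions or analyse sub-structures (folds)",
      nD, maxDistinctions))
  out <- list()
  addRelation <- function(idx, faces) {
    r <- relationPhi(D[idx], faces)
    if (r$phi <= phiTol()) return(invisible(NULL))
    out[[length(out) + 1L]] <<- methods::new(
      "Relation", members = as.integer(idx), faces = faces,
      purviewUnits = r$purview$units, purviewStates = r$purview$states,
      phi = r$phi)
  }
  # self-relations
  for (i in seq_len(nD)) {
    f <- enumerateFaces(D[i])
    if (length(f)) addRelation(i, f)
  }
  # pairs, then larger sets grown from related sets
  frontier <- list()
  pairRelated <- matrix(FALSE, nD, nD)
  if (nD >= 2L) {
    for (i in seq_len(nD - 1L)) for (j in (i + 1L):nD) {
      f <- enumerateFaces(D[c(i, j)])
      if (length(f)) {
        pairRelated[i, j] <- TRUE
        addRelation(c(i, j), f)
        frontier[[length(frontier) + 1L]] <- c(i, j)
      }
    }
  }
  while (length(frontier)) {
    nxt <- list()
    for (s in frontier) {
      last <- s[length(s)]
      if (last >= nD) next
      for (d2 in (last + 1L):nD) {
        if (!all(pairRelated[s, d2])) next
        cand <- c(s, d2)
        f <- enumerateFaces(D[cand])
        if (length(f) == 0L) next
        addRelation(cand, f)
        nxt[[length(nxt) + 1L]] <- cand
      }
    }
    frontier <- nxt
  }
  out
}

#' Exact relation counts for the fully congruent special case
#'
#' When every purview of every distinction shares a congruent unit, each of
#' the \eqn{2^{|D|} - 1} non-empty distinction subsets supports at least one
#' face, so the relation count is exactly \eqn{2^{|D|} - 1}
#' (\code{allCongruentRelationCount}). Since a system of n units has at most
#' \eqn{2^n - 1} distinctions, the number of relations is bounded by
#' \eqn{2^{2^n - 1} - 1} (\code{maxRelationCount}). Both are closed forms
#' for validating the brute-force enumeration; no general analytic count is
#' implemented.
#'
#' @param nDistinctions number of distinctions in the (fully congruent) set.
#' @return a count (numeric: the bound overflows integers quickly).
#' @export
allCongruentRelationCount <- function(nDistinctions) {
  2^nDistinctions - 1
}

#' @rdname allCongruentRelationCount
#' @param nUnits number of system units.
#' @export
maxRelationCount <- function(nUnits) {
  2^(2^nUnits - 1) - 1
}

#' @rdname phistruct-generics
#' @export
setMethod("phiValue", "Relation", function(x) x@phi)

setMethod("show", "Relation", function(object) {
  cat(sprintf(
    "Relation of degree %d: distinctions {%s}, %d face(s), joint purview {%s}, phi_r = %.6g\n",
    length(object@members),
    paste(object@members, collapse = ","),
    length(object@faces),
    paste(sprintf("%d=%d", object@purviewUnits, object@purviewStates),
          collapse = ","),
    object@phi))
  invisible(object)
})
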