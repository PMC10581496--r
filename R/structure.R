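# Phi-structures: assembling the cause-effect structure of a complex and
# computing structure integrated information Phi and Phi-folds.

#' @noRd
assembleStructure <- function(complex, D, R) {
  phiD <- sum(vapply(D, function(d) d@phi, numeric(1)))
  phiR <- sum(vapply(R, function(r) r@phi, numeric(1)))
  methods::new("PhiStructure",
               complex = complex,
               distinctions = D,
               relations = R,
               phi = phiD + phiR,
               phiDistinctions = phiD,
               phiRelations = phiR,
               nCandidateMechanisms = as.integer(attr(D, "nCandidates") %||% 0L))
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Unfold a complex into its Phi-structure
#'
#' Runs [computeDistinctions()] and [computeRelations()] for the complex (or
#' for a conditioned system analysed directly) and assembles the cause-effect
#' structure \eqn{C(D) = D \cup R(D)} with its structure integrated
#' information \eqn{\Phi = \sum_D \varphi_d + \sum_R \varphi_r}.
#'
#' @param x a [Complex-class] or [ConditionedSystem-class].
#' @param maxDistinctions passed to [computeRelations()].
#' @param ... unused.
#' @return a [PhiStructure-class].
#' @rdname unfold-methods
#' @examples
#' net <- makeDirectedCycle(6, k = 4, state = "Abcdef")
#' cx <- findFirstComplex(net)
#' st <- unfold(cx)
#' bigPhi(st)   # 7.6504 ibits
#' @export
setMethod("unfold", "Complex", function(x, maxDistinctions =
                                          getOption("phistruct.maxDistinctions",
                                                    20L), ...) {
  # units with a single reachable state cannot be intervened upon and are
  # rejected as system members (they belong in the background)
  sizes <- lengths(x@network@alphabets[x@members])
  if (any(sizes < 2L))
    stop("every member unit needs at least two counterfactual states")
  sys <- conditionSystem(x@network, x@members)
  D <- computeDistinctions(sys, x@result@ces)
  R <- computeRelations(D, maxDistinctions)
  assembleStructure(x, D, R)
})

#' @rdname unfold-methods
#' @export
setMethod("unfold", "ConditionedSystem",
          function(x, maxDistinctions =
                     getOption("phistruct.maxDistinctions", 20L), ...) {
  res <- systemPhi(x)
  D <- computeDistinctions(x, res@ces)
  R <- computeRelations(D, maxDistinctions)
  cx <- methods::new("Complex", members = x@members, state = x@state,
                     phi = res@phi, rank = NA_integer_, result = res,
                     network = x@network)
  assembleStructure(cx, D, R)
})

#' @rdname phistruct-generics
#' @export
setMethod("bigPhi", "PhiStructure", function(x) x@phi)

#' @rdname phistruct-generics
#' @export
setMethod("phiValue", "PhiStructure", function(x) x@phi)

#' @rdname phistruct-generics
#' @export
setMethod("distinctions", "PhiStructure", function(x) x@distinctions)

#' @rdname phistruct-generics
#' @export
setMethod("relations", "PhiStructure", function(x) x@relations)

setMethod("show", "PhiStructure", function(object) {
  cat(sprintf(
    "Phi-structure: %d distinction(s), %d relation(s)\n",
    length(object@distinctions), length(object@relations)))
  cat(sprintf("  Phi = %.6g ibits (sum phi_d = %.6g, sum phi_r = %.6g)\n",
              object@phi, object@phiDistinctions, object@phiRelations))
  cat(sprintf("  candidate mechanisms evaluated: %d\n",
              object@nCandidateMechanisms))
  invisible(object)
})

#' Distinction Phi-fold
#'
#' The sub-structure anchored on one distinction: the distinction itself plus
#' every relation that binds it (its context).
#'
#' @param structure a [PhiStructure-class].
#' @param d index of the distinction within \code{distinctions(structure)}.
#' @return list with \code{distinction}, \code{relations} (list),
#'   \code{relationIndices}, and \code{sumPhi} (the fold's
#'   \eqn{\varphi_d + \sum \varphi_r}).
#' @export
distinctionFold <- function(structure, d) {
  stopifnot(is(structure, "PhiStructure"))
  d <- as.integer(d)
  if (d < 1L || d > length(structure@distinctions))
    stop("no such distinction in this structure")
  idx <- which(vapply(structure@relations,
                      function(r) d %in% r@members, logical(1)))
  rels <- structure@relations[idx]
  list(distinction = structure@distinctions[[d]],
       relations = rels,
       relationIndices = idx,
       sumPhi = structure@distinctions[[d]]@phi +
         sum(vapply(rels, function(r) r@phi, numeric(1))))
}

#' Compound Phi-fold of a unit subset
#'
#' Union of the distinction folds of every mechanism containing any of the
#' given units (the sub-structure a unit subset contributes to, alone or in
#' combination).
#'
#' @param structure a [PhiStructure-class].
#' @param units network unit indices (or names, resolved against the
#'   complex's network).
#' @return list with \code{distinctionIndices}, \code{relationIndices},
#'   \code{sumPhi}.
#' @export
compoundFold <- function(structure, units) {
  stopifnot(is(structure, "PhiStructure"))
  if (is.character(units)) {
    if (is.null(structure@complex))
      stop("unit names require a structure with an attached complex")
    units <- match(units, structure@complex@network@units)
    if (anyNA(units)) stop("unknown unit name")
  }
  units <- as.integer(units)
  dIdx <- which(vapply(structure@distinctions, function(d)
    length(intersect(d@mechanism, units)) > 0L, logical(1)))
  rIdx <- sort(unique(unlist(lapply(dIdx, function(i)
    distinctionFold(structure, i)$relationIndices))))
  if (is.null(rIdx)) rIdx <- integer(0)
  list(distinctionIndices = dIdx,
       relationIndices = rIdx,
       sumPhi = sum(vapply(structure@distinctions[dIdx],
                           function(d) d@phi, numeric(1))) +
         sum(vapply(structure@relations[rIdx],
                    function(r) r@phi, numeric(1))))
}
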