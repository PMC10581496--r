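#' Network: a finite-state discrete causal network
#'
#' A \code{Network} holds an ordered set of units, per-unit finite state
#' alphabets, the full interventional transition probability matrix (TPM)
#' \eqn{p(\bar u \mid u)} over joint states, and the current state. Full
#' states are indexed in mixed-radix little-endian order (unit 1 varies
#' fastest); for binary units state label \code{"-1"} maps to index 1 (OFF)
#' and \code{"1"} to index 2 (ON).
#'
#' @slot units character vector of unit names.
#' @slot alphabets list of character vectors, the per-unit state labels
#'   (length at least 2 per unit).
#' @slot tpm numeric matrix of transition probabilities, rows = current full
#'   state, columns = next full state, both in little-endian state order.
#' @slot state integer vector of 1-based per-unit state indices, the current
#'   state of the network.
#'
#' @seealso [Network()], [logisticNetwork()], [conditionSystem()]
#' @export
setClass("Network",
  representation(
    units = "character",
    alphabets = "list",
    tpm = "matrix",
    state = "integer"
  )
)

setValidity("Network", function(object) {
  n <- length(object@units)
  if (length(object@alphabets) != n)
    return("alphabets must have one entry per unit")
  sizes <- lengths(object@alphabets)
  if (any(sizes < 2L))
    return("every unit needs an alphabet of size >= 2")
  D <- prod(sizes)
  if (!all(dim(object@tpm) == c(D, D)))
    return(sprintf("tpm must be %d x %d for this state space", D, D))
  if (any(object@tpm < -1e-12) || any(object@tpm > 1 + 1e-12))
    return("tpm entries must lie in [0, 1]")
  rs <- rowSums(object@tpm)
  if (any(abs(rs - 1) > 1e-8))
    return(sprintf("tpm row %d sums to %.12g, not 1",
                   which.max(abs(rs - 1)), rs[which.max(abs(rs - 1))]))
  if (length(object@state) != n)
    return("state must have one entry per unit")
  if (any(object@state < 1L) || any(object@state > sizes))
    return("state indices out of alphabet range")
  if (anyDuplicated(object@units))
    return("unit names must be unique")
  TRUE
})

#' ConditionedSystem: a candidate system with background-conditioned TPMs
#'
#' Restriction of a [Network] to a candidate system \eqn{S}. The remaining
#' units \eqn{W = U \setminus S} are background conditions: they are causally
#' marginalized conditional on the current universe state, yielding an effect
#' TPM \eqn{T_e = p_e(\bar s \mid s)} (background clamped at its current
#' state) and a cause TPM \eqn{T_c = p_c(s \mid \bar s)} (background prior
#' states mixed by their posterior probability given the current universe
#' state, under a uniform prior over prior universe states). Both factor into
#' per-unit tables, stored alongside the joint matrices.
#'
#' @slot network the parent [Network].
#' @slot members integer indices (into the network's units) of the system.
#' @slot state integer per-member state indices, the system's current state.
#' @slot Te effect TPM over system states: rows = current \eqn{s}, columns =
#'   next \eqn{\bar s}.
#' @slot Tc cause TPM over system states: rows = prior \eqn{\bar s}, columns
#'   = current \eqn{s}.
#' @slot eFactors list of per-member matrices \eqn{p_e(\bar s_i = a \mid s)}
#'   (rows = current system state, columns = the unit's alphabet).
#' @slot cFactors list of per-member matrices \eqn{p_c(s_i = a \mid \bar s)}
#'   (rows = prior system state).
#' @slot cache environment memoising marginalized distributions.
#'
#' @seealso [conditionSystem()], [systemPhi()]
#' @export
setClass("ConditionedSystem",
  representation(
    network = "Network",
    members = "integer",
    state = "integer",
    Te = "matrix",
    Tc = "matrix",
    eFactors = "list",
    cFactors = "list",
    cache = "environment"
  )
)

setValidity("ConditionedSystem", function(object) {
  ns <- length(object@members)
  if (ns < 1L) return("a system needs at least one member unit")
  sizes <- lengths(object@network@alphabets[object@members])
  D <- prod(sizes)
  if (!all(dim(object@Te) == c(D, D))) return("Te has wrong dimensions")
  if (nrow(object@Tc) > 0 && !all(dim(object@Tc) == c(D, D)))
    return("Tc has wrong dimensions")
  if (any(abs(rowSums(object@Te) - 1) > 1e-8))
    return("Te is not row-stochastic")
  if (nrow(object@Tc) > 0 && any(abs(rowSums(object@Tc) - 1) > 1e-8))
    return("Tc is not row-stochastic")
  TRUE
})

#' CauseEffectState: the maximal cause-effect state of a system
#'
#' The pair of cause and effect states selected by a system in its current
#' state, each maximizing intrinsic information (in ibits) over the system's
#' state space. A state index of \code{NA} flags a side with no cause or
#' effect power (intrinsic information 0).
#'
#' @slot causeState integer index of the maximal cause state (or NA).
#' @slot effectState integer index of the maximal effect state (or NA).
#' @slot iiCause maximal intrinsic cause information, ibits.
#' @slot iiEffect maximal intrinsic effect information, ibits.
#' @export
setClass("CauseEffectState",
  representation(
    causeState = "integer",
    effectState = "integer",
    iiCause = "numeric",
    iiEffect = "numeric"
  )
)

#' SystemPhiResult: system integrated information over the minimum partition
#'
#' @slot phi system integrated information \eqn{\varphi_s} (ibits): the
#'   minimum of cause and effect irreducibility at the minimum partition.
#' @slot phiCause,phiEffect directional integrated information at the MIP.
#' @slot normalized \eqn{\varphi_s} divided by the MIP's normalization.
#' @slot mip the minimum partition (list with parts, directions, cut sources,
#'   normalization), or an empty list for reducible / zero-power systems.
#' @slot ces the [CauseEffectState] the system specifies.
#' @slot members,state the system definition (network unit indices, states).
#' @slot nPartitions number of distinct cut-sets evaluated.
#' @slot reducible TRUE when some partition leaves the cause or effect
#'   probability unchanged (\eqn{\varphi_s = 0}).
#' @export
setClass("SystemPhiResult",
  representation(
    phi = "numeric",
    phiCause = "numeric",
    phiEffect = "numeric",
    normalized = "numeric",
    mip = "list",
    ces = "CauseEffectState",
    members = "integer",
    state = "integer",
    nPartitions = "integer",
    reducible = "logical"
  )
)

#' Complex: a maximal substrate
#'
#' A set of units whose system integrated information \eqn{\varphi_s} exceeds
#' that of every overlapping candidate evaluated during condensation.
#'
#' @slot members integer network unit indices.
#' @slot state integer per-member state indices.
#' @slot phi \eqn{\varphi_s^*} of the complex, ibits.
#' @slot rank extraction order (1 = first complex).
#' @slot result the full [SystemPhiResult] of the winning candidate.
#' @slot network the parent [Network] (kept so the complex can be unfolded).
#' @export
setClass("Complex",
  representation(
    members = "integer",
    state = "integer",
    phi = "numeric",
    rank = "integer",
    result = "SystemPhiResult",
    network = "Network"
  )
)

#' Distinction: a mechanism with its maximally irreducible cause and effect
#'
#' @slot mechanism integer network unit indices of the mechanism \eqn{M}.
#' @slot mechanismState integer state indices of \eqn{m}.
#' @slot causeUnits,causeStates the maximal cause purview \eqn{z^*_c}
#'   as (unit, state) pairs.
#' @slot effectUnits,effectStates the maximal effect purview \eqn{z^*_e}.
#' @slot phiCause,phiEffect integrated cause/effect information, ibits.
#' @slot phi distinction integrated information
#'   \eqn{\varphi_d = \min(\varphi_c, \varphi_e)}.
#' @slot congruent TRUE when both purview states are sub-states of the
#'   system's maximal cause-effect state.
#' @export
setClass("Distinction",
  representation(
    mechanism = "integer",
    mechanismState = "integer",
    causeUnits = "integer",
    causeStates = "integer",
    effectUnits = "integer",
    effectStates = "integer",
    phiCause = "numeric",
    phiEffect = "numeric",
    phi = "numeric",
    congruent = "logical"
  )
)

#' Relation: a congruent overlap among distinction purviews
#'
#' @slot members integer indices into the distinction set the relation binds.
#' @slot faces list of faces; each face is a list with \code{selection} (one
#'   of "cause", "effect", "both" per distinction), and the face purview
#'   \code{units} / \code{states} (the maximal congruent overlap).
#' @slot purviewUnits,purviewStates the joint (relation) purview: union of
#'   all face purviews as (unit, state) pairs.
#' @slot phi relation integrated information \eqn{\varphi_r}, ibits.
#' @export
setClass("Relation",
  representation(
    members = "integer",
    faces = "list",
    purviewUnits = "integer",
    purviewStates = "integer",
    phi = "numeric"
  )
)

#' PhiStructure: the unfolded cause-effect structure of a complex
#'
#' The set of congruent causal distinctions specified by a substrate's
#' subsets, the relations binding them, and the structure integrated
#' information \eqn{\Phi = \sum \varphi_d + \sum \varphi_r}.
#'
#' @slot complex the [Complex] that was unfolded (or NULL when a system was
#'   unfolded directly).
#' @slot distinctions list of [Distinction] objects.
#' @slot relations list of [Relation] objects.
#' @slot phi structure integrated information \eqn{\Phi}, ibits.
#' @slot phiDistinctions sum of distinction \eqn{\varphi_d}.
#' @slot phiRelations sum of relation \eqn{\varphi_r}.
#' @slot nCandidateMechanisms number of candidate mechanisms evaluated
#'   (\eqn{2^{|S|} - 1}).
#' @export
setClass("PhiStructure",
  representation(
    complex = "ANY",
    distinctions = "list",
    relations = "list",
    phi = "numeric",
    phiDistinctions = "numeric",
    phiRelations = "numeric",
    nCandidateMechanisms = "integer"
  )
)

setValidity("PhiStructure", function(object) {
  s <- sum(vapply(object@distinctions, function(d) d@phi, numeric(1))) +
    sum(vapply(object@relations, function(r) r@phi, numeric(1)))
  if (abs(s - object@phi) > 1e-8)
    return("phi must equal the sum of distinction and relation phi values")
  TRUE
})
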