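# System-level intrinsic information and the maximal cause-effect state.
#
# Intrinsic information is the product of selectivity and informativeness,
# in intrinsic bits (ibits):
#   ii_e(s, sbar) = p_e(sbar | s) * log2( p_e(sbar | s) / p_e(sbar) )
#   ii_c(s, sbar) = p_c<-(sbar | s) * log2( p_c(s | sbar) / p_c(s) )
# with the backward probability p_c<-(sbar | s) obtained by Bayes' rule under
# a uniform prior over cause states. Logarithms are base 2 throughout.

#' Interventional unconstrained effect probability
#'
#' The marginal probability of each effect state, averaged over all possible
#' current states with equal probability:
#' \eqn{p_e(\bar s) = |\Omega_S|^{-1} \sum_s p_e(\bar s \mid s)}.
#'
#' @param x a [ConditionedSystem-class] or an effect TPM matrix (rows =
#'   current state).
#' @param state optional effect state index; when given, the single
#'   probability is returned instead of the full vector.
#' @return numeric vector over effect states (or scalar).
#' @export
unconstrainedEffectProbability <- function(x, state = NULL) {
  Te <- if (is(x, "ConditionedSystem")) x@Te else as.matrix(x)
  p <- colMeans(Te)
  if (is.null(state)) p else p[[state]]
}

#' Interventional unconstrained cause probability
#'
#' \eqn{p_c(s) = |\Omega_S|^{-1} \sum_{\bar s} p_c(s \mid \bar s)}: the
#' probability of each current state averaged over all cause states.
#'
#' @param x a [ConditionedSystem-class] or a cause TPM matrix (rows = prior
#'   state).
#' @param state optional current-state index.
#' @return numeric vector over current states (or scalar).
#' @export
unconstrainedCauseProbability <- function(x, state = NULL) {
  Tc <- if (is(x, "ConditionedSystem")) causeTpm(x) else as.matrix(x)
  p <- colMeans(Tc)
  if (is.null(state)) p else p[[state]]
}

#' Intrinsic effect information of a system state
#'
#' \eqn{ii_e(s, \bar s) = p_e(\bar s \mid s)\,
#' \log_2(p_e(\bar s \mid s) / p_e(\bar s))}, with \eqn{0 \log 0 := 0}.
#' Values for non-maximal effect states may be negative.
#'
#' @param x a [ConditionedSystem-class] or an effect TPM matrix.
#' @param current current-state index; defaults to the system's state.
#' @param effectState optional effect-state index (scalar return).
#' @return numeric vector of ii values (ibits) over effect states, or scalar.
#' @export
iiEffect <- function(x, current = NULL, effectState = NULL) {
  Te <- if (is(x, "ConditionedSystem")) x@Te else as.matrix(x)
  if (is.null(current)) {
    if (!is(x, "ConditionedSystem"))
      stop("current state index required with a raw matrix")
    current <- stateToIndex(x@state, x@cache$sizes)
  }
  p <- Te[current, ]
  unc <- colMeans(Te)
  ii <- numeric(length(p))
  pos <- p > 0
  ii[pos] <- p[pos] * log2(p[pos] / unc[pos])
  if (is.null(effectState)) ii else ii[[effectState]]
}

#' Intrinsic cause information of a system state
#'
#' \eqn{ii_c(s, \bar s) = p_{c\leftarrow}(\bar s \mid s)\,
#' \log_2(p_c(s \mid \bar s) / p_c(s))} with the backward probability
#' \eqn{p_{c\leftarrow}(\bar s \mid s) = p_c(s \mid \bar s) /
#' \sum_{\hat s} p_c(s \mid \hat s)} (Bayes' rule, uniform prior over cause
#' states). The current state must be reachable.
#'
#' @inheritParams iiEffect
#' @param causeState optional cause-state index (scalar return).
#' @return numeric vector of ii values (ibits) over cause states, or scalar.
#' @export
iiCause <- function(x, current = NULL, causeState = NULL) {
  Tc <- if (is(x, "ConditionedSystem")) causeTpm(x) else as.matrix(x)
  if (is.null(current)) {
    if (!is(x, "ConditionedSystem"))
      stop("current state index required with a raw matrix")
    current <- stateToIndex(x@state, x@cache$sizes)
  }
  p <- Tc[, current]              # p_c(s | sbar) over sbar
  tot <- sum(p)
  if (tot <= 0)
    stop("current state is unreachable: p_c(s | sbar) = 0 for every sbar")
  back <- p / tot
  unc <- mean(p)
  ii <- numeric(length(p))
  pos <- p > 0
  ii[pos] <- back[pos] * log2(p[pos] / unc)
  if (is.null(causeState)) ii else ii[[causeState]]
}

#' Maximal cause-effect state of a system
#'
#' Selects, on each side, the state with maximal intrinsic information. When
#' several states are tied for maximal ii (within tolerance), the state
#' maximizing the directional integrated information \eqn{\varphi_{c/e}}
#' (over that side's normalized minimum partition) is chosen; residual ties
#' fall to the smallest state index. A side with maximal ii equal to 0 has no
#' cause or effect power and its selected state is \code{NA}.
#'
#' @param x a [ConditionedSystem-class].
#' @param tieBreak \code{"phi"} (default: the rule above) or \code{"index"}
#'   (smallest state index immediately).
#' @return a [CauseEffectState-class].
#' @export
maximalCauseEffectState <- function(x, tieBreak = c("phi", "index")) {
  tieBreak <- match.arg(tieBreak)
  tol <- phiTol()
  iie <- iiEffect(x)
  iic <- iiCause(x)
  pick <- function(ii, side) {
    top <- max(ii)
    if (top <= tol) return(list(state = NA_integer_, ii = 0))
    tied <- which(ii >= top - tol)
    if (length(tied) > 1L && tieBreak == "phi") {
      score <- vapply(tied, function(st)
        directionalMipPhi(x, side, st), numeric(1))
      tied <- tied[score >= max(score) - tol]
    }
    list(state = as.integer(tied[1L]), ii = ii[[tied[1L]]])
  }
  eres <- pick(iie, "effect")
  cres <- pick(iic, "cause")
  methods::new("CauseEffectState",
               causeState = cres$state, effectState = eres$state,
               iiCause = cres$ii, iiEffect = eres$ii)
}

# phi of one side at that side's own normalized minimum partition, used only
# to resolve ii ties between candidate cause/effect states
#' @noRd
directionalMipPhi <- function(sys, side, stateIdx) {
  parts <- systemPartitions(length(sys@members))
  tol <- phiTol()
  bestR <- Inf; bestPhi <- 0
  for (p in parts) {
    ph <- phiDirectional(sys, p, side, stateIdx)
    r <- ph / p$norm
    if (r < bestR - tol || (abs(r - bestR) <= tol && ph > bestPhi + tol)) {
      bestR <- r; bestPhi <- ph
    }
    if (ph <= 0) return(0)
  }
  bestPhi
}

setMethod("show", "CauseEffectState", function(object) {
  cat("Maximal cause-effect state\n")
  cat(sprintf("  cause state index:  %s  (ii_c = %.6g ibits)\n",
              ifelse(is.na(object@causeState), "none", object@causeState),
              object@iiCause))
  cat(sprintf("  effect state index: %s  (ii_e = %.6g ibits)\n",
              ifelse(is.na(object@effectState), "none", object@effectState),
              object@iiEffect))
  invisible(object)
})
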