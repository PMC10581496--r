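# Networks: construction, state handling, logistic-unit builder, validation.

#' Construct a Network from an explicit transition probability matrix
#'
#' @param tpm square numeric matrix of interventional transition
#'   probabilities \eqn{p(\bar u \mid u)}; rows index the current full state,
#'   columns the next full state, both in little-endian order (unit 1
#'   fastest).
#' @param units character vector of unit names; defaults to
#'   \code{LETTERS[1:n]}.
#' @param alphabets list of per-unit state-label vectors; defaults to binary
#'   \code{c("-1", "1")} for every unit, in which case the number of units is
#'   inferred as \code{log2(nrow(tpm))}.
#' @param state current state: a compact label string (for binary networks
#'   with single-letter unit names, e.g. \code{"Abc"}: uppercase = ON/+1,
#'   lowercase = OFF/-1), a vector of per-unit state labels, or a vector of
#'   1-based state indices (see [parseState()]).
#' @return a validated [Network-class] object.
#' @examples
#' # deterministic swap pair: A' = B, B' = A
#' swap <- Network(diag(4)[c(1, 3, 2, 4), ], units = c("A", "B"), state = "Ab")
#' @export
Network <- function(tpm, units = NULL, alphabets = NULL, state = NULL) {
  tpm <- as.matrix(tpm)
  if (nrow(tpm) != ncol(tpm)) stop("tpm must be square")
  if (is.null(alphabets)) {
    n <- as.integer(round(log2(nrow(tpm))))
    if (2^n != nrow(tpm))
      stop("tpm dimension is not a power of 2; supply explicit alphabets")
    if (is.null(units)) units <- LETTERS[seq_len(n)]
    alphabets <- rep(list(c("-1", "1")), n)
  } else {
    n <- length(alphabets)
    if (is.null(units)) units <- LETTERS[seq_len(n)]
  }
  names(alphabets) <- units
  sizes <- lengths(alphabets)
  if (is.null(state)) state <- rep(1L, n)
  stateIdx <- parseStateSpec(state, units, alphabets)
  dimnames(tpm) <- NULL
  methods::new("Network", units = units, alphabets = alphabets,
               tpm = tpm, state = stateIdx)
}

# Resolve the many accepted state specifications to 1-based indices.
#' @noRd
parseStateSpec <- function(state, units, alphabets) {
  n <- length(units)
  sizes <- lengths(alphabets)
  if (is.character(state) && length(state) == 1L && n > 1L &&
      all(nchar(units) == 1L) && nchar(state) == n) {
    chars <- strsplit(state, "")[[1]]
    if (all(toupper(chars) == toupper(units))) {
      binary <- all(sizes == 2L)
      if (!binary) stop("compact state labels need binary units")
      return(ifelse(chars == toupper(units), 2L, 1L))
    }
  }
  if (length(state) != n)
    stop(sprintf("state must have %d entries", n))
  if (is.numeric(state) && !is.character(state)) {
    v <- as.vector(state)
    # spin (-1/+1) and 0/1 readings only when unambiguous (a -1 or 0 present);
    # otherwise positive integers are 1-based state indices
    if (all(v %in% c(-1, 1)) && any(v == -1) && all(sizes == 2L))
      return(ifelse(v > 0, 2L, 1L))
    if (all(v %in% c(0, 1)) && any(v == 0) && all(sizes == 2L))
      return(as.integer(v) + 1L)
    if (all(v >= 1 & v <= sizes) && all(v == round(v)))
      return(as.integer(v))
    stop("numeric state not interpretable as -1/+1, 0/1 or state indices")
  }
  idx <- integer(n)
  for (i in seq_len(n)) {
    k <- match(as.character(state[i]), alphabets[[i]])
    if (is.na(k))
      stop(sprintf("state label '%s' not in alphabet of unit %s",
                   state[i], units[i]))
    idx[i] <- k
  }
  idx
}

#' Parse a state specification against a network
#'
#' @param x a [Network-class].
#' @param state a state specification (see [Network()]).
#' @return integer vector of 1-based per-unit state indices.
#' @export
parseState <- function(x, state) parseStateSpec(state, x@units, x@alphabets)

#' Compact label for a (sub)state
#'
#' For binary networks with single-letter unit names this produces the
#' conventional case-coded label (uppercase = ON). Otherwise labels are
#' joined as \code{unit=label} pairs.
#'
#' @param x a [Network-class].
#' @param state integer state indices (full state, or matching `units`).
#' @param units integer unit indices the state refers to (default: all).
#' @return character scalar.
#' @export
stateLabel <- function(x, state, units = seq_along(x@units)) {
  sizes <- lengths(x@alphabets)
  if (all(sizes[units] == 2L) && all(nchar(x@units[units]) == 1L)) {
    paste0(ifelse(state == 2L, toupper(x@units[units]),
                  tolower(x@units[units])), collapse = "")
  } else {
    paste(sprintf("%s=%s", x@units[units],
                  mapply(function(u, s) x@alphabets[[u]][s], units, state)),
          collapse = ",")
  }
}

#' Build a network of binary logistic units from a weight matrix
#'
#' Each unit \eqn{i} is a binary \eqn{\{-1, +1\}} unit whose probability of
#' switching ON is the logistic function
#' \eqn{p(U_i = 1 \mid u) = 1 / (1 + \exp(-k \sum_j w_{j,i} u_j))} of the
#' weighted sum of its inputs; the joint TPM is the product of the unit
#' factors (the units are conditionally independent given the previous
#' state). Incoming weights of every unit must sum to 1 (or to 0 for a unit
#' with no inputs, which is then an unconstrained coin-flip unit).
#'
#' @param weights numeric n x n matrix, \code{weights[j, i]} the connection
#'   from unit j to unit i.
#' @param k positive slope of the logistic; larger k = more deterministic.
#' @param state current state specification (see [Network()]).
#' @param units unit names; defaults to row/column names of \code{weights} or
#'   \code{LETTERS}.
#' @return a [Network-class].
#' @examples
#' w <- matrix(0, 2, 2); w[1, 2] <- 1
#' net <- logisticNetwork(w, k = 4, state = "Ab")
#' # p(B ON | A ON) = 1 / (1 + exp(-4)) = 0.98201
#' @export
logisticNetwork <- function(weights, k = 4, state = NULL, units = NULL) {
  weights <- as.matrix(weights)
  n <- nrow(weights)
  if (ncol(weights) != n) stop("weights must be square")
  if (!is.numeric(k) || length(k) != 1L || k <= 0)
    stop("k must be a positive scalar")
  colSumsW <- colSums(weights)
  bad <- !(abs(colSumsW - 1) <= 1e-8 | abs(colSumsW) <= 1e-8)
  if (any(bad))
    stop(sprintf(
      "incoming weights of unit %d sum to %.6g; columns must sum to 1 (or 0 for an input-less unit)",
      which(bad)[1], colSumsW[which(bad)[1]]))
  if (is.null(units)) {
    units <- colnames(weights)
    if (is.null(units)) units <- LETTERS[seq_len(n)]
  }
  sizes <- rep(2L, n)
  st <- stateTable(sizes)
  uVals <- (st == 2L) * 2 - 1        # state index -> {-1, +1}
  act <- uVals %*% weights           # D x n matrix of weighted inputs
  pOn <- 1 / (1 + exp(-k * act))
  factors <- lapply(seq_len(n), function(i) cbind(1 - pOn[, i], pOn[, i]))
  tpmFull <- expandRows(factors)
  if (is.null(state)) state <- rep(1L, n)
  net <- Network(tpmFull, units = units,
                 alphabets = rep(list(c("-1", "1")), n), state = state)
  net
}

#' @noRd
netSizes <- function(net) lengths(net@alphabets)

# Per-unit next-state conditionals p(next_i = a | full current state),
# derived from the joint TPM by marginalizing the other units' next states.
#' @noRd
unitFactorsU <- function(net) {
  sizes <- netSizes(net)
  st <- stateTable(sizes)
  lapply(seq_along(sizes), function(i) {
    ind <- matrix(0, nrow = nrow(st), ncol = sizes[i])
    ind[cbind(seq_len(nrow(st)), st[, i])] <- 1
    net@tpm %*% ind
  })
}

#' Diagnostic report on a network's TPM
#'
#' Pure report (never throws): row-sum deviations, out-of-range entries,
#' whether the joint TPM factors into the product of its per-unit next-state
#' marginals (the conditional-independence contract), and whether the table
#' is chance-level (identical rows: no cause-effect power).
#'
#' @param x a [Network-class], or a raw TPM matrix.
#' @return a list of class \code{"tpmDiagnostics"} with elements
#'   \code{valid}, \code{rowSumDeviation}, \code{badRows}, \code{negEntries},
#'   \code{independenceDeviation}, \code{conditionallyIndependent},
#'   \code{chanceLevel}, \code{messages}.
#' @export
validateTpm <- function(x) {
  if (is(x, "Network")) {
    net <- x
  } else {
    net <- tryCatch(Network(as.matrix(x)), error = function(e) NULL)
    if (is.null(net)) {
      tp <- as.matrix(x)
      rs <- rowSums(tp)
      out <- list(valid = FALSE,
                  rowSumDeviation = max(abs(rs - 1)),
                  badRows = which(abs(rs - 1) > 1e-8),
                  negEntries = sum(tp < 0),
                  independenceDeviation = NA_real_,
                  conditionallyIndependent = NA,
                  chanceLevel = NA,
                  messages = "matrix is not a valid TPM")
      class(out) <- "tpmDiagnostics"
      return(out)
    }
  }
  tp <- net@tpm
  rs <- rowSums(tp)
  badRows <- which(abs(rs - 1) > 1e-8)
  neg <- sum(tp < 0)
  rebuilt <- expandRows(unitFactorsU(net))
  indDev <- max(abs(rebuilt - tp))
  chance <- max(abs(sweep(tp, 2, colMeans(tp)))) <= 1e-10
  msgs <- character(0)
  if (length(badRows)) msgs <- c(msgs, sprintf(
    "row-sum violation in rows: %s", paste(badRows, collapse = ", ")))
  if (neg > 0) msgs <- c(msgs, sprintf("%d negative entries", neg))
  if (indDev > 1e-12) msgs <- c(msgs, sprintf(
    "joint differs from product of unit marginals by %.3g", indDev))
  if (chance) msgs <- c(msgs, "chance-level table: no cause-effect power")
  out <- list(valid = length(badRows) == 0L && neg == 0L,
              rowSumDeviation = max(abs(rs - 1)),
              badRows = badRows,
              negEntries = neg,
              independenceDeviation = indDev,
              conditionallyIndependent = indDev <= 1e-12,
              chanceLevel = chance,
              messages = msgs)
  class(out) <- "tpmDiagnostics"
  out
}

#' @export
print.tpmDiagnostics <- function(x, ...) {
  cat("TPM diagnostics\n")
  cat(sprintf("  valid (stochastic, non-negative): %s\n", x$valid))
  cat(sprintf("  max row-sum deviation:            %.3g\n", x$rowSumDeviation))
  cat(sprintf("  conditionally independent:        %s (max dev %.3g)\n",
              x$conditionallyIndependent, x$independenceDeviation))
  cat(sprintf("  chance-level (no power):          %s\n", x$chanceLevel))
  for (m in x$messages) cat("  note:", m, "\n")
  invisible(x)
}

#' @rdname phistruct-generics
#' @export
setMethod("unitNames", "Network", function(x) x@units)

#' @rdname phistruct-generics
#' @export
setMethod("alphabets", "Network", function(x) x@alphabets)

#' @rdname phistruct-generics
#' @export
setMethod("tpm", "Network", function(x) x@tpm)

#' @rdname phistruct-generics
#' @export
setMethod("currentState", "Network", function(x) x@state)

setMethod("show", "Network", function(object) {
  sizes <- netSizes(object)
  cat(sprintf("Network of %d units (%s), state space %d\n",
              length(object@units),
              paste(object@units, collapse = ", "), prod(sizes)))
  cat(sprintf("  current state: %s\n",
              stateLabel(object, object@state)))
  cat(sprintf("  alphabet sizes: %s\n", paste(sizes, collapse = " ")))
  invisible(object)
})
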