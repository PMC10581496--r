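# Serialization: network spec files (JSON / YAML), tab-delimited TPMs,
# Phi-structure output, and run configuration.
#
# All state-indexed tables are written row-major in the little-endian state
# order (unit 1 varies fastest); the TSV header declares the order so files
# are self-describing. Numbers serialize with 12 significant digits;
# comparisons in code always use tolerances, never string equality.

#' @noRd
ioDigits <- 12L

#' Read a network specification file
#'
#' Accepts JSON or YAML (by extension, or tried in that order) containing
#' either an explicit TPM (\code{units}, optional \code{alphabets},
#' \code{tpm} as a list of rows in little-endian state order, \code{state})
#' or a logistic specification (\code{weights} as a list of rows
#' \code{w[j][i]}, \code{k}, \code{state}). States may be compact case-coded
#' labels (e.g. \code{"Abc"}), per-unit labels, or 1-based indices.
#'
#' @param path file path.
#' @return a [Network-class].
#' @export
readNetwork <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  spec <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  networkFromSpec(spec)
}

#' @noRd
networkFromSpec <- function(spec) {
  if (!is.null(spec$weights)) {
    w <- if (is.matrix(spec$weights)) spec$weights else
      do.call(rbind, lapply(spec$weights, as.numeric))
    if (is.null(spec$k)) stop("logistic spec requires field 'k'")
    units <- spec$units %||% LETTERS[seq_len(nrow(w))]
    return(logisticNetwork(w, k = as.numeric(spec$k),
                           state = spec$state %||% NULL, units = units))
  }
  if (is.null(spec$tpm)) stop("network spec needs either 'tpm' or 'weights'")
  tpmM <- if (is.matrix(spec$tpm)) spec$tpm else
    do.call(rbind, lapply(spec$tpm, as.numeric))
  alph <- NULL
  if (!is.null(spec$alphabets))
    alph <- lapply(spec$alphabets, as.character)
  units <- spec$units %||% NULL
  rs <- rowSums(tpmM)
  bad <- which(abs(rs - 1) > 1e-8)
  if (length(bad))
    stop(sprintf("non-stochastic TPM: row %d sums to %.10g", bad[1], rs[bad[1]]))
  Network(tpmM, units = units, alphabets = alph, state = spec$state %||% NULL)
}

#' Write a network specification file
#'
#' @param net a [Network-class].
#' @param path output path; \code{.yaml}/\code{.yml} selects YAML, anything
#'   else JSON.
#' @return invisibly, the path.
#' @export
writeNetwork <- function(net, path) {
  spec <- list(
    units = net@units,
    alphabets = net@alphabets,
    stateOrder = "little-endian (unit 1 varies fastest)",
    # states as alphabet labels: label parsing is unambiguous on re-read
    state = vapply(seq_along(net@units), function(i)
      net@alphabets[[i]][net@state[i]], character(1)),
    # full precision: a written network re-reads bit-identically (JSON)
    tpm = lapply(seq_len(nrow(net@tpm)), function(i) net@tpm[i, ])
  )
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(spec, path, precision = 17L)
  } else {
    writeLines(jsonlite::toJSON(spec, auto_unbox = TRUE, digits = I(17),
                                pretty = TRUE), path)
  }
  invisible(path)
}

#' Export a TPM as a tab-delimited matrix
#'
#' One comment header line declares the state ordering; rows are current
#' states, columns next states.
#'
#' @param net a [Network-class] (or TPM matrix).
#' @param path output path.
#' @return invisibly, the path.
#' @export
exportTpm <- function(net, path) {
  tp <- if (is(net, "Network")) net@tpm else as.matrix(net)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# state-order: little-endian (unit 1 fastest); rows = current state, columns = next state", con)
  utils::write.table(signif(tp, ioDigits), con, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Import a tab-delimited TPM
#'
#' @param path file written by [exportTpm()] (or any headerless tab matrix;
#'   leading \code{#} lines are skipped).
#' @param ... passed to [Network()] (units, alphabets, state).
#' @return a [Network-class].
#' @export
importTpm <- function(path, ...) {
  tp <- as.matrix(utils::read.table(path, sep = "\t", comment.char = "#",
                                    header = FALSE))
  dimnames(tp) <- NULL
  Network(tp, ...)
}

#' @noRd
substateRecord <- function(net, units, states) {
  # both label and index forms, so files are readable and re-computable
  list(units = net@units[units],
       states = vapply(seq_along(units), function(i)
         net@alphabets[[units[i]]][states[i]], character(1)),
       unitIndices = as.integer(units),
       stateIndices = as.integer(states),
       label = stateLabel(net, states, units))
}

#' Serialize a Phi-structure to JSON
#'
#' Stable key ordering and a per-component phi ledger, so the total
#' \eqn{\Phi} can be re-derived from the file and files diff cleanly.
#'
#' @param structure a [PhiStructure-class].
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeStructure <- function(structure, path) {
  cx <- structure@complex
  net <- cx@network
  dRecs <- lapply(structure@distinctions, function(d) list(
    mechanism = substateRecord(net, d@mechanism, d@mechanismState),
    cause = substateRecord(net, d@causeUnits, d@causeStates),
    effect = substateRecord(net, d@effectUnits, d@effectStates),
    phiCause = signif(d@phiCause, ioDigits),
    phiEffect = signif(d@phiEffect, ioDigits),
    phi = signif(d@phi, ioDigits)))
  rRecs <- lapply(structure@relations, function(r) list(
    distinctions = r@members,
    degree = length(r@members),
    nFaces = length(r@faces),
    jointPurview = substateRecord(net, r@purviewUnits, r@purviewStates),
    phi = signif(r@phi, ioDigits)))
  out <- list(
    complex = list(
      units = net@units[cx@members],
      state = stateLabel(net, cx@state, cx@members),
      phiSystem = signif(cx@phi, ioDigits),
      rank = cx@rank),
    nCandidateMechanisms = structure@nCandidateMechanisms,
    nDistinctions = length(structure@distinctions),
    nRelations = length(structure@relations),
    distinctions = dRecs,
    relations = rRecs,
    phiLedger = list(
      sumPhiDistinctions = signif(structure@phiDistinctions, ioDigits),
      sumPhiRelations = signif(structure@phiRelations, ioDigits)),
    Phi = signif(structure@phi, ioDigits))
  writeLines(jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE, null = "null"), path)
  invisible(path)
}

#' Re-read a serialized Phi-structure (summary form)
#'
#' Returns the parsed JSON list; the bookkeeping identity
#' \code{Phi == sumPhiDistinctions + sumPhiRelations} can be re-checked from
#' it.
#'
#' @param path file written by [writeStructure()].
#' @return a list.
#' @export
readStructure <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = FALSE)
}

#' Run configuration
#'
#' Bundles the tunable knobs of the analysis pipeline with their defaults.
#' A configuration round-trips through YAML.
#'
#' @param tolerance absolute probability/phi comparison tolerance.
#' @param maxUnits cap on exhaustive subset/partition scans.
#' @param maxDistinctions cap on the relation enumeration.
#' @param tieBreak tie-break policy name for the maximal cause-effect state.
#' @param logLevel "quiet" or "info".
#' @return a list of class \code{"phiConfig"}.
#' @export
phiConfig <- function(tolerance = 1e-10, maxUnits = 8L,
                      maxDistinctions = 20L,
                      tieBreak = c("phi", "index"),
                      logLevel = c("info", "quiet")) {
  structure(list(tolerance = tolerance,
                 maxUnits = as.integer(maxUnits),
                 maxDistinctions = as.integer(maxDistinctions),
                 tieBreak = match.arg(tieBreak),
                 logLevel = match.arg(logLevel)),
            class = "phiConfig")
}

#' @rdname phiConfig
#' @param config a \code{"phiConfig"}.
#' @param path file path.
#' @export
writeConfig <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname phiConfig
#' @export
readConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  phiConfig(tolerance = raw$tolerance, maxUnits = raw$maxUnits,
            maxDistinctions = raw$maxDistinctions, tieBreak = raw$tieBreak,
            logLevel = raw$logLevel)
}

# apply a config to the session options used by the pipeline
#' @noRd
applyConfig <- function(config) {
  options(phistruct.tolerance = config$tolerance,
          phistruct.maxUnits = config$maxUnits,
          phistruct.maxDistinctions = config$maxDistinctions)
  invisible(config)
}
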