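# Internal state-space machinery.
#
# Full states of an n-unit system are enumerated in mixed-radix little-endian
# order: unit 1 varies fastest. This ordering is fixed for all file formats
# and round-trips bit-exactly through serialization.

#' @noRd
stateTable <- function(sizes) {
  n <- length(sizes)
  D <- prod(sizes)
  tab <- matrix(1L, nrow = D, ncol = max(n, 1L))
  if (n == 0L) return(tab[, 0, drop = FALSE])
  repEach <- 1L
  for (i in seq_len(n)) {
    tab[, i] <- rep(rep(seq_len(sizes[i]), each = repEach), length.out = D)
    repEach <- repEach * sizes[i]
  }
  tab
}

#' @noRd
stateToIndex <- function(state, sizes) {
  if (length(state) == 0L) return(1L)
  mult <- cumprod(c(1, sizes[-length(sizes)]))
  as.integer(1 + sum((state - 1) * mult))
}

#' @noRd
indexToState <- function(idx, sizes) {
  idx <- as.integer(idx) - 1L
  out <- integer(length(sizes))
  for (i in seq_along(sizes)) {
    out[i] <- idx %% sizes[i] + 1L
    idx <- idx %/% sizes[i]
  }
  out
}

# Combine per-unit distributions (ordered by ascending unit) into a joint
# distribution over the little-endian product space: earlier units fastest.
#' @noRd
combineDists <- function(dists) {
  Reduce(function(acc, d) as.vector(outer(acc, d)), dists)
}

# Row-wise product expansion of per-unit probability matrices (all with the
# same row space); column index of the result runs little-endian over the
# units in list order.
#' @noRd
expandRows <- function(mats) {
  out <- matrix(1, nrow = nrow(mats[[1L]]), ncol = 1L)
  for (m in mats) {
    out <- out[, rep(seq_len(ncol(out)), times = ncol(m)), drop = FALSE] *
      m[, rep(seq_len(ncol(m)), each = ncol(out)), drop = FALSE]
  }
  out
}

#' @noRd
phiTol <- function() getOption("phistruct.tolerance", 1e-10)

#' @noRd
maxUnitsCap <- function() getOption("phistruct.maxUnits", 8L)

#' @noRd
bitsOf <- function(mask, n) which(bitwAnd(mask, bitwShiftL(1L, seq_len(n) - 1L)) > 0L)

#' @noRd
maskOf <- function(units) {
  if (length(units) == 0L) return(0L)
  as.integer(sum(bitwShiftL(1L, as.integer(units) - 1L)))
}

# log2 with the 0 * log(0) := 0 convention applied by callers; plain guard here
#' @noRd
safeLog2Ratio <- function(num, den) {
  if (num <= 0) return(0)
  log2(num / den)
}
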