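# Test network builders, independent of the package's construction paths
# where it matters (joint TPMs assembled by explicit products / loops).

# local seed without disturbing the session RNG
localSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# own little-endian state table (independent of the package's)
oStateTable <- function(sizes) {
  grid <- do.call(expand.grid, lapply(sizes, seq_len))
  as.matrix(grid)   # expand.grid varies the first factor fastest
}

oIndex <- function(state, sizes) {
  mult <- cumprod(c(1, sizes[-length(sizes)]))
  as.integer(1 + sum((state - 1) * mult))
}

# random product-form TPM over arbitrary alphabets, assembled by explicit
# per-entry products (not the package's expandRows)
rProductTpm <- function(sizes, seed) {
  localSeed(seed, {
    D <- prod(sizes)
    st <- oStateTable(sizes)
    factors <- lapply(seq_along(sizes), function(i) {
      m <- matrix(runif(D * sizes[i]) + 0.05, D, sizes[i])
      m / rowSums(m)
    })
    tpm <- matrix(1, D, D)
    for (u in seq_len(D)) for (v in seq_len(D)) {
      p <- 1
      for (i in seq_along(sizes)) p <- p * factors[[i]][u, st[v, i]]
      tpm[u, v] <- p
    }
    tpm
  })
}

rProductNetwork <- function(n, seed, sizes = rep(2L, n), state = NULL) {
  tpmM <- rProductTpm(sizes, seed)
  if (is.null(state))
    state <- localSeed(seed + 1000L, sapply(sizes, function(s) sample.int(s, 1)))
  Network(tpmM, units = LETTERS[seq_len(n)],
          alphabets = lapply(sizes, function(s) as.character(seq_len(s) - 1)),
          state = state)
}

# deterministic permutation network (binary units): nextIndex[i] = image of i
permutationNetwork <- function(perm, n, state = rep(1L, n)) {
  D <- 2^n
  stopifnot(length(perm) == D)
  tpmM <- matrix(0, D, D)
  tpmM[cbind(seq_len(D), perm)] <- 1
  Network(tpmM, units = LETTERS[seq_len(n)], state = state)
}

# deterministic copy chain A -> B -> C (B' = A, C' = B, A' = A)
copyChainNet <- function(state = c(2L, 2L, 1L)) {
  sizes <- rep(2L, 3)
  st <- oStateTable(sizes)
  nxt <- cbind(st[, 1], st[, 1], st[, 2])   # A holds, B copies A, C copies B
  perm <- apply(nxt, 1, oIndex, sizes = sizes)
  permutationNetwork(perm, 3, state)
}

# two disconnected reciprocal copy pairs (A<->B, C<->D), logistic k
copyPairsNet <- function(k = 4, state = c(2L, 1L, 2L, 1L)) {
  w <- matrix(0, 4, 4)
  w[2, 1] <- 1; w[1, 2] <- 1
  w[4, 3] <- 1; w[3, 4] <- 1
  logisticNetwork(w, k = k, state = state)
}

# synthetic distinction for relation tests
synthDistinction <- function(cu, cs, eu, es, phi = 1,
                             mech = max(c(cu, eu)) + 1L) {
  new("Distinction",
      mechanism = as.integer(mech), mechanismState = rep(1L, length(mech)),
      causeUnits = as.integer(cu), causeStates = as.integer(cs),
      effectUnits = as.integer(eu), effectStates = as.integer(es),
      phiCause = phi, phiEffect = phi, phi = phi, congruent = TRUE)
}
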