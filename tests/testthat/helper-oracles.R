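# Brute-force oracles: independent re-implementations by explicit
# enumeration over the joint TPM, used to pin expected values for the
# package's factorized computations.

# effect TPM p_e(sbar | s) = p(sbar | s, w): slice the joint at the
# background's current state and marginalize background next-states
oEffectTpm <- function(tpmM, sizes, membersIdx, u) {
  n <- length(sizes)
  st <- oStateTable(sizes)
  bg <- setdiff(seq_len(n), membersIdx)
  sSizes <- sizes[membersIdx]
  Ds <- prod(sSizes)
  sysStates <- oStateTable(sSizes)
  Te <- matrix(0, Ds, Ds)
  for (si in seq_len(Ds)) {
    full <- integer(n)
    full[membersIdx] <- sysStates[si, ]
    full[bg] <- u[bg]
    row <- tpmM[oIndex(full, sizes), ]
    for (vi in seq_len(Ds)) {
      # sum over all full next states consistent with the member pattern
      tot <- 0
      for (fullNext in seq_len(nrow(st))) {
        if (all(st[fullNext, membersIdx] == sysStates[vi, ]))
          tot <- tot + row[fullNext]
      }
      Te[si, vi] <- tot
    }
  }
  Te
}

# posterior weights over prior background states given current state u,
# uniform prior over prior universe states
oCauseWeights <- function(tpmM, sizes, membersIdx, u) {
  n <- length(sizes)
  st <- oStateTable(sizes)
  bg <- setdiff(seq_len(n), membersIdx)
  uIdx <- oIndex(u, sizes)
  denom <- sum(tpmM[, uIdx])
  if (length(bg) == 0L) return(1)
  bSizes <- sizes[bg]
  bStates <- oStateTable(bSizes)
  w <- numeric(nrow(bStates))
  for (bi in seq_len(nrow(bStates))) {
    tot <- 0
    for (r in seq_len(nrow(st))) {
      if (all(st[r, bg] == bStates[bi, ])) tot <- tot + tpmM[r, uIdx]
    }
    w[bi] <- tot / denom
  }
  w
}

# cause TPM p_c(s | sbar): per-unit mixture over prior background states
# weighted by their posterior, factors recombined by product
oCauseTpm <- function(tpmM, sizes, membersIdx, u) {
  n <- length(sizes)
  st <- oStateTable(sizes)
  bg <- setdiff(seq_len(n), membersIdx)
  sSizes <- sizes[membersIdx]
  Ds <- prod(sSizes)
  sysStates <- oStateTable(sSizes)
  wts <- oCauseWeights(tpmM, sizes, membersIdx, u)
  bStates <- if (length(bg)) oStateTable(sizes[bg]) else
    matrix(integer(0), 1, 0)
  # p(next unit m = a | full prior state)
  unitMarg <- function(mUnit, a, fullPrior) {
    row <- tpmM[oIndex(fullPrior, sizes), ]
    tot <- 0
    for (v in seq_len(nrow(st))) if (st[v, mUnit] == a) tot <- tot + row[v]
    tot
  }
  Tc <- matrix(0, Ds, Ds)
  for (sbi in seq_len(Ds)) {
    for (si in seq_len(Ds)) {
      p <- 1
      for (k in seq_along(membersIdx)) {
        mix <- 0
        for (bi in seq_len(nrow(bStates))) {
          fullPrior <- integer(n)
          fullPrior[membersIdx] <- sysStates[sbi, ]
          if (length(bg)) fullPrior[bg] <- bStates[bi, ]
          mix <- mix + wts[bi] * unitMarg(membersIdx[k],
                                          sysStates[si, k], fullPrior)
        }
        p <- p * mix
      }
      Tc[sbi, si] <- p
    }
  }
  Tc
}

# Eq-28-style effect repertoire from a system effect TPM by explicit loops:
# per-unit p_e(z_i | m) averaging over uniform states of S \ M
oEffectRepertoire <- function(Te, sSizes, M, m, Z) {
  Ds <- prod(sSizes)
  sysStates <- oStateTable(sSizes)
  X <- setdiff(seq_along(sSizes), M)
  perUnit <- function(zUnit, a) {
    tot <- 0; cnt <- 0
    for (si in seq_len(Ds)) {
      if (length(M) && !all(sysStates[si, M] == m)) next
      cnt <- cnt + 1
      # marginal of unit zUnit's next state from the joint row
      pz <- 0
      for (vi in seq_len(Ds)) {
        if (sysStates[vi, zUnit] == a) pz <- pz + Te[si, vi]
      }
      tot <- tot + pz
    }
    tot / cnt
  }
  zStates <- oStateTable(sSizes[Z])
  tab <- numeric(nrow(zStates))
  for (zi in seq_len(nrow(zStates))) {
    p <- 1
    for (k in seq_along(Z)) p <- p * perUnit(Z[k], zStates[zi, k])
    tab[zi] <- p
  }
  tab
}

# partitioned per-unit probability (system level): unit j with inputs from X
# noised, remaining inputs held at `cond`
oPartitionedUnit <- function(Tmat, sSizes, j, X, cond, target) {
  sysStates <- oStateTable(sSizes)
  keep <- setdiff(seq_along(sSizes), X)
  tot <- 0; cnt <- 0
  for (si in seq_len(nrow(sysStates))) {
    if (length(keep) && !all(sysStates[si, keep] == cond[keep])) next
    cnt <- cnt + 1
    pz <- 0
    for (vi in seq_len(nrow(sysStates))) {
      if (sysStates[vi, j] == target) pz <- pz + Tmat[si, vi]
    }
    tot <- tot + pz
  }
  tot / cnt
}

# naive phi_s: all direction labelings of all set partitions, no dedup, no
# early exit; phi evaluated through oPartitionedUnit from the system TPMs
oSystemPhi <- function(sys) {
  Te <- effectTpm(sys); Tc <- causeTpm(sys)
  sSizes <- lengths(alphabets(sys@network)[members(sys)])
  ns <- length(sSizes)
  s <- sys@state
  sIdx <- oIndex(s, sSizes)
  # maximal states by ii (straight formulas)
  iie <- {
    p <- Te[sIdx, ]; unc <- colMeans(Te)
    v <- numeric(length(p)); pos <- p > 0
    v[pos] <- p[pos] * log2(p[pos] / unc[pos]); v
  }
  iic <- {
    p <- Tc[, sIdx]; v <- numeric(length(p)); pos <- p > 0
    v[pos] <- (p[pos] / sum(p)) * log2(p[pos] / mean(p)); v
  }
  if (max(iie) <= 1e-10 || max(iic) <= 1e-10) return(0)
  se <- which.max(iie); sc <- which.max(iic)
  seState <- oStateTable(sSizes)[se, ]
  scState <- oStateTable(sSizes)[sc, ]
  # all set partitions (own enumeration via recursive assignment)
  partitionsOf <- function(n) {
    res <- list()
    assign_ <- function(i, lab, mx) {
      if (i > n) { res[[length(res) + 1L]] <<- lab; return(invisible(NULL)) }
      for (b in seq_len(mx + 1L)) assign_(i + 1L, c(lab, b), max(mx, b))
    }
    assign_(2L, c(1L), 1L)
    res
  }
  dirs3 <- function(k) as.matrix(expand.grid(rep(list(1:3), k)))
  bestR <- Inf; bestPhi <- -Inf
  for (lab in partitionsOf(ns)) {
    k <- max(lab)
    if (k < 2L) next
    blocks <- lapply(seq_len(k), function(b) which(lab == b))
    dg <- dirs3(k)
    for (r in seq_len(nrow(dg))) {
      X <- vector("list", k)
      for (i in seq_len(k)) {
        if (dg[r, i] %in% c(1L, 3L)) X[[i]] <- setdiff(seq_len(ns), blocks[[i]])
        else {
          src <- integer(0)
          for (jj in seq_len(k))
            if (jj != i && dg[r, jj] %in% c(2L, 3L)) src <- c(src, blocks[[jj]])
          X[[i]] <- src
        }
      }
      norm <- sum(sapply(seq_len(k), function(i)
        length(blocks[[i]]) * length(X[[i]])))
      peTheta <- 1; pcTheta <- 1
      for (i in seq_len(k)) for (j in blocks[[i]]) {
        peTheta <- peTheta *
          oPartitionedUnit(Te, sSizes, j, X[[i]], s, seState[j])
        pcTheta <- pcTheta *
          oPartitionedUnit(Tc, sSizes, j, X[[i]], scState, s[j])
      }
      pe <- Te[sIdx, se] * max(0, log2(Te[sIdx, se] / peTheta))
      pcSel <- Tc[sc, sIdx] / sum(Tc[, sIdx])
      pc <- pcSel * max(0, log2(Tc[sc, sIdx] / pcTheta))
      ph <- min(pe, pc)
      rr <- ph / norm
      if (rr < bestR - 1e-10 ||
          (abs(rr - bestR) <= 1e-10 && ph > bestPhi + 1e-10)) {
        bestR <- rr; bestPhi <- ph
      }
    }
  }
  max(bestPhi, 0)
}

# relation oracles on character-encoded (unit:state) tuple sets
oTuples <- function(units, states) {
  if (length(units) == 0L) return(character(0))
  paste0(units, ":", states)
}

oCommonOverlap <- function(tupleSets) Reduce(intersect, tupleSets)

# all faces of a distinction set given (cause, effect) tuple-set pairs
oFaces <- function(cePairs) {
  h <- length(cePairs)
  grid <- as.matrix(expand.grid(rep(list(1:3), h)))
  faces <- list()
  for (r in seq_len(nrow(grid))) {
    sets <- list()
    np <- 0L
    for (i in seq_len(h)) {
      if (grid[r, i] %in% c(1L, 3L)) { sets <- c(sets, list(cePairs[[i]]$cause)); np <- np + 1L }
      if (grid[r, i] %in% c(2L, 3L)) { sets <- c(sets, list(cePairs[[i]]$effect)); np <- np + 1L }
    }
    if (np < 2L) next
    ov <- oCommonOverlap(sets)
    if (length(ov)) faces[[length(faces) + 1L]] <- list(sel = grid[r, ], overlap = ov)
  }
  faces
}

# unpruned relation enumeration over all subsets of a distinction list
oRelationsUnpruned <- function(D) {
  nD <- length(D)
  cePairs <- lapply(D, function(d) list(
    cause = oTuples(d@causeUnits, d@causeStates),
    effect = oTuples(d@effectUnits, d@effectStates)))
  out <- list()
  for (sz in seq_len(nD)) {
    for (combo in utils::combn(nD, sz, simplify = FALSE)) {
      faces <- oFaces(cePairs[combo])
      if (length(faces) == 0L) next
      joint <- unique(unlist(lapply(faces, `[[`, "overlap")))
      perUnit <- sapply(combo, function(i)
        D[[i]]@phi / length(union(cePairs[[i]]$cause, cePairs[[i]]$effect)))
      phi <- min(perUnit) * length(joint)
      if (phi > 1e-10)
        out[[length(out) + 1L]] <- list(members = combo, phi = phi,
                                        nFaces = length(faces))
    }
  }
  out
}

# independent enumeration of Eq-38 disintegrating partitions by filtering
# all assignments of mechanism and purview elements to labeled slots
oDisintegrationCount <- function(nM, nZ) {
  # represent a partition canonically as a sorted set of "Mset|Zset" pairs
  seen <- new.env(parent = emptyenv())
  maxBlocks <- nM + nZ
  mAssign <- as.matrix(do.call(expand.grid, rep(list(seq_len(maxBlocks)), nM)))
  zAssign <- as.matrix(do.call(expand.grid, rep(list(seq_len(maxBlocks)), nZ)))
  for (ra in seq_len(nrow(mAssign))) {
    for (rb in seq_len(nrow(zAssign))) {
      labs <- sort(unique(c(mAssign[ra, ], zAssign[rb, ])))
      if (length(labs) < 2L) next
      pairs <- character(0)
      ok <- TRUE
      for (b in labs) {
        Mi <- which(mAssign[ra, ] == b)
        Zi <- which(zAssign[rb, ] == b)
        if (length(Mi) == nM && length(Zi) > 0L) { ok <- FALSE; break }
        pairs <- c(pairs, paste0("M{", paste(Mi, collapse = ","),
                                 "}Z{", paste(Zi, collapse = ","), "}"))
      }
      if (!ok) next
      key <- paste(sort(pairs), collapse = ";")
      seen[[key]] <- TRUE
    }
  }
  length(ls(seen))
}
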