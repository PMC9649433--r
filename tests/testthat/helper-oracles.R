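# Shared fixtures and independent oracles used across the suite. The
# oracles deliberately re-derive quantities along a different route than
# the implementation (explicit loops, pairwise comparisons, geometric
# checks) so agreement is evidence, not tautology.

# --- toy 5-position database from hand-checkable sequences ------------
# surface positions {1,2,4} carry rsa 0.5, the rest 0.1; threshold
# 0.3717 separates them.
toyDb <- function(extra = list()) {
  grid <- alignmentGrid("GGGGG")
  rsa <- c(0.5, 0.5, 0.1, 0.5, 0.1)
  seqs <- c(W = "WGGGG", A1 = "AGGGG", A2 = "GAGGG", G = "GGGGG")
  profs <- list(
    alleleProfile("A*01:01", seqs[["W"]], rsa),
    alleleProfile("A*02:01", seqs[["A1"]], rsa),
    alleleProfile("A*03:01", seqs[["A2"]], rsa),
    alleleProfile("B*01:01", seqs[["G"]], rsa))
  buildAlleleDb(grid, c(profs, extra))
}

# --- independent position-scan Snowflake oracle -----------------------
oracleSnowflake <- function(donorAlleles, recipientAlleles, db,
                            threshold = 0.3717) {
  seen <- character(0)
  for (d in unique(donorAlleles)) {
    if (d %in% recipientAlleles) next
    prof <- getProfile(db, d)
    dv <- strsplit(prof@alignedSeq, "")[[1]]
    for (pos in seq_along(dv)) {
      r <- prof@rsa[pos]
      if (is.na(r) || r < threshold || dv[pos] == "-") next
      carried <- FALSE
      for (ra in unique(recipientAlleles)) {
        rv <- strsplit(getProfile(db, ra)@alignedSeq, "")[[1]]
        if (rv[pos] == dv[pos]) { carried <- TRUE; break }
      }
      if (!carried) seen <- union(seen, paste0(pos, "_", dv[pos]))
    }
  }
  length(seen)
}

# --- exhaustive two-sample rank-test oracle ---------------------------
# enumerates every group assignment and computes U by direct pairwise
# comparison (not rank sums)
oracleRankP <- function(g0, g1) {
  pooled <- c(g0, g1)
  m <- length(g0); N <- length(pooled)
  U <- function(x, y)
    sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  mu <- m * (N - m) / 2
  obs <- abs(U(g0, g1) - mu)
  combos <- utils::combn(N, m)
  devs <- apply(combos, 2, function(ix)
    abs(U(pooled[ix], pooled[-ix]) - mu))
  mean(devs >= obs - 1e-12)
}

# --- geometric occlusion check ----------------------------------------
# TRUE when every Shrake-Rupley test point of atom i lies strictly
# inside some other atom's probe-inflated sphere
allPointsOccluded <- function(atoms, i, probe = 1.4, nPoints = 960) {
  S <- spherePoints(nPoints)
  Ri <- atoms$radius[i] + probe
  pts <- sweep(S * Ri, 2, as.numeric(atoms[i, c("x", "y", "z")]), "+")
  others <- setdiff(seq_len(nrow(atoms)), i)
  covered <- rep(FALSE, nPoints)
  for (j in others) {
    Rj <- atoms$radius[j] + probe
    d2 <- (pts[, 1] - atoms$x[j])^2 + (pts[, 2] - atoms$y[j])^2 +
      (pts[, 3] - atoms$z[j])^2
    covered <- covered | (d2 < Rj^2)
  }
  all(covered)
}

# small random atom cloud for occlusion property tests
randomAtoms <- function(n, spread = 6) {
  data.frame(x = runif(n, 0, spread), y = runif(n, 0, spread),
             z = runif(n, 0, spread),
             radius = sample(c(1.52, 1.55, 1.7, 1.8), n, replace = TRUE))
}

# shared small pool for matching/imputation tests (built once per run)
.sharedPool <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- makeAllelePool(simulationConfig(seed = 424242, nCases = 20))
    cache
  }
})
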