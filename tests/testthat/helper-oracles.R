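# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: charges are evaluated by a per-residue loop,
# clustering by from-scratch recomputation of cluster means on the original
# matrix, smoothing by the direct recursion.

PK_ORACLE <- c(Amino = 8.6, Carboxyl = 3.6, C = 8.5, D = 3.9, E = 4.1,
               H = 6.5, K = 10.8, R = 12.5, Y = 10.1)

# Direct two-sum Henderson-Hasselbalch evaluation, residue by residue.
oracleNetCharge <- function(seq, pH, pk = PK_ORACLE) {
  res <- strsplit(seq, "")[[1]]
  z <- 1 / (1 + 10^(pH - pk["Amino"])) - 1 / (1 + 10^(pk["Carboxyl"] - pH))
  for (r in res) {
    if (r %in% c("K", "R", "H")) z <- z + 1 / (1 + 10^(pH - pk[r]))
    if (r %in% c("D", "E", "C", "Y")) z <- z - 1 / (1 + 10^(pk[r] - pH))
  }
  unname(z)
}

# pH-grid-scan pI: coarse scan for the sign change, then a fine grid.
oracleGridPI <- function(seq, step = 1e-5) {
  coarse <- seq(0.01, 13.99, by = 0.01)
  z <- vapply(coarse, function(p) oracleNetCharge(seq, p), numeric(1))
  i <- which(z <= 0)[1]
  lo <- coarse[max(i - 1, 1)]
  hi <- coarse[i]
  fine <- seq(lo, hi, by = step)
  zf <- vapply(fine, function(p) oracleNetCharge(seq, p), numeric(1))
  fine[which.min(abs(zf))]
}

# From-scratch average-linkage agglomeration: cluster-pair means recomputed
# from the original matrix at every step (O(n^3)); ties broken by the
# lexicographically smallest pair of smallest-member labels.
oracleAvgLinkage <- function(D) {
  labs <- rownames(D)
  clusters <- as.list(seq_len(nrow(D)))
  members <- character(0)
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- NULL; bestd <- Inf; bestkey <- NULL
    for (a in seq_along(clusters)) for (b in seq_len(a - 1)) {
      dv <- mean(D[clusters[[b]], clusters[[a]], drop = FALSE])
      key <- sort(c(min(labs[clusters[[b]]]), min(labs[clusters[[a]]])))
      takes <- dv < bestd ||
        (dv == bestd && (key[1] < bestkey[1] ||
                         (key[1] == bestkey[1] && key[2] < bestkey[2])))
      if (takes) { bestd <- dv; best <- c(b, a); bestkey <- key }
    }
    newc <- c(clusters[[best[1]]], clusters[[best[2]]])
    members <- c(members, paste(sort(labs[newc]), collapse = ","))
    heights <- c(heights, bestd)
    clusters[[best[1]]] <- newc
    clusters[[best[2]]] <- NULL
  }
  list(members = members, heights = heights)
}

# Direct recursion for exponential smoothing with damping d.
oracleSmooth <- function(x, d) {
  s <- numeric(length(x))
  s[1] <- x[1]
  for (t in seq_along(x)[-1]) s[t] <- (1 - d) * x[t] + d * s[t - 1]
  s
}

# Random protein sequence from the uniform residue alphabet.
randomSeq <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}

# Build an ultrametric dissimilarity matrix from a random binary tree by
# assigning decreasing heights to nested merges.
makeUltrametric <- function(n, seed) {
  set.seed(seed)
  labs <- sprintf("u%02d", seq_len(n))
  groups <- as.list(seq_len(n))
  D <- matrix(0, n, n, dimnames = list(labs, labs))
  h <- 0
  while (length(groups) > 1) {
    h <- h + runif(1, 0.5, 1.5)
    pick <- sample(length(groups), 2)
    g1 <- groups[[pick[1]]]; g2 <- groups[[pick[2]]]
    D[g1, g2] <- h; D[g2, g1] <- h
    groups[[pick[1]]] <- c(g1, g2)
    groups[[pick[2]]] <- NULL
  }
  D
}
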