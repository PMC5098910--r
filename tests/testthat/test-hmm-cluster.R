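test_that("toDissimilarity applies the log map, floor, and symmetrization", {
  P <- matrix(c(1, 0.5, 0.25, 1), 2, 2,
              dimnames = list(c("a", "b"), c("a", "b")))
  D <- toDissimilarity(P)
  expect_equal(D["a", "a"], 0)
  expect_equal(D["a", "b"], mean(c(-log(0.5), -log(0.25))))
  expect_equal(D, t(D))

  P0 <- matrix(c(1, 0, 0, 1), 2, 2, dimnames = dimnames(P))
  D0 <- toDissimilarity(P0)
  expect_equal(D0["a", "b"], -log(0.001), tolerance = 1e-12)
  expect_equal(D0["a", "b"], 6.9078, tolerance = 1e-4)

  # floor-all mode keeps the map monotone below the floor; zero-only does not
  tiny <- matrix(c(1, 1e-6, 1e-6, 1), 2, 2, dimnames = dimnames(P))
  expect_equal(toDissimilarity(tiny)["a", "b"], -log(0.001))
  expect_equal(toDissimilarity(tiny, zero_only = TRUE)["a", "b"], -log(1e-6))
})

test_that("toDissimilarity is monotone: higher probability, lower distance", {
  set.seed(41)
  p <- sort(runif(30))
  n <- length(p)
  P <- diag(n)
  P[upper.tri(P)] <- p[seq_len(n * (n - 1) / 2) %% length(p) + 1]
  P <- pmax(P, t(P)); diag(P) <- 1
  dimnames(P) <- list(sprintf("x%02d", 1:n), sprintf("x%02d", 1:n))
  D <- toDissimilarity(P)
  up <- upper.tri(P)
  ord <- order(P[up])
  expect_true(all(diff(D[up][ord]) <= 1e-12))
})

test_that("readProbabilityMatrix reads TSV/CSV and rescales percentages", {
  m <- matrix(c(1, 0.4, 0.4, 1), 2, 2,
              dimnames = list(c("a", "b"), c("a", "b")))
  f <- tempfile(fileext = ".tsv")
  write.table(m, f, sep = "\t", quote = FALSE, col.names = NA)
  expect_equal(readProbabilityMatrix(f), m)

  fc <- tempfile(fileext = ".csv")
  write.table(m * 100, fc, sep = ",", quote = FALSE, col.names = NA)
  expect_message(pm <- readProbabilityMatrix(fc), "percentages")
  expect_equal(pm, m)
})

test_that("averageLinkage: two items merge once at their dissimilarity", {
  D <- matrix(c(0, 2, 2, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  tree <- averageLinkage(D)
  expect_equal(tree$height, 2)
  expect_equal(nrow(tree$merge), 1)
  expect_error(averageLinkage(matrix(c(0, NA, NA, 0), 2, 2)), "NA")
})

test_that("averageLinkage equals the O(n^3) brute-force oracle on a hand matrix", {
  labs <- c("a", "b", "c", "d")
  D <- matrix(c(0, 1, 6, 8,
                1, 0, 5, 9,
                6, 5, 0, 2,
                8, 9, 2, 0), 4, 4, dimnames = list(labs, labs))
  tree <- averageLinkage(D)
  mt <- mergeTable(tree)
  oracle <- oracleAvgLinkage(D)
  expect_identical(mt$members, oracle$members)
  expect_equal(mt$height, oracle$heights)
  # known geometry: {a,b} at 1, {c,d} at 2, root at mean(6,8,5,9) = 7
  expect_equal(mt$height, c(1, 2, 7))
})

test_that("averageLinkage matches the oracle and hclust on random matrices", {
  set.seed(47)
  for (trial in 1:30) {
    n <- sample(3:8, 1)
    M <- matrix(runif(n * n, 0.1, 10), n, n)
    D <- (M + t(M)) / 2
    diag(D) <- 0
    dimnames(D) <- list(sprintf("r%02d", 1:n), sprintf("r%02d", 1:n))
    tree <- averageLinkage(D)
    mt <- mergeTable(tree)
    oracle <- oracleAvgLinkage(D)
    expect_identical(mt$members, oracle$members)
    expect_equal(mt$height, oracle$heights, tolerance = 1e-12)
    # independent reference implementation agrees on merge heights
    hc <- stats::hclust(stats::as.dist(D), method = "average")
    expect_equal(sort(tree$height), sort(hc$height), tolerance = 1e-12)
    expect_true(all(diff(tree$height) >= -1e-12))  # monotone merges
  }
})

test_that("clustering is invariant under permutation of input order", {
  set.seed(53)
  n <- 7
  M <- matrix(runif(n * n, 0.5, 5), n, n)
  D <- (M + t(M)) / 2; diag(D) <- 0
  dimnames(D) <- list(letters[1:n], letters[1:n])
  perm <- sample(n)
  mt1 <- mergeTable(averageLinkage(D))
  mt2 <- mergeTable(averageLinkage(D[perm, perm]))
  expect_identical(mt1$members, mt2$members)
  expect_equal(mt1$height, mt2$height, tolerance = 1e-12)
})

test_that("exact ties are broken by the lexicographically smallest label pair", {
  labs <- c("b", "a", "c")
  D <- matrix(c(0, 1, 1,
                1, 0, 1,
                1, 1, 0), 3, 3, dimnames = list(labs, labs))
  mt <- mergeTable(averageLinkage(D))
  expect_identical(mt$members[1], "a,b")
})

test_that("cophenetic distances reproduce constructed ultrametrics", {
  for (seed in 1:5) {
    D <- makeUltrametric(8, seed = seed)
    tree <- averageLinkage(D)
    C <- as.matrix(stats::cophenetic(tree))
    expect_equal(C[rownames(D), colnames(D)], D, tolerance = 1e-9)
  }
})

test_that("planted blocks are recovered at the obvious cut", {
  gen <- genBlockMatrix(c(5, 5), seed = 61)
  D <- toDissimilarity(gen$P)
  tree <- averageLinkage(D)
  k2 <- stats::cutree(tree, k = 2)
  expect_equal(length(unique(paste(k2, gen$blocks))), 2)

  one <- genBlockMatrix(7, seed = 62, within_mean = 0.9)
  Done <- toDissimilarity(one$P)
  t1 <- averageLinkage(Done)
  expect_lt(max(t1$height), log(1 / 0.5))
})

test_that("toNewick writes parent-child branch lengths that ape can parse", {
  D <- matrix(c(0, 2, 2, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  nwk <- toNewick(averageLinkage(D))
  expect_match(nwk, "^\\(.*\\);$")
  ph <- ape::read.tree(text = nwk)
  expect_setequal(ph$tip.label, c("a", "b"))
  expect_equal(sort(ph$edge.length), c(2, 2))

  # caterpillar: nested depth 3 for 4 leaves
  labs <- c("a", "b", "c", "d")
  Dc <- matrix(c(0, 1, 4, 8,
                 1, 0, 4, 8,
                 4, 4, 0, 8,
                 8, 8, 8, 0), 4, 4, dimnames = list(labs, labs))
  nwkc <- toNewick(averageLinkage(Dc))
  depth <- 0; cur <- 0
  for (ch in strsplit(nwkc, "")[[1]]) {
    if (ch == "(") { cur <- cur + 1; depth <- max(depth, cur) }
    if (ch == ")") cur <- cur - 1
  }
  expect_equal(depth, 3)

  # round-trip: tip-to-tip path lengths in the parsed tree equal twice the
  # merge heights (both leaves climb to their common ancestor)
  set.seed(67)
  M <- matrix(runif(36, 1, 9), 6, 6)
  D6 <- (M + t(M)) / 2; diag(D6) <- 0
  dimnames(D6) <- list(letters[1:6], letters[1:6])
  tr <- averageLinkage(D6)
  ph6 <- ape::read.tree(text = toNewick(tr))
  coph <- as.matrix(stats::cophenetic(tr))
  phDist <- ape::cophenetic.phylo(ph6)[rownames(coph), colnames(coph)]
  expect_equal(phDist, 2 * coph, tolerance = 1e-6)
})
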