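domtblLine <- function(target, tlen, query, eval) {
  sprintf("%s - %d %s - 120 %g 200.1 0.1 1 1 %g %g %g %g 10 100 5 95 3 97 0.9 -",
          target, tlen, query, eval, eval, eval, 180.0, 0.05)
}

test_that("readDomainHits parses the domtbl dialect and skips comments", {
  f <- tempfile()
  writeLines(c("#                     full sequence",
               "# target  acc tlen query ...",
               domtblLine("sp|P1|GCNA_MOUSE", 500, "protease", 1e-7),
               domtblLine("sp|P1|GCNA_MOUSE", 500, "zinc_finger", 1e-9),
               domtblLine("sp|P2|GCNA_HUMAN", 700, "hmg_box", 1e-6),
               "#"), f)
  hits <- readDomainHits(f, dialect = "hmmer3-domtbl")
  expect_equal(nrow(hits), 3)
  expect_equal(hits$evalue, c(1e-7, 1e-9, 1e-6))
  expect_equal(hits$length, c(500L, 500L, 700L))
  expect_equal(hits$species, c("MOUSE", "MOUSE", "HUMAN"))

  fEmpty <- tempfile()
  writeLines(c("# nothing", "# here"), fEmpty)
  expect_equal(nrow(readDomainHits(fEmpty, dialect = "hmmer3-domtbl")), 0)

  fBad <- tempfile()
  writeLines(c(domtblLine("a", 10, "protease", 1e-8), "b c"), fBad)
  expect_error(readDomainHits(fBad, dialect = "hmmer3-domtbl"), "line 2")
})

test_that("generator hit tables round-trip through the TSV dialect", {
  gen <- genHitTable(20, seed = 5)
  f <- tempfile(fileext = ".tsv")
  writeDomainHits(gen$hits, f)
  back <- readDomainHits(f, dialect = "tsv")
  expect_equal(back$protein, gen$hits$protein)
  expect_equal(back$evalue, gen$hits$evalue, tolerance = 1e-12)
  expect_equal(back$domain, gen$hits$domain)
})

test_that("filterSignificant uses a strict threshold", {
  hits <- data.frame(protein = c("a", "b", "c"), species = NA,
                     strain = NA, gene = NA, length = 100L,
                     domain = "protease", evalue = c(1e-7, 1e-5, 2e-5))
  kept <- filterSignificant(hits)
  expect_identical(kept$protein, "a")   # 1e-5 exactly is removed
  set.seed(13)
  rnd <- data.frame(protein = sprintf("p%d", 1:50), species = NA, strain = NA,
                    gene = NA, length = 100L, domain = "protease",
                    evalue = 10^runif(50, -9, -3))
  expect_identical(filterSignificant(rnd, 1e-5)$protein,
                   rnd$protein[rnd$evalue < 1e-5])
})

test_that("callOrthologs assigns full/partial/none from domain sets", {
  hits <- data.frame(
    protein = c("f", "f", "f", "p", "p", "n"),
    species = "SP", strain = NA_character_, gene = NA_character_,
    length = c(300L, 300L, 300L, 200L, 200L, 150L),
    domain = c("protease", "zinc_finger", "hmg_box",
               "protease", "zinc_finger", "hmg_box"),
    evalue = 1e-8)
  calls <- callOrthologs(hits)
  expect_equal(calls$status[calls$protein == "f"], "full")
  expect_equal(calls$status[calls$protein == "p"], "partial")
  expect_equal(calls$status[calls$protein == "n"], "none")
})

test_that("triage recovers generator ground truth exactly on 200 proteins", {
  gen <- genHitTable(200, seed = 7)
  calls <- callOrthologs(filterSignificant(gen$hits))
  expect_equal(nrow(calls), 200)
  got <- setNames(calls$status, calls$protein)
  expect_identical(unname(got[gen$truth$protein]), gen$truth$status)
  # counts equal a brute-force recount from the ground truth
  expect_equal(sum(calls$status == "full"),
               sum(gen$truth$status == "full"))
  expect_equal(sum(calls$status == "partial"),
               sum(gen$truth$status == "partial"))
  # calls partition the significant proteins
  expect_equal(sum(table(calls$status)), length(unique(calls$protein)))
})

test_that("decoy-only hit tables produce no calls", {
  hits <- data.frame(protein = c("d1", "d2"), species = NA, strain = NA,
                     gene = NA, length = 100L,
                     domain = c("protease", "hmg_box"),
                     evalue = c(1e-4, 0.5))
  expect_equal(nrow(callOrthologs(filterSignificant(hits))), 0)
})

test_that("lowering the threshold never increases the number of full calls", {
  gen <- genHitTable(100, seed = 19, decoy_rate = 0.8)
  nFull <- vapply(c(1e-3, 1e-5, 1e-7, 1e-9), function(th) {
    sum(callOrthologs(filterSignificant(gen$hits, th))$status == "full")
  }, numeric(1))
  expect_true(all(diff(nFull) <= 0))
})

test_that("triage is idempotent on its own surviving proteins", {
  gen <- genHitTable(80, seed = 23)
  sig <- filterSignificant(gen$hits)
  calls <- callOrthologs(sig)
  again <- callOrthologs(sig[sig$protein %in% calls$protein, ])
  expect_identical(calls, again)
})

test_that("the longest isoform per gene is kept, ties by smallest id", {
  hits <- data.frame(
    protein = c("G1-1", "G1-2", "G1-3", "H2-b", "H2-a"),
    species = "SP", strain = NA_character_, gene = NA_character_,
    length = c(300L, 500L, 400L, 200L, 200L),
    domain = "protease", evalue = 1e-9)
  calls <- callOrthologs(hits)
  expect_setequal(calls$protein, c("G1-2", "H2-a"))
  # explicit gene tags override the id-root rule
  hits$gene <- c("g", "g", "g", "h", "h")
  hits$protein <- c("x1", "x2", "x3", "y1", "y2")
  hits$length <- c(300L, 500L, 400L, 200L, 200L)
  calls2 <- callOrthologs(hits)
  expect_setequal(calls2$protein, c("x2", "y1"))
})

test_that("one strain per species survives, the one with the longest protein", {
  hits <- data.frame(
    protein = c("a1", "a2", "b1"),
    species = c("SP1", "SP1", "SP1"),
    strain = c("strainA", "strainB", "strainB"),
    gene = c("g1", "g2", "g3"),
    length = c(300L, 500L, 100L),
    domain = "protease", evalue = 1e-9)
  calls <- callOrthologs(hits)
  # strainB contributes the longest protein (a2); strainA's a1 is dropped
  expect_setequal(calls$protein, c("a2", "b1"))
})

test_that("dedupIdentical collapses identity components to one representative", {
  gen <- genHitTable(30, seed = 29)
  calls <- callOrthologs(filterSignificant(gen$hits))
  expect_identical(dedupIdentical(calls, NULL), calls)
  ids <- calls$protein[1:6]
  pairs <- data.frame(a = c(ids[1], ids[2], ids[4]),
                      b = c(ids[2], ids[3], ids[5]))
  out <- dedupIdentical(calls, pairs)
  # components {1,2,3} and {4,5} each keep exactly one member
  comp1 <- ids[1:3]; comp2 <- ids[4:5]
  expect_equal(sum(out$protein %in% comp1), 1)
  expect_equal(sum(out$protein %in% comp2), 1)
  bestOf <- function(members) {
    sub <- calls[calls$protein %in% members, ]
    sub$protein[order(-sub$length, sub$protein)][1]
  }
  expect_true(bestOf(comp1) %in% out$protein)
  expect_true(bestOf(comp2) %in% out$protein)
  expect_error(dedupIdentical(calls, data.frame(a = "nope", b = ids[1])),
               "unknown")
})
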