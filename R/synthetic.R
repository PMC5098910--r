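# Seeded generators for every input class the pipeline consumes, each a pure
# function of its arguments (seed included). Child seeds are derived from the
# root seed plus a fixed component label, so adding a generator never
# perturbs the streams of existing ones.

.childSeed <- function(seed, label) {
  h <- 0
  for (c in utf8ToInt(label)) h <- (h * 31 + c) %% 2013265921
  as.integer((as.numeric(seed) + h) %% 2147483647)
}

.withSeed <- function(seed, expr) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  expr
}

#' Synthetic residue composition profiles
#'
#' Frequency vectors used by [genSequences()] to emulate the compositional
#' contrast between ordered and disordered proteins: the disordered-like
#' profile is enriched in D, E, S, T, P, K and depleted in W, C, F, I, Y, V;
#' the ordered-like profile resembles a globular-protein background. These
#' are synthetic package constants following the qualitative enrichment
#' directions seen in real ordered/disordered reference sets; they are not
#' measurements of any published dataset.
#'
#' @param tag `"ordered_like"`, `"disordered_like"`, or `"uniform"`.
#' @return Named frequency vector over the 20 standard residues (sums to 1).
#' @export
compositionProfile <- function(tag = c("uniform", "ordered_like",
                                       "disordered_like")) {
  tag <- match.arg(tag)
  p <- switch(tag,
    uniform = stats::setNames(rep(0.05, 20L), AA20),
    ordered_like = c(
      A = 0.080, C = 0.020, D = 0.050, E = 0.060, F = 0.040,
      G = 0.070, H = 0.022, I = 0.065, K = 0.060, L = 0.090,
      M = 0.024, N = 0.044, P = 0.045, Q = 0.040, R = 0.050,
      S = 0.060, T = 0.055, V = 0.075, W = 0.014, Y = 0.036),
    disordered_like = c(
      A = 0.0600, C = 0.0050, D = 0.1100, E = 0.1300, F = 0.0100,
      G = 0.0800, H = 0.0200, I = 0.0150, K = 0.0900, L = 0.0300,
      M = 0.0100, N = 0.0350, P = 0.0800, Q = 0.0500, R = 0.0450,
      S = 0.1300, T = 0.0700, V = 0.0200, W = 0.0025, Y = 0.0075))
  p[AA20] / sum(p)
}

#' Generate synthetic protein sequences with optional planted motifs
#'
#' Residues are drawn i.i.d. from a composition profile; literal motif
#' strings may then be spliced in at fixed or random offsets, and every
#' planted feature is recorded in a ground-truth table.
#'
#' @param n Number of sequences.
#' @param length Either a single fixed length or a `c(min, max)` range
#'   sampled uniformly.
#' @param profile Profile tag (see [compositionProfile()]) or a named
#'   frequency vector.
#' @param seed Integer root seed.
#' @param plant Optional data.frame with columns `seq` (1-based sequence
#'   index), `motif` (literal string), and `offset` (0-based start, or `NA`
#'   for a random placement).
#' @param prefix Id prefix, default `"S"`.
#' @return A list with `records` (named [Biostrings::AAStringSet-class]) and
#'   `truth` (data.frame `id`, `motif`, `start`, `end`; 0-based half-open).
#' @export
genSequences <- function(n, length = 300L, profile = "uniform", seed = 1L,
                         plant = NULL, prefix = "S") {
  p <- if (is.character(profile)) compositionProfile(profile)
       else .asComposition(profile)
  .withSeed(.childSeed(seed, "sequences"), {
    lens <- if (base::length(length) == 2L)
      sample(length[1L]:length[2L], n, replace = TRUE)
    else rep(as.integer(length), n)
    ids <- sprintf("%s%03d", prefix, seq_len(n))
    seqs <- vapply(lens, function(L)
      paste(sample(AA20, L, replace = TRUE, prob = p), collapse = ""),
      character(1L))
    names(seqs) <- ids
    truth <- NULL
    if (!is.null(plant)) {
      rows <- vector("list", nrow(plant))
      for (k in seq_len(nrow(plant))) {
        i <- plant$seq[k]
        motif <- plant$motif[k]
        L <- nchar(seqs[[i]])
        w <- nchar(motif)
        if (w > L) stop("planted motif longer than sequence ", ids[i])
        off <- plant$offset[k]
        if (is.na(off)) off <- sample.int(L - w + 1L, 1L) - 1L
        if (off < 0L || off + w > L)
          stop("planted offset out of bounds for sequence ", ids[i])
        substr(seqs[[i]], off + 1L, off + w) <- motif
        rows[[k]] <- data.frame(id = ids[i], motif = motif,
                                start = off, end = off + w)
      }
      truth <- do.call(rbind, rows)
    }
    if (is.null(truth))
      truth <- data.frame(id = character(0), motif = character(0),
                          start = integer(0), end = integer(0))
    records <- Biostrings::AAStringSet(seqs)
    list(records = records, truth = truth)
  })
}

#' Generate a synthetic domain-hit table with ground-truth statuses
#'
#' Per protein, an intended architecture is sampled from `arch_freqs`
#' (`full` = all three diagnostic domains, `partial` = protease + zinc
#' finger, `none` = a random non-full, non-partial subset with at least one
#' domain). Present domains receive E-values log-uniform on
#' [1e-12, 1e-6]; with probability `decoy_rate` each absent domain emits a
#' decoy hit with an E-value log-uniform on [1e-4, 1], above the standard
#' significance threshold.
#'
#' @param n Number of proteins.
#' @param arch_freqs Named frequencies for `full`, `partial`, `none`
#'   (must sum to 1).
#' @param seed Integer root seed.
#' @param decoy_rate Probability of a decoy hit per absent domain,
#'   default 0.3.
#' @return A list with `hits` (data.frame in the TSV hit dialect) and
#'   `truth` (data.frame `protein`, `status`).
#' @export
genHitTable <- function(n, arch_freqs = c(full = 0.5, partial = 0.3,
                                          none = 0.2),
                        seed = 1L, decoy_rate = 0.3) {
  stopifnot(abs(sum(arch_freqs) - 1) < 1e-9,
            setequal(names(arch_freqs), c("full", "partial", "none")))
  noneSubsets <- list("protease", "zinc_finger", "hmg_box",
                      c("protease", "hmg_box"), c("zinc_finger", "hmg_box"))
  .withSeed(.childSeed(seed, "hit_table"), {
    ids <- sprintf("P%04d", seq_len(n))
    species <- sprintf("sp%02d", sample.int(max(2L, n %/% 4L), n,
                                            replace = TRUE))
    lens <- sample(200:1500, n, replace = TRUE)
    status <- sample(names(arch_freqs), n, replace = TRUE, prob = arch_freqs)
    rows <- lapply(seq_len(n), function(i) {
      present <- switch(status[i],
        full = DOMAIN_SET,
        partial = c("protease", "zinc_finger"),
        none = noneSubsets[[sample.int(length(noneSubsets), 1L)]])
      absent <- setdiff(DOMAIN_SET, present)
      decoys <- absent[stats::runif(length(absent)) < decoy_rate]
      dom <- c(present, decoys)
      ev <- c(10^stats::runif(length(present), -12, -6),
              10^stats::runif(length(decoys), -4, 0))
      data.frame(protein = ids[i], species = species[i],
                 strain = NA_character_, gene = NA_character_,
                 length = lens[i], domain = dom, evalue = ev,
                 stringsAsFactors = FALSE)
    })
    list(hits = do.call(rbind, rows),
         truth = data.frame(protein = ids, status = status,
                            stringsAsFactors = FALSE))
  })
}

#' Generate a block-structured probability matrix
#'
#' Within-block probabilities are Beta-distributed near `within_mean`;
#' between-block probabilities near `between_mean`; the diagonal is 1.
#' Directed entries are drawn independently (the matrix is asymmetric, as
#' directional HMM-HMM scores are), to be symmetrized by
#' [toDissimilarity()].
#'
#' @param block_sizes Integer vector of block sizes (>= 2 blocks for a
#'   clustering test; a single block is allowed).
#' @param seed Integer root seed.
#' @param within_mean,between_mean Means of the Beta draws, defaults 0.9 and
#'   0.01.
#' @param conc Beta concentration (a + b), default 20.
#' @return A list with `P` (labelled probability matrix) and `blocks`
#'   (integer block label per row).
#' @export
genBlockMatrix <- function(block_sizes, seed = 1L, within_mean = 0.9,
                           between_mean = 0.01, conc = 20) {
  n <- sum(block_sizes)
  blocks <- rep(seq_along(block_sizes), block_sizes)
  .withSeed(.childSeed(seed, "block_matrix"), {
    same <- outer(blocks, blocks, `==`)
    mu <- ifelse(same, within_mean, between_mean)
    P <- matrix(stats::rbeta(n * n, mu * conc, (1 - mu) * conc), n, n)
    diag(P) <- 1
    labs <- sprintf("F%03d", seq_len(n))
    dimnames(P) <- list(labs, labs)
    list(P = P, blocks = stats::setNames(blocks, labs))
  })
}

#' Generate a noisy step-function disorder track
#'
#' Emulates a per-residue disorder-predictor output: a step function
#' alternating between `levels` at the given boundaries, plus Gaussian noise.
#'
#' @param length Track length (residues).
#' @param boundaries 1-based positions at which a new segment starts
#'   (excluding position 1); may be empty.
#' @param levels Segment levels, recycled over segments; default
#'   `c(0.2, 0.8)`.
#' @param sigma Gaussian noise standard deviation, default 0.1.
#' @param seed Integer root seed.
#' @param id Track identifier.
#' @return A list with `track` (a [ScoreTrack-class]), `boundaries`, and
#'   `segment_levels` (noise-free level per segment).
#' @export
genScoreTrack <- function(length, boundaries = integer(0),
                          levels = c(0.2, 0.8), sigma = 0.1, seed = 1L,
                          id = "synthetic_track") {
  stopifnot(all(boundaries > 1L & boundaries <= length))
  starts <- c(1L, sort(as.integer(boundaries)))
  ends <- c(starts[-1L] - 1L, length)
  segLevels <- rep_len(levels, base::length(starts))
  base <- rep(segLevels, ends - starts + 1L)
  .withSeed(.childSeed(seed, "score_track"), {
    x <- base + stats::rnorm(length, 0, sigma)
    list(track = ScoreTrack(x, id = id), boundaries = starts[-1L],
         segment_levels = segLevels)
  })
}

#' A deterministic synthetic GCNA-like cDNA
#'
#' Constructs, with no randomness, a coding sequence whose translation
#' emulates the documented character of the murine germ-cell protein GCNA:
#' a strongly acidic, repetitive, serine/glutamate-rich chain that is
#' predicted disordered, carrying exactly 25 tandem copies of the 8-residue
#' GE(P/M/S)E(S/T)EAK repeat unit, three further acidic repeat classes, two
#' SUMO-interacting motifs, and a basic NLS-like stretch; the ORF starts at
#' the first ATG and is flanked by ATG-free 5' and 3' UTRs. This sequence is
#' SYNTHETIC: it is a stand-in with the stated compositional features, not
#' the real transcript, and computed values on it (isoelectric point,
#' motif coordinates) characterize the stand-in only — except the repeat
#' count, which is planted by construction.
#'
#' @return A list with `cdna` (length-1 named
#'   [Biostrings::DNAStringSet-class]), `protein` (the expected translation
#'   as a character string), and `repeat_count` (the planted count, 25).
#' @export
syntheticGcnaCdna <- function() {
  # SIM cores satisfy [DEST]{0,5}.[VILPTM][VIL][DESTVILMA][VIL].{0,1}[DEST]{1,10}
  sim1 <- "EEESAVVIVADDE"
  sim2 <- "DSTEGIVLVETDSE"
  nls <- "KRPRSPKKRK"
  nterm <- paste0("DSGAETQSGEASTSDSEDLQG", sim1, "GSQESDPE", nls,
                  "WSDQEASGSE", sim2, "GSDQE")
  reps <- paste(vapply(0:24, function(i) {
    paste0("GE", c("P", "M", "S")[i %% 3L + 1L], "E",
           c("S", "T")[i %% 2L + 1L], "EAK")
  }, character(1L)), collapse = "")
  repB <- strrep("SPEAEGSG", 8L)   # second repeat class
  repC <- strrep("EDGSSQNE", 6L)   # third repeat class
  repD <- strrep("ESGSAEDT", 5L)   # fourth repeat class
  cterm <- "GSDSEEDAQPSTSAGQDSSEEAQEESDW"
  protein <- paste0("M", nterm, repB, reps, repC, repD, cterm)

  codon <- c(A = "GCT", C = "TGT", D = "GAT", E = "GAA", F = "TTT",
             G = "GGA", H = "CAT", I = "ATT", K = "AAA", L = "CTT",
             M = "ATG", N = "AAT", P = "CCA", Q = "CAA", R = "AGA",
             S = "TCA", T = "ACA", V = "GTT", W = "TGG", Y = "TAT")
  orf <- paste(codon[strsplit(protein, "", fixed = TRUE)[[1L]]],
               collapse = "")
  utr5 <- "GCGGCCGCAGAGCTCGCTTTCTTCCCAGCACTCAGAGCAGAGAAG"   # no ATG
  utr3 <- "TGACCTCGACTCCAGCTCTGCCCTGTAATCCCAGCACTTGGGAAAAAAAAAAAA"
  cdna <- Biostrings::DNAStringSet(paste0(utr5, orf, "TAA", utr3))
  names(cdna) <- "synthetic_gcna"
  list(cdna = cdna, protein = protein, repeat_count = 25L)
}
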