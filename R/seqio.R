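#' Read a FASTA file of protein or nucleotide records
#'
#' Thin, validating reader on top of Biostrings. Headers are split at the
#' first whitespace into identifier and description; wrapped sequence lines
#' are joined; sequences are uppercased. For nucleotide input, `U` is mapped
#' to `T`. In `strict` mode (the default) any character outside the expected
#' alphabet (20 standard residues for protein, `ACGT` for DNA) is an error
#' naming the record and position; in `permissive` mode offending protein
#' characters are masked to `X` (and non-`ACGT` bases to `N`), which
#' downstream statistics then exclude.
#'
#' @param path Path to a FASTA file (LF or CRLF line endings).
#' @param type `"protein"`, `"dna"`, or `"auto"` (default), which calls the
#'   file DNA when every sequence character is in `ACGTU`.
#' @param mode `"strict"` (default) or `"permissive"`.
#' @return An [Biostrings::AAStringSet-class] or
#'   [Biostrings::DNAStringSet-class] with unique names; descriptions (header
#'   text after the first whitespace) are kept in `metadata(x)$description`.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">a demo", "MKLV", ">b", "GGGG"), fa)
#' readFasta(fa)
#' @export
readFasta <- function(path, type = c("auto", "protein", "dna"),
                      mode = c("strict", "permissive")) {
  type <- match.arg(type)
  mode <- match.arg(mode)
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L) stop("empty FASTA file: ", path)
  headers <- names(raw)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  seqs <- toupper(gsub("[\\s\r]", "", as.character(raw), perl = TRUE))
  if (any(nchar(seqs) == 0L))
    stop("record with empty sequence: ", ids[which(nchar(seqs) == 0L)[1L]])
  if (anyDuplicated(ids))
    stop("duplicate record ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))

  if (type == "auto") {
    type <- if (all(grepl("^[ACGTU]+$", seqs))) "dna" else "protein"
  }
  if (type == "dna") {
    seqs <- gsub("U", "T", seqs, fixed = TRUE)
    seqs <- .checkAlphabet(seqs, ids, DNA4, mode, mask = "N")
    out <- Biostrings::DNAStringSet(seqs)
  } else {
    seqs <- .checkAlphabet(seqs, ids, AA20, mode, mask = "X")
    out <- Biostrings::AAStringSet(seqs)
  }
  names(out) <- ids
  S4Vectors::metadata(out)$description <- stats::setNames(desc, ids)
  out
}

# Validate (or mask) characters outside `alphabet`; errors name record + 1-based position.
.checkAlphabet <- function(seqs, ids, alphabet, mode, mask) {
  pat <- sprintf("[^%s]", paste(alphabet, collapse = ""))
  bad <- regexpr(pat, seqs)
  if (any(bad > 0L)) {
    if (mode == "strict") {
      i <- which(bad > 0L)[1L]
      stop(sprintf("illegal character '%s' in record '%s' at position %d",
                   substr(seqs[i], bad[i], bad[i]), ids[i], bad[i]))
    }
    seqs <- gsub(pat, mask, seqs)
  }
  seqs
}

#' Write sequences to FASTA
#'
#' @param x An `XStringSet` (or named character vector) of sequences.
#' @param path Output file path.
#' @param width Line-wrap width (default 60).
#' @return Invisibly, `path`.
#' @export
writeFasta <- function(x, path, width = 60L) {
  if (is.character(x)) x <- Biostrings::BStringSet(x)
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Translate a coding sequence from its first start codon
#'
#' Scans the input from the frame offset for the first `ATG`, then translates
#' under the standard genetic code until (and excluding) the first in-frame
#' stop codon; a trailing partial codon is ignored. If no stop codon occurs,
#' the full read-through product is returned with a `"no stop"` warning
#' (documented contract for 3'-truncated inputs).
#'
#' @param cdna A single DNA sequence: character string,
#'   [Biostrings::DNAString-class], or a length-1 `DNAStringSet`.
#' @param frame Integer 0, 1 or 2: offset at which the ATG search begins.
#' @return A named length-1 [Biostrings::AAStringSet-class].
#' @examples
#' translateCds("ATGGGCTAA")   # "MG"
#' translateCds("CCATGAAATGA") # "MK"
#' @export
translateCds <- function(cdna, frame = 0L) {
  stopifnot(frame %in% 0:2)
  id <- "cds"
  if (methods::is(cdna, "DNAStringSet")) {
    stopifnot(length(cdna) == 1L)
    if (!is.null(names(cdna))) id <- names(cdna)[1L]
    cdna <- as.character(cdna[[1L]])
  } else if (methods::is(cdna, "DNAString")) {
    cdna <- as.character(cdna)
  } else if (is.character(cdna)) {
    if (!is.null(names(cdna))) id <- names(cdna)[1L]
    cdna <- toupper(cdna[[1L]])
  }
  n <- nchar(cdna)
  if (n - frame < 3L) stop("sequence shorter than one codon after frame offset")
  hit <- regexpr("ATG", substr(cdna, frame + 1L, n), fixed = TRUE)
  if (hit < 0L) stop("no ATG start codon found at/after frame offset ", frame)
  start <- frame + as.integer(hit)          # 1-based position of the A of ATG
  orf <- substr(cdna, start, n)
  ncod <- nchar(orf) %/% 3L
  codons <- substring(orf, 3L * seq_len(ncod) - 2L, 3L * seq_len(ncod))
  aa <- Biostrings::GENETIC_CODE[codons]
  if (anyNA(aa)) {
    i <- which(is.na(aa))[1L]
    stop(sprintf("ambiguous or invalid codon '%s' at codon %d", codons[i], i))
  }
  stopAt <- which(aa == "*")
  if (length(stopAt) == 0L) {
    warning("no stop codon: returning full read-through product")
    prot <- paste(aa, collapse = "")
  } else {
    prot <- paste(aa[seq_len(stopAt[1L] - 1L)], collapse = "")
  }
  if (nchar(prot) == 0L) stop("ORF is empty (stop codon immediately after ATG)")
  out <- Biostrings::AAStringSet(prot)
  names(out) <- id
  out
}

# Coerce sequence-like input (character / AAString / AAStringSet) to a named
# character vector of uppercase sequences, for the scanning/statistics layers.
.asSeqChar <- function(x) {
  if (methods::is(x, "XStringSet")) {
    s <- as.character(x)
  } else if (methods::is(x, "XString")) {
    s <- stats::setNames(as.character(x), "seq")
  } else if (is.character(x)) {
    s <- toupper(x)
    if (is.null(names(s)))
      names(s) <- if (length(s) == 1L) "seq" else paste0("seq", seq_along(s))
  } else {
    stop("expected a character vector, XString or XStringSet")
  }
  if (any(nchar(s) == 0L)) stop("empty sequence")
  s
}

# Residue count matrix (sequences x 20 standard residues); X and other
# non-standard letters are excluded by construction.
.residueCounts <- function(seqs) {
  m <- t(vapply(strsplit(seqs, "", fixed = TRUE),
                function(ch) tabulate(factor(ch, levels = AA20), 20L),
                integer(20L)))
  dimnames(m) <- list(names(seqs), AA20)
  m
}
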