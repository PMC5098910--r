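DOMAIN_SET <- c("protease", "zinc_finger", "hmg_box")

#' Read a per-domain HMM-search hit table
#'
#' Two dialects are supported:
#' \describe{
#'   \item{`hmmer3-domtbl`}{HMMER3 `--domtblout` output: whitespace-delimited,
#'     `#` comment lines ignored; the target name (column 1), target length
#'     (column 3), query name (column 4), and full-sequence independent
#'     E-value (column 7) are used — one row is kept per (target, query)
#'     pair. Species/strain/gene tags are parsed from UniProt-style target
#'     names `db|acc|NAME_SPECIES` when present, otherwise left `NA`.}
#'   \item{`tsv`}{A simple tab-separated table with header columns
#'     `protein`, `species`, `strain`, `gene`, `length`, `domain`, `evalue`.}
#' }
#'
#' @param path Path to the hit table.
#' @param dialect `"hmmer3-domtbl"` or `"tsv"`.
#' @return A data.frame of domain hits with columns `protein`, `species`,
#'   `strain`, `gene`, `length`, `domain`, `evalue`.
#' @export
readDomainHits <- function(path, dialect = c("hmmer3-domtbl", "tsv")) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    hits <- utils::read.table(path, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE, quote = "",
                              comment.char = "#")
    need <- c("protein", "species", "strain", "gene", "length", "domain",
              "evalue")
    if (!all(need %in% names(hits)))
      stop("tsv hit table must have columns: ", paste(need, collapse = ", "))
    hits <- hits[, need]
  } else {
    lines <- readLines(path)
    keep <- !grepl("^\\s*(#|$)", lines)
    data <- lines[keep]
    lineno <- which(keep)
    if (length(data) == 0L)
      return(.emptyHits())
    fields <- strsplit(trimws(data), "\\s+")
    short <- which(lengths(fields) < 7L)
    if (length(short) > 0L)
      stop("malformed domtbl row (fewer than 7 fields) at line ",
           lineno[short[1L]])
    target <- vapply(fields, `[[`, character(1L), 1L)
    tlen <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1L), 3L)))
    query <- vapply(fields, `[[`, character(1L), 4L)
    eval_ <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1L), 7L)))
    bad <- which(is.na(tlen) | is.na(eval_))
    if (length(bad) > 0L)
      stop("non-numeric length or E-value at line ", lineno[bad[1L]])
    # UniProt-style ids: db|ACC|NAME_SPECIES
    name <- sub("^.*\\|", "", target)
    species <- ifelse(grepl("_", name), sub("^[^_]*_", "", name), NA_character_)
    hits <- data.frame(protein = target, species = species,
                       strain = NA_character_, gene = NA_character_,
                       length = tlen, domain = query, evalue = eval_,
                       stringsAsFactors = FALSE)
    hits <- hits[!duplicated(hits[, c("protein", "domain")]), ]
  }
  if (any(hits$evalue <= 0)) stop("E-values must be positive")
  rownames(hits) <- NULL
  hits
}

.emptyHits <- function() {
  data.frame(protein = character(0), species = character(0),
             strain = character(0), gene = character(0),
             length = integer(0), domain = character(0),
             evalue = numeric(0), stringsAsFactors = FALSE)
}

#' Write a hit table in the simple TSV dialect
#'
#' @param hits A hit data.frame (see [readDomainHits()]).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeDomainHits <- function(hits, path) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Keep significant hits
#'
#' Retains hits with E-value strictly smaller than the threshold; a hit at
#' exactly the threshold is removed.
#'
#' @param hits Hit data.frame.
#' @param threshold Positive significance threshold, default `1e-5`.
#' @return The filtered hit data.frame.
#' @export
filterSignificant <- function(hits, threshold = 1e-5) {
  stopifnot(threshold > 0)
  out <- hits[hits$evalue < threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Call full and partial orthologs from significant domain hits
#'
#' Hits are grouped by protein to determine which of the three diagnostic
#' domains (`protease`, `zinc_finger`, `hmg_box`) each candidate carries.
#' Deduplication then follows the published triage rules: among predicted
#' isoforms of the same gene only the longest is kept (ties broken by
#' lexicographically smallest protein id); among strains of the same species
#' only the strain contributing the longest protein is kept (same
#' tie-break). Status is `full` when all three domains are present,
#' `partial` when protease and zinc finger are present but not all three,
#' and `none` otherwise.
#'
#' @param hits Significance-filtered hit data.frame (see
#'   [filterSignificant()]).
#' @param domains Character vector of the three diagnostic domain names.
#' @param isoform_delim Regular expression delimiting an isoform suffix in
#'   protein ids, used as the gene key when no `gene` tag is present
#'   (default `"-"`, the UniProt isoform convention).
#' @return A data.frame with columns `protein`, `species`, `length`,
#'   `domains` (comma-joined), `status`.
#' @export
callOrthologs <- function(hits, domains = DOMAIN_SET, isoform_delim = "-") {
  if (nrow(hits) == 0L)
    return(data.frame(protein = character(0), species = character(0),
                      length = integer(0), domains = character(0),
                      status = character(0), stringsAsFactors = FALSE))
  unknown <- setdiff(unique(hits$domain), domains)
  if (length(unknown) > 0L)
    stop("unknown domain name(s): ", paste(unknown, collapse = ", "))
  prot <- unique(hits[, c("protein", "species", "strain", "gene", "length")])
  if (anyDuplicated(prot$protein))
    stop("inconsistent per-protein annotation (species/strain/gene/length)")
  domlist <- tapply(hits$domain, hits$protein,
                    function(d) sort(unique(d)), simplify = FALSE)
  prot$domains <- vapply(domlist[prot$protein], paste, character(1L),
                         collapse = ",")

  # gene key: explicit gene tag, else id root before the isoform delimiter
  gene <- prot$gene
  root <- sub(paste0(isoform_delim, ".*$"), "", prot$protein)
  gene <- ifelse(is.na(gene) | gene == "", root, gene)
  prot$.gene <- paste(ifelse(is.na(prot$species), "", prot$species), gene)
  prot <- .keepBest(prot, prot$.gene)

  # one strain per species: keep the strain contributing the longest protein
  hasStrain <- !is.na(prot$strain) & !is.na(prot$species)
  if (any(hasStrain)) {
    sub <- prot[hasStrain, ]
    bestStrain <- do.call(rbind, lapply(split(sub, sub$species), function(g) {
      o <- order(-g$length, g$protein)
      g$strain[o[1L]]
    }))
    keepStrain <- stats::setNames(bestStrain[, 1L], rownames(bestStrain))
    drop <- hasStrain & prot$strain != keepStrain[prot$species]
    prot <- prot[!drop, , drop = FALSE]
  }

  has <- function(d) grepl(d, prot$domains, fixed = TRUE)
  full <- Reduce(`&`, lapply(domains, has))
  partial <- has(domains[1L]) & has(domains[2L]) & !full
  prot$status <- ifelse(full, "full", ifelse(partial, "partial", "none"))
  out <- prot[order(prot$protein),
              c("protein", "species", "length", "domains", "status")]
  rownames(out) <- NULL
  out
}

# Keep, within each group, the longest protein (ties: smallest id).
.keepBest <- function(prot, key) {
  o <- order(key, -prot$length, prot$protein)
  prot <- prot[o, , drop = FALSE]
  prot[!duplicated(key[o]), , drop = FALSE]
}

#' Collapse identical entries to one representative
#'
#' Given pairs of ids known to be identical (e.g. from an external
#' all-vs-all reciprocal comparison), connected components of the identity
#' relation are collapsed to a single representative: the longest member,
#' ties broken by lexicographically smallest id.
#'
#' @param calls Ortholog-call data.frame from [callOrthologs()].
#' @param identity_pairs Two-column data.frame or matrix of id pairs; may be
#'   empty.
#' @return The deduplicated call data.frame.
#' @export
dedupIdentical <- function(calls, identity_pairs) {
  if (is.null(identity_pairs) || NROW(identity_pairs) == 0L) return(calls)
  pairs <- as.matrix(identity_pairs)[, 1:2, drop = FALSE]
  unknown <- setdiff(unique(as.vector(pairs)), calls$protein)
  if (length(unknown) > 0L)
    stop("identity pair references unknown id(s): ",
         paste(unknown, collapse = ", "))
  comp <- stats::setNames(calls$protein, calls$protein)  # union-find, path-halving
  findRoot <- function(x) {
    while (comp[[x]] != x) {
      comp[[x]] <<- comp[[comp[[x]]]]
      x <- comp[[x]]
    }
    x
  }
  for (i in seq_len(nrow(pairs))) {
    a <- findRoot(pairs[i, 1L]); b <- findRoot(pairs[i, 2L])
    if (a != b) comp[[b]] <- a
  }
  root <- vapply(calls$protein, findRoot, character(1L))
  keep <- unlist(lapply(split(seq_len(nrow(calls)), root), function(idx) {
    idx[order(-calls$length[idx], calls$protein[idx])][1L]
  }), use.names = FALSE)
  out <- calls[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}
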