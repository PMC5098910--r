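#' Pooled amino-acid composition of a sequence set
#'
#' Residue counts pooled over all sequences, divided by the total number of
#' (standard) residues. Masked residues (`X`) are excluded.
#'
#' @param x Sequences (character vector or `AAStringSet`).
#' @return A named numeric vector of relative frequencies over the 20
#'   standard residues (sums to 1), with attribute `count` = total residues.
#' @examples
#' composition(c("GA", "AG")) # A 0.5, G 0.5
#' @export
composition <- function(x) {
  seqs <- .asSeqChar(x)
  cnt <- colSums(.residueCounts(seqs))
  total <- sum(cnt)
  if (total == 0L) stop("no standard residues in input")
  out <- cnt / total
  attr(out, "count") <- total
  out
}

#' Per-residue composition enrichment relative to a reference
#'
#' The normalized excess `(Cx - Corder) / Corder` of each residue's relative
#' frequency in the query composition (`Cx`) over the reference composition
#' (`Corder`). Residues with zero reference frequency are reported `NA`
#' (undefined), never infinite.
#'
#' @param query,reference Composition vectors (named frequencies over the 20
#'   residues, e.g. from [composition()]).
#' @return Named numeric vector of enrichments (>= -1 where defined).
#' @examples
#' uniform <- setNames(rep(0.05, 20), strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])
#' enrichment(composition("GGG"), uniform) # G: 19, all others: -1
#' @export
enrichment <- function(query, reference) {
  query <- .asComposition(query)
  reference <- .asComposition(reference)[names(query)]
  out <- ifelse(reference > 0, (query - reference) / reference, NA_real_)
  stats::setNames(as.numeric(out), names(query))
}

.asComposition <- function(x) {
  if (is.null(names(x))) {
    if (length(x) != 20L) stop("unnamed composition must have 20 entries")
    names(x) <- AA20
  }
  stopifnot(all(AA20 %in% names(x)))
  x <- x[AA20]
  if (any(x < 0)) stop("negative frequency")
  tot <- sum(x)
  if (abs(tot - 1) > 1e-6) x <- x / tot
  x
}

#' Bootstrap standard deviations of composition enrichments
#'
#' Residues of the query and reference datasets are independently resampled
#' with replacement (each at its original total size) `n_boot` times; the
#' enrichment `(Cx - Corder) / Corder` is recomputed per replicate, and the
#' per-residue standard deviation over replicates is returned. Residue-level
#' resampling at fixed total is realised exactly as multinomial draws from
#' the observed frequencies. A per-sequence resampling mode (`unit =
#' "sequence"`) draws whole sequences with replacement instead.
#'
#' @param query_records,reference_records Sequence sets (character vectors or
#'   `AAStringSet`s).
#' @param n_boot Number of bootstrap replicates, default 10000.
#' @param seed Integer seed; identical seeds give identical results.
#' @param unit `"residue"` (default) or `"sequence"`.
#' @return Named numeric vector of per-residue bootstrap SDs (`NA` where the
#'   observed reference frequency is zero).
#' @export
bootstrapSD <- function(query_records, reference_records, n_boot = 10000L,
                        seed = 1L, unit = c("residue", "sequence")) {
  unit <- match.arg(unit)
  stopifnot(n_boot >= 2L)
  qc <- composition(query_records)
  rc <- composition(reference_records)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  if (unit == "residue") {
    qn <- attr(qc, "count")
    rn <- attr(rc, "count")
    qf <- stats::rmultinom(n_boot, qn, qc) / qn       # 20 x n_boot
    rf <- stats::rmultinom(n_boot, rn, rc) / rn
  } else {
    qs <- .asSeqChar(query_records)
    rs <- .asSeqChar(reference_records)
    qf <- .resampleSeqFreqs(qs, n_boot)
    rf <- .resampleSeqFreqs(rs, n_boot)
  }
  enr <- ifelse(rf > 0, (qf - rf) / rf, NA_real_)
  out <- apply(enr, 1L, stats::sd, na.rm = TRUE)
  out[rc == 0] <- NA_real_
  stats::setNames(out, AA20)
}

.resampleSeqFreqs <- function(seqs, n_boot) {
  cnt <- .residueCounts(seqs)
  vapply(seq_len(n_boot), function(i) {
    pick <- sample.int(nrow(cnt), nrow(cnt), replace = TRUE)
    cs <- colSums(cnt[pick, , drop = FALSE])
    cs / sum(cs)
  }, numeric(20L))
}

#' Composition enrichment with bootstrap error bars
#'
#' Convenience wrapper combining [composition()], [enrichment()], and
#' [bootstrapSD()].
#'
#' @inheritParams bootstrapSD
#' @param reference Either a sequence set or a named frequency vector (e.g.
#'   [compositionProfile()]). Bootstrap SDs require sequences or counts; when
#'   a bare frequency vector is given, only the query side is resampled.
#' @return A data.frame with columns `residue`, `enrichment`, `sd`.
#' @export
compositionEnrichment <- function(query_records, reference, n_boot = 10000L,
                                  seed = 1L) {
  qc <- composition(query_records)
  if (is.numeric(reference)) {
    rc <- .asComposition(reference)
    enr <- enrichment(qc, rc)
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
    qn <- attr(qc, "count")
    qf <- stats::rmultinom(n_boot, qn, qc) / qn
    sds <- apply((qf - rc) / rc, 1L, stats::sd)
    sds[rc == 0] <- NA_real_
  } else {
    rc <- composition(reference)
    enr <- enrichment(qc, rc)
    sds <- bootstrapSD(query_records, reference, n_boot = n_boot, seed = seed)
  }
  data.frame(residue = AA20, enrichment = unname(enr[AA20]),
             sd = unname(sds[AA20]), row.names = NULL)
}

# Save/restore the global RNG state so seeded helpers do not perturb the
# caller's stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
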