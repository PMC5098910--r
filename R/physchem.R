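#' Net charge of a protein at a given pH
#'
#' Henderson-Hasselbalch per-group model: each chain carries exactly one
#' N-terminal amino group and one C-terminal carboxyl group; side chains of
#' K, R, H are basic and D, E, C, Y acidic. The net charge in elementary
#' charge units is
#' \deqn{Z(pH) = \sum_{basic} \frac{n_g}{1 + 10^{pH - pK_g}}
#'             - \sum_{acidic} \frac{n_g}{1 + 10^{pK_g - pH}}.}
#'
#' @param x Protein sequence(s): character vector,
#'   [Biostrings::AAString-class] or `AAStringSet`. Residues must be the 20
#'   standard letters; `X` (mask) is ignored.
#' @param pH pH at which to evaluate, in (0, 14). May be a vector if `x` is a
#'   single sequence.
#' @param pks A [PKSet-class]; default [paperPKSet()].
#' @return Numeric net charge(s), named as `x` (or along `pH` for a single
#'   sequence and vector `pH`).
#' @examples
#' netCharge("GG", 7)          # about -0.024: termini only
#' netCharge("KDKD", c(4, 10)) # decreasing in pH
#' @export
setGeneric("netCharge", function(x, pH = 7, pks = paperPKSet())
  standardGeneric("netCharge"))

#' @rdname netCharge
#' @export
setMethod("netCharge", "character", function(x, pH, pks) {
  .netChargeCounts(.ionizableCounts(.asSeqChar(x)), pH, pks)
})

#' @rdname netCharge
#' @export
setMethod("netCharge", "AAString", function(x, pH, pks) {
  netCharge(as.character(x), pH, pks)
})

#' @rdname netCharge
#' @export
setMethod("netCharge", "AAStringSet", function(x, pH, pks) {
  netCharge(as.character(x), pH, pks)
})

# Group-count matrix (rows = sequences, cols = the nine ionizable groups).
.ionizableCounts <- function(seqs) {
  bad <- regexpr("[^ACDEFGHIKLMNPQRSTVWYX]", seqs)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop(sprintf("non-standard residue '%s' in '%s' at position %d",
                 substr(seqs[i], bad[i], bad[i]), names(seqs)[i], bad[i]))
  }
  cnt <- .residueCounts(seqs)
  m <- cbind(Amino = 1, Carboxyl = 1,
             cnt[, c("C", "D", "E", "H", "K", "R", "Y"), drop = FALSE])
  rownames(m) <- names(seqs)
  m
}

BASIC_GROUPS  <- c("Amino", "K", "R", "H")
ACIDIC_GROUPS <- c("Carboxyl", "D", "E", "C", "Y")

# Charge from a group-count matrix; vectorized over pH when one sequence.
.netChargeCounts <- function(counts, pH, pks) {
  stopifnot(all(pH > 0 & pH < 14))
  pk <- pKValues(pks)
  if (length(pH) > 1L && nrow(counts) > 1L)
    stop("vector pH is only supported for a single sequence")
  chargeAt <- function(p) {
    pos <- counts[, BASIC_GROUPS, drop = FALSE] %*%
      (1 / (1 + 10^(p - pk[BASIC_GROUPS])))
    neg <- counts[, ACIDIC_GROUPS, drop = FALSE] %*%
      (1 / (1 + 10^(pk[ACIDIC_GROUPS] - p)))
    drop(pos - neg)
  }
  if (length(pH) == 1L) chargeAt(pH) else vapply(pH, chargeAt, numeric(1L))
}

#' Net charge profile over a pH grid
#'
#' @param x A single protein sequence (character or `AAString`).
#' @param pH Numeric grid of pH values (default `seq(1, 13, by = 0.1)`).
#' @inheritParams netCharge
#' @return A data.frame with columns `pH` and `charge`; the charge is
#'   strictly decreasing in pH.
#' @export
chargeProfile <- function(x, pH = seq(1, 13, by = 0.1), pks = paperPKSet()) {
  s <- .asSeqChar(x)
  stopifnot(length(s) == 1L)
  data.frame(pH = pH, charge = netCharge(s, pH, pks))
}

#' Theoretical isoelectric point
#'
#' The pH at which the Henderson-Hasselbalch net charge is zero, found by
#' bisection on (0, 14). The net charge is continuous and strictly decreasing
#' in pH for any chain (the termini alone guarantee at least one basic and
#' one acidic group), so the root is unique.
#'
#' @inheritParams netCharge
#' @param tol Bracket width at which bisection stops (pH units),
#'   default `1e-4`.
#' @return Numeric pI value(s) in pH units, named as `x`.
#' @examples
#' isoelectricPoint("GG") # 6.10: midpoint of the two terminal pKs
#' @export
setGeneric("isoelectricPoint", function(x, pks = paperPKSet(), tol = 1e-4)
  standardGeneric("isoelectricPoint"))

#' @rdname isoelectricPoint
#' @export
setMethod("isoelectricPoint", "character", function(x, pks, tol) {
  seqs <- .asSeqChar(x)
  counts <- .ionizableCounts(seqs)
  out <- vapply(seq_len(nrow(counts)), function(i) {
    .bisectPI(counts[i, , drop = FALSE], pks, tol)
  }, numeric(1L))
  stats::setNames(out, names(seqs))
})

#' @rdname isoelectricPoint
#' @export
setMethod("isoelectricPoint", "AAString", function(x, pks, tol) {
  isoelectricPoint(as.character(x), pks, tol)
})

#' @rdname isoelectricPoint
#' @export
setMethod("isoelectricPoint", "AAStringSet", function(x, pks, tol) {
  isoelectricPoint(as.character(x), pks, tol)
})

.bisectPI <- function(counts1, pks, tol) {
  lo <- 1e-6
  hi <- 14 - 1e-6
  f <- function(p) .netChargeCounts(counts1, p, pks)
  # monotone decreasing: f(lo) > 0 > f(hi) always holds with both termini
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Proteome acidity percentile of a pI
#'
#' Percentage of proteome isoelectric points strictly greater than the query
#' ("more acidic than x% of the proteome"); ties count as not-more-acidic.
#'
#' @param query_pI Numeric query pI.
#' @param proteome_pIs Non-empty numeric vector of proteome pIs.
#' @return Percentage in [0, 100].
#' @examples
#' acidityPercentile(4.2, c(5, 6, 7, 4)) # 75
#' @export
acidityPercentile <- function(query_pI, proteome_pIs) {
  if (length(proteome_pIs) == 0L) stop("empty proteome pI set")
  100 * sum(proteome_pIs > query_pI) / length(proteome_pIs)
}
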