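#' Kyte-Doolittle hydropathy scale
#'
#' The standard 20 published values, spanning -4.5 (R) to +4.5 (I).
#'
#' @param scaled If `TRUE`, affinely rescaled to [0, 1] as `(kd + 4.5) / 9`.
#' @return Named numeric vector over the 20 standard residues.
#' @export
kdHydropathy <- function(scaled = FALSE) {
  kd <- c(A =  1.8, C =  2.5, D = -3.5, E = -3.5, F =  2.8,
          G = -0.4, H = -3.2, I =  4.5, K = -3.9, L =  3.8,
          M =  1.9, N = -3.5, P = -1.6, Q = -3.5, R = -4.5,
          S = -0.8, T = -0.7, V =  4.2, W = -0.9, Y = -1.3)
  if (scaled) (kd + 4.5) / 9 else kd
}

#' Windowed scaled hydropathy profile
#'
#' Per-residue mean of the [0, 1]-scaled Kyte-Doolittle values over a
#' centered window; windows are truncated (shrink) at the termini so the
#' profile has exactly one value per residue. Masked residues (`X`) take the
#' scale midpoint 0.5 and are best avoided.
#'
#' @param x A single protein sequence (character, `AAString`, or length-1
#'   `AAStringSet`).
#' @param window Odd window size, default 5.
#' @return Numeric vector of per-residue scaled hydropathies in [0, 1].
#' @examples
#' kdProfile("IIIII")            # all 1
#' kdProfile("IRIRI", window = 3)
#' @export
kdProfile <- function(x, window = 5L) {
  s <- .asSeqChar(x)
  stopifnot(length(s) == 1L)
  n <- nchar(s)
  if (window %% 2L == 0L) stop("window must be odd")
  if (window < 1L || window > n) stop("window must be in [1, sequence length]")
  scale01 <- c(kdHydropathy(scaled = TRUE), X = 0.5)
  v <- scale01[strsplit(s, "", fixed = TRUE)[[1L]]]
  if (anyNA(v)) stop("non-standard residue in sequence")
  half <- (window - 1L) %/% 2L
  cs <- c(0, cumsum(v))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  unname((cs[hi + 1L] - cs[lo]) / (hi - lo + 1L))
}

#' Mean scaled hydropathy of a profile
#'
#' Arithmetic mean of the per-residue scaled hydropathy values: the sum of
#' the normalized hydropathies of all residues divided by chain length.
#'
#' @param profile Numeric hydropathy profile (e.g. from [kdProfile()]).
#' @return Scalar mean in [0, 1].
#' @export
meanScaledHydropathy <- function(profile) {
  if (length(profile) == 0L) stop("empty profile")
  mean(profile)
}

#' Absolute mean net charge at pH 7
#'
#' The absolute Henderson-Hasselbalch net charge at pH 7.0 divided by chain
#' length. With `approx = TRUE` the common integer-count approximation
#' `|#K + #R - #D - #E| / length` is used instead.
#'
#' @inheritParams netCharge
#' @param approx Use the (K+R-D-E) count approximation? Default `FALSE`.
#' @return Non-negative numeric value(s), named as `x`.
#' @export
meanNetCharge <- function(x, pks = paperPKSet(), approx = FALSE) {
  seqs <- .asSeqChar(x)
  n <- nchar(seqs)
  if (approx) {
    cnt <- .residueCounts(seqs)
    z <- cnt[, "K"] + cnt[, "R"] - cnt[, "D"] - cnt[, "E"]
  } else {
    z <- netCharge(seqs, pH = 7, pks = pks)
  }
  stats::setNames(abs(z) / n, names(seqs))
}

#' Classify points on the charge-hydropathy plane
#'
#' The empirical boundary between natively folded and natively unfolded
#' proteins on the (mean scaled hydropathy `H`, absolute mean net charge `R`)
#' plane is `Hb = (R + 1.151) / 2.785`. A protein is called `disordered`
#' when `H < Hb`, `folded` otherwise (points exactly on the boundary are
#' `folded`: disorder is the strict-inequality side).
#'
#' @param H Mean scaled hydropathy value(s) in [0, 1].
#' @param R Absolute mean net charge value(s), >= 0.
#' @return Character vector of calls, `"folded"` or `"disordered"`.
#' @examples
#' chClassify(H = 1.0, R = 0)   # folded
#' chClassify(H = 0.2, R = 0.3) # disordered
#' @export
chClassify <- function(H, R) {
  stopifnot(all(H >= 0 & H <= 1), all(R >= 0))
  ifelse(H < chBoundary(R), "disordered", "folded")
}

#' Charge-hydropathy boundary hydropathy at a given mean net charge
#'
#' @param R Absolute mean net charge value(s).
#' @return Boundary hydropathy `(R + 1.151) / 2.785`.
#' @export
chBoundary <- function(R) (R + 1.151) / 2.785

#' Charge-hydropathy analysis of a sequence set
#'
#' Computes, per sequence, the mean scaled hydropathy (windowed
#' Kyte-Doolittle, window 5 by default), the absolute mean net charge at
#' pH 7, and the folded/disordered call against the empirical boundary.
#' Sequences are expected to be the disordered-candidate regions themselves
#' (e.g. pre-cut N-terminal IDRs), not whole multidomain proteins.
#'
#' @param x Sequences (character vector or `AAStringSet`).
#' @param window Hydropathy window (odd), default 5.
#' @inheritParams meanNetCharge
#' @return A data.frame with columns `id`, `H`, `R`, `call`.
#' @export
chAnalyze <- function(x, window = 5L, pks = paperPKSet(), approx = FALSE) {
  seqs <- .asSeqChar(x)
  H <- vapply(seqs, function(s) meanScaledHydropathy(kdProfile(s, window)),
              numeric(1L))
  R <- meanNetCharge(seqs, pks = pks, approx = approx)
  data.frame(id = names(seqs), H = unname(H), R = unname(R),
             call = unname(chClassify(H, R)), row.names = NULL)
}

#' Plot a charge-hydropathy plane
#'
#' Scatter of `H` against `R` with the empirical folded/disordered boundary
#' line.
#'
#' @param ch A data.frame as returned by [chAnalyze()].
#' @param ... Further arguments passed to [graphics::plot()].
#' @return Invisibly, `ch`.
#' @export
plotChPlane <- function(ch, ...) {
  graphics::plot(ch$R, ch$H, xlab = "absolute mean net charge <R>",
                 ylab = "mean scaled hydropathy <H>",
                 pch = ifelse(ch$call == "disordered", 1, 17),
                 col = ifelse(ch$call == "disordered", "darkorange", "navy"),
                 ylim = c(0, 1), ...)
  r <- seq(0, max(ch$R, 0.6), length.out = 100)
  graphics::lines(r, chBoundary(r), lty = 2)
  invisible(ch)
}
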