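#' Ionization-constant set for the Henderson-Hasselbalch charge model
#'
#' A `PKSet` holds the nine pK values the charge model needs: the two chain
#' termini (`Amino`, `Carboxyl`) and the seven ionizable side chains
#' (`C`, `D`, `E`, `H`, `K`, `R`, `Y`). Basic groups (N-terminal amine, K, R,
#' H) contribute positive charge; acidic groups (C-terminal carboxyl, D, E, C,
#' Y) contribute negative charge.
#'
#' @slot pk Named numeric vector with exactly the nine group names above,
#'   values in pH units, each finite and strictly inside (0, 14).
#'
#' @seealso [paperPKSet()] for the EMBOSS-derived default set, [netCharge()],
#'   [isoelectricPoint()].
#' @export
setClass("PKSet", representation(pk = "numeric"))

PK_GROUPS <- c("Amino", "Carboxyl", "C", "D", "E", "H", "K", "R", "Y")

setValidity("PKSet", function(object) {
  pk <- object@pk
  if (!setequal(names(pk), PK_GROUPS) || length(pk) != 9L)
    return(sprintf("pK set must name exactly the nine groups: %s",
                   paste(PK_GROUPS, collapse = ", ")))
  if (any(!is.finite(pk)) || any(pk <= 0) || any(pk >= 14))
    return("all pK values must be finite and in (0, 14)")
  TRUE
})

#' Construct a pK set
#'
#' @param pk Named numeric vector giving pK values for the nine ionizable
#'   groups `Amino`, `Carboxyl`, `C`, `D`, `E`, `H`, `K`, `R`, `Y`.
#' @return A [PKSet-class] object.
#' @examples
#' pks <- PKSet(c(Amino = 8.6, Carboxyl = 3.6, C = 8.5, D = 3.9, E = 4.1,
#'                H = 6.5, K = 10.8, R = 12.5, Y = 10.1))
#' @export
PKSet <- function(pk) {
  new("PKSet", pk = pk[PK_GROUPS])
}

#' The EMBOSS pK set used for proteome-wide isoelectric points
#'
#' Amino 8.6, Carboxyl 3.6, C 8.5, D 3.9, E 4.1, H 6.5, K 10.8, R 12.5,
#' Y 10.1.
#'
#' @return A [PKSet-class].
#' @export
paperPKSet <- function() {
  PKSet(c(Amino = 8.6, Carboxyl = 3.6, C = 8.5, D = 3.9, E = 4.1,
          H = 6.5, K = 10.8, R = 12.5, Y = 10.1))
}

#' @describeIn PKSet-class Access the named vector of pK values.
#' @param object A `PKSet`.
#' @export
setGeneric("pKValues", function(object) standardGeneric("pKValues"))

#' @rdname PKSet-class
#' @export
setMethod("pKValues", "PKSet", function(object) object@pk)

setMethod("show", "PKSet", function(object) {
  cat("PKSet (pH units)\n")
  print(round(object@pk, 2))
})

#' Per-residue score track
#'
#' A `ScoreTrack` pairs a protein identifier with one numeric score per
#' residue (e.g. a disorder-predictor output) and records whether the track
#' has been exponentially smoothed and with what damping factor.
#'
#' @slot id Protein identifier.
#' @slot scores Numeric vector, one value per residue.
#' @slot smoothed Logical flag.
#' @slot damping Damping factor d used if smoothed, in [0, 1); `NA_real_`
#'   for raw tracks.
#'
#' @seealso [smoothTrack()], [readScoreTrack()], [genScoreTrack()]
#' @export
setClass("ScoreTrack",
         representation(id = "character", scores = "numeric",
                        smoothed = "logical", damping = "numeric"))

setValidity("ScoreTrack", function(object) {
  if (length(object@scores) < 1L) return("scores must be non-empty")
  if (any(!is.finite(object@scores))) return("scores must be finite")
  if (isTRUE(object@smoothed) &&
      (is.na(object@damping) || object@damping < 0 || object@damping >= 1))
    return("damping factor must be in [0, 1) for a smoothed track")
  TRUE
})

#' Construct a score track
#'
#' @param scores Numeric vector of per-residue scores.
#' @param id Protein identifier (default `"track"`).
#' @param smoothed Has the track been smoothed? Default `FALSE`.
#' @param damping Damping factor if smoothed.
#' @return A [ScoreTrack-class].
#' @export
ScoreTrack <- function(scores, id = "track", smoothed = FALSE,
                       damping = NA_real_) {
  new("ScoreTrack", id = id, scores = as.numeric(scores),
      smoothed = smoothed, damping = damping)
}

#' @describeIn ScoreTrack-class Numeric scores of the track.
#' @param object A `ScoreTrack`.
#' @export
setGeneric("trackScores", function(object) standardGeneric("trackScores"))

#' @rdname ScoreTrack-class
#' @export
setMethod("trackScores", "ScoreTrack", function(object) object@scores)

setMethod("show", "ScoreTrack", function(object) {
  cat(sprintf("ScoreTrack '%s': %d residues%s\n", object@id,
              length(object@scores),
              if (isTRUE(object@smoothed))
                sprintf(", smoothed (d = %g)", object@damping) else ""))
})

setMethod("length", "ScoreTrack", function(x) length(x@scores))
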