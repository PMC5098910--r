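# SUMO-interacting motif, ELM-style: a hydrophobic core surrounded by acidic
# or phosphorylatable residues, the C-terminal stretch being the longer one.
SIM_PATTERN <- "[DEST]{0,5}.[VILPTM][VIL][DESTVILMA][VIL].{0,1}[DEST]{1,10}"

# Murine-specific 8-residue tandem repeat unit.
GCNA_REPEAT_PATTERN <- "GE[PMS]E[ST]EAK"

#' Scan for SUMO-interacting motifs (SIMs)
#'
#' Matches the pattern
#' `[DEST]{0,5}.[VILPTM][VIL][DESTVILMA][VIL].{0,1}[DEST]{1,10}`.
#' By default the maximal non-overlapping set is reported (left-to-right,
#' each match leftmost and greedy); `overlapping = TRUE` enumerates every
#' match start instead.
#'
#' @param x Sequences (character vector or `AAStringSet`).
#' @param pattern Regular expression to scan for; default the SIM pattern.
#' @param overlapping Enumerate overlapping matches from every start
#'   position? Default `FALSE`.
#' @return A data.frame with columns `id`, `pattern`, `start`, `end`
#'   (0-based, half-open) and `match` (the matched substring).
#' @examples
#' scanSIM("EEEEAVVIVAD")
#' @export
scanSIM <- function(x, pattern = SIM_PATTERN, overlapping = FALSE) {
  seqs <- .asSeqChar(x)
  res <- lapply(names(seqs), function(id) {
    s <- seqs[[id]]
    if (!overlapping) {
      m <- gregexpr(pattern, s, perl = TRUE)[[1L]]
      if (m[1L] == -1L) return(NULL)
      start1 <- as.integer(m)
      len <- attr(m, "match.length")
    } else {
      start1 <- integer(0)
      len <- integer(0)
      for (i in seq_len(nchar(s))) {
        mm <- regexpr(pattern, substr(s, i, nchar(s)), perl = TRUE)
        if (mm == 1L) {           # match anchored at position i
          start1 <- c(start1, i)
          len <- c(len, attr(mm, "match.length"))
        }
      }
      if (length(start1) == 0L) return(NULL)
    }
    data.frame(id = id, pattern = pattern,
               start = start1 - 1L, end = start1 - 1L + len,
               match = substring(s, start1, start1 + len - 1L))
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(id = character(0), pattern = character(0),
                      start = integer(0), end = integer(0),
                      match = character(0))
  out
}

#' Count non-overlapping occurrences of a fixed-length degenerate motif
#'
#' Left-to-right scan for non-overlapping matches; the default pattern is the
#' 8-residue murine GE(P/M/S)E(S/T)EAK tandem-repeat unit.
#'
#' @param x Sequences (character vector or `AAStringSet`).
#' @param pattern Fixed-length degenerate motif as a regular expression.
#' @return Integer count(s), named as `x`.
#' @examples
#' countRepeat("GEPESEAKGEMETEAK") # 2
#' @export
countRepeat <- function(x, pattern = GCNA_REPEAT_PATTERN) {
  seqs <- .asSeqChar(x)
  vapply(seqs, function(s) {
    m <- gregexpr(pattern, s, perl = TRUE)[[1L]]
    if (m[1L] == -1L) 0L else length(m)
  }, integer(1L))
}

#' Exponentially smooth a score track
#'
#' Spreadsheet-convention exponential smoothing with damping factor `d`
#' (smoothing constant `1 - d`):
#' \deqn{s_1 = x_1, \qquad s_t = (1 - d)\,x_t + d\,s_{t-1}.}
#' A constant track is a fixed point; an impulse decays geometrically with
#' ratio `d`.
#'
#' @param track A [ScoreTrack-class] or numeric vector.
#' @param d Damping factor in [0, 1), default 0.9.
#' @return The same type as the input, smoothed.
#' @examples
#' trackScores(smoothTrack(ScoreTrack(c(1, 0, 0, 0)))) # 1, 0.9, 0.81, 0.729
#' @export
smoothTrack <- function(track, d = 0.9) {
  stopifnot(d >= 0, d < 1)
  x <- if (methods::is(track, "ScoreTrack")) track@scores else as.numeric(track)
  if (length(x) == 0L) stop("empty track")
  s <- as.numeric(stats::filter((1 - d) * x, d, method = "recursive",
                                init = x[1L]))
  if (methods::is(track, "ScoreTrack"))
    ScoreTrack(s, id = track@id, smoothed = TRUE, damping = d)
  else s
}

#' Read a per-residue score track from a plain-text file
#'
#' Accepts either one numeric score per line, or two whitespace-separated
#' columns `position score` with consecutive 1-based positions. Lines
#' beginning with `#` are ignored.
#'
#' @param path Path to the track file.
#' @param id Identifier to attach; defaults to the file name sans extension.
#' @return A [ScoreTrack-class].
#' @export
readScoreTrack <- function(path, id = NULL) {
  if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0L) stop("no data lines in ", path)
  fields <- strsplit(trimws(lines), "\\s+")
  nf <- lengths(fields)
  if (!all(nf == nf[1L]) || !nf[1L] %in% 1:2)
    stop("expected 1 or 2 columns throughout; first offending line: ",
         lineno[which(nf != nf[1L])[1L]])
  vals <- suppressWarnings(lapply(fields, as.numeric))
  bad <- which(vapply(vals, anyNA, logical(1L)))
  if (length(bad) > 0L)
    stop("non-numeric value at line ", lineno[bad[1L]])
  m <- do.call(rbind, vals)
  if (nf[1L] == 2L) {
    pos <- m[, 1L]
    if (any(pos != seq_along(pos)))
      stop("positions must be consecutive starting at 1; first gap near line ",
           lineno[which(pos != seq_along(pos))[1L]])
    scores <- m[, 2L]
  } else {
    scores <- m[, 1L]
  }
  ScoreTrack(scores, id = id)
}

#' Write a score track to a plain-text file
#'
#' @param track A [ScoreTrack-class] or numeric vector.
#' @param path Output path.
#' @param positions Write a two-column `position score` file? Default `FALSE`.
#' @return Invisibly, `path`.
#' @export
writeScoreTrack <- function(track, path, positions = FALSE) {
  x <- if (methods::is(track, "ScoreTrack")) track@scores else as.numeric(track)
  lines <- if (positions) paste(seq_along(x), format(x, digits = 15, trim = TRUE))
           else format(x, digits = 15, trim = TRUE)
  writeLines(lines, path)
  invisible(path)
}
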