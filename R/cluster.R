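#' Read a square probability matrix with header labels
#'
#' TSV or CSV, first column and header row carrying the labels. Values
#' greater than 1 are taken to be percentages and rescaled by 1/100 (with a
#' message), since HMM-HMM comparison tools report probabilities on either
#' scale.
#'
#' @param path Path to the matrix file.
#' @return A numeric matrix with identical row and column labels, entries in
#'   [0, 1].
#' @export
readProbabilityMatrix <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  m <- as.matrix(utils::read.table(path, header = TRUE, sep = sep,
                                   row.names = 1L, check.names = FALSE,
                                   comment.char = "#"))
  storage.mode(m) <- "double"
  if (nrow(m) != ncol(m)) stop("matrix is not square")
  if (!identical(rownames(m), colnames(m)))
    stop("row and column labels differ")
  if (any(!is.finite(m))) stop("non-finite matrix entries")
  if (any(m > 1)) {
    message("values > 1 detected: interpreting as percentages, rescaling by 1/100")
    m <- m / 100
  }
  if (any(m < 0) || any(m > 1)) stop("probabilities must lie in [0, 1]")
  m
}

#' Convert match probabilities to a negative-log dissimilarity matrix
#'
#' Entries are floored at `floor` (default 0.001) before taking the negative
#' natural logarithm, so that zero probabilities do not map to infinity; by
#' default the floor applies to every entry below it, which keeps the
#' probability-to-dissimilarity map monotone (`zero_only = TRUE` restricts
#' the substitution to literal zeros). Directed entry pairs are symmetrized,
#' by their arithmetic mean by default (`symmetrize = "max"` takes the more
#' probable direction, i.e. the smaller dissimilarity). The diagonal is
#' forced to zero.
#'
#' @param P Square numeric probability matrix (entries in [0, 1]).
#' @param floor Probability floor, default `0.001`.
#' @param zero_only Apply the floor only to exact zeros? Default `FALSE`.
#' @param symmetrize `"mean"` (default) or `"max"` (on the probability
#'   scale).
#' @return A symmetric non-negative dissimilarity matrix with zero diagonal.
#' @examples
#' P <- matrix(c(1, 0.5, 0.25, 1), 2, 2, dimnames = list(c("a","b"), c("a","b")))
#' toDissimilarity(P)
#' @export
toDissimilarity <- function(P, floor = 0.001, zero_only = FALSE,
                            symmetrize = c("mean", "max")) {
  symmetrize <- match.arg(symmetrize)
  if (!is.matrix(P) || nrow(P) != ncol(P)) stop("P must be a square matrix")
  if (any(P < 0) || any(P > 1)) stop("probabilities must lie in [0, 1]")
  Pf <- if (zero_only) ifelse(P == 0, floor, P) else pmax(P, floor)
  D <- -log(Pf)
  D <- if (symmetrize == "mean") (D + t(D)) / 2 else pmin(D, t(D))
  diag(D) <- 0
  dimnames(D) <- dimnames(P)
  D
}

#' Average-linkage hierarchical clustering with a deterministic tie-break
#'
#' UPGMA-style agglomeration on a symmetric dissimilarity matrix: the pair
#' of clusters with the smallest mean pairwise dissimilarity is merged at a
#' height equal to that mean, with inter-cluster means maintained by the
#' exact Lance-Williams average-linkage update. Exact ties are broken by the
#' lexicographically smallest pair of cluster representatives (a cluster is
#' represented by its smallest member label), making the result independent
#' of input row order.
#'
#' @param D Symmetric numeric dissimilarity matrix (labelled, zero diagonal,
#'   no `NA`s), or a [stats::dist] object.
#' @return An object of class `hclust` (usable with [stats::cutree()],
#'   [stats::cophenetic()], `plot()`), with `method = "average"`.
#' @export
averageLinkage <- function(D) {
  if (inherits(D, "dist")) D <- as.matrix(D)
  if (!is.matrix(D) || nrow(D) != ncol(D)) stop("D must be a square matrix")
  n <- nrow(D)
  if (n < 2L) stop("need at least two items")
  if (any(is.na(D))) stop("NA entries in dissimilarity matrix")
  if (max(abs(D - t(D))) > 1e-12) stop("dissimilarity matrix is not symmetric")
  labels <- rownames(D)
  if (is.null(labels)) labels <- paste0("L", seq_len(n))

  d <- D
  size <- rep(1L, n)
  rep_ <- labels                 # cluster representative: smallest member label
  id <- -seq_len(n)              # hclust coding: -leaf, +merge step
  active <- seq_len(n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)

  for (step in seq_len(n - 1L)) {
    best <- NULL
    bestd <- Inf
    for (ii in seq_along(active)) {
      for (jj in seq_len(ii - 1L)) {
        a <- active[jj]; b <- active[ii]
        dv <- d[a, b]
        if (dv < bestd - 0) {
          bestd <- dv; best <- c(a, b)
        } else if (dv == bestd) {
          # lexicographically smallest representative pair
          cur <- sort(c(rep_[a], rep_[b]))
          old <- sort(c(rep_[best[1L]], rep_[best[2L]]))
          if (cur[1L] < old[1L] ||
              (cur[1L] == old[1L] && cur[2L] < old[2L])) {
            best <- c(a, b)
          }
        }
      }
    }
    i <- best[1L]; j <- best[2L]
    m <- sort(c(id[i], id[j]))           # negatives (leaves) first, then by step
    merge[step, ] <- m
    height[step] <- bestd
    # Lance-Williams average update into slot i; retire slot j
    others <- setdiff(active, c(i, j))
    if (length(others) > 0L) {
      newd <- (size[i] * d[i, others] + size[j] * d[j, others]) /
        (size[i] + size[j])
      d[i, others] <- newd
      d[others, i] <- newd
    }
    size[i] <- size[i] + size[j]
    rep_[i] <- min(rep_[i], rep_[j])
    id[i] <- step
    active <- setdiff(active, j)
  }

  out <- structure(list(merge = merge, height = height,
                        order = .leafOrder(merge),
                        labels = labels, method = "average",
                        call = match.call(),
                        dist.method = "neg-log-probability"),
                   class = "hclust")
  out
}

# Left-to-right leaf order implied by the merge matrix (for plotting).
.leafOrder <- function(merge) {
  expand <- function(k) {
    if (k < 0L) return(-k)
    c(expand(merge[k, 1L]), expand(merge[k, 2L]))
  }
  expand(nrow(merge))
}

#' Merge table of a dendrogram
#'
#' @param tree An `hclust` object.
#' @return A data.frame with one row per agglomeration step: `step`,
#'   `members` (comma-joined leaf labels of the newly formed cluster), and
#'   `height`.
#' @export
mergeTable <- function(tree) {
  stopifnot(inherits(tree, "hclust"))
  members <- function(k) {
    if (k < 0L) return(tree$labels[-k])
    c(members(tree$merge[k, 1L]), members(tree$merge[k, 2L]))
  }
  data.frame(step = seq_along(tree$height),
             members = vapply(seq_along(tree$height), function(s)
               paste(sort(members(s)), collapse = ","), character(1L)),
             height = tree$height)
}

#' Export a dendrogram as a Newick string
#'
#' Leaves sit at height zero; each branch length is the difference between
#' the parent's merge height and the child's height.
#'
#' @param tree An `hclust` object (e.g. from [averageLinkage()]).
#' @param digits Significant digits for branch lengths, default 10.
#' @return A single Newick string terminated by `;`.
#' @examples
#' D <- matrix(c(0, 2, 2, 0), 2, 2, dimnames = list(c("a","b"), c("a","b")))
#' toNewick(averageLinkage(D)) # "(a:2,b:2);"
#' @export
toNewick <- function(tree, digits = 10L) {
  stopifnot(inherits(tree, "hclust"))
  fmt <- function(x) format(x, digits = digits, trim = TRUE, scientific = FALSE)
  node <- function(k, parentHeight) {
    if (k < 0L)
      return(sprintf("%s:%s", tree$labels[-k], fmt(parentHeight)))
    h <- tree$height[k]
    sprintf("(%s,%s):%s",
            node(tree$merge[k, 1L], h), node(tree$merge[k, 2L], h),
            fmt(parentHeight - h))
  }
  root <- nrow(tree$merge)
  h <- tree$height[root]
  sprintf("(%s,%s);", node(tree$merge[root, 1L], h),
          node(tree$merge[root, 2L], h))
}
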