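# Uncorrected pairwise distances with pairwise deletion, and desk-scale
# distance-based tree building.

code_sites <- function(x) {
  m <- match(x, DNA_STATES)          # anything not A/C/G/T becomes NA
  matrix(m, nrow = if (is.matrix(x)) nrow(x) else 1L)
}

#' Uncorrected p-distance between two aligned sequences
#'
#' Sites where either symbol is not one of A/C/G/T (gaps, \code{?}, \code{N}
#' and IUPAC partial ambiguities) are excluded per pair (pairwise deletion).
#' The distance is the mismatch fraction over the jointly resolved sites,
#' or \code{NA} when fewer than `min_overlap` sites remain.
#'
#' @param a,b aligned sequences: strings or character vectors of equal
#'   length.
#' @param min_overlap minimum number of jointly resolved sites for the
#'   distance to be defined (default 100).
#' @return numeric distance in \code{[0, 1]}, or \code{NA} if undefined; the
#'   overlap count is attached as attribute \code{"overlap"}.
#' @export
p_distance <- function(a, b, min_overlap = 100) {
  if (is.character(a) && length(a) == 1L) a <- strsplit(toupper(a), "")[[1L]]
  if (is.character(b) && length(b) == 1L) b <- strsplit(toupper(b), "")[[1L]]
  if (length(a) != length(b))
    stop("sequences have unequal lengths (", length(a), " vs ", length(b), ")")
  ca <- match(toupper(a), DNA_STATES)
  cb <- match(toupper(b), DNA_STATES)
  ok <- !is.na(ca) & !is.na(cb)
  overlap <- sum(ok)
  d <- if (overlap < min_overlap) NA_real_ else sum(ca[ok] != cb[ok]) / overlap
  structure(d, overlap = overlap)
}

#' All-pairs uncorrected distance matrix
#'
#' Computes every pairwise p-distance of an alignment under pairwise
#' deletion, together with per-pair overlap counts. Implemented with
#' indicator-matrix products, so it scales to a few thousand terminals.
#'
#' @param aln alignment matrix (see [as_alignment()]).
#' @param min_overlap minimum jointly resolved sites; pairs below it get
#'   \code{NA} ("undefined") distances.
#' @return an object of class \code{motu_dist}: list with \code{ids},
#'   \code{d} (symmetric distance matrix, \code{NA} where undefined),
#'   \code{overlap} (integer matrix) and \code{min_overlap}.
#' @export
distance_matrix <- function(aln, min_overlap = 100) {
  aln <- as_alignment(aln)
  ids <- rownames(aln)
  n <- nrow(aln)
  matches <- matrix(0, n, n)
  for (s in DNA_STATES) {
    x <- (aln == s) * 1
    matches <- matches + tcrossprod(x)
  }
  resolved <- matrix(as.numeric(matrix(aln %in% DNA_STATES, nrow = n)), n)
  overlap <- tcrossprod(resolved)
  d <- (overlap - matches) / overlap        # 0/0 -> NaN, masked below
  d[overlap < min_overlap] <- NA_real_
  diag(d) <- 0
  dimnames(d) <- list(ids, ids)
  ov <- matrix(as.integer(round(overlap)), n, dimnames = list(ids, ids))
  structure(list(ids = ids, d = d, overlap = ov,
                 min_overlap = min_overlap),
            class = "motu_dist")
}

#' @export
print.motu_dist <- function(x, ...) {
  n <- length(x$ids)
  nd <- sum(is.na(x$d[upper.tri(x$d)]))
  cat("Uncorrected distance matrix:", n, "terminals,",
      nd, "undefined pair(s) (overlap <", x$min_overlap, "sites)\n")
  invisible(x)
}

check_defined <- function(D) {
  if (anyNA(D$d))
    stop("distance matrix has undefined entries (overlap < ",
         D$min_overlap, " sites); remove the affected terminals or impute ",
         "before tree building")
}

#' Neighbor-joining tree from a distance matrix
#'
#' @param D a \code{motu_dist} object with all entries defined and at least
#'   three terminals.
#' @return unrooted `phylo` tree.
#' @export
neighbor_joining <- function(D) {
  check_defined(D)
  if (length(D$ids) < 3L) stop("neighbor joining needs at least 3 terminals")
  ape::nj(D$d)
}

#' UPGMA (average-linkage, ultrametric) tree from a distance matrix
#'
#' @inheritParams neighbor_joining
#' @return rooted ultrametric `phylo` tree.
#' @export
upgma_tree <- function(D) {
  check_defined(D)
  if (length(D$ids) < 2L) stop("UPGMA needs at least 2 terminals")
  phangorn::upgma(stats::as.dist(D$d))
}
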