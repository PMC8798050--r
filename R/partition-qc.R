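# Alignment-quality screens applied to partitions before phylogenetic
# analysis: relative composition frequency variation (RCFV), Bowker's
# maximum symmetry test, and completeness scores, with exclusion rules.

state_frequencies <- function(aln, states = DNA_STATES) {
  counts <- vapply(states,
                   function(s) rowSums(matrix(aln == s, nrow = nrow(aln))),
                   numeric(nrow(aln)))
  counts <- matrix(counts, nrow = nrow(aln),
                   dimnames = list(rownames(aln), states))
  tot <- rowSums(counts)
  list(freq = counts / tot, resolved = tot)
}

#' Relative composition frequency variation (RCFV)
#'
#' Per-taxon state frequencies are computed over resolved sites only; RCFV
#' is the sum over taxa and states of the absolute deviation from the
#' across-taxa mean frequency, divided by the number of taxa. Values of 0
#' indicate identical composition; compositional heterogeneity within a
#' partition is conventionally called high when RCFV >= 0.1.
#'
#' @param aln alignment matrix for one partition.
#' @return RCFV value (non-negative scalar). Taxa without any resolved site
#'   are excluded with a warning.
#' @export
rcfv <- function(aln) {
  aln <- as_alignment(aln)
  sf <- state_frequencies(aln)
  empty <- sf$resolved == 0
  if (any(empty)) {
    warning("excluding ", sum(empty),
            " taxon/taxa with zero resolved sites from RCFV")
    sf$freq <- sf$freq[!empty, , drop = FALSE]
  }
  f <- sf$freq
  if (nrow(f) < 2L) stop("RCFV needs at least two taxa with resolved sites")
  mu <- colMeans(f)
  sum(abs(sweep(f, 2L, mu))) / nrow(f)
}

#' Bowker's maximum symmetry test for one sequence pair
#'
#' Jointly resolved site pairs are tabulated into a 4x4 substitution count
#' matrix n; the statistic is S = sum over unordered state pairs with
#' n_ij + n_ji > 0 of (n_ij - n_ji)^2 / (n_ij + n_ji), with one degree of
#' freedom per included pair and an upper-tail chi-square p-value.
#' Rejection flags violations of the stationarity/reversibility/homogeneity
#' assumptions.
#'
#' @param a,b aligned sequences (strings or character vectors).
#' @return list with `statistic`, `df`, `p.value` and logical `degenerate`
#'   (no off-diagonal counts at all, in which case p = 1).
#' @export
bowker_test <- function(a, b) {
  if (is.character(a) && length(a) == 1L) a <- strsplit(toupper(a), "")[[1L]]
  if (is.character(b) && length(b) == 1L) b <- strsplit(toupper(b), "")[[1L]]
  if (length(a) != length(b)) stop("sequences have unequal lengths")
  ca <- match(toupper(a), DNA_STATES)
  cb <- match(toupper(b), DNA_STATES)
  ok <- !is.na(ca) & !is.na(cb)
  n <- matrix(tabulate((ca[ok] - 1L) * 4L + cb[ok], nbins = 16L), 4L, 4L,
              byrow = TRUE)
  S <- 0; df <- 0L
  for (i in 1:3) for (j in (i + 1L):4L) {
    tot <- n[i, j] + n[j, i]
    if (tot > 0) {
      S <- S + (n[i, j] - n[j, i])^2 / tot
      df <- df + 1L
    }
  }
  if (df == 0L)
    return(list(statistic = 0, df = 0L, p.value = 1, degenerate = TRUE))
  list(statistic = S, df = df,
       p.value = stats::pchisq(S, df, lower.tail = FALSE),
       degenerate = FALSE)
}

#' All-pairs Bowker p-values within a partition
#'
#' @param aln alignment matrix.
#' @param max_pairs optional cap on the number of pairs tested (sampled
#'   deterministically by taking the first pairs in row order) to bound
#'   runtime on large partitions; `Inf` tests all pairs.
#' @return list with `p` (symmetric matrix of p-values, `NA` on the
#'   diagonal), `min_p`, and `prop_failing` at alpha = 0.05.
#' @export
bowker_matrix <- function(aln, max_pairs = Inf) {
  aln <- as_alignment(aln)
  n <- nrow(aln)
  pm <- matrix(NA_real_, n, n, dimnames = list(rownames(aln), rownames(aln)))
  pairs <- which(upper.tri(pm), arr.ind = TRUE)
  if (nrow(pairs) > max_pairs) pairs <- pairs[seq_len(max_pairs), , drop = FALSE]
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1L]; j <- pairs[k, 2L]
    p <- bowker_test(aln[i, ], aln[j, ])$p.value
    pm[i, j] <- pm[j, i] <- p
  }
  ps <- pm[upper.tri(pm)]
  ps <- ps[!is.na(ps)]
  list(p = pm, min_p = if (length(ps)) min(ps) else NA_real_,
       prop_failing = if (length(ps)) mean(ps < 0.05) else NA_real_)
}

#' Alignment completeness score
#'
#' The fraction of matrix cells that are unambiguous nucleotides (anything
#' other than A/C/G/T — gaps, \code{?}, \code{N}, IUPAC ambiguities —
#' counts as missing).
#'
#' @param aln alignment matrix.
#' @param by `"overall"` for the scalar score Ca, `"taxon"` for per-row
#'   scores.
#' @return numeric in \code{[0, 1]} (vector when `by = "taxon"`).
#' @export
completeness_score <- function(aln, by = c("overall", "taxon")) {
  by <- match.arg(by)
  aln <- as_alignment(aln)
  resolved <- matrix(aln %in% DNA_STATES, nrow = nrow(aln))
  if (by == "overall") mean(resolved)
  else stats::setNames(rowMeans(resolved), rownames(aln))
}

#' Quality-control report for a partitioned supermatrix
#'
#' Computes, per partition, the RCFV value, the minimum pairwise Bowker
#' p-value (with the fraction of failing pairs), and the completeness score.
#'
#' @param aln concatenated alignment.
#' @param scheme partition scheme (see [concatenate_fragments()]).
#' @param max_pairs per-partition cap on Bowker pairs (see
#'   [bowker_matrix()]).
#' @return data.frame with one row per partition.
#' @export
qc_report <- function(aln, scheme, max_pairs = Inf) {
  rows <- lapply(seq_len(nrow(scheme)), function(i) {
    sub <- extract_partition(aln, scheme, scheme$fragment[i],
                             drop_empty = TRUE)
    bw <- bowker_matrix(sub, max_pairs = max_pairs)
    data.frame(fragment = scheme$fragment[i],
               rcfv = rcfv(sub),
               min_bowker_p = bw$min_p,
               prop_failing_pairs = bw$prop_failing,
               completeness = completeness_score(sub),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Apply the exclusion rules to a QC report
#'
#' A partition is dropped when its RCFV is at or above `rcfv_cutoff` or when
#' its minimum pairwise Bowker p-value falls below `symmetry_alpha`; reasons
#' are recorded.
#'
#' @param report data.frame from [qc_report()].
#' @param rcfv_cutoff drop partitions with RCFV >= this value (default 0.1).
#' @param symmetry_alpha drop partitions whose minimum pairwise Bowker
#'   p-value is below this level (default 0.05).
#' @return list with `kept` and `dropped` fragment names and the annotated
#'   `report` (columns `keep`, `reason`).
#' @export
filter_partitions <- function(report, rcfv_cutoff = 0.1,
                              symmetry_alpha = 0.05) {
  bad_rcfv <- report$rcfv >= rcfv_cutoff
  bad_sym <- !is.na(report$min_bowker_p) & report$min_bowker_p < symmetry_alpha
  reason <- character(nrow(report))
  reason[bad_sym] <- "symmetry"
  reason[bad_rcfv] <- "RCFV"
  reason[bad_rcfv & bad_sym] <- "RCFV+symmetry"
  report$keep <- !(bad_rcfv | bad_sym)
  report$reason <- ifelse(report$keep, "", reason)
  list(kept = report$fragment[report$keep],
       dropped = report$fragment[!report$keep],
       report = report)
}
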