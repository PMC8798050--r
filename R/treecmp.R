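# Bipartition machinery: split sets, Robinson-Foulds distances across
# replicate runs, rogue-terminal ranking, backbone constraints and
# compliance checking.

#' Nontrivial bipartitions of a tree
#'
#' Each split is encoded canonically as the sorted, pipe-joined labels of
#' the side that does not contain the alphabetically first leaf, so split
#' sets from different trees over the same leaves are directly comparable.
#' Multifurcations are handled (they simply yield fewer splits).
#'
#' @param tree a `phylo`.
#' @return character vector of canonical split keys (possibly empty).
#' @export
tree_splits <- function(tree) {
  tree <- ape::unroot(tree)
  labs <- tree$tip.label
  n <- length(labs)
  if (n < 4L) return(character(0))
  ref <- min(labs)
  pp <- ape::prop.part(tree)
  keys <- vapply(pp, function(cl) {
    side <- labs[cl]
    if (length(side) <= 1L || length(side) >= n - 1L) return(NA_character_)
    if (ref %in% side) side <- setdiff(labs, side)
    paste(sort(side), collapse = "|")
  }, "")
  unique(keys[!is.na(keys)])
}

split_key <- function(side, all_labels) {
  if (min(all_labels) %in% side) side <- setdiff(all_labels, side)
  paste(sort(side), collapse = "|")
}

#' Robinson-Foulds distance between two trees
#'
#' Trees are first restricted to their shared leaf set; the raw RF distance
#' is the size of the symmetric difference of the nontrivial split sets, and
#' the normalized value divides by 2(n - 3), the maximum attainable for
#' binary trees over n shared leaves. For multifurcating inputs the
#' attainable maximum is lower than 1; the value is reported unrescaled.
#'
#' @param t1,t2 `phylo` trees sharing at least four leaves.
#' @return list with `rf` (raw count), `nrf` (normalized) and `n_shared`.
#' @export
robinson_foulds <- function(t1, t2) {
  shared <- intersect(t1$tip.label, t2$tip.label)
  n <- length(shared)
  if (n < 4L)
    stop("trees share only ", n, " leaves; at least 4 are required")
  s1 <- tree_splits(ape::keep.tip(t1, shared))
  s2 <- tree_splits(ape::keep.tip(t2, shared))
  rf <- length(setdiff(s1, s2)) + length(setdiff(s2, s1))
  list(rf = rf, nrf = rf / (2 * (n - 3)), n_shared = n)
}

#' Pairwise normalized RF matrix over replicate trees
#'
#' @param trees a list of `phylo` trees or a `multiPhylo`.
#' @return list with `nrf` (hollow symmetric matrix) and `summary`
#'   (min/mean/max over distinct pairs).
#' @export
rf_matrix <- function(trees) {
  trees <- unclass(trees)
  k <- length(trees)
  if (k < 2L) stop("need at least two trees")
  nm <- names(trees) %||% paste0("tree", seq_len(k))
  m <- matrix(0, k, k, dimnames = list(nm, nm))
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    m[i, j] <- m[j, i] <- robinson_foulds(trees[[i]], trees[[j]])$nrf
  }
  vals <- m[upper.tri(m)]
  list(nrf = m,
       summary = c(min = min(vals), mean = mean(vals), max = max(vals)))
}

#' Rank leaves by topological instability across replicate trees
#'
#' A leaf's instability score is the mean, over all tree pairs, of the drop
#' in normalized RF distance when that leaf is pruned from both trees.
#' Leaves whose removal reconciles conflicting replicate topologies
#' ("wandering" terminals) score highest.
#'
#' @param trees list of `phylo` trees over a common leaf set (at least 5
#'   shared leaves, so pruning leaves 4).
#' @return data.frame with columns `leaf` and `score`, sorted descending.
#' @export
leaf_instability <- function(trees) {
  trees <- unclass(trees)
  leaves <- Reduce(intersect, lapply(trees, `[[`, "tip.label"))
  if (length(leaves) < 5L)
    stop("need at least 5 shared leaves to score instability")
  k <- length(trees)
  pairs <- utils::combn(k, 2L)
  base <- apply(pairs, 2L, function(p)
    robinson_foulds(trees[[p[1L]]], trees[[p[2L]]])$nrf)
  score <- vapply(leaves, function(l) {
    pruned <- lapply(trees, function(tr) ape::drop.tip(tr, l))
    drop_nrf <- apply(pairs, 2L, function(p)
      robinson_foulds(pruned[[p[1L]]], pruned[[p[2L]]])$nrf)
    mean(base - drop_nrf)
  }, 0)
  out <- data.frame(leaf = leaves, score = unname(score),
                    stringsAsFactors = FALSE)
  out[order(-out$score, out$leaf), , drop = FALSE]
}

#' Backbone topological constraint
#'
#' A backbone tree over anchor taxa whose relative topology an inference
#' over a superset of taxa must preserve; all other taxa are free. This is
#' the object written for a constrained search (e.g. IQ-TREE's \code{-g}).
#'
#' @param backbone `phylo` over the anchor taxa (multifurcations allowed).
#' @param taxa full taxon list; must contain all anchors.
#' @return object of class `backbone_constraint`.
#' @export
backbone_constraint <- function(backbone, taxa) {
  missing <- setdiff(backbone$tip.label, taxa)
  if (length(missing))
    stop("anchor taxa absent from the full taxon list: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  structure(list(backbone = backbone, taxa = taxa),
            class = "backbone_constraint")
}

#' Write a backbone constraint to a newick file
#'
#' Only anchor taxa appear in the file; unlisted taxa are unconstrained by
#' the convention of downstream search tools.
#'
#' @param bc a `backbone_constraint`.
#' @param path output path.
#' @export
write_constraint <- function(bc, path) {
  stopifnot(inherits(bc, "backbone_constraint"))
  write_tree(bc$backbone, path)
}

#' Check a full tree against a backbone constraint
#'
#' The full tree is restricted to the anchor taxa; it complies iff every
#' nontrivial split of the backbone occurs in the restricted tree. Adding
#' non-anchor taxa anywhere in the full tree cannot change the verdict.
#'
#' @param full `phylo` over a superset of the anchor taxa.
#' @param bc a `backbone_constraint`.
#' @return list with logical `compliant` and character `violated` (split
#'   keys of backbone splits missing from the restricted tree).
#' @export
check_backbone_compliance <- function(full, bc) {
  stopifnot(inherits(bc, "backbone_constraint"))
  anchors <- bc$backbone$tip.label
  missing <- setdiff(anchors, full$tip.label)
  if (length(missing))
    stop("full tree lacks anchor taxa: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  bs <- tree_splits(bc$backbone)
  if (!length(bs)) return(list(compliant = TRUE, violated = character(0)))
  restricted <- ape::keep.tip(full, anchors)
  violated <- setdiff(bs, tree_splits(restricted))
  list(compliant = length(violated) == 0L, violated = violated)
}
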