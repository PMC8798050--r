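# Per-branch quartet support from gene trees (ASTRAL-style pies) and
# four-cluster likelihood mapping (FcLM) on alignments.

#' Collapse poorly supported gene-tree branches
#'
#' Internal branches whose node support label is at most `threshold` are
#' contracted into multifurcations (so the quartets they subtend are counted
#' as unresolved). Branch lengths are discarded: only topology feeds the
#' quartet tallies.
#'
#' @param tree `phylo` with numeric node labels (support values); trees
#'   without node labels are returned unchanged.
#' @param threshold support value at or below which a branch is collapsed.
#' @return `phylo`, possibly multifurcating.
#' @export
collapse_low_support <- function(tree, threshold) {
  if (is.null(tree$node.label)) return(tree)
  sup <- suppressWarnings(as.numeric(tree$node.label))
  ntip <- length(tree$tip.label)
  nodes <- ntip + seq_len(tree$Nnode)
  drop_nodes <- nodes[!is.na(sup) & sup <= threshold]
  drop_nodes <- setdiff(drop_nodes, ntip + 1L)   # never the root
  tree$edge.length <- rep(1, nrow(tree$edge))
  tree$edge.length[tree$edge[, 2L] %in% drop_nodes] <- 0
  tree <- ape::di2multi(tree, tol = 1e-8)
  tree$edge.length <- NULL
  tree
}

# Quadripartition blocks (A, B | C, D) around every internal branch of a
# binary species tree: A and B are the child subtrees below the branch, C
# and D the two subtrees on the far side.
quadripartitions <- function(species_tree) {
  st <- ape::unroot(species_tree)
  if (!ape::is.binary(st))
    stop("species tree must be binary (after unrooting)")
  labs <- st$tip.label
  ntip <- length(labs)
  root <- ntip + 1L
  tipsets <- c(as.list(seq_len(ntip)), ape::prop.part(st))
  tips_of <- function(node) labs[tipsets[[node]]]
  parent <- integer(ntip + st$Nnode)
  parent[st$edge[, 2L]] <- st$edge[, 1L]
  children <- split(st$edge[, 2L], st$edge[, 1L])
  out <- list()
  for (v in setdiff(root + seq_len(st$Nnode) - 1L, root)) {
    kids <- children[[as.character(v)]]
    A <- tips_of(kids[1L]); B <- tips_of(kids[2L])
    u <- parent[v]
    sibs <- setdiff(children[[as.character(u)]], v)
    if (u == root) {
      C <- tips_of(sibs[1L]); D <- tips_of(sibs[2L])
    } else {
      C <- tips_of(sibs[1L])
      D <- setdiff(labs, tips_of(u))
    }
    out[[split_key(c(A, B), labs)]] <- list(A = A, B = B, C = C, D = D)
  }
  out
}

sample_quartets <- function(blocks, cap) {
  sizes <- vapply(blocks, length, 0L)
  total <- prod(sizes)
  if (total <= cap) {
    g <- expand.grid(a = blocks[[1L]], b = blocks[[2L]], c = blocks[[3L]],
                     d = blocks[[4L]], stringsAsFactors = FALSE)
    as.matrix(g)
  } else {
    cbind(a = sample(blocks[[1L]], cap, replace = TRUE),
          b = sample(blocks[[2L]], cap, replace = TRUE),
          c = sample(blocks[[3L]], cap, replace = TRUE),
          d = sample(blocks[[4L]], cap, replace = TRUE))
  }
}

# Which of the three resolutions does `tree` induce on the quartet
# (a, b, c, d)? 1 = ab|cd, 2 = ac|bd, 3 = ad|bc, NA = unresolved.
induced_quartet <- function(tree, q) {
  sub <- ape::keep.tip(tree, q)
  s <- tree_splits(sub)
  if (!length(s)) return(NA_integer_)
  keys <- c(split_key(q[1:2], q), split_key(q[c(1L, 3L)], q),
            split_key(q[c(1L, 4L)], q))
  match(s[1L], keys)
}

#' Per-branch quartet support from gene trees
#'
#' For every internal branch of a binary species tree, quartets with one
#' leaf in each block of the branch's quadripartition are enumerated (or
#' uniformly sampled above `max_quartets`); each gene tree's induced quartet
#' is classified as the species-tree resolution (q1) or one of the two
#' alternatives (q2, q3), and frequencies are reported over resolved
#' observations — the quantity ASTRAL prints with `-t 2`.
#'
#' @param species_tree binary `phylo` reference tree.
#' @param gene_trees list of `phylo` trees; leaf sets must be subsets of the
#'   species-tree leaves.
#' @param collapse_threshold if non-`NULL`, gene-tree branches with support
#'   at or below this value are collapsed first (see
#'   [collapse_low_support()]).
#' @param max_quartets per-branch cap on enumerated quartets.
#' @param seed RNG seed used when sampling above the cap.
#' @return data.frame with one row per internal branch: the branch's split
#'   key, `q1`, `q2`, `q3` (frequencies, `NA` when no gene tree contains a
#'   usable quartet) and `n` (resolved observations).
#' @export
branch_quartet_support <- function(species_tree, gene_trees,
                                   collapse_threshold = NULL,
                                   max_quartets = 100, seed = 1) {
  gene_trees <- unclass(gene_trees)
  extra <- setdiff(unique(unlist(lapply(gene_trees, `[[`, "tip.label"))),
                   species_tree$tip.label)
  if (length(extra))
    stop("gene-tree leaves absent from species tree: ",
         paste(utils::head(extra, 5L), collapse = ", "))
  if (!is.null(collapse_threshold))
    gene_trees <- lapply(gene_trees, collapse_low_support,
                         threshold = collapse_threshold)
  quads <- quadripartitions(species_tree)
  set.seed(seed)
  rows <- lapply(names(quads), function(key) {
    qs <- sample_quartets(quads[[key]], max_quartets)
    counts <- c(0L, 0L, 0L)
    for (gt in gene_trees) {
      present <- qs[rowSums(matrix(!(qs %in% gt$tip.label),
                                   nrow = nrow(qs))) == 0L, , drop = FALSE]
      for (r in seq_len(nrow(present))) {
        topo <- induced_quartet(gt, present[r, ])
        if (!is.na(topo)) counts[topo] <- counts[topo] + 1L
      }
    }
    n <- sum(counts)
    q <- if (n > 0L) counts / n else rep(NA_real_, 3L)
    data.frame(branch = key, q1 = q[1L], q2 = q[2L], q3 = q[3L], n = n,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

quartet_trees <- function(q, bl = 0.1) {
  make <- function(p) {
    txt <- sprintf("((%s:%g,%s:%g):%g,(%s:%g,%s:%g):%g);",
                   p[1L], bl, p[2L], bl, bl / 2, p[3L], bl, p[4L], bl, bl / 2)
    ape::read.tree(text = txt)
  }
  list(make(q), make(q[c(1L, 3L, 2L, 4L)]), make(q[c(1L, 4L, 2L, 3L)]))
}

#' Four-cluster likelihood mapping
#'
#' Quartets with one taxon drawn from each of four predefined disjoint
#' groups are evaluated under JC69: for each quartet the log-likelihoods of
#' the three possible topologies are maximized over branch lengths, turned
#' into normalized weights, and the quartet is attributed to the basin of
#' its highest-weight topology (ties within `tie_tol` are "unresolved").
#' Basin percentages over all evaluated quartets summarize where the signal
#' points.
#'
#' @param aln alignment matrix covering all group members.
#' @param groups named list of four disjoint, non-empty character vectors of
#'   terminal ids.
#' @param n_quartets cap on evaluated quartets; all combinations are used
#'   when their number is at most the cap, otherwise a uniform sample.
#' @param seed RNG seed (mandatory for sampling reproducibility).
#' @param min_overlap minimum pairwise jointly resolved sites within a
#'   quartet; quartets below it are skipped and counted.
#' @param tie_tol log-likelihood difference below which the top two
#'   topologies are considered tied.
#' @return object of class `fclm_report`: list with `basin_pct` (named
#'   percentages for T1, T2, T3, unresolved; sums to 100), `weights`
#'   (matrix, one row per evaluated quartet), `n_evaluated`, `n_skipped`,
#'   and `quartets`.
#' @export
fclm <- function(aln, groups, n_quartets = 1000, seed = 1,
                 min_overlap = 100, tie_tol = 1e-6) {
  aln <- as_alignment(aln)
  if (length(groups) != 4L || any(!lengths(groups)))
    stop("groups must be a list of four non-empty taxon sets")
  if (any(duplicated(unlist(groups))))
    stop("the four groups must be disjoint")
  missing <- setdiff(unlist(groups), rownames(aln))
  if (length(missing))
    stop("group taxa absent from alignment: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  set.seed(derive_seed(seed, "quartets"))
  qs <- sample_quartets(groups, n_quartets)
  n_skipped <- 0L
  weights <- matrix(numeric(0), ncol = 3L)
  basins <- integer(0)   # 1..3, 0 = unresolved
  kept <- character(0)
  for (r in seq_len(nrow(qs))) {
    q <- qs[r, ]
    sub <- aln[q, , drop = FALSE]
    ok <- TRUE
    for (i in 1:3) for (j in (i + 1L):4L) {
      if (attr(p_distance(sub[i, ], sub[j, ], min_overlap = min_overlap),
               "overlap") < min_overlap) ok <- FALSE
    }
    if (!ok) {
      n_skipped <- n_skipped + 1L
      next
    }
    ll <- vapply(quartet_trees(q), quartet_loglik, 0, sub = sub)
    w <- exp(ll - max(ll))
    w <- w / sum(w)
    weights <- rbind(weights, w)
    o <- order(ll, decreasing = TRUE)
    basins <- c(basins,
                if (ll[o[1L]] - ll[o[2L]] < tie_tol) 0L else o[1L])
    kept <- c(kept, paste(q, collapse = ","))
  }
  n_eval <- length(basins)
  pct <- if (n_eval) 100 * c(T1 = sum(basins == 1L), T2 = sum(basins == 2L),
                             T3 = sum(basins == 3L),
                             unresolved = sum(basins == 0L)) / n_eval
         else c(T1 = NA_real_, T2 = NA_real_, T3 = NA_real_,
                unresolved = NA_real_)
  colnames(weights) <- c("p1", "p2", "p3")
  structure(list(basin_pct = pct, weights = weights,
                 n_evaluated = n_eval, n_skipped = n_skipped,
                 quartets = kept),
            class = "fclm_report")
}

quartet_loglik <- function(tree, sub) {
  dat <- phangorn::phyDat(sub[tree$tip.label, , drop = FALSE], type = "DNA")
  fit <- phangorn::pml(tree, dat)
  fit <- suppressWarnings(
    phangorn::optim.pml(fit, optEdge = TRUE,
                        control = phangorn::pml.control(trace = 0,
                                                        epsilon = 1e-8,
                                                        maxit = 25)))
  as.numeric(fit$logLik)
}

#' @export
print.fclm_report <- function(x, ...) {
  cat("Four-cluster likelihood mapping:", x$n_evaluated,
      "quartets evaluated,", x$n_skipped, "skipped\n")
  print(round(x$basin_pct, 1))
  invisible(x)
}
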