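# Independent oracles and small fixture builders used across the suite.
# These deliberately avoid the code paths they check.

# Connected components of the threshold graph by boolean reachability
# (repeated squaring of the adjacency matrix), independent of the
# union-find used by cluster_single_linkage().
oracle_components <- function(d, t) {
  n <- nrow(d)
  adj <- !is.na(d) & d <= t
  diag(adj) <- TRUE
  reach <- adj
  repeat {
    nxt <- (reach %*% reach) > 0
    if (identical(nxt, reach > 0)) break
    reach <- nxt
  }
  comp <- integer(n)
  next_id <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) {
      next_id <- next_id + 1L
      comp[reach[i, ] > 0] <- next_id
    }
  }
  comp
}

# Partition equality up to cluster relabeling.
same_partition <- function(a, b) {
  identical(match(a, unique(a)), match(b, unique(b)))
}

# Wrap a plain symmetric matrix as the distance-matrix structure the
# clustering functions consume.
fake_dist <- function(d, ids = NULL, min_overlap = 1) {
  ids <- ids %||% rownames(d) %||% paste0("x", seq_len(nrow(d)))
  dimnames(d) <- list(ids, ids)
  ov <- matrix(1000L, nrow(d), ncol(d), dimnames = dimnames(d))
  structure(list(ids = ids, d = d, overlap = ov, min_overlap = min_overlap),
            class = "motu_dist")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

random_symmetric_dist <- function(n) {
  d <- matrix(0, n, n)
  d[upper.tri(d)] <- stats::runif(n * (n - 1) / 2)
  d <- d + t(d)
  fake_dist(d)
}

random_alignment <- function(n, len, missing_frac = 0) {
  m <- matrix(sample(c("A", "C", "G", "T"), n * len, replace = TRUE), n,
              dimnames = list(paste0("t", seq_len(n)), NULL))
  if (missing_frac > 0) {
    k <- round(missing_frac * n * len)
    m[sample(n * len, k)] <- sample(c("-", "?", "N"), k, replace = TRUE)
  }
  m
}

# Hand-built partition object for accounting tests.
new_partition_for_test <- function(assignment, threshold = 0.05,
                                   method = "single_linkage") {
  reps <- vapply(split(names(assignment), assignment),
                 function(m) sort(m)[1L], "")
  structure(list(assignment = assignment, representatives = reps,
                 threshold = threshold, method = method),
            class = "motu_partition")
}

# Canonical split key as tree_splits() encodes it, recomputed here so tests
# can state expected splits without calling package internals.
split_key_for <- function(side, all_labels) {
  if (min(all_labels) %in% side) side <- setdiff(all_labels, side)
  paste(sort(side), collapse = "|")
}

# Four-point classification of the quartet (a, b, c, d) in a tree with all
# branch lengths set to 1: the resolution with the smallest pair-sum wins;
# ties mean the quartet is unresolved. Independent of the split machinery.
oracle_quartet <- function(tree, q) {
  tree$edge.length <- rep(1, nrow(tree$edge))
  dm <- ape::cophenetic.phylo(tree)[q, q]
  s <- c(dm[1, 2] + dm[3, 4], dm[1, 3] + dm[2, 4], dm[1, 4] + dm[2, 3])
  if (sum(s == min(s)) > 1L) NA_integer_ else which.min(s)
}
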