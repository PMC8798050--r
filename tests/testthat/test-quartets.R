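test_that("concordant gene trees give q = (1, 0, 0) on every branch", {
  st <- ape::unroot(ape::read.tree(text = "(((A,B),(C,D)),((E,F),G));"))
  qs <- branch_quartet_support(st, rep(list(st), 10))
  expect_identical(nrow(qs), ape::Ntip(st) - 3L)
  expect_true(all(qs$q1 == 1))
  expect_true(all(qs$q2 == 0 & qs$q3 == 0))
  expect_true(all(abs(qs$q1 + qs$q2 + qs$q3 - 1) < 1e-9))
})

test_that("gene trees split evenly over the three resolutions give thirds", {
  st <- ape::read.tree(text = "((A,B),(C,D));")
  gts <- list(ape::read.tree(text = "((A,B),(C,D));"),
              ape::read.tree(text = "((A,C),(B,D));"),
              ape::read.tree(text = "((A,D),(B,C));"))
  qs <- branch_quartet_support(st, gts)
  expect_identical(nrow(qs), 1L)
  expect_equal(unlist(qs[1, c("q1", "q2", "q3")]), c(q1 = 1, q2 = 1, q3 = 1) / 3)
})

test_that("quartet frequencies match the four-point oracle on 6 leaves", {
  # symmetric species tree whose quadripartition blocks are known by hand
  st <- ape::read.tree(text = "((A,B),((C,D),(E,F)));")
  blocks <- list(
    list(A = "A", B = "B", C = c("C", "D"), D = c("E", "F")),
    list(A = "C", B = "D", C = c("E", "F"), D = c("A", "B")),
    list(A = "E", B = "F", C = c("C", "D"), D = c("A", "B")))
  # branch keys are canonical split keys (side not containing "A")
  names(blocks) <- vapply(blocks, function(b)
    split_key_for(c(b$A, b$B), LETTERS[1:6]), "")
  set.seed(41)
  gts <- lapply(1:5, function(i) ape::rtree(6, tip.label = LETTERS[1:6]))
  got <- branch_quartet_support(st, gts, max_quartets = 1000)
  expect_setequal(got$branch, names(blocks))

  for (key in names(blocks)) {
    bl <- blocks[[key]]
    counts <- c(0L, 0L, 0L)
    for (gt in gts) {
      for (a in bl$A) for (b in bl$B) for (c_ in bl$C) for (d in bl$D) {
        # the reference resolution pairs the two child blocks (a with b)
        topo <- oracle_quartet(gt, c(a, b, c_, d))
        if (!is.na(topo)) counts[topo] <- counts[topo] + 1L
      }
    }
    r <- which(got$branch == key)
    expect_identical(got$n[r], sum(counts))
    # q1 is the species-tree resolution; the labeling of the two
    # alternatives depends on block order, so compare them as a set
    expect_equal(got$q1[r], counts[1] / sum(counts))
    expect_equal(sort(c(got$q2[r], got$q3[r])),
                 sort(counts[2:3] / sum(counts)))
  }
})

test_that("quartet support is invariant to gene-tree order", {
  set.seed(43)
  st <- ape::rtree(7)
  gts <- lapply(1:6, function(i) ape::rtree(7))
  a <- branch_quartet_support(st, gts)
  b <- branch_quartet_support(st, rev(gts))
  expect_equal(a, b)
})

test_that("low-support branches are collapsed before tallying", {
  gt <- ape::read.tree(text = "((A,B)5,C,(D,E)95);")
  collapsed <- collapse_low_support(gt, 10)
  expect_identical(tree_splits(collapsed), split_key_for(c("D", "E"),
                                                         LETTERS[1:5]))
  expect_length(tree_splits(collapse_low_support(gt, 2)), 2L)

  st <- ape::read.tree(text = "((A,B),(C,D));")
  weak <- ape::read.tree(text = "((A,B)5,(C,D)8);")
  with_collapse <- branch_quartet_support(st, list(weak),
                                          collapse_threshold = 10)
  expect_identical(with_collapse$n, 0L)   # fully collapsed -> unresolved
  expect_true(is.na(with_collapse$q1))
  without <- branch_quartet_support(st, list(weak))
  expect_identical(without$n, 1L)
  expect_equal(without$q1, 1)
})

test_that("FcLM attributes simulated quartets to the generating topology", {
  # long internal branch: the signal for T1 = (G1,G2)|(G3,G4) is strong
  tr <- ape::read.tree(
    text = "((a1:0.05,a2:0.05):0.15,(b1:0.05,(c1:0.02,c2:0.02):0.05):0.15);")
  aln <- simulate_sequences(tr, 800, seed = 19)
  rep <- fclm(aln, list(G1 = c("a1"), G2 = c("a2"), G3 = c("b1"),
                        G4 = c("c1", "c2")),
              n_quartets = 10, seed = 2, min_overlap = 100)
  expect_equal(sum(rep$basin_pct), 100)
  expect_gte(rep$basin_pct[["T1"]], 95)
  expect_true(all(abs(rowSums(rep$weights) - 1) < 1e-9))
  # deterministic under the seed
  rep2 <- fclm(aln, list(G1 = "a1", G2 = "a2", G3 = "b1",
                         G4 = c("c1", "c2")),
               n_quartets = 10, seed = 2, min_overlap = 100)
  expect_identical(rep$basin_pct, rep2$basin_pct)
})

test_that("FcLM calls identical sequences unresolved and weak internal
           branches yield no dominant basin", {
  s <- strrep("ACGT", 60)
  ident <- as_alignment(c(a = s, b = s, c = s, d = s))
  r <- fclm(ident, list(A = "a", B = "b", C = "c", D = "d"), seed = 1,
            min_overlap = 50)
  expect_equal(unname(r$basin_pct["unresolved"]), 100)

  # near-zero internal branch over 4 clades: quartets resolve at random
  set.seed(47)
  clades <- paste0("(", c("g1a:0.05,g1b:0.05,g1c:0.05",
                          "g2a:0.05,g2b:0.05,g2c:0.05",
                          "g3a:0.05,g3b:0.05,g3c:0.05",
                          "g4a:0.05,g4b:0.05,g4c:0.05"), ")")
  tr <- ape::read.tree(text = sprintf("((%s:0.0001,%s:0.0001):0.0001,(%s:0.0001,%s:0.0001):0.0001);",
                                      clades[1], clades[2], clades[3],
                                      clades[4]))
  aln <- simulate_sequences(tr, 600, seed = 23)
  groups <- list(G1 = paste0("g1", letters[1:3]),
                 G2 = paste0("g2", letters[1:3]),
                 G3 = paste0("g3", letters[1:3]),
                 G4 = paste0("g4", letters[1:3]))
  weak <- fclm(aln, groups, n_quartets = 81, seed = 3, min_overlap = 100)
  expect_equal(sum(weak$basin_pct), 100)
  expect_lt(max(weak$basin_pct[c("T1", "T2", "T3")]), 60)
})
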