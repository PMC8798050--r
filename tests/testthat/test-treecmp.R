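test_that("RF distance handles identity, total conflict and restriction", {
  t1 <- ape::read.tree(text = "((A,B),(C,D),E);")
  expect_identical(robinson_foulds(t1, t1)$rf, 0L)
  expect_equal(robinson_foulds(t1, t1)$nrf, 0)

  t2 <- ape::read.tree(text = "((A,C),(B,D),E);")
  got <- robinson_foulds(t1, t2)
  expect_identical(got$rf, 4L)
  expect_equal(got$nrf, 1.0)

  # extra leaves are pruned to the shared set first
  t3 <- ape::read.tree(text = "(((A,X),B),((C,Y),D),E);")
  expect_identical(robinson_foulds(t1, t3)$rf, 0L)

  expect_error(robinson_foulds(ape::read.tree(text = "((A,B),C);"),
                               ape::read.tree(text = "((A,B),D);")),
               "share only")
})

test_that("RF matches phangorn on random 8-leaf pairs", {
  set.seed(13)
  for (i in 1:50) {
    t1 <- ape::rtree(8)
    t2 <- ape::rtree(8)
    expect_identical(robinson_foulds(t1, t2)$rf,
                     as.integer(phangorn::RF.dist(ape::unroot(t1),
                                                  ape::unroot(t2))))
  }
})

test_that("RF satisfies the metric axioms on random triples", {
  set.seed(17)
  for (i in 1:30) {
    n <- sample(5:10, 1)
    trs <- lapply(1:3, function(k) ape::rtree(n))
    d12 <- robinson_foulds(trs[[1]], trs[[2]])$rf
    d13 <- robinson_foulds(trs[[1]], trs[[3]])$rf
    d23 <- robinson_foulds(trs[[2]], trs[[3]])$rf
    expect_identical(d12, robinson_foulds(trs[[2]], trs[[1]])$rf)
    expect_lte(d13, d12 + d23)
    expect_identical(robinson_foulds(trs[[1]], trs[[1]])$rf, 0L)
  }
})

test_that("rf_matrix is hollow, symmetric and consistent with pairwise
           calls", {
  one <- ape::rtree(10)
  reps <- rep(list(one), 19)
  m0 <- rf_matrix(reps)
  expect_true(all(m0$nrf == 0))
  expect_equal(unname(m0$summary), c(0, 0, 0))

  set.seed(29)
  trees <- list(a = ape::rtree(8), b = ape::rtree(8))
  trees$c <- trees$a
  m <- rf_matrix(trees)
  off <- m$nrf[upper.tri(m$nrf)]
  expect_identical(sum(off == 0), 1L)   # exactly the a-c pair
  for (i in 1:2) for (j in (i + 1):3)
    expect_equal(m$nrf[i, j],
                 robinson_foulds(trees[[i]], trees[[j]])$nrf)
})

test_that("leaf instability flags the moved terminal", {
  base <- ape::read.tree(text = "(((A,B),(C,D)),((E,F),(G,H)));")
  ident <- leaf_instability(list(base, base))
  expect_true(all(ident$score == 0))

  # move H next to A in the second tree; everything else is unchanged
  moved <- ape::read.tree(text = "((((A,H),B),(C,D)),((E,F),G));")
  rank <- leaf_instability(list(base, moved))
  expect_identical(rank$leaf[1], "H")
  expect_gt(rank$score[1], 0)

  # consistent relabeling permutes scores with the leaves
  perm <- setNames(LETTERS[8:1], LETTERS[1:8])
  relabel <- function(tr) {
    tr$tip.label <- unname(perm[tr$tip.label]); tr
  }
  rank2 <- leaf_instability(list(relabel(base), relabel(moved)))
  expect_equal(setNames(rank2$score, rank2$leaf)[unname(perm[rank$leaf])],
               setNames(rank$score, unname(perm[rank$leaf])),
               tolerance = 1e-12)
})

test_that("pruning one leaf changes raw RF by at most 2 per tree", {
  set.seed(31)
  for (i in 1:20) {
    n <- sample(6:10, 1)
    t1 <- ape::rtree(n); t2 <- ape::rtree(n)
    base <- robinson_foulds(t1, t2)$rf
    leaf <- sample(t1$tip.label, 1)
    pruned <- robinson_foulds(ape::drop.tip(t1, leaf),
                              ape::drop.tip(t2, leaf))$rf
    expect_lte(abs(base - pruned), 4)   # 2 per tree in the pair
  }
})

test_that("backbone constraints are written and checked correctly", {
  anchors <- sprintf("a%02d", 1:35)
  bb <- ape::rtree(35)
  bb$tip.label <- anchors
  bc <- backbone_constraint(bb, c(anchors, sprintf("free%03d", 1:100)))
  f <- withr::local_tempfile(fileext = ".nwk")
  write_constraint(bc, f)
  back <- read_tree(f)
  expect_identical(ape::Ntip(back), 35L)
  expect_identical(robinson_foulds(back, bb)$rf, 0L)

  expect_error(backbone_constraint(bb, anchors[-1]), "absent from the full")

  star <- ape::read.tree(text = "(A,B,C,D);")
  any_tree <- ape::read.tree(text = "((A,C),(B,D),E);")
  sc <- backbone_constraint(star, c(LETTERS[1:4], "E"))
  expect_true(check_backbone_compliance(any_tree, sc)$compliant)

  bb2 <- ape::read.tree(text = "((A,B),(C,D));")
  bc2 <- backbone_constraint(bb2, c(LETTERS[1:4], "x", "y"))
  good <- ape::read.tree(text = "((A,(B,x)),((C,y),D));")
  expect_true(check_backbone_compliance(good, bc2)$compliant)
  bad <- ape::read.tree(text = "((A,(C,x)),((B,y),D));")
  verdict <- check_backbone_compliance(bad, bc2)
  expect_false(verdict$compliant)
  expect_identical(verdict$violated, split_key_for(c("A", "B"),
                                                   LETTERS[1:4]))
})

test_that("compliance is invariant to grafting free taxa", {
  set.seed(37)
  bb <- ape::rtree(6)
  bb$edge.length <- NULL
  bb$tip.label <- paste0("anchor", 1:6)
  # pair every anchor with a free taxon and add a free outgroup clade: the
  # restriction to anchors is unchanged, so the verdict must not change
  txt <- ape::write.tree(bb)
  for (i in 1:6)
    txt <- sub(paste0("anchor", i),
               sprintf("(anchor%d,free%d)", i, i), txt, fixed = TRUE)
  txt <- sub(";$", "", txt)
  full <- ape::read.tree(text = paste0("(", txt, ",(free7,free8));"))
  bc <- backbone_constraint(bb, full$tip.label)
  expect_true(check_backbone_compliance(full, bc)$compliant)

  # and a non-compliant core stays non-compliant after grafting
  bad_core <- ape::read.tree(text =
    "(((anchor1,anchor3),anchor2),(anchor4,(anchor5,(anchor6,free9))));")
  bc2 <- backbone_constraint(bb, c(bb$tip.label, "free9"))
  v1 <- check_backbone_compliance(ape::drop.tip(bad_core, "free9"), bc2)
  v2 <- check_backbone_compliance(bad_core, bc2)
  expect_identical(v1$compliant, v2$compliant)
  expect_identical(sort(v1$violated), sort(v2$violated))
})
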