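test_that("distance models transform mismatch fractions correctly", {
  aln <- c(a = "AAAA", b = "AAAA", c = "AATT")
  d <- distance_matrix(aln, "p")
  expect_equal(d["a", "b"], 0)
  expect_equal(d["a", "c"], 0.5)
  expect_equal(unname(diag(d)), rep(0, 3))
  expect_equal(distance_matrix(aln, "jc")["a", "c"],
               -0.75 * log(1 - 4 * 0.5 / 3))
  expect_equal(distance_matrix(aln, "poisson")["a", "c"], -log(0.5))
  # saturation guards
  sat <- c(a = "AAAA", b = "TTTA")
  expect_error(distance_matrix(sat, "jc"), "saturated pair a/b")
  # gapped columns use pairwise deletion
  gap <- c(a = "A-AA", b = "ATAA")
  expect_equal(distance_matrix(gap, "p")["a", "b"], 0)
})

test_that("distances match simulated substitution fractions", {
  set.seed(41)
  n <- 2000
  x <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  y <- x
  flip <- sample(n, 300)    # exactly 300 mismatches
  for (i in flip) y[i] <- sample(setdiff(c("A", "C", "G", "T"), y[i]), 1)
  d <- distance_matrix(rbind(a = x, b = y), "p")
  expect_equal(d["a", "b"], 300 / n)
})

test_that("3-taxon neighbor joining solves the three-point equations", {
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(d)
  dd <- ape::cophenetic.phylo(tr$phylo)[c("a", "b", "c"), c("a", "b", "c")]
  expect_equal(dd, d, tolerance = 1e-12)
})

test_that("NJ inverts additive matrices exactly (random 5-taxon trees)", {
  set.seed(55)
  for (rep in 1:20) {
    truth <- ape::rtree(5)
    d <- ape::cophenetic.phylo(truth)
    tr <- nj_tree(d)
    expect_equal(phangorn::RF.dist(ape::unroot(tr$phylo), ape::unroot(truth)), 0)
    dd <- ape::cophenetic.phylo(tr$phylo)[rownames(d), colnames(d)]
    expect_equal(dd, d, tolerance = 1e-9)
    # independent implementation agrees on the topology
    expect_equal(phangorn::RF.dist(tr$phylo, ape::nj(as.dist(d))), 0)
  }
})

test_that("all-equal distances resolve deterministically by the tie-break", {
  d <- matrix(1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(d) <- 0
  t1 <- nj_tree(d)
  t2 <- nj_tree(d)
  expect_identical(ape::write.tree(t1$phylo), ape::write.tree(t2$phylo))
  # lexicographically smallest pair (a, b) is joined first
  mrca_ab <- ape::getMRCA(t1$phylo, c("a", "b"))
  expect_setequal(chromosel:::descendant_tips(t1$phylo, mrca_ab),
                  match(c("a", "b"), t1$phylo$tip.label))
})

test_that("bootstrap support is 100 for a clean split and order-invariant", {
  aln <- c(a = strrep("AT", 30), b = strrep("AT", 30),
           c = strrep("GC", 30), d = strrep("GC", 30))
  tr <- bootstrap_support(aln, replicates = 50, seed = 3)
  expect_true(all(tr$support[!is.na(tr$support)] >= 0 &
                    tr$support[!is.na(tr$support)] <= 100))
  internal <- tr$support[tr$support > 0]
  expect_true(any(tr$support == 100))

  perm <- aln[c("d", "b", "a", "c")]
  tr2 <- bootstrap_support(perm, replicates = 50, seed = 3)
  expect_equal(sort(tr2$support), sort(tr$support))

  # bit-exact reproducibility under a fixed seed
  tr3 <- bootstrap_support(aln, replicates = 100, seed = 11)
  tr4 <- bootstrap_support(aln, replicates = 100, seed = 11)
  expect_identical(tr3$support, tr4$support)
  expect_identical(ape::write.tree(tr3$phylo), ape::write.tree(tr4$phylo))
})

test_that("branch labeling marks clade stems and validates monophyly", {
  tf <- tempfile()
  writeLines("(((a:1,b:1):1,(c:1,d:1):1):1,(e:1,f:1):2);", tf)
  tr <- read_newick(tf)
  lab <- label_branches(tr, list(TR = c("a", "b", "c", "d")))
  expect_equal(sum(lab$edge_types == "TR"), 1)
  expect_equal(sum(lab$edge_types == "background"),
               nrow(lab$phylo$edge) - 1)
  # the labeled edge subtends exactly the clade
  e <- which(lab$edge_types == "TR")
  node <- lab$phylo$edge[e, 2]
  expect_setequal(
    lab$phylo$tip.label[chromosel:::descendant_tips(lab$phylo, node)],
    c("a", "b", "c", "d"))

  expect_error(label_branches(tr, list(X = c("a", "c"))), "not monophyletic")
  expect_error(label_branches(tr, list(A = c("a", "b"), B = c("b", "a"))),
               "overlapping")

  # several disjoint clades -> one labeled stem each
  lab3 <- label_branches(tr, list(A = "a", B = "b", CD = c("c", "d"),
                                  E = "e", F1 = "f"))
  expect_equal(sum(lab3$edge_types != "background"), 5)
})
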