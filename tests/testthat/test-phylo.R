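test_that("p-distance and Poisson correction follow their formulas", {
  msa <- new_msa(c(a = "ACDE", b = "ACDE", c = "ACDF"))
  D0 <- distance_matrix(msa, correction = "none")
  expect_equal(D0["a", "b"], 0)
  expect_equal(D0["a", "c"], 0.25)
  Dp <- distance_matrix(msa, correction = "poisson")
  expect_equal(Dp["a", "c"], -log(0.75))
  # gaps and X excluded from the comparable set
  msa2 <- new_msa(c(a = "AC-EK", b = "ACDEX", c = "GGGGG"))
  expect_equal(distance_matrix(msa2, "none")["a", "b"], 0)
})

test_that("NJ reconstructs the worked additive example exactly", {
  D <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4, 4,
              dimnames = list(c("A", "B", "C", "D"), c("A", "B", "C", "D")))
  tr <- neighbor_joining(D)
  expect_true(is_separable(tr, c("A", "B")))
  expect_true(is_separable(tr, c("C", "D")))
  # leaf edges 1,2,3,4 and internal edge 1
  el <- sort(tr$edge.length)
  expect_equal(el, c(1, 1, 2, 3, 4))
  # NJ must reproduce the additive metric exactly
  expect_equal(as.matrix(ape::cophenetic.phylo(tr))[rownames(D), rownames(D)],
               D)
})

test_that("NJ recovers random additive trees and matches ape::nj", {
  for (i in 1:25) {
    tr <- random_additive_tree(sample(5:12, 1), seed = 500 + i)
    D <- ape::cophenetic.phylo(tr)
    nj1 <- neighbor_joining(D)
    expect_equal(ape::dist.topo(ape::unroot(tr), nj1), 0,
                 ignore_attr = TRUE)
    nj2 <- ape::nj(D)
    expect_equal(ape::dist.topo(nj1, nj2), 0, ignore_attr = TRUE)
  }
})

test_that("NJ topology is invariant to taxon order", {
  tr <- random_additive_tree(8, seed = 99)
  D <- ape::cophenetic.phylo(tr)
  p <- sample(nrow(D))
  nj1 <- neighbor_joining(D)
  nj2 <- neighbor_joining(D[p, p])
  expect_equal(ape::dist.topo(nj1, nj2), 0, ignore_attr = TRUE)
})

test_that("NJ rejects malformed matrices", {
  D <- matrix(runif(9), 3, 3)
  expect_error(neighbor_joining(D), ">= 4|symmetric")
  D4 <- matrix(runif(16), 4, 4)
  expect_error(neighbor_joining(D4), "symmetric")
})

test_that("is_separable detects single-edge bipartitions", {
  tr <- ape::read.tree(text = "((A1,A2),(B1,B2));")
  expect_true(is_separable(tr, c("A1", "A2")))
  tr2 <- ape::read.tree(text = "((A1,B1),(A2,B2));")
  expect_false(is_separable(tr2, c("A1", "A2")))
  expect_error(is_separable(tr, c("A1", "ZZ")), "unknown")
  expect_error(is_separable(tr, tr$tip.label), "proper")
})

test_that("is_separable agrees with bipartition enumeration via prop.part", {
  set.seed(55)
  for (i in 1:40) {
    tr <- ape::rtree(8)
    s <- sample(tr$tip.label, sample(2:6, 1))
    pp <- ape::prop.part(tr)
    labs <- attr(pp, "labels")
    oracle <- any(vapply(pp, function(cl) {
      side <- labs[cl]
      setequal(side, s) || setequal(setdiff(labs, side), s)
    }, TRUE)) || length(s) == 1L || length(s) == 7L
    expect_equal(is_separable(tr, s), oracle)
    # complement symmetry
    expect_equal(is_separable(tr, s),
                 is_separable(tr, setdiff(tr$tip.label, s)))
  }
})

test_that("reciprocal monophyly holds for root duplication, fails for grafts", {
  h <- small_bundle$histones
  tr <- gene_tree(data.frame(id = h$id, seq = h$seq))
  asg <- data.frame(id = h$id, label = paste0(h$group, "_like"))
  expect_true(reciprocal_monophyly(tr, asg)$monophyletic)
  # graft one A-labeled leaf inside the B clade
  tr2 <- ape::read.tree(text = "((a1,a2),((b1,rogue),(b2,b3)));")
  asg2 <- data.frame(id = c("a1", "a2", "b1", "b2", "b3", "rogue"),
                     label = c("A_like", "A_like", "B_like", "B_like",
                               "B_like", "A_like"))
  r <- reciprocal_monophyly(tr2, asg2)
  expect_false(r$monophyletic)
  expect_equal(r$offenders, "rogue")
})

test_that("recent independent duplications break reciprocal monophyly", {
  bneg <- simulate_dataset(sim_config(n_species = 8, n_decoys = 0,
                                      duplication_mode = "terminal",
                                      seed = 5))
  h <- bneg$histones
  tr <- gene_tree(data.frame(id = h$id, seq = h$seq))
  asg <- data.frame(id = h$id, label = paste0(h$group, "_like"))
  expect_false(reciprocal_monophyly(tr, asg)$monophyletic)
})

test_that("monophyly is invariant to branch lengths", {
  tr <- ape::read.tree(text = "((a1:1,a2:9):0.5,(b1:2,b2:0.1):7);")
  asg <- data.frame(id = c("a1", "a2", "b1", "b2"),
                    label = c("A_like", "A_like", "B_like", "B_like"))
  expect_true(reciprocal_monophyly(tr, asg)$monophyletic)
  tr$edge.length <- rep(1, nrow(tr$edge))
  expect_true(reciprocal_monophyly(tr, asg)$monophyletic)
})

test_that("parsimony events match hand-worked cases in both modes", {
  tr <- ape::read.tree(text = "((s1,s2),((s3,s4),(s5,s6)));")
  pres <- presence_matrix(paste0("s", 1:6), "A_like",
                          data.frame(species_id = paste0("s", 1:6),
                                     type = "A_like"))
  # present everywhere: no events
  for (m in c("fitch", "dollo"))
    expect_equal(parsimony_events(tr, pres, "A_like", m)$count, 0L)
  # single absence: one loss on that terminal edge
  pres2 <- pres; pres2["s4", "A_like"] <- 0L
  for (m in c("fitch", "dollo")) {
    ev <- parsimony_events(tr, pres2, "A_like", m)
    expect_equal(ev$count, 1L)
    expect_equal(ev$events$type, "loss")
    expect_equal(tr$tip.label[ev$events$node], "s4")
  }
})

test_that("fitch equals the brute-force minimum over ancestral states", {
  set.seed(66)
  for (rep in 1:12) {
    tr <- ape::rtree(sample(4:8, 1))
    for (j in 1:10) {
      st <- setNames(sample(0:1, length(tr$tip.label), replace = TRUE),
                     tr$tip.label)
      pres <- presence_matrix(tr$tip.label, "T",
                              data.frame(species_id = names(st)[st == 1],
                                         type = rep("T", sum(st))))
      fit <- parsimony_events(tr, pres, "T", "fitch")
      expect_equal(fit$count, brute_fitch(tr, st))
      expect_equal(nrow(fit$events), fit$count)
      # dollo >= fitch - 1, and fitch bounded by state boundaries
      dol <- parsimony_events(tr, pres, "T", "dollo")
      expect_gte(dol$count, fit$count - 1L)
    }
  }
})
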