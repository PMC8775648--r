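test_that("identical configs give identical bundles", {
  b1 <- simulate_dataset(sim_config(n_species = 5, n_decoys = 2, seed = 3))
  b2 <- simulate_dataset(sim_config(n_species = 5, n_decoys = 2, seed = 3))
  expect_identical(b1$histones, b2$histones)
  expect_identical(b1$proteomes, b2$proteomes)
  expect_identical(ape::write.tree(b1$tree), ape::write.tree(b2$tree))
  b3 <- simulate_dataset(sim_config(n_species = 5, n_decoys = 2, seed = 4))
  expect_false(identical(b1$histones$seq, b3$histones$seq))
})

test_that("species trees have binary rooted combinatorics and exact depth", {
  tr <- simulate_species_tree(4, seed = 1)
  expect_equal(tr$Nnode, 3L)           # internal nodes of a rooted binary
  expect_equal(nrow(tr$edge), 6L)      # edges
  expect_identical(ape::write.tree(simulate_species_tree(4, seed = 1)),
                   ape::write.tree(tr))
  # rescaled ultrametric: every root-to-tip path equals the target depth
  tr2 <- simulate_species_tree(12, seed = 2, depth = 0.09)
  depths <- ape::node.depth.edgelength(tr2)[1:12]
  expect_equal(depths, rep(0.09, 12), tolerance = 1e-10)
  expect_error(simulate_species_tree(3, seed = 1), ">= 4")
})

test_that("zero rates give two histones per species, equal to root copies", {
  cfg <- sim_config(n_species = 6, substitution_rate = 0, loss_rate = 0,
                    extra_duplication_rate = 0, n_decoys = 0, seed = 8)
  b <- simulate_dataset(cfg)
  h <- b$histones
  expect_equal(nrow(h), 12L)
  expect_true(all(table(h$species_id) == 2))
  expect_true(all(h$seq[h$group == "A"] == b$refs$seq[b$refs$id == "refA"]))
  expect_true(all(h$seq[h$group == "B"] == b$refs$seq[b$refs$id == "refB"]))
  expect_equal(nrow(b$events), 0L)
})

test_that("diagnostic sites are fixed within groups and differ between", {
  h <- default_bundle$histones
  d <- default_bundle$diag
  for (i in seq_len(nrow(d))) {
    resA <- unique(substr(h$seq[h$group == "A"], d$site[i], d$site[i]))
    resB <- unique(substr(h$seq[h$group == "B"], d$site[i], d$site[i]))
    expect_equal(resA, d$res_A[i])
    expect_equal(resB, d$res_B[i])
  }
  expect_true(all(d$res_A != d$res_B))
})

test_that("species missing a type trace back to recorded loss events", {
  cfg <- sim_config(n_species = 12, loss_rate = 0.08,
                    extra_duplication_rate = 0, n_decoys = 0, seed = 21)
  b <- simulate_dataset(cfg)
  h <- b$histones
  losses <- b$events[b$events$type == "loss", ]
  for (g in c("A", "B")) {
    have <- unique(h$species_id[h$group == g])
    missing <- setdiff(b$tree$tip.label, have)
    # leaves below each recorded loss edge of this type
    below <- character(0)
    for (nd in losses$node[losses$histone_type == g]) {
      if (nd <= length(b$tree$tip.label))
        below <- c(below, b$tree$tip.label[nd])
      else
        below <- c(below, ape::extract.clade(b$tree, nd)$tip.label)
    }
    expect_setequal(missing, unique(below))
  }
})

test_that("within-group divergence increases with configured depth", {
  depths <- c(0.02, 0.05, 0.09, 0.15, 0.25)
  mean_p <- vapply(depths, function(d) {
    ps <- vapply(1:4, function(r) {
      b <- simulate_dataset(sim_config(n_species = 6, tree_depth = d,
                                       n_decoys = 0, loss_rate = 0,
                                       extra_duplication_rate = 0,
                                       seed = 100 + r))
      h <- b$histones
      ha <- h[h$group == "A", ]
      M <- distance_matrix(new_msa(setNames(ha$seq, ha$id)), "none")
      mean(M[upper.tri(M)])
    }, 0)
    mean(ps)
  }, 0)
  expect_equal(cor(depths, mean_p, method = "spearman"), 1)
})

test_that("the default study conditions give ~85% within-group identity", {
  h <- default_bundle$histones
  for (g in c("A", "B")) {
    hg <- h[h$group == g, ]
    M <- identity_matrix(new_msa(setNames(hg$seq, hg$id)))
    expect_gt(mean(M[upper.tri(M)]), 0.78)
    expect_lt(mean(M[upper.tri(M)]), 0.92)
  }
})

test_that("emitted bundles reload losslessly through the package readers", {
  dir <- withr::local_tempdir()
  emit_dataset(small_bundle, dir)
  back <- load_dataset(dir)
  expect_equal(names(back$proteomes), names(small_bundle$proteomes))
  for (sp in names(back$proteomes)) {
    expect_equal(back$proteomes[[sp]]$id, small_bundle$proteomes[[sp]]$id)
    expect_equal(back$proteomes[[sp]]$seq, small_bundle$proteomes[[sp]]$seq)
  }
  expect_equal(back$histones$id, small_bundle$histones$id)
  expect_equal(ape::write.tree(back$tree), ape::write.tree(small_bundle$tree))
  # truth rows and emitted histone records are in bijection
  pooled_ids <- unlist(lapply(back$proteomes, `[[`, "id"))
  expect_true(all(back$histones$id %in% pooled_ids))
})
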