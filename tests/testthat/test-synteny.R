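test_that("similarity is symmetric with identity at 100", {
  set.seed(71)
  a <- random_aa(1, 80); b <- random_aa(1, 90)
  expect_equal(similarity(a, a), 100)
  expect_equal(similarity(a, b), similarity(b, a))
})

test_that("tandem doubling halves the attainable similarity", {
  set.seed(72)
  a <- random_aa(1, 100)
  expect_lte(similarity(a, paste0(a, a)), 60)
})

test_that("our aligner agrees with the Biostrings reference", {
  suppressPackageStartupMessages(requireNamespace("Biostrings"))
  e <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = e)
  set.seed(73)
  for (i in 1:10) {
    a <- random_aa(1, sample(30:150, 1))
    b <- random_aa(1, sample(30:150, 1))
    ours <- histoparalog:::align_pair(a, b)
    ref <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b),
      substitutionMatrix = e$BLOSUM62, type = "global",
      gapOpening = 10, gapExtension = 1)
    expect_equal(ours$score, Biostrings::score(ref))
    # ungapping our rows must return the inputs
    expect_equal(gsub("-", "", ours$a, fixed = TRUE), a)
    expect_equal(gsub("-", "", ours$b, fixed = TRUE), b)
  }
})

test_that("self-RBH is the identity map", {
  prot <- small_bundle$proteomes$sp001
  pairs <- reciprocal_best_hits(prot, prot)
  expect_equal(nrow(pairs), nrow(prot))
  expect_equal(pairs$query_id, pairs$ref_id)
  expect_true(all(pairs$similarity == 100))
})

test_that("a two-fold-length fusion fails the length filter", {
  set.seed(74)
  a <- random_aa(1, 120)
  q <- data.frame(id = "orig", species_id = "q", seq = a)
  r <- data.frame(id = "fusion", species_id = "r", seq = paste0(a, a))
  pairs <- reciprocal_best_hits(q, r)
  expect_equal(nrow(pairs), 0L)
})

test_that("RBH recovers simulated orthologs with no decoy pairs", {
  pr <- small_bundle$proteomes
  pairs <- reciprocal_best_hits(pr$sp002, pr$sp001)
  fam <- small_bundle$families
  fam_of <- function(ids, sp) {
    f <- fam[fam$species_id == sp, ]
    setNames(f$family, f$gene_id)[ids]
  }
  fq <- fam_of(pairs$query_id, "sp002")
  fr <- fam_of(pairs$ref_id, "sp001")
  real <- !is.na(fq) & !is.na(fr)
  expect_true(all(fq[real] == fr[real]))          # no cross-family pairs
  expect_equal(sum(is.na(fq) | is.na(fr)), 0L)    # no decoy pairs
  n_fam <- length(unique(fam$family[!is.na(fam$family)]))
  expect_gte(nrow(pairs[real, ]) / n_fam, 0.95)   # recovery
  # symmetry of the pair set
  rev <- reciprocal_best_hits(pr$sp001, pr$sp002)
  expect_setequal(paste(pairs$query_id, pairs$ref_id),
                  paste(rev$ref_id, rev$query_id))
})

test_that("neighborhood extraction respects contig edges", {
  ann <- small_bundle$annotations$sp001
  first <- ann$gene_id[which.min(ann$start)]
  nb <- neighborhood(ann, first, k = 3)
  expect_equal(nrow(nb$upstream), 0L)
  expect_equal(nrow(nb$downstream), 3L)
  expect_error(neighborhood(ann, "missing_gene", k = 3), "not annotated")
  mid <- ann$gene_id[order(ann$start)][8]
  nbm <- neighborhood(ann, mid, k = 2)
  expect_equal(nrow(nbm$upstream), 2L)
  expect_true(all(nbm$upstream$start < ann$start[ann$gene_id == mid]))
})

test_that("identical genomes give conservation 1", {
  ann <- small_bundle$annotations$sp001
  prot <- small_bundle$proteomes$sp001
  h <- small_bundle$histones
  focal <- intersect(ann$gene_id, h$id)[1]
  pairs <- reciprocal_best_hits(prot, prot)
  nb <- neighborhood(ann, focal, k = 3)
  cons <- conservation(nb, nb, pairs, k = 3)
  expect_equal(cons$combined, 1.0)
})

test_that("a planted neighborhood swap is detected", {
  bsw <- simulate_dataset(sim_config(n_species = 6, n_decoys = 2,
                                     swap_neighborhood_species = "sp003",
                                     seed = 9))
  h <- bsw$histones
  ann_q <- bsw$annotations$sp003; ann_r <- bsw$annotations$sp001
  pairs <- reciprocal_best_hits(bsw$proteomes$sp003, bsw$proteomes$sp001)
  hq <- h[h$species_id == "sp003", ]; hr <- h[h$species_id == "sp001", ]
  k <- bsw$config$neighborhood_size
  bq <- neighborhood(ann_q, hq$id[hq$group == "B"][1], k = k)
  ra <- neighborhood(ann_r, hr$id[hr$group == "A"][1], k = k)
  rb <- neighborhood(ann_r, hr$id[hr$group == "B"][1], k = k)
  cons_vs_a <- conservation(bq, ra, pairs, k = k)$combined
  cons_vs_b <- conservation(bq, rb, pairs, k = k)$combined
  expect_gt(cons_vs_a, cons_vs_b)  # B locus now carries the A neighborhood
})
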