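test_that("reference numbering skips gapped reference columns", {
  msa <- new_msa(c(ref = "A-CD", x = "AECD"))
  pos <- reference_numbering(msa, "ref")
  expect_equal(pos, c(1L, NA, 2L, 3L))
  expect_error(reference_numbering(msa, "nope"), "not in alignment")
  msa2 <- new_msa(c(ref = "---", x = "ACD"))
  expect_error(reference_numbering(msa2, "ref"), "all gaps")
})

test_that("ungapped reference length equals the largest assigned position", {
  msa <- align_center_star(setNames(small_bundle$histones$seq[1:6],
                                    small_bundle$histones$id[1:6]))
  pos <- reference_numbering(msa, msa$ids[1])
  expect_equal(max(pos, na.rm = TRUE),
               nchar(gsub("-", "", msa$rows[[msa$ids[1]]], fixed = TRUE)))
})

make_two_group_msa <- function(colsA, colsB) {
  # colsA/colsB: character vectors, one string per sequence, per group
  rows <- c(setNames(colsA, paste0("a", seq_along(colsA))),
            setNames(colsB, paste0("b", seq_along(colsB))))
  asg <- data.frame(id = names(rows),
                    label = rep(c("A_like", "B_like"),
                                c(length(colsA), length(colsB))))
  list(msa = new_msa(rows), asg = asg)
}

test_that("column D and information content follow their definitions", {
  # disjoint compositions: all Y vs all K
  x <- make_two_group_msa(rep("Y", 4), rep("K", 4))
  cp <- column_profiles(x$msa, x$asg)
  expect_equal(cp$D, 1.0)
  expect_equal(cp$IC_A, log2(20))
  expect_equal(cp$IC_B, log2(20))
  # identical compositions
  y <- make_two_group_msa(c("Y", "K"), c("Y", "K"))
  expect_equal(column_profiles(y$msa, y$asg)$D, 0)
  # half-shared: A = {Y, F}, B = {Y, K}
  z <- make_two_group_msa(c("Y", "F"), c("Y", "K"))
  cpz <- column_profiles(z$msa, z$asg)
  expect_equal(cpz$D, 0.5)
  expect_equal(cpz$IC_A, log2(20) - 1)
  expect_equal(cpz$IC_B, log2(20) - 1)
})

test_that("column profiles need two members per group and skip gaps", {
  x <- make_two_group_msa("Y", rep("K", 3))
  expect_error(column_profiles(x$msa, x$asg), ">= 2")
  g <- make_two_group_msa(c("Y-", "YK"), c("KK", "K-"))
  cp <- column_profiles(g$msa, g$asg)
  expect_equal(cp$D[1], 1.0)  # gaps ignored in column 1
})

test_that("D is symmetric in the groups and relabel-invariant", {
  x <- make_two_group_msa(c("YYK", "YKK"), c("KKE", "EKE"))
  cp1 <- column_profiles(x$msa, x$asg)
  asg_sw <- x$asg
  asg_sw$label <- ifelse(asg_sw$label == "A_like", "B_like", "A_like")
  cp2 <- column_profiles(x$msa, asg_sw)
  expect_equal(cp1$D, cp2$D)
  expect_equal(cp1$IC_A, cp2$IC_B)
  # apply a residue permutation to both groups
  perm <- chartr("YKE", "WRD", c("YYK", "YKK", "KKE", "EKE"))
  y <- make_two_group_msa(perm[1:2], perm[3:4])
  expect_equal(column_profiles(y$msa, y$asg)$D, cp1$D)
})

test_that("diagnostic calling ranks by D with threshold semantics", {
  x <- make_two_group_msa(c("YAC", "YAC"), c("KAC", "KAG"))
  cp <- column_profiles(x$msa, x$asg)
  expect_equal(nrow(call_diagnostic_columns(cp, tau_d = 0)), 3L)
  expect_equal(nrow(call_diagnostic_columns(cp, tau_d = 1 + 1e-9)), 0L)
  top <- call_diagnostic_columns(cp, tau_d = 0.9)
  expect_equal(top$column, 0L)
})

test_that("planted diagnostic sites occupy the top ranks by D", {
  h <- default_bundle$histones
  msa <- new_msa(setNames(h$seq, h$id))
  asg <- data.frame(id = h$id, label = paste0(h$group, "_like"))
  cp <- column_profiles(msa, asg)
  nd <- nrow(default_bundle$diag)
  top <- cp$column[order(-cp$D, cp$column)][seq_len(nd)] + 1L
  expect_setequal(top, default_bundle$diag$site)
})

test_that("pairwise identity counts comparable columns only", {
  expect_equal(pairwise_identity("ACDF", "ACDF"), 1.0)
  expect_equal(pairwise_identity("ACDF", "ACEF"), 0.75)
  # gap-residue is a mismatch, gap-gap columns drop out
  expect_equal(pairwise_identity("AC-D-", "ACED-"), 3 / 4)
  expect_equal(pairwise_identity("AC-D-", "ACEDK"), 3 / 5)
  expect_error(pairwise_identity("--", "--"), "comparable")
  set.seed(41)
  for (i in 1:5) {
    a <- random_aa(1, 30); b <- random_aa(1, 30)
    expect_equal(pairwise_identity(a, b), pairwise_identity(b, a))
  }
})

test_that("the bundled synthetic reference pair differs at 11 of 67 sites", {
  fp <- system.file("extdata", "synthetic_refpair.faa",
                    package = "histoparalog")
  refs <- read_fasta(fp)
  al <- histoparalog:::align_pair(refs$seq[1], refs$seq[2])
  expect_equal(pairwise_identity(al$a, al$b), 56 / 67)
})
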