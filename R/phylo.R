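# Distance matrices and deterministic neighbor-joining gene trees.
# Externally computed (e.g. maximum-likelihood) trees can be supplied as
# newick via ape::read.tree wherever a tree is consumed.

#' Pairwise evolutionary distances from an alignment
#'
#' p-distance = mismatches / columns where both rows carry a residue
#' (gaps and X excluded). The Poisson correction `d = -ln(1 - p)` accounts
#' for multiple hits; p is capped at 0.95 (with a message) to keep
#' distances finite.
#'
#' @param msa An `aa_msa` with >= 3 rows.
#' @param correction `"poisson"` (default) or `"none"`.
#' @return Symmetric distance matrix with zero diagonal.
#' @export
distance_matrix <- function(msa, correction = c("poisson", "none")) {
  correction <- match.arg(correction)
  n <- length(msa$ids)
  if (n < 3L) stopf("need >= 3 rows")
  mat <- do.call(rbind, strsplit(unname(msa$rows[msa$ids]), ""))
  ok <- matrix(mat %in% AA_ALPHABET, nrow = n)
  D <- matrix(0, n, n, dimnames = list(msa$ids, msa$ids))
  capped <- FALSE
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    comp <- ok[i, ] & ok[j, ]
    if (!any(comp)) stopf("no comparable columns between '%s' and '%s'",
                          msa$ids[i], msa$ids[j])
    p <- sum(mat[i, comp] != mat[j, comp]) / sum(comp)
    if (correction == "poisson") {
      if (p > 0.95) { p <- 0.95; capped <- TRUE }
      d <- -log(1 - p)
    } else d <- p
    D[i, j] <- D[j, i] <- d
  }
  if (capped) message("p-distance(s) > 0.95 capped before Poisson correction")
  D
}

#' Neighbor-joining tree
#'
#' Classic Saitou-Nei neighbor joining with the Studier-Keppler Q
#' criterion. Ties in Q are broken deterministically by the
#' lexicographically lowest pair of minimal descendant taxon ids. Negative
#' branch lengths are clamped to zero with the deficit moved to the sister
#' edge (their sum is preserved).
#'
#' @param D Symmetric distance matrix (>= 4 taxa, zero diagonal).
#' @return An unrooted `ape::phylo` tree.
#' @export
neighbor_joining <- function(D) {
  if (!is.matrix(D) || nrow(D) != ncol(D)) stopf("D must be square")
  if (max(abs(D - t(D))) > 1e-8) stopf("D must be symmetric")
  n <- nrow(D)
  if (n < 4L) stopf("need >= 4 taxa")
  labs <- rownames(D) %||% paste0("t", seq_len(n))
  nwk <- labs                     # newick substring per active node
  key <- labs                     # min descendant taxon id per active node
  fmt <- function(x) sprintf("%.10g", x)
  while (nrow(D) > 3L) {
    r <- nrow(D)
    R <- rowSums(D)
    Q <- (r - 2) * D - outer(R, R, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin < 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    if (nrow(cand) > 1L) {
      kk <- apply(cand, 1, function(ij) {
        k <- sort(c(key[ij[1]], key[ij[2]]))
        paste(k, collapse = "\r")
      })
      cand <- cand[order(kk), , drop = FALSE]
    }
    i <- cand[1, 1]; j <- cand[1, 2]
    vi <- D[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2))
    vj <- D[i, j] - vi
    if (vi < 0) { vj <- vj + vi; vi <- 0 }
    if (vj < 0) { vi <- vi + vj; vj <- 0 }
    if (vi < 0) vi <- 0   # both negative (D[i,j] < 0 cannot happen)
    newd <- (D[i, ] + D[j, ] - D[i, j]) / 2
    newd <- newd[-c(i, j)]
    u_nwk <- sprintf("(%s:%s,%s:%s)", nwk[i], fmt(vi), nwk[j], fmt(vj))
    u_key <- min(key[i], key[j])
    D <- D[-c(i, j), -c(i, j), drop = FALSE]
    D <- rbind(cbind(D, newd), c(newd, 0))
    nwk <- c(nwk[-c(i, j)], u_nwk)
    key <- c(key[-c(i, j)], u_key)
  }
  # final three-way join
  v1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  v2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  v3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  v <- pmax(c(v1, v2, v3), 0)
  txt <- sprintf("(%s:%s,%s:%s,%s:%s);", nwk[1], fmt(v[1]),
                 nwk[2], fmt(v[2]), nwk[3], fmt(v[3]))
  ape::read.tree(text = txt)
}

#' Gene tree from classified histones
#'
#' Center-star (or supplied) alignment, Poisson-corrected distances,
#' neighbor joining.
#'
#' @param records Protein-record `data.frame` of histones.
#' @param msa Optional precomputed `aa_msa` (e.g. imported MAFFT
#'   alignment); built with [align_center_star()] when `NULL`.
#' @param correction Distance correction, see [distance_matrix()].
#' @return An unrooted `ape::phylo` gene tree.
#' @export
gene_tree <- function(records, msa = NULL, correction = "poisson") {
  if (is.null(msa)) msa <- align_center_star(records)
  neighbor_joining(distance_matrix(msa, correction = correction))
}
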