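# Reciprocal-best-hit orthology and gene-neighborhood (synteny) comparison.

#' Percent similarity of two proteins
#'
#' Global alignment (BLOSUM62, gap open 10 / extend 1); similarity is 100
#' times the fraction of aligned pairs with a positive substitution score
#' over the full alignment length (gap columns count in the denominator) —
#' the "positives" convention of BLAST reports.
#'
#' @param a,b Amino-acid sequences (character) or one-row protein-record
#'   `data.frame`s.
#' @return Percent similarity in \[0, 100\].
#' @export
similarity <- function(a, b) {
  sa <- if (is.data.frame(a)) a$seq[[1]] else a
  sb <- if (is.data.frame(b)) b$seq[[1]] else b
  al <- align_pair(sa, sb)
  100 * al$positives / al$length
}

#' Reciprocal best hits between two proteomes
#'
#' A pair (q, r) is kept iff r is q's best hit in the reference, q is r's
#' best hit in the query (both by percent similarity, ties broken by id
#' order), the similarity exceeds `min_sim`, and the two lengths are
#' within `len_tol` of one another (`min / max >= 1 - len_tol`).
#'
#' @param proteome_q,proteome_ref Protein-record `data.frame`s.
#' @param min_sim Minimum percent similarity (default 40).
#' @param len_tol Length tolerance (default 0.2).
#' @param subset_q Optional ids restricting which query proteins are
#'   reported (best hits are still computed against the full proteomes).
#' @return `data.frame` with columns `query_id`, `ref_id`, `similarity`,
#'   `length_ratio`.
#' @export
reciprocal_best_hits <- function(proteome_q, proteome_ref, min_sim = 40,
                                 len_tol = 0.2, subset_q = NULL) {
  if (nrow(proteome_q) == 0L || nrow(proteome_ref) == 0L)
    stopf("empty proteome")
  qs <- setNames(proteome_q$seq, proteome_q$id)
  rs <- setNames(proteome_ref$seq, proteome_ref$id)
  S <- similarity_matrix(qs, rs)
  # best hit per query (rows) and per reference (columns); ties -> first id
  ordq <- order(names(qs)); ordr <- order(names(rs))
  S <- S[ordq, ordr, drop = FALSE]
  best_r <- apply(S, 1, which.max)
  best_q <- apply(S, 2, which.max)
  out <- NULL
  report <- if (is.null(subset_q)) rownames(S)
            else intersect(rownames(S), subset_q)
  for (qi in match(report, rownames(S))) {
    ri <- best_r[qi]
    if (best_q[ri] != qi) next
    sim <- S[qi, ri]
    if (sim <= min_sim) next
    lq <- nchar(qs[[rownames(S)[qi]]]); lr <- nchar(rs[[colnames(S)[ri]]])
    ratio <- min(lq, lr) / max(lq, lr)
    if (ratio < 1 - len_tol) next
    out <- rbind(out, data.frame(query_id = rownames(S)[qi],
                                 ref_id = colnames(S)[ri],
                                 similarity = sim, length_ratio = ratio,
                                 stringsAsFactors = FALSE))
  }
  out %||% data.frame(query_id = character(0), ref_id = character(0),
                      similarity = numeric(0), length_ratio = numeric(0),
                      stringsAsFactors = FALSE)
}

# full percent-similarity (positives) matrix between two named sequence
# vectors; the DP runs in compiled code
similarity_matrix <- function(qs, rs) {
  st <- .nw_stats_matrix(lapply(qs, nw_encode), lapply(rs, nw_encode),
                         blosum62_21(), 10, 1)
  S <- st$positives
  dimnames(S) <- list(names(qs), names(rs))
  S
}

#' Gene neighborhood of a focal gene
#'
#' The `k` nearest genes by start coordinate on each side of the focal
#' gene, on the focal gene's contig. Neighborhoods at contig edges are
#' shorter than `k` without error.
#'
#' @param annotations Annotation `data.frame` ([read_gff()]).
#' @param focal_id Gene id of the focal gene.
#' @param k Genes per side (default 5).
#' @return List with `focal_id`, `upstream`, `downstream` (annotation
#'   rows, sorted by genomic start).
#' @export
neighborhood <- function(annotations, focal_id, k = 5) {
  if (k < 1L) stopf("k must be >= 1")
  hit <- which(annotations$gene_id == focal_id)
  if (length(hit) == 0L) stopf("focal gene '%s' not annotated", focal_id)
  focal <- annotations[hit[1], ]
  same <- annotations[annotations$contig == focal$contig, , drop = FALSE]
  same <- same[order(same$start), , drop = FALSE]
  i <- which(same$gene_id == focal_id)
  up_idx <- seq(max(1L, i - k), i - 1L)
  dn_idx <- seq(i + 1L, min(nrow(same), i + k))
  list(focal_id = focal_id,
       upstream = if (i > 1L) same[up_idx, , drop = FALSE] else same[0, ],
       downstream = if (i < nrow(same)) same[dn_idx, , drop = FALSE]
                    else same[0, ])
}

#' Neighborhood conservation between two genomes
#'
#' Genes in each neighborhood are mapped to ortholog families via the
#' reciprocal-best-hit pairs (`query_id -> ref_id`; reference genes map to
#' themselves). Per side, conservation is the number of shared families
#' divided by `k`; the combined value is the mean of the two sides.
#'
#' @param nbhd_q,nbhd_r Neighborhoods from [neighborhood()] (query and
#'   reference genome).
#' @param pairs RBH `data.frame` from [reciprocal_best_hits()].
#' @param k Neighborhood size used (denominator).
#' @return List with `upstream`, `downstream`, `combined` fractions.
#' @export
conservation <- function(nbhd_q, nbhd_r, pairs, k = 5) {
  fam <- setNames(pairs$ref_id, pairs$query_id)
  fam_of <- function(ids, is_ref) {
    if (is_ref) ids else unname(fam[ids][!is.na(fam[ids])])
  }
  side <- function(q_side, r_side) {
    fq <- fam_of(q_side$gene_id, FALSE)
    fr <- r_side$gene_id
    length(intersect(fq, fr)) / k
  }
  up <- side(nbhd_q$upstream, nbhd_r$upstream)
  dn <- side(nbhd_q$downstream, nbhd_r$downstream)
  list(upstream = up, downstream = dn, combined = (up + dn) / 2)
}
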