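# Reference-anchored principal-component classification of histones into
# the two ancient paralog groups.

#' Project feature vectors onto principal components
#'
#' Features are z-scored (zero-variance features dropped with a message)
#' and projected onto the eigenvectors of the feature covariance matrix in
#' descending eigenvalue order. When both reference ids are given, the
#' first component's sign is oriented so the B reference scores higher
#' than the A reference (ties keep the + orientation); otherwise the sign
#' is fixed by making the largest-magnitude PC1 loading positive.
#'
#' @param vectors Numeric feature matrix with row names (ids); see
#'   [featurize_set()].
#' @param standardize Z-score features first (default `TRUE`).
#' @param ref_a,ref_b Optional row ids of the group A / group B reference
#'   sequences used to orient PC1.
#' @return A `data.frame` with columns `id`, `pc1`, `pc2`, plus attributes
#'   `loadings` and `var_explained`.
#' @export
pc_project <- function(vectors, standardize = TRUE,
                       ref_a = NULL, ref_b = NULL) {
  if (!is.matrix(vectors) || nrow(vectors) < 3L)
    stopf("need >= 3 feature vectors")
  v <- apply(vectors, 2, stats::var)
  if (any(v == 0)) {
    message("dropping zero-variance feature(s): ",
            paste(colnames(vectors)[v == 0], collapse = ", "))
    vectors <- vectors[, v > 0, drop = FALSE]
  }
  if (ncol(vectors) < 2L) stopf("fewer than 2 informative features")
  p <- prcomp(vectors, center = TRUE, scale. = standardize)
  scores <- p$x
  # deterministic default orientation
  for (j in 1:2) {
    l <- p$rotation[, j]
    if (l[which.max(abs(l))] < 0) scores[, j] <- -scores[, j]
  }
  if (!is.null(ref_a) && !is.null(ref_b)) {
    if (!all(c(ref_a, ref_b) %in% rownames(scores)))
      stopf("reference id(s) missing from feature matrix")
    if (scores[ref_b, 1] < scores[ref_a, 1]) scores[, 1] <- -scores[, 1]
  }
  out <- data.frame(id = rownames(scores), pc1 = scores[, 1],
                    pc2 = if (ncol(scores) >= 2) scores[, 2] else 0,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "loadings") <- p$rotation
  attr(out, "var_explained") <- p$sdev^2 / sum(p$sdev^2)
  out
}

#' Assign histones to paralog groups from PC1 scores
#'
#' The midpoint between the two reference scores splits PC1; a histone is
#' labeled with a reference's group when it falls on that reference's side
#' of the midpoint by at least `eps` times the reference separation, and
#' `unassigned` otherwise. The margin is the distance from the midpoint in
#' units of the reference separation.
#'
#' @param scores `data.frame` from [pc_project()] (columns `id`, `pc1`).
#' @param ref_a_id,ref_b_id Ids of the group A / group B references.
#' @param eps Dead-zone half width as a fraction of the reference
#'   separation (default 0.05).
#' @return A `data.frame` with columns `id`, `label` (`"A_like"`,
#'   `"B_like"`, `"unassigned"`), `pc1`, `margin`.
#' @export
assign_groups <- function(scores, ref_a_id, ref_b_id, eps = 0.05) {
  s <- setNames(scores$pc1, scores$id)
  if (!(ref_a_id %in% names(s)) || !(ref_b_id %in% names(s)))
    stopf("reference id(s) absent from scores")
  sa <- s[[ref_a_id]]; sb <- s[[ref_b_id]]
  if (sa == sb) stopf("references have identical PC1 scores")
  m <- (sa + sb) / 2
  d <- abs(sb - sa)
  rel <- (s - m) / d                  # signed distance in separation units
  side_a <- sign(sa - m)
  lab <- ifelse(abs(rel) >= eps,
                ifelse(sign(s - m) == side_a, "A_like", "B_like"),
                "unassigned")
  data.frame(id = names(s), label = unname(lab), pc1 = unname(s),
             margin = unname(abs(rel)), stringsAsFactors = FALSE)
}

#' Classify histones into A-like and B-like paralog groups
#'
#' End-to-end featurization + PCA + reference-anchored assignment.
#'
#' @param records Protein-record `data.frame` of detected histones,
#'   including both reference sequences.
#' @param ref_a_id,ref_b_id Record ids of the two references.
#' @param eps Dead zone for [assign_groups()].
#' @return As [assign_groups()], with the projection in attribute
#'   `projection`.
#' @export
classify_histones <- function(records, ref_a_id, ref_b_id, eps = 0.05) {
  X <- featurize_set(records)
  pr <- pc_project(X, ref_a = ref_a_id, ref_b = ref_b_id)
  out <- assign_groups(pr, ref_a_id, ref_b_id, eps = eps)
  attr(out, "projection") <- pr
  out
}
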