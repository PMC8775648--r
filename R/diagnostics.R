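# Per-column group composition, diagnostic-residue calling, information
# content, reference numbering, and pairwise identity.

#' Map alignment columns to reference numbering
#'
#' The k-th non-gap character of the reference row receives position k
#' (1-based); columns where the reference is gapped map to `NA`. Used to
#' report positions in the conventional numbering of a reference histone
#' (e.g. HMfB).
#'
#' @param msa An `aa_msa`.
#' @param ref_row_id Id of the reference row.
#' @return Integer vector of length `msa$ncol` (`NA` where the reference
#'   is gapped).
#' @export
reference_numbering <- function(msa, ref_row_id) {
  if (!ref_row_id %in% msa$ids) stopf("reference row '%s' not in alignment",
                                      ref_row_id)
  ch <- seq_chars(msa$rows[[ref_row_id]])
  if (all(ch == GAP_CHAR)) stopf("reference row is all gaps")
  pos <- rep(NA_integer_, length(ch))
  pos[ch != GAP_CHAR] <- seq_len(sum(ch != GAP_CHAR))
  pos
}

# per-group residue frequency distribution for one column (gaps/X excluded)
column_freqs <- function(col_chars) {
  keep <- col_chars %in% AA_ALPHABET
  if (!any(keep)) return(numeric(0))
  tab <- table(col_chars[keep])
  setNames(as.numeric(tab) / sum(tab), names(tab))
}

# total-variation distance between two residue distributions
tv_distance <- function(fa, fb) {
  res <- union(names(fa), names(fb))
  a <- setNames(rep(0, length(res)), res); a[names(fa)] <- fa
  b <- setNames(rep(0, length(res)), res); b[names(fb)] <- fb
  0.5 * sum(abs(a - b))
}

# information content (bits) of a residue distribution, no small-sample
# correction: log2(20) - Shannon entropy
info_content <- function(f) {
  if (length(f) == 0L) return(NA_real_)
  log2(20) + sum(f * log2(f))
}

#' Per-column group composition profiles
#'
#' For every alignment column, the residue frequency distribution of each
#' group (gaps and X excluded), the total-variation distance `D` between
#' the two group distributions, and each group's sequence-logo information
#' content (`log2(20)` minus the Shannon entropy, in bits, with no
#' small-sample correction).
#'
#' @param msa An `aa_msa` of classified histones.
#' @param assignments `data.frame` with columns `id`, `label`
#'   (`"A_like"` / `"B_like"`; other labels are ignored).
#' @param ref_row_id Optional reference row id for [reference_numbering()].
#' @return A `data.frame` with columns `column` (0-based), `ref_pos`, `D`,
#'   `IC_A`, `IC_B`, `top_A`, `top_A_freq`, `top_B`, `top_B_freq`;
#'   attribute `freqs` holds the full per-group distributions.
#' @export
column_profiles <- function(msa, assignments, ref_row_id = NULL) {
  ids_a <- assignments$id[assignments$label == "A_like"]
  ids_b <- assignments$id[assignments$label == "B_like"]
  ids_a <- intersect(ids_a, msa$ids); ids_b <- intersect(ids_b, msa$ids)
  if (length(ids_a) < 2L || length(ids_b) < 2L)
    stopf("each group needs >= 2 aligned members (A: %d, B: %d)",
          length(ids_a), length(ids_b))
  mat <- do.call(rbind, strsplit(unname(msa$rows[msa$ids]), ""))
  rownames(mat) <- msa$ids
  refpos <- if (is.null(ref_row_id)) rep(NA_integer_, msa$ncol)
            else reference_numbering(msa, ref_row_id)
  freqs <- vector("list", msa$ncol)
  out <- data.frame(column = seq_len(msa$ncol) - 1L, ref_pos = refpos,
                    D = NA_real_, IC_A = NA_real_, IC_B = NA_real_,
                    top_A = NA_character_, top_A_freq = NA_real_,
                    top_B = NA_character_, top_B_freq = NA_real_,
                    stringsAsFactors = FALSE)
  for (j in seq_len(msa$ncol)) {
    fa <- column_freqs(mat[ids_a, j])
    fb <- column_freqs(mat[ids_b, j])
    freqs[[j]] <- list(A = fa, B = fb)
    if (length(fa) && length(fb)) out$D[j] <- tv_distance(fa, fb)
    out$IC_A[j] <- info_content(fa)
    out$IC_B[j] <- info_content(fb)
    if (length(fa)) {
      out$top_A[j] <- names(fa)[which.max(fa)]
      out$top_A_freq[j] <- max(fa)
    }
    if (length(fb)) {
      out$top_B[j] <- names(fb)[which.max(fb)]
      out$top_B_freq[j] <- max(fb)
    }
  }
  attr(out, "freqs") <- freqs
  out
}

#' Call group-diagnostic alignment columns
#'
#' Columns whose between-group total-variation distance reaches `tau_d`,
#' sorted by `D` descending (ties by column index ascending).
#'
#' @param profiles Output of [column_profiles()].
#' @param tau_d Diagnostic threshold on `D` (default 0.9).
#' @return Subset of `profiles`, ordered by decreasing `D`.
#' @export
call_diagnostic_columns <- function(profiles, tau_d = 0.9) {
  if (nrow(profiles) == 0L) stopf("no column profiles supplied")
  keep <- !is.na(profiles$D) & profiles$D >= tau_d
  sub <- profiles[keep, , drop = FALSE]
  sub[order(-sub$D, sub$column), , drop = FALSE]
}

#' Pairwise identity of two aligned rows
#'
#' Identity = matches / comparable columns, where a column is comparable
#' when at least one row is non-gap; a gap aligned to a residue counts as a
#' mismatch, and gap-gap columns are excluded.
#'
#' @param a,b Gapped strings of equal length.
#' @return Identity fraction in \[0, 1\].
#' @examples
#' pairwise_identity("ACDF", "ACEF")  # 0.75
#' @export
pairwise_identity <- function(a, b) {
  ca <- seq_chars(a); cb <- seq_chars(b)
  if (length(ca) != length(cb)) stopf("rows have unequal length")
  comparable <- !(ca == GAP_CHAR & cb == GAP_CHAR)
  if (!any(comparable)) stopf("no comparable columns")
  sum(ca == cb & comparable & ca != GAP_CHAR) / sum(comparable)
}

#' Pairwise identity matrix of an alignment
#'
#' @param msa An `aa_msa`.
#' @return Symmetric matrix of identities with unit diagonal.
#' @export
identity_matrix <- function(msa) {
  n <- length(msa$ids)
  M <- matrix(1, n, n, dimnames = list(msa$ids, msa$ids))
  if (n < 2L) return(M)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    M[i, j] <- M[j, i] <- pairwise_identity(msa$rows[[msa$ids[i]]],
                                            msa$rows[[msa$ids[j]]])
  }
  M
}
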