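# Profile-matrix detection of histone-fold candidates.
#
# A position-specific log-odds matrix built from a seed alignment is slid
# ungapped along each protein; significance is calibrated against a
# composition-preserving shuffle null. This is a deterministic, fully
# specified alternative to profile-HMM search, adequate for the short,
# nearly indel-free archaeal histone fold.

#' Build a log-odds scoring profile from a seed alignment
#'
#' Columns with more than 50% gaps are dropped (with a message). For
#' retained column `c` and residue `a`,
#' `logodds[c, a] = log2(((count[c, a] + alpha) / (n_c + 20 * alpha)) / background[a])`
#' where `n_c` counts non-gap, non-`X` residues in the column.
#'
#' @param seed An `aa_msa` seed alignment with at least 2 rows.
#' @param alpha Pseudocount (Laplace `alpha = 1` by default).
#' @param background Either `"uniform"` or a named numeric vector of 20
#'   residue frequencies summing to 1 (e.g. from
#'   [residue_frequencies()] of the proteome to be scanned).
#' @return An object of class `scoring_profile`: list with `length`,
#'   `logodds` (L x 20, bits), `background`, `alpha`, `kept_columns`.
#' @export
build_profile <- function(seed, alpha = 1, background = "uniform") {
  if (!inherits(seed, "aa_msa")) stopf("seed must be an aa_msa")
  if (length(seed$ids) < 2L) stopf("seed alignment needs >= 2 rows")
  if (alpha <= 0) stopf("alpha must be positive")
  bg <- if (identical(background, "uniform"))
    setNames(rep(1 / 20, 20), AA_ALPHABET)
  else {
    if (!is.numeric(background) || length(background) != 20L)
      stopf("background must be 'uniform' or 20 frequencies")
    b <- background[AA_ALPHABET]
    if (any(is.na(b)) || any(b <= 0)) stopf("background frequencies must be > 0 for all 20 residues")
    b / sum(b)
  }
  mat <- do.call(rbind, strsplit(unname(seed$rows[seed$ids]), ""))
  gap_frac <- colMeans(mat == GAP_CHAR)
  keep <- which(gap_frac <= 0.5)
  if (length(keep) < ncol(mat))
    message(ncol(mat) - length(keep), " seed column(s) with > 50% gaps dropped")
  if (length(keep) == 0L) stopf("no seed columns left after gap filtering")
  L <- length(keep)
  counts <- matrix(0, nrow = L, ncol = 20,
                   dimnames = list(NULL, AA_ALPHABET))
  for (j in seq_len(L)) {
    col <- mat[, keep[j]]
    tab <- table(factor(col[col %in% AA_ALPHABET], levels = AA_ALPHABET))
    counts[j, ] <- as.numeric(tab)
  }
  n_c <- rowSums(counts)
  freq <- (counts + alpha) / (n_c + 20 * alpha)
  lo <- log2(sweep(freq, 2, bg, "/"))
  structure(list(length = L, logodds = lo, background = bg,
                 alpha = alpha, kept_columns = keep),
            class = "scoring_profile")
}

#' @export
print.scoring_profile <- function(x, ...) {
  cat("Scoring profile:", x$length, "columns, alpha =", x$alpha, "\n")
  cat("Max attainable score:", round(sum(apply(x$logodds, 1, max)), 2),
      "bits\n")
  invisible(x)
}

#' Residue frequencies of a proteome
#'
#' Background frequencies over the 20 canonical residues (X excluded),
#' regularized so no frequency is zero.
#'
#' @param records Protein-record `data.frame` or character vector of
#'   sequences.
#' @return Named numeric vector of 20 frequencies summing to 1.
#' @export
residue_frequencies <- function(records) {
  seqs <- if (is.data.frame(records)) records$seq else records
  ch <- unlist(strsplit(seqs, ""), use.names = FALSE)
  tab <- table(factor(ch[ch %in% AA_ALPHABET], levels = AA_ALPHABET))
  f <- (as.numeric(tab) + 1) / (sum(tab) + 20)
  setNames(f, AA_ALPHABET)
}

#' Score the best profile window in one protein
#'
#' The profile is slid ungapped along the protein; the best window's score
#' (bits) and 0-based start are returned. Proteins shorter than the profile
#' are slid inside it, with uncovered columns scoring 0; `X` residues score
#' 0 at any column.
#'
#' @param profile A `scoring_profile`.
#' @param protein One sequence (character) or a one-row protein-record
#'   `data.frame`.
#' @return A list with `score` (bits) and `start` (0-based window start;
#'   negative values are offsets of a short protein inside the profile).
#' @export
scan_protein <- function(profile, protein) {
  seq <- if (is.data.frame(protein)) protein$seq[[1]] else protein
  if (!is_valid_aa_string(seq)) stopf("invalid protein sequence")
  enc <- aa_encode(seq_chars(seq))
  r <- .scan_windows(enc, profile$logodds)
  list(score = r[[1]], start = as.integer(r[[2]]))
}

#' Calibrate a detection threshold and call hits
#'
#' The null score distribution pools, over every protein in the proteome,
#' the best-window scores of `n_shuffles` within-protein residue shuffles
#' (preserving each protein's length and composition). The calling
#' threshold is the `1 - fpr_target` quantile of that null; a protein is a
#' hit iff its observed score exceeds the threshold. The empirical p-value
#' is the fraction of null scores at or above the observed score.
#'
#' @param profile A `scoring_profile`.
#' @param proteome Protein-record `data.frame`.
#' @param n_shuffles Shuffles per protein (>= 10).
#' @param fpr_target Target false-positive rate (default 0.001).
#' @param seed Integer seed for the shuffle null.
#' @return A `data.frame` with columns `id`, `species_id`, `score`,
#'   `window_start`, `p_empirical`, `is_hit`, plus attribute `threshold`.
#' @export
calibrate_and_call <- function(profile, proteome, n_shuffles = 20,
                               fpr_target = 0.001, seed = 1) {
  if (!is.data.frame(proteome) || nrow(proteome) == 0L)
    stopf("empty proteome")
  if (n_shuffles < 10L) stopf("n_shuffles must be >= 10")
  enc <- lapply(proteome$seq, function(s) aa_encode(seq_chars(s)))
  obs <- .scan_windows_batch(enc, profile$logodds)
  starts <- vapply(enc, function(e)
    as.integer(.scan_windows(e, profile$logodds)[[2]]), 1L)
  null <- with_seed(seed, {
    sh <- vector("list", length(enc) * n_shuffles)
    k <- 0L
    for (e in enc) for (j in seq_len(n_shuffles)) {
      k <- k + 1L
      sh[[k]] <- e[sample.int(length(e))]
    }
    .scan_windows_batch(sh, profile$logodds)
  })
  tau <- as.numeric(quantile(null, probs = 1 - fpr_target, type = 1))
  p_emp <- vapply(obs, function(s) mean(null >= s), 0)
  out <- data.frame(
    id = proteome$id,
    species_id = proteome$species_id %||% NA_character_,
    score = obs, window_start = starts,
    p_empirical = p_emp, is_hit = obs > tau,
    stringsAsFactors = FALSE)
  attr(out, "threshold") <- tau
  out
}

#' Detect histone candidates in a proteome
#'
#' Convenience wrapper: proteome-composition background, profile build,
#' shuffle-null calibration, hit calling.
#'
#' @inheritParams calibrate_and_call
#' @param seed_alignment An `aa_msa` seed alignment of known histones.
#' @param alpha Pseudocount for [build_profile()].
#' @param background `"proteome"` (default; composition of the scanned
#'   proteome) or `"uniform"`.
#' @param denylist Character vector of protein ids forced to non-hits
#'   (reproduces manual exclusions); default none.
#' @return As [calibrate_and_call()], with the profile in attribute
#'   `profile`.
#' @export
detect_histones <- function(proteome, seed_alignment, n_shuffles = 20,
                            fpr_target = 0.001, seed = 1, alpha = 1,
                            background = c("proteome", "uniform"),
                            denylist = character()) {
  background <- match.arg(background)
  bg <- if (background == "proteome") residue_frequencies(proteome)
        else "uniform"
  prof <- build_profile(seed_alignment, alpha = alpha, background = bg)
  hits <- calibrate_and_call(prof, proteome, n_shuffles = n_shuffles,
                             fpr_target = fpr_target, seed = seed)
  if (length(denylist) > 0L)
    hits$is_hit[hits$id %in% denylist] <- FALSE
  attr(hits, "profile") <- prof
  hits
}
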