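# Pairwise and center-star multiple alignment (BLOSUM62, affine gaps).
# External MAFFT-style alignments can always be imported with
# read_alignment(); the built-in center-star construction is adequate for
# near-indel-free histone folds.

blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

# BLOSUM62 restricted to the package alphabet (20 residues + X), in the
# fixed encoding order used by nw_encode
blosum62_21 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ab <- c(AA_ALPHABET, "X")
      cache <<- blosum62()[ab, ab]
    }
    cache
  }
})

# encode a sequence for the C alignment core (X = 21)
nw_encode <- function(seq) {
  idx <- match(seq_chars(seq), c(AA_ALPHABET, "X"))
  if (anyNA(idx)) stopf("invalid residue in sequence")
  idx
}

# decode gapped index rows back to a gapped string
nw_decode <- function(idx) {
  ab <- c(AA_ALPHABET, "X")
  paste(ifelse(idx == 0L, GAP_CHAR, ab[pmax(idx, 1L)]), collapse = "")
}

# global pairwise alignment (Needleman-Wunsch-Gotoh, BLOSUM62, affine
# gaps: a k-long gap costs gap_open + k * gap_extend); returns gapped
# strings, score and positives count
align_pair <- function(a, b, gap_open = 10, gap_extend = 1) {
  r <- .nw_align_pair(nw_encode(a), nw_encode(b), blosum62_21(),
                      gap_open, gap_extend)
  list(a = nw_decode(r$a), b = nw_decode(r$b), score = r$score,
       positives = r$positives, length = r$length)
}

#' Center-star multiple alignment
#'
#' Picks the sequence minimizing the summed pairwise distance
#' (`100 - similarity`) as the center, aligns every other sequence to it by
#' global pairwise alignment (BLOSUM62, gap open 10 / extend 1) and merges
#' the pairwise alignments under the "once a gap, always a gap" rule.
#'
#' @param records Protein-record `data.frame` or named character vector.
#' @return An `aa_msa` object whose rows ungap to the input sequences.
#' @export
align_center_star <- function(records) {
  seqs <- if (is.data.frame(records)) setNames(records$seq, records$id)
          else records
  n <- length(seqs)
  if (n < 2L) stopf("need >= 2 sequences to align")
  ids <- names(seqs)
  # choose center by summed pairwise distance (100 - similarity)
  if (n == 2L) center <- 1L else {
    S <- similarity_matrix(seqs, seqs)
    center <- which.min(colSums(100 - S))
  }
  cseq <- seqs[[center]]
  # master gap structure of the center: vector of center positions with
  # inserted gap slots, grown as pairwise alignments are merged
  pair_aln <- vector("list", n)
  for (i in seq_len(n)) {
    if (i == center) next
    pair_aln[[i]] <- align_pair(seqs[[i]], cseq)
  }
  # count, for each center position (0..len), the max run of insertions
  # before that position across all pairwise alignments
  clen <- nchar(cseq)
  max_ins <- integer(clen + 1L)            # insertions before position k+1
  for (i in seq_len(n)) {
    if (i == center) next
    cg <- seq_chars(pair_aln[[i]]$b)
    pos <- 0L; run <- 0L
    for (ch in cg) {
      if (ch == GAP_CHAR) run <- run + 1L
      else {
        if (run > max_ins[pos + 1L]) max_ins[pos + 1L] <- run
        pos <- pos + 1L; run <- 0L
      }
    }
    if (run > max_ins[clen + 1L]) max_ins[clen + 1L] <- run
  }
  width <- clen + sum(max_ins)
  pad <- function(row_chars, center_chars) {
    # re-space one pairwise alignment onto the master column layout
    out <- character(0)
    pos <- 0L; buf <- character(0)
    flush <- function(buf, slot) {
      c(buf, rep(GAP_CHAR, slot - length(buf)))
    }
    for (k in seq_along(center_chars)) {
      if (center_chars[k] == GAP_CHAR) buf <- c(buf, row_chars[k])
      else {
        out <- c(out, flush(buf, max_ins[pos + 1L]), row_chars[k])
        buf <- character(0); pos <- pos + 1L
      }
    }
    c(out, flush(buf, max_ins[clen + 1L]))
  }
  rows <- character(n); names(rows) <- ids
  cch <- seq_chars(cseq)
  rows[center] <- paste(pad(cch, cch), collapse = "")
  for (i in seq_len(n)) {
    if (i == center) next
    rows[i] <- paste(pad(seq_chars(pair_aln[[i]]$a),
                         seq_chars(pair_aln[[i]]$b)), collapse = "")
  }
  new_msa(rows)
}
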