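# Physicochemical featurization: AAstat-style residue-class fractions plus
# the isoelectric point.

# fixed pKa table (EMBOSS-style values)
PKA_TABLE <- c(Nterm = 8.6, Cterm = 3.6,
               C = 8.5, D = 3.9, E = 4.1, Y = 10.1,   # acidic side chains
               H = 6.5, K = 10.8, R = 12.5)           # basic side chains
ACIDIC_GROUPS <- c("Cterm", "C", "D", "E", "Y")
BASIC_GROUPS  <- c("Nterm", "H", "K", "R")

# net charge of a peptide at a given pH, Henderson-Hasselbalch per group
net_charge <- function(seq, pH) {
  ch <- seq_chars(seq)
  cnt <- c(table(factor(ch, levels = AA_ALPHABET)))
  pos <- 1 / (1 + 10^(pH - PKA_TABLE["Nterm"]))
  for (a in c("H", "K", "R"))
    pos <- pos + cnt[[a]] / (1 + 10^(pH - PKA_TABLE[[a]]))
  neg <- 1 / (1 + 10^(PKA_TABLE["Cterm"] - pH))
  for (a in c("C", "D", "E", "Y"))
    neg <- neg + cnt[[a]] / (1 + 10^(PKA_TABLE[[a]] - pH))
  unname(pos - neg)
}

#' Isoelectric point of a peptide
#'
#' Finds the pH at which the net charge vanishes. Net charge sums
#' Henderson-Hasselbalch terms for the free termini and the ionizable side
#' chains (C, D, E, Y acidic; H, K, R basic) under a fixed pKa table
#' (N-terminus 8.6, C-terminus 3.6, C 8.5, D 3.9, E 4.1, H 6.5, K 10.8,
#' R 12.5, Y 10.1). The root is located by bisection on \[0, 14\] until the
#' absolute net charge falls below `tol`.
#'
#' @param seq Amino-acid sequence (X allowed; ignored, as X is never
#'   ionizable).
#' @param tol Convergence tolerance on the net charge (default 1e-4).
#' @return The isoelectric point in pH units.
#' @examples
#' isoelectric_point("GGGGG")  # termini only: (8.6 + 3.6) / 2
#' @export
isoelectric_point <- function(seq, tol = 1e-4) {
  if (!is_valid_aa_string(seq)) stopf("invalid or empty sequence")
  lo <- 0; hi <- 14
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    q <- net_charge(seq, mid)
    if (abs(q) < tol) return(mid)
    if (q > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Physicochemical feature vector of a sequence
#'
#' Fractions of the nine AAstat residue classes (Tiny, Small, Aliphatic,
#' Aromatic, NonPolar, Polar, Charged, Basic, Acidic) over the counted
#' residues (`X` excluded), with the isoelectric point appended.
#'
#' @param seq Amino-acid sequence.
#' @return Named numeric vector of length 10 (`Tiny` ... `Acidic`, `pI`).
#' @examples
#' featurize("IIII")["Aliphatic"]  # 1
#' @export
featurize <- function(seq) {
  if (!is_valid_aa_string(seq)) stopf("invalid or empty sequence")
  ch <- seq_chars(seq)
  ch <- ch[ch != "X"]
  if (length(ch) == 0L) stopf("sequence has no counted residues (all X)")
  fr <- vapply(AA_CLASSES, function(cls) mean(ch %in% cls), 0)
  c(fr, pI = isoelectric_point(seq))
}

#' Feature matrix for a set of sequences
#'
#' @param records Protein-record `data.frame` or named character vector.
#' @return Numeric matrix, one row per sequence, 10 feature columns.
#' @export
featurize_set <- function(records) {
  seqs <- if (is.data.frame(records)) setNames(records$seq, records$id)
          else records
  t(vapply(seqs, featurize, numeric(10)))
}
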