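# shared constants and small helpers

# canonical amino-acid alphabet, fixed order used by all matrices
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# residue classes in the AAstat convention (seqinr); overlapping by design,
# NonPolar and Polar partition the 20 canonical residues
AA_CLASSES <- list(
  Tiny      = c("A", "C", "G", "S", "T"),
  Small     = c("A", "C", "D", "G", "N", "P", "S", "T", "V"),
  Aliphatic = c("I", "L", "V"),
  Aromatic  = c("F", "H", "W", "Y"),
  NonPolar  = c("A", "C", "F", "G", "I", "L", "M", "P", "V", "W", "Y"),
  Polar     = c("D", "E", "H", "K", "N", "Q", "R", "S", "T"),
  Charged   = c("D", "E", "H", "K", "R"),
  Basic     = c("H", "K", "R"),
  Acidic    = c("D", "E")
)

GAP_CHAR <- "-"

seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# map residues to 1..20, X (or any non-canonical placeholder) to NA
aa_encode <- function(chars) match(chars, AA_ALPHABET)

is_valid_aa_string <- function(x) {
  !is.na(x) && nzchar(x) && grepl("^[ACDEFGHIKLMNPQRSTVWYX]+$", x)
}

# run code with a temporary RNG state so seeded operations do not clobber
# the caller's stream
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
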