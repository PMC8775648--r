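#' Read a protein FASTA file
#'
#' Reads an amino-acid FASTA file into a protein-record table. The header
#' token before the first whitespace becomes the record id; sequences are
#' uppercased and validated against the 20 canonical residues plus `X`.
#'
#' @param path Path to a FASTA text file.
#' @param species_id Optional species identifier attached to every record.
#' @return A `data.frame` with columns `id`, `species_id`, `seq`, and the
#'   (optional, `NA` when absent) locus columns `contig`, `start`, `end`,
#'   `strand`. Coordinates, where present, are 1-based inclusive.
#' @examples
#' tf <- tempfile(fileext = ".faa")
#' writeLines(c(">h1 histone", "MGELPI"), tf)
#' read_fasta(tf)
#' @export
read_fasta <- function(path, species_id = NA_character_) {
  if (!file.exists(path)) stopf("FASTA file not found: %s", path)
  # read as raw bytes so illegal residues survive to validation
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stopf("empty FASTA file: %s", path)
  ids <- vapply(strsplit(names(set), "[ \t]"), `[`, "", 1L)
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L)
    stopf("duplicate FASTA id(s): %s", paste(unique(dup), collapse = ", "))
  seqs <- toupper(as.character(set))
  for (i in seq_along(seqs)) {
    bad <- regexpr("[^ACDEFGHIKLMNPQRSTVWYX]", seqs[[i]])
    if (bad > 0L)
      stopf("illegal character '%s' at position %d of record '%s'",
            substr(seqs[[i]], bad, bad), bad, ids[[i]])
    if (!nzchar(seqs[[i]])) stopf("empty sequence for record '%s'", ids[[i]])
  }
  protein_set(ids, seqs, species_id = species_id)
}

# canonical protein-record table constructor
protein_set <- function(id, seq, species_id = NA_character_,
                        contig = NA_character_, start = NA_integer_,
                        end = NA_integer_, strand = NA_character_) {
  if (length(id) == 0L)
    return(data.frame(id = character(0), species_id = character(0),
                      seq = character(0), contig = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), stringsAsFactors = FALSE))
  df <- data.frame(id = as.character(id), species_id = species_id,
                   seq = as.character(seq), contig = contig,
                   start = as.integer(start), end = as.integer(end),
                   strand = strand, stringsAsFactors = FALSE)
  ok <- is.na(df$start) | is.na(df$end) | df$start <= df$end
  if (!all(ok)) stopf("locus with start > end for record '%s'",
                      df$id[which(!ok)[1]])
  df
}

#' Write protein records to FASTA
#'
#' Inverse of [read_fasta()]; sequence lines are wrapped at a fixed width.
#'
#' @param records A protein-record `data.frame` (columns `id`, `seq`), or a
#'   named character vector of sequences.
#' @param path Output path.
#' @param width Line width for sequence wrapping (default 60).
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(records, path, width = 60L) {
  if (is.character(records))
    records <- data.frame(id = names(records), seq = unname(records),
                          stringsAsFactors = FALSE)
  if (is.null(records) || nrow(records) == 0L)
    stopf("no records to write")
  set <- Biostrings::AAStringSet(setNames(records$seq, records$id))
  Biostrings::writeXStringSet(set, filepath = path, width = as.integer(width))
  invisible(path)
}

#' Read gene annotations from a GFF3 file
#'
#' Imports rows of the requested feature types and returns a flat annotation
#' table. The `ID` attribute (or `locus_tag` as fallback) becomes the gene
#' id; rows with neither are skipped with a warning. Coordinates stay
#' 1-based inclusive as in GFF3.
#'
#' @param path Path to a GFF3 file.
#' @param types Feature types to keep (default `c("CDS", "gene")`).
#' @return A `data.frame` with columns `gene_id`, `contig`, `start`, `end`,
#'   `strand`, `product`.
#' @export
read_gff <- function(path, types = c("CDS", "gene")) {
  if (!file.exists(path)) stopf("GFF file not found: %s", path)
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e) stopf("malformed GFF3 (%s): %s",
                                           path, conditionMessage(e)))
  gr <- gr[as.character(gr$type) %in% types]
  if (length(gr) == 0L) stopf("no rows of type %s in %s",
                              paste(types, collapse = "/"), path)
  md <- S4Vectors::mcols(gr)
  ids <- if ("ID" %in% names(md)) as.character(md$ID) else
    rep(NA_character_, length(gr))
  if ("locus_tag" %in% names(md)) {
    lt <- as.character(md$locus_tag)
    ids[is.na(ids)] <- lt[is.na(ids)]
  }
  keep <- !is.na(ids)
  if (any(!keep))
    warning(sum(!keep), " GFF row(s) without ID or locus_tag skipped")
  gr <- gr[keep]; ids <- ids[keep]
  prod <- if ("product" %in% names(S4Vectors::mcols(gr)))
    as.character(S4Vectors::mcols(gr)$product) else NA_character_
  ann <- data.frame(
    gene_id = ids,
    contig  = as.character(GenomicRanges::seqnames(gr)),
    start   = GenomicRanges::start(gr),
    end     = GenomicRanges::end(gr),
    strand  = as.character(GenomicRanges::strand(gr)),
    product = prod,
    stringsAsFactors = FALSE)
  if (anyDuplicated(ann$gene_id))
    stopf("duplicate gene_id in %s: %s", path,
          ann$gene_id[duplicated(ann$gene_id)][1])
  ann
}

#' Write gene annotations to a GFF3 file
#'
#' @param ann Annotation `data.frame` as returned by [read_gff()].
#' @param path Output path.
#' @param type Feature type written for every row (default `"CDS"`).
#' @param source Value of the GFF source column.
#' @return Invisibly, `path`.
#' @export
write_gff <- function(ann, path, type = "CDS", source = "histoparalog") {
  if (nrow(ann) == 0L) stopf("no annotations to write")
  lines <- sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t0\tID=%s%s",
                   ann$contig, source, type, ann$start, ann$end, ann$strand,
                   ann$gene_id,
                   ifelse(is.na(ann$product), "",
                          paste0(";product=", ann$product)))
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' Construct a multiple alignment object
#'
#' @param rows Named character vector of equal-length gapped strings
#'   (gap `"-"`; `"."` is normalized to `"-"`).
#' @return An object of class `aa_msa`: list with `ids`, `rows`, `ncol`.
#' @export
new_msa <- function(rows) {
  if (is.null(names(rows)) || anyDuplicated(names(rows)))
    stopf("alignment rows must have unique names")
  rows <- toupper(gsub(".", "-", rows, fixed = TRUE))
  lens <- nchar(rows)
  if (length(unique(lens)) != 1L)
    stopf("alignment rows have unequal lengths (offending row '%s': %d vs %d)",
          names(rows)[which(lens != lens[1])[1]],
          lens[which(lens != lens[1])[1]], lens[1])
  structure(list(ids = names(rows), rows = rows, ncol = unname(lens[1])),
            class = "aa_msa")
}

#' @export
print.aa_msa <- function(x, ...) {
  cat("Amino-acid alignment:", length(x$ids), "rows x", x$ncol, "columns\n")
  show <- utils::head(x$ids, 5)
  for (id in show)
    cat(sprintf("  %-20s %s%s\n", id, substr(x$rows[[id]], 1, 50),
                if (x$ncol > 50) "..." else ""))
  if (length(x$ids) > 5) cat("  ...\n")
  invisible(x)
}

#' Read an aligned FASTA file
#'
#' @param path Path to an aligned FASTA file (equal row lengths).
#' @return An `aa_msa` object; see [new_msa()].
#' @export
read_alignment <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stopf("empty alignment file: %s", path)
  ids <- vapply(strsplit(names(set), "[ \t]"), `[`, "", 1L)
  new_msa(setNames(as.character(set), ids))
}

#' Write an alignment to aligned FASTA
#'
#' @param msa An `aa_msa` object.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_alignment <- function(msa, path) {
  write_fasta(data.frame(id = msa$ids, seq = unname(msa$rows[msa$ids]),
                         stringsAsFactors = FALSE), path)
}

# drop gaps from one alignment row
ungap <- function(row) gsub("-", "", row, fixed = TRUE)
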