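# End-to-end orchestration: detect -> classify -> diagnose -> gene tree /
# monophyly -> presence parsimony -> synteny, over a simulated bundle or a
# dataset directory, producing a single report.

#' Load a dataset directory into a bundle
#'
#' Expects the layout written by [emit_dataset()]: `proteomes/*.faa`,
#' optionally `gff/*.gff`, `species_tree.nwk`, `refs.faa`,
#' `seed_alignment.faa`, and optional `truth/` TSVs.
#'
#' @param dir Dataset directory.
#' @return A `sim_bundle`-shaped list (truth fields `NULL` when absent).
#' @export
load_dataset <- function(dir) {
  pdir <- file.path(dir, "proteomes")
  if (!dir.exists(pdir)) stopf("no proteomes/ directory under %s", dir)
  faa <- sort(list.files(pdir, pattern = "\\.faa$", full.names = TRUE))
  if (length(faa) == 0L) stopf("no proteome FASTA files under %s", pdir)
  sp_ids <- sub("\\.faa$", "", basename(faa))
  proteomes <- setNames(lapply(seq_along(faa), function(i)
    read_fasta(faa[i], species_id = sp_ids[i])), sp_ids)
  gffs <- file.path(dir, "gff", paste0(sp_ids, ".gff"))
  annotations <- if (all(file.exists(gffs)))
    setNames(lapply(gffs, read_gff), sp_ids) else NULL
  tree_f <- file.path(dir, "species_tree.nwk")
  tree <- if (file.exists(tree_f)) ape::read.tree(tree_f) else NULL
  refs_f <- file.path(dir, "refs.faa")
  refs <- if (file.exists(refs_f)) read_fasta(refs_f) else NULL
  seed_f <- file.path(dir, "seed_alignment.faa")
  seed_msa <- if (file.exists(seed_f)) read_alignment(seed_f) else NULL
  truth_f <- file.path(dir, "truth", "histones.tsv")
  histones <- if (file.exists(truth_f))
    read.delim(truth_f, stringsAsFactors = FALSE) else NULL
  diag_f <- file.path(dir, "truth", "diagnostic_sites.tsv")
  diag <- if (file.exists(diag_f))
    read.delim(diag_f, stringsAsFactors = FALSE) else NULL
  fam_f <- file.path(dir, "truth", "families.tsv")
  families <- if (file.exists(fam_f))
    read.delim(fam_f, stringsAsFactors = FALSE) else NULL
  list(config = NULL, tree = tree, histones = histones,
       proteomes = proteomes, annotations = annotations, refs = refs,
       seed_msa = seed_msa, diag = diag, events = NULL,
       families = families)
}

#' Run the full histone-paralog pipeline
#'
#' Stages: (1) profile detection with shuffle-null calibration over the
#' pooled proteomes; (2) featurization + PCA + reference-anchored group
#' assignment; (3) alignment, diagnostic-column calling; (4) NJ gene tree
#' and reciprocal-monophyly test; (5) Fitch/Dollo presence parsimony per
#' histone type on the species tree (skipped without a species tree);
#' (6) neighborhood-conservation synteny against a reference species
#' (skipped without annotations). When truth tables are present,
#' classification accuracy is reported.
#'
#' @param bundle A `sim_bundle` ([simulate_dataset()]) or dataset
#'   directory path ([load_dataset()]).
#' @param fpr_target Detection false-positive-rate target (default 0.001).
#' @param n_shuffles Shuffles per protein for the detection null.
#' @param eps Classification dead zone ([assign_groups()]).
#' @param tau_d Diagnostic-column threshold ([call_diagnostic_columns()]).
#' @param min_fold_coverage Minimum fraction of a candidate protein
#'   covered by the histone-fold profile for it to enter the A/B
#'   classification (default 0.5). Single-fold (HMf-like) histones are
#'   close to 1; multi-domain proteins or fold doublets with a
#'   histone-like window fall below and are reported as other hits
#'   rather than classified.
#' @param k Neighborhood size for synteny.
#' @param n_synteny_species Number of (non-reference) species included in
#'   the synteny stage (bounds run time; default 5).
#' @param seed Integer seed; stage seeds are derived from it.
#' @param outdir Optional directory for stage TSV outputs.
#' @return A `histoparalog_report` list; see the fields of the printed
#'   summary.
#' @export
run_all <- function(bundle, fpr_target = 0.001, n_shuffles = 20,
                    eps = 0.05, tau_d = 0.9, min_fold_coverage = 0.5,
                    k = 5, n_synteny_species = 5, seed = 17,
                    outdir = NULL) {
  if (is.character(bundle)) bundle <- load_dataset(bundle)
  if (is.null(bundle$proteomes) || length(bundle$proteomes) == 0L)
    stopf("stage detect: no proteomes in dataset")
  if (is.null(bundle$seed_msa))
    stopf("stage detect: no seed alignment in dataset")
  if (is.null(bundle$refs))
    stopf("stage classify: no reference sequences in dataset")
  log_msg <- function(...) message("[run_all] ", ...)
  log_msg(sprintf(
    "defaults: fpr_target=%g n_shuffles=%d eps=%g tau_d=%g k=%d seed=%d",
    fpr_target, n_shuffles, eps, tau_d, k, seed))

  # -- detect ---------------------------------------------------------
  pooled <- do.call(rbind, unname(bundle$proteomes))
  hits <- detect_histones(pooled, bundle$seed_msa,
                          n_shuffles = n_shuffles,
                          fpr_target = fpr_target, seed = seed + 1L)
  detected <- pooled[pooled$id %in% hits$id[hits$is_hit], , drop = FALSE]
  log_msg(sum(hits$is_hit), " histone candidate(s) of ", nrow(pooled),
          " proteins")
  # A/B classification covers single-fold (HMf-like) candidates: the
  # profile must span most of the protein. Longer histone-fold carriers
  # (doublets, multi-domain proteins) are kept as "other" hits.
  L <- attr(hits, "profile")$length
  coverage <- L / nchar(detected$seq)
  other_hits <- detected$id[coverage < min_fold_coverage]
  if (length(other_hits) > 0L)
    log_msg(length(other_hits),
            " hit(s) below fold coverage excluded from classification: ",
            paste(other_hits, collapse = ", "))
  detected <- detected[coverage >= min_fold_coverage, , drop = FALSE]
  if (nrow(detected) < 3L) stopf("stage classify: fewer than 3 candidates")

  # -- classify -------------------------------------------------------
  ref_df <- bundle$refs
  records <- rbind(detected[, c("id", "species_id", "seq")],
                   data.frame(id = ref_df$id, species_id = NA_character_,
                              seq = ref_df$seq, stringsAsFactors = FALSE))
  records <- records[!duplicated(records$id), ]
  groups <- classify_histones(records, ref_a_id = "refA",
                              ref_b_id = "refB", eps = eps)

  # -- align + diagnose ----------------------------------------------
  msa <- align_center_star(setNames(records$seq, records$id))
  profiles <- column_profiles(msa, groups, ref_row_id = "refA")
  diag_cols <- call_diagnostic_columns(profiles, tau_d = tau_d)

  # -- gene tree + monophyly -----------------------------------------
  gt <- neighbor_joining(distance_matrix(msa, correction = "poisson"))
  nonref <- groups[!groups$id %in% c("refA", "refB"), , drop = FALSE]
  mono <- reciprocal_monophyly(ape::drop.tip(gt, c("refA", "refB")),
                               nonref)

  # -- presence parsimony --------------------------------------------
  events <- NULL
  if (!is.null(bundle$tree)) {
    sp_of <- setNames(pooled$species_id, pooled$id)
    tab <- data.frame(species_id = unname(sp_of[nonref$id]),
                      type = nonref$label, stringsAsFactors = FALSE)
    tab <- tab[tab$type %in% c("A_like", "B_like"), ]
    pres <- presence_matrix(bundle$tree$tip.label,
                            c("A_like", "B_like"), tab)
    events <- lapply(setNames(nm = c("A_like", "B_like")), function(ty)
      list(fitch = parsimony_events(bundle$tree, pres, ty, "fitch"),
           dollo = parsimony_events(bundle$tree, pres, ty, "dollo")))
    attr(events, "presence") <- pres
  } else log_msg("no species tree: events stage skipped")

  # -- synteny --------------------------------------------------------
  synteny <- NULL
  if (!is.null(bundle$annotations)) {
    ref_sp <- names(bundle$proteomes)[1]
    others <- setdiff(names(bundle$proteomes), ref_sp)
    sel <- utils::head(others, n_synteny_species)
    lab_of <- setNames(nonref$label, nonref$id)
    ref_ann <- bundle$annotations[[ref_sp]]
    ref_hist <- intersect(ref_ann$gene_id, names(lab_of))
    rows <- NULL
    for (sp in sel) {
      pairs <- reciprocal_best_hits(bundle$proteomes[[sp]],
                                    bundle$proteomes[[ref_sp]])
      q_hist <- intersect(bundle$annotations[[sp]]$gene_id, names(lab_of))
      for (h in q_hist) {
        nq <- neighborhood(bundle$annotations[[sp]], h, k = k)
        for (rh in ref_hist) {
          nr <- neighborhood(ref_ann, rh, k = k)
          cons <- conservation(nq, nr, pairs, k = k)
          rows <- rbind(rows, data.frame(
            species_id = sp, histone = h, histone_label = lab_of[[h]],
            ref_histone = rh, ref_label = lab_of[[rh]],
            conservation = cons$combined, stringsAsFactors = FALSE))
        }
      }
    }
    synteny <- rows
  } else log_msg("no annotations: synteny stage skipped")

  # -- truth comparison ----------------------------------------------
  accuracy <- NULL; recall <- NULL
  if (!is.null(bundle$histones)) {
    truth <- setNames(paste0(bundle$histones$group, "_like"),
                      bundle$histones$id)
    lab <- nonref[nonref$label %in% c("A_like", "B_like"), ]
    common <- intersect(lab$id, names(truth))
    if (length(common) > 0L)
      accuracy <- mean(setNames(lab$label, lab$id)[common] ==
                       truth[common])
    recall <- mean(bundle$histones$id %in% hits$id[hits$is_hit])
  }

  report <- structure(list(
    hits = hits, groups = groups, msa = msa, profiles = profiles,
    diagnostic_columns = diag_cols, gene_tree = gt, monophyly = mono,
    events = events, synteny = synteny,
    summary = list(
      n_proteins = nrow(pooled), n_histones = nrow(detected),
      n_other_hits = length(other_hits),
      n_a_like = sum(nonref$label == "A_like"),
      n_b_like = sum(nonref$label == "B_like"),
      n_unassigned = sum(nonref$label == "unassigned"),
      n_diagnostic_columns = nrow(diag_cols),
      reciprocal_monophyly = mono$monophyletic,
      event_counts = if (!is.null(events)) vapply(events, function(e)
        e$fitch$count, 1L) else NULL,
      classification_accuracy = accuracy, detection_recall = recall)),
    class = "histoparalog_report")
  if (!is.null(outdir)) write_report(report, outdir)
  report
}

#' @export
print.histoparalog_report <- function(x, ...) {
  s <- x$summary
  cat("Histone-paralog pipeline report\n")
  cat(sprintf("  proteins scanned:       %d\n", s$n_proteins))
  cat(sprintf("  histone candidates:     %d\n", s$n_histones))
  cat(sprintf("  A-like / B-like / unassigned: %d / %d / %d\n",
              s$n_a_like, s$n_b_like, s$n_unassigned))
  cat(sprintf("  diagnostic columns:     %d\n", s$n_diagnostic_columns))
  cat(sprintf("  reciprocal monophyly:   %s\n", s$reciprocal_monophyly))
  if (!is.null(s$event_counts))
    cat(sprintf("  fitch event counts:     %s\n",
                paste(names(s$event_counts), s$event_counts,
                      sep = "=", collapse = ", ")))
  if (!is.null(s$classification_accuracy))
    cat(sprintf("  classification accuracy: %.3f\n",
                s$classification_accuracy))
  if (!is.null(s$detection_recall))
    cat(sprintf("  detection recall:        %.3f\n", s$detection_recall))
  invisible(x)
}

# write stage TSVs of a report
write_report <- function(report, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(df, name) if (!is.null(df)) write.table(
    df, file.path(outdir, name), sep = "\t", quote = FALSE,
    row.names = FALSE)
  tsv(report$hits, "hits.tsv")
  tsv(report$groups, "groups.tsv")
  tsv(report$profiles, "columns.tsv")
  tsv(report$diagnostic_columns, "diagnostic_columns.tsv")
  ape::write.tree(report$gene_tree, file.path(outdir, "gene_tree.nwk"))
  tsv(report$synteny, "synteny.tsv")
  invisible(outdir)
}
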