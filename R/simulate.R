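# Seeded generator of synthetic datasets with the evolutionary structure
# the pipeline assumes: a species tree, one ancestral histone duplicated at
# the root into two groups with fixed group-diagnostic residues, Poisson
# background substitution along branches, sparse lineage-specific
# duplication/loss, conserved group-specific gene neighborhoods, and
# composition-matched decoy proteins — plus ground-truth tables.

# histone-like background residue composition (lysine/glutamate-rich, as in
# hyperthermophile histones); normalized on use
HISTONE_BG <- c(A = 0.090, C = 0.002, D = 0.035, E = 0.115, F = 0.020,
                G = 0.060, H = 0.012, I = 0.080, K = 0.115, L = 0.075,
                M = 0.020, N = 0.025, P = 0.015, Q = 0.025, R = 0.060,
                S = 0.040, T = 0.040, V = 0.065, W = 0.004, Y = 0.025)

# residue pools for the two groups' diagnostic sites: acidic/aromatic/
# aliphatic for group A vs basic/polar for group B, mirroring the
# physicochemical contrast between the two natural paralog groups
DIAG_POOL_A <- c("D", "E", "Y", "F", "L", "I", "V", "A")
DIAG_POOL_B <- c("K", "R", "H", "Q", "N", "S", "T", "G")

#' Simulation configuration
#'
#' Defaults define the reference study conditions: 30 species, 67-residue
#' ancestral histone, 8 diagnostic sites, tree depth 0.09 expected
#' substitutions/site from root to tip (within-group identity around 85%),
#' sparse lineage-specific loss and duplication, 10 decoys per species,
#' 5-gene neighborhoods.
#'
#' @param n_species Number of species (>= 4).
#' @param birth_rate Yule birth rate (shape only; depth is rescaled).
#' @param tree_depth Expected root-to-tip divergence, substitutions/site.
#' @param ancestor_length Ancestral histone length, residues.
#' @param n_diagnostic_sites Number of group-diagnostic sites.
#' @param substitution_rate Replacements/site per unit branch length.
#' @param loss_rate,extra_duplication_rate,hgt_rate Event probabilities per
#'   branch (per gene copy; HGT acts on terminal branches).
#' @param n_decoys Decoy proteins per species.
#' @param neighborhood_size Conserved neighbor genes per side of each
#'   histone locus.
#' @param duplication_mode `"root"` (ancient paralogy; the default) or
#'   `"terminal"` (independent recent duplications per species — the
#'   negative control for reciprocal monophyly).
#' @param swap_neighborhood_species Optional species ids whose A- and
#'   B-locus neighborhoods are exchanged (plants a detectable synteny
#'   swap).
#' @param leaky_diagnostic_rate Probability per branch that a diagnostic
#'   site escapes constraint (0 = absolutely conserved within groups).
#' @param seed Integer seed; identical configs give identical datasets.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_species = 30, birth_rate = 1, tree_depth = 0.09,
                       ancestor_length = 67, n_diagnostic_sites = 8,
                       substitution_rate = 1, loss_rate = 0.02,
                       extra_duplication_rate = 0.02, hgt_rate = 0,
                       n_decoys = 10, neighborhood_size = 5,
                       duplication_mode = c("root", "terminal"),
                       swap_neighborhood_species = NULL,
                       leaky_diagnostic_rate = 0, seed = 17) {
  duplication_mode <- match.arg(duplication_mode)
  cfg <- list(n_species = n_species, birth_rate = birth_rate,
              tree_depth = tree_depth, ancestor_length = ancestor_length,
              n_diagnostic_sites = n_diagnostic_sites,
              substitution_rate = substitution_rate, loss_rate = loss_rate,
              extra_duplication_rate = extra_duplication_rate,
              hgt_rate = hgt_rate, n_decoys = n_decoys,
              neighborhood_size = neighborhood_size,
              duplication_mode = duplication_mode,
              swap_neighborhood_species = swap_neighborhood_species,
              leaky_diagnostic_rate = leaky_diagnostic_rate, seed = seed)
  stopifnot(n_species >= 4, ancestor_length > 0,
            n_diagnostic_sites < ancestor_length,
            all(unlist(cfg[c("tree_depth", "substitution_rate", "loss_rate",
                             "extra_duplication_rate", "hgt_rate")]) >= 0))
  structure(cfg, class = "sim_config")
}

#' Simulate a rooted species tree
#'
#' Pure-birth (Yule) tree with `n_species` leaves named `sp001`, `sp002`,
#' ..., branch lengths rescaled so the root-to-tip divergence equals
#' `depth` (the tree is ultrametric).
#'
#' @param n_species Number of leaves (>= 4).
#' @param seed Integer seed.
#' @param birth_rate Yule birth rate.
#' @param depth Root-to-tip expected substitutions/site.
#' @return A rooted `ape::phylo` tree.
#' @export
simulate_species_tree <- function(n_species, seed, birth_rate = 1,
                                  depth = 0.09) {
  if (n_species < 4L) stopf("need >= 4 species")
  tree <- with_seed(seed, ape::rphylo(n_species, birth = birth_rate,
                                      death = 0))
  h <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length * depth / h
  tree$tip.label <- sprintf("sp%03d", seq_len(n_species))
  tree
}

# draw a random sequence from the histone-like background
draw_background_seq <- function(len, bg = HISTONE_BG) {
  paste(sample(AA_ALPHABET, len, replace = TRUE, prob = bg[AA_ALPHABET]),
        collapse = "")
}

# Poisson substitutions at the allowed sites, uniform among the 19 other
# residues
mutate_seq <- function(seq, rate, branch_len, allowed_sites) {
  n_mut <- rpois(1, rate * branch_len * length(allowed_sites))
  if (n_mut == 0L) return(seq)
  ch <- seq_chars(seq)
  sites <- sample(allowed_sites, n_mut, replace = TRUE)
  for (s in sites) ch[s] <- sample(setdiff(AA_ALPHABET, ch[s]), 1)
  paste(ch, collapse = "")
}

#' Evolve histone families along a species tree
#'
#' The ancestral histone is drawn from the background composition and (in
#' `"root"` mode) duplicated at the root into groups A and B; each
#' diagnostic site carries a distinct fixed residue per group (drawn once
#' from contrasting physicochemical pools, never substituted unless
#' `leaky_diagnostic_rate > 0`). Background sites substitute as a Poisson
#' process along branches; loss and extra duplication are Bernoulli per
#' copy per branch; HGT (terminal branches) replaces a species' copy with
#' a random donor's. In `"terminal"` mode a single ancestral gene evolves
#' and duplicates independently into an A- and a B-like copy on each
#' terminal branch.
#'
#' @param tree Rooted species tree ([simulate_species_tree()]).
#' @param config A [sim_config()].
#' @return List with `histones` (protein-record `data.frame` with truth
#'   columns `group`, `copy`), `roots` (named root sequences), `diag`
#'   (`data.frame` site / res_A / res_B), `events` (`data.frame` node /
#'   species below / type / histone_type).
#' @export
evolve_families <- function(tree, config) {
  cfg <- config
  L <- cfg$ancestor_length
  with_seed(cfg$seed + 1L, {
    diag_sites <- sort(sample.int(L, cfg$n_diagnostic_sites))
    res_a <- sample(DIAG_POOL_A, cfg$n_diagnostic_sites, replace = TRUE)
    res_b <- sample(DIAG_POOL_B, cfg$n_diagnostic_sites, replace = TRUE)
    bg_sites <- setdiff(seq_len(L), diag_sites)
    ancestor <- draw_background_seq(L)
    set_diag <- function(seq, res) {
      ch <- seq_chars(seq); ch[diag_sites] <- res
      paste(ch, collapse = "")
    }
    root_a <- set_diag(ancestor, res_a)
    root_b <- set_diag(ancestor, res_b)
    n_tip <- length(tree$tip.label)
    root <- n_tip + 1L
    children_of <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
    events <- data.frame(node = integer(0), type = character(0),
                         histone_type = character(0),
                         stringsAsFactors = FALSE)
    leaves <- list()
    mutate_copy <- function(copy, blen, terminal) {
      allowed <- if (cfg$leaky_diagnostic_rate > 0 &&
                     runif(1) < cfg$leaky_diagnostic_rate)
        seq_len(L) else bg_sites
      copy$seq <- mutate_seq(copy$seq, cfg$substitution_rate, blen, allowed)
      copy
    }
    recurse <- function(node, copies) {
      kid_edges <- children_of[[as.character(node)]]
      if (is.null(kid_edges)) {        # leaf
        leaves[[tree$tip.label[node]]] <<- copies
        return(invisible())
      }
      for (e in kid_edges) {
        child <- tree$edge[e, 2]
        blen <- tree$edge.length[e]
        terminal <- child <= n_tip
        cc <- lapply(copies, mutate_copy, blen = blen, terminal = terminal)
        # loss then duplication, Bernoulli per copy
        keep <- vapply(cc, function(x) runif(1) >= cfg$loss_rate, TRUE)
        for (i in which(!keep))
          events <<- rbind(events, data.frame(
            node = child, type = "loss", histone_type = cc[[i]]$group,
            stringsAsFactors = FALSE))
        cc <- cc[keep]
        extra <- list()
        for (cp in cc) if (runif(1) < cfg$extra_duplication_rate) {
          events <<- rbind(events, data.frame(
            node = child, type = "duplication", histone_type = cp$group,
            stringsAsFactors = FALSE))
          extra <- c(extra, list(cp))
        }
        cc <- c(cc, extra)
        if (terminal && cfg$duplication_mode == "terminal" &&
            length(cc) >= 1L) {
          # independent recent duplication: each species draws its own
          # site residues from the two contrasting pools, so the copies
          # acquire group-like chemistry without shared descent
          sp_res_a <- sample(DIAG_POOL_A, cfg$n_diagnostic_sites,
                             replace = TRUE)
          sp_res_b <- sample(DIAG_POOL_B, cfg$n_diagnostic_sites,
                             replace = TRUE)
          base <- cc[[1]]
          a <- base; a$group <- "A"; a$seq <- set_diag(a$seq, sp_res_a)
          b <- base; b$group <- "B"; b$seq <- set_diag(b$seq, sp_res_b)
          events <<- rbind(events, data.frame(
            node = child, type = "duplication", histone_type = "recent",
            stringsAsFactors = FALSE))
          cc <- list(a, b)
        }
        recurse(child, cc)
      }
    }
    start <- if (cfg$duplication_mode == "root")
      list(list(group = "A", seq = root_a), list(group = "B", seq = root_b))
    else list(list(group = "ancestral", seq = ancestor))
    recurse(root, start)
    # terminal-branch HGT: replace a species' copy with a donor's
    if (cfg$hgt_rate > 0) {
      sp_names <- names(leaves)
      for (sp in sp_names) if (runif(1) < cfg$hgt_rate &&
                               length(leaves[[sp]]) > 0L) {
        i <- sample.int(length(leaves[[sp]]), 1)
        donor <- sample(setdiff(sp_names, sp), 1)
        grp <- leaves[[sp]][[i]]$group
        match_d <- Filter(function(x) x$group == grp, leaves[[donor]])
        if (length(match_d) > 0L) {
          leaves[[sp]][[i]] <- match_d[[1]]
          events <- rbind(events, data.frame(
            node = match(sp, tree$tip.label), type = "hgt",
            histone_type = grp, stringsAsFactors = FALSE))
        }
      }
    }
    rows <- NULL
    for (sp in tree$tip.label) {
      cps <- leaves[[sp]]
      if (length(cps) == 0L) next
      for (i in seq_along(cps))
        rows <- rbind(rows, data.frame(
          id = sprintf("%s_h%d", sp, i), species_id = sp,
          seq = cps[[i]]$seq, group = cps[[i]]$group, copy = i,
          stringsAsFactors = FALSE))
    }
    list(histones = rows,
         roots = c(refA = root_a, refB = root_b, ancestor = ancestor),
         diag = data.frame(site = diag_sites, res_A = res_a, res_B = res_b,
                           stringsAsFactors = FALSE),
         events = events)
  })
}

#' Simulate a complete dataset
#'
#' Species tree, histone families, conserved group-specific gene
#' neighborhoods (each neighbor family evolves along the species tree like
#' an unconstrained protein), composition-matched decoys, references and a
#' seed alignment, all in memory.
#'
#' @param config A [sim_config()].
#' @return A `sim_bundle` list: `config`, `tree`, `histones` (with truth
#'   columns), `proteomes` (named list of protein-record `data.frame`s),
#'   `annotations` (named list of annotation `data.frame`s), `refs`
#'   (2-record `data.frame`, ids `refA`/`refB`), `seed_msa` (`aa_msa`),
#'   `diag`, `events`, `families` (true ortholog family of every
#'   non-decoy gene).
#' @export
simulate_dataset <- function(config = sim_config()) {
  cfg <- config
  tree <- simulate_species_tree(cfg$n_species, cfg$seed,
                                birth_rate = cfg$birth_rate,
                                depth = cfg$tree_depth)
  fam <- evolve_families(tree, cfg)
  k <- cfg$neighborhood_size
  with_seed(cfg$seed + 2L, {
    # neighbor gene families: k per side per histone locus, group-specific
    fam_names <- c(outer(c("famA_u", "famA_d", "famB_u", "famB_d"),
                         seq_len(k), paste0))
    fam_len <- sample(150:350, length(fam_names), replace = TRUE)
    fam_root <- setNames(vapply(fam_len, draw_background_seq, ""),
                         fam_names)
    # evolve each family along the tree (no site constraints)
    n_tip <- length(tree$tip.label)
    children_of <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
    fam_leaf <- list()
    recurse <- function(node, seqs) {
      kid_edges <- children_of[[as.character(node)]]
      if (is.null(kid_edges)) {
        fam_leaf[[tree$tip.label[node]]] <<- seqs
        return(invisible())
      }
      for (e in kid_edges) {
        child <- tree$edge[e, 2]
        blen <- tree$edge.length[e]
        ss <- vapply(seqs, function(s)
          mutate_seq(s, cfg$substitution_rate, blen,
                     seq_len(nchar(s))), "")
        recurse(child, ss)
      }
    }
    recurse(n_tip + 1L, fam_root)
    proteomes <- list(); annotations <- list(); families <- NULL
    for (sp in tree$tip.label) {
      hist_sp <- fam$histones[fam$histones$species_id == sp, , drop = FALSE]
      swap <- sp %in% (cfg$swap_neighborhood_species %||% character(0))
      # gene order along one contig: A locus block, B locus block, decoys
      ids <- character(0); seqs <- character(0); famlab <- character(0)
      add <- function(id, seq, f) {
        ids <<- c(ids, id); seqs <<- c(seqs, seq); famlab <<- c(famlab, f)
      }
      locus_block <- function(grp) {
        # histone of grp flanked by its family genes (or the other
        # group's families when swapped)
        nb_grp <- if (!swap) grp else setdiff(c("A", "B"), grp)
        for (j in seq_len(k))
          add(sprintf("%s_fam%s_u%d", sp, nb_grp, j),
              fam_leaf[[sp]][[sprintf("fam%s_u%d", nb_grp, j)]],
              sprintf("fam%s_u%d", nb_grp, j))
        h <- hist_sp[hist_sp$group == grp, , drop = FALSE]
        if (nrow(h) >= 1L) add(h$id[1], h$seq[1], paste0("histone_", grp))
        for (j in seq_len(k))
          add(sprintf("%s_fam%s_d%d", sp, nb_grp, j),
              fam_leaf[[sp]][[sprintf("fam%s_d%d", nb_grp, j)]],
              sprintf("fam%s_d%d", nb_grp, j))
        if (nrow(h) > 1L) for (i in 2:nrow(h))   # extra copies unplaced
          add(h$id[i], h$seq[i], paste0("histone_", grp))
      }
      if (cfg$duplication_mode == "root") {
        locus_block("A"); locus_block("B")
      } else {
        for (grp in unique(hist_sp$group)) {
          h <- hist_sp[hist_sp$group == grp, , drop = FALSE]
          for (i in seq_len(nrow(h))) add(h$id[i], h$seq[i],
                                          paste0("histone_", grp))
        }
      }
      for (d in seq_len(cfg$n_decoys))
        add(sprintf("%s_decoy%03d", sp, d),
            draw_background_seq(sample(80:500, 1)), NA_character_)
      if (length(ids) > 0L) {
        start <- cumsum(c(1, utils::head(nchar(seqs) * 3 + 100, -1)))
        ann <- data.frame(gene_id = ids, contig = paste0(sp, "_c1"),
                          start = as.integer(start),
                          end = as.integer(start + nchar(seqs) * 3 - 1),
                          strand = "+", product = NA_character_,
                          stringsAsFactors = FALSE)
      } else {
        # species with no genes at all (total loss, no decoys)
        ann <- data.frame(gene_id = character(0), contig = character(0),
                          start = integer(0), end = integer(0),
                          strand = character(0), product = character(0),
                          stringsAsFactors = FALSE)
      }
      proteomes[[sp]] <- protein_set(ids, seqs, species_id = sp)
      annotations[[sp]] <- ann
      if (length(ids) > 0L)
        families <- rbind(families, data.frame(
          gene_id = ids, species_id = sp, family = famlab,
          stringsAsFactors = FALSE))
    }
    refs <- protein_set(c("refA", "refB"),
                        c(fam$roots[["refA"]], fam$roots[["refB"]]))
    seed_msa <- new_msa(c(refA = fam$roots[["refA"]],
                          refB = fam$roots[["refB"]]))
    structure(list(config = cfg, tree = tree, histones = fam$histones,
                   proteomes = proteomes, annotations = annotations,
                   refs = refs, seed_msa = seed_msa, diag = fam$diag,
                   events = fam$events, families = families),
              class = "sim_bundle")
  })
}

#' Write a simulated dataset to disk
#'
#' Per-species proteome FASTA and GFF3, the species tree (newick),
#' reference and seed-alignment FASTA, and truth TSVs, reloadable through
#' the package's readers.
#'
#' @param bundle A `sim_bundle` from [simulate_dataset()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, `outdir`.
#' @export
emit_dataset <- function(bundle, outdir) {
  dir.create(file.path(outdir, "proteomes"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(outdir, "gff"), showWarnings = FALSE)
  dir.create(file.path(outdir, "truth"), showWarnings = FALSE)
  for (sp in names(bundle$proteomes)) {
    write_fasta(bundle$proteomes[[sp]],
                file.path(outdir, "proteomes", paste0(sp, ".faa")))
    write_gff(bundle$annotations[[sp]],
              file.path(outdir, "gff", paste0(sp, ".gff")))
  }
  ape::write.tree(bundle$tree, file.path(outdir, "species_tree.nwk"))
  write_fasta(bundle$refs, file.path(outdir, "refs.faa"))
  write_alignment(bundle$seed_msa, file.path(outdir, "seed_alignment.faa"))
  tsv <- function(df, name) write.table(
    df, file.path(outdir, "truth", name), sep = "\t", quote = FALSE,
    row.names = FALSE)
  tsv(bundle$histones, "histones.tsv")
  tsv(bundle$diag, "diagnostic_sites.tsv")
  tsv(bundle$events, "events.tsv")
  tsv(bundle$families, "families.tsv")
  invisible(outdir)
}
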