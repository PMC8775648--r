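# Reciprocal-monophyly testing on gene trees and parsimony mapping of
# histone-type gains/losses on a rooted species tree.

# leaf set below each node of an ape tree (indices into tip.labels)
descendant_sets <- function(tree) {
  n_tip <- length(tree$tip.label)
  n_node <- max(tree$edge)
  sets <- vector("list", n_node)
  for (i in seq_len(n_tip)) sets[[i]] <- i
  # ape postorder lists an edge after every edge of its child's subtree,
  # so the child set is complete when its edge is processed
  for (k in ape::postorder(tree)) {
    p <- tree$edge[k, 1]; ch <- tree$edge[k, 2]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  sets
}

#' Is a taxon set separable by one edge of an (unrooted) tree?
#'
#' TRUE iff some edge's bipartition equals (`taxon_set`, complement) —
#' i.e. the set is monophyletic on the unrooted tree. Branch lengths play
#' no role.
#'
#' @param tree An `ape::phylo` tree.
#' @param taxon_set Character vector; proper nonempty subset of the
#'   tree's tips.
#' @return Logical flag.
#' @export
is_separable <- function(tree, taxon_set) {
  tips <- tree$tip.label
  unknown <- setdiff(taxon_set, tips)
  if (length(unknown) > 0L) stopf("unknown taxon: %s", unknown[1])
  s <- unique(taxon_set)
  if (length(s) == 0L || length(s) >= length(tips))
    stopf("taxon_set must be a proper nonempty subset of the leaves")
  if (length(s) == 1L || length(s) == length(tips) - 1L) return(TRUE)
  target <- sort(match(s, tips))
  sets <- descendant_sets(tree)
  n_tip <- length(tips)
  for (st in sets[(n_tip + 1L):length(sets)]) {
    side <- sort(st)
    if (identical(side, target) ||
        identical(sort(setdiff(seq_len(n_tip), side)), target))
      return(TRUE)
  }
  FALSE
}

#' Test reciprocal monophyly of two paralog groups on a gene tree
#'
#' TRUE iff the A-labeled leaves (equivalently the B-labeled leaves) are
#' separable by a single edge. Unassigned leaves are excluded with a
#' message. On failure, a small set of offending leaves whose removal
#' restores separability is reported: for each tree bipartition, the
#' symmetric difference with the A-set is computed, and the smallest such
#' difference over all edges is returned (a greedy, single-edge repair).
#'
#' @param tree An `ape::phylo` gene tree whose tips are histone ids.
#' @param assignments `data.frame` with columns `id`, `label`.
#' @return List with `monophyletic` (flag) and `offenders` (character,
#'   empty when monophyletic).
#' @export
reciprocal_monophyly <- function(tree, assignments) {
  lab <- setNames(assignments$label, assignments$id)
  tips <- tree$tip.label
  keep <- tips[tips %in% names(lab) & lab[tips] %in% c("A_like", "B_like")]
  drop <- setdiff(tips, keep)
  if (length(drop) > 0L) {
    message(length(drop), " unlabeled leaf/leaves excluded from monophyly test")
    tree <- ape::drop.tip(tree, drop)
    tips <- tree$tip.label
  }
  a_set <- tips[lab[tips] == "A_like"]
  b_set <- tips[lab[tips] == "B_like"]
  if (length(a_set) < 2L || length(b_set) < 2L)
    stopf("each group needs >= 2 leaves (A: %d, B: %d)",
          length(a_set), length(b_set))
  if (is_separable(tree, a_set))
    return(list(monophyletic = TRUE, offenders = character(0)))
  # greedy repair: best single-edge bipartition
  n_tip <- length(tips)
  target <- sort(match(a_set, tips))
  sets <- descendant_sets(tree)
  best <- seq_len(n_tip)
  splits <- c(sets[(n_tip + 1L):length(sets)], as.list(seq_len(n_tip)))
  for (st in splits) {
    for (side in list(sort(st), sort(setdiff(seq_len(n_tip), st)))) {
      sd <- c(setdiff(side, target), setdiff(target, side))
      if (length(sd) < length(best) && length(sd) > 0L) best <- sd
    }
  }
  list(monophyletic = FALSE, offenders = tips[sort(best)])
}

#' Presence/absence matrix of histone types per species
#'
#' @param species Character vector of species ids (rows).
#' @param types Character vector of histone types (columns).
#' @param table `data.frame` with columns `species_id`, `type` listing
#'   which species carry which type.
#' @return Binary matrix species x type.
#' @export
presence_matrix <- function(species, types, table) {
  M <- matrix(0L, length(species), length(types),
              dimnames = list(species, types))
  for (k in seq_len(nrow(table))) {
    sp <- table$species_id[k]; ty <- table$type[k]
    if (sp %in% species && ty %in% types) M[sp, ty] <- 1L
  }
  M
}

#' Minimal gain/loss events for a histone type on a species tree
#'
#' `mode = "fitch"`: minimal number of binary state changes (Fitch small
#' parsimony, computed by dynamic programming over both root states; the
#' root state minimizing the count is chosen, ties preferring presence).
#' Events are placed on edges by a deterministic top-down resolution that
#' keeps the parent state on ties. `mode = "dollo"`: a single gain is fixed
#' at the most recent common ancestor of all present leaves and the
#' minimal set of loss edges explaining the absences below it is counted
#' (the event count excludes the fixed gain).
#'
#' @param species_tree Rooted binary `ape::phylo` tree over species.
#' @param presence Binary matrix from [presence_matrix()].
#' @param histone_type Column of `presence` to map.
#' @param mode `"fitch"` or `"dollo"`.
#' @return List with `count`, `events` (`data.frame`: `node`, the ape node
#'   id of the child end of the event edge; `type` `"gain"`/`"loss"`), and
#'   for dollo `gain_node` (`NA` when the type is absent everywhere).
#' @export
parsimony_events <- function(species_tree, presence, histone_type,
                             mode = c("fitch", "dollo")) {
  mode <- match.arg(mode)
  tips <- species_tree$tip.label
  if (!all(rownames(presence) %in% tips))
    stopf("species missing from tree: %s",
          setdiff(rownames(presence), tips)[1])
  if (!all(tips %in% rownames(presence)))
    stopf("species missing from presence matrix: %s",
          setdiff(tips, rownames(presence))[1])
  if (!histone_type %in% colnames(presence))
    stopf("unknown histone type '%s'", histone_type)
  state <- presence[tips, histone_type]
  n_tip <- length(tips)
  n_node <- max(species_tree$edge)
  root <- n_tip + 1L
  ord <- ape::postorder(species_tree)
  children <- split(species_tree$edge[, 2], species_tree$edge[, 1])
  if (mode == "fitch") {
    # binary Sankoff: cost[node, s+1] = min changes in subtree given state s.
    # Internal costs accumulate per child edge; ape postorder guarantees a
    # child's subtree is complete before its edge is processed.
    cost <- matrix(0, n_node, 2)
    for (i in seq_len(n_tip)) cost[i, 2L - state[i]] <- Inf
    for (k in ord) {
      p <- species_tree$edge[k, 1]; ch <- species_tree$edge[k, 2]
      for (s in 0:1)
        cost[p, s + 1L] <- cost[p, s + 1L] +
          min(cost[ch, s + 1L], cost[ch, 2L - s] + 1)
    }
    count <- min(cost[root, ])
    root_state <- if (cost[root, 2] <= cost[root, 1]) 1L else 0L
    # top-down resolution (breadth-first from the root), parent state kept
    # on ties
    final <- integer(n_node)
    final[root] <- root_state
    events <- data.frame(node = integer(0), type = character(0),
                         stringsAsFactors = FALSE)
    queue <- root
    while (length(queue) > 0L) {
      p <- queue[1]; queue <- queue[-1]
      s <- final[p]
      for (ch in children[[as.character(p)]] %||% integer(0)) {
        keep <- cost[ch, s + 1L]
        flip <- cost[ch, 2L - s] + 1
        final[ch] <- if (keep <= flip) s else 1L - s
        if (final[ch] != s)
          events <- rbind(events, data.frame(
            node = ch, type = if (final[ch] == 1L) "gain" else "loss",
            stringsAsFactors = FALSE))
        if (ch > n_tip) queue <- c(queue, ch)
      }
    }
    list(count = as.integer(count), events = events)
  } else {
    present <- which(state == 1L)
    if (length(present) == 0L)
      return(list(count = 0L,
                  events = data.frame(node = integer(0), type = character(0),
                                      stringsAsFactors = FALSE),
                  gain_node = NA_integer_))
    gain_node <- if (length(present) == 1L) present
                 else ape::getMRCA(species_tree, tips[present])
    # below the gain node, maximal all-absent subtrees each cost one loss
    sets <- descendant_sets(species_tree)
    absent_below <- vapply(seq_len(n_node), function(nd)
      all(state[sets[[nd]]] == 0L), TRUE)
    events <- data.frame(node = integer(0), type = character(0),
                         stringsAsFactors = FALSE)
    # walk from the gain node down; a loss where a child subtree is
    # all-absent but its parent's is not
    stack <- gain_node
    while (length(stack) > 0L) {
      nd <- stack[1]; stack <- stack[-1]
      cc <- children[[as.character(nd)]]
      for (ch in cc %||% integer(0)) {
        if (absent_below[ch])
          events <- rbind(events, data.frame(node = ch, type = "loss",
                                             stringsAsFactors = FALSE))
        else stack <- c(stack, ch)
      }
    }
    list(count = nrow(events), events = events, gain_node = gain_node)
  }
}
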