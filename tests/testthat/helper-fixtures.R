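# shared fixtures and independent oracles, built once per test run

# small default-structure bundle (root duplication)
small_bundle <- simulate_dataset(
  sim_config(n_species = 8, n_decoys = 3, seed = 5))

# the reference study conditions (30 species, 8 diagnostic sites, seed 17)
default_bundle <- simulate_dataset(sim_config())

random_aa <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(histoparalog:::AA_ALPHABET, len, replace = TRUE),
          collapse = ""), "")
}

# independent isoelectric-point oracle: vectorized net charge on a pH
# grid, pI located at the sign change (0.001 steps)
grid_pi <- function(seq, step = 0.001) {
  ch <- strsplit(seq, "")[[1]]
  cnt <- c(table(factor(ch, levels = histoparalog:::AA_ALPHABET)))
  pk <- c(Nterm = 8.6, Cterm = 3.6, C = 8.5, D = 3.9, E = 4.1, Y = 10.1,
          H = 6.5, K = 10.8, R = 12.5)
  ph <- seq(0, 14, step)
  q <- 1 / (1 + 10^(ph - pk["Nterm"])) - 1 / (1 + 10^(pk["Cterm"] - ph))
  for (a in c("H", "K", "R")) q <- q + cnt[[a]] / (1 + 10^(ph - pk[[a]]))
  for (a in c("C", "D", "E", "Y")) q <- q - cnt[[a]] / (1 + 10^(pk[[a]] - ph))
  i <- which(diff(sign(q)) != 0)[1]
  (ph[i] + ph[i + 1]) / 2
}

# brute-force small-parsimony oracle: enumerate every internal-state
# assignment of a binary character
brute_fitch <- function(tree, states) {
  n_tip <- length(tree$tip.label)
  internals <- (n_tip + 1L):max(tree$edge)
  best <- Inf
  for (mask in 0:(2^length(internals) - 1)) {
    asg <- integer(max(tree$edge))
    asg[seq_len(n_tip)] <- states[tree$tip.label]
    asg[internals] <- as.integer(intToBits(mask))[seq_along(internals)]
    best <- min(best, sum(asg[tree$edge[, 1]] != asg[tree$edge[, 2]]))
  }
  best
}

# random rooted binary tree with positive edge lengths (additive metric)
random_additive_tree <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n)
  tr$edge.length <- runif(nrow(tr$edge), 0.05, 1.0)
  tr
}
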