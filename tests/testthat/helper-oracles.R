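# Independent brute-force oracles used across the suite. These never call
# the implementation paths they check.

# Patristic distances by explicit root-to-tip path enumeration.
bf_patristic <- function(tree) {
  n_tip <- length(tree$tip.label)
  parent <- integer(max(tree$edge))
  elen <- numeric(max(tree$edge))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  elen[tree$edge[, 2]] <- tree$edge.length
  # list of (node, cumulative distance from tip) walking to the root
  path_up <- function(tip) {
    nodes <- tip; dists <- 0; node <- tip; d <- 0
    while (parent[node] != 0) {
      d <- d + elen[node]
      node <- parent[node]
      nodes <- c(nodes, node); dists <- c(dists, d)
    }
    stats::setNames(dists, nodes)
  }
  paths <- lapply(seq_len(n_tip), path_up)
  out <- matrix(0, n_tip, n_tip,
                dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n_tip - 1)) {
    for (j in seq.int(i + 1, n_tip)) {
      shared <- intersect(names(paths[[i]]), names(paths[[j]]))
      mrca <- shared[which.min(paths[[i]][shared])]
      out[i, j] <- out[j, i] <- paths[[i]][mrca] + paths[[j]][mrca]
    }
  }
  out
}

bf_mpd <- function(dist, species) {
  pairs <- utils::combn(species, 2)
  mean(apply(pairs, 2, function(p) dist[p[1], p[2]]))
}

# Hypergeometric tail by exhaustive subset enumeration (small N only).
bf_hyper_tail <- function(N, K, n, k, tail = "right") {
  subsets <- utils::combn(N, n)
  in_cat <- colSums(subsets <= K)  # items 1..K form the category
  if (tail == "right") mean(in_cat >= k) else mean(in_cat <= k)
}

# Exact Fisher p-values by enumeration of all tables with the observed
# margins, probabilities from binomial coefficients.
bf_fisher <- function(a, b, c, d, alternative = "two.sided") {
  r1 <- a + b; c1 <- a + c; N <- a + b + c + d
  support <- max(0, c1 - (N - r1)):min(r1, c1)
  pr <- vapply(support, function(x)
    exp(lchoose(r1, x) + lchoose(N - r1, c1 - x) - lchoose(N, c1)),
    numeric(1))
  p_obs <- pr[support == a]
  switch(alternative,
         two.sided = sum(pr[pr <= p_obs * (1 + 1e-7)]),
         greater = sum(pr[support >= a]),
         less = sum(pr[support <= a]))
}

# Random ultrametric tree with genus-first tip names resolvable by the
# taxon machinery.
rand_coal_tree <- function(n, seed) {
  tree <- halosucc:::with_local_seed(seed, ape::rcoal(n))
  tree$tip.label <- sprintf("T%02d sp", seq_len(n))
  tree
}

# Minimal taxon table for a set of species names.
toy_taxa <- function(species, genus = NULL, family = "F1", order = "O1",
                     ...) {
  if (is.null(genus))
    genus <- vapply(strsplit(species, " ", fixed = TRUE), `[`, "", 1)
  taxon_table(data.frame(species = species, genus = genus, family = family,
                         order = order, present_early = TRUE,
                         present_late = FALSE, season = "both", ...),
              require_presence = FALSE)
}

# Build a small plot table realising given per-species presence counts.
make_plots <- function(counts, n, site = "early", microtopo = "microhigh",
                       taxa = NULL, prefix = site) {
  species <- names(counts)
  if (is.null(taxa)) taxa <- toy_taxa(species)
  # deterministic placement: species s present in plots 1..counts[s]
  sp_str <- vapply(seq_len(n), function(j)
    paste(species[counts >= j], collapse = ";"), "")
  plot_table(data.frame(
    plot_id = sprintf("%s%03d", prefix, seq_len(n)), site = site,
    microtopo = microtopo, bare_ground_pct = 10, litter_pct = 0,
    species = sp_str, tamarisk_small = 0, tamarisk_medium = 0,
    tamarisk_big = 0), taxa)
}

# All permutations of 1..n as rows (n! x n), for exact rank-test oracles.
combinat_perms <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- combinat_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i)
    cbind(i, sub + (sub >= i))))
}

# The study stand-in is deterministic; build it once per test run.
standin_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- caspian_standin()
    cache
  }
})
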