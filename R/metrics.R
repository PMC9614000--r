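#' Patristic distance matrix
#'
#' Entry (i, j) is the sum of branch lengths along the unique path between
#' tips i and j, in the units of the branch lengths (millions of years for
#' a dated tree).
#'
#' @param tree An `ape::phylo` tree with at least two tips and branch
#'   lengths on every edge.
#' @return Symmetric numeric matrix with tip names as dimnames.
#' @export
patristic_matrix <- function(tree) {
  validate_tree(tree)
  if (ape::Ntip(tree) < 2) stop("need at least 2 tips")
  if (length(tree$edge.length) != nrow(tree$edge))
    stop("missing branch length")
  d <- stats::cophenetic(tree)
  # canonical tip order
  d[tree$tip.label, tree$tip.label]
}

#' Export a distance matrix as square CSV
#'
#' @param dist Distance matrix from [patristic_matrix()].
#' @param path Output path.
#' @export
write_distance_csv <- function(dist, path) {
  utils::write.csv(as.data.frame(dist), path, row.names = TRUE)
  invisible(path)
}

#' Mean pairwise distance (MPD)
#'
#' Unweighted mean of the n(n-1)/2 distinct pairwise patristic distances
#' of a species set; low values relative to a null indicate phylogenetic
#' clustering. Presence/absence only, no abundance weighting.
#'
#' @param dist Patristic distance matrix.
#' @param species Character set of at least two species, all present in
#'   the matrix.
#' @return Object of class `phylo_metric` with fields `metric`, `value`,
#'   `n_pairs` and `species`.
#' @export
mpd <- function(dist, species) {
  species <- unique(species)
  if (length(species) < 2) stop("need at least 2 species for MPD")
  unknown <- setdiff(species, rownames(dist))
  if (length(unknown))
    stop("species not in the distance matrix: ",
         paste(unknown, collapse = ", "))
  sub <- dist[species, species]
  value <- mean(sub[upper.tri(sub)])
  structure(list(metric = "MPD", value = value,
                 n_pairs = choose(length(species), 2), species = species),
            class = "phylo_metric")
}

#' @export
print.phylo_metric <- function(x, ...) {
  cat(x$metric, "=", format(x$value, digits = 6),
      "over", x$n_pairs, "pairs of", length(x$species), "species\n")
  invisible(x)
}

#' Taxonomic distinctness index (TDI)
#'
#' Mean pairwise taxonomic distance between the species of a community,
#' measured in rank steps through the genus-family-order hierarchy:
#' congeners are 1 step apart, confamilial non-congeners 2, same order but
#' different families 3, and different orders 4. The index therefore lies
#' in \[1, 4\]: 1 iff all species are congeneric, 4 iff every pair crosses
#' orders. Based on presence/absence only.
#'
#' @param taxa Taxon table supplying genus/family/order for every species.
#' @param species Character set of at least two species.
#' @param weights Named numeric rank-step weights
#'   (`genus`, `family`, `order`, `beyond`), configurable.
#' @return Object of class `phylo_metric`.
#' @export
#' @examples
#' tax <- taxon_table(data.frame(
#'   species = c("A x", "B y", "C z"), genus = c("A", "B", "C"),
#'   family = c("F1", "F1", "F2"), order = c("O1", "O1", "O2"),
#'   present_early = TRUE, present_late = FALSE, season = "both"))
#' taxonomic_distinctness(tax, tax$species)$value  # (2 + 4 + 4) / 3
taxonomic_distinctness <- function(taxa, species,
                                   weights = c(genus = 1, family = 2,
                                               order = 3, beyond = 4)) {
  species <- unique(species)
  if (length(species) < 2) stop("need at least 2 species for TDI")
  idx <- match(species, taxa$species)
  if (anyNA(idx))
    stop("species missing from the taxon table: ",
         paste(species[is.na(idx)], collapse = ", "))
  g <- taxa$genus[idx]; f <- taxa$family[idx]; o <- taxa$order[idx]
  if (any(!nzchar(g)) || any(!nzchar(f)) || any(!nzchar(o)) ||
      anyNA(g) || anyNA(f) || anyNA(o))
    stop("genus/family/order must be defined for every species")
  n <- length(species)
  pair_dist <- function(i, j) {
    if (g[i] == g[j]) weights[["genus"]]
    else if (f[i] == f[j]) weights[["family"]]
    else if (o[i] == o[j]) weights[["order"]]
    else weights[["beyond"]]
  }
  total <- 0
  for (i in seq_len(n - 1))
    for (j in seq.int(i + 1, n))
      total <- total + pair_dist(i, j)
  structure(list(metric = "TDI", value = total / choose(n, 2),
                 n_pairs = choose(n, 2), species = species),
            class = "phylo_metric")
}
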