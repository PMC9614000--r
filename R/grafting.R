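#' Graft missing species onto a backbone tree as basal polytomies
#'
#' Each species absent from the tree is attached within its genus when the
#' tree holds at least one congeneric tip, and otherwise within its family.
#' With two or more congeners the species is added as an extra child of the
#' genus crown node (a basal polytomy); with a single congener a node is
#' inserted on that tip's pendant edge at fraction `f` of its length; the
#' same rules apply at family rank when no congener exists. Pendant lengths
#' are chosen so every new tip reaches the common tip depth, hence an
#' ultrametric backbone stays ultrametric and all pre-existing pairwise
#' distances are unchanged.
#'
#' Species are grafted in alphabetical order so repeated grafts into the
#' same genus are deterministic.
#'
#' @param tree Ultrametric `ape::phylo` backbone with branch lengths in
#'   millions of years.
#' @param taxa Taxon table giving genus and family for the species to graft
#'   (and, where available, for backbone tips; a backbone tip's genus
#'   otherwise defaults to the first word of its label).
#' @param species Character vector of species names to graft.
#' @param f Attachment fraction along a single relative's pendant edge,
#'   measured from the tip (default 0.5).
#' @return List with elements `tree` (the enlarged tree) and `report`, a
#'   data frame with one row per grafted species: attachment rank
#'   (genus/family), a description of the attachment node, the pendant
#'   branch length and whether a new node was created.
#' @export
#' @examples
#' tr <- ape::read.tree(text = "((G1_a:1,G1_b:1):1,F2_x:2);")
#' tax <- taxon_table(data.frame(
#'   species = c("G1 a", "G1 b", "F2 x", "G1 c"),
#'   genus = c("G1", "G1", "F2", "G1"),
#'   family = c("Fam1", "Fam1", "Fam2", "Fam1"),
#'   order = "Ord1", present_early = TRUE, present_late = TRUE,
#'   season = "both"))
#' graft_species(tr, tax, "G1 c")$tree$tip.label
graft_species <- function(tree, taxa, species, f = 0.5) {
  stopifnot(f > 0, f < 1)
  validate_tree(tree)
  if (!is_ultrametric_tree(tree))
    stop("backbone tree must be ultrametric")
  # canonical in-memory convention: spaced, case-folded species labels
  tree$tip.label <- normalize_species_names(tree$tip.label)
  species <- sort(normalize_species_names(species))
  present <- intersect(species, tree$tip.label)
  if (length(present))
    stop("species already present in the tree: ",
         paste(present, collapse = ", "))
  missing_tax <- setdiff(species, taxa$species)
  if (length(missing_tax))
    stop("species missing from the taxon table: ",
         paste(missing_tax, collapse = ", "))
  report <- data.frame(species = character(0), rank = character(0),
                       attachment = character(0),
                       pendant_length = numeric(0),
                       created_new_node = logical(0))
  for (sp in species) {
    row <- taxa[taxa$species == sp, ]
    tip_genus <- tree_tip_genus(tree, taxa)
    tip_family <- tree_tip_family(tree, taxa)
    congeners <- tree$tip.label[tip_genus == row$genus]
    if (length(congeners)) {
      rank <- "genus"
      relatives <- congeners
      label <- row$genus
    } else {
      relatives <- tree$tip.label[!is.na(tip_family) & tip_family == row$family]
      rank <- "family"
      label <- row$family
      if (!length(relatives))
        stop("no congeneric or confamilial tip in the tree for: ", sp)
    }
    res <- attach_relative(tree, sp, relatives, rank, label, f)
    tree <- res$tree
    report <- rbind(report, res$report)
  }
  validate_tree(tree)
  list(tree = tree, report = report)
}

tree_tip_genus <- function(tree, taxa) {
  labels <- normalize_species_names(tree$tip.label)
  g <- taxa$genus[match(labels, taxa$species)]
  fallback <- vapply(strsplit(labels, " ", fixed = TRUE), `[`, "", 1)
  ifelse(is.na(g), fallback, g)
}

tree_tip_family <- function(tree, taxa) {
  taxa$family[match(normalize_species_names(tree$tip.label), taxa$species)]
}

attach_relative <- function(tree, sp, relatives, rank, label, f) {
  depths <- node_depths(tree)
  tip_depth <- max(depths[seq_along(tree$tip.label)])
  pend <- function(len) {
    y <- structure(list(edge = matrix(c(2L, 1L), 1, 2), tip.label = sp,
                        edge.length = len, Nnode = 1L), class = "phylo")
    y
  }
  if (length(relatives) >= 2) {
    node <- ape::getMRCA(tree, relatives)
    pendant <- tip_depth - depths[node]
    new_tree <- ape::bind.tree(tree, pend(pendant), where = node, position = 0)
    attachment <- paste0("crown of ", rank, " ", label)
    created <- FALSE
  } else {
    tip_idx <- which(tree$tip.label == relatives)
    edge_len <- tree$edge.length[tree$edge[, 2] == tip_idx]
    pendant <- f * edge_len
    new_tree <- ape::bind.tree(tree, pend(pendant), where = tip_idx,
                               position = pendant)
    attachment <- paste0("pendant edge of ", relatives,
                         " (", rank, " ", label, ")")
    created <- TRUE
  }
  list(tree = new_tree,
       report = data.frame(species = sp, rank = rank,
                           attachment = attachment,
                           pendant_length = pendant,
                           created_new_node = created))
}

#' Prune a tree to a focal species set
#'
#' Retains exactly the requested tips; unary internal nodes are suppressed
#' with their branch lengths summed, so all pairwise patristic distances
#' among retained tips are unchanged.
#'
#' @param tree An `ape::phylo` tree.
#' @param species Character set of tip labels to keep (at least two).
#' @return The pruned `ape::phylo` tree.
#' @export
prune_to_species <- function(tree, species) {
  species <- unique(normalize_species_names(species))
  if (length(species) < 2)
    stop("need at least 2 species to prune to")
  absent <- setdiff(species, tree$tip.label)
  if (length(absent))
    stop("species not in the tree: ", paste(absent, collapse = ", "))
  ape::keep.tip(tree, species)
}

#' Write a graft report to CSV
#'
#' @param report Data frame returned by [graft_species()].
#' @param path Output path.
#' @export
write_graft_report <- function(report, path) {
  utils::write.csv(report, path, row.names = FALSE)
  invisible(path)
}
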