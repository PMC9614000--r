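#' Read a Newick tree
#'
#' Thin validating wrapper around [ape::read.tree()]. Branch lengths are
#' required, tip labels must be unique, and underscores in labels are
#' converted to spaces so tip names match normalized species names.
#'
#' @param path Path to a Newick file.
#' @return An `ape::phylo` tree.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  check_newick_syntax(txt, path)
  tree <- tryCatch(ape::read.tree(text = txt),
                   error = function(e) stop("malformed Newick in ", path,
                                            ": ", conditionMessage(e)))
  if (is.null(tree)) stop("malformed Newick in ", path)
  tree$tip.label <- normalize_species_names(tree$tip.label)
  validate_tree(tree)
  tree
}

# Report the position of the first unbalanced parenthesis so parse errors
# name the offending character.
check_newick_syntax <- function(txt, path = "<text>") {
  chars <- strsplit(txt, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop("malformed Newick in ", path,
             ": unbalanced ')' at position ", i)
    }
  }
  if (depth > 0L)
    stop("malformed Newick in ", path, ": ", depth,
         " unclosed '(' (string ends at position ", length(chars), ")")
  if (!grepl(";", txt, fixed = TRUE))
    stop("malformed Newick in ", path, ": missing terminal ';'")
  invisible(TRUE)
}

validate_tree <- function(tree) {
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths")
  if (any(!is.finite(tree$edge.length)) || any(tree$edge.length < 0))
    stop("branch lengths must be finite and non-negative")
  invisible(tree)
}

#' Write a tree to a Newick file
#'
#' Spaces in tip labels are written as underscores, the inverse of
#' [read_newick()], so a write/read cycle is the identity.
#'
#' @param tree An `ape::phylo` tree.
#' @param path Output path.
#' @param digits Significant digits for branch lengths.
#' @export
write_newick <- function(tree, path, digits = 12) {
  validate_tree(tree)
  out <- tree
  out$tip.label <- gsub(" ", "_", out$tip.label)
  ape::write.tree(out, file = path, digits = digits)
  invisible(path)
}

#' Root-to-tip depths of all tips
#'
#' @param tree An `ape::phylo` tree with branch lengths.
#' @return Named numeric vector of root-to-tip path sums.
#' @export
tip_depths <- function(tree) {
  d <- node_depths(tree)[seq_along(tree$tip.label)]
  names(d) <- tree$tip.label
  d
}

# Distance from the root for every node (tips first, then internals).
node_depths <- function(tree) {
  n_all <- max(tree$edge)
  depth <- numeric(n_all)
  root <- ape::Ntip(tree) + 1L
  # edges in preorder so parents are visited before children
  ord <- ape::reorder.phylo(tree, "cladewise")
  for (i in seq_len(nrow(ord$edge))) {
    e <- ord$edge[i, ]
    depth[e[2]] <- depth[e[1]] + ord$edge.length[i]
  }
  depth[root] <- 0
  depth
}

#' Test whether a tree is ultrametric
#'
#' All root-to-tip path sums must agree within a relative tolerance.
#'
#' @param tree An `ape::phylo` tree.
#' @param tol Relative tolerance (default `1e-6`).
#' @return Logical.
#' @export
is_ultrametric_tree <- function(tree, tol = 1e-6) {
  d <- tip_depths(tree)
  (max(d) - min(d)) <= tol * max(d)
}

#' Read the tabular study inputs
#'
#' Reads the species, plot and soil CSV files (UTF-8, comma-separated,
#' header row mandatory, decimal point), normalizes species names through
#' the optional alias table, resolves every plot species against the taxon
#' table and reports row counts.
#'
#' @param species_path,plot_path,soil_path CSV file paths.
#' @param aliases_path Optional CSV with columns `variant`, `canonical`.
#' @param quiet Suppress the row-count log message.
#' @return List with elements `taxa`, `plots`, `soil`, `aliases`.
#' @export
read_study_tables <- function(species_path, plot_path, soil_path,
                              aliases_path = NULL, quiet = FALSE) {
  read1 <- function(p) {
    if (!file.exists(p)) stop("file not found: ", p)
    utils::read.csv(p, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  }
  aliases <- if (!is.null(aliases_path)) read1(aliases_path) else NULL
  raw_sp <- read1(species_path)
  n_raw <- nrow(raw_sp)
  if (!is.null(aliases)) {
    norm <- normalize_species_names(raw_sp$species, aliases)
    merged <- norm[duplicated(norm)]
    if (length(merged)) {
      if (!quiet)
        message("unified orthographic variants for: ",
                paste(unique(merged), collapse = ", "))
      raw_sp$species <- norm
      raw_sp <- raw_sp[!duplicated(raw_sp$species), , drop = FALSE]
    }
  }
  taxa <- taxon_table(raw_sp, aliases = aliases)
  plots_raw <- read1(plot_path)
  if (nrow(plots_raw) == 0) stop("no plots")
  plots <- plot_table(plots_raw, taxa, aliases = aliases)
  soil <- soil_table(read1(soil_path))
  if (!quiet)
    message("read ", n_raw, " species rows (", nrow(taxa), " taxa), ",
            nrow(plots), " plots, ", nrow(soil), " soil samples")
  list(taxa = taxa, plots = plots, soil = soil, aliases = aliases)
}

#' Write a study bundle to CSV (and Newick) files
#'
#' Inverse of [read_study_tables()]; used by the generators and the
#' pipeline to emit self-contained input sets.
#'
#' @param bundle List with `taxa`, `plots`, `soil` and optionally `tree`
#'   and `aliases`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_study_tables <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, f)
    utils::write.csv(as.data.frame(df), file.path(dir, f), row.names = FALSE,
                     quote = TRUE, fileEncoding = "UTF-8")
  w(bundle$taxa, "species.csv")
  w(bundle$plots, "plots.csv")
  w(bundle$soil, "soil.csv")
  if (!is.null(bundle$aliases)) w(bundle$aliases, "aliases.csv")
  if (!is.null(bundle$tree)) write_newick(bundle$tree, file.path(dir, "tree.nwk"))
  invisible(dir)
}
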