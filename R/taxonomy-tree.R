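#' Build an ultrametric tree from a nested taxonomy
#'
#' Constructs a dated tree in which species of one genus coalesce at the
#' genus crown age, genera of one family at the family crown age, families
#' of one order at the order crown age, and orders at the root. Unary
#' levels (e.g. a family with a single genus) are suppressed, so the tree
#' has no zero-length or redundant edges. Useful as a transparent
#' taxonomy-shaped stand-in when no calibrated phylogeny is available, and
#' for family-level trees (pass the family column as `tip`).
#'
#' @param df Data frame with a `tip` column and one column per grouping
#'   rank, coarsest last (e.g. `tip`, `genus`, `family`, `order`).
#' @param ranks Character vector of the grouping columns, finest first.
#' @param ages Named numeric crown ages (millions of years), one per rank
#'   plus `"root"`; must increase from finest rank to root.
#' @return An `ape::phylo` ultrametric tree with `df$tip` as tip labels.
#' @export
#' @examples
#' df <- data.frame(tip = c("A a", "A b", "B c", "C d"),
#'                  genus = c("A", "A", "B", "C"),
#'                  family = c("F1", "F1", "F1", "F2"))
#' tr <- taxonomy_tree(df, ranks = c("genus", "family"),
#'                     ages = c(genus = 10, family = 50, root = 100))
taxonomy_tree <- function(df, ranks = c("genus", "family", "order"),
                          ages = c(genus = 14, family = 52, order = 96,
                                   root = 140)) {
  stopifnot(all(c("tip", ranks) %in% names(df)),
            all(c(ranks, "root") %in% names(ages)))
  if (anyDuplicated(df$tip)) stop("duplicate tip labels")
  age_seq <- unname(ages[c(ranks, "root")])
  if (any(diff(age_seq) <= 0))
    stop("crown ages must increase from the finest rank to the root")
  # returns list(str = newick fragment without terminal length, age);
  # siblings of rank `level` join at the crown age of rank `level + 1`
  # (the root beyond the coarsest rank)
  build <- function(rows, level) {
    if (level == 0L) {
      if (nrow(rows) == 1L)
        return(list(str = gsub(" ", "_", rows$tip), age = 0))
      # several tips sharing every rank: coalesce at the finest crown age
      age <- age_seq[1]
      kids <- paste0(gsub(" ", "_", rows$tip), ":", age, collapse = ",")
      return(list(str = paste0("(", kids, ")"), age = age))
    }
    groups <- split(rows, rows[[ranks[level]]], drop = TRUE)
    kids <- lapply(groups, build, level = level - 1L)
    if (length(kids) == 1L) return(kids[[1]])
    age <- age_seq[level + 1L]
    inner <- paste(vapply(kids, function(k)
      paste0(k$str, ":", age - k$age), character(1)), collapse = ",")
    list(str = paste0("(", inner, ")"), age = age)
  }
  top <- build(df, length(ranks))
  if (top$age == 0) stop("need at least 2 distinct tips")
  tree <- ape::read.tree(text = paste0(top$str, ";"))
  tree$tip.label <- gsub("_", " ", tree$tip.label)
  validate_tree(tree)
  tree
}
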