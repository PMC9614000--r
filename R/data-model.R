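#' @keywords internal
"_PACKAGE"

# Fixed auger sampling scheme: depth intervals in cm.
DEPTH_INTERVALS <- data.frame(
  top    = c(0, 5, 10, 20, 30, 50, 70),
  bottom = c(5, 10, 20, 30, 50, 70, 100)
)

#' Label for a depth interval
#'
#' @param top,bottom Interval bounds in cm.
#' @return Character label such as `"30-50"`.
#' @export
depth_label <- function(top, bottom) paste0(top, "-", bottom)

#' Depth layers of the auger sampling scheme
#'
#' @return Character vector of the seven depth-interval labels, shallowest
#'   first.
#' @export
depth_layers <- function() depth_label(DEPTH_INTERVALS$top, DEPTH_INTERVALS$bottom)

#' Normalize species names
#'
#' Trims and collapses whitespace, replaces underscores by spaces,
#' capitalizes the genus and lower-cases the remaining epithets. Known
#' orthographic variants are then unified through an explicit alias table;
#' no fuzzy matching is performed, so distinct names never merge silently.
#'
#' @param x Character vector of species names.
#' @param aliases Optional data frame with columns `variant` and
#'   `canonical`, applied after orthographic normalization.
#' @return Character vector of normalized names.
#' @export
#' @examples
#' normalize_species_names("  halocnemum   STROBILACEUM ")
normalize_species_names <- function(x, aliases = NULL) {
  x <- gsub("_", " ", as.character(x))
  x <- gsub("\\s+", " ", trimws(x))
  fix_case <- function(s) {
    if (!nzchar(s)) return(s)
    words <- strsplit(s, " ", fixed = TRUE)[[1]]
    words[1] <- paste0(toupper(substr(words[1], 1, 1)),
                       tolower(substr(words[1], 2, nchar(words[1]))))
    if (length(words) > 1)
      words[-1] <- tolower(words[-1])
    paste(words, collapse = " ")
  }
  x <- vapply(x, fix_case, character(1), USE.NAMES = FALSE)
  if (!is.null(aliases)) {
    stopifnot(all(c("variant", "canonical") %in% names(aliases)))
    key <- normalize_species_names(aliases$variant)
    val <- normalize_species_names(aliases$canonical)
    hit <- match(x, key)
    x[!is.na(hit)] <- val[hit[!is.na(hit)]]
  }
  x
}

#' Construct and validate a taxon table
#'
#' A taxon table holds one row per species with its genus/family/order
#' placement, site presence, season of record and binary ecological traits.
#'
#' @param df Data frame with columns `species`, `genus`, `family`, `order`,
#'   `present_early`, `present_late`, `season` (spring/autumn/both), the
#'   logical traits `desert`, `halophyte`, `meadow`, `c4`, and optional
#'   `root_depth_cm` and `subfamily`.
#' @param aliases Optional alias table passed to
#'   [normalize_species_names()].
#' @param require_presence If `TRUE` (default), every record must be
#'   present at one of the two sites, as in a flora table.
#' @return The validated data frame with normalized names, invisibly
#'   classed as `succ_taxa`.
#' @export
taxon_table <- function(df, aliases = NULL, require_presence = TRUE) {
  needed <- c("species", "genus", "family", "order",
              "present_early", "present_late", "season")
  miss <- setdiff(needed, names(df))
  if (length(miss))
    stop("taxon table is missing columns: ", paste(miss, collapse = ", "))
  df$species <- normalize_species_names(df$species, aliases)
  df$genus <- trimws(df$genus)
  if (anyDuplicated(df$species))
    stop("duplicate species after normalization: ",
         paste(unique(df$species[duplicated(df$species)]), collapse = ", "))
  first_word <- vapply(strsplit(df$species, " ", fixed = TRUE), `[`, "", 1)
  bad <- df$genus != first_word
  if (any(bad))
    stop("genus must be the first word of the species name; offenders: ",
         paste(df$species[bad], collapse = ", "))
  if (any(!nzchar(df$family)) || any(!nzchar(df$order)))
    stop("family and order must be non-empty for every species")
  for (col in c("present_early", "present_late"))
    df[[col]] <- as.logical(df[[col]])
  if (require_presence && any(!df$present_early & !df$present_late))
    stop("flora records must be present at at least one site: ",
         paste(df$species[!df$present_early & !df$present_late], collapse = ", "))
  if (!all(df$season %in% c("spring", "autumn", "both")))
    stop("season must be one of spring/autumn/both")
  for (col in intersect(c("desert", "halophyte", "meadow", "c4"), names(df)))
    df[[col]] <- as.logical(df[[col]])
  class(df) <- c("succ_taxa", "data.frame")
  df
}

#' Derive the site floras and their partition
#'
#' Splits a flora into the early-site and late-site species sets and the
#' derived shared / lost (early-only) / acquired (late-only) sets.
#'
#' @param taxa A taxon table (see [taxon_table()]).
#' @return An object of class `site_flora`: a list with character vectors
#'   `early`, `late`, `shared`, `lost`, `acquired`.
#' @export
site_flora <- function(taxa) {
  early <- sort(taxa$species[taxa$present_early])
  late <- sort(taxa$species[taxa$present_late])
  fl <- list(
    early    = early,
    late     = late,
    shared   = intersect(early, late),
    lost     = setdiff(early, late),
    acquired = setdiff(late, early)
  )
  structure(fl, class = "site_flora")
}

#' @export
print.site_flora <- function(x, ...) {
  cat("Site flora:",
      length(x$early), "early,", length(x$late), "late,",
      length(x$shared), "shared,", length(x$lost), "lost,",
      length(x$acquired), "acquired\n")
  invisible(x)
}

#' Construct and validate a plot table
#'
#' One row per 2 x 2 m vegetation description. Species presence is strictly
#' binary; cover values in the input, if any, are ignored by every test.
#'
#' @param df Data frame with columns `plot_id`, `site` (early/late),
#'   `microtopo` (microhigh/microlow), `bare_ground_pct`, optional
#'   `litter_pct`, `species` (semicolon-joined presence list), optional
#'   tamarisk size-class counts `tamarisk_small`, `tamarisk_medium`,
#'   `tamarisk_big`, and optional `hole_id` pairing each plot with its
#'   nearest auger hole.
#' @param taxa Taxon table used to resolve plot species names.
#' @param aliases Optional alias table for name normalization.
#' @return Validated data frame classed `succ_plots`.
#' @export
plot_table <- function(df, taxa, aliases = NULL) {
  needed <- c("plot_id", "site", "microtopo", "bare_ground_pct", "species")
  miss <- setdiff(needed, names(df))
  if (length(miss))
    stop("plot table is missing columns: ", paste(miss, collapse = ", "))
  if (nrow(df) == 0) stop("no plots")
  if (anyDuplicated(df$plot_id)) stop("duplicate plot ids")
  if (!all(df$site %in% c("early", "late")))
    stop("plot site must be 'early' or 'late'")
  if (!all(df$microtopo %in% c("microhigh", "microlow")))
    stop("microtopography class must be 'microhigh' or 'microlow'")
  frac_cols <- intersect(c("bare_ground_pct", "litter_pct"), names(df))
  for (col in frac_cols) {
    v <- df[[col]]
    if (any(!is.finite(v)) || any(v < 0 | v > 100))
      stop(col, " must lie in [0, 100]")
  }
  spl <- plot_species_list(df, aliases = aliases)
  found <- unique(unlist(spl))
  unknown <- setdiff(found, taxa$species)
  if (length(unknown))
    stop("plot species not in the taxon table: ",
         paste(unknown, collapse = ", "))
  df$species <- vapply(spl, paste, "", collapse = ";")
  class(df) <- c("succ_plots", "data.frame")
  df
}

#' Split the semicolon-joined species column of a plot table
#'
#' @param plots Plot table or raw data frame with a `species` column.
#' @param aliases Optional alias table.
#' @return List of normalized species-name vectors, one per plot.
#' @export
plot_species_list <- function(plots, aliases = NULL) {
  lapply(strsplit(ifelse(is.na(plots$species), "", plots$species), ";",
                  fixed = TRUE),
         function(s) {
           s <- s[nzchar(trimws(s))]
           if (!length(s)) character(0) else normalize_species_names(s, aliases)
         })
}

#' Binary plot-by-species occupancy matrix
#'
#' @param plots Plot table.
#' @param species Species to include as columns; defaults to every species
#'   occurring in the table.
#' @return Logical matrix, rows named by `plot_id`.
#' @export
occupancy_matrix <- function(plots, species = NULL) {
  spl <- plot_species_list(plots)
  if (is.null(species)) species <- sort(unique(unlist(spl)))
  m <- matrix(FALSE, nrow(plots), length(species),
              dimnames = list(plots$plot_id, species))
  for (i in seq_along(spl)) m[i, intersect(spl[[i]], species)] <- TRUE
  m
}

#' Construct and validate a soil table
#'
#' @param df Data frame with columns `hole_id`, `site`, `microtopo`,
#'   `depth_top_cm`, `depth_bottom_cm`, `ec_dsm` (electrical conductivity,
#'   dS/m). Depth intervals must come from the fixed auger scheme
#'   0-5, 5-10, 10-20, 20-30, 30-50, 50-70, 70-100 cm.
#' @return Validated data frame classed `succ_soil`, with a derived
#'   `layer` label column.
#' @export
soil_table <- function(df) {
  needed <- c("hole_id", "site", "microtopo", "depth_top_cm",
              "depth_bottom_cm", "ec_dsm")
  miss <- setdiff(needed, names(df))
  if (length(miss))
    stop("soil table is missing columns: ", paste(miss, collapse = ", "))
  if (!all(df$site %in% c("early", "late")))
    stop("soil site must be 'early' or 'late'")
  if (!all(df$microtopo %in% c("microhigh", "microlow")))
    stop("microtopography class must be 'microhigh' or 'microlow'")
  lay <- depth_label(df$depth_top_cm, df$depth_bottom_cm)
  bad <- !lay %in% depth_layers()
  if (any(bad))
    stop("unknown depth interval(s): ", paste(unique(lay[bad]), collapse = ", "))
  if (any(!is.finite(df$ec_dsm)) || any(df$ec_dsm < 0))
    stop("EC must be finite and non-negative")
  df$layer <- lay
  class(df) <- c("succ_soil", "data.frame")
  df
}

#' Construct a test-result record
#'
#' Container used by every statistical test in the package so that each
#' p-value travels with its tail, correction metadata and group summaries.
#'
#' @param test Name of the test.
#' @param statistic Statistic value (may be `NA`).
#' @param p_value Raw p-value in (0, 1].
#' @param tail `"left"`, `"right"` or `"two-sided"`.
#' @param p_adjusted Optional corrected p-value.
#' @param correction Correction method (e.g. `"bonferroni"`) or `"none"`.
#' @param m Family size used by the correction.
#' @param groups Optional named list of group summaries.
#' @param degenerate Logical flag for degenerate comparisons.
#' @param note Optional free-text metadata.
#' @return Object of class `succ_test`.
#' @export
test_result <- function(test, statistic = NA_real_, p_value, tail,
                        p_adjusted = NULL, correction = "none", m = NULL,
                        groups = NULL, degenerate = FALSE, note = NULL) {
  if (!is.na(p_value) && (p_value <= 0 || p_value > 1))
    stop("p-value must lie in (0, 1]")
  if (!tail %in% c("left", "right", "two-sided"))
    stop("tail must be left/right/two-sided")
  structure(list(test = test, statistic = statistic, p_value = p_value,
                 p_adjusted = p_adjusted, tail = tail,
                 correction = correction, m = m, groups = groups,
                 degenerate = degenerate, note = note),
            class = "succ_test")
}

#' @export
print.succ_test <- function(x, ...) {
  cat(x$test, " (", x$tail, "): p = ", format(x$p_value, digits = 3), sep = "")
  if (!is.null(x$p_adjusted))
    cat(", ", x$correction, " (m = ", x$m, "): p = ",
        format(x$p_adjusted, digits = 3), sep = "")
  if (isTRUE(x$degenerate)) cat("  [degenerate]")
  cat("\n")
  invisible(x)
}

# Bonferroni with the family size recorded alongside.
bonferroni <- function(p, m) pmin(1, m * p)
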