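# Select plot rows by site and/or microtopography class.
select_plots <- function(plots, site = NULL, microtopo = NULL) {
  keep <- rep(TRUE, nrow(plots))
  if (!is.null(site)) keep <- keep & plots$site == site
  if (!is.null(microtopo)) keep <- keep & plots$microtopo == microtopo
  which(keep)
}

#' Prevalence of a species in a plot stratum
#'
#' The number of plots where the species was found divided by the total
#' number of plots in the stratum (a site, a site-by-microtopography
#' stratum, or the whole survey).
#'
#' @param plots Plot table.
#' @param species Species name.
#' @param site,microtopo Optional stratum selectors.
#' @return List with `species`, `stratum`, `count`, `total`, `fraction`.
#' @export
species_prevalence <- function(plots, species, site = NULL,
                               microtopo = NULL) {
  idx <- select_plots(plots, site, microtopo)
  if (!length(idx)) stop("empty stratum")
  species <- normalize_species_names(species)
  spl <- plot_species_list(plots[idx, , drop = FALSE])
  count <- sum(vapply(spl, function(s) species %in% s, logical(1)))
  list(species = species,
       stratum = paste(c(site, microtopo, if (is.null(c(site, microtopo)))
         "all plots"), collapse = " "),
       count = count, total = length(idx), fraction = count / length(idx))
}

#' Prevalence fractions for all species by site and microtopography
#'
#' @param plots Plot table.
#' @param species Optional species vector; defaults to everything present.
#' @return Data frame of fractions with one row per species and one column
#'   per site-by-microtopography stratum.
#' @export
prevalence_table <- function(plots, species = NULL) {
  if (is.null(species)) species <- sort(unique(unlist(plot_species_list(plots))))
  strata <- expand.grid(site = c("early", "late"),
                        microtopo = c("microhigh", "microlow"),
                        stringsAsFactors = FALSE)
  out <- data.frame(species = species)
  for (i in seq_len(nrow(strata))) {
    idx <- select_plots(plots, strata$site[i], strata$microtopo[i])
    col <- paste(strata$site[i], strata$microtopo[i], sep = "_")
    if (!length(idx)) { out[[col]] <- NA_real_; next }
    occ <- occupancy_matrix(plots[idx, , drop = FALSE], species)
    out[[col]] <- colMeans(occ)
  }
  out
}

#' Stratified Fisher tests of differential prevalence
#'
#' For each species, a 2 x 2 table of presence/absence against two plot
#' strata is tested with Fisher's exact test (two-sided,
#' minimum-likelihood convention). The Bonferroni family size defaults to
#' the number of species tested and is recorded in the output. The
#' preferred stratum is the one with the higher prevalence when the
#' corrected p-value is below `alpha`, else `"n.s."`.
#'
#' @param plots Plot table.
#' @param stratum_a,stratum_b Named lists with `site` and/or `microtopo`
#'   selecting two disjoint plot strata.
#' @param species Character vector of species to test.
#' @param correction `"bonferroni"` or `"none"`.
#' @param m Bonferroni family size; defaults to `length(species)`.
#' @param alpha Significance level for the preference call.
#' @return Data frame with fractions, counts, raw and corrected p-values
#'   and the preferred stratum per species.
#' @export
stratified_fisher_tests <- function(plots, stratum_a, stratum_b, species,
                                    correction = c("bonferroni", "none"),
                                    m = NULL, alpha = 0.05) {
  correction <- match.arg(correction)
  ia <- do.call(select_plots, c(list(plots), stratum_a))
  ib <- do.call(select_plots, c(list(plots), stratum_b))
  if (!length(ia) || !length(ib)) stop("each stratum needs at least 1 plot")
  if (length(intersect(ia, ib))) stop("strata must be disjoint")
  species <- normalize_species_names(species)
  if (is.null(m)) m <- length(species)
  occ_a <- occupancy_matrix(plots[ia, , drop = FALSE], species)
  occ_b <- occupancy_matrix(plots[ib, , drop = FALSE], species)
  lab <- function(s) paste(unlist(s), collapse = " ")
  res <- do.call(rbind, lapply(species, function(sp) {
    ka <- sum(occ_a[, sp]); kb <- sum(occ_b[, sp])
    na <- length(ia); nb <- length(ib)
    degenerate <- (ka + kb) == 0
    p <- if (degenerate) 1 else
      stats::fisher.test(matrix(c(ka, na - ka, kb, nb - kb), 2))$p.value
    data.frame(species = sp, fraction_a = ka / na, fraction_b = kb / nb,
               count_a = ka, count_b = kb, n_a = na, n_b = nb,
               p = p, degenerate = degenerate)
  }))
  res$p_corrected <- if (correction == "bonferroni") bonferroni(res$p, m) else res$p
  res$m <- m
  res$preferred <- ifelse(
    res$p_corrected < alpha & !res$degenerate,
    ifelse(res$fraction_a > res$fraction_b, lab(stratum_a), lab(stratum_b)),
    "n.s.")
  attr(res, "strata") <- list(a = stratum_a, b = stratum_b)
  res
}

# Mann-Whitney U via the rank-sum test: exact distribution for small
# untied samples, tie-corrected normal approximation otherwise.
rank_sum_test <- function(x, y, alternative = "two.sided") {
  exact <- (length(x) + length(y)) <= 40 && !anyDuplicated(c(x, y))
  suppressWarnings(
    stats::wilcox.test(x, y, alternative = alternative, exact = exact,
                       correct = TRUE)
  )
}

#' Mann-Whitney comparison of bare-ground fractions
#'
#' Two-sided Mann-Whitney U test of the bare-ground percentage between two
#' plot groups, with group means reported for summary (e.g. microhighs vs
#' microlows of one site, or one stratum across the two sites).
#'
#' @param plots Plot table.
#' @param stratum_a,stratum_b Stratum selectors as in
#'   [stratified_fisher_tests()].
#' @param variable Column compared (default `"bare_ground_pct"`).
#' @return A `succ_test`; `groups` carries the group means and sizes.
#' @export
bare_ground_comparison <- function(plots, stratum_a, stratum_b,
                                   variable = "bare_ground_pct") {
  ia <- do.call(select_plots, c(list(plots), stratum_a))
  ib <- do.call(select_plots, c(list(plots), stratum_b))
  if (length(ia) < 2 || length(ib) < 2)
    stop("each group needs at least 2 plots")
  a <- plots[[variable]][ia]; b <- plots[[variable]][ib]
  ht <- rank_sum_test(a, b, "two.sided")
  test_result("Mann-Whitney bare ground", statistic = unname(ht$statistic),
              p_value = ht$p.value, tail = "two-sided",
              groups = list(mean_a = mean(a), mean_b = mean(b),
                            n_a = length(a), n_b = length(b),
                            stratum_a = stratum_a, stratum_b = stratum_b))
}

#' Mann-Whitney comparison of soil salinity between microtopography classes
#'
#' @param soil Soil table.
#' @param site Site id.
#' @param layer Depth-interval label (see [depth_layers()]).
#' @return A `succ_test` with group means (dS/m).
#' @export
ec_microtopo_comparison <- function(soil, site, layer) {
  sub <- soil[soil$site == site & soil$layer == layer, ]
  a <- sub$ec_dsm[sub$microtopo == "microhigh"]
  b <- sub$ec_dsm[sub$microtopo == "microlow"]
  if (length(a) < 2 || length(b) < 2)
    stop("each microtopography class needs at least 2 samples")
  ht <- rank_sum_test(a, b, "two.sided")
  test_result("Mann-Whitney EC", statistic = unname(ht$statistic),
              p_value = ht$p.value, tail = "two-sided",
              groups = list(mean_microhigh = mean(a), mean_microlow = mean(b),
                            n_microhigh = length(a), n_microlow = length(b),
                            site = site, layer = layer))
}

#' Spearman screen of bare ground against soil EC by depth layer
#'
#' Plots are matched to auger holes through the `hole_id` pairing column;
#' for each depth layer, the bare-ground percentage of every matched plot
#' is correlated (Spearman) with the EC of its hole, both sites pooled.
#' With `layer = NULL` all sampled layers are screened and the layer with
#' maximum |r| is reported.
#'
#' @param plots Plot table with a `hole_id` column.
#' @param soil Soil table.
#' @param layer Single depth-interval label, or `NULL` to screen all.
#' @return For one layer a `succ_test` (statistic = rho); for the screen a
#'   list with `by_layer` (data frame) and `best` (the max-|r| layer's
#'   `succ_test`).
#' @export
ec_depth_correlation <- function(plots, soil, layer = NULL) {
  if (is.null(plots$hole_id)) stop("plot table has no hole_id pairing column")
  one <- function(lay) {
    sub <- soil[soil$layer == lay, ]
    ec <- tapply(sub$ec_dsm, sub$hole_id, mean)
    ecp <- ec[as.character(plots$hole_id)]
    ok <- !is.na(ecp)
    if (sum(ok) < 3) stop("fewer than 3 matched plot-EC pairs for ", lay)
    x <- plots$bare_ground_pct[ok]; y <- as.numeric(ecp[ok])
    exact <- sum(ok) <= 9 && !anyDuplicated(x) && !anyDuplicated(y)
    ht <- suppressWarnings(
      stats::cor.test(x, y, method = "spearman", exact = exact))
    test_result("Spearman bare ground vs EC",
                statistic = unname(ht$estimate), p_value = ht$p.value,
                tail = "two-sided",
                groups = list(layer = lay, n = sum(ok)))
  }
  if (!is.null(layer)) {
    if (!layer %in% depth_layers()) stop("unknown depth interval: ", layer)
    return(one(layer))
  }
  layers <- intersect(depth_layers(), unique(soil$layer))
  tests <- lapply(layers, one)
  by_layer <- data.frame(layer = layers,
                         r = vapply(tests, function(t) t$statistic, 0),
                         p = vapply(tests, function(t) t$p_value, 0),
                         n = vapply(tests, function(t) t$groups$n, 0))
  best <- tests[[which.max(abs(by_layer$r))]]
  list(by_layer = by_layer, best = best)
}

#' Fisher test of trait enrichment between persistent and lost species
#'
#' Compares a binary ecological trait between the species present at the
#' late site and the species lost from it (early-only), restricted to the
#' species recorded in the given season. Two-sided Fisher exact test with
#' trait fractions per group.
#'
#' @param flora A `site_flora`.
#' @param taxa Taxon table with the trait column and a `season` column.
#' @param trait One of `"desert"`, `"halophyte"`, `"meadow"`, `"c4"`.
#' @param season `"spring"` or `"autumn"`; species with season `"both"`
#'   count in either.
#' @return A `succ_test`; `groups` holds per-group trait fractions.
#' @export
trait_enrichment_test <- function(flora, taxa,
                                  trait = c("desert", "halophyte",
                                            "meadow", "c4"),
                                  season = c("spring", "autumn")) {
  trait <- match.arg(trait); season <- match.arg(season)
  seen <- function(sp) {
    s <- taxa$season[match(sp, taxa$species)]
    sp[s %in% c(season, "both")]
  }
  late <- seen(flora$late)
  lost <- seen(flora$lost)
  tv <- function(sp) taxa[[trait]][match(sp, taxa$species)]
  undef <- c(late[is.na(tv(late))], lost[is.na(tv(lost))])
  if (length(undef))
    stop("trait '", trait, "' undefined for: ", paste(undef, collapse = ", "))
  a <- sum(tv(late)); b <- sum(tv(lost))
  tab <- matrix(c(a, length(late) - a, b, length(lost) - b), 2)
  p <- stats::fisher.test(tab)$p.value
  test_result(paste0("trait enrichment (", trait, ", ", season, ")"),
              statistic = a / length(late) - b / length(lost),
              p_value = p, tail = "two-sided",
              groups = list(fraction_late = a / length(late),
                            fraction_lost = b / length(lost),
                            n_late = length(late), n_lost = length(lost)))
}

#' Nurse-plant association test
#'
#' Right-sided Fisher exact test of whether a target species occurs more
#' often in plots where the nurse condition holds (by default, at least
#' one big tamarisk bush) than in plots where it does not. Tamarisk size
#' classes are recorded for the early site only; passing late-site plots
#' is an error rather than a silent empty result.
#'
#' @param plots Early-site plot table with tamarisk size-class columns.
#' @param target Target species name.
#' @param nurse_col Column defining the nurse condition (count > 0).
#' @return A `succ_test` (degenerate and p = 1 when the nurse condition or
#'   the target does not vary).
#' @export
nurse_plant_association <- function(plots, target,
                                    nurse_col = "tamarisk_big") {
  if (any(plots$site != "early"))
    stop("tamarisk size classes are recorded for early-site plots only")
  if (is.null(plots[[nurse_col]]))
    stop("plot table has no column ", nurse_col)
  target <- normalize_species_names(target)
  nurse <- plots[[nurse_col]] > 0
  occ <- occupancy_matrix(plots, target)[, 1]
  if (all(nurse) || !any(nurse) || !any(occ))
    return(test_result("nurse-plant association", statistic = NA_real_,
                       p_value = 1, tail = "right", degenerate = TRUE,
                       groups = list(target = target, nurse = nurse_col)))
  tab <- matrix(c(sum(occ & nurse), sum(!occ & nurse),
                  sum(occ & !nurse), sum(!occ & !nurse)), 2)
  ht <- stats::fisher.test(tab, alternative = "greater")
  test_result("nurse-plant association", statistic = unname(ht$estimate),
              p_value = ht$p.value, tail = "right",
              groups = list(target = target, nurse = nurse_col,
                            with_nurse = sum(occ & nurse) / sum(nurse),
                            without_nurse = sum(occ & !nurse) / sum(!nurse)))
}

#' Lineage ratio within a flora
#'
#' Integer counts of two taxa (family, or subfamily when the taxon table
#' carries a `subfamily` column) within a species set, and their quotient.
#' Used for arid-indicator ratios such as chenopods over Asteraceae.
#'
#' @param species Character vector of species.
#' @param taxa Taxon table.
#' @param numerator,denominator Taxon labels matched against the family
#'   and, if present, subfamily columns.
#' @return List with `numerator_count`, `denominator_count`, `ratio`.
#' @export
lineage_ratio <- function(species, taxa, numerator, denominator) {
  idx <- match(species, taxa$species)
  if (anyNA(idx)) stop("species missing from the taxon table")
  labels <- function(i) {
    out <- taxa$family[i]
    if (!is.null(taxa$subfamily)) out <- c(out, taxa$subfamily[i])
    out[!is.na(out)]
  }
  count <- function(tax)
    sum(vapply(idx, function(i) tax %in% labels(i), logical(1)))
  num <- count(numerator); den <- count(denominator)
  if (den == 0) stop("denominator taxon ", denominator, " has zero species")
  list(numerator_count = num, denominator_count = den, ratio = num / den)
}

#' Prevalence-based extinction-randomness test
#'
#' If extinction were purely abundance-driven, species retained by the late
#' site should have been more prevalent at the early site than species that
#' were lost. One-sided Mann-Whitney test on per-species early-site
#' prevalence fractions, alternative: retained > lost.
#'
#' @param plots_early Early-site plot table (autumn descriptions).
#' @param retained Species retained at the late site.
#' @param lost Species lost from the late site.
#' @return A `succ_test`; `groups` holds the per-group median prevalence.
#' @export
extinction_randomness_test <- function(plots_early, retained, lost) {
  if (!nrow(plots_early)) stop("no plots")
  if (length(retained) < 2 || length(lost) < 2)
    stop("both species sets need at least 2 members")
  prev <- function(sp) {
    occ <- occupancy_matrix(plots_early, normalize_species_names(sp))
    colMeans(occ)
  }
  r <- prev(retained); l <- prev(lost)
  ht <- rank_sum_test(r, l, alternative = "greater")
  test_result("extinction randomness (prevalence)",
              statistic = unname(ht$statistic), p_value = ht$p.value,
              tail = "right",
              groups = list(median_retained = stats::median(r),
                            median_lost = stats::median(l),
                            n_retained = length(r), n_lost = length(l)))
}
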