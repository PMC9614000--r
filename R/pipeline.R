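#' Run the full succession analysis
#'
#' One-command orchestration of every stage: flora bookkeeping, grafting
#' of species absent from the backbone, species- and family-level MPD
#' permutation tests, taxonomic distinctness, family loss/gain and order
#' overrepresentation enrichment, microtopography prevalence tables,
#' bare-ground and salinity comparisons, the EC depth screen, trait
#' enrichment, nurse-plant association, lineage ratios and the
#' extinction-randomness test. Re-running with identical inputs, seed and
#' `n_perm` reproduces the report exactly.
#'
#' @param taxa Taxon table of the two-site flora.
#' @param plots Plot table.
#' @param soil Soil table.
#' @param backbone Backbone tree (`ape::phylo`); species of the flora
#'   missing from it are grafted. `NULL` skips the phylogenetic stages.
#' @param backbone_taxonomy Taxon table covering backbone tips and
#'   grafted species (defaults to `taxa`).
#' @param regional_families Regional family pool for the order test
#'   (`NULL` skips it).
#' @param focal_order Order tested for overrepresentation.
#' @param nurse_target Target species of the nurse-plant test.
#' @param ratio_taxa Numerator/denominator labels of the lineage ratio.
#' @param n_perm Permutations for the MPD null distributions.
#' @param seed Integer seed (mandatory).
#' @return A list of class `succ_report`.
#' @export
run_full_analysis <- function(taxa, plots, soil,
                              backbone = NULL, backbone_taxonomy = taxa,
                              regional_families = NULL,
                              focal_order = "Caryophyllales",
                              nurse_target = "Limonium scoparium",
                              ratio_taxa = c("Chenopodioideae",
                                             "Asteraceae"),
                              n_perm = 10000, seed) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  stage <- function(name, expr)
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  flora <- stage("data_model_io", {
    if (is.null(plots) || nrow(plots) == 0) stop("no plots")
    if (is.null(soil) || nrow(soil) == 0) stop("no soil samples")
    site_flora(taxa)
  })

  report <- list()
  report$flora_summary <- list(
    early = length(flora$early), late = length(flora$late),
    shared = length(flora$shared), lost = length(flora$lost),
    acquired = length(flora$acquired))

  # taxonomic distinctness for the five flora groups
  tdi_of <- function(sp) if (length(sp) >= 2)
    taxonomic_distinctness(taxa, sp)$value else NA_real_
  report$tdi <- stage("phylo_metrics", data.frame(
    group = c("early", "late", "shared", "only_early", "only_late"),
    n_species = c(length(flora$early), length(flora$late),
                  length(flora$shared), length(flora$lost),
                  length(flora$acquired)),
    tdi = c(tdi_of(flora$early), tdi_of(flora$late), tdi_of(flora$shared),
            tdi_of(flora$lost), tdi_of(flora$acquired))))

  # phylogenetic stages
  if (!is.null(backbone)) {
    all_species <- sort(union(flora$early, flora$late))
    to_graft <- setdiff(all_species, backbone$tip.label)
    grafted <- stage("tree_grafting",
                     graft_species(backbone, backbone_taxonomy, to_graft))
    flora_tree <- stage("tree_grafting",
                        prune_to_species(grafted$tree, all_species))
    dmat <- stage("phylo_metrics", patristic_matrix(flora_tree))
    report$graft <- list(n_grafted = nrow(grafted$report),
                         report = grafted$report,
                         n_tips_flora_tree = ape::Ntip(flora_tree))
    report$mpd_lost <- stage("null_models", perm_test_summary(
      mpd_permutation_test(dmat, flora$lost, all_species,
                           n_perm = n_perm, seed = seed)))
    report$mpd_acquired <- stage("null_models", perm_test_summary(
      mpd_permutation_test(dmat, flora$acquired, all_species,
                           n_perm = n_perm, seed = seed + 1L)))
    report$tree <- flora_tree
  }

  # family-level MPD over the regional family pool
  if (!is.null(regional_families)) {
    fam_df <- data.frame(tip = regional_families$family,
                         order = regional_families$order)
    fam_tree <- taxonomy_tree(fam_df, ranks = "order",
                              ages = c(order = 96, root = 140))
    fam_dmat <- patristic_matrix(fam_tree)
    site_fams <- sort(unique(taxa$family[taxa$present_early]))
    report$mpd_families <- stage("null_models", perm_test_summary(
      mpd_permutation_test(fam_dmat, site_fams, fam_tree$tip.label,
                           n_perm = n_perm, seed = seed + 2L)))
    report$order_overrepresentation <- stage("enrichment_tests",
      order_overrepresentation_test(regional_families, site_fams,
                                    focal_order))
  }

  # enrichment of loss and gain
  report$family_loss <- stage("enrichment_tests",
                              family_loss_tests(flora, taxa))
  gain_family <- names(which.max(table(
    taxa$family[match(flora$acquired, taxa$species)])))
  gain_K <- sum(taxa$family[match(flora$early, taxa$species)] ==
                  gain_family)
  gain_k <- sum(taxa$family[match(flora$acquired, taxa$species)] ==
                  gain_family)
  # the without-replacement null cannot host more gains than the family
  # has early-site species; fall back to the with-replacement variant
  gain_method <- if (gain_k > gain_K) "binomial" else "hypergeometric"
  report$family_gain <- stage("enrichment_tests", {
    if (gain_K == 0 && gain_k > 0)
      # proportional null undefined: the family holds no early species
      test_result("family gain (undefined)", statistic = gain_k,
                  p_value = 1, tail = "right", degenerate = TRUE,
                  groups = list(family = gain_family, N =
                                  length(flora$early), K = 0,
                                n = length(flora$acquired), k = gain_k))
    else
      family_gain_test(flora$early, flora$acquired, taxa, gain_family,
                       method = gain_method)
  })

  # microtopography prevalence and Fisher tables
  plot_species <- sort(unique(unlist(plot_species_list(plots))))
  report$prevalence <- stage("plot_statistics",
                             prevalence_table(plots, plot_species))
  fisher_site <- function(site) {
    sp <- plot_species[vapply(seq_along(plot_species), function(i)
      any(occupancy_matrix(plots[plots$site == site, , drop = FALSE],
                           plot_species[i])), logical(1))]
    stratified_fisher_tests(plots,
                            list(site = site, microtopo = "microhigh"),
                            list(site = site, microtopo = "microlow"),
                            sp)
  }
  report$microtopo_fisher <- stage("plot_statistics",
    list(early = fisher_site("early"), late = fisher_site("late")))
  report$between_site_fisher <- stage("plot_statistics", list(
    microhigh = stratified_fisher_tests(
      plots, list(site = "late", microtopo = "microhigh"),
      list(site = "early", microtopo = "microhigh"), plot_species),
    microlow = stratified_fisher_tests(
      plots, list(site = "late", microtopo = "microlow"),
      list(site = "early", microtopo = "microlow"), plot_species)))

  # bare ground and salinity
  bg <- function(a, b) bare_ground_comparison(plots, a, b)
  report$bare_ground <- stage("plot_statistics", list(
    early_h_vs_l = bg(list(site = "early", microtopo = "microhigh"),
                      list(site = "early", microtopo = "microlow")),
    late_h_vs_l = bg(list(site = "late", microtopo = "microhigh"),
                     list(site = "late", microtopo = "microlow")),
    microhigh_late_vs_early = bg(list(site = "late",
                                      microtopo = "microhigh"),
                                 list(site = "early",
                                      microtopo = "microhigh")),
    microlow_late_vs_early = bg(list(site = "late",
                                     microtopo = "microlow"),
                                list(site = "early",
                                     microtopo = "microlow"))))
  report$ec_screen <- stage("plot_statistics",
                            ec_depth_correlation(plots, soil))
  report$ec_microtopo <- stage("plot_statistics", {
    combos <- expand.grid(site = c("early", "late"),
                          layer = depth_layers(),
                          stringsAsFactors = FALSE)
    out <- lapply(seq_len(nrow(combos)), function(i)
      ec_microtopo_comparison(soil, combos$site[i], combos$layer[i]))
    names(out) <- paste(combos$site, combos$layer, sep = "_")
    out
  })

  # traits, nurse plant, lineage ratio, extinction randomness
  report$traits <- stage("plot_statistics", list(
    desert_spring = trait_enrichment_test(flora, taxa, "desert", "spring"),
    halophyte_spring = trait_enrichment_test(flora, taxa, "halophyte",
                                             "spring"),
    desert_autumn = trait_enrichment_test(flora, taxa, "desert", "autumn"),
    meadow_autumn = trait_enrichment_test(flora, taxa, "meadow",
                                          "autumn")))
  early_plots <- plots[plots$site == "early", , drop = FALSE]
  report$nurse_plant <- stage("plot_statistics",
    nurse_plant_association(early_plots, nurse_target))
  report$lineage_ratio <- stage("plot_statistics", list(
    late = lineage_ratio(flora$late, taxa, ratio_taxa[1], ratio_taxa[2]),
    early = lineage_ratio(flora$early, taxa, ratio_taxa[1],
                          ratio_taxa[2])))
  # prevalence is computable only for species recorded in the autumn
  # plot descriptions; spring-only records are excluded from both sets
  autumn_sp <- taxa$species[taxa$season %in% c("autumn", "both")]
  report$extinction_randomness <- stage("plot_statistics",
    extinction_randomness_test(early_plots,
                               intersect(flora$shared, autumn_sp),
                               intersect(flora$lost, autumn_sp)))

  report$provenance <- list(
    package_version = as.character(utils::packageVersion("halosucc")),
    seed = seed, n_perm = n_perm,
    n_taxa = nrow(taxa), n_plots = nrow(plots), n_soil = nrow(soil))
  structure(report, class = "succ_report")
}

#' @export
print.succ_report <- function(x, ...) {
  fs <- x$flora_summary
  cat("Succession analysis report\n")
  cat("  flora:", fs$early, "early /", fs$late, "late /", fs$shared,
      "shared /", fs$lost, "lost /", fs$acquired, "acquired\n")
  if (!is.null(x$mpd_lost))
    cat("  MPD p-left: lost =", format(x$mpd_lost$p_left, digits = 3),
        "| acquired =", format(x$mpd_acquired$p_left, digits = 3), "\n")
  cat("  gain test p =", format(x$family_gain$p_value, digits = 3),
      "| min family-loss p =", format(min(x$family_loss$p_right),
                                      digits = 3), "\n")
  if (!is.null(x$order_overrepresentation))
    cat("  order overrepresentation p =",
        format(x$order_overrepresentation$p_value, digits = 3), "\n")
  cat("  EC screen best layer:", x$ec_screen$best$groups$layer,
      "r =", format(x$ec_screen$best$statistic, digits = 3), "\n")
  invisible(x)
}

# flatten succ_test objects for JSON
succ_test_json <- function(t)
  list(test = t$test, statistic = t$statistic, p_value = t$p_value,
       p_adjusted = t$p_adjusted, tail = t$tail,
       correction = t$correction, m = t$m, groups = t$groups,
       degenerate = t$degenerate)

#' Write a report as structured JSON plus per-table CSVs
#'
#' Every number in the CSV tables also appears in the JSON; the JSON
#' layout is described by the schema shipped under
#' `inst/schema/report-schema.json`.
#'
#' @param report A `succ_report`.
#' @param dir Output directory.
#' @return The directory, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  out <- list(
    flora_summary = report$flora_summary,
    tdi = report$tdi,
    family_loss = report$family_loss,
    family_gain = succ_test_json(report$family_gain),
    bare_ground = lapply(report$bare_ground, succ_test_json),
    ec_screen = list(by_layer = report$ec_screen$by_layer,
                     best = succ_test_json(report$ec_screen$best)),
    traits = lapply(report$traits, succ_test_json),
    nurse_plant = succ_test_json(report$nurse_plant),
    lineage_ratio = report$lineage_ratio,
    extinction_randomness = succ_test_json(report$extinction_randomness),
    prevalence = report$prevalence,
    provenance = report$provenance)
  if (!is.null(report$mpd_lost)) {
    out$mpd_lost <- report$mpd_lost
    out$mpd_acquired <- report$mpd_acquired
  }
  if (!is.null(report$mpd_families))
    out$mpd_families <- report$mpd_families
  if (!is.null(report$order_overrepresentation))
    out$order_overrepresentation <-
      succ_test_json(report$order_overrepresentation)
  jsonlite::write_json(out, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  utils::write.csv(report$tdi, file.path(dir, "tdi.csv"),
                   row.names = FALSE)
  utils::write.csv(report$family_loss, file.path(dir, "family_loss.csv"),
                   row.names = FALSE)
  utils::write.csv(report$prevalence, file.path(dir, "prevalence.csv"),
                   row.names = FALSE)
  utils::write.csv(report$microtopo_fisher$early,
                   file.path(dir, "fisher_early.csv"), row.names = FALSE)
  utils::write.csv(report$microtopo_fisher$late,
                   file.path(dir, "fisher_late.csv"), row.names = FALSE)
  if (!is.null(report$graft))
    write_graft_report(report$graft$report,
                       file.path(dir, "graft_report.csv"))
  invisible(dir)
}
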