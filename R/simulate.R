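#' Configuration for the synthetic survey generator
#'
#' Bundles and validates every tunable of the generator chain. The
#' defaults mirror the study design the package analyses: a two-site
#' chronosequence flora of roughly 30 species per site losing about a
#' third of its species and gaining a handful, surveyed in 2 x 2 m plots
#' on two microtopography classes with EC profiles from 1-m auger holes.
#'
#' @param seed Integer seed (mandatory; all generator randomness derives
#'   from it).
#' @param n_tips Number of tips of the simulated backbone tree.
#' @param cuts Depth cuts (fractions of tree height, tips = 0) defining
#'   genera, families and orders.
#' @param early_size Early-site flora size.
#' @param loss_fraction Fraction of the early flora lost by the late site.
#' @param gain_count Number of species acquired by the late site.
#' @param gamma Gain clustering in \[0, 1\]: 0 draws acquisitions
#'   uniformly from the non-early tips, 1 draws them from a single clade.
#' @param plots_per_stratum Plots per site-by-microtopography stratum.
#' @param holes_per_stratum Auger holes per stratum.
#' @param baseline_occupancy Baseline per-species plot occupancy
#'   probability.
#' @param microtopo_logodds Per-species microhigh preference on the
#'   log-odds scale (scalar or named vector; positive favours microhighs).
#' @param ec_profile Named vector of mean EC (dS/m) by depth layer.
#' @param ec_site_offset Multiplicative EC offset of the late site
#'   (log scale).
#' @param ec_microtopo_offset Log-scale EC offset of microhighs.
#' @param ec_noise_sd,ec_hole_sd Log-scale EC noise: per-sample and
#'   shared per-hole components.
#' @param bare_intercept,bare_slope Logistic model of the bare-ground
#'   fraction against the 30-50 cm EC of the paired hole.
#' @param bare_noise_sd Logit-scale noise of the bare-ground fraction.
#' @return Validated list of class `sim_config`.
#' @export
simulation_config <- function(seed,
                              n_tips = 64,
                              cuts = c(genus = 0.2, family = 0.45,
                                       order = 0.7),
                              early_size = 31,
                              loss_fraction = 11 / 31,
                              gain_count = 4,
                              gamma = 1,
                              plots_per_stratum = 150,
                              holes_per_stratum = 12,
                              baseline_occupancy = 0.15,
                              microtopo_logodds = 0,
                              ec_profile = c("0-5" = 14, "5-10" = 13,
                                             "10-20" = 12, "20-30" = 11.5,
                                             "30-50" = 11, "50-70" = 11.5,
                                             "70-100" = 12),
                              ec_site_offset = 0.25,
                              ec_microtopo_offset = 0,
                              ec_noise_sd = 0.15,
                              ec_hole_sd = 0.25,
                              bare_intercept = -2.5,
                              bare_slope = 0.12,
                              bare_noise_sd = 0.5) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  stopifnot(n_tips >= 2, early_size >= 2, early_size <= n_tips,
            loss_fraction >= 0, loss_fraction < 1,
            gain_count >= 0, gamma >= 0, gamma <= 1,
            plots_per_stratum > 0, holes_per_stratum > 0,
            baseline_occupancy > 0, baseline_occupancy < 1,
            all(cuts > 0), all(cuts < 1), cuts[1] < cuts[2],
            cuts[2] < cuts[3],
            all(names(ec_profile) %in% depth_layers()))
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate an ultrametric pure-birth tree with a nested taxonomy
#'
#' Draws a Yule (pure-birth) tree and assigns a genus/family/order
#' taxonomy by cutting the tree at three increasing depths, so every
#' taxon is monophyletic by construction. Tips are renamed
#' `"G<genus> sp<i>"` so the genus is the first word of the species name.
#'
#' @param n_tips Number of tips (at least 2).
#' @param seed Integer seed.
#' @param birth Speciation rate of the pure-birth process.
#' @param cuts Depth cuts as fractions of tree height (see
#'   [simulation_config()]).
#' @return List with `tree` (`ape::phylo`) and `taxa` (a taxon table with
#'   presence flags all `FALSE`, to be filled by the flora generator).
#' @export
simulate_yule_tree <- function(n_tips, seed,
                               birth = 1,
                               cuts = c(genus = 0.2, family = 0.45,
                                        order = 0.7)) {
  if (n_tips < 2) stop("n_tips must be at least 2")
  tree <- with_local_seed(seed, ape::rphylo(n_tips, birth = birth,
                                            death = 0))
  tree$tip.label <- paste0("tip", seq_len(n_tips))
  height <- max(tip_depths(tree))
  grp <- function(frac) cut_tree_groups(tree, frac * height)
  genus <- grp(cuts[["genus"]])
  family <- grp(cuts[["family"]])
  order <- grp(cuts[["order"]])
  g_id <- as.integer(factor(genus, levels = unique(genus)))
  f_id <- as.integer(factor(family, levels = unique(family)))
  o_id <- as.integer(factor(order, levels = unique(order)))
  sp_index <- stats::ave(g_id, g_id, FUN = seq_along)
  species <- sprintf("G%02d sp%d", g_id, sp_index)
  tree$tip.label <- species
  taxa <- taxon_table(data.frame(
    species = species,
    genus = sprintf("G%02d", g_id),
    family = sprintf("F%02d", f_id),
    order = sprintf("O%02d", o_id),
    present_early = FALSE, present_late = FALSE,
    season = "both",
    desert = FALSE, halophyte = FALSE, meadow = FALSE, c4 = FALSE,
    stringsAsFactors = FALSE), require_presence = FALSE)
  list(tree = tree, taxa = taxa)
}

# Group tips by the lineage crossing the given age (time before present):
# two tips share a group iff their MRCA is younger than `age`.
cut_tree_groups <- function(tree, age) {
  depths <- node_depths(tree)
  height <- max(depths[seq_along(tree$tip.label)])
  node_age <- height - depths
  n_tip <- ape::Ntip(tree)
  parent <- integer(max(tree$edge))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  vapply(seq_len(n_tip), function(tip) {
    node <- tip
    while (parent[node] != 0 && node_age[parent[node]] < age)
      node <- parent[node]
    node
  }, integer(1))
}

#' Simulate paired succession floras
#'
#' Draws an early flora uniformly from the tips, loses a uniform subset of
#' it (phylogenetically random loss), and acquires `gain_count` new
#' species: uniformly from the non-early tips with probability
#' `1 - gamma`, or from a single randomly chosen genus clade with
#' probability `gamma` (clustered gain).
#'
#' @param sim Output of [simulate_yule_tree()].
#' @param config A [simulation_config()].
#' @return List with `flora` (a `site_flora`) and `taxa` (presence flags
#'   filled in).
#' @export
simulate_succession_floras <- function(sim, config) {
  tree <- sim$tree; taxa <- sim$taxa
  tips <- tree$tip.label
  n_lost <- round(config$loss_fraction * config$early_size)
  if (config$early_size + config$gain_count > length(tips))
    stop("flora sizes infeasible for tree size")
  res <- with_local_seed(config$seed + 1L, {
    early <- sample(tips, config$early_size)
    lost <- if (n_lost) sample(early, n_lost) else character(0)
    outside <- setdiff(tips, early)
    clustered <- stats::runif(1) < config$gamma
    acquired <- if (config$gain_count == 0) character(0)
    else if (clustered) {
      # draw from the finest taxonomic clade able to supply all gains:
      # a genus where possible, else a family, else an order
      pick <- NULL
      for (rank in c("genus", "family", "order")) {
        grp <- taxa[[rank]][match(outside, taxa$species)]
        sizes <- table(grp)
        ok <- names(sizes)[sizes >= config$gain_count]
        if (length(ok)) {
          pick <- outside[grp == sample(ok, 1)]
          break
        }
      }
      if (is.null(pick))
        stop("no clade large enough for clustered gains; ",
             "lower gain_count or enlarge the tree")
      sample(pick, config$gain_count)
    } else sample(outside, config$gain_count)
    list(early = early, lost = lost, acquired = acquired)
  })
  late <- union(setdiff(res$early, res$lost), res$acquired)
  taxa$present_early <- taxa$species %in% res$early
  taxa$present_late <- taxa$species %in% late
  flora_taxa <- taxa[taxa$present_early | taxa$present_late, , drop = FALSE]
  list(flora = site_flora(flora_taxa), taxa = taxa)
}

#' Simulate a plot and soil survey
#'
#' Per plot, species presence is Bernoulli with
#' `logit(p) = logit(baseline) + microtopography log-odds` for microhighs.
#' EC is drawn per auger hole and depth layer as a log-normal around the
#' layer profile with site and microtopography offsets plus a shared
#' per-hole effect; the bare-ground fraction of each plot is a logistic
#' function of the 30-50 cm EC of its paired hole plus logit-scale noise.
#' Identical config and seed give byte-identical tables.
#'
#' @param floras Output of [simulate_succession_floras()].
#' @param config A [simulation_config()].
#' @return List with validated `plots` and `soil` tables.
#' @export
simulate_plot_survey <- function(floras, config) {
  taxa <- floras$taxa
  flora <- floras$flora
  strata <- expand.grid(site = c("early", "late"),
                        microtopo = c("microhigh", "microlow"),
                        stringsAsFactors = FALSE)
  layers <- depth_layers()
  prof <- config$ec_profile[layers]
  res <- with_local_seed(config$seed + 2L, {
    soil <- list(); plots <- list(); hole_counter <- 0L
    for (i in seq_len(nrow(strata))) {
      site <- strata$site[i]; micro <- strata$microtopo[i]
      is_high <- micro == "microhigh"
      n_holes <- config$holes_per_stratum
      hole_ids <- sprintf("%s_%s_h%02d", site, substr(micro, 6, 6),
                          seq_len(n_holes) + hole_counter)
      hole_counter <- hole_counter + n_holes
      hole_eff <- stats::rnorm(n_holes, 0, config$ec_hole_sd)
      ec3050 <- numeric(n_holes)
      for (h in seq_len(n_holes)) {
        mu <- log(prof) +
          (site == "late") * config$ec_site_offset +
          is_high * config$ec_microtopo_offset +
          hole_eff[h]
        ec <- exp(mu + stats::rnorm(length(layers), 0, config$ec_noise_sd))
        ec3050[h] <- ec[layers == "30-50"]
        soil[[length(soil) + 1L]] <- data.frame(
          hole_id = hole_ids[h], site = site, microtopo = micro,
          depth_top_cm = DEPTH_INTERVALS$top,
          depth_bottom_cm = DEPTH_INTERVALS$bottom,
          ec_dsm = round(ec, 3))
      }
      n_plots <- config$plots_per_stratum
      pool <- if (site == "early") flora$early else flora$late
      pool <- sort(pool)
      logodds <- config$microtopo_logodds
      if (is.null(names(logodds))) {
        logodds <- rep_len(logodds, length(pool)); names(logodds) <- pool
      }
      eta <- stats::qlogis(config$baseline_occupancy) +
        ifelse(is.na(logodds[pool]), 0, logodds[pool]) * is_high
      p_occ <- stats::plogis(eta)
      hole_of <- rep_len(seq_len(n_holes), n_plots)
      for (j in seq_len(n_plots)) {
        present <- pool[stats::runif(length(pool)) < p_occ]
        bare <- stats::plogis(config$bare_intercept +
                                config$bare_slope * ec3050[hole_of[j]] +
                                stats::rnorm(1, 0, config$bare_noise_sd))
        plots[[length(plots) + 1L]] <- data.frame(
          plot_id = sprintf("%s_%s_p%03d", site, substr(micro, 6, 6), j),
          site = site, microtopo = micro,
          bare_ground_pct = round(100 * bare, 1),
          litter_pct = 0,
          species = paste(present, collapse = ";"),
          tamarisk_small = 0L, tamarisk_medium = 0L, tamarisk_big = 0L,
          hole_id = hole_ids[hole_of[j]])
      }
    }
    list(soil = do.call(rbind, soil), plots = do.call(rbind, plots))
  })
  flora_taxa <- taxa[taxa$present_early | taxa$present_late, , drop = FALSE]
  list(plots = plot_table(res$plots, flora_taxa),
       soil = soil_table(res$soil))
}

#' Generate a complete synthetic study bundle
#'
#' Chains [simulate_yule_tree()], [simulate_succession_floras()] and
#' [simulate_plot_survey()] into a bundle shaped like the field inputs:
#' backbone tree, taxon table, plot table and soil table, all derived
#' deterministically from the config seed.
#'
#' @param config A [simulation_config()].
#' @return List with `tree`, `taxa`, `flora`, `plots`, `soil`, `config`.
#' @export
simulate_study_bundle <- function(config) {
  sim <- simulate_yule_tree(config$n_tips, config$seed, cuts = config$cuts)
  fl <- simulate_succession_floras(sim, config)
  survey <- simulate_plot_survey(fl, config)
  flora_taxa <- fl$taxa[fl$taxa$present_early | fl$taxa$present_late, ,
                        drop = FALSE]
  class(flora_taxa) <- c("succ_taxa", "data.frame")
  list(tree = sim$tree, taxa = flora_taxa, flora = fl$flora,
       plots = survey$plots, soil = survey$soil, config = config)
}
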