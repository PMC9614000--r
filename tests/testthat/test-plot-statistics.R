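test_that("prevalence counts exactly and is invariant to plot order", {
  b <- standin_bundle()
  p <- species_prevalence(b$plots, "Petrosimonia brachiata", "late",
                          "microhigh")
  expect_equal(p$count, 162); expect_equal(p$total, 180)
  expect_equal(p$fraction, 0.9, tolerance = 1e-12)
  f <- species_prevalence(b$plots, "Frankenia hirsuta", "late",
                          "microhigh")$fraction
  expect_equal(f, 5 / 180, tolerance = 1e-12)
  # absent species and empty strata
  expect_equal(species_prevalence(b$plots, "Senecio noeanus")$fraction, 0)
  only_late <- b$plots[b$plots$site == "late", ]
  expect_error(species_prevalence(only_late, "Frankenia hirsuta", "early"),
               "empty stratum")
  shuffled <- b$plots[rev(seq_len(nrow(b$plots))), ]
  expect_equal(
    species_prevalence(shuffled, "Frankenia hirsuta", "early")$fraction,
    species_prevalence(b$plots, "Frankenia hirsuta", "early")$fraction)
})

test_that("stratified Fisher tests match enumeration and call preference", {
  b <- standin_bundle()
  res <- stratified_fisher_tests(
    b$plots, list(site = "early", microtopo = "microhigh"),
    list(site = "early", microtopo = "microlow"), "Suaeda acuminata",
    m = 18)
  expect_equal(res$fraction_a, 0.01)
  expect_equal(res$fraction_b, 22 / 245, tolerance = 1e-12)
  # significant before but not after Bonferroni over the species table
  expect_lt(res$p, 0.05)
  expect_gt(res$p_corrected, 0.05)
  expect_equal(res$preferred, "n.s.")
  # Fisher p equals brute-force table enumeration for small margins
  taxa <- toy_taxa(c("Ga x", "Gb y"))
  for (ka in 0:3) for (kb in 0:3) {
    pl <- rbind(make_plots(c("Ga x" = ka, "Gb y" = 1), 3, microtopo =
                             "microhigh", taxa = taxa, prefix = "h"),
                make_plots(c("Ga x" = kb, "Gb y" = 2), 3, microtopo =
                             "microlow", taxa = taxa, prefix = "l"))
    got <- stratified_fisher_tests(pl, list(microtopo = "microhigh"),
                                   list(microtopo = "microlow"), "Ga x",
                                   correction = "none")
    want <- bf_fisher(ka, 3 - ka, kb, 3 - kb)
    if (ka + kb == 0) want <- 1
    expect_equal(got$p, want, tolerance = 1e-10)
  }
  # identical prevalence in both strata: p = 1, n.s.
  taxa2 <- toy_taxa("Ga x")
  same <- rbind(make_plots(c("Ga x" = 5), 10, microtopo = "microhigh",
                           taxa = taxa2, prefix = "h"),
                make_plots(c("Ga x" = 5), 10, microtopo = "microlow",
                           taxa = taxa2, prefix = "l"))
  eq <- stratified_fisher_tests(same, list(microtopo = "microhigh"),
                                list(microtopo = "microlow"), "Ga x")
  expect_equal(eq$p, 1)
  expect_equal(eq$preferred, "n.s.")
  # degenerate: absent from both strata
  deg <- stratified_fisher_tests(same, list(microtopo = "microhigh"),
                                 list(microtopo = "microlow"), "Gb y")
  expect_true(deg$degenerate)
  expect_equal(deg$p, 1)
})

test_that("Bonferroni correction scales and saturates correctly", {
  p <- c(0.001, 0.2, 1)
  corr <- halosucc:::bonferroni(p, 16)
  expect_equal(corr, c(0.016, 1, 1))
})

test_that("bare-ground group means and rank tests match the survey design", {
  b <- standin_bundle()
  early <- bare_ground_comparison(
    b$plots, list(site = "early", microtopo = "microhigh"),
    list(site = "early", microtopo = "microlow"))
  expect_equal(early$groups$mean_a, 16, tolerance = 0.01)
  expect_equal(early$groups$mean_b, 26, tolerance = 0.01)
  expect_lt(early$p_value, 1e-6)
  late <- bare_ground_comparison(
    b$plots, list(site = "late", microtopo = "microhigh"),
    list(site = "late", microtopo = "microlow"))
  expect_equal(late$groups$mean_a, 31, tolerance = 0.01)
  expect_equal(late$groups$mean_b, 25, tolerance = 0.01)
  expect_lt(late$p_value, 0.05)
  # two identical samples: p = 1
  taxa <- toy_taxa("Ga x")
  same <- plot_table(data.frame(
    plot_id = sprintf("p%d", 1:8), site = "early",
    microtopo = rep(c("microhigh", "microlow"), each = 4),
    bare_ground_pct = rep(c(5, 10, 15, 20), 2), species = "Ga x"), taxa)
  expect_equal(bare_ground_comparison(same, list(microtopo = "microhigh"),
                                      list(microtopo = "microlow"))$p_value,
               1)
})

test_that("Mann-Whitney p-values are invariant to monotone transforms", {
  b <- standin_bundle()
  tr <- b$plots
  tr$bare_ground_pct <- log1p(tr$bare_ground_pct)
  a <- bare_ground_comparison(b$plots, list(site = "early",
                                            microtopo = "microhigh"),
                              list(site = "early", microtopo = "microlow"))
  bb <- bare_ground_comparison(tr, list(site = "early",
                                        microtopo = "microhigh"),
                               list(site = "early", microtopo = "microlow"))
  expect_equal(a$p_value, bb$p_value, tolerance = 1e-12)
})

test_that("EC screen: exact small-sample p, perfect monotone r, pairing", {
  # perfectly monotone pairs give r = 1
  taxa <- toy_taxa("Ga x")
  plots <- plot_table(data.frame(
    plot_id = sprintf("p%d", 1:6), site = "early", microtopo = "microhigh",
    bare_ground_pct = c(5, 10, 20, 30, 40, 55), species = "Ga x",
    hole_id = sprintf("h%d", 1:6)), taxa)
  soil <- soil_table(data.frame(
    hole_id = sprintf("h%d", 1:6), site = "early", microtopo = "microhigh",
    depth_top_cm = 30, depth_bottom_cm = 50,
    ec_dsm = c(1, 2, 4, 8, 9, 12)))
  res <- ec_depth_correlation(plots, soil, "30-50")
  expect_equal(unname(res$statistic), 1)
  # n = 6 exact p equals full permutation enumeration of ranks
  soil$ec_dsm <- c(3, 1, 6, 2, 9, 5)
  res2 <- ec_depth_correlation(plots, soil, "30-50")
  perms <- combinat_perms(6)
  rho_obs <- stats::cor(rank(plots$bare_ground_pct), rank(soil$ec_dsm))
  rhos <- apply(perms, 1, function(pp)
    stats::cor(seq_len(6), pp))
  p_exact <- mean(abs(rhos) >= abs(rho_obs) - 1e-12)
  expect_equal(res2$p_value, p_exact, tolerance = 1e-10)
  # fewer than 3 matched pairs is refused
  expect_error(ec_depth_correlation(plots[1:2, ], soil, "30-50"),
               "fewer than 3")
  # the stand-in screen singles out the 30-50 cm layer
  b <- standin_bundle()
  scr <- ec_depth_correlation(b$plots, b$soil)
  expect_equal(scr$best$groups$layer, "30-50")
  expect_equal(unname(scr$best$statistic), 0.3, tolerance = 0.02)
})

test_that("trait enrichment compares persistent and lost species by season", {
  b <- standin_bundle()
  des <- trait_enrichment_test(b$flora, b$taxa, "desert", "spring")
  expect_equal(des$groups$fraction_late, 15 / 18, tolerance = 1e-12)
  expect_equal(des$groups$fraction_lost, 2 / 11, tolerance = 1e-12)
  expect_lt(des$p_value, 0.01)
  hal <- trait_enrichment_test(b$flora, b$taxa, "halophyte", "spring")
  expect_equal(hal$p_value, 1)
  expect_equal(hal$groups$fraction_late, 16 / 18, tolerance = 1e-12)
  # in autumn the desert signal disappears, the meadow deficit appears
  expect_gt(trait_enrichment_test(b$flora, b$taxa, "desert",
                                  "autumn")$p_value, 0.05)
  expect_lt(trait_enrichment_test(b$flora, b$taxa, "meadow",
                                  "autumn")$p_value, 0.05)
  # a trait true everywhere cannot discriminate
  taxa <- taxon_table(data.frame(
    species = sprintf("G%d sp", 1:6), genus = sprintf("G%d", 1:6),
    family = "F1", order = "O1",
    present_early = TRUE, present_late = c(TRUE, TRUE, TRUE, TRUE, FALSE,
                                           FALSE),
    season = "both", desert = TRUE, halophyte = NA, meadow = FALSE,
    c4 = FALSE))
  expect_equal(trait_enrichment_test(site_flora(taxa), taxa, "desert",
                                     "spring")$p_value, 1)
  expect_error(trait_enrichment_test(site_flora(taxa), taxa, "halophyte",
                                     "spring"), "undefined")
})

test_that("nurse-plant association detects co-occurrence with big tamarisk", {
  b <- standin_bundle()
  early <- b$plots[b$plots$site == "early", ]
  res <- nurse_plant_association(early, "Limonium scoparium")
  expect_equal(res$p_value, 0.0018, tolerance = 0.05)
  expect_equal(res$tail, "right")
  # degenerate cases flag and return p = 1
  deg <- nurse_plant_association(early, "Senecio noeanus")
  expect_true(deg$degenerate); expect_equal(deg$p_value, 1)
  no_var <- early; no_var$tamarisk_big <- 1L
  expect_true(nurse_plant_association(no_var,
                                      "Limonium scoparium")$degenerate)
  expect_error(nurse_plant_association(b$plots, "Limonium scoparium"),
               "early-site plots only")
})

test_that("strong nurse effects are detected across simulated surveys", {
  taxa <- toy_taxa("Ga x")
  detected <- 0
  for (s in 1:40) {
    set.seed(s)
    nurse <- rep(c(1L, 0L), each = 150)
    p0 <- 0.15
    p1 <- stats::plogis(stats::qlogis(p0) + log(5))  # odds ratio 5
    present <- stats::rbinom(300, 1, ifelse(nurse == 1, p1, p0))
    pl <- plot_table(data.frame(
      plot_id = sprintf("p%03d", 1:300), site = "early",
      microtopo = "microhigh", bare_ground_pct = 10,
      species = ifelse(present == 1, "Ga x", ""),
      tamarisk_big = nurse), taxa)
    if (nurse_plant_association(pl, "Ga x")$p_value < 0.05)
      detected <- detected + 1
  }
  expect_gte(detected, 36)  # at least 90% of seeds
})

test_that("lineage ratios count family and subfamily labels", {
  b <- standin_bundle()
  late <- lineage_ratio(b$flora$late, b$taxa, "Chenopodioideae",
                        "Asteraceae")
  early <- lineage_ratio(b$flora$early, b$taxa, "Chenopodioideae",
                         "Asteraceae")
  # the chenopod share doubles on the older site
  expect_equal(late$ratio, 1)
  expect_equal(early$ratio, 0.5)
  expect_equal(late$ratio / early$ratio, 2)
  fam <- lineage_ratio(b$flora$late, b$taxa, "Amaranthaceae", "Poaceae")
  expect_equal(fam$numerator_count, 6)
  expect_equal(fam$denominator_count, 3)
  eq <- lineage_ratio(b$flora$late, b$taxa, "Fabaceae", "Brassicaceae")
  expect_equal(eq$ratio, 1)
  expect_error(lineage_ratio(b$flora$acquired, b$taxa, "Amaranthaceae",
                             "Poaceae"), "zero species")
})

test_that("extinction randomness compares early prevalence of retained vs lost", {
  b <- standin_bundle()
  early <- b$plots[b$plots$site == "early", ]
  autumn <- b$taxa$species[b$taxa$season %in% c("autumn", "both")]
  res <- extinction_randomness_test(early,
                                    intersect(b$flora$shared, autumn),
                                    intersect(b$flora$lost, autumn))
  expect_gt(res$p_value, 0.05)
  expect_lt(res$p_value, 0.15)
  # identical prevalence vectors cannot favour the alternative
  taxa <- toy_taxa(c("Ga x", "Gb y", "Gc z", "Gd w"))
  pl <- make_plots(c("Ga x" = 3, "Gb y" = 6, "Gc z" = 3, "Gd w" = 6), 10,
                   taxa = taxa)
  eq <- extinction_randomness_test(pl, c("Ga x", "Gb y"),
                                   c("Gc z", "Gd w"))
  expect_gte(eq$p_value, 0.5)
  expect_error(extinction_randomness_test(pl[0, ], c("Ga x", "Gb y"),
                                          c("Gc z", "Gd w")), "no plots")
  expect_error(extinction_randomness_test(pl, "Ga x", c("Gc z", "Gd w")),
               "at least 2")
})

test_that("a prevalence shift is detected by the one-sided rank test", {
  detected <- 0
  n_plots <- 60
  for (s in 1:40) {
    set.seed(1000 + s)
    retained <- pmin(n_plots, round(n_plots * (runif(15, 0, 0.5) + 0.3)))
    lost <- round(n_plots * runif(10, 0, 0.5))
    names(retained) <- sprintf("Ga r%d", 1:15)
    names(lost) <- sprintf("Gb l%d", 1:10)
    counts <- c(retained, lost)
    taxa <- toy_taxa(names(counts))
    pl <- make_plots(counts, n_plots, taxa = taxa)
    res <- extinction_randomness_test(pl, names(retained), names(lost))
    if (res$p_value < 0.05) detected <- detected + 1
  }
  expect_gte(detected, 32)  # at least 80% of seeds
})
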