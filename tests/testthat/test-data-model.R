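test_that("species name normalization handles case, whitespace and aliases", {
  expect_equal(normalize_species_names("  halocnemum   STROBILACEUM "),
               "Halocnemum strobilaceum")
  expect_equal(normalize_species_names("Suaeda_acuminata"),
               "Suaeda acuminata")
  al <- data.frame(variant = "Halocnemum strobilacium",
                   canonical = "Halocnemum strobilaceum")
  expect_equal(normalize_species_names("halocnemum strobilacium", al),
               "Halocnemum strobilaceum")
  # no fuzzy matching: unknown variants pass through unchanged
  expect_equal(normalize_species_names("Halocnemum strobilaceus", al),
               "Halocnemum strobilaceus")
})

test_that("taxon table validation enforces its invariants", {
  base <- data.frame(species = "Suaeda acuminata", genus = "Suaeda",
                     family = "Amaranthaceae", order = "Caryophyllales",
                     present_early = TRUE, present_late = FALSE,
                     season = "both")
  expect_s3_class(taxon_table(base), "succ_taxa")
  bad_genus <- transform(base, genus = "Atriplex")
  expect_error(taxon_table(bad_genus), "first word")
  expect_error(taxon_table(rbind(base, base)), "duplicate")
  expect_error(taxon_table(transform(base, family = "")), "non-empty")
  expect_error(taxon_table(transform(base, present_early = FALSE)),
               "at least one site")
  expect_error(taxon_table(transform(base, season = "winter")), "season")
})

test_that("site flora partition identities hold for random presence patterns", {
  set.seed(7)
  for (i in 1:200) {
    n <- sample(3:40, 1)
    df <- data.frame(species = sprintf("G%02d sp", seq_len(n)),
                     genus = sprintf("G%02d", seq_len(n)),
                     family = "F1", order = "O1",
                     present_early = sample(c(TRUE, FALSE), n, TRUE),
                     present_late = sample(c(TRUE, FALSE), n, TRUE),
                     season = "both")
    df$present_early[!df$present_early & !df$present_late] <- TRUE
    fl <- site_flora(taxon_table(df))
    expect_length(intersect(fl$lost, fl$acquired), 0)
    expect_setequal(fl$shared, intersect(fl$early, fl$late))
    expect_equal(length(fl$early), length(fl$shared) + length(fl$lost))
    expect_equal(length(fl$late), length(fl$shared) + length(fl$acquired))
  }
})

test_that("plot and soil validation rejects malformed inputs", {
  taxa <- toy_taxa(c("Ga x", "Gb y"))
  ok <- data.frame(plot_id = "p1", site = "early", microtopo = "microhigh",
                   bare_ground_pct = 10, species = "Ga x")
  expect_s3_class(plot_table(ok, taxa), "succ_plots")
  expect_error(plot_table(ok[0, ], taxa), "no plots")
  expect_error(plot_table(transform(ok, species = "Gc z"), taxa),
               "not in the taxon table")
  expect_error(plot_table(transform(ok, microtopo = "slope"), taxa),
               "microhigh")
  expect_error(plot_table(transform(ok, bare_ground_pct = 120), taxa),
               "0, 100")
  soil_ok <- data.frame(hole_id = "h1", site = "early",
                        microtopo = "microlow", depth_top_cm = 30,
                        depth_bottom_cm = 50, ec_dsm = 11)
  expect_s3_class(soil_table(soil_ok), "succ_soil")
  expect_error(soil_table(transform(soil_ok, depth_bottom_cm = 40)),
               "depth interval")
  expect_error(soil_table(transform(soil_ok, ec_dsm = -1)), "non-negative")
})

test_that("newick io round-trips random trees and reports malformed input", {
  for (i in 1:200) {
    tree <- rand_coal_tree(sample(3:50, 1), seed = i)
    path <- tempfile(fileext = ".nwk")
    write_newick(tree, path)
    back <- read_newick(path)
    expect_setequal(back$tip.label, tree$tip.label)
    d0 <- bf_patristic(tree); d1 <- patristic_matrix(back)
    expect_lt(max(abs(d0 - d1[rownames(d0), colnames(d0)])), 1e-9)
  }
  bad <- tempfile(); writeLines("(A:1,B:1", bad)
  expect_error(read_newick(bad), "position")
  dup <- tempfile(); writeLines("(A:1,A:1);", dup)
  expect_error(read_newick(dup), "duplicate")
})

test_that("study tables round-trip through CSV and unify alias spellings", {
  b <- standin_bundle()
  dir <- tempfile()
  write_study_tables(list(taxa = b$taxa, plots = b$plots, soil = b$soil,
                          aliases = b$aliases, tree = b$backbone$tree),
                     dir)
  back <- read_study_tables(file.path(dir, "species.csv"),
                            file.path(dir, "plots.csv"),
                            file.path(dir, "soil.csv"),
                            file.path(dir, "aliases.csv"), quiet = TRUE)
  expect_equal(as.data.frame(back$taxa), as.data.frame(b$taxa))
  expect_equal(back$plots$species, b$plots$species)
  expect_equal(back$soil$ec_dsm, b$soil$ec_dsm)
  tree <- read_newick(file.path(dir, "tree.nwk"))
  expect_setequal(tree$tip.label, b$backbone$tree$tip.label)

  # a variant spelling in the species file collapses onto its canonical row
  sp <- utils::read.csv(file.path(dir, "species.csv"))
  variant <- sp[sp$species == "Halocnemum strobilaceum", ]
  variant$species <- "Halocnemum strobilacium"
  utils::write.csv(rbind(sp, variant), file.path(dir, "species2.csv"),
                   row.names = FALSE)
  expect_message(
    merged <- read_study_tables(file.path(dir, "species2.csv"),
                                file.path(dir, "plots.csv"),
                                file.path(dir, "soil.csv"),
                                file.path(dir, "aliases.csv")),
    "strobilaceum")
  expect_equal(nrow(merged$taxa), nrow(b$taxa))
})
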