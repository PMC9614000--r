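test_that("hypergeometric tails match closed form and enumeration", {
  # drawing all four acquisitions from a six-species family out of 31
  expect_equal(hypergeometric_tail(31, 6, 4, 4),
               choose(6, 4) / choose(31, 4), tolerance = 1e-12)
  expect_equal(hypergeometric_tail(10, 4, 3, 0), 1)
  expect_error(hypergeometric_tail(10, 4, 3, 5), "infeasible")
  set.seed(17)
  for (i in 1:60) {
    N <- sample(5:12, 1); K <- sample(0:N, 1); n <- sample(1:N, 1)
    lo <- max(0, n - (N - K)); hi <- min(n, K)
    k <- (lo:hi)[sample.int(hi - lo + 1, 1)]
    expect_equal(hypergeometric_tail(N, K, n, k, "right"),
                 bf_hyper_tail(N, K, n, k, "right"), tolerance = 1e-10)
    expect_equal(hypergeometric_tail(N, K, n, k, "left"),
                 bf_hyper_tail(N, K, n, k, "left"), tolerance = 1e-10)
    # left(k) + right(k) - P(X = k) = 1 exactly
    expect_equal(hypergeometric_tail(N, K, n, k, "left") +
                   hypergeometric_tail(N, K, n, k, "right") -
                   stats::dhyper(k, K, N - K, n), 1, tolerance = 1e-12)
  }
})

test_that("the right tail is non-increasing in the observed count", {
  for (N in c(8, 20, 31)) {
    K <- floor(N / 3); n <- floor(N / 2)
    lo <- max(0, n - (N - K)); hi <- min(n, K)
    p <- vapply(lo:hi, function(k) hypergeometric_tail(N, K, n, k),
                numeric(1))
    expect_true(all(diff(p) <= 1e-12))
  }
})

test_that("family loss tests behave on the stand-in flora and edge cases", {
  b <- standin_bundle()
  res <- family_loss_tests(b$flora, b$taxa)
  # no family lost significantly more than chance predicts
  expect_true(all(res$p_right > 0.05))
  expect_true(all(res$K > 0))
  expect_equal(res$p_bonferroni, pmin(1, nrow(res) * res$p_right))
  expect_true(!is.unsorted(res$p_right))
  # a flora whose losses all fall in one family
  taxa <- taxon_table(data.frame(
    species = sprintf("G%d sp", 1:8),
    genus = sprintf("G%d", 1:8),
    family = rep(c("FamA", "FamB"), each = 4),
    order = "O1",
    present_early = TRUE,
    present_late = c(FALSE, FALSE, FALSE, TRUE, rep(TRUE, 4)),
    season = "both"))
  fl <- site_flora(taxa)
  one <- family_loss_tests(fl, taxa)
  expect_equal(one$p_right[one$family == "FamA"],
               hypergeometric_tail(8, 4, 3, 3))
  bad <- fl; bad$lost <- c(bad$lost, "Zz nope")
  expect_error(family_loss_tests(bad, taxa), "subset")
})

test_that("the gain test reproduces the without-replacement probability", {
  b <- standin_bundle()
  res <- family_gain_test(b$flora$early, b$flora$acquired, b$taxa,
                          "Amaranthaceae")
  expect_equal(res$p_value, choose(6, 4) / choose(31, 4), tolerance = 1e-12)
  expect_equal(res$groups$N, 31)
  expect_equal(res$groups$K, 6)
  expect_equal(res$groups$k, 4)
  # binomial (with-replacement) variant behind the flag
  bin <- family_gain_test(b$flora$early, b$flora$acquired, b$taxa,
                          "Amaranthaceae", method = "binomial")
  expect_equal(bin$p_value, (6 / 31)^4, tolerance = 1e-12)
  # no gain in the family
  none <- family_gain_test(b$flora$early, b$flora$acquired, b$taxa,
                           "Poaceae")
  expect_equal(none$p_value, 1)
  # enumeration agreement on a small instance: N = 10, K = 5, n = 3, k = 2
  taxa <- taxon_table(data.frame(
    species = sprintf("G%d sp", 1:14), genus = sprintf("G%d", 1:14),
    family = c(rep("FamA", 5), rep("FamB", 5), "FamA", "FamA", "FamB",
               "FamC"),
    order = "O1",
    present_early = c(rep(TRUE, 10), rep(FALSE, 4)),
    present_late = TRUE, season = "both"))
  fl <- site_flora(taxa)
  small <- family_gain_test(fl$early, setdiff(fl$acquired, "G14 sp"),
                            taxa, "FamA")
  expect_equal(small$p_value, bf_hyper_tail(10, 5, 3, 2), tolerance = 1e-10)
  # a family absent from the early pool cannot host gains under this null
  expect_error(family_gain_test(fl$early, fl$acquired, taxa, "FamC"),
               "proportional null is undefined")
  expect_error(family_gain_test(fl$early, c(fl$acquired, fl$early[1]),
                                taxa, "FamA"), "absent from the early")
})

test_that("order overrepresentation uses the regional pool correctly", {
  reg <- standin_regional_families()
  expect_equal(nrow(reg), 42)
  expect_equal(length(unique(reg$order)), 22)
  b <- standin_bundle()
  site_fams <- sort(unique(b$taxa$family[b$taxa$present_early]))
  res <- order_overrepresentation_test(reg, site_fams, "Caryophyllales")
  expect_equal(res$p_value, choose(16, 7) / choose(42, 7),
               tolerance = 1e-12)
  expect_equal(res$groups$p_left +
                 res$p_value - stats::dhyper(res$groups$k, res$groups$K,
                                             res$groups$N - res$groups$K,
                                             res$groups$n), 1,
               tolerance = 1e-12)
  # k = 0: right tail is the whole support
  none <- order_overrepresentation_test(reg, c("Poaceae", "Asteraceae"),
                                        "Caryophyllales")
  expect_equal(none$p_value, 1)
  # a complete small order drawn by a large sample: matches enumeration
  small <- data.frame(family = sprintf("F%d", 1:8),
                      order = c("OA", "OA", "OA", rep("OB", 5)))
  full <- order_overrepresentation_test(small, sprintf("F%d", 1:4), "OA")
  expect_equal(full$p_value, bf_hyper_tail(8, 3, 4, 3), tolerance = 1e-10)
  expect_error(order_overrepresentation_test(reg, site_fams, "Rosales2"),
               "absent from the regional")
  expect_error(order_overrepresentation_test(small, "F99", "OA"),
               "missing from the regional")
})
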