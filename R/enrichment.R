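#' Exact hypergeometric tail probability
#'
#' For a pool of `N` items of which `K` belong to a category, and `n`
#' draws without replacement containing `k` category members: the right
#' tail is P(X >= k) and the left tail P(X <= k) under the hypergeometric
#' distribution.
#'
#' @param N Pool size.
#' @param K Category size within the pool.
#' @param n Number of draws.
#' @param k Observed category count among the draws.
#' @param tail `"right"` (enrichment, default) or `"left"` (depletion).
#' @return The exact tail probability.
#' @export
#' @examples
#' hypergeometric_tail(31, 6, 4, 4)  # choose(6,4)/choose(31,4)
hypergeometric_tail <- function(N, K, n, k, tail = c("right", "left")) {
  tail <- match.arg(tail)
  stopifnot(N >= 0, K >= 0, K <= N, n >= 0, n <= N)
  lo <- max(0, n - (N - K)); hi <- min(n, K)
  if (k < lo || k > hi)
    stop("infeasible count k = ", k, " (support is [", lo, ", ", hi, "])")
  if (tail == "right")
    stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  else
    stats::phyper(k, K, N - K, n)
}

#' Hypergeometric test for family-level species loss
#'
#' For every family represented at the early site, the probability of
#' losing at least the observed number of species under random loss: with
#' `N` early-site species of which `K` belong to the family, and `n` lost
#' species of which `k` are in the family, the right-tail hypergeometric
#' p-value. Families with no early-site species are excluded. Reported
#' uncorrected (the conclusion is drawn from raw values), with a
#' Bonferroni column added for transparency.
#'
#' @param flora A `site_flora` object.
#' @param taxa Taxon table assigning each species one family.
#' @return Data frame (family, N, K, n, k, p_right, p_left, p_bonferroni)
#'   sorted by `p_right`.
#' @export
family_loss_tests <- function(flora, taxa) {
  early <- flora$early; lost <- flora$lost
  if (length(setdiff(lost, early)))
    stop("lost set must be a subset of the early flora")
  fam <- taxa$family[match(early, taxa$species)]
  if (anyNA(fam)) stop("early species missing from the taxon table")
  fams <- sort(unique(fam))
  N <- length(early); n <- length(lost)
  res <- do.call(rbind, lapply(fams, function(fm) {
    K <- sum(fam == fm)
    k <- sum(taxa$family[match(lost, taxa$species)] == fm)
    data.frame(family = fm, N = N, K = K, n = n, k = k,
               p_right = hypergeometric_tail(N, K, n, k, "right"),
               p_left = hypergeometric_tail(N, K, n, k, "left"))
  }))
  res$p_bonferroni <- bonferroni(res$p_right, nrow(res))
  res[order(res$p_right, res$family), ]
}

#' Hypergeometric test for clade-clustered species gain
#'
#' Probability that at least `k` of the `n` species acquired by the late
#' site fall in one focal family, when acquisition is modelled as drawing
#' without replacement from the early-site species pool (each family's
#' chance proportional to its share of the early flora). A with-replacement
#' binomial variant is available behind `method = "binomial"`.
#'
#' @param early_flora Character vector of early-site species.
#' @param acquired Character vector of species acquired by the late site
#'   (disjoint from `early_flora`).
#' @param taxa Taxon table.
#' @param family Focal family name.
#' @param method `"hypergeometric"` (default) or `"binomial"`.
#' @return A `succ_test` with the right-tail p-value and the N/K/n/k
#'   counts in `groups`.
#' @export
family_gain_test <- function(early_flora, acquired, taxa, family,
                             method = c("hypergeometric", "binomial")) {
  method <- match.arg(method)
  if (length(intersect(early_flora, acquired)))
    stop("acquired species must be absent from the early flora")
  fam_of <- function(sp) taxa$family[match(sp, taxa$species)]
  N <- length(early_flora)
  K <- sum(fam_of(early_flora) == family, na.rm = TRUE)
  n <- length(acquired)
  k <- sum(fam_of(acquired) == family, na.rm = TRUE)
  if (K == 0 && k > 0)
    stop("family ", family, " absent from the early flora but present ",
         "among acquisitions; the proportional null is undefined")
  p <- if (method == "hypergeometric")
    hypergeometric_tail(N, K, n, k, "right")
  else
    stats::pbinom(k - 1, n, K / N, lower.tail = FALSE)
  test_result(paste0("family gain (", method, ")"),
              statistic = k, p_value = p, tail = "right",
              groups = list(N = N, K = K, n = n, k = k, family = family))
}

#' Hypergeometric test for order overrepresentation among site families
#'
#' Whether the families present at a site contain more families of a focal
#' order than expected if site families were a uniform draw from the
#' regional family pool. The overrepresentation (right) tail is the
#' headline p-value; the left tail is also computed so either convention
#' can be checked.
#'
#' @param regional_families Data frame with columns `family`, `order`:
#'   the regional pool.
#' @param site_families Character vector of families recorded at the site
#'   (must be a subset of the regional pool).
#' @param order Focal order name.
#' @return A `succ_test`; `groups` holds N/K/n/k and the left tail.
#' @export
order_overrepresentation_test <- function(regional_families, site_families,
                                          order) {
  if (!order %in% regional_families$order)
    stop("order ", order, " absent from the regional family list")
  site_families <- unique(site_families)
  outside <- setdiff(site_families, regional_families$family)
  if (length(outside))
    stop("site families missing from the regional list: ",
         paste(outside, collapse = ", "))
  in_order <- regional_families$family[regional_families$order == order]
  N <- length(unique(regional_families$family))
  K <- length(unique(in_order))
  n <- length(site_families)
  k <- length(intersect(site_families, in_order))
  p_right <- hypergeometric_tail(N, K, n, k, "right")
  p_left <- hypergeometric_tail(N, K, n, k, "left")
  test_result("order overrepresentation", statistic = k, p_value = p_right,
              tail = "right",
              groups = list(N = N, K = K, n = n, k = k, order = order,
                            p_left = p_left),
              note = "both tails computed; right tail is overrepresentation")
}
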