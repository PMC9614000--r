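# Run an expression under a local, seeded RNG state, restoring the
# caller's state afterwards. Keeps pipeline results reproducible without
# clobbering the session RNG.
with_local_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

#' Permutation null distribution for MPD
#'
#' Draws `n_perm` uniform random subsets of size `|focal|` from the species
#' pool (without replacement within each draw), computes their MPD, and
#' compares the observed focal MPD against this null. The left tail
#' p-value, `(#\{null <= observed\} + 1) / (n_perm + 1)`, is the probability
#' of an MPD as low as or lower than observed under random membership, i.e.
#' the evidence for phylogenetic clustering; the right tail is the
#' analogous overdispersion probability. The add-one rule keeps Monte-Carlo
#' p-values inside (0, 1].
#'
#' @param dist Patristic distance matrix.
#' @param focal Focal species set (at least 2, strict subset of `pool`).
#' @param pool Null pool of candidate species; an explicit, logged
#'   parameter rather than an implied community.
#' @param n_perm Number of permutations (default 10000).
#' @param seed Integer seed; mandatory so pipeline runs are reproducible.
#' @param strict If `TRUE` (default), refuse fewer than 100 permutations.
#' @return Object of class `perm_test`: observed MPD, the null sample,
#'   null mean, both tail p-values, pool, seed.
#' @export
mpd_permutation_test <- function(dist, focal, pool, n_perm = 10000, seed,
                                 strict = TRUE) {
  focal <- unique(focal); pool <- unique(pool)
  if (length(focal) < 2) stop("focal set must contain at least 2 species")
  if (!all(focal %in% pool))
    stop("focal set must be a subset of the pool; offenders: ",
         paste(setdiff(focal, pool), collapse = ", "))
  if (!all(pool %in% rownames(dist)))
    stop("pool species missing from the distance matrix: ",
         paste(setdiff(pool, rownames(dist)), collapse = ", "))
  if (length(pool) <= length(focal))
    stop("pool must be strictly larger than the focal set")
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  if (strict && n_perm < 100)
    stop("fewer than 100 permutations refused in strict mode")
  D <- dist[pool, pool]
  k <- length(focal)
  obs <- mpd(dist, focal)$value
  denom <- k * (k - 1)
  null <- with_local_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      s <- sample.int(length(pool), k)
      sum(D[s, s]) / denom
    }, numeric(1))
  })
  p_left <- (sum(null <= obs) + 1) / (n_perm + 1)
  p_right <- (sum(null >= obs) + 1) / (n_perm + 1)
  structure(list(observed = obs, null = null, null_mean = mean(null),
                 n_perm = n_perm, pool = pool, focal = focal, seed = seed,
                 p_left = p_left, p_right = p_right),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat("MPD permutation test: observed =", format(x$observed, digits = 5),
      "| null mean =", format(x$null_mean, digits = 5),
      "| n_perm =", x$n_perm, "\n")
  cat("  p(left, clustering) =", format(x$p_left, digits = 4),
      " p(right, overdispersion) =", format(x$p_right, digits = 4),
      " pool size =", length(x$pool), "\n")
  invisible(x)
}

#' Summarize a permutation test as a JSON-ready list
#'
#' @param x A `perm_test` object.
#' @return Named list (observed, null_mean, p_left, p_right, n_perm,
#'   seed, pool_size).
#' @export
perm_test_summary <- function(x) {
  list(observed = x$observed, null_mean = x$null_mean,
       p_left = x$p_left, p_right = x$p_right,
       n_perm = x$n_perm, seed = x$seed, pool_size = length(x$pool))
}

#' Export the null sample for histogram plotting
#'
#' @param x A `perm_test` object.
#' @param path Output path of the one-column CSV.
#' @export
write_null_sample <- function(x, path) {
  utils::write.csv(data.frame(mpd_null = x$null), path, row.names = FALSE)
  invisible(path)
}
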