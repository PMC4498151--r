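# Empirical calibration of the shared-causal-variant prior p12: pick the
# grid value at which the posterior expectation of colocalisation, averaged
# over pairwise analyses with evidence of association for both traits, most
# closely matches the prior expectation.

#' Relative prior support for a shared causal variant
#'
#' `P4 / (P3 + P4)` from [hypothesis_priors()]: the prior probability that,
#' given causal variants exist for both traits in a region of `Q` SNPs, they
#' are the same variant. Strictly decreasing in `Q` and increasing in `p12`.
#'
#' @param Q Number of SNPs in the region (>= 2).
#' @param priors A [coloc_priors()] object.
#' @return The prior fraction in (0, 1).
#' @export
prior_h4_fraction <- function(Q, priors = coloc_priors()) {
  if (Q < 2) stop("prior_h4_fraction: Q must be >= 2 (P3 = 0 at Q = 1)")
  hp <- hypothesis_priors(Q, priors)
  hp$P4 / (hp$P3 + hp$P4)
}

#' Calibrate p12 by matching prior and posterior colocalisation support
#'
#' For each candidate `p12` on the grid, the colocalisation posteriors must
#' have been recomputed with that prior on identical data (see
#' [coloc_over_grid()]). Pairs with `PP3 + PP4 > threshold` at that grid
#' value are included (the inclusion mask is recomputed per grid value), and
#' the mean posterior fraction `PP4/(PP3 + PP4)` is compared with the mean
#' prior fraction `P4/(P3 + P4)` over the same pairs, each pairwise analysis
#' weighted equally. The chosen `p12` minimises the absolute difference;
#' ties go to the smaller value.
#'
#' @param pair_results Named list, one element per grid value (names =
#'   `format(grid)` order respected), each a list of `coloc_result` objects
#'   computed at that `p12`.
#' @param grid Candidate `p12` values (default `c(1e-7, 1e-6, 1e-5)`).
#' @param threshold Inclusion threshold on `PP3 + PP4` (default 0.8).
#' @param p1,p2 Per-trait priors held fixed across the grid.
#' @return An object of class `calibration_result`: `grid`, `prior_mean`,
#'   `posterior_mean`, `n_included`, `gap`, `chosen_p12`,
#'   `inclusion_threshold`, and `curves` (per-pair data.frame of `p12`, `Q`,
#'   `prior_fraction`, `posterior_fraction` for plotting).
#' @export
calibrate_p12 <- function(pair_results, grid = c(1e-7, 1e-6, 1e-5),
                          threshold = 0.8, p1 = 1e-4, p2 = 1e-4) {
  stopifnot(is.list(pair_results))
  if (length(pair_results) != length(grid)) {
    stop("calibrate_p12: one result collection required per grid value")
  }
  ord <- order(grid)
  grid <- grid[ord]
  pair_results <- pair_results[ord]

  prior_mean <- posterior_mean <- gap <- rep(NA_real_, length(grid))
  n_included <- integer(length(grid))
  curves <- list()
  for (g in seq_along(grid)) {
    pri <- coloc_priors(p1 = p1, p2 = p2, p12 = grid[g])
    results <- pair_results[[g]]
    pp34 <- vapply(results, function(r) r$pp3_plus_pp4, numeric(1))
    include <- pp34 > threshold
    n_included[g] <- sum(include)
    if (n_included[g] == 0L) {
      warning(sprintf("no pairs pass PP3+PP4 > %g at p12 = %g; grid value excluded",
                      threshold, grid[g]))
      next
    }
    inc <- results[include]
    post_frac <- vapply(inc, function(r) r$PP4 / (r$PP3 + r$PP4), numeric(1))
    pri_frac <- vapply(inc, function(r) prior_h4_fraction(r$Q, pri), numeric(1))
    posterior_mean[g] <- mean(post_frac)
    prior_mean[g] <- mean(pri_frac)
    gap[g] <- abs(posterior_mean[g] - prior_mean[g])
    curves[[g]] <- data.frame(
      p12 = grid[g],
      Q = vapply(inc, function(r) r$Q, numeric(1)),
      prior_fraction = pri_frac,
      posterior_fraction = post_frac
    )
  }
  if (all(is.na(gap))) {
    stop("calibrate_p12: no grid value has any pair passing the threshold")
  }
  chosen <- grid[which.min(gap)]  # which.min skips NA; ties -> smaller p12
  structure(
    list(grid = grid, prior_mean = prior_mean, posterior_mean = posterior_mean,
         n_included = n_included, gap = gap, chosen_p12 = chosen,
         inclusion_threshold = threshold,
         curves = do.call(rbind, curves)),
    class = "calibration_result"
  )
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("p12 calibration:\n")
  for (g in seq_along(x$grid)) {
    cat(sprintf("  p12 = %-8g prior %.4f  posterior %.4f  gap %.4f  (n = %d)\n",
                x$grid[g], x$prior_mean[g], x$posterior_mean[g], x$gap[g],
                x$n_included[g]))
  }
  cat(sprintf("  chosen p12 = %g\n", x$chosen_p12))
  invisible(x)
}

#' Recompute colocalisation posteriors across a p12 grid
#'
#' Per-SNP log Bayes factors do not depend on the priors, so a grid sweep
#' reuses them and only the hypothesis weights are recomputed. Produces the
#' `pair_results` structure consumed by [calibrate_p12()].
#'
#' @param pairs List of pairs, each a list with elements `labf1`, `labf2`
#'   (and optionally `Q`-consistent metadata passed to
#'   [coloc_posteriors()]).
#' @param grid Candidate `p12` values.
#' @param p1,p2 Per-trait priors held fixed.
#' @return Named list over grid values, each a list of `coloc_result`.
#' @export
coloc_over_grid <- function(pairs, grid = c(1e-7, 1e-6, 1e-5),
                            p1 = 1e-4, p2 = 1e-4) {
  stopifnot(is.list(pairs))
  out <- lapply(grid, function(p12) {
    pri <- coloc_priors(p1 = p1, p2 = p2, p12 = p12)
    lapply(pairs, function(pr) coloc_posteriors(pr$labf1, pr$labf2, pri))
  })
  names(out) <- format(grid)
  out
}
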