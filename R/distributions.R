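# Sampling distributions for probabilistic sensitivity analysis.
#
# The sensitivity range of each estimate is read as a 95% interval, so the
# implied standard deviation is (high - low) / (2 * 1.96). Probabilities get a
# beta distribution matched by the method of moments; costs a normal truncated
# at zero; a zero-width range collapses to a point mass.

#' Fit a sampling distribution to a parameter estimate
#'
#' @param baseline Central estimate (the distribution mean).
#' @param low,high Endpoints of the sensitivity range, read as a 95% interval:
#'   sd = (high - low) / 3.92.
#' @param kind `"probability"` (beta via method of moments), `"cost"` (normal
#'   truncated at 0), or `"count"` (always a point mass).
#' @return A `captree_dist` list with `family` (`"beta"`, `"normal"` or
#'   `"point"`), `mean`, `sd`, and for a beta the shapes `shape1`, `shape2`.
#' @export
fit_distribution <- function(baseline, low, high, kind) {
  if (low > baseline || baseline > high) {
    stop("baseline must lie in [low, high]", call. = FALSE)
  }
  sd <- (high - low) / (2 * stats::qnorm(0.975))
  if (high == low || kind == "count") {
    spec <- list(family = "point", mean = baseline, sd = 0)
  } else if (kind == "probability") {
    v <- sd^2
    if (v >= baseline * (1 - baseline)) {
      stop("beta method of moments infeasible for mean ", baseline,
           ", sd ", signif(sd, 4),
           ": variance must be < mean*(1-mean); reduce the range",
           call. = FALSE)
    }
    nu <- baseline * (1 - baseline) / v - 1
    spec <- list(family = "beta", mean = baseline, sd = sd,
                 shape1 = baseline * nu, shape2 = (1 - baseline) * nu)
  } else if (kind == "cost") {
    spec <- list(family = "normal", mean = baseline, sd = sd)
  } else {
    stop("unknown parameter kind: ", kind, call. = FALSE)
  }
  class(spec) <- "captree_dist"
  spec
}

#' Sample from a fitted distribution
#'
#' Draws from the current R random stream (seed the caller). Truncation of the
#' normal at zero is by resampling; for the bundled cost estimates zero is
#' nearly four standard deviations below the mean, so the truncation is
#' negligible and the sampled mean stays at the baseline.
#'
#' @param spec A `captree_dist` from [fit_distribution()].
#' @param n Number of samples.
#' @return Numeric vector of length `n`.
#' @export
sample_distribution <- function(spec, n) {
  switch(spec$family,
    point = rep(spec$mean, n),
    beta = stats::rbeta(n, spec$shape1, spec$shape2),
    normal = {
      x <- stats::rnorm(n, spec$mean, spec$sd)
      while (any(neg <- x < 0)) {
        x[neg] <- stats::rnorm(sum(neg), spec$mean, spec$sd)
      }
      x
    },
    stop("unknown distribution family: ", spec$family)
  )
}

# Fit distributions for every uncertain estimate in a parameter set.
# Returns a list keyed by "id" or "id/band".
fit_all_distributions <- function(params) {
  est <- params$estimates
  keys <- ifelse(est$age_band == "", est$id,
                 paste(est$id, est$age_band, sep = "/"))
  specs <- lapply(seq_len(nrow(est)), function(i) {
    fit_distribution(est$baseline[i], est$low[i], est$high[i], est$kind[i])
  })
  stats::setNames(specs, keys)
}
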