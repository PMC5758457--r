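# Probabilistic sensitivity analysis: parameter-level Monte Carlo.
#
# Each run draws every uncertain parameter independently from its fitted
# distribution (beta for probabilities, zero-truncated normal for costs),
# evaluates the closed-form tree for both strategies and all age bands, and
# summarizes each outcome with its Monte Carlo mean and percentile 95%
# credibility interval (empirical 2.5th/97.5th quantiles, linear
# interpolation). Note that for nonlinear outcomes the Monte Carlo mean need
# not equal the evaluation at the baseline parameters.

psa_outcomes <- function() {
  c("soc_pregnancy", "csti_pregnancy", "d_pregnancy",
    "soc_live_birth", "csti_live_birth", "d_live_birth",
    "soc_cost_iui", "csti_cost_iui", "d_cost_iui",
    "soc_cost_ivf", "csti_cost_ivf", "d_cost_ivf",
    "soc_cost_total", "csti_cost_total", "d_cost_total")
}

#' Sample one parameter draw
#'
#' Independent sample of every uncertain parameter from its fitted
#' distribution; point-mass parameters (including the cycle caps) pass through
#' at their baseline. Consumes the current R random stream.
#'
#' @param params A `captree_parameters` object.
#' @param specs Optional precomputed result of the internal distribution
#'   fitting (recomputed if `NULL`).
#' @return A `captree_draw` list, same shape as [baseline_draw()].
#' @export
sample_draw <- function(params, specs = NULL) {
  if (is.null(specs)) specs <- fit_all_distributions(params)
  draw <- baseline_draw(params)
  one <- function(key) sample_distribution(specs[[key]], 1)
  draw$c_iui <- one("c_iui")
  draw$c_ivf <- one("c_ivf")
  draw$p_low_cs <- one("p_low_cs")
  draw$p_tiui <- one("p_tiui")
  for (band in age_bands()) {
    draw$p_iui[[band]] <- one(paste0("p_iui/", band))
    draw$p_ivf[[band]] <- one(paste0("p_ivf/", band))
    draw$l_iui[[band]] <- one(paste0("l_iui/", band))
    draw$l_ivf[[band]] <- one(paste0("l_ivf/", band))
  }
  draw
}

# Sample n draws of every parameter as a list of numeric vectors keyed like
# fit_all_distributions(); sampling order is the estimates-table row order.
sample_draw_matrix <- function(params, n, specs = NULL) {
  if (is.null(specs)) specs <- fit_all_distributions(params)
  lapply(specs, sample_distribution, n = n)
}

#' Run a probabilistic sensitivity analysis
#'
#' @param params A `captree_parameters` object.
#' @param n_draws Number of Monte Carlo runs (>= 2); 10,000 is the
#'   conventional choice.
#' @param seed Integer seed; the whole analysis is reproducible from it.
#' @return A `captree_psa` object: `summary` (data.frame with `outcome`,
#'   `age`, `mean`, `lo`, `hi`, and `baseline` — the closed-form evaluation at
#'   baseline parameters, labelled separately from the Monte Carlo mean),
#'   `draws` (the n_draws x parameter matrix, retained for audit), `values`
#'   (per-draw outcome array), `n_draws`, `seed`.
#' @export
run_psa <- function(params, n_draws, seed) {
  if (length(n_draws) != 1 || is.na(n_draws) || n_draws < 2) {
    stop("n_draws must be >= 2", call. = FALSE)
  }
  n_draws <- as.integer(n_draws)
  set.seed(seed)
  specs <- fit_all_distributions(params)
  par <- sample_draw_matrix(params, n_draws, specs)

  bands <- age_bands()
  outs <- psa_outcomes()
  values <- array(NA_real_, dim = c(n_draws, length(outs), length(bands)),
                  dimnames = list(NULL, outs, bands))
  for (band in bands) {
    soc <- strategy_outcome_core(
      "SOC", p_iui = par[[paste0("p_iui/", band)]], p_tiui = par[["p_tiui"]],
      p_ivf = par[[paste0("p_ivf/", band)]],
      l_iui = par[[paste0("l_iui/", band)]],
      l_ivf = par[[paste0("l_ivf/", band)]],
      p_low_cs = par[["p_low_cs"]], c_iui = par[["c_iui"]],
      c_ivf = par[["c_ivf"]], n_iui = params$n_iui, n_ivf = params$n_ivf)
    csti <- strategy_outcome_core(
      "CS-TI", p_iui = par[[paste0("p_iui/", band)]], p_tiui = par[["p_tiui"]],
      p_ivf = par[[paste0("p_ivf/", band)]],
      l_iui = par[[paste0("l_iui/", band)]],
      l_ivf = par[[paste0("l_ivf/", band)]],
      p_low_cs = par[["p_low_cs"]], c_iui = par[["c_iui"]],
      c_ivf = par[["c_ivf"]], n_iui = params$n_iui, n_ivf = params$n_ivf)
    values[, , band] <- cbind(
      soc$cum_pregnancy, csti$cum_pregnancy,
      csti$cum_pregnancy - soc$cum_pregnancy,
      soc$cum_live_birth, csti$cum_live_birth,
      csti$cum_live_birth - soc$cum_live_birth,
      soc$cost_iui, csti$cost_iui, csti$cost_iui - soc$cost_iui,
      soc$cost_ivf, csti$cost_ivf, csti$cost_ivf - soc$cost_ivf,
      soc$cost_total, csti$cost_total, csti$cost_total - soc$cost_total)
  }

  base <- baseline_tables(params)
  summary <- do.call(rbind, lapply(bands, function(band) {
    do.call(rbind, lapply(outs, function(o) {
      v <- values[, o, band]
      q <- stats::quantile(v, c(0.025, 0.975), names = FALSE, type = 7)
      src <- if (o %in% names(base$rates)) base$rates else base$costs
      data.frame(outcome = o, age = band, mean = mean(v),
                 lo = q[1], hi = q[2],
                 baseline = src[src$age == band, o],
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(summary) <- NULL
  res <- list(summary = summary,
              draws = do.call(cbind, par),
              values = values, n_draws = n_draws, seed = seed)
  class(res) <- "captree_psa"
  res
}

#' @export
print.captree_psa <- function(x, ...) {
  cat("Probabilistic sensitivity analysis:", x$n_draws, "draws, seed",
      x$seed, "\n")
  print(utils::head(x$summary, 15), ...)
  invisible(x)
}
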