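# Closed-form evaluation of the treatment decision tree.
#
# Both strategies are capped sequences of independent Bernoulli cycles with a
# constant per-cycle conception probability within each modality:
#
#   SOC:   up to n_iui IUI cycles at p_iui[age], then (if no conception) up to
#          n_ivf IVF-ICSI cycles at p_ivf[age].
#   CS-TI: with probability p_low_cs (low Cap-Score) straight to n_ivf IVF
#          cycles; otherwise n_iui timed-IUI cycles at p_tiui (age-independent)
#          then n_ivf IVF cycles.
#
# Live birth is Bernoulli conditional on clinical pregnancy, with the
# conceiving modality's age-banded probability (timed IUI uses the IUI one).
# Costs are unit cost times expected cycles attempted; couples who never
# conceive consume every cycle. The Cap-Score test itself is unpriced and
# contributes no cost.
#
# Expected attempts for a capped geometric sequence: E[attempts] =
# sum_{k=0}^{n-1} (1-p)^k = (1 - (1-p)^n) / p, with the p = 0 limit equal to n.

strategies <- function() c("SOC", "CS-TI")

# (1 - (1-p)^n) / p, vectorized in p, with the p -> 0 limit.
geom_series <- function(p, n) {
  out <- ifelse(p == 0, n, (1 - (1 - p)^n) / p)
  out
}

check_age <- function(age) {
  if (length(age) != 1 || !age %in% age_bands()) {
    stop("unknown age band: ", paste(age, collapse = ","),
         " (expected one of ", paste(age_bands(), collapse = ", "), ")",
         call. = FALSE)
  }
  age
}

check_strategy <- function(strategy) {
  if (length(strategy) != 1 || !strategy %in% strategies()) {
    stop("unknown strategy: ", paste(strategy, collapse = ","),
         " (expected SOC or CS-TI)", call. = FALSE)
  }
  strategy
}

# Vectorized core: every argument except n_iui/n_ivf may be a vector (PSA
# passes one element per Monte Carlo draw). Returns a list of vectors.
strategy_outcome_core <- function(strategy, p_iui, p_tiui, p_ivf,
                                  l_iui, l_ivf, p_low_cs,
                                  c_iui, c_ivf, n_iui, n_ivf) {
  s_ivf <- (1 - p_ivf)^n_ivf
  e_ivf_series <- geom_series(p_ivf, n_ivf)
  if (strategy == "SOC") {
    s_iui <- (1 - p_iui)^n_iui
    via_iui <- 1 - s_iui
    via_tiui <- 0 * via_iui
    via_ivf <- s_iui * (1 - s_ivf)
    e_iui <- geom_series(p_iui, n_iui)
    e_ivf <- s_iui * e_ivf_series
  } else {
    s_tiui <- (1 - p_tiui)^n_iui
    via_iui <- 0 * p_ivf
    via_tiui <- (1 - p_low_cs) * (1 - s_tiui)
    via_ivf <- (p_low_cs + (1 - p_low_cs) * s_tiui) * (1 - s_ivf)
    e_iui <- (1 - p_low_cs) * geom_series(p_tiui, n_iui)
    e_ivf <- (p_low_cs + (1 - p_low_cs) * s_tiui) * e_ivf_series
  }
  cum_preg <- via_iui + via_tiui + via_ivf
  cum_lb <- (via_iui + via_tiui) * l_iui + via_ivf * l_ivf
  cost_iui <- c_iui * e_iui
  cost_ivf <- c_ivf * e_ivf
  list(
    cum_pregnancy = cum_preg, cum_live_birth = cum_lb,
    preg_via_iui = via_iui, preg_via_tiui = via_tiui, preg_via_ivf = via_ivf,
    e_iui_cycles = e_iui, e_ivf_cycles = e_ivf,
    cost_iui = cost_iui, cost_ivf = cost_ivf,
    cost_total = cost_iui + cost_ivf
  )
}

core_for <- function(strategy, draw, age) {
  strategy_outcome_core(
    strategy,
    p_iui = draw$p_iui[[age]], p_tiui = draw$p_tiui,
    p_ivf = draw$p_ivf[[age]],
    l_iui = draw$l_iui[[age]], l_ivf = draw$l_ivf[[age]],
    p_low_cs = draw$p_low_cs,
    c_iui = draw$c_iui, c_ivf = draw$c_ivf,
    n_iui = draw$n_iui, n_ivf = draw$n_ivf
  )
}

#' Cumulative clinical pregnancy probability
#'
#' Probability of at least one clinical pregnancy over the full treatment
#' pathway. Closed forms (q = 1 - p per cycle): for SOC,
#' 1 - q_iui^n_iui * q_ivf^n_ivf; for CS-TI the mixture over the Cap-Score
#' branch, p_low_cs * (1 - q_ivf^n_ivf) +
#' (1 - p_low_cs) * (1 - q_tiui^n_iui * q_ivf^n_ivf).
#'
#' @param strategy `"SOC"` or `"CS-TI"`.
#' @param draw A `captree_draw` (see [baseline_draw()], [sample_draw()]).
#' @param age One of [age_bands()].
#' @return Probability in `[0, 1]`.
#' @export
cumulative_pregnancy <- function(strategy, draw, age) {
  check_strategy(strategy); check_age(age); validate_draw(draw)
  core_for(strategy, draw, age)$cum_pregnancy
}

#' Probability of conceiving by each modality
#'
#' Decomposes the cumulative pregnancy probability into the mass conceiving
#' via standard IUI, via timed IUI (after a normal Cap-Score), and via
#' IVF-ICSI. The three components always sum to [cumulative_pregnancy()].
#'
#' @inheritParams cumulative_pregnancy
#' @return Named numeric vector `preg_via_iui`, `preg_via_tiui`, `preg_via_ivf`.
#' @export
modality_split <- function(strategy, draw, age) {
  check_strategy(strategy); check_age(age); validate_draw(draw)
  out <- core_for(strategy, draw, age)
  c(preg_via_iui = out$preg_via_iui, preg_via_tiui = out$preg_via_tiui,
    preg_via_ivf = out$preg_via_ivf)
}

#' Cumulative live-birth probability
#'
#' Weights each conceiving modality by its age-banded live-birth probability
#' conditional on clinical pregnancy; timed-IUI conceptions use the IUI
#' live-birth probability.
#'
#' @inheritParams cumulative_pregnancy
#' @return Probability in `[0, 1]`.
#' @export
cumulative_live_birth <- function(strategy, draw, age) {
  check_strategy(strategy); check_age(age); validate_draw(draw)
  core_for(strategy, draw, age)$cum_live_birth
}

#' Expected number of treatment cycles
#'
#' Expected IUI (or timed-IUI) and IVF-ICSI cycles attempted, counting cycles
#' until conception or until the cap. IVF attempts are weighted by the
#' probability of reaching the IVF stage.
#'
#' @inheritParams cumulative_pregnancy
#' @return Named numeric vector `e_iui_cycles`, `e_ivf_cycles`.
#' @export
expected_cycle_counts <- function(strategy, draw, age) {
  check_strategy(strategy); check_age(age); validate_draw(draw)
  out <- core_for(strategy, draw, age)
  c(e_iui_cycles = out$e_iui_cycles, e_ivf_cycles = out$e_ivf_cycles)
}

#' Expected treatment costs
#'
#' Unit cost times expected cycles, per modality; the Cap-Score test carries
#' no cost (no price has been set for it).
#'
#' @inheritParams cumulative_pregnancy
#' @return Named numeric vector `cost_iui`, `cost_ivf`, `cost_total` (USD).
#' @export
strategy_costs <- function(strategy, draw, age) {
  check_strategy(strategy); check_age(age); validate_draw(draw)
  out <- core_for(strategy, draw, age)
  c(cost_iui = out$cost_iui, cost_ivf = out$cost_ivf,
    cost_total = out$cost_total)
}

#' Full outcome for one strategy
#'
#' @inheritParams cumulative_pregnancy
#' @return A `captree_outcome` list: `strategy`, `age`, `cum_pregnancy`,
#'   `cum_live_birth`, the modality split, expected cycle counts, and costs.
#' @export
strategy_outcome <- function(strategy, draw, age) {
  check_strategy(strategy); check_age(age); validate_draw(draw)
  out <- core_for(strategy, draw, age)
  out <- c(list(strategy = strategy, age = age), out)
  class(out) <- "captree_outcome"
  out
}

#' Compare CS-TI against SOC for one age band
#'
#' @param draw A `captree_draw`.
#' @param age One of [age_bands()].
#' @return A `captree_comparison` list holding both strategy outcomes and the
#'   CS-TI minus SOC deltas `d_pregnancy`, `d_live_birth`, `d_cost_iui`,
#'   `d_cost_ivf`, `d_cost_total`.
#' @export
evaluate <- function(draw, age) {
  soc <- strategy_outcome("SOC", draw, age)
  csti <- strategy_outcome("CS-TI", draw, age)
  cmp <- list(
    age = age, soc = soc, csti = csti,
    d_pregnancy = csti$cum_pregnancy - soc$cum_pregnancy,
    d_live_birth = csti$cum_live_birth - soc$cum_live_birth,
    d_cost_iui = csti$cost_iui - soc$cost_iui,
    d_cost_ivf = csti$cost_ivf - soc$cost_ivf,
    d_cost_total = csti$cost_total - soc$cost_total
  )
  class(cmp) <- "captree_comparison"
  cmp
}

#' Baseline outcome tables
#'
#' Evaluates the model at the baseline parameter values and lays the results
#' out as the two headline tables: rates (cumulative clinical pregnancy and
#' live birth, SOC vs CS-TI with deltas) and costs (IUI, IVF, total, SOC vs
#' CS-TI with deltas), one row per age band. Values are full precision;
#' rounding happens only in the formatting layer.
#'
#' @param params A `captree_parameters` object.
#' @return List of two data.frames, `rates` and `costs`.
#' @export
baseline_tables <- function(params) {
  draw <- baseline_draw(params)
  rows <- lapply(age_bands(), function(age) evaluate(draw, age))
  rates <- data.frame(
    age = age_bands(),
    soc_pregnancy = vapply(rows, function(r) r$soc$cum_pregnancy, 0),
    csti_pregnancy = vapply(rows, function(r) r$csti$cum_pregnancy, 0),
    d_pregnancy = vapply(rows, function(r) r$d_pregnancy, 0),
    soc_live_birth = vapply(rows, function(r) r$soc$cum_live_birth, 0),
    csti_live_birth = vapply(rows, function(r) r$csti$cum_live_birth, 0),
    d_live_birth = vapply(rows, function(r) r$d_live_birth, 0),
    stringsAsFactors = FALSE
  )
  costs <- data.frame(
    age = age_bands(),
    soc_cost_iui = vapply(rows, function(r) r$soc$cost_iui, 0),
    csti_cost_iui = vapply(rows, function(r) r$csti$cost_iui, 0),
    d_cost_iui = vapply(rows, function(r) r$d_cost_iui, 0),
    soc_cost_ivf = vapply(rows, function(r) r$soc$cost_ivf, 0),
    csti_cost_ivf = vapply(rows, function(r) r$csti$cost_ivf, 0),
    d_cost_ivf = vapply(rows, function(r) r$d_cost_ivf, 0),
    soc_cost_total = vapply(rows, function(r) r$soc$cost_total, 0),
    csti_cost_total = vapply(rows, function(r) r$csti$cost_total, 0),
    d_cost_total = vapply(rows, function(r) r$d_cost_total, 0),
    stringsAsFactors = FALSE
  )
  list(rates = rates, costs = costs)
}
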