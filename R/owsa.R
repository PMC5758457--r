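# One-way (univariate) sensitivity analysis: vary each parameter across its
# sensitivity range with every other parameter held at baseline, and rank
# parameters by the absolute swing they induce in an outcome (the rows of a
# tornado diagram). Age-banded parameters vary only the analyzed band's value.

# Uncertain parameters relevant to one age band, in canonical (tie-break)
# order: the estimates-table order restricted to that band.
owsa_parameters <- function(params, age) {
  est <- params$estimates
  keep <- est$kind != "count" & (est$age_band == "" | est$age_band == age)
  est <- est[keep, ]
  est$key <- ifelse(est$age_band == "", est$id,
                    paste(est$id, est$age_band, sep = "/"))
  est
}

# Evaluate one named outcome at a (possibly perturbed) draw.
eval_outcome <- function(outcome, draw, age) {
  if (!outcome %in% psa_outcomes()) {
    stop("unknown outcome id: ", outcome,
         " (expected one of ", paste(psa_outcomes(), collapse = ", "), ")",
         call. = FALSE)
  }
  cmp <- evaluate(draw, age)
  switch(outcome,
    soc_pregnancy = cmp$soc$cum_pregnancy,
    csti_pregnancy = cmp$csti$cum_pregnancy,
    d_pregnancy = cmp$d_pregnancy,
    soc_live_birth = cmp$soc$cum_live_birth,
    csti_live_birth = cmp$csti$cum_live_birth,
    d_live_birth = cmp$d_live_birth,
    soc_cost_iui = cmp$soc$cost_iui,
    csti_cost_iui = cmp$csti$cost_iui,
    d_cost_iui = cmp$d_cost_iui,
    soc_cost_ivf = cmp$soc$cost_ivf,
    csti_cost_ivf = cmp$csti$cost_ivf,
    d_cost_ivf = cmp$d_cost_ivf,
    soc_cost_total = cmp$soc$cost_total,
    csti_cost_total = cmp$csti$cost_total,
    d_cost_total = cmp$d_cost_total)
}

# Set one parameter (id, band) in a draw to a value.
set_param <- function(draw, id, band, value) {
  if (band == "") draw[[id]] <- value else draw[[id]][[band]] <- value
  draw
}

#' One-way sensitivity analysis (tornado table)
#'
#' For each uncertain parameter, evaluates `outcome` with that parameter at
#' its low and at its high endpoint, all others at baseline; the influence is
#' the absolute difference. Rows are sorted by influence, descending, ties
#' broken by the canonical parameter order.
#'
#' @param params A `captree_parameters` object.
#' @param outcome One of the outcome ids (see [run_psa()] summary): a
#'   CS-TI-minus-SOC delta such as `"d_pregnancy"` or `"d_cost_total"`, or a
#'   single-strategy outcome such as `"soc_pregnancy"`.
#' @param age One of [age_bands()].
#' @return A `captree_tornado` data.frame: `parameter`, `age_band` (of the
#'   varied parameter, `""` for scalars), `low`, `high` (parameter endpoints),
#'   `at_low`, `at_high` (outcome values), `influence`, plus attributes
#'   `outcome`, `age`, `baseline_value`.
#' @export
run_owsa <- function(params, outcome, age) {
  check_age(age)
  base <- baseline_draw(params)
  base_val <- eval_outcome(outcome, base, age)  # also validates outcome id
  est <- owsa_parameters(params, age)
  rows <- lapply(seq_len(nrow(est)), function(i) {
    lo_draw <- set_param(base, est$id[i], est$age_band[i], est$low[i])
    hi_draw <- set_param(base, est$id[i], est$age_band[i], est$high[i])
    at_low <- eval_outcome(outcome, lo_draw, age)
    at_high <- eval_outcome(outcome, hi_draw, age)
    data.frame(parameter = est$id[i], age_band = est$age_band[i],
               low = est$low[i], high = est$high[i],
               at_low = at_low, at_high = at_high,
               influence = abs(at_high - at_low), stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(-tab$influence, seq_len(nrow(tab))), ]
  rownames(tab) <- NULL
  attr(tab, "outcome") <- outcome
  attr(tab, "age") <- age
  attr(tab, "baseline_value") <- base_val
  class(tab) <- c("captree_tornado", "data.frame")
  tab
}

#' Most influential parameter of a tornado table
#'
#' Top row of the table; if every influence is zero the first parameter in
#' canonical order is returned with a `degenerate` attribute set.
#'
#' @param tornado A `captree_tornado` from [run_owsa()].
#' @return Parameter id (character scalar).
#' @export
most_influential <- function(tornado) {
  if (!is.data.frame(tornado) || nrow(tornado) == 0) {
    stop("empty tornado table", call. = FALSE)
  }
  out <- tornado$parameter[1]
  attr(out, "degenerate") <- all(tornado$influence == 0)
  out
}

#' Tally of most-influential parameters over an outcome-by-age grid
#'
#' Runs the one-way analysis for every combination of the requested outcomes
#' and age bands, records the top-ranked parameter of each, and reports the
#' share of grid cells dominated by each parameter. The grid defaults to the
#' five CS-TI-minus-SOC delta outcomes over all five bands (25 cells) but is
#' configurable.
#'
#' @param params A `captree_parameters` object.
#' @param outcomes Character vector of outcome ids.
#' @param ages Character vector of age bands.
#' @return data.frame with one row per grid cell (`outcome`, `age`,
#'   `top_parameter`) and attribute `share`: named vector of the fraction of
#'   cells each top parameter dominates.
#' @export
owsa_grid <- function(params,
                      outcomes = c("d_pregnancy", "d_live_birth", "d_cost_iui",
                                   "d_cost_ivf", "d_cost_total"),
                      ages = age_bands()) {
  grid <- expand.grid(outcome = outcomes, age = ages,
                      stringsAsFactors = FALSE)
  grid$top_parameter <- vapply(seq_len(nrow(grid)), function(i) {
    as.character(most_influential(run_owsa(params, grid$outcome[i],
                                           grid$age[i])))
  }, "")
  share <- sort(table(grid$top_parameter) / nrow(grid), decreasing = TRUE)
  attr(grid, "share") <- stats::setNames(as.numeric(share), names(share))
  grid
}
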