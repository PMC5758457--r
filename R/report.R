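# Formatting and table writers. All model code keeps full precision; rounding
# to the printed precision (percent to two decimals, dollars to the nearest
# integer, both half-up away from zero) happens only here.

round_half_up <- function(x, digits = 0) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

#' Format a proportion as a percentage
#'
#' Two decimals, half-up rounding: `0.928846` becomes `"92.88%"`.
#'
#' @param x Numeric proportions (finite).
#' @return Character vector.
#' @export
format_percent <- function(x) {
  if (any(!is.finite(x))) stop("non-finite value", call. = FALSE)
  sprintf("%.2f%%", round_half_up(100 * x, 2))
}

#' Format a dollar amount
#'
#' Nearest dollar, half-up away from zero, thousands separators:
#' `6484.4` becomes `"$6,484"`, `-3409.6` becomes `"-$3,410"`.
#'
#' @param x Numeric USD amounts (finite).
#' @return Character vector.
#' @export
format_dollars <- function(x) {
  if (any(!is.finite(x))) stop("non-finite value", call. = FALSE)
  amt <- round_half_up(abs(x), 0)
  paste0(ifelse(x < 0, "-$", "$"),
         formatC(amt, format = "d", big.mark = ","))
}

#' Write the baseline outcome tables
#'
#' Renders [baseline_tables()] as two CSV files, `table2_baseline.csv`
#' (rates) and `table3_baseline.csv` (costs), one age band per row, full
#' precision.
#'
#' @param params A `captree_parameters` object.
#' @param dir Output directory (created if needed).
#' @return Paths of the written files, invisibly.
#' @export
write_baseline_tables <- function(params, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tabs <- baseline_tables(params)
  p2 <- file.path(dir, "table2_baseline.csv")
  p3 <- file.path(dir, "table3_baseline.csv")
  utils::write.csv(tabs$rates, p2, row.names = FALSE)
  utils::write.csv(tabs$costs, p3, row.names = FALSE)
  invisible(c(p2, p3))
}

#' Write PSA summary tables
#'
#' One CSV of the full summary (outcome, age, Monte Carlo mean, 95%
#' credibility interval, baseline evaluation) plus formatted "mean (lo-hi)"
#' views of the rate and cost outcomes; optionally the raw draw matrix for
#' audit.
#'
#' @param psa A `captree_psa` from [run_psa()].
#' @param dir Output directory.
#' @param draws Also write the raw parameter draw matrix (`psa_draws.csv`).
#' @return Paths of the written files, invisibly.
#' @export
write_psa_tables <- function(psa, dir, draws = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, "psa_summary.csv")
  utils::write.csv(psa$summary, paths, row.names = FALSE)

  s <- psa$summary
  is_rate <- grepl("pregnancy|live_birth", s$outcome)
  fmt <- ifelse(is_rate,
                sprintf("%s (%s-%s)", format_percent(pmax(pmin(s$mean, 1), -1)),
                        format_percent(pmax(pmin(s$lo, 1), -1)),
                        format_percent(pmax(pmin(s$hi, 1), -1))),
                sprintf("%s (%s-%s)", format_dollars(s$mean),
                        format_dollars(s$lo), format_dollars(s$hi)))
  pretty <- data.frame(outcome = s$outcome, age = s$age,
                       mean_ci = fmt, stringsAsFactors = FALSE)
  for (part in c("rates", "costs")) {
    keep <- if (part == "rates") is_rate else !is_rate
    wide <- stats::reshape(pretty[keep, ], idvar = "age",
                           timevar = "outcome", direction = "wide")
    names(wide) <- sub("^mean_ci\\.", "", names(wide))
    p <- file.path(dir, sprintf("psa_%s_formatted.csv", part))
    utils::write.csv(wide, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  if (draws) {
    p <- file.path(dir, "psa_draws.csv")
    utils::write.csv(as.data.frame(psa$draws), p, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Write a tornado table
#'
#' @param tornado A `captree_tornado` from [run_owsa()].
#' @param dir Output directory.
#' @return Path of the written file, invisibly.
#' @export
write_tornado_table <- function(tornado, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- file.path(dir, sprintf("tornado_%s_%s.csv", attr(tornado, "outcome"),
                              gsub("[<>]", "", attr(tornado, "age"))))
  utils::write.csv(as.data.frame(tornado), p, row.names = FALSE)
  invisible(p)
}

#' Plot a tornado diagram
#'
#' Horizontal bars spanning the outcome values at each parameter's low and
#' high endpoint, around the baseline evaluation. Base graphics; intended for
#' interactive inspection.
#'
#' @param tornado A `captree_tornado`.
#' @param ... Passed to [graphics::barplot()]-style annotation (currently the
#'   title via `main`).
#' @return `tornado`, invisibly.
#' @export
plot_tornado <- function(tornado, ...) {
  tab <- tornado[nrow(tornado):1, ]
  base <- attr(tornado, "baseline_value")
  lab <- ifelse(tab$age_band == "", tab$parameter,
                paste(tab$parameter, tab$age_band))
  old <- graphics::par(mar = c(4, 9, 3, 1))
  on.exit(graphics::par(old))
  lo <- pmin(tab$at_low, tab$at_high)
  hi <- pmax(tab$at_low, tab$at_high)
  graphics::plot(NULL, xlim = range(c(lo, hi, base)),
                 ylim = c(0.5, nrow(tab) + 0.5), yaxt = "n",
                 xlab = attr(tornado, "outcome"), ylab = "", ...)
  graphics::axis(2, at = seq_len(nrow(tab)), labels = lab, las = 1,
                 cex.axis = 0.8)
  graphics::rect(lo, seq_len(nrow(tab)) - 0.35, hi,
                 seq_len(nrow(tab)) + 0.35, col = "steelblue")
  graphics::abline(v = base, lty = 2)
  invisible(tornado)
}
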