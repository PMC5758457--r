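# Patient-level cohort microsimulation: the brute-force oracle for the
# closed-form tree, and the package's synthetic-data generator.
#
# Random-stream discipline: within one cohort the generator is consumed in a
# fixed, documented order — (1) the Cap-Score classification draws for all
# couples (CS-TI only), (2) the IUI-stage cycle draws, column by column up to
# the cap, (3) the IVF-stage cycle draws likewise, (4) the live-birth draws.
# Draws are made for every couple whether or not their branch uses them, so a
# cohort is replayable from its seed regardless of branch outcomes.

#' Simulate a single couple through the treatment pathway
#'
#' Consumes the current R random stream (seed the caller with `set.seed()`).
#' Draw order per couple: Cap-Score classification (CS-TI only), then one
#' uniform per IUI-stage cycle up to the cap, then one per IVF cycle, then one
#' live-birth draw — unused draws are still consumed so trajectories replay.
#'
#' @inheritParams cumulative_pregnancy
#' @return A `captree_trajectory` list: `strategy`, `age`, `cap_score_low`,
#'   `iui_cycles`, `ivf_cycles`, `conceived`, `modality` (`"iui"`, `"tiui"`,
#'   `"ivf"` or `"none"`), `live_birth`, `cost_accrued`.
#' @export
simulate_couple <- function(strategy, draw, age) {
  check_strategy(strategy); check_age(age); validate_draw(draw)
  cap_low <- if (strategy == "CS-TI") stats::runif(1) < draw$p_low_cs else FALSE

  p_iui_stage <- if (strategy == "SOC") draw$p_iui[[age]] else draw$p_tiui
  u_iui <- stats::runif(draw$n_iui)
  u_ivf <- stats::runif(draw$n_ivf)
  u_lb <- stats::runif(1)

  iui_cycles <- 0L
  ivf_cycles <- 0L
  modality <- "none"
  if (!cap_low && draw$n_iui > 0) {
    hit <- which(u_iui < p_iui_stage)
    if (length(hit)) {
      iui_cycles <- hit[1]
      modality <- if (strategy == "SOC") "iui" else "tiui"
    } else {
      iui_cycles <- draw$n_iui
    }
  }
  if (modality == "none" && draw$n_ivf > 0) {
    hit <- which(u_ivf < draw$p_ivf[[age]])
    if (length(hit)) {
      ivf_cycles <- hit[1]
      modality <- "ivf"
    } else {
      ivf_cycles <- draw$n_ivf
    }
  }
  conceived <- modality != "none"
  l <- switch(modality, iui = , tiui = draw$l_iui[[age]],
              ivf = draw$l_ivf[[age]], none = 0)
  traj <- list(
    strategy = strategy, age = age, cap_score_low = cap_low,
    iui_cycles = as.integer(iui_cycles), ivf_cycles = as.integer(ivf_cycles),
    conceived = conceived, modality = modality,
    live_birth = conceived && u_lb < l,
    cost_accrued = draw$c_iui * iui_cycles + draw$c_ivf * ivf_cycles
  )
  class(traj) <- "captree_trajectory"
  traj
}

# first success column of an n x k uniform matrix against probability p;
# 0 if none (k = 0) or no success. Returns list(cycles, success).
first_success <- function(u, p, k) {
  n <- nrow(u)
  if (k == 0) return(list(cycles = integer(n), success = logical(n)))
  hit <- u < p
  any_hit <- rowSums(hit) > 0
  first <- max.col(hit, ties.method = "first")  # undefined where !any_hit
  cycles <- ifelse(any_hit, first, k)
  list(cycles = as.integer(cycles), success = any_hit)
}

#' Simulate a cohort of couples
#'
#' Vectorized aggregate of `n` independent trajectories under one strategy,
#' parameter draw, and age band; the oracle counterpart of the closed-form
#' engine. Deterministic given `seed`.
#'
#' @inheritParams cumulative_pregnancy
#' @param n Number of couples (>= 1).
#' @param seed Integer seed for the cohort's random stream.
#' @return A `captree_cohort` list: `n`, empirical `pregnancy_rate` and
#'   `live_birth_rate` with binomial standard errors, modality conception
#'   rates, `mean_iui_cycles`, `mean_ivf_cycles`, `mean_cost` (with standard
#'   errors `se_*`), and the component mean costs `mean_cost_iui`,
#'   `mean_cost_ivf`.
#' @export
simulate_cohort <- function(n, strategy, draw, age, seed) {
  check_strategy(strategy); check_age(age); validate_draw(draw)
  if (length(n) != 1 || is.na(n) || n < 1) stop("n must be >= 1", call. = FALSE)
  n <- as.integer(n)
  set.seed(seed)

  cap_low <- if (strategy == "CS-TI") stats::runif(n) < draw$p_low_cs
             else rep(FALSE, n)
  p_iui_stage <- if (strategy == "SOC") draw$p_iui[[age]] else draw$p_tiui
  u_iui <- matrix(stats::runif(n * draw$n_iui), nrow = n)
  u_ivf <- matrix(stats::runif(n * draw$n_ivf), nrow = n)
  u_lb <- stats::runif(n)

  iui <- first_success(u_iui, p_iui_stage, draw$n_iui)
  # low Cap-Score couples skip the IUI stage entirely
  iui_cycles <- ifelse(cap_low, 0L, iui$cycles)
  iui_success <- !cap_low & iui$success

  ivf <- first_success(u_ivf, draw$p_ivf[[age]], draw$n_ivf)
  enters_ivf <- !iui_success
  ivf_cycles <- ifelse(enters_ivf, ivf$cycles, 0L)
  ivf_success <- enters_ivf & ivf$success

  conceived <- iui_success | ivf_success
  l <- ifelse(iui_success, draw$l_iui[[age]],
              ifelse(ivf_success, draw$l_ivf[[age]], 0))
  live <- conceived & (u_lb < l)
  cost <- draw$c_iui * iui_cycles + draw$c_ivf * ivf_cycles

  rate_se <- function(p) sqrt(p * (1 - p) / n)
  mean_se <- function(x) stats::sd(x) / sqrt(n)
  preg <- mean(conceived)
  lb <- mean(live)
  out <- list(
    n = n, strategy = strategy, age = age, seed = seed,
    pregnancy_rate = preg, se_pregnancy = rate_se(preg),
    live_birth_rate = lb, se_live_birth = rate_se(lb),
    rate_via_iui = mean(iui_success & strategy == "SOC"),
    rate_via_tiui = mean(iui_success & strategy == "CS-TI"),
    rate_via_ivf = mean(ivf_success),
    mean_iui_cycles = mean(iui_cycles), se_iui_cycles = mean_se(iui_cycles),
    mean_ivf_cycles = mean(ivf_cycles), se_ivf_cycles = mean_se(ivf_cycles),
    mean_cost = mean(cost), se_cost = mean_se(cost),
    mean_cost_iui = draw$c_iui * mean(iui_cycles),
    mean_cost_ivf = draw$c_ivf * mean(ivf_cycles)
  )
  class(out) <- "captree_cohort"
  out
}

#' Dump simulated trajectories as a data.frame
#'
#' Couple-level table for inspection or text fixtures; same stream discipline
#' as [simulate_cohort()] is *not* shared (each couple consumes its own draws
#' in [simulate_couple()] order).
#'
#' @inheritParams simulate_cohort
#' @return data.frame, one row per couple.
#' @export
simulate_trajectories <- function(n, strategy, draw, age, seed) {
  if (length(n) != 1 || is.na(n) || n < 1) stop("n must be >= 1", call. = FALSE)
  set.seed(seed)
  rows <- lapply(seq_len(n), function(i) {
    tr <- simulate_couple(strategy, draw, age)
    data.frame(couple = i, strategy = tr$strategy, age = tr$age,
               cap_score_low = tr$cap_score_low, iui_cycles = tr$iui_cycles,
               ivf_cycles = tr$ivf_cycles, conceived = tr$conceived,
               modality = tr$modality, live_birth = tr$live_birth,
               cost_accrued = tr$cost_accrued, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
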