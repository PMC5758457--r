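# Closed-form tree evaluation. Expected values are re-derived inline from the
# capped-geometric algebra (independent of the package's vectorized core);
# agreement with the patient-level microsimulation is tested separately.

test_that("cumulative pregnancy matches the capped-geometric closed forms", {
  # SOC <35: 1 - q_iui^3 * q_ivf^3
  expect_equal(cumulative_pregnancy("SOC", base_d, "<35"),
               1 - 0.839^3 * 0.494^3, tolerance = 1e-12)
  # CS-TI <35: mixture over the Cap-Score branch
  expect_equal(cumulative_pregnancy("CS-TI", base_d, "<35"),
               0.336 * (1 - 0.494^3) + 0.664 * (1 - 0.6^3 * 0.494^3),
               tolerance = 1e-12)

  # no conception possible when every pregnancy probability is zero
  zero <- base_d
  zero$p_tiui <- 0
  zero$p_iui[] <- 0
  zero$p_ivf[] <- 0
  for (s in c("SOC", "CS-TI")) {
    expect_equal(cumulative_pregnancy(s, zero, "38-40"), 0)
  }

  # IUI-only geometric failure when IVF never succeeds
  no_ivf <- base_d
  no_ivf$p_ivf[] <- 0
  expect_equal(cumulative_pregnancy("SOC", no_ivf, "<35"), 1 - 0.839^3,
               tolerance = 1e-12)

  # limit check: with no IVF cycles SOC is the textbook capped-geometric model
  cap0 <- base_d
  cap0$n_ivf <- 0L
  for (age in age_bands()) {
    expect_equal(cumulative_pregnancy("SOC", cap0, age),
                 1 - (1 - base_d$p_iui[[age]])^3, tolerance = 1e-12)
  }

  expect_error(cumulative_pregnancy("SOC", base_d, "30-35"), "unknown age band")
  expect_error(cumulative_pregnancy("IVF-first", base_d, "<35"),
               "unknown strategy")
})

test_that("modality split decomposes the pregnancy probability", {
  # frozen derived values, <35 baseline (verified against a 10^6-couple
  # independent microsimulation): via IUI = 1 - 0.839^3, via IVF = remainder
  sp <- modality_split("SOC", base_d, "<35")
  expect_equal(unname(sp["preg_via_iui"]), 0.4094102810, tolerance = 1e-9)
  expect_equal(unname(sp["preg_via_ivf"]), 0.5193918936, tolerance = 1e-9)
  expect_equal(unname(sp["preg_via_tiui"]), 0)

  # all couples routed to IVF when every Cap-Score is low
  forced <- base_d
  forced$p_low_cs <- 1
  sp <- modality_split("CS-TI", forced, "41-42")
  expect_equal(unname(sp["preg_via_iui"]), 0)
  expect_equal(unname(sp["preg_via_tiui"]), 0)

  # conservation across random draws, both strategies, all bands
  set.seed(101)
  for (rep in 1:200) {
    d <- runif_draw()
    age <- sample(age_bands(), 1)
    for (s in c("SOC", "CS-TI")) {
      expect_equal(sum(modality_split(s, d, age)),
                   cumulative_pregnancy(s, d, age), tolerance = 1e-12)
    }
  }
})

test_that("live birth weights conceptions by modality", {
  # SOC <35 at baseline, re-derived inline
  via_iui <- 1 - 0.839^3
  via_ivf <- 0.839^3 * (1 - 0.494^3)
  expect_equal(cumulative_live_birth("SOC", base_d, "<35"),
               via_iui * 0.559 + via_ivf * 0.879, tolerance = 1e-12)

  # certain delivery: live birth equals pregnancy
  all_live <- base_d
  all_live$l_iui[] <- 1
  all_live$l_ivf[] <- 1
  set.seed(7)
  for (s in c("SOC", "CS-TI")) {
    for (age in c("<35", ">42")) {
      expect_equal(cumulative_live_birth(s, all_live, age),
                   cumulative_pregnancy(s, all_live, age), tolerance = 1e-12)
    }
  }
  # and generally bounded by it
  for (rep in 1:50) {
    d <- runif_draw()
    expect_lte(cumulative_live_birth("CS-TI", d, "35-37"),
               cumulative_pregnancy("CS-TI", d, "35-37"))
  }
})

test_that("expected cycle counts follow the geometric series", {
  # frozen derived values, SOC <35 baseline:
  # e_iui = (1 - 0.839^3)/0.161, e_ivf = 0.839^3 (1 - 0.494^3)/0.506
  ec <- expected_cycle_counts("SOC", base_d, "<35")
  expect_equal(unname(ec["e_iui_cycles"]), 2.5429210, tolerance = 1e-7)
  expect_equal(unname(ec["e_ivf_cycles"]), 1.0264662, tolerance = 1e-7)

  # certain first-cycle success
  sure <- base_d
  sure$p_iui[] <- 1
  sure$p_tiui <- 1
  sure$p_ivf[] <- 1
  ec <- expected_cycle_counts("SOC", sure, "38-40")
  expect_equal(unname(ec), c(1, 0))

  # IUI branch unreachable when every Cap-Score is low
  forced <- base_d
  forced$p_low_cs <- 1
  ec <- expected_cycle_counts("CS-TI", forced, "38-40")
  expect_equal(unname(ec["e_iui_cycles"]), 0)

  # bounds across random draws
  set.seed(11)
  for (rep in 1:50) {
    d <- runif_draw()
    ec <- expected_cycle_counts("CS-TI", d, ">42")
    expect_true(all(ec >= 0) && ec["e_iui_cycles"] <= d$n_iui &&
                  ec["e_ivf_cycles"] <= d$n_ivf)
  }
})

test_that("costs are unit cost times expected cycles", {
  co <- strategy_costs("SOC", base_d, "<35")
  expect_equal(unname(co["cost_iui"]), 2550 * (1 - 0.839^3) / 0.161,
               tolerance = 1e-9)
  expect_equal(unname(co["cost_total"]),
               unname(co["cost_iui"] + co["cost_ivf"]), tolerance = 1e-12)

  # hopeless cohort consumes every cycle
  zero <- base_d
  zero$p_tiui <- 0
  zero$p_iui[] <- 0
  zero$p_ivf[] <- 0
  co <- strategy_costs("SOC", zero, "41-42")
  expect_equal(unname(co["cost_total"]), 3 * 2550 + 3 * 17651)

  # cost_iui non-increasing in p_iui under SOC
  lo <- base_d; lo$p_iui["<35"] <- 0.081
  hi <- base_d; hi$p_iui["<35"] <- 0.242
  expect_gte(strategy_costs("SOC", lo, "<35")["cost_iui"],
             strategy_costs("SOC", hi, "<35")["cost_iui"])
})

test_that("pregnancy is monotone in per-cycle probabilities", {
  set.seed(23)
  for (rep in 1:25) {
    d <- runif_draw()
    age <- sample(age_bands(), 1)
    for (id in c("p_iui", "p_ivf")) {
      bumped <- d
      bumped[[id]][[age]] <- min(1, d[[id]][[age]] + 0.05)
      expect_gte(cumulative_pregnancy("SOC", bumped, age),
                 cumulative_pregnancy("SOC", d, age))
    }
    bumped <- d
    bumped$p_tiui <- min(1, d$p_tiui + 0.05)
    expect_gte(cumulative_pregnancy("CS-TI", bumped, age),
               cumulative_pregnancy("CS-TI", d, age))
  }
})

test_that("comparison rows carry exact CS-TI minus SOC deltas", {
  cmp <- evaluate(base_d, "<35")
  expect_equal(cmp$d_pregnancy,
               cmp$csti$cum_pregnancy - cmp$soc$cum_pregnancy,
               tolerance = 1e-12)
  expect_equal(cmp$d_cost_total,
               cmp$csti$cost_total - cmp$soc$cost_total, tolerance = 1e-9)

  # CS-TI dominates SOC on pregnancy at baseline (p_tiui > p_iui everywhere)
  for (age in age_bands()) {
    expect_gte(evaluate(base_d, age)$d_pregnancy, 0)
  }

  # strategies coincide when the Cap-Score never fires and timed IUI offers
  # no advantage
  same <- base_d
  same$p_low_cs <- 0
  for (age in age_bands()) {
    same$p_tiui <- same$p_iui[[age]]
    cmp <- evaluate(same, age)
    for (dname in c("d_pregnancy", "d_live_birth", "d_cost_iui",
                    "d_cost_ivf", "d_cost_total")) {
      expect_equal(cmp[[dname]], 0, tolerance = 1e-12, info = dname)
    }
  }
})

test_that("baseline tables cover all bands at full precision", {
  tabs <- baseline_tables(table1)
  expect_equal(tabs$rates$age, age_bands())
  expect_equal(nrow(tabs$costs), 5L)
  expect_equal(tabs$costs$soc_cost_total,
               tabs$costs$soc_cost_iui + tabs$costs$soc_cost_ivf,
               tolerance = 1e-9)
  # spot values, re-derived inline
  expect_equal(tabs$rates$soc_live_birth[3],
               (1 - 0.882^3) * 0.462 + 0.882^3 * (1 - 0.68^3) * 0.772,
               tolerance = 1e-12)
  expect_equal(tabs$rates$csti_pregnancy[4],
               0.336 * (1 - 0.776^3) + 0.664 * (1 - 0.6^3 * 0.776^3),
               tolerance = 1e-12)
})
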