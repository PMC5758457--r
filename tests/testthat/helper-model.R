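# Shared fixtures: the bundled parameter table, its baseline draw, and a
# generator of random valid draws (uniform within each sensitivity range,
# independent of the PSA's fitted distributions).

table1 <- default_parameters()
base_d <- baseline_draw(table1)

runif_draw <- function(params = table1) {
  est <- params$estimates
  draw <- baseline_draw(params)
  for (i in seq_len(nrow(est))) {
    if (est$kind[i] == "count") next
    v <- stats::runif(1, est$low[i], est$high[i])
    if (est$age_band[i] == "") draw[[est$id[i]]] <- v
    else draw[[est$id[i]]][[est$age_band[i]]] <- v
  }
  draw
}

# parameter set with every sensitivity range collapsed to the baseline
collapsed_params <- function(params = table1) {
  est <- params$estimates
  est$low <- est$baseline
  est$high <- est$baseline
  parameter_set(est)
}
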