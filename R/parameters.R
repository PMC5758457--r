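# Parameter table: definition, loading, validation, and distribution fitting.

#' Maternal age bands
#'
#' The five ordered maternal-age strata used throughout the model. All
#' age-indexed parameters (per-cycle pregnancy probabilities, conditional
#' live-birth probabilities) carry one value per band, in this order.
#'
#' @return Character vector of band labels, youngest first.
#' @export
age_bands <- function() {
  c("<35", "35-37", "38-40", "41-42", ">42")
}

# Canonical schema: which ids exist, whether they are age-banded, and their kind.
param_schema <- function() {
  data.frame(
    id     = c("c_iui", "c_ivf", "p_low_cs", "p_iui", "p_tiui",
               "p_ivf", "l_iui", "l_ivf", "n_iui", "n_ivf"),
    banded = c(FALSE, FALSE, FALSE, TRUE, FALSE, TRUE, TRUE, TRUE, FALSE, FALSE),
    kind   = c("cost", "cost", "probability", "probability", "probability",
               "probability", "probability", "probability", "count", "count"),
    stringsAsFactors = FALSE
  )
}

#' Construct a validated parameter set
#'
#' @param estimates data.frame with columns `id`, `age_band` (empty string for
#'   scalar parameters), `kind` (`"cost"`, `"probability"` or `"count"`),
#'   `baseline`, `low`, `high`. One row per parameter estimate; age-banded
#'   parameters need one row per band.
#' @return An object of class `captree_parameters`: the estimates table plus
#'   the cycle caps `n_iui` and `n_ivf` pulled out as integers.
#' @export
parameter_set <- function(estimates) {
  validate_estimates(estimates)
  est <- estimates[order(match(estimates$id, param_schema()$id),
                         match(estimates$age_band, c("", age_bands()))), ]
  rownames(est) <- NULL
  ps <- list(
    estimates = est,
    n_iui = as.integer(est$baseline[est$id == "n_iui"]),
    n_ivf = as.integer(est$baseline[est$id == "n_ivf"])
  )
  class(ps) <- "captree_parameters"
  ps
}

validate_estimates <- function(est) {
  needed <- c("id", "age_band", "kind", "baseline", "low", "high")
  missing_cols <- setdiff(needed, names(est))
  if (length(missing_cols)) {
    stop("parameter table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(names(est), needed)
  if (length(extra)) {
    stop("parameter table has unknown column(s): ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  est$age_band[is.na(est$age_band)] <- ""
  schema <- param_schema()

  unknown <- setdiff(est$id, schema$id)
  if (length(unknown)) {
    stop("unknown parameter id(s): ", paste(unique(unknown), collapse = ", "),
         call. = FALSE)
  }

  # every schema slot present exactly once; banded ids need all five bands
  slots <- function(ids, bands) paste(ids, bands, sep = "/")
  want <- unlist(lapply(seq_len(nrow(schema)), function(i) {
    if (schema$banded[i]) slots(schema$id[i], age_bands()) else schema$id[i]
  }))
  have <- ifelse(est$age_band == "", est$id, slots(est$id, est$age_band))
  miss <- setdiff(want, have)
  if (length(miss)) {
    stop("missing parameter(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  dup <- have[duplicated(have)]
  if (length(dup)) {
    stop("duplicated parameter(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  bad_slot <- setdiff(have, want)
  if (length(bad_slot)) {
    stop("unexpected parameter row(s): ", paste(bad_slot, collapse = ", "),
         call. = FALSE)
  }

  kind_want <- schema$kind[match(est$id, schema$id)]
  if (any(est$kind != kind_want)) {
    bad <- have[est$kind != kind_want]
    stop("wrong kind for parameter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }

  num <- c("baseline", "low", "high")
  for (cl in num) {
    if (!is.numeric(est[[cl]]) || anyNA(est[[cl]])) {
      stop("column '", cl, "' must be numeric with no missing values",
           call. = FALSE)
    }
  }
  bad <- est$low > est$baseline | est$baseline > est$high
  if (any(bad)) {
    stop("baseline outside [low, high] for: ", paste(have[bad], collapse = ", "),
         call. = FALSE)
  }
  is_p <- est$kind == "probability"
  bad <- is_p & (est$low < 0 | est$high > 1)
  if (any(bad)) {
    stop("probability outside [0, 1] for: ", paste(have[bad], collapse = ", "),
         call. = FALSE)
  }
  is_c <- est$kind == "cost"
  bad <- is_c & est$low < 0
  if (any(bad)) {
    stop("negative cost for: ", paste(have[bad], collapse = ", "), call. = FALSE)
  }
  is_n <- est$kind == "count"
  bad <- is_n & (est$baseline < 0 | est$baseline != round(est$baseline))
  if (any(bad)) {
    stop("cycle caps must be non-negative integers: ",
         paste(have[bad], collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Default model parameters
#'
#' Loads the bundled parameter file: unit costs of IUI and IVF-ICSI (2016 USD),
#' the probability of a low Cap-Score, per-cycle clinical-pregnancy
#' probabilities by maternal-age band for IUI under standard care, for timed
#' IUI after a normal Cap-Score (age-independent), and for IVF-ICSI, and
#' live-birth probabilities conditional on clinical pregnancy by conceiving
#' modality, each with its low-high sensitivity range; plus the cycle caps
#' (three IUI, three IVF).
#'
#' @return A `captree_parameters` object.
#' @export
default_parameters <- function() {
  load_parameters(system.file("extdata", "table1_parameters.csv",
                              package = "captree", mustWork = TRUE))
}

#' Load a parameter set from file
#'
#' Reads either a comma-separated table (columns `id`, `age_band`, `kind`,
#' `baseline`, `low`, `high`) or a JSON array of records with the same fields,
#' selected by file extension. The result is fully validated: unknown
#' parameters are rejected and missing ones reported by name.
#'
#' @param path Path to a `.csv` or `.json` parameter file.
#' @return A `captree_parameters` object.
#' @export
load_parameters <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path, call. = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    est <- jsonlite::fromJSON(path)
    est <- as.data.frame(est, stringsAsFactors = FALSE)
    if (is.null(est$age_band)) est$age_band <- ""
  } else {
    est <- utils::read.csv(path, stringsAsFactors = FALSE,
                           colClasses = c(id = "character",
                                          age_band = "character"))
  }
  est$age_band[is.na(est$age_band)] <- ""
  parameter_set(est)
}

#' Write a parameter set to file
#'
#' Inverse of [load_parameters()]; CSV or JSON by extension.
#'
#' @param params A `captree_parameters` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(params, path) {
  stopifnot(inherits(params, "captree_parameters"))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(params$estimates, path, dataframe = "rows",
                         digits = NA)
  } else {
    utils::write.csv(params$estimates, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

# Look up one estimate row; band = "" for scalar parameters.
get_estimate <- function(params, id, band = "") {
  est <- params$estimates
  row <- est[est$id == id & est$age_band == band, ]
  if (nrow(row) != 1) {
    stop("no such parameter: ", id, if (nzchar(band)) paste0("/", band),
         call. = FALSE)
  }
  row
}

#' Baseline parameter draw
#'
#' Collapses a parameter set to one concrete realization at the baseline
#' values: scalars `c_iui`, `c_ivf`, `p_low_cs`, `p_tiui`; named vectors
#' `p_iui`, `p_ivf`, `l_iui`, `l_ivf` over the five age bands; integer cycle
#' caps `n_iui`, `n_ivf`. The same structure is produced by [sample_draw()]
#' with sampled values.
#'
#' @param params A `captree_parameters` object.
#' @return A `captree_draw` list.
#' @export
baseline_draw <- function(params) {
  est <- params$estimates
  pick <- function(id) {
    rows <- est[est$id == id, ]
    if (nrow(rows) == 1) return(rows$baseline)
    stats::setNames(rows$baseline, rows$age_band)[age_bands()]
  }
  draw <- list(
    c_iui = pick("c_iui"), c_ivf = pick("c_ivf"),
    p_low_cs = pick("p_low_cs"), p_tiui = pick("p_tiui"),
    p_iui = pick("p_iui"), p_ivf = pick("p_ivf"),
    l_iui = pick("l_iui"), l_ivf = pick("l_ivf"),
    n_iui = params$n_iui, n_ivf = params$n_ivf
  )
  class(draw) <- "captree_draw"
  draw
}

validate_draw <- function(draw) {
  probs <- c(draw$p_low_cs, draw$p_tiui, draw$p_iui, draw$p_ivf,
             draw$l_iui, draw$l_ivf)
  if (any(probs < 0 | probs > 1)) stop("draw has probability outside [0, 1]")
  if (draw$c_iui < 0 || draw$c_ivf < 0) stop("draw has negative cost")
  if (draw$n_iui < 0 || draw$n_ivf < 0) stop("draw has negative cycle cap")
  invisible(TRUE)
}

#' @export
print.captree_parameters <- function(x, ...) {
  cat("Model parameter set:", nrow(x$estimates), "estimates;",
      "cycle caps", x$n_iui, "IUI /", x$n_ivf, "IVF\n")
  print(x$estimates, ...)
  invisible(x)
}
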