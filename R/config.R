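#' Full simulation configuration
#'
#' Bundles growth, schedule and radiobiology parameters with the tumour
#' oxygenation kind, seed and replicate count. Defaults reproduce the
#' published default parameter tables (Spercent 3%, alpha 0.3, beta 0.03,
#' AR boost x10, 3 mmHg increments, 60% retrieval, 4 h delay, 4-day
#' quiescent half-life).
#'
#' @param growth a [growth_params()].
#' @param schedule a [treatment_schedule()].
#' @param radiobiology a [radiobiology_params()].
#' @param oxygenation `"oxic"`, `"moderate"` or `"severe"`.
#' @param seed integer RNG seed.
#' @param replicates simulations per parameter set (default 9).
#' @param output_dir directory for CSV/JSON outputs.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(growth = growth_params(),
                              schedule = treatment_schedule(),
                              radiobiology = radiobiology_params(),
                              oxygenation = c("oxic", "moderate", "severe"),
                              seed = 1L,
                              replicates = 9L,
                              output_dir = ".") {
  oxygenation <- match.arg(oxygenation)
  stopifnot(inherits(growth, "growth_params"),
            inherits(schedule, "treatment_schedule"),
            inherits(radiobiology, "radiobiology_params"),
            replicates >= 1)
  structure(list(growth = growth, schedule = schedule,
                 radiobiology = radiobiology, oxygenation = oxygenation,
                 seed = as.integer(seed),
                 replicates = as.integer(replicates),
                 output_dir = output_dir),
            class = "simulation_config")
}

.config_keys <- function() {
  g <- growth_params(); s <- treatment_schedule(); r <- radiobiology_params()
  c(paste0("growth.", names(unclass(g))),
    paste0("schedule.", setdiff(names(unclass(s)), "ar")),
    "schedule.ar_boost_factor", "schedule.ar_onset_week",
    "schedule.ar_active",
    paste0("radiobiology.", setdiff(names(unclass(r)), "oer")),
    paste0("oer.", names(unclass(r$oer))),
    "sim.oxygenation", "sim.seed", "sim.replicates", "sim.output_dir")
}

#' Read a simulation configuration file
#'
#' The format is flat `section.key = value` lines (`#` comments allowed);
#' any key not present keeps its default, unknown keys are rejected. An
#' empty file therefore yields the full default configuration.
#'
#' @param path file path.
#' @return a [simulation_config()].
#' @export
load_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(parts) != 2) stop("malformed config line: ", ln)
    key <- trimws(parts[1]); val <- trimws(parts[2])
    if (!key %in% .config_keys()) stop("unknown config key: ", key)
    kv[[key]] <- val
  }
  num <- function(v) {
    if (v %in% c("NA", "na")) return(NA_real_)
    x <- suppressWarnings(as.numeric(v))
    if (is.na(x)) stop("expected a number, got '", v, "'")
    x
  }
  pick <- function(prefix, defaults) {
    out <- defaults
    for (nm in names(defaults)) {
      k <- paste0(prefix, ".", nm)
      if (!is.null(kv[[k]])) out[[nm]] <- num(kv[[k]])
    }
    out
  }
  g <- do.call(growth_params, pick("growth", as.list(unclass(growth_params()))))
  oer_def <- as.list(unclass(oer_params()))
  oer <- do.call(oer_params, pick("oer", oer_def))
  rb_def <- as.list(unclass(radiobiology_params()))
  rb_def$oer <- NULL
  rb_args <- pick("radiobiology", rb_def)
  rb_args$oer <- oer
  rb <- do.call(radiobiology_params, rb_args)
  ar <- ar_state(
    boost_factor = if (!is.null(kv[["schedule.ar_boost_factor"]]))
      num(kv[["schedule.ar_boost_factor"]]) else 10,
    onset_week = if (!is.null(kv[["schedule.ar_onset_week"]]))
      num(kv[["schedule.ar_onset_week"]]) else NA,
    active = !is.null(kv[["schedule.ar_active"]]) &&
      num(kv[["schedule.ar_active"]]) != 0)
  s_def <- as.list(unclass(treatment_schedule()))
  s_def$ar <- NULL
  s_def$sf_scaling <- 1
  s_args <- pick("schedule", s_def)
  s_args$sf_scaling <- s_args$sf_scaling != 0
  s_args$ar <- ar
  sched <- do.call(treatment_schedule, s_args)
  simulation_config(
    growth = g, schedule = sched, radiobiology = rb,
    oxygenation = if (!is.null(kv[["sim.oxygenation"]]))
      kv[["sim.oxygenation"]] else "oxic",
    seed = if (!is.null(kv[["sim.seed"]])) num(kv[["sim.seed"]]) else 1L,
    replicates = if (!is.null(kv[["sim.replicates"]]))
      num(kv[["sim.replicates"]]) else 9L,
    output_dir = if (!is.null(kv[["sim.output_dir"]]))
      kv[["sim.output_dir"]] else ".")
}

#' Write a simulation configuration file
#'
#' Numeric values are written at full precision so that a
#' write-then-read round trip reproduces the configuration exactly.
#'
#' @param config a [simulation_config()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "simulation_config"))
  fmt <- function(v) {
    if (is.character(v)) v
    else if (is.na(v)) "NA"
    else format(v, digits = 17)
  }
  ln <- character(0)
  add <- function(prefix, lst) {
    for (k in names(lst)) {
      ln <<- c(ln, paste0(prefix, ".", k, " = ", fmt(lst[[k]])))
    }
  }
  add("growth", unclass(config$growth))
  s <- unclass(config$schedule)
  ar <- s$ar; s$ar <- NULL
  s$sf_scaling <- as.numeric(s$sf_scaling)
  add("schedule", s)
  ln <- c(ln, paste0("schedule.ar_boost_factor = ", fmt(ar$boost_factor)),
          paste0("schedule.ar_onset_week = ", fmt(ar$onset_week)),
          paste0("schedule.ar_active = ", as.numeric(ar$active)))
  rb <- unclass(config$radiobiology)
  oer <- rb$oer; rb$oer <- NULL
  add("radiobiology", rb)
  add("oer", unclass(oer))
  ln <- c(ln, paste0("sim.oxygenation = ", config$oxygenation),
          paste0("sim.seed = ", config$seed),
          paste0("sim.replicates = ", config$replicates),
          paste0("sim.output_dir = ", config$output_dir))
  writeLines(ln, path)
  invisible(path)
}

#' Build a synthetic cell population for testing
#'
#' Creates a store with an exactly specified composition:
#' `spec` is a data frame with columns `n` (count), `type`, and
#' optionally `state` (default CYCLING), `po2` (default: drawn from
#' `dist`) and `generation`. Division times are spread uniformly over
#' `time_span_h` hours; quiescent and D3 cells get exponential necrotic
#' death times.
#'
#' @param spec data frame describing the population.
#' @param dist a [po2_distribution()].
#' @param growth a [growth_params()] (cycle and half-life parameters).
#' @param time_span_h window over which division times are spread.
#' @param seed optional integer seed.
#' @return a [cell_store()].
#' @export
make_fixture_population <- function(spec,
                                    dist = po2_distribution("oxic"),
                                    growth = growth_params(),
                                    time_span_h = 48,
                                    seed = NULL) {
  stopifnot(is.data.frame(spec), all(c("n", "type") %in% names(spec)),
            all(spec$n >= 0))
  if (!is.null(seed)) set.seed(seed)
  store <- cell_store(dist, hypoxia_applied = TRUE)
  for (i in seq_len(nrow(spec))) {
    n <- spec$n[i]
    if (n == 0) next
    type <- match.arg(spec$type[i], .cell_types)
    state <- if ("state" %in% names(spec) && !is.na(spec$state[i]))
      spec$state[i] else "CYCLING"
    gen <- if ("generation" %in% names(spec) && !is.na(spec$generation[i]))
      spec$generation[i] else if (type == "T") 1 else 0
    po2 <- if ("po2" %in% names(spec) && !is.na(spec$po2[i]))
      rep(spec$po2[i], n) else sample_po2(dist, n)
    t_ev <- if (state == "HYPOXIC_QUIESCENT" || type == "D3") {
      if (type == "D3" && !is.finite(growth$d3_lifespan_days)) {
        rep(Inf, n)
      } else {
        rate <- if (state == "HYPOXIC_QUIESCENT") {
          log(2) / (growth$quiescent_half_life_days * 24)
        } else 1 / (growth$d3_lifespan_days * 24)
        stats::rexp(n, rate)
      }
    } else {
      stats::runif(n, 0, time_span_h)
    }
    for (j in seq_len(n)) {
      insert_cell(store, cell(type = type, po2 = po2[j], state = state,
                              generation = gen,
                              next_division_time = t_ev[j]))
    }
  }
  store
}
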