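#' Tumour growth parameters
#'
#' Defaults reproduce the published head-and-neck tumour growth
#' behaviour: a 3% symmetrical stem-division probability (giving a stem
#' population near 1% and an oxic volume doubling time near 37 days),
#' hypoxia onset at 10^6 cells, quiescence below 1 mmHg entered with
#' probability 50% and resolved by necrosis with a 4-day half-life.
#'
#' Cell-cycle calibration: cycle time ~ Normal(35 h, 6 h) truncated at
#' 8 h plus a short exponential G0 phase of mean 1 h, an effective stem
#' inter-division time of ~36 h. Cycle times are slowed at low oxygen by
#' the factor `1 + A exp(-pO2/s)`. Terminally differentiated (D3) cells
#' are shed/lost with an exponential lifespan (default mean 3.2 days),
#' the cell-loss mechanism that keeps the differentiated compartment near
#' 85% of the population; set `d3_lifespan_days = Inf` for immortal D3
#' cells.
#'
#' @param spercent probability of symmetrical stem division (S -> S,S).
#' @param cell_total cell count at which growth stops (default 10^8).
#' @param hypoxia_onset_cells population at which hypoxic tumours switch
#'   from the oxic to the configured pO2 histogram (default 10^6).
#' @param quiescence_threshold pO2 (mmHg) below which hypoxia-induced
#'   quiescence may be initiated.
#' @param quiescence_entry_prob probability that a cell below the
#'   threshold becomes quiescent when its pO2 is allocated.
#' @param quiescent_half_life_days necrotic half-life of quiescent cells.
#' @param cct_mean_h,cct_sd_h,cct_min_h truncated-normal cell-cycle time
#'   (hours).
#' @param g0_mean_h mean of the exponential G0 phase (hours).
#' @param transit_max_generation transit cells divide symmetrically until
#'   this generation; the terminal division yields two D2 daughters.
#' @param asym_split_transit probability that an asymmetric stem division
#'   produces (S, T) rather than (S, D1).
#' @param d3_lifespan_days mean exponential lifespan of D3 cells (days).
#' @param cct_slowing_amplitude,cct_slowing_scale_mmHg parameters A and s
#'   of the hypoxic cycle-slowing factor `1 + A exp(-pO2/s)`.
#' @return an object of class `growth_params`.
#' @export
growth_params <- function(spercent = 0.03,
                          cell_total = 1e8,
                          hypoxia_onset_cells = 1e6,
                          quiescence_threshold = 1,
                          quiescence_entry_prob = 0.5,
                          quiescent_half_life_days = 4,
                          cct_mean_h = 35,
                          cct_sd_h = 6,
                          cct_min_h = 8,
                          g0_mean_h = 1,
                          transit_max_generation = 5,
                          asym_split_transit = 0.5,
                          d3_lifespan_days = 3.2,
                          cct_slowing_amplitude = 1,
                          cct_slowing_scale_mmHg = 3) {
  p <- list(spercent = spercent, cell_total = cell_total,
            hypoxia_onset_cells = hypoxia_onset_cells,
            quiescence_threshold = quiescence_threshold,
            quiescence_entry_prob = quiescence_entry_prob,
            quiescent_half_life_days = quiescent_half_life_days,
            cct_mean_h = cct_mean_h, cct_sd_h = cct_sd_h,
            cct_min_h = cct_min_h, g0_mean_h = g0_mean_h,
            transit_max_generation = as.integer(transit_max_generation),
            asym_split_transit = asym_split_transit,
            d3_lifespan_days = d3_lifespan_days,
            cct_slowing_amplitude = cct_slowing_amplitude,
            cct_slowing_scale_mmHg = cct_slowing_scale_mmHg)
  validate_growth_params(p)
  structure(p, class = "growth_params")
}

validate_growth_params <- function(p) {
  for (k in c("spercent", "quiescence_entry_prob", "asym_split_transit")) {
    if (p[[k]] < 0 || p[[k]] > 1) {
      stop(sprintf("%s must be a probability in [0, 1], got %g", k, p[[k]]))
    }
  }
  if (p$cell_total <= p$hypoxia_onset_cells) {
    stop("cell_total must exceed hypoxia_onset_cells")
  }
  if (p$quiescent_half_life_days <= 0) stop("quiescent_half_life_days must be > 0")
  if (p$cct_mean_h <= 0 || p$cct_sd_h < 0 || p$cct_min_h <= 0) {
    stop("cell-cycle time parameters must be positive")
  }
  if (p$g0_mean_h < 0) stop("g0_mean_h must be >= 0")
  if (p$transit_max_generation < 1) stop("transit_max_generation must be >= 1")
  if (p$d3_lifespan_days <= 0) stop("d3_lifespan_days must be > 0 (use Inf)")
  if (p$cct_slowing_amplitude < 0 || p$cct_slowing_scale_mmHg <= 0) {
    stop("cycle-slowing parameters out of range")
  }
  invisible(p)
}

#' Accelerated repopulation state
#'
#' Accelerated repopulation multiplies the symmetrical stem-division
#' probability by `boost_factor` (capped at probability 1). During
#' treatment it switches on `onset_week` weeks after the first fraction
#' (`NA` disables it); `active = TRUE` applies the boost from the start
#' of a growth run.
#'
#' @param boost_factor multiplicative boost (default 10).
#' @param onset_week treatment week of onset (0-3 in practice; `NA` off).
#' @param active logical, boost active during free growth.
#' @return an object of class `ar_state`.
#' @export
ar_state <- function(boost_factor = 10, onset_week = NA, active = FALSE) {
  stopifnot(boost_factor >= 1, is.na(onset_week) || onset_week >= 0)
  structure(list(boost_factor = boost_factor,
                 onset_week = as.numeric(onset_week),
                 active = isTRUE(active)),
            class = "ar_state")
}

effective_spercent <- function(growth, ar) {
  if (isTRUE(ar$active)) min(growth$spercent * ar$boost_factor, 1)
  else growth$spercent
}

#' Assign a cell-cycle time
#'
#' Truncated-normal cycle time multiplied by the hypoxic slowing factor
#' `1 + A exp(-pO2/s)`: well-oxygenated cells cycle at the base rate,
#' cells near anoxia take up to `1 + A` times longer.
#'
#' @param po2 cellular pO2 in mmHg (vectorised).
#' @param params a [growth_params()].
#' @return cycle times in hours.
#' @export
assign_cct <- function(po2, params = growth_params()) {
  n <- length(po2)
  x <- stats::rnorm(n, params$cct_mean_h, params$cct_sd_h)
  bad <- which(x < params$cct_min_h)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), params$cct_mean_h, params$cct_sd_h)
    bad <- bad[x[bad] < params$cct_min_h]
  }
  x * (1 + params$cct_slowing_amplitude *
         exp(-po2 / params$cct_slowing_scale_mmHg))
}

#' Hypoxia-induced quiescence decision
#'
#' Cells whose pO2 falls below the quiescence threshold (1 mmHg) exit
#' the cell cycle with probability `quiescence_entry_prob`; the rest keep
#' cycling (anaerobic metabolism).
#'
#' @param po2 cellular pO2 in mmHg (vectorised).
#' @param params a [growth_params()].
#' @return character vector, `"CYCLING"` or `"HYPOXIC_QUIESCENT"`.
#' @export
maybe_enter_quiescence <- function(po2, params = growth_params()) {
  q <- po2 < params$quiescence_threshold &
    stats::runif(length(po2)) < params$quiescence_entry_prob
  ifelse(q, "HYPOXIC_QUIESCENT", "CYCLING")
}

#' Necrotic decay of the quiescent pool over an interval
#'
#' Each quiescent cell independently dies with probability
#' `1 - 2^(-elapsed/half_life)`.
#'
#' @param n_pool number of quiescent cells.
#' @param elapsed_h elapsed time in hours.
#' @param params a [growth_params()].
#' @return number of deaths (binomial draw).
#' @export
quiescent_decay <- function(n_pool, elapsed_h, params = growth_params()) {
  stopifnot(n_pool >= 0, elapsed_h >= 0)
  p_die <- 1 - 2^(-elapsed_h / (params$quiescent_half_life_days * 24))
  stats::rbinom(1, n_pool, p_die)
}

#' Apply hypoxia onset to a grown population
#'
#' Once a hypoxic tumour reaches the onset threshold (10^6 cells by
#' default) every living cell receives a fresh pO2 from the configured
#' hypoxic histogram and the quiescence rule is evaluated for each.
#' Applying onset twice, or to an oxic store, is an error.
#'
#' @param store a [cell_store()] built with a hypoxic distribution.
#' @param params a [growth_params()].
#' @return the store, invisibly.
#' @export
apply_hypoxia_onset <- function(store, params = growth_params()) {
  stopifnot(inherits(store, "cell_store"))
  cs_apply_onset(store$ptr, params)
  invisible(store)
}

#' Grow a virtual tumour
#'
#' Event-driven growth from a single oxic stem cell (or from an existing
#' population) to a target cell count. Cells divide in chronological
#' order; daughters follow the stem / transit / differentiating hierarchy,
#' inherit or redraw pO2, and may enter hypoxia-induced quiescence. For
#' hypoxic configurations the pO2 histogram switches from oxic-uniform to
#' the configured distribution when the population first reaches
#' `hypoxia_onset_cells`.
#'
#' @param growth a [growth_params()].
#' @param dist a [po2_distribution()].
#' @param ar an [ar_state()]; `active = TRUE` boosts symmetrical stem
#'   division throughout this run.
#' @param seed optional integer seed (`set.seed`) for reproducibility.
#' @param store continue growing an existing [cell_store()] instead of
#'   seeding a new tumour.
#' @param target stop once the living population reaches this count
#'   (defaults to `growth$cell_total`).
#' @param record_factor geometric spacing of time-series checkpoints.
#' @return a `growth_result`: list with `store`, `series` (data frame:
#'   `time_h`, `N_S` ... `N_D3`, `N_quiescent`, `N_total`), `status`
#'   (`"grown"`, `"extinct"` or `"stalled"`), `time_h` and `total`.
#' @export
run_growth <- function(growth = growth_params(),
                       dist = po2_distribution("oxic"),
                       ar = ar_state(),
                       seed = NULL,
                       store = NULL,
                       target = growth$cell_total,
                       record_factor = 1.02) {
  stopifnot(inherits(growth, "growth_params"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(store)) {
    store <- cell_store(dist)
    cs_reserve(store$ptr, min(target * 1.1, 2^31 - 1))
    cs_seed_stem(store$ptr, growth)
  } else {
    stopifnot(inherits(store, "cell_store"))
    cs_reserve(store$ptr, min(target * 1.1, 2^31 - 1))
  }
  res <- grow_cpp(store$ptr, growth, target, effective_spercent(growth, ar),
                  record_factor)
  series <- as.data.frame(res$series)
  names(series) <- c("time_h", "N_S", "N_T", "N_D1", "N_D2", "N_D3",
                     "N_quiescent")
  series$N_total <- series$N_S + series$N_T + series$N_D1 + series$N_D2 +
    series$N_D3
  structure(list(store = store, series = series,
                 status = c("grown", "extinct", "stalled")[res$status + 1L],
                 time_h = res$time_h, total = res$total),
            class = "growth_result")
}

#' @export
print.growth_result <- function(x, ...) {
  cat("<growth_result>", x$status, "-", format(x$total, big.mark = ","),
      "cells in", round(x$time_h / 24, 1), "days\n")
  invisible(x)
}

#' Cell-type composition of a store or growth result
#'
#' @param x a `cell_store` or `growth_result`.
#' @return named percentages over living cells: each type, `stem`,
#'   `differentiated` (D1+D2+D3) and `quiescent`.
#' @export
composition <- function(x) {
  if (inherits(x, "growth_result")) x <- x$store
  ct <- store_counts(x)
  tot <- ct[["total"]]
  typ <- ct[1:5] + ct[6:10]
  pct <- 100 * typ / tot
  c(pct,
    stem = unname(pct[1]),
    differentiated = unname(pct[3] + pct[4] + pct[5]),
    quiescent = unname(100 * sum(ct[6:10]) / tot))
}
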