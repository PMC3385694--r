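#' Fractionated radiotherapy schedule
#'
#' The conventional schedule is one 2 Gy fraction per day, five days per
#' week, continuing until every cell is killed (or `max_weeks` elapses).
#' Reoxygenation events, when enabled, occur a few hours after each
#' fraction (default 4 h): every cell receives a binomial number of
#' 3 mmHg pO2 increments and 60% of the hypoxia-quiescent pool is
#' eligible for retrieval back into the cycling population. Accelerated
#' repopulation boosts symmetrical stem division from its onset week.
#'
#' @param dose_per_fraction Gy per fraction (default 2).
#' @param fractions_per_day only 1 is supported (conventional schedule).
#' @param treatment_days_per_week fractions are delivered on the first
#'   `n` days of each week (default 5, Mon-Fri).
#' @param max_weeks stop delivering after this many weeks (non-control).
#' @param rox_onset_week treatment week at which reoxygenation events
#'   begin (`NA` disables reoxygenation).
#' @param rox_delay_h delay of the reoxygenation event after a fraction.
#' @param rox_increment_mmHg pO2 increment size (default 3 mmHg).
#' @param rox_quiescent_retrieval fraction of quiescent cells eligible
#'   for retrieval at each event (default 0.6).
#' @param rox_max_increments cap on increments per cell per event; the
#'   binomial is sampled conditional on not exceeding it (the probability
#'   of five or more increments is below 0.5% and treated as negligible).
#' @param sf_scaling scale the increment size and retrieval fraction
#'   linearly with (1 - SF(dose)) relative to the 2 Gy reference, so the
#'   defaults are exact for the conventional schedule.
#' @param ar an [ar_state()].
#' @return an object of class `treatment_schedule`.
#' @export
treatment_schedule <- function(dose_per_fraction = 2,
                               fractions_per_day = 1,
                               treatment_days_per_week = 5,
                               max_weeks = 20,
                               rox_onset_week = NA,
                               rox_delay_h = 4,
                               rox_increment_mmHg = 3,
                               rox_quiescent_retrieval = 0.6,
                               rox_max_increments = 4,
                               sf_scaling = TRUE,
                               ar = ar_state()) {
  stopifnot(dose_per_fraction >= 0, fractions_per_day == 1,
            treatment_days_per_week >= 1, treatment_days_per_week <= 7,
            max_weeks >= 1,
            is.na(rox_onset_week) || rox_onset_week >= 0,
            rox_delay_h >= 0, rox_delay_h < 24,
            rox_increment_mmHg >= 0,
            rox_quiescent_retrieval >= 0, rox_quiescent_retrieval <= 1,
            rox_max_increments >= 1,
            inherits(ar, "ar_state"))
  structure(list(dose_per_fraction = dose_per_fraction,
                 fractions_per_day = 1L,
                 treatment_days_per_week = as.integer(treatment_days_per_week),
                 max_weeks = as.integer(max_weeks),
                 rox_onset_week = as.numeric(rox_onset_week),
                 rox_delay_h = rox_delay_h,
                 rox_increment_mmHg = rox_increment_mmHg,
                 rox_quiescent_retrieval = rox_quiescent_retrieval,
                 rox_max_increments = as.integer(rox_max_increments),
                 sf_scaling = isTRUE(sf_scaling),
                 ar = ar),
            class = "treatment_schedule")
}

.flat_schedule <- function(sched, proliferation = TRUE) {
  list(dose_per_fraction = sched$dose_per_fraction,
       treatment_days_per_week = sched$treatment_days_per_week,
       max_weeks = sched$max_weeks,
       ar_onset_week = sched$ar$onset_week,
       ar_boost_factor = sched$ar$boost_factor,
       rox_onset_week = sched$rox_onset_week,
       rox_delay_h = sched$rox_delay_h,
       rox_increment_mmHg = sched$rox_increment_mmHg,
       rox_quiescent_retrieval = sched$rox_quiescent_retrieval,
       rox_max_increments = sched$rox_max_increments,
       proliferation = isTRUE(proliferation),
       sf_scaling = sched$sf_scaling)
}

#' Deliver a single dose fraction
#'
#' Every living cell is assessed independently: it dies with probability
#' `(1 - SF(d))` times the normalised OER lethality factor at its pO2,
#' halved for non-cycling cells (D2, D3, G0-phase and quiescent). Dead
#' cells are removed from the store.
#'
#' @param store a [cell_store()].
#' @param d dose in Gy.
#' @param rb a [radiobiology_params()].
#' @return named vector of kill counts by type (`q_*` entries count
#'   quiescent cells).
#' @export
apply_fraction <- function(store, d, rb = radiobiology_params()) {
  stopifnot(inherits(store, "cell_store"), d >= 0)
  apply_fraction_cpp(store$ptr, d, unclass(rb))
}

#' Sample reoxygenation increment counts
#'
#' The number of 3 mmHg pO2 increments a cell receives at a
#' reoxygenation event is Binomial(n, p) with `n` the number of available
#' increments (the living cell count) and `p = 1/n`, so the mean gain is
#' one increment (3 mmHg) per cell. Draws above `kmax` (probability
#' below 0.5%) are redrawn.
#'
#' @param n_draws number of samples to return.
#' @param n total number of increments (living cell count).
#' @param p per-increment probability (default `1/n`).
#' @param kmax maximum increments per cell (default 4).
#' @return integer vector of increment counts in `0:kmax`.
#' @export
sample_rox_increments <- function(n_draws, n, p = 1 / n, kmax = 4) {
  stopifnot(n >= 1, p >= 0, p <= 1, kmax >= 1)
  k <- stats::rbinom(n_draws, n, p)
  bad <- which(k > kmax)
  while (length(bad)) {
    k[bad] <- stats::rbinom(length(bad), n, p)
    bad <- bad[k[bad] > kmax]
  }
  k
}

#' Trigger one reoxygenation event
#'
#' Every cycling cell's pO2 is increased by `k` times the increment size
#' with `k` drawn from the truncated binomial of
#' [sample_rox_increments()] (capped at 100 mmHg). A random 60% of the
#' quiescent pool receives increments too, and any quiescent cell whose
#' pO2 rises to or above the quiescence threshold re-enters the cell
#' cycle with a fresh G0 + cycle-time schedule.
#'
#' @param store a [cell_store()].
#' @param sched a [treatment_schedule()].
#' @param growth a [growth_params()].
#' @return number of quiescent cells retrieved, invisibly.
#' @export
rox_event <- function(store, sched = treatment_schedule(),
                      growth = growth_params()) {
  stopifnot(inherits(store, "cell_store"),
            inherits(sched, "treatment_schedule"))
  invisible(rox_event_cpp(store$ptr, growth, sched$rox_increment_mmHg,
                          sched$rox_quiescent_retrieval,
                          sched$rox_max_increments))
}

#' Advance the simulation clock
#'
#' Processes division and necrosis events up to `t_h` (hours on the
#' store's clock). With `proliferation = FALSE` divisions are suspended
#' and only necrotic deaths fire.
#'
#' @param store a [cell_store()].
#' @param t_h target time in hours (must not be in the past).
#' @param growth a [growth_params()].
#' @param ar an [ar_state()] (`active = TRUE` boosts stem divisions).
#' @param proliferation logical.
#' @return the store, invisibly.
#' @export
advance_store <- function(store, t_h, growth = growth_params(),
                          ar = ar_state(), proliferation = TRUE) {
  stopifnot(inherits(store, "cell_store"), t_h >= cs_now(store$ptr))
  cs_advance(store$ptr, t_h, growth, effective_spercent(growth, ar),
             proliferation)
  invisible(store)
}

#' Run a fractionated radiotherapy course
#'
#' Alternates daily dose fractions (first `treatment_days_per_week` days
#' of each week) with continual proliferation, including weekends;
#' reoxygenation events follow each fraction after `rox_delay_h` when
#' enabled, and accelerated repopulation boosts symmetrical stem division
#' from its onset week. Treatment continues until no living cell remains
#' or `max_weeks` is reached.
#'
#' Three endpoints are recorded, each "the first fraction after which the
#' population stayed at zero": stem cells only, basal cells (S + T + D1),
#' and total cell kill.
#'
#' @param store a [cell_store()] holding the grown tumour (modified in
#'   place; use [clone_store()] to keep the original).
#' @param sched a [treatment_schedule()].
#' @param rb a [radiobiology_params()].
#' @param growth a [growth_params()] governing inter-fraction
#'   proliferation.
#' @param seed optional integer seed.
#' @param proliferation set `FALSE` to disable divisions entirely (used
#'   for closed-form comparisons with the LQ model).
#' @return a `treatment_result`: `per_fraction` data frame (`fraction`,
#'   `time_h`, `dose_Gy`, counts by type including quiescent cells,
#'   `N_quiescent`), logical `controlled`, `fractions_delivered`, and the
#'   three endpoints (`NA` when not reached).
#' @export
run_treatment <- function(store, sched = treatment_schedule(),
                          rb = radiobiology_params(),
                          growth = growth_params(),
                          seed = NULL, proliferation = TRUE) {
  stopifnot(inherits(store, "cell_store"),
            inherits(sched, "treatment_schedule"),
            inherits(rb, "radiobiology_params"),
            inherits(growth, "growth_params"))
  if (!is.null(seed)) set.seed(seed)
  res <- treat_cpp(store$ptr, growth, unclass(rb),
                   .flat_schedule(sched, proliferation))
  pf <- as.data.frame(res$per_fraction)
  names(pf) <- c("fraction", "time_h", "dose_Gy", "N_S", "N_T", "N_D1",
                 "N_D2", "N_D3", "N_quiescent")
  ep <- function(x) if (x < 0) NA_integer_ else as.integer(x)
  structure(list(per_fraction = pf,
                 controlled = res$controlled,
                 fractions_delivered = res$fractions_delivered,
                 stem_endpoint = ep(res$stem_endpoint),
                 basal_endpoint = ep(res$basal_endpoint),
                 control_endpoint = ep(res$control_endpoint),
                 store = store),
            class = "treatment_result")
}

#' @export
print.treatment_result <- function(x, ...) {
  cat("<treatment_result>",
      if (x$controlled) "controlled" else "NOT controlled",
      "after", x$fractions_delivered, "fractions",
      sprintf("(stem endpoint %s, basal %s, total %s)\n",
              x$stem_endpoint, x$basal_endpoint, x$control_endpoint))
  invisible(x)
}
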