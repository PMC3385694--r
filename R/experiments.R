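#' Doubling-time experiment with an accelerated-repopulation phase
#'
#' Grows an oxic tumour from a single stem cell to `target` cells,
#' estimates the pre-boost volume doubling time by log-linear fit over
#' the statistically stable window (counts above `stable_from`), then
#' continues the same tumour with the symmetrical stem-division
#' probability multiplied by `boost_factor` and estimates the post-boost
#' doubling time over the tail of the continuation (the first part of the
#' continuation is discarded while the population structure
#' re-equilibrates to the boosted stem compartment).
#'
#' @param growth a [growth_params()].
#' @param dist a [po2_distribution()].
#' @param target pre-boost growth target (cells).
#' @param boost_factor accelerated-repopulation boost (default 10).
#' @param extension post-boost growth continues to `extension * target`.
#' @param stable_from lower count bound of the pre-boost fit window.
#' @param seed optional integer seed.
#' @param keep_stores keep the cell stores in the result (default
#'   `FALSE`: only the time series and summaries are returned, so that
#'   replicate experiments do not accumulate multi-gigabyte populations).
#' @return list with `td_pre_days`, `td_post_days`, `composition` (at
#'   `target`, before the boost), and the two growth results.
#' @export
doubling_time_experiment <- function(growth = growth_params(),
                                     dist = po2_distribution("oxic"),
                                     target = 1e7,
                                     boost_factor = 10,
                                     extension = 4,
                                     stable_from = 1e4,
                                     seed = NULL,
                                     keep_stores = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  g <- growth
  g$cell_total <- max(g$cell_total, target)
  pre <- run_growth(g, dist, target = target)
  if (pre$status != "grown") stop("growth did not reach the target: ",
                                  pre$status)
  comp <- composition(pre)
  td_pre <- doubling_time(pre$series$time_h, pre$series$N_total,
                          window = c(stable_from, target))
  post <- run_growth(g, dist, ar = ar_state(boost_factor, active = TRUE),
                     store = pre$store, target = extension * target)
  # fit over the upper half (in doublings) of the continuation
  lo <- target * sqrt(extension)
  td_post <- doubling_time(post$series$time_h, post$series$N_total,
                           window = c(lo, extension * target))
  if (!keep_stores) {
    pre$store <- NULL
    post$store <- NULL
    gc(verbose = FALSE)
  }
  list(td_pre_days = td_pre, td_post_days = td_post, composition = comp,
       growth = pre, continuation = post)
}

#' Extra dose per fraction required under accelerated repopulation
#'
#' Reproduces the isoeffect analysis: a tumour is grown to `scale` cells
#' and treated with the conventional schedule without accelerated
#' repopulation to establish the isoeffect fraction count. The same
#' tumour (cloned) is then re-treated with the boost switched on at each
#' onset week; the extra 2 Gy fractions needed beyond the isoeffect
#' schedule are converted to an extra dose per fraction over the
#' post-onset part of the isoeffect schedule via the
#' biologically-effective-dose relation ([extra_dose_per_fraction()]).
#'
#' The comparison uses the stem-cell eradication endpoint: both the
#' baseline and boosted courses are then limited by the same population,
#' which makes the extra-fraction-to-schedule ratio (and therefore the
#' extra dose) insensitive to the onset week, as observed clinically.
#' See the methods vignette for the rationale.
#'
#' @param onset_weeks accelerated-repopulation onset weeks to test.
#' @param boost_factor boost applied to symmetrical stem division.
#' @param scale tumour size at the start of treatment (cells).
#' @param growth a [growth_params()].
#' @param dist a [po2_distribution()].
#' @param rb a [radiobiology_params()].
#' @param sched base [treatment_schedule()] (no AR; AR is added per run).
#' @param alpha_beta alpha/beta ratio for the BED conversion (Gy).
#' @param endpoint which eradication endpoint defines "control":
#'   `"stem"` (default), `"basal"` or `"total"`.
#' @param seed optional integer seed (growth phase and, when
#'   `course_seed` is `NULL`, the treatment courses).
#' @param grown optional pre-grown [cell_store()] at `scale`; growth is
#'   skipped and the store is cloned for every course.
#' @param course_seed optional integer; when given, the RNG is re-seeded
#'   with it before the baseline and before every boosted course, so all
#'   courses share one realisation until the boost first acts (common
#'   random numbers). The extra-fraction count then isolates the effect
#'   of accelerated repopulation from between-course Monte Carlo noise.
#' @return data frame with one row per onset week: `onset_week`,
#'   `isoeffect_fx`, `ar_fx`, `extra_fx`, `n_ar`, `extra_dose_Gy`
#'   (`n_ar`/`extra_dose_Gy` are `NA` when the onset lies at or beyond
#'   the end of the isoeffect schedule).
#' @seealso [extra_dose_summary()] to pool replicate runs.
#' @export
extra_dose_experiment <- function(onset_weeks = 0:3,
                                  boost_factor = 10,
                                  scale = 1e7,
                                  growth = growth_params(),
                                  dist = po2_distribution("oxic"),
                                  rb = radiobiology_params(),
                                  sched = treatment_schedule(),
                                  alpha_beta = 10,
                                  endpoint = c("stem", "basal", "total"),
                                  seed = NULL,
                                  grown = NULL,
                                  course_seed = NULL) {
  endpoint <- match.arg(endpoint)
  if (!is.null(seed)) set.seed(seed)
  g <- growth
  g$cell_total <- max(g$cell_total, scale)
  if (is.null(grown)) {
    gr <- run_growth(g, dist, target = scale)
    if (gr$status != "grown") stop("growth failed: ", gr$status)
    grown <- gr$store
    rm(gr)
  }
  ep <- function(tr) switch(endpoint, stem = tr$stem_endpoint,
                            basal = tr$basal_endpoint,
                            total = tr$control_endpoint)
  course <- function(s) {
    st <- clone_store(grown)
    tr <- run_treatment(st, s, rb, g, seed = course_seed)
    tr$store <- NULL
    rm(st)
    gc(verbose = FALSE)
    tr
  }
  base <- course(sched)
  n_iso <- ep(base)
  if (is.na(n_iso)) stop("baseline schedule did not reach the ", endpoint,
                         " endpoint")
  fx_per_week <- sched$treatment_days_per_week
  out <- data.frame(onset_week = onset_weeks, isoeffect_fx = n_iso,
                    ar_fx = NA_integer_, extra_fx = NA_real_,
                    n_ar = NA_real_, extra_dose_Gy = NA_real_)
  for (i in seq_along(onset_weeks)) {
    w <- onset_weeks[i]
    s_ar <- sched
    s_ar$ar <- ar_state(boost_factor, onset_week = w)
    tr <- course(s_ar)
    n_w <- ep(tr)
    if (is.na(n_w)) stop("AR schedule did not reach the ", endpoint,
                         " endpoint")
    out$ar_fx[i] <- n_w
    out$extra_fx[i] <- max(n_w - n_iso, 0)
    n_ar <- n_iso - fx_per_week * w
    if (n_ar >= 1) {
      out$n_ar[i] <- n_ar
      out$extra_dose_Gy[i] <- extra_dose_per_fraction(
        n_ar, out$extra_fx[i], d0 = sched$dose_per_fraction,
        alpha_beta = alpha_beta)
    }
  }
  out
}

#' Pool replicate extra-dose runs
#'
#' Averages the extra fractions and the post-onset schedule length over
#' replicate [extra_dose_experiment()] runs for each onset week before
#' applying the (nonlinear) BED conversion, which smooths the integer
#' quantisation of fraction counts.
#'
#' @param runs a row-bound data frame of [extra_dose_experiment()]
#'   results from replicate seeds.
#' @param d0 baseline dose per fraction (Gy).
#' @param alpha_beta alpha/beta ratio (Gy).
#' @return data frame per onset week: mean `extra_fx`, mean `n_ar`,
#'   `extra_dose_Gy`, and the replicate standard deviation of the
#'   per-run extra dose.
#' @export
extra_dose_summary <- function(runs, d0 = 2, alpha_beta = 10) {
  ok <- !is.na(runs$n_ar)
  runs <- runs[ok, ]
  weeks <- sort(unique(runs$onset_week))
  out <- data.frame(onset_week = weeks, extra_fx = NA_real_,
                    n_ar = NA_real_, extra_dose_Gy = NA_real_,
                    sd_extra_dose_Gy = NA_real_, n_runs = NA_integer_)
  for (i in seq_along(weeks)) {
    r <- runs[runs$onset_week == weeks[i], ]
    out$extra_fx[i] <- mean(r$extra_fx)
    out$n_ar[i] <- mean(r$n_ar)
    out$extra_dose_Gy[i] <- extra_dose_per_fraction(
      out$n_ar[i], out$extra_fx[i], d0 = d0, alpha_beta = alpha_beta)
    out$sd_extra_dose_Gy[i] <- stats::sd(r$extra_dose_Gy)
    out$n_runs[i] <- nrow(r)
  }
  out
}
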