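test_that("LQ surviving fraction matches closed forms", {
  expect_equal(survival_fraction(0), 1)
  expect_equal(survival_fraction(2), exp(-0.72))
  expect_equal(survival_fraction(2), 0.487, tolerance = 1e-3)
  expect_equal(survival_fraction(2, radiobiology_params(beta = 0.1)),
               exp(-1))
  expect_error(survival_fraction(-1), "non-negative")
})

test_that("kill probability combines SF, OER lethality and cycling status", {
  base <- 1 - exp(-0.72)
  expect_equal(kill_probability(2, 60), base)
  expect_equal(kill_probability(2, 0), base * oer(0) / oer(60))
  expect_equal(kill_probability(2, 60, cycling = FALSE), base * 0.5)
  expect_equal(kill_probability(2, 100), base)  # clipped above 60 mmHg
})

test_that("a fraction kills the expected share of an oxic cycling population", {
  n <- 1e5
  st <- fixture_store(n, po2 = 60, seed = 21)
  killed <- apply_fraction(st, 2)
  surv <- n_cells(st)
  p_surv <- exp(-0.72)
  expect_equal(surv / n, p_surv, tolerance = 3 * sqrt(p_surv * (1 - p_surv) / n) / p_surv)
  # zero dose kills nothing
  st0 <- fixture_store(1000, po2 = 60, seed = 22)
  expect_equal(sum(apply_fraction(st0, 0)), 0)
  expect_equal(n_cells(st0), 1000)
})

test_that("anoxic quiescent cells survive a fraction far better than oxic cycling cells", {
  n <- 2e4
  oxic <- fixture_store(n, po2 = 60, seed = 23)
  quies <- fixture_store(n, po2 = 0.2, state = "HYPOXIC_QUIESCENT", seed = 23)
  apply_fraction(oxic, 2)
  apply_fraction(quies, 2)
  p_ox <- 1 - n_cells(oxic) / n
  p_q <- 1 - n_cells(quies) / n
  # expected ratio: lethality(0.2)/lethality(60) * noncycling 0.5
  expect_lt(p_q, p_ox * 0.35)
  expect_equal(p_q, (1 - exp(-0.72)) * oer_lethality_factor(0.2) * 0.5,
               tolerance = 0.1)
})

test_that("reoxygenation increments follow the truncated binomial contract", {
  n <- 1e5
  # closed-form tail below 0.5%
  expect_lt(1 - pbinom(4, n, 1 / n), 0.005)
  set.seed(24)
  k <- sample_rox_increments(1e5, n = n)
  expect_true(all(k %in% 0:4))
  # mean gain ~ 3 mmHg: one increment per cell on average
  expect_equal(mean(3 * k), 3, tolerance = 0.02)
  expect_true(all(sample_rox_increments(100, n = 10, p = 0) == 0))
})

test_that("reoxygenation events shift the pO2 histogram right and retrieve quiescent cells", {
  sp <- data.frame(n = c(3000, 500), type = c("S", "S"), po2 = c(3, 0.4),
                   state = c("CYCLING", "HYPOXIC_QUIESCENT"))
  st <- make_fixture_population(sp, growth = growth_params(), seed = 25)
  sched <- treatment_schedule(rox_onset_week = 0)
  m0 <- mean(store_po2(st))
  q0 <- sum(census(st)[, "HYPOXIC_QUIESCENT"])
  expect_equal(q0, 500)
  for (i in 1:6) {
    m_before <- mean(store_po2(st))
    rox_event(st, sched)
    m_after <- mean(store_po2(st))
    expect_gte(m_after, m_before)  # increments are non-negative
  }
  expect_gt(mean(store_po2(st)), m0 + 10)
  expect_true(all(store_po2(st) <= 100))
  # the quiescent pool is reoxygenated above 1 mmHg and re-enters the cycle
  q_after <- sum(census(st)[, "HYPOXIC_QUIESCENT"])
  expect_lt(q_after, q0 * 0.1)
})

test_that("without proliferation the stem endpoint tracks the LQ closed form", {
  # all cells oxic cycling at 60 mmHg, daily fractions, no weekend gaps,
  # no proliferation: expected fraction count = ceil(ln N0 / (ad + bd^2))
  n0 <- 2000
  lq <- lq_fraction_count(n0, 2)
  sched <- treatment_schedule(treatment_days_per_week = 7)
  set.seed(26)
  got <- replicate(12, {
    st <- fixture_store(n0, po2 = 60)
    run_treatment(st, sched, proliferation = FALSE)$stem_endpoint
  })
  expect_true(all(!is.na(got)))
  # extinction of the last few cells adds a sub-fraction stochastic tail
  expect_gte(mean(got), lq - 0.5)
  expect_lte(mean(got), lq + 2)
})

test_that("fractions-to-control is monotone in tumour burden and dose", {
  sched <- treatment_schedule(treatment_days_per_week = 7)
  ep <- function(n0, d, seed) {
    set.seed(seed)
    st <- fixture_store(n0, po2 = 60)
    run_treatment(st, treatment_schedule(dose_per_fraction = d,
                                         treatment_days_per_week = 7),
                  proliferation = FALSE)$stem_endpoint
  }
  small <- sapply(1:5, function(s) ep(300, 2, s))
  large <- sapply(1:5, function(s) ep(3e4, 2, s + 50))
  expect_gt(mean(large), mean(small))
  low_d <- sapply(1:5, function(s) ep(1e4, 1.5, s + 100))
  high_d <- sapply(1:5, function(s) ep(1e4, 3, s + 150))
  expect_gt(mean(low_d), mean(high_d))
})

test_that("a full conventional course controls a small oxic tumour", {
  g <- small_growth()
  grown <- run_growth(g, seed = 27, target = 1e5)
  tr <- run_treatment(grown$store, treatment_schedule(), growth = g)
  expect_true(tr$controlled)
  expect_false(is.na(tr$stem_endpoint))
  # endpoints are ordered: stems die no later than basal, basal than total
  expect_lte(tr$stem_endpoint, tr$basal_endpoint)
  expect_lte(tr$basal_endpoint, tr$control_endpoint)
  # per-fraction counts decline overall and end at zero
  pf <- tr$per_fraction
  expect_equal(nrow(pf), tr$fractions_delivered)
  expect_lt(sum(pf[nrow(pf), c("N_S", "N_T", "N_D1", "N_D2", "N_D3")]),
            pf$N_S[1] + pf$N_T[1])
})

test_that("reoxygenation timing (4 h vs 23 h after a fraction) is immaterial for daily fractions", {
  g <- small_growth()
  grown <- run_growth(g, dist = po2_distribution("moderate"), seed = 28,
                      target = 1e5)
  fx <- sapply(c(4, 23), function(delay) {
    sapply(1:5, function(r) {
      set.seed(300 + r)   # same treatment seeds for both delays
      st <- clone_store(grown$store)
      tr <- run_treatment(st, treatment_schedule(rox_onset_week = 0,
                                                 rox_delay_h = delay),
                          growth = g)
      tr$stem_endpoint
    })
  })
  # difference between delays is within the replicate scatter
  pooled_sd <- sqrt(mean(c(var(fx[, 1]), var(fx[, 2]))))
  expect_lte(abs(mean(fx[, 1]) - mean(fx[, 2])),
             max(2 * pooled_sd, 1.5))
})

test_that("identical seed and configuration give identical treatment output", {
  g <- small_growth()
  run_once <- function() {
    grown <- run_growth(g, dist = po2_distribution("moderate"), seed = 29,
                        target = 3e4)
    run_treatment(grown$store, treatment_schedule(rox_onset_week = 1,
                                                  ar = ar_state(10, 1)),
                  growth = g, seed = 30)
  }
  a <- run_once()
  b <- run_once()
  expect_identical(a$per_fraction, b$per_fraction)
  expect_identical(a$stem_endpoint, b$stem_endpoint)
  expect_identical(a$control_endpoint, b$control_endpoint)
})
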