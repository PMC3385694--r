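test_that("cycle times are slowed exponentially at low oxygen", {
  p <- growth_params()
  set.seed(2)
  well_ox <- assign_cct(rep(100, 4000), p)
  anoxic <- assign_cct(rep(0, 4000), p)
  # at high pO2 the slowing factor vanishes
  expect_equal(mean(well_ox), p$cct_mean_h, tolerance = 0.02)
  # at 0 mmHg the mean is (1 + A) times the base cycle time
  expect_equal(mean(anoxic) / mean(well_ox),
               1 + p$cct_slowing_amplitude, tolerance = 0.03)
  expect_true(all(well_ox >= p$cct_min_h))
})

test_that("hypoxia-induced quiescence follows the threshold and 50% rule", {
  p <- growth_params()
  expect_identical(maybe_enter_quiescence(50, p), "CYCLING")
  set.seed(4)
  states <- maybe_enter_quiescence(rep(0.5, 1e4), p)
  frac <- mean(states == "HYPOXIC_QUIESCENT")
  expect_equal(frac, 0.5, tolerance = 3 * 0.5 / sqrt(1e4))
})

test_that("quiescent pool halves every half-life", {
  p <- growth_params()   # 4-day half-life
  set.seed(6)
  expect_equal(quiescent_decay(1e4, 0, p), 0)
  d4 <- quiescent_decay(1e4, 4 * 24, p)
  d8 <- quiescent_decay(1e4, 8 * 24, p)
  expect_equal(d4 / 1e4, 0.5, tolerance = 3 * 0.5 / sqrt(1e4) / 0.5)
  expect_equal(d8 / 1e4, 0.75, tolerance = 3 * sqrt(0.75 * 0.25 / 1e4) / 0.75)
})

test_that("forced symmetrical division yields a pure stem population", {
  g <- small_growth(spercent = 1)
  res <- run_growth(g, seed = 8, target = 512)
  cen <- census(res$store)
  expect_equal(sum(cen["S", ]), n_cells(res$store))
  expect_true(all(cen[c("T", "D1", "D2", "D3"), ] == 0))
})

test_that("transit cells divide out to D2 at the maximum generation", {
  g <- growth_params()
  st <- make_fixture_population(
    data.frame(n = 1, type = "T", po2 = 60,
               generation = g$transit_max_generation),
    seed = 10, time_span_h = 2)
  advance_store(st, 3, g)   # daughters cannot re-divide before 3 h
  cen <- census(st)
  expect_equal(sum(cen["D2", ]), 2)
  expect_equal(sum(cen["T", ]), 0)
  # below the cap, transit cells self-renew with an incremented generation
  st2 <- make_fixture_population(
    data.frame(n = 1, type = "T", po2 = 60, generation = 1),
    seed = 10, time_span_h = 2)
  advance_store(st2, 3, g)
  expect_equal(sum(census(st2)["T", ]), 2)
})

test_that("D3 cells never divide and are lost with their configured lifespan", {
  g <- growth_params(d3_lifespan_days = 2)
  st <- make_fixture_population(data.frame(n = 2000, type = "D3", po2 = 60),
                                growth = g, seed = 12)
  advance_store(st, 2 * 24, g)
  surv <- n_cells(st)
  expect_equal(surv / 2000, exp(-1), tolerance = 0.1)
  g_imm <- growth_params(d3_lifespan_days = Inf)
  st2 <- make_fixture_population(data.frame(n = 500, type = "D3", po2 = 60),
                                 growth = g_imm, seed = 12)
  advance_store(st2, 1000 * 24, g_imm)
  expect_equal(n_cells(st2), 500)
})

test_that("hypoxia onset fires at the configured count and recalibrates pO2", {
  g <- small_growth()   # onset at 2e4 cells
  res <- run_growth(g, dist = po2_distribution("moderate"), seed = 14,
                    target = 2e4)   # stop right at the onset threshold
  expect_equal(res$status, "grown")
  expect_true(tumoursim:::cs_hypoxia_applied(res$store$ptr))
  po2 <- store_po2(res$store)
  n <- length(po2)
  # the freshly allocated population follows the moderate histogram anchors
  anchors <- po2_distribution("moderate")$anchors
  for (j in 2:4) {
    p <- anchors$cum[j]
    expect_equal(mean(po2 <= anchors$po2[j]), p,
                 tolerance = 4 * sqrt(p * (1 - p) / n) / p)
  }
  # a quiescent pool has formed
  expect_gt(sum(census(res$store)[, "HYPOXIC_QUIESCENT"]), 0)
  # growing on, the standing distribution stays close to the anchors;
  # hypoxic cycle slowing over-represents slow low-pO2 cells slightly
  res2 <- run_growth(g, store = res$store, target = 6e4)
  po2b <- store_po2(res2$store)
  for (j in 2:4) {
    expect_equal(mean(po2b <= anchors$po2[j]), anchors$cum[j],
                 tolerance = 0.035 / anchors$cum[j])
  }
  # oxic tumours never leave the uniform 5-100 mmHg distribution
  res_ox <- run_growth(small_growth(), seed = 14, target = 6e4)
  expect_false(tumoursim:::cs_hypoxia_applied(res_ox$store$ptr))
  expect_gte(min(store_po2(res_ox$store)), 5)
})

test_that("onset cannot be applied twice or to an oxic store", {
  g <- small_growth()
  res <- run_growth(g, dist = po2_distribution("moderate"), seed = 16,
                    target = 3e4)
  expect_error(apply_hypoxia_onset(res$store, g), "already")
  res_ox <- run_growth(g, seed = 16, target = 1e3)
  expect_error(apply_hypoxia_onset(res_ox$store, g), "oxic")
})

test_that("hypoxic tumours grow more slowly than oxic ones", {
  g <- small_growth()
  ox <- run_growth(g, seed = 18, target = 1e5)
  hyp <- run_growth(g, dist = po2_distribution("moderate"), seed = 18,
                    target = 1e5)
  expect_equal(ox$status, "grown")
  expect_equal(hyp$status, "grown")
  expect_gt(hyp$time_h, ox$time_h)
})

test_that("pathological parameters lead to reported extinction, not a crash", {
  # every daughter becomes quiescent and necroses: the tumour dies out
  g <- small_growth(quiescence_threshold = 200, quiescence_entry_prob = 1)
  res <- run_growth(g, seed = 20, target = 1e4)
  expect_equal(res$status, "extinct")
  expect_equal(res$total, 0)
})

test_that("growth parameter validation rejects out-of-range values", {
  expect_error(growth_params(spercent = 1.5), "probability")
  expect_error(growth_params(cell_total = 1e5, hypoxia_onset_cells = 1e6),
               "exceed")
  expect_error(growth_params(quiescent_half_life_days = -1))
  expect_error(growth_params(d3_lifespan_days = 0), "Inf")
})
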