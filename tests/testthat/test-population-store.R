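test_that("insertion and next-divider retrieval honour chronological order", {
  st <- cell_store()
  insert_cell(st, cell("S", po2 = 60, next_division_time = 10))
  expect_equal(n_cells(st), 1)
  insert_cell(st, cell("S", po2 = 60, next_division_time = 5))
  expect_equal(n_cells(st), 2)
  expect_equal(pop_next_divider(st)$next_division_time, 5)
  expect_equal(pop_next_divider(st)$next_division_time, 10)
  expect_null(pop_next_divider(st))
})

test_that("pop sequence equals an independent full sort of the times", {
  set.seed(42)
  times <- runif(1000, 0, 500)
  st <- cell_store()
  for (t in times) insert_cell(st, cell("S", po2 = 60, next_division_time = t))
  expect_equal(drain_times(st), sort(times))
})

test_that("tied division times come out in insertion order", {
  st <- cell_store()
  po2s <- c(10, 20, 30)
  for (p in po2s) insert_cell(st, cell("S", po2 = p, next_division_time = 7))
  insert_cell(st, cell("S", po2 = 99, next_division_time = 8))
  got <- c(pop_next_divider(st)$po2, pop_next_divider(st)$po2,
           pop_next_divider(st)$po2)
  expect_equal(got, po2s)
  expect_equal(pop_next_divider(st)$po2, 99)
})

test_that("interleaved insert/pop matches a brute-force priority-queue oracle", {
  set.seed(99)
  st <- cell_store()
  # oracle: data frame ordered by (time, insertion index)
  pend <- data.frame(t = numeric(0), id = integer(0))
  id <- 0L
  clock <- 0
  popped_engine <- numeric(0)
  popped_oracle <- numeric(0)
  for (step in 1:2000) {
    if (nrow(pend) == 0 || runif(1) < 0.6) {
      t <- clock + runif(1, 0, 100)
      id <- id + 1L
      insert_cell(st, cell("S", po2 = 60, next_division_time = t))
      pend <- rbind(pend, data.frame(t = t, id = id))
    } else {
      got <- pop_next_divider(st)
      k <- order(pend$t, pend$id)[1]
      popped_engine <- c(popped_engine, got$next_division_time)
      popped_oracle <- c(popped_oracle, pend$t[k])
      clock <- max(clock, pend$t[k])
      pend <- pend[-k, ]
    }
  }
  expect_equal(popped_engine, popped_oracle)
})

test_that("rejects non-finite division times", {
  st <- cell_store()
  expect_error(insert_cell(st, cell("S", po2 = 60, next_division_time = NaN)),
               "finite")
})

test_that("census is exact for a mixed fixture and sums to the store count", {
  st <- make_fixture_population(
    data.frame(n = c(10, 90, 5), type = c("S", "D3", "T"),
               po2 = c(60, 40, 0.5),
               state = c("CYCLING", "CYCLING", "HYPOXIC_QUIESCENT")),
    seed = 1)
  cen <- census(st)
  expect_equal(sum(cen), n_cells(st))
  expect_equal(sum(cen["S", ]), 10)
  expect_equal(sum(cen["D3", ]), 90)
  expect_equal(unname(cen["T", "HYPOXIC_QUIESCENT"]), 5)
  # percentages over living cells
  expect_equal(100 * sum(cen["S", ]) / sum(cen), 10 / 105 * 100)
})

test_that("empty store censuses to all zeros", {
  expect_true(all(census(cell_store()) == 0))
})

test_that("conservation: growth changes the living count only by division", {
  res <- run_growth(small_growth(), seed = 3, target = 2000)
  expect_equal(res$status, "grown")
  expect_equal(n_cells(res$store), res$total)
  expect_equal(sum(census(res$store)), res$total)
  # counts recorded along the way never decrease by more than deaths allow
  expect_true(all(diff(res$series$time_h) >= 0))
})
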