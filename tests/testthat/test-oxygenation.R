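test_that("OER has the right anchors, limits and monotonicity", {
  expect_equal(oer(0), 1)
  expect_equal(oer(1e9), 0.81 / 0.324, tolerance = 1e-6)  # plateau 2.5
  expect_lt(oer(1e9), 2.5)
  grid <- seq(0, 100, by = 0.25)
  expect_true(all(diff(oer(grid)) > 0))
  # independent evaluation of the rational form at 60 mmHg
  x <- 60 / 0.616
  expect_equal(oer(60), (1 + 0.81 * x) / (1 + 0.324 * x))
})

test_that("lethality factor is the OER normalised at 60 mmHg, clipped at 1", {
  expect_equal(oer_lethality_factor(60), 1)
  expect_equal(oer_lethality_factor(100), 1)
  expect_equal(oer_lethality_factor(0), oer(0) / oer(60))
  grid <- seq(0, 100, by = 0.25)
  leth <- oer_lethality_factor(grid)
  expect_true(all(diff(leth) >= 0))
  expect_true(all(leth > 0 & leth <= 1))
})

test_that("oxic sampler is uniform on 5-100 mmHg", {
  d <- po2_distribution("oxic")
  set.seed(1)
  x <- sample_po2(d, 1e5)
  expect_gte(min(x), 5)
  expect_lte(max(x), 100)
  expect_equal(mean(x <= 52.5), 0.5, tolerance = 0.02)
})

test_that("hypoxic samplers reproduce their published histogram anchors", {
  n <- 1e5
  for (kind in c("moderate", "severe")) {
    anchors <- po2_distribution(kind)$anchors
    set.seed(7)
    x <- sample_po2(po2_distribution(kind), n)
    expect_true(all(x >= 0 & x <= 100))
    for (j in seq_len(nrow(anchors))) {
      p <- anchors$cum[j]
      tol <- 3 * sqrt(p * (1 - p) / n)
      expect_equal(mean(x <= anchors$po2[j]), p, tolerance = tol / p,
                   label = sprintf("%s fraction <= %g mmHg", kind,
                                   anchors$po2[j]))
    }
  }
})

test_that("quantile function is monotone and inverts the sampler", {
  d <- po2_distribution("moderate")
  u <- seq(0.001, 0.999, by = 0.001)
  q <- quantile_po2(d, u)
  expect_true(all(diff(q) >= 0))
  expect_equal(quantile_po2(d, 0.654), 20, tolerance = 1e-3)
})

test_that("pO2 inheritance passes the mother value to exactly one daughter", {
  d <- po2_distribution("oxic")
  set.seed(5)
  expect_identical(inherit_po2(12, 1, d), 12)
  for (i in 1:20) {
    pair <- inherit_po2(12, 2, d)
    expect_length(pair, 2)
    expect_equal(sum(pair == 12), 1)
  }
  expect_error(inherit_po2(12, 3, d), "1 or 2")
})

test_that("retaining daughter is a fair coin", {
  d <- po2_distribution("oxic")
  set.seed(11)
  n <- 4000
  first_retains <- replicate(n, inherit_po2(2.5, 2, d)[1] == 2.5)
  # 3-sigma binomial band around 0.5
  expect_equal(mean(first_retains), 0.5, tolerance = 3 * 0.5 / sqrt(n))
})

test_that("inheritance preserves the marginal pO2 distribution", {
  # a population built purely by inheritance + fresh draws keeps the
  # anchor CDF: every division keeps one old and adds one fresh value
  d <- po2_distribution("moderate")
  set.seed(13)
  pop <- sample_po2(d, 500)
  for (gen in 1:4) {
    daughters <- unlist(lapply(pop, inherit_po2, n_daughters = 2, dist = d))
    pop <- daughters
  }
  n <- length(pop)
  for (j in seq_len(nrow(d$anchors))) {
    p <- d$anchors$cum[j]
    expect_equal(mean(pop <= d$anchors$po2[j]), p,
                 tolerance = 4 * sqrt(p * (1 - p) / n) / p)
  }
})

test_that("pO2 histogram normalises and respects bin edges", {
  h <- po2_histogram(c(1, 1.5, 50, 99.9), bin_width = 2)
  expect_equal(sum(h$fraction), 1)
  expect_equal(h$fraction[h$bin_low_mmHg == 0], 0.5)
  expect_equal(nrow(h), 50)
})
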