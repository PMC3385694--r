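#' Tumour oxygenation distributions
#'
#' Constructs one of the three cellular pO2 distributions used by the
#' simulator. Oxic tumours draw pO2 uniformly on 5--100 mmHg, the range
#' spanned by Eppendorf electrode measurements in head-and-neck tumours.
#' The moderately and severely hypoxic distributions are quantile-anchored
#' samplers that reproduce, by construction, the published histogram
#' fractions of cells below 2, 5, 10 and 20 mmHg (moderate:
#' 7.3/22.1/45.6/65.4%; severe: 9.4/33.2/54.5/69.6%), with a log-normal
#' shaped tail above 20 mmHg truncated at 100 mmHg.
#'
#' Internally the sampler is an inverse-CDF: below 20 mmHg the CDF is a
#' monotone Hermite spline through the anchors (pinned at 0 mmHg), above
#' 20 mmHg it follows the conditional tail of a log-normal fitted to the
#' 10 and 20 mmHg quantiles. A dense quantile table is precomputed so that
#' both the R and C++ samplers draw from exactly the same function.
#'
#' @param kind one of `"oxic"`, `"moderate"`, `"severe"`.
#' @return an object of class `po2_distribution`.
#' @examples
#' d <- po2_distribution("moderate")
#' x <- sample_po2(d, 1000)
#' mean(x <= 10)  # close to 0.456
#' @export
po2_distribution <- function(kind = c("oxic", "moderate", "severe")) {
  kind <- match.arg(kind)
  anchors <- switch(kind,
    oxic = NULL,
    moderate = data.frame(po2 = c(2, 5, 10, 20),
                          cum = c(0.073, 0.221, 0.456, 0.654)),
    severe = data.frame(po2 = c(2, 5, 10, 20),
                        cum = c(0.094, 0.332, 0.545, 0.696))
  )
  obj <- list(kind = kind, anchors = anchors, support = c(0, 100))
  if (kind == "oxic") {
    obj$support <- c(5, 100)
  } else {
    obj$quantile_table <- .po2_quantile_table(anchors)
  }
  class(obj) <- "po2_distribution"
  obj
}

# Dense inverse-CDF table: spline body below 20 mmHg, log-normal tail above.
.po2_quantile_table <- function(anchors) {
  f20 <- anchors$cum[anchors$po2 == 20]
  # log-normal fitted to the 10 and 20 mmHg quantiles
  z10 <- stats::qnorm(anchors$cum[anchors$po2 == 10])
  z20 <- stats::qnorm(f20)
  sigma <- log(2) / (z20 - z10)
  mu <- log(10) - sigma * z10
  p100 <- stats::pnorm((log(100) - mu) / sigma)
  p20 <- stats::pnorm((log(20) - mu) / sigma)  # equals f20 by construction
  # body CDF: monotone spline through (0,0) and the anchors
  body_x <- c(0, anchors$po2)
  body_f <- c(0, anchors$cum)
  cdf_body <- stats::splinefun(body_x, body_f, method = "hyman")
  cdf <- function(x) {
    ifelse(x <= 20,
      pmin(pmax(cdf_body(pmax(x, 0)), 0), f20),
      f20 + (1 - f20) *
        (stats::pnorm((log(pmin(x, 100)) - mu) / sigma) - p20) / (p100 - p20))
  }
  # invert on a dense grid; linear interpolation between nodes
  grid_x <- sort(unique(c(seq(0, 20, by = 0.01), exp(seq(log(20), log(100),
                                                         length.out = 2000)))))
  grid_f <- cdf(grid_x)
  grid_f[length(grid_f)] <- 1
  keep <- c(TRUE, diff(grid_f) > 1e-12)
  list(u = grid_f[keep], q = grid_x[keep], mu = mu, sigma = sigma)
}

#' Draw cellular pO2 values
#'
#' @param dist a [po2_distribution()].
#' @param n number of draws.
#' @return numeric vector of pO2 values in mmHg within the distribution's
#'   support.
#' @export
sample_po2 <- function(dist, n = 1) {
  stopifnot(inherits(dist, "po2_distribution"))
  u <- stats::runif(n)
  quantile_po2(dist, u)
}

#' Quantile function of a pO2 distribution
#'
#' @param dist a [po2_distribution()].
#' @param u probabilities in \[0, 1\].
#' @return pO2 values in mmHg.
#' @export
quantile_po2 <- function(dist, u) {
  stopifnot(inherits(dist, "po2_distribution"))
  if (dist$kind == "oxic") {
    return(5 + 95 * u)
  }
  tab <- dist$quantile_table
  stats::approx(tab$u, tab$q, xout = u, yleft = 0, yright = 100,
                ties = "ordered")$y
}

#' pO2 inheritance at cell division
#'
#' For a single-daughter division the mother's pO2 is passed on unchanged.
#' For a two-daughter division one daughter, chosen by a fair coin, retains
#' the mother's pO2 and the other receives a fresh draw from the tumour's
#' pO2 distribution, so that the population marginal distribution is
#' preserved under pure inheritance.
#'
#' @param mother_po2 mother cell pO2 (mmHg, >= 0).
#' @param n_daughters 1 or 2.
#' @param dist a [po2_distribution()] supplying fresh draws.
#' @return numeric vector of length `n_daughters`.
#' @export
inherit_po2 <- function(mother_po2, n_daughters, dist) {
  stopifnot(mother_po2 >= 0, is.finite(mother_po2))
  if (!n_daughters %in% c(1L, 2L)) {
    stop("n_daughters must be 1 or 2")
  }
  if (n_daughters == 1L) {
    return(mother_po2)
  }
  fresh <- sample_po2(dist, 1)
  if (stats::runif(1) < 0.5) c(mother_po2, fresh) else c(fresh, mother_po2)
}

#' Oxygen enhancement ratio parameters
#'
#' Defaults describe the OER curve used to scale radiation lethality:
#' OER(pO2) = (1 + 0.81 x)/(1 + 0.324 x) with x = pO2/0.616 mmHg, rising
#' from 1 at anoxia towards an asymptote of 2.5, and normalised to 1 at
#' 60 mmHg when converted to a lethality factor.
#'
#' @param c1,c2 numerator and denominator slopes (dimensionless).
#' @param k pO2 scale (mmHg).
#' @param norm_po2 normalisation point of the lethality factor (mmHg).
#' @return an object of class `oer_params`.
#' @export
oer_params <- function(c1 = 0.81, c2 = 0.324, k = 0.616, norm_po2 = 60) {
  stopifnot(c1 > 0, c2 > 0, k > 0, norm_po2 > 0)
  structure(list(c1 = c1, c2 = c2, k = k, norm_po2 = norm_po2),
            class = "oer_params")
}

#' Oxygen enhancement ratio
#'
#' @param po2 pO2 in mmHg (>= 0), vectorised.
#' @param params an [oer_params()].
#' @return OER values in \[1, c1/c2).
#' @export
oer <- function(po2, params = oer_params()) {
  if (any(po2 < 0)) stop("po2 must be non-negative")
  x <- po2 / params$k
  (1 + params$c1 * x) / (1 + params$c2 * x)
}

#' Normalised OER lethality factor
#'
#' The OER curve converted into a multiplicative probability-of-death
#' factor: `oer(po2)/oer(norm_po2)`, clipped at 1 above the normalisation
#' point (60 mmHg by default), so fully oxygenated cells experience the
#' unmodified linear-quadratic kill and hypoxic cells are protected.
#'
#' @inheritParams oer
#' @return factors in (0, 1\].
#' @export
oer_lethality_factor <- function(po2, params = oer_params()) {
  pmin(oer(po2, params) / oer(params$norm_po2, params), 1)
}

#' Histogram of cellular pO2
#'
#' Bins pO2 values into fixed-width bins over \[0, 100\] mmHg, the form in
#' which tumour oxygenation histograms are reported.
#'
#' @param po2 numeric vector of pO2 values.
#' @param bin_width bin width in mmHg (default 2).
#' @return data frame with `bin_low_mmHg`, `bin_high_mmHg`, `fraction`.
#' @export
po2_histogram <- function(po2, bin_width = 2) {
  breaks <- seq(0, 100, by = bin_width)
  counts <- tabulate(findInterval(pmin(po2, 100 - 1e-9), breaks),
                     nbins = length(breaks) - 1)
  data.frame(bin_low_mmHg = breaks[-length(breaks)],
             bin_high_mmHg = breaks[-1],
             fraction = counts / max(sum(counts), 1L))
}
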