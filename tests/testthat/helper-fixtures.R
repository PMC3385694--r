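# shared fixtures: small synthetic populations built in code

fixture_store <- function(n, type = "S", po2 = 60, state = "CYCLING",
                          span = 48, seed = NULL, ...) {
  make_fixture_population(
    data.frame(n = n, type = type, po2 = po2, state = state,
               stringsAsFactors = FALSE),
    time_span_h = span, seed = seed, ...)
}

# small-tumour growth parameters used where full-scale defaults are too big
small_growth <- function(...) {
  growth_params(cell_total = 1e6, hypoxia_onset_cells = 2e4, ...)
}

# memoised default-parameter growth runs shared by the acceptance checks
.run_cache <- new.env(parent = emptyenv())

default_growth_data <- function() {
  if (!exists("gd", envir = .run_cache)) {
    g <- growth_params(cell_total = 1e7)
    comps <- list()
    series <- list()
    store <- NULL
    for (s in 1:3) {
      r <- run_growth(g, seed = 400 + s, target = 1e7)
      stopifnot(r$status == "grown")
      comps[[s]] <- composition(r)
      series[[s]] <- r$series
      if (s == 3) store <- r$store
      rm(r)
      gc(verbose = FALSE)
    }
    assign("gd", list(comps = comps, series = series, store = store,
                      growth = g),
           envir = .run_cache)
  }
  get("gd", envir = .run_cache)
}

# drain a store through pop_next_divider, returning the division times
drain_times <- function(store) {
  out <- numeric(0)
  repeat {
    cell <- pop_next_divider(store)
    if (is.null(cell)) break
    out <- c(out, cell$next_division_time)
  }
  out
}
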