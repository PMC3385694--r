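#' @useDynLib tumoursim, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

.cell_types <- c("S", "T", "D1", "D2", "D3")
.cell_states <- c(CYCLING = 0L, G0 = 1L, HYPOXIC_QUIESCENT = 2L, DEAD = 3L)

.dist_payload <- function(dist) {
  kind_code <- match(dist$kind, c("oxic", "moderate", "severe")) - 1L
  if (kind_code == 0L) {
    list(kind_code = 0L, u = numeric(0), q = numeric(0))
  } else {
    list(kind_code = kind_code, u = dist$quantile_table$u,
         q = dist$quantile_table$q)
  }
}

#' Create an empty cell store
#'
#' The store holds every simulated cell and a division-time ordering so
#' that the next chronological cell due to divide can be retrieved in
#' O(log n). Hypoxia-quiescent cells are kept apart from the cycling
#' population (they carry necrotic death events instead of division
#' events) and are reported separately by [census()].
#'
#' @param dist the tumour's [po2_distribution()]; fresh pO2 draws at
#'   division come from it once hypoxia onset has been applied, and from
#'   the oxic uniform distribution before.
#' @param hypoxia_applied logical; set `TRUE` when building a fixture that
#'   should sample immediately from a hypoxic distribution.
#' @return an object of class `cell_store`.
#' @export
cell_store <- function(dist = po2_distribution("oxic"),
                       hypoxia_applied = FALSE) {
  stopifnot(inherits(dist, "po2_distribution"))
  structure(list(ptr = cs_new(.dist_payload(dist), hypoxia_applied),
                 dist = dist),
            class = "cell_store")
}

#' Construct a cell description
#'
#' @param type one of `"S"` (stem), `"T"` (transit), `"D1"`, `"D2"`
#'   (differentiating), `"D3"` (fully differentiated).
#' @param po2 cellular pO2 in mmHg.
#' @param state `"CYCLING"` or `"HYPOXIC_QUIESCENT"` (G0 is derived from
#'   the cycle timing; dead cells are not stored).
#' @param generation transit generation counter (S cells: 0).
#' @param next_division_time simulation time (hours) of the cell's next
#'   division; for quiescent and D3 cells this is the scheduled necrotic
#'   death time.
#' @param cycle_start time the cell leaves G0 and enters the cycle;
#'   defaults to `-Inf` (already cycling).
#' @return a `cell` list.
#' @export
cell <- function(type, po2, state = "CYCLING", generation = 0,
                 next_division_time = 0, cycle_start = -Inf) {
  type <- match.arg(type, .cell_types)
  state <- match.arg(state, c("CYCLING", "HYPOXIC_QUIESCENT"))
  stopifnot(po2 >= 0, is.finite(po2), generation >= 0)
  structure(list(type = type, state = state, po2 = po2,
                 generation = as.integer(generation),
                 next_division_time = next_division_time,
                 cycle_start = cycle_start),
            class = "cell")
}

#' Insert a cell into the store
#'
#' @param store a [cell_store()].
#' @param x a [cell()].
#' @return the slot handle (integer), invisibly.
#' @export
insert_cell <- function(store, x) {
  stopifnot(inherits(store, "cell_store"), inherits(x, "cell"))
  if (!is.finite(x$next_division_time) && x$type != "D3") {
    stop("next_division_time must be finite")
  }
  invisible(cs_insert(store$ptr, match(x$type, .cell_types) - 1L,
                      .cell_states[[x$state]], x$po2, x$generation,
                      x$next_division_time, x$cycle_start))
}

#' Pop the next chronological cell due to divide
#'
#' Removes and returns the cycling cell with the smallest scheduled
#' division time (ties broken by insertion order). Necrotic death events
#' (quiescent and D3 cells) falling before that division are processed on
#' the way. Returns `NULL` when nothing is left to divide.
#'
#' @param store a [cell_store()].
#' @return a `cell`-like list, or `NULL` if the store is exhausted.
#' @export
pop_next_divider <- function(store) {
  stopifnot(inherits(store, "cell_store"))
  res <- cs_pop_next_divider(store$ptr)
  if (is.null(res)) return(NULL)
  res$type <- .cell_types[res$type + 1L]
  res$state <- names(.cell_states)[match(res$state, .cell_states)]
  res
}

#' Census of the living population
#'
#' @param store a [cell_store()].
#' @return a 5 x 3 matrix of counts, cell types (S, T, D1, D2, D3) by
#'   state (CYCLING, G0, HYPOXIC_QUIESCENT). Dead cells are not counted.
#' @export
census <- function(store) {
  stopifnot(inherits(store, "cell_store"))
  m <- cs_census(store$ptr)
  dimnames(m) <- list(.cell_types, c("CYCLING", "G0", "HYPOXIC_QUIESCENT"))
  m
}

#' Quick population counts
#'
#' @param store a [cell_store()].
#' @return named vector: live cells per type (quiescent counted in the
#'   `q_*` entries) and the living total.
#' @export
store_counts <- function(store) {
  stopifnot(inherits(store, "cell_store"))
  cs_counts(store$ptr)
}

#' Number of living cells
#' @param store a [cell_store()].
#' @return integer-valued count.
#' @export
n_cells <- function(store) unname(store_counts(store)["total"])

#' Deep-copy a cell store
#'
#' Useful for treating the same grown tumour under several schedules.
#'
#' @param store a [cell_store()].
#' @return an independent `cell_store`.
#' @export
clone_store <- function(store) {
  stopifnot(inherits(store, "cell_store"))
  structure(list(ptr = cs_clone(store$ptr), dist = store$dist),
            class = "cell_store")
}

#' pO2 values of the living population
#'
#' @param store a [cell_store()].
#' @param include_quiescent include the hypoxia-quiescent pool.
#' @return numeric vector of pO2 in mmHg.
#' @export
store_po2 <- function(store, include_quiescent = TRUE) {
  stopifnot(inherits(store, "cell_store"))
  cs_po2_values(store$ptr, include_quiescent)
}

#' pO2 values of the hypoxia-quiescent pool
#' @param store a [cell_store()].
#' @return numeric vector of pO2 in mmHg.
#' @export
quiescent_po2 <- function(store) {
  stopifnot(inherits(store, "cell_store"))
  cs_quiescent_po2(store$ptr)
}

#' @export
print.cell_store <- function(x, ...) {
  ct <- store_counts(x)
  cat("<cell_store>", format(ct[["total"]], big.mark = ","),
      "living cells at t =", round(cs_now(x$ptr), 1), "h\n")
  print(ct)
  invisible(x)
}
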