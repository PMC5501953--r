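#' Simulate cell dispensing into nanowells
#'
#' Cells are deposited by limiting dilution, so the number of cells per
#' well is modelled as i.i.d. Poisson with mean `lambda`. At the
#' dilution used in practice (lambda near 1) about one third of wells
#' receive exactly one cell. Each dispensed cell is independently viable
#' (Hoechst-positive, PI-negative) with probability `live_fraction`.
#'
#' @param layout a [chip_layout()]
#' @param lambda Poisson mean cells per well (> 0)
#' @param live_fraction probability a dispensed cell is live, between 0 and 1
#' @param species character vector of species labels to assign cells
#'   (uniformly at random); default single label "A"
#' @param seed RNG seed
#' @return a `sim_truth` list with elements:
#'   * `wells`: `data.table(row_, col_, well, barcode, sample_id,
#'     n_cells, n_live, doublet)` — `doublet` flags wells with >= 2 cells
#'   * `cells`: one row per dispensed cell
#'     (`cell_id, row_, col_, well, barcode, sample_id, live, species`)
#' @examples
#' truth <- simulate_dispense(chip_layout(12, 12), lambda = 1, seed = 3)
#' table(truth$wells$n_cells)
#' @export
simulate_dispense <- function(layout, lambda = 1, live_fraction = 0.9,
                              species = "A", seed = 1L) {
  stopifnot(inherits(layout, "chip_layout"))
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda <= 0)
    stop("lambda must be a positive number")
  if (live_fraction < 0 || live_fraction > 1)
    stop("live_fraction must be in [0, 1]")
  wells <- data.table::copy(layout$wells)
  withr::with_seed(seed, {
    wells[, n_cells := stats::rpois(.N, lambda)]
    cells <- wells[rep(seq_len(.N), n_cells),
                   .(row_, col_, well, barcode, sample_id)]
    cells[, cell_id := sprintf("cell%05d", seq_len(.N))]
    cells[, live := stats::runif(.N) < live_fraction]
    cells[, species := sample(species, .N, replace = TRUE)]
  })
  live_by_well <- cells[, .(n_live = sum(live)), by = well]
  wells[live_by_well, n_live := i.n_live, on = "well"]
  wells[is.na(n_live), n_live := 0L]
  wells[, doublet := n_cells >= 2L]
  structure(list(wells = wells[], cells = cells[]), class = "sim_truth")
}

#' Wells containing exactly one live cell (and nothing else)
#'
#' The selection target for downstream processing: wells whose entire
#' content is a single viable cell.
#'
#' @param truth a `sim_truth` from [simulate_dispense()]
#' @return `data.table` subset of `truth$wells`
#' @export
single_live_cell_wells <- function(truth) {
  ok <- truth$cells[, .(one_live = .N == 1L && all(live)), by = well][one_live == TRUE]
  truth$wells[well %in% ok$well]
}
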