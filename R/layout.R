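#' Generate well barcodes with a minimum pairwise Hamming distance
#'
#' Barcodes are drawn uniformly over DNA `len`-mers and accepted by
#' rejection so that every retained pair differs at `min_dist` or more
#' positions. Separable barcodes are what makes perfect-match
#' demultiplexing (no error correction) a sound design: a single
#' sequencing error can never convert one well barcode into another.
#'
#' @param n number of barcodes
#' @param len barcode length in bases (default 11)
#' @param min_dist minimum pairwise Hamming distance (default 3)
#' @param seed integer RNG seed
#' @return character vector of `n` distinct barcodes
#' @export
generate_barcodes <- function(n, len = 11L, min_dist = 3L, seed = 1L) {
  stopifnot(n >= 1, len >= 1, min_dist >= 1)
  if (4^len < n) stop("barcode space too small for ", n, " barcodes")
  withr::with_seed(seed, {
    bc <- unique(random_dna(ceiling(n * 1.2) + 8L, len))
    repeat {
      d <- hamming_matrix(bc)
      bad <- which(d < min_dist & upper.tri(d), arr.ind = TRUE)
      if (nrow(bad) > 0L) bc <- bc[-unique(bad[, 2L])]
      if (length(bc) >= n) return(bc[seq_len(n)])
      bc <- unique(c(bc, random_dna(2L * (n - length(bc)) + 8L, len)))
    }
  })
}

#' Microchip layout: well grid, barcode map and sample regions
#'
#' Describes a nanowell microchip: an `n_rows` x `n_cols` grid of wells
#' (default 72 x 72 = 5184 wells of 150 nl), a per-well 11-base DNA
#' barcode (unique across the chip, minimum pairwise Hamming distance 3),
#' and an assignment of wells to up to 8 dispensed samples as vertical
#' bands of columns.
#'
#' @param n_rows,n_cols grid dimensions (default 72 x 72)
#' @param well_volume well volume in nanoliters (metadata only)
#' @param n_samples number of dispensed samples, at most 8; wells are
#'   split into `n_samples` contiguous column bands labelled "S1".."S8"
#' @param barcode_len barcode length in bases
#' @param seed RNG seed for barcode generation
#' @return an object of class `chip_layout`: a list with `n_rows`,
#'   `n_cols`, `well_volume`, and `wells`, a `data.table` with columns
#'   `row_`, `col_`, `well` (id string "R01C01" style), `barcode`,
#'   `sample_id`
#' @examples
#' layout <- chip_layout(n_rows = 12, n_cols = 12)
#' nrow(layout$wells) # 144
#' @export
chip_layout <- function(n_rows = 72L, n_cols = 72L, well_volume = 150,
                        n_samples = 1L, barcode_len = 11L, seed = 1L) {
  stopifnot(n_rows >= 1, n_cols >= 1, n_samples >= 1)
  if (n_samples > 8L) stop("at most 8 samples can be dispensed on one chip")
  n <- as.integer(n_rows) * as.integer(n_cols)
  bc <- generate_barcodes(n, len = barcode_len, seed = seed)
  wells <- data.table::CJ(row_ = seq_len(n_rows), col_ = seq_len(n_cols))
  wells[, well := sprintf("R%02dC%02d", row_, col_)]
  wells[, barcode := bc]
  band <- pmin(ceiling(wells$col_ / (n_cols / n_samples)), n_samples)
  wells[, sample_id := sprintf("S%d", band)]
  out <- list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
              well_volume = well_volume, wells = wells[])
  class(out) <- "chip_layout"
  out
}

#' @export
print.chip_layout <- function(x, ...) {
  cat(sprintf("chip_layout: %d x %d wells (%d total), %d sample(s), %d nl/well\n",
              x$n_rows, x$n_cols, nrow(x$wells),
              length(unique(x$wells$sample_id)), x$well_volume))
  invisible(x)
}

#' Write / read a well-barcode map as TSV
#'
#' Columns: `row`, `col`, `barcode`, `sample`. Reading validates barcode
#' uniqueness (a duplicate barcode makes demultiplexing ill-defined and
#' is a hard error).
#'
#' @param layout a [chip_layout()]
#' @param path output TSV path
#' @return `write_barcode_map` returns `path`; `read_barcode_map` returns
#'   a `data.table` with columns `row_`, `col_`, `barcode`, `sample_id`
#' @export
write_barcode_map <- function(layout, path) {
  stopifnot(inherits(layout, "chip_layout"))
  out <- layout$wells[, .(row = row_, col = col_, barcode, sample = sample_id)]
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' @rdname write_barcode_map
#' @export
read_barcode_map <- function(path) {
  m <- data.table::fread(path, sep = "\t",
                         colClasses = list(character = c("barcode", "sample")))
  data.table::setnames(m, c("row", "col", "sample"), c("row_", "col_", "sample_id"))
  if (anyDuplicated(m$barcode))
    stop("duplicate barcode in map: ", m$barcode[duplicated(m$barcode)][1])
  m[]
}
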