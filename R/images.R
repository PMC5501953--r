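#' Render two-channel well images for a dispensed chip
#'
#' Emulates the chip imaging step: wells are tiled into fields of 6 x 6
#' wells, each field photographed once per channel (channel 1 = Hoechst,
#' stains every cell; channel 2 = PI, stains dead cells only — a
#' 72 x 72 chip gives 144 fields, 288 images in total). Every cell is a
#' Gaussian intensity blob at a random position inside its well; dead
#' cells appear in both channels. Images carry a constant background
#' plus Gaussian noise with standard deviation `amplitude / snr`
#' (`snr = Inf` gives noiseless images), and intensities are clamped to
#' the unit interval for 16-bit storage.
#'
#' @param truth a `sim_truth` from [simulate_dispense()]
#' @param layout the matching [chip_layout()]; `n_rows` and `n_cols`
#'   must be multiples of 6
#' @param optics list: `blob_sigma` (px), `snr`, `well_px` (pixels per
#'   well side), `amplitude`, `background`
#' @param seed RNG seed
#' @param dir if non-NULL, write one 16-bit TIFF per field per channel
#' @return `well_images` list: `ch1`, `ch2` (lists of field matrices),
#'   `objects` truth table (field, channel, row_, col_, cx, cy,
#'   cell_id), `fields` geometry table, `optics`
#' @export
render_well_images <- function(truth, layout,
                               optics = list(blob_sigma = 2, snr = 10,
                                             well_px = 24, amplitude = 0.5,
                                             background = 0.1),
                               seed = 1L, dir = NULL) {
  stopifnot(inherits(layout, "chip_layout"))
  o <- utils::modifyList(list(blob_sigma = 2, snr = 10, well_px = 24,
                              amplitude = 0.5, background = 0.1), optics)
  if (o$snr <= 0) stop("SNR must be positive")
  if (layout$n_rows %% 6L != 0L || layout$n_cols %% 6L != 0L)
    stop("chip dimensions must be multiples of the 6 x 6 field size")
  fr <- layout$n_rows %/% 6L; fc <- layout$n_cols %/% 6L
  wp <- o$well_px; fpx <- 6L * wp
  noise_sd <- if (is.finite(o$snr)) o$amplitude / o$snr else 0

  fields <- data.table::CJ(frow = seq_len(fr), fcol = seq_len(fc))
  fields[, field := seq_len(.N)]
  cells <- data.table::copy(truth$cells)
  cells[, `:=`(frow = (row_ - 1L) %/% 6L + 1L, fcol = (col_ - 1L) %/% 6L + 1L)]
  cells <- merge(cells, fields, by = c("frow", "fcol"))

  withr::with_seed(seed, {
    # four quadrant slots per well (pairwise separation 0.4 * well_px,
    # comfortably above the ~2.8 sigma radius of a blob's positive LoG
    # lobe at the default geometry); beyond four cells, cells stack on
    # occupied slots, as piled-up cells do
    slots <- cbind(c(0.3, 0.3, 0.7, 0.7), c(0.3, 0.7, 0.3, 0.7)) * wp
    place_well <- function(k) {
      if (k == 0L) return(matrix(numeric(0), 0L, 2L))
      idx <- if (k <= 4L) sample.int(4L, k) else
        c(sample.int(4L), sample.int(4L, k - 4L, replace = TRUE))
      slots[idx, , drop = FALSE] + matrix(stats::runif(2L * k, -1, 1), k, 2L)
    }
    cells[, c("dy", "dx") := {
      p <- place_well(.N)
      list(p[, 1L], p[, 2L])
    }, by = well]
    cells[, cy := ((row_ - 1L) %% 6L) * wp + dy]
    cells[, cx := ((col_ - 1L) %% 6L) * wp + dx]
    cells[, c("dy", "dx") := NULL]
    blob <- function(img, cx, cy) {
      r <- ceiling(4 * o$blob_sigma)
      xs <- max(1, floor(cx - r)):min(fpx, ceiling(cx + r))
      ys <- max(1, floor(cy - r)):min(fpx, ceiling(cy + r))
      g <- outer(ys - cy, xs - cx, function(dy, dx)
        exp(-(dx^2 + dy^2) / (2 * o$blob_sigma^2)))
      img[ys, xs] <- img[ys, xs] + o$amplitude * g
      img
    }
    ch1 <- vector("list", nrow(fields)); ch2 <- vector("list", nrow(fields))
    for (f in fields$field) {
      i1 <- matrix(o$background, fpx, fpx)
      i2 <- matrix(o$background, fpx, fpx)
      fc_cells <- cells[field == f]
      for (i in seq_len(nrow(fc_cells))) {
        i1 <- blob(i1, fc_cells$cx[i], fc_cells$cy[i])
        if (!fc_cells$live[i]) i2 <- blob(i2, fc_cells$cx[i], fc_cells$cy[i])
      }
      if (noise_sd > 0) {
        i1 <- i1 + matrix(stats::rnorm(fpx * fpx, 0, noise_sd), fpx)
        i2 <- i2 + matrix(stats::rnorm(fpx * fpx, 0, noise_sd), fpx)
      }
      ch1[[f]] <- pmin(pmax(i1, 0), 1)
      ch2[[f]] <- pmin(pmax(i2, 0), 1)
    }
  })
  objects <- data.table::rbindlist(list(
    cells[, .(field, channel = 1L, row_, col_, cx, cy, cell_id)],
    cells[live == FALSE, .(field, channel = 2L, row_, col_, cx, cy, cell_id)]))
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (f in fields$field) {
      tiff::writeTIFF(ch1[[f]], file.path(dir, sprintf("field%03d_ch1.tif", f)),
                      bits.per.sample = 16L)
      tiff::writeTIFF(ch2[[f]], file.path(dir, sprintf("field%03d_ch2.tif", f)),
                      bits.per.sample = 16L)
    }
  }
  structure(list(ch1 = ch1, ch2 = ch2, objects = objects, fields = fields,
                 optics = o, n_rows = layout$n_rows, n_cols = layout$n_cols),
            class = "well_images")
}

#' Read a directory of per-field TIFF images into a `well_images` object
#'
#' Expects files named `field%03d_ch1.tif` / `field%03d_ch2.tif` as
#' written by [render_well_images()].
#'
#' @param dir directory of TIFFs
#' @param n_rows,n_cols chip dimensions (multiples of 6)
#' @param well_px pixels per well side
#' @return `well_images` list (without truth objects)
#' @export
read_well_images <- function(dir, n_rows, n_cols, well_px = 24) {
  fr <- n_rows %/% 6L; fc <- n_cols %/% 6L
  fields <- data.table::CJ(frow = seq_len(fr), fcol = seq_len(fc))
  fields[, field := seq_len(.N)]
  ch1 <- lapply(fields$field, function(f)
    tiff::readTIFF(file.path(dir, sprintf("field%03d_ch1.tif", f))))
  ch2 <- lapply(fields$field, function(f)
    tiff::readTIFF(file.path(dir, sprintf("field%03d_ch2.tif", f))))
  structure(list(ch1 = ch1, ch2 = ch2, objects = NULL, fields = fields,
                 optics = list(well_px = well_px), n_rows = n_rows,
                 n_cols = n_cols), class = "well_images")
}
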