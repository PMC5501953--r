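gaussian_blob <- function(size, cy, cx, sigma, amp = 1) {
  outer(seq_len(size), seq_len(size), function(y, x)
    amp * exp(-((y - cy)^2 + (x - cx)^2) / (2 * sigma^2)))
}

test_that("LoG response is zero on constants and peaks at matched blobs", {
  const <- matrix(0.3, 40, 40)
  resp <- log_response(const, 2)
  expect_lt(max(abs(resp)), 1e-9 * 0.3)
  expect_error(log_response(const, -1), "positive")
  # planted blob of sigma s: maximum within 1 pixel of the center
  img <- 0.1 + gaussian_blob(41, 20.5, 23.5, sigma = 3)
  r <- log_response(img, 3)
  peak <- which(r == max(r), arr.ind = TRUE)[1, ]
  expect_lt(max(abs(peak - c(20.5, 23.5))), 1)
  # two well-separated blobs give two objects above threshold
  img2 <- 0.1 + gaussian_blob(60, 15, 15, 2) + gaussian_blob(60, 45, 45, 2)
  obj <- segment_objects(log_response(img2, 2), segmentation_config(min_area = 2))
  expect_equal(nrow(obj[kept == TRUE]), 2L)
})

test_that("blank noise at a 5-SD threshold yields no objects", {
  set.seed(41)
  hits <- replicate(20, {
    img <- matrix(rnorm(80 * 80, 0.2, 0.02), 80)
    r <- log_response(img, 2)
    cfg <- segmentation_config(threshold = 5 * sd(r), min_area = 1)
    nrow(segment_objects(r, cfg)[kept == TRUE])
  })
  expect_gte(mean(hits == 0), 0.95)
})

test_that("size and shape bounds reject objects", {
  img <- 0.1 + gaussian_blob(40, 20, 20, 2)
  r <- log_response(img, 2)
  none <- segment_objects(r, segmentation_config(min_area = 10000L,
                                                 max_area = 10001L))
  expect_equal(sum(none$kept), 0L)
  # eccentric streak rejected by the shape bound
  streak <- matrix(0.1, 40, 40); streak[20, 5:35] <- 1
  robj <- segment_objects(log_response(streak, 2),
                          segmentation_config(min_area = 2, max_eccentricity = 0.8))
  expect_true(all(!robj$kept | robj$eccentricity <= 0.8))
  expect_true(any(!robj$kept))
})

test_that("planted single-cell wells are detected with one object at SNR 10", {
  layout <- chip_layout(12, 12, seed = 3)
  truth <- simulate_dispense(layout, lambda = 0.8, seed = 4)
  img <- render_well_images(truth, layout, optics = list(snr = 10), seed = 5)
  calls <- call_wells(img)
  singles <- single_live_cell_wells(truth)
  got <- merge(calls, singles[, .(row_, col_)], by = c("row_", "col_"))
  expect_gte(mean(got$n_ch1 == 1L), 0.99)
})

test_that("well calls implement the one-live-no-dead selection logic", {
  layout <- chip_layout(6, 6, seed = 7)
  # wells: R1C1 one live; R1C2 one live + one dead; R2C1 empty chip area
  cells <- data.table(
    row_ = c(1L, 1L, 1L), col_ = c(1L, 2L, 2L),
    well = c("R01C01", "R01C02", "R01C02"),
    barcode = layout$wells$barcode[c(1, 2, 2)],
    sample_id = "S1", cell_id = c("a", "b", "c"),
    live = c(TRUE, TRUE, FALSE), species = "A")
  wells <- data.table::copy(layout$wells)
  wells[, n_cells := c(1L, 2L, rep(0L, 34))]
  wells[, n_live := c(1L, 1L, rep(0L, 34))]
  wells[, doublet := n_cells >= 2]
  truth <- structure(list(wells = wells, cells = cells), class = "sim_truth")
  img <- render_well_images(truth, layout, optics = list(snr = Inf), seed = 8)
  calls <- call_wells(img)
  expect_true(calls[row_ == 1 & col_ == 1, selected])
  expect_false(calls[row_ == 1 & col_ == 2, selected])
  expect_equal(calls[row_ == 1 & col_ == 2, reason], "PI-positive")
  expect_equal(sum(calls$selected), 1L)
  # empty chip selects nothing
  empty <- simulate_dispense(layout, lambda = 1e-9, seed = 9)
  img0 <- render_well_images(empty, layout, optics = list(snr = Inf), seed = 10)
  calls0 <- call_wells(img0)
  expect_equal(sum(calls0$selected), 0L)
})

test_that("noiseless selection recovers exactly the single-live-cell wells", {
  layout <- chip_layout(12, 12, seed = 11)
  truth <- simulate_dispense(layout, lambda = 1, live_fraction = 0.85, seed = 12)
  img <- render_well_images(truth, layout, optics = list(snr = Inf), seed = 13)
  calls <- select_wells(img, layout)
  singles <- single_live_cell_wells(truth)
  expect_setequal(calls[selected == TRUE, paste(row_, col_)],
                  singles[, paste(row_, col_)])
  # selected wells can never exceed wells with a channel-1 object
  expect_lte(sum(calls$selected), sum(calls$n_ch1 >= 1))
})

test_that("auto-threshold selection is invariant to affine intensity rescaling", {
  layout <- chip_layout(6, 6, seed = 15)
  truth <- simulate_dispense(layout, lambda = 1, seed = 16)
  img <- render_well_images(truth, layout, optics = list(snr = 20), seed = 17)
  base <- call_wells(img)
  scaled <- img
  scaled$ch1 <- lapply(img$ch1, function(x) 0.45 * x + 0.08)
  scaled$ch2 <- lapply(img$ch2, function(x) 0.45 * x + 0.08)
  resc <- call_wells(scaled)
  expect_equal(resc$selected, base$selected)
  expect_equal(resc$n_ch1, base$n_ch1)
})

test_that("dispense file lists selected wells and fits lambda by MLE", {
  layout <- chip_layout(24, 24, seed = 18)
  truth <- simulate_dispense(layout, lambda = 1, seed = 19)
  img <- render_well_images(truth, layout, optics = list(snr = Inf), seed = 20)
  calls <- select_wells(img, layout)
  path <- withr::local_tempfile(fileext = ".tsv")
  out <- write_dispense_file(calls, path)
  disp <- data.table::fread(path)
  expect_equal(nrow(disp), sum(calls$selected))
  expect_setequal(disp$barcode, calls[selected == TRUE, barcode])
  expect_named(out$summary$occupancy_histogram, c("0", "1", "2", "3", "4+"))
  expect_lt(abs(out$summary$lambda_mle - mean(truth$wells$n_cells)), 0.05)
})

test_that("rendered fields count 36 wells each and survive TIFF round trips", {
  layout <- chip_layout(12, 12, seed = 21)
  expect_equal((layout$n_rows * layout$n_cols) / 36, nrow(
    render_well_images(simulate_dispense(layout, 1e-9, seed = 1), layout,
                       optics = list(snr = Inf), seed = 2)$fields))
  # a 72x72 chip maps to 144 fields per channel
  ly <- full_layout()
  expect_equal((ly$n_rows %/% 6) * (ly$n_cols %/% 6), 144)
  truth <- simulate_dispense(layout, lambda = 0.7, seed = 22)
  dir <- withr::local_tempdir()
  img <- render_well_images(truth, layout, optics = list(snr = 15), seed = 23,
                            dir = dir)
  expect_length(list.files(dir, pattern = "_ch1\\.tif$"), 4L)
  back <- read_well_images(dir, 12, 12, well_px = img$optics$well_px)
  # 16-bit quantization: intensities match to 1/65535
  expect_lt(max(abs(back$ch1[[1]] - img$ch1[[1]])), 1 / 65535 + 1e-9)
  c1 <- call_wells(img); c2 <- call_wells(back)
  expect_equal(c2$selected, c1$selected)
})
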