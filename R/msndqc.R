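#' Simulate a dispenser checkerboard QC assay
#'
#' Lays out the standard checkerboard chip: one half of the 72 x 72
#' chip receives no-template control mix (NTC wells, n = 2520 by
#' default), the other half alternates lambda-DNA positive mix
#' (n = 1024) with no-template test wells (n = 1496); remaining wells
#' (fiducials and controls) are unused. Positive wells amplify with Ct
#' and Tm drawn from the positive models. A `true_misalignment` fraction
#' of Test wells receives contaminating positive mix (positive-like Ct
#' and Tm); a `background_rate` of spurious signal (off-target Tm, e.g.
#' primer dimers) applies equally to Test and NTC wells, which is
#' exactly what the Test-minus-NTC difference estimator corrects for.
#'
#' @param n_ntc,n_positive,n_test well counts (must fit on the chip)
#' @param n_rows,n_cols chip dimensions
#' @param true_misalignment probability a Test well is contaminated
#' @param background_rate probability of spurious signal in Test/NTC
#' @param ct_model,tm_model lists of `mean`/`sd` for positive
#'   amplification Ct and Tm
#' @param background_ct,background_tm models for spurious signal
#' @param seed RNG seed
#' @return `data.table(row_, col_, well_class, ct, tm, truth)` where
#'   `truth` is "clean", "misaligned" or "background"
#' @export
simulate_checkerboard <- function(n_ntc = 2520L, n_positive = 1024L,
                                  n_test = 1496L, n_rows = 72L, n_cols = 72L,
                                  true_misalignment = 0.001,
                                  background_rate = 0.001,
                                  ct_model = list(mean = 20, sd = 1),
                                  tm_model = list(mean = 85, sd = 0.3),
                                  background_ct = list(mean = 32, sd = 1.5),
                                  background_tm = list(mean = 78, sd = 1),
                                  seed = 1L) {
  n_wells <- n_rows * n_cols
  if (n_ntc + n_positive + n_test > n_wells)
    stop("well classes do not fit on the chip")
  wells <- data.table::CJ(row_ = seq_len(n_rows), col_ = seq_len(n_cols))
  cls <- rep("unused", n_wells)
  cls[seq_len(n_ntc)] <- "NTC"
  # second half: checkerboard of Positive and Test
  rest <- seq.int(n_ntc + 1L, n_ntc + n_positive + n_test)
  parity <- (wells$row_[rest] + wells$col_[rest]) %% 2L == 0L
  pos_idx <- rest[parity][seq_len(min(n_positive, sum(parity)))]
  if (length(pos_idx) < n_positive)
    pos_idx <- c(pos_idx, setdiff(rest, pos_idx)[seq_len(n_positive - length(pos_idx))])
  cls[pos_idx] <- "Positive"
  cls[setdiff(rest, pos_idx)] <- "Test"
  wells[, well_class := cls]
  wells[, `:=`(ct = NA_real_, tm = NA_real_, truth = "clean")]
  withr::with_seed(seed, {
    pos <- wells$well_class == "Positive"
    wells$ct[pos] <- stats::rnorm(sum(pos), ct_model$mean, ct_model$sd)
    wells$tm[pos] <- stats::rnorm(sum(pos), tm_model$mean, tm_model$sd)
    mis <- wells$well_class == "Test" & stats::runif(n_wells) < true_misalignment
    # contaminating positive mix: slightly diluted, so later Ct
    wells$ct[mis] <- stats::rnorm(sum(mis), ct_model$mean + 4, ct_model$sd)
    wells$tm[mis] <- stats::rnorm(sum(mis), tm_model$mean, tm_model$sd)
    wells$truth[mis] <- "misaligned"
    bg <- wells$well_class %in% c("Test", "NTC") & !mis &
      stats::runif(n_wells) < background_rate
    wells$ct[bg] <- stats::rnorm(sum(bg), background_ct$mean, background_ct$sd)
    wells$tm[bg] <- stats::rnorm(sum(bg), background_tm$mean, background_tm$sd)
    wells$truth[bg] <- "background"
  })
  wells[]
}

#' Melt-curve filter for checkerboard wells
#'
#' Builds the acceptance window mean(Tm) +/- 3 SD from Positive wells
#' (sample SD, n - 1 denominator) and excludes Test/NTC wells whose
#' signal melts outside it — off-target products such as primer dimers
#' rather than true cross-contamination. Wells without signal are
#' unaffected; Positive wells are never excluded.
#'
#' @param wells checkerboard table with `well_class`, `ct`, `tm`
#' @param n_sd window half-width in SD units (default 3)
#' @return the table with a logical `keep` column
#' @export
melt_filter <- function(wells, n_sd = 3) {
  wells <- data.table::as.data.table(wells)
  pos_tm <- wells[well_class == "Positive" & !is.na(tm), tm]
  if (length(pos_tm) < 2L) stop("need >= 2 Positive wells with Tm")
  ctr <- mean(pos_tm); s <- stats::sd(pos_tm)
  lo <- ctr - n_sd * s; hi <- ctr + n_sd * s
  wells[, keep := well_class == "Positive" | is.na(tm) | (tm >= lo & tm <= hi)]
  wells[]
}

#' Dispense-tip misalignment percentage
#'
#' A well "shows signal" when it has a Ct at or below `max_ct`. The
#' misalignment estimate is the percentage of Test wells with signal
#' minus the percentage of NTC wells with signal (NTC signal measures
#' background unrelated to tip misalignment). Wells removed by
#' [melt_filter()] are excluded from both numerator and denominator.
#' Negative values are reported as computed, not clamped.
#'
#' @param wells checkerboard table, ideally after [melt_filter()]
#' @param max_ct largest Ct accepted as signal (default 35)
#' @return list(`misalignment_pct`, `pct_test_signal`, `pct_ntc_signal`,
#'   `n_test`, `n_ntc`)
#' @export
misalignment_pct <- function(wells, max_ct = 35) {
  wells <- data.table::as.data.table(wells)
  if (!"keep" %in% names(wells)) wells[, keep := TRUE]
  w <- wells[keep == TRUE]
  sig <- !is.na(w$ct) & w$ct <= max_ct
  n_test <- sum(w$well_class == "Test")
  n_ntc <- sum(w$well_class == "NTC")
  p_test <- 100 * sum(sig & w$well_class == "Test") / n_test
  p_ntc <- 100 * sum(sig & w$well_class == "NTC") / n_ntc
  list(misalignment_pct = p_test - p_ntc, pct_test_signal = p_test,
       pct_ntc_signal = p_ntc, n_test = n_test, n_ntc = n_ntc)
}
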