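#' Segmentation configuration for well-image cell detection
#'
#' @param log_scale blob scale sigma in pixels for the LoG filter
#'   (user-selectable; match the expected cell radius)
#' @param threshold LoG response cutoff, or "auto" for a robust
#'   data-driven threshold: median + `auto_k` * MAD of the response,
#'   floored at a small fraction of the response range so that exactly
#'   noiseless images (MAD = 0) still threshold above numerical ripple.
#'   Both terms scale with the image, so auto-threshold selection is
#'   invariant to affine intensity rescaling.
#' @param auto_k MAD multiplier for the auto threshold (default 5)
#' @param min_area,max_area object size bounds in pixels
#' @param max_eccentricity shape bound in [0, 1); eccentricity comes
#'   from the second central moments of the object's pixels
#' @param debris_factor a size/shape-rejected object whose peak response
#'   exceeds `debris_factor` times the threshold is bright debris; wells
#'   containing one are excluded from selection
#' @return validated `segmentation_config` list
#' @export
segmentation_config <- function(log_scale = 2, threshold = "auto",
                                auto_k = 5, min_area = 4L, max_area = 400L,
                                max_eccentricity = 0.95, debris_factor = 2) {
  stopifnot(log_scale > 0, min_area < max_area,
            max_eccentricity >= 0, max_eccentricity < 1)
  structure(list(log_scale = log_scale, threshold = threshold,
                 auto_k = auto_k, min_area = as.integer(min_area),
                 max_area = as.integer(max_area),
                 max_eccentricity = max_eccentricity,
                 debris_factor = debris_factor),
            class = "segmentation_config")
}

# 2D convolution, 'same' output, replicate-padded borders, via FFT
conv2_same <- function(img, kern) {
  kr <- (nrow(kern) - 1L) %/% 2L; kc <- (ncol(kern) - 1L) %/% 2L
  # replicate-pad the image so a constant background stays constant
  pad <- img[c(rep(1L, kr), seq_len(nrow(img)), rep(nrow(img), kr)),
             c(rep(1L, kc), seq_len(ncol(img)), rep(ncol(img), kc))]
  n1 <- nrow(pad) + nrow(kern) - 1L
  n2 <- ncol(pad) + ncol(kern) - 1L
  P <- matrix(0, n1, n2); P[seq_len(nrow(pad)), seq_len(ncol(pad))] <- pad
  K <- matrix(0, n1, n2); K[seq_len(nrow(kern)), seq_len(ncol(kern))] <- kern
  full <- Re(stats::fft(stats::fft(P) * stats::fft(K), inverse = TRUE)) / (n1 * n2)
  r0 <- 2L * kr + 1L; c0 <- 2L * kc + 1L
  full[r0:(r0 + nrow(img) - 1L), c0:(c0 + ncol(img) - 1L)]
}

#' Scale-normalized Laplacian-of-Gaussian response
#'
#' Convolves the image with a scale-normalized LoG kernel
#' (sigma^2 * Laplacian of a Gaussian of width sigma), sign-flipped so
#' bright blobs give positive peaks; the response of a Gaussian blob of
#' matching sigma is maximal at the blob center. The discrete kernel is
#' mean-subtracted so a constant image maps to an exactly zero response.
#'
#' @param image numeric matrix of intensities
#' @param scale blob sigma in pixels (> 0)
#' @return response matrix, same dimensions as `image`
#' @export
log_response <- function(image, scale) {
  if (!is.numeric(scale) || scale <= 0) stop("scale must be positive")
  stopifnot(length(image) > 0)
  r <- ceiling(4 * scale)
  x <- seq(-r, r)
  g <- outer(x, x, function(dy, dx) {
    r2 <- dx^2 + dy^2
    -(r2 - 2 * scale^2) / scale^2 * exp(-r2 / (2 * scale^2))
  })
  g <- g - mean(g) # zero-sum: constant image -> exactly 0
  conv2_same(image, g)
}

#' Segment blob objects from a LoG response
#'
#' Thresholds the response, labels connected components, and measures
#' each object's centroid, area, peak response and eccentricity.
#' Objects outside the size or shape bounds are rejected but returned
#' with `kept = FALSE` (bright rejected objects drive the debris rule
#' in [call_wells()]).
#'
#' @param response matrix from [log_response()]
#' @param config a [segmentation_config()]
#' @return `data.table(object, cy, cx, area, peak, eccentricity, kept)`
#' @export
segment_objects <- function(response, config = segmentation_config()) {
  thr <- if (identical(config$threshold, "auto")) {
    # median + k*MAD is the robust rule; the relative floor keeps exactly
    # noiseless images (MAD = 0) above FFT ripple, and the tiny absolute
    # floor covers blank noiseless fields (response range 0)
    rng <- diff(range(response))
    max(stats::median(response) + config$auto_k * stats::mad(response),
        1e-6 * rng, 1e-9)
  } else config$threshold
  lab <- EBImage::bwlabel(response > thr)
  n <- max(lab)
  if (n == 0L)
    return(data.table::data.table(object = integer(0), cy = numeric(0),
                                  cx = numeric(0), area = integer(0),
                                  peak = numeric(0), eccentricity = numeric(0),
                                  kept = logical(0), threshold = numeric(0)))
  idx <- which(lab > 0)
  dt <- data.table::data.table(
    object = as.integer(lab[idx]),
    r = (idx - 1L) %% nrow(lab) + 1L,
    c = (idx - 1L) %/% nrow(lab) + 1L,
    v = response[idx])
  obj <- dt[, {
    mu20 <- if (.N > 1) stats::var(r) * (.N - 1) / .N else 0
    mu02 <- if (.N > 1) stats::var(c) * (.N - 1) / .N else 0
    mu11 <- if (.N > 1) stats::cov(r, c) * (.N - 1) / .N else 0
    tr <- mu20 + mu02
    det <- mu20 * mu02 - mu11^2
    disc <- sqrt(max(tr^2 / 4 - det, 0))
    l1 <- tr / 2 + disc; l2 <- tr / 2 - disc
    ecc <- if (l1 <= 0) 0 else sqrt(max(1 - l2 / l1, 0))
    .(cy = mean(r), cx = mean(c), area = .N, peak = max(v),
      eccentricity = ecc)
  }, by = object]
  obj[, kept := area >= config$min_area & area <= config$max_area &
        eccentricity <= config$max_eccentricity]
  obj[, threshold := thr]
  data.table::setorder(obj, object)
  obj[]
}

#' Call wells from per-channel segmented objects
#'
#' Maps each object to a well by centroid containment (objects
#' straddling a boundary go to the well holding the centroid; a
#' centroid outside all well bounds is logged and ignored) and selects
#' wells with exactly one channel-1 (Hoechst) object and no channel-2
#' (PI) object. Wells with a PI-positive object are dead-cell
#' rejections; wells with bright rejected objects are debris-excluded.
#'
#' @param images a `well_images` object
#' @param config a [segmentation_config()]
#' @return `well_call_table` data.table: `row_, col_, n_ch1, n_ch2,
#'   debris, selected, reason`
#' @export
call_wells <- function(images, config = segmentation_config()) {
  wp <- images$optics$well_px
  res <- vector("list", 2L * nrow(images$fields))
  for (f in images$fields$field) {
    frow <- images$fields$frow[f]; fcol <- images$fields$fcol[f]
    for (ch in 1:2) {
      img <- if (ch == 1L) images$ch1[[f]] else images$ch2[[f]]
      resp <- log_response(img, config$log_scale)
      obj <- segment_objects(resp, config)
      if (nrow(obj) == 0L) next
      obj[, `:=`(
        row_ = (frow - 1L) * 6L + pmin(pmax(ceiling(cy / wp), 1L), 6L),
        col_ = (fcol - 1L) * 6L + pmin(pmax(ceiling(cx / wp), 1L), 6L),
        channel = ch)]
      inside <- obj$cy >= 0.5 & obj$cy <= 6 * wp + 0.5 &
        obj$cx >= 0.5 & obj$cx <= 6 * wp + 0.5
      if (any(!inside))
        message(sum(!inside), " object centroid(s) outside well bounds; ignored")
      res[[(f - 1L) * 2L + ch]] <- obj[inside]
    }
  }
  objects <- data.table::rbindlist(res, fill = TRUE)
  wells <- data.table::CJ(row_ = seq_len(images$n_rows),
                          col_ = seq_len(images$n_cols))
  if (nrow(objects) > 0) {
    agg <- objects[, .(
      n_ch1 = sum(channel == 1L & kept),
      n_ch2 = sum(channel == 2L & kept),
      debris = any(!kept & peak >= config$debris_factor * threshold)),
      by = .(row_, col_)]
    wells <- merge(wells, agg, by = c("row_", "col_"), all.x = TRUE)
  } else {
    wells[, `:=`(n_ch1 = NA_integer_, n_ch2 = NA_integer_, debris = NA)]
  }
  wells[is.na(n_ch1), n_ch1 := 0L]
  wells[is.na(n_ch2), n_ch2 := 0L]
  wells[is.na(debris), debris := FALSE]
  wells[, selected := n_ch1 == 1L & n_ch2 == 0L & !debris]
  wells[, reason := data.table::fcase(
    selected, "selected",
    n_ch2 > 0L, "PI-positive",
    debris, "debris-excluded",
    n_ch1 == 0L, "no-cell",
    n_ch1 > 1L, "multiple-cells",
    default = "other")]
  class(wells) <- c("well_call_table", class(wells))
  wells[]
}

#' Select single-cell wells from rendered or loaded images
#'
#' Convenience wrapper: [call_wells()] plus the chip barcode map.
#'
#' @param images a `well_images`
#' @param layout the matching [chip_layout()]
#' @param config a [segmentation_config()]
#' @return well-call table joined with `barcode` and `sample_id`
#' @export
select_wells <- function(images, layout, config = segmentation_config()) {
  calls <- call_wells(images, config)
  merge(calls, layout$wells[, .(row_, col_, barcode, sample_id)],
        by = c("row_", "col_"))
}

#' Write the dispense file and Poisson occupancy summary
#'
#' The dispense file lists selected single-cell wells (row, col,
#' barcode) and directs targeted reagent delivery. The summary reports
#' the observed occupancy histogram (0, 1, 2, 3, 4+ objects in channel
#' 1) and the maximum-likelihood Poisson mean, which for i.i.d. counts
#' is the plain mean objects per well.
#'
#' @param calls output of [select_wells()] (needs `barcode`)
#' @param path output TSV path; the summary JSON goes to
#'   `<path>.summary.json`
#' @return list(`dispense` table, `summary` list) invisibly
#' @export
write_dispense_file <- function(calls, path) {
  sel <- calls[selected == TRUE, .(row = row_, col = col_, barcode)]
  data.table::fwrite(sel, path, sep = "\t")
  occ <- pmin(calls$n_ch1, 4L)
  hist <- as.integer(table(factor(occ, levels = 0:4)))
  summary <- list(
    n_wells = nrow(calls), n_selected = nrow(sel),
    occupancy_histogram = stats::setNames(as.list(hist),
                                          c("0", "1", "2", "3", "4+")),
    lambda_mle = mean(calls$n_ch1))
  write_json_file(summary, paste0(path, ".summary.json"))
  invisible(list(dispense = sel, summary = summary))
}
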