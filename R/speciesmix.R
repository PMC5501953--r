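#' Configuration for species-mixing (barnyard) analysis
#'
#' @param ambiguity_max_mismatch reads mapping to both genomes with at
#'   most this many mismatches each are ambiguous and excluded (default 3)
#' @param iqr_multiplier cutoff = median + this many IQRs (default 5)
#' @param labels species labels, c(first, second) — conventionally
#'   c("human", "mouse")
#' @return validated `species_config` list
#' @export
species_config <- function(ambiguity_max_mismatch = 3L, iqr_multiplier = 5,
                           labels = c("human", "mouse")) {
  stopifnot(ambiguity_max_mismatch >= 0, iqr_multiplier >= 0,
            length(labels) == 2L)
  structure(list(ambiguity_max_mismatch = as.integer(ambiguity_max_mismatch),
                 iqr_multiplier = iqr_multiplier, labels = labels),
            class = "species_config")
}

#' Per-read species assignment from dual-genome alignments
#'
#' Reads were mapped independently to the two genomes. A read that maps
#' to both with at most `ambiguity_max_mismatch` mismatches each could
#' belong to either species and is excluded. Otherwise it is assigned
#' to a genome where it maps within the mismatch budget; reads mapping
#' to neither genome within the budget are unassigned.
#'
#' @param nm_1,nm_2 integer vectors: best mismatch count per read in
#'   genome 1 / genome 2 (`NA` = unmapped)
#' @param config a [species_config()]
#' @return character vector with entries from `config$labels`,
#'   "ambiguous", or "unassigned"
#' @examples
#' exclude_ambiguous(c(1L, 0L, 0L), c(2L, NA, 5L))
#' @export
exclude_ambiguous <- function(nm_1, nm_2, config = species_config()) {
  stopifnot(length(nm_1) == length(nm_2))
  t_ <- config$ambiguity_max_mismatch
  in1 <- !is.na(nm_1) & nm_1 <= t_
  in2 <- !is.na(nm_2) & nm_2 <= t_
  out <- rep("unassigned", length(nm_1))
  out[in1 & in2] <- "ambiguous"
  out[in1 & !in2] <- config$labels[1]
  out[in2 & !in1] <- config$labels[2]
  out
}

#' Species classification cutoffs: median + k * IQR of the minority signal
#'
#' The cutoff for calling a cell species 1 is estimated from cells
#' dominated by species 2: among cells with more species-2 than
#' species-1 transcripts, take the median plus `iqr_multiplier` times
#' the inter-quartile range of their species-1 transcript counts (and
#' symmetrically for species 2). Quantiles use linear interpolation
#' (R type 7).
#'
#' @param transcripts_1,transcripts_2 per-cell transcript totals in each
#'   species
#' @param config a [species_config()]
#' @return named numeric vector `c(cutoff_1, cutoff_2)`
#' @export
compute_cutoffs <- function(transcripts_1, transcripts_2,
                            config = species_config()) {
  dom2 <- transcripts_2 > transcripts_1
  dom1 <- transcripts_1 > transcripts_2
  if (sum(dom2) < 2L || sum(dom1) < 2L)
    stop("need at least 2 cells dominated by each species to set cutoffs")
  cut1 <- stats::median(transcripts_1[dom2]) +
    config$iqr_multiplier * stats::IQR(transcripts_1[dom2], type = 7)
  cut2 <- stats::median(transcripts_2[dom1]) +
    config$iqr_multiplier * stats::IQR(transcripts_2[dom1], type = 7)
  stats::setNames(c(cut1, cut2), paste0("cutoff_", config$labels))
}

#' Classify cells against species cutoffs
#'
#' Strictly more transcripts than a species' cutoff classifies the cell
#' as that species; exceeding both cutoffs marks a cross-species
#' multiplet; exceeding neither leaves the cell unclassified (boundary
#' equality does not classify).
#'
#' @param transcripts_1,transcripts_2 per-cell totals
#' @param cutoffs from [compute_cutoffs()]
#' @param config a [species_config()]
#' @return character vector: label 1, label 2, "multiplet" or
#'   "unclassified"
#' @export
classify_species <- function(transcripts_1, transcripts_2, cutoffs,
                             config = species_config()) {
  over1 <- transcripts_1 > cutoffs[[1]]
  over2 <- transcripts_2 > cutoffs[[2]]
  out <- rep("unclassified", length(transcripts_1))
  out[over1 & !over2] <- config$labels[1]
  out[over2 & !over1] <- config$labels[2]
  out[over1 & over2] <- "multiplet"
  out
}

#' Multiplet rate from classified mixture cells
#'
#' The cross-species multiplet percentage is directly observable in a
#' barnyard mixture; same-species multiplets are invisible, but in a
#' one-to-one mixture they are expected at the same rate, so the
#' overall multiplet rate is estimated as twice the cross-species rate.
#'
#' @param labels classification vector over all mixture cells
#' @return list(`cross_species_pct`, `overall_estimate_pct`, `n_cells`,
#'   `n_multiplets`)
#' @examples
#' multiplet_rate(rep(c("human", "mouse", "multiplet"), c(247, 246, 6)))
#' @export
multiplet_rate <- function(labels) {
  n <- length(labels)
  k <- sum(labels == "multiplet")
  cross <- 100 * k / n
  list(cross_species_pct = cross, overall_estimate_pct = 2 * cross,
       n_cells = n, n_multiplets = k)
}

#' Single-cell purity per species
#'
#' For cells classified as a given species, purity is the fraction of
#' their transcripts detected in their own genome, own / (own + other),
#' summarized by the median across cells.
#'
#' @param transcripts_1,transcripts_2 per-cell totals
#' @param labels classification vector
#' @param config a [species_config()]
#' @return named numeric vector of per-species median purities
#' @export
species_purity <- function(transcripts_1, transcripts_2, labels,
                           config = species_config()) {
  tot <- transcripts_1 + transcripts_2
  p1 <- stats::median((transcripts_1 / tot)[labels == config$labels[1]])
  p2 <- stats::median((transcripts_2 / tot)[labels == config$labels[2]])
  stats::setNames(c(p1, p2), config$labels)
}

#' Full barnyard analysis from per-cell dual-genome totals
#'
#' Computes cutoffs, classifies every cell, and reports multiplet rates
#' and purities. Purity is taken over all species-classified cells by
#' default (mixture and pure-sample controls alike); set
#' `mixture_only = TRUE` (with an `is_mixture` flag) to restrict both
#' rate and purity to mixture wells.
#'
#' @param transcripts_1,transcripts_2 per-cell transcript totals
#' @param config a [species_config()]
#' @param is_mixture optional logical vector flagging mixture wells
#' @param mixture_only restrict purity to mixture wells
#' @return `species_calls` list: per-cell table, cutoffs, rates, purity
#' @export
barnyard_analysis <- function(transcripts_1, transcripts_2,
                              config = species_config(),
                              is_mixture = NULL, mixture_only = FALSE) {
  cutoffs <- compute_cutoffs(transcripts_1, transcripts_2, config)
  labels <- classify_species(transcripts_1, transcripts_2, cutoffs, config)
  if (is.null(is_mixture)) is_mixture <- rep(TRUE, length(labels))
  rate <- multiplet_rate(labels[is_mixture])
  pur_idx <- if (mixture_only) is_mixture else rep(TRUE, length(labels))
  purity <- species_purity(transcripts_1[pur_idx], transcripts_2[pur_idx],
                           labels[pur_idx], config)
  cells <- data.table::data.table(
    transcripts_1 = transcripts_1, transcripts_2 = transcripts_2,
    label = labels, is_mixture = is_mixture)
  data.table::setnames(cells, c("transcripts_1", "transcripts_2"),
                       paste0("transcripts_", config$labels))
  structure(list(cells = cells, cutoffs = cutoffs, rate = rate,
                 purity = purity, config = config),
            class = "species_calls")
}

#' @export
print.species_calls <- function(x, ...) {
  cat("barnyard analysis:", nrow(x$cells), "cells\n")
  print(table(x$cells$label))
  cat(sprintf("cutoffs: %s\ncross-species multiplets: %.2f%% (overall estimate %.2f%%)\n",
              paste(sprintf("%s=%.0f", names(x$cutoffs), x$cutoffs), collapse = ", "),
              x$rate$cross_species_pct, x$rate$overall_estimate_pct))
  cat(sprintf("median purity: %s\n",
              paste(sprintf("%s=%.3f", names(x$purity), x$purity), collapse = ", ")))
  invisible(x)
}

#' Simulate a barnyard (species-mixing) experiment
#'
#' Generates per-cell transcript totals for a one-to-one mixture of two
#' species dispensed on one chip. Each well is a doublet (two cells)
#' with probability `doublet_rate`; the second cell's species is drawn
#' uniformly, so only about half of all doublets are cross-species —
#' same-species doublets look like large singlets, which is exactly why
#' the overall multiplet estimator doubles the observed cross-species
#' rate. Each well draws an `impurity` fraction of its base transcript
#' complement from the other species (ambient RNA and chimeric PCR both
#' contribute in reality); contamination is a per-well quantity — it
#' scales with the well, not with the number of cells in it. Totals are
#' Poisson around `depth` per cell.
#'
#' @param n_1,n_2 target numbers of species-1 / species-2 cells
#' @param doublet_rate probability a well holds two cells
#' @param impurity length-2: cross-species transcript fraction for
#'   species-1 and species-2 singlets
#' @param depth mean transcripts per cell
#' @param config a [species_config()] (labels only)
#' @param seed RNG seed
#' @return `data.table` with per-cell `transcripts_<label1>`,
#'   `transcripts_<label2>` and a `truth` column
#'   ("singlet_<label>", "doublet_cross" or "doublet_same_<label>")
#' @export
simulate_barnyard <- function(n_1 = 250L, n_2 = 250L, doublet_rate = 0.024,
                              impurity = c(0.03, 0.06), depth = 5000,
                              config = species_config(), seed = 1L) {
  stopifnot(doublet_rate >= 0, doublet_rate <= 1,
            all(impurity >= 0 & impurity <= 1))
  impurity <- rep(impurity, length.out = 2L)
  n <- n_1 + n_2
  withr::with_seed(seed, {
    is_doublet <- stats::runif(n) < doublet_rate
    sp <- c(rep(1L, n_1), rep(2L, n_2))[sample.int(n)]
    tot <- stats::rpois(n, depth)
    own <- stats::rbinom(n, tot, 1 - impurity[sp])
    t1 <- ifelse(sp == 1L, own, tot - own)
    t2 <- tot - t1
    # the second cell of a doublet is either species with equal odds;
    # its transcripts are all own-species (contamination is per well)
    sp2 <- sample(1:2, n, replace = TRUE)
    tot2 <- stats::rpois(n, depth)
    t1 <- t1 + ifelse(is_doublet & sp2 == 1L, tot2, 0L)
    t2 <- t2 + ifelse(is_doublet & sp2 == 2L, tot2, 0L)
  })
  truth <- ifelse(!is_doublet, paste0("singlet_", config$labels[sp]),
                  ifelse(sp != sp2, "doublet_cross",
                         paste0("doublet_same_", config$labels[sp])))
  out <- data.table::data.table(t1 = t1, t2 = t2, truth = truth)
  data.table::setnames(out, c("t1", "t2"),
                       paste0("transcripts_", config$labels))
  out[]
}
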