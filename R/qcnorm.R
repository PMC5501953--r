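#' Per-cell quality-control statistics
#'
#' Computes the six per-cell statistics used to judge a single-cell
#' run: total sequenced reads, alignment rate (uniquely mapped /
#' total demultiplexed), mapped reads, total transcripts, percentage of
#' transcripts from mitochondrial genes, and number of detected genes
#' (count >= 1). Cells with zero transcripts get `pct_mito = 0` with a
#' warning (the ratio is undefined).
#'
#' @param tc a `transcript_counts` object
#' @param total_reads named numeric vector: demultiplexed reads per cell
#' @param mapped_reads named numeric vector: uniquely mapped reads per
#'   cell
#' @param min_transcripts QC cutoff forwarded to [qc_filter()]
#' @return `data.table` with one row per cell: `cell_id, total_reads,
#'   mapped_reads, alignment_rate, total_transcripts, pct_mito,
#'   n_genes_detected, qc_pass`
#' @export
compute_cell_qc <- function(tc, total_reads = NULL, mapped_reads = NULL,
                            min_transcripts = 0) {
  stopifnot(inherits(tc, "transcript_counts"))
  m <- tc$counts
  totals <- Matrix::colSums(m)
  mito <- Matrix::colSums(m[tc$gene_meta$mito, , drop = FALSE])
  if (any(totals == 0))
    warning(sum(totals == 0), " cell(s) with zero transcripts; pct_mito set to 0")
  qc <- data.table::data.table(
    cell_id = colnames(m),
    total_reads = if (is.null(total_reads)) NA_real_ else
      unname(total_reads[colnames(m)]),
    mapped_reads = if (is.null(mapped_reads)) NA_real_ else
      unname(mapped_reads[colnames(m)]),
    total_transcripts = totals,
    pct_mito = ifelse(totals > 0, 100 * mito / pmax(totals, 1), 0),
    n_genes_detected = Matrix::colSums(m >= 1))
  qc[, alignment_rate := mapped_reads / total_reads]
  if (any(!is.na(qc$mapped_reads) & !is.na(qc$total_reads) &
          qc$mapped_reads > qc$total_reads))
    stop("mapped_reads exceeds total_reads for some cell")
  qc[, qc_pass := qc_filter(total_transcripts, min_transcripts)]
  data.table::setcolorder(qc, c("cell_id", "total_reads", "alignment_rate",
                                "mapped_reads", "total_transcripts",
                                "pct_mito", "n_genes_detected", "qc_pass"))
  qc[]
}

#' Cell QC filter on total transcripts
#'
#' Cells pass when they reach a minimum number of detected transcripts.
#' The cutoff is data-set specific and chosen by inspection (poor
#' quality cells — few genes, high mitochondrial content — concentrate
#' at low transcript totals).
#'
#' @param total_transcripts numeric vector (or a QC table from
#'   [compute_cell_qc()])
#' @param min_transcripts non-negative cutoff
#' @return logical vector of pass flags
#' @export
qc_filter <- function(total_transcripts, min_transcripts) {
  stopifnot(min_transcripts >= 0)
  if (is.data.frame(total_transcripts))
    total_transcripts <- total_transcripts$total_transcripts
  total_transcripts >= min_transcripts
}

#' Median-ratio normalization of transcript counts
#'
#' Divides each cell's counts by a cell-specific scale factor: the
#' cell's total transcript count divided by the median total across
#' cells. After normalization every cell's total equals the median raw
#' total, and re-normalizing is a no-op. Chips are normalized jointly in
#' one pass; no additional between-chip normalization is applied.
#'
#' @param counts numeric matrix (genes x cells) or `transcript_counts`
#' @return list(`normalized` = real-valued matrix, `factors` = per-cell
#'   scale factors, `median_total`). Cells with zero total have factor 0
#'   and are dropped from the normalized matrix with a warning.
#' @examples
#' m <- matrix(c(1, 99, 2, 198, 3, 297), 2, dimnames = list(c("g1", "g2"), NULL))
#' normalize_counts(m)$factors # 0.5 1.0 1.5
#' @export
normalize_counts <- function(counts) {
  if (inherits(counts, "transcript_counts")) counts <- counts$counts
  counts <- as.matrix(counts)
  totals <- colSums(counts)
  if (all(totals == 0)) stop("no cell with nonzero total")
  med <- stats::median(totals[totals > 0])
  factors <- totals / med
  drop <- totals == 0
  if (any(drop))
    warning(sum(drop), " cell(s) with zero total excluded from normalization")
  normalized <- sweep(counts[, !drop, drop = FALSE], 2L, factors[!drop], "/")
  list(normalized = normalized, factors = factors, median_total = med)
}

#' Sequencing-saturation curve by read downsampling
#'
#' Simulates shallower sequencing: for each cell, a fraction d/D of its
#' gene-aligned reads is drawn without replacement (hypergeometric;
#' Bernoulli thinning available), where D is the observed mean depth and
#' d the target, and the whole counting chain (N-UMI exclusion, UMI
#' clustering, read-support filter) is re-run on the sample. Reported
#' per depth: median detected genes and median transcripts across
#' cells. Sampling precedes UMI collapsing, so duplicate reads of one
#' molecule thin realistically.
#'
#' @param reads read-level `data.table` with `cell_id`, `gene_id`,
#'   `umi` (one row per gene-aligned read)
#' @param depths target mean reads per cell (values <= observed mean)
#' @param config a [counting_config()]
#' @param method "hypergeometric" (without replacement) or "bernoulli"
#' @param seed RNG seed
#' @return `data.table(depth, fraction, median_genes, median_transcripts)`
#' @export
downsample_curve <- function(reads, depths, config = counting_config(),
                             method = c("hypergeometric", "bernoulli"),
                             seed = 1L) {
  method <- match.arg(method)
  reads <- data.table::as.data.table(reads)[!is.na(gene_id)]
  D <- nrow(reads) / data.table::uniqueN(reads$cell_id)
  if (any(depths > D * (1 + 1e-9)))
    stop("target depth exceeds observed mean depth ", round(D, 1))
  res <- lapply(seq_along(depths), function(k) {
    d <- depths[k]
    f <- min(d / D, 1)
    sub <- withr::with_seed(sub_seed(seed, k), {
      if (f >= 1) reads
      else if (method == "bernoulli")
        reads[stats::runif(.N) < f]
      else reads[, .SD[sample.int(.N, round(f * .N))], by = cell_id]
    })
    tc <- count_transcripts(sub[, .(cell_id, gene_id, umi)], config)
    data.table::data.table(
      depth = d, fraction = f,
      median_genes = stats::median(Matrix::colSums(tc$counts >= 1)),
      median_transcripts = stats::median(Matrix::colSums(tc$counts)))
  })
  data.table::rbindlist(res)
}
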