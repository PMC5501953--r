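#' Counting configuration for UMI-cluster quantification
#'
#' @param min_reads_per_umi minimum reads supporting a UMI cluster for
#'   it to count as a transcript (default 2: singleton UMIs seen in one
#'   read only are likely chimeric PCR products or sequencing errors and
#'   are excluded)
#' @param umi_max_mismatch UMIs within this Hamming distance are merged
#'   into one cluster (default 1)
#' @param strand_policy "sense" restricts gene assignment to same-strand
#'   overlap, "unstranded" ignores strand
#' @return validated `counting_config` list
#' @export
counting_config <- function(min_reads_per_umi = 2L, umi_max_mismatch = 1L,
                            strand_policy = c("sense", "unstranded")) {
  stopifnot(min_reads_per_umi >= 1, umi_max_mismatch >= 0)
  structure(list(min_reads_per_umi = as.integer(min_reads_per_umi),
                 umi_max_mismatch = as.integer(umi_max_mismatch),
                 strand_policy = match.arg(strand_policy)),
            class = "counting_config")
}

#' Keep only uniquely mapping reads
#'
#' Drops unaligned records and reads reported at more than one location.
#' Records must carry hit-count information (`nh`); without it the
#' unique-mapping filter cannot be applied and the function errors
#' rather than silently keeping multi-mappers.
#'
#' @param aln `data.table` with logical `mapped` and integer `nh`
#' @return list(`alignments` = filtered table, `counters` = list(input,
#'   unmapped, multimapped, kept))
#' @export
filter_alignments <- function(aln) {
  aln <- data.table::as.data.table(aln)
  if (nrow(aln) > 0 && (!"nh" %in% names(aln) || anyNA(aln$nh)))
    stop("alignments lack uniqueness information (NH); cannot filter")
  keep <- aln$mapped & aln$nh == 1L
  list(alignments = aln[keep],
       counters = list(input = nrow(aln), unmapped = sum(!aln$mapped),
                       multimapped = sum(aln$mapped & aln$nh > 1L),
                       kept = sum(keep)))
}

#' Assign alignments to genes by interval overlap
#'
#' A read is assigned to a gene when its aligned interval overlaps
#' exactly one gene (on the same strand under the "sense" policy);
#' reads overlapping zero or two+ genes get `NA` (intergenic /
#' ambiguous).
#'
#' @param aln `data.table` with `chrom`, `pos`, `width` (plus optional
#'   `strand`, defaulting to "+")
#' @param gene_model a `gene_model`
#' @param strand_policy see [counting_config()]
#' @return character vector of gene ids (NA where unassigned)
#' @export
assign_gene <- function(aln, gene_model, strand_policy = "sense") {
  if (nrow(aln) == 0L) return(character(0))
  strand <- if ("strand" %in% names(aln)) aln$strand else "+"
  reads <- GenomicRanges::GRanges(
    seqnames = aln$chrom,
    ranges = IRanges::IRanges(aln$pos, width = aln$width),
    strand = strand)
  gr <- gene_granges(gene_model)
  ov <- GenomicRanges::findOverlaps(
    reads, gr, ignore.strand = (strand_policy == "unstranded"))
  hits_per_read <- tabulate(S4Vectors::queryHits(ov), nbins = length(reads))
  gene <- rep(NA_character_, length(reads))
  uni <- S4Vectors::queryHits(ov)[hits_per_read[S4Vectors::queryHits(ov)] == 1L]
  gene[uni] <- gr$gene_id[S4Vectors::subjectHits(ov)[hits_per_read[S4Vectors::queryHits(ov)] == 1L]]
  gene
}

#' Exclude reads whose UMI contains N (or any non-ACGT character)
#'
#' @param dt `data.table` with a `umi` column
#' @return list(`reads` = retained rows, `n_dropped`)
#' @export
drop_n_umis <- function(dt) {
  bad <- grepl("[^ACGT]", dt$umi)
  list(reads = dt[!bad], n_dropped = sum(bad))
}

#' Cluster UMIs within one gene by mismatch tolerance
#'
#' Joins any two UMIs at Hamming distance <= `max_mismatch` and takes
#' connected components (so clusters are closed under chains of
#' single-mismatch links). Each cluster's read support is the sum of the
#' read counts of all member UMIs; counting clusters rather than raw
#' UMIs avoids inflating transcript counts through UMI sequencing
#' errors. Deterministic: members are reported sorted lexicographically.
#'
#' @param umis character vector of distinct UMIs (same length, ACGT)
#' @param reads integer read count per UMI
#' @param max_mismatch Hamming radius for joining (default 1)
#' @return `data.table(cluster, umis = list, read_support, n_umis)`
#' @examples
#' cluster_umis(c("AAAAAAAAAA", "AAAAAAAAAT", "CCCCCCCCCC"), c(3, 1, 2))
#' @export
cluster_umis <- function(umis, reads = rep(1L, length(umis)), max_mismatch = 1L) {
  stopifnot(length(umis) == length(reads))
  if (length(umis) == 0L)
    return(data.table::data.table(cluster = integer(0), umis = list(),
                                  read_support = integer(0), n_umis = integer(0)))
  if (length(unique(nchar(umis))) != 1L) stop("all UMIs must have the same length")
  if (any(grepl("[^ACGT]", umis))) stop("UMIs must contain only A/C/G/T")
  cl <- cluster_umis_cpp(rep(1L, length(umis)), umis, as.integer(max_mismatch))
  dt <- data.table::data.table(umi = umis, reads = as.integer(reads), cluster = cl)
  out <- dt[, .(umis = list(sort(umi)), read_support = sum(reads),
                n_umis = .N), by = cluster]
  data.table::setorder(out, cluster)
  out[]
}

#' Count transcripts from tagged, gene-assigned reads
#'
#' The central quantification step: for every (cell, gene), reads with
#' identical UMIs are collapsed (summing read counts), UMIs within
#' `umi_max_mismatch` are merged into clusters, clusters supported by
#' fewer than `min_reads_per_umi` reads are discarded, and the
#' transcript count is the number of surviving distinct UMI clusters.
#'
#' @param reads `data.table` with columns `cell_id` (or `barcode`),
#'   `gene_id`, `umi`, and optionally `reads` (pre-collapsed read
#'   counts, default 1 per row)
#' @param config a [counting_config()]
#' @param gene_meta,cell_meta optional metadata tables carried into the
#'   result (`gene_meta` needs `gene_id`; a `mito` flag is added from
#'   the "mt-"/"MT-" name prefix when missing)
#' @return a `transcript_counts` object: list with sparse `counts`
#'   (genes x cells, `Matrix::dgCMatrix`), `gene_meta`, `cell_meta`,
#'   `audit` (per cell/gene/cluster read support) and `counters`
#' @export
count_transcripts <- function(reads, config = counting_config(),
                              gene_meta = NULL, cell_meta = NULL) {
  reads <- data.table::as.data.table(reads)
  if (!"cell_id" %in% names(reads) && "barcode" %in% names(reads))
    data.table::setnames(reads, "barcode", "cell_id")
  stopifnot(all(c("cell_id", "gene_id", "umi") %in% names(reads)))
  if (!"reads" %in% names(reads)) reads[, reads := 1L]
  counters <- list(input_records = nrow(reads))

  x <- drop_n_umis(reads[!is.na(gene_id)])
  counters$no_gene <- sum(is.na(reads$gene_id))
  counters$n_umi_dropped <- x$n_dropped
  dt <- x$reads[, .(reads = sum(reads)), by = .(cell_id, gene_id, umi)]
  data.table::setorder(dt, cell_id, gene_id, umi)
  dt[, gid := .GRP, by = .(cell_id, gene_id)]
  dt[, cluster := cluster_umis_cpp(gid, umi, config$umi_max_mismatch)]
  audit <- dt[, .(read_support = sum(reads), n_umis = .N),
              by = .(cell_id, gene_id, cluster)]
  counters$umi_clusters <- nrow(audit)
  qual <- audit[read_support >= config$min_reads_per_umi]
  counters$clusters_kept <- nrow(qual)
  tab <- qual[, .(count = .N), by = .(cell_id, gene_id)]

  gene_ids <- if (!is.null(gene_meta)) gene_meta$gene_id else sort(unique(reads$gene_id))
  cell_ids <- if (!is.null(cell_meta)) cell_meta$cell_id else sort(unique(reads$cell_id))
  transcript_counts(tab, gene_ids, cell_ids, gene_meta, cell_meta,
                    audit = audit, counters = counters)
}

# build the transcript_counts container from a (cell, gene, count) table
transcript_counts <- function(tab, gene_ids, cell_ids, gene_meta = NULL,
                              cell_meta = NULL, audit = NULL, counters = NULL) {
  i <- match(tab$gene_id, gene_ids)
  j <- match(tab$cell_id, cell_ids)
  ok <- !is.na(i) & !is.na(j)
  counts <- Matrix::sparseMatrix(
    i = i[ok], j = j[ok], x = as.numeric(tab$count[ok]),
    dims = c(length(gene_ids), length(cell_ids)),
    dimnames = list(gene_ids, cell_ids))
  if (is.null(gene_meta))
    gene_meta <- data.table::data.table(gene_id = gene_ids)
  if (!"mito" %in% names(gene_meta))
    gene_meta[, mito := grepl("^(mt-|MT-)", gene_id)]
  if (is.null(cell_meta))
    cell_meta <- data.table::data.table(cell_id = cell_ids)
  structure(list(counts = counts, gene_meta = gene_meta,
                 cell_meta = cell_meta, audit = audit, counters = counters),
            class = "transcript_counts")
}

#' @export
print.transcript_counts <- function(x, ...) {
  cat(sprintf("transcript_counts: %d genes x %d cells, %d transcripts total\n",
              nrow(x$counts), ncol(x$counts), sum(x$counts)))
  invisible(x)
}

#' One-call quantification from demultiplexed reads and alignments
#'
#' Runs the full counting chain: unique-mapping filter, gene assignment
#' by interval overlap, N-UMI exclusion, UMI clustering and
#' read-support filtering. Demultiplexed reads supply (cell, UMI);
#' alignments supply the mapped position of read 2 of the same pair,
#' joined on `read_id`.
#'
#' @param demux result of [demultiplex()]
#' @param aln alignment table from [read_alignments()] (or compatible)
#' @param gene_model a `gene_model`
#' @param config a [counting_config()]
#' @param gene_meta,cell_meta forwarded to [count_transcripts()]
#' @return a `transcript_counts` object
#' @export
quantify_counts <- function(demux, aln, gene_model,
                            config = counting_config(),
                            gene_meta = NULL, cell_meta = NULL) {
  fa <- filter_alignments(aln)
  a <- fa$alignments
  a[, gene_id := assign_gene(a, gene_model, config$strand_policy)]
  tagged <- merge(demux$reads, a[, .(read_id, gene_id)], by = "read_id")
  tagged[, cell_id := paste0(sprintf("R%02dC%02d", row_, col_))]
  tc <- count_transcripts(tagged[, .(cell_id, gene_id, umi)], config,
                          gene_meta = gene_meta, cell_meta = cell_meta)
  tc$counters <- c(tc$counters, fa$counters)
  tc
}
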