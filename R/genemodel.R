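#' Synthetic gene model with sequences
#'
#' Builds a minimal annotation for simulation: one non-overlapping
#' interval per gene on a single synthetic chromosome, all on the plus
#' strand, with random DNA sequences. Non-overlapping single-interval
#' genes keep read-to-gene assignment unambiguous, so ground-truth
#' recovery tests are exact. Intervals are 1-based closed (the
#' GRanges/GTF convention).
#'
#' @param gene_ids character vector of gene identifiers
#' @param gene_len gene (transcript) length in bases
#' @param spacer intergenic gap in bases
#' @param chrom chromosome name
#' @param seed RNG seed for the sequences
#' @return object of class `gene_model`: list with `genes`
#'   (`data.table(gene_id, chrom, start, end, strand)`) and `seqs`
#'   (named character vector of gene sequences)
#' @export
synthetic_gene_model <- function(gene_ids, gene_len = 300L, spacer = 100L,
                                 chrom = "chrS1", seed = 1L) {
  stopifnot(length(gene_ids) >= 1, !anyDuplicated(gene_ids), gene_len >= 1)
  n <- length(gene_ids)
  start <- (seq_len(n) - 1L) * (gene_len + spacer) + 1L
  genes <- data.table::data.table(
    gene_id = gene_ids, chrom = chrom, start = start,
    end = start + gene_len - 1L, strand = "+")
  seqs <- withr::with_seed(seed, random_dna(n, gene_len))
  names(seqs) <- gene_ids
  structure(list(genes = genes, seqs = seqs), class = "gene_model")
}

#' Write a gene model as GTF
#'
#' One `gene` feature line per gene, 1-based closed coordinates, with a
#' `gene_id` attribute.
#'
#' @param gm a [synthetic_gene_model()]
#' @param path output path
#' @export
write_gtf <- function(gm, path) {
  stopifnot(inherits(gm, "gene_model"))
  g <- gm$genes
  lines <- sprintf('%s\tnanowell\tgene\t%d\t%d\t.\t%s\t.\tgene_id "%s";',
                   g$chrom, g$start, g$end, g$strand, g$gene_id)
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene annotation (GTF) into a gene model
#'
#' Parses with `rtracklayer` and keeps `gene` features (or all features
#' when none are typed `gene`). Malformed files raise an error.
#'
#' @param path GTF path
#' @return `gene_model` (without sequences)
#' @export
read_gene_model <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "gtf"),
                 error = function(e) stop("malformed GTF '", path, "': ",
                                          conditionMessage(e)))
  if ("type" %in% names(S4Vectors::mcols(gr)) &&
      any(S4Vectors::mcols(gr)$type == "gene"))
    gr <- gr[S4Vectors::mcols(gr)$type == "gene"]
  if (is.null(S4Vectors::mcols(gr)$gene_id))
    stop("malformed GTF '", path, "': no gene_id attribute")
  genes <- data.table::data.table(
    gene_id = as.character(S4Vectors::mcols(gr)$gene_id),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)))
  structure(list(genes = genes, seqs = NULL), class = "gene_model")
}

# GRanges view of the gene intervals
gene_granges <- function(gm) {
  GenomicRanges::GRanges(
    seqnames = gm$genes$chrom,
    ranges = IRanges::IRanges(gm$genes$start, gm$genes$end),
    strand = gm$genes$strand, gene_id = gm$genes$gene_id)
}
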