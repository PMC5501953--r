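#' Split read 1 into well barcode and UMI
#'
#' Positional split: bases 1-11 are the well barcode, bases 12-21 the
#' UMI; any remaining read-1 bases are ignored. Reads shorter than
#' barcode + UMI cannot be parsed and are flagged too short.
#'
#' @param seq character vector of read-1 sequences
#' @param structure a [read_structure()]
#' @return `data.table(barcode, umi, too_short)`
#' @examples
#' parse_read1("ACGTACGTACGTTTTGGGGCCAAAA")
#' @export
parse_read1 <- function(seq, structure = read_structure()) {
  need <- structure$barcode_len + structure$umi_len
  too_short <- nchar(seq) < need
  data.table::data.table(
    barcode = ifelse(too_short, NA_character_,
                     substr(seq, 1L, structure$barcode_len)),
    umi = ifelse(too_short, NA_character_,
                 substr(seq, structure$barcode_len + 1L, need)),
    too_short = too_short)
}

#' Demultiplex paired reads by perfect barcode match
#'
#' A read pair is assigned to a well if and only if its first 11 bases
#' exactly match one of the expected barcodes; no error correction is
#' attempted (the barcode design guarantees a minimum pairwise distance
#' of 3, so a mismatching barcode is evidence of a sequencing error, and
#' such reads are dropped rather than rescued). Reads are conserved:
#' assigned + unassigned + too-short = input pairs.
#'
#' @param r1,r2 character vectors of read sequences, or paths to FASTQ
#'   files (optionally gzipped)
#' @param barcode_map `data.table` with `barcode`, `row_`, `col_`,
#'   `sample_id` columns — from [read_barcode_map()] or
#'   `chip_layout()$wells`; duplicate barcodes are a hard error
#' @param ids optional read identifiers (defaults to FASTQ names or
#'   "read1", "read2", ...)
#' @param structure a [read_structure()]
#' @return list with
#'   * `reads`: `data.table(read_id, barcode, umi, cdna, row_, col_,
#'     sample_id)` for assigned pairs
#'   * `report`: list(total, assigned, unassigned, too_short,
#'     per_well counts table)
#' @export
demultiplex <- function(r1, r2, barcode_map, ids = NULL,
                        structure = read_structure()) {
  if (length(r1) == 1L && file.exists(r1)) {
    f1 <- read_fastq(r1); f2 <- read_fastq(r2)
    ids <- f1$id; r1 <- f1$seq; r2 <- f2$seq
  }
  stopifnot(length(r1) == length(r2))
  barcode_map <- data.table::as.data.table(barcode_map)
  if (anyDuplicated(barcode_map$barcode))
    stop("duplicate barcode in map")
  if (is.null(ids)) ids <- sprintf("read%d", seq_along(r1))
  p <- parse_read1(r1, structure)
  hit <- match(p$barcode, barcode_map$barcode)
  assigned <- !is.na(hit) & !p$too_short
  reads <- data.table::data.table(
    read_id = ids[assigned],
    barcode = p$barcode[assigned],
    umi = p$umi[assigned],
    cdna = r2[assigned],
    row_ = barcode_map$row_[hit[assigned]],
    col_ = barcode_map$col_[hit[assigned]],
    sample_id = barcode_map$sample_id[hit[assigned]])
  report <- list(
    total = length(r1),
    assigned = sum(assigned),
    unassigned = sum(!assigned & !p$too_short),
    too_short = sum(p$too_short),
    per_well = reads[, .N, by = .(row_, col_)])
  list(reads = reads[], report = report)
}

# minimal FASTQ reader via Biostrings; keeps ids and sequences
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  list(id = sub("\\s.*$", "", names(x)), seq = as.character(unname(x)))
}
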