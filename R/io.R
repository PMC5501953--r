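#' Write / read a transcript count matrix as Matrix Market
#'
#' Writes `matrix.mtx`, `genes.tsv` (gene_id, mito flag) and
#' `cells.tsv` (cell metadata) into a directory; `read_counts_mtx`
#' restores the `transcript_counts` object (without audit/counters).
#'
#' @param tc a `transcript_counts`
#' @param dir output directory (created if needed)
#' @return the directory, invisibly
#' @export
write_counts_mtx <- function(tc, dir) {
  stopifnot(inherits(tc, "transcript_counts"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(tc$counts, file.path(dir, "matrix.mtx"))
  data.table::fwrite(tc$gene_meta, file.path(dir, "genes.tsv"), sep = "\t")
  data.table::fwrite(tc$cell_meta, file.path(dir, "cells.tsv"), sep = "\t")
  invisible(dir)
}

#' @rdname write_counts_mtx
#' @export
read_counts_mtx <- function(dir) {
  m <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")), "CsparseMatrix")
  gene_meta <- data.table::fread(file.path(dir, "genes.tsv"), sep = "\t")
  cell_meta <- data.table::fread(file.path(dir, "cells.tsv"), sep = "\t")
  dimnames(m) <- list(gene_meta$gene_id, cell_meta$cell_id)
  structure(list(counts = m, gene_meta = gene_meta, cell_meta = cell_meta,
                 audit = NULL, counters = NULL),
            class = "transcript_counts")
}
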