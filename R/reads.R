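#' Paired-end read structure
#'
#' Read 1 (25 bp) carries the 11-base well barcode followed by the
#' 10-base UMI; read 2 (50 bp) carries cDNA sequence.
#'
#' @param barcode_len,umi_len,read1_len,read2_len lengths in bases
#' @return a validated `read_structure` list
#' @export
read_structure <- function(barcode_len = 11L, umi_len = 10L,
                           read1_len = 25L, read2_len = 50L) {
  stopifnot(barcode_len + umi_len <= read1_len, read2_len >= 1)
  structure(list(barcode_len = as.integer(barcode_len),
                 umi_len = as.integer(umi_len),
                 read1_len = as.integer(read1_len),
                 read2_len = as.integer(read2_len)),
            class = "read_structure")
}

#' Library noise model for the read simulator
#'
#' All rates are per the unit stated; 0 everywhere gives a noiseless
#' library. PCR duplication is either a fixed number of reads per
#' molecule or 1 + Poisson(mean - 1) (so every molecule is sequenced at
#' least once).
#'
#' @param base_error_rate per-base substitution probability applied to
#'   the barcode and the cDNA read
#' @param umi_error_rate per-base substitution probability in the UMI
#' @param umi_n_rate per-base probability an observed UMI base is an N
#' @param pcr_mean mean reads per molecule (>= 1)
#' @param pcr_model "shifted_poisson" or "fixed"
#' @param chimera_rate probability a read is a chimeric PCR product: its
#'   barcode+UMI end joined to the cDNA of a random other gene
#' @param ambient_fraction probability a read comes from pooled ambient
#'   RNA rather than the well's own cell
#' @param multimap_rate probability a read is reported multi-mapping
#' @param unmapped_rate probability a read fails to align
#' @return a validated `sim_noise` list
#' @export
sim_noise <- function(base_error_rate = 0, umi_error_rate = 0, umi_n_rate = 0,
                      pcr_mean = 2, pcr_model = c("shifted_poisson", "fixed"),
                      chimera_rate = 0, ambient_fraction = 0,
                      multimap_rate = 0, unmapped_rate = 0) {
  pcr_model <- match.arg(pcr_model)
  rates <- c(base_error_rate, umi_error_rate, umi_n_rate, chimera_rate,
             ambient_fraction, multimap_rate, unmapped_rate)
  stopifnot(all(rates >= 0 & rates <= 1), pcr_mean >= 1)
  structure(list(base_error_rate = base_error_rate,
                 umi_error_rate = umi_error_rate, umi_n_rate = umi_n_rate,
                 pcr_mean = pcr_mean, pcr_model = pcr_model,
                 chimera_rate = chimera_rate,
                 ambient_fraction = ambient_fraction,
                 multimap_rate = multimap_rate,
                 unmapped_rate = unmapped_rate),
            class = "sim_noise")
}

# substitute bases at a per-base rate; returns list(seq, n_changed).
# substitutions always change the base (uniform over the other three).
mutate_bases <- function(seqs, rate, to_n = FALSE) {
  n_changed <- integer(length(seqs))
  if (rate <= 0 || length(seqs) == 0L)
    return(list(seq = seqs, n_changed = n_changed))
  len <- nchar(seqs[1])
  k <- stats::rbinom(length(seqs), len, rate)
  hit <- which(k > 0L)
  for (i in hit) {
    pos <- sample.int(len, k[i])
    s <- seqs[i]
    for (p in pos) {
      old <- substr(s, p, p)
      new <- if (to_n) "N" else sample(setdiff(DNA_BASES, old), 1L)
      substr(s, p, p) <- new
    }
    seqs[i] <- s
  }
  n_changed[hit] <- k[hit]
  list(seq = seqs, n_changed = n_changed)
}

#' Emit sequencing reads from ground-truth transcript counts
#'
#' Converts a true molecule-count matrix into a paired-end library:
#' every true transcript receives a UMI drawn uniformly over the 4^10
#' 10-mers (with replacement, so UMI collisions can occur, as in a real
#' library), is PCR-amplified into one or more reads, and each read is
#' emitted as read 1 = barcode + UMI + poly-A pad and read 2 = cDNA
#' drawn from the gene sequence (poly-A filled when the transcript is
#' shorter than the read). Substitution errors, chimeric reads, ambient
#' reads, multi-mapping and unmapped flags are applied per the noise
#' model, and every read keeps a provenance record naming its cell,
#' gene and true UMI. Output order is a seeded permutation and the whole
#' library is byte-reproducible given (inputs, seed).
#'
#' @param counts integer matrix genes x cells of true transcript counts
#' @param cells `data.table` with columns `cell_id`, `barcode` (and
#'   optionally `row_`, `col_`, `sample_id`) mapping each count column to
#'   a well; every `colnames(counts)` entry must appear once
#' @param gene_model a [synthetic_gene_model()] covering `rownames(counts)`
#' @param structure a [read_structure()]
#' @param noise a [sim_noise()]
#' @param seed RNG seed
#' @param dir if non-NULL, write `<prefix>_R1.fastq.gz`,
#'   `<prefix>_R2.fastq.gz`, `<prefix>.sam`, `<prefix>_provenance.tsv`
#'   into this directory
#' @param prefix file name prefix used with `dir`
#' @return `sim_reads` list: `r1`, `r2`, `qname` character vectors;
#'   `provenance` data.table (read_id, cell_id, barcode, umi_true,
#'   umi_obs, barcode_obs, gene_true, gene_obs, start, nm, chimeric,
#'   ambient, mapped, nh); `files` (paths or NULL)
#' @export
emit_reads <- function(counts, cells, gene_model, structure = read_structure(),
                       noise = sim_noise(), seed = 1L, dir = NULL,
                       prefix = "sim") {
  stopifnot(inherits(gene_model, "gene_model"),
            inherits(structure, "read_structure"),
            inherits(noise, "sim_noise"),
            !is.null(gene_model$seqs))
  cells <- data.table::as.data.table(cells)
  if (!all(colnames(counts) %in% cells$cell_id))
    stop("every cell in counts must sit in a well with a barcode")
  if (!all(rownames(counts) %in% names(gene_model$seqs)))
    stop("gene model must cover all genes in counts")
  bc_of <- stats::setNames(cells$barcode, cells$cell_id)
  genes <- rownames(counts)
  glen <- nchar(gene_model$seqs[1])

  withr::with_seed(seed, {
    # molecules
    idx <- which(counts > 0, arr.ind = TRUE)
    tx <- data.table::data.table(
      gene_true = genes[idx[, 1L]],
      cell_id = colnames(counts)[idx[, 2L]],
      n = as.integer(counts[idx]))
    tx <- tx[rep(seq_len(.N), n), .(gene_true, cell_id)]
    ntx <- nrow(tx)
    tx[, umi_true := random_dna(ntx, structure$umi_len)]
    # amplification
    dup <- switch(noise$pcr_model,
      fixed = rep(as.integer(round(noise$pcr_mean)), ntx),
      shifted_poisson = 1L + stats::rpois(ntx, noise$pcr_mean - 1))
    rd <- tx[rep(seq_len(ntx), dup)]
    n <- nrow(rd)
    rd <- rd[sample.int(n)] # library order is not molecule order
    rd[, gene_obs := gene_true]
    rd[, `:=`(chimeric = FALSE, ambient = FALSE)]
    # ambient RNA: read comes from the pooled profile, fresh molecule
    if (noise$ambient_fraction > 0) {
      amb <- which(stats::runif(n) < noise$ambient_fraction)
      pool <- rowSums(counts)
      rd$gene_obs[amb] <- rd$gene_true[amb] <-
        sample(genes, length(amb), replace = TRUE, prob = pool + 1e-9)
      rd$umi_true[amb] <- random_dna(length(amb), structure$umi_len)
      rd$ambient[amb] <- TRUE
    }
    # chimeric PCR products: barcode+UMI joined to another gene's cDNA
    if (noise$chimera_rate > 0) {
      chi <- which(stats::runif(n) < noise$chimera_rate)
      rd$gene_obs[chi] <- sample(genes, length(chi), replace = TRUE)
      rd$chimeric[chi] <- TRUE
    }
    # cDNA read: uniform start within the transcript
    max_start <- max(glen - structure$read2_len + 1L, 1L)
    rd[, start_pos := sample.int(max_start, n, replace = TRUE)]
    r2 <- substr(gene_model$seqs[rd$gene_obs], rd$start_pos,
                 rd$start_pos + structure$read2_len - 1L)
    short <- nchar(r2) < structure$read2_len
    if (any(short)) # oligo-dT priming: fill with poly-A
      r2[short] <- paste0(r2[short], strrep("A", structure$read2_len - nchar(r2[short])))
    m2 <- mutate_bases(r2, noise$base_error_rate)
    rd[, nm := m2$n_changed]
    # observed UMI: substitution errors then N calls
    mu <- mutate_bases(rd$umi_true, noise$umi_error_rate)
    mn <- mutate_bases(mu$seq, noise$umi_n_rate, to_n = TRUE)
    rd[, umi_obs := mn$seq]
    # observed barcode
    mb <- mutate_bases(unname(bc_of[rd$cell_id]), noise$base_error_rate)
    rd[, barcode_obs := mb$seq]
    rd[, barcode := unname(bc_of[cell_id])]
    rd[, mapped := stats::runif(n) >= noise$unmapped_rate]
    rd[, nh := 1L + (stats::runif(n) < noise$multimap_rate)]
    rd[, read_id := sprintf("read%08d", seq_len(n))]
  })
  pad <- strrep("A", structure$read1_len - structure$barcode_len - structure$umi_len)
  r1 <- paste0(rd$barcode_obs, rd$umi_obs, pad)
  prov <- rd[, .(read_id, cell_id, barcode, umi_true, umi_obs, barcode_obs,
                 gene_true, gene_obs, start = start_pos, nm, chimeric,
                 ambient, mapped, nh)]
  files <- NULL
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    f1 <- file.path(dir, paste0(prefix, "_R1.fastq.gz"))
    f2 <- file.path(dir, paste0(prefix, "_R2.fastq.gz"))
    fs <- file.path(dir, paste0(prefix, ".sam"))
    fp <- file.path(dir, paste0(prefix, "_provenance.tsv"))
    write_fastq(rd$read_id, r1, f1)
    write_fastq(rd$read_id, m2$seq, f2)
    write_sam(prov, m2$seq, gene_model, fs)
    data.table::fwrite(prov, fp, sep = "\t")
    files <- list(r1 = f1, r2 = f2, sam = fs, provenance = fp)
  }
  structure(list(r1 = r1, r2 = m2$seq, qname = rd$read_id,
                 provenance = prov, files = files),
            class = "sim_reads")
}

# plain 4-line FASTQ records, gzipped when the path ends in .gz
write_fastq <- function(ids, seqs, path) {
  qual <- strrep("I", nchar(seqs))
  rec <- paste0("@", ids, "\n", seqs, "\n+\n", qual)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeLines(rec, con)
  invisible(path)
}

# one SAM record per read pair, keyed by the read-2 alignment; barcode
# and UMI in CB/UB tags, mismatches in NM, hit count in NH, gene in GX
write_sam <- function(prov, r2, gene_model, path) {
  g <- gene_model$genes
  chrlen <- g[, .(len = max(end) + 100L), by = chrom]
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", chrlen$chrom, chrlen$len))
  gs <- stats::setNames(g$start, g$gene_id)
  gc <- stats::setNames(g$chrom, g$gene_id)
  pos <- unname(gs[prov$gene_obs]) + prov$start - 1L
  flag <- ifelse(prov$mapped, 0L, 4L)
  rname <- ifelse(prov$mapped, unname(gc[prov$gene_obs]), "*")
  mapq <- ifelse(!prov$mapped, 0L, ifelse(prov$nh > 1L, 0L, 60L))
  cigar <- ifelse(prov$mapped, paste0(nchar(r2), "M"), "*")
  body <- paste0(prov$read_id, "\t", flag, "\t", rname, "\t",
                 ifelse(prov$mapped, pos, 0L), "\t", mapq, "\t", cigar,
                 "\t*\t0\t0\t", r2, "\t*",
                 "\tCB:Z:", prov$barcode_obs, "\tUB:Z:", prov$umi_obs,
                 ifelse(prov$mapped, paste0("\tNM:i:", prov$nm), ""),
                 "\tNH:i:", prov$nh,
                 ifelse(prov$mapped, paste0("\tGX:Z:", prov$gene_obs), ""))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read tagged alignments from SAM/BAM
#'
#' Loads alignment records with CB/UB/NM/NH/GX tags into a flat table.
#' SAM input is converted with `Rsamtools::asBam` first.
#'
#' @param path SAM or BAM file
#' @return `data.table(read_id, chrom, pos, width, mapped, mapq, nm, nh,
#'   cb, ub)`
#' @export
read_alignments <- function(path) {
  if (grepl("\\.sam$", path)) {
    bam <- sub("\\.sam$", "", path)
    path <- Rsamtools::asBam(path, bam, overwrite = TRUE, indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "qwidth", "mapq"),
    tag = c("NM", "NH", "CB", "UB", "GX"))
  b <- Rsamtools::scanBam(path, param = p)[[1]]
  n <- length(b$qname)
  tag_or <- function(tg, default) if (is.null(b$tag[[tg]])) rep(default, n) else b$tag[[tg]]
  data.table::data.table(
    read_id = b$qname,
    chrom = as.character(b$rname),
    pos = b$pos, width = b$qwidth,
    mapped = !bitwAnd(b$flag, 4L),
    mapq = b$mapq,
    nm = tag_or("NM", NA_integer_),
    nh = tag_or("NH", NA_integer_),
    cb = tag_or("CB", NA_character_),
    ub = tag_or("UB", NA_character_),
    gx = tag_or("GX", NA_character_))
}
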