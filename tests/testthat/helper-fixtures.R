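library(data.table)

# session-level cache for expensive fixtures (the full-size chip layout
# takes a few seconds to build because of the min-distance barcode design)
.fixtures <- new.env(parent = emptyenv())

full_layout <- function() {
  if (is.null(.fixtures$full_layout))
    .fixtures$full_layout <- chip_layout(n_rows = 72, n_cols = 72, seed = 1)
  .fixtures$full_layout
}

small_layout <- function(seed = 1) chip_layout(n_rows = 12, n_cols = 12, seed = seed)

# independent UMI-clustering oracle: brute-force pairwise Hamming
# adjacency + graph connected components (igraph), nothing shared with
# the package's union-find implementation
oracle_cluster <- function(umis, reads, max_mismatch) {
  n <- length(umis)
  d <- outer(seq_len(n), seq_len(n), Vectorize(function(i, j) hamming(umis[i], umis[j])))
  g <- igraph::graph_from_adjacency_matrix(d <= max_mismatch, mode = "undirected")
  comp <- igraph::components(g)$membership
  dt <- data.table(umi = umis, reads = reads, comp = comp)
  out <- dt[, .(read_support = sum(reads), n_umis = .N), by = comp]
  sort_support <- sort(out$read_support)
  list(n_clusters = nrow(out), supports = sort_support, membership = comp)
}

# random UMI multiset instance for property tests
random_umi_instance <- function(n_max = 200, len = 6, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- sample(2:n_max, 1)
  umis <- unique(nanowell:::random_dna(n, len))
  reads <- sample(1:5, length(umis), replace = TRUE)
  list(umis = umis, reads = reads)
}

# tiny simulated library shared by quantify/demux tests: noiseless,
# fixed 2 reads per molecule
tiny_library <- function(n_genes = 40, n_cells = 8, depth = 60, seed = 42,
                         noise = sim_noise(pcr_mean = 2, pcr_model = "fixed"),
                         layout = small_layout()) {
  truth <- simulate_dispense(layout, lambda = 1, seed = seed + 1)
  singles <- single_live_cell_wells(truth)
  stopifnot(nrow(singles) >= n_cells)
  expr <- simulate_expression(n_genes = n_genes, n_cells = n_cells,
                              depth = depth, seed = seed + 2)
  wells <- head(singles, n_cells)
  cells <- data.table(cell_id = colnames(expr$counts), barcode = wells$barcode,
                      row_ = wells$row_, col_ = wells$col_)
  gm <- synthetic_gene_model(rownames(expr$counts), seed = seed + 3)
  sim <- emit_reads(expr$counts, cells, gm, noise = noise, seed = seed + 4)
  list(layout = layout, expr = expr, cells = cells, gm = gm, sim = sim)
}

# run demux + quantify on an in-memory tiny library, return counts
# matrix aligned to the truth (genes x cells, truth cell ids)
quantify_library <- function(lib, config = counting_config()) {
  dm <- demultiplex(lib$sim$r1, lib$sim$r2, lib$layout$wells, ids = lib$sim$qname)
  prov <- lib$sim$provenance
  aln <- data.table(read_id = prov$read_id,
                    chrom = lib$gm$genes$chrom[1],
                    pos = lib$gm$genes[match(prov$gene_obs, gene_id), start] + prov$start - 1L,
                    width = 50L, mapped = prov$mapped, nh = prov$nh)
  well_ids <- sprintf("R%02dC%02d", lib$cells$row_, lib$cells$col_)
  tc <- quantify_counts(dm, aln, lib$gm, config,
                        gene_meta = lib$expr$gene_meta,
                        cell_meta = data.table(cell_id = well_ids))
  m <- as.matrix(tc$counts)[rownames(lib$expr$counts), well_ids, drop = FALSE]
  colnames(m) <- lib$cells$cell_id
  list(tc = tc, m = m)
}
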