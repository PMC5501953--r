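test_that("UMI clustering handles the canonical worked examples", {
  cl <- cluster_umis(c("AAAAAAAAAA", "AAAAAAAAAT", "CCCCCCCCCC"), c(3L, 1L, 2L))
  expect_equal(nrow(cl), 2L)
  expect_equal(sort(cl$read_support), c(2L, 4L))
  # single UMI
  one <- cluster_umis("ACGTACGTAC", 7L)
  expect_equal(one$read_support, 7L)
  # chain u1-u2-u3 with d(u1,u3)=2 merges transitively
  chain <- cluster_umis(c("AAAAAAAAAA", "AAAAAAAAAT", "AAAAAAAAGT"), c(1L, 1L, 1L))
  expect_equal(nrow(chain), 1L)
  expect_equal(chain$read_support, 3L)
  # invalid inputs
  expect_error(cluster_umis(c("AAAA", "AAAAA")), "same length")
  expect_error(cluster_umis(c("AAAN")), "A/C/G/T")
})

test_that("clustering equals the brute-force connected-components oracle", {
  skip_if_not_installed("igraph")
  set.seed(99)
  for (i in 1:120) {
    len <- sample(4:8, 1)
    inst <- random_umi_instance(n_max = 120, len = len)
    mm <- sample(0:2, 1)
    got <- cluster_umis(inst$umis, inst$reads, max_mismatch = mm)
    want <- oracle_cluster(inst$umis, inst$reads, max_mismatch = mm)
    expect_equal(nrow(got), want$n_clusters)
    expect_equal(sort(got$read_support), want$supports)
  }
})

test_that("transcript counts apply the read-support threshold", {
  # three clusters with supports 4, 2, 1 in one (cell, gene)
  reads <- data.table(
    cell_id = "c1", gene_id = "g1",
    umi = c(rep("AAAAAAAAAA", 4), rep("CCCCCCCCCC", 2), "GGGGGGGGGG"))
  counts_at <- function(mr) {
    tc <- count_transcripts(reads, counting_config(min_reads_per_umi = mr))
    as.numeric(tc$counts["g1", "c1"])
  }
  expect_equal(counts_at(1), 3)
  expect_equal(counts_at(2), 2)
  expect_equal(counts_at(3), 1)
  # no qualifying clusters -> zero
  tc0 <- count_transcripts(reads[7], counting_config(min_reads_per_umi = 2))
  expect_equal(sum(tc0$counts), 0)
})

test_that("two singleton UMIs one mismatch apart survive the >=2-read filter", {
  reads <- data.table(cell_id = "c1", gene_id = "g1",
                      umi = c("AAAAAAAAAA", "AAAAAAAAAT"))
  tc <- count_transcripts(reads, counting_config(min_reads_per_umi = 2))
  expect_equal(as.numeric(tc$counts["g1", "c1"]), 1)
  tc0 <- count_transcripts(reads, counting_config(min_reads_per_umi = 2,
                                                  umi_max_mismatch = 0))
  expect_equal(sum(tc0$counts), 0)
})

test_that("counts are monotone in the read threshold and mismatch radius", {
  set.seed(7)
  reads <- data.table(
    cell_id = sample(sprintf("c%d", 1:5), 4000, TRUE),
    gene_id = sample(sprintf("g%d", 1:20), 4000, TRUE),
    umi = nanowell:::random_dna(4000, 4))   # short UMIs force collisions
  tot <- function(mr, mm)
    sum(count_transcripts(reads, counting_config(mr, mm))$counts)
  expect_true(tot(1, 1) >= tot(2, 1) && tot(2, 1) >= tot(3, 1))
  # widening the merge radius can only reduce the number of clusters
  expect_true(tot(1, 0) >= tot(1, 1) && tot(1, 1) >= tot(1, 2))
  # conservation: matrix total equals number of qualifying clusters
  tc <- count_transcripts(reads, counting_config(2, 1))
  expect_equal(sum(tc$counts), tc$counters$clusters_kept)
})

test_that("N-containing UMIs are excluded before clustering", {
  reads <- data.table(cell_id = "c", gene_id = "g",
                      umi = c("ACGTNACGTA", "ACGTACGTAC", "ACGTACGTAC"))
  d <- drop_n_umis(reads)
  expect_equal(d$n_dropped, 1L)
  tc <- count_transcripts(reads, counting_config(min_reads_per_umi = 1))
  expect_equal(sum(tc$counts), 1)
  expect_equal(tc$counters$n_umi_dropped, 1L)
  # N fraction matches 1-(1-p)^10 on simulation
  p_n <- 0.02
  lib <- tiny_library(n_genes = 30, n_cells = 10, depth = 150, seed = 13,
                      noise = sim_noise(pcr_mean = 3, umi_n_rate = p_n))
  frac <- mean(grepl("N", lib$sim$provenance$umi_obs))
  p <- 1 - (1 - p_n)^10
  n <- nrow(lib$sim$provenance)
  expect_lt(abs(frac - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("unique-mapping filter drops multimappers and requires NH", {
  aln <- data.table(read_id = c("a", "b", "c"), mapped = c(TRUE, TRUE, FALSE),
                    nh = c(1L, 2L, 1L))
  f <- filter_alignments(aln)
  expect_equal(f$alignments$read_id, "a")
  expect_equal(f$counters$multimapped, 1L)
  expect_equal(f$counters$unmapped, 1L)
  expect_error(filter_alignments(aln[, .(read_id, mapped)]), "uniqueness")
  f0 <- filter_alignments(aln[0])
  expect_equal(nrow(f0$alignments), 0L)
})

test_that("gene assignment follows exact single-overlap semantics", {
  gm <- synthetic_gene_model(c("gA", "gB"), gene_len = 100L, spacer = 50L, seed = 2)
  # gA = 1..100, gap = 101..150, gB = 151..250
  aln <- data.table(chrom = "chrS1", pos = c(10L, 101L, 160L), width = 50L)
  got <- assign_gene(aln, gm)
  expect_equal(got, c("gA", NA, "gB"))
  # read overlapping two genes is ambiguous
  ov <- structure(list(genes = data.table(
    gene_id = c("g1", "g2"), chrom = "chrS1",
    start = c(1L, 40L), end = c(100L, 140L), strand = "+"), seqs = NULL),
    class = "gene_model")
  expect_true(is.na(assign_gene(data.table(chrom = "chrS1", pos = 50L, width = 10L), ov)))
  # strand policy
  neg <- structure(list(genes = data.table(gene_id = "g", chrom = "chrS1",
                                           start = 1L, end = 100L, strand = "-"),
                        seqs = NULL), class = "gene_model")
  r <- data.table(chrom = "chrS1", pos = 10L, width = 10L, strand = "+")
  expect_true(is.na(assign_gene(r, neg, "sense")))
  expect_equal(assign_gene(r, neg, "unstranded"), "g")
})

test_that("GTF round-trips and malformed files raise errors", {
  gm <- synthetic_gene_model(sprintf("g%02d", 1:5), seed = 4)
  path <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(gm, path)
  back <- read_gene_model(path)
  expect_equal(back$genes$gene_id, gm$genes$gene_id)
  expect_equal(back$genes$start, gm$genes$start)
  expect_equal(back$genes$end, gm$genes$end)
  bad <- withr::local_tempfile(fileext = ".gtf")
  writeLines("chr1\tx\tgene\tnot_a_number\t10\t.\t+\t.\tgene_id \"g\";", bad)
  expect_error(read_gene_model(bad), "malformed")
})

test_that("noiseless library quantifies back to the exact truth", {
  lib <- tiny_library(seed = 42)
  q <- quantify_library(lib, counting_config(min_reads_per_umi = 1))
  expect_identical(unname(q$m), unname(lib$expr$counts))
  # with 2 reads per molecule the default singleton filter changes nothing
  q2 <- quantify_library(lib, counting_config(min_reads_per_umi = 2))
  expect_identical(unname(q2$m), unname(lib$expr$counts))
})

test_that("UMI-error clustering reduces count inflation (RMSE vs truth)", {
  lib <- tiny_library(n_genes = 60, n_cells = 15, depth = 150, seed = 91,
                      noise = sim_noise(pcr_mean = 6, umi_error_rate = 0.01))
  rmse <- function(mm) {
    q <- quantify_library(lib, counting_config(min_reads_per_umi = 2,
                                               umi_max_mismatch = mm))
    sqrt(mean((q$m - lib$expr$counts)^2))
  }
  expect_lt(rmse(1), rmse(0))
})
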