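#' Simulate ground-truth transcript counts with cell-type structure
#'
#' Generates a genes x cells matrix of true transcript (molecule) counts
#' from a negative binomial model. Each cell type has
#' `markers_per_type` dedicated marker genes whose mean expression is
#' elevated `fold_change`-fold in its own type; all other (baseline)
#' genes share means drawn from a gamma profile. A configurable set of
#' genes is flagged mitochondrial (name prefix `"mt-"`) and scaled so the
#' expected mitochondrial fraction of each cell's transcripts equals
#' `mito_fraction` (around 6% is typical of healthy cultured cells).
#'
#' @param n_cell_types number of cell types
#' @param markers_per_type marker genes per type (may be 0)
#' @param n_genes total genes; must be >= `n_cell_types * markers_per_type`
#' @param n_cells total number of cells
#' @param type_props relative abundances of the types (recycled /
#'   normalized); default equal
#' @param depth mean true transcripts per cell
#' @param fold_change marker elevation in own type (1 = no structure)
#' @param dispersion negative binomial dispersion (var = mu + dispersion
#'   * mu^2); 0 gives Poisson
#' @param n_mito number of mitochondrial genes (prefix "mt-"); drawn from
#'   the baseline pool
#' @param mito_fraction expected fraction of transcripts from mito genes
#' @param type_names optional type labels (default "type1"...)
#' @param marker_names optional list (per type) of marker gene names, so
#'   simulations can carry real marker symbols (e.g. Ins1/Gcg/Sst/Ppy)
#' @param seed RNG seed
#' @return list with
#'   * `counts`: integer matrix genes x cells, dimnames set
#'   * `gene_meta`: `data.table(gene_id, mito, marker_of)`
#'   * `cell_meta`: `data.table(cell_id, type)`
#' @examples
#' sim <- simulate_expression(n_cell_types = 2, markers_per_type = 3,
#'                            n_genes = 50, n_cells = 20, seed = 1)
#' dim(sim$counts)
#' @export
simulate_expression <- function(n_cell_types = 1L, markers_per_type = 0L,
                                n_genes = 200L, n_cells = 100L,
                                type_props = NULL, depth = 1000,
                                fold_change = 20, dispersion = 0.25,
                                n_mito = 5L, mito_fraction = 0.06,
                                type_names = NULL, marker_names = NULL,
                                seed = 1L) {
  n_markers <- n_cell_types * markers_per_type
  if (n_genes < n_markers)
    stop("n_genes must be at least n_cell_types * markers_per_type")
  if (n_mito > n_genes - n_markers)
    stop("not enough baseline genes for ", n_mito, " mitochondrial genes")
  if (is.null(type_names)) type_names <- sprintf("type%d", seq_len(n_cell_types))
  stopifnot(length(type_names) == n_cell_types)
  if (is.null(type_props)) type_props <- rep(1, n_cell_types)
  type_props <- type_props / sum(type_props)

  gene_id <- sprintf("gene%04d", seq_len(n_genes))
  marker_of <- rep(NA_character_, n_genes)
  if (n_markers > 0L) {
    marker_idx <- seq_len(n_markers)
    marker_of[marker_idx] <- rep(type_names, each = markers_per_type)
    if (!is.null(marker_names)) {
      nm <- unlist(marker_names)
      stopifnot(length(nm) == n_markers)
      gene_id[marker_idx] <- nm
    }
  }
  mito_idx <- if (n_mito > 0L) seq.int(n_markers + 1L, n_markers + n_mito) else integer(0)
  gene_id[mito_idx] <- sprintf("mt-gene%04d", mito_idx)
  mito <- seq_len(n_genes) %in% mito_idx

  withr::with_seed(seed, {
    # cell types by multinomial draw at the given relative abundances
    type <- sample(type_names, n_cells, replace = TRUE, prob = type_props)
    # baseline mean profile: gamma-shaped, scaled to the target depth with
    # the mitochondrial share pinned to mito_fraction
    base <- stats::rgamma(n_genes, shape = 0.6, rate = 1) + 1e-4
    if (n_markers > 0L) {
      # marker genes (hormones and the like) are solidly expressed; a
      # common baseline keeps marker sets comparable on the expression
      # scale, as real cell-type markers are
      base[!is.na(marker_of)] <- mean(base[is.na(marker_of) & !mito])
    }
    base[mito] <- base[mito] / sum(base[mito]) * mito_fraction
    base[!mito] <- base[!mito] / sum(base[!mito]) * (1 - mito_fraction)
    mu <- matrix(base, n_genes, n_cells)
    if (n_markers > 0L && fold_change != 1) {
      for (k in seq_len(n_cell_types)) {
        rows <- which(marker_of == type_names[k])
        mu[rows, type == type_names[k]] <- mu[rows, type == type_names[k]] * fold_change
      }
      mu <- sweep(mu, 2L, colSums(mu), "/")
    }
    mu <- mu * depth
    counts <- if (dispersion > 0) {
      matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion),
             n_genes, n_cells)
    } else {
      matrix(stats::rpois(length(mu), lambda = mu), n_genes, n_cells)
    }
  })
  cell_id <- sprintf("cell%05d", seq_len(n_cells))
  dimnames(counts) <- list(gene_id, cell_id)
  list(counts = counts,
       gene_meta = data.table::data.table(gene_id = gene_id, mito = mito,
                                          marker_of = marker_of),
       cell_meta = data.table::data.table(cell_id = cell_id, type = type))
}
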