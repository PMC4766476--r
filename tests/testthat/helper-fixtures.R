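# Small in-code fixtures shared across tests.

toy_wells <- function(ratios, plate_id = "P1", control_role = "none") {
  n <- length(ratios)
  tibble::tibble(
    plate_id = plate_id,
    well_id = sprintf("A%02d", seq_len(n)),
    gene_id = paste0("g", seq_len(n)),
    dsrna_id = paste0("d", seq_len(n)),
    fluc = ratios,
    rluc = 1,
    control_role = control_role
  )
}

# a tiny count table with gene_id + named sample columns
toy_counts <- function(mat, gene_ids = paste0("g", seq_len(nrow(mat)))) {
  stopifnot(!is.null(colnames(mat)))
  dplyr::bind_cols(
    tibble::tibble(gene_id = gene_ids),
    tibble::as_tibble(as.data.frame(mat))
  )
}

four_cond_design <- function(n_rep = 3) {
  conds <- condition_levels()
  tibble::tibble(
    sample_id = as.vector(vapply(
      conds, function(cc) sprintf("%s_%d", cc, seq_len(n_rep)),
      character(n_rep)
    )),
    condition = rep(conds, each = n_rep),
    replicate = rep(seq_len(n_rep), times = length(conds))
  )
}

# build a norm-style table from per-condition replicate values
cond_matrix <- function(..., n_rep = 3) {
  vals <- list(...) # named by condition: each a length-n_rep vector or matrix
  conds <- names(vals)
  m <- do.call(cbind, lapply(conds, function(cc) {
    v <- vals[[cc]]
    if (is.null(dim(v))) v <- matrix(v, nrow = 1)
    colnames(v) <- sprintf("%s_%d", cc, seq_len(ncol(v)))
    v
  }))
  m
}

# the powered configuration used to demonstrate that the selection
# machinery recovers planted structure when the data carry enough
# information (high counts, low dispersion, strong knockdown arm)
powered_counts_cfg <- function(seed) {
  counts_sim_config(
    baseline_mean = 1000, dispersion = 0.005, fold_b_cdk12i = 0.25,
    seed = seed
  )
}
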