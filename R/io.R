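# Plain-TSV readers and writers for every interface the stages share.
# All files are UTF-8, tab-separated, '.' decimal separator, deterministic
# row order.

read_tsv_quiet <- function(path, col_types) {
  if (!file.exists(path)) {
    abort(sprintf("Input file not found: %s", path))
  }
  readr::read_tsv(path, col_types = col_types, progress = FALSE)
}

#' Read and write well-level screen tables
#'
#' The screen table is a TSV with header `plate_id well_id gene_id
#' dsrna_id fluc rluc control_role`.
#'
#' @param path File path.
#' @return `read_screen_table()` returns a tibble suitable for
#'   [normalize_wells()].
#' @export
read_screen_table <- function(path) {
  df <- read_tsv_quiet(path, readr::cols(
    plate_id = "c", well_id = "c", gene_id = "c", dsrna_id = "c",
    fluc = "d", rluc = "d", control_role = "c"
  ))
  check_columns(df, c("plate_id", "well_id", "gene_id", "dsrna_id",
                      "fluc", "rluc"), "screen table")
  df
}

#' @rdname read_screen_table
#' @param wells A screen plate table.
#' @export
write_screen_table <- function(wells, path) {
  readr::write_tsv(wells, path)
  invisible(path)
}

#' Read a per-dsRNA Z-score table
#'
#' TSV with header `gene_id dsrna_id z` and optionally `control_role`,
#' e.g. a published screen summary table transcribed to text.
#'
#' @param path File path.
#' @return A tibble consumable by [classify_genes()].
#' @export
read_zscore_table <- function(path) {
  df <- read_tsv_quiet(path, readr::cols(
    gene_id = "c", dsrna_id = "c", z = "d", .default = "c"
  ))
  check_columns(df, c("gene_id", "dsrna_id", "z"), "zscore table")
  df
}

#' Write Z-scores and gene calls
#'
#' `write_zscore_table()` emits `gene_id dsrna_id z`;
#' `write_gene_calls()` emits one row per gene in rank order:
#' `gene_id call n_passing mean_z z1 z2 ...`.
#'
#' @param zscores,calls Tables from [compute_zscores()] /
#'   [classify_genes()].
#' @param path File path.
#' @export
write_zscore_table <- function(zscores, path) {
  readr::write_tsv(zscores[, c("gene_id", "dsrna_id", "z")], path)
  invisible(path)
}

#' @rdname write_zscore_table
#' @export
write_gene_calls <- function(calls, path) {
  ranked <- rank_hits(calls)
  width <- max(lengths(ranked$z_values))
  zmat <- t(vapply(
    ranked$z_values,
    function(z) c(z, rep(NA_real_, width - length(z))),
    numeric(width)
  ))
  colnames(zmat) <- paste0("z", seq_len(width))
  out <- tibble(
    gene_id = ranked$gene_id,
    call = ranked$call,
    n_passing = ranked$n_passing,
    mean_z = ranked$rank_score
  ) %>% dplyr::bind_cols(as_tibble(as.data.frame(zmat)))
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read a gene-by-sample count matrix
#'
#' TSV whose first column is `gene_id` and remaining columns are sample
#' ids holding non-negative integer counts.
#'
#' @param path File path.
#' @return A count tibble.
#' @export
read_count_matrix <- function(path) {
  df <- read_tsv_quiet(path, readr::cols(gene_id = "c", .default = "d"))
  check_columns(df, "gene_id", "count matrix")
  df
}

#' Read a sample design table
#'
#' TSV with header `sample_id condition replicate`.
#'
#' @param path File path.
#' @return A design tibble.
#' @export
read_sample_design <- function(path) {
  df <- read_tsv_quiet(path, readr::cols(
    sample_id = "c", condition = "c", replicate = "i"
  ))
  validate_design(df)
}

#' Read a gene annotation table
#'
#' TSV with one association per line: `term_id term_name gene_id`.
#'
#' @param path File path.
#' @return An annotation tibble for [enrich()].
#' @export
read_annotation <- function(path) {
  df <- read_tsv_quiet(path, readr::cols(
    term_id = "c", term_name = "c", gene_id = "c"
  ))
  check_columns(df, c("term_id", "term_name", "gene_id"), "annotation")
  df
}

#' Write differential-comparison and enrichment tables
#'
#' `write_de_table()` emits `gene_id log2fc p q`; `write_enrichment()`
#' emits the term-finder style summary (`term_name cluster_frequency
#' genome_frequency corrected_p` plus the k/K/n/N audit columns).
#'
#' @param de,enr Result tables.
#' @param path File path.
#' @export
write_de_table <- function(de, path) {
  readr::write_tsv(as_tibble(unclass_de(de)), path)
  invisible(path)
}

#' @rdname write_de_table
#' @export
write_enrichment <- function(enr, path) {
  out <- tidy(enr)[, c(
    "term_name", "cluster_frequency", "genome_frequency", "p_corrected",
    "k", "K", "n", "N", "p_raw", "term_id"
  )]
  out <- rename(out, corrected_p = "p_corrected")
  readr::write_tsv(out, path)
  invisible(path)
}

#' Write the selection outputs
#'
#' Emits `group_a_genes.txt` and `group_b_genes.txt` (one gene id per
#' line), `selection_audit.tsv` (the full per-gene criterion audit) and
#' `std_profiles.tsv` (the standardized profile matrix, a plain matrix
#' suitable for external heatmap tools) into `dir`.
#'
#' @param result A `"selection_result"` from [select_groups()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_selection <- function(result, dir) {
  if (!inherits(result, "selection_result")) {
    abort("`result` must be a selection_result.")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c(
    "group_a_genes.txt", "group_b_genes.txt",
    "selection_audit.tsv", "std_profiles.tsv"
  ))
  writeLines(result$group_a, paths[1])
  writeLines(result$group_b, paths[2])
  readr::write_tsv(result$audit, paths[3])
  readr::write_tsv(result$std_profiles, paths[4])
  invisible(paths)
}

#' Published kinome screen Z-score summary
#'
#' Loads the transcribed per-dsRNA Z-score summary of the kinome reporter
#' screen shipped with the package: three assay-control rows (CncC and
#' MafS knockdowns repress the reporter, Keap1 knockdown raises it) and
#' eight screened genes with up to three dsRNAs each. Applying the default
#' consensus rule to the non-control rows reproduces the published hit
#' labels: five inducers (Cdk12, fray, Madm, Psi, CK2a) and three
#' suppressors (Fs(1)h, GSK-3, Nipped-A), with Cdk12 — the strongest
#' repressive effect in the screen — ranked first.
#'
#' @return A tibble `gene_id`, `dsrna_id`, `z`, `control_role`.
#' @export
#' @examples
#' z <- kinome_screen_zscores()
#' classify_genes(dplyr::filter(z, control_role == "none"))
kinome_screen_zscores <- function() {
  read_zscore_table(system.file(
    "extdata", "kinome_screen_zscores.tsv",
    package = "redoxscreen", mustWork = TRUE
  ))
}
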