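# One-call orchestration of the stages with file intermediates and a
# checksummed manifest. Every intermediate is a plain TSV, so any stage
# can be re-run or inspected on its own; identical config + seed gives an
# identical manifest.

#' Run the analysis pipeline end to end
#'
#' Executes the requested stages in dependency order:
#' `simulate` (synthetic screen, counts and annotation with truth tables),
#' `screen` (well normalization, Z-scores, gene calls),
#' `select` (differential tests and the two-group selection, which also
#' writes the four per-comparison DE tables), and
#' `enrich` (term enrichment of each selected group against all genes of
#' the count matrix). Unless the `simulate` stage is run, the inputs must
#' be provided as file paths. All outputs are TSVs under `out_dir`, listed
#' in `manifest.tsv` with MD5 checksums; the effective parameter set
#' (including the seed) is written to `params.json`, which is sufficient
#' to re-run the pipeline bit-identically.
#'
#' @param out_dir Output directory (created if needed).
#' @param stages Character vector of stages to run, any of `"simulate"`,
#'   `"screen"`, `"select"`, `"enrich"`.
#' @param seed Integer seed used by the `simulate` stage (overrides the
#'   seeds inside the configs so one number pins the whole run).
#' @param screen_cfg,counts_cfg Simulation configs (defaults
#'   [screen_sim_config()] / [counts_sim_config()]).
#' @param criteria [selection_criteria()] for the `select` stage.
#' @param k Cluster count for the `select` stage (default 8).
#' @param pseudocount Pseudocount for the differential tests (default
#'   0.5).
#' @param z_scope,z_threshold,min_consistent,opposite_sign_veto Screen
#'   stage parameters (see [compute_zscores()], [classify_genes()]).
#' @param correction Enrichment correction (`"bonferroni"` or `"bh"`).
#' @param screen_table,counts_table,design_table,annotation_table Input
#'   file paths for runs on real data (ignored for stages covered by
#'   `simulate`).
#' @return Invisibly, a list with the manifest tibble and the per-stage
#'   results.
#' @export
#' @examples
#' \donttest{
#' out <- run_pipeline(
#'   tempfile("run"),
#'   seed = 1,
#'   screen_cfg = screen_sim_config(n_genes = 30),
#'   counts_cfg = counts_sim_config(n_background = 60)
#' )
#' out$manifest
#' }
run_pipeline <- function(out_dir,
                         stages = c("simulate", "screen", "select", "enrich"),
                         seed = 1,
                         screen_cfg = screen_sim_config(),
                         counts_cfg = counts_sim_config(),
                         criteria = selection_criteria(),
                         k = 8,
                         pseudocount = 0.5,
                         z_scope = "plate",
                         z_threshold = 1.65,
                         min_consistent = 2,
                         opposite_sign_veto = TRUE,
                         correction = "bonferroni",
                         screen_table = NULL,
                         counts_table = NULL,
                         design_table = NULL,
                         annotation_table = NULL) {
  stages <- match.arg(stages, several.ok = TRUE)
  # validate declared inputs before any output is written
  for (p in c(screen_table, counts_table, design_table, annotation_table)) {
    if (!is.null(p) && !file.exists(p)) {
      abort(sprintf("Input file not found: %s", p))
    }
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  results <- list()
  outputs <- character()

  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("Stage '%s' failed: %s", stage, conditionMessage(e)),
            parent = e)
    })
  }

  path_of <- function(name) file.path(out_dir, name)
  # `note` and stage expressions are evaluated in this frame, so plain
  # assignment updates the pipeline state.
  note <- function(...) outputs <<- c(outputs, c(...))

  if ("simulate" %in% stages) {
    run_stage("simulate", {
      screen_cfg$seed <- seed
      counts_cfg$seed <- seed
      sim_screen <- gen_screen(screen_cfg)
      sim_counts <- gen_counts(counts_cfg)
      ann <- gen_annotation(sim_counts$truth, seed = seed)
      write_screen_table(sim_screen$wells, path_of("screen_wells.tsv"))
      readr::write_tsv(sim_screen$truth, path_of("screen_truth.tsv"))
      readr::write_tsv(sim_counts$counts, path_of("counts.tsv"))
      readr::write_tsv(sim_counts$design, path_of("design.tsv"))
      readr::write_tsv(sim_counts$truth, path_of("counts_truth.tsv"))
      readr::write_tsv(ann, path_of("annotation.tsv"))
      note("screen_wells.tsv", "screen_truth.tsv", "counts.tsv",
           "design.tsv", "counts_truth.tsv", "annotation.tsv")
      screen_table <- path_of("screen_wells.tsv")
      counts_table <- path_of("counts.tsv")
      design_table <- path_of("design.tsv")
      annotation_table <- path_of("annotation.tsv")
      results$simulate <- list(screen = sim_screen, counts = sim_counts,
                               annotation = ann)
    })
  }

  if ("screen" %in% stages) {
    run_stage("screen", {
      if (is.null(screen_table)) abort("No screen table; run 'simulate' or pass `screen_table`.")
      wells <- read_screen_table(screen_table)
      norm <- normalize_wells(wells)
      z <- compute_zscores(norm, z_scope = z_scope)
      calls <- classify_genes(
        z, z_threshold = z_threshold, min_consistent = min_consistent,
        opposite_sign_veto = opposite_sign_veto
      )
      write_zscore_table(z, path_of("zscores.tsv"))
      write_gene_calls(calls, path_of("gene_calls.tsv"))
      if (nrow(well_failures(norm)) > 0) {
        readr::write_tsv(well_failures(norm), path_of("well_failures.tsv"))
        note("well_failures.tsv")
      }
      note("zscores.tsv", "gene_calls.tsv")
      inform(sprintf(
        "screen: %d wells in, %d scored, %d genes called (%d inducers, %d suppressors)",
        nrow(wells), nrow(z), nrow(calls),
        sum(calls$call == "inducer"), sum(calls$call == "suppressor")
      ))
      results$screen <- list(zscores = z, calls = calls)
    })
  }

  if ("select" %in% stages || "enrich" %in% stages) {
    run_stage("select", {
      if (is.null(counts_table) || is.null(design_table)) {
        abort("No counts/design; run 'simulate' or pass `counts_table` and `design_table`.")
      }
      counts <- read_count_matrix(counts_table)
      design <- read_sample_design(design_table)
      sel <- select_groups(counts, design, criteria = criteria, k = k,
                           pseudocount = pseudocount)
      write_selection(sel, out_dir)
      note("group_a_genes.txt", "group_b_genes.txt",
           "selection_audit.tsv", "std_profiles.tsv")
      for (d in sel$de) {
        nm <- sprintf("de_%s_vs_%s.tsv", attr(d, "numerator"),
                      attr(d, "denominator"))
        write_de_table(d, path_of(nm))
        note(nm)
      }
      summary_wide <- sel$summary %>%
        tidyr::pivot_wider(id_cols = "gene_id", names_from = "condition",
                           values_from = "mean_expr",
                           names_prefix = "mean_")
      readr::write_tsv(summary_wide, path_of("expression_summary.tsv"))
      note("expression_summary.tsv")
      inform(sprintf(
        "select: %d genes in, %d pass min-read, group A %d, group B %d",
        nrow(sel$audit), sum(sel$audit$pass_min_reads),
        length(sel$group_a), length(sel$group_b)
      ))
      results$select <- sel
    })
  }

  if ("enrich" %in% stages) {
    run_stage("enrich", {
      if (is.null(annotation_table)) {
        abort("No annotation table; run 'simulate' or pass `annotation_table`.")
      }
      ann <- read_annotation(annotation_table)
      sel <- results$select
      background <- sel$audit$gene_id
      for (grp in c("group_a", "group_b")) {
        genes <- sel[[grp]]
        if (length(genes) == 0) next
        enr <- enrich(genes, background, ann, correction = correction)
        nm <- sprintf("enrichment_%s.tsv", grp)
        write_enrichment(enr, path_of(nm))
        note(nm)
      }
      results$enrich <- TRUE
    })
  }

  params <- list(
    seed = seed, stages = stages,
    screen = list(z_scope = z_scope, z_threshold = z_threshold,
                  min_consistent = min_consistent,
                  opposite_sign_veto = opposite_sign_veto),
    screen_sim = if ("simulate" %in% stages) unclass(screen_cfg),
    counts_sim = if ("simulate" %in% stages) unclass(counts_cfg),
    criteria = unclass(criteria), k = k, pseudocount = pseudocount,
    correction = correction
  )
  jsonlite::write_json(params, path_of("params.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  note("params.json")

  outputs <- unique(outputs)
  manifest <- tibble(
    file = outputs,
    md5 = unname(tools::md5sum(file.path(out_dir, outputs)))
  )
  readr::write_tsv(manifest, path_of("manifest.tsv"))
  invisible(list(manifest = manifest, results = results, out_dir = out_dir))
}
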