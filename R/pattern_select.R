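# Pattern-based gene-group selection for the four-condition stress design.
#
# Two gene groups are defined relative to the conditions Control, Paraquat,
# Cdk12i and Cdk12i_Paraquat:
#
#   Group A ("low-high-low-low"): genes induced by paraquat in a
#   Cdk12-dependent way — up under paraquat alone, with the induction
#   ablated when Cdk12 is knocked down.
#
#   Group B ("low-low-low-high"): genes suppressed by Cdk12 under stress —
#   up only when paraquat exposure is combined with Cdk12 knockdown.
#
# Selection composes a minimum-read filter, profile clustering under
# one-minus-Pearson distance with pattern-template labelling of cluster
# centroids, and five explicit per-gene criteria (fold-change/q cut-offs
# plus, for group A, a geometric-mean dependence rule). A full per-gene,
# per-criterion audit is always produced.

#' Selection thresholds for the two gene groups
#'
#' Returns the default criteria. Group A: `log2fc(Paraquat/Control) > 1`
#' with `q < 0.05`, `log2fc(Cdk12i/Control) > -1`, and the geometric-mean
#' dependence rule `mean(Cdk12i) < sqrt(mean(Control) * mean(Paraquat))`.
#' Group B: `log2fc > 0` with `q < 0.05` for Cdk12i_Paraquat/Paraquat and
#' Cdk12i_Paraquat/Cdk12i, plus `q < 0.05` for Cdk12i/Control (any
#' direction). All inequalities are strict. `min_reads_per_sample` is the
#' raw-count floor every sample must reach for a gene to be considered.
#'
#' @param lfc_pq_ctrl_min,q_pq_ctrl_max,lfc_cdk_ctrl_min,geometric_mean_rule
#'   Group-A thresholds (log2 units / q-values / logical).
#' @param lfc_cpq_pq_min,q_cpq_pq_max,q_cdk_ctrl_max,lfc_cpq_cdk_min,q_cpq_cdk_max
#'   Group-B thresholds.
#' @param min_reads_per_sample Minimum raw count per sample (default 1).
#' @return A list of class `"selection_criteria"`.
#' @export
selection_criteria <- function(lfc_pq_ctrl_min = 1,
                               q_pq_ctrl_max = 0.05,
                               lfc_cdk_ctrl_min = -1,
                               geometric_mean_rule = TRUE,
                               lfc_cpq_pq_min = 0,
                               q_cpq_pq_max = 0.05,
                               q_cdk_ctrl_max = 0.05,
                               lfc_cpq_cdk_min = 0,
                               q_cpq_cdk_max = 0.05,
                               min_reads_per_sample = 1) {
  qs <- c(q_pq_ctrl_max, q_cpq_pq_max, q_cdk_ctrl_max, q_cpq_cdk_max)
  if (any(qs <= 0 | qs > 1)) {
    abort("q-value thresholds must lie in (0, 1].")
  }
  crit <- list(
    lfc_pq_ctrl_min = lfc_pq_ctrl_min,
    q_pq_ctrl_max = q_pq_ctrl_max,
    lfc_cdk_ctrl_min = lfc_cdk_ctrl_min,
    geometric_mean_rule = isTRUE(geometric_mean_rule),
    lfc_cpq_pq_min = lfc_cpq_pq_min,
    q_cpq_pq_max = q_cpq_pq_max,
    q_cdk_ctrl_max = q_cdk_ctrl_max,
    lfc_cpq_cdk_min = lfc_cpq_cdk_min,
    q_cpq_cdk_max = q_cpq_cdk_max,
    min_reads_per_sample = min_reads_per_sample
  )
  if (any(!is.finite(unlist(crit[setdiff(names(crit), "geometric_mean_rule")])))) {
    abort("All thresholds must be finite.")
  }
  structure(crit, class = "selection_criteria")
}

#' Minimum-read gene filter
#'
#' Retains genes whose raw count reaches `min_reads` in every sample
#' (default 1: at least one read in every sample), removing genes too
#' sparsely observed to cluster or test.
#'
#' @param counts Raw count table (`gene_id` + sample columns).
#' @param min_reads Per-sample count floor (default 1).
#' @return The filtered count tibble.
#' @export
filter_min_reads <- function(counts, min_reads = 1) {
  if (min_reads < 0) abort("`min_reads` must be >= 0.")
  m <- as_count_matrix(counts)
  keep <- apply(m, 1, min) >= min_reads
  as_tibble(counts[keep, , drop = FALSE])
}

#' Standardize per-gene condition profiles
#'
#' Centres and scales each gene's 4-condition mean-expression profile to
#' mean 0, sd 1, the shape representation used for correlation-distance
#' clustering. Genes with zero profile variance carry no shape information
#' (Pearson correlation is undefined for them); they are flagged `flat`
#' and excluded from clustering downstream.
#'
#' @param summary A long tibble from [condition_means()] covering all four
#'   conditions.
#' @return A tibble `gene_id`, one standardized column per condition (in
#'   canonical order), and a logical `flat` column.
#' @export
profile_standardize <- function(summary) {
  check_columns(summary, c("gene_id", "condition", "mean_expr"), "summary")
  wide <- summary %>%
    tidyr::pivot_wider(
      id_cols = "gene_id", names_from = "condition", values_from = "mean_expr"
    )
  missing <- setdiff(CONDITION_LEVELS, names(wide))
  if (length(missing)) {
    abort(sprintf(
      "Summary lacks condition(s): %s.", paste(missing, collapse = ", ")
    ))
  }
  m <- as.matrix(as.data.frame(wide[, CONDITION_LEVELS]))
  ctr <- rowMeans(m)
  scl <- apply(m, 1, sd)
  flat <- scl == 0
  std <- (m - ctr) / ifelse(flat, 1, scl)
  std[flat, ] <- 0
  out <- tibble(gene_id = wide$gene_id) %>%
    dplyr::bind_cols(as_tibble(as.data.frame(std))) %>%
    mutate(flat = unname(flat))
  out
}

#' Cluster standardized profiles under one-minus-Pearson distance
#'
#' Agglomerative hierarchical clustering with average linkage on the
#' distance `d(x, y) = 1 - Pearson(x, y)` (0 for identical shapes, 2 for
#' anti-correlated ones), cut into `k` clusters. Each cluster centroid
#' (mean of member standardized profiles) is labelled with a pattern
#' template by [label_cluster_pattern()]. Flat genes are excluded.
#'
#' @param std Output of [profile_standardize()].
#' @param k Number of clusters (default 8; must be >= 2 and no larger than
#'   the number of non-flat genes).
#' @return A tibble `gene_id`, `cluster_id` (dense integers from 1),
#'   `pattern`; cluster centroids (matrix) and their patterns are attached
#'   as attributes `centroids` and `cluster_patterns`.
#' @export
cluster_profiles <- function(std, k = 8) {
  check_columns(std, c("gene_id", CONDITION_LEVELS, "flat"), "std")
  if (k < 2) abort("`k` must be at least 2.")
  use <- std[!std$flat, , drop = FALSE]
  if (nrow(use) < k) {
    abort(sprintf(
      "Need at least k = %d non-flat genes for clustering; have %d.",
      k, nrow(use)
    ))
  }
  m <- as.matrix(as.data.frame(use[, CONDITION_LEVELS]))
  rownames(m) <- use$gene_id
  d <- as.dist(1 - cor(t(m)))
  hc <- hclust(d, method = "average")
  cl <- cutree(hc, k = k)

  centroids <- t(vapply(
    split(seq_len(nrow(m)), cl),
    function(idx) colMeans(m[idx, , drop = FALSE]),
    numeric(length(CONDITION_LEVELS))
  ))
  colnames(centroids) <- CONDITION_LEVELS
  patterns <- apply(centroids, 1, label_cluster_pattern)

  out <- tibble(
    gene_id = use$gene_id,
    cluster_id = as.integer(cl),
    pattern = unname(patterns[as.character(cl)])
  )
  attr(out, "centroids") <- centroids
  attr(out, "cluster_patterns") <- patterns
  attr(out, "k") <- k
  out
}

#' Label a cluster centroid with a low/high pattern template
#'
#' A condition is `high` when the centroid entry is above 0 — above the
#' gene-row mean on the standardized scale — and `low` otherwise (an entry
#' of exactly 0 is labelled `low`).
#'
#' @param centroid Numeric 4-vector over the canonical condition order.
#' @return A pattern string such as `"low-high-low-low"`.
#' @export
#' @examples
#' label_cluster_pattern(c(-0.5, 1.5, -0.5, -0.5))
label_cluster_pattern <- function(centroid) {
  if (length(centroid) != length(CONDITION_LEVELS)) {
    abort(sprintf("`centroid` must have length %d.", length(CONDITION_LEVELS)))
  }
  paste(ifelse(centroid > 0, "high", "low"), collapse = "-")
}

# locate a comparison in a list of de_comparison objects
find_comparison <- function(de, numerator, denominator) {
  for (d in de) {
    if (identical(attr(d, "numerator"), numerator) &&
        identical(attr(d, "denominator"), denominator)) {
      return(d)
    }
  }
  abort(sprintf("Missing differential comparison %s vs %s.", numerator, denominator))
}

de_lookup <- function(d, genes, col) {
  d[[col]][match(genes, d$gene_id)]
}

#' Apply the group-A selection criteria (paraquat-induced, Cdk12-dependent)
#'
#' For each candidate gene: paraquat induction
#' (`log2fc(Paraquat/Control) > lfc_pq_ctrl_min`, `q < q_pq_ctrl_max`), no
#' strong baseline loss under Cdk12 knockdown alone
#' (`log2fc(Cdk12i/Control) > lfc_cdk_ctrl_min`), and the geometric-mean
#' dependence rule `mean(Cdk12i) < sqrt(mean(Control) * mean(Paraquat))`,
#' which requires the knockdown expression to fall below the geometric
#' midpoint of the uninduced and induced levels. All inequalities strict.
#'
#' @param genes Character vector of candidate gene ids (typically members
#'   of low-high-low-low clusters).
#' @param de List of `"de_comparison"` objects containing Paraquat vs
#'   Control and Cdk12i vs Control.
#' @param summary Long condition-mean table from [condition_means()].
#' @param criteria A [selection_criteria()] list.
#' @return An audit tibble with the evaluated quantity and pass flag per
#'   criterion and a `selected` column; selected genes pass everything.
#' @export
apply_group_a_criteria <- function(genes, de, summary,
                                   criteria = selection_criteria()) {
  d_pq <- find_comparison(de, "Paraquat", "Control")
  d_cdk <- find_comparison(de, "Cdk12i", "Control")
  wide <- summary %>%
    tidyr::pivot_wider(
      id_cols = "gene_id", names_from = "condition", values_from = "mean_expr"
    )
  idx <- match(genes, wide$gene_id)
  mean_ctrl <- wide$Control[idx]
  mean_pq <- wide$Paraquat[idx]
  mean_cdk <- wide$Cdk12i[idx]
  geo_bound <- sqrt(mean_ctrl * mean_pq)

  audit <- tibble(
    gene_id = genes,
    lfc_pq_ctrl = de_lookup(d_pq, genes, "log2fc"),
    q_pq_ctrl = de_lookup(d_pq, genes, "q"),
    lfc_cdk_ctrl = de_lookup(d_cdk, genes, "log2fc"),
    mean_cdk = mean_cdk,
    geo_bound = geo_bound
  ) %>%
    mutate(
      pass_pq_induced = .data$lfc_pq_ctrl > criteria$lfc_pq_ctrl_min &
        .data$q_pq_ctrl < criteria$q_pq_ctrl_max,
      pass_cdk_baseline = .data$lfc_cdk_ctrl > criteria$lfc_cdk_ctrl_min,
      pass_geo_mean = if (criteria$geometric_mean_rule) {
        .data$mean_cdk < .data$geo_bound
      } else {
        TRUE
      },
      selected = .data$pass_pq_induced & .data$pass_cdk_baseline &
        .data$pass_geo_mean
    )
  audit$selected[is.na(audit$selected)] <- FALSE
  audit
}

#' Apply the group-B selection criteria (Cdk12-suppressed under paraquat)
#'
#' For each candidate gene: up in the combined arm relative to paraquat
#' alone (`log2fc(Cdk12i_Paraquat/Paraquat) > lfc_cpq_pq_min`, `q <
#' q_cpq_pq_max`), differential between Cdk12i and Control in either
#' direction (`q < q_cdk_ctrl_max`), and up in the combined arm relative
#' to knockdown alone (`log2fc(Cdk12i_Paraquat/Cdk12i) > lfc_cpq_cdk_min`,
#' `q < q_cpq_cdk_max`). All inequalities strict.
#'
#' @inheritParams apply_group_a_criteria
#' @param de List of `"de_comparison"` objects containing Cdk12i_Paraquat
#'   vs Paraquat, Cdk12i vs Control, and Cdk12i_Paraquat vs Cdk12i.
#' @return An audit tibble as in [apply_group_a_criteria()].
#' @export
apply_group_b_criteria <- function(genes, de,
                                   criteria = selection_criteria()) {
  d_cpq_pq <- find_comparison(de, "Cdk12i_Paraquat", "Paraquat")
  d_cdk <- find_comparison(de, "Cdk12i", "Control")
  d_cpq_cdk <- find_comparison(de, "Cdk12i_Paraquat", "Cdk12i")

  audit <- tibble(
    gene_id = genes,
    lfc_cpq_pq = de_lookup(d_cpq_pq, genes, "log2fc"),
    q_cpq_pq = de_lookup(d_cpq_pq, genes, "q"),
    q_cdk_ctrl = de_lookup(d_cdk, genes, "q"),
    lfc_cpq_cdk = de_lookup(d_cpq_cdk, genes, "log2fc"),
    q_cpq_cdk = de_lookup(d_cpq_cdk, genes, "q")
  ) %>%
    mutate(
      pass_cpq_pq = .data$lfc_cpq_pq > criteria$lfc_cpq_pq_min &
        .data$q_cpq_pq < criteria$q_cpq_pq_max,
      pass_cdk_ctrl = .data$q_cdk_ctrl < criteria$q_cdk_ctrl_max,
      pass_cpq_cdk = .data$lfc_cpq_cdk > criteria$lfc_cpq_cdk_min &
        .data$q_cpq_cdk < criteria$q_cpq_cdk_max,
      selected = .data$pass_cpq_pq & .data$pass_cdk_ctrl & .data$pass_cpq_cdk
    )
  audit$selected[is.na(audit$selected)] <- FALSE
  audit
}

#' Select the two stress-response gene groups from raw counts
#'
#' Runs the full selection pipeline: minimum-read filter, CPM
#' normalization, condition means, profile standardization, average-linkage
#' clustering under one-minus-Pearson distance, pooling of clusters whose
#' centroid matches the target template (group A: `low-high-low-low`;
#' group B: `low-low-low-high`), and the per-group criteria filters with a
#' complete audit.
#'
#' @param counts Raw count table (`gene_id` + sample columns).
#' @param design Sample design table mapping the 12 samples to the four
#'   conditions.
#' @param criteria A [selection_criteria()] list.
#' @param k Number of profile clusters (default 8).
#' @param pseudocount Pseudocount for the differential tests (default 0.5
#'   CPM).
#' @return An object of class `"selection_result"`: a list with `group_a`,
#'   `group_b` (character vectors, sorted), `audit` (per gene: min-read
#'   and cluster-pattern criteria plus both groups' criterion columns),
#'   `clusters`, `summary`, `de` (the four comparisons), and `params`.
#' @export
select_groups <- function(counts, design, criteria = selection_criteria(),
                          k = 8, pseudocount = 0.5) {
  if (!inherits(criteria, "selection_criteria")) {
    criteria <- do.call(selection_criteria, criteria)
  }
  design <- validate_design(design)
  missing_cond <- setdiff(CONDITION_LEVELS, unique(design$condition))
  if (length(missing_cond)) {
    abort(sprintf(
      "Design lacks condition(s): %s.", paste(missing_cond, collapse = ", ")
    ))
  }

  kept <- filter_min_reads(counts, criteria$min_reads_per_sample)
  all_genes <- counts$gene_id
  pass_min_reads <- all_genes %in% kept$gene_id

  if (nrow(kept) == 0) {
    abort("No genes survive the minimum-read filter.")
  }

  norm <- cpm_normalize(kept)
  summary <- condition_means(norm, design)
  std <- profile_standardize(summary)
  if (sum(!std$flat) < k) {
    # a degenerate (e.g. variation-free) matrix: nothing can be clustered,
    # so no gene can match a pattern template and both groups are empty
    clusters <- tibble(
      gene_id = character(), cluster_id = integer(), pattern = character()
    )
    attr(clusters, "k") <- k
  } else {
    clusters <- cluster_profiles(std, k = k)
  }

  de <- list(
    differential_test(norm, design, "Paraquat", "Control", pseudocount),
    differential_test(norm, design, "Cdk12i", "Control", pseudocount),
    differential_test(norm, design, "Cdk12i_Paraquat", "Paraquat", pseudocount),
    differential_test(norm, design, "Cdk12i_Paraquat", "Cdk12i", pseudocount)
  )

  pat <- clusters$pattern[match(all_genes, clusters$gene_id)]
  in_a_cluster <- !is.na(pat) & pat == "low-high-low-low"
  in_b_cluster <- !is.na(pat) & pat == "low-low-low-high"

  audit_a <- apply_group_a_criteria(all_genes, de, summary, criteria)
  audit_b <- apply_group_b_criteria(all_genes, de, criteria)

  audit <- tibble(
    gene_id = all_genes,
    pass_min_reads = pass_min_reads,
    cluster_id = clusters$cluster_id[match(all_genes, clusters$gene_id)],
    pattern = pat,
    pass_pattern_a = in_a_cluster,
    pass_pattern_b = in_b_cluster
  ) %>%
    left_join(audit_a, by = "gene_id", suffix = c("", ".a")) %>%
    rename(selected_a_criteria = "selected") %>%
    left_join(audit_b, by = "gene_id", suffix = c("", ".b")) %>%
    rename(selected_b_criteria = "selected") %>%
    mutate(
      group_a = .data$pass_min_reads & .data$pass_pattern_a &
        .data$selected_a_criteria,
      group_b = .data$pass_min_reads & .data$pass_pattern_b &
        .data$selected_b_criteria
    )

  res <- list(
    group_a = sort(audit$gene_id[audit$group_a]),
    group_b = sort(audit$gene_id[audit$group_b]),
    audit = audit,
    clusters = clusters,
    summary = summary,
    std_profiles = std,
    de = de,
    params = list(criteria = criteria, k = k, pseudocount = pseudocount)
  )
  class(res) <- "selection_result"
  res
}

#' @export
print.selection_result <- function(x, ...) {
  cat("Stress-transcriptome gene-group selection\n")
  cat(sprintf(
    "  %d genes in, %d pass min-read filter, %d clustered (k = %d)\n",
    nrow(x$audit), sum(x$audit$pass_min_reads),
    nrow(x$clusters), x$params$k
  ))
  cat(sprintf(
    "  Group A (low-high-low-low, paraquat-induced Cdk12-dependent): %d genes\n",
    length(x$group_a)
  ))
  cat(sprintf(
    "  Group B (low-low-low-high, Cdk12-suppressed under paraquat): %d genes\n",
    length(x$group_b)
  ))
  invisible(x)
}

#' Tidy and summarise a selection result
#'
#' `tidy()` returns the per-gene audit table (one row per gene, every
#' criterion's evaluated quantity and pass flag, plus the final `group_a` /
#' `group_b` flags). `glance()` returns a one-row summary.
#'
#' @param x A `"selection_result"` from [select_groups()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.selection_result <- function(x, ...) {
  x$audit
}

#' @rdname tidy.selection_result
#' @export
glance.selection_result <- function(x, ...) {
  tibble(
    n_genes = nrow(x$audit),
    n_min_reads = sum(x$audit$pass_min_reads),
    n_clustered = nrow(x$clusters),
    k = x$params$k,
    n_group_a = length(x$group_a),
    n_group_b = length(x$group_b)
  )
}

#' @rdname tidy.selection_result
#' @param object A `"selection_result"`.
#' @param genes Which genes to draw: `"selected"` (default, both groups)
#'   or `"all"` clustered genes.
#' @export
autoplot.selection_result <- function(object, genes = c("selected", "all"),
                                      ...) {
  genes <- match.arg(genes)
  std <- object$std_profiles
  if (genes == "selected") {
    keep <- std$gene_id %in% c(object$group_a, object$group_b)
    std <- std[keep, , drop = FALSE]
  }
  df <- std %>%
    select(-"flat") %>%
    tidyr::pivot_longer(
      -"gene_id", names_to = "condition", values_to = "z"
    ) %>%
    mutate(
      condition = factor(.data$condition, levels = CONDITION_LEVELS),
      group = case_when(
        .data$gene_id %in% object$group_a ~ "Group A",
        .data$gene_id %in% object$group_b ~ "Group B",
        TRUE ~ "other"
      )
    )
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$condition, y = .data$gene_id, fill = .data$z
  )) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(
      low = "#2166AC", mid = "white", high = "#B2182B", midpoint = 0
    ) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$group),
                        scales = "free_y", space = "free_y") +
    ggplot2::labs(
      x = NULL, y = NULL, fill = "standardized\nexpression",
      title = "Condition profiles of selected genes"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(
      axis.text.y = ggplot2::element_blank(),
      axis.ticks.y = ggplot2::element_blank()
    )
}
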