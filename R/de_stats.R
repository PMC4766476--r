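# Condition-pair differential statistics for the four-arm stress design.
#
# Counts are normalized to counts per million (CPM), condition means are
# simple arithmetic means over replicates, and each ordered condition pair
# is tested gene-wise with Welch's unequal-variance t on log2(CPM + pc),
# followed by Benjamini-Hochberg correction across the genes of the
# comparison.

#' Counts-per-million normalization
#'
#' Scales each sample column so it sums to one million:
#' `cpm(g, s) = counts(g, s) * 1e6 / libsize(s)`.
#'
#' @param counts A data frame with a `gene_id` column and one non-negative
#'   integer column per sample.
#' @return A tibble of the same shape with CPM values.
#' @section Errors: a sample with zero library size raises an error naming
#'   the sample; duplicated gene or sample ids are rejected.
#' @export
#' @examples
#' counts <- tibble::tibble(gene_id = c("g1", "g2"), s1 = c(1L, 9L))
#' cpm_normalize(counts)
cpm_normalize <- function(counts) {
  m <- as_count_matrix(counts)
  libsize <- colSums(m)
  if (any(libsize == 0)) {
    abort(sprintf(
      "Sample(s) with zero library size: %s.",
      paste(colnames(m)[libsize == 0], collapse = ", ")
    ))
  }
  cpm <- sweep(m, 2, libsize, "/") * 1e6
  matrix_to_tbl(cpm)
}

# counts tibble (gene_id + sample columns) -> named matrix, with validation
as_count_matrix <- function(counts, what = "counts") {
  check_columns(counts, "gene_id", what)
  sample_cols <- setdiff(names(counts), "gene_id")
  if (length(sample_cols) == 0) {
    abort(sprintf("`%s` has no sample columns.", what))
  }
  if (anyDuplicated(counts$gene_id)) {
    abort(sprintf("`%s` has duplicated gene_id values.", what))
  }
  if (anyDuplicated(sample_cols)) {
    abort(sprintf("`%s` has duplicated sample columns.", what))
  }
  m <- as.matrix(as.data.frame(counts[, sample_cols]))
  if (!is.numeric(m)) abort(sprintf("`%s` sample columns must be numeric.", what))
  if (any(m < 0) || anyNA(m)) {
    abort(sprintf("`%s` must be non-negative with no missing values.", what))
  }
  rownames(m) <- counts$gene_id
  m
}

matrix_to_tbl <- function(m) {
  out <- as_tibble(as.data.frame(m))
  tibble(gene_id = rownames(m)) %>% dplyr::bind_cols(out)
}

validate_design <- function(design, sample_ids = NULL) {
  check_columns(design, c("sample_id", "condition"), "design")
  design <- as_tibble(design)
  if (anyDuplicated(design$sample_id)) {
    abort("`design` has duplicated sample_id values.")
  }
  unknown <- setdiff(design$condition, CONDITION_LEVELS)
  if (length(unknown)) {
    abort(sprintf(
      "Unknown condition label(s): %s. Expected %s.",
      paste(unknown, collapse = ", "), paste(CONDITION_LEVELS, collapse = ", ")
    ))
  }
  if (!is.null(sample_ids)) {
    missing <- setdiff(sample_ids, design$sample_id)
    if (length(missing)) {
      abort(sprintf(
        "Design does not cover sample column(s): %s.",
        paste(missing, collapse = ", ")
      ))
    }
  }
  design
}

#' Per-condition mean expression
#'
#' Arithmetic mean of normalized expression over each condition's
#' replicates, the quantity entering the geometric-mean dependence rule of
#' the group-A selection criteria.
#'
#' @param norm A normalized expression table (`gene_id` + sample columns),
#'   e.g. from [cpm_normalize()].
#' @param design A data frame with columns `sample_id`, `condition` (and
#'   optionally `replicate`) mapping samples to the four conditions.
#' @return A long tibble `gene_id`, `condition`, `mean_expr` with one row
#'   per gene and condition present in the design.
#' @export
condition_means <- function(norm, design) {
  m <- as_count_matrix(norm, "norm")
  design <- validate_design(design, colnames(m))
  conds <- unique(design$condition)
  design <- design[design$sample_id %in% colnames(m), , drop = FALSE]
  empty <- setdiff(conds, unique(design$condition))
  if (length(empty)) {
    abort(sprintf(
      "Condition(s) with zero samples in the matrix: %s.",
      paste(empty, collapse = ", ")
    ))
  }
  means <- purrr::map(conds, function(cond) {
    cols <- design$sample_id[design$condition == cond]
    rowMeans(m[, cols, drop = FALSE])
  })
  tibble(
    gene_id = rep(rownames(m), times = length(conds)),
    condition = rep(conds, each = nrow(m)),
    mean_expr = unlist(means, use.names = FALSE)
  )
}

#' Welch-t differential expression for one ordered condition pair
#'
#' For each gene, computes `log2fc = log2((mean_num + pc) / (mean_den +
#' pc))` from the per-condition means of the normalized values, a p-value
#' from Welch's unequal-variance t-test on `log2(x + pc)` with
#' Welch-Satterthwaite degrees of freedom, and Benjamini-Hochberg q-values
#' across all genes of the comparison. The pseudocount `pc` keeps fold
#' changes finite for genes with zero counts on one side.
#'
#' Degenerate genes are handled explicitly: if both groups have zero
#' variance and equal means the p-value is 1 by convention; if both
#' variances are zero but the means differ, a variance floor of 1e-12 is
#' applied, yielding a p-value near 0.
#'
#' @param norm A normalized expression table (`gene_id` + sample columns).
#' @param design Sample design table (see [condition_means()]).
#' @param numerator,denominator Condition labels of the ordered pair; the
#'   fold change is numerator over denominator.
#' @param pseudocount Pseudocount added on the normalized scale (default
#'   0.5 CPM).
#' @return A tibble of class `"de_comparison"` with columns `gene_id`,
#'   `log2fc`, `p`, `q`, carrying the pair as attributes `numerator` and
#'   `denominator`.
#' @section Errors: either side with fewer than 2 replicates is an error.
#' @export
#' @examples
#' norm <- tibble::tibble(
#'   gene_id = "g1",
#'   a1 = 4, a2 = 4, a3 = 4, b1 = 8, b2 = 8, b3 = 8
#' )
#' design <- tibble::tibble(
#'   sample_id = c("a1", "a2", "a3", "b1", "b2", "b3"),
#'   condition = rep(c("Control", "Paraquat"), each = 3)
#' )
#' differential_test(norm, design, "Paraquat", "Control", pseudocount = 0)
differential_test <- function(norm, design, numerator, denominator,
                              pseudocount = 0.5) {
  m <- as_count_matrix(norm, "norm")
  design <- validate_design(design)
  if (!is.numeric(pseudocount) || pseudocount < 0) {
    abort("`pseudocount` must be a non-negative number.")
  }
  cols_num <- intersect(design$sample_id[design$condition == numerator], colnames(m))
  cols_den <- intersect(design$sample_id[design$condition == denominator], colnames(m))
  if (length(cols_num) < 2 || length(cols_den) < 2) {
    abort(sprintf(
      "Both conditions need >= 2 replicates (found %d for %s, %d for %s).",
      length(cols_num), numerator, length(cols_den), denominator
    ))
  }

  x <- m[, cols_num, drop = FALSE]
  y <- m[, cols_den, drop = FALSE]
  log2fc <- log2((rowMeans(x) + pseudocount) / (rowMeans(y) + pseudocount))

  wt <- welch_rows(log2(x + pseudocount), log2(y + pseudocount))

  out <- tibble(
    gene_id = rownames(m),
    log2fc = unname(log2fc),
    p = wt$p,
    q = bh_adjust(wt$p)
  )
  attr(out, "numerator") <- numerator
  attr(out, "denominator") <- denominator
  attr(out, "pseudocount") <- pseudocount
  class(out) <- c("de_comparison", class(out))
  out
}

# Vectorized Welch t over matrix rows with explicit degenerate conventions.
welch_rows <- function(x, y, var_floor = 1e-12) {
  n1 <- ncol(x)
  n2 <- ncol(y)
  m1 <- rowMeans(x)
  m2 <- rowMeans(y)
  v1 <- rowSums((x - m1)^2) / (n1 - 1)
  v2 <- rowSums((y - m2)^2) / (n2 - 1)

  degenerate <- v1 == 0 & v2 == 0
  equal_deg <- degenerate & m1 == m2
  diff_deg <- degenerate & m1 != m2
  v1[diff_deg] <- var_floor
  v2[diff_deg] <- var_floor

  se2 <- v1 / n1 + v2 / n2
  tstat <- ifelse(se2 > 0, (m1 - m2) / sqrt(se2), 0)
  df <- ifelse(
    se2 > 0,
    se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1)),
    n1 + n2 - 2
  )
  p <- 2 * pt(-abs(tstat), df)
  p[equal_deg] <- 1
  list(t = unname(tstat), df = unname(df), p = unname(p))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Returns q-values in input order: `q_(i) = min_{j >= i} (p_(j) * m / j)`,
#' clipped at 1. Delegates to [stats::p.adjust()].
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of adjusted values, same length and order.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
bh_adjust <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1)) {
    abort("`p` must be numeric in [0, 1] with no missing values.")
  }
  p.adjust(p, method = "BH")
}

#' @export
print.de_comparison <- function(x, ...) {
  cat(sprintf(
    "Differential comparison: %s vs %s (pseudocount %g)\n",
    attr(x, "numerator"), attr(x, "denominator"),
    attr(x, "pseudocount") %||% NA_real_
  ))
  print(as_tibble(unclass_de(x)), ...)
  invisible(x)
}

unclass_de <- function(x) {
  class(x) <- setdiff(class(x), "de_comparison")
  x
}

#' @describeIn differential_test `tidy()` returns the per-gene table with
#'   the condition pair as columns.
#' @param x A `"de_comparison"` object.
#' @param ... Unused.
#' @export
tidy.de_comparison <- function(x, ...) {
  as_tibble(unclass_de(x)) %>%
    mutate(
      numerator = attr(x, "numerator"),
      denominator = attr(x, "denominator")
    )
}

#' @describeIn differential_test `glance()` summarises the comparison in
#'   one row.
#' @export
glance.de_comparison <- function(x, ...) {
  tibble(
    numerator = attr(x, "numerator"),
    denominator = attr(x, "denominator"),
    n_genes = nrow(x),
    n_sig_q05 = sum(x$q < 0.05),
    pseudocount = attr(x, "pseudocount") %||% NA_real_
  )
}

#' @describeIn differential_test `autoplot()` draws a volcano plot
#'   (log2 fold change vs -log10 p, significant genes highlighted).
#' @param object A `"de_comparison"` object.
#' @param q_cutoff Significance cut-off for highlighting (default 0.05).
#' @export
autoplot.de_comparison <- function(object, q_cutoff = 0.05, ...) {
  df <- as_tibble(unclass_de(object))
  df$significant <- df$q < q_cutoff
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$log2fc, y = -log10(pmax(.data$p, 1e-300)),
    colour = .data$significant
  )) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::scale_colour_manual(
      values = c(`TRUE` = "#B2182B", `FALSE` = "grey60"),
      labels = c(`TRUE` = sprintf("q < %g", q_cutoff), `FALSE` = "ns")
    ) +
    ggplot2::labs(
      x = sprintf(
        "log2 fold change (%s / %s)",
        attr(object, "numerator"), attr(object, "denominator")
      ),
      y = "-log10 p", colour = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Relative expression and fold induction from qPCR cycle thresholds
#'
#' `qpcr_relative_expression()` converts a target/reference Ct pair to a
#' relative expression level assuming perfect doubling per cycle:
#' `2^-(ct_target - ct_reference)` (the delta-Ct method, e.g. normalizing a
#' transcript to the Act5C internal control). `fold_induction()` is the
#' ratio of two relative expression levels (treated over control).
#'
#' @param ct_target,ct_reference Finite Ct values (cycles).
#' @return A numeric relative expression level (dimensionless).
#' @export
#' @examples
#' qpcr_relative_expression(22, 22) # 1
#' qpcr_relative_expression(23, 22) # 0.5
#' fold_induction(4.1, 1.0)
qpcr_relative_expression <- function(ct_target, ct_reference) {
  if (any(!is.finite(ct_target)) || any(!is.finite(ct_reference))) {
    abort("Ct values must be finite.")
  }
  2^(-(ct_target - ct_reference))
}

#' @rdname qpcr_relative_expression
#' @param re_treated,re_control Relative expression in the treated and
#'   control states; `re_control` must be positive.
#' @export
fold_induction <- function(re_treated, re_control) {
  if (any(!is.finite(re_treated)) || any(!is.finite(re_control))) {
    abort("Relative expression values must be finite.")
  }
  if (any(re_control <= 0)) {
    abort("`re_control` must be positive.")
  }
  re_treated / re_control
}
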