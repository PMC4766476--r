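# Term enrichment of a selected gene set against a background universe,
# using the hypergeometric upper tail with multiple-testing correction.
# The output mirrors the classic term-finder summary: per-term cluster
# frequency, genome (background) frequency, and a corrected p-value.

#' Hypergeometric upper-tail probability
#'
#' Probability of observing at least `k` annotated genes when drawing `n`
#' genes without replacement from a background of `N` genes of which `K`
#' carry the annotation:
#' `p = sum_{i = k}^{min(K, n)} C(K, i) C(N - K, n - i) / C(N, n)`.
#' Evaluated through [stats::phyper()], which works in log space and is
#' numerically stable for small tails. Vectorized over `k`.
#'
#' @param k Observed annotated genes in the draw (`0 <= k <= min(K, n)`).
#' @param K Annotated genes in the background.
#' @param n Size of the drawn gene set.
#' @param N Background size (`K <= N`, `n <= N`).
#' @return The upper-tail probability in `[0, 1]`.
#' @export
#' @examples
#' hypergeom_upper_tail(3, 4, 5, 10) # 66/252
#' hypergeom_upper_tail(0, 4, 5, 10) # exactly 1
hypergeom_upper_tail <- function(k, K, n, N) {
  if (length(K) != 1 || length(n) != 1 || length(N) != 1) {
    abort("`K`, `n` and `N` must be single integers.")
  }
  ints <- c(k, K, n, N)
  if (anyNA(ints) || any(ints != floor(ints)) || any(ints < 0)) {
    abort("All arguments must be non-negative integers.")
  }
  if (K > N || n > N) abort("Need K <= N and n <= N.")
  if (any(k > pmin(K, n))) abort("Need k <= min(K, n).")
  phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
}

#' Term enrichment of a gene set against a background
#'
#' Tests every annotation term represented in the gene set for
#' over-representation with the hypergeometric upper tail. Annotations are
#' intersected with the background universe before counting; a term is
#' tested only if it annotates at least one background gene and at least
#' one gene of the query set (`k >= 1`), and the multiple-testing burden
#' `m` counts exactly the tested terms.
#'
#' @param gene_set Character vector of query genes (must be a subset of
#'   `background`).
#' @param background Character vector: the gene universe.
#' @param annotation A data frame with columns `term_id`, `term_name`,
#'   `gene_id` (one association per row).
#' @param correction `"bonferroni"` (default, family-wise: `p * m` clipped
#'   at 1) or `"bh"` (false-discovery rate across tested terms).
#' @return A tibble of class `"enrichment_tbl"`, one row per tested term,
#'   sorted by corrected then raw p-value: `term_id`, `term_name`, `k`
#'   (hits), `K` (term size in background), `n` (set size), `N`
#'   (background size), `cluster_frequency` and `genome_frequency`
#'   (percentages `100 k / n` and `100 K / N`), `p_raw`, `p_corrected`.
#' @export
#' @examples
#' ann <- tibble::tibble(
#'   term_id = "T1", term_name = "toy term", gene_id = c("g1", "g2")
#' )
#' enrich(c("g1", "g2"), paste0("g", 1:10), ann)
enrich <- function(gene_set, background, annotation,
                   correction = c("bonferroni", "bh")) {
  correction <- match.arg(correction)
  check_columns(annotation, c("term_id", "term_name", "gene_id"), "annotation")
  gene_set <- unique(as.character(gene_set))
  background <- unique(as.character(background))
  if (length(gene_set) == 0) abort("`gene_set` must be non-empty.")
  if (length(background) == 0) abort("`background` must be non-empty.")
  outside <- setdiff(gene_set, background)
  if (length(outside)) {
    abort(sprintf(
      "`gene_set` contains gene(s) outside the background: %s%s.",
      paste(utils::head(outside, 5), collapse = ", "),
      if (length(outside) > 5) ", ..." else ""
    ))
  }

  ann <- as_tibble(annotation) %>%
    filter(.data$gene_id %in% background) %>%
    distinct(.data$term_id, .data$term_name, .data$gene_id)

  n_set <- length(gene_set)
  n_bg <- length(background)

  rows <- ann %>%
    group_by(.data$term_id, .data$term_name) %>%
    summarise(
      K = dplyr::n(),
      k = sum(.data$gene_id %in% gene_set),
      .groups = "drop"
    ) %>%
    filter(.data$k >= 1)

  if (nrow(rows) == 0) {
    out <- tibble(
      term_id = character(), term_name = character(),
      k = integer(), K = integer(), n = integer(), N = integer(),
      cluster_frequency = double(), genome_frequency = double(),
      p_raw = double(), p_corrected = double()
    )
    class(out) <- c("enrichment_tbl", class(out))
    return(out)
  }

  m <- nrow(rows)
  out <- rows %>%
    mutate(
      n = n_set, N = n_bg,
      cluster_frequency = 100 * .data$k / n_set,
      genome_frequency = 100 * .data$K / n_bg,
      p_raw = purrr::map2_dbl(
        .data$k, .data$K, ~ hypergeom_upper_tail(.x, .y, n_set, n_bg)
      ),
      p_corrected = if (correction == "bonferroni") {
        pmin(1, .data$p_raw * m)
      } else {
        bh_adjust(.data$p_raw)
      }
    ) %>%
    arrange(.data$p_corrected, .data$p_raw, .data$term_id) %>%
    select(
      "term_id", "term_name", "k", "K", "n", "N",
      "cluster_frequency", "genome_frequency", "p_raw", "p_corrected"
    )
  attr(out, "correction") <- correction
  attr(out, "m_tested") <- m
  class(out) <- c("enrichment_tbl", class(out))
  out
}

#' @export
print.enrichment_tbl <- function(x, ...) {
  cat(sprintf(
    "Term enrichment: %d term(s) tested, correction = %s\n",
    attr(x, "m_tested") %||% nrow(x), attr(x, "correction") %||% "?"
  ))
  y <- x
  class(y) <- setdiff(class(y), "enrichment_tbl")
  print(as_tibble(y), ...)
  invisible(x)
}

#' @describeIn enrich `tidy()` returns the enrichment rows as a plain
#'   tibble.
#' @param x An `"enrichment_tbl"`.
#' @param ... Unused.
#' @export
tidy.enrichment_tbl <- function(x, ...) {
  class(x) <- setdiff(class(x), "enrichment_tbl")
  as_tibble(x)
}

#' @describeIn enrich `glance()` gives a one-row summary (terms tested,
#'   significant terms, correction used).
#' @export
glance.enrichment_tbl <- function(x, ...) {
  tibble(
    m_tested = attr(x, "m_tested") %||% nrow(x),
    n_sig_05 = sum(x$p_corrected < 0.05),
    correction = attr(x, "correction") %||% NA_character_,
    n_set = if (nrow(x)) x$n[1] else NA_integer_,
    n_background = if (nrow(x)) x$N[1] else NA_integer_
  )
}

#' @describeIn enrich `autoplot()` draws cluster vs background frequency
#'   per term, sized by significance.
#' @param object An `"enrichment_tbl"`.
#' @param max_terms Show at most this many top terms (default 20).
#' @export
autoplot.enrichment_tbl <- function(object, max_terms = 20, ...) {
  df <- tidy(object) %>% utils::head(max_terms)
  df$term_name <- factor(df$term_name, levels = rev(df$term_name))
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$cluster_frequency, y = .data$term_name,
    size = -log10(pmax(.data$p_corrected, 1e-300))
  )) +
    ggplot2::geom_point(colour = "#2166AC", alpha = 0.8) +
    ggplot2::geom_point(
      ggplot2::aes(x = .data$genome_frequency),
      colour = "grey50", shape = 1
    ) +
    ggplot2::labs(
      x = "frequency (%): filled = gene set, open = background",
      y = NULL, size = "-log10 corrected p"
    ) +
    ggplot2::theme_minimal()
}
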