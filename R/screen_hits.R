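# Hit calling for dual-luciferase RNAi screens.
#
# The assay couples a pathway-responsive firefly luciferase (Fluc) reporter
# to a constitutive renilla luciferase (Rluc) transfection control in each
# well of a 384-well plate. Knockdown effects are read out as the Fluc/Rluc
# ratio, expressed as a robust Z-score against the plate's typical well,
# and genes are called inducers or suppressors when enough of their
# independent dsRNAs agree.

#' Normalize dual-reporter wells to the internal control
#'
#' Divides the pathway reporter signal (firefly luciferase) by the internal
#' control signal (renilla luciferase) well by well. The ratio cancels
#' well-to-well variation in cell number and transfection efficiency.
#'
#' Wells with a non-positive renilla readout indicate dead or untransfected
#' wells; they are dropped from the output and recorded as well failures
#' (retrievable with [well_failures()]) rather than failing the whole
#' plate.
#'
#' @param wells A data frame with columns `plate_id`, `well_id`, `gene_id`,
#'   `dsrna_id`, `fluc`, `rluc`, and optionally `control_role` (one of
#'   `"none"`, `"pathway-positive"`, `"pathway-negative"`; absent column
#'   means all `"none"`).
#' @return A tibble with the retained rows plus a `ratio` column
#'   (`fluc / rluc`). The dropped rows are attached as the
#'   `"well_failures"` attribute.
#' @seealso [compute_zscores()], [well_failures()]
#' @export
#' @examples
#' wells <- tibble::tibble(
#'   plate_id = "P1", well_id = c("A01", "A02", "A03"),
#'   gene_id = c("g1", "g2", "g3"), dsrna_id = c("d1", "d2", "d3"),
#'   fluc = c(1000, 400, 250), rluc = c(500, 200, 0)
#' )
#' norm <- normalize_wells(wells)
#' norm$ratio
#' well_failures(norm)
normalize_wells <- function(wells) {
  check_columns(
    wells,
    c("plate_id", "well_id", "gene_id", "dsrna_id", "fluc", "rluc"),
    "wells"
  )
  wells <- as_tibble(wells)
  if (!"control_role" %in% names(wells)) {
    wells$control_role <- "none"
  }
  if (any(!is.finite(wells$fluc)) || any(wells$fluc < 0, na.rm = TRUE)) {
    abort("`fluc` must be finite and non-negative.")
  }
  bad <- !is.finite(wells$rluc) | wells$rluc <= 0
  failures <- wells[bad, , drop = FALSE]
  out <- wells[!bad, , drop = FALSE]
  out$ratio <- out$fluc / out$rluc
  if (nrow(failures) > 0) {
    inform(sprintf(
      "Dropped %d well(s) with rluc <= 0 (dead/untransfected); see well_failures().",
      nrow(failures)
    ))
  }
  attr(out, "well_failures") <- failures
  out
}

#' Retrieve wells dropped during normalization
#'
#' @param norm A table returned by [normalize_wells()].
#' @return A tibble of the input rows that were rejected (renilla readout
#'   not positive); zero rows if none failed.
#' @export
well_failures <- function(norm) {
  wf <- attr(norm, "well_failures", exact = TRUE)
  if (is.null(wf)) {
    wf <- tibble(
      plate_id = character(), well_id = character(),
      gene_id = character(), dsrna_id = character(),
      fluc = double(), rluc = double(), control_role = character()
    )
  }
  as_tibble(wf)
}

#' Robust per-well Z-scores of normalized reporter activity
#'
#' Expresses each well's Fluc/Rluc ratio in robust standard deviations from
#' the typical well of its scoping unit:
#' `z = (ratio - median) / (1.4826 * MAD)`, with the median and the median
#' absolute deviation estimated from the non-control wells of the unit.
#' Control wells (any `control_role != "none"`) are excluded from the
#' location/scale estimate but still scored, so assay-validation controls
#' remain reportable.
#'
#' @param norm A table from [normalize_wells()] (must contain `ratio`).
#' @param z_scope Scoping unit for the median/MAD estimate: `"plate"`
#'   (default, standard high-throughput-screening practice, robust to
#'   plate-to-plate drift) or `"screen"` (single pooled estimate, useful
#'   for single-plate toy data).
#' @return A tibble with columns `plate_id`, `well_id`, `gene_id`,
#'   `dsrna_id`, `control_role`, `ratio`, `z`.
#' @section Errors: A scoping unit whose non-control wells have zero MAD
#'   (a constant plate) raises a degenerate-scale error naming the unit;
#'   fewer than 3 non-control wells in a unit is also an error.
#' @export
#' @examples
#' wells <- tibble::tibble(
#'   plate_id = "P1", well_id = sprintf("A%02d", 1:5),
#'   gene_id = paste0("g", 1:5), dsrna_id = paste0("d", 1:5),
#'   fluc = c(1, 2, 3, 4, 100), rluc = 1
#' )
#' compute_zscores(normalize_wells(wells), z_scope = "screen")
compute_zscores <- function(norm, z_scope = c("plate", "screen")) {
  z_scope <- match.arg(z_scope)
  check_columns(norm, c("plate_id", "gene_id", "dsrna_id", "ratio"), "norm")
  norm <- as_tibble(norm)
  if (!"control_role" %in% names(norm)) norm$control_role <- "none"
  norm$.unit <- if (z_scope == "plate") norm$plate_id else "screen"

  scored <- norm %>%
    group_by(.data$.unit) %>%
    group_modify_z() %>%
    ungroup() %>%
    select(-".unit")
  scored
}

# per-unit robust scaling; split out for clarity
group_modify_z <- function(grouped) {
  dplyr::group_modify(grouped, function(df, key) {
    ref <- df$ratio[df$control_role == "none"]
    if (length(ref) < 3) {
      abort(sprintf(
        "Scoping unit '%s' has %d non-control wells; need at least 3.",
        key$.unit, length(ref)
      ))
    }
    ctr <- median(ref)
    scale <- mad(ref, center = ctr) # constant 1.4826 by default
    if (scale == 0) {
      abort(sprintf(
        "Degenerate scale in scoping unit '%s': MAD of non-control ratios is 0.",
        key$.unit
      ))
    }
    df$z <- (df$ratio - ctr) / scale
    keep <- intersect(
      c("plate_id", "well_id", "gene_id", "dsrna_id",
        "control_role", "ratio", "z"),
      names(df)
    )
    df[, keep]
  })
}

#' Call pathway inducers and suppressors from per-dsRNA Z-scores
#'
#' Applies the multi-dsRNA consensus rule. A gene is called an *inducer*
#' (its product is required for reporter activity, so knockdown represses
#' the readout) when at least `min_consistent` of its dsRNAs score at or
#' below `-z_threshold`; a *suppressor* symmetric on the positive side.
#' With `opposite_sign_veto = TRUE` (default) a single dsRNA crossing the
#' threshold on the opposite side vetoes the call — discordant reagents
#' suggest off-target effects.
#'
#' The default 2-of-3 rule with veto tolerates one inert dsRNA per gene, a
#' common failure mode of long-dsRNA reagents, while a strict 3-of-3 rule
#' (`min_consistent = 3`) is available for conservative calling.
#'
#' If the veto is disabled and a gene reaches `min_consistent` on both
#' sides, the call follows the sign of its mean Z (exact zero mean gives
#' `"none"`).
#'
#' @param zscores A data frame with columns `gene_id`, `dsrna_id`, `z`
#'   (e.g. from [compute_zscores()] or [read_zscore_table()]). An optional
#'   `control_role` column is carried through.
#' @param z_threshold Positive Z magnitude a dsRNA must reach to count
#'   (default 1.65, the one-sided 5% normal tail).
#' @param min_consistent Number of concordant dsRNAs required (default 2).
#' @param opposite_sign_veto Veto calls with any opposite-side dsRNA at or
#'   beyond the threshold (default `TRUE`).
#' @return A tibble of class `"gene_calls"`, one row per gene: `gene_id`,
#'   `control_role`, `call` (`"inducer"`, `"suppressor"` or `"none"`),
#'   `n_passing` (dsRNAs passing on the called side; for `"none"` the
#'   larger side count), `rank_score` (mean Z) and `z_values` (list column
#'   of per-dsRNA Z-scores, input order).
#' @section Errors: missing (`NA`) Z-scores raise a missing-data error.
#' @seealso [rank_hits()]
#' @export
#' @examples
#' z <- tibble::tibble(
#'   gene_id = rep(c("Cdk12", "fray"), each = 3),
#'   dsrna_id = rep(c("d1", "d2", "d3"), 2),
#'   z = c(-25.1, -28.27, -39.64, -3.4, -3.82, -0.19)
#' )
#' classify_genes(z)
classify_genes <- function(zscores, z_threshold = 1.65, min_consistent = 2,
                           opposite_sign_veto = TRUE) {
  check_columns(zscores, c("gene_id", "dsrna_id", "z"), "zscores")
  if (!is.numeric(z_threshold) || length(z_threshold) != 1 || z_threshold <= 0) {
    abort("`z_threshold` must be a single positive number.")
  }
  if (min_consistent < 1) {
    abort("`min_consistent` must be at least 1.")
  }
  zscores <- as_tibble(zscores)
  if (!"control_role" %in% names(zscores)) zscores$control_role <- "none"
  if (anyNA(zscores$z) || any(!is.finite(zscores$z))) {
    abort("Missing or non-finite Z-scores; every retained dsRNA needs a finite z.")
  }
  if (nrow(zscores) == 0) {
    abort("`zscores` has no rows; every gene needs at least one dsRNA entry.")
  }

  calls <- zscores %>%
    group_by(.data$gene_id, .data$control_role) %>%
    summarise(
      n_neg = sum(.data$z <= -z_threshold),
      n_pos = sum(.data$z >= z_threshold),
      rank_score = mean(.data$z),
      z_values = list(.data$z),
      .groups = "drop"
    ) %>%
    mutate(
      inducer_ok = .data$n_neg >= min_consistent &
        (!opposite_sign_veto | .data$n_pos == 0),
      suppressor_ok = .data$n_pos >= min_consistent &
        (!opposite_sign_veto | .data$n_neg == 0),
      call = case_when(
        .data$inducer_ok & .data$suppressor_ok & .data$rank_score < 0 ~ "inducer",
        .data$inducer_ok & .data$suppressor_ok & .data$rank_score > 0 ~ "suppressor",
        .data$inducer_ok & .data$suppressor_ok ~ "none",
        .data$inducer_ok ~ "inducer",
        .data$suppressor_ok ~ "suppressor",
        TRUE ~ "none"
      ),
      n_passing = case_when(
        .data$call == "inducer" ~ .data$n_neg,
        .data$call == "suppressor" ~ .data$n_pos,
        TRUE ~ pmax(.data$n_neg, .data$n_pos)
      )
    ) %>%
    select(
      "gene_id", "control_role", "call", "n_passing", "rank_score", "z_values"
    )

  attr(calls, "config") <- list(
    z_threshold = z_threshold,
    min_consistent = min_consistent,
    opposite_sign_veto = opposite_sign_veto
  )
  class(calls) <- c("gene_calls", class(calls))
  calls
}

#' Order gene calls by effect strength
#'
#' Sorts inducers first, ascending by mean Z (the strongest repressive
#' effect — the most negative mean — ranks first), then suppressors
#' descending by mean Z, then uncalled genes; ties broken by `gene_id`.
#'
#' @param calls A `"gene_calls"` table from [classify_genes()].
#' @return The same table, reordered.
#' @export
rank_hits <- function(calls) {
  check_columns(calls, c("gene_id", "call", "rank_score"), "calls")
  if (nrow(calls) == 0) abort("`calls` must be non-empty.")
  cfg <- attr(calls, "config", exact = TRUE)
  block <- match(calls$call, c("inducer", "suppressor", "none"))
  key <- ifelse(calls$call == "suppressor", -calls$rank_score, calls$rank_score)
  key[calls$call == "none"] <- 0
  out <- calls[order(block, key, calls$gene_id), , drop = FALSE]
  attr(out, "config") <- cfg
  class(out) <- unique(c("gene_calls", class(out)))
  out
}

#' @export
print.gene_calls <- function(x, ...) {
  cfg <- attr(x, "config", exact = TRUE)
  n_ind <- sum(x$call == "inducer")
  n_sup <- sum(x$call == "suppressor")
  cat(sprintf(
    "Gene calls: %d genes (%d inducers, %d suppressors)\n",
    nrow(x), n_ind, n_sup
  ))
  if (!is.null(cfg)) {
    cat(sprintf(
      "Rule: |Z| >= %.4g on >= %d dsRNA(s), opposite-sign veto %s\n",
      cfg$z_threshold, cfg$min_consistent,
      if (isTRUE(cfg$opposite_sign_veto)) "on" else "off"
    ))
  }
  print(as_tibble(unclass_calls(x)), ...)
  invisible(x)
}

unclass_calls <- function(x) {
  class(x) <- setdiff(class(x), "gene_calls")
  x
}

#' @describeIn classify_genes `tidy()` unnests the per-dsRNA Z-scores into
#'   one row per gene and dsRNA slot.
#' @param x A `"gene_calls"` object.
#' @param ... Unused.
#' @export
tidy.gene_calls <- function(x, ...) {
  as_tibble(unclass_calls(x)) %>%
    mutate(z_values = purrr::map(.data$z_values, ~ tibble(
      dsrna_slot = seq_along(.x), z = .x
    ))) %>%
    tidyr::unnest("z_values")
}

#' @describeIn classify_genes `glance()` gives a one-row summary of the
#'   screen call set.
#' @export
glance.gene_calls <- function(x, ...) {
  cfg <- attr(x, "config", exact = TRUE) %||%
    list(z_threshold = NA_real_, min_consistent = NA_integer_,
         opposite_sign_veto = NA)
  tibble(
    n_genes = nrow(x),
    n_inducers = sum(x$call == "inducer"),
    n_suppressors = sum(x$call == "suppressor"),
    z_threshold = cfg$z_threshold,
    min_consistent = cfg$min_consistent,
    opposite_sign_veto = cfg$opposite_sign_veto
  )
}

#' @describeIn classify_genes `autoplot()` draws per-dsRNA Z-scores
#'   coloured by call, with the consensus threshold marked.
#' @param object A `"gene_calls"` object.
#' @export
autoplot.gene_calls <- function(object, ...) {
  cfg <- attr(object, "config", exact = TRUE) %||% list(z_threshold = 1.65)
  df <- tidy(rank_hits(object))
  df$gene_id <- factor(df$gene_id, levels = unique(df$gene_id))
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$gene_id, y = .data$z, colour = .data$call
  )) +
    ggplot2::geom_hline(
      yintercept = c(-1, 1) * cfg$z_threshold,
      linetype = "dashed", colour = "grey50"
    ) +
    ggplot2::geom_point(size = 2, alpha = 0.8) +
    ggplot2::scale_colour_manual(values = c(
      inducer = "#2166AC", suppressor = "#B2182B", none = "grey60"
    )) +
    ggplot2::labs(
      x = NULL, y = "robust Z (Fluc/Rluc)",
      colour = "call",
      title = "Per-dsRNA reporter Z-scores by gene"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
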