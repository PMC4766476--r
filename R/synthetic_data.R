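# Seeded generators with planted ground truth.
#
# Every generator is a pure function of its config (which includes the
# seed): the same config yields byte-identical output, so the analysis
# stages can be validated end to end against known truth without any
# external data.

#' Configuration for the synthetic dual-luciferase screen
#'
#' Defaults emulate a kinome-scale screen: 432 genes, 3 independent dsRNAs
#' per gene, 384-well plates, with per-plate assay controls (CncC and MafS
#' knockdowns behave like inducers, Keap1 like a suppressor, GFP is
#' neutral). Well ratios are lognormal around 1; a planted inducer
#' multiplies the firefly signal by `inducer_effect` (< 1), a suppressor
#' by `suppressor_effect` (> 1). A fraction `p_inert_dsrna` of hit genes
#' receives one inert dsRNA, emulating reagents that fail to knock down
#' their target.
#'
#' @param n_genes Number of screened genes (default 432).
#' @param n_dsrna_per_gene dsRNAs per gene (default 3).
#' @param plate_size Wells per plate (default 384); 4 wells per plate are
#'   reserved for controls.
#' @param ratio_meanlog,ratio_sdlog Lognormal parameters of the baseline
#'   Fluc/Rluc ratio (defaults 0 and 0.15).
#' @param rluc_meanlog,rluc_sdlog Lognormal parameters of the renilla
#'   readout (defaults `log(2000)` and 0.25; cancels in the ratio).
#' @param inducer_effect Multiplicative Fluc suppression for planted
#'   inducers, in (0, 1) (default 0.2).
#' @param suppressor_effect Multiplicative Fluc gain for planted
#'   suppressors, > 1 (default 3).
#' @param p_inert_dsrna Fraction of hit genes given exactly one inert
#'   dsRNA (default 1/3).
#' @param n_planted_inducers,n_planted_suppressors Planted hit counts
#'   (defaults 5 and 3).
#' @param seed Integer seed; part of the config so runs are replayable.
#' @return A list of class `"screen_sim_config"`.
#' @export
screen_sim_config <- function(n_genes = 432,
                              n_dsrna_per_gene = 3,
                              plate_size = 384,
                              ratio_meanlog = 0,
                              ratio_sdlog = 0.15,
                              rluc_meanlog = log(2000),
                              rluc_sdlog = 0.25,
                              inducer_effect = 0.2,
                              suppressor_effect = 3,
                              p_inert_dsrna = 1 / 3,
                              n_planted_inducers = 5,
                              n_planted_suppressors = 3,
                              seed = 1) {
  if (inducer_effect <= 0 || inducer_effect > 1) {
    abort("`inducer_effect` must lie in (0, 1].")
  }
  if (suppressor_effect < 1) abort("`suppressor_effect` must be >= 1.")
  if (p_inert_dsrna < 0 || p_inert_dsrna > 1) {
    abort("`p_inert_dsrna` must lie in [0, 1].")
  }
  if (n_planted_inducers + n_planted_suppressors > n_genes) {
    abort("More planted hits than genes.")
  }
  if (plate_size <= 4) abort("`plate_size` must exceed the 4 control wells.")
  structure(
    list(
      n_genes = n_genes, n_dsrna_per_gene = n_dsrna_per_gene,
      plate_size = plate_size,
      ratio_meanlog = ratio_meanlog, ratio_sdlog = ratio_sdlog,
      rluc_meanlog = rluc_meanlog, rluc_sdlog = rluc_sdlog,
      inducer_effect = inducer_effect, suppressor_effect = suppressor_effect,
      p_inert_dsrna = p_inert_dsrna,
      n_planted_inducers = n_planted_inducers,
      n_planted_suppressors = n_planted_suppressors,
      seed = seed
    ),
    class = "screen_sim_config"
  )
}

#' Generate a synthetic dual-luciferase screen with planted hits
#'
#' Lays wells out plate by plate (each plate carries one well each of the
#' CncC, MafS, Keap1 and GFP dsRNA controls), draws renilla readouts and
#' baseline ratios from lognormal distributions, and applies each dsRNA's
#' planted effect to the firefly signal only. The returned truth table
#' records every gene's role, effect size and inert dsRNA (if any).
#'
#' @param cfg A [screen_sim_config()].
#' @return A list with `wells` (a screen plate table as consumed by
#'   [normalize_wells()]) and `truth` (tibble `gene_id`, `role`, `effect`,
#'   `inert_dsrna`).
#' @export
#' @examples
#' sim <- gen_screen(screen_sim_config(n_genes = 24, seed = 7))
#' head(sim$wells)
#' dplyr::count(sim$truth, role)
gen_screen <- function(cfg = screen_sim_config()) {
  if (!inherits(cfg, "screen_sim_config")) {
    abort("`cfg` must come from screen_sim_config().")
  }
  withr::with_seed(cfg$seed, {
    gene_ids <- sprintf("gene%03d", seq_len(cfg$n_genes))
    roles <- rep("background", cfg$n_genes)
    if (cfg$n_planted_inducers > 0) {
      roles[seq_len(cfg$n_planted_inducers)] <- "inducer"
    }
    if (cfg$n_planted_suppressors > 0) {
      roles[cfg$n_planted_inducers + seq_len(cfg$n_planted_suppressors)] <-
        "suppressor"
    }
    effect <- dplyr::case_when(
      roles == "inducer" ~ cfg$inducer_effect,
      roles == "suppressor" ~ cfg$suppressor_effect,
      TRUE ~ 1
    )

    # one inert dsRNA for a random subset of hit genes
    hit_idx <- which(roles != "background")
    inert_genes <- hit_idx[runif(length(hit_idx)) < cfg$p_inert_dsrna]
    inert_slot <- rep(NA_integer_, cfg$n_genes)
    inert_slot[inert_genes] <- sample.int(cfg$n_dsrna_per_gene,
                                          length(inert_genes),
                                          replace = TRUE)

    truth <- tibble(
      gene_id = gene_ids,
      role = roles,
      effect = effect,
      inert_dsrna = ifelse(
        is.na(inert_slot), NA_character_,
        sprintf("%s_ds%d", gene_ids, inert_slot)
      )
    )

    sample_wells <- tibble(
      gene_id = rep(gene_ids, each = cfg$n_dsrna_per_gene),
      dsrna_slot = rep(seq_len(cfg$n_dsrna_per_gene), times = cfg$n_genes)
    ) %>%
      mutate(
        dsrna_id = sprintf("%s_ds%d", .data$gene_id, .data$dsrna_slot),
        control_role = "none",
        effect = ifelse(
          !is.na(inert_slot[match(.data$gene_id, gene_ids)]) &
            inert_slot[match(.data$gene_id, gene_ids)] == .data$dsrna_slot,
          1,
          effect[match(.data$gene_id, gene_ids)]
        )
      )

    per_plate <- cfg$plate_size - 4L
    n_plates <- ceiling(nrow(sample_wells) / per_plate)
    controls <- purrr::map_dfr(seq_len(n_plates), function(p) {
      tibble(
        gene_id = c("CncC", "MafS", "Keap1", "GFP"),
        dsrna_slot = 1L,
        dsrna_id = sprintf("%s_P%02d", c("CncC", "MafS", "Keap1", "GFP"), p),
        control_role = c(
          "pathway-positive", "pathway-positive", "pathway-negative", "neutral"
        ),
        effect = c(
          cfg$inducer_effect, cfg$inducer_effect, cfg$suppressor_effect, 1
        ),
        plate = p
      )
    })

    sample_wells$plate <- rep(seq_len(n_plates),
                              each = per_plate)[seq_len(nrow(sample_wells))]
    wells <- bind_rows(
      controls,
      sample_wells
    ) %>%
      arrange(.data$plate) %>%
      group_by(.data$plate) %>%
      mutate(
        well_index = row_number(),
        well_id = sprintf(
          "%s%02d",
          LETTERS[(.data$well_index - 1) %/% 24 + 1],
          (.data$well_index - 1) %% 24 + 1
        )
      ) %>%
      ungroup() %>%
      mutate(
        plate_id = sprintf("P%02d", .data$plate),
        rluc = rlnorm(n(), cfg$rluc_meanlog, cfg$rluc_sdlog),
        fluc = .data$rluc * rlnorm(n(), cfg$ratio_meanlog, cfg$ratio_sdlog) *
          .data$effect
      ) %>%
      select(
        "plate_id", "well_id", "gene_id", "dsrna_id", "fluc", "rluc",
        "control_role"
      )

    list(wells = wells, truth = truth)
  })
}

#' Configuration for the synthetic four-condition count matrix
#'
#' Defaults emulate the four-arm stress design (Control, Paraquat, Cdk12i,
#' Cdk12i_Paraquat, three replicates each) with negative-binomial counts,
#' variance `mu + phi * mu^2`. Planted group-A genes are induced
#' `fold_pq_induction`-fold by paraquat only (the induction is absent in
#' both knockdown arms); planted group-B genes are high only in the
#' combined arm (`fold_b_induction`-fold) with a mild suppression
#' (`fold_b_cdk12i`) in the knockdown-alone arm, so the knockdown arm
#' differs from control as the group-B selection criteria require while
#' staying "low" on the pattern scale. Housekeeping genes are flat at
#' twice the baseline; background genes are flat with lognormal gene-level
#' mean jitter.
#'
#' @param n_background,n_group_a,n_group_b,n_housekeeping Gene counts per
#'   role (defaults 400, 30, 30, 40).
#' @param baseline_mean Baseline expected count (default 100).
#' @param fold_pq_induction Paraquat induction of group-A genes (default
#'   8).
#' @param fold_b_induction Combined-arm induction of group-B genes
#'   (default 4).
#' @param fold_b_cdk12i Knockdown-alone multiplier for group-B genes
#'   (default 0.5).
#' @param dispersion NB dispersion `phi` (default 0.1); 0 gives Poisson
#'   counts.
#' @param n_replicates Replicates per condition (default 3).
#' @param libsize_jitter Half-width of the uniform library-size factor
#'   (default 0.2, i.e. factors in 0.8-1.2).
#' @param bg_mean_sdlog Lognormal sd of background gene-level mean jitter
#'   (default 0.5).
#' @param seed Integer seed.
#' @return A list of class `"counts_sim_config"`.
#' @export
counts_sim_config <- function(n_background = 400,
                              n_group_a = 30,
                              n_group_b = 30,
                              n_housekeeping = 40,
                              baseline_mean = 100,
                              fold_pq_induction = 8,
                              fold_b_induction = 4,
                              fold_b_cdk12i = 0.5,
                              dispersion = 0.1,
                              n_replicates = 3,
                              libsize_jitter = 0.2,
                              bg_mean_sdlog = 0.5,
                              seed = 1) {
  if (fold_pq_induction <= 1 || fold_b_induction <= 1) {
    abort("Planted induction folds must exceed 1.")
  }
  if (dispersion < 0) abort("`dispersion` must be >= 0.")
  if (baseline_mean <= 0) abort("`baseline_mean` must be positive.")
  if (libsize_jitter < 0 || libsize_jitter >= 1) {
    abort("`libsize_jitter` must lie in [0, 1).")
  }
  structure(
    list(
      n_background = n_background, n_group_a = n_group_a,
      n_group_b = n_group_b, n_housekeeping = n_housekeeping,
      baseline_mean = baseline_mean,
      fold_pq_induction = fold_pq_induction,
      fold_b_induction = fold_b_induction,
      fold_b_cdk12i = fold_b_cdk12i,
      dispersion = dispersion, n_replicates = n_replicates,
      libsize_jitter = libsize_jitter, bg_mean_sdlog = bg_mean_sdlog,
      seed = seed
    ),
    class = "counts_sim_config"
  )
}

#' Generate a synthetic four-condition count matrix with planted groups
#'
#' @param cfg A [counts_sim_config()].
#' @return A list with `counts` (tibble `gene_id` + one column per
#'   sample), `design` (tibble `sample_id`, `condition`, `replicate`) and
#'   `truth` (tibble `gene_id`, `role`, `mu_Control`, `mu_Paraquat`,
#'   `mu_Cdk12i`, `mu_Cdk12i_Paraquat`).
#' @export
#' @examples
#' sim <- gen_counts(counts_sim_config(n_background = 50, seed = 3))
#' dim(sim$counts)
gen_counts <- function(cfg = counts_sim_config()) {
  if (!inherits(cfg, "counts_sim_config")) {
    abort("`cfg` must come from counts_sim_config().")
  }
  withr::with_seed(cfg$seed, {
    b <- cfg$baseline_mean
    ids <- c(
      sprintf("grpA_%03d", seq_len(cfg$n_group_a)),
      sprintf("grpB_%03d", seq_len(cfg$n_group_b)),
      sprintf("hk_%03d", seq_len(cfg$n_housekeeping)),
      sprintf("bg_%03d", seq_len(cfg$n_background))
    )
    roles <- rep(
      c("group_a", "group_b", "housekeeping", "background"),
      c(cfg$n_group_a, cfg$n_group_b, cfg$n_housekeeping, cfg$n_background)
    )
    bg_mu <- b * rlnorm(cfg$n_background, 0, cfg$bg_mean_sdlog)
    mu <- rbind(
      matrix(
        rep(c(b, b * cfg$fold_pq_induction, b, b), each = cfg$n_group_a),
        nrow = cfg$n_group_a, ncol = 4
      ),
      matrix(
        rep(
          c(b, b, b * cfg$fold_b_cdk12i, b * cfg$fold_b_induction),
          each = cfg$n_group_b
        ),
        nrow = cfg$n_group_b, ncol = 4
      ),
      matrix(2 * b, nrow = cfg$n_housekeeping, ncol = 4),
      matrix(rep(bg_mu, 4), nrow = cfg$n_background, ncol = 4)
    )
    colnames(mu) <- CONDITION_LEVELS

    design <- tidyr::expand_grid(
      condition = CONDITION_LEVELS,
      replicate = seq_len(cfg$n_replicates)
    ) %>%
      mutate(sample_id = sprintf("%s_%d", .data$condition, .data$replicate)) %>%
      select("sample_id", "condition", "replicate")

    libfactor <- runif(nrow(design), 1 - cfg$libsize_jitter,
                       1 + cfg$libsize_jitter)
    counts <- matrix(0L, nrow = nrow(mu), ncol = nrow(design),
                     dimnames = list(ids, design$sample_id))
    for (j in seq_len(nrow(design))) {
      mu_j <- mu[, design$condition[j]] * libfactor[j]
      counts[, j] <- if (cfg$dispersion > 0) {
        rnbinom(nrow(mu), mu = mu_j, size = 1 / cfg$dispersion)
      } else {
        stats::rpois(nrow(mu), mu_j)
      }
    }

    truth <- tibble(gene_id = ids, role = roles) %>%
      dplyr::bind_cols(as_tibble(as.data.frame(mu)) %>%
                         setNames(paste0("mu_", CONDITION_LEVELS)))

    list(counts = matrix_to_tbl(counts), design = design, truth = truth)
  })
}

#' Generate an annotation table enriched for the planted roles
#'
#' Builds one term per planted (non-background) role annotating
#' `enriched_fraction` of that role's genes plus `background_leak` genes
#' drawn from outside the role, and `n_noise_terms` random terms of
#' 5-30 genes each — a ground-truth testbed for [enrich()].
#'
#' @param truth A truth tibble with columns `gene_id` and `role` (from
#'   [gen_counts()] or [gen_screen()]).
#' @param n_noise_terms Number of random terms (default 20).
#' @param enriched_fraction Fraction of each role's genes the role term
#'   annotates (default 0.8).
#' @param background_leak Genes from outside the role added to each role
#'   term (default 5).
#' @param seed Integer seed (default 1).
#' @return An annotation tibble `term_id`, `term_name`, `gene_id`.
#' @export
gen_annotation <- function(truth, n_noise_terms = 20, enriched_fraction = 0.8,
                           background_leak = 5, seed = 1) {
  check_columns(truth, c("gene_id", "role"), "truth")
  if (enriched_fraction <= 0 || enriched_fraction > 1) {
    abort("`enriched_fraction` must lie in (0, 1].")
  }
  withr::with_seed(seed, {
    roles <- setdiff(unique(truth$role), "background")
    role_terms <- purrr::map_dfr(roles, function(r) {
      members <- truth$gene_id[truth$role == r]
      if (length(members) == 0) {
        return(tibble(term_id = character(), term_name = character(),
                      gene_id = character()))
      }
      n_in <- max(1, round(enriched_fraction * length(members)))
      picked <- sort(sample(members, n_in))
      others <- setdiff(truth$gene_id, members)
      leak <- sort(sample(others, min(background_leak, length(others))))
      tibble(
        term_id = paste0("role:", r),
        term_name = sprintf("planted %s term", r),
        gene_id = c(picked, leak)
      )
    })
    noise_terms <- purrr::map_dfr(seq_len(n_noise_terms), function(i) {
      size <- sample(5:30, 1)
      tibble(
        term_id = sprintf("noise:%02d", i),
        term_name = sprintf("random term %d", i),
        gene_id = sort(sample(truth$gene_id, min(size, nrow(truth))))
      )
    })
    bind_rows(role_terms, noise_terms)
  })
}
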