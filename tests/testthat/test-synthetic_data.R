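test_that("generators are pure functions of config and seed", {
  cfg <- screen_sim_config(n_genes = 40, seed = 9)
  expect_identical(gen_screen(cfg), gen_screen(cfg))

  ccfg <- counts_sim_config(n_background = 50, seed = 9)
  expect_identical(gen_counts(ccfg), gen_counts(ccfg))

  truth <- gen_counts(ccfg)$truth
  expect_identical(gen_annotation(truth, seed = 3),
                   gen_annotation(truth, seed = 3))
  # a different seed gives a different draw
  expect_false(identical(gen_screen(cfg),
                         gen_screen(screen_sim_config(n_genes = 40, seed = 10))))
})

test_that("screen layout fills plates with per-plate controls", {
  sim <- gen_screen(screen_sim_config(seed = 5))
  wells <- sim$wells
  # 432 genes x 3 dsRNAs on 380 usable wells per plate -> 4 plates
  expect_equal(length(unique(wells$plate_id)), 4)
  expect_equal(sum(wells$control_role == "none"), 432 * 3)
  per_plate <- dplyr::count(wells, plate_id)
  expect_true(all(per_plate$n <= 384))
  # every plate carries the four assay controls
  ctrl <- dplyr::count(wells[wells$control_role != "none", ], plate_id)
  expect_true(all(ctrl$n == 4))
  # dsRNA ids unique within a plate
  expect_false(any(duplicated(wells[, c("plate_id", "dsrna_id")])))
})

test_that("planted screen effects are recovered and controls score correctly", {
  sim <- gen_screen(screen_sim_config(seed = 2))
  z <- compute_zscores(normalize_wells(sim$wells))
  calls <- classify_genes(z)

  truth <- sim$truth
  # genes with at least two effective (non-inert) dsRNAs at effect 0.2
  n_eff <- vapply(truth$gene_id, function(g) {
    3 - !is.na(truth$inert_dsrna[truth$gene_id == g])
  }, numeric(1))
  strong_inducers <- truth$gene_id[truth$role == "inducer" & n_eff >= 2]
  called <- calls$gene_id[calls$call == "inducer"]
  expect_true(all(strong_inducers %in% called))
  strong_sup <- truth$gene_id[truth$role == "suppressor" & n_eff >= 2]
  expect_true(all(strong_sup %in% calls$gene_id[calls$call == "suppressor"]))

  # Keap1-like control scores on the positive side, CncC-like negative
  expect_gt(min(z$z[z$gene_id == "Keap1"]), 0)
  expect_lt(max(z$z[z$gene_id == "CncC"]), 0)
})

test_that("a null screen yields only rare false-positive calls", {
  cfg <- screen_sim_config(n_planted_inducers = 0, n_planted_suppressors = 0,
                           seed = 3)
  sim <- gen_screen(cfg)
  calls <- classify_genes(compute_zscores(normalize_wells(sim$wells)))
  calls <- calls[calls$control_role == "none", ]
  # Normal-tail theory (two 5% tails, 2-of-3 consensus, veto) puts the
  # per-gene false-call probability near 1.5%; the lognormal ratio skew
  # and per-plate scale-estimation noise roughly double it in practice,
  # so a null screen must stay well under a 5% call rate.
  expect_lt(mean(calls$call != "none"), 0.05)
})

test_that("a null planted effect leaves inducers at chance recovery", {
  cfg <- screen_sim_config(inducer_effect = 1, seed = 4)
  sim <- gen_screen(cfg)
  calls <- classify_genes(compute_zscores(normalize_wells(sim$wells)))
  planted <- sim$truth$gene_id[sim$truth$role == "inducer"]
  called <- calls$gene_id[calls$call == "inducer"]
  expect_lt(mean(planted %in% called), 0.5)
})

test_that("count noise follows the negative-binomial mean-variance law", {
  # housekeeping genes share one mean; disable library jitter so the
  # pooled sample variance estimates mu + phi mu^2 directly
  cfg <- counts_sim_config(n_housekeeping = 300, n_background = 10,
                           libsize_jitter = 0, dispersion = 0.1, seed = 6)
  sim <- gen_counts(cfg)
  hk <- as.matrix(sim$counts[grepl("^hk_", sim$counts$gene_id), -1])
  mu <- 2 * cfg$baseline_mean
  expected_var <- mu + cfg$dispersion * mu^2
  expect_equal(mean(hk), mu, tolerance = 0.05)
  expect_equal(var(as.vector(hk)), expected_var, tolerance = 0.2)

  # dispersion zero collapses to Poisson (variance ~ mean)
  cfg0 <- counts_sim_config(n_housekeeping = 300, n_background = 10,
                            libsize_jitter = 0, dispersion = 0, seed = 6)
  hk0 <- as.matrix(gen_counts(cfg0)$counts[grepl("^hk_", sim$counts$gene_id), -1])
  expect_equal(var(as.vector(hk0)) / mean(hk0), 1, tolerance = 0.15)
})

test_that("planted fold changes are recovered from the generated counts", {
  cfg <- counts_sim_config(libsize_jitter = 0, seed = 7)
  sim <- gen_counts(cfg)
  cnt <- as.matrix(sim$counts[, -1])
  rownames(cnt) <- sim$counts$gene_id
  a_genes <- grepl("^grpA_", rownames(cnt))
  design <- sim$design
  pq <- rowMeans(cnt[a_genes, design$sample_id[design$condition == "Paraquat"]])
  ctrl <- rowMeans(cnt[a_genes, design$sample_id[design$condition == "Control"]])
  # 30 genes x 3 replicates on each side: the pooled induction ratio
  # settles near the planted 8-fold
  expect_equal(mean(pq) / mean(ctrl), 8, tolerance = 0.1)
})

test_that("annotation generator plants one enriched term per role", {
  truth <- gen_counts(counts_sim_config(n_background = 50, seed = 1))$truth
  ann <- gen_annotation(truth, n_noise_terms = 0, enriched_fraction = 1,
                        background_leak = 0, seed = 2)
  roles <- setdiff(unique(truth$role), "background")
  expect_setequal(unique(ann$term_id), paste0("role:", roles))
  for (r in roles) {
    members <- truth$gene_id[truth$role == r]
    expect_setequal(ann$gene_id[ann$term_id == paste0("role:", r)], members)
  }
  # a perfect-overlap query attains the closed-form minimal p
  members <- truth$gene_id[truth$role == "group_a"]
  enr <- enrich(members, truth$gene_id, ann)
  top <- enr[enr$term_id == "role:group_a", ]
  expect_equal(top$p_raw,
               1 / choose(nrow(truth), length(members)),
               tolerance = 1e-12)
})
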