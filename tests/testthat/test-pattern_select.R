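std_from_profiles <- function(profiles, ids = paste0("g", seq_len(nrow(profiles)))) {
  colnames(profiles) <- condition_levels()
  sm <- tidyr::pivot_longer(
    dplyr::bind_cols(tibble::tibble(gene_id = ids),
                     tibble::as_tibble(as.data.frame(profiles))),
    -gene_id, names_to = "condition", values_to = "mean_expr"
  )
  profile_standardize(sm)
}

test_that("minimum-read filter keeps genes covered in every sample", {
  m <- rbind(
    c(5L, 3L, 3L), c(0L, 9L, 9L), c(2L, 2L, 2L), c(7L, 0L, 7L), c(1L, 1L, 1L)
  )
  colnames(m) <- paste0("s", 1:3)
  kept <- filter_min_reads(toy_counts(m), min_reads = 1)
  expect_equal(kept$gene_id, c("g1", "g3", "g5"))
  expect_equal(nrow(filter_min_reads(toy_counts(m), min_reads = 0)), 5)
  expect_equal(filter_min_reads(toy_counts(m), min_reads = 3)$gene_id, "g1")
})

test_that("profile standardization centres rows and flags flat genes", {
  std <- std_from_profiles(rbind(c(0, 3, 0, 0), c(5, 5, 5, 5)))
  expect_false(std$flat[1])
  expect_true(std$flat[2])
  row1 <- as.numeric(std[1, condition_levels()])
  expect_equal(mean(row1), 0, tolerance = 1e-12)
  expect_equal(sd(row1), 1, tolerance = 1e-12)
  expect_true(row1[2] > 0 && all(row1[-2] < 0))
})

test_that("pattern labelling reads the centroid sign with a low tie rule", {
  expect_equal(label_cluster_pattern(c(-0.5, 1.5, -0.5, -0.5)),
               "low-high-low-low")
  expect_equal(label_cluster_pattern(c(-0.5, -0.5, -0.5, 1.5)),
               "low-low-low-high")
  expect_equal(label_cluster_pattern(c(0, 0, 0, 0)), "low-low-low-low")
  expect_error(label_cluster_pattern(c(1, 2)), "length 4")
})

test_that("correlation clustering groups identical shapes and splits opposites", {
  # two identical shapes, one anti-correlated: distance 0 merges first
  profiles <- rbind(
    c(1, 5, 1, 1), c(2, 10, 2, 2), c(5, 1, 5, 5)
  )
  cl <- cluster_profiles(std_from_profiles(profiles), k = 2)
  expect_equal(cl$cluster_id[1], cl$cluster_id[2])
  expect_false(cl$cluster_id[3] == cl$cluster_id[1])

  # six profiles in two obvious shape families
  shapes <- rbind(
    c(1, 9, 1, 1), c(2, 17, 2, 3), c(1, 10, 2, 1),
    c(1, 1, 1, 9), c(3, 2, 3, 20), c(2, 2, 1, 12)
  )
  std <- std_from_profiles(shapes)
  cl2 <- cluster_profiles(std, k = 2)
  expect_equal(length(unique(cl2$cluster_id[1:3])), 1)
  expect_equal(length(unique(cl2$cluster_id[4:6])), 1)
  expect_false(cl2$cluster_id[1] == cl2$cluster_id[4])

  # agreement with the exhaustive average-linkage oracle
  m <- as.matrix(as.data.frame(std[, condition_levels()]))
  d <- 1 - cor(t(m))
  expect_true(same_partition(cl2$cluster_id, avg_linkage_brute(d, 2)))

  expect_error(cluster_profiles(std, k = 7), "at least k")
})

test_that("clustering matches the brute-force oracle on random small inputs", {
  set.seed(31)
  for (i in 1:20) {
    n <- sample(4:6, 1)
    profiles <- matrix(rlnorm(n * 4, 3, 1), nrow = n)
    std <- std_from_profiles(profiles)
    if (any(std$flat)) next
    m <- as.matrix(as.data.frame(std[, condition_levels()]))
    d <- 1 - cor(t(m))
    for (k in 2:3) {
      ours <- cluster_profiles(std, k = k)$cluster_id
      expect_true(same_partition(ours, avg_linkage_brute(d, k)))
    }
  }
})

test_that("clustering is deterministic for identical input", {
  set.seed(8)
  profiles <- matrix(rlnorm(200 * 4, 3, 1), nrow = 200)
  std <- std_from_profiles(profiles)
  a <- cluster_profiles(std, k = 8)
  b <- cluster_profiles(std, k = 8)
  expect_identical(a, b)
})

make_de <- function(genes, num, den, log2fc, q) {
  out <- tibble::tibble(gene_id = genes, log2fc = log2fc,
                        p = q / 2, q = q)
  attr(out, "numerator") <- num
  attr(out, "denominator") <- den
  class(out) <- c("de_comparison", class(out))
  out
}

test_that("group-A criteria apply the printed cut-offs strictly", {
  summary <- tibble::tibble(
    gene_id = rep(c("gA", "gEdge", "gFail"), each = 4),
    condition = rep(condition_levels(), 3),
    mean_expr = c(
      1, 9, 2, 1,  # geometric bound sqrt(9) = 3; 2 < 3 passes
      4, 4, 4, 4,  # bound 4; 4 < 4 fails (strict)
      1, 9, 2, 1
    )
  )
  genes <- c("gA", "gEdge", "gFail")
  de <- list(
    make_de(genes, "Paraquat", "Control",
            log2fc = c(2, 2, 2), q = c(0.01, 0.01, 0.2)),
    make_de(genes, "Cdk12i", "Control",
            log2fc = c(-0.5, -0.5, -0.5), q = rep(0.5, 3))
  )
  audit <- apply_group_a_criteria(genes, de, summary)
  expect_equal(audit$pass_geo_mean, c(TRUE, FALSE, TRUE))
  expect_equal(audit$geo_bound[1], 3)
  expect_equal(audit$selected, c(TRUE, FALSE, FALSE))
  # gFail fails exactly the induction-significance criterion
  expect_false(audit$pass_pq_induced[3])
  expect_true(audit$pass_cdk_baseline[3] && audit$pass_geo_mean[3])

  expect_error(apply_group_a_criteria(genes, de[1], summary), "Missing")
})

test_that("group-B criteria require all three comparisons to pass", {
  genes <- c("gB", "gZero", "gQ")
  de <- list(
    make_de(genes, "Cdk12i_Paraquat", "Paraquat",
            log2fc = c(2, 0, 2), q = c(0.001, 0.001, 0.001)),
    make_de(genes, "Cdk12i", "Control",
            log2fc = c(-1, -1, -1), q = c(0.01, 0.01, 0.5)),
    make_de(genes, "Cdk12i_Paraquat", "Cdk12i",
            log2fc = c(3, 3, 3), q = c(0.001, 0.001, 0.001))
  )
  audit <- apply_group_b_criteria(genes, de)
  expect_equal(audit$selected, c(TRUE, FALSE, FALSE))
  # log2fc of exactly 0 fails the strict inequality
  expect_false(audit$pass_cpq_pq[2])
  # gQ fails only the knockdown-vs-control significance criterion
  expect_false(audit$pass_cdk_ctrl[3])
  expect_true(audit$pass_cpq_pq[3] && audit$pass_cpq_cdk[3])
})

test_that("criterion decisions are invariant to uniform expression rescaling", {
  set.seed(21)
  genes <- paste0("g", 1:40)
  summary <- tibble::tibble(
    gene_id = rep(genes, each = 4),
    condition = rep(condition_levels(), 40),
    mean_expr = rlnorm(160, 3, 1)
  )
  de <- list(
    make_de(genes, "Paraquat", "Control", rnorm(40, 1), runif(40)),
    make_de(genes, "Cdk12i", "Control", rnorm(40), runif(40))
  )
  base <- apply_group_a_criteria(genes, de, summary)
  for (c_scale in c(1e-3, 7, 1e4)) {
    scaled <- dplyr::mutate(summary, mean_expr = mean_expr * c_scale)
    expect_equal(apply_group_a_criteria(genes, de, scaled)$selected,
                 base$selected)
  }
})

test_that("tightening any threshold only shrinks the selected groups", {
  sim <- gen_counts(powered_counts_cfg(seed = 2))
  base <- select_groups(sim$counts, sim$design)
  tighter <- list(
    selection_criteria(lfc_pq_ctrl_min = 2),
    selection_criteria(q_pq_ctrl_max = 0.01),
    selection_criteria(q_cpq_pq_max = 0.005, q_cdk_ctrl_max = 0.005),
    selection_criteria(lfc_cpq_pq_min = 1, lfc_cpq_cdk_min = 1)
  )
  for (crit in tighter) {
    sel <- select_groups(sim$counts, sim$design, criteria = crit)
    expect_true(all(sel$group_a %in% base$group_a))
    expect_true(all(sel$group_b %in% base$group_b))
  }
})

test_that("selection recovers planted groups when the data are informative", {
  for (s in 1:3) {
    sim <- gen_counts(powered_counts_cfg(seed = s))
    sel <- select_groups(sim$counts, sim$design)
    truth_a <- sim$truth$gene_id[sim$truth$role == "group_a"]
    truth_b <- sim$truth$gene_id[sim$truth$role == "group_b"]
    expect_gte(mean(truth_a %in% sel$group_a), 0.9)
    expect_gte(mean(sel$group_a %in% truth_a), 0.9)
    expect_gte(mean(truth_b %in% sel$group_b), 0.9)
    expect_gte(mean(sel$group_b %in% truth_b), 0.9)
    # every selected gene passes all of its group's criteria in the audit
    audit <- generics::tidy(sel)
    sel_a <- audit[audit$gene_id %in% sel$group_a, ]
    expect_true(all(
      sel_a$pass_min_reads & sel_a$pass_pattern_a & sel_a$pass_pq_induced &
        sel_a$pass_cdk_baseline & sel_a$pass_geo_mean
    ))
  }
})

test_that("a variation-free matrix selects nothing", {
  m <- matrix(50L, nrow = 20, ncol = 12)
  colnames(m) <- four_cond_design()$sample_id
  sel <- select_groups(toy_counts(m), four_cond_design())
  expect_equal(length(sel$group_a), 0)
  expect_equal(length(sel$group_b), 0)
  expect_true(all(is.na(generics::tidy(sel)$pattern)))
})

test_that("selection tidiers summarise gene counts and flags", {
  sim <- gen_counts(powered_counts_cfg(seed = 4))
  sel <- select_groups(sim$counts, sim$design)
  gl <- generics::glance(sel)
  expect_equal(gl$n_group_a, length(sel$group_a))
  expect_equal(gl$k, 8)
  expect_s3_class(ggplot2::autoplot(sel), "ggplot")
  expect_output(print(sel), "Group A")
})
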