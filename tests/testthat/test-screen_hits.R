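test_that("well normalization divides Fluc by Rluc and drops dead wells", {
  wells <- tibble::tibble(
    plate_id = "P1", well_id = c("A01", "A02", "A03"),
    gene_id = c("g1", "g2", "g3"), dsrna_id = c("d1", "d2", "d3"),
    fluc = c(1000, 0, 250), rluc = c(500, 100, 200)
  )
  norm <- normalize_wells(wells)
  expect_equal(norm$ratio, c(2, 0, 1.25))
  expect_equal(nrow(well_failures(norm)), 0)

  wells$rluc <- c(100, 200, 0)
  expect_message(norm <- normalize_wells(wells), "Dropped 1 well")
  expect_equal(nrow(norm), 2)
  fails <- well_failures(norm)
  expect_equal(fails$well_id, "A03")
})

test_that("robust Z-scores match the hand computation and centre at zero", {
  norm <- normalize_wells(toy_wells(c(1, 2, 3, 4, 100)))
  z <- compute_zscores(norm, z_scope = "screen")
  # median 3, MAD (x1.4826) 1.4826: the median well scores 0,
  # the outlier scores 97 / 1.4826
  expect_equal(z$z[z$ratio == 3], 0)
  expect_equal(z$z[z$ratio == 100], 97 / 1.4826, tolerance = 1e-12)
  expect_equal(median(z$z), 0, tolerance = 1e-9)
  expect_equal(mad(z$z), 1, tolerance = 1e-9)
})

test_that("Z-score scoping units are estimated per plate and exclude controls", {
  # two plates with different scales; a huge control well must not shift
  # the location/scale estimate of its plate
  w1 <- toy_wells(c(1, 2, 3, 4, 5), plate_id = "P1")
  w2 <- toy_wells(c(10, 20, 30, 40, 50), plate_id = "P2")
  ctrl <- toy_wells(1e6, plate_id = "P1")
  ctrl$well_id <- "B01"
  ctrl$gene_id <- "Keap1"
  ctrl$dsrna_id <- "ctrl1"
  ctrl$control_role <- "pathway-negative"
  z <- compute_zscores(normalize_wells(dplyr::bind_rows(w1, w2, ctrl)))
  plate1 <- z[z$plate_id == "P1" & z$control_role == "none", ]
  plate2 <- z[z$plate_id == "P2" & z$control_role == "none", ]
  expect_equal(median(plate1$z), 0, tolerance = 1e-9)
  expect_equal(median(plate2$z), 0, tolerance = 1e-9)
  # same relative layout: per-plate scaling makes the z patterns identical
  expect_equal(plate1$z, plate2$z, tolerance = 1e-9)
  # the control well is scored against the non-control estimate
  expect_gt(z$z[z$gene_id == "Keap1"], 100)
})

test_that("degenerate and underpowered scoping units are rejected", {
  expect_error(
    compute_zscores(normalize_wells(toy_wells(rep(2, 6))), "screen"),
    "Degenerate scale.*screen"
  )
  expect_error(
    compute_zscores(normalize_wells(toy_wells(c(1, 2))), "screen"),
    "at least 3"
  )
})

test_that("consensus gene calls reproduce the published worked examples", {
  z3 <- function(gene, z) {
    tibble::tibble(
      gene_id = gene, dsrna_id = paste0(gene, "_d", seq_along(z)), z = z
    )
  }
  cdk12 <- z3("Cdk12", c(-25.1, -28.27, -39.64))
  fray <- z3("fray", c(-3.4, -3.82, -0.19))

  # strict 3-of-3: Cdk12 qualifies, fray does not
  strict <- classify_genes(dplyr::bind_rows(cdk12, fray), min_consistent = 3)
  expect_equal(strict$call[strict$gene_id == "Cdk12"], "inducer")
  expect_equal(strict$call[strict$gene_id == "fray"], "none")

  # default 2-of-3 rule admits fray, matching its published inducer label
  default <- classify_genes(dplyr::bind_rows(cdk12, fray))
  expect_equal(sort(default$call), c("inducer", "inducer"))

  expect_equal(classify_genes(z3("flat", c(0, 0, 0)))$call, "none")

  # a discordant dsRNA at +threshold vetoes an otherwise-passing gene
  disc <- z3("disc", c(-2, 2, -2))
  expect_equal(classify_genes(disc)$call, "none")
  expect_equal(
    classify_genes(disc, opposite_sign_veto = FALSE)$call, "inducer"
  )

  expect_error(classify_genes(z3("bad", c(-2, NA, 1))), "Missing")
})

test_that("call audit fields record passing counts and per-dsRNA values", {
  z <- kinome_screen_zscores()
  calls <- classify_genes(dplyr::filter(z, control_role == "none"))
  fray <- calls[calls$gene_id == "fray", ]
  expect_equal(fray$n_passing, 2L)
  expect_equal(fray$z_values[[1]], c(-3.4, -3.82, -0.19))
  expect_equal(fray$rank_score, mean(c(-3.4, -3.82, -0.19)))
})

test_that("raising the Z threshold never creates new calls", {
  # The subset property holds for the pure consensus count; the
  # opposite-sign veto is deliberately excluded here because raising the
  # threshold can deactivate a veto (a discordant dsRNA at +2 blocks a
  # call at threshold 1.65 but not at 3), which is intended behaviour.
  set.seed(41)
  for (i in 1:20) {
    z <- tibble::tibble(
      gene_id = rep(paste0("g", 1:30), each = 3),
      dsrna_id = paste0("d", 1:90),
      z = rnorm(90, sd = 2)
    )
    lo <- classify_genes(z, z_threshold = 1.2, opposite_sign_veto = FALSE)
    hi <- classify_genes(z, z_threshold = 2.5, opposite_sign_veto = FALSE)
    newly_called <- hi$call != "none" & lo$call == "none"
    expect_false(any(newly_called))
  }
})

test_that("hits rank by mean Z with documented tie-breaking", {
  z <- kinome_screen_zscores()
  ranked <- rank_hits(classify_genes(dplyr::filter(z, control_role == "none")))
  expect_equal(ranked$gene_id[1], "Cdk12")
  # inducers first (ascending mean z), then suppressors (descending)
  expect_equal(
    ranked$call, rep(c("inducer", "suppressor"), c(5, 3))
  )
  expect_equal(
    ranked$gene_id[6:8][order(-ranked$rank_score[6:8])], ranked$gene_id[6:8]
  )

  single <- classify_genes(tibble::tibble(
    gene_id = "solo", dsrna_id = "d1", z = -2, control_role = "none"
  ), min_consistent = 1)
  expect_equal(rank_hits(single)$gene_id, "solo")

  tie <- classify_genes(tibble::tibble(
    gene_id = rep(c("zeta", "alpha"), each = 2),
    dsrna_id = paste0("d", 1:4),
    z = rep(-3, 4)
  ))
  expect_equal(rank_hits(tie)$gene_id, c("alpha", "zeta"))
})

test_that("gene-call tidiers and plots expose the call set", {
  calls <- classify_genes(
    dplyr::filter(kinome_screen_zscores(), control_role == "none")
  )
  td <- generics::tidy(calls)
  expect_equal(nrow(td), 24) # 8 genes x 3 dsRNAs
  gl <- generics::glance(calls)
  expect_equal(gl$n_inducers, 5L)
  expect_equal(gl$n_suppressors, 3L)
  expect_s3_class(ggplot2::autoplot(calls), "ggplot")
})
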