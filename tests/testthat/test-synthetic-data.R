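test_that("apportionment hits the published-proportion arithmetic exactly", {
  w <- c(varietal = 636323, CVT71 = 12886, CVT423 = 7914, CVT185 = 8070,
         discordant = 368)
  counts <- apportion(6656, w)
  expect_equal(sum(counts), 6656)
  expect_equal(unname(counts[["varietal"]]), 6363)
  # each count within one of the ideal share
  expect_true(all(abs(counts - 6656 * w / sum(w)) < 1))
})

test_that("cohort generation is deterministic and matches its truth table", {
  d1 <- tempfile(); d2 <- tempfile()
  cfg <- cohort_sim_config(n_sites = 300, seed = 41,
                           fail_rates = c(LOW_COVERAGE = 0.02))
  generate_cohort(cfg, dir = d1)
  generate_cohort(cfg, dir = d2)
  for (f in list.files(d1)) {
    expect_identical(tools::md5sum(file.path(d1, f))[[1]],
                     tools::md5sum(file.path(d2, f))[[1]],
                     label = paste("byte-identical", f))
  }

  sim <- generate_cohort(cfg)
  tr <- sim$truth
  planted <- tr[is.na(tr$intended_fail), ]
  expect_equal(nrow(planted), 300)
  lab_counts <- apportion(300, cfg$proportions)
  expect_equal(sum(planted$label == "VARIETAL"),
               unname(lab_counts[["varietal"]]))
  expect_equal(sum(planted$label == "EXCLUDED_DISCORDANT"),
               unname(lab_counts[["discordant"]]))
  for (cl in cfg$clones) {
    expect_equal(sum(planted$outlier_clone == cl, na.rm = TRUE),
                 unname(lab_counts[[cl]]))
  }
})

test_that("discordant plantings give three distinct genotype categories", {
  sim <- generate_cohort(cohort_sim_config(n_sites = 3000, seed = 6))
  disc <- which(sim$truth$label == "EXCLUDED_DISCORDANT")
  expect_gt(length(disc), 0)
  for (i in disc) {
    expect_equal(sort(sim$cohort$category[i, ]),
                 c("HET", "HOM_ALT", "HOM_REF"))
  }
})

test_that("a zero-fail-rate cohort passes the cascade and reproduces its labels", {
  sim <- generate_cohort(cohort_sim_config(n_sites = 400, seed = 9))
  res <- filter_cohort(sim$cohort, sim$mask)
  expect_equal(unname(res$summary[["records_rejected"]]), 0)
  labels <- classify_cohort(res$passing)
  expect_equal(labels$kind, sim$truth$label)
  expect_equal(labels$outlier_clone, sim$truth$outlier_clone)
  expect_equal(labels$reported_category[labels$kind != "EXCLUDED_DISCORDANT"],
               sim$truth$reported_category[sim$truth$label != "EXCLUDED_DISCORDANT"])
})

test_that("generated annotations sit inside the passing bands", {
  sim <- generate_cohort(cohort_sim_config(n_sites = 500, seed = 15))
  s <- sim$cohort$sites
  expect_true(all(s$fs <= 10))
  expect_true(all(s$qd >= 10))
  expect_true(all(abs(s$read_pos_rank_sum) <= 2, na.rm = TRUE))
  expect_true(all(sim$cohort$depth >= 15))
  # rank-sum statistic only at sites with a heterozygous carrier
  has_het <- rowSums(sim$cohort$category == "HET") > 0
  expect_equal(!is.na(s$read_pos_rank_sum), has_het)
})

test_that("panel and chimera generators are deterministic with config invariants", {
  p1 <- generate_panel(panel_sim_config(seed = 7))
  p2 <- generate_panel(panel_sim_config(seed = 7))
  expect_identical(p1$panel, p2$panel)
  expect_equal(nrow(p1$panel), 98)
  expect_equal(sort(unique(p1$truth$class)), LETTERS[1:7])
  expect_error(panel_sim_config(class_counts = c(A = 1, B = 97, C = 1)))

  c1 <- generate_chimera_assays(chimera_sim_config(seed = 3))
  c2 <- generate_chimera_assays(chimera_sim_config(seed = 3))
  expect_identical(c1$assays, c2$assays)
  expect_true(all(c1$assays$alt_fraction >= 0 & c1$assays$alt_fraction <= 1))
  # noiseless expectations per the mixing model
  c0 <- generate_chimera_assays(chimera_sim_config(
    layer_genotypes = list(LOC = c(1, 0)), noise_sd = 0, seed = 1))
  a <- c0$assays
  expect_equal(a$alt_fraction[a$tissue == "SKIN"], 0.25)
  expect_equal(a$alt_fraction[a$tissue == "FLESH"], 0)
  c22 <- generate_chimera_assays(chimera_sim_config(
    layer_genotypes = list(LOC = c(2, 2)), noise_sd = 0, seed = 1))
  expect_true(all(c22$assays$alt_fraction == 1))
})

test_that("generated gene models are structurally valid and planted ORFs translate", {
  set.seed(23)
  world <- simulate_annotated_genome(n_chrom = 1, chrom_len = 50000,
                                     genes_per_chrom = 5)
  expect_gte(length(world$genes), 4)
  for (g in world$genes) {
    tx <- g$transcripts[[1]]
    cds_pos <- clonotyper:::intervals_to_positions(tx$cds)
    expect_equal(length(cds_pos) %% 3, 0)
    cds_seq <- clonotyper:::strand_seq(world$genome, g$chrom, sort(cds_pos),
                                       g$strand)
    expect_equal(substr(cds_seq, 1, 3), "ATG")
    expect_equal(substr(cds_seq, nchar(cds_seq) - 2, nchar(cds_seq)), "TAA")
  }
})
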