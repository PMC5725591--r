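empty_mask <- region_mask()

clean_record <- function(depths = c(30, 30, 30), cats = c("HET", "HET", "HET"),
                         fs = 5, qd = 15, rprs = 0.5, pos = 1000) {
  gt_of <- c(HOM_REF = "0/0", HET = "0/1", HOM_ALT = "1/1")
  ad_of <- function(cat, d) switch(cat,
    HOM_REF = paste0(d, ",0"), HET = paste0(d %/% 2, ",", d - d %/% 2),
    HOM_ALT = paste0("0,", d))
  variant_cohort(
    data.frame(chrom = "chr1", pos = pos, ref = "A", alt = "T", qual = 1000,
               fs = fs, qd = qd, read_pos_rank_sum = rprs, sb = NA_real_,
               af = NA_real_, stringsAsFactors = FALSE),
    c("CVT71", "CVT423", "CVT185"),
    gt = matrix(gt_of[cats], 1), depth = matrix(as.integer(depths), 1),
    ad = matrix(mapply(ad_of, cats, depths), 1))
}

test_that("recalibrated rules fire individually and report all violations", {
  expect_true(evaluate_filters(clean_record(), empty_mask)$passed)

  d <- evaluate_filters(clean_record(depths = c(12, 30, 30)), empty_mask)
  expect_setequal(d$reasons, c("LOW_COVERAGE", "INADEQUATE_COVERAGE_ANY_CLONE"))

  rec <- clean_record(cats = c("HOM_ALT", "HOM_ALT", "HOM_ALT"), rprs = NA)
  rec$ad[1, 1] <- "3,27"
  expect_setequal(evaluate_filters(rec, empty_mask)$reasons, "DISCORDANT_HOM")
  rec$ad[1, 1] <- "2,28"
  expect_true(evaluate_filters(rec, empty_mask)$passed)
  # homozygous-reference mirror of the discordant-read rule
  rec2 <- clean_record(cats = c("HOM_REF", "HET", "HET"))
  rec2$ad[1, 1] <- "27,3"
  expect_setequal(evaluate_filters(rec2, empty_mask)$reasons, "DISCORDANT_HOM")

  expect_setequal(evaluate_filters(clean_record(fs = 10.5), empty_mask)$reasons,
                  "HIGH_FS")
  expect_setequal(evaluate_filters(clean_record(qd = 9.9), empty_mask)$reasons,
                  "LOW_QD")
  expect_setequal(evaluate_filters(clean_record(rprs = 2.4), empty_mask)$reasons,
                  "BAD_READ_POS")
  expect_setequal(evaluate_filters(clean_record(rprs = -2.4), empty_mask)$reasons,
                  "BAD_READ_POS")
  # one-sided option keeps the literal signed rule
  p1 <- filter_params(rprs_two_sided = FALSE)
  expect_true(evaluate_filters(clean_record(rprs = -2.4), empty_mask, p1)$passed)
  expect_false(evaluate_filters(clean_record(rprs = 2.4), empty_mask, p1)$passed)

  mask <- region_mask("chr1", 990, 1010)
  expect_setequal(evaluate_filters(clean_record(), mask)$reasons, "IN_REPEAT")

  # multiple simultaneous violations are all reported
  d2 <- evaluate_filters(clean_record(depths = c(10, 30, 30), fs = 20), mask)
  expect_setequal(d2$reasons, c("IN_REPEAT", "LOW_COVERAGE",
                                "INADEQUATE_COVERAGE_ANY_CLONE", "HIGH_FS"))
})

test_that("thresholds are strict inequalities at the boundary", {
  expect_true(evaluate_filters(clean_record(fs = 10), empty_mask)$passed)
  expect_true(evaluate_filters(clean_record(qd = 10), empty_mask)$passed)
  expect_true(evaluate_filters(clean_record(rprs = 2), empty_mask)$passed)
  expect_true(evaluate_filters(clean_record(depths = c(15, 15, 15)),
                               empty_mask)$passed)
  expect_false(evaluate_filters(clean_record(depths = c(14, 15, 15)),
                                empty_mask)$passed)
})

test_that("spurious-allele rule catches third alleles and MULTI genotypes", {
  rec <- clean_record()
  rec$sites$alt <- "T,G"
  rec$ad[1, 1] <- "10,10,3"
  expect_setequal(evaluate_filters(rec, empty_mask)$reasons, "SPURIOUS_ALLELE")
  rec$ad[1, 1] <- "10,10,2"   # third allele below detection threshold
  expect_true(evaluate_filters(rec, empty_mask)$passed)

  rec2 <- clean_record()
  rec2$sites$alt <- "T,G"
  rec2$gt[1, 1] <- "1/2"
  rec2 <- variant_cohort(rec2$sites, rec2$clones, rec2$gt, rec2$depth, rec2$ad)
  expect_true("SPURIOUS_ALLELE" %in% evaluate_filters(rec2, empty_mask)$reasons)
})

test_that("absent annotations never fail their rule; absent depths are an error", {
  rec <- clean_record(fs = NA, qd = NA, rprs = NA)
  expect_true(evaluate_filters(rec, empty_mask)$passed)
  rec$depth[1, 2] <- NA_integer_
  expect_error(evaluate_filters(rec, empty_mask), "CVT423")
})

test_that("initial hard-filter preset wires each of its rules", {
  p <- filter_params(preset = "initial_hard_filter")
  base <- clean_record()
  expect_true(evaluate_filters(base, empty_mask, p)$passed)

  r <- clean_record(); r$sites$qual <- 99
  expect_setequal(evaluate_filters(r, empty_mask, p)$reasons, "QUAL_LOW")
  r <- clean_record(depths = c(14, 30, 30))
  expect_setequal(evaluate_filters(r, empty_mask, p)$reasons, "COVERAGE_BOUNDS")
  r <- clean_record(depths = c(91, 30, 30))
  expect_setequal(evaluate_filters(r, empty_mask, p)$reasons, "COVERAGE_BOUNDS")
  r <- clean_record(); r$sites$sb <- 0.5
  expect_setequal(evaluate_filters(r, empty_mask, p)$reasons, "STRAND_BIAS")
  r <- clean_record(fs = 0.5)
  expect_setequal(evaluate_filters(r, empty_mask, p)$reasons, "HIGH_FS")
  r <- clean_record(rprs = -2.5)
  expect_setequal(evaluate_filters(r, empty_mask, p)$reasons, "BAD_READ_POS")
  r <- clean_record(rprs = 2.6)
  expect_setequal(evaluate_filters(r, empty_mask, p)$reasons, "BAD_READ_POS")
  r <- clean_record(); r$sites$af <- 0.1
  expect_setequal(evaluate_filters(r, empty_mask, p)$reasons, "LOW_AF")
})

test_that("cohort filtering is order-independent, idempotent and truth-exact", {
  sim <- generate_cohort(cohort_sim_config(
    n_sites = 400, seed = 21,
    fail_rates = c(SPURIOUS_ALLELE = 0.025, LOW_COVERAGE = 0.02)))
  res <- filter_cohort(sim$cohort, sim$mask)
  expect_equal(unname(res$summary[["SPURIOUS_ALLELE"]]), 10)
  expect_equal(unname(res$summary[["LOW_COVERAGE"]]), 8)
  expect_equal(unname(res$summary[["records_rejected"]]), 18)

  # permutation of record order permutes decisions identically
  set.seed(1)
  perm <- sample(nrow(sim$cohort$sites))
  res_p <- filter_cohort(clonotyper:::cohort_subset(sim$cohort, perm), sim$mask)
  expect_identical(res_p$reason_matrix, res$reason_matrix[perm, ])

  # filtering the passing set again rejects nothing
  res2 <- filter_cohort(res$passing, sim$mask)
  expect_equal(unname(res2$summary[["records_rejected"]]), 0)

  # zero-fail-rate cohorts pass in full
  sim0 <- generate_cohort(cohort_sim_config(n_sites = 300, seed = 22))
  res0 <- filter_cohort(sim0$cohort, sim0$mask)
  expect_equal(nrow(res0$rejected_table), 0)
})

test_that("an empty cohort filters to empty outputs and zero counts", {
  sim <- generate_cohort(cohort_sim_config(n_sites = 10, seed = 1))
  empty <- clonotyper:::cohort_subset(sim$cohort, integer(0))
  res <- filter_cohort(empty, sim$mask)
  expect_equal(length(res$passing), 0L)
  expect_equal(nrow(res$rejected_table), 0)
  expect_true(all(res$summary == 0))
})
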