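test_that("GT fields map to genotype categories, including the full diploid index table", {
  expect_equal(gt_category(c("0/0", "0/1", "1/0", "1/1", "./.", "0|1", ".")),
               c("HOM_REF", "HET", "HET", "HOM_ALT", "MISSING", "HET", "MISSING"))

  # brute-force category table over all GT values 0/0 .. 2/2 for a site
  # with two ALT alleles: any index > 1 must give MULTI
  oracle <- function(a, b) {
    if (all(c(a, b) == 0)) "HOM_REF"
    else if (any(c(a, b) > 1)) "MULTI"
    else if (a == b) "HOM_ALT"
    else "HET"
  }
  for (a in 0:2) for (b in 0:2) {
    expect_equal(gt_category(paste(a, b, sep = "/")), oracle(a, b),
                 label = sprintf("GT %d/%d", a, b))
  }
})

test_that("multi-sample VCF parsing maps fields and flags absent annotations", {
  path <- write_mini_vcf(c(
    vcf_line(pos = 100, gts = c("0/1:12,11:23", "0/1:15,15:30", "0/0:28,0:28")),
    vcf_line(pos = 200, info = "QD=15",
             gts = c("./.:0,0:0", "1/1:0,30:30", "1/1:1,29:30")),
    vcf_line(pos = 300, alt = "T,G", gts = c("1/2:5,9,9:23", "0/1:15,15:30",
                                             "0/1:14,14:28"))
  ))
  cohort <- read_vcf_multisample(path, c("CVT71", "CVT423", "CVT185"))
  expect_equal(nrow(cohort$sites), 3)
  rec <- variant_record(cohort, 1)
  expect_equal(rec$calls$CVT71$category, "HET")
  expect_equal(rec$calls$CVT71$allele_depths, c(A = 12, T = 11))
  expect_equal(rec$calls$CVT71$depth, 23L)
  expect_equal(variant_record(cohort, 2)$calls$CVT71$category, "MISSING")
  expect_equal(variant_record(cohort, 3)$calls$CVT71$category, "MULTI")
  expect_true(is.na(cohort$sites$fs[2]))      # absent INFO key -> NA
  expect_equal(cohort$sites$qd[2], 15)

  expect_error(read_vcf_multisample(path, c("A", "B", "C")),
               "do not match")
})

test_that("VCF writing round-trips to field-identical records", {
  sim <- generate_cohort(cohort_sim_config(n_sites = 80, seed = 5,
                                           fail_rates = c(SPURIOUS_ALLELE = 0.05)))
  p1 <- tempfile(fileext = ".vcf")
  write_vcf(sim$cohort, p1)
  back <- read_vcf_multisample(p1, sim$config$clones)
  expect_equal(back$sites, sim$cohort$sites)
  expect_identical(back$gt, sim$cohort$gt)
  expect_identical(back$ad, sim$cohort$ad)
  expect_identical(back$depth, sim$cohort$depth)
})

test_that("BED masks follow 0-based half-open convention and merge overlaps", {
  path <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t0\t10", "chr1\t5\t20"), path)
  mask <- read_region_mask(path)
  expect_true(in_mask(mask, "chr1", 5))
  expect_true(in_mask(mask, "chr1", 1))
  expect_true(in_mask(mask, "chr1", 20))
  expect_false(in_mask(mask, "chr1", 21))
  # merged to a single (0, 20) interval
  expect_equal(nrow(clonotyper:::mask_as_bed(mask)), 1)
  expect_equal(clonotyper:::mask_as_bed(mask)$end, 20)

  writeLines("chr1\t10\t10", path)
  expect_error(read_region_mask(path), "start >= end")
})

test_that("mask membership boundaries hold on random intervals", {
  set.seed(31)
  for (rep in 1:40) {
    s <- sample(0:5000, 1)
    e <- s + sample(1:300, 1)
    mask <- region_mask("chrZ", s, e)
    expect_true(all(in_mask(mask, "chrZ", (s + 1):e)))
    expect_false(in_mask(mask, "chrZ", e + 1))
    if (s >= 1) expect_false(in_mask(mask, "chrZ", s))
  }
})

test_that("GFF3 gene models preserve coordinates, UTRs, introns and strand", {
  path <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t101\t400\t.\t+\t.\tID=g1",
    "chr1\tsrc\tmRNA\t101\t400\t.\t+\t.\tID=t1;Parent=g1",
    "chr1\tsrc\texon\t101\t400\t.\t+\t.\tParent=t1",
    "chr1\tsrc\tCDS\t151\t351\t.\t+\t.\tParent=t1",
    "chr1\tsrc\tgene\t501\t900\t.\t-\t.\tID=g2",
    "chr1\tsrc\tmRNA\t501\t900\t.\t-\t.\tID=t2;Parent=g2",
    "chr1\tsrc\texon\t501\t600\t.\t-\t.\tParent=t2",
    "chr1\tsrc\texon\t701\t900\t.\t-\t.\tParent=t2"
  ), path)
  genes <- read_gff3_genes(path)
  g1 <- genes$g1
  utr <- clonotyper:::transcript_utrs(g1$transcripts[[1]], "+")
  expect_equal(range(utr$utr5), c(101, 150))   # set-subtraction oracle
  expect_equal(range(utr$utr3), c(352, 400))
  g2 <- genes$g2
  expect_equal(clonotyper:::transcript_tss(g2$transcripts[[1]], "-"), 900)
  introns <- clonotyper:::transcript_introns(g2$transcripts[[1]])
  expect_equal(introns, iv(601L, 700L))        # gap-computation oracle

  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t1\t100\t.\t+\t.\tID=g1",
    "chr1\tsrc\tCDS\t10\t90\t.\t+\t.\tParent=orphan"
  ), path)
  expect_error(read_gff3_genes(path), "without an mRNA parent")
})

test_that("gene model invariants are enforced", {
  expect_error(make_gene(exons = iv(c(1, 50), c(60, 100)), cds = iv(10, 90)),
               "overlapping exons")
  expect_error(make_gene(exons = iv(101, 200), cds = iv(90, 150)),
               "CDS outside exons")
  expect_warning(make_gene(exons = iv(101, 200), cds = iv(110, 120)),
                 "not divisible by 3")
})

test_that("per-sample cohorts merge on (chrom, pos, ref) with missing fills", {
  mk <- function(clone, pos, gt, ad, dp, alt = "T") {
    variant_cohort(
      data.frame(chrom = "chr1", pos = pos, ref = "A", alt = alt,
                 qual = 900, fs = 1, qd = 20, read_pos_rank_sum = NA_real_,
                 sb = NA_real_, af = NA_real_, stringsAsFactors = FALSE),
      clone, gt = matrix(gt), depth = matrix(dp), ad = matrix(ad))
  }
  merged <- merge_cohorts(list(
    c1 = mk("c1", 100, "0/1", "10,10", 20),
    c2 = mk("c2", 100, "1/1", "0,25", 25, alt = "T"),
    c3 = mk("c3", 200, "0/1", "12,13", 25, alt = "G")
  ))
  expect_equal(nrow(merged$sites), 2)
  expect_equal(merged$gt[1, ], c("0/1", "1/1", "./."))
  expect_equal(merged$category[2, 3], "HET")
  expect_equal(merged$depth[1, 3], 0L)
  # ALT union keeps per-clone indices consistent
  expect_equal(merged$sites$alt, c("T", "G"))
})
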