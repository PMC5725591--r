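test_that("impact mapping is total and matches the category table", {
  cats <- c("START_LOST", "STOP_GAINED", "STOP_LOST", "SPLICE_SITE_ACCEPTOR",
            "SPLICE_SITE_DONOR", "NON_SYNONYMOUS_START", "SYNONYMOUS_CODING",
            "SYNONYMOUS_STOP", "START_GAINED", "NON_SYNONYMOUS_CODING",
            "DOWNSTREAM", "INTRON", "UPSTREAM", "UTR_3_PRIME", "UTR_5_PRIME")
  expect_equal(effect_impact(cats),
               c(rep("HIGH", 5), rep("LOW", 4), "MODERATE", rep("MODIFIER", 5)))
  expect_error(effect_impact("FRAMESHIFT"), "unknown effect category")
})

test_that("coding, UTR and flanking placements classify as expected", {
  w <- planted_orf_genome()
  g <- w$gene; genome <- w$genome

  # start codon disruption (ATG at 4151-4153)
  ref <- substring(genome[["chr1"]], 4152, 4152)  # "T"
  e <- classify_effects("chr1", 4152, ref, "C", g, genome)
  expect_equal(e$category, "START_LOST")
  expect_equal(e$impact, "HIGH")
  # configurable alternative-start set turns it into NON_SYNONYMOUS_START
  e2 <- classify_effects("chr1", 4152, ref, "C", g, genome,
                         alternative_starts = "ACG")
  expect_equal(e2$category, "NON_SYNONYMOUS_START")

  # stop codon TAA at 4349-4351: T>C loses the stop, A>G keeps a TAG stop
  e <- classify_effects("chr1", 4349, "T", "C", g, genome)
  expect_equal(e$category, "STOP_LOST")
  e <- classify_effects("chr1", 4351, "A", "G", g, genome)
  expect_equal(e$category, "SYNONYMOUS_STOP")

  # premature stop: plant in-frame TGG (codon 18) and mutate to TGA
  genome2 <- plant_seq(genome, "chr1", 4202, "TGG")
  e <- classify_effects("chr1", 4204, "G", "A", g, genome2)
  expect_equal(e$category, "STOP_GAINED")
  expect_equal(e$impact, "HIGH")

  # third-position silent change: GCT -> GCC (codon 19)
  genome3 <- plant_seq(genome, "chr1", 4205, "GCT")
  e <- classify_effects("chr1", 4207, "T", "C", g, genome3)
  expect_equal(e$category, "SYNONYMOUS_CODING")
  expect_equal(e$impact, "LOW")

  # UTRs and flanks
  base <- function(p) substring(genome[["chr1"]], p, p)
  mut <- function(p) setdiff(c("A", "C", "G", "T"), base(p))[1]
  expect_equal(classify_effects("chr1", 4120, base(4120), mut(4120),
                                g, genome)$category[1], "UTR_5_PRIME")
  expect_equal(classify_effects("chr1", 4380, base(4380), mut(4380),
                                g, genome)$category, "UTR_3_PRIME")
  up <- classify_effects("chr1", 101, base(101), mut(101), g, genome)
  expect_equal(up$category, "UPSTREAM")   # 4,000 nt 5' of the TSS
  expect_equal(up$impact, "MODIFIER")
  expect_equal(classify_effects("chr1", 8400, base(8400), mut(8400),
                                g, genome)$category, "DOWNSTREAM")
  # outside the 5 kb flank: no calls
  expect_equal(nrow(classify_effects("chr1", 9500, base(9500), mut(9500),
                                     g, genome)), 0)
})

test_that("splice windows span the first and last two intronic bases", {
  w <- planted_orf_genome()
  genome <- w$genome
  g <- make_gene(exons = iv(c(101, 301), c(200, 400)), cds = iv(c(151, 301), c(200, 397)))
  base <- function(p) substring(genome[["chr1"]], p, p)
  mut <- function(p) setdiff(c("A", "C", "G", "T"), base(p))[1]
  for (p in c(201, 202)) {
    expect_equal(classify_effects("chr1", p, base(p), mut(p), g, genome)$category,
                 "SPLICE_SITE_DONOR")
  }
  for (p in c(299, 300)) {
    expect_equal(classify_effects("chr1", p, base(p), mut(p), g, genome)$category,
                 "SPLICE_SITE_ACCEPTOR")
  }
  expect_equal(classify_effects("chr1", 250, base(250), mut(250), g, genome)$category,
               "INTRON")
  # minus strand flips donor and acceptor
  gm <- make_gene(strand = "-", exons = iv(c(101, 301), c(200, 400)),
                  cds = iv(c(103, 301), c(200, 400)))
  expect_equal(classify_effects("chr1", 300, base(300), mut(300), gm, genome)$category,
               "SPLICE_SITE_DONOR")
  expect_equal(classify_effects("chr1", 201, base(201), mut(201), gm, genome)$category,
               "SPLICE_SITE_ACCEPTOR")
})

test_that("a 5'UTR change creating an ATG adds START_GAINED", {
  w <- planted_orf_genome()
  genome <- plant_seq(w$genome, "chr1", 4130, "AGG")  # A?G -> ATG via ?>T
  e <- classify_effects("chr1", 4131, "G", "T", w$gene, genome)
  expect_setequal(e$category, c("UTR_5_PRIME", "START_GAINED"))
  # the same change without the surrounding A..G context stays plain UTR
  genome2 <- plant_seq(w$genome, "chr1", 4130, "CGC")
  e2 <- classify_effects("chr1", 4131, "G", "T", w$gene, genome2)
  expect_equal(e2$category, "UTR_5_PRIME")
})

test_that("classifier agrees with the transcript-rebuild oracle on random pairs", {
  set.seed(401)
  world <- simulate_annotated_genome(n_chrom = 1, chrom_len = 60000,
                                     genes_per_chrom = 6)
  genome <- world$genome
  n_checked <- 0
  for (rep in 1:250) {
    g <- world$genes[[sample(length(world$genes), 1)]]
    sp <- clonotyper:::gene_span(g)
    pos <- sample(max(1, sp[1] - 5500):(sp[2] + 5500), 1)
    ref <- toupper(substring(genome[[g$chrom]], pos, pos))
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    a <- classify_effects(g$chrom, pos, ref, alt, g, genome)
    b <- classify_effects_reference(g$chrom, pos, ref, alt, g, genome)
    expect_equal(sort(paste(a$transcript_id, a$category)),
                 sort(paste(b$transcript_id, b$category)),
                 label = sprintf("%s pos %d %s>%s", g$gene_id, pos, ref, alt))
    n_checked <- n_checked + 1
  }
  expect_equal(n_checked, 250)
})

test_that("categories are invariant under genome reverse-complementation", {
  set.seed(77)
  world <- simulate_annotated_genome(n_chrom = 1, chrom_len = 40000,
                                     genes_per_chrom = 4)
  genome <- world$genome
  L <- nchar(genome[["chr1"]])
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(genome[["chr1"]])))
  genome_rc <- c(chr1 = rc)
  flip <- function(p) L - p + 1L
  comp <- function(b) chartr("ACGT", "TGCA", b)
  for (g in world$genes) {
    tx <- g$transcripts[[1]]
    g_rc <- make_gene(gene_id = g$gene_id, strand = if (g$strand == "+") "-" else "+",
                      exons = iv(rev(flip(tx$exons$end)), rev(flip(tx$exons$start))),
                      cds = iv(rev(flip(tx$cds$end)), rev(flip(tx$cds$start))))
    sp <- clonotyper:::gene_span(g)
    positions <- sample(max(1, sp[1] - 3000):(sp[2] + 3000), 40)
    for (pos in positions) {
      ref <- toupper(substring(genome[["chr1"]], pos, pos))
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
      a <- classify_effects("chr1", pos, ref, alt, g, genome)
      b <- classify_effects("chr1", flip(pos), comp(ref), comp(alt), g_rc,
                            genome_rc)
      expect_equal(sort(a$category), sort(b$category),
                   label = sprintf("%s pos %d", g$gene_id, pos))
    }
  }
})

test_that("effect summaries reproduce the published category totals", {
  calls <- effect_calls_from_counts()
  es <- summarize_effects(calls$effects, calls$labels)
  m <- es$counts
  high <- rownames(m)[effect_impact(rownames(m)) == "HIGH"]
  expect_equal(sum(m[high, "TOTAL"]), 498)
  expect_equal(unname(m["UPSTREAM", ]), c(5196L, 27463L, 32659L))
  expect_equal(unname(m["SYNONYMOUS_CODING", "TOTAL"]), 15103L)
  expect_true(all(m[, "TOTAL"] == m[, "HET"] + m[, "HOM_ALT"]))

  empty <- summarize_effects(calls$effects[0, ], character())
  expect_true(all(empty$counts == 0))

  expect_error(summarize_effects(calls$effects, calls$labels[-1]),
               "no genotype label")
})

test_that("summaries count one per (site, category) pair; gene rollups dedup", {
  eff <- data.frame(site = c("s1", "s1", "s1", "s2"),
                    gene_id = c("g1", "g1", "g2", "g2"),
                    category = c("STOP_GAINED", "STOP_GAINED", "UPSTREAM",
                                 "UPSTREAM"),
                    stringsAsFactors = FALSE)
  eff$impact <- effect_impact(eff$category)
  es <- summarize_effects(eff, c(s1 = "HET", s2 = "HOM_ALT"))
  expect_equal(unname(es$counts["STOP_GAINED", "TOTAL"]), 1L)
  expect_equal(unname(es$counts["UPSTREAM", "TOTAL"]), 2L)
  expect_equal(high_impact_genes(eff), "g1")
  eff2 <- rbind(eff, data.frame(site = "s3", gene_id = "g3",
                                category = "START_LOST", impact = "HIGH"))
  expect_equal(high_impact_genes(eff2), c("g1", "g3"))
})
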