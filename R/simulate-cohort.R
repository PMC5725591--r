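#' Cohort simulation configuration
#'
#' Defaults reproduce the published study conditions for a three-clone
#' resequencing design: site-class proportions and per-class genotype
#' mixes from the three-clone concordance table (varietal sites dominate
#' at 636,323/665,561, clone-specific sites split 12,886 : 7,914 : 8,070
#' across clones, 368 fully discordant), and ~30-fold mean per-clone
#' coverage.
#'
#' @param n_sites number of concordance-analysis sites to plant.
#' @param proportions named weights over `varietal`, one entry per clone
#'   (clone-specific outlier counts) and `discordant`.
#' @param varietal_mix named weights over `HOM_ALT`, `HET` for varietal
#'   sites.
#' @param clone_mix matrix of weights, rows `HOM_REF`, `HOM_ALT`, `HET`,
#'   one column per clone: the outlier-genotype mix of clone-specific
#'   sites.
#' @param fail_rates named fractions of `n_sites` planted as extra
#'   records violating exactly one filter rule; names among `IN_REPEAT`,
#'   `SPURIOUS_ALLELE`, `LOW_COVERAGE`, `HIGH_FS`, `LOW_QD`,
#'   `BAD_READ_POS`, `DISCORDANT_HOM`.
#' @param clones clone (sample) names.
#' @param depth_mean,depth_size negative-binomial depth model per clone
#'   (mean 30, size 10), left-truncated at the intended coverage floor.
#' @param seed RNG seed (single global seed per generator call).
#' @param n_chrom,chrom_len,genes_per_chrom,repeat_fraction miniature
#'   genome parameters (see [simulate_annotated_genome]).
#' @return object of class `cohort_sim_config`.
#' @export
cohort_sim_config <- function(n_sites = 5000,
                              proportions = c(varietal = 636323,
                                              CVT71 = 12886, CVT423 = 7914,
                                              CVT185 = 8070, discordant = 368),
                              varietal_mix = c(HOM_ALT = 524899, HET = 111424),
                              clone_mix = cbind(CVT71 = c(784, 3606, 8496),
                                                CVT423 = c(403, 3113, 4398),
                                                CVT185 = c(400, 3245, 4425)),
                              fail_rates = numeric(),
                              clones = c("CVT71", "CVT423", "CVT185"),
                              depth_mean = 30, depth_size = 10, seed = 1,
                              n_chrom = 2, chrom_len = 250000,
                              genes_per_chrom = 20, repeat_fraction = 0.10) {
  rownames(clone_mix) <- c("HOM_REF", "HOM_ALT", "HET")
  stopifnot(n_sites >= 0, all(proportions >= 0),
            setequal(names(proportions), c("varietal", clones, "discordant")),
            identical(colnames(clone_mix), clones))
  if (length(fail_rates)) {
    stopifnot(all(fail_rates >= 0 & fail_rates <= 1),
              all(names(fail_rates) %in%
                    c("IN_REPEAT", "SPURIOUS_ALLELE", "LOW_COVERAGE",
                      "HIGH_FS", "LOW_QD", "BAD_READ_POS", "DISCORDANT_HOM")))
  }
  structure(list(n_sites = n_sites, proportions = proportions,
                 varietal_mix = varietal_mix, clone_mix = clone_mix,
                 fail_rates = fail_rates, clones = clones,
                 depth_mean = depth_mean, depth_size = depth_size,
                 seed = seed, n_chrom = n_chrom, chrom_len = chrom_len,
                 genes_per_chrom = genes_per_chrom,
                 repeat_fraction = repeat_fraction),
            class = "cohort_sim_config")
}

other_bases <- c(A = "T", C = "A", G = "A", T = "C")

#' Generate a synthetic multi-clone SNV cohort with planted truth
#'
#' Builds a miniature annotated genome, then plants `n_sites` variant
#' sites whose concordance labels follow the configured proportions:
#' varietal sites share one genotype across all clones, clone-specific
#' sites give exactly one clone a deviating genotype, discordant sites
#' give all three clones different genotype categories. Annotations
#' (QUAL, FS, QD, ReadPosRankSum) and depths are drawn so that every
#' planted site passes the recalibrated filter cascade; `fail_rates`
#' plants additional records each violating exactly one named rule.
#' ReadPosRankSum is emitted only at sites with a heterozygous carrier,
#' mirroring caller behaviour for rank-sum statistics.
#'
#' @param config a [cohort_sim_config].
#' @param dir optional output directory; when given, writes `genome.fa`,
#'   `genes.gff3`, `repeats.bed`, `cohort.vcf` and `truth.csv`.
#' @return list with `cohort` (a `variant_cohort`), `truth` (data frame:
#'   chrom, pos, ref, alt, label, outlier_clone, reported_category,
#'   intended_fail), `genome`, `genes`, `mask`, and `paths` when `dir`
#'   was given. Identical config and seed give byte-identical files.
#' @export
generate_cohort <- function(config = cohort_sim_config(), dir = NULL) {
  stopifnot(inherits(config, "cohort_sim_config"))
  set.seed(config$seed)
  world <- simulate_annotated_genome(config$n_chrom, config$chrom_len,
                                     config$genes_per_chrom,
                                     config$repeat_fraction)
  genome <- world$genome; mask <- world$mask
  clones <- config$clones
  k <- length(clones)

  n_fail <- if (length(config$fail_rates)) {
    stats::setNames(as.integer(round(config$fail_rates * config$n_sites)),
                    names(config$fail_rates))
  } else {
    integer(0)
  }
  n_total <- config$n_sites + sum(n_fail)

  # positions: clean sites off-mask, IN_REPEAT plantings on-mask
  chrom_names <- names(genome)
  chrom_len <- nchar(genome[[1]])
  masked <- mask_as_bed(mask)
  masked_pos <- do.call(rbind, lapply(chrom_names, function(ch) {
    rows <- masked[masked$chrom == ch, , drop = FALSE]
    if (!nrow(rows)) return(NULL)
    data.frame(chrom = ch,
               pos = unlist(mapply(seq.int, rows$start + 1L, rows$end,
                                   SIMPLIFY = FALSE)))
  }))
  n_repeat <- if ("IN_REPEAT" %in% names(n_fail)) n_fail[["IN_REPEAT"]] else 0L
  n_clean <- n_total - n_repeat
  per_chrom <- apportion(n_clean, stats::setNames(rep(1, length(chrom_names)),
                                                  chrom_names))
  clean_pos <- do.call(rbind, lapply(chrom_names, function(ch) {
    bad <- masked_pos$pos[masked_pos$chrom == ch]
    pool <- setdiff(seq_len(chrom_len), bad)
    data.frame(chrom = ch, pos = sort(sample(pool, per_chrom[[ch]])))
  }))
  rep_pos <- if (n_repeat > 0) {
    idx <- sample(nrow(masked_pos), n_repeat)
    masked_pos[idx, , drop = FALSE]
  } else {
    NULL
  }

  # labels for the concordance sites
  lab_counts <- apportion(config$n_sites, config$proportions)
  labels <- rep(names(lab_counts), lab_counts)
  var_counts <- apportion(lab_counts[["varietal"]], config$varietal_mix)
  var_cats <- rep(names(var_counts), var_counts)
  clone_cats <- lapply(clones, function(cl) {
    cc <- apportion(lab_counts[[cl]], stats::setNames(config$clone_mix[, cl],
                                                      rownames(config$clone_mix)))
    rep(names(cc), cc)
  })
  names(clone_cats) <- clones

  # assemble per-site genotype category matrix + metadata
  cat_m <- matrix("HOM_REF", n_total, k, dimnames = list(NULL, clones))
  label <- character(n_total); outlier <- rep(NA_character_, n_total)
  reported <- rep(NA_character_, n_total)
  intended_fail <- rep(NA_character_, n_total)

  i <- 0L
  for (cat in var_cats) {
    i <- i + 1L
    cat_m[i, ] <- cat; label[i] <- "VARIETAL"; reported[i] <- cat
  }
  shared_for_outlier <- function(out_cat) {
    # genotype shared by the two concordant clones, distinct from the outlier
    switch(out_cat, HOM_REF = "HET", HOM_ALT = "HET", HET = "HOM_ALT")
  }
  for (cl in clones) {
    for (cat in clone_cats[[cl]]) {
      i <- i + 1L
      cat_m[i, ] <- shared_for_outlier(cat)
      cat_m[i, cl] <- cat
      label[i] <- "CLONE_SPECIFIC"; outlier[i] <- cl; reported[i] <- cat
    }
  }
  for (d in seq_len(lab_counts[["discordant"]])) {
    i <- i + 1L
    cat_m[i, ] <- sample(c("HOM_REF", "HET", "HOM_ALT"))
    label[i] <- "EXCLUDED_DISCORDANT"
  }
  fail_order <- setdiff(names(n_fail), "IN_REPEAT")
  for (reason in c(fail_order, if (n_repeat > 0) "IN_REPEAT")) {
    base_cat <- if (reason == "DISCORDANT_HOM") "HOM_ALT" else "HET"
    for (f in seq_len(n_fail[[reason]])) {
      i <- i + 1L
      cat_m[i, ] <- base_cat
      label[i] <- "VARIETAL"; reported[i] <- base_cat
      intended_fail[i] <- reason
    }
  }

  # positions: clean first (concordance sites + off-mask failures), then
  # the IN_REPEAT block
  pos_tab <- rbind(clean_pos, rep_pos)
  chrom <- pos_tab$chrom; pos <- pos_tab$pos
  ref <- toupper(mapply(function(ch, p) genome_base(genome, ch, p), chrom, pos))
  alt <- unname(other_bases[ref])

  # depths and allele depths per clone
  depth <- matrix(pmax(15L, stats::rnbinom(n_total * k, mu = config$depth_mean,
                                           size = config$depth_size)),
                  n_total, k)
  alt_reads <- matrix(0L, n_total, k)
  het <- cat_m == "HET"
  alt_reads[het] <- pmin(depth[het] - 1L,
                         pmax(1L, stats::rbinom(sum(het), depth[het], 0.5)))
  hom_alt <- cat_m == "HOM_ALT"
  alt_reads[hom_alt] <- depth[hom_alt] -
    pmin(2L, stats::rbinom(sum(hom_alt), depth[hom_alt], 0.01))
  hom_ref <- cat_m == "HOM_REF"
  alt_reads[hom_ref] <- pmin(2L, stats::rbinom(sum(hom_ref), depth[hom_ref], 0.01))
  gt_of <- c(HOM_REF = "0/0", HET = "0/1", HOM_ALT = "1/1")
  gt <- matrix(gt_of[cat_m], n_total, k)
  ad <- matrix(paste0(depth - alt_reads, ",", alt_reads), n_total, k)

  # clean annotations within the passing bands
  qual <- round(stats::runif(n_total, 500, 3000), 2)
  fs <- round(stats::runif(n_total, 0, 8), 3)
  qd <- round(stats::runif(n_total, 11, 34), 2)
  has_het <- rowSums(het) > 0
  rprs <- ifelse(has_het, round(stats::runif(n_total, -1.8, 1.8), 3), NA_real_)

  # per-reason violations, each touching exactly one rule
  for (reason in names(n_fail)) {
    rows <- which(intended_fail == reason)
    for (r in rows) {
      j <- sample.int(k, 1)
      switch(reason,
        IN_REPEAT = NULL,  # placed on masked positions already
        SPURIOUS_ALLELE = {
          alt2 <- setdiff(c("A", "C", "G", "T"), c(ref[r], alt[r]))[1]
          alt[r] <- paste(alt[r], alt2, sep = ",")
          gt[r, j] <- "1/2"
          d <- depth[r, j]
          third <- max(3L, d %/% 3L)
          ad[r, j] <- paste(d - 2L * third, third, third, sep = ",")
        },
        LOW_COVERAGE = {
          depth[r, j] <- 10L
          a <- min(5L, alt_reads[r, j])
          ad[r, j] <- paste0(10L - a, ",", a)
        },
        HIGH_FS = fs[r] <- round(stats::runif(1, 12, 30), 3),
        LOW_QD = qd[r] <- round(stats::runif(1, 1, 7), 2),
        BAD_READ_POS = rprs[r] <- round(stats::runif(1, 2.5, 5), 3),
        DISCORDANT_HOM = {
          d <- depth[r, j]
          ad[r, j] <- paste0(5L, ",", d - 5L)
        })
    }
  }

  sites <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                      qual = qual, fs = fs, qd = qd,
                      read_pos_rank_sum = rprs, sb = NA_real_, af = NA_real_,
                      stringsAsFactors = FALSE)
  ord <- order(sites$chrom, sites$pos)
  sites <- sites[ord, , drop = FALSE]
  rownames(sites) <- NULL
  cohort <- variant_cohort(sites, clones,
                           gt = gt[ord, , drop = FALSE],
                           depth = depth[ord, , drop = FALSE],
                           ad = ad[ord, , drop = FALSE])
  truth <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                      label = label, outlier_clone = outlier,
                      reported_category = reported,
                      intended_fail = intended_fail,
                      stringsAsFactors = FALSE)[ord, , drop = FALSE]
  rownames(truth) <- NULL

  out <- list(cohort = cohort, truth = truth, genome = genome,
              genes = world$genes, mask = mask, config = config)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      genome = file.path(dir, "genome.fa"),
      genes = file.path(dir, "genes.gff3"),
      repeats = file.path(dir, "repeats.bed"),
      vcf = file.path(dir, "cohort.vcf"),
      truth = file.path(dir, "truth.csv")
    )
    write_genome_fasta(genome, paths$genome)
    write_gff3_genes(world$genes, paths$genes)
    write_region_mask(mask, paths$repeats)
    write_vcf(cohort, paths$vcf,
              contigs = stats::setNames(nchar(genome), names(genome)))
    utils::write.csv(truth, paths$truth, row.names = FALSE)
    out$paths <- paths
  }
  out
}
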