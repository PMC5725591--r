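#' Read a multi-sample VCF of clone genotypes
#'
#' Parses a VCF 4.1/4.2 file with one sample per clone into a
#' `variant_cohort`: a column-oriented container holding per-site fields
#' (CHROM, POS, REF, ALT, QUAL and the INFO annotations FS, QD,
#' ReadPosRankSum, SB, AF) and per-clone matrices (GT string, derived
#' genotype category, DP, AD). Genotype categories are derived from GT only;
#' allele depths are used downstream by the filter rules. INFO annotations
#' absent at a site are stored as `NA` ("absent").
#'
#' @param path VCF file path (plain text or bgzipped).
#' @param clone_names expected sample names, in order. A mismatch with the
#'   VCF header is a format error.
#' @return object of class `variant_cohort`.
#' @export
read_vcf_multisample <- function(path, clone_names) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  samples <- colnames(vcf@gt)[-1]
  if (!identical(samples, as.character(clone_names))) {
    stopf("VCF sample names (%s) do not match the expected clones (%s) [header line]",
          paste(samples, collapse = ","), paste(clone_names, collapse = ","))
  }
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  info_num <- function(key) {
    v <- vcfR::extract.info(vcf, element = key, as.numeric = TRUE)
    if (is.null(v)) rep(NA_real_, nrow(fix)) else as.numeric(v)
  }
  sites <- data.frame(
    chrom = fix[, "CHROM"],
    pos = as.integer(fix[, "POS"]),
    ref = fix[, "REF"],
    alt = fix[, "ALT"],
    qual = suppressWarnings(as.numeric(fix[, "QUAL"])),
    fs = info_num("FS"),
    qd = info_num("QD"),
    read_pos_rank_sum = info_num("ReadPosRankSum"),
    sb = info_num("SB"),
    af = info_num("AF"),
    stringsAsFactors = FALSE
  )
  gt <- vcfR::extract.gt(vcf, element = "GT")
  dp <- vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE)
  ad <- vcfR::extract.gt(vcf, element = "AD")
  if (is.null(dim(gt))) {
    gt <- matrix(gt, nrow = 1); dp <- matrix(dp, nrow = 1); ad <- matrix(ad, nrow = 1)
  }
  gt[is.na(gt)] <- "./."
  bad <- which(!grepl("^(\\.|[0-9]+)([/|](\\.|[0-9]+))?$", gt))
  if (length(bad)) {
    i <- (bad[1] - 1L) %% nrow(sites) + 1L
    stopf("malformed GT field at %s:%d", sites$chrom[i], sites$pos[i])
  }
  variant_cohort(sites, clone_names,
                 gt = unname(gt), depth = unname(dp), ad = unname(ad))
}

#' Construct a variant cohort container
#'
#' @param sites data frame with columns chrom, pos, ref, alt (comma-joined
#'   string for multi-allelic sites), qual, fs, qd, read_pos_rank_sum and
#'   optionally sb, af.
#' @param clones clone (sample) names.
#' @param gt,depth,ad site x clone matrices of GT strings, total depths and
#'   AD strings ("ref,alt1,...").
#' @return object of class `variant_cohort`.
#' @export
variant_cohort <- function(sites, clones, gt, depth, ad) {
  n <- nrow(sites)
  for (m in list(gt, depth, ad)) {
    stopifnot(nrow(m) == n, ncol(m) == length(clones))
  }
  stopifnot(all(sites$pos >= 1))
  if (any(mapply(function(r, a) r %in% strsplit(a, ",")[[1]],
                 sites$ref, sites$alt))) {
    stopf("REF allele repeated among ALT alleles")
  }
  category <- matrix(gt_category(as.vector(gt)), nrow = n,
                     ncol = length(clones))
  structure(
    list(sites = sites, clones = as.character(clones), gt = gt,
         category = category,
         depth = matrix(as.integer(depth), nrow = n, ncol = length(clones)),
         ad = ad),
    class = "variant_cohort"
  )
}

#' @export
print.variant_cohort <- function(x, ...) {
  cat(sprintf("<variant_cohort> %d sites x %d clones (%s)\n",
              nrow(x$sites), length(x$clones), paste(x$clones, collapse = ", ")))
  invisible(x)
}

#' @export
length.variant_cohort <- function(x) nrow(x$sites)

# subset a cohort by site index
cohort_subset <- function(cohort, i) {
  variant_cohort(cohort$sites[i, , drop = FALSE], cohort$clones,
                 gt = cohort$gt[i, , drop = FALSE],
                 depth = cohort$depth[i, , drop = FALSE],
                 ad = cohort$ad[i, , drop = FALSE])
}

#' Extract one site as a variant record
#'
#' Materialises site `i` of a cohort as a nested record: site fields,
#' quality annotations and one [genotype_call] per clone.
#'
#' @param cohort a `variant_cohort`.
#' @param i site index (1-based).
#' @return object of class `variant_record`.
#' @export
variant_record <- function(cohort, i) {
  stopifnot(i >= 1, i <= nrow(cohort$sites))
  s <- cohort$sites[i, ]
  alts <- strsplit(s$alt, ",")[[1]]
  calls <- lapply(seq_along(cohort$clones), function(j) {
    alleles <- gt_alleles(cohort$gt[i, j], s$ref, alts)
    ad <- suppressWarnings(as.integer(strsplit(cohort$ad[i, j], ",")[[1]]))
    names(ad) <- c(s$ref, alts)[seq_along(ad)]
    genotype_call(alleles, s$ref, alts[1], depth = cohort$depth[i, j],
                  allele_depths = ad)
  })
  names(calls) <- cohort$clones
  structure(
    list(chrom = s$chrom, pos = s$pos, ref = s$ref, alts = alts,
         calls = calls,
         ann = list(qual = s$qual, fs = s$fs, qd = s$qd,
                    read_pos_rank_sum = s$read_pos_rank_sum,
                    sb = s$sb, af = s$af)),
    class = "variant_record"
  )
}

#' Write a variant cohort as VCF 4.2
#'
#' Emits a plain-text VCF with QUAL, the INFO annotations carried by the
#' cohort (FS, QD, ReadPosRankSum, SB, AF; omitted where absent) and
#' GT:AD:DP genotype fields. Output is deterministic (no timestamps).
#'
#' @param cohort a `variant_cohort`.
#' @param path output file path.
#' @param contigs optional named integer vector of contig lengths for the
#'   header.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(cohort, path, contigs = NULL) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=clonotyper",
    if (!is.null(contigs)) {
      sprintf("##contig=<ID=%s,length=%d>", names(contigs), as.integer(contigs))
    },
    "##INFO=<ID=FS,Number=1,Type=Float,Description=\"Phred-scaled Fisher strand bias\">",
    "##INFO=<ID=QD,Number=1,Type=Float,Description=\"Quality by depth\">",
    "##INFO=<ID=ReadPosRankSum,Number=1,Type=Float,Description=\"Alt allele read-position rank-sum\">",
    "##INFO=<ID=SB,Number=1,Type=Float,Description=\"Strand bias\">",
    "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Alternate allele frequency\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", cohort$clones), collapse = "\t")
  )
  s <- cohort$sites
  fmt_num <- function(key, v) ifelse(is.na(v), NA, paste0(key, "=", formatC(v, format = "g", digits = 6)))
  info_parts <- cbind(fmt_num("FS", s$fs), fmt_num("QD", s$qd),
                      fmt_num("ReadPosRankSum", s$read_pos_rank_sum),
                      fmt_num("SB", s$sb), fmt_num("AF", s$af))
  info <- apply(info_parts, 1, function(r) {
    r <- r[!is.na(r)]
    if (length(r) == 0) "." else paste(r, collapse = ";")
  })
  gtcols <- matrix(paste(cohort$gt, cohort$ad, cohort$depth, sep = ":"),
                   nrow = nrow(s))
  body <- paste(s$chrom, s$pos, ".", s$ref, s$alt,
                ifelse(is.na(s$qual), ".", formatC(s$qual, format = "g", digits = 6)),
                "PASS", info, "GT:AD:DP",
                apply(gtcols, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Merge per-sample variant cohorts on (chrom, pos, ref)
#'
#' Utility for callers holding one single-sample VCF per clone. Sites are
#' matched on chromosome, position and reference allele; a clone without a
#' call at a matched site receives a missing genotype with zero depth. The
#' ALT list of the merged site is the union of per-clone ALTs (first come,
#' first indexed) and GT indices are remapped accordingly. Site annotations
#' are taken from the first cohort carrying the site.
#'
#' @param cohorts named list of single-clone `variant_cohort` objects.
#' @return a merged `variant_cohort`.
#' @export
merge_cohorts <- function(cohorts) {
  stopifnot(length(cohorts) >= 1, !is.null(names(cohorts)))
  keys <- unique(unlist(lapply(cohorts, function(x) {
    paste(x$sites$chrom, x$sites$pos, x$sites$ref, sep = "\r")
  })))
  parts <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
  ord <- order(parts[, 1], as.integer(parts[, 2]))
  keys <- keys[ord]; parts <- parts[ord, , drop = FALSE]
  n <- length(keys); k <- length(cohorts)
  alts <- vector("list", n)
  ann <- matrix(NA_real_, n, 6,
                dimnames = list(NULL, c("qual", "fs", "qd", "read_pos_rank_sum", "sb", "af")))
  gt <- matrix("./.", n, k); dp <- matrix(0L, n, k); ad <- matrix("0", n, k)
  for (j in seq_len(k)) {
    x <- cohorts[[j]]
    kx <- paste(x$sites$chrom, x$sites$pos, x$sites$ref, sep = "\r")
    at <- match(kx, keys)
    for (r in seq_along(at)) {
      i <- at[r]
      a_old <- strsplit(x$sites$alt[r], ",")[[1]]
      for (a in a_old) if (!a %in% alts[[i]]) alts[[i]] <- c(alts[[i]], a)
      idx_map <- c(0L, match(a_old, alts[[i]]))
      toks <- strsplit(x$gt[r, 1], "[/|]")[[1]]
      toks <- ifelse(toks == ".", ".", as.character(idx_map[as.integer(toks) + 1L]))
      gt[i, j] <- paste(toks, collapse = "/")
      dp[i, j] <- x$depth[r, 1]
      ad[i, j] <- x$ad[r, 1]
      for (cn in colnames(ann)) {
        if (is.na(ann[i, cn])) ann[i, cn] <- x$sites[[cn]][r]
      }
    }
  }
  sites <- data.frame(
    chrom = parts[, 1], pos = as.integer(parts[, 2]), ref = parts[, 3],
    alt = vapply(alts, paste, character(1), collapse = ","),
    qual = ann[, "qual"], fs = ann[, "fs"], qd = ann[, "qd"],
    read_pos_rank_sum = ann[, "read_pos_rank_sum"], sb = ann[, "sb"],
    af = ann[, "af"], stringsAsFactors = FALSE
  )
  variant_cohort(sites, names(cohorts), gt, dp, ad)
}
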