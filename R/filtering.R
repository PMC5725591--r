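#' Filter parameter presets
#'
#' Parameters of the SNV retention cascade. The default `"recalibrated"`
#' preset applies, per site: per-clone coverage >= `min_depth`; Fisher
#' strand `FS > max_fs` fails; quality-by-depth `QD < min_qd` fails;
#' `ReadPosRankSum` beyond `max_read_pos_rank_sum` fails (two-sided on the
#' absolute value by default, one-sided on the signed statistic when
#' `rprs_two_sided = FALSE`); homozygous calls with more than
#' `max_discordant_reads` reads supporting the opposite allele fail; a
#' clone showing three or more alleles each supported by at least
#' `allele_detection_min_reads` reads (or a MULTI genotype) marks the site
#' as carrying spurious alleles. All inequalities are strict, exactly as
#' stated: a site at `FS == max_fs` passes the FS rule.
#'
#' The non-default `"initial_hard_filter"` preset carries the earlier,
#' pre-recalibration rules: `QUAL < min_qual`; per-clone depth outside
#' `[0.5, 3] * mean_depth`; strand bias `SB > 0`; `FS < min_fs`;
#' `ReadPosRankSum` outside `rprs_range`; allele frequency `AF < min_af`.
#' Annotations absent at a site never fail their rule (rank-sum statistics
#' are undefined without heterozygous carriers).
#'
#' @param preset `"recalibrated"` (default) or `"initial_hard_filter"`.
#' @param min_depth minimum per-clone read depth (default 15).
#' @param max_fs maximum Fisher-strand phred score (default 10).
#' @param min_qd minimum quality-by-depth (default 10).
#' @param max_read_pos_rank_sum rank-sum cutoff (default 2).
#' @param rprs_two_sided apply the rank-sum cutoff to the absolute value
#'   (default TRUE).
#' @param max_discordant_reads tolerated opposite-allele reads in a
#'   homozygous call (default 2, i.e. ">2" fails).
#' @param allele_detection_min_reads reads needed to call an allele
#'   detected for the spurious-allele rule (default 3, i.e. ">2").
#' @param min_qual,mean_depth,max_sb,min_fs,rprs_range,min_af parameters of
#'   the initial preset.
#' @return object of class `filter_params`.
#' @export
filter_params <- function(preset = c("recalibrated", "initial_hard_filter"),
                          min_depth = 15, max_fs = 10, min_qd = 10,
                          max_read_pos_rank_sum = 2, rprs_two_sided = TRUE,
                          max_discordant_reads = 2,
                          allele_detection_min_reads = 3,
                          min_qual = 100, mean_depth = 30, max_sb = 0,
                          min_fs = 1, rprs_range = c(-2, 2.5), min_af = 0.2) {
  preset <- match.arg(preset)
  stopifnot(min_depth >= 0, max_fs >= 0, min_qd >= 0,
            max_read_pos_rank_sum >= 0, max_discordant_reads >= 0,
            allele_detection_min_reads >= 0)
  structure(
    list(preset = preset, min_depth = min_depth, max_fs = max_fs,
         min_qd = min_qd, max_read_pos_rank_sum = max_read_pos_rank_sum,
         rprs_two_sided = rprs_two_sided,
         max_discordant_reads = max_discordant_reads,
         allele_detection_min_reads = allele_detection_min_reads,
         min_qual = min_qual, mean_depth = mean_depth, max_sb = max_sb,
         min_fs = min_fs, rprs_range = rprs_range, min_af = min_af),
    class = "filter_params"
  )
}

filter_reasons <- c("IN_REPEAT", "SPURIOUS_ALLELE", "LOW_COVERAGE", "HIGH_FS",
                    "LOW_QD", "BAD_READ_POS", "DISCORDANT_HOM",
                    "INADEQUATE_COVERAGE_ANY_CLONE", "QUAL_LOW",
                    "COVERAGE_BOUNDS", "STRAND_BIAS", "LOW_AF")

# vectorised rule engine: returns a sites x reasons logical matrix
reason_matrix <- function(cohort, mask, params) {
  n <- nrow(cohort$sites); k <- length(cohort$clones)
  s <- cohort$sites
  R <- matrix(FALSE, n, length(filter_reasons),
              dimnames = list(NULL, filter_reasons))
  R[, "IN_REPEAT"] <- in_mask(mask, s$chrom, s$pos)

  called <- cohort$category != "MISSING"
  if (params$preset == "recalibrated" && any(is.na(cohort$depth) & called)) {
    j <- which(apply(is.na(cohort$depth) & called, 2, any))[1]
    stopf("missing depth for clone %s under the recalibrated preset",
          cohort$clones[j])
  }

  ad_int <- lapply(seq_len(k), function(j) {
    lapply(strsplit(cohort$ad[, j], ",", fixed = TRUE),
           function(v) suppressWarnings(as.integer(v)))
  })
  n_detected <- vapply(seq_len(k), function(j) {
    vapply(ad_int[[j]],
           function(v) sum(v >= params$allele_detection_min_reads, na.rm = TRUE),
           integer(1))
  }, integer(n))
  n_detected <- matrix(n_detected, nrow = n, ncol = k)
  R[, "SPURIOUS_ALLELE"] <-
    rowSums(n_detected >= 3) > 0 | rowSums(cohort$category == "MULTI") > 0

  if (params$preset == "recalibrated") {
    low_cov <- rowSums(cohort$depth < params$min_depth, na.rm = TRUE) > 0
    # one threshold realises both the stated coverage rule and the
    # "adequately covered in every clone" exclusion; counted under both
    R[, "LOW_COVERAGE"] <- low_cov
    R[, "INADEQUATE_COVERAGE_ANY_CLONE"] <- low_cov
    R[, "HIGH_FS"] <- !is.na(s$fs) & s$fs > params$max_fs
    R[, "LOW_QD"] <- !is.na(s$qd) & s$qd < params$min_qd
    rprs <- s$read_pos_rank_sum
    stat <- if (params$rprs_two_sided) abs(rprs) else rprs
    R[, "BAD_READ_POS"] <- !is.na(stat) & stat > params$max_read_pos_rank_sum
    ref_reads <- matrix(vapply(seq_len(k), function(j) {
      vapply(ad_int[[j]], function(v) if (length(v)) v[1] else NA_integer_,
             integer(1))
    }, integer(n)), nrow = n, ncol = k)
    alt_reads <- matrix(vapply(seq_len(k), function(j) {
      vapply(ad_int[[j]],
             function(v) if (length(v) > 1) sum(v[-1], na.rm = TRUE) else 0L,
             integer(1))
    }, integer(n)), nrow = n, ncol = k)
    disc <- (cohort$category == "HOM_ALT" &
               !is.na(ref_reads) & ref_reads > params$max_discordant_reads) |
            (cohort$category == "HOM_REF" &
               alt_reads > params$max_discordant_reads)
    R[, "DISCORDANT_HOM"] <- rowSums(disc, na.rm = TRUE) > 0
  } else {
    R[, "QUAL_LOW"] <- !is.na(s$qual) & s$qual < params$min_qual
    lo <- 0.5 * params$mean_depth; hi <- 3 * params$mean_depth
    R[, "COVERAGE_BOUNDS"] <-
      rowSums(cohort$depth < lo | cohort$depth > hi, na.rm = TRUE) > 0
    R[, "STRAND_BIAS"] <- !is.na(s$sb) & s$sb > params$max_sb
    R[, "HIGH_FS"] <- !is.na(s$fs) & s$fs < params$min_fs
    R[, "BAD_READ_POS"] <- !is.na(s$read_pos_rank_sum) &
      (s$read_pos_rank_sum < params$rprs_range[1] |
         s$read_pos_rank_sum > params$rprs_range[2])
    R[, "LOW_AF"] <- !is.na(s$af) & s$af < params$min_af
  }
  R
}

#' Evaluate all filter rules on a single variant record
#'
#' All violated rules are reported; rules do not short-circuit.
#'
#' @param record a [variant_record] (or a 1-site `variant_cohort`).
#' @param mask a [region_mask].
#' @param params a [filter_params] object.
#' @return object of class `filter_decision`: list with `passed` (logical)
#'   and `reasons` (character vector, empty iff passed).
#' @export
evaluate_filters <- function(record, mask, params = filter_params()) {
  cohort <- if (inherits(record, "variant_cohort")) record
            else record_as_cohort(record)
  stopifnot(nrow(cohort$sites) == 1)
  R <- reason_matrix(cohort, mask, params)
  reasons <- filter_reasons[R[1, ]]
  structure(list(passed = length(reasons) == 0, reasons = reasons),
            class = "filter_decision")
}

#' @export
print.filter_decision <- function(x, ...) {
  cat(if (x$passed) "<filter_decision> PASS\n"
      else sprintf("<filter_decision> FAIL: %s\n",
                   paste(x$reasons, collapse = ", ")))
  invisible(x)
}

# rebuild a 1-site cohort from a nested variant_record
record_as_cohort <- function(rec) {
  stopifnot(inherits(rec, "variant_record"))
  calls <- rec$calls
  sites <- data.frame(chrom = rec$chrom, pos = rec$pos, ref = rec$ref,
                      alt = paste(rec$alts, collapse = ","),
                      qual = rec$ann$qual %||% NA_real_,
                      fs = rec$ann$fs %||% NA_real_,
                      qd = rec$ann$qd %||% NA_real_,
                      read_pos_rank_sum = rec$ann$read_pos_rank_sum %||% NA_real_,
                      sb = rec$ann$sb %||% NA_real_,
                      af = rec$ann$af %||% NA_real_,
                      stringsAsFactors = FALSE)
  gt_of <- function(cl) {
    idx <- match(cl$alleles, c(rec$ref, rec$alts)) - 1L
    if (anyNA(idx)) "./." else paste(sort(idx), collapse = "/")
  }
  gt <- matrix(vapply(calls, gt_of, character(1)), nrow = 1)
  dp <- matrix(vapply(calls, function(cl) cl$depth, integer(1)), nrow = 1)
  ad <- matrix(vapply(calls, function(cl) {
    ordered <- cl$allele_depths[c(rec$ref, rec$alts)]
    ordered[is.na(ordered)] <- 0L
    paste(ordered, collapse = ",")
  }, character(1)), nrow = 1)
  variant_cohort(sites, names(calls), gt, dp, ad)
}

#' Apply the filter cascade to a whole cohort
#'
#' @param cohort a `variant_cohort`.
#' @param mask a [region_mask].
#' @param params a [filter_params] object.
#' @return object of class `filter_result`: list with `passing` and
#'   `rejected` cohorts, a `rejected_table` (chrom, pos, ref, alt, reasons),
#'   the full logical `reason_matrix`, and `summary` — a named count per
#'   reason (a record may count toward several) plus `records_rejected`.
#' @export
filter_cohort <- function(cohort, mask, params = filter_params()) {
  R <- reason_matrix(cohort, mask, params)
  fail <- rowSums(R) > 0
  reasons_str <- if (nrow(R) == 0) character(0)
    else apply(R, 1, function(r) paste(filter_reasons[r], collapse = ";"))
  rejected_table <- data.frame(
    chrom = cohort$sites$chrom[fail], pos = cohort$sites$pos[fail],
    ref = cohort$sites$ref[fail], alt = cohort$sites$alt[fail],
    reasons = reasons_str[fail], stringsAsFactors = FALSE
  )
  summary <- c(colSums(R), records_rejected = sum(fail))
  structure(
    list(passing = cohort_subset(cohort, which(!fail)),
         rejected = cohort_subset(cohort, which(fail)),
         rejected_table = rejected_table,
         reason_matrix = R, summary = summary, params = params),
    class = "filter_result"
  )
}

#' @export
print.filter_result <- function(x, ...) {
  n <- nrow(x$reason_matrix)
  cat(sprintf("<filter_result> %d sites: %d pass, %d rejected (%s preset)\n",
              n, n - x$summary[["records_rejected"]],
              x$summary[["records_rejected"]], x$params$preset))
  nz <- x$summary[x$summary > 0 & names(x$summary) != "records_rejected"]
  if (length(nz)) {
    for (r in names(nz)) cat(sprintf("  %-30s %d\n", r, nz[[r]]))
  }
  invisible(x)
}
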