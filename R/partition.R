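#' Classify one site by genotype concordance across clones
#'
#' Genotype equality means identical allele content (the unordered allele
#' pair), not merely the same category. With all calls equal the site is
#' `VARIETAL` (or `NOT_A_VARIANT` when every clone is homozygous
#' reference); with exactly one clone deviating from the genotype shared by
#' all others it is `CLONE_SPECIFIC`, reporting that clone and its
#' genotype category; otherwise it is `EXCLUDED_DISCORDANT`. MISSING or
#' MULTI calls violate the precondition (such sites must have been
#' filtered) and raise an error.
#'
#' @param calls named list of [genotype_call] objects, one per clone
#'   (three in the standard design; any number >= 2 is accepted, with
#'   "exactly one outlier" generalising the clone-specific case).
#' @return object of class `partition_label`: list with `kind`,
#'   `outlier_clone` (clone-specific only) and `reported_category` (the
#'   shared genotype for varietal sites, the outlier's genotype otherwise).
#' @export
classify_site <- function(calls) {
  stopifnot(length(calls) >= 2)
  cats <- vapply(calls, function(cl) cl$category, character(1))
  if (any(cats %in% c("MISSING", "MULTI"))) {
    stopf("classify_site requires called, biallelic genotypes (got %s); filter first",
          paste(cats[cats %in% c("MISSING", "MULTI")], collapse = ","))
  }
  keys <- vapply(calls, function(cl) paste(sort(cl$alleles), collapse = "/"),
                 character(1))
  tab <- table(keys)
  if (length(tab) == 1) {
    if (all(cats == "HOM_REF")) {
      label <- list(kind = "NOT_A_VARIANT", outlier_clone = NULL,
                    reported_category = NULL)
    } else {
      label <- list(kind = "VARIETAL", outlier_clone = NULL,
                    reported_category = cats[[1]])
    }
  } else if (length(tab) == 2 && min(tab) == 1 && max(tab) == length(calls) - 1) {
    out <- which(keys == names(tab)[tab == 1])
    label <- list(kind = "CLONE_SPECIFIC",
                  outlier_clone = names(calls)[out],
                  reported_category = cats[[out]])
  } else {
    label <- list(kind = "EXCLUDED_DISCORDANT", outlier_clone = NULL,
                  reported_category = NULL)
  }
  structure(label, class = "partition_label")
}

#' @export
print.partition_label <- function(x, ...) {
  cat(sprintf("<partition_label> %s%s%s\n", x$kind,
              if (!is.null(x$outlier_clone)) paste0(" outlier=", x$outlier_clone) else "",
              if (!is.null(x$reported_category)) paste0(" category=", x$reported_category) else ""))
  invisible(x)
}

#' Classify every site of a cohort by genotype concordance
#'
#' Vectorised equivalent of [classify_site] over a `variant_cohort` whose
#' sites all carry called, biallelic genotypes.
#'
#' @param cohort a `variant_cohort`.
#' @return data frame with columns `chrom`, `pos`, `kind`,
#'   `outlier_clone`, `reported_category`.
#' @export
classify_cohort <- function(cohort) {
  cat_m <- cohort$category
  k <- ncol(cat_m)
  if (any(cat_m %in% c("MISSING", "MULTI"))) {
    stopf("cohort contains MISSING or MULTI genotypes; filter first")
  }
  n_hr <- rowSums(cat_m == "HOM_REF")
  n_het <- rowSums(cat_m == "HET")
  n_ha <- rowSums(cat_m == "HOM_ALT")
  counts <- cbind(HOM_REF = n_hr, HET = n_het, HOM_ALT = n_ha)
  distinct <- rowSums(counts > 0)
  kind <- rep("EXCLUDED_DISCORDANT", nrow(cat_m))
  kind[distinct == 1 & n_hr == k] <- "NOT_A_VARIANT"
  kind[distinct == 1 & n_hr < k] <- "VARIETAL"
  one_out <- distinct == 2 & apply(counts, 1, function(r) any(r == 1) && any(r == k - 1))
  kind[one_out] <- "CLONE_SPECIFIC"

  outlier <- rep(NA_character_, nrow(cat_m))
  reported <- rep(NA_character_, nrow(cat_m))
  reported[kind == "VARIETAL"] <- cat_m[kind == "VARIETAL", 1]
  if (any(one_out)) {
    minority <- colnames(counts)[apply(counts[one_out, , drop = FALSE], 1,
                                       function(r) which(r == 1))]
    out_col <- vapply(seq_along(minority), function(i) {
      which(cat_m[which(one_out)[i], ] == minority[i])
    }, integer(1))
    outlier[one_out] <- cohort$clones[out_col]
    reported[one_out] <- minority
  }
  data.frame(chrom = cohort$sites$chrom, pos = cohort$sites$pos,
             kind = kind, outlier_clone = outlier,
             reported_category = reported, stringsAsFactors = FALSE)
}

#' Tabulate partition labels into a clone x category summary
#'
#' Produces the standard summary matrix of a three-clone (or n-clone)
#' concordance analysis: rows are genotype categories (`HOM_REF`,
#' `HOM_ALT`, `HET`) plus an `EXCLUDED` row for fully discordant sites;
#' columns are one per clone (clone-specific sites, placed by outlier
#' clone and its reported genotype), a `VARIETAL` column (shared genotype)
#' and a `TOTAL` column. `NOT_A_VARIANT` labels are excluded from every
#' cell and from the varietal fraction.
#'
#' @param labels data frame as returned by [classify_cohort] (columns
#'   `kind`, `outlier_clone`, `reported_category`), or a list of
#'   [classify_site] labels.
#' @param clones clone names in column order; defaults to the sorted
#'   outlier clones observed.
#' @return object of class `partition_summary`: list with the `counts`
#'   matrix, `total` (sites excluding `NOT_A_VARIANT`) and
#'   `varietal_fraction`.
#' @export
tabulate_partition <- function(labels, clones = NULL) {
  if (is.list(labels) && !is.data.frame(labels)) {
    labels <- data.frame(
      kind = vapply(labels, `[[`, "", "kind"),
      outlier_clone = vapply(labels, function(l) l$outlier_clone %||% NA_character_, ""),
      reported_category = vapply(labels, function(l) l$reported_category %||% NA_character_, ""),
      stringsAsFactors = FALSE
    )
  }
  if (is.null(clones)) {
    clones <- sort(unique(stats::na.omit(labels$outlier_clone)))
  }
  rows <- c("HOM_REF", "HOM_ALT", "HET", "EXCLUDED")
  counts <- matrix(0L, length(rows), length(clones) + 2,
                   dimnames = list(rows, c(clones, "VARIETAL", "TOTAL")))
  cs <- labels[labels$kind == "CLONE_SPECIFIC", ]
  if (nrow(cs)) {
    t1 <- table(factor(cs$reported_category, levels = rows),
                factor(cs$outlier_clone, levels = clones))
    counts[rows, clones] <- as.integer(t1)
  }
  va <- labels[labels$kind == "VARIETAL", ]
  if (nrow(va)) {
    counts[rows, "VARIETAL"] <-
      as.integer(table(factor(va$reported_category, levels = rows)))
  }
  counts["EXCLUDED", "TOTAL"] <- sum(labels$kind == "EXCLUDED_DISCORDANT")
  counts[, "TOTAL"] <- counts[, "TOTAL"] + rowSums(counts[, c(clones, "VARIETAL"), drop = FALSE])
  total <- sum(counts[, "TOTAL"])
  varietal_total <- sum(counts[, "VARIETAL"])
  structure(
    list(counts = counts, clones = clones, total = total,
         varietal_fraction = if (total > 0) varietal_total / total else NA_real_),
    class = "partition_summary"
  )
}

#' Build a partition summary directly from per-cell counts
#'
#' Convenience constructor for feeding published per-cell counts (e.g. a
#' printed concordance table) through the same tabulation path: cell
#' counts are expanded into labels and passed to [tabulate_partition].
#'
#' @param clone_specific matrix of clone-specific counts, rows `HOM_REF`,
#'   `HOM_ALT`, `HET`, one column per clone.
#' @param varietal named vector of varietal counts (`HOM_ALT`, `HET`).
#' @param excluded count of fully discordant sites.
#' @return a `partition_summary`.
#' @export
partition_summary_from_counts <- function(clone_specific, varietal, excluded = 0) {
  labs <- list()
  for (cl in colnames(clone_specific)) {
    for (cat in rownames(clone_specific)) {
      n <- clone_specific[cat, cl]
      if (n > 0) labs[[length(labs) + 1]] <- data.frame(
        kind = "CLONE_SPECIFIC", outlier_clone = cl, reported_category = cat,
        stringsAsFactors = FALSE)[rep(1, n), ]
    }
  }
  for (cat in names(varietal)) {
    n <- varietal[[cat]]
    if (n > 0) labs[[length(labs) + 1]] <- data.frame(
      kind = "VARIETAL", outlier_clone = NA_character_, reported_category = cat,
      stringsAsFactors = FALSE)[rep(1, n), ]
  }
  if (excluded > 0) labs[[length(labs) + 1]] <- data.frame(
    kind = "EXCLUDED_DISCORDANT", outlier_clone = NA_character_,
    reported_category = NA_character_, stringsAsFactors = FALSE)[rep(1, excluded), ]
  tabulate_partition(do.call(rbind, labs), clones = colnames(clone_specific))
}

#' @export
print.partition_summary <- function(x, ...) {
  cat(render_partition_report(x, format = "text"), sep = "\n")
  invisible(x)
}
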