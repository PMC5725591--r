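#' Published three-clone SNV concordance counts
#'
#' Per-cell counts of the published concordance analysis of clones
#' CVT 71, CVT 423 and CVT 185 of 'Nebbiolo' (genotype-category rows by
#' clone-specific / varietal columns, plus the fully discordant site
#' count), shipped as a plain CSV so the tabulation path can be exercised
#' against the published totals.
#'
#' @return list with `clone_specific` (3 x 3 count matrix), `varietal`
#'   (named vector) and `excluded` (count), as consumed by
#'   [partition_summary_from_counts].
#' @export
published_partition_counts <- function() {
  path <- system.file("extdata", "nebbiolo_partition_counts.csv",
                      package = "clonotyper", mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  cs_rows <- tab$category %in% c("HOM_REF", "HOM_ALT", "HET")
  clone_cols <- setdiff(names(tab), c("category", "VARIETAL"))
  cs <- as.matrix(tab[cs_rows, clone_cols])
  rownames(cs) <- tab$category[cs_rows]
  storage.mode(cs) <- "integer"
  varietal <- stats::setNames(tab$VARIETAL[tab$category %in% c("HOM_ALT", "HET")],
                              tab$category[tab$category %in% c("HOM_ALT", "HET")])
  list(clone_specific = cs, varietal = varietal,
       excluded = tab$VARIETAL[tab$category == "EXCLUDED"])
}

#' Published varietal-SNV effect counts
#'
#' Per-category heterozygous / homozygous-alternate counts of the
#' published transcript-effect annotation of the varietal SNV set.
#'
#' @return data frame with columns `category`, `impact`, `het`,
#'   `hom_alt`.
#' @export
published_effect_counts <- function() {
  path <- system.file("extdata", "nebbiolo_effect_counts.csv",
                      package = "clonotyper", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Expand published effect counts into per-site effect calls
#'
#' Builds one synthetic site per counted effect so the published
#' per-category counts can be driven through [summarize_effects].
#'
#' @param counts data frame as from [published_effect_counts].
#' @return list with `effects` (data frame: site, category) and `labels`
#'   (named site -> genotype vector).
#' @export
effect_calls_from_counts <- function(counts = published_effect_counts()) {
  n <- sum(counts$het) + sum(counts$hom_alt)
  site <- sprintf("site%06d", seq_len(n))
  category <- rep(rep(counts$category, 2), c(counts$het, counts$hom_alt))
  genotype <- rep(rep(c("HET", "HOM_ALT"), each = nrow(counts)),
                  c(counts$het, counts$hom_alt))
  list(effects = data.frame(site = site, category = category,
                            stringsAsFactors = FALSE),
       labels = stats::setNames(genotype, site))
}
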