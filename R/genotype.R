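#' Genotype categories
#'
#' The five diploid genotype categories used throughout the package:
#' `HOM_REF` (both alleles reference), `HET` (reference plus the first
#' alternate), `HOM_ALT` (both alleles the first alternate), `MULTI` (any
#' allele beyond the first alternate, or more than two distinct alleles) and
#' `MISSING` (no call).
#'
#' @return character vector of the category names.
#' @export
genotype_categories <- function() {
  c("HOM_REF", "HET", "HOM_ALT", "MULTI", "MISSING")
}

#' Derive the genotype category from a VCF GT string
#'
#' Phased (`|`) and unphased (`/`) separators are treated identically; a
#' single-allele (hemizygous-declared) GT is categorised by its one allele.
#' Any allele index above 1 (i.e. outside \{REF, first ALT\}) yields `MULTI`.
#'
#' @param gt character vector of GT fields (e.g. `"0/1"`, `"./."`, `"1|1"`).
#' @return character vector of categories.
#' @export
#' @examples
#' gt_category(c("0/0", "0/1", "1/1", "./.", "1/2", "0|1"))
gt_category <- function(gt) {
  vapply(strsplit(gt, "[/|]"), function(a) {
    a <- a[a != ""]
    if (length(a) == 0 || any(a == ".")) return("MISSING")
    ai <- suppressWarnings(as.integer(a))
    if (anyNA(ai)) return("MISSING")
    if (any(ai > 1) || length(unique(ai)) > 2) return("MULTI")
    if (all(ai == 0)) return("HOM_REF")
    if (all(ai == 1)) return("HOM_ALT")
    "HET"
  }, character(1))
}

# allele strings for a GT given ref and alt alleles; NA alleles for MISSING
gt_alleles <- function(gt, ref, alts) {
  all_alleles <- c(ref, alts)
  idx <- suppressWarnings(as.integer(strsplit(gt, "[/|]")[[1]]))
  if (anyNA(idx)) return(rep(NA_character_, 2L))
  out <- all_alleles[idx + 1L]
  if (length(out) == 1L) out <- c(out, out)
  out
}

#' Construct a single genotype call
#'
#' A light record of one clone's call at one site: category, allele pair,
#' total depth and per-allele depths. Consistency between category and
#' alleles is enforced.
#'
#' @param alleles character vector of one or two alleles.
#' @param ref reference allele at the site.
#' @param first_alt first alternate allele at the site.
#' @param depth total read depth (non-negative).
#' @param allele_depths named integer vector, allele -> supporting reads.
#' @return object of class `genotype_call`.
#' @export
genotype_call <- function(alleles, ref, first_alt, depth = NA_integer_,
                          allele_depths = NULL) {
  if (length(alleles) == 1L) alleles <- c(alleles, alleles)
  stopifnot(length(alleles) == 2L)
  category <- if (anyNA(alleles)) {
    "MISSING"
  } else if (any(!alleles %in% c(ref, first_alt)) ||
             length(unique(alleles)) > 2L) {
    "MULTI"
  } else if (all(alleles == ref)) {
    "HOM_REF"
  } else if (all(alleles == first_alt)) {
    "HOM_ALT"
  } else {
    "HET"
  }
  if (!is.na(depth) && length(allele_depths)) {
    if (depth < max(allele_depths)) {
      stopf("depth (%d) below the largest allele depth (%d)",
            depth, max(allele_depths))
    }
  }
  structure(
    list(category = category, alleles = alleles, depth = as.integer(depth),
         allele_depths = allele_depths),
    class = "genotype_call"
  )
}

#' @export
print.genotype_call <- function(x, ...) {
  cat(sprintf("<genotype_call> %s %s/%s depth=%s\n", x$category,
              x$alleles[1], x$alleles[2],
              ifelse(is.na(x$depth), ".", x$depth)))
  invisible(x)
}
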