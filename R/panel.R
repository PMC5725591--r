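#' Read an accession x marker genotype panel
#'
#' @param path CSV file with an `accession` column followed by one column
#'   per marker; cells are genotype tokens (e.g. `"AA"`, `"AT"`, composite
#'   chimeric tokens such as `"CC~CT"`, or `MISSING`).
#' @return data frame (the panel).
#' @export
read_marker_panel <- function(path) {
  panel <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  stopifnot("accession" %in% names(panel), ncol(panel) >= 2)
  panel
}

panel_markers <- function(panel) setdiff(names(panel), "accession")

#' Group accessions into multilocus genotype classes
#'
#' Classes are the equivalence classes of exact profile equality; a
#' composite chimeric token is a first-class state, so profiles differing
#' only in a chimeric token form distinct classes. Rows containing
#' `MISSING` tokens are excluded from grouping and reported separately.
#' Labels are letters assigned in order of first appearance, or — with
#' `canonical = TRUE` — by descending member count with ties broken by
#' lexicographic profile order, for reproducible reports.
#'
#' @param panel data frame from [read_marker_panel].
#' @param canonical use the canonical labelling (default FALSE).
#' @return object of class `genotype_classes`: list with `classes` (a list
#'   of `label`, `profile`, `members`), `markers` and `excluded`
#'   (accessions with missing tokens).
#' @export
group_profiles <- function(panel, canonical = FALSE) {
  markers <- panel_markers(panel)
  prof_m <- as.matrix(panel[, markers, drop = FALSE])
  has_missing <- rowSums(prof_m == "MISSING" | is.na(prof_m)) > 0
  excluded <- panel$accession[has_missing]
  keep <- panel[!has_missing, , drop = FALSE]
  if (nrow(keep) == 0) {
    return(structure(list(classes = list(), markers = markers,
                          excluded = excluded), class = "genotype_classes"))
  }
  key <- apply(keep[, markers, drop = FALSE], 1, paste, collapse = "|")
  first <- !duplicated(key)
  ord_keys <- key[first]
  if (canonical) {
    sizes <- as.integer(table(key)[ord_keys])
    ord_keys <- ord_keys[order(-sizes, ord_keys)]
  }
  classes <- lapply(seq_along(ord_keys), function(i) {
    rows <- which(key == ord_keys[i])
    list(label = class_letter(i),
         profile = stats::setNames(
           as.character(keep[rows[1], markers]), markers),
         members = keep$accession[rows])
  })
  structure(list(classes = classes, markers = markers, excluded = excluded),
            class = "genotype_classes")
}

class_letter <- function(i) {
  # A, B, ..., Z, AA, AB, ... for arbitrarily many classes
  out <- ""
  while (i > 0) {
    out <- paste0(LETTERS[(i - 1) %% 26 + 1], out)
    i <- (i - 1) %/% 26
  }
  out
}

#' @export
print.genotype_classes <- function(x, ...) {
  cat(sprintf("<genotype_classes> %d classes over %d markers\n",
              length(x$classes), length(x$markers)))
  for (cl in x$classes) {
    cat(sprintf("  %s (n=%d): %s\n", cl$label, length(cl$members),
                paste(cl$profile, collapse = " ")))
  }
  if (length(x$excluded)) {
    cat(sprintf("  excluded (MISSING tokens): %s\n",
                paste(x$excluded, collapse = ", ")))
  }
  invisible(x)
}

# class profiles as a classes x markers character matrix
class_profile_matrix <- function(classes) {
  stopifnot(inherits(classes, "genotype_classes"))
  m <- do.call(rbind, lapply(classes$classes, function(cl) cl$profile))
  rownames(m) <- vapply(classes$classes, `[[`, "", "label")
  m
}

#' Class membership counts
#'
#' @param classes a `genotype_classes` object.
#' @return named integer vector, label -> member count.
#' @export
class_counts <- function(classes) {
  stats::setNames(
    vapply(classes$classes, function(cl) length(cl$members), integer(1)),
    vapply(classes$classes, `[[`, "", "label"))
}

subset_discriminates <- function(prof, cols) {
  keys <- apply(prof[, cols, drop = FALSE], 1, paste, collapse = "|")
  !anyDuplicated(keys)
}

#' Minimal marker subsets that keep all genotype classes distinct
#'
#' Exhaustive search by increasing subset size: the smallest `k` with at
#' least one discriminating subset is found and every witness of that
#' size is returned. For panels too wide for exhaustion a greedy
#' forward-selection subset (most new class pairs separated first, ties
#' by marker order) is also reported.
#'
#' @param classes a `genotype_classes` object (profiles must already be
#'   distinct on the full panel).
#' @param max_exhaustive maximum panel width for the exhaustive search
#'   (default 20).
#' @return list with `size` (minimal k), `subsets` (list of character
#'   vectors, every witness of size k) and `greedy` (the greedy subset).
#' @export
minimal_discriminating_subsets <- function(classes, max_exhaustive = 20) {
  prof <- class_profile_matrix(classes)
  markers <- classes$markers
  if (nrow(prof) <= 1) {
    return(list(size = 0L, subsets = list(character(0)), greedy = character(0)))
  }
  if (!subset_discriminates(prof, markers)) {
    stopf("class profiles are not distinct on the full panel")
  }
  greedy <- greedy_discriminating_subset(prof, markers)
  if (length(markers) > max_exhaustive) {
    return(list(size = NA_integer_, subsets = list(), greedy = greedy))
  }
  for (k in seq_along(markers)) {
    combos <- utils::combn(markers, k, simplify = FALSE)
    hits <- Filter(function(cols) subset_discriminates(prof, cols), combos)
    if (length(hits)) {
      return(list(size = k, subsets = hits, greedy = greedy))
    }
  }
  list(size = length(markers), subsets = list(markers), greedy = greedy)
}

greedy_discriminating_subset <- function(prof, markers) {
  n <- nrow(prof)
  pairs <- utils::combn(n, 2)
  sep_by <- lapply(markers, function(m) {
    which(prof[pairs[1, ], m] != prof[pairs[2, ], m])
  })
  names(sep_by) <- markers
  chosen <- character(0)
  covered <- integer(0)
  while (length(covered) < ncol(pairs)) {
    gains <- vapply(markers, function(m) {
      length(setdiff(sep_by[[m]], covered))
    }, integer(1))
    if (max(gains) == 0) break
    pick <- markers[which.max(gains)]
    chosen <- c(chosen, pick)
    covered <- union(covered, sep_by[[pick]])
    markers <- setdiff(markers, pick)
  }
  chosen
}
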