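token_alleles <- function(token) {
  if (is.na(token)) stopf("missing genotype token")
  if (grepl("~", token, fixed = TRUE)) {
    # composite chimeric token: union of the layer alleles, as heterozygote
    parts <- strsplit(token, "~", fixed = TRUE)[[1]]
    al <- unique(unlist(strsplit(parts, "")))
    if (length(al) == 1) return(c(al, al))
    if (length(al) == 2) return(sort(al))
    stopf("chimeric token %s carries more than two alleles", token)
  }
  al <- strsplit(token, "")[[1]]
  if (length(al) == 1) return(c(al, al))
  if (length(al) != 2) stopf("genotype token %s is not diploid", token)
  sort(al)
}

shared_fraction <- function(a, b) {
  # multiset intersection of two allele pairs, halved
  shared <- 0
  bb <- b
  for (x in a) {
    hit <- match(x, bb)
    if (!is.na(hit)) {
      shared <- shared + 1
      bb <- bb[-hit]
    }
  }
  shared / 2
}

#' Allele-sharing distance between two multilocus profiles
#'
#' Per locus the proportion of shared alleles is the size of the multiset
#' intersection of the two diploid allele pairs divided by two; the
#' distance is `D = 1 - mean` over loci. Composite chimeric tokens
#' contribute the union of their layer alleles, treated as a heterozygote.
#' `D` is a bounded symmetric premetric (the triangle inequality is not
#' guaranteed).
#'
#' @param p,q named character vectors of genotype tokens over the same
#'   marker set.
#' @return numeric distance in `[0, 1]`.
#' @export
allele_sharing_distance <- function(p, q) {
  if (!setequal(names(p), names(q)) || length(p) != length(q)) {
    stopf("profiles cover different marker sets")
  }
  q <- q[names(p)]
  sh <- vapply(seq_along(p), function(i) {
    shared_fraction(token_alleles(p[[i]]), token_alleles(q[[i]]))
  }, numeric(1))
  1 - mean(sh)
}

# classes x classes x loci array of per-locus shared fractions
pairwise_shared_array <- function(profiles) {
  n <- nrow(profiles); L <- ncol(profiles)
  al <- array(list(), dim = c(n, L))
  for (i in seq_len(n)) for (l in seq_len(L)) {
    al[[i, l]] <- token_alleles(profiles[i, l])
  }
  arr <- array(1, dim = c(n, n, L))
  for (l in seq_len(L)) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      s <- shared_fraction(al[[i, l]], al[[j, l]])
      arr[i, j, l] <- s; arr[j, i, l] <- s
    }
  }
  dimnames(arr) <- list(rownames(profiles), rownames(profiles), colnames(profiles))
  arr
}

dist_from_shared <- function(arr, loci = seq_len(dim(arr)[3])) {
  m <- 1 - apply(arr[, , loci, drop = FALSE], c(1, 2), mean)
  diag(m) <- 0
  m
}

#' Allele-sharing distance matrix of genotype classes
#'
#' @param classes a `genotype_classes` object, or a character matrix of
#'   profiles (rows labelled).
#' @param reference optional named character vector: a reference profile
#'   (e.g. homozygous-reference at every marker) appended under label
#'   `"REF"`.
#' @return symmetric numeric matrix with zero diagonal.
#' @export
class_distance_matrix <- function(classes, reference = NULL) {
  prof <- if (inherits(classes, "genotype_classes")) {
    class_profile_matrix(classes)
  } else {
    as.matrix(classes)
  }
  if (!is.null(reference)) {
    reference <- reference[colnames(prof)]
    prof <- rbind(prof, REF = reference)
  }
  dist_from_shared(pairwise_shared_array(prof))
}
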