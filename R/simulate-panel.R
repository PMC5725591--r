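#' Default genotype-class profile matrix
#'
#' A synthetic reconstruction of the seven multilocus genotype classes
#' (A-G) of a 98-accession 'Nebbiolo' panel over 10 SNV markers. Only the
#' textually stated constraints are encoded: Ne_SNV1 and Ne_SNV14 are
#' each private to class A; the composite chimeric states at Ne_SNV31,
#' Ne_SNV33 and Ne_SNV62 are each private to class E; class C is
#' separated from its nearest neighbours only through Ne_SNV2 and
#' Ne_SNV12. Ne_SNV7 and Ne_SNV81 are placeholder marker names (the
#' published panel's full profile matrix is not reproduced here). The
#' matrix is constructed so that the smallest discriminating marker
#' subset has size 6.
#'
#' @return 7 x 10 character matrix of genotype tokens, rows `A`..`G`.
#' @export
default_class_profiles <- function() {
  markers <- c("Ne_SNV1", "Ne_SNV2", "Ne_SNV7", "Ne_SNV10", "Ne_SNV12",
               "Ne_SNV14", "Ne_SNV31", "Ne_SNV33", "Ne_SNV62", "Ne_SNV81")
  m <- rbind(
    A = c("GA", "CC", "TT", "AA", "CT", "CG", "CC",    "GG",    "TT",    "CC"),
    B = c("GG", "CC", "TT", "AA", "CT", "GG", "CC",    "GG",    "TT",    "CC"),
    C = c("GG", "CT", "TT", "AA", "CT", "GG", "CC",    "GG",    "TT",    "CC"),
    D = c("GG", "CC", "TT", "AA", "TT", "GG", "CC",    "GG",    "TT",    "CC"),
    E = c("GG", "CC", "TT", "AA", "TT", "GG", "CC~CT", "GG~AG", "TT~CT", "CC"),
    F = c("GG", "CC", "TT", "AG", "TT", "GG", "CC",    "GG",    "TT",    "CC"),
    G = c("GG", "CC", "TT", "AG", "TT", "GG", "CC",    "GG",    "TT",    "AC")
  )
  colnames(m) <- markers
  m
}

#' Reference (wild-type) marker profile
#'
#' A homozygous profile standing in for the reference genome in
#' relationship analyses; distinct from every class profile of
#' [default_class_profiles]. Labelled synthetic: the published assays do
#' not print the reference calls for all markers.
#'
#' @return named character vector of tokens.
#' @export
default_reference_profile <- function() {
  c(Ne_SNV1 = "GG", Ne_SNV2 = "CC", Ne_SNV7 = "GG", Ne_SNV10 = "AA",
    Ne_SNV12 = "CC", Ne_SNV14 = "GG", Ne_SNV31 = "TT", Ne_SNV33 = "AA",
    Ne_SNV62 = "CC", Ne_SNV81 = "CC")
}

#' Panel simulation configuration
#'
#' Class membership counts default to the published constraint set:
#' A = 1, B = 31, C = 2, D = 31, E = 2 accessions, with the remaining 31
#' split F = 21, G = 10 (the published material does not state the F/G
#' split; the 21/10 division is a generator default).
#'
#' @param n_accessions panel size (default 98).
#' @param class_profiles class x marker token matrix (profiles must be
#'   pairwise distinct).
#' @param class_counts named accession counts per class, summing to
#'   `n_accessions`.
#' @param seed RNG seed.
#' @return object of class `panel_sim_config`.
#' @export
panel_sim_config <- function(n_accessions = 98,
                             class_profiles = default_class_profiles(),
                             class_counts = c(A = 1, B = 31, C = 2, D = 31,
                                              E = 2, F = 21, G = 10),
                             seed = 7) {
  stopifnot(sum(class_counts) == n_accessions,
            setequal(names(class_counts), rownames(class_profiles)))
  if (anyDuplicated(apply(class_profiles, 1, paste, collapse = "|"))) {
    stopf("class profiles must be pairwise distinct")
  }
  structure(list(n_accessions = n_accessions,
                 class_profiles = class_profiles,
                 class_counts = class_counts, seed = seed),
            class = "panel_sim_config")
}

#' Generate a synthetic accession x marker panel
#'
#' Accessions are assigned to classes per the configured counts, shuffled
#' into a random order, and emitted with the full profile of their class
#' (chimeric states as composite tokens).
#'
#' @param config a [panel_sim_config].
#' @param dir optional output directory; writes `panel.csv` and
#'   `panel_truth.csv`.
#' @return list with `panel` (data frame: accession + one column per
#'   marker), `truth` (accession -> class data frame) and `paths` when
#'   `dir` was given.
#' @export
generate_panel <- function(config = panel_sim_config(), dir = NULL) {
  stopifnot(inherits(config, "panel_sim_config"))
  set.seed(config$seed)
  classes <- rep(names(config$class_counts), config$class_counts)
  classes <- sample(classes)
  acc <- sprintf("NB%03d", seq_len(config$n_accessions))
  prof <- config$class_profiles[classes, , drop = FALSE]
  panel <- data.frame(accession = acc, prof, check.names = FALSE,
                      row.names = NULL, stringsAsFactors = FALSE)
  truth <- data.frame(accession = acc, class = classes,
                      stringsAsFactors = FALSE)
  out <- list(panel = panel, truth = truth, config = config)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(panel = file.path(dir, "panel.csv"),
                  truth = file.path(dir, "panel_truth.csv"))
    utils::write.csv(panel, paths$panel, row.names = FALSE)
    utils::write.csv(truth, paths$truth, row.names = FALSE)
    out$paths <- paths
  }
  out
}
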