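#' Chimera assay simulation configuration
#'
#' Layer genotypes are alternate-allele dosages per diploid layer
#' (0, 1 or 2); tissue weights are L1 cell fractions, defaulting to the
#' standard ontogeny (leaf and berry skin from both layers, berry flesh
#' from L2 only). The default locus set mirrors a 10-marker assay of a
#' periclinal chimera: three loci heterozygous in L1 but homozygous in
#' L2, the rest layer-concordant.
#'
#' @param layer_genotypes named list, locus -> `c(l1, l2)` dosages.
#' @param tissue_weights named numeric vector of L1 fractions.
#' @param noise_sd standard deviation of Gaussian fraction noise
#'   (default 0.03); observed fractions are truncated to `[0, 1]`.
#' @param seed RNG seed.
#' @return object of class `chimera_sim_config`.
#' @export
chimera_sim_config <- function(layer_genotypes = default_layer_genotypes(),
                               tissue_weights = c(LEAF = 0.5, SKIN = 0.5,
                                                  FLESH = 0),
                               noise_sd = 0.03, seed = 3) {
  stopifnot(all(vapply(layer_genotypes, length, integer(1)) == 2),
            all(unlist(layer_genotypes) %in% 0:2),
            all(tissue_weights >= 0 & tissue_weights <= 1),
            noise_sd >= 0)
  structure(list(layer_genotypes = layer_genotypes,
                 tissue_weights = tissue_weights,
                 noise_sd = noise_sd, seed = seed),
            class = "chimera_sim_config")
}

#' Default layer-genotype truth: a CVT 185-like periclinal chimera
#'
#' Three loci heterozygous in L1 over a homozygous-reference L2 (the
#' intermediate-fraction signature), seven layer-concordant loci.
#'
#' @return named list, locus -> `c(l1, l2)` dosages.
#' @export
default_layer_genotypes <- function() {
  list(Ne_SNV31 = c(1, 0), Ne_SNV33 = c(1, 0), Ne_SNV62 = c(1, 0),
       Ne_SNV1 = c(0, 0), Ne_SNV2 = c(1, 1), Ne_SNV7 = c(2, 2),
       Ne_SNV10 = c(1, 1), Ne_SNV12 = c(0, 0), Ne_SNV14 = c(2, 2),
       Ne_SNV81 = c(1, 1))
}

#' All nine (L1, L2) dosage pairs, replicated per locus
#'
#' Truth grid for parameter-recovery simulations: `loci_per_pair` loci
#' for each of the nine layer-genotype combinations.
#'
#' @param loci_per_pair loci per (L1, L2) pair (default 50).
#' @return named list, locus -> `c(l1, l2)` dosages.
#' @export
layer_genotype_grid <- function(loci_per_pair = 50) {
  out <- list()
  for (l1 in 0:2) for (l2 in 0:2) {
    for (r in seq_len(loci_per_pair)) {
      out[[sprintf("P%d%d_%03d", l1, l2, r)]] <- c(l1, l2)
    }
  }
  out
}

#' Generate noisy tissue allelic-fraction assays
#'
#' Per locus and tissue the observed alternate-allele fraction is
#' `alpha_t * l1/2 + (1 - alpha_t) * l2/2 + N(0, noise_sd)`, truncated to
#' `[0, 1]`.
#'
#' @param config a [chimera_sim_config].
#' @param dir optional output directory; writes `assays.csv` and
#'   `layer_truth.csv`.
#' @return list with `assays` (data frame: locus, tissue, alt_fraction),
#'   `truth` (locus, l1_dosage, l2_dosage) and `paths` when `dir` was
#'   given.
#' @export
generate_chimera_assays <- function(config = chimera_sim_config(), dir = NULL) {
  stopifnot(inherits(config, "chimera_sim_config"))
  set.seed(config$seed)
  loci <- names(config$layer_genotypes)
  tissues <- names(config$tissue_weights)
  grid <- expand.grid(locus = loci, tissue = tissues,
                      stringsAsFactors = FALSE)
  l1 <- vapply(config$layer_genotypes[grid$locus], `[`, numeric(1), 1) / 2
  l2 <- vapply(config$layer_genotypes[grid$locus], `[`, numeric(1), 2) / 2
  alpha <- config$tissue_weights[grid$tissue]
  f <- expected_fraction(l1, l2, alpha) +
    stats::rnorm(nrow(grid), 0, config$noise_sd)
  grid$alt_fraction <- pmin(1, pmax(0, f))
  truth <- data.frame(
    locus = loci,
    l1_dosage = vapply(config$layer_genotypes, `[`, numeric(1), 1),
    l2_dosage = vapply(config$layer_genotypes, `[`, numeric(1), 2),
    row.names = NULL, stringsAsFactors = FALSE
  )
  out <- list(assays = grid, truth = truth, config = config)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(assays = file.path(dir, "assays.csv"),
                  truth = file.path(dir, "layer_truth.csv"))
    utils::write.csv(grid, paths$assays, row.names = FALSE)
    utils::write.csv(truth, paths$truth, row.names = FALSE)
    out$paths <- paths
  }
  out
}
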