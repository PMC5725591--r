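#' Chimera model configuration
#'
#' Linear-mixing model for tissue allelic fractions in a plant with
#' distinct meristem cell layers: a tissue with L1 cell fraction
#' `alpha` and layer genotypes contributing expected alternate-allele
#' fractions `L1`, `L2` (each 0, 0.5 or 1 for a diploid layer) shows
#' `alpha * L1 + (1 - alpha) * L2`. Defaults reflect leaf and berry skin
#' deriving from both layers (alpha 0.5) and berry flesh from L2 only
#' (alpha 0). The layer proportions of mixed tissues are assumptions, not
#' measurements; any alpha in (0, 1) reproduces the qualitative
#' intermediate-cluster pattern.
#'
#' @param tissue_weights named numeric vector of L1 fractions per tissue.
#' @param state_space expected per-layer fractions (default 0, 0.5, 1).
#' @param call_thresholds banded single-tissue calling thresholds: list
#'   with `hom_ref` (upper bound), `het` (interval), `hom_alt` (lower
#'   bound).
#' @param decision_margin minimum squared-error improvement a chimeric
#'   solution must achieve over the best non-chimeric one (default 0.01);
#'   ties resolve to non-chimeric.
#' @return object of class `chimera_config`.
#' @export
chimera_config <- function(tissue_weights = c(LEAF = 0.5, SKIN = 0.5, FLESH = 0),
                           state_space = c(0, 0.5, 1),
                           call_thresholds = list(hom_ref = 0.15,
                                                  het = c(0.35, 0.65),
                                                  hom_alt = 0.85),
                           decision_margin = 0.01) {
  stopifnot(all(tissue_weights >= 0 & tissue_weights <= 1),
            !is.null(names(tissue_weights)),
            call_thresholds$hom_ref < call_thresholds$het[1],
            call_thresholds$het[1] < call_thresholds$het[2],
            call_thresholds$het[2] < call_thresholds$hom_alt,
            decision_margin >= 0)
  structure(list(tissue_weights = tissue_weights, state_space = state_space,
                 call_thresholds = call_thresholds,
                 decision_margin = decision_margin),
            class = "chimera_config")
}

#' Expected allelic fraction under the layer-mixing model
#'
#' @param l1_state,l2_state expected alternate-allele fraction of each
#'   layer (in `[0, 1]`).
#' @param alpha L1 cell fraction of the tissue (in `[0, 1]`).
#' @return `alpha * l1_state + (1 - alpha) * l2_state`.
#' @export
expected_fraction <- function(l1_state, l2_state, alpha) {
  stopifnot(all(l1_state >= 0 & l1_state <= 1),
            all(l2_state >= 0 & l2_state <= 1),
            all(alpha >= 0 & alpha <= 1))
  alpha * l1_state + (1 - alpha) * l2_state
}

#' Banded genotype call from a single allelic fraction
#'
#' @param f observed alternate-allele fraction in `[0, 1]`.
#' @param thresholds `call_thresholds` list as in [chimera_config].
#' @return character vector over `HOM_REF`, `HET`, `HOM_ALT`,
#'   `INTERMEDIATE` — the last for fractions between the bands, the
#'   signature of a layer-discordant (chimeric) locus in mixed tissue.
#' @export
call_state <- function(f, thresholds = chimera_config()$call_thresholds) {
  stopifnot(all(f >= 0 & f <= 1))
  out <- rep("INTERMEDIATE", length(f))
  out[f <= thresholds$hom_ref] <- "HOM_REF"
  out[f >= thresholds$het[1] & f <= thresholds$het[2]] <- "HET"
  out[f >= thresholds$hom_alt] <- "HOM_ALT"
  out
}

#' Infer per-layer genotypes from tissue allelic fractions
#'
#' Exhaustive least-squares search over the 9 (L1, L2) state pairs for
#' one locus: the pair minimising the sum of squared deviations between
#' observed and expected fractions across tissues is returned. A chimeric
#' call (L1 != L2) is made only when the best chimeric solution improves
#' on the best layer-concordant one by at least the decision margin;
#' otherwise the best non-chimeric pair is reported (conservative
#' calling). States 0 and 1 are flagged as indistinguishable between a
#' homozygous and a hemizygous layer: allelic fractions carry no copy
#' number.
#'
#' @param assays data frame with columns `tissue` and `alt_fraction` for
#'   one locus (a `locus` column, if present, must be constant).
#' @param config a [chimera_config].
#' @return object of class `chimera_inference`: list with `locus`,
#'   `l1_state`, `l2_state`, `is_chimera`, `residual` (SSE of the
#'   reported pair), `margin` (SSE improvement of the best chimeric over
#'   the best non-chimeric pair) and `note`.
#' @export
infer_layer_genotypes <- function(assays, config = chimera_config()) {
  stopifnot(is.data.frame(assays), nrow(assays) >= 2)
  if (!is.null(assays$locus) && length(unique(assays$locus)) > 1) {
    stopf("infer_layer_genotypes works on a single locus")
  }
  tissues <- as.character(assays$tissue)
  unknown <- setdiff(tissues, names(config$tissue_weights))
  if (length(unknown)) stopf("unknown tissue name: %s", unknown[1])
  alpha <- config$tissue_weights[tissues]
  if (length(unique(alpha)) < 2) {
    stopf("unidentifiable configuration: all assayed tissues have the same L1 fraction")
  }
  f <- assays$alt_fraction
  stopifnot(all(f >= 0 & f <= 1))

  grid <- expand.grid(l1 = config$state_space, l2 = config$state_space)
  grid$sse <- vapply(seq_len(nrow(grid)), function(i) {
    sum((f - expected_fraction(grid$l1[i], grid$l2[i], alpha))^2)
  }, numeric(1))
  chim <- grid$l1 != grid$l2
  best_non <- grid[!chim, ][which.min(grid$sse[!chim]), ]
  best_chi <- grid[chim, ][which.min(grid$sse[chim]), ]
  margin <- best_non$sse - best_chi$sse
  if (margin >= config$decision_margin) best <- best_chi else best <- best_non

  ambiguous <- best$l1 %in% c(0, 1) || best$l2 %in% c(0, 1)
  structure(
    list(locus = if (!is.null(assays$locus)) assays$locus[1] else NA_character_,
         l1_state = best$l1, l2_state = best$l2,
         is_chimera = best$l1 != best$l2, residual = best$sse,
         margin = margin,
         note = if (ambiguous) "hom/hemizygous indistinguishable" else ""),
    class = "chimera_inference"
  )
}

#' @export
print.chimera_inference <- function(x, ...) {
  cat(sprintf("<chimera_inference> %s: L1=%g L2=%g %s (SSE %.4g)%s\n",
              x$locus, x$l1_state, x$l2_state,
              if (x$is_chimera) "CHIMERIC" else "concordant",
              x$residual,
              if (nzchar(x$note)) paste0(" [", x$note, "]") else ""))
  invisible(x)
}

#' Infer layer genotypes for every locus of an assay table
#'
#' @param assays data frame with columns `locus`, `tissue`,
#'   `alt_fraction`.
#' @param config a [chimera_config].
#' @return data frame with one row per locus: `locus`, `l1_state`,
#'   `l2_state`, `is_chimera`, `residual`, `note`.
#' @export
infer_chimeras <- function(assays, config = chimera_config()) {
  loci <- unique(assays$locus)
  rows <- lapply(loci, function(lc) {
    inf <- infer_layer_genotypes(assays[assays$locus == lc, , drop = FALSE],
                                 config)
    data.frame(locus = lc, l1_state = inf$l1_state, l2_state = inf$l2_state,
               is_chimera = inf$is_chimera, residual = inf$residual,
               note = inf$note, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
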