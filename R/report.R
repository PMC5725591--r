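#' Render a partition summary as text or JSON
#'
#' The text layout mirrors the standard three-clone concordance table:
#' genotype-category rows, one clone-specific column per clone, a
#' varietal column and totals, with the varietal percentage printed to
#' one decimal. The JSON twin carries exact integers and the full-
#' precision fraction.
#'
#' @param summary a `partition_summary`.
#' @param format `"text"` (character vector of lines) or `"json"`
#'   (JSON string).
#' @return character vector (text) or a JSON string.
#' @export
render_partition_report <- function(summary, format = c("text", "json")) {
  format <- match.arg(format)
  stopifnot(inherits(summary, "partition_summary"))
  m <- summary$counts
  if (format == "json") {
    obj <- list(
      counts = as.data.frame.table(m, responseName = "count",
                                   stringsAsFactors = FALSE),
      clone_specific_total = sum(m[c("HOM_REF", "HOM_ALT", "HET"),
                                   summary$clones]),
      varietal_total = sum(m[, "VARIETAL"]),
      excluded = unname(m["EXCLUDED", "TOTAL"]),
      total = summary$total,
      varietal_fraction = summary$varietal_fraction
    )
    return(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA))
  }
  fmtn <- function(x) format(x, big.mark = ",", trim = TRUE)
  header <- c("Genotype", summary$clones, "Varietal", "Total")
  rows <- list(header)
  for (r in rownames(m)) {
    rows[[length(rows) + 1]] <- c(r, fmtn(m[r, summary$clones]),
                                  fmtn(m[r, "VARIETAL"]), fmtn(m[r, "TOTAL"]))
  }
  totals <- colSums(m)
  rows[[length(rows) + 1]] <- c("TOTAL", fmtn(totals[summary$clones]),
                                fmtn(totals[["VARIETAL"]]),
                                fmtn(totals[["TOTAL"]]))
  widths <- apply(matrix(nchar(unlist(rows)), ncol = length(header),
                         byrow = TRUE), 2, max)
  lines <- vapply(rows, function(r) {
    paste(mapply(formatC, r, width = widths,
                 MoreArgs = list(flag = "-")), collapse = "  ")
  }, "")
  pct <- if (is.na(summary$varietal_fraction)) "n/a"
         else sprintf("%.1f%%", 100 * summary$varietal_fraction)
  c(lines, sprintf("Varietal fraction: %s", pct))
}

#' Render an effect summary as JSON
#'
#' @param summary an `effect_summary`.
#' @return JSON string with per-category counts, impact classes and the
#'   per-impact totals.
#' @export
render_effect_report <- function(summary) {
  stopifnot(inherits(summary, "effect_summary"))
  m <- summary$counts
  impact <- effect_impact(rownames(m))
  obj <- list(
    categories = data.frame(category = rownames(m), impact = impact,
                            het = m[, "HET"], hom_alt = m[, "HOM_ALT"],
                            total = m[, "TOTAL"], row.names = NULL,
                            stringsAsFactors = FALSE),
    impact_totals = as.list(tapply(m[, "TOTAL"], impact, sum))
  )
  jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' Drives every stage against generated inputs: cohort simulation, VCF
#' and mask round-trip through files, the filter cascade, concordance
#' partition with its report, transcript effect annotation with the
#' varietal-site effect summary, panel simulation and genotype-class
#' grouping with the minimal-marker search, the bootstrapped UPGMA tree,
#' the median-joining network, and chimera-assay simulation plus layer
#' inference. Every artifact is written under `out_dir` and listed in a
#' manifest with MD5 checksums; identical seeds give identical checksums.
#'
#' @param out_dir output directory (created if needed).
#' @param n_sites cohort sites to simulate (default 2000).
#' @param seed master seed; stage seeds are derived from it.
#' @param fail_rates per-rule planted failure fractions (see
#'   [cohort_sim_config]).
#' @param n_boot bootstrap replicates for the tree (default 1000).
#' @return the manifest, invisibly: list of artifact paths and MD5s.
#' @export
run_pipeline <- function(out_dir, n_sites = 2000, seed = 1,
                         fail_rates = c(IN_REPEAT = 0.01,
                                        SPURIOUS_ALLELE = 0.01,
                                        LOW_COVERAGE = 0.01, HIGH_FS = 0.01,
                                        LOW_QD = 0.01, BAD_READ_POS = 0.01,
                                        DISCORDANT_HOM = 0.01),
                         n_boot = 1000) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
  }
  log_line <- function(...) message(sprintf(...))

  log_line("[simulate] cohort of %d sites (seed %d)", n_sites, seed)
  sim <- stage("simulate", generate_cohort(
    cohort_sim_config(n_sites = n_sites, fail_rates = fail_rates,
                      seed = derive_seed(seed, 1)), dir = out_dir))

  log_line("[filter] recalibrated cascade")
  res <- stage("filter", {
    cohort <- read_vcf_multisample(sim$paths$vcf, sim$config$clones)
    mask <- read_region_mask(sim$paths$repeats)
    filter_cohort(cohort, mask, filter_params())
  })
  pass_vcf <- file.path(out_dir, "pass.vcf")
  write_vcf(res$passing, pass_vcf)
  utils::write.table(res$rejected_table, file.path(out_dir, "rejected.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(as.list(res$summary),
                       file.path(out_dir, "filter_summary.json"),
                       auto_unbox = TRUE, digits = NA)

  log_line("[partition] genotype concordance")
  labels <- stage("partition", classify_cohort(res$passing))
  utils::write.table(labels, file.path(out_dir, "labels.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  psum <- tabulate_partition(labels, clones = sim$config$clones)
  writeLines(render_partition_report(psum, "text"),
             file.path(out_dir, "table_partition.txt"))
  writeLines(render_partition_report(psum, "json"),
             file.path(out_dir, "table_partition.json"))

  log_line("[annotate] transcript effects")
  effects <- stage("annotate",
                   annotate_cohort(res$passing, sim$genes, sim$genome))
  utils::write.table(effects, file.path(out_dir, "effects.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  var_sites <- labels$kind == "VARIETAL" &
    labels$reported_category %in% c("HET", "HOM_ALT")
  site_labels <- stats::setNames(labels$reported_category[var_sites],
                                 paste0(labels$chrom, ":", labels$pos)[var_sites])
  esum <- summarize_effects(effects[effects$site %in% names(site_labels), ,
                                    drop = FALSE], site_labels)
  writeLines(render_effect_report(esum), file.path(out_dir, "table_effects.json"))

  log_line("[classify] accession panel")
  pan <- stage("classify", generate_panel(
    panel_sim_config(seed = derive_seed(seed, 2)), dir = out_dir))
  classes <- group_profiles(pan$panel, canonical = TRUE)
  cls_df <- do.call(rbind, lapply(classes$classes, function(cl) {
    data.frame(label = cl$label, n = length(cl$members),
               profile = paste(cl$profile, collapse = "|"),
               members = paste(cl$members, collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(cls_df, file.path(out_dir, "classes.csv"), row.names = FALSE)
  subsets <- minimal_discriminating_subsets(classes)
  jsonlite::write_json(subsets, file.path(out_dir, "subsets.json"),
                       auto_unbox = TRUE, digits = NA)

  log_line("[tree] bootstrapped UPGMA (%d reps)", n_boot)
  boot <- stage("tree", bootstrap_support(
    rbind(class_profile_matrix(classes),
          REF = default_reference_profile()[classes$markers]),
    n_reps = n_boot, seed = derive_seed(seed, 3)))
  ape::write.tree(boot$tree, file.path(out_dir, "tree.nwk"))

  log_line("[network] median-joining")
  net <- stage("network", median_joining_network(classes))
  write_network_gml(net, file.path(out_dir, "network.gml"))

  log_line("[chimera] layer inference")
  chi <- stage("chimera", generate_chimera_assays(
    chimera_sim_config(seed = derive_seed(seed, 4)), dir = out_dir))
  inf <- infer_chimeras(chi$assays)
  utils::write.csv(inf, file.path(out_dir, "inferences.csv"), row.names = FALSE)

  files <- sort(setdiff(list.files(out_dir), "manifest.json"))
  manifest <- list(
    seed = seed, n_sites = n_sites, n_boot = n_boot,
    artifacts = lapply(files, function(f) {
      list(file = f,
           md5 = unname(tools::md5sum(file.path(out_dir, f))))
    })
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  log_line("[done] %d artifacts in %s", length(files) + 1, out_dir)
  invisible(manifest)
}
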