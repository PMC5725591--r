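effect_impact_map <- c(
  START_LOST = "HIGH", STOP_GAINED = "HIGH", STOP_LOST = "HIGH",
  SPLICE_SITE_ACCEPTOR = "HIGH", SPLICE_SITE_DONOR = "HIGH",
  NON_SYNONYMOUS_START = "LOW", SYNONYMOUS_CODING = "LOW",
  SYNONYMOUS_STOP = "LOW", START_GAINED = "LOW",
  NON_SYNONYMOUS_CODING = "MODERATE",
  DOWNSTREAM = "MODIFIER", INTRON = "MODIFIER", UPSTREAM = "MODIFIER",
  UTR_3_PRIME = "MODIFIER", UTR_5_PRIME = "MODIFIER"
)

#' Impact class of an effect category
#'
#' Fixed mapping from effect category to impact class: disruptive coding
#' and splice-site changes are `HIGH`; silent or start-related changes are
#' `LOW`; missense changes are `MODERATE`; non-coding placements are
#' `MODIFIER`.
#'
#' @param category character vector of effect categories.
#' @return character vector of impact classes.
#' @export
effect_impact <- function(category) {
  out <- effect_impact_map[category]
  if (anyNA(out)) stopf("unknown effect category: %s",
                        paste(category[is.na(out)], collapse = ","))
  unname(out)
}

comp_base <- function(x) chartr("ACGTacgt", "TGCAtgca", x)

genome_base <- function(genome, chrom, pos) {
  substring(genome[[chrom]], pos, pos)
}

# genome: named character vector (or coercible DNAStringSet) of chromosomes
as_genome <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) {
    stats::setNames(as.character(genome), names(genome))
  } else {
    stopifnot(is.character(genome), !is.null(names(genome)))
    genome
  }
}

#' Classify the transcript-level effects of one SNV
#'
#' Places a biallelic SNV against every transcript of a gene model and
#' reports one effect per transcript region hit, using the conventions of
#' transcript-structure annotators: `UPSTREAM`/`DOWNSTREAM` within a
#' 5,000-nt window of the transcription start/end (strand-aware);
#' `INTRON`, with the first and last two intronic bases called
#' `SPLICE_SITE_DONOR`/`SPLICE_SITE_ACCEPTOR`; `UTR_5_PRIME`/`UTR_3_PRIME`
#' for non-coding exonic positions (a 5'UTR change creating a new ATG on
#' the coding strand additionally yields `START_GAINED`); and coding
#' positions translated on the coding strand with the standard genetic
#' code — `START_LOST` for a disrupted initiator codon (or
#' `NON_SYNONYMOUS_START` when the alternate codon is in
#' `alternative_starts`), `STOP_LOST`/`SYNONYMOUS_STOP` at the terminator,
#' `STOP_GAINED` for a new premature stop, and
#' `SYNONYMOUS_CODING`/`NON_SYNONYMOUS_CODING` otherwise.
#'
#' @param chrom,pos,ref,alt the SNV (1-based position; single-base
#'   alleles).
#' @param gene a [gene_model].
#' @param genome named character vector (or `DNAStringSet`) of chromosome
#'   sequences.
#' @param flank upstream/downstream window in nt (default 5000).
#' @param alternative_starts character vector of codons accepted as
#'   alternative initiators (default none).
#' @return data frame with columns `gene_id`, `transcript_id`, `category`,
#'   `impact`, `ref_codon`, `alt_codon` (codons `NA` outside the CDS);
#'   zero rows when the variant lies outside the gene and its flanks.
#' @export
classify_effects <- function(chrom, pos, ref, alt, gene, genome,
                             flank = 5000, alternative_starts = character()) {
  if (nchar(ref) != 1 || nchar(alt) != 1) {
    stopf("classify_effects handles single-nucleotide variants only (got %s>%s)",
          ref, alt)
  }
  genome <- as_genome(genome)
  if (chrom != gene$chrom) return(empty_effects())
  obs <- genome_base(genome, chrom, pos)
  if (!identical(toupper(obs), toupper(ref))) {
    stopf("reference allele mismatch at %s:%d (genome %s, variant %s)",
          chrom, pos, obs, ref)
  }
  out <- lapply(gene$transcripts, function(tx) {
    classify_tx_effect(pos, ref, alt, gene, tx, genome, flank,
                       alternative_starts)
  })
  res <- do.call(rbind, out)
  if (is.null(res)) empty_effects() else res
}

empty_effects <- function() {
  data.frame(gene_id = character(), transcript_id = character(),
             category = character(), impact = character(),
             ref_codon = character(), alt_codon = character(),
             stringsAsFactors = FALSE)
}

effect_row <- function(gene, tx, category, ref_codon = NA_character_,
                       alt_codon = NA_character_) {
  data.frame(gene_id = gene$gene_id, transcript_id = tx$transcript_id,
             category = category, impact = effect_impact(category),
             ref_codon = ref_codon, alt_codon = alt_codon,
             stringsAsFactors = FALSE)
}

classify_tx_effect <- function(pos, ref, alt, gene, tx, genome, flank,
                               alternative_starts) {
  strand <- gene$strand
  tsp <- transcript_span(tx)
  if (pos < tsp[1] || pos > tsp[2]) {
    # flanking regions, strand-aware
    if (strand == "+") {
      if (pos >= tsp[1] - flank && pos < tsp[1]) return(effect_row(gene, tx, "UPSTREAM"))
      if (pos > tsp[2] && pos <= tsp[2] + flank) return(effect_row(gene, tx, "DOWNSTREAM"))
    } else {
      if (pos > tsp[2] && pos <= tsp[2] + flank) return(effect_row(gene, tx, "UPSTREAM"))
      if (pos >= tsp[1] - flank && pos < tsp[1]) return(effect_row(gene, tx, "DOWNSTREAM"))
    }
    return(NULL)
  }
  cds_pos <- intervals_to_positions(tx$cds)
  if (pos %in% cds_pos) {
    return(classify_coding(pos, ref, alt, gene, tx, cds_pos, genome,
                           alternative_starts))
  }
  introns <- transcript_introns(tx)
  for (i in seq_len(nrow(introns))) {
    s <- introns$start[i]; e <- introns$end[i]
    if (pos >= s && pos <= e) {
      donor <- if (strand == "+") pos <= s + 1L else pos >= e - 1L
      acceptor <- if (strand == "+") pos >= e - 1L else pos <= s + 1L
      cat <- if (donor) "SPLICE_SITE_DONOR"
             else if (acceptor) "SPLICE_SITE_ACCEPTOR"
             else "INTRON"
      return(effect_row(gene, tx, cat))
    }
  }
  utrs <- transcript_utrs(tx, strand)
  if (pos %in% utrs$utr5) {
    rows <- effect_row(gene, tx, "UTR_5_PRIME")
    if (creates_start(pos, alt, utrs$utr5, strand, genome, gene$chrom)) {
      rows <- rbind(rows, effect_row(gene, tx, "START_GAINED"))
    }
    return(rows)
  }
  if (pos %in% utrs$utr3) return(effect_row(gene, tx, "UTR_3_PRIME"))
  # exonic but outside any annotated CDS/UTR (non-coding transcript)
  NULL
}

# spliced, coding-strand sequence from genomic positions given in
# ascending genomic order
strand_seq <- function(genome, chrom, positions, strand) {
  bases <- vapply(positions, function(p) genome_base(genome, chrom, p), "")
  if (strand == "-") bases <- rev(comp_base(bases))
  paste(bases, collapse = "")
}

creates_start <- function(pos, alt, utr5_pos, strand, genome, chrom) {
  utr5_pos <- sort(utr5_pos)
  refseq <- strand_seq(genome, chrom, utr5_pos, strand)
  i <- if (strand == "+") match(pos, utr5_pos)
       else length(utr5_pos) - match(pos, utr5_pos) + 1L
  alt_base <- if (strand == "+") alt else comp_base(alt)
  altseq <- refseq
  substr(altseq, i, i) <- toupper(alt_base)
  n <- nchar(refseq)
  for (off in max(1, i - 2):min(i, n - 2)) {
    if (toupper(substr(altseq, off, off + 2)) == "ATG" &&
        toupper(substr(refseq, off, off + 2)) != "ATG") {
      return(TRUE)
    }
  }
  FALSE
}

classify_coding <- function(pos, ref, alt, gene, tx, cds_pos, genome,
                            alternative_starts) {
  strand <- gene$strand
  L <- length(cds_pos)
  idx_genomic <- match(pos, cds_pos)
  i <- if (strand == "+") idx_genomic else L - idx_genomic + 1L
  codon_no <- (i - 1L) %/% 3L + 1L
  n_codons <- L %/% 3L
  codon_coding_idx <- ((codon_no - 1L) * 3L + 1L):(codon_no * 3L)
  codon_genomic <- if (strand == "+") cds_pos[codon_coding_idx]
                   else cds_pos[L - codon_coding_idx + 1L]
  bases <- vapply(codon_genomic, function(p) genome_base(genome, gene$chrom, p), "")
  if (strand == "-") bases <- comp_base(bases)
  ref_codon <- toupper(paste(bases, collapse = ""))
  within <- i - (codon_no - 1L) * 3L
  alt_base <- toupper(if (strand == "+") alt else comp_base(alt))
  alt_codon <- ref_codon
  substr(alt_codon, within, within) <- alt_base

  code <- Biostrings::GENETIC_CODE
  ref_aa <- code[[ref_codon]]
  alt_aa <- code[[alt_codon]]
  category <- if (codon_no == 1L) {
    if (alt_codon %in% alternative_starts) "NON_SYNONYMOUS_START" else "START_LOST"
  } else if (codon_no == n_codons && ref_aa == "*") {
    if (alt_aa == "*") "SYNONYMOUS_STOP" else "STOP_LOST"
  } else if (alt_aa == "*") {
    "STOP_GAINED"
  } else if (ref_aa == alt_aa) {
    "SYNONYMOUS_CODING"
  } else {
    "NON_SYNONYMOUS_CODING"
  }
  effect_row(gene, tx, category, ref_codon, alt_codon)
}

#' Annotate every site of a cohort against a gene set
#'
#' @param cohort a `variant_cohort` of biallelic SNVs.
#' @param genes named list of [gene_model] objects.
#' @param genome named character vector or `DNAStringSet`.
#' @param flank upstream/downstream window (default 5000 nt).
#' @return data frame of effects with a leading `site` column
#'   (`chrom:pos`) plus the [classify_effects] columns.
#' @export
annotate_cohort <- function(cohort, genes, genome, flank = 5000) {
  genome <- as_genome(genome)
  spans <- do.call(rbind, lapply(genes, function(g) {
    sp <- gene_span(g)
    data.frame(gene = g$gene_id, chrom = g$chrom, start = sp[1], end = sp[2],
               stringsAsFactors = FALSE)
  }))
  gr <- GenomicRanges::GRanges(spans$chrom,
                               IRanges::IRanges(pmax(1L, spans$start - flank),
                                                spans$end + flank))
  q <- GenomicRanges::GRanges(cohort$sites$chrom,
                              IRanges::IRanges(cohort$sites$pos, cohort$sites$pos))
  hits <- GenomicRanges::findOverlaps(q, gr)
  out <- vector("list", length(hits))
  for (h in seq_along(hits)) {
    i <- S4Vectors::queryHits(hits)[h]
    g <- genes[[spans$gene[S4Vectors::subjectHits(hits)[h]]]]
    alt1 <- strsplit(cohort$sites$alt[i], ",")[[1]][1]
    eff <- classify_effects(cohort$sites$chrom[i], cohort$sites$pos[i],
                            cohort$sites$ref[i], alt1, g, genome, flank)
    if (nrow(eff)) {
      eff <- cbind(site = paste0(cohort$sites$chrom[i], ":", cohort$sites$pos[i]),
                   eff, stringsAsFactors = FALSE)
      out[[h]] <- eff
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    cbind(site = character(), empty_effects(), stringsAsFactors = FALSE)
  } else {
    res
  }
}

#' Summarise effects by category and genotype class
#'
#' Tabulates effect calls into a category x genotype summary restricted to
#' heterozygous and homozygous-alternate sites. A site contributes one
#' count per distinct (site, category) pair, so a variant hitting several
#' transcripts in the same way is counted once per category.
#'
#' @param effects data frame with columns `site` and `category`.
#' @param labels named character vector mapping site -> genotype category
#'   (`"HET"` or `"HOM_ALT"`).
#' @return object of class `effect_summary`: counts matrix with columns
#'   `HET`, `HOM_ALT`, `TOTAL`, one row per effect category.
#' @export
summarize_effects <- function(effects, labels) {
  cats <- names(effect_impact_map)
  if (nrow(effects) == 0) {
    m <- matrix(0L, length(cats), 3, dimnames = list(cats, c("HET", "HOM_ALT", "TOTAL")))
    return(structure(list(counts = m), class = "effect_summary"))
  }
  unlabeled <- setdiff(unique(effects$site), names(labels))
  if (length(unlabeled)) {
    stopf("no genotype label for site(s): %s",
          paste(utils::head(unlabeled, 3), collapse = ", "))
  }
  gl <- labels[effects$site]
  if (!all(gl %in% c("HET", "HOM_ALT"))) {
    stopf("labels must be HET or HOM_ALT")
  }
  uniq <- !duplicated(paste(effects$site, effects$category))
  t1 <- table(factor(effects$category[uniq], levels = cats),
              factor(gl[uniq], levels = c("HET", "HOM_ALT")))
  m <- cbind(as.matrix(t1)[, c("HET", "HOM_ALT")], TOTAL = rowSums(t1))
  storage.mode(m) <- "integer"
  structure(list(counts = m), class = "effect_summary")
}

#' @export
print.effect_summary <- function(x, ...) {
  m <- x$counts
  cat("<effect_summary>\n")
  df <- data.frame(CATEGORY = rownames(m), IMPACT = effect_impact(rownames(m)),
                   m, check.names = FALSE, row.names = NULL)
  print(df, row.names = FALSE)
  tot <- colSums(m)
  cat(sprintf("TOTAL: HET %d, HOM_ALT %d, ALL %d\n", tot[1], tot[2], tot[3]))
  invisible(x)
}

#' Genes carrying at least one high-impact effect
#'
#' @param effects data frame with columns `gene_id` and `impact`.
#' @return character vector of distinct gene identifiers.
#' @export
high_impact_genes <- function(effects) {
  sort(unique(effects$gene_id[effects$impact == "HIGH"]))
}
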