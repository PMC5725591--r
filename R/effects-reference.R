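#' Reference effect classifier (transcript rebuild)
#'
#' Slow, independent implementation of [classify_effects] used for
#' validation: instead of codon-index arithmetic it applies the variant to
#' a copy of the chromosome sequence, rebuilds each transcript's full
#' spliced CDS and UTRs from both the reference and the mutated genome,
#' translates both CDS with [Biostrings::translate] and diffs the
#' results. Region placement is decided by explicit membership in the
#' rebuilt exon/intron/UTR position sets.
#'
#' @inheritParams classify_effects
#' @return data frame with the same columns as [classify_effects].
#' @export
classify_effects_reference <- function(chrom, pos, ref, alt, gene, genome,
                                       flank = 5000,
                                       alternative_starts = character()) {
  genome <- as_genome(genome)
  if (chrom != gene$chrom) return(empty_effects())
  chrom_ref <- genome[[chrom]]
  chrom_alt <- chrom_ref
  substr(chrom_alt, pos, pos) <- alt

  out <- lapply(gene$transcripts, function(tx) {
    ref_tx_effect(pos, gene, tx, chrom_ref, chrom_alt, flank,
                  alternative_starts)
  })
  res <- do.call(rbind, out)
  if (is.null(res)) empty_effects() else res
}

# spliced sequence of a set of genomic intervals on the coding strand
splice_seq <- function(chrom_seq, iv, strand) {
  pieces <- vapply(seq_len(nrow(iv)), function(i) {
    substr(chrom_seq, iv$start[i], iv$end[i])
  }, "")
  s <- paste(pieces, collapse = "")
  if (strand == "-") {
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }
  s
}

ref_tx_effect <- function(pos, gene, tx, chrom_ref, chrom_alt, flank,
                          alternative_starts) {
  strand <- gene$strand
  ex <- tx$exons[order(tx$exons$start), , drop = FALSE]
  span_lo <- min(ex$start); span_hi <- max(ex$end)

  if (pos < span_lo || pos > span_hi) {
    five_side <- if (strand == "+") pos < span_lo else pos > span_hi
    dist <- if (pos < span_lo) span_lo - pos else pos - span_hi
    if (dist > flank) return(NULL)
    return(effect_row(gene, tx, if (five_side) "UPSTREAM" else "DOWNSTREAM"))
  }

  exon_pos <- intervals_to_positions(ex)
  if (!pos %in% exon_pos) {
    # intronic: locate the surrounding intron by scanning exon boundaries
    gaps <- transcript_introns(tx)
    hit <- which(pos >= gaps$start & pos <= gaps$end)
    s <- gaps$start[hit]; e <- gaps$end[hit]
    donor_pos <- if (strand == "+") c(s, s + 1L) else c(e, e - 1L)
    acceptor_pos <- if (strand == "+") c(e - 1L, e) else c(s + 1L, s)
    cat <- if (pos %in% donor_pos) "SPLICE_SITE_DONOR"
           else if (pos %in% acceptor_pos) "SPLICE_SITE_ACCEPTOR"
           else "INTRON"
    return(effect_row(gene, tx, cat))
  }

  cds <- tx$cds
  cds_pos <- intervals_to_positions(cds)
  if (!pos %in% cds_pos) {
    if (length(cds_pos) == 0) return(NULL)
    before_cds <- pos < min(cds_pos)
    utr5 <- if (strand == "+") before_cds else !before_cds
    if (!utr5) return(effect_row(gene, tx, "UTR_3_PRIME"))
    # 5' UTR: rebuild the spliced UTR from both genomes, diff ATG content
    cds_lo <- min(cds_pos); cds_hi <- max(cds_pos)
    utr_iv <- clip_intervals(ex, cds_lo, cds_hi, keep_left = before_cds)
    u_ref <- splice_seq(chrom_ref, utr_iv, strand)
    u_alt <- splice_seq(chrom_alt, utr_iv, strand)
    atg_at <- function(s) {
      hits <- gregexpr("ATG", s, fixed = TRUE)[[1]]
      hits[hits > 0]
    }
    rows <- effect_row(gene, tx, "UTR_5_PRIME")
    if (length(setdiff(atg_at(u_alt), atg_at(u_ref))) > 0) {
      rows <- rbind(rows, effect_row(gene, tx, "START_GAINED"))
    }
    return(rows)
  }

  cds_ref <- splice_seq(chrom_ref, cds, strand)
  cds_alt <- splice_seq(chrom_alt, cds, strand)
  prot_ref <- as.character(Biostrings::translate(Biostrings::DNAString(cds_ref)))
  prot_alt <- as.character(Biostrings::translate(Biostrings::DNAString(cds_alt)))
  n_codons <- nchar(cds_ref) %/% 3L
  codon_of <- function(s, i) substr(s, 3 * i - 2, 3 * i)
  changed <- which(vapply(seq_len(n_codons), function(i) {
    codon_of(cds_ref, i) != codon_of(cds_alt, i)
  }, logical(1)))
  i <- changed[1]
  ref_codon <- codon_of(cds_ref, i); alt_codon <- codon_of(cds_alt, i)
  ref_aa <- substr(prot_ref, i, i); alt_aa <- substr(prot_alt, i, i)
  category <- if (i == 1L) {
    if (alt_codon %in% alternative_starts) "NON_SYNONYMOUS_START" else "START_LOST"
  } else if (i == n_codons && ref_aa == "*") {
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

# exonic sub-intervals strictly left (or right) of the CDS span
clip_intervals <- function(iv, lo, hi, keep_left) {
  out <- data.frame(start = integer(), end = integer())
  for (i in seq_len(nrow(iv))) {
    s <- iv$start[i]; e <- iv$end[i]
    if (keep_left) {
      if (s < lo) out <- rbind(out, data.frame(start = s, end = min(e, lo - 1L)))
    } else {
      if (e > hi) out <- rbind(out, data.frame(start = max(s, hi + 1L), end = e))
    }
  }
  out
}
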