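# Miniature annotated genome for desk-scale validation: a few hundred kb
# of random sequence per chromosome, multi-exon genes with planted ATG
# start and TAA stop codons, and a repeat mask covering a set fraction of
# each chromosome.

random_dna <- function(n, gc = 0.35) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# random multi-exon gene structure inside [lo, hi]; returns NULL when the
# window is too small
random_gene_structure <- function(lo, hi, n_exons = NULL) {
  if (is.null(n_exons)) n_exons <- sample(2:4, 1)
  exon_len <- sample(150:400, n_exons, replace = TRUE)
  intron_len <- if (n_exons > 1) sample(200:600, n_exons - 1, replace = TRUE) else integer(0)
  total <- sum(exon_len) + sum(intron_len)
  if (hi - lo + 1 < total) return(NULL)
  start <- lo + sample.int(hi - lo + 2 - total, 1) - 1L
  ex_start <- integer(n_exons); ex_end <- integer(n_exons)
  cur <- start
  for (i in seq_len(n_exons)) {
    ex_start[i] <- cur
    ex_end[i] <- cur + exon_len[i] - 1L
    cur <- ex_end[i] + (if (i < n_exons) intron_len[i] else 0L) + 1L
  }
  data.frame(start = ex_start, end = ex_end)
}

# carve a CDS out of an exon chain: UTRs at both transcript ends, total
# CDS length forced to a codon multiple by adjusting the 3' cut
carve_cds <- function(exons, strand) {
  n <- nrow(exons)
  utr_a <- sample(30:90, 1)   # bases trimmed at the genomic-left end
  utr_b <- sample(30:90, 1)   # bases trimmed at the genomic-right end
  cds <- exons
  cds$start[1] <- cds$start[1] + utr_a
  cds$end[n] <- cds$end[n] - utr_b
  len <- sum(cds$end - cds$start + 1)
  rem <- len %% 3
  if (rem > 0) {
    # shrink at the 3' (transcription) end so codon 1 stays put
    if (strand == "+") cds$end[n] <- cds$end[n] - rem
    else cds$start[1] <- cds$start[1] + rem
  }
  cds
}

plant_codon <- function(seq, positions, codon) {
  # positions in genomic order; codon given on the coding strand
  for (i in seq_along(positions)) {
    substr(seq, positions[i], positions[i]) <- substr(codon, i, i)
  }
  seq
}

#' Simulate an annotated miniature genome
#'
#' Generates random chromosome sequences, multi-exon protein-coding gene
#' models on both strands (start and stop codons planted into the
#' sequence so every CDS begins with ATG and ends with TAA on its coding
#' strand), and a repeat mask covering roughly `repeat_fraction` of each
#' chromosome, avoiding gene bodies.
#'
#' @param n_chrom number of chromosomes (default 2).
#' @param chrom_len length of each chromosome in bp (default 250000).
#' @param genes_per_chrom gene models per chromosome (default 20).
#' @param repeat_fraction fraction of each chromosome masked as repeat
#'   (default 0.10).
#' @param gc GC content of the random sequence (default 0.35).
#' @return list with `genome` (named character vector), `genes` (named
#'   list of [gene_model]) and `mask` (a [region_mask]). Uses the current
#'   RNG state; seed upstream for reproducibility.
#' @export
simulate_annotated_genome <- function(n_chrom = 2, chrom_len = 250000,
                                      genes_per_chrom = 20,
                                      repeat_fraction = 0.10, gc = 0.35) {
  genome <- character(n_chrom)
  names(genome) <- paste0("chr", seq_len(n_chrom))
  genes <- list()
  mask_rows <- list()
  for (ch in seq_len(n_chrom)) {
    chrom <- names(genome)[ch]
    seq <- random_dna(chrom_len, gc)
    # regular gene windows with intergenic spacers at both ends
    win <- floor(chrom_len / (genes_per_chrom + 1))
    for (g in seq_len(genes_per_chrom)) {
      lo <- (g - 1L) * win + 1000L
      hi <- g * win - 1000L
      exons <- random_gene_structure(lo, hi)
      if (is.null(exons)) next
      strand <- sample(c("+", "-"), 1)
      cds <- carve_cds(exons, strand)
      cds_pos <- intervals_to_positions(cds)
      L <- length(cds_pos)
      start_pos <- if (strand == "+") cds_pos[1:3] else cds_pos[(L - 2):L]
      stop_pos <- if (strand == "+") cds_pos[(L - 2):L] else cds_pos[1:3]
      seq <- plant_codon(seq, start_pos, if (strand == "+") "ATG" else "CAT")
      seq <- plant_codon(seq, stop_pos, if (strand == "+") "TAA" else "TTA")
      gid <- sprintf("GENE%s_%02d", toupper(chrom), g)
      genes[[gid]] <- gene_model(
        gid, chrom, strand,
        list(list(transcript_id = paste0(gid, ".1"), exons = exons, cds = cds))
      )
    }
    genome[[ch]] <- seq
    # repeats in the intergenic spacers between gene windows
    n_rep <- max(1L, round(repeat_fraction * chrom_len / 800))
    rep_at <- sort(sample.int(genes_per_chrom + 1, min(n_rep, genes_per_chrom + 1)))
    for (r in rep_at) {
      centre <- (r - 1L) * win + 500L
      width <- round(repeat_fraction * chrom_len / length(rep_at))
      s0 <- max(0L, centre - width %/% 2)
      mask_rows[[length(mask_rows) + 1]] <-
        data.frame(chrom = chrom, start = s0,
                   end = min(chrom_len, s0 + width))
    }
  }
  bed <- do.call(rbind, mask_rows)
  list(genome = genome, genes = genes,
       mask = region_mask(bed$chrom, bed$start, bed$end))
}

#' Write a genome as FASTA
#'
#' @param genome named character vector of sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  dss <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(dss, path)
  invisible(path)
}

#' Read a genome FASTA into a named character vector
#'
#' @param path FASTA file path.
#' @return named character vector of sequences.
#' @export
read_genome_fasta <- function(path) {
  dss <- Biostrings::readDNAStringSet(path)
  names(dss) <- sub("\\s.*$", "", names(dss))
  as_genome(dss)
}
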