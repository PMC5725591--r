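#' Construct a gene model
#'
#' Coordinates are 1-based closed throughout (GFF3 convention). Exons must
#' be sorted and non-overlapping; CDS intervals must fall inside exons. A
#' total CDS length not divisible by 3 is flagged with a warning (real
#' annotations can violate phase) but is not fatal.
#'
#' @param gene_id gene identifier.
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param transcripts list of transcripts; each a list with
#'   `transcript_id`, `exons` and `cds`, the latter two data frames with
#'   columns `start`, `end`.
#' @return object of class `gene_model`.
#' @export
gene_model <- function(gene_id, chrom, strand, transcripts) {
  stopifnot(strand %in% c("+", "-"), length(transcripts) >= 1)
  for (tx in transcripts) {
    ex <- tx$exons
    stopifnot(all(ex$start <= ex$end))
    if (nrow(ex) > 1) {
      o <- order(ex$start)
      if (any(ex$start[o][-1] <= ex$end[o][-nrow(ex)])) {
        stopf("overlapping exons in transcript %s", tx$transcript_id)
      }
    }
    if (nrow(tx$cds) > 0) {
      cds_pos <- intervals_to_positions(tx$cds)
      if (!all(cds_pos %in% intervals_to_positions(ex))) {
        stopf("CDS outside exons in transcript %s", tx$transcript_id)
      }
      if (length(cds_pos) %% 3 != 0) {
        warning(sprintf("CDS length of %s not divisible by 3",
                        tx$transcript_id), call. = FALSE)
      }
    }
  }
  structure(list(gene_id = gene_id, chrom = chrom, strand = strand,
                 transcripts = transcripts),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s %s:%d-%d (%s), %d transcript(s)\n",
              x$gene_id, x$chrom, gene_span(x)[1], gene_span(x)[2],
              x$strand, length(x$transcripts)))
  invisible(x)
}

intervals_to_positions <- function(iv) {
  if (nrow(iv) == 0) return(integer())
  unlist(mapply(seq.int, iv$start, iv$end, SIMPLIFY = FALSE), use.names = FALSE)
}

gene_span <- function(gene) {
  ex <- do.call(rbind, lapply(gene$transcripts, function(tx) tx$exons))
  c(min(ex$start), max(ex$end))
}

transcript_span <- function(tx) c(min(tx$exons$start), max(tx$exons$end))

# transcription start site honours strand: highest coordinate on "-"
transcript_tss <- function(tx, strand) {
  sp <- transcript_span(tx)
  if (strand == "+") sp[1] else sp[2]
}

# introns as a data frame of 1-based closed gaps between sorted exons
transcript_introns <- function(tx) {
  ex <- tx$exons[order(tx$exons$start), , drop = FALSE]
  if (nrow(ex) < 2) return(data.frame(start = integer(), end = integer()))
  data.frame(start = ex$end[-nrow(ex)] + 1L, end = ex$start[-1] - 1L)
}

# UTR positions: exonic positions outside the CDS span, split by strand side
transcript_utrs <- function(tx, strand) {
  ex_pos <- intervals_to_positions(tx$exons)
  if (nrow(tx$cds) == 0) {
    return(list(utr5 = integer(), utr3 = integer()))
  }
  cds_lo <- min(tx$cds$start); cds_hi <- max(tx$cds$end)
  left <- ex_pos[ex_pos < cds_lo]
  right <- ex_pos[ex_pos > cds_hi]
  if (strand == "+") list(utr5 = left, utr3 = right)
  else list(utr5 = right, utr3 = left)
}

#' Read gene models from a GFF3 file
#'
#' Accepts GFF3 with gene/mRNA/exon/CDS (and optional UTR) features linked
#' by `Parent` attributes; 1-based closed coordinates are preserved. UTRs
#' are derived from exon/CDS structure rather than trusted from the file.
#'
#' @param path GFF3 file path.
#' @return named list of [gene_model] objects.
#' @export
read_gff3_genes <- function(path) {
  gff <- rtracklayer::readGFF(path,
                              columns = c("seqid", "type", "start", "end", "strand"),
                              tags = c("ID", "Parent"))
  tab <- data.frame(
    seqid = as.character(gff$seqid), type = as.character(gff$type),
    start = as.integer(gff$start), end = as.integer(gff$end),
    strand = as.character(gff$strand),
    id = as.character(gff$ID),
    parent = vapply(gff$Parent, function(p) {
      if (length(p)) p[[1]] else NA_character_
    }, character(1)),
    stringsAsFactors = FALSE
  )

  genes <- tab[tab$type == "gene", ]
  mrnas <- tab[tab$type == "mRNA", ]
  exons <- tab[tab$type == "exon", ]
  cds <- tab[tab$type == "CDS", ]
  orphan <- !cds$parent %in% mrnas$id
  if (any(orphan)) {
    stopf("CDS feature without an mRNA parent (Parent=%s)",
          cds$parent[which(orphan)[1]])
  }
  out <- lapply(seq_len(nrow(genes)), function(g) {
    gid <- genes$id[g]
    mx <- mrnas[mrnas$parent == gid, , drop = FALSE]
    txs <- lapply(seq_len(nrow(mx)), function(t) {
      tid <- mx$id[t]
      ex <- exons[exons$parent == tid, c("start", "end")]
      cd <- cds[cds$parent == tid, c("start", "end")]
      list(transcript_id = tid,
           exons = ex[order(ex$start), , drop = FALSE],
           cds = cd[order(cd$start), , drop = FALSE])
    })
    gene_model(gid, genes$seqid[g], genes$strand[g], txs)
  })
  names(out) <- genes$id
  out
}

#' Write gene models as GFF3
#'
#' @param genes named list of [gene_model] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gff3_genes <- function(genes, path) {
  rows <- character()
  line <- function(chrom, type, s, e, strand, attr) {
    sprintf("%s\tclonotyper\t%s\t%d\t%d\t.\t%s\t.\t%s",
            chrom, type, s, e, strand, attr)
  }
  for (g in genes) {
    sp <- gene_span(g)
    rows <- c(rows, line(g$chrom, "gene", sp[1], sp[2], g$strand,
                         paste0("ID=", g$gene_id)))
    for (tx in g$transcripts) {
      tsp <- transcript_span(tx)
      rows <- c(rows, line(g$chrom, "mRNA", tsp[1], tsp[2], g$strand,
                           sprintf("ID=%s;Parent=%s", tx$transcript_id, g$gene_id)))
      for (i in seq_len(nrow(tx$exons))) {
        rows <- c(rows, line(g$chrom, "exon", tx$exons$start[i], tx$exons$end[i],
                             g$strand, paste0("Parent=", tx$transcript_id)))
      }
      for (i in seq_len(nrow(tx$cds))) {
        rows <- c(rows, line(g$chrom, "CDS", tx$cds$start[i], tx$cds$end[i],
                             g$strand, paste0("Parent=", tx$transcript_id)))
      }
    }
  }
  writeLines(c("##gff-version 3", rows), path)
  invisible(path)
}
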