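# shared in-code fixtures

write_mini_vcf <- function(lines, path = tempfile(fileext = ".vcf")) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=FS,Number=1,Type=Float,Description=\"FS\">",
    "##INFO=<ID=QD,Number=1,Type=Float,Description=\"QD\">",
    "##INFO=<ID=ReadPosRankSum,Number=1,Type=Float,Description=\"RPRS\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"GT\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"AD\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"DP\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "CVT71", "CVT423", "CVT185"), collapse = "\t")
  )
  writeLines(c(hdr, lines), path)
  path
}

vcf_line <- function(chrom = "chr1", pos, ref = "A", alt = "T", qual = 1000,
                     info = "FS=1;QD=20", gts) {
  paste(c(chrom, pos, ".", ref, alt, qual, "PASS", info, "GT:AD:DP", gts),
        collapse = "\t")
}

# one-transcript gene builder (1-based closed coordinates)
make_gene <- function(gene_id = "G1", chrom = "chr1", strand = "+",
                      exons, cds) {
  gene_model(gene_id, chrom, strand,
             list(list(transcript_id = paste0(gene_id, ".1"),
                       exons = exons, cds = cds)))
}

iv <- function(start, end) data.frame(start = start, end = end)

# a deterministic 10 kb chromosome for effect tests
test_genome <- function(seed = 99, len = 10000) {
  set.seed(seed)
  g <- c(chr1 = paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                      collapse = ""))
  g
}

# plant a string into a genome at 1-based position
plant_seq <- function(genome, chrom, pos, s) {
  substr(genome[[chrom]], pos, pos + nchar(s) - 1L) <- s
  genome
}

# simple plus-strand single-exon gene over a planted ORF, placed mid-
# chromosome so both 5 kb flanks exist: exon 4101-4400, CDS 4151-4351
# (67 codons) starting ATG and ending TAA
planted_orf_genome <- function() {
  g <- test_genome()
  g <- plant_seq(g, "chr1", 4151, "ATG")
  g <- plant_seq(g, "chr1", 4349, "TAA")
  list(genome = g,
       gene = make_gene(exons = iv(4101, 4400), cds = iv(4151, 4351)))
}

three_calls <- function(cat1, cat2, cat3, ref = "A", alt = "T") {
  al <- function(cat) switch(cat,
    HOM_REF = c(ref, ref), HET = c(ref, alt), HOM_ALT = c(alt, alt))
  list(CVT71 = genotype_call(al(cat1), ref, alt, depth = 30),
       CVT423 = genotype_call(al(cat2), ref, alt, depth = 30),
       CVT185 = genotype_call(al(cat3), ref, alt, depth = 30))
}
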