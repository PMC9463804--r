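# In-code fixtures: small GTF annotations and designed genomes.

gtf_line <- function(chrom, feat, s, e, strand, gene, tx,
                     biotype = "protein_coding", name = gene) {
  sprintf('%s\ttest\t%s\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s"; gene_name "%s"; gene_biotype "%s";',
          chrom, feat, s, e, strand, gene, tx, name, biotype)
}

write_gtf <- function(lines) {
  tf <- tempfile(fileext = ".gtf")
  writeLines(lines, tf)
  tf
}

# Two-gene fixture: one + strand coding 3-exon gene, one - strand lncRNA
# 2-exon gene.
two_gene_gtf <- function() {
  write_gtf(c(
    gtf_line("chr1", "exon", 101, 200, "+", "GA", "GA.t1"),
    gtf_line("chr1", "exon", 301, 400, "+", "GA", "GA.t1"),
    gtf_line("chr1", "exon", 501, 600, "+", "GA", "GA.t1"),
    gtf_line("chr1", "CDS", 151, 200, "+", "GA", "GA.t1"),
    gtf_line("chr1", "CDS", 301, 400, "+", "GA", "GA.t1"),
    gtf_line("chr1", "CDS", 501, 551, "+", "GA", "GA.t1"),
    gtf_line("chr1", "exon", 2001, 2100, "-", "GD", "GD.t1", biotype = "lncRNA"),
    gtf_line("chr1", "exon", 2201, 2300, "-", "GD", "GD.t1", biotype = "lncRNA")
  ))
}

# Richer toy annotation for classification tests:
#   chr1 +: GA (coding, 3 exons), GB (coding, 2 exons), GC (coding, 2 exons)
#           laid out left to right with GB between GA and GC
#   chr1 -: GD (lncRNA, 2 exons)
#   chr2 +: GE (lncRNA, 1 exon)
toy_gtf <- function() {
  write_gtf(c(
    gtf_line("chr1", "exon", 101, 200, "+", "GA", "GA.t1"),
    gtf_line("chr1", "exon", 301, 400, "+", "GA", "GA.t1"),
    gtf_line("chr1", "exon", 501, 600, "+", "GA", "GA.t1"),
    gtf_line("chr1", "CDS", 151, 200, "+", "GA", "GA.t1"),
    gtf_line("chr1", "CDS", 301, 400, "+", "GA", "GA.t1"),
    gtf_line("chr1", "CDS", 501, 551, "+", "GA", "GA.t1"),
    gtf_line("chr1", "exon", 701, 800, "+", "GB", "GB.t1"),
    gtf_line("chr1", "exon", 901, 1000, "+", "GB", "GB.t1"),
    gtf_line("chr1", "CDS", 751, 800, "+", "GB", "GB.t1"),
    gtf_line("chr1", "CDS", 901, 951, "+", "GB", "GB.t1"),
    gtf_line("chr1", "exon", 1101, 1200, "+", "GC", "GC.t1"),
    gtf_line("chr1", "exon", 1301, 1400, "+", "GC", "GC.t1"),
    gtf_line("chr1", "CDS", 1151, 1200, "+", "GC", "GC.t1"),
    gtf_line("chr1", "CDS", 1301, 1351, "+", "GC", "GC.t1"),
    gtf_line("chr1", "exon", 2001, 2100, "-", "GD", "GD.t1", biotype = "lncRNA"),
    gtf_line("chr1", "exon", 2201, 2300, "-", "GD", "GD.t1", biotype = "lncRNA"),
    gtf_line("chr2", "exon", 101, 400, "+", "GE", "GE.t1", biotype = "lncRNA")
  ))
}

toy_annotation <- function() read_gene_annotation(toy_gtf())

toy_call <- function(gene5, pos5, gene3, pos3, ann = NULL,
                     chrom5 = "chr1", strand5 = "+",
                     chrom3 = "chr1", strand3 = "+",
                     score = 0.9, sample = "S1", id = "C1") {
  list(chimera_id = id, gene5 = gene5, gene3 = gene3,
       chrom5 = chrom5, pos5 = pos5, strand5 = strand5,
       chrom3 = chrom3, pos3 = pos3, strand3 = strand3,
       score = score, junction_seq = NA_character_, sample = sample)
}

calls_df <- function(...) {
  rows <- list(...)
  df <- do.call(rbind, lapply(rows, function(r) {
    as.data.frame(r, stringsAsFactors = FALSE)
  }))
  class(df) <- c("chimera_calls", "data.frame")
  df
}

# Designed two-gene coding fixture with a real genome sequence, for frame
# arithmetic verified against brute-force translation:
#   F5: chrF +, exon 101-400, CDS 151-360 (ATG + 68 codons + TAA)
#   F3: chrF +, exon 501-800, CDS 551-760 (ATG + 68 codons + TAA)
# Also an A-free lncRNA pair (L5, L3) whose fusion contains no ATG.
frame_fixture <- function() {
  set.seed(1107)
  codons <- non_stop_codons()
  cds5 <- paste0("ATG", paste(sample(codons, 68, replace = TRUE), collapse = ""), "TAA")
  cds3 <- paste0("ATG", paste(sample(codons, 68, replace = TRUE), collapse = ""), "TAA")
  ## A-free backbone: no ATG (or stop) outside the two designed CDS regions
  chrF <- strsplit(random_dna_str(1200, c("C", "G", "T")), "")[[1]]
  chrF[151:360] <- strsplit(cds5, "")[[1]]
  chrF[551:760] <- strsplit(cds3, "")[[1]]
  genome <- Biostrings::DNAStringSet(setNames(paste(chrF, collapse = ""), "chrF"))
  gtf <- write_gtf(c(
    gtf_line("chrF", "exon", 101, 400, "+", "F5", "F5.t1"),
    gtf_line("chrF", "CDS", 151, 360, "+", "F5", "F5.t1"),
    gtf_line("chrF", "exon", 501, 800, "+", "F3", "F3.t1"),
    gtf_line("chrF", "CDS", 551, 760, "+", "F3", "F3.t1"),
    gtf_line("chrF", "exon", 821, 880, "+", "L5", "L5.t1", biotype = "lncRNA"),
    gtf_line("chrF", "exon", 901, 960, "+", "L3", "L3.t1", biotype = "lncRNA")
  ))
  list(ann = read_gene_annotation(gtf), genome = genome,
       cds5 = cds5, cds3 = cds3)
}

cli_path <- function() {
  system.file("cli", "chimera-pipeline.R", package = "chimeraScreen")
}

run_cli <- function(args) {
  rscript <- file.path(R.home("bin"), "Rscript")
  system2(rscript, c(cli_path(), args),
          stdout = TRUE, stderr = TRUE,
          env = paste0("R_LIBS=", paste(.libPaths(), collapse = ":")))
}
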