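test_that("fused transcripts chain exons and track the junction offset", {
  ## a 3-exon gene and a 12-exon gene: retaining 2 + last 9 gives 11 exons
  lines <- c(
    gtf_line("chrX", "exon", 101, 150, "+", "U5", "U5.t1", biotype = "lncRNA"),
    gtf_line("chrX", "exon", 201, 260, "+", "U5", "U5.t1", biotype = "lncRNA"),
    gtf_line("chrX", "exon", 301, 340, "+", "U5", "U5.t1", biotype = "lncRNA"))
  for (i in 1:12) {
    s <- 1000 + i * 100
    lines <- c(lines, gtf_line("chrX", "exon", s, s + 49, "+", "U3", "U3.t1",
                               biotype = "lncRNA"))
  }
  ann <- read_gene_annotation(write_gtf(lines))
  set.seed(4)
  genome <- Biostrings::DNAStringSet(c(chrX = random_dna_str(2400)))
  tx5 <- ann$genes$U5$transcripts[[1]]
  tx3 <- ann$genes$U3$transcripts[[1]]

  f <- fuse_transcripts(tx5, 2, tx3, 4, genome)
  expect_identical(f$n_exons, 11L)
  expect_identical(f$junction_offset, 110L)  # 50 + 60
  expect_identical(nchar(f$seq),
                   110L + 9L * 50L)
  ## splitting a transcript at an exon boundary and re-fusing is the identity
  self <- fuse_transcripts(tx3, 5, tx3, 6, genome)
  expect_identical(self$seq, chimeraScreen:::transcript_seq(tx3, genome))
  ## out-of-range exon indices are errors
  expect_error(fuse_transcripts(tx5, 0, tx3, 4, genome), "out of range")
  expect_error(fuse_transcripts(tx5, 2, tx3, 13, genome), "out of range")
})

test_that("minus-strand exons are reverse-complemented when splicing", {
  ann <- read_gene_annotation(two_gene_gtf())
  set.seed(8)
  genome <- Biostrings::DNAStringSet(c(chr1 = random_dna_str(2500)))
  tx <- ann$genes$GD$transcripts[[1]]
  s <- chimeraScreen:::transcript_seq(tx, genome)
  chr <- as.character(genome[[1]])
  expect_identical(s, paste0(
    chimeraScreen:::revcomp_chr(substr(chr, 2201, 2300)),
    chimeraScreen:::revcomp_chr(substr(chr, 2001, 2100))))
})

test_that("protein prediction follows the start-selection rule", {
  fx <- frame_fixture()
  tx5 <- fx$ann$genes$F5$transcripts[[1]]
  tx3 <- fx$ann$genes$F3$transcripts[[1]]
  l5 <- fx$ann$genes$L5$transcripts[[1]]
  l3 <- fx$ann$genes$L3$transcripts[[1]]

  ## annotated start codon within the retained 5' portion
  f <- fuse_transcripts(tx5, 1, tx3, 1, fx$genome)
  prot <- predict_protein(f, tx5)
  expect_identical(prot$origin, "FIVE_PRIME_CDS")
  expect_identical(prot$start_offset, 51L)  # CDS starts 50 nt into the exon
  ## agreement with the codon-table oracle applied from the same start
  expect_identical(prot$protein,
                   oracle_translate(substr(f$seq, 51, nchar(f$seq))))

  ## 5' portion entirely UTR: first internal ATG is used
  f2 <- fuse_transcripts(l5, 1, tx3, 1, fx$genome)
  prot2 <- predict_protein(f2, l5)
  expect_identical(prot2$origin, "INTERNAL_ATG")
  ## the 3' parent's own start codon is the first ATG here
  expect_identical(prot2$start_offset, 60L + 50L + 1L)
  expect_identical(prot2$protein,
                   chimeraScreen:::transcript_protein(tx3, fx$genome))

  ## no ATG anywhere: no protein
  f3 <- fuse_transcripts(l5, 1, l3, 1, fx$genome)
  prot3 <- predict_protein(f3, l5)
  expect_identical(prot3$origin, "NONE")
  expect_identical(prot3$protein, "")
})

test_that("isoform comparison reports length difference and shared suffix", {
  a <- structure(list(protein = "MKKKVSTOPFREE", origin = "FIVE_PRIME_CDS",
                      start_offset = 1L), class = "fusion_protein")
  expect_identical(compare_isoforms(a, a),
                   list(length_difference = 0L, shared_suffix = 13L))
  x <- "GHIKLMNPQ"
  cmp <- compare_isoforms(paste0("MKKKV", x), x)
  expect_identical(cmp$length_difference, 5L)
  expect_identical(cmp$shared_suffix, nchar(x))
  expect_error(compare_isoforms("", "M"), "empty")
})

test_that("exon-2 versus exon-1 fusions differ by 31 residues, split 5 + 26", {
  ex <- example_tmprss2_erg()
  tx5 <- ex$annotation$genes$TMPRSS2L$transcripts[[1]]
  tx3 <- ex$annotation$genes$ERGL$transcripts[[1]]

  f_e2e4 <- fuse_transcripts(tx5, 2, tx3, 4, ex$genome)
  f_e1e4 <- fuse_transcripts(tx5, 1, tx3, 4, ex$genome)
  e2e4 <- predict_protein(f_e2e4, tx5)
  e1e4 <- predict_protein(f_e1e4, tx5)

  ## translation starts at the 5' gene's start codon in exon 2 (e2e4) but
  ## at the 3' gene's own start codon (first internal ATG) in e1e4
  expect_identical(e2e4$origin, "FIVE_PRIME_CDS")
  expect_identical(e1e4$origin, "INTERNAL_ATG")

  cmp <- compare_isoforms(e2e4, e1e4)
  expect_identical(cmp$length_difference, 31L)
  expect_identical(cmp$shared_suffix, nchar(e1e4$protein))
  ## decomposition of the extension: residues encoded before the junction
  from5 <- (f_e2e4$junction_offset - e2e4$start_offset + 1L) / 3L
  expect_identical(from5, 5)
  expect_identical(31 - from5, 26)
})

test_that("in-frame planted fusions keep the 3' parent's terminal peptide", {
  plants <- data.frame(junction = "EE", relation = "INTER_CHROMOSOMAL",
                       frame = "IN_FRAME", n = 4L, stringsAsFactors = FALSE)
  cfg <- simulation_config(seed = 44, plants = plants)
  sim <- simulate_genome(cfg)
  planted <- plant_fusions(sim, cfg)
  for (i in seq_len(nrow(planted$calls))) {
    call <- as.list(planted$calls[i, ])
    tx5 <- sim$annotation$genes[[call$gene5]]$transcripts[[1]]
    tx3 <- sim$annotation$genes[[call$gene3]]$transcripts[[1]]
    ## EE junctions sit on exon boundaries: recover the exon indices
    donor_edges <- if (tx5$strand == "+") tx5$exons[, "end"] else tx5$exons[, "start"]
    acceptor_edges <- if (tx3$strand == "+") tx3$exons[, "start"] else tx3$exons[, "end"]
    n5 <- match(call$pos5, donor_edges)
    first3 <- match(call$pos3, acceptor_edges)
    f <- fuse_transcripts(tx5, n5, tx3, first3, sim$genome)
    prot <- predict_protein(f, tx5)
    expect_identical(prot$origin, "FIVE_PRIME_CDS")
    parent3 <- chimeraScreen:::transcript_protein(tx3, sim$genome)
    tail8 <- substr(parent3, nchar(parent3) - 7, nchar(parent3))
    expect_identical(substr(prot$protein, nchar(prot$protein) - 7,
                            nchar(prot$protein)), tail8)
  }
})
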