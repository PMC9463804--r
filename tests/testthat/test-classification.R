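test_that("junction classes cover E/E, E/M, M/E, M/M with 5' partner first", {
  ann <- toy_annotation()
  ## donor edge 400 (GA exon 2 end), acceptor edge 901 (GB exon 2 start)
  expect_identical(classify_junction(toy_call("GA", 400, "GB", 901), ann), "EE")
  expect_identical(classify_junction(toy_call("GA", 400, "GB", 950), ann), "EM")
  expect_identical(classify_junction(toy_call("GA", 350, "GB", 901), ann), "ME")
  expect_identical(classify_junction(toy_call("GA", 350, "GB", 950), ann), "MM")
  ## intronic junction positions are unclassifiable (flagged, not classed)
  expect_error(classify_junction(toy_call("GA", 250, "GB", 901), ann),
               class = "chimera_unclassifiable")
  cls <- suppressMessages(
    classify_calls(calls_df(toy_call("GA", 250, "GB", 901)), ann))
  expect_true(cls$flagged)
  expect_true(is.na(cls$junction_class))
})

test_that("genomic relation distinguishes read-through, intra and inter", {
  ann <- toy_annotation()
  ## different chromosomes
  expect_identical(classify_relation(
    toy_call("GA", 400, "GE", 200, chrom3 = "chr2"), ann),
    "INTER_CHROMOSOMAL")
  ## same chromosome, opposite strands (the EEF2/SLC25A42 situation)
  expect_identical(classify_relation(
    toy_call("GA", 400, "GD", 2300, strand3 = "-"), ann),
    "INTRA_CHROMOSOMAL")
  ## adjacent same-strand genes, 5' upstream: read-through (cis-SAGe)
  expect_identical(classify_relation(toy_call("GA", 400, "GB", 901), ann),
                   "READ_THROUGH")
  ## an interposed gene breaks adjacency
  expect_identical(classify_relation(toy_call("GA", 400, "GC", 1301), ann),
                   "INTRA_CHROMOSOMAL")
  ## wrong order (5' partner downstream) is not read-through
  expect_identical(classify_relation(toy_call("GB", 1000, "GA", 101), ann),
                   "INTRA_CHROMOSOMAL")
  expect_error(classify_relation(toy_call("GA", 400, "NOPE", 1), ann),
               "unknown gene")
})

test_that("frame class follows CDS phase arithmetic, verified by translation", {
  fx <- frame_fixture()
  ann <- fx$ann
  ## pos5 = 156: L5 = 6 CDS bases retained; pos3 = 551: phase3 = 0
  call_in <- toy_call("F5", 156, "F3", 551, chrom5 = "chrF", chrom3 = "chrF")
  expect_identical(classify_frame(call_in, ann), "IN_FRAME")
  ## brute force: translating the fused CDS preserves the 3' peptide
  fused <- paste0(substr(fx$cds5, 1, 6), fx$cds3)
  expect_identical(oracle_translate(fused),
                   paste0(substr(oracle_translate(fused), 1, 2),
                          oracle_translate(fx$cds3)))
  ## pos5 = 157: L5 = 7 shifts the frame
  call_out <- toy_call("F5", 157, "F3", 551, chrom5 = "chrF", chrom3 = "chrF")
  expect_identical(classify_frame(call_out, ann), "OUT_OF_FRAME")
  fused_out <- paste0(substr(fx$cds5, 1, 7), fx$cds3)
  tail3 <- oracle_translate(fx$cds3)
  expect_false(grepl(substr(tail3, 3, 20), oracle_translate(fused_out),
                     fixed = TRUE))
})

test_that("frame is NA for non-coding parents and UTR junctions", {
  fx <- frame_fixture()
  ## 5' parent lncRNA
  expect_identical(classify_frame(
    toy_call("L5", 850, "F3", 551, chrom5 = "chrF", chrom3 = "chrF"), fx$ann),
    "NA")
  ## coding parents but pos5 in the 5' UTR
  expect_identical(classify_frame(
    toy_call("F5", 120, "F3", 551, chrom5 = "chrF", chrom3 = "chrF"), fx$ann),
    "NA")
  ## pos3 in the 3' gene's UTR
  expect_identical(classify_frame(
    toy_call("F5", 156, "F3", 790, chrom5 = "chrF", chrom3 = "chrF"), fx$ann),
    "NA")
})

test_that("the any-transcript-pair frame rule is order-free", {
  ## two transcripts of the 5' gene with CDS phases differing by one base;
  ## only the later-sorted one is in frame with the acceptor
  gtf <- write_gtf(c(
    gtf_line("chr1", "exon", 101, 400, "+", "GM", "GM.t1"),
    gtf_line("chr1", "CDS", 152, 361, "+", "GM", "GM.t1"),
    gtf_line("chr1", "exon", 101, 400, "+", "GM", "GM.t2"),
    gtf_line("chr1", "CDS", 151, 360, "+", "GM", "GM.t2"),
    gtf_line("chr1", "exon", 501, 800, "+", "GZ", "GZ.t1"),
    gtf_line("chr1", "CDS", 551, 760, "+", "GZ", "GZ.t1")
  ))
  ann <- read_gene_annotation(gtf)
  ## L5 via t1 = 5, via t2 = 6; acceptor phase 0 -> only t2 matches
  expect_identical(classify_frame(toy_call("GM", 156, "GZ", 551), ann),
                   "IN_FRAME")
})

test_that("category profiles are per-group fractions that sum to one", {
  classified <- data.frame(
    chimera_id = sprintf("C%d", 1:10),
    sample = c(rep("A1", 10)),
    junction_class = c(rep("EE", 4), rep("EM", 5), "ME"),
    genomic_relation = c(rep("READ_THROUGH", 2), rep("INTRA_CHROMOSOMAL", 2),
                         rep("INTER_CHROMOSOMAL", 6)),
    frame_class = c(rep("IN_FRAME", 2), rep("OUT_OF_FRAME", 2), rep("NA", 6)),
    flagged = FALSE, stringsAsFactors = FALSE
  )
  groups <- cell_line_groups(G1 = "A1", G2 = "B1")
  prof <- category_profile(classified, groups)

  rel <- prof[prof$group == "G1" & prof$axis == "genomic_relation", ]
  expect_equal(rel$fraction[match(
    c("READ_THROUGH", "INTRA_CHROMOSOMAL", "INTER_CHROMOSOMAL"), rel$category)],
    c(0.2, 0.2, 0.6))
  for (ax in unique(prof$axis)) {
    expect_equal(sum(prof$fraction[prof$group == "G1" & prof$axis == ax]), 1,
                 tolerance = 1e-12)
  }
  ## MM absent from the junction axis when no MM calls remain
  expect_false("MM" %in% prof$category[prof$axis == "junction_class"])
  ## empty group: undefined markers, not zeros
  expect_true(all(is.na(prof$fraction[prof$group == "G2"])))

  ## single inter-chromosomal call -> fraction 1
  one <- classified[5, ]
  one$genomic_relation <- "INTER_CHROMOSOMAL"
  p1 <- category_profile(one, cell_line_groups(G1 = "A1"))
  expect_equal(p1$fraction[p1$axis == "genomic_relation" &
                             p1$category == "INTER_CHROMOSOMAL"], 1)
})

test_that("classification recovers every planted category on a synthetic cohort", {
  cfg <- simulation_config(seed = 83)
  sim <- simulate_genome(cfg)
  planted <- plant_fusions(sim, cfg)
  cls <- classify_calls(planted$calls, sim$annotation)
  cmp <- merge(cls, planted$truth, by = "chimera_id")
  expect_false(any(cmp$flagged))
  expect_identical(cmp$junction_class.x, cmp$junction_class.y)
  expect_identical(cmp$genomic_relation.x, cmp$genomic_relation.y)
  expect_identical(cmp$frame_class.x, cmp$frame_class.y)
})
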