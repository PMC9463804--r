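test_that("score filter discards strictly below threshold and traces", {
  calls <- calls_df(
    toy_call("GA", 400, "GB", 901, id = "C1", score = 0.59),
    toy_call("GA", 400, "GB", 950, id = "C2", score = 0.60),
    toy_call("GA", 350, "GB", 901, id = "C3", score = 1.0)
  )
  kept <- filter_by_score(calls)
  expect_identical(kept$chimera_id, c("C2", "C3"))
  tr <- filter_trace(kept)
  expect_identical(tr$stage, "score_filter")
  expect_identical(tr$input, 3L)
  expect_identical(tr$removed, 1L)
  ## empty input passes through
  expect_identical(nrow(filter_by_score(calls[0, ])), 0L)
})

test_that("M/M candidates are removed; other classes survive", {
  ann <- toy_annotation()
  calls <- calls_df(
    toy_call("GA", 400, "GB", 901, id = "EE"),
    toy_call("GA", 400, "GB", 950, id = "EM"),
    toy_call("GA", 350, "GB", 901, id = "ME"),
    toy_call("GA", 350, "GB", 950, id = "MM")
  )
  kept <- drop_mm(calls, ann)
  expect_identical(kept$chimera_id, c("EE", "EM", "ME"))
  ## unclassifiable calls are removed and logged separately
  calls2 <- calls_df(toy_call("GA", 250, "GB", 901, id = "INTRONIC"),
                     toy_call("GA", 400, "GB", 901, id = "OK"))
  kept2 <- suppressMessages(drop_mm(calls2, ann))
  expect_identical(kept2$chimera_id, "OK")
  expect_identical(attr(kept2, "dropped_unclassifiable"), "INTRONIC")
})

test_that("blacklist subtraction is by ordered symbol pair", {
  calls <- calls_df(
    toy_call("GA", 400, "GB", 901, id = "C1"),
    toy_call("GB", 1000, "GA", 101, id = "C2")
  )
  bl <- tempfile()
  writeLines("GA\tGB", bl)
  kept <- subtract_blacklist(calls, read_blacklist(bl))
  ## the reversed pair is retained
  expect_identical(kept$chimera_id, "C2")
  ## empty blacklist is the identity
  writeLines(character(0), bl)
  expect_identical(subtract_blacklist(calls, read_blacklist(bl))$chimera_id,
                   c("C1", "C2"))
})

test_that("chimeras seen in a normal sample are removed from all samples", {
  calls <- calls_df(
    toy_call("GA", 400, "GB", 901, id = "C1", sample = "PrEC"),
    toy_call("GA", 400, "GB", 901, id = "C2", sample = "NCI-H660"),
    toy_call("GA", 350, "GB", 901, id = "C3", sample = "NCI-H660")
  )
  kept <- subtract_samples(calls, "PrEC")
  expect_identical(kept$chimera_id, "C3")
  ## no normal samples: identity
  expect_identical(nrow(subtract_samples(calls, character())), 3L)
})

test_that("flank homology screen drops self-similar junctions only", {
  set.seed(402)
  left <- random_dna_str(400)
  ident50 <- random_dna_str(50)
  chrH <- paste0(left, ident50, random_dna_str(100), ident50, random_dna_str(30))
  genome <- Biostrings::DNAStringSet(c(chrH = chrH))
  ## identical 50-mers flank pos5 = 450 (upstream) and pos3 = 551 (downstream)
  call_dup <- toy_call("GX", 450, "GY", 551, chrom5 = "chrH", chrom3 = "chrH")
  res <- homology_check(call_dup, genome)
  expect_identical(res$decision, "drop")
  expect_equal(res$identity, 1)

  ## independent random flanks: keep; the Smith-Waterman oracle certifies
  ## that no alignment with span >= 20 and identity >= 0.8 exists
  ## (such an alignment would score >= 0.8*20 - 2*0.2*20 = 8)
  call_rand <- toy_call("GX", 300, "GY", 551, chrom5 = "chrH", chrom3 = "chrH")
  f5 <- substr(chrH, 251, 300)
  f3 <- substr(chrH, 551, 600)
  expect_lt(oracle_sw_score(f5, f3), 8)
  expect_identical(homology_check(call_rand, genome)$decision, "keep")

  ## flank truncated at the contig end, non-homologous: keep with warning
  call_edge <- toy_call("GX", 300, "GY", nchar(chrH) - 24,
                        chrom5 = "chrH", chrom3 = "chrH")
  expect_warning(res_edge <- homology_check(call_edge, genome), "truncated")
  expect_identical(res_edge$decision, "keep")
})

test_that("filter trace conserves counts at every stage", {
  ann <- toy_annotation()
  calls <- calls_df(
    toy_call("GA", 400, "GB", 901, id = "C1", score = 0.5),
    toy_call("GA", 400, "GB", 950, id = "C2"),
    toy_call("GA", 350, "GB", 950, id = "C3"),
    toy_call("GA", 400, "GB", 901, id = "C4", sample = "NORM1"),
    toy_call("GC", 1200, "GB", 901, id = "C5")
  )
  bl <- tempfile()
  writeLines("GC\tGB", bl)
  kept <- subtract_samples(
    subtract_blacklist(drop_mm(filter_by_score(calls), ann),
                       read_blacklist(bl)),
    "NORM1")
  tr <- filter_trace(kept)
  expect_identical(tr$stage,
                   c("score_filter", "drop_mm", "blacklist", "normal_samples"))
  expect_true(all(tr$output == tr$input - tr$removed))
  ## consecutive stages chain: output of stage i is input of stage i+1
  expect_identical(tr$input[-1], tr$output[-nrow(tr)])
  expect_identical(nrow(kept), tr$output[nrow(tr)])
})

test_that("blacklist and normal-sample subtraction commute", {
  calls <- calls_df(
    toy_call("GA", 400, "GB", 901, id = "C1", sample = "NORM1"),
    toy_call("GA", 400, "GB", 901, id = "C2", sample = "T1"),
    toy_call("GC", 1200, "GB", 901, id = "C3", sample = "T1"),
    toy_call("GA", 350, "GB", 950, id = "C4", sample = "T2")
  )
  bl <- tempfile()
  writeLines("GC\tGB", bl)
  blk <- read_blacklist(bl)
  a <- subtract_samples(subtract_blacklist(calls, blk), "NORM1")
  b <- subtract_blacklist(subtract_samples(calls, "NORM1"), blk)
  strip <- function(x) {
    x <- as.data.frame(x)
    attr(x, "filter_trace") <- NULL
    x
  }
  expect_identical(strip(a), strip(b))
})

test_that("specificity sets partition chimeras by exact group membership", {
  groups <- cell_line_groups(HSPC = c("H1", "H2"), CRPC = "C1", NEPC = "N1")
  calls <- calls_df(
    toy_call("GA", 400, "GB", 901, id = "X1", sample = "N1"),
    toy_call("GA", 400, "GB", 950, id = "X2", sample = "H1"),
    toy_call("GA", 400, "GB", 950, id = "X2b", sample = "N1"),
    toy_call("GA", 350, "GB", 901, id = "X3", sample = "C1")
  )
  sets <- specific_sets(calls, groups)
  expect_identical(nrow(sets$specific$NEPC), 1L)
  expect_identical(nrow(sets$specific$CRPC), 1L)
  ## chimera seen in HSPC and NEPC is in the HSPC&NEPC cell, no specific set
  expect_identical(nrow(sets$specific$HSPC), 0L)
  expect_identical(unname(sets$venn[["HSPC&NEPC"]]), 1L)
  ## Venn cells partition the union of distinct chimeras
  expect_identical(sum(sets$venn), 3L)
  ## unassigned sample is a contract violation
  bad <- calls_df(toy_call("GA", 400, "GB", 901, sample = "UNKNOWN"))
  expect_error(specific_sets(bad, groups), "contract violation")
})

test_that("the cascade removes exactly the planted decoys on synthetic data", {
  plants <- expand.grid(junction = c("EE", "EM", "ME"),
                        relation = "INTER_CHROMOSOMAL",
                        frame = c("IN_FRAME", "NA"),
                        stringsAsFactors = FALSE)
  plants$n <- 2L
  cfg <- simulation_config(seed = 61, plants = plants,
                           samples = c("T1", "T2"), normal_samples = "NORM",
                           plant_score = 0.9,
                           n_normal_decoys = 3, n_homology_decoys = 2)
  sim <- simulate_genome(cfg)
  planted <- plant_fusions(sim, cfg)

  kept <- homology_filter(
    subtract_samples(drop_mm(filter_by_score(planted$calls), sim$annotation),
                     "NORM"),
    planted$genome)

  decoy_ids <- planted$truth$chimera_id[planted$truth$is_normal_decoy |
                                          planted$truth$is_homology_decoy]
  true_ids <- setdiff(planted$truth$chimera_id, decoy_ids)
  expect_setequal(kept$chimera_id, true_ids)
  tr <- filter_trace(kept)
  expect_true(all(tr$output == tr$input - tr$removed))
  expect_identical(tr$removed[tr$stage == "homology_filter"], 2L)
})
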