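test_that("probes splice flanks across exon boundaries and truncate", {
  fx <- frame_fixture()
  ## long exons on both sides: full 30 + 30 probe
  p <- build_probe(toy_call("F5", 360, "F3", 551, chrom5 = "chrF",
                            chrom3 = "chrF"),
                   ann = fx$ann, genome = fx$genome, flank = 30)
  expect_identical(nchar(p$sequence), 60L)
  expect_identical(p$flank5_len, 30L)
  ## sequence content: last 30 bases before/at 360 + first 30 from 551
  expect_identical(p$sequence,
                   paste0(substr(as.character(fx$genome[[1]]), 331, 360),
                          substr(as.character(fx$genome[[1]]), 551, 580)))
  ## only 12 exonic bases upstream: probe truncates to 12 + 30
  p2 <- build_probe(toy_call("F5", 112, "F3", 551, chrom5 = "chrF",
                             chrom3 = "chrF"),
                    ann = fx$ann, genome = fx$genome, flank = 30)
  expect_identical(nchar(p2$sequence), 42L)
  expect_identical(p2$flank5_len, 12L)
  ## a provided junction_seq is used verbatim
  call <- toy_call("F5", 360, "F3", 551)
  call$junction_seq <- "ACGTACGTACGTACGTACGTA"
  expect_identical(build_probe(call)$sequence, "ACGTACGTACGTACGTACGTA")
})

test_that("junction read counting honours k errors and both strands", {
  set.seed(77)
  probe <- random_dna_str(40)
  embed <- function(s) paste0(random_dna_str(30), s, random_dna_str(30))
  mutate1 <- function(s, at) {
    ch <- strsplit(s, "")[[1]]
    ch[at] <- setdiff(c("A", "C", "G", "T"), ch[at])[1]
    paste(ch, collapse = "")
  }
  reads <- c(
    exact = embed(probe),
    one_sub = embed(mutate1(probe, 17)),
    revcomp = chimeraScreen:::revcomp_chr(embed(probe)),
    unrelated = random_dna_str(100)
  )
  expect_identical(count_junction_reads(probe, reads, max_errors = 0), 2L)
  expect_identical(count_junction_reads(probe, reads, max_errors = 1), 3L)
  ## short probes are refused as unspecific
  expect_error(count_junction_reads(random_dna_str(19), reads), "shorter than 20")
  ## a read shorter than probe - k contributes nothing
  expect_identical(count_junction_reads(probe, substr(probe, 1, 35),
                                        max_errors = 1), 0L)
  ## N never matches, in the read or in the probe
  read_with_n <- embed(paste0(substr(probe, 1, 9), "N", substr(probe, 11, 40)))
  expect_identical(count_junction_reads(probe, read_with_n, max_errors = 0), 0L)
  probe_with_n <- paste0(substr(probe, 1, 9), "N", substr(probe, 11, 40))
  expect_identical(count_junction_reads(probe_with_n, embed(probe),
                                        max_errors = 0), 0L)
  expect_identical(count_junction_reads(probe_with_n, embed(probe),
                                        max_errors = 1), 1L)
})

test_that("bit-parallel matcher equals the dynamic-programming oracle", {
  set.seed(20331)
  alphabet <- c("A", "C", "G", "T", "N")
  for (i in 1:300) {
    m <- sample(20:60, 1)
    n <- sample(50:150, 1)
    p <- paste(sample(alphabet, m, replace = TRUE,
                      prob = c(rep(0.245, 4), 0.02)), collapse = "")
    t <- paste(sample(alphabet, n, replace = TRUE,
                      prob = c(rep(0.245, 4), 0.02)), collapse = "")
    expect_identical(probe_match_distance(p, t), oracle_semiglobal(p, t))
  }
  ## probes longer than one machine word use the fallback path
  for (i in 1:20) {
    p <- random_dna_str(sample(65:90, 1))
    t <- random_dna_str(sample(100:200, 1))
    expect_identical(probe_match_distance(p, t), oracle_semiglobal(p, t))
  }
})

test_that("counts are monotone in allowed errors and probe length", {
  set.seed(515)
  junction <- random_dna_str(120)
  reads <- vapply(1:40, function(i) {
    s <- sample(1:21, 1)
    r <- substr(junction, s, s + 99)
    if (i %% 3 == 0) {
      ch <- strsplit(r, "")[[1]]
      at <- sample(seq_along(ch), 2)
      ch[at] <- vapply(ch[at], function(b) setdiff(c("A","C","G","T"), b)[1], "")
      r <- paste(ch, collapse = "")
    }
    r
  }, character(1))
  probes <- lapply(c(60, 50, 40), function(w) {
    substr(junction, 61 - w / 2, 60 + w / 2)  # nested around the centre
  })
  counts <- sapply(probes, function(p) {
    sapply(0:2, function(k) count_junction_reads(p, reads, max_errors = k))
  })
  ## non-decreasing in k (rows) for every probe
  expect_true(all(apply(counts, 2, function(x) all(diff(x) >= 0))))
  ## non-increasing as the probe grows (nested probes, same k)
  expect_true(all(apply(counts, 1, function(x) all(diff(x) >= 0))))
})

test_that("bin scale and presence counting follow the published footnote", {
  eps <- 1e-9
  expect_identical(bin_mean_reads(c(0, 1 - eps, 1, 5 - eps, 5, 10 - eps, 10, 250)),
                   c("-", "-", "+", "+", "++", "++", "+++", "+++"))
  expect_error(bin_mean_reads(-0.1), "non-negative")
  tab <- data.frame(fusion = c("F1", "F2", "F3"),
                    D1 = c("+", "-", "+++"), D2 = c("-", "-", "-"),
                    stringsAsFactors = FALSE)
  expect_identical(count_present(tab, "D1"), 2L)
  expect_identical(count_present(tab, "D2"), 0L)
  expect_error(count_present(tab, "D9"), "unknown column")
})

test_that("CPM normalisation scales by total reads", {
  expect_identical(normalize_cpm(0, 1e6), 0)
  expect_identical(normalize_cpm(5, 1e6), 5)
  expect_equal(normalize_cpm(3, 2e6), 1.5)
  expect_error(normalize_cpm(3, 0), "positive")
})

test_that("count_table aggregates raw counts, CPM and bins per sample", {
  set.seed(99)
  probe <- structure(list(chimera_id = "F1", sequence = random_dna_str(40),
                          flank5_len = 20L, flank3_len = 20L),
                     class = "junction_probe")
  reads <- c(paste0(random_dna_str(20), probe$sequence, random_dna_str(20)),
             replicate(9, random_dna_str(80)))
  tab <- count_table(list(probe), list(S1 = reads), max_errors = 0)
  expect_identical(tab$raw_count, 1L)
  expect_identical(tab$total_reads, 10L)
  expect_equal(tab$cpm, 1e5)
  expect_identical(tab$bin, "+")
})
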