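## Synthetic TMPRSS2/ERG-like reference: a hand-designed miniature of the
## exon/CDS architecture that distinguishes the two junction isoforms of
## the TMPRSS2-ERG fusion. These are NOT the real human transcripts — the
## real ones are orders of magnitude longer — but they reproduce the
## features the isoform comparison depends on:
##
##   * TMPRSS2-like 5' gene: exon 1 entirely untranslated; the start codon
##     sits 15 nt (5 codons) upstream of the exon-2 donor edge, so a fusion
##     retaining exons 1-2 keeps a short native ORF stub in frame 0 at the
##     junction.
##   * ERG-like 3' gene: 26 codons (78 nt) of exon 4 lie upstream of the
##     gene's own annotated start codon.
##
## Joining exons 1-2 of the 5' gene to exons 4..end of the 3' gene
## therefore yields a protein with a 31-residue N-terminal extension over
## the exon-1-only fusion (5 residues from the 5' gene + 26 from the 3'
## gene), the published e2e4-vs-e1e4 relationship.
##
## Sequence filler uses a C/G/T-only alphabet so that no spurious ATG or
## stop codon can arise in any frame within the untranslated stretches.

#' Synthetic TMPRSS2/ERG-like reference pair
#'
#' Builds a miniature two-gene annotation plus genome emulating the exon
#' architecture of the TMPRSS2-ERG fusion isoforms (see the package
#' vignette): joining two 5' exons to the 3' gene's exon 4 (`e2e4`-style)
#' keeps the 5' gene's start codon and yields a 31-residue N-terminal
#' extension — 5 residues encoded before the junction, 26 by the 3' exon 4
#' upstream of the 3' gene's own start — relative to the one-exon
#' (`e1e4`-style) fusion, which is translated from the 3' gene's own start
#' codon. Deterministic (internally seeded); entirely synthetic.
#'
#' @return List with `annotation` (`genome_annotation`), `genome`
#'   (`DNAStringSet`), and the gene ids `gene5` (`TMPRSS2L`) and `gene3`
#'   (`ERGL`).
#' @export
example_tmprss2_erg <- function() {
  with_seed(20260901L, {
    safe <- c("C", "G", "T")                      # no A: no ATG, no stop
    safe_dna <- function(n) random_dna(n, alphabet = safe)
    codons <- setdiff(all_codons(), STOP_CODONS)
    ## A-free codons cannot create an ATG (or stop) even across codon
    ## boundaries — used wherever the sequence must stay start-codon-free
    safe_codons <- setdiff(codons, grep("A", codons, value = TRUE))

    ## ---- TMPRSS2-like gene -------------------------------------------
    t_ex1 <- safe_dna(60)                          # exon 1: all 5' UTR
    t_ex2_utr <- safe_dna(40)
    t_ex2_cds <- paste0("ATG", paste(sample(safe_codons, 4), collapse = ""))
    t_ex2 <- paste0(t_ex2_utr, t_ex2_cds)          # 55 nt; donor edge ends codon 5
    t_ex3_cds <- paste0(paste(sample(codons, 20, replace = TRUE), collapse = ""), "TAA")
    t_ex3 <- paste0(t_ex3_cds, safe_dna(40))       # rest of CDS + 3' UTR

    ## ---- ERG-like gene -----------------------------------------------
    e_utr_ex <- lapply(c(50, 60, 55), safe_dna)    # exons 1-3: 5' UTR
    e_ex4_pre <- paste(sample(safe_codons, 26, replace = TRUE),
                       collapse = "")              # 78 nt upstream of the start
    e_cds_tail <- paste(sample(codons, 50, replace = TRUE), collapse = "")
    e_ex4 <- paste0(e_ex4_pre, "ATG", substr(e_cds_tail, 1, 60))
    e_ex5 <- paste0(substr(e_cds_tail, 61, 150), "TAA", safe_dna(45))

    build_gene <- function(gene_id, exon_seqs, cds_spliced_range, offset) {
      lens <- nchar(exon_seqs)
      starts <- integer(length(lens)); ends <- integer(length(lens))
      pos <- offset
      for (i in seq_along(lens)) {
        pos <- pos + 120L                          # intron / leading gap
        starts[i] <- pos + 1L
        ends[i] <- pos + lens[i]
        pos <- pos + lens[i]
      }
      sp_off <- cumsum(c(0L, lens[-length(lens)]))
      cds <- NULL
      if (!is.null(cds_spliced_range)) {
        rows <- list()
        for (i in seq_along(lens)) {
          a <- sp_off[i] + 1L; b <- sp_off[i] + lens[i]
          lo <- max(a, cds_spliced_range[1]); hi <- min(b, cds_spliced_range[2])
          if (lo > hi) next
          rows[[length(rows) + 1L]] <- c(starts[i] + (lo - a), starts[i] + (hi - a))
        }
        cds <- do.call(rbind, rows)
        colnames(cds) <- c("start", "end")
      }
      tx <- new_transcript_model(paste0(gene_id, ".t1"), "chrS", "+",
                                 cbind(start = starts, end = ends), cds,
                                 start_codon = if (is.null(cds)) NA_integer_ else cds[1, "start"])
      txs <- setNames(list(tx), tx$transcript_id)
      list(gene = new_gene_model(gene_id, gene_id, "chrS", "+", txs,
                                 "protein_coding"),
           end = pos, exon_seqs = exon_seqs, starts = starts, ends = ends)
    }

    t_exons <- c(t_ex1, t_ex2, t_ex3)
    ## spliced CDS: 15 nt (ATG + 4 codons) in exon 2, rest in exon 3
    t_cds_start <- nchar(t_ex1) + nchar(t_ex2_utr) + 1L
    t_cds_end <- t_cds_start + (15L + nchar(t_ex3_cds)) - 1L
    g5 <- build_gene("TMPRSS2L", t_exons, c(t_cds_start, t_cds_end), 0L)

    e_exons <- c(unlist(e_utr_ex), e_ex4, e_ex5)
    e_cds_start <- sum(nchar(unlist(e_utr_ex))) + nchar(e_ex4_pre) + 1L
    e_cds_len <- 3L + 60L + 90L + 3L              # ATG + tail split + TAA
    g3 <- build_gene("ERGL", e_exons, c(e_cds_start, e_cds_start + e_cds_len - 1L),
                     g5$end + 300L)

    ## genome: one chromosome with both genes laid out on the + strand
    chrom_len <- g3$end + 200L
    chrom <- strsplit(safe_dna(chrom_len), "")[[1]]
    fill_in <- function(g) {
      for (i in seq_along(g$starts)) {
        chrom[seq(g$starts[i], g$ends[i])] <<- strsplit(g$exon_seqs[i], "")[[1]]
      }
    }
    fill_in(g5); fill_in(g3)
    genome <- Biostrings::DNAStringSet(setNames(paste(chrom, collapse = ""), "chrS"))

    ann <- new_genome_annotation(list(TMPRSS2L = g5$gene, ERGL = g3$gene))
    list(annotation = ann, genome = genome, gene5 = "TMPRSS2L", gene3 = "ERGL")
  })
}
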