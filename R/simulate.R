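## Deterministic synthetic-data generator: genome + annotation, planted
## fusions of every requested (junction x relation x frame) category,
## normal-sample and flank-homology decoys, and sequencing reads with a
## known number of junction-spanning reads per fusion. The seed fully
## determines every output.

STOP_CODONS <- c("TAA", "TAG", "TGA")

all_codons <- function() {
  b <- c("A", "C", "G", "T")
  as.vector(outer(outer(b, b, paste0), b, paste0))
}

#' Build a simulation configuration
#'
#' All tunable knobs of the synthetic cohort in one validated object. The
#' seed is mandatory and fully determines every downstream output
#' (byte-identical FASTA/GTF/FASTQ on re-runs). Sequencing errors are
#' substitution-only by default (`indel_rate = 0`).
#'
#' @param seed Integer RNG seed (mandatory).
#' @param n_chromosomes,genes_per_chromosome Genome layout.
#' @param exon_count,exon_length,intron_length,intergenic_gap,utr_length
#'   Inclusive `c(min, max)` ranges (bases; `exon_count` in exons).
#' @param frac_coding Fraction of genes that carry a CDS; the rest are
#'   lncRNA.
#' @param plants Data frame of fusion plant requests with columns
#'   `junction` (`EE`/`EM`/`ME`/`MM`), `relation` (`READ_THROUGH`/
#'   `INTRA_CHROMOSOMAL`/`INTER_CHROMOSOMAL`), `frame` (`IN_FRAME`/
#'   `OUT_OF_FRAME`/`NA`), `n`, and optionally `strand5`/`strand3`
#'   constraints. `NULL` requests one plant of every combination.
#' @param samples Cohort sample labels (plants are assigned round-robin).
#' @param normal_samples Labels of normal (non-cancer) samples; required
#'   non-empty when `n_normal_decoys > 0`.
#' @param plant_score `NULL` to draw caller scores uniformly in `[0, 1]`,
#'   or a single value to pin every planted score.
#' @param n_normal_decoys Chimeras planted in a normal sample as well as a
#'   cohort sample (removed by normal-sample subtraction).
#' @param n_homology_decoys Chimeras whose two genomic junction flanks are
#'   made identical (removed by the flank-homology screen).
#' @param read_length,read_depth,n_background_reads,error_rate,indel_rate
#'   Read simulation: read length, junction-spanning reads per fusion,
#'   background reads per sample, per-base substitution and indel rates.
#' @param flank Junction probe flank (bases per side, default 30).
#' @return A validated `sim_config` list.
#' @export
simulation_config <- function(seed,
                              n_chromosomes = 2L,
                              genes_per_chromosome = 20L,
                              exon_count = c(3L, 6L),
                              exon_length = c(90L, 240L),
                              intron_length = c(60L, 200L),
                              intergenic_gap = c(200L, 500L),
                              utr_length = c(30L, 80L),
                              frac_coding = 0.7,
                              plants = NULL,
                              samples = "S1",
                              normal_samples = character(),
                              plant_score = NULL,
                              n_normal_decoys = 0L,
                              n_homology_decoys = 0L,
                              read_length = 100L,
                              read_depth = 10L,
                              n_background_reads = 300L,
                              error_rate = 0,
                              indel_rate = 0,
                              flank = 30L) {
  if (missing(seed) || !is.numeric(seed)) stop("config error: seed is mandatory")
  if (error_rate < 0 || indel_rate < 0) {
    stop("config error: error rates must be non-negative")
  }
  if (read_length < 2L * flank) {
    stop("config error: read_length must be at least twice the probe flank")
  }
  if (is.null(plants)) {
    plants <- expand.grid(junction = JUNCTION_CLASSES,
                          relation = GENOMIC_RELATIONS,
                          frame = FRAME_CLASSES,
                          stringsAsFactors = FALSE)
    plants$n <- 1L
  }
  stopifnot(all(c("junction", "relation", "frame", "n") %in% names(plants)))
  if (!all(plants$junction %in% JUNCTION_CLASSES) ||
      !all(plants$relation %in% GENOMIC_RELATIONS) ||
      !all(plants$frame %in% FRAME_CLASSES)) {
    stop("config error: unknown plant category")
  }
  ## satisfiability of explicit strand constraints
  if (all(c("strand5", "strand3") %in% names(plants))) {
    bad <- plants$relation == "READ_THROUGH" &
      !is.na(plants$strand5) & !is.na(plants$strand3) &
      plants$strand5 != plants$strand3
    if (any(bad)) {
      i <- which(bad)[1]
      stop("config error: unsatisfiable plant request: READ_THROUGH requires ",
           "same-strand parents (got ", plants$strand5[i], "/",
           plants$strand3[i], ")")
    }
  }
  if (n_normal_decoys > 0 && length(normal_samples) == 0) {
    stop("config error: normal decoys requested but normal_samples is empty")
  }
  structure(
    list(seed = as.integer(seed), n_chromosomes = n_chromosomes,
         genes_per_chromosome = genes_per_chromosome,
         exon_count = exon_count, exon_length = exon_length,
         intron_length = intron_length, intergenic_gap = intergenic_gap,
         utr_length = utr_length, frac_coding = frac_coding,
         plants = plants, samples = samples, normal_samples = normal_samples,
         plant_score = plant_score,
         n_normal_decoys = as.integer(n_normal_decoys),
         n_homology_decoys = as.integer(n_homology_decoys),
         read_length = as.integer(read_length),
         read_depth = as.integer(read_depth),
         n_background_reads = as.integer(n_background_reads),
         error_rate = error_rate, indel_rate = indel_rate,
         flank = as.integer(flank)),
    class = "sim_config"
  )
}

sample_range <- function(rng) {
  if (rng[1] >= rng[2]) rng[1] else sample(seq(rng[1], rng[2]), 1L)
}

#' Simulate a genome with annotation
#'
#' Genes are packed sequentially (non-overlapping) on each chromosome with
#' a deterministic strand pattern (`+ + - -` repeating) and a deterministic
#' coding/lncRNA pattern within each block of ten genes, so that
#' same-strand adjacent coding and lncRNA pairs exist for read-through
#' plants. Every coding gene carries a single transcript whose CDS starts
#' with ATG, ends with a stop codon, has length divisible by three and no
#' internal in-frame stop codon.
#'
#' @param cfg A `sim_config`.
#' @param dir Optional output directory; when given, `genome.fa` and
#'   `annotation.gtf` are written there (byte-identical per seed).
#' @return List with `genome` (`DNAStringSet`), `annotation`
#'   (`genome_annotation`), `config`, and (when written) `fasta`/`gtf`
#'   paths.
#' @export
simulate_genome <- function(cfg, dir = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    codons_ok <- setdiff(all_codons(), STOP_CODONS)
    genes <- list()
    chrom_seqs <- character(cfg$n_chromosomes)
    names(chrom_seqs) <- paste0("chr", seq_len(cfg$n_chromosomes))
    gene_counter <- 0L
    n_coding_per_block <- round(10 * cfg$frac_coding)

    for (ci in seq_len(cfg$n_chromosomes)) {
      chrom <- names(chrom_seqs)[ci]
      segments <- character(0)
      cursor <- 0L
      for (gi in seq_len(cfg$genes_per_chromosome)) {
        gene_counter <- gene_counter + 1L
        gene_id <- sprintf("GENE%03d", gene_counter)
        strand <- c("+", "+", "-", "-")[((gi - 1L) %% 4L) + 1L]
        coding <- ((gi - 1L) %% 10L) < n_coding_per_block

        gap <- sample_range(cfg$intergenic_gap)
        segments <- c(segments, random_dna(gap))
        cursor <- cursor + gap

        n_ex <- sample_range(cfg$exon_count)
        ex_lens <- vapply(seq_len(n_ex), function(i) sample_range(cfg$exon_length),
                          integer(1))
        in_lens <- if (n_ex > 1) {
          vapply(seq_len(n_ex - 1L), function(i) sample_range(cfg$intron_length),
                 integer(1))
        } else integer(0)
        total_ex <- sum(ex_lens)

        ## spliced transcript sequence (transcription orientation)
        if (coding) {
          u5 <- sample_range(cfg$utr_length)
          cds_len <- total_ex - u5 - sample_range(cfg$utr_length)
          cds_len <- cds_len - cds_len %% 3L
          if (cds_len < 9L) stop("config error: exons too short for a CDS")
          u3 <- total_ex - u5 - cds_len
          spliced <- paste0(
            random_dna(u5),
            "ATG",
            paste(sample(codons_ok, cds_len / 3L - 2L, replace = TRUE),
                  collapse = ""),
            "TAA",
            random_dna(u3))
        } else {
          u5 <- 0L; cds_len <- 0L
          spliced <- random_dna(total_ex)
        }

        ## genomic exon intervals (ascending)
        ex_start <- integer(n_ex); ex_end <- integer(n_ex)
        ## genomic slot j holds transcription-order exon tx_order[j]
        tx_order <- if (strand == "+") seq_len(n_ex) else rev(seq_len(n_ex))
        pos <- cursor
        gene_segments <- character(0)
        sp_off <- cumsum(c(0L, ex_lens[-n_ex]))  # spliced offset before tx exon i
        for (j in seq_len(n_ex)) {
          i_tx <- tx_order[j]
          len <- ex_lens[i_tx]
          ex_start[i_tx] <- pos + 1L
          ex_end[i_tx] <- pos + len
          chunk <- substr(spliced, sp_off[i_tx] + 1L, sp_off[i_tx] + len)
          if (strand == "-") chunk <- revcomp_chr(chunk)
          gene_segments <- c(gene_segments, chunk)
          pos <- pos + len
          if (j < n_ex) {
            gene_segments <- c(gene_segments, random_dna(in_lens[j]))
            pos <- pos + in_lens[j]
          }
        }
        segments <- c(segments, gene_segments)
        cursor <- pos

        exons <- cbind(start = ex_start, end = ex_end)  # transcription order
        cds <- NULL
        if (coding) {
          c1 <- u5 + 1L; c2 <- u5 + cds_len
          rows <- list()
          for (i in seq_len(n_ex)) {
            a <- sp_off[i] + 1L; b <- sp_off[i] + ex_lens[i]
            lo <- max(a, c1); hi <- min(b, c2)
            if (lo > hi) next
            if (strand == "+") {
              rows[[length(rows) + 1L]] <-
                c(ex_start[i] + (lo - a), ex_start[i] + (hi - a))
            } else {
              rows[[length(rows) + 1L]] <-
                c(ex_end[i] - (hi - a), ex_end[i] - (lo - a))
            }
          }
          cds <- do.call(rbind, rows)
          colnames(cds) <- c("start", "end")
        }
        tx <- new_transcript_model(paste0(gene_id, ".t1"), chrom, strand,
                                   exons, cds,
                                   start_codon = if (coding) {
                                     if (strand == "+") cds[1, "start"] else cds[1, "end"]
                                   } else NA_integer_)
        txs <- list(tx)
        names(txs) <- tx$transcript_id
        genes[[gene_id]] <- new_gene_model(
          gene_id, gene_id, chrom, strand, txs,
          biotype_attr = if (coding) "protein_coding" else "lncRNA")
      }
      segments <- c(segments, random_dna(sample_range(cfg$intergenic_gap)))
      chrom_seqs[chrom] <- paste(segments, collapse = "")
    }

    genome <- Biostrings::DNAStringSet(chrom_seqs)
    ann <- new_genome_annotation(genes)
    out <- list(genome = genome, annotation = ann, config = cfg)
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      out$fasta <- file.path(dir, "genome.fa")
      out$gtf <- file.path(dir, "annotation.gtf")
      Biostrings::writeXStringSet(genome, out$fasta)
      write_gene_annotation(ann, out$gtf)
    }
    out
  })
}

## ---- plant selection machinery -------------------------------------------

## transcription-order CDS segment table of a (single-transcript) gene
cds_segments <- function(tx) {
  lens <- tx$cds[, "end"] - tx$cds[, "start"] + 1L
  data.frame(i = seq_along(lens), len = lens,
             cum_before = cumsum(c(0L, lens[-length(lens)]))[seq_along(lens)])
}

## genomic position of the d-th base (transcription order) of row k of `tab`
row_pos <- function(tab, strand, k, d) {
  as.integer(unname(
    if (strand == "+") tab[k, "start"] + d - 1L else tab[k, "end"] - d + 1L))
}

## Candidate junction sites on the donor (5') or acceptor (3') side.
## Each candidate: pos (genomic) or an adjustable interval with a linear
## spliced-CDS offset, plus the spliced offsets needed for frame planting.
side_candidates <- function(gene, side, junction_E, coding_side, flank) {
  tx <- gene$transcripts[[1]]
  n_ex <- nrow(tx$exons)
  out <- list()
  if (coding_side) {
    if (nrow(tx$cds) < 1) return(out)
    segs <- cds_segments(tx)
    m <- nrow(segs)
    if (junction_E) {
      ks <- if (side == "donor") seq_len(max(0L, m - 1L)) else seq(2L, length.out = max(0L, m - 1L))
      for (k in ks) {
        d <- if (side == "donor") segs$len[k] else 1L
        cum <- segs$cum_before[k] + d          # L5 (donor, inclusive)
        off0 <- segs$cum_before[k] + d - 1L    # o3 (acceptor, strictly upstream)
        out[[length(out) + 1L]] <- list(
          pos = row_pos(tx$cds, tx$strand, k, d),
          cds_count = if (side == "donor") cum else off0,
          adjustable = FALSE)
      }
    } else {
      for (k in seq_len(m)) {
        if (segs$len[k] < 7L) next
        out[[length(out) + 1L]] <- list(
          seg = k, dmin = 2L, dmax = segs$len[k] - 1L,
          cum_before = segs$cum_before[k], tab = tx$cds, strand = tx$strand,
          side = side, adjustable = TRUE)
      }
    }
  } else {
    ## non-coding parent: frame is NA, no phase bookkeeping needed
    if (junction_E) {
      ks <- if (n_ex > 1) {
        if (side == "donor") seq_len(n_ex - 1L) else seq(2L, n_ex)
      } else 1L
      for (k in ks) {
        d <- if (side == "donor") tx$exons[k, "end"] - tx$exons[k, "start"] + 1L else 1L
        out[[length(out) + 1L]] <- list(
          pos = row_pos(tx$exons, tx$strand, k, d),
          cds_count = NA_integer_, adjustable = FALSE)
      }
    } else {
      for (k in seq_len(n_ex)) {
        len <- tx$exons[k, "end"] - tx$exons[k, "start"] + 1L
        dmin <- max(2L, flank + 1L)
        dmax <- min(len - 1L, len - flank)
        if (dmin > dmax) next
        out[[length(out) + 1L]] <- list(
          seg = k, dmin = dmin, dmax = dmax, cum_before = NA_integer_,
          tab = tx$exons, strand = tx$strand, side = side, adjustable = TRUE)
      }
    }
  }
  out
}

## Resolve an adjustable candidate at transcription offset d.
resolve_candidate <- function(cand, d) {
  if (!cand$adjustable) return(cand)
  cds_count <- if (is.na(cand$cum_before)) {
    NA_integer_
  } else if (cand$side == "donor") {
    cand$cum_before + d
  } else {
    cand$cum_before + d - 1L
  }
  list(pos = row_pos(cand$tab, cand$strand, cand$seg, d),
       cds_count = cds_count, adjustable = FALSE)
}

## Pick (pos5, pos3) from candidate lists satisfying the frame request.
## Returns NULL when the pair of candidates cannot satisfy it.
match_frame <- function(c5, c3, frame) {
  mid <- function(cand) cand$dmin + (cand$dmax - cand$dmin) %/% 2L
  if (frame == "NA") {
    r5 <- if (c5$adjustable) resolve_candidate(c5, mid(c5)) else c5
    r3 <- if (c3$adjustable) resolve_candidate(c3, mid(c3)) else c3
    return(list(r5 = r5, r3 = r3))
  }
  want_in <- frame == "IN_FRAME"
  if (!c5$adjustable && !c3$adjustable) {
    ok <- (c5$cds_count %% 3L) == (c3$cds_count %% 3L)
    if (ok == want_in) return(list(r5 = c5, r3 = c3))
    return(NULL)
  }
  if (c5$adjustable) {
    fixed <- if (c3$adjustable) resolve_candidate(c3, mid(c3)) else c3
    target <- fixed$cds_count %% 3L
    for (d in seq(c5$dmin, min(c5$dmax, c5$dmin + 5L))) {
      r5 <- resolve_candidate(c5, d)
      ok <- (r5$cds_count %% 3L) == target
      if (ok == want_in) return(list(r5 = r5, r3 = fixed))
    }
    return(NULL)
  }
  ## only c3 adjustable
  target <- c5$cds_count %% 3L
  for (d in seq(c3$dmin, min(c3$dmax, c3$dmin + 5L))) {
    r3 <- resolve_candidate(c3, d)
    ok <- (r3$cds_count %% 3L) == target
    if (ok == want_in) return(list(r5 = c5, r3 = r3))
  }
  NULL
}

## Gene pairs satisfying a genomic-relation request, in a stable order.
relation_pairs <- function(ann, relation, pool5, pool3) {
  idx <- ann$index
  pairs <- list()
  if (relation == "READ_THROUGH") {
    for (chrom in unique(idx$chrom)) {
      for (strand in c("+", "-")) {
        sel <- idx[idx$chrom == chrom & idx$strand == strand, , drop = FALSE]
        sel <- sel[order(sel$start), , drop = FALSE]
        if (nrow(sel) < 2) next
        ord <- if (strand == "+") seq_len(nrow(sel)) else rev(seq_len(nrow(sel)))
        ids <- sel$gene_id[ord]  # transcription order along the strand
        for (i in seq_len(length(ids) - 1L)) {
          g5 <- ids[i]; g3 <- ids[i + 1L]
          if (g5 %in% pool5 && g3 %in% pool3 &&
              count_genes_between(ann, g5, g3) == 0) {
            pairs[[length(pairs) + 1L]] <- c(g5, g3)
          }
        }
      }
    }
  } else if (relation == "INTRA_CHROMOSOMAL") {
    for (g5 in pool5) {
      for (g3 in pool3) {
        if (g5 == g3) next
        i5 <- idx[idx$gene_id == g5, ]; i3 <- idx[idx$gene_id == g3, ]
        if (i5$chrom != i3$chrom) next
        if (i5$strand != i3$strand) {
          pairs[[length(pairs) + 1L]] <- c(g5, g3)
        } else {
          upstream <- if (i5$strand == "+") i5$end < i3$start else i5$start > i3$end
          if (!upstream || count_genes_between(ann, g5, g3) > 0) {
            pairs[[length(pairs) + 1L]] <- c(g5, g3)
          }
        }
      }
    }
  } else {  # INTER_CHROMOSOMAL
    for (g5 in pool5) {
      for (g3 in pool3) {
        i5 <- idx[idx$gene_id == g5, ]; i3 <- idx[idx$gene_id == g3, ]
        if (i5$chrom != i3$chrom) pairs[[length(pairs) + 1L]] <- c(g5, g3)
      }
    }
  }
  pairs
}

#' Plant fusions with known categories into a simulated genome
#'
#' For every requested (junction class, genomic relation, frame class)
#' combination, selects a compatible gene pair and junction position pair,
#' emits a caller-style candidate row and a ground-truth record, and
#' derives the fused transcript sequence used for read simulation. Also
#' plants the configured number of normal-sample decoys (the same chimera
#' emitted in a normal sample) and flank-homology decoys (the genome is
#' edited so the two junction flanks are identical 50-mers).
#'
#' @param sim Output of [simulate_genome()].
#' @param cfg The same `sim_config`.
#' @return List with `calls` (`chimera_calls`), `truth` (per-plant
#'   `TruthRecord` table), `fusions` (per-chimera fused sequence and
#'   junction offset), `genome` (possibly edited by homology decoys) and
#'   `annotation`.
#' @export
plant_fusions <- function(sim, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  ann <- sim$annotation
  with_seed(cfg$seed + 1L, {
    idx <- ann$index
    coding_pool <- idx$gene_id[idx$biotype == "coding"]
    lnc_pool <- idx$gene_id[idx$biotype != "coding"]

    ## reserve lncRNA genes on the + strand for homology decoys (their
    ## genomic neighbourhood gets edited, so nothing else may use them)
    decoy_pool <- character(0)
    if (cfg$n_homology_decoys > 0) {
      cand <- idx$gene_id[idx$biotype != "coding" & idx$strand == "+"]
      need <- 2L * cfg$n_homology_decoys
      if (length(cand) < need) {
        stop("config error: not enough + strand lncRNA genes for ",
             cfg$n_homology_decoys, " homology decoys")
      }
      decoy_pool <- cand[seq_len(need)]
      lnc_pool <- setdiff(lnc_pool, decoy_pool)
    }

    requests <- sim_expand_requests(cfg)
    used_keys <- character(0)
    rows <- list(); truth <- list()

    for (r in seq_len(nrow(requests))) {
      req <- requests[r, ]
      coding5 <- req$frame != "NA"
      coding3 <- req$frame != "NA"
      pool5 <- if (coding5) coding_pool else lnc_pool
      pool3 <- if (coding3) coding_pool else lnc_pool
      pairs <- relation_pairs(ann, req$relation, pool5, pool3)
      if (length(pairs) > 1) pairs <- pairs[sample.int(length(pairs))]
      placed <- FALSE
      for (p in pairs) {
        g5 <- ann$genes[[p[1]]]; g3 <- ann$genes[[p[2]]]
        c5s <- side_candidates(g5, "donor", substr(req$junction, 1, 1) == "E",
                               coding5, cfg$flank)
        c3s <- side_candidates(g3, "acceptor", substr(req$junction, 2, 2) == "E",
                               coding3, cfg$flank)
        for (c5 in c5s) {
          for (c3 in c3s) {
            hit <- match_frame(c5, c3, req$frame)
            if (is.null(hit)) next
            key <- paste(g5$gene_id, g3$gene_id, hit$r5$pos, hit$r3$pos)
            if (key %in% used_keys) next
            used_keys <- c(used_keys, key)
            rows[[length(rows) + 1L]] <- list(
              gene5 = g5$gene_id, gene3 = g3$gene_id,
              chrom5 = g5$chrom, pos5 = hit$r5$pos, strand5 = g5$strand,
              chrom3 = g3$chrom, pos3 = hit$r3$pos, strand3 = g3$strand)
            truth[[length(truth) + 1L]] <- list(
              junction_class = req$junction, genomic_relation = req$relation,
              frame_class = req$frame, is_normal_decoy = FALSE,
              is_homology_decoy = FALSE)
            placed <- TRUE
            break
          }
          if (placed) break
        }
        if (placed) break
      }
      if (!placed) {
        stop("unsatisfiable plant request: ", req$junction, " + ",
             req$relation, " + ", req$frame,
             " (no compatible gene pair in the simulated genome)")
      }
    }

    ## normal decoys: lncRNA inter-chromosomal E/M chimeras observed in a
    ## normal sample as well
    n_main <- length(rows)
    for (d in seq_len(cfg$n_normal_decoys)) {
      pairs <- relation_pairs(ann, "INTER_CHROMOSOMAL", lnc_pool, lnc_pool)
      pairs <- pairs[sample.int(length(pairs))]
      placed <- FALSE
      for (p in pairs) {
        g5 <- ann$genes[[p[1]]]; g3 <- ann$genes[[p[2]]]
        c5s <- side_candidates(g5, "donor", TRUE, FALSE, cfg$flank)
        c3s <- side_candidates(g3, "acceptor", FALSE, FALSE, cfg$flank)
        if (length(c5s) == 0 || length(c3s) == 0) next
        hit <- match_frame(c5s[[1]], c3s[[1]], "NA")
        key <- paste(g5$gene_id, g3$gene_id, hit$r5$pos, hit$r3$pos)
        if (key %in% used_keys) next
        used_keys <- c(used_keys, key)
        rows[[length(rows) + 1L]] <- list(
          gene5 = g5$gene_id, gene3 = g3$gene_id,
          chrom5 = g5$chrom, pos5 = hit$r5$pos, strand5 = g5$strand,
          chrom3 = g3$chrom, pos3 = hit$r3$pos, strand3 = g3$strand)
        truth[[length(truth) + 1L]] <- list(
          junction_class = "EM", genomic_relation = "INTER_CHROMOSOMAL",
          frame_class = "NA", is_normal_decoy = TRUE,
          is_homology_decoy = FALSE)
        placed <- TRUE
        break
      }
      if (!placed) stop("could not place normal decoy ", d)
    }

    ## homology decoys: edit the genome so the 50-mer upstream of pos5
    ## equals the 50-mer downstream of pos3 (both + strand lncRNA genes)
    genome_chr <- as.character(sim$genome)
    for (d in seq_len(cfg$n_homology_decoys)) {
      g5 <- ann$genes[[decoy_pool[2L * d - 1L]]]
      g3 <- ann$genes[[decoy_pool[2L * d]]]
      c5s <- side_candidates(g5, "donor", TRUE, FALSE, cfg$flank)
      c3s <- side_candidates(g3, "acceptor", FALSE, FALSE, cfg$flank)
      hit <- match_frame(c5s[[length(c5s)]], c3s[[1]], "NA")
      pos5 <- hit$r5$pos; pos3 <- hit$r3$pos
      flank_seq <- substr(genome_chr[[g5$chrom]], pos5 - 49L, pos5)
      substr(genome_chr[[g3$chrom]], pos3, pos3 + 49L) <- flank_seq
      rows[[length(rows) + 1L]] <- list(
        gene5 = g5$gene_id, gene3 = g3$gene_id,
        chrom5 = g5$chrom, pos5 = pos5, strand5 = "+",
        chrom3 = g3$chrom, pos3 = pos3, strand3 = "+")
      rel <- if (g5$chrom != g3$chrom) {
        "INTER_CHROMOSOMAL"
      } else if (g5$end < g3$start && count_genes_between(ann, g5$gene_id, g3$gene_id) == 0) {
        "READ_THROUGH"           # both decoy genes are + strand
      } else {
        "INTRA_CHROMOSOMAL"
      }
      truth[[length(truth) + 1L]] <- list(
        junction_class = "EM", genomic_relation = rel,
        frame_class = "NA", is_normal_decoy = FALSE,
        is_homology_decoy = TRUE)
    }
    genome <- Biostrings::DNAStringSet(genome_chr)

    ## assemble the call table, truth records and fused sequences
    n <- length(rows)
    ids <- sprintf("FUS%04d", seq_len(n))
    samples <- rep_len(cfg$samples, n)
    scores <- if (is.null(cfg$plant_score)) runif(n) else rep(cfg$plant_score, n)
    calls <- do.call(rbind, lapply(seq_len(n), function(i) {
      as.data.frame(c(list(chimera_id = ids[i]), rows[[i]],
                      list(score = scores[i], junction_seq = NA_character_,
                           sample = samples[i])),
                    stringsAsFactors = FALSE)
    }))

    fusions <- list()
    junction_seqs <- character(n)
    for (i in seq_len(n)) {
      r <- rows[[i]]
      t5 <- ann$genes[[r$gene5]]$transcripts[[1]]
      t3 <- ann$genes[[r$gene3]]$transcripts[[1]]
      up <- spliced_upstream_seq(t5, r$pos5, genome)
      down <- spliced_downstream_seq(t3, r$pos3, genome)
      f5 <- min(cfg$flank, nchar(up)); f3 <- min(cfg$flank, nchar(down))
      junction_seqs[i] <- paste0(substr(up, nchar(up) - f5 + 1L, nchar(up)),
                                 substr(down, 1L, f3))
      fusions[[ids[i]]] <- list(seq = paste0(up, down),
                                junction_offset = nchar(up),
                                sample = samples[i])
    }
    calls$junction_seq <- junction_seqs
    calls <- as_chimera_calls(calls)

    truth <- do.call(rbind, lapply(seq_len(n), function(i) {
      as.data.frame(c(list(chimera_id = ids[i]), truth[[i]],
                      list(sample = samples[i])),
                    stringsAsFactors = FALSE)
    }))

    ## normal decoys appear in a normal sample too
    if (cfg$n_normal_decoys > 0) {
      dec <- which(truth$is_normal_decoy)
      extra <- as.data.frame(calls)[dec, , drop = FALSE]
      extra$sample <- rep_len(cfg$normal_samples, length(dec))
      calls <- as_chimera_calls(rbind(as.data.frame(calls), extra))
    }

    list(calls = calls, truth = truth, fusions = fusions,
         genome = genome, annotation = ann)
  })
}

sim_expand_requests <- function(cfg) {
  plants <- cfg$plants
  out <- plants[rep(seq_len(nrow(plants)), plants$n), , drop = FALSE]
  rownames(out) <- NULL
  out
}

apply_read_errors <- function(seqs, error_rate, indel_rate) {
  if (error_rate <= 0 && indel_rate <= 0) return(seqs)
  bases <- c("A", "C", "G", "T")
  vapply(seqs, function(s) {
    ch <- strsplit(s, "")[[1]]
    if (error_rate > 0) {
      hit <- which(runif(length(ch)) < error_rate)
      for (i in hit) ch[i] <- sample(setdiff(bases, ch[i]), 1L)
    }
    if (indel_rate > 0) {
      hit <- which(runif(length(ch)) < indel_rate)
      for (i in rev(hit)) {
        if (runif(1) < 0.5) {
          ch <- append(ch, sample(bases, 1L), after = i)
        } else {
          ch <- ch[-i]
        }
      }
    }
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

write_fastq <- function(seqs, path) {
  ids <- names(seqs)
  qual <- strrep("I", nchar(seqs))
  writeLines(as.vector(rbind(paste0("@", ids), unname(seqs), "+", qual)), path)
  invisible(path)
}

#' Simulate sequencing reads with planted junction-spanning evidence
#'
#' Background reads are drawn uniformly from (unfused) transcript
#' sequences, so they never span a planted junction. For every planted
#' fusion, exactly `read_depth` reads straddle the junction with at least
#' `flank` bases on each side; substitution (and optional indel) errors are
#' applied i.i.d. per base, and every second read is emitted
#' reverse-complemented.
#'
#' @param planted Output of [plant_fusions()].
#' @param cfg The same `sim_config`.
#' @param dir Optional directory; when given, one `<sample>.fastq` per
#'   sample is written (byte-identical per seed).
#' @return List with `reads` (named list sample → character vector of read
#'   sequences), `truth_counts` (data frame `chimera_id`, `sample`,
#'   `planted_reads`) and (when written) `fastq` paths.
#' @export
simulate_reads <- function(planted, cfg, dir = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  ann <- planted$annotation
  genome <- planted$genome
  with_seed(cfg$seed + 2L, {
    L <- cfg$read_length
    tx_seqs <- unlist(lapply(ann$genes, function(g) {
      setNames(transcript_seq(g$transcripts[[1]], genome),
               g$transcripts[[1]]$transcript_id)
    }))
    tx_seqs <- tx_seqs[nchar(tx_seqs) >= L]

    all_samples <- unique(c(cfg$samples, cfg$normal_samples))
    reads <- list()
    truth_counts <- list()
    for (s in all_samples) {
      rs <- character(0)
      if (cfg$n_background_reads > 0 && length(tx_seqs) > 0) {
        src <- sample(seq_along(tx_seqs), cfg$n_background_reads, replace = TRUE)
        starts <- vapply(src, function(i) {
          sample.int(nchar(tx_seqs[i]) - L + 1L, 1L)
        }, integer(1))
        rs <- substr(tx_seqs[src], starts, starts + L - 1L)
        names(rs) <- sprintf("bg%05d", seq_along(rs))
      }
      for (id in names(planted$fusions)) {
        fus <- planted$fusions[[id]]
        if (fus$sample != s) next
        depth <- cfg$read_depth
        truth_counts[[length(truth_counts) + 1L]] <- data.frame(
          chimera_id = id, sample = s, planted_reads = depth,
          stringsAsFactors = FALSE)
        if (depth == 0) next
        jo <- fus$junction_offset
        lo <- max(1L, jo + cfg$flank - L + 1L)
        hi <- min(nchar(fus$seq) - L + 1L, jo - cfg$flank + 1L)
        if (lo > hi) stop("fused transcript too short for spanning reads: ", id)
        starts <- lo + sample.int(hi - lo + 1L, depth, replace = TRUE) - 1L
        sp <- substr(rep(fus$seq, depth), starts, starts + L - 1L)
        sp <- apply_read_errors(sp, cfg$error_rate, cfg$indel_rate)
        flip <- seq_len(depth) %% 2L == 0L
        if (any(flip)) {
          sp[flip] <- as.character(Biostrings::reverseComplement(
            Biostrings::DNAStringSet(sp[flip])))
        }
        names(sp) <- sprintf("%s_sp%03d", id, seq_len(depth))
        rs <- c(rs, sp)
      }
      reads[[s]] <- rs
    }
    truth_counts <- if (length(truth_counts) > 0) {
      do.call(rbind, truth_counts)
    } else {
      data.frame(chimera_id = character(0), sample = character(0),
                 planted_reads = integer(0))
    }
    out <- list(reads = reads, truth_counts = truth_counts)
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      out$fastq <- vapply(all_samples, function(s) {
        write_fastq(reads[[s]], file.path(dir, paste0(s, ".fastq")))
      }, character(1))
    }
    out
  })
}

#' Simulate a full cohort (genome, planted fusions, reads)
#'
#' Convenience wrapper chaining [simulate_genome()], [plant_fusions()] and
#' [simulate_reads()].
#'
#' @param cfg A `sim_config`.
#' @param dir Optional output directory for FASTA/GTF/FASTQ files.
#' @return List combining the three stages' outputs.
#' @export
simulate_cohort <- function(cfg, dir = NULL) {
  sim <- simulate_genome(cfg, dir = dir)
  planted <- plant_fusions(sim, cfg)
  rd <- simulate_reads(planted, cfg, dir = dir)
  c(planted, rd, list(config = cfg))
}
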