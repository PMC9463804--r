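## In-memory gene/transcript/exon/CDS model built from GTF.
## Coordinate convention: 1-based, fully closed intervals (GTF) everywhere.

new_transcript_model <- function(transcript_id, chrom, strand, exons,
                                 cds = NULL, start_codon = NA_integer_) {
  stopifnot(strand %in% c("+", "-"))
  exons <- as.matrix(exons)
  storage.mode(exons) <- "integer"
  colnames(exons) <- c("start", "end")
  if (!is.null(cds) && nrow(cds) > 0) {
    cds <- as.matrix(cds)
    storage.mode(cds) <- "integer"
    colnames(cds) <- c("start", "end")
  } else {
    cds <- matrix(integer(0), ncol = 2, dimnames = list(NULL, c("start", "end")))
  }
  structure(
    list(transcript_id = transcript_id, chrom = chrom, strand = strand,
         exons = exons, cds = cds,
         start_codon = as.integer(unname(start_codon))),
    class = "transcript_model"
  )
}

new_gene_model <- function(gene_id, symbol, chrom, strand, transcripts,
                           biotype_attr = NA_character_) {
  spans <- do.call(rbind, lapply(transcripts, function(t) range(t$exons)))
  has_cds <- any(vapply(transcripts, function(t) nrow(t$cds) > 0, logical(1)))
  biotype <- if (has_cds) {
    "coding"
  } else if (!is.na(biotype_attr) && biotype_attr %in% c("lncRNA", "lincRNA")) {
    "lncRNA"
  } else if (is.na(biotype_attr)) {
    "lncRNA"
  } else {
    "other"
  }
  structure(
    list(gene_id = gene_id, symbol = symbol, chrom = chrom, strand = strand,
         start = min(spans), end = max(spans), biotype = biotype,
         transcripts = transcripts[order(names(transcripts))]),
    class = "gene_model"
  )
}

new_genome_annotation <- function(genes) {
  if (length(genes) > 0) genes <- genes[base::order(names(genes))]
  index <- data.frame(
    gene_id = vapply(genes, `[[`, "", "gene_id"),
    chrom   = vapply(genes, `[[`, "", "chrom"),
    strand  = vapply(genes, `[[`, "", "strand"),
    start   = vapply(genes, function(g) g$start, integer(1)),
    end     = vapply(genes, function(g) g$end, integer(1)),
    biotype = vapply(genes, `[[`, "", "biotype"),
    symbol  = vapply(genes, `[[`, "", "symbol"),
    stringsAsFactors = FALSE, row.names = NULL
  )
  index <- index[order(index$chrom, index$strand, index$start, index$gene_id), ,
                 drop = FALSE]
  rownames(index) <- NULL
  structure(list(genes = genes, index = index), class = "genome_annotation")
}

gtf_attr <- function(attrs, key) {
  m <- regmatches(attrs, regexpr(paste0(key, ' "[^"]*"'), attrs))
  if (length(m) == 0) return(NA_character_)
  sub(paste0(key, ' "([^"]*)"'), "\\1", m)
}

#' Read gene annotation from a GTF file
#'
#' Builds the in-memory gene → transcript → exon/CDS model that all junction
#' classification is performed against. Exons and CDS segments are stored
#' 5'→3' in transcription direction (descending genomic coordinate on the
#' minus strand). Coordinates are 1-based fully closed, the GTF convention.
#'
#' Only `exon`, `CDS` and `start_codon` feature rows are consumed; `gene`
#' and `transcript` rows are ignored (spans are recomputed from the exons).
#' Gene biotype is `"coding"` exactly when at least one transcript carries
#' CDS, otherwise it is taken from the `gene_biotype` attribute
#' (`lncRNA`/`lincRNA` map to `"lncRNA"`, anything else to `"other"`).
#'
#' @param path Path to a GTF file (Ensembl attribute dialect: `gene_id`,
#'   `transcript_id`, optional `gene_name` and `gene_biotype`).
#' @return A `genome_annotation` object: a sorted list of gene models plus a
#'   per-chromosome, per-strand index sorted by start coordinate.
#' @export
read_gene_annotation <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) return(new_genome_annotation(list()))

  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 9)
  if (length(bad) > 0) {
    stop("GTF parse error: line ", lineno[bad[1]], ": expected 9 tab-separated fields")
  }
  feat <- vapply(fields, `[[`, "", 3)
  use <- feat %in% c("exon", "CDS", "start_codon")
  fields <- fields[use]
  lineno <- lineno[use]
  feat <- feat[use]
  if (length(fields) == 0) return(new_genome_annotation(list()))

  chrom <- vapply(fields, `[[`, "", 1)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 4)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 5)))
  strand <- vapply(fields, `[[`, "", 7)
  attrs <- vapply(fields, `[[`, "", 9)
  if (anyNA(start) || anyNA(end)) {
    stop("GTF parse error: line ", lineno[which(is.na(start) | is.na(end))[1]],
         ": non-numeric coordinate")
  }
  if (!all(strand %in% c("+", "-"))) {
    stop("GTF parse error: line ", lineno[which(!strand %in% c("+", "-"))[1]],
         ": strand must be + or -")
  }
  gid <- vapply(attrs, gtf_attr, "", key = "gene_id", USE.NAMES = FALSE)
  tid <- vapply(attrs, gtf_attr, "", key = "transcript_id", USE.NAMES = FALSE)
  if (anyNA(gid)) {
    stop("GTF parse error: line ", lineno[which(is.na(gid))[1]],
         ": missing required attribute gene_id")
  }
  if (anyNA(tid)) {
    stop("GTF parse error: line ", lineno[which(is.na(tid))[1]],
         ": missing required attribute transcript_id")
  }
  gname <- vapply(attrs, gtf_attr, "", key = "gene_name", USE.NAMES = FALSE)
  gbio <- vapply(attrs, gtf_attr, "", key = "gene_biotype", USE.NAMES = FALSE)

  ## a transcript must belong to exactly one gene
  t2g <- unique(data.frame(tid = tid, gid = gid, stringsAsFactors = FALSE))
  dup <- t2g$tid[duplicated(t2g$tid)]
  if (length(dup) > 0) {
    stop("annotation validation error: transcript '", dup[1],
         "' is assigned to more than one gene")
  }

  genes <- list()
  for (g in sort(unique(gid))) {
    sel <- gid == g
    g_chrom <- unique(chrom[sel])
    g_strand <- unique(strand[sel])
    if (length(g_chrom) != 1 || length(g_strand) != 1) {
      stop("annotation validation error: gene '", g,
           "' spans multiple chromosomes or strands")
    }
    sym <- gname[sel]
    sym <- if (all(is.na(sym))) g else sym[!is.na(sym)][1]
    bio <- gbio[sel]
    bio <- if (all(is.na(bio))) NA_character_ else bio[!is.na(bio)][1]

    txs <- list()
    for (tr in sort(unique(tid[sel]))) {
      tsel <- sel & tid == tr
      ex <- cbind(start = start[tsel & feat == "exon"],
                  end = end[tsel & feat == "exon"])
      if (nrow(ex) == 0) next
      ex <- ex[order(ex[, "start"]), , drop = FALSE]
      if (nrow(ex) > 1 && any(ex[-1, "start"] <= ex[-nrow(ex), "end"])) {
        stop("annotation validation error: transcript '", tr,
             "' has overlapping or duplicate exons")
      }
      cd <- cbind(start = start[tsel & feat == "CDS"],
                  end = end[tsel & feat == "CDS"])
      cd <- cd[order(cd[, "start"]), , drop = FALSE]
      if (g_strand == "-") {
        ex <- ex[rev(seq_len(nrow(ex))), , drop = FALSE]
        cd <- cd[rev(seq_len(nrow(cd))), , drop = FALSE]
      }
      sc <- start[tsel & feat == "start_codon"]
      sc_end <- end[tsel & feat == "start_codon"]
      start_codon <- if (length(sc) > 0) {
        if (g_strand == "+") min(sc) else max(sc_end)
      } else if (nrow(cd) > 0) {
        ## infer: first CDS base in transcription direction
        if (g_strand == "+") cd[1, "start"] else cd[1, "end"]
      } else {
        NA_integer_
      }
      txs[[tr]] <- new_transcript_model(tr, g_chrom, g_strand, ex, cd, start_codon)
    }
    if (length(txs) == 0) next
    genes[[g]] <- new_gene_model(g, sym, g_chrom, g_strand, txs, bio)
  }
  new_genome_annotation(genes)
}

#' Write a gene annotation back to GTF
#'
#' Emits exon and CDS rows (with `gene_id`, `transcript_id`, `gene_name`,
#' `gene_biotype` attributes) such that [read_gene_annotation()] recovers an
#' identical model (round trip).
#'
#' @param ann A `genome_annotation`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_annotation <- function(ann, path) {
  stopifnot(inherits(ann, "genome_annotation"))
  out <- character(0)
  for (g in ann$genes) {
    bio <- switch(g$biotype, coding = "protein_coding", lncRNA = "lncRNA", g$biotype)
    attr_base <- sprintf('gene_id "%s"; gene_name "%s"; gene_biotype "%s";',
                         g$gene_id, g$symbol, bio)
    for (t in g$transcripts) {
      at <- sprintf('%s transcript_id "%s";', attr_base, t$transcript_id)
      ex <- t$exons[order(t$exons[, "start"]), , drop = FALSE]
      out <- c(out, sprintf("%s\tchimeraScreen\texon\t%d\t%d\t.\t%s\t.\t%s",
                            g$chrom, ex[, "start"], ex[, "end"], g$strand, at))
      if (nrow(t$cds) > 0) {
        ## GTF frame column: bases to skip to reach the next codon start
        lens <- t$cds[, "end"] - t$cds[, "start"] + 1L
        frames <- (3L - (cumsum(c(0L, lens[-length(lens)])) %% 3L)) %% 3L
        ord <- order(t$cds[, "start"])
        out <- c(out, sprintf("%s\tchimeraScreen\tCDS\t%d\t%d\t.\t%s\t%d\t%s",
                              g$chrom, t$cds[ord, "start"], t$cds[ord, "end"],
                              g$strand, frames[ord], at))
      }
    }
  }
  writeLines(out, path)
  invisible(path)
}

#' @export
print.genome_annotation <- function(x, ...) {
  n_tx <- sum(vapply(x$genes, function(g) length(g$transcripts), integer(1)))
  cat(sprintf("genome_annotation: %d genes (%d coding), %d transcripts, %d chromosomes\n",
              length(x$genes), sum(x$index$biotype == "coding"), n_tx,
              length(unique(x$index$chrom))))
  invisible(x)
}

get_gene <- function(ann, gene_id) {
  g <- ann$genes[[gene_id]]
  if (is.null(g)) stop("unknown gene '", gene_id, "' in annotation")
  g
}

gene_symbol <- function(ann, gene_id) get_gene(ann, gene_id)$symbol

#' Count genes lying strictly between two genes
#'
#' Number of other genes on the same chromosome and strand whose entire span
#' lies strictly between the spans of `a` and `b`. Symmetric in `a` and `b`.
#' Zero interposed genes is the adjacency ("neighboring genes") criterion
#' used for read-through (cis-SAGe) classification.
#'
#' @param ann A `genome_annotation`.
#' @param a,b Gene ids on the same chromosome and strand.
#' @return Non-negative integer.
#' @export
count_genes_between <- function(ann, a, b) {
  ga <- get_gene(ann, a)
  gb <- get_gene(ann, b)
  if (ga$chrom != gb$chrom || ga$strand != gb$strand) {
    stop("contract violation: genes '", a, "' and '", b,
         "' are not on the same chromosome and strand")
  }
  left_end <- min(ga$end, gb$end)
  right_start <- max(ga$start, gb$start)
  idx <- ann$index
  sel <- idx$chrom == ga$chrom & idx$strand == ga$strand &
    !(idx$gene_id %in% c(a, b)) &
    idx$start > left_end & idx$end < right_start
  sum(sel)
}

#' Classify a genomic position against a gene's exon boundaries
#'
#' A position is `EXON_EDGE` when, for any transcript of the gene, it equals
#' the transcription-orientation end of an exon (`role = "donor"`) or the
#' transcription-orientation start of an exon (`role = "acceptor"`). On the
#' minus strand the donor edge is the genomically smallest exon base.
#' Positions inside an exon but not at the required edge are
#' `EXON_INTERNAL`; intronic positions are `OUTSIDE_EXONS`.
#'
#' @param ann A `genome_annotation`.
#' @param gene Gene id.
#' @param pos Genomic position (1-based), within the gene span.
#' @param role `"donor"` (5' side of a junction) or `"acceptor"` (3' side).
#' @return One of `"EXON_EDGE"`, `"EXON_INTERNAL"`, `"OUTSIDE_EXONS"`.
#' @export
boundary_status <- function(ann, gene, pos, role = c("donor", "acceptor")) {
  role <- match.arg(role)
  g <- get_gene(ann, gene)
  if (pos < g$start || pos > g$end) {
    stop("contract violation: position ", pos, " outside span of gene '", gene, "'")
  }
  inside <- FALSE
  for (t in g$transcripts) {
    edges <- if ((g$strand == "+") == (role == "donor")) {
      t$exons[, "end"]
    } else {
      t$exons[, "start"]
    }
    if (pos %in% edges) return("EXON_EDGE")
    if (any(pos >= t$exons[, "start"] & pos <= t$exons[, "end"])) inside <- TRUE
  }
  if (inside) "EXON_INTERNAL" else "OUTSIDE_EXONS"
}

## ---- transcript-level helpers (shared by classification and ORF code) ----

## CDS bases of transcript `tx` at or upstream (transcription direction) of
## genomic position `pos`, inclusive.
cds_upstream_len <- function(tx, pos) {
  if (nrow(tx$cds) == 0) return(0L)
  if (tx$strand == "+") {
    sum(pmax(0L, pmin(tx$cds[, "end"], pos) - tx$cds[, "start"] + 1L))
  } else {
    sum(pmax(0L, tx$cds[, "end"] - pmax(tx$cds[, "start"], pos) + 1L))
  }
}

pos_in_cds <- function(tx, pos) {
  nrow(tx$cds) > 0 && any(pos >= tx$cds[, "start"] & pos <= tx$cds[, "end"])
}

pos_in_exons <- function(tx, pos) {
  any(pos >= tx$exons[, "start"] & pos <= tx$exons[, "end"])
}

## 0-based CDS offset of `pos` (bases strictly upstream of pos).
cds_offset <- function(tx, pos) cds_upstream_len(tx, pos) - 1L

load_genome <- function(genome) {
  if (is.character(genome) && length(genome) == 1 && file.exists(genome)) {
    genome <- Biostrings::readDNAStringSet(genome)
  }
  if (is(genome, "DNAStringSet")) {
    names(genome) <- sub("\\s.*$", "", names(genome))
    return(genome)
  }
  stop("genome must be a DNAStringSet or a FASTA path")
}

genome_seq <- function(genome, chrom, start, end, revcomp = FALSE) {
  if (!chrom %in% names(genome)) stop("unknown sequence '", chrom, "' in genome")
  s <- Biostrings::subseq(genome[[chrom]], start, end)
  if (revcomp) s <- Biostrings::reverseComplement(s)
  as.character(s)
}

## Spliced sequence of a transcript (transcription orientation).
transcript_seq <- function(tx, genome) {
  genome <- load_genome(genome)
  parts <- vapply(seq_len(nrow(tx$exons)), function(i) {
    s <- tx$exons[i, "start"]; e <- tx$exons[i, "end"]
    genome_seq(genome, tx$chrom, s, e, revcomp = tx$strand == "-")
  }, character(1))
  paste(parts, collapse = "")
}

## Spliced CDS sequence of a transcript.
transcript_cds_seq <- function(tx, genome) {
  if (nrow(tx$cds) == 0) return("")
  genome <- load_genome(genome)
  parts <- vapply(seq_len(nrow(tx$cds)), function(i) {
    genome_seq(genome, tx$chrom, tx$cds[i, "start"], tx$cds[i, "end"],
               revcomp = tx$strand == "-")
  }, character(1))
  paste(parts, collapse = "")
}

## Exonic (spliced) bases of `tx` at/upstream of pos (inclusive), 5' side of
## a junction; and at/downstream of pos (inclusive), 3' side.
spliced_upstream_seq <- function(tx, pos, genome) {
  genome <- load_genome(genome)
  parts <- character(0)
  for (i in seq_len(nrow(tx$exons))) {
    s <- tx$exons[i, "start"]; e <- tx$exons[i, "end"]
    if (pos >= s && pos <= e) {
      parts <- c(parts, if (tx$strand == "+") {
        genome_seq(genome, tx$chrom, s, pos)
      } else {
        genome_seq(genome, tx$chrom, pos, e, revcomp = TRUE)
      })
      return(paste(parts, collapse = ""))
    }
    parts <- c(parts, genome_seq(genome, tx$chrom, s, e, revcomp = tx$strand == "-"))
  }
  stop("position ", pos, " not exonic in transcript '", tx$transcript_id, "'")
}

spliced_downstream_seq <- function(tx, pos, genome) {
  genome <- load_genome(genome)
  parts <- character(0)
  started <- FALSE
  for (i in seq_len(nrow(tx$exons))) {
    s <- tx$exons[i, "start"]; e <- tx$exons[i, "end"]
    if (!started && pos >= s && pos <= e) {
      started <- TRUE
      parts <- c(parts, if (tx$strand == "+") {
        genome_seq(genome, tx$chrom, pos, e)
      } else {
        genome_seq(genome, tx$chrom, s, pos, revcomp = TRUE)
      })
    } else if (started) {
      parts <- c(parts, genome_seq(genome, tx$chrom, s, e, revcomp = tx$strand == "-"))
    }
  }
  if (!started) {
    stop("position ", pos, " not exonic in transcript '", tx$transcript_id, "'")
  }
  paste(parts, collapse = "")
}
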