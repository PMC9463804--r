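## Fused transcript assembly and ORF/protein isoform prediction
## (the e1e4-vs-e2e4 style comparison).

#' Assemble a fused transcript from two parental transcripts
#'
#' The fused exon chain is the first `n5` exons of the 5' transcript
#' followed by exons `first3` to the end of the 3' transcript, both in
#' transcription order. The spliced sequence reverse-complements
#' minus-strand exons; the junction offset is the length of the 5' portion.
#'
#' @param tx5 5' `transcript_model`.
#' @param n5 Number of 5' exons retained (1-based count, `>= 1`).
#' @param tx3 3' `transcript_model`.
#' @param first3 Index of the first retained 3' exon.
#' @param genome Genome sequences (`DNAStringSet` or FASTA path).
#' @return A `fusion_transcript`: retained exon tables, spliced `seq`,
#'   `junction_offset`, and provenance fields.
#' @export
fuse_transcripts <- function(tx5, n5, tx3, first3, genome) {
  genome <- load_genome(genome)
  n5 <- as.integer(n5)
  first3 <- as.integer(first3)
  if (n5 < 1 || n5 > nrow(tx5$exons)) {
    stop("exon index out of range: n5 = ", n5, " (5' transcript has ",
         nrow(tx5$exons), " exons)")
  }
  if (first3 < 1 || first3 > nrow(tx3$exons)) {
    stop("exon index out of range: first3 = ", first3, " (3' transcript has ",
         nrow(tx3$exons), " exons)")
  }
  splice <- function(tx, rows) {
    paste(vapply(rows, function(i) {
      genome_seq(genome, tx$chrom, tx$exons[i, "start"], tx$exons[i, "end"],
                 revcomp = tx$strand == "-")
    }, character(1)), collapse = "")
  }
  seq5 <- splice(tx5, seq_len(n5))
  seq3 <- splice(tx3, seq(first3, nrow(tx3$exons)))
  structure(
    list(tx5_id = tx5$transcript_id, tx3_id = tx3$transcript_id,
         n5 = n5, first3 = first3,
         exons5 = tx5$exons[seq_len(n5), , drop = FALSE],
         exons3 = tx3$exons[seq(first3, nrow(tx3$exons)), , drop = FALSE],
         strand5 = tx5$strand, strand3 = tx3$strand,
         chrom5 = tx5$chrom, chrom3 = tx3$chrom,
         seq = paste0(seq5, seq3),
         junction_offset = as.integer(nchar(seq5)),
         n_exons = n5 + (nrow(tx3$exons) - first3 + 1L)),
    class = "fusion_transcript"
  )
}

#' @export
print.fusion_transcript <- function(x, ...) {
  cat(sprintf("fusion_transcript: %s (first %d exons) + %s (exons %d..%d); %d exons, %d nt, junction at %d\n",
              x$tx5_id, x$n5, x$tx3_id, x$first3,
              x$first3 + nrow(x$exons3) - 1L, x$n_exons, nchar(x$seq),
              x$junction_offset))
  invisible(x)
}

## 1-based offset of genomic position `pos` within the retained 5' portion
## of the fused sequence; NA when not contained.
offset_in_exons <- function(exons, strand, pos) {
  off <- 0L
  for (i in seq_len(nrow(exons))) {
    s <- exons[i, "start"]; e <- exons[i, "end"]
    if (pos >= s && pos <= e) {
      return(as.integer(unname(off + if (strand == "+") pos - s + 1L else e - pos + 1L)))
    }
    off <- off + (e - s + 1L)
  }
  NA_integer_
}

translate_from <- function(seq, start) {
  sub <- substr(seq, start, nchar(seq))
  sub <- substr(sub, 1L, (nchar(sub) %/% 3L) * 3L)
  if (nchar(sub) == 0) return("")
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(sub),
                                           if.fuzzy.codon = "X"))
  stop_at <- regexpr("*", aa, fixed = TRUE)
  if (stop_at > 0) substr(aa, 1L, stop_at - 1L) else aa
}

#' Predict the protein product of a fused transcript
#'
#' If the 5' parent's annotated start codon lies within the retained 5'
#' portion, translation starts there and reads through the junction in that
#' single forward frame (`origin = "FIVE_PRIME_CDS"`). Otherwise the fused
#' sequence is scanned 5'→3' for the first `ATG` (`origin =
#' "INTERNAL_ATG"`); ambiguous bases never form a start codon. With no
#' usable start the origin is `"NONE"` and the protein is empty.
#' Translation uses the standard genetic code and stops at the first stop
#' codon (or the transcript end).
#'
#' @param f A `fusion_transcript`.
#' @param tx5 The 5' `transcript_model` (provides the annotated start
#'   codon).
#' @return A `fusion_protein`: `protein` (amino-acid string), `origin`,
#'   `start_offset` (1-based position of the start codon in the fused
#'   sequence).
#' @export
predict_protein <- function(f, tx5) {
  if (nchar(f$seq) == 0) stop("fused sequence is empty")
  start <- NA_integer_
  origin <- "NONE"
  if (!is.na(tx5$start_codon)) {
    off <- offset_in_exons(f$exons5, f$strand5, tx5$start_codon)
    if (!is.na(off) && substr(f$seq, off, off + 2L) == "ATG") {
      start <- off
      origin <- "FIVE_PRIME_CDS"
    }
  }
  if (is.na(start)) {
    hit <- regexpr("ATG", f$seq, fixed = TRUE)
    if (hit > 0) {
      start <- as.integer(hit)
      origin <- "INTERNAL_ATG"
    }
  }
  protein <- if (is.na(start)) "" else translate_from(f$seq, start)
  if (nchar(protein) == 0) {
    origin <- "NONE"
    start <- NA_integer_
  }
  structure(list(protein = protein, origin = origin, start_offset = start),
            class = "fusion_protein")
}

#' @export
print.fusion_protein <- function(x, ...) {
  cat(sprintf("fusion_protein (%s): %d aa\n", x$origin, nchar(x$protein)))
  if (nchar(x$protein) > 0) cat(" ", x$protein, "\n")
  invisible(x)
}

#' Compare two fusion protein isoforms
#'
#' @param a,b `fusion_protein`s (or amino-acid strings); both must be
#'   non-empty.
#' @return List with `length_difference` (`len(a) - len(b)`) and
#'   `shared_suffix` (length of the longest common C-terminal suffix).
#' @export
compare_isoforms <- function(a, b) {
  pa <- if (inherits(a, "fusion_protein")) a$protein else as.character(a)
  pb <- if (inherits(b, "fusion_protein")) b$protein else as.character(b)
  if (nchar(pa) == 0 || nchar(pb) == 0) {
    stop("cannot compare an empty protein")
  }
  ca <- rev(strsplit(pa, "")[[1]])
  cb <- rev(strsplit(pb, "")[[1]])
  m <- min(length(ca), length(cb))
  same <- ca[seq_len(m)] == cb[seq_len(m)]
  shared <- if (all(same)) m else which(!same)[1] - 1L
  list(length_difference = nchar(pa) - nchar(pb),
       shared_suffix = as.integer(shared))
}

#' Translate a transcript's annotated CDS
#'
#' Reference peptide of a parental transcript (stop codon removed), used to
#' check that in-frame fusions preserve the 3' parent's downstream peptide.
#'
#' @param tx A `transcript_model` with CDS.
#' @param genome Genome sequences.
#' @return Amino-acid string.
#' @export
transcript_protein <- function(tx, genome) {
  cds <- transcript_cds_seq(tx, genome)
  if (nchar(cds) == 0) stop("transcript '", tx$transcript_id, "' has no CDS")
  translate_from(cds, 1L)
}
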