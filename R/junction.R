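## AGREP-equivalent junction-spanning read counting: a junction probe is
## searched against every read (and its reverse complement) allowing up to
## k edit-distance errors, using a bit-parallel (Myers) matcher.

#' Build a junction-spanning probe for a chimera
#'
#' The probe is the last `min(flank, available)` transcribed (exonic) bases
#' of the 5' segment followed by the first `min(flank, available)` bases of
#' the 3' segment, spliced in transcription orientation. When the call
#' carries a `junction_seq`, that sequence is used verbatim (the flank split
#' is then taken as half the length, 5'-heavy for odd lengths).
#'
#' @param call A single call (list or one-row `chimera_calls`).
#' @param ann A `genome_annotation` (needed unless `junction_seq` is set).
#' @param genome Genome sequences (`DNAStringSet` or FASTA path).
#' @param flank Bases taken from each side of the junction (default 30).
#' @return A `junction_probe`: `chimera_id`, `sequence`, `flank5_len`,
#'   `flank3_len`.
#' @export
build_probe <- function(call, ann = NULL, genome = NULL, flank = 30) {
  if (!is.null(call$junction_seq) && !is.na(call$junction_seq)) {
    seq <- toupper(call$junction_seq)
    f5 <- as.integer(ceiling(nchar(seq) / 2))
    return(structure(list(chimera_id = call$chimera_id, sequence = seq,
                          flank5_len = f5, flank3_len = nchar(seq) - f5),
                     class = "junction_probe"))
  }
  if (is.null(ann) || is.null(genome)) {
    stop("no junction_seq on call '", call$chimera_id %||% "?",
         "': annotation and genome are required to build the probe")
  }
  genome <- load_genome(genome)
  g5 <- get_gene(ann, call$gene5)
  g3 <- get_gene(ann, call$gene3)
  t5 <- Filter(function(t) pos_in_exons(t, call$pos5), g5$transcripts)
  t3 <- Filter(function(t) pos_in_exons(t, call$pos3), g3$transcripts)
  if (length(t5) == 0) {
    stop("no transcript of '", call$gene5, "' has an exon containing position ",
         call$pos5)
  }
  if (length(t3) == 0) {
    stop("no transcript of '", call$gene3, "' has an exon containing position ",
         call$pos3)
  }
  up <- spliced_upstream_seq(t5[[1]], call$pos5, genome)
  down <- spliced_downstream_seq(t3[[1]], call$pos3, genome)
  f5 <- as.integer(min(flank, nchar(up)))
  f3 <- as.integer(min(flank, nchar(down)))
  seq <- paste0(substr(up, nchar(up) - f5 + 1L, nchar(up)), substr(down, 1L, f3))
  structure(list(chimera_id = call$chimera_id, sequence = seq,
                 flank5_len = f5, flank3_len = f3),
            class = "junction_probe")
}

#' @export
print.junction_probe <- function(x, ...) {
  cat(sprintf("junction_probe %s: %d + %d nt\n  %s | %s\n",
              x$chimera_id, x$flank5_len, x$flank3_len,
              substr(x$sequence, 1, x$flank5_len),
              substr(x$sequence, x$flank5_len + 1, nchar(x$sequence))))
  invisible(x)
}

probe_sequence <- function(probe) {
  if (inherits(probe, "junction_probe")) probe$sequence else toupper(as.character(probe))
}

load_reads <- function(reads) {
  if (is.character(reads) && length(reads) == 1 && file.exists(reads)) {
    fmt <- if (grepl("\\.f(ast)?q(\\.gz)?$", reads, ignore.case = TRUE)) "fastq" else "fasta"
    reads <- Biostrings::readDNAStringSet(reads, format = fmt)
  }
  if (is(reads, "DNAStringSet")) reads <- as.character(reads)
  unname(toupper(reads))
}

#' Semi-global match distance of a probe against texts
#'
#' Minimum edit distance (substitutions + insertions + deletions) between
#' the full probe and any substring of each text, computed with the
#' bit-parallel Myers algorithm (dynamic-programming fallback for probes
#' longer than 64 nt). `N` (or any non-ACGT symbol) in the probe or the text
#' never matches anything. The forward orientation only; see
#' [count_junction_reads()] for double-stranded counting.
#'
#' @param probe Probe sequence (`junction_probe` or character).
#' @param texts Character vector of texts (reads).
#' @return Integer vector of distances, one per text.
#' @export
probe_match_distance <- function(probe, texts) {
  cpp_semiglobal_distance(probe_sequence(probe), toupper(texts))
}

#' Count junction-spanning reads with up to k errors
#'
#' Counts the reads in which the full probe matches some substring of the
#' read, or of its reverse complement, within edit distance `max_errors`
#' (semi-global match). Each read is counted at most once even if both
#' orientations match. Probes shorter than 20 nt are refused as too
#' unspecific; reads shorter than `probe length - max_errors` cannot match
#' and contribute 0.
#'
#' @param probe A `junction_probe` or probe sequence.
#' @param reads Reads: FASTQ/FASTA path, `DNAStringSet`, or character
#'   vector.
#' @param max_errors Allowed edit distance (default 1, the "1 error
#'   allowed" setting).
#' @return Integer raw count.
#' @export
count_junction_reads <- function(probe, reads, max_errors = 1) {
  seq <- probe_sequence(probe)
  if (nchar(seq) < 20) {
    stop("probe shorter than 20 nt refused (too unspecific): length ", nchar(seq))
  }
  stopifnot(max_errors >= 0)
  reads <- load_reads(reads)
  if (length(reads) == 0) return(0L)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(reads)))
  sum(cpp_match_either(seq, reads, unname(rc), as.integer(max_errors)))
}

#' Count a probe panel across read sets
#'
#' @param probes List of `junction_probe`s.
#' @param reads_by_sample Named list (sample → reads as in
#'   [count_junction_reads()]).
#' @param max_errors Allowed edit distance per match (default 1).
#' @return Data frame of count records: `chimera_id`, `sample`,
#'   `raw_count`, `total_reads`, `cpm`, `bin`.
#' @export
count_table <- function(probes, reads_by_sample, max_errors = 1) {
  stopifnot(length(names(reads_by_sample)) == length(reads_by_sample))
  out <- list()
  for (s in names(reads_by_sample)) {
    reads <- load_reads(reads_by_sample[[s]])
    total <- length(reads)
    for (p in probes) {
      raw <- count_junction_reads(p, reads, max_errors = max_errors)
      out[[length(out) + 1L]] <- data.frame(
        chimera_id = p$chimera_id, sample = s, raw_count = raw,
        total_reads = total,
        cpm = if (total > 0) raw * 1e6 / total else NA_real_,
        bin = bin_mean_reads(raw),
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}

#' Bin mean read counts on the detection scale
#'
#' `-` for x < 1, `+` for 1 <= x < 5, `++` for 5 <= x < 10, `+++` for
#' x >= 10.
#'
#' @param x Numeric vector of non-negative mean read counts.
#' @return Character vector of bin symbols.
#' @export
bin_mean_reads <- function(x) {
  if (any(is.na(x)) || any(x < 0)) {
    stop("contract violation: mean read counts must be non-negative")
  }
  as.character(cut(x, breaks = c(0, 1, 5, 10, Inf), right = FALSE,
                   include.lowest = TRUE, labels = c("-", "+", "++", "+++")))
}

#' Count chimeras detected in a dataset column of a bin table
#'
#' A chimera counts as present when its bin symbol is anything other than
#' `-` (mean reads below 1).
#'
#' @param bin_table Data frame of bin symbols (rows = chimeras), e.g. from
#'   [read_bin_table()].
#' @param column Column (dataset/sample) name.
#' @return Integer number of detected chimeras.
#' @export
count_present <- function(bin_table, column) {
  if (!column %in% names(bin_table)) {
    stop("unknown column '", column, "' in bin table")
  }
  sum(bin_table[[column]] != "-")
}

#' Read a bin-symbol table
#'
#' Tab-separated table whose first column (`fusion`) names the chimeras and
#' whose remaining columns hold bin symbols per dataset.
#'
#' @param path Path to the TSV file.
#' @return Data frame with `fusion` plus one character column per dataset.
#' @export
read_bin_table <- function(path) {
  utils::read.delim(path, colClasses = "character", check.names = FALSE,
                    na.strings = NULL)
}

#' Counts-per-million normalisation
#'
#' @param raw_count Raw junction-spanning read count(s).
#' @param total_reads Total reads in the sample (must be positive).
#' @return `raw_count * 1e6 / total_reads`.
#' @export
normalize_cpm <- function(raw_count, total_reads) {
  if (any(total_reads <= 0)) stop("total_reads must be positive")
  raw_count * 1e6 / total_reads
}
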