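## The post-caller filtering cascade:
## score filter -> M/M removal -> normal-tissue blacklist subtraction ->
## normal-sample subtraction -> flank-homology screen -> group-specific sets.
##
## Every stage appends a row to the filter trace carried on the call table
## (attribute "filter_trace"); input = removed + output at every stage.

#' Filter trace of a call table
#'
#' @param calls A `chimera_calls` data frame that has passed through one or
#'   more filter stages.
#' @return Data frame with columns `stage`, `input`, `removed`, `output`
#'   (one row per stage, in execution order), or `NULL` if no stage ran.
#' @export
filter_trace <- function(calls) attr(calls, "filter_trace")

add_trace <- function(out, calls, stage, removed) {
  tr <- rbind(attr(calls, "filter_trace"),
              data.frame(stage = stage, input = nrow(calls),
                         removed = removed, output = nrow(calls) - removed,
                         stringsAsFactors = FALSE))
  attr(out, "filter_trace") <- tr
  class(out) <- c("chimera_calls", "data.frame")
  out
}

subset_calls <- function(calls, keep) {
  out <- as.data.frame(calls)[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter candidates by caller confidence score
#'
#' Retains calls with `score >= min_score`; the default 0.6 discards
#' everything the caller scored strictly below 0.6.
#'
#' @param calls A `chimera_calls` data frame.
#' @param min_score Minimum retained score (default 0.6).
#' @return Filtered `chimera_calls` with an updated filter trace.
#' @export
filter_by_score <- function(calls, min_score = 0.6) {
  keep <- calls$score >= min_score
  add_trace(subset_calls(calls, keep), calls, "score_filter", sum(!keep))
}

#' Remove M/M-class candidates
#'
#' Drops every call whose junction class is `MM` (both junction sites in
#' the middle of exons), the class with the lowest validation rate.
#' Unclassifiable calls (junction outside annotated exons) are also removed
#' and recorded separately in the `"dropped_unclassifiable"` attribute.
#'
#' @param calls A `chimera_calls` data frame.
#' @param ann A `genome_annotation`.
#' @return Filtered `chimera_calls` with an updated filter trace.
#' @export
drop_mm <- function(calls, ann) {
  cls <- classify_calls(calls, ann)
  keep <- !cls$flagged & cls$junction_class != "MM"
  keep[is.na(keep)] <- FALSE
  out <- add_trace(subset_calls(calls, keep), calls, "drop_mm", sum(!keep))
  attr(out, "dropped_unclassifiable") <- calls$chimera_id[cls$flagged]
  out
}

#' Subtract blacklisted gene pairs
#'
#' Removes calls whose ordered (5'→3') gene-symbol pair appears in the
#' blacklist of chimeras previously identified in normal tissues. Matching
#' is directional: the reversed pair does not match.
#'
#' @param calls A `chimera_calls` data frame.
#' @param blacklist A `chimera_blacklist` (see [read_blacklist()]).
#' @param ann Optional `genome_annotation` used to map gene ids to symbols;
#'   when `NULL`, `gene5`/`gene3` are taken to be symbols already.
#' @return Filtered `chimera_calls` with an updated filter trace.
#' @export
subtract_blacklist <- function(calls, blacklist, ann = NULL) {
  sym5 <- calls$gene5
  sym3 <- calls$gene3
  if (!is.null(ann)) {
    sym5 <- vapply(sym5, function(g) gene_symbol(ann, g), character(1))
    sym3 <- vapply(sym3, function(g) gene_symbol(ann, g), character(1))
  }
  bad_key <- paste(blacklist$gene5_symbol, blacklist$gene3_symbol, sep = "\r")
  keep <- !(paste(sym5, sym3, sep = "\r") %in% bad_key)
  add_trace(subset_calls(calls, keep), calls, "blacklist", sum(!keep))
}

#' Subtract chimeras observed in normal samples
#'
#' Any chimera (identity: gene pair plus exact junction coordinates)
#' observed in at least one normal sample is removed from all samples.
#'
#' @param calls A `chimera_calls` data frame.
#' @param normal_samples Character vector of normal sample labels (may be
#'   empty, in which case this stage removes nothing).
#' @return Filtered `chimera_calls` with an updated filter trace.
#' @export
subtract_samples <- function(calls, normal_samples) {
  key <- chimera_key(calls)
  normal_keys <- unique(key[calls$sample %in% normal_samples])
  keep <- !(key %in% normal_keys)
  add_trace(subset_calls(calls, keep), calls, "normal_samples", sum(!keep))
}

#' Flank-homology check for a single candidate junction
#'
#' Screens for junctions explainable by sequence homology between the two
#' genomic flanks (a hallmark of multi-mapping artifacts): extracts `flank`
#' bases upstream of `pos5` (transcription direction) and downstream of
#' `pos3`, computes the best local alignment between them (match +1,
#' mismatch -1, gap -2) and drops the call when the identity over the
#' aligned span is at least `min_identity` with an aligned span of at least
#' 20 bases. Flank windows extending past a contig end are truncated with a
#' warning; when both flanks end up shorter than 20 bases the call is kept
#' with a warning.
#'
#' @param call A single call (list or one-row data frame).
#' @param genome Genome sequences (`DNAStringSet` or FASTA path).
#' @param flank Flank length in bases (default 50).
#' @param min_identity Identity threshold in `[0, 1]` (default 0.8).
#' @return List with `decision` (`"keep"` or `"drop"`), `reason`,
#'   `identity` and `span` of the best local alignment.
#' @export
homology_check <- function(call, genome, flank = 50, min_identity = 0.8) {
  genome <- load_genome(genome)
  clen5 <- length(genome[[call$chrom5]])
  clen3 <- length(genome[[call$chrom3]])
  truncated <- FALSE

  if (call$strand5 == "+") {
    s <- call$pos5 - flank + 1L
    if (s < 1L) { s <- 1L; truncated <- TRUE }
    f5 <- genome_seq(genome, call$chrom5, s, call$pos5)
  } else {
    e <- call$pos5 + flank - 1L
    if (e > clen5) { e <- clen5; truncated <- TRUE }
    f5 <- genome_seq(genome, call$chrom5, call$pos5, e, revcomp = TRUE)
  }
  if (call$strand3 == "+") {
    e <- call$pos3 + flank - 1L
    if (e > clen3) { e <- clen3; truncated <- TRUE }
    f3 <- genome_seq(genome, call$chrom3, call$pos3, e)
  } else {
    s <- call$pos3 - flank + 1L
    if (s < 1L) { s <- 1L; truncated <- TRUE }
    f3 <- genome_seq(genome, call$chrom3, s, call$pos3, revcomp = TRUE)
  }
  if (truncated) {
    warning("flank window truncated at contig end for '",
            call$chimera_id %||% "?", "'")
  }
  if (nchar(f5) < 20 && nchar(f3) < 20) {
    warning("both flanks shorter than 20 bases for '",
            call$chimera_id %||% "?", "'; kept without homology check")
    return(list(decision = "keep", reason = "flanks_too_short",
                identity = NA_real_, span = NA_integer_))
  }
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  pa <- Biostrings::pairwiseAlignment(f5, f3, type = "local",
                                      substitutionMatrix = mat,
                                      gapOpening = 0, gapExtension = 2)
  span <- nchar(pa)
  identity <- if (span > 0) Biostrings::nmatch(pa) / span else 0
  if (span >= 20 && identity >= min_identity) {
    list(decision = "drop", reason = "flank_homology",
         identity = identity, span = span)
  } else {
    list(decision = "keep", reason = "no_homology",
         identity = identity, span = span)
  }
}

#' Apply the flank-homology screen to a call table
#'
#' @inheritParams homology_check
#' @param calls A `chimera_calls` data frame.
#' @return Filtered `chimera_calls`; dropped ids and their alignment
#'   identities are stored in the `"homology_dropped"` attribute.
#' @export
homology_filter <- function(calls, genome, flank = 50, min_identity = 0.8) {
  genome <- load_genome(genome)
  res <- lapply(seq_len(nrow(calls)), function(i) {
    homology_check(as.list(calls[i, , drop = FALSE]), genome,
                   flank = flank, min_identity = min_identity)
  })
  keep <- vapply(res, function(r) r$decision == "keep", logical(1))
  out <- add_trace(subset_calls(calls, keep), calls, "homology_filter", sum(!keep))
  attr(out, "homology_dropped") <- data.frame(
    chimera_id = calls$chimera_id[!keep],
    identity = vapply(res[!keep], `[[`, numeric(1), "identity"),
    span = vapply(res[!keep], `[[`, integer(1), "span"),
    stringsAsFactors = FALSE
  )
  out
}

#' Group-specific chimera sets and Venn cells
#'
#' A chimera (identity: gene pair plus exact junction coordinates) is
#' specific to a group when it is observed in at least one member sample of
#' that group and in no member of any other group. The Venn cells partition
#' the union of all observed chimeras by the exact set of groups each was
#' seen in.
#'
#' @param calls A `chimera_calls` data frame.
#' @param groups A `cell_line_groups` object covering every sample in
#'   `calls` (an unassigned sample is a contract violation).
#' @return A `specificity_sets` object: `specific` (named list of chimera
#'   key tables per group), `venn` (cell label → chimera count) and
#'   `membership` (per-chimera group sets).
#' @export
specific_sets <- function(calls, groups) {
  grp <- sample_group(groups, calls$sample)
  if (anyNA(grp)) {
    stop("contract violation: sample '", calls$sample[is.na(grp)][1],
         "' is not assigned to any group")
  }
  key <- chimera_key(calls)
  membership <- tapply(grp, key, function(g) sort(unique(g)))
  cells <- vapply(membership, paste, character(1), collapse = "&")
  keys <- names(membership)
  first <- calls[!duplicated(key), , drop = FALSE]
  first_key <- chimera_key(first)
  specific <- lapply(names(groups), function(g) {
    sel_keys <- keys[cells == g]
    out <- as.data.frame(first)[match(sel_keys, first_key),
                                c("chimera_id", "gene5", "gene3", "pos5", "pos3"),
                                drop = FALSE]
    rownames(out) <- NULL
    out
  })
  names(specific) <- names(groups)
  structure(
    list(specific = specific,
         venn = table(cells),
         membership = data.frame(key = keys, groups = cells,
                                 stringsAsFactors = FALSE, row.names = NULL)),
    class = "specificity_sets"
  )
}

#' @export
print.specificity_sets <- function(x, ...) {
  cat("specificity_sets:\n  specific chimeras per group:\n")
  for (g in names(x$specific)) {
    cat(sprintf("    %-8s %d\n", g, nrow(x$specific[[g]])))
  }
  cat("  Venn cells:\n")
  for (cell in names(x$venn)) {
    cat(sprintf("    %-20s %d\n", cell, x$venn[[cell]]))
  }
  invisible(x)
}
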