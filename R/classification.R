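## The three classification axes: junction class (E/E, E/M, M/E, M/M),
## genomic relation (read-through / intra- / inter-chromosomal) and
## predicted reading frame (in frame / out of frame / NA).

JUNCTION_CLASSES <- c("EE", "EM", "ME", "MM")
GENOMIC_RELATIONS <- c("READ_THROUGH", "INTRA_CHROMOSOMAL", "INTER_CHROMOSOMAL")
FRAME_CLASSES <- c("IN_FRAME", "OUT_OF_FRAME", "NA")

unclassifiable <- function(msg) {
  stop(structure(class = c("chimera_unclassifiable", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Classify a chimera junction against known exon boundaries
#'
#' The first letter describes the 5' partner. `E` means the junction site
#' coincides with an annotated exon boundary in the required role (donor for
#' the 5' side, acceptor for the 3' side, for any transcript of the gene);
#' `M` means it falls in the middle of an exon. Junction positions outside
#' all annotated exons (intronic) raise an error of class
#' `chimera_unclassifiable`.
#'
#' @param call A single call (one-row `chimera_calls` data frame or list
#'   with fields `gene5`, `pos5`, `gene3`, `pos3`).
#' @param ann A `genome_annotation`.
#' @return One of `"EE"`, `"EM"`, `"ME"`, `"MM"`.
#' @export
classify_junction <- function(call, ann) {
  s5 <- boundary_status(ann, call$gene5, call$pos5, "donor")
  s3 <- boundary_status(ann, call$gene3, call$pos3, "acceptor")
  if (s5 == "OUTSIDE_EXONS" || s3 == "OUTSIDE_EXONS") {
    unclassifiable(sprintf(
      "junction of '%s' falls outside annotated exons (5': %s, 3': %s)",
      call$chimera_id %||% "?", s5, s3))
  }
  paste0(if (s5 == "EXON_EDGE") "E" else "M",
         if (s3 == "EXON_EDGE") "E" else "M")
}

#' Classify the genomic relation of a chimera's parental genes
#'
#' `INTER_CHROMOSOMAL` when the parents lie on different chromosomes;
#' `READ_THROUGH` (cis-SAGe) when they are same-strand neighbours — no other
#' gene lies entirely between them — with the 5' partner upstream of the 3'
#' partner in transcription direction; otherwise `INTRA_CHROMOSOMAL`.
#'
#' @inheritParams classify_junction
#' @return One of `"READ_THROUGH"`, `"INTRA_CHROMOSOMAL"`,
#'   `"INTER_CHROMOSOMAL"`.
#' @export
classify_relation <- function(call, ann) {
  g5 <- get_gene(ann, call$gene5)
  g3 <- get_gene(ann, call$gene3)
  if (g5$chrom != g3$chrom) return("INTER_CHROMOSOMAL")
  if (g5$strand == g3$strand) {
    upstream <- if (g5$strand == "+") g5$end < g3$start else g5$start > g3$end
    if (upstream && count_genes_between(ann, call$gene5, call$gene3) == 0) {
      return("READ_THROUGH")
    }
  }
  "INTRA_CHROMOSOMAL"
}

#' Predict the reading-frame consequence of a chimera
#'
#' `NA` when either parent is non-coding, or when either junction position
#' falls outside the parent's CDS (UTR) in every coding transcript.
#' Otherwise, for each pair of coding transcripts whose CDS contains the
#' respective junction position, let `L5` be the number of CDS bases of the
#' 5' transcript at or upstream (transcription direction) of `pos5`
#' (inclusive) and `phase3` the CDS offset of `pos3` in the 3' transcript
#' modulo 3. The chimera is `IN_FRAME` when `L5 %% 3 == phase3` for any such
#' pair (the downstream peptide of the 3' parent is then preserved),
#' `OUT_OF_FRAME` otherwise. The any-pair rule is order-free over transcript
#' lists.
#'
#' @inheritParams classify_junction
#' @return One of `"IN_FRAME"`, `"OUT_OF_FRAME"`, `"NA"`.
#' @export
classify_frame <- function(call, ann) {
  g5 <- get_gene(ann, call$gene5)
  g3 <- get_gene(ann, call$gene3)
  if (g5$biotype != "coding" || g3$biotype != "coding") return("NA")
  t5s <- Filter(function(t) pos_in_cds(t, call$pos5), g5$transcripts)
  t3s <- Filter(function(t) pos_in_cds(t, call$pos3), g3$transcripts)
  if (length(t5s) == 0 || length(t3s) == 0) return("NA")
  for (t5 in t5s) {
    l5 <- cds_upstream_len(t5, call$pos5)
    for (t3 in t3s) {
      if (l5 %% 3L == cds_offset(t3, call$pos3) %% 3L) return("IN_FRAME")
    }
  }
  "OUT_OF_FRAME"
}

#' Classify every call along the three axes
#'
#' Vectorised wrapper around [classify_junction()], [classify_relation()]
#' and [classify_frame()]. Calls whose junction cannot be classified
#' (intronic position) get `NA` classifications and `flagged = TRUE`, with a
#' message naming them.
#'
#' @param calls A `chimera_calls` data frame.
#' @param ann A `genome_annotation`.
#' @return Data frame with columns `chimera_id`, `sample`,
#'   `junction_class`, `genomic_relation`, `frame_class`, `flagged`.
#' @export
classify_calls <- function(calls, ann) {
  n <- nrow(calls)
  out <- data.frame(
    chimera_id = calls$chimera_id, sample = calls$sample,
    junction_class = rep(NA_character_, n),
    genomic_relation = rep(NA_character_, n),
    frame_class = rep(NA_character_, n),
    flagged = rep(FALSE, n),
    stringsAsFactors = FALSE
  )
  flagged_ids <- character(0)
  for (i in seq_len(n)) {
    call <- as.list(calls[i, , drop = FALSE])
    jc <- tryCatch(classify_junction(call, ann),
                   chimera_unclassifiable = function(e) NA_character_)
    if (is.na(jc)) {
      out$flagged[i] <- TRUE
      flagged_ids <- c(flagged_ids, call$chimera_id)
      next
    }
    out$junction_class[i] <- jc
    out$genomic_relation[i] <- classify_relation(call, ann)
    out$frame_class[i] <- classify_frame(call, ann)
  }
  if (length(flagged_ids) > 0) {
    message("flagged ", length(flagged_ids),
            " unclassifiable call(s) (junction outside annotated exons): ",
            paste(utils::head(flagged_ids, 5), collapse = ", "),
            if (length(flagged_ids) > 5) ", ..." else "")
  }
  out
}

#' Per-group category fractions along each classification axis
#'
#' For each group and axis, the fraction of (classifiable) calls in every
#' category of that axis; fractions sum to 1 per non-empty group and axis.
#' The `MM` junction category only appears when MM calls are present (the
#' standard cascade removes them before profiling). Empty groups get `NA`
#' fractions, not zeros.
#'
#' @param classified Output of [classify_calls()] (must contain `sample`).
#' @param groups A `cell_line_groups` object; `NULL` pools everything into
#'   one group `"ALL"`.
#' @return Long data frame: `group`, `axis`, `category`, `count`,
#'   `fraction`.
#' @export
category_profile <- function(classified, groups = NULL) {
  if (is.null(groups)) {
    grp <- rep("ALL", nrow(classified))
    group_names <- "ALL"
  } else {
    grp <- sample_group(groups, classified$sample)
    group_names <- names(groups)
  }
  junction_lv <- if (any(classified$junction_class == "MM", na.rm = TRUE)) {
    JUNCTION_CLASSES
  } else {
    setdiff(JUNCTION_CLASSES, "MM")
  }
  axes <- list(junction_class = junction_lv,
               genomic_relation = GENOMIC_RELATIONS,
               frame_class = FRAME_CLASSES)
  out <- list()
  for (g in group_names) {
    sub <- classified[!is.na(grp) & grp == g & !classified$flagged, , drop = FALSE]
    for (ax in names(axes)) {
      counts <- table(factor(sub[[ax]], levels = axes[[ax]]))
      n_tot <- sum(counts)
      out[[length(out) + 1L]] <- data.frame(
        group = g, axis = ax, category = names(counts),
        count = as.integer(counts),
        fraction = if (n_tot > 0) as.numeric(counts) / n_tot else NA_real_,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}
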