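## Candidate chimera tables, blacklists and cell-line group assignments.

CALL_COLUMNS <- c("chimera_id", "gene5", "gene3", "chrom5", "pos5", "strand5",
                  "chrom3", "pos3", "strand3", "score", "junction_seq", "sample")

## Column-name adapter from EricScript output onto the minimal call dialect.
ERICSCRIPT_COLUMN_MAP <- c(
  gene5 = "GeneName1", gene3 = "GeneName2",
  chrom5 = "chr1", pos5 = "Breakpoint1", strand5 = "strand1",
  chrom3 = "chr2", pos3 = "Breakpoint2", strand3 = "strand2",
  score = "EricScore", junction_seq = "JunctionSequence"
)

as_chimera_calls <- function(df, allow_intragenic = FALSE) {
  missing_cols <- setdiff(CALL_COLUMNS, names(df))
  if (length(missing_cols) > 0) {
    stop("schema error: missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  df <- df[, CALL_COLUMNS, drop = FALSE]
  df$pos5 <- as.integer(df$pos5)
  df$pos3 <- as.integer(df$pos3)
  df$score <- as.numeric(df$score)
  df$junction_seq <- as.character(df$junction_seq)
  df$junction_seq[!nzchar(df$junction_seq) | is.na(df$junction_seq)] <- NA_character_
  if (any(df$score < 0 | df$score > 1, na.rm = TRUE)) {
    stop("invalid call: score must lie in [0, 1]")
  }
  if (!all(df$strand5 %in% c("+", "-")) || !all(df$strand3 %in% c("+", "-"))) {
    stop("invalid call: strands must be + or -")
  }
  intragenic <- df$gene5 == df$gene3
  if (any(intragenic) && !allow_intragenic) {
    stop("invalid call: intragenic candidate (gene5 == gene3) rejected: '",
         df$gene5[which(intragenic)[1]], "'")
  }
  rownames(df) <- NULL
  class(df) <- c("chimera_calls", "data.frame")
  df
}

#' Read a candidate chimera table
#'
#' Reads the minimal tab-separated call dialect (columns `chimera_id`,
#' `gene5`, `gene3`, `chrom5`, `pos5`, `strand5`, `chrom3`, `pos3`,
#' `strand3`, `score`, `junction_seq`, `sample`). `pos5` is the last
#' transcribed base of the 5' segment, `pos3` the first base of the 3'
#' segment. Exact duplicate candidates (same `gene5`, `gene3`, `pos5`,
#' `pos3`, `sample`) are collapsed with a warning; row order is otherwise
#' preserved. An empty `junction_seq` field is read as `NA`.
#'
#' @param path Path to the TSV file (header row required).
#' @param allow_intragenic Keep candidates with `gene5 == gene3`
#'   (default `FALSE`: such rows are rejected with an error).
#' @return A `chimera_calls` data frame.
#' @seealso [read_ericscript()] for EricScript-native output.
#' @export
read_calls <- function(path, allow_intragenic = FALSE) {
  df <- utils::read.delim(path, colClasses = "character", check.names = FALSE,
                          na.strings = NULL)
  missing_cols <- setdiff(CALL_COLUMNS, names(df))
  if (length(missing_cols) > 0) {
    stop("schema error: missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  num <- suppressWarnings(as.numeric(df$score))
  bad <- which(is.na(num))
  if (length(bad) > 0) {
    stop("row error: line ", bad[1] + 1L, ": non-numeric score '", df$score[bad[1]], "'")
  }
  df$score <- num
  bad_pos <- which(is.na(suppressWarnings(as.integer(df$pos5))) |
                     is.na(suppressWarnings(as.integer(df$pos3))))
  if (length(bad_pos) > 0) {
    stop("row error: line ", bad_pos[1] + 1L, ": non-numeric junction position")
  }
  calls <- as_chimera_calls(df, allow_intragenic = allow_intragenic)
  key <- chimera_key(calls, with_sample = TRUE)
  if (anyDuplicated(key)) {
    n_dup <- sum(duplicated(key))
    warning("removed ", n_dup, " duplicate call row(s) (same gene pair, junction and sample)")
    calls <- calls[!duplicated(key), , drop = FALSE]
    rownames(calls) <- NULL
    class(calls) <- c("chimera_calls", "data.frame")
  }
  calls
}

#' Write a candidate chimera table
#'
#' Inverse of [read_calls()]: `read_calls(write_calls(x))` recovers `x`.
#'
#' @param calls A `chimera_calls` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calls <- function(calls, path) {
  df <- as.data.frame(calls)
  df$score <- sprintf("%.15g", df$score)
  df$junction_seq[is.na(df$junction_seq)] <- ""
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read EricScript results into the call dialect
#'
#' Maps EricScript's native column names (`GeneName1`, `GeneName2`,
#' `Breakpoint1`, `EricScore`, ...) onto the minimal call table. Chimera ids
#' are synthesised as `gene5--gene3.<row>`.
#'
#' @param path Path to an EricScript `.results` TSV.
#' @param sample Sample label to attach to every row.
#' @return A `chimera_calls` data frame.
#' @export
read_ericscript <- function(path, sample) {
  df <- utils::read.delim(path, colClasses = "character", check.names = FALSE,
                          na.strings = NULL)
  missing_cols <- setdiff(unname(ERICSCRIPT_COLUMN_MAP), names(df))
  if (length(missing_cols) > 0) {
    stop("schema error: missing EricScript column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  out <- data.frame(lapply(ERICSCRIPT_COLUMN_MAP, function(cn) df[[cn]]),
                    stringsAsFactors = FALSE)
  out$chimera_id <- sprintf("%s--%s.%d", out$gene5, out$gene3, seq_len(nrow(out)))
  out$sample <- rep(sample, nrow(out))
  as_chimera_calls(out)
}

## Identity key of a chimera across samples: exact gene pair + junction.
chimera_key <- function(calls, with_sample = FALSE) {
  k <- paste(calls$gene5, calls$gene3, calls$pos5, calls$pos3, sep = "\r")
  if (with_sample) k <- paste(k, calls$sample, sep = "\r")
  k
}

#' Read a gene-pair blacklist
#'
#' Two-column (5' symbol, 3' symbol) whitespace- or tab-separated file of
#' chimeras observed in normal tissue. Pairs are ordered (5'→3'): a pair
#' listed only in the reverse orientation does not match. Duplicates
#' collapse (set semantics).
#'
#' @param path Path to the blacklist file.
#' @return A `chimera_blacklist` data frame with columns `gene5_symbol`,
#'   `gene3_symbol`.
#' @export
read_blacklist <- function(path) {
  lines <- readLines(path)
  keep <- nzchar(trimws(lines)) & !grepl("^#", lines)
  lineno <- which(keep)
  parts <- strsplit(trimws(lines[keep]), "[\t ]+")
  bad <- which(lengths(parts) != 2)
  if (length(bad) > 0) {
    stop("blacklist parse error: line ", lineno[bad[1]],
         ": expected two gene symbols")
  }
  df <- data.frame(
    gene5_symbol = vapply(parts, `[[`, "", 1),
    gene3_symbol = vapply(parts, `[[`, "", 2),
    stringsAsFactors = FALSE
  )
  df <- unique(df)
  rownames(df) <- NULL
  class(df) <- c("chimera_blacklist", "data.frame")
  df
}

#' Define cell-line groups
#'
#' Groups are named sets of sample labels (conventionally `HSPC`, `CRPC`,
#' `NEPC` and `NORMAL`); member sets must be disjoint.
#'
#' @param ... Named character vectors of sample names, or a single named
#'   list.
#' @return A `cell_line_groups` object (named list).
#' @export
cell_line_groups <- function(...) {
  groups <- list(...)
  if (length(groups) == 1 && is.list(groups[[1]]) && is.null(names(groups))) {
    groups <- groups[[1]]
  }
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    stop("every group must be named")
  }
  members <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(members)) {
    stop("group member sets must be disjoint; duplicated sample: '",
         members[duplicated(members)][1], "'")
  }
  structure(lapply(groups, as.character), class = "cell_line_groups")
}

## sample label -> group name (NA when unassigned)
sample_group <- function(groups, samples) {
  map <- rep(names(groups), lengths(groups))
  names(map) <- unlist(groups, use.names = FALSE)
  unname(map[samples])
}
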