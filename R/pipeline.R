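## End-to-end orchestration: the post-caller cascade in its canonical
## order, classification, specificity sets, junction counting and scoring,
## bundled into a reproducible run report.

#' Default pipeline configuration
#'
#' All thresholds in one list: `min_score` (caller score cut-off, 0.6),
#' `max_errors` (junction-count edit distance, 1), `flank` (probe flank,
#' 30), `homology_flank` (50), `min_identity` (0.8), `merge_window`
#' (near-duplicate junction merge half-width, 0 = exact-coordinate
#' identity), `score_threshold` (HIGH/LOW chimera-score cut, 1000),
#' `panel_size` (`NULL` = use all counted chimeras).
#'
#' @return Named list of configuration values.
#' @export
default_config <- function() {
  list(min_score = 0.6, max_errors = 1L, flank = 30L,
       homology_flank = 50L, min_identity = 0.8, merge_window = 0L,
       score_threshold = 1000, panel_size = NULL)
}

#' Read a pipeline configuration file (YAML)
#'
#' Unknown keys are rejected; missing keys fall back to [default_config()].
#'
#' @param path Path to a YAML file.
#' @return Configuration list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  base <- default_config()
  unknown <- setdiff(names(user), names(base))
  if (length(unknown) > 0) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  base[names(user)] <- user
  base
}

#' Write a pipeline configuration file (YAML)
#'
#' @param config Configuration list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Run the full post-caller pipeline
#'
#' Executes the cascade in its canonical order — score filter, M/M
#' removal, blacklist subtraction, normal-sample subtraction,
#' flank-homology screen — then classifies the survivors, derives
#' per-group category fractions and group-specific sets, counts
#' junction-spanning reads per sample, and scores samples. Optional inputs
#' (genome, reads, blacklist, groups, markers) switch their stages on.
#'
#' @param calls A `chimera_calls` data frame.
#' @param annotation A `genome_annotation`; every called gene must be
#'   present (a missing gene aborts the run naming it).
#' @param genome Optional genome (`DNAStringSet`/FASTA path) enabling the
#'   homology screen and sequence-derived probes.
#' @param reads Optional named list (sample → FASTQ/FASTA path,
#'   `DNAStringSet` or character vector) enabling junction counting.
#' @param blacklist Optional `chimera_blacklist`.
#' @param groups Optional `cell_line_groups` for profiling and specificity
#'   sets.
#' @param normal_samples Character vector of normal sample labels.
#' @param markers Optional marker-count data frame (`sample_id`, `chga`,
#'   `nse`, `syp`) enabling NE-activity scoring.
#' @param config Configuration list (see [default_config()]).
#' @param seed Optional integer recorded in the report (the pipeline
#'   itself is deterministic).
#' @return A `chimera_run` object.
#' @export
run_full <- function(calls, annotation, genome = NULL, reads = NULL,
                     blacklist = NULL, groups = NULL,
                     normal_samples = character(), markers = NULL,
                     config = default_config(), seed = NULL) {
  if (nrow(calls) > 0) {
    missing_genes <- setdiff(unique(c(calls$gene5, calls$gene3)),
                             names(annotation$genes))
    if (length(missing_genes) > 0) {
      stop("stage input_validation: annotation missing gene '",
           missing_genes[1], "'")
    }
  }

  kept <- filter_by_score(calls, min_score = config$min_score)
  kept <- drop_mm(kept, annotation)
  if (!is.null(blacklist)) {
    kept <- subtract_blacklist(kept, blacklist, ann = annotation)
  }
  kept <- subtract_samples(kept, normal_samples)
  if (!is.null(genome)) {
    kept <- homology_filter(kept, genome, flank = config$homology_flank,
                            min_identity = config$min_identity)
  }

  classification <- classify_calls(kept, annotation)
  profile <- if (nrow(kept) > 0) category_profile(classification, groups) else NULL
  specificity <- if (!is.null(groups) && nrow(kept) > 0) {
    specific_sets(kept, groups)
  } else NULL

  counts <- NULL
  if (!is.null(reads) && nrow(kept) > 0) {
    uniq <- kept[!duplicated(chimera_key(kept)), , drop = FALSE]
    probes <- lapply(seq_len(nrow(uniq)), function(i) {
      build_probe(as.list(uniq[i, , drop = FALSE]), ann = annotation,
                  genome = genome, flank = config$flank)
    })
    counts <- count_table(probes, reads, max_errors = config$max_errors)
  }

  scores <- NULL
  if (!is.null(markers) && !is.null(counts)) {
    wide <- tapply(counts$raw_count, list(counts$sample, counts$chimera_id), sum)
    wide[is.na(wide)] <- 0
    panel_size <- config$panel_size %||% ncol(wide)
    scores <- score_samples(wide, markers, threshold = config$score_threshold,
                            panel_size = panel_size)
  }

  structure(
    list(config = config, seed = seed,
         version = as.character(utils::packageVersion("chimeraScreen")),
         n_input = nrow(calls),
         trace = filter_trace(kept),
         calls = kept,
         classification = classification,
         profile = profile,
         specificity = specificity,
         counts = counts,
         scores = scores),
    class = "chimera_run"
  )
}

#' @export
print.chimera_run <- function(x, ...) {
  cat("chimera_run (chimeraScreen ", x$version, ")\n", sep = "")
  cat("  input calls: ", x$n_input, "\n", sep = "")
  if (!is.null(x$trace)) {
    for (i in seq_len(nrow(x$trace))) {
      cat(sprintf("  %-16s %4d -> %4d (removed %d)\n", x$trace$stage[i],
                  x$trace$input[i], x$trace$output[i], x$trace$removed[i]))
    }
  }
  if (!is.null(x$specificity)) {
    cat("  specific sets: ",
        paste(sprintf("%s=%d", names(x$specificity$specific),
                      vapply(x$specificity$specific, nrow, integer(1))),
              collapse = ", "), "\n", sep = "")
  }
  if (!is.null(x$counts)) {
    cat("  count records: ", nrow(x$counts), "\n", sep = "")
  }
  if (!is.null(x$scores)) {
    cat("  scored samples: ", nrow(x$scores), " (",
        sum(x$scores$group == "HIGH"), " HIGH)\n", sep = "")
  }
  invisible(x)
}

#' @export
summary.chimera_run <- function(object, ...) {
  print(object)
  if (!is.null(object$profile)) {
    cat("\ncategory fractions:\n")
    print(object$profile, row.names = FALSE)
  }
  invisible(object)
}

#' Write a machine-readable run report (JSON)
#'
#' Deterministic for fixed inputs: keys are emitted in a fixed sorted
#' order, so identical runs produce byte-identical reports.
#'
#' @param run A `chimera_run`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_report <- function(run, path) {
  report <- list(
    classification = run$classification,
    config = run$config[order(names(run$config))],
    counts = run$counts,
    n_input = run$n_input,
    profile = run$profile,
    scores = run$scores,
    seed = run$seed,
    specific_counts = if (!is.null(run$specificity)) {
      lapply(run$specificity$specific, nrow)
    } else NULL,
    trace = run$trace,
    version = run$version
  )
  report <- report[!vapply(report, is.null, logical(1))]
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}
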