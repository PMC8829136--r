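#' Time-series wounding experiment
#'
#' Bundles a gene-by-sample count matrix with its sample sheet (group,
#' sampling time in minutes, replicate) and optional gene metadata such as
#' transcription-factor family. The design mirrors the turnover experiment:
#' a wounded series (treatment, conventionally labelled Y) and an unwounded
#' control series (M) sampled on a shared time grid with replicates.
#'
#' @param counts non-negative integer matrix, genes in rows (rownames =
#'   gene ids), samples in columns (colnames = sample ids).
#' @param samples data frame with columns `sample_id`, `group`
#'   ("treatment"/"control"; "Y"/"M" are accepted aliases), `time_min`
#'   (non-negative minutes) and `replicate` (positive integer).
#' @param genes optional data frame with `gene_id` and `tf_family`
#'   (NA for non-TF genes).
#' @param truth optional ground-truth object from the synthetic generator.
#'
#' @return An object of class `wound_experiment`: a list with elements
#'   `counts`, `samples`, `genes`, `truth`. Samples are reordered by
#'   (group, time, replicate) with the treatment group first.
#' @export
#' @examples
#' cts <- matrix(rpois(12, 50), 3, 4,
#'               dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' sheet <- data.frame(sample_id = paste0("s", 1:4),
#'                     group = c("Y", "Y", "M", "M"),
#'                     time_min = c(0, 0, 0, 0), replicate = c(1, 2, 1, 2))
#' exp <- wound_experiment(cts, sheet)
#' dim(exp$counts)
wound_experiment <- function(counts, samples, genes = NULL, truth = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    abort("`counts` must carry gene rownames and sample colnames.")
  }
  samples <- as_tibble(samples)
  required <- c("sample_id", "group", "time_min", "replicate")
  missing_cols <- setdiff(required, names(samples))
  if (length(missing_cols) > 0) {
    abort(paste0("Sample sheet is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  samples$group <- normalize_group(samples$group)
  if (anyDuplicated(samples$sample_id)) {
    abort("Sample ids in the sheet must be unique.")
  }
  unmatched <- setdiff(colnames(counts), samples$sample_id)
  if (length(unmatched) > 0) {
    abort(paste0("Count column(s) absent from the sample sheet: ",
                 paste(unmatched, collapse = ", ")))
  }
  extra <- setdiff(samples$sample_id, colnames(counts))
  if (length(extra) > 0) {
    abort(paste0("Sheet sample(s) absent from the count matrix: ",
                 paste(extra, collapse = ", ")))
  }
  bad <- which(counts < 0 | counts != round(counts), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf("Counts must be non-negative integers; first offence at gene '%s', sample '%s'.",
                  rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]]))
  }
  storage.mode(counts) <- "integer"
  if (any(samples$time_min < 0)) abort("`time_min` must be non-negative.")
  if (any(samples$replicate < 1)) abort("`replicate` must be positive.")

  samples <- dplyr::arrange(
    samples,
    factor(.data$group, levels = c("treatment", "control")),
    .data$time_min, .data$replicate
  )
  counts <- counts[, samples$sample_id, drop = FALSE]

  n_rep <- dplyr::count(samples, .data$group, .data$time_min)
  if (any(n_rep$n < 2)) {
    warn("Some (group, time) combinations have fewer than 2 replicates; tests there are undefined.")
  }

  if (is.null(genes)) {
    genes <- tibble(gene_id = rownames(counts), tf_family = NA_character_)
  } else {
    genes <- as_tibble(genes)
    if (!"gene_id" %in% names(genes)) abort("`genes` needs a `gene_id` column.")
    if (!"tf_family" %in% names(genes)) genes$tf_family <- NA_character_
    genes <- genes[match(rownames(counts), genes$gene_id), , drop = FALSE]
    genes$gene_id <- rownames(counts)
  }

  structure(list(counts = counts, samples = samples, genes = genes,
                 truth = truth),
            class = "wound_experiment")
}

normalize_group <- function(x) {
  x <- as.character(x)
  map <- c(Y = "treatment", M = "control",
           treatment = "treatment", control = "control")
  out <- unname(map[x])
  if (anyNA(out)) {
    abort(paste0("Unknown group label(s): ",
                 paste(unique(x[is.na(out)]), collapse = ", "),
                 " (expected Y/M or treatment/control)."))
  }
  out
}

#' @export
print.wound_experiment <- function(x, ...) {
  grid <- sort(unique(x$samples$time_min))
  cat(sprintf("<wound_experiment> %d genes x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  cat(sprintf("  time grid (min): %s\n", paste(grid, collapse = ", ")))
  cat(sprintf("  groups: %s\n",
              paste(capture_counts(x$samples$group), collapse = ", ")))
  if (!is.null(x$truth)) cat("  ground truth attached\n")
  invisible(x)
}

capture_counts <- function(v) {
  tb <- table(v)
  paste0(names(tb), " (", as.integer(tb), ")")
}

#' Shared time grid of an experiment
#'
#' Time points present in both groups, excluding the pre-treatment baseline
#' (time 0) which serves as the reference only. Differential tests are
#' formed at these times.
#'
#' @param experiment a [wound_experiment()].
#' @param include_baseline keep time 0 in the grid.
#' @return Sorted numeric vector of minutes.
#' @export
shared_grid <- function(experiment, include_baseline = FALSE) {
  s <- experiment$samples
  tt <- intersect(s$time_min[s$group == "treatment"],
                  s$time_min[s$group == "control"])
  tt <- sort(unique(tt))
  if (!include_baseline) tt <- tt[tt > 0]
  tt
}

#' Tidy expression values of an experiment
#'
#' @param x a [wound_experiment()].
#' @param ... unused.
#' @return A long tibble: gene_id, sample_id, group, time_min, replicate,
#'   count.
#' @method tidy wound_experiment
#' @export
tidy.wound_experiment <- function(x, ...) {
  long <- as_tibble(x$counts, rownames = "gene_id")
  long <- tidyr::pivot_longer(long, -"gene_id",
                              names_to = "sample_id", values_to = "count")
  dplyr::left_join(long, x$samples, by = "sample_id")
}

#' @method glance wound_experiment
#' @export
glance.wound_experiment <- function(x, ...) {
  tibble(
    n_genes = nrow(x$counts),
    n_samples = ncol(x$counts),
    n_timepoints = length(unique(x$samples$time_min)),
    n_replicates = max(x$samples$replicate),
    has_truth = !is.null(x$truth)
  )
}
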