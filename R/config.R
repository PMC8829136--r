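#' Pipeline configuration
#'
#' Collects every tunable threshold of the wounding-chronology pipeline in
#' one validated list. Defaults mirror the published analysis where a value
#' is printed: DEGs require FDR < 0.05 and an absolute fold change of at
#' least 2 at one or more time points, plus a normalized count above 10 in
#' the lowest expressed sample; promoters are the 500 bp upstream of the
#' transcription start; overrepresentation is called at hypergeometric
#' p <= 0.05; module merging uses an eigengene-dissimilarity cut of 0.25
#' and a minimum module size of 30; regulatory (TF to gene) edges require
#' weight > 0.5 and gene-gene edges weight > 0.15.
#'
#' @param fdr_threshold FDR cut-off for per-time-point differential calls.
#' @param fc_threshold fold-change cut-off on the natural scale (>= 1).
#' @param min_count minimum normalized count required in the lowest
#'   expressed sample of a DEG.
#' @param promoter_window promoter length in base pairs.
#' @param enrichment_alpha raw hypergeometric p cut-off for enrichment.
#' @param enrichment_adjust apply Benjamini-Hochberg to enrichment p-values
#'   before thresholding (off by default; the published analysis thresholds
#'   raw p).
#' @param beta_candidates integer soft-threshold powers to scan.
#' @param scale_free_r2 minimum scale-free-topology fit to accept a power.
#' @param merge_cut_height eigengene dissimilarity below which modules merge.
#' @param min_module_size smallest branch kept as a module.
#' @param tf_edge_weight weight above which a TF-gene edge is reported.
#' @param gene_edge_weight weight above which a gene-gene edge is reported.
#' @param n_clusters fuzzy c-means cluster count (NULL = caller decides).
#' @param n_phases phase count per gene set, or "auto" for the merge-height
#'   gap rule.
#' @param seed integer seed controlling every stochastic step.
#'
#' @return A list of class `wound_config`.
#' @export
#' @examples
#' cfg <- wound_config(seed = 1)
#' cfg$fdr_threshold
wound_config <- function(fdr_threshold = 0.05,
                         fc_threshold = 2,
                         min_count = 10,
                         promoter_window = 500,
                         enrichment_alpha = 0.05,
                         enrichment_adjust = FALSE,
                         beta_candidates = c(1:10, 12, 14, 16, 18, 20),
                         scale_free_r2 = 0.8,
                         merge_cut_height = 0.25,
                         min_module_size = 30,
                         tf_edge_weight = 0.5,
                         gene_edge_weight = 0.15,
                         n_clusters = NULL,
                         n_phases = "auto",
                         seed = 1L) {
  cfg <- list(
    fdr_threshold = fdr_threshold, fc_threshold = fc_threshold,
    min_count = min_count, promoter_window = promoter_window,
    enrichment_alpha = enrichment_alpha, enrichment_adjust = enrichment_adjust,
    beta_candidates = as.integer(beta_candidates),
    scale_free_r2 = scale_free_r2,
    merge_cut_height = merge_cut_height, min_module_size = min_module_size,
    tf_edge_weight = tf_edge_weight, gene_edge_weight = gene_edge_weight,
    n_clusters = n_clusters, n_phases = n_phases, seed = as.integer(seed)
  )
  validate_config(cfg)
  structure(cfg, class = "wound_config")
}

validate_config <- function(cfg) {
  stopifnot(
    is.numeric(cfg$fdr_threshold), cfg$fdr_threshold > 0, cfg$fdr_threshold < 1,
    is.numeric(cfg$enrichment_alpha), cfg$enrichment_alpha > 0, cfg$enrichment_alpha < 1,
    cfg$fc_threshold >= 1, cfg$min_count >= 0, cfg$promoter_window > 0,
    all(cfg$beta_candidates >= 1), cfg$merge_cut_height > 0,
    cfg$min_module_size >= 1, cfg$tf_edge_weight > 0, cfg$gene_edge_weight > 0
  )
  invisible(cfg)
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys absent from the file keep their [wound_config()] defaults; unknown
#' keys are an error so typos cannot silently fall back.
#'
#' @param path path to a YAML key: value file.
#' @return A `wound_config` list.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- names(formals(wound_config))
  bad <- setdiff(names(raw), known)
  if (length(bad) > 0) {
    abort(paste0("Unknown configuration key(s): ", paste(bad, collapse = ", ")))
  }
  do.call(wound_config, raw)
}

#' @export
print.wound_config <- function(x, ...) {
  cat("<wound_config>\n")
  for (k in names(x)) {
    cat(sprintf("  %-18s %s\n", k, paste(format(x[[k]]), collapse = " ")))
  }
  invisible(x)
}
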