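#' Run the full wounding-chronology pipeline
#'
#' Drives every stage in order — differential expression and FDEG timing,
#' PCA contributions, fuzzy temporal clustering, TF-family / term / motif
#' overrepresentation, chronology phases, and the co-expression network
#' with optional volatile integration — and writes every artifact as TSV
#' (plus GraphML and a JSON run report) under `out_dir`. Stages whose
#' optional inputs are missing are skipped with a logged notice. Given the
#' same inputs and seed, outputs are byte-identical across runs.
#'
#' @param experiment a [wound_experiment()] (e.g. from [read_counts()] or
#'   [simulate_experiment()]).
#' @param config a [wound_config()].
#' @param annotation optional term gene sets (from [read_gmt()]).
#' @param promoters optional named promoter sequences.
#' @param pwms optional named list of `wound_pwm`s.
#' @param traits optional long trait tibble.
#' @param out_dir output directory (created if needed); NULL = no files.
#' @return A `wound_pipeline` list: de, pca, clusters, tf_enrichment,
#'   term_enrichment, motif_enrichment, chronology, phase_summary, network,
#'   report.
#' @export
run_pipeline <- function(experiment, config = wound_config(),
                         annotation = NULL, promoters = NULL, pwms = NULL,
                         traits = NULL, out_dir = NULL) {
  validate_config(config)
  notes <- character()
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    inform(paste0("[woundchron] ", msg))
    notes <<- c(notes, msg)
  }
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      abort(sprintf("Stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  say("differential expression at %d time points",
      length(shared_grid(experiment)))
  de <- stage("diffexpr", run_diffexpr(experiment, config))
  say("%d DEGs called", sum(de$genes$is_deg))

  pca <- stage("pca", {
    norm <- sweep(experiment$counts, 2, de$size_factors, "/")
    pca_contributions(log2(norm + 1), k = min(1000, nrow(norm)))
  })

  n_deg <- sum(de$genes$is_deg)
  clusters <- NULL
  if (n_deg >= 10) {
    c_use <- config$n_clusters %||% default_cluster_count(experiment)
    say("fuzzy clustering of %d DEG trajectories into %d clusters", n_deg, c_use)
    clusters <- stage("cluster",
                      cluster_trajectories(de, c = c_use,
                                           seed = config$seed))
  } else {
    say("fewer than 10 DEGs; clustering skipped")
  }

  tf_map <- setNames(experiment$genes$tf_family, experiment$genes$gene_id)
  background <- experiment$genes$gene_id
  tf_enrichment <- NULL
  term_enrichment <- NULL
  motif_enrichment <- NULL
  if (!is.null(clusters)) {
    cluster_sets <- split(names(clusters$hard_label), clusters$hard_label)
    tf_enrichment <- stage("enrich_tf", purrr::map_dfr(
      names(cluster_sets), function(cl) {
        fams <- tf_map[!is.na(tf_map)]
        res <- enrich_terms(cluster_sets[[cl]], fams, background,
                            alpha = config$enrichment_alpha,
                            adjust = config$enrichment_adjust)
        if (nrow(res) > 0) dplyr::mutate(res, cluster = cl, .before = 1)
      }))
    if (!is.null(annotation)) {
      term_enrichment <- stage("enrich_terms", purrr::map_dfr(
        names(cluster_sets), function(cl) {
          res <- enrich_terms(cluster_sets[[cl]], annotation, background,
                              alpha = config$enrichment_alpha,
                              adjust = config$enrichment_adjust)
          if (nrow(res) > 0) dplyr::mutate(res, cluster = cl, .before = 1)
        }))
    } else say("no term annotation supplied; term enrichment skipped")
    if (!is.null(promoters) && !is.null(pwms)) {
      motif_enrichment <- stage("enrich_motifs",
        motif_overrepresentation(cluster_sets, promoters, pwms,
                                 alpha = config$enrichment_alpha,
                                 adjust = config$enrichment_adjust))
    } else say("no promoters/PWMs supplied; motif stage skipped")
  }

  chron <- NULL
  phase_summary <- NULL
  if (n_deg >= 8) {
    chron <- stage("phases",
                   run_chronology(de, tf_map, k = config$n_phases))
    phase_summary <- stage("phase_report",
                           phase_report(chron, annotation, tf_map,
                                        alpha = config$enrichment_alpha))
  } else say("too few DEGs; chronology skipped")

  network <- NULL
  if (n_deg >= 30) {
    say("co-expression network on %d DEGs", n_deg)
    network <- stage("network",
                     run_coexpression(experiment, de, config, traits = traits))
  } else say("fewer than 30 DEGs; network skipped")
  if (is.null(traits)) say("no volatile table supplied; module-trait stage skipped")

  result <- structure(list(
    de = de, pca = pca, clusters = clusters,
    tf_enrichment = tf_enrichment, term_enrichment = term_enrichment,
    motif_enrichment = motif_enrichment,
    chronology = chron, phase_summary = phase_summary,
    network = network,
    report = list(seed = config$seed,
                  n_genes = nrow(experiment$counts),
                  n_samples = ncol(experiment$counts),
                  n_deg = n_deg,
                  n_clusters = if (!is.null(clusters)) ncol(clusters$membership),
                  n_modules = if (!is.null(network))
                    length(setdiff(unique(network$labels), "grey")),
                  beta = if (!is.null(network)) network$beta,
                  notes = notes)
  ), class = "wound_pipeline")

  if (!is.null(out_dir)) write_pipeline(result, experiment, out_dir)
  result
}

default_cluster_count <- function(experiment) {
  if (!is.null(experiment$truth)) {
    n <- length(setdiff(unique(experiment$truth$genes$cluster), "flat"))
    if (n >= 2) return(n)
  }
  6L
}

#' Write every pipeline artifact under a directory
#'
#' @param result a `wound_pipeline`.
#' @param experiment the analysed [wound_experiment()].
#' @param out_dir output directory.
#' @return `out_dir`, invisibly.
#' @export
write_pipeline <- function(result, experiment, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)

  de <- result$de
  wide <- tidyr::pivot_wider(
    de$tests[, c("gene_id", "time_min", "log2fc", "p", "fdr")],
    names_from = "time_min", values_from = c("log2fc", "p", "fdr"),
    names_glue = "{.value}_{time_min}"
  )
  deg_table <- dplyr::left_join(wide, de$genes, by = "gene_id")
  readr::write_tsv(deg_table, p("deg_table.tsv"), progress = FALSE)
  readr::write_tsv(burst_summary(de), p("fdeg_summary.tsv"), progress = FALSE)
  readr::write_tsv(result$pca$scores, p("pca_scores.tsv"), progress = FALSE)
  readr::write_tsv(result$pca$contributions, p("pca_contributions.tsv"),
                   progress = FALSE)

  if (!is.null(result$clusters)) {
    readr::write_tsv(tidy(result$clusters), p("cluster_membership.tsv"),
                     progress = FALSE)
    centers <- as_tibble(result$clusters$centers, rownames = "cluster")
    readr::write_tsv(centers, p("cluster_centers.tsv"), progress = FALSE)
  }
  if (!is.null(result$tf_enrichment)) {
    readr::write_tsv(result$tf_enrichment, p("tf_enrichment.tsv"),
                     progress = FALSE)
  }
  if (!is.null(result$term_enrichment)) {
    readr::write_tsv(result$term_enrichment, p("term_enrichment.tsv"),
                     progress = FALSE)
  }
  if (!is.null(result$motif_enrichment)) {
    readr::write_tsv(result$motif_enrichment, p("motif_enrichment.tsv"),
                     progress = FALSE)
  }
  if (!is.null(result$chronology)) {
    ph <- purrr::map_dfr(names(result$chronology$phases), function(s) {
      dplyr::mutate(result$chronology$phases[[s]], set = s, .before = 1)
    })
    readr::write_tsv(ph, p("phase_table.tsv"), progress = FALSE)
    readr::write_tsv(result$chronology$assignments, p("phase_assignments.tsv"),
                     progress = FALSE)
    if (!is.null(result$phase_summary)) {
      readr::write_tsv(
        dplyr::select(result$phase_summary, -dplyr::any_of("enrichment")),
        p("phase_summary.tsv"), progress = FALSE)
    }
  }
  if (!is.null(result$network)) {
    nw <- result$network
    readr::write_tsv(tidy(nw), p("module_assignment.tsv"), progress = FALSE)
    if (!is.null(nw$eigengenes)) {
      readr::write_tsv(as_tibble(nw$eigengenes, rownames = "sample_id"),
                       p("module_eigengenes.tsv"), progress = FALSE)
    }
    if (!is.null(nw$module_trait)) {
      readr::write_tsv(nw$module_trait, p("module_trait.tsv"), progress = FALSE)
    }
    readr::write_tsv(nw$edges, p("edges.tsv"), progress = FALSE)
    if (nrow(nw$edges) > 0) {
      tf_map <- setNames(experiment$genes$tf_family, experiment$genes$gene_id)
      write_graphml(nw$edges, nw$labels, tf_map, p("edges.graphml"))
    }
  }
  jsonlite::write_json(result$report, p("report.json"),
                       auto_unbox = TRUE, digits = 10, null = "null")
  invisible(out_dir)
}

#' @export
print.wound_pipeline <- function(x, ...) {
  cat("<wound_pipeline>\n")
  cat(sprintf("  DEGs: %d\n", x$report$n_deg))
  if (!is.null(x$report$n_clusters)) cat(sprintf("  clusters: %d\n", x$report$n_clusters))
  if (!is.null(x$report$n_modules)) {
    cat(sprintf("  modules: %d (beta = %d)\n", x$report$n_modules, x$report$beta))
  }
  invisible(x)
}

default_motif_consensus <- function() {
  c(pulse_up = "TTGACC",      # W-box, bound by WRKY factors
    sustained_up = "CACGTG",  # G-box, bound by bHLH factors
    pulse_down = "TGTCTC")    # auxin-response-like element
}

#' Simulate and write a complete input bundle
#'
#' Generates an experiment with ground truth plus matching annotation
#' (GMT), promoters (FASTA, with motifs planted per ground-truth cluster),
#' PWMs (MEME minimal format), and a volatile table, and writes them all
#' under `out_dir` together with the ground-truth table.
#'
#' @param out_dir output directory.
#' @param seed integer seed.
#' @param n_genes number of genes.
#' @param ... further arguments for [simulate_experiment()].
#' @return Invisibly, a list with the experiment, truth and file paths.
#' @export
simulate_inputs <- function(out_dir, seed = 1L, n_genes = 2000, ...) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  extra <- list(...)
  if (!"module_sizes" %in% names(extra)) {
    # keep the planted-module fractions of the default design at any size
    extra$module_sizes <- setNames(round(n_genes * c(0.04, 0.05, 0.06)),
                                   c("M1", "M2", "M3"))
  }
  exp <- do.call(simulate_experiment,
                 c(list(n_genes = n_genes, seed = seed), extra))
  truth <- exp$truth
  write_counts(exp, p("counts.tsv"), p("samples.tsv"))
  readr::write_tsv(exp$genes, p("genes.tsv"), progress = FALSE)
  ann <- simulate_annotation(truth, seed = seed + 1L)
  write_gmt(ann, p("annotation.gmt"))
  cons <- default_motif_consensus()
  promoters <- simulate_promoters(
    setNames(truth$genes$cluster, truth$genes$gene_id), cons, seed = seed + 2L)
  write_promoters(promoters, p("promoters.fasta"))
  pwms <- lapply(setNames(names(cons), paste0("motif_", names(cons))),
                 function(cl) consensus_pwm(cons[[cl]], name = cl))
  write_meme_pwm(pwms, p("pwms.meme"))
  vol <- simulate_volatiles(grid = sort(unique(exp$samples$time_min)),
                            seed = seed + 3L)
  write_trait_table(vol, p("volatiles.tsv"))
  readr::write_tsv(truth$genes, p("ground_truth.tsv"), progress = FALSE)
  invisible(list(experiment = exp, truth = truth, annotation = ann,
                 promoters = promoters, pwms = pwms, volatiles = vol,
                 paths = list(
                   counts = p("counts.tsv"), sheet = p("samples.tsv"),
                   genes = p("genes.tsv"), gmt = p("annotation.gmt"),
                   promoters = p("promoters.fasta"), pwms = p("pwms.meme"),
                   traits = p("volatiles.tsv"),
                   truth = p("ground_truth.tsv"))))
}
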