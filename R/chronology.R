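#' Partition DEGs into the four direction-by-role sets
#'
#' Splits the DEGs into up-regulated TFs, up-regulated structural genes,
#' down-regulated TFs and down-regulated structural genes — four mutually
#' exclusive sets that jointly cover all DEGs.
#'
#' @param deg_genes gene-level tibble from [run_diffexpr()] (`$genes`):
#'   needs gene_id, is_deg, direction.
#' @param tf_annotation named character vector gene_id -> TF family (NA or
#'   absent = structural gene), or a data frame with gene_id and tf_family.
#' @return Named list of gene-id vectors: up_tf, up_gene, down_tf,
#'   down_gene.
#' @export
partition_gene_sets <- function(deg_genes, tf_annotation) {
  if (is.data.frame(tf_annotation)) {
    tf_annotation <- setNames(tf_annotation$tf_family, tf_annotation$gene_id)
  }
  degs <- deg_genes[deg_genes$is_deg, ]
  if (any(is.na(degs$direction))) {
    abort("DEG without a direction; run call_degs() first.")
  }
  is_tf <- !is.na(tf_annotation[degs$gene_id])
  is_tf[is.na(is_tf)] <- FALSE
  up <- degs$direction == "up"
  list(
    up_tf = degs$gene_id[up & is_tf],
    up_gene = degs$gene_id[up & !is_tf],
    down_tf = degs$gene_id[!up & is_tf],
    down_gene = degs$gene_id[!up & !is_tf]
  )
}

#' Time-point correlation matrix of a gene set
#'
#' Pearson correlation, over the genes of one set, between every pair of
#' time-point columns of the log2 fold-change matrix. A zero-variance
#' column's correlations are undefined and set to 0 with a warning (its
#' diagonal stays 1).
#'
#' @param fc_matrix gene-by-time numeric matrix (>= 2 genes).
#' @return Symmetric time-by-time correlation matrix with unit diagonal.
#' @export
timepoint_correlation <- function(fc_matrix) {
  fc_matrix <- as.matrix(fc_matrix)
  if (nrow(fc_matrix) < 2) abort("Need at least 2 genes to correlate time points.")
  sds <- apply(fc_matrix, 2, sd)
  cc <- suppressWarnings(cor(fc_matrix))
  if (any(sds == 0)) {
    warn("Zero-variance time-point column(s); correlations set to 0.")
    cc[sds == 0, ] <- 0
    cc[, sds == 0] <- 0
  }
  diag(cc) <- 1
  cc
}

#' Segment the time axis into contiguous phases
#'
#' Agglomerative clustering of the correlation-matrix columns (Euclidean
#' distance, Ward-style minimum-variance merge cost) with merging
#' restricted to temporally adjacent clusters, so every cluster is a
#' contiguous interval of the grid. With `k = "auto"` the cut is placed at
#' the largest relative jump between successive merge heights (ties broken
#' toward fewer phases).
#'
#' @param corr time-by-time correlation matrix from
#'   [timepoint_correlation()].
#' @param k phase count, or "auto".
#' @param times grid times matching the matrix columns (defaults to
#'   numeric column names).
#' @return Tibble (phase, label, start_min, end_min, n_timepoints); phase
#'   intervals are left-closed and partition the grid in time order.
#' @export
infer_phases <- function(corr, k = "auto", times = NULL) {
  corr <- as.matrix(corr)
  Tn <- ncol(corr)
  if (is.null(times)) times <- as.numeric(colnames(corr))
  stopifnot(length(times) == Tn, !is.unsorted(times))
  if (!identical(k, "auto") && (k < 1 || k > Tn)) {
    abort("`k` must be between 1 and the number of time points.")
  }
  X <- t(corr)           # rows = time-point column vectors

  # contiguity-constrained agglomeration
  groups <- as.list(seq_len(Tn))
  heights <- numeric(0)
  boundaries <- list(seq_len(Tn))  # group start indices after each state
  ward_cost <- function(a, b) {
    ca <- colMeans(X[a, , drop = FALSE]); cb <- colMeans(X[b, , drop = FALSE])
    (length(a) * length(b)) / (length(a) + length(b)) * sum((ca - cb)^2)
  }
  while (length(groups) > 1) {
    costs <- vapply(seq_len(length(groups) - 1), function(i) {
      ward_cost(groups[[i]], groups[[i + 1]])
    }, numeric(1))
    i <- which.min(costs)
    heights <- c(heights, costs[i])
    groups[[i]] <- c(groups[[i]], groups[[i + 1]])
    groups[[i + 1]] <- NULL
    boundaries[[length(boundaries) + 1]] <-
      vapply(groups, function(g) g[1], integer(1))
  }
  # boundaries[[j]] is the segmentation with Tn - j + 1 clusters
  if (identical(k, "auto")) {
    k <- pick_k_by_gap(heights, Tn)
  }
  starts <- boundaries[[Tn - k + 1]]
  seg_of <- findInterval(seq_len(Tn), starts)
  purrr::map_dfr(seq_len(k), function(ph) {
    members <- which(seg_of == ph)
    tibble(phase = ph, label = as.character(utils::as.roman(ph)),
           start_min = times[min(members)], end_min = times[max(members)],
           n_timepoints = length(members))
  })
}

# Largest relative gap between successive merge heights (gap normalized by
# the tallest merge, so the rule is scale-free and robust to near-zero
# early merges); cutting after merge i leaves Tn - i clusters. Ties favour
# the later merge (fewer phases).
pick_k_by_gap <- function(heights, Tn) {
  nm <- length(heights)
  if (nm < 2) return(if (nm == 1) 2 else 1)
  hmax <- max(heights)
  if (hmax <= 0) return(1)
  gaps <- diff(heights) / hmax
  i <- max(which(gaps == max(gaps)))   # gap between merge i and i+1
  Tn - i
}

#' Assign DEGs to phases by first-DE time
#'
#' Each gene of each set maps to the phase of its own set whose interval
#' contains the gene's FDEG time (intervals are left-closed; times beyond
#' the last phase start fall in the last phase). Genes without an FDEG time
#' are left unassigned with a message.
#'
#' @param partition four gene sets from [partition_gene_sets()].
#' @param fdeg_times named numeric vector gene_id -> FDEG minutes.
#' @param phases named list of phase tibbles (one per set, from
#'   [infer_phases()]).
#' @return Tibble (gene_id, set, phase, label, fdeg_time).
#' @export
assign_gene_phases <- function(partition, fdeg_times, phases) {
  purrr::map_dfr(names(partition), function(set_name) {
    genes <- partition[[set_name]]
    ph <- phases[[set_name]]
    if (length(genes) == 0 || is.null(ph)) return(NULL)
    ft <- fdeg_times[genes]
    missing <- is.na(ft)
    if (any(missing)) {
      inform(sprintf("%d gene(s) in %s have no FDEG time and stay unassigned.",
                     sum(missing), set_name))
    }
    idx <- findInterval(ft, ph$start_min)
    idx[!is.na(idx) & idx < 1] <- 1L
    tibble(gene_id = genes, set = set_name,
           phase = unname(ifelse(missing, NA_integer_, ph$phase[idx])),
           label = unname(ifelse(missing, NA_character_, ph$label[idx])),
           fdeg_time = unname(ft))
  })
}

#' Infer the transcriptional chronology of the wounding response
#'
#' Runs the full phase-inference procedure: partitions DEGs into the four
#' direction-by-role sets, computes each set's time-point Pearson
#' correlation matrix from the log2 fold changes, segments the grid into
#' contiguous phases per set, and assigns every DEG to a phase by its FDEG
#' time. Sets with fewer than 2 genes are skipped with a warning.
#'
#' @param de a `wound_de` from [run_diffexpr()].
#' @param tf_annotation gene -> TF family map (vector or data frame).
#' @param k phase count per set, or "auto".
#' @return A `wound_chronology`: `$partition`, `$correlations` (per set),
#'   `$phases` (per set), `$assignments` (tibble), `$grid`.
#' @export
run_chronology <- function(de, tf_annotation, k = "auto") {
  partition <- partition_gene_sets(de$genes, tf_annotation)
  fc <- fold_change_matrix(de)
  fdeg <- setNames(de$genes$fdeg_time, de$genes$gene_id)
  correlations <- list(); phases <- list()
  for (set_name in names(partition)) {
    genes <- partition[[set_name]]
    if (length(genes) < 2) {
      warn(sprintf("Set %s has fewer than 2 genes; phases skipped.", set_name))
      next
    }
    cc <- timepoint_correlation(fc[genes, , drop = FALSE])
    correlations[[set_name]] <- cc
    phases[[set_name]] <- infer_phases(cc, k = k, times = de$grid)
  }
  assignments <- assign_gene_phases(partition, fdeg, phases)
  structure(list(partition = partition, correlations = correlations,
                 phases = phases, assignments = assignments,
                 grid = de$grid),
            class = "wound_chronology")
}

#' Per-phase enrichment and top TF families
#'
#' For every (set, phase), reports term overrepresentation via
#' [enrich_terms()] against the background of all DEGs, and the three most
#' frequent TF families (ties broken alphabetically).
#'
#' @param chronology a `wound_chronology`.
#' @param annotation named list of term gene sets (GMT-shaped), or NULL to
#'   skip term enrichment.
#' @param tf_annotation gene -> TF family map.
#' @param alpha enrichment significance cut-off.
#' @return Tibble (set, phase, label, n_genes, top_families,
#'   enrichment list-column).
#' @export
phase_report <- function(chronology, annotation = NULL, tf_annotation = NULL,
                         alpha = 0.05) {
  if (is.data.frame(tf_annotation)) {
    tf_annotation <- setNames(tf_annotation$tf_family, tf_annotation$gene_id)
  }
  asn <- chronology$assignments
  asn <- asn[!is.na(asn$phase), ]
  background <- unlist(chronology$partition, use.names = FALSE)
  combos <- dplyr::distinct(asn[, c("set", "phase", "label")])
  combos <- dplyr::arrange(combos, .data$set, .data$phase)
  purrr::map_dfr(seq_len(nrow(combos)), function(i) {
    sel <- asn$set == combos$set[i] & asn$phase == combos$phase[i]
    genes <- asn$gene_id[sel]
    fams <- tf_annotation[genes]
    fams <- fams[!is.na(fams)]
    top <- if (length(fams) > 0) {
      tb <- sort(table(fams), decreasing = TRUE)
      ord <- order(-as.integer(tb), names(tb))
      paste(names(tb)[ord][seq_len(min(3, length(tb)))], collapse = ",")
    } else NA_character_
    enr <- if (!is.null(annotation)) {
      list(enrich_terms(genes, annotation, background, alpha = alpha))
    } else list(NULL)
    tibble(set = combos$set[i], phase = combos$phase[i],
           label = combos$label[i], n_genes = length(genes),
           top_families = top, enrichment = enr)
  })
}

#' @method tidy wound_chronology
#' @export
tidy.wound_chronology <- function(x, ...) x$assignments

#' @method glance wound_chronology
#' @export
glance.wound_chronology <- function(x, ...) {
  tibble(
    set = names(x$partition),
    n_genes = lengths(x$partition),
    n_phases = vapply(names(x$partition), function(s) {
      if (is.null(x$phases[[s]])) NA_integer_ else nrow(x$phases[[s]])
    }, integer(1))
  )
}

#' @export
print.wound_chronology <- function(x, ...) {
  cat("<wound_chronology>\n")
  for (s in names(x$phases)) {
    ph <- x$phases[[s]]
    cat(sprintf("  %-9s %d genes, %d phase(s): %s\n", s,
                length(x$partition[[s]]), nrow(ph),
                paste(sprintf("%s[%g-%g]", ph$label, ph$start_min, ph$end_min),
                      collapse = " ")))
  }
  invisible(x)
}
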