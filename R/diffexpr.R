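#' Median-of-ratios size factors
#'
#' Library-size normalization: each sample's factor is the median across
#' genes of its ratio to the per-gene geometric-mean reference, computed on
#' genes with nonzero counts in every sample, then rescaled so the factors
#' have geometric mean 1. If no gene is nonzero everywhere, falls back to
#' upper-quartile normalization with a message.
#'
#' @param counts gene-by-sample count matrix.
#' @return Named numeric vector of positive per-sample factors.
#' @export
#' @examples
#' m <- matrix(c(10, 20, 30, 20, 40, 60), ncol = 2,
#'             dimnames = list(paste0("g", 1:3), c("a", "b")))
#' size_factors(m)  # ratio 2, geometric mean 1
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  keep <- rowSums(counts > 0) == ncol(counts)
  if (any(keep)) {
    logref <- rowMeans(log(counts[keep, , drop = FALSE]))
    sf <- apply(counts[keep, , drop = FALSE], 2, function(y) {
      exp(median(log(y) - logref))
    })
  } else {
    inform("No gene is nonzero in every sample; using upper-quartile normalization.")
    sf <- apply(counts, 2, function(y) quantile(y[y > 0], 0.75))
    if (any(!is.finite(sf) | sf <= 0)) {
      abort("Upper-quartile normalization failed: a sample has no nonzero counts.")
    }
  }
  sf <- sf / exp(mean(log(sf)))
  setNames(sf, colnames(counts))
}

#' Normalized counts
#' @param experiment a [wound_experiment()].
#' @return Matrix of counts divided by median-of-ratios size factors.
#' @export
normalized_counts <- function(experiment) {
  sf <- size_factors(experiment$counts)
  sweep(experiment$counts, 2, sf, "/")
}

# Vectorized NB Wald test on normalized count matrices (genes x replicates).
# Dispersion is method-of-moments, pooled across groups by degrees of
# freedom and floored at 1e-8; the Wald statistic for the log2 mean
# difference (delta-method variance) is referred to a t distribution with
# n1 + n2 - 2 df, a small-sample correction for replicate-level designs.
nb_wald_matrix <- function(yt, yc, phi = NULL, df = NULL) {
  nt <- ncol(yt); nc <- ncol(yc)
  stopifnot(nt >= 2, nc >= 2)
  if (is.null(df)) df <- nt + nc - 2
  mt <- rowMeans(yt); mc <- rowMeans(yc)
  if (is.null(phi)) {
    vt <- apply(yt, 1, var); vc <- apply(yc, 1, var)
    phi <- ((nt - 1) * (vt - mt) / pmax(mt, 1e-8)^2 +
            (nc - 1) * (vc - mc) / pmax(mc, 1e-8)^2) / (nt + nc - 2)
  }
  phi <- pmax(phi, 1e-8)
  log2fc <- log2((mt + 0.5) / (mc + 0.5))
  mtf <- pmax(mt, 0.5); mcf <- pmax(mc, 0.5)
  se <- sqrt((mtf + phi * mtf^2) / (nt * mtf^2) +
             (mcf + phi * mcf^2) / (nc * mcf^2)) / log(2)
  stat <- log2fc / se
  p <- 2 * pt(-abs(stat), df = df)
  both_zero <- mt == 0 & mc == 0
  log2fc[both_zero] <- 0
  stat[both_zero] <- 0
  p[both_zero] <- 1
  tibble(log2fc = log2fc, se = se, stat = stat, p = pmin(p, 1))
}

#' Negative-binomial Wald test for one contrast
#'
#' Two-group comparison of (normalized) counts under an NB model with
#' method-of-moments dispersion pooled across the groups (floored at 1e-8).
#' The log2 fold change uses a 0.5 pseudocount on the group means; the Wald
#' statistic uses the delta-method variance of the log2 means and a t
#' reference with `n1 + n2 - 2` degrees of freedom.
#'
#' @param y_treat,y_ctrl count vectors (>= 2 replicates each).
#' @param factors optional size factors, `c(treatment, control)` order;
#'   counts are divided by them before testing.
#' @return One-row tibble: log2fc, se, stat, p.
#' @export
#' @examples
#' nb_wald_test(c(40, 50, 45), c(9, 11, 10))
nb_wald_test <- function(y_treat, y_ctrl, factors = NULL) {
  if (!is.null(factors)) {
    stopifnot(length(factors) == length(y_treat) + length(y_ctrl))
    y_treat <- y_treat / factors[seq_along(y_treat)]
    y_ctrl <- y_ctrl / factors[-seq_along(y_treat)]
  }
  nb_wald_matrix(matrix(y_treat, 1), matrix(y_ctrl, 1))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment applied within one comparison
#' (here, one time point's p-value vector).
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return FDR vector of the same length.
#' @export
bh_adjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  p.adjust(p, method = "BH")
}

#' Per-time-point differential expression
#'
#' Tests treatment vs control at every time point shared by the two groups
#' (the pre-treatment baseline, time 0, is excluded), adjusts p-values with
#' Benjamini-Hochberg within each time point, flags per-(gene, time)
#' differential expression at `fdr_threshold` and `fc_threshold`, and calls
#' gene-level DEG status, direction and first-DE (FDEG) time via
#' [call_degs()].
#'
#' @param experiment a [wound_experiment()].
#' @param config a [wound_config()].
#' @return A `wound_de` object: `$tests` (gene x time tibble with log2fc,
#'   p, fdr, de_flag), `$genes` (gene-level tibble with is_deg, direction,
#'   fdeg_time, min_norm_count), `$grid`, `$size_factors`.
#' @export
run_diffexpr <- function(experiment, config = wound_config()) {
  sf <- size_factors(experiment$counts)
  norm <- sweep(experiment$counts, 2, sf, "/")
  s <- experiment$samples
  grid <- shared_grid(experiment)
  if (length(grid) == 0) abort("No post-treatment time point is shared by both groups.")

  # Dispersion is a gene property; the time course supplies replication at
  # every (group, time) cell, so the method-of-moments estimate is pooled
  # per gene across all cells and the Wald t uses the total residual df.
  disp <- pooled_dispersion(norm, s)

  tests <- purrr::map_dfr(grid, function(tt) {
    treat_ids <- s$sample_id[s$group == "treatment" & s$time_min == tt]
    ctrl_ids <- s$sample_id[s$group == "control" & s$time_min == tt]
    res <- nb_wald_matrix(norm[, treat_ids, drop = FALSE],
                          norm[, ctrl_ids, drop = FALSE],
                          phi = disp$phi, df = disp$df)
    res$fdr <- bh_adjust(res$p)
    tibble(gene_id = rownames(norm), time_min = tt,
           log2fc = res$log2fc, p = res$p, fdr = res$fdr)
  })
  tests$de_flag <- tests$fdr < config$fdr_threshold &
    abs(tests$log2fc) >= log2(config$fc_threshold)

  min_norm <- apply(norm, 1, min)
  genes <- call_degs(tests, min_norm, config)

  structure(list(tests = tests, genes = genes, grid = grid,
                 size_factors = sf,
                 thresholds = config[c("fdr_threshold", "fc_threshold",
                                       "min_count")]),
            class = "wound_de")
}

# Per-gene NB dispersion pooled across every (group, time) replicate cell:
# phi_hat = weighted mean of (var - mean)/mean^2 with df = n_cell - 1
# weights, floored at 1e-8.
pooled_dispersion <- function(norm, samples) {
  cells <- split(samples$sample_id,
                 interaction(samples$group, samples$time_min, drop = TRUE))
  cells <- cells[lengths(cells) >= 2]
  num <- rep(0, nrow(norm)); den <- 0
  for (ids in cells) {
    y <- norm[, ids, drop = FALSE]
    m <- rowMeans(y)
    v <- apply(y, 1, var)
    w <- length(ids) - 1
    num <- num + w * (v - m) / pmax(m, 1e-8)^2
    den <- den + w
  }
  list(phi = pmax(num / den, 1e-8), df = den)
}

#' Call DEGs with direction and first-DE time
#'
#' A gene is a DEG iff some time point has FDR below threshold and
#' |log2 FC| at or above log2 of the fold-change threshold, and its lowest
#' normalized count across all samples of the series exceeds `min_count`.
#' The FDEG time is the earliest flagged time point; direction is the sign
#' of the fold change at that time.
#'
#' @param tests per-(gene, time) tibble with gene_id, time_min, log2fc,
#'   fdr, de_flag columns (de_flag recomputed if absent).
#' @param min_norm_counts named (or gene-ordered) vector of each gene's
#'   minimum normalized count.
#' @param config a [wound_config()].
#' @return Gene-level tibble: gene_id, is_deg, direction, fdeg_time,
#'   min_norm_count, n_de_timepoints.
#' @export
call_degs <- function(tests, min_norm_counts, config = wound_config()) {
  if (!"de_flag" %in% names(tests)) {
    tests$de_flag <- tests$fdr < config$fdr_threshold &
      abs(tests$log2fc) >= log2(config$fc_threshold)
  }
  per_gene <- tests |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::arrange(.data$time_min, .by_group = TRUE) |>
    dplyr::summarise(
      fdeg_time = find_fdeg(.data$de_flag, .data$time_min),
      n_de_timepoints = sum(.data$de_flag),
      direction = if (all(!.data$de_flag)) NA_character_ else {
        ifelse(.data$log2fc[which(.data$de_flag)[1]] >= 0, "up", "down")
      },
      .groups = "drop"
    )
  if (!is.null(names(min_norm_counts))) {
    per_gene$min_norm_count <- unname(min_norm_counts[per_gene$gene_id])
  } else {
    per_gene$min_norm_count <- min_norm_counts[match(per_gene$gene_id,
                                                     unique(tests$gene_id))]
  }
  per_gene$is_deg <- per_gene$n_de_timepoints > 0 &
    per_gene$min_norm_count > config$min_count
  per_gene$fdeg_time[!per_gene$is_deg] <- NA_real_
  per_gene$direction[!per_gene$is_deg] <- NA_character_
  per_gene[, c("gene_id", "is_deg", "direction", "fdeg_time",
               "min_norm_count", "n_de_timepoints")]
}

#' First time point of differential expression
#'
#' @param de_flags logical vector of per-time differential calls.
#' @param times matching time points (ascending).
#' @return Earliest flagged time, or NA if never flagged.
#' @export
#' @examples
#' find_fdeg(c(FALSE, TRUE, TRUE), c(5, 10, 20))  # 10
find_fdeg <- function(de_flags, times) {
  stopifnot(length(de_flags) == length(times), !is.unsorted(times))
  i <- which(de_flags)
  if (length(i) == 0) NA_real_ else times[i[1]]
}

#' Per-time-point DEG / FDEG burst summary
#'
#' Counts, at each time point, the DEGs flagged there and the DEGs flagged
#' there for the first time (FDEGs), split by gene direction, with the
#' cumulative fraction of all DEGs already seen.
#'
#' @param de a `wound_de` from [run_diffexpr()].
#' @return Tibble: time_min, n_deg, n_deg_up, n_deg_down, n_fdeg,
#'   n_fdeg_up, n_fdeg_down, cum_fdeg_fraction.
#' @export
burst_summary <- function(de) {
  deg <- de$genes[de$genes$is_deg, ]
  flagged <- dplyr::inner_join(de$tests[de$tests$de_flag, ],
                               deg[, c("gene_id", "direction", "fdeg_time")],
                               by = "gene_id")
  out <- purrr::map_dfr(de$grid, function(tt) {
    at_t <- flagged[flagged$time_min == tt, ]
    first <- at_t[at_t$fdeg_time == tt, ]
    tibble(time_min = tt,
           n_deg = nrow(at_t),
           n_deg_up = sum(at_t$direction == "up"),
           n_deg_down = sum(at_t$direction == "down"),
           n_fdeg = nrow(first),
           n_fdeg_up = sum(first$direction == "up"),
           n_fdeg_down = sum(first$direction == "down"))
  })
  out$cum_fdeg_fraction <- if (nrow(deg) == 0) {
    rep(0, nrow(out))
  } else cumsum(out$n_fdeg) / nrow(deg)
  out
}

#' Principal components and gene contributions
#'
#' PCA of samples on log-scale expression (genes are the variables, each
#' centered). Per-gene contribution to the first component is the squared
#' loading, normalized to sum to 1; the top `k` genes by contribution
#' reproduce the "best-represented genes on PC1" ranking.
#'
#' @param expr gene-by-sample numeric matrix (e.g. log2 normalized counts).
#' @param k how many top genes to flag.
#' @return A `wound_pca`: `$scores` (sample x PC tibble), `$contributions`
#'   (gene_id, loading, contribution, rank, top_k), `$var_explained`.
#' @export
pca_contributions <- function(expr, k = 1000) {
  expr <- as.matrix(expr)
  k <- min(k, nrow(expr))
  if (all(apply(expr, 1, var) < 1e-12)) abort("no variance in the expression matrix")
  pc <- prcomp(t(expr), center = TRUE, scale. = FALSE)
  load1 <- pc$rotation[, 1]
  contrib <- load1^2 / sum(load1^2)
  ord <- order(contrib, decreasing = TRUE)
  contributions <- tibble(
    gene_id = rownames(expr),
    loading = unname(load1),
    contribution = unname(contrib)
  )
  contributions$rank <- match(seq_len(nrow(expr)), ord)
  contributions$top_k <- contributions$rank <= k
  scores <- as_tibble(pc$x[, seq_len(min(5, ncol(pc$x))), drop = FALSE],
                      rownames = "sample_id")
  structure(list(scores = scores,
                 contributions = dplyr::arrange(contributions, .data$rank),
                 var_explained = pc$sdev^2 / sum(pc$sdev^2), k = k),
            class = "wound_pca")
}

#' @export
print.wound_pca <- function(x, ...) {
  cat(sprintf("<wound_pca> PC1 explains %.1f%% of variance; top %d genes flagged\n",
              100 * x$var_explained[1], x$k))
  invisible(x)
}

#' @method tidy wound_de
#' @export
tidy.wound_de <- function(x, ...) x$tests

#' @method glance wound_de
#' @export
glance.wound_de <- function(x, ...) {
  tibble(
    n_genes = nrow(x$genes),
    n_deg = sum(x$genes$is_deg),
    n_up = sum(x$genes$direction == "up", na.rm = TRUE),
    n_down = sum(x$genes$direction == "down", na.rm = TRUE),
    n_timepoints = length(x$grid)
  )
}

#' @export
print.wound_de <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<wound_de> %d genes x %d time points; %d DEGs (%d up / %d down)\n",
              g$n_genes, g$n_timepoints, g$n_deg, g$n_up, g$n_down))
  invisible(x)
}
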