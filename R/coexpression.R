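#' Soft-threshold selection by scale-free topology fit
#'
#' For each candidate power, builds the weighted adjacency
#' `((cor + 1)/2)^beta`, computes each gene's connectivity (row sum minus
#' the self term), bins the connectivities and fits
#' `log10(freq) ~ log10(k)`; the scale-free fit R-squared counts only when
#' the slope is negative. The chosen power is the smallest with fit at or
#' above `r2_cut`, else the best-fitting candidate with a warning.
#'
#' @param expr gene-by-sample matrix (standardized log expression).
#' @param beta_candidates integer powers to scan.
#' @param r2_cut minimum acceptable fit.
#' @param n_bins connectivity histogram bins.
#' @return List: `beta` (chosen power) and `fit_table` (tibble beta, r2,
#'   slope, mean_connectivity).
#' @export
pick_soft_threshold <- function(expr, beta_candidates = c(1:10, 12, 14, 16, 18, 20),
                                r2_cut = 0.8, n_bins = 10) {
  expr <- as.matrix(expr)
  if (nrow(expr) < 30) warn("Fewer than 30 genes; the scale-free fit is unstable.")
  cc <- cor(t(expr))
  fit_table <- purrr::map_dfr(beta_candidates, function(beta) {
    a <- wgcna_adjacency(cc, beta)
    k <- rowSums(a) - 1
    tibble(beta = beta, !!!scale_free_fit(k, n_bins),
           mean_connectivity = mean(k))
  })
  ok <- fit_table$slope < 0 & fit_table$r2 >= r2_cut
  beta <- if (any(ok)) {
    min(fit_table$beta[ok])
  } else {
    warn(sprintf("No candidate power reaches scale-free fit %.2f; using the best (R2 = %.2f).",
                 r2_cut, max(fit_table$r2[fit_table$slope < 0], -Inf)))
    neg <- fit_table$slope < 0
    if (any(neg)) fit_table$beta[neg][which.max(fit_table$r2[neg])]
    else fit_table$beta[which.max(fit_table$r2)]
  }
  list(beta = beta, fit_table = fit_table)
}

scale_free_fit <- function(k, n_bins = 10) {
  if (max(k) - min(k) < 1e-12) return(list(r2 = 0, slope = 0))
  bins <- cut(k, breaks = n_bins)
  kmean <- tapply(k, bins, mean)
  freq <- tapply(k, bins, length)
  keep <- !is.na(kmean) & freq > 0 & kmean > 0
  if (sum(keep) < 3) return(list(r2 = 0, slope = 0))
  x <- log10(kmean[keep]); y <- log10(freq[keep] / sum(freq[keep]))
  fit <- lm(y ~ x)
  list(r2 = summary(fit)$r.squared, slope = unname(coef(fit)[2]))
}

#' Weighted adjacency from a correlation matrix
#'
#' Connection strength `((cor + 1)/2)^beta`: the signed-scale rescaling of
#' the correlation raised to the soft-threshold power, so a correlation of
#' 1 maps to 1, -1 to 0, and 0 to `0.5^beta`.
#'
#' @param cor_matrix correlation matrix in [-1, 1].
#' @param beta positive soft-threshold power.
#' @return Symmetric adjacency in [0, 1] with unit diagonal.
#' @export
wgcna_adjacency <- function(cor_matrix, beta) {
  stopifnot(beta > 0, all(abs(cor_matrix) <= 1 + 1e-12))
  a <- (abs((cor_matrix + 1) / 2))^beta
  diag(a) <- 1
  a
}

#' Topological overlap matrix
#'
#' Unsigned TOM: `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)`
#' with the diagonal excluded from the shared-neighbour sums and from the
#' connectivities; `TOM_ii = 1`.
#'
#' @param adjacency symmetric adjacency in [0, 1].
#' @return Symmetric TOM in [0, 1].
#' @export
tom_similarity <- function(adjacency) {
  a <- as.matrix(adjacency)
  diag(a) <- 0
  shared <- a %*% a
  k <- rowSums(a)
  kmin <- outer(k, k, pmin)
  tom <- (shared + a) / (kmin + 1 - a)
  diag(tom) <- 1
  tom
}

module_colors <- function() {
  c("turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
    "magenta", "purple", "greenyellow", "tan", "salmon", "cyan",
    "midnightblue", "lightcyan", "grey60", "lightgreen", "lightyellow",
    "royalblue", "darkred", "darkgreen", "darkturquoise", "darkgrey",
    "orange", "darkorange", "skyblue", "saddlebrown", "steelblue",
    "paleturquoise", "violet", "darkolivegreen", "darkmagenta")
}

#' Detect co-expression modules from a TOM
#'
#' Average-linkage hierarchical clustering on the dissimilarity `1 - TOM`,
#' cut at a fixed height into branches; branches smaller than
#' `min_module_size` are assigned the unclustered label "grey". Remaining
#' modules receive size-ordered colour names (ties broken by first gene
#' index), so labels are deterministic and invariant to gene order.
#'
#' @param tom TOM matrix with gene dimnames.
#' @param min_module_size smallest branch kept as a module.
#' @param cut_height static tree-cut height on 1 - TOM.
#' @return Named character vector gene_id -> module label.
#' @export
detect_modules <- function(tom, min_module_size = 30, cut_height = 0.99) {
  genes <- rownames(tom)
  ord <- order(genes)              # canonical order: labels gene-order invariant
  d <- stats::as.dist(1 - tom[ord, ord])
  tree <- hclust(d, method = "average")
  # average linkage is monotone; guard cutree against tie-induced rounding
  tree$height <- cummax(tree$height)
  raw <- cutree(tree, h = cut_height)
  tb <- table(raw)
  big <- names(tb)[tb >= min_module_size]
  if (length(big) == 0) warn("All genes are unassigned (grey).")
  first_idx <- vapply(big, function(b) min(which(raw == b)), integer(1))
  big <- big[order(-tb[big], first_idx)]
  labels <- setNames(rep("grey", length(raw)), genes[ord])
  cols <- module_colors()
  for (i in seq_along(big)) {
    labels[raw == big[i]] <- cols[((i - 1) %% length(cols)) + 1]
  }
  labels[genes]
}

#' Module eigengene
#'
#' First principal component of a module's standardized expression over
#' samples: the unit-norm right singular vector, sign-oriented so it
#' correlates non-negatively with the module's mean expression profile. A
#' single-gene module's eigengene is that gene's standardized profile,
#' rescaled to unit norm.
#'
#' @param expr standardized gene-by-sample matrix (full experiment).
#' @param module_genes gene ids of one module.
#' @return List: `eigengene` (named vector over samples, unit norm) and
#'   `var_explained`.
#' @export
module_eigengene <- function(expr, module_genes) {
  X <- expr[module_genes, , drop = FALSE]
  if (nrow(X) == 0) abort("Empty module.")
  if (nrow(X) == 1) {
    v <- X[1, ] / sqrt(sum(X[1, ]^2))
    return(list(eigengene = v, var_explained = 1))
  }
  sv <- svd(X, nu = 0, nv = 1)
  v <- sv$v[, 1]
  if (cor(v, colMeans(X)) < 0) v <- -v
  list(eigengene = setNames(v, colnames(expr)),
       var_explained = sv$d[1]^2 / sum(sv$d^2))
}

#' Merge modules with similar eigengenes
#'
#' Average-linkage clustering of modules on eigengene dissimilarity
#' `1 - cor(ME_a, ME_b)`, cut at `merge_cut_height`; groups falling under
#' the cut are merged into the label of their largest member module, and
#' eigengenes are recomputed. "grey" never merges.
#'
#' @param expr standardized gene-by-sample matrix.
#' @param labels gene -> module label vector.
#' @param merge_cut_height dissimilarity threshold (merge below it).
#' @return List: `labels` (post-merge), `eigengenes` (sample x module
#'   matrix), `var_explained`, `merge_log` (tibble old_label, new_label).
#' @export
merge_modules <- function(expr, labels, merge_cut_height = 0.25) {
  mods <- setdiff(sort(unique(labels)), "grey")
  me <- vapply(mods, function(m) {
    module_eigengene(expr, names(labels)[labels == m])$eigengene
  }, numeric(ncol(expr)))
  new_of <- setNames(mods, mods)
  if (length(mods) >= 2) {
    diss <- 1 - cor(me)
    tree <- hclust(stats::as.dist(diss), method = "average")
    grp <- cutree(tree, h = merge_cut_height)
    for (g in unique(grp)) {
      members <- mods[grp == g]
      if (length(members) > 1) {
        sizes <- vapply(members, function(m) sum(labels == m), integer(1))
        target <- members[which.max(sizes)]
        new_of[members] <- target
      }
    }
  }
  merged <- labels
  chg <- labels != "grey"
  merged[chg] <- new_of[labels[chg]]
  final_mods <- setdiff(sort(unique(merged)), "grey")
  me_out <- vapply(final_mods, function(m) {
    module_eigengene(expr, names(merged)[merged == m])$eigengene
  }, numeric(ncol(expr)))
  ve <- vapply(final_mods, function(m) {
    module_eigengene(expr, names(merged)[merged == m])$var_explained
  }, numeric(1))
  rownames(me_out) <- colnames(expr)
  list(labels = merged, eigengenes = me_out, var_explained = ve,
       merge_log = tibble(old_label = mods, new_label = unname(new_of[mods])))
}

#' Module-volatile correlation
#'
#' Averages each module eigengene over the treatment replicates at every
#' time point, log2(x + 1)-scales the volatile peak areas, and reports the
#' Pearson correlation of each (module, metabolite) pair over the shared
#' time grid with a two-sided t-test p-value (df = shared time points - 2).
#'
#' @param eigengenes sample-by-module matrix (rownames = sample ids).
#' @param samples sample sheet tibble (sample_id, group, time_min).
#' @param traits long trait tibble (metabolite, time_min, value).
#' @param log_traits log2(value + 1)-scale the traits first.
#' @return Tibble (module, metabolite, r, p, significant, n_timepoints).
#' @export
module_trait_correlation <- function(eigengenes, samples, traits,
                                     log_traits = TRUE) {
  treat <- samples[samples$group == "treatment", ]
  me_by_time <- apply(eigengenes, 2, function(v) {
    tapply(v[treat$sample_id], treat$time_min, mean)
  })
  me_times <- as.numeric(rownames(me_by_time))
  shared <- intersect(me_times, unique(traits$time_min))
  if (length(shared) < 3) abort("Fewer than 3 shared time points between eigengenes and traits.")
  shared <- sort(shared)
  nt <- length(shared)
  purrr::map_dfr(colnames(eigengenes), function(mod) {
    mv <- me_by_time[match(shared, me_times), mod]
    purrr::map_dfr(unique(traits$metabolite), function(met) {
      tv <- traits$value[traits$metabolite == met][
        match(shared, traits$time_min[traits$metabolite == met])]
      if (log_traits) tv <- log2(tv + 1)
      r <- suppressWarnings(cor(mv, tv))
      if (is.na(r)) r <- 0
      r <- max(min(r, 1), -1)
      tstat <- r * sqrt((nt - 2) / max(1 - r^2, 1e-12))
      p <- 2 * pt(-abs(tstat), df = nt - 2)
      tibble(module = mod, metabolite = met, r = r, p = min(p, 1),
             significant = p < 0.05, n_timepoints = nt)
    })
  })
}

#' Extract weight-thresholded edges within modules
#'
#' Within each (non-grey) module, pairs involving a transcription factor
#' are reported as directed regulatory edges (TF -> target) when their
#' weight exceeds `tf_edge_weight`; pairs of structural genes are reported
#' as undirected co-expression edges when their weight exceeds
#' `gene_edge_weight`. TF-TF pairs use the regulatory threshold and are
#' reported once in deterministic (alphabetical) orientation.
#'
#' @param weights symmetric weight matrix (TOM) with gene dimnames.
#' @param labels gene -> module label vector.
#' @param tf_annotation gene -> TF family map (vector or data frame).
#' @param tf_edge_weight,gene_edge_weight thresholds (exclusive).
#' @return Tibble (from, to, weight, type, module), ordered by module,
#'   from, to.
#' @export
extract_edges <- function(weights, labels, tf_annotation,
                          tf_edge_weight = 0.5, gene_edge_weight = 0.15) {
  if (is.data.frame(tf_annotation)) {
    tf_annotation <- setNames(tf_annotation$tf_family, tf_annotation$gene_id)
  }
  genes <- rownames(weights)
  is_tf <- !is.na(tf_annotation[genes])
  is_tf[is.na(is_tf)] <- FALSE
  names(is_tf) <- genes
  out <- purrr::map_dfr(setdiff(sort(unique(labels)), "grey"), function(mod) {
    mg <- sort(intersect(genes, names(labels)[labels == mod]))
    if (length(mg) < 2) return(NULL)
    pairs <- which(upper.tri(matrix(0, length(mg), length(mg))), arr.ind = TRUE)
    w <- weights[mg, mg][pairs]
    gi <- mg[pairs[, 1]]; gj <- mg[pairs[, 2]]
    ti <- is_tf[gi]; tj <- is_tf[gj]
    type <- ifelse(ti & tj, "tf_tf", ifelse(ti | tj, "tf_gene", "gene_gene"))
    from <- ifelse(type == "tf_gene" & tj, gj, gi)
    to <- ifelse(type == "tf_gene" & tj, gi, gj)
    keep <- (type %in% c("tf_gene", "tf_tf") & w > tf_edge_weight) |
      (type == "gene_gene" & w > gene_edge_weight)
    tibble(from = unname(from[keep]), to = unname(to[keep]),
           weight = unname(w[keep]), type = unname(type[keep]), module = mod)
  })
  if (nrow(out) == 0) {
    return(tibble(from = character(), to = character(), weight = numeric(),
                  type = character(), module = character()))
  }
  dplyr::arrange(out, .data$module, .data$from, .data$to)
}

#' Export a module edge list as GraphML
#'
#' @param edges edge tibble from [extract_edges()].
#' @param labels gene -> module label vector (node attribute).
#' @param tf_annotation gene -> TF family map.
#' @param path output .graphml path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(edges, labels, tf_annotation, path) {
  if (is.data.frame(tf_annotation)) {
    tf_annotation <- setNames(tf_annotation$tf_family, tf_annotation$gene_id)
  }
  nodes <- sort(unique(c(edges$from, edges$to)))
  g <- igraph::graph_from_data_frame(
    edges[, c("from", "to", "weight", "type")],
    directed = TRUE,
    vertices = data.frame(
      name = nodes,
      module = unname(labels[nodes]),
      is_tf = !is.na(tf_annotation[nodes]) & nodes %in% names(tf_annotation)
    )
  )
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Run the co-expression analysis end to end
#'
#' Builds the network on the DEGs: standardized log2(normalized count + 1)
#' expression, Pearson correlation, soft-threshold pick, adjacency, TOM,
#' static-cut module detection, eigengene-based merging, optional
#' module-volatile correlation, and weight-thresholded edge extraction.
#'
#' @param experiment a [wound_experiment()].
#' @param de the matching `wound_de` (defines the DEG set).
#' @param config a [wound_config()].
#' @param traits optional long trait tibble (metabolite, time_min, value).
#' @param beta fixed soft threshold; NULL = pick by scale-free fit.
#' @return A `wound_network`: beta, fit_table, labels, eigengenes,
#'   var_explained, merge_log, module_trait (or NULL), edges, tom (matrix),
#'   expr (standardized matrix).
#' @export
run_coexpression <- function(experiment, de, config = wound_config(),
                             traits = NULL, beta = NULL) {
  deg_ids <- de$genes$gene_id[de$genes$is_deg]
  if (length(deg_ids) < 3) abort("Too few DEGs for a co-expression network.")
  norm <- sweep(experiment$counts, 2, de$size_factors, "/")
  le <- log2(norm[deg_ids, , drop = FALSE] + 1)
  v <- apply(le, 1, sd)
  le <- le[v > 0, , drop = FALSE]
  expr <- (le - rowMeans(le)) / apply(le, 1, sd)

  if (is.null(beta)) {
    pick <- pick_soft_threshold(expr, config$beta_candidates,
                                r2_cut = config$scale_free_r2)
    beta <- pick$beta
    fit_table <- pick$fit_table
  } else {
    fit_table <- NULL
  }
  cc <- cor(t(expr))
  adj <- wgcna_adjacency(cc, beta)
  tom <- tom_similarity(adj)
  dimnames(tom) <- dimnames(adj)
  labels0 <- detect_modules(tom, min_module_size = config$min_module_size)
  if (all(labels0 == "grey")) {
    merged <- list(labels = labels0, eigengenes = NULL, var_explained = NULL,
                   merge_log = tibble(old_label = character(),
                                      new_label = character()))
  } else {
    merged <- merge_modules(expr, labels0, config$merge_cut_height)
  }
  mt <- if (!is.null(traits) && !is.null(merged$eigengenes)) {
    module_trait_correlation(merged$eigengenes, experiment$samples, traits)
  }
  tf_map <- setNames(experiment$genes$tf_family, experiment$genes$gene_id)
  edges <- if (any(merged$labels != "grey")) {
    extract_edges(tom, merged$labels, tf_map,
                  tf_edge_weight = config$tf_edge_weight,
                  gene_edge_weight = config$gene_edge_weight)
  } else {
    tibble(from = character(), to = character(), weight = numeric(),
           type = character(), module = character())
  }
  structure(list(beta = beta, fit_table = fit_table,
                 initial_labels = labels0, labels = merged$labels,
                 eigengenes = merged$eigengenes,
                 var_explained = merged$var_explained,
                 merge_log = merged$merge_log,
                 module_trait = mt, edges = edges, tom = tom, expr = expr),
            class = "wound_network")
}

#' @method tidy wound_network
#' @export
tidy.wound_network <- function(x, ...) {
  tibble(gene_id = names(x$labels), module = unname(x$labels))
}

#' @method glance wound_network
#' @export
glance.wound_network <- function(x, ...) {
  mods <- setdiff(unique(x$labels), "grey")
  tibble(beta = x$beta, n_genes = length(x$labels),
         n_modules = length(mods), n_grey = sum(x$labels == "grey"),
         n_edges = nrow(x$edges))
}

#' @export
print.wound_network <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<wound_network> beta = %d; %d modules over %d genes (%d grey); %d edges\n",
              g$beta, g$n_modules, g$n_genes, g$n_grey, g$n_edges))
  invisible(x)
}
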