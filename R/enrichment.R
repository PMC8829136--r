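#' Hypergeometric upper-tail probability
#'
#' P(X >= k) where X counts annotated genes in a draw of `n` from a
#' background of `N` genes of which `K` are annotated — the
#' overrepresentation p-value used for TF families, functional terms and
#' promoter motifs.
#'
#' @param k annotated genes observed in the cluster.
#' @param K annotated genes in the background.
#' @param n cluster size.
#' @param N background size.
#' @return P(X >= k), in (0, 1].
#' @export
#' @examples
#' hypergeom_upper_tail(4, 5, 10, 20)
hypergeom_upper_tail <- function(k, K, n, N) {
  if (any(k < 0 | K < 0 | n < 0 | N < 0 | k > n | k > K | n > N | K > N)) {
    abort("Inconsistent hypergeometric arguments (need k <= min(K, n), n <= N, K <= N).")
  }
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Term overrepresentation in a gene cluster
#'
#' One upper-tail hypergeometric test per annotation term with at least one
#' background gene. P-values are raw by default, mirroring the published
#' p <= 0.05 calls; set `adjust = TRUE` for Benjamini-Hochberg.
#'
#' @param cluster_genes character vector of cluster gene ids (must be a
#'   subset of `background_genes`).
#' @param annotation named list of gene-id vectors (e.g. from [read_gmt()]),
#'   or a named character vector gene_id -> category (e.g. TF family).
#' @param background_genes the gene universe.
#' @param alpha significance cut-off.
#' @param adjust apply BH across terms before thresholding.
#' @return Tibble (term, k, K, n, N, p, significant), p ascending with ties
#'   broken by term id.
#' @export
enrich_terms <- function(cluster_genes, annotation, background_genes,
                         alpha = 0.05, adjust = FALSE) {
  if (!is.list(annotation)) {
    annotation <- split(names(annotation), annotation)
  }
  background_genes <- unique(background_genes)
  extra <- setdiff(cluster_genes, background_genes)
  if (length(extra) > 0) {
    abort(paste0("Cluster gene(s) outside the background: ",
                 paste(head(extra, 3), collapse = ", ")))
  }
  if (length(cluster_genes) == 0) {
    warn("Empty cluster; no enrichment computed.")
    return(tibble(term = character(), k = integer(), K = integer(),
                  n = integer(), N = integer(), p = numeric(),
                  significant = logical()))
  }
  N <- length(background_genes)
  n <- length(unique(cluster_genes))
  res <- purrr::map_dfr(names(annotation), function(term) {
    members <- intersect(annotation[[term]], background_genes)
    K <- length(members)
    if (K == 0) return(NULL)
    k <- length(intersect(cluster_genes, members))
    tibble(term = term, k = k, K = K, n = n, N = N,
           p = hypergeom_upper_tail(k, K, n, N))
  })
  if (nrow(res) == 0) {
    res$significant <- logical(0)
    return(res)
  }
  p_eff <- if (adjust) bh_adjust(res$p) else res$p
  res$significant <- p_eff <= alpha
  dplyr::arrange(res, .data$p, .data$term)
}

#' Scan a promoter sequence with a PWM
#'
#' Log-odds scoring against a background distribution (uniform 0.25 by
#' default): a window scores `sum_j log2(p_j(base)/bg(base))` with a 1e-4
#' pseudocount folded into the probabilities before the log. Both strands
#' are scanned (the reverse strand via the reverse-complement motif);
#' offsets are 0-based on the forward strand. Windows containing N are
#' skipped.
#'
#' @param sequence character scalar over ACGTN.
#' @param pwm a `wound_pwm` (4 x width probability matrix, rows A,C,G,T).
#' @param threshold score threshold in bits; default 80% of the motif's
#'   maximum achievable score.
#' @return Tibble (offset, strand, score); zero rows if the sequence is
#'   shorter than the motif.
#' @export
#' @examples
#' pwm <- consensus_pwm("ACG", leak = 0)
#' pwm_scan("TACGT", pwm, threshold = 5)
pwm_scan <- function(sequence, pwm, threshold = NULL) {
  L <- pwm_log_odds(pwm)
  w <- ncol(L)
  if (is.null(threshold)) threshold <- 0.8 * pwm_max_score(pwm)
  s <- chartr("acgtn", "ACGTN", sequence)
  code <- match(strsplit(s, "")[[1]], c("A", "C", "G", "T"))  # N -> NA
  n <- length(code)
  if (n < w) {
    return(tibble(offset = integer(), strand = character(), score = numeric()))
  }
  n_win <- n - w + 1
  idx <- outer(seq_len(n_win), 0:(w - 1), "+")
  base_at <- matrix(code[idx], n_win, w)
  valid <- rowSums(is.na(base_at)) == 0

  score_with <- function(M) {
    sc <- rep(NA_real_, n_win)
    if (any(valid)) {
      b <- base_at[valid, , drop = FALSE]
      flat <- M[cbind(as.vector(b), rep(seq_len(w), each = sum(valid)))]
      sc[valid] <- rowSums(matrix(flat, sum(valid), w))
    }
    sc
  }
  fwd <- score_with(L)
  Lrc <- L[4:1, w:1, drop = FALSE]   # reverse-complement motif
  rev <- score_with(Lrc)

  hits <- dplyr::bind_rows(
    tibble(offset = which(fwd >= threshold) - 1L, strand = "+",
           score = fwd[fwd >= threshold & !is.na(fwd)]),
    tibble(offset = which(rev >= threshold) - 1L, strand = "-",
           score = rev[rev >= threshold & !is.na(rev)])
  )
  dplyr::arrange(hits, .data$offset, .data$strand)
}

pwm_log_odds <- function(pwm, pseudocount = 1e-4) {
  m <- unclass(pwm)
  bg <- attr(pwm, "background") %||% rep(0.25, 4)
  p <- sweep(m + pseudocount, 2, colSums(m + pseudocount), "/")
  log2(p / bg)
}

#' Maximum achievable PWM score in bits
#' @param pwm a `wound_pwm`.
#' @return Numeric scalar.
#' @export
pwm_max_score <- function(pwm) {
  sum(apply(pwm_log_odds(pwm), 2, max))
}

#' Motif overrepresentation across gene clusters
#'
#' Scans every promoter with every PWM, collapses hits to gene level (a
#' gene counts once per motif regardless of hit multiplicity), and tests
#' each (cluster, motif) pair with the upper-tail hypergeometric against
#' the background of all genes with promoters.
#'
#' @param clusters named list of gene-id vectors, or a named character
#'   vector gene_id -> cluster label.
#' @param promoters named character vector of promoter sequences.
#' @param pwms named list of `wound_pwm`s.
#' @param alpha significance cut-off on the raw p.
#' @param threshold per-motif score threshold (default 80% of maximum).
#' @param adjust apply BH within each cluster.
#' @return Tibble (cluster, motif, k, K, n, N, p, significant).
#' @export
motif_overrepresentation <- function(clusters, promoters, pwms,
                                     alpha = 0.05, threshold = NULL,
                                     adjust = FALSE) {
  if (!is.list(clusters)) clusters <- split(names(clusters), clusters)
  background <- names(promoters)
  covered <- length(intersect(unlist(clusters), background)) /
    max(length(unique(unlist(clusters))), 1)
  if (covered < 0.9) {
    warn(sprintf("Promoters available for only %.0f%% of cluster genes.",
                 100 * covered))
  }
  hit_genes <- lapply(pwms, function(pwm) {
    names(promoters)[vapply(promoters, function(s) {
      nrow(pwm_scan(s, pwm, threshold = threshold)) > 0
    }, logical(1))]
  })
  purrr::map_dfr(names(clusters), function(cl) {
    genes_cl <- intersect(clusters[[cl]], background)
    res <- purrr::map_dfr(names(pwms), function(mt) {
      k <- length(intersect(genes_cl, hit_genes[[mt]]))
      tibble(cluster = cl, motif = mt, k = k,
             K = length(hit_genes[[mt]]), n = length(genes_cl),
             N = length(background),
             p = hypergeom_upper_tail(k, length(hit_genes[[mt]]),
                                      length(genes_cl), length(background)))
    })
    p_eff <- if (adjust) bh_adjust(res$p) else res$p
    res$significant <- p_eff <= alpha
    dplyr::arrange(res, .data$p, .data$motif)
  })
}
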