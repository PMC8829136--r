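#' Standardize fold-change trajectories
#'
#' Z-scores each gene's trajectory across time (mean 0, population standard
#' deviation 1), the standardization fuzzy c-means expects. Zero-variance
#' trajectories cannot be standardized and are dropped with a message.
#'
#' @param profiles gene-by-time numeric matrix (log2 fold changes).
#' @return Standardized matrix, possibly with fewer rows.
#' @export
#' @examples
#' standardize_profiles(rbind(g1 = c(1, 2, 3)))
standardize_profiles <- function(profiles) {
  profiles <- as.matrix(profiles)
  if (ncol(profiles) < 3) abort("Need at least 3 time points to standardize.")
  mu <- rowMeans(profiles)
  sdp <- sqrt(rowMeans((profiles - mu)^2))   # population sd
  keep <- sdp > 0
  if (!all(keep)) {
    inform(sprintf("Dropping %d zero-variance trajectorie(s).", sum(!keep)))
  }
  (profiles[keep, , drop = FALSE] - mu[keep]) / sdp[keep]
}

#' Fuzzifier lower-bound estimate
#'
#' Minimum usable fuzzy c-means fuzzifier for a dataset of `n_genes`
#' trajectories in `n_timepoints` dimensions, after Schwaemmle and Jensen's
#' lower bound (the default used by fuzzy clustering of expression
#' profiles):
#' `m = 1 + (1418/N + 22.05) D^-2 + (12.33/N + 0.243) D^(-0.0406 ln N - 0.1134)`.
#' Estimates below 1.05 fall back to 1.25.
#'
#' @param n_genes number of trajectories (>= 10).
#' @param n_timepoints trajectory dimension.
#' @return Fuzzifier m > 1.
#' @export
estimate_fuzzifier <- function(n_genes, n_timepoints) {
  stopifnot(n_genes >= 10, n_timepoints >= 2)
  N <- n_genes; D <- n_timepoints
  m <- 1 + (1418 / N + 22.05) * D^(-2) +
    (12.33 / N + 0.243) * D^(-0.0406 * log(N) - 0.1134)
  if (m < 1.05) m <- 1.25
  m
}

#' Fuzzy c-means clustering
#'
#' Standard fuzzy c-means with Euclidean distance: alternating membership
#' and center updates from `c` data points sampled (without replacement)
#' as initial centers. Convergence when the largest center shift falls
#' below `tol`. If a cluster is empty (no trajectory has its largest
#' membership there) after convergence, the run is re-seeded once; a
#' persistent empty cluster is kept with a warning.
#'
#' @param profiles gene-by-time matrix (usually standardized).
#' @param c number of clusters (2 <= c < number of rows).
#' @param m fuzzifier (> 1); default from [estimate_fuzzifier()].
#' @param seed integer seed for center initialization.
#' @param tol convergence tolerance on the center shift.
#' @param max_iter iteration cap.
#' @param n_starts number of seeded restarts; the run with the lowest final
#'   objective is kept (fuzzy c-means is sensitive to its initial centers).
#' @param init optional row indices of the initial centers (overrides seed
#'   and restarts).
#' @return A `wound_fuzzy`: `$membership` (rows sum to 1), `$centers`,
#'   `$hard_label`, `$m`, `$objective` (per-iteration, non-increasing),
#'   `$iterations`, `$converged`.
#' @export
fuzzy_cmeans <- function(profiles, c, m = NULL, seed = 1L, tol = 1e-6,
                         max_iter = 1000, n_starts = 8, init = NULL) {
  X <- as.matrix(profiles)
  n <- nrow(X)
  stopifnot(c >= 2, c < n)
  if (is.null(m)) m <- estimate_fuzzifier(n, ncol(X))
  stopifnot(m > 1)

  run_once <- function(run_seed) {
    idx <- if (!is.null(init)) init else
      with_seed(run_seed, sample.int(n, c))
    centers <- X[idx, , drop = FALSE]
    obj <- numeric(0)
    for (it in seq_len(max_iter)) {
      d2 <- outer(rowSums(X^2), rep(1, c)) - 2 * X %*% t(centers) +
        outer(rep(1, n), rowSums(centers^2))
      d2 <- pmax(d2, 0)
      u <- membership_from_d2(d2, m)
      um <- u^m
      obj <- c(obj, sum(um * d2))
      new_centers <- (t(um) %*% X) / colSums(um)
      shift <- max(abs(new_centers - centers))
      centers <- new_centers
      if (shift < tol) break
    }
    hard <- max.col(u, ties.method = "first")
    list(u = u, centers = centers, obj = obj, it = it,
         converged = shift < tol, hard = hard,
         empty = length(unique(hard)) < c)
  }

  if (!is.null(init)) {
    fit <- run_once(seed)
  } else {
    fits <- lapply(seq_len(n_starts), function(i) run_once(seed + i - 1L))
    objectives <- vapply(fits, function(f) f$obj[length(f$obj)], numeric(1))
    fit <- fits[[which.min(objectives)]]
  }
  if (fit$empty) {
    fit <- run_once(seed + n_starts)
    if (fit$empty) warn("A cluster remained empty after re-seeding.")
  }
  rownames(fit$u) <- rownames(X)
  colnames(fit$u) <- paste0("C", seq_len(c))
  rownames(fit$centers) <- colnames(fit$u)
  colnames(fit$centers) <- colnames(X)
  structure(list(membership = fit$u, centers = fit$centers,
                 hard_label = setNames(colnames(fit$u)[fit$hard], rownames(X)),
                 m = m, objective = fit$obj, iterations = fit$it,
                 converged = fit$converged),
            class = "wound_fuzzy")
}

membership_from_d2 <- function(d2, m) {
  n <- nrow(d2); c <- ncol(d2)
  u <- matrix(0, n, c)
  zero <- d2 < 1e-300
  has_zero <- rowSums(zero) > 0
  if (any(has_zero)) {
    u[has_zero, ] <- zero[has_zero, , drop = FALSE] /
      rowSums(zero[has_zero, , drop = FALSE])
  }
  if (any(!has_zero)) {
    # log-space for numerical stability when m is close to 1
    lw <- -log(d2[!has_zero, , drop = FALSE]) / (m - 1)
    lw <- lw - apply(lw, 1, max)
    w <- exp(lw)
    u[!has_zero, ] <- w / rowSums(w)
  }
  u
}

#' Direction of a cluster trajectory
#'
#' A cluster is "up" iff the signed area (trapezoidal integral over time)
#' of its mean unstandardized log2 fold-change trajectory is positive. An
#' exact zero area is broken toward the sign at the earliest nonzero point,
#' with a message.
#'
#' @param center numeric trajectory (unstandardized log2 FC).
#' @param times matching time points.
#' @return "up" or "down".
#' @export
classify_direction <- function(center, times) {
  stopifnot(length(center) == length(times), !is.unsorted(times))
  dt <- diff(times)
  area <- sum((center[-1] + center[-length(center)]) / 2 * dt)
  if (area > 0) return("up")
  if (area < 0) return("down")
  nz <- which(center != 0)
  inform("Zero signed area; breaking the tie by the earliest nonzero point.")
  if (length(nz) == 0 || center[nz[1]] > 0) "up" else "down"
}

#' Cluster DEG fold-change trajectories
#'
#' End-to-end temporal clustering: assembles the per-gene log2 fold-change
#' matrix of DEGs over the time grid, standardizes it, estimates the
#' fuzzifier, runs fuzzy c-means, and labels each cluster up- or
#' down-regulated from its mean unstandardized trajectory.
#'
#' @param de a `wound_de` from [run_diffexpr()].
#' @param c cluster count.
#' @param m optional fuzzifier (estimated if NULL).
#' @param seed integer seed.
#' @return A `wound_fuzzy` with extra elements `$directions` (per cluster),
#'   `$mean_trajectories` (cluster x time, unstandardized) and `$grid`.
#' @export
cluster_trajectories <- function(de, c, m = NULL, seed = 1L) {
  deg_ids <- de$genes$gene_id[de$genes$is_deg]
  if (length(deg_ids) <= c) abort("Fewer DEGs than requested clusters.")
  fc <- fold_change_matrix(de, deg_ids)
  std <- standardize_profiles(fc)
  fit <- fuzzy_cmeans(std, c = c, m = m, seed = seed)
  kept <- rownames(std)
  mean_traj <- t(vapply(colnames(fit$membership), function(cl) {
    members <- kept[fit$hard_label == cl]
    if (length(members) == 0) rep(NA_real_, ncol(fc))
    else colMeans(fc[members, , drop = FALSE])
  }, numeric(ncol(fc))))
  colnames(mean_traj) <- colnames(fc)
  dirs <- vapply(seq_len(nrow(mean_traj)), function(i) {
    if (anyNA(mean_traj[i, ])) NA_character_
    else classify_direction(mean_traj[i, ], de$grid)
  }, character(1))
  fit$directions <- setNames(dirs, rownames(mean_traj))
  fit$mean_trajectories <- mean_traj
  fit$grid <- de$grid
  fit
}

#' Log2 fold-change matrix from a differential result
#' @param de a `wound_de`.
#' @param gene_ids genes to keep (default: all).
#' @return Gene-by-time matrix of log2 fold changes.
#' @export
fold_change_matrix <- function(de, gene_ids = NULL) {
  tests <- de$tests
  if (!is.null(gene_ids)) tests <- tests[tests$gene_id %in% gene_ids, ]
  wide <- tidyr::pivot_wider(tests[, c("gene_id", "time_min", "log2fc")],
                             names_from = "time_min", values_from = "log2fc")
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$gene_id
  m[, order(as.numeric(colnames(m))), drop = FALSE]
}

#' @method tidy wound_fuzzy
#' @export
tidy.wound_fuzzy <- function(x, ...) {
  long <- as_tibble(x$membership, rownames = "gene_id")
  long <- tidyr::pivot_longer(long, -"gene_id",
                              names_to = "cluster", values_to = "membership")
  long$hard_label <- unname(x$hard_label[long$gene_id])
  if (!is.null(x$directions)) {
    long$direction <- unname(x$directions[long$cluster])
  }
  long
}

#' @method glance wound_fuzzy
#' @export
glance.wound_fuzzy <- function(x, ...) {
  tibble(n_genes = nrow(x$membership), n_clusters = ncol(x$membership),
         fuzzifier = x$m, iterations = x$iterations,
         converged = x$converged,
         objective = x$objective[length(x$objective)])
}

#' @export
print.wound_fuzzy <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<wound_fuzzy> %d genes in %d clusters (m = %.3f, %d iterations%s)\n",
              g$n_genes, g$n_clusters, g$fuzzifier, g$iterations,
              if (g$converged) "" else ", not converged"))
  if (!is.null(x$directions)) {
    cat("  directions:", paste(names(x$directions), x$directions,
                               sep = "=", collapse = " "), "\n")
  }
  invisible(x)
}
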