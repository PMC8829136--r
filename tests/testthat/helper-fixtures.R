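# Small fixtures shared across test files. Everything is generated in code;
# sizes are kept small so the whole suite stays fast.

tiny_experiment <- function(n_genes = 300, seed = 42, ...) {
  simulate_experiment(
    n_genes = n_genes,
    archetype_mix = c(flat = 0.6, pulse = 0.2, sustained = 0.12,
                      oscillating = 0.08),
    module_sizes = if (n_genes >= 200) c(M1 = 20, M2 = 25, M3 = 30),
    seed = seed, ...
  )
}

# four planted archetype-direction groups for clustering recovery
four_group_experiment <- function(n_genes = 1200, seed = 1) {
  tmpl <- list(
    A = archetype_spec("pulse", "up", peak_min = 10, decay_rate = 1 / 8),
    B = archetype_spec("pulse", "down", peak_min = 10, decay_rate = 1 / 8),
    C = archetype_spec("sustained", "up", onset_min = 40, decay_rate = 0.15),
    D = archetype_spec("sustained", "down", onset_min = 40, decay_rate = 0.15)
  )
  sz <- floor(n_genes * 0.4 / 4)
  simulate_experiment(
    n_genes = n_genes,
    archetype_mix = c(flat = 0.6, pulse = 0.2, sustained = 0.2),
    module_sizes = c(A = sz, B = sz, C = sz, D = sz),
    module_templates = tmpl, seed = seed
  )
}

# definitional BH oracle: fdr_i = min over j with p_(j) >= p_(i) of p_(j)*m/j
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}

# hypergeometric upper tail by direct binomial-coefficient arithmetic
hyper_oracle <- function(k, K, n, N) {
  if (k == 0) return(1)
  js <- k:min(K, n)
  sum(exp(lchoose(K, js) + lchoose(N - K, n - js) - lchoose(N, n)))
}

# naive per-window PWM rescoring on both strands
pwm_scan_oracle <- function(sequence, pwm, threshold) {
  bases <- strsplit(sequence, "")[[1]]
  m <- unclass(pwm) + 1e-4
  m <- sweep(m, 2, colSums(m), "/")
  lo <- log2(m / 0.25)
  w <- ncol(lo)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  out <- list()
  for (off in seq_len(length(bases) - w + 1)) {
    win <- bases[off:(off + w - 1)]
    if (any(!win %in% names(comp))) next
    sc_f <- sum(vapply(seq_len(w), function(j) lo[win[j], j], numeric(1)))
    rc <- rev(unname(comp[win]))
    sc_r <- sum(vapply(seq_len(w), function(j) lo[rc[j], j], numeric(1)))
    if (sc_f >= threshold) {
      out[[length(out) + 1]] <- data.frame(offset = off - 1L, strand = "+",
                                           score = sc_f)
    }
    if (sc_r >= threshold) {
      out[[length(out) + 1]] <- data.frame(offset = off - 1L, strand = "-",
                                           score = sc_r)
    }
  }
  if (length(out) == 0) {
    return(data.frame(offset = integer(), strand = character(),
                      score = numeric()))
  }
  df <- do.call(rbind, out)
  df[order(df$offset, df$strand), ]
}

# O(n^3) TOM oracle
tom_oracle <- function(a) {
  n <- nrow(a)
  diag(a) <- 0
  k <- rowSums(a)
  tom <- matrix(1, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      l <- 0
      for (u in seq_len(n)) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
      tom[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
    }
  }
  tom
}

adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  total <- choose(sum(tab), 2)
  expected <- sum_a * sum_b / total
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

random_dna <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
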