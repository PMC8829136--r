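test_that("adjacency follows the printed closed forms", {
  cc <- matrix(c(1, 1, 1, 1), 2, 2)
  expect_equal(wgcna_adjacency(cc, 7)[1, 2], 1)
  cc[1, 2] <- cc[2, 1] <- -1
  expect_equal(wgcna_adjacency(cc, 7)[1, 2], 0)
  cc[1, 2] <- cc[2, 1] <- 0
  expect_equal(wgcna_adjacency(cc, 16)[1, 2], 2^-16)

  # monotone: larger beta weakly shrinks every off-diagonal entry
  set.seed(15)
  r <- cor(matrix(rnorm(200), 20, 10))
  a4 <- wgcna_adjacency(r, 4); a8 <- wgcna_adjacency(r, 8)
  off <- upper.tri(r)
  expect_true(all(a8[off] <= a4[off] + 1e-15))
})

test_that("TOM matches the O(n^3) oracle and closed forms", {
  # triangle of full-strength edges
  tri <- matrix(1, 3, 3)
  expect_equal(tom_similarity(tri)[1, 2], 1)
  # isolated pair
  pair <- diag(4)
  pair[1, 2] <- pair[2, 1] <- 0.5
  expect_equal(tom_similarity(pair)[1, 2], 0.5)

  set.seed(16)
  for (i in 1:5) {
    a <- matrix(runif(400), 20, 20)
    a <- (a + t(a)) / 2
    diag(a) <- 1
    tom <- tom_similarity(a)
    expect_lt(max(abs(tom - tom_oracle(a))), 1e-12)
    expect_equal(tom, t(tom))
    expect_true(all(tom >= 0 & tom <= 1 + 1e-12))
  }
})

test_that("scale-free fit prefers heavy-tailed connectivity", {
  set.seed(17)
  # hub-structured data: per-gene loadings with a heavy tail
  n <- 300; s <- 40
  loads <- pmin(1, 0.1 + rexp(n, rate = 4))
  latent <- rnorm(s)
  expr <- loads %o% latent + matrix(rnorm(n * s, sd = sqrt(1 - 0.3)), n, s)
  rownames(expr) <- paste0("g", 1:n)
  # whether the 0.8 fit is reached varies with the draw; the fallback warns
  pick <- suppressWarnings(
    pick_soft_threshold(expr, beta_candidates = c(1, 2, 4, 6, 8, 10)))
  expect_true(pick$beta %in% c(1, 2, 4, 6, 8, 10))
  expect_equal(nrow(pick$fit_table), 6)
  # independent genes give a near-constant connectivity at beta 1: poor fit
  indep <- matrix(rnorm(n * s), n, s, dimnames = list(paste0("g", 1:n), NULL))
  expect_warning(pick_ind <- pick_soft_threshold(indep, beta_candidates = 1),
                 "No candidate power")
  ft <- pick_ind$fit_table
  expect_lt(ft$r2[1] * (ft$slope[1] < 0), 0.8)
})

test_that("module detection recovers planted blocks and respects min size", {
  # three blocks with within-block correlation 0.8 and none between,
  # soft-thresholded at the published power 16
  set.seed(18)
  cc <- matrix(0, 60, 60)
  for (b in 0:2) cc[b * 20 + 1:20, b * 20 + 1:20] <- 0.8
  diag(cc) <- 1
  dimnames(cc) <- list(paste0("g", 1:60), paste0("g", 1:60))
  tom <- tom_similarity(wgcna_adjacency(cc, 16))
  dimnames(tom) <- dimnames(cc)
  labels <- detect_modules(tom, min_module_size = 10)
  truth <- rep(1:3, each = 20)
  expect_gte(adjusted_rand(labels, truth), 0.9)

  # a block below min_module_size goes grey
  expect_warning(labels30 <- detect_modules(tom, min_module_size = 30),
                 "grey")
  expect_true(all(labels30 == "grey"))

  # label assignment is invariant to gene order
  perm <- sample(60)
  labels_perm <- detect_modules(tom[perm, perm], min_module_size = 10)
  expect_equal(labels_perm[rownames(tom)], labels)
})

test_that("module eigengenes are unit-norm, sign-oriented, PCA-optimal", {
  set.seed(19)
  s <- 24
  prof <- sin(seq(0, 2 * pi, length.out = s))
  expr <- t(replicate(15, prof + rnorm(s, sd = 0.1)))
  rownames(expr) <- paste0("g", 1:15)
  expr <- (expr - rowMeans(expr)) / apply(expr, 1, sd)
  colnames(expr) <- paste0("s", 1:s)
  me <- module_eigengene(expr, rownames(expr))
  expect_equal(sum(me$eigengene^2), 1, tolerance = 1e-12)
  expect_gte(cor(me$eigengene, colMeans(expr)), 0)
  # identical profiles: rank-1, 100% variance explained
  same <- expr[rep(1, 5), ]
  rownames(same) <- paste0("h", 1:5)
  me1 <- module_eigengene(same, rownames(same))
  expect_equal(me1$var_explained, 1, tolerance = 1e-12)
  expect_gt(abs(cor(me1$eigengene, same[1, ])), 0.999)
  # optimality: no random unit vector explains more variance
  proj_var <- function(v) sum((expr %*% v)^2)
  best <- proj_var(me$eigengene)
  for (i in 1:20) {
    v <- rnorm(s); v <- v / sqrt(sum(v^2))
    expect_lte(proj_var(v), best + 1e-8)
  }
})

test_that("modules with similar eigengenes merge below the cut height", {
  set.seed(20)
  s <- 30
  latent <- rnorm(s)
  mk <- function(n, base, sd) {
    m <- t(replicate(n, base + rnorm(s, sd = sd)))
    (m - rowMeans(m)) / apply(m, 1, sd)
  }
  expr <- rbind(mk(12, latent, 0.1), mk(12, latent, 0.1),
                mk(12, rnorm(s), 0.1))
  rownames(expr) <- paste0("g", 1:36)
  colnames(expr) <- paste0("s", 1:s)
  labels <- setNames(rep(c("blue", "red", "yellow"), each = 12),
                     rownames(expr))
  merged <- merge_modules(expr, labels, merge_cut_height = 0.25)
  # the two modules sharing a latent factor collapse to one label
  expect_equal(length(unique(merged$labels[1:24])), 1)
  expect_equal(length(unique(merged$labels)), 2)
  log_tbl <- merged$merge_log
  expect_equal(nrow(log_tbl), 3)
  # an orthogonal module stays: dissimilarity ~1 >> 0.25
  expect_false(merged$labels[25] %in% merged$labels[1:24])
})

test_that("module-trait correlation hits identity fixed points", {
  exp <- tiny_experiment(seed = 22)
  samples <- exp$samples
  grid <- sort(unique(samples$time_min))
  # one eigengene that equals a trait profile on the treatment average
  profile <- seq_along(grid)
  me <- matrix(0, nrow(samples), 1,
               dimnames = list(samples$sample_id, "blue"))
  me[, 1] <- profile[match(samples$time_min, grid)] +
    ifelse(samples$group == "treatment", 0, 0)
  traits <- tibble::tibble(metabolite = "m1", time_min = grid,
                           value = 2^profile - 1)   # log2(v+1) = profile
  res <- module_trait_correlation(me, samples, traits)
  expect_equal(res$r, 1, tolerance = 1e-12)
  res2 <- module_trait_correlation(-me, samples, traits)
  expect_equal(res2$r, -1, tolerance = 1e-12)
  expect_error(
    module_trait_correlation(me[samples$time_min %in% grid[1:2], , drop = FALSE],
                             samples[samples$time_min %in% grid[1:2], ], traits),
    "Fewer than 3"
  )
})

test_that("edge extraction applies the 0.5 and 0.15 cuts exactly", {
  genes <- c("tf1", "g1", "g2", "g3")
  w <- matrix(0, 4, 4, dimnames = list(genes, genes))
  w["tf1", "g1"] <- w["g1", "tf1"] <- 0.6    # TF edge, kept
  w["tf1", "g2"] <- w["g2", "tf1"] <- 0.4    # TF edge, dropped
  w["g1", "g2"] <- w["g2", "g1"] <- 0.4      # gene edge, kept
  w["g2", "g3"] <- w["g3", "g2"] <- 0.15     # boundary: not greater -> dropped
  labels <- setNames(rep("blue", 4), genes)
  tf <- c(tf1 = "WRKY")
  edges <- extract_edges(w, labels, tf)
  expect_equal(nrow(edges), 2)
  tfe <- edges[edges$type == "tf_gene", ]
  expect_equal(tfe$from, "tf1")
  expect_equal(tfe$to, "g1")
  gge <- edges[edges$type == "gene_gene", ]
  expect_equal(sort(c(gge$from, gge$to)), c("g1", "g2"))
  # empty module -> empty edges
  empty <- extract_edges(w, setNames(rep("grey", 4), genes), tf)
  expect_equal(nrow(empty), 0)
})

test_that("GraphML export round-trips nodes and attributes", {
  edges <- tibble::tibble(from = c("tf1", "g1"), to = c("g1", "g2"),
                          weight = c(0.6, 0.3),
                          type = c("tf_gene", "gene_gene"),
                          module = "blue")
  labels <- c(tf1 = "blue", g1 = "blue", g2 = "blue")
  f <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(edges, labels, c(tf1 = "WRKY"), f)
  g <- igraph::read_graph(f, format = "graphml")
  expect_equal(igraph::vcount(g), 3)
  expect_equal(igraph::ecount(g), 2)
  expect_setequal(igraph::V(g)$module, "blue")
  expect_equal(sum(igraph::V(g)$is_tf), 1)
})

test_that("planted modules and their volatile associations are recovered", {
  exp <- tiny_experiment(n_genes = 700, seed = 23)
  cfg <- wound_config(min_module_size = 15, seed = 23)
  de <- run_diffexpr(exp, cfg)
  traits <- simulate_volatiles(seed = 23)
  nw <- suppressWarnings(run_coexpression(exp, de, cfg, traits = traits))
  tg <- exp$truth$genes
  mods <- tidy(nw)
  tt <- tg[match(mods$gene_id, tg$gene_id), ]
  sel <- !is.na(tt$module)
  expect_gte(adjusted_rand(tt$module[sel], mods$module[sel]), 0.9)
  # eigengene tracks the planted module signal
  # modules this small (20-30 genes) recover the latent a little less
  # sharply than the full-scale design, hence the 0.9 floor here
  ms <- exp$truth$module_signal
  for (m in colnames(ms)) {
    lab <- names(which.max(table(mods$module[sel][tt$module[sel] == m])))
    if (lab == "grey") next
    expect_gte(abs(cor(nw$eigengenes[, lab], ms[, m])), 0.9)
  }
  # the delayed-rise volatile is most correlated with the late sustained
  # module (M2)
  m2_lab <- names(which.max(table(mods$module[sel][tt$module[sel] == "M2"])))
  mt <- nw$module_trait[nw$module_trait$metabolite == "indole", ]
  expect_equal(mt$module[which.max(mt$r)], m2_lab)
})
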