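test_that("size factors recover known library-size ratios", {
  m <- matrix(c(10, 20, 30, 20, 40, 60), ncol = 2,
              dimnames = list(paste0("g", 1:3), c("a", "b")))
  sf <- size_factors(m)
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)
  expect_equal(exp(mean(log(sf))), 1, tolerance = 1e-12)

  same <- cbind(a = c(5, 8, 13), b = c(5, 8, 13))
  rownames(same) <- paste0("g", 1:3)
  expect_equal(unname(size_factors(same)), c(1, 1))

  # an all-zero gene cannot enter the reference
  withzero <- rbind(m, g4 = c(0, 0))
  expect_equal(size_factors(withzero), sf)

  # no all-nonzero gene -> upper-quartile fallback
  uq <- rbind(g1 = c(0, 10), g2 = c(10, 0), g3 = c(20, 0))
  expect_message(sfu <- size_factors(uq), "upper-quartile")
  expect_equal(exp(mean(log(sfu))), 1, tolerance = 1e-12)
})

test_that("NB Wald test honours its fixed points and fold-change arithmetic", {
  null <- nb_wald_test(c(10, 10, 10), c(10, 10, 10))
  expect_equal(null$log2fc, 0)
  expect_equal(null$p, 1)

  res <- nb_wald_test(c(40, 50, 45), c(9, 11, 10))
  expect_equal(res$log2fc, log2(45.5 / 10.5), tolerance = 1e-12)
  expect_lt(res$p, 0.05)

  zero <- nb_wald_test(c(0, 0, 0), c(0, 0, 0))
  expect_equal(zero$log2fc, 0)
  expect_equal(zero$p, 1)
})

test_that("NB Wald p-values are roughly uniform under the null", {
  set.seed(21)
  n <- 4000
  mu <- exp(runif(n, log(50), log(2000)))
  yt <- matrix(rnbinom(n * 3, mu = rep(mu, 3), size = 20), n, 3)
  yc <- matrix(rnbinom(n * 3, mu = rep(mu, 3), size = 20), n, 3)
  p <- vapply(seq_len(n), function(i) nb_wald_test(yt[i, ], yc[i, ])$p,
              numeric(1))
  expect_gt(mean(p < 0.05), 0.02)
  expect_lt(mean(p < 0.05), 0.10)
})

test_that("BH adjustment matches p.adjust fixed points", {
  expect_equal(bh_adjust(0.04), 0.04)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04, 0.05)), rep(0.05, 5))
  set.seed(3)
  p <- runif(50)
  expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-15)
  expect_error(bh_adjust(c(0.5, 1.2)))
})

test_that("DEG calling applies the FDR, fold-change and count filters", {
  grid <- c(5, 10, 20)
  mk_tests <- function(fdr10, lfc10) {
    tidyr::expand_grid(gene_id = c("gA", "gB", "gC"), time_min = grid) |>
      dplyr::mutate(
        log2fc = ifelse(.data$gene_id != "gC" & .data$time_min == 10, lfc10, 0.1),
        fdr = ifelse(.data$gene_id != "gC" & .data$time_min == 10, fdr10, 0.9),
        p = fdr
      )
  }
  tests <- mk_tests(0.01, 1.5)
  counts_min <- c(gA = 15, gB = 8, gC = 50)
  res <- call_degs(tests, counts_min, wound_config())
  expect_true(res$is_deg[res$gene_id == "gA"])
  expect_equal(res$fdeg_time[res$gene_id == "gA"], 10)
  expect_equal(res$direction[res$gene_id == "gA"], "up")
  # min count 8 <= 10 blocks the call even though the test passes
  expect_false(res$is_deg[res$gene_id == "gB"])
  expect_true(is.na(res$fdeg_time[res$gene_id == "gB"]))
  # never DE
  expect_false(res$is_deg[res$gene_id == "gC"])

  # below fold-change threshold at any FDR -> not DE
  weak <- call_degs(mk_tests(0.001, 0.7), counts_min, wound_config())
  expect_false(any(weak$is_deg))
})

test_that("find_fdeg returns the earliest flagged time", {
  expect_equal(find_fdeg(c(FALSE, TRUE, TRUE), c(5, 10, 20)), 10)
  expect_true(is.na(find_fdeg(c(FALSE, FALSE), c(5, 10))))
})

test_that("burst summary counts are consistent with the DEG set", {
  exp <- tiny_experiment(seed = 8)
  de <- run_diffexpr(exp, wound_config(seed = 8))
  b <- burst_summary(de)
  expect_equal(sum(b$n_fdeg), sum(de$genes$is_deg))
  expect_true(all(b$n_fdeg <= b$n_deg))
  expect_equal(b$cum_fdeg_fraction[nrow(b)], 1)
  expect_true(all(b$n_deg_up + b$n_deg_down == b$n_deg))
})

test_that("detection power is monotone in amplitude", {
  run_amp <- function(amp) {
    tmpl <- list(P = archetype_spec("pulse", "up", peak_min = 10,
                                    decay_rate = 1 / 8))
    exp <- simulate_experiment(
      n_genes = 500, archetype_mix = c(flat = 0.8, pulse = 0.2),
      module_sizes = c(P = 100), module_templates = tmpl,
      amplitude_range = c(amp, amp), latent_sd = 0,
      baseline_mean_range = c(100, 2000), seed = 31
    )
    de <- run_diffexpr(exp, wound_config(seed = 31))
    planted <- exp$truth$genes$gene_id[exp$truth$genes$archetype == "pulse"]
    mean(de$genes$is_deg[match(planted, de$genes$gene_id)])
  }
  expect_gte(run_amp(3), run_amp(1))
})

test_that("PCA contributions are normalized and find the dominant axis", {
  set.seed(5)
  latent <- sin(seq(0, pi, length.out = 12))
  expr <- rbind(
    outer(rnorm(20, 1, 0.05), latent),       # genes following one profile
    matrix(rnorm(60 * 12, sd = 1e-4), 60)    # near-constant genes
  )
  rownames(expr) <- paste0("g", 1:80)
  colnames(expr) <- paste0("s", 1:12)
  pc <- pca_contributions(expr, k = 20)
  expect_gt(pc$var_explained[1], 0.99)
  expect_equal(sum(pc$contributions$contribution), 1, tolerance = 1e-12)
  expect_setequal(pc$contributions$gene_id[pc$contributions$top_k],
                  paste0("g", 1:20))
  expect_error(pca_contributions(matrix(1, 3, 3)), "no variance")
})
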