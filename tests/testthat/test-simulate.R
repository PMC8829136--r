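test_that("archetype profiles follow their closed forms", {
  flat <- archetype_spec("flat", "up")
  expect_equal(archetype_profile(flat, c(0, 10, 220)), c(0, 0, 0))

  pulse <- archetype_spec("pulse", "up", amplitude = 3, peak_min = 10,
                          decay_rate = 1 / 5)
  expect_equal(archetype_profile(pulse, 10), 3)
  expect_equal(archetype_profile(pulse, 20), 3 * exp(-(10 / 5)^2 / 2),
               tolerance = 1e-12)   # ~0.406

  sus <- archetype_spec("sustained", "down", amplitude = 2, onset_min = 40,
                        decay_rate = 0.15)
  expect_equal(archetype_profile(sus, 40), -2 * 0.5)
  expect_true(all(diff(archetype_profile(sus, seq(0, 220, 10))) <= 0))

  osc <- archetype_spec("oscillating", "up", amplitude = 2, onset_min = 20,
                        decay_rate = 0.003, period_min = 80)
  tt <- seq(0, 220, 0.5)
  expect_true(all(abs(archetype_profile(osc, tt)) <= 2))
  expect_equal(archetype_profile(osc, 20), 2 * exp(-0.003 * 20))
})

test_that("generated counts are reproducible and respect the null case", {
  e1 <- simulate_experiment(n_genes = 120, module_sizes = NULL, seed = 5)
  e2 <- simulate_experiment(n_genes = 120, module_sizes = NULL, seed = 5)
  expect_identical(e1$counts, e2$counts)

  flat_only <- simulate_experiment(n_genes = 60, module_sizes = NULL,
                                   archetype_mix = c(flat = 1), seed = 2)
  expect_true(all(is.na(flat_only$truth$genes$fdeg_time)))
  expect_true(all(flat_only$truth$genes$archetype == "flat"))
})

test_that("generated counts match the NB mean-variance law", {
  # one gene, many replicates: empirical mean ~ mu, var ~ mu + phi mu^2
  set.seed(11)
  mu <- 200; phi <- 0.05; n <- 10000
  draws <- rnbinom(n, mu = mu, size = 1 / phi)
  expect_equal(mean(draws), mu, tolerance = 0.03)
  expect_equal(var(draws), mu + phi * mu^2, tolerance = 0.1)

  # treatment/control ratio at the pulse peak approaches 2^amplitude
  tmpl <- list(P = archetype_spec("pulse", "up", amplitude = 3,
                                  peak_min = 10, decay_rate = 1 / 8))
  exp <- simulate_experiment(
    n_genes = 2000, archetype_mix = c(flat = 0.8, pulse = 0.2),
    module_sizes = c(P = 400), module_templates = tmpl,
    latent_sd = 0, amplitude_range = c(3, 3), seed = 3
  )
  s <- exp$samples
  sf <- exp$truth$params$size_factors
  norm <- sweep(exp$counts, 2, sf[colnames(exp$counts)], "/")
  pulse_genes <- exp$truth$genes$gene_id[exp$truth$genes$archetype == "pulse"]
  tr <- s$sample_id[s$group == "treatment" & s$time_min == 10]
  ct <- s$sample_id[s$group == "control" & s$time_min == 10]
  ratio <- mean(norm[pulse_genes, tr]) / mean(norm[pulse_genes, ct])
  expect_equal(ratio, 8, tolerance = 0.1)
})

test_that("ground-truth FDEG times agree with thresholded noiseless profiles", {
  exp <- tiny_experiment(n_genes = 200, seed = 9)
  tg <- exp$truth$genes
  grid <- exp$truth$params$grid
  prof <- exp$truth$profiles
  thr <- log2(exp$truth$params$fc_threshold)
  recomputed <- apply(prof, 1, function(p) {
    ok <- which(abs(p) >= thr & grid > 0)
    if (length(ok) == 0) NA_real_ else grid[min(ok)]
  })
  expect_equal(unname(recomputed), tg$fdeg_time)
})

test_that("promoter planting follows the plant and background probabilities", {
  clusters <- setNames(rep(c("pulse_up", "flat"), each = 150),
                       sprintf("g%03d", 1:300))
  cons <- c(pulse_up = "TTGACCA")

  always <- simulate_promoters(clusters, cons, plant_prob = 1,
                               background_prob = 0, seed = 1)
  expect_true(all(nchar(always) == 500))
  target <- names(clusters)[clusters == "pulse_up"]
  expect_true(all(grepl("TTGACCA", always[target], fixed = TRUE)))

  never <- simulate_promoters(clusters, cons, plant_prob = 0,
                              background_prob = 0, seed = 1)
  # expected chance hits: ~494 windows x 2 strands x (1/4)^7 ~ 6% of genes
  hit_rate <- mean(grepl("TTGACCA", never[target], fixed = TRUE))
  expect_lt(hit_rate, 0.15)

  expect_error(
    simulate_promoters(clusters, c(pulse_up = random_dna(501, 1)),
                       window = 500),
    "longer than"
  )
})

test_that("volatile patterns obey their noiseless shape contracts", {
  vol <- simulate_volatiles(noise_cv = 0, seed = 1)
  after40 <- function(met) {
    v <- vol[vol$metabolite == met & vol$time_min >= 40, ]
    v$value[order(v$time_min)]
  }
  expect_true(all(diff(after40("indole")) >= 0))          # delayed rise
  expect_true(all(diff(after40("hexanal")) <= 0))         # early decay
  hx <- after40("hexanal")
  expect_lt(hx[length(hx)], hx[1])
  est <- vol[vol$metabolite == "hexenyl-acetate" & vol$time_min > 0, ]
  expect_equal(length(unique(est$value)), 1)              # constant after 0

  n1 <- simulate_volatiles(noise_cv = 0.2, seed = 4)
  n2 <- simulate_volatiles(noise_cv = 0.2, seed = 4)
  expect_identical(n1, n2)
})
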