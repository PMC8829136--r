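test_that("hypergeometric upper tail matches direct arithmetic", {
  expect_equal(hypergeom_upper_tail(0, 5, 10, 20), 1)
  expect_equal(hypergeom_upper_tail(5, 5, 20, 20), 1)  # forced full draw
  expect_equal(hypergeom_upper_tail(4, 5, 10, 20), 28028 / 184756,
               tolerance = 1e-12)
  expect_error(hypergeom_upper_tail(6, 5, 10, 20), "Inconsistent")

  # monotone non-increasing in k
  ps <- vapply(0:8, function(k) hypergeom_upper_tail(k, 10, 8, 40), numeric(1))
  expect_true(all(diff(ps) <= 0))
})

test_that("term enrichment flags a planted excess and trivial nulls", {
  background <- sprintf("g%03d", 1:200)
  cluster <- background[1:40]
  ann <- list(
    planted = c(background[1:25], background[190:200]),  # 25/40 in cluster
    everything = background,                             # no signal
    disjoint = background[100:120]
  )
  res <- enrich_terms(cluster, ann, background, alpha = 0.05)
  expect_equal(res$term[1], "planted")
  expect_lte(res$p[1], 0.05)
  expect_true(res$significant[1])
  expect_equal(res$p[res$term == "everything"], 1)
  expect_equal(res$p[res$term == "disjoint"], 1)
  expect_equal(res$k[res$term == "disjoint"], 0)

  expect_warning(empty <- enrich_terms(character(), ann, background), "Empty")
  expect_equal(nrow(empty), 0)
  expect_error(enrich_terms("not_in_bg", ann, background), "outside")
})

test_that("PWM scanning matches hand-computed scores and null sequences", {
  pwm <- consensus_pwm("ACG", leak = 0)
  hits <- pwm_scan("TACGT", pwm, threshold = 5)
  fwd <- hits[hits$strand == "+", ]
  expect_equal(nrow(fwd), 1)
  expect_equal(fwd$offset, 1L)
  expect_equal(fwd$score, 3 * log2((1 + 1e-4) / (1 + 4e-4) / 0.25),
               tolerance = 1e-12)    # ~6 bits
  expect_equal(nrow(pwm_scan("TTTTT", pwm, threshold = 5)), 0)
  # shorter than the motif -> empty
  expect_equal(nrow(pwm_scan("AC", pwm)), 0)
  # N windows are skipped: only the N-free AG window can score
  expect_equal(nrow(pwm_scan("ANAGT", consensus_pwm("AG"), threshold = 0)), 1)
  expect_equal(pwm_scan("ANAGT", consensus_pwm("AG"), threshold = 0)$offset, 2L)
})

test_that("scanning is strand-symmetric and matches the naive oracle", {
  pwm <- consensus_pwm("ACGGT", leak = 0.03)
  thr <- 0.8 * pwm_max_score(pwm)
  revcomp <- function(s) {
    chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }
  for (seed in 1:20) {
    s <- random_dna(200, seed)
    ours <- pwm_scan(s, pwm)
    oracle <- pwm_scan_oracle(s, pwm, thr)
    expect_equal(nrow(ours), nrow(oracle))
    if (nrow(ours) > 0) {
      expect_equal(ours$offset, oracle$offset)
      expect_equal(ours$strand, oracle$strand)
      expect_equal(ours$score, oracle$score, tolerance = 1e-9)
    }
    # mirrored hits on the reverse complement
    rc_hits <- pwm_scan(revcomp(s), pwm)
    expect_equal(nrow(rc_hits), nrow(ours))
    if (nrow(ours) > 0) {
      expect_setequal(200 - 5 - rc_hits$offset, ours$offset)
    }
  }
})

test_that("motif overrepresentation counts genes once and finds plants", {
  clusters <- setNames(rep(c("target", "flat"), each = 120),
                       sprintf("g%03d", 1:240))
  cons <- c(target = "TTGACCA")
  promoters <- simulate_promoters(clusters, cons, plant_prob = 0.8,
                                  background_prob = 0.1, seed = 6)
  pwm <- list(wbox = consensus_pwm("TTGACCA", leak = 0.01))
  res <- motif_overrepresentation(split(names(clusters), clusters),
                                  promoters, pwm)
  target_row <- res[res$cluster == "target", ]
  flat_row <- res[res$cluster == "flat", ]
  expect_true(target_row$significant)
  expect_lte(target_row$p, 0.05)
  expect_false(flat_row$significant)

  # multiplicity does not change gene-level counts: planting the motif
  # twice in one promoter leaves k unchanged
  p2 <- promoters
  p2[1] <- paste0("TTGACCA", substr(p2[1], 8, 493), "TTGACCA")
  res2 <- motif_overrepresentation(split(names(clusters), clusters), p2, pwm)
  had_hit <- nrow(pwm_scan(promoters[1], pwm$wbox)) > 0
  if (had_hit) {
    expect_equal(res2$k[res2$cluster == "target"],
                 target_row$k)
  }
})
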