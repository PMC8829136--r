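#' Archetype fold-change profiles
#'
#' The generator models treatment/control log2 fold change over time with
#' four archetypes seen in wounding time courses: a single Gaussian pulse,
#' a sustained (logistic) induction, a damped oscillation, and a flat null
#' profile. Profiles are signed by `direction`.
#'
#' * pulse: `A * exp(-decay_rate^2 * (t - peak_min)^2 / 2)` (decay_rate is
#'   1/sigma in 1/min, so sigma = 1/decay_rate minutes),
#' * sustained: `A * plogis(decay_rate * (t - onset_min))`,
#' * oscillating: `A * cos(2*pi*(t - onset_min)/period_min) * exp(-decay_rate*t)`,
#' * flat: 0.
#'
#' @param kind one of "pulse", "sustained", "oscillating", "flat".
#' @param direction "up" or "down".
#' @param amplitude peak absolute log2 fold change (>= 0; 0 for flat).
#' @param onset_min,peak_min timing parameters in minutes.
#' @param decay_rate rate parameter in 1/min (see shapes above).
#' @param period_min oscillation period in minutes.
#' @return An `archetype_spec` list.
#' @export
#' @examples
#' sp <- archetype_spec("pulse", "up", amplitude = 3, peak_min = 10,
#'                      decay_rate = 0.2)
#' archetype_profile(sp, c(10, 20))
archetype_spec <- function(kind = c("pulse", "sustained", "oscillating", "flat"),
                           direction = c("up", "down"),
                           amplitude = 2, onset_min = 0, peak_min = NULL,
                           decay_rate = 0.2, period_min = 80) {
  kind <- match.arg(kind)
  direction <- match.arg(direction)
  if (is.null(peak_min)) peak_min <- max(10, onset_min)
  if (kind == "flat") amplitude <- 0
  stopifnot(amplitude >= 0, onset_min >= 0, peak_min >= onset_min,
            decay_rate >= 0, period_min > 0)
  structure(list(kind = kind, direction = direction, amplitude = amplitude,
                 onset_min = onset_min, peak_min = peak_min,
                 decay_rate = decay_rate, period_min = period_min),
            class = "archetype_spec")
}

#' @rdname archetype_spec
#' @param spec an `archetype_spec`.
#' @param t numeric vector of minutes (>= 0).
#' @return `archetype_profile()`: numeric vector of log2 fold changes,
#'   `|value| <= amplitude`.
#' @export
archetype_profile <- function(spec, t) {
  stopifnot(all(t >= 0))
  base <- switch(spec$kind,
    flat = rep(0, length(t)),
    pulse = spec$amplitude *
      exp(-(spec$decay_rate^2) * (t - spec$peak_min)^2 / 2),
    sustained = spec$amplitude *
      stats::plogis(spec$decay_rate * (t - spec$onset_min)),
    oscillating = spec$amplitude *
      cos(2 * pi * (t - spec$onset_min) / spec$period_min) *
      exp(-spec$decay_rate * t)
  )
  if (spec$direction == "down") base <- -base
  base
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

default_grid <- function() c(0, 0.5, 5, 10, 20, 30, 40, 70, 100, 160, 220)

default_module_templates <- function() {
  list(
    M1 = archetype_spec("pulse", "up", peak_min = 10, decay_rate = 1 / 8),
    M2 = archetype_spec("sustained", "up", onset_min = 40, decay_rate = 0.15),
    M3 = archetype_spec("pulse", "down", peak_min = 30, decay_rate = 1 / 20)
  )
}

#' Simulate a wounding time-series experiment with known ground truth
#'
#' Generates negative-binomial counts for a treatment (wounded) and control
#' (unwounded) series on a shared time grid. A fraction of genes receive a
#' non-flat log2 fold-change archetype; three co-expression modules are
#' planted by default, each sharing one archetype plus a per-sample latent
#' factor (loading 0.8) that induces within-module correlation beyond the
#' mean profile. Ground truth (archetype, first time the noiseless profile
#' crosses the fold-change threshold, cluster, module, TF family) is
#' attached to the returned experiment.
#'
#' @param n_genes number of genes.
#' @param grid sampling times in minutes (must include 0, the baseline).
#' @param n_reps replicates per group and time point.
#' @param archetype_mix named fractions over flat/pulse/sustained/oscillating
#'   (must sum to 1); applied to genes outside planted modules.
#' @param amplitude_range uniform range of |log2 FC| amplitudes.
#' @param nb_dispersion NB dispersion phi (variance = mu + phi mu^2).
#' @param baseline_mean_range log-uniform range of baseline mean counts.
#' @param libsize_range uniform range of per-sample library-size factors.
#' @param module_sizes planted module sizes (set `NULL` or `integer(0)` for
#'   no modules); module archetypes follow `module_templates`.
#' @param module_templates named list of `archetype_spec`s, one per module.
#' @param latent_loading loading of the shared per-sample latent factor for
#'   module genes; residual loading is `sqrt(1 - loading^2)`.
#' @param latent_sd standard deviation (log2 units) of the latent factor.
#' @param tf_fraction background probability a gene carries a TF family.
#' @param tf_bias_cluster,tf_bias_family,tf_bias_prob plant an excess of one
#'   TF family in one ground-truth cluster (early pulse-up WRKY by default),
#'   so family overrepresentation has a known positive.
#' @param fc_threshold fold-change threshold defining the true first-DE time.
#' @param seed integer seed.
#' @return A [wound_experiment()] with a `wound_truth` object in `$truth`.
#' @export
simulate_experiment <- function(n_genes = 2000,
                                grid = default_grid(),
                                n_reps = 3,
                                archetype_mix = c(flat = 0.8, pulse = 0.10,
                                                  sustained = 0.06,
                                                  oscillating = 0.04),
                                amplitude_range = c(2, 4),
                                nb_dispersion = 0.05,
                                baseline_mean_range = c(20, 2000),
                                libsize_range = c(0.8, 1.25),
                                module_sizes = c(M1 = 80, M2 = 100, M3 = 120),
                                module_templates = default_module_templates(),
                                latent_loading = 0.8,
                                latent_sd = 0.4,
                                tf_fraction = 0.08,
                                tf_bias_cluster = "pulse_up",
                                tf_bias_family = "WRKY",
                                tf_bias_prob = 0.3,
                                fc_threshold = 2,
                                seed = 1L) {
  stopifnot(length(grid) >= 3, 0 %in% grid, n_reps >= 2)
  grid <- sort(unique(grid))
  if (abs(sum(archetype_mix) - 1) > 1e-8 || any(archetype_mix < 0)) {
    abort("`archetype_mix` fractions must be non-negative and sum to 1.")
  }
  kinds <- c("flat", "pulse", "sustained", "oscillating")
  if (!all(names(archetype_mix) %in% kinds)) {
    abort(paste0("Unknown archetype(s): ",
                 paste(setdiff(names(archetype_mix), kinds), collapse = ", ")))
  }
  if (is.null(module_sizes)) module_sizes <- integer(0)
  n_module_genes <- sum(module_sizes)
  n_nonflat_free <- round(n_genes * (1 - archetype_mix[["flat"]])) - n_module_genes
  if (n_nonflat_free < 0) {
    abort("Planted modules exceed the non-flat gene budget implied by `archetype_mix`.")
  }

  with_seed(seed, {
    gene_ids <- sprintf("g%05d", seq_len(n_genes))

    # --- per-gene archetype assignment --------------------------------
    specs <- vector("list", n_genes)
    module <- rep(NA_character_, n_genes)
    idx <- seq_len(n_genes)
    mod_idx <- if (n_module_genes > 0) sample(idx, n_module_genes) else integer(0)
    pos <- 0
    for (m in seq_along(module_sizes)) {
      take <- mod_idx[pos + seq_len(module_sizes[[m]])]
      pos <- pos + module_sizes[[m]]
      tmpl <- module_templates[[m]]
      for (g in take) {
        sp <- tmpl
        sp$amplitude <- runif(1, amplitude_range[1], amplitude_range[2])
        specs[[g]] <- sp
      }
      module[take] <- names(module_sizes)[m] %||% paste0("M", m)
    }
    free_idx <- setdiff(idx, mod_idx)
    nonflat_kinds <- setdiff(names(archetype_mix)[archetype_mix > 0], "flat")
    w <- archetype_mix[nonflat_kinds]
    free_nonflat <- if (n_nonflat_free > 0) sample(free_idx, n_nonflat_free) else integer(0)
    for (g in free_nonflat) {
      kind <- sample(nonflat_kinds, 1, prob = w)
      dirn <- sample(c("up", "down"), 1)
      amp <- runif(1, amplitude_range[1], amplitude_range[2])
      sp <- switch(kind,
        pulse = {
          peak <- sample(c(5, 10, 20, 30, 40), 1)
          archetype_spec("pulse", dirn, amp, peak_min = peak,
                         decay_rate = 2 / peak)
        },
        sustained = archetype_spec("sustained", dirn, amp,
                                   onset_min = sample(c(20, 30, 40, 70), 1),
                                   decay_rate = 0.15),
        oscillating = {
          period <- sample(c(80, 120), 1)
          archetype_spec("oscillating", dirn, amp, onset_min = period / 4,
                         decay_rate = 0.003, period_min = period)
        }
      )
      specs[[g]] <- sp
    }
    for (g in setdiff(free_idx, free_nonflat)) {
      specs[[g]] <- archetype_spec("flat", "up", amplitude = 0)
    }

    # --- noiseless profiles and ground-truth first-DE times -----------
    profiles <- t(vapply(specs, archetype_profile, numeric(length(grid)),
                         t = grid))
    dimnames(profiles) <- list(gene_ids, as.character(grid))
    thr <- log2(fc_threshold)
    fdeg_true <- apply(profiles, 1, function(p) {
      ok <- which(abs(p) >= thr & grid > 0)
      if (length(ok) == 0) NA_real_ else grid[min(ok)]
    })

    # --- sample layout -------------------------------------------------
    samples <- tidyr::expand_grid(
      group = c("treatment", "control"),
      time_min = grid,
      replicate = seq_len(n_reps)
    )
    samples$sample_id <- sprintf("%s_t%g_r%d",
                                 ifelse(samples$group == "treatment", "Y", "M"),
                                 samples$time_min, samples$replicate)
    n_samp <- nrow(samples)
    size_fac <- runif(n_samp, libsize_range[1], libsize_range[2])

    # --- module latent factors ----------------------------------------
    mods <- names(module_sizes)
    latent <- matrix(0, n_samp, length(mods),
                     dimnames = list(samples$sample_id, mods))
    if (length(mods) > 0) {
      latent[] <- rnorm(n_samp * length(mods), sd = latent_sd)
    }

    # --- counts --------------------------------------------------------
    mu0 <- exp(runif(n_genes, log(baseline_mean_range[1]),
                     log(baseline_mean_range[2])))
    treat <- samples$group == "treatment"
    t_of_sample <- match(samples$time_min, grid)
    signal <- profiles[, t_of_sample, drop = FALSE]
    signal[, !treat] <- 0
    module_signal <- matrix(0, n_samp, length(mods),
                            dimnames = list(samples$sample_id, mods))
    if (length(mods) > 0) {
      resid_load <- sqrt(1 - latent_loading^2)
      for (m in seq_along(mods)) {
        gsel <- which(module == mods[m])
        eps <- matrix(rnorm(length(gsel) * n_samp, sd = latent_sd),
                      length(gsel), n_samp)
        signal[gsel, ] <- signal[gsel, ] +
          latent_loading * matrix(latent[, m], length(gsel), n_samp, byrow = TRUE) +
          resid_load * eps
        module_signal[, m] <- ifelse(treat,
                                     archetype_profile(module_templates[[m]],
                                                       samples$time_min), 0) +
          latent_loading * latent[, m]
      }
    }
    mu <- mu0 * 2^signal * matrix(size_fac, n_genes, n_samp, byrow = TRUE)
    counts <- matrix(rnbinom(n_genes * n_samp, mu = mu, size = 1 / nb_dispersion),
                     n_genes, n_samp,
                     dimnames = list(gene_ids, samples$sample_id))

    # --- TF families ---------------------------------------------------
    families <- c("bHLH", "ERF", "WRKY", "MYB", "NAC", "Dof", "C2H2", "bZIP")
    kind_v <- vapply(specs, `[[`, character(1), "kind")
    dirn_v <- vapply(specs, `[[`, character(1), "direction")
    cluster <- ifelse(kind_v == "flat", "flat", paste(kind_v, dirn_v, sep = "_"))
    tf_family <- ifelse(runif(n_genes) < tf_fraction,
                        sample(families, n_genes, replace = TRUE),
                        NA_character_)
    if (!is.null(tf_bias_cluster)) {
      biased <- cluster == tf_bias_cluster & runif(n_genes) < tf_bias_prob
      tf_family[biased] <- tf_bias_family
    }

    truth_genes <- tibble(
      gene_id = gene_ids,
      archetype = kind_v,
      direction = ifelse(kind_v == "flat", NA_character_, dirn_v),
      amplitude = vapply(specs, `[[`, numeric(1), "amplitude"),
      onset_min = vapply(specs, `[[`, numeric(1), "onset_min"),
      peak_min = vapply(specs, `[[`, numeric(1), "peak_min"),
      fdeg_time = unname(fdeg_true),
      cluster = cluster,
      module = module,
      tf_family = tf_family,
      baseline_mean = mu0
    )
    truth <- structure(list(
      genes = truth_genes,
      profiles = profiles,
      module_signal = module_signal,
      module_templates = module_templates,
      params = list(grid = grid, n_reps = n_reps,
                    nb_dispersion = nb_dispersion,
                    fc_threshold = fc_threshold,
                    latent_loading = latent_loading,
                    latent_sd = latent_sd,
                    size_factors = setNames(size_fac, samples$sample_id),
                    seed = seed)
    ), class = "wound_truth")

    wound_experiment(counts,
                     samples[, c("sample_id", "group", "time_min", "replicate")],
                     genes = tibble(gene_id = gene_ids, tf_family = tf_family),
                     truth = truth)
  })
}

#' @export
print.wound_truth <- function(x, ...) {
  cat(sprintf("<wound_truth> %d genes, %d non-flat, modules: %s\n",
              nrow(x$genes), sum(x$genes$archetype != "flat"),
              paste(colnames(x$module_signal), collapse = ", ")))
  invisible(x)
}

#' Simulate promoter sequences with planted motifs
#'
#' Every gene receives one uniform-random upstream sequence of
#' `window` nucleotides. Genes of a cluster named in `consensus` have that
#' cluster's consensus planted verbatim at a random offset with probability
#' `plant_prob`; all other genes receive a plant at `background_prob`.
#'
#' @param gene_clusters named character vector: gene id -> cluster label.
#' @param consensus named character vector: cluster label -> consensus
#'   sequence over ACGT.
#' @param window promoter length in bp.
#' @param plant_prob,background_prob planting probabilities.
#' @param seed integer seed.
#' @return Named character vector of sequences.
#' @export
simulate_promoters <- function(gene_clusters, consensus, window = 500,
                               plant_prob = 0.8, background_prob = 0.1,
                               seed = 1L) {
  bad <- nchar(consensus) > window
  if (any(bad)) {
    abort(paste0("Consensus longer than the promoter window: ",
                 paste(names(consensus)[bad], collapse = ", ")))
  }
  if (length(consensus) > 0 &&
      !all(grepl("^[ACGT]+$", consensus))) {
    abort("Consensus sequences must be over the alphabet ACGT.")
  }
  with_seed(seed, {
    alphabet <- c("A", "C", "G", "T")
    out <- vapply(names(gene_clusters), function(g) {
      s <- sample(alphabet, window, replace = TRUE)
      cl <- gene_clusters[[g]]
      for (target in names(consensus)) {
        p <- if (identical(cl, target)) plant_prob else background_prob
        if (runif(1) < p) {
          motif <- strsplit(consensus[[target]], "")[[1]]
          off <- sample.int(window - length(motif) + 1, 1)
          s[off:(off + length(motif) - 1)] <- motif
        }
      }
      paste(s, collapse = "")
    }, character(1))
    setNames(out, names(gene_clusters))
  })
}

#' Build a PWM from a consensus sequence
#'
#' The consensus base carries probability `1 - 3 * leak` per position; each
#' other base carries `leak`.
#'
#' @param consensus string over ACGT.
#' @param name motif name.
#' @param leak per-position probability of each non-consensus base.
#' @return A `wound_pwm`.
#' @export
consensus_pwm <- function(consensus, name = consensus, leak = 0.02) {
  bases <- strsplit(toupper(consensus), "")[[1]]
  stopifnot(all(bases %in% c("A", "C", "G", "T")), leak >= 0, leak < 1 / 3)
  m <- matrix(leak, 4, length(bases),
              dimnames = list(c("A", "C", "G", "T"), NULL))
  for (j in seq_along(bases)) m[bases[j], j] <- 1 - 3 * leak
  new_pwm(m, name = name)
}

default_volatile_patterns <- function() {
  c(indole = "delayed_rise", nerolidol = "delayed_rise",
    ocimene = "delayed_rise", farnesene = "delayed_rise",
    hexanal = "early_decay", `Z3-hexen-1-ol` = "early_decay",
    `Z3-hexenal` = "early_decay", heptanol = "early_decay",
    `hexenyl-acetate` = "constant_after", `benzyl-acetate` = "constant_after")
}

#' Simulate volatile (trait) trajectories
#'
#' Emulates the three accumulation patterns seen after wounding:
#' `constant_after` (jumps at wounding, then level), `delayed_rise`
#' (flat, then accumulates from 40 min on) and `early_decay` (abundant,
#' then declines from 40 min on). Noise is multiplicative log-normal with
#' coefficient of variation `noise_cv`; `noise_cv = 0` returns the exact
#' pattern shapes.
#'
#' @param grid time points in minutes.
#' @param patterns named character vector metabolite -> pattern.
#' @param noise_cv multiplicative noise CV.
#' @param change_min minute at which delayed/decaying patterns change.
#' @param seed integer seed.
#' @return Long tibble (metabolite, time_min, value, pattern), peak-area
#'   scale.
#' @export
simulate_volatiles <- function(grid = default_grid(),
                               patterns = default_volatile_patterns(),
                               noise_cv = 0.1, change_min = 40, seed = 1L) {
  stopifnot(all(patterns %in% c("constant_after", "delayed_rise", "early_decay")))
  grid <- sort(unique(grid))
  shape <- function(pat) {
    switch(pat,
      constant_after = ifelse(grid > 0, 5000, 200),
      delayed_rise = ifelse(grid <= change_min, 400,
                            400 * (1 + 8 * (grid - change_min) /
                                     max(max(grid) - change_min, 1))),
      early_decay = ifelse(grid <= change_min, 5000,
                           5000 * exp(-0.012 * (grid - change_min)))
    )
  }
  with_seed(seed, {
    purrr::map_dfr(names(patterns), function(met) {
      base <- shape(patterns[[met]])
      noisy <- if (noise_cv > 0) {
        sdlog <- sqrt(log(1 + noise_cv^2))
        base * exp(rnorm(length(base), -sdlog^2 / 2, sdlog))
      } else base
      tibble(metabolite = met, time_min = grid, value = noisy,
             pattern = patterns[[met]])
    })
  })
}

#' Simulate GO/KEGG-like term annotation as gene sets
#'
#' Plants one term per ground-truth cluster (covering `enrich_frac` of the
#' cluster plus random background genes) and adds `n_random` random terms,
#' so term overrepresentation has known positives.
#'
#' @param truth a `wound_truth`.
#' @param enrich_frac fraction of each cluster covered by its planted term.
#' @param background_frac fraction of other genes included in planted terms.
#' @param n_random number of unenriched random terms.
#' @param seed integer seed.
#' @return Named list of gene-id vectors (a GMT-shaped annotation map).
#' @export
simulate_annotation <- function(truth, enrich_frac = 0.7,
                                background_frac = 0.02, n_random = 20,
                                seed = 1L) {
  g <- truth$genes
  with_seed(seed, {
    sets <- list()
    for (cl in setdiff(unique(g$cluster), "flat")) {
      members <- g$gene_id[g$cluster == cl]
      others <- g$gene_id[g$cluster != cl]
      sets[[paste0("TERM_", cl)]] <- unique(c(
        sample(members, round(enrich_frac * length(members))),
        sample(others, round(background_frac * length(others)))
      ))
    }
    for (i in seq_len(n_random)) {
      sets[[sprintf("TERM_rand%02d", i)]] <-
        sample(g$gene_id, max(10, round(0.03 * nrow(g))))
    }
    sets
  })
}
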