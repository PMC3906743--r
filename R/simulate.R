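#' Configure the synthetic-data generator
#'
#' One configuration object drives every generator in the package. Defaults
#' emulate the transfection study design the pipeline was built around: four
#' treatment groups (two controls, two transfected variants) of three pooled
#' arrays each, roughly 18k detectable probes on a platform where about 10%
#' of probes never rise above background, a small fraction of planted
#' differential-expression effects, and an abundant 12-probe panel shifted
#' 1.1- to 1.4-fold.
#'
#' @param n_probes Number of probes on the simulated platform.
#' @param groups Named integer vector: samples per treatment group. The
#'   first group is the baseline; `de_group` names the group receiving
#'   planted effects.
#' @param de_group Group in which planted DE effects appear (default: the
#'   last group).
#' @param de_fraction Fraction of probes planted as DE, in `[0, 1]`.
#' @param de_effect_log2 Absolute log2 shift of each planted probe (signs
#'   are drawn at random).
#' @param abundance_tiers Data frame with columns `mean` and `sd`: log2
#'   abundance tiers probes are assigned to uniformly at random.
#' @param noise_fraction Fraction of probes that are pure noise (uniform
#'   detection p-values, no signal above background).
#' @param panel_size Number of abundant panel probes (the mito-panel
#'   analogue); 0 disables the panel.
#' @param panel_effect_range_log2 Length-2 vector: planted panel effects are
#'   drawn uniformly in this log2 range (default `log2(c(1.1, 1.4))`).
#' @param module_sizes Integer vector of co-expression module sizes.
#' @param regulator_r Target correlation between each module's regulator and
#'   the module members, in `[0, 1)`.
#' @param delta_r Wiring change of the planted differential regulator in
#'   two-condition simulations.
#' @param noise_sd Residual log2 noise sd.
#' @param qpcr Named list for the qPCR generator: `treatments`, `primers`
#'   (first entry is the reference primer), `fold` (true fold change of each
#'   non-reference primer in each non-control treatment), `n_samples` per
#'   treatment, `n_rep` technical replicates, `rep_sd` cycle noise.
#' @param seed Integer seed; identical configurations give identical output.
#'
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_probes = 20000L,
                       groups = c(control_a = 3L, control_b = 3L,
                                  variant1 = 3L, variant3 = 3L),
                       de_group = NULL,
                       de_fraction = 0.05,
                       de_effect_log2 = 1.0,
                       abundance_tiers = data.frame(
                         mean = c(8, 11, 14), sd = c(1.2, 1.2, 0.8)),
                       noise_fraction = 0.1,
                       panel_size = 12L,
                       panel_effect_range_log2 = log2(c(1.1, 1.4)),
                       module_sizes = c(16L, 16L),
                       regulator_r = 0.9,
                       delta_r = 0.8,
                       noise_sd = 0.25,
                       qpcr = list(
                         treatments = c("control", "variant3"),
                         primers = c("actb", "all_species"),
                         fold = 30,
                         n_samples = 3L, n_rep = 3L, rep_sd = 0.1),
                       seed = 1L) {
  if (n_probes < 1L || any(groups < 1L)) {
    abort("dimensions must be positive")
  }
  if (is.null(names(groups)) || anyDuplicated(names(groups))) {
    abort("`groups` must be uniquely named")
  }
  if (de_fraction < 0 || de_fraction > 1 ||
      noise_fraction < 0 || noise_fraction > 1) {
    abort("fractions must lie in [0, 1]")
  }
  if (is.null(de_group)) de_group <- names(groups)[length(groups)]
  if (!de_group %in% names(groups)) abort("`de_group` must be a group name")
  if (any(abundance_tiers$sd <= 0) || noise_sd <= 0) {
    abort("standard deviations must be positive")
  }
  if (regulator_r < 0 || regulator_r >= 1) {
    abort("`regulator_r` must lie in [0, 1)")
  }
  if (panel_size > 0 && diff(range(panel_effect_range_log2)) < 0) {
    abort("`panel_effect_range_log2` must be (low, high)")
  }
  if (any(unlist(qpcr$fold) <= 0)) abort("qPCR fold changes must be positive")
  structure(
    list(n_probes = as.integer(n_probes), groups = groups,
         de_group = de_group, de_fraction = de_fraction,
         de_effect_log2 = de_effect_log2, abundance_tiers = abundance_tiers,
         noise_fraction = noise_fraction, panel_size = as.integer(panel_size),
         panel_effect_range_log2 = panel_effect_range_log2,
         module_sizes = as.integer(module_sizes), regulator_r = regulator_r,
         delta_r = delta_r, noise_sd = noise_sd, qpcr = qpcr,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

probe_ids <- function(n) sprintf("P%05d", seq_len(n))

#' Simulate a transfection-style expression experiment
#'
#' Generates a raw-scale probe x sample matrix with per-cell detection
#' p-values, sample metadata, and a truth table of planted effects. Signals
#' are Gaussian on the log2 scale around tier means (the raw values written
#' out are `2^signal`, so the pipeline's log2 step recovers them exactly).
#' A `de_fraction` of probes is shifted by `de_effect_log2` (random sign) in
#' `de_group`; `panel_size` probes from the most abundant tier get modest
#' positive shifts drawn from `panel_effect_range_log2`. Expressed probes
#' receive Beta(0.1, 10)-skewed detection p-values, noise probes Uniform(0,1)
#' signals-at-background and p-values.
#'
#' @param config A [sim_config()].
#' @return A list with elements `expr` (an [expr_matrix()], raw scale) and
#'   `truth` (a tibble: `probe_id`, `de_flag`, `effect_log2`, `module`,
#'   `regulator`, `panel`).
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_local_seed(config$seed, {
    n <- config$n_probes
    ids <- probe_ids(n)
    samples <- rep(names(config$groups), times = config$groups)
    sample_id <- paste0(samples, "_", unlist(lapply(config$groups, seq_len)))
    n_s <- length(sample_id)

    noise <- runif(n) < config$noise_fraction
    tier <- sample.int(nrow(config$abundance_tiers), n, replace = TRUE)
    base <- rnorm(n, config$abundance_tiers$mean[tier],
                  config$abundance_tiers$sd[tier])

    expressed <- which(!noise)
    de_flag <- rep(FALSE, n)
    effect <- rep(0, n)
    n_de <- round(config$de_fraction * length(expressed))
    de_idx <- if (n_de > 0) sample(expressed, n_de) else integer(0L)
    de_flag[de_idx] <- TRUE
    effect[de_idx] <- config$de_effect_log2 *
      sample(c(-1, 1), n_de, replace = TRUE)

    panel <- rep(FALSE, n)
    if (config$panel_size > 0L) {
      top_tier <- which.max(config$abundance_tiers$mean)
      pool <- setdiff(which(!noise & tier == top_tier), de_idx)
      p_idx <- sample(pool, min(config$panel_size, length(pool)))
      panel[p_idx] <- TRUE
      de_flag[p_idx] <- TRUE
      effect[p_idx] <- runif(length(p_idx),
                             config$panel_effect_range_log2[1L],
                             config$panel_effect_range_log2[2L])
    }

    log2_signal <- matrix(rnorm(n * n_s, mean = base, sd = config$noise_sd),
                          nrow = n, ncol = n_s)
    in_de_group <- samples == config$de_group
    log2_signal[, in_de_group] <- log2_signal[, in_de_group] + effect
    # noise probes sit at background regardless of tier
    log2_signal[noise, ] <- rnorm(sum(noise) * n_s, mean = 4, sd = 0.5)

    detp <- matrix(rbeta(n * n_s, 0.1, 10), nrow = n, ncol = n_s)
    detp[noise, ] <- runif(sum(noise) * n_s)

    values <- 2^log2_signal
    dimnames(values) <- list(ids, sample_id)
    meta <- tibble(sample_id = sample_id, group = samples)
    truth <- tibble(
      probe_id = ids, de_flag = de_flag, effect_log2 = effect,
      module = NA_character_, regulator = FALSE, panel = panel
    )
    list(expr = expr_matrix(values, meta, detection_p = detp, scale = "raw"),
         truth = truth)
  })
}

# loading of module members on their latent factor; members correlate with
# the factor at member_cor, so a regulator loaded at r / member_cor shows
# mean |r| ~ r to the module
member_cor <- 0.97

#' Simulate modular co-expression with an attached regulator
#'
#' Each module shares one latent factor per sample; members are the factor
#' plus independent Gaussian noise (correlating with it at ~0.97), and one
#' designated regulator per module is loaded so that its expected
#' correlation to the members equals `regulator_r`. Probes outside modules
#' are independent noise. Output is standardized-scale, ready for
#' [correlation_matrix()].
#'
#' @param config A [sim_config()]; `groups` only sets the total sample
#'   count here.
#' @return A list with `expr` (an [expr_matrix()], standardized scale) and
#'   `truth` (tibble with module labels and regulator flags).
#' @export
simulate_coexpression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (sum(config$module_sizes) > config$n_probes) {
    abort("module sizes must sum to at most `n_probes`")
  }
  if (config$regulator_r > member_cor) {
    abort(sprintf("`regulator_r` must be <= %.2f under this generative model",
                  member_cor))
  }
  with_local_seed(config$seed + 1L, {
    n <- config$n_probes
    n_s <- sum(config$groups)
    ids <- probe_ids(n)
    sample_id <- sprintf("S%03d", seq_len(n_s))
    x <- matrix(rnorm(n * n_s), nrow = n, ncol = n_s,
                dimnames = list(ids, sample_id))
    module <- rep(NA_character_, n)
    regulator <- rep(FALSE, n)
    pos <- 1L
    member_noise_sd <- sqrt(1 / member_cor^2 - 1)
    for (k in seq_along(config$module_sizes)) {
      size <- config$module_sizes[k]
      f <- rnorm(n_s)
      members <- pos:(pos + size - 1L)
      pos <- pos + size
      lab <- sprintf("M%d", k)
      for (i in members) {
        x[i, ] <- f + rnorm(n_s, sd = member_noise_sd)
        module[i] <- lab
      }
      # first member of each module is its regulator, re-generated with the
      # configured loading on the shared factor
      reg <- members[1L]
      rho <- config$regulator_r / member_cor
      x[reg, ] <- rho * f + sqrt(1 - rho^2) * rnorm(n_s)
      regulator[reg] <- TRUE
    }
    meta <- tibble(sample_id = sample_id, group = "all")
    truth <- tibble(probe_id = ids, de_flag = FALSE, effect_log2 = 0,
                    module = module, regulator = regulator, panel = FALSE)
    list(expr = expr_matrix(x, meta, scale = "standardized"), truth = truth)
  })
}

#' Simulate a two-condition experiment with one rewired regulator
#'
#' Builds paired condition matrices over the same genes: a target set shares
#' a latent factor in both conditions; several candidate regulators load on
#' that factor, and exactly one (the planted regulator) changes its loading
#' by `delta_r` between conditions A and B while the others keep theirs.
#' The truth table records each regulator's signed correlation change
#' (`effect_log2` column reused as `delta_r_true = r_A - r_B`), so the true
#' differential-wiring score `sum((r_A - r_B)^2)` is recoverable without
#' re-running the generator.
#'
#' @param config A [sim_config()]; the first two groups give the two
#'   condition sample counts (each must be at least 10), `module_sizes[1]`
#'   the target-set size, and `length(module_sizes)` must leave room for at
#'   least 2 regulators (`n_probes >= targets + 2`).
#' @return A list with `expr_a`, `expr_b` (standardized [expr_matrix()]s)
#'   and `truth`.
#' @export
simulate_two_condition <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n_a <- config$groups[[1L]]
  n_b <- config$groups[[2L]]
  if (n_a < 10L || n_b < 10L) abort("each condition needs >= 10 samples")
  n_targets <- config$module_sizes[1L]
  n_reg <- config$n_probes - n_targets
  if (n_reg < 2L) abort("need at least 2 regulators")
  with_local_seed(config$seed + 2L, {
    gen_cond <- function(n_s, loadings, prefix) {
      f <- rnorm(n_s)
      member_noise_sd <- sqrt(1 / member_cor^2 - 1)
      tgt <- t(vapply(seq_len(n_targets),
                      function(i) f + rnorm(n_s, sd = member_noise_sd),
                      numeric(n_s)))
      reg <- t(vapply(loadings, function(rho) {
        rho * f + sqrt(1 - rho^2) * rnorm(n_s)
      }, numeric(n_s)))
      x <- rbind(tgt, reg)
      dimnames(x) <- list(c(sprintf("T%03d", seq_len(n_targets)),
                            sprintf("R%03d", seq_len(n_reg))),
                          sprintf("%s%03d", prefix, seq_len(n_s)))
      x
    }
    base_load <- rep(0.5, n_reg)
    load_a <- base_load
    load_a[1L] <- min(0.9, 0.1 + config$delta_r)
    load_b <- base_load
    load_b[1L] <- load_a[1L] - config$delta_r
    xa <- gen_cond(n_a, load_a, "A")
    xb <- gen_cond(n_b, load_b, "B")
    meta_a <- tibble(sample_id = colnames(xa), group = "A")
    meta_b <- tibble(sample_id = colnames(xb), group = "B")
    delta_true <- c(rep(0, n_targets), (load_a - load_b) * member_cor)
    truth <- tibble(
      probe_id = rownames(xa),
      de_flag = c(rep(TRUE, n_targets), rep(FALSE, n_reg)),
      effect_log2 = delta_true,
      module = c(rep("targets", n_targets), rep(NA_character_, n_reg)),
      regulator = c(rep(FALSE, n_targets), rep(TRUE, n_reg)),
      panel = FALSE
    )
    list(expr_a = expr_matrix(xa, meta_a, scale = "standardized"),
         expr_b = expr_matrix(xb, meta_b, scale = "standardized"),
         truth = truth)
  })
}

#' Simulate a triplicate qPCR Ct table
#'
#' Generates Ct observations per (sample, primer, replicate) with a flat
#' reference primer and target primers whose true fold change in each
#' non-control treatment is encoded as a `-log2(fold)` Ct shift. Each sample
#' carries a random additive offset shared across its primers (pipetting /
#' cDNA input variation) that cancels in the delta-delta-Ct contrast.
#'
#' @param config A [sim_config()]; see the `qpcr` field.
#' @return A tibble with columns `sample_id`, `primer`, `treatment`,
#'   `replicate`, `ct`, `censored`.
#' @export
simulate_qpcr <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  q <- config$qpcr
  if (length(q$treatments) < 2L || length(q$primers) < 2L) {
    abort("need >= 2 treatments and >= 2 primers (first primer = reference)")
  }
  if (any(unlist(q$fold) <= 0)) abort("fold changes must be positive")
  with_local_seed(config$seed + 3L, {
    ref <- q$primers[1L]
    targets <- q$primers[-1L]
    fold <- q$fold
    if (length(fold) == 1L) {
      fold <- rep(fold, length(targets))
    }
    base_ct <- setNames(c(23, runif(length(targets), 24, 27)), q$primers)
    grid <- tidyr::expand_grid(
      treatment = q$treatments,
      sample = seq_len(q$n_samples),
      primer = q$primers,
      replicate = seq_len(q$n_rep)
    )
    grid$sample_id <- paste0(grid$treatment, "_s", grid$sample)
    offs <- rnorm(length(unique(grid$sample_id)), sd = 0.2)
    names(offs) <- unique(grid$sample_id)
    shift <- rep(0, nrow(grid))
    for (i in seq_along(targets)) {
      in_trt <- grid$primer == targets[i] &
        grid$treatment != q$treatments[1L]
      shift[in_trt] <- -log2(fold[i])
    }
    ct <- base_ct[grid$primer] + offs[grid$sample_id] + shift +
      rnorm(nrow(grid), sd = q$rep_sd)
    tibble(
      sample_id = grid$sample_id, primer = grid$primer,
      treatment = grid$treatment, replicate = grid$replicate,
      ct = as.numeric(ct), censored = FALSE
    )
  })
}
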