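test_that("generators are deterministic given an identical configuration", {
  cfg <- sim_config(n_probes = 200, seed = 11)
  a <- simulate_expression(cfg)
  b <- simulate_expression(cfg)
  expect_identical(a$expr$values, b$expr$values)
  expect_identical(a$expr$detection_p, b$expr$detection_p)
  expect_identical(a$truth, b$truth)

  cfg2 <- sim_config(n_probes = 40, groups = c(all = 30), module_sizes = 10,
                     seed = 11)
  expect_identical(simulate_coexpression(cfg2)$expr$values,
                   simulate_coexpression(cfg2)$expr$values)
  expect_identical(simulate_qpcr(cfg), simulate_qpcr(cfg))
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(n_probes = 0), "positive")
  expect_error(sim_config(de_fraction = 1.5), "fractions")
  expect_error(sim_config(regulator_r = 1), "regulator_r")
  expect_error(sim_config(noise_sd = -1), "positive")
  expect_error(
    simulate_coexpression(sim_config(n_probes = 10, module_sizes = c(8, 8),
                                     groups = c(all = 20))),
    "sum")
  expect_error(sim_config(qpcr = list(treatments = c("a", "b"),
                                      primers = c("r", "t"), fold = -2,
                                      n_samples = 3, n_rep = 3,
                                      rep_sd = 0.1)),
               "positive")
})

test_that("no planted effect means no DE truth and near-zero group differences", {
  cfg <- sim_config(n_probes = 300, de_fraction = 0, panel_size = 0,
                    groups = c(control = 50, treated = 50), seed = 3)
  sim <- simulate_expression(cfg)
  expect_true(all(!sim$truth$de_flag))
  expect_true(all(sim$truth$effect_log2 == 0))
  m <- log2_transform(sim$expr)
  ctr <- de_scores(m, "treated", "control")
  expressed <- rowSums(sim$expr$detection_p < 0.01) >= 1
  expect_lt(max(abs(ctr$de[expressed])), 0.3)
  expect_lt(abs(mean(ctr$de[expressed])), 0.02)
})

test_that("planted log2 effects are recovered by direct averaging at large n", {
  cfg <- sim_config(n_probes = 400, de_fraction = 0.1, de_effect_log2 = 1.0,
                    panel_size = 0, groups = c(control = 200, treated = 200),
                    seed = 5)
  sim <- simulate_expression(cfg)
  ctr <- de_scores(log2_transform(sim$expr), "treated", "control")
  planted <- sim$truth$de_flag
  est <- ctr$de[planted] * sign(sim$truth$effect_log2[planted])
  expect_gt(sum(planted), 20)
  expect_lt(abs(mean(est) - 1.0), 0.05)
})

test_that("panel probes come back at 1.1-1.4-fold up to sampling noise", {
  cfg <- sim_config(n_probes = 400, de_fraction = 0, panel_size = 12,
                    groups = c(control = 200, treated = 200), seed = 6)
  sim <- simulate_expression(cfg)
  ctr <- de_scores(log2_transform(sim$expr), "treated", "control")
  panel <- ctr[sim$truth$panel, ]
  expect_identical(nrow(panel), 12L)
  expect_true(all(panel$fold > 1.05 & panel$fold < 1.45))
  expect_true(all(sim$truth$effect_log2[sim$truth$panel] >= log2(1.1)))
  expect_true(all(sim$truth$effect_log2[sim$truth$panel] <= log2(1.4)))
})

test_that("module members share a factor and the regulator tracks it at the configured r", {
  cfg <- sim_config(n_probes = 60, groups = c(all = 60), module_sizes = 16,
                    regulator_r = 0.9, seed = 8)
  co <- simulate_coexpression(cfg)
  r <- cor(t(co$expr$values))
  reg <- which(co$truth$regulator)
  members <- which(!is.na(co$truth$module) & !co$truth$regulator)
  outside <- which(is.na(co$truth$module))
  expect_gt(mean(abs(r[reg, members])), 0.8)
  expect_lt(mean(abs(r[reg, members])), 0.95)

  # no signal: a regulator at r = 0 looks like any non-member
  cfg0 <- sim_config(n_probes = 60, groups = c(all = 60), module_sizes = 16,
                     regulator_r = 0, seed = 8)
  co0 <- simulate_coexpression(cfg0)
  r0 <- cor(t(co0$expr$values))
  reg0 <- which(co0$truth$regulator)
  mem0 <- which(!is.na(co0$truth$module) & !co0$truth$regulator)
  out0 <- which(is.na(co0$truth$module))[1L]
  expect_lt(abs(mean(abs(r0[reg0, mem0])) - mean(abs(r0[out0, mem0]))), 0.1)
})

test_that("two disjoint modules are tighter within than between", {
  cfg <- sim_config(n_probes = 40, groups = c(all = 80),
                    module_sizes = c(12, 12), seed = 9)
  co <- simulate_coexpression(cfg)
  r <- abs(cor(t(co$expr$values)))
  m1 <- which(co$truth$module %in% "M1")
  m2 <- which(co$truth$module %in% "M2")
  within <- mean(c(r[m1, m1][upper.tri(r[m1, m1])],
                   r[m2, m2][upper.tri(r[m2, m2])]))
  between <- mean(r[m1, m2])
  expect_gt(within, between)
})

test_that("two-condition truth encodes the planted wiring change and its sign", {
  cfg <- sim_config(n_probes = 30, groups = c(A = 30, B = 30),
                    module_sizes = 20, delta_r = 0.8, seed = 10)
  tc <- simulate_two_condition(cfg)
  regs <- tc$truth[tc$truth$regulator, ]
  # planted regulator carries the largest true sum of squared wiring change
  true_score <- regs$effect_log2^2
  expect_identical(which.max(true_score), 1L)
  expect_true(all(true_score[-1L] == 0))

  # null contrast: same generative parameters in both conditions
  tc0 <- simulate_two_condition(
    sim_config(n_probes = 30, groups = c(A = 30, B = 30), module_sizes = 20,
               delta_r = 0, seed = 10))
  expect_true(all(tc0$truth$effect_log2[tc0$truth$regulator] == 0))

  # measured wiring change matches the truth in sign and rough size,
  # and negates exactly under condition swap
  des <- tc$truth$probe_id[tc$truth$de_flag]
  d_ab <- mean(cor(t(tc$expr_a$values["R001", , drop = FALSE]),
                   t(tc$expr_a$values[des, , drop = FALSE])) -
                 cor(t(tc$expr_b$values["R001", , drop = FALSE]),
                     t(tc$expr_b$values[des, , drop = FALSE])))
  expect_lt(abs(d_ab - regs$effect_log2[1L]), 0.2)
  d_ba <- mean(cor(t(tc$expr_b$values["R001", , drop = FALSE]),
                   t(tc$expr_b$values[des, , drop = FALSE])) -
                 cor(t(tc$expr_a$values["R001", , drop = FALSE]),
                     t(tc$expr_a$values[des, , drop = FALSE])))
  expect_equal(d_ba, -d_ab)
})

test_that("qPCR generator encodes fold changes that delta-delta-Ct recovers", {
  base <- sim_config(seed = 21,
                     qpcr = list(treatments = c("control", "treated"),
                                 primers = c("ref", "tgt"), fold = 1,
                                 n_samples = 3L, n_rep = 3L, rep_sd = 0.1))
  ct <- simulate_qpcr(base)
  f1 <- ddct_fold(fit_ct_anova(ct), "tgt", "ref", "treated", "control")
  expect_lt(abs(f1 - 1), 0.25)

  # a per-sample additive shift cancels exactly in the contrast
  shifted <- ct
  one <- shifted$sample_id == shifted$sample_id[1L]
  shifted$ct[one] <- shifted$ct[one] + 2.0
  f1s <- ddct_fold(fit_ct_anova(shifted), "tgt", "ref", "treated", "control")
  expect_equal(f1s, f1, tolerance = 1e-10)
})

test_that("a 30-fold planted change is recovered within 20% in >=95% of seeded runs", {
  hits <- vapply(1:100, function(s) {
    cfg <- sim_config(seed = s,
                      qpcr = list(treatments = c("control", "treated"),
                                  primers = c("ref", "tgt"), fold = 30,
                                  n_samples = 3L, n_rep = 3L, rep_sd = 0.1))
    f <- ddct_fold(fit_ct_anova(simulate_qpcr(cfg)),
                   "tgt", "ref", "treated", "control")
    f >= 25 && f <= 36
  }, logical(1))
  expect_gte(sum(hits), 95)
})
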