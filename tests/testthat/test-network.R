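test_that("correlation matrix matches a direct covariance/sd computation", {
  x <- withr::with_seed(3, matrix(rnorm(100), 5, 20))
  m <- make_expr(x, scale = "standardized")
  net <- correlation_matrix(m)
  expect_equal(diag(net$r), rep(1, 5), ignore_attr = TRUE)
  for (i in 1:5) {
    for (j in 1:5) {
      num <- mean((x[i, ] - mean(x[i, ])) * (x[j, ] - mean(x[j, ])))
      den <- sqrt(mean((x[i, ] - mean(x[i, ]))^2) *
                    mean((x[j, ] - mean(x[j, ]))^2))
      expect_equal(net$r[i, j], num / den, tolerance = 1e-12)
    }
  }
  # antisymmetric pair
  y <- rbind(a = x[1, ], b = -x[1, ] )
  net2 <- correlation_matrix(make_expr(y, scale = "standardized"))
  expect_equal(net2$r["a", "b"], -1)
  flat <- x
  rownames(flat) <- paste0("g", 1:5)
  flat <- rbind(flat, konst = rep(1, 20))
  expect_error(correlation_matrix(make_expr(flat, scale = "standardized")),
               "konst")
})

test_that("PCIT eliminates an exactly-explained chain edge and keeps the direct ones", {
  # x - z - y chain with r_xy = r_xz * r_yz
  r <- matrix(c(1, 0.25, 0.5,
                0.25, 1, 0.5,
                0.5, 0.5, 1), 3, 3,
              dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  net <- structure(list(genes = c("x", "y", "z"), r = r, adjacency = NULL),
                   class = "coexpr_network")
  out <- pcit_filter(net)
  expect_false(out$adjacency["x", "y"])
  expect_true(out$adjacency["x", "z"])
  expect_true(out$adjacency["y", "z"])
  # hand check of the trio tolerance for the eliminated edge
  p_xz_y <- (0.5 - 0.25 * 0.5) / sqrt((1 - 0.25^2) * (1 - 0.5^2))
  eps <- (0 + 2 * abs(p_xz_y / 0.5)) / 3
  expect_true(0.25 <= eps * 0.5)
})

test_that("vectorized PCIT equals the literal triple-loop oracle on random instances", {
  for (s in 1:10) {
    n <- withr::with_seed(s, sample(4:25, 1))
    x <- withr::with_seed(s + 100, matrix(rnorm(n * 12), n, 12))
    net <- correlation_matrix(make_expr(x, scale = "standardized"))
    out <- pcit_filter(net)
    expect_identical(unname(out$adjacency), pcit_brute(net$r))
  }
})

test_that("PCIT output is invariant under gene permutation and sparser than the raw graph", {
  co <- simulate_coexpression(sim_config(n_probes = 100,
                                         groups = c(all = 50),
                                         module_sizes = 16, seed = 23))
  net <- correlation_matrix(co$expr)
  out <- pcit_filter(net)
  n <- length(net$genes)
  expect_lt(sum(out$adjacency), n * (n - 1))
  # planted-module edges survive at high recall
  members <- which(!is.na(co$truth$module))
  mod_adj <- out$adjacency[members, members]
  expect_gte(mean(mod_adj[upper.tri(mod_adj)]), 0.9)

  perm <- withr::with_seed(7, sample(n))
  mp <- co$expr
  mp$values <- mp$values[perm, ]
  out_p <- pcit_filter(correlation_matrix(mp))
  expect_identical(out_p$adjacency[net$genes, net$genes], out$adjacency)

  expect_error(pcit_filter(net, max_genes = 10), "cap")
})

test_that("module-to-regulator scores are mean absolute correlations with fixed tie-breaks", {
  x <- withr::with_seed(41, matrix(rnorm(4 * 30), 4, 30,
                                   dimnames = list(c("g1", "g2", "g3", "tf"),
                                                   NULL)))
  colnames(x) <- sprintf("s%02d", 1:30)
  net <- correlation_matrix(make_expr(x, scale = "standardized"))
  rk <- module_to_regulator(net, c("g1", "g2", "g3"), "tf")
  hand <- mean(c(abs(net$r["tf", "g1"]), abs(net$r["tf", "g2"]),
                 abs(net$r["tf", "g3"])))
  expect_equal(rk$mean_abs_r, hand)

  # a regulator duplicating a member of a tight module scores within
  # 1/|module| of 1
  f <- withr::with_seed(43, rnorm(30))
  tight <- t(vapply(1:3, function(i) f + rnorm(30, sd = 0.02), numeric(30)))
  rownames(tight) <- c("g1", "g2", "g3")
  y <- rbind(tight, tf = tight["g1", ])
  net2 <- correlation_matrix(make_expr(y, scale = "standardized"))
  rk2 <- module_to_regulator(net2, c("g1", "g2", "g3"), "tf")
  expect_gte(rk2$mean_abs_r, 1 - 1 / 3)

  # sign-flip invariance of a module gene
  xf <- x
  xf["g2", ] <- -xf["g2", ]
  netf <- correlation_matrix(make_expr(xf, scale = "standardized"))
  expect_equal(module_to_regulator(netf, c("g1", "g2", "g3"), "tf")$mean_abs_r,
               rk$mean_abs_r)

  # deterministic lexicographic tie-break
  z <- rbind(m = x[1, ], ta = x[2, ], tb = x[2, ])
  netz <- correlation_matrix(make_expr(z, scale = "standardized"))
  rkz <- module_to_regulator(netz, "m", c("tb", "ta"))
  expect_identical(rkz$regulator, c("ta", "tb"))
  expect_identical(rkz$rank, 1:2)
  expect_error(module_to_regulator(net, "nope", "tf"), "intersect")
})

test_that("RIF sums match a spelled-out computation on a small fixture", {
  tc <- simulate_two_condition(sim_config(n_probes = 7,
                                          groups = c(A = 15, B = 15),
                                          module_sizes = 4, seed = 29))
  regs <- tc$truth$probe_id[tc$truth$regulator]
  des <- tc$truth$probe_id[tc$truth$de_flag]
  pif <- setNames(c(1.5, -0.5, 2, 0.25), des)
  out <- rif_scores(tc$expr_a, tc$expr_b, regs, des, pif = pif)
  for (g in regs) {
    r1 <- 0
    r2 <- 0
    for (j in des) {
      ra <- cor(tc$expr_a$values[g, ], tc$expr_a$values[j, ])
      rb <- cor(tc$expr_b$values[g, ], tc$expr_b$values[j, ])
      ea <- mean(tc$expr_a$values[j, ])
      eb <- mean(tc$expr_b$values[j, ])
      r1 <- r1 + pif[[j]] * (ra - rb)^2
      r2 <- r2 + (ea * ra)^2 - (eb * rb)^2
    }
    expect_equal(out$rif1[out$regulator == g], r1 / length(des))
    expect_equal(out$rif2[out$regulator == g], r2 / length(des))
  }
  expect_equal(mean(out$rif1_z), 0, tolerance = 1e-12)
  expect_equal(sd(out$rif1_z), 1, tolerance = 1e-12)
})

test_that("RIF is null on identical conditions and behaves under condition swap", {
  tc <- simulate_two_condition(sim_config(n_probes = 12,
                                          groups = c(A = 12, B = 12),
                                          module_sizes = 6, seed = 33))
  regs <- tc$truth$probe_id[tc$truth$regulator]
  des <- tc$truth$probe_id[tc$truth$de_flag]
  same <- rif_scores(tc$expr_a, tc$expr_a, regs, des)
  expect_true(all(same$rif1 == 0))
  expect_true(all(same$rif1_z == 0))

  fwd <- rif_scores(tc$expr_a, tc$expr_b, regs, des)
  rev <- rif_scores(tc$expr_b, tc$expr_a, regs, des)
  expect_equal(rev$rif1, fwd$rif1)
  expect_equal(rev$rif2, -fwd$rif2)
  expect_equal(rev$rif2_z, -fwd$rif2_z)

  # zero-variance regulator is excluded with a report
  flat <- tc$expr_a
  flat$values[regs[2], ] <- 5
  expect_warning(out <- rif_scores(flat, tc$expr_b, regs, des),
                 regs[2])
  expect_false(regs[2] %in% out$regulator)
})
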