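test_that("Friedman statistic agrees with base R and degenerates gracefully", {
  set.seed(51)
  m <- matrix(rnorm(12 * 4), 12, 4)
  mine <- friedman_with_dunn(m)
  ref <- friedman.test(m)
  expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(mine$p, ref$p.value, tolerance = 1e-12)

  # identical columns: statistic 0, p 1
  same <- matrix(rep(rnorm(5), 3), 5, 3)
  deg <- friedman_with_dunn(same)
  expect_equal(deg$statistic, 0)
  expect_equal(deg$p, 1)

  m_na <- m; m_na[1, 1] <- NA
  expect_error(friedman_with_dunn(m_na), "missing cells")
  expect_error(friedman_with_dunn(m[, 1:2]), ">= 3 stimuli")
})

test_that("exact Friedman p equals the full permutation enumeration", {
  set.seed(52)
  m <- matrix(rnorm(12), 4, 3)
  mine <- friedman_with_dunn(m, method = "exact")
  expect_equal(mine$p, brute_friedman_exact_p(m), tolerance = 1e-10)

  # and a table with ties
  m2 <- matrix(c(1, 2, 2, 3, 1, 2, 2, 2, 1, 1, 3, 2), 4, 3)
  expect_equal(friedman_with_dunn(m2, method = "exact")$p,
               brute_friedman_exact_p(m2), tolerance = 1e-10)
})

test_that("Dunn post hoc flags exactly the planted stimulus", {
  set.seed(53)
  base <- matrix(rnorm(12 * 4, sd = 1e-3), 12, 4)
  colnames(base) <- c("ctrl", "s1", "s2", "s3")
  base[, "s2"] <- base[, "s2"] + 10
  res <- friedman_with_dunn(base, control = "ctrl")
  ph <- res$posthoc
  expect_lt(ph$p_adj[ph$comparison == "s2 vs ctrl"], 0.01)
  expect_gt(min(ph$p_adj[ph$comparison != "s2 vs ctrl"]), 0.5)
  # adjusted p never below raw p
  expect_true(all(ph$p_adj >= ph$p_raw - 1e-12))
})

test_that("Kruskal-Wallis agrees with base R and its exact enumeration", {
  set.seed(54)
  g <- list(a = rnorm(8), b = rnorm(8) + 0.5, c = rnorm(8))
  mine <- kruskal_wallis_dunn(g)
  ref <- kruskal.test(g)
  expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(mine$p, ref$p.value, tolerance = 1e-12)

  tiny <- list(a = c(1.2, 5.1), b = c(2.3, 4.4), c = c(8.1, 9.5))
  expect_equal(kruskal_wallis_dunn(tiny, method = "exact")$p,
               brute_kw_exact_p(tiny), tolerance = 1e-10)
  # with ties
  tiny2 <- list(a = c(1, 2), b = c(2, 3), c = c(3, 3))
  expect_equal(kruskal_wallis_dunn(tiny2, method = "exact")$p,
               brute_kw_exact_p(tiny2), tolerance = 1e-10)

  ident <- list(a = c(1, 2, 3), b = c(1, 2, 3))
  res <- kruskal_wallis_dunn(ident)
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 1)
  expect_error(kruskal_wallis_dunn(list(a = 1, b = c(1, 2))), "n >= 2")

  # large planted shifts make every pairwise comparison significant
  shifted <- list(a = rnorm(10), b = rnorm(10) + 50, c = rnorm(10) + 100)
  expect_true(all(kruskal_wallis_dunn(shifted)$posthoc$p_adj < 0.05))
})

test_that("rank tests are invariant under monotone transforms", {
  set.seed(55)
  m <- matrix(rexp(10 * 4), 10, 4)
  expect_equal(friedman_with_dunn(m)$statistic,
               friedman_with_dunn(log(m))$statistic, tolerance = 1e-12)
  g <- list(a = runif(6), b = runif(6), c = runif(6))
  expect_equal(kruskal_wallis_dunn(g)$statistic,
               kruskal_wallis_dunn(lapply(g, exp))$statistic, tolerance = 1e-12)
})

test_that("RM-ANOVA F and GG-corrected p match an aov + direct-formula oracle", {
  set.seed(56)
  m <- matrix(rnorm(6 * 3, mean = rep(c(0, 0.5, 1), each = 6)), 6, 3)
  res <- rm_anova_gg_dunnett(m)

  # oracle route: base aov with an Error stratum
  df <- data.frame(y = as.vector(m),
                   subj = factor(rep(seq_len(6), times = 3)),
                   cond = factor(rep(seq_len(3), each = 6)))
  av <- summary(aov(y ~ cond + Error(subj / cond), data = df))
  Ftab <- av[["Error: subj:cond"]][[1]]
  expect_equal(res$statistic, Ftab["cond", "F value"], tolerance = 1e-10)

  # oracle epsilon from the covariance double-centering definition
  S <- cov(m); k <- ncol(m)
  Cc <- diag(k) - 1 / k
  A <- Cc %*% S %*% Cc
  eps_oracle <- sum(diag(A))^2 / ((k - 1) * sum(A * A))
  expect_equal(res$epsilon, eps_oracle, tolerance = 1e-12)
  expect_equal(res$p,
               pf(res$statistic, eps_oracle * (k - 1),
                  eps_oracle * (k - 1) * (nrow(m) - 1), lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("RM-ANOVA handles sphericity limits and degenerate variance", {
  # compound-symmetric (perfectly spherical) data: epsilon near 1
  set.seed(57)
  subj <- rnorm(40, sd = 2)
  m <- sapply(1:4, function(j) subj + rnorm(40))
  expect_gt(rm_anova_gg_dunnett(m)$epsilon, 0.9)

  # conditions identical up to animal offsets: F = 0, p = 1
  base <- rnorm(8)
  res2 <- rm_anova_gg_dunnett(cbind(a = base, b = base, c = base))
  expect_equal(res2$statistic, 0)
  expect_equal(res2$p, 1)

  # zero within-animal variance but real condition shifts: no valid F ratio
  m3 <- cbind(a = base, b = base + 1, c = base + 2)
  expect_error(rm_anova_gg_dunnett(m3), "degenerate within-animal variance")
})

test_that("Dunnett comparisons flag planted condition effects", {
  set.seed(58)
  m <- matrix(rnorm(12 * 4, sd = 0.3), 12, 4)
  colnames(m) <- c("solvent", "lowA", "hit", "lowB")
  m[, "hit"] <- m[, "hit"] + 3
  res <- rm_anova_gg_dunnett(m, control = "solvent")
  ph <- res$posthoc
  expect_lt(ph$p_adj[ph$comparison == "hit vs solvent"], 1e-4)
  expect_gt(min(ph$p_adj[ph$comparison != "hit vs solvent"]), 0.1)
  # adjusted p exceeds the unadjusted two-sided t p (multiplicity costs power)
  t_raw <- ph$t[ph$comparison == "lowA vs solvent"]
  p_raw <- 2 * pt(-abs(t_raw), (12 - 1) * (4 - 1))
  expect_gte(ph$p_adj[ph$comparison == "lowA vs solvent"], p_raw - 1e-6)
})
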