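test_that("design matrix applies the log transforms with fixed column order", {
  tab <- tibble::tibble(species_name = c("a_a", "b_b", "c_c"),
                        sgs = c(0, 1.72, 6.39),
                        density = c(1, 1, 1), ei = c(2, 4, 8))
  des <- pmm_design(tab, c("density", "ei"))
  expect_equal(des$y, log(tab$sgs + 1))
  expect_equal(colnames(des$X), c("(Intercept)", "log(density)", "log(ei)"))
  expect_equal(des$X[, "log(density)"], rep(0, 3))
  expect_equal(des$y[1], 0)
  tab$density[2] <- -1
  expect_error(pmm_design(tab, "density"), "rows 2")
  expect_error(pmm_design(tibble::tibble(sgs = c(1, NA)), character()),
               "rows 2")
})

test_that("the modelled feeding-trial design has 43 species and 4 columns", {
  d <- hare_seed_traits()
  modelled <- d[!is.na(d$sgs), ]
  expect_equal(nrow(modelled), 43)
  expect_false("anthriscus_sylvestris" %in% modelled$species_name)
  des <- pmm_design(modelled, c("density", "ei", "area"))
  expect_equal(dim(des$X), c(43, 4))
})

test_that("sampler matches the conjugate closed-form posterior under pinned variances", {
  set.seed(41)
  n <- 60
  X <- cbind(1, rnorm(n), rnorm(n))
  beta_true <- c(1, 0.5, -0.25)
  s2 <- 0.49
  y <- drop(X %*% beta_true) + rnorm(n, 0, sqrt(s2))
  # near-degenerate inverse-gamma prior pins sigma2_e at s2; flat beta prior
  # => beta | y ~ N((X'X)^-1 X'y, s2 (X'X)^-1)
  fit <- pmm_fit(y, X, R = NULL, iterations = 30000, burnin = 2000, thin = 5,
                 chains = 2, seed = 2, prior_shape = 1e7, prior_rate = 1e7 * s2)
  XtXi <- solve(crossprod(X))
  mean_exact <- drop(XtXi %*% crossprod(X, y))
  sd_exact <- sqrt(s2 * diag(XtXi))
  draws <- as.matrix(fit$draws[, c("(Intercept)", "x1", "x2")])
  mcse <- apply(draws, 2, sd) / sqrt(min(fit$diagnostics$ess))
  expect_true(all(abs(colMeans(draws) - mean_exact) < 3 * mcse))
  expect_equal(apply(draws, 2, sd), sd_exact, tolerance = 0.05,
               ignore_attr = TRUE)
  expect_equal(mean(fit$draws$sigma2_resid), s2, tolerance = 0.01)
})

test_that("identical seed and settings give bit-identical retained draws", {
  set.seed(43)
  n <- 30
  X <- cbind(1, rnorm(n))
  y <- rnorm(n)
  R <- vcv_to_correlation(phylo_vcv(sim_yule_tree(n, 1, seed = 5)))
  f1 <- pmm_fit(y, X, R, iterations = 2000, burnin = 500, thin = 5, seed = 9)
  f2 <- pmm_fit(y, X, R, iterations = 2000, burnin = 500, thin = 5, seed = 9)
  expect_identical(f1$draws, f2$draws)
  expect_identical(f1$dic, f2$dic)
  f3 <- pmm_fit(y, X, R, iterations = 2000, burnin = 500, thin = 5, seed = 10)
  expect_false(identical(f1$draws, f3$draws))
  # retained draw count and positivity invariants
  expect_equal(nrow(f1$draws), 2 * (2000 - 500) / 5)
  expect_true(all(f1$draws$sigma2_phylo > 0))
  expect_true(all(f1$draws$sigma2_resid > 0))
  expect_true(all(f1$draws$h2 >= 0 & f1$draws$h2 <= 1))
})

test_that("posterior summaries are invariant under joint row permutation", {
  set.seed(44)
  n <- 50
  tr <- sim_yule_tree(n, 1)
  R <- vcv_to_correlation(phylo_vcv(tr))
  X <- cbind(1, rnorm(n))
  y <- drop(X %*% c(0.5, 1)) + drop(crossprod(chol(0.5 * R), rnorm(n))) +
    rnorm(n, 0, 0.7)
  perm <- sample(n)
  f1 <- pmm_fit(y, X, R, iterations = 8000, burnin = 1000, thin = 5, seed = 3)
  f2 <- pmm_fit(y[perm], X[perm, ], R[perm, perm],
                iterations = 8000, burnin = 1000, thin = 5, seed = 3)
  t1 <- tidy(f1); t2 <- tidy(f2)
  expect_equal(t1$estimate, t2$estimate, tolerance = 0.08)
  expect_equal(f1$dic, f2$dic, tolerance = 2)
})

test_that("heritability posterior concentrates near zero without phylogenetic signal", {
  set.seed(45)
  n <- 100
  tr <- sim_yule_tree(n, 1)
  R <- vcv_to_correlation(phylo_vcv(tr))
  X <- matrix(1, n, 1)
  y <- rnorm(n)   # beta = 0, sigma2_p = 0
  fit <- pmm_fit(y, X, R, iterations = 10000, burnin = 1000, thin = 5, seed = 4)
  h2 <- pmm_heritability(fit)
  expect_lt(h2$mean, 0.15)
  expect_lte(h2$hpd_lower, h2$mean)
  expect_gte(h2$hpd_upper, h2$mean)
})

test_that("heritability is zero by construction without a phylogenetic term", {
  set.seed(46)
  fit <- pmm_fit(rnorm(20), matrix(1, 20, 1), NULL,
                 iterations = 2000, burnin = 500, thin = 5)
  h2 <- pmm_heritability(fit)
  expect_equal(h2$mean, 0)
  expect_equal(h2$hpd_lower, 0)
  expect_equal(h2$hpd_upper, 0)
})

test_that("hpd_interval returns the narrowest covering window", {
  expect_equal(hpd_interval(rep(0.5, 50)), c(lower = 0.5, upper = 0.5))
  # right-skewed sample: HPD must be narrower than the central interval
  set.seed(47)
  x <- rexp(10000)
  hpd <- hpd_interval(x, 0.9)
  cent <- quantile(x, c(0.05, 0.95))
  expect_lt(hpd[["upper"]] - hpd[["lower"]], cent[[2]] - cent[[1]])
  expect_equal(hpd[["lower"]], 0, tolerance = 0.01)
})

test_that("DIC penalizes unsupported predictors on null data", {
  set.seed(48)
  wins <- 0
  for (rep in 1:5) {
    n <- 60
    X0 <- matrix(1, n, 1)
    Xf <- cbind(1, matrix(rnorm(3 * n), n, 3))
    y <- rnorm(n)
    f0 <- pmm_fit(y, X0, NULL, iterations = 4000, burnin = 500, thin = 5,
                  chains = 1, seed = rep)
    ff <- pmm_fit(y, Xf, NULL, iterations = 4000, burnin = 500, thin = 5,
                  chains = 1, seed = rep)
    if (f0$dic <= ff$dic) wins <- wins + 1
  }
  expect_gte(wins, 3)
})

test_that("all-subsets ranking enumerates, orders, and flags competing models", {
  set.seed(49)
  n <- 60
  tab <- tibble::tibble(species_name = paste0("s", 1:n),
                        density = exp(rnorm(n)), ei = exp(rnorm(n)),
                        area = exp(rnorm(n)))
  tab$sgs <- pmax(exp(1 + log(tab$density) + rnorm(n, 0, 0.4)) - 1, 0)
  rk <- pmm_dredge(tab, c("density", "ei", "area"),
                   iterations = 3000, burnin = 500, thin = 5, chains = 1)
  expect_equal(nrow(rk), 8)
  expect_equal(rk$delta_dic[1], 0)
  expect_true(all(diff(rk$dic) >= 0))
  expect_true(rk$competing[1])
  expect_false(any(rk$failed))
  expect_match(rk$model[1], "density")
  # two predictors -> 4 models including intercept-only
  rk2 <- pmm_dredge(tab, c("density", "ei"),
                    iterations = 2000, burnin = 500, thin = 5, chains = 1)
  expect_equal(nrow(rk2), 4)
  expect_true("1" %in% rk2$model)
})

test_that("chain diagnostics report effective sizes and split-Rhat near 1", {
  set.seed(50)
  fit <- pmm_fit(rnorm(40), cbind(1, rnorm(40)), NULL,
                 iterations = 5000, burnin = 500, thin = 5, chains = 2)
  expect_true(all(fit$diagnostics$ess > 100))
  expect_true(all(fit$diagnostics$rhat < 1.1))
  g <- glance(fit)
  expect_named(g, c("n", "dic", "pd", "h2_mean", "h2_hpd_lower",
                    "h2_hpd_upper", "max_rhat", "min_ess"))
})

test_that("non positive definite correlation matrices are rejected", {
  R <- matrix(1, 5, 5)   # rank 1
  expect_error(pmm_fit(rnorm(5), matrix(1, 5, 1), R,
                       iterations = 200, burnin = 100, thin = 1),
               class = "endolink_not_pd")
  expect_error(pmm_fit(rnorm(5), matrix(1, 5, 1), NULL,
                       iterations = 100, burnin = 200, thin = 1),
               "exceed")
})
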