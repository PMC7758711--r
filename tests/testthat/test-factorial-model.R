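test_that("LS means equal cell means on a balanced saturated design", {
  # 2 treatments x 2 times, 2 noise-free obs per cell, cell values 0/0/0/1
  tab <- make_phen(c("A", "B"), c(4, 8), reps = 2, substrates = "s",
                   mu = function(tr, t, s) {
                     if (tr == "B" && t == 8) 1 else 0
                   })
  fit <- fit_factorial_model(tab)
  cm <- fit$cell_means
  expect_close(cm["A.4", "s"], 0, 1e-12)
  expect_close(cm["B.8", "s"], 1, 1e-12)
  expect_close(cm["A.8", "s"], 0, 1e-12)
  expect_close(cm["B.4", "s"], 0, 1e-12)
})

test_that("fitted + residuals reconstructs the observed matrix and residuals are orthogonal to the design", {
  tab <- make_phen(c("MC", "RP", "DP"), c(0, 4, 8), reps = 3,
                   substrates = paste0("s", 1:4),
                   mu = function(tr, t, s) 2 + 0.1 * t, sd = 0.3, seed = 42)
  fit <- fit_factorial_model(tab)
  expect_close(fit$fitted + fit$residuals, fit$Y, 1e-8)
  X <- model.matrix(~ fit$treatment * fit$time)
  expect_close(crossprod(X, fit$residuals), 0 * crossprod(X, fit$residuals),
               1e-8)
})

test_that("sequential interaction SS matches the classical balanced two-way decomposition", {
  tab <- make_phen(c("A", "B"), c(1, 2, 3), reps = 4, substrates = "s",
                   mu = function(tr, t, s) (tr == "B") * t, sd = 1,
                   seed = 7)
  fit <- fit_factorial_model(tab)
  oracle <- twoway_oracle(tab$value, tab$treatment, tab$transfer)
  ss <- setNames(fit$ss_table$SS, fit$ss_table$term)
  expect_close(ss[["treatment"]], oracle$ss1)
  expect_close(ss[["time"]], oracle$ss2)
  expect_close(ss[["treatment:time"]], oracle$ssint)
  expect_close(ss[["residual"]], oracle$sse)
})

test_that("empty design cells are rejected by name", {
  tab <- make_phen(c("A", "B"), c(1, 2), reps = 2, substrates = "s")
  tab <- tab[!(tab$treatment == "B" & tab$transfer == 2), ]
  expect_error(fit_factorial_model(tab), "empty design cell.*B.*2")
})

test_that("incomplete substrate profiles are rejected", {
  tab <- make_phen(c("A", "B"), c(1, 2), reps = 2,
                   substrates = c("s1", "s2"))
  expect_error(fit_factorial_model(tab[-1, ]), "exactly one value")
})

test_that("observed RRPP F is permutation-free and equals the classical univariate F", {
  tab <- make_phen(c("A", "B"), c(1, 2, 3), reps = 3, substrates = "s",
                   mu = function(tr, t, s) (tr == "B") * t * 0.5, sd = 0.4,
                   seed = 9)
  r1 <- rrpp_interaction_test(tab, n_permutations = 19, seed = 1)
  r2 <- rrpp_interaction_test(tab, n_permutations = 99, seed = 999)
  expect_identical(r1$observed, r2$observed)
  expect_close(r1$observed, classical_interaction_F(tab))
  expect_equal(unname(r1$df), c(2, 12))
})

test_that("multivariate RRPP F agrees with distance-based permutational MANOVA", {
  skip_if_not_installed("vegan")
  tab <- make_phen(c("A", "B", "C"), c(4, 8), reps = 4,
                   substrates = paste0("s", 1:3),
                   mu = function(tr, t, s) 1 + (tr == "C") * t * 0.05,
                   sd = 0.2, seed = 31)
  mine <- rrpp_interaction_test(tab, n_permutations = 9, seed = 1)
  pv <- pivot_phenotypes(tab)
  ad <- vegan::adonis2(pv$Y ~ treatment * factor(transfer), data = pv$meta,
                       method = "euclidean", by = "terms", permutations = 9)
  expect_close(mine$observed,
               ad["treatment:factor(transfer)", "F"], 1e-6)
})

test_that("RRPP p equals the complete-enumeration proportion for small n", {
  # n = 6: cells sized 2/2/1/1, 6! = 720 permutations, exact enumeration
  tab <- make_phen(c("A", "B"), c(1, 2), reps = 2, substrates = "s",
                   mu = function(tr, t, s) (tr == "B") * (t == 2) * 2,
                   sd = 0.5, seed = 3)
  tab <- tab[-c(3, 7), ]  # drop one replicate from two cells
  res <- suppressWarnings(
    rrpp_interaction_test(tab, n_permutations = 719, seed = 1))
  expect_true(res$exact)

  # independent oracle: enumerate permutations of reduced-model residuals,
  # refit with lm, recompute the classical interaction F
  d <- tab
  d$treatment <- factor(d$treatment); d$time <- factor(d$transfer)
  red <- lm(value ~ treatment + time, data = d)
  fitted_red <- fitted(red); resid_red <- resid(red)
  Fs <- vapply(perms_of(6), function(p) {
    d2 <- d
    d2$value <- fitted_red + resid_red[p]
    an <- anova(lm(value ~ treatment * time, data = d2))
    an["treatment:time", "F value"]
  }, numeric(1))
  F_obs <- classical_interaction_F(tab)
  p_exact <- mean(Fs >= F_obs - 1e-8 * max(1, abs(F_obs)))
  expect_close(res$p, p_exact, 1e-10)
  expect_close(res$observed, F_obs)
})

test_that("permutation p-values respect their attainable bounds", {
  tab <- make_phen(c("A", "B"), c(1, 2), reps = 3, substrates = "s",
                   mu = function(tr, t, s) (tr == "B") * (t == 2) * 10,
                   sd = 0.1, seed = 5)
  res <- rrpp_interaction_test(tab, n_permutations = 99, seed = 2)
  expect_gte(res$p, 1 / 100)
  expect_lte(res$p, 1)
})

test_that("PCA of fitted values: proportions sum to 1, rank-1 means explain everything", {
  tab <- make_phen(c("A", "B"), c(1, 2, 3), reps = 2,
                   substrates = c("s1", "s2", "s3"),
                   mu = function(tr, t, s) t * (1 + (s == "s2")),
                   sd = 0.1, seed = 8)
  fit <- fit_factorial_model(tab)
  ord <- pca_of_fitted(fit)
  expect_close(sum(ord$proportions), 1, 1e-9)
  expect_true(all(ord$proportions >= 0))
  # oracle: eigenvalues of the covariance of fitted values
  ev <- eigen(cov(fit$fitted), symmetric = TRUE)$values
  expect_close(sort(ord$eigenvalues, decreasing = TRUE)[seq_along(ev)],
               pmax(ev, 0), 1e-8)

  # rank-1 structure: means vary along a single direction
  tab1 <- make_phen(c("A", "B"), c(1, 2), reps = 2,
                    substrates = c("s1", "s2"),
                    mu = function(tr, t, s) t + (tr == "B") * 2)
  ord1 <- pca_of_fitted(fit_factorial_model(tab1))
  expect_close(ord1$proportions[1], 1, 1e-9)
})
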