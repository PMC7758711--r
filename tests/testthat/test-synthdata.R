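test_that("generators are deterministic under a fixed seed", {
  cfg <- sim_config(n_replicates_per_treatment = 3, seed = 7)
  expect_identical(simulate_phenotypes(cfg), simulate_phenotypes(cfg))
  p1 <- simulate_mutations(cfg)
  p2 <- simulate_mutations(cfg)
  expect_identical(p1$mutations, p2$mutations)
  expect_identical(simulate_community(cfg), simulate_community(cfg))
  expect_identical(simulate_growth(cfg), simulate_growth(cfg))
  # different seed changes the draws
  cfg2 <- sim_config(n_replicates_per_treatment = 3, seed = 8)
  expect_false(identical(simulate_phenotypes(cfg), simulate_phenotypes(cfg2)))
})

test_that("phenotypes equal baseline + displacement in the noise-free limit", {
  cfg <- sim_config(n_replicates_per_treatment = 2, replicate_sd = 0,
                    residual_sd = 0, seed = 1)
  phen <- simulate_phenotypes(cfg)
  for (i in sample(nrow(phen), 50)) {
    tr <- phen$treatment[i]
    ti <- match(phen$transfer[i], cfg$transfers)
    s <- phen$substrate[i]
    expect_equal(phen$value[i],
                 unname(cfg$baseline[s] + cfg$trajectory_effects[[tr]][ti, s]))
  }
})

test_that("null trajectory effects leave group means at baseline", {
  cfg <- sim_config(n_replicates_per_treatment = 100,
                    treatments = c("MC", "RP"), transfers = c(0, 4),
                    substrates = c("xylan", "lignin"),
                    replicate_sd = 0.05, residual_sd = 0.1, seed = 3)
  cfg$trajectory_effects <- lapply(cfg$trajectory_effects, function(m) m * 0)
  phen <- simulate_phenotypes(cfg)
  agg <- aggregate(value ~ treatment + substrate, phen, mean)
  # within Monte-Carlo error at n = 100 replicates x 2 transfers
  mc_se <- sqrt(0.05^2 + 0.1^2) / sqrt(200)
  expect_true(all(abs(agg$value - cfg$baseline[agg$substrate]) < 4 * mc_se))
})

test_that("phenotype noise is truncated at zero", {
  cfg <- sim_config(n_replicates_per_treatment = 20,
                    baseline = NULL, residual_sd = 5, seed = 2)
  phen <- simulate_phenotypes(cfg)
  expect_true(all(phen$value >= 0))
})

test_that("mutation counts follow the configured Poisson rate", {
  lambda <- 33 / 24
  cfg <- sim_config(n_replicates_per_treatment = c(MC = 4000, RP = 3000,
                                                   DP = 3000),
                    mutation_rate_lambda = lambda, seed = 11)
  prof <- simulate_mutations(cfg)
  n_clones <- nrow(prof$clones)
  expect_equal(n_clones, 10000)
  mean_count <- nrow(prof$mutations) / n_clones
  se <- sqrt(lambda / n_clones)
  expect_lt(abs(mean_count - lambda), 2 * se)
})

test_that("lambda = 0 gives mutation-free clones; a degenerate pool gives a shared locus", {
  cfg0 <- sim_config(n_replicates_per_treatment = 3,
                     mutation_rate_lambda = 0, seed = 5)
  prof0 <- simulate_mutations(cfg0)
  expect_equal(nrow(prof0$mutations), 0)
  expect_equal(nrow(prof0$clones), 9)

  cfg1 <- sim_config(n_replicates_per_treatment = 4, locus_pool_size = 1,
                     mutation_rate_lambda = 50, seed = 5)
  prof1 <- simulate_mutations(cfg1)
  expect_true(all(prof1$mutations$locus_tag == prof1$mutations$locus_tag[1]))
  J <- similarity_matrix(prof1, classes = "all")
  expect_true(all(J == 1))
})

test_that("community compositions are simplex-valued and drift-free when told to be", {
  cfg <- sim_config(n_replicates_per_treatment = 4, seed = 9)
  ab <- simulate_community(cfg)
  sums <- tapply(ab$rel_abundance, paste(ab$replicate_id, ab$transfer), sum)
  expect_true(all(abs(sums - 1) < 1e-9))

  cfg0 <- sim_config(n_replicates_per_treatment = 4, sorting_drift_sd = 0,
                     reinvasion_scenario = FALSE, seed = 9)
  ab0 <- simulate_community(cfg0)
  byrep <- split(ab0, ab0$replicate_id)
  for (d in byrep) {
    wide <- tapply(d$rel_abundance, list(d$transfer, d$species), sum)
    expect_true(all(apply(wide, 2, function(col) diff(range(col)) < 1e-12)))
  }
})

test_that("reinvasion crashes the designated species mid-series in half the replicates", {
  cfg <- sim_config(n_replicates_per_treatment = c(MC = 1, RP = 1, DP = 6),
                    reinvasion_scenario = TRUE, seed = 13)
  ab <- simulate_community(cfg)
  mid <- setdiff(cfg$transfers, range(cfg$transfers))
  bac <- ab[ab$species == "Bacillus" & ab$transfer %in% mid, ]
  crashed <- tapply(bac$rel_abundance, bac$replicate_id,
                    function(x) all(x < 1e-3))
  expect_equal(sum(crashed), ceiling(6 / 2))
  # recovery: crashed replicates regain the species by the final transfer
  fin <- ab[ab$species == "Bacillus" & ab$transfer == max(cfg$transfers), ]
  expect_true(all(fin$rel_abundance[crashed[fin$replicate_id]] > 1e-3))
})

test_that("drifting replicates diverge in Bray-Curtis terms", {
  diverged <- vapply(1:100, function(s) {
    cfg <- sim_config(n_replicates_per_treatment = 2, sorting_drift_sd = 1,
                      reinvasion_scenario = FALSE, seed = s)
    ab <- simulate_community(cfg)
    d <- pairwise_dissimilarity(ab, max(cfg$transfers))
    d$dissimilarity[1] > 0
  }, logical(1))
  expect_true(mean(diverged) == 1)
})

test_that("growth simulation round-trips the Malthusian parameter", {
  gr <- data.frame(treatment = c("ancestor", "MC"),
                   condition = "alone",
                   mean = c(4.6, 0), sd = 0)
  cfg <- sim_config(n_replicates_per_treatment = 2, growth_rates = gr,
                    n_growth_replicates = 3, seed = 21)
  rec <- simulate_growth(cfg)
  m <- malthusian(rec$n0, rec$nf)
  expect_close(m[rec$treatment == "ancestor"], rep(4.6, 3), 1e-12)
  expect_close(m[rec$treatment == "MC"], rep(0, 3), 1e-12)
  expect_close(rec$nf[rec$treatment == "MC"], rec$n0[rec$treatment == "MC"],
               1e-6)
})

test_that("recovered growth rates are unbiased (CLT check)", {
  gr <- data.frame(treatment = "MC", condition = "alone",
                   mean = 4.6, sd = 0.2)
  cfg <- sim_config(n_replicates_per_treatment = 2, growth_rates = gr,
                    n_growth_replicates = 1000, seed = 22)
  rec <- simulate_growth(cfg)
  m <- malthusian(rec$n0, rec$nf)
  expect_lt(abs(mean(m) - 4.6), 2 * 0.2 / sqrt(1000))
})

test_that("configuration errors are caught", {
  expect_error(sim_config(treatments = character(0)), "empty treatments")
  expect_error(sim_config(substrates = character(0)), "empty substrates")
  expect_error(sim_config(residual_sd = -1), "sd parameters")
  expect_error(sim_config(mutation_rate_lambda = -0.1), "mutation_rate_lambda")
  expect_error(sim_config(nonsyn_fraction = 1.2), "nonsyn_fraction")
  expect_error(sim_config(n_replicates_per_treatment = 0), "positive")
  w <- matrix(-1, 3, 60)
  expect_error(sim_config(hotspot_weights = w), "nonnegative")
})
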