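toy_profiles <- function() {
  clones <- data.frame(
    clone_id = c("a1", "a2", "b1", "b2"),
    treatment = c("A", "A", "B", "B"))
  mutations <- data.frame(
    clone_id = c("a1", "a1", "a2", "b1", "b2", "b2"),
    locus_tag = c("g1", "g2", "g1", "g3", "g3", "g4"),
    mutation_class = c("nonsynonymous", "nonsynonymous", "nonsynonymous",
                       "nonsynonymous", "nonsynonymous", "synonymous"))
  mutation_profiles(clones, mutations)
}

test_that("jaccard index follows the set formula and the empty-union convention", {
  expect_equal(jaccard_index(c("g1", "g2"), c("g2", "g3")), 1 / 3)
  expect_equal(jaccard_index(c("g1"), c("g2")), 0)
  expect_equal(jaccard_index(character(0), character(0)), 1)
  expect_equal(jaccard_index(character(0), character(0),
                             empty_union = "zero"), 0)
  expect_equal(jaccard_index(c("g1", "g1"), c("g1")), 1)  # duplicates
  expect_equal(jaccard_index(character(0), c("g1")), 0)
})

test_that("similarity matrix is symmetric, unit-diagonal, and matches per-pair set arithmetic", {
  set.seed(17)
  pool <- sprintf("locus_%02d", 1:12)
  clones <- data.frame(clone_id = sprintf("c%02d", 1:24),
                       treatment = rep(c("MC", "RP", "DP"), c(12, 6, 6)))
  muts <- do.call(rbind, lapply(clones$clone_id, function(id) {
    k <- rpois(1, 1.5)
    if (k == 0) return(NULL)
    data.frame(clone_id = id, locus_tag = sample(pool, min(k, 12)),
               mutation_class = "nonsynonymous")
  }))
  prof <- mutation_profiles(clones, muts)
  J <- similarity_matrix(prof)
  expect_equal(dim(J), c(24, 24))
  expect_true(isSymmetric(J))
  expect_true(all(diag(J) == 1))
  # brute-force pair loop oracle
  sets <- lapply(clones$clone_id, function(id) {
    unique(muts$locus_tag[muts$clone_id == id])
  })
  for (i in sample(24, 6)) for (j in sample(24, 6)) {
    a <- sets[[i]]; b <- sets[[j]]
    u <- length(unique(c(a, b)))
    expected <- if (u == 0) 1 else sum(a %in% b) / u
    expect_close(J[i, j], expected, 1e-12)
  }
})

test_that("similarity matrix respects the class filter and is stable under clone reordering", {
  prof <- toy_profiles()
  J_ns <- similarity_matrix(prof, classes = "nonsynonymous")
  # b2's synonymous g4 is filtered out, so b1 and b2 share {g3} exactly
  expect_equal(J_ns["b1", "b2"], 1)
  J_all <- similarity_matrix(prof, classes = "all")
  expect_equal(J_all["b1", "b2"], 1 / 2)
  expect_error(similarity_matrix(prof, classes = "missense"),
               "unknown mutation class")

  perm <- c("b2", "a1", "b1", "a2")
  prof2 <- mutation_profiles(
    prof$clones[match(perm, prof$clones$clone_id), ], prof$mutations)
  J2 <- similarity_matrix(prof2, classes = "all")
  expect_close(J2[rownames(J_all), colnames(J_all)], J_all, 1e-12)
})

test_that("parallelism F is seed-independent with paper-style degrees of freedom", {
  set.seed(19)
  cfg <- sim_config(seed = 19)
  prof <- simulate_mutations(cfg)
  J <- similarity_matrix(prof)
  r1 <- parallelism_perm_anova(J, prof$clones$treatment, 49, seed = 1)
  r2 <- parallelism_perm_anova(J, prof$clones$treatment, 99, seed = 77)
  expect_identical(r1$observed, r2$observed)
  expect_equal(unname(r1$df), c(5, 570))  # 6 groups over 24^2 cells
})

test_that("a constant similarity matrix gives F = 0 and p = 1", {
  J <- matrix(1, 6, 6)
  res <- parallelism_perm_anova(J, rep(c("A", "B"), each = 3), 19, seed = 1)
  expect_equal(res$observed, 0)
  expect_equal(res$p, 1)
})

test_that("clone-label permutation p equals complete enumeration on 4 clones", {
  prof <- toy_profiles()
  J <- similarity_matrix(prof, classes = "all")
  labels <- prof$clones$treatment
  res <- parallelism_perm_anova(J, labels, n_permutations = 23, seed = 1)
  expect_true(res$exact)
  # oracle: every relabeling via lm-based one-way ANOVA over all 16 cells
  vals <- as.vector(J)
  F_of <- function(lab) {
    li <- rep(lab, times = 4); lj <- rep(lab, each = 4)
    g <- factor(paste(pmin(li, lj), pmax(li, lj)))
    an <- anova(lm(vals ~ g))
    an["g", "F value"]
  }
  Fs <- vapply(perms_of(4), function(p) F_of(labels[p]), numeric(1))
  p_exact <- mean(Fs >= F_of(labels) - 1e-12)
  expect_close(res$p, p_exact, 1e-12)
  expect_close(res$observed, F_of(labels))
})

test_that("pairwise contrasts recover the pooled-variance t and its sign convention", {
  prof <- toy_profiles()
  J <- similarity_matrix(prof, classes = "all")
  ct <- pairwise_treatment_contrasts(J, prof$clones$treatment,
                                     n_permutations = 23, seed = 2)
  expect_named(ct, "A:B")
  # textbook pooled t oracle: between-group cells vs pooled within cells
  li <- rep(prof$clones$treatment, times = 4)
  lj <- rep(prof$clones$treatment, each = 4)
  g <- paste(pmin(li, lj), pmax(li, lj), sep = ":")
  between <- as.vector(J)[g == "A:B"]
  within <- as.vector(J)[g %in% c("A:A", "B:B")]
  nx <- length(between); ny <- length(within)
  sp2 <- ((nx - 1) * var(between) + (ny - 1) * var(within)) / (nx + ny - 2)
  t_oracle <- (mean(between) - mean(within)) / sqrt(sp2 * (1/nx + 1/ny))
  expect_close(ct[["A:B"]]$observed, t_oracle, 1e-10)
  expect_lt(ct[["A:B"]]$observed, 0)  # differentiated toy treatments
})

test_that("identical group values give a zero contrast", {
  J <- matrix(0.5, 6, 6); diag(J) <- 0.5
  ct <- pairwise_treatment_contrasts(J, rep(c("A", "B"), each = 3),
                                     n_permutations = 19, seed = 3)
  expect_equal(ct[["A:B"]]$observed, 0)
})

test_that("mutation count ANOVA delegates to Welch's test and counts all called mutations", {
  clones <- data.frame(clone_id = sprintf("c%d", 1:9),
                       treatment = rep(c("A", "B", "C"), each = 3))
  counts <- c(0, 1, 2, 2, 3, 4, 1, 1, 3)
  muts <- do.call(rbind, lapply(seq_along(counts), function(i) {
    if (counts[i] == 0) return(NULL)
    data.frame(clone_id = sprintf("c%d", i),
               locus_tag = sprintf("L%d_%d", i, seq_len(counts[i])),
               mutation_class = "nonsynonymous")
  }))
  prof <- mutation_profiles(clones, muts)
  res <- mutation_count_anova(prof, "all")
  oracle <- welch_oracle(counts, clones$treatment)
  expect_close(res$F, oracle$F, 1e-10)
  expect_close(res$df2, oracle$df2, 1e-8)
  expect_close(res$p, oracle$p, 1e-10)
})
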