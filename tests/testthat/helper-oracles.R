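# Fixtures and independent oracles used across the suite. The oracles are
# deliberately naive (loops, textbook formulas, recursive enumeration) and
# share no code with the package internals they check.

# Tidy phenotype table from a mean function mu(treatment, transfer,
# substrate) plus iid Gaussian noise.
make_phen <- function(treatments, transfers, reps, substrates,
                      mu = function(tr, t, s) 1,
                      sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rows <- expand.grid(rep = seq_len(reps), substrate = substrates,
                      transfer = transfers, treatment = treatments,
                      stringsAsFactors = FALSE)
  rows$replicate_id <- paste0(rows$treatment, "_", rows$rep)
  rows$value <- mapply(mu, rows$treatment, rows$transfer, rows$substrate) +
    rnorm(nrow(rows), 0, sd)
  rows$value <- pmax(rows$value, 0)
  rows[, c("replicate_id", "treatment", "transfer", "substrate", "value")]
}

# All permutations of 1..n, recursively (independent of package internals).
perms_of <- function(n) {
  if (n == 1) return(list(1L))
  smaller <- perms_of(n - 1)
  out <- list()
  for (p in smaller) {
    for (pos in 0:(n - 1)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos)
    }
  }
  out
}

# Welch's heteroscedastic one-way ANOVA by the textbook formula.
welch_oracle <- function(values, groups) {
  groups <- factor(groups)
  ni <- tapply(values, groups, length)
  mi <- tapply(values, groups, mean)
  vi <- tapply(values, groups, var)
  wi <- ni / vi
  k <- nlevels(groups)
  mw <- sum(wi * mi) / sum(wi)
  A <- sum(wi * (mi - mw)^2) / (k - 1)
  lambda <- sum((1 - wi / sum(wi))^2 / (ni - 1))
  B <- 1 + 2 * (k - 2) / (k^2 - 1) * lambda
  Fv <- A / B
  df2 <- (k^2 - 1) / (3 * lambda)
  list(F = Fv, df1 = k - 1, df2 = df2,
       p = pf(Fv, k - 1, df2, lower.tail = FALSE))
}

# Balanced two-way ANOVA decomposition from cell means (textbook formulas).
twoway_oracle <- function(y, f1, f2) {
  f1 <- factor(f1); f2 <- factor(f2)
  n <- tapply(y, list(f1, f2), length)
  stopifnot(length(unique(as.vector(n))) == 1)
  r <- n[1, 1]
  cm <- tapply(y, list(f1, f2), mean)
  m1 <- rowMeans(cm); m2 <- colMeans(cm); mg <- mean(y)
  a <- nlevels(f1); b <- nlevels(f2)
  ss1 <- r * b * sum((m1 - mg)^2)
  ss2 <- r * a * sum((m2 - mg)^2)
  ssint <- r * sum((cm - outer(m1, rep(1, b)) -
                      outer(rep(1, a), m2) + mg)^2)
  sse <- sum((y - cm[cbind(f1, f2)])^2)
  list(ss1 = ss1, ss2 = ss2, ssint = ssint, sse = sse,
       df = c(a - 1, b - 1, (a - 1) * (b - 1), length(y) - a * b))
}

# Classical univariate interaction F via lm/anova (used as an oracle for
# the multivariate trace statistic collapsed to p = 1).
classical_interaction_F <- function(table) {
  fit <- lm(value ~ factor(treatment) * factor(transfer), data = table)
  an <- anova(fit)
  an["factor(treatment):factor(transfer)", "F value"]
}

# First eigenvector by power iteration on the covariance matrix —
# an independent route to the trajectory direction.
power_iteration_direction <- function(points, iters = 500) {
  x <- sweep(points, 2, colMeans(points))
  cv <- crossprod(x) / (nrow(x) - 1)
  v <- rep(1, ncol(cv)) / sqrt(ncol(cv))
  for (i in seq_len(iters)) {
    v <- cv %*% v
    v <- v / sqrt(sum(v^2))
  }
  as.vector(v)
}

expect_close <- function(object, expected, tol = 1e-8) {
  expect_true(max(abs(object - expected)) < tol,
              label = sprintf("max|%s - %s| = %g",
                              deparse(substitute(object)),
                              deparse(substitute(expected)),
                              max(abs(object - expected))))
}
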