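#' @keywords internal
#' Evaluate `expr` with the RNG seeded at `seed`, restoring the caller's
#' RNG state afterwards so generators never perturb each other's draws.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# All permutations of 1..n as an n! x n matrix (recursive heap-style build).
# Only called for n! <= 5040, where enumeration is cheap.
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 1L
  for (i in seq_len(nrow(sub))) {
    for (pos in seq_len(n)) {
      out[row, ] <- append(sub[i, ], n, after = pos - 1L)
      row <- row + 1L
    }
  }
  out
}

#' Build the set of row permutations used by a permutation test.
#'
#' When the number of requested permutations is at least `n! - 1` and `n!`
#' is small enough to enumerate (<= 5040), the complete set of non-identity
#' permutations is used and the test is exact; otherwise `n_permutations`
#' random permutations are drawn. The identity (observed) arrangement is
#' always accounted for separately by the caller.
#'
#' @param n number of exchangeable rows.
#' @param n_permutations requested number of permutations (>= 1).
#' @return integer matrix, one permutation per row, with attribute
#'   `exact = TRUE` when the set is a complete enumeration.
#' @keywords internal
permutation_schedule <- function(n, n_permutations) {
  if (n_permutations < 1) stop("n_permutations must be >= 1", call. = FALSE)
  nfact <- suppressWarnings(factorial(n))
  if (is.finite(nfact) && nfact <= 5040 && n_permutations >= nfact - 1) {
    perms <- all_permutations(as.integer(n))
    identity <- vapply(seq_len(nrow(perms)),
                       function(i) all(perms[i, ] == seq_len(n)), logical(1))
    perms <- perms[!identity, , drop = FALSE]
    attr(perms, "exact") <- TRUE
    return(perms)
  }
  perms <- t(vapply(seq_len(n_permutations), function(i) sample.int(n),
                    integer(n)))
  attr(perms, "exact") <- FALSE
  perms
}

#' Summarize a permutation test
#'
#' Packages an observed statistic together with its permutation distribution
#' into a result object carrying the effect size and p-value conventions
#' used throughout the package: the observed arrangement counts as one
#' permutation, so `p = (b + 1) / (m + 1)` where `b` is the number of
#' permuted statistics at least as extreme as the observed one, and the
#' effect size `Z` is the standard deviate of the observed statistic
#' against the permutation distribution (optionally on the log scale for
#' strictly positive statistics).
#'
#' @param statistic_name label for the statistic (e.g. `"F"`, `"|d|"`).
#' @param observed observed value of the statistic.
#' @param permuted numeric vector of statistics from permuted data
#'   (excluding the observed arrangement).
#' @param seed seed used to draw the permutations.
#' @param transform `"none"` (default) or `"log"`; with `"log"` the Z score
#'   is computed on log-transformed statistics (positive statistics only).
#' @param alternative `"greater"` (default, for F-like statistics) or
#'   `"two.sided"` (extremeness judged on absolute value, for signed t-like
#'   statistics).
#' @param df optional named numeric vector of degrees of freedom.
#' @return object of class `perm_test` with fields `statistic_name`,
#'   `observed`, `perm_mean`, `perm_sd`, `Z`, `p`, `n_permutations`,
#'   `exact`, `seed`, `df`, and the full distribution in `distribution`
#'   (observed value first).
#' @export
perm_test_result <- function(statistic_name, observed, permuted, seed,
                             transform = c("none", "log"),
                             alternative = c("greater", "two.sided"),
                             df = NULL) {
  transform <- match.arg(transform)
  alternative <- match.arg(alternative)
  dist <- c(observed, permuted)
  m <- length(permuted)
  # relative tolerance so structural ties (permutations equivalent by
  # design symmetry) are counted as ties despite round-off
  tol <- 1e-8 * max(1, abs(observed))
  if (alternative == "greater") {
    p <- sum(dist >= observed - tol) / (m + 1)
  } else {
    p <- sum(abs(dist) >= abs(observed) - tol) / (m + 1)
  }
  zdist <- dist
  if (transform == "log") {
    if (any(dist <= 0)) stop("log transform requires positive statistics",
                             call. = FALSE)
    zdist <- log(dist)
  }
  mu <- mean(zdist)
  sdv <- stats::sd(zdist)
  z <- if (isTRUE(sdv > 0)) (zdist[1] - mu) / sdv else NA_real_
  structure(list(statistic_name = statistic_name,
                 observed = observed,
                 perm_mean = mean(dist[-1]),
                 perm_sd = stats::sd(dist[-1]),
                 Z = z, p = p,
                 n_permutations = m,
                 exact = isTRUE(attr(permuted, "exact")),
                 seed = seed, df = df,
                 transform = transform,
                 alternative = alternative,
                 distribution = dist),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  dfs <- if (!is.null(x$df)) {
    paste0(" (df = ", paste(signif(x$df, 6), collapse = ", "), ")")
  } else ""
  cat("Permutation test: ", x$statistic_name, " = ",
      signif(x$observed, 6), dfs, "\n",
      "  Z = ", signif(x$Z, 4), ", p = ", signif(x$p, 4),
      "  [", x$n_permutations,
      if (x$exact) " permutations, exact]" else " permutations]", "\n",
      sep = "")
  invisible(x)
}
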