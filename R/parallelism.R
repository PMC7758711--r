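MUTATION_CLASSES <- c("nonsynonymous", "synonymous", "indel", "intergenic")

#' Construct a set of clone mutation profiles
#'
#' Container for the called-variant table of sequenced evolved clones:
#' which genetic loci are mutated in each clone, and the class of each
#' mutation. Clones with zero mutations are valid and must still be
#' registered (they enter the Jaccard analysis as empty locus sets).
#'
#' @param clones data.frame with columns `clone_id` (unique) and
#'   `treatment`.
#' @param mutations data.frame with columns `clone_id`, `locus_tag`,
#'   `mutation_class` (one of nonsynonymous, synonymous, indel,
#'   intergenic); zero rows allowed.
#' @return object of class `mutation_profiles`.
#' @export
mutation_profiles <- function(clones, mutations) {
  stopifnot(all(c("clone_id", "treatment") %in% names(clones)),
            all(c("clone_id", "locus_tag", "mutation_class") %in%
                  names(mutations)))
  clones$clone_id <- as.character(clones$clone_id)
  clones$treatment <- as.character(clones$treatment)
  if (anyDuplicated(clones$clone_id)) {
    stop("duplicate clone_id in clone table", call. = FALSE)
  }
  mutations$clone_id <- as.character(mutations$clone_id)
  mutations$locus_tag <- as.character(mutations$locus_tag)
  mutations$mutation_class <- as.character(mutations$mutation_class)
  bad <- setdiff(mutations$mutation_class, MUTATION_CLASSES)
  if (length(bad)) {
    stop("unknown mutation class: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  orphan <- setdiff(mutations$clone_id, clones$clone_id)
  if (length(orphan)) {
    stop("mutations listed for unregistered clone(s): ",
         paste(orphan, collapse = ", "), call. = FALSE)
  }
  structure(list(clones = clones, mutations = mutations),
            class = "mutation_profiles")
}

#' @export
print.mutation_profiles <- function(x, ...) {
  cat("Mutation profiles: ", nrow(x$clones), " clones, ",
      nrow(x$mutations), " mutations across ",
      length(unique(x$mutations$locus_tag)), " loci\n", sep = "")
  print(table(x$clones$treatment))
  invisible(x)
}

# Per-clone locus sets, optionally restricted to given mutation classes.
locus_sets <- function(profiles, classes = "all") {
  stopifnot(inherits(profiles, "mutation_profiles"))
  if (identical(classes, "all")) classes <- MUTATION_CLASSES
  bad <- setdiff(classes, MUTATION_CLASSES)
  if (length(bad)) {
    stop("unknown mutation class: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  mut <- profiles$mutations[profiles$mutations$mutation_class %in% classes, ]
  sets <- split(mut$locus_tag, factor(mut$clone_id,
                                      levels = profiles$clones$clone_id))
  lapply(sets, unique)
}

#' Jaccard index of two locus sets
#'
#' Similarity of the mutational profiles of two clones: number of loci
#' mutated in common divided by the total number of loci mutated in
#' either. When both sets are empty the index is 1 by default (two
#' mutation-free clones have identical profiles); set
#' `empty_union = "zero"` for the opposite convention.
#'
#' @param lociA,lociB character vectors of locus tags (duplicates ignored).
#' @param empty_union value when both sets are empty: `"one"` (default) or
#'   `"zero"`.
#' @return similarity in \[0, 1\].
#' @export
jaccard_index <- function(lociA, lociB, empty_union = c("one", "zero")) {
  empty_union <- match.arg(empty_union)
  a <- unique(as.character(lociA))
  b <- unique(as.character(lociB))
  u <- length(union(a, b))
  if (u == 0) return(if (empty_union == "one") 1 else 0)
  length(intersect(a, b)) / u
}

#' Jaccard similarity matrix over all clone pairs
#'
#' @param profiles a [mutation_profiles()] object.
#' @param classes mutation classes to retain before comparing locus sets;
#'   default `"nonsynonymous"` (the parallelism analysis concerns loci
#'   affected by non-synonymous mutations); `"all"` keeps every class.
#' @inheritParams jaccard_index
#' @return square symmetric matrix with unit diagonal (under the default
#'   empty-union convention), rows/columns named by `clone_id`, with the
#'   applied class filter in attribute `classes`.
#' @export
similarity_matrix <- function(profiles, classes = "nonsynonymous",
                              empty_union = c("one", "zero")) {
  empty_union <- match.arg(empty_union)
  sets <- locus_sets(profiles, classes)
  ids <- profiles$clones$clone_id
  if (length(ids) < 2) stop("need >= 2 clones", call. = FALSE)
  n <- length(ids)
  J <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    J[i, i] <- jaccard_index(sets[[i]], sets[[i]], empty_union)
    if (i < n) for (j in seq((i + 1), n)) {
      J[i, j] <- J[j, i] <- jaccard_index(sets[[i]], sets[[j]], empty_union)
    }
  }
  attr(J, "classes") <- classes
  J
}

# Group id of every ordered cell (i, j) of the similarity matrix: the
# unordered treatment pair of the two clones. labels: character vector per
# clone. Returns a character vector of length n^2 (column-major).
cell_groups <- function(labels) {
  li <- rep(labels, times = length(labels))        # row index varies fastest
  lj <- rep(labels, each = length(labels))
  paste(pmin(li, lj), pmax(li, lj), sep = ":")
}

oneway_F_stats <- function(values, groups) {
  gs <- rowsum(values, groups)
  gn <- as.vector(rowsum(rep(1, length(values)), groups))
  gm <- gs / gn
  grand <- mean(values)
  ssb <- sum(gn * (gm - grand)^2)
  sst <- sum((values - grand)^2)
  ssw <- sst - ssb
  g <- length(gn)
  df1 <- g - 1
  df2 <- length(values) - g
  if (ssb <= 1e-14 * max(sst, 1)) return(c(F = 0, df1 = df1, df2 = df2))
  if (ssw <= 0) return(c(F = Inf, df1 = df1, df2 = df2))
  c(F = (ssb / df1) / (ssw / df2), df1 = df1, df2 = df2)
}

# Integer variant of cell_groups for the permutation loops: codes are
# 1-based treatment codes, row/col index templates are precomputed once.
cell_group_codes <- function(codes, row_idx, col_idx) {
  ci <- codes[row_idx]
  cj <- codes[col_idx]
  pmin(ci, cj) * length(codes) + pmax(ci, cj)
}

#' Permutational ANOVA of mutational parallelism
#'
#' Tests whether the Jaccard similarity of clone mutational profiles
#' depends on the treatment comparison — i.e. whether clones from the
#' same or from particular pairs of treatments share mutated loci more
#' than expected. The observations are all N^2 ordered cells of the
#' similarity matrix (diagonal included); each cell is grouped by the
#' unordered treatment pair of its two clones (T(T+1)/2 groups; 6 for 3
#' treatments, giving the (5, N^2 - 6) degrees of freedom of a 24-clone
#' experiment). The observed statistic is the one-way ANOVA F across
#' groups; significance comes from permutation.
#'
#' @param matrix square Jaccard similarity matrix (see
#'   [similarity_matrix()]).
#' @param treatments character vector mapping each clone (matrix row) to
#'   its treatment; recycled from names if a named vector.
#' @param n_permutations number of permutations (default 10000).
#' @param seed integer seed.
#' @param scheme `"clone_labels"` (default): permute the clone-to-treatment
#'   map and regroup the cells, respecting the dependence structure of the
#'   matrix; `"cell_values"`: permute the cell values over the fixed
#'   grouping (sensitivity analysis).
#' @return a [perm_test_result()] object with the F statistic and its
#'   degrees of freedom.
#' @export
parallelism_perm_anova <- function(matrix, treatments,
                                   n_permutations = 10000, seed,
                                   scheme = c("clone_labels",
                                              "cell_values")) {
  scheme <- match.arg(scheme)
  stopifnot(is.matrix(matrix), nrow(matrix) == ncol(matrix))
  n <- nrow(matrix)
  labels <- as.character(treatments)
  if (length(labels) != n) {
    stop("`treatments` must map every clone in the matrix", call. = FALSE)
  }
  if (length(unique(labels)) < 2) {
    stop("need >= 2 treatments represented", call. = FALSE)
  }
  vals <- as.vector(matrix)
  obs_groups <- cell_groups(labels)
  obs <- oneway_F_stats(vals, obs_groups)
  codes <- as.integer(factor(labels))
  row_idx <- rep(seq_len(n), times = n)
  col_idx <- rep(seq_len(n), each = n)
  perm_F <- with_seed(seed, {
    if (scheme == "clone_labels") {
      perms <- permutation_schedule(n, n_permutations)
      out <- vapply(seq_len(nrow(perms)), function(i) {
        g <- cell_group_codes(codes[perms[i, ]], row_idx, col_idx)
        oneway_F_stats(vals, g)[["F"]]
      }, numeric(1))
      attr(out, "exact") <- attr(perms, "exact")
      out
    } else {
      vapply(seq_len(n_permutations), function(i) {
        oneway_F_stats(vals[sample.int(length(vals))], obs_groups)[["F"]]
      }, numeric(1))
    }
  })
  perm_test_result("F (treatment comparison)", obs[["F"]], perm_F, seed,
                   df = c(df1 = obs[["df1"]], df2 = obs[["df2"]]))
}

pooled_t <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) /
    (nx + ny - 2)
  if (sp2 <= 0) return(0)
  (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
}

#' Pairwise treatment contrasts of mutational similarity
#'
#' For each pair of treatments (A, B), contrasts the similarity of
#' between-treatment clone pairs (cells in group A:B) against the
#' similarity of within-treatment pairs of the same two treatments (cells
#' in A:A and B:B pooled), with a pooled-variance two-sample t statistic.
#' A negative t means clones are less similar across the two treatments
#' than within them — genetic differentiation between treatments.
#' Significance is two-sided, by the same permutation scheme as
#' [parallelism_perm_anova()].
#'
#' @inheritParams parallelism_perm_anova
#' @return named list of [perm_test_result()] objects, one per treatment
#'   pair (`"A:B"`).
#' @export
pairwise_treatment_contrasts <- function(matrix, treatments,
                                         n_permutations = 10000, seed,
                                         scheme = c("clone_labels",
                                                    "cell_values")) {
  scheme <- match.arg(scheme)
  n <- nrow(matrix)
  labels <- as.character(treatments)
  stopifnot(length(labels) == n)
  vals <- as.vector(matrix)
  trts <- sort(unique(labels))
  pairs <- utils::combn(trts, 2, simplify = FALSE)

  contrast_t <- function(groups) {
    vapply(pairs, function(pr) {
      between <- vals[groups == paste(pr[1], pr[2], sep = ":")]
      within <- vals[groups %in% paste(pr, pr, sep = ":")]
      if (length(between) < 2 || length(within) < 2) {
        stop("contrast group with < 2 cells for ",
             paste(pr, collapse = ":"), call. = FALSE)
      }
      pooled_t(between, within)
    }, numeric(1))
  }
  obs <- contrast_t(cell_groups(labels))
  perm_t <- with_seed(seed, {
    if (scheme == "clone_labels") {
      perms <- permutation_schedule(n, n_permutations)
      out <- t(vapply(seq_len(nrow(perms)), function(i) {
        contrast_t(cell_groups(labels[perms[i, ]]))
      }, numeric(length(pairs))))
      attr(out, "exact") <- attr(perms, "exact")
      out
    } else {
      g0 <- cell_groups(labels)
      t(vapply(seq_len(n_permutations), function(i) {
        vals_p <- vals[sample.int(length(vals))]
        vapply(pairs, function(pr) {
          pooled_t(vals_p[g0 == paste(pr[1], pr[2], sep = ":")],
                   vals_p[g0 %in% paste(pr, pr, sep = ":")])
        }, numeric(1))
      }, numeric(length(pairs))))
    }
  })
  out <- lapply(seq_along(pairs), function(j) {
    pd <- perm_t[, j]
    attr(pd, "exact") <- isTRUE(attr(perm_t, "exact"))
    perm_test_result("t (between vs within)", obs[j], pd, seed,
                     alternative = "two.sided")
  })
  names(out) <- vapply(pairs, paste, character(1), collapse = ":")
  out
}

#' Welch's ANOVA on per-clone mutation counts
#'
#' Compares the number of mutations per evolved clone between treatments
#' using Welch's heteroscedastic one-way ANOVA (Welch-Satterthwaite
#' denominator degrees of freedom).
#'
#' @param profiles a [mutation_profiles()] object.
#' @param classes mutation classes counted; default `"all"`.
#' @return list with `F`, `df1`, `df2`, `p`, the per-treatment counts and
#'   the class filter (see [welch_anova()]).
#' @export
mutation_count_anova <- function(profiles, classes = "all") {
  sets <- locus_sets(profiles, classes)
  if (identical(classes, "all")) {
    # count every called mutation, not distinct loci
    mut <- profiles$mutations
  } else {
    mut <- profiles$mutations[profiles$mutations$mutation_class %in%
                                classes, ]
  }
  counts <- as.vector(table(factor(mut$clone_id,
                                   levels = profiles$clones$clone_id)))
  groups <- profiles$clones$treatment
  tab <- table(groups)
  if (sum(tab >= 2) < 2) {
    stop("need >= 2 treatments with >= 2 clones each", call. = FALSE)
  }
  res <- welch_anova(counts, groups)
  res$counts <- stats::setNames(counts, profiles$clones$clone_id)
  res$classes <- classes
  res
}
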