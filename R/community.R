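#' Bray-Curtis dissimilarity between two nonnegative profiles
#'
#' `sum(|x - y|) / sum(x + y)`: the standard ecological measure of
#' compositional divergence, 0 for identical profiles and 1 for profiles
#' with disjoint support. Also used here for multivariate substrate-use
#' phenotypes.
#'
#' @param x,y nonnegative numeric vectors of equal length.
#' @return dissimilarity in \[0, 1\].
#' @export
bray_curtis <- function(x, y) {
  if (length(x) != length(y)) stop("profiles differ in length",
                                   call. = FALSE)
  if (any(x < 0) || any(y < 0)) stop("profiles must be nonnegative",
                                     call. = FALSE)
  tot <- sum(x) + sum(y)
  if (tot == 0) stop("both profiles are all-zero", call. = FALSE)
  sum(abs(x - y)) / tot
}

# Extract per-replicate profiles at one transfer from either an abundance
# table (species/rel_abundance) or a phenotype table (substrate/value).
replicate_profiles <- function(table, transfer) {
  if (all(c("species", "rel_abundance") %in% names(table))) {
    feature <- "species"; value <- "rel_abundance"
  } else if (all(c("substrate", "value") %in% names(table))) {
    feature <- "substrate"; value <- "value"
  } else {
    stop("table must have species/rel_abundance or substrate/value columns",
         call. = FALSE)
  }
  sub <- table[table$transfer == transfer, , drop = FALSE]
  if (nrow(sub) == 0) stop("no records at transfer ", transfer,
                           call. = FALSE)
  feats <- unique(as.character(table[[feature]]))
  reps <- unique(as.character(sub$replicate_id))
  if (length(reps) < 2) stop("need >= 2 replicates at transfer ", transfer,
                             call. = FALSE)
  profs <- lapply(reps, function(r) {
    ri <- sub[sub$replicate_id == r, , drop = FALSE]
    stats::setNames(ri[[value]][match(feats, as.character(ri[[feature]]))],
                    feats)
  })
  names(profs) <- reps
  profs
}

#' Pairwise Bray-Curtis dissimilarity between replicates at a transfer
#'
#' Computes the Bray-Curtis dissimilarity for every unordered pair of
#' replicates at the given transfer. Community tables contribute
#' species relative-abundance profiles; phenotype tables contribute the
#' multivariate substrate-respiration profile, so the same divergence
#' measure applies to community structure and to evolved metabolism.
#'
#' @param table an abundance table (`replicate_id`, `transfer`, `species`,
#'   `rel_abundance`) or tidy phenotype table (`replicate_id`,
#'   `treatment`, `transfer`, `substrate`, `value`).
#' @param transfer transfer (time level) at which to compare replicates.
#' @return data.frame with columns `rep_a`, `rep_b`, `transfer`,
#'   `dissimilarity`, one row per unordered replicate pair.
#' @export
pairwise_dissimilarity <- function(table, transfer) {
  profs <- replicate_profiles(table, transfer)
  reps <- names(profs)
  pairs <- utils::combn(reps, 2, simplify = FALSE)
  data.frame(
    rep_a = vapply(pairs, `[`, character(1), 1),
    rep_b = vapply(pairs, `[`, character(1), 2),
    transfer = transfer,
    dissimilarity = vapply(pairs, function(pr) {
      bray_curtis(profs[[pr[1]]], profs[[pr[2]]])
    }, numeric(1)),
    stringsAsFactors = FALSE)
}

#' Dissimilarity trajectories across all transfers
#'
#' Convenience wrapper running [pairwise_dissimilarity()] at every
#' transfer present in the table.
#'
#' @inheritParams pairwise_dissimilarity
#' @param transfers transfers to include (default: all in the table).
#' @return row-bound data.frame of per-transfer pairwise dissimilarities.
#' @export
dissimilarity_over_time <- function(table,
                                    transfers = sort(unique(table$transfer))) {
  do.call(rbind, lapply(transfers, function(t) {
    pairwise_dissimilarity(table, t)
  }))
}

regression_result <- function(coefficients, r_squared, F, df, p,
                              term = NULL) {
  structure(list(coefficients = coefficients, R_squared = r_squared,
                 F = F, df = df, p = p, term = term),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  trm <- if (!is.null(x$term)) paste0(" [", x$term, "]") else ""
  cat("Regression", trm, ": R^2 = ", signif(x$R_squared, 4),
      ", F(", x$df[1], ", ", x$df[2], ") = ", signif(x$F, 5),
      ", p = ", signif(x$p, 4), "\n", sep = "")
  invisible(x)
}

#' Covariance of phenotype divergence with community divergence over time
#'
#' Tests whether the divergence of the focal species' evolved metabolic
#' phenotype between replicate communities tracks the divergence of
#' community structure increasingly over time. Phenotype dissimilarity
#' (per replicate pair and transfer) is regressed on community
#' dissimilarity, transfer (continuous), and their product; the reported
#' test is the sequential F of the interaction term. A strengthening
#' association appears as a positive interaction.
#'
#' @param phenotype_dissim,community_dissim data.frames as returned by
#'   [dissimilarity_over_time()] (columns `rep_a`, `rep_b`, `transfer`,
#'   `dissimilarity`), matched on replicate pair and transfer.
#' @return a `regression_result` for the interaction term, with the full
#'   lm coefficients and the model R^2.
#' @export
covariance_regression <- function(phenotype_dissim, community_dissim) {
  key <- function(d) paste(d$rep_a, d$rep_b, d$transfer, sep = "|")
  m <- match(key(phenotype_dissim), key(community_dissim))
  if (anyNA(m)) stop("phenotype and community dissimilarities must share ",
                     "(replicate pair, transfer) keys", call. = FALSE)
  dat <- data.frame(phen = phenotype_dissim$dissimilarity,
                    comm = community_dissim$dissimilarity[m],
                    transfer = phenotype_dissim$transfer)
  if (nrow(unique(dat)) < 4) stop("need >= 4 distinct observations",
                                  call. = FALSE)
  fit <- stats::lm(phen ~ comm * transfer, data = dat)
  an <- stats::anova(fit)
  irow <- "comm:transfer"
  ss_int <- an[irow, "Sum Sq"]
  df2 <- an["Residuals", "Df"]
  if (is.na(an[irow, "F value"]) || ss_int <= 1e-14) {
    Fv <- 0; pv <- 1
  } else {
    Fv <- an[irow, "F value"]; pv <- an[irow, "Pr(>F)"]
  }
  r2 <- if (sum(an[, "Sum Sq"]) > 0) {
    1 - an["Residuals", "Sum Sq"] / sum(an[, "Sum Sq"])
  } else 0
  regression_result(stats::coef(fit), r2, Fv, c(1, df2), pv,
                    term = "community dissimilarity x transfer")
}

#' Regression of evolved substrate use on final species abundance
#'
#' Simple linear regression of a per-replicate substrate-respiration
#' value (e.g. endpoint cellulose use) on the final relative abundance of
#' a community member (e.g. *Bacillus*), quantifying the association of
#' evolved metabolism with community composition.
#'
#' @param final_abundance numeric vector, one value per replicate.
#' @param substrate_value numeric vector, matched to `final_abundance`.
#' @return a `regression_result` with slope/intercept, R^2,
#'   F(1, n - 2) and p.
#' @export
abundance_phenotype_regression <- function(final_abundance,
                                           substrate_value) {
  if (length(final_abundance) != length(substrate_value)) {
    stop("inputs differ in length", call. = FALSE)
  }
  n <- length(final_abundance)
  if (n < 3) stop("need >= 3 replicates", call. = FALSE)
  if (stats::var(final_abundance) == 0) {
    stop("zero variance in predictor", call. = FALSE)
  }
  fit <- stats::lm(substrate_value ~ final_abundance)
  sm <- summary(fit)
  ss_reg <- sum((stats::fitted(fit) - mean(substrate_value))^2)
  if (ss_reg <= 1e-14) {
    Fv <- 0; pv <- 1; r2 <- 0
  } else {
    Fv <- sm$fstatistic[["value"]]
    pv <- stats::pf(Fv, 1, n - 2, lower.tail = FALSE)
    r2 <- sm$r.squared
  }
  regression_result(stats::coef(fit), r2, Fv, c(1, n - 2), pv,
                    term = "final abundance")
}
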