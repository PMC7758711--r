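#' Pivot a tidy phenotype table to a response matrix
#'
#' Converts tidy records of respiration per replicate x treatment x
#' transfer x substrate into the n x p response matrix used by the
#' trajectory analysis (one row per population sample, one column per
#' substrate), plus the accompanying design metadata.
#'
#' @param table data.frame with columns `replicate_id`, `treatment`,
#'   `transfer`, `substrate`, `value`.
#' @return list with `Y` (n x p numeric matrix, substrate columns in first
#'   appearance order) and `meta` (data.frame of `replicate_id`,
#'   `treatment`, `transfer` per row of `Y`).
#' @export
pivot_phenotypes <- function(table) {
  req <- c("replicate_id", "treatment", "transfer", "substrate", "value")
  missing_cols <- setdiff(req, names(table))
  if (length(missing_cols)) {
    stop("phenotype table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  substrates <- unique(as.character(table$substrate))
  key <- interaction(table$replicate_id, table$treatment, table$transfer,
                     drop = TRUE, lex.order = TRUE)
  rows <- split(seq_len(nrow(table)), key)
  n <- length(rows)
  Y <- matrix(NA_real_, n, length(substrates),
              dimnames = list(NULL, substrates))
  meta <- data.frame(replicate_id = character(n), treatment = character(n),
                     transfer = numeric(n), stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    idx <- rows[[i]]
    sub_i <- as.character(table$substrate[idx])
    if (anyDuplicated(sub_i) || !setequal(sub_i, substrates)) {
      stop("incomplete or duplicated substrate profile for (",
           table$replicate_id[idx[1]], ", transfer ",
           table$transfer[idx[1]], "): every sample needs exactly one ",
           "value per substrate", call. = FALSE)
    }
    Y[i, sub_i] <- table$value[idx]
    meta$replicate_id[i] <- as.character(table$replicate_id[idx[1]])
    meta$treatment[i] <- as.character(table$treatment[idx[1]])
    meta$transfer[i] <- table$transfer[idx[1]]
  }
  list(Y = Y, meta = meta)
}

# Orthonormal basis (n x rank) of the column space of X.
ortho_basis <- function(X) {
  qrx <- qr(X)
  qr.Q(qrx)[, seq_len(qrx$rank), drop = FALSE]
}

#' Fit the treatment x time factorial model to a multivariate phenotype
#'
#' Ordinary least-squares fit of the full factorial model
#' `phenotype ~ treatment * time` (time = transfer, treated as a
#' categorical factor) to the multivariate substrate-use response, with
#' the additive `treatment + time` model as the reduced model used for
#' residual randomization. Sums of squares are sequential
#' (treatment, then time, then their interaction), computed as traces of
#' the corresponding cross-product matrices.
#'
#' @param table tidy phenotype table (see [pivot_phenotypes()]).
#' @param scale logical; if `TRUE`, substrate columns are scaled to unit
#'   variance before analysis (default `FALSE`: raw respiration scale).
#' @return object of class `pta_fit`: the response matrix, design factors,
#'   fitted values and residuals of the full and reduced models, the
#'   sequential ANOVA table (`ss_table`), and least-squares cell means
#'   (`cell_means`, one row per treatment x time cell).
#' @export
fit_factorial_model <- function(table, scale = FALSE) {
  pv <- pivot_phenotypes(table)
  Y <- pv$Y
  if (scale) Y <- base::scale(Y, center = FALSE,
                              scale = apply(Y, 2, stats::sd))
  meta <- pv$meta
  treatment <- factor(meta$treatment, levels = unique(meta$treatment))
  time <- factor(meta$transfer, levels = sort(unique(meta$transfer)))
  if (nlevels(treatment) < 2) stop("need >= 2 treatments", call. = FALSE)
  if (nlevels(time) < 2) stop("need >= 2 time levels", call. = FALSE)
  counts <- table(treatment, time)
  if (any(counts == 0)) {
    empty <- which(counts == 0, arr.ind = TRUE)[1, ]
    stop("empty design cell: treatment '", levels(treatment)[empty[1]],
         "' at transfer ", levels(time)[empty[2]], call. = FALSE)
  }
  if (length(unique(as.vector(counts))) > 1) {
    warning("unbalanced design: sequential sums of squares depend on term ",
            "order (treatment, time, treatment:time)", call. = FALSE)
  }

  X_full <- stats::model.matrix(~ treatment * time)
  X_red  <- stats::model.matrix(~ treatment + time)
  X_trt  <- stats::model.matrix(~ treatment)
  n <- nrow(Y)
  Q1 <- matrix(1 / sqrt(n), n, 1)          # intercept space
  Q_trt  <- ortho_basis(X_trt)
  Q_red  <- ortho_basis(X_red)
  Q_full <- ortho_basis(X_full)

  proj_ss <- function(Q, Y) sum((crossprod(Q, Y))^2)
  ss_total <- sum(Y^2) - proj_ss(Q1, Y)
  ss_trt <- proj_ss(Q_trt, Y) - proj_ss(Q1, Y)
  ss_time <- proj_ss(Q_red, Y) - proj_ss(Q_trt, Y)
  ss_int <- proj_ss(Q_full, Y) - proj_ss(Q_red, Y)
  ss_res <- sum(Y^2) - proj_ss(Q_full, Y)

  a <- nlevels(treatment); b <- nlevels(time)
  df <- c(treatment = a - 1, time = b - 1,
          interaction = (a - 1) * (b - 1), residual = n - a * b)
  if (df[["residual"]] <= 0) {
    stop("no residual degrees of freedom: need replicate observations ",
         "within treatment x time cells", call. = FALSE)
  }
  fitted_full <- Q_full %*% crossprod(Q_full, Y)
  fitted_red  <- Q_red %*% crossprod(Q_red, Y)

  grid <- expand.grid(treatment = levels(treatment), time = levels(time),
                      KEEP.OUT.ATTRS = FALSE)
  # saturated factorial: LS means are the per-cell means of fitted values
  cell_key <- interaction(treatment, time, drop = FALSE)
  cm <- rowsum(fitted_full, cell_key) /
    as.vector(table(cell_key)[levels(cell_key)])
  grid_key <- interaction(grid$treatment, grid$time)
  cell_means <- cm[match(as.character(grid_key), rownames(cm)), ,
                   drop = FALSE]
  rownames(cell_means) <- as.character(grid_key)

  ss_table <- data.frame(
    term = c("treatment", "time", "treatment:time", "residual"),
    df = as.numeric(df),
    SS = c(ss_trt, ss_time, ss_int, ss_res),
    stringsAsFactors = FALSE)
  ss_table$MS <- ss_table$SS / ss_table$df

  structure(list(Y = Y, meta = meta, treatment = treatment, time = time,
                 Q_red = Q_red, Q_full = Q_full,
                 fitted = fitted_full, residuals = Y - fitted_full,
                 fitted_reduced = fitted_red,
                 residuals_reduced = Y - fitted_red,
                 ss_table = ss_table, ss_total = ss_total, df = df,
                 cell_grid = grid, cell_means = cell_means,
                 scale = scale),
            class = "pta_fit")
}

#' @export
print.pta_fit <- function(x, ...) {
  cat("Factorial fit: ", ncol(x$Y), " responses, ",
      nlevels(x$treatment), " treatments x ", nlevels(x$time),
      " time levels, n = ", nrow(x$Y), "\n", sep = "")
  print(x$ss_table, row.names = FALSE)
  invisible(x)
}

# Interaction F for a response matrix given precomputed bases/df.
interaction_F <- function(Y, Q_red, Q_full, df) {
  ss_int <- sum((crossprod(Q_full, Y))^2) - sum((crossprod(Q_red, Y))^2)
  ss_res <- sum(Y^2) - sum((crossprod(Q_full, Y))^2)
  if (ss_int <= 0) return(0)
  (ss_int / df[["interaction"]]) / (ss_res / df[["residual"]])
}

#' Permutational MANOVA of the treatment x time interaction (RRPP)
#'
#' Tests whether the effect of time on the multivariate substrate-use
#' phenotype differs between treatments. The observed statistic is the
#' multivariate pseudo-F of the interaction term,
#' `F = (SS_int / df_int) / (SS_res / df_res)`, with sums of squares the
#' traces of the relevant cross-product matrices. The null distribution is
#' generated by randomization of residuals in a permutation procedure
#' (RRPP): residuals of the reduced additive model `treatment + time` are
#' permuted across observations, added back to the reduced-model fitted
#' values, and the full model is refit to each pseudo-dataset.
#'
#' @inheritParams fit_factorial_model
#' @param n_permutations number of permutations (default 999). When the
#'   complete enumeration of row permutations is no larger, the test is
#'   exact.
#' @param seed integer seed for the permutation draws (mandatory).
#' @param transform passed to [perm_test_result()]; `"log"` computes the
#'   effect size Z on log-F.
#' @return a [perm_test_result()] object; `df` carries the interaction and
#'   residual degrees of freedom.
#' @export
rrpp_interaction_test <- function(table, n_permutations = 999, seed,
                                  scale = FALSE,
                                  transform = c("none", "log")) {
  transform <- match.arg(transform)
  fit <- fit_factorial_model(table, scale = scale)
  n <- nrow(fit$Y)
  F_obs <- interaction_F(fit$Y, fit$Q_red, fit$Q_full, fit$df)
  perms <- with_seed(seed, permutation_schedule(n, n_permutations))
  Fr <- fit$fitted_reduced
  Rr <- fit$residuals_reduced
  F_perm <- vapply(seq_len(nrow(perms)), function(i) {
    interaction_F(Fr + Rr[perms[i, ], , drop = FALSE],
                  fit$Q_red, fit$Q_full, fit$df)
  }, numeric(1))
  attr(F_perm, "exact") <- attr(perms, "exact")
  perm_test_result("F (treatment x time)", F_obs, F_perm, seed,
                   transform = transform,
                   df = c(df1 = fit$df[["interaction"]],
                          df2 = fit$df[["residual"]]))
}

#' Principal components of model fitted values
#'
#' Ordination used to visualize evolutionary trajectories: principal
#' components are estimated from the covariance of the full-model fitted
#' values (no variable scaling), and all observations are projected onto
#' them.
#'
#' @param fit a `pta_fit` from [fit_factorial_model()].
#' @return object of class `pta_ordination` with `eigenvalues`,
#'   `proportions` (variance proportions, summing to 1), `scores`
#'   (observations projected onto the components), `loadings` (one row per
#'   substrate), and the design `meta` data for plotting.
#' @export
pca_of_fitted <- function(fit) {
  stopifnot(inherits(fit, "pta_fit"))
  if (nrow(fit$fitted) < 2) stop("need >= 2 observations", call. = FALSE)
  pc <- stats::prcomp(fit$fitted, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  scores <- sweep(fit$Y, 2, colMeans(fit$fitted)) %*% pc$rotation
  structure(list(eigenvalues = ev,
                 proportions = ev / sum(ev),
                 scores = scores,
                 loadings = pc$rotation,
                 meta = fit$meta),
            class = "pta_ordination")
}

#' @export
print.pta_ordination <- function(x, ...) {
  k <- min(3, length(x$proportions))
  cat("PCA of fitted values: first ", k, " components explain ",
      paste0(round(100 * x$proportions[seq_len(k)], 1), "%",
             collapse = ", "),
      " of variation\n", sep = "")
  invisible(x)
}
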