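#' Path length of an ordered trajectory
#'
#' Total Euclidean length of the path traced by an ordered sequence of
#' points in phenotype space: the sum of distances between consecutive
#' points. A single point has length 0.
#'
#' @param points k x p numeric matrix, rows ordered (e.g. by transfer).
#' @return nonnegative scalar.
#' @export
path_length <- function(points) {
  points <- as.matrix(points)
  k <- nrow(points)
  if (k < 1) stop("trajectory needs >= 1 point", call. = FALSE)
  if (k == 1) return(0)
  sum(sqrt(rowSums((points[-1, , drop = FALSE] -
                      points[-k, , drop = FALSE])^2)))
}

# Principal axis of a trajectory: first eigenvector of the covariance of
# its points, sign-oriented so that the displacement from first to last
# point projects positively onto it.
traj_direction <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 2) stop("trajectory needs >= 2 points", call. = FALSE)
  cv <- stats::cov(points)
  if (sum(diag(cv)) <= 0) {
    stop("degenerate direction: trajectory has zero variance", call. = FALSE)
  }
  v <- eigen(cv, symmetric = TRUE)$vectors[, 1]
  disp <- points[nrow(points), ] - points[1, ]
  s <- sum(v * disp)
  if (abs(s) < 1e-12) {
    # symmetric path: orient along increasing time via successive steps
    steps <- points[-1, , drop = FALSE] - points[-nrow(points), , drop = FALSE]
    s <- sum(seq_len(nrow(steps)) * (steps %*% v))
    if (abs(s) < 1e-12) {
      stop("degenerate direction: principal axis orientation is ambiguous",
           call. = FALSE)
    }
  }
  if (s < 0) v <- -v
  v
}

#' Angle between the principal directions of two trajectories
#'
#' Each trajectory's direction is the first eigenvector of the covariance
#' of its points (sign-oriented along increasing time); the angle is
#' `acos` of the absolute dot product, in degrees, hence in \[0, 90\].
#'
#' @param trajA,trajB k x p matrices of ordered trajectory points.
#' @return angle in degrees.
#' @export
direction_angle <- function(trajA, trajB) {
  va <- traj_direction(trajA)
  vb <- traj_direction(trajB)
  acos(min(1, abs(sum(va * vb)))) * 180 / pi
}

# Procrustes-standardized configuration: centroid at the origin, centroid
# size (root summed squared distances from centroid) equal to 1.
shape_config <- function(points) {
  points <- as.matrix(points)
  centered <- sweep(points, 2, colMeans(points))
  size <- sqrt(sum(centered^2))
  if (size <= 0) stop("degenerate shape: zero centroid size", call. = FALSE)
  centered / size
}

#' Procrustes shape distance between two trajectories
#'
#' Both trajectories are translated to a common centroid, scaled to unit
#' centroid size, and optimally superimposed by an orthogonal rotation
#' (solved via singular value decomposition). The shape distance is the
#' square root of the summed squared coordinate differences of the
#' superimposed configurations; it is 0 for trajectories related by any
#' combination of translation, uniform scaling and rotation.
#'
#' @param trajA,trajB k x p matrices with equal k.
#' @return nonnegative scalar.
#' @export
shape_distance <- function(trajA, trajB) {
  a <- shape_config(trajA)
  b <- shape_config(trajB)
  if (!all(dim(a) == dim(b))) {
    stop("trajectories must have the same number of points and dimensions",
         call. = FALSE)
  }
  sv <- svd(crossprod(b, a))
  rot <- sv$u %*% t(sv$v)
  sqrt(sum((a - b %*% rot)^2))
}

#' Build per-treatment trajectories from a factorial fit
#'
#' Extracts, for each treatment, the ordered sequence of least-squares
#' cell means across time levels — the evolutionary trajectory of the
#' multivariate phenotype — and computes its attributes (path length,
#' principal direction, Procrustes shape configuration). Degenerate
#' trajectories (all points identical) are flagged rather than dropped.
#'
#' @param fit a `pta_fit` from [fit_factorial_model()].
#' @return object of class `trajectory_set`: list with `points` (named
#'   list of k x p matrices), `path_length` (named vector), `direction`
#'   (named list of unit vectors or `NULL` when degenerate), `shape`
#'   (named list of standardized configurations or `NULL`), `degenerate`
#'   (named logical).
#' @export
build_trajectories <- function(fit) {
  stopifnot(inherits(fit, "pta_fit"))
  if (nlevels(fit$time) < 2) stop("need >= 2 time levels", call. = FALSE)
  trajectories_from_cellmeans(fit$cell_means, levels(fit$treatment),
                              levels(fit$time))
}

# cell_means: rows named "<treatment>.<time>" in expand.grid order
# (treatment fastest). Shared with the permutation loop of the pairwise
# tests, where cell means are recomputed per pseudo-dataset.
trajectories_from_cellmeans <- function(cell_means, treatments, times) {
  k <- length(times)
  points <- lapply(seq_along(treatments), function(i) {
    idx <- i + (seq_len(k) - 1) * length(treatments)
    m <- cell_means[idx, , drop = FALSE]
    rownames(m) <- times
    m
  })
  names(points) <- treatments
  pl <- vapply(points, path_length, numeric(1))
  degen <- vapply(points, function(m) {
    max(abs(sweep(m, 2, colMeans(m)))) < 1e-12
  }, logical(1))
  direction <- lapply(seq_along(points), function(i) {
    if (degen[i]) NULL else traj_direction(points[[i]])
  })
  shape <- lapply(seq_along(points), function(i) {
    if (degen[i]) NULL else shape_config(points[[i]])
  })
  names(direction) <- names(shape) <- treatments
  structure(list(points = points, path_length = pl, direction = direction,
                 shape = shape, degenerate = degen),
            class = "trajectory_set")
}

#' @export
print.trajectory_set <- function(x, ...) {
  cat("Trajectory set (", length(x$points), " treatments, ",
      nrow(x$points[[1]]), " time points, ", ncol(x$points[[1]]),
      " phenotype dimensions)\n", sep = "")
  cat("Path lengths:\n")
  print(signif(x$path_length, 5))
  if (any(x$degenerate)) {
    cat("Degenerate (zero-variance) trajectories: ",
        paste(names(x$degenerate)[x$degenerate], collapse = ", "), "\n",
        sep = "")
  }
  invisible(x)
}

pair_attribute <- function(traj, A, B, attribute) {
  switch(attribute,
    distance = abs(traj$path_length[[A]] - traj$path_length[[B]]),
    angle = direction_angle(traj$points[[A]], traj$points[[B]]),
    shape = shape_distance(traj$points[[A]], traj$points[[B]]),
    stop("unknown trajectory attribute: ", attribute, call. = FALSE))
}

#' Pairwise permutation tests of trajectory attributes
#'
#' For every pair of treatments, compares an attribute of their
#' evolutionary trajectories: the absolute difference in path length
#' (`"distance"`), the angle between principal directions (`"angle"`), or
#' the Procrustes shape distance (`"shape"`). Null distributions come from
#' the same residual-randomization scheme as [rrpp_interaction_test()]
#' (reduced model `treatment + time`, under which trajectories are
#' parallel): each permutation builds a pseudo-dataset, recomputes the
#' treatment x time cell means, rebuilds the trajectories and re-measures
#' the attribute. All pairs share the same permutation draws.
#'
#' @inheritParams rrpp_interaction_test
#' @param attribute `"distance"`, `"angle"` or `"shape"`.
#' @return named list of [perm_test_result()] objects, one per treatment
#'   pair (`"A:B"`).
#' @export
pairwise_trajectory_tests <- function(table,
                                      attribute = c("distance", "angle",
                                                    "shape"),
                                      n_permutations = 999, seed,
                                      scale = FALSE,
                                      transform = c("none", "log")) {
  attribute <- match.arg(attribute)
  transform <- match.arg(transform)
  fit <- fit_factorial_model(table, scale = scale)
  treatments <- levels(fit$treatment)
  times <- levels(fit$time)
  pairs <- utils::combn(treatments, 2, simplify = FALSE)
  traj_obs <- build_trajectories(fit)
  obs <- vapply(pairs, function(pr) {
    pair_attribute(traj_obs, pr[1], pr[2], attribute)
  }, numeric(1))

  n <- nrow(fit$Y)
  cell_key <- interaction(fit$treatment, fit$time, drop = FALSE)
  cell_counts <- as.vector(table(cell_key))
  grid_order <- levels(cell_key)   # expand.grid order: treatment fastest
  Fr <- fit$fitted_reduced
  Rr <- fit$residuals_reduced
  perms <- with_seed(seed, permutation_schedule(n, n_permutations))
  perm_stats <- matrix(NA_real_, nrow(perms), length(pairs))
  for (i in seq_len(nrow(perms))) {
    Ystar <- Fr + Rr[perms[i, ], , drop = FALSE]
    cm <- rowsum(Ystar, cell_key, reorder = TRUE) / cell_counts
    cm <- cm[grid_order, , drop = FALSE]
    traj <- trajectories_from_cellmeans(cm, treatments, times)
    perm_stats[i, ] <- vapply(pairs, function(pr) {
      pair_attribute(traj, pr[1], pr[2], attribute)
    }, numeric(1))
  }
  out <- lapply(seq_along(pairs), function(j) {
    pd <- perm_stats[, j]
    attr(pd, "exact") <- attr(perms, "exact")
    perm_test_result(paste0("|d ", attribute, "|"), obs[j], pd, seed,
                     transform = transform)
  })
  names(out) <- vapply(pairs, paste, character(1), collapse = ":")
  out
}
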