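#' Malthusian growth parameter
#'
#' Fitness/growth-rate measure of serial-transfer experiments:
#' `ln(nf / n0)` over a growth cycle, optionally divided by the cycle
#' duration to give a per-day rate. The whole-cycle value is the default
#' unit: within a fixed 6-day cycle the time scale cancels from all
#' between-treatment comparisons.
#'
#' @param n0,nf start and end population densities (CFU/mL), strictly
#'   positive; vectorized.
#' @param duration cycle length in days (default 6).
#' @param per_day if `TRUE`, return the per-day rate `ln(nf/n0)/duration`.
#' @return Malthusian parameter(s).
#' @export
malthusian <- function(n0, nf, duration = 6, per_day = FALSE) {
  if (any(n0 <= 0) || any(nf <= 0)) {
    stop("densities must be strictly positive", call. = FALSE)
  }
  m <- log(nf / n0)
  if (per_day) m / duration else m
}

#' Attach Malthusian rates to a growth table
#'
#' @param records growth data.frame with `n0`, `nf` and optional
#'   `duration` columns.
#' @param per_day passed to [malthusian()].
#' @return `records` with a `rate` column appended.
#' @export
growth_rates <- function(records, per_day = FALSE) {
  req <- c("population_id", "treatment", "condition", "n0", "nf")
  missing_cols <- setdiff(req, names(records))
  if (length(missing_cols)) {
    stop("growth table missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  dur <- if ("duration" %in% names(records)) records$duration else 6
  records$rate <- malthusian(records$n0, records$nf, dur, per_day)
  records
}

anova_row <- function(an, row) {
  ss <- an[row, "Sum Sq"]
  if (is.na(an[row, "F value"]) || ss <= 1e-14) {
    list(F = 0, p = 1, df = c(an[row, "Df"], an["Residuals", "Df"]))
  } else {
    list(F = an[row, "F value"], p = an[row, "Pr(>F)"],
         df = c(an[row, "Df"], an["Residuals", "Df"]))
  }
}

#' Two-way ANOVA of growth rates: treatment x growth condition
#'
#' Fixed-effects two-way ANOVA (with interaction) of Malthusian growth
#' rates on evolution treatment and growth condition (alone vs alongside
#' the ancestral community). The treatment x condition interaction is the
#' test of whether evolution changed how growth responds to the community
#' context.
#'
#' @param records growth table with columns `population_id`, `treatment`,
#'   `condition`, `n0`, `nf` and optional `duration`.
#' @param per_day passed to [malthusian()].
#' @return list with the full ANOVA table (`table`), the interaction
#'   `F`, `df` and `p`, and the per-record rates.
#' @export
growth_interaction_anova <- function(records, per_day = FALSE) {
  records <- growth_rates(records, per_day)
  records$treatment <- factor(records$treatment)
  records$condition <- factor(records$condition)
  if (nlevels(records$treatment) < 2 || nlevels(records$condition) < 2) {
    stop("need >= 2 levels of treatment and condition", call. = FALSE)
  }
  if (any(table(records$treatment, records$condition) == 0)) {
    stop("empty treatment x condition cell", call. = FALSE)
  }
  fit <- stats::aov(rate ~ treatment * condition, data = records)
  an <- stats::anova(fit)
  intr <- anova_row(an, "treatment:condition")
  list(table = an, F = intr$F, df = intr$df, p = intr$p, rates = records)
}

#' One-way ANOVA with Tukey HSD pairwise comparisons
#'
#' Used for the competition outcome: final relative abundance of the
#' focal species (per population) compared across evolution treatments,
#' followed by Tukey honest-significant-difference pairwise tests
#' (studentized range, pooled within-group variance).
#'
#' @param values numeric outcome per population.
#' @param groups group labels (e.g. treatment), >= 2 groups with >= 2
#'   values each.
#' @return list with the ANOVA `table`, `F`, `df`, `p`, and `tukey`
#'   (data.frame of pairwise differences with adjusted p-values).
#' @export
competition_oneway_anova <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need >= 2 groups", call. = FALSE)
  if (any(table(groups) < 2)) stop("every group needs >= 2 values",
                                   call. = FALSE)
  fit <- stats::aov(values ~ groups)
  an <- stats::anova(fit)
  main <- anova_row(an, "groups")
  tk <- stats::TukeyHSD(fit)$groups
  tukey <- data.frame(contrast = rownames(tk), diff = tk[, "diff"],
                      lwr = tk[, "lwr"], upr = tk[, "upr"],
                      p_adj = tk[, "p adj"], row.names = NULL,
                      stringsAsFactors = FALSE)
  list(table = an, F = main$F, df = main$df, p = main$p, tukey = tukey)
}

#' Welch's heteroscedastic one-way ANOVA
#'
#' One-way comparison of group means without assuming equal variances
#' (Welch-Satterthwaite approximation for the denominator degrees of
#' freedom), via [stats::oneway.test()].
#'
#' @param values numeric vector.
#' @param groups group labels.
#' @return list with `F`, `df1`, `df2` (fractional), `p`.
#' @export
welch_anova <- function(values, groups) {
  groups <- factor(groups)
  vars <- tapply(values, groups, stats::var)
  if (all(is.na(vars) | vars == 0)) {
    stop("zero within-group variance in all groups: Welch's ANOVA is ",
         "undefined", call. = FALSE)
  }
  ot <- stats::oneway.test(values ~ groups, var.equal = FALSE)
  list(F = unname(ot$statistic), df1 = unname(ot$parameter[1]),
       df2 = unname(ot$parameter[2]), p = unname(ot$p.value))
}
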