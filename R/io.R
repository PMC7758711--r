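check_columns <- function(df, required, what, path) {
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop(what, " file '", path, "' is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
}

#' Read and validate a tidy phenotype CSV
#'
#' Expected header: `replicate_id,treatment,transfer,substrate,value`.
#' Rejects duplicate (replicate, transfer, substrate) keys, negative or
#' non-numeric respiration values and negative transfers, naming the
#' offending row.
#'
#' @param path CSV file path.
#' @return validated data.frame.
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("replicate_id", "treatment", "transfer", "substrate",
                      "value"), "phenotype", path)
  if (!is.numeric(df$value) || anyNA(df$value)) {
    bad <- which(is.na(suppressWarnings(as.numeric(df$value))))[1]
    stop("phenotype row ", bad, ": field 'value' is not numeric",
         call. = FALSE)
  }
  if (any(df$value < 0)) {
    stop("phenotype row ", which(df$value < 0)[1],
         ": field 'value' is negative (respiration must be >= 0)",
         call. = FALSE)
  }
  if (any(df$transfer < 0)) {
    stop("phenotype row ", which(df$transfer < 0)[1],
         ": field 'transfer' must be a nonnegative integer", call. = FALSE)
  }
  key <- paste(df$replicate_id, df$transfer, df$substrate, sep = "|")
  if (anyDuplicated(key)) {
    stop("phenotype row ", which(duplicated(key))[1],
         ": duplicate (replicate_id, transfer, substrate) key",
         call. = FALSE)
  }
  df
}

#' Write a phenotype table to CSV
#' @param table phenotype data.frame.
#' @param path output path.
#' @export
write_phenotypes <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and validate a clone mutation TSV
#'
#' Expected columns: `clone_id`, `treatment`, `locus_tag`,
#' `mutation_class` (optional `gene_name` is carried through). Rows with
#' an empty `locus_tag` register a clone with zero mutations. Unknown
#' mutation classes are rejected.
#'
#' @param path TSV file path.
#' @return a [mutation_profiles()] object.
#' @export
read_mutations <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  check_columns(df, c("clone_id", "treatment", "locus_tag",
                      "mutation_class"), "mutation", path)
  clones <- unique(df[, c("clone_id", "treatment")])
  has_mut <- !is.na(df$locus_tag) & nzchar(df$locus_tag)
  mutation_profiles(clones, df[has_mut, , drop = FALSE])
}

#' Write mutation profiles to TSV
#'
#' Clones with zero mutations are written as a single row with an empty
#' `locus_tag` and `mutation_class`, so the clone roster survives a
#' round trip.
#'
#' @param profiles a [mutation_profiles()] object.
#' @param path output path.
#' @export
write_mutations <- function(profiles, path) {
  stopifnot(inherits(profiles, "mutation_profiles"))
  mut <- profiles$mutations[, c("clone_id", "locus_tag", "mutation_class")]
  mut$treatment <- profiles$clones$treatment[
    match(mut$clone_id, profiles$clones$clone_id)]
  empty <- setdiff(profiles$clones$clone_id, mut$clone_id)
  if (length(empty)) {
    mut <- rbind(mut, data.frame(
      clone_id = empty, locus_tag = "", mutation_class = "",
      treatment = profiles$clones$treatment[
        match(empty, profiles$clones$clone_id)],
      stringsAsFactors = FALSE))
  }
  mut <- mut[, c("clone_id", "treatment", "locus_tag", "mutation_class")]
  utils::write.table(mut, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read and validate a community relative-abundance TSV
#'
#' Expected columns: `replicate_id`, `transfer`, `species`,
#' `rel_abundance`. Every (replicate, transfer) composition must sum to 1
#' within 1e-6 and abundances must lie in \[0, 1\]; violations are
#' rejected naming the offending rows.
#'
#' @param path TSV file path.
#' @return validated data.frame.
#' @export
read_abundance <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  check_columns(df, c("replicate_id", "transfer", "species",
                      "rel_abundance"), "abundance", path)
  if (any(df$rel_abundance < 0 | df$rel_abundance > 1)) {
    stop("abundance row ",
         which(df$rel_abundance < 0 | df$rel_abundance > 1)[1],
         ": field 'rel_abundance' outside [0, 1]", call. = FALSE)
  }
  key <- factor(paste(df$replicate_id, df$transfer, sep = "|"))
  sums <- tapply(df$rel_abundance, key, sum)
  off <- which(abs(sums - 1) > 1e-6)
  if (length(off)) {
    grp <- names(sums)[off[1]]
    rows <- which(as.character(key) == grp)
    stop("abundance rows ", rows[1], "-", rows[length(rows)], " (",
         grp, "): composition sums to ", signif(sums[off[1]], 6),
         ", not 1", call. = FALSE)
  }
  df
}

#' Write an abundance table to TSV
#' @param table abundance data.frame.
#' @param path output path.
#' @export
write_abundance <- function(table, path) {
  utils::write.table(table, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read and validate a growth/density CSV
#'
#' Expected columns: `population_id`, `treatment`, `condition`,
#' `t0_cfu`, `t6_cfu`, optional `duration_days`. Densities must be
#' strictly positive. Returned with the package-standard column names
#' `n0`, `nf`, `duration`.
#'
#' @param path CSV file path.
#' @return validated data.frame.
#' @export
read_growth <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("population_id", "treatment", "condition", "t0_cfu",
                      "t6_cfu"), "growth", path)
  bad <- which(df$t0_cfu <= 0 | df$t6_cfu <= 0)
  if (length(bad)) {
    stop("growth row ", bad[1],
         ": densities must be strictly positive", call. = FALSE)
  }
  out <- data.frame(population_id = df$population_id,
                    treatment = df$treatment, condition = df$condition,
                    n0 = df$t0_cfu, nf = df$t6_cfu,
                    duration = if ("duration_days" %in% names(df))
                      df$duration_days else 6,
                    stringsAsFactors = FALSE)
  out
}

#' Write a growth table to CSV
#' @param records growth data.frame with `n0`, `nf`, `duration` columns.
#' @param path output path.
#' @export
write_growth <- function(records, path) {
  out <- data.frame(population_id = records$population_id,
                    treatment = records$treatment,
                    condition = records$condition,
                    t0_cfu = records$n0, t6_cfu = records$nf,
                    duration_days = if ("duration" %in% names(records))
                      records$duration else 6)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
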