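# Covariate construction: composite IQ and rough median/mode imputation.

#' Composite IQ: median of available IQ measures
#'
#' The composite is the median of all non-missing IQ measurements for a
#' subject (mean of the two central values for an even count); missing if no
#' measurement was observed. Computed before any imputation.
#'
#' @param iq_measures numeric vector (possibly with `NA`s).
#' @return A single number, or `NA` if all inputs are missing.
#' @export
#' @examples
#' composite_iq(c(100, 110, NA, NA))  # 105
composite_iq <- function(iq_measures) {
  x <- iq_measures[!is.na(iq_measures)]
  if (length(x) == 0L) return(NA_real_)
  stats::median(x)
}

#' Add a composite-IQ column to a phenotype table
#'
#' @param pheno data.frame containing the IQ measure columns.
#' @param iq_cols names of the IQ measure columns.
#' @return `pheno` with an `iq_composite` column appended.
#' @export
add_composite_iq <- function(pheno,
                             iq_cols = c("iq_verbal", "iq_performance",
                                         "iq_full2", "iq_full4")) {
  missing_cols <- setdiff(iq_cols, names(pheno))
  if (length(missing_cols)) {
    stop("phenotype table lacks IQ columns: ", paste(missing_cols, collapse = ", "))
  }
  pheno$iq_composite <- apply(as.matrix(pheno[iq_cols]), 1L, composite_iq)
  pheno
}

#' Rough imputation: median for quantitative, mode for categorical columns
#'
#' Missing entries of numeric columns are replaced by the median of the
#' observed values; missing entries of factor/character columns by the mode,
#' with ties broken by the lexicographically smallest level. Observed values
#' are never altered, so the operation is idempotent.
#'
#' @param table data.frame; columns must each have at least one observed
#'   value.
#' @param cols columns to impute (default all).
#' @return The imputed data.frame (no missing values remain in `cols`).
#' @export
#' @examples
#' roughfix_impute(data.frame(age = c(8, NA, 12)))
roughfix_impute <- function(table, cols = names(table)) {
  stopifnot(is.data.frame(table))
  for (cn in cols) {
    x <- table[[cn]]
    miss <- is.na(x)
    if (!any(miss)) next
    if (all(miss)) stop("column '", cn, "' is entirely missing; cannot impute")
    if (is.numeric(x)) {
      x[miss] <- stats::median(x[!miss])
    } else if (is.factor(x)) {
      x[miss] <- stat_mode(x)
    } else if (is.character(x)) {
      x[miss] <- stat_mode(x)
    } else if (is.logical(x)) {
      x[miss] <- as.logical(stat_mode(x))
    } else {
      stop("column '", cn, "' has unsupported type for imputation")
    }
    table[[cn]] <- x
  }
  table
}

#' Prepare model covariates from a raw phenotype table
#'
#' Adds the composite IQ, then rough-imputes the covariate columns used by
#' the classifiers and association models.
#'
#' @param pheno phenotype data.frame (e.g. from [simulate_cohort()]).
#' @return data.frame with complete `age`, `gender`, `handedness`, `site`,
#'   `iq_composite` columns.
#' @export
prepare_covariates <- function(pheno) {
  pheno <- add_composite_iq(pheno)
  roughfix_impute(pheno, intersect(
    c("age", "gender", "handedness", "site", "iq_composite"), names(pheno)
  ))
}
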