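#' Default newborn screening analyte panel
#'
#' Column layout shared by every cohort table in the package. The first seven
#' columns are fixed infant covariates; every further column is one measured
#' analyte (amino acids, acylcarnitines, endocrine/enzyme markers and the
#' hemoglobin fractions HbF, HbF1 and HbA).
#'
#' @name panel
NULL

#' Fixed (non-analyte) cohort columns, in schema order.
#' @rdname panel
#' @export
cohort_core_columns <- c(
  "id", "site", "sex", "birth_weight_g", "ga_weeks",
  "collection_age_hours", "screen_positive"
)

# Analytes whose levels carry gestational-age signal in the default generator,
# beyond the hemoglobin ratio. Kept in screening-strength order.
ga_informative_analytes <- c("17OHP", "C4DC", "TYR", "ALA", "C5", "C5DC")

# Analytes simulated with no GA dependence (pure biological noise).
ga_null_analytes <- c(
  "TSH", "PHE", "LEU", "MET", "CIT", "ARG", "VAL", "GLY", "ORN", "PRO", "SER",
  "C0", "C2", "C3", "C4", "C6", "C8", "C10", "C12", "C14", "C16", "C18",
  "C3DC", "C5OH", "C6DC", "C8DC", "C14OH", "C16OH", "C18OH",
  "GALT", "BIO", "IRT", "SUAC"
)

# Hemoglobin fractions; the modelling feature derived from them is
# hb_ratio = (HbF + HbF1) / (HbF + HbF1 + HbA).
hemoglobin_columns <- c("HbF", "HbF1", "HbA")

#' Analyte columns of a cohort table
#'
#' Every column that is not one of the fixed covariates (and not a derived
#' flag) is treated as a measured analyte.
#'
#' @param cohort a cohort data frame.
#' @return character vector of analyte column names.
#' @export
analyte_columns <- function(cohort) {
  derived <- c("hb_ratio", "preterm", "sga10", "sga3", "lga", "unclassifiable")
  setdiff(names(cohort), c(cohort_core_columns, derived))
}

#' Modelling analytes: measured analytes with the hemoglobin triplet replaced
#' by the derived fetal-to-adult ratio (when the triplet is present).
#'
#' @param cohort a cohort data frame (before or after preprocessing).
#' @return character vector of predictor analyte names.
#' @export
modeling_analytes <- function(cohort) {
  a <- analyte_columns(cohort)
  if (all(hemoglobin_columns %in% a)) {
    c("hb_ratio", setdiff(a, hemoglobin_columns))
  } else {
    setdiff(a, hemoglobin_columns)
  }
}
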