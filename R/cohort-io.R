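# Cohort CSV schema: id, site, sex (M/F), birth_weight_g, ga_weeks,
# collection_age_hours, screen_positive (0/1), then one column per analyte.
# Missing values are written as empty cells; numerics are written with 17
# significant digits so a write/read round trip is lossless.

#' Write a cohort table to CSV
#'
#' @param cohort cohort data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  cols <- intersect(c(cohort_core_columns, analyte_columns(cohort)),
                    names(cohort))
  out <- cohort[, cols, drop = FALSE]
  txt <- vapply(out, function(col) {
    if (is.numeric(col)) {
      s <- sprintf("%.17g", col)
      s[is.na(col)] <- ""
      s
    } else {
      s <- as.character(col)
      s[is.na(s)] <- ""
      s
    }
  }, character(nrow(out)))
  if (nrow(out) == 0) txt <- matrix(character(0), 0, length(cols))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(cols, collapse = ","), con)
  if (nrow(out) > 0) {
    writeLines(apply(txt, 1, paste, collapse = ","), con)
  }
  invisible(path)
}

#' Read a cohort table from CSV
#'
#' Validates the schema (all core columns present, `sex` in M/F,
#' `screen_positive` 0/1) and reports the exact row and column of any
#' non-numeric cell in a numeric column.
#'
#' @param path CSV path written by [write_cohort()] (or matching its schema).
#' @return cohort data frame.
#' @export
read_cohort <- function(path) {
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                         na.strings = NULL)
  missing_core <- setdiff(cohort_core_columns, names(raw))
  if (length(missing_core)) {
    stop(sprintf("schema_error: missing column(s): %s",
                 paste(missing_core, collapse = ", ")), call. = FALSE)
  }
  numeric_cols <- setdiff(names(raw), c("id", "site", "sex"))
  out <- raw
  for (cn in numeric_cols) {
    v <- raw[[cn]]
    blank <- v == ""
    num <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(num) & !blank)
    if (length(bad)) {
      stop(sprintf("parse_error: non-numeric value '%s' in column '%s', row %d",
                   v[bad[1]], cn, bad[1]), call. = FALSE)
    }
    num[blank] <- NA_real_
    out[[cn]] <- num
  }
  for (cn in c("id", "site", "sex")) out[[cn]][out[[cn]] == ""] <- NA_character_
  bad_sex <- !is.na(out$sex) & !out$sex %in% c("M", "F")
  if (any(bad_sex)) {
    stop(sprintf("parse_error: invalid sex '%s' in row %d",
                 out$sex[which(bad_sex)[1]], which(bad_sex)[1]), call. = FALSE)
  }
  sp <- out$screen_positive
  if (any(!is.na(sp) & !sp %in% c(0, 1))) {
    stop("parse_error: screen_positive must be 0/1", call. = FALSE)
  }
  out$screen_positive <- as.integer(sp)
  out
}
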