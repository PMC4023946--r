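#' @keywords internal
"_PACKAGE"

## Canonical column layout of a cohort table. Binary covariates are coded
## 0/1 (NA = missing); procedure_type is a 6-level factor with
## "gastrointestinal" as the reference category throughout.

#' Names of the binary patient covariates
#'
#' The ten dichotomous patient-level covariates used by the SSI risk models,
#' in the order they appear in cohort files and coefficient tables.
#'
#' @return Character vector of column names.
#' @export
binary_covariates <- function() {
  c("gender_female", "age_ge65", "asa_gt2", "preop_ge48h", "altemeier_gt2",
    "endoscopic", "duration_gt_p75", "emergency", "ambulatory",
    "followup_ge15")
}

#' Names of the modelling covariates
#'
#' The eleven patient covariates entering the multivariate models: the ten
#' binary indicators plus the six-category surgical procedure type.
#'
#' @return Character vector of covariate names.
#' @export
model_covariates <- function() {
  c("gender_female", "age_ge65", "asa_gt2", "preop_ge48h", "altemeier_gt2",
    "endoscopic", "procedure_type", "duration_gt_p75", "emergency",
    "ambulatory", "followup_ge15")
}

#' Levels of the procedure-type covariate
#'
#' @return Character vector; the first level ("gastrointestinal") is the
#'   reference category in all models.
#' @export
procedure_levels <- function() {
  c("gastrointestinal", "gynecologic", "cardiovascular", "orthopedic",
    "ophthalmic", "other")
}

cohort_required_cols <- function() {
  c("hospital_id", "ward_id", "ssi", binary_covariates(), "procedure_type")
}

cohort_optional_cols <- function() {
  c("duration_minutes", "followup_days")
}

#' Construct a cohort table
#'
#' Validates a patient-level data frame and stamps it with the `ssi_cohort`
#' class. A cohort holds one row per surgical procedure with hospital and
#' ward identifiers, the binary SSI outcome, and the patient covariates.
#'
#' @param df Data frame with at least `hospital_id`, `ward_id`, `ssi`, the
#'   binary covariates of [binary_covariates()] and `procedure_type`.
#' @param provenance Free-text provenance string stored as an attribute.
#' @return A data frame of class `ssi_cohort`.
#' @export
as_cohort <- function(df, provenance = "unspecified") {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  missing_cols <- setdiff(cohort_required_cols(), names(df))
  if (length(missing_cols) > 0L) {
    stop("cohort is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (nrow(df) == 0L) stop("cohort has no records")
  for (col in c("ssi", binary_covariates())) {
    v <- df[[col]]
    bad <- which(!(is.na(v) | v %in% c(0, 1)))
    if (length(bad) > 0L) {
      stop(sprintf("non-binary value in column '%s' at row %d", col, bad[1]))
    }
    df[[col]] <- as.integer(v)
  }
  if (anyNA(df$ssi)) {
    stop(sprintf("missing outcome in column 'ssi' at row %d",
                 which(is.na(df$ssi))[1]))
  }
  pt <- as.character(df$procedure_type)
  bad <- which(!(is.na(pt) | pt %in% procedure_levels()))
  if (length(bad) > 0L) {
    stop(sprintf("unknown procedure_type '%s' at row %d", pt[bad[1]], bad[1]))
  }
  df$procedure_type <- factor(pt, levels = procedure_levels())
  ## each ward must live in exactly one hospital
  map <- unique(df[, c("hospital_id", "ward_id")])
  dup <- map$ward_id[duplicated(map$ward_id)]
  if (length(dup) > 0L) {
    stop("ward_id '", dup[1], "' appears under more than one hospital_id")
  }
  attr(df, "provenance") <- provenance
  class(df) <- c("ssi_cohort", "data.frame")
  df
}

#' @export
print.ssi_cohort <- function(x, ...) {
  cat(sprintf(
    "SSI cohort: %d patients, %d wards, %d hospitals, %d SSI (%.2f%%)\n",
    nrow(x), length(unique(x$ward_id)), length(unique(x$hospital_id)),
    sum(x$ssi), 100 * mean(x$ssi)))
  cat("provenance:", attr(x, "provenance"), "\n")
  invisible(x)
}

#' Write a cohort to CSV
#'
#' Writes the cohort in the package's CSV dialect: UTF-8, comma-separated,
#' fixed header order (`hospital_id, ward_id, ssi`, the binary covariates,
#' `procedure_type`, then any of `duration_minutes`, `followup_days`
#' present), missing values as empty fields.
#'
#' @param cohort An `ssi_cohort`.
#' @param path File path to write to.
#' @return Invisibly, `path`.
#' @export
write_cohort <- function(cohort, path) {
  cols <- c(cohort_required_cols(),
            intersect(cohort_optional_cols(), names(cohort)))
  out <- as.data.frame(cohort)[, cols]
  out$procedure_type <- as.character(out$procedure_type)
  utils::write.csv(out, path, row.names = FALSE, na = "", quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a cohort from CSV
#'
#' Parses a file written in the dialect of [write_cohort()]. Binary columns
#' admit only `0`, `1` or an empty field (missing); any other value is a
#' parse error naming the offending row and column. Unknown columns are a
#' parse error.
#'
#' @param path File path to read.
#' @return An `ssi_cohort`; provenance records the source filename.
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "",
                        fileEncoding = "UTF-8")
  unknown <- setdiff(names(df),
                     c(cohort_required_cols(), cohort_optional_cols()))
  if (length(unknown) > 0L) {
    stop("unknown column(s) in cohort file: ", paste(unknown, collapse = ", "))
  }
  for (col in intersect(c("ssi", binary_covariates()), names(df))) {
    v <- df[[col]]
    bad <- which(!(is.na(v) | v %in% c(0, 1)))
    if (length(bad) > 0L) {
      stop(sprintf("parse error in column '%s', row %d: value '%s' is not 0/1",
                   col, bad[1], v[bad[1]]))
    }
  }
  as_cohort(df, provenance = paste0("file:", basename(path)))
}
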