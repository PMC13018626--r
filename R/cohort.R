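#' Cohort column schema
#'
#' Describes the expected columns of a cohort CSV: one row per patient,
#' demographic/comorbidity/imaging/operative features plus 14 binary
#' postoperative event columns (8 ICU-level, 6 IMC-level). Booleans are
#' stored as 0/1 so that CSV round trips are bit-exact. An optional numeric
#' column `intraop_risk_range` is accepted but not required (a generic slot
#' for intraoperative risk summaries whose construction is site-specific).
#'
#' @return data.frame with columns `column`, `type`
#'   (one of id/numeric/integer/binary/categorical) and `levels`
#'   (comma-separated vocabulary for categoricals, otherwise `NA`).
#' @export
cohort_schema <- function() {
  rbind(
    data.frame(column = "patient_id", type = "id", levels = NA_character_),
    data.frame(column = c("age", "bmi", "weight", "tumor_volume",
                          "surgery_duration"),
               type = "numeric", levels = NA_character_),
    data.frame(column = c("asa", "gcs"), type = "integer",
               levels = NA_character_),
    data.frame(column = "sex", type = "categorical", levels = "female,male"),
    data.frame(column = "tumor_location", type = "categorical",
               levels = "supratentorial,infratentorial"),
    data.frame(column = "suspected_diagnosis", type = "categorical",
               levels = paste("meningioma", "metastasis", "LGG", "HGG", "GBM",
                              "neuroma", "haemangioblastoma", "other",
                              sep = ",")),
    data.frame(column = "surgical_position", type = "categorical",
               levels = "supine,prone,semi_sitting,lateral"),
    data.frame(column = c("preop_deficit", "seizure_history", "hypertension",
                          "coagulation_disorder", "diabetes",
                          "cardiovascular_disease", "pulmonary_disease",
                          "other_disease", "hydrocephalus", "midline_shift",
                          icu_event_columns(), imc_event_columns()),
               type = "binary", levels = NA_character_)
  )
}

schema_levels <- function(schema, column) {
  strsplit(schema$levels[schema$column == column], ",", fixed = TRUE)[[1]]
}

#' Read a patient cohort from CSV
#'
#' Strict reader: every schema column must be present, no missing values are
#' tolerated (rows are rejected, never imputed), categorical values must come
#' from the closed vocabularies, and basic plausibility invariants
#' (age > 0, 3 <= GCS <= 15, tumor volume >= 0, surgery duration > 0,
#' unique patient ids) are enforced.
#'
#' @param path CSV file path (comma-separated, UTF-8, header required).
#' @param schema column specification, defaults to [cohort_schema()].
#' @param name cohort name stored as an attribute.
#' @return a `triage_cohort` data.frame.
#' @export
read_cohort <- function(path, schema = cohort_schema(), name = basename(path)) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  missing_cols <- setdiff(schema$column, names(raw))
  if (length(missing_cols) > 0L) {
    stop("cohort schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  }
  as_cohort(raw, schema = schema, name = name)
}

#' @rdname read_cohort
#' @param x data.frame of raw (character or typed) cohort columns.
#' @export
as_cohort <- function(x, schema = cohort_schema(), name = "cohort") {
  missing_cols <- setdiff(schema$column, names(x))
  if (length(missing_cols) > 0L) {
    stop("cohort schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  }
  ids <- as.character(x$patient_id)
  blank <- function(v) is.na(v) | (is.character(v) & trimws(v) == "")
  for (i in seq_len(nrow(schema))) {
    col <- schema$column[i]
    v <- x[[col]]
    bad <- blank(v)
    if (any(bad)) {
      stop("missing value in column '", col, "' for patient_id ",
           paste(ids[bad], collapse = ", "))
    }
    x[[col]] <- switch(
      schema$type[i],
      id = as.character(v),
      numeric = as.numeric(v),
      integer = as.integer(v),
      binary = {
        b <- as.integer(v)
        if (any(is.na(b)) || !all(b %in% c(0L, 1L))) {
          stop("column '", col, "' must be 0/1")
        }
        b
      },
      categorical = {
        vocab <- schema_levels(schema, col)
        v <- as.character(v)
        if (!all(v %in% vocab)) {
          stop("vocabulary error in column '", col, "': unknown value(s) ",
               paste(unique(setdiff(v, vocab)), collapse = ", "))
        }
        v
      }
    )
    if (any(is.na(x[[col]]))) {
      stop("column '", col, "' could not be parsed as ", schema$type[i])
    }
  }
  if (anyDuplicated(x$patient_id)) stop("duplicate patient_id in cohort")
  if (any(x$age <= 0)) stop("invariant violated: age must be > 0")
  if (any(x$gcs < 3L | x$gcs > 15L)) stop("invariant violated: GCS in 3..15")
  if (any(x$asa < 1L | x$asa > 4L)) stop("invariant violated: ASA in 1..4")
  if (any(x$tumor_volume < 0)) stop("invariant violated: tumor_volume >= 0")
  if (any(x$surgery_duration <= 0)) {
    stop("invariant violated: surgery_duration > 0")
  }
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  attr(x, "name") <- name
  class(x) <- c("triage_cohort", "data.frame")
  x
}

#' Write a cohort to CSV
#'
#' Inverse of [read_cohort()]: `read_cohort(write_cohort(x, p))` reproduces
#' `x` field-for-field.
#'
#' @param cohort a `triage_cohort` data.frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Numeric feature matrix for the boosted-tree learner
#'
#' Encodes the prognostic features (everything except patient id and the
#' postoperative event columns, which define the outcome) as a numeric
#' matrix. Binary columns stay 0/1, `sex` becomes an indicator for male,
#' `tumor_location` an indicator for infratentorial, and the remaining
#' categoricals are integer-coded in vocabulary order (trees partition on
#' thresholds, so ordinal coding of nominal levels costs at most extra
#' splits, not expressiveness).
#'
#' @param cohort a `triage_cohort` data.frame.
#' @return numeric matrix with one column per feature.
#' @export
cohort_feature_matrix <- function(cohort) {
  schema <- cohort_schema()
  code <- function(col) {
    vocab <- schema_levels(schema, col)
    match(cohort[[col]], vocab) - 1L
  }
  X <- cbind(
    age = cohort$age,
    sex_male = as.integer(cohort$sex == "male"),
    asa = cohort$asa,
    bmi = cohort$bmi,
    weight = cohort$weight,
    gcs = cohort$gcs,
    preop_deficit = cohort$preop_deficit,
    seizure_history = cohort$seizure_history,
    hypertension = cohort$hypertension,
    coagulation_disorder = cohort$coagulation_disorder,
    diabetes = cohort$diabetes,
    cardiovascular_disease = cohort$cardiovascular_disease,
    pulmonary_disease = cohort$pulmonary_disease,
    other_disease = cohort$other_disease,
    tumor_volume = cohort$tumor_volume,
    hydrocephalus = cohort$hydrocephalus,
    midline_shift = cohort$midline_shift,
    tumor_location_infra = as.integer(cohort$tumor_location == "infratentorial"),
    suspected_diagnosis = code("suspected_diagnosis"),
    surgery_duration = cohort$surgery_duration,
    surgical_position = code("surgical_position")
  )
  storage.mode(X) <- "double"
  X
}
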