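# Table schemas for the three registry extracts (maternal, infant, cause-of-death
# questionnaire). Files are plain UTF-8 CSV; missing values are empty fields;
# logical flags are encoded 1/0.

SCHEMA_VERSION <- "1.0"

#' Enumerated level dictionaries used across the registry schema
#'
#' Fixed level sets for every categorical column in the maternal and infant
#' tables. Readers reject values outside these sets; the synthetic generator
#' draws from them.
#'
#' @format A named list of character vectors, one per categorical variable.
#' @export
registry_enums <- list(
  age_category        = c("lt20", "20-25", "26-30", "gt30"),
  education           = c("no_formal", "primary_secondary", "university_plus"),
  bmi_category        = c("underweight", "normal", "overweight"),
  parity_category     = c("0", "1-2", "3plus"),
  anc_visits_category = c("0-1", "2", "3", "4plus"),
  ga_at_enrollment_category = c("lt8", "8-11.6", "12-20", "gt20"),
  delivery_attendant  = c("obstetrician", "non_ob_physician", "nurse_midwife",
                          "tba", "family", "self", "other"),
  delivery_location   = c("hospital", "clinic_health_center", "home", "other"),
  birth_outcome       = c("live_birth", "stillbirth", "miscarriage",
                          "medical_termination"),
  cause_of_death      = c("congenital_anomaly", "infection", "prematurity",
                          "asphyxia", "unknown")
)

.maternal_flags <- c("resident_in_cluster", "died_before_delivery",
                     "pregnancy_complication")
.maternal_enum_cols <- c("age_category", "education", "bmi_category",
                         "parity_category", "anc_visits_category",
                         "ga_at_enrollment_category", "delivery_attendant",
                         "delivery_location")

.infant_flags <- c("multiple_gestation", "alive_at_28d", "skin_to_skin",
                   "bathed_within_6h", "breastfed_within_1h", "bag_mask",
                   "antibiotics", "oxygen", "cpap", "mech_vent",
                   "cod_form_available")

.cod_flags <- c("major_congenital_anomaly", "tetanus", "omphalitis", "sepsis",
                "pneumonia", "infection_suspected",
                "breathing_difficulty_at_birth", "respiratory_distress",
                "maternal_pregnancy_complication")

#' Registry table schema
#'
#' Column names, flag columns, enum columns and numeric columns for each of
#' the three registry tables, under a named schema version. `read_tables()`
#' rejects a file whose header set does not match the declared version.
#'
#' @return A list with elements `version` and per-table column declarations.
#' @export
registry_schema <- function() {
  list(
    version = SCHEMA_VERSION,
    maternal = list(
      columns = c("mother_id", "cluster_id", "delivery_year",
                  .maternal_flags[1:2], .maternal_enum_cols,
                  "pregnancy_complication"),
      flags = .maternal_flags,
      enums = .maternal_enum_cols,
      integers = "delivery_year"
    ),
    infant = list(
      columns = c("infant_id", "mother_id", "birth_outcome", "birth_weight_g",
                  "ga_delivery_weeks", "multiple_gestation", "alive_at_28d",
                  "age_at_death_days", "skin_to_skin", "bathed_within_6h",
                  "breastfed_within_1h", "bag_mask", "antibiotics", "oxygen",
                  "cpap", "mech_vent", "cod_form_available"),
      flags = .infant_flags,
      enums = "birth_outcome",
      integers = "age_at_death_days",
      numerics = c("birth_weight_g", "ga_delivery_weeks")
    ),
    cod = list(
      columns = c("infant_id", .cod_flags[1:6], "ga_delivery_weeks",
                  "birth_weight_g", .cod_flags[7:9]),
      flags = .cod_flags,
      enums = character(0),
      numerics = c("ga_delivery_weeks", "birth_weight_g")
    )
  )
}

.decode_enum <- function(x, col, table, levels) {
  x[x == ""] <- NA_character_
  bad <- which(!is.na(x) & !x %in% levels)
  if (length(bad)) {
    stop(sprintf(
      "table '%s', column '%s', row %d: unknown value '%s' (valid: %s)",
      table, col, bad[1], x[bad[1]], paste(levels, collapse = ", ")),
      call. = FALSE)
  }
  factor(x, levels = levels)
}

.decode_num <- function(x, col, table) {
  x[x == ""] <- NA_character_
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & is.na(out))
  if (length(bad)) {
    stop(sprintf("table '%s', column '%s', row %d: non-numeric value '%s'",
                 table, col, bad[1], x[bad[1]]), call. = FALSE)
  }
  out
}

.decode_table <- function(raw, spec, table) {
  expected <- spec$columns
  if (!setequal(names(raw), expected)) {
    missing <- setdiff(expected, names(raw))
    extra <- setdiff(names(raw), expected)
    stop(sprintf(
      "table '%s' header does not match schema %s%s%s", table, SCHEMA_VERSION,
      if (length(missing)) paste0("; missing: ", paste(missing, collapse = ", ")) else "",
      if (length(extra)) paste0("; unexpected: ", paste(extra, collapse = ", ")) else ""),
      call. = FALSE)
  }
  raw <- raw[expected]
  for (col in intersect(spec$flags, names(raw))) {
    v <- as.character(raw[[col]])
    v[v == ""] <- NA_character_
    bad <- which(!is.na(v) & !v %in% c("0", "1", "TRUE", "FALSE"))
    if (length(bad)) {
      stop(sprintf("table '%s', column '%s', row %d: invalid flag value '%s'",
                   table, col, bad[1], v[bad[1]]), call. = FALSE)
    }
    raw[[col]] <- ifelse(is.na(v), NA, v %in% c("1", "TRUE"))
  }
  for (col in spec$enums) {
    raw[[col]] <- .decode_enum(as.character(raw[[col]]), col, table,
                               registry_enums[[col]])
  }
  for (col in c(spec$integers, spec$numerics)) {
    if (!is.null(col) && col %in% names(raw)) {
      raw[[col]] <- .decode_num(as.character(raw[[col]]), col, table)
    }
  }
  raw
}

#' Read and validate the three registry CSV tables
#'
#' Reads the maternal, infant and cause-of-death questionnaire CSVs, checks
#' each header against the shipped schema, decodes flags and enumerations,
#' and fails with the offending table, column, row and value on any
#' malformed field.
#'
#' @param maternal,infant,cod Paths to the three CSV files. `cod` may be
#'   `NULL` when no questionnaire table is available.
#' @return A list with data frames `maternal`, `infant`, `cod` (the latter
#'   `NULL` if not supplied) and a `validation` element counting missing
#'   fields per table.
#' @export
read_tables <- function(maternal, infant, cod = NULL) {
  schema <- registry_schema()
  read_one <- function(path, name) {
    if (!file.exists(path)) {
      stop(sprintf("file not found for table '%s': %s", name, path),
           call. = FALSE)
    }
    raw <- utils::read.csv(path, colClasses = "character",
                           check.names = FALSE, fileEncoding = "UTF-8")
    .decode_table(raw, schema[[name]], name)
  }
  out <- list(
    maternal = read_one(maternal, "maternal"),
    infant = read_one(infant, "infant"),
    cod = if (!is.null(cod)) read_one(cod, "cod") else NULL
  )
  out$validation <- lapply(out[!vapply(out, is.null, TRUE)], function(df) {
    if (is.data.frame(df)) c(rows = nrow(df), missing_fields = sum(is.na(df)))
  })
  out
}

.encode_for_csv <- function(df) {
  for (col in names(df)) {
    v <- df[[col]]
    if (is.logical(v)) {
      df[[col]] <- ifelse(is.na(v), "", ifelse(v, "1", "0"))
    } else if (is.factor(v)) {
      df[[col]] <- ifelse(is.na(v), "", as.character(v))
    } else if (is.numeric(v)) {
      df[[col]] <- ifelse(is.na(v), "", format(v, trim = TRUE, scientific = FALSE))
    } else {
      df[[col]] <- ifelse(is.na(v), "", as.character(v))
    }
  }
  df
}

#' Write a registry table to CSV
#'
#' Inverse of [read_tables()]: flags become 1/0, missing values empty fields.
#' Output is byte-stable for identical inputs, which the pipeline relies on
#' for reproducibility checks.
#'
#' @param df A decoded registry table.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_registry_csv <- function(df, path) {
  utils::write.csv(.encode_for_csv(df), path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8", eol = "\n")
  invisible(path)
}
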