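#' @include AllClasses.R
NULL

SCHEMA_VERSION <- "1"

STORE_TABLES <- c("person", "sample", "analyte", "source", "aliquot_fact",
                  "vocabulary", "vocabulary_map", "audit_log", "meta")

schema_sql <- function() c(
  "CREATE TABLE meta (key TEXT PRIMARY KEY, value TEXT NOT NULL)",
  "CREATE TABLE person (
     person_key    INTEGER PRIMARY KEY AUTOINCREMENT,
     person_id_ext TEXT NOT NULL,
     project       TEXT NOT NULL DEFAULT 'default',
     gender        TEXT NOT NULL DEFAULT 'unknown',
     ethnicity     TEXT NOT NULL DEFAULT 'unknown',
     condition     TEXT NOT NULL DEFAULT 'unknown',
     treatment     TEXT NOT NULL DEFAULT 'unknown',
     response      TEXT NOT NULL DEFAULT 'unknown',
     age_years     INTEGER,
     age_band      TEXT,
     UNIQUE (person_id_ext, project),
     CHECK ((age_years IS NULL) = (age_band IS NULL)))",
  "CREATE TABLE sample (
     sample_key    INTEGER PRIMARY KEY AUTOINCREMENT,
     sample_id_ext TEXT NOT NULL,
     project       TEXT NOT NULL DEFAULT 'default',
     person_key    INTEGER REFERENCES person (person_key),
     year INTEGER CHECK (year IS NULL OR year >= 0),
     month INTEGER CHECK (month IS NULL OR month >= 0),
     week INTEGER CHECK (week IS NULL OR week >= 0),
     day INTEGER CHECK (day IS NULL OR day >= 0),
     draw INTEGER CHECK (draw IS NULL OR draw >= 0),
     UNIQUE (sample_id_ext, project))",
  "CREATE TABLE analyte (
     analyte_key  INTEGER PRIMARY KEY AUTOINCREMENT,
     analyte_name TEXT NOT NULL,
     assay_family TEXT NOT NULL,
     UNIQUE (analyte_name, assay_family))",
  "CREATE TABLE source (
     source_key  INTEGER PRIMARY KEY AUTOINCREMENT,
     file_name   TEXT NOT NULL,
     file_hash   TEXT NOT NULL,
     upload_date TEXT NOT NULL,
     assay       TEXT NOT NULL CHECK (assay <> ''),
     run_date    TEXT,
     operator    TEXT,
     instrument  TEXT,
     lot         TEXT,
     pi          TEXT,
     project     TEXT,
     tissue      TEXT,
     timepoint_hint TEXT,
     UNIQUE (file_name, file_hash))",
  "CREATE TABLE aliquot_fact (
     fact_key       INTEGER PRIMARY KEY AUTOINCREMENT,
     aliquot_id_ext TEXT NOT NULL CHECK (aliquot_id_ext <> ''),
     analyte_key    INTEGER NOT NULL REFERENCES analyte (analyte_key),
     sample_key     INTEGER REFERENCES sample (sample_key),
     source_key     INTEGER NOT NULL REFERENCES source (source_key),
     tissue         TEXT NOT NULL DEFAULT 'unknown',
     stim           TEXT NOT NULL DEFAULT 'none',
     readout        REAL NOT NULL,
     units          TEXT NOT NULL CHECK (units <> ''),
     quantification TEXT NOT NULL
       CHECK (quantification IN ('in_range','below_loq','above_loq')),
     UNIQUE (aliquot_id_ext, analyte_key, source_key, stim))",
  "CREATE INDEX idx_fact_sample ON aliquot_fact (sample_key)",
  "CREATE INDEX idx_fact_aliquot ON aliquot_fact (aliquot_id_ext)",
  "CREATE TABLE vocabulary (
     attribute   TEXT NOT NULL,
     scope       TEXT NOT NULL,
     valid_value TEXT NOT NULL,
     UNIQUE (attribute, scope, valid_value))",
  "CREATE TABLE vocabulary_map (
     attribute   TEXT NOT NULL,
     scope       TEXT NOT NULL,
     incoming    TEXT NOT NULL,
     valid_value TEXT NOT NULL,
     UNIQUE (attribute, scope, incoming))",
  "CREATE TABLE audit_log (
     audit_key INTEGER PRIMARY KEY AUTOINCREMENT,
     ts        TEXT NOT NULL,
     action    TEXT NOT NULL,
     detail    TEXT)"
)

#' Create or reopen a warehouse store
#'
#' Creates the star schema (fact table plus the four dimension tables,
#' vocabulary tables and audit log) in a single-file embedded relational
#' store, or reopens an existing one. Reopening preserves all contents;
#' a file that is not a valid store is rejected.
#'
#' @param path file path for the store; `":memory:"` gives a transient
#'   in-memory store (useful for tests and simulations)
#' @return an [AssayWarehouse-class] handle
#' @seealso [closeStore()], [integrityReport()], [upsertDimension()]
#' @export
#' @examples
#' wh <- createStore(":memory:")
#' integrityReport(wh)$n_facts
#' closeStore(wh)
createStore <- function(path) {
  existed <- path != ":memory:" && file.exists(path)
  con <- tryCatch(suppressWarnings(DBI::dbConnect(RSQLite::SQLite(), path)),
    error = function(e) stop("schema validation failed: '", path,
                             "' is not a valid warehouse store (",
                             conditionMessage(e), ")", call. = FALSE))
  DBI::dbExecute(con, "PRAGMA foreign_keys = ON")
  if (existed) {
    ok <- tryCatch({
      tabs <- DBI::dbListTables(con)
      all(STORE_TABLES %in% tabs) &&
        identical(DBI::dbGetQuery(con,
          "SELECT value FROM meta WHERE key = 'schema_version'")$value,
          SCHEMA_VERSION)
    }, error = function(e) FALSE)
    if (!ok) {
      DBI::dbDisconnect(con)
      stop("schema validation failed: '", path,
           "' is not a valid warehouse store", call. = FALSE)
    }
  } else {
    DBI::dbWithTransaction(con, {
      for (s in schema_sql()) DBI::dbExecute(con, s)
      DBI::dbExecute(con,
        "INSERT INTO meta (key, value) VALUES ('schema_version', ?)",
        params = list(SCHEMA_VERSION))
    })
    seed_default_vocabularies(con)
  }
  methods::new("AssayWarehouse", con = con, path = path)
}

#' Close a warehouse store
#' @param store an [AssayWarehouse-class]
#' @return invisibly `TRUE`
#' @export
closeStore <- function(store) {
  DBI::dbDisconnect(store@con)
  invisible(TRUE)
}

audit <- function(store, action, detail = NULL) {
  DBI::dbExecute(store@con,
    "INSERT INTO audit_log (ts, action, detail) VALUES (?, ?, ?)",
    params = list(format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), action,
                  if (is.null(detail)) NA_character_
                  else jsonlite::toJSON(detail, auto_unbox = TRUE)))
  invisible(NULL)
}

# ---------------------------------------------------------------------------
# dimension upserts
# ---------------------------------------------------------------------------

validate_person <- function(r) {
  assert_scalar_string(r$person_id_ext, "person_id_ext")
  if (!is.null(r$age_years) && !is.na(r$age_years)) {
    if (is.na(suppressWarnings(as.integer(r$age_years))))
      stop("field 'age_years' must be an integer", call. = FALSE)
  }
  invisible(r)
}

validate_sample <- function(r) {
  assert_scalar_string(r$sample_id_ext, "sample_id_ext")
  for (f in SAMPLE_ATTRS) {
    v <- r[[f]]
    if (!is.null(v) && !is.na(v)) {
      iv <- suppressWarnings(as.integer(v))
      if (is.na(iv) || iv != as.numeric(v) || iv < 0L)
        stop("field '", f, "' must be a non-negative integer", call. = FALSE)
    }
  }
  invisible(r)
}

#' Insert or update a dimension record
#'
#' Upserts a record into one of the four dimension tables, returning the
#' surrogate key. When the record's natural key already exists the existing
#' surrogate key is returned (and, for persons/samples, non-missing
#' attributes are updated); surrogate keys are never reused. Sources are
#' never updated: a duplicate `(file_name, file_hash)` is rejected, which
#' is what makes batch loads idempotent.
#'
#' Natural keys: person `(person_id_ext, project)`; sample
#' `(sample_id_ext, project)`; analyte `(analyte_name, assay_family)`;
#' source `(file_name, file_hash)`.
#'
#' @param store an [AssayWarehouse-class]
#' @param table one of `"person"`, `"sample"`, `"analyte"`, `"source"`
#' @param record named list of fields for the record
#' @return the surrogate key (integer)
#' @export
upsertDimension <- function(store, table, record) {
  table <- match.arg(table, c("person", "sample", "analyte", "source"))
  con <- store@con
  switch(table,
    person = {
      validate_person(record)
      project <- record$project %||% "default"
      key <- DBI::dbGetQuery(con,
        "SELECT person_key FROM person WHERE person_id_ext = ? AND project = ?",
        params = list(record$person_id_ext, project))$person_key
      age <- record$age_years %||% NA
      age <- if (is.na(age)) NA_integer_ else as.integer(age)
      vals <- list(
        gender = record$gender %||% "unknown",
        ethnicity = record$ethnicity %||% "unknown",
        condition = record$condition %||% "unknown",
        treatment = record$treatment %||% "unknown",
        response = record$response %||% "unknown",
        age_years = age,
        age_band = if (is.na(age)) NA_character_ else ageBand(age))
      if (length(key)) {
        set <- names(record)[names(record) %in%
                             c(PERSON_ATTRS, "age_years")]
        if (length(set)) {
          set <- unique(c(set, if ("age_years" %in% set) "age_band"))
          DBI::dbExecute(con, paste0("UPDATE person SET ",
            paste0(set, " = ?", collapse = ", "), " WHERE person_key = ?"),
            params = c(unname(vals[set]), list(key[1L])))
        }
        return(as.integer(key[1L]))
      }
      DBI::dbExecute(con,
        "INSERT INTO person (person_id_ext, project, gender, ethnicity,
           condition, treatment, response, age_years, age_band)
         VALUES (?,?,?,?,?,?,?,?,?)",
        params = c(list(record$person_id_ext, project), unname(vals)))
      as.integer(DBI::dbGetQuery(con,
        "SELECT last_insert_rowid() AS k")$k)
    },
    sample = {
      validate_sample(record)
      project <- record$project %||% "default"
      key <- DBI::dbGetQuery(con,
        "SELECT sample_key FROM sample WHERE sample_id_ext = ? AND project = ?",
        params = list(record$sample_id_ext, project))$sample_key
      tp <- lapply(SAMPLE_ATTRS, function(f) {
        v <- record[[f]] %||% NA
        if (is.na(v)) NA_integer_ else as.integer(v)
      })
      names(tp) <- SAMPLE_ATTRS
      pk <- record$person_key %||% NA
      pk <- if (is.na(pk)) NA_integer_ else as.integer(pk)
      if (length(key)) {
        set <- names(record)[names(record) %in% c(SAMPLE_ATTRS, "person_key")]
        if (length(set)) {
          vals <- c(tp, list(person_key = pk))
          DBI::dbExecute(con, paste0("UPDATE sample SET ",
            paste0(set, " = ?", collapse = ", "), " WHERE sample_key = ?"),
            params = c(unname(vals[set]), list(key[1L])))
        }
        return(as.integer(key[1L]))
      }
      DBI::dbExecute(con,
        "INSERT INTO sample (sample_id_ext, project, person_key,
           year, month, week, day, draw) VALUES (?,?,?,?,?,?,?,?)",
        params = c(list(record$sample_id_ext, project, pk), unname(tp)))
      as.integer(DBI::dbGetQuery(con,
        "SELECT last_insert_rowid() AS k")$k)
    },
    analyte = {
      assert_scalar_string(record$analyte_name, "analyte_name")
      assert_scalar_string(record$assay_family, "assay_family")
      key <- DBI::dbGetQuery(con,
        "SELECT analyte_key FROM analyte
         WHERE analyte_name = ? AND assay_family = ?",
        params = list(record$analyte_name, record$assay_family))$analyte_key
      if (length(key)) return(as.integer(key[1L]))
      DBI::dbExecute(con,
        "INSERT INTO analyte (analyte_name, assay_family) VALUES (?, ?)",
        params = list(record$analyte_name, record$assay_family))
      as.integer(DBI::dbGetQuery(con,
        "SELECT last_insert_rowid() AS k")$k)
    },
    source = {
      assert_scalar_string(record$file_name, "file_name")
      assert_scalar_string(record$file_hash, "file_hash")
      assert_scalar_string(record$assay, "assay")
      prior <- DBI::dbGetQuery(con,
        "SELECT source_key, upload_date FROM source
         WHERE file_name = ? AND file_hash = ?",
        params = list(record$file_name, record$file_hash))
      if (nrow(prior))
        stop("duplicate upload: '", record$file_name,
             "' with identical content was already loaded on ",
             prior$upload_date[1L], call. = FALSE)
      DBI::dbExecute(con,
        "INSERT INTO source (file_name, file_hash, upload_date, assay,
           run_date, operator, instrument, lot, pi, project, tissue,
           timepoint_hint) VALUES (?,?,?,?,?,?,?,?,?,?,?,?)",
        params = list(record$file_name, record$file_hash,
          record$upload_date %||% format(Sys.Date()),
          record$assay, record$run_date %||% NA_character_,
          record$operator %||% NA_character_,
          record$instrument %||% NA_character_,
          record$lot %||% NA_character_, record$pi %||% NA_character_,
          record$project %||% NA_character_,
          record$tissue %||% NA_character_,
          record$timepoint_hint %||% NA_character_))
      as.integer(DBI::dbGetQuery(con,
        "SELECT last_insert_rowid() AS k")$k)
    })
}

# ---------------------------------------------------------------------------
# integrity
# ---------------------------------------------------------------------------

#' Referential-integrity and linkage report
#'
#' Full-scan counts of the store: total facts, facts not yet linked to a
#' sample, samples not yet linked to a person, and orphan foreign keys
#' (non-null FKs that do not resolve — always zero on a healthy store).
#'
#' @param store an [AssayWarehouse-class]
#' @return a list of counts, class `"integrityReport"`
#' @export
integrityReport <- function(store) {
  con <- store@con
  q <- function(sql) DBI::dbGetQuery(con, sql)[[1L]]
  rep <- list(
    n_facts = q("SELECT COUNT(*) FROM aliquot_fact"),
    n_facts_unmapped = q(
      "SELECT COUNT(*) FROM aliquot_fact WHERE sample_key IS NULL"),
    n_persons = q("SELECT COUNT(*) FROM person"),
    n_samples = q("SELECT COUNT(*) FROM sample"),
    n_samples_unlinked = q(
      "SELECT COUNT(*) FROM sample WHERE person_key IS NULL"),
    n_analytes = q("SELECT COUNT(*) FROM analyte"),
    n_sources = q("SELECT COUNT(*) FROM source"),
    n_orphan_facts = q(
      "SELECT COUNT(*) FROM aliquot_fact f
       LEFT JOIN analyte a ON f.analyte_key = a.analyte_key
       LEFT JOIN source s ON f.source_key = s.source_key
       LEFT JOIN sample m ON f.sample_key = m.sample_key
       WHERE a.analyte_key IS NULL OR s.source_key IS NULL
          OR (f.sample_key IS NOT NULL AND m.sample_key IS NULL)"),
    n_orphan_samples = q(
      "SELECT COUNT(*) FROM sample m
       LEFT JOIN person p ON m.person_key = p.person_key
       WHERE m.person_key IS NOT NULL AND p.person_key IS NULL"))
  structure(rep, class = "integrityReport")
}

#' @export
print.integrityReport <- function(x, ...) {
  cat("Integrity report\n")
  cat(sprintf("  facts: %d (%d unmapped to sample)\n",
              x$n_facts, x$n_facts_unmapped))
  cat(sprintf("  samples: %d (%d unlinked to person)\n",
              x$n_samples, x$n_samples_unlinked))
  cat(sprintf("  persons: %d  analytes: %d  sources: %d\n",
              x$n_persons, x$n_analytes, x$n_sources))
  cat(sprintf("  orphan FKs: %d fact(s), %d sample(s)\n",
              x$n_orphan_facts, x$n_orphan_samples))
  invisible(x)
}

#' Export a store table to CSV
#'
#' Writes one of the star-schema tables to CSV with a fixed column order
#' (the schema order), suitable for hand-off to downstream analysis tools.
#'
#' @param store an [AssayWarehouse-class]
#' @param table table name
#' @param path output CSV path
#' @return invisibly, the exported data.frame
#' @export
exportTable <- function(store, table, path) {
  table <- match.arg(table, STORE_TABLES)
  df <- DBI::dbGetQuery(store@con, paste0("SELECT * FROM ", table))
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(df)
}
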