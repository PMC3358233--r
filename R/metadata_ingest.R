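#' @include batch_ingest.R
NULL

# attributes whose vocabularies are global vs scoped to a project
GLOBAL_VOCAB_ATTRS <- c("condition", "ethnicity", "gender")
PROJECT_VOCAB_ATTRS <- c("response", "treatment", "timepoint_label")
VOCAB_ATTRS <- c(GLOBAL_VOCAB_ATTRS, PROJECT_VOCAB_ATTRS)

#' Read a flexible-format metadata sheet
#'
#' The only layout constraint is that records are in rows with attributes
#' in columns, the first row being the header. All cells are read as
#' trimmed strings; fully blank rows are dropped. Duplicate header names
#' are a format error.
#'
#' @param file CSV or XLSX path
#' @return a character data.frame (possibly 0-row)
#' @export
readMetadataSheet <- function(file) {
  m <- read_rect_text(file)
  if (nrow(m) < 1L) stop("metadata sheet has no header row", call. = FALSE)
  hdr <- trim(m[1L, ])
  if (any(!nzchar(hdr)))
    stop("empty column name in metadata header", call. = FALSE)
  if (anyDuplicated(hdr))
    stop("duplicate column name in metadata header: ",
         hdr[duplicated(hdr)][1L], call. = FALSE)
  dat <- if (nrow(m) > 1L) m[-1L, , drop = FALSE] else m[0L, , drop = FALSE]
  dat <- apply(dat, 2L, trim)
  dim(dat) <- c(nrow(m) - 1L, length(hdr))
  keep <- apply(dat, 1L, function(r) any(nzchar(r)))
  dat <- dat[keep, , drop = FALSE]
  df <- as.data.frame(dat, stringsAsFactors = FALSE)
  names(df) <- hdr
  df
}

#' Construct a controlled vocabulary
#'
#' @param attribute attribute name (e.g. `"gender"`)
#' @param valid_values the controlled term set
#' @param scope `"global"` (condition, ethnicity, gender) or
#'   `"project:<name>"` (response, treatment, time-point labels)
#' @param value_map named character vector mapping incoming strings to
#'   valid values (e.g. `c(M = "male", F = "female")`)
#' @return a [ControlledVocabulary-class]
#' @export
controlledVocabulary <- function(attribute, valid_values, scope = "global",
                                 value_map = character()) {
  methods::new("ControlledVocabulary", attribute = attribute, scope = scope,
    validValues = valid_values,
    valueMap = if (length(value_map)) value_map else
      stats::setNames(character(0), character(0)))
}

#' Seed vocabularies shipped with a fresh store
#'
#' Editable defaults for the three global attributes. They are a starting
#' point, not a reference terminology.
#' @return list of [ControlledVocabulary-class] objects
#' @export
defaultVocabularies <- function() {
  list(
    controlledVocabulary("gender", c("male", "female", "unknown")),
    controlledVocabulary("ethnicity",
      c("white", "black", "asian", "hispanic", "other", "unknown")),
    controlledVocabulary("condition",
      c("healthy", "lupus", "rheumatoid arthritis", "unknown")))
}

seed_default_vocabularies <- function(con) {
  for (v in defaultVocabularies())
    for (val in v@validValues)
      DBI::dbExecute(con,
        "INSERT OR IGNORE INTO vocabulary (attribute, scope, valid_value)
         VALUES (?, 'global', ?)", params = list(v@attribute, val))
  invisible(NULL)
}

vocab_scope_for <- function(attribute, project) {
  if (attribute %in% GLOBAL_VOCAB_ATTRS) "global"
  else paste0("project:", project %||% "default")
}

#' Register or extend a controlled vocabulary in the store
#'
#' Valid values and incoming-value mappings are persisted in the store.
#' Global and project scopes are disjoint per attribute: a vocabulary for
#' a globally scoped attribute (condition, ethnicity, gender) cannot be
#' registered under a project scope, and vice versa.
#'
#' @param store an [AssayWarehouse-class]
#' @param vocab a [ControlledVocabulary-class]
#' @return invisibly the store
#' @export
addVocabulary <- function(store, vocab) {
  stopifnot(methods::is(vocab, "ControlledVocabulary"))
  methods::validObject(vocab)
  is_global <- vocab@scope == "global"
  if (vocab@attribute %in% GLOBAL_VOCAB_ATTRS && !is_global)
    stop("attribute '", vocab@attribute, "' is globally scoped; ",
         "a project-scoped vocabulary is not allowed", call. = FALSE)
  if (vocab@attribute %in% PROJECT_VOCAB_ATTRS && is_global)
    stop("attribute '", vocab@attribute, "' is project-scoped; ",
         "a global vocabulary is not allowed", call. = FALSE)
  con <- store@con
  for (val in vocab@validValues)
    DBI::dbExecute(con,
      "INSERT OR IGNORE INTO vocabulary (attribute, scope, valid_value)
       VALUES (?,?,?)", params = list(vocab@attribute, vocab@scope, val))
  if (length(vocab@valueMap))
    addValueMappings(store, vocab@attribute, vocab@valueMap,
      project = sub("^project:", "", vocab@scope))
  invisible(store)
}

#' Retrieve a stored vocabulary
#'
#' @param store an [AssayWarehouse-class]
#' @param attribute attribute name
#' @param project project name, used for project-scoped attributes
#' @return a [ControlledVocabulary-class], or `NULL` if none registered
#' @export
getVocabulary <- function(store, attribute, project = "default") {
  scope <- vocab_scope_for(attribute, project)
  vals <- DBI::dbGetQuery(store@con,
    "SELECT valid_value FROM vocabulary WHERE attribute = ? AND scope = ?
     ORDER BY valid_value", params = list(attribute, scope))$valid_value
  if (!length(vals)) return(NULL)
  maps <- DBI::dbGetQuery(store@con,
    "SELECT incoming, valid_value FROM vocabulary_map
     WHERE attribute = ? AND scope = ?", params = list(attribute, scope))
  controlledVocabulary(attribute, vals, scope = scope,
    value_map = stats::setNames(maps$valid_value, maps$incoming))
}

#' Persist incoming-value mappings for an attribute
#'
#' Records `incoming -> valid value` assignments (the scripted equivalent
#' of the drag-and-drop value-mapping step). Every target must already be
#' a valid value of the attribute's vocabulary.
#'
#' @param store an [AssayWarehouse-class]
#' @param attribute attribute name
#' @param mappings named character vector, `incoming -> valid value`
#' @param project project name for project-scoped attributes
#' @return invisibly the store
#' @export
addValueMappings <- function(store, attribute, mappings, project = "default") {
  scope <- vocab_scope_for(attribute, project)
  vals <- DBI::dbGetQuery(store@con,
    "SELECT valid_value FROM vocabulary WHERE attribute = ? AND scope = ?",
    params = list(attribute, scope))$valid_value
  bad <- setdiff(unname(mappings), vals)
  if (length(bad))
    stop("mapping target(s) not in the '", attribute, "' vocabulary: ",
         paste(bad, collapse = ", "), call. = FALSE)
  for (i in seq_along(mappings))
    DBI::dbExecute(store@con,
      "INSERT OR REPLACE INTO vocabulary_map
         (attribute, scope, incoming, valid_value) VALUES (?,?,?,?)",
      params = list(attribute, scope, names(mappings)[i], mappings[[i]]))
  invisible(store)
}

#' Propose mappings of incoming values onto a vocabulary
#'
#' Auto-proposes a mapping wherever a case-folded, whitespace-trimmed
#' incoming value equals a valid value; everything else is returned as
#' unresolved for explicit assignment (no fuzzy matching). The proposal
#' never fails.
#'
#' @param raw_values character vector of incoming values
#' @param vocab a [ControlledVocabulary-class]
#' @return list with `mapped` (named character, incoming -> valid value)
#'   and `unresolved` (character)
#' @export
#' @examples
#' v <- controlledVocabulary("gender", c("male", "female"))
#' proposeValueMapping(c("Male", "F"), v)
proposeValueMapping <- function(raw_values, vocab) {
  stopifnot(methods::is(vocab, "ControlledVocabulary"))
  raw_values <- unique(trim(raw_values))
  raw_values <- raw_values[nzchar(raw_values)]
  hit <- match(tolower(raw_values), tolower(vocab@validValues))
  mapped <- stats::setNames(vocab@validValues[hit[!is.na(hit)]],
                            raw_values[!is.na(hit)])
  list(mapped = mapped, unresolved = raw_values[is.na(hit)])
}

#' Construct a column mapping
#'
#' @param ... or a single named character vector: entries of the form
#'   `` `Sheet Column` = "attribute" ``; attributes are `person_id`,
#'   `sample_id`, the person attributes (gender, ethnicity, condition,
#'   treatment, response, age_years) and the sample time-point ordinals
#'   (year, month, week, day, draw)
#' @return a [ColumnMapping-class]
#' @export
#' @examples
#' columnMapping(ID = "person_id", Gender = "gender", Age = "age_years")
columnMapping <- function(...) {
  args <- list(...)
  entries <- if (length(args) == 1L && is.null(names(args)) ||
                 (length(args) == 1L && identical(names(args), "")))
    args[[1L]] else unlist(args)
  methods::new("ColumnMapping", entries = entries)
}

#' Load a metadata sheet into the person and sample dimensions
#'
#' Applies a [ColumnMapping-class] to a raw metadata table and upserts
#' persons and/or samples by external ID. Vocabulary-controlled attributes
#' must resolve completely: each incoming value must either equal a valid
#' value verbatim, or be covered by a stored or supplied value mapping —
#' otherwise the whole load is rejected listing the offending values
#' (no silent coercion). Blank vocabulary cells store the `"unknown"`
#' sentinel. Time-point cells must be non-negative integers, and each
#' sample row must set at least one time-point level. Supplied
#' `value_maps` are persisted on success. Metadata may be loaded before
#' or after the batch results they describe.
#'
#' @param store an [AssayWarehouse-class]
#' @param raw data.frame from [readMetadataSheet()]
#' @param colmap a [ColumnMapping-class]
#' @param value_maps optional list: attribute -> named character mapping,
#'   used in addition to mappings already stored
#' @param project project scope for IDs and project-level vocabularies
#' @return list of class `"metadataSummary"`: persons/samples created and
#'   updated
#' @export
loadMetadata <- function(store, raw, colmap, value_maps = list(),
                         project = "default") {
  stopifnot(methods::is(colmap, "ColumnMapping"))
  methods::validObject(colmap)
  e <- colmap@entries
  missing_cols <- setdiff(names(e), names(raw))
  if (length(missing_cols))
    stop("mapped column(s) absent from sheet: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  attr_col <- stats::setNames(names(e), e)   # attribute -> sheet column
  n <- nrow(raw)
  con <- store@con

  # --- resolve vocabulary-controlled columns ------------------------------
  resolved <- list()
  unresolved <- character(0)
  for (a in intersect(unname(e), VOCAB_ATTRS)) {
    incoming <- trim(raw[[attr_col[[a]]]])
    vocab <- getVocabulary(store, a, project)
    if (is.null(vocab))
      stop("no vocabulary registered for attribute '", a, "'", call. = FALSE)
    vmap <- vocab@valueMap
    extra <- value_maps[[a]]
    if (length(extra)) vmap[names(extra)] <- unname(extra)
    out <- rep(NA_character_, n)
    out[!nzchar(incoming)] <- "unknown"
    idx <- nzchar(incoming)
    hit <- unname(vmap[incoming[idx]])
    exact <- incoming[idx] %in% vocab@validValues
    hit[is.na(hit) & exact] <- incoming[idx][is.na(hit) & exact]
    out[idx] <- hit
    if (anyNA(out))
      unresolved <- c(unresolved, paste0(a, ": ",
        paste(unique(incoming[is.na(out)]), collapse = ", ")))
    resolved[[a]] <- out
  }
  if (length(unresolved))
    stop("unresolved vocabulary value(s); map them first: ",
         paste(unique(unresolved), collapse = "; "), call. = FALSE)

  # --- typed columns ------------------------------------------------------
  as_int_col <- function(a, nonneg = TRUE) {
    x <- trim(raw[[attr_col[[a]]]])
    out <- rep(NA_integer_, n)
    idx <- nzchar(x)
    v <- suppressWarnings(as.numeric(x[idx]))
    bad <- is.na(v) | v != floor(v) | (nonneg & v < 0)
    if (any(bad))
      stop("non-integer value(s) in column '", attr_col[[a]], "' (",
           a, "): ", paste(unique(x[idx][bad]), collapse = ", "),
           call. = FALSE)
    out[idx] <- as.integer(v)
    out
  }
  tp_cols <- intersect(unname(e), SAMPLE_ATTRS)
  tp <- lapply(stats::setNames(tp_cols, tp_cols), as_int_col)
  age <- if ("age_years" %in% e) as_int_col("age_years") else NULL

  created <- c(person = 0L, sample = 0L)
  updated <- c(person = 0L, sample = 0L)
  DBI::dbExecute(con, "BEGIN IMMEDIATE")
  ok <- FALSE
  on.exit(if (!ok) DBI::dbExecute(con, "ROLLBACK"))

  # --- persons (set-based upsert) -----------------------------------------
  person_key_by_id <- NULL
  if ("person_id" %in% e) {
    pid <- trim(raw[[attr_col[["person_id"]]]])
    if (any(!nzchar(pid)))
      stop("empty person ID in row ", which(!nzchar(pid))[1L], call. = FALSE)
    pdf <- data.frame(person_id_ext = pid, project = project,
                      stringsAsFactors = FALSE)
    for (a in intersect(unname(e), PERSON_ATTRS)) {
      if (a == "age_years") {
        pdf$age_years <- age
        pdf$age_band <- ageBand(age)
      } else pdf[[a]] <- resolved[[a]]
    }
    # a sheet may repeat a person across rows (e.g. one row per sample);
    # collapse, but conflicting attribute values are an error
    pdf <- unique(pdf)
    if (anyDuplicated(pdf$person_id_ext))
      stop("conflicting attribute values for person ID: ",
           pdf$person_id_ext[duplicated(pdf$person_id_ext)][1L],
           call. = FALSE)
    ex <- DBI::dbGetQuery(con,
      "SELECT person_key, person_id_ext FROM person WHERE project = ?",
      params = list(project))
    is_new <- !(pdf$person_id_ext %in% ex$person_id_ext)
    newdf <- pdf[is_new, , drop = FALSE]
    if (nrow(newdf)) DBI::dbWriteTable(con, "person", newdf, append = TRUE)
    upd <- pdf[!is_new, , drop = FALSE]
    setcols <- setdiff(names(pdf), c("person_id_ext", "project"))
    if (nrow(upd) && length(setcols)) {
      sql <- paste0("UPDATE person SET ",
        paste0(setcols, " = ?", collapse = ", "),
        " WHERE person_id_ext = ? AND project = ?")
      DBI::dbExecute(con, sql, params = c(unname(as.list(upd[setcols])),
        list(upd$person_id_ext, rep(project, nrow(upd)))))
    }
    created["person"] <- nrow(newdf); updated["person"] <- nrow(upd)
    ex <- DBI::dbGetQuery(con,
      "SELECT person_key, person_id_ext FROM person WHERE project = ?",
      params = list(project))
    person_key_by_id <- stats::setNames(ex$person_key, ex$person_id_ext)
  }

  # --- samples ------------------------------------------------------------
  if ("sample_id" %in% e) {
    sid <- trim(raw[[attr_col[["sample_id"]]]])
    if (any(!nzchar(sid)))
      stop("empty sample ID in row ", which(!nzchar(sid))[1L], call. = FALSE)
    if (anyDuplicated(sid))
      stop("duplicate sample ID in sheet: ", sid[duplicated(sid)][1L],
           call. = FALSE)
    if (!length(tp_cols))
      stop("a sample sheet must map at least one time-point level ",
           "(year, month, week, day, draw)", call. = FALSE)
    tpm <- do.call(cbind, tp)
    if (n && any(rowSums(!is.na(tpm)) == 0L))
      stop("row ", which(rowSums(!is.na(tpm)) == 0L)[1L],
           ": every sample needs at least one time-point level",
           call. = FALSE)
    sdf <- data.frame(sample_id_ext = sid, project = project,
                      stringsAsFactors = FALSE)
    for (a in tp_cols) sdf[[a]] <- tp[[a]]
    if (!is.null(person_key_by_id)) {
      pid <- trim(raw[[attr_col[["person_id"]]]])
      sdf$person_key <- unname(person_key_by_id[pid])
    }
    ex <- DBI::dbGetQuery(con,
      "SELECT sample_key, sample_id_ext FROM sample WHERE project = ?",
      params = list(project))
    is_new <- !(sdf$sample_id_ext %in% ex$sample_id_ext)
    newdf <- sdf[is_new, , drop = FALSE]
    if (nrow(newdf)) DBI::dbWriteTable(con, "sample", newdf, append = TRUE)
    upd <- sdf[!is_new, , drop = FALSE]
    setcols <- setdiff(names(sdf), c("sample_id_ext", "project"))
    if (nrow(upd) && length(setcols)) {
      sql <- paste0("UPDATE sample SET ",
        paste0(setcols, " = ?", collapse = ", "),
        " WHERE sample_id_ext = ? AND project = ?")
      DBI::dbExecute(con, sql, params = c(unname(as.list(upd[setcols])),
        list(upd$sample_id_ext, rep(project, nrow(upd)))))
    }
    created["sample"] <- nrow(newdf); updated["sample"] <- nrow(upd)
  }

  DBI::dbExecute(con, "COMMIT")
  ok <- TRUE
  # persist any transient mappings that were actually used
  for (a in names(value_maps))
    if (length(value_maps[[a]]))
      addValueMappings(store, a, value_maps[[a]], project)
  audit(store, "load_metadata",
        list(created = as.list(created), updated = as.list(updated)))
  structure(list(n_persons_created = unname(created["person"]),
                 n_persons_updated = unname(updated["person"]),
                 n_samples_created = unname(created["sample"]),
                 n_samples_updated = unname(updated["sample"])),
            class = "metadataSummary")
}

#' @export
print.metadataSummary <- function(x, ...) {
  cat(sprintf(
    "Metadata load: persons %d created / %d updated; samples %d created / %d updated\n",
    x$n_persons_created, x$n_persons_updated,
    x$n_samples_created, x$n_samples_updated))
  invisible(x)
}
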