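#' @include warehouse.R
NULL

#' Registered assay families
#'
#' The three assay families the warehouse ingests: bead-based multiplex
#' immunoassay (`luminex`), electrochemiluminescence panel (`msd`) and
#' phosphoepitope flow cytometry (`phospho_flow`).
#' @export
ASSAY_FAMILIES <- c("luminex", "msd", "phospho_flow")

read_rect_text <- function(file) {
  ext <- tolower(tools::file_ext(file))
  if (ext %in% c("xlsx", "xls")) {
    if (!requireNamespace("readxl", quietly = TRUE))
      stop("reading XLSX requires the 'readxl' package; ",
           "convert the sheet to CSV instead", call. = FALSE)
    m <- suppressMessages(as.matrix(readxl::read_excel(file,
      col_names = FALSE, col_types = "text", .name_repair = "minimal")))
    m[is.na(m)] <- ""
    return(unname(m))
  }
  nf <- utils::count.fields(file, sep = ",", quote = "\"",
                            blank.lines.skip = FALSE)
  nf <- nf[!is.na(nf)]
  if (length(unique(nf)) > 1L) {
    bad <- which(nf != nf[1L])[1L]
    stop(sprintf(
      "ragged sheet: row %d has %d field(s), expected %d (file '%s')",
      bad, nf[bad], nf[1L], file), call. = FALSE)
  }
  df <- utils::read.csv(file, header = FALSE, colClasses = "character",
                        check.names = FALSE, blank.lines.skip = FALSE)
  unname(as.matrix(df))
}

#' Construct a BatchSheet from in-memory cells
#'
#' Low-level constructor used by [parseBatchSheet()] and by the synthetic
#' study generator (which builds sheets directly rather than round-tripping
#' through files). `cells` must contain one row per non-blank readout.
#'
#' @param fileName verbatim file name for the source record
#' @param assayFamily one of [ASSAY_FAMILIES]
#' @param analytes,units parallel character vectors (sheet column order)
#' @param cells data.frame with `aliquot_id_ext`, `stim`, `analyte`,
#'   `units`, `readout`, `quantification`
#' @param nDataRows number of aliquot rows in the sheet
#' @param nBlank number of blank cells skipped
#' @param fileHash md5 of the sheet; computed from a canonical
#'   serialization when omitted
#' @return a [BatchSheet-class]
#' @export
batchSheet <- function(fileName, assayFamily, analytes, units, cells,
                       nDataRows, nBlank = 0L, fileHash = NULL) {
  assayFamily <- match.arg(assayFamily, ASSAY_FAMILIES)
  hasStim <- !all(cells$stim == "none")
  if (is.null(fileHash))
    fileHash <- objectHash(list(analytes, units, cells))
  methods::new("BatchSheet", fileName = fileName, fileHash = fileHash,
    assayFamily = assayFamily, analytes = analytes, units = units,
    hasStim = hasStim, cells = cells, nDataRows = as.integer(nDataRows),
    nBlank = as.integer(nBlank))
}

#' Parse a canonical wide-format batch-results sheet
#'
#' The canonical layout (CSV, or first worksheet of an XLSX) is: header row
#' 1 = ID column label, optional `stim` column label, then analyte names;
#' header row 2 = units per analyte (blank over the ID/stim columns); one
#' data row per aliquot. Readout cells are plain numbers (`in_range`), or
#' carry a `<`/`>` prefix marking a value below/above the limit of
#' quantification; blank cells emit no fact. Lab-native exports must be
#' pre-converted to this layout.
#'
#' @param file path to a CSV or XLSX sheet
#' @param assay_family one of [ASSAY_FAMILIES]
#' @return a [BatchSheet-class]
#' @export
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("aliquot_id,IL-6,TNF", ",pg/ml,pg/ml",
#'              "A1,12.5,<0.4", "A2,9.1,"), f)
#' sh <- parseBatchSheet(f, "msd")
#' sh@cells$quantification
parseBatchSheet <- function(file, assay_family) {
  assay_family <- match.arg(assay_family, ASSAY_FAMILIES)
  m <- read_rect_text(file)
  if (nrow(m) < 2L)
    stop("sheet must have two header rows (analytes, units)", call. = FALSE)
  hdr <- trim(m[1L, ])
  hasStim <- ncol(m) >= 2L && tolower(hdr[2L]) == "stim"
  first_data_col <- if (hasStim) 3L else 2L
  if (ncol(m) < first_data_col)
    stop("sheet has no analyte columns", call. = FALSE)
  acols <- first_data_col:ncol(m)
  analytes <- hdr[acols]
  if (any(!nzchar(analytes)))
    stop(sprintf("empty analyte name in header row 1, column %d",
                 acols[which(!nzchar(analytes))[1L]]), call. = FALSE)
  if (anyDuplicated(analytes))
    stop("duplicate analyte column: ",
         analytes[duplicated(analytes)][1L], call. = FALSE)
  units <- trim(m[2L, acols])
  if (any(!nzchar(units)))
    stop(sprintf("missing units in header row 2, column %d",
                 acols[which(!nzchar(units))[1L]]), call. = FALSE)

  dat <- if (nrow(m) > 2L) m[3:nrow(m), , drop = FALSE] else
    m[0L, , drop = FALSE]
  # drop fully blank trailing rows
  keep <- apply(dat, 1L, function(r) any(nzchar(trim(r))))
  dat <- dat[keep, , drop = FALSE]
  nrows <- nrow(dat)

  ids <- trim(dat[, 1L])
  if (nrows && any(!nzchar(ids)))
    stop(sprintf("empty aliquot ID in data row %d",
                 which(!nzchar(ids))[1L] + 2L), call. = FALSE)
  stim <- if (hasStim) trim(dat[, 2L]) else rep("none", nrows)
  stim[!nzchar(stim)] <- "none"
  if (nrows && anyDuplicated(paste(ids, stim, sep = "\r")))
    stop("duplicate (aliquot ID, stim) row: ",
         ids[duplicated(paste(ids, stim, sep = "\r"))][1L], call. = FALSE)

  # vectorized cell parse over the readout block
  block <- trim(dat[, acols, drop = FALSE])
  dim(block) <- c(nrows, length(acols))
  cellv <- as.vector(block)
  blank <- !nzchar(cellv)
  pre <- substr(cellv, 1L, 1L)
  quant <- ifelse(pre == "<", "below_loq",
                  ifelse(pre == ">", "above_loq", "in_range"))
  numstr <- ifelse(pre %in% c("<", ">"), trim(substring(cellv, 2L)), cellv)
  val <- suppressWarnings(as.numeric(numstr))
  bad <- !blank & (is.na(val) | !is.finite(val))
  if (any(bad)) {
    i <- which(bad)[1L]
    r <- ((i - 1L) %% nrows) + 1L
    c <- ((i - 1L) %/% nrows) + 1L
    stop(sprintf(
      "unparseable cell '%s' at data row %d, analyte column '%s' (file '%s')",
      cellv[i], r + 2L, analytes[c], file), call. = FALSE)
  }
  keepc <- !blank
  ridx <- ((which(keepc) - 1L) %% nrows) + 1L
  cidx <- ((which(keepc) - 1L) %/% nrows) + 1L
  cells <- data.frame(
    aliquot_id_ext = ids[ridx], stim = stim[ridx],
    analyte = analytes[cidx], units = units[cidx],
    readout = val[keepc], quantification = quant[keepc],
    stringsAsFactors = FALSE)
  batchSheet(fileName = basename(file), assayFamily = assay_family,
    analytes = analytes, units = units, cells = cells,
    nDataRows = nrows, nBlank = sum(blank), fileHash = fileHash(file))
}

#' Source attributes classifying a batch upload
#'
#' The attributes under which a batch-results file is classified at upload
#' time: operator, run date, assay, instrument, tissue, a time-point hint,
#' kit lot, PI and project. The tissue is stamped onto every fact of the
#' batch; the time-point hint is informational only (time points live on
#' the sample dimension after metadata load, which takes precedence).
#'
#' @param assay assay label, e.g. `"Human Luminex 51plex"` (required)
#' @param tissue tissue of the batch's aliquots (default `"unknown"`)
#' @param operator,run_date,instrument,lot,pi,project,timepoint_hint
#'   optional classification attributes
#' @return a named list of class `"sourceAttributes"`
#' @export
sourceAttributes <- function(assay, tissue = "unknown", operator = NULL,
    run_date = NULL, instrument = NULL, lot = NULL, pi = NULL,
    project = NULL, timepoint_hint = NULL) {
  assert_scalar_string(assay, "assay")
  structure(list(assay = assay, tissue = tissue, operator = operator,
    run_date = run_date, instrument = instrument, lot = lot, pi = pi,
    project = project, timepoint_hint = timepoint_hint),
    class = "sourceAttributes")
}

#' Load a parsed batch sheet into the warehouse
#'
#' Registers one source record for the file (re-loading a file with
#' identical content is rejected, naming the prior upload date), creates
#' any analytes not yet known to the sheet's assay family, and inserts one
#' aliquot-level fact per non-blank cell with `sample_key` unset — linkage
#' to samples happens later, via [openLinkSession()]. The load is atomic.
#'
#' @param store an [AssayWarehouse-class]
#' @param sheet a [BatchSheet-class]
#' @param attrs a [sourceAttributes()] list
#' @return a load summary (class `"loadSummary"`): `source_key`,
#'   `n_facts`, `n_analytes_new`, `n_blank_skipped`
#' @export
loadBatch <- function(store, sheet, attrs) {
  stopifnot(methods::is(sheet, "BatchSheet"),
            inherits(attrs, "sourceAttributes"))
  con <- store@con
  DBI::dbExecute(con, "BEGIN IMMEDIATE")
  ok <- FALSE
  on.exit(if (!ok) DBI::dbExecute(con, "ROLLBACK"))
  n_before <- DBI::dbGetQuery(con, "SELECT COUNT(*) AS n FROM analyte")$n
  source_key <- upsertDimension(store, "source", c(
    list(file_name = sheet@fileName, file_hash = sheet@fileHash),
    unclass(attrs)))
  akey <- vapply(sheet@analytes, function(a)
    upsertDimension(store, "analyte",
      list(analyte_name = a, assay_family = sheet@assayFamily)), 1L)
  n_after <- DBI::dbGetQuery(con, "SELECT COUNT(*) AS n FROM analyte")$n
  cells <- sheet@cells
  if (nrow(cells)) {
    facts <- data.frame(
      aliquot_id_ext = cells$aliquot_id_ext,
      analyte_key = unname(akey[cells$analyte]),
      sample_key = NA_integer_,
      source_key = source_key,
      tissue = attrs$tissue %||% "unknown",
      stim = cells$stim,
      readout = cells$readout,
      units = cells$units,
      quantification = cells$quantification,
      stringsAsFactors = FALSE)
    DBI::dbWriteTable(con, "aliquot_fact", facts, append = TRUE)
  }
  DBI::dbExecute(con, "COMMIT")
  ok <- TRUE
  audit(store, "load_batch", list(file = sheet@fileName,
    source_key = source_key, facts = nrow(cells)))
  structure(list(source_key = source_key, n_facts = nrow(cells),
    n_analytes_new = n_after - n_before, n_blank_skipped = sheet@nBlank),
    class = "loadSummary")
}

#' @export
print.loadSummary <- function(x, ...) {
  cat(sprintf(
    "Load summary: %d fact(s), %d new analyte(s), %d blank cell(s) skipped (source %d)\n",
    x$n_facts, x$n_analytes_new, x$n_blank_skipped, x$source_key))
  invisible(x)
}

#' Re-pivot the facts of one source back to sheet form
#'
#' Inverse of [loadBatch()] for a single source: returns a wide data.frame
#' (aliquot ID, stim if present, one column per analyte) whose numeric
#' cells reproduce the original sheet's readouts bit-exact. Used for
#' round-trip verification and source-level export.
#'
#' @param store an [AssayWarehouse-class]
#' @param source_key source surrogate key
#' @return wide data.frame of readouts
#' @export
exportSourceSheet <- function(store, source_key) {
  df <- DBI::dbGetQuery(store@con,
    "SELECT f.aliquot_id_ext, f.stim, a.analyte_name, f.readout
     FROM aliquot_fact f JOIN analyte a ON f.analyte_key = a.analyte_key
     WHERE f.source_key = ? ORDER BY f.fact_key",
    params = list(source_key))
  if (!nrow(df)) return(data.frame(aliquot_id_ext = character(0)))
  dt <- data.table::as.data.table(df)
  wide <- data.table::dcast(dt, aliquot_id_ext + stim ~ analyte_name,
                            value.var = "readout")
  as.data.frame(wide)
}
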