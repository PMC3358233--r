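#' @include id_linkage.R
NULL

#' Cube measures
#'
#' Per-cell statistics: `N` (number of data points), `mean`, `median`,
#' `min`, `max`, plus the extension measures `sd` (sample standard
#' deviation, n-1) and `cv` (coefficient of variation, sd/mean).
#' @export
CUBE_MEASURES <- c("N", "mean", "median", "min", "max", "sd", "cv")

# hierarchy paths; a level not listed here is a flat (leaf) dimension
CUBE_HIERARCHIES <- list(
  Assay = c("Assay", "Analyte", "Units"),
  Time = c("Year", "Month", "Week", "Day", "Draw"),
  Source = c("PI", "Project", "Lot", "Document"))

PERSON_LEVELS <- c("Gender", "AgeBand", "Ethnicity", "Condition",
                   "Treatment", "Response")
TIME_LEVELS <- c("Year", "Month", "Week", "Day", "Draw")
CUBE_LEVELS <- c("Assay", "Analyte", "Units", TIME_LEVELS, PERSON_LEVELS,
                 "PI", "Project", "Lot", "Document", "Tissue", "Stim",
                 "Quantification")

#' Describe the cube schema
#'
#' Dimensions and hierarchy levels available for queries, and the measure
#' set. `sd` and `cv` are extensions beyond the core five measures.
#'
#' @return a list with `dimensions`, `hierarchies` and `measures`
#' @export
cubeSchema <- function() {
  list(
    dimensions = list(
      Assay = c("Assay", "Analyte", "Units"),
      Time = TIME_LEVELS,
      Person = PERSON_LEVELS,
      Source = c("PI", "Project", "Lot", "Document"),
      Tissue = "Tissue", Stim = "Stim", Quantification = "Quantification"),
    hierarchies = CUBE_HIERARCHIES,
    measures = list(core = c("N", "mean", "median", "min", "max"),
                    extension = c("sd", "cv")))
}

#' Construct a cube query
#'
#' @param rows,cols ordered dimension levels for the two axes (any of
#'   `Assay, Analyte, Units, Year, Month, Week, Day, Draw, Gender,
#'   AgeBand, Ethnicity, Condition, Treatment, Response, PI, Project,
#'   Lot, Document, Tissue, Stim, Quantification`)
#' @param filters named list, `level -> character vector of members to
#'   keep`
#' @param measures subset of [CUBE_MEASURES]
#' @return a [CubeQuery-class]
#' @export
#' @examples
#' cubeQuery(rows = "Analyte", cols = "Gender",
#'           filters = list(Assay = "Human Luminex 51plex"),
#'           measures = c("N", "mean"))
cubeQuery <- function(rows = character(0), cols = character(0),
                      filters = list(), measures = c("N", "mean")) {
  rows <- as.character(rows); cols <- as.character(cols)
  bad <- setdiff(c(rows, cols, names(filters)), CUBE_LEVELS)
  if (length(bad))
    stop("unknown dimension level(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (length(intersect(rows, cols)))
    stop("level(s) on both axes: ",
         paste(intersect(rows, cols), collapse = ", "), call. = FALSE)
  if (anyDuplicated(rows) || anyDuplicated(cols))
    stop("a level appears twice on one axis", call. = FALSE)
  badm <- setdiff(measures, CUBE_MEASURES)
  if (length(badm))
    stop("unknown measure(s): ", paste(badm, collapse = ", "),
         call. = FALSE)
  filters <- lapply(filters, as.character)
  methods::new("CubeQuery", rows = rows, cols = cols, filters = filters,
               measures = as.character(measures))
}

# ---------------------------------------------------------------------------
# joined fact frame + member derivation
# ---------------------------------------------------------------------------

fetch_joined <- function(store, context = FALSE) {
  extra <- if (context)
    ", p.person_id_ext, m.sample_id_ext, s.operator, s.run_date" else ""
  sql <- paste0(
    "SELECT f.fact_key, f.readout, f.units, f.tissue, f.stim,
            f.quantification, f.sample_key,
            a.analyte_name, a.assay_family,
            s.assay, s.pi, s.project AS src_project, s.lot, s.file_name,
            m.person_key, m.year, m.month, m.week, m.day, m.draw,
            p.gender, p.ethnicity, p.condition, p.treatment, p.response,
            p.age_band", extra, "
     FROM aliquot_fact f
     JOIN analyte a ON f.analyte_key = a.analyte_key
     JOIN source s ON f.source_key = s.source_key
     LEFT JOIN sample m ON f.sample_key = m.sample_key
     LEFT JOIN person p ON m.person_key = p.person_key")
  data.table::as.data.table(DBI::dbGetQuery(store@con, sql))
}

# member strings for one level; unmapped facts fall under "(unmapped)",
# null ordinals/attributes under "(unspecified)"
derive_member <- function(df, level) {
  unmapped_person <- is.na(df$sample_key) | is.na(df$person_key)
  v <- switch(level,
    Assay = df$assay,
    Analyte = df$analyte_name,
    Units = df$units,
    Year = , Month = , Week = , Day = , Draw = {
      x <- as.character(df[[tolower(level)]])
      x[is.na(x)] <- "(unspecified)"
      x[is.na(df$sample_key)] <- "(unmapped)"
      x
    },
    Gender = , Ethnicity = , Condition = , Treatment = , Response = {
      x <- df[[tolower(level)]]
      x[is.na(x)] <- "unknown"
      x[unmapped_person] <- "(unmapped)"
      x
    },
    AgeBand = {
      x <- df$age_band
      x[is.na(x)] <- "unknown"
      x[unmapped_person] <- "(unmapped)"
      x
    },
    PI = { x <- df$pi; x[is.na(x)] <- "(unspecified)"; x },
    Project = { x <- df$src_project; x[is.na(x)] <- "(unspecified)"; x },
    Lot = { x <- df$lot; x[is.na(x)] <- "(unspecified)"; x },
    Document = df$file_name,
    Tissue = df$tissue,
    Stim = df$stim,
    Quantification = df$quantification,
    stop("unknown level: ", level, call. = FALSE))
  as.character(v)
}

add_members <- function(df, levels) {
  for (lv in unique(levels)) data.table::set(df, j = lv,
    value = derive_member(df, lv))
  df
}

apply_filters <- function(df, filters) {
  for (lv in names(filters)) df <- df[df[[lv]] %in% filters[[lv]], ]
  df
}

group_measures <- function(dt, groupcols, measures) {
  ms <- measures
  if (!nrow(dt)) {
    cols <- c(
      stats::setNames(rep(list(character(0)), length(groupcols)),
                      groupcols),
      lapply(stats::setNames(ms, ms), function(m)
        if (m == "N") integer(0) else numeric(0)))
    return(data.table::as.data.table(cols))
  }
  agg <- dt[, {
    v <- readout
    res <- list()
    if ("N" %in% ms) res$N <- .N
    if ("mean" %in% ms) res$mean <- mean(v)
    if ("median" %in% ms) res$median <- stats::median(v)
    if ("min" %in% ms) res$min <- min(v)
    if ("max" %in% ms) res$max <- max(v)
    if (any(c("sd", "cv") %in% ms)) {
      s <- stats::sd(v)
      if ("sd" %in% ms) res$sd <- s
      if ("cv" %in% ms)
        res$cv <- if (is.na(s) || mean(v) == 0) NA_real_ else s / mean(v)
    }
    res
  }, by = groupcols]
  agg
}

#' Aggregate the cube for a query
#'
#' Computes the requested measures for every populated cell of the pivot,
#' including roll-up subtotals: for each prefix depth of the row and
#' column axes, levels beyond the prefix carry the `"(all)"` member. Each
#' cell aggregates exactly the facts whose members match its row/column
#' tuple and all filters. Facts not yet linked to a sample (or person)
#' contribute under the `"(unmapped)"` member of time and person levels,
#' never silently dropped. No cell — including subtotals — ever pools
#' facts with different units strings: when `Units` is not on an axis it
#' is carried as a hidden innermost grouping column.
#'
#' @param store an [AssayWarehouse-class]
#' @param query a [CubeQuery-class]
#' @return a [PivotResult-class]
#' @export
aggregateCube <- function(store, query) {
  stopifnot(methods::is(query, "CubeQuery"))
  rows <- query@rows; cols <- query@cols
  measures <- query@measures
  need <- unique(c(rows, cols, names(query@filters), "Units"))
  df <- fetch_joined(store)
  df <- add_members(df, need)
  df <- apply_filters(df, query@filters)
  units_hidden <- !("Units" %in% c(rows, cols))

  pieces <- list()
  seen <- character(0)
  for (r in 0:length(rows)) for (cc in 0:length(cols)) {
    gr <- c(rows[seq_len(r)], cols[seq_len(cc)])
    gr_eff <- unique(c(gr, "Units"))   # units never pooled
    sig <- paste(sort(gr_eff), collapse = "\r")
    if (sig %in% seen) next
    seen <- c(seen, sig)
    agg <- group_measures(df, gr_eff, measures)
    for (lv in setdiff(c(rows, cols), gr_eff))
      data.table::set(agg, j = lv, value = "(all)")
    pieces[[length(pieces) + 1L]] <- agg
  }
  cells <- data.table::rbindlist(pieces, use.names = TRUE, fill = TRUE)
  keycols <- unique(c(rows, cols, "Units"))
  data.table::setcolorder(cells, c(keycols,
                                   intersect(CUBE_MEASURES, names(cells))))
  data.table::setorderv(cells, keycols)
  # a cell with Units (all) would pool units; by construction none exists
  methods::new("PivotResult", query = query, rowLevels = rows,
    colLevels = cols, unitsHidden = units_hidden,
    cells = as.data.frame(cells))
}

#' Cells of a pivot result
#' @param result a [PivotResult-class]
#' @return data.frame: one row per populated cell (member columns, then
#'   one column per measure)
#' @export
pivotCells <- function(result) result@cells

#' Expand one member into its child level
#'
#' Appends the next hierarchy level below the innermost level of the
#' chosen axis (Assay -> Analyte -> Units; Year -> ... -> Draw;
#' PI -> Project -> Lot -> Document) and re-aggregates, showing child
#' detail only under `member`; all parent cells are retained as subtotal
#' rows. Expanding a leaf level is a no-op with a message.
#'
#' @param store an [AssayWarehouse-class]
#' @param result a [PivotResult-class]
#' @param axis `"rows"` or `"cols"`
#' @param member the member to expand
#' @return a [PivotResult-class]
#' @export
drillDown <- function(store, result, axis = c("rows", "cols"), member) {
  axis <- match.arg(axis)
  lv <- if (axis == "rows") result@rowLevels else result@colLevels
  if (!length(lv))
    stop("axis '", axis, "' has no levels to expand", call. = FALSE)
  leaf <- lv[length(lv)]
  child <- NA_character_
  for (h in CUBE_HIERARCHIES) {
    i <- match(leaf, h)
    if (!is.na(i) && i < length(h)) { child <- h[i + 1L]; break }
  }
  if (is.na(child)) {
    message("'", leaf, "' is a leaf level; nothing to expand")
    return(result)
  }
  q <- result@query
  newq <- cubeQuery(
    rows = if (axis == "rows") c(q@rows, child) else q@rows,
    cols = if (axis == "cols") c(q@cols, child) else q@cols,
    filters = q@filters, measures = q@measures)
  res <- aggregateCube(store, newq)
  cl <- res@cells
  keep <- !(cl[[child]] != "(all)" & cl[[leaf]] != member)
  res@cells <- cl[keep, , drop = FALSE]
  res
}

#' Retrieve the facts behind one cell
#'
#' Returns all and only the facts that contributed to a cell, with their
#' person, sample and source context (the detail-table view behind any
#' aggregate number). The row count always equals the cell's `N`.
#'
#' @param store an [AssayWarehouse-class]
#' @param result a [PivotResult-class]
#' @param cell row index into `pivotCells(result)`
#' @return data.frame of contributing facts with context columns
#' @export
drillThrough <- function(store, result, cell) {
  cl <- result@cells
  if (!(is.numeric(cell) && length(cell) == 1L && cell >= 1 &&
        cell <= nrow(cl)))
    stop("cell must be a row index into pivotCells(result)", call. = FALSE)
  q <- result@query
  membercols <- unique(c(result@rowLevels, result@colLevels, "Units"))
  df <- fetch_joined(store, context = TRUE)
  df <- add_members(df, unique(c(membercols, names(q@filters))))
  df <- apply_filters(df, q@filters)
  for (lv in membercols) {
    mv <- as.character(cl[[lv]][cell])
    if (!is.na(mv) && mv != "(all)") df <- df[df[[lv]] == mv, ]
  }
  out <- df[, c("person_id_ext", "gender", "sample_id_ext",
                "year", "month", "week", "day", "draw",
                "analyte_name", "stim", "tissue", "readout", "units",
                "quantification", "assay", "file_name", "lot", "pi",
                "src_project", "fact_key"), with = FALSE]
  data.table::setnames(out, "src_project", "project")
  data.table::setorderv(out, "fact_key")
  as.data.frame(out)
}

#' Compute the measure vector of a value multiset
#'
#' `N` is the count; `mean` the arithmetic mean; `median` the middle
#' order statistic (mean of the two middles for even N); `min`/`max` the
#' extrema; `sd` the sample standard deviation (n-1 denominator, `NA`
#' for N < 2); `cv = sd/mean` (`NA` when the mean is 0). All statistics
#' except `N` are `NA` on an empty multiset.
#'
#' @param values numeric vector (empty allowed)
#' @return named list of the seven measures
#' @export
#' @examples
#' computeMeasures(c(2, 4))
computeMeasures <- function(values) {
  stopifnot(is.numeric(values))
  n <- length(values)
  if (n == 0L)
    return(list(N = 0L, mean = NA_real_, median = NA_real_,
                min = NA_real_, max = NA_real_, sd = NA_real_,
                cv = NA_real_))
  s <- stats::sd(values)
  m <- mean(values)
  list(N = n, mean = m, median = stats::median(values),
       min = min(values), max = max(values), sd = s,
       cv = if (is.na(s) || m == 0) NA_real_ else s / m)
}

# ---------------------------------------------------------------------------
# export / import
# ---------------------------------------------------------------------------

flatten_colname <- function(members, measure) {
  paste(c(members, measure), collapse = "/")
}

#' Export a pivot result
#'
#' `csv`: a wide table — one column per row-axis level (plus `Units` when
#' it is a hidden grouping), then one data column per column-member tuple
#' and measure, nested headers flattened with `"/"`. `json`: a lossless
#' serialization of the query, the axis levels and every cell, which
#' [importPivot()] reads back exactly; it validates against the schema
#' shipped in `inst/extdata/pivot-schema.json`.
#'
#' @param result a non-empty [PivotResult-class]
#' @param path output file path
#' @param format `"csv"` or `"json"`
#' @return invisibly `path`
#' @export
exportPivot <- function(result, path, format = c("csv", "json")) {
  format <- match.arg(format)
  cl <- data.table::as.data.table(result@cells)
  if (!nrow(cl)) stop("cannot export an empty pivot", call. = FALSE)
  if (format == "json") {
    q <- result@query
    obj <- list(
      query = list(rows = q@rows, cols = q@cols, filters = q@filters,
                   measures = q@measures),
      rowLevels = result@rowLevels, colLevels = result@colLevels,
      unitsHidden = result@unitsHidden,
      cells = result@cells)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns", null = "null", na = "null")
    return(invisible(path))
  }
  rowcols <- c(result@rowLevels, if (result@unitsHidden) "Units")
  colcols <- result@colLevels
  measures <- intersect(CUBE_MEASURES, names(cl))
  for (m in measures) data.table::set(cl, j = m,
                                      value = as.numeric(cl[[m]]))
  if (!length(rowcols)) { cl[, `..row` := "(all)"]; rowcols <- "..row" }
  if (length(colcols)) {
    cl[, `..colid` := do.call(paste, c(.SD, sep = "/")),
       .SDcols = colcols]
  } else cl[, `..colid` := ""]
  long <- data.table::melt(cl,
    id.vars = c(rowcols, "..colid"), measure.vars = measures,
    variable.name = "..measure", value.name = "..value")
  long[, `..head` := ifelse(nzchar(`..colid`),
    paste(`..colid`, `..measure`, sep = "/"), as.character(`..measure`))]
  wide <- data.table::dcast(long,
    stats::as.formula(paste(paste(sprintf("`%s`", rowcols), collapse = "+"),
                            "~ `..head`")),
    value.var = "..value")
  data.table::setorderv(wide, rowcols)
  if (identical(rowcols, "..row")) data.table::setnames(wide, "..row", "row")
  utils::write.csv(as.data.frame(wide), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Re-import an exported pivot
#'
#' The JSON format reproduces the full [PivotResult-class]; the CSV
#' format is read back as a long data.frame of cells (row members, column
#' member tokens, measure, value).
#'
#' @param path file written by [exportPivot()]
#' @param format `"csv"` or `"json"`
#' @return a [PivotResult-class] (json) or a long cells data.frame (csv)
#' @export
importPivot <- function(path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "json") {
    o <- jsonlite::read_json(path, simplifyVector = TRUE)
    q <- cubeQuery(rows = unlist(o$query$rows) %||% character(0),
      cols = unlist(o$query$cols) %||% character(0),
      filters = as.list(o$query$filters),
      measures = unlist(o$query$measures))
    cells <- as.data.frame(o$cells, stringsAsFactors = FALSE)
    return(methods::new("PivotResult", query = q,
      rowLevels = unlist(o$rowLevels) %||% character(0),
      colLevels = unlist(o$colLevels) %||% character(0),
      unitsHidden = isTRUE(o$unitsHidden), cells = cells))
  }
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = NA, stringsAsFactors = FALSE)
  datacols <- names(df)[vapply(names(df), function(nm) {
    tok <- strsplit(nm, "/", fixed = TRUE)[[1L]]
    tok[length(tok)] %in% CUBE_MEASURES
  }, TRUE)]
  idcols <- setdiff(names(df), datacols)
  out <- list()
  for (nm in datacols) {
    tok <- strsplit(nm, "/", fixed = TRUE)[[1L]]
    measure <- tok[length(tok)]
    colmem <- tok[-length(tok)]
    piece <- df[idcols]
    if (length(colmem))
      for (i in seq_along(colmem)) piece[[paste0("col_", i)]] <- colmem[i]
    piece$measure <- measure
    piece$value <- as.numeric(df[[nm]])
    out[[nm]] <- piece
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[!is.na(res$value), , drop = FALSE]
}

#' Validate an exported pivot JSON against the shipped schema
#'
#' Checks the structural contract of the JSON export (required fields and
#' their types) as declared in `inst/extdata/pivot-schema.json`.
#'
#' @param path JSON file written by `exportPivot(..., format = "json")`
#' @param schema path to the schema file (default: the shipped one)
#' @return `TRUE` invisibly, or an error describing the first violation
#' @export
validatePivotJSON <- function(path,
    schema = system.file("extdata", "pivot-schema.json",
                         package = "ImmunoCube")) {
  sch <- jsonlite::read_json(schema)
  o <- jsonlite::read_json(path)
  for (req in unlist(sch$required))
    if (is.null(o[[req]]))
      stop("pivot JSON missing required field '", req, "'", call. = FALSE)
  types <- list(query = "list", rowLevels = c("list", "character", "NULL"),
                colLevels = c("list", "character", "NULL"),
                unitsHidden = "logical", cells = "list")
  for (nm in names(types))
    if (!is.null(o[[nm]]) && !any(class(o[[nm]]) %in% types[[nm]]))
      stop("pivot JSON field '", nm, "' has wrong type", call. = FALSE)
  for (req in unlist(sch$properties$query$required))
    if (is.null(o$query[[req]]) && req != "filters")
      stop("pivot JSON query missing '", req, "'", call. = FALSE)
  if (!all(unlist(o$query$measures) %in% CUBE_MEASURES))
    stop("pivot JSON declares unknown measures", call. = FALSE)
  invisible(TRUE)
}
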