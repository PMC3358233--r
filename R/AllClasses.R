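#' @include utils.R
NULL

# ---------------------------------------------------------------------------
# AssayWarehouse — handle on the embedded star-schema store
# ---------------------------------------------------------------------------

#' AssayWarehouse: a handle on the star-schema store
#'
#' Wraps a connection to the single-file embedded relational store holding
#' the five star-schema tables (`aliquot_fact` plus the `person`, `sample`,
#' `analyte` and `source` dimensions), the controlled vocabularies and the
#' audit log. Create or reopen one with [createStore()].
#'
#' @slot con a `DBIConnection` to the store
#' @slot path the store file path (`":memory:"` for a transient store)
#' @export
setClass("AssayWarehouse",
  representation(con = "ANY", path = "character"))

setValidity("AssayWarehouse", function(object) {
  if (!methods::is(object@con, "DBIConnection"))
    return("'con' must be a DBIConnection")
  TRUE
})

# ---------------------------------------------------------------------------
# BatchSheet — a parsed canonical wide-format batch results sheet
# ---------------------------------------------------------------------------

#' BatchSheet: a parsed batch-results sheet
#'
#' The canonical wide layout has two header rows (analyte names, then units
#' per analyte), one data row per aliquot with the aliquot identifier in the
#' first column and, for stimulation assays, a `stim` column in the second.
#' Parsing classifies every non-blank cell as `in_range`, `below_loq`
#' (`"<"` prefix) or `above_loq` (`">"` prefix); blank cells emit no fact.
#'
#' @slot fileName source file name (verbatim)
#' @slot fileHash md5 digest of the file content
#' @slot assayFamily registered assay family of the sheet
#' @slot analytes analyte column names, in sheet order
#' @slot units units string per analyte column
#' @slot hasStim whether the sheet carries a stim column
#' @slot cells one row per non-blank cell: `aliquot_id_ext`, `stim`,
#'   `analyte`, `units`, `readout`, `quantification`
#' @slot nDataRows number of data rows in the sheet
#' @slot nBlank number of blank (skipped) cells
#' @export
setClass("BatchSheet",
  representation(fileName = "character", fileHash = "character",
    assayFamily = "character", analytes = "character", units = "character",
    hasStim = "logical", cells = "data.frame", nDataRows = "integer",
    nBlank = "integer"))

setValidity("BatchSheet", function(object) {
  if (length(object@analytes) != length(object@units))
    return("each analyte column needs exactly one units entry")
  if (any(!nzchar(object@units)))
    return("every analyte column must have a non-empty units entry")
  need <- c("aliquot_id_ext", "stim", "analyte", "units", "readout",
            "quantification")
  if (!all(need %in% names(object@cells)))
    return("cells is missing required columns")
  if (nrow(object@cells)) {
    if (!all(object@cells$quantification %in% QUANTIFICATION_LEVELS))
      return("quantification outside {in_range, below_loq, above_loq}")
    if (!all(is.finite(object@cells$readout)))
      return("non-finite readout in cells")
  }
  TRUE
})

# ---------------------------------------------------------------------------
# ControlledVocabulary
# ---------------------------------------------------------------------------

#' ControlledVocabulary: valid values for a metadata attribute
#'
#' Attributes are harmonized against a fixed term set so that incoming
#' spreadsheets with varying terminology ("M"/"F" versus "male"/"female",
#' "SLE" versus "lupus") store only controlled values. Condition, ethnicity
#' and gender vocabularies are global; response, treatment and time-point
#' label vocabularies are scoped to a project.
#'
#' @slot attribute attribute name (e.g. `"gender"`)
#' @slot scope `"global"` or `"project:<name>"`
#' @slot validValues the controlled term set
#' @slot valueMap named character: incoming string -> valid value
#' @export
setClass("ControlledVocabulary",
  representation(attribute = "character", scope = "character",
    validValues = "character", valueMap = "character"))

setValidity("ControlledVocabulary", function(object) {
  if (length(object@attribute) != 1L || !nzchar(object@attribute))
    return("attribute must be a single non-empty string")
  if (length(object@scope) != 1L ||
      !(object@scope == "global" || grepl("^project:.+", object@scope)))
    return("scope must be 'global' or 'project:<name>'")
  if (anyDuplicated(object@validValues))
    return("validValues must be unique")
  if (length(object@valueMap)) {
    if (is.null(names(object@valueMap)) || any(!nzchar(names(object@valueMap))))
      return("valueMap must be a named character vector")
    if (!all(object@valueMap %in% object@validValues))
      return("every valueMap target must be a valid value")
  }
  TRUE
})

# ---------------------------------------------------------------------------
# ColumnMapping
# ---------------------------------------------------------------------------

#' ColumnMapping: sheet columns mapped to warehouse attributes
#'
#' Maps metadata-sheet columns onto person and sample attributes. At least
#' one of `person_id` / `sample_id` must be mapped; person attributes are
#' only active when `person_id` is mapped and sample attributes only when
#' `sample_id` is. No sheet column may be mapped twice.
#'
#' @slot entries named character vector, `sheet column -> attribute`
#' @export
setClass("ColumnMapping", representation(entries = "character"))

PERSON_ATTRS <- c("gender", "ethnicity", "condition", "treatment",
                  "response", "age_years")
SAMPLE_ATTRS <- c("year", "month", "week", "day", "draw")
MAPPABLE_ATTRS <- c("person_id", "sample_id", PERSON_ATTRS, SAMPLE_ATTRS)

setValidity("ColumnMapping", function(object) {
  e <- object@entries
  if (!length(e) || is.null(names(e)) || any(!nzchar(names(e))))
    return("entries must be a named character vector (sheet column -> attribute)")
  if (anyDuplicated(names(e)))
    return("a sheet column is mapped twice")
  if (anyDuplicated(e))
    return("an attribute receives two sheet columns")
  bad <- setdiff(e, MAPPABLE_ATTRS)
  if (length(bad))
    return(paste0("unknown attribute(s): ", paste(bad, collapse = ", ")))
  if (!any(c("person_id", "sample_id") %in% e))
    return("at least one of person_id, sample_id must be mapped")
  if (any(PERSON_ATTRS %in% e) && !("person_id" %in% e))
    return("person attributes require person_id to be mapped")
  if (any(SAMPLE_ATTRS %in% e) && !("sample_id" %in% e))
    return("sample attributes require sample_id to be mapped")
  TRUE
})

# ---------------------------------------------------------------------------
# LinkSession
# ---------------------------------------------------------------------------

#' LinkSession: an identifier-reconciliation session
#'
#' Holds the two sides of a mapping task — unmapped child identifiers
#' (aliquot IDs or sample IDs) and candidate parent identifiers (sample IDs
#' or person IDs) — together with the ordered list of string transforms
#' applied to each side and the currently proposed pairs. Working strings
#' are always re-derivable from the verbatim external IDs by replaying the
#' transform list.
#'
#' @slot level `"aliquot_sample"` or `"sample_person"`
#' @slot child data.frame with `key`, `ext_id`, `working`
#' @slot parent data.frame with `key`, `ext_id`, `working`
#' @slot transforms list of recorded transforms (`side`, `op`, `phrase`)
#' @slot pairs data.frame with `child_key`, `parent_key`, `how`
#' @slot ambiguous child keys whose working string matched >= 2 parents
#' @slot sourceFilter source keys the session was opened under (empty = all)
#' @export
setClass("LinkSession",
  representation(level = "character", child = "data.frame",
    parent = "data.frame", transforms = "list", pairs = "data.frame",
    ambiguous = "character", sourceFilter = "integer"))

setValidity("LinkSession", function(object) {
  if (!object@level %in% c("aliquot_sample", "sample_person"))
    return("level must be 'aliquot_sample' or 'sample_person'")
  if (anyDuplicated(object@pairs$child_key))
    return("a child is mapped to more than one parent")
  TRUE
})

# ---------------------------------------------------------------------------
# CubeQuery / PivotResult
# ---------------------------------------------------------------------------

#' CubeQuery: an OLAP request against the warehouse cube
#'
#' Dimension levels are placed on the row and column axes, member filters
#' restrict the fact set, and measures are computed per cell. A level may
#' appear on at most one axis. Construct with [cubeQuery()].
#'
#' @slot rows ordered dimension levels on the row axis
#' @slot cols ordered dimension levels on the column axis
#' @slot filters named list: level -> member set to keep
#' @slot measures subset of `N, mean, median, min, max, sd, cv`
#' @export
setClass("CubeQuery",
  representation(rows = "character", cols = "character",
    filters = "list", measures = "character"))

#' PivotResult: an aggregated pivot with roll-up subtotals
#'
#' One row of `cells` per populated cell of the pivot, at every roll-up
#' depth: prefix levels not expanded carry the `"(all)"` member. When
#' `Units` is not on an axis it is retained as a hidden innermost grouping
#' (`unitsHidden = TRUE`) so that no cell pools facts with different units
#' strings. Cells are addressed by row number for [drillThrough()].
#'
#' @slot query the originating [CubeQuery-class]
#' @slot rowLevels,colLevels axis levels, in nesting order
#' @slot unitsHidden whether units is an implicit grouping column
#' @slot cells data.frame of member columns plus one column per measure
#' @export
setClass("PivotResult",
  representation(query = "CubeQuery", rowLevels = "character",
    colLevels = "character", unitsHidden = "logical", cells = "data.frame"))

setValidity("PivotResult", function(object) {
  cl <- object@cells
  if ("N" %in% names(cl) && nrow(cl)) {
    if (any(cl$N < 0) || any(cl$N != round(cl$N)))
      return("N cells must be non-negative integers")
    if (all(c("min", "median", "max") %in% names(cl))) {
      i <- cl$N >= 1
      if (any(cl$min[i] > cl$median[i] + 1e-12) ||
          any(cl$median[i] > cl$max[i] + 1e-12))
        return("min <= median <= max violated")
    }
  }
  TRUE
})

# ---------------------------------------------------------------------------
# StudySpec
# ---------------------------------------------------------------------------

#' StudySpec: parameters of the synthetic vaccination cohort
#'
#' Describes a synthetic influenza-vaccination-style study: healthy
#' participants each sampled at three visits (day 0, 7 and 28), serum
#' assayed on a 51-plex bead panel split across two kit lots, a 4-plex
#' electrochemiluminescence panel, and PBMC phospho-flow under seven
#' cytokine stimulations plus an unstimulated baseline. Effects (gender
#' fold-ratios, lot factors) are planted multiplicatively on log-normal
#' readouts; the generator's manifest records the ground truth.
#' Construct with [studySpec()].
#'
#' @slot nPersons number of participants
#' @slot visitDays study-day ordinals of the visits
#' @slot luminexAnalytes 51 bead-panel analyte names
#' @slot msdAnalytes 4-plex panel analyte names
#' @slot stims stimulation conditions for phospho-flow (excl. unstim)
#' @slot phosphoReadouts phospho readout columns
#' @slot lots kit lot names for the bead panel
#' @slot lotFactors multiplicative lot factor per lot
#' @slot genderEffect named fold-ratios (female/male) per bead analyte;
#'   analytes not named have fold 1
#' @slot msdGenderEffect named fold-ratios for the 4-plex panel
#' @slot noiseSigma log-scale standard deviation of readout noise
#' @slot baselineRange range the per-analyte baseline medians are drawn from
#' @slot belowLoqQuantile fraction of bead readouts flagged below the LOQ
#' @slot idPrefix,idSuffix decoration applied to aliquot identifiers
#' @slot il6Pstat1Coupling optional coupling: higher serum IL-6 shifts the
#'   IL-6-stimulated pSTAT1 induction down (0 = off)
#' @slot assays which assay families to generate
#' @slot seed integer seed; fully determines the output
#' @export
setClass("StudySpec",
  representation(nPersons = "integer", visitDays = "integer",
    luminexAnalytes = "character", msdAnalytes = "character",
    stims = "character", phosphoReadouts = "character",
    lots = "character", lotFactors = "numeric",
    genderEffect = "numeric", msdGenderEffect = "numeric",
    noiseSigma = "numeric", baselineRange = "numeric",
    belowLoqQuantile = "numeric", idPrefix = "character",
    idSuffix = "character", il6Pstat1Coupling = "numeric",
    assays = "character", seed = "integer"))

setValidity("StudySpec", function(object) {
  if (object@nPersons < 1L) return("nPersons must be >= 1")
  if (!length(object@visitDays) || any(object@visitDays < 0L))
    return("visitDays must be non-negative ordinals")
  if (any(object@genderEffect <= 0) || any(object@msdGenderEffect <= 0) ||
      any(object@lotFactors <= 0))
    return("all fold-ratios and lot factors must be > 0")
  if (object@noiseSigma <= 0) return("noiseSigma must be > 0")
  if (length(object@lotFactors) != length(object@lots))
    return("one lot factor per lot")
  if (!all(object@assays %in% c("luminex", "msd", "phospho_flow")))
    return("assays must be a subset of luminex, msd, phospho_flow")
  TRUE
})

# ---------------------------------------------------------------------------
# show methods
# ---------------------------------------------------------------------------

setMethod("show", "AssayWarehouse", function(object) {
  n <- function(t) tryCatch(
    DBI::dbGetQuery(object@con, paste0("SELECT COUNT(*) AS n FROM ", t))$n,
    error = function(e) NA_integer_)
  cat("AssayWarehouse <", object@path, ">\n", sep = "")
  cat(sprintf("  facts: %d  persons: %d  samples: %d  analytes: %d  sources: %d\n",
      n("aliquot_fact"), n("person"), n("sample"), n("analyte"), n("source")))
})

setMethod("show", "BatchSheet", function(object) {
  cat(sprintf("BatchSheet '%s' (%s): %d analytes x %d rows, %d facts, %d blank\n",
      object@fileName, object@assayFamily, length(object@analytes),
      object@nDataRows, nrow(object@cells), object@nBlank))
})

setMethod("show", "ControlledVocabulary", function(object) {
  cat(sprintf("ControlledVocabulary '%s' [%s]: {%s}; %d mapped value(s)\n",
      object@attribute, object@scope,
      paste(object@validValues, collapse = ", "), length(object@valueMap)))
})

setMethod("show", "LinkSession", function(object) {
  cat(sprintf("LinkSession %s: %d unmapped child(ren), %d parent(s), %d proposed pair(s), %d ambiguous\n",
      object@level, nrow(object@child), nrow(object@parent),
      nrow(object@pairs), length(object@ambiguous)))
  if (length(object@transforms))
    cat("  transforms:",
        paste(vapply(object@transforms, function(t)
          sprintf("%s(%s,'%s')", t$op, t$side, t$phrase %||% ""), ""),
          collapse = " -> "), "\n")
})

setMethod("show", "CubeQuery", function(object) {
  cat("CubeQuery rows=[", paste(object@rows, collapse = ", "),
      "] cols=[", paste(object@cols, collapse = ", "),
      "] measures=[", paste(object@measures, collapse = ", "), "]",
      if (length(object@filters)) sprintf(" %d filter(s)", length(object@filters)),
      "\n", sep = "")
})

setMethod("show", "PivotResult", function(object) {
  cat(sprintf("PivotResult: %d cell(s); rows=[%s] cols=[%s]%s\n",
      nrow(object@cells), paste(object@rowLevels, collapse = ", "),
      paste(object@colLevels, collapse = ", "),
      if (object@unitsHidden) " (units held as hidden grouping)" else ""))
})

setMethod("show", "StudySpec", function(object) {
  cat(sprintf("StudySpec: %d persons x %d visits; %d bead analytes in %d lot(s); seed %d\n",
      object@nPersons, length(object@visitDays),
      length(object@luminexAnalytes), length(object@lots), object@seed))
})
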