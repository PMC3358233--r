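#' @include synthetic_study.R
NULL

#' Load a generated study into a warehouse
#'
#' Loads the person and sample metadata sheets (resolving "M"/"F" through
#' the declared gender value map and auto-proposing the ethnicity
#' mappings) and every generated batch sheet with its source attributes.
#' Metadata and batch results can be loaded in either order; this helper
#' loads metadata first by default.
#'
#' @param store an [AssayWarehouse-class]
#' @param manifest a manifest from [generateStudy()]
#' @param metadata_first load metadata before batch results
#' @return invisibly a list of per-step summaries
#' @export
loadStudy <- function(store, manifest, metadata_first = TRUE) {
  stopifnot(inherits(manifest, "studyManifest"))
  load_meta <- function() {
    eth <- proposeValueMapping(manifest$person_sheet$ethnicity,
                               getVocabulary(store, "ethnicity"))
    if (length(eth$unresolved))
      stop("unexpected unresolved ethnicity values: ",
           paste(eth$unresolved, collapse = ", "), call. = FALSE)
    ps <- loadMetadata(store, manifest$person_sheet,
      columnMapping(c(person_id = "person_id", gender = "gender",
                      ethnicity = "ethnicity", age = "age_years")),
      value_maps = c(manifest$value_maps, list(ethnicity = eth$mapped)))
    ss <- loadMetadata(store, manifest$sample_sheet,
      columnMapping(c(sample_id = "sample_id", day = "day")))
    list(persons = ps, samples = ss)
  }
  out <- list()
  if (metadata_first) out$metadata <- load_meta()
  for (nm in names(manifest$sheets))
    out[[nm]] <- loadBatch(store, manifest$sheets[[nm]],
                           manifest$sheet_attrs[[nm]])
  if (!metadata_first) out$metadata <- load_meta()
  invisible(out)
}

#' Link a loaded study by stripping the declared ID phrases
#'
#' Runs the two reconciliation levels with the manifest's declared
#' decoration phrases: aliquot IDs are stripped down to sample IDs and
#' mapped with [mapEquals()]; sample IDs are stripped of their visit
#' suffix down to person IDs and mapped likewise. Both commits must be
#' complete (no ambiguous or unmatched children).
#'
#' @param store an [AssayWarehouse-class]
#' @param manifest a manifest from [generateStudy()]
#' @return invisibly a list of the two commit summaries
#' @export
linkStudy <- function(store, manifest) {
  stopifnot(inherits(manifest, "studyManifest"))
  out <- list()
  s <- openLinkSession(store, "aliquot_sample")
  if (nrow(s@child)) {
    for (ph in manifest$strip_phrases$aliquot)
      s <- stripPhrase(s, "child", ph)
    s <- mapEquals(s)
    out$aliquot_sample <- commitSession(s, store)
  }
  s2 <- suppressWarnings(openLinkSession(store, "sample_person"))
  if (nrow(s2@child)) {
    for (ph in manifest$strip_phrases$sample)
      s2 <- stripPhrase(s2, "child", ph)
    s2 <- mapEquals(s2)
    out$sample_person <- commitSession(s2, store)
  }
  invisible(out)
}

#' Generate, load and link a synthetic study in one call
#'
#' @param spec a [StudySpec-class]
#' @param store_path store location (default: in-memory)
#' @return list with `store`, `manifest` and the final [integrityReport()]
#' @export
runStudyPipeline <- function(spec = studySpec(), store_path = ":memory:") {
  manifest <- generateStudy(spec)
  store <- createStore(store_path)
  loadStudy(store, manifest)
  linkStudy(store, manifest)
  list(store = store, manifest = manifest,
       report = integrityReport(store))
}

#' Screen cube means for gender-biased analytes
#'
#' The scripted equivalent of scanning a pivot of analyte rows against
#' gender columns: aggregates mean readout by analyte and gender for one
#' assay (optionally within one kit lot) and flags analytes whose
#' female/male mean ratio differs from 1 by more than the threshold in
#' either direction.
#'
#' @param store an [AssayWarehouse-class]
#' @param assay assay member to filter on (source `assay` attribute)
#' @param threshold percent difference (20 means "> 20%")
#' @param lot optional kit lot member to restrict to
#' @return data.frame: `analyte`, `n_male`, `n_female`, `male_mean`,
#'   `female_mean`, `fold` (female/male) and `flagged`
#' @export
genderBiasScreen <- function(store, assay = "Human Luminex 51plex",
                             threshold = 20, lot = NULL) {
  filters <- list(Assay = assay)
  if (!is.null(lot)) filters$Lot <- lot
  q <- cubeQuery(rows = "Analyte", cols = "Gender", filters = filters,
                 measures = c("N", "mean"))
  cl <- pivotCells(aggregateCube(store, q))
  cl <- cl[cl$Analyte != "(all)" & cl$Gender %in% c("male", "female"), ]
  if (!nrow(cl))
    return(data.frame(analyte = character(0), n_male = integer(0),
      n_female = integer(0), male_mean = numeric(0),
      female_mean = numeric(0), fold = numeric(0), flagged = logical(0)))
  dt <- data.table::as.data.table(cl)
  wide <- data.table::dcast(dt, Analyte ~ Gender,
                            value.var = c("N", "mean"))
  res <- data.frame(analyte = wide$Analyte,
    n_male = wide$N_male, n_female = wide$N_female,
    male_mean = wide$mean_male, female_mean = wide$mean_female,
    stringsAsFactors = FALSE)
  res$fold <- res$female_mean / res$male_mean
  res$flagged <- !is.na(res$fold) &
    pmax(res$fold, 1 / res$fold) - 1 > threshold / 100
  res[order(res$analyte), , drop = FALSE]
}
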