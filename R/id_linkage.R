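#' @include metadata_ingest.R
NULL

#' Open an identifier-reconciliation session
#'
#' At the `aliquot_sample` level the child side holds the distinct aliquot
#' IDs of facts not yet linked to a sample and the parent side all sample
#' IDs; at the `sample_person` level the child side holds samples not yet
#' linked to a person and the parent side all person IDs. The child side
#' can be restricted to particular source documents. Working strings start
#' as the verbatim external IDs; transforms applied later never touch the
#' stored IDs.
#'
#' @param store an [AssayWarehouse-class]
#' @param level `"aliquot_sample"` or `"sample_person"`
#' @param source_keys optional integer vector restricting the child side
#'   to facts from these sources (aliquot level only)
#' @return a [LinkSession-class]; empty (with a warning) if the filter
#'   matches nothing
#' @export
openLinkSession <- function(store, level = c("aliquot_sample",
                            "sample_person"), source_keys = NULL) {
  level <- match.arg(level)
  con <- store@con
  if (level == "aliquot_sample") {
    sql <- "SELECT DISTINCT aliquot_id_ext FROM aliquot_fact
            WHERE sample_key IS NULL"
    if (length(source_keys))
      sql <- paste0(sql, " AND source_key IN (",
                    paste(as.integer(source_keys), collapse = ","), ")")
    kids <- DBI::dbGetQuery(con, paste(sql, "ORDER BY aliquot_id_ext"))
    child <- data.frame(key = kids$aliquot_id_ext,
                        ext_id = kids$aliquot_id_ext,
                        working = kids$aliquot_id_ext,
                        stringsAsFactors = FALSE)
    par <- DBI::dbGetQuery(con,
      "SELECT sample_key, sample_id_ext FROM sample ORDER BY sample_key")
    parent <- data.frame(key = as.character(par$sample_key),
                         ext_id = par$sample_id_ext,
                         working = par$sample_id_ext,
                         stringsAsFactors = FALSE)
  } else {
    kids <- DBI::dbGetQuery(con,
      "SELECT sample_key, sample_id_ext FROM sample
       WHERE person_key IS NULL ORDER BY sample_key")
    child <- data.frame(key = as.character(kids$sample_key),
                        ext_id = kids$sample_id_ext,
                        working = kids$sample_id_ext,
                        stringsAsFactors = FALSE)
    par <- DBI::dbGetQuery(con,
      "SELECT person_key, person_id_ext FROM person ORDER BY person_key")
    parent <- data.frame(key = as.character(par$person_key),
                         ext_id = par$person_id_ext,
                         working = par$person_id_ext,
                         stringsAsFactors = FALSE)
  }
  if (!nrow(child))
    warning("no unmapped ", if (level == "aliquot_sample") "aliquots"
            else "samples", " under the given filter; session is empty")
  methods::new("LinkSession", level = level, child = child, parent = parent,
    transforms = list(),
    pairs = data.frame(child_key = character(0), parent_key = character(0),
                       how = character(0), stringsAsFactors = FALSE),
    ambiguous = character(0),
    sourceFilter = as.integer(source_keys %||% integer(0)))
}

replay_transforms <- function(ids, transforms, side) {
  for (t in transforms) {
    if (t$side != side) next
    ids <- switch(t$op,
      strip = gsub(t$phrase, "", ids, fixed = TRUE),
      casefold = tolower(ids),
      stop("unknown transform op: ", t$op))
  }
  ids
}

#' Remove a phrase from one side's working strings
#'
#' Every occurrence of `phrase` is removed (fixed-string, per-occurrence)
#' from the working string of each entry on the chosen side; the transform
#' is recorded so the working strings can be replayed from the verbatim
#' external IDs. Stored IDs are never modified.
#'
#' @param session a [LinkSession-class]
#' @param side `"child"` or `"parent"`
#' @param phrase non-empty string to remove
#' @return the updated session
#' @export
#' @examples
#' # "HIMC-S001_A" --strip "HIMC-"--> "S001_A" --strip "_A"--> "S001"
stripPhrase <- function(session, side = c("child", "parent"), phrase) {
  side <- match.arg(side)
  if (!is.character(phrase) || length(phrase) != 1L || !nzchar(phrase))
    stop("phrase must be a single non-empty string", call. = FALSE)
  slot(session, side)$working <-
    gsub(phrase, "", slot(session, side)$working, fixed = TRUE)
  session@transforms <- c(session@transforms,
                          list(list(side = side, op = "strip",
                                    phrase = phrase)))
  session
}

#' Case-fold one side's working strings
#'
#' Matching in [mapEquals()] is case-sensitive by default; this optional
#' transform lower-cases a side when case differences are known to be
#' incidental.
#'
#' @inheritParams stripPhrase
#' @return the updated session
#' @export
caseFold <- function(session, side = c("child", "parent")) {
  side <- match.arg(side)
  slot(session, side)$working <- tolower(slot(session, side)$working)
  session@transforms <- c(session@transforms,
                          list(list(side = side, op = "casefold",
                                    phrase = NULL)))
  session
}

#' Propose pairs for all exactly matching working strings
#'
#' Every unproposed child whose working string equals the working string
#' of exactly one parent is paired with that parent. Children matching no
#' parent stay unproposed; children matching two or more parents are
#' recorded as ambiguous and left unproposed — ambiguity is surfaced,
#' never auto-resolved.
#'
#' @param session a [LinkSession-class]
#' @return the updated session
#' @export
mapEquals <- function(session) {
  par_tab <- table(session@parent$working)
  unique_parents <- names(par_tab)[par_tab == 1L]
  open <- !(session@child$key %in% session@pairs$child_key)
  w <- session@child$working
  matchable <- open & (w %in% unique_parents)
  ambiguous <- open & (w %in% names(par_tab)[par_tab > 1L])
  idx <- match(w[matchable], session@parent$working)
  if (any(matchable)) {
    session@pairs <- rbind(session@pairs, data.frame(
      child_key = session@child$key[matchable],
      parent_key = session@parent$key[idx],
      how = "equals", stringsAsFactors = FALSE))
  }
  session@ambiguous <- unique(c(session@ambiguous,
                                session@child$key[ambiguous]))
  methods::validObject(session)
  session
}

#' Propose a single explicit pair
#'
#' The scripted equivalent of dragging one child ID onto a parent ID.
#' Re-mapping a child that already has a proposal requires `override`.
#'
#' @param session a [LinkSession-class]
#' @param child_key,parent_key session keys of the pair
#' @param override replace an existing proposal for this child
#' @return the updated session
#' @export
mapPair <- function(session, child_key, parent_key, override = FALSE) {
  if (!child_key %in% session@child$key)
    stop("unknown child key: ", child_key, call. = FALSE)
  if (!parent_key %in% session@parent$key)
    stop("unknown parent key: ", parent_key, call. = FALSE)
  has <- session@pairs$child_key == child_key
  if (any(has)) {
    if (!override)
      stop("child '", child_key, "' already has a proposed pair; ",
           "use override = TRUE to replace it", call. = FALSE)
    session@pairs <- session@pairs[!has, , drop = FALSE]
  }
  session@pairs <- rbind(session@pairs, data.frame(
    child_key = child_key, parent_key = parent_key, how = "manual",
    stringsAsFactors = FALSE))
  methods::validObject(session)
  session
}

#' Commit proposed pairs to the store
#'
#' Updates the child foreign keys (fact `sample_key`, or sample
#' `person_key`) for every proposed pair, atomically: if any targeted
#' child was mapped concurrently since the session was opened, the whole
#' commit aborts and the store is unchanged. The applied transforms and
#' pairs are written to the audit log.
#'
#' @param session a [LinkSession-class] with at least one proposed pair
#' @param store the [AssayWarehouse-class] the session was opened on
#' @return list of class `"commitSummary"`: `n_committed`,
#'   `n_children_unmapped` (children left without a proposal),
#'   `n_facts_updated` (aliquot level)
#' @export
commitSession <- function(session, store) {
  if (!nrow(session@pairs))
    stop("nothing to commit: the session has no proposed pairs",
         call. = FALSE)
  con <- store@con
  pairs <- session@pairs
  DBI::dbExecute(con, "BEGIN IMMEDIATE")
  ok <- FALSE
  on.exit(if (!ok) DBI::dbExecute(con, "ROLLBACK"))
  n_facts_updated <- NA_integer_
  if (session@level == "aliquot_sample") {
    map <- data.frame(aliquot_id_ext = pairs$child_key,
                      new_sample_key = as.integer(pairs$parent_key),
                      stringsAsFactors = FALSE)
    DBI::dbWriteTable(con, "link_map_tmp", map, temporary = TRUE,
                      overwrite = TRUE)
    srcflt <- if (length(session@sourceFilter))
      paste0(" AND source_key IN (",
             paste(session@sourceFilter, collapse = ","), ")") else ""
    conflict <- DBI::dbGetQuery(con, paste0(
      "SELECT COUNT(*) AS n FROM aliquot_fact
       WHERE aliquot_id_ext IN (SELECT aliquot_id_ext FROM link_map_tmp)
         AND sample_key IS NOT NULL", srcflt))$n
    if (conflict > 0)
      stop("commit aborted: ", conflict, " fact(s) in this session were ",
           "mapped concurrently; store unchanged", call. = FALSE)
    n_facts_updated <- DBI::dbExecute(con, paste0(
      "UPDATE aliquot_fact SET sample_key =
         (SELECT new_sample_key FROM link_map_tmp t
          WHERE t.aliquot_id_ext = aliquot_fact.aliquot_id_ext)
       WHERE aliquot_id_ext IN (SELECT aliquot_id_ext FROM link_map_tmp)
         AND sample_key IS NULL", srcflt))
    DBI::dbRemoveTable(con, "link_map_tmp")
  } else {
    map <- data.frame(sample_key = as.integer(pairs$child_key),
                      new_person_key = as.integer(pairs$parent_key))
    DBI::dbWriteTable(con, "link_map_tmp", map, temporary = TRUE,
                      overwrite = TRUE)
    conflict <- DBI::dbGetQuery(con,
      "SELECT COUNT(*) AS n FROM sample
       WHERE sample_key IN (SELECT sample_key FROM link_map_tmp)
         AND person_key IS NOT NULL")$n
    if (conflict > 0)
      stop("commit aborted: ", conflict, " sample(s) in this session were ",
           "mapped concurrently; store unchanged", call. = FALSE)
    DBI::dbExecute(con,
      "UPDATE sample SET person_key =
         (SELECT new_person_key FROM link_map_tmp t
          WHERE t.sample_key = sample.sample_key)
       WHERE sample_key IN (SELECT sample_key FROM link_map_tmp)")
    DBI::dbRemoveTable(con, "link_map_tmp")
  }
  DBI::dbExecute(con, "COMMIT")
  ok <- TRUE
  audit(store, "link_commit", list(level = session@level,
    transforms = session@transforms, n_pairs = nrow(pairs)))
  structure(list(
    n_committed = nrow(pairs),
    n_children_unmapped = nrow(session@child) - nrow(pairs),
    n_facts_updated = n_facts_updated), class = "commitSummary")
}

#' @export
print.commitSummary <- function(x, ...) {
  cat(sprintf("Commit: %d pair(s) committed, %d child(ren) left unmapped",
              x$n_committed, x$n_children_unmapped))
  if (!is.na(x$n_facts_updated))
    cat(sprintf(" (%d fact rows updated)", x$n_facts_updated))
  cat("\n")
  invisible(x)
}

#' Save / load a link session as JSON
#'
#' Sessions are serializable so a proposed mapping can be reviewed or
#' replayed; working strings are re-derived from the external IDs and the
#' transform list on load.
#'
#' @param session a [LinkSession-class]
#' @param path JSON file path
#' @return `writeLinkSession`: invisibly `path`; `readLinkSession`: the
#'   session
#' @export
writeLinkSession <- function(session, path) {
  obj <- list(level = session@level, child = session@child,
    parent = session@parent, transforms = session@transforms,
    pairs = session@pairs, ambiguous = session@ambiguous,
    sourceFilter = session@sourceFilter)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname writeLinkSession
#' @export
readLinkSession <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_df <- function(x, cols) {
    if (is.null(x) || !length(x) || (is.data.frame(x) && !nrow(x))) {
      df <- as.data.frame(stats::setNames(
        rep(list(character(0)), length(cols)), cols),
        stringsAsFactors = FALSE)
      return(df)
    }
    as.data.frame(lapply(x[cols], as.character), stringsAsFactors = FALSE)
  }
  tr <- o$transforms
  transforms <- if (is.null(tr) || !length(tr)) list()
    else if (is.data.frame(tr)) lapply(seq_len(nrow(tr)), function(i) {
      ph <- if ("phrase" %in% names(tr)) tr$phrase[i] else NULL
      list(side = tr$side[i], op = tr$op[i],
           phrase = if (is.null(ph) || is.na(ph)) NULL else ph)
    })
    else lapply(tr, function(t)
      list(side = t$side, op = t$op, phrase = t$phrase))
  child <- as_df(o$child, c("key", "ext_id", "working"))
  parent <- as_df(o$parent, c("key", "ext_id", "working"))
  # replay: working strings are a pure function of ext IDs + transforms
  child$working <- replay_transforms(child$ext_id, transforms, "child")
  parent$working <- replay_transforms(parent$ext_id, transforms, "parent")
  methods::new("LinkSession", level = o$level, child = child,
    parent = parent, transforms = transforms,
    pairs = as_df(o$pairs, c("child_key", "parent_key", "how")),
    ambiguous = as.character(o$ambiguous %||% character(0)),
    sourceFilter = as.integer(o$sourceFilter %||% integer(0)))
}
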