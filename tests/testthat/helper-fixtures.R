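# shared fixtures: all built in code at test time

local_store <- function(path = ":memory:", envir = parent.frame()) {
  s <- createStore(path)
  withr::defer(try(closeStore(s), silent = TRUE), envir = envir)
  s
}

write_csv_lines <- function(lines, file = tempfile(fileext = ".csv")) {
  writeLines(lines, file)
  file
}

# a small 4-plex sheet in the canonical layout (2 header rows + ID column)
msd_fixture_csv <- function(file = tempfile(fileext = ".csv")) {
  write_csv_lines(c(
    "aliquot_id,IL-1b,IL-6,IL-8,TNF",
    ",pg/ml,pg/ml,pg/ml,pg/ml",
    "A1,1.5,22.1,8.0,3.3",
    "A2,<0.4,18.9,7.2,2.9",
    "A3,2.1,25.4,>100,3.8"), file)
}

# phospho-flow sheet: stim column, 3 readouts, 2 aliquots x 8 stim rows
phospho_fixture_csv <- function(file = tempfile(fileext = ".csv")) {
  stims <- c("none", "IFNa", "IFNg", "IL-2", "IL-6", "IL-7", "IL-10",
             "IL-21")
  rows <- unlist(lapply(c("A1", "A2"), function(id)
    sprintf("%s,%s,%g,%g,%g", id, stims,
            seq_along(stims) + 10, seq_along(stims) + 20,
            seq_along(stims) + 30)))
  write_csv_lines(c("aliquot_id,stim,pSTAT1,pSTAT3,pSTAT5",
                    ",,MFI,MFI,MFI", rows), file)
}

# load a tiny fully-linked store by hand for cube unit tests
tiny_linked_store <- function(envir = parent.frame()) {
  s <- local_store(envir = envir)
  loadMetadata(s,
    data.frame(pid = c("P1", "P2"), g = c("male", "female"),
               stringsAsFactors = FALSE),
    columnMapping(c(pid = "person_id", g = "gender")))
  loadMetadata(s,
    data.frame(pid = c("P1", "P1", "P2", "P2"),
               sid = c("S1", "S2", "S3", "S4"),
               day = c(0, 7, 0, 7), stringsAsFactors = FALSE),
    columnMapping(c(pid = "person_id", sid = "sample_id", day = "day")))
  sheet <- batchSheet("tiny.csv", "msd", c("IL-6", "TNF"),
    c("pg/ml", "pg/ml"),
    data.frame(
      aliquot_id_ext = rep(c("S1", "S2", "S3", "S4"), each = 2L),
      stim = "none",
      analyte = rep(c("IL-6", "TNF"), 4L),
      units = "pg/ml",
      readout = c(10, 1, 20, 2, 30, 3, 40, 4),
      quantification = "in_range", stringsAsFactors = FALSE),
    nDataRows = 4L)
  loadBatch(s, sheet, sourceAttributes(assay = "MSD 4plex",
                                       tissue = "serum"))
  ses <- mapEquals(openLinkSession(s, "aliquot_sample"))
  commitSession(ses, s)
  s
}

# ---------------------------------------------------------------------------
# independent flat filter-then-group oracle for the cube
# (base R only; reimplements the member rules naively)
# ---------------------------------------------------------------------------

oracle_flat <- function(store) {
  con <- store@con
  f <- DBI::dbGetQuery(con, "SELECT * FROM aliquot_fact")
  a <- DBI::dbGetQuery(con, "SELECT * FROM analyte")
  so <- DBI::dbGetQuery(con, "SELECT * FROM source")
  m <- DBI::dbGetQuery(con, "SELECT * FROM sample")
  p <- DBI::dbGetQuery(con, "SELECT * FROM person")
  df <- merge(f, a, by = "analyte_key")
  df <- merge(df, so, by = "source_key", suffixes = c("", ".src"))
  df <- merge(df, m, by = "sample_key", all.x = TRUE,
              suffixes = c("", ".smp"))
  df <- merge(df, p, by = "person_key", all.x = TRUE,
              suffixes = c("", ".per"))
  df
}

oracle_member <- function(df, level) {
  time_lv <- c(Year = "year", Month = "month", Week = "week",
               Day = "day", Draw = "draw")
  pers_lv <- c(Gender = "gender", AgeBand = "age_band",
               Ethnicity = "ethnicity", Condition = "condition",
               Treatment = "treatment", Response = "response")
  un_p <- is.na(df$sample_key) | is.na(df$person_key)
  if (level %in% names(time_lv)) {
    x <- as.character(df[[time_lv[[level]]]])
    x[is.na(x)] <- "(unspecified)"
    x[is.na(df$sample_key)] <- "(unmapped)"
  } else if (level %in% names(pers_lv)) {
    x <- df[[pers_lv[[level]]]]
    x[is.na(x)] <- "unknown"
    x[un_p] <- "(unmapped)"
  } else {
    x <- switch(level,
      Assay = df$assay, Analyte = df$analyte_name, Units = df$units,
      PI = df$pi, Project = df$project, Lot = df$lot,
      Document = df$file_name, Tissue = df$tissue, Stim = df$stim,
      Quantification = df$quantification)
    if (level %in% c("Assay", "PI", "Project", "Lot"))
      x[is.na(x)] <- "(unspecified)"
  }
  as.character(x)
}

# full-depth reference cells: one row per populated (members..., Units)
oracle_cells <- function(store, query) {
  df <- oracle_flat(store)
  axes <- c(query@rows, query@cols)
  need <- unique(c(axes, names(query@filters), "Units"))
  for (lv in need) df[[paste0(".", lv)]] <- oracle_member(df, lv)
  for (lv in names(query@filters))
    df <- df[df[[paste0(".", lv)]] %in% query@filters[[lv]], ,
             drop = FALSE]
  gcols <- paste0(".", unique(c(axes, "Units")))
  if (!nrow(df))
    return(data.frame(key = character(0), N = integer(0),
                      mean = numeric(0), median = numeric(0),
                      min = numeric(0), max = numeric(0)))
  key <- do.call(paste, c(df[gcols], sep = "\r"))
  groups <- split(df$readout, key)
  out <- data.frame(key = names(groups), stringsAsFactors = FALSE)
  out$N <- vapply(groups, length, 1L)
  out$mean <- vapply(groups, mean, 1)
  out$median <- vapply(groups, stats::median, 1)
  out$min <- vapply(groups, min, 1)
  out$max <- vapply(groups, max, 1)
  out
}

# compare implementation cells at full depth against the oracle
expect_matches_oracle <- function(store, query) {
  res <- aggregateCube(store, query)
  cl <- pivotCells(res)
  axes <- c(res@rowLevels, res@colLevels)
  if (length(axes))
    for (lv in axes) cl <- cl[cl[[lv]] != "(all)", , drop = FALSE]
  keycols <- unique(c(axes, "Units"))
  key <- if (nrow(cl)) do.call(paste, c(cl[keycols], sep = "\r"))
         else character(0)
  ref <- oracle_cells(store, query)
  expect_identical(sort(key), sort(ref$key))
  i <- match(key, ref$key)
  expect_identical(as.integer(cl$N), as.integer(ref$N[i]))
  for (msr in intersect(c("mean", "median", "min", "max"), names(cl)))
    expect_equal(cl[[msr]], ref[[msr]][i], tolerance = 1e-9)
  invisible(res)
}

# ---------------------------------------------------------------------------
# randomized small stores and queries
# ---------------------------------------------------------------------------

random_store <- function(seed, envir = parent.frame()) {
  set.seed(seed)
  s <- local_store(envir = envir)
  n_per <- sample(4:8, 1)
  pid <- paste0("P", seq_len(n_per))
  persons <- data.frame(person_id = pid,
    gender = sample(c("male", "female", ""), n_per, replace = TRUE),
    age = ifelse(runif(n_per) < 0.8,
                 as.character(sample(20:89, n_per, replace = TRUE)), ""),
    stringsAsFactors = FALSE)
  loadMetadata(s, persons,
    columnMapping(c(person_id = "person_id", gender = "gender",
                    age = "age_years")))
  # samples: most linked to persons, some day-less (draw only)
  n_samp <- sample(8:15, 1)
  sid <- paste0("S", seq_len(n_samp))
  samples <- data.frame(
    person_id = sample(pid, n_samp, replace = TRUE), sample_id = sid,
    day = ifelse(runif(n_samp) < 0.8,
                 as.character(sample(c(0, 7, 28), n_samp, TRUE)), ""),
    draw = ifelse(runif(n_samp) < 0.3, "1", ""),
    stringsAsFactors = FALSE)
  samples$draw[!nzchar(samples$day)] <- "1"
  loadMetadata(s, samples,
    columnMapping(c(person_id = "person_id", sample_id = "sample_id",
                    day = "day", draw = "draw")))
  n_sheets <- sample(2:4, 1)
  for (k in seq_len(n_sheets)) {
    fam <- sample(c("luminex", "msd", "phospho_flow"), 1)
    n_an <- sample(2:5, 1)
    analytes <- paste0("An", sample(1:8, n_an))
    units <- sample(c("raw MFI", "pg/ml"), n_an, replace = TRUE)
    ids <- unique(c(sample(sid, min(length(sid), sample(4:10, 1))),
                    if (runif(1) < 0.5) paste0("X", k)))  # X* stay unmapped
    stims <- if (fam == "phospho_flow") c("none", "IL-6") else "none"
    grid <- expand.grid(id = ids, stim = stims, ai = seq_len(n_an),
                        stringsAsFactors = FALSE)
    keep <- runif(nrow(grid)) > 0.1   # ~10% blanks
    grid <- grid[keep, , drop = FALSE]
    cells <- data.frame(
      aliquot_id_ext = grid$id, stim = grid$stim,
      analyte = analytes[grid$ai], units = units[grid$ai],
      readout = round(rlnorm(nrow(grid), 3, 1), 3),
      quantification = sample(QUANTIFICATION_LEVELS, nrow(grid), TRUE,
                              prob = c(0.9, 0.07, 0.03)),
      stringsAsFactors = FALSE)
    sheet <- batchSheet(sprintf("rnd_%d_%d.csv", seed, k), fam,
                        analytes, units, cells, nDataRows = length(ids))
    loadBatch(s, sheet, sourceAttributes(
      assay = paste0("assay-", fam), tissue = sample(c("serum", "PBMC"), 1),
      lot = sample(c("L1", "L2", NA), 1), pi = "PI-x",
      project = sample(c("projA", "projB"), 1)))
  }
  ses <- suppressWarnings(openLinkSession(s, "aliquot_sample"))
  ses <- mapEquals(ses)
  if (nrow(ses@pairs)) commitSession(ses, s)
  s
}

random_query <- function(seed) {
  set.seed(seed)
  lvls <- c("Assay", "Analyte", "Units", "Day", "Draw", "Gender",
            "AgeBand", "Tissue", "Stim", "Quantification", "Lot",
            "Project", "Document")
  k <- sample(0:2, 2, replace = TRUE)
  ax <- sample(lvls, sum(k))
  rows <- if (k[1]) ax[seq_len(k[1])] else character(0)
  cols <- if (k[2]) ax[k[1] + seq_len(k[2])] else character(0)
  filters <- list()
  if (runif(1) < 0.6)
    filters <- switch(sample(4, 1),
      list(Tissue = "serum"),
      list(Stim = c("none", "IL-6")),
      list(Gender = c("male", "female", "unknown")),
      list(Day = c("0", "7", "(unmapped)")))
  cubeQuery(rows = rows, cols = cols, filters = filters,
            measures = c("N", "mean", "median", "min", "max"))
}
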