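link_fixture <- function(envir = parent.frame()) {
  s <- local_store(envir = envir)
  loadMetadata(s,
    data.frame(sid = c("S001", "S002", "S003"), day = c(0, 7, 28)),
    columnMapping(c(sid = "sample_id", day = "day")))
  cells <- data.frame(
    aliquot_id_ext = paste0("HIMC-S00", 1:3, "_A"), stim = "none",
    analyte = "IL-6", units = "pg/ml", readout = c(1, 2, 3),
    quantification = "in_range", stringsAsFactors = FALSE)
  sheet <- batchSheet("b.csv", "msd", "IL-6", "pg/ml", cells,
                      nDataRows = 3L)
  loadBatch(s, sheet, sourceAttributes(assay = "MSD"))
  s
}

test_that("sessions hold only unmapped children; filters restrict by source", {
  s <- link_fixture()
  ses <- openLinkSession(s, "aliquot_sample")
  expect_identical(nrow(ses@child), 3L)
  expect_identical(ses@child$working, ses@child$ext_id)  # verbatim start
  # second source, then filter to it
  cells <- data.frame(aliquot_id_ext = "HIMC-S003_B", stim = "none",
    analyte = "IL-6", units = "pg/ml", readout = 9,
    quantification = "in_range", stringsAsFactors = FALSE)
  summ <- loadBatch(s, batchSheet("b2.csv", "msd", "IL-6", "pg/ml",
                                  cells, 1L),
                    sourceAttributes(assay = "MSD"))
  ses2 <- openLinkSession(s, "aliquot_sample",
                          source_keys = summ$source_key)
  expect_identical(ses2@child$ext_id, "HIMC-S003_B")
  expect_warning(
    openLinkSession(s, "aliquot_sample", source_keys = 999L), "empty")
})

test_that("phrase stripping is per-occurrence, recorded, and replayable", {
  s <- link_fixture()
  ses <- openLinkSession(s, "aliquot_sample")
  expect_error(stripPhrase(ses, "child", ""), "non-empty")
  # phrase absent from all strings: identity
  ses_id <- stripPhrase(ses, "child", "ZZZ")
  expect_identical(ses_id@child$working, ses@child$working)
  ses <- stripPhrase(ses, "child", "HIMC-")
  ses <- stripPhrase(ses, "child", "_A")
  expect_identical(ses@child$working, c("S001", "S002", "S003"))
  expect_identical(ses@child$ext_id,
                   paste0("HIMC-S00", 1:3, "_A"))  # IDs untouched
  # per-occurrence semantics against a brute-force gsub oracle
  expect_identical(gsub("AB-", "", "AB-AB-1", fixed = TRUE), "1")
  ses3 <- ses
  ses3@child$working <- "AB-AB-1"
  ses3 <- stripPhrase(ses3, "child", "AB-")
  expect_identical(ses3@child$working[1], "1")
  # replay: transforms regenerate working strings from external IDs
  f <- tempfile(fileext = ".json")
  writeLinkSession(ses, f)
  back <- readLinkSession(f)
  expect_identical(back@child$working, ses@child$working)
  expect_identical(back@transforms, ses@transforms)
})

test_that("map-equals pairs unique matches and surfaces ambiguity", {
  s <- link_fixture()
  ses <- openLinkSession(s, "aliquot_sample")
  ses <- stripPhrase(ses, "child", "HIMC-")
  ses <- stripPhrase(ses, "child", "_A")
  ses <- mapEquals(ses)
  expect_identical(nrow(ses@pairs), 3L)
  expect_length(ses@ambiguous, 0L)
  # duplicate parent working strings leave the child unproposed
  ses2 <- openLinkSession(s, "aliquot_sample")
  ses2@parent$working <- rep("S001", nrow(ses2@parent))
  ses2@child$working <- "S001"
  ses2 <- mapEquals(ses2)
  expect_identical(nrow(ses2@pairs), 0L)
  expect_true(length(ses2@ambiguous) >= 1L)
})

test_that("manual pairs need an override to replace a proposal", {
  s <- link_fixture()
  ses <- openLinkSession(s, "aliquot_sample")
  ck <- ses@child$key[1]
  pk1 <- ses@parent$key[1]; pk2 <- ses@parent$key[2]
  ses <- mapPair(ses, ck, pk1)
  expect_identical(nrow(ses@pairs), 1L)
  expect_error(mapPair(ses, ck, pk2), "override")
  ses <- mapPair(ses, ck, pk2, override = TRUE)
  expect_identical(ses@pairs$parent_key, pk2)
  expect_error(mapPair(ses, "nope", pk1), "unknown child")
})

test_that("commits are atomic and update exactly the proposed children", {
  s <- link_fixture()
  ses <- openLinkSession(s, "aliquot_sample")
  expect_error(commitSession(ses, s), "no proposed pairs")
  ses <- stripPhrase(ses, "child", "HIMC-")
  ses <- stripPhrase(ses, "child", "_A")
  ses <- mapEquals(ses)
  summ <- commitSession(ses, s)
  expect_identical(summ$n_committed, 3L)
  expect_identical(integrityReport(s)$n_facts_unmapped, 0L)
  # committing the same session again conflicts and leaves the store as-is
  before <- DBI::dbGetQuery(s@con,
    "SELECT fact_key, sample_key FROM aliquot_fact ORDER BY fact_key")
  expect_error(commitSession(ses, s), "concurrent|abort")
  after <- DBI::dbGetQuery(s@con,
    "SELECT fact_key, sample_key FROM aliquot_fact ORDER BY fact_key")
  expect_identical(before, after)
})

test_that("a partial conflict aborts the whole commit (all or none)", {
  s <- link_fixture()
  ses <- openLinkSession(s, "aliquot_sample")
  ses <- stripPhrase(ses, "child", "HIMC-")
  ses <- stripPhrase(ses, "child", "_A")
  ses <- mapEquals(ses)
  # concurrently map one of the session's children behind its back
  DBI::dbExecute(s@con,
    "UPDATE aliquot_fact SET sample_key = 1
     WHERE aliquot_id_ext = 'HIMC-S002_A'")
  expect_error(commitSession(ses, s), "abort")
  n <- DBI::dbGetQuery(s@con,
    "SELECT COUNT(*) AS n FROM aliquot_fact
     WHERE sample_key IS NOT NULL")$n
  expect_identical(n, 1L)   # only the concurrent write, nothing from us
})

test_that("sample-to-person linkage works through the same machinery", {
  s <- local_store()
  loadMetadata(s, data.frame(pid = c("P01", "P02"), g = c("male", "female")),
               columnMapping(c(pid = "person_id", g = "gender")))
  loadMetadata(s, data.frame(sid = c("P01-D00", "P02-D07"), day = c(0, 7)),
               columnMapping(c(sid = "sample_id", day = "day")))
  ses <- openLinkSession(s, "sample_person")
  expect_identical(nrow(ses@child), 2L)
  ses <- stripPhrase(ses, "child", "-D00")
  ses <- stripPhrase(ses, "child", "-D07")
  ses <- mapEquals(ses)
  commitSession(ses, s)
  expect_identical(integrityReport(s)$n_samples_unlinked, 0L)
  expect_identical(nrow(suppressWarnings(
    openLinkSession(s, "sample_person"))@child), 0L)  # session now empty
})
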