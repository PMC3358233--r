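test_that("metadata sheets read as trimmed strings, blanks dropped", {
  f <- write_csv_lines(c("ID,Gender,Day", "p1 , M ,0", "p2,F,7",
                         "p3,M,28", ",,", "p4,F,0", "p5,M,7", ",,"))
  raw <- readMetadataSheet(f)
  expect_identical(dim(raw), c(5L, 3L))
  expect_identical(raw$ID[1], "p1")      # trimmed
  expect_identical(raw$Gender[1], "M")
  hdr_only <- readMetadataSheet(write_csv_lines("ID,Gender,Day"))
  expect_identical(nrow(hdr_only), 0L)
  expect_identical(names(hdr_only), c("ID", "Gender", "Day"))
  expect_error(readMetadataSheet(write_csv_lines(c("ID,ID", "a,b"))),
               "duplicate column")
})

test_that("column mappings enforce activation and uniqueness rules", {
  expect_s4_class(columnMapping(c(ID = "person_id", G = "gender")),
                  "ColumnMapping")
  # person attributes need person_id
  expect_error(columnMapping(c(SID = "sample_id", G = "gender")),
               "person attributes require person_id")
  expect_error(columnMapping(c(ID = "person_id", D = "day")),
               "sample attributes require sample_id")
  expect_error(columnMapping(c(G = "gender")), "at least one of")
  expect_error(columnMapping(c(A = "gender", A = "ethnicity")),
               "mapped twice")
  expect_error(columnMapping(c(ID = "person_id", X = "shoe_size")),
               "unknown attribute")
})

test_that("value-mapping proposals auto-match case-folded equals only", {
  v <- controlledVocabulary("gender", c("male", "female"))
  p <- proposeValueMapping(c("male", "Female "), v)
  expect_identical(p$mapped, c(male = "male", Female = "female"))
  expect_length(p$unresolved, 0L)
  # the classic abbreviation case stays unresolved until mapped by hand
  p2 <- proposeValueMapping(c("M", "F"), v)
  expect_setequal(p2$unresolved, c("M", "F"))
  expect_length(p2$mapped, 0L)
  vc <- controlledVocabulary("condition", c("healthy", "lupus"))
  p3 <- proposeValueMapping("SLE", vc)
  expect_identical(p3$unresolved, "SLE")   # no fuzzy matching
})

test_that("vocabulary targets must be valid values; scopes stay disjoint", {
  expect_error(controlledVocabulary("gender", c("male", "female"),
                                    value_map = c(M = "m")),
               "valid value")
  s <- local_store()
  expect_error(addVocabulary(s, controlledVocabulary("gender", "male",
    scope = "project:flu")), "globally scoped")
  expect_error(addVocabulary(s,
    controlledVocabulary("treatment", c("vaccine", "placebo"))),
    "project-scoped")
  addVocabulary(s, controlledVocabulary("treatment",
    c("vaccine", "placebo"), scope = "project:flu"))
  v <- getVocabulary(s, "treatment", project = "flu")
  expect_setequal(v@validValues, c("vaccine", "placebo"))
})

test_that("metadata loads resolve vocabularies; unresolved values reject the load", {
  s <- local_store()
  f <- write_csv_lines(c("ID,Gender", "p1,M", "p2,F", "p3,male"))
  cm <- columnMapping(c(ID = "person_id", Gender = "gender"))
  raw <- readMetadataSheet(f)
  expect_error(loadMetadata(s, raw, cm), "unresolved.*M")
  expect_identical(integrityReport(s)$n_persons, 0L)  # rejected atomically
  summ <- loadMetadata(s, raw, cm,
                       value_maps = list(gender = c(M = "male",
                                                    F = "female")))
  expect_identical(summ$n_persons_created, 3L)
  g <- DBI::dbGetQuery(s@con, "SELECT gender FROM person")$gender
  vocab <- getVocabulary(s, "gender")
  expect_true(all(g %in% vocab@validValues))   # vocabulary closure
  # the supplied mappings were persisted for later loads
  expect_identical(unname(getVocabulary(s, "gender")@valueMap["M"]), "male")
})

test_that("reloading an identical sheet creates nothing and changes nothing", {
  s <- local_store()
  f <- write_csv_lines(c("ID,Gender,Age", "p1,male,34", "p2,female,67"))
  cm <- columnMapping(c(ID = "person_id", Gender = "gender",
                        Age = "age_years"))
  loadMetadata(s, readMetadataSheet(f), cm)
  before <- DBI::dbGetQuery(s@con, "SELECT * FROM person ORDER BY person_key")
  summ <- loadMetadata(s, readMetadataSheet(f), cm)
  expect_identical(summ$n_persons_created, 0L)
  expect_identical(summ$n_persons_updated, 2L)
  after <- DBI::dbGetQuery(s@con, "SELECT * FROM person ORDER BY person_key")
  expect_identical(before, after)   # byte-identical dimension table
})

test_that("sample sheets set time-point ordinals and reject non-integers", {
  s <- local_store()
  f <- write_csv_lines(c("SID,Day", "s1,0", "s2,7", "s3,28"))
  cm <- columnMapping(c(SID = "sample_id", Day = "day"))
  loadMetadata(s, readMetadataSheet(f), cm)
  d <- DBI::dbGetQuery(s@con, "SELECT day FROM sample ORDER BY day")$day
  expect_identical(d, c(0L, 7L, 28L))
  bad <- write_csv_lines(c("SID,Day", "s4,soon"))
  expect_error(loadMetadata(s, readMetadataSheet(bad), cm),
               "non-integer.*soon")
  # a sample row with no time-point level at all is rejected
  bad2 <- write_csv_lines(c("SID,Day", "s5,"))
  expect_error(loadMetadata(s, readMetadataSheet(bad2), cm),
               "time-point")
})

test_that("blank vocabulary cells store the 'unknown' sentinel", {
  s <- local_store()
  f <- write_csv_lines(c("ID,Gender", "p1,", "p2,female"))
  loadMetadata(s, readMetadataSheet(f),
               columnMapping(c(ID = "person_id", Gender = "gender")))
  g <- DBI::dbGetQuery(s@con,
    "SELECT gender FROM person WHERE person_id_ext = 'p1'")$gender
  expect_identical(g, "unknown")
})

test_that("batch results and metadata can arrive in either order", {
  run <- function(metadata_first) {
    s <- createStore(":memory:")
    on.exit(closeStore(s))
    manifest <- generateStudy(studySpec(nPersons = 6, seed = 3,
                                        assays = "msd"))
    loadStudy(s, manifest, metadata_first = metadata_first)
    linkStudy(s, manifest)
    rep <- integrityReport(s)
    c(rep$n_facts_unmapped, rep$n_samples_unlinked, rep$n_facts)
  }
  expect_identical(run(TRUE), run(FALSE))
  expect_identical(run(TRUE)[1:2], c(0L, 0L))
})
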