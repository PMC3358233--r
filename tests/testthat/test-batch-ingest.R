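test_that("the quantification marker grammar classifies cells", {
  f <- msd_fixture_csv()
  sh <- parseBatchSheet(f, "msd")
  cells <- sh@cells
  plain <- cells[cells$aliquot_id_ext == "A1" & cells$analyte == "IL-1b", ]
  expect_equal(plain$readout, 1.5)
  expect_identical(plain$quantification, "in_range")
  below <- cells[cells$aliquot_id_ext == "A2" & cells$analyte == "IL-1b", ]
  expect_equal(below$readout, 0.4)     # numeric part retained
  expect_identical(below$quantification, "below_loq")
  above <- cells[cells$aliquot_id_ext == "A3" & cells$analyte == "IL-8", ]
  expect_equal(above$readout, 100)
  expect_identical(above$quantification, "above_loq")
})

test_that("fact count equals non-blank cells (conservation)", {
  set.seed(42)
  n_rows <- 10L; n_cols <- 51L
  analytes <- paste0("An", seq_len(n_cols))
  vals <- matrix(sprintf("%.2f", runif(n_rows * n_cols, 1, 100)),
                 n_rows, n_cols)
  blank_at <- sample(length(vals), 4L)
  vals[blank_at] <- ""
  lines <- c(paste(c("id", analytes), collapse = ","),
             paste(c("", rep("raw MFI", n_cols)), collapse = ","),
             vapply(seq_len(n_rows), function(i)
               paste(c(paste0("R", i), vals[i, ]), collapse = ","), ""))
  f <- write_csv_lines(lines)
  sh <- parseBatchSheet(f, "luminex")
  # independent brute-force cell walk
  raw <- utils::read.csv(f, header = FALSE, colClasses = "character")
  walked <- sum(nzchar(trimws(as.matrix(raw[-(1:2), -1]))))
  expect_identical(nrow(sh@cells), walked)
  expect_identical(nrow(sh@cells), n_rows * n_cols - 4L)
  expect_identical(sh@nBlank, 4L)
  s <- local_store()
  summ <- loadBatch(s, sh, sourceAttributes(assay = "Human Luminex 51plex"))
  expect_identical(summ$n_facts, walked)
  expect_identical(integrityReport(s)$n_facts, walked)
})

test_that("format errors carry row/column coordinates", {
  ragged <- write_csv_lines(c("id,A,B", ",u,u", "r1,1,2,3"))
  expect_error(parseBatchSheet(ragged, "msd"), "row 3 has 4 field")
  nonnum <- write_csv_lines(c("id,A,B", ",u,u", "r1,1,2", "r2,oops,4"))
  expect_error(parseBatchSheet(nonnum, "msd"), "'oops'.*row 4.*'A'")
  nounits <- write_csv_lines(c("id,A,B", ",u,", "r1,1,2"))
  expect_error(parseBatchSheet(nounits, "msd"), "units.*column 3")
  dupids <- write_csv_lines(c("id,A", ",u", "r1,1", "r1,2"))
  expect_error(parseBatchSheet(dupids, "msd"), "duplicate")
})

test_that("an MSD 4-plex sheet with 3 rows yields 12 facts, 4 analytes", {
  s <- local_store()
  sh <- parseBatchSheet(msd_fixture_csv(), "msd")
  summ <- loadBatch(s, sh, sourceAttributes(assay = "MSD 4plex",
                                            tissue = "serum"))
  expect_identical(summ$n_facts, 12L)
  expect_identical(summ$n_analytes_new, 4L)
  an <- DBI::dbGetQuery(s@con, "SELECT analyte_name FROM analyte")
  expect_setequal(an$analyte_name, c("IL-1b", "IL-6", "IL-8", "TNF"))
})

test_that("a phospho-flow sheet yields 8 stims x 3 readouts = 24 facts per aliquot", {
  s <- local_store()
  sh <- parseBatchSheet(phospho_fixture_csv(), "phospho_flow")
  expect_true(sh@hasStim)
  summ <- loadBatch(s, sh, sourceAttributes(
    assay = "Cytokine-stimulated phospho-flow", tissue = "PBMC"))
  expect_identical(summ$n_facts, 48L)   # 2 aliquots x 24
  per <- DBI::dbGetQuery(s@con,
    "SELECT aliquot_id_ext, COUNT(*) AS n FROM aliquot_fact
     GROUP BY aliquot_id_ext")
  expect_true(all(per$n == 24L))
  stims <- DBI::dbGetQuery(s@con,
    "SELECT DISTINCT stim FROM aliquot_fact")$stim
  expect_length(stims, 8L)
  expect_true("none" %in% stims)
})

test_that("an empty sheet registers its source but loads no facts", {
  f <- write_csv_lines(c("id,IL-6", ",pg/ml"))
  s <- local_store()
  summ <- loadBatch(s, parseBatchSheet(f, "msd"),
                    sourceAttributes(assay = "MSD 4plex"))
  expect_identical(summ$n_facts, 0L)
  expect_identical(integrityReport(s)$n_sources, 1L)
})

test_that("re-loading the same file is rejected and changes nothing", {
  s <- local_store()
  f <- msd_fixture_csv()
  loadBatch(s, parseBatchSheet(f, "msd"),
            sourceAttributes(assay = "MSD 4plex"))
  before <- integrityReport(s)
  expect_error(
    loadBatch(s, parseBatchSheet(f, "msd"),
              sourceAttributes(assay = "MSD 4plex")),
    "duplicate upload")
  expect_identical(integrityReport(s), before)
})

test_that("units are stored verbatim from the column header", {
  f <- write_csv_lines(c("id,A,B,C", ",raw MFI,average MFI,pg/ml",
                         "r1,1,2,3"))
  s <- local_store()
  loadBatch(s, parseBatchSheet(f, "luminex"),
            sourceAttributes(assay = "lmx"))
  u <- DBI::dbGetQuery(s@con,
    "SELECT a.analyte_name, f.units FROM aliquot_fact f
     JOIN analyte a ON f.analyte_key = a.analyte_key ORDER BY analyte_name")
  expect_identical(u$units, c("raw MFI", "average MFI", "pg/ml"))
})

test_that("export of one source re-pivots to the original cells bit-exact", {
  set.seed(11)
  analytes <- c("IL-6", "TNF", "VEGF")
  vals <- matrix(rlnorm(15, 5, 1), 5, 3)
  lines <- c("id,IL-6,TNF,VEGF", ",pg/ml,pg/ml,pg/ml",
             vapply(1:5, function(i) paste(c(paste0("A", i),
               sprintf("%.17g", vals[i, ])), collapse = ","), ""))
  f <- write_csv_lines(lines)
  s <- local_store()
  sh <- parseBatchSheet(f, "msd")
  summ <- loadBatch(s, sh, sourceAttributes(assay = "MSD"))
  wide <- exportSourceSheet(s, summ$source_key)
  wide <- wide[order(wide$aliquot_id_ext), ]
  expect_identical(wide$aliquot_id_ext, paste0("A", 1:5))
  for (j in seq_along(analytes))
    expect_identical(wide[[analytes[j]]], vals[, j])  # bit-exact
})
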