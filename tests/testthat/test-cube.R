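test_that("a single fact aggregates to one cell with N = 1", {
  s <- local_store()
  cells <- data.frame(aliquot_id_ext = "A1", stim = "none",
    analyte = "IL-6", units = "pg/ml", readout = 42.5,
    quantification = "in_range", stringsAsFactors = FALSE)
  loadBatch(s, batchSheet("one.csv", "msd", "IL-6", "pg/ml", cells, 1L),
            sourceAttributes(assay = "MSD"))
  res <- aggregateCube(s, cubeQuery(rows = "Gender",
                                    measures = c("N", "mean")))
  cl <- pivotCells(res)
  detail <- cl[cl$Gender == "(unmapped)", ]   # unlinked fact is visible
  expect_identical(nrow(detail), 1L)
  expect_identical(as.integer(detail$N), 1L)
  expect_equal(detail$mean, 42.5)
})

test_that("cube cells equal the flat filter-group oracle on a fixed fixture", {
  s <- tiny_linked_store()
  q <- cubeQuery(rows = "Analyte", cols = "Gender",
                 measures = c("N", "mean", "median", "min", "max"))
  res <- expect_matches_oracle(s, q)
  cl <- pivotCells(res)
  hit <- cl$Analyte == "IL-6" & cl$Gender == "male"
  expect_equal(cl$mean[hit], mean(c(10, 20)))
  # filter/axis commutation: filtering to a member equals reading its slice
  qf <- cubeQuery(rows = "Analyte", filters = list(Gender = "male"),
                  measures = c("N", "mean", "median", "min", "max"))
  slice <- pivotCells(aggregateCube(s, qf))
  slice <- slice[slice$Analyte != "(all)", ]
  axis <- cl[cl$Gender == "male" & cl$Analyte != "(all)", ]
  expect_equal(slice$mean[order(slice$Analyte)],
               axis$mean[order(axis$Analyte)])
  expect_identical(as.integer(slice$N[order(slice$Analyte)]),
                   as.integer(axis$N[order(axis$Analyte)]))
})

test_that("random stores and queries match the oracle cell-for-cell", {
  for (seed in 1:6) {
    s <- random_store(seed)
    for (qseed in 1:3)
      expect_matches_oracle(s, random_query(seed * 100 + qseed))
  }
})

test_that("invalid queries are rejected", {
  expect_error(cubeQuery(rows = "Shoe"), "unknown dimension")
  expect_error(cubeQuery(rows = "Gender", cols = "Gender"), "both axes")
  expect_error(cubeQuery(rows = "Gender", measures = "mode"),
               "unknown measure")
  expect_error(cubeQuery(filters = list(Color = "red")),
               "unknown dimension")
})

test_that("roll-up subtotals obey count additivity and the weighted-mean identity", {
  s <- random_store(99)
  q <- cubeQuery(rows = c("Assay", "Analyte"), cols = "Gender",
                 measures = c("N", "mean", "min", "max"))
  cl <- pivotCells(aggregateCube(s, q))
  parents <- cl[cl$Assay != "(all)" & cl$Analyte == "(all)", ]
  for (i in seq_len(nrow(parents))) {
    p <- parents[i, ]
    ch <- cl[cl$Assay == p$Assay & cl$Analyte != "(all)" &
             cl$Gender == p$Gender & cl$Units == p$Units, ]
    expect_identical(sum(ch$N), as.integer(p$N))
    expect_equal(sum(ch$N * ch$mean) / sum(ch$N), p$mean,
                 tolerance = 1e-12)
    expect_equal(min(ch$min), p$min)
    expect_equal(max(ch$max), p$max)
  }
})

test_that("drill-down expands one member and keeps subtotals", {
  s <- tiny_linked_store()
  res <- aggregateCube(s, cubeQuery(rows = "Assay",
                                    measures = c("N", "mean")))
  res2 <- drillDown(s, res, "rows", "MSD 4plex")
  cl <- pivotCells(res2)
  kids <- cl[cl$Assay == "MSD 4plex" & cl$Analyte != "(all)", ]
  expect_setequal(kids$Analyte, c("IL-6", "TNF"))
  # parent subtotal retained, additive over children
  par <- cl[cl$Assay == "MSD 4plex" & cl$Analyte == "(all)", ]
  expect_identical(as.integer(sum(kids$N)), as.integer(par$N))
  # expanding past the bottom of the hierarchy is a no-op with a message
  res3 <- drillDown(s, res2, "rows", "IL-6")      # -> Units level
  expect_message(drillDown(s, res3, "rows", "pg/ml"), "leaf")
})

test_that("drill-through returns exactly the contributing facts", {
  s <- random_store(7)
  q <- cubeQuery(rows = c("Analyte"), cols = c("Gender"),
                 filters = list(Tissue = "serum"),
                 measures = c("N", "mean"))
  res <- aggregateCube(s, q)
  cl <- pivotCells(res)
  for (i in seq_len(nrow(cl))) {
    det <- drillThrough(s, res, i)
    expect_identical(nrow(det), as.integer(cl$N[i]))
    expect_equal(mean(det$readout), cl$mean[i])   # re-aggregation, exact
    expect_true(all(det$units == det$units[1]))   # units never pooled
  }
})

test_that("measure vectors match a naive reference on random multisets", {
  naive <- function(v) {
    n <- length(v)
    srt <- sort(v)
    med <- if (n == 0) NA_real_
      else if (n %% 2 == 1) srt[(n + 1) / 2]
      else (srt[n / 2] + srt[n / 2 + 1]) / 2
    m <- if (n) sum(v) / n else NA_real_
    s2 <- if (n >= 2) sum((v - m)^2) / (n - 1) else NA_real_
    list(N = n, mean = m, median = med,
         min = if (n) min(v) else NA_real_,
         max = if (n) max(v) else NA_real_,
         sd = sqrt(s2),
         cv = if (!is.na(s2) && m != 0) sqrt(s2) / m else NA_real_)
  }
  expect_identical(computeMeasures(numeric(0))$N, 0L)
  expect_true(is.na(computeMeasures(numeric(0))$mean))
  expect_equal(computeMeasures(c(2, 4))[c("mean", "median", "min", "max")],
               list(mean = 3, median = 3, min = 2, max = 4))
  set.seed(20)
  for (rep in 1:8) {
    v <- rlnorm(sample(c(1, 2, 5, 1000), 1), 2, 1.5)
    got <- computeMeasures(v)
    ref <- naive(v)
    for (msr in names(ref))
      if (is.na(ref[[msr]])) expect_true(is.na(got[[msr]]))
      else expect_equal(got[[msr]], ref[[msr]], tolerance = 1e-9)
  }
  # sd undefined below 2 values; cv undefined at mean 0
  expect_true(is.na(computeMeasures(5)$sd))
  expect_true(is.na(computeMeasures(c(-1, 1))$cv))
})

test_that("pivot exports round-trip through CSV and JSON", {
  s <- tiny_linked_store()
  res <- aggregateCube(s, cubeQuery(rows = "Analyte", cols = "Gender",
                                    measures = c("N", "mean")))
  cl <- pivotCells(res)
  fj <- tempfile(fileext = ".json")
  exportPivot(res, fj, "json")
  expect_true(validatePivotJSON(fj))
  back <- importPivot(fj, "json")
  expect_equal(pivotCells(back), cl)
  expect_identical(back@rowLevels, res@rowLevels)
  fc <- tempfile(fileext = ".csv")
  exportPivot(res, fc, "csv")
  long <- importPivot(fc, "csv")
  # every original cell value is reproduced in the flat import
  for (i in seq_len(nrow(cl))) {
    hit <- long$Analyte == cl$Analyte[i] & long$col_1 == cl$Gender[i] &
      long$measure == "mean"
    expect_equal(long$value[hit], cl$mean[i])
  }
  expect_error(exportPivot(methods::new("PivotResult",
    query = cubeQuery(), rowLevels = character(0),
    colLevels = character(0), unitsHidden = TRUE,
    cells = data.frame()), tempfile(), "csv"), "empty")
})

test_that("identical stores and queries export byte-identical files", {
  make_export <- function() {
    s <- createStore(":memory:")
    on.exit(closeStore(s))
    manifest <- generateStudy(studySpec(nPersons = 8, seed = 5,
                                        assays = "msd"))
    loadStudy(s, manifest); linkStudy(s, manifest)
    res <- aggregateCube(s, cubeQuery(rows = "Analyte", cols = "Gender",
                                      measures = c("N", "mean", "median")))
    f <- tempfile(fileext = ".csv")
    exportPivot(res, f, "csv")
    tools::md5sum(f)[[1]]
  }
  expect_identical(make_export(), make_export())
})
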