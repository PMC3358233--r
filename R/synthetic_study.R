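#' @include cube.R
NULL

#' The default 51-plex bead panel
#'
#' Analyte names for the synthetic serum cytokine panel, including the
#' four analytes carrying the default planted gender effect (ENA-78,
#' GM-CSF, leptin, PDGFBB).
#' @return character vector of 51 analyte names
#' @export
luminexPanel <- function() {
  c("ENA-78", "GM-CSF", "leptin", "PDGFBB", "IL-6", "CD40Ligand", "VEGF",
    "IL-1a", "IL-1b", "IL-1RA", "IL-2", "IL-4", "IL-5", "IL-7", "IL-8",
    "IL-10", "IL-12p40", "IL-12p70", "IL-13", "IL-15", "IL-17", "IL-23",
    "TNFa", "TNFb", "IFNa", "IFNb", "IFNg", "MCP-1", "MCP-3", "MIP-1a",
    "MIP-1b", "RANTES", "Eotaxin", "GROa", "IP-10", "MIG", "TGFa",
    "TGFb", "G-CSF", "M-CSF", "FGF-basic", "HGF", "NGF", "EGF", "SCF",
    "TRAIL", "FasL", "ICAM-1", "VCAM-1", "PAI-1", "Resistin")
}

#' Construct a synthetic study specification
#'
#' Defaults describe the emulated design: 434 healthy participants each
#' sampled at days 0, 7 and 28 around an influenza vaccination; serum on
#' a 51-plex bead panel run in two kit lots (H51-1, H51-2) whose absolute
#' values differ by a multiplicative lot factor; a 4-plex
#' electrochemiluminescence panel (IL-1b, IL-6, IL-8, TNF); and PBMC
#' phospho-flow (pSTAT1/3/5) under seven cytokine stimulations plus an
#' unstimulated baseline. Readouts are log-normal; planted effects are
#' multiplicative fold-ratios. The default gender effect puts a 1.4-fold
#' female/male ratio on the four biased analytes — comfortably above the
#' 20% screening threshold given the cohort size and a log-scale noise
#' sigma of 0.3 — and 1.0 everywhere else. The seed fully determines all
#' output.
#'
#' @param nPersons number of participants
#' @param visitDays visit-day ordinals
#' @param luminexAnalytes bead panel (51 names by default)
#' @param msdAnalytes 4-plex panel
#' @param stims stimulation conditions (excluding unstimulated)
#' @param phosphoReadouts phospho readout columns
#' @param lots,lotFactors bead kit lots and their multiplicative factors
#' @param genderEffect named female/male fold-ratios for bead analytes
#' @param msdGenderEffect named fold-ratios for the 4-plex panel
#' @param noiseSigma log-scale noise standard deviation
#' @param baselineRange range baseline medians are drawn from (raw MFI)
#' @param belowLoqQuantile fraction of bead readouts flagged below LOQ
#' @param idPrefix,idSuffix aliquot identifier decoration
#' @param il6Pstat1Coupling if > 0, persons with higher serum IL-6 get
#'   proportionally lower IL-6-stimulated pSTAT1 induction
#' @param assays assay families to generate
#' @param seed integer seed
#' @return a [StudySpec-class]
#' @export
studySpec <- function(nPersons = 434, visitDays = c(0, 7, 28),
    luminexAnalytes = luminexPanel(),
    msdAnalytes = c("IL-1b", "IL-6", "IL-8", "TNF"),
    stims = c("IFNa", "IFNg", "IL-2", "IL-6", "IL-7", "IL-10", "IL-21"),
    phosphoReadouts = c("pSTAT1", "pSTAT3", "pSTAT5"),
    lots = c("H51-1", "H51-2"), lotFactors = c(1, 1.3),
    genderEffect = c("ENA-78" = 1.4, "GM-CSF" = 1.4, "leptin" = 1.4,
                     "PDGFBB" = 1.4),
    msdGenderEffect = c("IL-6" = 1.3),
    noiseSigma = 0.3, baselineRange = c(500, 20000),
    belowLoqQuantile = 0.01, idPrefix = "HIMC-", idSuffix = "_A",
    il6Pstat1Coupling = 0,
    assays = c("luminex", "msd", "phospho_flow"), seed = 1) {
  methods::new("StudySpec", nPersons = as.integer(nPersons),
    visitDays = as.integer(visitDays),
    luminexAnalytes = luminexAnalytes, msdAnalytes = msdAnalytes,
    stims = stims, phosphoReadouts = phosphoReadouts, lots = lots,
    lotFactors = stats::setNames(as.numeric(lotFactors), lots),
    genderEffect = genderEffect, msdGenderEffect = msdGenderEffect,
    noiseSigma = noiseSigma, baselineRange = as.numeric(baselineRange),
    belowLoqQuantile = belowLoqQuantile, idPrefix = idPrefix,
    idSuffix = idSuffix, il6Pstat1Coupling = il6Pstat1Coupling,
    assays = assays, seed = as.integer(seed))
}

# deterministic stim x readout induction factors for phospho-flow
phospho_induction <- function(stims, readouts) {
  ind <- matrix(1, nrow = length(stims) + 1L, ncol = length(readouts),
                dimnames = list(c("none", stims), readouts))
  set_if <- function(stim, readout, f)
    if (stim %in% rownames(ind) && readout %in% colnames(ind))
      ind[stim, readout] <<- f
  set_if("IFNa", "pSTAT1", 5); set_if("IFNa", "pSTAT3", 2)
  set_if("IFNa", "pSTAT5", 1.5)
  set_if("IFNg", "pSTAT1", 6)
  set_if("IL-2", "pSTAT5", 8)
  set_if("IL-6", "pSTAT1", 3); set_if("IL-6", "pSTAT3", 6)
  set_if("IL-7", "pSTAT5", 7)
  set_if("IL-10", "pSTAT3", 4)
  set_if("IL-21", "pSTAT3", 3); set_if("IL-21", "pSTAT5", 2)
  ind
}

fmt_num <- function(x) sprintf("%.17g", x)

write_batch_csv <- function(path, ids, stim, analytes, units, values,
                            quant) {
  # values/quant: matrices [aliquot-row x analyte]
  cellmat <- matrix(fmt_num(values), nrow = nrow(values))
  cellmat[quant == "below_loq"] <- paste0("<",
    cellmat[quant == "below_loq"])
  cellmat[quant == "above_loq"] <- paste0(">",
    cellmat[quant == "above_loq"])
  has_stim <- !is.null(stim)
  h1 <- paste(c("aliquot_id", if (has_stim) "stim", analytes),
              collapse = ",")
  h2 <- paste(c("", if (has_stim) "", units), collapse = ",")
  body <- apply(cbind(ids, if (has_stim) stim, cellmat), 1L, paste,
                collapse = ",")
  writeLines(c(h1, h2, body), path)
  path
}

#' Generate a complete synthetic study
#'
#' Emits the person and sample metadata sheets and the batch-results
#' sheets of all requested assay families, with decorated aliquot IDs
#' that are recoverable by stripping the declared phrases. The returned
#' manifest carries the written file paths, the in-memory parsed sheets
#' (so simulations can skip file round-trips), the declared ID-stripping
#' phrases, per-sheet source attributes, and the ground-truth parameters
#' including true per-analyte per-gender means.
#'
#' Person genders are Bernoulli(0.5) (written as "M"/"F", which must be
#' vocabulary-mapped on load), ages uniform on 20-89 (banded by decade),
#' ethnicities drawn from a small capitalized set. Readouts are
#' log-normal around per-analyte baselines times the gender fold and the
#' lot factor; about `belowLoqQuantile` of bead readouts fall below the
#' per-analyte LOQ and are written with the `"<"` marker.
#'
#' @param spec a [StudySpec-class]
#' @param outdir directory for the generated files, or `NULL` to generate
#'   in memory only
#' @return a manifest (class `"studyManifest"`)
#' @export
generateStudy <- function(spec, outdir = NULL) {
  stopifnot(methods::is(spec, "StudySpec"))
  methods::validObject(spec)
  set.seed(spec@seed)
  np <- spec@nPersons
  days <- spec@visitDays
  sigma <- spec@noiseSigma

  pid <- sprintf("P%04d", seq_len(np))
  gender <- ifelse(stats::rbinom(np, 1L, 0.5) == 1L, "female", "male")
  age <- as.integer(floor(stats::runif(np, 20, 90)))
  ethnicity <- sample(c("White", "Black", "Asian", "Hispanic"), np,
                      replace = TRUE)
  person_sheet <- data.frame(person_id = pid,
    gender = ifelse(gender == "female", "F", "M"),
    ethnicity = ethnicity, age = age, stringsAsFactors = FALSE)

  sidx <- rep(seq_len(np), each = length(days))
  sday <- rep(days, np)
  sample_id <- sprintf("%s-D%02d", pid[sidx], sday)
  sample_sheet <- data.frame(sample_id = sample_id, day = sday,
                             stringsAsFactors = FALSE)
  aliquot_id <- paste0(spec@idPrefix, sample_id, spec@idSuffix)
  lot_of_person <- spec@lots[((seq_len(np) - 1L) %% length(spec@lots)) + 1L]
  lot_of_sample <- lot_of_person[sidx]
  gender_of_sample <- gender[sidx]
  ns <- length(sample_id)

  # optional person-level serum IL-6 latent effect (couples to pSTAT1)
  u_il6 <- if (spec@il6Pstat1Coupling > 0)
    stats::rnorm(np, 0, 0.2) else rep(0, np)

  sheets <- list()
  attrs <- list()
  files <- list()
  truth <- list()

  gf <- function(analyte, effect)
    unname(ifelse(is.na(effect[analyte]), 1, effect[analyte]))

  if ("luminex" %in% spec@assays) {
    na <- length(spec@luminexAnalytes)
    base <- stats::runif(na, log(spec@baselineRange[1L]),
                         log(spec@baselineRange[2L]))
    names(base) <- spec@luminexAnalytes
    fold <- vapply(spec@luminexAnalytes, gf, 1,
                   effect = spec@genderEffect)
    lot_mix <- mean(spec@lotFactors)   # persons split evenly across lots
    truth$luminex <- data.frame(
      analyte = spec@luminexAnalytes, assay_family = "luminex",
      gender_fold = fold,
      male_mean_true = exp(base + sigma^2 / 2) * lot_mix,
      female_mean_true = exp(base + sigma^2 / 2) * lot_mix * fold,
      row.names = NULL, stringsAsFactors = FALSE)
    for (lot in spec@lots) {
      in_lot <- lot_of_sample == lot
      idsl <- aliquot_id[in_lot]
      mu <- outer(rep(0, sum(in_lot)), base, "+") +
        log(spec@lotFactors[[lot]]) +
        (gender_of_sample[in_lot] == "female") %o% log(fold)
      vals <- matrix(stats::rlnorm(length(mu), as.vector(mu), sigma),
                     nrow = nrow(mu))
      loq <- exp(base + stats::qnorm(spec@belowLoqQuantile) * sigma)
      quant <- matrix("in_range", nrow(vals), ncol(vals))
      quant[vals < rep(loq, each = nrow(vals))] <- "below_loq"
      units <- rep("raw MFI", na)
      fname <- sprintf("luminex_%s.csv", lot)
      cells <- data.frame(
        aliquot_id_ext = rep(idsl, times = na),
        stim = "none",
        analyte = rep(spec@luminexAnalytes, each = length(idsl)),
        units = rep(units, each = length(idsl)),
        readout = as.vector(vals),
        quantification = as.vector(quant), stringsAsFactors = FALSE)
      sh <- batchSheet(fname, "luminex", spec@luminexAnalytes, units,
                       cells, nDataRows = length(idsl))
      at <- sourceAttributes(assay = "Human Luminex 51plex",
        tissue = "cryopreserved serum", lot = lot, pi = "PI-01",
        project = "flu-cohort", operator = "op-01",
        run_date = "2011-02-01", instrument = "LX200")
      if (!is.null(outdir)) {
        p <- file.path(outdir, fname)
        write_batch_csv(p, idsl, NULL, spec@luminexAnalytes, units,
                        vals, quant)
        files[[fname]] <- p
      }
      sheets[[fname]] <- sh
      attrs[[fname]] <- at
    }
  }

  if ("msd" %in% spec@assays) {
    na <- length(spec@msdAnalytes)
    base <- stats::runif(na, log(1), log(50))
    names(base) <- spec@msdAnalytes
    fold <- vapply(spec@msdAnalytes, gf, 1, effect = spec@msdGenderEffect)
    truth$msd <- data.frame(
      analyte = spec@msdAnalytes, assay_family = "msd",
      gender_fold = fold,
      male_mean_true = exp(base + sigma^2 / 2),
      female_mean_true = exp(base + sigma^2 / 2) * fold,
      row.names = NULL, stringsAsFactors = FALSE)
    mu <- outer(rep(0, ns), base, "+") +
      (gender_of_sample == "female") %o% log(fold)
    if ("IL-6" %in% spec@msdAnalytes)
      mu[, match("IL-6", spec@msdAnalytes)] <-
        mu[, match("IL-6", spec@msdAnalytes)] + u_il6[sidx]
    vals <- matrix(stats::rlnorm(length(mu), as.vector(mu), sigma),
                   nrow = ns)
    quant <- matrix("in_range", nrow(vals), ncol(vals))
    units <- rep("pg/ml", na)
    fname <- "msd.csv"
    cells <- data.frame(
      aliquot_id_ext = rep(aliquot_id, times = na), stim = "none",
      analyte = rep(spec@msdAnalytes, each = ns),
      units = rep(units, each = ns),
      readout = as.vector(vals), quantification = as.vector(quant),
      stringsAsFactors = FALSE)
    sheets[[fname]] <- batchSheet(fname, "msd", spec@msdAnalytes, units,
                                  cells, nDataRows = ns)
    attrs[[fname]] <- sourceAttributes(assay = "MSD 4plex",
      tissue = "cryopreserved serum", pi = "PI-01",
      project = "flu-cohort", operator = "op-02",
      run_date = "2011-03-01", instrument = "SECTOR6000")
    if (!is.null(outdir)) {
      p <- file.path(outdir, fname)
      write_batch_csv(p, aliquot_id, NULL, spec@msdAnalytes, units,
                      vals, quant)
      files[[fname]] <- p
    }
  }

  if ("phospho_flow" %in% spec@assays) {
    stims_all <- c("none", spec@stims)
    nr <- length(spec@phosphoReadouts)
    base <- stats::runif(nr, log(50), log(500))
    names(base) <- spec@phosphoReadouts
    ind <- phospho_induction(spec@stims, spec@phosphoReadouts)
    rows_id <- rep(aliquot_id, each = length(stims_all))
    rows_stim <- rep(stims_all, times = ns)
    mu <- log(ind[rows_stim, , drop = FALSE]) +
      outer(rep(0, length(rows_id)), base, "+")
    if (spec@il6Pstat1Coupling > 0 && "pSTAT1" %in% spec@phosphoReadouts) {
      j <- match("pSTAT1", spec@phosphoReadouts)
      hit <- rows_stim == "IL-6"
      mu[hit, j] <- mu[hit, j] -
        spec@il6Pstat1Coupling * u_il6[sidx][match(rows_id[hit],
                                                   aliquot_id)]
    }
    vals <- matrix(stats::rlnorm(length(mu), as.vector(mu), sigma),
                   nrow = length(rows_id))
    quant <- matrix("in_range", nrow(vals), ncol(vals))
    units <- rep("MFI", nr)
    fname <- "phospho.csv"
    cells <- data.frame(
      aliquot_id_ext = rep(rows_id, times = nr),
      stim = rep(rows_stim, times = nr),
      analyte = rep(spec@phosphoReadouts, each = length(rows_id)),
      units = rep(units, each = length(rows_id)),
      readout = as.vector(vals), quantification = as.vector(quant),
      stringsAsFactors = FALSE)
    sheets[[fname]] <- batchSheet(fname, "phospho_flow",
      spec@phosphoReadouts, units, cells, nDataRows = length(rows_id))
    attrs[[fname]] <- sourceAttributes(
      assay = "Cytokine-stimulated phospho-flow",
      tissue = "cryopreserved PBMC", pi = "PI-01",
      project = "flu-cohort", operator = "op-03",
      run_date = "2011-04-01", instrument = "LSRII")
    if (!is.null(outdir)) {
      p <- file.path(outdir, fname)
      write_batch_csv(p, rows_id, rows_stim, spec@phosphoReadouts,
                      units, vals, quant)
      files[[fname]] <- p
    }
  }

  if (!is.null(outdir)) {
    pp <- file.path(outdir, "persons.csv")
    utils::write.csv(person_sheet, pp, row.names = FALSE)
    files[["persons.csv"]] <- pp
    sp <- file.path(outdir, "samples.csv")
    utils::write.csv(sample_sheet, sp, row.names = FALSE)
    files[["samples.csv"]] <- sp
  }

  truth_df <- do.call(rbind, truth)
  rownames(truth_df) <- NULL
  manifest <- structure(list(
    spec = spec,
    files = files,
    sheets = sheets,
    sheet_attrs = attrs,
    person_sheet = person_sheet,
    sample_sheet = sample_sheet,
    strip_phrases = list(
      aliquot = c(spec@idPrefix, spec@idSuffix),
      sample = sprintf("-D%02d", days)),
    value_maps = list(gender = c(M = "male", F = "female")),
    truth = truth_df,
    n_persons = np, n_samples = ns,
    seed = spec@seed), class = "studyManifest")
  if (!is.null(outdir)) {
    mf <- file.path(outdir, "manifest.json")
    # relative names keep the manifest byte-identical across directories
    jsonlite::write_json(list(
      files = lapply(files, basename),
      strip_phrases = manifest$strip_phrases,
      value_maps = lapply(manifest$value_maps, as.list),
      truth = truth_df, n_persons = np, n_samples = ns,
      seed = spec@seed), mf, auto_unbox = TRUE, digits = NA)
    manifest$files[["manifest.json"]] <- mf
  }
  manifest
}

#' @export
print.studyManifest <- function(x, ...) {
  cat(sprintf(
    "Synthetic study: %d persons, %d samples, %d sheet(s)%s (seed %d)\n",
    x$n_persons, x$n_samples, length(x$sheets),
    if (length(x$files)) sprintf(", %d file(s) written", length(x$files))
    else "", x$seed))
  invisible(x)
}

#' Ground-truth answer key for the gender screen
#'
#' Returns the bead-panel analytes whose TRUE (noise-free) female/male
#' fold differs from 1 by more than the threshold — the expected result
#' of screening cube means by gender at that threshold.
#'
#' @param manifest a manifest from [generateStudy()]
#' @param threshold percent difference (20 means "> 20%")
#' @return character vector of analyte names
#' @export
groundTruthScreen <- function(manifest, threshold = 20) {
  stopifnot(inherits(manifest, "studyManifest"))
  tr <- manifest$truth[manifest$truth$assay_family == "luminex", ]
  f <- tr$gender_fold
  hit <- pmax(f, 1 / f) - 1 > threshold / 100
  tr$analyte[hit]
}
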