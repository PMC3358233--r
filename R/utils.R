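#' @import methods
#' @importFrom stats median sd rbinom rlnorm runif qlnorm setNames
#' @importFrom utils read.csv write.csv head
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Quantification flags for aliquot-level readouts
#'
#' The three-state classification of a readout relative to the calibrated
#' range of the assay: within range, below the limit of quantification
#' (LOQ), or above it.
#' @export
QUANTIFICATION_LEVELS <- c("in_range", "below_loq", "above_loq")

#' Age bands derived from age at enrollment
#'
#' Persons are banded in decades for cube segregation: `<20`, `20-29`,
#' ..., `70-79`, `80+`.
#'
#' @param age_years integer vector of ages (NA allowed)
#' @return character vector of band labels, NA where age is NA
#' @export
#' @examples
#' ageBand(c(19, 20, 34, 85, NA))
ageBand <- function(age_years) {
  age_years <- as.integer(age_years)
  band <- rep(NA_character_, length(age_years))
  ok <- !is.na(age_years)
  a <- age_years[ok]
  b <- ifelse(a < 20, "<20",
       ifelse(a >= 80, "80+",
              paste0((a %/% 10) * 10, "-", (a %/% 10) * 10 + 9)))
  band[ok] <- b
  band
}

# strict scalar coercions used by record validation ------------------------

assert_scalar_string <- function(x, field, allow_empty = FALSE) {
  if (is.null(x) || length(x) != 1L || is.na(x) || !is.character(x))
    stop(sprintf("field '%s' must be a single string", field), call. = FALSE)
  if (!allow_empty && !nzchar(x))
    stop(sprintf("field '%s' must be non-empty", field), call. = FALSE)
  x
}

trim <- function(x) gsub("^\\s+|\\s+$", "", x)

# md5 digest of an on-disk file (base R)
fileHash <- function(path) {
  unname(tools::md5sum(path.expand(path)))
}

# md5 digest of an arbitrary R object, via canonical serialization
objectHash <- function(x) {
  tf <- tempfile(fileext = ".bin")
  on.exit(unlink(tf), add = TRUE)
  con <- file(tf, "wb")
  serialize(x, con, version = 2L)
  close(con)
  fileHash(tf)
}

# parse a readout cell under the quantification-marker grammar:
#   "123.4" -> in_range, "<3.2" -> below_loq, ">9000" -> above_loq,
#   "" -> blank (no fact).  Anything else is a format error.
parse_readout_cell <- function(cell) {
  cell <- trim(cell)
  if (!nzchar(cell) || is.na(cell)) return(NULL)
  quant <- "in_range"
  num <- cell
  first <- substr(cell, 1L, 1L)
  if (first == "<") { quant <- "below_loq"; num <- substring(cell, 2L) }
  else if (first == ">") { quant <- "above_loq"; num <- substring(cell, 2L) }
  val <- suppressWarnings(as.numeric(trim(num)))
  if (is.na(val) || !is.finite(val)) return(NA)   # signals format error
  list(readout = val, quantification = quant)
}

# data.table NSE columns
.datatable.aware <- TRUE
utils::globalVariables(c("readout", "..row", "..colid", "..measure",
                         "..value", "..head", ".SD", ".N"))
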