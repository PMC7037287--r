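# Element symbols measured throughout the soil-grapevine-wine system.
GT_ELEMENTS <- c("Cu", "Zn", "Pb", "Cd", "Ni", "Co", "As", "Cr", "Hg")

# Compartments ordered along the transfer chain.
GT_COMPARTMENTS <- c("soil", "root", "cane", "leaf", "grape", "must", "wine")

# Canonical unit per compartment: dry-weight mass fractions for soil and
# plant tissue, volume concentrations for the beverages.
GT_CANONICAL_UNIT <- c(
  soil = "mg/kg DW", root = "mg/kg DW", cane = "mg/kg DW",
  leaf = "mg/kg DW", grape = "mg/kg DW", must = "mg/L", wine = "mg/L"
)

#' Element symbols recognised by the pipeline
#'
#' @return Character vector of the nine element symbols (Cu, Zn, Pb, Cd, Ni,
#'   Co, As, Cr, Hg) in the canonical reporting order.
#' @export
gt_elements <- function() GT_ELEMENTS

#' Compartments of the soil-grapevine-wine system
#'
#' @return Character vector of compartment names ordered along the transfer
#'   chain: soil, root, cane, leaf, grape, must, wine.
#' @export
gt_compartments <- function() GT_COMPARTMENTS

#' Path to a bundled example data file
#'
#' Fixture tables transcribing the published study data (soil at four depths,
#' plant organs, must and wine), the regulatory threshold tables and the
#' default synthetic-gradient configuration ship under \code{extdata}.
#'
#' @param file File name, e.g. \code{"table1_soil.csv"}. With no argument,
#'   lists the available files.
#' @return Full path to the file, or a character vector of file names.
#' @export
gt_example <- function(file = NULL) {
  dir <- system.file("extdata", package = "grapetrace", mustWork = TRUE)
  if (is.null(file)) return(list.files(dir))
  path <- file.path(dir, file)
  if (!file.exists(path)) stop("no bundled file called '", file, "'")
  path
}

#' Round half away from zero
#'
#' Reporting helper matching the table convention that .005 rounds up, unlike
#' the IEEE round-half-even used by \code{round()}.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Build validated concentration records
#'
#' Constructs the tidy record table used by every pipeline stage: one row per
#' element measurement (a replicate mean with its standard deviation) for a
#' site, variety and compartment. Values below the limit of quantification
#' are carried as censored records with value 0 and \code{censored = TRUE}.
#'
#' @param area Site label.
#' @param variety Cultivar label; \code{"n/a"} for soil.
#' @param compartment One of \code{gt_compartments()}.
#' @param element One of \code{gt_elements()}.
#' @param value Non-negative replicate mean.
#' @param sd Non-negative standard deviation of the replicates.
#' @param n Number of replicates (default 3).
#' @param unit \code{"mg/kg DW"}, \code{"mg/L"} or \code{"ug/L"}.
#' @param depth_cm Depth interval label such as \code{"0-20"}; required for
#'   soil records and disallowed otherwise.
#' @param distance_km Distance to the pollution source, or \code{NA}.
#' @param censored Logical; below-LOQ flag.
#' @return A \code{data.frame} of class \code{concentration_records}.
#' @export
concentration_records <- function(area, variety = "n/a", compartment, element,
                                  value, sd = 0, n = 3L, unit = NULL,
                                  depth_cm = NA_character_,
                                  distance_km = NA_real_, censored = FALSE) {
  if (is.null(unit)) unit <- GT_CANONICAL_UNIT[compartment]
  df <- data.frame(
    area = as.character(area), distance_km = as.numeric(distance_km),
    variety = as.character(variety), compartment = as.character(compartment),
    depth_cm = as.character(depth_cm), element = as.character(element),
    value = as.numeric(value), sd = as.numeric(sd), n = as.integer(n),
    unit = as.character(unit), censored = as.logical(censored),
    stringsAsFactors = FALSE
  )
  validate_records(df)
}

#' Validate a concentration record table
#'
#' Enforces the record invariants: known element and compartment, non-negative
#' value and sd, unit consistent with the compartment, a depth label present
#' exactly when the compartment is soil, and censored records carrying value
#' zero.
#'
#' @param df Data frame with the record columns.
#' @return The validated data frame, classed \code{concentration_records}.
#' @export
validate_records <- function(df) {
  required <- c("area", "variety", "compartment", "element",
                "value", "sd", "n", "unit")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("missing record columns: ", paste(missing, collapse = ", "))
  if (!"depth_cm" %in% names(df)) df$depth_cm <- NA_character_
  if (!"distance_km" %in% names(df)) df$distance_km <- NA_real_
  if (!"censored" %in% names(df)) df$censored <- FALSE
  df$censored[is.na(df$censored)] <- FALSE

  bad <- which(!df$element %in% GT_ELEMENTS)
  if (length(bad))
    stop("unknown element symbol '", df$element[bad[1]], "' in row ", bad[1])
  bad <- which(!df$compartment %in% GT_COMPARTMENTS)
  if (length(bad))
    stop("unknown compartment '", df$compartment[bad[1]], "' in row ", bad[1])
  bad <- which(is.na(df$value) | df$value < 0)
  if (length(bad))
    stop("negative or missing value in row ", bad[1])
  bad <- which(is.na(df$sd) | df$sd < 0)
  if (length(bad))
    stop("negative or missing sd in row ", bad[1])
  bad <- which(df$n < 1L)
  if (length(bad))
    stop("non-positive replicate count in row ", bad[1])
  is_soil <- df$compartment == "soil"
  bad <- which(is_soil & (is.na(df$depth_cm) | df$depth_cm == ""))
  if (length(bad))
    stop("soil record without depth interval in row ", bad[1])
  bad <- which(!is_soil & !is.na(df$depth_cm) & df$depth_cm != "")
  if (length(bad))
    stop("depth interval given for non-soil record in row ", bad[1])
  solid <- df$compartment %in% c("soil", "root", "cane", "leaf", "grape")
  bad <- which(solid & df$unit != "mg/kg DW")
  if (length(bad))
    stop("soil/plant record in row ", bad[1], " must be in mg/kg DW, got '",
         df$unit[bad[1]], "'")
  bad <- which(!solid & !df$unit %in% c("mg/L", "ug/L"))
  if (length(bad))
    stop("must/wine record in row ", bad[1], " must be in mg/L or ug/L")
  bad <- which(df$censored & df$value != 0)
  if (length(bad))
    stop("censored record in row ", bad[1], " must carry value 0")
  df$depth_cm[!is_soil] <- NA_character_
  class(df) <- unique(c("concentration_records", class(df)))
  df
}

#' Load a tidy concentration table
#'
#' Reads a delimited text file of element measurements, validates every row,
#' turns \code{"LOQ"}/\code{"LOD"} value cells into censored records (value 0,
#' flag set) and converts each row to the canonical unit of its compartment:
#' mg/kg DW for soil and plant tissue, mg/L for must and wine (\eqn{\mu}g/L
#' divided by 1000).
#'
#' @param path Path to a CSV (or TSV, see \code{sep}) file whose header names
#'   the record fields.
#' @param sep Field separator, default comma.
#' @return A \code{concentration_records} data frame.
#' @export
load_concentration_table <- function(path, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, na.strings = c("NA", ""))
  if (nrow(df) == 0) {
    df <- data.frame(area = character(), distance_km = numeric(),
                     variety = character(), compartment = character(),
                     depth_cm = character(), element = character(),
                     value = numeric(), sd = numeric(), n = integer(),
                     unit = character(), censored = logical())
    class(df) <- unique(c("concentration_records", class(df)))
    return(df)
  }
  val <- as.character(df$value)
  cens <- !is.na(val) & toupper(trimws(val)) %in% c("LOQ", "LOD", "<LOQ", "<LOD")
  df$value <- suppressWarnings(as.numeric(val))
  df$value[cens] <- 0
  if (!"censored" %in% names(df)) df$censored <- FALSE
  df$censored <- as.logical(df$censored) | cens
  df$sd <- suppressWarnings(as.numeric(as.character(df$sd)))
  df$sd[is.na(df$sd) & df$censored] <- 0
  if (!"n" %in% names(df)) df$n <- 3L
  df$n[is.na(df$n)] <- 3L
  # canonical units: beverages in mg/L
  ugl <- which(df$unit == "ug/L" | df$unit == "µg/L")
  if (length(ugl)) {
    df$value[ugl] <- df$value[ugl] / 1000
    df$sd[ugl] <- df$sd[ugl] / 1000
    df$unit[ugl] <- "mg/L"
  }
  validate_records(df)
}

#' Write a concentration table
#'
#' Writes records in the same tidy CSV layout that
#' \code{\link{load_concentration_table}} reads, so a written table round-trips
#' bit-for-bit at the stored precision.
#'
#' @param records A \code{concentration_records} data frame.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_concentration_table <- function(records, path) {
  cols <- c("area", "distance_km", "variety", "compartment", "depth_cm",
            "element", "value", "sd", "n", "unit", "censored")
  utils::write.csv(records[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
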