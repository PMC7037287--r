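#' Load a soil threshold table
#'
#' Reads the tiered soil limits (normal value, alert and intervention
#' thresholds, each split by land-use susceptibility) from a CSV so other
#' jurisdictions can be swapped in. The bundled
#' \code{gt_example("thresholds_ro_order756.csv")} transcribes the Romanian
#' Order 756/1997 tiers used in the study.
#'
#' @param path CSV with columns \code{element}, \code{normal},
#'   \code{alert_susceptible}, \code{alert_less_susceptible},
#'   \code{intervention_susceptible}, \code{intervention_less_susceptible}
#'   (mg/kg DW).
#' @return Data frame of thresholds, one row per element.
#' @export
load_soil_thresholds <- function(path = gt_example("thresholds_ro_order756.csv")) {
  th <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("element", "normal", "alert_susceptible", "alert_less_susceptible",
            "intervention_susceptible", "intervention_less_susceptible")
  missing <- setdiff(need, names(th))
  if (length(missing))
    stop("threshold table lacks columns: ", paste(missing, collapse = ", "))
  for (lu in c("susceptible", "less_susceptible")) {
    a <- th[[paste0("alert_", lu)]]; i <- th[[paste0("intervention_", lu)]]
    bad <- which(!(th$normal <= a & a <= i))
    if (length(bad))
      stop("thresholds not ordered normal <= alert <= intervention for ",
           th$element[bad[1]], " (", lu, ")")
  }
  th
}

#' Load a beverage maximum-permissible-limit table
#'
#' @param path CSV with columns \code{element}, \code{matrix} (\code{must} or
#'   \code{wine}) and \code{mpl} (mg/L; empty when the element has no limit).
#'   The bundled \code{gt_example("mpl_oiv.csv")} holds the wine limits used
#'   in the study and the higher must limits for Cu, Zn and Pb.
#' @return Data frame of limits.
#' @export
load_beverage_mpl <- function(path = gt_example("mpl_oiv.csv")) {
  mpl <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("element", "matrix", "mpl") %in% names(mpl)))
  mpl
}

soil_tiers <- c("within_normal", "above_normal", "above_alert",
                "above_intervention")

#' Grade soil concentrations against tiered regulatory limits
#'
#' Assigns each soil record the highest tier whose bound it strictly exceeds:
#' \code{within_normal}, \code{above_normal}, \code{above_alert} or
#' \code{above_intervention}. A value exactly at a bound stays in the lower
#' tier. \code{ratio_to_limit} is the value divided by the normal value.
#'
#' @param records Soil \code{concentration_records}.
#' @param thresholds Threshold table from \code{\link{load_soil_thresholds}}.
#' @param land_use \code{"susceptible"} (default) or
#'   \code{"less_susceptible"}.
#' @return The records with columns \code{tier}, \code{land_use} and
#'   \code{ratio_to_limit} appended.
#' @export
grade_soil <- function(records, thresholds = load_soil_thresholds(),
                       land_use = c("susceptible", "less_susceptible")) {
  land_use <- match.arg(land_use)
  if (any(records$compartment != "soil"))
    stop("grade_soil() applies to soil records only")
  idx <- match(records$element, thresholds$element)
  if (anyNA(idx))
    stop("no threshold row for element ",
         records$element[which(is.na(idx))[1]])
  normal <- thresholds$normal[idx]
  alert <- thresholds[[paste0("alert_", land_use)]][idx]
  interv <- thresholds[[paste0("intervention_", land_use)]][idx]
  tier <- ifelse(records$value > interv, "above_intervention",
          ifelse(records$value > alert, "above_alert",
          ifelse(records$value > normal, "above_normal", "within_normal")))
  records$tier <- factor(tier, levels = soil_tiers)
  records$land_use <- land_use
  records$ratio_to_limit <- records$value / normal
  records
}

#' Grade must and wine against maximum permissible limits
#'
#' \code{above_mpl} when the value strictly exceeds the limit for the
#' element in that matrix, \code{within_mpl} otherwise, and \code{no_limit}
#' for elements without one (Ni, Co, Cr, Hg).
#'
#' @param records Must/wine \code{concentration_records} in mg/L.
#' @param mpl Limit table from \code{\link{load_beverage_mpl}}.
#' @return The records with \code{tier} and \code{ratio_to_limit} appended
#'   (\code{ratio_to_limit} is NA where no limit exists).
#' @export
grade_beverage <- function(records, mpl = load_beverage_mpl()) {
  if (any(!records$compartment %in% c("must", "wine")))
    stop("grade_beverage() applies to must and wine records only")
  key <- paste(mpl$element, mpl$matrix)
  idx <- match(paste(records$element, records$compartment), key)
  lim <- mpl$mpl[idx]
  tier <- ifelse(is.na(lim), "no_limit",
          ifelse(records$value > lim, "above_mpl", "within_mpl"))
  records$tier <- factor(tier, levels = c("within_mpl", "above_mpl",
                                          "no_limit"))
  records$ratio_to_limit <- records$value / lim
  records
}

#' Exceedance tier counts per area and element
#'
#' Pure aggregation of \code{\link{grade_soil}} / \code{\link{grade_beverage}}
#' output: how many records of each area x element fall in each tier.
#'
#' @param records \code{concentration_records} (soil and/or beverages).
#' @param thresholds Soil threshold table.
#' @param mpl Beverage limit table.
#' @param land_use Land-use susceptibility for the soil tiers.
#' @return Data frame with columns \code{area}, \code{element}, \code{matrix},
#'   \code{tier} and \code{count}.
#' @export
exceedance_report <- function(records, thresholds = load_soil_thresholds(),
                              mpl = load_beverage_mpl(),
                              land_use = "susceptible") {
  parts <- list()
  soil <- records[records$compartment == "soil", , drop = FALSE]
  if (nrow(soil))
    parts$soil <- grade_soil(soil, thresholds, land_use)
  bev <- records[records$compartment %in% c("must", "wine"), , drop = FALSE]
  if (nrow(bev))
    parts$bev <- grade_beverage(bev, mpl)
  if (!length(parts)) stop("no soil or beverage records to grade")
  graded <- do.call(rbind, lapply(parts, function(p)
    data.frame(area = p$area, element = p$element,
               matrix = ifelse(p$compartment == "soil", "soil",
                               p$compartment),
               tier = as.character(p$tier), stringsAsFactors = FALSE)))
  out <- stats::aggregate(count ~ area + element + matrix + tier,
                          data = cbind(graded, count = 1L), FUN = sum)
  out[order(out$area, out$element, out$matrix, out$tier), ]
}
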