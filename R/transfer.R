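# Default translocation-factor chain: each compartment against the adjacent
# upstream one (grapes against canes, not leaves).
GT_TF_PAIRS <- list(c("root", "soil"), c("cane", "root"), c("leaf", "cane"),
                    c("grape", "cane"), c("must", "grape"), c("wine", "must"))

# Mobility-ratio chain: every compartment against (top)soil.
GT_MR_PAIRS <- list(c("root", "soil"), c("cane", "soil"), c("leaf", "soil"),
                    c("grape", "soil"), c("must", "soil"), c("wine", "soil"))

#' Concentration ratio between two compartments
#'
#' The elementary translocation/mobility quotient. A zero or censored
#' denominator yields \code{NA} with a warning, never infinity; a censored
#' numerator counts as 0.
#'
#' @param numerator,denominator Non-negative concentrations.
#' @return \code{numerator / denominator}, or \code{NA} where the denominator
#'   is zero or missing.
#' @export
transfer_ratio <- function(numerator, denominator) {
  bad <- is.na(denominator) | denominator <= 0
  if (any(bad, na.rm = TRUE))
    warning("zero or missing denominator; ratio undefined, returned as NA")
  out <- ifelse(bad, NA_real_, numerator / denominator)
  out[!bad & is.na(numerator)] <- NA_real_
  out
}

# value lookup per (area, variety, element) for one compartment; soil uses
# the chosen reference and is shared across varieties.
compartment_values <- function(records, compartment, soil_reference) {
  if (compartment == "soil") {
    soil <- records[records$compartment == "soil", , drop = FALSE]
    if (soil_reference == "topsoil_0_20")
      soil <- soil[soil$depth_cm == "0-20", , drop = FALSE]
    if (!nrow(soil)) return(NULL)
    agg <- stats::aggregate(value ~ area + element, data = soil, FUN = mean)
    cen <- stats::aggregate(censored ~ area + element, data = soil, FUN = all)
    agg$censored <- cen$censored[match(paste(agg$area, agg$element),
                                       paste(cen$area, cen$element))]
    agg$variety <- NA_character_
    agg
  } else {
    x <- records[records$compartment == compartment, , drop = FALSE]
    if (!nrow(x)) return(NULL)
    agg <- stats::aggregate(value ~ area + variety + element, data = x,
                            FUN = mean)
    cen <- stats::aggregate(censored ~ area + variety + element, data = x,
                            FUN = all)
    agg$censored <- cen$censored[match(
      paste(agg$area, agg$variety, agg$element),
      paste(cen$area, cen$variety, cen$element))]
    agg
  }
}

lookup_value <- function(tab, area, variety, element) {
  if (is.null(tab)) return(list(value = NA_real_, censored = FALSE))
  hit <- if (is.na(tab$variety[1]))
    which(tab$area == area & tab$element == element)
  else
    which(tab$area == area & tab$variety == variety & tab$element == element)
  if (!length(hit)) return(list(value = NA_real_, censored = FALSE))
  list(value = tab$value[hit[1]], censored = isTRUE(tab$censored[hit[1]]))
}

#' Translocation-factor / mobility-ratio chain summaries
#'
#' Computes, for each compartment pair and element, the per-variety transfer
#' ratio, its cross-variety mean, sample SD and relative SD, the
#' accumulator/indicator/excluder classification of the mean, and a
#' descending element ranking per pair — the layout of the study's transfer
#' tables.
#'
#' Ratios are formed per site and then combined across sites within a variety
#' according to \code{site_policy}; censored concentrations count as 0 in
#' numerators and make denominators undefined (ratio \code{NA}, with a
#' warning).
#'
#' @param records A \code{concentration_records} data frame.
#' @param pairs List of \code{c(numerator, denominator)} compartment pairs.
#'   Defaults to the translocation chain
#'   root/soil, cane/root, leaf/cane, grape/cane, must/grape, wine/must.
#' @param elements Elements to include (default: all present).
#' @param soil_reference Soil denominator policy: \code{"depth_average"}
#'   (default, used for translocation factors) or \code{"topsoil_0_20"}
#'   (the mobility-ratio convention).
#' @param site_policy \code{"per_site_mean"} (default; ratio per site, then
#'   averaged across sites) or \code{"pooled"} (concentrations averaged
#'   across sites before the ratio).
#' @param band Indicator band passed to \code{\link{classify_mobility}}.
#' @return A data frame of class \code{transfer_table}: one row per
#'   pair x element with one column per variety, \code{mean},
#'   \code{sd_sample}, \code{rsd_pct} and \code{classification}; the per-pair
#'   ranking strings are in \code{attr(, "ranking")}.
#' @examples
#' cfg <- synthetic_config(seed = 1, cv_noise = 0)
#' tf_chain(generate_dataset(cfg))
#' @export
tf_chain <- function(records, pairs = GT_TF_PAIRS, elements = NULL,
                     soil_reference = c("depth_average", "topsoil_0_20"),
                     site_policy = c("per_site_mean", "pooled"),
                     band = c(0.75, 1.25)) {
  soil_reference <- match.arg(soil_reference)
  site_policy <- match.arg(site_policy)
  if (is.null(elements))
    elements <- intersect(GT_ELEMENTS, unique(records$element))
  varieties <- unique(records$variety[records$variety != "n/a"])
  areas <- unique(records$area)
  comps <- unique(unlist(pairs))
  tabs <- lapply(stats::setNames(comps, comps), function(cp)
    compartment_values(records, cp, soil_reference))
  for (cp in comps)
    if (is.null(tabs[[cp]]))
      warning("no records for compartment '", cp,
              "'; its ratios are reported as missing")
  rows <- list()
  for (pair in pairs) {
    num <- pair[1]; den <- pair[2]
    for (e in elements) {
      per_var <- vapply(varieties, function(v) {
        vals <- vapply(areas, function(a) {
          nv <- lookup_value(tabs[[num]], a, v, e)
          dv <- lookup_value(tabs[[den]], a, v, e)
          c(if (nv$censored) 0 else nv$value,
            if (dv$censored) NA_real_ else dv$value)
        }, numeric(2))
        if (site_policy == "pooled") {
          nm <- mean(vals[1, ], na.rm = TRUE)
          dm <- mean(vals[2, ], na.rm = TRUE)
          suppressWarnings(transfer_ratio(nm, dm))
        } else {
          r <- suppressWarnings(transfer_ratio(vals[1, ], vals[2, ]))
          if (all(is.na(r))) NA_real_ else mean(r, na.rm = TRUE)
        }
      }, numeric(1))
      sm <- if (all(is.na(per_var)))
        list(mean = NA_real_, sd_sample = NA_real_, rsd_pct = NA_real_)
      else summarize_transfer(per_var)
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(pair = paste(num, den, sep = "/"), element = e,
                   stringsAsFactors = FALSE),
        as.data.frame(as.list(stats::setNames(per_var, varieties)),
                      check.names = FALSE),
        data.frame(mean = sm$mean, sd_sample = sm$sd_sample,
                   rsd_pct = sm$rsd_pct,
                   classification = if (is.na(sm$mean)) NA_character_
                     else classify_mobility(sm$mean, band)))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  ranking <- vapply(unique(out$pair), function(p) {
    m <- out$mean[out$pair == p]
    names(m) <- out$element[out$pair == p]
    if (anyNA(m)) NA_character_ else rank_elements(m)
  }, character(1))
  attr(out, "ranking") <- ranking
  attr(out, "soil_reference") <- soil_reference
  attr(out, "site_policy") <- site_policy
  class(out) <- c("transfer_table", class(out))
  out
}

#' @rdname tf_chain
#' @details \code{mr_chain()} is \code{tf_chain()} preset to the
#'   mobility-ratio convention: every compartment against the 0-20 cm
#'   topsoil.
#' @export
mr_chain <- function(records, elements = NULL,
                     soil_reference = "topsoil_0_20",
                     site_policy = "per_site_mean", band = c(0.75, 1.25)) {
  tf_chain(records, pairs = GT_MR_PAIRS, elements = elements,
           soil_reference = soil_reference, site_policy = site_policy,
           band = band)
}

#' @export
print.transfer_table <- function(x, digits = 3, ...) {
  cat("Transfer summaries (soil reference: ",
      attr(x, "soil_reference"), ", site policy: ",
      attr(x, "site_policy"), ")\n", sep = "")
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], round_half_up, digits = digits)
  print(df, row.names = FALSE)
  rk <- attr(x, "ranking")
  cat("\nElement ranking by mean ratio:\n")
  for (p in names(rk)) cat("  ", p, ": ", rk[[p]], "\n", sep = "")
  invisible(x)
}

#' Mean, sample SD and relative SD of per-variety ratios
#'
#' The summary triplet printed under each transfer-table block. The RSD is
#' 100 * SD / mean; when every ratio is zero the RSD is undefined and
#' reported as \code{NA}. (With exactly one nonzero ratio among n the RSD is
#' the pure number 100 * sqrt(n), e.g. 173.2 for n = 3.)
#'
#' @param values Numeric vector of per-variety ratios; \code{NA}s are
#'   dropped.
#' @return List with \code{mean}, \code{sd_sample}, \code{rsd_pct}.
#' @examples
#' summarize_transfer(c(0.411, 0.418, 0.534))
#' @export
summarize_transfer <- function(values) {
  values <- values[!is.na(values)]
  if (!length(values)) stop("all ratios are missing")
  m <- mean(values)
  s <- if (length(values) > 1) stats::sd(values) else NA_real_
  list(mean = m, sd_sample = s,
       rsd_pct = if (!is.na(s) && m > 0) 100 * s / m else NA_real_)
}

#' Classify plant behaviour from a mean mobility ratio
#'
#' Ratios clearly above 1 mark an accumulator (the plant enriches the
#' element), around 1 an indicator (indifferent behaviour), clearly below 1
#' an excluder. "Around 1" is operationalised by the configurable band.
#'
#' @param mean_ratio Non-negative mean ratio.
#' @param band Two-element \code{c(lo, hi)} indicator band, default
#'   \code{c(0.75, 1.25)}.
#' @return \code{"accumulator"}, \code{"indicator"} or \code{"excluder"}.
#' @export
classify_mobility <- function(mean_ratio, band = c(0.75, 1.25)) {
  if (band[1] > band[2]) stop("indicator band has lo > hi")
  if (any(mean_ratio < 0)) stop("mean ratio must be non-negative")
  ifelse(mean_ratio > band[2], "accumulator",
         ifelse(mean_ratio < band[1], "excluder", "indicator"))
}

#' Render a descending element ranking string
#'
#' @param means Named numeric vector of mean ratios per element, no missing
#'   values.
#' @return Elements joined by \code{">"} in strictly descending order of the
#'   mean; ties are broken alphabetically and flagged via
#'   \code{attr(, "ties")}.
#' @examples
#' rank_elements(c(Cr = 2.90, Co = 2.17, As = 1.30))
#' @export
rank_elements <- function(means) {
  if (anyNA(means)) stop("ranking requires non-missing means")
  ord <- order(-means, names(means))
  out <- paste(names(means)[ord], collapse = ">")
  ties <- anyDuplicated(means) > 0
  attr(out, "ties") <- ties
  out
}
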