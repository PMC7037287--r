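#' Grouped summary statistics for concentration records
#'
#' Reproduces the "Average" rows of the study tables: arithmetic mean, sample
#' standard deviation (n-1 denominator), relative standard deviation, minimum
#' and maximum of the record values within each group. Censored records enter
#' with value 0 and are counted in \code{n_censored}. Groups are emitted in
#' order of first appearance in the input.
#'
#' @param records A \code{concentration_records} data frame.
#' @param group_by Character vector of grouping columns, any subset of
#'   \code{c("area", "variety", "compartment", "element", "depth_cm")}.
#' @return A data frame with one row per group: the grouping columns plus
#'   \code{mean}, \code{sd_sample}, \code{rsd_pct}, \code{n_values},
#'   \code{n_censored}, \code{min}, \code{max}, \code{unit} and
#'   \code{singleton} (TRUE when the sample SD is undefined and reported as 0).
#' @examples
#' soil <- load_concentration_table(gt_example("table1_soil.csv"))
#' aggregate_concentrations(soil, c("area", "element"))
#' @export
aggregate_concentrations <- function(records, group_by = "element") {
  stopifnot(nrow(records) > 0)
  bad <- setdiff(group_by, names(records))
  if (length(bad)) stop("unknown grouping column: ", paste(bad, collapse = ", "))
  key <- do.call(paste, c(records[group_by], sep = "\r"))
  key <- factor(key, levels = unique(key))
  out <- lapply(levels(key), function(k) {
    g <- records[key == k, , drop = FALSE]
    if (length(unique(g$unit)) > 1)
      stop("mixed units within group '", gsub("\r", "/", k), "'")
    v <- g$value
    s <- if (length(v) > 1) stats::sd(v) else 0
    m <- mean(v)
    cbind(
      g[1, group_by, drop = FALSE],
      data.frame(mean = m, sd_sample = s,
                 rsd_pct = if (m > 0) 100 * s / m else NA_real_,
                 n_values = length(v), n_censored = sum(g$censored),
                 min = min(v), max = max(v), unit = g$unit[1],
                 singleton = length(v) == 1)
    )
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Records attaining the minimum and maximum value
#'
#' Reproduces the "Minimum values" / "Maximum values" table rows: returns the
#' records holding the smallest and largest \code{value}, ties broken by input
#' order.
#'
#' @param records A non-empty \code{concentration_records} data frame.
#' @return A list with elements \code{min} and \code{max}, each a one-row
#'   record data frame.
#' @export
extremes <- function(records) {
  if (nrow(records) == 0) stop("extremes() needs at least one record")
  list(min = records[which.min(records$value), , drop = FALSE],
       max = records[which.max(records$value), , drop = FALSE])
}
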