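#' Pearson correlation cell with significance stars
#'
#' Product-moment correlation with a two-tailed p value from the t
#' transform, formatted as one cell of a correlation table: \code{"*"} at
#' p <= 0.05, \code{"**"} at p <= 0.01. Zero-variance input (e.g. an element
#' entirely below LOQ in one compartment) is flagged degenerate and its r is
#' reported as 0, the convention of the study's correlation table.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return A one-row data frame: \code{r}, \code{p_two_tailed}, \code{stars},
#'   \code{n}, \code{degenerate}.
#' @examples
#' pearson_cell(1:4, c(2, 1, 4, 3)) # r = 0.6
#' @export
pearson_cell <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3)
    return(data.frame(r = NA_real_, p_two_tailed = NA_real_, stars = "",
                      n = length(x), degenerate = NA,
                      stringsAsFactors = FALSE))
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(data.frame(r = 0, p_two_tailed = NA_real_, stars = "",
                      n = length(x), degenerate = TRUE,
                      stringsAsFactors = FALSE))
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  p <- ct$p.value
  data.frame(r = unname(ct$estimate), p_two_tailed = p,
             stars = if (is.na(p)) "" else if (p <= 0.01) "**"
                     else if (p <= 0.05) "*" else "",
             n = length(x), degenerate = FALSE, stringsAsFactors = FALSE)
}

#' Correlation matrix of one element across compartments and distance
#'
#' Builds, for one element, the per-site-per-variety value vectors of each
#' requested compartment (soil is depth-averaged) plus optionally the
#' distance to the pollution source, and correlates every pair. Reported as
#' a lower-triangular table with a unit diagonal, stars attached, mirroring
#' the study's correlation tables.
#'
#' @param records A \code{concentration_records} data frame.
#' @param element Element symbol.
#' @param variables Compartments to include, plus \code{"distance"}.
#' @return A list of class \code{correlation_matrix}: \code{element},
#'   \code{variables}, numeric matrices \code{r} and \code{p}, character
#'   matrix \code{stars}, logical \code{degenerate}, \code{n}.
#' @export
correlation_matrix <- function(records, element,
                               variables = c("distance", "soil", "root",
                                             "cane", "leaf", "grape",
                                             "must", "wine")) {
  rec <- records[records$element == element, , drop = FALSE]
  if (!nrow(rec)) stop("no records for element ", element)
  varieties <- unique(rec$variety[rec$variety != "n/a"])
  areas <- unique(rec$area)
  grid <- expand.grid(area = areas, variety = varieties,
                      stringsAsFactors = FALSE)
  col_for <- function(v) {
    if (v == "distance") {
      d <- rec$distance_km[match(grid$area, rec$area)]
      if (all(is.na(d))) stop("records carry no distance_km values")
      return(d)
    }
    tab <- compartment_values(rec, v, "depth_average")
    vapply(seq_len(nrow(grid)), function(i)
      lookup_value(tab, grid$area[i], grid$variety[i], element)$value,
      numeric(1))
  }
  mat <- vapply(variables, col_for, numeric(nrow(grid)))
  k <- length(variables)
  r <- diag(1, k); p <- matrix(NA_real_, k, k)
  stars <- matrix("", k, k); degen <- matrix(FALSE, k, k)
  for (i in seq_len(k)) for (j in seq_len(i - 1)) {
    cell <- pearson_cell(mat[, i], mat[, j])
    r[i, j] <- r[j, i] <- cell$r
    p[i, j] <- p[j, i] <- cell$p_two_tailed
    stars[i, j] <- stars[j, i] <- cell$stars
    degen[i, j] <- degen[j, i] <- isTRUE(cell$degenerate)
  }
  dimnames(r) <- dimnames(p) <- dimnames(stars) <- dimnames(degen) <-
    list(variables, variables)
  out <- list(element = element, variables = variables, r = r, p = p,
              stars = stars, degenerate = degen, n = nrow(grid))
  class(out) <- "correlation_matrix"
  out
}

#' @export
print.correlation_matrix <- function(x, digits = 4, ...) {
  cat("Pearson correlations for", x$element, "(n =", x$n, "per cell)\n")
  k <- length(x$variables)
  disp <- matrix("", k, k, dimnames = list(x$variables, x$variables))
  for (i in seq_len(k)) {
    disp[i, i] <- "1.000"
    for (j in seq_len(i - 1))
      disp[i, j] <- paste0(formatC(x$r[i, j], digits = digits,
                                   format = "f"), x$stars[i, j])
  }
  print(disp, quote = FALSE)
  cat("* p <= 0.05, ** p <= 0.01 (two-tailed)\n")
  invisible(x)
}

#' One-way ANOVA with Duncan multiple-range compact letter display
#'
#' Fits a one-way ANOVA on the groups and separates their means with
#' Duncan's multiple range test: the range spanning p ordered means is
#' compared against a studentized-range critical value at the stage-wise
#' significance level \eqn{\alpha_p = 1 - (1 - \alpha)^{p - 1}}. Once a range
#' is found non-significant, all means inside it are declared homogeneous
#' (the protection rule of the multiple-range procedure). Groups are lettered
#' in descending-mean order starting at "a"; two groups share a letter iff
#' the test does not separate them.
#'
#' @param groups Named list of numeric vectors (>= 2 groups, each with >= 2
#'   values).
#' @param alpha Significance level; the study tables use 0.05 (Roman
#'   letters) and 0.005 (Greek letters).
#' @return An object of class \code{duncan_letters}: data frame
#'   \code{display} (group, n, mean, letters, in descending-mean order),
#'   \code{anova_p}, \code{alpha}, \code{df_error}, \code{ms_error}.
#' @examples
#' anova_duncan(list(a = c(1, 1.1, 0.9), b = c(5, 5.2, 4.9)), alpha = 0.05)
#' @export
anova_duncan <- function(groups, alpha = 0.05) {
  if (length(groups) < 2) stop("at least two groups are required")
  sizes <- vapply(groups, length, 1L)
  if (any(sizes < 2)) stop("every group needs at least two values")
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("group", seq_along(groups))
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), sizes), levels = names(groups))
  fit <- stats::lm(y ~ g)
  av <- stats::anova(fit)
  mse <- av["Residuals", "Mean Sq"]
  dfe <- av["Residuals", "Df"]
  means <- vapply(groups, mean, 0)
  ord <- order(-means)
  k <- length(groups)
  # pairwise separation under the multiple-range protection rule
  sep <- matrix(TRUE, k, k)
  nonsig_span <- rep(FALSE, k + 1) # spans already absorbed
  for (span in k:2) {
    alpha_p <- 1 - (1 - alpha)^(span - 1)
    qcrit <- stats::qtukey(1 - alpha_p, span, dfe)
    for (i in 1:(k - span + 1)) {
      j <- i + span - 1
      gi <- ord[i]; gj <- ord[j]
      if (!sep[gi, gj]) next   # inside an absorbed non-significant range
      se <- sqrt(mse / 2 * (1 / sizes[gi] + 1 / sizes[gj]))
      if (mse == 0) {
        signif <- means[gi] != means[gj]
      } else {
        signif <- abs(means[gi] - means[gj]) > qcrit * se
      }
      if (!signif) {
        for (a in i:j) for (b in i:j)
          sep[ord[a], ord[b]] <- FALSE
      }
    }
  }
  diag(sep) <- FALSE
  letters_vec <- cld_from_separation(sep, ord)
  display <- data.frame(group = names(groups)[ord], n = sizes[ord],
                        mean = means[ord], letters = letters_vec[ord],
                        stringsAsFactors = FALSE)
  rownames(display) <- NULL
  out <- list(display = display, anova_p = av[1, "Pr(>F)"], alpha = alpha,
              df_error = dfe, ms_error = mse)
  class(out) <- "duncan_letters"
  out
}

# Compact letter display from a logical separation matrix. Under the
# multiple-range rule the homogeneous sets are intervals of the mean-ordered
# groups, so letters are the maximal non-separated intervals.
cld_from_separation <- function(sep, ord) {
  k <- nrow(sep)
  intervals <- list()
  i <- 1
  while (i <= k) {
    j <- i
    while (j < k && !sep[ord[i], ord[j + 1]]) j <- j + 1
    intervals[[length(intervals) + 1L]] <- i:j
    i <- i + 1
  }
  # drop intervals contained in an earlier (longer) one
  keep <- rep(TRUE, length(intervals))
  for (a in seq_along(intervals)) for (b in seq_along(intervals))
    if (a != b && keep[a] && keep[b] &&
        all(intervals[[a]] %in% intervals[[b]])) keep[a] <- FALSE
  intervals <- intervals[keep]
  lab <- rep("", k)
  for (m in seq_along(intervals))
    for (pos in intervals[[m]])
      lab[ord[pos]] <- paste0(lab[ord[pos]], letters[m])
  lab
}

#' @export
print.duncan_letters <- function(x, ...) {
  cat(sprintf("One-way ANOVA p = %.4g; Duncan letters at alpha = %g\n",
              x$anova_p, x$alpha))
  df <- x$display
  df$mean <- signif(df$mean, 5)
  print(df, row.names = FALSE)
  cat("Groups sharing a letter are not separated by the range test.\n")
  invisible(x)
}
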