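# Elements used for geographic discrimination of must/wine by default:
# the eight identified as most discriminant in this system; Co is excluded
# because it sits entirely below LOQ in the beverages.
GT_LDA_ELEMENTS <- c("Cr", "Hg", "As", "Cu", "Zn", "Pb", "Ni", "Cd")

#' Observation x element feature matrix from concentration records
#'
#' Reshapes records of one compartment into a numeric matrix (rows:
#' area/variety/replicate observations; columns: elements) for the
#' multivariate stages. Censored cells are imputed as LOQ/2 so that
#' all-censored columns do not zero out scatter matrices.
#'
#' @param records A \code{concentration_records} data frame.
#' @param compartments Compartments to keep (rows are observations within
#'   them).
#' @param elements Element columns, default the discrimination set.
#' @param loq Named per-element LOQ used for the LOQ/2 imputation of
#'   censored cells (default 0, i.e. censored stays 0).
#' @return List with matrix \code{x} and character vector \code{labels}
#'   (the area of each row).
#' @export
element_features <- function(records, compartments,
                             elements = GT_LDA_ELEMENTS, loq = NULL) {
  rec <- records[records$compartment %in% compartments &
                   records$element %in% elements, , drop = FALSE]
  if (!nrow(rec)) stop("no records in the requested compartments")
  if (!is.null(loq)) {
    imp <- rec$censored & rec$element %in% names(loq)
    rec$value[imp] <- loq[rec$element[imp]] / 2
  }
  rec$obs <- paste(rec$area, rec$variety, rec$compartment, sep = "|")
  obs <- unique(rec$obs)
  x <- matrix(NA_real_, length(obs), length(elements),
              dimnames = list(obs, elements))
  for (i in seq_along(obs)) {
    sub <- rec[rec$obs == obs[i], ]
    m <- tapply(sub$value, sub$element, mean)
    x[i, names(m)] <- m
  }
  if (anyNA(x)) stop("missing element cells in the feature matrix")
  list(x = x, labels = vapply(strsplit(obs, "|", fixed = TRUE), `[[`, "", 1))
}

#' Linear discriminant analysis of geographic origin
#'
#' Fisher discriminant axes separating the labelled classes, with the
#' explained-variance share of each axis (from the between-class
#' eigenvalues), per-observation scores, the resubstitution confusion matrix
#' and accuracy. Features are z-score standardized by default; priors are
#' proportional to class counts.
#'
#' @param features Numeric observation x element matrix.
#' @param labels Class label (area) per observation.
#' @param standardize Standardize columns before fitting (default TRUE).
#' @return Object of class \code{discriminant_model}: \code{lda} (the
#'   underlying fit), \code{explained_pct}, \code{scores},
#'   \code{confusion}, \code{accuracy_pct}, \code{labels}.
#' @export
lda_fit <- function(features, labels, standardize = TRUE) {
  labels <- factor(labels)
  if (nlevels(labels) < 2) stop("at least two classes are required")
  if (nrow(features) <= nlevels(labels))
    stop("need more observations than classes")
  if (standardize) features <- scale(features)
  sds <- apply(features, 2, stats::sd)
  if (any(!is.finite(sds)) || any(sds == 0))
    stop("constant or collinear feature columns; drop those elements")
  centered <- features - rowsum(features, labels)[labels, ] /
    as.vector(table(labels))[labels]
  if (qr(centered)$rank < ncol(features))
    stop("within-class scatter is singular; drop collinear elements")
  fit <- tryCatch(MASS::lda(features, grouping = labels),
                  error = function(e)
                    stop("within-class scatter is singular; ",
                         "drop collinear elements (", conditionMessage(e),
                         ")"))
  ev <- fit$svd^2
  pred <- stats::predict(fit)
  confusion <- table(truth = labels, predicted = pred$class)
  out <- list(lda = fit,
              explained_pct = 100 * ev / sum(ev),
              scores = pred$x,
              confusion = confusion,
              accuracy_pct = 100 * sum(diag(confusion)) / length(labels),
              labels = labels, standardize = standardize)
  class(out) <- "discriminant_model"
  out
}

#' @export
print.discriminant_model <- function(x, ...) {
  cat("Linear discriminant model,", nlevels(x$labels), "classes,",
      length(x$labels), "observations\n")
  cat("Axis explained variance (%):",
      paste(sprintf("F%d = %.2f", seq_along(x$explained_pct),
                    x$explained_pct), collapse = ", "), "\n")
  cat("Resubstitution accuracy:", sprintf("%.2f%%", x$accuracy_pct), "\n")
  print(x$confusion)
  invisible(x)
}

#' Cross-validated classification accuracy of the discriminant model
#'
#' Each observation (or fold) is predicted by a model fitted without it;
#' accuracy is 100 * trace / total of the resulting confusion matrix.
#'
#' @param features Numeric observation x element matrix.
#' @param labels Class label per observation.
#' @param scheme \code{"leave_one_out"} (default) or \code{"k_fold"}.
#' @param k Number of folds for \code{"k_fold"}.
#' @param folds Optional integer fold assignment per observation (overrides
#'   the seed-dependent random split).
#' @param standardize Standardize columns within each training fold.
#' @return List with \code{confusion} and \code{cv_accuracy_pct}.
#' @export
crossvalidate <- function(features, labels,
                          scheme = c("leave_one_out", "k_fold"), k = 5,
                          folds = NULL, standardize = TRUE) {
  scheme <- match.arg(scheme)
  labels <- factor(labels)
  n <- nrow(features)
  if (is.null(folds)) {
    folds <- if (scheme == "leave_one_out") seq_len(n)
             else sample(rep_len(seq_len(k), n))
  }
  pred <- factor(rep(NA_character_, n), levels = levels(labels))
  for (f in unique(folds)) {
    test <- folds == f
    train_lab <- droplevels(labels[!test])
    if (nlevels(train_lab) < nlevels(labels))
      stop("a fold removes an entire class; use fewer folds")
    xtr <- features[!test, , drop = FALSE]
    xte <- features[test, , drop = FALSE]
    if (standardize) {
      mu <- colMeans(xtr); sg <- apply(xtr, 2, stats::sd)
      if (any(sg == 0)) stop("constant feature column within a fold")
      xtr <- scale(xtr, mu, sg); xte <- scale(xte, mu, sg)
    }
    fit <- MASS::lda(xtr, grouping = train_lab)
    pred[test] <- stats::predict(fit, xte)$class
  }
  confusion <- table(truth = labels, predicted = pred)
  list(confusion = confusion,
       cv_accuracy_pct = 100 * sum(diag(confusion)) / n)
}

#' Hierarchical clustering of element profiles
#'
#' Agglomerative clustering of item-by-element profiles: z-score
#' standardization per element (so scale differences between elements do not
#' dominate), Euclidean distance and Ward linkage by default, all
#' configurable. Ties are broken deterministically by input order
#' (\code{stats::hclust} behaviour). The tree can be exported as Newick text
#' with branch lengths from the merge heights.
#'
#' @param profiles Numeric item x element matrix with rownames.
#' @param metric Distance metric for \code{stats::dist}.
#' @param linkage Linkage method for \code{stats::hclust} (default
#'   \code{"ward.D2"}).
#' @param standardize Z-score columns first (default TRUE).
#' @return Object of class \code{profile_dendrogram}: \code{hclust},
#'   \code{newick}, \code{labels}.
#' @examples
#' soil <- load_concentration_table(gt_example("table1_soil.csv"))
#' prof <- soil_profile_matrix(soil)
#' hcluster(prof)
#' @export
hcluster <- function(profiles, metric = "euclidean", linkage = "ward.D2",
                     standardize = TRUE) {
  if (nrow(profiles) < 2) stop("at least two items are required")
  if (any(!is.finite(profiles))) stop("non-finite cells in the profiles")
  x <- profiles
  if (standardize) {
    x <- scale(x)
    x[, apply(profiles, 2, stats::sd) == 0] <- 0
  }
  hc <- stats::hclust(stats::dist(x, method = metric), method = linkage)
  out <- list(hclust = hc,
              newick = ape::write.tree(ape::as.phylo(hc)),
              labels = rownames(profiles))
  class(out) <- "profile_dendrogram"
  out
}

#' @export
print.profile_dendrogram <- function(x, ...) {
  cat("Hierarchical clustering of", length(x$labels), "profiles (",
      x$hclust$method, "linkage )\n")
  cat("Merge heights:", paste(signif(x$hclust$height, 4), collapse = ", "),
      "\n")
  cat("Newick:", x$newick, "\n")
  invisible(x)
}

#' Cut a profile dendrogram into k clusters
#'
#' @param dendro A \code{profile_dendrogram}.
#' @param k Number of clusters.
#' @return Named integer vector of cluster memberships.
#' @export
cut_profiles <- function(dendro, k) {
  stats::cutree(dendro$hclust, k = k)
}

#' Site-by-element soil profile matrix
#'
#' One row per area x depth soil sample, columns the elements: the layout
#' clustered to compare pollution fingerprints between sites.
#'
#' @param records \code{concentration_records} containing soil rows.
#' @param elements Elements to keep.
#' @return Numeric matrix with "area depth" rownames.
#' @export
soil_profile_matrix <- function(records, elements = gt_elements()) {
  soil <- records[records$compartment == "soil" &
                    records$element %in% elements, , drop = FALSE]
  if (!nrow(soil)) stop("no soil records")
  soil$row <- paste(soil$area, soil$depth_cm)
  rows <- unique(soil$row)
  x <- matrix(NA_real_, length(rows), length(elements),
              dimnames = list(rows, elements))
  for (i in seq_along(rows)) {
    sub <- soil[soil$row == rows[i], ]
    m <- tapply(sub$value, sub$element, mean)
    x[i, names(m)] <- m
  }
  if (anyNA(x)) stop("missing element cells in the soil profiles")
  x
}
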