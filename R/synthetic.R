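# Default ground-truth transfer chain (root/soil, cane/root, leaf/cane,
# grape/cane, must/grape, wine/must) per element. Values follow the mean
# translocation factors observed in the study system: attenuation towards the
# berry for most elements, cobalt fully blocked before the must.
GT_DEFAULT_PARTITION <- list(
  Cu = c(0.45, 0.18, 0.98, 0.11, 2.19, 0.06),
  Zn = c(0.18, 1.02, 0.86, 0.05, 2.28, 0.33),
  Pb = c(0.05, 1.16, 1.22, 0.09, 0.13, 0.30),
  Cd = c(0.58, 1.73, 0.68, 0.15, 0.11, 0.33),
  Ni = c(0.82, 1.12, 2.57, 0.20, 0.34, 0.14),
  Co = c(2.17, 2.28, 1.35, 0.11, 0.00, 0.00),
  As = c(1.30, 0.62, 2.23, 0.53, 0.07, 0.66),
  Cr = c(2.90, 0.23, 0.51, 0.24, 4.54, 0.85),
  Hg = c(0.60, 1.41, 1.93, 0.53, 0.02, 0.08)
)

# Soil concentration at the source (mg/kg DW) and exponential decay rate
# (per km), set to the magnitudes of the smelter-adjacent and remote sites:
# smelter-driven elements (Cu, Zn, Pb, Cd) decay fast, geogenic ones slowly.
GT_DEFAULT_SOURCE <- c(Cu = 3500, Zn = 2800, Pb = 3600, Cd = 25, Ni = 25,
                       Co = 20, As = 4.5, Cr = 2.5, Hg = 0.06)
GT_DEFAULT_DECAY <- c(Cu = 0.025, Zn = 0.065, Pb = 0.10, Cd = 0.08,
                      Ni = 0.02, Co = 0.015, As = 0.015, Cr = 0.012,
                      Hg = 0.003)

GT_DEPTHS <- c("0-20", "20-40", "40-60", "60-80")

#' Configuration for the synthetic pollution-gradient generator
#'
#' Describes a point-source gradient with known ground truth: per-element
#' soil concentration at the source decaying exponentially with distance,
#' a true transfer-ratio vector along the
#' soil-root-cane-leaf/grape-must-wine chain, multiplicative lognormal
#' replicate noise, and left-censoring below a per-element limit of
#' quantification.
#'
#' @param seed Integer seed; every draw is a deterministic function of the
#'   seed and the record's site/variety/compartment/depth/element index, so
#'   subsetting the design does not shift draws.
#' @param sites Data frame with columns \code{label} and \code{distance_km}.
#' @param varieties Character vector of cultivar labels for the plant and
#'   beverage compartments.
#' @param elements Character vector of element symbols.
#' @param source_strength Named vector: soil concentration at distance 0
#'   (mg/kg DW) per element.
#' @param decay_rate Named vector: exponential decay rate per km per element.
#' @param partition Named list: per element, the six true transfer ratios
#'   (root/soil, cane/root, leaf/cane, grape/cane, must/grape, wine/must).
#' @param depth_slope Named vector: multiplicative trend across the four soil
#'   depth layers (layer l is scaled by \code{depth_slope^(l-1)}).
#' @param cv_noise Lognormal coefficient of variation per replicate;
#'   0.1 means 10 percent relative spread.
#' @param n_replicates Replicates per record, default 3.
#' @param loq Named vector: censoring threshold per element (in the unit of
#'   the compartment the value lands in).
#' @return A validated list of class \code{synthetic_config}.
#' @export
synthetic_config <- function(seed = 1L,
                             sites = data.frame(
                               label = c("Near", "Edge", "Remote"),
                               distance_km = c(0, 5, 60)),
                             varieties = c("cv_A", "cv_B", "cv_C"),
                             elements = gt_elements(),
                             source_strength = GT_DEFAULT_SOURCE,
                             decay_rate = GT_DEFAULT_DECAY,
                             partition = GT_DEFAULT_PARTITION,
                             depth_slope = NULL,
                             cv_noise = 0.1,
                             n_replicates = 3L,
                             loq = NULL) {
  if (is.null(depth_slope))
    depth_slope <- stats::setNames(rep(1, length(elements)), elements)
  if (is.null(loq))
    loq <- stats::setNames(rep(0.001, length(elements)), elements)
  cfg <- list(seed = as.integer(seed), sites = sites, varieties = varieties,
              elements = elements,
              source_strength = source_strength[elements],
              decay_rate = decay_rate[elements],
              partition = partition[elements],
              depth_slope = depth_slope[elements],
              cv_noise = cv_noise, n_replicates = as.integer(n_replicates),
              loq = loq[elements])
  validate_synthetic_config(cfg)
}

validate_synthetic_config <- function(cfg) {
  stopifnot(is.data.frame(cfg$sites),
            all(c("label", "distance_km") %in% names(cfg$sites)))
  if (any(cfg$sites$distance_km < 0)) stop("distances must be non-negative")
  if (cfg$n_replicates < 1L) stop("n_replicates must be at least 1")
  if (cfg$cv_noise < 0) stop("cv_noise must be non-negative")
  for (f in c("source_strength", "decay_rate", "depth_slope", "loq")) {
    v <- cfg[[f]]
    if (any(is.na(v))) stop("missing ", f, " for some element")
    if (any(v < 0)) stop(f, " must be non-negative")
  }
  for (e in cfg$elements) {
    p <- cfg$partition[[e]]
    if (is.null(p) || length(p) != 6 || any(p < 0))
      stop("partition for ", e, " must be 6 non-negative ratios")
  }
  class(cfg) <- "synthetic_config"
  cfg
}

# Deterministic per-record stream: a polynomial hash of the design indices,
# folded into [0, 2^31 - 2], seeds the draws of one record.
record_seed <- function(seed, i_site, i_var, i_comp, i_depth, i_elem) {
  m <- 2147483647
  h <- (seed %% m) + 1
  for (x in c(i_site, i_var, i_comp, i_depth, i_elem))
    h <- (h * 31 + x * 2654435) %% m
  as.integer(h)
}

# n lognormal factors with unit mean and coefficient of variation cv
lognormal_factors <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  s2 <- log(1 + cv^2)
  stats::rlnorm(n, meanlog = -s2 / 2, sdlog = sqrt(s2))
}

#' Generate a synthetic gradient dataset
#'
#' Draws a full concentration table from a \code{\link{synthetic_config}}:
#' soil means decay exponentially with distance and follow the depth trend;
#' each downstream compartment mean is the upstream mean (depth-averaged soil
#' for roots) times the configured true ratio; each replicate is the
#' compartment mean times a lognormal factor with the configured CV. Records
#' whose value falls strictly below the element's LOQ are emitted censored.
#' Fully reproducible from the seed.
#'
#' @param config A \code{synthetic_config}.
#' @param emit \code{"mean"} (default) emits one record per design cell with
#'   the replicate mean, SD and n; \code{"replicates"} emits one record per
#'   replicate (sd 0, n 1), as used for observation-level chemometrics.
#' @return A \code{concentration_records} data frame.
#' @export
generate_dataset <- function(config, emit = c("mean", "replicates")) {
  emit <- match.arg(emit)
  cfg <- validate_synthetic_config(unclass(config))
  comps <- GT_COMPARTMENTS
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  rows <- list()
  for (i_site in seq_len(nrow(cfg$sites))) {
    site <- cfg$sites$label[i_site]
    d <- cfg$sites$distance_km[i_site]
    for (i_elem in seq_along(cfg$elements)) {
      e <- cfg$elements[i_elem]
      soil0 <- cfg$source_strength[[e]] * exp(-cfg$decay_rate[[e]] * d)
      layer_mult <- cfg$depth_slope[[e]]^(seq_along(GT_DEPTHS) - 1)
      soil_means <- soil0 * layer_mult
      # soil records, variety n/a
      for (i_depth in seq_along(GT_DEPTHS)) {
        rows[[length(rows) + 1L]] <- synth_record(
          cfg, site, d, "n/a", "soil", GT_DEPTHS[i_depth], e,
          soil_means[i_depth], i_site, 0L, 1L, i_depth, i_elem, emit)
      }
      # plant and beverage compartments per variety; the grape branches off
      # the cane (leaves are a side branch, not upstream of the berry)
      p <- cfg$partition[[e]]
      soil_mean <- mean(soil_means)
      chain_means <- c(root = soil_mean * p[1])
      chain_means["cane"] <- chain_means["root"] * p[2]
      chain_means["leaf"] <- chain_means["cane"] * p[3]
      chain_means["grape"] <- chain_means["cane"] * p[4]
      chain_means["must"] <- chain_means["grape"] * p[5]
      chain_means["wine"] <- chain_means["must"] * p[6]
      for (i_var in seq_along(cfg$varieties)) {
        v <- cfg$varieties[i_var]
        for (i_comp in seq_along(comps[-1])) {
          comp <- comps[-1][i_comp]
          rows[[length(rows) + 1L]] <- synth_record(
            cfg, site, d, v, comp, NA_character_, e,
            chain_means[[comp]], i_site, i_var, i_comp + 1L, 0L, i_elem, emit)
        }
      }
    }
  }
  cols <- names(rows[[1]])
  out <- as.data.frame(stats::setNames(lapply(cols, function(cl)
    unlist(lapply(rows, `[[`, cl), use.names = FALSE)), cols),
    stringsAsFactors = FALSE)
  validate_records(out)
}

synth_record <- function(cfg, site, d, variety, comp, depth, e, mu,
                         i_site, i_var, i_comp, i_depth, i_elem, emit) {
  set.seed(record_seed(cfg$seed, i_site, i_var, i_comp, i_depth, i_elem))
  draws <- mu * lognormal_factors(cfg$n_replicates, cfg$cv_noise)
  unit <- GT_CANONICAL_UNIT[[comp]]
  loq <- cfg$loq[[e]]
  if (emit == "replicates") {
    cens <- draws < loq
    list(area = rep(site, length(draws)), distance_km = rep(d, length(draws)),
         variety = rep(variety, length(draws)),
         compartment = rep(comp, length(draws)),
         depth_cm = rep(depth, length(draws)),
         element = rep(e, length(draws)),
         value = ifelse(cens, 0, draws), sd = rep(0, length(draws)),
         n = rep(1L, length(draws)), unit = rep(unit, length(draws)),
         censored = cens)
  } else {
    m <- mean(draws)
    s <- if (length(draws) > 1) stats::sd(draws) else 0
    cens <- m < loq
    list(area = site, distance_km = d, variety = variety,
         compartment = comp, depth_cm = depth, element = e,
         value = if (cens) 0 else m, sd = if (cens) 0 else s,
         n = cfg$n_replicates, unit = unit, censored = cens)
  }
}

#' Generate a synthetic calibration point set
#'
#' Simulates instrument responses on a straight calibration line with
#' Gaussian residual noise, for exercising the detection/quantification limit
#' computation. The default level series is the standard five-point
#' multielement calibration (2.5, 5, 10, 25, 50).
#'
#' @param seed Integer seed.
#' @param slope True slope (> 0).
#' @param intercept True intercept.
#' @param resid_sd Residual standard deviation (>= 0).
#' @param levels Concentration levels; at least 3.
#' @return Data frame with columns \code{level} and \code{response}.
#' @export
generate_calibration <- function(seed = 1L, slope = 1, intercept = 0,
                                 resid_sd = 0,
                                 levels = c(2.5, 5, 10, 25, 50)) {
  if (slope <= 0) stop("slope must be positive")
  if (resid_sd < 0) stop("resid_sd must be non-negative")
  if (length(levels) < 3) stop("at least 3 calibration levels are required")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  data.frame(level = levels,
             response = intercept + slope * levels +
               stats::rnorm(length(levels), 0, resid_sd))
}

#' Read or write a synthetic-gradient configuration as YAML
#'
#' @param path YAML file path. The bundled default
#'   \code{gt_example("gradient_default.yaml")} mimics three sites at 0, 5
#'   and 60 km from a smelter.
#' @return \code{read_synthetic_config}: a \code{synthetic_config}.
#' @export
read_synthetic_config <- function(path) {
  y <- yaml::read_yaml(path)
  synthetic_config(
    seed = y$seed,
    sites = data.frame(label = vapply(y$sites, `[[`, "", "label"),
                       distance_km = vapply(y$sites, function(s)
                         as.numeric(s$distance_km), 0)),
    varieties = unlist(y$varieties),
    elements = names(y$elements),
    source_strength = vapply(y$elements, function(e) as.numeric(e$source), 0),
    decay_rate = vapply(y$elements, function(e) as.numeric(e$decay), 0),
    partition = lapply(y$elements, function(e) as.numeric(e$partition)),
    depth_slope = vapply(y$elements, function(e) as.numeric(e$depth_slope), 0),
    cv_noise = y$cv_noise, n_replicates = y$n_replicates,
    loq = vapply(y$elements, function(e) as.numeric(e$loq), 0))
}

#' @rdname read_synthetic_config
#' @param config A \code{synthetic_config} to serialise.
#' @export
write_synthetic_config <- function(config, path) {
  y <- list(
    seed = config$seed,
    sites = lapply(seq_len(nrow(config$sites)), function(i)
      list(label = config$sites$label[i],
           distance_km = config$sites$distance_km[i])),
    varieties = as.list(config$varieties),
    cv_noise = config$cv_noise,
    n_replicates = config$n_replicates,
    elements = stats::setNames(lapply(config$elements, function(e)
      list(source = unname(config$source_strength[[e]]),
           decay = unname(config$decay_rate[[e]]),
           partition = as.numeric(config$partition[[e]]),
           depth_slope = unname(config$depth_slope[[e]]),
           loq = unname(config$loq[[e]]))), config$elements))
  yaml::write_yaml(y, path)
  invisible(path)
}
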