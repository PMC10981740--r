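#' Read an occurrence table
#'
#' CSV with columns `longitude,latitude,year`.
#'
#' @param path CSV file path.
#' @return validated occurrence data.frame.
#' @export
read_occurrences <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_occurrences(x)
}

#' Validate occurrence records
#'
#' @param x data.frame with `longitude`, `latitude`, `year`.
#' @return `x` validated.
#' @export
validate_occurrences <- function(x) {
  need <- c("longitude", "latitude", "year")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("occurrence table missing columns: ", paste(miss, collapse = ", "))
  if (any(abs(x$longitude) > 180) || any(abs(x$latitude) > 90))
    stop("occurrence coordinates out of range")
  x
}

#' Spatially thin occurrence records
#'
#' Greedy single pass in stable input order: a record is kept iff no
#' previously kept record lies within `min_dist` (planar distance in
#' decimal degrees). Deterministic; idempotent.
#'
#' @param occ occurrence data.frame.
#' @param min_dist thinning distance in degrees (default 0.0083, about
#'   30 arc seconds at low latitudes).
#' @return thinned occurrence data.frame.
#' @export
thin_occurrences <- function(occ, min_dist = 0.0083) {
  occ <- validate_occurrences(occ)
  n <- nrow(occ)
  if (n == 0) stop("cannot thin an empty occurrence set")
  keep <- logical(n)
  kx <- numeric(0); ky <- numeric(0)
  for (i in seq_len(n)) {
    if (!length(kx) ||
        all((occ$longitude[i] - kx)^2 + (occ$latitude[i] - ky)^2 >= min_dist^2)) {
      keep[i] <- TRUE
      kx <- c(kx, occ$longitude[i]); ky <- c(ky, occ$latitude[i])
    }
  }
  occ[keep, , drop = FALSE]
}

#' Filter variables by pairwise Pearson correlation
#'
#' Iterates variables in input (column) order; a variable is retained iff
#' its absolute Pearson correlation with every already-retained variable is
#' below `cutoff`. Zero-variance variables are excluded with a warning.
#'
#' @param env_matrix numeric matrix or data.frame (columns = variables).
#' @param cutoff absolute-correlation cutoff (default 0.8); variables with
#'   |r| >= cutoff against a retained variable are dropped.
#' @return character vector of retained variable names.
#' @export
filter_variables_by_correlation <- function(env_matrix, cutoff = 0.8) {
  m <- as.matrix(env_matrix)
  if (nrow(m) < 2) stop("need at least 2 observations per variable")
  vars <- colnames(m)
  if (is.null(vars)) vars <- paste0("V", seq_len(ncol(m)))
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0)) {
    warning("zero-variance variable(s) excluded: ",
            paste(vars[sds == 0], collapse = ", "))
  }
  retained <- character(0)
  for (j in seq_along(vars)) {
    if (sds[j] == 0) next
    if (!length(retained)) { retained <- vars[j]; next }
    rr <- abs(stats::cor(m[, j], m[, retained, drop = FALSE]))
    if (all(rr < cutoff)) retained <- c(retained, vars[j])
  }
  retained
}

#' Extract year-matched environmental values at occurrence records
#'
#' For each record, samples every environmental layer of that record's year
#' at the record's cell. Records falling on NoData cells or outside the grid
#' extent are dropped, with the count reported as an attribute.
#'
#' @param occ occurrence data.frame.
#' @param yearly_stacks named list: `yearly_stacks[["1990"]]` is itself a
#'   named list of `grid_raster` layers (one per variable) for that year.
#' @return matrix with one row per retained record and one column per
#'   variable; attributes `dropped` (count) and `occ` (the retained records).
#' @export
extract_time_specific_env <- function(occ, yearly_stacks) {
  occ <- validate_occurrences(occ)
  yrs <- as.character(occ$year)
  missing_years <- setdiff(unique(yrs), names(yearly_stacks))
  if (length(missing_years))
    stop("no environmental layers for year(s): ",
         paste(missing_years, collapse = ", "))
  vars <- names(yearly_stacks[[1]])
  out <- matrix(NA_real_, nrow = nrow(occ), ncol = length(vars),
                dimnames = list(NULL, vars))
  for (i in seq_len(nrow(occ))) {
    stack <- yearly_stacks[[yrs[i]]]
    for (v in vars) {
      cell <- cell_from_xy(stack[[v]], occ$longitude[i], occ$latitude[i])
      if (!is.na(cell)) out[i, v] <- stack[[v]]$values[cell]
    }
  }
  ok <- stats::complete.cases(out)
  res <- out[ok, , drop = FALSE]
  attr(res, "dropped") <- sum(!ok)
  attr(res, "occ") <- occ[ok, , drop = FALSE]
  res
}

#' Fit an ellipsoid niche model in environmental space
#'
#' Default mode: centroid = column means, shape = sample covariance, with
#' suitability(x) = exp(-D^2(x) / 2) where D^2 is the Mahalanobis distance —
#' maximum suitability 1 at the centroid, decreasing towards the periphery.
#' `method = "mve"` uses the classic minimum-volume-ellipsoid estimator
#' ([MASS::cov.mve]) for a robust centroid/shape.
#'
#' @param env_matrix numeric matrix of environmental values at calibration
#'   records (rows > columns).
#' @param method `"covariance"` (default) or `"mve"`.
#' @param seed used only by the stochastic MVE search.
#' @return object of class `ellipsoid_niche` with `centroid`, `covariance`,
#'   `vars`.
#' @export
fit_ellipsoid <- function(env_matrix, method = c("covariance", "mve"),
                          seed = NULL) {
  method <- match.arg(method)
  m <- as.matrix(env_matrix)
  if (!all(is.finite(m))) stop("environmental matrix contains non-finite values")
  if (nrow(m) <= ncol(m))
    stop("need more records than variables to fit an ellipsoid")
  if (method == "covariance") {
    centroid <- colMeans(m)
    covariance <- stats::cov(m)
  } else {
    if (!is.null(seed)) set.seed(seed)
    mve <- MASS::cov.mve(m)
    centroid <- mve$center
    covariance <- mve$cov
  }
  ev <- eigen(covariance, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-12 * max(ev))
    stop("singular covariance: reduce or decorrelate the variables before fitting")
  structure(
    list(centroid = centroid, covariance = covariance,
         vars = colnames(m), method = method),
    class = "ellipsoid_niche"
  )
}

#' Ellipsoid suitability of environmental points
#'
#' exp(-Mahalanobis D^2 / 2): 1 at the centroid, strictly decreasing with
#' distance from it.
#'
#' @param niche an `ellipsoid_niche`.
#' @param env numeric matrix (or vector for a single point) of environmental
#'   values, columns matching the fitted variables.
#' @return numeric suitabilities in (0, 1].
#' @export
niche_suitability <- function(niche, env) {
  stopifnot(inherits(niche, "ellipsoid_niche"))
  if (is.null(dim(env))) env <- matrix(env, nrow = 1)
  d2 <- stats::mahalanobis(env, niche$centroid, niche$covariance)
  exp(-d2 / 2)
}

#' Suitability raster from environmental layers
#'
#' @param niche an `ellipsoid_niche`.
#' @param layers named list of co-registered `grid_raster` layers covering
#'   the fitted variables.
#' @return `grid_raster` of suitabilities (NoData propagated).
#' @export
suitability_raster <- function(niche, layers) {
  vars <- niche$vars
  if (is.null(vars)) vars <- names(layers)
  base <- layers[[vars[1]]]
  for (v in vars[-1]) stop_if_misaligned(base, layers[[v]], "environmental layers")
  env <- sapply(vars, function(v) as.vector(layers[[v]]$values))
  env <- matrix(env, ncol = length(vars), dimnames = list(NULL, vars))
  ok <- stats::complete.cases(env)
  suit <- rep(NA_real_, nrow(env))
  if (any(ok)) suit[ok] <- niche_suitability(niche, env[ok, , drop = FALSE])
  grid_raster(matrix(suit, nrow = nrow(base$values)),
              base$xll, base$yll, base$cellsize, base$crs)
}

#' Percentile threshold of calibration suitabilities
#'
#' Linear-interpolation percentile (R quantile type 7) of the suitability
#' values at the calibration records; the conventional "10th percentile"
#' presence threshold.
#'
#' @param calibration_suit numeric vector of suitabilities at calibration
#'   records (>= 10 values).
#' @param percentile percentile in (0, 1); default 0.10.
#' @return threshold value.
#' @export
suitability_threshold <- function(calibration_suit, percentile = 0.10) {
  if (length(calibration_suit) < 10)
    stop("need at least 10 calibration suitability values for the percentile threshold")
  unname(stats::quantile(calibration_suit, percentile, type = 7, names = FALSE))
}

#' Binarize a suitability raster at a percentile threshold
#'
#' A cell is predicted present (1) iff its suitability is >= the 10th
#' percentile (by default) of the calibration-record suitabilities; NoData
#' is preserved.
#'
#' @param niche an `ellipsoid_niche` (carried for provenance only).
#' @param calibration_suit suitabilities at the calibration records.
#' @param raster `grid_raster` of suitabilities.
#' @param percentile threshold percentile, default 0.10.
#' @return list: `raster` (binary `grid_raster`) and `threshold`.
#' @export
binarize <- function(niche, calibration_suit, raster, percentile = 0.10) {
  thr <- suitability_threshold(calibration_suit, percentile)
  v <- raster$values
  b <- ifelse(is.na(v), NA_real_, as.numeric(v >= thr))
  list(raster = grid_raster(b, raster$xll, raster$yll,
                            raster$cellsize, raster$crs),
       threshold = thr)
}

#' Split occurrences into calibration and validation sets
#'
#' Seeded random partition (70/30 by default).
#'
#' @param occ occurrence data.frame.
#' @param frac calibration fraction, default 0.7.
#' @param seed RNG seed for the shuffle.
#' @return list with `train` and `test` data.frames.
#' @export
split_occurrences <- function(occ, frac = 0.7, seed = 1L) {
  occ <- validate_occurrences(occ)
  set.seed(seed)
  n <- nrow(occ)
  idx <- sample.int(n)
  n_train <- max(1L, round(frac * n))
  list(train = occ[sort(idx[seq_len(n_train)]), , drop = FALSE],
       test = occ[sort(idx[-seq_len(n_train)]), , drop = FALSE])
}

# Partial AUC of the sensitivity vs proportion-of-area curve restricted to
# sensitivity >= 1 - E, plus the same area under the null (diagonal) line.
partial_auc_pair <- function(area_frac, sens, E) {
  # area_frac and sens are evaluated on a shared descending-threshold grid:
  # both non-decreasing as the threshold drops. E = 0 disables truncation
  # (full curve, classic AUC ratio).
  keep <- if (E <= 0) rep(TRUE, length(sens)) else sens >= (1 - E) - 1e-12
  if (sum(keep) < 2) return(c(model = NA_real_, null = NA_real_))
  x <- area_frac[keep]; y <- sens[keep]
  o <- order(x)
  x <- x[o]; y <- y[o]
  dx <- diff(x)
  model <- sum(dx * (y[-1] + y[-length(y)]) / 2)
  null <- sum(dx * (x[-1] + x[-length(x)]) / 2)
  c(model = model, null = null)
}

#' Partial ROC test of a suitability model
#'
#' Bootstrap partial-ROC evaluation: the curve of sensitivity
#' (1 - omission of test records) against the proportion of the background
#' predicted present is integrated over the high-sensitivity region
#' (sensitivity >= 1 - E), and compared with the area under the random
#' (diagonal) expectation over the same region. Each iteration bootstraps a
#' fraction of the test records; the AUC ratio is model/null, and the
#' p-value is the fraction of iterations with ratio <= 1.
#'
#' @param suitability `grid_raster` of suitabilities (the background).
#' @param test_occ test occurrence data.frame.
#' @param E omission tolerance defining the truncation (default 0.10;
#'   the curve is integrated where sensitivity >= 1 - E); E = 0 disables
#'   truncation and integrates the full curve (classic AUC ratio).
#' @param iterations bootstrap iterations (default 1000).
#' @param bootstrap_frac fraction of test points per iteration (default 0.5).
#' @param background_n background sample size (default 50000; sampled with
#'   replacement if the raster has fewer finite cells).
#' @param seed RNG seed.
#' @return list: `auc_ratio_mean`, `p_value`, `ratios`, `degenerate` flag.
#' @export
partial_roc <- function(suitability, test_occ, E = 0.10, iterations = 1000L,
                        bootstrap_frac = 0.5, background_n = 50000L,
                        seed = 1L) {
  bg_all <- as.vector(suitability$values)
  bg_all <- bg_all[is.finite(bg_all)]
  if (!length(bg_all)) stop("suitability raster has no finite cells")
  set.seed(seed)
  bg <- if (length(bg_all) >= background_n) {
    sample(bg_all, background_n)
  } else {
    sample(bg_all, background_n, replace = TRUE)
  }
  degenerate <- stats::var(bg) == 0
  cells <- cell_from_xy(suitability, test_occ$longitude, test_occ$latitude)
  if (anyNA(cells)) stop("test occurrences outside the raster extent")
  s_test <- suitability$values[cells]
  if (anyNA(s_test)) stop("test occurrences on NoData cells")
  if (length(s_test) < 10) stop("need at least 10 test points for partial ROC")
  # descending-threshold grid from background quantiles
  th <- sort(unique(stats::quantile(bg, probs = seq(0, 1, by = 0.005),
                                    type = 7, names = FALSE)),
             decreasing = TRUE)
  # area fraction predicted present at each threshold (non-decreasing)
  area_frac <- vapply(th, function(t) mean(bg >= t), numeric(1))
  n_boot <- max(2L, round(bootstrap_frac * length(s_test)))
  ratios <- numeric(iterations)
  for (it in seq_len(iterations)) {
    sb <- sample(s_test, n_boot, replace = TRUE)
    sens <- vapply(th, function(t) mean(sb >= t), numeric(1))
    pa <- partial_auc_pair(area_frac, sens, E)
    ratios[it] <- if (is.na(pa["model"]) || pa["null"] <= 0) NA_real_
      else pa["model"] / pa["null"]
  }
  ratios <- ratios[is.finite(ratios)]
  if (degenerate) {
    warning("constant suitability raster: partial ROC ratio is 1 by construction")
    ratios <- rep(1, iterations)
  }
  list(auc_ratio_mean = mean(ratios),
       p_value = mean(ratios <= 1),
       ratios = ratios,
       degenerate = degenerate)
}

#' Omission, prevalence and binomial significance of a binary model
#'
#' Omission = fraction of records on absence (0) cells; background
#' prevalence = suitable cells / finite cells; binomial test of observing at
#' least the attained number of test-record hits if records fell on suitable
#' cells with probability equal to the prevalence.
#'
#' @param binary binary `grid_raster` (0/1, NoData allowed).
#' @param train_occ,test_occ occurrence data.frames.
#' @return list of class `niche_evaluation`: `omission_train`,
#'   `omission_test`, `omission_mean`, `prevalence`, `binomial_p`,
#'   `n_train`, `n_test`.
#' @export
evaluate_binary_model <- function(binary, train_occ, test_occ) {
  v <- as.vector(binary$values)
  fin <- is.finite(v)
  if (!any(fin)) stop("binary raster has no finite cells")
  prevalence <- sum(v[fin] >= 1) / sum(fin)
  omit <- function(occ) {
    cells <- cell_from_xy(binary, occ$longitude, occ$latitude)
    if (anyNA(cells)) stop("occurrences outside the raster extent")
    vals <- binary$values[cells]
    if (anyNA(vals)) stop("occurrences on NoData cells")
    mean(vals < 1)
  }
  om_tr <- omit(train_occ)
  om_te <- omit(test_occ)
  n_test <- nrow(test_occ)
  hits <- round((1 - om_te) * n_test)
  binom_p <- stats::pbinom(hits - 1, n_test, prevalence, lower.tail = FALSE)
  structure(
    list(omission_train = om_tr, omission_test = om_te,
         omission_mean = (om_tr + om_te) / 2,
         prevalence = prevalence, binomial_p = binom_p,
         n_train = nrow(train_occ), n_test = n_test),
    class = "niche_evaluation"
  )
}

#' @export
print.niche_evaluation <- function(x, ...) {
  cat(sprintf(
    paste0("Niche model evaluation\n",
           "  omission (train): %.3f   omission (test): %.3f   mean: %.3f\n",
           "  background prevalence: %.3f\n",
           "  binomial test P(X >= hits): %.4g  (n_test = %d)\n"),
    x$omission_train, x$omission_test, x$omission_mean,
    x$prevalence, x$binomial_p, x$n_test))
  invisible(x)
}
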