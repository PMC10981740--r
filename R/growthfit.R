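#' Thermal growth-rate function objects
#'
#' The intrinsic growth rate is modelled as a convex-exponent thermal
#' performance curve
#' \deqn{r(T) = r_{max} / \exp(v_0 (T - T_{opt})^2 - v_0 (T - T_{opt}))}
#' with maximum rate parameter `r_max` (per day), kurtosis / niche-breadth
#' parameter `v_0` (> 0), and optimum-temperature parameter `T_opt` (°C).
#' Note the exponent vanishes at both T = T_opt and T = T_opt + 1, so the
#' curve's literal maximum sits at T_opt + 1/2 with value r_max * exp(v_0/4);
#' see [growth_curve_maximum()].
#'
#' @param r_max maximum intrinsic growth rate parameter, per day (> 0).
#' @param v_0 positive kurtosis parameter.
#' @param t_opt optimum-temperature parameter, °C.
#' @param se optional named numeric vector of standard errors
#'   (`r_max`, `v_0`, `t_opt`).
#' @param residual_se optional residual standard error of the fit.
#' @param df optional residual degrees of freedom.
#' @return an object of class `growth_model`.
#' @export
growth_model <- function(r_max, v_0, t_opt, se = NULL,
                         residual_se = NULL, df = NULL) {
  stopifnot(r_max > 0, v_0 > 0, is.finite(t_opt))
  structure(
    list(r_max = r_max, v_0 = v_0, t_opt = t_opt,
         se = se, residual_se = residual_se, df = df),
    class = "growth_model"
  )
}

#' @export
print.growth_model <- function(x, ...) {
  cat("Thermal growth-rate curve r(T) = r_max * exp(-v_0*(T-T_opt)^2 + v_0*(T-T_opt))\n")
  est <- c(r_max = x$r_max, v_0 = x$v_0, t_opt = x$t_opt)
  tab <- data.frame(Estimate = est)
  if (!is.null(x$se)) tab$`Std. Error` <- x$se[names(est)]
  print(tab)
  if (!is.null(x$residual_se))
    cat(sprintf("Residual standard error %.5g on %d degrees of freedom\n",
                x$residual_se, x$df))
  invisible(x)
}

#' Evaluate the thermal growth curve
#'
#' @param model a `growth_model`.
#' @param T temperature(s), °C; vectorized.
#' @return intrinsic growth rate(s), per day (strictly positive).
#' @export
evaluate_growth <- function(model, T) {
  stopifnot(inherits(model, "growth_model"))
  u <- T - model$t_opt
  model$r_max * exp(-model$v_0 * u^2 + model$v_0 * u)
}

#' Fit the thermal growth curve to (temperature, r) points
#'
#' Levenberg–Marquardt nonlinear least squares (via [minpack.lm::nls.lm])
#' on the convex-exponent curve. Positivity of `v_0` is enforced by fitting
#' on the log scale; its standard error is recovered by the delta method.
#' Asymptotic standard errors come from the Jacobian at the solution,
#' residual variance with n - 3 degrees of freedom.
#'
#' @param points data.frame with columns `temperature` and `r` (finite).
#' @param init optional named list of starting values (`r_max`, `v_0`,
#'   `t_opt`). By default the fit starts at the temperature with the highest
#'   mean response and runs a short deterministic multi-start over
#'   `v_0` in {0.01, 0.05, 0.2}, keeping the lowest-deviance converged fit.
#' @param maxiter maximum LM iterations.
#' @param ptol convergence tolerance on the parameter step.
#' @return a fitted `growth_model` carrying standard errors, residual SE,
#'   degrees of freedom, and the data (`points`) for fit statistics.
#' @export
fit_growth_function <- function(points, init = NULL,
                                maxiter = 1000L, ptol = 1e-10) {
  if (!all(c("temperature", "r") %in% names(points))) {
    if (ncol(points) >= 2) names(points)[1:2] <- c("temperature", "r")
    else stop("points must have columns temperature, r")
  }
  points <- points[is.finite(points$r), , drop = FALSE]
  T <- points$temperature; r <- points$r
  if (length(unique(T)) < 3)
    stop("need at least 3 distinct temperatures to fit the growth curve")
  n <- length(r)
  resid_fn <- function(par) {
    u <- T - par[["t_opt"]]
    r - exp(par[["log_r_max"]]) * exp(exp(par[["log_v_0"]]) * (u - u^2))
  }
  run_lm <- function(init) {
    rm0 <- max(init$r_max, 1e-3)
    par0 <- c(log_r_max = log(rm0), log_v_0 = log(init$v_0),
              t_opt = init$t_opt)
    tryCatch(minpack.lm::nls.lm(
      par = par0, fn = resid_fn,
      control = minpack.lm::nls.lm.control(
        maxiter = maxiter, ptol = ptol, ftol = ptol)),
      error = function(e) NULL)
  }
  if (!is.null(init)) {
    if (is.null(init$v_0)) init$v_0 <- 0.05
    starts <- list(init)
  } else {
    # initialize at the temperature with the highest mean response; a short
    # deterministic multi-start over the breadth parameter guards against
    # local optima when the warm tail is noisy
    mu <- tapply(r, T, mean)
    t0 <- as.numeric(names(mu))[which.max(mu)]
    r0 <- max(mu)
    starts <- lapply(c(0.01, 0.05, 0.2),
                     function(v) list(r_max = r0, v_0 = v, t_opt = t0))
  }
  fits <- Filter(function(f) !is.null(f) && !(f$info %in% c(0, 9)),
                 lapply(starts, run_lm))
  if (!length(fits))
    stop("growth-curve fit failed to converge from any starting value")
  fit <- fits[[which.min(vapply(fits, function(f) f$deviance, numeric(1)))]]
  if (fit$info == 5) {
    stop("growth-curve fit failed to converge (", fit$message,
         "); last iterate: r_max=", exp(fit$par[["log_r_max"]]),
         ", v_0=", exp(fit$par[["log_v_0"]]),
         ", t_opt=", fit$par[["t_opt"]])
  }
  est_t <- unlist(fit$par)
  r_max <- exp(est_t[["log_r_max"]])
  v_0 <- exp(est_t[["log_v_0"]])
  t_opt <- est_t[["t_opt"]]
  df <- n - 3L
  if (df <= 0) stop("not enough points for standard errors (need n > 3)")
  sigma2 <- fit$deviance / df
  cov_t <- tryCatch(sigma2 * solve(fit$hessian), error = function(e) NULL)
  if (is.null(cov_t)) {
    warning("singular Jacobian at the solution; standard errors unavailable ",
            "(degenerate design, e.g. constant r data drives v_0 to its bound)")
    se <- c(r_max = NA_real_, v_0 = NA_real_, t_opt = NA_real_)
  } else {
    se_t <- sqrt(pmax(diag(cov_t), 0))
    # delta method back from the log scale
    se <- c(r_max = r_max * se_t[["log_r_max"]],
            v_0 = v_0 * se_t[["log_v_0"]],
            t_opt = se_t[["t_opt"]])
  }
  m <- growth_model(r_max, v_0, t_opt, se = se,
                    residual_se = sqrt(sigma2), df = df)
  m$points <- points
  m$niter <- fit$niter
  m
}

#' Analytic maximum of the growth curve
#'
#' The exponent -v_0 u^2 + v_0 u (u = T - T_opt) has roots at u = 0 and
#' u = 1 and peaks at u = 1/2, so the curve's maximum is at
#' T* = T_opt + 1/2 with value r* = r_max * exp(v_0 / 4). Exposed as a
#' diagnostic because the parameter named "optimum temperature" is not the
#' literal argmax of the curve as written.
#'
#' @param model a `growth_model`.
#' @return list with `T_star` and `r_star`.
#' @export
growth_curve_maximum <- function(model) {
  stopifnot(inherits(model, "growth_model"))
  list(T_star = model$t_opt + 0.5,
       r_star = model$r_max * exp(model$v_0 / 4))
}

#' Fit statistics for a growth-curve fit
#'
#' Coefficient of determination R^2 = 1 - SSR/SST, per-parameter
#' t-statistics estimate/SE and two-sided p-values on n - 3 degrees of
#' freedom.
#'
#' @param model fitted `growth_model` (with SEs).
#' @param points optional data.frame `temperature, r`; defaults to the data
#'   stored in the model.
#' @return list with `r_squared` and a data.frame `coefficients`
#'   (estimate, se, t, p).
#' @export
fit_statistics <- function(model, points = NULL) {
  stopifnot(inherits(model, "growth_model"))
  if (is.null(points)) points <- model$points
  if (is.null(points)) stop("no data available for fit statistics")
  r <- points$r
  if (stats::var(r) == 0) stop("R^2 undefined: zero variance in r")
  pred <- evaluate_growth(model, points$temperature)
  ssr <- sum((r - pred)^2)
  sst <- sum((r - mean(r))^2)
  est <- c(r_max = model$r_max, v_0 = model$v_0, t_opt = model$t_opt)
  se <- model$se[names(est)]
  tval <- ifelse(est == 0, 0, est / se)
  df <- if (!is.null(model$df)) model$df else length(r) - 3L
  pval <- 2 * stats::pt(abs(tval), df = df, lower.tail = FALSE)
  list(
    r_squared = 1 - ssr / sst,
    coefficients = data.frame(
      parameter = names(est), estimate = unname(est), se = unname(se),
      t = unname(tval), p = unname(pval))
  )
}

#' Serialize a growth model to JSON
#'
#' @param model fitted `growth_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_growth_model <- function(model, path) {
  x <- list(r_max = model$r_max, v_0 = model$v_0, t_opt = model$t_opt,
            se = as.list(model$se), residual_se = model$residual_se,
            df = model$df)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a growth model from JSON
#'
#' @param path JSON path written by [write_growth_model()].
#' @return a `growth_model`.
#' @export
read_growth_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  growth_model(x$r_max, x$v_0, x$t_opt,
               se = unlist(x$se), residual_se = x$residual_se, df = x$df)
}
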